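#' Read and write truth-panel TSV files
#'
#' The truth-panel interchange format: a tab-separated table with header
#' columns `chrom`, `pos`, `ref`, `alt`, `vtype`, `truth_gt`, `aaf`,
#' `on_array`, `call_rate`, `hwe_p`, `maf`, `multi_allelic`.
#'
#' @param truth Truth catalog data.frame (see [generate_truth()]).
#' @param path File path.
#' @return `read_truth_tsv` returns the data.frame; `write_truth_tsv`
#'   returns `path` invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  need <- c("chrom", "pos", "ref", "alt", "vtype", "truth_gt", "aaf", "on_array")
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("truth TSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

GT_TO_VCF <- c(RR = "0/0", RA = "0/1", AA = "1/1")
VCF_TO_GT <- c(`0/0` = "RR", `0/1` = "RA", `1/0` = "RA", `1/1` = "AA",
               `0|0` = "RR", `0|1` = "RA", `1|0` = "RA", `1|1` = "AA")

#' Write a call set as minimal VCF 4.2
#'
#' One sample column (`GT:DP`), INFO keys `DP` plus the seven filtration
#' annotations (absent annotations are omitted from INFO, as real callers
#' do for undefined rank sums), and the FILTER column as `PASS`,
#' semicolon-joined failed item names, or `.` when unfiltered. Output is
#' deterministic text: identical call sets produce byte-identical files.
#'
#' @param callset A `wgs_callset` or records data.frame.
#' @param path Output path (plain text).
#' @param sample_name Sample column header.
#' @param contig_length Declared contig length (defaults to the accounting
#'   ledger's reference length when available).
#' @return `path`, invisibly.
#' @export
write_callset_vcf <- function(callset, path, sample_name = "SAMPLE",
                              contig_length = NULL) {
  rec <- as_records(callset)
  if (is.null(contig_length) && inherits(callset, "wgs_callset")) {
    contig_length <- callset$read_accounting$effective_ref_length
  }
  contig_length <- contig_length %||% 2.86e9
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=depthconcord",
    sprintf("##contig=<ID=1,length=%.0f>", contig_length),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand phred score\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Strand odds ratio\">",
    "##INFO=<ID=HaplotypeScore,Number=1,Type=Float,Description=\"Haplotype count score\">",
    "##FILTER=<ID=QD,Description=\"QD below threshold\">",
    "##FILTER=<ID=FS,Description=\"FS above threshold\">",
    "##FILTER=<ID=MQ,Description=\"MQ below threshold\">",
    "##FILTER=<ID=MQRankSum,Description=\"MQRankSum below threshold\">",
    "##FILTER=<ID=ReadPosRankSum,Description=\"ReadPosRankSum below threshold\">",
    "##FILTER=<ID=SOR,Description=\"SOR above threshold\">",
    "##FILTER=<ID=HaplotypeScore,Description=\"HaplotypeScore above threshold\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  body <- if (nrow(rec)) {
    info <- vapply(seq_len(nrow(rec)), function(i) {
      parts <- c(sprintf("DP=%d", as.integer(rec$dp[i])))
      for (item in ANNOTATION_ITEMS) {
        v <- rec[[item]][i]
        if (!is.null(v) && !is.na(v)) {
          parts <- c(parts, sprintf("%s=%.3f", item, v))
        }
      }
      paste(parts, collapse = ";")
    }, character(1))
    filt <- rec$filter %||% rep(".", nrow(rec))
    paste(rec$chrom, rec$pos, ".", rec$ref, rec$alt, ".", filt, info,
          "GT:DP", paste0(GT_TO_VCF[rec$gt], ":", as.integer(rec$dp)),
          sep = "\t")
  } else {
    character(0)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a minimal VCF 4.2 call set
#'
#' Parses a plain-text VCF into the package's call-record layout via
#' \pkg{vcfR}. The genotype is taken from the first sample's `GT`; `DP` and
#' the seven filtration annotations come from INFO (absent keys become
#' `NA`); variant type is inferred from the allele lengths (multi-allelic
#' ALT entries are typed from their first allele and retain the full ALT
#' string for downstream exclusion).
#'
#' @param path VCF file path.
#' @return A call-record data.frame (`chrom`, `pos`, `ref`, `alt`, `gt`,
#'   `dp`, annotation columns, `vtype`, `filter`).
#' @export
read_callset_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(empty_records())
  }
  gt_raw <- vcfR::extract.gt(v, element = "GT")[, 1]
  gt <- unname(VCF_TO_GT[gt_raw])
  dp <- suppressWarnings(as.integer(vcfR::extract.info(v, element = "DP")))
  ann <- lapply(ANNOTATION_ITEMS, function(item) {
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = item)))
  })
  names(ann) <- ANNOTATION_ITEMS
  first_alt <- sub(",.*$", "", fix$ALT)
  vtype <- ifelse(nchar(fix$REF) == 1L & nchar(first_alt) == 1L, "SNV", "indel")
  filt <- fix$FILTER
  filt[is.na(filt)] <- "."
  out <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT, gt = gt, dp = dp,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(ann))
  out$vtype <- vtype
  out$filter <- filt
  out
}

empty_records <- function() {
  out <- data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                    alt = character(0), gt = character(0), dp = integer(0),
                    stringsAsFactors = FALSE)
  for (item in ANNOTATION_ITEMS) out[[item]] <- numeric(0)
  out$vtype <- character(0)
  out$filter <- character(0)
  out
}

#' Read and write HLA genotype TSV tables
#'
#' Tab-separated (`tool`, `gene`, `allele1`, `allele2`) with `NA` for
#' unavailable (tool, gene) pairs; the truth table omits the `tool` column.
#'
#' @param calls HLA call data.frame.
#' @param path File path.
#' @return `read_hla_tsv` returns the data.frame; `write_hla_tsv` returns
#'   `path` invisibly.
#' @export
write_hla_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_hla_tsv
#' @export
read_hla_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("gene", "allele1", "allele2")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("HLA TSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$allele1[df$allele1 == "NA"] <- NA_character_
  df$allele2[df$allele2 == "NA"] <- NA_character_
  df
}
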