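#' QC-filter the microarray truth panel
#'
#' Restricts a truth catalog to the on-array evaluation panel, applying the
#' array-side QC exclusions: call rate < 0.99, Hardy-Weinberg p < 1e-6,
#' MAF < 0.01, and multi-allelic variants are removed. On-array variants
#' with missing QC metadata are rejected per-variant with a logged reason
#' (a message naming the count).
#'
#' @param panel Truth catalog data.frame (see [generate_truth()]).
#' @return The retained on-array truth variants.
#' @examples
#' truth <- generate_truth(sim_config(n_variants = 2000, base_seed = 2))
#' nrow(qc_filter_truth(truth))
#' @export
qc_filter_truth <- function(panel) {
  stopifnot(is.data.frame(panel))
  onarr <- panel[isTRUE_v(panel$on_array), , drop = FALSE]
  meta_ok <- !is.na(onarr$call_rate) & !is.na(onarr$hwe_p) &
    !is.na(onarr$maf) & !is.na(onarr$multi_allelic)
  if (any(!meta_ok)) {
    message(sum(!meta_ok), " on-array variant(s) rejected: missing QC metadata")
  }
  onarr <- onarr[meta_ok, , drop = FALSE]
  keep <- onarr$call_rate >= 0.99 & onarr$hwe_p >= 1e-6 &
    onarr$maf >= 0.01 & !onarr$multi_allelic
  out <- onarr[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

isTRUE_v <- function(x) !is.na(x) & x

#' Classify one truth site against its call
#'
#' The cell assignment behind the concordance matrix. An absent call is a
#' hom-ref call (sites not in the VCF are assessed as reference/reference);
#' a call sharing the truth alternate allele lands in the
#' (truth genotype, call genotype) cell; a non-reference call with a
#' different alternate allele is alt-discordant (a false positive).
#'
#' @param truth_gt Truth genotype, one of `"RR"`, `"RA"`, `"AA"`.
#' @param truth_alt Truth alternate allele string.
#' @param call_gt Call genotype or `NA` when no record exists at the site.
#' @param call_alt Call alternate allele or `NA`.
#' @return A string: `"RR/RR"`-style cell label or `"alt_discordant"`.
#' @examples
#' classify_site("RA", "C", "RA", "C")  # "RA/RA"
#' classify_site("RR", "C", NA, NA)     # "RR/RR"
#' classify_site("RA", "C", "AA", "T")  # "alt_discordant"
#' @export
classify_site <- function(truth_gt, truth_alt, call_gt, call_alt) {
  stopifnot(truth_gt %in% GENOTYPES)
  if (is.na(call_gt)) {
    call_gt <- "RR"
  } else if (call_gt != "RR" && !identical(call_alt, truth_alt)) {
    return("alt_discordant")
  }
  paste(truth_gt, call_gt, sep = "/")
}

#' Build the 3x3 genotype concordance matrix
#'
#' Crosses the truth-panel genotypes with the call-set genotypes at the same
#' sites. Sites are matched on (chrom, pos, ref); the alternate allele is
#' compared semantically, and a non-reference call whose alternate allele
#' differs from the truth allele is tallied separately as alt-discordant.
#' Panel sites with no (passing) record are called hom-ref. Multi-allelic
#' call records (comma-separated ALT) are excluded from matching and
#' counted, mirroring the array-side multi-allelic exclusion.
#'
#' @param panel QC-filtered truth panel (see [qc_filter_truth()]).
#' @param calls A filtered `wgs_callset` or records data.frame.
#' @param pass_only Use only PASS records (default); failing records are
#'   then treated as absent, matching evaluation after filtration.
#' @return A `concordance_matrix`: list with `counts` (3x3 integer matrix,
#'   truth rows x call columns), `alt_discordant`, `n_truth_sites`, and
#'   `n_multiallelic_excluded`. The nine cells plus `alt_discordant` always
#'   sum to `n_truth_sites`.
#' @export
concordance_matrix <- function(panel, calls, pass_only = TRUE) {
  stopifnot(is.data.frame(panel))
  rec <- as_records(calls)
  if (pass_only && !is.null(rec$filter)) {
    rec <- rec[rec$filter %in% c("PASS", "."), , drop = FALSE]
  }
  multi <- grepl(",", rec$alt, fixed = TRUE)
  rec <- rec[!multi, , drop = FALSE]

  idx <- match(site_key(panel$chrom, panel$pos, panel$ref),
               site_key(rec$chrom, rec$pos, rec$ref))
  call_gt <- rec$gt[idx]
  call_alt <- rec$alt[idx]
  call_gt[is.na(call_gt)] <- "RR"

  alt_disc <- call_gt != "RR" & call_alt != panel$alt
  counts <- table(factor(panel$truth_gt[!alt_disc], levels = GENOTYPES),
                  factor(call_gt[!alt_disc], levels = GENOTYPES))
  counts <- matrix(as.integer(counts), 3, 3, dimnames = list(
    truth = GENOTYPES, call = GENOTYPES))

  structure(list(counts = counts,
                 alt_discordant = sum(alt_disc),
                 n_truth_sites = nrow(panel),
                 n_multiallelic_excluded = sum(multi)),
            class = "concordance_matrix")
}

#' @export
print.concordance_matrix <- function(x, ...) {
  cat(sprintf("<concordance_matrix> %d truth sites, %d alt-discordant, %d multi-allelic excluded\n",
              x$n_truth_sites, x$alt_discordant, x$n_multiallelic_excluded))
  print(x$counts)
  invisible(x)
}

#' Concordance metrics from the 3x3 matrix
#'
#' * CR: concordant genotypes (matrix diagonal) over all truth sites.
#' * FPR: truth hom-ref sites called non-reference, plus alt-discordant
#'   sites, over all truth sites.
#' * FNR: truth non-reference sites called hom-ref, over all truth sites.
#' * NTPR: concordant non-reference calls over truth sites where the call
#'   set made any non-reference call (including alt-discordant); `NA` when
#'   no non-reference call exists.
#'
#' @param m A `concordance_matrix`.
#' @return Data.frame with columns `cr`, `fpr`, `fnr`, `ntpr` (proportions),
#'   and `n` (truth sites).
#' @examples
#' counts <- matrix(0, 3, 3, dimnames = list(c("RR","RA","AA"), c("RR","RA","AA")))
#' counts["RR","RR"] <- 90; counts["RA","RA"] <- 5
#' counts["RA","RR"] <- 3;  counts["RR","RA"] <- 1
#' m <- structure(list(counts = counts, alt_discordant = 1, n_truth_sites = 100),
#'                class = "concordance_matrix")
#' compute_metrics(m)  # cr 0.95, fpr 0.02, fnr 0.03, ntpr 5/7
#' @export
compute_metrics <- function(m) {
  stopifnot(inherits(m, "concordance_matrix"))
  n <- m$n_truth_sites
  if (n == 0L) stop("empty truth panel: metrics undefined", call. = FALSE)
  cm <- m$counts
  cr <- sum(diag(cm)) / n
  fpr <- (cm["RR", "RA"] + cm["RR", "AA"] + m$alt_discordant) / n
  fnr <- (cm["RA", "RR"] + cm["AA", "RR"]) / n
  ntpr_num <- cm["RA", "RA"] + cm["AA", "AA"]
  ntpr_den <- sum(cm[, c("RA", "AA")]) + m$alt_discordant
  ntpr <- if (ntpr_den == 0) NA_real_ else ntpr_num / ntpr_den
  data.frame(cr = cr, fpr = fpr, fnr = fnr, ntpr = ntpr, n = n)
}

#' Heterozygote-only concordance rate
#'
#' CR restricted to truth heterozygous sites: the (RA, RA) cell over the
#' truth-RA row of the matrix. Heterozygotes are the genotypes most
#' vulnerable to allele dropout, so their CR lags the overall CR at low
#' depth.
#'
#' @param m A `concordance_matrix`.
#' @return Proportion (`NA` when the panel has no heterozygous truth site).
#' @export
het_only_cr <- function(m) {
  stopifnot(inherits(m, "concordance_matrix"))
  den <- sum(m$counts["RA", ])
  if (den == 0) NA_real_ else m$counts["RA", "RA"] / den
}

#' Alternate-allele-frequency bin labels
#'
#' The five AAF strata: `>=0.5`, `0.1-0.5`, `0.05-0.1`, `0.01-0.05`,
#' `<0.01`. Bins are half-open on the low side; 0.5 belongs to `>=0.5`.
#'
#' @param aaf Numeric vector of frequencies in \[0, 1\].
#' @return Factor with the five bin labels (rarest first).
#' @examples
#' aaf_bin(c(0.3, 0.5, 0.001))
#' @export
aaf_bin <- function(aaf) {
  stopifnot(all(aaf >= 0 & aaf <= 1, na.rm = TRUE))
  cut(aaf, breaks = c(-Inf, 0.01, 0.05, 0.1, 0.5, Inf),
      labels = c("<0.01", "0.01-0.05", "0.05-0.1", "0.1-0.5", ">=0.5"),
      right = FALSE)
}

#' AAF-stratified concordance metrics
#'
#' Partitions the truth panel into the five AAF bins and computes the
#' concordance metrics within each bin.
#'
#' @param panel QC-filtered truth panel with `aaf` populated.
#' @param calls A filtered `wgs_callset` or records data.frame.
#' @param pass_only Passed through to [concordance_matrix()].
#' @return Data.frame with one row per non-empty bin: `bin`, `cr`, `fpr`,
#'   `fnr`, `ntpr`, `n`.
#' @export
stratify_by_aaf <- function(panel, calls, pass_only = TRUE) {
  stopifnot(is.data.frame(panel), !is.null(panel$aaf))
  bins <- aaf_bin(panel$aaf)
  out <- lapply(levels(bins), function(b) {
    sub <- panel[bins == b, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    met <- compute_metrics(concordance_matrix(sub, calls, pass_only = pass_only))
    cbind(data.frame(bin = b, stringsAsFactors = FALSE), met)
  })
  do.call(rbind, out)
}

#' Transition/transversion ratio
#'
#' Transitions (A<->G, C<->T) over transversions among biallelic SNV
#' records; a standard call-set quality indicator (~2.0-2.1 genome-wide in
#' humans; error-dominated call sets drift toward the random expectation of
#' 0.5). Non-SNV and multi-allelic records are skipped; the skipped count is
#' attached as attribute `"n_skipped"`.
#'
#' @param x A `wgs_callset` or records data.frame.
#' @param pass_only Use only PASS records (default TRUE).
#' @return Ts/Tv ratio (`NA` when there are no transversions, with a
#'   warning), with attributes `n_ts`, `n_tv`, `n_skipped`.
#' @examples
#' rec <- data.frame(chrom = "1", pos = 1:3, ref = c("A", "C", "A"),
#'                   alt = c("G", "T", "C"), vtype = "SNV", filter = "PASS")
#' ts_tv_ratio(rec)  # 2
#' @export
ts_tv_ratio <- function(x, pass_only = TRUE) {
  rec <- as_records(x)
  if (pass_only && !is.null(rec$filter)) {
    rec <- rec[rec$filter %in% c("PASS", "."), , drop = FALSE]
  }
  is_snv <- nchar(rec$ref) == 1L & nchar(rec$alt) == 1L &
    !grepl(",", rec$alt, fixed = TRUE)
  n_skipped <- sum(!is_snv)
  rec <- rec[is_snv, , drop = FALSE]
  pair <- paste0(rec$ref, rec$alt)
  n_ts <- sum(pair %in% c("AG", "GA", "CT", "TC"))
  n_tv <- nrow(rec) - n_ts
  ratio <- if (n_tv == 0) {
    warning("no transversions: Ts/Tv undefined", call. = FALSE)
    NA_real_
  } else {
    n_ts / n_tv
  }
  structure(ratio, n_ts = n_ts, n_tv = n_tv, n_skipped = n_skipped)
}

#' Concordance against the all-reads call set
#'
#' Uses the maximum-depth ("all reads") call set as the truth parameter: the
#' denominator is the sites of the requested variant type called (PASS) in
#' the full-depth set. For SNVs a subsampled site is concordant when its
#' genotype and alternate allele match, with absent sites assessed as
#' hom-ref (so they are discordant unless the full set called hom-ref). For
#' indels concordance requires an indel record at the same position with
#' identical ref and alt strings -- position alone is not enough.
#'
#' @param full The all-reads `wgs_callset` or records data.frame (filtered).
#' @param sub The subsampled call set to evaluate (filtered).
#' @param vtype `"SNV"` or `"indel"`.
#' @return Proportion concordant, with attribute `n` (denominator sites).
#' @export
allreads_concordance <- function(full, sub, vtype = c("SNV", "indel")) {
  vtype <- match.arg(vtype)
  f <- as_records(full)
  s <- as_records(sub)
  if (!is.null(f$filter)) f <- f[f$filter %in% c("PASS", "."), , drop = FALSE]
  if (!is.null(s$filter)) s <- s[s$filter %in% c("PASS", "."), , drop = FALSE]
  f <- f[f$vtype == vtype, , drop = FALSE]
  if (nrow(f) == 0L) {
    stop("no ", vtype, " sites in the full-depth call set", call. = FALSE)
  }
  if (vtype == "SNV") {
    idx <- match(site_key(f$chrom, f$pos, f$ref), site_key(s$chrom, s$pos, s$ref))
    sub_gt <- s$gt[idx]
    sub_alt <- s$alt[idx]
    sub_gt[is.na(sub_gt)] <- "RR"
    conc <- (sub_gt == "RR" & f$gt == "RR") |
      (sub_gt != "RR" & sub_gt == f$gt & !is.na(sub_alt) & sub_alt == f$alt)
  } else {
    s_ind <- s[s$vtype == "indel", , drop = FALSE]
    key_f <- paste(f$chrom, f$pos, f$ref, f$alt, sep = ":")
    key_s <- paste(s_ind$chrom, s_ind$pos, s_ind$ref, s_ind$alt, sep = ":")
    conc <- key_f %in% key_s
  }
  structure(mean(conc), n = nrow(f))
}

#' Count called variants by type
#'
#' @param x A filtered `wgs_callset` or records data.frame; only PASS
#'   records are counted.
#' @return List with `n_snv`, `n_indel`, `n_total`.
#' @examples
#' rec <- data.frame(vtype = c("SNV", "SNV", "indel"),
#'                   filter = c("PASS", "QD", "PASS"))
#' count_variants(rec)  # 1 SNV, 1 indel
#' @export
count_variants <- function(x) {
  rec <- as_records(x)
  if (!is.null(rec$filter)) {
    rec <- rec[rec$filter %in% c("PASS", "."), , drop = FALSE]
  }
  n_snv <- sum(rec$vtype == "SNV")
  n_indel <- sum(rec$vtype == "indel")
  list(n_snv = n_snv, n_indel = n_indel, n_total = n_snv + n_indel)
}
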