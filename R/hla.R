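#' Classical HLA genes and tool availability
#'
#' The eight classical genes typed at four-digit (two-field) resolution:
#' three class I (A, B, C) and five class II (DRB1, DQA1, DQB1, DPA1,
#' DPB1). Of the five genotyping approaches emulated, PHLAT and HLA-VBseq
#' cannot type DPA1 or DPB1; those (tool, gene) pairs are reported `NA` and
#' excluded from per-tool averages.
#'
#' @return `hla_genes()`: character vector of the eight gene labels.
#'   `hla_tools()`: character vector of the five tool labels.
#'   `hla_gene_available(tool, gene)`: logical (vectorized).
#' @examples
#' hla_gene_available("PHLAT", "DPA1")  # FALSE
#' @export
hla_genes <- function() HLA_GENES

HLA_GENES <- c("A", "B", "C", "DRB1", "DQA1", "DQB1", "DPA1", "DPB1")

#' @rdname hla_genes
#' @export
hla_tools <- function() c("PHLAT", "HLA-VBseq", "HLA-HD", "HISAT-genotype", "SNP2HLA")

#' @rdname hla_genes
#' @param tool,gene Character vectors (recycled).
#' @export
hla_gene_available <- function(tool, gene) {
  !(tool %in% c("PHLAT", "HLA-VBseq") & gene %in% c("DPA1", "DPB1"))
}

#' Default HLA truth genotypes
#'
#' The wet-lab (SSO/SBT) four-digit genotypes of the evaluated individual,
#' one unordered allele pair per classical gene. Used as the default truth
#' table for the HLA arm of the sweep.
#'
#' @return Data.frame with columns `gene`, `allele1`, `allele2`.
#' @examples
#' default_hla_truth()
#' @export
default_hla_truth <- function() {
  data.frame(
    gene = c("A", "C", "B", "DRB1", "DQA1", "DQB1", "DPA1", "DPB1"),
    allele1 = c("24:02", "01:02", "40:02", "09:01", "01:04", "03:03",
                "01:03", "02:01"),
    allele2 = c("24:02", "03:04", "40:02", "14:54", "03:02", "05:03",
                "01:03", "02:01"),
    stringsAsFactors = FALSE
  )
}

#' Normalize an HLA allele string to four-digit resolution
#'
#' Accepts `"GENE*FF:PP"` or bare `"FF:PP"` forms; fields beyond the second
#' (e.g. synonymous or intronic fields) are truncated, so `"A*24:02:01"`
#' compares equal to `"24:02"`.
#'
#' @param x Character vector of allele strings.
#' @return Character vector of `"FF:PP"` strings (`NA` passes through).
#' @examples
#' normalize_hla_allele(c("A*24:02:01", "24:02"))
#' @export
normalize_hla_allele <- function(x) {
  out <- sub("^[A-Za-z0-9-]+\\*", "", x)
  vapply(strsplit(out, ":", fixed = TRUE), function(f) {
    if (length(f) == 0L || anyNA(f)) NA_character_
    else paste(f[seq_len(min(2L, length(f)))], collapse = ":")
  }, character(1))
}

#' Score one HLA genotype call against truth
#'
#' Per-allele credit: the size of the maximum matching between the two
#' unordered allele pairs (treated as multisets), divided by 2. A fully
#' correct genotype scores 1, one correct allele scores 0.5, none scores 0;
#' truth `{X, X}` against call `{X, Y}` scores 0.5 because the second truth
#' copy of X is unmatched. Invariant under allele order in both arguments.
#'
#' @param truth,call Character vectors of length 2 (allele strings; any
#'   four-digit form accepted, see [normalize_hla_allele()]).
#' @return Accuracy in `{0, 0.5, 1}` (`NA` when the call is `NA`).
#' @examples
#' hla_score_genotype(c("09:01", "14:54"), c("14:54", "09:01"))  # 1
#' hla_score_genotype(c("24:02", "24:02"), c("24:02", "11:01"))  # 0.5
#' @export
hla_score_genotype <- function(truth, call) {
  stopifnot(length(truth) == 2L, length(call) == 2L)
  if (anyNA(call)) return(NA_real_)
  t <- normalize_hla_allele(truth)
  c2 <- normalize_hla_allele(call)
  straight <- (t[1] == c2[1]) + (t[2] == c2[2])
  crossed <- (t[1] == c2[2]) + (t[2] == c2[1])
  max(straight, crossed) / 2
}

#' Score a table of per-tool HLA calls
#'
#' Joins tool calls to the truth genotypes by gene and scores each
#' available (tool, gene) pair.
#'
#' @param truth_hla Truth table (`gene`, `allele1`, `allele2`), one row per
#'   gene; see [default_hla_truth()].
#' @param calls Call table (`tool`, `gene`, `allele1`, `allele2`), e.g. from
#'   [generate_hla_calls()].
#' @return `calls` with a `score` column appended (`NA` for unavailable
#'   pairs).
#' @export
hla_score_table <- function(truth_hla, calls) {
  stopifnot(is.data.frame(truth_hla), is.data.frame(calls))
  idx <- match(calls$gene, truth_hla$gene)
  if (anyNA(idx)) {
    stop("call table contains gene(s) absent from truth: ",
         paste(unique(calls$gene[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  calls$score <- vapply(seq_len(nrow(calls)), function(i) {
    hla_score_genotype(
      c(truth_hla$allele1[idx[i]], truth_hla$allele2[idx[i]]),
      c(calls$allele1[i], calls$allele2[i])
    )
  }, numeric(1))
  calls
}

#' Per-gene accuracy over replicates
#'
#' `100 * mean(scores)`, presented to one decimal (half-up): the accuracy of
#' one (tool, gene) pair averaged over replicate datasets.
#'
#' @param scores Non-empty numeric vector of replicate scores in \[0, 1\].
#' @return Percent accuracy, one decimal.
#' @examples
#' hla_gene_accuracy(c(rep(1, 9), 0.5))  # 95
#' @export
hla_gene_accuracy <- function(scores) {
  if (length(scores) == 0L) stop("no scores to average", call. = FALSE)
  round_half_up(100 * mean(scores), 1)
}

#' Average accuracy across genes for one tool
#'
#' The unweighted mean of the per-gene percent accuracies over available
#' genes only (`NA` entries -- genes the tool cannot type -- are excluded),
#' presented to one decimal (half-up). With the standard availability mask
#' this averages 6 genes for PHLAT and HLA-VBseq and 8 for the others.
#'
#' @param per_gene Named or unnamed numeric vector of per-gene percent
#'   accuracies, `NA` for unavailable genes.
#' @return Percent accuracy, one decimal.
#' @examples
#' hla_average_accuracy(c(100, 60, 40, 40, 100, 100, NA, NA))  # 73.3
#' @export
hla_average_accuracy <- function(per_gene) {
  ok <- !is.na(per_gene)
  if (!any(ok)) stop("all genes unavailable: average undefined", call. = FALSE)
  round_half_up(mean(per_gene[ok]), 1)
}

#' Tabulate per-gene and average accuracy per tool
#'
#' Aggregates a long table of replicate scores into a Table-style report:
#' one row per gene plus an `Average` row, one column per tool, `NA` for
#' unavailable pairs. Additional depth columns can be produced by calling
#' this once per depth.
#'
#' @param scores Long data.frame with columns `tool`, `gene`, `score`
#'   (replicate rows allowed; `NA` scores mark unavailable pairs).
#' @return Data.frame: `gene` column (eight genes in canonical order plus
#'   `"Average"`), one numeric percent column per tool.
#' @export
hla_accuracy_report <- function(scores) {
  stopifnot(all(c("tool", "gene", "score") %in% names(scores)))
  tools <- unique(scores$tool)
  genes <- intersect(HLA_GENES, unique(scores$gene))
  out <- data.frame(gene = c(genes, "Average"), stringsAsFactors = FALSE)
  for (tool in tools) {
    per_gene <- vapply(genes, function(g) {
      s <- scores$score[scores$tool == tool & scores$gene == g]
      if (all(is.na(s))) NA_real_ else hla_gene_accuracy(s[!is.na(s)])
    }, numeric(1))
    out[[tool]] <- c(per_gene, hla_average_accuracy(per_gene))
  }
  out
}
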