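#' Hard-filter thresholds
#'
#' The per-annotation exclusion rules applied to called variants, following
#' the GATK VariantFiltration convention. A record fails an item when its
#' annotation crosses the threshold in the failing direction; a record with
#' the annotation absent never fails that item (rank-sum annotations are
#' undefined at hom-alt sites). Thresholds are strict inequalities exactly
#' as written, so boundary values (e.g. QD = 2.0) pass.
#'
#' SNVs: QD < 2.0, FS > 60.0, MQ < 40.0, MQRankSum < -12.5,
#' ReadPosRankSum < -8.0, HaplotypeScore > 13.0, SOR > 3.0.
#' Indels: QD < 2.0, FS > 200.0, ReadPosRankSum < -20.0, SOR > 10.0.
#'
#' @return Named list with elements `SNV` and `indel`; each a data.frame of
#'   `item`, `op` (`"<"` fails below, `">"` fails above) and `threshold`.
#' @examples
#' hard_filter_thresholds()$indel
#' @export
hard_filter_thresholds <- function() {
  list(
    SNV = data.frame(
      item = c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum",
               "HaplotypeScore", "SOR"),
      op = c("<", ">", "<", "<", "<", ">", ">"),
      threshold = c(2.0, 60.0, 40.0, -12.5, -8.0, 13.0, 3.0),
      stringsAsFactors = FALSE
    ),
    indel = data.frame(
      item = c("QD", "FS", "ReadPosRankSum", "SOR"),
      op = c("<", ">", "<", ">"),
      threshold = c(2.0, 200.0, -20.0, 10.0),
      stringsAsFactors = FALSE
    )
  )
}

#' Apply the hard filter to call records
#'
#' Sets the `filter` column to `"PASS"` or to the semicolon-joined names of
#' every failed item (all failures are recorded, not just the first).
#' Idempotent: the result depends only on the annotations and variant type.
#'
#' @param x A `wgs_callset` or a call-record data.frame with columns `vtype`
#'   and the annotation columns present in [hard_filter_thresholds()]
#'   (absent columns and `NA` values never trigger their rule).
#' @return The input, with `filter` set on every record.
#' @examples
#' rec <- data.frame(vtype = "SNV", QD = 1.5, FS = 10, MQ = 60,
#'                   MQRankSum = 0, ReadPosRankSum = 0, SOR = 1,
#'                   HaplotypeScore = 2)
#' apply_hard_filter(rec)$filter  # "QD"
#' @export
apply_hard_filter <- function(x) {
  rec <- as_records(x)
  if (is.null(rec$vtype)) stop("records must carry vtype", call. = FALSE)
  bad <- setdiff(unique(rec$vtype), c("SNV", "indel"))
  if (length(bad)) {
    stop("unknown vtype value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  rules <- hard_filter_thresholds()
  fails <- matrix(FALSE, nrow = nrow(rec), ncol = length(ANNOTATION_ITEMS),
                  dimnames = list(NULL, ANNOTATION_ITEMS))
  for (vt in names(rules)) {
    rows <- rec$vtype == vt
    if (!any(rows)) next
    rl <- rules[[vt]]
    for (j in seq_len(nrow(rl))) {
      item <- rl$item[j]
      if (is.null(rec[[item]])) next
      v <- rec[[item]][rows]
      hit <- if (rl$op[j] == "<") v < rl$threshold[j] else v > rl$threshold[j]
      hit[is.na(hit)] <- FALSE
      fails[rows, item] <- hit
    }
  }
  filt <- apply(fails, 1L, function(f) {
    if (any(f)) paste(ANNOTATION_ITEMS[f], collapse = ";") else "PASS"
  })
  rec$filter <- if (nrow(rec)) filt else character(0)
  if (inherits(x, "wgs_callset")) {
    x$records <- rec
    x
  } else {
    rec
  }
}

#' Per-item exclusion rates
#'
#' For each filtration item, the percentage of all records failing it. A
#' record failing k items counts once toward each of the k items, so rates
#' need not sum to the overall exclusion rate.
#'
#' @param x A filtered `wgs_callset` or records data.frame (`filter` set).
#' @return Data.frame with columns `item` and `rate` (percent, one row per
#'   annotation item in [hard_filter_thresholds()] order).
#' @examples
#' rec <- data.frame(vtype = rep("SNV", 10), QD = c(rep(20, 8), 1, 1))
#' exclusion_rates(apply_hard_filter(rec))
#' @export
exclusion_rates <- function(x) {
  rec <- as_records(x)
  if (nrow(rec) == 0L) stop("no records: exclusion rates undefined", call. = FALSE)
  if (is.null(rec$filter) || any(rec$filter == ".")) {
    stop("filter status must be set on all records (see apply_hard_filter)",
         call. = FALSE)
  }
  failed <- strsplit(rec$filter, ";", fixed = TRUE)
  counts <- vapply(ANNOTATION_ITEMS, function(item)
    sum(vapply(failed, function(f) item %in% f, logical(1))), numeric(1))
  data.frame(item = ANNOTATION_ITEMS,
             rate = 100 * counts / nrow(rec),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filtration strategies
#'
#' The pipeline filters call sets through a pluggable strategy. `"hard"` is
#' the built-in hard filter; `"pass"` marks every record PASS and stands in
#' for model-based recalibration (VQSR), which is out of scope for the
#' simulator.
#'
#' @param name `"hard"` or `"pass"`.
#' @return A function mapping a `wgs_callset` (or records data.frame) to the
#'   same object with `filter` set.
#' @examples
#' strat <- filter_strategy("pass")
#' @export
filter_strategy <- function(name = c("hard", "pass")) {
  name <- match.arg(name)
  switch(name,
    hard = apply_hard_filter,
    pass = function(x) {
      rec <- as_records(x)
      rec$filter <- rep("PASS", nrow(rec))
      if (inherits(x, "wgs_callset")) {
        x$records <- rec
        x
      } else {
        rec
      }
    }
  )
}
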