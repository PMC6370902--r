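#' Depth from total sequenced bases
#'
#' Mean fold-coverage implied by a total base count over the effective
#' (non-N) reference length: `total_bases / effective_ref_length`. This is
#' the FASTQ-stage depth definition (raw reads, and raw reads after
#' trimming).
#'
#' @param total_bases Total sequenced bases (>= 0).
#' @param effective_ref_length Reference length in bases, excluding unknown
#'   (N) bases; must be > 0.
#' @return Fold-coverage (numeric scalar).
#' @examples
#' depth_from_bases(2.86e9 * 10.5, 2.86e9)  # 10.5
#' @export
depth_from_bases <- function(total_bases, effective_ref_length) {
  stop_if_not_scalar_num(total_bases, "total_bases")
  stop_if_not_scalar_num(effective_ref_length, "effective_ref_length")
  if (effective_ref_length <= 0) {
    stop("effective_ref_length must be > 0", call. = FALSE)
  }
  if (total_bases < 0) stop("total_bases must be >= 0", call. = FALSE)
  total_bases / effective_ref_length
}

#' Mean depth over variant records
#'
#' Arithmetic mean of per-record `DP`; the VCF-stage depth (variant depth,
#' and variant depth after filtration when applied to PASS records only).
#'
#' @param records A call-record data.frame (or `wgs_callset`) with a `dp`
#'   column.
#' @return Mean `DP` (fold-coverage).
#' @examples
#' variant_depth(data.frame(dp = c(10, 20, 30)))  # 20
#' @export
variant_depth <- function(records) {
  records <- as_records(records)
  if (nrow(records) == 0L) {
    stop("no variant records: variant depth is undefined", call. = FALSE)
  }
  if (anyNA(records$dp)) stop("every record must carry DP", call. = FALSE)
  mean(records$dp)
}

#' Percent depth reduction between two pipeline stages
#'
#' `100 * (1 - depth_after / depth_before)`, presented to one decimal
#' (half-up) by default; pass `digits = NULL` for the unrounded value.
#'
#' @param depth_before,depth_after Fold-coverage at the earlier and later
#'   stage; `depth_before` must be > 0.
#' @param digits Decimals for half-up presentation rounding, or `NULL`.
#' @return Percent reduction (can be negative when depth increases, as it
#'   does at low depth between unique-read and variant stages).
#' @examples
#' reduction_percent(523, 359)   # 31.4
#' reduction_percent(10.5, 9.1)  # 13.3
#' @export
reduction_percent <- function(depth_before, depth_after, digits = 1) {
  stop_if_not_scalar_num(depth_before, "depth_before")
  stop_if_not_scalar_num(depth_after, "depth_after")
  if (depth_before <= 0) stop("depth_before must be > 0", call. = FALSE)
  out <- 100 * (1 - depth_after / depth_before)
  if (is.null(digits)) out else round_half_up(out, digits)
}

#' Fold change between two depths
#'
#' `depth_to / depth_from`, unrounded. (From the printed one-decimal depths
#' 0.052x and 2.36x this evaluates to 45.38; reports derived from unrounded
#' stage depths can differ in the last digit.)
#'
#' @param depth_from,depth_to Fold-coverage; `depth_from` must be > 0.
#' @return Ratio.
#' @examples
#' fold_change(0.052, 2.36)
#' @export
fold_change <- function(depth_from, depth_to) {
  stop_if_not_scalar_num(depth_from, "depth_from")
  stop_if_not_scalar_num(depth_to, "depth_to")
  if (depth_from <= 0) stop("depth_from must be > 0", call. = FALSE)
  depth_to / depth_from
}

#' Six-stage depth profile of a simulated dataset
#'
#' Computes the six pipeline depth stages for one call set: raw read depth
#' (`rrd`), raw read depth after trimming (`rrdat`), mapped read depth
#' (`mrd`) and unique read depth (`urd`) from the simulator's read
#' accounting ledger, and variant depth (`vd`, mean DP over all records) and
#' variant depth after filtration (`vdaf`, mean DP over PASS records) from
#' the records themselves. The first four satisfy
#' `rrd >= rrdat >= mrd >= urd`; `vd`/`vdaf` may exceed `urd` at low depth
#' because only covered sites yield variant records (the Poisson mean
#' conditional on coverage exceeds the unconditional mean).
#'
#' @param callset A `wgs_callset` whose records have a `filter` column set
#'   (see [apply_hard_filter()]); unfiltered records (`"."`) are treated as
#'   PASS for `vdaf`.
#' @return One-row data.frame with columns `target_depth`, `replicate`,
#'   `rrd`, `rrdat`, `mrd`, `urd`, `vd`, `vdaf` (NA for `vd`/`vdaf` when no
#'   records / no passing records exist).
#' @export
depth_stage_profile <- function(callset) {
  stopifnot(inherits(callset, "wgs_callset"))
  ra <- callset$read_accounting
  L <- ra$effective_ref_length
  rec <- callset$records
  pass <- rec[rec$filter %in% c("PASS", "."), , drop = FALSE]
  data.frame(
    target_depth = callset$target_depth,
    replicate = callset$replicate_id,
    rrd = depth_from_bases(ra$rrd_bases, L),
    rrdat = depth_from_bases(ra$rrdat_bases, L),
    mrd = depth_from_bases(ra$mrd_bases, L),
    urd = depth_from_bases(ra$urd_bases, L),
    vd = if (nrow(rec)) variant_depth(rec) else NA_real_,
    vdaf = if (nrow(pass)) variant_depth(pass) else NA_real_
  )
}

# Accept either a wgs_callset or a bare records data.frame.
as_records <- function(x) {
  if (inherits(x, "wgs_callset")) x$records
  else if (is.data.frame(x)) x
  else stop("expected a wgs_callset or a records data.frame", call. = FALSE)
}
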