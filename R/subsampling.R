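#' Replicate plan for a target depth
#'
#' Low-depth datasets are noisy, so depths strictly below the replicate
#' threshold (default 45x) get `n_replicates` (default 10) independently
#' seeded datasets whose metrics are averaged; depths at or above the
#' threshold get a single dataset. Seeds are
#' `base_seed + 1000 * depth_index + replicate_id`, which is collision-free
#' for schedules under 1000 replicates per level.
#'
#' @param target_depth Fold-coverage (> 0).
#' @param config A [sim_config()].
#' @param depth_index Position of `target_depth` in `config$depth_schedule`;
#'   defaults to looking it up, and must be supplied for off-schedule depths.
#' @return A `replicate_plan`: list with `target_depth`, `n_replicates`,
#'   `seeds` (integer vector, one per replicate) and `depth_index`.
#' @examples
#' cfg <- sim_config(depth_schedule = c(10, 45, 100))
#' plan_replicates(10, cfg)$n_replicates   # 10
#' plan_replicates(45, cfg)$n_replicates   # 1 (threshold is strict)
#' @export
plan_replicates <- function(target_depth, config,
                            depth_index = match(target_depth, config$depth_schedule)) {
  stopifnot(inherits(config, "sim_config"))
  stop_if_not_scalar_num(target_depth, "target_depth")
  if (target_depth <= 0) stop("target_depth must be > 0", call. = FALSE)
  if (is.na(depth_index)) {
    stop("target_depth is not in config$depth_schedule; supply depth_index",
         call. = FALSE)
  }
  n_rep <- if (target_depth < config$replicate_threshold) config$n_replicates else 1L
  seeds <- config$base_seed + 1000L * as.integer(depth_index) + seq_len(n_rep)
  structure(list(target_depth = target_depth, n_replicates = n_rep,
                 seeds = as.integer(seeds),
                 depth_index = as.integer(depth_index)),
            class = "replicate_plan")
}

#' Seeded Bernoulli subsampling
#'
#' Retains each item independently with probability `fraction`, preserving
#' input order (samtools `view -s` semantics: per-read coin flips, not an
#' exact count). Works on vectors and on data.frames (rows).
#'
#' @param items Vector or data.frame.
#' @param fraction Retention probability in \[0, 1\].
#' @param seed Integer seed; fixed seed gives identical output.
#' @return The retained items, in input order.
#' @examples
#' subsample_fraction(1:10, 0.5, seed = 1)
#' @export
subsample_fraction <- function(items, fraction, seed) {
  stop_if_not_scalar_num(fraction, "fraction")
  if (fraction < 0 || fraction > 1) {
    stop("fraction must lie in [0, 1]", call. = FALSE)
  }
  n <- if (is.data.frame(items)) nrow(items) else length(items)
  keep <- withr::with_seed(as.integer(seed), stats::runif(n) < fraction)
  if (is.data.frame(items)) {
    out <- items[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    items[keep]
  }
}

#' Average metric values over replicates
#'
#' The unweighted arithmetic mean of the replicate metric values; a single
#' value passes through unchanged. The replicate standard deviation is
#' attached as attribute `"sd"` for diagnostics (NA for a single replicate).
#'
#' @param values Non-empty numeric vector.
#' @return Mean value with attribute `sd`.
#' @examples
#' aggregate_replicates(c(0.98, 1.00))  # 0.99
#' @export
aggregate_replicates <- function(values) {
  if (length(values) == 0L) stop("no replicate values to aggregate", call. = FALSE)
  if (!is.numeric(values)) stop("replicate values must be numeric", call. = FALSE)
  structure(mean(values), sd = stats::sd(values))
}
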