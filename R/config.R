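#' Simulation configuration
#'
#' Builds and validates the configuration object shared by the simulator and
#' the sweep pipeline. Defaults describe a desk-scale rendition of a deep
#' human WGS experiment: a GRCh37-sized effective genome, an individual
#' carrying a catalog of SNVs and indels whose alternate-allele frequencies
#' follow a beta-shaped population spectrum, a SNP-array-like subset of the
#' catalog carrying genotyping QC metadata, and a titration of target mean
#' depths spanning 0.05x to 410x.
#'
#' @param genome_length Effective (non-N) reference length in bases.
#' @param n_variants Number of truth catalog sites.
#' @param indel_fraction Proportion of truth sites that are indels.
#' @param aaf_spec Alternate-allele-frequency distribution. A list with
#'   `dist` one of `"beta"` (fields `shape1`, `shape2`), `"fixed"` (field
#'   `value`) or `"uniform"`.
#' @param array_fraction Probability that an SNV truth site is on the
#'   microarray panel (arrays genotype SNPs, so indels are never on-array).
#' @param depth_schedule Numeric vector of target mean depths (fold-coverage).
#' @param replicate_threshold Depth below which replicate datasets are
#'   simulated (strictly below; default 45).
#' @param n_replicates Replicates per low-depth level (default 10).
#' @param tstv Target transition/transversion ratio for simulated SNV alleles.
#' @param error_model Named list overriding any of: `floor` (minimum read
#'   count for a site to be callable), `dropout` (logical; model het allele
#'   dropout by binomial read sampling), `het_error`, `hom_error`,
#'   `homref_error` (per-site genotype error rates for het, hom-alt and
#'   array hom-ref truth sites), `alt_error` (probability a call carries a
#'   wrong alternate allele), `fp_rate` (expected false-positive records per
#'   truth site at saturating depth).
#' @param ann_model Named list overriding annotation-model parameters:
#'   `artifact_weight` (named vector over the seven annotations: probability
#'   a record draws the item from its failing component), `hs_depth_knee`
#'   and `hs_depth_slope` (the HaplotypeScore artifact weight grows as
#'   `slope * log10(depth/knee)` above `knee`, emulating haplotype-count
#'   inflation in very deep data).
#' @param accounting Named list overriding read-accounting retention rates:
#'   `trim_retain`, `map_retain` (fixed), `dup_sat`, `dup_half` (duplicate
#'   loss saturates as `dup_sat * d/(d + dup_half)` with depth `d`).
#' @param hla_error Named list overriding HLA miscall parameters: `floor_rates`
#'   (named per-tool asymptotic per-allele miscall probabilities, optionally a
#'   per-gene named vector per tool) and `decay` (depth scale; the miscall
#'   probability is `1 - (1 - floor) * (1 - exp(-depth/decay))`).
#' @param base_seed Integer base seed; all dataset seeds derive from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_variants = 1000, depth_schedule = c(1, 10), base_seed = 7)
#' cfg$error_model$floor
#' @export
sim_config <- function(genome_length = 2.86e9,
                       n_variants = 1e5,
                       indel_fraction = 0.15,
                       aaf_spec = list(dist = "beta", shape1 = 0.25, shape2 = 0.8),
                       array_fraction = 0.13,
                       depth_schedule = default_depth_schedule(),
                       replicate_threshold = 45,
                       n_replicates = 10,
                       tstv = 2.1,
                       error_model = list(),
                       ann_model = list(),
                       accounting = list(),
                       hla_error = list(),
                       base_seed = 1L) {
  em <- utils::modifyList(list(
    floor = 1L,
    dropout = TRUE,
    het_error = 0.002,
    hom_error = 5e-4,
    homref_error = 1e-3,
    alt_error = 1e-3,
    fp_rate = 0.01
  ), as.list(error_model))

  am <- utils::modifyList(list(
    artifact_weight = c(QD = 0.003, FS = 0.003, MQ = 0.003,
                        MQRankSum = 0.002, ReadPosRankSum = 0.002,
                        HaplotypeScore = 0.003, SOR = 0.003),
    hs_depth_knee = 100,
    hs_depth_slope = 0.25
  ), as.list(ann_model))

  ac <- utils::modifyList(list(
    trim_retain = 0.97,
    map_retain = 0.98,
    dup_sat = 0.33,
    dup_half = 25
  ), as.list(accounting))

  he <- utils::modifyList(list(
    floor_rates = c(PHLAT = 0.15, `HLA-VBseq` = 0.12, `HLA-HD` = 0.01,
                    `HISAT-genotype` = 0.03, SNP2HLA = 0.05),
    decay = 3
  ), as.list(hla_error))

  cfg <- structure(list(
    genome_length = genome_length,
    n_variants = as.integer(n_variants),
    indel_fraction = indel_fraction,
    aaf_spec = aaf_spec,
    array_fraction = array_fraction,
    depth_schedule = as.numeric(depth_schedule),
    replicate_threshold = replicate_threshold,
    n_replicates = as.integer(n_replicates),
    tstv = tstv,
    error_model = em,
    ann_model = am,
    accounting = ac,
    hla_error = he,
    base_seed = as.integer(base_seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (!is.numeric(genome_length) || genome_length <= 0)
      stop("genome_length must be > 0", call. = FALSE)
    if (n_variants < 1L)
      stop("n_variants must be >= 1", call. = FALSE)
    if (indel_fraction < 0 || indel_fraction > 1)
      stop("indel_fraction must lie in [0, 1]", call. = FALSE)
    if (array_fraction < 0 || array_fraction > 1)
      stop("array_fraction must lie in [0, 1]", call. = FALSE)
    if (length(depth_schedule) < 1L || any(depth_schedule <= 0))
      stop("depth_schedule values must be > 0", call. = FALSE)
    if (replicate_threshold <= 0 || n_replicates < 1L)
      stop("replicate_threshold must be > 0 and n_replicates >= 1", call. = FALSE)
    if (!aaf_spec$dist %in% c("beta", "fixed", "uniform"))
      stop("aaf_spec$dist must be one of 'beta', 'fixed', 'uniform'", call. = FALSE)
    if (tstv <= 0) stop("tstv must be > 0", call. = FALSE)
    if (error_model$floor < 0) stop("error_model$floor must be >= 0", call. = FALSE)
  })
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome_length: %.4g  n_variants: %d  indel_fraction: %.3g\n",
              x$genome_length, x$n_variants, x$indel_fraction))
  cat(sprintf("  depth schedule: %d levels, %.3gx-%.3gx; replicates: %d below %gx\n",
              length(x$depth_schedule), min(x$depth_schedule),
              max(x$depth_schedule), x$n_replicates, x$replicate_threshold))
  cat(sprintf("  base_seed: %d\n", x$base_seed))
  invisible(x)
}

#' Default depth titration schedule
#'
#' A union of logarithmically and linearly spaced target depths trimmed to
#' `n` unique levels spanning `min_depth` to `max_depth`. Mixing both
#' spacings concentrates levels in the low-depth regime (where accuracy
#' changes fastest) while still sampling the deep tail at regular intervals.
#'
#' @param n Number of depth levels (default 54).
#' @param min_depth,max_depth Range endpoints (fold-coverage).
#' @return Sorted numeric vector of length `n`, with the endpoints included.
#' @examples
#' sched <- default_depth_schedule()
#' length(sched); range(sched)
#' @export
default_depth_schedule <- function(n = 54, min_depth = 0.05, max_depth = 410) {
  stopifnot(n >= 2, min_depth > 0, max_depth > min_depth)
  k <- ceiling(n / 2)
  levels <- numeric(0)
  repeat {
    logs <- 10^seq(log10(min_depth), log10(max_depth), length.out = k)
    lins <- seq(min_depth, max_depth, length.out = k)
    levels <- sort(unique(signif(c(logs, lins), 3)))
    if (length(levels) >= n) break
    k <- k + 1L
  }
  idx <- unique(round(seq(1L, length(levels), length.out = n)))
  out <- levels[idx]
  out[1] <- signif(min_depth, 3)
  out[length(out)] <- signif(max_depth, 3)
  out
}

#' Read / write a simulation configuration
#'
#' Configurations round-trip through YAML (`.yaml`/`.yml`) or JSON (any other
#' extension). Reading re-validates through [sim_config()], so hand-edited
#' files are checked on load.
#'
#' @param path File path.
#' @param config A `sim_config` object.
#' @return `read_sim_config` returns a `sim_config`; `write_sim_config`
#'   returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  for (fld in c("error_model", "ann_model", "accounting", "hla_error")) {
    if (!is.null(raw[[fld]])) raw[[fld]] <- lapply(raw[[fld]], unlist_named)
  }
  do.call(sim_config, raw[names(raw) %in% names(formals(sim_config))])
}

unlist_named <- function(x) {
  if (is.list(x) && all(vapply(x, is.atomic, logical(1))) &&
      all(lengths(x) == 1L) && !is.null(names(x))) unlist(x) else x
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  # named vectors serialize as key/value maps, not bare arrays
  for (fld in c("error_model", "ann_model", "accounting", "hla_error")) {
    x[[fld]] <- lapply(x[[fld]], function(v) {
      if (is.atomic(v) && !is.null(names(v))) as.list(v) else v
    })
  }
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
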