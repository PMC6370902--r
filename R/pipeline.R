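#' Run the full depth-titration sweep
#'
#' Orchestrates the end-to-end experiment: generate the truth catalog and
#' QC-filtered array panel once, then for every depth level and replicate
#' simulate a call set, filter it, and measure panel concordance (overall,
#' heterozygote-only, and AAF-stratified), concordance against the
#' maximum-depth ("all reads") dataset for SNVs and indels, the six-stage
#' depth profile, variant counts, Ts/Tv, per-item exclusion rates, and HLA
#' genotyping accuracy. Replicates follow [plan_replicates()]; every dataset
#' seed derives deterministically from `config$base_seed`, so a rerun with
#' the same configuration reproduces byte-identical outputs.
#'
#' Output files (tab-separated, one tidy table per analysis) are written to
#' `outdir`: `metrics.tsv` (depth, replicate, stratum rows), `counts.tsv`,
#' `tstv.tsv`, `depth_stages.tsv`, `allreads.tsv`, `exclusion_rates.tsv`,
#' `hla_scores.tsv`, plus `manifest.json` recording the configuration, its
#' digest, per-dataset seeds, file names and package version.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @param depths Depth levels to run (default: the configured schedule).
#' @param strategy Filtration strategy name for [filter_strategy()].
#' @param hla_truth HLA truth table (default [default_hla_truth()]).
#' @param run_hla Run the HLA arm (default TRUE).
#' @return The manifest, invisibly (a list; `$failures` names any depth
#'   level that failed and was skipped).
#' @export
run_sweep <- function(config, outdir, depths = config$depth_schedule,
                      strategy = "hard", hla_truth = default_hla_truth(),
                      run_hla = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(outdir, 2) != 0) stop("outdir is not writable", call. = FALSE)
  filt <- filter_strategy(strategy)

  truth <- generate_truth(config)
  panel <- qc_filter_truth(truth)
  depth_index <- match(depths, config$depth_schedule)
  if (anyNA(depth_index)) {
    stop("all requested depths must be in config$depth_schedule", call. = FALSE)
  }

  # maximum-depth dataset is the "all reads" reference for Fig-5-style CRs
  i_ref <- which.max(depths)
  ref_plan <- plan_replicates(depths[i_ref], config, depth_index[i_ref])
  reference <- filt(simulate_callset(truth, depths[i_ref], ref_plan$seeds[1],
                                     config, replicate_id = 1L))

  metrics <- counts <- tstv <- stages <- allreads <- excl <- hla <- list()
  seed_log <- list()
  failures <- character(0)

  for (i in seq_along(depths)) {
    d <- depths[i]
    res <- tryCatch({
      plan <- plan_replicates(d, config, depth_index[i])
      rows_m <- rows_c <- rows_t <- rows_s <- rows_a <- rows_e <- rows_h <- list()
      for (r in seq_len(plan$n_replicates)) {
        seedr <- plan$seeds[r]
        cs <- if (i == i_ref && r == 1L) reference else {
          filt(simulate_callset(truth, d, seedr, config, replicate_id = r))
        }
        cm <- concordance_matrix(panel, cs)
        met <- compute_metrics(cm)
        strat <- stratify_by_aaf(panel, cs)
        rows_m[[r]] <- rbind(
          data.frame(target_depth = d, replicate = r, stratum = "all", met),
          data.frame(target_depth = d, replicate = r, stratum = "het",
                     cr = het_only_cr(cm), fpr = NA, fnr = NA, ntpr = NA,
                     n = sum(cm$counts["RA", ])),
          data.frame(target_depth = d, replicate = r,
                     stratum = paste0("aaf_", strat$bin),
                     strat[, c("cr", "fpr", "fnr", "ntpr", "n")])
        )
        cv <- count_variants(cs)
        rows_c[[r]] <- data.frame(target_depth = d, replicate = r,
                                  n_snv = cv$n_snv, n_indel = cv$n_indel,
                                  n_total = cv$n_total)
        tt <- ts_tv_ratio(cs)
        rows_t[[r]] <- data.frame(target_depth = d, replicate = r,
                                  tstv = as.numeric(tt),
                                  n_ts = attr(tt, "n_ts"), n_tv = attr(tt, "n_tv"))
        rows_s[[r]] <- depth_stage_profile(cs)
        er <- exclusion_rates(cs)
        rows_e[[r]] <- data.frame(target_depth = d, replicate = r, er)
        snv_cr <- allreads_concordance(reference, cs, "SNV")
        ind_cr <- tryCatch(allreads_concordance(reference, cs, "indel"),
                           error = function(e) structure(NA_real_, n = 0L))
        rows_a[[r]] <- data.frame(
          target_depth = d, replicate = r,
          vtype = c("SNV", "indel"),
          concordance = c(as.numeric(snv_cr), as.numeric(ind_cr)),
          n = c(attr(snv_cr, "n"), attr(ind_cr, "n"))
        )
        if (run_hla) {
          hc <- generate_hla_calls(hla_truth, hla_tools(), d, seedr, config)
          sc <- hla_score_table(hla_truth, hc)
          rows_h[[r]] <- data.frame(target_depth = d, replicate = r,
                                    sc[, c("tool", "gene", "score")])
        }
        seed_log[[length(seed_log) + 1L]] <- data.frame(target_depth = d,
                                                        replicate = r,
                                                        seed = seedr)
      }
      list(m = rows_m, c = rows_c, t = rows_t, s = rows_s, a = rows_a,
           e = rows_e, h = rows_h)
    }, error = function(e) {
      warning(sprintf("depth %g failed and was skipped: %s", d,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(res)) {
      failures <- c(failures, as.character(d))
      next
    }
    metrics[[i]] <- do.call(rbind, res$m)
    counts[[i]] <- do.call(rbind, res$c)
    tstv[[i]] <- do.call(rbind, res$t)
    stages[[i]] <- do.call(rbind, res$s)
    allreads[[i]] <- do.call(rbind, res$a)
    excl[[i]] <- do.call(rbind, res$e)
    if (run_hla) hla[[i]] <- do.call(rbind, res$h)
  }

  files <- c(metrics = "metrics.tsv", counts = "counts.tsv", tstv = "tstv.tsv",
             depth_stages = "depth_stages.tsv", allreads = "allreads.tsv",
             exclusion_rates = "exclusion_rates.tsv")
  tables <- list(metrics = metrics, counts = counts, tstv = tstv,
                 depth_stages = stages, allreads = allreads,
                 exclusion_rates = excl)
  if (run_hla) {
    files <- c(files, hla_scores = "hla_scores.tsv")
    tables$hla_scores <- hla
  }
  for (nm in names(files)) {
    write_tsv_num(do.call(rbind, tables[[nm]]), file.path(outdir, files[[nm]]))
  }

  cfg_path <- file.path(outdir, "config.json")
  write_sim_config(config, cfg_path)
  manifest <- list(
    package = "depthconcord",
    version = as.character(utils::packageVersion("depthconcord")),
    config_digest = unname(tools::md5sum(cfg_path)),
    depths = depths,
    strategy = strategy,
    seeds = do.call(rbind, seed_log),
    files = as.list(files),
    failures = failures
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       pretty = TRUE)
  invisible(manifest)
}

# Fixed-format numeric TSV so reruns are byte-identical across platforms.
write_tsv_num <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), "NA", formatC(x, digits = 10, format = "g"))
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Aggregate sweep outputs into a summary report
#'
#' Reads the tidy tables written by [run_sweep()], averages metric values
#' over replicates (the replicate policy of the design), and writes
#' `summary.tsv`: one row per (depth, stratum, metric) with the replicate
#' mean, standard deviation and replicate count. Also reports the first
#' depth level whose replicate-mean overall CR exceeds `threshold_cr`, and a
#' per-tool/per-gene HLA accuracy table when HLA scores are present.
#' Optionally renders depth-versus-metric curves on a log-scaled depth axis
#' (requires \pkg{ggplot2}).
#'
#' @param outdir Directory containing [run_sweep()] outputs.
#' @param threshold_cr CR threshold to annotate (default 0.99).
#' @param plot Write `report_curves.pdf` into `outdir` (default FALSE).
#' @return List with `summary` (long data.frame), `cr_threshold_depth`
#'   (numeric, `NA` when never exceeded), and `hla` (accuracy report per
#'   depth, or `NULL`).
#' @export
make_report <- function(outdir, threshold_cr = 0.99, plot = FALSE) {
  mfile <- file.path(outdir, "metrics.tsv")
  if (!file.exists(mfile)) {
    stop("no sweep outputs in ", outdir, " (metrics.tsv missing)", call. = FALSE)
  }
  met <- utils::read.delim(mfile, stringsAsFactors = FALSE)
  long <- stats::reshape(
    met[, c("target_depth", "replicate", "stratum", "cr", "fpr", "fnr", "ntpr")],
    direction = "long", varying = c("cr", "fpr", "fnr", "ntpr"),
    v.names = "value", timevar = "metric",
    times = c("cr", "fpr", "fnr", "ntpr")
  )
  agg <- stats::aggregate(value ~ target_depth + stratum + metric, data = long,
                          FUN = mean, na.action = stats::na.omit)
  sdv <- stats::aggregate(value ~ target_depth + stratum + metric, data = long,
                          FUN = stats::sd, na.action = stats::na.omit)
  nrep <- stats::aggregate(value ~ target_depth + stratum + metric, data = long,
                           FUN = length, na.action = stats::na.omit)
  names(agg)[4] <- "mean"
  agg$sd <- sdv$value
  agg$n_replicates <- nrep$value
  agg <- agg[order(agg$stratum, agg$metric, agg$target_depth), ]
  rownames(agg) <- NULL
  write_tsv_num(agg, file.path(outdir, "summary.tsv"))

  cr_all <- agg[agg$stratum == "all" & agg$metric == "cr", ]
  above <- cr_all$target_depth[cr_all$mean > threshold_cr]
  cr_threshold_depth <- if (length(above)) min(above) else NA_real_

  hfile <- file.path(outdir, "hla_scores.tsv")
  hla_rep <- NULL
  if (file.exists(hfile)) {
    hs <- utils::read.delim(hfile, stringsAsFactors = FALSE)
    hla_rep <- lapply(split(hs, hs$target_depth), hla_accuracy_report)
  }

  if (isTRUE(plot)) {
    if (!requireNamespace("ggplot2", quietly = TRUE)) {
      warning("ggplot2 not available; skipping plots", call. = FALSE)
    } else {
      dat <- agg[agg$stratum == "all", ]
      p <- ggplot2::ggplot(
        dat,
        ggplot2::aes(x = dat$target_depth, y = dat$mean, colour = dat$metric)
      ) +
        ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
        ggplot2::scale_x_log10() +
        ggplot2::labs(x = "depth (fold-coverage, log scale)", y = "metric value") +
        ggplot2::theme_bw()
      ggplot2::ggsave(file.path(outdir, "report_curves.pdf"), p,
                      width = 7, height = 4.5)
    }
  }

  list(summary = agg, cr_threshold_depth = cr_threshold_depth, hla = hla_rep)
}
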