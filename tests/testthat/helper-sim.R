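# Shared fixtures and the independent concordance oracle.

# Error model with every stochastic error channel switched off: calls equal
# truth at every covered site.
clean_error_model <- function(...) {
  utils::modifyList(list(floor = 1L, dropout = FALSE, het_error = 0,
                         hom_error = 0, homref_error = 0, alt_error = 0,
                         fp_rate = 0), list(...))
}

# Annotation model whose draws always pass the hard filter.
clean_ann_model <- function() {
  list(artifact_weight = c(QD = 0, FS = 0, MQ = 0, MQRankSum = 0,
                           ReadPosRankSum = 0, HaplotypeScore = 0, SOR = 0),
       hs_depth_knee = 100, hs_depth_slope = 0)
}

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(genome_length = 1e6, n_variants = 500, array_fraction = 0.5,
         depth_schedule = c(0.5, 5, 30), base_seed = 42L),
    list(...)
  )
  do.call(sim_config, args)
}

# One hand-rolled call record with passing annotations unless overridden.
make_record <- function(pos, ref = "A", alt = "G", gt = "RA", dp = 30,
                        vtype = "SNV", QD = 20, FS = 5, MQ = 60,
                        MQRankSum = 0, ReadPosRankSum = 0, SOR = 1,
                        HaplotypeScore = 2, filter = "PASS", chrom = "1") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gt = gt,
             dp = dp, QD = QD, FS = FS, MQ = MQ, MQRankSum = MQRankSum,
             ReadPosRankSum = ReadPosRankSum, SOR = SOR,
             HaplotypeScore = HaplotypeScore, vtype = vtype, filter = filter,
             stringsAsFactors = FALSE)
}

make_panel <- function(pos, truth_gt, alt = "C", ref = "A", chrom = "1",
                       aaf = 0.2) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, vtype = "SNV",
             truth_gt = truth_gt, aaf = aaf, on_array = TRUE,
             stringsAsFactors = FALSE)
}

# Independent oracle: site-by-site recount of CR/FPR/FNR/NTPR without the
# concordance-matrix machinery. Classification logic is written out longhand.
brute_force_metrics <- function(panel, calls) {
  rec <- if (inherits(calls, "wgs_callset")) calls$records else calls
  if (!is.null(rec$filter)) rec <- rec[rec$filter %in% c("PASS", "."), ]
  rec <- rec[!grepl(",", rec$alt, fixed = TRUE), ]
  keys <- paste(rec$chrom, rec$pos, rec$ref)
  n <- nrow(panel)
  n_conc <- n_fp <- n_fn <- ntpr_num <- ntpr_den <- 0L
  for (i in seq_len(n)) {
    j <- match(paste(panel$chrom[i], panel$pos[i], panel$ref[i]), keys)
    tg <- panel$truth_gt[i]
    if (is.na(j)) {
      cg <- "RR"
      disc_alt <- FALSE
    } else {
      cg <- rec$gt[j]
      disc_alt <- cg != "RR" && rec$alt[j] != panel$alt[i]
    }
    if (disc_alt) {
      n_fp <- n_fp + 1L
      ntpr_den <- ntpr_den + 1L
    } else {
      if (cg == tg) n_conc <- n_conc + 1L
      if (tg == "RR" && cg != "RR") n_fp <- n_fp + 1L
      if (tg != "RR" && cg == "RR") n_fn <- n_fn + 1L
      if (cg != "RR") {
        ntpr_den <- ntpr_den + 1L
        if (cg == tg) ntpr_num <- ntpr_num + 1L
      }
    }
  }
  data.frame(cr = n_conc / n, fpr = n_fp / n, fnr = n_fn / n,
             ntpr = if (ntpr_den == 0) NA_real_ else ntpr_num / ntpr_den,
             n = n)
}

# Random truth panel plus a call set exercising every classification branch:
# concordant/discordant genotypes, absent sites, alt-discordant calls,
# multi-allelic records, and failing filters.
random_panel_and_calls <- function(n_sites, seed) {
  withr::with_seed(seed, {
    pos <- sort(sample.int(1e6, n_sites))
    panel <- make_panel(pos,
                        truth_gt = sample(c("RR", "RA", "AA"), n_sites,
                                          replace = TRUE, prob = c(.5, .3, .2)),
                        alt = sample(c("C", "G", "T"), n_sites, replace = TRUE),
                        aaf = runif(n_sites))
    present <- runif(n_sites) < 0.8
    m <- sum(present)
    calls <- make_record(
      pos = pos[present],
      alt = ifelse(runif(m) < 0.9, panel$alt[present],
                   sample(c("C", "G", "T"), m, replace = TRUE)),
      gt = sample(c("RR", "RA", "AA"), m, replace = TRUE,
                  prob = c(.1, .5, .4)),
      filter = sample(c("PASS", "QD"), m, replace = TRUE, prob = c(.9, .1))
    )
    multi <- runif(m) < 0.05
    calls$alt[multi] <- paste0(calls$alt[multi], ",T")
    list(panel = panel, calls = calls)
  })
}
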