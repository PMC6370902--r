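test_that("array QC drops low-quality and multi-allelic panel variants", {
  base <- data.frame(
    chrom = "1", pos = 1:5, ref = "A", alt = "C", vtype = "SNV",
    truth_gt = "RA", aaf = 0.2, on_array = TRUE,
    call_rate = c(0.98, 1, 1, 1, 1),
    hwe_p = c(0.5, 1e-5, 1e-7, 0.5, 0.5),
    maf = c(0.2, 0.2, 0.2, 0.005, 0.2),
    multi_allelic = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  kept <- qc_filter_truth(base)
  # row 1 fails call rate, row 3 HWE, row 4 MAF, row 5 multi-allelic;
  # row 2 is retained because 1e-5 >= 1e-6
  expect_equal(kept$pos, 2L)
  off <- base
  off$on_array <- FALSE
  expect_equal(nrow(qc_filter_truth(off)), 0L)
  miss <- base
  miss$maf[2] <- NA
  expect_message(out <- qc_filter_truth(miss), "missing QC metadata")
  expect_equal(nrow(out), 0L)
})

test_that("site classification follows the missing-as-homref and alt-discordance rules", {
  expect_equal(classify_site("RA", "C", "RA", "C"), "RA/RA")
  expect_equal(classify_site("RR", "C", NA, NA), "RR/RR")
  expect_equal(classify_site("RA", "C", "AA", "T"), "alt_discordant")
  expect_equal(classify_site("AA", "C", "RR", "T"), "AA/RR")
  expect_error(classify_site("XX", "C", "RA", "C"))
})

test_that("metrics from a hand-built matrix match hand enumeration", {
  panel <- make_panel(1:100, truth_gt = c(rep("RR", 91), rep("RA", 9)))
  calls <- rbind(
    make_record(92:96, alt = "C"),                 # 5 concordant hets
    make_record(91, gt = "RA", alt = "C"),         # truth RR called RA
    make_record(100, gt = "AA", alt = "T")         # alt-discordant
  )
  m <- concordance_matrix(panel, calls)
  expect_equal(m$counts["RR", "RR"], 90L)
  expect_equal(m$counts["RA", "RA"], 5L)
  expect_equal(m$counts["RA", "RR"], 3L)
  expect_equal(m$counts["RR", "RA"], 1L)
  expect_equal(m$alt_discordant, 1L)
  expect_equal(sum(m$counts) + m$alt_discordant, m$n_truth_sites)

  met <- compute_metrics(m)
  expect_equal(met$cr, 0.95)
  expect_equal(met$fpr, 0.02)
  expect_equal(met$fnr, 0.03)
  expect_equal(met$ntpr, 5 / 7)
  expect_equal(het_only_cr(m), 5 / 8)
})

test_that("an all-concordant panel yields perfect metrics", {
  panel <- make_panel(1:50, truth_gt = rep(c("RR", "RA", "AA"), length.out = 50))
  nonref <- panel$truth_gt != "RR"
  calls <- make_record(panel$pos[nonref], gt = panel$truth_gt[nonref], alt = "C")
  met <- compute_metrics(concordance_matrix(panel, calls))
  expect_equal(met$cr, 1)
  expect_equal(met$fpr, 0)
  expect_equal(met$fnr, 0)
  expect_equal(met$ntpr, 1)
})

test_that("matrix conservation holds over random panels", {
  for (s in 1:25) {
    pc <- random_panel_and_calls(n_sites = 200, seed = s)
    m <- concordance_matrix(pc$panel, pc$calls)
    expect_equal(sum(m$counts) + m$alt_discordant, m$n_truth_sites)
  }
})

test_that("failing records are treated as uncalled sites", {
  panel <- make_panel(1:2, truth_gt = c("RA", "RA"))
  calls <- rbind(make_record(1, alt = "C"),
                 make_record(2, alt = "C", filter = "QD"))
  m <- concordance_matrix(panel, calls)
  expect_equal(m$counts["RA", "RA"], 1L)
  expect_equal(m$counts["RA", "RR"], 1L)
})

test_that("AAF bins partition the frequency range with closed 0.5 boundary", {
  expect_equal(as.character(aaf_bin(0.3)), "0.1-0.5")
  expect_equal(as.character(aaf_bin(0.5)), ">=0.5")
  expect_equal(as.character(aaf_bin(c(0.005, 0.01, 0.05, 0.1))),
               c("<0.01", "0.01-0.05", "0.05-0.1", "0.1-0.5"))
  # the five bins cover [0, 1] without gaps
  expect_false(anyNA(aaf_bin(runif(1000))))
})

test_that("AAF stratification computes per-bin metrics", {
  panel <- make_panel(1:40, truth_gt = rep("RA", 40),
                      aaf = rep(c(0.005, 0.03, 0.07, 0.3, 0.6), 8))
  calls <- make_record(panel$pos, alt = "C")
  strat <- stratify_by_aaf(panel, calls)
  expect_equal(nrow(strat), 5L)
  expect_true(all(strat$cr == 1))
  expect_equal(sum(strat$n), 40L)
})

test_that("Ts/Tv counts transitions over transversions", {
  rec <- rbind(make_record(1, ref = "A", alt = "G"),
               make_record(2, ref = "C", alt = "T"),
               make_record(3, ref = "A", alt = "C"))
  expect_equal(as.numeric(ts_tv_ratio(rec)), 2)
  only_ts <- make_record(1, ref = "A", alt = "G")
  expect_warning(r <- ts_tv_ratio(only_ts), "no transversions")
  expect_true(is.na(r))
  mixed <- rbind(rec, make_record(4, ref = "AT", alt = "A", vtype = "indel"))
  expect_equal(attr(ts_tv_ratio(mixed), "n_skipped"), 1L)
})

test_that("simulated call sets recover the injected Ts/Tv ratio", {
  cfg <- tiny_config(n_variants = 20000, genome_length = 1e7, tstv = 2.1,
                     indel_fraction = 0, error_model = clean_error_model(),
                     base_seed = 19L)
  truth <- generate_truth(cfg)
  cs <- simulate_callset(truth, 30, seed = 23L, config = cfg)
  tt <- ts_tv_ratio(cs)
  n <- attr(tt, "n_ts") + attr(tt, "n_tv")
  p_hat <- attr(tt, "n_ts") / n
  p_exp <- 2.1 / 3.1
  expect_lt(abs(p_hat - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))
})

test_that("all-reads SNV concordance treats absent sites as hom-ref", {
  full <- rbind(make_record(1:3, alt = "C"), make_record(4, gt = "AA", alt = "C"))
  sub_same <- full
  expect_equal(as.numeric(allreads_concordance(full, sub_same, "SNV")), 1)
  sub_missing <- full[-2, ]
  expect_equal(as.numeric(allreads_concordance(full, sub_missing, "SNV")), 0.75)
  sub_diffalt <- full
  sub_diffalt$alt[1] <- "T"
  expect_equal(as.numeric(allreads_concordance(full, sub_diffalt, "SNV")), 0.75)
  expect_error(allreads_concordance(full, sub_same, "indel"), "no indel")
})

test_that("variant counts split PASS records by type", {
  rec <- rbind(make_record(1:3),
               make_record(4, filter = "QD"),
               make_record(5:6, ref = "AT", alt = "A", vtype = "indel"))
  cv <- count_variants(rec)
  expect_equal(cv, list(n_snv = 3L, n_indel = 2L, n_total = 5L))
  empty <- count_variants(rec[0, ])
  expect_equal(empty$n_total, 0L)
})

test_that("called variant counts increase with subsampling fraction in expectation", {
  cfg <- tiny_config(n_variants = 5000, genome_length = 1e7, base_seed = 29L)
  truth <- generate_truth(cfg)
  cs <- apply_hard_filter(simulate_callset(truth, 30, seed = 31L, config = cfg))
  totals <- vapply(c(0.2, 0.5, 0.9), function(f) {
    mean(vapply(1:20, function(s) {
      count_variants(subsample_fraction(cs$records, f, seed = s))$n_total
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(totals) > 0))
})
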