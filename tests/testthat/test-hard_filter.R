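test_that("single-item violations are flagged by name and boundaries pass", {
  rec <- rbind(
    make_record(100, QD = 1.5),                       # QD < 2.0
    make_record(200, HaplotypeScore = 14),            # HaplotypeScore > 13.0
    make_record(300, vtype = "indel", ref = "AT", alt = "A", FS = 100),
    make_record(400, QD = 2.0),                       # boundary passes
    make_record(500, FS = 60.0),
    make_record(600, SOR = 3.0)
  )
  out <- apply_hard_filter(rec)
  expect_identical(out$filter,
                   c("QD", "HaplotypeScore", "PASS", "PASS", "PASS", "PASS"))
})

test_that("indels use their own thresholds and rule set", {
  rec <- rbind(
    make_record(1, vtype = "indel", ref = "A", alt = "AT", FS = 250),
    make_record(2, vtype = "indel", ref = "A", alt = "AT", SOR = 5),   # SNV would fail
    make_record(3, vtype = "indel", ref = "A", alt = "AT", MQ = 10),   # MQ not an indel rule
    make_record(4, vtype = "indel", ref = "A", alt = "AT", ReadPosRankSum = -21)
  )
  out <- apply_hard_filter(rec)
  expect_identical(out$filter, c("FS", "PASS", "PASS", "ReadPosRankSum"))
})

test_that("missing annotations never trigger their rule", {
  rec <- make_record(1, MQRankSum = NA, ReadPosRankSum = NA)
  expect_identical(apply_hard_filter(rec)$filter, "PASS")
  rec2 <- make_record(2)
  rec2$HaplotypeScore <- NULL
  expect_identical(apply_hard_filter(rec2)$filter, "PASS")
})

test_that("filtering is idempotent and multi-item failures record every item", {
  rec <- rbind(make_record(1, QD = 1, SOR = 9, FS = 80), make_record(2))
  once <- apply_hard_filter(rec)
  expect_identical(once$filter[1], "QD;FS;SOR")
  expect_identical(apply_hard_filter(once), once)
  expect_error(apply_hard_filter(make_record(1, vtype = "MNP")), "vtype")
})

test_that("exclusion rates count each failing record once per item", {
  rec <- rbind(
    make_record(1:2, HaplotypeScore = 14),
    make_record(3:10)
  )
  rates <- exclusion_rates(apply_hard_filter(rec))
  expect_equal(rates$rate[rates$item == "HaplotypeScore"], 20)
  expect_equal(sum(rates$rate[rates$item != "HaplotypeScore"]), 0)
  expect_true(all(rates$rate >= 0 & rates$rate <= 100))
  expect_error(exclusion_rates(rec[0, ]), "no records")
  expect_error(exclusion_rates(make_record(1, filter = ".")), "filter status")
})

test_that("within-range annotation distributions give 100 percent PASS", {
  cfg <- tiny_config(n_variants = 2000, genome_length = 1e7,
                     ann_model = clean_ann_model())
  truth <- generate_truth(cfg)
  cs <- apply_hard_filter(simulate_callset(truth, 30, seed = 5L, config = cfg))
  expect_true(all(cs$records$filter == "PASS"))
})

test_that("HaplotypeScore exclusion grows with the artifact weight", {
  cfg0 <- tiny_config(n_variants = 3000, genome_length = 1e7)
  truth <- generate_truth(cfg0)
  rates <- vapply(c(0.01, 0.05, 0.2), function(w) {
    am <- clean_ann_model()
    am$artifact_weight["HaplotypeScore"] <- w
    cfg <- tiny_config(n_variants = 3000, genome_length = 1e7, ann_model = am)
    cs <- apply_hard_filter(simulate_callset(truth, 30, seed = 11L, config = cfg))
    exclusion_rates(cs)$rate[exclusion_rates(cs)$item == "HaplotypeScore"]
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("the pass-through strategy marks everything PASS", {
  rec <- rbind(make_record(1, QD = 0.1), make_record(2, FS = 500))
  expect_identical(filter_strategy("pass")(rec)$filter, c("PASS", "PASS"))
})
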