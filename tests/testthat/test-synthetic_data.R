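test_that("truth generation is deterministic and respects sizing limits", {
  cfg <- tiny_config(n_variants = 1000, genome_length = 1e6, base_seed = 1L)
  expect_identical(generate_truth(cfg), generate_truth(cfg))
  expect_error(generate_truth(tiny_config(n_variants = 100, genome_length = 50)),
               "exceeds genome_length")
})

test_that("truth catalog structure follows the configuration", {
  truth <- generate_truth(tiny_config(n_variants = 2000, indel_fraction = 0))
  expect_equal(nrow(truth), 2000L)
  expect_true(all(truth$vtype == "SNV"))
  expect_true(all(truth$ref != truth$alt))

  truth2 <- generate_truth(tiny_config(n_variants = 4000, indel_fraction = 0.3,
                                       base_seed = 7L))
  frac <- mean(truth2$vtype == "indel")
  se <- sqrt(0.3 * 0.7 / 4000)
  expect_lt(abs(frac - 0.3), 3 * se)
  snv <- truth2$vtype == "SNV"
  expect_true(all(nchar(truth2$ref[snv]) == 1 & nchar(truth2$alt[snv]) == 1))
  expect_true(all(nchar(truth2$ref[!snv]) > 1 | nchar(truth2$alt[!snv]) > 1))
  # hom-ref genotypes only on the array evaluation subset
  expect_true(all(truth2$on_array[truth2$truth_gt == "RR"]))
  expect_true(all(truth2$aaf >= 0 & truth2$aaf <= 1))
})

test_that("genotypes follow Hardy-Weinberg at a fixed allele frequency", {
  # at AAF 0.5 the heterozygote share is 2pq = 0.5; array_fraction 1 keeps
  # the unconditional HWE draw for every site
  cfg <- tiny_config(n_variants = 10000, genome_length = 1e7,
                     indel_fraction = 0, array_fraction = 1,
                     aaf_spec = list(dist = "fixed", value = 0.5),
                     base_seed = 3L)
  truth <- generate_truth(cfg)
  het <- mean(truth$truth_gt == "RA")
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(het - 0.5), 3 * se)
})

test_that("AAF bin occupancy recovers the configured spectrum", {
  spec <- list(dist = "beta", shape1 = 0.25, shape2 = 0.8)
  cfg <- tiny_config(n_variants = 20000, genome_length = 1e7,
                     aaf_spec = spec, base_seed = 5L)
  truth <- generate_truth(cfg)
  occ <- prop.table(table(aaf_bin(truth$aaf)))
  edges <- c(0, 0.01, 0.05, 0.1, 0.5, 1)
  expected <- diff(pbeta(edges, spec$shape1, spec$shape2))
  expect_true(all(occ > 0))
  for (b in seq_along(expected)) {
    se <- sqrt(expected[b] * (1 - expected[b]) / 20000)
    expect_lt(abs(occ[[b]] - expected[b]), 3 * se)
  }
})

test_that("site missingness matches the Poisson zero class", {
  cfg <- tiny_config(n_variants = 20000, genome_length = 1e7,
                     error_model = clean_error_model(), base_seed = 9L)
  truth <- generate_truth(cfg)
  carriers <- sum(truth$truth_gt != "RR")
  d <- 0.05
  cs <- simulate_callset(truth, d, seed = 21L, config = cfg)
  absent <- 1 - nrow(cs$records) / carriers
  p <- exp(-d)
  se <- sqrt(p * (1 - p) / carriers)
  expect_lt(abs(absent - p), 3 * se)
})

test_that("an error-free call set reproduces the truth at every covered site", {
  cfg <- tiny_config(n_variants = 1000, genome_length = 1e6,
                     error_model = clean_error_model(), base_seed = 2L)
  truth <- generate_truth(cfg)
  cs <- simulate_callset(truth, 100, seed = 4L, config = cfg)
  idx <- match(cs$records$pos, truth$pos)
  expect_false(anyNA(idx))
  expect_identical(cs$records$gt, truth$truth_gt[idx])
  expect_identical(cs$records$alt, truth$alt[idx])
})

test_that("identical seeds give byte-identical VCF output", {
  cfg <- tiny_config(n_variants = 400, base_seed = 6L)
  truth <- generate_truth(cfg)
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_callset_vcf(simulate_callset(truth, 10, seed = 8L, config = cfg), f1)
  write_callset_vcf(simulate_callset(truth, 10, seed = 8L, config = cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_gt(length(readLines(f1)), 20L)
})

test_that("VCF call sets round-trip through write and read", {
  cfg <- tiny_config(n_variants = 300, base_seed = 13L)
  truth <- generate_truth(cfg)
  cs <- apply_hard_filter(simulate_callset(truth, 20, seed = 1L, config = cfg))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_callset_vcf(cs, path)
  back <- read_callset_vcf(path)
  expect_equal(nrow(back), nrow(cs$records))
  expect_identical(back$gt, cs$records$gt)
  expect_identical(back$pos, as.integer(cs$records$pos))
  expect_identical(back$filter, cs$records$filter)
  expect_equal(back$QD, cs$records$QD, tolerance = 1e-3)
  # hom-alt records dropped their rank sums on write and read back as NA
  expect_true(all(is.na(back$MQRankSum[back$gt == "AA"])))
})

test_that("HLA call simulation honours error rates and availability masks", {
  cfg <- tiny_config(hla_error = list(floor_rates = c(
    PHLAT = 0, `HLA-VBseq` = 0, `HLA-HD` = 0, `HISAT-genotype` = 0, SNP2HLA = 0
  ), decay = 1e-9))
  truth <- default_hla_truth()
  calls <- generate_hla_calls(truth, hla_tools(), depth = 30, seed = 1L,
                              config = cfg)
  # zero miscall probability: every available call equals truth
  avail <- hla_gene_available(calls$tool, calls$gene)
  scored <- hla_score_table(truth, calls)
  expect_true(all(scored$score[avail] == 1))
  # masked pairs are NA
  expect_true(all(is.na(calls$allele1[!avail])))
  expect_setequal(calls$gene[!avail], c("DPA1", "DPB1"))
  expect_setequal(calls$tool[!avail], c("PHLAT", "HLA-VBseq"))

  # miscall probability 1 for one tool drives its per-gene accuracy to 0
  cfg_bad <- tiny_config(hla_error = list(floor_rates = c(
    PHLAT = 1, `HLA-VBseq` = 0, `HLA-HD` = 0, `HISAT-genotype` = 0, SNP2HLA = 0
  ), decay = 1e-9))
  bad <- hla_score_table(truth, generate_hla_calls(truth, "PHLAT", 100, 2L, cfg_bad))
  expect_true(all(hla_gene_accuracy(bad$score[!is.na(bad$score)]) == 0))

  expect_error(
    generate_hla_calls(data.frame(gene = "DRB9", allele1 = "01:01",
                                  allele2 = "01:01"),
                       "PHLAT", 10, 1L, cfg),
    "unknown HLA gene"
  )
})

test_that("HLA call simulation is deterministic for a fixed seed", {
  cfg <- tiny_config()
  a <- generate_hla_calls(default_hla_truth(), hla_tools(), 5, 77L, cfg)
  b <- generate_hla_calls(default_hla_truth(), hla_tools(), 5, 77L, cfg)
  expect_identical(a, b)
})
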