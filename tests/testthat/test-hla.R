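test_that("genotype scoring gives per-allele credit and ignores allele order", {
  expect_equal(hla_score_genotype(c("24:02", "24:02"), c("24:02", "24:02")), 1)
  expect_equal(hla_score_genotype(c("24:02", "24:02"), c("24:02", "11:01")), 0.5)
  expect_equal(hla_score_genotype(c("09:01", "14:54"), c("14:54", "09:01")), 1)
  expect_equal(hla_score_genotype(c("09:01", "14:54"), c("01:01", "02:02")), 0)
  # symmetric under reordering of either argument
  withr::with_seed(1, {
    pool <- c("01:01", "02:01", "03:03")
    for (i in 1:20) {
      t <- sample(pool, 2, replace = TRUE)
      c1 <- sample(pool, 2, replace = TRUE)
      expect_equal(hla_score_genotype(t, c1), hla_score_genotype(rev(t), rev(c1)))
      expect_equal(hla_score_genotype(t, c1), hla_score_genotype(t, rev(c1)))
    }
  })
  expect_true(is.na(hla_score_genotype(c("01:01", "02:01"), c(NA, NA))))
})

test_that("allele strings normalize to four-digit resolution", {
  expect_equal(normalize_hla_allele("A*24:02"), "24:02")
  expect_equal(normalize_hla_allele("24:02:01:02"), "24:02")
  expect_equal(hla_score_genotype(c("A*24:02:01", "24:02"), c("24:02", "24:02")), 1)
})

test_that("per-gene accuracy averages replicate scores as percent", {
  expect_equal(hla_gene_accuracy(c(rep(1, 9), 0.5)), 95)
  expect_equal(hla_gene_accuracy(rep(1, 10)), 100)
  expect_equal(hla_gene_accuracy(rep(0, 4)), 0)
  expect_error(hla_gene_accuracy(numeric(0)), "no scores")
})

test_that("tool averages cover available genes only", {
  expect_equal(hla_average_accuracy(c(100, 60, 40, 40, 100, 100, NA, NA)), 73.3)
  expect_equal(hla_average_accuracy(c(95, 90, 100, 100, 100, 90, 100, 100)), 96.9)
  expect_equal(hla_average_accuracy(rep(88.8, 8)), 88.8)  # constant map
  expect_error(hla_average_accuracy(c(NA_real_, NA_real_)), "all genes unavailable")
})

test_that("score tables join calls to truth by gene", {
  truth <- default_hla_truth()
  calls <- data.frame(tool = "X", gene = c("A", "DRB1"),
                      allele1 = c("24:02", "09:01"),
                      allele2 = c("11:01", "14:54"), stringsAsFactors = FALSE)
  sc <- hla_score_table(truth, calls)
  expect_equal(sc$score, c(0.5, 1))
  bad <- calls
  bad$gene[1] <- "DRB9"
  expect_error(hla_score_table(truth, bad), "absent from truth")
})

test_that("the accuracy report tabulates genes, tools and averages", {
  scores <- rbind(
    data.frame(tool = "t1", gene = rep(c("A", "B"), each = 2),
               score = c(1, 1, 0.5, 0.5)),
    data.frame(tool = "t2", gene = c("A", "B"), score = c(NA, 1))
  )
  rep_tab <- hla_accuracy_report(scores)
  expect_equal(rep_tab$gene, c("A", "B", "Average"))
  expect_equal(rep_tab$t1, c(100, 50, 75))
  expect_equal(rep_tab$t2, c(NA, 100, 100))
})
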