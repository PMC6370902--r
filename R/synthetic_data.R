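#' Generate a diploid truth catalog
#'
#' Draws `n_variants` distinct sites on one contig. Each site carries an
#' alternate-allele frequency (AAF) from the configured spectrum, a diploid
#' genotype drawn under Hardy-Weinberg equilibrium at that frequency, a
#' variant type (SNV alleles honour the configured Ts/Tv target; indels are
#' 1-3 bp insertions or deletions), and, for SNV sites sampled onto the
#' microarray panel, genotyping QC metadata (call rate, HWE p-value,
#' observed MAF, multi-allelism flag).
#'
#' Hom-ref genotypes are retained only for on-array sites (those exist on an
#' array regardless of the individual's genotype); a non-array site is a
#' variant the individual carries, so hom-ref draws there are resampled
#' conditional on carrying at least one alternate allele.
#'
#' @param config A [sim_config()].
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt`, `vtype`
#'   (`"SNV"`/`"indel"`), `truth_gt` (`"RR"`/`"RA"`/`"AA"`), `aaf`,
#'   `on_array`, `call_rate`, `hwe_p`, `maf`, `multi_allelic` (QC columns
#'   `NA` off-array), sorted by position. Deterministic for a fixed
#'   `base_seed`.
#' @examples
#' truth <- generate_truth(sim_config(n_variants = 500, base_seed = 1))
#' table(truth$vtype, truth$truth_gt)
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_variants
  if (n > config$genome_length) {
    stop("n_variants (", n, ") exceeds genome_length (", config$genome_length,
         "): cannot place distinct sites", call. = FALSE)
  }
  withr::with_seed(config$base_seed, {
    pos <- sort(sample(config$genome_length, n))
    vtype <- ifelse(stats::runif(n) < config$indel_fraction, "indel", "SNV")
    aaf <- draw_aaf(n, config$aaf_spec)

    # SNV alleles with the target Ts/Tv mix
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
    purine <- ref %in% c("A", "G")
    tv1 <- ifelse(purine, "C", "A")
    tv2 <- ifelse(purine, "T", "G")
    is_ts <- stats::runif(n) < config$tstv / (1 + config$tstv)
    alt <- ifelse(is_ts, ts_partner[ref], ifelse(stats::runif(n) < 0.5, tv1, tv2))

    # indel alleles: anchor base plus a 1-3 bp inserted/deleted segment
    idx_ind <- which(vtype == "indel")
    if (length(idx_ind)) {
      seg_len <- sample(1:3, length(idx_ind), replace = TRUE)
      seg <- vapply(seg_len, function(l)
        paste(sample(bases, l, replace = TRUE), collapse = ""), character(1))
      anchor <- sample(bases, length(idx_ind), replace = TRUE)
      is_del <- stats::runif(length(idx_ind)) < 0.5
      ref[idx_ind] <- ifelse(is_del, paste0(anchor, seg), anchor)
      alt[idx_ind] <- ifelse(is_del, anchor, paste0(anchor, seg))
    }

    # HWE genotypes; array membership is SNV-only
    p <- aaf
    q <- 1 - p
    u <- stats::runif(n)
    gt <- ifelse(u < q^2, "RR", ifelse(u < q^2 + 2 * p * q, "RA", "AA"))
    on_array <- vtype == "SNV" & stats::runif(n) < config$array_fraction
    resample <- gt == "RR" & !on_array
    if (any(resample)) {
      # conditional on carrying an alt allele: P(RA) : P(AA) = 2q : p
      pr <- p[resample]
      qr <- q[resample]
      gt[resample] <- ifelse(stats::runif(sum(resample)) < 2 * qr / (2 * qr + pr),
                             "RA", "AA")
    }

    call_rate <- hwe_p <- maf <- rep(NA_real_, n)
    multi_allelic <- rep(NA, n)
    ia <- which(on_array)
    if (length(ia)) {
      call_rate[ia] <- clamp(1 - stats::rexp(length(ia), rate = 500), 0, 1)
      hwe_p[ia] <- stats::runif(length(ia))
      maf[ia] <- clamp(pmin(aaf[ia], 1 - aaf[ia]) +
                         stats::rnorm(length(ia), 0, 0.002), 0, 0.5)
      multi_allelic[ia] <- stats::runif(length(ia)) < 0.01
    }

    data.frame(chrom = "1", pos = pos, ref = ref, alt = alt, vtype = vtype,
               truth_gt = gt, aaf = aaf, on_array = on_array,
               call_rate = call_rate, hwe_p = hwe_p, maf = maf,
               multi_allelic = multi_allelic, stringsAsFactors = FALSE)
  })
}

draw_aaf <- function(n, spec) {
  x <- switch(spec$dist,
    beta = stats::rbeta(n, spec$shape1, spec$shape2),
    fixed = rep(spec$value, n),
    uniform = stats::runif(n),
    stop("unknown aaf_spec dist: ", spec$dist, call. = FALSE)
  )
  clamp(x, 1e-4, 1 - 1e-4)
}

#' Simulate a depth-dependent call set
#'
#' Emulates the output of an alignment + caller + annotation pipeline at a
#' target mean depth. Each truth site receives a Poisson(depth) read count;
#' sites below the callable floor are absent. At heterozygous sites the
#' sampled reads are split Binomial(k, 1/2) between alleles, so single-allele
#' draws produce allele dropout (all-ref: the site is not called; all-alt: a
#' spurious hom-alt call) -- the mechanism that makes low-depth call sets
#' both sparse and error-prone. Flat per-site error rates add residual het /
#' hom-alt / hom-ref genotype errors and wrong-alternate-allele calls, and a
#' configurable rate of false-positive records is placed at non-truth
#' positions. Every record carries `DP` and the seven GATK-style annotations
#' (`QD`, `FS`, `MQ`, `MQRankSum`, `ReadPosRankSum`, `SOR`,
#' `HaplotypeScore`), each drawn from a passing ("clean") component or, with
#' the configured artifact weight, from a failing component; the
#' HaplotypeScore artifact weight grows with depth above the configured knee.
#' Rank-sum annotations are absent (`NA`) on hom-alt records, where no
#' reference reads exist to rank.
#'
#' @param truth Truth catalog from [generate_truth()].
#' @param depth Target mean depth (fold-coverage, > 0).
#' @param seed Integer seed for this dataset.
#' @param config The [sim_config()] used to build `truth`.
#' @param replicate_id Replicate index recorded in the result.
#' @return A `wgs_callset`: list with `target_depth`, `replicate_id`,
#'   `records` (data.frame of VCF-style records with `filter = "."`,
#'   position-sorted), `read_accounting` (per-stage total base counts and the
#'   effective reference length) and `seed`.
#' @examples
#' cfg <- sim_config(n_variants = 200, base_seed = 1)
#' truth <- generate_truth(cfg)
#' cs <- simulate_callset(truth, depth = 30, seed = 99, config = cfg)
#' head(cs$records)
#' @export
simulate_callset <- function(truth, depth, seed, config, replicate_id = 1L) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(truth))
  stop_if_not_scalar_num(depth, "depth")
  if (depth <= 0) stop("depth must be > 0", call. = FALSE)
  em <- config$error_model

  withr::with_seed(as.integer(seed), {
    n <- nrow(truth)
    k <- stats::rpois(n, depth)
    callable <- k >= em$floor

    # --- records at carrier truth sites -------------------------------------
    carrier <- truth$truth_gt != "RR" & callable
    gt <- truth$truth_gt[carrier]
    kk <- k[carrier]
    drop_site <- rep(FALSE, length(gt))

    if (isTRUE(em$dropout)) {
      het <- which(gt == "RA")
      if (length(het)) {
        alt_reads <- stats::rbinom(length(het), kk[het], 0.5)
        drop_site[het[alt_reads == 0]] <- TRUE      # no alt read: not called
        gt[het[alt_reads == kk[het]]] <- "AA"       # no ref read: hom-alt call
      }
    }
    het <- which(gt == "RA" & !drop_site)
    if (length(het) && em$het_error > 0) {
      err <- het[stats::runif(length(het)) < em$het_error]
      to_rr <- err[stats::runif(length(err)) < 0.5]
      drop_site[to_rr] <- TRUE
      gt[setdiff(err, to_rr)] <- "AA"
    }
    hom <- which(gt == "AA" & !drop_site & truth$truth_gt[carrier] == "AA")
    if (length(hom) && em$hom_error > 0) {
      gt[hom[stats::runif(length(hom)) < em$hom_error]] <- "RA"
    }

    keep <- !drop_site
    rec_truth <- data.frame(
      chrom = truth$chrom[carrier][keep],
      pos = truth$pos[carrier][keep],
      ref = truth$ref[carrier][keep],
      alt = truth$alt[carrier][keep],
      gt = gt[keep],
      dp = kk[keep],
      vtype = truth$vtype[carrier][keep],
      stringsAsFactors = FALSE
    )

    # --- spurious het calls at callable array hom-ref sites -----------------
    rr <- which(truth$truth_gt == "RR" & callable)
    rr <- rr[stats::runif(length(rr)) < em$homref_error]
    rec_rr <- if (length(rr)) data.frame(
      chrom = truth$chrom[rr], pos = truth$pos[rr], ref = truth$ref[rr],
      alt = truth$alt[rr], gt = "RA", dp = k[rr], vtype = truth$vtype[rr],
      stringsAsFactors = FALSE
    ) else NULL

    rec <- rbind(rec_truth, rec_rr)

    # wrong alternate allele on a fraction of SNV calls
    if (em$alt_error > 0 && nrow(rec)) {
      swap <- which(rec$vtype == "SNV" & stats::runif(nrow(rec)) < em$alt_error)
      if (length(swap)) {
        rec$alt[swap] <- vapply(seq_along(swap), function(i) {
          sample(setdiff(c("A", "C", "G", "T"),
                         c(rec$ref[swap[i]], rec$alt[swap[i]])), 1)
        }, character(1))
      }
    }

    # --- false-positive records at non-truth positions ----------------------
    n_fp <- stats::rpois(1, em$fp_rate * n * (1 - exp(-depth)))
    if (n_fp > 0) {
      fp_pos <- setdiff(sample(config$genome_length, n_fp + 50L), truth$pos)
      fp_pos <- sort(fp_pos[seq_len(min(n_fp, length(fp_pos)))])
      m <- length(fp_pos)
      fp_ref <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
      fp_alt <- vapply(fp_ref, function(r)
        sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
      # conditional Poisson truncated at the callable floor
      p0 <- stats::ppois(em$floor - 1, depth)
      fp_dp <- stats::qpois(stats::runif(m, p0, 1), depth)
      rec_fp <- data.frame(
        chrom = "1", pos = fp_pos, ref = fp_ref, alt = fp_alt,
        gt = sample(c("RA", "AA"), m, replace = TRUE, prob = c(0.8, 0.2)),
        dp = fp_dp, vtype = "SNV", stringsAsFactors = FALSE
      )
      rec <- rbind(rec, rec_fp)
    }

    rec <- rec[order(rec$pos), , drop = FALSE]
    rownames(rec) <- NULL

    # --- annotations --------------------------------------------------------
    rec <- cbind(rec, draw_annotations(nrow(rec), rec$vtype, depth, config))
    rec$MQRankSum[rec$gt == "AA"] <- NA_real_
    rec$ReadPosRankSum[rec$gt == "AA"] <- NA_real_
    rec$filter <- "."

    structure(list(
      target_depth = depth,
      replicate_id = as.integer(replicate_id),
      records = rec,
      read_accounting = read_accounting(depth, config),
      seed = as.integer(seed)
    ), class = "wgs_callset")
  })
}

ANNOTATION_ITEMS <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum",
                      "SOR", "HaplotypeScore")

# Per-item clean/artifact mixtures. Clean draws sit inside the SNV passing
# ranges (which are at least as strict as the indel ones); artifact draws
# violate the item's own threshold for the record's variant type.
draw_annotations <- function(n, vtype, depth, config) {
  am <- config$ann_model
  w <- am$artifact_weight[ANNOTATION_ITEMS]
  names(w) <- ANNOTATION_ITEMS
  w[is.na(w)] <- 0
  w["HaplotypeScore"] <- w["HaplotypeScore"] +
    am$hs_depth_slope * max(0, log10(depth / am$hs_depth_knee))
  w <- clamp(w, 0, 1)

  out <- matrix(NA_real_, nrow = n, ncol = length(ANNOTATION_ITEMS),
                dimnames = list(NULL, ANNOTATION_ITEMS))
  if (n == 0L) return(as.data.frame(out))
  indel <- vtype == "indel"
  for (item in ANNOTATION_ITEMS) {
    fail <- stats::runif(n) < w[[item]]
    out[, item] <- ann_clean(item, n)
    nf <- sum(fail)
    if (nf) out[fail, item] <- ann_fail(item, nf, indel[fail])
  }
  as.data.frame(out)
}

ann_clean <- function(item, n) {
  switch(item,
    QD = clamp(stats::rnorm(n, 20, 5), 2.5, 40),
    FS = clamp(stats::rexp(n, 1 / 4), 0, 55),
    MQ = clamp(stats::rnorm(n, 59.5, 1.2), 41, 60),
    MQRankSum = clamp(stats::rnorm(n, 0, 1.5), -10, 10),
    ReadPosRankSum = clamp(stats::rnorm(n, 0, 1.2), -7, 7),
    SOR = clamp(stats::rlnorm(n, log(0.9), 0.35), 0, 2.9),
    HaplotypeScore = clamp(stats::rexp(n, 1 / 3), 0, 12.5)
  )
}

ann_fail <- function(item, n, indel) {
  switch(item,
    QD = stats::runif(n, 0, 1.9),
    FS = ifelse(indel, 200, 60) + stats::rexp(n, 1 / 40),
    MQ = stats::runif(n, 10, 39),
    MQRankSum = -12.5 - stats::rexp(n, 1 / 3),
    ReadPosRankSum = ifelse(indel, -20, -8) - stats::rexp(n, 1 / 4),
    SOR = ifelse(indel, 10, 3) + stats::rexp(n, 1 / 1.5),
    HaplotypeScore = 13 + stats::rexp(n, 1 / 8)
  )
}

# Per-stage total base counts implied by a target unique-read depth.
# Trimming and mapping lose fixed fractions; duplicate loss saturates with
# depth, reproducing the deeper-data-loses-more pattern of real libraries.
read_accounting <- function(depth, config) {
  ac <- config$accounting
  L <- config$genome_length
  urd_bases <- L * depth
  dup_retain <- 1 - ac$dup_sat * depth / (depth + ac$dup_half)
  mrd_bases <- urd_bases / dup_retain
  rrdat_bases <- mrd_bases / ac$map_retain
  rrd_bases <- rrdat_bases / ac$trim_retain
  list(rrd_bases = rrd_bases, rrdat_bases = rrdat_bases,
       mrd_bases = mrd_bases, urd_bases = urd_bases,
       effective_ref_length = L)
}

#' @export
print.wgs_callset <- function(x, ...) {
  cat(sprintf("<wgs_callset> target depth %.3gx, replicate %d, %d records, seed %d\n",
              x$target_depth, x$replicate_id, nrow(x$records), x$seed))
  invisible(x)
}

#' Simulate per-tool HLA genotype calls
#'
#' Emulates four-digit HLA typing output for a set of tools at one depth.
#' Each allele of each available (tool, gene) pair is independently miscalled
#' with probability `1 - (1 - floor) * (1 - exp(-depth/decay))`: typing is
#' near-random at vanishing depth and approaches each tool's asymptotic
#' per-allele error floor once reads saturate the locus. Miscalled alleles
#' are replaced by a different allele drawn from a per-gene pool of common
#' alternatives. Pairs a tool cannot type (DPA1/DPB1 for PHLAT and
#' HLA-VBseq) are emitted as `NA`.
#'
#' @param truth_hla Data.frame with columns `gene`, `allele1`, `allele2`
#'   (four-digit allele strings, e.g. `"24:02"`); one row per classical gene
#'   present. See [default_hla_truth()].
#' @param tools Character vector of tool labels; see [hla_tools()].
#' @param depth Target mean depth (fold-coverage).
#' @param seed Integer seed.
#' @param config A [sim_config()] (supplies `hla_error`).
#' @return Data.frame with columns `tool`, `gene`, `allele1`, `allele2`
#'   (`NA` alleles for unavailable pairs).
#' @examples
#' cfg <- sim_config()
#' calls <- generate_hla_calls(default_hla_truth(), hla_tools(), 13.7, 1, cfg)
#' subset(calls, tool == "PHLAT")
#' @export
generate_hla_calls <- function(truth_hla, tools = hla_tools(), depth, seed, config) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(truth_hla))
  bad <- setdiff(truth_hla$gene, HLA_GENES)
  if (length(bad)) {
    stop("unknown HLA gene label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    grid <- expand.grid(tool = tools, gene = truth_hla$gene,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    res <- lapply(seq_len(nrow(grid)), function(i) {
      tool <- grid$tool[i]
      gene <- grid$gene[i]
      if (!hla_gene_available(tool, gene)) {
        return(data.frame(tool = tool, gene = gene, allele1 = NA_character_,
                          allele2 = NA_character_, stringsAsFactors = FALSE))
      }
      tr <- truth_hla[truth_hla$gene == gene, ]
      truth_pair <- c(tr$allele1[1], tr$allele2[1])
      p <- hla_miscall_prob(tool, gene, depth, config)
      # a miscall is an allele outside the true genotype, so it never
      # earns partial credit by colliding with the other truth allele
      call <- vapply(truth_pair, function(a) {
        if (stats::runif(1) < p) hla_decoy(gene, exclude = truth_pair) else a
      }, character(1), USE.NAMES = FALSE)
      data.frame(tool = tool, gene = gene, allele1 = call[1], allele2 = call[2],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
}

hla_miscall_prob <- function(tool, gene, depth, config) {
  he <- config$hla_error
  fr <- he$floor_rates
  floor_rate <- if (is.list(fr)) {
    v <- fr[[tool]]
    if (is.null(v)) 0.1 else if (length(v) > 1L) (v[[gene]] %||% v[[1]]) else v
  } else {
    if (tool %in% names(fr)) fr[[tool]] else 0.1
  }
  clamp(1 - (1 - floor_rate) * (1 - exp(-depth / he$decay)), 0, 1)
}

hla_decoy <- function(gene, exclude = NULL) {
  pool <- setdiff(HLA_DECOY_POOL[[gene]], exclude)
  sample(pool, 1)
}

HLA_DECOY_POOL <- list(
  A = c("02:01", "02:06", "11:01", "24:02", "26:01", "31:01", "33:03"),
  B = c("07:02", "15:01", "35:01", "40:02", "44:03", "51:01", "52:01"),
  C = c("01:02", "03:03", "03:04", "04:01", "07:02", "12:02", "14:02"),
  DRB1 = c("01:01", "04:05", "08:03", "09:01", "14:54", "15:01", "15:02"),
  DQA1 = c("01:02", "01:03", "01:04", "03:02", "03:03", "05:01", "06:01"),
  DQB1 = c("03:01", "03:02", "03:03", "04:01", "05:03", "06:01", "06:02"),
  DPA1 = c("01:03", "02:01", "02:02", "04:01"),
  DPB1 = c("02:01", "02:02", "04:01", "04:02", "05:01", "09:01")
)
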