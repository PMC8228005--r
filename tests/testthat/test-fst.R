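test_that("a fixed difference gives FST 1 under both estimators", {
  g <- geno_from_counts(c(20, 0, 0), c(0, 0, 20))  # group I all 0, group II all 2
  for (est in c("weir_cockerham", "pure_drift_moment")) {
    tr <- fst_per_snp(g, est)
    expect_equal(tr$fst_raw, 1, tolerance = 1e-12)
  }
})

test_that("identical group frequencies give a non-positive finite-sample estimate", {
  # both groups at p = 0.5, n = 20 each, het counts at expectation
  g <- geno_from_counts(c(5, 10, 5), c(5, 10, 5))
  tr <- fst_per_snp(g, "weir_cockerham")
  expect_lte(tr$fst_raw, 0)
  sm <- smooth_track(tr, window_snps = 1, clamp_negative = TRUE)
  expect_identical(sm$fst_smooth, 0)
})

test_that("Weir-Cockerham matches the formula-transcription oracle", {
  g <- geno_from_counts(c(6, 8, 6), c(10, 8, 2))
  tr <- fst_per_snp(g, "weir_cockerham")
  expect_equal(tr$fst_raw, wc_oracle(c(6, 8, 6), c(10, 8, 2)), tolerance = 1e-12)

  set.seed(31)
  for (i in 1:100) {
    c1 <- as.vector(stats::rmultinom(1, sample(4:40, 1), runif(3, 0.05, 1)))
    c2 <- as.vector(stats::rmultinom(1, sample(4:40, 1), runif(3, 0.05, 1)))
    ptot <- (2 * (c1[3] + c2[3]) + c1[2] + c2[2]) / (2 * sum(c1, c2))
    if (ptot <= 0 || ptot >= 1 || sum(c1) < 2 || sum(c2) < 2) next
    tr <- fst_per_snp(geno_from_counts(c1, c2), "weir_cockerham")
    expect_equal(tr$fst_raw, wc_oracle(c1, c2), tolerance = 1e-12)
  }
})

test_that("variants failing preconditions get a missing FST", {
  # monomorphic overall and a group with < 2 called samples
  d <- cbind(c(2L, 2L, 2L, 2L), c(NA, NA, 1L, 2L))
  g <- genotype_matrix(d,
                       data.frame(id = c("mono", "thin"), chrom = "1",
                                  pos_bp = c(1L, 2L), allele_a = "A", allele_b = "B"),
                       data.frame(sample_id = c("a", "b", "c", "d"),
                                  group = c("I", "I", "II", "II")))
  tr <- fst_per_snp(g, "weir_cockerham")
  expect_true(all(is.na(tr$fst_raw)))
  expect_error(fst_per_snp(keep_samples_for_test(g, 1:2), "weir_cockerham"),
               "both groups")
})

test_that("smoothing reproduces hand-computable windows", {
  tr <- make_track(rep(0.3, 20))
  sm <- smooth_track(tr, 5)
  expect_equal(sm$fst_smooth, rep(0.3, 20), tolerance = 1e-12)

  spike <- make_track(c(rep(0, 9), 1, rep(0, 9)))
  sm5 <- smooth_track(spike, 5)
  expect_equal(sm5$fst_smooth[10], 0.2, tolerance = 1e-12)
  # truncated end windows renormalize: first SNP averages over 3 SNPs
  edge <- make_track(c(1, 0, 0, 0, 0, 0))
  sme <- smooth_track(edge, 5)
  expect_equal(sme$fst_smooth[1], 1 / 3, tolerance = 1e-12)
})

test_that("smoothing equals the naive reference on random multi-chromosome tracks", {
  set.seed(32)
  for (kernel in c("uniform_mean", "triangular")) {
    x <- runif(300)
    x[sample(300, 25)] <- NA
    chrom <- sort(rep_len(c("1", "2", "3"), 300))
    tr <- make_track(x, chrom = chrom)
    sm <- smooth_track(tr, 9, kernel)
    expect_equal(sm$fst_smooth, naive_smooth(x, chrom, 9, kernel), tolerance = 1e-12)
  }
})

test_that("a window longer than a chromosome degrades to its mean with a warning", {
  tr <- make_track(c(0.1, 0.2, 0.3), chrom = c("1", "1", "1"))
  expect_warning(sm <- smooth_track(tr, 9), "fewer SNPs")
  expect_equal(sm$fst_smooth, rep(0.2, 3), tolerance = 1e-12)
})

test_that("outlier calling is a strict rank rule", {
  tr <- make_track(rep(0.5, 100))
  sm <- smooth_track(tr, 1)
  flagged <- call_outliers(sm, 0.99)
  expect_identical(sum(flagged$is_outlier), 0L)

  set.seed(33)
  vals <- sample(seq(0.001, 1, length.out = 1000))
  tr2 <- smooth_track(make_track(vals), 1)
  fl <- call_outliers(tr2, 0.99)
  expect_identical(sum(fl$is_outlier), 10L)
  expect_setequal(tr2$id[fl$is_outlier], tr2$id[order(-vals)][1:10])

  # monotone-transform invariance of the flags
  tr3 <- tr2
  tr3$fst_smooth <- exp(5 * tr3$fst_smooth)
  fl3 <- call_outliers(tr3, 0.99)
  expect_identical(fl3$is_outlier, fl$is_outlier)
})

test_that("region merging respects the gap and conserves flagged SNPs", {
  tr <- make_track(rep(0, 3), pos_bp = c(1000000L, 1200000L, 5000000L))
  tr$fst_smooth <- c(0.5, 0.6, 0.7)
  tr$is_outlier <- TRUE
  regs <- merge_regions(tr, 1e6)
  expect_identical(nrow(regs), 2L)
  expect_identical(regs$n_snps, c(2L, 1L))
  expect_identical(regs$start_bp, c(1000000L, 5000000L))
  expect_identical(regs$end_bp, c(1200000L, 5000000L))
  expect_equal(regs$peak_fst_smooth, c(0.6, 0.7))

  none <- tr
  none$is_outlier <- FALSE
  expect_identical(nrow(merge_regions(none, 1e6)), 0L)

  set.seed(34)
  for (i in 1:10) {
    m <- 200
    t2 <- make_track(runif(m), chrom = sort(rep_len(c("1", "2"), m)),
                     pos_bp = as.integer(rep_len(cumsum(sample(1e4:2e6, 100)), m)))
    t2 <- smooth_track(t2, 1)
    t2$is_outlier <- runif(m) < 0.1
    regs <- merge_regions(t2, 1e6)
    expect_identical(sum(regs$n_snps), sum(t2$is_outlier))
    expect_identical(length(unlist(strsplit(regs$member_ids, ","))),
                     sum(t2$is_outlier))
  }
})

test_that("the scan composes its stages deterministically", {
  cfg <- sim_config(n_samples_per_group = 20, n_snps = 500, n_chromosomes = 2,
                    planted_windows = data.frame(chrom = "2", start_snp_index = 100,
                                                 n_snps = 10, delta = 0.6),
                    seed = 35)
  sim <- simulate_genotypes(cfg)
  s1 <- fst_scan(sim$genotypes, fst_config())
  s2 <- fst_scan(sim$genotypes, fst_config())
  expect_identical(s1$track, s2$track)
  expect_identical(s1$regions, s2$regions)
  # the planted window is recovered
  rec <- evaluate_recovery(s1, sim$truth)
  expect_identical(rec$sensitivity, 1)
})

test_that("null scans flag close to the nominal fraction", {
  cfg <- sim_config(n_samples_per_group = 30, n_snps = 2000, n_chromosomes = 2,
                    missing_rate = 0, seed = 36)
  sim <- simulate_genotypes(cfg)
  scan <- fst_scan(sim$genotypes, fst_config())
  m <- sum(!is.na(scan$track$fst_smooth))
  frac <- sum(scan$track$is_outlier, na.rm = TRUE) / m
  se <- sqrt(0.01 * 0.99 / m)
  expect_lt(abs(frac - 0.01), 3 * se + 1e-9)
})

test_that("the two estimators agree in the equal-n large-sample limit", {
  set.seed(37)
  m <- 1000; n <- 100
  pi_ <- runif(m, 0.1, 0.9)
  p1 <- pmin(0.99, pmax(0.01, pi_ + rnorm(m, 0, 0.08)))
  p2 <- pmin(0.99, pmax(0.01, pi_ + rnorm(m, 0, 0.08)))
  d <- cbind(matrix(rbinom(n * m, 2, rep(p1, each = n)), nrow = n))
  d2 <- cbind(matrix(rbinom(n * m, 2, rep(p2, each = n)), nrow = n))
  g <- genotype_matrix(rbind(d, d2),
                       data.frame(id = sprintf("v%04d", 1:m), chrom = "1",
                                  pos_bp = 1000L * (1:m), allele_a = "A",
                                  allele_b = "B"),
                       data.frame(sample_id = sprintf("s%03d", 1:(2 * n)),
                                  group = rep(c("I", "II"), each = n)))
  wc <- fst_per_snp(g, "weir_cockerham")$fst_raw
  dm <- fst_per_snp(g, "pure_drift_moment")$fst_raw
  ok <- !is.na(wc) & !is.na(dm)
  expect_gt(stats::cor(wc[ok], dm[ok]), 0.99)
})

test_that("peak smoothed FST in the planted window is monotone in delta", {
  deltas <- c(0.1, 0.25, 0.4, 0.6)
  peak_at <- function(delta, seed) {
    cfg <- sim_config(n_samples_per_group = 30, n_snps = 600, n_chromosomes = 1,
                      planted_windows = data.frame(chrom = "1", start_snp_index = 200,
                                                   n_snps = 15, delta = delta),
                      missing_rate = 0, seed = seed)
    sim <- simulate_genotypes(cfg)
    scan <- fst_scan(sim$genotypes, fst_config())
    win <- sim$truth$intervals
    inwin <- scan$track$chrom == win$chrom &
      scan$track$pos_bp >= win$start_bp & scan$track$pos_bp <= win$end_bp
    max(scan$track$fst_smooth[inwin], na.rm = TRUE)
  }
  # common random numbers: the same seeds across the delta grid
  peaks <- sapply(deltas, function(d) mean(sapply(101:103, function(s) peak_at(d, s))))
  expect_true(all(diff(peaks) > 0))
})

test_that("the pure-drift moment estimator is mean-unbiased for c", {
  cfg <- sim_config(n_samples_per_group = 50, n_snps = 2000, n_chromosomes = 1,
                    background_c = 0.05, missing_rate = 0, seed = 38)
  sim <- simulate_genotypes(cfg)
  ct <- fst_per_snp(sim$genotypes, "pure_drift_moment")$fst_raw
  expect_lt(abs(mean(ct, na.rm = TRUE) - 0.05), 0.2 * 0.05)
})

test_that("track and region writers produce readable files", {
  cfg <- sim_config(n_samples_per_group = 15, n_snps = 300, n_chromosomes = 2,
                    planted_windows = data.frame(chrom = "1", start_snp_index = 50,
                                                 n_snps = 8, delta = 0.6),
                    seed = 39)
  sim <- simulate_genotypes(cfg)
  scan <- fst_scan(sim$genotypes, fst_config(smooth_window_snps = 5))
  td <- withr::local_tempdir()
  write_fst_track(scan, file.path(td, "track.tsv"))
  tr <- utils::read.table(file.path(td, "track.tsv"), header = TRUE, sep = "\t",
                          comment.char = "#")
  expect_identical(nrow(tr), nrow(scan$track))
  write_regions(scan, file.path(td, "regions"))
  bed <- utils::read.table(file.path(td, "regions.bed"), sep = "\t")
  expect_identical(nrow(bed), nrow(scan$regions))
  # BED is 0-based half-open: width matches the inclusive span
  expect_identical(bed$V3 - bed$V2, scan$regions$end_bp - scan$regions$start_bp + 1L)
})
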