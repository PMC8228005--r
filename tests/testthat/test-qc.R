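test_that("missingness filter removes strictly above the threshold", {
  g <- random_genotypes(100, 3, seed = 4)
  g$dosage[1:2, 1] <- NA   # 2.0% missing: retained at the 2% threshold
  g$dosage[1:3, 2] <- NA   # 3.0% missing: removed
  r <- missingness_filter(g, 0.02)
  expect_identical(r$removed, "v002")
  expect_setequal(r$genotypes$variants$id, c("v001", "v003"))

  r0 <- missingness_filter(g, 0)
  expect_identical(r0$genotypes$variants$id, "v003")
})

test_that("HWE exact test matches the enumeration oracle for all totals <= 50", {
  worst <- 0
  for (n in 1:50) {
    for (n_AA in 0:n) {
      for (n_Aa in 0:(n - n_AA)) {
        n_aa <- n - n_AA - n_Aa
        worst <- max(worst, abs(hwe_exact_test(n_AA, n_Aa, n_aa) -
                                  hwe_oracle(n_AA, n_Aa, n_aa)))
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("HWE exact p agrees with chi-square in order of magnitude at n=121", {
  p_exact <- hwe_exact_test(14, 57, 50)
  expect_equal(p_exact, hwe_oracle(14, 57, 50), tolerance = 1e-12)
  cnt <- c(14, 57, 50)
  n <- sum(cnt)
  pA <- (2 * cnt[1] + cnt[2]) / (2 * n)
  expd <- n * c(pA^2, 2 * pA * (1 - pA), (1 - pA)^2)
  p_chisq <- stats::pchisq(sum((cnt - expd)^2 / expd), df = 1, lower.tail = FALSE)
  expect_lt(abs(log10(p_exact) - log10(p_chisq)), 1)
})

test_that("HWE edge cases: monomorphic p = 1, tiny-count enumeration, errors", {
  expect_identical(hwe_exact_test(7, 0, 0), 1)
  expect_identical(hwe_exact_test(0, 0, 9), 1)
  # 2 diploids with 2 A and 2 a alleles: attainable het counts {0, 2} with
  # P(0) = 1/3, P(2) = 2/3; observing het = 0 gives p = 1/3
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3, tolerance = 1e-12)
  expect_equal(hwe_exact_test(0, 2, 0), 1, tolerance = 1e-12)
  expect_error(hwe_exact_test(0, 0, 0), "at least one")
  expect_error(hwe_exact_test(-1, 2, 0), "non-negative")
})

test_that("HWE filter removes exactly the variants the oracle flags", {
  # an extreme heterozygote excess at n = 150 is maximally improbable
  g <- geno_from_counts(c(0, 75, 0), c(0, 75, 0))
  g$variants$id <- "het_excess"
  p <- hwe_oracle(0, 150, 0)
  r <- hwe_filter(g, 1e-7)
  expect_identical(length(r$removed) == 1L, p < 1e-7)
  # alpha = 0 removes nothing
  r0 <- hwe_filter(g, 0)
  expect_length(r0$removed, 0)
  # monomorphic variants are never removed
  gm <- geno_from_counts(c(0, 0, 40), c(0, 0, 40))
  expect_length(hwe_filter(gm, 1e-7)$removed, 0)
})

test_that("GRM matches the direct double-sum formula on random fixtures", {
  g <- random_genotypes(10, 20, missing_rate = 0.1, seed = 9)
  G <- grm(g)
  # oracle: explicit double loop over sample pairs
  p <- colMeans(g$dosage, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  d <- g$dosage[, keep, drop = FALSE]
  pk <- p[keep]
  scale <- 2 * sum(pk * (1 - pk))
  G2 <- matrix(0, 10, 10)
  for (i in 1:10) {
    for (j in 1:10) {
      acc <- 0
      for (k in seq_along(pk)) {
        xi <- if (is.na(d[i, k])) 0 else d[i, k] - 2 * pk[k]
        xj <- if (is.na(d[j, k])) 0 else d[j, k] - 2 * pk[k]
        acc <- acc + xi * xj
      }
      G2[i, j] <- acc / scale
    }
  }
  expect_lt(max(abs(G - G2)), 1e-10)
  expect_lt(max(abs(G - t(G))), 1e-12)
  expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("duplicated samples have GRM entry equal to their diagonal", {
  g <- random_genotypes(6, 40, seed = 10)
  g$dosage[2, ] <- g$dosage[1, ]
  G <- grm(g)
  expect_equal(G[1, 2], G[1, 1], tolerance = 1e-12)
  expect_equal(G[1, 2], G[2, 2], tolerance = 1e-12)
})

test_that("GRM errors when every variant is monomorphic", {
  g <- genotype_matrix(matrix(2L, nrow = 3, ncol = 2),
                       data.frame(id = c("a", "b"), chrom = "1",
                                  pos_bp = c(1L, 2L), allele_a = "A", allele_b = "B"),
                       data.frame(sample_id = c("x", "y", "z")))
  expect_error(grm(g), "monomorphic")
})

test_that("relatedness pruning leaves no over-cutoff pair and is greedy-minimal", {
  g <- random_genotypes(8, 60, seed = 12)
  expect_length(relatedness_prune(g, 0.75)$removed, 0)

  # a clone pair shares its GRM entry with the clone's diagonal (~0.7 in
  # this small fixture); prune at a cutoff below it
  gdup <- g
  gdup$dosage[2, ] <- gdup$dosage[1, ]
  r <- relatedness_prune(gdup, 0.5)
  expect_length(r$removed, 1)
  expect_true(r$removed %in% c("s001", "s002"))

  gcl <- g
  gcl$dosage[2, ] <- gcl$dosage[1, ]
  gcl$dosage[3, ] <- gcl$dosage[1, ]
  r3 <- relatedness_prune(gcl, 0.5)
  expect_length(r3$removed, 2)
  G <- grm(r3$genotypes)
  expect_lte(max(G[upper.tri(G)]), 0.5)
})

test_that("relatedness pruning postcondition holds on random related fixtures", {
  for (seed in 1:5) {
    g <- random_genotypes(12, 50, seed = seed)
    g$dosage[2, ] <- g$dosage[1, ]          # clone pair
    g$dosage[5, ] <- g$dosage[4, ]          # second clone pair
    r <- relatedness_prune(g, 0.5)
    G <- grm(r$genotypes)
    expect_lte(max(G[upper.tri(G)]), 0.5)
  }
})

test_that("LD pruning removes duplicated columns and respects chromosomes", {
  g <- random_genotypes(30, 10, n_chrom = 2, seed = 14)
  # duplicate one variant pair on each chromosome (r^2 = 1)
  g$dosage[, 2] <- g$dosage[, 1]
  g$dosage[, 7] <- g$dosage[, 6]
  r <- ld_prune(g, window_snps = 5, step_snps = 2, r2_max = 0.2)
  expect_true("v002" %in% r$removed)
  expect_true("v007" %in% r$removed)
  # an identical column on the other chromosome must not trigger removal
  g2 <- random_genotypes(30, 10, n_chrom = 2, seed = 15)
  g2$dosage[, 6] <- g2$dosage[, 1]  # v006 is on chromosome 2, v001 on 1
  r2 <- ld_prune(g2, window_snps = 5, step_snps = 2, r2_max = 0.2)
  expect_false(any(c("v001", "v006") %in% r2$removed))
})

test_that("LD pruning is a fixed point and rarely fires on independent variants", {
  g <- random_genotypes(200, 60, seed = 16)
  r <- ld_prune(g, window_snps = 10, step_snps = 3, r2_max = 0.2)
  expect_lt(length(r$removed), 15)
  r2 <- ld_prune(r$genotypes, window_snps = 10, step_snps = 3, r2_max = 0.2)
  expect_length(r2$removed, 0)
})

test_that("LD pruning validates the window/step configuration", {
  g <- random_genotypes(10, 10, seed = 17)
  expect_error(ld_prune(g, 5, 5, 0.2), "window_snps > step_snps")
  expect_error(ld_prune(g, 5, 0, 0.2), "step_snps")
})

test_that("the QC chain orders its filters and its counts reconcile", {
  g <- random_genotypes(40, 80, n_chrom = 2, missing_rate = 0.015,
                        groups = TRUE, seed = 18)
  g$dosage[2, ] <- g$dosage[1, ]                 # relatedness casualty
  g$dosage[, 3] <- g$dosage[, 2]                 # LD casualty
  res <- run_qc(g, qc_config(ld_window_snps = 10, ld_step_snps = 3))
  tab <- res$report$steps
  expect_identical(rownames(tab),
                   c("missingness", "hwe", "relatedness", "monomorphic", "ld"))
  # variant bookkeeping: in - removed of one step = in of the next
  vin <- tab$v_in; vrm <- tab$v_removed
  expect_identical(vin[-1], (vin - vrm)[-length(vin)])
  expect_identical(res$report$n_variants_out,
                   vin[length(vin)] - vrm[length(vrm)])
  expect_identical(res$report$n_samples_out,
                   res$report$n_samples_in - sum(tab$s_removed))
  expect_identical(sum(lengths(res$removed[c("missingness", "hwe", "monomorphic", "ld")])),
                   res$report$n_variants_in - res$report$n_variants_out)
})
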