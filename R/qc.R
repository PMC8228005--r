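# Quality-control chain: per-variant missingness, Hardy-Weinberg exact test,
# GRM-based relatedness pruning, sliding-window LD pruning. All four filters
# are implemented from first principles; the chain order is
# missingness -> HWE -> relatedness -> (monomorphic) -> LD.

#' Quality-control configuration
#'
#' Defaults are the thresholds commonly used on porcine SNP-array data:
#' variants with more than 2\% missing calls removed, Hardy-Weinberg exact
#' p-value below 1e-7 removed, samples pruned so no genomic-relationship
#' entry exceeds 0.75, and LD pruning with a 50-SNP window advanced by 5 SNPs
#' at r-squared 0.2.
#'
#' @param max_missing_rate maximum tolerated per-variant missing fraction;
#'   removal is strict (`> max_missing_rate` removes).
#' @param hwe_alpha Hardy-Weinberg exact-test p-value threshold; variants
#'   with `p < hwe_alpha` are removed.
#' @param rel_cutoff maximum tolerated off-diagonal GRM entry between any
#'   retained pair of samples.
#' @param ld_window_snps,ld_step_snps,ld_r2_max sliding-window LD pruning
#'   parameters: window size in SNPs, step in SNPs, maximum squared Pearson
#'   correlation of dosages.
#' @return A classed list of validated settings.
#' @export
qc_config <- function(max_missing_rate = 0.02, hwe_alpha = 1e-7,
                      rel_cutoff = 0.75, ld_window_snps = 50,
                      ld_step_snps = 5, ld_r2_max = 0.2) {
  cfg <- list(max_missing_rate = max_missing_rate, hwe_alpha = hwe_alpha,
              rel_cutoff = rel_cutoff, ld_window_snps = as.integer(ld_window_snps),
              ld_step_snps = as.integer(ld_step_snps), ld_r2_max = ld_r2_max)
  if (cfg$max_missing_rate < 0 || cfg$max_missing_rate > 1)
    stop("max_missing_rate must be in [0, 1]")
  if (cfg$hwe_alpha < 0 || cfg$hwe_alpha > 1)
    stop("hwe_alpha must be in [0, 1]")
  if (cfg$rel_cutoff <= 0) stop("rel_cutoff must be positive")
  if (cfg$ld_step_snps < 1 || cfg$ld_window_snps <= cfg$ld_step_snps)
    stop("require ld_window_snps > ld_step_snps >= 1")
  if (cfg$ld_r2_max <= 0 || cfg$ld_r2_max > 1)
    stop("ld_r2_max must be in (0, 1]")
  structure(cfg, class = "qc_config")
}

#' Per-variant missingness filter
#'
#' Removes variants whose missing-call fraction strictly exceeds
#' `max_missing_rate`; a variant at exactly the threshold is retained.
#'
#' @param g a [genotype_matrix()].
#' @param max_missing_rate maximum tolerated missing fraction.
#' @return A list with elements `genotypes` (filtered matrix) and `removed`
#'   (character vector of removed variant ids).
#' @export
missingness_filter <- function(g, max_missing_rate = 0.02) {
  if (n_variants(g) == 0L) return(list(genotypes = g, removed = character()))
  miss <- per_variant_missing(g)
  drop <- miss > max_missing_rate
  list(genotypes = keep_variants(g, !drop), removed = g$variants$id[drop])
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test of Hardy-Weinberg genotype proportions: given the
#' observed allele counts, the probability of each attainable heterozygote
#' count is computed in closed form and the two-sided p-value is the sum of
#' the probabilities of all heterozygote counts no more probable than the
#' observed one. No mid-p correction is applied. Monomorphic variants have a
#' single attainable configuration and return p = 1.
#'
#' @param n_AA,n_Aa,n_aa observed genotype counts (non-negative, total >= 1).
#' @return The exact p-value, in (0, 1].
#' @examples
#' hwe_exact_test(14, 57, 50)
#' hwe_exact_test(25, 0, 0)   # monomorphic: p = 1
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotyped sample required")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  rare <- min(nA, na)
  h <- seq.int(rare %% 2L, rare, by = 2L)
  # log P(het = h | nA, na) up to the common normalizer
  logp <- lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
    lfactorial((na - h) / 2) + h * log(2)
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  pobs <- p[match(n_Aa, h)]
  min(1, sum(p[p <= pobs * (1 + 1e-12)]))
}

variant_geno_counts <- function(g) {
  d <- g$dosage
  cbind(n_AA = colSums(d == 2L, na.rm = TRUE),
        n_Aa = colSums(d == 1L, na.rm = TRUE),
        n_aa = colSums(d == 0L, na.rm = TRUE))
}

#' Hardy-Weinberg filter
#'
#' Applies [hwe_exact_test()] to every variant over all samples pooled and
#' removes variants with `p < alpha`.
#'
#' @param g a [genotype_matrix()] with at least one sample.
#' @param alpha p-value threshold.
#' @return A list with elements `genotypes` and `removed` (variant ids).
#' @export
hwe_filter <- function(g, alpha = 1e-7) {
  if (n_samples(g) < 1) stop("at least one sample required")
  if (n_variants(g) == 0L) return(list(genotypes = g, removed = character()))
  cnt <- variant_geno_counts(g)
  p <- vapply(seq_len(nrow(cnt)), function(j) {
    if (sum(cnt[j, ]) == 0) return(1)  # fully missing variant: untestable
    hwe_exact_test(cnt[j, 1], cnt[j, 2], cnt[j, 3])
  }, numeric(1))
  drop <- p < alpha
  list(genotypes = keep_variants(g, !drop), removed = g$variants$id[drop])
}

#' Genomic relationship matrix
#'
#' VanRaden method-1 GRM: dosages are centered at twice the observed allele
#' frequency, missing entries mean-imputed (centered to zero), and the
#' cross-product scaled by `2 * sum(p * (1 - p))` over polymorphic variants.
#' Monomorphic variants contribute nothing and are excluded from the scale.
#' The diagonal is approximately 1 plus the genomic inbreeding coefficient.
#'
#' @param g a [genotype_matrix()] with at least two samples.
#' @return A symmetric positive semi-definite matrix with sample-id dimnames.
#' @export
grm <- function(g) {
  if (n_samples(g) < 2) stop("at least two samples required")
  p <- colMeans(g$dosage, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("all variants are monomorphic: GRM scale is zero")
  d <- g$dosage[, poly, drop = FALSE]
  pj <- p[poly]
  z <- sweep(d, 2L, 2 * pj)
  z[is.na(z)] <- 0
  gmat <- tcrossprod(z) / (2 * sum(pj * (1 - pj)))
  dimnames(gmat) <- list(g$samples$sample_id, g$samples$sample_id)
  gmat
}

#' Relatedness pruning
#'
#' Computes the GRM once, then greedily removes samples until no off-diagonal
#' entry exceeds `cutoff`: at each step the sample participating in the most
#' over-cutoff pairs is dropped, ties broken by higher missingness and then
#' by lexicographically smaller sample id.
#'
#' @param g a [genotype_matrix()].
#' @param cutoff maximum tolerated off-diagonal GRM entry.
#' @return A list with elements `genotypes` and `removed` (sample ids).
#' @export
relatedness_prune <- function(g, cutoff = 0.75) {
  gmat <- grm(g)
  n <- nrow(gmat)
  ids <- g$samples$sample_id
  miss <- per_sample_missing(g)
  ut <- which(upper.tri(gmat) & gmat > cutoff, arr.ind = TRUE)
  removed <- character()
  active <- rep(TRUE, n)
  pairs <- ut
  while (nrow(pairs) > 0) {
    cnt <- tabulate(c(pairs[, 1], pairs[, 2]), nbins = n)
    cand <- which(cnt == max(cnt))
    cand <- cand[order(-miss[cand], ids[cand])]
    victim <- cand[1]
    removed <- c(removed, ids[victim])
    active[victim] <- FALSE
    pairs <- pairs[pairs[, 1] != victim & pairs[, 2] != victim, , drop = FALSE]
  }
  list(genotypes = keep_samples(g, active), removed = removed)
}

# r-squared on mean-imputed, variance-standardized dosages; a monomorphic
# column has zero variance and is treated as uncorrelated with everything.
dosage_r2 <- function(d) {
  mu <- colMeans(d, na.rm = TRUE)
  for (j in seq_len(ncol(d))) d[is.na(d[, j]), j] <- mu[j]
  sds <- apply(d, 2, stats::sd)
  r <- suppressWarnings(stats::cor(d))
  r[is.na(r)] <- 0
  diag(r) <- 1
  r^2
}

#' Sliding-window LD pruning
#'
#' Within each window of `window_snps` variants, advanced by `step_snps` and
#' never spanning chromosomes, any pair of retained variants with squared
#' Pearson correlation of (mean-imputed, standardized) dosages above
#' `r2_max` triggers removal of the later-positioned variant of the pair
#' (ties broken by lexicographically larger id) until no violating pair
#' remains.
#'
#' @param g a [genotype_matrix()] with variants sorted by (chrom, pos).
#' @param window_snps,step_snps,r2_max pruning parameters; see [qc_config()].
#' @return A list with elements `genotypes` and `removed` (variant ids).
#' @export
ld_prune <- function(g, window_snps = 50, step_snps = 5, r2_max = 0.2) {
  if (step_snps < 1 || window_snps <= step_snps)
    stop("require window_snps > step_snps >= 1")
  keep <- rep(TRUE, n_variants(g))
  for (chrom in unique(g$variants$chrom)) {
    idx <- which(g$variants$chrom == chrom)
    nv <- length(idx)
    if (nv < 2) next
    starts <- seq.int(1L, nv, by = step_snps)
    for (st in starts) {
      win <- idx[st:min(nv, st + window_snps - 1L)]
      win <- win[keep[win]]
      if (length(win) < 2) next
      r2 <- dosage_r2(g$dosage[, win, drop = FALSE])
      nw <- length(win)
      alive <- rep(TRUE, nw)
      for (a in seq_len(nw - 1L)) {
        if (!alive[a]) next
        for (b in seq.int(a + 1L, nw)) {
          if (!alive[b]) next
          if (r2[a, b] > r2_max) {
            # remove the later-positioned variant; positions are sorted so b
            # is later unless tied, then drop the lexicographically larger id
            drop_b <- g$variants$pos_bp[win[b]] > g$variants$pos_bp[win[a]] ||
              (g$variants$pos_bp[win[b]] == g$variants$pos_bp[win[a]] &&
                 g$variants$id[win[b]] > g$variants$id[win[a]])
            if (drop_b) alive[b] <- FALSE else { alive[a] <- FALSE; break }
          }
        }
      }
      keep[win[!alive]] <- FALSE
    }
  }
  list(genotypes = keep_variants(g, keep), removed = g$variants$id[!keep])
}

monomorphic_filter <- function(g) {
  if (n_variants(g) == 0L) return(list(genotypes = g, removed = character()))
  p <- colMeans(g$dosage, na.rm = TRUE) / 2
  drop <- is.na(p) | p <= 0 | p >= 1
  list(genotypes = keep_variants(g, !drop), removed = g$variants$id[drop])
}

#' Run the full QC chain
#'
#' Applies, in order: missingness filter, Hardy-Weinberg filter, relatedness
#' pruning, removal of variants left monomorphic after sample pruning (FST is
#' undefined for them), and LD pruning. Returns the filtered genotypes plus a
#' `qc_report` whose per-step counts reconcile exactly
#' (`in - removed = out`).
#'
#' @param g a [genotype_matrix()].
#' @param config a [qc_config()].
#' @return A list with elements `genotypes`, `report` (class `qc_report`),
#'   and `removed` (list of removed-id vectors per step).
#' @export
run_qc <- function(g, config = qc_config()) {
  stopifnot(inherits(config, "qc_config"))
  steps <- list()
  removed <- list()
  v_in <- n_variants(g); s_in <- n_samples(g)

  r <- missingness_filter(g, config$max_missing_rate)
  steps$missingness <- c(v_in = n_variants(g), v_removed = length(r$removed),
                         s_in = n_samples(g), s_removed = 0L)
  removed$missingness <- r$removed; g <- r$genotypes

  r <- hwe_filter(g, config$hwe_alpha)
  steps$hwe <- c(v_in = n_variants(g), v_removed = length(r$removed),
                 s_in = n_samples(g), s_removed = 0L)
  removed$hwe <- r$removed
  g <- r$genotypes

  r <- relatedness_prune(g, config$rel_cutoff)
  steps$relatedness <- c(v_in = n_variants(g), v_removed = 0L,
                         s_in = n_samples(g), s_removed = length(r$removed))
  removed$relatedness <- r$removed; g <- r$genotypes

  r <- monomorphic_filter(g)
  steps$monomorphic <- c(v_in = n_variants(g), v_removed = length(r$removed),
                         s_in = n_samples(g), s_removed = 0L)
  removed$monomorphic <- r$removed; g <- r$genotypes

  r <- ld_prune(g, config$ld_window_snps, config$ld_step_snps, config$ld_r2_max)
  steps$ld <- c(v_in = n_variants(g), v_removed = length(r$removed),
                s_in = n_samples(g), s_removed = 0L)
  removed$ld <- r$removed; g <- r$genotypes

  tab <- do.call(rbind, steps)
  report <- structure(list(steps = as.data.frame(tab),
                           n_variants_in = v_in, n_variants_out = n_variants(g),
                           n_samples_in = s_in, n_samples_out = n_samples(g)),
                      class = "qc_report")
  list(genotypes = g, report = report, removed = removed)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Quality control report\n")
  cat("  variants: ", x$n_variants_in, " -> ", x$n_variants_out,
      "   samples: ", x$n_samples_in, " -> ", x$n_samples_out, "\n", sep = "")
  tab <- x$steps
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-12s removed %d variant(s), %d sample(s)\n",
                rownames(tab)[i], tab$v_removed[i], tab$s_removed[i]))
  }
  invisible(x)
}

#' Write a QC report to TSV
#'
#' @param report a `qc_report` from [run_qc()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(report, path) {
  tab <- cbind(step = rownames(report$steps), report$steps)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# qc report: variants %d -> %d, samples %d -> %d",
                     report$n_variants_in, report$n_variants_out,
                     report$n_samples_in, report$n_samples_out), con)
  utils::write.table(tab, con, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
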