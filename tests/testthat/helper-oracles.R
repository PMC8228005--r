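# Independent oracles and fixture builders shared across the test files.
# Each oracle is a deliberately different derivation from the code path it
# checks (recurrence vs closed form, scalar loops vs vectorized algebra,
# all-pairs scans vs indexed overlap).

# Exact Hardy-Weinberg p-value by enumerating attainable heterozygote
# counts with the probability-ratio recurrence
#   P(h + 2) / P(h) = 4 * nAA(h) * naa(h) / ((h + 2) * (h + 1)),
# nAA(h) = (nA - h) / 2, naa(h) = (na - h) / 2.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  rare <- min(nA, na)
  hs <- seq.int(rare %% 2L, rare, by = 2L)
  p <- numeric(length(hs))
  p[1] <- 1
  for (i in seq_along(hs)[-1]) {
    h <- hs[i - 1]
    p[i] <- p[i - 1] * ((nA - h) / 2) * ((na - h) / 2) * 4 / ((h + 2) * (h + 1))
  }
  p <- p / sum(p)
  pobs <- p[match(n_Aa, hs)]
  min(1, sum(p[p <= pobs * (1 + 1e-12)]))
}

# Weir & Cockerham (1984) two-population theta-hat transcribed step by step
# from per-group genotype counts c = (n_aa, n_Aa, n_AA) i.e. dosage 0/1/2.
wc_oracle <- function(c1, c2) {
  n1 <- sum(c1); n2 <- sum(c2)
  p1 <- (2 * c1[3] + c1[2]) / (2 * n1)
  p2 <- (2 * c2[3] + c2[2]) / (2 * n2)
  h1 <- c1[2] / n1
  h2 <- c2[2] / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# O(n * w) reference smoother: explicit loop over centered shrinking
# windows with kernel weights, skipping NA values with renormalization.
naive_smooth <- function(x, chrom, window_snps, kernel = "uniform_mean") {
  h <- (window_snps - 1L) %/% 2L
  w_full <- if (kernel == "uniform_mean") rep(1, window_snps) else
    (h + 1) - abs(seq.int(-h, h))
  out <- rep(NA_real_, length(x))
  for (i in seq_along(x)) {
    acc <- 0; wsum <- 0
    for (off in -h:h) {
      j <- i + off
      if (j < 1 || j > length(x)) next
      if (chrom[j] != chrom[i]) next
      if (is.na(x[j])) next
      wt <- w_full[off + h + 1]
      acc <- acc + wt * x[j]
      wsum <- wsum + wt
    }
    if (wsum > 0) out[i] <- acc / wsum
  }
  out
}

# All-pairs interval intersector (1-based inclusive coordinates).
brute_overlap <- function(regions, ann) {
  hits <- list()
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(ann))) {
      if (regions$chrom[i] != ann$chrom[j]) next
      s <- max(regions$start_bp[i], ann$start_bp[j])
      e <- min(regions$end_bp[i], ann$end_bp[j])
      if (e >= s)
        hits[[length(hits) + 1]] <- data.frame(region = i, name = ann$name[j],
                                               overlap_bp = e - s + 1L,
                                               stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(data.frame(region = integer(), name = character(),
                                       overlap_bp = integer()))
  do.call(rbind, hits)
}

# Random genotype fixture with n samples, m variants on one or more
# chromosomes; optionally attaches alternating I/II groups.
random_genotypes <- function(n, m, n_chrom = 1, missing_rate = 0,
                             groups = FALSE, seed = 1) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  d <- matrix(rbinom(n * m, 2L, rep(p, each = n)), nrow = n)
  if (missing_rate > 0) d[runif(length(d)) < missing_rate] <- NA_integer_
  chrom <- sort(rep_len(as.character(seq_len(n_chrom)), m))
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix) seq(1000, by = 1000, length.out = length(ix))))
  variants <- data.frame(id = sprintf("v%03d", seq_len(m)),
                         chrom = chrom, pos_bp = unname(pos),
                         allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                        stringsAsFactors = FALSE)
  if (groups) samples$group <- rep(c("I", "II"), length.out = n)
  genotype_matrix(d, variants, samples)
}

# Build a two-group genotype matrix from per-group genotype counts
# c = (n dosage0, n dosage1, n dosage2) at a single variant.
geno_from_counts <- function(c1, c2) {
  d <- c(rep(0L, c1[1]), rep(1L, c1[2]), rep(2L, c1[3]),
         rep(0L, c2[1]), rep(1L, c2[2]), rep(2L, c2[3]))
  n <- length(d)
  genotype_matrix(matrix(d, ncol = 1),
                  data.frame(id = "v1", chrom = "1", pos_bp = 100L,
                             allele_a = "A", allele_b = "B"),
                  data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                             group = rep(c("I", "II"), c(sum(c1), sum(c2)))))
}

# Minimal FST track builder for smoothing/outlier/merge unit tests.
make_track <- function(fst_raw, chrom = "1", pos_bp = NULL) {
  m <- length(fst_raw)
  chrom <- rep_len(chrom, m)
  if (is.null(pos_bp)) pos_bp <- as.integer(seq_len(m) * 1000L)
  data.frame(id = sprintf("v%04d", seq_len(m)), chrom = chrom,
             pos_bp = pos_bp, fst_raw = fst_raw, fst_smooth = NA_real_,
             is_outlier = NA, stringsAsFactors = FALSE)
}

n_samples_of <- function(g) nrow(g$samples)

# re-run the constructor so metadata edits get re-validated and re-sorted
sort_variants_for_test <- function(g) genotype_matrix(g$dosage, g$variants, g$samples)

keep_samples_for_test <- function(g, idx) {
  genotype_matrix(g$dosage[idx, , drop = FALSE], g$variants,
                  g$samples[idx, , drop = FALSE])
}

annotation_set_for_test <- function(name, chrom, start_bp, len) {
  structure(data.frame(name = name, chrom = chrom,
                       start_bp = as.integer(start_bp),
                       end_bp = as.integer(start_bp + len),
                       category = NA_character_, stringsAsFactors = FALSE),
            class = c("annotation_set", "data.frame"))
}
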