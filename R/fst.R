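# Core computation: per-SNP FST between phenotype groups I and II, window
# smoothing, empirical-quantile outlier calling, and region merging.

#' FST scan configuration
#'
#' @param estimator `"weir_cockerham"` (two-population variance-components
#'   point estimate, the default) or `"pure_drift_moment"` (moment estimate
#'   of the drift parameter c under the pure-drift model, bias-corrected for
#'   binomial sampling of alleles).
#' @param smooth_window_snps odd window size, in SNPs, for track smoothing.
#' @param smooth_kernel `"uniform_mean"` or `"triangular"`.
#' @param outlier_quantile genome-wide empirical quantile above which a
#'   smoothed value is flagged (strictly above; default 0.99).
#' @param region_merge_gap_bp flagged SNPs on one chromosome closer than
#'   this are merged into one region (default 1 Mb).
#' @param clamp_negative clamp negative finite-sample FST estimates to zero
#'   before smoothing (default TRUE); unclamped values are retained in the
#'   track for audit.
#' @return A classed list of validated settings.
#' @export
fst_config <- function(estimator = c("weir_cockerham", "pure_drift_moment"),
                       smooth_window_snps = 9,
                       smooth_kernel = c("uniform_mean", "triangular"),
                       outlier_quantile = 0.99,
                       region_merge_gap_bp = 1e6,
                       clamp_negative = TRUE) {
  estimator <- match.arg(estimator)
  smooth_kernel <- match.arg(smooth_kernel)
  smooth_window_snps <- as.integer(smooth_window_snps)
  if (smooth_window_snps < 1 || smooth_window_snps %% 2 == 0)
    stop("smooth_window_snps must be an odd integer >= 1")
  if (outlier_quantile <= 0 || outlier_quantile >= 1)
    stop("outlier_quantile must be in (0, 1)")
  if (region_merge_gap_bp < 0) stop("region_merge_gap_bp must be >= 0")
  structure(list(estimator = estimator,
                 smooth_window_snps = smooth_window_snps,
                 smooth_kernel = smooth_kernel,
                 outlier_quantile = outlier_quantile,
                 region_merge_gap_bp = region_merge_gap_bp,
                 clamp_negative = clamp_negative),
            class = "fst_config")
}

group_freq_stats <- function(g) {
  grp <- g$samples$group
  if (nlevels(droplevels(grp[!is.na(grp)])) < 2 || !all(c("I", "II") %in% grp))
    stop("both groups I and II must be present; call attach_groups() first")
  d1 <- g$dosage[grp == "I" & !is.na(grp), , drop = FALSE]
  d2 <- g$dosage[grp == "II" & !is.na(grp), , drop = FALSE]
  list(n1 = colSums(!is.na(d1)), n2 = colSums(!is.na(d2)),
       p1 = colMeans(d1, na.rm = TRUE) / 2, p2 = colMeans(d2, na.rm = TRUE) / 2,
       h1 = colMeans(d1 == 1L, na.rm = TRUE), h2 = colMeans(d2 == 1L, na.rm = TRUE))
}

# Weir & Cockerham (1984) two-population theta-hat for diploid data,
# vectorized over variants. Returns NA where preconditions fail.
wc_theta <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  theta <- a / (a + b + cc)
  theta[a + b + cc == 0] <- NA_real_
  theta
}

# Moment estimate of the drift parameter c: group frequencies scatter around
# the pooled frequency with variance c * p(1-p). The unweighted two-group
# sample variance s2 = (p1-p2)^2 / 2 has expectation
# pi(1-pi) * [c + (1-c) * m], m the mean binomial sampling variance
# coefficient 1/(2 n_i) over groups; pi(1-pi) is estimated unbiasedly by
# pbar(1-pbar) + s2/2, and the estimator solves for c.
drift_moment_c <- function(n1, n2, p1, p2) {
  s2 <- (p1 - p2)^2 / 2
  pbar <- (2 * n1 * p1 + 2 * n2 * p2) / (2 * n1 + 2 * n2)
  m <- (1 / (2 * n1) + 1 / (2 * n2)) / 2
  t <- pbar * (1 - pbar) + s2 / 2
  ct <- (s2 / t - m) / (1 - m)
  ct[t == 0] <- NA_real_
  ct
}

#' Per-SNP FST between groups I and II
#'
#' Computes the raw per-variant differentiation track. A variant is skipped
#' (FST set to `NA`, excluded from smoothing) unless both groups have at
#' least two samples with non-missing calls and the variant is polymorphic
#' over all samples pooled.
#'
#' @param g a [genotype_matrix()] with groups attached.
#' @param estimator see [fst_config()].
#' @return A data.frame track with columns `id`, `chrom`, `pos_bp`,
#'   `fst_raw` (unclamped estimate), `fst_smooth` (`NA`, filled by
#'   [smooth_track()]) and `is_outlier` (`NA`, filled by [call_outliers()]).
#' @export
fst_per_snp <- function(g, estimator = c("weir_cockerham", "pure_drift_moment")) {
  estimator <- match.arg(estimator)
  st <- group_freq_stats(g)
  ptot <- (2 * st$n1 * st$p1 + 2 * st$n2 * st$p2) / (2 * st$n1 + 2 * st$n2)
  ok <- st$n1 >= 2 & st$n2 >= 2 & !is.na(ptot) & ptot > 0 & ptot < 1
  fst <- rep(NA_real_, n_variants(g))
  if (estimator == "weir_cockerham") {
    fst[ok] <- wc_theta(st$n1[ok], st$n2[ok], st$p1[ok], st$p2[ok],
                        st$h1[ok], st$h2[ok])
  } else {
    fst[ok] <- drift_moment_c(st$n1[ok], st$n2[ok], st$p1[ok], st$p2[ok])
  }
  data.frame(id = g$variants$id, chrom = g$variants$chrom,
             pos_bp = g$variants$pos_bp, fst_raw = fst,
             fst_smooth = NA_real_, is_outlier = NA,
             stringsAsFactors = FALSE)
}

kernel_weights <- function(window_snps, kernel) {
  h <- (window_snps - 1L) %/% 2L
  if (kernel == "uniform_mean") rep(1, window_snps)
  else (h + 1) - abs(seq.int(-h, h))  # triangular
}

# Kernel-weighted moving average with zero-padding at chromosome ends; the
# padding contributes zero weight to both numerator and denominator, which
# realizes the shrinking-window (renormalized) truncation. NA values drop
# out with renormalization the same way.
weighted_moving_average <- function(x, w) {
  nw <- length(w)
  h <- (nw - 1L) %/% 2L
  obs <- as.numeric(!is.na(x))
  x0 <- ifelse(is.na(x), 0, x)
  if (nw == 1L) return(ifelse(obs > 0, x0, NA_real_))
  pad <- rep(0, h)
  num <- stats::filter(c(pad, x0, pad), w, sides = 2)
  den <- stats::filter(c(pad, obs, pad), w, sides = 2)
  num <- num[(h + 1):(h + length(x))]
  den <- den[(h + 1):(h + length(x))]
  out <- as.numeric(num) / as.numeric(den)
  out[den == 0] <- NA_real_
  out
}

#' Smooth an FST track over SNP windows
#'
#' Fills `fst_smooth`: at each SNP, the kernel-weighted mean of the raw FST
#' values over a window of `window_snps` SNPs centered there, truncated at
#' chromosome ends with weight renormalization (shrinking window). Missing
#' raw values are excluded with renormalization. If a chromosome holds fewer
#' SNPs than the window, the window degenerates to the chromosome-wide mean
#' (a warning notes this).
#'
#' @param track a track from [fst_per_snp()], sorted by (chrom, pos).
#' @param window_snps odd window size in SNPs.
#' @param kernel `"uniform_mean"` or `"triangular"`.
#' @param clamp_negative clamp negative raw values to zero before smoothing.
#' @return The track with `fst_smooth` filled.
#' @export
smooth_track <- function(track, window_snps = 9,
                         kernel = c("uniform_mean", "triangular"),
                         clamp_negative = TRUE) {
  kernel <- match.arg(kernel)
  window_snps <- as.integer(window_snps)
  if (window_snps < 1 || window_snps %% 2 == 0)
    stop("window_snps must be an odd integer >= 1")
  w <- kernel_weights(window_snps, kernel)
  x_all <- if (clamp_negative) pmax(track$fst_raw, 0) else track$fst_raw
  for (chrom in unique(track$chrom)) {
    idx <- which(track$chrom == chrom)
    if (length(idx) < window_snps)
      warning("chromosome ", chrom, " has fewer SNPs (", length(idx),
              ") than the smoothing window; using chromosome-wide mean")
    track$fst_smooth[idx] <- weighted_moving_average(x_all[idx], w)
  }
  track
}

#' Flag outlier SNPs above an empirical quantile
#'
#' The threshold is the empirical quantile (R's default type-7
#' linear-interpolation definition) of all smoothed values genome-wide
#' within the dataset; a SNP is flagged iff its smoothed value is strictly
#' above the threshold. Being rank-based, the flags are invariant to any
#' monotone increasing transform of the smoothed track.
#'
#' @param track a smoothed track from [smooth_track()].
#' @param quantile flagging quantile in (0, 1), default 0.99.
#' @return The track with `is_outlier` filled; the threshold is stored in
#'   `attr(track, "threshold")`.
#' @export
call_outliers <- function(track, quantile = 0.99) {
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  sm <- track$fst_smooth
  if (all(is.na(sm))) stop("no smoothed values present; run smooth_track() first")
  thr <- stats::quantile(sm, probs = quantile, na.rm = TRUE, type = 7, names = FALSE)
  track$is_outlier <- !is.na(sm) & sm > thr
  attr(track, "threshold") <- thr
  track
}

#' Merge flagged SNPs into regions
#'
#' Consecutive flagged SNPs on one chromosome separated by at most
#' `merge_gap_bp` base pairs form a region; region bounds are the min/max
#' member positions (1-based inclusive). The total member count over all
#' regions equals the number of flagged SNPs.
#'
#' @param track a flagged track from [call_outliers()].
#' @param merge_gap_bp maximum within-region gap in bp (default 1 Mb).
#' @return A data.frame with columns `chrom`, `start_bp`, `end_bp`,
#'   `n_snps`, `peak_fst_smooth`, `member_ids` (comma-separated).
#' @export
merge_regions <- function(track, merge_gap_bp = 1e6) {
  empty <- data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), n_snps = integer(),
                      peak_fst_smooth = numeric(), member_ids = character(),
                      stringsAsFactors = FALSE)
  if (is.null(track$is_outlier) || all(is.na(track$is_outlier)))
    stop("outlier flags not computed; run call_outliers() first")
  f <- which(track$is_outlier %in% TRUE)
  if (!length(f)) return(empty)
  newreg <- c(TRUE, track$chrom[f[-1]] != track$chrom[f[-length(f)]] |
                track$pos_bp[f[-1]] - track$pos_bp[f[-length(f)]] > merge_gap_bp)
  rid <- cumsum(newreg)
  out <- lapply(split(f, rid), function(ix) {
    data.frame(chrom = track$chrom[ix[1]],
               start_bp = min(track$pos_bp[ix]),
               end_bp = max(track$pos_bp[ix]),
               n_snps = length(ix),
               peak_fst_smooth = max(track$fst_smooth[ix]),
               member_ids = paste(track$id[ix], collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Selection-signature FST scan
#'
#' The central fit of the package: composes [fst_per_snp()],
#' [smooth_track()], [call_outliers()] and [merge_regions()] into one
#' deterministic scan of a QC'd, group-assigned genotype matrix.
#'
#' @param g a [genotype_matrix()] with groups I/II attached (ideally after
#'   [run_qc()]).
#' @param config an [fst_config()].
#' @return An object of class `fst_scan` with elements `track` (per-SNP
#'   values and flags), `regions`, `threshold`, `config`, `n_samples` and
#'   `group_sizes`. Methods: `print`, `summary`, `plot`.
#' @examples
#' cfg <- sim_config(n_samples_per_group = 25, n_snps = 400, n_chromosomes = 2,
#'                   planted_windows = data.frame(chrom = "1", start_snp_index = 50,
#'                                                n_snps = 10, delta = 0.5),
#'                   seed = 7)
#' sim <- simulate_genotypes(cfg)
#' scan <- fst_scan(sim$genotypes, fst_config(smooth_window_snps = 5))
#' scan
#' summary(scan)
#' @export
fst_scan <- function(g, config = fst_config()) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(config, "fst_config"))
  track <- fst_per_snp(g, config$estimator)
  track <- smooth_track(track, config$smooth_window_snps, config$smooth_kernel,
                        clamp_negative = config$clamp_negative)
  track <- call_outliers(track, config$outlier_quantile)
  regions <- merge_regions(track, config$region_merge_gap_bp)
  structure(list(track = track, regions = regions,
                 threshold = attr(track, "threshold"),
                 config = config,
                 n_samples = n_samples(g),
                 group_sizes = table(g$samples$group)),
            class = "fst_scan")
}

#' @export
print.fst_scan <- function(x, ...) {
  cat("FST selection-signature scan (", x$config$estimator, ")\n", sep = "")
  cat("  samples: ", x$n_samples, " (I=", x$group_sizes[["I"]],
      ", II=", x$group_sizes[["II"]], ")", "; variants: ", nrow(x$track), "\n", sep = "")
  cat(sprintf("  smoothing: %d-SNP %s; outlier quantile: %.3f (threshold %.5f)\n",
              x$config$smooth_window_snps, x$config$smooth_kernel,
              x$config$outlier_quantile, x$threshold))
  cat("  flagged SNPs: ", sum(x$track$is_outlier, na.rm = TRUE),
      "; regions: ", nrow(x$regions), "\n", sep = "")
  invisible(x)
}

#' @export
summary.fst_scan <- function(object, ...) {
  x <- object
  flagged <- sum(x$track$is_outlier, na.rm = TRUE)
  per_chrom <- tapply(x$track$is_outlier, x$track$chrom, sum, na.rm = TRUE)
  out <- list(estimator = x$config$estimator, n_variants = nrow(x$track),
              n_flagged = flagged, threshold = x$threshold,
              flagged_per_chrom = per_chrom, regions = x$regions)
  class(out) <- "summary.fst_scan"
  out
}

#' @export
print.summary.fst_scan <- function(x, ...) {
  cat("FST scan summary (", x$estimator, ")\n", sep = "")
  cat("  ", x$n_flagged, " of ", x$n_variants, " SNPs above the threshold ",
      sprintf("%.5f", x$threshold), "\n", sep = "")
  pc <- x$flagged_per_chrom[x$flagged_per_chrom > 0]
  if (length(pc))
    cat("  flagged per chromosome: ",
        paste(names(pc), pc, sep = ":", collapse = " "), "\n", sep = "")
  if (nrow(x$regions)) {
    cat("  regions:\n")
    print(x$regions[, c("chrom", "start_bp", "end_bp", "n_snps", "peak_fst_smooth")])
  } else cat("  no outlier regions\n")
  invisible(x)
}

#' @export
plot.fst_scan <- function(x, ...) {
  tr <- x$track
  key <- chrom_sort_key(tr$chrom)
  chroms <- unique(tr$chrom[order(key[[1]], key[[2]], key[[3]])])
  ci <- match(tr$chrom, chroms)
  offs <- c(0, cumsum(tapply(tr$pos_bp, factor(tr$chrom, levels = chroms), max)))
  xpos <- tr$pos_bp + offs[ci]
  col <- ifelse(tr$is_outlier %in% TRUE, "red", c("grey30", "grey60")[1 + ci %% 2])
  graphics::plot(xpos, tr$fst_smooth, col = col, pch = 20, cex = 0.5,
                 xlab = "genome position", ylab = "smoothed FST",
                 main = sprintf("smoothed FST (%s), q = %.2f",
                                x$config$estimator, x$config$outlier_quantile), ...)
  graphics::abline(h = x$threshold, lty = 2, col = "blue")
  invisible(x)
}

#' Write an FST track to TSV
#'
#' @param scan an `fst_scan` object (or a bare track data.frame).
#' @param path output file; a commented header records the configuration.
#' @return Invisibly, `path`.
#' @export
write_fst_track <- function(scan, path) {
  track <- if (inherits(scan, "fst_scan")) scan$track else scan
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# per-SNP FST track; dosage counts copies of allele_a (A1)", con)
  if (inherits(scan, "fst_scan"))
    writeLines(sprintf("# estimator=%s window=%d kernel=%s quantile=%g threshold=%.8g merge_gap_bp=%g",
                       scan$config$estimator, scan$config$smooth_window_snps,
                       scan$config$smooth_kernel, scan$config$outlier_quantile,
                       scan$threshold, scan$config$region_merge_gap_bp), con)
  utils::write.table(track, con, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Write outlier regions as BED and TSV
#'
#' The BED file uses the standard 0-based half-open convention (internal
#' 1-based inclusive coordinates are converted at write time); the TSV keeps
#' 1-based inclusive coordinates and the peak statistics.
#'
#' @param scan an `fst_scan` object (or a regions data.frame).
#' @param prefix output path prefix; writes `<prefix>.bed` and
#'   `<prefix>.tsv`.
#' @return Invisibly, the files written.
#' @export
write_regions <- function(scan, prefix) {
  regions <- if (inherits(scan, "fst_scan")) scan$regions else scan
  bed <- paste0(prefix, ".bed"); tsv <- paste0(prefix, ".tsv")
  bedtab <- data.frame(chrom = regions$chrom,
                       start = regions$start_bp - 1L, end = regions$end_bp,
                       name = sprintf("region_%d", seq_len(nrow(regions))),
                       stringsAsFactors = FALSE)
  utils::write.table(bedtab, bed, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  con <- file(tsv, "w")
  on.exit(close(con))
  writeLines("# outlier regions, 1-based inclusive coordinates", con)
  utils::write.table(regions, con, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(c(bed, tsv))
}
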