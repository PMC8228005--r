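# Population-structure diagnostics: spectral decomposition of the GRM and a
# breed/group cluster report on the leading axes.

#' SVD of the genomic relationship matrix
#'
#' Symmetric eigendecomposition of the GRM; for a symmetric PSD matrix this
#' coincides with its singular value decomposition. Sample scores are the
#' eigenvectors scaled by the square roots of the eigenvalues, so the full
#' set of components reconstructs the GRM. Eigenvector signs are fixed by
#' making the largest-magnitude loading positive, which keeps output
#' deterministic across runs and platforms.
#'
#' @param grm symmetric positive semi-definite matrix, e.g. from [grm()].
#' @param k number of leading components to report (default 10, capped at
#'   the matrix dimension).
#' @return An object of class `structure_result` with elements `scores`
#'   (n x k), `singular_values` (non-increasing), `variance_explained`
#'   (fractions of total variance), and `vectors` (the k eigenvectors).
#' @export
svd_structure <- function(grm, k = 10) {
  if (k <= 0) stop("k must be a positive integer")
  n <- nrow(grm)
  if (!isTRUE(all.equal(grm, t(grm), tolerance = 1e-8)))
    stop("grm must be symmetric")
  k <- min(as.integer(k), n)
  e <- eigen(grm, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  scores <- vecs[, seq_len(k), drop = FALSE] %*% diag(sqrt(vals[seq_len(k)]), k)
  rownames(scores) <- rownames(grm)
  colnames(scores) <- paste0("PC", seq_len(k))
  total <- sum(vals)
  structure(list(scores = scores,
                 singular_values = vals[seq_len(k)],
                 variance_explained = if (total > 0) vals[seq_len(k)] / total else rep(NA_real_, k),
                 vectors = vecs[, seq_len(k), drop = FALSE],
                 eigenvalues_all = vals),
            class = "structure_result")
}

#' @export
print.structure_result <- function(x, ...) {
  k <- length(x$singular_values)
  cat("structure_result: ", nrow(x$scores), " samples, ", k, " components\n", sep = "")
  cat("  variance explained:",
      paste(sprintf("%.3f", x$variance_explained[seq_len(min(5, k))]), collapse = " "),
      if (k > 5) "..." else "", "\n")
  invisible(x)
}

# Mean silhouette width of `labels` over the rows of `xy` (Euclidean).
# NA when fewer than two distinct labels or any label has < 1 member.
silhouette_score <- function(xy, labels) {
  labels <- as.character(labels)
  ok <- !is.na(labels)
  xy <- xy[ok, , drop = FALSE]
  labels <- labels[ok]
  lev <- unique(labels)
  if (length(lev) < 2 || nrow(xy) < 3) return(NA_real_)
  d <- as.matrix(stats::dist(xy))
  s <- numeric(nrow(xy))
  for (i in seq_len(nrow(xy))) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    b <- min(vapply(setdiff(lev, labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Breed/group cluster report on the leading axes
#'
#' Reproduces the usual visual check on the first two GRM axes: per-label
#' centroids and a silhouette-style separation score, computed separately
#' for breed labels and for phenotype-group labels. A well-designed
#' case/control contrast shows strong breed separation and no group
#' separation (no stratification by phenotype).
#'
#' @param s a [svd_structure()] result.
#' @param samples the sample metadata data.frame aligned with the GRM rows
#'   (columns `sample_id`, `breed`, `group`).
#' @param plot_file optional path of a PNG scatter plot of components 1-2,
#'   colored by breed, plotting symbol by group.
#' @return A list with `breed_separation`, `group_separation` (mean
#'   silhouette widths on axes 1-2; NA for a single label), `centroids`
#'   (per breed x group), and `plot_file`.
#' @export
cluster_report <- function(s, samples, plot_file = NULL) {
  stopifnot(inherits(s, "structure_result"))
  if (nrow(s$scores) != nrow(samples))
    stop("scores and samples are not aligned")
  xy <- s$scores[, 1:2, drop = FALSE]
  breed <- as.character(samples$breed)
  group <- as.character(samples$group)
  cent <- stats::aggregate(xy, by = list(breed = ifelse(is.na(breed), "<NA>", breed),
                                         group = ifelse(is.na(group), "<NA>", group)),
                           FUN = mean)
  rep <- list(breed_separation = silhouette_score(xy, breed),
              group_separation = silhouette_score(xy, group),
              centroids = cent, plot_file = plot_file)
  if (!is.null(plot_file)) {
    grDevices::png(plot_file, width = 800, height = 800, res = 120)
    on.exit(grDevices::dev.off())
    bl <- factor(ifelse(is.na(breed), "unknown", breed))
    gl <- factor(ifelse(is.na(group), "unknown", group))
    graphics::plot(xy[, 1], xy[, 2],
                   col = as.integer(bl) + 1L, pch = c(1, 17, 3)[as.integer(gl)],
                   xlab = sprintf("PC1 (%.1f%%)", 100 * s$variance_explained[1]),
                   ylab = sprintf("PC2 (%.1f%%)", 100 * s$variance_explained[2]),
                   main = "GRM structure (components 1-2)")
    graphics::legend("topright", bty = "n",
                     legend = c(levels(bl), paste("group", levels(gl))),
                     col = c(seq_along(levels(bl)) + 1L, rep(1, nlevels(gl))),
                     pch = c(rep(15, nlevels(bl)), c(1, 17, 3)[seq_len(nlevels(gl))]))
  }
  rep
}

#' Write structure scores to TSV
#'
#' @param s a [svd_structure()] result.
#' @param path output file; columns `sample_id`, `PC1..PCk`.
#' @return Invisibly, `path`.
#' @export
write_structure_scores <- function(s, path) {
  tab <- data.frame(sample_id = rownames(s$scores), s$scores,
                    check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# GRM eigendecomposition scores; variance explained: %s",
                     paste(sprintf("%.4f", s$variance_explained), collapse = ",")), con)
  utils::write.table(tab, con, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
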