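# Synthetic genotypes under the Balding-Nichols pure-drift model, with
# planted differentiated windows and matching toy annotation files, so every
# pipeline stage can be exercised and calibrated without external data.

#' Simulation configuration
#'
#' Defaults emulate a desk-scale version of a two-group SNP-array study:
#' 40 diploid samples per phenotype group, 5000 biallelic SNPs spread over
#' 5 chromosomes at ~25 kb mean spacing, ancestral minor-allele frequencies
#' uniform on (0.05, 0.5), background drift c = 0.01 and a 1\% missing-call
#' rate.
#'
#' @param n_samples_per_group diploid samples in each of groups I and II.
#' @param n_snps total SNP count, split evenly over chromosomes.
#' @param n_chromosomes number of simulated autosomes, labelled "1", "2", ...
#' @param spacing_bp mean inter-SNP distance; positions are cumulative
#'   Exponential(`spacing_bp`) draws rounded up to at least 1 bp, so maps are
#'   sorted by construction.
#' @param ancestral_maf_range range of the uniform ancestral frequency draw.
#' @param background_c drift parameter of the Balding-Nichols model: group
#'   frequencies are Beta-distributed around the ancestral frequency `pi`
#'   with mean `pi` and variance `c * pi * (1 - pi)`.
#' @param planted_windows optional data.frame with columns `chrom`,
#'   `start_snp_index` (1-based index within the chromosome), `n_snps`, and
#'   either `delta` (group frequency shift: +/- delta/2 applied with
#'   opposite signs to the two groups, clipped to \[0.01, 0.99\]) or
#'   `c_planted` (locally elevated drift parameter replacing
#'   `background_c`).
#' @param missing_rate uniform missing-call probability per genotype.
#' @param n_breeds 1 (default) or 2; with 2 breeds, breed frequencies are
#'   first drawn around the ancestral frequency with drift `c_breed`, and
#'   group frequencies then drift within breed — this feeds the structure
#'   module's breed-separation check.
#' @param c_breed breed-level drift parameter used when `n_breeds = 2`.
#' @param seed mandatory integer seed; every run is reproducible from it.
#' @return A classed list of validated settings.
#' @export
sim_config <- function(n_samples_per_group = 40, n_snps = 5000,
                       n_chromosomes = 5, spacing_bp = 25000,
                       ancestral_maf_range = c(0.05, 0.5),
                       background_c = 0.01, planted_windows = NULL,
                       missing_rate = 0.01, n_breeds = 1, c_breed = 0.1,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required for every simulation")
  cfg <- list(n_samples_per_group = as.integer(n_samples_per_group),
              n_snps = as.integer(n_snps), n_chromosomes = as.integer(n_chromosomes),
              spacing_bp = spacing_bp, ancestral_maf_range = ancestral_maf_range,
              background_c = background_c, planted_windows = planted_windows,
              missing_rate = missing_rate, n_breeds = as.integer(n_breeds),
              c_breed = c_breed, seed = as.integer(seed))
  if (cfg$background_c <= 0 || cfg$background_c >= 1)
    stop("background_c must be in (0, 1)")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (cfg$n_samples_per_group < 2) stop("need at least 2 samples per group")
  if (cfg$n_snps < 1 || cfg$n_chromosomes < 1 || cfg$n_snps < cfg$n_chromosomes)
    stop("invalid n_snps / n_chromosomes")
  if (!cfg$n_breeds %in% 1:2) stop("n_breeds must be 1 or 2")
  if (!is.null(cfg$planted_windows)) {
    pw <- as.data.frame(cfg$planted_windows, stringsAsFactors = FALSE)
    need <- c("chrom", "start_snp_index", "n_snps")
    if (!all(need %in% names(pw)))
      stop("planted_windows needs columns ", paste(need, collapse = ", "))
    if (!("delta" %in% names(pw)) && !("c_planted" %in% names(pw)))
      stop("planted_windows needs a delta or c_planted column")
    cfg$planted_windows <- pw
  }
  structure(cfg, class = "sim_config")
}

beta_drift <- function(pi_, c_) {
  a <- pi_ * (1 - c_) / c_
  b <- (1 - pi_) * (1 - c_) / c_
  stats::rbeta(length(pi_), a, b)
}

#' Simulate a two-group genotype dataset under pure drift
#'
#' Per SNP, an ancestral frequency is drawn uniformly from
#' `ancestral_maf_range`; each group's frequency is a Beta draw around it
#' with variance `background_c * pi * (1 - pi)` (Balding-Nichols); planted
#' windows add an opposite-sign `+/- delta/2` shift (or locally elevated
#' drift `c_planted`); genotypes are Binomial(2, p) per sample, and missing
#' calls are sprinkled uniformly. A toy gene annotation places one named
#' gene inside each planted window plus decoy genes elsewhere, so the
#' annotate module can be exercised against known truth.
#'
#' @param cfg a [sim_config()].
#' @return A list with elements `genotypes` (a [genotype_matrix()] with
#'   groups attached; two breeds when `n_breeds = 2`), `truth` (class
#'   `sim_truth`: planted intervals with `chrom`, `start_bp`, `end_bp`,
#'   `delta`, plus the per-SNP true group frequencies), and `genes` (an
#'   `annotation_set` of planted + decoy genes).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  m <- cfg$n_snps; nchr <- cfg$n_chromosomes
  per_chr <- rep(m %/% nchr, nchr)
  if (m %% nchr) per_chr[seq_len(m %% nchr)] <- per_chr[seq_len(m %% nchr)] + 1L
  chrom <- rep(as.character(seq_len(nchr)), per_chr)
  pos <- as.integer(unlist(lapply(per_chr, function(k)
    cumsum(pmax(1, round(stats::rexp(k, rate = 1 / cfg$spacing_bp)))))))
  ids <- sprintf("SNP%05d", seq_len(m))

  pi_ <- stats::runif(m, cfg$ancestral_maf_range[1], cfg$ancestral_maf_range[2])
  c_snp <- rep(cfg$background_c, m)

  # resolve planted windows to absolute SNP indices
  planted_idx <- vector("list", 0)
  pw <- cfg$planted_windows
  truth_int <- data.frame(chrom = character(), start_bp = integer(),
                          end_bp = integer(), delta = numeric(),
                          stringsAsFactors = FALSE)
  if (!is.null(pw) && nrow(pw)) {
    for (i in seq_len(nrow(pw))) {
      ch <- as.character(pw$chrom[i])
      in_chr <- which(chrom == ch)
      if (!length(in_chr)) stop("planted window on unknown chromosome ", ch)
      st <- pw$start_snp_index[i]
      en <- st + pw$n_snps[i] - 1L
      if (st < 1 || en > length(in_chr))
        stop("planted window ", i, " exceeds chromosome ", ch,
             " (", length(in_chr), " SNPs)")
      idx <- in_chr[st:en]
      planted_idx[[i]] <- idx
      if (!is.null(pw$c_planted) && !is.na(pw$c_planted[i]))
        c_snp[idx] <- pw$c_planted[i]
      truth_int <- rbind(truth_int, data.frame(
        chrom = ch, start_bp = pos[idx[1]], end_bp = pos[idx[length(idx)]],
        delta = if (!is.null(pw$delta)) pw$delta[i] else NA_real_,
        stringsAsFactors = FALSE))
    }
  }

  n <- cfg$n_samples_per_group
  breeds <- if (cfg$n_breeds == 2) c("breed1", "breed2") else "sim"
  geno <- NULL; samp <- NULL
  freqs <- list()
  for (b in seq_along(breeds)) {
    pib <- if (cfg$n_breeds == 2) beta_drift(pi_, cfg$c_breed) else pi_
    p1 <- beta_drift(pib, c_snp)
    p2 <- beta_drift(pib, c_snp)
    if (!is.null(pw) && !is.null(pw$delta)) {
      for (i in seq_len(nrow(pw))) {
        if (is.na(pw$delta[i])) next
        idx <- planted_idx[[i]]
        p1[idx] <- pmin(0.99, pmax(0.01, p1[idx] + pw$delta[i] / 2))
        p2[idx] <- pmin(0.99, pmax(0.01, p2[idx] - pw$delta[i] / 2))
      }
    }
    g1 <- matrix(stats::rbinom(n * m, 2L, rep(p1, each = n)), nrow = n)
    g2 <- matrix(stats::rbinom(n * m, 2L, rep(p2, each = n)), nrow = n)
    geno <- rbind(geno, g1, g2)
    samp <- rbind(samp, data.frame(
      sample_id = sprintf("%s_%s%03d", breeds[b], rep(c("I", "II"), each = n), c(1:n, 1:n)),
      breed = breeds[b], group = rep(c("I", "II"), each = n),
      stringsAsFactors = FALSE))
    freqs[[breeds[b]]] <- rbind(I = p1, II = p2)
  }
  if (cfg$missing_rate > 0)
    geno[stats::runif(length(geno)) < cfg$missing_rate] <- NA_integer_

  variants <- data.frame(id = ids, chrom = chrom, pos_bp = pos,
                         allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)
  g <- genotype_matrix(geno, variants, samp)

  # toy gene models: one gene per planted window, decoys elsewhere
  genes <- make_toy_genes(truth_int, chrom, pos, cfg)
  truth <- structure(list(intervals = truth_int, freqs = freqs,
                          ancestral = pi_, map = variants[, c("id", "chrom", "pos_bp")]),
                     class = "sim_truth")
  list(genotypes = g, truth = truth, genes = genes)
}

make_toy_genes <- function(truth_int, chrom, pos, cfg) {
  names <- character(); chs <- character(); st <- integer(); en <- integer()
  if (nrow(truth_int)) {
    names <- sprintf("PLANTED%d", seq_len(nrow(truth_int)))
    chs <- truth_int$chrom
    st <- truth_int$start_bp
    en <- truth_int$end_bp
  }
  # decoys: midpoint genes on each chromosome, away from planted windows
  for (ch in unique(chrom)) {
    cpos <- pos[chrom == ch]
    mid <- cpos[length(cpos) %/% 2]
    dst <- mid; den <- mid + 10000L
    clash <- nrow(truth_int) && any(truth_int$chrom == ch &
                                      truth_int$start_bp <= den &
                                      truth_int$end_bp >= dst)
    if (clash) { dst <- cpos[1]; den <- cpos[1] + 10000L }
    names <- c(names, sprintf("DECOY%s", ch))
    chs <- c(chs, ch); st <- c(st, dst); en <- c(en, den)
  }
  annotation_set(names, chs, st, en, category = "toy")
}

#' Score region recovery against simulation truth
#'
#' A planted window counts as recovered when at least one region overlaps
#' it by one base pair or more; a region overlapping no planted window is a
#' false region.
#'
#' @param regions a regions data.frame (or `fst_scan` object).
#' @param truth a `sim_truth` from [simulate_genotypes()].
#' @return A list with `sensitivity` (recovered / planted; `NA` when
#'   nothing was planted), `n_false`, and the logical vector `recovered`.
#' @export
evaluate_recovery <- function(regions, truth) {
  if (inherits(regions, "fst_scan")) regions <- regions$regions
  tr <- truth$intervals
  if (!nrow(tr)) {
    return(list(sensitivity = NA_real_, n_false = nrow(regions),
                recovered = logical()))
  }
  if (!nrow(regions)) {
    return(list(sensitivity = 0, n_false = 0L,
                recovered = rep(FALSE, nrow(tr))))
  }
  overlaps <- function(ch, s, e) regions$chrom == ch &
    regions$start_bp <= e & regions$end_bp >= s
  hit_mat <- vapply(seq_len(nrow(tr)), function(i)
    overlaps(tr$chrom[i], tr$start_bp[i], tr$end_bp[i]),
    logical(nrow(regions)))
  hit_mat <- matrix(hit_mat, nrow = nrow(regions))
  recovered <- apply(hit_mat, 2, any)
  false_regions <- !apply(hit_mat, 1, any)
  list(sensitivity = mean(recovered), n_false = sum(false_regions),
       recovered = recovered)
}

#' Write simulation truth to disk
#'
#' Planted intervals go to a BED file (0-based half-open) and a TSV with
#' the effect sizes; per-SNP true group frequencies to a second TSV.
#'
#' @param truth a `sim_truth`.
#' @param prefix output path prefix.
#' @return Invisibly, the files written.
#' @export
write_sim_truth <- function(truth, prefix) {
  bed <- paste0(prefix, "_truth.bed")
  tsv <- paste0(prefix, "_truth.tsv")
  fr <- paste0(prefix, "_freqs.tsv")
  ti <- truth$intervals
  utils::write.table(data.frame(ti$chrom, ti$start_bp - 1L, ti$end_bp,
                                sprintf("planted_%d", seq_len(nrow(ti)))),
                     bed, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(ti, tsv, quote = FALSE, sep = "\t", row.names = FALSE)
  ftab <- truth$map
  for (b in names(truth$freqs)) {
    ftab[[paste0(b, "_pI")]] <- truth$freqs[[b]]["I", ]
    ftab[[paste0(b, "_pII")]] <- truth$freqs[[b]]["II", ]
  }
  utils::write.table(ftab, fr, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(c(bed, tsv, fr))
}
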