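# In-memory genotype model shared by all pipeline stages.
#
# Dosages count copies of allele_a (the A1 column of the binary dialect) and
# live in {0, 1, 2}; missing calls are NA. Rows are samples, columns variants.

#' Construct a genotype matrix
#'
#' Bundles a samples-by-variants dosage matrix with its sample and variant
#' metadata into the container every other function in the package consumes.
#' Variants are sorted by (chromosome, position); samples keep their order.
#'
#' @param dosage integer matrix, samples in rows, variants in columns; values
#'   in `{0, 1, 2}` counting copies of `allele_a`, `NA` for missing calls.
#' @param variants data.frame with columns `id`, `chrom`, `pos_bp`,
#'   `allele_a`, `allele_b`; positions are 1-based as in `.bim`/`.map` files.
#' @param samples data.frame with columns `sample_id` and optionally `breed`
#'   and `group` (factor levels `"I"` = phenotype present, `"II"` = absent).
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `variants`, `samples`.
#' @examples
#' g <- genotype_matrix(
#'   dosage   = matrix(c(0L, 1L, 2L, 2L, NA, 0L), nrow = 3),
#'   variants = data.frame(id = c("v1", "v2"), chrom = c("1", "1"),
#'                         pos_bp = c(100L, 200L),
#'                         allele_a = "A", allele_b = "B"),
#'   samples  = data.frame(sample_id = c("s1", "s2", "s3"))
#' )
#' g
#' @export
genotype_matrix <- function(dosage, variants, samples) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(samples$breed)) samples$breed <- NA_character_
  if (is.null(samples$group)) samples$group <- factor(rep(NA_character_, nrow(samples)), levels = c("I", "II"))
  samples$group <- factor(as.character(samples$group), levels = c("I", "II"))
  variants$chrom <- as.character(variants$chrom)
  variants$id <- as.character(variants$id)
  variants$pos_bp <- as.integer(variants$pos_bp)
  g <- structure(list(dosage = dosage, variants = variants, samples = samples),
                 class = "genotype_matrix")
  validate_genotype_matrix(g)
  sort_variants(g)
}

validate_genotype_matrix <- function(g) {
  d <- g$dosage
  if (nrow(d) != nrow(g$samples))
    stop("dosage has ", nrow(d), " rows but there are ", nrow(g$samples), " samples")
  if (ncol(d) != nrow(g$variants))
    stop("dosage has ", ncol(d), " columns but there are ", nrow(g$variants), " variants")
  bad <- d[!is.na(d)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("dosage values must be 0, 1, 2 or NA")
  if (anyDuplicated(g$variants$id))
    stop("variant ids are not unique")
  if (anyDuplicated(g$samples$sample_id))
    stop("sample ids are not unique")
  if (nrow(g$variants) && any(g$variants$pos_bp < 1L, na.rm = TRUE))
    stop("variant positions must be >= 1 (1-based coordinates)")
  invisible(g)
}

# Numeric chromosomes first in numeric order, then the rest lexicographically.
chrom_sort_key <- function(chrom) {
  stripped <- sub("^(chr|ssc)", "", tolower(as.character(chrom)))
  num <- suppressWarnings(as.numeric(stripped))
  list(is.na(num), num, as.character(chrom))
}

sort_variants <- function(g) {
  key <- chrom_sort_key(g$variants$chrom)
  ord <- order(key[[1]], key[[2]], key[[3]], g$variants$pos_bp)
  if (!identical(ord, seq_len(nrow(g$variants)))) {
    g$variants <- g$variants[ord, , drop = FALSE]
    rownames(g$variants) <- NULL
    g$dosage <- g$dosage[, ord, drop = FALSE]
  }
  g
}

#' @export
print.genotype_matrix <- function(x, ...) {
  nb <- length(unique(stats::na.omit(x$samples$breed)))
  ng <- table(x$samples$group)
  cat("genotype_matrix: ", nrow(x$samples), " samples x ", nrow(x$variants),
      " variants\n", sep = "")
  cat("  chromosomes: ", length(unique(x$variants$chrom)),
      "; breeds: ", nb,
      "; groups: I=", ng[["I"]], " II=", ng[["II"]],
      " unassigned=", sum(is.na(x$samples$group)), "\n", sep = "")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing call rate: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

n_samples <- function(g) nrow(g$samples)
n_variants <- function(g) nrow(g$variants)

keep_samples <- function(g, keep) {
  g$samples <- g$samples[keep, , drop = FALSE]
  rownames(g$samples) <- NULL
  g$dosage <- g$dosage[keep, , drop = FALSE]
  g
}

keep_variants <- function(g, keep) {
  g$variants <- g$variants[keep, , drop = FALSE]
  rownames(g$variants) <- NULL
  g$dosage <- g$dosage[, keep, drop = FALSE]
  g
}

per_variant_missing <- function(g) colMeans(is.na(g$dosage))
per_sample_missing <- function(g) rowMeans(is.na(g$dosage))

#' Drop non-autosomal variants
#'
#' A chromosome is treated as autosomal when its label, after stripping an
#' optional `chr`/`SSC` prefix, is a plain integer. Sex chromosomes, MT and
#' scaffolds are removed; the scan operates on autosomes only by default.
#'
#' @param g a [genotype_matrix()].
#' @return `g` restricted to autosomal variants.
#' @export
drop_nonautosomal <- function(g) {
  stripped <- sub("^(chr|ssc)", "", tolower(g$variants$chrom))
  keep <- grepl("^[0-9]+$", stripped)
  keep_variants(g, keep)
}

# ---------------------------------------------------------------------------
# PLINK-dialect readers/writers

#' Read a PLINK genotype fileset
#'
#' Reads either the binary dialect (`.bed`/`.bim`/`.fam`, SNP-major, magic
#' bytes `0x6C 0x1B 0x01`) or the text dialect (`.ped`/`.map`). Dosage counts
#' copies of `allele_a`: for binary files this is the A1 column of the
#' `.bim`; the text dialect stores no allele order, so `allele_a` is assigned
#' the lexicographically smaller observed allele (a variant with a single
#' observed allele records it as `allele_b`). Variants are sorted by
#' (chromosome, position); sample order is preserved. The `.fam` phenotype
#' column is mapped to groups (2 = `"I"`, 1 = `"II"`, other = unassigned) and
#' the family id to `breed` (`"0"` = unknown).
#'
#' @param prefix path prefix of the fileset (without extension).
#' @param dialect `"binary"` or `"text"`.
#' @return A [genotype_matrix()].
#' @seealso [write_genotypes()], [attach_groups()]
#' @export
read_genotypes <- function(prefix, dialect = c("binary", "text")) {
  dialect <- match.arg(dialect)
  if (dialect == "binary") read_plink_binary(prefix) else read_plink_text(prefix)
}

read_plink_binary <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim"); fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("file not found: ", f)
  bimdf <- if (file.size(bim) == 0) {
    data.frame(chrom = character(), id = character(), cm = character(),
               pos_bp = integer(), allele_a = character(), allele_b = character(),
               stringsAsFactors = FALSE)
  } else {
    utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                      colClasses = c("character", "character", "character",
                                     "integer", "character", "character"))
  }
  names(bimdf) <- c("chrom", "id", "cm", "pos_bp", "allele_a", "allele_b")
  famdf <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE,
                             colClasses = "character")
  if (ncol(famdf) < 6) stop("format error in ", fam, ": expected 6 columns")
  names(famdf)[1:6] <- c("fid", "sample_id", "pat", "mat", "sex", "pheno")
  n <- nrow(famdf); m <- nrow(bimdf)
  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("format error in ", bed, ": bad magic bytes")
  if (raw[3] != as.raw(0x01))
    stop("format error in ", bed, ": not SNP-major")
  bps <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bps * m)
    stop("format error in ", bed, ": expected ", bps * m, " data bytes for ",
         n, " samples x ", m, " variants, found ", length(body))
  # 2-bit codes, low bits first: 00 hom A1 (2), 01 missing, 10 het (1), 11 hom A2 (0)
  lut <- matrix(NA_integer_, nrow = 256, ncol = 4)
  code_dos <- c(2L, NA_integer_, 1L, 0L)
  for (b in 0:255) for (s in 0:3) lut[b + 1, s + 1] <- code_dos[bitwAnd(bitwShiftR(b, 2L * s), 3L) + 1L]
  bytes <- as.integer(body)
  dim(bytes) <- c(bps, m)
  dos <- matrix(NA_integer_, nrow = n, ncol = m)
  for (s in 0:3) {
    samp_idx <- seq.int(s + 1L, length.out = max(0L, ((n - s - 1L) %/% 4L) + 1L), by = 4L)
    if (s + 1L > n || !length(samp_idx)) next
    byte_rows <- ((samp_idx - 1L) %/% 4L) + 1L
    dos[samp_idx, ] <- lut[cbind(as.vector(bytes[byte_rows, , drop = FALSE]) + 1L,
                                 s + 1L)]
  }
  samples <- data.frame(sample_id = famdf$sample_id,
                        breed = ifelse(famdf$fid == "0", NA_character_, famdf$fid),
                        group = pheno_to_group(famdf$pheno),
                        stringsAsFactors = FALSE)
  variants <- bimdf[, c("id", "chrom", "pos_bp", "allele_a", "allele_b")]
  genotype_matrix(dos, variants, samples)
}

pheno_to_group <- function(pheno) {
  factor(ifelse(pheno == "2", "I", ifelse(pheno == "1", "II", NA_character_)),
         levels = c("I", "II"))
}

group_to_pheno <- function(group) {
  ifelse(is.na(group), "-9", ifelse(group == "I", "2", "1"))
}

read_plink_text <- function(prefix) {
  ped <- paste0(prefix, ".ped"); map <- paste0(prefix, ".map")
  for (f in c(ped, map)) if (!file.exists(f)) stop("file not found: ", f)
  mapdf <- utils::read.table(map, header = FALSE, stringsAsFactors = FALSE,
                             colClasses = c("character", "character", "character", "integer"))
  names(mapdf) <- c("chrom", "id", "cm", "pos_bp")
  m <- nrow(mapdf)
  lines <- readLines(ped)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  dos <- matrix(NA_integer_, nrow = n, ncol = m)
  a1 <- matrix(NA_character_, nrow = n, ncol = m)
  a2 <- matrix(NA_character_, nrow = n, ncol = m)
  meta <- vector("list", n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(tok) != 6 + 2 * m)
      stop("format error in ", ped, " line ", i, ": expected ", 6 + 2 * m,
           " fields, found ", length(tok))
    al <- tok[-(1:6)]
    bad <- !grepl("^[A-Za-z0-9]+$", al)
    if (any(bad))
      stop("format error in ", ped, " line ", i, ": unknown genotype symbol '",
           al[which(bad)[1]], "'")
    meta[[i]] <- tok[1:6]
    a1[i, ] <- al[seq(1, 2 * m, by = 2)]
    a2[i, ] <- al[seq(2, 2 * m, by = 2)]
  }
  a1[a1 == "0"] <- NA; a2[a2 == "0"] <- NA
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    w <- which(half, arr.ind = TRUE)[1, ]
    stop("format error in ", ped, " line ", w[1], ": half-missing genotype at variant ",
         mapdf$id[w[2]])
  }
  allele_a <- character(m); allele_b <- character(m)
  for (j in seq_len(m)) {
    obs <- sort(unique(c(a1[, j], a2[, j])))
    obs <- obs[!is.na(obs)]
    if (length(obs) > 2)
      stop("format error in ", ped, ": variant ", mapdf$id[j],
           " has more than two alleles (multi-allelic variants are unsupported)")
    if (length(obs) == 2) { allele_a[j] <- obs[1]; allele_b[j] <- obs[2] }
    else if (length(obs) == 1) { allele_a[j] <- "0"; allele_b[j] <- obs[1] }
    else { allele_a[j] <- "0"; allele_b[j] <- "0" }
    dos[, j] <- (a1[, j] == allele_a[j]) + (a2[, j] == allele_a[j])
    dos[is.na(a1[, j]), j] <- NA_integer_
  }
  metam <- do.call(rbind, meta)
  samples <- data.frame(sample_id = metam[, 2],
                        breed = ifelse(metam[, 1] == "0", NA_character_, metam[, 1]),
                        group = pheno_to_group(metam[, 6]),
                        stringsAsFactors = FALSE)
  variants <- data.frame(id = mapdf$id, chrom = mapdf$chrom, pos_bp = mapdf$pos_bp,
                         allele_a = allele_a, allele_b = allele_b,
                         stringsAsFactors = FALSE)
  genotype_matrix(dos, variants, samples)
}

#' Write a PLINK genotype fileset
#'
#' Inverse of [read_genotypes()]. The binary dialect round-trips dosages,
#' the variant map, allele order and sample ids losslessly; the text dialect
#' round-trips dosages for variants whose `allele_a` sorts before `allele_b`
#' (the reader's convention), which holds for all simulator output (A/B
#' coding).
#'
#' @param g a [genotype_matrix()].
#' @param prefix output path prefix.
#' @param dialect `"binary"` or `"text"`.
#' @return Invisibly, the character vector of files written.
#' @export
write_genotypes <- function(g, prefix, dialect = c("binary", "text")) {
  dialect <- match.arg(dialect)
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  if (dialect == "binary") write_plink_binary(g, prefix) else write_plink_text(g, prefix)
}

fam_table <- function(g) {
  data.frame(fid = ifelse(is.na(g$samples$breed), "0", g$samples$breed),
             iid = g$samples$sample_id, pat = "0", mat = "0", sex = "0",
             pheno = group_to_pheno(g$samples$group), stringsAsFactors = FALSE)
}

write_plink_binary <- function(g, prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim"); fam <- paste0(prefix, ".fam")
  utils::write.table(fam_table(g), fam, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  bimdf <- data.frame(chrom = g$variants$chrom, id = g$variants$id,
                      cm = rep_len("0", n_variants(g)),
                      pos = g$variants$pos_bp, a1 = g$variants$allele_a,
                      a2 = g$variants$allele_b, stringsAsFactors = FALSE)
  utils::write.table(bimdf, bim, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  n <- n_samples(g); m <- n_variants(g)
  bps <- ceiling(n / 4)
  # dosage -> 2-bit code: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  code <- matrix(3L, nrow = n, ncol = m)
  code[g$dosage == 1L] <- 2L
  code[g$dosage == 2L] <- 0L
  code[is.na(g$dosage)] <- 1L
  con <- file(bed, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  if (m > 0) {
    padded <- matrix(0L, nrow = 4 * bps, ncol = m)
    if (n > 0) padded[seq_len(n), ] <- code
    shifts <- c(1L, 4L, 16L, 64L)
    bytes <- matrix(0L, nrow = bps, ncol = m)
    for (s in 1:4) {
      bytes <- bytes + padded[seq.int(s, by = 4L, length.out = bps), , drop = FALSE] * shifts[s]
    }
    writeBin(as.raw(bytes), con)
  }
  invisible(c(bed, bim, fam))
}

write_plink_text <- function(g, prefix) {
  ped <- paste0(prefix, ".ped"); map <- paste0(prefix, ".map")
  mapdf <- data.frame(chrom = g$variants$chrom, id = g$variants$id,
                      cm = rep_len("0", n_variants(g)),
                      pos = g$variants$pos_bp, stringsAsFactors = FALSE)
  utils::write.table(mapdf, map, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  n <- n_samples(g); m <- n_variants(g)
  aa <- g$variants$allele_a; ab <- g$variants$allele_b
  need_a <- colSums(g$dosage > 0, na.rm = TRUE) > 0
  need_b <- colSums(g$dosage < 2, na.rm = TRUE) > 0
  if (any(need_a & aa == "0"))
    stop("cannot write text dialect: dosage > 0 at variant ",
         g$variants$id[which(need_a & aa == "0")[1]], " with unknown allele_a")
  if (any(need_b & ab == "0"))
    stop("cannot write text dialect: dosage < 2 at variant ",
         g$variants$id[which(need_b & ab == "0")[1]], " with unknown allele_b")
  meta <- fam_table(g)
  con <- file(ped, "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    d <- g$dosage[i, ]
    g1 <- ifelse(is.na(d), "0", ifelse(d >= 1, aa, ab))
    g2 <- ifelse(is.na(d), "0", ifelse(d == 2, aa, ab))
    writeLines(paste(c(unlist(meta[i, ], use.names = FALSE),
                       as.vector(rbind(g1, g2))), collapse = "\t"), con)
  }
  invisible(c(ped, map))
}

#' Attach case/control group assignments
#'
#' Populates the `group` field of the sample metadata from a two-column
#' table (`sample_id`, `group`). Samples without an assignment are dropped
#' (their count is reported via `message()`); assignment ids absent from the
#' genotypes are reported as a warning; duplicate ids with conflicting groups
#' are an error.
#'
#' @param g a [genotype_matrix()].
#' @param assignments data.frame with columns `sample_id` and `group`
#'   (values `"I"`/`"II"`), or the path of a tab-separated file with those
#'   two columns (header optional).
#' @return `g` with groups attached and unassigned samples removed.
#' @export
attach_groups <- function(g, assignments) {
  if (is.character(assignments) && length(assignments) == 1) {
    tab <- utils::read.table(assignments, header = FALSE, stringsAsFactors = FALSE,
                             colClasses = "character", comment.char = "#")
    if (nrow(tab) && tolower(tab[1, 1]) == "sample_id") tab <- tab[-1, , drop = FALSE]
    assignments <- data.frame(sample_id = tab[, 1], group = tab[, 2],
                              stringsAsFactors = FALSE)
  }
  assignments <- as.data.frame(assignments, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(assignments)))
    stop("assignments must have columns sample_id and group")
  assignments$sample_id <- as.character(assignments$sample_id)
  assignments$group <- as.character(assignments$group)
  if (!all(assignments$group %in% c("I", "II")))
    stop("group values must be \"I\" or \"II\"")
  dup <- assignments$sample_id[duplicated(assignments$sample_id)]
  if (length(dup)) {
    for (id in unique(dup)) {
      gv <- unique(assignments$group[assignments$sample_id == id])
      if (length(gv) > 1)
        stop("conflicting group assignments for sample ", id)
    }
    assignments <- assignments[!duplicated(assignments$sample_id), , drop = FALSE]
  }
  unknown <- setdiff(assignments$sample_id, g$samples$sample_id)
  if (length(unknown))
    warning("assignment ids not present in genotypes: ",
            paste(unknown, collapse = ", "))
  idx <- match(g$samples$sample_id, assignments$sample_id)
  g$samples$group <- factor(assignments$group[idx], levels = c("I", "II"))
  drop <- is.na(g$samples$group)
  if (any(drop)) {
    message(sum(drop), " sample(s) without a group assignment dropped")
    g <- keep_samples(g, !drop)
  }
  g
}
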