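# Offline region annotation: interval overlap of outlier regions against
# user-supplied gene/QTL interval sets, shared-gene intersection, and
# hypergeometric (one-sided Fisher) enrichment with Benjamini-Hochberg
# adjustment. Coordinates are 1-based inclusive internally; BED input is
# converted from 0-based half-open on load and back on write.

#' Load a named-interval annotation set
#'
#' Three formats are accepted:
#' \describe{
#'   \item{`"tsv"`}{gene-table layout with header columns `Symbol`, `SSC`
#'     (or `chrom`) and `Location` as `"start..end"`, plus an optional
#'     `Category` column; alternatively generic columns `name`, `chrom`,
#'     `start_bp`, `end_bp`, `category`.}
#'   \item{`"bed"`}{0-based half-open; columns chrom, start, end, and
#'     optionally name and category. Converted to 1-based inclusive.}
#'   \item{`"gff3"`}{read via \pkg{rtracklayer}; the record name is the
#'     `Name`/`ID`/`gene_id` attribute and the category the feature type.}
#' }
#'
#' @param path input file.
#' @param format `"tsv"`, `"bed"` or `"gff3"`.
#' @return An `annotation_set`: a data.frame with columns `name`, `chrom`,
#'   `start_bp`, `end_bp` (1-based inclusive), `category`.
#' @examples
#' tab <- system.file("extdata", "landrace_genes.tsv", package = "driftscan")
#' genes <- load_annotations(tab, "tsv")
#' nrow(genes)  # 17
#' @export
load_annotations <- function(path, format = c("tsv", "bed", "gff3")) {
  format <- match.arg(format)
  ann <- switch(format,
                tsv = load_ann_tsv(path),
                bed = load_ann_bed(path),
                gff3 = load_ann_gff3(path))
  if (nrow(ann)) {
    bad <- which(ann$end_bp < ann$start_bp)
    if (length(bad))
      stop("annotation '", ann$name[bad[1]], "': end < start")
    if (anyDuplicated(ann$name)) {
      warning("duplicate annotation names made unique")
      ann$name <- make.unique(ann$name)
    }
  }
  structure(ann, class = c("annotation_set", "data.frame"))
}

annotation_set <- function(name, chrom, start_bp, end_bp, category = NA_character_) {
  ann <- data.frame(name = as.character(name), chrom = as.character(chrom),
                    start_bp = as.integer(start_bp), end_bp = as.integer(end_bp),
                    category = rep_len(as.character(category), length(name)),
                    stringsAsFactors = FALSE)
  if (nrow(ann) && any(ann$end_bp < ann$start_bp)) stop("end < start")
  structure(ann, class = c("annotation_set", "data.frame"))
}

load_ann_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, comment.char = "#",
                           check.names = FALSE)
  if (!nrow(tab)) return(annotation_set(character(), character(), integer(), integer()))
  lc <- tolower(names(tab))
  if ("location" %in% lc) {
    loc <- tab[[which(lc == "location")[1]]]
    parts <- regmatches(loc, regexec("^\\s*(\\d+)\\.\\.(\\d+)\\s*$", loc))
    bad <- which(vapply(parts, length, 1L) != 3)
    if (length(bad))
      stop("malformed Location at line ", bad[1] + 1, " of ", path)
    start <- as.integer(vapply(parts, `[`, "", 2))
    end <- as.integer(vapply(parts, `[`, "", 3))
    name <- tab[[which(lc %in% c("symbol", "name"))[1]]]
    chrom <- tab[[which(lc %in% c("ssc", "chrom", "chr"))[1]]]
    cat_col <- which(lc == "category")
    category <- if (length(cat_col)) tab[[cat_col[1]]] else NA_character_
    annotation_set(name, chrom, start, end, category)
  } else {
    need <- c("name", "chrom", "start_bp", "end_bp")
    if (!all(need %in% lc))
      stop("TSV annotation file must have a Location column or columns ",
           paste(need, collapse = ", "))
    names(tab) <- lc
    annotation_set(tab$name, tab$chrom, tab$start_bp, tab$end_bp,
                   if ("category" %in% lc) tab$category else NA_character_)
  }
}

load_ann_bed <- function(path) {
  tab <- tryCatch(utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                                    stringsAsFactors = FALSE, comment.char = "#"),
                  error = function(e) {
                    if (grepl("no lines available", conditionMessage(e)))
                      return(NULL)
                    stop(e)
                  })
  if (is.null(tab) || !nrow(tab))
    return(annotation_set(character(), character(), integer(), integer()))
  if (ncol(tab) < 3) stop("BED file needs at least 3 columns: ", path)
  start0 <- suppressWarnings(as.integer(tab[[2]]))
  end0 <- suppressWarnings(as.integer(tab[[3]]))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad)) stop("malformed BED line ", bad[1], " of ", path)
  name <- if (ncol(tab) >= 4) as.character(tab[[4]]) else
    sprintf("interval_%d", seq_len(nrow(tab)))
  category <- if (ncol(tab) >= 5) as.character(tab[[5]]) else NA_character_
  annotation_set(name, tab[[1]], start0 + 1L, end0, category)
}

load_ann_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  name <- if (!is.null(md$Name)) as.character(md$Name) else NULL
  if (is.null(name) || all(is.na(name)))
    name <- if (!is.null(md$ID)) as.character(md$ID) else as.character(md$gene_id)
  if (is.null(name)) name <- sprintf("feature_%d", seq_along(gr))
  category <- if (!is.null(md$category)) as.character(md$category)
  else as.character(md$type)
  annotation_set(name, as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr), GenomicRanges::end(gr), category)
}

#' Write an annotation set as BED
#'
#' Converts the internal 1-based inclusive coordinates back to BED's
#' 0-based half-open convention, so `load_annotations(.., "bed")` of the
#' output reproduces the input set.
#'
#' @param ann an `annotation_set`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_annotations_bed <- function(ann, path) {
  tab <- data.frame(chrom = ann$chrom, start = ann$start_bp - 1L,
                    end = ann$end_bp, name = ann$name,
                    category = ifelse(is.na(ann$category), ".", ann$category),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Normalize chromosome names
#'
#' Strips `chr`/`SSC` prefixes (case-insensitive) and applies an optional
#' user alias map, so `"14"`, `"SSC14"` and `"chr14"` compare equal.
#'
#' @param x character vector of chromosome labels.
#' @param aliases optional named character vector mapping labels to
#'   canonical names, applied after prefix stripping.
#' @return Normalized labels.
#' @export
normalize_chrom <- function(x, aliases = NULL) {
  out <- sub("^(chr|ssc)", "", as.character(x), ignore.case = TRUE)
  if (!is.null(aliases)) {
    hit <- match(out, names(aliases))
    out[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
  }
  out
}

#' Overlap outlier regions with an annotation set
#'
#' A hit is any intersection of one base pair or more between a region and
#' an annotation interval (both 1-based inclusive; chromosome names are
#' normalized on both sides via [normalize_chrom()]). Overlap is computed
#' with \pkg{GenomicRanges}.
#'
#' @param regions a regions data.frame (from [merge_regions()] or an
#'   `fst_scan` object's `$regions`), or an `fst_scan` object.
#' @param ann an `annotation_set`.
#' @param aliases optional chromosome alias map, see [normalize_chrom()].
#' @return A data.frame with one row per (region, annotation) hit: columns
#'   `region`, `chrom`, `region_start`, `region_end`, `name`, `category`,
#'   `overlap_bp`.
#' @export
overlap_regions <- function(regions, ann, aliases = NULL) {
  if (inherits(regions, "fst_scan")) regions <- regions$regions
  empty <- data.frame(region = integer(), chrom = character(),
                      region_start = integer(), region_end = integer(),
                      name = character(), category = character(),
                      overlap_bp = integer(), stringsAsFactors = FALSE)
  if (!nrow(regions) || !nrow(ann)) return(empty)
  rchr <- normalize_chrom(regions$chrom, aliases)
  achr <- normalize_chrom(ann$chrom, aliases)
  missing_chr <- setdiff(unique(rchr), unique(achr))
  if (length(missing_chr))
    warning("region chromosome(s) absent from annotation set: ",
            paste(missing_chr, collapse = ", "))
  gr_r <- GenomicRanges::GRanges(rchr, IRanges::IRanges(regions$start_bp, regions$end_bp))
  gr_a <- GenomicRanges::GRanges(achr, IRanges::IRanges(ann$start_bp, ann$end_bp))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_r, gr_a))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  if (!length(qh)) return(empty)
  ov <- GenomicRanges::pintersect(gr_r[qh], gr_a[sh])
  data.frame(region = qh, chrom = regions$chrom[qh],
             region_start = regions$start_bp[qh], region_end = regions$end_bp[qh],
             name = ann$name[sh], category = ann$category[sh],
             overlap_bp = GenomicRanges::width(ov), stringsAsFactors = FALSE)
}

#' Genes shared between two result sets
#'
#' @param set_a,set_b character vectors of gene symbols.
#' @return The sorted intersection of the distinct symbols.
#' @examples
#' shared_genes(c("A2ML1", "MSI1", "ROBO2"), c("ROBO2", "A2ML1", "MSI2"))
#' @export
shared_genes <- function(set_a, set_b) {
  sort(intersect(unique(as.character(set_a)), unique(as.character(set_b))))
}

#' Category over-representation test
#'
#' One-sided Fisher exact test (hypergeometric upper tail) per category on
#' the 2x2 table of hit/non-hit by in/out of category, with
#' Benjamini-Hochberg adjustment across categories.
#'
#' @param hit_genes character vector of genes found in outlier regions;
#'   must be a subset of `background`.
#' @param category_map data.frame with columns `gene` and `category` (a gene
#'   may appear under several categories).
#' @param background character vector of all candidate genes (defaults in
#'   pipelines to every gene of the supplied gene-model file).
#' @return A data.frame sorted by p-value with columns `category`, `k_hit`,
#'   `n_hit_genes`, `K_category`, `N_background`, `p_value`, `q_value`.
#' @export
enrichment_test <- function(hit_genes, category_map, background) {
  background <- unique(as.character(background))
  hit_genes <- unique(as.character(hit_genes))
  if (!length(background)) stop("background gene set is empty")
  if (!all(hit_genes %in% background))
    stop("hit_genes must be a subset of background: missing ",
         paste(setdiff(hit_genes, background), collapse = ", "))
  category_map <- as.data.frame(category_map, stringsAsFactors = FALSE)
  if (!all(c("gene", "category") %in% names(category_map)))
    stop("category_map must have columns gene and category")
  category_map <- category_map[category_map$gene %in% background, , drop = FALSE]
  cats <- unique(category_map$category)
  N <- length(background); n <- length(hit_genes)
  rows <- lapply(cats, function(cat) {
    members <- unique(category_map$gene[category_map$category == cat])
    K <- length(members)
    k <- length(intersect(hit_genes, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(category = cat, k_hit = k, n_hit_genes = n, K_category = K,
               N_background = N, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(category = character(), k_hit = integer(),
                                      n_hit_genes = integer(), K_category = integer(),
                                      N_background = integer(), p_value = numeric(),
                                      q_value = numeric(), stringsAsFactors = FALSE))
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), , drop = FALSE]
}
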