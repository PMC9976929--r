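.region_set <- function(df, mode) {
  stopifnot(all(c("region_id", "chrom", "start", "end") %in% names(df)))
  if (anyDuplicated(df$region_id)) stop("duplicate region identifiers")
  if (any(df$start > df$end)) stop("region with start > end")
  rownames(df) <- NULL
  attr(df, "mode") <- mode
  class(df) <- c("region_set", "data.frame")
  df
}

#' Gene regions from an annotation
#'
#' One region per gene: the merged span of all its transcripts, identified by
#' the gene id. Donor and sex chromosomes can be excluded to mirror the
#' insertion filters.
#'
#' @param annotation A `feature_annotation`.
#' @param exclude_chroms Chromosomes to drop (e.g. donor and sex chromosomes).
#' @return A `region_set` (data frame `region_id`, `chrom`, `start`, `end`).
#' @export
make_gene_regions <- function(annotation, exclude_chroms = character()) {
  g <- annotation$gene_table
  g <- g[!(g$chrom %in% exclude_chroms), , drop = FALSE]
  if (nrow(g) == 0L) stop("no gene regions left after chromosome exclusion")
  .region_set(data.frame(region_id = g$gene_id, chrom = g$chrom,
                         start = g$start, end = g$end,
                         stringsAsFactors = FALSE), "gene")
}

#' Fixed-size window regions
#'
#' Tiles each chromosome with non-overlapping windows of the given size; the
#' last, possibly partial, window is included. Region ids are
#' `chrom:start-end` (1-based closed).
#'
#' @param lengths Named vector of chromosome lengths (see [chrom_lengths()]).
#' @param size Window size in bp (>= 1).
#' @param chroms Chromosomes to tile (default: all in `lengths`).
#' @return A `region_set`.
#' @export
make_window_regions <- function(lengths, size, chroms = names(lengths)) {
  stopifnot(size >= 1)
  out <- do.call(rbind, lapply(chroms, function(chrom) {
    len <- lengths[[chrom]]
    starts <- seq(1L, len, by = size)
    ends <- pmin(starts + size - 1L, len)
    data.frame(region_id = sprintf("%s:%d-%d", chrom, starts, ends),
               chrom = chrom, start = starts, end = ends,
               stringsAsFactors = FALSE)
  }))
  .region_set(out, "window")
}

#' Custom regions from a GTF file
#'
#' Accepts a user annotation (e.g. promoters, enhancers); ids are taken from
#' the `gene_id` (or `ID`) attribute and must be unique.
#'
#' @param path GTF file.
#' @param exclude_chroms Chromosomes to drop.
#' @return A `region_set`.
#' @export
load_custom_regions <- function(path, exclude_chroms = character()) {
  gr <- rtracklayer::import(path, format = "gtf")
  if (length(gr) == 0L) stop("no regions in file: ", path)
  ids <- S4Vectors::mcols(gr)$gene_id
  if (is.null(ids)) ids <- S4Vectors::mcols(gr)$ID
  if (is.null(ids)) stop("custom region file carries no gene_id/ID attribute")
  df <- data.frame(region_id = as.character(ids),
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  df <- df[!(df$chrom %in% exclude_chroms), , drop = FALSE]
  if (nrow(df) == 0L) stop("no regions left after chromosome exclusion")
  .region_set(df, "custom")
}

#' Aggregate per-site rates into per-region neutral rates
#'
#' The neutral rate of a region is the sum of the rates of all motif sites
#' whose start lies inside it; a site inside two overlapping regions
#' contributes to both. In null mode the per-site rates are identically 1, so
#' the region rate reduces to the motif count.
#'
#' @param rates Site rate table (`chrom`, `pos`, `lambda`) from
#'   [predict_site_rates()] or [constant_site_rates()], sorted by position
#'   within chromosome, or a `motif_index` (implies `mode = "null"`).
#' @param regions A `region_set`.
#' @param mode `"mutagenesis"` (sum of rates) or `"null"` (motif count).
#' @return Data frame `region_id`, `chrom`, `start`, `end`, `n_motif_sites`,
#'   `Lambda`, with attribute `"mode"`.
#' @export
aggregate_region_rates <- function(rates, regions,
                                   mode = c("mutagenesis", "null")) {
  mode <- match.arg(mode)
  if (inherits(rates, "motif_index")) {
    mode <- "null"
    rates <- constant_site_rates(rates)
  }
  if (mode == "null") rates$lambda <- 1
  missing_chrom <- setdiff(unique(regions$chrom), unique(rates$chrom))
  if (length(missing_chrom)) {
    stop("region chromosome(s) absent from the rate table: ",
         paste(missing_chrom, collapse = ", "))
  }
  n_sites <- integer(nrow(regions))
  Lambda <- numeric(nrow(regions))
  for (chrom in unique(regions$chrom)) {
    rsel <- which(regions$chrom == chrom)
    s <- rates[rates$chrom == chrom, , drop = FALSE]
    o <- order(s$pos)
    pos <- s$pos[o]
    csum <- cumsum(s$lambda[o])
    i1 <- findInterval(regions$start[rsel] - 1L, pos)
    i2 <- findInterval(regions$end[rsel], pos)
    n_sites[rsel] <- i2 - i1
    Lambda[rsel] <- ifelse(i2 > 0, csum[pmax(i2, 1L)], 0) -
      ifelse(i1 > 0, csum[pmax(i1, 1L)], 0)
  }
  out <- data.frame(region_id = regions$region_id, chrom = regions$chrom,
                    start = regions$start, end = regions$end,
                    n_motif_sites = n_sites, Lambda = Lambda,
                    stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  out
}
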