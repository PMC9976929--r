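#' Snap insertion positions to the nearest motif site
#'
#' Mapping artifacts can place an insertion a few nucleotides off the
#' canonical TA/TTAA position. Each record is moved to the nearest indexed
#' motif start within `max_shift` bp of its reported position; ties are broken
#' towards the leftmost motif. Records with no motif within range, or on a
#' chromosome absent from the index, are dropped and counted.
#'
#' @param insertions Data frame from [read_insertions()].
#' @param index A `motif_index`.
#' @param max_shift Maximum allowed shift in bp (default 5).
#' @return The snapped data frame, with attribute `"snap_report"`: a list with
#'   `n_input`, `n_snapped` (moved), `n_exact`, `n_dropped`.
#' @export
snap_to_motif <- function(insertions, index, max_shift = 5L) {
  stopifnot(inherits(index, "motif_index"), max_shift >= 0)
  if (nrow(insertions) == 0L) {
    attr(insertions, "snap_report") <- list(n_input = 0L, n_exact = 0L,
                                            n_snapped = 0L, n_dropped = 0L)
    return(insertions)
  }
  new_pos <- rep(NA_integer_, nrow(insertions))
  for (chrom in unique(insertions$chrom)) {
    sel <- which(insertions$chrom == chrom)
    sites <- index$positions[[chrom]]
    if (is.null(sites) || length(sites) == 0L) next
    p <- insertions$pos[sel]
    i <- findInterval(p, sites)
    lo <- ifelse(i >= 1L, sites[pmax(i, 1L)], NA_integer_)
    hi <- ifelse(i < length(sites), sites[pmin(i + 1L, length(sites))],
                 NA_integer_)
    d_lo <- abs(p - lo); d_hi <- abs(hi - p)
    d_lo[is.na(d_lo)] <- .Machine$integer.max
    d_hi[is.na(d_hi)] <- .Machine$integer.max
    # leftmost wins ties
    best <- ifelse(d_lo <= d_hi, lo, hi)
    best_d <- pmin(d_lo, d_hi)
    best[best_d > max_shift] <- NA_integer_
    new_pos[sel] <- best
  }
  keep <- !is.na(new_pos)
  report <- list(n_input = nrow(insertions),
                 n_exact = sum(keep & new_pos == insertions$pos),
                 n_snapped = sum(keep & new_pos != insertions$pos),
                 n_dropped = sum(!keep))
  out <- insertions[keep, , drop = FALSE]
  out$pos <- new_pos[keep]
  rownames(out) <- NULL
  attr(out, "snap_report") <- report
  out
}

#' Exclude donor and sex chromosomes
#'
#' Transposons re-insert preferentially near their donor locus ("local
#' hopping"), which the rate model does not capture; the chromosome carrying
#' the donor transposon concatemer is therefore removed entirely, as are sex
#' chromosomes (present in differing copy number between animals).
#'
#' @param insertions Insertion data frame.
#' @param donor_chrom Donor chromosome id, or `NULL` to disable.
#' @param sex_chroms Character vector of sex chromosome ids.
#' @return Filtered data frame with attribute `"filter_report"`: counts
#'   removed per reason and the fraction retained.
#' @export
filter_insertions <- function(insertions, donor_chrom = NULL,
                              sex_chroms = c("chrX", "chrY")) {
  n0 <- nrow(insertions)
  is_donor <- if (is.null(donor_chrom)) rep(FALSE, n0) else
    insertions$chrom %in% donor_chrom
  is_sex <- insertions$chrom %in% sex_chroms
  keep <- !(is_donor | is_sex)
  out <- insertions[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_report") <- list(
    n_input = n0,
    donor_chromosome = sum(is_donor),
    sex_chromosome = sum(is_sex & !is_donor),
    fraction_retained = if (n0 == 0L) 1 else sum(keep) / n0)
  out
}

#' Unique insertion sites
#'
#' Collapses records to distinct genomic sites, discarding coverage (read
#' counts). `unique_sites()` pools all samples and yields genome-wide unique
#' sites (the positives used to train the mutagenesis model);
#' `unique_sites_per_sample()` keeps the sample identity and feeds the
#' per-sample count matrix of the selection model.
#'
#' @param insertions Insertion data frame (snapped).
#' @return Data frame of distinct `(chrom, pos)` rows, or distinct
#'   `(chrom, pos, sample_id)` rows, sorted by chromosome and position.
#' @export
unique_sites <- function(insertions) {
  out <- unique(insertions[, c("chrom", "pos"), drop = FALSE])
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname unique_sites
#' @export
unique_sites_per_sample <- function(insertions) {
  out <- unique(insertions[, c("chrom", "pos", "sample_id"), drop = FALSE])
  out <- out[order(out$chrom, out$pos, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full preprocessing chain
#'
#' Snap to motif, drop donor/sex chromosomes, and report.
#'
#' @inheritParams snap_to_motif
#' @inheritParams filter_insertions
#' @return Filtered, snapped insertion data frame carrying both reports.
#' @export
preprocess_insertions <- function(insertions, index, max_shift = 5L,
                                  donor_chrom = NULL,
                                  sex_chroms = c("chrX", "chrY")) {
  snapped <- snap_to_motif(insertions, index, max_shift = max_shift)
  out <- filter_insertions(snapped, donor_chrom = donor_chrom,
                           sex_chroms = sex_chroms)
  attr(out, "snap_report") <- attr(snapped, "snap_report")
  out
}
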