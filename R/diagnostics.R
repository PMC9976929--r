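#' Sequence-logo information content around insertion sites
#'
#' For each position in a window around the motif start, computes the
#' information content in bits, `2 - H`, where `H` is the Shannon entropy of
#' the empirical A/C/G/T distribution at that position (N and off-chromosome
#' padding are excluded from the tally). Invariant positions (e.g. the motif
#' itself after snapping) score exactly 2 bits; a uniform position scores 0.
#'
#' @param sites Data frame `chrom`, `pos` (motif starts).
#' @param genome `DNAStringSet`.
#' @param motif Motif string (defines the window core).
#' @param flank Flank in bp on either side (default 10).
#' @return Data frame with `offset` (relative to the motif start), the four
#'   base frequencies, and `bits`.
#' @export
sequence_logo_bits <- function(sites, genome, motif, flank = 10L) {
  stopifnot(nrow(sites) >= 1L)
  w <- nchar(motif) + 2L * flank
  chars <- character(0)
  seqs <- character(nrow(sites))
  for (chrom in unique(sites$chrom)) {
    sel <- which(sites$chrom == chrom)
    p <- sites$pos[sel]
    clen <- length(genome[[chrom]])
    start <- p - flank; end <- p + nchar(motif) - 1L + flank
    cs <- pmax(start, 1L); ce <- pmin(end, clen)
    s <- as.character(Biostrings::extractAt(genome[[chrom]],
                                            IRanges::IRanges(cs, ce)))
    seqs[sel] <- paste0(strrep("N", pmax(1L - start, 0L)), s,
                        strrep("N", pmax(end - clen, 0L)))
  }
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), nrow = length(seqs),
              byrow = TRUE)
  bases <- c("A", "C", "G", "T")
  out <- do.call(rbind, lapply(seq_len(w), function(j) {
    counts <- vapply(bases, function(b) sum(m[, j] == b), numeric(1))
    tot <- sum(counts)
    freq <- if (tot > 0) counts / tot else rep(0, 4)
    h <- -sum(ifelse(freq > 0, freq * log2(freq), 0))
    data.frame(offset = j - flank - 1L, A = freq[1], C = freq[2],
               G = freq[3], T = freq[4],
               bits = if (tot > 0) 2 - h else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

# signed distance of each position to the nearest anchor; anchors is a data
# frame with `pos` and optional `strand`; sign is (pos - anchor), flipped on
# the minus strand so positive always means downstream of the anchor
.signed_nearest <- function(p, anchors) {
  v <- anchors$pos
  o <- order(v)
  v <- v[o]
  strand <- if (!is.null(anchors$strand)) anchors$strand[o] else
    rep("+", length(v))
  i <- findInterval(p, v)
  lo <- pmax(i, 1L); hi <- pmin(i + 1L, length(v))
  d_lo <- abs(p - v[lo]); d_hi <- abs(v[hi] - p)
  d_lo[i < 1L] <- Inf; d_hi[i >= length(v)] <- Inf
  pick <- ifelse(d_lo <= d_hi, lo, hi)
  signed <- p - v[pick]
  ifelse(strand[pick] == "-", -signed, signed)
}

#' Fold-enrichment profile around feature anchors
#'
#' Bins the signed distance of each site to its nearest anchor into windows
#' (500 bp by default) and reports, per bin, the ratio of the proportion of
#' insertion sites to the proportion of control sites. Bins with no controls
#' are emitted as `NA`.
#'
#' @param sites,controls Data frames `chrom`, `pos`.
#' @param anchors Named list (per chromosome) of data frames with `pos` and
#'   optionally `strand` ("-" flips the sign so positive offsets are always
#'   downstream of the anchor).
#' @param window Bin width in bp (default 500).
#' @param span Half-width of the profiled range in bp (default 5000).
#' @return Data frame `bin_start`, `bin_end`, `prop_sites`, `prop_controls`,
#'   `fold`.
#' @export
fold_enrichment_profile <- function(sites, controls, anchors, window = 500L,
                                    span = 5000L) {
  stopifnot(nrow(controls) > 0L)
  signed_d <- function(df) {
    unlist(lapply(unique(df$chrom), function(chrom) {
      a <- anchors[[chrom]]
      p <- df$pos[df$chrom == chrom]
      if (is.null(a) || nrow(a) == 0L) return(rep(NA_real_, length(p)))
      .signed_nearest(p, a)
    }))
  }
  ds <- signed_d(sites); dc <- signed_d(controls)
  breaks <- seq(-span, span, by = window)
  bin <- function(d) {
    d <- d[!is.na(d) & d >= -span & d < span]
    tabulate(findInterval(d, breaks), nbins = length(breaks) - 1L)
  }
  cs <- bin(ds); cc <- bin(dc)
  prop_s <- cs / max(length(ds[!is.na(ds)]), 1L)
  prop_c <- cc / max(length(dc[!is.na(dc)]), 1L)
  fold <- ifelse(cc > 0, prop_s / prop_c, NA_real_)
  data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1],
             prop_sites = prop_s, prop_controls = prop_c, fold = fold)
}

#' Precision among top-ranked regions against a truth catalogue
#'
#' Ranks regions by p-value (ascending) and reports, for each N, the fraction
#' of truth-set members among the regions ranked in the top N. Tied p-values
#' share the highest rank of their tie group, so no member of a tie group
#' enters the top-N set until N reaches the end of the group.
#'
#' @param ids Region/gene identifiers (deduplicated; keep the lowest p per
#'   gene beforehand).
#' @param p P-values (or any ascending ranking score), same length as `ids`.
#' @param truth Character vector of known positives (non-empty).
#' @return Data frame `N`, `n_true`, `precision`.
#' @export
precision_curve <- function(ids, p, truth) {
  stopifnot(length(ids) == length(p))
  if (length(truth) == 0L) stop("empty truth set")
  if (anyDuplicated(ids)) stop("duplicate identifiers; deduplicate first")
  r <- rank(p, ties.method = "max")
  is_true <- ids %in% truth
  n <- length(ids)
  n_true <- vapply(seq_len(n), function(N) sum(is_true[r <= N]), numeric(1))
  data.frame(N = seq_len(n), n_true = n_true,
             precision = n_true / seq_len(n))
}

#' Jaccard index of two gene lists
#'
#' Intersection over union of the two sets; returns 0 (with a message) when
#' both are empty.
#'
#' @param a,b Character vectors.
#' @return Scalar in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- union(a, b)
  if (length(u) == 0L) {
    message("both lists empty; Jaccard index defined as 0")
    return(0)
  }
  length(intersect(a, b)) / length(u)
}
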