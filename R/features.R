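# Distance machinery for the mutagenesis feature set. All positions 1-based;
# distances are unsigned bp, 0 when the query lies on/inside the feature.

# nearest distance from each position in p to any point in sorted vector v
.dist_to_points <- function(p, v) {
  if (length(v) == 0L) return(rep(NA_real_, length(p)))
  i <- findInterval(p, v)
  lo <- ifelse(i >= 1L, v[pmax(i, 1L)], NA_real_)
  hi <- ifelse(i < length(v), v[pmin(i + 1L, length(v))], NA_real_)
  pmin(abs(p - lo), abs(hi - p), na.rm = TRUE)
}

# nearest gap from each position in p to merged sorted intervals (closed)
.dist_to_intervals <- function(p, iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(rep(NA_real_, length(p)))
  i <- findInterval(p, iv$start)
  inside <- i >= 1L & p <= iv$end[pmax(i, 1L)]
  d_left <- ifelse(i >= 1L, p - iv$end[pmax(i, 1L)], NA_real_)
  d_right <- ifelse(i < nrow(iv), iv$start[pmin(i + 1L, nrow(iv))] - p,
                    NA_real_)
  d <- pmin(d_left, d_right, na.rm = TRUE)
  d[inside] <- 0
  d
}

# distance feature for sites on one chromosome; fallback = chrom length when
# the chromosome carries no feature of this class
.feature_distance <- function(p, feat, chrom, fallback, warned_env = NULL) {
  obj <- feat[[chrom]]
  d <- if (is.data.frame(obj)) .dist_to_intervals(p, obj)
       else .dist_to_points(p, obj)
  if (anyNA(d)) {
    if (!is.null(warned_env) && is.null(warned_env$seen[[chrom]])) {
      warning("no features on chromosome '", chrom,
              "'; distance falls back to chromosome length", call. = FALSE)
      warned_env$seen[[chrom]] <- TRUE
    }
    d[is.na(d)] <- fallback
  }
  d
}

# one-hot encode fixed-width sequence windows; N (and off-chromosome padding)
# becomes an all-zero block
.onehot <- function(seq_chars) {
  n <- length(seq_chars)
  if (n == 0L) return(matrix(numeric(0), 0, 0))
  w <- nchar(seq_chars[1])
  m <- matrix(unlist(strsplit(seq_chars, "", fixed = TRUE)), nrow = n,
              byrow = TRUE)
  bases <- c("A", "C", "G", "T")
  out <- matrix(0, n, 4L * w)
  for (j in seq_len(w)) {
    for (b in seq_along(bases)) {
      out[, 4L * (j - 1L) + b] <- as.numeric(m[, j] == bases[b])
    }
  }
  colnames(out) <- as.vector(outer(bases, seq_len(w),
                                   function(b, j) sprintf("seq_%02d_%s", j, b)))
  out
}

#' Feature schema of the mutagenesis model
#'
#' @param motif Motif string, determining the sequence-window width
#'   (10 bp + motif + 10 bp).
#' @param flank Flank size in bp (default 10).
#' @return Character vector of ordered feature names.
#' @export
feature_schema <- function(motif, flank = 10L) {
  w <- nchar(motif) + 2L * flank
  seq_names <- as.vector(outer(c("A", "C", "G", "T"), seq_len(w),
                               function(b, j) sprintf("seq_%02d_%s", j, b)))
  c(seq_names, "d_tss", "d_tts", "d_gene", "d_dnase", "d_atac")
}

#' Extract mutagenesis-model features for motif sites
#'
#' For each site (a motif start) the feature vector is the one-hot encoded
#' sequence of a fixed window spanning 10 bp upstream, the motif, and 10 bp
#' downstream, plus the unsigned distances to the nearest TSS, TTS, gene body,
#' DNase-seq peak and ATAC-seq peak (0 for sites on/inside a feature, e.g.
#' intragenic sites have `d_gene = 0`). Window positions falling off the
#' chromosome are encoded as all-zero one-hot columns.
#'
#' @param sites Data frame with columns `chrom`, `pos`.
#' @param genome `DNAStringSet`.
#' @param annotation A `feature_annotation`.
#' @param motif Motif string ("TA"/"TTAA").
#' @param flank Sequence flank in bp (default 10).
#' @return Numeric matrix, one row per site, columns per [feature_schema()].
#' @export
extract_features <- function(sites, genome, annotation, motif, flank = 10L) {
  schema <- feature_schema(motif, flank)
  n <- nrow(sites)
  out <- matrix(0, n, length(schema), dimnames = list(NULL, schema))
  if (n == 0L) return(out)
  warned <- new.env(); warned$seen <- list()
  w <- nchar(motif) + 2L * flank
  for (chrom in unique(sites$chrom)) {
    sel <- which(sites$chrom == chrom)
    p <- sites$pos[sel]
    clen <- length(genome[[chrom]])
    start <- p - flank
    end <- p + nchar(motif) - 1L + flank
    cs <- pmax(start, 1L); ce <- pmin(end, clen)
    seqs <- as.character(Biostrings::extractAt(
      genome[[chrom]], IRanges::IRanges(cs, ce)))
    pad_l <- strrep("N", pmax(1L - start, 0L))
    pad_r <- strrep("N", pmax(end - clen, 0L))
    seqs <- paste0(pad_l, seqs, pad_r)
    stopifnot(all(nchar(seqs) == w))
    out[sel, seq_len(4L * w)] <- .onehot(seqs)
    out[sel, "d_tss"] <- .feature_distance(p, annotation$tss, chrom, clen,
                                           warned)
    out[sel, "d_tts"] <- .feature_distance(p, annotation$tts, chrom, clen,
                                           warned)
    out[sel, "d_gene"] <- .feature_distance(p, annotation$genes, chrom, clen,
                                            warned)
    out[sel, "d_dnase"] <- .feature_distance(p, annotation$dnase, chrom, clen,
                                             warned)
    out[sel, "d_atac"] <- .feature_distance(p, annotation$atac, chrom, clen,
                                            warned)
  }
  out
}
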