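#' Read a genome from a FASTA file
#'
#' Loads all records of a (multi-)FASTA file into a [Biostrings::DNAStringSet],
#' uppercasing the sequence and validating that only the A/C/G/T/N alphabet is
#' used and that record names are unique.
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet`, one entry per chromosome.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  # read raw (readDNAStringSet silently drops invalid letters) and validate
  raw <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(raw) == 0L) stop("empty FASTA: ", path)
  # keep only the first whitespace-delimited token of each header
  names(raw) <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(names(raw))) {
    dup <- unique(names(raw)[duplicated(names(raw))])
    stop("duplicate chromosome name(s) in FASTA: ", paste(dup, collapse = ", "))
  }
  chars <- toupper(as.character(raw))
  for (i in seq_along(chars)) {
    stripped <- gsub("[ACGTN]", "", chars[[i]])
    if (nchar(stripped) > 0L) {
      stop("invalid symbol(s) in record '", names(raw)[i], "': ",
           paste(unique(strsplit(stripped, "")[[1]]), collapse = ", "))
    }
  }
  seqs <- Biostrings::DNAStringSet(chars)
  names(seqs) <- names(raw)
  seqs
}

#' Chromosome lengths of a genome
#' @param genome A `DNAStringSet` as returned by [read_genome()].
#' @return Named integer vector of lengths in bp.
#' @export
chrom_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

#' Build an index of TA/TTAA motif sites
#'
#' Scans every chromosome for exact forward-strand occurrences of the target
#' motif. TA and TTAA are reverse-complement palindromes, so a forward scan
#' finds every double-stranded occurrence; non-palindromic motifs would need a
#' second scan of the reverse strand.
#'
#' @param genome A `DNAStringSet`.
#' @param motif `"TA"` (Sleeping Beauty) or `"TTAA"` (PiggyBac).
#' @param analysis_chroms Chromosomes that form the analysis universe (used
#'   for `total_sites`, the denominator of the calibration constant f0).
#'   Defaults to all chromosomes of `genome`.
#' @return An object of class `motif_index`: list with `motif`, `positions`
#'   (per chromosome, sorted 1-based starts), `analysis_chroms`,
#'   `chrom_lengths` and `total_sites`.
#' @export
build_motif_index <- function(genome, motif = c("TA", "TTAA"),
                              analysis_chroms = names(genome)) {
  motif <- match.arg(motif)
  if (length(analysis_chroms) == 0L) stop("empty analysis chromosome set")
  if (!all(analysis_chroms %in% names(genome))) {
    stop("analysis chromosomes absent from genome: ",
         paste(setdiff(analysis_chroms, names(genome)), collapse = ", "))
  }
  positions <- lapply(seq_along(genome), function(i) {
    m <- Biostrings::matchPattern(motif, genome[[i]])
    as.integer(Biostrings::start(m))
  })
  names(positions) <- names(genome)
  idx <- structure(
    list(motif = motif,
         positions = positions,
         analysis_chroms = analysis_chroms,
         chrom_lengths = chrom_lengths(genome),
         total_sites = sum(lengths(positions[analysis_chroms]))),
    class = "motif_index")
  idx
}

#' @export
print.motif_index <- function(x, ...) {
  cat("Motif index (", x$motif, "): ",
      format(sum(lengths(x$positions)), big.mark = ","), " sites on ",
      length(x$positions), " chromosome(s); ",
      format(x$total_sites, big.mark = ","),
      " in the analysis universe (", length(x$analysis_chroms),
      " chromosome(s))\n", sep = "")
  invisible(x)
}

#' Read a transposon insertion table
#'
#' Reads a tab-separated table with header columns `chrom`, `pos`, `sample_id`
#' and optionally `strand` and `read_count`. Read counts are parsed and kept
#' for provenance but play no role downstream: the pipeline works on unique
#' insertion sites.
#'
#' @param path Path to the TSV file.
#' @param zero_based If `TRUE`, input positions are 0-based and are converted
#'   to the package's internal 1-based convention on read.
#' @return A `data.frame` with columns `chrom`, `pos` (1-based), `sample_id`,
#'   `raw_pos` and, when present in the file, `read_count`.
#' @export
read_insertions <- function(path, zero_based = FALSE) {
  if (!file.exists(path)) stop("insertion table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  required <- c("chrom", "pos", "sample_id")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("insertion table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(tab) == 0L) {
    warning("insertion table has a header but no records: ", path)
    return(data.frame(chrom = character(), pos = integer(),
                      sample_id = character(), raw_pos = integer()))
  }
  pos_num <- suppressWarnings(as.numeric(tab$pos))
  bad <- which(is.na(pos_num) | pos_num != floor(pos_num) | pos_num < 0)
  if (length(bad)) {
    stop("non-integer or negative position at line ", bad[1] + 1L,
         " (value '", tab$pos[bad[1]], "')")
  }
  if (any(!nzchar(tab$sample_id))) stop("empty sample_id encountered")
  out <- data.frame(chrom = tab$chrom,
                    pos = as.integer(pos_num) + as.integer(zero_based),
                    sample_id = tab$sample_id,
                    raw_pos = as.integer(pos_num),
                    stringsAsFactors = FALSE)
  if ("read_count" %in% names(tab)) {
    rc <- suppressWarnings(as.integer(tab$read_count))
    if (any(is.na(rc) | rc < 0)) stop("invalid read_count values")
    out$read_count <- rc
  }
  out
}

#' Write an insertion table
#'
#' Inverse of [read_insertions()]: writes `chrom`, `pos`, `sample_id` (plus
#' `read_count` when present) as TSV in the package's 1-based convention.
#'
#' @param insertions Data frame with at least `chrom`, `pos`, `sample_id`.
#' @param path Output path.
#' @export
write_insertions <- function(insertions, path) {
  cols <- intersect(c("chrom", "pos", "sample_id", "read_count"),
                    names(insertions))
  utils::write.table(insertions[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- feature annotation ----------------------------------------------------

.sort_points <- function(x) lapply(x, function(v) sort(unique(as.integer(v))))

# merge possibly overlapping 1-based closed intervals, per chromosome
.merge_intervals <- function(df) {
  if (is.null(df) || nrow(df) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  df <- df[order(df$start, df$end), , drop = FALSE]
  start <- df$start; end <- df$end
  keep_start <- start[1]; keep_end <- end[1]
  out_s <- integer(0); out_e <- integer(0)
  if (nrow(df) > 1L) {
    for (i in 2:nrow(df)) {
      if (start[i] <= keep_end + 1L) {
        keep_end <- max(keep_end, end[i])
      } else {
        out_s <- c(out_s, keep_start); out_e <- c(out_e, keep_end)
        keep_start <- start[i]; keep_end <- end[i]
      }
    }
  }
  data.frame(start = c(out_s, keep_start), end = c(out_e, keep_end))
}

.split_intervals <- function(chrom, start, end) {
  sp <- split(data.frame(start = as.integer(start), end = as.integer(end)),
              chrom)
  lapply(sp, .merge_intervals)
}

#' Construct a feature annotation
#'
#' Low-level constructor for the container holding the genomic features used
#' by the mutagenesis model: TSS and TTS coordinates (points), merged gene
#' bodies, and merged DNase-/ATAC-seq peak intervals, all per chromosome and
#' 1-based.
#'
#' @param gene_table Data frame with `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (one merged span per gene).
#' @param dnase,atac Data frames with `chrom`, `start`, `end` (may be empty or
#'   `NULL`).
#' @return Object of class `feature_annotation`.
#' @export
feature_annotation <- function(gene_table,
                               dnase = NULL, atac = NULL) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in%
                  names(gene_table)))
  if (anyDuplicated(gene_table$gene_id)) {
    stop("duplicate gene identifiers in annotation")
  }
  if (any(gene_table$start > gene_table$end)) stop("gene with start > end")
  plus <- gene_table$strand != "-"
  tss <- ifelse(plus, gene_table$start, gene_table$end)
  tts <- ifelse(plus, gene_table$end, gene_table$start)
  empty <- data.frame(chrom = character(), start = integer(), end = integer())
  if (is.null(dnase)) dnase <- empty
  if (is.null(atac)) atac <- empty
  structure(
    list(gene_table = gene_table,
         tss = .sort_points(split(tss, gene_table$chrom)),
         tts = .sort_points(split(tts, gene_table$chrom)),
         genes = .split_intervals(gene_table$chrom, gene_table$start,
                                  gene_table$end),
         dnase = .split_intervals(dnase$chrom, dnase$start, dnase$end),
         atac = .split_intervals(atac$chrom, atac$start, atac$end)),
    class = "feature_annotation")
}

#' @export
print.feature_annotation <- function(x, ...) {
  cat("Feature annotation: ", nrow(x$gene_table), " genes on ",
      length(unique(x$gene_table$chrom)), " chromosome(s); ",
      sum(vapply(x$dnase, nrow, 1L)), " DNase peaks; ",
      sum(vapply(x$atac, nrow, 1L)), " ATAC peaks\n", sep = "")
  invisible(x)
}

#' Read a gene annotation from GTF
#'
#' Imports a GTF file and reduces it to one merged genomic span per gene
#' identifier (union of all its transcripts). The TSS is the 5' end and the
#' TTS the 3' end of that span, by strand. Records with an unknown strand are
#' treated as `+` with a warning.
#'
#' @param path GTF file.
#' @param dnase,atac Optional peak data frames (see [read_peaks()]) attached to
#'   the returned annotation.
#' @return A `feature_annotation`.
#' @export
read_annotation <- function(path, dnase = NULL, atac = NULL) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("cannot parse GTF '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (length(gr) == 0L) stop("no features in annotation: ", path)
  ids <- S4Vectors::mcols(gr)$gene_id
  if (is.null(ids)) ids <- S4Vectors::mcols(gr)$ID
  if (is.null(ids)) stop("GTF has no gene_id attribute: ", path)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) {
    warning("features with unknown strand treated as '+'")
    strand[strand == "*"] <- "+"
  }
  df <- data.frame(gene_id = ids,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = strand, stringsAsFactors = FALSE)
  # one merged span per gene id; strand/chrom taken from its records
  merged <- do.call(rbind, lapply(split(df, df$gene_id), function(g) {
    if (length(unique(g$chrom)) > 1L) {
      stop("gene '", g$gene_id[1], "' spans multiple chromosomes")
    }
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               start = min(g$start), end = max(g$end),
               strand = g$strand[1], stringsAsFactors = FALSE)
  }))
  rownames(merged) <- NULL
  feature_annotation(merged, dnase = dnase, atac = atac)
}

#' Read peak intervals from BED or narrowPeak
#'
#' Reads a BED-family file into a per-chromosome interval table. narrowPeak
#' files (BED6+4) carry a -log10 q-value in column 9; peaks failing the
#' q-value threshold are dropped. Plain BED files have no q-value column and
#' pass the filter unconditionally. Overlapping retained peaks are merged.
#'
#' @param path BED or narrowPeak file.
#' @param qvalue_threshold Retain peaks with q-value below this (default 0.05).
#' @return Data frame `chrom`, `start`, `end` (1-based closed, merged).
#' @export
read_peaks <- function(path, qvalue_threshold = 0.05) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  n_fields <- max(utils::count.fields(path, sep = "\t"), 0L)
  if (is.na(n_fields) || length(readLines(path, n = 1L)) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  if (n_fields >= 10L) {
    extra <- c(signalValue = "numeric", pValue = "numeric",
               qValue = "numeric", peak = "integer")
    gr <- rtracklayer::import(path, format = "BED", extraCols = extra)
    keep <- 10 ^ (-S4Vectors::mcols(gr)$qValue) < qvalue_threshold
    gr <- gr[keep]
  } else {
    gr <- rtracklayer::import(path, format = "BED")
  }
  if (length(gr) == 0L) {
    stop("no peaks retained from '", path, "' after q-value filter")
  }
  gr <- GenomicRanges::reduce(gr)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}
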