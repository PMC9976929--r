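#' Configuration for a synthetic transposon screen
#'
#' Bundles every knob of the generative model behind the synthetic screens:
#' genome geometry, annotation density, the feature-to-rate bias weights, the
#' global depth/chromosome factors of the count model, and planted selection
#' coefficients. The seed fully determines every downstream artifact.
#'
#' @param seed Integer seed.
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @param motif `"TA"` or `"TTAA"`.
#' @param n_genes Total number of (non-overlapping) genes.
#' @param gene_length Length range `c(min, max)` in bp.
#' @param n_peaks Peaks per accessibility assay per chromosome.
#' @param peak_length Peak length range `c(min, max)` in bp.
#' @param bias_weights Named coefficients on the log insertion rate:
#'   `gene` (indicator of an intragenic site), `tss` (multiplies
#'   `exp(-d_tss / tss_decay)`), `atac`, `dnase` (in-peak indicators).
#' @param tss_decay Decay length of the TSS-proximity feature in bp.
#' @param n_samples Number of tumours.
#' @param depth_factors Per-sample depth factors sigma (default: a 4-fold
#'   geometric spread around 1).
#' @param chrom_factors Per-chromosome factors chi (default: an even spread
#'   over \[0.8, 1.25\]).
#' @param selected_regions Data frame `region_id`, `beta` of planted selected
#'   genes (`NULL` for a null screen).
#' @param insertions_per_sample Expected neutral unique insertions per sample
#'   at depth factor 1.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chroms = 2L, chrom_length = 1e6,
                       motif = c("TA", "TTAA"), n_genes = 100L,
                       gene_length = c(5000L, 15000L), n_peaks = 20L,
                       peak_length = c(1000L, 3000L),
                       bias_weights = c(gene = 0.5, tss = 1.5, atac = 1.5,
                                        dnase = 1.0),
                       tss_decay = 1e4, n_samples = 10L,
                       depth_factors = NULL, chrom_factors = NULL,
                       selected_regions = NULL,
                       insertions_per_sample = 2000) {
  motif <- match.arg(motif)
  stopifnot(chrom_length >= 1000, n_chroms >= 1, n_samples >= 1)
  if (is.null(depth_factors)) {
    depth_factors <- exp(seq(log(0.5), log(2), length.out = n_samples))
  }
  if (is.null(chrom_factors)) {
    chrom_factors <- if (n_chroms == 1L) 1 else
      seq(0.8, 1.25, length.out = n_chroms)
  }
  stopifnot(length(depth_factors) == n_samples,
            length(chrom_factors) == n_chroms,
            all(depth_factors > 0), all(chrom_factors > 0))
  structure(list(
    seed = seed, n_chroms = n_chroms, chrom_length = chrom_length,
    motif = motif, n_genes = n_genes, gene_length = gene_length,
    n_peaks = n_peaks, peak_length = peak_length,
    bias_weights = bias_weights, tss_decay = tss_decay,
    n_samples = n_samples,
    depth_factors = stats::setNames(depth_factors,
                                    sprintf("T%02d", seq_len(n_samples))),
    chrom_factors = stats::setNames(chrom_factors,
                                    sprintf("chr%d", seq_len(n_chroms))),
    selected_regions = selected_regions,
    insertions_per_sample = insertions_per_sample), class = "sim_config")
}

# place n non-overlapping intervals of the given lengths on [1, len]
.place_intervals <- function(n, len, length_range) {
  if (n == 0L) return(data.frame(start = integer(), end = integer()))
  widths <- sample(length_range[1]:length_range[2], n, replace = TRUE)
  free <- len - sum(widths)
  if (free < n + 1L) {
    stop("infeasible placement: ", n, " features of total width ",
         sum(widths), " do not fit in ", len, " bp")
  }
  gaps <- stats::rmultinom(1, free - (n + 1L), rep(1, n + 1L))[, 1] + 1L
  starts <- cumsum(gaps[seq_len(n)] + c(0L, widths[-n]))
  data.frame(start = as.integer(starts),
             end = as.integer(starts + widths - 1L))
}

#' Generate a synthetic genome, annotation and neutral rate field
#'
#' Draws random uniform-composition DNA, places non-overlapping genes and
#' per-assay accessibility peaks, indexes every motif site, and computes the
#' true neutral insertion rate of each site,
#' `lambda_m` proportional to `exp(bias_weights . features(m))`, normalized so
#' the genome-wide sum equals `insertions_per_sample`.
#'
#' @param config A `sim_config`.
#' @return List of class `sim_genome`: `genome` (`DNAStringSet`),
#'   `annotation` (`feature_annotation`), `index` (`motif_index`),
#'   `true_rates` (data frame `chrom`, `pos`, `lambda`), `regions` (the gene
#'   `region_set`), `peaks` (list `dnase`, `atac`), `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- names(config$chrom_factors)
  seqs <- vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), config$chrom_length,
                 replace = TRUE), collapse = "")
  }, character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms

  per_chrom <- diff(round(seq(0, config$n_genes,
                              length.out = config$n_chroms + 1L)))
  gene_table <- do.call(rbind, lapply(seq_along(chroms), function(i) {
    iv <- .place_intervals(per_chrom[i], config$chrom_length,
                           config$gene_length)
    data.frame(gene_id = sprintf("gene_%s_%03d", chroms[i],
                                 seq_len(nrow(iv))),
               chrom = chroms[i], start = iv$start, end = iv$end,
               strand = sample(c("+", "-"), nrow(iv), replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  peak_set <- function() {
    do.call(rbind, lapply(chroms, function(ch) {
      w <- sample(config$peak_length[1]:config$peak_length[2],
                  config$n_peaks, replace = TRUE)
      s <- sample.int(config$chrom_length - max(w), config$n_peaks)
      data.frame(chrom = ch, start = s, end = s + w - 1L,
                 stringsAsFactors = FALSE)
    }))
  }
  dnase <- if (config$n_peaks > 0L) peak_set() else NULL
  atac <- if (config$n_peaks > 0L) peak_set() else NULL
  annotation <- feature_annotation(gene_table, dnase = dnase, atac = atac)
  index <- build_motif_index(genome, config$motif)

  sites <- constant_site_rates(index)[, c("chrom", "pos")]
  w <- config$bias_weights
  loglam <- numeric(nrow(sites))
  for (ch in chroms) {
    sel <- which(sites$chrom == ch)
    p <- sites$pos[sel]
    d_gene <- .dist_to_intervals(p, annotation$genes[[ch]])
    d_atac <- .dist_to_intervals(p, annotation$atac[[ch]])
    d_dnase <- .dist_to_intervals(p, annotation$dnase[[ch]])
    d_tss <- .dist_to_points(p, annotation$tss[[ch]])
    d0 <- function(d) ifelse(is.na(d), 0, as.numeric(d == 0))
    loglam[sel] <- w[["gene"]] * d0(d_gene) +
      w[["atac"]] * d0(d_atac) + w[["dnase"]] * d0(d_dnase) +
      w[["tss"]] * ifelse(is.na(d_tss), 0, exp(-d_tss / config$tss_decay))
  }
  lambda <- exp(loglam)
  sites$lambda <- lambda * config$insertions_per_sample / sum(lambda)
  structure(list(genome = genome, annotation = annotation, index = index,
                 true_rates = sites,
                 regions = make_gene_regions(annotation),
                 peaks = list(dnase = dnase, atac = atac),
                 config = config),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("Synthetic screen genome: ", x$config$n_chroms, " x ",
      format(x$config$chrom_length, big.mark = ","), " bp, motif ",
      x$config$motif, " (", format(x$index$total_sites, big.mark = ","),
      " sites), ", nrow(x$annotation$gene_table), " genes, ",
      x$config$n_samples, " samples\n", sep = "")
  invisible(x)
}

#' Simulate one screen from a synthetic genome
#'
#' For every sample i and motif site m the number of independent insertion
#' events is Poisson with mean
#' `sigma_i * chi_k(m) * lambda_m * exp(beta(region(m)))` (beta = 0 outside
#' planted selected regions); the emitted record is the unique site, present
#' when at least one event occurred. Optionally jitters reported positions to
#' exercise motif snapping, and decorates records with simulated read counts.
#'
#' @param sim A `sim_genome`.
#' @param seed Integer seed for this screen (defaults to the config seed).
#' @param shift_prob Probability that a record's reported position is shifted.
#' @param max_shift Maximum jitter in bp.
#' @param read_counts If `TRUE`, adds a simulated `read_count` column.
#' @return Insertion data frame `chrom`, `pos`, `sample_id` (+ `read_count`),
#'   with attribute `"truth"` (per-site means and planted betas).
#' @export
simulate_screen <- function(sim, seed = NULL, shift_prob = 0, max_shift = 3L,
                            read_counts = FALSE) {
  stopifnot(inherits(sim, "sim_genome"))
  config <- sim$config
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  rates <- sim$true_rates
  beta_site <- numeric(nrow(rates))
  if (!is.null(config$selected_regions) &&
      nrow(config$selected_regions) > 0L) {
    reg <- merge(config$selected_regions, sim$regions, by = "region_id")
    for (r in seq_len(nrow(reg))) {
      hit <- rates$chrom == reg$chrom[r] & rates$pos >= reg$start[r] &
        rates$pos <= reg$end[r]
      beta_site[hit] <- pmax(beta_site[hit], reg$beta[r])
    }
  }
  chi <- config$chrom_factors[rates$chrom]
  base_mu <- rates$lambda * chi * exp(beta_site)
  out <- vector("list", config$n_samples)
  for (i in seq_len(config$n_samples)) {
    mu <- base_mu * config$depth_factors[i]
    present <- stats::rbinom(length(mu), 1L, -expm1(-mu)) == 1L
    df <- data.frame(chrom = rates$chrom[present], pos = rates$pos[present],
                     sample_id = names(config$depth_factors)[i],
                     stringsAsFactors = FALSE)
    out[[i]] <- df
  }
  out <- do.call(rbind, out)
  if (read_counts && nrow(out) > 0L) {
    out$read_count <- 1L + stats::rpois(nrow(out), 5)
  }
  if (shift_prob > 0 && nrow(out) > 0L) {
    jit <- stats::rbinom(nrow(out), 1L, shift_prob) == 1L
    shift <- sample(c(-max_shift:-1, 1:max_shift), sum(jit), replace = TRUE)
    out$pos[jit] <- pmax(1L, out$pos[jit] + shift)
  }
  rownames(out) <- NULL
  attr(out, "truth") <- list(
    lambda = rates, beta = config$selected_regions,
    depth_factors = config$depth_factors,
    chrom_factors = config$chrom_factors, seed = seed)
  out
}

#' Write a synthetic screen to standard file formats
#'
#' Emits the genome (FASTA), gene annotation (GTF), peak files (BED, one per
#' assay), an insertion table (TSV) and a ground-truth JSON (planted betas,
#' global factors, rate-field summary) into a directory.
#'
#' @param sim A `sim_genome`.
#' @param insertions Insertion data frame from [simulate_screen()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, insertions, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             annotation = file.path(dir, "genes.gtf"),
             dnase = file.path(dir, "dnase.bed"),
             atac = file.path(dir, "atac.bed"),
             insertions = file.path(dir, "insertions.tsv"),
             truth = file.path(dir, "truth.json"))
  Biostrings::writeXStringSet(sim$genome, paths[["genome"]])
  g <- sim$annotation$gene_table
  gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                               strand = g$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$gene_id <- g$gene_id
  rtracklayer::export(gr, paths[["annotation"]], format = "gtf")
  write_bed <- function(df, path) {
    if (is.null(df)) df <- data.frame(chrom = character(), start = integer(),
                                      end = integer())
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start, df$end))
    rtracklayer::export(gr, path, format = "bed")
  }
  write_bed(sim$peaks$dnase, paths[["dnase"]])
  write_bed(sim$peaks$atac, paths[["atac"]])
  write_insertions(insertions, paths[["insertions"]])
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- attr(insertions, "truth")
    jsonlite::write_json(
      list(seed = sim$config$seed,
           motif = sim$config$motif,
           selected_regions = sim$config$selected_regions,
           depth_factors = as.list(sim$config$depth_factors),
           chrom_factors = as.list(sim$config$chrom_factors),
           lambda_total = sum(sim$true_rates$lambda),
           n_motif_sites = sim$index$total_sites),
      paths[["truth"]], auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    paths <- paths[names(paths) != "truth"]
  }
  invisible(paths)
}
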