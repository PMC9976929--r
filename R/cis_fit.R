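#' Detect positively selected regions in a transposon screen
#'
#' The central fitting function of the package. Insertion counts per sample
#' and region are modelled as Poisson with
#' `log E_ij = beta_j + log sigma_i + log chi_k + log Lambda_j`:
#' `Lambda_j` is the region's neutral insertion rate (sum of calibrated
#' per-site rates from the mutagenesis model, or the motif count in null
#' mode), `sigma_i` and `chi_k` are sequencing-depth and chromosome factors
#' estimated in a first Poisson GLM over genome-wide bins, and `beta_j` is the
#' region's selection coefficient, estimated per region with the global
#' factors fixed as offsets. Each region passing the tumour-count filter is
#' tested for `beta_j > 0` by a one-sided Wald test; the family-wise error
#' rate is controlled by Bonferroni correction over the tested regions.
#'
#' @param insertions Preprocessed insertion data frame (snapped, filtered;
#'   see [preprocess_insertions()]).
#' @param regions A `region_set` ([make_gene_regions()],
#'   [make_window_regions()], [load_custom_regions()]).
#' @param rates Per-site rate table ([predict_site_rates()]) or a
#'   `motif_index` (forces null mode: background = motif counts).
#' @param lengths Named chromosome lengths (needed to tile the bins of the
#'   first stage; taken from `rates` when it is a `motif_index`).
#' @param mode `"mutagenesis"` or `"null"`.
#' @param bin_size Bin size for the global-factor stage (default 50000 bp).
#' @param fwer Family-wise error level (default 0.05).
#' @param min_tumours,min_fraction Tumour-count filter parameters (defaults
#'   3 and 0.05).
#' @return Object of class `cis_fit`. Its `$results` data frame has one row
#'   per region: `region_id`, `chrom`, `start`, `end`, `n_motif_sites`,
#'   `Lambda`, `total_insertions`, `n_samples_hit`, `beta`, `se`, `z`,
#'   `pvalue`, `padj`, `tested`, `significant`.
#' @seealso [fit_mutagenesis()], [summary.cis_fit()], [coef.cis_fit()],
#'   [predict.cis_fit()], [simulate.cis_fit()]
#' @export
call_cis <- function(insertions, regions, rates, lengths = NULL,
                     mode = c("mutagenesis", "null"), bin_size = 50000L,
                     fwer = 0.05, min_tumours = 3L, min_fraction = 0.05) {
  mode <- match.arg(mode)
  cl <- match.call()
  if (inherits(rates, "motif_index")) {
    mode <- "null"
    if (is.null(lengths)) lengths <- rates$chrom_lengths
    rates <- constant_site_rates(rates)
  }
  if (is.null(lengths)) {
    stop("supply `lengths` (named chromosome lengths) to tile the ",
         "global-factor bins")
  }
  chroms <- intersect(names(lengths), unique(rates$chrom))
  if (length(chroms) == 0L) stop("no chromosome shared by lengths and rates")
  insertions <- insertions[insertions$chrom %in% chroms, , drop = FALSE]
  if (nrow(insertions) == 0L) stop("no insertions on analysis chromosomes")
  regions <- regions[regions$chrom %in% chroms, , drop = FALSE]

  # stage 1: depth and chromosome factors on genome-wide bins
  bins <- make_window_regions(lengths[chroms], bin_size)
  bin_rates <- aggregate_region_rates(rates, bins, mode)
  bin_counts <- build_count_matrix(insertions, bins)
  factors <- fit_global_factors(bin_counts, bin_rates)

  # stage 2: per-region selection coefficients with fixed offsets
  region_rates <- aggregate_region_rates(rates, regions, mode)
  counts <- build_count_matrix(insertions, regions)
  n_hit <- colSums(counts >= 1L)
  tested <- tumour_count_filter(counts, min_tumours, min_fraction) &
    region_rates$Lambda > 0
  sum_products <- colSums(factors$products)  # per chromosome: sum_i sigma_i chi_k
  S <- region_rates$Lambda * sum_products[region_rates$chrom]
  K <- colSums(counts)
  beta <- ifelse(K > 0, log(K / S), -Inf)
  se <- ifelse(K > 0, 1 / sqrt(K), Inf)
  pvalue <- wald_one_sided(beta, pmax(se, .Machine$double.eps))
  m <- sum(tested)
  padj <- rep(NA_real_, length(pvalue))
  if (m >= 1L) padj[tested] <- bonferroni(pvalue[tested], m)
  results <- data.frame(
    region_id = region_rates$region_id, chrom = region_rates$chrom,
    start = region_rates$start, end = region_rates$end,
    n_motif_sites = region_rates$n_motif_sites, Lambda = region_rates$Lambda,
    total_insertions = as.integer(K), n_samples_hit = as.integer(n_hit),
    beta = beta, se = se, z = ifelse(is.finite(beta), beta / se, -Inf),
    pvalue = pvalue, padj = padj, tested = as.logical(tested),
    significant = as.logical(tested) & !is.na(padj) & padj < fwer,
    stringsAsFactors = FALSE)
  structure(
    list(results = results, factors = factors, counts = counts,
         m = m, fwer = fwer, mode = mode,
         config = list(bin_size = bin_size, fwer = fwer,
                       min_tumours = min_tumours,
                       min_fraction = min_fraction, mode = mode,
                       n_samples = nrow(counts),
                       n_regions = nrow(regions), m_tested = m),
         call = cl),
    class = "cis_fit")
}

#' @export
print.cis_fit <- function(x, ...) {
  r <- x$results
  cat("Common insertion site fit (", x$mode, " background)\n", sep = "")
  cat("  ", nrow(r), " regions, ", x$m, " tested (tumour-count filter), ",
      sum(r$significant), " significant at FWER ", x$fwer,
      " (Bonferroni, one-sided Wald)\n", sep = "")
  cat("  ", x$config$n_samples, " samples, ",
      sum(r$total_insertions), " region-assigned insertions\n", sep = "")
  invisible(x)
}

#' Summarize a common-insertion-site fit
#'
#' @param object A `cis_fit`.
#' @param ... Unused.
#' @return Object of class `summary.cis_fit` whose print method lists the
#'   significant regions sorted by adjusted p-value.
#' @method summary cis_fit
#' @export
summary.cis_fit <- function(object, ...) {
  r <- object$results
  sig <- r[r$significant, , drop = FALSE]
  sig <- sig[order(sig$padj, sig$pvalue), , drop = FALSE]
  structure(list(fit = object, significant = sig), class = "summary.cis_fit")
}

#' @export
print.summary.cis_fit <- function(x, ...) {
  print(x$fit)
  if (nrow(x$significant) == 0L) {
    cat("No significant regions.\n")
  } else {
    cat("\nSignificant regions:\n")
    cols <- c("region_id", "chrom", "total_insertions", "n_samples_hit",
              "beta", "se", "pvalue", "padj")
    out <- x$significant[, cols]
    out$beta <- round(out$beta, 3); out$se <- round(out$se, 3)
    out$pvalue <- signif(out$pvalue, 3); out$padj <- signif(out$padj, 3)
    print(out, row.names = FALSE)
  }
  invisible(x)
}

#' @method coef cis_fit
#' @export
coef.cis_fit <- function(object, all = FALSE, ...) {
  r <- object$results
  if (!all) r <- r[r$tested, , drop = FALSE]
  stats::setNames(r$beta, r$region_id)
}

#' Expected insertion counts from a fitted selection model
#'
#' @param object A `cis_fit`.
#' @param type `"expected"` for the fitted means (including the estimated
#'   selection coefficients, with `beta` treated as 0 where untested or
#'   unidentified), `"neutral"` for the background expectation
#'   `sigma_i * chi_k * Lambda_j` with no selection.
#' @param ... Unused.
#' @return Matrix samples x regions.
#' @export
predict.cis_fit <- function(object, type = c("expected", "neutral"), ...) {
  type <- match.arg(type)
  r <- object$results
  E0 <- object$factors$products[, r$chrom, drop = FALSE] *
    rep(r$Lambda, each = nrow(object$counts))
  dimnames(E0) <- dimnames(object$counts)
  if (type == "neutral") return(E0)
  b <- ifelse(r$tested & is.finite(r$beta), r$beta, 0)
  E0 * rep(exp(b), each = nrow(object$counts))
}

#' @method residuals cis_fit
#' @export
residuals.cis_fit <- function(object, type = c("pearson", "deviance"), ...) {
  type <- match.arg(type)
  E <- predict(object, type = "expected")
  k <- object$counts
  if (type == "pearson") {
    res <- (k - E) / sqrt(pmax(E, .Machine$double.eps))
  } else {
    dev <- 2 * (ifelse(k > 0, k * log(k / pmax(E, .Machine$double.eps)), 0) -
                  (k - E))
    res <- sign(k - E) * sqrt(pmax(dev, 0))
  }
  res
}

#' Simulate screens from a fitted selection model
#'
#' Draws per-sample, per-region insertion counts from the fitted Poisson
#' means (a parametric-bootstrap generator).
#'
#' @param object A `cis_fit`.
#' @param nsim Number of replicate count matrices.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return List of `nsim` count matrices (samples x regions).
#' @export
simulate.cis_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  E <- predict(object, type = "expected")
  lapply(seq_len(nsim), function(i) {
    matrix(stats::rpois(length(E), E), nrow(E), ncol(E),
           dimnames = dimnames(E))
  })
}

#' Plot a common-insertion-site fit
#'
#' Manhattan-style base-graphics plot of `-log10` adjusted p-values along the
#' genome, with the FWER threshold as a horizontal line.
#'
#' @param x A `cis_fit`.
#' @param ... Passed to [graphics::plot()].
#' @method plot cis_fit
#' @export
plot.cis_fit <- function(x, ...) {
  r <- x$results[x$results$tested, , drop = FALSE]
  if (nrow(r) == 0L) stop("no tested regions to plot")
  r <- r[order(r$chrom, r$start), , drop = FALSE]
  chrom_f <- factor(r$chrom, levels = unique(r$chrom))
  y <- -log10(pmax(r$padj, 1e-300))
  graphics::plot(seq_len(nrow(r)), y, col = as.integer(chrom_f),
                 pch = 16, xlab = "region (genome order)",
                 ylab = expression(-log[10] ~ "adjusted p"), ...)
  graphics::abline(h = -log10(x$fwer), lty = 2)
  invisible(x)
}
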