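#' Per-sample, per-region insertion count matrix
#'
#' Counts, for every sample and region, the distinct snapped insertion
#' positions falling inside the region (duplicate records of the same site in
#' the same sample count once). A site inside two overlapping regions is
#' counted in both.
#'
#' @param insertions Preprocessed insertion data frame.
#' @param regions A `region_set` or region data frame.
#' @return Integer matrix, samples in rows (ordered ids), regions in columns,
#'   with attribute `"chrom_of_region"`.
#' @export
build_count_matrix <- function(insertions, regions) {
  us <- unique_sites_per_sample(insertions)
  samples <- sort(unique(insertions$sample_id))
  k <- matrix(0L, length(samples), nrow(regions),
              dimnames = list(samples, regions$region_id))
  for (chrom in unique(regions$chrom)) {
    rsel <- which(regions$chrom == chrom)
    s <- us[us$chrom == chrom, , drop = FALSE]
    if (nrow(s) == 0L) next
    o <- order(s$pos)
    pos <- s$pos[o]
    sid <- s$sample_id[o]
    i1 <- findInterval(regions$start[rsel] - 1L, pos)
    i2 <- findInterval(regions$end[rsel], pos)
    for (r in seq_along(rsel)) {
      if (i2[r] > i1[r]) {
        tab <- table(sid[(i1[r] + 1L):i2[r]])
        k[names(tab), rsel[r]] <- k[names(tab), rsel[r]] + as.integer(tab)
      }
    }
  }
  attr(k, "chrom_of_region") <- stats::setNames(regions$chrom,
                                                regions$region_id)
  k
}

#' Fit global sequencing-depth and chromosome factors
#'
#' First stage of the selection model: a Poisson GLM with log link over
#' genome-wide bins (50 kb by default elsewhere), with a per-sample factor
#' (sequencing depth), a per-chromosome factor, and the log neutral bin rate
#' as a fixed offset. Only the product surface sigma_i * chi_k is
#' identifiable; it is returned as a matrix and used as the fixed offset of
#' the second stage. Individual factors are also reported, normalized so the
#' first sample and first chromosome equal 1.
#'
#' @param bin_counts Count matrix over bins from [build_count_matrix()].
#' @param bin_rates Bin rate table from [aggregate_region_rates()] (bins with
#'   `Lambda = 0` are dropped).
#' @param epsilon Relative deviance-change convergence tolerance passed to
#'   `glm` (default 1e-8).
#' @param maxit Maximum IRLS iterations (default 100).
#' @return Object of class `global_factors`: `sigma`, `chi` (named, natural
#'   scale, reference levels = 1), `products` (samples x chromosomes matrix of
#'   sigma_i * chi_k including the intercept), `fit` (the glm), `converged`.
#' @export
fit_global_factors <- function(bin_counts, bin_rates, epsilon = 1e-8,
                               maxit = 100L) {
  stopifnot(identical(colnames(bin_counts), bin_rates$region_id))
  keep <- bin_rates$Lambda > 0
  if (!any(keep)) stop("all bins have zero neutral rate")
  counts <- bin_counts[, keep, drop = FALSE]
  Lambda <- bin_rates$Lambda[keep]
  chrom <- bin_rates$chrom[keep]
  samples <- rownames(bin_counts)
  chroms <- unique(bin_rates$chrom)

  zero_samples <- samples[rowSums(counts) == 0]
  if (length(zero_samples)) {
    warning("sample(s) with zero insertions: ",
            paste(zero_samples, collapse = ", "),
            "; their depth factor tends to zero")
  }
  long <- data.frame(
    count = as.vector(counts),
    sample = factor(rep(samples, times = ncol(counts)), levels = samples),
    chrom = factor(rep(chrom, each = nrow(counts)), levels = chroms),
    Lambda = rep(Lambda, each = nrow(counts)))
  terms <- c(if (length(samples) > 1L) "sample",
             if (length(chroms) > 1L) "chrom")
  rhs <- paste(c(if (length(terms)) terms else "1",
                 "offset(log(Lambda))"), collapse = " + ")
  fit <- stats::glm(stats::as.formula(paste("count ~", rhs)),
                    family = stats::poisson(),
                    data = long,
                    control = stats::glm.control(epsilon = epsilon,
                                                 maxit = maxit))
  if (!fit$converged) stop("global-factor GLM did not converge in ",
                           maxit, " iterations")
  grid <- expand.grid(sample = factor(samples, levels = samples),
                      chrom = factor(chroms, levels = chroms),
                      Lambda = 1)
  eta <- stats::predict(fit, newdata = grid, type = "link")
  products <- matrix(exp(eta), length(samples), length(chroms),
                     dimnames = list(samples, chroms))
  structure(
    list(sigma = stats::setNames(products[, 1] / products[1, 1], samples),
         chi = stats::setNames(products[1, ] / products[1, 1], chroms),
         products = products, fit = fit, converged = fit$converged),
    class = "global_factors")
}

#' @export
print.global_factors <- function(x, ...) {
  cat("Global factors (Poisson GLM on genome-wide bins)\n")
  cat("  depth factors sigma (ref = 1): ",
      paste(sprintf("%s=%.3g", names(x$sigma), x$sigma), collapse = ", "),
      "\n", sep = "")
  cat("  chromosome factors chi (ref = 1): ",
      paste(sprintf("%s=%.3g", names(x$chi), x$chi), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Per-region selection coefficient
#'
#' Second stage: for one region, an intercept-only Poisson GLM of the
#' per-sample counts with fixed offsets (depth x chromosome product times the
#' region's neutral rate). The MLE has closed form: `beta = log(K / S)` with
#' `K` the total count and `S` the total exponential offset, and the observed
#' Fisher information gives `se = 1 / sqrt(K)`. A region with no insertions
#' yields `beta = -Inf` (p-value 1 downstream).
#'
#' @param k Per-sample counts for the region.
#' @param exp_offset Per-sample exponentiated offsets
#'   (`sigma_i * chi_k * Lambda_j`), same length as `k`.
#' @return List with `beta`, `se`, `K`, `S`.
#' @export
fit_region_selection <- function(k, exp_offset) {
  stopifnot(length(k) == length(exp_offset))
  S <- sum(exp_offset)
  if (S <= 0) stop("total exponential offset is zero; region has no ",
                   "neutral rate")
  K <- sum(k)
  if (K == 0) return(list(beta = -Inf, se = Inf, K = 0, S = S))
  list(beta = log(K / S), se = 1 / sqrt(K), K = K, S = S)
}

#' One-sided Wald test for positive selection
#'
#' Tests beta > 0: `p = P(Z >= beta / se)` under the standard normal.
#'
#' @param beta Selection coefficient estimate(s).
#' @param se Standard error(s) (> 0).
#' @return Upper-tail p-value(s); `beta = -Inf` yields 1.
#' @export
wald_one_sided <- function(beta, se) {
  if (any(se <= 0, na.rm = TRUE)) stop("standard error must be positive")
  z <- ifelse(is.infinite(beta) & beta < 0, -Inf, beta / se)
  stats::pnorm(z, lower.tail = FALSE)
}

#' Tumour-count filter
#'
#' A region is tested only if it carries insertions in at least
#' `max(min_tumours, ceiling(min_fraction * n_samples))` samples, the
#' support threshold applied before multiple-testing correction.
#'
#' @param counts Count matrix (samples x regions).
#' @param min_tumours Absolute minimum number of tumours (default 3).
#' @param min_fraction Minimum fraction of all tumours (default 0.05).
#' @return Logical vector per region (named), `TRUE` = tested.
#' @export
tumour_count_filter <- function(counts, min_tumours = 3L,
                                min_fraction = 0.05) {
  n <- nrow(counts)
  stopifnot(n >= 1L)
  threshold <- max(min_tumours, ceiling(min_fraction * n))
  hits <- colSums(counts >= 1L)
  stats::setNames(hits >= threshold, colnames(counts))
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` with `m` the number of tested regions.
#'
#' @param p P-values.
#' @param m Number of tests (default `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  stopifnot(m >= 1)
  pmin(1, m * p)
}
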