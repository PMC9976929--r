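tile2 <- function(len = 2000L, size = 500L) {
  make_window_regions(c(c1 = len, c2 = len), size)
}

test_that("count matrix counts unique per-sample sites, matching brute force", {
  ins <- data.frame(chrom = c("c1", "c1", "c1", "c1", "c2"),
                    pos = c(100L, 100L, 120L, 140L, 100L),
                    sample_id = c("T01", "T01", "T01", "T01", "T02"))
  regions <- tile2()
  k <- build_count_matrix(ins, regions)
  expect_equal(unname(k["T01", "c1:1-500"]), 3L)  # duplicate site counted once
  expect_equal(unname(k["T02", "c2:1-500"]), 1L)
  expect_equal(sum(k), 4L)

  set.seed(23)
  rnd <- data.frame(chrom = sample(c("c1", "c2"), 500, TRUE),
                    pos = sample.int(2000L, 500, TRUE),
                    sample_id = sample(sprintf("T%02d", 1:6), 500, TRUE))
  k2 <- build_count_matrix(rnd, regions)
  u <- unique(rnd)
  for (r in sample.int(nrow(regions), 5)) {
    inr <- u$chrom == regions$chrom[r] & u$pos >= regions$start[r] &
      u$pos <= regions$end[r]
    expect_equal(unname(colSums(k2)[r]), sum(inr))
  }
})

test_that("global factors recover margins and ratios", {
  # sample B has exactly twice A's counts in every bin, one chromosome
  bins <- make_window_regions(c(c1 = 500000L), 50000L)
  kA <- c(5L, 8L, 3L, 9L, 4L, 7L, 6L, 2L, 5L, 4L)
  k <- rbind(A = kA, B = 2L * kA)
  colnames(k) <- bins$region_id
  rates <- data.frame(region_id = bins$region_id, chrom = bins$chrom,
                      start = bins$start, end = bins$end,
                      n_motif_sites = 10L, Lambda = runif(10, 0.5, 2))
  gf <- fit_global_factors(k, rates)
  expect_equal(unname(gf$sigma["B"] / gf$sigma["A"]), 2, tolerance = 1e-6)

  # margin matching: fitted per-sample and per-chromosome totals equal
  # observed totals (score equations of the Poisson GLM)
  sim <- cached_sim()
  scr <- preprocess_insertions(simulate_screen(sim, seed = 12), sim$index)
  bins2 <- make_window_regions(chrom_lengths(sim$genome), 50000L)
  br <- aggregate_region_rates(sim$true_rates, bins2, "mutagenesis")
  bc <- build_count_matrix(scr, bins2)
  gf2 <- fit_global_factors(bc, br)
  fitted_long <- stats::fitted(gf2$fit)
  df <- gf2$fit$data
  obs_sample <- tapply(df$count, df$sample, sum)
  fit_sample <- tapply(fitted_long, df$sample, sum)
  expect_equal(unname(fit_sample), unname(obs_sample), tolerance = 1e-6)
  obs_chrom <- tapply(df$count, df$chrom, sum)
  fit_chrom <- tapply(fitted_long, df$chrom, sum)
  expect_equal(unname(fit_chrom), unname(obs_chrom), tolerance = 1e-6)

  # single sample, single chromosome: product = total count / total Lambda
  k1 <- matrix(kA, 1, 10, dimnames = list("A", bins$region_id))
  gf1 <- fit_global_factors(k1, rates)
  expect_equal(unname(gf1$products[1, 1]), sum(kA) / sum(rates$Lambda),
               tolerance = 1e-8)
})

test_that("per-region closed form equals iterative GLM and scales correctly", {
  k <- c(2, 3, 5); off <- rep(1, 3)
  fr <- fit_region_selection(k, off)
  expect_equal(fr$beta, log(10 / 3))
  expect_equal(fr$se, 1 / sqrt(10))

  oracle <- stats::glm(k ~ 1 + offset(log(off)), family = stats::poisson(),
                       control = stats::glm.control(epsilon = 1e-12))
  expect_equal(fr$beta, unname(stats::coef(oracle)), tolerance = 1e-8)
  expect_equal(fr$se, unname(sqrt(diag(stats::vcov(oracle)))),
               tolerance = 1e-6)

  # null case and scale equivariance
  expect_equal(fit_region_selection(c(4, 6), c(4, 6))$beta, 0)
  f1 <- fit_region_selection(k, off)
  f2 <- fit_region_selection(k, 2 * off)
  expect_equal(exp(f2$beta), exp(f1$beta) / 2)

  # zero count: beta -Inf, p-value 1
  f0 <- fit_region_selection(c(0, 0), c(1, 1))
  expect_equal(f0$beta, -Inf)
  expect_equal(wald_one_sided(f0$beta, 1), 1)
  expect_error(fit_region_selection(1, 0), "zero")
})

test_that("one-sided Wald test behaves at its landmarks", {
  expect_equal(wald_one_sided(0, 1), 0.5)
  expect_equal(wald_one_sided(stats::qnorm(0.95) * 2, 2), 0.05)
  expect_gt(wald_one_sided(-0.3, 1), 0.5)
  expect_error(wald_one_sided(1, 0), "positive")
})

test_that("tumour-count filter applies max(3, ceil(5%)) and Bonferroni caps", {
  mk <- function(n_samples, n_hit) {
    k <- matrix(0L, n_samples, 1, dimnames = list(sprintf("T%03d",
                                                          1:n_samples), "r"))
    k[seq_len(n_hit), 1] <- 1L
    k
  }
  expect_true(tumour_count_filter(mk(30, 3)))   # threshold max(3, 2) = 3
  expect_false(tumour_count_filter(mk(30, 2)))
  expect_true(tumour_count_filter(mk(100, 5)))  # threshold 5
  expect_false(tumour_count_filter(mk(100, 4)))

  expect_equal(bonferroni(0.001, 10), 0.01)
  expect_equal(bonferroni(0.5, 10), 1)
  expect_equal(bonferroni(0.123, 1), 0.123)
  expect_equal(bonferroni(c(0.01, 0.2), 3),
               stats::p.adjust(c(0.01, 0.2), "bonferroni", n = 3))
})

test_that("end-to-end fit honours the filter and exposes model methods", {
  sim <- cached_sim()
  cfg <- sim$config
  scr <- preprocess_insertions(simulate_screen(sim, seed = 44), sim$index)
  fit <- call_cis(scr, sim$regions, sim$true_rates,
                  lengths = chrom_lengths(sim$genome), mode = "mutagenesis")
  r <- fit$results
  # a region failing the tumour filter can never be significant
  expect_false(any(r$significant & !r$tested))
  expect_equal(fit$m, sum(r$tested))
  expect_equal(r$padj[r$tested],
               pmin(1, fit$m * r$pvalue[r$tested]))
  # identity at the MLE: exp(beta) = K / S for tested regions
  tested <- r[r$tested & r$total_insertions > 0, ]
  S <- tested$Lambda * unname(colSums(fit$factors$products)[tested$chrom])
  expect_equal(exp(tested$beta), tested$total_insertions / S,
               tolerance = 1e-10)

  # methods: coef, predict, residuals, simulate
  expect_named(coef(fit), r$region_id[r$tested])
  E <- predict(fit, type = "neutral")
  expect_equal(dim(E), dim(fit$counts))
  expect_true(all(E > 0))
  res <- residuals(fit)
  expect_equal(dim(res), dim(fit$counts))
  simk <- simulate(fit, nsim = 2, seed = 1)
  expect_length(simk, 2)
  expect_equal(dim(simk[[1]]), dim(fit$counts))

  # results independent of insertion record order
  scr2 <- scr[sample.int(nrow(scr)), ]
  fit2 <- call_cis(scr2, sim$regions, sim$true_rates,
                   lengths = chrom_lengths(sim$genome), mode = "mutagenesis")
  expect_equal(fit2$results, fit$results)
})
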