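test_that("calibration constant f0 is the negative-to-universe ratio", {
  idx <- structure(list(motif = "TA", positions = list(chr1 = 1:250000),
                        analysis_chroms = "chr1",
                        chrom_lengths = c(chr1 = 500000L),
                        total_sites = 250000L), class = "motif_index")
  expect_equal(compute_f0(1000, idx), 0.004)
  expect_equal(compute_f0(250000, idx), 1)
  idx$total_sites <- 0L
  expect_error(compute_f0(10, idx), "no sites")
})

test_that("site_rate implements the calibrated odds-to-rate transform", {
  expect_equal(site_rate(0.5, 0.01), log(1.01))
  # the rate and the per-site insertion probability are two faces of the
  # same quantity: 1 - exp(-lambda) = w*f0 / (1 + w*f0)
  y <- 0.9; f0 <- 0.1; w <- y / (1 - y)
  lam <- site_rate(y, f0)
  expect_equal(lam, log(1.9))
  expect_equal(1 - exp(-lam), w * f0 / (1 + w * f0))
  # clipping floor: probabilities at 0 give a tiny but positive rate
  expect_lt(site_rate(0, 0.5), 1e-6)
  expect_gt(site_rate(0, 0.5), 0)
  # strict monotonicity in both arguments
  ys <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(site_rate(ys, 0.3)) > 0))
  expect_true(all(site_rate(0.7, c(0.1, 0.2, 0.5)) ==
                    cummax(site_rate(0.7, c(0.1, 0.2, 0.5)))))
  expect_error(site_rate(1.5, 0.1), "0, 1")
  expect_error(site_rate(0.5, 0), "f0")
})

test_that("negative sampling is uniform, disjoint from positives and reproducible", {
  sim <- cached_sim()
  pos <- data.frame(chrom = "chr1", pos = sim$index$positions$chr1[1:10])
  n_avail <- sim$index$total_sites - 10L

  a <- sample_negatives(sim$index, 5000, exclude = pos, seed = 9)
  b <- sample_negatives(sim$index, 5000, exclude = pos, seed = 9)
  expect_identical(a, b)
  expect_false(any(paste(a$chrom, a$pos) %in% paste(pos$chrom, pos$pos)))
  expect_error(sample_negatives(sim$index, n_avail + 1L, exclude = pos),
               "available")

  # exhaustion: asking for everything returns exactly the complement
  tiny <- structure(list(motif = "TA",
                         positions = list(chr1 = as.integer(1:100 * 2)),
                         analysis_chroms = "chr1",
                         chrom_lengths = c(chr1 = 300L),
                         total_sites = 100L), class = "motif_index")
  tp <- data.frame(chrom = "chr1", pos = 1:10 * 2L)
  all90 <- sample_negatives(tiny, 90, exclude = tp, seed = 1)
  expect_setequal(all90$pos, setdiff(1:100 * 2L, 1:10 * 2L))

  # chromosome proportions of a large draw match the index proportions
  big <- sample_negatives(sim$index, 10000, seed = 4)
  observed <- table(factor(big$chrom, names(sim$index$positions)))
  expected_p <- lengths(sim$index$positions) / sim$index$total_sites
  expect_gt(stats::chisq.test(observed, p = expected_p)$p.value, 1e-3)
})

test_that("internal AUC equals the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(21)
  y <- rbinom(300, 1, 0.4)
  s <- rnorm(300) + y
  ours <- ciscall:::.auc(y, s)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("classifier training is reproducible and separates a planted feature", {
  # perfectly separable toy: positives at distance 0, negatives at 10000
  set.seed(33)
  n <- 400
  schema <- feature_schema("TA")
  x <- matrix(0, n, length(schema), dimnames = list(NULL, schema))
  y <- rep(c(1L, 0L), each = n / 2)
  x[, "d_atac"] <- ifelse(y == 1L, 0, 10000) + rnorm(n, sd = 10)
  x[, "d_tss"] <- runif(n, 0, 5e4)
  fit <- fit_mutagenesis_xy(x, y, f0 = 0.01, motif = "TA",
                            search_budget = 2, cv_folds = 2,
                            test_fraction = 0.2, seed = 7)
  expect_s3_class(fit, "mutagenesis_fit")
  expect_equal(fit$training_metadata$auc_test, 1.0)

  refit <- fit_mutagenesis_xy(x, y, f0 = 0.01, motif = "TA",
                              search_budget = 2, cv_folds = 2,
                              test_fraction = 0.2, seed = 7)
  expect_identical(fit$training_metadata$best_hyperparameters,
                   refit$training_metadata$best_hyperparameters)
  expect_equal(predict(fit, x, type = "prob"),
               predict(refit, x, type = "prob"))

  # rate predictions are a monotone transform of probabilities
  pr <- predict(fit, x, type = "prob")
  lam <- predict(fit, x, type = "rate")
  expect_equal(order(pr), order(lam))
  expect_error(predict(fit, x[, -1]), "schema")
  expect_error(fit_mutagenesis_xy(x, rep(1L, n), 0.01, "TA"),
               "single class")
})

test_that("constant classifier rates reduce region rates to motif counts", {
  sim <- cached_sim()
  rates <- constant_site_rates(sim$index, lambda = log(1 + 0.01))
  agg_c <- aggregate_region_rates(rates, sim$regions, mode = "mutagenesis")
  agg_0 <- aggregate_region_rates(sim$index, sim$regions)
  expect_equal(agg_c$Lambda, log(1.01) * agg_0$Lambda)
  expect_equal(agg_c$n_motif_sites, agg_0$n_motif_sites)
})
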