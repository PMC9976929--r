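# area under the ROC curve as the normalized Mann-Whitney statistic
.auc <- function(labels, scores) {
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined: single-class labels")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sample random control motif sites
#'
#' Draws a uniform sample without replacement from the indexed motif sites of
#' the analysis chromosomes, excluding a set of positions (typically the
#' observed insertion sites, so labels stay clean).
#'
#' @param index A `motif_index`.
#' @param n Number of control sites.
#' @param exclude Data frame with `chrom`, `pos` to exclude (or `NULL`).
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return Data frame `chrom`, `pos` sorted by chromosome and position.
#' @export
sample_negatives <- function(index, n, exclude = NULL, seed = NULL) {
  chroms <- index$analysis_chroms
  pool <- data.frame(
    chrom = rep(chroms, lengths(index$positions[chroms])),
    pos = unlist(index$positions[chroms], use.names = FALSE),
    stringsAsFactors = FALSE)
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    key <- paste(pool$chrom, pool$pos)
    pool <- pool[!(key %in% paste(exclude$chrom, exclude$pos)), , drop = FALSE]
  }
  if (n > nrow(pool)) {
    stop("requested ", n, " negatives but only ", nrow(pool),
         " non-positive motif sites are available")
  }
  if (!is.null(seed)) set.seed(seed)
  take <- sample.int(nrow(pool), n)
  out <- pool[take, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Calibration constant f0
#'
#' Ratio of the number of negative (random control) training sites to the
#' total number of motif sites in the analysis universe. It rescales the
#' balanced-training-set odds of the classifier to genome-scale odds.
#'
#' @param n_neg Number of negatives in the training set.
#' @param index A `motif_index` (supplies `total_sites`).
#' @return f0 in (0, 1].
#' @export
compute_f0 <- function(n_neg, index) {
  stopifnot(n_neg >= 1)
  if (index$total_sites == 0L) stop("motif index has no sites")
  if (n_neg > index$total_sites) stop("more negatives than motif sites")
  n_neg / index$total_sites
}

#' Convert classifier probabilities to neutral insertion rates
#'
#' With classification probability y for a site to be an observed insertion
#' site rather than a random control, the calibrated odds are
#' `w = f0 * y / (1 - y)` and the neutral Poisson rate is
#' `lambda = log(1 + w)`, so that the per-site insertion probability is
#' `1 - exp(-lambda) = w / (1 + w)`. Probabilities are clipped to
#' `[eps, 1 - eps]` before the odds transform.
#'
#' @param y_hat Probabilities in \[0, 1\].
#' @param f0 Calibration constant in (0, 1].
#' @param eps Clipping constant (default 1e-6).
#' @return Numeric vector of rates, same length as `y_hat`.
#' @export
site_rate <- function(y_hat, f0, eps = 1e-6) {
  if (any(y_hat < 0 | y_hat > 1, na.rm = TRUE) || anyNA(y_hat)) {
    stop("probabilities must lie in [0, 1]")
  }
  if (any(f0 <= 0 | f0 > 1)) stop("f0 must lie in (0, 1]")
  y <- pmin(pmax(y_hat, eps), 1 - eps)
  log1p(f0 * y / (1 - y))
}

# draw one random hyperparameter configuration for ranger
.draw_hyperparams <- function(p) {
  list(num.trees = sample(c(100L, 200L, 300L, 500L), 1L),
       mtry = sample(unique(pmax(1L, round(c(sqrt(p), p / 3, p / 10,
                                             sqrt(p) * 2)))), 1L),
       min.node.size = sample(c(1L, 5L, 10L, 25L, 50L), 1L),
       max.depth = sample(c(0L, 4L, 8L, 16L), 1L),  # 0 = unlimited
       replace = sample(c(TRUE, FALSE), 1L),
       sample.fraction = sample(c(0.5, 0.7, 1.0), 1L))
}

.fit_ranger <- function(x, y, hp, seed, num_threads = 1L) {
  df <- as.data.frame(x)
  df$.y <- factor(y, levels = c(0L, 1L))
  ranger::ranger(
    dependent.variable.name = ".y", data = df, probability = TRUE,
    num.trees = hp$num.trees, mtry = min(hp$mtry, ncol(x)),
    min.node.size = hp$min.node.size, max.depth = hp$max.depth,
    replace = hp$replace,
    sample.fraction = if (hp$replace) hp$sample.fraction else
      min(hp$sample.fraction, 0.9),
    seed = seed, num.threads = num_threads, verbose = FALSE)
}

.predict_prob <- function(forest, x) {
  pr <- stats::predict(forest, data = as.data.frame(x),
                       num.threads = 1L)$predictions
  pr[, "1"]
}

#' Fit the mutagenesis model
#'
#' Trains a random-forest classifier to discriminate observed (genome-wide
#' unique) insertion sites from an equal number of random control motif sites,
#' using sequence context and feature distances (see [extract_features()]).
#' The data are split into a training and a held-out test set; hyperparameters
#' (number of trees, mtry, minimum node size, maximum depth, bootstrap flag,
#' sample fraction) are chosen by randomized search with k-fold
#' cross-validation inside the training split, optimizing the AUC. The model
#' stores the calibration constant `f0` so calibrated per-site rates can be
#' predicted for every motif site in the genome.
#'
#' @param insertions Preprocessed insertion data frame (snapped, filtered).
#' @param genome `DNAStringSet`.
#' @param annotation `feature_annotation`.
#' @param index `motif_index` for the screen's motif.
#' @param search_budget Randomized-search iterations (default 100; use ~10 for
#'   a fast profile).
#' @param cv_folds Cross-validation folds within the training split
#'   (default 5; >= 2).
#' @param test_fraction Held-out fraction for the final AUC (default 0.1).
#' @param seed Integer seed governing negative sampling, the split, the fold
#'   assignment and the forests.
#' @param num_threads Threads for ranger (default 1).
#' @return Object of class `mutagenesis_fit`: the forest, `f0`, the feature
#'   schema, the motif, and `training_metadata` (chosen hyperparameters, CV
#'   table, held-out AUC, counts, seed).
#' @seealso [predict.mutagenesis_fit()], [predict_site_rates()]
#' @export
fit_mutagenesis <- function(insertions, genome, annotation, index,
                            search_budget = 100L, cv_folds = 5L,
                            test_fraction = 0.1, seed = 1L,
                            num_threads = 1L) {
  stopifnot(cv_folds >= 2L, search_budget >= 1L,
            test_fraction > 0, test_fraction < 1)
  positives <- unique_sites(insertions)
  positives <- positives[positives$chrom %in% index$analysis_chroms, ,
                         drop = FALSE]
  if (nrow(positives) == 0L) stop("no insertion sites on analysis chromosomes")
  negatives <- sample_negatives(index, nrow(positives), exclude = positives,
                                seed = seed)
  x <- rbind(
    extract_features(positives, genome, annotation, index$motif),
    extract_features(negatives, genome, annotation, index$motif))
  y <- rep(c(1L, 0L), c(nrow(positives), nrow(negatives)))
  if (length(unique(y)) < 2L) stop("degenerate labels: single class")
  fit_mutagenesis_xy(x, y, f0 = compute_f0(nrow(negatives), index),
                     motif = index$motif, search_budget = search_budget,
                     cv_folds = cv_folds, test_fraction = test_fraction,
                     seed = seed, num_threads = num_threads)
}

#' Fit the mutagenesis classifier on a prepared feature matrix
#'
#' Lower-level entry point behind [fit_mutagenesis()], useful when features
#' and labels are constructed by other means (e.g. simulations).
#'
#' @param x Feature matrix (columns named per [feature_schema()]).
#' @param y Binary labels (1 = observed insertion site, 0 = control).
#' @param f0 Calibration constant (see [compute_f0()]).
#' @param motif Motif string recorded in the model.
#' @inheritParams fit_mutagenesis
#' @return A `mutagenesis_fit`.
#' @export
fit_mutagenesis_xy <- function(x, y, f0, motif, search_budget = 100L,
                               cv_folds = 5L, test_fraction = 0.1,
                               seed = 1L, num_threads = 1L) {
  stopifnot(nrow(x) == length(y))
  if (length(unique(y)) < 2L) stop("degenerate labels: single class")
  set.seed(seed)
  n <- nrow(x)
  test_idx <- sample.int(n, max(1L, round(test_fraction * n)))
  train_idx <- setdiff(seq_len(n), test_idx)
  if (length(unique(y[train_idx])) < 2L || length(unique(y[test_idx])) < 2L) {
    stop("train/test split left a single-class partition; enlarge the data")
  }
  folds <- sample(rep_len(seq_len(cv_folds), length(train_idx)))

  cv_table <- vector("list", search_budget)
  for (it in seq_len(search_budget)) {
    hp <- .draw_hyperparams(ncol(x))
    aucs <- vapply(seq_len(cv_folds), function(k) {
      tr <- train_idx[folds != k]; va <- train_idx[folds == k]
      if (length(unique(y[va])) < 2L) return(NA_real_)
      forest <- .fit_ranger(x[tr, , drop = FALSE], y[tr], hp,
                            seed = seed + it, num_threads = num_threads)
      .auc(y[va], .predict_prob(forest, x[va, , drop = FALSE]))
    }, numeric(1))
    cv_table[[it]] <- c(hp, list(cv_auc = mean(aucs, na.rm = TRUE)))
  }
  cv_df <- do.call(rbind, lapply(cv_table, as.data.frame))
  best <- as.list(cv_df[which.max(cv_df$cv_auc), ])
  forest <- .fit_ranger(x[train_idx, , drop = FALSE], y[train_idx], best,
                        seed = seed, num_threads = num_threads)
  auc_test <- .auc(y[test_idx],
                   .predict_prob(forest, x[test_idx, , drop = FALSE]))
  structure(
    list(forest = forest, f0 = f0, schema = colnames(x), motif = motif,
         training_metadata = list(
           best_hyperparameters = best[setdiff(names(best), "cv_auc")],
           cv_results = cv_df, auc_test = auc_test,
           n_pos = sum(y == 1L), n_neg = sum(y == 0L),
           n_train = length(train_idx), n_test = length(test_idx),
           cv_folds = cv_folds, search_budget = search_budget,
           metric = "AUC", seed = seed)),
    class = "mutagenesis_fit")
}

#' @export
print.mutagenesis_fit <- function(x, ...) {
  md <- x$training_metadata
  cat("Mutagenesis model (", x$motif, " motif)\n", sep = "")
  cat("  training sites: ", md$n_pos, " observed + ", md$n_neg,
      " random controls\n", sep = "")
  cat("  held-out AUC:   ", round(md$auc_test, 3),
      "  (", md$n_test, " sites)\n", sep = "")
  cat("  calibration f0: ", signif(x$f0, 4), "\n", sep = "")
  cat("  search: ", md$search_budget, " random configurations, ",
      md$cv_folds, "-fold CV, metric ", md$metric, "\n", sep = "")
  invisible(x)
}

#' Predict from a mutagenesis model
#'
#' @param object A `mutagenesis_fit`.
#' @param newdata Feature matrix matching the model's schema, or a data frame
#'   of sites with `chrom`, `pos` when `genome` and `annotation` are supplied.
#' @param type `"prob"` for classification probabilities, `"rate"` for
#'   calibrated neutral Poisson rates.
#' @param genome,annotation Needed when `newdata` is a site table.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.mutagenesis_fit <- function(object, newdata,
                                    type = c("rate", "prob"),
                                    genome = NULL, annotation = NULL, ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata) && all(c("chrom", "pos") %in% names(newdata))) {
    if (is.null(genome) || is.null(annotation)) {
      stop("supply `genome` and `annotation` to featurize a site table")
    }
    newdata <- extract_features(newdata, genome, annotation, object$motif)
  }
  if (!identical(colnames(newdata), object$schema)) {
    stop("feature schema mismatch between model and newdata")
  }
  y <- .predict_prob(object$forest, newdata)
  if (type == "prob") y else site_rate(y, object$f0)
}

#' Predict neutral insertion rates for every motif site
#'
#' Evaluates the trained model over all indexed motif sites on the analysis
#' chromosomes, in batches, and returns the per-site rate table that the
#' selection model aggregates into region rates.
#'
#' @param model A `mutagenesis_fit`.
#' @param index A `motif_index` (same motif as the model).
#' @param genome,annotation Genome and features used to build site features.
#' @param chunk_size Sites per prediction batch (default 50000).
#' @return Data frame `chrom`, `pos`, `lambda`, sorted, one row per indexed
#'   motif site on the analysis chromosomes.
#' @export
predict_site_rates <- function(model, index, genome, annotation,
                               chunk_size = 50000L) {
  if (!identical(model$motif, index$motif)) {
    stop("model motif (", model$motif, ") does not match index motif (",
         index$motif, ")")
  }
  chroms <- index$analysis_chroms
  sites <- data.frame(
    chrom = rep(chroms, lengths(index$positions[chroms])),
    pos = unlist(index$positions[chroms], use.names = FALSE),
    stringsAsFactors = FALSE)
  lambda <- numeric(nrow(sites))
  starts <- seq(1L, nrow(sites), by = chunk_size)
  for (s in starts) {
    e <- min(s + chunk_size - 1L, nrow(sites))
    lambda[s:e] <- predict(model, sites[s:e, , drop = FALSE], type = "rate",
                           genome = genome, annotation = annotation)
  }
  sites$lambda <- lambda
  sites[order(sites$chrom, sites$pos), , drop = FALSE]
}

#' Constant-rate site table
#'
#' Assigns the same rate to every indexed motif site; with `lambda = 1` the
#' aggregated region rate equals the motif count, i.e. the null-mode
#' background in which only motif density is controlled for.
#'
#' @param index A `motif_index`.
#' @param lambda Constant rate (default 1).
#' @return Data frame `chrom`, `pos`, `lambda`.
#' @export
constant_site_rates <- function(index, lambda = 1) {
  chroms <- index$analysis_chroms
  data.frame(
    chrom = rep(chroms, lengths(index$positions[chroms])),
    pos = unlist(index$positions[chroms], use.names = FALSE),
    lambda = lambda, stringsAsFactors = FALSE)
}
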