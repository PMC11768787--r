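#' Leave-one-subject-out folds
#'
#' One fold per subject: training rows are every other subject's windows
#' (including their prototype-flagged rows); test rows belong to the
#' held-out subject only.
#'
#' @param table Labelled feature table with a `subject_id` column.
#' @return List of folds, each `list(subject_id, train, test)` with row
#'   indices into `table`.
#' @export
loso_folds <- function(table) {
  subjects <- unique(table$subject_id)
  if (length(subjects) < 2L) {
    abort("Leave-one-subject-out requires at least 2 subjects.")
  }
  lapply(subjects, function(s) {
    list(subject_id = s,
         train = which(table$subject_id != s),
         test = which(table$subject_id == s))
  })
}

#' Specificity-band threshold selection
#'
#' Scans candidate thresholds (the observed scores) and returns the one
#' whose training specificity is closest to the 0.95 centre of the target
#' band; among ties the more sensitive (lower) threshold wins. The
#' `in_band` attribute records whether the achieved specificity actually
#' falls inside the open band (with coarse score distributions, e.g.
#' perfectly separated classes, it may not — the closest-to-0.95 fallback
#' then applies).
#'
#' @param scores Training scores (higher = more tremor-like).
#' @param labels 0/1 training labels.
#' @param band Open specificity band, default `(0.945, 0.955)`.
#' @return The threshold, with attributes `specificity`, `sensitivity`,
#'   `in_band`.
#' @export
select_threshold <- function(scores, labels, band = c(0.945, 0.955)) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    abort("Threshold selection requires both classes in the training labels.")
  }
  neg <- sort(scores[labels == 0L])
  pos <- sort(scores[labels == 1L])
  cand <- sort(unique(c(scores, max(scores) + 1)))
  # prediction rule: positive iff score >= threshold
  spec <- findInterval(cand - 1e-12, neg) / length(neg)
  sens <- 1 - findInterval(cand - 1e-12, pos) / length(pos)
  target <- mean(band)
  d <- abs(spec - target)
  best <- which(d <= min(d) + 1e-12)
  best <- best[which.max(sens[best])]
  thr <- cand[best]
  attr(thr, "specificity") <- spec[best]
  attr(thr, "sensitivity") <- sens[best]
  attr(thr, "in_band") <- spec[best] > band[1] && spec[best] < band[2]
  thr
}

#' Area under the ROC curve (rank statistic)
#'
#' Computed from mean ranks (Mann-Whitney), which handles ties exactly.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels (both classes present).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity, specificity and AUROC at a fixed threshold
#'
#' @param scores Test scores.
#' @param labels 0/1 test labels.
#' @param threshold Decision threshold (positive iff `score >= threshold`).
#' @return Tibble with one row: `sensitivity`, `specificity`, `auroc`
#'   (`NA` where the relevant class is absent).
#' @export
compute_metrics <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  sens <- if (any(labels == 1L)) mean(pred[labels == 1L] == 1L) else NA_real_
  spec <- if (any(labels == 0L)) mean(pred[labels == 0L] == 0L) else NA_real_
  tibble::tibble(sensitivity = sens, specificity = spec,
                 auroc = auroc(scores, labels))
}

#' Class-imbalance-aware baseline classifiers
#'
#' The l2-regularised logistic baseline re-weights observations by inverse
#' class frequency; the random forest draws class-balanced bootstrap
#' samples per tree. Both are deterministic given `seed`.
#'
#' @param table Normalised, labelled training feature table.
#' @param which `"logistic"`, `"random_forest"`, or both.
#' @param reg Ridge penalty for the logistic model.
#' @param ntree Trees in the forest.
#' @param seed Seed for the forest's bootstrap.
#' @return Named list of fitted baselines (`pn_baseline` objects).
#' @export
train_baselines <- function(table, which = c("logistic", "random_forest"),
                            reg = 1e-3, ntree = 200L, seed = 1L) {
  which <- match.arg(which, several.ok = TRUE)
  cols <- feature_columns(table)
  X <- as.matrix(table[cols])
  y <- as.integer(table$label == "tremor")
  if (length(unique(y)) < 2L) abort("Training labels must contain both classes.")
  out <- list()
  if ("logistic" %in% which) {
    w <- ifelse(y == 1L, length(y) / (2 * sum(y == 1L)),
                length(y) / (2 * sum(y == 0L)))
    fit <- glmnet::glmnet(X, factor(y, levels = c(0, 1)), family = "binomial",
                          alpha = 0, lambda = reg, weights = w,
                          standardize = FALSE, thresh = 1e-10)
    out$logistic <- structure(list(fit = fit, cols = cols,
                                   threshold = NA_real_),
                              class = c("pn_baseline_logistic", "pn_baseline"))
  }
  if ("random_forest" %in% which) {
    m <- min(table(y))
    fit <- with_seed(seed, randomForest::randomForest(
      x = X, y = factor(y, levels = c(0, 1)),
      ntree = ntree, strata = factor(y, levels = c(0, 1)),
      sampsize = c(m, m), replace = TRUE))
    out$random_forest <- structure(list(fit = fit, cols = cols,
                                        threshold = NA_real_),
                                   class = c("pn_baseline_rf", "pn_baseline"))
  }
  out
}

#' @export
predict.pn_baseline_logistic <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else as.matrix(newdata[object$cols])
  as.numeric(predict(object$fit, X, type = "response"))
}

#' @export
predict.pn_baseline_rf <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else as.matrix(newdata[object$cols])
  as.numeric(predict(object$fit, X, type = "prob")[, "1"])
}

fit_model_for_eval <- function(train_tbl, model, model_args) {
  switch(model,
    single_layer = {
      basis <- suppressWarnings(do.call(
        build_basis_set, c(list(table = train_tbl),
                           model_args$basis %||% list())))
      do.call(train_single_layer,
              c(list(table = train_tbl, basis_set = basis),
                model_args$single %||% list()))
    },
    two_layer = do.call(train_two_layer,
                        c(list(table = train_tbl),
                          model_args$two_layer %||% list())),
    logistic = train_baselines(train_tbl, "logistic",
                               seed = model_args$seed %||% 1L)$logistic,
    random_forest = train_baselines(train_tbl, "random_forest",
                                    seed = model_args$seed %||% 1L)$random_forest,
    abort(sprintf("Unknown model type '%s'.", model))
  )
}

#' Leave-one-subject-out evaluation of a tremor detector
#'
#' For every fold: z-score statistics are fitted on the training subjects
#' only (fold-safe default; set `paper_normalization = TRUE` to fit on all
#' subjects, the global variant), the model is trained on the training
#' windows, the decision threshold is selected on training scores inside
#' the specificity band, and the held-out subject's windows are scored.
#' No held-out data influences basis fitting, normalisation (default),
#' thresholding or weight training.
#'
#' @param features Raw (unnormalised) labelled feature table for the
#'   cohort, e.g. from [featurize_cohort()].
#' @param model `"two_layer"`, `"single_layer"`, `"logistic"` or
#'   `"random_forest"`.
#' @param band Specificity band for [select_threshold()].
#' @param paper_normalization Fit z-score statistics on all subjects
#'   (including the held-out one) instead of the fold-safe default.
#' @param model_args Optional list of per-model arguments (elements
#'   `basis`, `single`, `two_layer`, `seed`).
#' @return A `pn_evaluation` object: per-fold metrics (`folds`),
#'   window-level predictions (`windows`), stratified tables
#'   (`stratified`), duration-agreement statistics (`agreement`) and the
#'   config echo. [tidy()] returns the fold table, [glance()] the
#'   aggregate row.
#' @export
evaluate_loso <- function(features, model = c("two_layer", "single_layer",
                                              "logistic", "random_forest"),
                          band = c(0.945, 0.955),
                          paper_normalization = FALSE,
                          model_args = list()) {
  model <- match.arg(model)
  features <- features[!features$excluded, , drop = FALSE]
  folds <- loso_folds(features)
  global_stats <- if (paper_normalization) zscore_fit(features) else NULL
  fold_rows <- list()
  window_rows <- list()
  for (f in folds) {
    train_raw <- features[f$train, , drop = FALSE]
    test_raw <- features[f$test, , drop = FALSE]
    stats <- global_stats %||% zscore_fit(train_raw)
    train_tbl <- zscore_apply(train_raw, stats)
    test_tbl <- zscore_apply(test_raw, stats)
    fitted <- fit_model_for_eval(train_tbl, model, model_args)
    train_scores <- predict(fitted, train_tbl)
    y_train <- as.integer(train_tbl$label == "tremor")
    thr <- select_threshold(train_scores, y_train, band = band)
    test_scores <- predict(fitted, test_tbl)
    y_test <- as.integer(test_tbl$label == "tremor")
    met <- compute_metrics(test_scores, y_test, as.numeric(thr))
    fold_rows[[f$subject_id]] <- dplyr::bind_cols(
      tibble::tibble(subject_id = f$subject_id,
                     threshold = as.numeric(thr),
                     threshold_in_band = attr(thr, "in_band"),
                     n_test = nrow(test_tbl),
                     n_test_tremor = sum(y_test)),
      met,
      tibble::tibble(
        predicted_tremor_s = 2 * sum(test_scores >= as.numeric(thr)),
        true_tremor_s = 2 * sum(y_test))
    )
    window_rows[[f$subject_id]] <- tibble::tibble(
      subject_id = f$subject_id,
      window_start = if ("window_start" %in% names(test_tbl)) {
        test_tbl$window_start
      } else {
        NA_real_
      },
      label = test_tbl$label,
      sub_class = test_tbl$sub_class,
      prototype = test_tbl$prototype,
      score = test_scores,
      pred = as.integer(test_scores >= as.numeric(thr))
    )
  }
  folds_tbl <- dplyr::bind_rows(fold_rows)
  windows_tbl <- dplyr::bind_rows(window_rows)
  strat <- stratified_metrics(windows_tbl)
  tremor_folds <- folds_tbl[folds_tbl$true_tremor_s > 0, , drop = FALSE]
  agreement <- if (nrow(tremor_folds) >= 3L) {
    duration_agreement(tremor_folds$predicted_tremor_s,
                       tremor_folds$true_tremor_s)
  } else {
    NULL
  }
  structure(list(folds = folds_tbl,
                 windows = windows_tbl,
                 stratified = strat,
                 agreement = agreement,
                 config = list(model = model, band = band,
                               paper_normalization = paper_normalization)),
            class = "pn_evaluation")
}

#' @export
print.pn_evaluation <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<LOSO evaluation> %s: sens %.2f (%.2f), spec %.2f (%.2f), AUROC %.2f (%.2f) over %d folds\n",
    x$config$model, g$sensitivity_mean, g$sensitivity_sd,
    g$specificity_mean, g$specificity_sd, g$auroc_mean, g$auroc_sd,
    nrow(x$folds)))
  invisible(x)
}

#' Sub-class-stratified metrics
#'
#' Sensitivity per tremor sub-class is computed per fold over the fold's
#' prototype-tagged tremor windows of that sub-class (the stratification
#' follows the prototypical-example annotations); specificity per
#' non-tremor sub-class over all of the fold's windows of the sub-class.
#' Cells aggregate as mean and SD across the folds possessing the
#' sub-class (absent sub-classes yield no cell, not a zero), with the fold
#' count reported.
#'
#' @param windows Window-level prediction table (from [evaluate_loso()]):
#'   columns `subject_id`, `label`, `sub_class`, `prototype`, `pred`.
#' @return List of two tibbles, `sensitivity` (tremor sub-classes) and
#'   `specificity` (non-tremor sub-classes), with per-fold mean, sd and
#'   `n_folds`.
#' @export
stratified_metrics <- function(windows) {
  sens_tbl <- windows |>
    dplyr::filter(.data$label == "tremor", .data$prototype,
                  .data$sub_class %in% tremor_sub_classes()) |>
    dplyr::group_by(.data$sub_class, .data$subject_id) |>
    dplyr::summarise(value = mean(.data$pred == 1L), .groups = "drop") |>
    dplyr::group_by(.data$sub_class) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = stats::sd(.data$value),
                     n_folds = dplyr::n(), .groups = "drop")
  spec_tbl <- windows |>
    dplyr::filter(.data$label == "non_tremor",
                  .data$sub_class %in% non_tremor_sub_classes()) |>
    dplyr::group_by(.data$sub_class, .data$subject_id) |>
    dplyr::summarise(value = mean(.data$pred == 0L), .groups = "drop") |>
    dplyr::group_by(.data$sub_class) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = stats::sd(.data$value),
                     n_folds = dplyr::n(), .groups = "drop")
  list(sensitivity = sens_tbl, specificity = spec_tbl)
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' @param x,y Numeric vectors.
#' @param level Confidence level (default 0.8).
#' @return Tibble with `r`, `lower`, `upper`, `n`.
#' @export
pearson_ci <- function(x, y, level = 0.8) {
  n <- length(x)
  r <- suppressWarnings(stats::cor(x, y))
  if (!is.finite(r)) {
    return(tibble::tibble(r = NA_real_, lower = NA_real_, upper = NA_real_,
                          n = n))
  }
  if (n > 3L && abs(r) < 1) {
    z <- atanh(r)
    se <- 1 / sqrt(n - 3)
    q <- stats::qnorm(1 - (1 - level) / 2)
    lo <- tanh(z - q * se)
    hi <- tanh(z + q * se)
  } else {
    lo <- hi <- r
  }
  tibble::tibble(r = r, lower = lo, upper = hi, n = n)
}

#' Intra-class correlation ICC(2,1) with confidence interval
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC between
#' two measurement columns (here: predicted vs annotated tremor seconds
#' per subject), with the Shrout--Fleiss F-based confidence interval.
#' Absolute agreement penalises systematic offsets, so `y = x + c` gives
#' ICC < 1 even though the Pearson correlation is 1.
#'
#' @param x,y Paired measurements (length n >= 3).
#' @param level Confidence level (default 0.8).
#' @return Tibble with `icc`, `lower`, `upper`, `n`.
#' @export
icc21_ci <- function(x, y, level = 0.8) {
  M <- cbind(x, y)
  n <- nrow(M)
  k <- 2L
  if (n < 3L) abort("ICC requires at least 3 paired measurements.")
  grand <- mean(M)
  rowm <- rowMeans(M)
  colm <- colMeans(M)
  MSR <- k * sum((rowm - grand)^2) / (n - 1)
  MSC <- n * sum((colm - grand)^2) / (k - 1)
  resid <- M - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand
  MSE <- sum(resid^2) / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  alpha <- 1 - level
  if (MSE <= 0 && MSC <= 0) {
    lo <- hi <- icc
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    # suppress qbeta accuracy chatter for the extreme df the F quantile
    # can reach on near-degenerate inputs
    FL <- suppressWarnings(stats::qf(1 - alpha / 2, n - 1, v))
    FU <- suppressWarnings(stats::qf(1 - alpha / 2, v, n - 1))
    lo <- (n * (MSR - FL * MSE)) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    hi <- (n * (FU * MSR - MSE)) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  }
  tibble::tibble(icc = icc, lower = lo, upper = hi, n = n)
}

#' Agreement between predicted and annotated tremor duration
#'
#' @param predicted_s,true_s Per-subject tremor seconds.
#' @param level Confidence level for both intervals (default 0.8).
#' @return List with `pearson` ([pearson_ci()]) and `icc` ([icc21_ci()]).
#' @export
duration_agreement <- function(predicted_s, true_s, level = 0.8) {
  list(pearson = pearson_ci(true_s, predicted_s, level = level),
       icc = icc21_ci(true_s, predicted_s, level = level))
}

#' Learning curves under cumulative training-data sampling
#'
#' Per fold and seed, training windows are sampled cumulatively: the
#' sample at a larger duration is a superset of the sample at any smaller
#' duration (nested sampling reduces comparison noise between durations).
#' The model factory is refitted on each sample and scored on the held-out
#' subject. When a requested duration covers the full training set, the
#' full table is used in its original order, reproducing the standard
#' LOSO fit exactly.
#'
#' @param features Raw labelled feature table.
#' @param durations_min Training durations (minutes of 2-s windows).
#' @param model_factory `function(train_tbl) -> model` with a `predict()`
#'   method returning scores.
#' @param seeds Integer seeds for the sampling order.
#' @param paper_normalization See [evaluate_loso()].
#' @return A `pn_learning_curve` tibble: one row per
#'   (duration, seed, fold) with the fold AUROC, plus the `summary`
#'   attribute aggregating mean AUROC per duration.
#' @export
learning_curve <- function(features, durations_min, model_factory,
                           seeds = 1L, paper_normalization = FALSE) {
  features <- features[!features$excluded, , drop = FALSE]
  folds <- loso_folds(features)
  global_stats <- if (paper_normalization) zscore_fit(features) else NULL
  rows <- list()
  for (seed in seeds) {
    for (f in folds) {
      train_raw <- features[f$train, , drop = FALSE]
      test_raw <- features[f$test, , drop = FALSE]
      if (!any(test_raw$label == "tremor") ||
          !any(test_raw$label == "non_tremor")) {
        next   # AUROC undefined for single-class test subjects
      }
      stats <- global_stats %||% zscore_fit(train_raw)
      test_tbl <- zscore_apply(test_raw, stats)
      n_train <- nrow(train_raw)
      ord <- with_seed(derive_seed(seed, match(f$subject_id,
                                               vapply(folds, `[[`, "",
                                                      "subject_id"))),
                       sample.int(n_train))
      # guarantee both classes from the smallest sample onwards
      pos <- ord[train_raw$label[ord] == "tremor"]
      neg <- ord[train_raw$label[ord] == "non_tremor"]
      lead <- c(head(pos, 2L), head(neg, 2L))
      ord <- c(lead, setdiff(ord, lead))
      for (d in sort(durations_min)) {
        k <- min(n_train, max(4L, round(d * 60 / 2)))
        sel <- if (k >= n_train) seq_len(n_train) else sort(ord[seq_len(k)])
        train_tbl <- zscore_apply(train_raw[sel, , drop = FALSE], stats)
        fit <- model_factory(train_tbl)
        sc <- predict(fit, test_tbl)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          duration_min = d, seed = seed, subject_id = f$subject_id,
          n_windows = k,
          auroc = auroc(sc, as.integer(test_tbl$label == "tremor")))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  summary <- out |>
    dplyr::group_by(.data$duration_min) |>
    dplyr::summarise(auroc_mean = mean(.data$auroc),
                     auroc_sd = stats::sd(.data$auroc), .groups = "drop")
  structure(out, class = c("pn_learning_curve", class(out)),
            summary = summary)
}
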