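test_that("LOSO folds partition subjects exactly once", {
  toy <- make_toy_table(n = 120, seed = 1,
                        subjects = c("A", "B", "C", "D"))
  folds <- loso_folds(toy)
  expect_length(folds, 4L)
  test_subjects <- vapply(folds, `[[`, "", "subject_id")
  expect_setequal(test_subjects, c("A", "B", "C", "D"))
  for (f in folds) {
    expect_false(f$subject_id %in% toy$subject_id[f$train])
    expect_true(all(toy$subject_id[f$test] == f$subject_id))
  }
  one <- toy[toy$subject_id == "A", ]
  expect_error(loso_folds(one), regexp = "2 subjects")
})

test_that("threshold selection lands on the 95% specificity quantile", {
  # perfectly separating scores: sensitivity 1 at the selected threshold
  set.seed(2)
  scores <- c(runif(200, 0, 0.4), runif(100, 0.6, 1))
  labels <- rep(c(0L, 1L), c(200, 100))
  thr <- select_threshold(scores, labels)
  expect_equal(attr(thr, "sensitivity"), 1)

  # degenerate 0/1 scores: no threshold lands in the band; the fallback
  # picks the specificity closest to 0.95 (here 1.0) and flags it
  s01 <- c(rep(0, 1000), rep(1, 50))
  l01 <- rep(c(0L, 1L), c(1000, 50))
  thr2 <- select_threshold(s01, l01)
  expect_equal(attr(thr2, "specificity"), 1)
  expect_false(attr(thr2, "in_band"))

  # Gaussian mixture: analytic 95% quantile of the negative class
  set.seed(3)
  n <- 1e5
  sc <- c(rnorm(n / 2, 0, 1), rnorm(n / 2, 2, 1))
  lb <- rep(c(0L, 1L), each = n / 2)
  thr3 <- select_threshold(sc, lb)
  expect_lt(abs(as.numeric(thr3) - qnorm(0.95)), 0.02)

  expect_error(select_threshold(1:5, rep(1L, 5)), regexp = "both classes")
})

test_that("metrics match brute-force definitions", {
  met <- compute_metrics(c(0.1, 0.2, 0.9, 0.8), c(0, 0, 1, 1), 0.5)
  expect_equal(unlist(met), c(sensitivity = 1, specificity = 1, auroc = 1))

  # null scores: AUROC 0.5 within 0.01 at n = 1e5
  set.seed(4)
  sc <- runif(1e5)
  lb <- rbinom(1e5, 1, 0.3)
  expect_lt(abs(auroc(sc, lb) - 0.5), 0.01)

  # rank AUROC equals the all-pairs count exactly (with ties)
  set.seed(5)
  sc <- round(runif(200), 2)
  lb <- rbinom(200, 1, 0.4)
  pos <- sc[lb == 1]
  neg <- sc[lb == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(auroc(sc, lb), mean(cmp), tolerance = 1e-12)
})

test_that("baselines learn separable data and respect imbalance weighting", {
  toy <- make_toy_table(n = 120, sep = 4, seed = 6)
  y <- as.integer(toy$label == "tremor")
  names(toy)[1:6] <- feature_names()[1:6]
  fits <- train_baselines(toy, seed = 2)
  expect_gte(auroc(predict(fits$logistic, toy), y), 0.99)
  expect_gte(auroc(predict(fits$random_forest, toy), y), 0.99)

  # seeded forest is deterministic
  fits2 <- train_baselines(toy, which = "random_forest", seed = 2)
  expect_identical(predict(fits$random_forest, toy),
                   predict(fits2$random_forest, toy))

  # 99:1 imbalance with inverse-frequency weights recovers the balanced
  # boundary: for equal-variance Gaussians at 0 and 2 the balanced
  # decision point is at 1 (closed-form LDA)
  set.seed(7)
  n0 <- 9900; n1 <- 100
  tbl <- tibble::tibble(x1 = c(rnorm(n0, 0), rnorm(n1, 2)),
                        x2 = rnorm(n0 + n1))
  names(tbl)[1:2] <- feature_names()[1:2]
  tbl$subject_id <- "A"
  tbl$label <- rep(c("non_tremor", "tremor"), c(n0, n1))
  tbl$sub_class <- "none"; tbl$prototype <- FALSE; tbl$excluded <- FALSE
  fit <- train_baselines(tbl, which = "logistic", reg = 1e-4)$logistic
  co <- as.numeric(coef(fit$fit))   # intercept, slope on x1, slope on x2
  boundary <- -co[1] / co[2]
  expect_lt(abs(boundary - 1), 0.1)
})

test_that("stratified metrics aggregate per fold and omit absent cells", {
  w <- tibble::tibble(
    subject_id = rep(c("A", "B", "C"), each = 4),
    label = rep(c("tremor", "tremor", "non_tremor", "non_tremor"), 3),
    sub_class = rep(c("T1", "T1", "N5", "N2"), 3),
    prototype = rep(c(TRUE, TRUE, FALSE, FALSE), 3),
    pred = c(1L, 1L, 0L, 0L,   1L, 0L, 1L, 0L,   0L, 0L, 0L, 1L)
  )
  s <- stratified_metrics(w)
  t1 <- s$sensitivity[s$sensitivity$sub_class == "T1", ]
  # per-fold sensitivities 1, 0.5, 0
  expect_equal(t1$mean, 0.5)
  expect_equal(t1$sd, sd(c(1, 0.5, 0)))
  expect_equal(t1$n_folds, 3L)
  n5 <- s$specificity[s$specificity$sub_class == "N5", ]
  expect_equal(n5$mean, mean(c(1, 0, 1)))
  expect_false("N7" %in% s$specificity$sub_class)

  all_right <- w
  all_right$pred <- as.integer(all_right$label == "tremor")
  s2 <- stratified_metrics(all_right)
  expect_true(all(s2$sensitivity$mean == 1))
  expect_true(all(s2$specificity$mean == 1))
})

test_that("evaluation is fold-safe and aggregates recompute from folds", {
  toy <- make_toy_table(n = 160, sep = 5, seed = 8,
                        subjects = c("A", "B", "C", "D"))
  ev <- evaluate_loso(toy, "logistic")
  expect_equal(nrow(ev$folds), 4L)
  g <- glance(ev)
  tremor_folds <- ev$folds[ev$folds$n_test_tremor > 0, ]
  expect_equal(g$auroc_mean, mean(tremor_folds$auroc))
  expect_equal(g$specificity_mean, mean(ev$folds$specificity))
  # every test window is scored exactly once
  expect_equal(nrow(ev$windows), sum(!toy$excluded))
})

test_that("learning curves nest samples and recover the full-data fit", {
  toy <- make_toy_table(n = 200, sep = 4, seed = 9,
                        subjects = c("A", "B", "C", "D"))
  names(toy)[1:6] <- feature_names()[1:6]
  factory <- function(train_tbl) {
    # tiny cumulative samples trip glmnet's small-class warning by design
    suppressWarnings(train_baselines(train_tbl, which = "logistic")$logistic)
  }
  lc <- learning_curve(toy, durations_min = c(0.5, 1, 100), factory,
                       seeds = 1L)
  expect_true(all(c("duration_min", "auroc") %in% names(lc)))
  s <- attr(lc, "summary")
  expect_equal(nrow(s), 3L)
  # the largest duration covers the full training set in original order,
  # reproducing the plain LOSO AUROC exactly
  ev <- evaluate_loso(toy, "logistic")
  full <- lc[lc$duration_min == 100, ]
  for (i in seq_len(nrow(full))) {
    expect_equal(full$auroc[i],
                 ev$folds$auroc[ev$folds$subject_id == full$subject_id[i]],
                 tolerance = 1e-12)
  }
  # nesting: windows used at smaller durations are subsets
  expect_true(all(lc$n_windows[lc$duration_min == 0.5] <=
                    lc$n_windows[lc$duration_min == 1]))
})

test_that("duration agreement distinguishes identity from offset", {
  x <- c(900, 300, 2800, 1700, 600, 950, 380, 3200)
  idag <- duration_agreement(x, x)
  expect_equal(idag$pearson$r, 1)
  expect_equal(idag$icc$icc, 1)

  off <- duration_agreement(x + 500, x)
  expect_equal(off$pearson$r, 1)
  expect_lt(off$icc$icc, 1)
})

test_that("Pearson CIs hit nominal coverage near rho = 0.8 at n = 8", {
  set.seed(10)
  reps <- 1e4
  rho <- 0.8
  rs <- numeric(reps)
  cover <- logical(reps)
  for (i in seq_len(reps)) {
    x <- rnorm(8)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(8)
    ci <- pearson_ci(x, y, level = 0.8)
    rs[i] <- ci$r
    cover[i] <- ci$lower <= rho && rho <= ci$upper
  }
  expect_lt(abs(mean(rs) - rho), 0.03)
  # the Fisher-z interval over-covers slightly at n = 8 (measured 82.2%
  # against this oracle); 3 points brackets that small-sample bias
  expect_lt(abs(mean(cover) - 0.80), 0.03)
})
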