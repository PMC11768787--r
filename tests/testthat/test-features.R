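test_that("windows tile segments in non-overlapping 2-s blocks", {
  rec <- make_sine_recording(duration_s = 60, rate_hz = 200, seed = 2)
  rec50 <- downsample(rec)
  segs <- tibble::tibble(subject_id = "T", segment_id = 1:3,
                         start_s = c(0, 10, 20), end_s = c(7, 11.9, 50))
  w <- window_segments(rec50, segs)
  expect_equal(sum(w$segment_id == 1L), 3L)   # floor(7 / 2)
  expect_equal(sum(w$segment_id == 2L), 0L)   # 1.9 s segment
  expect_equal(sum(w$segment_id == 3L), 15L)
  expect_true(all(w$window_end - w$window_start == 2))
  one <- tibble::tibble(subject_id = "T", segment_id = 1L, start_s = 0,
                        end_s = 60)
  expect_equal(nrow(window_segments(rec50, one)), 30L)
})

test_that("band power matches Parseval on tones and is flat on white noise", {
  expect_equal(band_power(numeric(100), c(4, 8)), 0)
  expect_equal(band_power(numeric(100), c(0.3, 2)), 0)

  t <- (0:99) / 50
  x <- sin(2 * pi * 5 * t)
  bp <- band_power(x, c(4, 8))
  expect_lt(abs(bp - 0.5) / 0.5, 0.10)   # sine variance A^2/2

  # flat spectrum: ratio of mean band powers (4-8 vs 8-12) near 1
  set.seed(31)
  p48 <- p812 <- numeric(1000)
  for (i in 1:1000) {
    w <- rnorm(100)
    p48[i] <- band_power(w, c(4, 8))
    p812[i] <- band_power(w, c(8, 12))
  }
  expect_lt(abs(mean(p48) / mean(p812) - 1), 0.05)

  expect_error(band_power(x, c(8, 4)), regexp = "lo < hi")
  expect_error(band_power(x, c(0, 8)), regexp = "within")
})

test_that("disjoint sub-band powers nest inside the broad band", {
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(100) + sin(2 * pi * runif(1, 1, 10) * (0:99) / 50)
    total <- band_power(x, c(0.2, 14))
    parts <- band_power(x, c(0.3, 2)) + band_power(x, c(4, 8)) +
      band_power(x, c(8, 12))
    expect_lte(parts, total + 1e-12)
  }
})

test_that("dominant peaks resolve frequency to the 0.5 Hz bin grid", {
  t <- (0:99) / 50
  pk <- dominant_peak(sin(2 * pi * 5 * t), c(4, 8))
  expect_lt(abs(pk["freq"] - 5), 0.5)

  z <- dominant_peak(numeric(100), c(4, 8))
  expect_equal(unname(z["height"]), 0)
  expect_equal(unname(z["freq"]), 4)   # lowest bin convention

  two <- sin(2 * pi * 5 * t) + 0.5 * sin(2 * pi * 10 * t)
  pk2 <- dominant_peak(two, c(0.2, 14))
  expect_lt(abs(pk2["freq"] - 5), 0.5)

  expect_error(dominant_peak(two, c(4.1, 4.2)), regexp = "no periodogram")
})

test_that("sample entropy follows its conventions and the brute-force count", {
  expect_equal(sample_entropy(rep(1, 100)), 0)

  # deterministic sine below iid noise of equal variance (paired seeds)
  t <- (0:99) / 50
  wins <- 0L
  for (s in 1:100) {
    set.seed(s)
    noise <- rnorm(100, 0, sqrt(0.5))
    se_sine <- sample_entropy(sin(2 * pi * 5 * t + runif(1, 0, 2 * pi)))
    se_noise <- sample_entropy(noise)
    if (se_sine < se_noise) wins <- wins + 1L
  }
  expect_equal(wins, 100L)

  # exact equality with an independent O(N^2) loop implementation
  for (s in 1:5) {
    set.seed(s)
    x <- rnorm(100)
    expect_identical(sample_entropy(x), sampen_bruteforce(x))
  }
})

test_that("spectral entropy spans its [0, 1] range as documented", {
  p <- numeric(50); p[10] <- 1
  expect_equal(protonet:::entropy_from_psd(p), 0)
  expect_equal(protonet:::entropy_from_psd(rep(0.02, 50)), 1)
  set.seed(13)
  vals <- vapply(1:1000, function(i) spectral_entropy(rnorm(100)),
                 numeric(1))
  # a single unaveraged periodogram has exponential bin fluctuations, which
  # cap the expected normalised entropy near 1 - gamma/log(nbins) ~ 0.893
  expect_gt(mean(vals), 0.88)
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("the 45-feature contract and its frozen order hold", {
  set.seed(5)
  acc <- matrix(rnorm(300), 100, 3)
  f <- extract_features(acc)
  expect_length(f, 45L)
  expect_identical(names(f), feature_names())
  expect_length(protonet:::axis_feature_names(), 15L)
  expect_true(all(is.finite(f)))

  zero <- extract_features(matrix(0, 100, 3))
  expect_true(all(is.finite(zero)))
  expect_equal(unname(zero["sd_x"]), 0)
  expect_equal(unname(zero["bp_tremor_y"]), 0)
  expect_equal(unname(zero["sampen_z"]), 0)

  expect_error(extract_features(matrix(0, 99, 3)), regexp = "100 samples")
  expect_error(extract_features(matrix(0, 100, 2)), regexp = "n x 3")
})

test_that("features are invariant to axis-wise sign flips", {
  set.seed(6)
  acc <- matrix(rnorm(300), 100, 3) + 0.5
  f <- extract_features(acc)
  g <- extract_features(-acc)
  expect_equal(f, g, tolerance = 1e-12)
})

test_that("feature values are pinned against a golden reference", {
  t <- (0:99) / 50
  acc <- cbind(sin(2 * pi * 5 * t), 0.5 * sin(2 * pi * 1.5 * t),
               rep(1, 100))
  f <- extract_features(acc)
  expect_equal(unname(f["sd_x"]), sd(acc[, 1]), tolerance = 1e-12)
  expect_equal(unname(f["peak_freq_tremor_x"]), 5)
  expect_equal(unname(f["peak_freq_low_y"]), 1.5)
  expect_equal(unname(f["bp_tremor_x"]), 0.49999928174898167,
               tolerance = 1e-9)
  expect_equal(unname(f["spec_entropy_x"]), 0.22416897765732574,
               tolerance = 1e-9)
  expect_equal(unname(f["sampen_y"]), 0.2638145910451376, tolerance = 1e-9)
})

test_that("z-scoring normalises, handles constants, and transfers", {
  toy <- make_toy_table(n = 60, d = 4, seed = 3)
  names(toy)[1:4] <- feature_names()[1:4]
  toy[[feature_names()[4]]] <- 2   # constant column
  fit <- zscore_fit(toy)
  z <- zscore_apply(toy, fit)
  cols <- protonet:::feature_columns(z)
  M <- as.matrix(z[cols])
  expect_true(all(abs(colMeans(M)) < 1e-10))
  expect_true(all(abs(apply(M[, 1:3], 2, sd) - 1) < 1e-10))
  expect_true(all(M[, 4] == 0))   # centred, sd treated as 1

  # applying train stats to held-out rows equals direct recomputation
  train <- toy[1:40, ]
  test <- toy[41:60, ]
  st <- zscore_fit(train)
  ztest <- zscore_apply(test, st)
  manual <- (test[[cols[2]]] - st$mean[2]) / st$sd[2]
  expect_equal(ztest[[cols[2]]], manual, tolerance = 1e-12)

  bad <- st
  bad$mean <- bad$mean[-1]
  expect_error(zscore_apply(test, bad), regexp = "match")
})
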