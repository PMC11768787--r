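#' Window a recording inside stationary segments
#'
#' Lays contiguous, non-overlapping 2-s windows from the start of each
#' stationary segment; a trailing partial window is dropped.
#'
#' @param rec A 50 Hz [recording()].
#' @param segments Segment tibble from [segment_stationary()].
#' @param window_s Window length in seconds (default 2).
#' @return A tibble with columns `subject_id`, `segment_id`,
#'   `window_start`, `window_end`.
#' @export
window_segments <- function(rec, segments, window_s = 2) {
  out <- lapply(seq_len(nrow(segments)), function(i) {
    len <- segments$end_s[i] - segments$start_s[i]
    k <- floor(len / window_s + 1e-9)
    if (k < 1L) return(NULL)
    starts <- segments$start_s[i] + window_s * (seq_len(k) - 1L)
    tibble::tibble(subject_id = segments$subject_id[i],
                   segment_id = segments$segment_id[i],
                   window_start = starts,
                   window_end = starts + window_s)
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(subject_id = character(), segment_id = integer(),
                          window_start = numeric(), window_end = numeric())
  }
  out
}

# Hann-tapered one-sided periodogram with density scaling.
# Returns freq (Hz) and psd (power per Hz) for bins 0 .. fs/2.
periodogram_hann <- function(x, fs) {
  n <- length(x)
  h <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  X <- fft(h * x)   # DC bin kept; feature bands never include it
  half <- floor(n / 2)
  p <- Mod(X[1:(half + 1)])^2 / (fs * sum(h^2))
  scale2 <- rep(2, half + 1)
  scale2[1] <- 1
  if (n %% 2 == 0) scale2[half + 1] <- 1
  list(freq = (0:half) * fs / n, psd = p * scale2)
}

#' Band power of a window
#'
#' Integral of the Hann-tapered one-sided periodogram over the half-open
#' frequency band `[lo, hi)`. The half-open convention keeps the pipeline's
#' sub-bands (0.3--2, 4--8, 8--12 Hz) disjoint.
#'
#' @param x Numeric window (one axis).
#' @param band Numeric `c(lo, hi)` in Hz, within (0, fs/2].
#' @param fs Sampling rate in Hz (default 50).
#' @return Band power (signal units squared).
#' @export
band_power <- function(x, band, fs = 50) {
  if (band[1] >= band[2]) abort("Band must satisfy lo < hi.")
  if (band[1] <= 0 || band[2] > fs / 2 + 1e-9) {
    abort(sprintf("Band must lie within (0, %g] Hz.", fs / 2))
  }
  pg <- periodogram_hann(x, fs)
  df <- fs / length(x)
  sel <- pg$freq >= band[1] & pg$freq < band[2]
  sum(pg$psd[sel]) * df
}

#' Dominant spectral peak in a band
#'
#' Frequency and PSD height of the maximum periodogram bin inside the
#' half-open band `[lo, hi)`; ties break toward the lower frequency. For an
#' all-zero window the height is 0 and the frequency is the lowest bin in
#' the band (documented convention).
#'
#' @inheritParams band_power
#' @return Named numeric `c(freq, height)`.
#' @export
dominant_peak <- function(x, band, fs = 50) {
  if (band[1] >= band[2]) abort("Band must satisfy lo < hi.")
  pg <- periodogram_hann(x, fs)
  sel <- which(pg$freq >= band[1] & pg$freq < band[2])
  if (length(sel) == 0L) abort("Band contains no periodogram bins.")
  i <- sel[which.max(pg$psd[sel])]
  c(freq = pg$freq[i], height = pg$psd[i])
}

#' Sample entropy of a window
#'
#' Standard SampEn(m, r): the negative log ratio of the number of template
#' pairs matching at length `m + 1` to those matching at length `m` under
#' the Chebyshev distance with tolerance `r`. Conventions for degenerate
#' windows: a constant window (`sd(x) == 0`) returns 0; when no pair
#' matches at length `m + 1` (or none at `m`), the documented cap value
#' `-log(2 / ((N - m - 1) (N - m)))` (the largest finite estimate for the
#' window length) is returned.
#'
#' @param x Numeric window.
#' @param m Template length (default 2).
#' @param r Match tolerance; default `0.2 * sd(x)`.
#' @return Non-negative scalar.
#' @export
sample_entropy <- function(x, m = 2L, r = NULL) {
  n <- length(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(0)
  if (is.null(r)) r <- 0.2 * s
  cap <- -log(2 / ((n - m - 1) * (n - m)))
  nt <- n - m   # template count for both lengths (standard convention)
  # Chebyshev distances between length-(m+1) prefixes, built incrementally.
  dmat <- matrix(0, nt, nt)
  for (k in 0:(m - 1)) {
    seg <- x[(1:nt) + k]
    dmat <- pmax(dmat, abs(outer(seg, seg, "-")))
  }
  B <- (sum(dmat <= r) - nt) / 2
  seg <- x[(1:nt) + m]
  dmat <- pmax(dmat, abs(outer(seg, seg, "-")))
  A <- (sum(dmat <= r) - nt) / 2
  if (A == 0 || B == 0) return(cap)
  -log(A / B)
}

# Shannon entropy of a PSD mass vector, normalised to [0, 1].
entropy_from_psd <- function(p) {
  tot <- sum(p)
  if (tot <= 0 || length(p) < 2L) return(0)
  q <- p / tot
  q <- q[q > 0]
  -sum(q * log(q)) / log(length(p))
}

#' Spectral entropy of a window
#'
#' Shannon entropy of the Hann periodogram normalised to a probability
#' mass over the bins in 0.2--25 Hz (DC excluded), divided by the log of
#' the bin count, giving a value in \[0, 1\]: 0 for a single-bin spectrum,
#' 1 for an exactly flat one. An all-zero window returns 0.
#'
#' @inheritParams band_power
#' @param band Frequency range over which the mass is formed.
#' @return Scalar in \[0, 1\].
#' @export
spectral_entropy <- function(x, fs = 50, band = c(0.2, 25)) {
  pg <- periodogram_hann(x, fs)
  sel <- pg$freq >= band[1] & pg$freq <= band[2] & pg$freq > 0
  entropy_from_psd(pg$psd[sel])
}

# Frozen feature bands and per-axis feature order. 15 features per axis:
# sd, 4 band powers, (freq, height) of the dominant peak in the same 4
# bands, sample entropy, spectral entropy.
feature_bands <- function() {
  list(low = c(0.3, 2), tremor = c(4, 8), high = c(8, 12), broad = c(0.2, 14))
}

axis_feature_names <- function() {
  bands <- names(feature_bands())
  c("sd",
    paste0("bp_", bands),
    as.vector(rbind(paste0("peak_freq_", bands), paste0("peak_height_", bands))),
    "sampen", "spec_entropy")
}

#' Names of the 45 window features
#'
#' Per-axis order: standard deviation; band powers in 0.3--2, 4--8, 8--12
#' and 0.2--14 Hz; dominant-peak frequency and height in the same four
#' bands; sample entropy; spectral entropy. Axes concatenate x, y, z.
#'
#' @return Character vector of length 45.
#' @export
feature_names <- function() {
  as.vector(vapply(c("x", "y", "z"),
                   function(a) paste0(axis_feature_names(), "_", a),
                   character(15L)))
}

extract_axis_features <- function(x, fs) {
  bands <- feature_bands()
  pg <- periodogram_hann(x, fs)
  df <- fs / length(x)
  out <- numeric(15L)
  out[1L] <- stats::sd(x)
  for (b in seq_along(bands)) {
    sel <- pg$freq >= bands[[b]][1] & pg$freq < bands[[b]][2]
    out[1L + b] <- sum(pg$psd[sel]) * df
  }
  pos <- 6L
  for (b in seq_along(bands)) {
    sel <- which(pg$freq >= bands[[b]][1] & pg$freq < bands[[b]][2])
    i <- sel[which.max(pg$psd[sel])]
    out[pos] <- pg$freq[i]
    out[pos + 1L] <- pg$psd[i]
    pos <- pos + 2L
  }
  out[14L] <- sample_entropy(x)
  sel <- pg$freq >= 0.2 & pg$freq <= 25 & pg$freq > 0
  out[15L] <- entropy_from_psd(pg$psd[sel])
  out
}

#' Extract the 45-dimensional feature vector of one 2-s window
#'
#' @param acc `100 x 3` numeric matrix (columns x, y, z) of detrended
#'   50 Hz acceleration.
#' @param fs Sampling rate (default 50).
#' @return Named numeric vector of length 45 (see [feature_names()]).
#' @export
extract_features <- function(acc, fs = 50) {
  if (!is.matrix(acc) || ncol(acc) != 3L) {
    abort("`acc` must be an n x 3 matrix.")
  }
  if (nrow(acc) != 2 * fs) {
    abort(sprintf("Window must contain exactly %d samples.", 2L * fs))
  }
  out <- c(extract_axis_features(acc[, 1L], fs),
           extract_axis_features(acc[, 2L], fs),
           extract_axis_features(acc[, 3L], fs))
  names(out) <- feature_names()
  out
}

#' Featurize one preprocessed recording
#'
#' Windows the stationary segments ([window_segments()]), extracts the
#' 45-dimensional feature vector per window and, when an annotation track
#' is supplied, attaches window labels via [label_windows()].
#'
#' @param rec Detrended 50 Hz [recording()].
#' @param segments Segments from [segment_stationary()].
#' @param track Optional [annotation_track()].
#' @return A feature table: one row per window with metadata columns
#'   followed by the 45 feature columns; attribute `normalization` is
#'   `"raw"`.
#' @export
featurize_recording <- function(rec, segments, track = NULL) {
  windows <- window_segments(rec, segments)
  if (!is.null(track)) {
    windows <- label_windows(windows, track)
  }
  rate <- rec_rate(rec)
  t0 <- rec$time_s[1L]
  acc <- rec_matrix(rec)
  n_win <- nrow(windows)
  feats <- matrix(NA_real_, n_win, 45L, dimnames = list(NULL, feature_names()))
  for (i in seq_len(n_win)) {
    a <- round((windows$window_start[i] - t0) * rate) + 1L
    idx <- a:(a + 2L * rate - 1L)
    feats[i, ] <- extract_features(acc[idx, , drop = FALSE], fs = rate)
  }
  out <- dplyr::bind_cols(windows, tibble::as_tibble(feats))
  attr(out, "normalization") <- "raw"
  out
}

#' Preprocess and featurize a whole synthetic cohort
#'
#' Runs [preprocess_recording()] and [featurize_recording()] for every
#' subject and row-binds the resulting feature tables.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param lam Trend-filter regularisation.
#' @param ... Passed to [segment_stationary()].
#' @return A raw feature table covering all subjects.
#' @export
featurize_cohort <- function(cohort, lam = 10000, ...) {
  tables <- lapply(seq_len(nrow(cohort)), function(i) {
    pp <- preprocess_recording(cohort$recording[[i]], lam = lam, ...)
    featurize_recording(pp$recording, pp$segments, cohort$annotations[[i]])
  })
  out <- dplyr::bind_rows(tables)
  attr(out, "normalization") <- "raw"
  out
}

# Canonical 45 feature columns when present; otherwise every numeric
# non-metadata column (so ad-hoc feature tables work throughout).
feature_columns <- function(table) {
  canon <- intersect(feature_names(), names(table))
  if (length(canon) > 0L) return(canon)
  meta <- c("subject_id", "segment_id", "window_start", "window_end",
            "label", "sub_class", "prototype", "excluded", "seed")
  num <- names(table)[vapply(table, is.numeric, logical(1L))]
  setdiff(num, meta)
}

#' Z-score normalisation of a feature table
#'
#' `zscore_fit()` computes per-feature means and SDs; `zscore_apply()`
#' standardises a table with given statistics (columns with zero SD are
#' centred and left unscaled, i.e. the SD is treated as 1);
#' `zscore_fit_apply()` does both in one call. The fold-safe pattern is to
#' fit on training subjects only and apply to held-out data; fitting on all
#' subjects reproduces the global-normalisation variant.
#'
#' @param table A feature table.
#' @param stats A `zscore_fit()` result.
#' @return `zscore_fit()`: a list with `mean`, `sd` vectors.
#'   `zscore_apply()`: the standardised table with attributes
#'   `normalization = "zscored"` and `zscore_stats`.
#' @export
zscore_fit <- function(table) {
  cols <- feature_columns(table)
  if (length(cols) == 0L) abort("No feature columns found.")
  X <- as.matrix(table[cols])
  list(mean = colMeans(X), sd = apply(X, 2L, stats::sd))
}

#' @rdname zscore_fit
#' @export
zscore_apply <- function(table, stats) {
  cols <- feature_columns(table)
  if (length(stats$mean) != length(cols) ||
      !identical(names(stats$mean), cols)) {
    abort("Normalisation statistics do not match the table's feature columns.")
  }
  sds <- ifelse(stats$sd > 0, stats$sd, 1)
  out <- table
  for (j in seq_along(cols)) {
    out[[cols[j]]] <- (out[[cols[j]]] - stats$mean[j]) / sds[j]
  }
  attr(out, "normalization") <- "zscored"
  attr(out, "zscore_stats") <- stats
  out
}

#' @rdname zscore_fit
#' @export
zscore_fit_apply <- function(table, stats = NULL) {
  if (is.null(stats)) stats <- zscore_fit(table)
  zscore_apply(table, stats)
}
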