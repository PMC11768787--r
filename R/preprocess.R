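#' Downsample a 200 Hz recording to 50 Hz with anti-aliasing
#'
#' Applies a fourth-order (5-tap, symmetric, zero-phase) moving-average
#' filter to each axis and keeps every 4th sample. The symmetric centred
#' FIR introduces no phase shift, so annotation times stay aligned. Edge
#' samples are handled by replicate-padding. Output length is
#' `floor(N / 4)`.
#'
#' @param rec A [recording()] at 200 Hz.
#' @return A [recording()] at 50 Hz.
#' @export
downsample <- function(rec) {
  if (rec_rate(rec) != 200) {
    abort(sprintf("downsample() expects a 200 Hz recording, got %g Hz.",
                  rec_rate(rec)),
          class = "pn_validation_error")
  }
  n <- nrow(rec)
  n_out <- floor(n / 4)
  if (n_out < 1L) abort("Recording too short to downsample.")
  idx <- seq(1L, by = 4L, length.out = n_out)
  ma5 <- function(x) {
    xp <- c(rep(x[1L], 2L), x, rep(x[n], 2L))
    as.numeric(stats::filter(xp, rep(1 / 5, 5L), sides = 2))[3L:(n + 2L)]
  }
  df <- tibble::tibble(time_s = rec$time_s[idx],
                       acc_x = ma5(rec$acc_x)[idx],
                       acc_y = ma5(rec$acc_y)[idx],
                       acc_z = ma5(rec$acc_z)[idx])
  recording(df, subject_id = rec_subject(rec), side = rec_side(rec),
            rate_hz = 50)
}

# Magnitude response of the 5-tap moving average at frequency f (Hz) for
# sampling rate fs; used by tests as the analytic oracle.
ma5_gain <- function(f, fs) {
  abs(sin(5 * pi * f / fs) / (5 * sin(pi * f / fs)))
}

#' l1 trend filtering
#'
#' Computes the piecewise-linear trend
#' \deqn{\hat t = \arg\min_t \tfrac12\|x - t\|_2^2 + \lambda \|D^{(2)} t\|_1}
#' where \eqn{D^{(2)}} is the second-difference operator. The l1 penalty on
#' second differences yields a continuous piecewise-linear fit whose kinks
#' appear only where the data demand them; subtracting the trend removes
#' gravity and slow orientation drift while preserving oscillatory content.
#'
#' Solved by a log-barrier interior-point method on the equivalent dual
#' box-constrained QP
#' \deqn{\min_\nu \tfrac12 \|D^\top \nu\|^2 - \nu^\top D x,\;
#'       \|\nu\|_\infty \le \lambda,}
#' with banded sparse Newton systems (the standard algorithm for this
#' problem; iteration counts are essentially independent of \eqn{\lambda}
#' and signal length). The primal trend is recovered as
#' \eqn{t = x - D^\top \nu}, followed by an exact active-set polish on the
#' identified kink pattern (kept only when it lowers the objective).
#'
#' @param x Numeric signal (length >= 3, finite).
#' @param lam Regularisation weight \eqn{\lambda \ge 0} (default 10000, the
#'   pipeline setting at 50 Hz).
#' @param gap_tol Relative duality-gap stopping tolerance.
#' @param max_newton Cap on total Newton steps.
#' @return The trend, a numeric vector like `x`, with attributes
#'   `objective` (primal objective per Newton step) and `iterations`.
#' @export
l1_trend_filter <- function(x, lam = 10000, gap_tol = 1e-10,
                            max_newton = 400L) {
  if (!all(is.finite(x))) abort("`x` must be finite.")
  n <- length(x)
  if (n < 3L) abort("`x` must have at least 3 samples.")
  if (lam < 0) abort("`lam` must be non-negative.")
  if (lam == 0) {
    out <- x
    attr(out, "objective") <- 0
    attr(out, "iterations") <- 0L
    return(out)
  }
  m <- n - 2L
  D <- Matrix::bandSparse(m, n, k = 0:2,
                          diagonals = list(rep(1, m), rep(-2, m), rep(1, m)))
  Dt <- Matrix::t(D)
  H <- Matrix::tcrossprod(D)            # pentadiagonal, SPD
  c0 <- as.numeric(D %*% x)
  nu <- numeric(m)
  Hnu <- numeric(m)
  # start with a duality gap on the scale of the objective at the OLS line
  i1 <- seq_len(n)
  line <- stats::lm.fit(cbind(1, i1), x)$fitted.values
  t_bar <- max(1, 2 * m / max(l1_objective(x, line, lam), 1e-8))
  obj_trace <- numeric(0L)
  primal_of <- function(nu) {
    t_hat <- x - as.numeric(Dt %*% nu)
    l1_objective(x, t_hat, lam)
  }
  barrier <- function(nu, Hnu) {
    t_bar * (0.5 * sum(nu * Hnu) - sum(c0 * nu)) -
      sum(log(lam - nu)) - sum(log(lam + nu))
  }
  steps <- 0L
  repeat {
    # Newton minimisation of the barrier objective at this t_bar
    for (newton in seq_len(60L)) {
      steps <- steps + 1L
      d1 <- 1 / (lam - nu)
      d2 <- 1 / (lam + nu)
      g <- t_bar * (Hnu - c0) + d1 - d2
      Hs <- t_bar * H + Matrix::Diagonal(m, d1^2 + d2^2)
      dnu <- as.numeric(Matrix::solve(Hs, -g))
      decrement <- sum(-g * dnu)
      s <- 1
      while (max(abs(nu + s * dnu)) >= lam) s <- s / 2
      f0 <- barrier(nu, Hnu)
      repeat {
        nu_try <- nu + s * dnu
        Hnu_try <- as.numeric(H %*% nu_try)
        if (barrier(nu_try, Hnu_try) <= f0 + 0.25 * s * sum(g * dnu) ||
            s < 1e-12) {
          break
        }
        s <- s / 2
      }
      nu <- nu_try
      Hnu <- Hnu_try
      obj_trace[steps] <- primal_of(nu)
      # decrement of the t_bar-scaled objective ~ t_bar * accuracy, so the
      # threshold tracks t_bar to keep a fixed accuracy in original units
      if (decrement / 2 < 1e-6 * t_bar || steps >= max_newton) break
    }
    gap <- 2 * m / t_bar
    scale <- max(abs(obj_trace[steps]), 1)
    if (gap < gap_tol * scale || steps >= max_newton) break
    t_bar <- t_bar * 50
  }
  t_hat <- x - as.numeric(Dt %*% nu)
  # Exact active-set polish on the kink pattern: free kinks keep the full
  # penalty weight of their sign, all other second differences are pinned
  # to zero; the KKT solution is exact when the pattern is right and is
  # kept only if it lowers the objective.
  d2t <- as.numeric(D %*% t_hat)
  act <- which(abs(nu) > lam * (1 - 1e-6) & abs(d2t) > 1e-10 * max(abs(d2t), 1e-30))
  t_pol <- tryCatch({
    rhs <- x
    if (length(act) > 0L) {
      rhs <- x - lam * as.numeric(Matrix::t(D[act, , drop = FALSE]) %*%
                                    sign(d2t[act]))
    }
    inact <- setdiff(seq_len(m), act)
    if (length(inact) == 0L) {
      rhs
    } else {
      Dc <- D[inact, , drop = FALSE]
      mu <- Matrix::solve(Matrix::tcrossprod(Dc), Dc %*% rhs)
      as.numeric(rhs - Matrix::t(Dc) %*% mu)
    }
  }, error = function(e) NULL)
  if (!is.null(t_pol) &&
      l1_objective(x, t_pol, lam) < l1_objective(x, t_hat, lam)) {
    t_hat <- t_pol
    obj_trace <- c(obj_trace, l1_objective(x, t_hat, lam))
  }
  out <- t_hat
  attr(out, "objective") <- obj_trace
  attr(out, "iterations") <- length(obj_trace)
  out
}

l1_objective <- function(x, t_hat, lam) {
  d2 <- diff(t_hat, differences = 2L)
  0.5 * sum((x - t_hat)^2) + lam * sum(abs(d2))
}

#' Remove orientation drift from a recording
#'
#' Applies [l1_trend_filter()] to each axis and subtracts the trend,
#' removing gravity and slow device-orientation changes while keeping the
#' oscillatory content used by the feature extractor.
#'
#' @param rec A [recording()] (typically 50 Hz, after [downsample()]).
#' @param lam Trend-filter regularisation (default 10000).
#' @param ... Passed to [l1_trend_filter()].
#' @return The detrended recording; the removed trend is stored in the
#'   `trend` attribute as an `n x 3` matrix.
#' @export
detrend_recording <- function(rec, lam = 10000, ...) {
  acc <- rec_matrix(rec)
  trend <- matrix(0, nrow(acc), 3L)
  for (j in 1:3) {
    tr <- l1_trend_filter(acc[, j], lam = lam, ...)
    trend[, j] <- as.numeric(tr)
  }
  out <- rec_replace_acc(rec, acc - trend)
  attr(out, "trend") <- trend
  out
}

# Penalised exact changepoint search (PELT) with a Gaussian mean+variance
# segment cost, C(seg) = m * log(max(sigma2_hat, var_floor)), computed in
# O(1) from cumulative sums. Returns 0-based changepoint sample indices.
pelt_meanvar <- function(x, penalty, min_len, var_floor = 1e-12) {
  n <- length(x)
  s1 <- c(0, cumsum(x))
  s2 <- c(0, cumsum(x^2))
  seg_cost <- function(s, t) {
    # segment (s+1):t, s and t 0-based boundary indices
    m <- t - s
    mu <- (s1[t + 1L] - s1[s + 1L]) / m
    sig2 <- (s2[t + 1L] - s2[s + 1L]) / m - mu^2
    m * log(pmax(sig2, var_floor))
  }
  F_cost <- rep(Inf, n + 1L)
  F_cost[1L] <- -penalty
  last_cp <- integer(n + 1L)
  cand <- 0L
  for (t in seq(min_len, n)) {
    ok <- cand[t - cand >= min_len]
    if (length(ok) == 0L) next
    vals <- F_cost[ok + 1L] + seg_cost(ok, t) + penalty
    best <- which.min(vals)
    F_cost[t + 1L] <- vals[best]
    last_cp[t + 1L] <- ok[best]
    # Prune: drop s that can never be optimal again.
    prunable <- ok[F_cost[ok + 1L] + seg_cost(ok, t) > F_cost[t + 1L]]
    cand <- c(setdiff(cand, prunable), t)
  }
  cps <- integer(0L)
  t <- n
  while (t > 0L) {
    s <- last_cp[t + 1L]
    if (s > 0L) cps <- c(s, cps)
    t <- s
  }
  cps
}

#' Segment a detrended recording into approximately stationary pieces
#'
#' Runs penalised changepoint detection (PELT, Gaussian mean+variance cost)
#' on the acceleration magnitude \eqn{\|a\|} and converts the changepoints
#' into non-overlapping segments of at least `min_len_s` seconds. Segments
#' shorter than `min_len_s` cannot arise (the minimum length is enforced
#' inside the search); a defensive merge step folds any residual short
#' segment into its more similar neighbour. The interface is pluggable:
#' pass a different `method` function to swap segmenters.
#'
#' @param rec A detrended [recording()] (50 Hz).
#' @param min_len_s Minimum segment length in seconds (default 2).
#' @param penalty Changepoint penalty; default `8 * log(n)` which keeps
#'   homogeneous noise unsplit while detecting activity-scale variance
#'   changes.
#' @param method Optional replacement segmenter,
#'   `function(magnitude, penalty, min_len_samples) -> integer changepoints`
#'   (0-based sample indices).
#' @return A tibble of segments with columns `subject_id`, `segment_id`,
#'   `start_s`, `end_s`.
#' @export
segment_stationary <- function(rec, min_len_s = 2, penalty = NULL,
                               method = NULL) {
  rate <- rec_rate(rec)
  n <- nrow(rec)
  if (n < min_len_s * rate) {
    abort("Recording shorter than the minimum segment length.",
          class = "pn_validation_error")
  }
  mag <- sqrt(rec$acc_x^2 + rec$acc_y^2 + rec$acc_z^2)
  if (is.null(penalty)) penalty <- 8 * log(n)
  min_len <- max(2L, ceiling(min_len_s * rate))
  segmenter <- method %||% pelt_meanvar
  cps <- segmenter(mag, penalty, min_len)
  bounds <- c(0L, cps, n)
  starts <- head(bounds, -1L)
  ends <- tail(bounds, -1L)
  # Defensive merge of sub-minimum segments into the neighbour with the
  # closer log-variance.
  repeat {
    lens <- ends - starts
    short <- which(lens < min_len)
    if (length(short) == 0L || length(starts) == 1L) break
    i <- short[1L]
    seg_var <- function(k) stats::var(mag[(starts[k] + 1L):ends[k]])
    merge_left <- i > 1L &&
      (i == length(starts) ||
         abs(log(seg_var(i) + 1e-12) - log(seg_var(i - 1L) + 1e-12)) <=
           abs(log(seg_var(i) + 1e-12) - log(seg_var(i + 1L) + 1e-12)))
    if (merge_left) {
      ends[i - 1L] <- ends[i]
    } else {
      starts[i + 1L] <- starts[i]
    }
    starts <- starts[-i]
    ends <- ends[-i]
  }
  t0 <- rec$time_s[1L]
  tibble::tibble(subject_id = rec_subject(rec),
                 segment_id = seq_along(starts),
                 start_s = t0 + starts / rate,
                 end_s = t0 + ends / rate)
}

#' Full per-recording preprocessing
#'
#' [downsample()] (200 -> 50 Hz), [detrend_recording()] (l1 trend filter,
#' lambda = 10000) and [segment_stationary()] in sequence.
#'
#' @param rec A 200 Hz [recording()].
#' @param lam Trend-filter regularisation.
#' @param ... Passed to [segment_stationary()].
#' @return A list with elements `recording` (50 Hz, detrended) and
#'   `segments`.
#' @export
preprocess_recording <- function(rec, lam = 10000, ...) {
  rec50 <- detrend_recording(downsample(rec), lam = lam)
  list(recording = rec50, segments = segment_stationary(rec50, ...))
}
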