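# Shared fixtures and independent oracles for the test suite.

# Small labelled feature table with arbitrary columns f1..fd: two Gaussian
# classes separated by `sep` along the all-ones direction.
make_toy_table <- function(n = 120, d = 6, sep = 4, seed = 1,
                           subjects = c("A", "B", "C")) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), each = n / 2)
    X <- matrix(rnorm(n * d), n, d) + outer(y, rep(sep / sqrt(d), d))
    tbl <- tibble::as_tibble(as.data.frame(X))
    names(tbl) <- paste0("f", seq_len(d))
    tbl$subject_id <- rep(subjects, length.out = n)
    tbl$label <- ifelse(y == 1L, "tremor", "non_tremor")
    tbl$sub_class <- ifelse(y == 1L, "T1", "N7")
    tbl$prototype <- TRUE
    tbl$excluded <- FALSE
    tbl
  })
}

# Minimal valid recording: tri-axial sinusoid + noise at the given rate.
make_sine_recording <- function(duration_s = 10, rate_hz = 200, freq = 5,
                                amp = 0.1, noise = 0.001, seed = 1,
                                subject_id = "T") {
  withr::with_seed(seed, {
    n <- duration_s * rate_hz
    t <- (seq_len(n) - 1) / rate_hz
    df <- tibble::tibble(
      time_s = t,
      acc_x = amp * sin(2 * pi * freq * t) + rnorm(n, 0, noise),
      acc_y = rnorm(n, 0, noise),
      acc_z = 1 + rnorm(n, 0, noise)
    )
    recording(df, subject_id = subject_id, side = "right", rate_hz = rate_hz)
  })
}

# Independent l1 trend filtering oracle: plain ADMM on the second-difference
# split (a different algorithm from the package's interior-point solver),
# followed by an exact equality-constrained solve on the kink support the
# ADMM iterate identifies (its z update is exactly sparse). Small
# instances only.
l1tf_admm_oracle <- function(x, lam, rho = NULL, iters = 20000L) {
  n <- length(x)
  m <- n - 2L
  D <- diff(diag(n), differences = 2L)
  DtD <- crossprod(D)
  rho <- rho %||% lam
  R <- chol(diag(n) + rho * DtD)
  z <- as.numeric(D %*% x)
  u <- numeric(m)
  t_hat <- x
  for (it in seq_len(iters)) {
    rhs <- x + rho * as.numeric(crossprod(D, z - u))
    t_hat <- backsolve(R, forwardsolve(t(R), rhs))
    Dt <- as.numeric(D %*% t_hat)
    z_old <- z
    z <- sign(Dt + u) * pmax(abs(Dt + u) - lam / rho, 0)
    u <- u + Dt - z
    if (it %% 500L == 0L) {
      r <- sqrt(sum((Dt - z)^2))
      s <- rho * sqrt(sum(as.numeric(crossprod(D, z - z_old))^2))
      if (r < 1e-11 * sqrt(m) && s < 1e-11 * sqrt(n)) break
    }
  }
  # exact solve for the identified support: fix the sign pattern of the
  # active kinks and pin every inactive second difference to zero
  act <- which(z != 0)
  rhs <- x
  if (length(act) > 0L) {
    rhs <- x - lam * as.numeric(t(D[act, , drop = FALSE]) %*% sign(z[act]))
  }
  inact <- setdiff(seq_len(m), act)
  t_exact <- if (length(inact) == 0L) {
    rhs
  } else {
    Dc <- D[inact, , drop = FALSE]
    mu <- solve(Dc %*% t(Dc), Dc %*% rhs)
    as.numeric(rhs - t(Dc) %*% mu)
  }
  if (l1tf_objective(x, t_exact, lam) < l1tf_objective(x, t_hat, lam)) {
    t_exact
  } else {
    t_hat
  }
}

# Objective of the l1 trend filtering problem.
l1tf_objective <- function(x, t_hat, lam) {
  0.5 * sum((x - t_hat)^2) + lam * sum(abs(diff(t_hat, differences = 2L)))
}

# Brute-force O(N^2) sample-entropy oracle with explicit loops.
sampen_bruteforce <- function(x, m = 2L, r = 0.2 * sd(x)) {
  n <- length(x)
  nt <- n - m
  countB <- 0L
  countA <- 0L
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      dB <- 0
      for (k in 0:(m - 1)) dB <- max(dB, abs(x[i + k] - x[j + k]))
      if (dB <= r) {
        countB <- countB + 1L
        dA <- max(dB, abs(x[i + m] - x[j + m]))
        if (dA <= r) countA <- countA + 1L
      }
    }
  }
  if (countA == 0L || countB == 0L) {
    return(-log(2 / ((n - m - 1) * (n - m))))
  }
  -log(countA / countB)
}

# Best assignment agreement between a clustering and planted labels (small
# K only; exhaustive permutation search).
cluster_agreement <- function(z, truth) {
  labs <- sort(unique(truth))
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- 0
  for (p in perms(labs)) {
    if (max(z) > length(p)) next
    m <- mean(p[z] == truth)
    if (!is.na(m) && m > best) best <- m
  }
  best
}

# Reduced synthetic study conditions used by the end-to-end tests and the
# acceptance script: small enough to run on one CPU, large enough to keep
# several training subjects per fold.
easy_eval_config <- function() {
  cfg <- difficulty_presets("easy")
  cfg$n_tremor <- 4
  cfg$n_pd_no_tremor <- 3
  cfg$n_control <- 3
  cfg$duration_s <- 360
  cfg
}

hard_eval_config <- function() {
  cfg <- difficulty_presets("hard")
  cfg$n_tremor <- 3
  cfg$n_pd_no_tremor <- 1
  cfg$n_control <- 2
  cfg$duration_s <- 300
  cfg
}

two_layer_eval_args <- function() {
  list(two_layer = list(max_iter = 100L))
}
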