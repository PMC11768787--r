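#' Diagonal Normal-inverse-Gamma prior
#'
#' Conjugate prior for a diagonal Gaussian component: per-dimension mean
#' `m0` with strength `kappa0`, and inverse-Gamma shape `a0` / scale `b0`
#' (per dimension) on the variances.
#'
#' @param m0 Prior mean vector.
#' @param kappa0 Prior mean strength (> 0).
#' @param a0 Inverse-Gamma shape (> 0).
#' @param b0 Inverse-Gamma scale vector (> 0), recycled to `length(m0)`.
#' @return A `pn_nig_prior` list.
#' @export
nig_prior <- function(m0, kappa0 = 0.01, a0 = 1, b0 = 1) {
  if (kappa0 <= 0 || a0 <= 0 || any(b0 <= 0)) {
    abort("NIG prior requires kappa0 > 0, a0 > 0, b0 > 0.")
  }
  structure(list(m0 = as.numeric(m0), kappa0 = kappa0, a0 = a0,
                 b0 = rep_len(as.numeric(b0), length(m0))),
            class = "pn_nig_prior")
}

# Sufficient statistics of a cluster: n, per-dim sum and sum of squares.
cluster_posterior <- function(prior, n, s1, s2) {
  kappa_n <- prior$kappa0 + n
  m_n <- (prior$kappa0 * prior$m0 + s1) / kappa_n
  a_n <- prior$a0 + n / 2
  xbar <- if (n > 0) s1 / n else prior$m0
  ss <- if (n > 0) pmax(s2 - n * xbar^2, 0) else 0
  b_n <- prior$b0 + 0.5 * ss +
    prior$kappa0 * n * (xbar - prior$m0)^2 / (2 * kappa_n)
  list(kappa_n = kappa_n, m_n = m_n, a_n = a_n, b_n = b_n)
}

# Log posterior-predictive density (product of per-dimension Student-t's)
# of every row of X under a cluster posterior. Vectorised over rows;
# written with explicit recycling (X is row-major-recycled via transpose)
# to keep this hot path allocation-light.
log_predictive <- function(X, post) {
  nu <- 2 * post$a_n
  s2 <- post$b_n * (post$kappa_n + 1) / (post$a_n * post$kappa_n)
  Xt <- t.default(X)                       # d x n: columns recycle per-dim
  Q <- (Xt - post$m_n)^2 / (nu * s2)
  const <- sum(lgamma((nu + 1) / 2) - lgamma(nu / 2) -
                 0.5 * log(nu * pi * s2))
  const - (nu + 1) / 2 * .colSums(log1p(Q), nrow(Q), ncol(Q))
}

# Per-dimension log marginal likelihood of a cluster's data under the NIG
# prior (analytic), used for the collapsed complete-data objective.
log_marginal <- function(prior, n, s1, s2) {
  if (n == 0) return(0)
  post <- cluster_posterior(prior, n, s1, s2)
  sum(lgamma(post$a_n) - lgamma(prior$a0) +
        prior$a0 * log(prior$b0) - post$a_n * log(post$b_n) +
        0.5 * (log(prior$kappa0) - log(post$kappa_n))) -
    (n * length(prior$m0) / 2) * log(2 * pi)
}

# Collapsed complete-data log posterior: CRP partition prior plus the
# product of per-cluster marginal likelihoods.
mapdp_objective <- function(X, z, prior, alpha) {
  n <- nrow(X)
  ks <- sort(unique(z))
  ll <- 0
  for (k in ks) {
    idx <- z == k
    nk <- sum(idx)
    ll <- ll + log_marginal(prior, nk, colSums(X[idx, , drop = FALSE]),
                            colSums(X[idx, , drop = FALSE]^2)) + lgamma(nk)
  }
  ll + length(ks) * log(alpha) + lgamma(alpha) - lgamma(alpha + n)
}

#' MAP inference for a diagonal-Gaussian Dirichlet process mixture
#'
#' Iterative maximum a posteriori assignment: each sweep scores every point
#' against the existing components' NIG posterior-predictive densities
#' (plus a `log` cluster-size term) and against a fresh cluster drawn from
#' the prior (paying `log(alpha)`), reassigns points, opens at most one new
#' cluster per sweep (seeded by the point that most prefers one), drops
#' emptied clusters and refreshes the component posteriors. Iterates to an
#' assignment fixed point, so the number of components K is inferred from
#' the data. Deterministic given data order and configuration.
#'
#' @param X Numeric matrix (rows = points).
#' @param prior A [nig_prior()]; defaults to a data-driven prior (pooled
#'   mean and variance, `kappa0 = 0.01`, `a0 = 1`).
#' @param alpha DP concentration (> 0).
#' @param max_sweeps Sweep cap (assignment fixed points occur much
#'   earlier in practice).
#' @param z_init Optional initial assignment vector (warm start, e.g. from
#'   the previous basis refresh during two-layer training).
#' @return A `pn_dpm_fit` list: `assignments`, `components` (tibble with
#'   per-component `mean`, `variance` list-columns and `n`), `K`, `alpha`,
#'   `logp` (collapsed complete-data log posterior), `objective_trace`.
#' @export
fit_mapdp <- function(X, prior = NULL, alpha = 1, max_sweeps = 100L,
                      z_init = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) abort("`X` must be finite.")
  if (alpha <= 0) abort("`alpha` must be positive.")
  n <- nrow(X)
  d <- ncol(X)
  if (is.null(prior)) {
    pooled_var <- pmax(apply(X, 2L, stats::var), 1e-6)
    if (n == 1L) pooled_var <- rep(1, d)
    prior <- nig_prior(colMeans(X), kappa0 = 0.01, a0 = 1, b0 = pooled_var)
  }
  # one assignment sweep against the current components; returns the new
  # assignment vector plus each point's best-existing score
  X2 <- X^2
  sweep_once <- function(z) {
    ks <- sort(unique(z))
    K <- length(ks)
    z <- match(z, ks)
    S1 <- rowsum(X, z)
    S2 <- rowsum(X2, z)
    nk <- tabulate(z, K)
    scores <- matrix(-Inf, n, K + 1L)
    for (k in seq_len(K)) {
      post <- cluster_posterior(prior, nk[k], S1[k, ], S2[k, ])
      scores[, k] <- log_predictive(X, post) + log(nk[k])
    }
    prior_post <- cluster_posterior(prior, 0, numeric(d), numeric(d))
    scores[, K + 1L] <- log_predictive(X, prior_post) + log(alpha)
    z_new <- max.col(scores, ties.method = "first")
    best_existing <- max.col(scores[, seq_len(K), drop = FALSE],
                             ties.method = "first")
    fit_score <- scores[cbind(seq_len(n), best_existing)]
    wants_new <- which(z_new == K + 1L)
    if (length(wants_new) > 0L) {
      # open one cluster per sweep, seeded by the strongest preference
      gain <- scores[wants_new, K + 1L] - fit_score[wants_new]
      opener <- wants_new[which.max(gain)]
      z_new[wants_new] <- best_existing[wants_new]
      z_new[opener] <- K + 1L
    }
    list(z = z_new, fit_score = fit_score)
  }
  sweeps_to_fixed_point <- function(z, cap = max_sweeps) {
    last_score <- NULL
    for (s in seq_len(cap)) {
      res <- sweep_once(z)
      last_score <- res$fit_score
      if (identical(res$z, z)) break
      z <- res$z
    }
    list(z = z, fit_score = last_score)
  }
  # Hill climbing on the collapsed complete-data log posterior with
  # objective-guarded split proposals: a plain assignment sweep rarely
  # escapes a single fitted wide component (no lone point improves the
  # objective by leaving, so a fresh cluster seeded by one point collapses
  # back). Each proposal therefore seeds a new cluster with the
  # worst-fitting point's local neighbourhood, runs sweeps to a fixed
  # point, and keeps the split only when the collapsed objective improves.
  z <- if (!is.null(z_init) && length(z_init) == n) {
    match(z_init, sort(unique(z_init)))
  } else {
    rep(1L, n)
  }
  fp <- sweeps_to_fixed_point(z)
  z <- fp$z
  trace <- mapdp_objective(X, z, prior, alpha)
  if (n > 2L) {
    for (round in seq_len(30L)) {
      # candidate openers: the worst-fitting point of every current cluster
      openers <- vapply(sort(unique(z)), function(k) {
        idx <- which(z == k)
        idx[which.min(fp$fit_score[idx])]
      }, integer(1L))
      openers <- head(openers[order(fp$fit_score[openers])], 3L)
      improved <- FALSE
      for (opener in openers) {
        dist2 <- rowSums(sweep(X, 2L, X[opener, ])^2)
        q <- min(max(3L, floor(sum(z == z[opener]) / 4)), n - 1L)
        seed_members <- order(dist2)[seq_len(q)]
        z_try <- z
        z_try[seed_members] <- max(z) + 1L
        fp_try <- sweeps_to_fixed_point(z_try, cap = 30L)
        obj_try <- mapdp_objective(X, fp_try$z, prior, alpha)
        if (obj_try > trace[length(trace)] + 1e-9) {
          z <- fp_try$z
          fp <- fp_try
          trace <- c(trace, obj_try)
          improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
  }
  ks <- sort(unique(z))
  z <- match(z, ks)
  comps <- lapply(seq_along(ks), function(k) {
    idx <- z == k
    post <- cluster_posterior(prior, sum(idx),
                              colSums(X[idx, , drop = FALSE]),
                              colSums(X[idx, , drop = FALSE]^2))
    tibble::tibble(component = k, n = sum(idx),
                   mean = list(post$m_n),
                   variance = list(post$b_n / (post$a_n + 1.5)))
  })
  structure(list(assignments = z,
                 components = dplyr::bind_rows(comps),
                 K = length(ks),
                 alpha = alpha,
                 prior = prior,
                 logp = trace[length(trace)],
                 objective_trace = trace),
            class = "pn_dpm_fit")
}

#' Unsupervised DPM hyperparameter selection
#'
#' Fits [fit_mapdp()] at every grid point and returns the fit maximising
#' the collapsed complete-data log posterior; ties break toward the
#' smallest `alpha`. The default grid is `alpha` in \{0.1, 1, 10\} crossed
#' with inverse-Gamma scales \{0.1, 1, 10\} times the pooled per-dimension
#' variance, with `m0` the pooled mean, `kappa0 = 0.01`, `a0 = 1`.
#'
#' @param X Numeric matrix.
#' @param alphas Candidate concentrations.
#' @param b0_scales Candidate multipliers of the pooled variance.
#' @param kappa0,a0 Fixed prior strength/shape.
#' @return The winning `pn_dpm_fit`, with the selected `alpha` and prior
#'   inside.
#' @export
select_dpm_hyperparameters <- function(X, alphas = c(0.1, 1, 10),
                                       b0_scales = c(0.1, 1, 10),
                                       kappa0 = 0.01, a0 = 1,
                                       z_init = NULL) {
  X <- as.matrix(X)
  if (length(alphas) == 0L || length(b0_scales) == 0L) {
    abort("Hyperparameter grid must be non-empty.")
  }
  pooled_var <- pmax(apply(X, 2L, stats::var), 1e-6)
  if (nrow(X) == 1L) pooled_var <- rep(1, ncol(X))
  m0 <- colMeans(X)
  best <- NULL
  best_key <- c(-Inf, Inf)
  for (a in sort(alphas)) {
    for (s in b0_scales) {
      prior <- nig_prior(m0, kappa0 = kappa0, a0 = a0, b0 = s * pooled_var)
      fit <- fit_mapdp(X, prior = prior, alpha = a, z_init = z_init)
      fit$b0_scale <- s
      better <- fit$logp > best_key[1L] + 1e-9 ||
        (abs(fit$logp - best_key[1L]) <= 1e-9 && a < best_key[2L])
      if (is.null(best) || better) {
        best <- fit
        best_key <- c(fit$logp, a)
      }
    }
  }
  best
}

# Merge components smaller than min_size into the nearest (Euclidean
# centre distance) retained component, then refresh posteriors.
enforce_min_component_size <- function(fit, X, min_size = 3L) {
  repeat {
    sizes <- fit$components$n
    if (all(sizes >= min_size) || length(sizes) <= 1L) return(fit)
    small <- which.min(sizes)
    centers <- do.call(rbind, fit$components$mean)
    dists <- sqrt(rowSums(sweep(centers, 2L, centers[small, ])^2))
    dists[small] <- Inf
    target <- which.min(dists)
    z <- fit$assignments
    z[z == small] <- target
    ks <- sort(unique(z))
    z <- match(z, ks)
    comps <- lapply(seq_along(ks), function(k) {
      idx <- z == k
      post <- cluster_posterior(fit$prior, sum(idx),
                                colSums(X[idx, , drop = FALSE]),
                                colSums(X[idx, , drop = FALSE]^2))
      tibble::tibble(component = k, n = sum(idx),
                     mean = list(post$m_n),
                     variance = list(post$b_n / (post$a_n + 1.5)))
    })
    fit$assignments <- z
    fit$components <- dplyr::bind_rows(comps)
    fit$K <- length(ks)
    fit$logp <- mapdp_objective(X, z, fit$prior, fit$alpha)
  }
}

#' Build the prototype basis set from a labelled feature table
#'
#' For each sub-class with data, fits a MAP Dirichlet-process mixture
#' (with unsupervised hyperparameter selection) and turns every mixture
#' component into one RBF prototype basis: centre = component mean, scale
#' = component diagonal variance. Tremor sub-classes (`T1`..`T7`) use only
#' prototype-flagged windows; non-tremor sub-classes (`N1`..`N7`) use all
#' windows of the sub-class. The total basis count is
#' \eqn{K = \sum_\lambda K^{(\lambda)}}. Sub-classes without rows are
#' skipped (recorded in the `skipped` attribute).
#'
#' @param table Labelled feature table (z-scored for the single-layer
#'   model; embedded coordinates for the second layer of the two-layer
#'   model).
#' @param cols Feature columns to cluster on; defaults to the 45 canonical
#'   feature columns present in `table`.
#' @param min_component_size Components smaller than this merge into their
#'   nearest neighbour (avoids singular Mahalanobis scales).
#' @param hyper_grid Named list of arguments forwarded to
#'   [select_dpm_hyperparameters()].
#' @param hyper_selected Optional named list (`sub_class` ->
#'   `c(alpha, b0_scale)`) pinning the hyperparameters per sub-class
#'   (skips the grid; used when refreshing second-layer bases during
#'   two-layer training).
#' @param warm_assignments Optional named list (`sub_class` -> assignment
#'   vector) warm-starting each sub-class's DPM.
#' @param scale_floor_frac Per-dimension basis scales are floored at this
#'   fraction of the sub-class's pooled variance. Tight single-subject
#'   clusters otherwise produce near-singular Mahalanobis metrics whose
#'   activations vanish for every other subject's windows; the floor keeps
#'   the bases informative across subjects while leaving well-spread
#'   component scales untouched.
#' @return A `pn_basis_set`: tibble with columns `sub_class`, `class`,
#'   `component`, `n` and list-columns `center`, `scale`; attributes `K`,
#'   `Lambda`, `skipped`.
#' @export
build_basis_set <- function(table, cols = NULL, min_component_size = 3L,
                            hyper_grid = list(), hyper_selected = NULL,
                            warm_assignments = NULL, scale_floor_frac = 1) {
  cols <- cols %||% feature_columns(table)
  if (length(cols) == 0L) abort("No feature columns found.")
  if (!"excluded" %in% names(table)) table$excluded <- FALSE
  if (!"prototype" %in% names(table)) table$prototype <- FALSE
  groups <- list()
  for (sc in tremor_sub_classes()) {
    rows <- table[!table$excluded & table$sub_class == sc & table$prototype &
                    table$label == "tremor", , drop = FALSE]
    groups[[sc]] <- list(rows = rows, class = "tremor")
  }
  for (sc in non_tremor_sub_classes()) {
    rows <- table[!table$excluded & table$sub_class == sc &
                    table$label == "non_tremor", , drop = FALSE]
    groups[[sc]] <- list(rows = rows, class = "non_tremor")
  }
  bases <- list()
  selected <- list()
  assignments <- list()
  skipped <- character(0L)
  for (sc in names(groups)) {
    rows <- groups[[sc]]$rows
    if (nrow(rows) == 0L) {
      skipped <- c(skipped, sc)
      next
    }
    X <- as.matrix(rows[cols])
    args <- hyper_grid
    if (!is.null(hyper_selected) && sc %in% names(hyper_selected)) {
      args$alphas <- hyper_selected[[sc]][1L]
      args$b0_scales <- hyper_selected[[sc]][2L]
    }
    if (!is.null(warm_assignments) && sc %in% names(warm_assignments)) {
      args$z_init <- warm_assignments[[sc]]
    }
    fit <- do.call(select_dpm_hyperparameters, c(list(X = X), args))
    fit <- enforce_min_component_size(fit, X, min_size = min_component_size)
    selected[[sc]] <- c(fit$alpha, fit$b0_scale)
    assignments[[sc]] <- fit$assignments
    comp <- fit$components
    floor_vec <- scale_floor_frac * pmax(apply(X, 2L, stats::var), 1e-8)
    if (nrow(X) == 1L) floor_vec <- rep(1e-8, ncol(X))
    bases[[sc]] <- tibble::tibble(
      sub_class = sc,
      class = groups[[sc]]$class,
      component = comp$component,
      n = comp$n,
      center = comp$mean,
      scale = lapply(comp$variance, function(v) pmax(v, floor_vec, 1e-8))
    )
  }
  if (length(bases) == 0L) {
    abort("All sub-classes are empty; cannot build a basis set.")
  }
  out <- dplyr::bind_rows(bases)
  if (length(skipped) > 0L) {
    warn(sprintf("No rows for sub-class(es): %s; skipped.",
                 paste(skipped, collapse = ", ")))
  }
  structure(out,
            class = c("pn_basis_set", class(out)),
            K = nrow(out),
            Lambda = length(unique(out$sub_class)),
            cols = cols,
            hyper_selected = selected,
            assignments = assignments,
            skipped = skipped)
}

#' @export
print.pn_basis_set <- function(x, ...) {
  cat(sprintf("<basis set> K = %d bases over %d sub-classes (dim %d)\n",
              attr(x, "K"), attr(x, "Lambda"), length(x$center[[1L]])))
  NextMethod()
}
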