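#' Gaussian RBF activation with Mahalanobis distance
#'
#' \eqn{d(x, c) = \sqrt{\sum_j (x_j - c_j)^2 / s_j}} with the basis's
#' diagonal scale (variance) vector \eqn{s}, and activation
#' \eqn{\rho = \exp(-d^2 / 2)}, bounded in (0, 1\] and equal to 1 exactly
#' at the centre. With unit scales this reduces to the Euclidean Gaussian
#' kernel \eqn{\exp(-\|x - c\|^2 / 2)}.
#'
#' @param x Input vector.
#' @param center Basis centre (same length as `x`).
#' @param scale Diagonal scale (variance) vector, positive.
#' @return Scalar activation in (0, 1].
#' @export
rbf_activation <- function(x, center, scale) {
  if (length(x) != length(center) || length(center) != length(scale)) {
    abort("`x`, `center` and `scale` must have the same length.")
  }
  d2 <- sum((x - center)^2 / scale)
  exp(-d2 / 2)
}

# Activation design matrix Phi (N x K) of rows of X against K bases given
# as a centre matrix and a scale matrix (rows = bases). The squared
# Mahalanobis distances expand into two matrix products:
# d2[n,k] = sum_j x_nj^2 / s_kj - 2 sum_j x_nj c_kj / s_kj + sum_j c_kj^2 / s_kj.
rbf_design <- function(X, centers, scales) {
  Sinv <- 1 / scales
  CS <- centers * Sinv
  d2 <- X^2 %*% t.default(Sinv) - 2 * X %*% t.default(CS) +
    rep(rowSums(centers * CS), each = nrow(X))
  d2[d2 < 0] <- 0   # guard tiny negative round-off
  # clamp away from exact 0 so activations stay in (0, 1] under underflow
  Phi <- pmax(exp(-d2 / 2), 1e-300)
  stopifnot(all(Phi <= 1 + 1e-12))
  Phi
}

basis_matrices <- function(basis_set) {
  list(centers = do.call(rbind, basis_set$center),
       scales = do.call(rbind, basis_set$scale))
}

#' Binary cross-entropy loss
#'
#' \eqn{E = -\frac1N \sum_n [y_n \log \hat y_n + (1-y_n)\log(1-\hat y_n)]}
#' with predictions clipped to \[1e-12, 1 - 1e-12\].
#'
#' @param y 0/1 labels.
#' @param y_hat Predicted probabilities of the positive class.
#' @return Scalar loss.
#' @export
loss_cross_entropy <- function(y, y_hat) {
  y_hat <- clip_prob(y_hat)
  -mean(y * log(y_hat) + (1 - y) * log(1 - y_hat))
}

#' Forward pass of the single-layer prototypical network
#'
#' Computes the RBF activations of the inputs against the prototype bases
#' and maps the linear superposition through the output non-linearity. The
#' two-class softmax output layer over (non-tremor, tremor) scores is
#' mathematically a logistic function of the score difference, which is
#' how it is computed.
#'
#' @param X Numeric matrix of (normalised) feature rows.
#' @param model A fitted `pn_rbf_single`.
#' @return Vector of tremor-class probabilities.
#' @export
forward_single <- function(X, model) {
  Phi <- rbf_design(as.matrix(X), model$centers, model$scales)
  score <- drop(model$intercept + Phi %*% model$weights)
  1 / (1 + exp(-score))
}

#' Fit the single-layer prototypical RBF network
#'
#' The basis parameters come from the per-sub-class DPM summaries
#' ([build_basis_set()]); this step fits the l2-regularised logistic
#' weights on the basis activations of the training windows.
#'
#' @param table Normalised, labelled feature table (training rows).
#' @param basis_set A `pn_basis_set` built on the same feature space.
#' @param reg l2 penalty passed to [glmnet::glmnet()] as `lambda`.
#' @return A `pn_rbf_single` model (decision threshold unset).
#' @export
train_single_layer <- function(table, basis_set, reg = 1e-3) {
  cols <- attr(basis_set, "cols")
  X <- as.matrix(table[cols])
  y <- as.integer(table$label == "tremor")
  if (length(unique(y)) < 2L) {
    abort("Training labels must contain both classes.")
  }
  bm <- basis_matrices(basis_set)
  Phi <- rbf_design(X, bm$centers, bm$scales)
  fit <- glmnet::glmnet(Phi, factor(y, levels = c(0, 1)), family = "binomial",
                        alpha = 0, lambda = reg, standardize = FALSE,
                        thresh = 1e-10)
  structure(list(basis_set = basis_set,
                 centers = bm$centers,
                 scales = bm$scales,
                 cols = cols,
                 weights = as.numeric(fit$beta),
                 intercept = as.numeric(fit$a0),
                 reg = reg,
                 threshold = NA_real_),
            class = "pn_rbf_single")
}

#' @export
print.pn_rbf_single <- function(x, ...) {
  cat(sprintf("<single-layer prototypical RBF> K = %d bases, threshold %s\n",
              nrow(x$centers),
              ifelse(is.na(x$threshold), "unset", sprintf("%.3f", x$threshold))))
  invisible(x)
}

#' Select first-layer inducing points
#'
#' Greedy deterministic selection of `K1` inducing points by maximal
#' Gaussian-process posterior variance under an isotropic Gaussian kernel
#' (an informative-vector-machine style coverage criterion): each step
#' picks the candidate about which the currently selected set is least
#' informative, so duplicated rows are never picked twice while distinct
#' candidates remain. The shared isotropic first-layer scale is
#' `s1 = (s1_scale * median pairwise distance of the selected points)^2`.
#'
#' @param X Numeric matrix of training rows.
#' @param K1 Number of inducing points (1 <= K1 <= N).
#' @param lengthscale Kernel lengthscale; default the median pairwise
#'   distance of (a deterministic subsample of) `X`.
#' @param s1_scale Multiplier converting the selected-set median distance
#'   into the (small) first-layer basis scale.
#' @return List with `centers` (K1 x D), `s1` (scalar variance), `idx`.
#' @export
select_inducing_points <- function(X, K1, lengthscale = NULL, s1_scale = 0.5) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (K1 < 1L || K1 > N) abort("`K1` must satisfy 1 <= K1 <= N.")
  if (is.null(lengthscale)) {
    sub <- X[seq(1L, N, length.out = min(N, 400L)), , drop = FALSE]
    dm <- stats::dist(sub)
    lengthscale <- stats::median(dm)
    if (!is.finite(lengthscale) || lengthscale <= 0) lengthscale <- 1
  }
  kern <- function(A, b) {
    exp(-rowSums(sweep(A, 2L, b)^2) / (2 * lengthscale^2))
  }
  v <- rep(1, N)          # prior variance (unit-diagonal kernel)
  Q <- matrix(0, N, K1)   # whitened cross-covariances to selected points
  idx <- integer(K1)
  for (m in seq_len(K1)) {
    j <- which.max(v)
    idx[m] <- j
    kj <- kern(X, X[j, ])
    qm <- if (m == 1L) kj else kj - Q[, 1:(m - 1L), drop = FALSE] %*% Q[j, 1:(m - 1L)]
    qm <- drop(qm) / sqrt(max(v[j], 1e-12))
    Q[, m] <- qm
    v <- pmax(v - qm^2, 0)
    v[idx[1:m]] <- -Inf   # never reselect
  }
  centers <- X[idx, , drop = FALSE]
  med <- if (K1 > 1L) stats::median(stats::dist(centers)) else lengthscale
  if (!is.finite(med) || med <= 0) med <- lengthscale
  list(centers = centers, s1 = (s1_scale * med)^2, idx = idx)
}

# Second-layer design + forward pass of a two-layer model given embeddings.
two_layer_forward <- function(X_star, model) {
  Phi2 <- rbf_design(X_star, model$C2_centers, model$C2_scales)
  S <- cbind(Phi2, 1) %*% model$W2
  Yhat <- softmax_rows(S)
  list(Phi2 = Phi2, Yhat = Yhat, prob = Yhat[, 2L])
}

#' Gradient of the cross-entropy loss with respect to the embeddings
#'
#' Closed-form chain rule through the second-layer Gaussian/Mahalanobis
#' bases: with \eqn{G = \partial E / \partial \Phi^{(2)}} and
#' \eqn{\Phi^{(2)}_{nk} = \exp(-d^2(x^*_n, c_k)/2)},
#' \eqn{\partial E/\partial x^*_{nj} = \sum_k G_{nk} \Phi^{(2)}_{nk}
#' (c_{kj} - x^*_{nj}) / s_{kj}}.
#'
#' @param X_star N x M embedding matrix.
#' @param y 0/1 labels.
#' @param model Two-layer model (supplies second-layer bases and weights).
#' @return N x M gradient matrix.
#' @export
embedding_gradient <- function(X_star, y, model) {
  N <- nrow(X_star)
  fw <- two_layer_forward(X_star, model)
  Y <- cbind(1 - y, y)
  dS <- (fw$Yhat - Y) / N                       # N x 2
  G <- dS %*% t(model$W2[seq_len(ncol(fw$Phi2)), , drop = FALSE])  # N x K2
  T_mat <- G * fw$Phi2
  Sinv <- 1 / model$C2_scales                   # K2 x M
  T_mat %*% (model$C2_centers * Sinv) - X_star * (T_mat %*% Sinv)
}

# Fit the second-layer prototype bases by per-sub-class DPMs on the
# prototype rows mapped into the embedding space.
fit_second_layer_bases <- function(X_star, meta, hyper_grid = list(),
                                   hyper_selected = NULL,
                                   warm_assignments = NULL) {
  emb_cols <- paste0("emb_", seq_len(ncol(X_star)))
  emb_tbl <- tibble::as_tibble(as.data.frame(X_star))
  names(emb_tbl) <- emb_cols
  tbl <- dplyr::bind_cols(meta, emb_tbl)
  suppressWarnings(
    build_basis_set(tbl, cols = emb_cols, hyper_grid = hyper_grid,
                    hyper_selected = hyper_selected,
                    warm_assignments = warm_assignments)
  )
}

#' Initialise the two-layer prototypical RBF network
#'
#' First-layer inducing points come from [select_inducing_points()]; the
#' initial embeddings are the PCA projection of the inputs onto the first
#' `M` principal components estimated from the inducing points; the first
#' layer weights follow as the least-squares (pseudo-inverse) fit of the
#' first-layer activations to those embeddings; second-layer bases are the
#' DPM summaries of the prototype rows in the embedding space; the
#' second-layer weights are seeded standard-normal draws.
#'
#' @param table Normalised, labelled feature table (training rows).
#' @param M Embedding dimensionality (default 15).
#' @param K1 Number of inducing points (default 40, capped at N).
#' @param s1_scale First-layer scale multiplier (see
#'   [select_inducing_points()]).
#' @param seed Seed for the `W2` initialisation.
#' @param hyper_grid DPM hyperparameter grid for the second-layer bases.
#' @param cols Feature columns; defaults to the canonical 45.
#' @return A list `(model, state)`: the untrained `pn_rbf_two_layer` and a
#'   training state with `X_star`, `Phi1`, `y`, `meta`.
#' @export
init_two_layer <- function(table, M = 15L, K1 = 40L, s1_scale = 0.5,
                           seed = 1L, hyper_grid = list(), cols = NULL) {
  cols <- cols %||% feature_columns(table)
  X <- as.matrix(table[cols])
  D <- ncol(X)
  if (M >= D) abort("Embedding dimension `M` must be smaller than the input dimension.")
  y <- as.integer(table$label == "tremor")
  K1 <- min(K1, nrow(X))
  ind <- select_inducing_points(X, K1, s1_scale = s1_scale)
  pca <- stats::prcomp(ind$centers, center = TRUE, scale. = FALSE)
  n_pc <- min(M, ncol(pca$rotation))
  proj <- pca$rotation[, seq_len(n_pc), drop = FALSE]
  X_star0 <- sweep(X, 2L, pca$center) %*% proj
  if (n_pc < M) {
    X_star0 <- cbind(X_star0, matrix(0, nrow(X), M - n_pc))
  }
  Phi1 <- rbf_design(X, ind$centers, matrix(ind$s1, K1, D))
  W1 <- pinv_solve(Phi1, X_star0)
  X_star <- Phi1 %*% W1
  meta <- table[intersect(c("subject_id", "label", "sub_class", "prototype",
                            "excluded"), names(table))]
  basis2 <- fit_second_layer_bases(X_star, meta, hyper_grid)
  bm2 <- basis_matrices(basis2)
  K2 <- nrow(bm2$centers)
  W2 <- with_seed(seed, matrix(rnorm((K2 + 1L) * 2L), K2 + 1L, 2L))
  model <- structure(list(C1 = ind$centers, s1 = ind$s1,
                          W1 = W1,
                          C2 = basis2,
                          C2_centers = bm2$centers,
                          C2_scales = bm2$scales,
                          W2 = W2,
                          M = M, D = D, cols = cols,
                          threshold = NA_real_,
                          config = list(K1 = K1, s1_scale = s1_scale,
                                        seed = seed)),
                     class = "pn_rbf_two_layer")
  list(model = model,
       state = list(X_star = X_star, X_star0 = X_star0, Phi1 = Phi1, y = y,
                    meta = meta))
}

#' Train the two-layer prototypical RBF network
#'
#' The alternating scheme sidesteps vanishing gradients in stacked RBF
#' layers by optimising the internal embeddings directly. Each iteration:
#' (1) a gradient step moves the embeddings `X*` downhill on the
#' cross-entropy loss; (2) the first-layer weights are refitted as the
#' least-squares (pseudo-inverse) map from the fixed first-layer
#' activations onto the updated `X*`; (3) the embeddings are recomputed
#' through the updated first layer, every `refresh_every` iterations the
#' second-layer prototype bases are refitted by DPMs on the prototype rows
#' in the new embedding space, and the second-layer weights take a
#' gradient step `W2 <- W2 - eta/N * t(Phi2a) (Yhat - Y)`. The learning
#' rate halves whenever a proposed iteration increases the loss (the
#' iteration is rolled back), so the accepted loss trajectory is
#' non-increasing; training stops when the relative loss change drops
#' below `tol` or at `max_iter`.
#'
#' @param table Normalised, labelled feature table of training windows.
#' @param M,K1,s1_scale,seed,hyper_grid,cols Passed to [init_two_layer()].
#' @param eta Initial learning rate for the embedding and `W2` steps.
#' @param tol Relative loss-change stopping tolerance.
#' @param max_iter Iteration cap.
#' @param refresh_every Second-layer basis refresh cadence (iterations).
#' @return A fitted `pn_rbf_two_layer` with a `history` element (loss per
#'   accepted iteration); the decision threshold is left unset.
#' @export
train_two_layer <- function(table, M = 15L, K1 = 40L, s1_scale = 0.5,
                            eta = 0.05, tol = 1e-5, max_iter = 500L,
                            refresh_every = 10L, seed = 1L,
                            hyper_grid = list(), cols = NULL) {
  if (length(unique(table$label)) < 2L) {
    abort("Training labels must contain both classes.")
  }
  init <- init_two_layer(table, M = M, K1 = K1, s1_scale = s1_scale,
                         seed = seed, hyper_grid = hyper_grid, cols = cols)
  model <- init$model
  state <- init$state
  y <- state$y
  Y <- cbind(1 - y, y)
  N <- length(y)
  loss_of <- function(X_star, model) {
    fw <- two_layer_forward(X_star, model)
    loss_cross_entropy(y, fw$prob)
  }
  E_prev <- loss_of(state$X_star, model)
  E0 <- E_prev
  history <- E_prev
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    if (it %% refresh_every == 0L) {
      # Refresh the second-layer bases on the prototype rows in the
      # current embedding space (hyperparameters pinned to the values
      # selected at initialisation). The refresh is made approximately
      # function-preserving: W2 is refitted by least squares so the new
      # bases reproduce the pre-refresh scores. It is a
      # re-parameterisation, not a descent step, so it is accepted
      # unconditionally and the loss baseline is reset.
      S_old <- cbind(two_layer_forward(state$X_star, model)$Phi2, 1) %*%
        model$W2
      basis2 <- fit_second_layer_bases(
        state$X_star, state$meta,
        hyper_selected = attr(model$C2, "hyper_selected"),
        warm_assignments = attr(model$C2, "assignments"))
      bm2 <- basis_matrices(basis2)
      model$C2 <- basis2
      model$C2_centers <- bm2$centers
      model$C2_scales <- bm2$scales
      Phi2_new <- rbf_design(state$X_star, bm2$centers, bm2$scales)
      model$W2 <- pinv_solve(cbind(Phi2_new, 1), S_old)
      E_prev <- loss_of(state$X_star, model)
    }
    snapshot <- list(model = model, X_star = state$X_star, eta = eta)
    accepted <- FALSE
    for (try in 1:30) {
      # (1) embedding gradient step
      g <- embedding_gradient(state$X_star, y, model)
      X_star_new <- state$X_star - eta * g
      # (2) least-squares refit of W1 via the pseudo-inverse
      model$W1 <- pinv_solve(state$Phi1, X_star_new)
      # (3) recompute embeddings through the updated first layer, then
      #     step the second-layer weights
      X_star_new <- state$Phi1 %*% model$W1
      fw <- two_layer_forward(X_star_new, model)
      # Damped Newton (IRLS) step for the second-layer weights: the raw
      # cross-entropy gradient (1/N) Phi2a' (Yhat - Y) is preconditioned
      # by the softmax curvature, which copes with the very uneven column
      # scales of sparse prototype activations; eta damps the step and the
      # backoff below guards it. Only the column difference of W2 affects
      # the softmax, so the step is applied antisymmetrically.
      A <- cbind(fw$Phi2, 1)
      p_hat <- fw$Yhat[, 2L]
      grad_w <- crossprod(A, p_hat - y) / N
      r_w <- pmax(p_hat * (1 - p_hat), 1e-6)
      H_w <- crossprod(A, A * r_w) / N
      diag(H_w) <- diag(H_w) + 1e-6
      delta <- solve(H_w, grad_w)
      model$W2[, 2L] <- model$W2[, 2L] - eta * delta / 2
      model$W2[, 1L] <- model$W2[, 1L] + eta * delta / 2
      E_new <- loss_of(X_star_new, model)
      if (eta == 0 || E_new <= E_prev + 1e-12) {
        accepted <- TRUE
        state$X_star <- X_star_new
        break
      }
      # roll back and halve the learning rate
      model <- snapshot$model
      eta <- eta / 2
      if (eta < 1e-8) break
    }
    if (!accepted) break
    if (E_new > 10 * E0) {
      abort(sprintf(
        "Two-layer training diverged (loss %.3g vs initial %.3g).",
        E_new, E0))
    }
    history <- c(history, E_new)
    dE <- abs(E_prev - E_new) / max(E_prev, 1e-12)
    E_prev <- E_new
    if (dE < tol) break
  }
  model$history <- history
  model$iterations <- it
  model$eta_final <- eta
  model
}

#' @export
print.pn_rbf_two_layer <- function(x, ...) {
  cat(sprintf(
    "<two-layer prototypical RBF> K1 = %d inducing points -> M = %d, K2 = %d prototype bases\n",
    nrow(x$C1), x$M, nrow(x$C2_centers)))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d iterations, loss %.4f -> %.4f\n",
                length(x$history) - 1L, x$history[1L],
                x$history[length(x$history)]))
  }
  invisible(x)
}

# Embed new (normalised) feature rows through the first layer.
embed_two_layer <- function(model, X) {
  Phi1 <- rbf_design(as.matrix(X), model$C1,
                     matrix(model$s1, nrow(model$C1), model$D))
  Phi1 %*% model$W1
}

#' Predict tremor probabilities
#'
#' Single dispatch over both prototypical network types. Input must be
#' normalised with the same z-score statistics as the training table.
#'
#' @param object A fitted `pn_rbf_single` or `pn_rbf_two_layer`.
#' @param newdata Feature table or matrix.
#' @param type `"prob"` for probabilities, `"class"` for thresholded 0/1
#'   labels (threshold 0.5 when unset).
#' @param ... Unused.
#' @return Numeric vector of probabilities or integer labels.
#' @export
predict.pn_rbf_single <- function(object, newdata, type = c("prob", "class"),
                                  ...) {
  type <- match.arg(type)
  X <- if (is.matrix(newdata)) newdata else as.matrix(newdata[object$cols])
  p <- forward_single(X, object)
  if (type == "prob") return(p)
  thr <- if (is.na(object$threshold)) 0.5 else object$threshold
  as.integer(p >= thr)
}

#' @rdname predict.pn_rbf_single
#' @export
predict.pn_rbf_two_layer <- function(object, newdata,
                                     type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- if (is.matrix(newdata)) newdata else as.matrix(newdata[object$cols])
  X_star <- embed_two_layer(object, X)
  p <- two_layer_forward(X_star, object)$prob
  if (type == "prob") return(p)
  thr <- if (is.na(object$threshold)) 0.5 else object$threshold
  as.integer(p >= thr)
}
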