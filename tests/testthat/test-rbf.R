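test_that("the Gaussian/Mahalanobis activation matches a loop oracle", {
  set.seed(1)
  for (i in 1:5) {
    x <- rnorm(45)
    cen <- rnorm(45)
    sc <- runif(45, 0.2, 3)
    d2 <- 0
    for (j in 1:45) d2 <- d2 + (x[j] - cen[j])^2 / sc[j]
    expect_equal(rbf_activation(x, cen, sc), exp(-d2 / 2),
                 tolerance = 1e-12)
  }
  x <- rnorm(10)
  expect_equal(rbf_activation(x, x, runif(10, 0.5, 2)), 1)
  # unit scales reduce to the Euclidean Gaussian kernel
  cen <- rnorm(10)
  expect_equal(rbf_activation(x, cen, rep(1, 10)),
               exp(-sum((x - cen)^2) / 2), tolerance = 1e-12)
  expect_error(rbf_activation(x, cen[1:5], rep(1, 10)), regexp = "length")
})

test_that("activations always lie in (0, 1]", {
  set.seed(2)
  X <- matrix(rnorm(600, sd = 20), 60, 10)
  C <- matrix(rnorm(50), 5, 10)
  S <- matrix(runif(50, 0.01, 1), 5, 10)
  Phi <- protonet:::rbf_design(X, C, S)
  expect_true(all(Phi > 0))
  expect_true(all(Phi <= 1))
})

test_that("the single-layer forward pass is score-then-sigmoid", {
  toy <- make_toy_table(n = 80, d = 5, seed = 4)
  basis <- suppressWarnings(build_basis_set(toy, cols = paste0("f", 1:5)))
  model <- train_single_layer(toy, basis)
  X <- as.matrix(toy[paste0("f", 1:5)])
  p <- forward_single(X, model)
  # independent two-line recomputation
  bm <- protonet:::basis_matrices(basis)
  Phi <- protonet:::rbf_design(X, bm$centers, bm$scales)
  p2 <- 1 / (1 + exp(-(model$intercept + Phi %*% model$weights)))
  expect_equal(p, drop(p2), tolerance = 1e-12)

  # zero weights give probability 1/2 everywhere
  m0 <- model
  m0$weights[] <- 0
  m0$intercept <- 0
  expect_true(all(forward_single(X, m0) == 0.5))

  # a huge positive weight saturates towards 1 at the basis centre
  m1 <- m0
  m1$weights[1] <- 50
  expect_gt(forward_single(matrix(bm$centers[1, ], 1), m1), 0.999)
})

test_that("single-layer training separates, flips, and shrinks correctly", {
  toy <- make_toy_table(n = 120, d = 6, sep = 4, seed = 4)
  basis <- suppressWarnings(build_basis_set(toy, cols = paste0("f", 1:6)))
  model <- train_single_layer(toy, basis)
  y <- as.integer(toy$label == "tremor")
  expect_gte(auroc(predict(model, toy), y), 0.99)

  # flipped labels negate the weights (same basis set)
  flipped <- toy
  flipped$label <- ifelse(toy$label == "tremor", "non_tremor", "tremor")
  m2 <- train_single_layer(flipped, basis)
  expect_equal(m2$weights, -model$weights, tolerance = 1e-6)

  # heavy regularisation collapses to the class prior via the intercept
  m3 <- train_single_layer(toy, basis, reg = 1e6)
  p3 <- predict(m3, toy)
  expect_lt(max(p3) - min(p3), 1e-3)
  expect_equal(mean(p3), mean(y), tolerance = 0.01)

  one_class <- toy[toy$label == "tremor", ]
  expect_error(train_single_layer(one_class, basis), regexp = "both classes")
})

test_that("inducing-point selection covers structure without duplicates", {
  set.seed(3)
  X <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
             matrix(rnorm(40, 10, 0.1), 20, 2))
  ip <- select_inducing_points(X, 2)
  expect_true((ip$idx[1] <= 20) != (ip$idx[2] <= 20))
  expect_gt(ip$s1, 0)

  expect_equal(sort(select_inducing_points(X, nrow(X))$idx), 1:40)
  expect_error(select_inducing_points(X, 41), regexp = "K1")

  Xdup <- rbind(X, X[1, , drop = FALSE])
  ipd <- select_inducing_points(Xdup, 5)
  expect_false(any(duplicated(Xdup[ipd$idx, ])))
})

test_that("two-layer initialisation follows PCA + least squares + seed", {
  # data living in a 3-dim principal subspace of R^10 is recovered
  set.seed(6)
  B <- qr.Q(qr(matrix(rnorm(100), 10, 10)))[, 1:3]
  Z <- matrix(rnorm(450), 150, 3) %*% diag(c(4, 2, 1))
  tbl <- tibble::as_tibble(as.data.frame(Z %*% t(B)))
  names(tbl) <- paste0("f", 1:10)
  tbl$subject_id <- "A"
  tbl$label <- rep(c("tremor", "non_tremor"), 75)
  tbl$sub_class <- rep(c("T1", "N7"), 75)
  tbl$prototype <- TRUE
  tbl$excluded <- FALSE
  init <- init_two_layer(tbl, M = 3, K1 = 60, cols = paste0("f", 1:10))
  # the initial PCA embedding spans the planted subspace exactly
  Q <- qr.Q(qr(cbind(1, Z)))   # centred subspace
  X0 <- init$state$X_star0
  resid <- X0 - Q %*% crossprod(Q, X0)
  expect_lt(max(abs(resid)) / max(abs(X0)), 1e-6)

  # seeded W2 reproducibility
  init2 <- init_two_layer(tbl, M = 3, K1 = 60, cols = paste0("f", 1:10))
  expect_identical(init$model$W2, init2$model$W2)
  init3 <- init_two_layer(tbl, M = 3, K1 = 60, seed = 99,
                          cols = paste0("f", 1:10))
  expect_false(identical(init$model$W2, init3$model$W2))

  expect_error(init_two_layer(tbl, M = 10, cols = paste0("f", 1:10)),
               regexp = "smaller")
})

test_that("the pseudo-inverse step attains the least-squares optimum", {
  set.seed(8)
  Phi1 <- matrix(runif(200 * 12), 200, 12)
  X_star <- matrix(rnorm(200 * 4), 200, 4)
  W1 <- protonet:::pinv_solve(Phi1, X_star)
  resid <- norm(Phi1 %*% W1 - X_star, "F")
  W_qr <- qr.solve(Phi1, X_star)
  resid_qr <- norm(Phi1 %*% W_qr - X_star, "F")
  expect_lt(abs(resid - resid_qr) / resid_qr, 1e-8)
  # when the columns can represent the target exactly, the fit is exact
  X_rep <- Phi1 %*% matrix(rnorm(48), 12, 4)
  W_rep <- protonet:::pinv_solve(Phi1, X_rep)
  expect_lt(max(abs(Phi1 %*% W_rep - X_rep)), 1e-6)
})

test_that("cross-entropy loss matches closed forms and a recomputation", {
  y <- c(0, 1, 1, 0)
  expect_equal(loss_cross_entropy(y, y), 0, tolerance = 1e-10)
  expect_equal(loss_cross_entropy(y, rep(0.5, 4)), log(2), tolerance = 1e-12)
  set.seed(10)
  yh <- runif(50)
  yy <- rbinom(50, 1, 0.5)
  manual <- -mean(yy * log(yh) + (1 - yy) * log(1 - yh))
  expect_equal(loss_cross_entropy(yy, yh), manual, tolerance = 1e-12)
})

test_that("embedding and W2 gradients match central finite differences", {
  set.seed(2)
  N <- 8; M <- 3; K2 <- 4
  X_star <- matrix(rnorm(N * M), N, M)
  model <- list(C2_centers = matrix(rnorm(K2 * M), K2, M),
                C2_scales = matrix(runif(K2 * M, 0.5, 2), K2, M),
                W2 = matrix(rnorm((K2 + 1) * 2), K2 + 1, 2))
  y <- rbinom(N, 1, 0.5)
  E_of <- function(Xs) {
    loss_cross_entropy(y, protonet:::two_layer_forward(Xs, model)$prob)
  }
  g <- embedding_gradient(X_star, y, model)
  num <- matrix(0, N, M)
  for (i in 1:N) {
    for (j in 1:M) {
      e <- 1e-6
      Xp <- X_star; Xp[i, j] <- Xp[i, j] + e
      Xm <- X_star; Xm[i, j] <- Xm[i, j] - e
      num[i, j] <- (E_of(Xp) - E_of(Xm)) / (2 * e)
    }
  }
  expect_lt(max(abs(g - num)) / max(abs(num)), 1e-4)

  # raw W2 gradient (1/N) Phi2a' (Yhat - Y) vs finite differences
  fw <- protonet:::two_layer_forward(X_star, model)
  Y <- cbind(1 - y, y)
  gW <- crossprod(cbind(fw$Phi2, 1), fw$Yhat - Y) / N
  E_W <- function(W) {
    Yh <- protonet:::softmax_rows(cbind(fw$Phi2, 1) %*% W)
    loss_cross_entropy(y, Yh[, 2])
  }
  numW <- matrix(0, K2 + 1, 2)
  for (i in 1:(K2 + 1)) {
    for (j in 1:2) {
      e <- 1e-6
      Wp <- model$W2; Wp[i, j] <- Wp[i, j] + e
      Wm <- model$W2; Wm[i, j] <- Wm[i, j] - e
      numW[i, j] <- (E_W(Wp) - E_W(Wm)) / (2 * e)
    }
  }
  expect_lt(max(abs(gW - numW)) / max(abs(numW)), 1e-4)

  # stationary cases
  X0 <- X_star
  X0[1, ] <- model$C2_centers[2, ]
  fw0 <- protonet:::two_layer_forward(X0, model)
  expect_equal(fw0$Phi2[1, 2], 1)
  m0 <- model
  m0$W2[] <- 0
  expect_true(all(embedding_gradient(X_star, y, m0) == 0))
})

test_that("two-layer training learns separable data monotonically", {
  toy <- make_toy_table(n = 120, d = 6, sep = 4, seed = 4)
  m <- train_two_layer(toy, M = 3, K1 = 20, cols = paste0("f", 1:6),
                       max_iter = 120)
  y <- as.integer(toy$label == "tremor")
  expect_gte(auroc(predict(m, toy), y), 0.99)
  expect_lt(tail(m$history, 1), m$history[1])
  # accepted loss trajectory is non-increasing away from basis refreshes
  refresh_its <- seq(10, m$iterations, by = 10)
  deltas <- diff(m$history)
  ok <- deltas <= 1e-12
  ok[refresh_its[refresh_its <= length(deltas)]] <- TRUE
  expect_true(all(ok))
})

test_that("a zero learning rate freezes training immediately", {
  toy <- make_toy_table(n = 80, d = 5, seed = 9)
  m <- train_two_layer(toy, M = 3, K1 = 15, cols = paste0("f", 1:5),
                       eta = 0, max_iter = 50)
  expect_lte(m$iterations, 2L)
  expect_true(all(abs(diff(m$history)) < 1e-5 * m$history[1]))
})

test_that("with K1 = N and tiny scales the first layer interpolates", {
  set.seed(12)
  toy <- make_toy_table(n = 40, d = 5, seed = 12)
  cols <- paste0("f", 1:5)
  X <- as.matrix(toy[cols])
  ip <- select_inducing_points(X, nrow(X))
  s1 <- (1e-3 * sqrt(ip$s1) / 0.5)^2   # 1e-3 of the median distance
  Phi1 <- protonet:::rbf_design(X, ip$centers, matrix(s1, nrow(X), 5))
  X_star <- matrix(rnorm(40 * 3), 40, 3)
  W1 <- protonet:::pinv_solve(Phi1, X_star)
  expect_lt(max(abs(Phi1 %*% W1 - X_star)), 1e-4)
})

test_that("prediction dispatches over both model types", {
  toy <- make_toy_table(n = 80, d = 5, seed = 4)
  basis <- suppressWarnings(build_basis_set(toy, cols = paste0("f", 1:5)))
  sl <- train_single_layer(toy, basis)
  tl <- train_two_layer(toy, M = 3, K1 = 15, cols = paste0("f", 1:5),
                        max_iter = 30)
  for (m in list(sl, tl)) {
    p <- predict(m, toy)
    expect_true(all(p >= 0 & p <= 1))
    cls <- predict(m, toy, type = "class")
    expect_identical(cls, as.integer(p >= 0.5))
    m$threshold <- 0.9
    expect_identical(predict(m, toy, type = "class"),
                     as.integer(p >= 0.9))
  }
})
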