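test_that("soft thresholding matches its closed form", {
  expect_equal(soft_threshold(1.2, 0.5), 0.7)
  expect_equal(soft_threshold(-0.3, 0.5), 0)
  y <- rnorm(20)
  expect_identical(soft_threshold(y, 0), y)
  expect_error(soft_threshold(1, -1), class = "netpls_invalid_argument")
})

test_that("unpenalized components equal the first singular-vector pair of X'Y", {
  set.seed(31)
  for (rep in 1:20) {
    X <- scale(matrix(rnorm(20 * 5), 20, 5), scale = FALSE)
    Y <- scale(matrix(rnorm(20 * 8), 20, 8), scale = FALSE)
    cmp <- fit_component(X, Y)
    sv <- svd(crossprod(X, Y), nu = 1, nv = 1)
    s <- sign(sum(cmp$v * sv$u[, 1]))
    expect_equal(cmp$v, s * sv$u[, 1], tolerance = 1e-6)
    expect_equal(cmp$w, s * sv$v[, 1], tolerance = 1e-6)
    expect_equal(cmp$t, drop(X %*% cmp$v), tolerance = 1e-12)
    expect_equal(cmp$u, drop(Y %*% cmp$w), tolerance = 1e-12)
  }
})

test_that("rank-1 noiseless data recovers its generating directions", {
  set.seed(33)
  t0 <- rnorm(30)
  a <- rnorm(6); b <- rnorm(4)
  X <- scale(tcrossprod(t0, a), scale = FALSE)
  Y <- scale(tcrossprod(t0, b), scale = FALSE)
  cmp <- fit_component(X, Y)
  expect_equal(abs(cmp$v), abs(a) / sqrt(sum(a^2)), tolerance = 1e-8)
  expect_equal(abs(cmp$w), abs(b) / sqrt(sum(b^2)), tolerance = 1e-8)
  expect_gt(abs(cor(cmp$t, scale(t0, scale = FALSE))), 1 - 1e-8)
  d <- deflate(X, Y, cmp)
  expect_lt(max(abs(d$X)), 1e-10)
  expect_lt(max(abs(d$Y)), 1e-10)
})

test_that("a large enough penalty annihilates the weights (degenerate signal)", {
  set.seed(35)
  X <- scale(matrix(rnorm(100), 20, 5), scale = FALSE)
  Y <- scale(matrix(rnorm(80), 20, 4), scale = FALSE)
  lam <- max(abs(crossprod(X, Y))) * 2
  expect_error(fit_component(X, Y, lambda_x = lam),
               class = "netpls_degenerate_component")
})

test_that("deflation leaves residuals orthogonal to the score", {
  set.seed(37)
  X <- scale(matrix(rnorm(200), 20, 10), scale = FALSE)
  Y <- scale(matrix(rnorm(120), 20, 6), scale = FALSE)
  cmp <- fit_component(X, Y, lambda_x = 0.3, lambda_y = 0.2)
  d <- deflate(X, Y, cmp)
  expect_lt(max(abs(crossprod(d$X, cmp$t))), 1e-10)
  cmp$t <- numeric(20)
  expect_error(deflate(X, Y, cmp), class = "netpls_degenerate_score")
})

test_that("sparsity of v is nonincreasing in lambda_x for fixed w", {
  set.seed(39)
  for (rep in 1:10) {
    X <- scale(matrix(rnorm(300), 30, 10), scale = FALSE)
    Y <- scale(matrix(rnorm(150), 30, 5), scale = FALSE)
    w <- rnorm(5); w <- w / sqrt(sum(w^2))
    z <- drop(crossprod(X, Y) %*% w)
    lams <- seq(0, max(abs(z)), length.out = 25)
    nnz <- vapply(lams, function(l) sum(soft_threshold(z, l) != 0), 0L)
    expect_true(all(diff(nnz) <= 0))
  }
})

test_that("full-model properties: exact fit, orthogonal scores, telescoping deflation", {
  set.seed(41)
  n <- 40; p <- 4; q <- 6
  X <- matrix(rnorm(n * p), n, p)
  Theta <- matrix(rnorm(p * q), p, q)
  Y <- X %*% Theta                               # noiseless linear truth
  # k = p components deflate X completely, so the fit is exact
  fit <- fit_spls(X, Y, k = p)
  expect_lt(max(abs(predict(fit, X) - Y)), 1e-6)
  G <- crossprod(fit$T)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)     # mutually orthogonal scores
  # telescoping: sum_h t_h l_h' + X_residual = processed X exactly
  Xc <- scale(X)
  recon <- fit$x_residual
  for (h in seq_len(fit$k))
    recon <- recon + tcrossprod(fit$T[, h], fit$L[, h])
  expect_equal(recon, Xc, tolerance = 1e-10, ignore_attr = TRUE)
  # k = 1 consistency with fit_component on the processed matrices
  one <- fit_spls(X, Y, k = 1)
  cmp <- fit_component(scale(X), scale(Y, scale = FALSE))
  expect_equal(one$V[, 1], cmp$v, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("unpenalized score path matches an independent NIPALS reference", {
  set.seed(43)
  X <- matrix(rnorm(30 * 7), 30, 7)
  Y <- X %*% matrix(rnorm(7 * 5), 7, 5) + 0.5 * matrix(rnorm(30 * 5), 30, 5)
  fit <- fit_spls(X, Y, k = 3)
  ref <- nipals_pls(scale(X), scale(Y, scale = FALSE), k = 3)
  for (h in 1:3) {
    r <- abs(cor(fit$T[, h], ref$T[, h]))
    expect_gt(r, 1 - 1e-6)
  }
})

test_that("selected support is invariant under column rescaling when standardizing", {
  set.seed(45)
  X <- matrix(rnorm(50 * 8), 50, 8)
  Y <- X[, 1:2] %*% matrix(c(2, -1, 1, 2), 2) + 0.2 * matrix(rnorm(100), 50, 2)
  f1 <- fit_spls(X, Y, k = 1, lambda_x = 10)
  X2 <- sweep(X, 2, c(100, 0.01, rep(1, 6)), "*")
  f2 <- fit_spls(X2, Y, k = 1, lambda_x = 10)
  expect_identical(which(f1$V[, 1] != 0), which(f2$V[, 1] != 0))
})

test_that("PRESS behaves on noiseless, noisy and permuted data", {
  set.seed(47)
  n <- 100
  X <- matrix(rnorm(n * 5), n, 5)
  Y <- X %*% matrix(rnorm(10), 5, 2)
  pr <- press(X, Y, k = 5, seed = 9)
  expect_lt(pr$total, 1e-6 * sum(Y^2))           # noiseless linear truth

  # pure-noise response: PRESS close to the fold-adjusted variance, never 0
  tot <- replicate(10, {
    Yn <- matrix(rnorm(n * 2), n, 2)
    press(X, Yn, k = 2, seed = sample.int(1e6, 1))$total
  })
  expect_true(all(tot > sum(scale(Y, scale = FALSE)^2) * 0))
  expect_true(all(tot > 0))

  # relabeling invariance: permuting subjects together with folds
  folds <- make_folds(n, 5, seed = 2)
  Yn <- Y + matrix(rnorm(n * 2), n, 2)
  perm <- sample(n)
  expect_equal(press(X[perm, ], Yn[perm, ], k = 2, folds = folds[perm])$total,
               press(X, Yn, k = 2, folds = folds)$total, tolerance = 1e-10)

  expect_error(press(X, Y, k = 2, folds = rep(c(1, 2), c(98, 2))),
               class = "netpls_invalid_folds")
})

test_that("penalty tuning drives irrelevant weights to zero and respects its contract", {
  set.seed(49)
  nrep <- 50L
  irrelevant_zeroed <- 0L; irrelevant_total <- 0L; relevant_kept <- 0L
  for (s in seq_len(nrep)) {
    set.seed(500 + s)
    n <- 60
    X <- matrix(rnorm(n * 8), n, 8)
    Y <- X[, 1:2] %*% matrix(c(2, 1, -1, 2), 2) + 0.3 * matrix(rnorm(n * 2), n, 2)
    surf <- tune_penalties(X, Y, k = 2, seed = s)
    fit <- suppressWarnings(fit_spls(X, Y, k = 2,
                                     lambda_x = surf$chosen$lambda_x,
                                     lambda_y = surf$chosen$lambda_y))
    irr <- fit$V[3:8, , drop = FALSE]
    irrelevant_zeroed <- irrelevant_zeroed + sum(irr == 0)
    irrelevant_total <- irrelevant_total + length(irr)
    # the two signal variables may split across the two components
    relevant_kept <- relevant_kept +
      all(rowSums(fit$V[1:2, , drop = FALSE] != 0) > 0)
    # search contract: the optimum is no worse than any traced evaluation
    expect_lte(surf$best_press, min(surf$evaluations$press) + 1e-9)
  }
  # prediction-optimal L1 tuning may retain an occasional spurious weight,
  # but the chosen penalty must zero the overwhelming majority of
  # irrelevant entries while keeping the true support active
  expect_gte(irrelevant_zeroed / irrelevant_total, 0.9)
  expect_gte(relevant_kept / nrep, 0.9)
})

test_that("Q2 is near 1 for clean signal, non-positive for noise, and never above 1", {
  set.seed(51)
  n <- 80
  X <- matrix(rnorm(n * 5), n, 5)
  # single latent direction, so the first component carries all the signal
  Y <- (X %*% rnorm(5)) %*% t(rnorm(3))
  q <- q2_criterion(X, Y, k_max = 3, seed = 3)
  expect_gt(q$q2[1], 0.9)
  expect_true(all(q$q2 <= 1))
  expect_gte(q$suggested_k, 1L)

  neg <- vapply(1:20, function(s) {
    set.seed(700 + s)
    Yn <- matrix(rnorm(n * 2), n, 2)
    q2_criterion(X, Yn, k_max = 1, seed = s)$q2[1]
  }, numeric(1))
  expect_gte(mean(neg <= 0), 0.9)
})
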