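# Sparse partial least squares linking the reduced biomarker matrix X
# (n x p) to the reduced image matrix Y (n x q). Each component maximizes
# the penalized covariance criterion
#   L(v, w) = -v' X'Y w + lambda_X ||v||_1 + lambda_Y ||w||_1,  ||v|| = ||w|| = 1,
# by alternating soft-thresholded updates initialized at the first singular
# vectors of X'Y, followed by score/loading computation and rank-1
# deflation of both matrices by the X score t. Penalties are tuned by
# 5-fold PRESS cross-validation with an alternating 1-D golden-section
# ("binary") search per axis.

#' Soft-thresholding operator
#'
#' \code{sign(y) * max(|y| - lam, 0)}, applied elementwise.
#'
#' @param y Numeric vector.
#' @param lam Nonnegative threshold.
#' @return Thresholded vector.
#' @export
soft_threshold <- function(y, lam) {
  if (lam < 0) stop_netpls("'lam' must be nonnegative", "netpls_invalid_argument")
  sign(y) * pmax(abs(y) - lam, 0)
}

.normalize <- function(x) {
  nx <- sqrt(sum(x^2))
  if (nx == 0) x else x / nx
}

#' Fit a single sparse PLS component
#'
#' Alternates \code{v <- normalize(soft_threshold(X'Y w, lambda_x))} and
#' \code{w <- normalize(soft_threshold(Y'X v, lambda_y))} from the first
#' singular-vector pair of \code{X'Y} until the max-norm change of both
#' weights falls below \code{tol}. Scores and loadings follow:
#' \code{t = Xv}, \code{u = Yw}, \code{l = X't / t't}, \code{m = Y't / t't}.
#' The sign is fixed so the largest-magnitude entry of \code{v} is positive.
#' X and Y must already be column-centered.
#'
#' @param X Centered n x p matrix.
#' @param Y Centered n x q matrix.
#' @param lambda_x,lambda_y Nonnegative L1 penalties on \code{v} / \code{w}.
#' @param tol Convergence tolerance (max-norm of weight change).
#' @param max_iter Iteration cap; non-convergence warns, \code{converged = FALSE}.
#' @return \code{spls_component}: \code{v, w, t, u, x_loading, y_loading,
#'   iterations, converged}.
#' @export
fit_component <- function(X, Y, lambda_x = 0, lambda_y = 0,
                          tol = 1e-6, max_iter = 500L) {
  if (anyNA(X) || anyNA(Y))
    stop_netpls("X/Y must not contain NA", "netpls_invalid_argument")
  XtY <- crossprod(X, Y)
  sv <- svd(XtY, nu = 1L, nv = 1L)
  v <- .normalize(sv$u[, 1L]); w <- .normalize(sv$v[, 1L])
  converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    v_new <- soft_threshold(drop(XtY %*% w), lambda_x)
    if (all(v_new == 0))
      stop_netpls("lambda_x annihilated the X weight vector",
                  "netpls_degenerate_component")
    v_new <- .normalize(v_new)
    w_new <- soft_threshold(drop(crossprod(XtY, v_new)), lambda_y)
    if (all(w_new == 0))
      stop_netpls("lambda_y annihilated the Y weight vector",
                  "netpls_degenerate_component")
    w_new <- .normalize(w_new)
    delta <- max(max(abs(v_new - v)), max(abs(w_new - w)))
    v <- v_new; w <- w_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("component did not converge in ", max_iter, " iterations")
  s <- sign(v[which.max(abs(v))])
  v <- s * v; w <- s * w
  t_vec <- drop(X %*% v)
  tt <- sum(t_vec^2)
  if (tt == 0)
    stop_netpls("X score is identically zero", "netpls_degenerate_component")
  structure(list(v = v, w = w, t = t_vec, u = drop(Y %*% w),
                 x_loading = drop(crossprod(X, t_vec)) / tt,
                 y_loading = drop(crossprod(Y, t_vec)) / tt,
                 iterations = it, converged = converged),
            class = "spls_component")
}

#' Deflate X and Y by a fitted component
#'
#' \code{X' = X - t l'}, \code{Y' = Y - t m'}; the residual X is orthogonal
#' to the score: \code{X'' t = 0}.
#'
#' @param X,Y Matrices the component was fitted on.
#' @param component \code{spls_component}.
#' @return List \code{(X, Y)} of deflated matrices.
#' @export
deflate <- function(X, Y, component) {
  tt <- sum(component$t^2)
  if (tt == 0) stop_netpls("zero score vector", "netpls_degenerate_score")
  list(X = X - tcrossprod(component$t, component$x_loading),
       Y = Y - tcrossprod(component$t, component$y_loading))
}

#' Fit a k-component sparse PLS model
#'
#' X columns are centered and scaled to unit variance; Y columns are
#' centered only (stored, so predictions invert the transforms). Components
#' are fitted with deflation in between; a degenerate component at step j
#' truncates the model to j - 1 components with a warning. The p x q
#' coefficient matrix is the usual PLS construction
#' \code{C = V (L'V)^{-1} M'} on the processed scales, so
#' \code{predict()} gives \code{yhat = x_scaled C + y_center}.
#'
#' @param X n x p predictor matrix (raw scale).
#' @param Y n x q response matrix (raw scale).
#' @param k Number of components (default 10).
#' @param lambda_x,lambda_y L1 penalties.
#' @param tol,max_iter Passed to \code{\link{fit_component}}.
#' @param scale_x Scale X columns to unit variance (default TRUE).
#' @return \code{netpls_spls} model: \code{components}, score matrices
#'   \code{T}, \code{U}, weight/loading matrices \code{V}, \code{W},
#'   \code{L}, \code{M}, coefficient matrix \code{C}, penalties and
#'   centering/scaling parameters.
#' @export
fit_spls <- function(X, Y, k = 10L, lambda_x = 0, lambda_y = 0,
                     tol = 1e-6, max_iter = 500L, scale_x = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (nrow(Y) != n) stop_netpls("X and Y must have the same rows",
                                "netpls_dimension_mismatch")
  if (k > min(n - 1L, p, q))
    warning("k exceeds min(n - 1, p, q); components may be degenerate")
  x_center <- colMeans(X)
  x_scale <- if (scale_x) apply(X, 2L, stats::sd) else rep(1, p)
  x_scale[x_scale == 0] <- 1
  y_center <- colMeans(Y)
  Xc <- sweep(sweep(X, 2L, x_center), 2L, x_scale, "/")
  Yc <- sweep(Y, 2L, y_center)
  Xd <- Xc; Yd <- Yc
  comps <- vector("list", k)
  for (h in seq_len(k)) {
    cmp <- tryCatch(
      fit_component(Xd, Yd, lambda_x, lambda_y, tol, max_iter),
      netpls_degenerate_component = function(e) NULL)
    if (is.null(cmp)) {
      warning("degenerate component at step ", h, "; truncating model to ",
              h - 1L, " component(s)")
      comps <- comps[seq_len(h - 1L)]
      break
    }
    comps[[h]] <- cmp
    defl <- deflate(Xd, Yd, cmp)
    Xd <- defl$X; Yd <- defl$Y
  }
  comps <- Filter(Negate(is.null), comps)
  k_eff <- length(comps)
  if (k_eff == 0L)
    stop_netpls("no component could be fitted at these penalties",
                "netpls_degenerate_component")
  V <- vapply(comps, `[[`, numeric(p), "v")
  W <- vapply(comps, `[[`, numeric(q), "w")
  L <- vapply(comps, `[[`, numeric(p), "x_loading")
  M <- vapply(comps, `[[`, numeric(q), "y_loading")
  Tm <- vapply(comps, `[[`, numeric(n), "t")
  Um <- vapply(comps, `[[`, numeric(n), "u")
  dim(V) <- c(p, k_eff); dim(W) <- c(q, k_eff)
  dim(L) <- c(p, k_eff); dim(M) <- c(q, k_eff)
  dim(Tm) <- c(n, k_eff); dim(Um) <- c(n, k_eff)
  rownames(V) <- colnames(X); rownames(L) <- colnames(X)
  C <- V %*% solve(crossprod(L, V), t(M))
  structure(list(components = comps, k = k_eff,
                 V = V, W = W, L = L, M = M, T = Tm, U = Um, C = C,
                 penalties = list(lambda_x = lambda_x, lambda_y = lambda_y),
                 x_center = x_center, x_scale = x_scale, y_center = y_center,
                 x_residual = Xd, y_residual = Yd),
            class = "netpls_spls")
}

#' Predict responses from a sparse PLS model
#'
#' @param object \code{netpls_spls} model.
#' @param newdata n x p matrix on the raw X scale.
#' @param k Number of components to use (default: all fitted).
#' @param ... Unused.
#' @return n x q matrix of predictions on the raw Y scale.
#' @export
predict.netpls_spls <- function(object, newdata, k = object$k, ...) {
  Xs <- sweep(sweep(as.matrix(newdata), 2L, object$x_center), 2L,
              object$x_scale, "/")
  C <- if (k == object$k) object$C else
    object$V[, 1:k, drop = FALSE] %*%
      solve(crossprod(object$L[, 1:k, drop = FALSE],
                      object$V[, 1:k, drop = FALSE]),
            t(object$M[, 1:k, drop = FALSE]))
  sweep(Xs %*% C, 2L, object$y_center, "+")
}

#' Seeded fold assignment for cross-validation
#'
#' Uniform random partition into \code{nfolds} parts, optionally stratified
#' by a binary label so each fold sees both classes.
#'
#' @param n Number of subjects.
#' @param nfolds Number of folds (default 5).
#' @param seed Integer seed.
#' @param labels Optional binary labels for stratification.
#' @return Integer n-vector with values in \code{1:nfolds}.
#' @export
make_folds <- function(n, nfolds = 5L, seed = 1L, labels = NULL) {
  set.seed(derive_seed(seed, "folds"))
  folds <- integer(n)
  if (is.null(labels)) {
    folds <- sample(rep_len(seq_len(nfolds), n))
  } else {
    for (cl in unique(labels)) {
      i <- which(labels == cl)
      folds[i] <- sample(rep_len(seq_len(nfolds), length(i)))
    }
  }
  folds
}

# PRESS per response column for each component count 1..k, from one fold
# split; refits (including re-centering/re-scaling) on each training part.
.press_path <- function(X, Y, lambda_x, lambda_y, k, folds, scale_x = TRUE) {
  q <- ncol(Y)
  press <- matrix(0, k, q)
  for (f in sort(unique(folds))) {
    tr <- folds != f; te <- !tr
    fit <- tryCatch(
      suppressWarnings(fit_spls(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                                k = k, lambda_x = lambda_x,
                                lambda_y = lambda_y, scale_x = scale_x)),
      netpls_error = function(e) NULL)
    if (is.null(fit)) return(NULL)          # degenerate at these penalties
    for (h in seq_len(k)) {
      hh <- min(h, fit$k)                   # truncated models reuse best k
      pr <- predict(fit, X[te, , drop = FALSE], k = hh)
      press[h, ] <- press[h, ] + colSums((Y[te, , drop = FALSE] - pr)^2)
    }
  }
  press
}

#' PRESS cross-validation of a sparse PLS fit
#'
#' Prediction error sum of squares: with folds \eqn{\kappa},
#' \eqn{PRESS_j = \sum_i (y_{ij} - \hat y_{(-\kappa(i)) j})^2}, each
#' held-out prediction coming from a model refitted (including
#' re-centering) without that fold.
#'
#' @param X,Y Raw-scale matrices.
#' @param lambda_x,lambda_y Penalties.
#' @param k Number of components.
#' @param folds Optional fold assignment (1..nfolds per subject); generated
#'   with \code{\link{make_folds}} when absent.
#' @param nfolds,seed,labels Used when \code{folds} is missing.
#' @return List: \code{press_j} (per response column), \code{total},
#'   \code{folds}. Degenerate penalties give \code{total = Inf}.
#' @export
press <- function(X, Y, lambda_x = 0, lambda_y = 0, k = 10L, folds = NULL,
                  nfolds = 5L, seed = 1L, labels = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  folds <- folds %||% make_folds(nrow(X), nfolds, seed, labels)
  if (min(table(folds)) < 3L)
    stop_netpls("each fold needs at least 3 subjects", "netpls_invalid_folds")
  pp <- .press_path(X, Y, lambda_x, lambda_y, k, folds)
  if (is.null(pp))
    return(list(press_j = rep(Inf, ncol(Y)), total = Inf, folds = folds))
  list(press_j = pp[k, ], total = sum(pp[k, ]), folds = folds)
}

#' Tune the L1 penalties by PRESS with alternating line search
#'
#' The two-dimensional search is run as alternating one-dimensional
#' golden-section (bisection-style) searches per axis over
#' \eqn{[0, \lambda_{max}]}, \eqn{\lambda_{max} = \max |X'Y|} on the
#' processed scales, with total PRESS as the objective. Degenerate penalty
#' values score \code{Inf}, which pushes the search away from them. The
#' full evaluation trace is retained.
#'
#' @param X,Y Raw-scale matrices.
#' @param k Number of components (default 10).
#' @param nfolds,seed,labels Fold construction (folds fixed across the search).
#' @param n_line Golden-section iterations per axis pass (default 6).
#' @param max_alternations Axis alternations (default 3).
#' @param rel_tol Stop when a full alternation improves PRESS by less than
#'   this fraction (default 1e-3).
#' @return \code{press_surface}: \code{evaluations} data frame
#'   (lambda_x, lambda_y, press), \code{chosen} penalties, \code{folds},
#'   \code{best_press}.
#' @export
tune_penalties <- function(X, Y, k = 10L, nfolds = 5L, seed = 1L,
                           labels = NULL, n_line = 6L, max_alternations = 3L,
                           rel_tol = 1e-3) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  folds <- make_folds(nrow(X), nfolds, seed, labels)
  xs <- apply(X, 2L, stats::sd); xs[xs == 0] <- 1
  Xc <- sweep(sweep(X, 2L, colMeans(X)), 2L, xs, "/")
  Yc <- sweep(Y, 2L, colMeans(Y))
  lam_max <- max(abs(crossprod(Xc, Yc)))
  evals <- new.env(parent = emptyenv())
  trace <- list()
  objective <- function(lx, ly) {
    key <- paste(signif(lx, 10), signif(ly, 10))
    if (!is.null(evals[[key]])) return(evals[[key]])
    val <- press(X, Y, lx, ly, k, folds = folds)$total
    evals[[key]] <- val
    trace[[length(trace) + 1L]] <<- c(lambda_x = lx, lambda_y = ly, press = val)
    val
  }
  golden <- function(fn, lo, hi, iters) {
    phi <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
    f1 <- fn(x1); f2 <- fn(x2)
    for (i in seq_len(iters)) {
      if (f1 <= f2) { b <- x2; x2 <- x1; f2 <- f1
        x1 <- b - phi * (b - a); f1 <- fn(x1)
      } else { a <- x1; x1 <- x2; f1 <- f2
        x2 <- a + phi * (b - a); f2 <- fn(x2) }
    }
    cand <- c(a, x1, x2, b)
    fc <- c(fn(a), f1, f2, fn(b))
    cand[which.min(fc)]
  }
  lx <- 0; ly <- 0
  best <- objective(lx, ly)
  for (pass in seq_len(max_alternations)) {
    lx <- golden(function(l) objective(l, ly), 0, lam_max, n_line)
    ly <- golden(function(l) objective(lx, l), 0, lam_max, n_line)
    new_best <- objective(lx, ly)
    if (!is.finite(best) || (best - new_best) < rel_tol * max(best, 1e-12)) break
    best <- new_best
  }
  ev <- as.data.frame(do.call(rbind, trace))
  # the returned optimum is the best pair actually evaluated anywhere on
  # the trace (an axis pass can end off the incumbent)
  ibest <- which.min(ev$press)
  if (!is.finite(ev$press[ibest]))
    stop_netpls("all evaluated penalty pairs were degenerate",
                "netpls_degenerate_component")
  structure(list(evaluations = ev,
                 chosen = list(lambda_x = ev$lambda_x[ibest],
                               lambda_y = ev$lambda_y[ibest]),
                 folds = folds, best_press = ev$press[ibest]),
            class = "press_surface")
}

#' Per-component Q2 diagnostic
#'
#' \eqn{Q^2(h) = 1 - PRESS(h) / RSS(h-1)}: cross-validated predictive
#' relevance of adding the h-th component, with \eqn{RSS(h-1)} the residual
#' sum of squares of the full-data model with h - 1 components
#' (\eqn{RSS(0)} = total centered sum of squares of Y). The suggested
#' component count is the largest h whose \eqn{Q^2} clears the conventional
#' 0.0975 cut (configurable).
#'
#' @param X,Y Raw-scale matrices.
#' @param k_max Maximum components to assess.
#' @param lambda_x,lambda_y Penalties.
#' @param nfolds,seed,labels Fold construction.
#' @param threshold Relevance cut (default 0.0975).
#' @return List: \code{q2} (length \code{k_max}), \code{suggested_k},
#'   \code{press_total}, \code{rss}.
#' @export
q2_criterion <- function(X, Y, k_max = 10L, lambda_x = 0, lambda_y = 0,
                         nfolds = 5L, seed = 1L, labels = NULL,
                         threshold = 0.0975) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  folds <- make_folds(nrow(X), nfolds, seed, labels)
  pp <- .press_path(X, Y, lambda_x, lambda_y, k_max, folds)
  if (is.null(pp))
    stop_netpls("penalties are degenerate on a training fold",
                "netpls_degenerate_component")
  press_total <- rowSums(pp)
  full <- suppressWarnings(fit_spls(X, Y, k = k_max, lambda_x = lambda_x,
                                    lambda_y = lambda_y))
  rss <- numeric(k_max + 1L)
  rss[1L] <- sum(sweep(Y, 2L, colMeans(Y))^2)
  for (h in seq_len(k_max))
    rss[h + 1L] <- sum((Y - predict(full, X, k = min(h, full$k)))^2)
  q2 <- 1 - press_total / rss[seq_len(k_max)]
  above <- which(q2 >= threshold)
  list(q2 = q2, suggested_k = if (length(above)) max(above) else 0L,
       press_total = press_total, rss = rss)
}
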