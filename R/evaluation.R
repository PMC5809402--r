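# Bootstrap evaluation of clustering-based dimension reductions. The sPLS
# stage is simplified to a univariate response (a volumetric-ratio
# surrogate); per bootstrap replicate each clustering method reduces the
# panel to representatives, a lasso with 5-fold CV screens them, backward
# stepwise BIC refines the linear model, and the fit is scored by in-sample
# adjusted R^2 and out-of-bag MSE.

#' Univariate volumetric-ratio response
#'
#' Per subject, the summed intensity inside a designated region divided by
#' the summed intensity over the whole mask — a synthetic surrogate for a
#' regional-volume-to-intracranial-volume ratio.
#'
#' @param dataset \code{synthetic_dataset}.
#' @param region Index of the ground-truth region to use (default 1).
#' @return Numeric n-vector.
#' @export
univariate_response <- function(dataset, region = 1L) {
  vox <- dataset$ground_truth$region_voxels[[region]]
  num <- rowSums(dataset$images$data[, vox, drop = FALSE])
  den <- rowSums(dataset$images$data)
  if (any(den == 0)) stop_netpls("zero total intensity", "netpls_invalid_input")
  num / den
}

# one clustering -> representative-name reduction; all three methods return
# a character vector of representative column names
.reps_network <- function(X) {
  panel <- biomarker_panel(X)
  g <- suppressWarnings(estimate_dependency_graph(panel))
  cl <- suppressWarnings(suppressMessages(cluster_links(g)))
  if (length(cl$clusters) == 0L) return(colnames(X)[which.max(apply(X, 2, stats::var))])
  cl <- suppressMessages(select_representatives(cl, g, panel))
  unique(cl$representative)
}

.reps_by_variance <- function(X, membership) {
  vars <- apply(X, 2L, stats::var)
  unname(vapply(split(colnames(X), membership), function(mem)
    mem[which.max(vars[mem])], character(1L)))
}

.reps_hierarchical <- function(X, k) {
  d <- stats::as.dist(1 - abs(stats::cor(X)))
  memb <- stats::cutree(stats::hclust(d, method = "average"),
                        k = min(k, ncol(X)))
  .reps_by_variance(X, memb)
}

.reps_mixture <- function(X, k) {
  # columns embedded by classical MDS of correlation distance, then a
  # Gaussian mixture with k components clusters the embedding
  d <- 1 - abs(stats::cor(X))
  emb <- stats::cmdscale(stats::as.dist(d), k = min(5L, ncol(X) - 1L))
  k <- min(k, ncol(X) - 1L)
  mc <- tryCatch(
    mclust::Mclust(emb, G = k, verbose = FALSE),
    error = function(e) NULL)
  memb <- if (is.null(mc) || is.null(mc$classification))
    stats::cutree(stats::hclust(stats::as.dist(d)), k = k)
  else mc$classification
  .reps_by_variance(X, memb)
}

# lasso screen (5-fold CV) + backward stepwise BIC linear model; returns
# in-sample adjusted R^2 and OOB MSE
.fit_and_score <- function(Xb, yb, Xoob, yoob, seed) {
  set.seed(seed)
  survivors <- character(0)
  if (ncol(Xb) >= 2L) {
    cv <- tryCatch(glmnet::cv.glmnet(Xb, yb, nfolds = 5L),
                   error = function(e) NULL)
    if (!is.null(cv)) {
      beta <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1L, 1L]
      survivors <- names(beta)[beta != 0]
    }
  } else survivors <- colnames(Xb)
  if (length(survivors) == 0L) {
    mu <- mean(yb)
    return(c(adj_r2 = 0, oob_mse = mean((yoob - mu)^2)))
  }
  df <- data.frame(.y = yb, Xb[, survivors, drop = FALSE], check.names = FALSE)
  full <- stats::lm(.y ~ ., data = df)
  red <- stats::step(full, direction = "backward", k = log(nrow(Xb)), trace = 0)
  pr <- stats::predict(red, newdata = data.frame(Xoob, check.names = FALSE))
  c(adj_r2 = summary(red)$adj.r.squared, oob_mse = mean((yoob - pr)^2))
}

#' Bootstrap comparison of clustering-based reductions
#'
#' Per replicate: draw a bootstrap sample of subjects; apply each clustering
#' method to the resampled panel to pick representative variables
#' (\code{network} = this package's dependency-graph pipeline;
#' \code{hierarchical} = average linkage on correlation distance cut to the
#' network method's cluster count; \code{mixture} = Gaussian-mixture
#' clustering of a correlation-distance embedding with the same count);
#' screen them with a 5-fold-CV lasso, refine by backward stepwise BIC, and
#' record in-sample adjusted R^2 plus MSE on the out-of-bag subjects.
#' Replicate-level failures are logged and counted, not fatal.
#'
#' @param panel Complete \code{biomarker_panel} (or numeric matrix).
#' @param response Numeric n-vector.
#' @param methods Subset of \code{c("network", "hierarchical", "mixture")}.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed (replicates use derived sub-seeds).
#' @return \code{evaluation_result}: \code{results} data frame (method,
#'   replicate, adj_r2, oob_mse, p_clusters), \code{B}, \code{seed},
#'   \code{failures}.
#' @export
bootstrap_compare <- function(panel, response,
                              methods = c("network", "hierarchical", "mixture"),
                              B = 200L, seed = 1L) {
  X <- if (inherits(panel, "biomarker_panel")) panel$values else as.matrix(panel)
  if (anyNA(X)) stop_netpls("panel must be complete", "netpls_invalid_argument")
  n <- nrow(X)
  if (B < 1L) stop_netpls("B must be >= 1", "netpls_invalid_argument")
  rows <- list(); failures <- 0L
  for (b in seq_len(B)) {
    sb <- derive_seed(seed, paste0("boot", b))
    set.seed(sb)
    idx <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), unique(idx))
    if (length(oob) < 2L) { failures <- failures + 1L; next }
    Xb <- X[idx, , drop = FALSE]; yb <- response[idx]
    Xoob <- X[oob, , drop = FALSE]; yoob <- response[oob]
    reps_net <- tryCatch(.reps_network(Xb), error = function(e) NULL)
    if (is.null(reps_net)) { failures <- failures + 1L; next }
    k_b <- length(reps_net)
    for (m in methods) {
      reps <- tryCatch(switch(m,
        network = reps_net,
        hierarchical = .reps_hierarchical(Xb, k_b),
        mixture = .reps_mixture(Xb, k_b)), error = function(e) NULL)
      if (is.null(reps)) { failures <- failures + 1L; next }
      sc <- tryCatch(
        .fit_and_score(Xb[, reps, drop = FALSE], yb,
                       Xoob[, reps, drop = FALSE], yoob,
                       derive_seed(sb, m)),
        error = function(e) NULL)
      if (is.null(sc)) { failures <- failures + 1L; next }
      rows[[length(rows) + 1L]] <-
        data.frame(method = m, replicate = b, adj_r2 = sc[["adj_r2"]],
                   oob_mse = sc[["oob_mse"]], p_clusters = k_b)
    }
  }
  structure(list(results = do.call(rbind, rows), B = B, seed = seed,
                 failures = failures),
            class = "evaluation_result")
}
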