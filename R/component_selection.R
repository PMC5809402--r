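# Selection of diagnosis-relevant components: backward-stepwise logistic
# regression on the sPLS component scores, minimizing BIC. The scores used
# are the X scores T by default; the Y scores U are available behind a flag
# because both appear in practice.

#' Logistic regression on component scores
#'
#' Maximum-likelihood logit fit via iteratively reweighted least squares
#' (\code{stats::glm}, tolerance 1e-8), with
#' \code{BIC = -2 loglik + (m + 1) log(n)}. Perfect separation (diverging
#' coefficients / fitted probabilities at 0 or 1) raises an error by
#' default; \code{ridge = 1e-4} enables a ridge-stabilized Newton fallback.
#'
#' @param scores n x m numeric matrix (m = 0 gives the intercept-only model).
#' @param labels Binary 0/1 vector with both classes present.
#' @param ridge Ridge penalty for the stabilized fallback (0 = off).
#' @return List: \code{coefficients} (intercept first), \code{loglik},
#'   \code{bic}, \code{p_values} (Wald, per score column), \code{separation}.
#' @export
fit_logistic <- function(scores, labels, ridge = 0) {
  labels <- as.numeric(labels)
  n <- length(labels)
  if (length(unique(labels)) < 2L)
    stop_netpls("labels contain a single class", "netpls_invalid_input")
  scores <- as.matrix(scores)
  if (nrow(scores) != n && ncol(scores) == 0L) scores <- matrix(0, n, 0L)
  m <- ncol(scores)
  if (m >= n) stop_netpls("more scores than subjects", "netpls_invalid_input")
  if (ridge > 0) return(.ridge_logit(scores, labels, ridge))
  df <- data.frame(.y = labels)
  if (m > 0) {
    colnames(scores) <- paste0("s", seq_len(m))
    df <- cbind(df, scores)
  }
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = list(epsilon = 1e-8, maxit = 100L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep && (max(abs(stats::coef(fit))) > 15 ||
              any(stats::fitted(fit) < 1e-8) || any(stats::fitted(fit) > 1 - 1e-8)))
    stop_netpls(paste0("perfect separation detected; refit with ridge ",
                       "(fit_logistic(..., ridge = 1e-4)) or drop the score"),
                "netpls_separation")
  ll <- as.numeric(stats::logLik(fit))
  sm <- summary(fit)$coefficients
  pv <- if (m > 0) sm[-1L, 4L] else numeric(0)
  list(coefficients = stats::coef(fit), loglik = ll,
       bic = -2 * ll + (m + 1) * log(n),
       p_values = pv, separation = sep)
}

# ridge-stabilized Newton logit; same return contract as fit_logistic
.ridge_logit <- function(scores, labels, ridge, tol = 1e-8, max_iter = 100L) {
  n <- length(labels); m <- ncol(scores)
  A <- cbind(`(Intercept)` = 1, scores)
  beta <- numeric(m + 1L)
  for (i in seq_len(max_iter)) {
    p <- stats::plogis(drop(A %*% beta))
    Wv <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(A, A * Wv) + ridge * diag(m + 1L)
    g <- crossprod(A, labels - p) - ridge * beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  p <- stats::plogis(drop(A %*% beta))
  ll <- sum(labels * log(pmax(p, 1e-300)) + (1 - labels) * log(pmax(1 - p, 1e-300)))
  se <- sqrt(diag(solve(crossprod(A, A * pmax(p * (1 - p), 1e-10)) +
                          ridge * diag(m + 1L))))
  z <- beta / se
  pv <- if (m > 0) 2 * stats::pnorm(-abs(z[-1L])) else numeric(0)
  list(coefficients = stats::setNames(drop(beta), colnames(A)), loglik = ll,
       bic = -2 * ll + (m + 1) * log(n), p_values = pv, separation = FALSE)
}

#' Backward-stepwise component selection by BIC
#'
#' Starts from the logistic model on all k score columns and greedily drops
#' the single column whose removal most decreases BIC, stopping when no
#' removal helps; the path may end at the intercept-only model (empty
#' selection). Pure backward: dropped components never re-enter.
#'
#' @param scores n x k score matrix (\code{T} or \code{U} of a fitted model).
#' @param labels Binary 0/1 diagnosis labels.
#' @param score_source Label recorded on the result (\code{"T"} or \code{"U"}).
#' @param ridge Passed to \code{\link{fit_logistic}} (separation fallback).
#' @return \code{selection_result}: \code{selected_indices},
#'   \code{coefficients}, \code{p_values}, \code{bic_trace} (BIC after each
#'   accepted elimination, starting at the full model), \code{score_source}.
#' @export
backward_stepwise_bic <- function(scores, labels, score_source = "T",
                                  ridge = 0) {
  scores <- as.matrix(scores)
  k <- ncol(scores)
  if (k < 1L) stop_netpls("need at least one score column", "netpls_invalid_input")
  current <- seq_len(k)
  fit <- fit_logistic(scores[, current, drop = FALSE], labels, ridge)
  trace <- fit$bic
  repeat {
    if (length(current) == 0L) break
    cand_bic <- vapply(seq_along(current), function(i) {
      fit_logistic(scores[, current[-i], drop = FALSE], labels, ridge)$bic
    }, numeric(1L))
    best <- which.min(cand_bic)
    if (cand_bic[best] < fit$bic - 1e-12) {
      current <- current[-best]
      fit <- fit_logistic(scores[, current, drop = FALSE], labels, ridge)
      trace <- c(trace, fit$bic)
    } else break
  }
  structure(list(selected_indices = current,
                 coefficients = fit$coefficients,
                 p_values = fit$p_values,
                 bic_trace = trace,
                 final_bic = fit$bic,
                 score_source = score_source),
            class = "selection_result")
}

#' Report the selected components in substantive terms
#'
#' For each selected component: the nonzero X-weight entries (representative
#' biomarkers with their loadings), the clusters each representative stands
#' for with all co-clustered variables, the voxel map obtained by re-mapping
#' the Y weights through the basis (with its nonzero-voxel count), and the
#' logistic coefficient and Wald p-value.
#'
#' @param selection \code{selection_result}.
#' @param model \code{netpls_spls} fitted on the reduced matrices.
#' @param basis \code{rbf_basis} that produced the reduced Y.
#' @param clusters \code{overlapping_cluster_set} with representatives.
#' @param map_tol Absolute threshold for the brain-map nonzero count
#'   (default 0, strict nonzeros).
#' @return \code{component_report}: list with one entry per selected
#'   component plus a \code{note} when the selection is empty.
#' @export
report_components <- function(selection, model, basis, clusters, map_tol = 0) {
  if (nrow(model$V) == 0L || ncol(basis$B) != nrow(model$W))
    stop_netpls("model and basis lineage are inconsistent",
                "netpls_consistency")
  reps <- rownames(model$V)
  if (length(selection$selected_indices) == 0L)
    return(structure(list(components = list(),
                          note = "no component was selected; the intercept-only model had the lowest BIC"),
                     class = "component_report"))
  coefs <- selection$coefficients[-1L]
  out <- vector("list", length(selection$selected_indices))
  for (i in seq_along(selection$selected_indices)) {
    h <- selection$selected_indices[i]
    v <- model$V[, h]
    nz <- which(v != 0)
    cluster_info <- lapply(reps[nz], function(r) {
      idx <- which(clusters$representative == r)
      list(representative = r,
           clusters = idx,
           co_clustered = sort(unique(setdiff(unlist(clusters$clusters[idx]), r))))
    })
    bm <- remap_weights(model$W[, h], basis, tol = map_tol, source = h)
    out[[i]] <- list(component = h,
                     x_loadings = stats::setNames(v[nz], reps[nz]),
                     clusters = cluster_info,
                     brain_map = bm,
                     n_nonzero_voxels = bm$n_nonzero,
                     logistic_coefficient = unname(coefs[i]),
                     p_value = unname(selection$p_values[i]))
  }
  structure(list(components = out, note = NULL), class = "component_report")
}
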