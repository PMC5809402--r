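# Biomarker-side dimension reduction. A dependency graph over the variables
# (maximum-weight spanning forest on Gaussian mutual-information weights,
# BIC-pruned; or a simple correlation threshold) is decomposed into
# overlapping link communities; each node cluster keeps one representative —
# the highest information-centrality member (clusters of >= 3) or the higher
# variance member (2-node clusters) — and the distinct representatives form
# the n x p predictor matrix X.

#' Biomarker panel
#'
#' @param values n x p0 numeric matrix (NA = missing). Binary variables are
#'   carried as numeric 0/1 columns.
#' @param names Optional column names (must be unique); taken from
#'   \code{colnames(values)} when absent.
#' @return \code{biomarker_panel}: \code{values}, \code{names},
#'   \code{missing_mask}, \code{zero_variance} (flags).
#' @export
biomarker_panel <- function(values, names = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(names)) names <- paste0("V", seq_len(ncol(values)))
  if (anyDuplicated(names))
    stop_netpls("biomarker names must be unique", "netpls_invalid_argument")
  colnames(values) <- names
  zv <- apply(values, 2L, function(x) {
    x <- x[!is.na(x)]
    length(x) == 0L || stats::sd(x) == 0
  })
  structure(list(values = values, names = names,
                 missing_mask = is.na(values), zero_variance = zv),
            class = "biomarker_panel")
}

#' Impute missing biomarker values by iterative conditional regression
#'
#' Missing entries are initialized at the column mean, then updated in
#' sweeps: each incomplete column is regressed (ridge-stabilized least
#' squares) on the other columns over its observed rows and its missing
#' entries are replaced by the predictions, until the largest update falls
#' below \code{tol}. Observed entries are never changed and the result is
#' deterministic given the seed.
#'
#' @param panel \code{biomarker_panel}.
#' @param seed Integer seed, recorded with the result.
#' @param max_sweeps Maximum full passes over the incomplete columns.
#' @param tol Convergence tolerance on the largest imputed-value change.
#' @return A complete \code{biomarker_panel} (original \code{missing_mask}
#'   retained for provenance).
#' @export
impute_missing <- function(panel, seed = 1L, max_sweeps = 10L, tol = 1e-6) {
  M <- panel$missing_mask
  X <- panel$values
  if (!any(M)) return(panel)
  if (any(colSums(!M) == 0L))
    stop_netpls("a column has no observed values and cannot be imputed",
                "netpls_unimputable_column")
  if (any(rowSums(!M) == 0L))
    stop_netpls("a row has no observed values and cannot be imputed",
                "netpls_unimputable_column")
  set.seed(derive_seed(seed, "impute"))
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[M[, j], j] <- mu[j]
  bad <- seq_len(ncol(X))[colSums(M) > 0L]
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    for (j in bad) {
      obs <- !M[, j]
      A <- cbind(1, X[, -j, drop = FALSE])
      beta <- tryCatch(
        solve(crossprod(A[obs, , drop = FALSE]) + 1e-8 * diag(ncol(A)),
              crossprod(A[obs, , drop = FALSE], X[obs, j])),
        error = function(e) NULL)
      if (is.null(beta)) next
      pred <- drop(A[M[, j], , drop = FALSE] %*% beta)
      delta <- max(delta, max(abs(pred - X[M[, j], j])))
      X[M[, j], j] <- pred
    }
    if (delta < tol) break
  }
  out <- panel
  out$values <- X
  out$imputation_seed <- seed
  out
}

#' Estimate the biomarker dependency graph
#'
#' Default \code{forest} mode: a maximum-weight spanning forest over
#' pairwise Gaussian mutual-information weights
#' \eqn{w_{ab} = -\tfrac12 \log(1 - \rho_{ab}^2)}, followed by per-edge BIC
#' pruning — an edge survives iff its likelihood-ratio gain beats the
#' one-parameter BIC penalty, \eqn{2 n w_{ab} > \log n}. This realizes
#' "statistical dependence by decomposing the joint density" as a
#' decomposable (tree-structured) Gaussian model with a well-defined,
#' testable estimator. \code{threshold} mode keeps every pair with
#' \eqn{|\rho|} above \code{threshold}.
#'
#' @param panel Complete \code{biomarker_panel} (or numeric matrix).
#' @param mode \code{"forest"} (default) or \code{"threshold"}.
#' @param threshold Absolute-correlation cutoff for threshold mode.
#' @return \code{dependency_graph}: an \code{igraph} graph (\code{$graph})
#'   with edge attribute \code{weight} (mutual information) and \code{rho},
#'   plus \code{n} and \code{mode}.
#' @export
estimate_dependency_graph <- function(panel, mode = c("forest", "threshold"),
                                      threshold = 0.3) {
  mode <- match.arg(mode)
  X <- if (inherits(panel, "biomarker_panel")) panel$values else as.matrix(panel)
  if (anyNA(X))
    stop_netpls("panel must be complete; run impute_missing() first",
                "netpls_invalid_argument")
  n <- nrow(X)
  if (n < 3L) stop_netpls("need at least 3 observations", "netpls_insufficient_data")
  keep <- apply(X, 2L, stats::sd) > 0
  if (!all(keep)) {
    warning("excluding constant column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  nm <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  rho <- stats::cor(X)
  rho[rho > 1 - 1e-12] <- 1 - 1e-12   # numeric guard off the diagonal copy
  rho[rho < -1 + 1e-12] <- -1 + 1e-12
  mi <- -0.5 * log(1 - rho^2)
  pairs <- which(upper.tri(rho), arr.ind = TRUE)
  if (mode == "forest") {
    g_full <- igraph::graph_from_data_frame(
      data.frame(from = nm[pairs[, 1L]], to = nm[pairs[, 2L]],
                 weight = mi[pairs], rho = rho[pairs]),
      directed = FALSE, vertices = nm)
    # igraph::mst minimizes, so negate to get the maximum-weight forest
    g <- igraph::mst(g_full, weights = -igraph::E(g_full)$weight)
    drop_e <- which(2 * n * igraph::E(g)$weight <= log(n))
    if (length(drop_e)) g <- igraph::delete_edges(g, drop_e)
  } else {
    sel <- abs(rho[pairs]) > threshold
    g <- igraph::graph_from_data_frame(
      data.frame(from = nm[pairs[sel, 1L]], to = nm[pairs[sel, 2L]],
                 weight = mi[pairs][sel], rho = rho[pairs][sel]),
      directed = FALSE, vertices = nm)
  }
  structure(list(graph = g, n = n, mode = mode), class = "dependency_graph")
}

#' Build a dependency graph directly from an edge list (mainly for testing
#' and for importing externally estimated networks).
#'
#' @param edges Two-column character matrix/data.frame of endpoints.
#' @param weights Optional edge weights (default 1).
#' @param vertices Optional vertex universe.
#' @return \code{dependency_graph}.
#' @export
dependency_graph_from_edges <- function(edges, weights = NULL, vertices = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edges)[1:2] <- c("from", "to")
  edges$weight <- weights %||% rep(1, nrow(edges))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
  if (any(igraph::which_loop(g)) || any(igraph::which_multiple(g)))
    stop_netpls("self-loops / duplicate edges are not allowed",
                "netpls_invalid_argument")
  structure(list(graph = g, n = NA_integer_, mode = "external"),
            class = "dependency_graph")
}

# Jaccard similarity of the inclusive neighbourhoods of the two non-shared
# endpoints, for every pair of edges sharing a vertex. Returns a dense
# M x M similarity matrix (graphs here have at most a few hundred edges).
.edge_similarity <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  M <- nrow(el)
  nb <- lapply(seq_len(igraph::vcount(g)), function(v)
    sort(c(v, as.integer(igraph::neighbors(g, v)))))
  S <- matrix(0, M, M)
  inc <- lapply(seq_len(igraph::vcount(g)), function(v)
    as.integer(igraph::incident(g, v)))
  for (v in seq_along(inc)) {
    es <- inc[[v]]
    if (length(es) < 2L) next
    for (a in seq_len(length(es) - 1L)) for (b in (a + 1L):length(es)) {
      ei <- es[a]; ej <- es[b]
      i_other <- setdiff(el[ei, ], v); j_other <- setdiff(el[ej, ], v)
      u <- nb[[i_other]]; w <- nb[[j_other]]
      s <- length(intersect(u, w)) / length(union(u, w))
      S[ei, ej] <- S[ej, ei] <- max(S[ei, ej], s)
    }
  }
  diag(S) <- 1
  S
}

# partition density of an edge partition: D = (2/M) sum_c m_c (m_c - n_c + 1)
# / ((n_c - 2)(n_c - 1)); communities of 2 nodes contribute 0
partition_density <- function(membership, el) {
  M <- nrow(el)
  d <- 0
  for (cid in unique(membership)) {
    e <- membership == cid
    m_c <- sum(e)
    n_c <- length(unique(as.vector(el[e, ])))
    if (n_c > 2L) d <- d + m_c * (m_c - n_c + 1) / ((n_c - 2) * (n_c - 1))
  }
  2 * d / M
}

#' Overlapping clusters by link-community detection
#'
#' Edges are embedded by the Jaccard similarity of their endpoints'
#' inclusive neighbourhoods, agglomerated by single linkage, and the
#' dendrogram is cut where the partition density is maximal. Each link
#' community's endpoint set is a node cluster; a node whose edges fall in
#' several communities appears in several clusters (overlap). On acyclic
#' components the partition density is identically zero, so there the edges
#' are grouped into maximal stars around branch vertices (each edge anchored
#' at its higher-degree endpoint, ties broken lexicographically); degenerate
#' two-node clusters are retained.
#'
#' @param graph \code{dependency_graph}.
#' @return \code{overlapping_cluster_set}: \code{clusters} (list of sorted
#'   name vectors, size >= 2), \code{edge_communities}, \code{representative}
#'   (unset, \code{NA}), \code{p} (unset).
#' @export
cluster_links <- function(graph) {
  g <- graph$graph
  if (igraph::ecount(g) == 0L) {
    warning("graph has no edges; returning an empty cluster set")
    return(structure(list(clusters = list(), edge_communities = list(),
                          representative = character(0), p = 0L),
                     class = "overlapping_cluster_set"))
  }
  comp <- igraph::components(g)
  clusters <- list(); ecomms <- list()
  for (cid in seq_len(comp$no)) {
    vs <- which(comp$membership == cid)
    if (length(vs) < 2L) next
    sub <- igraph::induced_subgraph(g, vs)
    el_names <- igraph::as_edgelist(sub)
    m <- nrow(el_names)
    deg <- igraph::degree(sub)
    names(deg) <- igraph::V(sub)$name
    if (m == igraph::vcount(sub) - 1L) {
      # tree component: star decomposition around branch vertices
      anchor <- apply(el_names, 1L, function(e) {
        if (deg[e[1L]] > deg[e[2L]]) e[1L]
        else if (deg[e[2L]] > deg[e[1L]]) e[2L]
        else sort(e)[1L]
      })
      memb <- match(anchor, unique(anchor))
    } else {
      el_idx <- igraph::as_edgelist(sub, names = FALSE)
      S <- .edge_similarity(sub)
      hc <- stats::hclust(stats::as.dist(1 - S), method = "single")
      cuts <- c(0, sort(unique(hc$height)))
      best <- NULL; best_d <- -Inf
      for (h in cuts) {
        mm <- stats::cutree(hc, h = h + 1e-12)
        d <- partition_density(mm, el_idx)
        if (d > best_d + 1e-12) { best_d <- d; best <- mm }
      }
      memb <- best
    }
    for (k in unique(memb)) {
      e <- memb == k
      ecomms[[length(ecomms) + 1L]] <- el_names[e, , drop = FALSE]
      clusters[[length(clusters) + 1L]] <- sort(unique(as.vector(el_names[e, ])))
    }
  }
  # deduplicate identical node sets (keep first edge community as provenance)
  key <- vapply(clusters, paste, character(1L), collapse = "\r")
  keep <- !duplicated(key)
  structure(list(clusters = clusters[keep], edge_communities = ecomms[keep],
                 representative = rep(NA_character_, sum(keep)), p = NA_integer_),
            class = "overlapping_cluster_set")
}

#' Information centrality of nodes in (a subgraph of) the dependency graph
#'
#' Stephenson–Zelen information centrality: with \eqn{C = (L + J)^{-1}}
#' (weighted Laplacian of the induced subgraph plus the all-ones matrix),
#' the information of the i–j path ensemble is
#' \eqn{I_{ij} = (C_{ii} + C_{jj} - 2 C_{ij})^{-1}} and node i's centrality
#' is the harmonic-style aggregate
#' \eqn{IC_i = \left[C_{ii} + (T - 2 R_i)/n\right]^{-1}} with
#' \eqn{T = \mathrm{tr}(C)}, \eqn{R_i} the i-th row sum. Higher = more
#' central. Disconnected node sets are scored per connected component (with
#' a warning).
#'
#' @param graph \code{dependency_graph}.
#' @param nodes Character vector of vertex names (>= 3; for 2-node clusters
#'   the variance rule applies instead and this function refuses).
#' @param use_weights Use edge weights as conductances (default TRUE).
#' @return Named numeric vector of centrality scores.
#' @export
information_centrality <- function(graph, nodes = igraph::V(graph$graph)$name,
                                   use_weights = TRUE) {
  g <- igraph::induced_subgraph(graph$graph, nodes)
  if (igraph::vcount(g) < 3L)
    stop_netpls("information centrality needs >= 3 nodes; use the variance rule",
                "netpls_small_cluster")
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    warning("induced subgraph is disconnected; scoring per component")
    out <- numeric(0)
    for (cid in seq_len(comp$no)) {
      vs <- igraph::V(g)$name[comp$membership == cid]
      if (length(vs) == 1L) out[vs] <- 0
      else if (length(vs) == 2L) out[vs] <- NA_real_
      else out <- c(out, information_centrality(graph, vs, use_weights))
    }
    return(out[nodes[nodes %in% names(out)]])
  }
  w <- if (use_weights && "weight" %in% igraph::edge_attr_names(g))
    igraph::E(g)$weight else rep(1, igraph::ecount(g))
  L <- igraph::laplacian_matrix(g, weights = w, sparse = FALSE)
  nv <- nrow(L)
  C <- solve(L + matrix(1, nv, nv))
  Tt <- sum(diag(C)); R <- rowSums(C)
  ic <- 1 / (diag(C) + (Tt - 2 * R) / nv)
  stats::setNames(ic, igraph::V(g)$name)
}

#' Choose one representative variable per cluster
#'
#' Clusters of size >= 3 take the member with the highest information
#' centrality within the cluster's induced subgraph; two-node clusters take
#' the member with the larger variance in the (imputed) panel. Ties break
#' lexicographically by name and are logged. Clusters electing the same
#' representative are later collapsed to one predictor column.
#'
#' @param clusters \code{overlapping_cluster_set} from \code{\link{cluster_links}}.
#' @param graph \code{dependency_graph} the clusters came from.
#' @param panel Complete \code{biomarker_panel}.
#' @return The cluster set with \code{representative} filled and \code{p}
#'   set to the number of distinct representatives.
#' @export
select_representatives <- function(clusters, graph, panel) {
  X <- panel$values
  reps <- character(length(clusters$clusters))
  for (i in seq_along(clusters$clusters)) {
    cl <- clusters$clusters[[i]]
    if (length(cl) >= 3L) {
      ic <- information_centrality(graph, cl)
      ic[is.na(ic)] <- -Inf
      reps[i] <- cl[argmax_lex(ic[cl], cl, "information centrality")]
    } else {
      vars <- apply(X[, cl, drop = FALSE], 2L, stats::var)
      reps[i] <- cl[argmax_lex(vars, cl, "variance")]
    }
  }
  clusters$representative <- reps
  clusters$p <- length(unique(reps))
  clusters
}

#' Assemble the reduced n x p predictor matrix
#'
#' Takes the panel columns of the distinct representatives, in order of
#' first appearance; each column is copied bit-identically from the panel.
#'
#' @param panel Complete \code{biomarker_panel}.
#' @param clusters \code{overlapping_cluster_set} with representatives set.
#' @return \code{reduced_biomarker_matrix}: \code{X} (n x p, columns named by
#'   representatives), \code{provenance} (per column: the clusters it
#'   represents and their members).
#' @export
reduce_biomarkers <- function(panel, clusters) {
  if (anyNA(clusters$representative))
    stop_netpls("representatives are not set; run select_representatives()",
                "netpls_invalid_argument")
  reps <- unique(clusters$representative)
  missing <- setdiff(reps, colnames(panel$values))
  if (length(missing))
    stop_netpls(paste0("representative(s) not in panel: ",
                       paste(missing, collapse = ", ")),
                "netpls_internal_consistency")
  X <- panel$values[, reps, drop = FALSE]
  prov <- lapply(reps, function(r) {
    idx <- which(clusters$representative == r)
    list(clusters = idx, members = clusters$clusters[idx])
  })
  names(prov) <- reps
  structure(list(X = X, provenance = prov), class = "reduced_biomarker_matrix")
}
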