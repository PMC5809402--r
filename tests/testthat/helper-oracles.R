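# Independent oracles used by the tests. These deliberately take different
# computational routes from the package implementation.

# Information-centrality oracle via effective resistances from the Moore-
# Penrose pseudoinverse of the Laplacian: IC_i = n / sum_j r_ij with
# r_ij = L+_ii + L+_jj - 2 L+_ij.
ic_oracle <- function(adj) {
  n <- nrow(adj)
  L <- diag(rowSums(adj)) - adj
  Lp <- MASS::ginv(L)
  r <- outer(diag(Lp), diag(Lp), "+") - 2 * Lp
  n / rowSums(r)
}

# all set partitions of 1..n as restricted-growth strings
set_partitions <- function(n) {
  out <- list()
  rec <- function(s, mx) {
    if (length(s) == n) { out[[length(out) + 1L]] <<- s; return(invisible()) }
    for (v in seq_len(mx + 1L)) rec(c(s, v), max(mx, v))
  }
  rec(1L, 1L)
  out
}

# partition density of an edge partition given an edge list (2-col matrix)
pd_oracle <- function(membership, el) {
  M <- nrow(el)
  d <- 0
  for (cid in unique(membership)) {
    e <- membership == cid
    m_c <- sum(e)
    n_c <- length(unique(as.vector(el[e, , drop = FALSE])))
    if (n_c > 2L) d <- d + m_c * (m_c - n_c + 1) / ((n_c - 2) * (n_c - 1))
  }
  2 * d / M
}

# classical NIPALS PLS2 (regression mode) on pre-processed matrices;
# returns score matrices for k components
nipals_pls <- function(X, Y, k, tol = 1e-10, max_iter = 2000) {
  Tm <- matrix(0, nrow(X), k); Um <- matrix(0, nrow(X), k)
  for (h in seq_len(k)) {
    u <- Y[, which.max(apply(Y, 2, var))]
    for (i in seq_len(max_iter)) {
      v <- drop(crossprod(X, u)); v <- v / sqrt(sum(v^2))
      tt <- drop(X %*% v)
      w <- drop(crossprod(Y, tt)); w <- w / sqrt(sum(w^2))
      u_new <- drop(Y %*% w)
      if (sqrt(sum((u_new - u)^2)) < tol * sqrt(sum(u_new^2))) { u <- u_new; break }
      u <- u_new
    }
    l <- drop(crossprod(X, tt)) / sum(tt^2)
    m <- drop(crossprod(Y, tt)) / sum(tt^2)
    X <- X - tcrossprod(tt, l)
    Y <- Y - tcrossprod(tt, m)
    Tm[, h] <- tt; Um[, h] <- u
  }
  list(T = Tm, U = Um)
}

# the two-triangles-sharing-a-vertex graph used in several clustering tests
two_triangle_graph <- function() {
  dependency_graph_from_edges(rbind(
    c("A", "B"), c("A", "C"), c("B", "C"),
    c("C", "D"), c("C", "E"), c("D", "E")))
}

# small complete biomarker panel with b independent correlated blocks
block_panel <- function(n, block_sizes, rho, seed) {
  set.seed(seed)
  p0 <- sum(block_sizes)
  X <- matrix(0, n, p0)
  nm <- character(p0)
  col0 <- 0L
  for (b in seq_along(block_sizes)) {
    sz <- block_sizes[b]
    s <- rnorm(n)
    X[, col0 + seq_len(sz)] <- sqrt(rho) * s +
      sqrt(1 - rho) * matrix(rnorm(n * sz), n, sz)
    nm[col0 + seq_len(sz)] <- sprintf("blk%02d_v%d", b, seq_len(sz))
    col0 <- col0 + sz
  }
  colnames(X) <- nm
  biomarker_panel(X)
}

# representative-identifiable block panel: each block has one low-noise hub
# plus four noisier peripherals of the same latent block factor, so a
# structure-aware representative choice (the hub) is strictly better than a
# variance-based one (a peripheral)
hub_block_panel <- function(n, nblocks, seed) {
  set.seed(seed)
  p0 <- nblocks * 5L
  X <- matrix(0, n, p0)
  nm <- character(p0)
  f <- matrix(rnorm(n * nblocks), n, nblocks)
  for (b in seq_len(nblocks)) {
    j0 <- (b - 1L) * 5L
    X[, j0 + 1L] <- f[, b] + 0.4 * rnorm(n)
    for (j in 2:5) X[, j0 + j] <- f[, b] + rnorm(n)
    nm[j0 + (1:5)] <- sprintf("blk%02d_%s", b, c("hub", paste0("p", 1:4)))
  }
  colnames(X) <- nm
  list(panel = biomarker_panel(X), factors = f)
}
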