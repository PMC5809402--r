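test_that("imputation leaves observed values alone and honors collinearity", {
  set.seed(3)
  X <- matrix(rnorm(200), 50, 4)
  colnames(X) <- letters[1:4]
  p0 <- biomarker_panel(X)
  expect_identical(impute_missing(p0), p0)      # complete panel unchanged

  X2 <- X
  X2[, 2] <- 3 * X2[, 1] - 1                    # perfectly collinear pair
  truth <- X2[7, 2]
  X2[7, 2] <- NA
  imp <- impute_missing(biomarker_panel(X2), seed = 1)
  expect_lt(abs(imp$values[7, 2] - truth), 1e-6)
  obs <- !is.na(X2)
  expect_identical(imp$values[obs], X2[obs])

  X3 <- X; X3[, 3] <- NA
  expect_error(impute_missing(biomarker_panel(X3)),
               class = "netpls_unimputable_column")
})

test_that("forest estimation picks the max-weight spanning structure", {
  # A -> B -> C chain: rho(AB) = rho(BC) = 0.9, rho(AC) = 0.81; the
  # max-weight forest over MI weights is {A-B, B-C} (enumerating all three
  # spanning trees of the triangle confirms it: the A-C edge is weakest)
  set.seed(5)
  n <- 4000
  a <- rnorm(n)
  b <- 0.9 * a + sqrt(1 - 0.81) * rnorm(n)
  c <- 0.9 * b + sqrt(1 - 0.81) * rnorm(n)
  g <- estimate_dependency_graph(cbind(A = a, B = b, C = c))
  el <- apply(igraph::as_edgelist(g$graph), 1, function(e)
    paste(sort(e), collapse = "-"))
  expect_setequal(el, c("A-B", "B-C"))

  # independent variables: BIC pruning leaves (almost) nothing
  set.seed(6)
  g2 <- estimate_dependency_graph(matrix(rnorm(2000 * 6), 2000, 6))
  expect_lte(igraph::ecount(g2$graph), 1L)

  # forest property: always acyclic
  for (s in 1:5) {
    pan <- block_panel(100, c(4, 4, 4), 0.6, seed = s)
    gf <- estimate_dependency_graph(pan)
    expect_equal(igraph::ecount(gf$graph),        # acyclic: |E| = |V| - #components
                 igraph::vcount(gf$graph) - igraph::components(gf$graph)$no)
  }

  expect_error(estimate_dependency_graph(matrix(rnorm(4), 2, 2)),
               class = "netpls_insufficient_data")
})

test_that("two correlated variables yield a single BIC-passing edge", {
  set.seed(8)
  a <- rnorm(300); b <- 0.7 * a + rnorm(300)
  g <- estimate_dependency_graph(cbind(A = a, B = b))
  expect_equal(igraph::ecount(g$graph), 1L)
})

test_that("link clustering finds overlapping communities on the two-triangle graph", {
  cl <- cluster_links(two_triangle_graph())
  expect_length(cl$clusters, 2L)
  expect_setequal(vapply(cl$clusters, paste, "", collapse = ""),
                  c("ABC", "CDE"))
  # overlap semantics: the shared vertex appears in both clusters
  expect_true(all(vapply(cl$clusters, function(x) "C" %in% x, TRUE)))

  # brute-force partition-density oracle over all 203 partitions of 6 edges
  g <- two_triangle_graph()$graph
  el <- igraph::as_edgelist(g, names = FALSE)
  parts <- set_partitions(igraph::ecount(g))
  dens <- vapply(parts, pd_oracle, numeric(1), el = el)
  best <- parts[[which.max(dens)]]
  groups <- split(seq_len(nrow(el)), best)
  best_sets <- lapply(groups, function(e)
    sort(unique(igraph::V(g)$name[as.vector(el[e, , drop = FALSE])])))
  expect_setequal(vapply(best_sets, paste, "", collapse = ""),
                  c("ABC", "CDE"))
})

test_that("degenerate link-community cases behave as specified", {
  # a single triangle -> one 3-vertex cluster
  tri <- dependency_graph_from_edges(rbind(c("A", "B"), c("B", "C"), c("A", "C")))
  cl <- cluster_links(tri)
  expect_length(cl$clusters, 1L)
  expect_setequal(cl$clusters[[1]], c("A", "B", "C"))

  # two disconnected edges -> two 2-vertex clusters
  ee <- dependency_graph_from_edges(rbind(c("A", "B"), c("C", "D")))
  cl2 <- cluster_links(ee)
  expect_length(cl2$clusters, 2L)
  expect_true(all(lengths(cl2$clusters) == 2L))

  # edgeless graph -> empty set with a warning
  g0 <- dependency_graph_from_edges(matrix(character(0), 0, 2),
                                    vertices = c("A", "B"))
  expect_warning(cl3 <- cluster_links(g0), "no edges")
  expect_length(cl3$clusters, 0L)

  # determinism: same graph -> identical clusters
  expect_identical(cluster_links(two_triangle_graph())$clusters,
                   cluster_links(two_triangle_graph())$clusters)
})

test_that("tree components decompose into stars around branch vertices", {
  # path A-B-C-D: stars at B (A-B, B-C by lexicographic tie) and C (C-D)
  path <- dependency_graph_from_edges(rbind(c("A", "B"), c("B", "C"), c("C", "D")))
  cl <- cluster_links(path)
  expect_true(all(lengths(cl$clusters) >= 2L))
  expect_setequal(unique(unlist(cl$clusters)), c("A", "B", "C", "D"))
  # star K1,4: a single community containing all five vertices
  star <- dependency_graph_from_edges(cbind("hub", paste0("leaf", 1:4)))
  cls <- cluster_links(star)
  expect_length(cls$clusters, 1L)
  expect_length(cls$clusters[[1]], 5L)
})

test_that("information centrality matches structural expectations", {
  star <- dependency_graph_from_edges(cbind("C", c("A", "B", "D")))
  ic <- information_centrality(star)
  expect_gt(ic["C"], max(ic[c("A", "B", "D")]))

  path <- dependency_graph_from_edges(rbind(c("A", "B"), c("B", "C")))
  icp <- information_centrality(path)
  expect_gt(icp["B"], icp["A"])
  expect_equal(unname(icp["A"]), unname(icp["C"]))  # symmetry forces the tie

  k4 <- dependency_graph_from_edges(t(combn(c("A", "B", "C", "D"), 2)))
  ick <- information_centrality(k4)
  expect_equal(max(ick) - min(ick), 0, tolerance = 1e-12)

  expect_error(information_centrality(star, c("A", "B")),
               class = "netpls_small_cluster")
})

test_that("information centrality equals the effective-resistance oracle on random graphs", {
  set.seed(17)
  for (rep in 1:20) {
    nv <- sample(3:7, 1)
    repeat {
      adj <- matrix(0, nv, nv)
      adj[upper.tri(adj)] <- runif(nv * (nv - 1) / 2) < 0.5
      adj <- adj + t(adj)
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      if (igraph::is_connected(g) && sum(adj) > 0) break
    }
    dimnames(adj) <- list(paste0("v", 1:nv), paste0("v", 1:nv))
    dg <- dependency_graph_from_edges(t(apply(which(upper.tri(adj) & adj == 1,
                                                    arr.ind = TRUE), 1,
                                              function(i) rownames(adj)[i])))
    ic <- information_centrality(dg, use_weights = FALSE)
    oracle <- ic_oracle(adj[names(ic), names(ic)])
    expect_equal(unname(ic), oracle, tolerance = 1e-9)
  }
})

test_that("representative selection applies the centrality and variance rules", {
  set.seed(21)
  X <- matrix(rnorm(400), 100, 4)
  X[, 1] <- X[, 1] * 2                     # var(A) > var(B)
  colnames(X) <- c("A", "B", "C", "D")
  pan <- biomarker_panel(X)
  g <- dependency_graph_from_edges(rbind(c("A", "B"), c("C", "A"), c("C", "B"),
                                         c("C", "D")))
  cl2 <- structure(list(clusters = list(c("A", "B")),
                        representative = NA_character_, p = NA_integer_,
                        edge_communities = list()),
                   class = "overlapping_cluster_set")
  out <- select_representatives(cl2, g, pan)
  expect_identical(out$representative, "A")   # variance rule, size 2

  cl4 <- structure(list(clusters = list(c("A", "B", "C", "D")),
                        representative = NA_character_, p = NA_integer_,
                        edge_communities = list()),
                   class = "overlapping_cluster_set")
  out4 <- select_representatives(cl4, g, pan)
  expect_identical(out4$representative, "C")  # star center, centrality rule
})

test_that("reduction collapses duplicate representatives and copies columns bit-identically", {
  set.seed(23)
  X <- matrix(rnorm(300), 100, 3)
  colnames(X) <- c("X1", "X2", "Z")
  pan <- biomarker_panel(X)
  cl <- structure(list(clusters = list(c("Z", "X1"), c("Z", "X2")),
                       representative = c("Z", "Z"), p = 1L,
                       edge_communities = list()),
                  class = "overlapping_cluster_set")
  red <- reduce_biomarkers(pan, cl)
  expect_equal(ncol(red$X), 1L)
  expect_identical(unname(red$X[, "Z"]), unname(X[, "Z"]))
  expect_equal(red$provenance$Z$clusters, c(1L, 2L))

  cl$representative <- c("Z", "nope")
  expect_error(reduce_biomarkers(pan, cl), class = "netpls_internal_consistency")
})

test_that("planted correlation blocks are recovered with in-block representatives", {
  hits <- 0L; total <- 0L
  for (s in 1:10) {
    pan <- block_panel(500, rep(5L, 4L), 0.7, seed = 100 + s)
    g <- estimate_dependency_graph(pan)
    cl <- suppressWarnings(suppressMessages(cluster_links(g)))
    cl <- suppressMessages(select_representatives(cl, g, pan))
    blocks <- split(colnames(pan$values),
                    rep(seq_len(4), each = 5))
    for (blk in blocks) {
      total <- total + 1L
      ok <- any(vapply(seq_along(cl$clusters), function(i)
        mean(cl$clusters[[i]] %in% blk) > 0.5 &&
          cl$representative[i] %in% blk, TRUE))
      hits <- hits + ok
    }
  }
  expect_gte(hits / total, 0.9)
})
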