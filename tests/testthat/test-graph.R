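test_that("backbone equals the exhaustive optimum on small complete graphs", {
  for (n in 4:6) {
    for (s in 1:3) {
      w <- random_pli_matrix(n, seed = 100 * n + s)
      got <- spanning_backbone(w)
      want <- brute_force_max_tree(w)
      expect_equal(unname(got$adjacency), unname(want$adjacency),
                   info = sprintf("n=%d seed=%d", n, s))
      expect_equal(got$total_weight, want$total_weight)
    }
  }
})

test_that("backbone has N-1 links, is connected and acyclic across sizes", {
  for (n in c(5, 12, 33, 78)) {
    w <- random_pli_matrix(n, seed = n)
    bb <- spanning_backbone(w)
    expect_identical(sum(bb$adjacency) / 2, n - 1)
    g <- igraph::graph_from_adjacency_matrix(bb$adjacency, mode = "undirected")
    expect_true(igraph::is_connected(g))
    expect_identical(igraph::girth(g)$girth, Inf)  # no cycles
  }
})

test_that("backbone out-weighs random spanning trees", {
  w <- random_pli_matrix(20, seed = 5)
  bb <- spanning_backbone(w)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  set.seed(17)
  worst <- vapply(1:1000, function(i) {
    st <- igraph::sample_spanning_tree(g)
    sum(w[igraph::ends(g, st, names = FALSE)])
  }, numeric(1))
  expect_gte(bb$total_weight, max(worst))
})

test_that("star-favoring weights yield the star backbone", {
  n <- 10
  w <- matrix(0.1, n, n); w[1, ] <- w[, 1] <- 0.9; diag(w) <- 0
  bb <- spanning_backbone(w)
  star <- matrix(0L, n, n); star[1, -1] <- star[-1, 1] <- 1L
  expect_identical(unname(bb$adjacency), star)
})

test_that("backbone errors on a disconnected weight graph", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.5
  w[3, 4] <- w[4, 3] <- 0.5
  expect_error(spanning_backbone(w), "disconnected")
})

test_that("multiplex block structure and link counts match the closed forms", {
  adj <- spanning_backbone(random_pli_matrix(78, seed = 2))$adjacency
  layers <- make_tree_layers(adj, 6)
  mp <- build_multiplex(layers, 1)
  expect_identical(dim(mp$supra), c(468L, 468L))
  expect_identical(mp$supra, t(mp$supra))
  intra <- sum(vapply(1:6, function(l) {
    rng <- ((l - 1) * 78 + 1):(l * 78)
    sum(mp$supra[rng, rng]) / 2
  }, numeric(1)))
  expect_identical(intra, 6 * 77)                  # L (N-1)
  expect_identical(sum(mp$supra) / 2 - intra, 78 * 6 * 5 / 2)  # N L (L-1) / 2

  # generic sizes
  for (cfg in list(c(3, 10), c(2, 5), c(4, 7))) {
    L <- cfg[1]; n <- cfg[2]
    a <- spanning_backbone(random_pli_matrix(n, seed = n + L))$adjacency
    m <- build_multiplex(make_tree_layers(a, L), 1)
    expect_identical(sum(m$supra) / 2, L * (n - 1) + n * L * (L - 1) / 2)
  }

  # single layer, weight 1 -> supra equals the layer
  single <- build_multiplex(make_tree_layers(adj, 1), 1)
  expect_identical(unname(single$supra), unname(adj * 1))

  expect_error(build_multiplex(list(adj, adj[1:5, 1:5])), "same node count")
})

test_that("identical layers reduce multilayer EC to single-layer EC", {
  a <- spanning_backbone(random_pli_matrix(30, seed = 9))$adjacency
  mp <- build_multiplex(make_tree_layers(a, 6), 1)
  ec <- multilayer_eigenvector_centrality(mp)
  # independent oracle: igraph single-layer eigenvector centrality
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  ref <- igraph::eigen_centrality(g)$vector
  cosine <- sum(ec$values * ref) / sqrt(sum(ec$values^2) * sum(ref^2))
  expect_gt(cosine, 1 - 1e-10)
})

test_that("identical star layers put the center on top with equal leaves", {
  n <- 12
  star <- matrix(0L, n, n); star[1, -1] <- star[-1, 1] <- 1L
  dimnames(star) <- list(paste0("R", 1:n), paste0("R", 1:n))
  ec <- multilayer_eigenvector_centrality(build_multiplex(make_tree_layers(star, 4)))
  expect_identical(unname(which.max(ec$values)), 1L)
  expect_lt(diff(range(ec$values[-1])), 1e-10)
})

test_that("supra eigenpair satisfies its defining residual", {
  a <- spanning_backbone(random_pli_matrix(25, seed = 13))$adjacency
  mp <- build_multiplex(make_tree_layers(a, 3), 1)
  ec <- multilayer_eigenvector_centrality(mp)
  v <- ec$supra_vector
  resid <- sqrt(sum((mp$supra %*% v - ec$eigenvalue * v)^2)) / sqrt(sum(v^2))
  expect_lt(resid, 1e-8)
  expect_true(all(ec$values > 0))  # Perron-Frobenius on a connected supra
})

test_that("centrality is equivariant under node relabeling", {
  a <- spanning_backbone(random_pli_matrix(15, seed = 21))$adjacency
  ec <- multilayer_eigenvector_centrality(build_multiplex(make_tree_layers(a, 3)))
  set.seed(4)
  p <- sample(15)
  ap <- a[p, p]
  ecp <- multilayer_eigenvector_centrality(build_multiplex(make_tree_layers(ap, 3)))
  expect_equal(unname(ecp$values), unname(ec$values[p]), tolerance = 1e-9)
})

test_that("interlayer weight does not move the identical-layers eigenvector", {
  a <- spanning_backbone(random_pli_matrix(20, seed = 31))$adjacency
  base <- multilayer_eigenvector_centrality(
    build_multiplex(make_tree_layers(a, 4), 1))$values
  for (w in c(0.5, 2, 10)) {
    got <- multilayer_eigenvector_centrality(
      build_multiplex(make_tree_layers(a, 4), w))$values
    expect_equal(unname(got), unname(base), tolerance = 1e-8)
  }
})

test_that("disconnected supra matrices are rejected", {
  a <- matrix(0L, 4, 4); a[1, 2] <- a[2, 1] <- 1L; a[3, 4] <- a[4, 3] <- 1L
  mp <- build_multiplex(make_tree_layers(a, 2), 0)
  expect_error(multilayer_eigenvector_centrality(mp), "disconnected")
})

test_that("subnetwork_mean averages the right nodes", {
  v <- c(R1 = 0.2, R2 = 0.4, R3 = 0.6, R4 = 1)
  ec <- structure(list(values = v, aggregation = "mean", eigenvalue = 1,
                       node_labels = names(v)),
                  class = "centrality_vector")
  expect_identical(subnetwork_mean(ec, c("R1", "R2", "R3")), 0.4)
  expect_identical(subnetwork_mean(ec, "R4"), 1)
  expect_identical(subnetwork_mean(ec, 1:4), mean(v))
  uniform <- ec; uniform$values[] <- 0.7
  expect_identical(subnetwork_mean(uniform, c(2, 4)), 0.7)
  expect_error(subnetwork_mean(ec, character()), "empty")
  expect_error(subnetwork_mean(ec, "R9"), "R9")
})
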