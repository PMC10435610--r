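# Shared fixtures and independent oracles.

# bin-aligned sinusoid: frequency k * fs / n is an exact DFT line
aligned_freq <- function(k, n, fs) k * fs / n

sinusoid_matrix <- function(n, fs, freqs, phases = rep(0, length(freqs))) {
  t <- (0:(n - 1)) / fs
  m <- vapply(seq_along(freqs), function(i) cos(2 * pi * freqs[i] * t + phases[i]),
              numeric(n))
  colnames(m) <- paste0("R", seq_along(freqs))
  m
}

random_pli_matrix <- function(n, seed) {
  set.seed(seed)
  w <- matrix(stats::runif(n * n), n)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  dimnames(w) <- list(paste0("R", 1:n), paste0("R", 1:n))
  w
}

# exhaustive maximum-weight spanning tree: enumerate all (N-1)-edge
# subsets of the complete graph, keep connected acyclic ones
brute_force_max_tree <- function(w) {
  n <- nrow(w)
  edges <- which(upper.tri(w), arr.ind = TRUE)
  combos <- utils::combn(nrow(edges), n - 1)
  best <- -Inf
  best_adj <- NULL
  for (ci in seq_len(ncol(combos))) {
    sel <- edges[combos[, ci], , drop = FALSE]
    g <- igraph::graph_from_edgelist(sel, directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    if (!igraph::is_connected(g)) next
    tw <- sum(w[sel])
    if (tw > best) {
      best <- tw
      adj <- matrix(0L, n, n)
      adj[sel] <- 1L
      best_adj <- adj + t(adj)
    }
  }
  list(adjacency = best_adj, total_weight = best)
}

# independent backward eliminator on a plain numeric design matrix,
# using QR algebra directly (no formula interface, no standardization)
oracle_backward <- function(y, X, threshold = 0.10) {
  active <- seq_len(ncol(X))
  repeat {
    if (length(active) == 0L) return(integer(0))
    Xa <- cbind(1, X[, active, drop = FALSE])
    qr_fit <- qr(Xa)
    beta <- qr.coef(qr_fit, y)
    res <- y - Xa %*% beta
    df <- length(y) - ncol(Xa)
    sigma2 <- sum(res^2) / df
    XtXinv <- chol2inv(qr.R(qr_fit))
    se <- sqrt(diag(XtXinv) * sigma2)
    tval <- beta / se
    pv <- 2 * stats::pt(abs(tval[-1]), df, lower.tail = FALSE)
    worst <- which.max(pv)
    if (pv[worst] >= threshold) active <- active[-worst] else return(active)
  }
}

make_tree_layers <- function(adj, L, bands = names(default_bands())) {
  lapply(seq_len(L), function(i) {
    structure(list(adjacency = adj, band = bands[i],
                   total_weight = sum(adj) / 2),
              class = "spanning_tree_layer")
  })
}
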