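# Spanning-tree backbones, the multiplex supra-adjacency matrix, and
# multilayer eigenvector centrality.

#' Maximum-weight spanning tree backbone of a connectivity matrix
#'
#' Binarizes a weighted network by Kruskal's algorithm, keeping the
#' spanning tree that maximizes total connection weight (equivalently the
#' minimum spanning tree on distance `1 - w`): the strongest-connection
#' backbone, with `N - 1` links, no cycles, and every node included.
#' Deterministic: equal-weight edges are broken lexicographically on
#' `(min node index, max node index)`.
#'
#' @param conn A [connectivity_matrix], or a symmetric numeric matrix with
#'   zero diagonal. Entries of exactly zero are treated as absent edges.
#' @return A `spanning_tree_layer`: binary symmetric adjacency (field
#'   `adjacency`), band label (`band`), and the total retained weight
#'   (`total_weight`).
#' @export
spanning_backbone <- function(conn) {
  if (inherits(conn, "connectivity_matrix")) {
    w <- conn$weights
    band_name <- if (is.null(conn$band)) NA_character_ else conn$band$name
  } else {
    w <- as.matrix(conn)
    band_name <- NA_character_
  }
  n <- nrow(w)
  stopifnot(ncol(w) == n, n >= 2L)
  idx <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no nonzero edges: graph is fully disconnected")
  ew <- w[idx]
  # decreasing weight, ties by (min node, max node) ascending
  ord <- order(-ew, idx[, 1], idx[, 2])
  parent <- seq_len(n)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  adj <- matrix(0L, n, n)
  taken <- 0L
  total <- 0
  for (e in ord) {
    a <- idx[e, 1]; b <- idx[e, 2]
    ra <- find_root(a); rb <- find_root(b)
    if (ra != rb) {
      parent[ra] <- rb
      adj[a, b] <- adj[b, a] <- 1L
      total <- total + ew[e]
      taken <- taken + 1L
      if (taken == n - 1L) break
    }
  }
  if (taken < n - 1L) {
    roots <- vapply(seq_len(n), find_root, integer(1))
    comps <- split(seq_len(n), roots)
    stop("weight graph is disconnected; components: ",
         paste(vapply(comps, function(cc) paste0("{", paste(cc, collapse = ","), "}"),
                      character(1)), collapse = " "))
  }
  dimnames(adj) <- dimnames(w)
  structure(list(adjacency = adj, band = band_name, total_weight = total),
            class = "spanning_tree_layer")
}

#' @export
print.spanning_tree_layer <- function(x, ...) {
  cat(sprintf("<spanning_tree_layer> band %s: %d nodes, %d links, total weight %.4g\n",
              x$band, nrow(x$adjacency), sum(x$adjacency) / 2, x$total_weight))
  invisible(x)
}

#' Assemble the multiplex supra-adjacency matrix
#'
#' Stacks L spanning-tree layers of N nodes into an `(L*N) x (L*N)` block
#' matrix: layer adjacencies on the diagonal blocks, and
#' `interlayer_weight` times the identity in every off-diagonal block, so
#' each node is linked only to its own replicas in the other layers. With
#' unit interlayer weight the multiplex is binary and carries
#' `L * (N - 1)` intralayer plus `N * L * (L - 1) / 2` interlayer
#' undirected links.
#'
#' @param layers List of `spanning_tree_layer` objects (or plain adjacency
#'   matrices) sharing N and node order.
#' @param interlayer_weight Weight of node-to-replica links (default 1).
#' @return A `multiplex_network` with fields `supra`, `L`, `N`,
#'   `layer_order`, `interlayer_weight`, `node_labels`.
#' @export
build_multiplex <- function(layers, interlayer_weight = 1) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  adjs <- lapply(layers, function(l) {
    if (inherits(l, "spanning_tree_layer")) l$adjacency else as.matrix(l)
  })
  ns <- vapply(adjs, nrow, integer(1))
  if (length(unique(ns)) != 1L ||
      !all(vapply(adjs, ncol, integer(1)) == ns[1])) {
    stop("all layers must be square with the same node count; got sizes ",
         paste(ns, collapse = ", "))
  }
  n <- ns[1]
  L <- length(adjs)
  layer_order <- vapply(seq_along(layers), function(i) {
    l <- layers[[i]]
    if (inherits(l, "spanning_tree_layer") && !is.na(l$band)) l$band
    else paste0("layer", i)
  }, character(1))
  supra <- matrix(0, L * n, L * n)
  for (l in seq_len(L)) {
    rng <- ((l - 1L) * n + 1L):(l * n)
    supra[rng, rng] <- adjs[[l]]
  }
  if (L > 1L) {
    for (l1 in seq_len(L - 1L)) {
      for (l2 in (l1 + 1L):L) {
        r1 <- ((l1 - 1L) * n + 1L):(l1 * n)
        r2 <- ((l2 - 1L) * n + 1L):(l2 * n)
        supra[cbind(r1, r2)] <- interlayer_weight
        supra[cbind(r2, r1)] <- interlayer_weight
      }
    }
  }
  node_labels <- rownames(adjs[[1]])
  if (is.null(node_labels)) node_labels <- paste0("R", seq_len(n))
  structure(list(supra = supra, L = L, N = n, layer_order = layer_order,
                 interlayer_weight = interlayer_weight,
                 node_labels = node_labels),
            class = "multiplex_network")
}

#' @export
print.multiplex_network <- function(x, ...) {
  cat(sprintf("<multiplex_network> L = %d layers x N = %d nodes (supra %d x %d), interlayer weight %g\n",
              x$L, x$N, nrow(x$supra), ncol(x$supra), x$interlayer_weight))
  cat("  layers:", paste(x$layer_order, collapse = ", "), "\n")
  invisible(x)
}

#' Multilayer eigenvector centrality
#'
#' Leading eigenvector of the supra-adjacency matrix (nonnegative by
#' Perron-Frobenius on a connected supra graph), with each node's L layer
#' replicas aggregated by the configured rule (default: mean) and the
#' aggregated vector rescaled so its maximum entry is 1. The leading
#' eigenvalue and the raw supra eigenvector are returned alongside for
#' diagnostics.
#'
#' @param mplex A [build_multiplex] result.
#' @param aggregation `"mean"` or `"sum"` over layer replicas (identical
#'   up to the final rescaling).
#' @return A `centrality_vector`: `values` (length N, max 1),
#'   `aggregation`, `eigenvalue`, `supra_vector` (length L*N, unit norm),
#'   `node_labels`.
#' @export
multilayer_eigenvector_centrality <- function(mplex, aggregation = c("mean", "sum")) {
  stopifnot(inherits(mplex, "multiplex_network"))
  aggregation <- match.arg(aggregation)
  g <- igraph::graph_from_adjacency_matrix(mplex$supra != 0, mode = "undirected")
  if (!igraph::is_connected(g)) {
    comps <- igraph::components(g)
    stop("supra matrix is disconnected (", comps$no, " components); ",
         "centrality is defined only on connected multiplex networks")
  }
  es <- eigen(mplex$supra, symmetric = TRUE)
  v <- es$vectors[, 1]
  if (sum(v) < 0) v <- -v
  if (min(v) < -1e-8) {
    stop("leading eigenvector has negative entries (min ", format(min(v)),
         "); supra matrix is not a valid nonnegative adjacency")
  }
  v <- pmax(v, 0)
  v <- v / sqrt(sum(v^2))
  reps <- matrix(v, nrow = mplex$N, ncol = mplex$L)
  agg <- if (aggregation == "mean") rowMeans(reps) else rowSums(reps)
  values <- agg / max(agg)
  names(values) <- mplex$node_labels
  structure(list(values = values, aggregation = aggregation,
                 eigenvalue = es$values[1], supra_vector = v,
                 node_labels = mplex$node_labels),
            class = "centrality_vector")
}

#' @export
print.centrality_vector <- function(x, ...) {
  cat(sprintf("<centrality_vector> %d nodes, aggregation = %s, leading eigenvalue %.6g\n",
              length(x$values), x$aggregation, x$eigenvalue))
  invisible(x)
}

#' Mean centrality over a node subset
#'
#' Averages nodal centrality values over a named subnetwork (e.g. the
#' frontoparietal node set), giving one scalar per subject per timepoint.
#'
#' @param ec A `centrality_vector` (or plain named numeric vector).
#' @param subnet Integer indices into the node vector, or character labels
#'   resolved against the node labels.
#' @return Arithmetic mean of the selected values.
#' @export
subnetwork_mean <- function(ec, subnet) {
  values <- if (inherits(ec, "centrality_vector")) ec$values else ec
  if (length(subnet) == 0L) stop("subnetwork is empty")
  if (is.character(subnet)) {
    missing <- setdiff(subnet, names(values))
    if (length(missing)) {
      stop("subnetwork labels not found: ", paste(missing, collapse = ", "))
    }
    idx <- match(subnet, names(values))
  } else {
    idx <- as.integer(subnet)
    if (any(idx < 1L | idx > length(values))) {
      stop("subnetwork indices out of range 1..", length(values))
    }
  }
  if (anyDuplicated(idx)) stop("subnetwork contains duplicate nodes")
  mean(values[idx])
}
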