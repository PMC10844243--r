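#' Network generators and edge-list input
#'
#' Networks are undirected, unweighted, simple [igraph][igraph::igraph-package]
#' graphs. The adjacency matrix `w_ij` used by the dynamics and the theory is
#' obtained with [net_adjacency()].
#'
#' @name networks
NULL

#' Erdos-Renyi random graph with a fixed number of edges
#'
#' Draws a simple undirected graph on `n_nodes` nodes with exactly `n_edges`
#' edges, each edge set equally likely (the G(n, M) model). This matches
#' connecting uniformly random not-yet-adjacent pairs one by one until the
#' requested number of edges is reached. Connectivity is not enforced; query
#' it with [igraph::is_connected()].
#'
#' @param n_nodes Number of nodes.
#' @param n_edges Number of edges; must lie in `[0, n_nodes*(n_nodes-1)/2]`.
#' @return An undirected igraph graph with exactly `n_edges` edges.
#' @examples
#' g <- net_er_fixed(50, 125)
#' igraph::ecount(g) # 125
#' net_average_degree(g) # 5
#' @export
net_er_fixed <- function(n_nodes, n_edges) {
  n_nodes <- as.integer(n_nodes)
  max_edges <- n_nodes * (n_nodes - 1) / 2
  if (n_edges < 0 || n_edges > max_edges) {
    stop("`n_edges` must be between 0 and ", max_edges, " for ", n_nodes,
      " nodes, got ", n_edges,
      call. = FALSE
    )
  }
  idx <- sample.int(max_edges, n_edges)
  # map linear upper-triangle index to a pair (i, j), i < j
  ends <- pair_from_index(idx, n_nodes)
  g <- igraph::graph_from_edgelist(ends, directed = FALSE)
  igraph::add_vertices(g, n_nodes - igraph::vcount(g))
}

# Inverse of the row-major upper-triangle enumeration (1,2), (1,3), ...
pair_from_index <- function(idx, n) {
  if (length(idx) == 0) {
    return(matrix(integer(0), ncol = 2))
  }
  i <- findInterval(idx - 1, cumsum(c(0, (n - 1):1)), left.open = FALSE)
  offset <- idx - c(0, cumsum((n - 1):1))[i]
  cbind(i, i + offset)
}

#' Barabasi-Albert preferential-attachment network
#'
#' Grows a network from a complete triangle seed; each new node attaches to
#' `m` distinct existing nodes sampled without replacement with probability
#' proportional to their current degree. With `m = 2` the edge count is
#' exactly `3 + m * (n_nodes - 3)` (97 edges for 50 nodes).
#'
#' @param n_nodes Final number of nodes (at least 3).
#' @param m Edges added per new node; must not exceed the current graph size.
#' @return An undirected igraph graph.
#' @examples
#' g <- net_ba(50, 2)
#' igraph::ecount(g) # 97 for every seed
#' @export
net_ba <- function(n_nodes, m = 2) {
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 3) stop("`n_nodes` must be at least 3 (triangle seed)", call. = FALSE)
  if (m > 3) stop("`m` must not exceed the seed graph size (3)", call. = FALSE)
  deg <- rep(2L, 3)
  edges <- matrix(c(1L, 2L, 1L, 3L, 2L, 3L), ncol = 2, byrow = TRUE)
  if (n_nodes > 3) {
    edges <- rbind(edges, matrix(0L, nrow = m * (n_nodes - 3L), ncol = 2))
    deg <- c(deg, integer(n_nodes - 3L))
    row <- 4L
    for (v in 4:n_nodes) {
      targets <- sample.int(v - 1L, m, prob = deg[seq_len(v - 1L)])
      edges[row:(row + m - 1L), ] <- cbind(rep(v, m), targets)
      deg[targets] <- deg[targets] + 1L
      deg[v] <- m
      row <- row + m
    }
  }
  igraph::graph_from_edgelist(edges, directed = FALSE)
}

#' Node-fitness random graph
#'
#' Assigns node `i` the fitness `f_i = (i + i0 - 1)^(-alpha)` and connects
#' each pair `(i, j)` independently with probability
#' `f_i * f_j / (sum_l f_l)^2` (clipped at 1), then returns the largest
#' connected component. The offset `i0 = N^(1 - 1/alpha) *
#' (10 * sqrt(2) * |1 - alpha|)^(1/alpha)` caps the maximum expected degree;
#' the absolute value `|1 - alpha|` is this package's reading of the
#' construction, which is otherwise complex-valued for `alpha > 1`.
#'
#' With independent pair connections the expected edge count is below 1/2
#' for any `N` (the pair probabilities sum to less than one), so dense
#' realizations require the fixed-edge-count variant: when `n_edges` is
#' given, pairs are drawn repeatedly with probability proportional to
#' `f_i * f_j` (the same per-attempt pair probability) and added if not yet
#' adjacent, until `n_edges` distinct edges exist — the static-model
#' construction that yields, e.g., 125-edge networks on 50 nodes.
#'
#' @param n_nodes Number of nodes before extracting the largest component.
#' @param alpha Positive exponent controlling degree heterogeneity.
#' @param n_edges Optional target edge count for the fixed-edge-count
#'   variant; `NULL` (default) connects each pair independently.
#' @return The largest connected component, an undirected igraph graph.
#' @export
net_fitness <- function(n_nodes, alpha = 2, n_edges = NULL) {
  if (alpha <= 0) stop("`alpha` must be positive", call. = FALSE)
  p <- net_fitness_probs(n_nodes, alpha)
  if (is.null(n_edges)) {
    u <- matrix(0, n_nodes, n_nodes)
    ut <- upper.tri(u)
    u[ut] <- runif(sum(ut))
    adj <- (u < p) & ut
  } else {
    max_edges <- n_nodes * (n_nodes - 1) / 2
    if (n_edges > max_edges) stop("`n_edges` exceeds the pair count", call. = FALSE)
    adj <- matrix(FALSE, n_nodes, n_nodes)
    ut <- which(upper.tri(adj))
    got <- 0L
    while (got < n_edges) {
      pick <- sample(ut, 1, prob = p[ut] * !adj[ut])
      adj[pick] <- TRUE
      got <- got + 1L
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj | t(adj), mode = "undirected")
  net_largest_component(g)
}

#' Fitness-model connection probabilities
#'
#' The per-pair connection probability matrix of [net_fitness()], exposed so
#' that the generator can be validated against its defining formula.
#'
#' @inheritParams net_fitness
#' @return A symmetric `n_nodes` x `n_nodes` matrix of probabilities with
#'   zero diagonal.
#' @export
net_fitness_probs <- function(n_nodes, alpha = 2) {
  i0 <- n_nodes^(1 - 1 / alpha) * (10 * sqrt(2) * abs(1 - alpha))^(1 / alpha)
  f <- (seq_len(n_nodes) + i0 - 1)^(-alpha)
  p <- pmin(outer(f, f) / sum(f)^2, 1)
  diag(p) <- 0
  p
}

#' Read an undirected edge list
#'
#' One edge per line, two whitespace-separated node labels; lines starting
#' with `#` are comments. Duplicate edges and self-loops are dropped.
#'
#' @param path Path to the edge-list file.
#' @return An undirected simple igraph graph.
#' @export
net_read_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge-list file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(fields) != 2)
  if (length(bad) > 0) {
    stop("malformed edge-list line ", which(keep)[bad[1]], ": ",
      lines[keep][bad[1]],
      call. = FALSE
    )
  }
  ends <- do.call(rbind, fields)
  g <- igraph::graph_from_edgelist(ends, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Largest connected component
#'
#' @param net An igraph graph.
#' @return The induced subgraph on the largest connected component.
#' @export
net_largest_component <- function(net) {
  comp <- igraph::components(net)
  igraph::induced_subgraph(net, which(comp$membership == which.max(comp$csize)))
}

#' Average degree
#'
#' @param net An igraph graph.
#' @return Mean node degree `2E/N`.
#' @export
net_average_degree <- function(net) {
  2 * igraph::ecount(net) / igraph::vcount(net)
}

#' Adjacency matrix of a network
#'
#' @param net An igraph graph.
#' @return A dense symmetric 0/1 matrix with zero diagonal.
#' @export
net_adjacency <- function(net) {
  w <- as.matrix(igraph::as_adjacency_matrix(net, sparse = TRUE))
  storage.mode(w) <- "double"
  w
}

#' Write an edge list
#'
#' @param net An igraph graph.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
net_write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net)
  writeLines(paste(el[, 1], el[, 2]), path)
  invisible(path)
}
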