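# Binarized-graph metrics: clustering, path length, efficiencies, small-world
# normalization against degree-preserving random networks, hub detection.
# All metrics operate on undirected, unweighted, loop-free graphs.

adj_of <- function(net) {
  if (inherits(net, "binary_network")) net$adjacency
  else {
    a <- (as.matrix(net) != 0) * 1
    diag(a) <- 0
    storage.mode(a) <- "double"
    a
  }
}

#' Shortest-path length matrix of a binary network
#'
#' Breadth-first search from every node, carried out as repeated boolean
#' matrix products (cheap at connectome size). Unreachable pairs are `Inf`;
#' the diagonal is 0.
#'
#' @param net a `binary_network` or adjacency matrix.
#' @return numeric N x N matrix of hop counts.
#' @export
distance_matrix <- function(net) {
  a <- adj_of(net)
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  if (n < 2) return(d)
  reach <- a > 0
  d[reach] <- 1
  frontier <- a
  step <- 1L
  repeat {
    frontier <- (frontier %*% a) > 0
    new <- frontier & !reach & !diag(TRUE, n)
    if (!any(new)) break
    step <- step + 1L
    d[new] <- step
    reach <- reach | new
    if (step >= n - 1L) break
  }
  d
}

#' Clustering coefficient
#'
#' Per node: existing edges among its neighbors divided by the theoretically
#' possible `D(D-1)/2`; nodes of degree < 2 score 0. The network value `cp`
#' is the mean over all nodes.
#'
#' @param net a `binary_network` or adjacency matrix.
#' @return list with `cp` (scalar) and `nodal` (per-node vector).
#' @export
clustering_coefficient <- function(net) {
  a <- adj_of(net)
  deg <- rowSums(a)
  tri <- diag(a %*% a %*% a) / 2       # edges among neighbors of each node
  poss <- deg * (deg - 1) / 2
  nodal <- ifelse(poss > 0, tri / poss, 0)
  list(cp = mean(nodal), nodal = nodal)
}

#' Characteristic path length
#'
#' Mean shortest-path length over all ordered node pairs. On a disconnected
#' graph the mean is restricted to reachable pairs and the attribute
#' `disconnected` is set to `TRUE` (an infinite mean would be unusable for
#' random-network normalization).
#'
#' @param net a `binary_network` or adjacency matrix.
#' @return scalar with attribute `disconnected`.
#' @export
characteristic_path_length <- function(net) {
  d <- distance_matrix(net)
  off <- d[row(d) != col(d)]
  fin <- off[is.finite(off)]
  if (!length(fin)) stop("no reachable node pairs: path length undefined")
  structure(mean(fin), disconnected = any(!is.finite(off)))
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over ordered pairs; unreachable pairs
#' contribute 0, so no connectedness requirement.
#' @param net a `binary_network` or adjacency matrix.
#' @return scalar in \[0, 1\].
#' @export
global_efficiency <- function(net) {
  n <- nrow(adj_of(net))
  if (n < 2) stop("global efficiency needs at least 2 nodes")
  mean(nodal_global_efficiency(net))
}

#' Nodal global efficiency
#'
#' Per node, the mean inverse distance to every other node (unreachable
#' contributes 0). The mean over nodes equals [global_efficiency()].
#' @param net a `binary_network` or adjacency matrix.
#' @return per-node numeric vector.
#' @export
nodal_global_efficiency <- function(net) {
  d <- distance_matrix(net)
  n <- nrow(d)
  if (n < 2) stop("nodal efficiency needs at least 2 nodes")
  inv <- 1 / d
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

#' Nodal local efficiency
#'
#' Efficiency of communication within each node's immediate neighborhood:
#' the global efficiency of the subgraph induced on the node's neighbors.
#' By default the node itself is excluded from its neighborhood subgraph
#' (the Latora-Marchiori convention used by standard connectome toolboxes);
#' `include_self = TRUE` evaluates the variant where the subgraph contains
#' the node as well. Nodes of degree < 2 score 0.
#'
#' @param net a `binary_network` or adjacency matrix.
#' @param include_self include the index node in its own neighborhood
#'   subgraph (non-default variant).
#' @return per-node numeric vector in \[0, 1\].
#' @export
nodal_local_efficiency <- function(net, include_self = FALSE) {
  a <- adj_of(net)
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] > 0)
    if (include_self) nb <- sort(c(i, nb))
    k <- length(nb)
    if (k < 2) return(0)
    d <- distance_matrix(a[nb, nb, drop = FALSE])
    inv <- 1 / d
    diag(inv) <- 0
    sum(inv) / (k * (k - 1))
  }, numeric(1))
}

#' Local efficiency of the network
#'
#' Mean of [nodal_local_efficiency()] over all nodes.
#' @inheritParams nodal_local_efficiency
#' @return scalar in \[0, 1\].
#' @export
local_efficiency <- function(net, include_self = FALSE) {
  mean(nodal_local_efficiency(net, include_self = include_self))
}

#' Degree-preserving random reference network
#'
#' Maslov-Sneppen double-edge swaps: repeatedly pick two edges (a,b), (c,d)
#' and rewire to (a,d), (c,b), rejecting proposals that would create a
#' self-loop or a multi-edge. The degree sequence is preserved exactly while
#' topology (clustering, path structure) is randomized.
#'
#' @param net a `binary_network`.
#' @param n_swaps_per_edge attempted swaps per edge (default 10).
#' @param seed integer seed for the rewiring stream.
#' @return a `binary_network` with identical degree sequence.
#' @export
random_reference <- function(net, n_swaps_per_edge = 10, seed = 1L) {
  a <- adj_of(net)
  e <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  K <- nrow(e)
  if (K < 2) {
    warning("fewer than 2 edges: returning the input network")
    return(as_binary_network(a, sparsity = net$sparsity %||% NA_real_))
  }
  n_att <- ceiling(n_swaps_per_edge * K)
  with_seed(seed, {
    if (n_att > 0) {
      pick <- matrix(sample.int(K, 2 * n_att, replace = TRUE), ncol = 2)
      flip <- stats::runif(n_att) < 0.5
      for (t in seq_len(n_att)) {
        i <- pick[t, 1]; j <- pick[t, 2]
        if (i == j) next
        a1 <- e[i, 1]; b1 <- e[i, 2]
        c1 <- e[j, 1]; d1 <- e[j, 2]
        if (flip[t]) { tmp <- c1; c1 <- d1; d1 <- tmp }
        # propose (a1,d1) and (c1,b1)
        if (a1 == d1 || c1 == b1) next
        if (a[a1, d1] > 0 || a[c1, b1] > 0) next
        a[a1, b1] <- 0; a[b1, a1] <- 0
        a[c1, d1] <- 0; a[d1, c1] <- 0
        a[a1, d1] <- 1; a[d1, a1] <- 1
        a[c1, b1] <- 1; a[b1, c1] <- 1
        e[i, ] <- c(min(a1, d1), max(a1, d1))
        e[j, ] <- c(min(c1, b1), max(c1, b1))
      }
    }
  })
  as_binary_network(a, sparsity = net$sparsity %||% NA_real_)
}

#' Small-world indices via random-network normalization
#'
#' `Gamma = Cp / mean(Cp_random)`, `Lambda = Lp / mean(Lp_random)`,
#' `Sigma = Gamma / Lambda`, where the reference values come from
#' `n_random` degree-matched rewired networks ([random_reference()]).
#' A small-world network satisfies Lambda ~ 1, Gamma > 1, Sigma > 1.
#'
#' @param net a `binary_network`.
#' @param n_random number of reference networks (study convention: 1000).
#' @param n_swaps_per_edge swaps per edge for each reference network.
#' @param seed integer seed; reference networks use derived substreams.
#' @return list with `gamma`, `lambda`, `sigma`, `cp`, `lp`, `cp_rand`,
#'   `lp_rand`, `n_random`.
#' @export
small_world <- function(net, n_random = 1000L, n_swaps_per_edge = 10, seed = 1L) {
  stopifnot(n_random >= 1)
  cp <- clustering_coefficient(net)$cp
  lp <- as.numeric(characteristic_path_length(net))
  cpr <- lpr <- numeric(n_random)
  for (b in seq_len(n_random)) {
    rnet <- random_reference(net, n_swaps_per_edge = n_swaps_per_edge,
                             seed = substream_seed(seed, "rewire", b))
    cpr[b] <- clustering_coefficient(rnet)$cp
    lpr[b] <- as.numeric(characteristic_path_length(rnet))
  }
  if (mean(cpr) == 0) stop("mean random-network clustering is 0: Gamma undefined")
  g <- cp / mean(cpr)
  l <- lp / mean(lpr)
  list(gamma = g, lambda = l, sigma = g / l,
       cp = cp, lp = lp, cp_rand = mean(cpr), lp_rand = mean(lpr),
       n_random = n_random)
}

#' Detect network hubs
#'
#' A node is a hub when its (group-averaged) nodal efficiency is at least
#' one standard deviation above the mean over all nodes. With zero spread
#' no node can stand out and the hub set is empty.
#'
#' @param values per-node metric values (typically group means).
#' @return integer vector of hub node indices.
#' @export
detect_hubs <- function(values) {
  stopifnot(length(values) >= 2)
  s <- stats::sd(values)
  if (s == 0) return(integer(0))
  which(values >= mean(values) + s)
}

#' All global metrics of one binary network
#'
#' Convenience wrapper collecting Cp, Lp, Gamma, Lambda, Sigma, global and
#' local efficiency into a one-row data frame.
#'
#' @inheritParams small_world
#' @return one-row data.frame.
#' @export
global_metrics <- function(net, n_random = 1000L, n_swaps_per_edge = 10,
                           seed = 1L) {
  sw <- small_world(net, n_random = n_random,
                    n_swaps_per_edge = n_swaps_per_edge, seed = seed)
  data.frame(cp = sw$cp, lp = sw$lp, gamma = sw$gamma, lambda = sw$lambda,
             sigma = sw$sigma, eglob = global_efficiency(net),
             eloc = local_efficiency(net),
             sparsity = net$sparsity %||% NA_real_, n_random = n_random)
}
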