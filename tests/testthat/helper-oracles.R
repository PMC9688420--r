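# Independent brute-force oracles for graph metrics, used to validate the
# package implementations. These deliberately share no code with R/.

oracle_fw <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_cp_nodal <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (x in seq_len(k - 1))
      for (y in (x + 1):k)
        if (a[nb[x], nb[y]] > 0) tri <- tri + 1
    tri / (k * (k - 1) / 2)
  }, numeric(1))
}

oracle_lp <- function(a) {
  d <- oracle_fw(a)
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

oracle_enod <- function(a) {
  d <- oracle_fw(a)
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    v <- 1 / d[i, -i]
    v[!is.finite(v)] <- 0
    sum(v) / (n - 1)
  }, numeric(1))
}

oracle_eglob <- function(a) mean(oracle_enod(a))

oracle_eloc_nodal <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    d <- oracle_fw(a[nb, nb, drop = FALSE])
    v <- 1 / d[row(d) != col(d)]
    v[!is.finite(v)] <- 0
    sum(v) / (k * (k - 1))
  }, numeric(1))
}

# graph constructors ----------------------------------------------------------

graph_from_code <- function(n, code) {
  a <- matrix(0, n, n)
  m <- n * (n - 1) / 2
  bits <- as.integer(intToBits(code))[seq_len(m)]
  a[upper.tri(a)] <- bits
  a + t(a)
}

rand_graph <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- as.numeric(runif(n * (n - 1) / 2) < p)
  a + t(a)
}

ring_lattice <- function(n, k_each_side) {
  a <- matrix(0, n, n)
  for (i in seq_len(n))
    for (s in seq_len(k_each_side)) {
      j <- ((i - 1 + s) %% n) + 1
      a[i, j] <- 1; a[j, i] <- 1
    }
  a
}

add_shortcuts <- function(a, n_extra, seed) {
  set.seed(seed)
  non <- which(upper.tri(a) & a == 0)
  pick <- sample(non, n_extra)
  a[pick] <- 1
  t(a * upper.tri(a)) + a * upper.tri(a)
}

net_of <- function(a, sparsity = NA_real_) {
  cmz <- structure(list(z = a, valid_mask = rep(TRUE, nrow(a))),
                   class = "connectivity_matrix")
  s <- sum(a[upper.tri(a)]) / (nrow(a) * (nrow(a) - 1) / 2)
  # direct wrap: treat a as adjacency
  structure(list(adjacency = a, sparsity = sparsity, edge_count = sum(a) / 2),
            class = "binary_network")
}

# small synthetic cohorts at a reduced sampling rate (band-limited signals
# carry the same information at any rate above Nyquist; see vignette)
fast_spec <- function(seed, ...) cohort_spec(fs = 2, seed = seed, ...)
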