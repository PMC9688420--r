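# Functional connectivity: Pearson correlation matrices, Fisher z with
# negative zeroing, and sparsity-based binarization into equal-K networks.

#' Fisher z-transformation
#'
#' `atanh(r)`, applied in this pipeline after zeroing negative correlations,
#' so the working domain is \[0, 1). Coefficients of magnitude 1 (identical
#' series) are clipped to `1 - 1e-7` with a warning rather than mapped to
#' infinity.
#'
#' @param r correlation coefficient(s) in \[-1, 1\].
#' @return transformed value(s).
#' @export
fisher_z <- function(r) {
  stopifnot(all(abs(r) <= 1, na.rm = TRUE))
  clip <- !is.na(r) & abs(r) == 1
  if (any(clip)) {
    warning("correlation(s) of magnitude 1 clipped to 1 - 1e-7 before atanh")
    r[clip] <- sign(r[clip]) * (1 - 1e-7)
  }
  atanh(r)
}

#' Build a connectivity matrix from a hemodynamic recording
#'
#' Pearson correlations between the full-length HbO series of every channel
#' pair, negatives zeroed (their biological meaning in rs-fNIRS is
#' ambiguous), then Fisher z-transformed. Zero-variance or pruned channels
#' are marked invalid and their correlations set missing.
#'
#' @param rec a `hemo_recording` (uses `rec$hbo`), or a plain time x channel
#'   matrix.
#' @return object of class `connectivity_matrix`: `r` (N x N Pearson),
#'   `z` (N x N, negatives zeroed, diagonal 0 and excluded downstream),
#'   `valid_mask`, `subject_id`.
#' @export
correlation_matrix <- function(rec) {
  x <- if (inherits(rec, "hemo_recording")) rec$hbo else as.matrix(rec)
  subject_id <- if (inherits(rec, "hemo_recording")) rec$subject_id else NA_character_
  stopifnot(nrow(x) >= 3)
  mu <- colMeans(x)
  sds <- sqrt(pmax(colMeans(x * x) - mu * mu, 0))
  # relative floor guards against cancellation marking constants as varying
  valid <- !is.na(sds) & sds > 1e-7 * sqrt(colMeans(x * x) + 1e-300)
  if (inherits(rec, "hemo_recording") && !is.null(rec$channel_mask))
    valid <- valid & rec$channel_mask
  n <- ncol(x)
  r <- matrix(NA_real_, n, n)
  if (sum(valid) >= 2)
    r[valid, valid] <- stats::cor(x[, valid, drop = FALSE])
  diag(r) <- 1
  rz <- pmax(r, 0)
  clip <- !is.na(rz) & rz >= 1 & row(rz) != col(rz)
  if (any(clip)) {
    warning("off-diagonal correlation(s) of 1 clipped before Fisher transform")
    rz[clip] <- 1 - 1e-7
  }
  z <- suppressWarnings(atanh(rz))
  diag(z) <- 0
  structure(list(r = r, z = z, valid_mask = valid, subject_id = subject_id),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  off <- x$r[upper.tri(x$r)]
  cat("Connectivity matrix:", nrow(x$r), "channels,",
      sum(x$valid_mask), "valid; mean r =",
      round(mean(off, na.rm = TRUE), 3), "\n")
  invisible(x)
}

as_binary_network <- function(adjacency, sparsity = NA_real_) {
  storage.mode(adjacency) <- "double"
  diag(adjacency) <- 0
  structure(list(adjacency = adjacency, sparsity = sparsity,
                 edge_count = sum(adjacency) / 2),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat("Binary network:", nrow(x$adjacency), "nodes,", x$edge_count,
      "edges", if (!is.na(x$sparsity)) paste0("(sparsity ", x$sparsity, ")"),
      "\n")
  invisible(x)
}

#' Binarize a connectivity matrix at a given sparsity
#'
#' Retains exactly the `round(s * N(N-1)/2)` strongest off-diagonal z values
#' as edges (equal edge count K across subjects, so group comparisons are on
#' same-size networks). Rounding is half-away-from-zero. Ties at the cutoff
#' are broken deterministically by ascending (row, column) index. If fewer
#' than K nonzero z values exist, all nonzero values become edges and the
#' shortfall is reported as a warning.
#'
#' @param cm a `connectivity_matrix` (or symmetric nonnegative matrix).
#' @param s sparsity, fraction of all possible edges in (0, 1).
#' @return a `binary_network`.
#' @export
binarize_at_sparsity <- function(cm, s) {
  stopifnot(s > 0, s < 1)
  z <- if (inherits(cm, "connectivity_matrix")) cm$z else as.matrix(cm)
  valid <- if (inherits(cm, "connectivity_matrix")) cm$valid_mask
           else rep(TRUE, nrow(z))
  zv <- z[valid, valid, drop = FALSE]
  n <- nrow(zv)
  k <- round_half_up(s * n * (n - 1) / 2)
  ut <- which(upper.tri(zv), arr.ind = TRUE)
  vals <- zv[upper.tri(zv)]
  ord <- order(-vals, ut[, 1], ut[, 2])
  avail <- sum(vals > 0, na.rm = TRUE)
  if (k > avail) {
    warning(sprintf("requested %d edges but only %d positive z values; keeping %d",
                    k, avail, avail))
    k <- avail
  }
  a <- matrix(0, n, n)
  if (k > 0) {
    keep <- ord[seq_len(k)]
    a[cbind(ut[keep, 1], ut[keep, 2])] <- 1
    a <- a + t(a)
  }
  if (!all(valid)) {  # re-embed into full channel space, invalid rows empty
    full <- matrix(0, length(valid), length(valid))
    full[valid, valid] <- a
    a <- full
  }
  net <- as_binary_network(a, sparsity = s)
  net$valid_mask <- valid
  net
}

#' Binarize across a sparsity sweep
#'
#' Networks at every sparsity from `s_min` to `s_max` inclusive (default
#' 20-40% in 1% steps, 21 networks). Because edges are kept top-down, edge
#' sets are nested along the sweep.
#'
#' @inheritParams binarize_at_sparsity
#' @param s_min,s_max,step sweep limits and step size.
#' @return named list of `binary_network`s (names = sparsity values).
#' @export
sparsity_sweep <- function(cm, s_min = 0.20, s_max = 0.40, step = 0.01) {
  stopifnot(s_min <= s_max, step > 0)
  ss <- s_min + step * seq(0, round((s_max - s_min) / step))
  ss <- ss[ss <= s_max + 1e-9]
  nets <- lapply(ss, function(s) binarize_at_sparsity(cm, s))
  names(nets) <- formatC(ss, format = "g")
  nets
}
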