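# internal helpers: seeded substreams, rounding, zero-phase Butterworth SOS filter

# Named random substreams derived from one master seed. Streams keep subject-level
# draws independent of each other and of analysis-stage randomness (rewiring, CV,
# permutations) so that adding a stage never perturbs another stage's draws.
.stream_ids <- c(simulate = 1L, optics = 2L, artifact = 3L,
                 rewire = 4L, cv = 5L, perm = 6L, misc = 7L)

#' Derive a named random substream seed from a master seed
#'
#' All randomness in the package flows from one master seed through named
#' substreams (`"simulate"`, `"optics"`, `"artifact"`, `"rewire"`, `"cv"`,
#' `"perm"`, `"misc"`), so that adding or reordering one analysis stage
#' never perturbs another stage's draws. The result is a positive integer
#' below 2^31.
#'
#' @param master integer master seed.
#' @param stream substream name (see above).
#' @param index within-stream index (e.g., subject or replicate number).
#' @return an integer seed.
#' @export
substream_seed <- function(master, stream, index = 0L) {
  id <- .stream_ids[[stream]]
  # stays below 2^31 - 1; constants are arbitrary coprime multipliers
  as.integer((as.double(master) %% 65011 * 33013 +
                id * 2600017 + as.double(index) * 7919) %% 2147483587 + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# round half away from zero (edge-count convention; documented, R's round() is half-even)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- order-n Butterworth band-pass as second-order sections -----------------
# The classic transfer-function form is ill-conditioned for passbands far below
# Nyquist (0.01-0.08 Hz at 50 Hz), so the digital filter is assembled from the
# analog prototype pole by pole and applied as cascaded biquads.

butter_bandpass_sos <- function(order, low, high, fs) {
  stopifnot(low > 0, low < high, high < fs / 2)
  w1 <- 2 * fs * tan(pi * low / fs)     # prewarped edges, rad/s
  w2 <- 2 * fs * tan(pi * high / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # unit-circle LP poles
  ap <- c(vapply(proto, function(p) {
    d <- sqrt(as.complex((p * bw)^2 / 4 - w0^2))
    c(p * bw / 2 + d, p * bw / 2 - d)
  }, complex(2)))
  zp <- (2 * fs + ap) / (2 * fs - ap)   # bilinear transform
  used <- rep(FALSE, length(zp))
  sos <- list()
  for (i in seq_along(zp)) {
    if (used[i]) next
    used[i] <- TRUE
    d <- abs(zp - Conj(zp[i])); d[used] <- Inf
    j <- which.min(d); used[j] <- TRUE
    a <- c(1, -Re(zp[i] + zp[j]), Re(zp[i] * zp[j]))
    sos[[length(sos) + 1L]] <- list(b = c(1, 0, -1), a = a)
  }
  # unit gain at the geometric center frequency, spread evenly over sections
  z <- exp(1i * 2 * pi * sqrt(low * high) / fs)
  H <- prod(vapply(sos, function(s)
    sum(s$b * z^(0:-2)) / sum(s$a * z^(0:-2)), complex(1)))
  g <- (1 / Mod(H))^(1 / length(sos))
  lapply(sos, function(s) list(b = s$b * g, a = s$a))
}

# squared magnitude response of the cascade at frequencies f (Hz); the
# forward-backward (zero-phase) filter has response |H|^2
sos_power_response <- function(sos, f, fs) {
  z <- exp(1i * 2 * pi * f / fs)
  H <- rep(1 + 0i, length(z))
  for (s in sos) H <- H * as.vector(outer(z, 0:-2, `^`) %*% s$b) /
    as.vector(outer(z, 0:-2, `^`) %*% s$a)
  Mod(H)^2
}
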