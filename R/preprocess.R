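# Raw optics -> HbO/HbR concentrations: channel pruning, optical density,
# motion-artifact detection + cubic-spline correction, modified Beer-Lambert
# inversion, zero-phase band-pass, wavelet-based denoising.

#' Preprocessing configuration
#'
#' Defaults follow the standard rs-fNIRS chain: intensity validity bounds
#' (0, 1e7) and SNR >= 2 for channel pruning; motion parameters tMotion =
#' 0.5 s, tMask = 1 s, STDEVthresh = 30, AMPthresh = 0.5; pass band
#' 0.01-0.08 Hz; differential pathlength factor 6; wavelet shrinkage
#' constant 1.5 (Tukey-fence style multiple of each scale's IQR).
#'
#' @param od_low,od_high mean-intensity validity bounds.
#' @param snr_thresh minimum mean/SD intensity ratio.
#' @param t_motion,t_mask motion window and dilation lengths (s).
#' @param stdev_thresh gradient threshold in units of the channel's robust
#'   gradient SD.
#' @param amp_thresh absolute peak-to-peak threshold within a motion window.
#' @param band pass band (Hz), must satisfy 0 < low < high < fs/2.
#' @param dpf differential pathlength factor.
#' @param wavelet_alpha IQR multiple beyond which detail coefficients are
#'   clipped; `Inf` disables shrinkage.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(od_low = 0, od_high = 1e7, snr_thresh = 2,
                              t_motion = 0.5, t_mask = 1, stdev_thresh = 30,
                              amp_thresh = 0.5, band = c(0.01, 0.08),
                              dpf = 6, wavelet_alpha = 1.5) {
  stopifnot(band[1] > 0, band[1] < band[2], t_motion > 0, t_mask > 0)
  structure(list(od_low = od_low, od_high = od_high, snr_thresh = snr_thresh,
                 t_motion = t_motion, t_mask = t_mask,
                 stdev_thresh = stdev_thresh, amp_thresh = amp_thresh,
                 band = band, dpf = dpf, wavelet_alpha = wavelet_alpha),
            class = "preprocess_config")
}

new_hemo_recording <- function(subject_id, hbo, hbr, fs,
                               channel_mask = rep(TRUE, ncol(hbo)),
                               provenance = list()) {
  stopifnot(identical(dim(hbo), dim(hbr)))
  structure(list(subject_id = subject_id, hbo = hbo, hbr = hbr, fs = fs,
                 channel_mask = channel_mask, provenance = provenance),
            class = "hemo_recording")
}

#' @export
print.hemo_recording <- function(x, ...) {
  cat("Hemodynamic recording", x$subject_id, ":", nrow(x$hbo), "samples x",
      ncol(x$hbo), "channels at", x$fs, "Hz;", sum(!x$channel_mask),
      "pruned;", length(x$provenance), "processing steps\n")
  invisible(x)
}

add_provenance <- function(rec, step, ...) {
  rec$provenance <- c(rec$provenance, list(c(list(step = step), list(...))))
  rec
}

#' Extinction coefficients for HbO and HbR
#'
#' Napierian extinction coefficients at 730, 808 and 850 nm in
#' 1/(µM·cm), converted (x ln 10 / 1e6) from the widely used compiled
#' molar (log10) tabulation of hemoglobin spectra (Prahl's compilation).
#' Users may substitute their own table with the same shape.
#'
#' @return 3 x 2 matrix, rows = wavelengths (nm), columns = `hbo`, `hbr`.
#' @export
extinction_coefficients <- function() {
  molar <- rbind(`730` = c(hbo = 390.0, hbr = 1102.2),
                 `808` = c(hbo = 859.0, hbr = 738.3),
                 `850` = c(hbo = 1058.0, hbr = 691.3))
  molar * log(10) / 1e6
}

#' Identify bad channels in a raw recording
#'
#' A channel is pruned when, at any wavelength, its mean intensity falls
#' outside `(od_low, od_high)`, any sample is non-positive, or its
#' signal-to-noise ratio (mean/SD) is below `snr_thresh`. A constant
#' positive channel has infinite SNR and is kept.
#'
#' @param raw a `raw_recording`.
#' @param cfg a [preprocess_config()].
#' @return logical vector, `TRUE` = good channel. Errors if every channel
#'   is pruned.
#' @export
prune_channels <- function(raw, cfg = preprocess_config()) {
  stopifnot(dim(raw$samples)[1] >= 1)
  nch <- dim(raw$samples)[2]
  good <- vapply(seq_len(nch), function(ch) {
    for (w in seq_len(dim(raw$samples)[3])) {
      x <- raw$samples[, ch, w]
      if (any(x <= 0)) return(FALSE)
      m <- mean(x); s <- stats::sd(x)
      if (m <= cfg$od_low || m >= cfg$od_high) return(FALSE)
      snr <- if (is.na(s) || s == 0) Inf else m / s
      if (snr < cfg$snr_thresh) return(FALSE)
    }
    TRUE
  }, logical(1))
  if (!any(good)) stop("all channels pruned: nothing to analyze")
  good
}

#' Convert intensities to optical densities
#'
#' `OD(t) = -log(I(t) / mean(I))` per channel and wavelength (natural log;
#' the extinction table is Napierian to match). Pruned channels are set to
#' `NA`.
#'
#' @param raw a `raw_recording`.
#' @param channel_mask logical good-channel mask (default: all good).
#' @return time x channel x wavelength array of optical densities.
#' @export
intensity_to_od <- function(raw, channel_mask = NULL) {
  d <- dim(raw$samples)
  mask <- channel_mask %||% rep(TRUE, d[2])
  od <- array(NA_real_, d, dimnames = dimnames(raw$samples))
  for (ch in which(mask)) {
    for (w in seq_len(d[3])) {
      x <- raw$samples[, ch, w]
      if (any(x <= 0))
        stop("non-positive intensity on unpruned channel ", ch)
      od[, ch, w] <- -log(x / mean(x))
    }
  }
  od
}

#' Invert the modified Beer-Lambert law
#'
#' Per channel and time point, solves the least-squares system
#' `OD(lambda) = [eps_hbo(lambda), eps_hbr(lambda)] %*% c(dHbO, dHbR) * L * DPF`
#' for the two concentration changes, with `L` the source-detector
#' separation and DPF from the configuration. With three wavelengths the
#' system is overdetermined; consistent data are recovered exactly.
#'
#' @param od time x channel x wavelength optical-density array.
#' @param layout probe layout (supplies `separation_cm`).
#' @param cfg a [preprocess_config()] (supplies `dpf`).
#' @param extinction extinction table, rows = wavelengths, columns
#'   `hbo`, `hbr` (see [extinction_coefficients()]).
#' @param subject_id carried into the result.
#' @param fs sampling rate carried into the result.
#' @return a `hemo_recording` (concentrations in µM).
#' @export
od_to_concentration <- function(od, layout, cfg = preprocess_config(),
                                extinction = extinction_coefficients(),
                                subject_id = NA_character_, fs = NA_real_) {
  stopifnot(dim(od)[3] >= 2)
  E <- as.matrix(extinction)
  if (!all(c("hbo", "hbr") %in% colnames(E)))
    stop("extinction table must have 'hbo' and 'hbr' columns")
  if (nrow(E) != dim(od)[3])
    stop("extinction table rows must match the number of wavelengths")
  if (anyNA(E)) stop("missing extinction entry")
  if (qr(E)$rank < 2) stop("singular extinction matrix")
  pinv <- solve(crossprod(E), t(E))          # 2 x n_wl
  nch <- dim(od)[2]
  nsamp <- dim(od)[1]
  hbo <- hbr <- matrix(NA_real_, nsamp, nch, dimnames = list(NULL, seq_len(nch)))
  mask <- rep(FALSE, nch)
  for (ch in seq_len(nch)) {
    if (anyNA(od[, ch, ])) next
    conc <- od[, ch, ] %*% t(pinv) / (layout$separation_cm[ch] * cfg$dpf)
    hbo[, ch] <- conc[, 1]
    hbr[, ch] <- conc[, 2]
    mask[ch] <- TRUE
  }
  new_hemo_recording(subject_id, hbo, hbr, fs, channel_mask = mask,
                     provenance = list(list(step = "od_to_concentration",
                                            dpf = cfg$dpf)))
}

# motion detection on one time x channel matrix: within sliding windows of
# t_motion, flag where the absolute one-sample gradient exceeds
# stdev_thresh x the channel's robust gradient SD, or the windowed
# peak-to-peak amplitude exceeds amp_thresh; flags dilated by t_mask
motion_mask_matrix <- function(x, fs, cfg) {
  n <- nrow(x)
  w <- max(2L, round(cfg$t_motion * fs))
  dil <- round(cfg$t_mask * fs)
  out <- matrix(FALSE, n, ncol(x))
  for (ch in seq_len(ncol(x))) {
    v <- x[, ch]
    if (anyNA(v)) next
    g <- abs(diff(v))
    sdg <- stats::mad(g)
    if (sdg == 0) sdg <- stats::sd(g)
    bad_g <- if (is.na(sdg) || sdg == 0) rep(FALSE, n - 1)
             else g > cfg$stdev_thresh * sdg
    # windowed peak-to-peak via strided max/min
    if (n >= w) {
      em <- stats::embed(v, w)
      p2p <- do.call(pmax, as.data.frame(em)) - do.call(pmin, as.data.frame(em))
      bad_w <- p2p > cfg$amp_thresh              # window ending at t = w..n
    } else bad_w <- logical(0)
    flag <- rep(FALSE, n)
    if (any(bad_g)) {
      i <- which(bad_g)
      flag[i] <- TRUE; flag[i + 1L] <- TRUE
    }
    if (any(bad_w)) {
      for (i in which(bad_w)) flag[(i):(i + w - 1L)] <- TRUE
    }
    if (any(flag) && dil > 0) {
      runs <- rle(flag)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (k in which(runs$values)) {
        flag[max(1L, starts[k] - dil):min(n, ends[k] + dil)] <- TRUE
      }
    }
    out[, ch] <- flag
  }
  out
}

#' Detect motion artifacts
#'
#' Within every sliding window of length `t_motion`, a channel segment is
#' flagged when the peak-to-peak amplitude exceeds `amp_thresh` or the
#' one-sample signal change exceeds `stdev_thresh` times the channel's
#' robust (MAD-based) gradient SD. Flagged segments are dilated by `t_mask`
#' seconds on both sides. With both thresholds infinite nothing is flagged.
#'
#' @param rec a `hemo_recording` (detection runs on the HbO series), or a
#'   plain time x channel matrix plus `fs`.
#' @param cfg a [preprocess_config()].
#' @param fs sampling rate, required when `rec` is a matrix.
#' @return logical time x channel matrix, `TRUE` = motion-contaminated.
#' @export
detect_motion_artifacts <- function(rec, cfg = preprocess_config(), fs = NULL) {
  if (inherits(rec, "hemo_recording"))
    motion_mask_matrix(rec$hbo, rec$fs, cfg)
  else motion_mask_matrix(as.matrix(rec), fs, cfg)
}

# spline-correct one channel given a flag vector
spline_correct_channel <- function(v, flag) {
  runs <- rle(flag)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  n <- length(v)
  for (k in which(runs$values)) {
    a <- starts[k]; b <- ends[k]
    seg <- v[a:b]
    len <- b - a + 1L
    fit <- if (len < 4) {
      stats::fitted(stats::lm(seg ~ seq_len(len)))     # linear detrend
    } else {
      # interpolating cubic spline: subtracting it removes the segment's
      # entire fluctuation (the artifact waveform), leaving the re-leveled
      # baseline; in-band signal is ~constant over artifact time scales
      stats::spline(seq_len(len), seg, xout = seq_len(len))$y
    }
    corrected <- seg - fit
    level <- if (a > 1) v[a - 1] else seg[1]
    corrected <- corrected - corrected[1] + level
    v[a:b] <- corrected
    if (b < n) v[(b + 1):n] <- v[(b + 1):n] + (corrected[len] - seg[len])
  }
  v
}

#' Correct motion artifacts by cubic-spline subtraction
#'
#' Within each flagged segment an interpolating cubic spline is fitted and
#' subtracted, removing the artifact waveform; the segment is
#' then re-leveled to join the preceding sample and all subsequent samples
#' are offset so the corrected series is continuous (no step at segment
#' edges). Unflagged samples are only ever changed by these constant
#' re-leveling offsets. Segments shorter than 4 samples fall back to a
#' linear detrend.
#'
#' @param rec a `hemo_recording` or time x channel matrix.
#' @param mask logical matrix from [detect_motion_artifacts()].
#' @return same type as `rec`, corrected.
#' @export
spline_correct <- function(rec, mask) {
  is_rec <- inherits(rec, "hemo_recording")
  x <- if (is_rec) rec$hbo else as.matrix(rec)
  stopifnot(identical(dim(x), dim(mask)))
  for (ch in seq_len(ncol(x))) {
    if (any(mask[, ch]) && !anyNA(x[, ch]))
      x[, ch] <- spline_correct_channel(x[, ch], mask[, ch])
  }
  if (is_rec) {
    rec$hbo <- x
    for (ch in seq_len(ncol(rec$hbr)))
      if (any(mask[, ch]) && !anyNA(rec$hbr[, ch]))
        rec$hbr[, ch] <- spline_correct_channel(rec$hbr[, ch], mask[, ch])
    add_provenance(rec, "spline_correct", n_flagged = sum(mask))
  } else x
}

#' Zero-phase band-pass filter
#'
#' Order-3 Butterworth band-pass with zero-phase (forward-backward)
#' response, applied per channel as the squared magnitude response of the
#' second-order-section design evaluated in the frequency domain. At
#' passbands this far below Nyquist (0.01-0.08 Hz at 50 Hz) the
#' frequency-domain application is numerically exact and free of the long
#' edge transients of time-domain recursion, whose impulse response rings
#' for minutes at the low band edge. Passband gain is within \[0.9, 1\]
#' and attenuation at twice the upper band edge exceeds 99%.
#'
#' @param rec a `hemo_recording` or time x channel matrix.
#' @param cfg a [preprocess_config()] (supplies `band`).
#' @param fs sampling rate, required when `rec` is a matrix.
#' @return same type as `rec`, filtered (columns demeaned by construction).
#' @export
bandpass <- function(rec, cfg = preprocess_config(), fs = NULL) {
  is_rec <- inherits(rec, "hemo_recording")
  x <- if (is_rec) rec$hbo else as.matrix(rec)
  fs <- if (is_rec) rec$fs else fs
  n <- nrow(x)
  if (n < 3 * ceiling(fs / cfg$band[1]))
    stop("recording too short for the requested band: need at least ",
         3 * ceiling(fs / cfg$band[1]), " samples")
  sos <- butter_bandpass_sos(3, cfg$band[1], cfg$band[2], fs)
  H2 <- sos_power_response(sos, (seq_len(n) - 1) / n * fs, fs)
  filt <- function(m) {
    ok <- !apply(m, 2, anyNA)
    if (any(ok)) {
      mc <- sweep(m[, ok, drop = FALSE], 2,
                  colMeans(m[, ok, drop = FALSE]))
      m[, ok] <- Re(stats::mvfft(stats::mvfft(mc) * H2, inverse = TRUE)) / n
    }
    m
  }
  if (is_rec) {
    rec$hbo <- filt(rec$hbo)
    rec$hbr <- filt(rec$hbr)
    add_provenance(rec, "bandpass", band = cfg$band)
  } else filt(x)
}

# ---- periodized Daubechies-4 discrete wavelet transform ---------------------
.db4_h <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
.db4_g <- rev(.db4_h) * c(1, -1, 1, -1)

dwt_step <- function(x, h, g) {
  n <- length(x)
  idx <- outer(seq(1, n, by = 2) - 1, seq_along(h) - 1, `+`) %% n + 1
  xm <- matrix(x[idx], ncol = length(h))
  list(a = as.numeric(xm %*% h), d = as.numeric(xm %*% g))
}

idwt_step <- function(a, d, h, g) {
  n <- 2 * length(a)
  x <- numeric(n)
  for (k in seq_along(h)) {
    pos <- (seq(1, n, by = 2) - 1 + (k - 1)) %% n + 1
    x[pos] <- x[pos] + a * h[k] + d * g[k]
  }
  x
}

dwt_periodized <- function(x, levels) {
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- dwt_step(a, .db4_h, .db4_g)
    details[[j]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details)
}

idwt_periodized <- function(w) {
  a <- w$approx
  for (j in rev(seq_along(w$details)))
    a <- idwt_step(a, w$details[[j]], .db4_h, .db4_g)
  a
}

#' Wavelet-based denoising
#'
#' Per channel: multilevel periodized Daubechies-4 decomposition (input
#' reflected-padded to a power of two); at each well-populated scale (at
#' least 128 coefficients, so the robust spread estimate is reliable and
#' the sparse coarse scales carrying the band-limited signal are left
#' alone), detail coefficients whose magnitude exceeds `wavelet_alpha`
#' times that scale's interquartile range are clipped to that bound (a
#' Tukey-fence shrinkage that suppresses sparse large transients while
#' leaving the bulk untouched); then reconstruction and unpadding.
#' `wavelet_alpha = Inf` is an exact no-op up to reconstruction round-off.
#'
#' @param rec a `hemo_recording` or time x channel matrix.
#' @param cfg a [preprocess_config()] (supplies `wavelet_alpha`).
#' @return same type as `rec`, denoised; length always preserved.
#' @export
wavelet_denoise <- function(rec, cfg = preprocess_config()) {
  is_rec <- inherits(rec, "hemo_recording")
  x <- if (is_rec) rec$hbo else as.matrix(rec)
  alpha <- cfg$wavelet_alpha
  denoise1 <- function(v) {
    n <- length(v)
    n2 <- 2^ceiling(log2(n))
    if (n2 > n) {
      pad <- n2 - n
      v <- c(v, rev(v)[seq_len(pad)])    # reflection padding
    }
    levels <- max(1L, floor(log2(length(v))) - 3L)
    w <- dwt_periodized(v, levels)
    if (is.finite(alpha)) {
      # shrink only well-populated fine scales: the robust IQR spread needs
      # enough coefficients, and the sparse coarse scales carry the
      # band-limited signal itself rather than transients
      w$details <- lapply(w$details, function(d) {
        if (length(d) < 128) return(d)
        thr <- alpha * stats::IQR(d)
        if (thr > 0) sign(d) * pmin(abs(d), thr) else d
      })
    }
    idwt_periodized(w)[seq_len(n)]
  }
  for (ch in seq_len(ncol(x)))
    if (!anyNA(x[, ch])) x[, ch] <- denoise1(x[, ch])
  if (is_rec) {
    rec$hbo <- x
    add_provenance(rec, "wavelet_denoise", alpha = alpha)
  } else x
}

#' Full preprocessing chain
#'
#' Fixed order: prune channels -> optical density -> motion detection and
#' spline correction (on each wavelength's OD, masks OR-combined per
#' channel) -> Beer-Lambert inversion -> zero-phase band-pass -> wavelet
#' denoising. Every step appends to the recording's provenance. Pruned
#' channels propagate as `NA`.
#'
#' @param raw a `raw_recording`.
#' @param layout probe layout.
#' @param cfg a [preprocess_config()].
#' @return a `hemo_recording`.
#' @export
preprocess <- function(raw, layout, cfg = preprocess_config()) {
  mask <- prune_channels(raw, cfg)
  od <- intensity_to_od(raw, mask)
  nwl <- dim(od)[3]
  mot <- matrix(FALSE, dim(od)[1], dim(od)[2])
  for (w in seq_len(nwl))
    mot <- mot | motion_mask_matrix(od[, , w], raw$fs, cfg)
  for (w in seq_len(nwl))
    od[, , w] <- spline_correct(od[, , w], mot)
  rec <- od_to_concentration(od, layout, cfg, subject_id = raw$subject_id,
                             fs = raw$fs)
  rec$channel_mask <- rec$channel_mask & mask
  rec$provenance <- c(list(list(step = "prune", n_pruned = sum(!mask)),
                           list(step = "intensity_to_od"),
                           list(step = "motion_correct",
                                n_flagged = sum(mot))),
                      rec$provenance)
  rec <- bandpass(rec, cfg)
  rec <- wavelet_denoise(rec, cfg)
  rec
}
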