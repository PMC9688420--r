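# Seeded synthetic rs-fNIRS cohorts: probe layout + band-limited correlated
# hemodynamics + clinical covariates, with a planted nodal-local-efficiency
# deficit at one occipital channel and HAMD coupled to its severity.

#' Default resting-state channel covariance template
#'
#' A block-structured correlation matrix over the probe layout: channels
#' within the frontal/central blocks correlate at `r_within`, within the
#' occipital block at `r_occipital` (stronger, so the occipital block forms
#' a local-efficiency hub), and between blocks at `r_between`. The default
#' levels are calibrated so the grand mean off-diagonal correlation of
#' simulated cohorts lands near 0.31-0.32, the value typical of rs-fNIRS
#' connectomes of this kind.
#'
#' @param layout a [generate_probe_layout()] object.
#' @param r_within,r_occipital,r_between block correlation levels.
#' @return N x N correlation matrix (unit diagonal, positive definite).
#' @export
default_base_covariance <- function(layout = generate_probe_layout(),
                                    r_within = 0.43, r_occipital = 0.55,
                                    r_between = 0.24) {
  reg <- layout$region
  n <- length(reg)
  C <- matrix(r_between, n, n)
  for (rg in unique(reg)) {
    idx <- which(reg == rg)
    C[idx, idx] <- if (rg == "occipital") r_occipital else r_within
  }
  diag(C) <- 1
  C
}

#' Default physiological noise specification for the optical forward model
#'
#' Amplitudes are in optical-density units; the hemodynamic signal itself
#' contributes ~2e-3 OD rms at the default HbO amplitude, so the components
#' below give physiologically plausible relative power (cardiac pulsation
#' near 1.2 Hz, respiration near 0.25 Hz, Mayer waves near 0.1 Hz) plus a
#' small white measurement-noise floor.
#'
#' @return list with `cardiac`, `respiratory`, `mayer` (each `freq_hz`,
#'   `amp_od`), `white_od_sd`, `hbo_sd_um` (µM rms of the hemodynamic
#'   signal) and `i0` (baseline intensity, a.u.).
#' @export
default_noise_spec <- function() {
  list(cardiac = list(freq_hz = 1.2, amp_od = 2.0e-3),
       respiratory = list(freq_hz = 0.25, amp_od = 1.5e-3),
       mayer = list(freq_hz = 0.10, amp_od = 2.0e-3),
       white_od_sd = 2e-4,
       hbo_sd_um = 0.05,
       i0 = 1e5)
}

# calibrated generator constants (frozen; see the methods vignette):
# effect_size_d -> fractional weakening of covariance among the effect
# channel's template neighbors, and the relative per-subject severity jitter
.effect_cal <- list(slope = 0.29, jitter_rel = 0.85)

#' Specify a synthetic cohort
#'
#' Collects every generative parameter: group sizes, recording geometry,
#' channel covariance, the planted group effect, the HAMD coupling, noise
#' components and the master seed. Defaults reproduce the emulated study:
#' n = 34 depression / 30 control, 600 s recordings at 50 Hz over 39
#' channels, HAMD 22.55 +/- 1.27 vs 6.66 +/- 1.51, and a nodal
#' local-efficiency deficit of standardized size `effect_size_d` at channel
#' 36 (occipital).
#'
#' @param n_group1,n_group2 depression / control group sizes.
#' @param duration_s,fs recording length (s) and sampling rate (Hz);
#'   `duration_s * fs` must be a whole number of samples.
#' @param base_covariance channel covariance template; default
#'   [default_base_covariance()].
#' @param effect_channel channel carrying the planted deficit.
#' @param effect_size_d target standardized group difference in nodal local
#'   efficiency at `effect_channel` (>= 0).
#' @param hamd_coupling HAMD points per SD of planted-effect severity
#'   within group 1 (couples HAMD to the effect channel's metric).
#' @param noise_spec see [default_noise_spec()].
#' @param artifact_rate expected motion artifacts per minute (optical route).
#' @param seed master seed; all per-subject streams derive from it.
#' @param hamd_mean,hamd_sd per-group HAMD means and SDs.
#' @param coupling_sd SD of the per-subject global coupling factor (drives
#'   between-subject spread of mean connectivity).
#' @param band the spontaneous-activity band (Hz) the hemodynamic signals
#'   are confined to.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_group1 = 34L, n_group2 = 30L,
                        duration_s = 600, fs = 50,
                        base_covariance = NULL,
                        effect_channel = 36L, effect_size_d = 0.85,
                        hamd_coupling = 1.15,
                        noise_spec = default_noise_spec(),
                        artifact_rate = 0.5, seed = 1L,
                        hamd_mean = c(22.55, 6.66),
                        hamd_sd = c(1.27, 1.51),
                        coupling_sd = 0.18,
                        band = c(0.01, 0.08)) {
  stopifnot(n_group1 >= 0, n_group2 >= 0, fs > 0, duration_s > 0,
            effect_size_d >= 0, artifact_rate >= 0)
  n_samp <- duration_s * fs
  if (abs(n_samp - round(n_samp)) > 1e-8)
    stop("duration_s * fs must be an integer sample count")
  if (is.null(base_covariance)) base_covariance <- default_base_covariance()
  C <- base_covariance
  if (!isSymmetric(unname(C), tol = 1e-10)) stop("base_covariance must be symmetric")
  if (any(abs(diag(C) - 1) > 1e-10)) stop("base_covariance must have unit diagonal")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop(sprintf("base_covariance is not positive semi-definite (eigenvalue %.3g)",
                 min(ev)))
  structure(list(n_group1 = as.integer(n_group1), n_group2 = as.integer(n_group2),
                 duration_s = duration_s, fs = fs,
                 base_covariance = C,
                 effect_channel = as.integer(effect_channel),
                 effect_size_d = effect_size_d,
                 hamd_coupling = hamd_coupling,
                 noise_spec = noise_spec, artifact_rate = artifact_rate,
                 seed = as.integer(seed),
                 hamd_mean = hamd_mean, hamd_sd = hamd_sd,
                 coupling_sd = coupling_sd, band = band),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Cohort spec:", x$n_group1, "depression +", x$n_group2, "control;",
      x$duration_s, "s at", x$fs, "Hz;", nrow(x$base_covariance),
      "channels; planted d =", x$effect_size_d, "at channel",
      x$effect_channel, "; seed", x$seed, "\n")
  invisible(x)
}

# template neighborhood of the effect channel: neighbors in the base
# covariance binarized at 25% sparsity (the normalization sparsity)
effect_neighborhood <- function(spec) {
  cm <- structure(list(z = atanh(pmin(pmax(spec$base_covariance, 0), 1 - 1e-7)),
                       valid_mask = rep(TRUE, nrow(spec$base_covariance))),
                  class = "connectivity_matrix")
  diag(cm$z) <- 0
  net <- binarize_at_sparsity(cm, 0.25)
  which(net$adjacency[spec$effect_channel, ] > 0)
}

# per-subject covariance: global coupling factor g scales all off-diagonals;
# in group 1 the entries among the effect channel's template neighbors are
# additionally weakened by the severity-dependent factor lambda
subject_covariance <- function(spec, g, lambda, nb) {
  C <- spec$base_covariance
  n <- nrow(C)
  Cs <- g * C + (1 - g) * diag(n)
  if (lambda < 1 && length(nb) >= 2) {
    blk <- Cs[nb, nb]
    blk <- lambda * blk + (1 - lambda) * diag(length(nb)) * diag(blk)
    diag(blk) <- diag(Cs)[nb]
    Cs[nb, nb] <- blk
  }
  # repair tiny negative eigenvalues introduced by the block edit
  ev <- eigen(Cs, symmetric = TRUE)
  if (min(ev$values) < 1e-10) {
    v <- pmax(ev$values, 1e-8)
    Cs <- ev$vectors %*% (v * t(ev$vectors))
    s <- 1 / sqrt(diag(Cs))
    Cs <- Cs * tcrossprod(s)
  }
  Cs
}

# band-limited correlated Gaussian signals, synthesized in the frequency
# domain: complex Gaussian coefficients shaped by four zero-phase passes of
# the same order-3 Butterworth band-pass used in preprocessing (the sharper
# confinement of the same filter family makes the pipeline's own band-pass
# near-idempotent on generated signals), then mixed by chol(C). Only bins
# with non-negligible response are drawn.
band_limited_mvn <- function(n_samp, chol_C, fs, band) {
  sos <- butter_bandpass_sos(3, band[1], band[2], fs)
  f <- (seq_len(n_samp) - 1) / n_samp * fs
  amp <- sos_power_response(sos, f, fs)^4   # (|H|^2)^4: four zero-phase passes
  amp <- amp / sqrt(mean(amp^2))            # unit-variance shaped noise
  half <- 2:ceiling((n_samp + 1) / 2)       # positive-frequency bins, no DC
  keep <- half[amp[half] > 1e-7]
  nc <- ncol(chol_C)
  X <- matrix(0 + 0i, n_samp, nc)
  Z <- matrix(complex(real = stats::rnorm(length(keep) * nc),
                      imaginary = stats::rnorm(length(keep) * nc)),
              length(keep), nc)
  X[keep, ] <- sqrt(n_samp / 2) * Z * amp[keep]
  X[n_samp + 2 - keep, ] <- Conj(X[keep, ])
  Y <- Re(stats::mvfft(X, inverse = TRUE)) / n_samp
  Y %*% chol_C
}

#' Generate a synthetic two-group cohort (direct hemodynamic route)
#'
#' Draws, per subject, a band-limited multichannel HbO signal with channel
#' covariance equal to the subject's covariance (the template scaled by a
#' per-subject coupling factor; in group 1 additionally weakened among the
#' effect channel's neighborhood according to the planted effect size and a
#' per-subject severity), plus the clinical table. HAMD in group 1 is the
#' group baseline plus `hamd_coupling` times the standardized severity plus
#' rounding noise, so depression severity is coupled to the effect channel's
#' local efficiency. Identical spec (including seed) gives bit-identical
#' output.
#'
#' @param spec a [cohort_spec()].
#' @param layout a [generate_probe_layout()]; defaults to the standard
#'   39-channel montage.
#' @return list with `subjects` (data.frame: subject, group, age, sex, hamd,
#'   medication, severity) and `recordings` (list of `hemo_recording`).
#' @export
generate_hemo_cohort <- function(spec, layout = generate_probe_layout(nrow(spec$base_covariance) * 0 + 19L,
                                                                      15L, nrow(spec$base_covariance))) {
  n1 <- spec$n_group1; n2 <- spec$n_group2
  nb <- effect_neighborhood(spec)
  nsamp <- round(spec$duration_s * spec$fs)
  weaken <- .effect_cal$slope * spec$effect_size_d
  subjects <- list(); recordings <- vector("list", n1 + n2)
  idx <- 0L
  for (grp in 1:2) {
    ng <- if (grp == 1) n1 else n2
    for (s in seq_len(ng)) {
      idx <- idx + 1L
      sid <- sprintf("%s%02d", if (grp == 1) "dep" else "con", s)
      rec <- with_seed(substream_seed(spec$seed, "simulate", idx), {
        g <- min(max(stats::rnorm(1, 1, spec$coupling_sd), 0.5), 1.4)
        u <- stats::rnorm(1)
        lambda <- if (grp == 1)
          min(max(1 - weaken * (1 + .effect_cal$jitter_rel * u), 0), 1) else 1
        hamd_noise_sd <- sqrt(max(spec$hamd_sd[grp]^2 -
                                    (if (grp == 1) spec$hamd_coupling^2 else 0),
                                  0.09))
        hamd <- max(0, round(spec$hamd_mean[grp] +
                               (if (grp == 1) spec$hamd_coupling * u else 0) +
                               stats::rnorm(1, 0, hamd_noise_sd)))
        age <- round(min(max(stats::rnorm(1, if (grp == 1) 38.41 else 34.43,
                                          if (grp == 1) 13.14 else 5.03), 18), 65))
        sex <- if (stats::runif(1) < (if (grp == 1) 24 / 34 else 22 / 30))
          "F" else "M"
        med <- grp == 1 && stats::runif(1) < 0.8
        Cs <- subject_covariance(spec, g, lambda, nb)
        hbo <- band_limited_mvn(nsamp, chol(Cs), spec$fs, spec$band) *
          spec$noise_spec$hbo_sd_um
        colnames(hbo) <- seq_len(ncol(hbo))
        list(subject = data.frame(subject = sid,
                                  group = if (grp == 1) "depression" else "control",
                                  age = age, sex = sex, hamd = hamd,
                                  medication = med, severity = if (grp == 1) u else NA_real_),
             rec = new_hemo_recording(sid, hbo = hbo, hbr = -0.3 * hbo,
                                      fs = spec$fs,
                                      provenance = list(list(step = "simulate",
                                                             seed = spec$seed,
                                                             lambda = lambda,
                                                             coupling = g))))
      })
      subjects[[idx]] <- rec$subject
      recordings[[idx]] <- rec$rec
    }
  }
  list(subjects = do.call(rbind, subjects), recordings = recordings)
}

#' Forward-model raw optical intensities for one subject
#'
#' Embeds the subject's hemodynamic signal into three-wavelength light
#' intensities via the modified Beer-Lambert law (extinction coefficients
#' from [extinction_coefficients()], path length from the layout separation
#' and the differential pathlength factor), then adds sinusoidal cardiac,
#' respiratory and Mayer-wave optical-density components with per-channel
#' random phases plus white measurement noise:
#' `I = i0 * exp(-OD_total)`.
#'
#' @param subject one row of the cohort clinical table, or a subject id.
#' @param layout probe layout.
#' @param spec the [cohort_spec()].
#' @param hemo optional `hemo_recording` for this subject (it is generated
#'   from the subject's stream if omitted; pass the cohort's recording to
#'   guarantee consistency with [generate_hemo_cohort()]).
#' @param subject_index index of the subject in the cohort (drives the
#'   optics substream; default 1).
#' @param dpf differential pathlength factor of the forward model.
#' @return object of class `raw_recording`: `samples` (time x channel x
#'   wavelength array of intensities), `wavelengths_nm`, `fs`,
#'   `artifact_log`, `subject_id`.
#' @export
generate_raw_intensity <- function(subject, layout, spec, hemo = NULL,
                                   subject_index = 1L, dpf = 6) {
  sid <- if (is.data.frame(subject)) subject$subject[1] else as.character(subject)
  ns <- spec$noise_spec
  if (is.null(hemo)) {
    one <- spec
    one$n_group1 <- 0L; one$n_group2 <- 1L
    one$seed <- substream_seed(spec$seed, "optics", subject_index)
    hemo <- generate_hemo_cohort(one, layout)$recordings[[1]]
  }
  nsamp <- nrow(hemo$hbo)
  nch <- n_channels(layout)
  stopifnot(ncol(hemo$hbo) == nch)
  ext <- extinction_coefficients()
  wl <- as.numeric(rownames(ext))
  tt <- (seq_len(nsamp) - 1) / spec$fs
  pl <- layout$separation_cm * dpf
  samples <- array(NA_real_, c(nsamp, nch, length(wl)),
                   dimnames = list(NULL, seq_len(nch), wl))
  with_seed(substream_seed(spec$seed, "optics", 10000L + subject_index), {
    for (ch in seq_len(nch)) {
      physio <- 0
      for (comp in c("cardiac", "respiratory", "mayer")) {
        cmp <- ns[[comp]]
        physio <- physio + cmp$amp_od *
          sin(2 * pi * cmp$freq_hz * tt + stats::runif(1, 0, 2 * pi))
      }
      for (w in seq_along(wl)) {
        od <- (ext[w, "hbo"] * hemo$hbo[, ch] + ext[w, "hbr"] * hemo$hbr[, ch]) *
          pl[ch] + physio +
          if (ns$white_od_sd > 0) stats::rnorm(nsamp, 0, ns$white_od_sd) else 0
        samples[, ch, w] <- ns$i0 * exp(-od)
      }
    }
  })
  structure(list(subject_id = sid, samples = samples, wavelengths_nm = wl,
                 fs = spec$fs,
                 artifact_log = data.frame(channel = integer(0),
                                           onset_sample = integer(0),
                                           type = character(0))),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  d <- dim(x$samples)
  cat("Raw optical recording", x$subject_id, ":", d[1], "samples x", d[2],
      "channels x", d[3], "wavelengths at", x$fs, "Hz;",
      nrow(x$artifact_log), "logged artifacts\n")
  invisible(x)
}

#' Inject motion artifacts into a raw recording
#'
#' Adds abrupt-onset artifacts at Poisson-random times and channels:
#' `spike` events (instantaneous jump with exponential recovery, total
#' duration <= 1 s) and baseline `shift` events (step persisting to the end
#' of the record). Amplitudes are `amplitude_sd` times the channel's
#' log-intensity SD, applied multiplicatively to all wavelengths, and every
#' event is appended to `artifact_log`.
#'
#' @param rec a `raw_recording`.
#' @param rate_per_min expected events per minute (Poisson).
#' @param spec the [cohort_spec()] (supplies the seed).
#' @param amplitude_sd artifact amplitude in units of channel log-intensity
#'   SD.
#' @return the recording with artifacts applied and an updated log.
#' @export
inject_motion_artifacts <- function(rec, rate_per_min, spec,
                                    amplitude_sd = 10) {
  stopifnot(rate_per_min >= 0)
  if (rate_per_min == 0) return(rec)
  nsamp <- dim(rec$samples)[1]; nch <- dim(rec$samples)[2]
  nwl <- dim(rec$samples)[3]
  fs <- rec$fs
  with_seed(substream_seed(spec$seed, "artifact",
                           sum(utf8ToInt(rec$subject_id))), {
    n_ev <- stats::rpois(1, rate_per_min * nsamp / fs / 60)
    if (n_ev == 0) return(rec)
    log_add <- data.frame(channel = sample.int(nch, n_ev, replace = TRUE),
                          onset_sample = sample.int(max(nsamp - fs, 1), n_ev,
                                                    replace = TRUE),
                          type = sample(c("spike", "shift"), n_ev,
                                        replace = TRUE))
    for (ev in seq_len(n_ev)) {
      ch <- log_add$channel[ev]; on <- log_add$onset_sample[ev]
      sgn <- sample(c(-1, 1), 1)
      dur <- round(stats::runif(1, 0.2, 1) * fs)
      for (w in seq_len(nwl)) {
        x <- rec$samples[, ch, w]
        amp <- amplitude_sd * stats::sd(log(x)) * sgn
        if (log_add$type[ev] == "spike") {
          span <- on:min(on + dur - 1, nsamp)
          shape <- exp(-(seq_along(span) - 1) / (0.25 * fs))
          x[span] <- x[span] * exp(-amp * shape)
        } else {
          x[on:nsamp] <- x[on:nsamp] * exp(-amp)
        }
        rec$samples[, ch, w] <- x
      }
    }
    rec$artifact_log <- rbind(rec$artifact_log, log_add)
    rec
  })
}
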