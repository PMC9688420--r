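make_raw <- function(samples, fs = 10) {
  structure(list(subject_id = "t", samples = samples,
                 wavelengths_nm = c(730, 808, 850),
                 fs = fs,
                 artifact_log = data.frame(channel = integer(0),
                                           onset_sample = integer(0),
                                           type = character(0))),
            class = "raw_recording")
}

test_that("channel pruning applies intensity, positivity and SNR rules", {
  set.seed(1)
  n <- 200
  s <- array(1000 + rnorm(n * 4 * 3, sd = 10), c(n, 4, 3))
  s[, 2, 1] <- 2                               # constant positive: SNR Inf, kept
  s[, 3, 2] <- rnorm(n, mean = 1, sd = 1)      # SNR ~1 < 2 -> pruned
  s[5, 4, 3] <- -1                             # non-positive sample -> pruned
  raw <- make_raw(s)
  mask <- prune_channels(raw)
  expect_identical(mask, c(TRUE, TRUE, FALSE, FALSE))
  s_hi <- s; s_hi[, 1, 1] <- 2e7               # mean above od_high
  expect_false(prune_channels(make_raw(s_hi))[1])
  s_all <- array(-1, c(10, 2, 3))
  expect_error(prune_channels(make_raw(s_all)), "all channels pruned")
})

test_that("optical density is the negative log ratio to the channel mean", {
  s <- array(5, c(100, 2, 3))
  expect_equal(intensity_to_od(make_raw(s)), array(0, c(100, 2, 3)),
               ignore_attr = TRUE)
  # one sample at e times the mean gives OD = -1 there
  x <- c(rep((3 - exp(1)) / 2, 2), exp(1))
  s2 <- array(rep(x, 6), c(3, 2, 3))
  od <- intensity_to_od(make_raw(s2))
  expect_equal(od[3, 1, 1], -1)
  s3 <- s; s3[1, 1, 1] <- 0
  expect_error(intensity_to_od(make_raw(s3)), "non-positive")
})

test_that("Beer-Lambert inversion recovers known concentration changes exactly", {
  lay <- generate_probe_layout(2, 2, 2, c(`1` = "frontal", `2` = "central"))
  cfg <- preprocess_config()
  E <- extinction_coefficients()
  n <- 50
  hbo <- sin(seq_len(n) / 5) * 0.3
  hbr <- cos(seq_len(n) / 7) * 0.1
  od <- array(NA_real_, c(n, 2, 3))
  for (ch in 1:2)
    od[, ch, ] <- cbind(hbo, hbr) %*% t(E) * lay$separation_cm[ch] * cfg$dpf
  rec <- od_to_concentration(od, lay, cfg)
  expect_equal(rec$hbo[, 1], hbo)
  expect_equal(rec$hbr[, 2], hbr)
  # zero OD -> zero concentrations; doubling DPF halves the estimates
  expect_equal(od_to_concentration(od * 0, lay, cfg)$hbo[, 1], rep(0, n))
  rec2 <- od_to_concentration(od, lay, preprocess_config(dpf = 12))
  expect_equal(rec2$hbo[, 1], hbo / 2)
  bad <- E; bad[, "hbr"] <- bad[, "hbo"]
  expect_error(od_to_concentration(od, lay, cfg, extinction = bad), "singular")
  expect_error(od_to_concentration(od, lay, cfg,
                                   extinction = E * c(1, NA, 1)), "missing")
})

test_that("motion detection flags abrupt changes and dilates by the mask window", {
  fs <- 10
  cfg <- preprocess_config()
  flat <- matrix(0, 300, 1)
  expect_false(any(detect_motion_artifacts(flat, cfg, fs = fs)))
  set.seed(2)
  x <- matrix(cumsum(rnorm(300, sd = 0.001)), ncol = 1)   # smooth background
  x[150:300] <- x[150:300] + 10 * sd(x)                   # 10-SD step
  m <- detect_motion_artifacts(x, cfg, fs = fs)
  expect_true(all(m[(150 - fs):(150 + fs), 1]))           # step +/- 1 s covered
  expect_false(any(m[1:100, 1]))
  inf_cfg <- preprocess_config(stdev_thresh = Inf, amp_thresh = Inf)
  expect_false(any(detect_motion_artifacts(x, inf_cfg, fs = fs)))
})

test_that("spline correction removes a baseline shift and respects locality", {
  n <- 200
  v <- rep(1, n)
  v[100:n] <- v[100:n] + 5                     # pure baseline shift
  mask <- matrix(FALSE, n, 1)
  mask[95:105, 1] <- TRUE
  out <- spline_correct(matrix(v), mask)
  expect_lt(max(abs(out - 1)), 1e-6)           # flat again
  # empty mask: identity
  expect_identical(spline_correct(matrix(v), matrix(FALSE, n, 1)), matrix(v))
  # unflagged samples change only by segment-wise constant offsets
  set.seed(3)
  w <- cumsum(rnorm(n, sd = 0.1))
  w[80:90] <- w[80:90] + 3
  mask2 <- matrix(FALSE, n, 1); mask2[78:92, 1] <- TRUE
  out2 <- spline_correct(matrix(w), mask2)
  pre <- 1:77; post <- 93:n
  expect_equal(out2[pre, 1], w[pre])
  expect_equal(diff(out2[post, 1]), diff(w[post]))   # shifted by a constant
})

test_that("band-pass response meets its passband and stopband contract", {
  fs <- 50
  cfg <- preprocess_config()
  tt <- seq(0, 600 - 1 / fs, by = 1 / fs)
  probe <- function(f) {
    y <- bandpass(matrix(sin(2 * pi * f * tt)), cfg, fs = fs)
    max(abs(y[10000:20000, 1]))
  }
  expect_gte(probe(0.05), 0.9)
  expect_lte(probe(1.2), 0.1)
  expect_lte(probe(0.16), 0.1)                 # >= 90% attenuation at 2x edge
  expect_equal(bandpass(matrix(0, 30000, 1), cfg, fs = fs),
               matrix(0, 30000, 1))
  expect_error(bandpass(matrix(rnorm(100)), cfg, fs = fs), "too short")
  # near-idempotence for in-band content
  x <- matrix(sin(2 * pi * 0.04 * tt) + 0.5 * sin(2 * pi * 0.02 * tt))
  y1 <- bandpass(x, cfg, fs = fs)
  y2 <- bandpass(y1, cfg, fs = fs)
  expect_lt(abs(sqrt(mean(y2^2)) / sqrt(mean(y1^2)) - 1), 0.05)
})

test_that("the periodized DWT reconstructs perfectly and denoising clips spikes", {
  set.seed(4)
  x <- matrix(rnorm(777), ncol = 1)            # non-dyadic length
  cfg_inf <- preprocess_config(wavelet_alpha = Inf)
  expect_equal(wavelet_denoise(x, cfg_inf), x, tolerance = 1e-8)
  expect_equal(nrow(wavelet_denoise(x, preprocess_config())), 777)
  # smooth signal plus sparse large spikes
  n <- 1024
  base <- sin(2 * pi * (1:n) / 128)
  spikes <- rep(0, n); spikes[c(200, 600, 900)] <- 8
  y <- wavelet_denoise(matrix(base + spikes), preprocess_config())[, 1]
  expect_lt(max(abs((y - base)[c(200, 600, 900)])), 4)   # >= 50% suppression
  bg <- setdiff(1:n, as.vector(outer(c(200, 600, 900), -8:8, `+`)))
  rms_change <- sqrt(mean((y - base)[bg]^2)) / sqrt(mean(base[bg]^2))
  expect_lt(rms_change, 0.05)
})

test_that("noiseless optics round-trip recovers the planted hemodynamics", {
  ns <- default_noise_spec()
  ns$cardiac$amp_od <- 0; ns$respiratory$amp_od <- 0; ns$mayer$amp_od <- 0
  ns$white_od_sd <- 0
  spec <- cohort_spec(n_group1 = 0, n_group2 = 1, duration_s = 600, fs = 25,
                      noise_spec = ns, seed = 8)
  lay <- generate_probe_layout()
  coh <- generate_hemo_cohort(spec, lay)
  raw <- generate_raw_intensity(coh$subjects$subject[1], lay, spec,
                                hemo = coh$recordings[[1]])
  rec <- preprocess(raw, lay)
  planted <- coh$recordings[[1]]$hbo
  cors <- vapply(1:39, function(ch) cor(rec$hbo[, ch], planted[, ch]),
                 numeric(1))
  expect_gt(min(cors), 0.99)
  steps <- vapply(rec$provenance, function(p) p$step, character(1))
  expect_identical(steps, c("prune", "intensity_to_od", "motion_correct",
                            "od_to_concentration", "bandpass",
                            "wavelet_denoise"))
})
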