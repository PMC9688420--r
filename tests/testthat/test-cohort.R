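test_that("cohort specs validate their covariance and geometry contracts", {
  expect_s3_class(cohort_spec(), "cohort_spec")
  expect_error(cohort_spec(duration_s = 10.3, fs = 3), "integer sample count")
  C <- default_base_covariance()
  C[1, 2] <- 0.9; C[2, 1] <- 0.1
  expect_error(cohort_spec(base_covariance = C), "symmetric")
  C <- default_base_covariance(); diag(C)[3] <- 2
  expect_error(cohort_spec(base_covariance = C), "unit diagonal")
  C <- matrix(0.99, 4, 4) * (1 - diag(4)) + diag(4)
  C[1, 2] <- C[2, 1] <- -0.99                # indefinite
  expect_error(cohort_spec(base_covariance = C), "eigenvalue")
})

test_that("identical specs give bit-identical cohorts", {
  spec <- cohort_spec(n_group1 = 2, n_group2 = 2, duration_s = 120, fs = 5,
                      seed = 42)
  a <- generate_hemo_cohort(spec)
  b <- generate_hemo_cohort(spec)
  expect_identical(a, b)
  c2 <- generate_hemo_cohort(cohort_spec(n_group1 = 2, n_group2 = 2,
                                         duration_s = 120, fs = 5, seed = 43))
  expect_false(identical(a$recordings[[1]]$hbo, c2$recordings[[1]]$hbo))
})

test_that("clinical table matches the emulated study's marginals", {
  spec <- cohort_spec(duration_s = 60, fs = 5, seed = 11)
  coh <- generate_hemo_cohort(spec)
  subj <- coh$subjects
  expect_equal(nrow(subj), 64)
  expect_equal(sum(subj$group == "depression"), 34)
  expect_equal(mean(subj$hamd[subj$group == "depression"]), 22.55,
               tolerance = 2 / 22.55)
  expect_equal(mean(subj$hamd[subj$group == "control"]), 6.66,
               tolerance = 2 / 6.66)
  expect_true(all(subj$hamd >= 0 & subj$hamd == round(subj$hamd)))
  expect_true(all(subj$medication[subj$group == "control"] == FALSE))
  expect_length(coh$recordings, 64)
})

test_that("an empty patient group is allowed", {
  coh <- generate_hemo_cohort(cohort_spec(n_group1 = 0, n_group2 = 2,
                                          duration_s = 60, fs = 5, seed = 1))
  expect_equal(nrow(coh$subjects), 2)
  expect_true(all(coh$subjects$group == "control"))
})

test_that("zero planted effect leaves the two groups' covariances equal", {
  spec <- cohort_spec(n_group1 = 4, n_group2 = 4, duration_s = 6000, fs = 5,
                      effect_size_d = 0, seed = 21)
  coh <- generate_hemo_cohort(spec)
  g1 <- which(coh$subjects$group == "depression")
  covmean <- function(idx) {
    m <- Reduce(`+`, lapply(coh$recordings[idx],
                            function(r) stats::cor(r$hbo)))
    m / length(idx)
  }
  c1 <- covmean(g1); c2 <- covmean(setdiff(1:8, g1))
  expect_gt(stats::cor(c1[upper.tri(c1)], c2[upper.tri(c2)]), 0.9)
})

test_that("hemodynamic signals are band-limited to 0.01-0.08 Hz", {
  spec <- cohort_spec(n_group1 = 0, n_group2 = 1, seed = 5)   # study fs = 50
  rec <- generate_hemo_cohort(spec)$recordings[[1]]
  x <- rec$hbo[, 1]
  n <- length(x)
  pw <- Mod(stats::fft(x))[2:(n / 2)]^2
  f <- (1:(n / 2 - 1)) / n * spec$fs
  inband <- f >= 0.01 & f <= 0.08
  expect_gt(sum(pw[inband]) / sum(pw), 0.95)
})

test_that("planted deficit lowers channel-36 local efficiency near target d", {
  d36 <- vapply(1:15, function(b) {
    coh <- generate_hemo_cohort(fast_spec(700 + b))
    mets <- cohort_metrics(coh$recordings, sparsity = 0.25)
    g1 <- coh$subjects$group == "depression"
    x <- mets$eloc_nodal[, 36]
    cohens_d_pooled(mean(x[!g1]), sd(x[!g1]), sum(!g1),
                    mean(x[g1]), sd(x[g1]), sum(g1))
  }, numeric(1))
  expect_equal(mean(d36), 0.85, tolerance = 0.2 / 0.85)
  # HAMD is coupled to the planted severity: negative metric-HAMD relation
  coh <- generate_hemo_cohort(fast_spec(900))
  g1 <- coh$subjects$group == "depression"
  el <- cohort_metrics(coh$recordings, 0.25)$eloc_nodal[g1, 36]
  expect_lt(cor(el, coh$subjects$hamd[g1]), 0)
})

test_that("raw optical forward model embeds physiology and recovers hemodynamics", {
  spec <- cohort_spec(n_group1 = 0, n_group2 = 1, duration_s = 360, fs = 50,
                      seed = 31)
  lay <- generate_probe_layout()
  raw <- generate_raw_intensity("s1", lay, spec, subject_index = 1)
  expect_identical(dim(raw$samples), c(18000L, 39L, 3L))
  expect_true(all(raw$samples > 0))
  expect_identical(raw, generate_raw_intensity("s1", lay, spec, subject_index = 1))
  # cardiac line near 1.2 Hz present in OD, absent after band-pass
  od <- -log(raw$samples[, 1, 1] / mean(raw$samples[, 1, 1]))
  n <- length(od)
  pw <- Mod(stats::fft(od - mean(od)))[2:(n / 2)]^2
  f <- (1:(n / 2 - 1)) / n * 50
  peak <- f[which.max(pw)]
  expect_equal(peak, 1.2, tolerance = 0.1 / 1.2)
  filt <- bandpass(matrix(od), preprocess_config(), fs = 50)
  pwf <- Mod(stats::fft(filt[, 1] - mean(filt[, 1])))[2:(n / 2)]^2
  cardiac <- abs(f - 1.2) < 0.05
  expect_lt(sum(pwf[cardiac]) / sum(pw[cardiac]), 1e-4)
})

test_that("artifact injection is seeded, logged, and Poisson-counted", {
  spec <- cohort_spec(n_group1 = 0, n_group2 = 1, duration_s = 600, fs = 10,
                      seed = 41)
  lay <- generate_probe_layout()
  raw <- generate_raw_intensity("s1", lay, spec, subject_index = 2)
  expect_identical(inject_motion_artifacts(raw, 0, spec), raw)
  art <- inject_motion_artifacts(raw, 2, spec)
  expect_gt(nrow(art$artifact_log), 7)      # Poisson(20): P(<8) ~ 1e-3
  expect_lt(nrow(art$artifact_log), 37)
  expect_identical(inject_motion_artifacts(raw, 2, spec), art)
  expect_true(all(art$artifact_log$type %in% c("spike", "shift")))
})
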