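# MBLL inversion, motion correction, band-pass, rest z-scoring.

test_that("band-pass meets its response contract", {
  fs <- 11; t <- seq(0, 500, by = 1 / fs)
  mid <- 1500:4000
  # DC removed
  expect_lt(max(abs(bandpass(rep(3, 2000), fs))), 1e-6)
  # 1.1 Hz (cardiac) attenuated by >= 20 dB
  y <- bandpass(sin(2 * pi * 1.1 * t), fs)
  expect_lt(sqrt(mean(y[mid]^2)), 0.1)
  # 0.05 Hz passband preserved within 10%
  x <- sin(2 * pi * 0.05 * t)
  y <- bandpass(x, fs)
  expect_equal(sqrt(mean(y[mid]^2)), sqrt(mean(x[mid]^2)), tolerance = 0.1)
  # linear
  x2 <- cos(2 * pi * 0.03 * t)
  expect_equal(bandpass(x + 2 * x2, fs), bandpass(x, fs) + 2 * bandpass(x2, fs),
               tolerance = 1e-10)
  expect_error(bandpass(x, fs, low = 0.1, high = 6), "fs/2")
})

test_that("MBLL inversion is the exact 2x2 solve", {
  const <- mbll_constants()
  # zero in, zero out
  expect_equal(mbll_invert(cbind(0, 0), const),
               cbind(hbo = 0, hbr = 0))
  # round trip
  hbo <- c(1, 0.2, -0.5); hbr <- c(-0.3, 0.1, 0.2)
  conc <- mbll_invert(mbll_forward(hbo, hbr, const), const)
  expect_equal(unname(conc[, "hbo"]), hbo, tolerance = 1e-9)
  expect_equal(unname(conc[, "hbr"]), hbr, tolerance = 1e-9)
  # agreement with per-sample solve()
  set.seed(8)
  od <- matrix(rnorm(40), 20, 2)
  ref <- t(apply(od, 1, function(r) solve(const$m, r)))
  expect_equal(unname(mbll_invert(od, const)), unname(ref), tolerance = 1e-12)
  expect_error(mbll_constants(ext_hbo = c(1, 1), ext_hbr = c(1, 1 + 1e-9)),
               "ill-conditioned")
})

test_that("motion correction flags exactly the spike run and is bounded", {
  fs <- 11; t <- seq(0, 300, by = 1 / fs)
  clean <- sin(2 * pi * 0.05 * t)
  mc <- motion_correct(clean, fs)
  expect_false(any(mc$mask))
  expect_identical(mc$series, clean)
  set.seed(9)
  noisy <- clean + rnorm(length(clean), 0, 0.05)
  spiked <- noisy
  spiked[1200:1202] <- spiked[1200:1202] + 10 * sd(noisy)
  mc <- motion_correct(spiked, fs)
  expect_true(all(1200:1202 %in% which(mc$mask)))
  expect_lte(max(abs(mc$series)), max(abs(spiked)))
  expect_lt(max(abs(mc$series[1200:1202] - clean[1200:1202])), 0.5)
})

test_that("motion correction passes through when most samples are flagged", {
  # an absolute threshold far below the signal scale flags most samples
  t <- seq(0, 100, by = 1 / 11)
  x <- sin(2 * pi * 1.1 * t)
  expect_warning(mc <- motion_correct(x, 11, spike_amp = 0.3), "50%")
  expect_identical(mc$series, x)
})

test_that("rest z-scoring normalizes and refuses double application", {
  fs <- 11; n <- 540 * fs
  segments <- list(rest = c(0, 300), digits1 = c(300, 330),
                   narration = c(330, 510), digits2 = c(510, 540))
  set.seed(10)
  hbo <- matrix(rnorm(n * 3, mean = 5, sd = 2), n, 3)
  h <- hemo_series(hbo, -0.3 * hbo, fs, segments)
  hz <- zscore_by_rest(h)
  idx <- narrafnirs:::.seg_idx(segments$rest, fs, n)
  for (ch in 1:3) {
    expect_lt(abs(mean(hz$hbo[idx, ch])), 1e-6)
    expect_equal(sd(hz$hbo[idx, ch]), 1, tolerance = 1e-6)
  }
  expect_error(zscore_by_rest(hz), "already")
  # affine invariance: z(a x + b) = z(x)
  h2 <- hemo_series(3 * hbo + 7, hbo, fs, segments)
  expect_equal(zscore_by_rest(h2)$hbo, hz$hbo, tolerance = 1e-9)
  # constant channel flagged bad
  hbo[, 2] <- 1
  hb <- hemo_series(hbo, hbo, fs, segments)
  ws <- capture_warnings(hzb <- zscore_by_rest(hb))
  expect_true(all(grepl("zero rest SD", ws)))
  expect_true(2 %in% hzb$bad_channels)
})

test_that("noise-free chain recovers the injected in-band signal", {
  np <- noise_params(drift_amp = 0, cardiac_amp = 0, respiratory_amp = 0,
                     white_sd = 0, lfo_amp = 0)
  spec <- cohort_spec(n_ptsd = 2, n_tec = 2, seed = 12,
                      effect = effect_params(noise = np, subject_amp_cv = 0))
  s <- generate_cohort(spec)[1, ]
  tr <- generate_transcript(s, spec)
  rec <- generate_fnirs(s, tr, spec, return_truth = TRUE)
  h <- preprocess_recording(rec, zscore = FALSE)
  truth_f <- narrafnirs:::.pipeline_filter(attr(rec, "truth"), spec$session$fs_hz)
  ch <- spec$session$target_channel
  expect_gt(cor(h$hbo[, ch], truth_f), 0.999)
  expect_false(any(!is.finite(h$hbo)))
})

test_that("noise-free OD is exactly the forward image of the response", {
  np <- noise_params(drift_amp = 0, cardiac_amp = 0, respiratory_amp = 0,
                     white_sd = 0, lfo_amp = 0)
  spec <- cohort_spec(n_ptsd = 2, n_tec = 2, seed = 13,
                      effect = effect_params(noise = np, subject_amp_cv = 0))
  s <- generate_cohort(spec)[1, ]
  tr <- generate_transcript(s, spec)
  rec <- generate_fnirs(s, tr, spec, return_truth = TRUE)
  truth <- attr(rec, "truth")
  od_expect <- mbll_forward(truth, -spec$effect$hbr_ratio * truth)
  ch <- spec$session$target_channel
  expect_equal(rec$od[, ch, 1], unname(od_expect[, 1]), tolerance = 1e-12)
  expect_equal(rec$od[, ch, 2], unname(od_expect[, 2]), tolerance = 1e-12)
  # mbll_invert . forward is the identity to 1e-9
  conc <- mbll_invert(rec$od[, ch, ])
  expect_equal(unname(conc[, "hbo"]), truth, tolerance = 1e-9)
})
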