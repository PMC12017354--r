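# Synthetic cohort generator: determinism, clinical draws, transcripts,
# fNIRS calibration structure.

test_that("identical spec and seed reproduce the cohort exactly", {
  spec <- cohort_spec(n_ptsd = 3, n_tec = 3, seed = 7)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)
  s <- c1[1, ]
  expect_identical(generate_transcript(s, spec), generate_transcript(s, spec))
  expect_identical(generate_prosody(s, spec), generate_prosody(s, spec))
  tr <- generate_transcript(s, spec)
  r1 <- generate_fnirs(s, tr, spec)
  r2 <- generate_fnirs(s, tr, spec)
  expect_identical(r1$od, r2$od)
  # a different seed changes the data
  spec2 <- cohort_spec(n_ptsd = 3, n_tec = 3, seed = 8)
  expect_false(identical(generate_cohort(spec2), c1))
})

test_that("CAPS-5 draws respect the inclusion floor and printed mean", {
  spec <- cohort_spec(seed = 1)
  coh <- generate_cohort(spec)
  expect_true(all(coh$caps5_total[coh$group == "PTSD"] >= 45))
  expect_true(all(coh$caps5_total[coh$group == "TEC"] < 45))
  # seed-averaged mean recovery (mean-calibrated truncated normal)
  caps <- unlist(lapply(1:40, function(s) {
    coh <- generate_cohort(cohort_spec(seed = s))
    coh$caps5_total[coh$group == "PTSD"]
  }))
  se <- sd(caps) / sqrt(length(caps))
  expect_lt(abs(mean(caps) - 50.89), 2 * se + 0.05)
})

test_that("cohort validation rejects undersized groups", {
  expect_error(cohort_spec(n_ptsd = 1), "at least 2")
})

test_that("transcripts have increasing onsets inside the narration", {
  spec <- cohort_spec(n_ptsd = 2, n_tec = 2, seed = 5)
  coh <- generate_cohort(spec)
  for (i in seq_len(4)) {
    tr <- generate_transcript(coh[i, ], spec)
    expect_true(all(diff(tr$onset_s) > 0))
    expect_true(all(tr$onset_s >= 0 & tr$onset_s < 180))
    expect_true(all(tr$offset_s > tr$onset_s))
    expect_equal(nrow(tr), 450)
  }
})

test_that("a zero negative rate produces no negative tokens", {
  spec <- cohort_spec(n_ptsd = 2, n_tec = 2, seed = 6)
  s <- generate_cohort(spec)[1, ]
  s$neg_rate_true <- 0
  tr <- generate_transcript(s, spec)
  expect_equal(sum(tr$category == "negative"), 0)
})

test_that("transcript negative rates track the subject's true rate", {
  spec <- cohort_spec(n_ptsd = 2, n_tec = 2, seed = 9)
  s <- generate_cohort(spec)[1, ]
  s$neg_rate_true <- 8
  frac <- vapply(1:80, function(i) {
    s$id <- sprintf("R%02d", i)
    mean(generate_transcript(s, spec)$category == "negative")
  }, numeric(1))
  expect_lt(abs(mean(frac) * 100 - 8), 3 * 100 * sd(frac) / sqrt(80))
})

test_that("lexical richness targets order the groups correctly", {
  spec <- cohort_spec(n_ptsd = 6, n_tec = 6, seed = 14)
  coh <- generate_cohort(spec)
  hr <- vapply(seq_len(nrow(coh)), function(i)
    honore_r(generate_transcript(coh[i, ], spec)$token), numeric(1))
  # configured targets are on the R/100 scale: 30.23 vs 34.59
  expect_lt(mean(hr[coh$group == "PTSD"]) / 100, 33)
  expect_gt(mean(hr[coh$group == "TEC"]) / 100, mean(hr[coh$group == "PTSD"]) / 100)
})

test_that("criterion-D subscores correlate with true negative-word rates", {
  rs <- vapply(1:25, function(s) {
    coh <- generate_cohort(cohort_spec(seed = s))
    p <- coh[coh$group == "PTSD", ]
    cor(p$neg_rate_true, p$capsD)
  }, numeric(1))
  se <- sd(rs) / sqrt(length(rs))
  expect_lt(abs(mean(rs) - 0.349), 2 * se + 0.03)
})

test_that("group mean negative rates keep the PTSD > TEC sign", {
  # at the default study size the configured group gap (5.89 vs 4.21,
  # SDs ~2.8) flips sign in well under 5% of cohorts
  signs <- vapply(1:20, function(s) {
    coh <- generate_cohort(cohort_spec(seed = s))
    mean(coh$neg_rate_true[coh$group == "PTSD"]) >
      mean(coh$neg_rate_true[coh$group == "TEC"])
  }, logical(1))
  expect_gte(mean(signs), 0.95)
})

test_that("fNIRS calibration is deterministic and structurally sound", {
  spec <- cohort_spec(seed = 3)
  cal <- fnirs_calibration(spec)
  expect_identical(cal, fnirs_calibration(spec))
  expect_true(all(cal$amp > 0))
  expect_gt(cal$amp[["PTSD"]], cal$amp[["TEC"]] * 0.5)
  expect_gt(cal$rest_sd, 0)
  # onset ordering invariant of the control response landmarks
  hrf <- spec$effect$hrf_tec
  expect_true(hrf$onset_s < hrf$peak_s && hrf$peak_s < hrf$return_s)
})

test_that("fNIRS rejects onsets outside the narration", {
  spec <- cohort_spec(n_ptsd = 2, n_tec = 2, seed = 4)
  s <- generate_cohort(spec)[1, ]
  tr <- generate_transcript(s, spec)
  tr$onset_s[5] <- 400
  expect_error(generate_fnirs(s, tr, spec), "narration")
})
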