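# Event windows, activation, channelwise tests, time-course profiling.

mk_hemo <- function(x, fs = 11, nch = 1) {
  n <- length(x)
  segments <- list(rest = c(0, 300), digits1 = c(300, 330),
                   narration = c(330, 510), digits2 = c(510, 540))
  h <- hemo_series(matrix(rep(x, nch), n, nch), matrix(0, n, nch), fs,
                   segments, zscored = TRUE)
  h
}

test_that("window extraction obeys shape and boundary rules", {
  fs <- 11
  x <- rnorm(540 * fs)
  h <- mk_hemo(x)
  w <- extract_windows(h, 1, c(340, 400, 470))
  expect_equal(dim(w$windows), c(3, 110))
  expect_equal(w$windows[2, ], x[(400 * fs + 1):(400 * fs + 110)])
  # onset too near the recording end is dropped
  expect_message(w2 <- extract_windows(h, 1, c(400, 536)), "dropped")
  expect_equal(nrow(w2$windows), 1)
  expect_equal(w2$dropped, 536)
  # constant series gives constant windows
  wc <- extract_windows(mk_hemo(rep(2, 540 * fs)), 1, c(350, 360))
  expect_true(all(wc$windows == 2))
  hraw <- mk_hemo(x); hraw$zscored <- FALSE
  expect_error(extract_windows(hraw, 1, 340), "z-scored")
})

test_that("subject activation is windows mean minus pooled digit mean", {
  fs <- 11; n <- 540 * fs
  x <- numeric(n)
  segments <- list(rest = c(0, 300), digits1 = c(300, 330),
                   narration = c(330, 510), digits2 = c(510, 540))
  x[narrafnirs:::.seg_idx(segments$digits1, fs, n)] <- 0.2
  x[narrafnirs:::.seg_idx(segments$digits2, fs, n)] <- 0.2
  x[(350 * fs):(505 * fs)] <- 0.5
  h <- mk_hemo(x)
  act <- subject_activation(h, c(355, 380, 420)) # windows within the 0.5 block
  expect_equal(unname(act), 0.3, tolerance = 1e-10)
  # identical windows and digits cancel
  expect_equal(unname(subject_activation(mk_hemo(rep(1, n)), c(340, 400))), 0)
  # brute-force recomputation on a random fixture
  set.seed(21)
  xr <- rnorm(n)
  h <- mk_hemo(xr)
  onsets <- c(335.2, 361.7, 402.1, 455.9)
  act <- subject_activation(h, onsets)
  wm <- mean(unlist(lapply(onsets, function(o) {
    i0 <- floor(o * fs) + 1
    xr[i0:(i0 + 109)]
  })))
  dm <- mean(xr[c(narrafnirs:::.seg_idx(segments$digits1, fs, n),
                  narrafnirs:::.seg_idx(segments$digits2, fs, n))])
  expect_equal(unname(act), wm - dm, tolerance = 1e-12)
  hs <- mk_hemo(xr); hs$segments$digits2 <- NULL
  expect_error(subject_activation(hs, onsets), "digit")
})

test_that("Mann-Whitney channel test matches exact enumeration", {
  tab <- data.frame(subject = rep(1:6, 1), group = rep(c("PTSD", "TEC"), each = 3),
                    channel = 1, activation = c(1, 2, 3, 4, 5, 6))
  res <- group_channel_test(tab)
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1) # 2 / choose(6,3)
  expect_equal(res$cliffs_delta, -1)
  # identical groups: delta 0, p near 1, no crash
  tab2 <- data.frame(group = rep(c("PTSD", "TEC"), each = 4), channel = 1,
                     activation = rep(c(5, 6, 7, 8), 2), subject = 1:8)
  res2 <- group_channel_test(tab2)
  expect_equal(res2$cliffs_delta, 0)
  expect_gt(res2$p, 0.5)
})

test_that("small-group channel tests use exact enumeration", {
  # brute-force oracle: enumerate all group assignments of the pooled
  # sample and compute the two-sided tail probability of U
  enum_p <- function(x, y) {
    pool <- c(x, y); n1 <- length(x)
    idx <- combn(length(pool), n1)
    ustat <- function(a) {
      xx <- pool[a]; yy <- pool[-a]
      sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
    }
    us <- apply(idx, 2, ustat)
    u <- ustat(seq_len(n1))
    min(1, 2 * min(mean(us <= u + 1e-9), mean(us >= u - 1e-9)))
  }
  set.seed(22)
  for (r in 1:8) {
    x <- rnorm(sample(4:6, 1)); y <- rnorm(sample(4:6, 1), 0.5)
    tab <- data.frame(subject = seq_along(c(x, y)),
                      group = rep(c("PTSD", "TEC"), c(length(x), length(y))),
                      channel = 1, activation = c(x, y))
    expect_equal(group_channel_test(tab)$p, enum_p(x, y), tolerance = 1e-12)
  }
  # the tie-corrected normal approximation stays close to exact at n = 8
  devs <- vapply(1:20, function(r) {
    set.seed(100 + r)
    x <- rnorm(8); y <- rnorm(8, 0.5)
    abs(wilcox.test(x, y, exact = TRUE)$p.value -
          suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                       correct = TRUE)$p.value))
  }, numeric(1))
  expect_lt(median(devs), 0.01)
  expect_lt(max(devs), 0.035)
})

test_that("BH step-up matches the definitional recomputation", {
  bh_brute <- function(p) {
    m <- length(p); o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(1, q)[order(o)]
  }
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  set.seed(23)
  for (r in 1:10) {
    p <- runif(sample(5:100, 1))
    expect_equal(p.adjust(p, "BH"), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("grand average pools events then subjects", {
  w1 <- list(windows = matrix(0, 2, 10))
  w2 <- list(windows = matrix(1, 5, 10))
  expect_equal(grand_average(list(w1, w2)), rep(0.5, 10))
  one <- list(windows = matrix(rnorm(10), 1, 10))
  expect_equal(grand_average(list(one)), one$windows[1, ])
  # invariant to event order within subject
  set.seed(24)
  m <- matrix(rnorm(50), 5, 10)
  wa <- list(windows = m)
  wb <- list(windows = m[sample(5), ])
  expect_equal(grand_average(list(wa)), grand_average(list(wb)))
  expect_error(grand_average(list()), "empty")
})

test_that("time-course characterization finds landmarks and trends", {
  fs <- 11
  # strictly increasing ramp: perfect rank correlation
  ramp <- seq(0, 1, length.out = 110)
  pr <- characterize_timecourse(ramp, fs)
  expect_equal(pr$spearman_r, 1)
  # flat zero: no latency, difference 0
  expect_message(pf <- characterize_timecourse(rep(0, 110), fs), "zero baseline")
  expect_true(pf$no_latency)
  expect_equal(pf$difference, 0)
  # trapezoid with landmarks at 3.82 / 7.55 s
  t <- (0:109) / fs
  tz <- narrafnirs:::.tec_shape(t, list(onset_s = 3.82, peak_s = 7.55,
                                        return_s = 12))
  set.seed(25)
  tz <- tz + rnorm(110, 0, 0.005)
  pt <- characterize_timecourse(tz, fs)
  expect_false(pt$no_latency)
  expect_lt(abs(pt$latency_s - 3.82), 1 / fs + 0.35)
  expect_equal(pt$peak_time_s, 7.55, tolerance = 0.2)
  expect_equal(pt$difference, max(tz) - min(tz))
  # slope consistency: per-sample slope times rise length ~ peak - start
  rise <- pt$slope_per_sample * (pt$peak_time_s - pt$latency_s) * fs
  expect_equal(rise, pt$peak - tz[round(pt$latency_s * fs) + 1],
               tolerance = 0.12)
})
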