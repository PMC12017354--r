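# Event-locked analysis: window extraction around negative-word onsets,
# baseline-subtracted activation, channelwise Mann-Whitney tests with
# Benjamini-Hochberg FDR, group-average time courses and their
# characterization (latency, slope, peak, Spearman trend).

#' Extract event-locked windows
#'
#' One row per onset with at least `window_s` of recording remaining;
#' onsets too close to the end of the recording are dropped (and
#' reported). Overlapping windows are permitted.
#'
#' @param hemo A z-scored [hemo_series()].
#' @param channel Channel index.
#' @param onsets Event onsets in recording time (seconds, sorted).
#' @param window_s Window length in seconds (default 10).
#' @return List of class `event_window_set`: `windows` (events x
#'   samples), `onsets` kept, `dropped` onsets, `fs_hz`, `channel`.
#' @export
extract_windows <- function(hemo, channel, onsets, window_s = 10) {
  stopifnot(inherits(hemo, "hemo_series"))
  if (!isTRUE(hemo$zscored)) stop("extract_windows expects z-scored input")
  if (is.unsorted(onsets)) stop("onsets must be sorted")
  fs <- hemo$fs_hz
  n <- nrow(hemo$hbo)
  len <- round(window_s * fs)
  i0 <- floor(onsets * fs) + 1L
  keep <- i0 + len - 1L <= n & i0 >= 1L
  if (!all(keep))
    message(sum(!keep), " onset(s) dropped (window exceeds recording)")
  i0 <- i0[keep]
  w <- matrix(NA_real_, length(i0), len)
  x <- hemo$hbo[, channel]
  for (k in seq_along(i0)) w[k, ] <- x[seq.int(i0[k], i0[k] + len - 1L)]
  structure(list(windows = w, onsets = onsets[keep],
                 dropped = onsets[!keep], fs_hz = fs, channel = channel,
                 window_s = window_s),
            class = "event_window_set")
}

#' Per-channel activation against the digit-task baseline
#'
#' Mean of all event-window samples (events pooled) minus the mean over
#' the two pooled digit-repetition segments, per channel.
#'
#' @param hemo A z-scored [hemo_series()] with `digits1` and `digits2`
#'   segments.
#' @param onsets Event onsets in recording time (seconds).
#' @param channels Channel indices (default all).
#' @param window_s Window length in seconds.
#' @return Named numeric vector of activation values (z-units); `NA` for
#'   channels flagged bad. Subjects with no usable onset yield an error
#'   attribute via zero rows upstream.
#' @export
subject_activation <- function(hemo, onsets, channels = NULL, window_s = 10) {
  stopifnot(inherits(hemo, "hemo_series"))
  if (is.null(hemo$segments$digits1) || is.null(hemo$segments$digits2))
    stop("both digit segments are required for baseline subtraction")
  if (is.null(channels)) channels <- seq_len(ncol(hemo$hbo))
  fs <- hemo$fs_hz
  n <- nrow(hemo$hbo)
  len <- round(window_s * fs)
  i0 <- floor(onsets * fs) + 1L
  i0 <- i0[i0 >= 1L & i0 + len - 1L <= n]
  if (length(i0) == 0) stop("no usable onsets for this subject")
  widx <- as.vector(outer(seq_len(len) - 1L, i0, "+"))
  didx <- c(.seg_idx(hemo$segments$digits1, fs, n),
            .seg_idx(hemo$segments$digits2, fs, n))
  act <- colMeans(hemo$hbo[widx, channels, drop = FALSE]) -
    colMeans(hemo$hbo[didx, channels, drop = FALSE])
  names(act) <- as.character(channels)
  act
}

#' Channelwise Mann-Whitney group comparison with BH-FDR
#'
#' Two-sided Mann-Whitney U per channel (exact when both groups have at
#' most 8 subjects and no ties; tie-corrected normal approximation with
#' continuity correction otherwise), Benjamini-Hochberg adjusted across
#' channels, with Cliff's delta and group medians.
#'
#' @param table data.frame with columns `subject`, `group` (values
#'   `"PTSD"`/`"TEC"`), `channel`, `activation`.
#' @return data.frame with one row per channel: U statistic, raw p,
#'   BH-FDR q, Cliff's delta, group medians.
#' @export
group_channel_test <- function(table) {
  stopifnot(all(c("group", "channel", "activation") %in% names(table)))
  chans <- sort(unique(table$channel))
  res <- lapply(chans, function(ch) {
    d <- table[table$channel == ch & is.finite(table$activation), ]
    x <- d$activation[d$group == "PTSD"]
    y <- d$activation[d$group == "TEC"]
    if (length(x) < 2 || length(y) < 2)
      stop("need >= 2 subjects per group per channel")
    exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
    ht <- suppressWarnings(
      wilcox.test(x, y, exact = exact, correct = TRUE))
    data.frame(channel = ch, U = unname(ht$statistic), p = ht$p.value,
               cliffs_delta = cliffs_delta(x, y),
               median_ptsd = median(x), median_tec = median(y))
  })
  res <- do.call(rbind, res)
  res$q <- p.adjust(res$p, method = "BH")
  res[, c("channel", "U", "p", "q", "cliffs_delta",
          "median_ptsd", "median_tec")]
}

#' Group grand-average event-locked time course
#'
#' Within-subject mean over events, then unweighted mean over subjects,
#' per time point.
#'
#' @param windowsets List of `event_window_set` objects (one per
#'   subject), all at the same channel and window length.
#' @return Numeric vector (one value per window sample).
#' @export
grand_average <- function(windowsets) {
  windowsets <- Filter(function(w) nrow(w$windows) > 0, windowsets)
  if (length(windowsets) == 0) stop("empty group")
  per_subj <- vapply(windowsets, function(w) colMeans(w$windows),
                     numeric(ncol(windowsets[[1]]$windows)))
  rowMeans(per_subj)
}

#' Characterize an event-locked group-average time course
#'
#' Baseline statistics come from the first `baseline_window_s` seconds of
#' the window. Latency is the first time the series stays above
#' `baseline mean + theta * baseline SD` for at least `m_s` continuous
#' seconds; if that criterion is met at t = 0 or never, the profile is
#' flagged "no latency". The slope is the least-squares slope of the
#' series between latency and peak (per sample, with a per-second
#' version scaled by `fs_hz`). The difference is the peak minus either
#' the window minimum (default) or the baseline mean. A Spearman rank
#' correlation of the series against time (midrank ties) summarizes the
#' overall trend.
#'
#' @param series Numeric vector (one event-locked window).
#' @param fs_hz Sampling rate.
#' @param baseline_window_s Baseline span in seconds (default 2).
#' @param theta Threshold in baseline SDs (default 2).
#' @param m_s Minimum suprathreshold run in seconds (default 1).
#' @param difference `"min"` (peak minus window minimum, default) or
#'   `"baseline"` (peak minus baseline mean).
#' @return List of class `timecourse_profile`: `latency_s`, `no_latency`,
#'   `slope_per_sample`, `slope_per_s`, `peak`, `peak_time_s`,
#'   `difference`, `spearman_r`, `spearman_p`.
#' @export
characterize_timecourse <- function(series, fs_hz, baseline_window_s = 2,
                                    theta = 2, m_s = 1,
                                    difference = c("min", "baseline")) {
  difference <- match.arg(difference)
  n <- length(series)
  nb <- max(2L, round(baseline_window_s * fs_hz))
  base <- series[seq_len(nb)]
  mu <- mean(base); s <- sd(base)
  if (s == 0) {
    message("zero baseline SD; threshold degenerates to the baseline mean")
  }
  thr <- mu + theta * s
  need <- max(1L, round(m_s * fs_hz))
  above <- series > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= need)
  latency_idx <- if (length(ok)) starts[ok[1]] else NA_integer_
  no_latency <- is.na(latency_idx) || latency_idx == 1L
  latency_s <- if (no_latency) NA_real_ else (latency_idx - 1L) / fs_hz
  peak_idx <- which.max(series)
  peak <- series[peak_idx]
  slope_ps <- NA_real_
  if (!no_latency && peak_idx > latency_idx) {
    seg <- seq.int(latency_idx, peak_idx)
    slope_ps <- unname(coef(lm(series[seg] ~ seg))[2])
  }
  diffv <- if (difference == "min") peak - min(series) else peak - mu
  ct <- suppressWarnings(
    cor.test(series, seq_len(n), method = "spearman", exact = FALSE))
  structure(list(latency_s = latency_s, no_latency = no_latency,
                 slope_per_sample = slope_ps,
                 slope_per_s = if (is.na(slope_ps)) NA_real_ else slope_ps * fs_hz,
                 peak = peak, peak_time_s = (peak_idx - 1L) / fs_hz,
                 difference = diffv,
                 spearman_r = unname(ct$estimate), spearman_p = ct$p.value),
            class = "timecourse_profile")
}
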