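# Optical-density simulation: event-locked hemodynamics at the target
# channel, physiological noise everywhere, forward modified
# Beer-Lambert mapping to two-wavelength OD.

# unit-peak piecewise-linear control response: flat until onset_s after
# the word, linear rise to 1 at peak_s, linear return to 0 at return_s
.tec_shape <- function(t, hrf) {
  y <- numeric(length(t))
  ris <- t >= hrf$onset_s & t < hrf$peak_s
  fal <- t >= hrf$peak_s & t < hrf$return_s
  y[ris] <- (t[ris] - hrf$onset_s) / (hrf$peak_s - hrf$onset_s)
  y[fal] <- 1 - (t[fal] - hrf$peak_s) / (hrf$return_s - hrf$peak_s)
  y
}

# unit-mean no-latency bump: ramp beginning lead_s before the word onset
# (t is measured from the ramp start), then a sustained level carrying a
# slow vasomotor-style fluctuation (relative depth ring_depth, period
# ring_period_s, crest ring_crest_s after the word onset) through
# sustain_s. The response is already elevated when the word is spoken.
.ptsd_bump <- function(t, hrf) {
  y <- numeric(length(t))
  ring <- function(v) {
    1 + hrf$ring_depth *
      cos(2 * pi * (v - (hrf$lead_s + hrf$ring_crest_s)) / hrf$ring_period_s)
  }
  ris <- t >= 0 & t < hrf$rise_s
  hold <- t >= hrf$rise_s & t < hrf$sustain_s
  y[ris] <- ring(hrf$rise_s) * t[ris] / hrf$rise_s
  y[hold] <- ring(t[hold])
  y
}

# superpose unit responses at `onsets` (absolute seconds) on an n-sample
# grid at fs
.superpose <- function(n, fs, onsets, shape_fun, hrf, span_s) {
  x <- numeric(n)
  m <- ceiling(span_s * fs) + 1L
  rel <- (seq_len(m) - 1) / fs
  for (t0 in onsets) {
    i0 <- floor(t0 * fs) + 1L
    idx <- seq.int(i0, min(n, i0 + m - 1L))
    x[idx] <- x[idx] + shape_fun(rel[seq_along(idx)] + (i0 - 1) / fs - t0,
                                 hrf)
  }
  x
}

# recording-time geometry: the device records edge_buffer_s before and
# after the session, so segment bounds shift by the buffer
.rec_geometry <- function(ses) {
  b <- ses$edge_buffer_s
  list(n = round((ses$total_s + 2 * b) * ses$fs_hz),
       offset_s = b,
       segments = lapply(ses$segments, function(s) s + b))
}

# clean unit-scale target-channel HbO on the recording time base
# (onsets_abs already in recording seconds)
.clean_hbo <- function(group, onsets_abs, spec) {
  ses <- spec$session
  eff <- spec$effect
  geo <- .rec_geometry(ses)
  n <- geo$n
  if (group == "TEC") {
    .superpose(n, ses$fs_hz, onsets_abs, .tec_shape, eff$hrf_tec,
               eff$hrf_tec$return_s)
  } else {
    nar <- geo$segments$narration
    t <- (seq_len(n) - 1) / ses$fs_hz
    plateau <- as.numeric(t >= nar[1] & t < nar[2])
    plateau + eff$hrf_ptsd$bump_rel *
      .superpose(n, ses$fs_hz, pmax(onsets_abs - eff$hrf_ptsd$lead_s, 0),
                 .ptsd_bump, eff$hrf_ptsd, eff$hrf_ptsd$sustain_s)
  }
}

# --- deterministic calibration -------------------------------------------

.calib_cache <- new.env(parent = emptyenv())

# expected rest SD (concentration units after the pipeline filter) of
# the generated noise, by analytic propagation of each component
.expected_rest_sd <- function(spec, constants = mbll_constants()) {
  ns <- spec$effect$noise
  ses <- spec$session
  fs <- ses$fs_hz
  n <- .rec_geometry(ses)$n
  minv <- constants$minv
  t <- (seq_len(n) - 1) / fs
  mid <- seq.int(round(n * 0.3), round(n * 0.7))
  # zero-phase |H(f)|^2 amplitude gain at a single frequency
  gain_f <- function(f) {
    y <- .pipeline_filter(sin(2 * pi * f * t), fs)
    sqrt(2) * sqrt(mean(y[mid]^2))
  }
  # white-noise SD multiplier: energy of the zero-phase impulse response
  imp <- numeric(n); imp[round(n / 2)] <- 1
  g_white <- sqrt(sum(.pipeline_filter(imp, fs)^2))
  # independent white OD noise at the two wavelengths
  v_white <- (ns$white_sd * g_white)^2 * (minv[1, 1]^2 + minv[1, 2]^2)
  # coherent sinusoids (same trace added at both wavelengths)
  csum <- abs(minv[1, 1] + minv[1, 2])
  v_sin <- 0
  for (comp in list(c(ns$cardiac_hz, ns$cardiac_amp),
                    c(ns$respiratory_hz, ns$respiratory_amp),
                    c(mean(ns$lfo_hz_range), ns$lfo_amp),
                    c(ns$drift_hz[1], ns$drift_amp),
                    c(ns$drift_hz[2], 0.6 * ns$drift_amp))) {
    if (comp[2] > 0)
      v_sin <- v_sin + (comp[2] * gain_f(comp[1]) * csum)^2 / 2
  }
  unname(sqrt(v_white + v_sin))
}

# windowed-mean-minus-digit-baseline functional of a filtered template:
# windows at `onsets` (absolute s), both digit blocks pooled
.wd_functional <- function(xf, onsets, spec) {
  ses <- spec$session
  segs <- .rec_geometry(ses)$segments
  fs <- ses$fs_hz
  n <- length(xf)
  len <- round(10 * fs)
  i0 <- floor(onsets * fs) + 1L
  i0 <- i0[i0 + len - 1L <= n]
  widx <- as.vector(outer(seq_len(len) - 1L, i0, "+"))
  didx <- c(.seg_idx(segs$digits1, fs, n),
            .seg_idx(segs$digits2, fs, n))
  mean(xf[widx]) - mean(xf[didx])
}

# pipeline gain of a unit-amplitude clean response: own-event window
# contribution of a single filtered response, plus the expected overlap
# field of the other events. Onset positions are uniform over the
# narration, so the expected superposition is the event rate times the
# narration boxcar convolved with the response shape -- a field that
# also leaks into the trailing digit block and is subtracted with it.
.template_gain <- function(group, spec) {
  ses <- spec$session
  eff <- spec$effect
  fs <- ses$fs_hz
  gk <- .group_key(group)
  rate <- eff$token_rate_hz * eff$neg_rate[[gk]][["mean"]] / 100
  geo <- .rec_geometry(ses)
  nar <- geo$segments$narration
  n <- geo$n
  mid_on <- nar[1] + ses$narration_s / 2
  # survey grid covering every possible onset position
  grid_on <- nar[1] + seq(0.25, ses$narration_s - 0.25, by = 0.5)
  t <- (seq_len(n) - 1) / fs
  box <- as.numeric(t >= nar[1] & t < nar[2])
  # expected per-unit-rate overlap field: boxcar (*) response shape
  conv_field <- function(shape_fun, hrf, span_s) {
    m <- ceiling(span_s * fs) + 1L
    k <- shape_fun((seq_len(m) - 1) / fs, hrf) / fs
    y <- stats::filter(box, k, method = "convolution", sides = 1)
    y[is.na(y)] <- 0
    as.numeric(y)
  }
  if (group == "TEC") {
    own <- .superpose(n, fs, mid_on, .tec_shape, eff$hrf_tec,
                      eff$hrf_tec$return_s)
    own_g <- .wd_functional(.pipeline_filter(own, fs), mid_on, spec)
    ped <- conv_field(.tec_shape, eff$hrf_tec, eff$hrf_tec$return_s)
    ped_g <- .wd_functional(.pipeline_filter(ped, fs), grid_on, spec)
    own_g + rate * ped_g
  } else {
    brel <- eff$hrf_ptsd$bump_rel
    own <- .superpose(n, fs, mid_on - eff$hrf_ptsd$lead_s, .ptsd_bump,
                      eff$hrf_ptsd, eff$hrf_ptsd$sustain_s)
    own_g <- .wd_functional(.pipeline_filter(own, fs), mid_on, spec)
    ped <- conv_field(.ptsd_bump, eff$hrf_ptsd, eff$hrf_ptsd$sustain_s)
    ped_g <- .wd_functional(.pipeline_filter(ped, fs), grid_on, spec)
    pl <- .wd_functional(.pipeline_filter(box, fs), grid_on, spec)
    pl + brel * (own_g + rate * ped_g)
  }
}

#' Calibrated target-channel amplitudes
#'
#' Concentration amplitudes for the two groups such that the full
#' pipeline's windowed, digit-baseline-subtracted group mean lands at
#' the configured z-unit targets. The calibration is closed-form given
#' the expected event rate: a deterministic response template at the
#' group-mean word rate is pushed through the analysis band-pass, and
#' the generated noise mix is propagated analytically to a rest SD.
#' Nothing is re-tuned per seed.
#'
#' @param spec A [cohort_spec()].
#' @return List with `amp` (named per group), `rest_sd`, `gain`.
#' @export
fnirs_calibration <- function(spec) {
  key <- paste(utils::capture.output(utils::str(
    list(spec$effect[c("neg_rate", "hrf_tec", "hrf_ptsd", "window_mean_z",
                       "token_rate_hz", "noise", "hbr_ratio")],
    spec$session))), collapse = "")
  key <- paste0("k", sum(utf8ToInt(key) * (seq_along(utf8ToInt(key)) %% 97)))
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  rest_sd <- .expected_rest_sd(spec)
  # in the noise-free limit the rest-referenced scale is taken as unity,
  # so calibrated amplitudes stay finite and nonzero
  if (rest_sd == 0) rest_sd <- 1
  gain <- c(PTSD = .template_gain("PTSD", spec),
            TEC = .template_gain("TEC", spec))
  amp <- c(PTSD = spec$effect$window_mean_z$ptsd * rest_sd / gain[["PTSD"]],
           TEC = spec$effect$window_mean_z$tec * rest_sd / gain[["TEC"]])
  out <- list(amp = amp, rest_sd = rest_sd, gain = gain)
  .calib_cache[[key]] <- out
  out
}

#' Generate a two-wavelength optical recording for one subject
#'
#' The target channel carries the group's event-locked Oxy-Hb response
#' (controls: delayed piecewise-linear rise-fall per negative word;
#' PTSD-like: narration-long plateau plus small no-latency bumps) with
#' Deoxy-Hb tied at a fixed negative ratio; concentrations are mapped to
#' 730/850 nm optical densities by the forward modified Beer-Lambert
#' model. Every channel receives slow drift, cardiac and respiratory
#' oscillations, white noise and (optionally) motion spikes in OD space.
#'
#' @param subject One row of [generate_cohort()] output.
#' @param transcript The subject's [generate_transcript()] output.
#' @param spec The [cohort_spec()].
#' @param constants [mbll_constants()] used for the forward model.
#' @param return_truth Attach the clean target-channel HbO as attribute
#'   `truth` (for round-trip checks).
#' @return An `optical_recording`: list with `od` array (time x channel
#'   x wavelength), `fs_hz`, `segments`, `wavelengths_nm`,
#'   `neg_onsets_abs` (absolute seconds), `sd_separation_cm`.
#' @export
generate_fnirs <- function(subject, transcript, spec,
                           constants = mbll_constants(),
                           return_truth = FALSE) {
  ses <- spec$session
  eff <- spec$effect
  fs <- ses$fs_hz
  geo <- .rec_geometry(ses)
  n <- geo$n
  nar <- geo$segments$narration
  if (any(transcript$onset_s < 0 | transcript$onset_s > ses$narration_s))
    stop("transcript onsets must lie inside the narration segment")
  onsets_abs <- nar[1] + transcript$onset_s[transcript$category == "negative"]
  calib <- fnirs_calibration(spec)
  sseed <- derive_seed(spec$seed, subject$id, "fnirs")
  with_local_seed(sseed, {
    cv <- eff$subject_amp_cv
    amp_mult <- if (cv > 0) exp(rnorm(1, -cv^2 / 2, cv)) else 1
    amp <- calib$amp[[subject$group]] * amp_mult
    hbo <- amp * .clean_hbo(subject$group, onsets_abs, spec)
    hbr <- -eff$hbr_ratio * hbo
    od_sig <- mbll_forward(hbo, hbr, constants)
    ns <- eff$noise
    t <- (seq_len(n) - 1) / fs
    nch <- ses$n_channels
    # task-engagement envelope for the spontaneous LFO: full amplitude
    # through rest, suppressed from the first digit task onward
    rest_end <- geo$segments$rest[2]
    supp <- ns$lfo_task_suppression
    lfo_env <- supp + (1 - supp) /
      (1 + exp((t - rest_end) / (ns$lfo_ramp_s / 4)))
    od <- array(0, dim = c(n, nch, 2),
                dimnames = list(NULL, NULL, as.character(ses$wavelengths_nm)))
    for (ch in seq_len(nch)) {
      drift <- ns$drift_amp *
        (sin(2 * pi * ns$drift_hz[1] * t + runif(1, 0, 2 * pi)) +
           0.6 * sin(2 * pi * ns$drift_hz[2] * t + runif(1, 0, 2 * pi)))
      cardiac <- ns$cardiac_amp * sin(2 * pi * ns$cardiac_hz * t +
                                        runif(1, 0, 2 * pi))
      resp <- ns$respiratory_amp * sin(2 * pi * ns$respiratory_hz * t +
                                         runif(1, 0, 2 * pi))
      lfo <- ns$lfo_amp * lfo_env *
        sin(2 * pi * runif(1, ns$lfo_hz_range[1], ns$lfo_hz_range[2]) * t +
              runif(1, 0, 2 * pi))
      phys <- drift + cardiac + resp + lfo
      for (w in 1:2) {
        x <- phys + rnorm(n, 0, ns$white_sd)
        if (ns$motion_spike_rate > 0) {
          k <- rpois(1, ns$motion_spike_rate * ses$total_s)
          if (k > 0) {
            pos <- sample.int(n - 4L, k)
            for (p in pos) {
              len <- sample(2:4, 1)
              x[seq.int(p, p + len - 1L)] <-
                x[seq.int(p, p + len - 1L)] +
                sample(c(-1, 1), 1) * ns$motion_spike_amp
            }
          }
        }
        od[, ch, w] <- x
      }
    }
    od[, ses$target_channel, 1] <- od[, ses$target_channel, 1] + od_sig[, 1]
    od[, ses$target_channel, 2] <- od[, ses$target_channel, 2] + od_sig[, 2]
    rec <- structure(list(od = od, fs_hz = fs, segments = geo$segments,
                          wavelengths_nm = ses$wavelengths_nm,
                          sd_separation_cm = ses$sd_separation_cm,
                          neg_onsets_abs = onsets_abs,
                          target_channel = ses$target_channel),
                     class = "optical_recording")
    if (return_truth) attr(rec, "truth") <- hbo
    rec
  })
}
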