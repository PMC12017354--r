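# Seeded synthetic cohort generator: subjects, timed transcripts,
# prosody tracks and two-wavelength optical-density recordings whose
# statistical structure mirrors the reported group effects, so the whole
# downstream pipeline is testable without any recorded data.
#
# All draws come from per-subject, per-purpose seed streams derived from
# the cohort seed, so each modality can be regenerated independently and
# identical (spec, seed) pairs give identical datasets.

#' Session layout of the narration protocol
#'
#' 540 s session: 300 s rest, 30 s digit recitation, 180 s impromptu
#' trauma narration, 30 s digit recitation; 48 optical channels sampled
#' at 11 Hz at 730/850 nm.
#'
#' @param rest_s,digits1_s,narration_s,digits2_s Segment durations (s).
#' @param fs_hz Optical sampling rate.
#' @param n_channels Number of channels.
#' @param target_channel Channel carrying the event-locked response
#'   (montage position over the left anterior medial prefrontal cortex).
#' @param wavelengths_nm Measurement wavelengths.
#' @param sd_separation_cm Source-detector separation.
#' @param edge_buffer_s Device run-in/run-out recorded before and after
#'   the session (default 20 s). Keeps filter edge effects outside the
#'   labelled segments, as continuous acquisition does in practice.
#' @return List of class `session_layout`; `segments` holds the labelled
#'   intervals in session seconds.
#' @export
session_layout <- function(rest_s = 300, digits1_s = 30, narration_s = 180,
                           digits2_s = 30, fs_hz = 11, n_channels = 48,
                           target_channel = 27,
                           wavelengths_nm = c(730, 850),
                           sd_separation_cm = 3.0,
                           edge_buffer_s = 20) {
  stopifnot(fs_hz > 0, narration_s > 0, target_channel >= 1,
            target_channel <= n_channels)
  t0 <- c(0, rest_s, rest_s + digits1_s, rest_s + digits1_s + narration_s)
  t1 <- c(t0[-1], t0[4] + digits2_s)
  segments <- list(rest = c(t0[1], t1[1]), digits1 = c(t0[2], t1[2]),
                   narration = c(t0[3], t1[3]), digits2 = c(t0[4], t1[4]))
  structure(list(rest_s = rest_s, digits1_s = digits1_s,
                 narration_s = narration_s, digits2_s = digits2_s,
                 total_s = t1[4], edge_buffer_s = edge_buffer_s,
                 fs_hz = fs_hz, n_channels = n_channels,
                 target_channel = target_channel,
                 wavelengths_nm = wavelengths_nm,
                 sd_separation_cm = sd_separation_cm, segments = segments),
            class = "session_layout")
}

#' Physiological and instrumental noise parameters (OD units)
#'
#' @param drift_amp Slow (thermal-scale) drift amplitude.
#' @param drift_hz Two drift component frequencies (Hz); the second is
#'   added at 60% amplitude.
#' @param cardiac_hz,cardiac_amp Cardiac oscillation (out of analysis band).
#' @param respiratory_hz,respiratory_amp Respiratory oscillation; its
#'   filter leakage is the dominant in-band noise, as physiological
#'   oscillations dominate real optical recordings.
#' @param white_sd White (instrument) noise SD.
#' @param lfo_amp Resting amplitude of the spontaneous low-frequency
#'   (Mayer-wave band) oscillation; per-channel random frequency in
#'   `lfo_hz_range` and random phase. Task engagement suppresses
#'   spontaneous oscillations, so during the digit and narration
#'   segments the amplitude is scaled by `lfo_task_suppression` (smooth
#'   `lfo_ramp_s` transition). This makes the rest SD used for
#'   z-scoring substantially larger than task-epoch noise, as the
#'   reported between-subject activation SDs imply.
#' @param lfo_hz_range,lfo_task_suppression,lfo_ramp_s See `lfo_amp`.
#' @param motion_spike_rate Expected motion spikes per second (default 0;
#'   enable to exercise motion correction).
#' @param motion_spike_amp Spike amplitude.
#' @return List of class `noise_params`.
#' @export
noise_params <- function(drift_amp = 1e-3, drift_hz = c(0.0012, 0.0028),
                         cardiac_hz = 1.1,
                         cardiac_amp = 8e-4, respiratory_hz = 0.25,
                         respiratory_amp = 4e-4, white_sd = 8e-5,
                         lfo_amp = 5e-3, lfo_hz_range = c(0.085, 0.115),
                         lfo_task_suppression = 0.05, lfo_ramp_s = 6,
                         motion_spike_rate = 0, motion_spike_amp = 5e-3) {
  stopifnot(drift_amp >= 0, cardiac_amp >= 0, respiratory_amp >= 0,
            white_sd >= 0, lfo_amp >= 0, motion_spike_rate >= 0,
            motion_spike_amp >= 0,
            lfo_task_suppression >= 0, lfo_task_suppression <= 1)
  structure(as.list(environment()), class = "noise_params")
}

#' Group-effect parameters of the synthetic cohort
#'
#' Defaults encode the reported group contrasts: negative-word rates
#' (percent of tokens), positive/factual rates, lexical-richness
#' targets, prosody (pitch, semitone declination, pauses), the
#' event-locked hemodynamic landmarks (delayed rise-fall for controls, a
#' tonic no-latency plateau for the PTSD-like group), windowed
#' activation targets in rest-referenced z-units, and the criterion-D
#' correlation target.
#'
#' @param neg_rate,pos_rate,factual_rate,honore_target,pitch,semitone,
#'   pause_count Per-group parameter lists (`ptsd`, `tec`).
#' @param caps5 CAPS-5 total distribution for the PTSD-like group
#'   (mean, sd, floor) and TEC mean/sd.
#' @param capsD_correlation_target Target correlation between the
#'   negative-word rate and the criterion-D subscore.
#' @param hrf_tec Piecewise-linear response landmarks (s after word
#'   onset): flat until `onset_s`, linear rise to the peak at `peak_s`,
#'   linear return to zero at `return_s`.
#' @param hrf_ptsd No-latency realization: tonic narration-long plateau
#'   plus sustained event bumps. Each bump begins `lead_s` seconds
#'   before the word onset (pre-articulatory arousal during speech
#'   planning), ramps over `rise_s`, and is held through `sustain_s`
#'   (measured from the ramp start) with amplitude `bump_rel` relative
#'   to the plateau -- so the response is already elevated when the word
#'   is spoken, i.e. genuinely latency-free. The sustained level carries
#'   a slow vasomotor-style fluctuation (`ring_depth`, `ring_period_s`,
#'   crest `ring_crest_s` after the onset), giving the slight
#'   non-monotone wobble of the sustained state.
#' @param window_mean_z Windowed, digit-baseline-subtracted activation
#'   targets in z-units per group.
#' @param token_rate_hz Narration speech rate (tokens per second).
#' @param subject_amp_cv Between-subject lognormal CV of response
#'   amplitude.
#' @param hbr_ratio Deoxy-Hb change as a negative fraction of Oxy-Hb.
#' @param noise A [noise_params()] object.
#' @return List of class `effect_params`.
#' @export
effect_params <- function(
    neg_rate = list(ptsd = c(mean = 5.89, sd = 3.00),
                    tec = c(mean = 4.21, sd = 2.83)),
    pos_rate = list(ptsd = 2.60, tec = 2.90),
    factual_rate = list(ptsd = 20, tec = 20),
    honore_target = list(ptsd = 30.23, tec = 34.59),
    pitch = list(ptsd = c(mean = 201.21, sd = 32.84),
                 tec = c(mean = 180.47, sd = 43.91)),
    semitone = list(ptsd = c(mean = -15.11, sd = 6.53),
                    tec = c(mean = -17.10, sd = 6.59)),
    pause_count = list(ptsd = c(mean = 385.09, sd = 118.34),
                       tec = c(mean = 362.60, sd = 316.22)),
    caps5 = list(ptsd = c(mean = 50.89, sd = 7.57, floor = 45),
                 tec = c(mean = 18, sd = 7)),
    capsD_correlation_target = 0.349,
    hrf_tec = list(onset_s = 3.82, peak_s = 7.55, return_s = 12.0),
    hrf_ptsd = list(lead_s = 2.0, rise_s = 1.5, sustain_s = 18.0,
                    bump_rel = 0.35, ring_depth = 0.6,
                    ring_period_s = 7.0, ring_crest_s = 1.8),
    window_mean_z = list(ptsd = 0.153, tec = 0.047),
    token_rate_hz = 2.5,
    subject_amp_cv = 0.4,
    hbr_ratio = 0.3,
    noise = noise_params()) {
  stopifnot(hrf_tec$onset_s < hrf_tec$peak_s,
            hrf_tec$peak_s < hrf_tec$return_s,
            all(unlist(neg_rate) >= 0), token_rate_hz > 0)
  structure(as.list(environment()), class = "effect_params")
}

#' Cohort specification
#'
#' @param n_ptsd,n_tec Group sizes (>= 2 each; defaults 35 and 37).
#' @param seed Master seed; identical spec + seed reproduces the cohort
#'   exactly.
#' @param effect An [effect_params()] object.
#' @param session A [session_layout()] object.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_ptsd = 35, n_tec = 37, seed = 1,
                        effect = effect_params(),
                        session = session_layout()) {
  if (n_ptsd < 2 || n_tec < 2) stop("need at least 2 subjects per group")
  structure(list(n_ptsd = n_ptsd, n_tec = n_tec, seed = as.integer(seed),
                 effect = effect, session = session),
            class = "cohort_spec")
}

.group_key <- function(group) c(PTSD = "ptsd", TEC = "tec")[[group]]

#' Generate subject records
#'
#' Demographics are drawn from group-identical distributions. CAPS-5
#' totals for the PTSD-like group come from a mean-calibrated truncated
#' normal with a hard floor at the inclusion threshold. The criterion-D
#' subscore is a linear function of the subject's true negative-word
#' rate plus noise, scaled so the expected within-group correlation
#' equals the configured target.
#'
#' @param spec A [cohort_spec()].
#' @return data.frame with one row per subject: id, group, age, sex,
#'   education, caps5_total, capsD, neg_rate_true.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  eff <- spec$effect
  rows <- list()
  for (group in c("PTSD", "TEC")) {
    gk <- .group_key(group)
    n <- if (group == "PTSD") spec$n_ptsd else spec$n_tec
    nr <- eff$neg_rate[[gk]]
    # linear capsD model: capsD = base + b * (rate - mean) + noise, with
    # noise SD chosen from the realized (truncated) rate SD so that
    # cor(rate, capsD) = target in expectation
    mu_star <- truncnorm_calibrate(nr[["mean"]], nr[["sd"]], 0)
    sd_x <- truncnorm_moments(mu_star, nr[["sd"]], 0)$sd
    r <- eff$capsD_correlation_target
    b <- 0.5
    sd_eps <- b * sd_x * sqrt(1 / r^2 - 1)
    for (i in seq_len(n)) {
      sseed <- derive_seed(spec$seed, group, i, "subject")
      rows[[length(rows) + 1L]] <- with_local_seed(sseed, {
        age <- round(min(60, max(18, rnorm(1, 35, 10))))
        sex <- if (runif(1) < 0.5) "F" else "M"
        edu <- round(min(20, max(6, rnorm(1, 12, 3))))
        caps <- if (group == "PTSD") {
          cp <- eff$caps5$ptsd
          rtrunc_meancal(1, cp[["mean"]], cp[["sd"]], cp[["floor"]])
        } else {
          ct <- eff$caps5$tec
          min(44, max(0, rnorm(1, ct[["mean"]], ct[["sd"]])))
        }
        rate <- rtrunc_meancal(1, nr[["mean"]], nr[["sd"]], 0)
        base <- if (group == "PTSD") 14 else 6
        capsD <- base + b * (rate - nr[["mean"]]) + rnorm(1, 0, sd_eps)
        capsD <- min(28, max(0, capsD))
        data.frame(id = sprintf("%s%02d", substr(group, 1, 1), i),
                   group = group, age = age, sex = sex, education = edu,
                   caps5_total = caps, capsD = capsD, neg_rate_true = rate,
                   stringsAsFactors = FALSE)
      })
    }
  }
  do.call(rbind, rows)
}

# ---- lexicon -------------------------------------------------------------

.lexicon_design <- list(
  negative = list(core = 30, rare = 150),
  positive = list(core = 30, rare = 120),
  factual = list(core = 30, rare = 400),
  neutral = list(core = 30, rare = 1400))

#' The packaged synthetic lexicon
#'
#' Deterministic word -> category map covering the generator's whole
#' vocabulary, so lexicon tagging is exact on synthetic transcripts.
#' Words are synthetic surface forms (`neg_c01`, `neu_r0042`, ...); each
#' category has a small "core" of repeatable words and a large "rare"
#' pool used for hapax legomena. The same table ships as
#' `inst/extdata/lexicon.tsv`.
#'
#' @return Named character vector (word -> category).
#' @export
default_lexicon <- function() {
  out <- character(0)
  for (cat in names(.lexicon_design)) {
    d <- .lexicon_design[[cat]]
    pre <- substr(cat, 1, 3)
    core <- sprintf("%s_c%02d", pre, seq_len(d$core))
    rare <- sprintf("%s_r%04d", pre, seq_len(d$rare))
    w <- structure(rep(cat, d$core + d$rare), names = c(core, rare))
    out <- c(out, w)
  }
  out
}

# Zipf probabilities over the category cores
.core_probs <- function(n_core) {
  p <- 1 / seq_len(n_core)
  p / sum(p)
}

# Fraction of tokens drawn as fresh rare (hapax) words, solved so the
# expected hapax ratio V1/V matches the lexical-richness target
# (printed Honore values interpreted on an ln-scale, see vignette).
.solve_unique_frac <- function(n_tokens, honore_target, cat_probs) {
  rho_target <- 1 - log(n_tokens) / honore_target
  rho_target <- min(0.95, max(0.05, rho_target))
  zipf <- .core_probs(30)
  q <- as.vector(outer(zipf, cat_probs))   # core-type probs, sum 1
  rho <- function(f) {
    m <- (1 - f) * n_tokens
    v1c <- sum(m * q * (1 - q)^(m - 1))
    vc <- sum(1 - (1 - q)^m)
    (f * n_tokens + v1c) / (f * n_tokens + vc)
  }
  uniroot(function(f) rho(f) - rho_target, c(0.01, 0.98), tol = 1e-8)$root
}

#' Generate a timed transcript for one subject
#'
#' Tokens arrive at the configured speech rate with jittered, strictly
#' increasing onsets inside the narration segment. Each token's category
#' is drawn with the subject's true negative rate; surface forms come
#' from the packaged lexicon, mixing a Zipf-weighted category core with
#' fresh rare words at a per-group fraction tuned to the
#' lexical-richness target.
#'
#' @param subject One row of [generate_cohort()] output.
#' @param spec The [cohort_spec()].
#' @return data.frame with columns token, onset_s, offset_s, category
#'   (onsets in narration-relative seconds).
#' @export
generate_transcript <- function(subject, spec) {
  eff <- spec$effect
  ses <- spec$session
  if (ses$narration_s <= 0) stop("narration duration must be positive")
  gk <- .group_key(subject$group)
  n <- round(eff$token_rate_hz * ses$narration_s)
  p_neg <- subject$neg_rate_true / 100
  p_pos <- eff$pos_rate[[gk]] / 100
  p_fact <- eff$factual_rate[[gk]] / 100
  p_neu <- max(0, 1 - p_neg - p_pos - p_fact)
  cat_probs <- c(negative = p_neg, positive = p_pos, factual = p_fact,
                 neutral = p_neu)
  f <- .solve_unique_frac(n, eff$honore_target[[gk]], cat_probs)
  sseed <- derive_seed(spec$seed, subject$id, "transcript")
  with_local_seed(sseed, {
    dt <- 1 / eff$token_rate_hz
    onset <- (seq_len(n) - 1) * dt + runif(n, 0, 0.6 * dt)
    # jitter < spacing keeps onsets strictly increasing
    offset <- onset + pmin(0.75 * dt, c(diff(onset) - 0.02, 0.75 * dt))
    category <- sample(names(cat_probs), n, replace = TRUE, prob = cat_probs)
    # per-transcript shuffled rare pools give within-transcript hapaxes
    pools <- lapply(names(.lexicon_design), function(cat) {
      d <- .lexicon_design[[cat]]
      sample(sprintf("%s_r%04d", substr(cat, 1, 3), seq_len(d$rare)))
    })
    names(pools) <- names(.lexicon_design)
    used <- sapply(pools, function(x) 0L)
    zipf <- .core_probs(30)
    fresh <- runif(n) < f
    token <- character(n)
    for (i in seq_len(n)) {
      cat <- category[i]
      if (fresh[i] && used[[cat]] < length(pools[[cat]])) {
        used[[cat]] <- used[[cat]] + 1L
        token[i] <- pools[[cat]][used[[cat]]]
      } else {
        token[i] <- sprintf("%s_c%02d", substr(cat, 1, 3),
                            sample.int(30, 1, prob = zipf))
      }
    }
    data.frame(token = token, onset_s = onset, offset_s = offset,
               category = category, stringsAsFactors = FALSE)
  })
}

#' Generate a frame-level prosody track for one subject
#'
#' f0 declines exponentially (linearly in semitones) across voiced
#' frames so that the decile-median semitone estimator recovers the
#' subject's drawn semitone change; the voiced-frame mean equals the
#' drawn mean pitch. Unvoiced runs realize the drawn pause count.
#'
#' @param subject One row of [generate_cohort()] output.
#' @param spec The [cohort_spec()].
#' @param frame_hz Frame rate (default 100 frames/s).
#' @return data.frame `t_s`, `f0_hz`, `voiced` covering the narration;
#'   the drawn subject values are attached as attribute `draws`.
#' @export
generate_prosody <- function(subject, spec, frame_hz = 100) {
  stopifnot(frame_hz > 0)
  eff <- spec$effect
  gk <- .group_key(subject$group)
  n <- round(spec$session$narration_s * frame_hz)
  sseed <- derive_seed(spec$seed, subject$id, "prosody")
  with_local_seed(sseed, {
    pt <- eff$pitch[[gk]]
    st <- eff$semitone[[gk]]
    pc <- eff$pause_count[[gk]]
    pitch_true <- rtrunc_meancal(1, pt[["mean"]], pt[["sd"]], 80)
    semitone_true <- rnorm(1, st[["mean"]], st[["sd"]])
    k <- round(rtrunc_meancal(1, pc[["mean"]], pc[["sd"]], 0))
    k <- min(k, floor(n / 30))
    voiced <- rep(TRUE, n)
    if (k > 0) {
      slot <- n / k
      gmin <- ceiling(0.06 * frame_hz)
      for (j in seq_len(k)) {
        g <- sample(seq.int(gmin, min(3 * gmin + 2, floor(slot) - 2)), 1)
        lo <- floor((j - 1) * slot) + 2L
        hi <- floor(j * slot) - g
        if (hi < lo) next
        s0 <- sample(seq.int(lo, hi), 1)
        voiced[seq.int(s0, s0 + g - 1L)] <- FALSE
      }
    }
    v <- sum(voiced)
    # decile medians sit ~5% from each end, so they span 90% of the
    # full exponential; widen the span to compensate
    span <- semitone_true / 0.9
    i <- seq_len(v) - 1
    f0v <- 2^((span * i / max(1, v - 1)) / 12)
    f0v <- f0v * exp(rnorm(v, 0, 0.01))
    f0v <- f0v * pitch_true / mean(f0v)
    f0 <- rep(NA_real_, n)
    f0[voiced] <- f0v
    out <- data.frame(t_s = (seq_len(n) - 1) / frame_hz, f0_hz = f0,
                      voiced = voiced)
    attr(out, "draws") <- list(pitch = pitch_true,
                               semitone = semitone_true, pauses = k)
    out
  })
}
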