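# Prosodic features from frame-level f0 tracks.
# A track is a data.frame with uniform frame times t_s, f0_hz (NA when
# unvoiced) and a logical voiced flag.

#' Mean pitch over voiced frames
#'
#' @param track Prosody track data.frame (`t_s`, `f0_hz`, `voiced`).
#' @return Mean f0 in Hz; `NA` with a warning when no frame is voiced.
#' @export
mean_pitch <- function(track) {
  f0 <- track$f0_hz[track$voiced]
  if (length(f0) < 1) {
    warning("no voiced frames; mean pitch undefined")
    return(NA_real_)
  }
  mean(f0)
}

#' Semitone change across the narration
#'
#' `12 * log2(median f0 of the final voiced decile / median f0 of the
#' first voiced decile)`. Negative values indicate pitch declination.
#'
#' @param track Prosody track data.frame.
#' @return Semitone change; `NA` with a warning when fewer than two voiced
#'   frames exist.
#' @export
semitone_change <- function(track) {
  f0 <- track$f0_hz[track$voiced]
  v <- length(f0)
  if (v < 2) {
    warning("fewer than 2 voiced frames; semitone change undefined")
    return(NA_real_)
  }
  k <- max(1L, floor(v / 10))
  first <- median(f0[seq_len(k)])
  last <- median(f0[seq.int(v - k + 1L, v)])
  12 * log2(last / first)
}

#' Count pauses (long unvoiced runs)
#'
#' Number of maximal unvoiced runs lasting at least `min_pause_s`
#' (closed threshold: a run of exactly `min_pause_s` counts).
#'
#' @param track Prosody track data.frame.
#' @param min_pause_s Minimum pause duration in seconds (default 0.06,
#'   i.e. 60 ms; must exceed the frame spacing).
#' @return Integer pause count.
#' @export
count_pauses <- function(track, min_pause_s = 0.06) {
  dt <- median(diff(track$t_s))
  if (min_pause_s <= dt) stop("min_pause_s must exceed the frame spacing")
  r <- rle(!track$voiced)
  runs <- r$lengths[r$values]
  sum(runs * dt >= min_pause_s - 1e-9)
}

#' Per-subject prosody feature row
#'
#' @param track Prosody track data.frame.
#' @param min_pause_s Pause threshold passed to [count_pauses()].
#' @return One-row data.frame with mean pitch, semitone change and pause
#'   count.
#' @export
prosody_features <- function(track, min_pause_s = 0.06) {
  data.frame(mean_pitch_hz = mean_pitch(track),
             semitone_change = semitone_change(track),
             n_pauses = count_pauses(track, min_pause_s))
}
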