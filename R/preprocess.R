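# Optical-density -> hemoglobin preprocessing chain.
#
# Stage order: motion correction in OD space -> MBLL inversion ->
# zero-phase band-pass -> rest-referenced z-scoring. Inverting before
# filtering keeps the filter linear in concentration.

#' Modified Beer-Lambert constants
#'
#' Extinction coefficients (cm^-1 mM^-1) at the two measurement
#' wavelengths, differential pathlength factors, and source-detector
#' separation. Defaults use a standard compiled extinction table at
#' 730/850 nm and an adult-forehead DPF of 6.0.
#'
#' @param wavelengths_nm Two wavelengths, default `c(730, 850)`.
#' @param ext_hbo,ext_hbr Extinction coefficients per wavelength.
#' @param dpf Differential pathlength factor per wavelength.
#' @param path_cm Source-detector separation in cm.
#' @return An object of class `mbll_constants`.
#' @export
mbll_constants <- function(wavelengths_nm = c(730, 850),
                           ext_hbo = c(0.390, 1.058),
                           ext_hbr = c(1.102, 0.691),
                           dpf = c(6.0, 6.0),
                           path_cm = 3.0) {
  stopifnot(length(wavelengths_nm) == 2, length(ext_hbo) == 2,
            length(ext_hbr) == 2, length(dpf) == 2, path_cm > 0)
  ext <- cbind(hbo = ext_hbo, hbr = ext_hbr)
  rownames(ext) <- as.character(wavelengths_nm)
  m <- diag(dpf * path_cm) %*% ext
  if (kappa(m) >= 1e3) stop("extinction system is ill-conditioned")
  structure(list(wavelengths_nm = wavelengths_nm, ext = ext, dpf = dpf,
                 path_cm = path_cm, m = m, minv = solve(m)),
            class = "mbll_constants")
}

#' Forward modified Beer-Lambert model
#'
#' Maps concentration changes to optical-density changes:
#' `dOD(lambda) = (eHbO(lambda) dHbO + eHbR(lambda) dHbR) * L * DPF(lambda)`.
#'
#' @param hbo,hbr Numeric vectors of concentration changes.
#' @param constants An [mbll_constants()] object.
#' @return Matrix with one column per wavelength.
#' @export
mbll_forward <- function(hbo, hbr, constants = mbll_constants()) {
  stopifnot(length(hbo) == length(hbr))
  od <- cbind(hbo, hbr) %*% t(constants$m)
  colnames(od) <- as.character(constants$wavelengths_nm)
  od
}

#' Invert the modified Beer-Lambert model
#'
#' Per-sample solution of the 2x2 linear system for (dHbO, dHbR).
#'
#' @param od Matrix with one column per wavelength (same order as
#'   `constants$wavelengths_nm`).
#' @param constants An [mbll_constants()] object.
#' @return Matrix with columns `hbo`, `hbr`.
#' @export
mbll_invert <- function(od, constants = mbll_constants()) {
  od <- as.matrix(od)
  stopifnot(ncol(od) == 2)
  conc <- od %*% t(constants$minv)
  colnames(conc) <- c("hbo", "hbr")
  conc
}

#' Motion-artifact correction by robust spike interpolation
#'
#' Samples whose deviation from a running median exceeds `z_thresh`
#' robust SDs (or the absolute `spike_amp`) are flagged and replaced by
#' cubic-spline interpolation across the flagged runs. If more than half
#' the samples are flagged the series is passed through unchanged with a
#' warning.
#'
#' @param x Numeric series.
#' @param fs_hz Sampling rate.
#' @param window_s Running-median window in seconds (default 1).
#' @param z_thresh Robust z threshold (default 5).
#' @param spike_amp Optional absolute amplitude threshold.
#' @return List with `series` and logical `mask` of corrected samples.
#' @export
motion_correct <- function(x, fs_hz, window_s = 1, z_thresh = 5,
                           spike_amp = Inf) {
  n <- length(x)
  k <- round(window_s * fs_hz)
  if (k %% 2 == 0) k <- k + 1
  k <- max(3L, min(k, if (n %% 2 == 0) n - 1 else n))
  if (n <= k) stop("series shorter than the detection window")
  med <- stats::runmed(x, k, endrule = "median")
  r <- x - med
  sigma <- stats::mad(r)
  mask <- abs(r) > spike_amp
  if (sigma > 0) mask <- mask | (abs(r) > z_thresh * sigma)
  if (!any(mask)) return(list(series = x, mask = mask))
  if (mean(mask) > 0.5) {
    warning("more than 50% of samples flagged; series passed through")
    return(list(series = x, mask = mask))
  }
  idx <- seq_len(n)
  fit <- stats::spline(idx[!mask], x[!mask], xout = idx[mask], method = "fmm")
  x[mask] <- fit$y
  list(series = x, mask = mask)
}

# Zero-phase IIR over matrix columns with reflection padding;
# compiled kernel in src/filtfilt.cpp.
.filtfilt_mat <- function(b, a, x, pad, odd_pad = TRUE) {
  iir_filtfilt_cpp(b, a, x, as.integer(pad), isTRUE(odd_pad))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Cascade of an order-3 Butterworth low-pass and an order-3 high-pass,
#' each applied forward and backward (zero phase). The low-pass runs
#' first with even-reflection padding, so strong out-of-band
#' oscillations (e.g. cardiac) are removed before the high-pass's long
#' odd-reflection padding, keeping edge transients out of the rest and
#' digit segments. Accepts a vector or a matrix (filtered column-wise).
#'
#' @param x Numeric vector or matrix (time in rows).
#' @param fs_hz Sampling rate.
#' @param low,high Band edges in Hz (default 0.01-0.20).
#' @param order Order of each stage (default 3).
#' @return Filtered data of the same shape.
#' @export
bandpass <- function(x, fs_hz, low = 0.01, high = 0.20, order = 3) {
  if (!(low > 0 && low < high && high < fs_hz / 2))
    stop("band must satisfy 0 < low < high < fs/2")
  lp <- signal::butter(order, high / (fs_hz / 2), type = "low")
  hp <- signal::butter(order, low / (fs_hz / 2), type = "high")
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1)
  y <- .filtfilt_mat(lp$b, lp$a, x, ceiling(5 * fs_hz / high),
                     odd_pad = FALSE)
  y <- .filtfilt_mat(hp$b, hp$a, y, ceiling(1.5 * fs_hz / low),
                     odd_pad = TRUE)
  if (vec) drop(y) else y
}

#' Polynomial detrending
#'
#' Removes a least-squares polynomial (default cubic) from each column.
#' Used before band-pass filtering so that very slow drifts, whose
#' periods rival the recording length, do not leak filter edge
#' transients into the rest and digit segments.
#'
#' @param x Numeric vector or matrix (time in rows).
#' @param order Polynomial order (default 3); 0 removes the mean only.
#' @return Detrended data of the same shape.
#' @export
detrend_poly <- function(x, order = 3) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  B <- cbind(1, if (order >= 1) stats::poly(seq_len(n), order))
  out <- x - B %*% qr.solve(B, x)
  if (vec) drop(out) else out
}

# drift-removal + band-pass operator shared by the preprocessing chain
# and the generator's calibration probes
.pipeline_filter <- function(x, fs_hz, low = 0.01, high = 0.20,
                             detrend_order = 3) {
  bandpass(detrend_poly(x, detrend_order), fs_hz, low, high)
}

# sample index range of a labelled segment
.seg_idx <- function(seg, fs_hz, n) {
  i0 <- floor(seg[1] * fs_hz) + 1L
  i1 <- min(floor(seg[2] * fs_hz), n)
  seq.int(i0, i1)
}

#' Construct a hemoglobin concentration series container
#'
#' @param hbo,hbr Matrices (time x channel).
#' @param fs_hz Sampling rate.
#' @param segments Named list of `c(start_s, end_s)` session segments
#'   (`rest`, `digits1`, `narration`, `digits2`).
#' @param zscored Whether the series is already rest-referenced.
#' @param bad_channels Integer indices of channels excluded downstream.
#' @return Object of class `hemo_series`.
#' @export
hemo_series <- function(hbo, hbr, fs_hz, segments, zscored = FALSE,
                        bad_channels = integer(0)) {
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  stopifnot(all(dim(hbo) == dim(hbr)), fs_hz > 0)
  structure(list(hbo = hbo, hbr = hbr, fs_hz = fs_hz, segments = segments,
                 zscored = zscored, bad_channels = bad_channels),
            class = "hemo_series")
}

#' Rest-referenced z-scoring
#'
#' Transforms every sample of every channel to
#' `(x - mean_rest) / sd_rest` using that channel's resting-state
#' statistics. Channels with zero rest SD are flagged bad and set to
#' `NA`. Applying the transform twice is an error.
#'
#' @param hemo A [hemo_series()] object with a `rest` segment of at
#'   least 30 s.
#' @return The z-scored `hemo_series`.
#' @export
zscore_by_rest <- function(hemo) {
  stopifnot(inherits(hemo, "hemo_series"))
  if (isTRUE(hemo$zscored)) stop("series is already rest-referenced (z-scored)")
  rest <- hemo$segments$rest
  if (is.null(rest) || diff(rest) < 30) stop("rest segment of >= 30 s required")
  idx <- .seg_idx(rest, hemo$fs_hz, nrow(hemo$hbo))
  bad <- hemo$bad_channels
  for (nm in c("hbo", "hbr")) {
    m <- hemo[[nm]]
    mu <- colMeans(m[idx, , drop = FALSE])
    sd <- apply(m[idx, , drop = FALSE], 2, sd)
    zero <- which(sd == 0)
    if (length(zero)) {
      warning("channel(s) with zero rest SD flagged bad: ",
              paste(zero, collapse = ", "))
      bad <- union(bad, zero)
      sd[zero] <- NA_real_
    }
    hemo[[nm]] <- sweep(sweep(m, 2, mu, "-"), 2, sd, "/")
  }
  hemo$bad_channels <- sort(bad)
  hemo$zscored <- TRUE
  hemo
}

#' Full preprocessing chain for an optical recording
#'
#' Motion correction per wavelength series in OD space, MBLL inversion to
#' concentration changes, zero-phase band-pass, then rest-referenced
#' z-scoring.
#'
#' @param rec An `optical_recording` (see [generate_fnirs()]): list with
#'   `od` array (time x channel x wavelength), `fs_hz`, `segments`.
#' @param constants [mbll_constants()].
#' @param low,high Filter band in Hz.
#' @param detrend_order Polynomial detrend order applied before
#'   filtering (default 3).
#' @param motion Logical; run motion correction (default `TRUE`).
#' @param zscore Logical; rest-reference the output (default `TRUE`).
#' @return A [hemo_series()] object; the fraction of motion-corrected
#'   samples per channel is attached as attribute `motion_fraction`.
#' @export
preprocess_recording <- function(rec, constants = mbll_constants(),
                                 low = 0.01, high = 0.20,
                                 detrend_order = 3,
                                 motion = TRUE, zscore = TRUE) {
  od <- rec$od
  n <- dim(od)[1]; nch <- dim(od)[2]
  hbo <- matrix(NA_real_, n, nch)
  hbr <- matrix(NA_real_, n, nch)
  mfrac <- numeric(nch)
  for (ch in seq_len(nch)) {
    o <- od[, ch, ]
    if (motion) {
      m1 <- motion_correct(o[, 1], rec$fs_hz)
      m2 <- motion_correct(o[, 2], rec$fs_hz)
      o <- cbind(m1$series, m2$series)
      mfrac[ch] <- mean(m1$mask | m2$mask)
    }
    conc <- mbll_invert(o, constants)
    hbo[, ch] <- conc[, "hbo"]
    hbr[, ch] <- conc[, "hbr"]
  }
  hbo <- .pipeline_filter(hbo, rec$fs_hz, low, high, detrend_order)
  hbr <- .pipeline_filter(hbr, rec$fs_hz, low, high, detrend_order)
  out <- hemo_series(hbo, hbr, rec$fs_hz, rec$segments)
  if (zscore) out <- zscore_by_rest(out)
  if (any(!is.finite(out$hbo[, setdiff(seq_len(nch), out$bad_channels)])))
    stop("non-finite values after preprocessing")
  attr(out, "motion_fraction") <- mfrac
  out
}
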