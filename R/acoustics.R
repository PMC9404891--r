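# Short-time analysis grid shared by the synthesizer and the analyzers:
# Gaussian window of `frame_length` s, hop of `hop` s, frames fully inside the
# signal. Returns integer sample indices of frame centers.
frame_centers <- function(n_samples, sample_rate, frame_length = 0.03, hop = 0.01) {
  wl <- round(frame_length * sample_rate)
  half <- wl %/% 2
  hp <- round(hop * sample_rate)
  if (n_samples < wl) return(integer(0))
  seq.int(half + 1L, n_samples - half, by = hp)
}

gaussian_window <- function(wl) {
  i <- seq_len(wl) - (wl + 1) / 2
  exp(-0.5 * (i / (wl / 6))^2)
}

# dB convention used throughout: a full-scale sine (peak 1, RMS 1/sqrt(2))
# reads 96 dB, the usual 16-bit headroom mapping.
rms_to_db <- function(rms) 96 + 20 * log10(pmax(rms, 1e-12) * sqrt(2))
db_to_amp <- function(db) 10^((db - 96) / 20) / sqrt(2)

#' Fundamental-frequency contour by windowed autocorrelation
#'
#' Tracks f0 frame-by-frame with a Gaussian-windowed normalized
#' autocorrelation. Within each frame the autocorrelation is searched over the
#' lag band corresponding to `[fmin, fmax]`; the peak lag is refined by
#' parabolic interpolation. Frames whose peak normalized autocorrelation falls
#' below `voicing_threshold`, or whose energy is negligible, are marked
#' unvoiced (`NA`).
#'
#' @param w a [waveform()].
#' @param fmin,fmax f0 search band in Hz; `fmin < fmax < sample_rate/2`.
#' @param frame_length analysis window length in seconds (Gaussian window).
#' @param hop hop between frame centers in seconds.
#' @param voicing_threshold minimum normalized autocorrelation peak for a
#'   frame to count as voiced.
#' @return An object of class `f0_contour`: a list with `times` (s, frame
#'   centers), `f0` (Hz, `NA` when unvoiced), `strength` (normalized
#'   autocorrelation peak), `amp_db` (per-frame Gaussian-weighted RMS in dB),
#'   `frame_length`, `hop`.
#' @export
compute_f0_contour <- function(w, fmin = 75, fmax = 600,
                               frame_length = 0.03, hop = 0.01,
                               voicing_threshold = 0.45) {
  stopifnot(inherits(w, "waveform"))
  sr <- w$sample_rate
  if (!(fmin < fmax && fmax < sr / 2)) {
    stop("need fmin < fmax < sample_rate/2")
  }
  x <- w$samples
  centers <- frame_centers(length(x), sr, frame_length, hop)
  if (length(centers) == 0) {
    stop("waveform shorter than one analysis window (",
         frame_length, " s at ", sr, " Hz)")
  }
  wl <- round(frame_length * sr)
  half <- wl %/% 2
  win <- gaussian_window(2L * half + 1L)
  lag_min <- max(2L, floor(sr / fmax))
  lag_max <- ceiling(sr / fmin)
  nfft <- stats::nextn(2L * half + 1L + lag_max, 2)
  # autocorrelation of the analysis window, used to undo the taper-induced
  # lag bias of the windowed signal autocorrelation
  ftw <- stats::fft(c(win, numeric(nfft - length(win))))
  ac_win <- Re(stats::fft(Mod(ftw)^2, inverse = TRUE))[1:(lag_max + 1L)]
  ac_win <- ac_win / ac_win[1L]

  n_f <- length(centers)
  f0 <- rep(NA_real_, n_f)
  strength <- numeric(n_f)
  amp_db <- numeric(n_f)
  for (k in seq_len(n_f)) {
    c0 <- centers[k]
    seg <- x[(c0 - half):(c0 + half)] * win
    amp_db[k] <- rms_to_db(sqrt(sum((x[(c0 - half):(c0 + half)])^2 * win) / sum(win)))
    e <- sum(seg^2)
    if (e < 1e-10) next
    # FFT autocorrelation of the windowed frame
    ft <- stats::fft(c(seg, numeric(nfft - length(seg))))
    ac <- Re(stats::fft(Mod(ft)^2, inverse = TRUE))[1:(lag_max + 1L)]
    # clamp at 1: the taper correction can overshoot on non-stationary frames
    ac <- pmin((ac / ac[1L]) / ac_win, 1)
    # candidate peaks: local maxima of the corrected autocorrelation in the
    # lag band; a small per-octave cost prefers the shortest near-equal lag
    # (a periodic signal peaks identically at every multiple of its period)
    lags <- lag_min:lag_max
    v <- ac[lags + 1L]
    is_pk <- c(FALSE, v[-c(1, length(v))] > v[-c(length(v) - 1, length(v))] &
                 v[-c(1, length(v))] >= v[-(1:2)], FALSE)
    cand <- lags[is_pk]
    if (length(cand) == 0) cand <- lags[which.max(v)]
    score <- ac[cand + 1L] - 0.05 * log2(cand / lag_min)
    lag <- cand[which.max(score)]
    val <- ac[lag + 1L]
    if (val < voicing_threshold) next
    # sub-sample refinement: least-squares parabola over a neighbourhood that
    # widens with the lag (long-lag peaks are broad, so averaging more points
    # suppresses noise without biasing the apex)
    hw <- min(8L, max(1L, lag %/% 25L), lag - lag_min, lag_max - lag)
    if (hw >= 1) {
      ll <- (lag - hw):(lag + hw)
      cf <- stats::lm.fit(cbind(1, ll - lag, (ll - lag)^2),
                          ac[ll + 1L])$coefficients
      delta <- if (is.finite(cf[3]) && cf[3] < 0) -cf[2] / (2 * cf[3]) else 0
      delta <- max(-hw, min(hw, delta))
    } else delta <- 0
    f0[k] <- sr / (lag + delta)
    strength[k] <- val
  }
  structure(list(times = (centers - 1L) / sr, f0 = f0, strength = strength,
                 amp_db = amp_db, frame_length = frame_length, hop = hop),
            class = "f0_contour")
}

#' Extract call-level acoustic features
#'
#' Reduces a waveform to the seven summary features used for call typing:
#' duration of the voiced span, mean/min/max of the f0 contour over voiced
#' frames, and mean/min/max per-frame intensity (dB, full-scale sine = 96 dB)
#' over the same span. Duration runs from the first to the last voiced frame,
#' endpoint-inclusive (one window length is added to the span of frame
#' centers).
#'
#' @inheritParams compute_f0_contour
#' @param contour optionally, a precomputed [compute_f0_contour()] result.
#' @return An object of class `call_features`: list with `duration`,
#'   `mean_f0`, `min_f0`, `max_f0`, `mean_amp`, `min_amp`, `max_amp`.
#' @export
extract_features <- function(w, fmin = 75, fmax = 600, contour = NULL) {
  if (is.null(contour)) contour <- compute_f0_contour(w, fmin, fmax)
  voiced <- which(!is.na(contour$f0))
  if (length(voiced) == 0) stop("no call detected: all frames unvoiced")
  span <- voiced[1]:voiced[length(voiced)]
  f0v <- contour$f0[voiced]
  ampv <- contour$amp_db[span]
  structure(list(
    duration = contour$times[voiced[length(voiced)]] - contour$times[voiced[1]] +
      contour$frame_length,
    mean_f0 = mean(f0v), min_f0 = min(f0v), max_f0 = max(f0v),
    mean_amp = mean(ampv), min_amp = min(ampv), max_amp = max(ampv)
  ), class = "call_features")
}

#' @export
print.call_features <- function(x, ...) {
  cat(sprintf(paste0("<call_features: %.3f s, f0 %.0f [%.0f-%.0f] Hz, ",
                     "amp %.1f [%.1f-%.1f] dB>\n"),
              x$duration, x$mean_f0, x$min_f0, x$max_f0,
              x$mean_amp, x$min_amp, x$max_amp))
  invisible(x)
}

feature_names <- c("duration", "mean_f0", "min_f0", "max_f0",
                   "mean_amp", "min_amp", "max_amp")

#' Call-type profiles of the study repertoire
#'
#' The three call types heard during group movements — coo, leap coo and bark —
#' summarised by their seven-feature centroid and per-feature dispersion (SD).
#' The bark type is represented by a single exemplar, so it has no dispersion
#' of its own and borrows the pooled coo/leap-coo SD per feature (the only
#' available variance estimate).
#'
#' @return A data.frame with one row per (type, feature): columns `type`,
#'   `n`, `feature`, `centroid`, `sd`.
#' @export
call_type_profiles <- function() {
  coo <- c(0.23, 282, 244, 303, 53, 43, 56)
  coo_sd <- c(0.04, 29, 36, 42, 10, 10, 10)
  leap <- c(0.26, 361, 260, 490, 58, 45, 63)
  leap_sd <- c(0.11, 15, 60, 45, 6, 5, 6)
  bark <- c(0.06, 378, 360, 398, 73, 68, 75)
  pooled <- sqrt(((22 - 1) * coo_sd^2 + (7 - 1) * leap_sd^2) / (22 + 7 - 2))
  data.frame(
    type = rep(c("coo", "leap_coo", "bark"), each = 7),
    n = rep(c(22L, 7L, 1L), each = 7),
    feature = rep(feature_names, 3),
    centroid = c(coo, leap, bark),
    sd = c(coo_sd, leap_sd, pooled),
    stringsAsFactors = FALSE
  )
}

profile_matrix <- function(profiles, what) {
  m <- matrix(profiles[[what]], nrow = 7,
              dimnames = list(profiles$feature[1:7], unique(profiles$type)))
  t(m)
}

#' Classify a call by nearest standardized profile
#'
#' Assigns a feature vector to the call type whose centroid is nearest in
#' per-feature-standardized Euclidean distance: each feature difference is
#' divided by the profile's dispersion and the seven standardized differences
#' are summed in quadrature. Ties are broken by profile order (coo, leap coo,
#' bark).
#'
#' @param f a `call_features` object (or named list with the seven features).
#' @param profiles profile table as returned by [call_type_profiles()].
#' @return List with `type` (character) and `distance` (standardized
#'   Euclidean distance to the winning centroid).
#' @export
classify_call <- function(f, profiles = call_type_profiles()) {
  stopifnot(nrow(profiles) > 0)
  x <- unlist(f[feature_names])
  cen <- profile_matrix(profiles, "centroid")
  sds <- profile_matrix(profiles, "sd")
  d <- sqrt(rowSums(((matrix(x, nrow(cen), 7, byrow = TRUE) - cen) / sds)^2))
  best <- which(d <= min(d) + 1e-12)[1]  # ties: first profile in order
  list(type = rownames(cen)[best], distance = unname(d[best]))
}

#' Batch feature extraction over a directory of WAV files
#'
#' @param wav_dir directory containing mono 16-bit PCM WAV files, one call per
#'   file.
#' @param profiles profile table for classification.
#' @return data.frame with one row per file: file, duration_s, mean_f0,
#'   min_f0, max_f0, mean_amp_db, min_amp_db, max_amp_db, call_type, distance.
#' @export
extract_features_dir <- function(wav_dir, profiles = call_type_profiles()) {
  files <- sort(list.files(wav_dir, pattern = "\\.wav$", ignore.case = TRUE))
  rows <- lapply(files, function(f) {
    ft <- extract_features(read_wav(file.path(wav_dir, f)))
    cl <- classify_call(ft, profiles)
    data.frame(file = f, duration_s = ft$duration,
               mean_f0 = ft$mean_f0, min_f0 = ft$min_f0, max_f0 = ft$max_f0,
               mean_amp_db = ft$mean_amp, min_amp_db = ft$min_amp,
               max_amp_db = ft$max_amp, call_type = cl$type,
               distance = cl$distance, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
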