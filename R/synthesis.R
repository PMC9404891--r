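# Solve for p such that the frame-sampled monotone profile u^p (u on a 0..1
# grid over F frames) has the required mean m. Gives a smooth rise from 0 to 1
# whose time average is controlled, used to shape both the f0 contour and the
# dB envelope so a call spans [min, max] with the prescribed mean.
profile_exponent <- function(F, m) {
  if (F < 2) return(1)
  u <- (seq_len(F) - 1) / (F - 1)
  lo <- 1 / F
  hi <- (F - 1) / F
  m <- min(max(m, lo + 0.02), hi - 0.02)
  stats::uniroot(function(p) mean(u^p) - m, c(1e-3, 1e3), tol = 1e-10)$root
}

rise_profile <- function(F, minv, meanv, maxv) {
  if (F < 2 || maxv <= minv) return(rep(meanv, max(F, 1)))
  u <- (seq_len(F) - 1) / (F - 1)
  p <- profile_exponent(F, (meanv - minv) / (maxv - minv))
  minv + (maxv - minv) * u^p
}

#' Synthesize a call of a given type
#'
#' Builds a mono 44.1 kHz waveform as a 5-harmonic stack (1/k amplitude
#' rolloff) whose fundamental rises monotonically across the call from the
#' type's minimum to its maximum f0 with time mean equal to the type's mean
#' f0, and whose dB envelope does the same for the three intensity targets.
#' Targets are placed on the same analysis grid (0.03 s window, 0.01 s hop)
#' that [compute_f0_contour()] uses, so a jitter-free synthesis round-trips
#' through [extract_features()] to the type centroid. dB calibration: a
#' full-scale sine reads 96 dB.
#'
#' With `jitter > 0` every target is perturbed multiplicatively by
#' `exp(rnorm(1, 0, jitter))` (min/mean/max trios re-sorted to stay ordered).
#'
#' @param call_type one of `"coo"`, `"leap_coo"`, `"bark"`.
#' @param jitter multiplicative perturbation SD on the log scale; 0 gives the
#'   exact type centroid.
#' @param seed integer seed for the jitter draws.
#' @param sample_rate output sampling rate in Hz.
#' @return A [waveform()].
#' @export
synthesize_call <- function(call_type, jitter = 0, seed = 1L,
                            sample_rate = 44100) {
  profiles <- call_type_profiles()
  if (!call_type %in% unique(profiles$type)) {
    stop("unknown call type: ", call_type,
         " (known: ", paste(unique(profiles$type), collapse = ", "), ")")
  }
  cen <- profiles$centroid[profiles$type == call_type]
  names(cen) <- profiles$feature[profiles$type == call_type]
  if (jitter > 0) {
    cen <- with_seed(sub_seed(seed, paste0("synth-", call_type)), {
      z <- cen * exp(stats::rnorm(7, 0, jitter))
      z[c("min_f0", "mean_f0", "max_f0")] <- sort(z[c("min_f0", "mean_f0", "max_f0")])
      z[c("min_amp", "mean_amp", "max_amp")] <- sort(z[c("min_amp", "mean_amp", "max_amp")])
      z
    })
  }
  sr <- sample_rate
  n <- round(cen[["duration"]] * sr)
  centers <- frame_centers(n, sr)
  F <- length(centers)
  if (F == 0) stop("call too short to synthesize at this sampling rate")

  f0_target <- rise_profile(F, cen[["min_f0"]], cen[["mean_f0"]], cen[["max_f0"]])
  db_target <- rise_profile(F, cen[["min_amp"]], cen[["mean_amp"]], cen[["max_amp"]])
  idx <- seq_len(n)
  k <- 1:5
  stack_rms <- sqrt(sum(1 / k^2) / 2)
  render <- function(f0_frames, db_frames) {
    f0_s <- stats::approx(centers, f0_frames, xout = idx, rule = 2)$y
    db_s <- stats::approx(centers, db_frames, xout = idx, rule = 2)$y
    phase <- cumsum(f0_s) / sr
    stack <- rowSums(sapply(k, function(kk) sin(2 * pi * kk * phase) / kk))
    db_to_amp(db_s) / stack_rms * stack
  }
  # Short-time analysis smooths fast target changes near the call edges, so
  # calibrate: measure the rendered call on the same grid and feed the error
  # back into the frame targets (a contraction; a few passes suffice).
  f0_adj <- f0_target
  db_adj <- db_target
  w <- waveform(render(f0_adj, db_adj), sr)
  for (it in 1:3) {
    ct <- compute_f0_contour(w)
    meas_f0 <- ct$f0
    ok <- !is.na(meas_f0)
    f0_adj[ok] <- f0_adj[ok] + (f0_target[ok] - meas_f0[ok])
    db_adj <- db_adj + (db_target - ct$amp_db)
    w <- waveform(render(f0_adj, db_adj), sr)
  }
  w
}

#' Synthesize a labelled set of calls
#'
#' @param counts named integer vector: number of calls per type.
#' @param jitter passed to [synthesize_call()].
#' @param seed master seed; each call gets its own sub-seed.
#' @return List with `waveforms` (list of [waveform()]) and `types`
#'   (character vector of true labels).
#' @export
synthesize_call_set <- function(counts = c(coo = 22L, leap_coo = 7L, bark = 1L),
                                jitter = 0, seed = 1L) {
  types <- rep(names(counts), counts)
  waves <- lapply(seq_along(types), function(i) {
    synthesize_call(types[i], jitter = jitter, seed = sub_seed(seed, paste0("call", i)))
  })
  list(waveforms = waves, types = types)
}
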