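#' Extract the amplitude envelope of an audio signal
#'
#' The magnitude of the analytic (Hilbert) signal is squared, averaged over
#' consecutive non-overlapping windows of `fs / target_rate` samples, and
#' compressed by a power nonlinearity (cube root by default; exponent 1
#' disables compression). This yields one non-negative envelope sample per
#' output frame at `target_rate`.
#'
#' @param audio Mono numeric waveform. Multichannel input is an error: mix
#'   down first.
#' @param fs Input sampling rate, Hz; must exceed `2 * target_rate`.
#' @param target_rate Output feature rate, Hz.
#' @param power Compression exponent applied to the windowed power
#'   (default 1/3).
#' @param block Block index stored on the feature.
#' @param kind Feature kind label (`envelope_raw` or `envelope_denoised`).
#' @return A [stimulus_feature()] of the envelope kind.
#' @export
extract_envelope <- function(audio, fs, target_rate, power = 1 / 3,
                             block = NA_integer_, kind = "envelope_raw") {
  if (is.matrix(audio) && min(dim(audio)) > 1)
    stop("multichannel input: mix to mono before envelope extraction")
  audio <- as.numeric(audio)
  if (fs <= 2 * target_rate) stop("fs must exceed 2 * target_rate")
  win <- fs / target_rate
  if (abs(win - round(win)) > 1e-6)
    stop("fs must be an integer multiple of target_rate")
  win <- as.integer(round(win))
  p <- Mod(analytic_signal(audio))^2
  nwin <- floor(length(p) / win)
  m <- matrix(p[seq_len(nwin * win)], nrow = win)
  env <- colMeans(m)^power
  stimulus_feature(env, target_rate, kind, block)
}

#' Wiener noise reduction with the noise spectrum taken from the signal start
#'
#' The input is high-pass filtered at 1 Hz, then processed frame-wise in the
#' STFT domain: the noise power spectral density is estimated as the mean
#' frame power over the first `noise_seconds` of the signal (assumed to hold
#' only the stationary floor, e.g. ventilation noise), and each frame/bin is
#' scaled by the Wiener gain `max(0, 1 - PSD_noise / PSD_frame)`. The output
#' is reconstructed by weighted overlap-add and has the input length.
#'
#' @param audio Mono numeric waveform.
#' @param fs Sampling rate, Hz.
#' @param noise_seconds Duration of the leading noise-only segment used for
#'   the noise PSD (default 1 s).
#' @param frame_s,hop_s STFT frame and hop in seconds (defaults 32 ms / 8 ms,
#'   Hann window).
#' @param smooth_frames Moving-average length (frames) used to stabilize the
#'   per-frame PSD estimate before the gain is computed.
#' @return Denoised waveform, same length as the input.
#' @export
wiener_denoise <- function(audio, fs, noise_seconds = 1.0,
                           frame_s = 0.032, hop_s = 0.008,
                           smooth_frames = 25) {
  audio <- as.numeric(audio)
  if (noise_seconds >= length(audio) / fs)
    stop("noise_seconds must be shorter than the signal")
  if (all(audio == 0)) return(audio)
  audio <- highpass_1hz(audio, fs)
  frame <- max(16L, as.integer(round(frame_s * fs)))
  hop <- max(1L, as.integer(round(hop_s * fs)))
  S <- stft_mat(audio, frame, hop)
  starts <- attr(S, "starts")
  P <- Mod(S)^2
  noise_frames <- which(starts + frame - 1 <= noise_seconds * fs)
  if (!length(noise_frames)) noise_frames <- 1L
  psd_noise <- rowMeans(P[, noise_frames, drop = FALSE])
  # variance of the single-frame periodogram would leak stationary noise
  # through the gain; a short moving average across frames stabilizes it
  Ps <- t(apply(P, 1, function(row) {
    k <- min(as.integer(smooth_frames), length(row))
    as.numeric(stats::filter(row, rep(1 / k, k), sides = 2, circular = TRUE))
  }))
  gain <- 1 - psd_noise / pmax(Ps, 1e-300)
  gain[gain < 0] <- 0
  S2 <- S * gain
  attributes(S2) <- attributes(S)
  istft_mat(S2)
}

# Gentle 1 Hz high-pass (2nd-order Butterworth, zero-phase) used before
# noise-PSD estimation; removes DC/drift without touching the audio band.
highpass_1hz <- function(x, fs) {
  bf <- signal::butter(2, 1 / (fs / 2), type = "high")
  as.numeric(signal::filtfilt(bf, x))
}

#' Detect acoustic onsets by spectral flux
#'
#' A spectral-flux novelty curve (half-wave-rectified frame-to-frame increase
#' of STFT magnitude, summed over bins) is compared against an adaptive
#' running-median threshold; peaks exceeding it, separated by at least
#' `min_ioi_s`, are marked as onsets in a binary vector at `target_rate`.
#' Designed for naturalistic input: the raw (not denoised) audio is used.
#'
#' @param audio Mono numeric waveform.
#' @param fs Sampling rate, Hz.
#' @param target_rate Output feature rate, Hz.
#' @param min_ioi_s Minimum inter-onset interval, seconds (default 50 ms).
#' @param frame_s,hop_s STFT frame and hop, seconds.
#' @param delta Threshold offset as a multiple of the novelty median absolute
#'   deviation.
#' @param block Block index stored on the feature.
#' @return A [stimulus_feature()] of kind `onsets`.
#' @export
detect_onsets <- function(audio, fs, target_rate, min_ioi_s = 0.05,
                          frame_s = 0.032, hop_s = 0.008, delta = 4,
                          block = NA_integer_) {
  audio <- as.numeric(audio)
  n_out <- as.integer(round(length(audio) / fs * target_rate))
  if (all(audio == 0) || length(audio) < fs * 0.05)
    return(stimulus_feature(numeric(n_out), target_rate, "onsets", block))
  frame <- max(16L, as.integer(round(frame_s * fs)))
  hop <- max(1L, as.integer(round(hop_s * fs)))
  S <- Mod(stft_mat(audio, frame, hop))[seq_len(frame %/% 2 + 1), , drop = FALSE]
  dS <- diff(t(S))
  dS[dS < 0] <- 0
  flux <- c(0, rowSums(dS))
  med <- stats::runmed(flux, k = odd_at_least(round(1.0 / hop_s)), endrule = "median")
  thr <- med + delta * stats::mad(flux) + 1e-12
  above <- flux > thr
  frame_t <- (seq_along(flux) - 1) * hop / fs  # flux index i marks the rise into frame i
  min_gap <- min_ioi_s
  onset_t <- numeric(0)
  i <- 1L
  while (i <= length(flux)) {
    if (above[i] && (i == 1L || flux[i] >= flux[max(1, i - 1)]) &&
        (i == length(flux) || flux[i] >= flux[min(length(flux), i + 1)])) {
      t0 <- frame_t[i]
      if (!length(onset_t) || t0 - onset_t[length(onset_t)] >= min_gap)
        onset_t <- c(onset_t, t0)
    }
    i <- i + 1L
  }
  v <- numeric(n_out)
  idx <- pmin(n_out, pmax(1L, as.integer(round(onset_t * target_rate)) + 1L))
  v[idx] <- 1
  stimulus_feature(v, target_rate, "onsets", block)
}

odd_at_least <- function(k) { k <- max(3L, as.integer(k)); if (k %% 2 == 0) k + 1L else k }

#' Correct the constant hardware delay of sound markers
#'
#' Every marker onset is shifted forward by `delay_ms` (rounded to the
#' nearest sample), compensating the constant latency between the logged
#' marker and the physical sound onset. Ordering is preserved. Markers that
#' would move past the recording end are clamped and flagged.
#'
#' @param markers Marker data.frame with `onset_sample`.
#' @param fs Sampling rate, Hz.
#' @param delay_ms Constant delay in milliseconds (default 30).
#' @param n_samples Recording length, for clamping (optional).
#' @return The marker table with shifted `onset_sample` and a logical
#'   `clamped` column when clamping occurred.
#' @export
correct_marker_delay <- function(markers, fs, delay_ms = 30, n_samples = NULL) {
  if (!is.finite(delay_ms)) stop("delay must be finite")
  shift <- as.integer(round(delay_ms / 1000 * fs))
  markers$onset_sample <- markers$onset_sample + shift
  if (!is.null(n_samples)) {
    over <- markers$onset_sample > n_samples
    if (any(over)) {
      warning(sum(over), " marker(s) shifted past the recording end; clamped")
      markers$clamped <- over
      markers$onset_sample[over] <- n_samples
    }
  }
  markers
}

#' Refine letter-onset markers to the first energetic peak
#'
#' Letters embedded in a continuous soundscape become audible only once
#' their energy rises above the background; the nominal marker can precede
#' that moment. For each marker the short-time energy within
#' `[marker, marker + search_ms]` is scanned and the marker is moved forward
#' to the first local energy peak exceeding `rel_threshold` of the window
#' maximum. Shifts are non-negative and reported per letter; windows with no
#' supra-threshold energy keep the original marker and are flagged.
#'
#' @param audio Mono waveform the markers refer to.
#' @param fs Audio sampling rate, Hz.
#' @param letter_markers data.frame with `onset_sample` (at `fs`).
#' @param search_ms Search window length, ms (default 20).
#' @param rel_threshold Fraction of the window's maximum energy a peak must
#'   exceed (default 0.1).
#' @param energy_ms Short-time energy window, ms (smoothed over 1 ms to
#'   suppress carrier-frequency ripple).
#' @return List: `markers` (shifted table), `shifts_ms` (per letter), and
#'   `flagged` (no supra-threshold energy found).
#' @export
refine_letter_onsets <- function(audio, fs, letter_markers, search_ms = 20,
                                 rel_threshold = 0.1, energy_ms = 4) {
  w <- max(2L, as.integer(round(energy_ms / 1000 * fs)))
  sm <- max(1L, as.integer(round(0.001 * fs)))
  span <- as.integer(round(search_ms / 1000 * fs))
  shifts <- numeric(nrow(letter_markers))
  flagged <- logical(nrow(letter_markers))
  for (i in seq_len(nrow(letter_markers))) {
    s0 <- letter_markers$onset_sample[i]
    if (s0 + span + w + sm - 1 > length(audio))
      stop("marker ", i, " has less than search_ms of audio after it")
    seg <- audio[s0:(s0 + span + w + sm - 1)]
    e2 <- stats::filter(seg^2, rep(1 / w, w), sides = 1)  # energy ending at j
    e <- as.numeric(stats::filter(e2, rep(1 / sm, sm), sides = 1))[w + sm - 2 + seq_len(span + 1)]
    mx <- max(e)
    if (mx == 0) {
      flagged[i] <- TRUE
      next
    }
    if (e[1] >= 0.95 * mx) next                 # marker already at full energy
    pk <- which(e >= rel_threshold * mx &
                e > c(-Inf, e[-length(e)]) &
                e >= c(e[-1], -Inf))
    if (!length(pk)) {
      flagged[i] <- TRUE
      next
    }
    shifts[i] <- (pk[1] - 1) / fs * 1000
    letter_markers$onset_sample[i] <- s0 + pk[1] - 1L
  }
  list(markers = letter_markers, shifts_ms = shifts, flagged = flagged)
}
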