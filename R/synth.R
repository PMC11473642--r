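#' Configuration for the synthetic study generator
#'
#' Encodes the study conditions the generator emulates: a session of 28
#' surgery-task blocks (14 low-demand, 14 high-demand), a continuous
#' operating-room-like soundscape at 48 kHz with spoken-letter-like tokens
#' every 3 s drawn from a 12-letter set, and 24-channel EEG at 500 Hz.
#'
#' @param n_participants Number of simulated participants.
#' @param n_blocks Blocks per participant (default 28).
#' @param blocks_per_condition Blocks per demand condition (default 14; must
#'   satisfy `2 * blocks_per_condition == n_blocks`).
#' @param block_duration_s Soundscape duration per block in seconds.
#' @param audio_fs Audio sampling rate, Hz (default 48000).
#' @param eeg_fs EEG sampling rate, Hz (default 500).
#' @param n_channels Number of EEG channels (default 24, 10-20 labels).
#' @param letter_iti_s Inter-trial interval between letter tokens, seconds
#'   (default 3).
#' @param letter_set Token alphabet (default the 12 consonants
#'   B,C,D,F,H,K,L,M,P,Q,S,T).
#' @param letter_dur_s Duration of a synthesized letter token, seconds.
#' @param transient_rate Poisson rate (events/s) of soundscape transients
#'   (monitor beeps, instrument clatter).
#' @param snr_db Planted neural response power relative to EEG background
#'   noise, in dB.
#' @param marker_delay_ms Constant hardware delay planted on all sound
#'   markers (default 30 ms) so the correction stage is testable.
#' @param seed Integer seed; together with the config it fully determines
#'   every generated output.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_participants = 22, n_blocks = 28,
                         blocks_per_condition = n_blocks / 2,
                         block_duration_s = 60, audio_fs = 48000,
                         eeg_fs = 500, n_channels = 24, letter_iti_s = 3.0,
                         letter_set = c("B", "C", "D", "F", "H", "K", "L",
                                        "M", "P", "Q", "S", "T"),
                         letter_dur_s = 0.3, transient_rate = 0.5,
                         snr_db = 0, marker_delay_ms = 30, seed = 1L) {
  if (block_duration_s <= 0) stop("invalid config: block_duration_s must be positive")
  if (blocks_per_condition * 2 != n_blocks)
    stop("invalid config: blocks_per_condition x 2 must equal n_blocks")
  if (letter_iti_s <= letter_dur_s)
    stop("invalid config: letter_iti_s must exceed the token duration")
  if (n_channels < 2 || n_channels > 24) stop("invalid config: n_channels must be in 2..24")
  structure(list(
    n_participants = n_participants, n_blocks = n_blocks,
    blocks_per_condition = blocks_per_condition,
    block_duration_s = block_duration_s, audio_fs = audio_fs,
    eeg_fs = eeg_fs, n_channels = n_channels, letter_iti_s = letter_iti_s,
    letter_set = letter_set, letter_dur_s = letter_dur_s,
    transient_rate = transient_rate, snr_db = snr_db,
    marker_delay_ms = marker_delay_ms, seed = as.integer(seed)
  ), class = "synth_config")
}

# Gaussian bump helper for kernel construction.
gauss_bump <- function(t_ms, center_ms, sd_ms) exp(-0.5 * ((t_ms - center_ms) / sd_ms)^2)

#' Ground truth of the planted responses and behavioral effects
#'
#' Fixes every quantity the downstream analyses try to recover: the evoked
#' (ERP) kernel with N1/P2/N2 deflections, the envelope- and onset-TRF lag
#' kernels, the channel topographies the responses project through, a
#' multiplicative demand effect on kernel amplitude, a per-block linear
#' amplitude drift, and the fixed/random effects of every behavioral and
#' subjective outcome.
#'
#' Defaults plant no demand effect on the neural kernels
#' (`condition_scale = 1`) and no drift (`time_slope = 0`); behavioral fixed
#' effects default to demand effects of realistic size for a 0-20 workload
#' scale and a session-long learning curve on the surgery metrics.
#'
#' @param cfg A [synth_config()].
#' @param condition_scale Multiplicative high-demand scaling of all neural
#'   kernels (1 = no effect).
#' @param time_slope Linear per-block fractional drift of kernel amplitude
#'   (e.g. -0.01 shrinks responses by 1% of baseline per block).
#' @param erp_peaks,trf_env_peaks,trf_ons_peaks Data frames with columns
#'   `center_ms`, `sd_ms`, `amp` defining Gaussian deflections.
#' @param behavior_params Named list of per-outcome parameters; see source.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(cfg,
                         condition_scale = 1,
                         time_slope = 0,
                         erp_peaks = data.frame(
                           center_ms = c(100, 200, 250),
                           sd_ms = c(20, 30, 35),
                           amp = c(-2, 1.5, -1)),
                         trf_env_peaks = data.frame(
                           center_ms = c(80, 170, 270),
                           sd_ms = c(18, 28, 35),
                           amp = c(-1.5, 1.0, -0.6)),
                         trf_ons_peaks = data.frame(
                           center_ms = c(110, 200, 250),
                           sd_ms = c(18, 28, 35),
                           amp = c(-1.5, 1.0, -0.6)),
                         behavior_params = NULL) {
  fs <- cfg$eeg_fs
  mk_kernel <- function(peaks, t_min_ms, t_max_ms) {
    t_ms <- seq(t_min_ms, t_max_ms, by = 1000 / fs)
    k <- numeric(length(t_ms))
    for (i in seq_len(nrow(peaks)))
      k <- k + peaks$amp[i] * gauss_bump(t_ms, peaks$center_ms[i], peaks$sd_ms[i])
    list(t_ms = t_ms, values = k)
  }
  mont <- standard_montage(default_channels()[seq_len(cfg$n_channels)])
  fc <- standard_montage("FCz")
  d2 <- (mont$x - fc$x)^2 + (mont$y - fc$y)^2 + (mont$z - fc$z)^2
  pat <- exp(-d2 / (2 * 60^2))
  pat <- pat / sqrt(sum(pat^2))  # unit norm
  if (is.null(behavior_params)) {
    behavior_params <- list(
      effort      = list(intercept = 8,  beta_cond = 3.7, beta_time = 0,  sd_id = 1.5, sd_res = 2.0),
      frustration = list(intercept = 5,  beta_cond = 2.7, beta_time = 0,  sd_id = 1.5, sd_res = 2.2),
      distraction = list(intercept = 6,  beta_cond = 1.3, beta_time = 0,  sd_id = 1.5, sd_res = 2.0),
      duration    = list(asymptote = 75, learn_amp = 30, learn_tau = 5, sd_id = 8, sd_res = 6),
      mistakes    = list(p0 = 0.11, p_slope = -0.002),
      tissue      = list(intercept = log(6.2), beta_time = -0.005, beta_cond = 0, sd_id = 0.2),
      memory      = list(p_err_low = 0.03, p_err_high = 0.25, p_blank = 0.4, sd_id = 0.05)
    )
  }
  for (p in behavior_params)
    for (nm in grep("^sd_", names(p), value = TRUE))
      if (p[[nm]] < 0) stop("invalid config: negative SD in behavior_params")
  structure(list(
    erp_kernel = mk_kernel(erp_peaks, 0, 600),
    trf_kernel_env = mk_kernel(trf_env_peaks, 0, 450),
    trf_kernel_ons = mk_kernel(trf_ons_peaks, 0, 450),
    spatial_patterns = list(erp = pat, env = pat, ons = pat),
    condition_scale = condition_scale,
    time_slope = time_slope,
    behavior_params = behavior_params
  ), class = "ground_truth")
}

#' Generate one block's operating-room-like soundscape
#'
#' Stationary colored (pink) ventilation-like noise plus Poisson-scheduled
#' transient events (tone pips and noise bursts emulating monitor beeps and
#' instrument clatter), with a 500 ms linear fade-in. Every transient onset is
#' logged sample-accurately.
#'
#' @param cfg A [synth_config()].
#' @param block Block index (1-based).
#' @param transient_rate Events per second; defaults to `cfg$transient_rate`.
#' @param noise_level RMS of the stationary noise floor. The default makes
#'   the ventilation-like floor loud relative to the transient events
#'   (floor RMS 0.4 of the transient peak), emulating an operating room
#'   where the stationary floor dominates the raw envelope.
#' @param transient_level Peak amplitude scale of transients.
#' @return List with `audio` (numeric vector at `cfg$audio_fs`), `clean`
#'   (the transients alone, without the stationary floor), `events`
#'   (data.frame `onset_sample`, `onset_s`, `kind`), and `fs`.
#' @export
make_soundscape <- function(cfg, block, transient_rate = cfg$transient_rate,
                            noise_level = 0.12, transient_level = 0.3) {
  if (block > cfg$n_blocks) stop("block index exceeds n_blocks")
  if (cfg$block_duration_s <= 0) stop("invalid config: non-positive duration")
  set.seed(cfg$seed + 1000L * block)
  fs <- cfg$audio_fs
  n <- round(cfg$block_duration_s * fs)
  noise <- colored_noise(n, alpha = 1) * noise_level
  clean <- numeric(n)
  events <- data.frame(onset_sample = integer(), onset_s = numeric(),
                       kind = character(), stringsAsFactors = FALSE)
  if (transient_rate > 0) {
    n_ev <- stats::rpois(1, transient_rate * cfg$block_duration_s)
    if (n_ev > 0) {
      onsets <- sort(stats::runif(n_ev, 0.6, cfg$block_duration_s - 0.2))
      kinds <- sample(c("beep", "clatter"), n_ev, replace = TRUE)
      for (i in seq_len(n_ev)) {
        dur <- stats::runif(1, 0.05, 0.15)
        m <- round(dur * fs)
        tok <- if (kinds[i] == "beep") {
          # monitor beep: fast 5 ms ramps, sustained tone
          f0 <- stats::runif(1, 500, 4000)
          nr <- max(1L, round(0.005 * fs))
          env <- c(seq(0, 1, length.out = nr), rep(1, max(0, m - 2 * nr)),
                   seq(1, 0, length.out = nr))[seq_len(m)]
          sin(2 * pi * f0 * seq_len(m) / fs) * env
        } else {
          # instrument clatter: impulsive attack, exponential decay
          stats::rnorm(m) * exp(-seq_len(m) / (0.25 * m))
        }
        s0 <- round(onsets[i] * fs)
        idx <- s0:(min(n, s0 + m - 1))
        clean[idx] <- clean[idx] + transient_level * tok[seq_along(idx)]
      }
      events <- data.frame(onset_sample = round(onsets * fs),
                           onset_s = onsets, kind = kinds,
                           stringsAsFactors = FALSE)
    }
  }
  audio <- noise + clean
  nf <- min(n, round(0.5 * fs))
  fade <- seq(0, 1, length.out = nf)
  audio[seq_len(nf)] <- audio[seq_len(nf)] * fade
  clean[seq_len(nf)] <- clean[seq_len(nf)] * fade
  list(audio = audio, clean = clean, events = events, fs = fs)
}

#' Generate the letter token stream of one block
#'
#' Four letters are drawn from the alphabet excluding the block's
#' to-be-remembered letters; tokens are presented as consecutive groups of
#' those four, shuffled within group, with no immediate repetitions, at the
#' configured inter-trial interval.
#'
#' @param cfg A [synth_config()].
#' @param forbidden Letters excluded from presentation (the memory set).
#' @param n_events Number of tokens; defaults to as many as fit in the block.
#' @param start_s Onset of the first token, seconds.
#' @param seed Optional seed override (defaults to a block-independent draw
#'   from the current RNG state).
#' @return data.frame with `onset_s` and `letter`.
#' @export
make_letter_stream <- function(cfg, forbidden = character(), n_events = NULL,
                               start_s = 1.0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  admissible <- setdiff(cfg$letter_set, forbidden)
  if (length(admissible) < 4)
    stop("invalid config: fewer than 4 admissible letters")
  if (is.null(n_events))
    n_events <- max(0L, floor((cfg$block_duration_s - start_s - cfg$letter_dur_s) /
                              cfg$letter_iti_s) + 1L)
  chosen <- sample(admissible, 4)
  seq_out <- character(0)
  while (length(seq_out) < n_events) {
    g <- sample(chosen)
    while (length(seq_out) > 0 && g[1] == seq_out[length(seq_out)])
      g <- sample(chosen)
    seq_out <- c(seq_out, g)
  }
  seq_out <- seq_out[seq_len(n_events)]
  data.frame(onset_s = start_s + (seq_len(n_events) - 1) * cfg$letter_iti_s,
             letter = seq_out, stringsAsFactors = FALSE)
}

#' Synthesize a spoken-letter-like token
#'
#' A brief formant-like chirp: two harmonically unrelated partials whose
#' frequencies depend on the letter, with 10 ms on/off ramps. Only onset
#' timing and energy matter to the pipeline; this is not speech.
#'
#' @param letter Single character token.
#' @param fs Sampling rate, Hz.
#' @param dur_s Token duration, seconds.
#' @param ramp_s On/offset ramp, seconds (default 10 ms).
#' @return Numeric waveform.
#' @export
synth_letter_token <- function(letter, fs, dur_s = 0.3, ramp_s = 0.01) {
  m <- round(dur_s * fs)
  idx <- which(LETTERS == toupper(letter))
  if (!length(idx)) idx <- 1L
  f1 <- 300 + 40 * idx
  f2 <- 1200 + 90 * idx
  t <- seq_len(m) / fs
  x <- 0.6 * sin(2 * pi * f1 * t) + 0.4 * sin(2 * pi * (f2 + 200 * t) * t)
  nr <- max(1L, round(ramp_s * fs))
  ramp <- seq(0, 1, length.out = nr)
  x[seq_len(nr)] <- x[seq_len(nr)] * ramp
  x[(m - nr + 1):m] <- x[(m - nr + 1):m] * rev(ramp)
  x
}

#' Render a full block: soundscape plus letter tokens
#'
#' @param cfg A [synth_config()].
#' @param block Block index.
#' @param forbidden Memory-set letters excluded from the stream.
#' @param letter_level Peak amplitude of letter tokens.
#' @return List: `audio` (mix), `clean` (transients + letters, no stationary
#'   floor), `events` (transients), `letters` (token table), `fs`.
#' @export
render_block_audio <- function(cfg, block, forbidden = character(),
                               letter_level = 0.35) {
  sc <- make_soundscape(cfg, block)
  letters <- make_letter_stream(cfg, forbidden)
  fs <- cfg$audio_fs
  n <- length(sc$audio)
  for (i in seq_len(nrow(letters))) {
    tok <- synth_letter_token(letters$letter[i], fs, cfg$letter_dur_s) * letter_level
    s0 <- round(letters$onset_s[i] * fs) + 1L
    idx <- s0:min(n, s0 + length(tok) - 1L)
    sc$audio[idx] <- sc$audio[idx] + tok[seq_along(idx)]
    sc$clean[idx] <- sc$clean[idx] + tok[seq_along(idx)]
  }
  c(sc, list(letters = letters))
}

#' Simulate one block of EEG with planted responses
#'
#' The forward generative model: for each stimulus feature, the planted lag
#' kernel is convolved with the feature and projected through its channel
#' topography; evoked templates are added at letter onsets; 1/f background
#' noise (optionally 50 Hz line noise, blink bursts, and broken channels) is
#' added at the configured SNR. Markers carry the configured constant
#' hardware delay so the correction stage is testable.
#'
#' @param cfg A [synth_config()].
#' @param truth A [ground_truth()].
#' @param features Named list of [stimulus_feature()]s at `cfg$eeg_fs`
#'   (names: `env` and/or `ons`), aligned to the block timeline.
#' @param letter_events data.frame with `onset_s` (true acoustic onsets), or
#'   NULL for no evoked responses.
#' @param block Block index (drives the condition/time modulation).
#' @param condition 0 (low demand) or 1 (high demand).
#' @param snr_db Signal-to-noise ratio in dB; `Inf` for noise-free.
#' @param line_noise,blink Logical switches for planted 50 Hz and blink
#'   artifacts.
#' @param bad_channels Labels to overwrite with a broken signal (flat).
#' @param noisy_channels Labels to overwrite with high-amplitude noise.
#' @param seed Seed for the noise draw.
#' @return A [recording()] with letter / sound_start / sound_stop markers.
#' @export
simulate_eeg <- function(cfg, truth, features = list(), letter_events = NULL,
                         block = 1L, condition = 0L, snr_db = cfg$snr_db,
                         line_noise = FALSE, blink = FALSE,
                         bad_channels = character(), noisy_channels = character(),
                         seed = cfg$seed + block) {
  fs <- cfg$eeg_fs
  n <- round(cfg$block_duration_s * fs)
  labels <- default_channels()[seq_len(cfg$n_channels)]
  nch <- cfg$n_channels
  scale_bt <- (if (condition == 1) truth$condition_scale else 1) *
    (1 + truth$time_slope * (block - 1))
  sig <- matrix(0, nch, n)
  for (nm in names(features)) {
    f <- features[[nm]]
    if (abs(f$rate - fs) > 1e-9) stop("features must be at the EEG rate")
    kern <- if (nm == "env") truth$trf_kernel_env else truth$trf_kernel_ons
    if (length(kern$values) > n) stop("invalid config: kernel support exceeds block length")
    resp <- fft_conv_causal(f$values, kern$values, n)
    pat <- truth$spatial_patterns[[nm]][seq_len(nch)]
    sig <- sig + scale_bt * (pat %o% resp)
  }
  if (!is.null(letter_events) && nrow(letter_events) > 0) {
    tmpl <- truth$erp_kernel$values
    pat <- truth$spatial_patterns$erp[seq_len(nch)]
    for (t0 in letter_events$onset_s) {
      s0 <- round(t0 * fs) + 1L
      idx <- s0:min(n, s0 + length(tmpl) - 1L)
      if (s0 > n) next
      sig[, idx] <- sig[, idx] + scale_bt * (pat %o% tmpl[seq_along(idx)])
    }
  }
  set.seed(seed)
  dat <- sig
  if (is.finite(snr_db)) {
    sig_rms <- sqrt(mean(sig^2))
    if (sig_rms == 0) sig_rms <- 1
    noise_rms <- sig_rms / 10^(snr_db / 20)
    # 1/f cortical sources with slow amplitude modulation (EEG background is
    # non-stationary/kurtotic), mixed through smooth random topographies
    # (volume-conduction-like spatial correlation) + 5% sensor noise
    mont <- standard_montage(labels)
    src <- t(vapply(seq_len(nch), function(i) {
      am <- colored_noise(n, alpha = 2)
      am <- 0.4 + abs(am) / stats::sd(am)
      colored_noise(n, alpha = 1) * am
    }, numeric(n)))
    mix <- vapply(seq_len(nch), function(i) {
      ctr <- mont[sample(nch, 1), c("x", "y", "z")]
      d2 <- (mont$x - ctr$x)^2 + (mont$y - ctr$y)^2 + (mont$z - ctr$z)^2
      w <- exp(-d2 / (2 * 55^2)) * sample(c(-1, 1), 1)
      w / sqrt(sum(w^2))
    }, numeric(nch))
    noise <- mix %*% src
    noise <- noise / sqrt(mean(noise^2))
    sensor <- t(vapply(seq_len(nch), function(i) stats::rnorm(n), numeric(n)))
    noise <- (noise + 0.05 * sensor) * noise_rms
    dat <- dat + noise
    if (line_noise)
      dat <- dat + 0.5 * noise_rms *
        matrix(sin(2 * pi * 50 * seq_len(n) / fs), nch, n, byrow = TRUE)
    if (blink) {
      fp <- standard_montage("Fp1")
      d2 <- (labels_xyz(labels, "x") - fp$x)^2 +
            (labels_xyz(labels, "y") - fp$y)^2 +
            (labels_xyz(labels, "z") - fp$z)^2
      bpat <- exp(-d2 / (2 * 45^2))
      bts <- blink_course(n, fs)
      dat <- dat + 8 * noise_rms * (bpat %o% bts)
    }
  }
  for (b in bad_channels) dat[match(b, labels), ] <- 0
  for (b in noisy_channels) dat[match(b, labels), ] <- stats::rnorm(n, sd = 50 * stats::sd(dat))
  delay <- ms_to_samples(cfg$marker_delay_ms, fs)
  markers <- data.frame(onset_sample = c(1L, n),
                        label = c("sound_start", "sound_stop"),
                        block = block, condition = condition,
                        stringsAsFactors = FALSE)
  if (!is.null(letter_events) && nrow(letter_events) > 0) {
    lm <- data.frame(onset_sample = round(letter_events$onset_s * fs) + 1L - delay,
                     label = paste0("letter_", letter_events$letter),
                     block = block, condition = condition,
                     stringsAsFactors = FALSE)
    markers <- rbind(markers, lm)
    markers <- markers[order(markers$onset_sample), ]
    rownames(markers) <- NULL
  }
  recording(dat, fs, labels, markers = markers,
            history = sprintf("simulate_eeg(block=%d, snr_db=%g)", block, snr_db))
}

# Causal convolution keeping the first n samples (kernel lag 0 aligned).
fft_conv_causal <- function(x, h, n = length(x)) {
  nfft <- next_pow2(length(x) + length(h) - 1)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - length(x)))) *
                     stats::fft(c(h, numeric(nfft - length(h)))), inverse = TRUE)) / nfft
  y[seq_len(n)]
}

labels_xyz <- function(labels, col) standard_montage(labels)[[col]]

# Blink-like burst train: slow biphasic events at 0.2-1 Hz random intervals.
blink_course <- function(n, fs) {
  x <- numeric(n)
  t0 <- stats::runif(1, 1, 3)
  tmpl_t <- seq(0, 0.4, by = 1 / fs)
  tmpl <- gauss_bump(tmpl_t * 1000, 200, 60)
  while (t0 * fs < n) {
    s0 <- round(t0 * fs) + 1L
    idx <- s0:min(n, s0 + length(tmpl) - 1L)
    x[idx] <- x[idx] + tmpl[seq_along(idx)]
    t0 <- t0 + stats::runif(1, 1, 5)  # 0.2-1 Hz burst rate
  }
  x
}

#' Simulate the behavioral and subjective block table
#'
#' One row per (participant, block): demand condition (14/14, randomized with
#' 7 per condition in each session half), visual-analog workload ratings on
#' 0-20, surgery-task duration with an exponential learning curve, mistakes
#' in 0..3, Poisson tissue-damage counts with a time-on-task trend, and
#' item-wise simulated memory responses (letters, with 'X' for forgotten
#' items) scored downstream by [memory_score()].
#'
#' @param cfg A [synth_config()].
#' @param truth A [ground_truth()].
#' @param seed Seed (defaults to `cfg$seed`).
#' @return data.frame (`block_table`) with one row per participant x block.
#' @export
simulate_behavior <- function(cfg, truth, seed = cfg$seed) {
  set.seed(seed + 77L)
  bp <- truth$behavior_params
  out <- list()
  for (p in seq_len(cfg$n_participants)) {
    cond <- c(sample(rep(0:1, each = cfg$blocks_per_condition / 2)),
              sample(rep(0:1, each = cfg$n_blocks / 2 - cfg$blocks_per_condition / 2)))
    # guarantee overall 14/14 even when halves are odd-sized
    if (sum(cond) != cfg$blocks_per_condition)
      cond <- sample(rep(0:1, each = cfg$blocks_per_condition))
    b_id <- function(sd) stats::rnorm(1, 0, sd)
    id_eff <- lapply(bp[c("effort", "frustration", "distraction")],
                     function(q) b_id(q$sd_id))
    id_dur <- b_id(bp$duration$sd_id)
    id_tis <- b_id(bp$tissue$sd_id)
    id_mem <- b_id(bp$memory$sd_id)
    for (b in seq_len(cfg$n_blocks)) {
      cd <- cond[b]
      rating <- function(q, eff) {
        v <- q$intercept + q$beta_cond * cd + q$beta_time * b + eff +
          stats::rnorm(1, 0, q$sd_res)
        min(20, max(0, v))
      }
      dur <- bp$duration$asymptote +
        bp$duration$learn_amp * exp(-(b - 1) / bp$duration$learn_tau) +
        id_dur + stats::rnorm(1, 0, bp$duration$sd_res)
      p_mist <- min(1, max(0, bp$mistakes$p0 + bp$mistakes$p_slope * b))
      mistakes <- stats::rbinom(1, 3, p_mist)
      lam <- exp(bp$tissue$intercept + bp$tissue$beta_time * b +
                 bp$tissue$beta_cond * cd + id_tis)
      tissue <- stats::rpois(1, lam)
      L <- if (cd == 0) 2L else 8L
      target <- sample(cfg$letter_set, L)
      p_err <- min(1, max(0, (if (cd == 0) bp$memory$p_err_low else bp$memory$p_err_high) + id_mem))
      response <- vapply(target, function(ch) {
        if (stats::runif(1) < p_err) {
          if (stats::runif(1) < bp$memory$p_blank) "X"
          else sample(setdiff(cfg$letter_set, ch), 1)
        } else ch
      }, character(1))
      out[[length(out) + 1L]] <- data.frame(
        participant = p, block = b, condition = cd,
        effort = rating(bp$effort, id_eff$effort),
        frustration = rating(bp$frustration, id_eff$frustration),
        distraction = rating(bp$distraction, id_eff$distraction),
        duration = dur, mistakes = mistakes, tissue_damage = tissue,
        target_seq = paste(target, collapse = ""),
        response_seq = paste(response, collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  tab$memory_score <- mapply(memory_score, tab$target_seq, tab$response_seq,
                             USE.NAMES = FALSE)
  class(tab) <- c("block_table", "data.frame")
  tab
}

#' Directly simulate feature/EEG block pairs at the analysis rate
#'
#' A reduced-rate generator for TRF-focused studies: stimulus features and
#' EEG are produced directly at the common analysis rate (no audio synthesis
#' or filtering), with a planted lag kernel, a channel topography, and 1/f
#' noise at the requested SNR. Used for kernel-recovery and cross-validation
#' studies where only the regression layer is under test.
#'
#' @param n_blocks Number of blocks.
#' @param block_s Block duration, seconds.
#' @param rate Common analysis rate, Hz.
#' @param kernel Numeric lag kernel (starting at lag 0, at `rate`).
#' @param pattern Channel topography (unit norm recommended).
#' @param snr_db SNR in dB (`Inf` = noise-free).
#' @param feature_kind Feature type for the generated regressor.
#' @param seed Integer seed.
#' @return List of blocks, each `list(feature, eeg)` where `eeg` is a
#'   samples x channels matrix.
#' @export
simulate_trf_blocks <- function(n_blocks = 8, block_s = 300, rate = 125,
                                kernel, pattern = rep(1 / sqrt(4), 4),
                                snr_db = 0, feature_kind = "envelope_denoised",
                                seed = 1L) {
  set.seed(seed)
  n <- round(block_s * rate)
  nch <- length(pattern)
  lapply(seq_len(n_blocks), function(b) {
    # sparse-event-driven envelope: smoothed impulse train, OR-like
    ev <- stats::rbinom(n, 1, 1.2 / rate) * stats::runif(n, 0.5, 1.5)
    sm <- hann_window(round(0.06 * rate))
    feat <- fft_conv_causal(ev, sm / sum(sm), n)
    resp <- fft_conv_causal(feat, kernel, n)
    sig <- resp %o% pattern
    if (is.finite(snr_db)) {
      nr <- sqrt(mean(sig^2)) / 10^(snr_db / 20)
      noise <- vapply(seq_len(nch), function(i) colored_noise(n, 1), numeric(n)) * nr
      sig <- sig + noise
    }
    list(feature = stimulus_feature(pmax(feat, 0), rate, feature_kind, b),
         eeg = sig)
  })
}
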