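make_rec <- function(x, fs = 500, label = "Cz") {
  recording(matrix(x, 1, length(x)), fs, label)
}

test_that("band-limiting preserves the passband and kills the stopband", {
  fs <- 500
  t <- seq_len(fs * 60) / fs
  mid <- (10 * fs):(50 * fs)
  r10 <- bandpass_fir(make_rec(sin(2 * pi * 10 * t)))
  expect_equal(max(abs(r10$data[1, mid])), 1, tolerance = 0.01)
  r45 <- bandpass_fir(make_rec(sin(2 * pi * 45 * t)))
  expect_lt(20 * log10(max(abs(r45$data[1, mid]))), -20)
  rdc <- bandpass_fir(make_rec(rep(100, length(t))))
  expect_lt(mean(abs(rdc$data[1, mid])), 1)
  expect_equal(ncol(r10$data), length(t))       # length preserved
  expect_error(bandpass_fir(make_rec(rnorm(fs)), lp_edge = 300), "Nyquist")
})

test_that("zero-phase filtering does not shift latencies", {
  fs <- 500
  x <- numeric(fs * 30)
  x[fs * 15] <- 1                                # impulse at 15 s
  r <- bandpass_fir(make_rec(x), hp_edge = NULL) # low-pass only
  expect_equal(which.max(r$data[1, ]), fs * 15)
})

test_that("restriction to sound trims five seconds per side", {
  fs <- 500
  mk <- data.frame(onset_sample = c(1L, 60L * fs, 70L * fs, 79L * fs),
                   label = c("sound_start", "sound_stop",
                             "sound_start", "sound_stop"),
                   block = c(1L, 1L, 2L, 2L), condition = 0L)
  rec <- recording(matrix(rnorm(80 * fs), 1), fs, "Cz", markers = mk)
  expect_warning(segs <- restrict_to_sound(rec), "dropped")  # 9 s block 2
  expect_equal(length(segs), 1)
  expect_equal(ncol(segs[[1]]$data) / fs, 50, tolerance = 0.001)
  # unpaired markers error
  mk2 <- mk[-2, ]
  rec2 <- recording(matrix(rnorm(80 * fs), 1), fs, "Cz", markers = mk2)
  expect_error(restrict_to_sound(rec2), "block 1")
})

test_that("restriction with zero trim is idempotent on a restricted segment", {
  fs <- 500
  mk <- data.frame(onset_sample = c(1L, 40L * fs), label = c("sound_start", "sound_stop"),
                   block = 1L, condition = 0L)
  rec <- recording(matrix(rnorm(40 * fs), 1), fs, "Cz", markers = mk)
  seg <- restrict_to_sound(rec)[[1]]
  seg$markers <- data.frame(onset_sample = c(1L, ncol(seg$data)),
                            label = c("sound_start", "sound_stop"),
                            block = 1L, condition = 0L)
  seg2 <- restrict_to_sound(seg, trim_s = 0)[[1]]
  expect_equal(seg2$data, seg$data)
})

test_that("bad-channel rejection spares clean data and catches planted faults", {
  cfg <- synth_config(n_participants = 1, n_blocks = 2,
                      blocks_per_condition = 1, block_duration_s = 60,
                      seed = 21)
  tr <- ground_truth(cfg)
  clean <- simulate_eeg(cfg, tr, features = list(), snr_db = 0, seed = 1)
  expect_equal(length(reject_bad_channels(clean, seed = 1)$bads), 0)
  flat <- simulate_eeg(cfg, tr, features = list(), snr_db = 0,
                       bad_channels = "F3", seed = 2)
  expect_equal(reject_bad_channels(flat, seed = 1)$bads, "F3")
  broken <- simulate_eeg(cfg, tr, features = list(), snr_db = 0,
                         bad_channels = c("F3", "C4"),
                         noisy_channels = c("Pz", "O1", "T7", "Fp2", "P8"),
                         seed = 3)
  bads <- reject_bad_channels(broken, seed = 1)$bads
  expect_equal(length(bads), 5)                 # cap of five
  expect_true(all(bads %in% c("F3", "C4", "Pz", "O1", "T7", "Fp2", "P8")))
  nomont <- clean
  nomont$montage <- NULL
  expect_error(reject_bad_channels(nomont), "montage")
})

test_that("joint-probability rejection flags the improbable epoch", {
  set.seed(31)
  ep <- array(rnorm(24 * 100 * 50), c(24, 100, 50))
  ep[, , 17] <- ep[, , 17] * 10
  mask <- jointprob_reject(ep, 3)
  expect_false(mask[17])
  expect_gte(sum(mask), 45)
  # threshold to infinity keeps everything
  expect_true(all(jointprob_reject(ep, Inf)))
  # identical epochs: warning, none rejected
  ep2 <- array(rep(rnorm(4 * 50), 30), c(4, 50, 30))
  expect_warning(m2 <- jointprob_reject(ep2, 3), "identical")
  expect_true(all(m2))
  expect_error(jointprob_reject(ep[, , 1:5], 3), "10 epochs")
})

test_that("ICA removes a planted blink and spares clean data", {
  cfg <- synth_config(n_participants = 1, n_blocks = 2,
                      blocks_per_condition = 1, block_duration_s = 120,
                      seed = 6)
  tr <- ground_truth(cfg)
  base <- bandpass_fir(simulate_eeg(cfg, tr, features = list(), snr_db = 0,
                                    seed = 11))
  # plant a blink with known pattern and time course on top of clean data
  fp <- standard_montage("Fp1")
  mont <- standard_montage(base$labels)
  d2 <- (mont$x - fp$x)^2 + (mont$y - fp$y)^2 + (mont$z - fp$z)^2
  bpat <- exp(-d2 / (2 * 45^2))
  set.seed(99)
  n <- ncol(base$data)
  bts <- numeric(n)
  t0 <- 2
  tmpl <- exp(-0.5 * ((seq(0, 0.4, by = 1 / 500) - 0.2) / 0.06)^2)
  while (t0 * 500 < n - length(tmpl)) {
    i <- round(t0 * 500)
    bts[i:(i + length(tmpl) - 1)] <- bts[i:(i + length(tmpl) - 1)] + tmpl
    t0 <- t0 + runif(1, 1.2, 4)
  }
  amp <- 8 * stats::sd(base$data)
  dirty <- base
  dirty$data <- base$data + amp * (bpat %o% bts)
  cleaned <- ica_clean(dirty, seed = 3)
  removed <- attr(cleaned, "removed")
  expect_true("blink" %in% removed$class[removed$index])
  # blink-specific variance in frontal channels attenuated by >= 80%
  fr <- match(c("Fp1", "Fp2", "AFz"), base$labels)
  blink_var <- function(dat) {
    sum(vapply(fr, function(ch) stats::cov(dat[ch, ], bts)^2 / stats::var(bts),
               numeric(1)))
  }
  expect_gte(1 - blink_var(cleaned$data) / blink_var(dirty$data), 0.8)
  # artifact-free data: at most one component removed
  cl0 <- ica_clean(base, seed = 3)
  expect_lte(length(attr(cl0, "removed")$index), 1)
})

test_that("back-projection with no removed components is the identity", {
  set.seed(41)
  n <- 5000
  mix <- matrix(rnorm(16), 4, 4)
  src <- matrix(rnorm(4 * n)^3, 4, n)            # non-Gaussian sources
  X <- mix %*% src
  dec <- oreeg:::fastica_decompose(X, seed = 1)
  back <- dec$mixing %*% (dec$unmixing %*% (X - rowMeans(X))) + rowMeans(X)
  expect_equal(back, X, tolerance = 1e-8)
})

test_that("spherical interpolation reconstructs a smooth topography", {
  labels <- default_channels()
  mont <- standard_montage(labels)
  fc <- standard_montage("FCz")
  d2 <- (mont$x - fc$x)^2 + (mont$y - fc$y)^2 + (mont$z - fc$z)^2
  topo <- exp(-d2 / (2 * 70^2))
  set.seed(51)
  dat <- topo %o% rep(1, 100) + 0 * matrix(0, 24, 100)
  rec <- recording(dat, 500, labels, bads = "Fz")
  out <- interpolate_and_reref(rec)
  # undo the mastoid reference for the comparison
  ref <- colMeans(dat[match(c("M1", "M2"), labels), ])
  want <- topo[match("Fz", labels)] - ref[1]
  expect_equal(unname(out$data[match("Fz", labels), 1]), want,
               tolerance = 0.1 * abs(want))
  # mastoid mean is identically zero
  mm <- colMeans(out$data[match(c("M1", "M2"), labels), ])
  expect_true(all(abs(mm) < 1e-10))
})

test_that("re-referencing leaves mastoid-referenced data unchanged", {
  labels <- default_channels()
  set.seed(52)
  dat <- matrix(rnorm(24 * 200), 24, 200)
  mast <- match(c("M1", "M2"), labels)
  dat <- sweep(dat, 2, colMeans(dat[mast, ]))    # already mastoid-referenced
  rec <- recording(dat, 500, labels)
  out <- interpolate_and_reref(rec)
  expect_equal(out$data, dat, tolerance = 1e-10, ignore_attr = TRUE)
  # cap on bad channels
  rec$bads <- labels[1:6]
  expect_error(interpolate_and_reref(rec), "more than 5")
})

test_that("ICA cleanup raises the downstream evoked-response SNR", {
  cfg <- synth_config(n_participants = 1, n_blocks = 2,
                      blocks_per_condition = 1, block_duration_s = 120,
                      seed = 61)
  tr <- ground_truth(cfg)
  lets <- data.frame(onset_s = seq(2, 115, by = 3),
                     letter = rep(c("B", "C", "D", "F"), length.out = 38))
  dirty <- simulate_eeg(cfg, tr, features = list(), letter_events = lets,
                        snr_db = -22, blink = TRUE, seed = 12)
  dirty <- bandpass_fir(dirty)
  lm <- grepl("^letter", dirty$markers$label)
  dirty$markers[lm, ] <- correct_marker_delay(dirty$markers[lm, , drop = FALSE],
                                              dirty$fs, cfg$marker_delay_ms)
  # plain averaging isolates the ICA effect (epoch rejection, tested
  # elsewhere, would absorb part of the blink contamination by itself)
  erp_snr <- function(rec) {
    ep <- baseline_correct(epoch_letters(rec))
    avg <- average_block(ep)$average
    ch <- which.max(tr$spatial_patterns$erp)
    sel <- ep$times_ms >= 80 & ep$times_ms <= 120
    abs(min(avg[ch, sel])) / stats::sd(avg[ch, ep$times_ms < 0])
  }
  cleaned <- ica_clean(dirty, seed = 3)
  expect_gt(erp_snr(cleaned), erp_snr(dirty))
})
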