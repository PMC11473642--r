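test_that("window specifications match the response-dependent search grid", {
  expect_equal(window_spec("ERP", "N1")$search_ms, c(80, 150))
  expect_equal(window_spec("ERP", "P2")$search_ms, c(150, 250))
  expect_equal(window_spec("ERP", "N2")$search_ms, c(200, 300))
  expect_equal(window_spec("TRF_ons", "N1")$search_ms, c(80, 150))
  expect_equal(window_spec("TRF_env", "N1")$search_ms, c(50, 120))
  expect_equal(window_spec("TRF_env", "P2")$search_ms, c(120, 220))
  expect_equal(window_spec("TRF_env", "N2")$search_ms, c(220, 320))
  expect_equal(window_spec("ERP", "N1")$half_width_ms, 25)
  expect_equal(window_spec("ERP", "P2")$half_width_ms, 50)
  expect_equal(window_spec("ERP", "N1")$polarity, "neg")
  expect_equal(window_spec("ERP", "P2")$polarity, "pos")
  expect_equal(window_spec("ERP", "N2")$polarity, "neg")
})

test_that("peaks are found at the planted latency and channel", {
  labels <- default_channels()
  pat <- oreeg:::frontocentral_prior(labels)
  times <- seq(-200, 600, by = 2)
  resp <- planted_response(times, pat, center_ms = 100, amp = -1)
  pk <- find_peak(resp, times, window_spec("ERP", "N1"))
  expect_equal(pk$latency_ms, 100)
  expect_equal(pk$channel, which.max(pat))
  expect_false(pk$flagged)
  # flat response: flagged fallback
  pk2 <- find_peak(matrix(0, 24, length(times)), times, window_spec("ERP", "N1"))
  expect_true(pk2$flagged)
})

test_that("window covariances isolate a planted rank-1 source", {
  labels <- default_channels()[1:6]
  set.seed(91)
  a <- rnorm(6); a <- a / sqrt(sum(a^2))
  times <- seq(-200, 600, by = 2)
  src <- -exp(-0.5 * ((times - 100) / 15)^2)
  resp <- (a %o% src) + 0.01 * matrix(rnorm(6 * length(times)), 6)
  cv <- window_covariances(resp, times, 100, window_spec("ERP", "N1"))
  expect_true(isSymmetric(cv$S) && isSymmetric(cv$R))
  expect_gte(min(eigen(cv$S, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  e <- eigen(cv$S - cv$R, symmetric = TRUE)
  expect_gte(abs(cor(e$vectors[, 1], a)), 0.99)
})

test_that("white-noise window and baseline covariances converge", {
  set.seed(92)
  times <- seq(-200, 600, by = 0.1)             # dense: many samples
  resp <- matrix(rnorm(4 * length(times)), 4)
  cv <- window_covariances(resp, times, 115, window_spec("ERP", "N1"))
  # same statistics: Frobenius difference small relative to the norms
  rel <- sqrt(sum((cv$S - cv$R)^2)) / sqrt(sum(cv$R^2))
  expect_lt(rel, 0.25)
})

test_that("covariance cleaning removes exactly the planted outlier, jointly", {
  set.seed(93)
  base <- crossprod(matrix(rnorm(100 * 5), 100)) / 99
  S <- lapply(1:20, function(i) base + 0.01 * crossprod(matrix(rnorm(25), 5)) / 4)
  R <- lapply(1:20, function(i) base + 0.01 * crossprod(matrix(rnorm(25), 5)) / 4)
  S[[7]] <- S[[7]] * 100
  cl <- clean_and_average(S, R)
  expect_equal(cl$excluded, 7L)
  # identical covariances: nothing excluded, mean equals the input
  Sid <- lapply(1:5, function(i) base)
  cl2 <- clean_and_average(Sid, Sid)
  expect_equal(length(cl2$excluded), 0)
  expect_equal(cl2$S_bar, base)
  expect_error(clean_and_average(S[1:2], R[1:2]), "3 participants")
})

test_that("the identity pencil has unit eigenvalues", {
  f <- ged_decompose(diag(4), diag(4))
  expect_equal(f$evals, rep(1, 4), tolerance = 1e-10)
})

test_that("a rank-1 contrast is solved analytically", {
  set.seed(94)
  R <- crossprod(matrix(rnorm(60 * 3), 60)) / 59
  a <- c(1, -2, 0.5); a <- a / sqrt(sum(a^2))
  S <- R + 3 * tcrossprod(a)
  f <- ged_decompose(S, R, shrink = 0.01)
  expect_gte(abs(cor(f$W[, 1], solve(f$R_reg, a))), 0.999)
  expect_gte(abs(cor(f$A[, 1], a)), 0.99)
  # Rayleigh quotient of the top filter equals its eigenvalue
  w <- f$W[, 1]
  rq <- drop(crossprod(w, S %*% w) / crossprod(w, f$R_reg %*% w))
  expect_equal(rq, f$evals[1], tolerance = 1e-8)
})

test_that("GED matches brute-force Rayleigh maximization on toy pencils", {
  set.seed(95)
  for (i in 1:3) {
    R <- crossprod(matrix(rnorm(40 * 2), 40)) / 39
    S <- crossprod(matrix(rnorm(40 * 2), 40)) / 39
    f <- ged_decompose(S, R, shrink = 0.01)
    theta <- seq(0, pi, length.out = 50001)
    rq <- vapply(theta, function(t) {
      w <- c(cos(t), sin(t))
      drop(crossprod(w, S %*% w) / crossprod(w, f$R_reg %*% w))
    }, numeric(1))
    expect_equal(f$evals[1], max(rq), tolerance = 1e-6)
  }
  # 3-channel case against a coarse grid lower bound
  R <- crossprod(matrix(rnorm(50 * 3), 50)) / 49
  S <- crossprod(matrix(rnorm(50 * 3), 50)) / 49
  f <- ged_decompose(S, R, shrink = 0.01)
  best <- 0
  for (t1 in seq(0, pi, length.out = 101)) {
    for (t2 in seq(0, 2 * pi, length.out = 201)) {
      w <- c(sin(t1) * cos(t2), sin(t1) * sin(t2), cos(t1))
      best <- max(best, drop(crossprod(w, S %*% w) / crossprod(w, f$R_reg %*% w)))
    }
  }
  expect_gte(f$evals[1], best - 1e-3)
  expect_lte(best, f$evals[1] + 1e-8)
})

test_that("eigenvalues are invariant to channel permutation", {
  set.seed(96)
  R <- crossprod(matrix(rnorm(60 * 4), 60)) / 59
  S <- crossprod(matrix(rnorm(60 * 4), 60)) / 59
  f1 <- ged_decompose(S, R)
  p <- c(3, 1, 4, 2)
  f2 <- ged_decompose(S[p, p], R[p, p])
  expect_equal(f1$evals, f2$evals, tolerance = 1e-9)
})

test_that("component selection fixes the sign and ignores eigenvector sign", {
  labels <- default_channels()
  pat <- oreeg:::frontocentral_prior(labels)
  times <- seq(-200, 600, by = 2)
  resp <- planted_response(times, pat, center_ms = 100, amp = -1)
  spec <- window_spec("ERP", "N1")
  cv <- window_covariances(resp, times, 100, spec)
  f <- ged_decompose(cv$S + diag(1e-9, 24), cv$R + diag(1e-6, 24))
  sel1 <- select_component(f, spec, resp, times, c(75, 125), labels)
  fneg <- f; fneg$W <- -f$W; fneg$A <- -f$A
  sel2 <- select_component(fneg, spec, resp, times, c(75, 125), labels)
  w1 <- sel1$W[, sel1$chosen] * sel1$sign
  w2 <- sel2$W[, sel2$chosen] * sel2$sign
  expect_equal(w1, w2, tolerance = 1e-10)
  comp <- drop(crossprod(w1, resp))
  expect_lt(mean(comp[times >= 75 & times <= 125]), 0)  # N1 negativity
})

test_that("a selector filter reduces to the channel window mean, linearly", {
  labels <- default_channels()[1:5]
  times <- seq(-200, 600, by = 2)
  set.seed(97)
  responses <- lapply(1:3, function(b) matrix(rnorm(5 * length(times)), 5))
  f <- structure(list(W = diag(5), A = diag(5), chosen = 3L, sign = 1),
                 class = "ged_filter")
  amps <- component_amplitudes(f, responses, times, c(80, 120))
  sel <- times >= 80 & times <= 120
  expect_equal(amps, vapply(responses, function(r) mean(r[3, sel]), numeric(1)))
  # linearity in the data
  amps2 <- component_amplitudes(f, lapply(responses, `*`, 2.5), times, c(80, 120))
  expect_equal(amps2, 2.5 * amps, tolerance = 1e-12)
  expect_true(is.na(component_amplitudes(f, list(NULL), times, c(80, 120))))
})

test_that("the full pipeline recovers the planted topography", {
  labels <- default_channels()
  pat <- oreeg:::frontocentral_prior(labels)
  times <- seq(-200, 600, by = 2)
  set.seed(98)
  responses <- lapply(1:10, function(p)
    lapply(1:4, function(b) planted_response(times, pat, 100, amp = -1, snr_db = 0)))
  g <- ged_pipeline(responses, times, window_spec("ERP", "N1"), labels)
  expect_equal(g$filter$chosen, 1L)
  expect_gte(abs(cor(g$filter$A_chosen, pat)), 0.9)
  expect_equal(nrow(g$amplitudes), 40)
})

test_that("a second, stronger off-window source promotes component two", {
  labels <- default_channels()
  mont <- standard_montage(labels)
  # window source: fronto-central; distractor source: occipital, stronger,
  # present in window AND baseline (so it dominates variance but not the
  # window/baseline contrast once the true source is considered)
  pat1 <- oreeg:::frontocentral_prior(labels)
  oz <- standard_montage("O1")
  d2 <- (mont$x - oz$x)^2 + (mont$y - oz$y)^2 + (mont$z - oz$z)^2
  pat2 <- exp(-d2 / (2 * 40^2)); pat2 <- pat2 / sqrt(sum(pat2^2))
  times <- seq(-200, 600, by = 2)
  set.seed(99)
  src1 <- -exp(-0.5 * ((times - 100) / 20)^2)
  src2 <- 3 * sin(2 * pi * times / 24) * (times >= 50 & times <= 150)
  responses <- lapply(1:8, function(p) lapply(1:3, function(b) {
    r <- pat1 %o% src1 + pat2 %o% src2
    r + 0.02 * matrix(rnorm(length(r)), nrow(r))
  }))
  g <- ged_pipeline(responses, times, window_spec("ERP", "N1"), labels)
  # the plausibility check must not keep an occipital component when the
  # fronto-central one is available
  expect_gte(abs(cor(abs(g$filter$A_chosen), pat1)), 0.5)
})

test_that("per-block amplitudes recover a planted time-on-task slope sign", {
  labels <- default_channels()
  pat <- oreeg:::frontocentral_prior(labels)
  times <- seq(-200, 600, by = 2)
  spec <- window_spec("ERP", "N1")
  hits <- 0L
  n_blocks <- 12
  for (s in 1:100) {
    set.seed(3000 + s)
    responses <- lapply(1:6, function(p) lapply(1:n_blocks, function(b)
      planted_response(times, pat, 100, amp = -(1 - 0.02 * (b - 1)),
                       snr_db = -3)))
    g <- ged_pipeline(responses, times, spec, labels)
    sl <- stats::coef(stats::lm(amplitude ~ block, g$amplitudes))["block"]
    if (sl > 0) hits <- hits + 1L  # N1 shrinks toward zero: signed slope +
  }
  expect_gte(hits, 95)
})

test_that("a multiplicative demand effect survives to the amplitude ratio", {
  labels <- default_channels()
  pat <- oreeg:::frontocentral_prior(labels)
  times <- seq(-200, 600, by = 2)
  spec <- window_spec("ERP", "N1")
  set.seed(3101)
  conds <- rep(0:1, each = 4)
  responses <- lapply(1:8, function(p) lapply(seq_along(conds), function(b)
    planted_response(times, pat, 100,
                     amp = -1 * if (conds[b] == 1) 1.5 else 1,
                     snr_db = 10)))
  g <- ged_pipeline(responses, times, spec, labels)
  amp <- g$amplitudes
  amp$condition <- conds[amp$block]
  ratio <- mean(amp$amplitude[amp$condition == 1]) /
    mean(amp$amplitude[amp$condition == 0])
  expect_equal(ratio, 1.5, tolerance = 0.1)
})
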