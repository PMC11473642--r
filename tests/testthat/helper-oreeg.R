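# Shared fixtures and independent oracles, all built in code.

# Small study configuration used across tests.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_participants = 2, n_blocks = 4, blocks_per_condition = 2,
         block_duration_s = 30, audio_fs = 8000, seed = 123L),
    list(...))
  if (!("blocks_per_condition" %in% names(list(...))) &&
      "n_blocks" %in% names(list(...)))
    args$blocks_per_condition <- args$n_blocks / 2
  do.call(synth_config, args)
}

# N1-trough-plus-P2-peak lag kernel at a given rate (lags 0..max_ms).
test_kernel <- function(rate, max_ms = 450, n1_ms = 100, n1_amp = -1.5,
                        p2_ms = 200, p2_amp = 1) {
  t_ms <- seq(0, max_ms, by = 1000 / rate)
  n1_amp * exp(-0.5 * ((t_ms - n1_ms) / 20)^2) +
    p2_amp * exp(-0.5 * ((t_ms - p2_ms) / 30)^2)
}

# Independent dynamic-programming Levenshtein oracle (unit costs); the
# placeholder "X" in the response never matches.
dp_levenshtein <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  na <- length(a); nb <- length(b)
  D <- matrix(0L, na + 1, nb + 1)
  D[, 1] <- 0:na
  D[1, ] <- 0:nb
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      cost <- if (a[i] == b[j] && b[j] != "X") 0L else 1L
      D[i + 1, j + 1] <- min(D[i, j + 1] + 1L, D[i + 1, j] + 1L, D[i, j] + cost)
    }
  }
  D[na + 1, nb + 1]
}

# Independent enumeration oracle for the two-sided exact signed-rank p:
# iterates over sign assignments with a plain for-loop (no bit tricks).
enum_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  tot <- n * (n + 1) / 2
  v_obs <- sum(r[d > 0])
  w_obs <- min(v_obs, tot - v_obs)
  count <- 0L
  for (m in 0:(2^n - 1)) {
    v <- 0
    mm <- m
    for (i in seq_len(n)) {
      if (mm %% 2 == 1) v <- v + r[i]
      mm <- mm %/% 2
    }
    if (min(v, tot - v) <= w_obs) count <- count + 1L
  }
  count / 2^n
}

# Noise-free multichannel response with one planted Gaussian source.
planted_response <- function(times_ms, pattern, center_ms = 100, sd_ms = 20,
                             amp = -1, snr_db = Inf) {
  src <- amp * exp(-0.5 * ((times_ms - center_ms) / sd_ms)^2)
  resp <- pattern %o% src
  if (is.finite(snr_db)) {
    noise <- matrix(stats::rnorm(length(resp)), nrow(resp), ncol(resp))
    noise <- noise * sqrt(mean(resp^2)) / sqrt(mean(noise^2)) / 10^(snr_db / 20)
    resp <- resp + noise
  }
  resp
}
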