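#' Zero-phase FIR band limiting
#'
#' Applies Hamming-windowed FIR high-pass and low-pass filters sequentially,
#' with the conventional orders for 500 Hz data (3300 for the 0.5 Hz
#' high-pass, 220 for the 30 Hz low-pass; rescaled proportionally at other
#' rates). Each linear-phase filter is applied in a single pass with exact
#' group-delay compensation, so latencies do not shift and the signal length
#' is preserved.
#'
#' @param rec A [recording()].
#' @param hp_edge High-pass passband edge, Hz (default 0.5); NULL skips it.
#' @param lp_edge Low-pass passband edge, Hz (default 30); NULL skips it.
#' @param hp_order,lp_order Filter orders at 500 Hz; rescaled by `fs / 500`.
#' @return Filtered [recording()].
#' @export
bandpass_fir <- function(rec, hp_edge = 0.5, lp_edge = 30,
                         hp_order = 3300, lp_order = 220) {
  fs <- rec$fs
  nyq <- fs / 2
  scale <- fs / 500
  apply_fir <- function(data, h) {
    t(apply(data, 1, fft_conv_same, h = h))
  }
  if (!is.null(hp_edge)) {
    if (hp_edge >= nyq) stop("high-pass edge must be below Nyquist")
    ord <- even_order(hp_order * scale)
    # -6 dB cutoff halfway into the 0.5 Hz transition band below the edge
    cutoff <- hp_edge - 0.5 / 2
    h <- signal::fir1(ord, cutoff / nyq, type = "high")
    h <- h - mean(h)  # force exact null at DC
    rec$data <- apply_fir(rec$data, h)
    rec <- add_history(rec, sprintf("highpass_fir(%g Hz, order %d)", hp_edge, ord))
  }
  if (!is.null(lp_edge)) {
    if (lp_edge >= nyq) stop("low-pass edge must be below Nyquist")
    ord <- even_order(lp_order * scale)
    cutoff <- lp_edge + 7.5 / 2  # 7.5 Hz transition band
    h <- signal::fir1(ord, cutoff / nyq, type = "low")
    rec$data <- apply_fir(rec$data, h)
    rec <- add_history(rec, sprintf("lowpass_fir(%g Hz, order %d)", lp_edge, ord))
  }
  rec
}

even_order <- function(x) { x <- as.integer(round(x)); if (x %% 2 == 1) x + 1L else x }

#' Restrict a recording to the sound-presentation segments
#'
#' Cuts one segment per block spanning the interval between its
#' `sound_start` and `sound_stop` markers, with the first and last `trim_s`
#' seconds removed (screen-switch artifacts). Segments shorter than `min_s`
#' are dropped with a warning. Marker onsets are re-expressed relative to
#' each segment.
#'
#' @param rec A [recording()] whose markers contain paired
#'   `sound_start` / `sound_stop` events per block.
#' @param trim_s Seconds trimmed from each end (default 5).
#' @param min_s Minimum surviving segment length, seconds (default 10).
#' @return List of [recording()] segments, one per surviving block.
#' @export
restrict_to_sound <- function(rec, trim_s = 5, min_s = 10) {
  mk <- rec$markers
  blocks <- sort(unique(mk$block[mk$label %in% c("sound_start", "sound_stop")]))
  out <- list()
  for (b in blocks) {
    s <- mk$onset_sample[mk$label == "sound_start" & mk$block == b]
    e <- mk$onset_sample[mk$label == "sound_stop" & mk$block == b]
    if (length(s) != 1L || length(e) != 1L)
      stop("unpaired sound markers in block ", b)
    s2 <- s + round(trim_s * rec$fs)
    e2 <- e - round(trim_s * rec$fs)
    if ((e2 - s2 + 1) / rec$fs < min_s) {
      warning("block ", b, " shorter than ", min_s, " s after trimming; dropped")
      next
    }
    inside <- mk$onset_sample >= s2 & mk$onset_sample <= e2 &
      !(mk$label %in% c("sound_start", "sound_stop")) & mk$block == b
    seg_mk <- mk[inside, , drop = FALSE]
    seg_mk$onset_sample <- seg_mk$onset_sample - s2 + 1L
    rownames(seg_mk) <- NULL
    seg <- recording(rec$data[, s2:e2, drop = FALSE], rec$fs, rec$labels,
                     montage = rec$montage, markers = seg_mk, bads = rec$bads,
                     history = c(rec$history,
                                 sprintf("restrict_to_sound(block=%d)", b)))
    seg$block <- b
    seg$condition <- if (nrow(seg_mk)) seg_mk$condition[1] else
      mk$condition[mk$label == "sound_start" & mk$block == b][1]
    out[[as.character(b)]] <- seg
  }
  out
}

#' Iterative bad-channel rejection by neighbor reconstruction
#'
#' Over `iterations` randomized passes, each channel is reconstructed per
#' analysis window from a random subset of its nearest neighbors (by montage
#' distance, least-squares fit). A channel is flagged in a pass when its
#' correlation with the reconstruction falls below `criterion` in more than
#' `max_broken` of the windows. Channels flagged in at least `vote` of the
#' passes enter the bad list, capped at `max_remove` (worst first, ranked by
#' flag rate then mean correlation). The data are not modified; only `bads`
#' is updated.
#'
#' @param rec A [recording()] with montage.
#' @param criterion Minimum acceptable correlation (default 0.8).
#' @param max_broken Maximum tolerated fraction of sub-criterion windows
#'   (default 0.5).
#' @param iterations Number of randomized passes (default 10).
#' @param vote Fraction of passes required to reject (default 0.5).
#' @param max_remove Cap on removed channels (default 5).
#' @param window_s Analysis window, seconds (default 5).
#' @param n_neighbors Neighbor pool size; `sample_k` drawn per pass.
#' @param sample_k Neighbors used per reconstruction.
#' @param seed RNG seed for the randomized neighbor draws.
#' @return The [recording()] with `bads` updated.
#' @export
reject_bad_channels <- function(rec, criterion = 0.8, max_broken = 0.5,
                                iterations = 10, vote = 0.5, max_remove = 5,
                                window_s = 5, n_neighbors = 10, sample_k = 6,
                                seed = 1L) {
  if (is.null(rec$montage)) stop("montage required for bad-channel rejection")
  set.seed(seed)
  X <- rec$data
  nch <- nrow(X); n <- ncol(X)
  wlen <- max(10L, round(window_s * rec$fs))
  starts <- seq(1, n - wlen + 1, by = wlen)
  if (!length(starts)) starts <- 1L
  m <- rec$montage[match(rec$labels, rec$montage$label), ]
  D <- as.matrix(stats::dist(m[, c("x", "y", "z")]))
  votes <- matrix(0L, nch, iterations)
  mean_corr <- matrix(NA_real_, nch, iterations)
  for (it in seq_len(iterations)) {
    for (ci in seq_len(nch)) {
      pool <- order(D[ci, ])[-1][seq_len(min(n_neighbors, nch - 1))]
      nb <- sample(pool, min(sample_k, length(pool)))
      cors <- vapply(starts, function(s0) {
        idx <- s0:min(n, s0 + wlen - 1)
        y <- X[ci, idx]
        A <- t(X[nb, idx, drop = FALSE])
        fit <- tryCatch(suppressWarnings(stats::lsfit(A, y, intercept = TRUE)),
                        error = function(e) NULL)
        if (is.null(fit)) return(0)
        r <- safe_cor(y, y - fit$residuals)
        if (is.na(r)) 0 else r
      }, numeric(1))
      broken_frac <- mean(cors < criterion)
      votes[ci, it] <- as.integer(broken_frac > max_broken)
      mean_corr[ci, it] <- mean(cors)
    }
  }
  flag_rate <- rowMeans(votes)
  cand <- which(flag_rate >= vote)
  if (length(cand) > max_remove) {
    worst <- order(-flag_rate[cand], rowMeans(mean_corr)[cand])
    cand <- cand[worst[seq_len(max_remove)]]
  }
  rec$bads <- union(rec$bads, rec$labels[cand])
  add_history(rec, sprintf("reject_bad_channels(removed=%s)",
                           if (length(cand)) paste(rec$labels[cand], collapse = ",") else "none"))
}

#' Joint-probability epoch rejection
#'
#' Estimates an empirical amplitude density per channel (histogram, Scott's
#' rule) over all epochs, computes each epoch's joint negative
#' log-probability per channel (local measure) and summed over channels
#' (global measure), and rejects epochs exceeding `mean + sd_threshold * SD`
#' on either measure.
#'
#' @param epochs Array channels x time x epochs.
#' @param sd_threshold Rejection threshold in SD units (3 for ERP epochs,
#'   5 at the ICA stage).
#' @return Logical keep-mask of length `dim(epochs)[3]`.
#' @export
jointprob_reject <- function(epochs, sd_threshold) {
  stopifnot(length(dim(epochs)) == 3)
  ne <- dim(epochs)[3]
  if (ne < 10) stop("need at least 10 epochs for joint-probability rejection")
  nch <- dim(epochs)[1]
  nll <- matrix(0, nch, ne)
  for (c in seq_len(nch)) {
    v <- as.numeric(epochs[c, , ])
    s <- stats::sd(v)
    if (s < 1e-300) next  # degenerate channel: contributes nothing
    nbin <- max(10L, ceiling(diff(range(v)) / (3.49 * s * length(v)^(-1 / 3))))
    h <- graphics::hist(v, breaks = nbin, plot = FALSE)
    p <- h$density[pmax(1L, pmin(length(h$density),
                                 findInterval(v, h$breaks, all.inside = TRUE)))]
    p <- pmax(p, 1e-12)
    nll[c, ] <- colSums(matrix(-log(p), ncol = ne))
  }
  col_var <- apply(nll, 1, stats::sd)
  if (all(nll == 0) || (all(col_var == 0) && stats::sd(colSums(nll)) == 0)) {
    warning("epochs are identical (zero variance); no rejection performed")
    return(rep(TRUE, ne))
  }
  local_bad <- rep(FALSE, ne)
  for (c in seq_len(nch)) {
    mu <- mean(nll[c, ]); s <- stats::sd(nll[c, ])
    if (s > 0) local_bad <- local_bad | (nll[c, ] > mu + sd_threshold * s)
  }
  g <- colSums(nll)
  gs <- stats::sd(g)
  global_bad <- if (gs > 0) g > mean(g) + sd_threshold * gs else rep(FALSE, ne)
  !(local_bad | global_bad)
}

# FastICA (logcosh contrast, deflation mode) on channels x samples data.
# Components are extracted one at a time in order of non-Gaussianity, each
# orthogonalized against the previous ones in whitened space; strongly
# non-Gaussian sources (artifacts) converge first. Trailing components that
# span the Gaussian residual subspace have no identifiable rotation; they
# are accepted at their stable orientation unless a leading component fails,
# which raises an error with iteration diagnostics.
# Returns unmixing (comps x channels, applies to centered data) and mixing.
fastica_decompose <- function(X, n_comp = nrow(X), maxit = 300, tol = 1e-6,
                              seed = 1L) {
  set.seed(seed)
  mu <- rowMeans(X)
  Xc <- X - mu
  n <- ncol(Xc)
  C <- tcrossprod(Xc) / (n - 1)
  e <- eigen(C, symmetric = TRUE)
  keep <- utils::head(which(e$values > max(e$values) * 1e-10), n_comp)
  K <- diag(1 / sqrt(e$values[keep]), length(keep)) %*% t(e$vectors[, keep, drop = FALSE])
  Z <- K %*% Xc
  p <- nrow(Z)
  B <- matrix(0, p, 0)
  iters <- integer(p)
  converged <- logical(p)
  for (j in seq_len(p)) {
    w <- stats::rnorm(p)
    if (ncol(B)) w <- w - B %*% crossprod(B, w)
    w <- w / sqrt(sum(w^2))
    for (it in seq_len(maxit)) {
      wz <- drop(crossprod(w, Z))
      g <- tanh(wz)
      w1 <- drop(Z %*% g) / n - mean(1 - g^2) * w
      if (ncol(B)) w1 <- w1 - B %*% crossprod(B, w1)
      nrm <- sqrt(sum(w1^2))
      if (nrm < 1e-12) { w1 <- stats::rnorm(p); w1 <- w1 / sqrt(sum(w1^2)); next }
      w1 <- w1 / nrm
      delta <- abs(abs(sum(w1 * w)) - 1)
      w <- drop(w1)
      if (delta < tol) { converged[j] <- TRUE; break }
    }
    iters[j] <- it
    B <- cbind(B, w)
  }
  if (!any(converged))
    stop(sprintf("ICA did not converge: no component stabilized within %d iterations (per-component iterations: %s)",
                 maxit, paste(iters, collapse = ", ")))
  unmix <- t(B) %*% K                    # comps x channels
  mixing <- MASS_ginv(unmix)             # channels x comps
  list(unmixing = unmix, mixing = mixing, center = mu, n_iter = iters,
       converged = converged)
}

# Moore-Penrose pseudoinverse (SVD based).
MASS_ginv <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > max(s$d) * tol
  s$v[, pos, drop = FALSE] %*% diag(1 / s$d[pos], sum(pos)) %*% t(s$u[, pos, drop = FALSE])
}

# Power fraction of a time series below / above a frequency split.
power_fraction <- function(x, fs, f_lo = NULL, f_hi = NULL) {
  n <- length(x)
  P <- Mod(stats::fft(x - mean(x)))^2
  half <- seq_len(floor(n / 2))
  f <- (half - 1) * fs / n
  tot <- sum(P[half])
  if (tot == 0) return(0)
  if (!is.null(f_lo)) sum(P[half][f < f_lo]) / tot else sum(P[half][f > f_hi]) / tot
}

# Heuristic artifact classification of ICA components (replaces a trained
# classifier): blink = frontal-dominant topography + sub-2 Hz dominance;
# muscle = temporal/mastoid-edge topography + >20 Hz dominance; horizontal
# eye movement = opposed lateral-frontal dipole pair.
classify_components <- function(mixing, sources, labels, fs,
                                blink_lf_frac = 0.6, muscle_hf_frac = 0.5) {
  frontal <- intersect(c("Fp1", "Fp2", "AFz"), labels)
  edge <- intersect(c("M1", "M2", "T7", "T8", "F7", "F8", "P7", "P8"), labels)
  latf <- intersect(c("F7", "F8"), labels)
  out <- character(ncol(mixing))
  for (j in seq_len(ncol(mixing))) {
    a <- abs(mixing[, j]); a <- a / max(a)
    lf <- power_fraction(sources[j, ], fs, f_lo = 2)
    hf <- power_fraction(sources[j, ], fs, f_hi = 20)
    front_dom <- mean(a[match(frontal, labels)]) > 2 * mean(a)
    edge_dom <- mean(a[match(edge, labels)]) > 1.5 * mean(a)
    out[j] <- "brain"
    if (front_dom && lf > blink_lf_frac) out[j] <- "blink"
    else if (edge_dom && hf > muscle_hf_frac) out[j] <- "muscle"
    else if (length(latf) == 2) {
      v <- mixing[match(latf, labels), j]
      if (prod(sign(v)) < 0 && all(abs(v) > 0.7 * max(abs(mixing[, j]))))
        out[j] <- "heog"
    }
  }
  out
}

#' ICA-based artifact removal
#'
#' Fits ICA on a 1 Hz high-pass-filtered copy of the data, cut into
#' consecutive one-second epochs cleaned by [jointprob_reject()] at `sd`
#' standard deviations. Components classified as blink, muscle, or
#' horizontal-eye by topography/spectrum heuristics (plus any
#' `manual_remove` indices, e.g. mastoid-muscle components) are zeroed, and
#' the remaining components are back-projected onto the original,
#' unfiltered data.
#'
#' @param rec A [recording()] (already band-limited and restricted).
#' @param hp_for_ica High-pass edge for the ICA copy, Hz (default 1; FIR
#'   order 825 at 500 Hz).
#' @param epoch_s Epoch length for pre-ICA cleaning, seconds (default 1).
#' @param sd Joint-probability threshold at the ICA stage (default 5).
#' @param manual_remove Integer component indices to remove regardless of
#'   classification.
#' @param seed RNG seed for the ICA initialization.
#' @param min_samples_factor Minimum samples required, as a multiple of
#'   `n_channels^2` (stability heuristic, default 20).
#' @return The cleaned [recording()]; attributes `ica` (decomposition) and
#'   `removed` (indices and classes) are attached.
#' @export
ica_clean <- function(rec, hp_for_ica = 1, epoch_s = 1, sd = 5,
                      manual_remove = integer(), seed = 1L,
                      min_samples_factor = 20) {
  nch <- nrow(rec$data)
  if (ncol(rec$data) < min_samples_factor * nch^2)
    stop("too few samples for a stable ICA decomposition")
  copy <- rec
  ord <- even_order(825 * rec$fs / 500)
  h <- signal::fir1(ord, (hp_for_ica - 0.5) / (rec$fs / 2), type = "high")
  copy$data <- t(apply(copy$data, 1, fft_conv_same, h = h))
  elen <- round(epoch_s * rec$fs)
  ne <- floor(ncol(copy$data) / elen)
  ep <- array(copy$data[, seq_len(ne * elen)], dim = c(nch, elen, ne))
  mask <- jointprob_reject(ep, sd)
  train <- matrix(ep[, , mask], nrow = nch)
  dec <- fastica_decompose(train, seed = seed)
  src_orig <- dec$unmixing %*% (rec$data - rowMeans(rec$data))
  classes <- classify_components(dec$mixing, src_orig, rec$labels, rec$fs)
  remove <- union(which(classes != "brain"), manual_remove)
  keep <- setdiff(seq_len(nrow(src_orig)), remove)
  cleaned <- dec$mixing[, keep, drop = FALSE] %*% src_orig[keep, , drop = FALSE] +
    rowMeans(rec$data)
  rec$data <- cleaned
  rec <- add_history(rec, sprintf("ica_clean(removed=%s)",
                                  if (length(remove)) paste0(remove, ":", classes[remove], collapse = ",")
                                  else "none"))
  attr(rec, "ica") <- dec
  attr(rec, "removed") <- list(index = remove, class = classes)
  rec
}

# Spherical-spline interpolation matrix (Perrin-style, stiffness m = 4):
# rows = target electrodes, columns = source (good) electrodes.
spherical_spline_matrix <- function(good_xyz, bad_xyz, m = 4, terms = 30) {
  unit <- function(P) P / sqrt(rowSums(P^2))
  G <- unit(as.matrix(good_xyz)); B <- unit(as.matrix(bad_xyz))
  legendre_g <- function(cosang) {
    # sum_{l=1}^{terms} (2l+1) / (l (l+1))^m * P_l(x) / (4 pi)
    x <- cosang
    Pl_prev <- rep(1, length(x)); Pl <- x
    acc <- (2 * 1 + 1) / (1 * 2)^m * Pl
    for (l in 2:terms) {
      Pl_next <- ((2 * l - 1) * x * Pl - (l - 1) * Pl_prev) / l
      acc <- acc + (2 * l + 1) / (l * (l + 1))^m * Pl_next
      Pl_prev <- Pl; Pl <- Pl_next
    }
    acc / (4 * pi)
  }
  ng <- nrow(G)
  Ggg <- matrix(legendre_g(pmin(1, pmax(-1, tcrossprod(G)))), ng, ng)
  Gbg <- matrix(legendre_g(pmin(1, pmax(-1, B %*% t(G)))), nrow(B), ng)
  A <- rbind(cbind(Ggg, 1), c(rep(1, ng), 0))
  Ainv <- solve(A)
  # value at bad = [Gbg 1] %*% Ainv %*% [z; 0]
  cbind(Gbg, 1) %*% Ainv[, seq_len(ng), drop = FALSE]
}

#' Interpolate rejected channels and re-reference to linked mastoids
#'
#' Bad channels are reconstructed by spherical-spline interpolation from the
#' good channels, then every channel is re-referenced to the mean of M1 and
#' M2 (which is identically zero afterwards, by construction).
#'
#' @param rec A [recording()] with `bads` set (at most 5).
#' @return Interpolated, mastoid-referenced [recording()] with empty `bads`.
#' @export
interpolate_and_reref <- function(rec) {
  if (length(rec$bads) > 5)
    stop("more than 5 bad channels; upstream cap violated")
  if (!all(c("M1", "M2") %in% rec$labels))
    stop("mastoid channels M1/M2 required for re-referencing")
  if (length(rec$bads)) {
    if (!all(rec$bads %in% rec$labels)) stop("bads must be a subset of labels")
    m <- rec$montage[match(rec$labels, rec$montage$label), ]
    bad_i <- match(rec$bads, rec$labels)
    good_i <- setdiff(seq_along(rec$labels), bad_i)
    W <- spherical_spline_matrix(m[good_i, c("x", "y", "z")],
                                 m[bad_i, c("x", "y", "z")])
    rec$data[bad_i, ] <- W %*% rec$data[good_i, , drop = FALSE]
    rec <- add_history(rec, sprintf("interpolate(%s)", paste(rec$bads, collapse = ",")))
    rec$bads <- character()
  }
  ref <- colMeans(rec$data[match(c("M1", "M2"), rec$labels), , drop = FALSE])
  rec$data <- sweep(rec$data, 2, ref)
  add_history(rec, "reref_linked_mastoids")
}
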