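#' Scale EEG data prior to TRF estimation
#'
#' Elementwise multiplication by a constant scaling factor (default 0.0313,
#' the conventional scaling for microvolt EEG in forward-model estimation);
#' recorded in the history.
#'
#' @param rec A [recording()].
#' @param factor Scale factor.
#' @return Scaled [recording()].
#' @export
scale_eeg <- function(rec, factor = 0.0313) {
  rec$data <- rec$data * factor
  add_history(rec, sprintf("scale_eeg(%g)", factor))
}

#' Decimate a recording to the common analysis rate
#'
#' Keeps every `q`-th sample (apply a low-pass, e.g. [bandpass_fir()] at
#' 30 Hz, first). Marker onsets are converted to the new rate.
#'
#' @param rec A [recording()].
#' @param q Integer decimation factor.
#' @return Decimated [recording()].
#' @export
decimate_recording <- function(rec, q) {
  q <- as.integer(q)
  idx <- seq(1, ncol(rec$data), by = q)
  rec$data <- rec$data[, idx, drop = FALSE]
  if (nrow(rec$markers))
    rec$markers$onset_sample <- pmax(1L, as.integer(ceiling(rec$markers$onset_sample / q)))
  rec$fs <- rec$fs / q
  add_history(rec, sprintf("decimate(%d)", q))
}

#' Build the time-lag design matrix
#'
#' Column `k` holds the stimulus feature delayed by the `k`-th lag of the
#' sample grid spanning `lag_min_ms` to `lag_max_ms` (both endpoints
#' included); out-of-range samples are zero-filled. Positive lags mean the
#' EEG at time `t` is predicted from the stimulus at `t - lag`.
#'
#' @param feature A [stimulus_feature()] or numeric vector.
#' @param lag_min_ms,lag_max_ms Lag range, ms.
#' @param rate Common analysis rate, Hz (taken from the feature if absent).
#' @return Matrix samples x n_lags with attributes `lags_samples`,
#'   `lags_ms`, `rate`.
#' @export
build_lagged <- function(feature, lag_min_ms, lag_max_ms, rate = NULL) {
  if (inherits(feature, "stimulus_feature")) {
    if (is.null(rate)) rate <- feature$rate
    feature <- feature$values
  }
  if (is.null(rate)) stop("rate required for bare numeric features")
  if (lag_min_ms > lag_max_ms) stop("lag_min_ms must not exceed lag_max_ms")
  lags <- seq(ms_to_samples(lag_min_ms, rate), ms_to_samples(lag_max_ms, rate))
  n <- length(feature)
  X <- matrix(0, n, length(lags))
  for (j in seq_along(lags)) {
    L <- lags[j]
    if (L >= 0) {
      if (L < n) X[(L + 1):n, j] <- feature[seq_len(n - L)]
    } else {
      if (-L < n) X[seq_len(n + L), j] <- feature[(-L + 1):n]
    }
  }
  attr(X, "lags_samples") <- lags
  attr(X, "lags_ms") <- lags / rate * 1000
  attr(X, "rate") <- rate
  X
}

#' Ridge-regression TRF fit
#'
#' Solves `W = (X'X + lambda * mean(diag(X'X)) * I)^-1 X'Y` on mean-centered
#' `X` and `Y` (the intercept is carried separately). Normalizing the
#' penalty by the mean diagonal of `X'X` makes the lambda grid dimensionless
#' with respect to the feature scale.
#'
#' @param X Lagged design from [build_lagged()].
#' @param Y EEG matrix, samples x channels.
#' @param lambda Shrinkage parameter (>= 0).
#' @return Object of class `trf_model`: `weights` (lags x channels),
#'   `bias`, `lambda`, `lags_ms`, `rate`.
#' @export
ridge_fit <- function(X, Y, lambda) {
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  XtX <- crossprod(Xc)
  mbar <- mean(diag(XtX))
  A <- XtX + diag(lambda * mbar, ncol(X))
  W <- tryCatch(solve(A, crossprod(Xc, Yc)), error = function(e)
    stop("singular system; use lambda > 0 for collinear designs"))
  structure(list(weights = W, bias = my - drop(mx %*% W),
                 lambda = lambda, lags_ms = attr(X, "lags_ms"),
                 lags_samples = attr(X, "lags_samples"),
                 rate = attr(X, "rate"), mx = mx),
            class = "trf_model")
}

#' @export
print.trf_model <- function(x, ...) {
  cat(sprintf("<trf_model> %d lags (%g..%g ms) x %d channels, lambda=%g\n",
              nrow(x$weights), min(x$lags_ms), max(x$lags_ms),
              ncol(x$weights), x$lambda))
  invisible(x)
}

#' Predict EEG from a fitted TRF
#' @param object A `trf_model`.
#' @param X Lagged design with the model's lags.
#' @param ... Unused.
#' @return Predicted samples x channels matrix.
#' @export
predict.trf_model <- function(object, X, ...) {
  if (ncol(X) != nrow(object$weights)) stop("design lags do not match the model")
  sweep(X %*% object$weights, 2, object$bias, "+")
}

#' Prediction accuracy of a TRF on held-out data
#'
#' Pearson correlation between predicted and observed EEG, per channel;
#' zero-variance channels are skipped (NA) and counted.
#'
#' @param model A `trf_model`.
#' @param X Lagged design of the test data (same lags).
#' @param Y Observed EEG, samples x channels.
#' @return Numeric vector of per-channel r.
#' @export
predict_accuracy <- function(model, X, Y) {
  Yhat <- predict(model, X)
  vapply(seq_len(ncol(Y)), function(c) safe_cor(Yhat[, c], Y[, c]), numeric(1))
}

#' Partition blocks into contiguous cross-validation segments
#'
#' `n_blocks` successive blocks are split into `k` contiguous segments of
#' two to three blocks (for 28 blocks and k = 10: eight segments of 3 and
#' two of 2, remainder assigned to the earliest segments).
#'
#' @param n_blocks Total block count.
#' @param k Number of segments.
#' @return List of integer vectors of block indices.
#' @export
partition_segments <- function(n_blocks, k = 10) {
  if (n_blocks < k) stop("need at least k blocks")
  base <- n_blocks %/% k
  rem <- n_blocks %% k
  sizes <- c(rep(base + 1, rem), rep(base, k - rem))
  ends <- cumsum(sizes)
  mapply(function(e, s) (e - s + 1):e, ends, sizes, SIMPLIFY = FALSE)
}

# Per-block sufficient statistics for centered ridge solves and for
# correlation-based evaluation without materializing predictions.
block_stats <- function(X, Y) {
  list(n = nrow(X), sx = colSums(X), sy = colSums(Y),
       Sxx = crossprod(X), Sxy = crossprod(X, Y), syy = colSums(Y^2))
}

combine_stats <- function(stats_list) {
  out <- stats_list[[1]]
  for (s in stats_list[-1]) {
    out$n <- out$n + s$n; out$sx <- out$sx + s$sx; out$sy <- out$sy + s$sy
    out$Sxx <- out$Sxx + s$Sxx; out$Sxy <- out$Sxy + s$Sxy
    out$syy <- out$syy + s$syy
  }
  out
}

# Per-channel Pearson r between X %*% W and Y on a test block, computed
# from the block's sufficient statistics (Pearson r is invariant to the
# model's constant offset, so only covariances are needed).
stats_pred_r <- function(st, W) {
  mx <- st$sx / st$n; my <- st$sy / st$n
  Sxy_c <- st$Sxy - outer(mx, my) * st$n
  Sxx_c <- st$Sxx - st$n * tcrossprod(mx)
  syy_c <- st$syy - st$n * my^2
  num <- colSums(W * Sxy_c)              # cov(Xw_c, y_c) * (n-1)
  varh <- colSums(W * (Sxx_c %*% W))     # var(Xw_c) * (n-1)
  r <- num / sqrt(pmax(varh, 1e-300) * pmax(syy_c, 1e-300))
  r[varh <= 1e-12 | syy_c <= 1e-12] <- NA_real_
  r
}

# Centered ridge solution path over a lambda grid from pooled stats,
# via one eigendecomposition. Returns list(per lambda: list(W, bias)).
ridge_path <- function(st, grid) {
  mx <- st$sx / st$n; my <- st$sy / st$n
  Sxx_c <- st$Sxx - st$n * tcrossprod(mx)
  Sxy_c <- st$Sxy - outer(mx, my) * st$n
  mbar <- mean(diag(Sxx_c))
  e <- eigen(Sxx_c, symmetric = TRUE)
  VtS <- crossprod(e$vectors, Sxy_c)
  lapply(grid, function(lam) {
    W <- e$vectors %*% (VtS / (pmax(e$values, 0) + lam * mbar))
    list(W = W, bias = my - drop(mx %*% W), mx = mx)
  })
}

#' Segment-wise cross-validation of the TRF shrinkage parameter
#'
#' Blocks are partitioned into `k` contiguous segments; each segment is held
#' out once. For each outer fold, lambda is selected on the training
#' segments alone (inner leave-one-segment-out, correlation averaged over
#' folds and channels), the model is trained on all training segments at
#' that lambda, and the held-out segment is predicted. This yields per-fold
#' held-out correlations (averaged into one prediction value per
#' participant), the per-fold selected lambdas, and their mode (ties broken
#' toward the larger lambda) for subsequent per-block models.
#'
#' @param blocks List of blocks, each `list(feature, eeg)` with `eeg` a
#'   samples x channels matrix at the analysis rate.
#' @param grid Lambda grid (default `10^(-8..8)`).
#' @param lag_min_ms,lag_max_ms Lag range (defaults 0-450 ms).
#' @param k Number of segments (default 10).
#' @return Object of class `trf_cv`: `lambda_modal`, `lambda_per_fold`,
#'   `pred_r` (overall prediction value), `fold_r` (per fold),
#'   `channel_r` (per channel), `grid`, `segments`.
#' @export
crossval_lambda <- function(blocks, grid = 10^seq(-8, 8),
                            lag_min_ms = 0, lag_max_ms = 450, k = 10) {
  if (!length(grid)) stop("lambda grid is empty")
  nb <- length(blocks)
  k <- min(k, nb)  # fewer blocks than segments: one block per segment
  segs <- partition_segments(nb, k)
  rate <- if (inherits(blocks[[1]]$feature, "stimulus_feature"))
    blocks[[1]]$feature$rate else attr(blocks[[1]], "rate")
  st <- lapply(blocks, function(b) {
    X <- build_lagged(b$feature, lag_min_ms, lag_max_ms, rate)
    block_stats(X, as.matrix(b$eeg))
  })
  seg_st <- lapply(segs, function(ix) combine_stats(st[ix]))
  nch <- length(st[[1]]$sy)
  lambda_per_fold <- numeric(k)
  fold_r <- numeric(k)
  channel_r <- matrix(NA_real_, k, nch)
  for (f in seq_len(k)) {
    train_segs <- setdiff(seq_len(k), f)
    # inner CV across training segments to pick lambda
    inner_r <- matrix(NA_real_, length(train_segs), length(grid))
    for (ii in seq_along(train_segs)) {
      g <- train_segs[ii]
      fit_st <- combine_stats(seg_st[setdiff(train_segs, g)])
      path <- ridge_path(fit_st, grid)
      inner_r[ii, ] <- vapply(path, function(m) {
        mean(vapply(segs[[g]], function(b)
          mean(stats_pred_r(st[[b]], m$W), na.rm = TRUE), numeric(1)))
      }, numeric(1))
    }
    mean_r <- colMeans(inner_r)
    li <- which.max(mean_r)
    lambda_per_fold[f] <- grid[li]
    # train on all training segments at the selected lambda, test held-out
    full_st <- combine_stats(seg_st[train_segs])
    m <- ridge_path(full_st, grid[li])[[1]]
    ch <- t(vapply(segs[[f]], function(b) stats_pred_r(st[[b]], m$W),
                   numeric(nch)))
    channel_r[f, ] <- colMeans(ch, na.rm = TRUE)
    fold_r[f] <- mean(ch, na.rm = TRUE)
  }
  tab <- table(lambda_per_fold)
  modal_candidates <- as.numeric(names(tab)[tab == max(tab)])
  structure(list(lambda_modal = max(modal_candidates),
                 lambda_per_fold = lambda_per_fold,
                 pred_r = mean(fold_r), fold_r = fold_r,
                 channel_r = channel_r, grid = grid, segments = segs,
                 lag_min_ms = lag_min_ms, lag_max_ms = lag_max_ms),
            class = "trf_cv")
}

#' @export
print.trf_cv <- function(x, ...) {
  cat(sprintf("<trf_cv> %d folds, modal lambda %g, prediction r %.4f\n",
              length(x$fold_r), x$lambda_modal, x$pred_r))
  invisible(x)
}

#' Per-block TRF models at the modal lambda, z-scored per participant
#'
#' Fits one forward model per block over an extended lag range (default
#' -220 to 500 ms) at the participant's modal cross-validation lambda, then
#' z-scores the weights jointly across time points, channels, and blocks
#' within the participant (so amplitudes are comparable across participants
#' in later statistics).
#'
#' @param blocks List of blocks (`list(feature, eeg)`).
#' @param cv A `trf_cv` from [crossval_lambda()] (supplies the modal
#'   lambda); or pass `lambda` directly.
#' @param lag_min_ms,lag_max_ms Lag range (defaults -220 and 500 ms).
#' @param lambda Optional explicit lambda overriding `cv`.
#' @param zscore Standardize weights across (lag, channel, block)
#'   (default TRUE).
#' @return List of `trf_model`s (one per block) with `zscored` flag.
#' @export
per_block_trf <- function(blocks, cv = NULL, lag_min_ms = -220,
                          lag_max_ms = 500, lambda = NULL, zscore = TRUE) {
  if (is.null(lambda)) {
    if (is.null(cv)) stop("no cross-validation record: supply `cv` or `lambda`")
    lambda <- cv$lambda_modal
  }
  models <- lapply(blocks, function(b) {
    X <- build_lagged(b$feature, lag_min_ms, lag_max_ms)
    ridge_fit(X, b$eeg, lambda)
  })
  if (zscore) {
    all_w <- unlist(lapply(models, function(m) m$weights))
    mu <- mean(all_w); s <- stats::sd(all_w)
    if (s == 0) s <- 1
    models <- lapply(models, function(m) {
      m$weights <- (m$weights - mu) / s
      m$zscored <- TRUE
      m
    })
  }
  models
}

#' Compare prediction accuracies across acoustic features
#'
#' Pairwise Wilcoxon signed-rank tests between the per-participant
#' prediction values of the three features, with a Bonferroni-corrected
#' alpha of 0.05 / number of pairs.
#'
#' @param pred Data frame or matrix, participants x feature kinds (named
#'   columns).
#' @return data.frame with one row per pair: `a`, `b`, `W`, `p`,
#'   `alpha_bonferroni`, `significant`.
#' @export
compare_features <- function(pred) {
  pred <- as.data.frame(pred)
  kinds <- colnames(pred)
  pairs <- utils::combn(kinds, 2, simplify = FALSE)
  alpha <- as.numeric(bonferroni_alpha(0.05, length(pairs)))
  out <- do.call(rbind, lapply(pairs, function(pr) {
    wt <- wilcoxon_signed_rank(pred[[pr[1]]], pred[[pr[2]]])
    data.frame(a = pr[1], b = pr[2], W = wt$W, p = wt$p,
               alpha_bonferroni = alpha,
               significant = !is.na(wt$p) && wt$p < alpha,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
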