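#' Window specification for a response component
#'
#' Fixes the peak-search window, the half-width of the amplitude window
#' around the found peak, and the expected polarity for each combination of
#' response type (evoked ERP, envelope-TRF, onset-TRF) and deflection
#' (N1/P2/N2). The envelope TRF peaks earlier, so its search windows are
#' shifted: ERP and onset-TRF use N1 80-150, P2 150-250, N2 200-300 ms;
#' envelope-TRF uses N1 50-120, P2 120-220, N2 220-320 ms. Half-widths are
#' +/-25 ms (N1) and +/-50 ms (P2/N2); polarity is negative for N1/N2 and
#' positive for P2.
#'
#' @param response One of `"ERP"`, `"TRF_env"`, `"TRF_ons"`.
#' @param component One of `"N1"`, `"P2"`, `"N2"`.
#' @return Object of class `window_spec`.
#' @export
window_spec <- function(response = c("ERP", "TRF_env", "TRF_ons"),
                        component = c("N1", "P2", "N2")) {
  response <- match.arg(response)
  component <- match.arg(component)
  windows <- list(
    default = list(N1 = c(80, 150), P2 = c(150, 250), N2 = c(200, 300)),
    TRF_env = list(N1 = c(50, 120), P2 = c(120, 220), N2 = c(220, 320))
  )
  w <- if (response == "TRF_env") windows$TRF_env[[component]]
       else windows$default[[component]]
  structure(list(
    response = response, component = component,
    search_ms = w,
    half_width_ms = if (component == "N1") 25 else 50,
    polarity = if (component == "P2") "pos" else "neg"
  ), class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> %s %s: search %g-%g ms, +/-%g ms, %s\n",
              x$response, x$component, x$search_ms[1], x$search_ms[2],
              x$half_width_ms, x$polarity))
  invisible(x)
}

#' Find the component peak of a participant-mean response
#'
#' Locates the polarity-consistent extremum inside the search window of the
#' given [window_spec()] across channels, and the channel carrying the
#' largest same-polarity amplitude at that latency. If no sample of the
#' right polarity exists, the absolute-amplitude extremum is used and the
#' result flagged.
#'
#' @param response Channels x time matrix (participant mean over blocks).
#' @param times_ms Time axis, ms.
#' @param spec A [window_spec()].
#' @return List: `latency_ms`, `channel` (index), `amplitude`, `flagged`.
#' @export
find_peak <- function(response, times_ms, spec) {
  sel <- which(times_ms >= spec$search_ms[1] & times_ms <= spec$search_ms[2])
  win <- response[, sel, drop = FALSE]
  sgn <- if (spec$polarity == "neg") -1 else 1
  v <- sgn * win
  flagged <- FALSE
  if (max(v) <= 0) {  # no polarity-consistent extremum
    flagged <- TRUE
    v <- abs(win)
  }
  idx <- which(v == max(v), arr.ind = TRUE)[1, ]
  list(latency_ms = times_ms[sel[idx["col"]]],
       channel = unname(idx["row"]),
       amplitude = response[idx["row"], sel[idx["col"]]],
       flagged = flagged)
}

#' Signal and reference covariance of one participant's response
#'
#' The signal covariance S is computed from the mean-centered samples inside
#' the peak window (peak +/- half width); the reference covariance R from
#' the mean-centered baseline samples. Windows truncated by the epoch edge
#' are shrunk symmetrically.
#'
#' @param response Channels x time matrix.
#' @param times_ms Time axis, ms.
#' @param peak_ms Peak latency for this participant (from [find_peak()]).
#' @param spec A [window_spec()].
#' @param baseline_ms Baseline window (default c(-200, 0)).
#' @return List `S`, `R` (channel x channel), `window_ms` actually used.
#' @export
window_covariances <- function(response, times_ms, peak_ms, spec,
                               baseline_ms = c(-200, 0)) {
  hw <- spec$half_width_ms
  lo <- peak_ms - hw; hi <- peak_ms + hw
  if (lo < min(times_ms) || hi > max(times_ms)) {
    shrink <- max(min(times_ms) - lo, hi - max(times_ms))
    lo <- lo + shrink; hi <- hi - shrink
    message(sprintf("peak window truncated; shrunk symmetrically to %g-%g ms", lo, hi))
  }
  cov_of <- function(sel) {
    Xw <- response[, sel, drop = FALSE]
    Xw <- Xw - rowMeans(Xw)
    tcrossprod(Xw) / (ncol(Xw) - 1)
  }
  list(S = cov_of(times_ms >= lo & times_ms <= hi),
       R = cov_of(times_ms >= baseline_ms[1] & times_ms <= baseline_ms[2]),
       window_ms = c(lo, hi))
}

#' Outlier-cleaned grand-average covariances
#'
#' Computes the grand mean of the per-participant S and R matrices, the
#' Frobenius (matrix Euclidean) distance of each participant's matrices to
#' the means, removes participants deviating by more than `sd` standard
#' deviations on either matrix (joint exclusion), and recomputes the means
#' once over the remainder.
#'
#' @param S_list,R_list Lists of channel x channel covariance matrices.
#' @param sd Outlier threshold in SD units (default 3).
#' @return List: `S_bar`, `R_bar`, `excluded` (participant indices).
#' @export
clean_and_average <- function(S_list, R_list, sd = 3) {
  np <- length(S_list)
  if (np < 3) stop("need at least 3 participants")
  mean_mat <- function(lst) Reduce(`+`, lst) / length(lst)
  S_bar <- mean_mat(S_list); R_bar <- mean_mat(R_list)
  dist_to <- function(lst, M) vapply(lst, function(X) sqrt(sum((X - M)^2)), numeric(1))
  dS <- dist_to(S_list, S_bar); dR <- dist_to(R_list, R_bar)
  out_of <- function(d) if (stats::sd(d) == 0) rep(FALSE, length(d))
                        else d > mean(d) + sd * stats::sd(d)
  excluded <- which(out_of(dS) | out_of(dR))
  keep <- setdiff(seq_len(np), excluded)
  if (!length(keep)) stop("all participants excluded by covariance cleaning")
  list(S_bar = mean_mat(S_list[keep]), R_bar = mean_mat(R_list[keep]),
       excluded = excluded)
}

#' Generalized eigenvalue decomposition of the cleaned covariance pair
#'
#' Shrinks the reference matrix toward a scaled identity
#' (`R_reg = (1 - shrink) R + shrink * mean(eig(R)) * I`), then solves the
#' symmetric-definite pencil `S w = mu R_reg w` via a Cholesky whitening of
#' `R_reg`, giving real eigenvalues sorted in descending order. Each
#' component's forward-model topography is `A_j = S w_j`, normalized to
#' unit maximum absolute value.
#'
#' @param S_bar,R_bar Cleaned mean covariance matrices.
#' @param shrink Shrinkage parameter (default 0.01).
#' @return Object of class `ged_filter`: `evals`, `W` (filters in columns),
#'   `A` (topographies in columns), `S_bar`, `R_reg`.
#' @export
ged_decompose <- function(S_bar, R_bar, shrink = 0.01) {
  if (!isTRUE(all.equal(dim(S_bar), dim(R_bar))))
    stop("S and R must have the same size")
  S_bar <- (S_bar + t(S_bar)) / 2
  R_bar <- (R_bar + t(R_bar)) / 2
  gamma <- mean(eigen(R_bar, symmetric = TRUE, only.values = TRUE)$values)
  R_reg <- (1 - shrink) * R_bar + shrink * gamma * diag(nrow(R_bar))
  L <- t(chol(R_reg))                      # R_reg = L L'
  M <- forwardsolve(L, t(forwardsolve(L, S_bar)))
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  W <- backsolve(t(L), e$vectors)          # w = L'^-1 u
  A <- S_bar %*% W
  A <- sweep(A, 2, apply(abs(A), 2, max), "/")
  structure(list(evals = e$values, W = W, A = A,
                 S_bar = S_bar, R_reg = R_reg, shrink = shrink,
                 chosen = 1L, sign = 1),
            class = "ged_filter")
}

#' @export
print.ged_filter <- function(x, ...) {
  cat(sprintf("<ged_filter> %d components, top eigenvalues: %s; chosen #%d (sign %+d)\n",
              length(x$evals),
              paste(sprintf("%.3g", utils::head(x$evals, 3)), collapse = ", "),
              x$chosen, x$sign))
  invisible(x)
}

# Smooth fronto-central prior topography used by the plausibility check.
frontocentral_prior <- function(labels) {
  mont <- standard_montage(labels)
  fc <- standard_montage("FCz")
  d2 <- (mont$x - fc$x)^2 + (mont$y - fc$y)^2 + (mont$z - fc$z)^2
  p <- exp(-d2 / (2 * 60^2))
  p / sqrt(sum(p^2))
}

#' Select and sign the physiologically plausible component
#'
#' The component with the largest eigenvalue is used by default. An
#' automatic plausibility score (correlation of the absolute forward
#' topography with a smooth fronto-central prior, and polarity consistency
#' of the window mean after sign fixing) can promote the second component
#' when the first fails both checks. The filter sign is set so that the
#' component's mean over the peak window matches the spec polarity
#' (negative for N1/N2, positive for P2).
#'
#' @param filter A `ged_filter`.
#' @param spec A [window_spec()].
#' @param grand_response Channels x time grand-mean response.
#' @param times_ms Time axis.
#' @param window_ms Peak window (2-vector) used for the polarity check.
#' @param labels Channel labels (for the spatial prior).
#' @param topo_threshold Minimum prior correlation to count as plausible.
#' @param override Optional explicit component index.
#' @return The filter with `chosen`, `sign`, and `flagged` set.
#' @export
select_component <- function(filter, spec, grand_response, times_ms,
                             window_ms, labels, topo_threshold = 0.5,
                             override = NULL) {
  check <- function(j) {
    topo_ok <- {
      r <- safe_cor(abs(filter$A[, j]), frontocentral_prior(labels))
      !is.na(r) && r >= topo_threshold
    }
    comp <- drop(crossprod(filter$W[, j], grand_response))
    win <- comp[times_ms >= window_ms[1] & times_ms <= window_ms[2]]
    bl <- comp[times_ms < 0]
    wm <- mean(win)
    # a plausible component shows a sustained deflection: its window mean
    # stands out against both the window's own fluctuation (ruling out
    # zero-mean oscillations) and the baseline fluctuation
    resp_ok <- is.finite(wm) && abs(wm) > stats::sd(win) &&
      abs(wm) > stats::sd(bl)
    c(topo_ok = topo_ok, resp_ok = resp_ok)
  }
  filter$flagged <- FALSE
  if (!is.null(override)) {
    filter$chosen <- as.integer(override)
  } else {
    c1 <- check(1)
    if (!any(c1) && ncol(filter$W) >= 2 && any(check(2))) {
      filter$chosen <- 2L
    } else {
      filter$chosen <- 1L
      if (!any(c1)) filter$flagged <- TRUE
    }
  }
  j <- filter$chosen
  comp <- drop(crossprod(filter$W[, j], grand_response))
  wm <- mean(comp[times_ms >= window_ms[1] & times_ms <= window_ms[2]])
  want_neg <- spec$polarity == "neg"
  filter$sign <- if ((wm < 0) == want_neg) 1 else -1
  # orient the stored topography consistently with the signed filter
  filter$A_chosen <- filter$A[, j] * filter$sign
  filter
}

#' Per-block component amplitudes
#'
#' Applies the chosen, signed spatial filter to every block's response and
#' averages the component time series over the peak window, yielding one
#' amplitude per (block, response, component).
#'
#' @param filter A `ged_filter` after [select_component()].
#' @param block_responses List of channels x time matrices (NULL entries
#'   yield NA).
#' @param times_ms Time axis.
#' @param window_ms Peak window (2-vector).
#' @return Numeric vector of amplitudes, one per block.
#' @export
component_amplitudes <- function(filter, block_responses, times_ms, window_ms) {
  w <- filter$W[, filter$chosen] * filter$sign
  sel <- times_ms >= window_ms[1] & times_ms <= window_ms[2]
  vapply(block_responses, function(resp) {
    if (is.null(resp)) return(NA_real_)
    comp <- drop(crossprod(w, resp))
    mean(comp[sel])
  }, numeric(1))
}

#' Cross-participant GED analysis of one response/component pair
#'
#' The generic-filter workflow: per-participant peaks on the block-mean
#' responses, per-participant window/baseline covariances, outlier-cleaned
#' grand averages, GED, plausibility-checked component selection, and
#' per-block amplitudes for every participant.
#'
#' @param responses List (participants) of lists (blocks) of channels x time
#'   matrices.
#' @param times_ms Time axis shared by all responses.
#' @param spec A [window_spec()].
#' @param labels Channel labels.
#' @param baseline_ms Baseline window.
#' @param shrink GED shrinkage (default 0.01).
#' @param override Optional component override.
#' @return List: `filter`, `peaks` (per participant), `amplitudes`
#'   (data.frame participant x block), `excluded`.
#' @export
ged_pipeline <- function(responses, times_ms, spec, labels,
                         baseline_ms = c(-200, 0), shrink = 0.01,
                         override = NULL) {
  np <- length(responses)
  means <- lapply(responses, function(bl) {
    ok <- Filter(Negate(is.null), bl)
    Reduce(`+`, ok) / length(ok)
  })
  peaks <- lapply(means, find_peak, times_ms = times_ms, spec = spec)
  covs <- lapply(seq_len(np), function(p)
    window_covariances(means[[p]], times_ms, peaks[[p]]$latency_ms, spec,
                       baseline_ms))
  cl <- clean_and_average(lapply(covs, `[[`, "S"), lapply(covs, `[[`, "R"))
  filt <- ged_decompose(cl$S_bar, cl$R_bar, shrink)
  grand <- Reduce(`+`, means) / np
  gpk <- find_peak(grand, times_ms, spec)
  gwin <- c(gpk$latency_ms - spec$half_width_ms,
            gpk$latency_ms + spec$half_width_ms)
  filt <- select_component(filt, spec, grand, times_ms, gwin, labels,
                           override = override)
  amps <- do.call(rbind, lapply(seq_len(np), function(p) {
    win <- covs[[p]]$window_ms
    a <- component_amplitudes(filt, responses[[p]], times_ms, win)
    data.frame(participant = p, block = seq_along(a), amplitude = a)
  }))
  list(filter = filt, peaks = peaks, amplitudes = amps,
       excluded = cl$excluded)
}
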