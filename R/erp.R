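#' Epoch a segment around letter onsets
#'
#' Extracts one epoch per letter marker spanning `tmin_ms` to `tmax_ms`
#' relative to the (delay- and onset-corrected) stimulus onset. Letters
#' whose epoch would cross the segment boundary are dropped (counted, not
#' zero-padded, to keep baseline statistics unbiased).
#'
#' @param rec A [recording()] segment.
#' @param letter_markers Marker rows to epoch; defaults to all markers whose
#'   label starts with `"letter"`.
#' @param tmin_ms,tmax_ms Epoch span relative to onset, ms (defaults -200
#'   and 600).
#' @return List: `epochs` (channels x time x n array), `times_ms`,
#'   `n_dropped`, `markers` (rows actually used).
#' @export
epoch_letters <- function(rec, letter_markers = NULL,
                          tmin_ms = -200, tmax_ms = 600) {
  if (is.null(letter_markers))
    letter_markers <- rec$markers[grepl("^letter", rec$markers$label), , drop = FALSE]
  fs <- rec$fs
  pre <- ms_to_samples(-tmin_ms, fs)
  post <- ms_to_samples(tmax_ms, fs)
  n <- ncol(rec$data)
  ok <- letter_markers$onset_sample - pre >= 1 &
        letter_markers$onset_sample + post <= n
  used <- letter_markers[ok, , drop = FALSE]
  times_ms <- seq(-pre, post) / fs * 1000
  if (nrow(used) == 0) {
    warning("no extractable epochs in this segment")
    return(list(epochs = array(0, c(nrow(rec$data), pre + post + 1, 0)),
                times_ms = times_ms, n_dropped = sum(!ok), markers = used))
  }
  ep <- array(0, c(nrow(rec$data), pre + post + 1, nrow(used)))
  for (i in seq_len(nrow(used))) {
    s0 <- used$onset_sample[i]
    ep[, , i] <- rec$data[, (s0 - pre):(s0 + post), drop = FALSE]
  }
  list(epochs = ep, times_ms = times_ms, n_dropped = sum(!ok), markers = used)
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over the baseline window
#' (default -200 to 0 ms before onset).
#'
#' @param epochs Output of [epoch_letters()] (list with `epochs`,
#'   `times_ms`) or a bare channels x time x n array plus `times_ms`.
#' @param window_ms Baseline window, ms.
#' @param times_ms Time axis (required for bare arrays).
#' @return Same structure with corrected epochs.
#' @export
baseline_correct <- function(epochs, window_ms = c(-200, 0), times_ms = NULL) {
  wrapped <- is.list(epochs) && !is.null(epochs$epochs)
  ep <- if (wrapped) epochs$epochs else epochs
  tm <- if (wrapped) epochs$times_ms else times_ms
  sel <- tm >= window_ms[1] & tm <= window_ms[2]
  if (!any(sel)) stop("baseline window contains no samples")
  for (i in seq_len(dim(ep)[3])) {
    bl <- rowMeans(ep[, sel, i, drop = FALSE])
    ep[, , i] <- ep[, , i] - bl
  }
  if (wrapped) { epochs$epochs <- ep; epochs } else ep
}

#' Average the kept epochs of one block
#'
#' Arithmetic mean over the epochs surviving joint-probability rejection;
#' the kept count is recorded.
#'
#' @param epochs Epoch structure (see [baseline_correct()]).
#' @param mask Logical keep-mask from [jointprob_reject()]; default keeps
#'   all.
#' @return List of class `erp_entry`: `average` (channels x time),
#'   `times_ms`, `n_epochs_kept`, `mask`.
#' @export
average_block <- function(epochs, mask = NULL) {
  wrapped <- is.list(epochs) && !is.null(epochs$epochs)
  ep <- if (wrapped) epochs$epochs else epochs
  tm <- if (wrapped) epochs$times_ms else NULL
  ne <- dim(ep)[3]
  if (is.null(mask)) mask <- rep(TRUE, ne)
  if (length(mask) != ne) stop("mask length must equal the number of epochs")
  if (!any(mask) || ne == 0) {
    warning("all epochs rejected; empty ERP entry")
    return(structure(list(average = NULL, times_ms = tm, n_epochs_kept = 0L,
                          mask = mask), class = "erp_entry"))
  }
  avg <- apply(ep[, , mask, drop = FALSE], c(1, 2), mean)
  structure(list(average = avg, times_ms = tm, n_epochs_kept = sum(mask),
                 mask = mask), class = "erp_entry")
}

#' @export
print.erp_entry <- function(x, ...) {
  cat(sprintf("<erp_entry> %s, %d epochs kept\n",
              if (is.null(x$average)) "empty"
              else paste(dim(x$average), collapse = " x "),
              x$n_epochs_kept))
  invisible(x)
}

#' Per-block ERPs for one participant's segments
#'
#' Convenience wrapper: epochs each segment's letters, baseline-corrects,
#' rejects improbable epochs at `sd_threshold` standard deviations, and
#' averages per block.
#'
#' @param segments List of [recording()] segments (from
#'   [restrict_to_sound()]).
#' @param sd_threshold Joint-probability threshold (default 3).
#' @param tmin_ms,tmax_ms Epoch span, ms.
#' @return List of `erp_entry` objects, one per block, with `block` and
#'   `condition` fields attached.
#' @export
erp_by_block <- function(segments, sd_threshold = 3,
                         tmin_ms = -200, tmax_ms = 600) {
  lapply(segments, function(seg) {
    ep <- epoch_letters(seg, tmin_ms = tmin_ms, tmax_ms = tmax_ms)
    ep <- baseline_correct(ep)
    ne <- dim(ep$epochs)[3]
    mask <- if (ne >= 10) jointprob_reject(ep$epochs, sd_threshold)
            else rep(TRUE, ne)
    entry <- average_block(ep, mask)
    entry$block <- seg$block
    entry$condition <- seg$condition
    entry
  })
}
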