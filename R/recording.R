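#' Standard 10-20 montage for the 24-channel mobile cap
#'
#' Cartesian head coordinates (mm, RAS-oriented, head-sized sphere) for the
#' 24 recording electrodes of the wireless cap used throughout the package
#' (plus the FCz recording reference). Positions follow the standard 10-20
#' extended layout.
#'
#' @param labels Optional character vector restricting the returned rows.
#' @return A data.frame with columns `label`, `x`, `y`, `z`.
#' @export
standard_montage <- function(labels = NULL) {
  m <- data.frame(
    label = c("Fp1", "Fp2", "AFz", "Fz", "F3", "F4", "F7", "F8", "Cz", "C3",
              "C4", "T7", "T8", "CPz", "Pz", "M1", "M2", "P3", "P4", "P7",
              "P8", "POz", "O1", "O2", "FCz"),
    x = c(-29.4, 29.9, 0.2, 0.3, -50.2, 51.8, -70.3, 73.0, 0.4, -65.4, 67.1,
          -84.2, 85.1, 0.4, 0.3, -86.1, 85.8, -53.0, 55.7, -72.4, 73.1, 0.2,
          -29.4, 29.8, 0.4),
    y = c(83.9, 84.9, 80.8, 58.5, 53.1, 54.3, 42.5, 44.4, -9.2, -11.6, -10.9,
          -16.0, -15.0, -47.3, -81.1, -45.0, -45.0, -78.8, -78.6, -73.5,
          -73.1, -102.2, -112.4, -112.2, 27.4),
    z = c(-7.0, -7.1, 35.4, 66.5, 42.2, 40.8, -11.4, -12.0, 100.2, 64.4, 63.6,
          -9.3, -9.5, 99.4, 82.6, -68.0, -68.0, 55.9, 56.6, -2.5, -2.5, 50.6,
          8.8, 8.8, 88.7),
    stringsAsFactors = FALSE
  )
  if (!is.null(labels)) {
    miss <- setdiff(labels, m$label)
    if (length(miss)) stop("unknown electrode label(s): ", paste(miss, collapse = ", "))
    m <- m[match(labels, m$label), , drop = FALSE]
    rownames(m) <- NULL
  }
  m
}

#' Default channel set of the 24-channel cap
#' @return Character vector of 24 10-20 labels.
#' @export
default_channels <- function() {
  c("Fp1", "Fp2", "AFz", "Fz", "F3", "F4", "F7", "F8", "Cz", "C3", "C4",
    "T7", "T8", "CPz", "Pz", "M1", "M2", "P3", "P4", "P7", "P8", "POz",
    "O1", "O2")
}

#' Construct a multichannel EEG recording
#'
#' The central container passed between preprocessing stages: a channels x
#' samples matrix with sampling rate, electrode labels and positions, an event
#' marker table, the list of rejected channels, and an append-only history of
#' applied processing steps.
#'
#' @param data Numeric matrix, channels x samples (microvolts).
#' @param fs Sampling rate in Hz.
#' @param labels Character vector of unique channel labels, one per row.
#' @param montage data.frame with `label`, `x`, `y`, `z`; defaults to the
#'   built-in 10-20 positions for the given labels.
#' @param markers data.frame of events with at least `onset_sample` and
#'   `label`; may carry `block` and `condition`.
#' @param bads Character vector of rejected channel labels.
#' @param history Character vector of processing steps already applied.
#' @return An object of class `recording`.
#' @export
recording <- function(data, fs, labels, montage = NULL,
                      markers = empty_markers(), bads = character(),
                      history = character()) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be numeric")
  if (length(labels) != nrow(data)) stop("`labels` length must equal nrow(data)")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("`fs` must be a positive scalar")
  if (is.null(montage)) {
    montage <- tryCatch(standard_montage(labels), error = function(e) NULL)
  }
  rownames(data) <- labels
  structure(
    list(data = data, fs = fs, labels = as.character(labels),
         montage = montage, markers = markers,
         bads = as.character(bads), history = as.character(history)),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat(sprintf("  markers: %d  bads: %s\n", nrow(x$markers),
              if (length(x$bads)) paste(x$bads, collapse = ", ") else "none"))
  if (length(x$history)) cat("  history:", paste(x$history, collapse = " -> "), "\n")
  invisible(x)
}

#' Empty marker table
#' @return Zero-row data.frame with the standard marker columns.
#' @export
empty_markers <- function() {
  data.frame(onset_sample = integer(), label = character(),
             block = integer(), condition = integer(),
             stringsAsFactors = FALSE)
}

n_samples <- function(rec) ncol(rec$data)

add_history <- function(rec, step) {
  rec$history <- c(rec$history, step)
  rec
}

#' Construct a stimulus feature time series
#'
#' A single feature aligned to the EEG timeline: a continuous envelope
#' (non-negative) or a binary onset vector, at a stated feature rate.
#'
#' @param values Numeric vector.
#' @param rate Feature sampling rate (Hz).
#' @param kind One of `"envelope_raw"`, `"envelope_denoised"`, `"onsets"`.
#' @param block Block index the feature belongs to.
#' @return Object of class `stimulus_feature`.
#' @export
stimulus_feature <- function(values, rate,
                             kind = c("envelope_raw", "envelope_denoised", "onsets"),
                             block = NA_integer_) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (kind == "onsets") {
    if (!all(values %in% c(0, 1))) stop("onset features must be binary 0/1")
  } else if (any(values < 0)) {
    stop("envelope features must be non-negative")
  }
  structure(list(values = values, rate = rate, kind = kind, block = block),
            class = "stimulus_feature")
}

#' @export
print.stimulus_feature <- function(x, ...) {
  cat(sprintf("<stimulus_feature> kind=%s rate=%g Hz n=%d (%.1f s) block=%s\n",
              x$kind, x$rate, length(x$values), length(x$values) / x$rate,
              as.character(x$block)))
  invisible(x)
}
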