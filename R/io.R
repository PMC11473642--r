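# Minimal RIFF/WAVE PCM I/O (mono or interleaved multichannel, 16/24-bit).

#' Write a waveform as a PCM WAV file
#'
#' @param x Numeric vector (or samples x channels matrix) in [-1, 1];
#'   values are clipped.
#' @param path Output path.
#' @param fs Sampling rate, Hz.
#' @param bits 16 or 24.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, fs, bits = 16) {
  if (!bits %in% c(16L, 24L)) stop("bits must be 16 or 24")
  x <- as.matrix(x)
  nch <- ncol(x); nsamp <- nrow(x)
  x[x > 1] <- 1
  x[x < -1] <- -1
  bytes_per <- bits / 8
  data_len <- nsamp * nch * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_len), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")             # PCM
  writeBin(as.integer(nch), con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * nch * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(nch * bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_len), con, size = 4, endian = "little")
  q <- as.integer(round(t(x) * (2^(bits - 1) - 1)))          # interleave
  if (bits == 16) {
    writeBin(as.vector(q), con, size = 2, endian = "little")
  } else {
    q[q < 0] <- q[q < 0] + 2^24
    b <- rbind(q %% 256L, (q %/% 256L) %% 256L, (q %/% 65536L) %% 256L)
    writeBin(as.raw(as.vector(b)), con)
  }
  invisible(path)
}

#' Read a PCM WAV file written by [write_wav()]
#'
#' @param path Input path.
#' @return List: `x` (samples x channels matrix in [-1, 1]), `fs`, `bits`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fs <- NULL; nch <- NULL; bits <- NULL; x <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    len <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      nch <- fmt[2]
      fs <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (len > 16) invisible(readBin(con, raw(), n = len - 16))
    } else if (id == "data") {
      if (bits == 16) {
        x <- readBin(con, integer(), n = len / 2, size = 2, endian = "little")
      } else {
        b <- as.integer(readBin(con, raw(), n = len))
        m <- matrix(b, nrow = 3)
        x <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
        x[x >= 2^23] <- x[x >= 2^23] - 2^24
      }
      break
    } else {
      invisible(readBin(con, raw(), n = len))
    }
  }
  if (is.null(x)) stop("no data chunk found")
  list(x = matrix(x / (2^(bits - 1) - 1), ncol = nch, byrow = TRUE),
       fs = fs, bits = bits)
}

#' Write a marker table as CSV
#'
#' Columns `onset_sample`, `onset_s`, `label` (plus `block`, `condition`
#' when present).
#'
#' @param markers Marker data.frame.
#' @param path Output path.
#' @param fs Sampling rate used to derive `onset_s`.
#' @return `path`, invisibly.
#' @export
write_markers <- function(markers, path, fs) {
  markers$onset_s <- (markers$onset_sample - 1) / fs
  utils::write.csv(markers, path, row.names = FALSE)
  invisible(path)
}

#' Write a stimulus feature as CSV (time, value) with a JSON sidecar
#' @param feature A [stimulus_feature()].
#' @param path CSV path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_feature <- function(feature, path) {
  df <- data.frame(time = (seq_along(feature$values) - 1) / feature$rate,
                   value = feature$values)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(kind = feature$kind, rate = feature$rate,
                            block = feature$block),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are rejected so typos cannot silently disable a stage.
#'
#' @param path YAML file.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c(names(formals(synth_config)), "out_dir", "feature_rate",
             "condition_scale", "time_slope", "stages")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg
}
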