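# End-to-end orchestration on synthetic data. The stages mirror the
# recording-to-statistics workflow: simulate -> acoustic features ->
# EEG preprocessing -> ERP -> TRF -> GED -> mixed models.

concat_segments <- function(segs) {
  lens <- vapply(segs, function(s) ncol(s$data), integer(1))
  offs <- cumsum(c(0L, lens[-length(lens)]))
  mk <- do.call(rbind, lapply(seq_along(segs), function(i) {
    m <- segs[[i]]$markers
    if (nrow(m)) m$onset_sample <- m$onset_sample + offs[i]
    m
  }))
  rec <- recording(do.call(cbind, lapply(segs, `[[`, "data")),
                   segs[[1]]$fs, segs[[1]]$labels,
                   montage = segs[[1]]$montage, markers = mk,
                   bads = segs[[1]]$bads, history = segs[[1]]$history)
  attr(rec, "boundaries") <- data.frame(
    block = vapply(segs, function(s) s$block, numeric(1)),
    condition = vapply(segs, function(s) s$condition, numeric(1)),
    start = offs + 1L, end = offs + lens)
  rec
}

split_segments <- function(rec, boundaries = attr(rec, "boundaries")) {
  lapply(seq_len(nrow(boundaries)), function(i) {
    b <- boundaries[i, ]
    inside <- rec$markers$onset_sample >= b$start & rec$markers$onset_sample <= b$end
    mk <- rec$markers[inside, , drop = FALSE]
    if (nrow(mk)) mk$onset_sample <- mk$onset_sample - b$start + 1L
    seg <- recording(rec$data[, b$start:b$end, drop = FALSE], rec$fs,
                     rec$labels, montage = rec$montage, markers = mk,
                     bads = rec$bads, history = rec$history)
    seg$block <- b$block
    seg$condition <- b$condition
    seg
  })
}

#' Simulate and analyze one participant end to end
#'
#' Renders each block's soundscape, extracts the three acoustic features,
#' simulates EEG with the planted responses, preprocesses (band-limiting,
#' marker-delay correction, restriction to sound, optional bad-channel
#' rejection / ICA / interpolation and mastoid re-referencing), and returns
#' per-block ERPs plus feature/EEG block pairs at the analysis rate.
#'
#' @param cfg A [synth_config()].
#' @param truth A [ground_truth()].
#' @param participant Participant index (seeds the blocks).
#' @param conditions 0/1 vector of block conditions (defaults to the
#'   balanced randomized assignment).
#' @param forbidden_by_block List of memory-letter sets per block.
#' @param feature_rate Common analysis rate, Hz (default 125; must divide
#'   `eeg_fs`).
#' @param stages Character vector of optional stages to run, among
#'   `"reject_channels"`, `"ica"`, `"interp_reref"`.
#' @return List: `erps`, `trf_blocks` (per feature kind), `conditions`.
#' @export
simulate_participant <- function(cfg, truth, participant = 1L,
                                 conditions = NULL, forbidden_by_block = NULL,
                                 feature_rate = 125,
                                 stages = character()) {
  q <- cfg$eeg_fs / feature_rate
  if (abs(q - round(q)) > 1e-9) stop("feature_rate must divide eeg_fs")
  if (is.null(conditions))
    conditions <- sample(rep(0:1, each = cfg$blocks_per_condition))
  pseed <- cfg$seed + 100000L * participant
  segs <- list(); feats <- list()
  for (b in seq_len(cfg$n_blocks)) {
    bcfg <- cfg; bcfg$seed <- pseed
    forb <- if (is.null(forbidden_by_block)) character()
            else forbidden_by_block[[b]]
    aud <- render_block_audio(bcfg, b, forbidden = forb)
    env_raw <- extract_envelope(aud$audio, aud$fs, feature_rate, block = b)
    den <- wiener_denoise(aud$audio, aud$fs)
    env_den <- extract_envelope(den, aud$fs, feature_rate, block = b,
                                kind = "envelope_denoised")
    ons <- detect_onsets(aud$audio, aud$fs, feature_rate, block = b)
    # planted truth features at the EEG rate drive the simulated response
    env_true <- extract_envelope(aud$clean, aud$fs, cfg$eeg_fs,
                                 kind = "envelope_denoised")
    n_eeg <- round(cfg$block_duration_s * cfg$eeg_fs)
    ons_true <- numeric(n_eeg)
    ev_t <- c(aud$events$onset_s, aud$letters$onset_s)
    ons_true[pmin(n_eeg, round(ev_t * cfg$eeg_fs) + 1L)] <- 1
    rec <- simulate_eeg(bcfg, truth,
                        features = list(
                          env = stimulus_feature(env_true$values, cfg$eeg_fs,
                                                 "envelope_denoised", b),
                          ons = stimulus_feature(ons_true, cfg$eeg_fs,
                                                 "onsets", b)),
                        letter_events = aud$letters, block = b,
                        condition = conditions[b], seed = pseed + b)
    rec <- bandpass_fir(rec)
    lm <- grepl("^letter", rec$markers$label)
    rec$markers[lm, ] <- correct_marker_delay(rec$markers[lm, , drop = FALSE],
                                              rec$fs, cfg$marker_delay_ms)
    seg <- restrict_to_sound(rec)[[1]]
    segs[[b]] <- seg
    trim <- round(5 * feature_rate)
    sel <- function(f) {
      v <- f$values[(trim + 1):(length(f$values) - trim)]
      stimulus_feature(v, feature_rate, f$kind, b)
    }
    feats[[b]] <- list(envelope_raw = sel(env_raw),
                       envelope_denoised = sel(env_den),
                       onsets = sel(ons))
  }
  whole <- concat_segments(segs)
  if ("reject_channels" %in% stages)
    whole <- reject_bad_channels(whole, seed = pseed)
  if ("ica" %in% stages)
    whole <- ica_clean(whole, seed = pseed)
  if ("interp_reref" %in% stages)
    whole <- interpolate_and_reref(whole)
  segs <- split_segments(whole)
  erps <- erp_by_block(segs)
  trf_blocks <- lapply(c(envelope_raw = "envelope_raw",
                         envelope_denoised = "envelope_denoised",
                         onsets = "onsets"), function(kind) {
    lapply(seq_along(segs), function(b) {
      eeg <- scale_eeg(decimate_recording(segs[[b]], q))
      f <- feats[[b]][[kind]]
      L <- min(length(f$values), ncol(eeg$data))
      list(feature = stimulus_feature(f$values[seq_len(L)], feature_rate,
                                      f$kind, b),
           eeg = t(eeg$data[, seq_len(L), drop = FALSE]))
    })
  })
  list(erps = erps, trf_blocks = trf_blocks, conditions = conditions)
}

#' Run the full synthetic study
#'
#' Simulates the behavioral table and every participant's audio/EEG,
#' estimates TRF prediction accuracies per acoustic feature (segment-wise
#' cross-validation), compares features by signed-rank tests, computes
#' per-block TRFs and ERPs, extracts GED component amplitudes per response
#' window, appends them to the block table, and fits the nested
#' condition/time mixed-model sequence to every outcome.
#'
#' Intended for demonstration-scale configurations; the defaults of
#' [synth_config()] describe a full 22 x 28-block session, which is heavy.
#'
#' @param cfg A [synth_config()].
#' @param truth A [ground_truth()] (defaults to `ground_truth(cfg)`).
#' @param feature_rate Analysis rate, Hz.
#' @param components Response components to extract (default N1).
#' @param cv_k Cross-validation segments (default `min(10, n_blocks)`).
#' @param stages Optional preprocessing stages (see
#'   [simulate_participant()]).
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return List of class `or_pipeline`: `block_table`, `predictions`,
#'   `feature_tests`, `models`, `ged`.
#' @export
run_pipeline <- function(cfg, truth = ground_truth(cfg), feature_rate = 125,
                         components = "N1", cv_k = min(10, cfg$n_blocks),
                         stages = character(), out_dir = NULL) {
  set.seed(cfg$seed)
  behavior <- simulate_behavior(cfg, truth)
  preds <- list(); erp_resp <- list(); trf_resp <- list()
  amp_rows <- list()
  cond_by_p <- list()
  per_block_models <- list()
  for (p in seq_len(cfg$n_participants)) {
    conds <- behavior$condition[behavior$participant == p]
    forb <- lapply(strsplit(behavior$target_seq[behavior$participant == p], ""),
                   identity)
    sim <- simulate_participant(cfg, truth, p, conditions = conds,
                                forbidden_by_block = forb,
                                feature_rate = feature_rate, stages = stages)
    pr <- vapply(sim$trf_blocks, function(blocks)
      crossval_lambda(blocks, k = cv_k)$pred_r, numeric(1))
    preds[[p]] <- pr
    cv_den <- crossval_lambda(sim$trf_blocks$envelope_denoised, k = cv_k)
    cv_ons <- crossval_lambda(sim$trf_blocks$onsets, k = cv_k)
    mk_resp <- function(models) lapply(models, function(m) t(m$weights))
    per_block_models[[p]] <- list(
      env = per_block_trf(sim$trf_blocks$envelope_denoised, cv_den),
      ons = per_block_trf(sim$trf_blocks$onsets, cv_ons))
    erp_resp[[p]] <- lapply(sim$erps, function(e) e$average)
    trf_resp[[p]] <- list(env = mk_resp(per_block_models[[p]]$env),
                          ons = mk_resp(per_block_models[[p]]$ons))
    cond_by_p[[p]] <- conds
  }
  predictions <- as.data.frame(do.call(rbind, preds))
  predictions$participant <- seq_len(cfg$n_participants)
  feature_tests <- compare_features(
    predictions[, c("envelope_raw", "envelope_denoised", "onsets")])
  labels <- default_channels()[seq_len(cfg$n_channels)]
  erp_times <- seq(-ms_to_samples(200, cfg$eeg_fs),
                   ms_to_samples(600, cfg$eeg_fs)) / cfg$eeg_fs * 1000
  trf_times <- seq(ms_to_samples(-220, feature_rate),
                   ms_to_samples(500, feature_rate)) / feature_rate * 1000
  ged_out <- list()
  block_table <- behavior
  for (comp in components) {
    runs <- list(
      ERP = list(resp = erp_resp, times = erp_times, spec = window_spec("ERP", comp)),
      TRF_env = list(resp = lapply(trf_resp, `[[`, "env"), times = trf_times,
                     spec = window_spec("TRF_env", comp)),
      TRF_ons = list(resp = lapply(trf_resp, `[[`, "ons"), times = trf_times,
                     spec = window_spec("TRF_ons", comp)))
    for (nm in names(runs)) {
      r <- runs[[nm]]
      g <- ged_pipeline(r$resp, r$times, r$spec, labels)
      ged_out[[paste(nm, comp, sep = "_")]] <- g
      col <- paste("amp", nm, comp, sep = "_")
      amp <- g$amplitudes
      key_bt <- paste(block_table$participant, block_table$block)
      key_amp <- paste(amp$participant, amp$block)
      block_table[[col]] <- amp$amplitude[match(key_bt, key_amp)]
    }
  }
  models <- list()
  for (outc in c("effort", "frustration", "distraction", "duration"))
    models[[outc]] <- select_model(block_table, outc, "lmm")
  for (outc in c("mistakes", "tissue_damage"))
    models[[outc]] <- select_model(block_table, outc, "poisson")
  models$memory_score <- select_model(block_table, "memory_score", "clmm")
  for (col in grep("^amp_", names(block_table), value = TRUE))
    models[[col]] <- select_model(block_table, col, "lmm")
  out <- structure(list(block_table = block_table, predictions = predictions,
                        feature_tests = feature_tests, models = models,
                        ged = ged_out, cfg = cfg, truth = truth),
                   class = "or_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' @export
print.or_pipeline <- function(x, ...) {
  cat(sprintf("<or_pipeline> %d participants x %d blocks\n",
              x$cfg$n_participants, x$cfg$n_blocks))
  cat("prediction values (mean):\n")
  print(round(colMeans(x$predictions[, setdiff(names(x$predictions), "participant")]), 4))
  cat("feature comparisons:\n")
  print(x$feature_tests)
  cat("selected models:\n")
  print(model_selection_table(x$models))
  invisible(x)
}

#' Model-selection summary table
#'
#' One row per outcome: the chosen model and the condition/time estimates
#' with significance markers at the Bonferroni-corrected level.
#'
#' @param models Named list of chosen `model_fit`s (from [run_pipeline()]
#'   or [select_model()]).
#' @param alpha Corrected per-test level (default `0.05 / 3`).
#' @return data.frame summary.
#' @export
model_selection_table <- function(models, alpha = bonferroni_alpha(0.05, 3)) {
  rows <- lapply(names(models), function(nm) {
    m <- models[[nm]]
    get_coef <- function(pred) {
      i <- match(pred, rownames(m$coefficients))
      if (is.na(i)) c(NA_real_, NA_real_)
      else c(m$coefficients$estimate[i], m$coefficients$p[i])
    }
    cc <- get_coef("condition"); tt <- get_coef("time")
    star <- function(b, p) {
      if (is.na(b)) return("")
      paste0(signif(b, 3), if (!is.na(p) && p < alpha) "*" else "")
    }
    data.frame(response = nm, model = m$formula_id,
               condition = star(cc[1], cc[2]), time = star(tt[1], tt[2]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$block_table, file.path(out_dir, "block_table.csv"),
                   row.names = FALSE)
  utils::write.csv(out$predictions, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(out$feature_tests, file.path(out_dir, "feature_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(model_selection_table(out$models),
                   file.path(out_dir, "model_selection.csv"), row.names = FALSE)
  cfg <- out$cfg
  jsonlite::write_json(cfg[!vapply(cfg, is.function, logical(1))],
                       file.path(out_dir, "config.json"), auto_unbox = TRUE)
  if (!is.null(out$truth))
    jsonlite::write_json(unclass(out$truth),
                         file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
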