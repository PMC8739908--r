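#' Default pipeline configuration
#'
#' Nested parameter list for the four-stage chain
#' (preprocess, detect, features, classify).  Two preprocessing bands are
#' carried: the 5--40 Hz detection band feeding the TERMA detectors, and
#' the 0.5--35 Hz Butterworth + FIR chain with resampling to 260 Hz
#' feeding the AR features — the classification chain additionally has
#' baseline wander handled by its own high-pass, while the detection
#' chain uses the wavelet baseline removal.
#'
#' @param ... named overrides, e.g. `detect = list(beta = 0.1)`; unknown
#'   keys are an error.
#' @return An object of class `pipeline_config` (a nested list).
#' @export
pipeline_config <- function(...) {
  base <- list(
    seed = 1L,
    preprocess = list(
      wavelet = "db4", drift_freq = 0.5,
      detect_band = list(low = 5, high = 40),
      classify_band = list(low = 0.5, high = 35),
      resample_fs = 260,
      segment_window_ms = 250),
    detect = list(
      w1_ms = 97, w2_ms = 611, w3_ms = 100, w4_ms = 400,
      beta = 0.08, frft_alpha = 0.01,
      blank_pre_ms = 1000 * 30 / 360, blank_post_ms = 1000 * 60 / 360,
      pr_window_ms = 300, rt_window_ms = 450,
      match_tol_ms = 30, refractory_ms = 200, pt_floor = 1e-4),
    features = list(ar_order = 3L, group_size = 2L, type = "ar"),
    classify = list(kind = "svm_rbf", split = 0.7))
  merge_config(base, list(...), "pipeline_config")
}

merge_config <- function(base, override, cls = NULL) {
  for (nm in names(override)) {
    if (!nm %in% names(base))
      stop("unknown config key: '", nm, "'")
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  if (!is.null(cls)) class(base) <- cls
  base
}

#' Read / write a pipeline configuration as YAML
#'
#' The file round-trips losslessly; unknown keys in the file are
#' rejected at read time.
#'
#' @param path YAML file path.
#' @param config a [pipeline_config()].
#' @return `read_pipeline_config` returns a [pipeline_config()];
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Detect R, P and T peaks with per-wave preprocessing bands
#'
#' The convenience front end used by the pipeline.  R and P peaks are
#' detected on the 5--40 Hz detection chain (bandpass plus wavelet
#' baseline removal), where the narrow P wave survives and the QRS
#' dominates; T peaks are detected on the 0.5--35 Hz classification
#' chain, whose gentle high-pass leaves the broad T wave intact (the
#' 5 Hz edge renders the T biphasic and makes its apex ambiguous under
#' noise).  Each wave is delineated on the band where its morphology is
#' preserved.
#'
#' @param record a raw [ecg_record()].
#' @param config a [pipeline_config()].
#' @return list with `peaks` (a [peak_set()]), `record_detect` (the
#'   detection-chain record) and `record_twave` (the T-wave chain).
#' @export
detect_all_peaks <- function(record, config = pipeline_config()) {
  stopifnot(inherits(record, "ecg_record"),
            inherits(config, "pipeline_config"))
  pp <- config$preprocess
  params <- config_terma_params(config)
  rec_det <- remove_baseline_dwt(
    bandpass_filter(record, bandpass_spec(pp$detect_band$low,
                                          pp$detect_band$high,
                                          "butterworth")),
    wavelet_plan(pp$wavelet, pp$drift_freq))
  rec_t <- bandpass_filter(record,
    bandpass_spec(pp$classify_band$low, pp$classify_band$high,
                  "butter_fir_combo"))
  rp <- detect_r_peaks(rec_det, params)
  peaks <- if (length(rp$r)) {
    pk_p <- detect_pt_peaks(rec_det, rp, params)
    pk_t <- detect_pt_peaks(rec_t, rp, params)
    peak_set(r = rp$r, p = pk_p$p, t = pk_t$t)
  } else rp
  list(peaks = peaks, record_detect = rec_det, record_twave = rec_t)
}

config_terma_params <- function(config) {
  d <- config$detect
  terma_params(w1_ms = d$w1_ms, w2_ms = d$w2_ms, w3_ms = d$w3_ms,
               w4_ms = d$w4_ms, beta = d$beta,
               frft_alpha = d$frft_alpha,
               blank_pre_ms = d$blank_pre_ms,
               blank_post_ms = d$blank_post_ms,
               pr_window_ms = d$pr_window_ms,
               rt_window_ms = d$rt_window_ms,
               match_tol_ms = d$match_tol_ms,
               refractory_ms = d$refractory_ms, pt_floor = d$pt_floor)
}

#' Run the four-stage analysis pipeline
#'
#' Preprocesses the record (detection chain: 5--40 Hz bandpass plus
#' wavelet baseline removal), detects R then P/T peaks, builds the
#' classification-chain record (0.5--35 Hz, resampled to 260 Hz), maps
#' the peaks to the resampled rate and extracts AR + interval features.
#' When per-beat `labels` are supplied (e.g. from an annotation file or
#' the synthetic ground truth) a classifier is trained and evaluated on
#' a stratified held-out split.
#'
#' @param record an [ecg_record()].
#' @param config a [pipeline_config()].
#' @param labels optional per-detected-beat class labels for the
#'   classification stage.
#' @param use_peaks optional [peak_set()] to use instead of running the
#'   detector (e.g. database annotations).
#' @param verbose log per-stage timing to `stderr`.
#' @return list with `peaks`, `features`, `classifier` (or `NULL`),
#'   `record_detect` and `record_classify`.
#' @export
run_pipeline <- function(record, config = pipeline_config(),
                         labels = NULL, use_peaks = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(record, "ecg_record"),
            inherits(config, "pipeline_config"))
  say <- function(stage, t0) if (verbose)
    message(sprintf("[%s] %.2fs", stage, proc.time()[3] - t0))
  run_stage <- function(stage, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say(stage, t0)
    out
  }
  pp <- config$preprocess
  params <- config_terma_params(config)
  chains <- run_stage("preprocess", {
    rec_det <- remove_baseline_dwt(
      bandpass_filter(record, bandpass_spec(pp$detect_band$low,
                                            pp$detect_band$high,
                                            "butterworth")),
      wavelet_plan(pp$wavelet, pp$drift_freq))
    rec_t <- bandpass_filter(record,
      bandpass_spec(pp$classify_band$low, pp$classify_band$high,
                    "butter_fir_combo"))
    list(det = rec_det, t = rec_t)
  })
  rec_det <- chains$det
  peaks <- run_stage("detect", {
    if (is.null(use_peaks)) {
      rp <- detect_r_peaks(rec_det, params)
      if (length(rp$r)) {
        # P from the 5-40 Hz chain, T from the 0.5-35 Hz chain: each
        # wave is delineated on the band that preserves its morphology
        pk_p <- detect_pt_peaks(rec_det, rp, params)
        pk_t <- detect_pt_peaks(chains$t, rp, params)
        peak_set(r = rp$r, p = pk_p$p, t = pk_t$t)
      } else rp
    } else use_peaks
  })
  rec_cls <- run_stage("preprocess-classify", {
    r <- bandpass_filter(record,
      bandpass_spec(pp$classify_band$low, pp$classify_band$high,
                    "butter_fir_combo"))
    resample_record(r, pp$resample_fs)
  })
  feats <- run_stage("features", {
    if (length(peaks$r) < 2) NULL else {
      scale_f <- rec_cls$fs / record$fs
      remap <- function(v) ifelse(is.na(v), NA,
                                  pmax(1, round((v - 1) * scale_f) + 1))
      peaks_rs <- peak_set(r = remap(peaks$r), p = remap(peaks$p),
                           t = remap(peaks$t))
      extract_features(rec_cls, peaks_rs,
                       ar_order = config$features$ar_order,
                       group_size = config$features$group_size,
                       window_ms = pp$segment_window_ms,
                       labels = labels,
                       type = config$features$type)
    }
  })
  clf <- NULL
  if (!is.null(labels) && !is.null(feats) &&
      length(unique(feats$label)) >= 2 && all(table(feats$label) >= 2)) {
    clf <- run_stage("classify", train_beat_classifier(
      feats, classifier_spec(kind = config$classify$kind,
                             seed = config$seed),
      split = config$classify$split))
  }
  list(peaks = peaks, features = feats, classifier = clf,
       record_detect = rec_det, record_classify = rec_cls)
}

#' Score detected peaks against reference annotations
#'
#' Matches each wave type within the tolerance and reports Eq.-style
#' detection metrics per wave.
#'
#' @param peaks detected [peak_set()].
#' @param truth reference [peak_set()] (or list with `r_indices`,
#'   `p_indices`, `t_indices` as produced by [generate_ecg()]).
#' @param fs sampling frequency, Hz.
#' @param tol_ms matching tolerance (default 30 ms).
#' @return named list (`r`, `p`, `t`), each containing `counts` and
#'   `metrics`.
#' @export
evaluate_peaks <- function(peaks, truth, fs, tol_ms = 30) {
  tr <- if (inherits(truth, "peak_set"))
    list(r = truth$r, p = truth$p, t = truth$t)
  else list(r = truth$r_indices, p = truth$p_indices,
            t = truth$t_indices)
  out <- lapply(c(r = "r", p = "p", t = "t"), function(w) {
    cc <- match_peaks(peaks[[w]], tr[[w]], tol_ms, fs)
    list(counts = cc, metrics = detection_metrics(cc))
  })
  out
}
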