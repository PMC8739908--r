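#' TERMA detection parameters
#'
#' Windows are stated in milliseconds and converted to odd sample counts
#' at the record's rate, so behaviour is sampling-rate independent.
#' Defaults: the event window `w1` (97 ms) spans a QRS complex and the
#' cycle window `w2` (611 ms) a heartbeat; the peak window `w3` (100 ms)
#' matches the P-wave duration of a fit individual and the wave window
#' `w4` (400 ms) the QT interval.  The QRS blanking spans are the
#' 30-samples-before / 60-samples-after windows defined at 360 Hz,
#' i.e. 83.3 ms and 166.7 ms.  `beta` scales the mean of the enhanced
#' signal into the offset `gamma = beta * mu` added to the cycle moving
#' average when thresholding R blocks; the P/T stage compares its two
#' moving averages directly with no offset.
#'
#' @param w1_ms,w2_ms event- and cycle-scale windows for R detection, ms.
#' @param w3_ms,w4_ms peak- and wave-scale windows for P/T detection, ms.
#' @param beta threshold offset factor (dimensionless).
#' @param frft_alpha FrFT order used by the enhancement stage.
#' @param blank_pre_ms,blank_post_ms QRS blanking spans around each R, ms.
#' @param pr_window_ms maximum P-to-following-R gap, ms.
#' @param rt_window_ms maximum preceding-R-to-T gap, ms.
#' @param match_tol_ms annotation matching tolerance, ms.
#' @param refractory_ms minimum separation of R blocks; closer detections
#'   are merged keeping the stronger peak.
#' @param pt_floor relative amplitude floor for P/T candidates: a block
#'   is kept only when its enhanced peak exceeds `pt_floor` times the
#'   median squared R amplitude.  The P/T comparison has no offset term,
#'   so without a floor even the numerical residue left after QRS
#'   blanking would form blocks; the floor is relative, preserving
#'   amplitude invariance.
#' @return An object of class `terma_params`.
#' @export
terma_params <- function(w1_ms = 97, w2_ms = 611, w3_ms = 100,
                         w4_ms = 400, beta = 0.08, frft_alpha = 0.01,
                         blank_pre_ms = 1000 * 30 / 360,
                         blank_post_ms = 1000 * 60 / 360,
                         pr_window_ms = 300, rt_window_ms = 450,
                         match_tol_ms = 30, refractory_ms = 200,
                         pt_floor = 1e-4) {
  if (!(w1_ms > 0 && w2_ms > w1_ms))
    stop("need 0 < w1_ms < w2_ms")
  if (!(w3_ms > 0 && w4_ms > w3_ms))
    stop("need 0 < w3_ms < w4_ms")
  if (beta < 0) stop("'beta' must be nonnegative")
  structure(list(w1_ms = w1_ms, w2_ms = w2_ms, w3_ms = w3_ms,
                 w4_ms = w4_ms, beta = beta, frft_alpha = frft_alpha,
                 blank_pre_ms = blank_pre_ms,
                 blank_post_ms = blank_post_ms,
                 pr_window_ms = pr_window_ms,
                 rt_window_ms = rt_window_ms,
                 match_tol_ms = match_tol_ms,
                 refractory_ms = refractory_ms, pt_floor = pt_floor),
            class = "terma_params")
}

#' Centred moving average with zero padding
#'
#' Mean over an odd window centred on each sample; samples outside the
#' signal count as zero, so output length equals input length.
#'
#' @param x numeric vector.
#' @param window odd positive integer window, in samples.
#' @return numeric vector, same length as `x`.
#' @examples
#' moving_average(c(0, 0, 3, 0, 0), 3)  # 0 1 1 1 0
#' @export
moving_average <- function(x, window) {
  window <- as.integer(window)
  if (window < 1 || window %% 2L == 0L)
    stop("'window' must be an odd positive sample count")
  if (window == 1L) return(as.numeric(x))
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- (window - 1L) / 2L
  lo <- pmax(0L, seq_len(n) - half - 1L)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo + 1L]) / window
}

#' Find blocks of interest
#'
#' Maximal runs where the event-scale moving average exceeds the
#' threshold sequence; runs narrower than `min_width` samples are
#' discarded.  One waveform event is expected per surviving block.
#'
#' @param event_ma numeric vector (event-scale moving average).
#' @param threshold numeric vector, same length (cycle-scale moving
#'   average plus any offset).
#' @param min_width minimum run width in samples (runs of exactly
#'   `min_width` are kept).
#' @return data.frame with columns `start`, `end` (inclusive, 1-based).
#' @export
blocks_of_interest <- function(event_ma, threshold, min_width = 1L) {
  if (length(event_ma) != length(threshold))
    stop("'event_ma' and 'threshold' must have equal length")
  above <- event_ma > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_width
  data.frame(start = starts[keep], end = ends[keep])
}

#' Detect R peaks by TERMA + FrFT fusion
#'
#' The record (already bandpassed and baseline-free) is enhanced with the
#' fractional Fourier transform and squared; an event-scale and a
#' cycle-scale moving average are computed over the enhanced signal; the
#' threshold is the cycle average plus `beta` times the enhanced signal's
#' mean; maximal runs where the event average exceeds the threshold and
#' that are at least one event window wide become blocks of interest; the
#' R peak of each block is the argmax of the enhanced signal inside it.
#' Blocks closer than the refractory span are merged, keeping the
#' stronger peak.  Because every quantity in the threshold scales with
#' the squared signal, detections are invariant to amplitude scaling.
#'
#' @param record an [ecg_record()] (bandpassed, baseline-removed).
#' @param params a [terma_params()].
#' @param frft_method FrFT discretisation passed to [enhance()].
#' @return a [peak_set()] with the `r` component filled.
#' @export
detect_r_peaks <- function(record, params = terma_params(),
                           frft_method = "auto") {
  stopifnot(inherits(record, "ecg_record"),
            inherits(params, "terma_params"))
  fs <- record$fs
  enh <- enhance(record$samples, params$frft_alpha, method = frft_method)
  if (all(enh == 0)) return(peak_set())
  w1 <- odd_window(params$w1_ms, fs)
  w2 <- odd_window(params$w2_ms, fs)
  ma_event <- moving_average(enh, w1)
  ma_cycle <- moving_average(enh, w2)
  thr <- ma_cycle + params$beta * mean(enh)
  blocks <- blocks_of_interest(ma_event, thr, min_width = w1)
  if (nrow(blocks) == 0) return(peak_set())
  peaks <- mapply(function(s, e) s - 1L + which.max(enh[s:e]),
                  blocks$start, blocks$end)
  # refractory merge: peaks closer than refractory_ms keep the stronger
  refr <- params$refractory_ms * fs / 1000
  peaks <- sort(peaks)
  repeat {
    gaps <- diff(peaks)
    close_i <- which(gaps < refr)
    if (!length(close_i)) break
    i <- close_i[1]
    drop <- if (enh[peaks[i]] >= enh[peaks[i + 1]]) i + 1L else i
    peaks <- peaks[-drop]
  }
  peak_set(r = peaks)
}

#' Zero out QRS regions around known R peaks
#'
#' Sets samples in `[r - blank_pre, r + blank_post]` (inclusive, clipped
#' at the record ends) to zero for every R peak, removing the QRS so the
#' lower-amplitude P and T waves dominate the subsequent enhancement.
#'
#' @param x numeric signal.
#' @param r_peaks numeric vector of R indices (1-based).
#' @param blank_pre,blank_post spans in samples before/after each R.
#' @return the blanked signal.
#' @export
blank_qrs <- function(x, r_peaks, blank_pre, blank_post) {
  x <- as.numeric(x)
  n <- length(x)
  for (r in r_peaks) {
    lo <- max(1L, floor(r - blank_pre))
    hi <- min(n, ceiling(r + blank_post))
    if (lo <= hi) x[lo:hi] <- 0
  }
  x
}

#' Detect P and T peaks after QRS removal
#'
#' QRS regions are blanked, the remainder is FrFT-enhanced and squared,
#' and a peak-scale moving average (P-duration window) is compared
#' directly against a wave-scale average (QT-duration window) — no offset
#' term, unlike the R stage.  Each surviving block contributes one
#' candidate (its argmax).  A candidate is eligible as P when its gap to
#' the *following* R is within the PR window and as T when its gap from
#' the *preceding* R is within the RT window; when both apply it goes to
#' the side whose gap criterion is the tighter fraction of its window,
#' ties breaking to T.  At most one P and one T survive per RR interval
#' (the candidate nearest its R wins); beats with no surviving candidate
#' simply have `NA` in that slot.
#'
#' @param record an [ecg_record()] (same preprocessing as R detection).
#' @param r_peaks a [peak_set()] or vector of R indices.
#' @param params a [terma_params()].
#' @param frft_method FrFT discretisation passed to [enhance()].
#' @return a [peak_set()] with `r`, `p` and `t` filled (`p`, `t` aligned
#'   per beat, `NA` where undetected).
#' @export
detect_pt_peaks <- function(record, r_peaks, params = terma_params(),
                            frft_method = "auto") {
  stopifnot(inherits(record, "ecg_record"),
            inherits(params, "terma_params"))
  r <- if (inherits(r_peaks, "peak_set")) r_peaks$r else
    sort(as.numeric(r_peaks))
  if (!length(r)) stop("'r_peaks' must contain at least one R peak")
  fs <- record$fs
  blank_pre <- params$blank_pre_ms * fs / 1000
  blank_post <- params$blank_post_ms * fs / 1000
  y <- blank_qrs(record$samples, r, blank_pre, blank_post)
  enh <- enhance(y, params$frft_alpha, method = frft_method)
  nb <- length(r)
  empty <- peak_set(r = r, p = rep(NA_real_, nb), t = rep(NA_real_, nb))
  if (all(enh == 0)) return(empty)
  w3 <- odd_window(params$w3_ms, fs)
  w4 <- odd_window(params$w4_ms, fs)
  ma_peak <- moving_average(enh, w3)
  ma_wave <- moving_average(enh, w4)
  min_w <- max(1L, (w3 - 1L) %/% 2L)
  blocks <- blocks_of_interest(ma_peak, ma_wave, min_width = min_w)
  if (nrow(blocks) == 0) return(empty)
  cand <- mapply(function(s, e) s - 1L + which.max(enh[s:e]),
                 blocks$start, blocks$end)
  # amplitude floor relative to the R peaks keeps numerical residue and
  # far QRS tails from posing as P/T candidates (scale-invariant)
  ref <- stats::median(record$samples[round(r)]^2)
  cand <- cand[enh[cand] >= params$pt_floor * ref]
  if (!length(cand)) return(empty)
  pr_win <- params$pr_window_ms * fs / 1000
  rt_win <- params$rt_window_ms * fs / 1000
  p_out <- rep(NA_real_, nb); t_out <- rep(NA_real_, nb)
  p_gap <- rep(Inf, nb); t_gap <- rep(Inf, nb)
  for (c0 in cand) {
    nxt <- which(r > c0)[1]                     # beat whose P this may be
    prv <- if (any(r < c0)) max(which(r < c0)) else NA  # beat whose T
    gap_n <- if (!is.na(nxt)) r[nxt] - c0 else Inf
    gap_p <- if (!is.na(prv)) c0 - r[prv] else Inf
    ok_p <- gap_n <= pr_win
    ok_t <- gap_p <= rt_win
    if (!ok_p && !ok_t) next
    as_t <- if (ok_p && ok_t) {
      # both windows admit it: tighter relative gap wins, ties to T
      (gap_p / rt_win) <= (gap_n / pr_win)
    } else ok_t
    if (as_t) {
      if (gap_p < t_gap[prv]) { t_out[prv] <- c0; t_gap[prv] <- gap_p }
    } else {
      if (gap_n < p_gap[nxt]) { p_out[nxt] <- c0; p_gap[nxt] <- gap_n }
    }
  }
  peak_set(r = r, p = p_out, t = t_out)
}

#' Match detected peaks against a reference within a tolerance
#'
#' Greedy one-to-one nearest matching: candidate pairs within the
#' tolerance are taken in order of increasing distance, each detection
#' and each reference peak used at most once.  Matched pairs are TP,
#' unmatched detections FP, unmatched reference peaks FN.
#'
#' @param detected,truth sorted numeric index vectors (`NA`s ignored).
#' @param tol_ms matching tolerance in milliseconds (default 30).
#' @param fs sampling frequency, Hz.
#' @return a [confusion_counts()] (with `tn = 0`, undefined for
#'   detection).
#' @export
match_peaks <- function(detected, truth, tol_ms = 30, fs) {
  detected <- sort(detected[!is.na(detected)])
  truth <- sort(truth[!is.na(truth)])
  tol <- tol_ms * fs / 1000
  if (!length(detected) || !length(truth))
    return(confusion_counts(tp = 0, fp = length(detected),
                            fn = length(truth)))
  d <- abs(outer(detected, truth, "-"))
  pairs <- which(d <= tol, arr.ind = TRUE)
  if (nrow(pairs)) {
    pairs <- pairs[order(d[pairs]), , drop = FALSE]
    used_d <- logical(length(detected)); used_t <- logical(length(truth))
    tp <- 0L
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (!used_d[i] && !used_t[j]) {
        used_d[i] <- used_t[j] <- TRUE
        tp <- tp + 1L
      }
    }
  } else tp <- 0L
  confusion_counts(tp = tp, fp = length(detected) - tp,
                   fn = length(truth) - tp)
}
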