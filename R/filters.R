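#' Bandpass specification
#'
#' @param low_cut,high_cut band edges in Hz; `0 < low_cut < high_cut`
#'   and `high_cut` must stay below Nyquist at use time.
#' @param design `"butterworth"` for a 4th-order Butterworth bandpass
#'   (the 5--40 Hz detection chain), or `"butter_fir_combo"` for a
#'   Butterworth high-pass followed by a 12th-order FIR low-pass (the
#'   0.5--35 Hz classification chain).
#' @return An object of class `bandpass_spec`.
#' @export
bandpass_spec <- function(low_cut = 5, high_cut = 40,
                          design = c("butterworth", "butter_fir_combo")) {
  design <- match.arg(design)
  if (!(low_cut > 0 && high_cut > low_cut))
    stop("need 0 < low_cut < high_cut")
  structure(list(low_cut = low_cut, high_cut = high_cut, design = design),
            class = "bandpass_spec")
}

#' Zero-phase bandpass filtering
#'
#' Applies the chosen design forward and backward
#' ([signal::filtfilt()]), so the passband is traversed twice (doubling
#' the stopband attenuation in dB) and the net phase is zero — peaks do
#' not move, which matters when detections are scored against annotations
#' with a 30 ms tolerance.
#'
#' @param record an [ecg_record()] or numeric vector.
#' @param spec a [bandpass_spec()]; the default is the 5--40 Hz detection
#'   band.
#' @param fs sampling frequency when `record` is a bare vector.
#' @return filtered record of the same class and length as the input.
#' @export
bandpass_filter <- function(record, spec = bandpass_spec(), fs = NULL) {
  stopifnot(inherits(spec, "bandpass_spec"))
  is_rec <- inherits(record, "ecg_record")
  if (!is_rec && is.null(fs))
    stop("supply 'fs' for a bare numeric signal")
  if (is_rec) fs <- record$fs
  x <- as_record_samples(record)
  nyq <- fs / 2
  if (spec$high_cut >= nyq)
    stop("high_cut ", spec$high_cut, " Hz is at or above Nyquist (",
         nyq, " Hz)")
  if (spec$design == "butterworth") {
    bf <- signal::butter(4, c(spec$low_cut, spec$high_cut) / nyq,
                         type = "pass")
    y <- signal::filtfilt(bf, x)
  } else {
    hp <- signal::butter(4, spec$low_cut / nyq, type = "high")
    y <- signal::filtfilt(hp, x)
    lp <- signal::fir1(12, spec$high_cut / nyq, type = "low")
    y <- signal::filtfilt(as.numeric(lp), 1, y)
  }
  if (is_rec)
    ecg_record(y, fs, lead_name = record$lead_name,
               base_time = record$base_time)
  else y
}

#' Resample a record to a new rate
#'
#' Polyphase rational resampling ([signal::resample()]) after reducing
#' `target_fs / fs` to smallest terms (e.g. 360 to 260 Hz is 13/18).
#' Duration is preserved to within one sample.
#'
#' @param record an [ecg_record()].
#' @param target_fs new sampling frequency, Hz.
#' @return an [ecg_record()] at `target_fs`.
#' @export
resample_record <- function(record, target_fs = 260) {
  stopifnot(inherits(record, "ecg_record"))
  if (target_fs <= 0) stop("'target_fs' must be positive")
  if (target_fs == record$fs) return(record)
  frac <- rational_approx(target_fs / record$fs)
  y <- signal::resample(record$samples, frac[1], frac[2])
  n_target <- round(length(record$samples) * target_fs / record$fs)
  if (length(y) > n_target) y <- y[seq_len(n_target)]
  if (length(y) < n_target) y <- c(y, rep(y[length(y)],
                                          n_target - length(y)))
  ecg_record(y, target_fs, lead_name = record$lead_name,
             base_time = record$base_time)
}

# smallest p/q with |p/q - x| tiny, denominators up to 10000
rational_approx <- function(x, max_den = 10000L) {
  for (q in seq_len(max_den)) {
    p <- round(x * q)
    if (p >= 1 && abs(p / q - x) < 1e-9) return(c(p, q))
  }
  stop("cannot express rate ratio ", x, " as a small rational")
}

#' Cut fixed-length beat segments centred on R peaks
#'
#' Each segment spans `round(window_ms * fs / 1000)` samples, forced odd
#' by adding one when even so that "centred on the R peak" is exact: 65
#' samples for 250 ms at 260 Hz, 91 at 360 Hz.  Beats whose window would
#' cross a record boundary are dropped; the number dropped is attached as
#' the `dropped` attribute and reported via a warning.
#'
#' @param record an [ecg_record()].
#' @param r_peaks a [peak_set()] or numeric vector of R indices (1-based).
#' @param window_ms segment length in milliseconds (default 250).
#' @return list of numeric segments with attributes `dropped` (count) and
#'   `kept` (indices into the input peak vector that survived).
#' @export
segment_beats <- function(record, r_peaks, window_ms = 250) {
  stopifnot(inherits(record, "ecg_record"))
  r <- if (inherits(r_peaks, "peak_set")) r_peaks$r else as.numeric(r_peaks)
  if (length(r) == 0)
    return(structure(list(), dropped = 0L, kept = integer()))
  w <- odd_window(window_ms, record$fs)
  half <- (w - 1L) / 2L
  n <- length(record$samples)
  ok <- which(r - half >= 1 & r + half <= n)
  if (length(ok) < length(r))
    warning(length(r) - length(ok),
            " beat(s) dropped: window crosses the record boundary")
  segs <- lapply(r[ok], function(ri)
    record$samples[(ri - half):(ri + half)])
  structure(segs, dropped = length(r) - length(ok), kept = ok)
}

#' Normalise a beat segment onto the interval from -1 to 1
#'
#' Affine map sending the segment minimum to -1 and maximum to +1, making
#' downstream features independent of recording gain.  A constant
#' segment has no span to map; it returns all zeros (the midpoint) with
#' attribute `constant = TRUE` and a warning.
#'
#' @param segment numeric vector.
#' @return normalised vector with `min == -1`, `max == +1`.
#' @examples
#' normalize_segment(c(0, 5, 10))  # -1 0 1
#' @export
normalize_segment <- function(segment) {
  segment <- as.numeric(segment)
  rng <- range(segment)
  if (diff(rng) == 0) {
    warning("constant segment cannot be normalised; returning zeros")
    return(structure(rep(0, length(segment)), constant = TRUE))
  }
  2 * (segment - rng[1]) / diff(rng) - 1
}
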