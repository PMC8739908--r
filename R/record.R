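#' Construct a single-lead ECG record
#'
#' The basic container used throughout the package: a numeric vector of
#' amplitudes in millivolts together with its sampling frequency.  All
#' sample indices in the R API are 1-based; file formats that count from
#' zero (WFDB, the CSV `index` column) are translated at the I/O boundary.
#'
#' @param samples numeric vector of amplitudes, in mV. Must be finite and
#'   of length at least 2.
#' @param fs sampling frequency in Hz (> 0).
#' @param lead_name label of the recorded lead, e.g. `"MLII"`.
#' @param base_time optional acquisition start time (any scalar; carried
#'   along, never interpreted).
#' @return An object of class `ecg_record` with fields `samples`, `fs`,
#'   `lead_name` and `base_time`.
#' @examples
#' rec <- ecg_record(sin(2 * pi * 1 * seq(0, 2, by = 1/250)), fs = 250)
#' rec
#' @export
ecg_record <- function(samples, fs, lead_name = "MLII", base_time = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("an ECG record needs at least 2 samples")
  if (!all(is.finite(samples)))
    stop("ECG samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive number (Hz)")
  structure(
    list(samples = samples, fs = as.numeric(fs),
         lead_name = as.character(lead_name), base_time = base_time),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples @ %g Hz (%.2f s), lead %s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              x$lead_name))
  invisible(x)
}

#' @export
length.ecg_record <- function(x) length(x$samples)

#' Duration of an ECG record in seconds
#' @param record an [ecg_record()].
#' @return duration in seconds.
#' @export
record_duration <- function(record) length(record$samples) / record$fs

as_record_samples <- function(x) {
  if (inherits(x, "ecg_record")) x$samples else as.numeric(x)
}

#' Construct a set of detected or ground-truth fiducial peaks
#'
#' Holds the R, P and T peak sample positions (1-based) for one record.
#' Each component must be strictly increasing; `NA` entries are allowed in
#' `p` and `t` to mark beats where the corresponding wave was not found
#' (e.g. absent P waves in ventricular ectopy).
#'
#' @param r,p,t integer sample indices of R, P and T peaks.
#' @return An object of class `peak_set`.
#' @export
peak_set <- function(r = integer(), p = integer(), t = integer()) {
  chk <- function(v, nm, na_ok) {
    v <- as.numeric(v)
    if (!na_ok && anyNA(v)) stop("'", nm, "' peaks may not contain NA")
    vv <- v[!is.na(v)]
    if (length(vv) && (any(vv < 1) || is.unsorted(vv, strictly = TRUE)))
      stop("'", nm, "' peak indices must be strictly increasing and >= 1")
    v
  }
  structure(list(r = chk(r, "r", FALSE),
                 p = chk(p, "p", TRUE),
                 t = chk(t, "t", TRUE)),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> R: %d, P: %d (%d missing), T: %d (%d missing)\n",
              length(x$r),
              sum(!is.na(x$p)), sum(is.na(x$p)),
              sum(!is.na(x$t)), sum(is.na(x$t))))
  invisible(x)
}

#' Construct an annotation set
#'
#' Sample positions with per-position symbols, as read from or written to
#' WFDB annotation files or annotation CSVs.  Indices are 1-based and must
#' be strictly increasing; when `n_samples` is given each index must lie
#' inside the record.
#'
#' @param indices 1-based sample positions, strictly increasing.
#' @param symbols character labels, one per index (beat-class or wave-type
#'   codes such as `"N"`, `"V"`, `"p"`, `"t"`).
#' @param n_samples optional record length used to validate the indices.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(indices = integer(), symbols = character(),
                           n_samples = NULL) {
  indices <- as.numeric(indices)
  symbols <- as.character(symbols)
  if (length(indices) != length(symbols))
    stop("'indices' and 'symbols' must have equal length")
  if (length(indices)) {
    if (anyNA(indices) || any(indices < 1))
      stop("annotation indices must be >= 1 and non-missing")
    if (is.unsorted(indices, strictly = TRUE))
      stop("annotation indices must be strictly increasing")
    if (!is.null(n_samples) && any(indices > n_samples))
      stop("annotation index beyond record length (",
           max(indices), " > ", n_samples, ")")
  }
  structure(list(indices = indices, symbols = symbols),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d annotations (%s)\n", length(x$indices),
              paste(utils::head(unique(x$symbols), 6), collapse = " ")))
  invisible(x)
}

#' Confusion counts for detector and classifier evaluation
#'
#' @param tp,fp,fn,tn nonnegative counts. For peak detection `tn` is
#'   undefined and held at 0.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp = 0, fp = 0, fn = 0, tn = 0) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(v < 0) || anyNA(v)) stop("confusion counts must be nonnegative")
  structure(as.list(v), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%g FP=%g FN=%g TN=%g\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

# run an expression with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

odd_window <- function(ms, fs) {
  w <- round(ms * fs / 1000)
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  w
}
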