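#' Fit an autoregressive model to a beat segment
#'
#' Estimates the coefficients of `k(v) = sum_f x_f k(v-f) + eps(v)` on a
#' de-meaned segment.  Burg (the default) minimises forward and backward
#' prediction error and always yields a stationary model; Yule--Walker
#' and least-squares fits are available for comparison.  The innovation
#' variance is the residual variance of the one-step predictor.
#'
#' @param segment numeric vector, length > 3 * `order`.
#' @param order AR order `j` (>= 1).
#' @param method `"burg"`, `"yule_walker"` or `"least_squares"`.
#' @param demean subtract the segment mean before fitting (default TRUE;
#'   the model has no intercept).  Disable for data known to be zero-mean
#'   — e.g. a noise-free recursion, which the least-squares fit then
#'   recovers exactly, whereas Burg's backward-error term keeps even
#'   exact decaying recursions from reproducing their coefficients.
#' @return An object of class `ar_model` with fields `order`, `coeffs`
#'   and `noise_var`.
#' @export
fit_ar <- function(segment, order,
                   method = c("burg", "yule_walker", "least_squares"),
                   demean = TRUE) {
  method <- match.arg(method)
  segment <- as.numeric(segment)
  order <- as.integer(order)
  if (order < 1) stop("'order' must be >= 1")
  if (length(segment) <= 3 * order)
    stop("segment too short for order ", order,
         " (need > ", 3 * order, " samples)")
  if (stats::var(segment) == 0)
    stop("constant segment has no AR structure")
  fit <- switch(method,
    burg = stats::ar.burg(segment, aic = FALSE, order.max = order,
                          demean = demean, var.method = 1),
    yule_walker = stats::ar.yw(segment, aic = FALSE, order.max = order,
                               demean = demean),
    least_squares = stats::ar.ols(segment, aic = FALSE,
                                  order.max = order, demean = demean,
                                  intercept = FALSE))
  structure(list(order = order, coeffs = as.numeric(fit$ar),
                 noise_var = as.numeric(fit$var.pred), method = method),
            class = "ar_model")
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf("<ar_model> order %d (%s): %s; sigma^2 = %.4g\n",
              x$order, x$method,
              paste(sprintf("%.3f", x$coeffs), collapse = ", "),
              x$noise_var))
  invisible(x)
}

#' Prediction-error variance as a function of AR order
#'
#' The model-order selection curve: the one-step prediction-error
#' variance of the Burg (or other) fit at each order `1..max_order`.
#' For Burg the curve is non-increasing (nested models, reflection-
#' coefficient recursion).
#'
#' @param segment numeric vector.
#' @param max_order largest order to evaluate; must be below a third of
#'   the segment length.
#' @param method passed to [fit_ar()].
#' @return numeric vector of variances, one per order.
#' @export
prediction_error_curve <- function(segment, max_order = 10,
                                   method = "burg") {
  max_order <- as.integer(max_order)
  if (max_order >= length(segment) / 3)
    stop("'max_order' must be below length(segment)/3")
  vapply(seq_len(max_order),
         function(j) fit_ar(segment, j, method)$noise_var,
         numeric(1))
}

#' Knee-point model order selection
#'
#' Picks the order at the curve's breakpoint: the point of maximum
#' perpendicular distance from the chord joining the first and last
#' points of the error curve.  Ties (including exactly linear or flat
#' curves, where every distance is zero) resolve to the smallest order.
#'
#' @param curve numeric vector of prediction-error variances for orders
#'   `1..length(curve)`; length >= 3.
#' @return the selected integer order.
#' @examples
#' select_order_knee(c(10, 2, 1.9, 1.85, 1.84))  # 2
#' @export
select_order_knee <- function(curve) {
  m <- length(curve)
  if (m < 3) stop("'curve' must have length >= 3")
  x1 <- 1; y1 <- curve[1]; x2 <- m; y2 <- curve[m]
  xs <- seq_len(m)
  # distance to chord up to a common positive factor
  d <- abs((y2 - y1) * (xs - x1) - (x2 - x1) * (curve - y1))
  # linear/flat curves: every distance is roundoff -> smallest order
  if (max(d) <= 1e-9 * m * (1 + abs(y1) + abs(y2))) return(1L)
  which.max(d)  # which.max takes the first (smallest order) on ties
}

#' Group consecutive beats
#'
#' Non-overlapping runs of `group_size` consecutive beats; a trailing
#' partial group is dropped.
#'
#' @param r_peaks a [peak_set()] or vector of R indices.
#' @param group_size beats per group (default 2).
#' @return list of integer vectors of beat numbers.
#' @export
beat_groups <- function(r_peaks, group_size = 2L) {
  r <- if (inherits(r_peaks, "peak_set")) r_peaks$r else r_peaks
  group_size <- as.integer(group_size)
  if (group_size < 1) stop("'group_size' must be >= 1")
  ng <- length(r) %/% group_size
  lapply(seq_len(ng), function(i)
    ((i - 1L) * group_size + 1L):(i * group_size))
}

#' Extract AR + interval features per beat group
#'
#' For every group of `group_size` consecutive beats: the AR coefficients
#' of the samples running from the first beat's segment start to the last
#' beat's segment end, plus the RR interval within the group (averaged
#' over the group's consecutive pairs), and the PR and RT intervals of
#' the group's first beat (`NA` when that beat's P or T is missing).
#' Groups whose span crosses a record boundary are dropped.
#'
#' A morphology mode is also provided: per *beat*, the `[-1, 1]`
#' normalised segment samples (65 of them at 260 Hz) flattened next to
#' three RR characteristics (previous RR, next RR, and the beat's
#' deviation from the record's mean RR), the sampled-waveform feature
#' layout used by morphology-based classifiers.
#'
#' @param record a preprocessed [ecg_record()].
#' @param peaks a [peak_set()] with `r` (and ideally `p`, `t`) filled.
#' @param ar_order AR order for the feature fit (default 3).
#' @param group_size beats per group (default 2).
#' @param window_ms beat segment window, ms (default 250).
#' @param labels optional per-beat class labels carried into the output.
#' @param type `"ar"` (default) or `"morphology"`.
#' @param method AR estimation method, see [fit_ar()].
#' @return data.frame, one row per group (`"ar"`) or per beat
#'   (`"morphology"`), with feature columns and, when supplied, `label`.
#' @export
extract_features <- function(record, peaks, ar_order = 3L,
                             group_size = 2L, window_ms = 250,
                             labels = NULL,
                             type = c("ar", "morphology"),
                             method = "burg") {
  type <- match.arg(type)
  stopifnot(inherits(record, "ecg_record"), inherits(peaks, "peak_set"))
  fs <- record$fs
  r <- peaks$r
  if (length(r) < max(2L, group_size))
    stop("need at least ", max(2L, group_size), " R peaks")
  if (!is.null(labels) && length(labels) != length(r))
    stop("'labels' must have one entry per beat")
  w <- odd_window(window_ms, fs)
  half <- (w - 1L) / 2L
  n <- length(record$samples)

  if (type == "morphology") {
    segs <- segment_beats(record, peaks, window_ms)
    kept <- attr(segs, "kept")
    rr <- diff(r) / fs
    rr_prev <- c(NA, rr); rr_next <- c(rr, NA)
    mean_rr <- mean(rr)
    rows <- lapply(seq_along(segs), function(i) {
      b <- kept[i]
      c(normalize_segment(segs[[i]]),
        rr_prev = unname(rr_prev[b]), rr_next = unname(rr_next[b]),
        rr_dev = unname(ifelse(is.na(rr_prev[b]), NA,
                               rr_prev[b] - mean_rr)))
    })
    out <- as.data.frame(do.call(rbind, rows))
    names(out) <- c(paste0("m", seq_len(w)), "rr_prev", "rr_next",
                    "rr_dev")
    if (!is.null(labels)) out$label <- labels[kept]
    return(out)
  }

  groups <- beat_groups(peaks, group_size)
  rows <- list()
  for (g in groups) {
    first <- g[1]; last <- g[length(g)]
    lo <- r[first] - half; hi <- r[last] + half
    if (lo < 1 || hi > n) next
    seg <- record$samples[lo:hi]
    ar <- fit_ar(seg, ar_order, method)
    rr <- if (length(g) > 1) mean(diff(r[g])) / fs else
      if (first > 1) (r[first] - r[first - 1]) / fs else NA_real_
    pr <- if (!is.na(peaks$p[first])) (r[first] - peaks$p[first]) / fs
          else NA_real_
    rt <- if (!is.na(peaks$t[first])) (peaks$t[first] - r[first]) / fs
          else NA_real_
    row <- c(ar$coeffs, rr = rr, pr = pr, rt = rt)
    names(row)[seq_len(ar_order)] <- paste0("ar", seq_len(ar_order))
    rows[[length(rows) + 1L]] <-
      c(as.list(row), list(label = if (is.null(labels)) NA_character_
                           else labels[first]))
  }
  if (!length(rows)) stop("no complete beat group fits in the record")
  out <- do.call(rbind, lapply(rows, as.data.frame))
  if (is.null(labels)) out$label <- NULL
  rownames(out) <- NULL
  out
}
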