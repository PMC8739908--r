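#' Beat morphology template
#'
#' Describes one heartbeat as three Gaussian-shaped waves (P, QRS, T) plus,
#' for paced beats, a narrow stimulus spike.  Durations are in
#' milliseconds, amplitudes in millivolts; the Gaussian width of each wave
#' is `duration / 5`, so the stated duration covers roughly +-2.5 standard
#' deviations.  Defaults describe a fit individual: P duration 100 ms and
#' QT interval 400 ms, with the T peak placed at
#' `qt_interval - qrs_duration/2 - t_duration/2` after the R peak.
#'
#' Class presets emulate separable arrhythmia morphologies, not clinical
#' detail: `PVC` doubles the QRS duration and suppresses the P wave (with
#' a discordant T), `APC` is an early beat with a smaller, narrower P,
#' `LBBB`/`RBBB` widen the QRS with reduced amplitude (LBBB also inverts
#' the T), and `PACE` adds a narrow pacing spike ahead of the QRS.
#'
#' @param class_label one of `"regular"`, `"PVC"`, `"APC"`, `"LBBB"`,
#'   `"RBBB"`, `"PACE"`.
#' @param ... named overrides of any template field.
#' @return An object of class `beat_template`.
#' @examples
#' beat_template("PVC")
#' @export
beat_template <- function(class_label = "regular", ...) {
  class_label <- match.arg(class_label, beat_classes())
  tpl <- list(
    p_amplitude = 0.15, p_duration = 100,
    qrs_amplitude = 1.0, qrs_duration = 80,
    t_amplitude = 0.30, t_duration = 160,
    pr_interval = 160, qt_interval = 400,
    spike_amplitude = 0, spike_duration = 20, spike_lead = 40,
    rr_factor = 1,
    class_label = class_label)
  preset <- switch(class_label,
    regular = list(),
    PVC  = list(qrs_duration = 160, p_amplitude = 0, qrs_amplitude = 1.2,
                t_amplitude = -0.35),
    APC  = list(p_amplitude = 0.25, p_duration = 70, pr_interval = 140,
                rr_factor = 0.85),
    LBBB = list(qrs_duration = 140, qrs_amplitude = 0.8, t_amplitude = -0.3),
    RBBB = list(qrs_duration = 120, qrs_amplitude = 0.7, t_amplitude = 0.25),
    PACE = list(spike_amplitude = 0.7, qrs_duration = 100,
                qrs_amplitude = 0.9))
  tpl[names(preset)] <- preset
  override <- list(...)
  bad <- setdiff(names(override), names(tpl))
  if (length(bad)) stop("unknown template field(s): ",
                        paste(bad, collapse = ", "))
  tpl[names(override)] <- override
  validate_beat_template(tpl)
  structure(tpl, class = "beat_template")
}

#' The supported beat classes
#' @return character vector of class labels.
#' @export
beat_classes <- function()
  c("regular", "PVC", "APC", "LBBB", "RBBB", "PACE")

validate_beat_template <- function(tpl) {
  dur <- c(tpl$p_duration, tpl$qrs_duration, tpl$t_duration,
           tpl$pr_interval, tpl$qt_interval)
  if (any(dur <= 0)) stop("all template durations must be > 0")
  if (tpl$pr_interval <= tpl$p_duration / 2)
    stop("pr_interval must exceed half the P duration")
  if (tpl$qt_interval <= tpl$qrs_duration)
    stop("qt_interval must exceed the QRS duration")
  invisible(tpl)
}

#' Synthetic-ECG configuration
#'
#' @param fs sampling frequency in Hz; at least 80 Hz so the 5--40 Hz
#'   detection band stays below Nyquist.
#' @param duration_s record duration in seconds.
#' @param heart_rate beats per minute; a scalar, or a vector recycled over
#'   beats for per-beat rates.
#' @param baseline_wander_freq frequency of the sinusoidal baseline drift,
#'   in Hz; must be below 1 Hz (respiratory-band drift).
#' @param baseline_wander_amp drift amplitude in mV.
#' @param noise_std standard deviation of additive white noise, mV.
#' @param rr_jitter_frac i.i.d. Gaussian jitter on each beat period,
#'   as a fraction of the period (default 0.02).
#' @param seed integer RNG seed; a fixed seed makes the generated record
#'   bit-identical across calls.
#' @param beat_classes character vector of per-beat class labels, recycled
#'   over beats.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(fs = 360, duration_s = 30, heart_rate = 60,
                         baseline_wander_freq = 0.33,
                         baseline_wander_amp = 0.1,
                         noise_std = 0.02, rr_jitter_frac = 0.02,
                         seed = 1L, beat_classes = "regular") {
  if (fs < 80) stop("'fs' must be at least 80 Hz")
  if (duration_s <= 0) stop("'duration_s' must be positive")
  if (any(heart_rate <= 0)) stop("'heart_rate' must be positive")
  if (baseline_wander_freq >= 1 || baseline_wander_freq <= 0)
    stop("'baseline_wander_freq' must lie in (0, 1) Hz")
  if (baseline_wander_amp < 0 || noise_std < 0 || rr_jitter_frac < 0)
    stop("amplitudes, noise and jitter must be nonnegative")
  cls <- match.arg(beat_classes, termaecg::beat_classes(),
                   several.ok = TRUE)
  structure(list(fs = fs, duration_s = duration_s,
                 heart_rate = heart_rate,
                 baseline_wander_freq = baseline_wander_freq,
                 baseline_wander_amp = baseline_wander_amp,
                 noise_std = noise_std, rr_jitter_frac = rr_jitter_frac,
                 seed = as.integer(seed), beat_classes = beat_classes),
            class = "synth_config")
}

#' Generate a synthetic ECG record with exact ground truth
#'
#' Builds a quasi-periodic train of beats, each the sum of Gaussian-shaped
#' P, QRS and T waves (plus a pacing spike for `PACE` beats), then adds
#' sinusoidal baseline wander and white noise.  Wave centres are snapped
#' to the sample grid, so in the noiseless signal every ground-truth R
#' index is exactly the sample of maximum QRS amplitude, the P index
#' precedes its R by `round(pr_interval * fs / 1000)` samples, and the T
#' index follows it by
#' `round((qt_interval - qrs_duration/2 - t_duration/2) * fs / 1000)`.
#'
#' @param config a [synth_config()].
#' @param template_overrides named list mapping class labels to
#'   [beat_template()] objects replacing the built-in presets.
#' @return A list with components `record` (an [ecg_record()]) and
#'   `truth`, itself a list with `r_indices`, `p_indices`, `t_indices`
#'   (1-based; `NA` where the class suppresses the wave) and
#'   `beat_labels`.
#' @examples
#' cfg <- synth_config(duration_s = 10, noise_std = 0, rr_jitter_frac = 0,
#'                     baseline_wander_amp = 0)
#' sim <- generate_ecg(cfg)
#' length(sim$truth$r_indices)  # 10 beats at 60 bpm over 10 s
#' @export
generate_ecg <- function(config, template_overrides = list()) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs
  n <- round(fs * config$duration_s)
  templates <- lapply(stats::setNames(nm = beat_classes()), beat_template)
  for (nm in names(template_overrides)) {
    tpl <- template_overrides[[nm]]
    stopifnot(inherits(tpl, "beat_template"))
    templates[[nm]] <- tpl
  }
  max_qt <- max(vapply(templates, `[[`, numeric(1), "qt_interval"))
  if (any(60 / config$heart_rate < max_qt / 1000))
    stop("heart rate implies beat periods shorter than the QT interval")

  with_seed(config$seed, {
    # ---- beat timing -----------------------------------------------------
    hr <- config$heart_rate
    centres <- numeric(0); labels <- character(0)
    t_cur <- 0.5 * 60 / hr[1L]
    i <- 1L
    repeat {
      cls <- config$beat_classes[(i - 1L) %% length(config$beat_classes) + 1L]
      tpl <- templates[[cls]]
      if (i > 1L) {
        period <- 60 / hr[(i - 1L) %% length(hr) + 1L] * tpl$rr_factor
        jit <- if (config$rr_jitter_frac > 0)
          stats::rnorm(1L, 0, config$rr_jitter_frac * period) else 0
        t_cur <- t_cur + period + jit
      }
      tail_s <- (tpl$qt_interval - tpl$qrs_duration / 2) / 1000
      if (t_cur + tail_s > config$duration_s ||
          round(t_cur * fs) + 1 > n) break
      centres <- c(centres, t_cur); labels <- c(labels, cls)
      i <- i + 1L
    }
    nb <- length(centres)
    if (nb == 0L) stop("record too short to hold a single beat")

    # ---- wave synthesis --------------------------------------------------
    x <- numeric(n)
    r_idx <- p_idx <- t_idx <- rep(NA_real_, nb)
    add_wave <- function(x, centre_idx, amp, dur_ms) {
      if (amp == 0) return(x)
      sd_samp <- (dur_ms / 5) * fs / 1000
      lo <- max(1L, floor(centre_idx - 5 * sd_samp))
      hi <- min(n, ceiling(centre_idx + 5 * sd_samp))
      k <- lo:hi
      x[k] <- x[k] + amp * exp(-((k - centre_idx)^2) / (2 * sd_samp^2))
      x
    }
    for (b in seq_len(nb)) {
      tpl <- templates[[labels[b]]]
      rc <- round(centres[b] * fs) + 1
      r_idx[b] <- rc
      x <- add_wave(x, rc, tpl$qrs_amplitude, tpl$qrs_duration)
      if (tpl$p_amplitude != 0) {
        pc <- rc - round(tpl$pr_interval * fs / 1000)
        if (pc >= 1) {
          p_idx[b] <- pc
          x <- add_wave(x, pc, tpl$p_amplitude, tpl$p_duration)
        }
      }
      if (tpl$t_amplitude != 0) {
        toff <- tpl$qt_interval - tpl$qrs_duration / 2 - tpl$t_duration / 2
        tc <- rc + round(toff * fs / 1000)
        if (tc <= n) {
          t_idx[b] <- tc
          x <- add_wave(x, tc, tpl$t_amplitude, tpl$t_duration)
        }
      }
      if (tpl$spike_amplitude != 0) {
        sc <- rc - round(tpl$spike_lead * fs / 1000)
        x <- add_wave(x, sc, tpl$spike_amplitude, tpl$spike_duration)
      }
    }

    # ---- baseline wander and noise (after wave synthesis) ---------------
    tt <- (seq_len(n) - 1) / fs
    if (config$baseline_wander_amp > 0) {
      phase <- stats::runif(1L, 0, 2 * pi)
      x <- x + config$baseline_wander_amp *
        sin(2 * pi * config$baseline_wander_freq * tt + phase)
    }
    if (config$noise_std > 0)
      x <- x + stats::rnorm(n, 0, config$noise_std)

    list(record = ecg_record(x, fs),
         truth = list(r_indices = r_idx, p_indices = p_idx,
                      t_indices = t_idx, beat_labels = labels))
  })
}

#' Simulate an autoregressive process
#'
#' Generates `n` samples of the AR recursion
#' `k(v) = sum_f x_f k(v - f) + eps(v)` with white zero-mean innovations
#' of variance `noise_var`.  The coefficient polynomial must be
#' stationary (all characteristic roots outside the unit circle in the
#' `1 - x_1 z - ... - x_j z^j` parameterisation).  When `init` is
#' supplied the recursion starts deterministically from that state with
#' no burn-in; otherwise a burn-in of `200 + 10 * order` samples is
#' discarded.
#'
#' @param coeffs AR coefficients `x_1 .. x_j`; may be empty (white noise).
#' @param noise_var innovation variance (>= 0).
#' @param n number of samples to return.
#' @param seed integer RNG seed.
#' @param init optional numeric vector of initial values, most recent
#'   last, of length `length(coeffs)`.
#' @return numeric vector of length `n`.
#' @examples
#' x <- generate_ar_process(c(0.75, -0.5), 1, 500, seed = 42)
#' @export
generate_ar_process <- function(coeffs, noise_var, n, seed = 1L,
                                init = NULL) {
  coeffs <- as.numeric(coeffs)
  p <- length(coeffs)
  if (n <= p) stop("'n' must exceed the AR order")
  if (noise_var < 0) stop("'noise_var' must be nonnegative")
  if (p > 0) {
    roots <- polyroot(c(1, -coeffs))
    if (any(Mod(roots) <= 1 + 1e-10))
      stop("non-stationary AR coefficients (characteristic root on or ",
           "inside the unit circle)")
  }
  if (!is.null(init) && length(init) != p)
    stop("'init' must have length equal to the AR order")
  burn <- if (is.null(init)) 200L + 10L * p else 0L
  with_seed(seed, {
    eps <- if (noise_var > 0)
      stats::rnorm(n + burn, 0, sqrt(noise_var)) else numeric(n + burn)
    state <- if (is.null(init)) numeric(p) else rev(as.numeric(init))
    out <- numeric(n + burn)
    for (v in seq_len(n + burn)) {
      val <- eps[v]
      if (p > 0) val <- val + sum(coeffs * state)
      out[v] <- val
      if (p > 0) state <- c(val, state[-p])[seq_len(p)]
    }
    out[(burn + 1):(burn + n)]
  })
}
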