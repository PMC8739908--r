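# Orthogonal wavelet filter bank coefficients (decomposition low-pass).
# Standard published Daubechies / Symlet values.
wavelet_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255092145, 0.22414386804185735,
          0.836516303737469, 0.48296291314469025),
  db4 = c(-0.010597401785069032, 0.0328830116668852,
          0.030841381835560764, -0.18703481171909309,
          -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965),
  sym4 = c(-0.07576571478927333, -0.02963552764599851,
           0.49761866763201545, 0.8037387518059161,
           0.29785779560527736, -0.09921954357684722,
           -0.012603967262037833, 0.0322231006040427)
)

get_wavelet <- function(name) {
  lo <- wavelet_filters[[name]]
  if (is.null(lo)) stop("unknown wavelet: '", name, "' (supported: ",
                        paste(names(wavelet_filters), collapse = ", "), ")")
  m <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(m) - 1)  # quadrature mirror
  list(dec_lo = lo, dec_hi = hi, rec_lo = rev(lo), rec_hi = rev(hi),
       length = m)
}

# one periodised analysis step: x (even length) -> list(approx, detail)
dwt_step <- function(x, filt) {
  n <- length(x)
  half <- n %/% 2
  a <- numeric(half); d <- numeric(half)
  base <- 2 * (seq_len(half) - 1)            # 0-based start of each window
  for (m in seq_len(filt$length)) {
    idx <- (base + m - 1) %% n + 1
    a <- a + filt$dec_lo[m] * x[idx]
    d <- d + filt$dec_hi[m] * x[idx]
  }
  list(approx = a, detail = d)
}

# transpose (exact inverse for orthonormal filters)
idwt_step <- function(approx, detail, filt) {
  half <- length(approx)
  n <- 2 * half
  x <- numeric(n)
  base <- 2 * (seq_len(half) - 1)
  for (m in seq_len(filt$length)) {
    # for fixed m the targets 2k+m-1 (mod n) are n/2 distinct residues,
    # so plain indexed accumulation is collision-free
    idx <- (base + m - 1) %% n + 1
    x[idx] <- x[idx] + filt$dec_lo[m] * approx + filt$dec_hi[m] * detail
  }
  x
}

#' Periodised discrete wavelet transform
#'
#' Pyramidal analysis down to `level` scales with periodic boundary
#' handling; the signal length must be divisible by `2^level`.  The
#' transform is orthonormal, so [idwt()] reconstructs the input exactly
#' (to floating-point roundoff).
#'
#' @param x numeric signal, length divisible by `2^level`.
#' @param wavelet filter name (`"haar"`, `"db2"`, `"db4"`, `"sym4"`).
#' @param level number of decomposition scales (>= 1).
#' @return A list of class `dwt_decomp` with `approx` (the level-`level`
#'   approximation coefficients), `details` (list of detail coefficient
#'   vectors, scale 1 first), `wavelet` and `level`.
#' @export
dwt <- function(x, wavelet = "db4", level = 1L) {
  filt <- get_wavelet(wavelet)
  level <- as.integer(level)
  if (level < 1) stop("'level' must be >= 1")
  if (length(x) %% 2^level != 0)
    stop("signal length ", length(x), " not divisible by 2^", level)
  details <- vector("list", level)
  a <- as.numeric(x)
  for (l in seq_len(level)) {
    s <- dwt_step(a, filt)
    details[[l]] <- s$detail
    a <- s$approx
  }
  structure(list(approx = a, details = details, wavelet = wavelet,
                 level = level), class = "dwt_decomp")
}

#' Inverse periodised discrete wavelet transform
#'
#' @param decomp a `dwt_decomp` from [dwt()] (coefficients may have been
#'   modified, e.g. the approximation zeroed for baseline removal).
#' @return the reconstructed numeric signal.
#' @export
idwt <- function(decomp) {
  stopifnot(inherits(decomp, "dwt_decomp"))
  filt <- get_wavelet(decomp$wavelet)
  a <- decomp$approx
  for (l in rev(seq_len(decomp$level)))
    a <- idwt_step(a, decomp$details[[l]], filt)
  a
}

#' Centre frequency of a wavelet
#'
#' The dominant spectral frequency of the wavelet function, the
#' dimensionless factor that links decomposition scale to
#' pseudofrequency.  The wavelet function is approximated by the cascade
#' algorithm (reconstructing a unit detail coefficient through
#' `precision` synthesis levels) and the frequency of its spectral peak
#' is read off an FFT over the support of the filter.  For db4 this
#' evaluates to 0.714..., i.e. 0.7 to one decimal.
#'
#' @param wavelet filter name.
#' @param precision number of cascade refinement levels (default 10).
#' @return centre frequency, cycles per unit support (dimensionless).
#' @examples
#' round(wavelet_center_frequency("db4"), 1)  # 0.7
#' @export
wavelet_center_frequency <- function(wavelet = "db4", precision = 10L) {
  filt <- get_wavelet(wavelet)
  # cascade: psi ~ synthesis of a single detail coefficient at depth
  # `precision`; spacing between output samples is 2^-precision
  p <- filt$rec_hi
  for (l in seq_len(precision - 1L)) {
    up <- numeric(2L * length(p) - 1L)
    up[seq(1L, length(up), by = 2L)] <- p
    p <- stats::convolve(up, rev(filt$rec_lo), type = "open")
  }
  n <- length(p)
  domain <- n / 2^precision          # support length in wavelet time units
  spec <- Mod(stats::fft(p))
  kmax <- which.max(spec[2:(n %/% 2)])  # skip DC
  kmax / domain
}

#' Pseudofrequency of a wavelet decomposition scale
#'
#' `R_a = R_c * fs / 2^a`: the characteristic frequency associated with
#' scale `a` of a dyadic decomposition at sampling frequency `fs`, given
#' the wavelet's centre frequency `R_c`.
#'
#' @param r_c wavelet centre frequency (dimensionless).
#' @param fs sampling frequency, Hz.
#' @param a integer scale (>= 0).
#' @return pseudofrequency in Hz.
#' @examples
#' pseudofrequency(0.7, 360, 9)  # 0.492..., ~0.5 Hz
#' @export
pseudofrequency <- function(r_c, fs, a) {
  if (fs <= 0) stop("'fs' must be positive")
  if (any(a < 0) || any(a != round(a))) stop("'a' must be integer >= 0")
  r_c * fs / 2^a
}

#' Choose the decomposition depth that reaches the baseline-drift band
#'
#' Returns the smallest scale whose pseudofrequency, rounded to one
#' decimal, is at or below the drift frequency.  With db4
#' (`r_c = 0.7`) at 360 Hz and a 0.5 Hz drift target this gives scale 9.
#'
#' @param r_c wavelet centre frequency.
#' @param fs sampling frequency, Hz.
#' @param drift_freq target drift frequency, Hz (default 0.5, where the
#'   bulk of respiratory baseline wander sits).
#' @return integer scale.
#' @examples
#' select_baseline_scale(0.7, 360)  # 9
#' @export
select_baseline_scale <- function(r_c, fs, drift_freq = 0.5) {
  if (drift_freq <= 0) stop("'drift_freq' must be positive")
  a <- 1L
  while (round(pseudofrequency(r_c, fs, a), 1) > drift_freq) {
    a <- a + 1L
    if (a > 64L) stop("no scale reaches the drift band")
  }
  a
}

#' Wavelet plan for baseline removal
#'
#' Bundles the wavelet name, its centre frequency and the decomposition
#' depth targeted at the drift band.
#'
#' @param wavelet_name filter name (default `"db4"`).
#' @param drift_freq drift target in Hz (default 0.5).
#' @param max_scale optional explicit decomposition depth; computed from
#'   the centre frequency and `drift_freq` when `NULL`.
#' @param fs sampling frequency the plan is resolved against; may be left
#'   `NULL` and resolved at use time from the record.
#' @return An object of class `wavelet_plan`.
#' @export
wavelet_plan <- function(wavelet_name = "db4", drift_freq = 0.5,
                         max_scale = NULL, fs = NULL) {
  r_c <- wavelet_center_frequency(wavelet_name)
  if (!is.null(max_scale) && max_scale < 1)
    stop("'max_scale' must be >= 1")
  structure(list(wavelet_name = wavelet_name, center_freq = r_c,
                 drift_freq = drift_freq, max_scale = max_scale, fs = fs),
            class = "wavelet_plan")
}

#' Remove baseline wander with a dyadic wavelet decomposition
#'
#' Decomposes the record to the scale whose pseudofrequency reaches the
#' drift band (scale 9 for db4 at 360 Hz and a 0.5 Hz target) and zeroes
#' the coefficients carrying the drift before reconstructing.  Both the
#' deepest approximation *and* the deepest detail level are zeroed: the
#' scale-9 detail band is centred on the 0.5 Hz pseudofrequency where
#' most baseline wander lives, so removing the approximation alone would
#' leave the bulk of a 0.5 Hz drift in place (db4's short filters also
#' leak low-frequency energy across the scale-9 band edge).  The record
#' is padded by symmetric reflection to a multiple of `2^scale` before
#' the periodised transform and truncated back afterwards, so output
#' length equals input length.
#'
#' @param record an [ecg_record()] (or bare numeric vector plus `fs`).
#' @param plan a [wavelet_plan()]; default db4 targeting 0.5 Hz.
#' @param fs sampling frequency when `record` is a bare vector.
#' @return an [ecg_record()] with the drift removed.
#' @export
remove_baseline_dwt <- function(record, plan = wavelet_plan(), fs = NULL) {
  if (!inherits(record, "ecg_record")) {
    if (is.null(fs)) stop("supply 'fs' for a bare numeric signal")
    record <- ecg_record(record, fs)
  }
  stopifnot(inherits(plan, "wavelet_plan"))
  a <- plan$max_scale
  if (is.null(a))
    a <- select_baseline_scale(plan$center_freq, record$fs,
                               plan$drift_freq)
  x <- record$samples
  n <- length(x)
  if (n < 2^a)
    stop("record too short (", n, " samples) for scale ", a)
  block <- 2^a
  n_pad <- ceiling(n / block) * block
  if (n_pad > n) {
    # symmetric (reflective) padding on the right
    extra <- n_pad - n
    refl <- x[pmax(1L, n - seq_len(extra) + 1L)]
    xp <- c(x, refl)
  } else xp <- x
  dec <- dwt(xp, plan$wavelet_name, a)
  dec$approx[] <- 0
  dec$details[[a]][] <- 0
  y <- idwt(dec)[seq_len(n)]
  ecg_record(y, record$fs, lead_name = record$lead_name,
             base_time = record$base_time)
}
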