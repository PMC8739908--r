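#' Read an ECG record from WFDB or CSV
#'
#' Minimal readers for the two supported dialects.  WFDB records are read
#' from a header/signal file pair (`<record>.hea` + `<record>.dat`),
#' supporting signal formats 16 (16-bit little-endian) and 212 (packed
#' 12-bit pairs); raw ADC units are converted to millivolts as
#' `(adu - baseline) / gain`.  CSV files carry two columns `index,mv`
#' with 0-based sample numbers and require `fs_override` because the file
#' stores no sampling frequency.
#'
#' @param path for `format = "wfdb"`, the record path *without* extension;
#'   for `"csv"`, the file path.
#' @param format `"wfdb"` or `"csv"`.
#' @param fs_override sampling frequency in Hz; required for CSV, and when
#'   given for WFDB it overrides the header value.
#' @param channel which signal of a multi-channel WFDB record to load
#'   (default: the first).
#' @return An [ecg_record()].
#' @seealso [write_record()], [read_annotations()]
#' @export
read_record <- function(path, format = c("wfdb", "csv"),
                        fs_override = NULL, channel = 1L) {
  format <- match.arg(format)
  if (format == "csv") {
    if (is.null(fs_override))
      stop("CSV records carry no sampling frequency; supply 'fs_override'")
    if (!file.exists(path)) stop("no such file: ", path)
    df <- utils::read.csv(path)
    if (!all(c("index", "mv") %in% names(df)))
      stop("CSV record must have columns 'index' and 'mv'")
    if (nrow(df) >= 2 && is.unsorted(df$index, strictly = TRUE))
      stop("non-monotone sample index in ", path)
    ecg_record(df$mv, fs_override)
  } else {
    hea <- paste0(path, ".hea")
    if (!file.exists(hea)) stop("no such file: ", hea)
    h <- parse_wfdb_header(hea)
    if (channel < 1 || channel > h$n_sig)
      stop("channel ", channel, " not present (record has ",
           h$n_sig, " signals)")
    adc <- read_wfdb_signal(dirname(hea), h)
    sig <- h$signals[[channel]]
    mv <- (adc[, channel] - sig$baseline) / sig$gain
    ecg_record(mv, if (is.null(fs_override)) h$fs else fs_override,
               lead_name = sig$description)
  }
}

#' Write an ECG record to WFDB or CSV
#'
#' Inverse of [read_record()].  WFDB output uses signal format 16 with the
#' given gain (adu/mV) and zero baseline; amplitudes are quantised to
#' `round(mv * gain)`, so a read-back record equals the original up to
#' that quantisation.  CSV output stores `index,mv` with 0-based indices
#' at full double precision.
#'
#' @param record an [ecg_record()].
#' @param path record path without extension (WFDB) or file path (CSV).
#' @param format `"wfdb"` or `"csv"`.
#' @param gain ADC gain in adu per mV for WFDB output.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, format = c("wfdb", "csv"),
                         gain = 200) {
  format <- match.arg(format)
  stopifnot(inherits(record, "ecg_record"))
  if (format == "csv") {
    df <- data.frame(index = seq_along(record$samples) - 1L,
                     mv = record$samples)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    rn <- basename(path)
    n <- length(record$samples)
    adc <- as.integer(round(record$samples * gain))
    if (any(abs(adc) > 32767))
      stop("amplitudes overflow 16-bit range at gain ", gain)
    header <- c(
      sprintf("%s 1 %s %d", rn, format(record$fs), n),
      sprintf("%s.dat 16 %s(0)/mV 16 0 %d 0 0 %s",
              rn, format(gain), adc[1], record$lead_name))
    writeLines(header, paste0(path, ".hea"))
    con <- file(paste0(path, ".dat"), "wb")
    on.exit(close(con))
    writeBin(adc, con, size = 2L, endian = "little")
  }
  invisible(path)
}

parse_wfdb_header <- function(hea) {
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 3) stop("malformed WFDB header: ", hea)
  n_sig <- as.integer(top[2])
  fs <- as.numeric(sub("/.*$", "", top[3]))  # strip counter freq if any
  n_samp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  if (is.na(n_sig) || is.na(fs)) stop("malformed WFDB header: ", hea)
  sigs <- lapply(lines[1 + seq_len(n_sig)], function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) < 2) stop("malformed WFDB signal line: ", ln)
    fmt <- as.integer(sub("x.*$", "", sub(":.*$", "", sub("\\+.*$", "", tok[2]))))
    gain_spec <- if (length(tok) >= 3) tok[3] else "200"
    gain <- as.numeric(sub("\\(.*$", "", sub("/.*$", "", gain_spec)))
    if (is.na(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", gain_spec))
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_spec)) else 0
    desc <- if (length(tok) >= 9)
      paste(tok[9:length(tok)], collapse = " ") else "ECG"
    list(file = tok[1], format = fmt, gain = gain, baseline = baseline,
         description = desc)
  })
  fmts <- vapply(sigs, `[[`, numeric(1), "format")
  if (!all(fmts %in% c(16, 212)))
    stop("unsupported WFDB signal format(s): ",
         paste(setdiff(fmts, c(16, 212)), collapse = ", "))
  list(n_sig = n_sig, fs = fs, n_samp = n_samp, signals = sigs)
}

read_wfdb_signal <- function(dir, h) {
  dat <- file.path(dir, h$signals[[1]]$file)
  if (!file.exists(dat)) stop("no such file: ", dat)
  raw <- readBin(dat, "raw", n = file.info(dat)$size)
  fmt <- h$signals[[1]]$format
  if (fmt == 16) {
    v <- readBin(raw, "integer", n = length(raw) %/% 2, size = 2L,
                 signed = TRUE, endian = "little")
    matrix(v, ncol = h$n_sig, byrow = TRUE)
  } else {  # 212: 3 bytes -> 2 twelve-bit two's-complement samples
    nb <- (length(raw) %/% 3) * 3
    b <- as.integer(raw[seq_len(nb)])
    b0 <- b[seq(1, nb, 3)]; b1 <- b[seq(2, nb, 3)]; b2 <- b[seq(3, nb, 3)]
    s1 <- bitwAnd(b1, 15L) * 256L + b0
    s2 <- bitwAnd(b1 %/% 16L, 15L) * 256L + b2
    fix <- function(s) ifelse(s > 2047L, s - 4096L, s)
    v <- as.vector(rbind(fix(s1), fix(s2)))
    n_keep <- (length(v) %/% h$n_sig) * h$n_sig
    matrix(v[seq_len(n_keep)], ncol = h$n_sig, byrow = TRUE)
  }
}

# MIT annotation code table (subset relevant to beat classes and waves)
wfdb_ann_codes <- c(N = 1L, L = 2L, R = 3L, a = 4L, V = 5L, F = 6L,
                    J = 7L, A = 8L, S = 9L, E = 10L, j = 11L, "/" = 12L,
                    Q = 13L, p = 24L, t = 27L, e = 34L, f = 38L)

#' Map beat class labels to WFDB annotation symbols
#'
#' `regular` -> `N`, `PVC` -> `V`, `APC` -> `A`, `LBBB` -> `L`,
#' `RBBB` -> `R`, `PACE` -> `/`; unknown labels map to `Q`.
#'
#' @param labels character vector of class labels (or symbols for the
#'   inverse direction).
#' @param to `"symbol"` or `"class"`.
#' @return character vector.
#' @export
beat_class_symbols <- function(labels, to = c("symbol", "class")) {
  to <- match.arg(to)
  map <- c(regular = "N", PVC = "V", APC = "A", LBBB = "L", RBBB = "R",
           PACE = "/")
  if (to == "symbol") {
    out <- unname(map[labels]); out[is.na(out)] <- "Q"; out
  } else {
    inv <- stats::setNames(names(map), map)
    out <- unname(inv[labels]); out[is.na(out)] <- "regular"; out
  }
}

#' Read annotations from a WFDB annotation file or CSV
#'
#' WFDB (MIT) annotation files are streams of 16-bit little-endian words,
#' each a 6-bit type code plus a 10-bit time increment, with `SKIP`
#' pseudo-annotations carrying 32-bit increments and `NUM`/`SUB`/`CHN`/
#' `AUX` fields skipped over.  CSV annotation files carry two columns
#' `index,symbol` (0-based indices).
#'
#' @param path annotation file path (`.atr` or `.csv`).
#' @param format `"wfdb"` or `"csv"`.
#' @param n_samples optional record length for validation.
#' @return An [annotation_set()] (1-based indices).
#' @export
read_annotations <- function(path, format = c("wfdb", "csv"),
                             n_samples = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = c("integer", "character"))
    if (nrow(df) == 0)
      return(annotation_set(n_samples = n_samples))
    return(annotation_set(df$index + 1L, df$symbol, n_samples))
  }
  raw <- readBin(path, "raw", n = file.info(path)$size)
  w <- readBin(raw, "integer", n = length(raw) %/% 2, size = 2L,
               signed = FALSE, endian = "little")
  sym_tab <- stats::setNames(names(wfdb_ann_codes), wfdb_ann_codes)
  idx <- numeric(0); sym <- character(0)
  time <- 0; i <- 1L
  while (i <= length(w)) {
    code <- w[i] %/% 1024L
    inc <- w[i] %% 1024L
    if (code == 0L && inc == 0L) break            # EOF
    if (code == 59L) {                            # SKIP: 32-bit increment
      if (i + 2L > length(w)) stop("truncated SKIP in ", path)
      hi <- w[i + 1L]; lo <- w[i + 2L]
      val <- hi * 65536 + lo
      if (val >= 2^31) val <- val - 2^32
      time <- time + val
      i <- i + 3L
      next
    }
    if (code %in% c(60L, 61L, 62L)) { i <- i + 1L; next }  # NUM/SUB/CHN
    if (code == 63L) {                            # AUX: skip payload
      i <- i + 1L + (inc + inc %% 2L) %/% 2L
      next
    }
    time <- time + inc
    idx <- c(idx, time + 1)                       # 0-based file -> 1-based
    s <- sym_tab[as.character(code)]
    sym <- c(sym, if (is.na(s)) "Q" else unname(s))
    i <- i + 1L
  }
  annotation_set(idx, sym, n_samples)
}

#' Write annotations to a WFDB annotation file or CSV
#'
#' Inverse of [read_annotations()].
#'
#' @param annotations an [annotation_set()].
#' @param path output file path.
#' @param format `"wfdb"` or `"csv"`.
#' @param n_samples optional record length; indices beyond it are an error.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path,
                              format = c("wfdb", "csv"),
                              n_samples = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(annotations, "annotation_set"))
  if (!is.null(n_samples) && length(annotations$indices) &&
      any(annotations$indices > n_samples))
    stop("annotation index beyond record length")
  if (format == "csv") {
    df <- data.frame(index = as.integer(annotations$indices) - 1L,
                     symbol = annotations$symbols)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  codes <- wfdb_ann_codes[annotations$symbols]
  codes[is.na(codes)] <- wfdb_ann_codes[["Q"]]
  t0 <- c(0, annotations$indices[-length(annotations$indices)] - 1)
  incs <- (annotations$indices - 1) - t0
  words <- integer(0)
  for (k in seq_along(incs)) {
    d <- incs[k]
    if (d > 1023) {
      val <- as.integer(d)
      words <- c(words, 59L * 1024L, val %/% 65536L, val %% 65536L,
                 codes[k] * 1024L)
    } else {
      words <- c(words, codes[k] * 1024L + as.integer(d))
    }
  }
  words <- c(words, 0L)                            # EOF word
  con <- file(path, "wb")
  on.exit(close(con))
  # writeBin has no unsigned 16-bit type; emit the two bytes directly
  lo <- words %% 256L; hi <- words %/% 256L
  writeBin(as.raw(as.vector(rbind(lo, hi))), con)
  invisible(path)
}

#' Write detected peaks as an annotation CSV
#'
#' Emits one row per beat with columns `beat,p_idx,r_idx,t_idx` (0-based
#' indices, empty where missing), the format produced by the `detect`
#' command-line stage.
#'
#' @param peaks a [peak_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_peaks_csv <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_set"))
  nb <- length(peaks$r)
  pad <- function(v) { length(v) <- nb; v }
  df <- data.frame(beat = seq_len(nb),
                   p_idx = pad(peaks$p) - 1,
                   r_idx = peaks$r - 1,
                   t_idx = pad(peaks$t) - 1)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
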