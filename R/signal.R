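#' Single-channel electrophysiology trace
#'
#' Container for a raw or preprocessed single-channel recording, e.g. a
#' local field potential.  Amplitudes are in arbitrary units before
#' preprocessing and dimensionless in \eqn{[-1, 1]} afterwards.
#'
#' @param samples numeric vector of amplitudes.
#' @param fs_hz sampling rate in Hz (> 0).
#' @param preprocessed logical; set by [preprocess()].
#' @param ground_truth optional [ground_truth()] stage annotation.
#' @return An object of class `signal_record`.
#' @seealso [preprocess()], [simulate_sle_lfp()], [read_signal_csv()]
#' @export
signal_record <- function(samples, fs_hz, preprocessed = FALSE,
                          ground_truth = NULL) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || !is.finite(fs_hz) ||
      fs_hz <= 0)
    stop("'fs_hz' must be a single positive number")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("'samples' must be finite and non-missing")
  if (!is.null(ground_truth) && !inherits(ground_truth, "ground_truth"))
    stop("'ground_truth' must be a ground_truth object or NULL")
  structure(
    list(samples = samples, fs_hz = fs_hz,
         preprocessed = isTRUE(preprocessed), ground_truth = ground_truth),
    class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("signal_record: %d samples @ %g Hz (%.1f s)%s\n",
              length(x$samples), x$fs_hz, length(x$samples) / x$fs_hz,
              if (x$preprocessed) ", preprocessed" else ""))
  if (!is.null(x$ground_truth))
    cat(sprintf("  ground truth: %d stage interval(s), EcSOT = %s s\n",
                nrow(x$ground_truth$stage_intervals),
                format(x$ground_truth$ecsot_s)))
  invisible(x)
}

#' Read a two-column signal file
#'
#' Reads a plain-text file with columns `time_s, amplitude` (header
#' optional).  The sampling rate is taken from the median time step.
#'
#' @param path file path.
#' @param fs_hz sampling rate; if `NULL`, inferred from the time column.
#' @return A [signal_record()].
#' @export
read_signal_csv <- function(path, fs_hz = NULL) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  d <- read.csv(path, header = has_header)
  if (ncol(d) < 2L) stop("expected two columns: time_s, amplitude")
  tm <- as.numeric(d[[1L]]); amp <- as.numeric(d[[2L]])
  if (is.null(fs_hz)) {
    dt <- stats::median(diff(tm))
    if (!is.finite(dt) || dt <= 0) stop("cannot infer sampling rate")
    fs_hz <- 1 / dt
  }
  signal_record(amp, fs_hz)
}

#' Write a signal to a two-column CSV
#'
#' @param sig a [signal_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(sig, path) {
  stopifnot(inherits(sig, "signal_record"))
  d <- data.frame(time_s = (seq_along(sig$samples) - 1) / sig$fs_hz,
                  amplitude = sig$samples)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Preprocess a raw recording
#'
#' Removes the DC component, notch-filters the mains frequency and its
#' harmonics with a linear-phase FIR filter, and rescales the amplitude so
#' that `max(abs(samples)) == 1`.
#'
#' The notch filter is a single multiband FIR (windowed frequency-sampling
#' design) with stop bands of width `2 * notch_halfwidth_hz` centred on
#' `mains_hz` and every harmonic below Nyquist; it is applied by FFT
#' convolution and the group delay is compensated, so the output is
#' aligned with the input.
#'
#' @param raw a [signal_record()], at least 2 s long, sampled at 800 Hz
#'   or faster.
#' @param mains_hz mains frequency whose harmonics are removed (default
#'   60 Hz).
#' @param notch_halfwidth_hz half-width of each stop band in Hz.
#' @param n_taps FIR length (odd; reduced automatically for short
#'   signals).
#' @return A [signal_record()] with `preprocessed = TRUE`, zero mean and
#'   peak amplitude 1.
#' @export
preprocess <- function(raw, mains_hz = 60, notch_halfwidth_hz = 2,
                       n_taps = 4097) {
  stopifnot(inherits(raw, "signal_record"))
  x <- raw$samples; fs <- raw$fs_hz
  if (length(x) < 2 * fs) stop("signal shorter than 2 s")
  if (fs < 800) stop("sampling rate below 800 Hz is not supported")
  if (max(x) - min(x) <= 0) stop("constant signal cannot be normalized")

  x <- x - mean(x)

  harmonics <- seq(mains_hz, fs / 2 - notch_halfwidth_hz, by = mains_hz)
  if (length(harmonics)) {
    n_taps <- min(n_taps, 2 * (length(x) %/% 3) + 1)
    if (n_taps %% 2 == 0) n_taps <- n_taps - 1
    h <- .design_notch_fir(fs, harmonics, notch_halfwidth_hz, n_taps)
    x <- .fft_filter_zero_phase(x, h)
  }

  x <- x - mean(x)
  x <- x / max(abs(x))
  signal_record(x, fs, preprocessed = TRUE, ground_truth = raw$ground_truth)
}

# multiband notch FIR via signal::fir2 with a dense interpolation grid
.design_notch_fir <- function(fs, harmonics, halfwidth, n_taps) {
  nyq <- fs / 2
  f <- 0; m <- 1
  for (h in harmonics) {
    lo <- (h - halfwidth) / nyq; hi <- (h + halfwidth) / nyq
    f <- c(f, lo - 1e-4, lo, hi, hi + 1e-4)
    m <- c(m, 1, 0, 0, 1)
  }
  f <- c(f, 1); m <- c(m, 1)
  signal::fir2(n_taps - 1, f, m, grid_n = max(8192, 2^ceiling(log2(n_taps))))
}

# linear-phase FIR applied by FFT convolution; the signal is
# reflect-padded by the (odd) filter's group delay (nh-1)/2 on both ends
# to suppress start-up transients, and the delay is removed so the output
# aligns with the input
.fft_filter_zero_phase <- function(x, h) {
  n <- length(x); nh <- length(h)
  delay <- (nh - 1) / 2
  p <- min(delay, n - 1L)
  xp <- c(2 * x[1L] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
  np <- length(xp)
  nfft <- nextn(np + nh - 1, 2)
  y <- Re(fft(fft(c(xp, rep(0, nfft - np))) *
             fft(c(h, rep(0, nfft - nh))), inverse = TRUE)) / nfft
  y[(delay + p + 1):(delay + p + n)]
}

#' Read one channel from an EDF recording
#'
#' Minimal reader for the European Data Format (EDF/EDF+C): fixed-layout
#' ASCII header followed by 16-bit little-endian data records, converted
#' to physical units by each channel's calibration.  Discontinuous
#' (EDF+D) files are not supported.
#'
#' @param path EDF file path.
#' @param channel channel index or label.
#' @return A [signal_record()] with the channel's samples and sampling
#'   rate.
#' @export
read_signal_edf <- function(path, channel = 1L) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  rd(8)                                   # version
  rd(80); rd(80)                          # patient / recording id
  rd(8); rd(8)                            # start date / time
  header_bytes <- as.integer(rd(8))
  rd(44)                                  # reserved
  n_records <- as.integer(rd(8))
  record_s <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (!is.finite(ns) || ns < 1L) stop("malformed EDF header")

  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  vapply(seq_len(ns), function(i) rd(80), character(1))  # transducer
  vapply(seq_len(ns), function(i) rd(8), character(1))   # unit
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  vapply(seq_len(ns), function(i) rd(80), character(1))  # prefiltering
  nspr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  vapply(seq_len(ns), function(i) rd(32), character(1))  # reserved

  ch <- if (is.character(channel)) match(channel, labels) else as.integer(channel)
  if (is.na(ch) || ch < 1L || ch > ns) stop("channel not found")
  seek(con, header_bytes)

  gain <- (pmax_[ch] - pmin_[ch]) / (dmax_[ch] - dmin_[ch])
  offset <- pmin_[ch] - gain * dmin_[ch]
  out <- vector("list", n_records)
  for (r in seq_len(n_records)) {
    rec <- readBin(con, "integer", sum(nspr), size = 2L,
                   signed = TRUE, endian = "little")
    lo <- if (ch > 1L) sum(nspr[seq_len(ch - 1L)]) else 0L
    out[[r]] <- rec[(lo + 1L):(lo + nspr[ch])]
  }
  x <- gain * unlist(out, use.names = FALSE) + offset
  signal_record(x, nspr[ch] / record_s)
}

# minimal single-channel EDF writer (testing aid for the reader)
.write_edf <- function(sig, path, label = "LFP", record_s = 1) {
  x <- sig$samples
  nspr <- as.integer(round(sig$fs_hz * record_s))
  n_records <- ceiling(length(x) / nspr)
  x <- c(x, rep(0, n_records * nspr - length(x)))
  # physical limits are stored as 8-char ASCII; digitize against the
  # stored (rounded) values so read-back error stays at half an LSB
  pmin_ <- floor(min(x) * 1000) / 1000
  pmax_ <- ceiling(max(x) * 1000) / 1000
  if (pmax_ <= pmin_) pmax_ <- pmin_ + 1
  dig <- as.integer(round((x - pmin_) / (pmax_ - pmin_) * 65535 - 32768))
  dig <- pmin(pmax(dig, -32768L), 32767L)

  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(s, n) {
    s <- substr(format(s), 1L, n)
    writeChar(sprintf("%-*s", n, s), con, n, eos = NULL)
  }
  pad("0", 8); pad("X", 80); pad("X", 80)
  pad("01.01.26", 8); pad("00.00.00", 8)
  pad(256 + 256, 8); pad("", 44)
  pad(n_records, 8); pad(format(record_s), 8); pad(1, 4)
  pad(label, 16); pad("", 80); pad("au", 8)
  pad(sprintf("%.3f", pmin_), 8); pad(sprintf("%.3f", pmax_), 8)
  pad("-32768", 8); pad("32767", 8)
  pad("", 80); pad(nspr, 8); pad("", 32)
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}
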