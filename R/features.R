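#' Physiological frequency bands
#'
#' The seven bands used as the wavelet feature space.  The delta band is
#' bounded below at 0.5 Hz to keep the wavelet scale grid finite.
#'
#' @return A `band_set`: a data frame with columns `name`, `low_hz`,
#'   `high_hz`, one row per band, ordered by lower edge.
#' @export
default_bands <- function() {
  band_set(data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma", "super_gamma",
             "fast_ripple"),
    low_hz  = c(0.5, 4,  8, 15,  40, 100, 250),
    high_hz = c(4,   8, 15, 40, 100, 250, 400)))
}

#' Construct a validated band set
#'
#' @param bands data frame with columns `name`, `low_hz`, `high_hz`.
#' @return The validated data frame with class `band_set`.
#' @export
band_set <- function(bands) {
  stopifnot(is.data.frame(bands),
            all(c("name", "low_hz", "high_hz") %in% names(bands)))
  if (any(bands$high_hz <= bands$low_hz))
    stop("each band must have high_hz > low_hz")
  if (is.unsorted(bands$low_hz, strictly = TRUE))
    stop("bands must be ordered by increasing low_hz")
  if (nrow(bands) > 1L &&
      any(bands$low_hz[-1L] < bands$high_hz[-nrow(bands)]))
    stop("bands must not overlap")
  class(bands) <- c("band_set", "data.frame")
  bands
}

#' Per-window feature matrix
#'
#' @param x T x D numeric matrix of feature vectors, one row per window;
#'   column names label the bands (and their rate-of-change columns).
#' @param window_s window length in seconds.
#' @param times_s window start times (length T).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(x, window_s = 1, times_s = NULL) {
  x <- as.matrix(x)
  if (anyNA(x) || any(!is.finite(x)))
    stop("feature matrix must be finite and non-missing")
  if (is.null(times_s)) times_s <- (seq_len(nrow(x)) - 1) * window_s
  if (length(times_s) != nrow(x))
    stop("'times_s' must have one entry per window")
  structure(list(x = x, window_s = window_s, times_s = as.numeric(times_s)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d windows x %d features (window %g s)\n",
              nrow(x$x), ncol(x$x), x$window_s))
  cat("  features:", paste(colnames(x$x), collapse = ", "), "\n")
  invisible(x)
}

# coerce feature_matrix | matrix -> plain matrix
.fm_matrix <- function(f) {
  if (inherits(f, "feature_matrix")) f$x else as.matrix(f)
}

#' Morlet wavelet band features per window
#'
#' Computes the continuous wavelet transform of a preprocessed signal with
#' an analytic Morlet mother wavelet (centre frequency `omega0 = 6`,
#' unit-energy scale normalization) on a per-band geometric grid of
#' scales, and summarizes each non-overlapping window and band by the mean
#' absolute wavelet coefficient.
#'
#' The scale-to-frequency map is `f = omega0 * fs / (2 * pi * s)` with `s`
#' in samples.  Bands whose lower edge reaches the Nyquist frequency are
#' dropped with a warning.
#'
#' @param sig a preprocessed [signal_record()].
#' @param bands a [band_set()]; defaults to the seven bands of
#'   [default_bands()].
#' @param window_s window length in seconds (default 1; `window_s * fs`
#'   must be a positive integer).
#' @param scales_per_band number of wavelet scales per band (>= 6).
#' @return A [feature_matrix()] with one column per retained band.
#' @export
cwt_band_features <- function(sig, bands = default_bands(), window_s = 1,
                              scales_per_band = 6) {
  stopifnot(inherits(sig, "signal_record"))
  if (!isTRUE(sig$preprocessed))
    stop("signal must be preprocessed before feature extraction")
  if (!inherits(bands, "band_set")) bands <- band_set(bands)
  fs <- sig$fs_hz
  win_n <- window_s * fs
  if (abs(win_n - round(win_n)) > 1e-8 || win_n < 1)
    stop("'window_s' times the sampling rate must be a positive integer")
  win_n <- as.integer(round(win_n))
  scales_per_band <- max(2L, as.integer(scales_per_band))

  keep <- bands$low_hz < fs / 2
  if (!all(keep)) {
    warning("dropping band(s) above Nyquist: ",
            paste(bands$name[!keep], collapse = ", "))
    bands <- bands[keep, , drop = FALSE]
  }
  if (!nrow(bands)) stop("no band lies below the Nyquist frequency")

  x <- sig$samples
  n <- length(x)
  n_windows <- n %/% win_n
  if (n_windows < 1L) stop("signal shorter than one window")

  omega0 <- 6
  nfft <- nextn(n, 2)
  xf <- fft(c(x, rep(0, nfft - n)))
  # angular frequency grid of the padded FFT (positive half only matters)
  wk <- 2 * pi * (0:(nfft - 1)) / nfft
  wk[wk > pi] <- 0          # analytic wavelet: kill negative frequencies
  pos <- wk > 0

  grp <- rep(seq_len(n_windows), each = win_n)
  used <- seq_len(n_windows * win_n)

  feat <- matrix(0, n_windows, nrow(bands),
                 dimnames = list(NULL, bands$name))
  for (b in seq_len(nrow(bands))) {
    hi <- min(bands$high_hz[b], fs / 2)
    freqs <- exp(seq(log(bands$low_hz[b]), log(hi),
                     length.out = scales_per_band))
    acc <- numeric(n)
    for (f0 in freqs) {
      s <- omega0 * fs / (2 * pi * f0)    # scale in samples
      psi_hat <- numeric(nfft)
      psi_hat[pos] <- sqrt(2 * pi * s) * pi^(-0.25) *
        exp(-((s * wk[pos] - omega0)^2) / 2)
      w <- fft(xf * psi_hat, inverse = TRUE)[seq_len(n)] / nfft
      acc <- acc + Mod(w)
    }
    acc <- acc / length(freqs)
    feat[, b] <- rowsum(acc[used], grp) / win_n
  }
  feature_matrix(feat, window_s = window_s)
}

#' Append rate-of-change features
#'
#' Extends a 7-D (or generally D-band) coefficient matrix with the first
#' difference of each column from the previous window; the first window's
#' rate of change is 0 so feature and label sequences stay aligned.
#'
#' @param f a [feature_matrix()] of plain band coefficients.
#' @return A [feature_matrix()] with twice as many columns; the new
#'   columns are named `d_<band>`.
#' @export
append_rate_of_change <- function(f) {
  stopifnot(inherits(f, "feature_matrix"))
  if (any(startsWith(colnames(f$x), "d_")))
    stop("rate-of-change columns already present")
  x <- f$x
  dc <- rbind(0, diff(x))
  colnames(dc) <- paste0("d_", colnames(x))
  feature_matrix(cbind(x, dc), window_s = f$window_s, times_s = f$times_s)
}

#' Write features to CSV
#'
#' @param f a [feature_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(f, path) {
  stopifnot(inherits(f, "feature_matrix"))
  d <- cbind(data.frame(window_start_s = f$times_s), as.data.frame(f$x))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read features from CSV
#'
#' @param path a file written by [write_features_csv()].
#' @return A [feature_matrix()].
#' @export
read_features_csv <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  if (names(d)[1L] != "window_start_s")
    stop("expected first column 'window_start_s'")
  times <- d[[1L]]
  x <- as.matrix(d[, -1L, drop = FALSE])
  ws <- if (length(times) > 1L) stats::median(diff(times)) else 1
  feature_matrix(x, window_s = ws, times_s = times)
}
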