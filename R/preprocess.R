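# Window preprocessing: a raw 14 x 128 window becomes the 14 x 64 network
# input. Inertial channels are smoothed by overlapping piecewise quadratic
# fits and down-sampled; sEMG channels are denoised in frequency/amplitude
# and compressed through a 4-level db5 discrete wavelet transform.

RAW_WINDOW_LEN <- 128L
PP_LEN <- 64L

#' Piecewise quadratic smoother configuration
#'
#' @param unit_length points per fitting unit.
#' @param overlap points shared by adjacent units; overlapping fits are
#'   averaged to remove jumps at unit boundaries.
#' @param downsample_factor keep every `downsample_factor`-th point.
#' @export
smoother_config <- function(unit_length = 16L, overlap = 2L,
                            downsample_factor = 2L) {
  unit_length <- as.integer(unit_length)
  overlap <- as.integer(overlap)
  if (!(unit_length > overlap && overlap >= 0L)) {
    stop_config("need unit_length > overlap >= 0")
  }
  stride <- unit_length - overlap
  if ((RAW_WINDOW_LEN - unit_length) %% stride != 0L) {
    stop_config("unit/overlap scheme must tile a ", RAW_WINDOW_LEN,
                "-point window exactly")
  }
  structure(list(unit_length = unit_length, overlap = overlap,
                 downsample_factor = as.integer(downsample_factor)),
            class = "slr_smoother_config")
}

#' sEMG wavelet compression configuration
#'
#' @param family wavelet family; only `"db5"` is built in.
#' @param levels decomposition depth.
#' @param noise_cutoff_hz frequency below which content is treated as noise
#'   and removed before the transform.
#' @param amplitude_floor samples with absolute value below this are zeroed;
#'   `NULL` means 3 x the channel's median absolute deviation.
#' @param extend how the decomposition is brought to 64 points:
#'   `"interp"` linearly interpolates the deepest approximation band,
#'   `"concat"` concatenates approximation and detail coefficients.
#' @param sample_rate sampling rate in Hz.
#' @export
wavelet_config <- function(family = "db5", levels = 4L, noise_cutoff_hz = 15,
                           amplitude_floor = NULL,
                           extend = c("interp", "concat"), sample_rate = 100) {
  if (!identical(family, "db5")) stop_config("only the db5 family is supported")
  levels <- as.integer(levels)
  if (levels < 1L) stop_config("levels must be >= 1")
  if (RAW_WINDOW_LEN %% 2L^levels != 0L || RAW_WINDOW_LEN / 2L^levels < 4L) {
    stop_config("levels too deep for a ", RAW_WINDOW_LEN, "-point window")
  }
  if (noise_cutoff_hz >= sample_rate / 2) {
    stop_config("noise_cutoff_hz must be below the Nyquist frequency")
  }
  structure(list(family = family, levels = levels,
                 noise_cutoff_hz = noise_cutoff_hz,
                 amplitude_floor = amplitude_floor,
                 extend = match.arg(extend), sample_rate = sample_rate),
            class = "slr_wavelet_config")
}

#' Least-squares quadratic fit on one unit
#'
#' Fits `y = A n^2 + B n + C` over `n = 1..length(points)` by minimizing the
#' sum of squared residuals. Exact for data already quadratic in `n`.
#'
#' @param points numeric vector (one smoothing unit).
#' @return named vector `c(A, B, C)`.
#' @export
fit_quadratic_unit <- function(points) {
  if (!all(is.finite(points))) stop_config("non-finite values in unit")
  n <- seq_along(points)
  X <- cbind(n^2, n, 1)
  beta <- unname(qr.solve(X, points))
  c(A = beta[1], B = beta[2], C = beta[3])
}

#' Smooth and down-sample one inertial channel
#'
#' The 128-point channel is tiled by overlapping units (default 16 points,
#' 2-point overlap), each fit with a quadratic; the reconstruction evaluates
#' the fitted polynomials, averaging where units overlap, and keeps every
#' other point.
#'
#' @param channel numeric vector of length 128.
#' @param cfg a [smoother_config()].
#' @return numeric vector of length 64.
#' @export
smooth_inertial_channel <- function(channel, cfg = smoother_config()) {
  if (length(channel) != RAW_WINDOW_LEN) {
    stop_config("channel must have exactly ", RAW_WINDOW_LEN, " points")
  }
  u <- cfg$unit_length
  stride <- u - cfg$overlap
  starts <- seq(1L, RAW_WINDOW_LEN - u + 1L, by = stride)
  acc <- numeric(RAW_WINDOW_LEN)
  cnt <- numeric(RAW_WINDOW_LEN)
  n <- seq_len(u)
  for (s in starts) {
    idx <- s:(s + u - 1L)
    co <- fit_quadratic_unit(channel[idx])
    acc[idx] <- acc[idx] + co["A"] * n^2 + co["B"] * n + co["C"]
    cnt[idx] <- cnt[idx] + 1
  }
  recon <- acc / cnt
  recon[seq(1L, RAW_WINDOW_LEN, by = cfg$downsample_factor)]
}

# ---- discrete wavelet transform (db5, periodized) -------------------------

# Daubechies-5 decomposition low-pass filter (orthonormal, 10 taps).
DB5_LO <- c(0.0033357252854737712, -0.012580751999081999,
            -0.006241490212798274, 0.07757149384004572,
            -0.032244869584638375, -0.24229488706638203,
            0.13842814590132074, 0.7243085284377729,
            0.6038292697971896, 0.16010239797419293)
# Quadrature mirror high-pass filter.
DB5_HI <- rev(DB5_LO) * (-1)^seq_along(DB5_LO)

# One periodized analysis step; returns approximation and detail halves.
# Energy-preserving (orthonormal filter bank on the circle).
dwt_step_per <- function(x) {
  n <- length(x)
  stopifnot(n %% 2L == 0L)
  m <- length(DB5_LO)
  half <- n / 2L
  cA <- numeric(half)
  cD <- numeric(half)
  for (k in seq_len(half)) {
    # circular convolution sampled at even positions
    seg <- x[((2L * k + 4L - seq_len(m)) %% n) + 1L]
    cA[k] <- sum(DB5_LO * seg)
    cD[k] <- sum(DB5_HI * seg)
  }
  list(cA = cA, cD = cD)
}

# Multi-level periodized decomposition: list(cA, details = list(cD_L, ...)).
dwt_periodized <- function(x, levels) {
  details <- vector("list", levels)
  cur <- x
  for (j in seq_len(levels)) {
    st <- dwt_step_per(cur)
    details[[j]] <- st$cD
    cur <- st$cA
  }
  list(cA = cur, details = rev(details))  # deepest detail first
}

# Hard frequency-domain high-pass: zero all Fourier bins whose frequency is
# below the cutoff (noise band), including DC.
fft_highpass <- function(x, cutoff_hz, sample_rate) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * sample_rate / n
  f <- pmin(f, sample_rate - f)
  X[f < cutoff_hz] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Denoise and compress one sEMG channel
#'
#' Removes low-frequency noise content (below `noise_cutoff_hz`) in the
#' Fourier domain, suppresses samples beneath the amplitude floor, applies a
#' 4-level periodized db5 wavelet decomposition and brings the result to 64
#' points (default: amplitude-normalized deepest approximation band,
#' linearly interpolated).
#'
#' @param channel numeric vector of length 128.
#' @param cfg a [wavelet_config()].
#' @return numeric vector of length 64.
#' @export
compress_semg_channel <- function(channel, cfg = wavelet_config()) {
  if (length(channel) != RAW_WINDOW_LEN) {
    stop_config("channel must have exactly ", RAW_WINDOW_LEN, " points")
  }
  x <- fft_highpass(channel, cfg$noise_cutoff_hz, cfg$sample_rate)
  floor_v <- cfg$amplitude_floor %||% (3 * stats::mad(x))
  x[abs(x) < floor_v] <- 0
  dec <- dwt_periodized(x, cfg$levels)
  if (cfg$extend == "concat") {
    out <- c(dec$cA, unlist(dec$details))
    if (length(out) > PP_LEN) out <- out[seq_len(PP_LEN)]
    out
  } else {
    # scale back to signal amplitude (each level scales by sqrt(2)), then
    # linearly interpolate the approximation band onto 64 points
    appx <- dec$cA / 2^(cfg$levels / 2)
    stats::approx(seq(1, PP_LEN, length.out = length(appx)), appx,
                  xout = seq_len(PP_LEN))$y
  }
}

# ---- whole windows and datasets -------------------------------------------

#' Preprocess one raw window
#'
#' Applies [compress_semg_channel()] to the eight sEMG rows and
#' [smooth_inertial_channel()] to the six inertial rows, then (when training
#' statistics are supplied) z-normalizes each channel. Training and online
#' recognition use the identical code path.
#'
#' @param window 14 x 128 numeric matrix.
#' @param smoother a [smoother_config()].
#' @param wavelet a [wavelet_config()].
#' @param stats optional per-channel normalization statistics from
#'   [channel_stats()].
#' @return 14 x 64 numeric matrix.
#' @export
preprocess_window <- function(window, smoother = smoother_config(),
                              wavelet = wavelet_config(), stats = NULL) {
  window <- as.matrix(window)
  if (nrow(window) != N_CHANNELS || ncol(window) != RAW_WINDOW_LEN) {
    stop_config("window must be ", N_CHANNELS, " x ", RAW_WINDOW_LEN)
  }
  out <- matrix(0, N_CHANNELS, PP_LEN)
  for (r in SEMG_ROWS) out[r, ] <- compress_semg_channel(window[r, ], wavelet)
  for (r in IMU_ROWS) out[r, ] <- smooth_inertial_channel(window[r, ], smoother)
  if (!is.null(stats)) {
    out <- (out - stats$mean) / stats$sd
  }
  out
}

#' Per-channel normalization statistics
#'
#' sEMG and inertial channels live on scales orders of magnitude apart after
#' preprocessing; the network input is therefore z-normalized per channel
#' with statistics estimated on the training set and frozen for inference.
#'
#' @param x 14 x 64 x N array of preprocessed samples.
#' @return list with per-channel `mean` and `sd` (sd floored at 1e-8).
#' @export
channel_stats <- function(x) {
  stopifnot(length(dim(x)) == 3L, dim(x)[1] == N_CHANNELS)
  m <- apply(x, 1, mean)
  s <- pmax(apply(x, 1, stats::sd), 1e-8)
  list(mean = m, sd = s)
}

# Centered crop of the sample core (samples are 164-207 points long; the
# network consumes the central 128).
crop_core <- function(x, len = RAW_WINDOW_LEN) {
  T_ <- ncol(x)
  if (T_ < len) stop_config("sample shorter than ", len, " points")
  s <- floor((T_ - len) / 2) + 1L
  x[, s:(s + len - 1L), drop = FALSE]
}

#' Preprocess a whole offline dataset
#'
#' Crops the central 128 points of each raw sample, preprocesses every
#' window, estimates normalization statistics on the training split and
#' applies them to all samples.
#'
#' @param dataset an `slr_dataset` from [build_offline_dataset()].
#' @param smoother a [smoother_config()].
#' @param wavelet a [wavelet_config()].
#' @return object of class `slr_pp_dataset` with `x` (14 x 64 x N array),
#'   `labels`, split indices and the frozen `stats`.
#' @export
preprocess_dataset <- function(dataset, smoother = smoother_config(),
                               wavelet = wavelet_config()) {
  n <- length(dataset$samples)
  x <- array(0, c(N_CHANNELS, PP_LEN, n))
  for (i in seq_len(n)) {
    x[, , i] <- preprocess_window(crop_core(dataset$samples[[i]]),
                                  smoother, wavelet)
  }
  stats <- channel_stats(x[, , dataset$train_idx, drop = FALSE])
  x <- (x - c(stats$mean)) / c(stats$sd)
  structure(list(
    x = x, labels = dataset$labels, n_classes = dataset$n_classes,
    empty_class = dataset$empty_class,
    train_idx = dataset$train_idx, test_idx = dataset$test_idx,
    stats = stats, smoother = smoother, wavelet = wavelet
  ), class = "slr_pp_dataset")
}

#' @export
print.slr_pp_dataset <- function(x, ...) {
  cat(sprintf("slr_pp_dataset: %d preprocessed samples (14 x 64), %d classes\n",
              dim(x$x)[3], x$n_classes))
  invisible(x)
}
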