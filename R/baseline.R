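# Traditional segmentation-recognition baseline: high-pass the sEMG,
# detect effective-region boundaries by windowed-energy voting rules,
# extract handcrafted features from each detected segment and classify it
# with an RBF-kernel SVM. There is no verification stage.

#' Energy segmenter configuration
#'
#' @param energy_window non-overlapping energy window length in samples.
#' @param energy_threshold energy threshold separating active from blank
#'   windows (sensor-scale specific; see [calibrate_energy_threshold()]).
#' @param start_rule pair `(k, w)`: a segment starts when `k` of `w`
#'   consecutive windows exceed the threshold (boundary = first sample of
#'   the group's first window).
#' @param end_rule pair `(k, w)`: inside a segment, it ends when `k` of `w`
#'   consecutive windows fall below the threshold.
#' @param highpass_hz sEMG high-pass cutoff (4th-order Butterworth IIR,
#'   causal).
#' @export
segmenter_config <- function(energy_window = 16L, energy_threshold = 582,
                             start_rule = c(4L, 6L), end_rule = c(5L, 7L),
                             highpass_hz = 5) {
  if (energy_window < 1L) stop_config("energy_window must be positive")
  if (start_rule[1] > start_rule[2] || end_rule[1] > end_rule[2]) {
    stop_config("voting rules must be (k, w) pairs with k <= w")
  }
  list(energy_window = as.integer(energy_window),
       energy_threshold = energy_threshold,
       start_rule = as.integer(start_rule), end_rule = as.integer(end_rule),
       highpass_hz = highpass_hz)
}

#' Average energy of a multichannel sEMG block
#'
#' `E = (1/n) * sum over channels and samples of squared values`, with
#' `n` the window length (16) and 8 sEMG channels.
#'
#' @param semg_block 8 x 16 numeric matrix.
#' @export
window_energy <- function(semg_block) {
  if (!is.matrix(semg_block) || nrow(semg_block) != 8L ||
      ncol(semg_block) != 16L) {
    stop_config("window_energy expects an 8 x 16 block")
  }
  sum(semg_block^2) / ncol(semg_block)
}

# Causal high-pass of the sEMG rows.
highpass_semg <- function(values, sample_rate, cutoff_hz) {
  bf <- signal::butter(4, cutoff_hz / (sample_rate / 2), type = "high")
  out <- values
  for (r in SEMG_ROWS) {
    out[r, ] <- as.numeric(signal::filter(bf, values[r, ]))
  }
  out
}

# Energy sequence over non-overlapping windows of the (filtered) sEMG rows.
stream_energies <- function(filtered_values, cfg) {
  wlen <- cfg$energy_window
  nw <- ncol(filtered_values) %/% wlen
  vapply(seq_len(nw), function(i) {
    block <- filtered_values[SEMG_ROWS, ((i - 1L) * wlen + 1L):(i * wlen),
                             drop = FALSE]
    sum(block^2) / wlen
  }, numeric(1))
}

#' Detect effective segments by energy voting
#'
#' The sEMG channels are high-pass filtered, the stream is cut into
#' non-overlapping 16-sample windows and scanned window by window. Outside
#' a segment, a start fires when 4 of 6 consecutive windows exceed the
#' energy threshold; inside, an end fires when 5 of 7 consecutive windows
#' fall below it. Boundaries are the first sample of the firing group's
#' first window; a segment still open at stream end is closed there.
#'
#' @param stream a [signal_stream()].
#' @param cfg a [segmenter_config()].
#' @return data frame of 0-based half-open `start`, `end` sample spans.
#' @export
detect_segments <- function(stream, cfg = segmenter_config()) {
  filtered <- highpass_semg(stream$values, stream$sample_rate,
                            cfg$highpass_hz)
  e <- stream_energies(filtered, cfg)
  segments_from_energies(e, cfg, ncol(stream$values))
}

# Rule scan over a precomputed energy sequence (separated for testing).
segments_from_energies <- function(e, cfg, stream_length) {
  wlen <- cfg$energy_window
  ks <- cfg$start_rule[1]; ws <- cfg$start_rule[2]
  ke <- cfg$end_rule[1]; we <- cfg$end_rule[2]
  above <- e > cfg$energy_threshold
  nw <- length(e)
  segs <- list()
  inside <- FALSE
  start <- NA_integer_
  i <- 1L
  while (i <= nw) {
    if (!inside) {
      if (i + ws - 1L <= nw && sum(above[i:(i + ws - 1L)]) >= ks) {
        start <- (i - 1L) * wlen
        inside <- TRUE
        i <- i + ws
      } else {
        i <- i + 1L
      }
    } else {
      if (i + we - 1L <= nw && sum(!above[i:(i + we - 1L)]) >= ke) {
        end <- (i - 1L) * wlen
        if (end > start) {
          segs[[length(segs) + 1L]] <- data.frame(start = start, end = end)
        }
        inside <- FALSE
        i <- i + we
      } else {
        i <- i + 1L
      }
    }
  }
  if (inside) {
    segs[[length(segs) + 1L]] <- data.frame(start = start,
                                            end = stream_length)
  }
  if (length(segs) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  do.call(rbind, segs)
}

#' Calibrate the energy threshold on annotated data
#'
#' The published threshold (582) is specific to the original sensor scale.
#' This helper derives the threshold from the blank-region window energies
#' of a reference stream: a quantile of those energies times a headroom
#' factor. The default uses the median, which stays on the noise floor even
#' when blank regions contain non-gesture interference bursts (those are
#' genuine movements with gesture-scale energy and must not inflate the
#' threshold).
#'
#' @param stream a [signal_stream()].
#' @param regions ground-truth effective regions of that stream.
#' @param cfg a [segmenter_config()].
#' @param probs quantile of blank-region energies to use.
#' @param headroom multiplier applied on top of the quantile.
#' @export
calibrate_energy_threshold <- function(stream, regions,
                                       cfg = segmenter_config(),
                                       probs = 0.5, headroom = 10) {
  filtered <- highpass_semg(stream$values, stream$sample_rate,
                            cfg$highpass_hz)
  e <- stream_energies(filtered, cfg)
  wlen <- cfg$energy_window
  w_start <- (seq_along(e) - 1L) * wlen
  w_end <- w_start + wlen
  in_region <- vapply(seq_along(e), function(i) {
    any(w_end[i] > regions$start & w_start[i] < regions$end)
  }, logical(1))
  if (!any(!in_region)) stop_config("no blank windows to calibrate on")
  headroom * unname(stats::quantile(e[!in_region], probs))
}

# ---- handcrafted features -------------------------------------------------

#' Feature extraction specification
#'
#' sEMG channels contribute root mean square, zero-crossing count,
#' autoregressive coefficients and pooled short-time Fourier magnitudes;
#' inertial channels contribute RMS, AR coefficients, Welch power in equal
#' frequency bands and wavelet sub-band energies.
#'
#' @param ar_order autoregressive model order.
#' @param stft_window,stft_hop short-time Fourier frame length and hop.
#' @param psd_bands number of equal-width Welch PSD bands.
#' @param wavelet_levels db5 decomposition depth for sub-band energies.
#' @param min_length minimum segment length the features support.
#' @export
feature_spec <- function(ar_order = 4L, stft_window = 32L, stft_hop = 16L,
                         psd_bands = 4L, wavelet_levels = 3L,
                         min_length = 48L) {
  list(ar_order = as.integer(ar_order), stft_window = as.integer(stft_window),
       stft_hop = as.integer(stft_hop), psd_bands = as.integer(psd_bands),
       wavelet_levels = as.integer(wavelet_levels),
       min_length = as.integer(min_length))
}

rms_of <- function(x) sqrt(mean(x^2))

zero_crossings <- function(x) sum(x[-1] * x[-length(x)] < 0)

ar_coefs <- function(x, p) {
  if (stats::sd(x) < 1e-12) return(numeric(p))
  fit <- tryCatch(
    stats::ar(x, aic = FALSE, order.max = p, method = "yule-walker",
              demean = TRUE),
    error = function(e) NULL)
  if (is.null(fit)) return(numeric(p))
  co <- fit$ar
  c(co, numeric(p - length(co)))
}

# Frames of |FFT| magnitudes averaged over time; Hamming window.
stft_mean_mag <- function(x, wlen, hop) {
  win <- signal::hamming(wlen)
  starts <- seq(1L, length(x) - wlen + 1L, by = hop)
  nbins <- wlen %/% 2L + 1L
  acc <- numeric(nbins)
  for (s in starts) {
    X <- stats::fft(x[s:(s + wlen - 1L)] * win)
    acc <- acc + Mod(X[seq_len(nbins)])
  }
  acc / length(starts)
}

# Welch PSD averaged into equal-width frequency bands.
welch_band_power <- function(x, wlen, hop, n_bands) {
  win <- signal::hamming(wlen)
  starts <- seq(1L, length(x) - wlen + 1L, by = hop)
  nbins <- wlen %/% 2L + 1L
  acc <- numeric(nbins)
  for (s in starts) {
    X <- stats::fft(x[s:(s + wlen - 1L)] * win)
    acc <- acc + Mod(X[seq_len(nbins)])^2 / sum(win^2)
  }
  psd <- acc / length(starts)
  band <- cut(seq_len(nbins), breaks = n_bands, labels = FALSE)
  vapply(seq_len(n_bands), function(b) mean(psd[band == b]), numeric(1))
}

# db5 sub-band energies (approximation + each detail level).
wavelet_energies <- function(x, levels) {
  n <- (length(x) %/% 2L^levels) * 2L^levels
  dec <- dwt_periodized(x[seq_len(n)], levels)
  c(sum(dec$cA^2), vapply(dec$details, function(d) sum(d^2), numeric(1)))
}

#' Extract the handcrafted feature vector of one segment
#'
#' @param segment_values 14 x L matrix (sEMG rows already high-passed).
#' @param spec a [feature_spec()].
#' @return numeric feature vector of fixed length for a fixed spec.
#' @export
extract_features <- function(segment_values, spec = feature_spec()) {
  L <- ncol(segment_values)
  if (L < spec$min_length) {
    stop_config("segment shorter than the minimum feature support (",
                spec$min_length, " samples)")
  }
  feats <- c()
  for (r in SEMG_ROWS) {
    x <- segment_values[r, ]
    feats <- c(feats, rms_of(x), zero_crossings(x),
               ar_coefs(x, spec$ar_order),
               stft_mean_mag(x, spec$stft_window, spec$stft_hop))
  }
  for (r in IMU_ROWS) {
    x <- segment_values[r, ]
    feats <- c(feats, rms_of(x), ar_coefs(x, spec$ar_order),
               welch_band_power(x, spec$stft_window, spec$stft_hop,
                                spec$psd_bands),
               wavelet_energies(x, spec$wavelet_levels))
  }
  unname(feats)
}

#' Train the baseline RBF-SVM on offline samples
#'
#' High-passes each raw sample's sEMG rows, extracts the handcrafted
#' features and fits a radial-basis SVM (`C = 256`, `gamma = 0.0175`).
#'
#' @param dataset an `slr_dataset` of raw samples.
#' @param spec a [feature_spec()].
#' @param cfg a [segmenter_config()] (for the high-pass cutoff).
#' @param cost,gamma SVM hyperparameters.
#' @param cross if positive, also run k-fold cross-validation (accuracy is
#'   stored in the fitted model).
#' @param seed RNG seed for the cross-validation folds.
#' @return object of class `slr_baseline`.
#' @export
train_baseline_svm <- function(dataset, spec = feature_spec(),
                               cfg = segmenter_config(), cost = 256,
                               gamma = 0.0175, cross = 0, seed = 1L) {
  fs <- dataset$config$sample_rate
  feats <- t(vapply(dataset$samples, function(s) {
    extract_features(highpass_semg(s, fs, cfg$highpass_hz), spec)
  }, numeric(length(extract_features(
    highpass_semg(dataset$samples[[1]], fs, cfg$highpass_hz), spec)))))
  tr <- dataset$train_idx
  model <- with_seed(seed,
    e1071::svm(x = feats[tr, , drop = FALSE],
               y = factor(dataset$labels[tr]),
               kernel = "radial", cost = cost, gamma = gamma,
               cross = cross, scale = TRUE))
  structure(list(model = model, spec = spec, seg_cfg = cfg,
                 sample_rate = fs, n_classes = dataset$n_classes),
            class = "slr_baseline")
}

#' Run the segmentation-recognition baseline over a stream
#'
#' Detects segments by energy voting, classifies each detected segment long
#' enough to support the features and emits one accepted event per segment
#' (this mechanism has no verification stage).
#'
#' @param stream a [signal_stream()].
#' @param baseline a trained `slr_baseline`.
#' @param cfg segmenter configuration; defaults to the one stored at
#'   training time (override to use a calibrated threshold).
#' @return recognition-event data frame as in [run_online()] (difference is
#'   `NA`).
#' @export
run_baseline <- function(stream, baseline, cfg = baseline$seg_cfg) {
  if (!inherits(baseline, "slr_baseline")) {
    stop_config("baseline model is not trained (expected slr_baseline)")
  }
  t0 <- proc.time()[["elapsed"]]
  filtered <- highpass_semg(stream$values, stream$sample_rate,
                            cfg$highpass_hz)
  segs <- segments_from_energies(stream_energies(filtered, cfg), cfg,
                                 ncol(stream$values))
  events <- list()
  for (k in seq_len(nrow(segs))) {
    len <- segs$end[k] - segs$start[k]
    if (len < baseline$spec$min_length) next
    vals <- filtered[, (segs$start[k] + 1L):segs$end[k], drop = FALSE]
    f <- extract_features(vals, baseline$spec)
    cls <- as.integer(as.character(
      stats::predict(baseline$model, t(as.matrix(f)))))
    events[[length(events) + 1L]] <- data.frame(
      window_start = segs$start[k], window_end = segs$end[k],
      predicted_class = cls, difference = NA_real_, accepted = TRUE)
  }
  out <- if (length(events) == 0L) empty_events() else do.call(rbind, events)
  attr(out, "elapsed_s") <- proc.time()[["elapsed"]] - t0
  attr(out, "n_segments") <- nrow(segs)
  out
}
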