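#' Generator configuration for synthetic sign-language signals
#'
#' Bundles the knobs of the synthetic multichannel signal generator: an
#' 8-channel sEMG + 3-axis ACC + 3-axis GYR recording rig sampled at 100 Hz,
#' a gesture vocabulary with one reserved "empty" (no action) class, and
#' continuous streams in which gestures are separated by 0.5-5 s blank gaps
#' optionally carrying non-gesture interference (walking, arm swings, ...).
#'
#' @param n_classes total number of classes including the empty class (>= 2).
#' @param samples_per_class samples generated per class for offline datasets.
#' @param sample_rate sampling rate in Hz.
#' @param noise_sd standard deviation of additive measurement noise, on the
#'   unit amplitude scale of the class envelopes. Keep at or below ~0.3 for
#'   class-separable data (see the methods vignette).
#' @param amp_jitter half-width of the per-sample uniform amplitude scaling
#'   (execution-intensity variation between repetitions of a gesture).
#' @param time_jitter half-width of the per-sample uniform time shift of
#'   the class shapes, as a fraction of the sample (execution-timing
#'   variation).
#' @param interference_rate expected number of non-gesture interference
#'   bursts injected per composed stream (Poisson).
#' @param gap_range_s blank-gap duration range between gestures, seconds.
#' @param duration_range per-sample length bounds in samples.
#' @param test_fraction held-out fraction for the stratified offline split.
#' @param seed default seed for generator entry points.
#' @return a list of class `slr_generator_config`.
#' @export
generator_config <- function(n_classes = 10L, samples_per_class = 20L,
                             sample_rate = 100, noise_sd = 0.1,
                             amp_jitter = 0.2, time_jitter = 0.05,
                             interference_rate = 0, gap_range_s = c(0.5, 5),
                             duration_range = c(164L, 207L),
                             test_fraction = 0.1, seed = 1L) {
  n_classes <- as.integer(n_classes)
  if (is.na(n_classes) || n_classes < 2L) {
    stop_config("n_classes must be >= 2 (at least one gesture plus empty)")
  }
  if (sample_rate <= 0) stop_config("sample_rate must be positive")
  if (length(gap_range_s) != 2L || gap_range_s[1] > gap_range_s[2]) {
    stop_config("gap_range_s must be an ordered pair")
  }
  duration_range <- as.integer(duration_range)
  if (length(duration_range) != 2L || any(is.na(duration_range)) ||
      duration_range[1] < 1L || duration_range[1] > duration_range[2]) {
    stop_config("duration_range must be ordered positive integer bounds")
  }
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop_config("test_fraction must be in (0, 1)")
  }
  structure(list(
    n_classes = n_classes,
    samples_per_class = as.integer(samples_per_class),
    sample_rate = sample_rate,
    noise_sd = noise_sd,
    amp_jitter = amp_jitter,
    time_jitter = time_jitter,
    interference_rate = interference_rate,
    gap_range_s = gap_range_s,
    duration_range = duration_range,
    test_fraction = test_fraction,
    seed = as.integer(seed)
  ), class = "slr_generator_config")
}

# ---- class templates ------------------------------------------------------

# A multi-Gaussian amplitude envelope on normalized time [0, 1].
rand_envelope <- function(n_bumps = sample(1:3, 1)) {
  list(
    centers = runif(n_bumps, 0.15, 0.85),
    widths = runif(n_bumps, 0.08, 0.25),
    amps = runif(n_bumps, 0.5, 2)
  )
}

eval_envelope <- function(par, t) {
  y <- numeric(length(t))
  for (i in seq_along(par$amps)) {
    y <- y + par$amps[i] * exp(-0.5 * ((t - par$centers[i]) / par$widths[i])^2)
  }
  y
}

# A smooth low-frequency trajectory for one inertial axis.
rand_curve <- function() {
  k <- sample(1:2, 1)
  list(
    offset = runif(1, -0.5, 0.5),
    amps = runif(k, 0.3, 1.5),
    cycles = runif(k, 0.5, 3),
    phases = runif(k, 0, 2 * pi)
  )
}

eval_curve <- function(par, t) {
  y <- rep(par$offset, length(t))
  for (i in seq_along(par$amps)) {
    y <- y + par$amps[i] * sin(2 * pi * par$cycles[i] * t + par$phases[i])
  }
  y
}

zero_envelope <- function() list(centers = 0.5, widths = 0.2, amps = 0)
zero_curve <- function() list(offset = 0, amps = 0, cycles = 1, phases = 0)

#' Build per-class signal templates
#'
#' Each gesture class gets eight per-channel sEMG amplitude envelopes
#' (multi-Gaussian bumps) and six smooth inertial trajectory curves, drawn
#' once from the template RNG so a class always reproduces the same shapes.
#' The last class id (`n_classes`) is the reserved "empty" class with
#' identically zero envelopes and curves.
#'
#' @param n_classes number of classes including the empty class.
#' @param seed template RNG seed.
#' @param duration_range integer sample-count bounds for generated samples.
#' @return list of `n_classes` templates; element `i` describes class id `i`.
#' @export
gesture_templates <- function(n_classes, seed = 1L,
                              duration_range = c(164L, 207L)) {
  n_classes <- as.integer(n_classes)
  stopifnot(n_classes >= 2L)
  with_seed(seed, {
    lapply(seq_len(n_classes), function(k) {
      empty <- k == n_classes
      structure(list(
        class_id = k,
        is_empty = empty,
        duration_range = as.integer(duration_range),
        semg_envelopes = if (empty) replicate(8, zero_envelope(), simplify = FALSE)
                         else replicate(8, rand_envelope(), simplify = FALSE),
        imu_curves = if (empty) replicate(6, zero_curve(), simplify = FALSE)
                     else replicate(6, rand_curve(), simplify = FALSE)
      ), class = "slr_template")
    })
  })
}

#' @export
#' @rdname gesture_templates
#' @param templates a template list from [gesture_templates()].
empty_class_id <- function(templates) {
  ids <- vapply(templates, function(tp) tp$class_id, integer(1))
  flags <- vapply(templates, function(tp) isTRUE(tp$is_empty), logical(1))
  if (!any(flags)) stop_config("template set has no empty class")
  ids[which(flags)[1]]
}

# Interference shapes live in a pool disjoint from the gesture vocabulary:
# they are genuine movements (amplitudes comparable to real classes), not
# noise, and must never be annotated as gestures.
interference_templates <- function(n = 6L, seed = 99L) {
  with_seed(seed, {
    lapply(seq_len(n), function(k) {
      list(
        semg_envelopes = replicate(8, rand_envelope(), simplify = FALSE),
        imu_curves = replicate(6, rand_curve(), simplify = FALSE),
        duration_range = c(40L, 160L)
      )
    })
  })
}

# ---- sample synthesis -----------------------------------------------------

# Zero-mean band-limited carrier noise emulating the sEMG frequency band
# (roughly 20-48 Hz equivalent at a 100 Hz rate), unit variance.
band_noise <- function(n) {
  w <- stats::rnorm(n + 32)
  bf <- signal::butter(2, c(0.35, 0.95), type = "pass")
  x <- signal::filter(bf, w)
  x <- as.numeric(x)[-seq_len(32)]  # drop filter warm-up
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Synthesize one multichannel gesture sample
#'
#' sEMG channels are band-limited Gaussian noise amplitude-modulated by the
#' class envelope; inertial channels are the class trajectory curves plus
#' white jitter. Sample length is drawn uniformly from the template's
#' duration bounds.
#'
#' @param template a template from [gesture_templates()].
#' @param cfg a [generator_config()].
#' @param seed RNG seed; identical seeds give identical samples.
#' @return a 14 x L numeric matrix (rows 1-8 sEMG, 9-11 ACC, 12-14 GYR).
#' @export
synthesize_sample <- function(template, cfg = generator_config(), seed = 1L) {
  dr <- template$duration_range
  if (length(dr) != 2L || dr[1] > dr[2] || dr[1] < 1L) {
    stop_config("invalid duration_range in template")
  }
  with_seed(seed, synthesize_sample_impl(template, cfg))
}

# RNG-consuming core, used directly by compose_stream under its own seed.
# Per-sample amplitude/timing jitter emulates repetition-to-repetition
# variation in how a signer executes the same gesture.
synthesize_sample_impl <- function(template, cfg) {
  dr <- template$duration_range
  L <- sample(dr[1]:dr[2], 1)
  t <- seq(0, 1, length.out = L)
  aj <- cfg$amp_jitter %||% 0
  tj <- cfg$time_jitter %||% 0
  scale_g <- stats::runif(1, 1 - aj, 1 + aj)
  ts <- t - stats::runif(1, -tj, tj)
  x <- matrix(0, N_CHANNELS, L)
  for (c in 1:8) {
    env <- eval_envelope(template$semg_envelopes[[c]], ts) * scale_g *
      stats::runif(1, 1 - aj / 2, 1 + aj / 2)
    x[SEMG_ROWS[c], ] <- env * band_noise(L) + cfg$noise_sd * stats::rnorm(L)
  }
  for (c in 1:6) {
    x[IMU_ROWS[c], ] <- eval_curve(template$imu_curves[[c]], ts) * scale_g +
      cfg$noise_sd * stats::rnorm(L)
  }
  x
}

# ---- continuous streams ---------------------------------------------------

#' Construct a continuous annotated signal stream
#'
#' Concatenates scheduled gestures separated by blank gaps whose lengths are
#' uniform in `cfg$gap_range_s` (50-500 samples at 100 Hz). Blank regions
#' carry baseline noise; when `cfg$interference_rate > 0`, non-gesture
#' interference bursts are added inside blank gaps only and are not
#' annotated. Region coordinates are 0-based half-open `[start, end)`.
#'
#' @param templates template list covering every id in `schedule`.
#' @param schedule integer vector of gesture class ids, in stream order.
#' @param cfg a [generator_config()].
#' @param seed RNG seed.
#' @param pad_to_s if the composed stream is shorter than this many
#'   seconds, the trailing blank is extended with baseline noise to reach
#'   it (`NULL` to disable).
#' @return list with `stream` (a [signal_stream()]), `regions` (data frame
#'   `start`, `end`, `class_id`), and `interference` (data frame of injected
#'   burst spans, possibly empty).
#' @export
compose_stream <- function(templates, schedule, cfg = generator_config(),
                           seed = cfg$seed, pad_to_s = NULL) {
  if (length(schedule) == 0L) stop_config("schedule must be non-empty")
  ids <- vapply(templates, function(tp) tp$class_id, integer(1))
  if (!all(schedule %in% ids)) {
    stop_config("schedule contains class ids with no template: ",
                paste(setdiff(schedule, ids), collapse = ", "))
  }
  with_seed(seed, {
    fs <- cfg$sample_rate
    gap_lo <- max(1L, as.integer(round(cfg$gap_range_s[1] * fs)))
    gap_hi <- as.integer(round(cfg$gap_range_s[2] * fs))
    pieces <- list()
    gap_spans <- list()   # 0-based [start, end) of blank gaps
    regions <- list()
    pos <- 0L             # 0-based cursor
    push_gap <- function() {
      g <- sample(gap_lo:gap_hi, 1)
      pieces[[length(pieces) + 1L]] <<-
        matrix(stats::rnorm(N_CHANNELS * g, sd = cfg$noise_sd), N_CHANNELS, g)
      gap_spans[[length(gap_spans) + 1L]] <<- c(pos, pos + g)
      pos <<- pos + g
    }
    push_gap()
    for (cid in schedule) {
      tp <- templates[[which(ids == cid)[1]]]
      s <- synthesize_sample_impl(tp, cfg)
      pieces[[length(pieces) + 1L]] <- s
      regions[[length(regions) + 1L]] <-
        data.frame(start = pos, end = pos + ncol(s), class_id = cid)
      pos <- pos + ncol(s)
      push_gap()
    }
    values <- do.call(cbind, pieces)
    if (!is.null(pad_to_s) && ncol(values) < pad_to_s * fs) {
      extra <- as.integer(ceiling(pad_to_s * fs)) - ncol(values)
      pad <- matrix(stats::rnorm(N_CHANNELS * extra, sd = cfg$noise_sd),
                    N_CHANNELS, extra)
      gap_spans[[length(gap_spans)]][2] <-
        gap_spans[[length(gap_spans)]][2] + extra
      values <- cbind(values, pad)
    }
    regions <- do.call(rbind, regions)
    gaps <- do.call(rbind, gap_spans)

    interference <- data.frame(start = integer(0), end = integer(0))
    n_int <- if (cfg$interference_rate > 0) {
      stats::rpois(1, cfg$interference_rate)
    } else 0L
    if (n_int > 0) {
      pool <- interference_templates()
      margin <- 5L
      for (i in seq_len(n_int)) {
        itp <- pool[[sample(length(pool), 1)]]
        blen <- sample(itp$duration_range[1]:itp$duration_range[2], 1)
        room <- gaps[, 2] - gaps[, 1] - blen - 2L * margin
        ok <- which(room > 0)
        if (length(ok) == 0L) next
        gi <- ok[sample(length(ok), 1)]
        off <- sample(0:room[gi], 1)
        b0 <- gaps[gi, 1] + margin + off          # 0-based start
        cols <- (b0 + 1L):(b0 + blen)             # 1-based matrix columns
        tt <- seq(0, 1, length.out = blen)
        for (c in 1:8) {
          env <- eval_envelope(itp$semg_envelopes[[c]], tt)
          values[SEMG_ROWS[c], cols] <- values[SEMG_ROWS[c], cols] +
            env * band_noise(blen)
        }
        for (c in 1:6) {
          values[IMU_ROWS[c], cols] <- values[IMU_ROWS[c], cols] +
            eval_curve(itp$imu_curves[[c]], tt)
        }
        interference <- rbind(interference,
                              data.frame(start = b0, end = b0 + blen))
      }
    }
    list(stream = signal_stream(values, fs),
         regions = regions,
         interference = interference)
  })
}

#' Multichannel signal stream container
#'
#' @param values 14 x T numeric matrix in the canonical channel order
#'   (rows 1-8 sEMG, 9-11 accelerometer, 12-14 gyroscope).
#' @param sample_rate sampling rate in Hz.
#' @return object of class `signal_stream`.
#' @export
signal_stream <- function(values, sample_rate = 100) {
  values <- as.matrix(values)
  if (nrow(values) != N_CHANNELS) {
    stop_config("a signal_stream must have exactly ", N_CHANNELS, " channels")
  }
  if (sample_rate <= 0) stop_config("sample_rate must be positive")
  structure(list(values = values, sample_rate = sample_rate,
                 channel_roles = channel_roles()),
            class = "signal_stream")
}

#' @export
print.signal_stream <- function(x, ...) {
  cat(sprintf("signal_stream: 14 channels x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$values), x$sample_rate, ncol(x$values) / x$sample_rate))
  invisible(x)
}

# ---- offline datasets -----------------------------------------------------

#' Generate a labeled offline sample collection
#'
#' Draws `samples_per_class` samples for every class (including empty) and
#' records a stratified train/test split with `test_fraction` held out per
#' class (default 10%).
#'
#' @param cfg a [generator_config()].
#' @param templates optional template list; generated from `cfg` if absent.
#' @param seed RNG seed.
#' @return object of class `slr_dataset`: raw variable-length samples,
#'   integer labels, split indices and the templates used.
#' @export
build_offline_dataset <- function(cfg = generator_config(), templates = NULL,
                                  seed = cfg$seed) {
  if (cfg$samples_per_class < 2L) {
    stop_config("samples_per_class must be >= 2")
  }
  if (is.null(templates)) {
    templates <- gesture_templates(cfg$n_classes, seed = seed,
                                   duration_range = cfg$duration_range)
  }
  with_seed(seed + 1L, {
    samples <- list()
    labels <- integer(0)
    for (tp in templates) {
      for (i in seq_len(cfg$samples_per_class)) {
        samples[[length(samples) + 1L]] <- synthesize_sample_impl(tp, cfg)
        labels <- c(labels, tp$class_id)
      }
    }
    test_idx <- integer(0)
    for (cid in unique(labels)) {
      idx <- which(labels == cid)
      n_test <- max(1L, round(cfg$test_fraction * length(idx)))
      test_idx <- c(test_idx, sample(idx, n_test))
    }
    test_idx <- sort(test_idx)
    structure(list(
      samples = samples,
      labels = labels,
      n_classes = cfg$n_classes,
      empty_class = empty_class_id(templates),
      train_idx = setdiff(seq_along(samples), test_idx),
      test_idx = test_idx,
      templates = templates,
      config = cfg
    ), class = "slr_dataset")
  })
}

#' @export
print.slr_dataset <- function(x, ...) {
  cat(sprintf(
    "slr_dataset: %d samples, %d classes (empty = %d), %d train / %d test\n",
    length(x$samples), x$n_classes, x$empty_class,
    length(x$train_idx), length(x$test_idx)))
  invisible(x)
}

# ---- plain-text I/O -------------------------------------------------------

#' Read and write streams and ground-truth annotations
#'
#' Streams are stored as tab-separated sample-by-channel tables with a
#' `# sample_rate:` header comment; ground-truth regions as CSV with columns
#' `start`, `end`, `class_id` (0-based half-open sample indices).
#'
#' @param stream a [signal_stream()].
#' @param path file path.
#' @name stream_io
#' @export
write_stream_tsv <- function(stream, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate: %g", stream$sample_rate), con)
  tab <- t(stream$values)
  colnames(tab) <- sprintf("%s%d", c(rep("semg", 8), rep("acc", 3), rep("gyr", 3)),
                           c(1:8, 1:3, 1:3))
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' @rdname stream_io
#' @export
read_stream_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  fs <- as.numeric(sub("^# sample_rate:\\s*", "", first))
  tab <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  signal_stream(t(as.matrix(tab)), fs)
}

#' @rdname stream_io
#' @param regions data frame with columns `start`, `end`, `class_id`.
#' @export
write_regions_csv <- function(regions, path) {
  utils::write.csv(regions, path, row.names = FALSE, quote = FALSE)
}

#' @rdname stream_io
#' @export
read_regions_csv <- function(path) {
  utils::read.csv(path)
}
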