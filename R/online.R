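# Online recognition-verification engine: a 128-point window slides over
# the continuous stream with a random step of 8-20 samples; each filled
# window is preprocessed, classified, encoded and verified against the
# predicted class's reference vector. Accepted results skip the next few
# steps so the same action is not re-recognized.

#' Sliding-window configuration
#'
#' @param window_length window size in samples.
#' @param step_min,step_max bounds of the uniform random sliding step.
#' @param skip_steps_on_accept steps skipped after an accepted result.
#' @param seed RNG seed for the step sequence.
#' @export
sliding_window_config <- function(window_length = 128L, step_min = 8L,
                                  step_max = 20L, skip_steps_on_accept = 5L,
                                  seed = 1L) {
  window_length <- as.integer(window_length)
  step_min <- as.integer(step_min)
  step_max <- as.integer(step_max)
  if (!(0L < step_min && step_min <= step_max && step_max < window_length)) {
    stop_config("need 0 < step_min <= step_max < window_length")
  }
  list(window_length = window_length, step_min = step_min,
       step_max = step_max,
       skip_steps_on_accept = as.integer(skip_steps_on_accept),
       seed = as.integer(seed))
}

#' Enumerate sliding-window spans
#'
#' The first window starts at sample 0; each subsequent start advances by a
#' seeded uniform random integer step in `[step_min, step_max]`. Only
#' windows that fit entirely inside the stream are returned.
#'
#' @param stream_length stream length in samples.
#' @param cfg a [sliding_window_config()].
#' @return data frame of 0-based half-open spans `start`, `end`.
#' @export
iterate_windows <- function(stream_length, cfg = sliding_window_config()) {
  stopifnot(stream_length >= 0)
  with_seed(cfg$seed, {
    starts <- integer(0)
    s <- 0L
    while (s + cfg$window_length <= stream_length) {
      starts <- c(starts, s)
      s <- s + if (cfg$step_min == cfg$step_max) cfg$step_min else
        sample(cfg$step_min:cfg$step_max, 1L)
    }
    data.frame(start = starts, end = starts + cfg$window_length)
  })
}

empty_events <- function() {
  data.frame(window_start = integer(0), window_end = integer(0),
             predicted_class = integer(0), difference = numeric(0),
             accepted = logical(0))
}

#' Run the recognition-verification engine over a stream
#'
#' Every window is preprocessed with the classifier's stored preprocessing
#' and normalization context, classified, and -- unless the prediction is
#' the empty class, which is treated as "no action" -- encoded and verified
#' against the reference set. Windows evaluated while skipping after an
#' acceptance produce no events; rejected windows are emitted with
#' `accepted = FALSE` for diagnostics.
#'
#' @param stream a [signal_stream()].
#' @param classifier trained `slr_classifier`.
#' @param verifier trained `slr_verifier`.
#' @param refs `slr_reference_set` built on the same class set.
#' @param cfg a [sliding_window_config()].
#' @return data frame of recognition events: `window_start`, `window_end`
#'   (0-based half-open), `predicted_class`, `difference`, `accepted`.
#' @export
run_online <- function(stream, classifier, verifier, refs,
                       cfg = sliding_window_config()) {
  if (is.null(classifier$stats)) {
    stop_config("classifier carries no normalization statistics")
  }
  if (!setequal(refs$classes, seq_len(classifier$n_classes))) {
    stop_config("reference set classes do not match the classifier")
  }
  t0 <- proc.time()[["elapsed"]]
  windows <- iterate_windows(ncol(stream$values), cfg)
  events <- list()
  skip <- 0L
  for (w in seq_len(nrow(windows))) {
    if (skip > 0L) {
      skip <- skip - 1L
      next
    }
    s <- windows$start[w]
    raw <- stream$values[, (s + 1L):(s + cfg$window_length), drop = FALSE]
    pp <- preprocess_window(raw, classifier$smoother, classifier$wavelet,
                            stats = classifier$stats)
    pred <- predict(classifier, pp)
    if (pred$class_id == classifier$empty_class) next
    enc <- encode_samples(verifier, pp)
    ver <- verify_prediction(enc[, 1], refs, pred$class_id)
    events[[length(events) + 1L]] <- data.frame(
      window_start = s, window_end = windows$end[w],
      predicted_class = pred$class_id, difference = ver$difference,
      accepted = ver$accepted)
    if (ver$accepted) skip <- cfg$skip_steps_on_accept
  }
  out <- if (length(events) == 0L) empty_events() else do.call(rbind, events)
  attr(out, "elapsed_s") <- proc.time()[["elapsed"]] - t0
  attr(out, "n_windows") <- nrow(windows)
  out
}

#' Disable verification in a reference set
#'
#' Returns a copy whose clamped thresholds are `+Inf`, so every
#' classification result is accepted. Used to measure what the verification
#' stage contributes.
#'
#' @param refs an `slr_reference_set`.
#' @export
disable_verification <- function(refs) {
  refs$clamped <- rep(Inf, length(refs$clamped))
  refs
}
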