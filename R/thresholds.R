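# Per-class standard reference vectors and acceptance thresholds V_Th.
# A prediction is verified by comparing the Euclidean distance between the
# window's encoding and the predicted class's reference vector ("the
# difference") against that class's threshold: 2.5 times the 80% quantile
# of within-class differences, clamped into [14, 18].

#' Threshold configuration
#'
#' @param quantile within-class difference quantile used as the base value.
#' @param multiplier scale factor applied to the quantile.
#' @param clamp_low,clamp_high clamping bounds for the stored threshold.
#' @export
threshold_config <- function(quantile = 0.8, multiplier = 2.5,
                             clamp_low = 14, clamp_high = 18) {
  if (!(quantile > 0 && quantile < 1)) stop_config("quantile must be in (0,1)")
  if (multiplier <= 0) stop_config("multiplier must be positive")
  if (clamp_low > clamp_high) stop_config("clamp bounds must be ordered")
  list(quantile = quantile, multiplier = multiplier,
       clamp_low = clamp_low, clamp_high = clamp_high)
}

#' Per-class mean reference vectors
#'
#' The reference vector of a class is the arithmetic mean of the encodings
#' of all its training samples.
#'
#' @param encodings 64 x N matrix of sample encodings.
#' @param labels length-N integer class labels.
#' @return 64 x K matrix with one column per class, column names the class
#'   ids (ascending).
#' @export
compute_reference_vectors <- function(encodings, labels) {
  classes <- sort(unique(labels))
  if (length(classes) == 0L) stop_config("no samples")
  refs <- vapply(classes, function(cl) {
    cols <- which(labels == cl)
    if (length(cols) == 0L) stop_config("class ", cl, " has no samples")
    rowMeans(encodings[, cols, drop = FALSE])
  }, numeric(nrow(encodings)))
  colnames(refs) <- classes
  refs
}

#' Class threshold from a difference sequence
#'
#' Sorts the within-class difference values ascending (`Sd`), takes the
#' element at index `I = floor(quantile * N)` (1-based, at least 1), scales
#' it by the multiplier and clamps the result into
#' `[clamp_low, clamp_high]`.
#'
#' @param differences within-class difference values (non-empty).
#' @param cfg a [threshold_config()].
#' @return list with `raw` and `clamped` threshold values.
#' @export
compute_class_threshold <- function(differences, cfg = threshold_config()) {
  if (length(differences) == 0L) stop_config("empty difference sequence")
  Sd <- sort(differences)
  I <- max(1L, floor(cfg$quantile * length(Sd)))
  raw <- cfg$multiplier * Sd[I]
  list(raw = raw,
       clamped = min(cfg$clamp_high, max(cfg$clamp_low, raw)))
}

#' Build the per-class reference set
#'
#' Encodes the training samples, averages them into per-class reference
#' vectors and derives each class's threshold from the distances of its own
#' training encodings to the reference.
#'
#' @param verifier a trained `slr_verifier`.
#' @param ppdata the `slr_pp_dataset` the verifier was trained on.
#' @param cfg a [threshold_config()].
#' @param idx sample indices to build from (default: the training split).
#' @return object of class `slr_reference_set`: reference vectors plus raw
#'   and clamped thresholds per class.
#' @export
build_reference_set <- function(verifier, ppdata, cfg = threshold_config(),
                                idx = ppdata$train_idx) {
  enc <- encode_samples(verifier, ppdata$x[, , idx, drop = FALSE])
  labels <- ppdata$labels[idx]
  refs <- compute_reference_vectors(enc, labels)
  classes <- as.integer(colnames(refs))
  raw <- numeric(length(classes))
  clamped <- numeric(length(classes))
  for (k in seq_along(classes)) {
    cols <- which(labels == classes[k])
    d <- sqrt(colSums((enc[, cols, drop = FALSE] - refs[, k])^2))
    th <- compute_class_threshold(d, cfg)
    raw[k] <- th$raw
    clamped[k] <- th$clamped
  }
  structure(list(classes = classes, vectors = refs, raw = raw,
                 clamped = clamped, config = cfg),
            class = "slr_reference_set")
}

#' @export
print.slr_reference_set <- function(x, ...) {
  cat(sprintf(
    "slr_reference_set: %d classes, clamped thresholds in [%.2f, %.2f]\n",
    length(x$classes), min(x$clamped), max(x$clamped)))
  invisible(x)
}

#' Verify a classification result
#'
#' Computes the difference (Euclidean distance) between an encoding and the
#' reference vector of the predicted class; the prediction is accepted iff
#' the difference is strictly less than the class threshold.
#'
#' @param encoding 64-dimensional encoding of the window.
#' @param refs an `slr_reference_set`.
#' @param predicted_class class id from the classification model.
#' @return list with `difference` and logical `accepted`.
#' @export
verify_prediction <- function(encoding, refs, predicted_class) {
  k <- match(predicted_class, refs$classes)
  if (is.na(k)) stop_config("unknown class: ", predicted_class)
  difference <- sqrt(sum((encoding - refs$vectors[, k])^2))
  list(difference = difference, accepted = difference < refs$clamped[k])
}

#' Summarize a threshold table
#'
#' @param thresholds numeric threshold values (non-empty).
#' @param low,high inclusive range bounds.
#' @return list with `count_in_range` and `fraction`.
#' @export
threshold_summary <- function(thresholds, low = 14, high = 18) {
  if (length(thresholds) == 0L) stop_config("empty threshold list")
  count <- sum(thresholds >= low & thresholds <= high)
  list(count_in_range = count, fraction = count / length(thresholds))
}

#' Published 86-class threshold table
#'
#' The per-class verification thresholds reported for the 86-category
#' Chinese sign-language vocabulary (including the empty class `[]`) of the
#' online recognition experiments, shipped as a packaged fixture. Values
#' are on the raw (unclamped) scale; 78 of the 86 (90.70%) lie in the
#' operational clamping range \[14, 18\].
#'
#' @return data frame with columns `label` and `threshold`.
#' @export
load_reference_thresholds <- function() {
  path <- system.file("extdata", "class_thresholds_86.csv",
                      package = "slrmech", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
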