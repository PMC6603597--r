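# Continuous-stream scoring: every accepted recognition event is assigned
# exactly one outcome against the ground-truth effective regions --
# correct, or one of the five misrecognition categories:
#   insert       blank region recognized as a gesture
#   misalignment window straddling the adjacent zone and part of a region
#   repeat       same region correctly recognized more than once
#   substitute   region recognized as the wrong class
#   delete       region missed entirely (no correct/substitute match)

#' Event/region matching configuration
#'
#' @param overlap_full minimum overlap fraction for an event to count as
#'   aligned with a region (correct/repeat/substitute).
#' @param overlap_partial overlap fraction below which an event is an
#'   insert; between the two bounds it is a misalignment.
#' @param denominator overlap fraction denominator: `"event"` divides by
#'   the event length (fixed-size sliding windows), `"min"` by the shorter
#'   of event and region (variable-length baseline segments).
#' @export
matching_config <- function(overlap_full = 0.6, overlap_partial = 0.25,
                            denominator = c("event", "min")) {
  if (!(0 < overlap_partial && overlap_partial < overlap_full &&
        overlap_full <= 1)) {
    stop_config("need 0 < overlap_partial < overlap_full <= 1")
  }
  list(overlap_full = overlap_full, overlap_partial = overlap_partial,
       denominator = match.arg(denominator))
}

#' Assign one accepted event an outcome
#'
#' Computes the best overlap fraction `f` of the event span against the
#' regions. `f < overlap_partial` is an insert;
#' `overlap_partial <= f < overlap_full` a misalignment; aligned events are
#' correct on first match of the right class, repeat on later ones, and
#' substitute when the class differs.
#'
#' @param event one-row event (needs `window_start`, `window_end`,
#'   `predicted_class`).
#' @param regions sorted ground-truth region data frame.
#' @param cfg a [matching_config()].
#' @param matched integer vector of region row indices already matched
#'   correct (the caller's registry).
#' @return list with `outcome` and the matched `region` row index (`NA` for
#'   insert/misalignment).
#' @export
match_event <- function(event, regions, cfg = matching_config(),
                        matched = integer(0)) {
  if (nrow(regions) == 0L) {
    return(list(outcome = "insert", region = NA_integer_))
  }
  ov <- pmax(0, pmin(event$window_end, regions$end) -
                  pmax(event$window_start, regions$start))
  ev_len <- event$window_end - event$window_start
  denom <- if (cfg$denominator == "min") {
    pmin(ev_len, regions$end - regions$start)
  } else ev_len
  f <- ov / denom
  best <- which.max(f)
  if (f[best] < cfg$overlap_partial) {
    return(list(outcome = "insert", region = NA_integer_))
  }
  if (f[best] < cfg$overlap_full) {
    return(list(outcome = "misalignment", region = NA_integer_))
  }
  if (event$predicted_class == regions$class_id[best]) {
    if (best %in% matched) {
      list(outcome = "repeat", region = best)
    } else {
      list(outcome = "correct", region = best)
    }
  } else {
    list(outcome = "substitute", region = best)
  }
}

#' Score a recognition run into the outcome taxonomy
#'
#' Applies [match_event()] to the accepted events in stream order,
#' maintaining the matched-region registry; regions that attract neither a
#' correct nor a substitute event are counted as deletes.
#'
#' @param events recognition-event data frame ([run_online()] /
#'   [run_baseline()]); only `accepted` rows are scored.
#' @param regions ground-truth regions (disjoint, sorted).
#' @param cfg a [matching_config()].
#' @return object of class `taxonomy_counts`: named integer counts
#'   `insert`, `misalignment`, `repeat`, `substitute`, `delete`, `correct`,
#'   with the per-event assignment as attribute `assignments`.
#' @export
score_run <- function(events, regions, cfg = matching_config()) {
  if (nrow(regions) > 1L) {
    r <- regions[order(regions$start), ]
    if (any(r$start[-1] < r$end[-nrow(r)])) {
      stop_config("ground-truth regions overlap")
    }
    regions <- r
  }
  acc <- events[events$accepted, , drop = FALSE]
  acc <- acc[order(acc$window_start), , drop = FALSE]
  counts <- c(insert = 0L, misalignment = 0L, "repeat" = 0L,
              substitute = 0L, delete = 0L, correct = 0L)
  correct_matched <- integer(0)
  sub_matched <- integer(0)
  assignments <- character(nrow(acc))
  for (k in seq_len(nrow(acc))) {
    m <- match_event(acc[k, ], regions, cfg, matched = correct_matched)
    assignments[k] <- m$outcome
    counts[m$outcome] <- counts[m$outcome] + 1L
    if (m$outcome == "correct") correct_matched <- c(correct_matched, m$region)
    if (m$outcome == "substitute") sub_matched <- c(sub_matched, m$region)
  }
  counts["delete"] <- sum(!(seq_len(nrow(regions)) %in%
                              c(correct_matched, sub_matched)))
  structure(as.list(counts), assignments = assignments,
            class = "taxonomy_counts")
}

#' @export
print.taxonomy_counts <- function(x, ...) {
  cat("taxonomy_counts:",
      paste(sprintf("%s=%d", names(x), unlist(x)), collapse = " "), "\n")
  invisible(x)
}

#' Compare recognition mechanisms on one stream
#'
#' Scores each mechanism's event table against the same ground truth and
#' collects the outcome counts, per-event assignments and timing summaries
#' (wall time per run and per processed window/segment, taken from the
#' attributes [run_online()] and [run_baseline()] attach).
#'
#' @param event_sets named list of recognition-event data frames, one per
#'   mechanism.
#' @param regions ground-truth regions shared by all runs.
#' @param cfgs a single [matching_config()] or a named list parallel to
#'   `event_sets` (the baseline's variable-length segments typically use
#'   `denominator = "min"`).
#' @return object of class `slr_evaluation_report`.
#' @export
evaluation_report <- function(event_sets, regions, cfgs = matching_config()) {
  stopifnot(length(event_sets) > 0, !is.null(names(event_sets)))
  if (inherits(cfgs, "list") && !is.null(cfgs$overlap_full)) {
    cfgs <- stats::setNames(rep(list(cfgs), length(event_sets)),
                            names(event_sets))
  }
  mech <- lapply(names(event_sets), function(nm) {
    ev <- event_sets[[nm]]
    counts <- score_run(ev, regions, cfgs[[nm]])
    units <- attr(ev, "n_windows") %||% attr(ev, "n_segments")
    elapsed <- attr(ev, "elapsed_s")
    list(counts = counts, assignments = attr(counts, "assignments"),
         n_events = nrow(ev), n_accepted = sum(ev$accepted),
         elapsed_s = elapsed,
         ms_per_unit = if (!is.null(elapsed) && !is.null(units) && units > 0)
           1000 * elapsed / units else NA_real_)
  })
  names(mech) <- names(event_sets)
  structure(list(mechanisms = mech, n_regions = nrow(regions)),
            class = "slr_evaluation_report")
}

#' @export
print.slr_evaluation_report <- function(x, ...) {
  cat(sprintf("slr_evaluation_report: %d regions\n", x$n_regions))
  for (nm in names(x$mechanisms)) {
    m <- x$mechanisms[[nm]]
    cat(sprintf("  %s (%d accepted / %d events", nm, m$n_accepted,
                m$n_events))
    if (!is.na(m$ms_per_unit)) {
      cat(sprintf(", %.2f ms/unit", m$ms_per_unit))
    }
    cat("): ")
    cat(paste(sprintf("%s=%d", names(m$counts), unlist(m$counts)),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' Write recognition events to CSV
#'
#' @param events recognition-event data frame.
#' @param path file path.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  utils::read.csv(path)
}
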