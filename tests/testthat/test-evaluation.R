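regions3 <- data.frame(start = c(100L, 600L, 1100L),
                       end = c(280L, 790L, 1300L),
                       class_id = c(1L, 2L, 3L))

ev_row <- function(start, cls) {
  data.frame(window_start = start, window_end = start + 128L,
             predicted_class = cls, difference = 1, accepted = TRUE)
}

test_that("single events land in the right taxonomy bucket", {
  cfg <- matching_config()
  # entirely inside a blank region
  m <- match_event(ev_row(350, 1L), regions3, cfg)
  expect_equal(m$outcome, "insert")
  # straddling the adjacent zone: overlap fraction between 0.25 and 0.6
  m <- match_event(ev_row(40, 1L), regions3, cfg)   # 68/128 = 0.53
  expect_equal(m$outcome, "misalignment")
  # aligned with the right class
  m <- match_event(ev_row(120, 1L), regions3, cfg)  # fully inside
  expect_equal(m$outcome, "correct")
  expect_equal(m$region, 1L)
  # aligned with the wrong class
  m <- match_event(ev_row(120, 2L), regions3, cfg)
  expect_equal(m$outcome, "substitute")
  # aligned again after a previous correct match
  m <- match_event(ev_row(130, 1L), regions3, cfg, matched = 1L)
  expect_equal(m$outcome, "repeat")
})

test_that("runs are scored into complete, mutually exclusive counts", {
  # no events: every region is a delete
  sc <- score_run(ev_row(0, 1L)[0, ], regions3)
  expect_equal(sc$delete, 3L)
  expect_equal(sc$correct + sc$insert + sc$misalignment +
                 sc$`repeat` + sc$substitute, 0L)
  # one correct event per region
  ev <- rbind(ev_row(120, 1L), ev_row(620, 2L), ev_row(1130, 3L))
  sc <- score_run(ev, regions3)
  expect_equal(sc$correct, 3L)
  expect_equal(sc$delete, 0L)
  expect_equal(sum(unlist(sc[c("insert", "misalignment", "repeat",
                               "substitute")])), 0L)
  # two correct events on one region: 1 correct + 1 repeat
  ev2 <- rbind(ev_row(120, 1L), ev_row(140, 1L))
  sc2 <- score_run(ev2, regions3)
  expect_equal(sc2$correct, 1L)
  expect_equal(sc2$`repeat`, 1L)
  expect_equal(sc2$delete, 2L)
  # substituted regions are not deletes
  sc3 <- score_run(ev_row(120, 3L), regions3)
  expect_equal(sc3$substitute, 1L)
  expect_equal(sc3$delete, 2L)
})

test_that("overlapping ground-truth regions are rejected", {
  bad <- data.frame(start = c(0L, 50L), end = c(100L, 150L),
                    class_id = c(1L, 2L))
  expect_error(score_run(ev_row(0, 1L), bad), "overlap")
})

test_that("randomized runs match an exhaustive assignment oracle", {
  # independent re-implementation: exhaustively compute every event-region
  # overlap fraction, bucket the event, track correct matches in order
  oracle_score <- function(events, regions, cfg) {
    acc <- events[events$accepted, , drop = FALSE]
    acc <- acc[order(acc$window_start), , drop = FALSE]
    counts <- c(insert = 0, misalignment = 0, "repeat" = 0,
                substitute = 0, delete = 0, correct = 0)
    seen_correct <- c(); seen_sub <- c()
    for (k in seq_len(nrow(acc))) {
      fs <- numeric(nrow(regions))
      for (r in seq_len(nrow(regions))) {
        lo <- max(acc$window_start[k], regions$start[r])
        hi <- min(acc$window_end[k], regions$end[r])
        fs[r] <- max(0, hi - lo) / (acc$window_end[k] - acc$window_start[k])
      }
      r <- which.max(fs)
      out <- if (fs[r] < cfg$overlap_partial) "insert"
      else if (fs[r] < cfg$overlap_full) "misalignment"
      else if (acc$predicted_class[k] != regions$class_id[r]) "substitute"
      else if (r %in% seen_correct) "repeat" else "correct"
      if (out == "correct") seen_correct <- c(seen_correct, r)
      if (out == "substitute") seen_sub <- c(seen_sub, r)
      counts[out] <- counts[out] + 1
    }
    counts["delete"] <- sum(!(seq_len(nrow(regions)) %in%
                                c(seen_correct, seen_sub)))
    counts
  }
  cfg <- matching_config()
  set.seed(14)
  for (trial in 1:10) {
    n_ev <- sample(0:15, 1)
    starts <- sort(sample(0:1300, n_ev, replace = TRUE))
    events <- data.frame(window_start = starts, window_end = starts + 128L,
                         predicted_class = sample(1:3, n_ev, replace = TRUE),
                         difference = 0, accepted = TRUE)
    sc <- score_run(events, regions3, cfg)
    oc <- oracle_score(events, regions3, cfg)
    expect_equal(unlist(sc), oc[names(unlist(sc))])
    # invariants: event outcomes account for every accepted event,
    # deletes complement the matched regions
    expect_equal(sc$insert + sc$misalignment + sc$`repeat` +
                   sc$substitute + sc$correct, n_ev)
    expect_lte(sc$delete, nrow(regions3))
  }
})

test_that("baseline segments are matched by the shorter-span denominator", {
  cfg <- matching_config(denominator = "min")
  # a long detected segment swallowing a short region still aligns
  long_ev <- data.frame(window_start = 80L, window_end = 400L,
                        predicted_class = 1L, difference = NA,
                        accepted = TRUE)
  m <- match_event(long_ev, regions3, cfg)
  expect_equal(m$outcome, "correct")
  # with the event-length denominator it would only be a misalignment
  m2 <- match_event(long_ev, regions3, matching_config())
  expect_equal(m2$outcome, "misalignment")
})

test_that("matching configuration is validated", {
  expect_error(matching_config(overlap_full = 1.2), "overlap")
  expect_error(matching_config(overlap_partial = 0.7), "overlap")
})

test_that("mechanism reports combine counts, assignments and timing", {
  ev <- rbind(ev_row(120, 1L), ev_row(620, 2L))
  attr(ev, "elapsed_s") <- 0.5
  attr(ev, "n_windows") <- 100L
  rep <- evaluation_report(list(rv = ev, seg = ev_row(1130, 3L)), regions3)
  expect_named(rep$mechanisms, c("rv", "seg"))
  expect_equal(rep$mechanisms$rv$counts$correct, 2L)
  expect_equal(rep$mechanisms$rv$ms_per_unit, 5)
  expect_length(rep$mechanisms$rv$assignments, 2L)
  expect_equal(rep$mechanisms$seg$counts$delete, 2L)
  expect_output(print(rep), "slr_evaluation_report")
})

test_that("event tables round-trip through CSV", {
  ev <- rbind(ev_row(120, 1L), ev_row(620, 2L))
  f <- tempfile(fileext = ".csv")
  write_events_csv(ev, f)
  back <- read_events_csv(f)
  expect_equal(back$window_start, ev$window_start)
  expect_equal(back$predicted_class, ev$predicted_class)
})
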