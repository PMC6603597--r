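test_that("synthesized samples have the canonical shape and length bounds", {
  cfg <- small_config()
  tps <- gesture_templates(5, seed = 1)
  for (seed in 1:10) {
    s <- synthesize_sample(tps[[2]], cfg, seed = seed)
    expect_equal(nrow(s), 14L)
    expect_gte(ncol(s), 164L)
    expect_lte(ncol(s), 207L)
  }
})

test_that("noise-free empty-class samples have silent sEMG channels", {
  cfg <- generator_config(n_classes = 3, noise_sd = 0,
                          amp_jitter = 0, time_jitter = 0)
  tps <- gesture_templates(3, seed = 1)
  empty <- tps[[empty_class_id(tps)]]
  s <- synthesize_sample(empty, cfg, seed = 4)
  expect_equal(max(abs(s[1:8, ])), 0)
})

test_that("sample synthesis is deterministic in the seed", {
  cfg <- small_config()
  tp <- gesture_templates(5, seed = 1)[[3]]
  expect_identical(synthesize_sample(tp, cfg, seed = 9),
                   synthesize_sample(tp, cfg, seed = 9))
  expect_false(identical(synthesize_sample(tp, cfg, seed = 9),
                         synthesize_sample(tp, cfg, seed = 10)))
})

test_that("invalid template duration bounds are rejected", {
  tp <- gesture_templates(3, seed = 1)[[1]]
  tp$duration_range <- c(200L, 100L)
  expect_error(synthesize_sample(tp, small_config(), seed = 1), "duration")
})

test_that("composed streams annotate one region per scheduled gesture", {
  cfg <- small_config()
  tps <- gesture_templates(5, seed = 2)
  out <- compose_stream(tps, schedule = rep(1:4, length.out = 10), cfg,
                        seed = 5)
  expect_equal(nrow(out$regions), 10L)
  expect_identical(out$regions$class_id, rep(1:4, length.out = 10))
  # regions are disjoint, sorted, inside the stream
  expect_true(all(diff(out$regions$start) > 0))
  expect_true(all(out$regions$start[-1] >= out$regions$end[-10]))
  expect_true(all(out$regions$end <= ncol(out$stream$values)))
})

test_that("inter-region gaps stay within the configured 0.5-5 s range", {
  cfg <- small_config()
  for (seed in c(5, 6, 7)) {
    out <- compose_stream(gesture_templates(5, seed = 2),
                          schedule = rep(1:4, length.out = 8), cfg,
                          seed = seed)
    gaps <- out$regions$start[-1] - out$regions$end[-8]
    expect_true(all(gaps >= 50 & gaps <= 500))
  }
})

test_that("stream composition is deterministic and rejects unknown labels", {
  cfg <- small_config()
  tps <- gesture_templates(5, seed = 2)
  a <- compose_stream(tps, 1:3, cfg, seed = 11)
  b <- compose_stream(tps, 1:3, cfg, seed = 11)
  expect_identical(a$stream$values, b$stream$values)
  expect_identical(a$regions, b$regions)
  expect_error(compose_stream(tps, c(1, 99), cfg, seed = 1), "class ids")
})

test_that("interference bursts never overlap annotated regions", {
  cfg <- small_config(interference_rate = 6)
  tps <- gesture_templates(5, seed = 2)
  for (seed in 1:5) {
    out <- compose_stream(tps, schedule = rep(1:4, 2), cfg, seed = seed)
    if (nrow(out$interference) == 0L) next
    for (k in seq_len(nrow(out$interference))) {
      ov <- pmin(out$interference$end[k], out$regions$end) -
        pmax(out$interference$start[k], out$regions$start)
      expect_true(all(ov <= 0))
    }
  }
})

test_that("offline datasets are uniform over classes with a ~10% test split", {
  cfg <- generator_config(n_classes = 10, samples_per_class = 20)
  ds <- build_offline_dataset(cfg, seed = 8)
  expect_length(ds$samples, 200L)
  expect_true(all(table(ds$labels) == 20L))
  # stratified split: 2 test samples per class at 10% of 20
  expect_true(all(table(ds$labels[ds$test_idx]) == 2L))
  expect_length(intersect(ds$train_idx, ds$test_idx), 0L)
  expect_error(build_offline_dataset(
    generator_config(n_classes = 3, samples_per_class = 1)), "samples_per_class")
})

test_that("dataset generation is bit-reproducible under a fixed seed", {
  cfg <- generator_config(n_classes = 3, samples_per_class = 4)
  a <- build_offline_dataset(cfg, seed = 13)
  b <- build_offline_dataset(cfg, seed = 13)
  expect_identical(a$samples, b$samples)
  expect_identical(a$test_idx, b$test_idx)
})

test_that("classes are separable by a nearest-centroid oracle at moderate noise", {
  # envelope-level features: mean |sEMG| and mean IMU value per channel
  # on a fixed-length resampled grid
  env_features <- function(s) {
    grid <- seq(0, 1, length.out = 32)
    f <- c()
    for (r in 1:8) {
      f <- c(f, approx(seq(0, 1, length.out = ncol(s)), abs(s[r, ]),
                       xout = grid)$y)
    }
    for (r in 9:14) {
      f <- c(f, approx(seq(0, 1, length.out = ncol(s)), s[r, ],
                       xout = grid)$y)
    }
    f
  }
  cfg <- generator_config(n_classes = 6, samples_per_class = 30,
                          noise_sd = 0.25)
  ds <- build_offline_dataset(cfg, seed = 17)
  X <- vapply(ds$samples, env_features, numeric(14 * 32))
  gesture <- ds$labels != ds$empty_class  # 5 gesture classes
  tr <- intersect(ds$train_idx, which(gesture))
  te <- intersect(ds$test_idx, which(gesture))
  classes <- sort(unique(ds$labels[tr]))
  cent <- vapply(classes, function(cl) {
    rowMeans(X[, tr[ds$labels[tr] == cl], drop = FALSE])
  }, numeric(nrow(X)))
  pred <- classes[apply(X[, te], 2, function(v) {
    which.min(colSums((cent - v)^2))
  })]
  expect_gt(mean(pred == ds$labels[te]), 0.9)
})

test_that("stream and region round-trips through plain-text files", {
  out <- small_stream()
  f1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".csv")
  write_stream_tsv(out$stream, f1)
  write_regions_csv(out$regions, f2)
  st2 <- read_stream_tsv(f1)
  expect_equal(st2$sample_rate, out$stream$sample_rate)
  expect_equal(st2$values, out$stream$values, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(read_regions_csv(f2), out$regions)
})
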