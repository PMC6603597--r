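test_that("quadratic unit fits recover exact polynomials", {
  n <- 1:16
  expect_equal(fit_quadratic_unit(n^2), c(A = 1, B = 0, C = 0),
               tolerance = 1e-10)
  expect_equal(fit_quadratic_unit(rep(7, 16)), c(A = 0, B = 0, C = 7),
               tolerance = 1e-10)
  expect_error(fit_quadratic_unit(c(1:15, NA)), "finite")
})

test_that("quadratic fits match a normal-equations least-squares oracle", {
  set.seed(42)
  for (i in 1:5) {
    y <- 0.3 * (1:16) + rnorm(16, sd = 0.5)  # noisy linear
    X <- cbind((1:16)^2, 1:16, 1)
    oracle <- solve(t(X) %*% X, t(X) %*% y)[, 1]
    expect_equal(unname(fit_quadratic_unit(y)), oracle, tolerance = 1e-9)
  }
})

test_that("the piecewise smoother reproduces global quadratics exactly", {
  n <- 1:128
  ch <- 0.01 * n^2 - 0.5 * n + 3
  out <- smooth_inertial_channel(ch)
  expect_length(out, 64L)
  expect_equal(out, ch[seq(1, 128, by = 2)], tolerance = 1e-9)
})

test_that("overlap points average the two adjacent unit fits", {
  set.seed(1)
  ch <- cumsum(rnorm(128))
  cfg <- smoother_config()  # 16-point units, 2-point overlap, stride 14
  out <- smooth_inertial_channel(ch, cfg)
  # reconstruction index 15 lies in unit 1 (local n = 15) and unit 2
  # (starting at 15, local n = 1); kept indices are 1,3,...  so index 15 is
  # output position 8
  f1 <- fit_quadratic_unit(ch[1:16])
  f2 <- fit_quadratic_unit(ch[15:30])
  v1 <- f1["A"] * 15^2 + f1["B"] * 15 + f1["C"]
  v2 <- f2["A"] * 1^2 + f2["B"] * 1 + f2["C"]
  expect_equal(out[8], unname((v1 + v2) / 2), tolerance = 1e-9)
})

test_that("smoother validates shapes and tiling schemes", {
  expect_error(smooth_inertial_channel(rnorm(100)), "128")
  expect_error(smoother_config(unit_length = 16, overlap = 3), "tile")
  expect_error(smoother_config(unit_length = 4, overlap = 4), "overlap")
})

test_that("the db5 analysis step matches an independent reference", {
  # frozen from a PyWavelets periodization-mode decomposition of
  # x = (0:15)^1.5 + sin(0:15)
  x <- (0:15)^1.5 + sin(0:15)
  st <- slrmech:::dwt_step_per(x)
  expect_equal(st$cA,
               c(82.05721472, 43.57508425, 3.26646735, 7.75906453,
                 15.65381666, 28.52640198, 40.06861585, 47.80113136),
               tolerance = 1e-7)
  expect_equal(st$cD,
               c(-4.32329086, 1.18152607, -0.19383874, -0.07706358,
                 0.26217333, -0.13997487, -27.84311382, 9.20666473),
               tolerance = 1e-7)
})

test_that("the periodized wavelet transform preserves energy", {
  set.seed(7)
  for (i in 1:5) {
    x <- rnorm(128)
    dec <- slrmech:::dwt_periodized(x, 4)
    expect_equal(sum(x^2), sum(dec$cA^2) + sum(unlist(dec$details)^2),
                 tolerance = 1e-9)
  }
})

test_that("sEMG compression suppresses sub-cutoff tones and zeros", {
  expect_equal(compress_semg_channel(numeric(128)), numeric(64))
  t <- (0:127) / 100
  tone <- sin(2 * pi * 5 * t)  # 5 Hz, below the 15 Hz noise cutoff
  out <- compress_semg_channel(tone)
  expect_length(out, 64L)
  expect_lt(sum(out^2), 0.01 * sum(tone^2))
})

test_that("sEMG compression output has fixed length and bounded energy", {
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(128, sd = 2)
    out <- compress_semg_channel(x)
    expect_length(out, 64L)
    expect_lte(sum(out^2), sum(x^2))
  }
  # coefficient-concatenation variant also yields 64 points
  out2 <- compress_semg_channel(rnorm(128),
                                wavelet_config(extend = "concat"))
  expect_length(out2, 64L)
})

test_that("wavelet configuration is validated", {
  expect_error(wavelet_config(levels = 7), "levels")
  expect_error(wavelet_config(noise_cutoff_hz = 60), "Nyquist")
  expect_error(wavelet_config(family = "haar"), "db5")
})

test_that("window preprocessing maps 14 x 128 onto 14 x 64 deterministically", {
  set.seed(3)
  w <- matrix(rnorm(14 * 128), 14, 128)
  out <- preprocess_window(w)
  expect_equal(dim(out), c(14L, 64L))
  expect_identical(out, preprocess_window(w))
  expect_error(preprocess_window(w[, 1:100]), "14 x 128")
  # zero window stays zero before normalization
  expect_equal(preprocess_window(matrix(0, 14, 128)), matrix(0, 14, 64))
})

test_that("normalization statistics are applied identically in both modes", {
  set.seed(4)
  w <- matrix(rnorm(14 * 128), 14, 128)
  stats <- list(mean = rnorm(14), sd = runif(14, 0.5, 2))
  a <- preprocess_window(w, stats = stats)
  b <- (preprocess_window(w) - stats$mean) / stats$sd
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("dataset preprocessing freezes training statistics", {
  pp <- small_pp()
  expect_equal(dim(pp$x)[1:2], c(14L, 64L))
  expect_equal(dim(pp$x)[3], length(small_dataset()$samples))
  # training split is standardized per channel by construction
  xtr <- pp$x[, , pp$train_idx]
  m <- apply(xtr, 1, mean)
  s <- apply(xtr, 1, sd)
  expect_equal(m, rep(0, 14), tolerance = 1e-8)
  expect_equal(s, rep(1, 14), tolerance = 1e-6)
})
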