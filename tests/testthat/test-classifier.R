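test_that("leaky_relu follows its closed form", {
  expect_equal(leaky_relu(2), 2)
  expect_equal(leaky_relu(-2, 0.01), -0.02)
  expect_equal(leaky_relu(0), 0)
  expect_equal(leaky_relu(c(-1, 1), 0.1), c(-0.1, 1))
  expect_error(leaky_relu(1, lambda = 1.5), "lambda")
})

test_that("named structures satisfy the layout constraints", {
  specs <- lapply(c("A", "B", "C", "D", "E"), slrmech:::vgg_preset)
  names(specs) <- c("A", "B", "C", "D", "E")
  totals <- vapply(specs, function(s) sum(lengths(s$blocks)), integer(1))
  # A and C have equal total convolution counts
  expect_equal(totals[["A"]], totals[["C"]])
  expect_equal(totals[["A"]], 4L)
  # B and D share block count and per-block layer counts
  expect_equal(lengths(specs$B$blocks), lengths(specs$D$blocks))
  # widths differ between B and D in the deeper blocks
  expect_false(identical(specs$B$blocks, specs$D$blocks))
  # monotone block depth for all five
  for (s in specs) expect_true(all(diff(lengths(s$blocks)) >= 0))
  # E adds one block to D
  expect_equal(length(specs$E$blocks), length(specs$D$blocks) + 1L)
})

test_that("structure D exposes a 1024-dimensional flattened feature", {
  set.seed(1)
  net <- build_architecture("D", n_classes = 10)
  expect_equal(net$feature_size, 1024L)
  expect_equal(net$spec$adaptive_pool, 2L)
  # exactly one fully connected layer when adaptive pooling is present
  expect_equal(sum(vapply(net$layers, function(l) l$type == "fc",
                          logical(1))), 1L)
  # one max-pool per block
  expect_equal(sum(vapply(net$layers, function(l) l$type == "maxpool",
                          logical(1))), 4L)
})

test_that("without adaptive pooling the feature length is 64 / 2^pools", {
  set.seed(1)
  spec <- architecture_spec(list(8, 16), adaptive_pool = NULL,
                            fc_layers = c(32))
  net <- build_architecture(spec, n_classes = 5)
  expect_equal(net$feature_size, 16L * (64L / 2^2))
  expect_equal(sum(vapply(net$layers, function(l) l$type == "fc",
                          logical(1))), 2L)  # one hidden + class layer
})

test_that("block-depth monotonicity is enforced", {
  expect_error(architecture_spec(list(c(64, 64), 128)), "at least as many")
})

test_that("all five structures run forward on a batch", {
  set.seed(2)
  x <- array(rnorm(14 * 64 * 3), c(14, 64, 3))
  for (name in c("A", "B", "C", "D", "E")) {
    net <- build_architecture(name, n_classes = 7)
    out <- slrmech:::net_forward(net$layers, x)$out
    expect_equal(dim(out), c(7L, 3L))
  }
})

test_that("training reduces the loss on an easy fixture", {
  log <- small_classifier()$log
  expect_true(all(diff(log$loss[1:5]) < 0.05))  # non-increasing trend
  expect_lt(log$loss[5], log$loss[1])
  expect_gt(tail(log$test_accuracy, 1), 0.9)
  expect_true(all(c("loss", "test_accuracy", "train_time", "test_time")
                  %in% names(log)))
})

test_that("training is deterministic under a fixed seed", {
  pp <- small_pp()
  cfg <- train_config(batch_size = 32, lr = 1e-3, epochs = 2, seed = 99)
  a <- train_classifier(pp, tiny_arch(), cfg)
  b <- train_classifier(pp, tiny_arch(), cfg)
  expect_identical(a$log$loss, b$log$loss)
  expect_identical(a$network$layers, b$network$layers)
})

test_that("training rejects degenerate datasets", {
  pp <- small_pp()
  pp$train_idx <- integer(0)
  expect_error(train_classifier(pp, tiny_arch()), "empty")
  pp2 <- small_pp()
  pp2$train_idx <- c(which(pp2$labels == 1)[1], which(pp2$labels == 2))
  expect_error(train_classifier(pp2, tiny_arch()), "at least 2")
})

test_that("prediction returns a normalized posterior with matching argmax", {
  clf <- small_classifier()
  pp <- small_pp()
  p1 <- predict(clf, pp$x[, , 1])
  expect_equal(sum(p1$posterior), 1, tolerance = 1e-6)
  expect_equal(p1$class_id, which.max(p1$posterior))
  expect_error(predict(clf, pp$x[1:10, , 1]), "shape")
})

test_that("batched and single-sample prediction agree", {
  clf <- small_classifier()
  pp <- small_pp()
  idx <- c(2, 15, 40)
  batch <- predict(clf, pp$x[, , idx])
  for (k in seq_along(idx)) {
    single <- predict(clf, pp$x[, , idx[k]])
    expect_equal(single$posterior, batch$posterior[, k], tolerance = 1e-10)
    expect_equal(single$class_id, batch$class_id[k])
  }
})

test_that("the learning-rate schedule decays by 0.1 every 10 epochs", {
  expect_equal(slrmech:::lr_at_epoch(1e-4, 1), 1e-4)
  expect_equal(slrmech:::lr_at_epoch(1e-4, 10), 1e-4)
  expect_equal(slrmech:::lr_at_epoch(1e-4, 11), 1e-5)
  expect_equal(slrmech:::lr_at_epoch(1e-4, 21), 1e-6)
})

test_that("batch normalization stabilizes the training loss", {
  pp <- small_pp()
  spec_bn <- architecture_spec(list(8, 16), batch_norm = TRUE)
  spec_nobn <- architecture_spec(list(8, 16), batch_norm = FALSE)
  cfg <- train_config(batch_size = 32, lr = 1e-3, epochs = 8, seed = 31)
  with_bn <- train_classifier(pp, spec_bn, cfg)
  without <- train_classifier(pp, spec_nobn, cfg)
  # BN reaches a lower loss with smaller epoch-to-epoch variation
  expect_lt(sd(diff(with_bn$log$loss)), sd(diff(without$log$loss)))
  expect_lt(tail(with_bn$log$loss, 1), tail(without$log$loss, 1))
})

test_that("network gradients match numerical differentiation", {
  set.seed(5)
  net <- build_architecture(architecture_spec(list(4), adaptive_pool = 2),
                            n_classes = 3)
  x <- array(rnorm(14 * 64 * 2), c(14, 64, 2))
  labels <- c(1L, 3L)
  # batch-statistics mode throughout so the analytic BN backward applies
  loss_at <- function(layers) {
    fw <- slrmech:::net_forward(layers, x, training = TRUE)
    slrmech:::softmax_ce(fw$out, labels)$loss
  }
  fw <- slrmech:::net_forward(net$layers, x, training = TRUE)
  ce <- slrmech:::softmax_ce(fw$out, labels)
  bw <- slrmech:::net_backward(net$layers, fw$caches, ce$dlogits)
  # check a handful of conv and fc weight entries
  for (li in which(vapply(net$layers, function(l)
    l$type %in% c("conv", "fc"), logical(1)))) {
    for (k in c(1, 5)) {
      eps <- 1e-6
      lp <- net$layers; lp[[li]]$W[k] <- lp[[li]]$W[k] + eps
      lm <- net$layers; lm[[li]]$W[k] <- lm[[li]]$W[k] - eps
      num <- (loss_at(lp) - loss_at(lm)) / (2 * eps)
      expect_equal(bw$grads[[li]]$W[k], num, tolerance = 1e-4)
    }
  }
})
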