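# Siamese verification network: two weight-sharing copies of the
# classifier's convolutional trunk (structure D + adaptive pooling, 1024
# features) followed by a 1024 -> 64 fully connected encoder. The output is
# the Euclidean distance between the two 64-dimensional encodings.

ENCODING_DIM <- 64L

#' Sample training pairs for the verifier
#'
#' Draws `multiplier` times as many pairs as there are samples, half from
#' the same class and half from different classes (within one pair of the
#' target), and records a 90/10 train/test split of the pairs.
#'
#' @param labels integer class labels of the available samples.
#' @param multiplier pair count as a multiple of the sample count.
#' @param seed RNG seed.
#' @param train_fraction fraction of pairs used for training.
#' @return data frame with columns `i`, `j` (sample indices), `y` (0 = same
#'   class, 1 = different) and `train` (logical split flag).
#' @export
sample_pairs <- function(labels, multiplier = 5L, seed = 1L,
                         train_fraction = 0.9) {
  if (multiplier < 1L) stop_config("multiplier must be positive")
  classes <- unique(labels)
  if (length(classes) < 2L) {
    stop_config("cannot form different-class pairs from a single class")
  }
  by_class <- split(seq_along(labels), labels)
  if (any(lengths(by_class) < 2L)) {
    stop_config("every class needs at least 2 samples to form same pairs")
  }
  n_pairs <- multiplier * length(labels)
  n_same <- n_pairs %/% 2L
  with_seed(seed, {
    cls_same <- sample(names(by_class), n_same, replace = TRUE)
    same <- t(vapply(cls_same, function(cl) sample(by_class[[cl]], 2L),
                     integer(2)))
    n_diff <- n_pairs - n_same
    i <- sample(seq_along(labels), n_diff, replace = TRUE)
    j <- vapply(i, function(ii) {
      repeat {
        jj <- sample(seq_along(labels), 1L)
        if (labels[jj] != labels[ii]) return(jj)
      }
    }, integer(1))
    pairs <- data.frame(
      i = c(same[, 1], i), j = c(same[, 2], j),
      y = rep(c(0L, 1L), c(n_same, n_diff)))
    pairs <- pairs[sample(nrow(pairs)), ]
    rownames(pairs) <- NULL
    pairs$train <- seq_len(nrow(pairs)) <= round(train_fraction * nrow(pairs))
    pairs
  })
}

#' Pairwise loss functions
#'
#' `contrastive_loss()` is the classical margin loss
#' `(1-y) D^2/2 + y max(0, m - D)^2 / 2`; its gradient vanishes for
#' different-class pairs beyond the margin. `sigmoid_modification_loss()`
#' instead treats `p = sigmoid(D - m)` as the probability that the pair is
#' cross-class and scores it with binary cross-entropy against the label;
#' `p = 0.5` exactly at the boundary point `D = m` and the gradient is
#' nonzero everywhere.
#'
#' @param D non-negative encoding distance(s).
#' @param y pair label: 0 = same class, 1 = different class.
#' @param m margin / boundary point.
#' @return loss value(s).
#' @export
contrastive_loss <- function(D, y, m) {
  (1 - y) * 0.5 * D^2 + y * 0.5 * pmax(0, m - D)^2
}

#' @rdname contrastive_loss
#' @export
sigmoid_modification_loss <- function(D, y, m) {
  p <- pair_difference_probability(D, m)
  -(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
}

#' @rdname contrastive_loss
#' @export
pair_difference_probability <- function(D, m) {
  stats::plogis(D - m)
}

# dLoss/dD for a batch.
pair_loss_grad <- function(D, y, m, loss) {
  if (loss == "sigmoid_modification") {
    stats::plogis(D - m) - y
  } else {
    (1 - y) * D - y * pmax(0, m - D)
  }
}

#' Verifier training configuration
#'
#' @param batch_size pairs per batch.
#' @param lr initial Adam learning rate, scaled by 0.1 every 10 epochs.
#' @param epochs maximum training epochs.
#' @param pair_multiplier pair count as a multiple of the dataset size.
#' @param margin boundary point `m` of the pairwise loss, on the encoding
#'   distance scale.
#' @param loss `"sigmoid_modification"` or `"contrastive"`.
#' @param init `"transfer_from_classifier"` (copy the trained classifier's
#'   convolutional trunk) or `"normal"`.
#' @param init_sd weight standard deviation for normally initialized parts.
#' @param plateau_tol,plateau_epochs training stops early once the relative
#'   change of both separation quantiles (L1, L2) stays below `plateau_tol`
#'   for `plateau_epochs` consecutive epochs.
#' @param seed RNG seed.
#' @export
verifier_config <- function(batch_size = 256L, lr = 1e-4, epochs = 15L,
                            pair_multiplier = 5L, margin = 10,
                            loss = c("sigmoid_modification", "contrastive"),
                            init = c("transfer_from_classifier", "normal"),
                            init_sd = 0.02, plateau_tol = 0.01,
                            plateau_epochs = 3L, seed = 1L) {
  if (pair_multiplier < 1L) stop_config("pair_multiplier must be positive")
  if (margin <= 0) stop_config("margin must be positive")
  list(batch_size = as.integer(batch_size), lr = lr,
       epochs = as.integer(epochs),
       pair_multiplier = as.integer(pair_multiplier), margin = margin,
       loss = match.arg(loss), init = match.arg(init), init_sd = init_sd,
       plateau_tol = plateau_tol, plateau_epochs = as.integer(plateau_epochs),
       seed = as.integer(seed))
}

# Build the encoder layer stack: classifier trunk + 1024 -> 64 head.
build_encoder_layers <- function(arch, n_classes, init, init_sd,
                                 classifier_model = NULL) {
  net <- build_architecture(arch, n_classes = n_classes, init_sd = init_sd)
  trunk <- net$layers[seq_len(net$flatten_idx)]
  if (init == "transfer_from_classifier") {
    if (is.null(classifier_model)) {
      stop_config("transfer initialization needs a trained classifier")
    }
    src <- classifier_model$network
    if (src$flatten_idx != net$flatten_idx ||
        src$feature_size != net$feature_size) {
      stop_config("classifier trunk does not match the verifier architecture")
    }
    trunk <- src$layers[seq_len(src$flatten_idx)]
  }
  head <- nn_fc(net$feature_size, ENCODING_DIM, init_sd)
  list(layers = c(trunk, list(head)), feature_size = net$feature_size)
}

encoder_encode <- function(encoder, x, training = FALSE, batch = 512L) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  n <- dim(x)[3]
  out <- matrix(0, ENCODING_DIM, n)
  for (b0 in seq(1L, n, by = batch)) {
    bi <- b0:min(b0 + batch - 1L, n)
    out[, bi] <- net_forward(encoder$layers, x[, , bi, drop = FALSE],
                             training = training)$out
  }
  out
}

#' Encode samples and measure encoding distance
#'
#' `encode_samples()` maps preprocessed samples to 64-dimensional vectors;
#' `encode_distance()` returns the Euclidean distance between the encodings
#' of two samples (symmetric, zero for identical inputs).
#'
#' @param encoder a trained `slr_verifier` (or its encoder component).
#' @param x 14 x 64 matrix or 14 x 64 x N array.
#' @param x1,x2 preprocessed samples (14 x 64 matrices).
#' @export
encode_samples <- function(encoder, x) {
  if (inherits(encoder, "slr_verifier")) encoder <- encoder$encoder
  encoder_encode(encoder, x, training = FALSE)
}

#' @rdname encode_samples
#' @export
encode_distance <- function(encoder, x1, x2) {
  e <- encode_samples(encoder, array(c(x1, x2), c(dim(x1), 2L)))
  sqrt(sum((e[, 1] - e[, 2])^2))
}

# Held-out separation report: L1 = 95% quantile of different-pair distances,
# L2 = 5% quantile of same-pair distances, plus distance histograms.
distance_report <- function(D, y, breaks = 30L) {
  L1 <- unname(stats::quantile(D[y == 1L], 0.95, type = 7))
  L2 <- unname(stats::quantile(D[y == 0L], 0.05, type = 7))
  h <- graphics::hist(D, breaks = breaks, plot = FALSE)
  same_h <- graphics::hist(D[y == 0L], breaks = h$breaks, plot = FALSE)$counts
  diff_h <- graphics::hist(D[y == 1L], breaks = h$breaks, plot = FALSE)$counts
  list(L1 = L1, L2 = L2,
       median_same = stats::median(D[y == 0L]),
       median_diff = stats::median(D[y == 1L]),
       breaks = h$breaks, same_counts = same_h, diff_counts = diff_h)
}

#' Train the Siamese verification model
#'
#' Both branches share one parameter set; each batch stacks the two sides
#' of its pairs, encodes them in one pass, applies the pairwise loss to the
#' Euclidean distances and backpropagates the summed branch gradients.
#' After each epoch the held-out pairs are scored into a distance report
#' (L1/L2 separation quantiles); training stops early when both quantiles
#' plateau.
#'
#' @param ppdata an `slr_pp_dataset`.
#' @param pairs pair table from [sample_pairs()]; drawn automatically from
#'   `ppdata` when `NULL`.
#' @param cfg a [verifier_config()].
#' @param classifier_model trained `slr_classifier` used when
#'   `cfg$init == "transfer_from_classifier"`.
#' @param arch trunk architecture (must match the classifier's when
#'   transferring).
#' @return object of class `slr_verifier` with the encoder, the held-out
#'   `report` and a per-epoch `log`.
#' @export
train_verifier <- function(ppdata, pairs = NULL, cfg = verifier_config(),
                           classifier_model = NULL, arch = "D") {
  if (is.null(pairs)) {
    pairs <- sample_pairs(ppdata$labels, cfg$pair_multiplier, seed = cfg$seed)
  }
  tr_pairs <- pairs[pairs$train, ]
  te_pairs <- pairs[!pairs$train, ]
  with_seed(cfg$seed + 1L, {
    enc <- build_encoder_layers(arch, ppdata$n_classes, cfg$init, cfg$init_sd,
                                classifier_model)
    layers <- enc$layers
    state <- adam_init(layers)
    step <- 0L
    log <- data.frame()
    hist_L1 <- c(); hist_L2 <- c()
    for (epoch in seq_len(cfg$epochs)) {
      lr <- lr_at_epoch(cfg$lr, epoch)
      idx <- sample(nrow(tr_pairs))
      losses <- c()
      for (b0 in seq(1L, length(idx), by = cfg$batch_size)) {
        bi <- idx[b0:min(b0 + cfg$batch_size - 1L, length(idx))]
        pb <- tr_pairs[bi, ]
        nb <- nrow(pb)
        X <- ppdata$x[, , c(pb$i, pb$j), drop = FALSE]
        fw <- net_forward(layers, X, training = TRUE)
        layers <- fw$layers
        E <- fw$out
        e1 <- E[, seq_len(nb), drop = FALSE]
        e2 <- E[, nb + seq_len(nb), drop = FALSE]
        diff <- e1 - e2
        D <- sqrt(colSums(diff^2))
        loss_fun <- if (cfg$loss == "sigmoid_modification") {
          sigmoid_modification_loss
        } else contrastive_loss
        losses <- c(losses, mean(loss_fun(D, pb$y, cfg$margin)))
        dD <- pair_loss_grad(D, pb$y, cfg$margin, cfg$loss) / nb
        unit <- sweep(diff, 2, pmax(D, 1e-8), "/")
        dE1 <- sweep(unit, 2, dD, "*")
        dE <- cbind(dE1, -dE1)
        bw <- net_backward(layers, fw$caches, dE)
        step <- step + 1L
        up <- adam_step(layers, bw$grads, state, lr, step)
        layers <- up$layers
        state <- up$state
      }
      encoder <- list(layers = layers, feature_size = enc$feature_size)
      De <- pair_distances(encoder, ppdata, te_pairs)
      rep_e <- distance_report(De, te_pairs$y)
      log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                   loss = mean(losses),
                                   L1 = rep_e$L1, L2 = rep_e$L2))
      hist_L1 <- c(hist_L1, rep_e$L1)
      hist_L2 <- c(hist_L2, rep_e$L2)
      if (plateau_reached(hist_L1, hist_L2, cfg$plateau_tol,
                          cfg$plateau_epochs)) break
    }
    encoder <- list(layers = layers, feature_size = enc$feature_size)
    structure(list(encoder = encoder,
                   report = distance_report(
                     pair_distances(encoder, ppdata, te_pairs), te_pairs$y),
                   log = log, cfg = cfg, n_classes = ppdata$n_classes),
              class = "slr_verifier")
  })
}

# Distances for a pair table (inference mode).
pair_distances <- function(encoder, ppdata, pairs, batch = 512L) {
  D <- numeric(nrow(pairs))
  for (b0 in seq(1L, nrow(pairs), by = batch)) {
    bi <- b0:min(b0 + batch - 1L, nrow(pairs))
    pb <- pairs[bi, ]
    nb <- nrow(pb)
    E <- encoder_encode(encoder, ppdata$x[, , c(pb$i, pb$j), drop = FALSE])
    D[bi] <- sqrt(colSums((E[, seq_len(nb), drop = FALSE] -
                             E[, nb + seq_len(nb), drop = FALSE])^2))
  }
  D
}

# L1/L2 are considered stable when their relative change stays within tol
# over `need` consecutive epoch-to-epoch transitions.
plateau_reached <- function(L1, L2, tol, need) {
  n <- length(L1)
  if (n < need + 1L) return(FALSE)
  rel <- function(v) abs(diff(v)) / pmax(abs(v[-length(v)]), 1e-12)
  all(utils::tail(rel(L1), need) < tol) &&
    all(utils::tail(rel(L2), need) < tol)
}

#' @export
print.slr_verifier <- function(x, ...) {
  cat(sprintf(
    "slr_verifier: %d epochs, held-out L1 = %.2f, L2 = %.2f (median diff %.2f / same %.2f)\n",
    nrow(x$log), x$report$L1, x$report$L2,
    x$report$median_diff, x$report$median_same))
  invisible(x)
}
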