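# Shared fixtures, built once per test run. Everything is generated in code
# under fixed seeds; the "small" pipeline (5 classes, 40 samples each, a
# 3-block network) is large enough for the end-to-end mechanism to work and
# small enough to train in seconds.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, expr, envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

small_config <- function(...) {
  generator_config(n_classes = 5, samples_per_class = 40, noise_sd = 0.1, ...)
}

small_dataset <- function() fixture("small_ds", {
  build_offline_dataset(small_config(), seed = 3L)
})

small_pp <- function() fixture("small_pp", preprocess_dataset(small_dataset()))

small_arch <- function() architecture_spec(list(8, 16, c(32, 32)))

tiny_arch <- function() architecture_spec(list(8, 16))

small_classifier <- function() fixture("small_clf", {
  train_classifier(small_pp(), small_arch(),
                   train_config(batch_size = 32, lr = 1e-3, epochs = 10,
                                seed = 7))
})

small_verifier <- function() fixture("small_ver", {
  train_verifier(small_pp(),
                 cfg = verifier_config(batch_size = 64, lr = 1e-3,
                                       epochs = 6, margin = 10, seed = 5),
                 classifier_model = small_classifier(), arch = small_arch())
})

# Unclamped threshold rule: the published [14, 18] clamp belongs to the
# original sensor scale, not the synthetic one.
synthetic_threshold_config <- function() {
  threshold_config(clamp_low = 0, clamp_high = Inf)
}

small_refs <- function() fixture("small_refs", {
  build_reference_set(small_verifier(), small_pp(),
                      synthetic_threshold_config())
})

# Continuous stream with interference, from the same class templates.
small_stream <- function() fixture("small_stream", {
  compose_stream(small_dataset()$templates, schedule = rep(1:4, each = 3),
                 small_config(interference_rate = 4), seed = 21)
})
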