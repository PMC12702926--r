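# The bioactivity classifier: a two-hidden-layer multilayer perceptron on
# ECFP4 bit vectors, trained with Adam on binary cross-entropy. The
# architecture (2048 -> 512 -> 128 -> 1, ReLU, 20% dropout between the
# hidden layers, sigmoid output) is deliberately small enough to train on a
# single CPU in seconds at the scale of curated kinase activity sets.
# The training loop is compiled (src/mlp_core.cpp) but draws all its
# randomness — weight initialization, minibatch shuffling, dropout masks —
# from R's RNG, so a single seed makes training bit-reproducible.
# Inference is plain R matrix algebra.

#' MLP architecture and training hyperparameters
#'
#' @param hidden sizes of the two hidden layers (default `c(512, 128)`).
#' @param dropout dropout rate applied between the hidden layers during
#'   training (default 0.2).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param epochs training epochs (default 20).
#' @param batch_size minibatch size (default 32; conventional default, the
#'   method description leaves it open).
#' @param seed integer seed driving initialization, shuffling and dropout.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(hidden = c(512L, 128L), dropout = 0.2,
                       learning_rate = 0.001, epochs = 20L, batch_size = 32L,
                       seed = 42L) {
  stopifnot(length(hidden) >= 1, all(hidden > 0), dropout >= 0, dropout < 1,
            learning_rate > 0, epochs > 0, batch_size > 0)
  structure(list(hidden = as.integer(hidden), activation = "relu",
                 dropout = dropout, output = "sigmoid",
                 optimizer = "adam", learning_rate = learning_rate,
                 loss = "binary_cross_entropy",
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Stratified train/test split
#'
#' Splits record indices so that each class keeps the global class
#' proportion within one example in both subsets. Reproducible for a fixed
#' seed; train and test are disjoint and exhaustive.
#'
#' @param labels binary 0/1 vector.
#' @param test_fraction fraction held out (default 0.2).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_stratified <- function(labels, test_fraction = 0.2, seed = 42L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("input error: both classes must be present", call. = FALSE)
  }
  stopifnot(test_fraction > 0, test_fraction < 1)
  test_idx <- integer(0)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    n_test <- round(length(idx) * test_fraction)
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  test_idx <- sort(test_idx)
  list(train = setdiff(seq_along(labels), test_idx), test = test_idx)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

relu <- function(x) x * (x > 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Train the MLP bioactivity classifier
#'
#' Minimizes binary cross-entropy with Adam over minibatches. Dropout
#' (inverted scaling) is applied between the hidden layers during training
#' only. The training fingerprints are retained inside the classifier: they
#' define the applicability domain used at screening time.
#'
#' @param X 0/1 fingerprint matrix (rows = training compounds).
#' @param y binary 0/1 label vector.
#' @param spec a [model_spec()].
#' @return object of class `trained_classifier`: layer weights, the spec,
#'   the per-epoch mean loss trace and `training_fingerprints`.
#' @export
train_mlp <- function(X, y, spec = model_spec()) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (length(unique(y)) < 2) {
    stop("input error: degenerate labels (single class)", call. = FALSE)
  }
  stopifnot(nrow(X) == length(y))
  if (length(spec$hidden) != 2) {
    stop("the training core expects exactly two hidden layers", call. = FALSE)
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  fit <- .mlp_train_core(X, y, spec$hidden[1], spec$hidden[2], spec$dropout,
                         spec$learning_rate, spec$epochs, spec$batch_size)
  layers <- list(list(W = fit$W1, b = as.numeric(fit$b1)),
                 list(W = fit$W2, b = as.numeric(fit$b2)),
                 list(W = fit$W3, b = as.numeric(fit$b3)))
  structure(list(spec = spec, layers = layers,
                 loss_trace = as.numeric(fit$loss_trace),
                 n_train = nrow(X), n_bits = ncol(X),
                 training_fingerprints = X),
            class = "trained_classifier")
}

#' Predict activity probabilities
#'
#' Deterministic forward pass (no dropout at inference). Compounds are
#' called active at probability >= 0.5 downstream; only the probabilities
#' are returned here.
#'
#' @param classifier a [train_mlp()] result.
#' @param X fingerprint matrix with the same bit length as at training.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict_proba <- function(classifier, X) {
  stopifnot(inherits(classifier, "trained_classifier"))
  X <- as.matrix(X)
  if (ncol(X) != classifier$n_bits) {
    stop("input error: fingerprint length mismatch", call. = FALSE)
  }
  l <- classifier$layers
  a1 <- relu(sweep(X %*% l[[1]]$W, 2, l[[1]]$b, "+"))
  a2 <- relu(sweep(a1 %*% l[[2]]$W, 2, l[[2]]$b, "+"))
  as.numeric(sigmoid(sweep(a2 %*% l[[3]]$W, 2, l[[3]]$b, "+")))
}

#' Save / load a trained classifier
#'
#' The model directory holds `spec.json` (architecture and hyperparameters,
#' human-readable) plus the weight arrays and training fingerprints as R
#' serialized arrays — plain data, no code objects.
#'
#' @param classifier a `trained_classifier`.
#' @param dir model directory (created if needed).
#' @return `dir`, invisibly (`save_classifier`); the classifier
#'   (`load_classifier`).
#' @export
save_classifier <- function(classifier, dir) {
  stopifnot(inherits(classifier, "trained_classifier"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(classifier$spec),
                       file.path(dir, "spec.json"), auto_unbox = TRUE)
  saveRDS(classifier$layers, file.path(dir, "weights.rds"))
  saveRDS(classifier$training_fingerprints,
          file.path(dir, "training_fingerprints.rds"))
  saveRDS(list(loss_trace = classifier$loss_trace,
               n_train = classifier$n_train, n_bits = classifier$n_bits),
          file.path(dir, "meta.rds"))
  invisible(dir)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(dir) {
  spec_l <- jsonlite::read_json(file.path(dir, "spec.json"),
                                simplifyVector = TRUE)
  spec <- model_spec(hidden = spec_l$hidden, dropout = spec_l$dropout,
                     learning_rate = spec_l$learning_rate,
                     epochs = spec_l$epochs, batch_size = spec_l$batch_size,
                     seed = spec_l$seed)
  meta <- readRDS(file.path(dir, "meta.rds"))
  structure(list(spec = spec, layers = readRDS(file.path(dir, "weights.rds")),
                 loss_trace = meta$loss_trace, n_train = meta$n_train,
                 n_bits = meta$n_bits,
                 training_fingerprints =
                   readRDS(file.path(dir, "training_fingerprints.rds"))),
            class = "trained_classifier")
}
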