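#' Train a one-vs-all perceptron on component feature vectors
#'
#' One weight vector (plus bias) is learned per network label. Training
#' uses the classic stochastic update: examples are visited one at a time
#' in a per-epoch shuffled order, each label's unit has target +1 for its
#' own class and -1 otherwise, the unit's output is the sign of its
#' activation, and on error the weights move by
#' `lr * (target - output) * x`. Weights start at zero and the shuffle is
#' driven by the seed, so training is fully reproducible.
#'
#' @param features numeric matrix (rows = examples, columns = features) or
#'   list of [feature_vector()] objects sharing `R` and encoding.
#' @param labels character vector of true network labels, one per row.
#' @param learning_rate positive step size (default 0.1).
#' @param epochs number of passes over the training set (default 50).
#' @param seed RNG seed for the per-epoch shuffling.
#' @param label_set label set defining the units and the tie-break order.
#' @return An object of class `perceptron_model` with `weights` (matrix
#'   `n_labels x (n_features + 1)`, bias in the last column), `R`,
#'   `encoding`, and the hyperparameters.
#' @export
perceptron_train <- function(features, labels, learning_rate = 0.1,
                             epochs = 50L, seed = 1L,
                             label_set = network_labels()) {
  fm <- as_feature_matrix(features)
  if (nrow(fm$mat) == 0L) stop("empty training set", call. = FALSE)
  if (length(labels) != nrow(fm$mat))
    stop("labels length ", length(labels), " != number of examples ",
         nrow(fm$mat), call. = FALSE)
  check_labels(labels, label_set)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)

  x <- unname(cbind(fm$mat, 1))   # bias input in the last slot
  n <- nrow(x)
  L <- length(label_set)
  w <- matrix(0, nrow = L, ncol = ncol(x),
              dimnames = list(label_set, NULL))
  targets <- matrix(-1, nrow = n, ncol = L)
  targets[cbind(seq_len(n), match(labels, label_set))] <- 1

  with_seed(seed, {
    for (e in seq_len(epochs)) {
      for (i in sample.int(n)) {
        act <- drop(w %*% x[i, ])
        out <- ifelse(act >= 0, 1, -1)
        err <- targets[i, ] - out
        upd <- err != 0
        if (any(upd))
          w[upd, ] <- w[upd, , drop = FALSE] +
            learning_rate * err[upd] %o% x[i, ]
      }
    }
  })
  structure(list(weights = w, R = fm$R, encoding = fm$encoding,
                 label_set = label_set,
                 hyperparams = list(learning_rate = learning_rate,
                                    epochs = epochs, seed = seed)),
            class = "perceptron_model")
}

#' @export
print.perceptron_model <- function(x, ...) {
  cat("<perceptron_model> ", nrow(x$weights), " units x ",
      ncol(x$weights) - 1L, " features (+bias), lr=",
      x$hyperparams$learning_rate, ", epochs=", x$hyperparams$epochs,
      "\n", sep = "")
  invisible(x)
}

#' Classify a feature vector with a trained perceptron
#'
#' The predicted network is the label whose unit gives the maximal dot
#' product with the input (bias included). Ties break by the fixed label
#' order of the model.
#'
#' @param model a [perceptron_model][perceptron_train()].
#' @param fv a [feature_vector()] or bare numeric vector of matching
#'   length.
#' @return A list with `label`, `scores` (named per-label activations),
#'   and `confidence` (softmax of the scores, a heuristic indicator).
#' @export
perceptron_classify <- function(model, fv) {
  stopifnot(inherits(model, "perceptron_model"))
  v <- if (inherits(fv, "feature_vector")) fv$values else as.numeric(fv)
  if (length(v) != ncol(model$weights) - 1L)
    stop("feature length ", length(v), " does not match model (",
         ncol(model$weights) - 1L, ")", call. = FALSE)
  scores <- drop(model$weights %*% c(v, 1))
  best <- which(scores == max(scores))[1L]  # first index = label order
  z <- scores - max(scores)
  list(label = model$label_set[best], scores = scores,
       confidence = exp(z) / sum(exp(z)))
}

# Accept a feature matrix, a list of feature_vectors, or a bare matrix,
# returning list(mat, R, encoding) with consistency checks.
as_feature_matrix <- function(features) {
  if (is.matrix(features))
    return(list(mat = features, R = round(ncol(features)^(1 / 3)),
                encoding = "raw_mean"))
  if (is.list(features) &&
      all(vapply(features, inherits, TRUE, "feature_vector"))) {
    Rs <- unique(vapply(features, function(f) f$R, 1L))
    enc <- unique(vapply(features, function(f) f$encoding, ""))
    if (length(Rs) > 1L || length(enc) > 1L)
      stop("feature vectors disagree on R or encoding", call. = FALSE)
    lens <- unique(lengths(lapply(features, function(f) f$values)))
    if (length(lens) > 1L)
      stop("inconsistent feature vector lengths: ",
           paste(lens, collapse = ", "), call. = FALSE)
    return(list(mat = do.call(rbind, lapply(features, `[[`, "values")),
                R = Rs, encoding = enc))
  }
  stop("features must be a matrix or a list of feature_vector objects",
       call. = FALSE)
}
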