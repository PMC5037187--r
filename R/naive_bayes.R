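#' Train a naive Bayes classifier on binned feature vectors
#'
#' Estimates class priors and per-feature conditional probability tables
#' by frequency counting over the discretized (bin codes 1..n_bins)
#' training features, with optional Laplace smoothing:
#' `prior(l) = (n_l + alpha) / (N + alpha * L)` and
#' `cpt(l, f, v) = (n_{l,f,v} + alpha) / (n_l + alpha * n_bins)`.
#' `alpha = 0` is the pure frequency-count rule; the default `alpha = 1`
#' avoids zero probabilities that would annihilate a whole posterior on a
#' single unseen bin.
#'
#' @param features numeric matrix of bin codes (rows = examples) or list
#'   of binned [feature_vector()] objects.
#' @param labels character vector of true network labels.
#' @param alpha Laplace pseudo-count (>= 0, default 1).
#' @param n_bins number of bins (default 11).
#' @param label_set label set (defines classes and tie-break order).
#' @return An object of class `naive_bayes_model` with `priors` (named
#'   vector), `cpt` (array `n_labels x n_features x n_bins`), `alpha`,
#'   `R`, `n_bins`.
#' @export
nb_train <- function(features, labels, alpha = 1, n_bins = 11L,
                     label_set = network_labels()) {
  fm <- as_feature_matrix(features)
  mat <- fm$mat
  if (nrow(mat) == 0L) stop("empty training set", call. = FALSE)
  if (is.list(features) && length(features) &&
      inherits(features[[1]], "feature_vector") &&
      fm$encoding != "binned")
    stop("naive Bayes requires binned encoding, got ", fm$encoding,
         call. = FALSE)
  if (any(mat != round(mat)) || any(mat < 1 | mat > n_bins))
    stop("features must be integer bin codes in 1..", n_bins,
         call. = FALSE)
  if (length(labels) != nrow(mat))
    stop("labels length mismatch", call. = FALSE)
  check_labels(labels, label_set)
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)

  L <- length(label_set)
  nf <- ncol(mat)
  n <- nrow(mat)
  counts <- table(factor(labels, levels = label_set))
  priors <- (as.numeric(counts) + alpha) / (n + alpha * L)
  names(priors) <- label_set

  cpt <- array(0, dim = c(L, nf, n_bins),
               dimnames = list(label_set, NULL, NULL))
  for (li in seq_len(L)) {
    rows <- which(labels == label_set[li])
    nl <- length(rows)
    if (nl > 0) {
      sub <- mat[rows, , drop = FALSE]
      for (v in seq_len(n_bins))
        cpt[li, , v] <- (colSums(sub == v) + alpha) / (nl + alpha * n_bins)
    } else {
      cpt[li, , ] <- if (alpha > 0) 1 / n_bins else NA_real_
    }
  }
  structure(list(priors = priors, cpt = cpt, alpha = alpha, R = fm$R,
                 n_bins = as.integer(n_bins), label_set = label_set),
            class = "naive_bayes_model")
}

#' @export
print.naive_bayes_model <- function(x, ...) {
  cat("<naive_bayes_model> ", length(x$label_set), " classes x ",
      dim(x$cpt)[2], " features x ", x$n_bins, " bins, alpha=", x$alpha,
      "\n", sep = "")
  invisible(x)
}

#' Classify a binned feature vector with a naive Bayes model
#'
#' Applies Bayes' rule under the conditional-independence assumption:
#' `score(l) = log prior(l) + sum_f log cpt(l, f, x_f)`, in log space for
#' stability. The predicted network is the argmax, ties broken by the
#' fixed label order. The normalized posteriors accompany the label as a
#' confidence indicator: several similar large posteriors flag a map that
#' spans learned networks.
#'
#' @param model a [naive_bayes_model][nb_train()].
#' @param fv a binned [feature_vector()] or bare integer vector of bin
#'   codes.
#' @return A list with `label`, `log_posterior` (unnormalized per-label
#'   scores), and `posterior` (normalized across labels).
#' @export
nb_classify <- function(model, fv) {
  stopifnot(inherits(model, "naive_bayes_model"))
  v <- if (inherits(fv, "feature_vector")) fv$values else as.numeric(fv)
  nf <- dim(model$cpt)[2]
  if (length(v) != nf)
    stop("feature length ", length(v), " does not match model (", nf, ")",
         call. = FALSE)
  if (any(v != round(v)) || any(v < 1 | v > model$n_bins))
    stop("bin codes must be integers in 1..", model$n_bins, call. = FALSE)
  L <- length(model$label_set)
  scores <- vapply(seq_len(L), function(li)
    log(model$priors[li]) +
      sum(log(model$cpt[cbind(li, seq_len(nf), v)])),
    0)
  names(scores) <- model$label_set
  best <- which(scores == max(scores))[1L]
  z <- scores - max(scores)
  post <- exp(z) / sum(exp(z))
  list(label = model$label_set[best], log_posterior = scores,
       posterior = post)
}

#' Back-project learned model parameters onto the brain grid
#'
#' Renders, per network, what a trained model looks for in voxel space:
#' for a perceptron each cell's learned weight is painted uniformly over
#' that cell's voxels; for naive Bayes each cell shows the most likely
#' bin code (argmax of the conditional probabilities), shifted to be
#' centered at zero so the map reads like a signed weight image.
#'
#' @param model a [perceptron_model][perceptron_train()] or
#'   [naive_bayes_model][nb_train()].
#' @param origin_shape the analysis grid shape to paint onto.
#' @param voxel_size_mm voxel size for the output volumes.
#' @return Named list mapping each network label to a [brain_volume()].
#' @export
backproject_weights <- function(model, origin_shape,
                                voxel_size_mm = c(3, 3, 3)) {
  origin_shape <- as.integer(origin_shape)
  stopifnot(length(origin_shape) == 3L)
  if (inherits(model, "perceptron_model")) {
    R <- model$R
    cellvals <- model$weights[, -ncol(model$weights), drop = FALSE]
  } else if (inherits(model, "naive_bayes_model")) {
    R <- model$R
    nf <- dim(model$cpt)[2]
    center <- (model$n_bins + 1) / 2
    cellvals <- t(vapply(seq_along(model$label_set), function(li)
      apply(model$cpt[li, , , drop = FALSE], 2, which.max) - center,
      numeric(nf)))
    rownames(cellvals) <- model$label_set
  } else {
    stop("model must be a perceptron_model or naive_bayes_model",
         call. = FALSE)
  }
  if (ncol(cellvals) != R^3)
    stop("model feature count ", ncol(cellvals), " != R^3 = ", R^3,
         call. = FALSE)
  idx <- cell_index(origin_shape, R)
  out <- lapply(seq_len(nrow(cellvals)), function(li) {
    vals <- array(cellvals[li, ][idx], dim = origin_shape)
    brain_volume(vals, voxel_size_mm = voxel_size_mm,
                 mask = array(TRUE, origin_shape),
                 space_tag = paste0("backprojection_",
                                    rownames(cellvals)[li]))
  })
  names(out) <- rownames(cellvals)
  out
}
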