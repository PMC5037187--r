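#' Serialize a classifier model to a JSON document
#'
#' Weights / probability tables are stored as nested arrays with the
#' configuration echoed, so a saved model reproduces its predictions
#' bit-for-bit after [read_model()].
#'
#' @param model a `perceptron_model` or `naive_bayes_model`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "perceptron_model")) {
    doc <- list(kind = "perceptron",
                label_set = model$label_set,
                R = model$R, encoding = model$encoding,
                hyperparams = model$hyperparams,
                weights = unclass(as.data.frame(t(model$weights))))
  } else if (inherits(model, "naive_bayes_model")) {
    L <- length(model$label_set)
    cpt <- lapply(seq_len(L), function(li)
      t(matrix(model$cpt[li, , ], ncol = model$n_bins)))
    names(cpt) <- model$label_set
    doc <- list(kind = "naive_bayes",
                label_set = model$label_set,
                R = model$R, alpha = model$alpha, n_bins = model$n_bins,
                priors = as.list(model$priors),
                cpt = cpt)
  } else stop("unsupported model class", call. = FALSE)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a classifier model from JSON
#' @param path JSON file written by [write_model()].
#' @return The reconstructed model object.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (doc$kind == "perceptron") {
    w <- t(as.matrix(as.data.frame(doc$weights)))
    rownames(w) <- doc$label_set
    structure(list(weights = w, R = doc$R, encoding = doc$encoding,
                   label_set = doc$label_set,
                   hyperparams = doc$hyperparams),
              class = "perceptron_model")
  } else if (doc$kind == "naive_bayes") {
    L <- length(doc$label_set)
    nf <- ncol(doc$cpt[[1]])
    cpt <- array(0, dim = c(L, nf, doc$n_bins),
                 dimnames = list(doc$label_set, NULL, NULL))
    for (li in seq_len(L)) cpt[li, , ] <- t(doc$cpt[[li]])
    priors <- unlist(doc$priors)[doc$label_set]
    structure(list(priors = priors, cpt = cpt, alpha = doc$alpha,
                   R = doc$R, n_bins = as.integer(doc$n_bins),
                   label_set = doc$label_set),
              class = "naive_bayes_model")
  } else stop("unknown model kind: ", doc$kind, call. = FALSE)
}
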