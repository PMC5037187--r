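#' Baseline decision-tree / SVM classifiers (delegation hooks)
#'
#' Thin wrappers exposing third-party decision-tree (\pkg{rpart}) and SVM
#' (\pkg{e1071}) implementations behind the same train/classify surface
#' as the bespoke classifiers, for baseline comparison only. They are
#' excluded from the package's core guarantees.
#'
#' @param features numeric feature matrix (rows = examples).
#' @param labels character vector of network labels.
#' @param kind `"tree"` or `"svm"`.
#' @param label_set allowed label set.
#' @param ... passed to the backend fit function.
#' @return An object of class `delegate_model`.
#' @export
delegate_train <- function(features, labels, kind = c("tree", "svm"),
                           label_set = network_labels(), ...) {
  kind <- match.arg(kind)
  fm <- as_feature_matrix(features)
  check_labels(labels, label_set)
  df <- as.data.frame(fm$mat)
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$.label <- factor(labels, levels = label_set)
  fit <- if (kind == "tree") {
    if (!requireNamespace("rpart", quietly = TRUE))
      stop("decision-tree backend missing (package 'rpart')",
           call. = FALSE)
    rpart::rpart(.label ~ ., data = df, method = "class", ...)
  } else {
    if (!requireNamespace("e1071", quietly = TRUE))
      stop("SVM backend missing (package 'e1071')", call. = FALSE)
    e1071::svm(.label ~ ., data = df, ...)
  }
  structure(list(kind = kind, fit = fit, R = fm$R,
                 label_set = label_set, n_features = ncol(fm$mat)),
            class = "delegate_model")
}

#' @rdname delegate_train
#' @param model a `delegate_model`.
#' @param fv feature vector or numeric vector.
#' @export
delegate_classify <- function(model, fv) {
  stopifnot(inherits(model, "delegate_model"))
  v <- if (inherits(fv, "feature_vector")) fv$values else as.numeric(fv)
  if (length(v) != model$n_features)
    stop("feature length mismatch", call. = FALSE)
  df <- as.data.frame(as.list(v))
  names(df) <- paste0("f", seq_along(v))
  pred <- if (model$kind == "tree")
    stats::predict(model$fit, df, type = "class")
  else stats::predict(model$fit, df)
  list(label = as.character(pred), scores = NULL)
}
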