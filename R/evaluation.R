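#' Split a dataset into tuning and held-out subject sets
#'
#' Subject-level random partition used to pick the resize parameter R
#' before the final evaluation: half the subjects, rounding up (15 of 30,
#' 12 of 23), selected by a seeded RNG.
#'
#' @param dataset an [rsn_dataset()].
#' @param tuning_count number of tuning subjects; default
#'   `ceiling(n_subjects / 2)`.
#' @param seed RNG seed for the subject draw.
#' @return A list with `tuning` and `heldout`, both [rsn_dataset()]s, and
#'   `tuning_subjects`.
#' @export
split_tuning <- function(dataset, tuning_count = NULL, seed = 1L) {
  ns <- n_subjects(dataset)
  if (is.null(tuning_count)) tuning_count <- ceiling(ns / 2)
  tuning_count <- as.integer(tuning_count)
  if (tuning_count < 1L || tuning_count >= ns)
    stop("tuning_count must be in [1, n_subjects): got ", tuning_count,
         " of ", ns, call. = FALSE)
  tune_ids <- with_seed(seed, sample(dataset$subjects, tuning_count))
  list(tuning = subset_subjects(dataset, tune_ids),
       heldout = subset_subjects(dataset,
                                 setdiff(dataset$subjects, tune_ids)),
       tuning_subjects = tune_ids)
}

#' Derived metrics from a confusion matrix
#'
#' Rows are true labels, columns predicted. Overall accuracy is
#' trace/total; per-class accuracy is diagonal over row sum (identical to
#' sensitivity); specificity, PPV and NPV are computed one-vs-rest.
#' Undefined ratios (zero denominators) are reported as `NA`, not 0.
#'
#' @param confusion square nonnegative integer matrix with identical row
#'   and column label order.
#' @param chance chance level for the binomial test (default 1/n_labels).
#' @return An object of class `evaluation_report` with the confusion
#'   matrix, `overall_accuracy`, `per_class_accuracy`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `n_components`, `n_correct`, `p_value`.
#' @export
compute_metrics <- function(confusion, chance = NULL) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stop("confusion matrix must be square, got ", nrow(confusion), "x",
         ncol(confusion), call. = FALSE)
  if (any(confusion < 0)) stop("negative confusion counts", call. = FALSE)
  labels <- rownames(confusion) %||% paste0("class_", seq_len(nrow(confusion)))
  total <- sum(confusion)
  correct <- sum(diag(confusion))
  safe_div <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  tp <- diag(confusion)
  fn <- rowSums(confusion) - tp
  fp <- colSums(confusion) - tp
  tn <- total - tp - fn - fp
  if (is.null(chance)) chance <- 1 / nrow(confusion)
  rep <- list(
    confusion = confusion,
    overall_accuracy = safe_div(correct, total),
    per_class_accuracy = stats::setNames(safe_div(tp, tp + fn), labels),
    sensitivity = stats::setNames(safe_div(tp, tp + fn), labels),
    specificity = stats::setNames(safe_div(tn, tn + fp), labels),
    ppv = stats::setNames(safe_div(tp, tp + fp), labels),
    npv = stats::setNames(safe_div(tn, tn + fn), labels),
    n_components = total,
    n_correct = correct,
    p_value = if (total > 0) binomial_p(correct, total, chance)
              else NA_real_,
    viewer_id = NA_character_)
  class(rep) <- "evaluation_report"
  rep
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  cat("<evaluation_report>",
      if (!is.na(x$viewer_id)) paste0(" viewer=", x$viewer_id), "\n",
      sep = "")
  cat("  overall accuracy: ",
      round(100 * x$overall_accuracy, 1), "% (", x$n_correct, "/",
      x$n_components, ", p=", signif(x$p_value, 3), ")\n", sep = "")
  print(round(rbind(accuracy = x$per_class_accuracy,
                    sensitivity = x$sensitivity,
                    specificity = x$specificity,
                    ppv = x$ppv, npv = x$npv), digits))
  invisible(x)
}

#' Upper-tail binomial test probability against chance labeling
#'
#' Probability of observing at least `correct` successes in `total`
#' independent guesses at success probability `chance` — the p-value for
#' classification accuracy against random label guessing (chance 1/5 for
#' five networks). Computed as an exact tail sum of binomial point
#' masses accumulated in log space; no normal approximation.
#'
#' @param correct number of correctly classified components.
#' @param total number of components.
#' @param chance per-component success probability under guessing.
#' @return The p-value `P(X >= correct)`.
#' @export
binomial_p <- function(correct, total, chance = 0.2) {
  if (total < 0 || correct < 0 || correct > total)
    stop("need 0 <= correct <= total", call. = FALSE)
  if (chance <= 0 || chance >= 1)
    stop("chance must be in (0, 1)", call. = FALSE)
  if (correct == 0) return(1)
  k <- correct:total
  logp <- lchoose(total, k) + k * log(chance) +
    (total - k) * log1p(-chance)
  m <- max(logp)
  exp(m + log(sum(exp(logp - m))))
}

# Fold plan for leave-one-subject-out CV: one fold per subject, training
# on every other subject's components. Exposed for structural leakage
# checks in tests.
loocv_folds <- function(dataset) {
  lapply(dataset$subjects, function(s)
    list(test_subject = s,
         train_subjects = setdiff(dataset$subjects, s)))
}

#' Leave-one-subject-out cross-validation of a classifier
#'
#' For each subject, a model is trained on all components of all other
#' subjects and then predicts every component of the held-out subject;
#' predictions accumulate into one confusion matrix. This mirrors the
#' clinical scenario of predicting a new patient from all known patients.
#' The correlation classifier uses an external template set and no
#' training, so its predictions are computed directly per component.
#'
#' @param dataset an [rsn_dataset()] whose components carry labels from
#'   `viewer_id`.
#' @param classifier one of `"correlation"`, `"perceptron"`,
#'   `"naive_bayes"`, `"tree"`, `"svm"`.
#' @param R resize parameter for feature-based classifiers (ignored, with
#'   a message, for correlation).
#' @param viewer_id which viewer's labels define the ground truth.
#' @param templates a [template_set()], required for `"correlation"`.
#' @param alpha naive Bayes smoothing.
#' @param learning_rate,epochs,seed perceptron hyperparameters.
#' @param perceptron_encoding feature encoding fed to the perceptron
#'   (`"raw_mean"` default, `"zscore"` selectable).
#' @param chance chance level for the binomial test.
#' @param verbose print one line per fold.
#' @return An [evaluation_report][compute_metrics()] with additional
#'   elements `predictions` (data.frame of subject, component, truth,
#'   predicted) and `folds`.
#' @export
loocv_evaluate <- function(dataset,
                           classifier = c("correlation", "perceptron",
                                          "naive_bayes", "tree", "svm"),
                           R = 10L, viewer_id = "viewer1",
                           templates = NULL, alpha = 1,
                           learning_rate = 0.1, epochs = 50L, seed = 1L,
                           perceptron_encoding = "raw_mean",
                           chance = NULL, verbose = FALSE) {
  classifier <- match.arg(classifier)
  labels <- viewer_labels(dataset, viewer_id)
  subj <- vapply(dataset$components, function(cm) cm$subject_id, "")
  comp <- vapply(dataset$components, function(cm) cm$component_index, 1L)

  labeled <- !is.na(labels)
  skip_subj <- setdiff(dataset$subjects, unique(subj[labeled]))
  if (length(skip_subj))
    warning("subject(s) with zero components labeled by ", viewer_id,
            " skipped: ", paste(skip_subj, collapse = ", "),
            call. = FALSE)
  if (!any(labeled))
    stop("no components labeled by viewer ", viewer_id, call. = FALSE)

  if (classifier == "correlation") {
    if (is.null(templates))
      stop("correlation classifier requires a template set", call. = FALSE)
    message("correlation classifier runs at full resolution; R ignored")
    pred <- vapply(dataset$components,
                   function(cm) correlation_classify(cm, templates)$label,
                   "")
  } else {
    enc <- if (classifier == "naive_bayes") "binned"
           else if (classifier == "perceptron") perceptron_encoding
           else "raw_mean"
    fmat <- feature_matrix(dataset, R, encoding = enc)
    pred <- rep(NA_character_, length(labels))
    for (fold in loocv_folds(dataset)) {
      tr <- labeled & subj %in% fold$train_subjects
      te <- labeled & subj == fold$test_subject
      if (!any(te)) next
      if (!any(tr))
        stop("fold for subject ", fold$test_subject,
             " has an empty training set", call. = FALSE)
      xtr <- fmat[tr, , drop = FALSE]
      ytr <- labels[tr]
      pred[te] <- switch(classifier,
        naive_bayes = {
          m <- nb_train(xtr, ytr, alpha = alpha,
                        label_set = dataset$label_set)
          vapply(which(te), function(i)
            nb_classify(m, fmat[i, ])$label, "")
        },
        perceptron = {
          m <- perceptron_train(xtr, ytr, learning_rate = learning_rate,
                                epochs = epochs, seed = seed,
                                label_set = dataset$label_set)
          vapply(which(te), function(i)
            perceptron_classify(m, fmat[i, ])$label, "")
        },
        {
          m <- delegate_train(xtr, ytr, kind = classifier,
                              label_set = dataset$label_set)
          vapply(which(te), function(i)
            delegate_classify(m, fmat[i, ])$label, "")
        })
      if (verbose) {
        wrong <- which(te & pred != labels)
        message("fold ", fold$test_subject, ": ",
                sum(te & pred == labels, na.rm = TRUE), "/", sum(te),
                " correct",
                if (length(wrong)) paste0(" (missed IC ",
                  paste(comp[wrong], collapse = ","), ")"))
      }
    }
  }

  use <- labeled & !is.na(pred)
  confusion <- table(
    factor(labels[use], levels = dataset$label_set),
    factor(pred[use], levels = dataset$label_set))
  confusion <- matrix(as.integer(confusion),
                      nrow = length(dataset$label_set),
                      dimnames = list(dataset$label_set,
                                      dataset$label_set))
  rep <- compute_metrics(confusion, chance = chance)
  rep$viewer_id <- viewer_id
  rep$classifier <- classifier
  rep$R <- if (classifier == "correlation") NA_integer_ else as.integer(R)
  rep$predictions <- data.frame(subject = subj[use],
                                component = comp[use],
                                truth = labels[use],
                                predicted = pred[use],
                                stringsAsFactors = FALSE)
  rep$folds <- loocv_folds(dataset)
  rep
}

#' Select the resize parameter R on a tuning set
#'
#' Runs [loocv_evaluate()] on the tuning dataset for each candidate R and
#' returns the accuracy-maximizing value, ties broken toward the smallest
#' R, plus the full tuning curve.
#'
#' @param tuning tuning [rsn_dataset()].
#' @param classifier a feature-based classifier kind (not correlation).
#' @param R_grid integer candidates (default 5..20, i.e. 125 to 8000
#'   features).
#' @param viewer_id ground-truth viewer.
#' @param verbose print one line per grid point.
#' @param ... further arguments to [loocv_evaluate()].
#' @return A list with `best_R` and `curve` (data.frame of `R`,
#'   `accuracy`).
#' @export
tune_R <- function(tuning, classifier = "naive_bayes", R_grid = 5:20,
                   viewer_id = "viewer1", verbose = FALSE, ...) {
  if (length(R_grid) == 0L) stop("empty R grid", call. = FALSE)
  if (classifier == "correlation")
    stop("the correlation classifier has no resize parameter",
         call. = FALSE)
  acc <- vapply(R_grid, function(R) {
    a <- loocv_evaluate(tuning, classifier = classifier, R = R,
                        viewer_id = viewer_id, ...)$overall_accuracy
    if (verbose) message("R=", R, ": tuning accuracy ", round(a, 4))
    a
  }, 0)
  list(best_R = pick_best_R(R_grid, acc),
       curve = data.frame(R = as.integer(R_grid), accuracy = acc))
}

#' Argmax R with smallest-R tie-break
#' @param R_grid integer candidates.
#' @param accuracies matching accuracy values.
#' @return The smallest R attaining the maximal accuracy.
#' @export
pick_best_R <- function(R_grid, accuracies) {
  stopifnot(length(R_grid) == length(accuracies), length(R_grid) > 0)
  ord <- order(R_grid)
  R_grid <- R_grid[ord]; accuracies <- accuracies[ord]
  R_grid[which.max(accuracies)]  # which.max takes the first (smallest R)
}

#' Average evaluation reports over expert viewers
#'
#' The final headline accuracy averages the per-viewer results: overall
#' accuracy is the arithmetic mean of member overall accuracies, and
#' per-class metrics are averaged where defined in all members. The
#' member confusion matrices are carried along separately, never summed,
#' because the viewers may have labeled different component sets.
#'
#' @param reports list of [evaluation_report][compute_metrics()]s.
#' @return An `evaluation_report` with `viewer_id = "averaged"`.
#' @export
average_over_viewers <- function(reports) {
  if (length(reports) == 0L) stop("no reports to average", call. = FALSE)
  stopifnot(all(vapply(reports, inherits, TRUE, "evaluation_report")))
  avg_named <- function(field) {
    vals <- do.call(rbind, lapply(reports, `[[`, field))
    out <- colMeans(vals)
    out[apply(is.na(vals), 2, any)] <- NA_real_
    out
  }
  rep <- list(
    confusion = lapply(reports, `[[`, "confusion"),
    overall_accuracy = mean(vapply(reports, `[[`, 0, "overall_accuracy")),
    per_class_accuracy = avg_named("per_class_accuracy"),
    sensitivity = avg_named("sensitivity"),
    specificity = avg_named("specificity"),
    ppv = avg_named("ppv"),
    npv = avg_named("npv"),
    n_components = sum(vapply(reports, `[[`, 0, "n_components")),
    n_correct = sum(vapply(reports, `[[`, 0, "n_correct")),
    p_value = NA_real_,
    viewer_id = "averaged",
    members = reports)
  class(rep) <- "evaluation_report"
  rep
}

#' Serialize an evaluation report as JSON and TSV
#'
#' @param report an [evaluation_report][compute_metrics()].
#' @param stem output path stem; writes `<stem>.json` and `<stem>.tsv`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_evaluation_report <- function(report, stem) {
  conf <- report$confusion
  doc <- list(viewer_id = report$viewer_id,
              classifier = report$classifier %||% NA,
              R = report$R %||% NA,
              overall_accuracy = report$overall_accuracy,
              n_components = report$n_components,
              n_correct = report$n_correct,
              p_value = report$p_value,
              per_class_accuracy = as.list(report$per_class_accuracy),
              sensitivity = as.list(report$sensitivity),
              specificity = as.list(report$specificity),
              ppv = as.list(report$ppv),
              npv = as.list(report$npv),
              confusion = conf)
  json <- paste0(stem, ".json")
  jsonlite::write_json(doc, json, auto_unbox = TRUE, digits = NA,
                       na = "null")
  tsv <- paste0(stem, ".tsv")
  m <- rbind(accuracy = report$per_class_accuracy,
             sensitivity = report$sensitivity,
             specificity = report$specificity,
             ppv = report$ppv, npv = report$npv)
  utils::write.table(data.frame(metric = rownames(m), m,
                                check.names = FALSE),
                     tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(json, tsv))
}
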