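# Write the fully resolved configuration next to a command's outputs so
# every artifact records how it was produced.
write_run_config <- function(config, out_dir, name = "run_config.json") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(config, file.path(out_dir, name),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(file.path(out_dir, name))
}

#' Simulate a synthetic dataset bundle
#'
#' Writes a NIfTI + TSV bundle of synthetic labeled IC maps (see
#' [make_dataset()]) plus the resolved generator configuration.
#'
#' @param out_dir output directory.
#' @param ... passed to [generator_config()].
#' @return The output directory, invisibly.
#' @export
cmd_simulate <- function(out_dir, ...) {
  config <- generator_config(...)
  make_dataset(config, out_dir = out_dir)
  write_run_config(c(command = "simulate", unclass(config)), out_dir)
  invisible(out_dir)
}

#' Train a classifier on a labeled bundle and serialize the model
#'
#' @param bundle_dir dataset bundle directory (NIfTI + `labels.tsv`).
#' @param out_dir output directory for `model.json`.
#' @param classifier `"perceptron"` or `"naive_bayes"` (the correlation
#'   classifier has no trained model; tree/svm baselines are not
#'   serialized).
#' @param R resize parameter.
#' @param viewer_id ground-truth viewer column.
#' @param alpha,learning_rate,epochs,seed classifier hyperparameters.
#' @return Path of the model JSON, invisibly.
#' @export
cmd_train <- function(bundle_dir, out_dir,
                      classifier = c("naive_bayes", "perceptron"),
                      R = 10L, viewer_id = "viewer1", alpha = 1,
                      learning_rate = 0.1, epochs = 50L, seed = 1L) {
  classifier <- match.arg(classifier)
  ds <- load_dataset(bundle_dir, file.path(bundle_dir, "labels.tsv"))
  labels <- viewer_labels(ds, viewer_id)
  if (all(is.na(labels)))
    stop("no components carry labels from viewer ", viewer_id,
         call. = FALSE)
  keep <- !is.na(labels)
  enc <- if (classifier == "naive_bayes") "binned" else "raw_mean"
  fmat <- feature_matrix(ds, R, encoding = enc)[keep, , drop = FALSE]
  model <- if (classifier == "naive_bayes")
    nb_train(fmat, labels[keep], alpha = alpha, label_set = ds$label_set)
  else
    perceptron_train(fmat, labels[keep], learning_rate = learning_rate,
                     epochs = epochs, seed = seed,
                     label_set = ds$label_set)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, "model.json")
  write_model(model, path)
  write_run_config(list(command = "train", classifier = classifier,
                        R = R, viewer_id = viewer_id, alpha = alpha,
                        learning_rate = learning_rate, epochs = epochs,
                        seed = seed, bundle = bundle_dir), out_dir)
  invisible(path)
}

#' Classify a bundle and write the ordered labeled report
#'
#' Labels every component of a bundle with a serialized model (or a
#' template set for the correlation classifier), writing the ordered
#' HTML report with per-component confidence plus a predictions TSV.
#'
#' @param bundle_dir dataset bundle directory.
#' @param out_dir output directory.
#' @param model_path model JSON from [cmd_train()] (omit for
#'   correlation).
#' @param templates_dir template directory for the correlation
#'   classifier.
#' @param threshold report display threshold on |t|.
#' @return Path of the HTML report, invisibly.
#' @export
cmd_classify <- function(bundle_dir, out_dir, model_path = NULL,
                         templates_dir = NULL, threshold = 0) {
  ds <- load_dataset(bundle_dir, file.path(bundle_dir, "labels.tsv"))
  if (!is.null(model_path)) {
    model <- read_model(model_path)
    enc <- if (inherits(model, "naive_bayes_model")) "binned"
           else "raw_mean"
    fmat <- feature_matrix(ds, model$R, encoding = enc)
    res <- lapply(seq_len(nrow(fmat)), function(i) {
      if (inherits(model, "naive_bayes_model")) {
        r <- nb_classify(model, fmat[i, ])
        list(label = r$label, score = max(r$posterior))
      } else {
        r <- perceptron_classify(model, fmat[i, ])
        list(label = r$label, score = max(r$confidence))
      }
    })
  } else if (!is.null(templates_dir)) {
    templates <- read_template_set(templates_dir)
    res <- lapply(ds$components, function(cm) {
      r <- correlation_classify(cm, templates)
      list(label = r$label, score = r$ranking$correlation[1])
    })
  } else {
    stop("supply model_path or templates_dir", call. = FALSE)
  }
  predictions <- data.frame(
    subject = vapply(ds$components, function(cm) cm$subject_id, ""),
    component = vapply(ds$components, function(cm) cm$component_index, 1L),
    label = vapply(res, `[[`, "", "label"),
    score = vapply(res, `[[`, 0, "score"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  html <- file.path(out_dir, "report.html")
  write_labeled_report(ds$components, predictions, html,
                       threshold = threshold)
  write_run_config(list(command = "classify", bundle = bundle_dir,
                        model = model_path, templates = templates_dir,
                        threshold = threshold), out_dir)
  invisible(html)
}

#' Tune the resize parameter on a bundle
#'
#' Splits off a tuning subject set, runs the R grid search there, and
#' writes the selected R plus the full accuracy curve as TSV.
#'
#' @param bundle_dir dataset bundle directory.
#' @param out_dir output directory.
#' @param classifier feature-based classifier kind.
#' @param R_grid integer candidates.
#' @param viewer_id ground-truth viewer.
#' @param seed seed for the tuning split.
#' @param ... passed through to [loocv_evaluate()].
#' @return The selected R, invisibly.
#' @export
cmd_tune <- function(bundle_dir, out_dir, classifier = "naive_bayes",
                     R_grid = 5:20, viewer_id = "viewer1", seed = 1L,
                     ...) {
  ds <- load_dataset(bundle_dir, file.path(bundle_dir, "labels.tsv"))
  sp <- split_tuning(ds, seed = seed)
  tr <- tune_R(sp$tuning, classifier = classifier, R_grid = R_grid,
               viewer_id = viewer_id, verbose = TRUE, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(tr$curve, file.path(out_dir, "tuning_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_config(list(command = "tune", classifier = classifier,
                        R_grid = R_grid, best_R = tr$best_R,
                        viewer_id = viewer_id, seed = seed,
                        tuning_subjects = sp$tuning_subjects), out_dir)
  invisible(tr$best_R)
}

#' Evaluate a classifier by leave-one-subject-out cross-validation
#'
#' Runs the LOOCV protocol per viewer, averages over viewers, and writes
#' all evaluation reports (JSON + TSV).
#'
#' @param bundle_dir dataset bundle directory.
#' @param out_dir output directory.
#' @param classifier classifier kind.
#' @param R resize parameter (ignored for correlation).
#' @param viewers viewer columns to evaluate; results are averaged.
#' @param templates_dir template directory (correlation only).
#' @param exclude_tuning optionally exclude a tuning split (by `seed`)
#'   from the final evaluation.
#' @param seed seed for the tuning split when `exclude_tuning`.
#' @param ... passed to [loocv_evaluate()].
#' @return The averaged [evaluation_report][compute_metrics()],
#'   invisibly.
#' @export
cmd_evaluate <- function(bundle_dir, out_dir, classifier = "naive_bayes",
                         R = 10L, viewers = c("viewer1", "viewer2"),
                         templates_dir = NULL, exclude_tuning = FALSE,
                         seed = 1L, ...) {
  ds <- load_dataset(bundle_dir, file.path(bundle_dir, "labels.tsv"))
  if (exclude_tuning) ds <- split_tuning(ds, seed = seed)$heldout
  templates <- if (!is.null(templates_dir))
    read_template_set(templates_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reports <- lapply(viewers, function(v) {
    r <- loocv_evaluate(ds, classifier = classifier, R = R,
                        viewer_id = v, templates = templates,
                        verbose = TRUE, ...)
    write_evaluation_report(r, file.path(out_dir, paste0("eval_", v)))
    r
  })
  avg <- average_over_viewers(reports)
  write_evaluation_report(avg, file.path(out_dir, "eval_averaged"))
  write_run_config(list(command = "evaluate", classifier = classifier,
                        R = R, viewers = viewers,
                        exclude_tuning = exclude_tuning, seed = seed,
                        bundle = bundle_dir), out_dir)
  invisible(avg)
}

#' Decompose a 4D resting scan into spatial components (delegated)
#'
#' Hands spatial ICA to an established external implementation
#' (scikit-learn's FastICA via the `python` interpreter on the PATH);
#' the unmixing algorithm is not re-derived here. The resulting
#' `n_components` spatial maps are variance-normalized per map and
#' written as a classification-ready bundle. If no usable backend is
#' found the command fails with a "decomposition backend missing" error;
#' classification remains fully usable on precomputed maps.
#'
#' @param rest_4d path to a 4D NIfTI resting time series.
#' @param out_dir output bundle directory.
#' @param n_components number of components (default 28, an intermediate
#'   model order; must be >= 2).
#' @param seed RNG seed passed to the backend.
#' @return The output directory, invisibly.
#' @export
cmd_decompose <- function(rest_4d, out_dir, n_components = 28L,
                          seed = 1L) {
  n_components <- as.integer(n_components)
  if (n_components < 2L)
    stop("n_components must be >= 2", call. = FALSE)
  img <- RNifti::readNifti(rest_4d)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected a 4D time series, got ", length(d), "D", call. = FALSE)
  vox <- RNifti::pixdim(img)[1:3]

  py <- Sys.which("python")
  if (!nzchar(py))
    stop("decomposition backend missing: no python interpreter on PATH",
         call. = FALSE)
  td <- tempfile("ica")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  # exchange data as flat binary doubles: voxels x time
  x <- matrix(as.numeric(img), nrow = prod(d[1:3]), ncol = d[4])
  writeBin(as.vector(x), file.path(td, "x.bin"))
  script <- file.path(td, "ica.py")
  writeLines(c(
    "import sys, numpy as np",
    "from sklearn.decomposition import FastICA",
    "nv, nt, nc, seed = (int(a) for a in sys.argv[1:5])",
    "x = np.fromfile(sys.argv[5], dtype=np.float64).reshape((nt, nv)).T",
    "x = x - x.mean(axis=1, keepdims=True)",
    "ica = FastICA(n_components=nc, random_state=seed, max_iter=1000)",
    "s = ica.fit_transform(x)  # voxels x components (spatial ICA)",
    "np.asarray(s, dtype=np.float64).T.tofile(sys.argv[6])"),
    script)
  status <- system2(py, c(script, prod(d[1:3]), d[4], n_components,
                          as.integer(seed), file.path(td, "x.bin"),
                          file.path(td, "s.bin")),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0)
    stop("decomposition backend missing or failed ",
         "(python/scikit-learn FastICA exited with status ", status, ")",
         call. = FALSE)
  s <- matrix(readBin(file.path(td, "s.bin"), "double",
                      n = prod(d[1:3]) * n_components),
              nrow = prod(d[1:3]), byrow = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- character(n_components)
  for (k in seq_len(n_components)) {
    m <- array(s[, k], dim = d[1:3])
    m <- m / stats::sd(m)  # pseudo-t scale: unit-variance map
    fn <- sprintf("component_%02d.nii.gz", k)
    write_component_volume(
      brain_volume(m, voxel_size_mm = vox,
                   mask = array(TRUE, d[1:3]), space_tag = "ica"),
      file.path(out_dir, fn))
    rows[k] <- paste("decomposed", k, fn, "", "", sep = "\t")
  }
  writeLines(c(paste("subject_id", "component_index", "volume_file",
                     "viewer1", "viewer2", sep = "\t"), rows),
             file.path(out_dir, "labels.tsv"))
  write_run_config(list(command = "decompose", input = rest_4d,
                        n_components = n_components, seed = seed),
                   out_dir)
  invisible(out_dir)
}
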