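#' Construct a multi-subject dataset of component maps
#'
#' @param components list of [component_map()] objects.
#' @param viewers character vector of viewer ids present in the labels.
#' @param label_set allowed network label set.
#' @return An object of class `rsn_dataset` with elements `components`,
#'   `subjects` (unique subject ids), `viewers`, `label_set`.
#' @export
rsn_dataset <- function(components, viewers = NULL,
                        label_set = network_labels()) {
  stopifnot(all(vapply(components, inherits, TRUE, "component_map")))
  if (length(components)) {
    shapes <- vapply(components, function(cm)
      paste(cm$volume$shape, collapse = "x"), "")
    if (length(unique(shapes)) > 1L)
      stop("all volumes must share one grid; found shapes: ",
           paste(unique(shapes), collapse = " vs "), call. = FALSE)
    vox <- vapply(components, function(cm)
      paste(signif(cm$volume$voxel_size_mm, 6), collapse = "x"), "")
    if (length(unique(vox)) > 1L)
      stop("all volumes must share one voxel size; found: ",
           paste(unique(vox), collapse = " vs "), call. = FALSE)
    key <- vapply(components, function(cm)
      paste(cm$subject_id, cm$component_index), "")
    if (anyDuplicated(key))
      stop("duplicate (subject, component_index) pairs: ",
           paste(key[duplicated(key)], collapse = ", "), call. = FALSE)
  }
  if (is.null(viewers))
    viewers <- sort(unique(unlist(lapply(components, function(cm)
      names(cm$viewer_labels)))))
  subjects <- unique(vapply(components, function(cm) cm$subject_id, ""))
  structure(
    list(components = components, subjects = subjects,
         viewers = viewers, label_set = label_set),
    class = "rsn_dataset")
}

#' @export
print.rsn_dataset <- function(x, ...) {
  cat("<rsn_dataset> ", length(x$subjects), " subjects, ",
      length(x$components), " components, viewers: ",
      paste(x$viewers, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of subjects in a dataset
#' @param dataset an [rsn_dataset()].
#' @return integer subject count.
#' @export
n_subjects <- function(dataset) length(dataset$subjects)

#' Load a dataset from a volume directory and a label table
#'
#' The label table is tab-separated UTF-8 with a header row and columns
#' `subject_id`, `component_index`, `volume_file`, plus one column per
#' viewer (e.g. `viewer1`, `viewer2`); blank cells mean unlabeled. All
#' volumes must share one grid (shape and voxel size); the loader verifies
#' this and never resamples.
#'
#' @param volume_dir directory containing the NIfTI volumes named in the
#'   table's `volume_file` column.
#' @param label_table path to the TSV label table.
#' @param label_set allowed network label set.
#' @param mask optional shared brain mask (logical array or NIfTI path)
#'   applied to every volume, overriding per-volume nonzero masks.
#' @return An [rsn_dataset()].
#' @export
load_dataset <- function(volume_dir, label_table,
                         label_set = network_labels(), mask = NULL) {
  tab <- utils::read.delim(label_table, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           fileEncoding = "UTF-8")
  required <- c("subject_id", "component_index", "volume_file")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("label table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  viewer_cols <- setdiff(names(tab), required)
  if (nrow(tab) == 0L)
    return(rsn_dataset(list(), viewers = viewer_cols, label_set = label_set))

  bad_rows <- integer()
  for (vc in viewer_cols) {
    vals <- tab[[vc]]
    bad <- which(nzchar(vals) & !(vals %in% label_set))
    bad_rows <- union(bad_rows, bad)
  }
  if (length(bad_rows))
    stop("label table rows with labels outside {",
         paste(label_set, collapse = ", "), "}: rows ",
         paste(sort(bad_rows), collapse = ", "), call. = FALSE)

  if (is.character(mask)) mask <- read_component_volume(mask)$values != 0

  components <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    f <- file.path(volume_dir, tab$volume_file[i])
    if (!file.exists(f))
      stop("label table row ", i, " (subject ", tab$subject_id[i],
           ", component ", tab$component_index[i],
           "): volume file not found: ", f, call. = FALSE)
    vol <- read_component_volume(f, mask = mask)
    labs <- character()
    for (vc in viewer_cols)
      if (nzchar(tab[[vc]][i])) labs[vc] <- tab[[vc]][i]
    components[[i]] <- component_map(
      tab$subject_id[i], as.integer(tab$component_index[i]), vol,
      viewer_labels = labs, label_set = label_set)
  }
  # canonical order: subject then component index, so row permutations of
  # the table load to equal datasets
  ord <- order(vapply(components, function(cm) cm$subject_id, ""),
               vapply(components, function(cm) cm$component_index, 1L))
  rsn_dataset(components[ord], viewers = viewer_cols, label_set = label_set)
}

#' Write a dataset as a NIfTI + TSV bundle
#'
#' Writes one NIfTI file per component plus a `labels.tsv` table in the
#' format consumed by [load_dataset()], so generated datasets round-trip.
#'
#' @param dataset an [rsn_dataset()].
#' @param out_dir output directory (created if needed).
#' @param gzip write `.nii.gz` (default) or plain `.nii`.
#' @return The path of the label table, invisibly.
#' @export
write_dataset_bundle <- function(dataset, out_dir, gzip = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  viewers <- dataset$viewers
  rows <- lapply(dataset$components, function(cm) {
    fn <- sprintf("%s_ic%02d%s", cm$subject_id, cm$component_index, ext)
    write_component_volume(cm$volume, file.path(out_dir, fn))
    r <- c(subject_id = cm$subject_id,
           component_index = as.character(cm$component_index),
           volume_file = fn)
    for (v in viewers) r[v] <- if (v %in% names(cm$viewer_labels))
      cm$viewer_labels[[v]] else ""
    r
  })
  tab <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  path <- file.path(out_dir, "labels.tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Extract the labels a viewer assigned, one per component
#'
#' @param dataset an [rsn_dataset()].
#' @param viewer_id viewer column name.
#' @return character vector, `NA` where the viewer left a component
#'   unlabeled.
#' @export
viewer_labels <- function(dataset, viewer_id) {
  vapply(dataset$components, function(cm) {
    if (viewer_id %in% names(cm$viewer_labels))
      cm$viewer_labels[[viewer_id]] else NA_character_
  }, "")
}

#' Restrict a dataset to a subset of subjects
#' @param dataset an [rsn_dataset()].
#' @param subjects character vector of subject ids to keep.
#' @return An [rsn_dataset()].
#' @export
subset_subjects <- function(dataset, subjects) {
  keep <- vapply(dataset$components,
                 function(cm) cm$subject_id %in% subjects, TRUE)
  rsn_dataset(dataset$components[keep], viewers = dataset$viewers,
              label_set = dataset$label_set)
}
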