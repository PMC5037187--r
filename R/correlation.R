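#' Construct a template set for the spatial-correlation classifier
#'
#' A set of labeled reference network maps on the same grid as the subject
#' maps. The published template maps are not redistributable, so users
#' supply their own directory of NIfTI volumes plus a TSV, or use
#' [make_archetypes()] to fabricate a synthetic set.
#'
#' @param volumes list of [brain_volume()] objects.
#' @param labels character vector of network labels, one per volume.
#' @param names optional template names (default `template_1`, ...).
#' @param label_set allowed label set.
#' @return An object of class `template_set`.
#' @export
template_set <- function(volumes, labels, names = NULL,
                         label_set = network_labels()) {
  stopifnot(all(vapply(volumes, inherits, TRUE, "brain_volume")),
            length(volumes) == length(labels))
  check_labels(labels, label_set)
  shapes <- vapply(volumes, function(v) paste(v$shape, collapse = "x"), "")
  if (length(unique(shapes)) > 1L)
    stop("templates must share one grid; found: ",
         paste(unique(shapes), collapse = " vs "), call. = FALSE)
  if (is.null(names)) names <- sprintf("template_%d", seq_along(volumes))
  structure(list(volumes = volumes, labels = as.character(labels),
                 names = names, label_set = label_set),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat("<template_set> ", length(x$volumes), " templates: ",
      paste(sprintf("%s(%s)", x$names, x$labels), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Load a template set from a directory of NIfTI volumes plus a TSV
#'
#' The TSV needs columns `volume_file` and `label`.
#'
#' @param dir directory containing the volumes and the table.
#' @param table_file name of the TSV inside `dir`.
#' @param label_set allowed label set.
#' @return A [template_set()].
#' @export
read_template_set <- function(dir, table_file = "templates.tsv",
                              label_set = network_labels()) {
  tab <- utils::read.delim(file.path(dir, table_file), sep = "\t",
                           colClasses = "character")
  vols <- lapply(file.path(dir, tab$volume_file), read_component_volume)
  template_set(vols, tab$label,
               names = tools::file_path_sans_ext(tab$volume_file,
                                                 compression = TRUE),
               label_set = label_set)
}

#' Write a template set as a NIfTI + TSV directory
#' @param templates a [template_set()].
#' @param dir output directory.
#' @return the TSV path, invisibly.
#' @export
write_template_set <- function(templates, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- paste0(templates$names, ".nii.gz")
  for (i in seq_along(templates$volumes))
    write_component_volume(templates$volumes[[i]], file.path(dir, files[i]))
  path <- file.path(dir, "templates.tsv")
  utils::write.table(data.frame(volume_file = files,
                                label = templates$labels),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify a component by spatial correlation against templates
#'
#' Computes the Pearson correlation between the component map and every
#' template at full grid resolution over the intersection of their masks,
#' ranks templates by descending correlation, and inherits the network
#' label of the best-correlating template. A template whose overlap with
#' the component has zero variance has undefined correlation and is
#' ranked last with score `-Inf`. Ties keep template list order.
#'
#' @param component a [component_map()] or [brain_volume()].
#' @param templates a [template_set()] on the same grid.
#' @return A list with `label` (inherited network), and `ranking` — a
#'   data.frame of `template`, `label`, `correlation` in descending order.
#' @export
correlation_classify <- function(component, templates) {
  vol <- if (inherits(component, "component_map")) component$volume
         else component
  stopifnot(inherits(vol, "brain_volume"),
            inherits(templates, "template_set"))
  r <- vapply(templates$volumes, function(tv) {
    if (!identical(tv$shape, vol$shape))
      stop("template grid ", paste(tv$shape, collapse = "x"),
           " does not match component grid ",
           paste(vol$shape, collapse = "x"), call. = FALSE)
    both <- tv$mask & vol$mask
    if (sum(both) < 2L) return(-Inf)
    x <- vol$values[both]; y <- tv$values[both]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(-Inf)
    stats::cor(x, y)
  }, 0)
  if (all(!is.finite(r)))
    stop("correlation undefined against every template ",
         "(zero-variance overlap)", call. = FALSE)
  ord <- order(r, decreasing = TRUE)  # stable: ties keep list order
  ranking <- data.frame(template = templates$names[ord],
                        label = templates$labels[ord],
                        correlation = r[ord],
                        stringsAsFactors = FALSE)
  list(label = ranking$label[1L], ranking = ranking)
}
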