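#' Construct a brain volume
#'
#' A `brain_volume` is a 3D scalar field of t-statistics on a fixed analysis
#' grid, together with voxel dimensions and an in-brain logical mask. All
#' classifiers in the package consume these volumes; the reference analysis
#' grid is 53 x 63 x 46 voxels at 3 mm isotropic in MNI space.
#'
#' Non-finite values are replaced by 0 so that dot products and Pearson
#' correlations downstream stay finite. If no mask is supplied the mask
#' defaults to the nonzero voxels of the volume.
#'
#' @param values numeric 3D array of t-statistics.
#' @param voxel_size_mm positive numeric triple, voxel edge lengths in mm.
#' @param mask logical 3D array of the same shape, or `NULL` for the
#'   default nonzero-voxel mask.
#' @param space_tag free-text grid identifier (e.g. `"MNI-3mm"`).
#' @return An object of class `brain_volume` with elements `values`,
#'   `shape`, `voxel_size_mm`, `mask`, `space_tag`.
#' @export
brain_volume <- function(values, voxel_size_mm = c(3, 3, 3), mask = NULL,
                         space_tag = "unknown") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3D array, got ", length(dim(values)), " dims",
         call. = FALSE)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be a positive triple", call. = FALSE)
  values[!is.finite(values)] <- 0
  if (is.null(mask)) {
    mask <- values != 0
  } else {
    if (!identical(dim(mask), dim(values)))
      stop("mask shape ", paste(dim(mask), collapse = "x"),
           " does not match volume shape ",
           paste(dim(values), collapse = "x"), call. = FALSE)
    mask <- array(as.logical(mask), dim = dim(values))
    mask[is.na(mask)] <- FALSE
  }
  structure(
    list(values = values, shape = dim(values),
         voxel_size_mm = as.numeric(voxel_size_mm), mask = mask,
         space_tag = space_tag),
    class = "brain_volume")
}

#' @export
print.brain_volume <- function(x, ...) {
  cat("<brain_volume> ", paste(x$shape, collapse = " x "),
      " voxels @ ", paste(x$voxel_size_mm, collapse = "x"), " mm, ",
      sum(x$mask), " in mask, space ", x$space_tag, "\n", sep = "")
  invisible(x)
}

#' Read a component t-map from a NIfTI file
#'
#' Reads a 3D (or 4D with a singleton fourth dimension) NIfTI volume and
#' returns a [brain_volume()]. Shape and voxel size come from the header;
#' NaN/Inf voxels are zeroed; the mask defaults to nonzero voxels unless an
#' explicit mask volume is given.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param mask optional logical array or path to a mask NIfTI on the same
#'   grid; overrides the default nonzero mask.
#' @return A [brain_volume()].
#' @export
read_component_volume <- function(path, mask = NULL) {
  if (!file.exists(path))
    stop("cannot read volume: file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1L, drop = TRUE]
    d <- dim(img)
  }
  if (length(d) != 3L)
    stop("expected a 3D volume in ", path, ", got ", length(d),
         " dimensions", call. = FALSE)
  vox <- RNifti::pixdim(img)[seq_len(3L)]
  if (is.character(mask)) {
    mvol <- read_component_volume(mask)
    if (!identical(mvol$shape, d))
      stop("mask grid ", paste(mvol$shape, collapse = "x"),
           " does not match volume grid ", paste(d, collapse = "x"),
           call. = FALSE)
    mask <- mvol$values != 0
  }
  brain_volume(array(as.numeric(img), dim = d), voxel_size_mm = vox,
               mask = mask, space_tag = basename(path))
}

#' Write a brain volume to a NIfTI file
#'
#' @param volume a [brain_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_component_volume <- function(volume, path) {
  stopifnot(inherits(volume, "brain_volume"))
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Construct a component map
#'
#' One independent component's spatial t-map, tagged with its subject,
#' component index, and zero or more viewer-assigned network labels.
#'
#' @param subject_id subject identifier string.
#' @param component_index integer component number (>= 1) within subject.
#' @param volume a [brain_volume()].
#' @param viewer_labels named character vector or list mapping viewer id to
#'   a network label; may be empty.
#' @param label_set allowed label set.
#' @return An object of class `component_map`.
#' @export
component_map <- function(subject_id, component_index, volume,
                          viewer_labels = character(),
                          label_set = network_labels()) {
  stopifnot(inherits(volume, "brain_volume"))
  component_index <- as.integer(component_index)
  if (is.na(component_index) || component_index < 1L)
    stop("component_index must be an integer >= 1", call. = FALSE)
  viewer_labels <- unlist(viewer_labels)
  if (length(viewer_labels)) check_labels(viewer_labels, label_set)
  structure(
    list(subject_id = as.character(subject_id),
         component_index = component_index,
         volume = volume,
         viewer_labels = viewer_labels),
    class = "component_map")
}

#' @export
print.component_map <- function(x, ...) {
  labs <- if (length(x$viewer_labels))
    paste(names(x$viewer_labels), x$viewer_labels, sep = "=",
          collapse = ", ") else "unlabeled"
  cat("<component_map> subject ", x$subject_id, " IC", x$component_index,
      " [", labs, "]\n", sep = "")
  invisible(x)
}
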