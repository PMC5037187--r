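#' Construct a feature vector
#'
#' A flattened R x R x R representation of a component map. Encodings:
#' `raw_mean` (block-mean t values), `zscore` (standardized within the
#' vector), `binned` (integer codes 1..11 from [bin_scheme()]).
#'
#' @param values numeric vector of length `R^3`.
#' @param R resize parameter.
#' @param encoding one of `"raw_mean"`, `"zscore"`, `"binned"`.
#' @param origin_shape shape of the source grid.
#' @return An object of class `feature_vector`.
#' @export
feature_vector <- function(values, R, encoding = c("raw_mean", "zscore",
                                                   "binned"),
                           origin_shape = NULL) {
  encoding <- match.arg(encoding)
  R <- as.integer(R)
  if (length(values) != R^3)
    stop("feature vector length ", length(values), " != R^3 = ", R^3,
         call. = FALSE)
  if (encoding == "binned" &&
      (any(values != as.integer(values)) || any(values < 1 | values > 11)))
    stop("binned encoding requires integer values in 1..11", call. = FALSE)
  structure(list(values = as.numeric(values), R = R, encoding = encoding,
                 origin_shape = origin_shape),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("<feature_vector> R=", x$R, " (", length(x$values), " features, ",
      x$encoding, ")\n", sep = "")
  invisible(x)
}

# Partition an axis of length L into R index intervals
# [floor(a*L/R), floor((a+1)*L/R)); returns the cell index (1..R, possibly
# 0-length cells when R > L) of each voxel along that axis.
axis_cells <- function(L, R) {
  edges <- floor(seq_len(R) * L / R)   # upper bounds, last == L
  findInterval(seq_len(L) - 1L, c(0L, edges), rightmost.closed = FALSE,
               left.open = FALSE)
}

# Map every voxel of a grid to its flat cell id under lexicographic
# (i, j, k) ordering with k fastest. Cached per (shape, R) within a call
# chain via the returned integer array.
cell_index <- function(shape, R) {
  ci <- axis_cells(shape[1], R)
  cj <- axis_cells(shape[2], R)
  ck <- axis_cells(shape[3], R)
  # flat id = ((i-1)*R + (j-1))*R + k, built by outer sums
  i_part <- (ci - 1L) * R * R
  j_part <- (cj - 1L) * R
  array(rep(i_part, times = shape[2] * shape[3]) +
          rep(rep(j_part, each = shape[1]), times = shape[3]) +
          rep(ck, each = shape[1] * shape[2]),
        dim = shape)
}

#' Block-mean resize of a volume to an R x R x R feature vector
#'
#' Each axis of the grid is partitioned into `R` contiguous index
#' intervals, giving `R^3` cells that tile the volume exactly once; the
#' feature for a cell is the arithmetic mean of the in-mask voxel values
#' falling in it, and 0 for cells with no in-mask voxel. `R = 5` gives 125
#' features and `R = 20` gives 8000, the endpoints of the tuning grid.
#'
#' @param volume a [brain_volume()].
#' @param R integer resize parameter (>= 1; may exceed an axis length, in
#'   which case the surplus cells are empty and 0).
#' @return A [feature_vector()] with encoding `raw_mean`.
#' @export
block_resize <- function(volume, R) {
  stopifnot(inherits(volume, "brain_volume"))
  R <- as.integer(R)
  if (is.na(R) || R < 1L) stop("R must be an integer >= 1", call. = FALSE)
  idx <- cell_index(volume$shape, R)
  m <- volume$mask
  sums <- numeric(R^3)
  cnts <- numeric(R^3)
  if (any(m)) {
    s <- rowsum(volume$values[m], idx[m])
    ids <- as.integer(rownames(s))
    sums[ids] <- s[, 1L]
    cnts[ids] <- rowsum(rep(1, sum(m)), idx[m])[, 1L]
  }
  vals <- ifelse(cnts > 0, sums / pmax(cnts, 1), 0)
  feature_vector(vals, R, "raw_mean", origin_shape = volume$shape)
}

#' Z-transform a feature vector
#'
#' Standardizes the vector to mean 0 and (sample) standard deviation 1,
#' the transform applied to each whole-brain component map before binning
#' for the naive Bayes classifier. A constant vector maps to all zeros.
#'
#' @param fv a [feature_vector()] with encoding `raw_mean`.
#' @return A [feature_vector()] with encoding `zscore`.
#' @export
zscore_features <- function(fv) {
  stopifnot(inherits(fv, "feature_vector"))
  if (length(fv$values) < 2L)
    stop("Z-transform needs at least 2 features", call. = FALSE)
  s <- stats::sd(fv$values)
  vals <- if (s == 0) rep(0, length(fv$values))
          else (fv$values - mean(fv$values)) / s
  feature_vector(vals, fv$R, "zscore", origin_shape = fv$origin_shape)
}

#' The 11-interval Z-score binning scheme
#'
#' Default cut points -1.2, -0.9, -0.6, -0.3, 0, 0.3, 0.6, 0.9, 1.2, 1.5
#' define 11 bins covering the real line; most Z values of a smoothed
#' component map fall between -1.2 and 1.5, so the extreme bins capture
#' the activation tails.
#'
#' @param edges strictly increasing cut points.
#' @return An object of class `bin_scheme` with `edges` and `n_bins`.
#' @export
bin_scheme <- function(edges = c(-1.2, -0.9, -0.6, -0.3, 0,
                                 0.3, 0.6, 0.9, 1.2, 1.5)) {
  if (is.unsorted(edges, strictly = TRUE))
    stop("bin edges must be strictly increasing", call. = FALSE)
  structure(list(edges = as.numeric(edges),
                 n_bins = length(edges) + 1L),
            class = "bin_scheme")
}

#' Discretize a Z-scored feature vector into bin codes
#'
#' Bin k holds values in (edge\[k-1\], edge\[k\]\] (left-open,
#' right-closed), with bin 1 extending to -Inf and the last bin open
#' above the top edge, so every finite value gets exactly one code in
#' 1..n_bins.
#'
#' @param fv a [feature_vector()] with encoding `zscore`.
#' @param scheme a [bin_scheme()].
#' @return A [feature_vector()] with encoding `binned`.
#' @export
bin_features <- function(fv, scheme = bin_scheme()) {
  stopifnot(inherits(fv, "feature_vector"), inherits(scheme, "bin_scheme"))
  codes <- findInterval(fv$values, scheme$edges, left.open = TRUE) + 1L
  feature_vector(codes, fv$R, "binned", origin_shape = fv$origin_shape)
}

#' Full feature pipeline for one volume
#'
#' Convenience chain: [block_resize()] then, on request,
#' [zscore_features()] and [bin_features()]. The naive Bayes classifier
#' uses `binned`, the perceptron `raw_mean`.
#'
#' @param volume a [brain_volume()].
#' @param R resize parameter.
#' @param encoding target encoding.
#' @param scheme binning scheme for `encoding = "binned"`.
#' @return A [feature_vector()].
#' @export
extract_features <- function(volume, R,
                             encoding = c("raw_mean", "zscore", "binned"),
                             scheme = bin_scheme()) {
  encoding <- match.arg(encoding)
  fv <- block_resize(volume, R)
  if (encoding == "raw_mean") return(fv)
  fv <- zscore_features(fv)
  if (encoding == "zscore") return(fv)
  bin_features(fv, scheme)
}

#' Feature matrix for a whole dataset
#'
#' Applies [extract_features()] to every component; rows are components in
#' dataset order, columns the R^3 features. Feature extraction is purely
#' per-component (the Z-transform is within-map), so rows are independent
#' and the matrix can be computed once and subset per cross-validation
#' fold without information leakage.
#'
#' @param dataset an [rsn_dataset()].
#' @param R resize parameter.
#' @param encoding feature encoding.
#' @param scheme binning scheme.
#' @return Numeric matrix `n_components x R^3`.
#' @export
feature_matrix <- function(dataset, R, encoding = "raw_mean",
                           scheme = bin_scheme()) {
  mat <- t(vapply(dataset$components, function(cm)
    extract_features(cm$volume, R, encoding, scheme)$values,
    numeric(R^3)))
  rownames(mat) <- vapply(dataset$components, function(cm)
    paste0(cm$subject_id, ":", cm$component_index), "")
  mat
}

#' Export a feature matrix as TSV for audit
#' @param mat matrix from [feature_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(mat, path) {
  utils::write.table(data.frame(component = rownames(mat), mat,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
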