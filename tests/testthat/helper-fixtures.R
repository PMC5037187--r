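# Shared fixtures, built in code at test time.

# A small analysis grid that keeps the unit tests fast while preserving
# the anisotropic shape of the reference grid.
small_shape <- c(20L, 24L, 18L)

small_config <- function(n_subjects = 4L, seed = 101L, jitter_mm = 3,
                         ...) {
  generator_config(grid_shape = small_shape, n_subjects = n_subjects,
                   smoothing_fwhm_mm = 8, jitter_mm = jitter_mm,
                   seed = seed, ...)
}

# Deterministic toy volume with a full mask.
toy_volume <- function(shape = c(4L, 4L, 4L), values = NULL) {
  if (is.null(values)) values <- seq_len(prod(shape))
  brain_volume(array(as.numeric(values), dim = shape),
               mask = array(TRUE, shape))
}

# Random volume under a fixed seed.
random_volume <- function(shape = small_shape, seed = 1) {
  set.seed(seed)
  brain_volume(array(rnorm(prod(shape)), dim = shape),
               mask = array(TRUE, shape))
}

# Linearly separable feature clusters: one tight Gaussian cluster per
# label around an orthogonal-ish center.
separable_features <- function(n_per_class = 6, dim = 10, spread = 0.05,
                               seed = 5) {
  set.seed(seed)
  labels <- rep(network_labels(), each = n_per_class)
  centers <- diag(5)[, rep(1:5, each = n_per_class)]
  x <- t(rbind(centers, matrix(0, dim - 5, length(labels)))) +
    matrix(rnorm(length(labels) * dim, sd = spread),
           ncol = dim)
  list(x = x, labels = labels)
}

# Small binned training set for naive Bayes toys: bins restricted to 1..3.
binned_toy <- function(n = 12, nf = 3, n_classes = 3, seed = 9) {
  set.seed(seed)
  labs <- network_labels()[sample.int(n_classes, n, replace = TRUE)]
  x <- matrix(sample.int(3, n * nf, replace = TRUE), nrow = n)
  list(x = x, labels = labs)
}

# The two expert-viewer confusion matrices printed for the naive Bayes
# classifier on the epilepsy cohort (rows = true, columns = predicted).
viewer1_confusion <- function() {
  m <- matrix(c(34, 0, 1, 3, 0,
                0, 43, 0, 0, 0,
                2, 0, 36, 3, 0,
                7, 1, 8, 44, 0,
                0, 0, 0, 3, 15),
              nrow = 5, byrow = TRUE,
              dimnames = list(network_labels(), network_labels()))
  m
}

viewer2_confusion <- function() {
  m <- matrix(c(24, 0, 0, 2, 0,
                0, 41, 0, 0, 0,
                1, 2, 36, 1, 0,
                6, 0, 3, 47, 0,
                0, 0, 0, 3, 15),
              nrow = 5, byrow = TRUE,
              dimnames = list(network_labels(), network_labels()))
  m
}
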