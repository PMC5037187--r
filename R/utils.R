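#' Canonical resting-state network labels
#'
#' The fixed label set and order used throughout the package: auditory,
#' visual, default-mode, sensorimotor, executive control. The order is also
#' the deterministic tie-break order used by every classifier.
#'
#' @return Character vector of the five network labels.
#' @export
network_labels <- function() {
  c("auditory", "visual", "default_mode", "sensorimotor", "executive_control")
}

#' Validate a vector of network labels
#'
#' @param labels character vector to check.
#' @param label_set allowed label set (default [network_labels()]).
#' @return `labels`, invisibly, if all are valid.
#' @keywords internal
check_labels <- function(labels, label_set = network_labels()) {
  bad <- setdiff(unique(labels[!is.na(labels) & nzchar(labels)]), label_set)
  if (length(bad) > 0) {
    stop("unknown network label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(label_set, collapse = ", "), call. = FALSE)
  }
  invisible(labels)
}

# Run code with a temporary RNG state seeded by `seed`; the caller's
# .Random.seed is restored afterwards so library code never clobbers the
# user's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a master seed and a stream index, staying inside
# 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
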