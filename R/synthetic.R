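#' Generator configuration for synthetic IC maps
#'
#' The defaults mirror the analysis conditions the classifiers are built
#' for: a 53 x 63 x 46 grid at 3 mm isotropic, 10 mm FWHM Gaussian
#' smoothing, and roughly 8 signal ICs per subject covering five
#' networks. `noise_sd` is the standard deviation of the smoothed noise
#' field on the pseudo-t scale where noise is unit variance, so the
#' default 1 is the nominal t-map regime and larger values dial the
#' separability down; `peak_t` sets blob peak height on the same scale.
#' `jitter_mm` displaces each subject's blob centers to emulate
#' inter-subject anatomical variability.
#'
#' @param grid_shape integer triple.
#' @param voxel_size_mm voxel edge lengths in mm.
#' @param smoothing_fwhm_mm Gaussian smoothing FWHM.
#' @param noise_sd smoothed-noise standard deviation (pseudo-t units).
#' @param jitter_mm SD of per-subject blob center displacement.
#' @param ics_per_subject components generated per subject.
#' @param n_subjects number of subjects.
#' @param viewer_disagreement probability that the second simulated
#'   viewer relabels a component to a random other network.
#' @param peak_t blob peak amplitude in pseudo-t units.
#' @param seed master RNG seed; the dataset is a pure function of this
#'   configuration.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(grid_shape = c(53L, 63L, 46L),
                             voxel_size_mm = c(3, 3, 3),
                             smoothing_fwhm_mm = 10,
                             noise_sd = 1,
                             jitter_mm = 6,
                             ics_per_subject = 8L,
                             n_subjects = 20L,
                             viewer_disagreement = 0.1,
                             peak_t = 8,
                             seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size_mm = as.numeric(voxel_size_mm),
              smoothing_fwhm_mm = smoothing_fwhm_mm,
              noise_sd = noise_sd, jitter_mm = jitter_mm,
              ics_per_subject = as.integer(ics_per_subject),
              n_subjects = as.integer(n_subjects),
              viewer_disagreement = viewer_disagreement,
              peak_t = peak_t, seed = as.integer(seed))
  stopifnot(length(cfg$grid_shape) == 3L, all(cfg$grid_shape >= 1L),
            all(cfg$voxel_size_mm > 0), cfg$smoothing_fwhm_mm >= 0,
            cfg$noise_sd >= 0, cfg$jitter_mm >= 0,
            cfg$ics_per_subject >= 1L, cfg$n_subjects >= 1L,
            cfg$viewer_disagreement >= 0, cfg$viewer_disagreement <= 1,
            cfg$peak_t > 0)
  class(cfg) <- "generator_config"
  cfg
}

# Default network archetype geometry on the reference grid, as fractional
# grid coordinates so other grid shapes scale along. Centers are fixtures
# approximating canonical topographies, not anatomical claims; the
# auditory/sensorimotor and visual/default-mode pairs are deliberately
# the spatially closest, mirroring the confusions the classifiers face in
# practice. Networks spanning multiple ICs get two variants.
default_archetype_specs <- function() {
  blob <- function(cx, cy, cz, sigma = 8, amp = 1)
    list(center_frac = c(cx, cy, cz), sigma_mm = sigma, amplitude = amp)
  list(
    list(label = "auditory", variant = 1L,           # bilateral temporal
         blobs = list(blob(0.22, 0.48, 0.38), blob(0.78, 0.48, 0.38))),
    list(label = "visual", variant = 1L,             # medial occipital
         blobs = list(blob(0.50, 0.14, 0.42, sigma = 10))),
    list(label = "visual", variant = 2L,             # lateral occipital
         blobs = list(blob(0.28, 0.18, 0.48), blob(0.72, 0.18, 0.48))),
    list(label = "default_mode", variant = 1L,       # PCC + mPFC midline
         blobs = list(blob(0.50, 0.34, 0.60), blob(0.50, 0.82, 0.55))),
    list(label = "default_mode", variant = 2L,       # bilateral parietal
         blobs = list(blob(0.24, 0.36, 0.66), blob(0.76, 0.36, 0.66))),
    list(label = "sensorimotor", variant = 1L,       # bilateral dorsal
         blobs = list(blob(0.30, 0.52, 0.80), blob(0.70, 0.52, 0.80))),
    list(label = "sensorimotor", variant = 2L,       # midline SMA
         blobs = list(blob(0.50, 0.58, 0.88, sigma = 9))),
    list(label = "executive_control", variant = 1L,  # bilateral frontal
         blobs = list(blob(0.30, 0.78, 0.70), blob(0.70, 0.78, 0.70))))
}

# Sum-of-Gaussians field via separable 1D profiles; sigma combines the
# blob scale with the smoothing kernel (Gaussian * Gaussian = Gaussian).
blob_field <- function(shape, voxel_mm, blobs, fwhm_mm,
                       centers_vox = NULL) {
  sig_sm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  acc <- array(0, dim = shape)
  for (bi in seq_along(blobs)) {
    b <- blobs[[bi]]
    ctr <- if (is.null(centers_vox)) b$center_frac * shape
           else centers_vox[[bi]]
    s_vox <- sqrt(b$sigma_mm^2 + sig_sm^2) / voxel_mm  # per-axis, voxels
    g1 <- lapply(1:3, function(a)
      exp(-((seq_len(shape[a]) - ctr[a])^2) / (2 * s_vox[a]^2)))
    acc <- acc + b$amplitude *
      outer(outer(g1[[1]], g1[[2]]), g1[[3]])
  }
  acc
}

# FFT-based Gaussian smoothing with periodic boundary; adequate for
# synthetic noise fields whose energy is far from the grid faces.
gaussian_smooth_fft <- function(arr, fwhm_mm, voxel_mm) {
  if (fwhm_mm <= 0) return(arr)
  shape <- dim(arr)
  sig_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / voxel_mm
  k1 <- lapply(1:3, function(a) {
    f <- c(0:(shape[a] %/% 2), -((shape[a] - shape[a] %/% 2 - 1):1)) /
      shape[a]
    exp(-2 * pi^2 * sig_vox[a]^2 * f^2)
  })
  ker <- outer(outer(k1[[1]], k1[[2]]), k1[[3]])
  Re(stats::fft(stats::fft(arr) * ker, inverse = TRUE)) / prod(shape)
}

#' Fabricate a synthetic template set of network archetypes
#'
#' Builds one noise-free reference map per archetype variant: a sum of
#' Gaussian blobs at canonical per-network locations, at the smoothness
#' implied by the configured FWHM, normalized to unit peak. Deterministic
#' for a fixed configuration. The visual, default-mode and sensorimotor
#' networks carry two variants each (these networks typically split into
#' multiple ICs), giving 8 archetypes over the five networks.
#'
#' @param config a [generator_config()].
#' @param specs archetype specifications (see
#'   `default_archetype_specs()`); centers as fractions of the grid.
#' @return A [template_set()] whose template names encode label and
#'   variant.
#' @export
make_archetypes <- function(config = generator_config(),
                            specs = default_archetype_specs()) {
  shape <- config$grid_shape
  for (sp in specs)
    for (b in sp$blobs)
      if (any(b$center_frac <= 0) || any(b$center_frac >= 1))
        stop("blob center outside grid for label ", sp$label,
             call. = FALSE)
  vols <- lapply(specs, function(sp) {
    f <- blob_field(shape, config$voxel_size_mm, sp$blobs,
                    config$smoothing_fwhm_mm)
    f <- f / max(f)
    brain_volume(f, voxel_size_mm = config$voxel_size_mm,
                 mask = array(TRUE, shape), space_tag = "synthetic")
  })
  template_set(vols,
               labels = vapply(specs, `[[`, "", "label"),
               names = vapply(specs, function(sp)
                 sprintf("%s_v%d", sp$label, sp$variant), ""))
}

#' Simulate one subject's IC maps
#'
#' Samples `ics_per_subject` archetypes (every network represented at
#' least once whenever that many components are drawn), displaces each
#' blob center by a per-subject Gaussian jitter, and composes the map as
#' `peak_t * blob field + noise_sd * smoothed unit-variance noise` — a
#' pseudo-t map in which the noise floor has standard deviation
#' `noise_sd`. The generating network is stored as the `truth` attribute
#' on each component's `viewer_labels`-independent slot.
#'
#' @param archetypes a [template_set()] from [make_archetypes()] (used
#'   for its label/variant roster; geometry is rebuilt from `specs`).
#' @param config a [generator_config()].
#' @param subject_id subject identifier.
#' @param specs archetype specifications matching `archetypes`.
#' @param seed RNG seed for this subject (derived from the config seed by
#'   [make_dataset()]).
#' @return List of [component_map()]s with an attribute `truth` giving
#'   the generating network per component.
#' @export
make_subject <- function(archetypes, config, subject_id,
                         specs = default_archetype_specs(),
                         seed = config$seed) {
  shape <- config$grid_shape
  vox <- config$voxel_size_mm
  n_ic <- config$ics_per_subject
  n_arch <- length(specs)
  if (n_ic > n_arch)
    stop("ics_per_subject (", n_ic, ") exceeds available archetype ",
         "variants (", n_arch, ")", call. = FALSE)
  labels_all <- vapply(specs, `[[`, "", "label")

  # sample() treats a length-1 x as 1:x; this keeps set semantics
  resample <- function(x, n) x[sample.int(length(x), n)]

  with_seed(seed, {
    # choose archetypes: cover every network first, then fill randomly
    chosen <- integer(0)
    if (n_ic >= length(unique(labels_all))) {
      for (lb in unique(labels_all))
        chosen <- c(chosen, resample(which(labels_all == lb), 1L))
    }
    pool <- setdiff(seq_len(n_arch), chosen)
    extra <- n_ic - length(chosen)
    if (extra > 0)
      chosen <- c(chosen, resample(pool, extra))
    chosen <- sort(chosen[seq_len(n_ic)])

    comps <- vector("list", n_ic)
    truth <- character(n_ic)
    for (i in seq_along(chosen)) {
      sp <- specs[[chosen[i]]]
      jit_vox <- config$jitter_mm / vox
      centers <- lapply(sp$blobs, function(b)
        b$center_frac * shape + stats::rnorm(3, 0, jit_vox))
      sig <- blob_field(shape, vox, sp$blobs, config$smoothing_fwhm_mm,
                        centers_vox = centers)
      if (max(sig) > 0) sig <- sig / max(sig)
      vals <- config$peak_t * sig
      if (config$noise_sd > 0) {
        noise <- gaussian_smooth_fft(
          array(stats::rnorm(prod(shape)), dim = shape),
          config$smoothing_fwhm_mm, vox)
        noise <- noise / stats::sd(noise)   # unit-sd smoothed noise
        vals <- vals + config$noise_sd * noise
      }
      truth[i] <- sp$label
      comps[[i]] <- component_map(
        subject_id, i,
        brain_volume(vals, voxel_size_mm = vox,
                     mask = array(TRUE, shape), space_tag = "synthetic"))
    }
    attr(comps, "truth") <- truth
    comps
  })
}

#' Simulate a full multi-subject labeled dataset with two viewers
#'
#' Generates `n_subjects` subjects via [make_subject()] and attaches two
#' simulated expert viewers: viewer 1 reports the generating network
#' exactly; viewer 2 independently relabels each component to a random
#' other network with probability `viewer_disagreement`. The result is a
#' pure function of the configuration and round-trips through
#' [write_dataset_bundle()] / [load_dataset()].
#'
#' @param config a [generator_config()].
#' @param specs archetype specifications.
#' @param out_dir optional directory; when given, the NIfTI + TSV bundle
#'   is written there.
#' @return An [rsn_dataset()] with viewers `viewer1`, `viewer2`.
#' @export
make_dataset <- function(config = generator_config(),
                         specs = default_archetype_specs(),
                         out_dir = NULL) {
  archetypes <- make_archetypes(config, specs)
  components <- list()
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("sub%02d", s)
    comps <- make_subject(archetypes, config, sid, specs = specs,
                          seed = derive_seed(config$seed, s))
    truth <- attr(comps, "truth")
    v2 <- with_seed(derive_seed(config$seed, 100000L + s), {
      flip <- stats::runif(length(truth)) < config$viewer_disagreement
      vapply(seq_along(truth), function(i) {
        if (!flip[i]) truth[i]
        else sample(setdiff(network_labels(), truth[i]), 1L)
      }, "")
    })
    for (i in seq_along(comps))
      comps[[i]]$viewer_labels <- c(viewer1 = truth[i], viewer2 = v2[i])
    components <- c(components, comps)
  }
  ds <- rsn_dataset(components, viewers = c("viewer1", "viewer2"))
  if (!is.null(out_dir)) {
    write_dataset_bundle(ds, out_dir)
    jsonlite::write_json(unclass(config),
                         file.path(out_dir, "generator_config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  ds
}
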