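# --- spatial correlation classifier ---------------------------------

test_that("a component identical to a template inherits its label at r = 1", {
  cfg <- small_config()
  arch <- make_archetypes(cfg)
  res <- correlation_classify(arch$volumes[[3]], arch)
  expect_identical(res$label, arch$labels[3])
  expect_equal(res$ranking$correlation[1], 1, tolerance = 1e-12)
})

test_that("correlation ranking matches the textbook Pearson formula", {
  shape <- c(2L, 2L, 2L)
  mk <- function(x) brain_volume(array(x, shape), mask = array(TRUE, shape))
  set.seed(31)
  tmpl_vals <- replicate(3, rnorm(8), simplify = FALSE)
  comp_vals <- rnorm(8)
  templates <- template_set(lapply(tmpl_vals, mk),
                            labels = c("auditory", "visual", "default_mode"))
  res <- correlation_classify(mk(comp_vals), templates)
  pearson <- function(x, y)
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r_oracle <- vapply(tmpl_vals, pearson, 0, x = comp_vals)
  ord <- order(r_oracle, decreasing = TRUE)
  expect_equal(res$ranking$correlation, r_oracle[ord], tolerance = 1e-12)
  expect_identical(res$label,
                   c("auditory", "visual", "default_mode")[ord[1]])
})

test_that("an anti-correlated template ranks last at r = -1", {
  shape <- c(2L, 2L, 2L)
  mk <- function(x) brain_volume(array(x, shape), mask = array(TRUE, shape))
  set.seed(32)
  a <- rnorm(8)
  templates <- template_set(list(mk(a), mk(rnorm(8)), mk(rnorm(8))),
                            labels = c("auditory", "visual", "sensorimotor"))
  res <- correlation_classify(mk(-a), templates)
  expect_identical(res$ranking$template[3], "template_1")
  expect_equal(res$ranking$correlation[3], -1, tolerance = 1e-12)
})

test_that("zero-variance overlaps rank last; all-undefined errors", {
  shape <- c(2L, 2L, 2L)
  mk <- function(x, m = array(TRUE, shape))
    brain_volume(array(x, shape), mask = m)
  flat <- mk(rep(1, 8))      # sd 0 within mask
  good <- mk(rnorm(8))
  comp <- mk(rnorm(8))
  res <- correlation_classify(comp,
    template_set(list(flat, good), labels = c("auditory", "visual")))
  expect_identical(res$ranking$template[2], "template_1")
  expect_identical(res$ranking$correlation[2], -Inf)
  expect_error(
    correlation_classify(comp,
      template_set(list(flat), labels = "auditory")),
    "undefined")
})

test_that("correlation classification ignores positive affine rescaling", {
  cfg <- small_config()
  arch <- make_archetypes(cfg)
  comps <- make_subject(arch, cfg, "s1", seed = 77)
  v <- comps[[2]]$volume
  r1 <- correlation_classify(v, arch)
  v2 <- brain_volume(3.7 * v$values + 1.1, mask = v$mask)
  r2 <- correlation_classify(v2, arch)
  expect_identical(r1$label, r2$label)
  expect_equal(r1$ranking$correlation, r2$ranking$correlation,
               tolerance = 1e-9)
})

# --- perceptron ------------------------------------------------------

test_that("orthogonal one-hot examples are learned perfectly", {
  x <- diag(5)
  labels <- network_labels()
  m <- perceptron_train(x, labels, epochs = 20, seed = 2)
  pred <- vapply(1:5, function(i) perceptron_classify(m, x[i, ])$label, "")
  expect_identical(pred, labels)
})

test_that("training reaches zero error on separable clusters, reproducibly", {
  d <- separable_features()
  m1 <- perceptron_train(d$x, d$labels, epochs = 50, seed = 4)
  m2 <- perceptron_train(d$x, d$labels, epochs = 50, seed = 4)
  expect_identical(m1$weights, m2$weights)   # determinism under the seed
  pred <- vapply(seq_len(nrow(d$x)), function(i)
    perceptron_classify(m1, d$x[i, ])$label, "")
  expect_identical(pred, d$labels)
  # a different seed shuffles differently but still separates
  m3 <- perceptron_train(d$x, d$labels, epochs = 50, seed = 9)
  pred3 <- vapply(seq_len(nrow(d$x)), function(i)
    perceptron_classify(m3, d$x[i, ])$label, "")
  expect_identical(pred3, d$labels)
})

test_that("classification is the argmax of dot products with fixed ties", {
  # all-zero weights: all scores tie, first label in fixed order wins
  m0 <- structure(list(weights = matrix(0, 5, 4,
                                        dimnames = list(network_labels(),
                                                        NULL)),
                       R = 1L, encoding = "raw_mean",
                       label_set = network_labels(),
                       hyperparams = list()),
                  class = "perceptron_model")
  expect_identical(perceptron_classify(m0, c(1, 2, 3))$label, "auditory")

  # weights(visual) = fv, others orthogonal: visual wins
  fv <- c(1, 0, 0, 2)
  w <- rbind(c(0, 1, 0, 0), fv, c(0, 0, 1, 0), c(0, 1, -1, 0),
             c(0, -1, 0, 0))
  rownames(w) <- network_labels()
  m <- structure(list(weights = cbind(w, bias = 0), R = 1L,
                      encoding = "raw_mean", label_set = network_labels(),
                      hyperparams = list()),
                 class = "perceptron_model")
  expect_identical(perceptron_classify(m, fv)$label, "visual")

  # random models agree with brute-force enumeration of the dot products
  set.seed(41)
  for (i in 1:50) {
    W <- matrix(rnorm(5 * 7), 5, 7,
                dimnames = list(network_labels(), NULL))
    mr <- structure(list(weights = W, R = 1L, encoding = "raw_mean",
                         label_set = network_labels(),
                         hyperparams = list()),
                    class = "perceptron_model")
    v <- rnorm(6)
    scores <- W %*% c(v, 1)
    expect_identical(perceptron_classify(mr, v)$label,
                     network_labels()[which.max(scores)])
  }
})

test_that("perceptron input validation", {
  expect_error(perceptron_train(matrix(0, 0, 3), character()), "empty")
  d <- separable_features()
  m <- perceptron_train(d$x, d$labels, epochs = 1)
  expect_error(perceptron_classify(m, rnorm(3)), "does not match")
  fvs <- list(feature_vector(1:8, 2), feature_vector(1:27, 3))
  expect_error(perceptron_train(fvs, c("auditory", "visual")),
               "disagree|lengths")
})

# --- naive Bayes -----------------------------------------------------

test_that("pure frequency counting (alpha = 0) yields degenerate CPTs", {
  x <- matrix(c(3, 1,
                3, 2,
                1, 2), nrow = 3, byrow = TRUE)
  labs <- c("auditory", "auditory", "visual")
  m <- nb_train(x, labs, alpha = 0)
  expect_identical(unname(m$cpt["auditory", 1, 3]), 1)       # always bin 3
  expect_identical(unname(m$cpt["auditory", 2, 1]), 0.5)
  expect_identical(m$priors[["auditory"]], 2 / 3)
})

test_that("Laplace-smoothed CPTs match hand counting", {
  # 3 examples, 2 labels, 2 features; counts done by hand:
  # auditory: rows (1,2), feature1 bins {2,2}, feature2 bins {1,3}
  x <- matrix(c(2, 1,
                2, 3,
                1, 1), nrow = 3, byrow = TRUE)
  labs <- c("auditory", "auditory", "visual")
  m <- nb_train(x, labs, alpha = 1)
  expect_equal(unname(m$cpt["auditory", 1, 2]), (2 + 1) / (2 + 11))
  expect_equal(unname(m$cpt["auditory", 1, 1]), (0 + 1) / (2 + 11))
  expect_equal(unname(m$cpt["auditory", 2, 3]), (1 + 1) / (2 + 11))
  expect_equal(unname(m$cpt["visual", 1, 1]), (1 + 1) / (1 + 11))
  expect_equal(m$priors[["auditory"]], (2 + 1) / (3 + 5))
})

test_that("CPTs normalize over bins for every (label, feature)", {
  d <- binned_toy(n = 30, nf = 4)
  for (alpha in c(0.5, 1, 3)) {
    m <- nb_train(d$x, d$labels, alpha = alpha)
    sums <- apply(m$cpt, c(1, 2), sum)
    expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-9)
    expect_equal(sum(m$priors), 1, tolerance = 1e-12)
  }
})

test_that("with uniform CPTs the posterior reduces to the priors", {
  labs <- rep(c("auditory", "visual", "visual"), 4)
  m <- nb_train(matrix(1, 12, 2), labs, alpha = 1e9)  # huge smoothing
  res <- nb_classify(m, c(5, 9))
  expect_identical(res$label, "visual")   # larger prior
  expect_gt(res$posterior[["visual"]], res$posterior[["auditory"]])
})

test_that("posterior equals exhaustive joint-probability enumeration", {
  d <- binned_toy(n = 18, nf = 3, n_classes = 3)
  m <- nb_train(d$x, d$labels, alpha = 1)
  classes <- network_labels()
  grid <- expand.grid(v1 = 1:3, v2 = 1:3, v3 = 1:3)
  for (g in seq_len(nrow(grid))) {
    v <- as.numeric(grid[g, ])
    joint <- vapply(seq_along(classes), function(li)
      m$priors[li] * m$cpt[li, 1, v[1]] * m$cpt[li, 2, v[2]] *
        m$cpt[li, 3, v[3]], 0)
    res <- nb_classify(m, v)
    expect_equal(unname(res$posterior), joint / sum(joint),
                 tolerance = 1e-12)
    expect_identical(res$label, classes[which.max(joint)])
  }
})

test_that("posteriors are invariant to a consistent feature permutation", {
  d <- binned_toy(n = 20, nf = 5)
  m <- nb_train(d$x, d$labels)
  perm <- c(4, 1, 5, 2, 3)
  mp <- m
  mp$cpt <- m$cpt[, perm, , drop = FALSE]
  v <- c(1, 3, 2, 2, 1)
  expect_equal(nb_classify(m, v)$posterior,
               nb_classify(mp, v[perm])$posterior, tolerance = 1e-12)
})

test_that("naive Bayes input validation", {
  expect_error(nb_train(matrix(0, 0, 2), character()), "empty")
  expect_error(nb_train(matrix(c(1, 12), 1, 2), "auditory"), "1..11")
  d <- binned_toy()
  m <- nb_train(d$x, d$labels)
  expect_error(nb_classify(m, c(1, 2, 12)), "1..11")
  expect_error(nb_classify(m, c(1, 2)), "does not match")
  fvs <- list(bin_features(zscore_features(feature_vector(rnorm(8), 2))))
  expect_error(nb_train(lapply(fvs, function(f)
    feature_vector(f$values, 2, "raw_mean")), "auditory"),
    "binned|1..11")
})

# --- weight back-projection ------------------------------------------

test_that("back-projection paints cells locally on the original grid", {
  L <- network_labels()
  w <- matrix(0, 5, 9, dimnames = list(L, NULL))
  m0 <- structure(list(weights = w, R = 2L, encoding = "raw_mean",
                       label_set = L, hyperparams = list()),
                  class = "perceptron_model")
  vols <- backproject_weights(m0, c(6L, 6L, 6L))
  expect_identical(names(vols), L)
  expect_true(all(vols$auditory$values == 0))

  w2 <- w; w2["visual", 1] <- 2.5   # cell (1,1,1) only
  m1 <- m0; m1$weights <- w2
  v <- backproject_weights(m1, c(6L, 6L, 6L))$visual$values
  expect_true(all(v[1:3, 1:3, 1:3] == 2.5))
  v[1:3, 1:3, 1:3] <- 0
  expect_true(all(v == 0))
})

test_that("naive Bayes back-projection shows zero-centered modal bins", {
  d <- binned_toy(n = 24, nf = 8)
  m <- nb_train(d$x, d$labels)
  vols <- backproject_weights(m, c(4L, 4L, 4L))
  rng <- range(vols[[1]]$values)
  expect_gte(rng[1], 1 - 6)   # bin codes 1..11 shifted by the center 6
  expect_lte(rng[2], 11 - 6)
})

test_that("trained perceptron weights localize on the generating blobs", {
  cfg <- small_config(n_subjects = 6, noise_sd = 0.25)
  ds <- make_dataset(cfg)
  arch <- make_archetypes(cfg)
  labs <- viewer_labels(ds, "viewer1")
  fm <- feature_matrix(ds, 5)
  m <- perceptron_train(fm, labs, seed = 3)
  vols <- backproject_weights(m, cfg$grid_shape)
  set.seed(55)
  for (lb in c("auditory", "executive_control")) {
    wv <- vols[[lb]]$values
    top <- wv >= quantile(wv, 0.9)
    ai <- which(arch$labels == lb)[1]
    blob <- arch$volumes[[ai]]$values > 0.5
    jaccard <- function(a, b) sum(a & b) / sum(a | b)
    rand <- array(FALSE, dim(wv))
    rand[sample(length(rand), sum(top))] <- TRUE
    expect_gt(jaccard(top, blob), jaccard(rand, blob))
    expect_gt(jaccard(top, blob), 0)
  }
})

# --- serialization and delegates -------------------------------------

test_that("models round-trip through JSON with identical predictions", {
  d <- separable_features()
  pm <- perceptron_train(d$x, d$labels, seed = 6)
  path <- tempfile(fileext = ".json")
  write_model(pm, path)
  pm2 <- read_model(path)
  expect_equal(pm2$weights, pm$weights, tolerance = 1e-15)
  v <- rnorm(ncol(d$x))
  expect_identical(perceptron_classify(pm, v)$label,
                   perceptron_classify(pm2, v)$label)

  bd <- binned_toy(n = 20, nf = 4)
  nm <- nb_train(bd$x, bd$labels)
  write_model(nm, path)
  nm2 <- read_model(path)
  expect_equal(nm2$cpt, nm$cpt, tolerance = 1e-15)
  expect_equal(nb_classify(nm2, c(1, 2, 3, 1))$posterior,
               nb_classify(nm, c(1, 2, 3, 1))$posterior,
               tolerance = 1e-12)
})

test_that("tree and SVM baselines separate the toy clusters", {
  d <- separable_features(n_per_class = 12)
  for (kind in c("tree", "svm")) {
    m <- delegate_train(d$x, d$labels, kind = kind)
    pred <- vapply(seq_len(nrow(d$x)), function(i)
      delegate_classify(m, d$x[i, ])$label, "")
    expect_gt(mean(pred == d$labels), 0.9)
  }
})
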