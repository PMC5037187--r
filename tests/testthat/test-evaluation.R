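make_labeled_dataset <- function(n_subjects = 4, seed = 101, ...) {
  make_dataset(small_config(n_subjects = n_subjects, seed = seed, ...))
}

test_that("tuning splits take half the subjects (rounding up), seeded", {
  mk <- function(n) {
    comps <- lapply(seq_len(n), function(s)
      component_map(sprintf("s%02d", s), 1,
                    random_volume(c(4L, 4L, 4L), seed = s),
                    viewer_labels = c(viewer1 = "auditory")))
    rsn_dataset(comps)
  }
  sp23 <- split_tuning(mk(23), tuning_count = 12, seed = 5)
  expect_identical(n_subjects(sp23$tuning), 12L)
  expect_identical(n_subjects(sp23$heldout), 11L)
  sp30 <- split_tuning(mk(30), seed = 5)   # default: half rounding up
  expect_identical(n_subjects(sp30$tuning), 15L)
  expect_identical(n_subjects(sp30$heldout), 15L)
  # disjoint partition whose union is the input
  expect_length(intersect(sp30$tuning$subjects, sp30$heldout$subjects), 0)
  expect_setequal(c(sp30$tuning$subjects, sp30$heldout$subjects),
                  mk(30)$subjects)
  # determinism and error bounds
  expect_identical(split_tuning(mk(23), 12, seed = 5)$tuning_subjects,
                   sp23$tuning_subjects)
  expect_error(split_tuning(mk(4), tuning_count = 4), "tuning_count")
})

test_that("confusion-matrix metrics match a brute-force one-vs-rest tally", {
  set.seed(61)
  conf <- matrix(rpois(25, 6), 5, 5,
                 dimnames = list(network_labels(), network_labels()))
  rep <- compute_metrics(conf)
  total <- sum(conf)
  expect_equal(rep$overall_accuracy, sum(diag(conf)) / total)
  for (li in 1:5) {
    tp <- conf[li, li]
    fn <- sum(conf[li, -li])
    fp <- sum(conf[-li, li])
    tn <- total - tp - fn - fp
    expect_equal(rep$sensitivity[[li]], tp / (tp + fn))
    expect_equal(rep$specificity[[li]], tn / (tn + fp))
    expect_equal(rep$ppv[[li]], tp / (tp + fp))
    expect_equal(rep$npv[[li]], tn / (tn + fn))
    expect_equal(rep$per_class_accuracy[[li]], tp / sum(conf[li, ]))
  }
})

test_that("diagonal matrices score 1 and empty rows report NA, not 0", {
  ident <- diag(c(3, 5, 2, 7, 1))
  dimnames(ident) <- list(network_labels(), network_labels())
  rep <- compute_metrics(ident)
  expect_equal(rep$overall_accuracy, 1)
  expect_true(all(rep$per_class_accuracy == 1))
  empty_row <- ident; empty_row[2, ] <- 0
  rep2 <- compute_metrics(empty_row)
  expect_true(is.na(rep2$per_class_accuracy[["visual"]]))
  expect_false(anyNA(rep2$per_class_accuracy[-2]))
  expect_error(compute_metrics(matrix(1, 2, 3)), "square")
})

test_that("the binomial tail matches the closed form and pbinom", {
  expect_identical(binomial_p(0, 10), 1)
  expect_equal(binomial_p(5, 5, 0.2), 0.2^5, tolerance = 1e-12)
  set.seed(71)
  for (i in 1:20) {
    total <- sample(5:300, 1)
    correct <- sample(0:total, 1)
    chance <- runif(1, 0.05, 0.9)
    expect_equal(binomial_p(correct, total, chance),
                 pbinom(correct - 1, total, chance, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  expect_error(binomial_p(6, 5), "correct")
  expect_error(binomial_p(1, 5, 0), "chance")
})

test_that("averaging over viewers is the arithmetic mean where defined", {
  r1 <- compute_metrics(viewer1_confusion())
  r2 <- compute_metrics(viewer2_confusion())
  avg <- average_over_viewers(list(r1, r2))
  expect_equal(avg$overall_accuracy,
               (r1$overall_accuracy + r2$overall_accuracy) / 2)
  expect_equal(avg$per_class_accuracy[["visual"]], 1)
  expect_identical(avg$viewer_id, "averaged")
  # confusion matrices carried separately, never summed
  expect_length(avg$confusion, 2L)
  # averaging identical reports is the identity
  same <- average_over_viewers(list(r1, r1))
  expect_equal(same$overall_accuracy, r1$overall_accuracy)
  expect_error(average_over_viewers(list()), "no reports")
})

test_that("LOOCV has one fold per subject with no leakage", {
  ds <- make_labeled_dataset(n_subjects = 2)
  folds <- rsnlabel:::loocv_folds(ds)
  expect_length(folds, 2L)
  for (f in folds) {
    expect_false(f$test_subject %in% f$train_subjects)
    expect_setequal(c(f$test_subject, f$train_subjects), ds$subjects)
  }
  rep <- loocv_evaluate(ds, "naive_bayes", R = 4, viewer_id = "viewer1")
  expect_identical(rep$n_components, length(ds$components))
  expect_identical(nrow(rep$predictions), length(ds$components))
  # every component predicted exactly once
  expect_false(anyDuplicated(paste(rep$predictions$subject,
                                   rep$predictions$component)) > 0)
})

test_that("perfectly archetypal components are classified perfectly", {
  cfg <- small_config(n_subjects = 3, noise_sd = 0, jitter_mm = 0)
  ds <- make_dataset(cfg)
  arch <- make_archetypes(cfg)
  rep <- suppressMessages(
    loocv_evaluate(ds, "correlation", viewer_id = "viewer1",
                   templates = arch))
  expect_equal(rep$overall_accuracy, 1)
})

test_that("subjects without the viewer's labels are skipped with warning", {
  ds <- make_labeled_dataset(n_subjects = 3)
  # strip one subject's labels
  drop <- ds$subjects[2]
  ds$components <- lapply(ds$components, function(cm) {
    if (cm$subject_id == drop) cm$viewer_labels <- character()
    cm
  })
  expect_warning(
    rep <- loocv_evaluate(ds, "naive_bayes", R = 4,
                          viewer_id = "viewer1"),
    "skipped")
  expect_lt(rep$n_components, 3 * 8)
})

test_that("tune_R returns the argmax with smallest-R tie-break", {
  expect_identical(pick_best_R(5:8, c(0.5, 0.9, 0.9, 0.7)), 6L)
  expect_identical(pick_best_R(c(8L, 5L, 6L), c(0.9, 0.9, 0.9)), 5L)
  expect_identical(pick_best_R(7L, 0.3), 7L)
  # inserting a strictly better R never returns a worse one
  set.seed(81)
  for (i in 1:20) {
    grid <- sort(sample(2:30, 6))
    acc <- runif(6)
    base <- pick_best_R(grid, acc)
    newR <- max(grid) + 1L
    expect_identical(pick_best_R(c(grid, newR), c(acc, max(acc) + 0.05)),
                     newR)
    expect_identical(pick_best_R(c(grid, newR), c(acc, 0)), base)
  }

  # a flat curve on a separable dataset returns the smallest R
  cfg <- small_config(n_subjects = 3, noise_sd = 0, jitter_mm = 0)
  ds <- make_dataset(cfg)
  tr <- tune_R(ds, "naive_bayes", R_grid = c(4L, 5L), viewer_id = "viewer1")
  expect_true(all(tr$curve$accuracy == tr$curve$accuracy[1]))
  expect_identical(tr$best_R, 4L)
  # a single-point grid returns that point
  expect_identical(tune_R(ds, "naive_bayes", R_grid = 5L,
                          viewer_id = "viewer1")$best_R, 5L)
  expect_error(tune_R(ds, "naive_bayes", R_grid = integer()), "empty")
  expect_error(tune_R(ds, "correlation", R_grid = 4L), "resize")
})
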