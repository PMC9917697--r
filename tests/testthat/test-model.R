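test_that("encoding maps lesions to the declared coordinates", {
  normal <- fixture_patient_table(n = 1, seed = 1)
  normal[1, c("prolapse_p1", "prolapse_p2", "prolapse_p3",
              "prolapse_a1", "prolapse_a2", "prolapse_a3",
              "prolapse_anterolateral_commissure",
              "prolapse_posteromedial_commissure", "ruptured_chordae",
              "calc_leaflet", "calc_annulus", "calc_chordae",
              "commissure_fusion")] <- FALSE
  normal$leaflet_morphology <- "normal"
  normal$leaflet_motion <- "normal"
  normal$vegetation_class <- 0L
  normal$perforation_cleft_class <- 0L
  m <- encode_features(normal)
  expect_true(all(m == 0))
  expect_identical(attr(m, "encoding_version"), "1")

  case <- normal
  case$leaflet_motion <- "restriction"
  case$calc_leaflet <- TRUE
  case$perforation_cleft_class <- 1L
  mc <- encode_features(case)
  nonzero <- colnames(mc)[mc[1, ] != 0]
  expect_setequal(nonzero, c("leaflet_motion", "calc_leaflet",
                             "perforation_cleft_class"))
  expect_equal(unname(mc[1, "leaflet_motion"]), 2)
  expect_equal(unname(mc[1, "calc_leaflet"]), 1)
  expect_equal(unname(mc[1, "perforation_cleft_class"]), 1)
})

test_that("demographics and diagnosis never enter the feature vector", {
  a <- fixture_patient_table(n = 4, seed = 8)
  b <- a
  b$age <- b$age + 25
  b$sex <- rev(b$sex)
  b$diagnosis <- "barlows_syndrome"
  expect_identical(encode_features(a), encode_features(b))
  expect_false(any(c("age", "sex", "diagnosis") %in%
                     colnames(encode_features(a))))
})

test_that("unknown categories are rejected naming field and value", {
  tbl <- fixture_patient_table(n = 2, seed = 8)
  tbl$leaflet_morphology[1] <- "thickened"
  expect_error(encode_features(tbl), "thickened")
  expect_error(encode_features(tbl), "leaflet_morphology")
})

test_that("seeded folds are near-equal partitions", {
  f143 <- kfold_split(143, 3, seed = 0)
  expect_identical(sort(as.integer(table(f143)), decreasing = TRUE),
                   c(48L, 48L, 47L))
  expect_identical(as.integer(table(kfold_split(6, 3, seed = 1))),
                   c(2L, 2L, 2L))
  expect_identical(sort(as.integer(table(kfold_split(7, 3, seed = 1))),
                        decreasing = TRUE),
                   c(3L, 2L, 2L))
  expect_identical(kfold_split(143, 3, seed = 0), f143)
  expect_false(identical(kfold_split(143, 3, seed = 1), f143))
  expect_true(all(kfold_split(50, 5, seed = 2) %in% 1:5))
  expect_error(kfold_split(4, 5, seed = 0), "2 <= k <= n")
  strat <- kfold_split(30, 3, seed = 0, labels = rep(c(0, 1), c(24, 6)))
  for (f in 1:3) expect_identical(sum(strat[25:30] == f), 2L)
})

test_that("accuracy is the correct-classification fraction", {
  cm <- matrix(c(20, 3, 5, 20), 2, 2)  # rows true, cols predicted
  expect_equal(accuracy(cm), 40 / 48)
  expect_equal(accuracy(matrix(c(7, 0, 0, 9), 2, 2)), 1)
  set.seed(17)
  for (i in 1:20) {
    truth <- rbinom(30, 1, 0.5)
    pred <- rbinom(30, 1, 0.5)
    cm <- table(factor(truth, 0:1), factor(pred, 0:1))
    expect_equal(accuracy(matrix(as.numeric(cm), 2, 2)),
                 mean(truth == pred))
  }
  expect_error(accuracy(matrix(0, 2, 2)), "no observations")
  expect_error(accuracy(matrix(1, 3, 3)), "2x2")
})

test_that("importance aggregation superposes and ranks stably", {
  v <- c(leaflet_motion = 60, calc_leaflet = 30, prolapse_p2 = 10)
  same <- aggregate_importance(list(v, v, v))
  expect_equal(same$importance, unname(v))
  expect_identical(same$feature, names(v))
  onehot <- aggregate_importance(list(c(a = 100, b = 0, c = 0),
                                      c(a = 0, b = 100, c = 0),
                                      c(a = 0, b = 0, c = 100)))
  expect_equal(onehot$importance, rep(100 / 3, 3))
  expect_identical(onehot$feature, c("a", "b", "c"))  # tie keeps input order
  # superposing the three published per-fold leaders keeps restricted
  # leaflet motion ranked first overall
  folds <- list(
    c(leaflet_motion = 42.04, calc_leaflet = 23.0, redundancy = 8.94,
      perforation_cleft = 0, prolapse_p3 = 0),
    c(leaflet_motion = 45.42, calc_leaflet = 0, redundancy = 0,
      perforation_cleft = 10.99, prolapse_p3 = 10.54),
    c(leaflet_motion = 50.42, calc_leaflet = 9.66, redundancy = 0,
      perforation_cleft = 8.39, prolapse_p3 = 0)
  )
  agg <- aggregate_importance(folds)
  expect_identical(agg$feature[1], "leaflet_motion")
  expect_equal(sum(agg$importance), 100)
  expect_error(aggregate_importance(list(c(a = 1), c(a = 1, b = 2))),
               "same length")
  expect_error(aggregate_importance(list(c(a = -1, b = 2))), "non-negative")
})

test_that("a feature-representable separable rule is learned exactly", {
  co <- generate_cohort(n_patients = 200, seed = 3)
  co$approach <- ifelse(co$leaflet_motion == "restriction",
                        "replacement", "repair")
  cv <- train_eval(co, model_config(seed = 0))
  expect_equal(cv$mean_accuracy, 1)
  expect_equal(cv$fold_accuracy, rep(1, 3))
})

test_that("a score-thresholded cohort is classified with high accuracy", {
  co <- generate_cohort(n_patients = 300, seed = 2)
  co$approach <- ifelse(co$complexity_score > 8.5, "replacement", "repair")
  cv <- train_eval(co, model_config(seed = 0))
  expect_gt(cv$mean_accuracy, 0.8)
})

test_that("cross-validation bookkeeping is internally consistent", {
  co <- generate_cohort(n_patients = 143, seed = 0)
  cv <- train_eval(co, model_config(seed = 0))
  sizes <- as.integer(table(cv$fold_assignment))
  expect_identical(sort(sizes, decreasing = TRUE), c(48L, 48L, 47L))
  for (f in 1:3) {
    expect_equal(sum(cv$confusion[[f]]), sizes[f])
    expect_equal(cv$fold_accuracy[f], accuracy(cv$confusion[[f]]))
    imp <- cv$importance[, f]
    expect_true(all(imp >= 0))
    expect_equal(sum(imp), 100, tolerance = 1e-6)
  }
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracy))
  pooled <- sum(vapply(cv$confusion, function(m) sum(diag(m)), numeric(1)))
  expect_equal(cv$pooled_accuracy, pooled / 143)
  expect_equal(sum(cv$aggregate_importance$importance), 100,
               tolerance = 1e-6)
  # deterministic under a fixed seed
  cv2 <- train_eval(co, model_config(seed = 0))
  expect_equal(cv, cv2)
})

test_that("a single-class training split is reported, not swallowed", {
  co <- generate_cohort(n_patients = 30, seed = 6)
  co$approach <- c("replacement", rep("repair", 29))
  expect_error(train_eval(co, model_config(seed = 0)), "single class")
})

test_that("the cutoff baseline scores held-out folds with trained cutoffs", {
  co <- generate_cohort(n_patients = 200, seed = 12)
  bl <- cutoff_classifier_cv(co, k_folds = 3, seed = 0)
  expect_length(bl$fold_accuracy, 3)
  expect_equal(bl$mean_accuracy, mean(bl$fold_accuracy))
  # recount fold 1 by hand
  fold <- bl$fold_assignment
  tr <- fold != 1
  cut <- youden_cutoff(
    roc_curve(co$complexity_score[tr],
              co$approach[tr] == "replacement"))$cutoff
  expect_equal(bl$cutoffs[1], cut)
  pred <- co$complexity_score[!tr] > cut
  expect_equal(bl$fold_accuracy[1],
               mean(pred == (co$approach[!tr] == "replacement")))
})
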