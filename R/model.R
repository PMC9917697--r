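#' Gradient boosting configuration
#'
#' Hyperparameters of the surgical-approach classifier. The defaults are the
#' reference settings: 15 base classifiers (boosting rounds), learning rate
#' 0.3, maximum tree depth 2, 3-fold cross-validation, seed 0. All remaining
#' boosting hyperparameters stay at the xgboost library defaults.
#'
#' @param n_base_classifiers boosting rounds; at least 1.
#' @param learning_rate shrinkage in (0, 1].
#' @param max_tree_depth maximum depth of each tree; at least 1.
#' @param k_folds number of cross-validation folds; at least 2.
#' @param seed integer seed for fold assignment and training.
#' @param importance_measure xgboost importance metric to aggregate:
#'   `"Gain"` (default), `"Cover"` or `"Frequency"`.
#' @param stratified logical; if `TRUE`, folds are drawn within each class
#'   separately. Default `FALSE` (simple random folds).
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_base_classifiers = 15, learning_rate = 0.3,
                         max_tree_depth = 2, k_folds = 3, seed = 0,
                         importance_measure = c("Gain", "Cover", "Frequency"),
                         stratified = FALSE) {
  importance_measure <- match.arg(importance_measure)
  stopifnot(n_base_classifiers >= 1, learning_rate > 0, learning_rate <= 1,
            max_tree_depth >= 1, k_folds >= 2)
  structure(list(
    n_base_classifiers = as.integer(n_base_classifiers),
    learning_rate = learning_rate,
    max_tree_depth = as.integer(max_tree_depth),
    k_folds = as.integer(k_folds),
    seed = as.integer(seed),
    importance_measure = importance_measure,
    stratified = isTRUE(stratified)
  ), class = "model_config")
}

# Versioned encoding map: feature column -> numeric coding. Ordinal levels
# follow clinical severity. Version bumps whenever order or coding changes.
.mv_encoding_version <- "1"
.mv_encoded_features <- c(
  # effective variables
  "ruptured_chordae", "leaflet_morphology", "leaflet_motion",
  "vegetation_class", "perforation_cleft_class",
  "calc_annulus", "calc_leaflet", "calc_chordae", "commissure_fusion",
  # uncertain variables: the 8 prolapse indicators
  "prolapse_p1", "prolapse_p2", "prolapse_p3",
  "prolapse_a1", "prolapse_a2", "prolapse_a3",
  "prolapse_anterolateral_commissure", "prolapse_posteromedial_commissure"
)

#' Encode patients as a numeric feature matrix
#'
#' Maps patient records to the fixed-order numeric matrix consumed by the
#' classifier. Effective variables (chordal rupture, morphology, motion,
#' vegetation and perforation/cleft classes, the four
#' calcification/fusion indicators) and uncertain variables (the 8 prolapse
#' indicators) enter the matrix; demographics and diagnosis (sex, age,
#' etiology) are ineffective variables and are never encoded. Binary flags
#' are 0/1; `leaflet_morphology` is ordinal normal=0, thickening=1,
#' redundant=2; `leaflet_motion` is ordinal normal=0, excessive=1,
#' restriction=2; count classes keep their 0/1/2 coding. The encoding map is
#' versioned via the `encoding_version` attribute.
#'
#' @param patients data frame with the [echo_features()] columns.
#' @return A numeric matrix, one row per patient, with an
#'   `encoding_version` attribute.
#' @export
encode_features <- function(patients) {
  stopifnot(is.data.frame(patients))
  missing_cols <- setdiff(.mv_feature_fields, names(patients))
  if (length(missing_cols)) {
    stop("missing required feature columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  code_ord <- function(x, levels, field) {
    bad <- !x %in% levels
    if (any(bad)) {
      stop("unknown value '", x[bad][1], "' in field '", field, "'",
           call. = FALSE)
    }
    as.numeric(match(x, levels) - 1L)
  }
  code_flag <- function(x, field) {
    if (!is.logical(x) || any(is.na(x))) {
      stop("field '", field, "' must be non-missing logical", call. = FALSE)
    }
    as.numeric(x)
  }
  code_class <- function(x, field) {
    if (any(is.na(x)) || !all(x %in% c(0, 1, 2))) {
      stop("field '", field, "' must be 0, 1 or 2", call. = FALSE)
    }
    as.numeric(x)
  }
  n <- nrow(patients)
  m <- matrix(NA_real_, nrow = n, ncol = length(.mv_encoded_features),
              dimnames = list(NULL, .mv_encoded_features))
  for (fn in .mv_encoded_features) {
    m[, fn] <- switch(
      fn,
      leaflet_morphology = code_ord(as.character(patients[[fn]]),
                                    .mv_morphology_levels, fn),
      leaflet_motion = code_ord(as.character(patients[[fn]]),
                                .mv_motion_levels, fn),
      vegetation_class = ,
      perforation_cleft_class = code_class(patients[[fn]], fn),
      code_flag(patients[[fn]], fn)
    )
  }
  attr(m, "encoding_version") <- .mv_encoding_version
  m
}

#' Seeded k-fold assignment
#'
#' Partitions `n` cases into `k` near-equal folds by a seeded random
#' permutation: the shuffled indices are cut into consecutive blocks, the
#' first `n mod k` blocks holding one extra case, so fold sizes differ by at
#' most one (143 cases in 3 folds give sizes 48, 48, 47).
#'
#' @param n number of cases.
#' @param k number of folds, between 2 and `n`.
#' @param seed integer seed.
#' @param labels optional vector of class labels; when supplied, folds are
#'   drawn within each class (stratified splitting).
#' @return Integer vector of length `n` with fold ids in `1:k`.
#' @examples
#' table(kfold_split(143, 3, seed = 0))
#' @export
kfold_split <- function(n, k, seed = 0, labels = NULL) {
  stopifnot(is.numeric(n), is.numeric(k))
  if (k < 2 || k > n) {
    stop("k must satisfy 2 <= k <= n (got k = ", k, ", n = ", n, ")",
         call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  assign_block <- function(m) {
    sizes <- rep(m %/% k, k) + c(rep(1L, m %% k), rep(0L, k - m %% k))
    rep(seq_len(k), sizes)
  }
  fold <- integer(n)
  if (is.null(labels)) {
    fold[sample.int(n)] <- assign_block(n)
  } else {
    stopifnot(length(labels) == n)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx[sample.int(length(idx))]] <- assign_block(length(idx))
    }
  }
  fold
}

#' Accuracy of a confusion matrix
#'
#' `(TP + TN) / (TP + FN + FP + TN)`: the fraction of correctly classified
#' cases in a 2x2 confusion matrix (rows = true class, columns = predicted).
#'
#' @param cm a 2x2 numeric matrix with non-negative entries and positive sum.
#' @return A number in \eqn{[0, 1]}.
#' @examples
#' accuracy(matrix(c(20, 5, 3, 20), 2, 2))
#' @export
accuracy <- function(cm) {
  cm <- as.matrix(cm)
  if (!all(dim(cm) == c(2L, 2L)) || any(cm < 0) || any(is.na(cm))) {
    stop("cm must be a 2x2 matrix of non-negative counts", call. = FALSE)
  }
  if (sum(cm) == 0) {
    stop("confusion matrix has no observations", call. = FALSE)
  }
  sum(diag(cm)) / sum(cm)
}

#' Cross-validated gradient-boosted classifier of surgical approach
#'
#' Trains a gradient-boosted tree classifier (xgboost, binary logistic
#' objective) of repair vs. replacement on the encoded echocardiographic
#' features under seeded k-fold cross-validation: each fold serves once as
#' the test set while the remaining folds train the model. Reports per-fold
#' confusion matrices, accuracies, the unweighted mean of fold accuracies
#' (with the pooled-prediction accuracy alongside), and per-fold and
#' aggregated feature importance.
#'
#' @param cohort data frame with the [echo_features()] columns and an
#'   `approach` column (`"repair"`/`"replacement"`).
#' @param config a [model_config()].
#' @return An object of class `cv_result`: list with `fold_assignment`,
#'   `confusion` (list of 2x2 matrices, rows = true, cols = predicted),
#'   `fold_accuracy`, `mean_accuracy`, `pooled_accuracy`, `importance`
#'   (per-fold percentage matrix, features x folds), `aggregate_importance`
#'   (ranked data frame from [aggregate_importance()]), `predictions`
#'   (per-patient predicted class), and `config`.
#' @export
train_eval <- function(cohort, config = model_config()) {
  stopifnot(is.data.frame(cohort))
  if (!"approach" %in% names(cohort)) {
    stop("cohort must have an 'approach' column", call. = FALSE)
  }
  x <- encode_features(cohort)
  y <- .coerce_labels(cohort$approach, positive = "replacement")
  n <- nrow(x)
  k <- config$k_folds
  fold <- kfold_split(n, k, seed = config$seed,
                      labels = if (config$stratified) y else NULL)

  classes <- c("repair", "replacement")
  conf <- vector("list", k)
  acc <- numeric(k)
  imp <- matrix(0, nrow = ncol(x), ncol = k,
                dimnames = list(colnames(x), paste0("fold", seq_len(k))))
  pred_class <- character(n)

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })

  for (f in seq_len(k)) {
    tr <- fold != f
    te <- !tr
    if (length(unique(y[tr])) < 2L) {
      stop("training split for fold ", f, " contains a single class; ",
           "re-seed the fold assignment or enlarge the cohort",
           call. = FALSE)
    }
    set.seed(config$seed + f)
    booster <- xgboost::xgb.train(
      params = xgboost::xgb.params(
        objective = "binary:logistic",
        learning_rate = config$learning_rate,
        max_depth = config$max_tree_depth,
        nthread = 1L,
        seed = config$seed + f
      ),
      data = xgboost::xgb.DMatrix(x[tr, , drop = FALSE], label = y[tr],
                                  nthread = 1L),
      nrounds = config$n_base_classifiers,
      verbose = 0
    )
    p <- stats::predict(booster,
                        xgboost::xgb.DMatrix(x[te, , drop = FALSE],
                                             nthread = 1L))
    yhat <- as.integer(p > 0.5)
    pred_class[te] <- classes[yhat + 1L]
    cm <- table(factor(classes[y[te] + 1L], levels = classes),
                factor(classes[yhat + 1L], levels = classes))
    cm <- matrix(as.numeric(cm), 2, 2,
                 dimnames = list(true = classes, predicted = classes))
    conf[[f]] <- cm
    acc[f] <- accuracy(cm)
    it <- xgboost::xgb.importance(model = booster)
    if (nrow(it)) {
      v <- it[[config$importance_measure]]
      imp[it$Feature, f] <- 100 * v / sum(v)
    }
  }

  out <- list(
    fold_assignment = fold,
    confusion = conf,
    fold_accuracy = acc,
    mean_accuracy = mean(acc),
    pooled_accuracy = mean(pred_class == classes[y + 1L]),
    importance = imp,
    aggregate_importance = aggregate_importance(
      lapply(seq_len(k), function(f) imp[, f])),
    predictions = pred_class,
    config = config
  )
  class(out) <- "cv_result"
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated boosted classifier (%d rounds, ",
              x$config$k_folds, x$config$n_base_classifiers))
  cat(sprintf("eta %.2f, depth %d, seed %d)\n", x$config$learning_rate,
              x$config$max_tree_depth, x$config$seed))
  cat("fold accuracies:", paste(sprintf("%.3f", x$fold_accuracy),
                                collapse = ", "), "\n")
  cat(sprintf("mean accuracy: %.4f (pooled: %.4f)\n",
              x$mean_accuracy, x$pooled_accuracy))
  cat("top features by aggregate importance:\n")
  top <- utils::head(x$aggregate_importance, 5)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %-35s %6.2f%%\n", top$feature[i], top$importance[i]))
  }
  invisible(x)
}

#' Aggregate per-fold feature importances
#'
#' Superposes importance vectors from the cross-validation folds: elementwise
#' sum, renormalized to percentages. The ranking is a stable descending sort;
#' ties keep the declared feature (input) order.
#'
#' @param per_fold list of equal-length named non-negative numeric vectors.
#' @return Data frame with `feature` and `importance` (percent, summing to
#'   100), in descending order of importance.
#' @examples
#' aggregate_importance(list(c(a = 50, b = 50), c(a = 100, b = 0)))
#' @export
aggregate_importance <- function(per_fold) {
  stopifnot(is.list(per_fold), length(per_fold) >= 1L)
  len <- unique(vapply(per_fold, length, integer(1)))
  if (length(len) != 1L) {
    stop("importance vectors must all have the same length", call. = FALSE)
  }
  for (v in per_fold) {
    if (any(v < 0) || any(is.na(v))) {
      stop("importance vectors must be non-negative and non-missing",
           call. = FALSE)
    }
  }
  total <- Reduce(`+`, per_fold)
  if (sum(total) > 0) total <- 100 * total / sum(total)
  nm <- names(total)
  if (is.null(nm)) nm <- paste0("f", seq_along(total))
  o <- order(-total)  # stable: ties keep input order
  data.frame(feature = nm[o], importance = unname(total[o]),
             stringsAsFactors = FALSE)
}

#' Cross-validated single-cutoff score classifier
#'
#' Baseline against which the boosted model is compared: within each
#' training split the Youden-optimal cutoff of the complexity score is
#' selected, and held-out patients are called replacements when their score
#' exceeds that cutoff. Uses the same fold assignment contract as
#' [train_eval()].
#'
#' @param cohort data frame with `complexity_score` and `approach` columns.
#' @param k_folds,seed fold parameters (matching [model_config()] defaults).
#' @param fold optional precomputed fold assignment (overrides `k_folds`
#'   and `seed`).
#' @return List with `fold_accuracy`, `mean_accuracy`, `cutoffs` (per-fold
#'   training cutoffs), and `fold_assignment`.
#' @export
cutoff_classifier_cv <- function(cohort, k_folds = 3, seed = 0, fold = NULL) {
  stopifnot(is.data.frame(cohort),
            all(c("complexity_score", "approach") %in% names(cohort)))
  scores <- cohort$complexity_score
  y <- .coerce_labels(cohort$approach, positive = "replacement")
  n <- length(y)
  if (is.null(fold)) fold <- kfold_split(n, k_folds, seed = seed)
  k <- max(fold)
  acc <- numeric(k)
  cuts <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    cut <- youden_cutoff(roc_curve(scores[tr], y[tr], positive = 1))$cutoff
    cuts[f] <- cut
    yhat <- as.integer(scores[!tr] > cut)
    acc[f] <- mean(yhat == y[!tr])
  }
  list(fold_accuracy = acc, mean_accuracy = mean(acc), cutoffs = cuts,
       fold_assignment = fold)
}
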