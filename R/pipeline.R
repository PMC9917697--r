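#' Read and validate a patient table
#'
#' Reads a patient CSV (one row per patient) and validates every row against
#' the feature schema: the [echo_features()] columns plus `patient_id`,
#' `sex`, `age`, `diagnosis` and `approach` are required; unknown columns
#' are preserved. Rows that fail validation are collected into a row-indexed
#' error report rather than aborting the read, so a single malformed row
#' never silently drops the rest of the file.
#'
#' @param path path to a CSV file, or a data frame already in memory.
#' @param require_approach logical; require the `approach` column (set
#'   `FALSE` for unlabeled tables to be scored only).
#' @return A list with `records` (data frame of the valid rows, with
#'   logical/integer columns coerced) and `errors` (data frame with `row`,
#'   `field`, `message`; zero rows when the table is clean).
#' @export
validate_table <- function(path, require_approach = TRUE) {
  df <- if (is.data.frame(path)) {
    path
  } else {
    stopifnot(is.character(path), length(path) == 1L)
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  required <- c("patient_id", "sex", "age", "diagnosis", .mv_feature_fields)
  if (require_approach) required <- c(required, "approach")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }

  errors <- list()
  note <- function(row, field, msg) {
    errors[[length(errors) + 1L]] <<- data.frame(
      row = row, field = field, message = msg, stringsAsFactors = FALSE)
  }
  to_flag <- function(x) {
    if (is.logical(x)) return(x)
    if (is.numeric(x)) return(ifelse(x %in% c(0, 1), x == 1, NA))
    lx <- tolower(trimws(as.character(x)))
    ifelse(lx %in% c("true", "t", "yes", "1"), TRUE,
           ifelse(lx %in% c("false", "f", "no", "0"), FALSE, NA))
  }

  ok <- rep(TRUE, nrow(df))
  for (fl in .mv_flag_fields) {
    v <- to_flag(df[[fl]])
    bad <- which(is.na(v))
    for (r in bad) note(r, fl, paste0("not interpretable as a flag: '",
                                      df[[fl]][r], "'"))
    ok[bad] <- FALSE
    df[[fl]] <- v
  }
  for (cl in .mv_class_fields) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) | !(v %in% c(0, 1, 2)))
    for (r in bad) note(r, cl, paste0("must be 0, 1 or 2, got '",
                                      df[[cl]][r], "'"))
    ok[bad] <- FALSE
    df[[cl]] <- as.integer(v)
  }
  morph <- tolower(trimws(as.character(df$leaflet_morphology)))
  bad <- which(!morph %in% .mv_morphology_levels)
  for (r in bad) note(r, "leaflet_morphology",
                      paste0("unknown value '", df$leaflet_morphology[r],
                             "'; expected ",
                             paste(.mv_morphology_levels, collapse = "/")))
  ok[bad] <- FALSE
  df$leaflet_morphology <- morph
  mot <- tolower(trimws(as.character(df$leaflet_motion)))
  bad <- which(!mot %in% .mv_motion_levels)
  for (r in bad) note(r, "leaflet_motion",
                      paste0("unknown value '", df$leaflet_motion[r],
                             "'; expected ",
                             paste(.mv_motion_levels, collapse = "/")))
  ok[bad] <- FALSE
  df$leaflet_motion <- mot
  if (require_approach) {
    app <- tolower(trimws(as.character(df$approach)))
    bad <- which(!app %in% c("repair", "replacement"))
    for (r in bad) note(r, "approach",
                        paste0("unknown value '", df$approach[r],
                               "'; expected repair/replacement"))
    ok[bad] <- FALSE
    df$approach <- app
  }

  list(
    records = df[ok, , drop = FALSE],
    errors = if (length(errors)) {
      do.call(rbind, errors)
    } else {
      data.frame(row = integer(), field = character(),
                 message = character(), stringsAsFactors = FALSE)
    }
  )
}

#' Correlation between complexity and technique scores
#'
#' Correlates the lesion complexity score with the surgical technique score
#' across repaired valves: more complex lesions require more repair
#' maneuvers. Pearson's product-moment r is the default (the conventional
#' "r"); Spearman's rank correlation is available since both scores are
#' ordinal.
#'
#' @param complexity,technique equal-length numeric vectors (length >= 3),
#'   each with nonzero variance.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A list with `r`, `p` (two-sided), `n` and `method`.
#' @examples
#' correlate_scores(c(3, 7, 9, 8), c(2, 5, 5, 4))
#' @export
correlate_scores <- function(complexity, technique,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  keep <- stats::complete.cases(complexity, technique)
  x <- complexity[keep]
  y <- technique[keep]
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need at least 3 complete score pairs", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("cannot correlate a zero-variance score vector", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       method = method)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on one cohort: simulate (or load), score, summarise,
#' ROC analysis of the complexity score, cross-validated boosted classifier
#' with the single-cutoff baseline, and the complexity-vs-technique
#' correlation. A manifest records the configuration, seeds and stage list
#' so that every reported number is regenerable.
#'
#' @param cohort optional patient table (data frame or CSV path, validated
#'   via [validate_table()]); when `NULL`, a synthetic cohort is generated.
#' @param cohort_config configuration for the simulator (ignored when
#'   `cohort` is given).
#' @param model_cfg a [model_config()].
#' @param n_patients,seed overrides for the simulator.
#' @param n_boot bootstrap replicates for the AUC interval.
#' @return An object of class `mv_report`: list with `cohort`, `summary`,
#'   `roc`, `cv`, `cutoff_baseline`, `correlation` (`NULL` when no
#'   technique scores are available) and `manifest`.
#' @examples
#' \donttest{
#' rep <- run_pipeline(n_patients = 143, seed = 0, n_boot = 200)
#' rep$summary$stratum_counts
#' }
#' @export
run_pipeline <- function(cohort = NULL,
                         cohort_config = default_cohort_config(),
                         model_cfg = model_config(),
                         n_patients = NULL, seed = NULL, n_boot = 2000) {
  stages <- character()
  if (is.null(cohort)) {
    cohort <- generate_cohort(cohort_config, n_patients = n_patients,
                              seed = seed)
    stages <- c(stages, "simulate")
  } else {
    v <- validate_table(cohort)
    if (nrow(v$errors)) {
      stop("input table failed validation (", nrow(v$errors),
           " problem rows); see validate_table()", call. = FALSE)
    }
    cohort <- score_cohort(v$records)
    stages <- c(stages, "validate", "score")
  }
  summary <- cohort_summary(cohort)
  stages <- c(stages, "summarise")

  roc_seed <- if (!is.null(seed)) seed else cohort_config$seed
  roc <- roc_analysis(cohort, n_boot = n_boot, seed = roc_seed)
  stages <- c(stages, "roc")

  cv <- train_eval(cohort, model_cfg)
  baseline <- cutoff_classifier_cv(cohort, fold = cv$fold_assignment)
  stages <- c(stages, "evaluate")

  correlation <- NULL
  if ("technique_score" %in% names(cohort) &&
      sum(!is.na(cohort$technique_score)) >= 3) {
    correlation <- correlate_scores(cohort$complexity_score,
                                    cohort$technique_score)
    stages <- c(stages, "correlate")
  }

  manifest <- list(
    tool = "mvscore",
    version = as.character(utils::packageVersion("mvscore")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    n_patients = nrow(cohort),
    seed = roc_seed,
    model_config = unclass(model_cfg),
    outcome_link = as.list(cohort_config$outcome_link),
    n_boot = n_boot,
    stages = stages
  )
  out <- list(cohort = cohort, summary = summary, roc = roc, cv = cv,
              cutoff_baseline = baseline, correlation = correlation,
              manifest = manifest)
  class(out) <- "mv_report"
  out
}

#' @export
print.mv_report <- function(x, ...) {
  cat("== mvscore analysis report ==\n\n")
  print(x$summary)
  cat(sprintf("\nComplexity-score ROC: AUC %.3f (95%% CI %.3f-%.3f), ",
              x$roc$auc, x$roc$auc_ci[["low"]], x$roc$auc_ci[["high"]]))
  cat(sprintf("Youden cutoff %.1f (sens %.2f, spec %.2f)\n",
              x$roc$cutoff$cutoff, x$roc$cutoff$sensitivity,
              x$roc$cutoff$specificity))
  cat(sprintf("\nBoosted classifier mean accuracy: %.4f ",
              x$cv$mean_accuracy))
  cat(sprintf("(single-cutoff baseline: %.4f)\n",
              x$cutoff_baseline$mean_accuracy))
  if (!is.null(x$correlation)) {
    cat(sprintf("Complexity vs technique score: r = %.4f (p = %.2g, n = %d)\n",
                x$correlation$r, x$correlation$p, x$correlation$n))
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Serializes an `mv_report` under a run directory: `cohort.csv` (the scored
#' table), `report.json` (summary tables, ROC results, cross-validation
#' results, correlation, manifest) and `manifest.json`.
#'
#' @param report an `mv_report` from [run_pipeline()].
#' @param dir output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mv_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    cohort = file.path(dir, "cohort.csv"),
    report = file.path(dir, "report.json"),
    manifest = file.path(dir, "manifest.json")
  )
  utils::write.csv(report$cohort, paths[["cohort"]], row.names = FALSE)
  payload <- list(
    stratum_counts = report$summary$stratum_counts,
    etiology_by_stratum = as.data.frame.matrix(
      report$summary$etiology_by_stratum),
    approach_by_stratum = as.data.frame.matrix(
      report$summary$approach_by_stratum),
    roc = list(
      auc = report$roc$auc,
      auc_ci = as.list(report$roc$auc_ci),
      cutoff = report$roc$cutoff,
      curve = data.frame(threshold = report$roc$roc$thresholds,
                         sensitivity = report$roc$roc$sensitivity,
                         one_minus_specificity = report$roc$roc$fpr)
    ),
    cv = list(
      fold_accuracy = report$cv$fold_accuracy,
      mean_accuracy = report$cv$mean_accuracy,
      pooled_accuracy = report$cv$pooled_accuracy,
      confusion = lapply(report$cv$confusion, function(m) {
        as.data.frame.matrix(as.table(m))
      }),
      aggregate_importance = report$cv$aggregate_importance
    ),
    cutoff_baseline = report$cutoff_baseline[c("fold_accuracy",
                                               "mean_accuracy", "cutoffs")],
    correlation = report$correlation,
    manifest = report$manifest
  )
  jsonlite::write_json(payload, paths[["report"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(report$manifest, paths[["manifest"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
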