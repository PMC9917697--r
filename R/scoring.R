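#' Lesion complexity score with component breakdown
#'
#' Computes the weighted lesion complexity score of one patient: the sum of
#' the weights of the echocardiographic lesions present in the profile
#' (see [default_weights()] for the weight table). The returned breakdown
#' lists the contribution of every scoring category so that the total is
#' auditable; zero contributions are dropped.
#'
#' Leaflet motion is scored once per patient: a profile reporting restriction
#' scores 2 regardless of how many segments are involved, and hypermobility
#' scores 1. With `pooled_lesion_variant = TRUE` in the weight table,
#' vegetation and perforation/cleft are pooled: one such lesion of either
#' kind scores 1 and more than one scores 4 in a single
#' `vegetation_perforation_cleft` component.
#'
#' @param features an [echo_features()] profile.
#' @param weights an `mv_weights` table; defaults to [default_weights()].
#' @return An object of class `complexity_breakdown`: a list with
#'   `contributions` (named integer vector over the nonzero scoring
#'   categories) and `total` (non-negative integer).
#' @examples
#' # A1 prolapse plus one cleft: 2 + 1 = 3, the simple stratum
#' complexity_score(echo_features(prolapse_a1 = TRUE,
#'                                perforation_cleft_class = 1))
#' @export
complexity_score <- function(features, weights = default_weights()) {
  if (!inherits(features, "echo_features")) {
    features <- do.call(echo_features, as.list(features)[.mv_feature_fields])
  } else {
    validate_features(features)
  }
  validate_weights(weights)
  f <- features
  w <- weights

  contrib <- c(
    prolapse_p1 = if (f$prolapse_p1) w$prolapse[["p1"]] else 0L,
    prolapse_p2 = if (f$prolapse_p2) w$prolapse[["p2"]] else 0L,
    prolapse_p3 = if (f$prolapse_p3) w$prolapse[["p3"]] else 0L,
    prolapse_a1 = if (f$prolapse_a1) w$prolapse[["a1"]] else 0L,
    prolapse_a2 = if (f$prolapse_a2) w$prolapse[["a2"]] else 0L,
    prolapse_a3 = if (f$prolapse_a3) w$prolapse[["a3"]] else 0L,
    prolapse_anterolateral_commissure =
      if (f$prolapse_anterolateral_commissure)
        w$prolapse[["anterolateral_commissure"]] else 0L,
    prolapse_posteromedial_commissure =
      if (f$prolapse_posteromedial_commissure)
        w$prolapse[["posteromedial_commissure"]] else 0L,
    ruptured_chordae = if (f$ruptured_chordae) w$ruptured_chordae else 0L,
    leaflet_morphology = w$morphology[[f$leaflet_morphology]],
    calc_leaflet = if (f$calc_leaflet) w$calcification[["leaflet"]] else 0L,
    calc_annulus = if (f$calc_annulus) w$calcification[["annulus"]] else 0L,
    calc_chordae = if (f$calc_chordae) w$calcification[["chordae"]] else 0L,
    commissure_fusion = if (f$commissure_fusion) w$commissure_fusion else 0L,
    leaflet_motion = w$motion[[f$leaflet_motion]]
  )

  if (isTRUE(w$pooled_lesion_variant)) {
    n_lesions <- f$vegetation_class + f$perforation_cleft_class
    pooled <- if (n_lesions == 0) 0L
              else if (n_lesions == 1) 1L
              else w$pooled_multi_weight
    contrib <- c(contrib, vegetation_perforation_cleft = pooled)
  } else {
    contrib <- c(
      contrib,
      vegetation = w$vegetation[[as.character(f$vegetation_class)]],
      perforation_cleft =
        w$perforation_cleft[[as.character(f$perforation_cleft_class)]]
    )
  }

  contrib <- contrib[contrib > 0]
  out <- list(contributions = contrib, total = as.integer(sum(contrib)))
  class(out) <- "complexity_breakdown"
  out
}

#' @export
print.complexity_breakdown <- function(x, ...) {
  cat("Complexity score:", x$total,
      sprintf("(%s stratum)\n", as.character(assign_stratum(x$total))))
  if (length(x$contributions)) {
    for (nm in names(x$contributions)) {
      cat(sprintf("  %-35s %d\n", nm, x$contributions[[nm]]))
    }
  } else {
    cat("  no scored lesions\n")
  }
  invisible(x)
}

#' Complexity stratum of a score
#'
#' Maps complexity scores to the three published strata: simple (score
#' 1--4), intermediate (5--8), complex (9 or more). A score of 0 (no scored
#' lesion) falls below the published range and is mapped to the simple
#' stratum with a warning.
#'
#' @param total integer vector of non-negative complexity scores, or a
#'   `complexity_breakdown`.
#' @return A factor with levels `simple`, `intermediate`, `complex`.
#' @examples
#' assign_stratum(c(3, 8, 9))
#' @export
assign_stratum <- function(total) {
  if (inherits(total, "complexity_breakdown")) total <- total$total
  if (!is.numeric(total) || any(is.na(total))) {
    stop("complexity score must be numeric and non-missing", call. = FALSE)
  }
  if (any(total < 0)) {
    stop("complexity score must be non-negative", call. = FALSE)
  }
  if (any(total == 0)) {
    warning("complexity score 0 is below the defined strata (1-4, 5-8, >=9);",
            " mapping to 'simple'", call. = FALSE)
  }
  factor(
    ifelse(total <= 4, "simple",
           ifelse(total <= 8, "intermediate", "complex")),
    levels = c("simple", "intermediate", "complex")
  )
}

#' Surgical technique score
#'
#' Counts the principal maneuvers used to repair a valve: annuloplasty,
#' chordal replacement (1 per segment resuspended), cleft closure, leaflet
#' resection, vegetation removal, and commissurotomy each contribute their
#' count; a re-repair adds 1 and revision of the annuloplasty ring during a
#' re-repair adds a further 1.
#'
#' @param techniques a [repair_techniques()] record.
#' @param commissurotomy_weight points per commissure incised; default 1 (one
#'   maneuver per commissurotomy), configurable to 2.
#' @return A non-negative integer score.
#' @examples
#' # two chordal segments resuspended plus a ring: 1 x 2 + 1 = 3
#' technique_score(repair_techniques(annuloplasty = TRUE,
#'                                   chordal_segments_resuspended = 2))
#' @export
technique_score <- function(techniques, commissurotomy_weight = 1) {
  if (!inherits(techniques, "repair_techniques")) {
    techniques <- do.call(repair_techniques, as.list(techniques))
  }
  if (!is.numeric(commissurotomy_weight) || commissurotomy_weight < 0) {
    stop("commissurotomy_weight must be non-negative", call. = FALSE)
  }
  t <- techniques
  as.integer(
    as.integer(t$annuloplasty) +
      t$chordal_segments_resuspended +
      t$cleft_closures +
      t$leaflet_resections +
      t$vegetation_removals +
      t$commissurotomies * commissurotomy_weight +
      as.integer(t$re_repair) +
      as.integer(t$ring_revision)
  )
}

#' Score every patient in a table
#'
#' Applies [complexity_score()] and [assign_stratum()] to each row of a
#' patient table (one row per patient, columns named as in
#' [echo_features()]), appending `complexity_score`, `stratum`, and one
#' `score_<component>` column per weight-table category. Existing columns of
#' those names are overwritten; all other columns are preserved.
#'
#' @param patients a data frame with the feature columns.
#' @param weights an `mv_weights` table.
#' @return The input data frame with score columns appended.
#' @export
score_cohort <- function(patients, weights = default_weights()) {
  stopifnot(is.data.frame(patients))
  missing_cols <- setdiff(.mv_feature_fields, names(patients))
  if (length(missing_cols)) {
    stop("missing required feature columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(patients)
  comp_names <- names(breakdown_components(weights))
  comp <- matrix(0L, nrow = n, ncol = length(comp_names),
                 dimnames = list(NULL, comp_names))
  totals <- integer(n)
  for (i in seq_len(n)) {
    b <- complexity_score(as.list(patients[i, .mv_feature_fields,
                                           drop = FALSE]),
                          weights)
    totals[i] <- b$total
    comp[i, names(b$contributions)] <- b$contributions
  }
  patients$complexity_score <- totals
  patients$stratum <- suppressWarnings(as.character(assign_stratum(totals)))
  for (cn in comp_names) patients[[paste0("score_", cn)]] <- comp[, cn]
  patients
}

# All component keys a breakdown can emit under a given weight table.
breakdown_components <- function(weights = default_weights()) {
  base <- c(
    "prolapse_p1", "prolapse_p2", "prolapse_p3",
    "prolapse_a1", "prolapse_a2", "prolapse_a3",
    "prolapse_anterolateral_commissure",
    "prolapse_posteromedial_commissure",
    "ruptured_chordae", "leaflet_morphology",
    "calc_leaflet", "calc_annulus", "calc_chordae",
    "commissure_fusion", "leaflet_motion"
  )
  extra <- if (isTRUE(weights$pooled_lesion_variant)) {
    "vegetation_perforation_cleft"
  } else {
    c("vegetation", "perforation_cleft")
  }
  stats::setNames(rep(0L, length(base) + length(extra)), c(base, extra))
}
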