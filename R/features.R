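#' Echocardiographic lesion profile of one patient
#'
#' Constructs the categorical lesion profile used by the complexity score and
#' the surgical-approach classifier: prolapse flags for the six leaflet
#' segments (Carpentier A1--A3, P1--P3) and the two commissures, chordal
#' rupture, leaflet morphology, calcification sites, commissural fusion,
#' vegetation and perforation/cleft count classes, and leaflet motion.
#'
#' Count classes are coded 0, 1, 2 with 2 meaning "two or more" lesions.
#' All arguments default to the normal/absent state, so a profile lists only
#' the lesions present.
#'
#' @param prolapse_p1,prolapse_p2,prolapse_p3 logical; posterior segment
#'   prolapse.
#' @param prolapse_a1,prolapse_a2,prolapse_a3 logical; anterior segment
#'   prolapse.
#' @param prolapse_anterolateral_commissure,prolapse_posteromedial_commissure
#'   logical; commissural prolapse.
#' @param ruptured_chordae logical; ruptured chordae tendineae present.
#' @param leaflet_morphology one of `"normal"`, `"thickening"`, `"redundant"`.
#' @param calc_leaflet,calc_annulus,calc_chordae logical; calcification of the
#'   leaflet, annulus, or chordae tendineae (additive sites).
#' @param commissure_fusion logical; commissural fusion present.
#' @param vegetation_class integer 0, 1 or 2 (2 = two or more vegetations).
#' @param perforation_cleft_class integer 0, 1 or 2 (2 = two or more
#'   perforations/clefts).
#' @param leaflet_motion one of `"normal"`, `"excessive"`, `"restriction"`.
#' @return An object of class `echo_features` (a named list).
#' @examples
#' # isolated A1 prolapse with a single leaflet cleft
#' echo_features(prolapse_a1 = TRUE, perforation_cleft_class = 1)
#' @export
echo_features <- function(prolapse_p1 = FALSE,
                          prolapse_p2 = FALSE,
                          prolapse_p3 = FALSE,
                          prolapse_a1 = FALSE,
                          prolapse_a2 = FALSE,
                          prolapse_a3 = FALSE,
                          prolapse_anterolateral_commissure = FALSE,
                          prolapse_posteromedial_commissure = FALSE,
                          ruptured_chordae = FALSE,
                          leaflet_morphology = "normal",
                          calc_leaflet = FALSE,
                          calc_annulus = FALSE,
                          calc_chordae = FALSE,
                          commissure_fusion = FALSE,
                          vegetation_class = 0,
                          perforation_cleft_class = 0,
                          leaflet_motion = "normal") {
  f <- list(
    prolapse_p1 = prolapse_p1,
    prolapse_p2 = prolapse_p2,
    prolapse_p3 = prolapse_p3,
    prolapse_a1 = prolapse_a1,
    prolapse_a2 = prolapse_a2,
    prolapse_a3 = prolapse_a3,
    prolapse_anterolateral_commissure = prolapse_anterolateral_commissure,
    prolapse_posteromedial_commissure = prolapse_posteromedial_commissure,
    ruptured_chordae = ruptured_chordae,
    leaflet_morphology = leaflet_morphology,
    calc_leaflet = calc_leaflet,
    calc_annulus = calc_annulus,
    calc_chordae = calc_chordae,
    commissure_fusion = commissure_fusion,
    vegetation_class = vegetation_class,
    perforation_cleft_class = perforation_cleft_class,
    leaflet_motion = leaflet_motion
  )
  validate_features(f)
  class(f) <- "echo_features"
  f
}

# Field groups reused by validation, CSV I/O and the model encoder.
.mv_flag_fields <- c(
  "prolapse_p1", "prolapse_p2", "prolapse_p3",
  "prolapse_a1", "prolapse_a2", "prolapse_a3",
  "prolapse_anterolateral_commissure", "prolapse_posteromedial_commissure",
  "ruptured_chordae",
  "calc_leaflet", "calc_annulus", "calc_chordae",
  "commissure_fusion"
)
.mv_class_fields <- c("vegetation_class", "perforation_cleft_class")
.mv_feature_fields <- c(
  "prolapse_p1", "prolapse_p2", "prolapse_p3",
  "prolapse_a1", "prolapse_a2", "prolapse_a3",
  "prolapse_anterolateral_commissure", "prolapse_posteromedial_commissure",
  "ruptured_chordae", "leaflet_morphology",
  "calc_leaflet", "calc_annulus", "calc_chordae", "commissure_fusion",
  "vegetation_class", "perforation_cleft_class", "leaflet_motion"
)
.mv_morphology_levels <- c("normal", "thickening", "redundant")
.mv_motion_levels <- c("normal", "excessive", "restriction")

validate_features <- function(f) {
  for (fl in .mv_flag_fields) {
    v <- f[[fl]]
    if (length(v) != 1L || is.na(v) || !is.logical(v)) {
      stop("field '", fl, "' must be a single non-missing logical",
           call. = FALSE)
    }
  }
  for (cl in .mv_class_fields) {
    v <- f[[cl]]
    if (length(v) != 1L || is.na(v) || !is.numeric(v) || !v %in% c(0, 1, 2)) {
      stop("field '", cl, "' must be 0, 1 or 2 (2 meaning two or more)",
           call. = FALSE)
    }
  }
  if (length(f$leaflet_morphology) != 1L ||
      !f$leaflet_morphology %in% .mv_morphology_levels) {
    stop("field 'leaflet_morphology' must be one of: ",
         paste(.mv_morphology_levels, collapse = ", "),
         " (got '", paste(f$leaflet_morphology, collapse = ","), "')",
         call. = FALSE)
  }
  if (length(f$leaflet_motion) != 1L ||
      !f$leaflet_motion %in% .mv_motion_levels) {
    stop("field 'leaflet_motion' must be one of: ",
         paste(.mv_motion_levels, collapse = ", "),
         " (got '", paste(f$leaflet_motion, collapse = ","), "')",
         call. = FALSE)
  }
  invisible(f)
}

#' @export
print.echo_features <- function(x, ...) {
  present <- .mv_flag_fields[vapply(.mv_flag_fields,
                                    function(fl) isTRUE(x[[fl]]), logical(1))]
  cat("Echocardiographic lesion profile\n")
  cat("  flags present:    ",
      if (length(present)) paste(present, collapse = ", ") else "none", "\n")
  cat("  morphology:       ", x$leaflet_morphology, "\n")
  cat("  motion:           ", x$leaflet_motion, "\n")
  cat("  vegetation:       ", x$vegetation_class, "\n")
  cat("  perforation/cleft:", x$perforation_cleft_class, "\n")
  invisible(x)
}

#' Repair maneuvers performed on one valve
#'
#' Records the principal techniques used in a mitral valve repair, the input
#' to the surgical technique score: each maneuver counts 1, except chordal
#' replacement which counts 1 per leaflet segment resuspended by chords.
#' Revision of an annuloplasty ring only arises during a re-repair.
#'
#' @param annuloplasty logical; annuloplasty ring implanted.
#' @param chordal_segments_resuspended integer; number of leaflet segments
#'   resuspended with artificial or native chords.
#' @param cleft_closures,leaflet_resections,vegetation_removals,commissurotomies
#'   non-negative integer counts of the respective maneuvers.
#' @param re_repair logical; the operation was a repeat repair.
#' @param ring_revision logical; the annuloplasty ring was revised during a
#'   re-repair (requires `re_repair = TRUE`).
#' @return An object of class `repair_techniques`.
#' @examples
#' repair_techniques(annuloplasty = TRUE, chordal_segments_resuspended = 2)
#' @export
repair_techniques <- function(annuloplasty = FALSE,
                              chordal_segments_resuspended = 0,
                              cleft_closures = 0,
                              leaflet_resections = 0,
                              vegetation_removals = 0,
                              commissurotomies = 0,
                              re_repair = FALSE,
                              ring_revision = FALSE) {
  t <- list(
    annuloplasty = annuloplasty,
    chordal_segments_resuspended = chordal_segments_resuspended,
    cleft_closures = cleft_closures,
    leaflet_resections = leaflet_resections,
    vegetation_removals = vegetation_removals,
    commissurotomies = commissurotomies,
    re_repair = re_repair,
    ring_revision = ring_revision
  )
  counts <- c("chordal_segments_resuspended", "cleft_closures",
              "leaflet_resections", "vegetation_removals", "commissurotomies")
  for (cn in counts) {
    v <- t[[cn]]
    if (length(v) != 1L || is.na(v) || !is.numeric(v) || v < 0 ||
        v != round(v)) {
      stop("technique count '", cn, "' must be a non-negative integer",
           call. = FALSE)
    }
  }
  for (fl in c("annuloplasty", "re_repair", "ring_revision")) {
    if (length(t[[fl]]) != 1L || is.na(t[[fl]]) || !is.logical(t[[fl]])) {
      stop("field '", fl, "' must be a single non-missing logical",
           call. = FALSE)
    }
  }
  if (isTRUE(t$ring_revision) && !isTRUE(t$re_repair)) {
    stop("ring_revision requires re_repair", call. = FALSE)
  }
  class(t) <- "repair_techniques"
  t
}
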