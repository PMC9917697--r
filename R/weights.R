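#' Default lesion complexity weights
#'
#' Returns the default weight table of the complexity scoring system. Each
#' echocardiographic lesion category carries a small non-negative integer
#' weight and the complexity score of a patient is the sum of the weights of
#' the lesions present:
#'
#' \itemize{
#'   \item posterior leaflet prolapse: 1 per prolapsing segment (P1, P2, P3);
#'   \item anterior leaflet prolapse: 2 per prolapsing segment (A1, A2, A3);
#'   \item commissural prolapse: 2 per prolapsing commissure
#'     (anterolateral, posteromedial);
#'   \item ruptured chordae tendineae: 1;
#'   \item leaflet morphology: normal 0, thickening 1, redundant 3;
#'   \item calcification: leaflet 1, annulus 3, chordae tendineae 3
#'     (additive across sites);
#'   \item commissure fusion: 2;
#'   \item perforation or cleft: one lesion 1, two or more 2;
#'   \item vegetation: one 1, two or more 2;
#'   \item leaflet motion: normal 0, excessive (hypermobility) 1,
#'     restriction 2 (scored once per patient, not per segment).
#' }
#'
#' The weights are configurable (see [load_weights()]); the defaults above
#' define the reference scoring system and the published strata boundaries
#' (simple 0--4, intermediate 5--8, complex >= 9) assume them.
#'
#' @param pooled_lesion_variant logical; if `TRUE`, vegetation and
#'   perforation/cleft are pooled into a single category scored 1 if exactly
#'   one such lesion is present and 4 if more than one (an alternative
#'   reading of the scoring rules). Default `FALSE`: the two categories are
#'   scored separately, each capped at 2.
#' @return An object of class `mv_weights`: a named list of weight vectors.
#' @seealso [complexity_score()], [load_weights()]
#' @examples
#' w <- default_weights()
#' w$prolapse[["a2"]]   # anterior segments weigh 2
#' @export
default_weights <- function(pooled_lesion_variant = FALSE) {
  w <- list(
    prolapse = c(
      p1 = 1L, p2 = 1L, p3 = 1L,
      a1 = 2L, a2 = 2L, a3 = 2L,
      anterolateral_commissure = 2L,
      posteromedial_commissure = 2L
    ),
    ruptured_chordae = 1L,
    morphology = c(normal = 0L, thickening = 1L, redundant = 3L),
    calcification = c(leaflet = 1L, annulus = 3L, chordae = 3L),
    commissure_fusion = 2L,
    perforation_cleft = c(`0` = 0L, `1` = 1L, `2` = 2L),
    vegetation = c(`0` = 0L, `1` = 1L, `2` = 2L),
    motion = c(normal = 0L, excessive = 1L, restriction = 2L),
    pooled_lesion_variant = isTRUE(pooled_lesion_variant),
    pooled_multi_weight = 4L
  )
  class(w) <- "mv_weights"
  w
}

#' Load a weight configuration from YAML or JSON
#'
#' Reads a weight table from a configuration file. Keys mirror the structure
#' of [default_weights()]; any key omitted from the file keeps its default
#' value, so a configuration need only list the weights it overrides.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return An `mv_weights` object.
#' @export
load_weights <- function(path) {
  stopifnot(is.character(path), length(path) == 1L, file.exists(path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  w <- default_weights()
  for (key in names(cfg)) {
    if (!key %in% names(w)) {
      stop("unknown weight key: '", key, "'", call. = FALSE)
    }
    val <- cfg[[key]]
    if (is.list(val)) val <- unlist(val)
    if (length(w[[key]]) > 1L) {
      bad <- setdiff(names(val), names(w[[key]]))
      if (length(bad)) {
        stop("unknown entries under '", key, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      w[[key]][names(val)] <- val
    } else {
      w[[key]] <- val
    }
  }
  validate_weights(w)
  w
}

validate_weights <- function(w) {
  numeric_keys <- c("prolapse", "ruptured_chordae", "morphology",
                    "calcification", "commissure_fusion",
                    "perforation_cleft", "vegetation", "motion",
                    "pooled_multi_weight")
  for (key in numeric_keys) {
    v <- w[[key]]
    if (any(!is.finite(v)) || any(v < 0) || any(v != round(v))) {
      stop("weights under '", key, "' must be non-negative integers",
           call. = FALSE)
    }
  }
  invisible(w)
}

#' @export
print.mv_weights <- function(x, ...) {
  cat("Mitral valve lesion complexity weights\n")
  cat("  prolapse per segment:   ",
      paste(names(x$prolapse), x$prolapse, sep = "=", collapse = " "), "\n")
  cat("  ruptured chordae:       ", x$ruptured_chordae, "\n")
  cat("  morphology:             ",
      paste(names(x$morphology), x$morphology, sep = "=", collapse = " "), "\n")
  cat("  calcification per site: ",
      paste(names(x$calcification), x$calcification, sep = "=",
            collapse = " "), "\n")
  cat("  commissure fusion:      ", x$commissure_fusion, "\n")
  cat("  perforation/cleft class:",
      paste(names(x$perforation_cleft), x$perforation_cleft, sep = "=",
            collapse = " "), "\n")
  cat("  vegetation class:       ",
      paste(names(x$vegetation), x$vegetation, sep = "=", collapse = " "), "\n")
  cat("  leaflet motion:         ",
      paste(names(x$motion), x$motion, sep = "=", collapse = " "), "\n")
  if (isTRUE(x$pooled_lesion_variant)) {
    cat("  (pooled vegetation/perforation/cleft variant, multi-lesion weight",
        x$pooled_multi_weight, ")\n")
  }
  invisible(x)
}
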