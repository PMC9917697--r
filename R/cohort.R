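#' Default synthetic cohort configuration
#'
#' Returns the generative model for synthetic surgical cohorts. The model is
#' hierarchical: each patient draws an etiology from `etiology_mix`, then
#' draws every echocardiographic feature from the etiology-specific tables in
#' `feature_freqs`, the complexity score follows deterministically from the
#' features, and the surgical approach is Bernoulli with log-odds of
#' replacement `intercept + slope * score` plus repairability emphasis terms
#' (`outcome_emphasis`) for restricted leaflet motion, leaflet calcification
#' and perforation/cleft lesions: leaflet-quality lesions push toward
#' replacement beyond their contribution to the summed score, so the label
#' carries feature-level signal that no single score cutoff can fully
#' exploit. The link remains monotone in the score and in every individual
#' lesion. Adverse events after
#' repair are Bernoulli with a stratum-specific rate. Repaired valves also
#' receive a plausible set of repair maneuvers driven by their lesions, so
#' that a technique score can be computed.
#'
#' The defaults emulate a 143-patient mitral valve surgery cohort of 86
#' repairs and 57 replacements: the etiology mix follows the observed
#' diagnosis counts (mitral valve prolapse 55, infective endocarditis 24,
#' rheumatic heart disease 39, atrial mitral regurgitation 16, Barlow's
#' syndrome 4, other 5, out of 143); rheumatic profiles concentrate leaflet
#' thickening, restriction, calcification and commissural fusion (hence the
#' complex stratum); prolapse profiles concentrate P2-dominant segmental
#' prolapse with excessive motion; atrial mitral regurgitation profiles are
#' near-normal (annular dilatation leaves the leaflets intact, hence the
#' simple stratum); endocarditis profiles carry vegetations and
#' perforations/clefts. The outcome link (`intercept`, `slope`) is calibrated
#' so that the score-vs-replacement concordance (AUC) on a large cohort is
#' approximately 0.75 and the replacement fraction approximately 57/143.
#'
#' Features are sampled independently within etiology: only marginal
#' frequencies are modelled, not patient-level joint dependence.
#'
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()], [cohort_summary()]
#' @export
default_cohort_config <- function() {
  freq <- function(prolapse, ruptured_chordae, morphology, calc,
                   commissure_fusion, vegetation, perforation_cleft, motion) {
    list(prolapse = prolapse, ruptured_chordae = ruptured_chordae,
         morphology = morphology, calc = calc,
         commissure_fusion = commissure_fusion, vegetation = vegetation,
         perforation_cleft = perforation_cleft, motion = motion)
  }
  pro <- function(p1 = 0, p2 = 0, p3 = 0, a1 = 0, a2 = 0, a3 = 0,
                  alc = 0, pmc = 0) {
    c(prolapse_p1 = p1, prolapse_p2 = p2, prolapse_p3 = p3,
      prolapse_a1 = a1, prolapse_a2 = a2, prolapse_a3 = a3,
      prolapse_anterolateral_commissure = alc,
      prolapse_posteromedial_commissure = pmc)
  }
  cat3 <- function(x0, x1, x2) c(`0` = x0, `1` = x1, `2` = x2)
  morph <- function(n, t, r) c(normal = n, thickening = t, redundant = r)
  mot <- function(n, e, r) c(normal = n, excessive = e, restriction = r)
  calc <- function(l = 0, a = 0, c = 0) c(leaflet = l, annulus = a, chordae = c)

  cfg <- list(
    n_patients = 143L,
    # observed diagnosis counts 55/24/39/16/4/5 of 143
    etiology_mix = c(
      mitral_valve_prolapse      = 55 / 143,
      infective_endocarditis     = 24 / 143,
      rheumatic_heart_disease    = 39 / 143,
      atrial_mitral_regurgitation = 16 / 143,
      barlows_syndrome           = 4 / 143,
      other                      = 5 / 143
    ),
    feature_freqs = list(
      # degenerative prolapse: P2-dominant segmental prolapse, frequent
      # chordal rupture, hypermobile leaflets
      mitral_valve_prolapse = freq(
        prolapse = pro(p1 = 0.22, p2 = 0.75, p3 = 0.40,
                       a1 = 0.18, a2 = 0.32, a3 = 0.26, pmc = 0.15),
        ruptured_chordae = 0.50,
        morphology = morph(0.48, 0.48, 0.04),
        calc = calc(l = 0.02, c = 0.04),
        commissure_fusion = 0.01,
        vegetation = cat3(0.98, 0.02, 0),
        perforation_cleft = cat3(0.92, 0.06, 0.02),
        motion = mot(0.06, 0.90, 0.04)
      ),
      # endocarditis: vegetations, perforations, some destruction-driven
      # prolapse and rupture
      infective_endocarditis = freq(
        prolapse = pro(p1 = 0.06, p2 = 0.26, p3 = 0.10,
                       a1 = 0.10, a2 = 0.28, a3 = 0.10, pmc = 0.04),
        ruptured_chordae = 0.30,
        morphology = morph(0.54, 0.42, 0.04),
        calc = calc(l = 0.04, c = 0.04),
        commissure_fusion = 0.02,
        vegetation = cat3(0.22, 0.50, 0.28),
        perforation_cleft = cat3(0.38, 0.42, 0.20),
        motion = mot(0.30, 0.58, 0.12)
      ),
      # rheumatic disease: thickening, restriction, calcification of leaflet
      # and subvalvular apparatus, commissural fusion
      rheumatic_heart_disease = freq(
        prolapse = pro(p2 = 0.05, a2 = 0.05),
        ruptured_chordae = 0.18,
        morphology = morph(0.02, 0.94, 0.04),
        calc = calc(l = 0.86, a = 0.02, c = 0.86),
        commissure_fusion = 0.90,
        vegetation = cat3(0.93, 0.04, 0.03),
        perforation_cleft = cat3(0.92, 0.04, 0.04),
        motion = mot(0.02, 0.06, 0.92)
      ),
      # annular dilatation with intact leaflets
      atrial_mitral_regurgitation = freq(
        prolapse = pro(p1 = 0.03, p2 = 0.05),
        ruptured_chordae = 0.02,
        morphology = morph(0.86, 0.14, 0),
        calc = calc(),
        commissure_fusion = 0,
        vegetation = cat3(1, 0, 0),
        perforation_cleft = cat3(0.97, 0.03, 0),
        motion = mot(0.68, 0.32, 0)
      ),
      # Barlow's: diffuse redundant billowing tissue, multisegment prolapse
      barlows_syndrome = freq(
        prolapse = pro(p1 = 0.50, p2 = 0.80, p3 = 0.50,
                       a1 = 0.30, a2 = 0.50, a3 = 0.40, pmc = 0.25),
        ruptured_chordae = 0.30,
        morphology = morph(0, 0.10, 0.90),
        calc = calc(l = 0.05),
        commissure_fusion = 0,
        vegetation = cat3(1, 0, 0),
        perforation_cleft = cat3(0.95, 0.05, 0),
        motion = mot(0, 0.95, 0.05)
      ),
      # miscellaneous regurgitation/stenosis with mild findings
      other = freq(
        prolapse = pro(p1 = 0.05, p2 = 0.15, p3 = 0.05, a1 = 0.05),
        ruptured_chordae = 0.08,
        morphology = morph(0.70, 0.28, 0.02),
        calc = calc(l = 0.05, c = 0.05),
        commissure_fusion = 0.03,
        vegetation = cat3(0.96, 0.04, 0),
        perforation_cleft = cat3(0.90, 0.08, 0.02),
        motion = mot(0.55, 0.35, 0.10)
      )
    ),
    # log-odds of replacement: intercept + slope * complexity score, plus
    # repairability emphasis terms for the lesions that compromise leaflet
    # quality beyond their score weight (restricted motion, leaflet
    # calcification, perforation/cleft). (intercept, slope) are calibrated
    # against the concordance oracle (target score-vs-label AUC 0.75) and
    # the observed 57/143 replacement fraction; the emphasis terms are fixed
    # clinical constants on the log-odds scale.
    outcome_link = c(intercept = -2.06, slope = 0.15),
    outcome_emphasis = c(motion_restriction = 1.2,
                         calc_leaflet = 0.9,
                         perforation_cleft_per_lesion = 0.6),
    # unsuccessful-repair fractions by stratum (4/33, 6/45, 5/9)
    adverse_rate_by_stratum = c(simple = 0.12, intermediate = 0.13,
                                complex = 0.56),
    # demographics: never used by the classifier
    sex_male_prob = 88 / 143,
    age_mean = 52,
    age_sd = 13,
    seed = 0L
  )
  class(cfg) <- "cohort_config"
  cfg
}

#' Load a cohort configuration from YAML or JSON
#'
#' Reads simulator settings from a configuration file and merges them over
#' [default_cohort_config()]: top-level keys (`n_patients`, `seed`,
#' `etiology_mix`, `outcome_link`, `outcome_emphasis`,
#' `adverse_rate_by_stratum`, demographics) replace their defaults, and
#' `feature_freqs` entries are merged per etiology and per feature group, so
#' a file need only state what it overrides. The merged configuration is
#' validated before being returned.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `cohort_config`.
#' @export
load_cohort_config <- function(path) {
  stopifnot(is.character(path), length(path) == 1L, file.exists(path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- default_cohort_config()
  vec_keys <- c("etiology_mix", "outcome_link", "outcome_emphasis",
                "adverse_rate_by_stratum")
  for (key in names(raw)) {
    if (!key %in% names(cfg)) {
      stop("unknown cohort config key: '", key, "'", call. = FALSE)
    }
    if (key == "feature_freqs") {
      for (et in names(raw$feature_freqs)) {
        if (!et %in% names(cfg$feature_freqs)) {
          stop("unknown etiology in feature_freqs: '", et, "'",
               call. = FALSE)
        }
        for (grp in names(raw$feature_freqs[[et]])) {
          val <- raw$feature_freqs[[et]][[grp]]
          if (is.list(val)) val <- unlist(val)
          old <- cfg$feature_freqs[[et]][[grp]]
          if (is.null(old)) {
            stop("unknown feature group '", grp, "' under '", et, "'",
                 call. = FALSE)
          }
          if (!is.null(names(val)) && length(old) > 1L) {
            old[names(val)] <- val
            cfg$feature_freqs[[et]][[grp]] <- old
          } else {
            cfg$feature_freqs[[et]][[grp]] <- val
          }
        }
      }
    } else if (key %in% vec_keys) {
      val <- raw[[key]]
      if (is.list(val)) val <- unlist(val)
      old <- cfg[[key]]
      old[names(val)] <- val
      cfg[[key]] <- old
    } else {
      cfg[[key]] <- raw[[key]]
    }
  }
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1L ||
      is.na(cfg$n_patients) || cfg$n_patients < 0 ||
      cfg$n_patients != round(cfg$n_patients)) {
    stop("n_patients must be a single non-negative integer", call. = FALSE)
  }
  check_prob_vec <- function(v, what) {
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
      stop(what, " must contain probabilities in [0, 1]", call. = FALSE)
    }
  }
  check_simplex <- function(v, what) {
    check_prob_vec(v, what)
    if (abs(sum(v) - 1) > 1e-9) {
      stop(what, " must sum to 1 (got ", format(sum(v)), ")", call. = FALSE)
    }
  }
  check_simplex(cfg$etiology_mix, "etiology_mix")
  if (!setequal(names(cfg$feature_freqs), names(cfg$etiology_mix))) {
    stop("feature_freqs must have one entry per etiology", call. = FALSE)
  }
  for (et in names(cfg$feature_freqs)) {
    ff <- cfg$feature_freqs[[et]]
    check_prob_vec(ff$prolapse, paste0(et, "$prolapse"))
    check_prob_vec(ff$ruptured_chordae, paste0(et, "$ruptured_chordae"))
    check_prob_vec(ff$calc, paste0(et, "$calc"))
    check_prob_vec(ff$commissure_fusion, paste0(et, "$commissure_fusion"))
    check_simplex(ff$morphology, paste0(et, "$morphology"))
    check_simplex(ff$vegetation, paste0(et, "$vegetation"))
    check_simplex(ff$perforation_cleft, paste0(et, "$perforation_cleft"))
    check_simplex(ff$motion, paste0(et, "$motion"))
  }
  if (length(cfg$outcome_link) != 2L || any(!is.finite(cfg$outcome_link))) {
    stop("outcome_link must be c(intercept, slope)", call. = FALSE)
  }
  if (!setequal(names(cfg$outcome_emphasis),
                c("motion_restriction", "calc_leaflet",
                  "perforation_cleft_per_lesion")) ||
      any(!is.finite(cfg$outcome_emphasis)) || any(cfg$outcome_emphasis < 0)) {
    stop("outcome_emphasis must be non-negative terms for ",
         "motion_restriction, calc_leaflet and perforation_cleft_per_lesion",
         call. = FALSE)
  }
  check_prob_vec(cfg$adverse_rate_by_stratum, "adverse_rate_by_stratum")
  if (!setequal(names(cfg$adverse_rate_by_stratum),
                c("simple", "intermediate", "complex"))) {
    stop("adverse_rate_by_stratum needs simple/intermediate/complex entries",
         call. = FALSE)
  }
  invisible(cfg)
}

# Per-patient substream: patient i always sees the same RNG state for a
# given root seed, so cohort prefixes are stable when n_patients changes.
.patient_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 + i * 1000003) %% 2147483647)
}

#' Generate a synthetic surgical cohort
#'
#' Samples `config$n_patients` patient records from the generative model in
#' `config` (see [default_cohort_config()]). Each patient uses an RNG
#' substream derived from the root seed and the patient index, so generation
#' is deterministic given `(config, seed)` and the first `m` records of a
#' cohort of size `n > m` equal the cohort of size `m`.
#'
#' @param config a `cohort_config`; defaults to [default_cohort_config()].
#' @param n_patients,seed optional overrides of the config fields.
#' @return A data frame with one row per patient: `patient_id`, `sex`,
#'   `age`, `diagnosis`, the [echo_features()] columns, `complexity_score`,
#'   `stratum`, per-component `score_*` columns, `approach`
#'   (repair/replacement), `adverse_event` (only meaningful after repair;
#'   `FALSE` for replacements), and `technique_score` (`NA` for
#'   replacements).
#' @examples
#' cohort <- generate_cohort(n_patients = 20, seed = 1)
#' table(cohort$stratum, cohort$approach)
#' @export
generate_cohort <- function(config = default_cohort_config(),
                            n_patients = NULL, seed = NULL) {
  if (!is.null(n_patients)) config$n_patients <- n_patients
  if (!is.null(seed)) config$seed <- seed
  validate_cohort_config(config)
  n <- as.integer(config$n_patients)
  if (n == 0L) return(empty_cohort())

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- .generate_patient(config, i)
  }
  cols <- names(rows[[1L]])
  cohort <- as.data.frame(
    lapply(stats::setNames(cols, cols),
           function(cn) unlist(lapply(rows, `[[`, cn), use.names = FALSE)),
    stringsAsFactors = FALSE
  )
  rownames(cohort) <- NULL
  cohort
}

.generate_patient <- function(config, i) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.patient_seed(config$seed, i))

  etiology <- sample(names(config$etiology_mix), 1L,
                     prob = config$etiology_mix)
  sex <- if (stats::runif(1) < config$sex_male_prob) "male" else "female"
  age <- round(min(max(stats::rnorm(1, config$age_mean, config$age_sd), 18),
                   90))
  ff <- config$feature_freqs[[etiology]]
  pro_draw <- stats::runif(length(ff$prolapse)) < ff$prolapse
  names(pro_draw) <- names(ff$prolapse)
  f <- echo_features(
    prolapse_p1 = pro_draw[["prolapse_p1"]],
    prolapse_p2 = pro_draw[["prolapse_p2"]],
    prolapse_p3 = pro_draw[["prolapse_p3"]],
    prolapse_a1 = pro_draw[["prolapse_a1"]],
    prolapse_a2 = pro_draw[["prolapse_a2"]],
    prolapse_a3 = pro_draw[["prolapse_a3"]],
    prolapse_anterolateral_commissure =
      pro_draw[["prolapse_anterolateral_commissure"]],
    prolapse_posteromedial_commissure =
      pro_draw[["prolapse_posteromedial_commissure"]],
    ruptured_chordae = stats::runif(1) < ff$ruptured_chordae,
    leaflet_morphology = sample(names(ff$morphology), 1L,
                                prob = ff$morphology),
    calc_leaflet = stats::runif(1) < ff$calc[["leaflet"]],
    calc_annulus = stats::runif(1) < ff$calc[["annulus"]],
    calc_chordae = stats::runif(1) < ff$calc[["chordae"]],
    commissure_fusion = stats::runif(1) < ff$commissure_fusion,
    vegetation_class = as.integer(sample(names(ff$vegetation), 1L,
                                         prob = ff$vegetation)),
    perforation_cleft_class =
      as.integer(sample(names(ff$perforation_cleft), 1L,
                        prob = ff$perforation_cleft)),
    leaflet_motion = sample(names(ff$motion), 1L, prob = ff$motion)
  )
  b <- complexity_score(f)
  stratum <- as.character(suppressWarnings(assign_stratum(b$total)))

  z <- config$outcome_link[["intercept"]] +
    config$outcome_link[["slope"]] * b$total +
    config$outcome_emphasis[["motion_restriction"]] *
      (f$leaflet_motion == "restriction") +
    config$outcome_emphasis[["calc_leaflet"]] * f$calc_leaflet +
    config$outcome_emphasis[["perforation_cleft_per_lesion"]] *
      f$perforation_cleft_class
  p_repl <- stats::plogis(z)
  approach <- if (stats::runif(1) < p_repl) "replacement" else "repair"
  adverse <- if (approach == "repair") {
    stats::runif(1) < config$adverse_rate_by_stratum[[stratum]]
  } else FALSE
  tech <- if (approach == "repair") {
    technique_score(.generate_techniques(f))
  } else NA_integer_

  row <- list(patient_id = i, sex = sex, age = age, diagnosis = etiology)
  for (fn in .mv_feature_fields) row[[fn]] <- f[[fn]]
  row$complexity_score <- b$total
  row$stratum <- stratum
  comp <- breakdown_components()
  comp[names(b$contributions)] <- b$contributions
  for (cn in names(comp)) row[[paste0("score_", cn)]] <- unname(comp[[cn]])
  row$approach <- approach
  row$adverse_event <- adverse
  row$technique_score <- tech
  row
}

# Repair maneuvers implied by the lesions: nearly every repair gets a ring;
# prolapsing segments are resuspended with chords; clefts are closed;
# vegetations removed; fused commissures incised. Prior valve surgery is an
# exclusion criterion of the emulated cohort, so re-repair never occurs.
.generate_techniques <- function(f) {
  n_seg <- sum(f$prolapse_p1, f$prolapse_p2, f$prolapse_p3,
               f$prolapse_a1, f$prolapse_a2, f$prolapse_a3,
               f$prolapse_anterolateral_commissure,
               f$prolapse_posteromedial_commissure)
  repair_techniques(
    annuloplasty = stats::runif(1) < 0.97,
    chordal_segments_resuspended =
      stats::rbinom(1, n_seg + as.integer(f$ruptured_chordae), 0.7),
    cleft_closures = stats::rbinom(1, f$perforation_cleft_class, 0.9),
    leaflet_resections =
      stats::rbinom(1, 1, if (f$leaflet_morphology == "redundant") 0.6
                          else if (n_seg > 0) 0.25 else 0.02),
    vegetation_removals = stats::rbinom(1, f$vegetation_class, 0.9),
    commissurotomies = if (f$commissure_fusion) {
      stats::rbinom(1, 2, 0.8)
    } else 0L
  )
}

empty_cohort <- function() {
  out <- generate_cohort(n_patients = 1L, seed = 0L)
  out[0L, , drop = FALSE]
}

#' Summarise a cohort by stratum
#'
#' Tabulates a cohort (real or synthetic) by complexity stratum: counts and
#' percentages per stratum, and etiology-by-stratum and approach-by-stratum
#' cross-tables. Percentages are rounded to one decimal.
#'
#' @param cohort a data frame with at least a `stratum` column; `diagnosis`
#'   and `approach` columns are cross-tabulated when present.
#' @return An object of class `cohort_summary`: a list with
#'   `stratum_counts` (data frame with `stratum`, `n`, `pct`),
#'   `etiology_by_stratum` and `approach_by_stratum` (contingency tables, or
#'   `NULL` when the column is absent), and `n_total`.
#' @examples
#' summary38 <- cohort_summary(
#'   data.frame(stratum = rep(c("simple", "intermediate", "complex"),
#'                            c(38, 61, 44))))
#' summary38$stratum_counts
#' @export
cohort_summary <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  if (nrow(cohort) == 0L) {
    stop("cannot summarise an empty cohort", call. = FALSE)
  }
  if (!"stratum" %in% names(cohort)) {
    stop("cohort must have a 'stratum' column", call. = FALSE)
  }
  strat <- factor(cohort$stratum,
                  levels = c("simple", "intermediate", "complex"))
  n <- nrow(cohort)
  counts <- table(strat)
  out <- list(
    stratum_counts = data.frame(
      stratum = names(counts),
      n = as.integer(counts),
      pct = round(100 * as.integer(counts) / n, 1),
      stringsAsFactors = FALSE
    ),
    etiology_by_stratum = if ("diagnosis" %in% names(cohort)) {
      table(diagnosis = cohort$diagnosis, stratum = strat)
    } else NULL,
    approach_by_stratum = if ("approach" %in% names(cohort)) {
      table(approach = cohort$approach, stratum = strat)
    } else NULL,
    n_total = n
  )
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort of", x$n_total, "patients\n\nBy complexity stratum:\n")
  print(x$stratum_counts, row.names = FALSE)
  if (!is.null(x$approach_by_stratum)) {
    cat("\nSurgical approach by stratum:\n")
    print(x$approach_by_stratum)
  }
  if (!is.null(x$etiology_by_stratum)) {
    cat("\nEtiology by stratum:\n")
    print(x$etiology_by_stratum)
  }
  invisible(x)
}
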