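# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately brute-force and separate from the package
# implementation paths it checks.

# Draw a random but valid lesion profile as a plain list.
random_profile <- function() {
  flags <- c("prolapse_p1", "prolapse_p2", "prolapse_p3",
             "prolapse_a1", "prolapse_a2", "prolapse_a3",
             "prolapse_anterolateral_commissure",
             "prolapse_posteromedial_commissure",
             "ruptured_chordae",
             "calc_leaflet", "calc_annulus", "calc_chordae",
             "commissure_fusion")
  p <- lapply(stats::setNames(flags, flags), function(f) runif(1) < 0.4)
  p$leaflet_morphology <- sample(c("normal", "thickening", "redundant"), 1)
  p$leaflet_motion <- sample(c("normal", "excessive", "restriction"), 1)
  p$vegetation_class <- sample(0:2, 1)
  p$perforation_cleft_class <- sample(0:2, 1)
  p
}

# Additivity oracle: the complexity total recomputed as a sum over an
# explicit (condition, weight) list written out term by term.
oracle_complexity_total <- function(p) {
  morph_w <- c(normal = 0, thickening = 1, redundant = 3)
  motion_w <- c(normal = 0, excessive = 1, restriction = 2)
  sum(
    1 * p$prolapse_p1, 1 * p$prolapse_p2, 1 * p$prolapse_p3,
    2 * p$prolapse_a1, 2 * p$prolapse_a2, 2 * p$prolapse_a3,
    2 * p$prolapse_anterolateral_commissure,
    2 * p$prolapse_posteromedial_commissure,
    1 * p$ruptured_chordae,
    morph_w[[p$leaflet_morphology]],
    1 * p$calc_leaflet, 3 * p$calc_annulus, 3 * p$calc_chordae,
    2 * p$commissure_fusion,
    min(p$perforation_cleft_class, 2),
    min(p$vegetation_class, 2),
    motion_w[[p$leaflet_motion]]
  )
}

# Mann-Whitney concordance probability by explicit pair enumeration.
oracle_concordance <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (sp in pos) for (sn in neg) {
    tot <- tot + (sp > sn) + 0.5 * (sp == sn)
  }
  tot / (length(pos) * length(neg))
}

# Exhaustive TP/FP counting at one threshold (positive when score > t).
oracle_roc_point <- function(scores, labels, t) {
  c(sens = sum(scores > t & labels == 1) / sum(labels == 1),
    fpr = sum(scores > t & labels == 0) / sum(labels == 0))
}

# Brute-force Youden maximization over every finite threshold, ties toward
# the lower threshold.
oracle_youden <- function(scores, labels) {
  s <- sort(unique(scores))
  thr <- if (length(s) > 1) (s[-length(s)] + s[-1]) / 2 else numeric(0)
  best <- list(cutoff = NA_real_, j = -Inf)
  for (t in thr) {
    pt <- oracle_roc_point(scores, labels, t)
    j <- pt[["sens"]] + (1 - pt[["fpr"]]) - 1
    if (j > best$j + 1e-12) best <- list(cutoff = t, j = j)
  }
  best
}

# A scored-and-labelled toy set with both classes under a fixed seed.
random_scored_set <- function(n, integer_scores = TRUE) {
  repeat {
    scores <- if (integer_scores) sample(0:14, n, replace = TRUE)
              else round(runif(n, 0, 14), 2)
    labels <- rbinom(n, 1, plogis(-2 + 0.35 * scores))
    if (length(unique(labels)) == 2) return(list(scores = scores,
                                                 labels = labels))
  }
}

# Worked lesion profiles with known totals.
worked_profiles <- function() {
  list(
    list(features = echo_features(prolapse_a1 = TRUE,
                                  perforation_cleft_class = 1),
         total = 3),
    list(features = echo_features(prolapse_a1 = TRUE, prolapse_a2 = TRUE,
                                  prolapse_a3 = TRUE,
                                  leaflet_motion = "excessive"),
         total = 7),
    list(features = echo_features(prolapse_a2 = TRUE, prolapse_a3 = TRUE,
                                  prolapse_posteromedial_commissure = TRUE,
                                  leaflet_morphology = "redundant"),
         total = 9),
    list(features = echo_features(leaflet_morphology = "thickening",
                                  calc_chordae = TRUE,
                                  commissure_fusion = TRUE,
                                  leaflet_motion = "restriction"),
         total = 8)
  )
}

# A small well-formed patient table for I/O tests.
fixture_patient_table <- function(n = 10, seed = 42) {
  co <- generate_cohort(n_patients = n, seed = seed)
  co[, c("patient_id", "sex", "age", "diagnosis", "approach",
         "prolapse_p1", "prolapse_p2", "prolapse_p3",
         "prolapse_a1", "prolapse_a2", "prolapse_a3",
         "prolapse_anterolateral_commissure",
         "prolapse_posteromedial_commissure",
         "ruptured_chordae", "leaflet_morphology",
         "calc_leaflet", "calc_annulus", "calc_chordae",
         "commissure_fusion", "vegetation_class",
         "perforation_cleft_class", "leaflet_motion")]
}
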