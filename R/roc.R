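#' ROC curve of a score against a binary label
#'
#' Builds the receiver operating characteristic curve of a continuous or
#' integer score as a classifier of a binary label, with higher scores
#' indicating the positive class. One curve point is produced per candidate
#' threshold; thresholds are placed at the midpoints between consecutive
#' distinct observed scores (so integer-valued scores yield half-integer
#' cutoffs such as 8.5), plus `-Inf` and `+Inf` for the (1,1) and (0,0)
#' endpoints. A case is called positive when its score exceeds the
#' threshold.
#'
#' @param scores numeric vector.
#' @param labels binary vector (logical, 0/1, or a two-level factor/character
#'   with the positive class given by `positive`).
#' @param positive the label value treated as positive; default `1`. For the
#'   complexity score the positive class is valve replacement (higher lesion
#'   complexity makes the valve less repairable).
#' @return An object of class `mv_roc`: a list with `thresholds`,
#'   `sensitivity`, `fpr` (1 - specificity), `auc` (trapezoidal area), and
#'   the input counts `n_pos`, `n_neg`.
#' @seealso [roc_auc()], [youden_cutoff()], [auc_ci()]
#' @examples
#' r <- roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' r$auc
#' @export
roc_curve <- function(scores, labels, positive = 1) {
  y <- .coerce_labels(labels, positive)
  if (length(scores) != length(y)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  if (any(!is.finite(scores))) {
    stop("scores must be finite and non-missing", call. = FALSE)
  }
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both label classes must be present to build an ROC curve",
         call. = FALSE)
  }
  s <- sort(unique(scores))
  thr <- c(-Inf, if (length(s) > 1L) (s[-length(s)] + s[-1L]) / 2, Inf)
  sens <- vapply(thr, function(t) sum(scores > t & y == 1L) / n_pos,
                 numeric(1))
  fpr <- vapply(thr, function(t) sum(scores > t & y == 0L) / n_neg,
                numeric(1))
  # order by decreasing threshold: (0,0) first, (1,1) last
  o <- order(thr, decreasing = TRUE)
  out <- list(thresholds = thr[o], sensitivity = sens[o], fpr = fpr[o],
              auc = .trapezoid_auc(fpr[o], sens[o]),
              n_pos = n_pos, n_neg = n_neg)
  class(out) <- "mv_roc"
  out
}

.coerce_labels <- function(labels, positive) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) return(as.integer(labels == positive))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) {
      stop("numeric labels must be 0/1", call. = FALSE)
    }
    return(as.integer(labels == positive))
  }
  stop("labels must be logical, 0/1, or character/factor", call. = FALSE)
}

.trapezoid_auc <- function(fpr, sens) {
  o <- order(fpr, sens)
  sum(diff(fpr[o]) * (sens[o][-1] + sens[o][-length(sens)]) / 2)
}

#' @export
print.mv_roc <- function(x, ...) {
  cat(sprintf("ROC curve: %d positives, %d negatives, %d thresholds\n",
              x$n_pos, x$n_neg, length(x$thresholds)))
  cat(sprintf("AUC (trapezoid): %.4f\n", x$auc))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the ROC polygon of [roc_curve()]. Because every
#' distinct score is a threshold, this equals the Mann--Whitney concordance
#' probability: the probability that a random positive case outscores a
#' random negative one, ties counting one half.
#'
#' @inheritParams roc_curve
#' @return A number in \eqn{[0, 1]}.
#' @examples
#' roc_auc(c(1, 2, 2, 3), c(0, 1, 0, 1))  # 0.875
#' @export
roc_auc <- function(scores, labels, positive = 1) {
  roc_curve(scores, labels, positive)$auc
}

#' Bootstrap confidence interval for the AUC
#'
#' Percentile bootstrap interval for the AUC, resampling positives and
#' negatives separately (stratified, preserving class sizes), deterministic
#' given the seed.
#'
#' @inheritParams roc_curve
#' @param n_boot number of bootstrap replicates, at least 100; default 2000.
#' @param seed integer seed for the resampling stream.
#' @param conf confidence level; default 0.95.
#' @return Named numeric vector `c(low, high)`.
#' @examples
#' auc_ci(c(1, 2, 3, 4), c(0, 0, 1, 1), n_boot = 200, seed = 1)
#' @export
auc_ci <- function(scores, labels, n_boot = 2000, seed = 0, conf = 0.95,
                   positive = 1) {
  if (!is.numeric(n_boot) || n_boot < 100) {
    stop("n_boot must be at least 100", call. = FALSE)
  }
  y <- .coerce_labels(labels, positive)
  if (length(scores) != length(y)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  ipos <- which(y == 1L)
  ineg <- which(y == 0L)
  if (!length(ipos) || !length(ineg)) {
    stop("both label classes must be present", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  reps <- vapply(seq_len(n_boot), function(b) {
    bp <- sample(ipos, length(ipos), replace = TRUE)
    bn <- sample(ineg, length(ineg), replace = TRUE)
    idx <- c(bp, bn)
    roc_auc(scores[idx], y[idx], positive = 1)
  }, numeric(1))
  alpha <- (1 - conf) / 2
  q <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

#' Youden-optimal cutoff of an ROC curve
#'
#' Selects the threshold maximizing the Youden index
#' \eqn{J = \mathrm{sensitivity} + \mathrm{specificity} - 1}. Ties are broken
#' toward the lower threshold, favouring sensitivity. Only finite thresholds
#' are eligible (the degenerate all-positive / all-negative rules at
#' \eqn{\pm\infty} have \eqn{J = 0}).
#'
#' @param roc an `mv_roc` object from [roc_curve()].
#' @return A list with `cutoff`, `j`, `sensitivity`, `specificity`.
#' @examples
#' youden_cutoff(roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1)))
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "mv_roc"))
  finite <- is.finite(roc$thresholds)
  thr <- roc$thresholds[finite]
  sens <- roc$sensitivity[finite]
  spec <- 1 - roc$fpr[finite]
  j <- sens + spec - 1
  # max J; ties toward the lower threshold (higher sensitivity)
  best_j <- max(j)
  cand <- which(j >= best_j - 1e-12)
  pick <- cand[which.min(thr[cand])]
  list(cutoff = thr[pick], j = j[pick],
       sensitivity = sens[pick], specificity = spec[pick])
}

#' Full ROC analysis of a scored cohort
#'
#' Convenience wrapper running [roc_curve()], [auc_ci()] and
#' [youden_cutoff()] on a scored patient table.
#'
#' @param cohort data frame with the score and label columns.
#' @param score_col,label_col column names; defaults `complexity_score` and
#'   `approach`.
#' @param positive positive label value; default `"replacement"`.
#' @inheritParams auc_ci
#' @return A list with `roc` (`mv_roc`), `auc`, `auc_ci`, and `cutoff` (the
#'   [youden_cutoff()] list).
#' @export
roc_analysis <- function(cohort, score_col = "complexity_score",
                         label_col = "approach", positive = "replacement",
                         n_boot = 2000, seed = 0) {
  stopifnot(is.data.frame(cohort))
  for (cn in c(score_col, label_col)) {
    if (!cn %in% names(cohort)) {
      stop("column '", cn, "' not found in cohort", call. = FALSE)
    }
  }
  scores <- cohort[[score_col]]
  labels <- cohort[[label_col]]
  roc <- roc_curve(scores, labels, positive)
  list(
    roc = roc,
    auc = roc$auc,
    auc_ci = auc_ci(scores, labels, n_boot = n_boot, seed = seed,
                    positive = positive),
    cutoff = youden_cutoff(roc)
  )
}
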