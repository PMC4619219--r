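#' Score thresholds
#'
#' All thresholds are squared distances; the scoring loops never take a
#' square root. Defaults: squared contact distance threshold 7 um^2,
#' squared maximum adjacent-distance restraint 20.25 um^2, squared
#' minimum adjacent-distance restraint 0.2 um^2.
#'
#' @param contact_d2 squared contact distance threshold (um^2).
#' @param max_d2 squared maximum adjacent-distance restraint (um^2).
#' @param min_d2 squared minimum adjacent-distance restraint (um^2).
#' @return a list of class `ScoreThresholds`.
#' @export
score_thresholds <- function(contact_d2 = 7, max_d2 = 20.25, min_d2 = 0.2) {
  if (!(0 < min_d2 && min_d2 < contact_d2 && contact_d2 < max_d2)) {
    stop("thresholds must satisfy 0 < min_d2 < contact_d2 < max_d2")
  }
  structure(list(contact_d2 = contact_d2, max_d2 = max_d2, min_d2 = min_d2),
            class = "ScoreThresholds")
}

#' Sub-score weights
#'
#' Weights of the four sub-scores in the final weighted average. Defaults
#' (CS 2, NS 2, IF 3, MS 1) favour the interaction-frequency score, which
#' carries the contact counts.
#'
#' @param w_cs,w_ns,w_if,w_ms non-negative weights; their sum must be
#'   positive.
#' @return a list of class `ScoreWeights`.
#' @export
score_weights <- function(w_cs = 2, w_ns = 2, w_if = 3, w_ms = 1) {
  w <- c(w_cs, w_ns, w_if, w_ms)
  if (any(w < 0) || sum(w) <= 0) {
    stop("weights must be non-negative with a positive sum")
  }
  structure(list(w_cs = w_cs, w_ns = w_ns, w_if = w_if, w_ms = w_ms),
            class = "ScoreWeights")
}

as_coords <- function(s) {
  coords <- if (inherits(s, "Structure3D")) unclass(s) else s
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("a structure must be an n x 3 matrix")
  if (!all(is.finite(coords))) stop("structure coordinates must be finite")
  coords
}

#' Create a Structure3D
#'
#' A `Structure3D` is an ordered n x 3 coordinate matrix (micrometres),
#' point k corresponding to retained region k of its contact matrix.
#'
#' @param coords n x 3 numeric matrix.
#' @return an object of class `Structure3D`.
#' @export
structure3d <- function(coords) {
  coords <- as_coords(coords)
  class(coords) <- c("Structure3D", class(coords))
  coords
}

#' @export
print.Structure3D <- function(x, ...) {
  cat(sprintf("Structure3D: %d loci (um)\n", nrow(x)))
  print(utils::head(unclass(x), 5L))
  if (nrow(x) > 5L) cat(sprintf("  ... %d more loci\n", nrow(x) - 5L))
  invisible(x)
}

#' Pair satisfaction labels
#'
#' Labels every unordered off-diagonal pair of loci against the contact
#' matrix: 1 contact satisfied (`d^2 <= contact_d2`), 2 contact
#' unsatisfied, 3 non-contact satisfied (`d^2 > contact_d2`), 4
#' non-contact unsatisfied; the diagonal is 0 and excluded from all
#' scores.
#'
#' @param s a `Structure3D` (or n x 3 matrix).
#' @param m a `ContactMatrix` with `n_regions(m) == nrow(s)`.
#' @param thresholds a [score_thresholds()] object.
#' @return list with integer `labels` (n x n) and squared-distance matrix
#'   `d2`.
#' @export
pair_satisfaction <- function(s, m, thresholds = score_thresholds()) {
  coords <- as_coords(s)
  stopifnot(inherits(m, "ContactMatrix"))
  if (nrow(coords) != n_regions(m)) {
    stop("structure length does not match the contact matrix")
  }
  cpp_pair_labels(coords, m$freq, thresholds$contact_d2)
}

#' Contact satisfaction percentage
#'
#' `CS = 100 * (contacts satisfied) / (contact pairs)`. Returns `NA` when
#' the instance has no contact pairs; `NA` sub-scores drop out of the
#' weighted total with their weight.
#'
#' @param labels label matrix from [pair_satisfaction()].
#' @return percentage in \[0, 100\], or `NA`.
#' @export
score_cs <- function(labels) {
  ut <- labels[upper.tri(labels)]
  n_contact <- sum(ut == 1L | ut == 2L)
  if (n_contact == 0L) return(NA_real_)
  100 * sum(ut == 1L) / n_contact
}

#' Non-contact satisfaction percentage
#'
#' `NS = 100 * (non-contacts satisfied) / (non-contact pairs)`; `NA` when
#' there are no non-contact pairs.
#'
#' @inheritParams score_cs
#' @return percentage in \[0, 100\], or `NA`.
#' @export
score_ns <- function(labels) {
  ut <- labels[upper.tri(labels)]
  n_noncontact <- sum(ut == 3L | ut == 4L)
  if (n_noncontact == 0L) return(NA_real_)
  100 * sum(ut == 3L) / n_noncontact
}

#' Interaction-frequency satisfaction percentage
#'
#' Contact satisfaction weighted by interaction frequency:
#' `IF = 100 * sum(freq over satisfied contacts) / sum(freq over all
#' contact pairs)`; `NA` when the total IF is zero.
#'
#' @inheritParams score_cs
#' @param m the `ContactMatrix` the labels were computed against.
#' @return percentage in \[0, 100\], or `NA`.
#' @export
score_if <- function(labels, m) {
  ut <- upper.tri(labels)
  contact <- ut & (labels == 1L | labels == 2L)
  total_if <- sum(m$freq[contact])
  if (total_if <= 0) return(NA_real_)
  100 * sum(m$freq[ut & labels == 1L]) / total_if
}

#' Adjacent-distance (max/min restraint) satisfaction percentage
#'
#' Over chain-consecutive loci (k, k+1), a bond is satisfied when
#' `min_d2 <= d^2 <= max_d2`. The denominator is the number of regions n
#' (not the n-1 bonds), so a perfect chain scores `100 * (n-1) / n`.
#'
#' @param s a `Structure3D` (or n x 3 matrix).
#' @param thresholds a [score_thresholds()] object.
#' @return percentage in \[0, 100\], or `NA` when n < 2.
#' @export
score_ms <- function(s, thresholds = score_thresholds()) {
  coords <- as_coords(s)
  n <- nrow(coords)
  if (n < 2L) return(NA_real_)
  d2 <- rowSums((coords[-1L, , drop = FALSE] -
                   coords[-n, , drop = FALSE])^2)
  100 * sum(d2 >= thresholds$min_d2 & d2 <= thresholds$max_d2) / n
}

#' Weighted total score
#'
#' Weighted average of the available sub-scores; `NA` sub-scores are
#' excluded and the weights renormalized over the rest.
#'
#' @param cs,ns,if_score,ms sub-score percentages (`NA` = not applicable).
#' @param weights a [score_weights()] object.
#' @return weighted percentage.
#' @export
score_total <- function(cs, ns, if_score, ms, weights = score_weights()) {
  s <- c(cs, ns, if_score, ms)
  w <- c(weights$w_cs, weights$w_ns, weights$w_if, weights$w_ms)
  ok <- !is.na(s)
  if (!any(ok) || sum(w[ok]) <= 0) stop("all sub-scores are not applicable")
  sum(w[ok] * s[ok]) / sum(w[ok])
}

#' Mean distances of unsatisfied pairs
#'
#' Arithmetic mean of the (unsquared) distances over unsatisfied contacts
#' (label 2) and unsatisfied non-contacts (label 4); `NA` when a class is
#' empty.
#'
#' @param labels label matrix from [pair_satisfaction()].
#' @param d2 squared-distance matrix from [pair_satisfaction()].
#' @return list with `mean_unsat_contact_dist` and
#'   `mean_unsat_noncontact_dist` (micrometres).
#' @export
unsat_distance_summary <- function(labels, d2) {
  ut <- upper.tri(labels)
  mean_or_na <- function(mask) {
    if (!any(mask)) return(NA_real_)
    mean(sqrt(d2[mask]))
  }
  list(mean_unsat_contact_dist = mean_or_na(ut & labels == 2L),
       mean_unsat_noncontact_dist = mean_or_na(ut & labels == 4L))
}

#' Full score report for a structure against a contact matrix
#'
#' Computes the four sub-scores, the weighted total, the pair
#' satisfaction label matrix and the unsatisfied-pair distance summary.
#'
#' @param s a `Structure3D` (or n x 3 matrix).
#' @param m a `ContactMatrix`.
#' @param thresholds a [score_thresholds()] object.
#' @param weights a [score_weights()] object.
#' @return an object of class `ScoreReport`: fields `cs`, `ns`,
#'   `if_score`, `ms`, `total`, `labels`, `d2`,
#'   `mean_unsat_contact_dist`, `mean_unsat_noncontact_dist`.
#' @export
score_structure <- function(s, m, thresholds = score_thresholds(),
                            weights = score_weights()) {
  ps <- pair_satisfaction(s, m, thresholds)
  cs <- score_cs(ps$labels)
  ns <- score_ns(ps$labels)
  ifs <- score_if(ps$labels, m)
  ms <- score_ms(s, thresholds)
  tot <- score_total(cs, ns, ifs, ms, weights)
  unsat <- unsat_distance_summary(ps$labels, ps$d2)
  structure(
    list(cs = cs, ns = ns, if_score = ifs, ms = ms, total = tot,
         labels = ps$labels, d2 = ps$d2,
         mean_unsat_contact_dist = unsat$mean_unsat_contact_dist,
         mean_unsat_noncontact_dist = unsat$mean_unsat_noncontact_dist,
         thresholds = thresholds, weights = weights),
    class = "ScoreReport"
  )
}

#' @export
print.ScoreReport <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "n/a" else sprintf("%.2f", v)
  cat("ScoreReport\n")
  cat(sprintf("  CS  %s %%   NS  %s %%   IF  %s %%   MS  %s %%\n",
              fmt(x$cs), fmt(x$ns), fmt(x$if_score), fmt(x$ms)))
  cat(sprintf("  total (weighted) %s %%\n", fmt(x$total)))
  cat(sprintf("  mean unsatisfied contact distance     %s um\n",
              fmt(x$mean_unsat_contact_dist)))
  cat(sprintf("  mean unsatisfied non-contact distance %s um\n",
              fmt(x$mean_unsat_noncontact_dist)))
  invisible(x)
}

# fast path used by the optimizer: total score straight from C++
total_score_fast <- function(coords, m, thresholds, weights) {
  cpp_total_score(as_coords(coords), m$freq, thresholds$contact_d2,
                  thresholds$max_d2, thresholds$min_d2,
                  c(weights$w_cs, weights$w_ns, weights$w_if, weights$w_ms))
}
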