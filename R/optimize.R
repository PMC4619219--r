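#' Optimizer configuration
#'
#' Bundles every tunable of the three-stage optimizer. Defaults follow
#' the full-scale protocol: 50,000 adaptation iterations with 10 trial
#' moves per locus, 50 simulated-annealing sweeps, and 10,000 GA
#' mutations per model. The SA temperature schedule is geometric,
#' `T_k = sa_T0 * sa_cooling^k`, with the 0-100 total score used directly
#' as the energy.
#'
#' @param adapt_iters adaptation iterations (one iteration = one
#'   attempted move at every locus, in random order).
#' @param adapt_trials candidate moves per locus per attempt.
#' @param sa_iters simulated-annealing sweeps over the ensemble.
#' @param sa_T0 initial temperature (> 0).
#' @param sa_cooling geometric cooling factor in (0, 1).
#' @param ga_keep_frac fraction of the ensemble surviving GA selection.
#' @param ga_mutations score-gated single-point mutations per model.
#' @param ensemble_max cap on ensemble size carried out of adaptation.
#' @param seed integer seed for the whole run (`NULL` = do not reseed).
#' @param init `"auto"`, `"growth"` or `"sphere"`.
#' @param thresholds a [score_thresholds()] object.
#' @param weights a [score_weights()] object.
#' @return a list of class `OptimizerConfig`.
#' @export
optimizer_config <- function(adapt_iters = 50000L, adapt_trials = 10L,
                             sa_iters = 50L, sa_T0 = 1.0, sa_cooling = 0.95,
                             ga_keep_frac = 0.5, ga_mutations = 10000L,
                             ensemble_max = 50L, seed = NULL,
                             init = c("auto", "growth", "sphere"),
                             thresholds = score_thresholds(),
                             weights = score_weights()) {
  init <- match.arg(init)
  stopifnot(adapt_iters >= 1, adapt_trials >= 1, sa_iters >= 0,
            sa_T0 > 0, sa_cooling > 0, sa_cooling < 1,
            ga_keep_frac > 0, ga_keep_frac <= 1, ga_mutations >= 0,
            ensemble_max >= 1)
  structure(
    list(adapt_iters = as.integer(adapt_iters),
         adapt_trials = as.integer(adapt_trials),
         sa_iters = as.integer(sa_iters), sa_T0 = sa_T0,
         sa_cooling = sa_cooling, ga_keep_frac = ga_keep_frac,
         ga_mutations = as.integer(ga_mutations),
         ensemble_max = as.integer(ensemble_max), seed = seed, init = init,
         thresholds = thresholds, weights = weights),
    class = "OptimizerConfig"
  )
}

thr_vec <- function(cfg) cfg$thresholds
wt_vec <- function(cfg) c(cfg$weights$w_cs, cfg$weights$w_ns,
                          cfg$weights$w_if, cfg$weights$w_ms)

new_ensemble <- function(members, scores) {
  structure(list(members = members, scores = as.numeric(scores)),
            class = "Ensemble")
}

#' @export
print.Ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d models; scores %.2f .. %.2f\n",
              length(x$members), min(x$scores), max(x$scores)))
  invisible(x)
}

#' One adaptation move
#'
#' Generates `trials` candidate displacement vectors for locus `i`; each
#' candidate translates points `i..n` rigidly (the chain downstream of
#' the moved point follows). The best-scoring candidate is applied only
#' if it strictly improves the current total score.
#'
#' @param s a `Structure3D`.
#' @param m the `ContactMatrix` scored against.
#' @param i locus index (1-based).
#' @param trials number of candidate moves.
#' @param thresholds,weights scoring parameters.
#' @return list with `structure`, logical `accepted`, and `score`.
#' @export
adaptation_move <- function(s, m, i, trials = 10L,
                            thresholds = score_thresholds(),
                            weights = score_weights()) {
  coords <- as_coords(s)
  if (i < 1L || i > nrow(coords)) stop("locus index out of range")
  res <- cpp_adaptation_move(coords, m$freq, thresholds$contact_d2,
                             thresholds$max_d2, thresholds$min_d2,
                             c(weights$w_cs, weights$w_ns, weights$w_if,
                               weights$w_ms),
                             as.integer(i) - 1L, as.integer(trials))
  list(structure = structure3d(res$coords), accepted = res$accepted,
       score = res$score)
}

#' Run the adaptation stage
#'
#' Repeats greedy adaptation iterations (one attempted move per locus per
#' iteration, random visiting order). Every score-improving iteration is
#' snapshotted; the returned ensemble keeps the `ensemble_max` most
#' recent (equivalently best, the greedy score being non-decreasing)
#' snapshots. If no iteration improves, the ensemble is the input
#' structure alone.
#'
#' @param s0 initial `Structure3D`.
#' @param m a `ContactMatrix`.
#' @param cfg an [optimizer_config()].
#' @return an `Ensemble`; attribute `"trace"` carries the score after
#'   each iteration.
#' @export
adaptation_run <- function(s0, m, cfg = optimizer_config()) {
  coords <- as_coords(s0)
  t <- thr_vec(cfg)
  res <- cpp_adaptation_run(coords, m$freq, t$contact_d2, t$max_d2, t$min_d2,
                            wt_vec(cfg), cfg$adapt_iters, cfg$adapt_trials,
                            cfg$ensemble_max)
  e <- new_ensemble(lapply(res$members, structure3d), res$scores)
  attr(e, "trace") <- res$trace
  e
}

#' Simulated-annealing acceptance rule
#'
#' A candidate with score `E_new >= E_current` is always accepted; a
#' worse candidate is accepted when `exp(-(E_current - E_new) / T)`
#' exceeds a uniform draw on \[0, 1).
#'
#' @param E_current,E_new total scores of the incumbent and candidate.
#' @param temperature current temperature (> 0).
#' @return logical.
#' @export
sa_accept <- function(E_current, E_new, temperature) {
  if (temperature <= 0) stop("temperature must be positive")
  if (E_new >= E_current) return(TRUE)
  exp(-(E_current - E_new) / temperature) > stats::runif(1L)
}

#' Run the simulated-annealing stage
#'
#' For each of `sa_iters` sweeps at temperature `T_k = sa_T0 *
#' sa_cooling^k`, every ensemble member independently proposes a
#' candidate via one adaptation pass whose moves are applied
#' unconditionally (so candidates can be worse), and incumbent vs
#' candidate is resolved by [sa_accept()]. Each member's best-ever
#' structure is archived and returned, so reported scores never fall
#' below entry scores.
#'
#' @param e an `Ensemble` (from [adaptation_run()]).
#' @param m a `ContactMatrix`.
#' @param cfg an [optimizer_config()].
#' @return an `Ensemble` of per-member best-ever structures.
#' @export
sa_run <- function(e, m, cfg = optimizer_config()) {
  stopifnot(inherits(e, "Ensemble"), length(e$members) >= 1L)
  if (cfg$sa_iters == 0L) return(e)
  t <- thr_vec(cfg)
  w <- wt_vec(cfg)
  cur <- e$members
  cur_score <- e$scores
  best <- cur
  best_score <- cur_score
  for (k in seq_len(cfg$sa_iters)) {
    temp <- cfg$sa_T0 * cfg$sa_cooling^(k - 1L)
    for (j in seq_along(cur)) {
      prop <- cpp_adaptation_pass(as_coords(cur[[j]]), m$freq,
                                  t$contact_d2, t$max_d2, t$min_d2, w,
                                  cfg$adapt_trials, FALSE)
      if (sa_accept(cur_score[j], prop$score, temp)) {
        cur[[j]] <- structure3d(prop$coords)
        cur_score[j] <- prop$score
        if (prop$score > best_score[j]) {
          best[[j]] <- cur[[j]]
          best_score[j] <- prop$score
        }
      }
    }
  }
  new_ensemble(best, best_score)
}

#' GA natural selection
#'
#' Keeps the top `ceiling(keep_frac * size)` members by total score, ties
#' broken by earlier index; at least one member always survives.
#'
#' @param e an `Ensemble`.
#' @param keep_frac fraction to keep, in (0, 1\].
#' @return an `Ensemble`.
#' @export
ga_select <- function(e, keep_frac = 0.5) {
  stopifnot(inherits(e, "Ensemble"), length(e$members) >= 1L)
  k <- max(1L, as.integer(ceiling(keep_frac * length(e$members))))
  ord <- order(-e$scores, seq_along(e$scores))
  keep <- sort(ord[seq_len(k)])
  new_ensemble(e$members[keep], e$scores[keep])
}

#' GA crossover
#'
#' Single-point (or, given several points, multi-point) coordinate
#' crossover between two parent models of equal length: child 1 takes
#' parent A up to the crossover point and parent B after it, child 2 the
#' converse.
#'
#' @param a,b parent `Structure3D`s of equal length n.
#' @param point crossover point(s), each in 1..n-1: the children switch
#'   parents after that locus.
#' @return list of two child `Structure3D`s.
#' @export
ga_crossover <- function(a, b, point) {
  ca <- as_coords(a)
  cb <- as_coords(b)
  n <- nrow(ca)
  if (nrow(cb) != n) stop("parents must have equal length")
  if (any(point < 1L | point >= n)) stop("crossover point out of range")
  take_a <- rep(TRUE, n)  # TRUE = child1 takes from parent A
  for (p in sort(unique(as.integer(point)))) {
    take_a[(p + 1L):n] <- !take_a[(p + 1L):n]
  }
  c1 <- ca; c1[!take_a, ] <- cb[!take_a, ]
  c2 <- cb; c2[!take_a, ] <- ca[!take_a, ]
  list(structure3d(c1), structure3d(c2))
}

#' GA mutation
#'
#' Applies `n_mut` random single-point displacements (no suffix
#' propagation); each is kept only when the total score strictly
#' increases, so the final score never falls below the input score.
#'
#' @param s a `Structure3D`.
#' @param m a `ContactMatrix`.
#' @param n_mut number of attempted mutations.
#' @param thresholds,weights scoring parameters.
#' @return list with `structure` and `score`.
#' @export
ga_mutate <- function(s, m, n_mut = 10000L,
                      thresholds = score_thresholds(),
                      weights = score_weights()) {
  res <- cpp_ga_mutate(as_coords(s), m$freq, thresholds$contact_d2,
                       thresholds$max_d2, thresholds$min_d2,
                       c(weights$w_cs, weights$w_ns, weights$w_if,
                         weights$w_ms), as.integer(n_mut))
  list(structure = structure3d(res$coords), score = res$score)
}

#' Run the genetic-algorithm stage
#'
#' Selection of the top `ga_keep_frac` scorers, crossover over random
#' disjoint pairs of survivors at a random single point (children are
#' appended, so the population may grow before the final pick), then
#' score-gated mutation of every member.
#'
#' @param e an `Ensemble`.
#' @param m a `ContactMatrix`.
#' @param cfg an [optimizer_config()].
#' @return an `Ensemble`.
#' @export
ga_run <- function(e, m, cfg = optimizer_config()) {
  stopifnot(inherits(e, "Ensemble"), length(e$members) >= 1L)
  e <- ga_select(e, cfg$ga_keep_frac)
  members <- e$members
  scores <- e$scores
  n_surv <- length(members)
  if (n_surv >= 2L) {
    ord <- sample.int(n_surv)
    n_pair <- n_surv %/% 2L
    n_loci <- nrow(as_coords(members[[1L]]))
    for (p in seq_len(n_pair)) {
      ia <- ord[2L * p - 1L]
      ib <- ord[2L * p]
      pt <- sample.int(n_loci - 1L, 1L)
      kids <- ga_crossover(members[[ia]], members[[ib]], pt)
      for (kid in kids) {
        members[[length(members) + 1L]] <- kid
        scores[length(scores) + 1L] <-
          total_score_fast(kid, m, cfg$thresholds, cfg$weights)
      }
    }
  }
  for (j in seq_along(members)) {
    mut <- ga_mutate(members[[j]], m, cfg$ga_mutations,
                     cfg$thresholds, cfg$weights)
    members[[j]] <- mut$structure
    scores[j] <- mut$score
  }
  new_ensemble(members, scores)
}

#' Select the final conformation
#'
#' The highest-scoring ensemble member; ties go to the lowest index.
#'
#' @param e a non-empty `Ensemble`.
#' @return list with `structure` and `score`.
#' @export
select_final <- function(e) {
  stopifnot(inherits(e, "Ensemble"))
  if (length(e$members) == 0L) stop("ensemble is empty")
  i <- which.max(e$scores)
  list(structure = e$members[[i]], score = e$scores[i])
}
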