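#' Reconstruct a 3D chromosome model from a contact matrix
#'
#' The full pipeline: initialization (growth for > 200 regions, random
#' sphere otherwise), greedy adaptation producing an ensemble, simulated
#' annealing over the ensemble with per-member best-ever archiving, a
#' genetic algorithm (selection, crossover, score-gated mutation), and
#' the final argmax pick. With `cfg$seed` set, the whole run is
#' deterministic.
#'
#' @param m a `ContactMatrix`.
#' @param cfg an [optimizer_config()].
#' @param verbose print per-stage progress.
#' @return a list of class `hicfold_fit`: `structure` (the final
#'   `Structure3D`), `report` (its [score_structure()] `ScoreReport`),
#'   `stage_scores` (named best score after init, adaptation, SA, GA),
#'   `trace` (adaptation score after each iteration), `ensemble` (the
#'   final GA ensemble) and `config`.
#' @export
reconstruct <- function(m, cfg = optimizer_config(), verbose = FALSE) {
  stopifnot(inherits(m, "ContactMatrix"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- n_regions(m)
  strategy <- if (cfg$init == "auto") choose_init(n) else cfg$init
  s0 <- if (strategy == "growth") growth_init(n) else sphere_init(n)
  score0 <- total_score_fast(s0, m, cfg$thresholds, cfg$weights)
  if (verbose) message(sprintf("init (%s): score %.2f", strategy, score0))

  e <- adaptation_run(s0, m, cfg)
  trace <- attr(e, "trace")
  score_adapt <- max(e$scores)
  if (verbose) {
    message(sprintf("adaptation: %d ensemble members, best %.2f",
                    length(e$members), score_adapt))
  }

  e <- sa_run(e, m, cfg)
  score_sa <- max(e$scores)
  if (verbose) message(sprintf("simulated annealing: best %.2f", score_sa))

  e <- ga_run(e, m, cfg)
  score_ga <- max(e$scores)
  if (verbose) message(sprintf("genetic algorithm: best %.2f", score_ga))

  fin <- select_final(e)
  structure(
    list(structure = fin$structure,
         report = score_structure(fin$structure, m, cfg$thresholds,
                                  cfg$weights),
         stage_scores = c(init = score0, adaptation = score_adapt,
                          sa = score_sa, ga = score_ga, final = fin$score),
         trace = trace, ensemble = e, config = cfg),
    class = "hicfold_fit"
  )
}

#' @export
print.hicfold_fit <- function(x, ...) {
  cat(sprintf("hicfold fit: %d loci, final score %.2f %%\n",
              nrow(x$structure), x$stage_scores[["final"]]))
  cat("stage best scores:\n")
  print(round(x$stage_scores, 2))
  invisible(x)
}
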