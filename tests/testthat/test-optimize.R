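test_that("adaptation_move never worsens and moves only the suffix", {
  set.seed(51)
  st <- synthetic_truth(n = 12, seed = 51)
  # truth against its own matrix is near-perfect: CS/NS/IF all 100, so a
  # strict improvement is impossible on those sub-scores and almost
  # surely impossible overall -> the move must be rejected, unchanged
  before <- score_structure(st$truth, st$matrix)$total
  res <- adaptation_move(st$truth, st$matrix, i = 5, trials = 5)
  expect_gte(res$score, before)
  if (!res$accepted) expect_identical(unclass(res$structure),
                                      unclass(st$truth))

  # a move at locus i translates points i..n rigidly: prefix fixed and
  # suffix internally rigid even when accepted
  set.seed(52)
  bad <- structure3d(unclass(st$truth) +
                       matrix(runif(36, -2, 2), 12, 3))
  res <- adaptation_move(bad, st$matrix, i = 7, trials = 25)
  expect_identical(unclass(res$structure)[1:6, ], unclass(bad)[1:6, ])
  shift <- unclass(res$structure)[7:12, ] - unclass(bad)[7:12, ]
  expect_lt(max(abs(sweep(shift, 2, shift[1, ]))), 1e-12)

  # i = n: only the last point may move
  res <- adaptation_move(bad, st$matrix, i = 12, trials = 25)
  expect_identical(unclass(res$structure)[1:11, ],
                   unclass(bad)[1:11, ])
  expect_error(adaptation_move(bad, st$matrix, i = 13), "out of range")
})

test_that("adaptation_move repairs a displaced suffix with high probability", {
  # a suffix translation is exactly the move class adaptation explores,
  # so a chain broken by translating points 5..n away from the prefix is
  # reliably improved by a move at locus 5
  st <- synthetic_truth(n = 10, seed = 53)
  broken <- unclass(st$truth)
  broken[5:10, ] <- broken[5:10, ] + matrix(c(2, 0, 0), 6, 3, byrow = TRUE)
  base <- score_structure(broken, st$matrix)$total
  accepts <- 0L
  set.seed(54)
  for (k in 1:100) {
    res <- adaptation_move(structure3d(broken), st$matrix, i = 5,
                           trials = 25)
    if (res$accepted) {
      accepts <- accepts + 1L
      expect_gt(res$score, base)
    }
  }
  expect_gt(accepts / 100, 0.9)
})

test_that("adaptation_run is monotone, snapshot-capped and deterministic", {
  st <- synthetic_truth(n = 20, seed = 55)
  cfg <- test_config(adapt_iters = 300L, ensemble_max = 5L, seed = NULL)
  set.seed(56)
  s0 <- sphere_init(20)
  init_score <- score_structure(s0, st$matrix)$total
  e <- adaptation_run(s0, st$matrix, cfg)
  trace <- attr(e, "trace")
  expect_length(trace, 300L)
  expect_true(all(diff(trace) >= 0))
  expect_gte(max(e$scores), init_score)
  expect_lte(length(e$members), 5L)
  # cached scores are consistent with their structures
  for (k in seq_along(e$members)) {
    expect_equal(e$scores[k],
                 score_structure(e$members[[k]], st$matrix)$total)
  }
  set.seed(56)
  e2 <- adaptation_run(sphere_init(20), st$matrix, cfg)
  expect_identical(lapply(e2$members, unclass), lapply(e$members, unclass))
})

test_that("a perfect-score structure yields the trivial ensemble", {
  # a structure scoring 100 admits no strict improvement
  coords <- cbind(c(0, 1, 2), 0, 0)
  f <- matrix(1, 3, 3); diag(f) <- 0
  m <- contact_matrix(f, resolution = 1e6)
  t <- score_thresholds(contact_d2 = 7, max_d2 = 20.25, min_d2 = 0.2)
  # with only contacts, NS is n/a; MS denominator penalty avoided by
  # dropping MS weight so the structure scores exactly 100
  cfg <- optimizer_config(adapt_iters = 20L, ensemble_max = 5L,
                          weights = score_weights(2, 2, 3, 0),
                          thresholds = t)
  expect_equal(hicfold:::total_score_fast(coords, m, t,
                                          score_weights(2, 2, 3, 0)), 100)
  set.seed(57)
  e <- adaptation_run(structure3d(coords), m, cfg)
  expect_length(e$members, 1L)
  expect_identical(unclass(e$members[[1]]), coords)
})

test_that("sa_accept implements the Boltzmann rule", {
  set.seed(58)
  expect_true(sa_accept(80, 80, 5))
  expect_true(sa_accept(70, 80, 5))
  expect_error(sa_accept(80, 70, 0), "positive")
  expect_error(sa_accept(80, 70, -1), "positive")
  # T -> 0+: worse solutions effectively never accepted
  expect_false(any(replicate(50, sa_accept(80, 70, 1e-9))))
  # Monte-Carlo estimate of the acceptance frequency at exp(-1)
  acc <- mean(replicate(20000, sa_accept(80, 70, 10)))
  expect_equal(acc, exp(-1), tolerance = 0.025)
})

test_that("sa_run retains per-member best-ever scores deterministically", {
  st <- synthetic_truth(n = 15, seed = 59)
  cfg <- test_config(adapt_iters = 100L, sa_iters = 5L, ensemble_max = 4L)
  set.seed(60)
  e <- adaptation_run(sphere_init(15), st$matrix, cfg)
  expect_identical(sa_run(e, st$matrix,
                          test_config(sa_iters = 0L)), e)
  set.seed(61)
  r1 <- sa_run(e, st$matrix, cfg)
  expect_length(r1$members, length(e$members))
  expect_true(all(r1$scores >= e$scores))
  for (k in seq_along(r1$members)) {
    expect_equal(r1$scores[k],
                 score_structure(r1$members[[k]], st$matrix)$total)
  }
  set.seed(61)
  r2 <- sa_run(e, st$matrix, cfg)
  expect_identical(lapply(r1$members, unclass), lapply(r2$members, unclass))
})

test_that("ga_select keeps the top fraction with stable ties", {
  mk <- function(scores) {
    members <- lapply(seq_along(scores), function(i) {
      structure3d(matrix(i, 2, 3))
    })
    hicfold:::new_ensemble(members, scores)
  }
  e <- mk(c(90, 80, 70, 60))
  expect_equal(ga_select(e, 0.5)$scores, c(90, 80))
  expect_identical(ga_select(e, 1), e)
  # ties broken by earlier index
  e2 <- mk(c(70, 90, 90, 50))
  expect_equal(unclass(ga_select(e2, 0.5)$members[[1]])[1, 1], 2)
  # random scores: equals sort-and-slice oracle
  set.seed(62)
  for (rep in 1:5) {
    sc <- runif(7, 0, 100)
    k <- sample(7, 1)
    got <- ga_select(mk(sc), k / 7)$scores
    expect_equal(sort(got, decreasing = TRUE),
                 sort(sc, decreasing = TRUE)[seq_len(k)])
  }
})

test_that("ga_crossover swaps coordinates at the crossover point", {
  a <- structure3d(cbind(101:105, 0, 0))
  b <- structure3d(cbind(201:205, 0, 0))
  kids <- ga_crossover(a, b, 2)
  expect_equal(unclass(kids[[1]])[, 1], c(101, 102, 203, 204, 205))
  expect_equal(unclass(kids[[2]])[, 1], c(201, 202, 103, 104, 105))

  same <- ga_crossover(a, a, 1)
  expect_identical(unclass(same[[1]]), unclass(a))

  # children partition the parental coordinates exactly
  set.seed(63)
  ca <- matrix(rnorm(30), 10, 3); cb <- matrix(rnorm(30), 10, 3)
  pt <- sample(1:9, 1)
  kids <- ga_crossover(structure3d(ca), structure3d(cb), pt)
  for (i in 1:10) {
    rows <- rbind(unclass(kids[[1]])[i, ], unclass(kids[[2]])[i, ])
    expect_true(all(rows[1, ] == ca[i, ] | rows[1, ] == cb[i, ]))
    expect_equal(rows[1, ] + rows[2, ], ca[i, ] + cb[i, ])
  }

  # multi-point crossover switches parents at every point
  kids <- ga_crossover(a, b, c(1, 3))
  expect_equal(unclass(kids[[1]])[, 1], c(101, 202, 203, 104, 105))

  expect_error(ga_crossover(a, structure3d(cbind(1:4, 0, 0)), 2), "length")
  expect_error(ga_crossover(a, b, 5), "range")
})

test_that("ga_mutate is score-gated and n_mut = 0 is the identity", {
  st <- synthetic_truth(n = 15, seed = 64)
  set.seed(65)
  s <- sphere_init(15)
  base <- score_structure(s, st$matrix)$total
  expect_identical(unclass(ga_mutate(s, st$matrix, 0L)$structure),
                   unclass(s))
  res <- ga_mutate(s, st$matrix, 500L)
  expect_gte(res$score, base)
  expect_equal(res$score, score_structure(res$structure, st$matrix)$total)
})

test_that("ga_run grows then refines; singleton ensembles degenerate safely", {
  st <- synthetic_truth(n = 12, seed = 66)
  set.seed(67)
  e <- adaptation_run(sphere_init(12), st$matrix,
                      test_config(adapt_iters = 100L, ensemble_max = 6L))
  cfg <- test_config(ga_mutations = 200L)
  set.seed(68)
  g <- ga_run(e, st$matrix, cfg)
  expect_gte(max(g$scores), max(e$scores))
  for (k in seq_along(g$members)) {
    expect_equal(g$scores[k],
                 score_structure(g$members[[k]], st$matrix)$total)
  }
  # singleton: selection and crossover are identities, mutation runs
  single <- hicfold:::new_ensemble(e$members[1], e$scores[1])
  set.seed(69)
  g1 <- ga_run(single, st$matrix, cfg)
  expect_length(g1$members, 1L)
  expect_gte(g1$scores[1], single$scores[1])
})

test_that("select_final picks the argmax with lowest-index ties", {
  mk <- function(scores) hicfold:::new_ensemble(
    lapply(seq_along(scores), function(i) structure3d(matrix(i, 2, 3))),
    scores)
  f <- select_final(mk(c(77.5, 81.2)))
  expect_equal(f$score, 81.2)
  expect_equal(unclass(f$structure)[1, 1], 2)
  f2 <- select_final(mk(c(50, 90, 90)))
  expect_equal(unclass(f2$structure)[1, 1], 2)
  expect_equal(select_final(mk(42))$score, 42)
  expect_error(select_final(hicfold:::new_ensemble(list(), numeric(0))),
               "empty")
  set.seed(70)
  sc <- runif(9, 0, 100)
  expect_equal(select_final(mk(sc))$score, max(sc))
})

test_that("structure length is preserved through every stage", {
  st <- synthetic_truth(n = 14, seed = 71)
  cfg <- test_config(adapt_iters = 50L, sa_iters = 2L,
                     ga_mutations = 50L, ensemble_max = 3L, seed = 72L)
  fit <- reconstruct(st$matrix, cfg)
  expect_equal(nrow(fit$structure), 14L)
  for (mem in fit$ensemble$members) expect_equal(nrow(mem), 14L)
})
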