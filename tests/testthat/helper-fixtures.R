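# Random (structure, matrix) instances for oracle-equivalence and
# property tests. Integer frequencies keep oracle/package sums exactly
# comparable; the diagonal is deliberately non-zero to prove exclusion.

rand_instance <- function(n) {
  coords <- matrix(stats::runif(3 * n, -3, 3), n, 3)
  f <- matrix(stats::rpois(n * n, 0.7), n, n)
  f[stats::runif(n * n) < 0.4] <- 0
  f <- f + t(f)
  diag(f) <- stats::rpois(n, 2)
  list(coords = coords,
       m = contact_matrix(f, resolution = 1e6, origin = 0))
}

# Scaled-down optimizer settings for tests: the stage structure and all
# contracts are identical to the full protocol, only iteration counts
# shrink to fit the test-time budget.
test_config <- function(adapt_iters = 2000L, sa_iters = 10L,
                        ga_mutations = 2000L, ensemble_max = 10L, ...) {
  optimizer_config(adapt_iters = adapt_iters, sa_iters = sa_iters,
                   ga_mutations = ga_mutations, ensemble_max = ensemble_max,
                   ...)
}

random_rotation <- function() {
  qr_q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(qr_q) < 0) qr_q[, 1] <- -qr_q[, 1]
  qr_q
}
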