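#' Generate a ground-truth chromosome chain
#'
#' A fixed-bond-length random walk confined to a sphere: each step is an
#' isotropic direction scaled to exactly `bond_len`; directions leading
#' outside the confinement sphere are re-drawn, so every bond has exact
#' length and every point lies inside the sphere. Defaults (bond 1.5 um,
#' confinement radius 6 um against a 7 um^2 squared contact threshold)
#' give chains whose contact maps mix short-range chain neighbours with
#' confinement-induced long-range contacts, the qualitative anatomy of an
#' intra-chromosomal Hi-C map.
#'
#' @param n number of loci.
#' @param bond_len bond length (um).
#' @param confine_r confinement sphere radius (um); must exceed
#'   `bond_len`.
#' @return a `Structure3D`.
#' @export
make_truth <- function(n, bond_len = 1.5, confine_r = 6) {
  if (n < 1L) stop("n must be at least 1")
  if (confine_r <= bond_len) stop("confine_r must exceed bond_len")
  coords <- matrix(0, n, 3L)
  for (i in seq_len(n - 1L) + 1L) {
    repeat {
      dir <- stats::rnorm(3L)
      dir <- dir / sqrt(sum(dir^2))
      cand <- coords[i - 1L, ] + dir * bond_len
      if (sum(cand^2) <= confine_r^2) break
    }
    coords[i, ] <- cand
  }
  structure3d(coords)
}

#' Contact matrix implied by a structure
#'
#' Thresholds the pairwise squared distances of a structure at
#' `contact_d2`: pair (i, j), i != j, is a contact iff
#' `d^2 <= contact_d2`. Frequencies are either binary (1) or
#' over-dispersed counts `1 + rpois(lambda / d^2)`, mimicking the
#' distance decay of Hi-C interaction frequencies. Dropout then zeroes
#' each contact entry independently (symmetrically) with the given rate;
#' the dropped pairs are recorded in attribute `"dropped"`.
#'
#' @param s a `Structure3D`.
#' @param contact_d2 squared contact distance threshold (um^2).
#' @param freq_law `"binary"` or `"poisson"`.
#' @param dropout per-contact dropout probability in \[0, 1).
#' @param lambda intensity of the Poisson law (ignored for binary).
#' @param resolution,origin metadata for the resulting matrix.
#' @return a `ContactMatrix`; attribute `"dropped"` holds a 2-column
#'   matrix of the zeroed (i, j) pairs (i < j).
#' @export
truth_to_matrix <- function(s, contact_d2 = 7,
                            freq_law = c("binary", "poisson"),
                            dropout = 0, lambda = 10,
                            resolution = 1e6, origin = 0) {
  freq_law <- match.arg(freq_law)
  if (contact_d2 <= 0) stop("contact_d2 must be positive")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  coords <- as_coords(s)
  n <- nrow(coords)
  d2 <- as.matrix(stats::dist(coords))^2
  contact <- d2 <= contact_d2
  diag(contact) <- FALSE
  freq <- matrix(0, n, n)
  if (freq_law == "binary") {
    freq[contact] <- 1
  } else {
    ut <- which(upper.tri(contact) & contact, arr.ind = TRUE)
    if (nrow(ut)) {
      counts <- 1 + stats::rpois(nrow(ut), lambda / pmax(d2[ut], 1e-6))
      freq[ut] <- counts
      freq[ut[, c(2L, 1L), drop = FALSE]] <- counts
    }
  }
  dropped <- matrix(integer(0), 0L, 2L)
  if (dropout > 0) {
    ut <- which(upper.tri(freq) & freq > 0, arr.ind = TRUE)
    if (nrow(ut)) {
      hit <- stats::runif(nrow(ut)) < dropout
      dropped <- ut[hit, , drop = FALSE]
      freq[dropped] <- 0
      freq[dropped[, c(2L, 1L), drop = FALSE]] <- 0
    }
  }
  out <- contact_matrix(freq, resolution = resolution, origin = origin)
  attr(out, "dropped") <- dropped
  out
}

#' Generate a synthetic truth: chain plus implied contact matrix
#'
#' Convenience wrapper bundling [make_truth()] and [truth_to_matrix()].
#'
#' @inheritParams make_truth
#' @inheritParams truth_to_matrix
#' @param seed optional integer seed applied before generation.
#' @return a list of class `SyntheticTruth`: `truth` (`Structure3D`),
#'   `matrix` (`ContactMatrix`), and `params`.
#' @export
synthetic_truth <- function(n = 30, bond_len = 1.5, confine_r = 6,
                            contact_d2 = 7, freq_law = "binary",
                            dropout = 0, lambda = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- make_truth(n, bond_len, confine_r)
  m <- truth_to_matrix(truth, contact_d2 = contact_d2, freq_law = freq_law,
                       dropout = dropout, lambda = lambda)
  structure(
    list(truth = truth, matrix = m,
         params = list(n = n, bond_len = bond_len, confine_r = confine_r,
                       contact_d2 = contact_d2, freq_law = freq_law,
                       dropout = dropout, lambda = lambda, seed = seed)),
    class = "SyntheticTruth"
  )
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "SyntheticTruth: %d loci, bond %.2f um, confinement %.1f um, %s contacts, dropout %.2f\n",
    p$n, p$bond_len, p$confine_r, p$freq_law, p$dropout))
  invisible(x)
}
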