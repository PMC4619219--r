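#' Random unit-capped displacement vectors
#'
#' Isotropic directions (normalized standard-normal triples) scaled by a
#' uniform length on \[0, 1) micrometres — the displacement law shared by
#' growth initialization, adaptation moves and GA mutation.
#'
#' @param k number of vectors.
#' @return k x 3 matrix of displacement vectors.
#' @export
random_vectors <- function(k) {
  dir <- matrix(stats::rnorm(3 * k), ncol = 3L)
  dir <- dir / sqrt(rowSums(dir^2))
  dir * stats::runif(k)
}

#' Growth initialization
#'
#' Builds a chain one locus at a time: the first point at the origin, each
#' subsequent point displaced from its predecessor by a random vector of
#' length in \[0, 1) um. Used for large chromosomes (> 200 regions); no
#' self-avoidance is imposed.
#'
#' @param n number of loci (>= 1).
#' @return a `Structure3D`.
#' @export
growth_init <- function(n) {
  if (n < 1L) stop("n must be at least 1")
  structure3d(cpp_growth_init(as.integer(n)))
}

#' Random-sphere initialization
#'
#' Places n points uniformly on the surface of a sphere (default radius
#' 1 um). Used for chromosomes with at most 200 regions.
#'
#' @param n number of loci (>= 1).
#' @param radius sphere radius in micrometres.
#' @return a `Structure3D`.
#' @export
sphere_init <- function(n, radius = 1) {
  if (n < 1L) stop("n must be at least 1")
  dir <- matrix(stats::rnorm(3 * n), ncol = 3L)
  dir <- dir / sqrt(rowSums(dir^2))
  structure3d(dir * radius)
}

#' Choose the initialization strategy for a chromosome size
#'
#' `"growth"` for more than 200 regions, `"sphere"` otherwise (the
#' boundary n = 200 uses the sphere).
#'
#' @param n number of retained regions.
#' @return `"growth"` or `"sphere"`.
#' @export
choose_init <- function(n) {
  if (n < 1L) stop("n must be at least 1")
  if (n > 200L) "growth" else "sphere"
}
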