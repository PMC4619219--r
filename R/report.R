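#' Write a structure as a PDB bead model
#'
#' One CA atom per locus in chain order, consecutive loci connected by
#' CONECT records. Coordinates (micrometres) are multiplied by `scale`
#' and written into the fixed-width PDB coordinate columns, so the
#' read-back is faithful to 3 decimals of the scaled units.
#'
#' @param s a `Structure3D`.
#' @param path output file.
#' @param scale multiplicative factor applied to coordinates before
#'   writing (default 1: micrometre values written as-is).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path, scale = 1) {
  coords <- as_coords(s)
  n <- nrow(coords)
  if (n < 1L) stop("cannot write an empty structure")
  xyz <- coords * scale
  if (any(abs(xyz) > 9999.999)) {
    stop("scaled coordinates exceed PDB fixed-width columns; lower `scale`")
  }
  lines <- character(0)
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      i, i, xyz[i, 1L], xyz[i, 2L], xyz[i, 3L]))
  }
  if (n > 1L) {
    lines <- c(lines, sprintf("CONECT%5d%5d", seq_len(n - 1L), 2:n))
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read a PDB bead model written by [write_pdb()]
#'
#' @param path PDB file.
#' @param scale the scale factor used at write time; coordinates are
#'   divided by it.
#' @return a `Structure3D`.
#' @export
read_pdb <- function(path, scale = 1) {
  lines <- readLines(path)
  atoms <- grep("^(ATOM|HETATM)", lines, value = TRUE)
  if (!length(atoms)) stop("no atom records found")
  xyz <- cbind(as.numeric(substr(atoms, 31L, 38L)),
               as.numeric(substr(atoms, 39L, 46L)),
               as.numeric(substr(atoms, 47L, 54L)))
  structure3d(xyz / scale)
}

#' Write the satisfaction label matrix (heat-map data)
#'
#' Tab-delimited integer matrix over \{0, 1, 2, 3, 4\}: 1 contact
#' satisfied, 2 contact unsatisfied, 3 non-contact satisfied, 4
#' non-contact unsatisfied, 0 diagonal/excluded — the data behind the
#' red / white / light-blue / dark-blue satisfaction heat map.
#'
#' @param labels label matrix from [pair_satisfaction()] or a
#'   `ScoreReport`.
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
heatmap_matrix <- function(labels, path) {
  if (inherits(labels, "ScoreReport")) labels <- labels$labels
  utils::write.table(labels, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Plot the satisfaction heat map
#'
#' Base-graphics rendering with the conventional legend: contact
#' satisfied red, contact unsatisfied white, non-contact satisfied light
#' blue, non-contact unsatisfied dark blue.
#'
#' @param labels label matrix or `ScoreReport`.
#' @param ... passed to [graphics::image()].
#' @export
plot_satisfaction <- function(labels, ...) {
  if (inherits(labels, "ScoreReport")) labels <- labels$labels
  n <- nrow(labels)
  cols <- c("grey85", "red", "white", "lightblue", "darkblue")
  graphics::image(seq_len(n), seq_len(n), t(labels[n:1, , drop = FALSE]),
                  col = cols, breaks = seq(-0.5, 4.5, by = 1),
                  xlab = "region", ylab = "region", ...)
  invisible(NULL)
}

#' Short- vs long-range contact satisfaction
#'
#' Contact satisfaction computed separately over near-diagonal pairs
#' (`|i - j| <= cutoff`) and distal pairs (`|i - j| > cutoff`). A class
#' with no contact pairs reports `NA`.
#'
#' @param labels label matrix from [pair_satisfaction()] or a
#'   `ScoreReport`.
#' @param cutoff band half-width in regions (default 10).
#' @return list with `short_cs` and `long_cs` percentages.
#' @export
range_split <- function(labels, cutoff = 10L) {
  if (inherits(labels, "ScoreReport")) labels <- labels$labels
  n <- nrow(labels)
  band <- abs(row(labels) - col(labels)) <= cutoff
  ut <- upper.tri(labels)
  cs_over <- function(mask) {
    n_contact <- sum(mask & (labels == 1L | labels == 2L))
    if (n_contact == 0L) return(NA_real_)
    100 * sum(mask & labels == 1L) / n_contact
  }
  list(short_cs = cs_over(ut & band), long_cs = cs_over(ut & !band))
}

# Spearman correlation of two models' pairwise-distance matrices:
# superposition-free and invariant to rotation, translation and mirror.
distance_spearman <- function(a, b) {
  da <- as.vector(stats::dist(as_coords(a)))
  db <- as.vector(stats::dist(as_coords(b)))
  stats::cor(da, db, method = "spearman")
}

#' Convergence test: independent runs on the same matrix
#'
#' Runs the full pipeline twice with different seeds and compares the
#' results: both score reports, the absolute total-score gap, and the
#' Spearman correlation of the two models' pairwise-distance matrices.
#'
#' @param m a `ContactMatrix`.
#' @param cfg an [optimizer_config()] (its `seed` is overridden).
#' @param seeds integer vector of two seeds.
#' @return a list: `fit_a`, `fit_b`, `score_gap`, `spearman`.
#' @export
convergence_test <- function(m, cfg = optimizer_config(), seeds = c(1L, 2L)) {
  stopifnot(length(seeds) == 2L)
  cfg_a <- cfg; cfg_a$seed <- seeds[1L]
  cfg_b <- cfg; cfg_b$seed <- seeds[2L]
  fit_a <- reconstruct(m, cfg_a)
  fit_b <- reconstruct(m, cfg_b)
  list(fit_a = fit_a, fit_b = fit_b,
       score_gap = abs(fit_a$report$total - fit_b$report$total),
       spearman = distance_spearman(fit_a$structure, fit_b$structure))
}

#' Robustness-by-recovery test
#'
#' Builds model A from the input matrix, derives the binary contact
#' matrix A implies at the contact threshold, rebuilds model B from that
#' derived matrix, and compares: the A-vs-B distance-matrix Spearman
#' correlation and B's CS/NS against the derived (A-implied) matrix.
#'
#' @param m a `ContactMatrix`.
#' @param cfg an [optimizer_config()].
#' @param seed seed for the A build; the B build uses `seed + 1`.
#' @return a list: `fit_a`, `fit_b`, `derived_matrix`, `spearman`,
#'   `recovered_cs`, `recovered_ns`.
#' @export
recovery_test <- function(m, cfg = optimizer_config(), seed = 1L) {
  cfg_a <- cfg; cfg_a$seed <- seed
  fit_a <- reconstruct(m, cfg_a)
  derived <- truth_to_matrix(fit_a$structure,
                             contact_d2 = cfg$thresholds$contact_d2,
                             freq_law = "binary", dropout = 0,
                             resolution = m$resolution, origin = m$origin)
  cfg_b <- cfg; cfg_b$seed <- seed + 1L
  fit_b <- reconstruct(derived, cfg_b)
  list(fit_a = fit_a, fit_b = fit_b, derived_matrix = derived,
       spearman = distance_spearman(fit_a$structure, fit_b$structure),
       recovered_cs = fit_b$report$cs, recovered_ns = fit_b$report$ns)
}
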