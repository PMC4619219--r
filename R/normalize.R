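#' Normalize a ContactMatrix
#'
#' Two matrix-balancing schemes are offered. `"ice"` is iterative
#' correction: the matrix is repeatedly divided by the outer product of
#' its marginal sums (rescaled to mean 1 over non-empty rows) until the
#' maximum relative deviation of the marginals from their mean falls below
#' `tol`. `"coverage"` is single-pass square-root (vanilla) coverage
#' normalization, `freq[i,j] / sqrt(rowsum_i * rowsum_j)`. All-zero rows
#' are excluded from balancing and left untouched.
#'
#' @param m a `ContactMatrix`.
#' @param method `"ice"`, `"coverage"` or `"none"`.
#' @param tol convergence tolerance on the marginals (ICE only).
#' @param max_iter maximum balancing iterations (ICE only); on
#'   non-convergence a warning reports the residual and the best iterate
#'   is returned.
#' @return a `ContactMatrix` with real-valued `freq`.
#' @export
normalize_matrix <- function(m, method = c("none", "ice", "coverage"),
                             tol = 1e-6, max_iter = 200L) {
  stopifnot(inherits(m, "ContactMatrix"))
  method <- match.arg(method)
  if (method == "none") return(m)
  freq <- m$freq
  nz <- rowSums(freq) > 0
  if (method == "coverage") {
    s <- rowSums(freq)
    d <- sqrt(s)
    d[!nz] <- 1  # leave empty rows untouched
    freq <- freq / outer(d, d)
  } else {
    resid <- Inf
    for (it in seq_len(max_iter)) {
      s <- rowSums(freq)
      snorm <- s / mean(s[nz])
      snorm[!nz] <- 1
      resid <- max(abs(snorm[nz] - 1))
      if (resid < tol) break
      freq <- freq / outer(snorm, snorm)
    }
    if (resid >= tol) {
      warning(sprintf(
        "ICE did not converge in %d iterations (residual %.3g); returning best iterate",
        max_iter, resid))
    }
  }
  freq <- (freq + t(freq)) / 2  # guard symmetry against rounding
  contact_matrix(freq, resolution = m$resolution, origin = m$origin,
                 gap_mask = m$gap_mask, region_index = m$region_index)
}

#' Write / read a ContactMatrix as dense tab-delimited text
#'
#' Metadata (resolution, origin, gap mask, region index) is carried in
#' `#key=value` header lines so the read-back reconstructs the full
#' object.
#'
#' @param m a `ContactMatrix`.
#' @param path output file.
#' @return `write_contact_matrix` returns `path` invisibly;
#'   `read_contact_matrix` returns a `ContactMatrix`.
#' @export
write_contact_matrix <- function(m, path) {
  stopifnot(inherits(m, "ContactMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("#resolution=%.15g", m$resolution),
    sprintf("#origin=%.15g", m$origin),
    sprintf("#gap_mask=%s", paste(as.integer(m$gap_mask), collapse = ",")),
    sprintf("#region_index=%s", paste(m$region_index, collapse = ","))
  ), con)
  utils::write.table(m$freq, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_matrix
#' @export
read_contact_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^#%s=", key), "",
                           grep(sprintf("^#%s=", key), hdr, value = TRUE)[1L])
  freq <- as.matrix(utils::read.table(text = lines[!grepl("^#", lines)],
                                      sep = "\t"))
  dimnames(freq) <- NULL
  contact_matrix(
    freq,
    resolution = as.numeric(get("resolution")),
    origin = as.numeric(get("origin")),
    gap_mask = as.logical(as.integer(strsplit(get("gap_mask"), ",")[[1L]])),
    region_index = as.integer(strsplit(get("region_index"), ",")[[1L]])
  )
}

#' Write / read a ContactMatrix in sparse triplet format
#'
#' One `i j value` line per non-zero upper-triangle (and diagonal) entry,
#' 1-based retained-row indices, with the same `#key=value` metadata
#' header as the dense writer plus `#n=` for the dimension.
#'
#' @inheritParams write_contact_matrix
#' @export
write_contact_triplets <- function(m, path) {
  stopifnot(inherits(m, "ContactMatrix"))
  idx <- which(upper.tri(m$freq, diag = TRUE) & m$freq != 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("#n=%d", n_regions(m)),
    sprintf("#resolution=%.15g", m$resolution),
    sprintf("#origin=%.15g", m$origin),
    sprintf("#gap_mask=%s", paste(as.integer(m$gap_mask), collapse = ",")),
    sprintf("#region_index=%s", paste(m$region_index, collapse = ","))
  ), con)
  if (nrow(idx)) {
    writeLines(sprintf("%d\t%d\t%.15g", idx[, 1L], idx[, 2L],
                       m$freq[idx]), con)
  }
  invisible(path)
}

#' @rdname write_contact_triplets
#' @export
read_contact_triplets <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^#%s=", key), "",
                           grep(sprintf("^#%s=", key), hdr, value = TRUE)[1L])
  n <- as.integer(get("n"))
  freq <- matrix(0, n, n)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body)) {
    trip <- utils::read.table(text = body, sep = "\t")
    for (k in seq_len(nrow(trip))) {
      i <- trip[k, 1L]; j <- trip[k, 2L]
      freq[i, j] <- trip[k, 3L]
      freq[j, i] <- trip[k, 3L]
    }
  }
  contact_matrix(
    freq,
    resolution = as.numeric(get("resolution")),
    origin = as.numeric(get("origin")),
    gap_mask = as.logical(as.integer(strsplit(get("gap_mask"), ",")[[1L]])),
    region_index = as.integer(strsplit(get("region_index"), ",")[[1L]])
  )
}
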