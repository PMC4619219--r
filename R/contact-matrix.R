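#' Construct a ContactMatrix
#'
#' A `ContactMatrix` holds a symmetric, non-negative interaction-frequency
#' matrix over fixed-length genomic regions (loci), together with the bin
#' resolution, the genomic coordinate of region 0, a gap mask over the
#' original (pre-omission) regions, and the mapping from retained matrix
#' rows back to original region numbers.
#'
#' @param freq symmetric non-negative numeric matrix (interaction
#'   frequencies; counts before normalization, reals after).
#' @param resolution region length in base pairs.
#' @param origin genomic coordinate (bp) of original region 0.
#' @param gap_mask logical vector over the original regions, `TRUE` where a
#'   region has been omitted. Defaults to no omissions.
#' @param region_index integer vector mapping retained row `k` to its
#'   original (1-based) region number. Defaults to `1:nrow(freq)`.
#' @return an object of class `ContactMatrix`.
#' @export
contact_matrix <- function(freq, resolution, origin = 0,
                           gap_mask = NULL, region_index = NULL) {
  freq <- as.matrix(freq)
  if (nrow(freq) != ncol(freq)) stop("freq must be square")
  if (any(freq < 0)) stop("freq must be non-negative")
  if (max(abs(freq - t(freq))) > 1e-8) stop("freq must be symmetric")
  if (resolution <= 0) stop("resolution must be positive")
  n <- nrow(freq)
  if (is.null(region_index)) region_index <- seq_len(n)
  if (length(region_index) != n) stop("region_index length must match freq")
  if (is.null(gap_mask)) gap_mask <- rep(FALSE, max(region_index, n))
  if (sum(!gap_mask) != n) stop("gap_mask inconsistent with retained count")
  structure(
    list(freq = freq, resolution = as.numeric(resolution),
         origin = as.numeric(origin), gap_mask = gap_mask,
         region_index = as.integer(region_index)),
    class = "ContactMatrix"
  )
}

#' Number of retained regions of a ContactMatrix
#' @param m a `ContactMatrix`.
#' @return integer count of retained regions (matrix dimension).
#' @export
n_regions <- function(m) nrow(m$freq)

#' @export
print.ContactMatrix <- function(x, ...) {
  n <- n_regions(x)
  cat(sprintf(
    "ContactMatrix: %d retained regions (of %d), resolution %s bp, origin %s\n",
    n, length(x$gap_mask), format(x$resolution, big.mark = ","),
    format(x$origin, big.mark = ",")))
  cat(sprintf("  total IF (off-diagonal, upper triangle): %g\n",
              sum(x$freq[upper.tri(x$freq)])))
  invisible(x)
}

#' Parse an intra-chromosomal contact list
#'
#' Reads a whitespace/tab-delimited contact list with one record per line:
#' `chrom pos_a pos_b`. Lines starting with `#` and blank lines are
#' skipped. Only records whose chromosome matches `chrom` are returned;
#' records on other chromosomes (including inter-chromosomal pairs encoded
#' on other identifiers) are filtered out.
#'
#' @param x a file path or a character vector of lines.
#' @param chrom chromosome identifier to retain (e.g. `"chr22"`).
#' @return a `data.frame` with columns `chrom`, `pos_a`, `pos_b`.
#' @export
parse_contacts <- function(x, chrom) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  out_chrom <- character(0)
  pos_a <- numeric(0)
  pos_b <- numeric(0)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx)) {
    fields <- strsplit(trimws(lines[idx]), "[ \t]+")
    nf <- lengths(fields)
    if (any(nf < 3L)) {
      bad <- idx[which(nf < 3L)[1L]]
      stop(sprintf("malformed contact line %d: fewer than 3 fields", bad))
    }
    cs <- vapply(fields, `[[`, "", 1L)
    pa <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
    pb <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    bad <- which(!is.finite(pa) | !is.finite(pb) | pa < 0 | pb < 0 |
                   pa != floor(pa) | pb != floor(pb))
    if (length(bad)) {
      stop(sprintf(
        "malformed contact line %d: coordinates must be non-negative integers",
        idx[bad[1L]]))
    }
    sel <- cs == chrom
    out_chrom <- cs[sel]
    pos_a <- pa[sel]
    pos_b <- pb[sel]
  }
  if (!length(out_chrom)) {
    warning(sprintf("no contacts found for chromosome '%s'", chrom))
  }
  data.frame(chrom = out_chrom, pos_a = pos_a, pos_b = pos_b,
             stringsAsFactors = FALSE)
}

#' Bin contact records into a ContactMatrix
#'
#' The genomic span is the highest minus the lowest coordinate observed
#' (or minus `origin` when overridden), divided into half-open bins of
#' `resolution` bp. Each record increments `freq[i, j]` and `freq[j, i]`
#' by one, so a record whose two ends fall in the same bin adds 2 to that
#' diagonal entry and the invariant
#' `sum(upper.tri) + sum(diag)/2 == n_records` holds.
#'
#' @param records data.frame from [parse_contacts()].
#' @param resolution bin size in base pairs (default 1 Mb).
#' @param origin coordinate of region 0; defaults to the lowest coordinate
#'   observed in `records`. Pass `0` for dataset-independent binning.
#' @return a `ContactMatrix` of raw counts.
#' @export
build_matrix <- function(records, resolution = 1e6, origin = NULL) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("cannot build a contact matrix from an empty record list")
  }
  if (resolution <= 0) stop("resolution must be positive")
  pos <- c(records$pos_a, records$pos_b)
  if (is.null(origin)) origin <- min(pos)
  if (any(pos < origin)) stop("coordinates below the chosen origin")
  span <- max(pos) - origin
  n <- max(1L, as.integer(ceiling(span / resolution)))
  bin <- function(p) pmin(floor((p - origin) / resolution), n - 1L) + 1L
  i <- bin(records$pos_a)
  j <- bin(records$pos_b)
  freq <- matrix(0, n, n)
  tab <- table(factor(i, levels = seq_len(n)), factor(j, levels = seq_len(n)))
  freq <- unclass(tab) + t(unclass(tab))
  dimnames(freq) <- NULL
  contact_matrix(freq, resolution = resolution, origin = origin)
}

#' Read BED-style gap intervals
#'
#' @param path BED file (`chrom start end`, 0-based half-open).
#' @param chrom optional chromosome filter.
#' @return data.frame with columns `start`, `end`, sorted, non-overlapping
#'   intervals merged.
#' @export
read_gaps_bed <- function(path, chrom = NULL) {
  bed <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 3L) stop("BED file must have at least 3 columns")
  if (!is.null(chrom)) bed <- bed[bed[[1L]] == chrom, , drop = FALSE]
  iv <- data.frame(start = as.numeric(bed[[2L]]), end = as.numeric(bed[[3L]]))
  iv <- iv[order(iv$start), , drop = FALSE]
  if (nrow(iv) > 1L) {  # merge overlaps so downstream code can assume disjoint
    merged <- iv[1L, , drop = FALSE]
    for (k in 2L:nrow(iv)) {
      last <- nrow(merged)
      if (iv$start[k] <= merged$end[last]) {
        merged$end[last] <- max(merged$end[last], iv$end[k])
      } else {
        merged <- rbind(merged, iv[k, ])
      }
    }
    iv <- merged
  }
  rownames(iv) <- NULL
  iv
}

#' Remove centromere/gap regions from a ContactMatrix
#'
#' Rows and columns whose genomic interval overlaps a gap interval are
#' deleted. With `gaps = "auto"` the single longest contiguous run of
#' all-zero rows is removed (centromeres leave no mappable Hi-C signal);
#' if no row is all-zero the matrix is returned unchanged.
#'
#' @param m a `ContactMatrix`.
#' @param gaps a data.frame with `start`/`end` columns (bp, half-open),
#'   `"auto"`, or `NULL`/empty for a no-op.
#' @return a `ContactMatrix` with the surviving rows; `gap_mask` and
#'   `region_index` record the omissions against the original regions.
#' @export
remove_gaps <- function(m, gaps = "auto") {
  stopifnot(inherits(m, "ContactMatrix"))
  n <- n_regions(m)
  if (is.null(gaps) || (is.data.frame(gaps) && nrow(gaps) == 0L)) return(m)
  if (identical(gaps, "auto")) {
    zero <- rowSums(m$freq) == 0
    if (!any(zero)) return(m)
    r <- rle(zero)
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    drop <- seq(starts[best], ends[best])
  } else {
    reg_start <- m$origin + (m$region_index - 1L) * m$resolution
    reg_end <- reg_start + m$resolution
    drop <- which(vapply(seq_len(n), function(k) {
      any(gaps$start < reg_end[k] & gaps$end > reg_start[k])
    }, logical(1L)))
    if (!length(drop)) return(m)
  }
  if (length(drop) == n) stop("gap annotation removes every region")
  keep <- setdiff(seq_len(n), drop)
  gap_mask <- m$gap_mask
  gap_mask[m$region_index[drop]] <- TRUE
  contact_matrix(m$freq[keep, keep, drop = FALSE],
                 resolution = m$resolution, origin = m$origin,
                 gap_mask = gap_mask,
                 region_index = m$region_index[keep])
}
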