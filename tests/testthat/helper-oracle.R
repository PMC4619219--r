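# Independent brute-force scoring oracle: plain double loops over all
# pairs, no shared code with the package's scoring path.

oracle_labels <- function(coords, freq, contact_d2 = 7) {
  n <- nrow(coords)
  lab <- matrix(0L, n, n)
  d2m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d2 <- sum((coords[i, ] - coords[j, ])^2)
      d2m[i, j] <- d2
      lab[i, j] <- if (freq[i, j] > 0) {
        if (d2 <= contact_d2) 1L else 2L
      } else {
        if (d2 > contact_d2) 3L else 4L
      }
    }
  }
  list(labels = lab, d2 = d2m)
}

oracle_scores <- function(coords, freq, contact_d2 = 7, max_d2 = 20.25,
                          min_d2 = 0.2, w = c(2, 2, 3, 1)) {
  n <- nrow(coords)
  c_sat <- 0L; c_tot <- 0L; nc_sat <- 0L; nc_tot <- 0L
  if_sat <- 0; if_tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d2 <- sum((coords[i, ] - coords[j, ])^2)
      if (freq[i, j] > 0) {
        c_tot <- c_tot + 1L
        if_tot <- if_tot + freq[i, j]
        if (d2 <= contact_d2) {
          c_sat <- c_sat + 1L
          if_sat <- if_sat + freq[i, j]
        }
      } else {
        nc_tot <- nc_tot + 1L
        if (d2 > contact_d2) nc_sat <- nc_sat + 1L
      }
    }
  }
  ms_sat <- 0L
  for (k in seq_len(n - 1L)) {
    b2 <- sum((coords[k, ] - coords[k + 1L, ])^2)
    if (b2 >= min_d2 && b2 <= max_d2) ms_sat <- ms_sat + 1L
  }
  cs <- if (c_tot > 0) 100 * c_sat / c_tot else NA_real_
  ns <- if (nc_tot > 0) 100 * nc_sat / nc_tot else NA_real_
  ifs <- if (if_tot > 0) 100 * if_sat / if_tot else NA_real_
  ms <- if (n >= 2) 100 * ms_sat / n else NA_real_
  s <- c(cs, ns, ifs, ms)
  ok <- !is.na(s)
  list(cs = cs, ns = ns, if_score = ifs, ms = ms,
       total = sum(w[ok] * s[ok]) / sum(w[ok]))
}
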