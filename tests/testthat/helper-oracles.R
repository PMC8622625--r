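# Independent oracles used across the suite. These deliberately take the
# slow, direct route (exhaustive pair enumeration, brute-force clustering)
# so they share no code with the implementation they check.

# Kendall tau-b by exhaustive enumeration of all index pairs, with missing
# entries treated as a shared value below every observed one.
oracle_ici_tau <- function(x, y) {
  sub <- function(v) {
    m <- is.na(v)
    v[m] <- if (all(m)) 0 else min(v[!m]) - 1
    v
  }
  x <- sub(x); y <- sub(y)
  n <- length(x)
  C <- D <- Tx <- Ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0) Tx <- Tx + 1
      if (dy == 0) Ty <- Ty + 1
      if (dx * dy > 0) C <- C + 1 else if (dx * dy < 0) D <- D + 1
    }
  }
  P <- n * (n - 1) / 2
  den <- sqrt((P - Tx) * (P - Ty))
  if (den == 0) NaN else (C - D) / den
}

# All-pairs single-linkage m/z clustering at a ppm tolerance: peaks i, j
# are linked iff |mz_i - mz_j| <= tol_ppm * 1e-6 * mean(mz_i, mz_j);
# groups are the connected components of the link graph.
oracle_single_linkage <- function(mz, tol_ppm) {
  n <- length(mz)
  comp <- seq_len(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (abs(mz[i] - mz[j]) <= tol_ppm * 1e-6 * mean(c(mz[i], mz[j]))) {
        old <- comp[j]
        comp[comp == old] <- comp[i]
      }
    }
  }
  match(comp, unique(comp))
}

# Tukey five-number-summary hinges computed from first principles:
# medians of the lower/upper halves, the overall median belonging to both
# halves when n is odd.
oracle_hinges <- function(v) {
  v <- sort(v)
  n <- length(v)
  half <- ceiling(n / 2)
  c(median(v[seq_len(half)]), median(v[seq(n - half + 1, n)]))
}

# Minimal hand-built assigned peak table (long format, one row per
# candidate) for correspondence tests.
make_peaks <- function(mz, intensity = rep(1, length(mz)),
                       emf = rep("C10H20O2", length(mz)),
                       isotopologue = rep(0L, length(mz)),
                       adduct = rep("H", length(mz)),
                       category = rep("GP", length(mz)),
                       multi_class = rep(FALSE, length(mz)),
                       peak_id = NULL) {
  data.frame(
    peak_id = peak_id %||% seq_along(mz), mz = mz, intensity = intensity,
    emf = emf, isotopologue = isotopologue, adduct = adduct,
    category = category, multi_class = multi_class, stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-class metadata table for a set of sample ids.
make_metadata <- function(sample_ids, classes,
                          instrument = rep("Fusion1", length(sample_ids))) {
  data.frame(sample_id = sample_ids, patient_id = sample_ids,
             class = classes, instrument = instrument,
             statin = FALSE, stringsAsFactors = FALSE)
}
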