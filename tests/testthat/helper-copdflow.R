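# Shared fixtures and independent oracles for the test suite.

# Memoized default config (data files load once per test run).
test_config <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) cfg <<- engine_config()
    cfg
  }
})

# Three reproducible attempts around typical adult values.
good_attempts <- function() {
  tibble::tibble(fvc = c(3.30, 3.20, 3.10), fev1 = c(2.20, 2.10, 2.05))
}

# Brute-force pairwise oracle for the two-best reproducibility rule:
# a session passes iff there is a pair of attempts that are the two largest
# values of the parameter (every other attempt is <= the smaller of the pair)
# whose difference is within the threshold — checked for FVC and FEV1
# independently by enumerating all pairs.
oracle_two_best_ok <- function(values, threshold) {
  n <- length(values)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pair_min <- min(values[i], values[j])
      others <- values[-c(i, j)]
      if (all(others <= pair_min) &&
          abs(values[i] - values[j]) <= threshold + 1e-9) {
        return(TRUE)
      }
    }
  }
  FALSE
}

oracle_reproducible <- function(fvc, fev1, threshold = 0.15) {
  oracle_two_best_ok(fvc, threshold) && oracle_two_best_ok(fev1, threshold)
}

# Vectorised pairwise oracle over matrices of attempt triples (n x 3).
oracle_reproducible_grid <- function(v, threshold) {
  a <- v[, 1]; b <- v[, 2]; c3 <- v[, 3]
  thr <- threshold + 1e-9
  (pmin(a, b) >= c3 & abs(a - b) <= thr) |
    (pmin(a, c3) >= b & abs(a - c3) <= thr) |
    (pmin(b, c3) >= a & abs(b - c3) <= thr)
}

# Independent BODE/BODEx component-point oracles, written directly from the
# published band definitions (not via the package's band-lookup machinery).
oracle_bmi_points <- function(x) ifelse(x > 21, 0L, 1L)
oracle_fev1_points <- function(x) {
  ifelse(x >= 65, 0L, ifelse(x >= 50, 1L, ifelse(x >= 36, 2L, 3L)))
}
oracle_mmrc_points <- function(x) {
  ifelse(x <= 1, 0L, ifelse(x == 2, 1L, ifelse(x == 3, 2L, 3L)))
}
oracle_walk_points <- function(x) {
  ifelse(x >= 350, 0L, ifelse(x >= 250, 1L, ifelse(x >= 150, 2L, 3L)))
}
oracle_exac_points <- function(x) {
  ifelse(x < 1, 0L, ifelse(x < 3, 1L, 2L))
}

# Independent Jaccard oracle using basic membership arithmetic.
oracle_jaccard <- function(features, profile) {
  inter <- sum(profile %in% features)
  uni <- length(profile) + sum(!(features %in% profile))
  if (uni == 0) 0 else inter / uni
}

# Lattice of staging inputs at every cut-point boundary (+/- epsilon).
staging_lattice <- function(walk = TRUE) {
  grid <- expand.grid(
    bmi = c(16, 20.99, 21, 21.01, 28),
    fev1_pct = c(20, 35.99, 36, 49.99, 50, 64.99, 65, 90),
    mmrc = 0:4,
    exacerbations = 0:4,
    KEEP.OUT.ATTRS = FALSE
  )
  if (walk) {
    grid <- merge(grid, data.frame(
      six_mwd = c(100, 149.99, 150, 249.99, 250, 349.99, 350, 450)))
  }
  tibble::as_tibble(grid)
}
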