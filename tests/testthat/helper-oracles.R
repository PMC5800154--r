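# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the spline oracle is the raw Cox-de Boor
# recursion, the Moran oracle a literal double loop over the formula.

# full clamped cubic B-spline family on [min(times), max(times)] with the
# given interior knots, evaluated by the Cox-de Boor recursion
cox_de_boor_basis <- function(x, interior, lo, hi, degree = 3L) {
  U <- c(rep(lo, degree + 1L), sort(interior), rep(hi, degree + 1L))
  nb <- length(U) - degree - 1L
  one <- function(i, p, t) {
    if (p == 0L) {
      # half-open spans; the final span is closed so the basis covers t = hi
      if (U[i] <= t && (t < U[i + 1L] || (t == hi && U[i + 1L] == hi && U[i] < hi)))
        return(1)
      return(0)
    }
    left <- 0
    if (U[i + p] > U[i])
      left <- (t - U[i]) / (U[i + p] - U[i]) * one(i, p - 1L, t)
    right <- 0
    if (U[i + p + 1L] > U[i + 1L])
      right <- (U[i + p + 1L] - t) / (U[i + p + 1L] - U[i + 1L]) * one(i + 1L, p - 1L, t)
    left + right
  }
  out <- matrix(0, length(x), nb)
  for (r in seq_along(x)) for (i in seq_len(nb)) out[r, i] <- one(i, degree, x[r])
  out
}

# the package's centered no-intercept basis, rebuilt from the oracle
oracle_centered_basis <- function(times, interior) {
  full <- cox_de_boor_basis(times, interior, min(times), max(times))
  B <- full[, -1L, drop = FALSE]
  sweep(B, 2L, colMeans(B))
}

# double-loop Moran's I
moran_brute <- function(values, w) {
  N <- length(values)
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) num <- num + w[i, j] * z[i] * z[j]
  (N / sum(w)) * num / sum(z^2)
}

# tiny two-gender panel used by several file-level tests
toy_panel <- function() {
  counts_panel(regions = c("A", "B", "C"),
               waves = c(2000L, 2005L, 2010L),
               genders = c("male", "female"),
               Y = array(c(1:9, 9:1), c(2, 3, 3)),
               n = array(20L, c(2, 3, 3)))
}

# ring adjacency over N labelled regions
ring_adjacency <- function(N, labels = LETTERS[seq_len(N)]) {
  W <- matrix(0, N, N)
  for (i in seq_len(N)) {
    W[i, i %% N + 1L] <- 1
    W[i %% N + 1L, i] <- 1
  }
  adjacency(labels, W)
}

# forge a minimal scm_fit whose draws are fully controlled by the test
forge_fit <- function(draws, spec, regions, waves, genders = c("male", "female")) {
  J <- length(genders); N <- length(regions); T_ <- length(waves)
  panel <- counts_panel(regions, waves, genders,
                        Y = array(1L, c(J, N, T_)), n = array(2L, c(J, N, T_)))
  basis <- spline_basis(waves, spec$interior_knots)
  structure(list(chains = list(draws), deviance = list(rep(0, nrow(draws))),
                 param_names = colnames(draws), psrf = NULL,
                 Dbar = 0, pD = 0, DIC = 0, spec = spec, basis = basis,
                 panel = panel),
            class = "scm_fit")
}
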