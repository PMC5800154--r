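#' Prevalence table over panel margins
#'
#' Aggregated prevalence 100 * sum(Y) / sum(n) over the requested margins,
#' reported in percent to two decimals (half-up, matching conventional
#' survey-table formatting).
#'
#' @param panel a \code{\link{counts_panel}}.
#' @param by character vector naming grouping axes, a subset of
#'   \code{c("gender", "region", "wave")}; empty = overall prevalence.
#' @return data.frame with the grouping columns plus \code{cases}, \code{n}
#'   and \code{prevalence} (percent, 2 dp).
#' @export
prevalence <- function(panel, by = c("region", "wave")) {
  stopifnot(inherits(panel, "counts_panel"))
  if (length(by))
    by <- match.arg(by, c("gender", "region", "wave"), several.ok = TRUE)
  g <- expand.grid(gender = panel$genders, region = panel$regions,
                   wave = panel$waves, stringsAsFactors = FALSE)
  g$cases <- as.vector(panel$Y); g$den <- as.vector(panel$n)
  if (length(by) == 0L) {
    out <- data.frame(cases = sum(g$cases), n = sum(g$den))
  } else {
    agg <- stats::aggregate(cbind(cases, den) ~ ., data = g[, c(by, "cases", "den")],
                            FUN = sum)
    out <- agg[do.call(order, agg[by]), , drop = FALSE]
    names(out)[names(out) == "den"] <- "n"
  }
  if (any(out$n == 0)) {
    bad <- out[out$n == 0, by, drop = FALSE]
    stop("zero denominator for margin: ",
         paste(apply(bad, 1L, paste, collapse = "/"), collapse = ", "))
  }
  out$prevalence <- round_half_up(100 * out$cases / out$n, 2L)
  rownames(out) <- NULL
  out
}

# deterministic half-up rounding (round() is round-half-even); tiny epsilon
# guards binary representation of exact halves like 0.125
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Expected counts by indirect age standardization
#'
#' E[j,i,t] = sum_a n[j,i,t,a] * r[j,a], where r are age-specific reference
#' rates. By default the reference rates are computed from the panel itself
#' by pooling all regions at the reference wave, per gender and age group.
#'
#' @param age_panel an \code{\link{age_stratified_panel}}.
#' @param reference_wave calendar year of the reference wave (default: first
#'   wave).
#' @param reference_rates optional matrix (J x A, dimnames gender x age
#'   group) of externally supplied rates in [0, 1]; overrides the pooled
#'   computation.
#' @return Numeric array E of dim c(J, N, T) with dimnames.
#' @export
expected_counts <- function(age_panel, reference_wave = NULL,
                            reference_rates = NULL) {
  stopifnot(inherits(age_panel, "age_stratified_panel"))
  J <- length(age_panel$genders); N <- length(age_panel$regions)
  Tn <- length(age_panel$waves); A <- length(age_panel$age_groups)
  if (is.null(reference_rates)) {
    if (is.null(reference_wave)) reference_wave <- age_panel$waves[1L]
    tr <- match(reference_wave, age_panel$waves)
    if (is.na(tr)) stop("reference wave ", reference_wave, " not in panel")
    # pool regions at the reference wave: r[j,a]
    Yref <- apply(age_panel$Y[, , tr, , drop = FALSE], c(1L, 4L), sum)
    nref <- apply(age_panel$n[, , tr, , drop = FALSE], c(1L, 4L), sum)
    if (any(nref == 0)) stop("empty age stratum at reference wave")
    reference_rates <- Yref / nref
  } else {
    reference_rates <- as.matrix(reference_rates)
    if (!is.null(colnames(reference_rates))) {
      miss <- setdiff(age_panel$age_groups, colnames(reference_rates))
      if (length(miss)) stop("age group(s) absent from reference rates: ",
                             paste(miss, collapse = ", "))
      reference_rates <- reference_rates[, age_panel$age_groups, drop = FALSE]
    }
    if (!all(dim(reference_rates) == c(J, A)))
      stop("reference_rates must be J x A")
    if (any(reference_rates < 0 | reference_rates > 1))
      stop("reference rates must lie in [0, 1]")
  }
  E <- array(0, c(J, N, Tn),
             dimnames = list(age_panel$genders, age_panel$regions, age_panel$waves))
  for (a in seq_len(A)) {
    na <- array(age_panel$n[, , , a, drop = FALSE], c(J, N, Tn))
    E <- E + na * reference_rates[, a]   # recycles over the gender axis
  }
  E
}

#' Standardized prevalence ratios (indirect standardization)
#'
#' SPR[j,i,t] = Y[j,i,t] / E[j,i,t] with E from
#' \code{\link{expected_counts}}. SPR = 1 means the cell's case load matches
#' what the reference age-specific rates predict from its age structure.
#'
#' @inheritParams expected_counts
#' @return data.frame with columns gender, region, year, Y, E, spr.
#' @export
spr <- function(age_panel, reference_wave = NULL, reference_rates = NULL) {
  E <- expected_counts(age_panel, reference_wave, reference_rates)
  Y <- apply(age_panel$Y, c(1L, 2L, 3L), sum)
  if (any(E == 0 & Y > 0)) stop("undefined SPR: expected count 0 with observed cases")
  g <- expand.grid(gender = age_panel$genders, region = age_panel$regions,
                   year = age_panel$waves, stringsAsFactors = FALSE)
  g$Y <- as.vector(Y); g$E <- as.vector(E)
  g$spr <- ifelse(g$E > 0, g$Y / g$E, NA_real_)
  g
}

#' Moran's I with permutation inference
#'
#' Global spatial autocorrelation I = (N / S0) * (z' W z) / (z' z) with z the
#' centered values and S0 the sum of all weights. Significance is assessed by
#' a two-sided permutation test that shuffles values across regions:
#' pseudo-p = (#\{|I_perm| >= |I_obs|\} + 1) / (n_perm + 1).
#'
#' @param values numeric vector, one value per region of \code{W}.
#' @param W an \code{\link{adjacency}}.
#' @param standardize \code{"row"} (default; each region's weights sum to 1,
#'   the GeoDa default) or \code{"binary"}.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for the permutation draw.
#' @param alternative only \code{"two.sided"} is offered.
#' @return An object of class \code{moran_result}: list with \code{I},
#'   \code{p_value}, \code{n_perm}, \code{seed}, \code{I_perm}.
#' @export
morans_i <- function(values, W, standardize = c("row", "binary"),
                     n_perm = 999L, seed = 1L, alternative = "two.sided") {
  stopifnot(inherits(W, "adjacency"))
  standardize <- match.arg(standardize)
  alternative <- match.arg(alternative, "two.sided")
  N <- length(W$regions)
  if (!is.null(names(values))) {
    if (!setequal(names(values), W$regions))
      stop("names of values do not match adjacency regions")
    values <- values[W$regions]
  }
  if (length(values) != N) stop("values length does not match adjacency regions")
  if (N < 3L) stop("Moran's I needs at least 3 regions")
  if (stats::var(values) == 0) stop("zero variance: values are constant")
  w <- W$W
  if (standardize == "row") {
    rs <- rowSums(w)
    if (any(rs == 0)) stop("row-standardization impossible: isolated region")
    w <- w / rs
  }
  S0 <- sum(w)
  moran_stat <- function(x) {
    z <- x - mean(x)
    (N / S0) * drop(crossprod(z, w %*% z)) / sum(z^2)
  }
  I_obs <- moran_stat(values)
  I_perm <- numeric(n_perm)
  if (n_perm > 0L) {
    set.seed(seed)
    for (b in seq_len(n_perm)) I_perm[b] <- moran_stat(sample(values))
  }
  p <- (sum(abs(I_perm) >= abs(I_obs) - 1e-12) + 1) / (n_perm + 1)
  structure(list(I = I_obs, p_value = p, n_perm = n_perm, seed = seed,
                 I_perm = I_perm),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f, permutation p = %.4f (%d permutations)\n",
              x$I, x$p_value, x$n_perm))
  invisible(x)
}
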