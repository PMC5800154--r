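#' Per-draw linear-predictor draws for one cell
#'
#' Internal workhorse for the posterior surfaces: reconstructs eta[j,i,t]
#' for every stored draw from the flattened draw matrix.
#'
#' @noRd
eta_draws_cell <- function(dr, fit, j, i, t) {
  spec <- fit$spec; B <- fit$basis$B; K <- fit$basis$K
  acols <- paste0("a[", j, ",", seq_len(K), "]")
  S <- as.vector(dr[, acols, drop = FALSE] %*% B[t, ])
  delta <- exp(dr[, paste0("log_delta[", t, "]")])
  shared <- dr[, paste0("b0[", i, "]")]
  if (spec$include_shared_spacetime)
    shared <- shared +
      as.vector(dr[, paste0("bik[", i, ",", seq_len(K), "]"), drop = FALSE] %*% B[t, ])
  w <- if (j == 1L) delta else 1 / delta
  eta <- shared * w + S + dr[, paste0("b[", j, ",", i, "]")]
  if (spec$include_specific_spacetime)
    eta <- eta +
      as.vector(dr[, paste0("bjik[", j, ",", i, ",", seq_len(K), "]"),
                   drop = FALSE] %*% B[t, ])
  if (j == 2L && spec$include_beta_it)
    eta <- eta + dr[, paste0("beta[", i, ",", t, "]")]
  eta
}

summarize_draws <- function(x) {
  q <- stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
  c(mean = mean(x), median = q[2L], lower = q[1L], upper = q[3L])
}

#' Posterior odds-ratio surface exp(eta)
#'
#' The relative odds ratio exp(eta[j,i,t]) of each gender-region-wave cell
#' versus the gender baseline exp(alpha_j), summarized per draw on the OR
#' scale (mean, median and central 95\% interval).
#'
#' @param fit an \code{scm_fit}.
#' @return data.frame: gender, region, year, mean, median, lower, upper.
#' @export
or_surface <- function(fit) {
  stopifnot(inherits(fit, "scm_fit"))
  dr <- posterior_draws(fit)
  p <- fit$panel
  J <- length(p$genders); N <- length(p$regions); T_ <- length(p$waves)
  out <- expand.grid(gender = p$genders, region = p$regions, year = p$waves,
                     stringsAsFactors = FALSE)
  stats_m <- matrix(0, nrow(out), 4L)
  r <- 0L
  for (t in seq_len(T_)) for (i in seq_len(N)) for (j in seq_len(J)) {
    r <- r + 1L
    stats_m[r, ] <- summarize_draws(exp(eta_draws_cell(dr, fit, j, i, t)))
  }
  colnames(stats_m) <- c("mean", "median", "lower", "upper")
  cbind(out, as.data.frame(stats_m))
}

#' Posterior map of the shared spatial component exp(b0)
#'
#' @param fit an \code{scm_fit}.
#' @return data.frame: region, mean, median, lower, upper of exp(b0_i).
#' @export
shared_map <- function(fit) {
  stopifnot(inherits(fit, "scm_fit"))
  dr <- posterior_draws(fit)
  N <- length(fit$panel$regions)
  s <- t(vapply(seq_len(N), function(i)
    summarize_draws(exp(dr[, paste0("b0[", i, "]")])), numeric(4L)))
  data.frame(region = fit$panel$regions, s)
}

#' Posterior trajectory of the shared-component weights delta_t
#'
#' @param fit an \code{scm_fit}.
#' @return data.frame: year, mean, median, lower, upper of
#'   delta_t = exp(log_delta_t).
#' @export
delta_trajectory <- function(fit) {
  stopifnot(inherits(fit, "scm_fit"))
  dr <- posterior_draws(fit)
  T_ <- length(fit$panel$waves)
  s <- t(vapply(seq_len(T_), function(t)
    summarize_draws(exp(dr[, paste0("log_delta[", t, "]")])), numeric(4L)))
  data.frame(year = fit$panel$waves, s)
}

#' Posterior table of the differential spatial pattern exp(beta_it)
#'
#' The female-versus-male differential field per region and wave, on the
#' odds scale.
#'
#' @param fit an \code{scm_fit} whose variant includes beta_it.
#' @return data.frame: region, year, mean, median, lower, upper.
#' @export
beta_table <- function(fit) {
  stopifnot(inherits(fit, "scm_fit"))
  if (!(fit$spec$include_beta_it && length(fit$panel$genders) == 2L))
    stop("this fit's variant does not include beta_it")
  dr <- posterior_draws(fit)
  p <- fit$panel
  out <- expand.grid(region = p$regions, year = p$waves, stringsAsFactors = FALSE)
  s <- matrix(0, nrow(out), 4L); r <- 0L
  for (t in seq_along(p$waves)) for (i in seq_along(p$regions)) {
    r <- r + 1L
    s[r, ] <- summarize_draws(exp(dr[, paste0("beta[", i, ",", t, "]")]))
  }
  colnames(s) <- c("mean", "median", "lower", "upper")
  cbind(out, as.data.frame(s))
}

#' Posterior summaries of the shared-variance fractions eta_j(t)
#'
#' Computes the across-region variance share of the weighted shared
#' component per posterior draw and summarizes it per gender and wave.
#' Every per-draw share lies in [0, 1] only when the shared term is part of
#' eta; shares are reported as computed (ratio of empirical variances).
#'
#' @param fit an \code{scm_fit}.
#' @param max_draws cap on the number of draws used (subsampled evenly;
#'   default 2000) — the share is a smooth functional, so a few thousand
#'   draws pin it down.
#' @return data.frame: gender, year, mean, median, lower, upper.
#' @export
eta_share_summary <- function(fit, max_draws = 2000L) {
  stopifnot(inherits(fit, "scm_fit"))
  dr <- posterior_draws(fit)
  if (nrow(dr) > max_draws)
    dr <- dr[round(seq(1L, nrow(dr), length.out = max_draws)), , drop = FALSE]
  p <- fit$panel; spec <- fit$spec; basis <- fit$basis
  J <- length(p$genders); N <- length(p$regions); T_ <- length(p$waves)
  K <- basis$K
  out <- expand.grid(gender = p$genders, year = p$waves, stringsAsFactors = FALSE)
  s <- matrix(NA_real_, nrow(out), 4L); r <- 0L
  for (t in seq_len(T_)) for (j in seq_len(J)) {
    r <- r + 1L
    etam <- sapply(seq_len(N), function(i) eta_draws_cell(dr, fit, j, i, t))
    delta <- exp(dr[, paste0("log_delta[", t, "]")])
    sharedm <- sapply(seq_len(N), function(i) {
      sh <- dr[, paste0("b0[", i, "]")]
      if (spec$include_shared_spacetime)
        sh <- sh + as.vector(dr[, paste0("bik[", i, ",", seq_len(K), "]"),
                                drop = FALSE] %*% basis$B[t, ])
      sh * (if (j == 1L) delta else 1 / delta)
    })
    rv <- function(m) {
      mu <- rowMeans(m)
      rowSums((m - mu)^2) / (ncol(m) - 1)
    }
    share <- rv(sharedm) / rv(etam)
    share[!is.finite(share)] <- NA_real_
    ok <- !is.na(share)
    if (any(ok)) s[r, ] <- summarize_draws(share[ok])
  }
  colnames(s) <- c("mean", "median", "lower", "upper")
  cbind(out, as.data.frame(s))
}
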