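#' Specify one of the seven shared-component model variants
#'
#' The variants differ in the interior-knot set of the cubic B-spline and in
#' which random-spline fields are kept. Variants 1 and 3 retain the shared
#' spatio-temporal field RS_0i(t); the gender-specific random splines
#' RS_ji(t) are switched off in all seven numbered variants (they were the
#' first component dropped during model reduction) but remain available for
#' custom specifications. The female-vs-male differential spatial pattern
#' beta_it is present in every variant.
#'
#' @param variant integer 1-7, or NULL to build a custom spec from the
#'   remaining arguments.
#' @param interior_knots knot years (custom specs).
#' @param include_shared_spacetime include RS_0i(t) (MCAR random spline).
#' @param include_specific_spacetime include RS_ji(t).
#' @param include_beta_it include the per-wave differential spatial field.
#' @param prior_config a \code{\link{prior_config}}.
#' @return An object of class \code{model_spec}.
#' @export
model_spec <- function(variant = 5L, interior_knots = NULL,
                       include_shared_spacetime = FALSE,
                       include_specific_spacetime = FALSE,
                       include_beta_it = TRUE,
                       prior_config = scmspline::prior_config()) {
  if (!is.null(variant)) {
    variant <- as.integer(variant)
    if (variant < 1L || variant > 7L) stop("variant must be 1..7")
    tab <- variant_table()
    row <- tab[tab$variant == variant, ]
    interior_knots <- row$knots[[1L]]
    include_shared_spacetime <- row$rs0
    include_specific_spacetime <- row$rsj
    include_beta_it <- TRUE
  } else if (is.null(interior_knots)) {
    stop("custom specs need interior_knots")
  }
  structure(list(variant = variant,
                 interior_knots = as.numeric(interior_knots),
                 include_shared_spacetime = include_shared_spacetime,
                 include_specific_spacetime = include_specific_spacetime,
                 include_beta_it = include_beta_it,
                 prior_config = prior_config),
            class = "model_spec")
}

#' The seven model variants
#'
#' @return data.frame with columns variant, knots (list of knot-year
#'   vectors), rs0 (shared spatio-temporal field kept), rsj (gender-specific
#'   random splines kept).
#' @export
variant_table <- function() {
  data.frame(
    variant = 1:7,
    knots = I(list(1997, 1997, 2000, 2000, c(1997, 2000), c(1997, 2004),
                   c(1997, 2000, 2004))),
    rs0 = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    rsj = rep(FALSE, 7)
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> variant %s, knots {%s}, RS0i %s, RSji %s, beta_it %s\n",
              if (is.null(x$variant)) "custom" else x$variant,
              paste(x$interior_knots, collapse = ", "),
              x$include_shared_spacetime, x$include_specific_spacetime,
              x$include_beta_it))
  invisible(x)
}

#' Prior hyperparameter configuration
#'
#' Defaults follow the model's stated priors: a tight normal prior on the
#' log shared-component weights (read as a BUGS-style precision of 10, i.e.
#' variance 0.1 — switchable to a literal variance of 10), vague N(0, 1e4)
#' priors on the intercepts, spline coefficients and unstructured spatial
#' effects, an intrinsic CAR prior on the differential field beta_it (and on
#' the gender-specific random-spline coefficients when present), a separable
#' MCAR (Wishart x ICAR) prior on the shared random-spline coefficients, and
#' one of three precision hyperpriors used in the sensitivity analysis.
#'
#' @param preset precision hyperprior: 1 = gamma(5, 5e-4) on the precision;
#'   2 = uniform(0, 1) on the standard deviation; 3 = half-normal
#'   (precision 0.01, i.e. sd 10) on the variance.
#' @param log_delta_scale 10, interpreted per \code{log_delta_reading}.
#' @param log_delta_reading "precision" (variance 1/10) or "variance".
#' @param vague_var variance of the vague normal priors (alpha, a_jk, b_0i,
#'   b_ji).
#' @param wishart_df,wishart_scale MCAR coefficient-precision hyperprior
#'   Wishart(df, scale * I_K).
#' @return An object of class \code{prior_config}.
#' @export
prior_config <- function(preset = 1L, log_delta_scale = 10,
                         log_delta_reading = c("precision", "variance"),
                         vague_var = 1e4,
                         wishart_df = NULL, wishart_scale = 100) {
  log_delta_reading <- match.arg(log_delta_reading)
  preset <- as.integer(preset)
  if (!preset %in% 1:3) stop("preset must be 1, 2 or 3")
  ldv <- if (log_delta_reading == "precision") 1 / log_delta_scale else log_delta_scale
  structure(list(preset = preset,
                 log_delta_var = ldv,
                 log_delta_reading = log_delta_reading,
                 vague_var = vague_var,
                 gamma_shape = 5.0, gamma_rate = 5.0e-4,
                 wishart_df = wishart_df, wishart_scale = wishart_scale),
            class = "prior_config")
}

#' Zero-initialized parameter set for a model spec
#'
#' @param spec a \code{\link{model_spec}}.
#' @param J,N,T_ number of genders, regions, waves.
#' @return An object of class \code{scm_parameters}: list with fields
#'   \code{alpha} (J), \code{a} (J x K spline coefficients), \code{b0} (N),
#'   \code{b} (J x N), \code{log_delta} (T), \code{beta_it} (N x T),
#'   \code{bik} (N x K or NULL), \code{bjik} (J x N x K or NULL),
#'   \code{log_tau_beta}, \code{log_tau_bjk}, \code{omega} (K x K or NULL).
#' @export
new_parameters <- function(spec, J, N, T_) {
  K <- length(spec$interior_knots) + 3L
  list(alpha = numeric(J),
       a = matrix(0, J, K),
       b0 = numeric(N),
       b = matrix(0, J, N),
       log_delta = numeric(T_),
       beta_it = if (spec$include_beta_it && J == 2L) matrix(0, N, T_) else NULL,
       bik = if (spec$include_shared_spacetime) matrix(0, N, K) else NULL,
       bjik = if (spec$include_specific_spacetime) array(0, c(J, N, K)) else NULL,
       log_tau_beta = 0,
       log_tau_bjk = 0,
       omega = if (spec$include_shared_spacetime) diag(K) else NULL)
}

#' Linear predictor eta[j,i,t] of the shared component model
#'
#' For males (j = 1) the shared spatial/spatio-temporal term is scaled by
#' the wave weight delta_t; for females (j = 2) it is scaled by 1/delta_t,
#' and the differential field beta_it is added:
#' \deqn{eta_{1it} = (b_{0i} + RS_{0i}(t)) \delta_t + S_1(t) + b_{1i} + RS_{1i}(t)}
#' \deqn{eta_{2it} = (b_{0i} + RS_{0i}(t)) / \delta_t + S_2(t) + b_{2i} + RS_{2i}(t) + \beta_{it}}
#' Components absent from the spec are simply omitted.
#'
#' @param params an \code{\link{new_parameters}}-shaped parameter set.
#' @param basis a \code{\link{spline_basis}} built on the panel waves with
#'   the spec's knots.
#' @param spec a \code{\link{model_spec}}.
#' @return Array eta of dim c(J, N, T).
#' @export
linear_predictor <- function(params, basis, spec) {
  J <- length(params$alpha); N <- length(params$b0); T_ <- length(params$log_delta)
  B <- basis$B                                   # T x K
  if (ncol(params$a) != basis$K) stop("spline coefficient length mismatch")
  delta <- exp(params$log_delta)
  shared <- matrix(params$b0, N, T_)             # N x T
  if (spec$include_shared_spacetime && !is.null(params$bik))
    shared <- shared + params$bik %*% t(B)
  S <- params$a %*% t(B)                         # J x T
  eta <- array(0, c(J, N, T_))
  for (j in seq_len(J)) {
    wshared <- if (j == 1L) shared * rep(delta, each = N)
               else sweep(shared, 2L, delta, "/")
    etaj <- wshared + matrix(S[j, ], N, T_, byrow = TRUE) + params$b[j, ]
    if (spec$include_specific_spacetime && !is.null(params$bjik))
      etaj <- etaj + matrix(params$bjik[j, , ], N, basis$K) %*% t(B)
    if (j == 2L && spec$include_beta_it && !is.null(params$beta_it))
      etaj <- etaj + params$beta_it
    eta[j, , ] <- etaj
  }
  eta
}

#' Binomial log-likelihood of a counts panel under the SCM
#'
#' Y[j,i,t] ~ Binomial(n[j,i,t], p[j,i,t]) with
#' logit p[j,i,t] = alpha_j + eta[j,i,t]. Includes the binomial coefficient,
#' so -2 * log_likelihood is the BUGS-convention deviance.
#'
#' @inheritParams linear_predictor
#' @param panel a \code{\link{counts_panel}}.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(panel, params, basis, spec) {
  stopifnot(inherits(panel, "counts_panel"))
  J <- length(panel$genders)
  if (length(params$alpha) != J) stop("params/panel gender mismatch")
  eta <- linear_predictor(params, basis, spec)
  p <- stats::plogis(params$alpha + eta)    # alpha recycles over first axis
  sum(stats::dbinom(panel$Y, panel$n, p, log = TRUE))
}

# intrinsic CAR (pairwise-difference) log-kernel on a connected graph:
# ((N-1)/2) log tau - (tau/2) * sum_{edges} (x_a - x_b)^2
# (improper: flat in the constant direction, hence the sum-to-zero constraint)
icar_logpdf <- function(x, edges, tau) {
  ssq <- sum((x[edges[, 1L]] - x[edges[, 2L]])^2)
  ((length(x) - 1) / 2) * log(tau) - 0.5 * tau * ssq
}

# hyperprior log-density of theta = log(precision tau) under the three
# sensitivity presets (includes the Jacobian of the log transform)
log_tau_hyperprior <- function(theta, prior) {
  tau <- exp(theta)
  switch(prior$preset,
    # 1: tau ~ gamma(shape, rate)
    stats::dgamma(tau, prior$gamma_shape, rate = prior$gamma_rate, log = TRUE) + theta,
    # 2: sd ~ uniform(0, 1)  => support tau > 1; |d sd / d theta| = sd / 2
    if (tau > 1) log(0.5) - theta / 2 else -Inf,
    # 3: variance ~ half-normal with precision 0.01 (sd 10)
    {
      v <- exp(-theta)
      log(2) + stats::dnorm(v, 0, 10, log = TRUE) + log(v)
    })
}

# Wishart(df, V) log-density of a symmetric positive-definite matrix
wishart_logpdf <- function(X, df, V) {
  K <- nrow(X)
  cX <- chol(X); cV <- chol(V)
  ldX <- 2 * sum(log(diag(cX))); ldV <- 2 * sum(log(diag(cV)))
  lgammaK <- (K * (K - 1) / 4) * log(pi) + sum(lgamma((df + 1 - seq_len(K)) / 2))
  ((df - K - 1) / 2) * ldX - 0.5 * sum(diag(chol2inv(cV) %*% X)) -
    (df * K / 2) * log(2) - (df / 2) * ldV - lgammaK
}

#' Joint log-prior of the SCM parameters
#'
#' Vague normals on alpha, a_jk, b_0i and b_ji; a tight normal on
#' log delta_t; intrinsic CAR kernels (one per wave) with a common precision
#' on beta_it; ICAR kernels per gender and coefficient on the
#' gender-specific random-spline coefficients; a separable MCAR
#' (coefficient-precision Kronecker ICAR) kernel on the shared random-spline
#' coefficients; plus the precision/Wishart hyperprior terms.
#'
#' @inheritParams linear_predictor
#' @param W an \code{\link{adjacency}}; must be connected when any CAR term
#'   is active.
#' @return Scalar log-prior (improper CAR kernels included up to their usual
#'   constants).
#' @export
log_prior <- function(params, spec, W, prior = spec$prior_config) {
  stopifnot(inherits(W, "adjacency"))
  J <- length(params$alpha)
  car_active <- (!is.null(params$beta_it)) || (!is.null(params$bik)) ||
    (!is.null(params$bjik))
  if (car_active && !W$connected)
    stop("adjacency graph must be connected when CAR priors are active")
  vs <- sqrt(prior$vague_var)
  lp <- sum(stats::dnorm(params$alpha, 0, vs, log = TRUE)) +
    sum(stats::dnorm(params$a, 0, vs, log = TRUE)) +
    sum(stats::dnorm(params$b0, 0, vs, log = TRUE)) +
    sum(stats::dnorm(params$b, 0, vs, log = TRUE)) +
    sum(stats::dnorm(params$log_delta, 0, sqrt(prior$log_delta_var), log = TRUE))
  edges <- W$edges
  if (!is.null(params$beta_it)) {
    tau <- exp(params$log_tau_beta)
    for (t in seq_len(ncol(params$beta_it)))
      lp <- lp + icar_logpdf(params$beta_it[, t], edges, tau)
    lp <- lp + log_tau_hyperprior(params$log_tau_beta, prior)
  }
  if (!is.null(params$bjik)) {
    tau <- exp(params$log_tau_bjk)
    for (j in seq_len(J)) for (k in seq_len(dim(params$bjik)[3L]))
      lp <- lp + icar_logpdf(params$bjik[j, , k], edges, tau)
    lp <- lp + log_tau_hyperprior(params$log_tau_bjk, prior)
  }
  if (!is.null(params$bik)) {
    # MCAR: |Omega|^{(N-1)/2} exp(-1/2 tr(Omega B' Q B)), Q = D - W
    N <- length(params$b0)
    Q <- diag(rowSums(W$W)) - W$W
    S <- t(params$bik) %*% Q %*% params$bik
    ldO <- determinant(params$omega, logarithm = TRUE)$modulus
    lp <- lp + ((N - 1) / 2) * as.numeric(ldO) - 0.5 * sum(diag(params$omega %*% S))
    K <- ncol(params$bik)
    df <- if (is.null(prior$wishart_df)) K + 1 else prior$wishart_df
    lp <- lp + wishart_logpdf(params$omega, df, diag(K) * prior$wishart_scale)
  }
  lp
}

#' Shared-variance fractions eta_j(t)
#'
#' Per gender and wave, the across-region variance of the weighted shared
#' term divided by the across-region variance of the full linear predictor:
#' \deqn{\eta_1(t) = var_i((b_{0i}+RS_{0i}(t))\delta_t) / var_i(eta_{1it})}
#' and with 1/delta_t for females. Undefined waves (zero predictor variance)
#' are reported as NA.
#'
#' @inheritParams linear_predictor
#' @return J x T matrix of variance shares.
#' @export
variance_shares <- function(params, basis, spec) {
  N <- length(params$b0)
  if (N < 2L) stop("variance shares need at least 2 regions")
  J <- length(params$alpha); T_ <- length(params$log_delta)
  eta <- linear_predictor(params, basis, spec)
  delta <- exp(params$log_delta)
  shared <- matrix(params$b0, N, T_)
  if (spec$include_shared_spacetime && !is.null(params$bik))
    shared <- shared + params$bik %*% t(basis$B)
  out <- matrix(NA_real_, J, T_, dimnames = list(NULL, basis$times))
  for (j in seq_len(J)) {
    w <- if (j == 1L) rep(delta, each = N) else rep(1 / delta, each = N)
    ws <- shared * w
    for (t in seq_len(T_)) {
      ve <- stats::var(eta[j, , t])
      out[j, t] <- if (ve > 0) stats::var(ws[, t]) / ve else NA_real_
    }
  }
  out
}
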