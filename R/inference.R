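#' MCMC protocol configuration
#'
#' Defaults follow the fitting protocol of the analysis this package
#' implements: two independent chains of 50,000 iterations each (including
#' a 5,000-iteration burn-in), no thinning, adaptive random-walk step sizes
#' frozen at the end of burn-in.
#'
#' @param n_chains number of chains (>= 2 for convergence diagnostics).
#' @param n_iter total iterations per chain, including burn-in.
#' @param burn_in discarded initial iterations per chain.
#' @param thin keep every thin-th post-burn-in draw.
#' @param seed base seed; chain c uses seed + c - 1.
#' @param jitter_sd spread of the overdispersed initialization of chains
#'   2, 3, ...
#' @return An object of class \code{mcmc_config}.
#' @export
mcmc_config <- function(n_chains = 2L, n_iter = 50000L, burn_in = 5000L,
                        thin = 1L, seed = 1L, jitter_sd = 0.5) {
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (n_chains < 1L) stop("need at least one chain")
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), jitter_sd = jitter_sd),
            class = "mcmc_config")
}

# canonical flattening order of the sampled parameters (must match the
# column order written by the C++ sampler)
param_names <- function(spec, J, N, T_, K) {
  nm <- c(paste0("alpha[", seq_len(J), "]"),
          unlist(lapply(seq_len(J), function(j) paste0("a[", j, ",", seq_len(K), "]"))),
          paste0("b0[", seq_len(N), "]"),
          unlist(lapply(seq_len(J), function(j) paste0("b[", j, ",", seq_len(N), "]"))),
          paste0("log_delta[", seq_len(T_), "]"))
  if (spec$include_beta_it && J == 2L)
    nm <- c(nm, unlist(lapply(seq_len(T_), function(t)
      paste0("beta[", seq_len(N), ",", t, "]"))))
  if (spec$include_shared_spacetime)
    nm <- c(nm, unlist(lapply(seq_len(K), function(k)
      paste0("bik[", seq_len(N), ",", k, "]"))))
  if (spec$include_specific_spacetime)
    nm <- c(nm, unlist(lapply(seq_len(J), function(j)
      unlist(lapply(seq_len(K), function(k)
        paste0("bjik[", j, ",", seq_len(N), ",", k, "]"))))))
  nm <- c(nm, "log_tau_beta")
  if (spec$include_specific_spacetime) nm <- c(nm, "log_tau_bjk")
  nm
}

# inverse of the flattening: a draw vector back to a parameter list
vector_to_params <- function(v, spec, J, N, T_, K) {
  p <- new_parameters(spec, J, N, T_)
  at <- 0L
  take <- function(k) { r <- v[at + seq_len(k)]; at <<- at + k; r }
  p$alpha <- take(J)
  p$a <- matrix(take(J * K), J, K, byrow = TRUE)
  p$b0 <- take(N)
  p$b <- matrix(take(J * N), J, N, byrow = TRUE)
  p$log_delta <- take(T_)
  if (spec$include_beta_it && J == 2L) p$beta_it <- matrix(take(N * T_), N, T_)
  if (spec$include_shared_spacetime) p$bik <- matrix(take(N * K), N, K)
  if (spec$include_specific_spacetime) {
    arr <- array(0, c(J, N, K))
    for (j in seq_len(J)) arr[j, , ] <- matrix(take(N * K), N, K)
    p$bjik <- arr
  }
  p$log_tau_beta <- take(1L)
  if (spec$include_specific_spacetime) p$log_tau_bjk <- take(1L)
  p
}

# build the C++ argument lists shared by the sampler and the cross-check hook
cpp_payload <- function(panel, W, spec, basis) {
  J <- length(panel$genders)
  list(Y = aperm(panel$Y, c(2L, 3L, 1L)),
       n = aperm(panel$n, c(2L, 3L, 1L)),
       B = basis$B,
       edges = W$edges - 1L,
       Wm = W$W,
       spec = list(rs0 = spec$include_shared_spacetime,
                   rsj = spec$include_specific_spacetime,
                   beta = spec$include_beta_it && J == 2L),
       prior = unclass(spec$prior_config))
}

# starting state; chain > 1 gets jittered (overdispersed) unconstrained
# coordinates, constrained vectors are jittered then re-centered
initial_state <- function(panel, spec, basis, chain, jitter_sd) {
  J <- length(panel$genders); N <- length(panel$regions)
  T_ <- length(panel$waves); K <- basis$K
  p <- new_parameters(spec, J, N, T_)
  prev <- apply(panel$Y, 1L, sum) / pmax(apply(panel$n, 1L, sum), 1)
  p$alpha <- stats::qlogis(pmin(pmax(prev, 1e-4), 1 - 1e-4))
  p$log_tau_beta <- log(spec$prior_config$gamma_shape / spec$prior_config$gamma_rate)
  p$log_tau_bjk <- p$log_tau_beta
  if (chain > 1L) {
    p$alpha <- p$alpha + stats::rnorm(J, 0, jitter_sd)
    p$a <- p$a + stats::rnorm(J * K, 0, jitter_sd)
    p$log_delta <- p$log_delta + stats::rnorm(T_, 0, jitter_sd)
    jz <- function(x) { x <- x + stats::rnorm(length(x), 0, jitter_sd / 2); x - mean(x) }
    p$b0 <- jz(p$b0)
    for (j in seq_len(J)) p$b[j, ] <- jz(p$b[j, ])
    if (!is.null(p$beta_it))
      for (t in seq_len(T_)) p$beta_it[, t] <- jz(p$beta_it[, t]) / 10
  }
  c(p[c("alpha", "a", "b0", "b", "log_delta")],
    list(beta_it = p$beta_it, bik = p$bik, bjik = aperm_bjik(p$bjik),
         log_tau_beta = p$log_tau_beta, log_tau_bjk = p$log_tau_bjk,
         omega = p$omega))
}

# C++ stores bjik as an N x K x J cube
aperm_bjik <- function(x) if (is.null(x)) NULL else aperm(x, c(2L, 3L, 1L))

#' Fit the shared component model by MCMC
#'
#' Adaptive random-walk Metropolis-within-Gibbs sampling of the posterior
#' defined by \code{\link{log_likelihood}} + \code{\link{log_prior}}.
#' Sum-to-zero constraints on all spatial fields are maintained at every
#' draw by sum-preserving proposals; the MCAR coefficient precision (when
#' the shared random spline is active) gets a conjugate Wishart Gibbs step.
#' Runs are bitwise reproducible given the config seed.
#'
#' @param panel a \code{\link{counts_panel}}.
#' @param W an \code{\link{adjacency}} over the panel's regions.
#' @param spec a \code{\link{model_spec}}.
#' @param mcmc an \code{\link{mcmc_config}}.
#' @return An object of class \code{scm_fit}: posterior draws per chain
#'   (matrices with named columns), per-chain deviance draws, PSRF per
#'   parameter, Dbar/pD/DIC, acceptance diagnostics and the configuration.
#' @export
fit_scm <- function(panel, W, spec, mcmc = mcmc_config()) {
  stopifnot(inherits(panel, "counts_panel"), inherits(W, "adjacency"),
            inherits(spec, "model_spec"), inherits(mcmc, "mcmc_config"))
  if (!setequal(W$regions, panel$regions))
    stop("adjacency regions do not match panel regions")
  if (!identical(W$regions, panel$regions)) {
    idx <- match(panel$regions, W$regions)
    W <- adjacency(panel$regions, W$W[idx, idx])
  }
  J <- length(panel$genders); N <- length(panel$regions); T_ <- length(panel$waves)
  if (N == 1L) warning("single region: spatial terms are disabled (fixed at 0)")
  car_active <- (spec$include_beta_it && J == 2L) ||
    spec$include_shared_spacetime || spec$include_specific_spacetime
  if (car_active && N > 1L && !W$connected)
    stop("adjacency graph must be connected when CAR priors are active")
  basis <- spline_basis(panel$waves, spec$interior_knots)
  pay <- cpp_payload(panel, W, spec, basis)
  lchoose_sum <- sum(lchoose(panel$n, panel$Y))
  nm <- param_names(spec, J, N, T_, basis$K)

  chains <- vector("list", mcmc$n_chains)
  devs <- vector("list", mcmc$n_chains)
  accs <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(mcmc$seed + ch - 1L)
    init <- initial_state(panel, spec, basis, ch, mcmc$jitter_sd)
    res <- .scm_mcmc_cpp(pay$Y, pay$n, pay$B, pay$edges, pay$Wm, pay$spec,
                         pay$prior, init, mcmc$n_iter, mcmc$burn_in,
                         mcmc$thin, lchoose_sum)
    colnames(res$draws) <- nm
    chains[[ch]] <- res$draws
    devs[[ch]] <- as.numeric(res$deviance)
    accs[[ch]] <- as.numeric(res$acceptance)
  }

  psrf <- if (mcmc$n_chains >= 2L) {
    keep <- apply(chains[[1L]], 2L, stats::sd) > 0
    gelman_rubin(lapply(chains, function(m) m[, keep, drop = FALSE]))
  } else NULL

  all_draws <- do.call(rbind, chains)
  theta_bar <- vector_to_params(colMeans(all_draws), spec, J, N, T_, basis$K)
  d_at_mean <- -2 * log_likelihood(panel, theta_bar, basis, spec)
  dd <- dic(unlist(devs), d_at_mean)

  structure(list(chains = chains, deviance = devs, acceptance = accs,
                 param_names = nm, psrf = psrf,
                 Dbar = dd$Dbar, pD = dd$pD, DIC = dd$DIC,
                 spec = spec, mcmc = mcmc, basis = basis, panel = panel,
                 adjacency = W),
            class = "scm_fit")
}

#' @export
print.scm_fit <- function(x, ...) {
  cat(sprintf("<scm_fit> variant %s | %d chains x %d kept draws\n",
              if (is.null(x$spec$variant)) "custom" else x$spec$variant,
              length(x$chains), nrow(x$chains[[1L]])))
  cat(sprintf("  Dbar %.1f, pD %.1f, DIC %.1f\n", x$Dbar, x$pD, x$DIC))
  if (!is.null(x$psrf))
    cat(sprintf("  max PSRF %.3f (%s)\n", max(x$psrf),
                names(x$psrf)[which.max(x$psrf)]))
  invisible(x)
}

#' Pooled posterior draws of a fit
#'
#' @param fit an \code{scm_fit}.
#' @return Matrix of all post-burn-in draws (chains stacked), named columns.
#' @export
posterior_draws <- function(fit) {
  stopifnot(inherits(fit, "scm_fit"))
  do.call(rbind, fit$chains)
}

#' Brooks-Gelman-Rubin potential scale reduction factor
#'
#' PSRF = sqrt(((n-1)/n * W + B/n) / W) per parameter, with W the mean
#' within-chain variance and B/n the between-chain variance of the chain
#' means. Values near 1 indicate the chains have mixed.
#'
#' @param chains list (length >= 2) of draw matrices (same named columns) or
#'   of numeric vectors for a single parameter.
#' @return Named vector of PSRF values.
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2L)
    stop("need at least 2 chains")
  if (!is.matrix(chains[[1L]])) chains <- lapply(chains, as.matrix)
  n <- nrow(chains[[1L]])
  if (n < 10L) stop("need at least 10 draws per chain")
  m <- length(chains)
  means <- sapply(chains, colMeans)                     # P x m
  vars <- sapply(chains, function(x) apply(x, 2L, stats::var))
  if (is.null(dim(means))) { means <- rbind(means); vars <- rbind(vars) }
  W <- rowMeans(vars)
  if (any(W == 0)) stop("zero within-chain variance for: ",
                        paste(rownames(means)[W == 0], collapse = ", "))
  B_over_n <- apply(means, 1L, stats::var)              # var of chain means
  psrf <- sqrt(((n - 1) / n * W + B_over_n) / W)
  names(psrf) <- colnames(chains[[1L]])
  psrf
}

#' Deviance information criterion
#'
#' Dbar = mean posterior deviance; pD = Dbar - D(theta_bar); DIC = Dbar + pD
#' = D(theta_bar) + 2 pD, with deviance = -2 log-likelihood.
#'
#' @param deviance_draws numeric vector of per-draw deviances, or an
#'   \code{scm_fit} (in which case \code{deviance_at_mean} is ignored).
#' @param deviance_at_mean deviance evaluated at the posterior mean
#'   parameters.
#' @return List with \code{Dbar}, \code{pD}, \code{DIC}.
#' @export
dic <- function(deviance_draws, deviance_at_mean = NULL) {
  if (inherits(deviance_draws, "scm_fit")) {
    f <- deviance_draws
    return(list(Dbar = f$Dbar, pD = f$pD, DIC = f$DIC))
  }
  if (is.null(deviance_at_mean)) stop("deviance_at_mean required")
  Dbar <- mean(deviance_draws)
  pD <- Dbar - deviance_at_mean
  list(Dbar = Dbar, pD = pD, DIC = Dbar + pD)
}

#' Rank fitted models by DIC
#'
#' @param fits list of \code{scm_fit} objects fitted to the same panel.
#' @param labels optional model labels (default: variant numbers).
#' @return data.frame with model, Dbar, pD, DIC, best flag, sorted by DIC.
#' @export
compare_fits <- function(fits, labels = NULL) {
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "scm_fit")))
  ref <- fits[[1L]]$panel
  same <- vapply(fits, function(f)
    identical(f$panel$Y, ref$Y) && identical(f$panel$n, ref$n), TRUE)
  if (!all(same)) stop("fits were not run on the same panel")
  if (is.null(labels))
    labels <- vapply(fits, function(f)
      if (is.null(f$spec$variant)) "custom" else as.character(f$spec$variant), "")
  out <- data.frame(model = labels,
                    Dbar = vapply(fits, function(f) f$Dbar, 0),
                    pD = vapply(fits, function(f) f$pD, 0),
                    DIC = vapply(fits, function(f) f$DIC, 0))
  out <- out[order(out$DIC), , drop = FALSE]
  out$best <- seq_len(nrow(out)) == 1L
  rownames(out) <- NULL
  out
}

#' Prior sensitivity analysis
#'
#' Refits the model under the three precision hyperprior presets (gamma on
#' the precision, uniform on the sd, half-normal on the variance) with
#' identical seeds, and tabulates the quantities the sensitivity check
#' reports: exp(alpha_j), delta at the first wave, the OR at the first
#' region/first wave per gender, and DIC(pD).
#'
#' @param panel,W,spec,mcmc as in \code{\link{fit_scm}}; \code{spec}'s own
#'   preset is ignored.
#' @param presets integer vector of presets to run (default 1:3).
#' @return List with \code{summary} (long data.frame: quantity, preset,
#'   mean, lo, hi), \code{dic} (per preset) and \code{fits}.
#' @export
sensitivity <- function(panel, W, spec, mcmc = mcmc_config(), presets = 1:3) {
  fits <- lapply(presets, function(pr) {
    sp <- spec
    sp$prior_config <- prior_config(pr,
      log_delta_reading = spec$prior_config$log_delta_reading,
      vague_var = spec$prior_config$vague_var)
    fit_scm(panel, W, sp, mcmc)
  })
  names(fits) <- paste0("priors", presets)
  rows <- list()
  for (z in seq_along(fits)) {
    f <- fits[[z]]
    dr <- posterior_draws(f)
    q <- function(x) c(mean(x), stats::quantile(x, c(0.025, 0.975)))
    ors <- or_surface(f)
    first <- ors[ors$region == f$panel$regions[1L] &
                 ors$year == f$panel$waves[1L], ]
    ent <- rbind(
      `exp(alpha) male` = q(exp(dr[, "alpha[1]"])),
      `exp(alpha) female` = q(exp(dr[, "alpha[2]"])),
      `delta[1]` = q(exp(dr[, "log_delta[1]"])),
      `OR male` = unlist(first[first$gender == f$panel$genders[1L],
                               c("mean", "lower", "upper")]),
      `OR female` = unlist(first[first$gender == f$panel$genders[2L],
                                 c("mean", "lower", "upper")]))
    rows[[z]] <- data.frame(quantity = rownames(ent), preset = presets[z],
                            mean = ent[, 1L], lo = ent[, 2L], hi = ent[, 3L],
                            row.names = NULL)
  }
  dics <- data.frame(preset = presets,
                     DIC = vapply(fits, function(f) f$DIC, 0),
                     pD = vapply(fits, function(f) f$pD, 0))
  list(summary = do.call(rbind, rows), dic = dics, fits = fits)
}
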