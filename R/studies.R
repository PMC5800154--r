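#' Parameter-recovery study
#'
#' Repeatedly simulates panels from the default variant-5 scenario (at a
#' chosen per-gender cell size), refits the generating model, and records
#' whether the central 95\% credible intervals cover the true delta_t,
#' alpha_j and S_j(t) values, together with the absolute error of the
#' posterior-mean delta_t trajectory.
#'
#' @param n_reps number of simulated replicates.
#' @param n per-gender per-cell denominator.
#' @param mcmc an \code{\link{mcmc_config}} template; its seed is offset per
#'   replicate.
#' @param seed base seed controlling both the simulations and the fits.
#' @param spec generating/fitted \code{\link{model_spec}}.
#' @return List with \code{coverage} (data.frame: family, covered, total,
#'   rate), \code{delta_mae} (per-replicate mean absolute error of the
#'   posterior-mean delta_t), and \code{psrf_max} (per replicate).
#' @export
recovery_study <- function(n_reps = 20L, n = 300L,
                           mcmc = mcmc_config(n_chains = 2L, n_iter = 10000L,
                                              burn_in = 2500L),
                           seed = 1L, spec = model_spec(5L)) {
  fam <- c(delta = 0L, alpha = 0L, S = 0L)
  tot <- c(delta = 0L, alpha = 0L, S = 0L)
  mae <- numeric(n_reps)
  psrf_max <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    sc <- simulation_scenario(spec = spec, n = n, seed = seed + 1000L * r)
    sim <- simulate_panel(sc)
    mc <- mcmc
    mc$seed <- as.integer(seed + 17L * r)
    fit <- fit_scm(sim$panel, sc$adjacency, spec, mc)
    dr <- posterior_draws(fit)
    T_ <- length(sc$waves); K <- fit$basis$K
    ci <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
    # delta_t
    dmean <- numeric(T_)
    for (t in seq_len(T_)) {
      d <- exp(dr[, paste0("log_delta[", t, "]")])
      dmean[t] <- mean(d)
      q <- ci(d)
      fam["delta"] <- fam["delta"] + (q[1] <= exp(sim$truth$log_delta[t]) &&
                                        exp(sim$truth$log_delta[t]) <= q[2])
      tot["delta"] <- tot["delta"] + 1L
    }
    mae[r] <- mean(abs(dmean - exp(sim$truth$log_delta)))
    # alpha_j
    for (j in 1:2) {
      q <- ci(dr[, paste0("alpha[", j, "]")])
      fam["alpha"] <- fam["alpha"] + (q[1] <= sim$truth$alpha[j] &&
                                        sim$truth$alpha[j] <= q[2])
      tot["alpha"] <- tot["alpha"] + 1L
    }
    # S_j(t) curve values
    for (j in 1:2) {
      acols <- paste0("a[", j, ",", seq_len(K), "]")
      Sdraws <- dr[, acols, drop = FALSE] %*% t(fit$basis$B)   # M x T
      Strue <- evaluate_curve(fit$basis, sim$truth$a[j, ])
      for (t in seq_len(T_)) {
        q <- ci(Sdraws[, t])
        fam["S"] <- fam["S"] + (q[1] <= Strue[t] && Strue[t] <= q[2])
        tot["S"] <- tot["S"] + 1L
      }
    }
    psrf_max[r] <- if (is.null(fit$psrf)) NA_real_ else max(fit$psrf)
  }
  list(coverage = data.frame(family = names(fam), covered = as.integer(fam),
                             total = as.integer(tot),
                             rate = as.numeric(fam) / as.numeric(tot)),
       delta_mae = mae, psrf_max = psrf_max)
}

#' DIC model-selection study
#'
#' Simulates replicates under one variant and asks how often that variant
#' attains the smallest DIC among a candidate set.
#'
#' @param n_reps number of replicates.
#' @param variants candidate variant numbers; \code{truth_variant} must be
#'   among them.
#' @param truth_variant generating variant.
#' @param mcmc an \code{\link{mcmc_config}} template (seed offset per
#'   replicate and variant).
#' @param seed base seed.
#' @param n per-gender per-cell denominator.
#' @return List with \code{wins} (named count per variant), \code{win_rate}
#'   of the generating variant, and the per-replicate DIC table.
#' @export
selection_study <- function(n_reps = 10L, variants = c(2L, 5L, 6L),
                            truth_variant = 5L,
                            mcmc = mcmc_config(n_chains = 2L, n_iter = 6000L,
                                               burn_in = 1500L),
                            seed = 1L, n = 300L) {
  stopifnot(truth_variant %in% variants)
  dics <- matrix(NA_real_, n_reps, length(variants),
                 dimnames = list(NULL, paste0("variant", variants)))
  for (r in seq_len(n_reps)) {
    sc <- simulation_scenario(spec = model_spec(truth_variant), n = n,
                              seed = seed + 2000L * r)
    sim <- simulate_panel(sc)
    for (z in seq_along(variants)) {
      mc <- mcmc
      mc$seed <- as.integer(seed + 31L * r + z)
      fit <- fit_scm(sim$panel, sc$adjacency, model_spec(variants[z]), mc)
      dics[r, z] <- fit$DIC
    }
  }
  winner <- variants[apply(dics, 1L, which.min)]
  wins <- table(factor(winner, levels = variants))
  list(wins = wins,
       win_rate = as.numeric(wins[as.character(truth_variant)]) / n_reps,
       dic = as.data.frame(dics))
}
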