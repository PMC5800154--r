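#!/usr/bin/env Rscript
# Fits the final shared component model (variant 5: cubic B-spline with
# knots at 1997 and 2000, no random splines) to the synthetic panel from
# 02_simulate.R and writes the posterior surfaces: OR maps, shared-component
# map, delta_t trajectory, beta_it table and variance shares.

library(scmspline)
dir.create("results", showWarnings = FALSE)

panel <- read_panel("results/synthetic_panel.csv",
                    schema = list(gender_levels = c("male", "female")))
adj <- default_adjacency()
spec <- model_spec(5L)

fit <- fit_scm(panel, adj, spec,
               mcmc_config(n_chains = 2L, n_iter = 20000L, burn_in = 5000L,
                           seed = 20180102L))
print(fit)
cat(sprintf("Convergence: max PSRF %.3f across %d parameters.\n",
            max(fit$psrf), length(fit$psrf)))

write.csv(or_surface(fit), "results/or_surface.csv", row.names = FALSE)
write.csv(shared_map(fit), "results/shared_map.csv", row.names = FALSE)
write.csv(delta_trajectory(fit), "results/delta.csv", row.names = FALSE)
write.csv(beta_table(fit), "results/beta.csv", row.names = FALSE)
write.csv(eta_share_summary(fit), "results/eta_share.csv", row.names = FALSE)

dt <- delta_trajectory(fit)
cat("Posterior mean delta_t (shared-component weight) by wave:\n")
print(dt, row.names = FALSE, digits = 3)
sm <- shared_map(fit)
cat("Highest shared-component region:", sm$region[which.max(sm$mean)], "\n")
bt <- beta_table(fit)
cat(sprintf("exp(beta_it) across cells: %.3f-%.3f (near-null differential field).\n",
            min(bt$mean), max(bt$mean)))
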