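quick_mcmc <- function(seed = 1L, n_iter = 3000L, burn = 1000L)
  mcmc_config(n_chains = 2L, n_iter = n_iter, burn_in = burn, seed = seed)

test_that("PSRF separates converged from non-converged chains", {
  set.seed(8)
  same <- list(matrix(rnorm(5000), ncol = 1), matrix(rnorm(5000), ncol = 1))
  psrf <- gelman_rubin(same)
  expect_gte(psrf, 0.99); expect_lte(psrf, 1.05)
  apart <- list(matrix(rnorm(5000, 0), ncol = 1),
                matrix(rnorm(5000, 10), ncol = 1))
  expect_gt(gelman_rubin(apart), 1.2)
})

test_that("PSRF reproduces the between/within formula on a toy", {
  set.seed(2)
  c1 <- rnorm(50); c2 <- rnorm(50, 0.3)
  n <- 50
  W <- (var(c1) + var(c2)) / 2
  B_over_n <- var(c(mean(c1), mean(c2)))
  want <- sqrt(((n - 1) / n * W + B_over_n) / W)
  expect_equal(unname(gelman_rubin(list(c1, c2))), want, tolerance = 1e-12)
  expect_error(gelman_rubin(list(c1)), "at least 2")
  expect_error(gelman_rubin(list(rep(1, 50), rep(1, 50))), "zero within-chain")
})

test_that("DIC combines Dbar and pD by the standard identity", {
  expect_equal(dic(rep(42, 100), 42), list(Dbar = 42, pD = 0, DIC = 42))
  expect_equal(dic(c(1100, 1110), 1080)$DIC, 1105 + 25 + 25 - 25)  # 1130
  d <- dic(c(1100, 1110), 1080)
  expect_equal(d$DIC, d$Dbar + d$pD, tolerance = 1e-12)
})

test_that("pD approximates the effective parameter count on a conjugate toy", {
  # x_i ~ N(theta, 1), flat-ish prior: posterior theta ~ N(xbar, 1/n);
  # E[D(theta)] - D(theta_bar) = n * Var(theta) = 1 effective parameter
  set.seed(5)
  n <- 20L
  x <- rnorm(n, 2, 1)
  theta_draws <- rnorm(200000, mean(x), sqrt(1 / n))
  dev <- vapply(theta_draws, function(th) sum((x - th)^2), 0)
  res <- dic(dev, sum((x - mean(x))^2))
  expect_equal(res$pD, 1, tolerance = 0.02)
})

test_that("fits are bitwise reproducible under identical seeds", {
  sc <- simulation_scenario(seed = 2L)
  sim <- simulate_panel(sc)
  f1 <- fit_scm(sim$panel, sc$adjacency, sc$spec, quick_mcmc(9L, 1200L, 400L))
  f2 <- fit_scm(sim$panel, sc$adjacency, sc$spec, quick_mcmc(9L, 1200L, 400L))
  expect_identical(f1$chains, f2$chains)
  expect_identical(f1$deviance, f2$deviance)
  f3 <- fit_scm(sim$panel, sc$adjacency, sc$spec, quick_mcmc(10L, 1200L, 400L))
  expect_false(identical(f1$chains[[1]], f3$chains[[1]]))
})

test_that("sum-to-zero constraints hold at every stored draw", {
  sc <- simulation_scenario(seed = 4L)
  sim <- simulate_panel(sc)
  fit <- fit_scm(sim$panel, sc$adjacency, sc$spec, quick_mcmc(3L, 1500L, 500L))
  dr <- posterior_draws(fit)
  b0 <- dr[, paste0("b0[", 1:7, "]")]
  expect_lt(max(abs(rowSums(b0))), 1e-9)
  for (j in 1:2)
    expect_lt(max(abs(rowSums(dr[, paste0("b[", j, ",", 1:7, "]")]))), 1e-9)
  for (t in 1:8)
    expect_lt(max(abs(rowSums(dr[, paste0("beta[", 1:7, ",", t, "]")]))), 1e-9)
  # geometric mean of exp(b0) is exactly 1 per draw under the constraint
  expect_equal(apply(exp(b0), 1, function(z) prod(z)^(1 / 7))[1:5],
               rep(1, 5), tolerance = 1e-12)
  # DIC identity on a real fit
  expect_equal(fit$DIC, fit$Dbar + fit$pD, tolerance = 1e-9)
})

test_that("posterior matches dense quadrature on a reduced conjugate analog", {
  # one region, one gender, two waves: the likelihood depends only on
  # alpha +/- s with s the (rank-1) spline contrast; quadrature over
  # (alpha, s) is exact up to grid error
  spec <- model_spec(NULL, interior_knots = numeric(0),
                     include_beta_it = FALSE)
  panel <- counts_panel("A", c(2000L, 2010L), "all",
                        Y = array(c(30L, 45L), c(1, 1, 2)),
                        n = array(100L, c(1, 1, 2)))
  W1 <- adjacency("A", matrix(0, 1, 1))
  expect_warning(
    fit <- fit_scm(panel, W1, spec,
                   mcmc_config(n_chains = 2, n_iter = 22000, burn_in = 4000,
                               seed = 6)),
    "single region")
  dr <- posterior_draws(fit)
  alpha_draws <- dr[, "alpha[1]"]

  basis <- spline_basis(panel$waves, numeric(0))
  bnorm2 <- sum(basis$B[1, ]^2)           # prior var of s = 1e4 * bnorm2
  agrid <- seq(-1.6, 0.9, length.out = 901)
  sgrid <- seq(-1.0, 1.6, length.out = 901)
  lp <- outer(agrid, sgrid, function(a, s) {
    l1 <- a + s; l2 <- a - s
    30 * l1 - 100 * log1p(exp(l1)) + 45 * l2 - 100 * log1p(exp(l2)) -
      a^2 / (2 * 1e4) - s^2 / (2 * 1e4 * bnorm2)
  })
  post <- exp(lp - max(lp)); post <- post / sum(post)
  m_quad <- sum(rowSums(post) * agrid)
  sd_quad <- sqrt(sum(rowSums(post) * (agrid - m_quad)^2))

  # batch-means Monte Carlo standard errors
  nb <- 40L
  bm <- function(x, f) {
    bs <- vapply(split(x, cut(seq_along(x), nb)), f, 0)
    sd(bs) / sqrt(nb)
  }
  expect_lt(abs(mean(alpha_draws) - m_quad), 3 * bm(alpha_draws, mean))
  expect_lt(abs(sd(alpha_draws) - sd_quad),
            3 * max(bm(alpha_draws, sd), 1e-3))
  # intercept-only reading: posterior mean of plogis(alpha + s-curve)
  # recovers the pooled prevalence within Monte Carlo error
  s_draws <- dr[, paste0("a[1,", 1:3, "]")] %*% basis$B[1, ]
  phat <- mean(plogis(cbind(alpha_draws + s_draws, alpha_draws - s_draws)))
  expect_lt(abs(phat - 75 / 200), 0.01)
})

test_that("two-chain self-consistency reaches PSRF below 1.1", {
  sc <- simulation_scenario(seed = 6L)
  sim <- simulate_panel(sc)
  fit <- fit_scm(sim$panel, sc$adjacency, sc$spec,
                 mcmc_config(n_chains = 2, n_iter = 16000, burn_in = 4000,
                             seed = 21))
  expect_lt(max(fit$psrf), 1.1)
})

test_that("fit rejects structurally invalid inputs", {
  sc <- simulation_scenario(seed = 2L)
  sim <- simulate_panel(sc)
  Wd <- adjacency(sc$regions, matrix(0, 7, 7))   # no edges: disconnected
  expect_error(fit_scm(sim$panel, Wd, sc$spec, quick_mcmc()), "connected")
  W3 <- ring_adjacency(3L)
  expect_error(fit_scm(sim$panel, W3, sc$spec, quick_mcmc()), "match")
})

test_that("model comparison ranks by DIC and guards against mixed panels", {
  sc <- simulation_scenario(seed = 12L)
  sim <- simulate_panel(sc)
  mc <- quick_mcmc(7L, 2000L, 600L)
  f5 <- fit_scm(sim$panel, sc$adjacency, model_spec(5L), mc)
  f2 <- fit_scm(sim$panel, sc$adjacency, model_spec(2L), mc)
  tab <- compare_fits(list(f2, f5))
  expect_equal(tab$model[tab$best], tab$model[which.min(tab$DIC)])
  expect_equal(tab$DIC, sort(tab$DIC))
  expect_equal(nrow(compare_fits(list(f5))), 1L)
  other <- simulate_panel(simulation_scenario(seed = 13L))
  f_other <- fit_scm(other$panel, sc$adjacency, model_spec(5L), mc)
  expect_error(compare_fits(list(f5, f_other)), "same panel")
})

test_that("sensitivity analysis is deterministic and schema-stable", {
  sc <- simulation_scenario(seed = 3L)
  sim <- simulate_panel(sc)
  res <- sensitivity(sim$panel, sc$adjacency, sc$spec,
                     mcmc = quick_mcmc(5L, 1500L, 500L), presets = c(1L, 1L))
  s <- res$summary
  r1 <- s[seq_len(5), c("mean", "lo", "hi")]
  r2 <- s[5 + seq_len(5), c("mean", "lo", "hi")]
  rownames(r1) <- rownames(r2) <- NULL
  expect_equal(r1, r2)
  expect_setequal(s$quantity[1:5],
                  c("exp(alpha) male", "exp(alpha) female", "delta[1]",
                    "OR male", "OR female"))
  expect_named(res$dic, c("preset", "DIC", "pD"))
})
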