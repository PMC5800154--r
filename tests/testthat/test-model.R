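waves8 <- c(1991, 1993, 1997, 2000, 2004, 2006, 2009, 2011)

test_that("the variant table encodes all seven model configurations", {
  tab <- variant_table()
  expect_equal(nrow(tab), 7L)
  expect_equal(tab$knots[[1]], 1997)
  expect_equal(tab$knots[[5]], c(1997, 2000))
  expect_equal(tab$knots[[6]], c(1997, 2004))
  expect_equal(tab$knots[[7]], c(1997, 2000, 2004))
  expect_equal(tab$rs0, c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_false(any(tab$rsj))
  s5 <- model_spec(5L)
  expect_equal(s5$interior_knots, c(1997, 2000))
  expect_false(s5$include_shared_spacetime)
  expect_false(s5$include_specific_spacetime)
  expect_true(s5$include_beta_it)
})

test_that("linear predictor follows the printed decomposition", {
  spec <- model_spec(5L)
  basis <- spline_basis(waves8, spec$interior_knots)
  p <- new_parameters(spec, 2L, 3L, 8L)
  # everything zero, delta = 1 -> eta = 0, OR = 1
  eta0 <- linear_predictor(p, basis, spec)
  expect_equal(as.numeric(eta0), rep(0, 48))
  expect_equal(exp(eta0[1, 1, 1]), 1)
  # direct arithmetic: b0 = 0.1, delta = 2, b1 = 0.03 -> eta1 = 0.2 + 0.03
  p$b0 <- rep(0.1, 3); p$log_delta <- rep(log(2), 8); p$b[1, ] <- 0.03
  eta <- linear_predictor(p, basis, spec)
  expect_equal(as.numeric(eta[1, , ]), rep(0.1 * 2 + 0.03, 24))
  # female shares divide by delta: 0.1 / 2
  expect_equal(as.numeric(eta[2, , ]), rep(0.1 / 2, 24))
})

test_that("linear predictor matches a term-by-term oracle on all variants", {
  set.seed(14)
  for (v in 1:7) {
    for (rsj in c(FALSE, TRUE)) {
      spec <- model_spec(v)
      if (rsj) {   # exercise the gender-specific random-spline path too
        spec <- model_spec(NULL, interior_knots = spec$interior_knots,
                           include_shared_spacetime = spec$include_shared_spacetime,
                           include_specific_spacetime = TRUE)
      }
      basis <- spline_basis(waves8, spec$interior_knots)
      K <- basis$K; N <- 4L
      p <- new_parameters(spec, 2L, N, 8L)
      p$alpha <- rnorm(2); p$a <- matrix(rnorm(2 * K), 2)
      p$b0 <- rnorm(N); p$b <- matrix(rnorm(2 * N), 2)
      p$log_delta <- rnorm(8, 0, 0.3)
      p$beta_it <- matrix(rnorm(N * 8, 0, 0.2), N)
      if (!is.null(p$bik)) p$bik <- matrix(rnorm(N * K, 0, 0.2), N)
      if (!is.null(p$bjik)) p$bjik <- array(rnorm(2 * N * K, 0, 0.2), c(2, N, K))
      eta <- linear_predictor(p, basis, spec)
      for (j in 1:2) for (i in seq_len(N)) for (t in 1:8) {
        shared <- p$b0[i]
        if (spec$include_shared_spacetime)
          shared <- shared + sum(p$bik[i, ] * basis$B[t, ])
        w <- if (j == 1) exp(p$log_delta[t]) else 1 / exp(p$log_delta[t])
        want <- shared * w + sum(p$a[j, ] * basis$B[t, ]) + p$b[j, i]
        if (spec$include_specific_spacetime)
          want <- want + sum(p$bjik[j, i, ] * basis$B[t, ])
        if (j == 2 && spec$include_beta_it) want <- want + p$beta_it[i, t]
        expect_equal(eta[j, i, t], want, tolerance = 1e-12)
      }
    }
  }
})

test_that("variant 5 predictor reduces to the closed form without random splines", {
  spec <- model_spec(5L)
  basis <- spline_basis(waves8, spec$interior_knots)
  set.seed(3)
  p <- new_parameters(spec, 2L, 7L, 8L)
  p$alpha <- rnorm(2); p$a <- matrix(rnorm(10), 2); p$b0 <- rnorm(7)
  p$b <- matrix(rnorm(14), 2); p$log_delta <- rnorm(8, 0, .2)
  p$beta_it <- matrix(rnorm(56, 0, .1), 7)
  eta <- linear_predictor(p, basis, spec)
  d <- exp(p$log_delta); S <- p$a %*% t(basis$B)
  for (i in 1:7) {
    expect_equal(unname(eta[1, i, ]), unname(p$b0[i] * d + S[1, ] + p$b[1, i]))
    expect_equal(unname(eta[2, i, ]),
                 unname(p$b0[i] / d + S[2, ] + p$b[2, i] + p$beta_it[i, ]))
  }
})

test_that("log-likelihood is the summed binomial log-pmf", {
  # single informative cell: Y = 1, n = 1, eta = 0, alpha = 0 -> log(0.5)
  spec <- model_spec(NULL, interior_knots = numeric(0),
                     include_beta_it = FALSE)
  panel1 <- counts_panel("A", c(2000, 2005), "all",
                         Y = array(c(1, 0), c(1, 1, 2)),
                         n = array(c(1, 0), c(1, 1, 2)))
  basis1 <- spline_basis(panel1$waves, numeric(0))
  p1 <- new_parameters(spec, 1L, 1L, 2L)
  expect_equal(log_likelihood(panel1, p1, basis1, spec), log(0.5))
  # Y = n/2 at p = 0.5 equals the closed-form pmf
  panel2 <- counts_panel("A", c(2000, 2005), "all",
                         Y = array(c(5, 0), c(1, 1, 2)),
                         n = array(c(10, 0), c(1, 1, 2)))
  expect_equal(log_likelihood(panel2, p1, basis1, spec),
               dbinom(5, 10, 0.5, log = TRUE))
  # full synthetic panel against an explicit dbinom loop
  sc <- simulation_scenario(seed = 5L)
  sim <- simulate_panel(sc)
  spec5 <- sc$spec
  basis <- spline_basis(sim$panel$waves, spec5$interior_knots)
  ll <- log_likelihood(sim$panel, sim$truth, basis, spec5)
  oracle <- 0
  for (j in 1:2) for (i in 1:7) for (t in 1:8) {
    pr <- plogis(sim$truth$alpha[j] + sim$eta[j, i, t])
    oracle <- oracle + dbinom(sim$panel$Y[j, i, t], sim$panel$n[j, i, t], pr,
                              log = TRUE)
  }
  expect_equal(ll, oracle, tolerance = 1e-10)
})

test_that("intrinsic CAR kernel penalizes pairwise differences", {
  edges <- cbind(1L, 2L)   # two connected regions
  k0 <- scmspline:::icar_logpdf(c(0, 0), edges, tau = 1)
  k1 <- scmspline:::icar_logpdf(c(1, -1), edges, tau = 1)
  expect_equal(k1 - k0, -2)          # (1/2) * tau * (1 - (-1))^2 = 2
  # constant vectors are unpenalized (improper flat direction)
  expect_equal(scmspline:::icar_logpdf(rep(3, 5), cbind(1:4, 2:5), 2),
               scmspline:::icar_logpdf(rep(0, 5), cbind(1:4, 2:5), 2))
})

test_that("precision hyperpriors match independent density oracles", {
  pc <- prior_config(1)
  # gamma(5, 5e-4) at tau = 1 (theta = 0), plus log-scale Jacobian
  want <- 5 * log(5e-4) - lgamma(5) + (5 - 1) * log(1) - 5e-4 * 1 + 0
  expect_equal(scmspline:::log_tau_hyperprior(0, pc), want, tolerance = 1e-12)
  # uniform-sd preset: support only for tau > 1
  pc2 <- prior_config(2)
  expect_equal(scmspline:::log_tau_hyperprior(2, pc2), log(0.5) - 1)
  expect_identical(scmspline:::log_tau_hyperprior(-1, pc2), -Inf)
  # half-normal variance preset at theta = 0: v = 1
  pc3 <- prior_config(3)
  want3 <- log(2) + dnorm(1, 0, 10, log = TRUE) + 0
  expect_equal(scmspline:::log_tau_hyperprior(0, pc3), want3)
})

test_that("log-prior demands a connected graph for CAR terms", {
  spec <- model_spec(5L)
  p <- new_parameters(spec, 2L, 4L, 8L)
  Wd <- adjacency(LETTERS[1:4],
                  rbind(c(0, 1, 0, 0), c(1, 0, 0, 0),
                        c(0, 0, 0, 1), c(0, 0, 1, 0)))
  expect_false(Wd$connected)
  expect_error(log_prior(p, spec, Wd), "connected")
})

test_that("C++ posterior evaluation mirrors the R reference exactly", {
  set.seed(77)
  adj <- default_adjacency()
  for (v in c(1L, 2L, 5L)) {
    for (preset in 1:3) {
      spec <- model_spec(v, prior_config = prior_config(preset))
      sc <- simulation_scenario(spec = model_spec(5L), seed = 50L + v)
      sim <- simulate_panel(sc)
      basis <- spline_basis(waves8, spec$interior_knots)
      K <- basis$K
      p <- new_parameters(spec, 2L, 7L, 8L)
      p$alpha <- rnorm(2); p$a <- matrix(rnorm(2 * K), 2)
      p$b0 <- rnorm(7); p$b0 <- p$b0 - mean(p$b0)
      p$b <- matrix(rnorm(14), 2); p$b <- p$b - rowMeans(p$b)
      p$log_delta <- rnorm(8, 0, .2)
      p$beta_it <- apply(matrix(rnorm(56, 0, .1), 7), 2, function(x) x - mean(x))
      p$log_tau_beta <- runif(1, 1, 3)
      if (!is.null(p$bik)) {
        p$bik <- apply(matrix(rnorm(7 * K, 0, .1), 7), 2, function(x) x - mean(x))
        p$omega <- crossprod(matrix(rnorm(K * K), K)) + diag(K)
      }
      r_ll <- log_likelihood(sim$panel, p, basis, spec)
      r_lp <- log_prior(p, spec, adj)
      pay <- scmspline:::cpp_payload(sim$panel, adj, spec, basis)
      init <- c(p[c("alpha", "a", "b0", "b", "log_delta")],
                list(beta_it = p$beta_it, bik = p$bik,
                     bjik = scmspline:::aperm_bjik(p$bjik),
                     log_tau_beta = p$log_tau_beta,
                     log_tau_bjk = p$log_tau_bjk, omega = p$omega))
      cp <- scmspline:::.scm_logpost_cpp(init, pay$Y, pay$n, pay$B, pay$edges,
                                         pay$Wm, pay$spec, pay$prior)
      lcs <- sum(lchoose(sim$panel$n, sim$panel$Y))
      expect_equal(r_ll, cp$loglik + lcs, tolerance = 1e-8)
      expect_equal(r_lp, cp$logprior, tolerance = 1e-8)
    }
  }
})

test_that("variance shares obey their defining identities", {
  spec <- model_spec(5L)
  basis <- spline_basis(waves8, spec$interior_knots)
  p <- new_parameters(spec, 2L, 3L, 8L)
  p$b0 <- c(0.3, -0.1, -0.2)
  p$log_delta <- rnorm(8, 0, 0.2)
  # eta is exactly the weighted shared term -> share = 1 everywhere
  sh <- variance_shares(p, basis, spec)
  expect_equal(as.numeric(sh), rep(1, 16))
  # spatially constant shared term with varying specific effects -> share = 0
  p2 <- new_parameters(spec, 2L, 3L, 8L)
  p2$b0 <- rep(0.2, 3)
  p2$b <- matrix(rnorm(6), 2)
  expect_equal(as.numeric(variance_shares(p2, basis, spec)), rep(0, 16))
  # toy oracle: direct variance ratio
  p3 <- new_parameters(spec, 2L, 3L, 8L)
  p3$b0 <- c(0.3, -0.1, -0.2); p3$b <- matrix(rnorm(6, 0, 0.1), 2)
  p3$log_delta <- rep(log(1.3), 8)
  sh3 <- variance_shares(p3, basis, spec)
  eta <- linear_predictor(p3, basis, spec)
  expect_equal(unname(sh3[1, 4]), var(p3$b0 * 1.3) / var(eta[1, , 4]))
  expect_equal(unname(sh3[2, 4]), var(p3$b0 / 1.3) / var(eta[2, , 4]))
})
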