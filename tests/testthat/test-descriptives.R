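test_that("prevalence reproduces the published province-wave cells", {
  p <- table2_fixture()
  pr <- prevalence(p, by = c("region", "wave"))
  cell <- function(r, w) pr$prevalence[pr$region == r & pr$wave == w]
  expect_equal(cell("Jiangsu", 1991), 10.68)
  expect_equal(cell("Jiangsu", 1997), 36.73)
  expect_equal(cell("Henan", 2004), 42.15)
  overall <- prevalence(p, by = "wave")
  expect_equal(overall$prevalence[overall$wave == 1991], 14.09)
  expect_equal(overall$prevalence[overall$wave == 2011], 32.37)
})

test_that("prevalence handles margins, zeros and degenerate denominators", {
  p0 <- counts_panel("A", c(2000, 2005), "all",
                     Y = array(0, c(1, 1, 2)), n = array(50, c(1, 1, 2)))
  expect_equal(prevalence(p0, by = "wave")$prevalence, c(0, 0))
  pz <- counts_panel("A", c(2000, 2005), "all",
                     Y = array(0, c(1, 1, 2)), n = array(c(10, 0), c(1, 1, 2)))
  expect_error(prevalence(pz, by = "wave"), "zero denominator.*2005")
  # pooled prevalence equals the case-weighted mix of gender prevalences
  p <- toy_panel()
  by_g <- prevalence(p, by = "gender")
  pooled <- prevalence(pool_genders(p), by = character(0))
  expect_equal(pooled$prevalence,
               round(sum(by_g$cases) / sum(by_g$n) * 100, 2))
})

test_that("expected counts follow the indirect-standardization formula", {
  # single age group, rate 0.5, n = 100 -> E = 50
  ap <- age_stratified_panel("A", c(2000, 2005), "all", "all-ages",
                             Y = array(c(50, 60), c(1, 1, 2, 1)),
                             n = array(100, c(1, 1, 2, 1)))
  E <- expected_counts(ap, reference_wave = 2000)
  expect_equal(as.numeric(E), c(50, 50))

  # 2 regions x 2 age groups toy against a hand-computed sum n * r
  n <- array(c(40, 60, 80, 20), c(1, 2, 1, 2))   # region x age
  Y <- array(c(4, 12, 16, 8), c(1, 2, 1, 2))
  ap2 <- age_stratified_panel(c("A", "B"), 2000, "all", c("young", "old"), Y, n)
  r_young <- (4 + 12) / (40 + 60); r_old <- (16 + 8) / (80 + 20)
  E2 <- expected_counts(ap2, reference_wave = 2000)
  expect_equal(as.numeric(E2[1, , 1]),
               c(40 * r_young + 80 * r_old, 60 * r_young + 20 * r_old))
  # standardization identity: at the reference wave, sum_i E = sum_i Y
  expect_equal(sum(E2), sum(Y))

  expect_error(expected_counts(ap2, reference_rates =
    matrix(0.1, 1, 1, dimnames = list("all", "young"))), "absent")
})

test_that("SPR is the elementwise observed/expected ratio", {
  n <- array(c(40, 60, 80, 20), c(1, 2, 1, 2))
  Y <- array(c(4, 12, 16, 8), c(1, 2, 1, 2))
  ap <- age_stratified_panel(c("A", "B"), 2000, "all", c("young", "old"), Y, n)
  rr <- matrix(c(0.05, 0.4), 1, 2, dimnames = list("all", c("young", "old")))
  s <- spr(ap, reference_rates = rr)
  # brute-force oracle
  eA <- 40 * 0.05 + 80 * 0.4; eB <- 60 * 0.05 + 20 * 0.4
  expect_equal(s$spr[s$region == "A"], (4 + 16) / eA)
  expect_equal(s$spr[s$region == "B"], (12 + 8) / eB)
  # Y = E everywhere -> SPR = 1 (self-referenced rates)
  s1 <- spr(ap, reference_wave = 2000)
  expect_equal(sum(s1$Y), sum(s1$E))
  # doubling all counts and denominators leaves SPR unchanged
  ap2 <- age_stratified_panel(c("A", "B"), 2000, "all", c("young", "old"),
                              2 * Y, 2 * n)
  s2 <- spr(ap2, reference_rates = rr)
  expect_equal(s2$spr, s$spr)
  # doubling only the cases doubles SPR
  ap3 <- age_stratified_panel(c("A", "B"), 2000, "all", c("young", "old"),
                              2 * Y, n)
  expect_equal(spr(ap3, reference_rates = rr)$spr, 2 * s$spr)
})

test_that("Moran's I matches a double-loop oracle on random instances", {
  set.seed(11)
  for (rep in 1:100) {
    N <- 10L
    W <- matrix(0, N, N)
    while (TRUE) {
      W[] <- 0
      idx <- which(upper.tri(W))
      on <- sample(idx, 14L)
      W[on] <- 1; W <- pmax(W, t(W))
      if (all(rowSums(W) > 0)) break
    }
    adj <- adjacency(LETTERS[1:N], W)
    x <- rnorm(N)
    # binary weights
    res_b <- morans_i(x, adj, standardize = "binary", n_perm = 0)
    expect_lt(abs(res_b$I - moran_brute(x, W)), 1e-12)
    # row-standardized weights
    res_r <- morans_i(x, adj, standardize = "row", n_perm = 0)
    expect_lt(abs(res_r$I - moran_brute(x, W / rowSums(W))), 1e-12)
  }
})

test_that("Moran's I agrees with an independent library implementation", {
  skip_if_not_installed("ape")
  set.seed(21)
  adj <- ring_adjacency(8L)
  x <- rnorm(8)
  ours <- morans_i(x, adj, standardize = "row", n_perm = 0)
  theirs <- ape::Moran.I(x, adj$W / rowSums(adj$W), scaled = FALSE)
  expect_equal(ours$I, theirs$observed, tolerance = 1e-10)
})

test_that("Moran's I sign behaviour: clustering up, alternation to -1", {
  # two disconnected cliques with opposite values -> strong clustering
  W <- matrix(0, 6, 6); W[1:3, 1:3] <- 1; W[4:6, 4:6] <- 1; diag(W) <- 0
  adj <- adjacency(LETTERS[1:6], W)
  expect_gt(morans_i(c(1, 1, 1, -1, -1, -1), adj, n_perm = 0)$I, 0)
  # alternating values on a 4-cycle, row-standardized -> exactly -1
  expect_equal(morans_i(c(1, -1, 1, -1), ring_adjacency(4L),
                        standardize = "row", n_perm = 0)$I, -1)
})

test_that("permutation pseudo-p approaches the exhaustive enumeration", {
  adj <- ring_adjacency(5L)
  x <- c(0.3, -1.2, 0.8, 1.5, -0.9)
  obs <- morans_i(x, adj, n_perm = 0)$I
  # enumerate all 120 orderings by recursion
  all_perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in all_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  w <- adj$W / rowSums(adj$W)
  I_all <- vapply(all_perms(x), function(p) moran_brute(p, w), 0)
  p_exact <- mean(abs(I_all) >= abs(obs) - 1e-12)
  res <- morans_i(x, adj, n_perm = 9999, seed = 5)
  expect_lt(abs(res$p_value - p_exact), 0.015)
})

test_that("permutation p-values are super-uniform under the null", {
  set.seed(33)
  adj <- ring_adjacency(7L)
  pvals <- replicate(500, {
    morans_i(rnorm(7), adj, n_perm = 199, seed = sample.int(1e6, 1))$p_value
  })
  for (alpha in c(0.05, 0.1, 0.2)) {
    slack <- 2.5 * sqrt(alpha * (1 - alpha) / 500)
    expect_lte(mean(pvals <= alpha), alpha + slack)
  }
})

test_that("Moran's I input validation", {
  adj <- ring_adjacency(4L)
  expect_error(morans_i(rep(1, 4), adj), "zero variance")
  expect_error(morans_i(rnorm(3), adj), "does not match")
  expect_error(morans_i(rnorm(2), ring_adjacency(2L)), "at least 3")
})
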