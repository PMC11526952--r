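# The moment system has two exact oracles: the panmictic mutation-drift
# balance (pi = 4 N mu) and the two-deme structured coalescent
# (pi_w = 8 N mu, pi_b = 8 N mu + mu / m, from pi = 2 mu E[T] with
# E[T_same] = 4N and E[T_diff] = 4N + 1/(2m)).

test_that("single-deme equilibrium equals 4 N mu", {
  cases <- list(c(N = 250000, mu = 1e-8),   # theta = 0.01
                c(N = 2500, mu = 1e-8),
                c(N = 500, mu = 2e-6))
  for (cs in cases) {
    p <- gd_params(mu = cs[["mu"]], deme_size = cs[["N"]])
    eq <- equilibrium_diversity(build_lattice(1, 1), p)
    expect_equal(eq$pi[1, 1], 4 * cs[["N"]] * cs[["mu"]], tolerance = 1e-12)
  }
})

test_that("two-deme equilibrium matches the structured-coalescent closed form", {
  grid <- expand.grid(N = c(100, 1000, 20000), mu = c(1e-6, 1e-8),
                      m = c(0.01, 0.2, 0.001))
  for (k in seq_len(nrow(grid))) {
    N <- grid$N[k]; mu <- grid$mu[k]; m <- grid$m[k]
    p <- gd_params(mu = mu, deme_size = N, mig = m)
    eq <- equilibrium_diversity(build_lattice(1, 2), p)
    cf <- two_deme_closed_form(N, mu, m)
    expect_equal(eq$pi[1, 1], cf$pi_w, tolerance = 1e-8)
    expect_equal(eq$pi[2, 2], cf$pi_w, tolerance = 1e-8)
    expect_equal(eq$pi[1, 2], cf$pi_b, tolerance = 1e-8)
  }
})

test_that("equilibrium matrices are symmetric, positive, Wahlund-ordered", {
  sys <- small_system(4, 5, m = 0.02)
  eq <- equilibrium_diversity(sys$landscape, sys$params)
  expect_true(all(eq$pi > 0))
  expect_equal(eq$pi, t(eq$pi))
  # within-deme diversity cannot exceed between-deme diversity at equilibrium
  expect_true(all(diag(eq$pi) <= eq$pi + 1e-15))
})

test_that("between-component diversity has no equilibrium (reported Inf)", {
  mask <- matrix(TRUE, 2, 3); mask[, 2] <- FALSE
  L <- landscape_from_mask(mask)
  p <- gd_params(mu = 1e-7, deme_size = 100, mig = 0.1)
  eq <- equilibrium_diversity(L, p)
  comp <- landscape_components(L)
  same <- outer(comp, comp, "==")
  expect_true(all(is.finite(eq$pi[same])))
  expect_true(all(is.infinite(eq$pi[!same])))
})

test_that("evolve_diversity is the identity at t = 0 and fixes the equilibrium", {
  sys <- small_system()
  eq <- equilibrium_diversity(sys$landscape, sys$params)
  expect_identical(evolve_diversity(eq, sys$landscape, sys$params, 0), eq)
  ev <- evolve_diversity(eq, sys$landscape, sys$params, 5000)
  expect_equal(ev$pi, eq$pi, tolerance = 1e-7)
})

test_that("single-deme transient follows the explicit scalar solution", {
  # d pi/dt = 2 mu - pi / (2N)  =>  pi(t) = 4 N mu (1 - exp(-t / (2N)))
  N <- 1000; mu <- 1e-6
  p <- gd_params(mu = mu, deme_size = N)
  L <- build_lattice(1, 1)
  st <- gd_diversity(matrix(0, 1, 1), L$demes)
  prev <- 0
  for (t in c(100, 500, 2000, 20000)) {
    ev <- evolve_diversity(st, L, p, t)
    expect_equal(ev$pi[1, 1], 4 * N * mu * (1 - exp(-t / (2 * N))),
                 tolerance = 1e-7)
    # monotone approach from below
    expect_gt(ev$pi[1, 1], prev)
    expect_lt(ev$pi[1, 1], 4 * N * mu)
    prev <- ev$pi[1, 1]
  }
})

test_that("transients relax to the sparse-solve equilibrium", {
  sys <- small_system(2, 2, mu = 1e-6, N = 30, m = 0.05)
  eq <- equilibrium_diversity(sys$landscape, sys$params)
  st <- gd_diversity(matrix(0, 4, 4), sys$landscape$demes)
  t_long <- 100 * 2 * 30 * 4              # 100 x (2 N_total)
  ev <- evolve_diversity(st, sys$landscape, sys$params, t_long)
  expect_equal(max(abs(ev$pi - eq$pi)) / max(eq$pi), 0, tolerance = 1e-6)
})

test_that("evolution preserves symmetry and positivity", {
  sys <- small_system(3, 3, m = 0.02)
  set.seed(1)
  base <- equilibrium_diversity(sys$landscape, sys$params)
  for (rep in 1:5) {
    jitter <- matrix(runif(81, 0.5, 1.5), 9, 9)
    jitter <- (jitter + t(jitter)) / 2
    st <- gd_diversity(base$pi * jitter, sys$landscape$demes)
    ev <- evolve_diversity(st, sys$landscape, sys$params, 500)
    expect_equal(ev$pi, t(ev$pi))
    expect_true(all(ev$pi >= 0))
  }
})

test_that("habitat removal restricts the state and rewires the landscape", {
  sys <- small_system(10, 10, m = 0.05)
  eq <- equilibrium_diversity(sys$landscape, sys$params)
  # no-op removal
  same <- apply_habitat_loss(eq, sys$landscape, integer(0))
  expect_identical(same$state, eq)
  # remove 3 full west columns: 70 demes survive
  removed <- edge_contraction_demes(sys$landscape, 0.30)
  red <- apply_habitat_loss(eq, sys$landscape, removed)
  expect_equal(length(red$landscape$demes), 70)
  expect_equal(dim(red$state$pi), c(70, 70))
  keep <- !(sys$landscape$demes %in% removed)
  expect_equal(red$state$pi, eq$pi[keep, keep],
               ignore_attr = TRUE)
  expect_error(apply_habitat_loss(eq, sys$landscape, sys$landscape$demes))
  expect_error(apply_habitat_loss(eq, sys$landscape, 999))
})

test_that("species_pi and local_pi summarize the matrix as advertised", {
  const <- gd_diversity(matrix(0.007, 3, 3), 1:3)
  expect_equal(species_pi(const), 0.007)
  expect_equal(local_pi(const), 0.007)
  # two-deme worked example: (2 * 0.008 + 2 * 0.0081) / 4
  st <- gd_diversity(matrix(c(0.008, 0.0081, 0.0081, 0.008), 2, 2), 1:2)
  expect_equal(species_pi(st), 0.00805)
  expect_equal(local_pi(st), 0.008)
  expect_equal(species_pi(st, weights = c(1, 0)), 0.008)
  expect_error(species_pi(st, weights = c(0.4, 0.4)))
  # single deme: species pi is the sole entry
  one <- gd_diversity(matrix(0.01, 1, 1), 5)
  expect_equal(species_pi(one), 0.01)
})

test_that("pairwise F_ST matches its Hudson-style definition", {
  st <- gd_diversity(matrix(c(0.008, 0.0081, 0.0081, 0.008), 2, 2), 1:2)
  expect_equal(pairwise_fst(st), 1 - 0.008 / 0.0081)
  expect_equal(pairwise_fst(gd_diversity(matrix(0.004, 3, 3), 1:3)), 0)
  # complete fixation: no within-deme variation, positive between
  fix <- matrix(0.01, 2, 2); diag(fix) <- 0
  expect_equal(pairwise_fst(gd_diversity(fix, 1:2)), 1)
  expect_error(pairwise_fst(gd_diversity(matrix(0.1, 1, 1), 1)))
})

test_that("migration tuning brackets, converges and is monotone", {
  L <- build_lattice(4, 4)
  p <- gd_params(mu = 1e-7, deme_size = 50)
  # achieved F_ST decreases with m
  ms <- 10^seq(-5, log10(0.25), length.out = 6)
  fst <- vapply(ms, function(m) {
    pp <- p; pp$mig <- m
    pairwise_fst(equilibrium_diversity(L, pp))
  }, numeric(1))
  expect_true(all(diff(fst) < 0))
  # round trip at a moderate target
  m3 <- tune_migration(L, p, 0.3)
  expect_false(attr(m3, "unreachable"))
  pp <- p; pp$mig <- as.numeric(m3)
  expect_equal(pairwise_fst(equilibrium_diversity(L, pp)), 0.3,
               tolerance = 1e-3 / 0.3)
  # target 0 returns the upper search bound with a small achieved F_ST
  m0 <- suppressWarnings(tune_migration(L, p, 0))
  expect_equal(as.numeric(m0), 0.25)
  expect_lt(attr(m0, "achieved_fst"), 0.05)
  expect_error(tune_migration(L, p, 1.2))
})
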