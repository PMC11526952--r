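test_that("edge contraction removes whole columns west to east, top down", {
  L <- build_lattice(10, 10)
  expect_equal(length(edge_contraction_demes(L, 0)), 0)
  r30 <- edge_contraction_demes(L, 0.30)
  expect_equal(sort(r30), 1:30)           # 3 full west columns
  r35 <- edge_contraction_demes(L, 0.35)
  expect_equal(sort(r35), 1:35)           # 3 columns + top 5 cells of the 4th
  expect_equal(r35[31:35], 31:35)
  expect_error(edge_contraction_demes(L, 1))
  # east edge removes the last columns
  expect_equal(sort(edge_contraction_demes(L, 0.2, edge = "east")), 81:100)
})

test_that("fragmentation masks hit the target loss and are seed-reproducible", {
  L <- build_lattice(10, 10)
  full <- fragmentation_mask(L, 0)
  expect_true(all(full))
  expect_equal(attr(full, "realized_loss"), 0)
  m1 <- fragmentation_mask(L, 0.5, seed = 7)
  expect_equal(sum(!m1), 50)
  expect_equal(attr(m1, "realized_loss"), 0.5)
  m2 <- fragmentation_mask(L, 0.5, seed = 7)
  expect_identical(as.logical(m1), as.logical(m2))
  expect_false(identical(as.logical(m1),
                         as.logical(fragmentation_mask(L, 0.5, seed = 8))))
  # coarser blocks: 2x2 on a 20x20 grid is 1/100 of the landscape
  L20 <- build_lattice(20, 20)
  mb <- fragmentation_mask(L20, 0.3, cell_block = 1 / 100, seed = 1)
  expect_equal(attr(mb, "block_side"), 2)
  expect_equal(sum(!mb) %% 4, 0)          # whole 2x2 blocks only
  expect_gte(attr(mb, "realized_loss"), 0.3)
})

test_that("a checkerboard mask fragments into one patch per occupied cell", {
  cb <- outer(1:10, 1:10, function(i, j) (i + j) %% 2 == 0)
  met <- landscape_metrics(cb)
  expect_equal(met$patch_count, sum(cb))  # 50 isolated patches
  expect_equal(met$core_area_total, 0)
  expect_equal(met$connectedness, 0)
})

test_that("fragmentation metrics match brute-force expectations", {
  full <- landscape_metrics(matrix(TRUE, 10, 10))
  expect_equal(full$patch_count, 1)
  expect_equal(full$core_area_total, 64)  # interior 8x8
  expect_equal(full$connectedness, 1)
  expect_equal(full$perimeter_total, 40)
  single <- landscape_metrics(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  expect_equal(single$patch_count, 1)
  expect_equal(single$core_area_total, 0)
  expect_equal(single$perimeter_total, 4)
  # removing an interior ring increases perimeter while area shrinks
  ring <- matrix(TRUE, 10, 10); ring[3:8, 3:8] <- FALSE; ring[4:7, 4:7] <- TRUE
  met <- landscape_metrics(ring)
  expect_lt(met$occupied, 100)
  expect_gt(met$perimeter_total, full$perimeter_total)
})

test_that("zero-loss scenarios change nothing", {
  sys <- small_system(4, 4, m = 0.05)
  tr <- run_scenario(gd_scenario("edge_contraction", 0), sys$landscape,
                     sys$params)
  expect_equal(tr$summaries$species_loss, rep(0, 3), tolerance = 1e-7)
  expect_equal(tr$summaries$local_loss, rep(0, 3), tolerance = 1e-7)
  expect_equal(tr$n_components, 1)
})

test_that("edge-contraction losses are ordered short <= medium <= long", {
  L <- build_lattice(6, 6)
  p <- gd_params(mu = 1e-7, deme_size = 25)
  m <- tune_migration(L, p, 0.2); p$mig <- as.numeric(m)
  for (fr in c(0.2, 0.5, 0.8)) {
    tr <- run_scenario(
      gd_scenario("edge_contraction", fr,
                  horizons = c(short = 0, medium = 700, long = 5000)),
      L, p)
    expect_equal(tr$n_components, 1)
    expect_true(all(diff(tr$summaries$species_loss) > -1e-10))
    expect_gt(tr$summaries$species_loss[1], 0)
    # long-term loss tracks area loss to within a few percent
    expect_equal(tr$summaries$species_loss[3], fr, tolerance = 0.12)
  }
})

test_that("fragmentation inflates pooled diversity but erodes local diversity", {
  L <- build_lattice(6, 6)
  p <- gd_params(mu = 1e-7, deme_size = 25)
  m <- tune_migration(L, p, 0.3); p$mig <- as.numeric(m)
  horizon_long <- 2 * 2 * 25 * 36         # 2 x (2 N_total) generations
  tr <- run_scenario(
    gd_scenario("fragmentation", 0.85, seed = 5,
                horizons = c(short = 0, medium = 300, long = horizon_long)),
    L, p)
  expect_gt(tr$n_components, 1)
  # Wahlund divergence: pooled pi up (negative loss), local pi down
  expect_lt(tr$summaries$species_loss[3], 0)
  expect_gt(tr$summaries$local_loss[3], 0)
})

test_that("gradual and instantaneous loss share the long-term equilibrium", {
  L <- build_lattice(5, 5)
  p <- gd_params(mu = 1e-7, deme_size = 20)
  m <- tune_migration(L, p, 0.2); p$mig <- as.numeric(m)
  inst <- run_scenario(gd_scenario("edge_contraction", 0.5), L, p)
  grad <- run_scenario(gd_scenario("gradual", 0.5, rate = 0.04), L, p)
  grad11 <- run_scenario(gd_scenario("gradual", 0.5, rate = 0.04,
                                     rate_interval = 11), L, p)
  expect_equal(grad$summaries$species_loss[3], inst$summaries$species_loss[3],
               tolerance = 1e-8)
  expect_equal(grad11$summaries$species_loss[3],
               inst$summaries$species_loss[3], tolerance = 1e-8)
  # the cadence only matters transiently
  expect_false(isTRUE(all.equal(grad11$summaries$species_loss[1],
                                inst$summaries$species_loss[1])))
})

test_that("local long-term loss declines with realized fragmentation loss", {
  L <- build_lattice(5, 5)
  p <- gd_params(mu = 1e-7, deme_size = 20)
  m <- tune_migration(L, p, 0.3); p$mig <- as.numeric(m)
  eq <- equilibrium_diversity(L, p)
  lp0 <- local_pi(eq)
  horizon <- 2 * 2 * 20 * 25
  res <- t(vapply(1:40, function(s) {
    msk <- fragmentation_mask(L, runif(1, 0.2, 0.8), seed = s)
    red <- apply_habitat_loss(eq, L, attr(msk, "removed_cells"))
    st <- evolve_diversity(red$state, red$landscape, p, horizon)
    c(loss = attr(msk, "realized_loss"),
      rel_change = local_pi(st) / lp0 - 1)
  }, numeric(2)))
  fit <- lm(rel_change ~ loss, data = as.data.frame(res))
  expect_lt(coef(fit)[2], 0)
  # magnitude of the same order as the area-loss proportionality
  expect_gt(abs(coef(fit)[2]), 0.3)
})

test_that("restoration copies diversity sensibly and relaxes from below", {
  # duplicating the only deme leaves species pi unchanged at time 0
  L1 <- landscape_from_mask(matrix(c(TRUE, FALSE), 1, 2))
  p <- gd_params(mu = 1e-6, deme_size = 100, mig = 0.1)
  eq1 <- equilibrium_diversity(L1, p)
  for (mode in c("natural", "translocation")) {
    res <- restore_habitat(eq1, L1, 2L, mode = mode)
    expect_equal(species_pi(res$state), species_pi(eq1), tolerance = 1e-12)
    expect_equal(length(res$landscape$demes), 2)
  }
  expect_error(restore_habitat(eq1, L1, 1L), "already occupied")

  # translocation founds new demes with at least the natural-mode diversity
  # whenever between-deme exceeds within-deme diversity (two-deme closed form)
  L2 <- landscape_from_mask(matrix(c(TRUE, TRUE, FALSE), 1, 3))
  p2 <- gd_params(mu = 1e-6, deme_size = 500, mig = 0.005)
  eq2 <- equilibrium_diversity(L2, p2)
  nat <- restore_habitat(eq2, L2, 3L, mode = "natural")
  tra <- restore_habitat(eq2, L2, 3L, mode = "translocation")
  new_idx <- which(nat$landscape$demes == 3L)
  expect_gt(tra$state$pi[new_idx, new_idx], nat$state$pi[new_idx, new_idx])

  # after restoration the species relaxes towards the enlarged equilibrium
  # from below (single component)
  eq_full <- equilibrium_diversity(nat$landscape, p2)
  st <- nat$state
  sp_prev <- species_pi(st)
  for (t in c(2000, 20000)) {
    st <- evolve_diversity(st, nat$landscape, p2, t)
    sp_now <- species_pi(st)
    expect_gte(sp_now, sp_prev - 1e-12)
    sp_prev <- sp_now
  }
  expect_lte(sp_prev, species_pi(eq_full) * (1 + 1e-8))
})

test_that("restoration scenario reports a shrinking deficit", {
  L <- build_lattice(4, 4)
  p <- gd_params(mu = 1e-7, deme_size = 25)
  m <- tune_migration(L, p, 0.2); p$mig <- as.numeric(m)
  tr <- run_scenario(gd_scenario("restoration", 0.5, mode = "natural"), L, p)
  expect_true(all(diff(tr$summaries$species_loss) <= 1e-10))
  expect_equal(tr$summaries$species_loss[3], 0, tolerance = 1e-8)
})
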