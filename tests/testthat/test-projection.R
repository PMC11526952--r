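test_that("Red List categories map to their decline ranges", {
  expect_equal(category_to_area_loss("CR")$mid, 0.875)
  expect_equal(category_to_area_loss("VU")$min, 0.30)
  expect_equal(category_to_area_loss("LC")$max, 0.25)
  expect_equal(category_to_area_loss("EN")$mid, 0.65)
  expect_equal(category_to_area_loss("Extinct")$mid, 0.975)
  expect_equal(category_to_area_loss("vulnerable")$mid, 0.40)
  multi <- category_to_area_loss(c("LC", "VU", "EN", "CR"))
  expect_true(all(diff(multi$mid) > 0))   # severity is ordered
  expect_error(category_to_area_loss("DD"))
})

test_that("LPI declines average per-population arithmetic losses", {
  one <- lpi_decline(data.frame(time = c(1970, 2020),
                                abundance = c(100, 36)))
  expect_equal(one$decline, 0.64)
  expect_false(one$excluded)
  # growing population: zero decline, flagged excluded
  up <- lpi_decline(data.frame(time = c(1, 2), abundance = c(50, 80)))
  expect_equal(up$decline, 0)
  expect_true(up$excluded)
  # two populations with declines 0.4 and 0.8 average to 0.6
  two <- lpi_decline(list(
    data.frame(time = c(1, 9), abundance = c(10, 6)),
    data.frame(time = c(1, 9), abundance = c(10, 2))))
  expect_equal(two$decline, 0.6)
  expect_error(lpi_decline(list()))
  expect_error(lpi_decline(data.frame(time = 1, abundance = 5)))
})

test_that("GBF indicators combine additively on the survivors", {
  x <- combine_gbf_indicators(0.176, 0.267)
  expect_equal(as.numeric(x), 0.176 + (1 - 0.176) * 0.267)
  expect_equal(attr(x, "display"), "39%")
  expect_equal(as.numeric(combine_gbf_indicators(0, 0)), 0)
  expect_equal(as.numeric(combine_gbf_indicators(1, 0.5)), 1)
  expect_error(combine_gbf_indicators(1.2, 0))
})

test_that("loss tables reproduce their generating runs and interpolate", {
  L <- build_lattice(4, 4)
  p <- gd_params(mu = 1e-7, deme_size = 50)
  tab <- build_loss_table(fst_grid = c(0.1, 0.3), loss_grid = c(0, 0.25, 0.5),
                          landscape = L, params = p,
                          horizons = c("short", "long"))
  # loss 0 column is exactly zero
  expect_equal(unname(tab$values[, 1, ]), matrix(0, 2, 2))
  # node lookup reproduces the stored values exactly
  for (f in tab$fst_grid) for (lo in tab$loss_grid) {
    expect_equal(loss_lookup(tab, f, lo, "long"),
                 tab$values[as.character(f), as.character(lo), "long"],
                 ignore_attr = TRUE)
  }
  # monotone in area loss at fixed F_ST; short <= long
  expect_true(all(apply(tab$values[, , "long"], 1, diff) >= 0))
  expect_true(all(tab$values[, , "short"] <= tab$values[, , "long"] + 1e-12))
  # refined-grid check: on a locally refined table, midpoint interpolation
  # agrees with a direct run to within a percentage point
  fine <- build_loss_table(fst_grid = c(0.15, 0.2, 0.25),
                           loss_grid = c(0.3, 0.375, 0.45),
                           landscape = L, params = p, horizons = "long")
  mid_direct <- build_loss_table(fst_grid = 0.175, loss_grid = 0.34,
                                 landscape = L, params = p,
                                 horizons = "long")$values[1, 1, 1]
  mid_interp <- loss_lookup(fine, 0.175, 0.34, "long")
  expect_lt(abs(mid_interp - mid_direct), 0.01)
  # clamped outside the grid
  expect_equal(loss_lookup(tab, 0.01, 0.25, "long"),
               loss_lookup(tab, 0.1, 0.25, "long"))
})

test_that("projections are seeded, ordered by severity, and bounded", {
  L <- build_lattice(4, 4)
  p <- gd_params(mu = 1e-7, deme_size = 50)
  tab <- build_loss_table(fst_grid = c(0.05, 0.2, 0.4),
                          loss_grid = c(0, 0.3, 0.6, 0.9),
                          landscape = L, params = p,
                          horizons = c("short", "medium", "long"),
                          horizon_times = c(short = 0, medium = 400,
                                            long = 4000))
  records <- synth_species_table(
    counts_by_category = c(LC = 30, VU = 30, EN = 30, CR = 30),
    n_lpi = 40, n_gbf = 30, seed = 2)
  pr1 <- project_species(records, tab, seed = 7)
  pr2 <- project_species(records, tab, seed = 7)
  expect_identical(pr1$per_species, pr2$per_species)
  expect_true(all(pr1$per_species$loss_min <= pr1$per_species$loss_mid + 1e-9))
  expect_true(all(pr1$per_species$loss_mid <= pr1$per_species$loss_max + 1e-9))
  # monotone in Red List severity at every horizon and metric
  ps <- pr1$per_species[pr1$per_species$source == "redlist", ]
  cat_of <- records$category[match(ps$species_id, records$species_id)]
  for (met in unique(ps$metric)) for (h in unique(ps$horizon[ps$metric == met])) {
    sub <- ps[ps$metric == met & ps$horizon == h, ]
    ml <- tapply(sub$loss_mid, cat_of[ps$metric == met & ps$horizon == h],
                 mean)
    expect_true(ml[["LC"]] < ml[["VU"]],
                label = sprintf("LC < VU for %s/%s", met, h))
    expect_true(ml[["VU"]] < ml[["EN"]],
                label = sprintf("VU < EN for %s/%s", met, h))
    expect_true(ml[["EN"]] < ml[["CR"]],
                label = sprintf("EN < CR for %s/%s", met, h))
  }
  # known parameters are honoured: VU species with z_mar = 0.3 has
  # richness-loss bounds 1-(0.7)^0.3 and 1-(0.5)^0.3 (about 10% and 19%)
  rec1 <- data.frame(species_id = "sp1", source = "redlist", category = "VU",
                     criterion = "A2c", decline_fraction = NA,
                     pops_lost = NA, frac_below_ne500 = NA,
                     fst = 0.05, z_mar = 0.3, z_gdar = NA)
  pr3 <- project_species(rec1, tab, seed = 1)
  mar <- pr3$per_species[pr3$per_species$metric == "richness_mar", ]
  expect_equal(mar$loss_min, predict_loss(0.3, 0.7), tolerance = 1e-12)
  expect_equal(mar$loss_max, predict_loss(0.3, 0.5), tolerance = 1e-12)
  # zero-loss records project zero loss
  rec0 <- data.frame(species_id = "sp0", source = "lpi", category = NA,
                     criterion = NA, decline_fraction = 0, pops_lost = NA,
                     frac_below_ne500 = NA, fst = 0.2, z_mar = 0.3,
                     z_gdar = NA)
  pr0 <- project_species(rec0, tab, seed = 1)
  expect_equal(max(abs(pr0$per_species$loss_mid)), 0, tolerance = 1e-9)
})

test_that("aggregates are stable across seeds to Monte Carlo error", {
  L <- build_lattice(4, 4)
  p <- gd_params(mu = 1e-7, deme_size = 50)
  tab <- build_loss_table(fst_grid = c(0.05, 0.3), loss_grid = c(0, 0.4, 0.8),
                          landscape = L, params = p, horizons = "long")
  records <- synth_species_table(
    counts_by_category = c(VU = 100, EN = 100), n_lpi = 0, n_gbf = 0,
    seed = 3)
  means <- vapply(1:6, function(s) {
    pr <- project_species(records, tab, seed = s)
    a <- pr$aggregates
    a$mean_loss[a$metric == "pi_species_pi" & a$horizon == "long"]
  }, numeric(1))
  expect_lt(sd(means) / mean(means), 0.1)
})

test_that("synthetic species tables honour requested composition", {
  rec <- synth_species_table(seed = 5)
  expect_equal(nrow(rec), 2240 + 1621 + 916 + 1688 + 500 + 200)
  expect_equal(sum(rec$category == "VU", na.rm = TRUE), 2240)
  expect_equal(sum(rec$category == "EN", na.rm = TRUE), 1621)
  expect_equal(sum(rec$category == "CR", na.rm = TRUE), 916)
  expect_equal(sum(rec$category == "LC", na.rm = TRUE), 1688)
  expect_identical(rec, synth_species_table(seed = 5))
  # empty request yields an empty table with the full schema
  none <- synth_species_table(counts_by_category = c(VU = 0), n_lpi = 0,
                              n_gbf = 0)
  expect_equal(nrow(none), 0)
  expect_true(all(c("species_id", "source", "decline_fraction") %in%
                    names(none)))
  # LPI declines match the calibrated distribution (64% mean, IQR 40-93%)
  big <- synth_species_table(counts_by_category = c(VU = 0), n_lpi = 4000,
                             n_gbf = 0, seed = 8)
  expect_equal(mean(big$decline_fraction), 0.64, tolerance = 0.03)
  q <- quantile(big$decline_fraction, c(0.25, 0.75))
  expect_equal(unname(q[1]), 0.40, tolerance = 0.05)
  expect_equal(unname(q[2]), 0.93, tolerance = 0.05)
})
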