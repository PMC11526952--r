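#' Red List category to habitat-area-loss range
#'
#' Maps a Red List category to the population/area decline range of its
#' A-criteria thresholds, used as a proxy for habitat-area loss: least
#' concern / near threatened below the 25% threshold, vulnerable 30-50%,
#' endangered 50-80%, critically endangered 80-95%, extinct or likely
#' extinct 95-100%. The midpoint is the arithmetic mean of the bounds.
#'
#' @param category Red List category; accepts codes (`"LC"`, `"NT"`,
#'   `"VU"`, `"EN"`, `"CR"`, `"EX"`, `"EW"`) or full names (case
#'   insensitive).
#' @param criterion Optional criterion string (e.g. `"A2c"`), recorded but
#'   not used in the mapping.
#' @return Data frame with columns `min`, `mid`, `max` (fractions) and
#'   `criterion`; one row per input category.
#' @examples
#' category_to_area_loss("CR")$mid   # 0.875
#' @export
category_to_area_loss <- function(category, criterion = NA_character_) {
  key <- toupper(trimws(as.character(category)))
  long <- c("LEAST CONCERN" = "LC", "NEAR THREATENED" = "NT",
            "VULNERABLE" = "VU", "ENDANGERED" = "EN",
            "CRITICALLY ENDANGERED" = "CR", "EXTINCT" = "EX",
            "EXTINCT IN THE WILD" = "EW", "LIKELY EXTINCT" = "EX")
  key <- ifelse(key %in% names(long), long[key], key)
  ranges <- list(
    LC = c(0, 0.25), NT = c(0, 0.25),
    VU = c(0.30, 0.50), EN = c(0.50, 0.80), CR = c(0.80, 0.95),
    EX = c(0.95, 1.0), EW = c(0.95, 1.0)
  )
  bad <- !(key %in% names(ranges))
  if (any(bad)) stop("unknown Red List category: ",
                     paste(unique(category[bad]), collapse = ", "))
  lo <- vapply(key, function(k) ranges[[k]][1], numeric(1))
  hi <- vapply(key, function(k) ranges[[k]][2], numeric(1))
  data.frame(min = lo, mid = (lo + hi) / 2, max = hi,
             criterion = rep_len(criterion, length(key)), row.names = NULL)
}

#' Species-level population decline from census series
#'
#' For each monitored population computes the arithmetic abundance decline
#' from the earliest to the latest census, `1 - N_present / N_past`,
#' clipped to `[0, 1]`; the species value is the arithmetic mean over
#' populations. Species whose mean decline is not positive are flagged
#' `excluded` (only declining species feed diversity-loss projections).
#'
#' @param series A data frame with columns `time` and `abundance` (single
#'   population), or a list of such data frames (one per population).
#' @return List with `decline` (the clipped species mean), `raw_decline`
#'   (unclipped mean), `per_population` and `excluded`.
#' @examples
#' lpi_decline(data.frame(time = c(1970, 2020), abundance = c(100, 36)))
#' @export
lpi_decline <- function(series) {
  if (is.data.frame(series)) series <- list(series)
  if (length(series) == 0) stop("empty census series")
  per <- vapply(series, function(s) {
    stopifnot(all(c("time", "abundance") %in% names(s)))
    if (nrow(s) < 2) stop("each population needs at least 2 census points")
    s <- s[order(s$time), ]
    past <- s$abundance[1]; present <- s$abundance[nrow(s)]
    if (past <= 0) stop("earliest abundance must be positive")
    min(max(1 - present / past, 0), 1)
  }, numeric(1))
  raw <- vapply(series, function(s) {
    s <- s[order(s$time), ]
    1 - s$abundance[nrow(s)] / s$abundance[1]
  }, numeric(1))
  m <- mean(per)
  list(decline = m, raw_decline = mean(raw), per_population = per,
       excluded = mean(raw) <= 0)
}

#' Combine the two GBF genetic-indicator fractions
#'
#' Adds the fraction of populations already lost (indicator 2) and the
#' fraction of the remaining populations below the Ne = 500 safety threshold
#' (indicator 1, anticipated to be lost next):
#' `lost + (1 - lost) * below`. The display value is truncated (floored) to
#' a whole percent; the raw fraction is returned.
#'
#' @param lost_fraction Fraction of populations already lost, in `[0, 1]`.
#' @param fraction_below_ne500 Fraction of remaining populations with
#'   Ne < 500, in `[0, 1]`.
#' @return Numeric fraction with attribute `display` (e.g. `"39%"`).
#' @examples
#' combine_gbf_indicators(0.176, 0.267)   # 0.396, displayed "39%"
#' @export
combine_gbf_indicators <- function(lost_fraction, fraction_below_ne500) {
  if (any(lost_fraction < 0 | lost_fraction > 1) ||
      any(fraction_below_ne500 < 0 | fraction_below_ne500 > 1))
    stop("indicator fractions must be in [0, 1]")
  out <- lost_fraction + (1 - lost_fraction) * fraction_below_ne500
  structure(out, display = sprintf("%d%%", floor(out * 100)))
}

#' Precompute a (F_ST, area loss, horizon) diversity-loss table
#'
#' For each F_ST on the grid, tunes the migration rate of the landscape,
#' equilibrates the moment system and runs the habitat-loss scenario at each
#' area-loss level, recording the fractional loss of species-wide diversity
#' (edge contraction) or of mean within-deme diversity (the fragmentation
#' variant, where pooled diversity inflates and the within-population metric
#' is the informative one; fragmentation cells average over `n_maps` seeded
#' maps).
#'
#' @param fst_grid Ascending F_ST values.
#' @param loss_grid Ascending area-loss fractions in `[0, 1)`.
#' @param landscape A `gd_landscape` (default 10 x 10 lattice).
#' @param params A [gd_params()]; its `mig` is retuned per row.
#' @param horizons Character subset of `c("short", "medium", "long")` to
#'   compute (long = reduced equilibrium for connected survivors).
#' @param scenario `"edge_contraction"` or `"fragmentation"`.
#' @param horizon_times Named vector of generations for the horizons.
#' @param n_maps Fragmentation maps averaged per cell.
#' @param seed Seed for fragmentation maps.
#' @return An object of class `gd_loss_table`: list with `fst_grid`,
#'   `loss_grid`, `horizons`, `values` (array fst x loss x horizon of
#'   fractional losses), `metric`, `metadata`. Untunable F_ST rows are
#'   flagged in `metadata$unreachable`.
#' @export
build_loss_table <- function(fst_grid, loss_grid,
                             landscape = build_lattice(10, 10),
                             params = gd_params(mu = 1e-8, deme_size = 25),
                             horizons = c("short", "medium", "long"),
                             scenario = c("edge_contraction", "fragmentation"),
                             horizon_times = c(short = 0, medium = 2200,
                                               long = 13800),
                             n_maps = 5, seed = 1L) {
  scenario <- match.arg(scenario)
  horizons <- match.arg(horizons, c("short", "medium", "long"),
                        several.ok = TRUE)
  stopifnot(!is.unsorted(fst_grid), !is.unsorted(loss_grid))
  stopifnot(all(loss_grid >= 0), all(loss_grid < 1))
  metric <- if (scenario == "edge_contraction") "species_pi" else "local_pi"
  vals <- array(NA_real_,
                dim = c(length(fst_grid), length(loss_grid), length(horizons)),
                dimnames = list(fst = fst_grid, loss = loss_grid,
                                horizon = horizons))
  unreachable <- logical(length(fst_grid))
  migs <- numeric(length(fst_grid))
  for (fi in seq_along(fst_grid)) {
    m <- suppressWarnings(tune_migration(landscape, params, fst_grid[fi]))
    unreachable[fi] <- attr(m, "unreachable")
    migs[fi] <- as.numeric(m)
    p <- params; p$mig <- as.numeric(m)
    eq0 <- equilibrium_diversity(landscape, p)
    ref0 <- if (metric == "species_pi") species_pi(eq0) else local_pi(eq0)
    for (li in seq_along(loss_grid)) {
      fr <- loss_grid[li]
      if (fr == 0) { vals[fi, li, ] <- 0; next }
      cell <- matrix(0, 0, length(horizons))
      maps <- if (scenario == "edge_contraction") 1L else n_maps
      for (mp in seq_len(maps)) {
        removed <- if (scenario == "edge_contraction") {
          edge_contraction_demes(landscape, fr)
        } else {
          attr(fragmentation_mask(landscape, fr, seed = seed + 1000 * fi +
                                    10 * li + mp), "removed_cells")
        }
        red <- apply_habitat_loss(eq0, landscape, removed)
        st <- red$state
        prev_t <- 0
        row <- numeric(length(horizons))
        for (hi in seq_along(horizons)) {
          h <- horizons[hi]
          if (h == "long" &&
              max(landscape_components(red$landscape)) == 1L) {
            sth <- equilibrium_diversity(red$landscape, p)
          } else {
            st <- evolve_diversity(st, red$landscape, p,
                                   horizon_times[[h]] - prev_t)
            prev_t <- horizon_times[[h]]
            sth <- st
          }
          v <- if (metric == "species_pi") species_pi(sth) else local_pi(sth)
          row[hi] <- 1 - v / ref0
        }
        cell <- rbind(cell, row)
      }
      vals[fi, li, ] <- colMeans(cell)
    }
  }
  structure(
    list(fst_grid = fst_grid, loss_grid = loss_grid, horizons = horizons,
         values = vals, metric = metric, scenario = scenario,
         metadata = list(mig = migs, unreachable = unreachable,
                         params = params,
                         landscape = c(rows = landscape$rows,
                                       cols = landscape$cols),
                         horizon_times = horizon_times,
                         area_loss_proxy = paste(
                           "population/area decline used as a proxy for",
                           "habitat loss"))),
    class = "gd_loss_table"
  )
}

#' @export
print.gd_loss_table <- function(x, ...) {
  cat(sprintf("Loss table (%s, %s): %d F_ST x %d loss x %d horizons\n",
              x$scenario, x$metric, length(x$fst_grid), length(x$loss_grid),
              length(x$horizons)))
  invisible(x)
}

#' Interpolated lookup in a loss table
#'
#' Bilinear interpolation of the fractional diversity loss between the
#' (F_ST, area-loss) grid nodes at a given horizon; queries outside the grid
#' are clamped to its edges.
#'
#' @param table A [build_loss_table()] result.
#' @param fst,loss Query coordinates (vectorized, recycled).
#' @param horizon One of the table's horizons.
#' @return Numeric vector of fractional losses.
#' @export
loss_lookup <- function(table, fst, loss, horizon = "long") {
  stopifnot(inherits(table, "gd_loss_table"))
  if (!(horizon %in% table$horizons))
    stop("horizon not present in table: ", horizon)
  n <- max(length(fst), length(loss))
  fst <- rep_len(fst, n); loss <- rep_len(loss, n)
  V <- table$values[, , horizon, drop = TRUE]
  if (is.null(dim(V))) V <- matrix(V, length(table$fst_grid),
                                   length(table$loss_grid))
  interp1 <- function(grid, q) {
    q <- pmin(pmax(q, grid[1]), grid[length(grid)])
    i <- findInterval(q, grid, rightmost.closed = TRUE)
    i <- pmin(i, length(grid) - 1L)
    if (length(grid) == 1L) return(list(i = rep(1L, length(q)),
                                        w = rep(0, length(q))))
    w <- (q - grid[i]) / (grid[i + 1L] - grid[i])
    list(i = i, w = w)
  }
  a <- interp1(table$fst_grid, fst)
  b <- interp1(table$loss_grid, loss)
  if (length(table$fst_grid) == 1L) {
    v0 <- V[1, b$i]; v1 <- V[1, pmin(b$i + 1L, ncol(V))]
    return(v0 * (1 - b$w) + v1 * b$w)
  }
  i2 <- pmin(a$i + 1L, nrow(V)); j2 <- pmin(b$i + 1L, ncol(V))
  v00 <- V[cbind(a$i, b$i)]; v10 <- V[cbind(i2, b$i)]
  v01 <- V[cbind(a$i, j2)]; v11 <- V[cbind(i2, j2)]
  (v00 * (1 - a$w) + v10 * a$w) * (1 - b$w) +
    (v01 * (1 - a$w) + v11 * a$w) * b$w
}

#' Project diversity losses for a species-indicator table
#'
#' Translates each species record into area-loss bounds (Red List category
#' range, LPI decline, or combined GBF indicators), assigns F_ST and
#' power-law exponents (known values where present, otherwise drawn from the
#' distribution of species with genomic data: F_ST from a Normal(0.270,
#' 0.211) truncated to `[0.01, 0.99]`, exponents uniform on `[0.01, 0.8]`),
#' and computes richness losses via the MAR power law and nucleotide-
#' diversity losses via the moment-system loss table at every horizon.
#'
#' @param records Data frame as produced by [synth_species_table()] (columns
#'   `species_id`, `source`, `category`, `criterion`, `decline_fraction`,
#'   `pops_lost`, `frac_below_ne500`, `fst`, `z_mar`, `z_gdar`).
#' @param table A [build_loss_table()] result (pi losses).
#' @param sampling List of sampling-distribution settings:
#'   `fst_mean`, `fst_sd`, `fst_range`, `z_range`.
#' @param seed RNG seed (projections are reproducible given the seed).
#' @return An object of class `gd_projection`: list with `per_species`
#'   (long data frame: species_id, source, metric, horizon, loss_min,
#'   loss_mid, loss_max, fst, z), `aggregates` (mean and quartiles of
#'   `loss_mid` by source, metric, horizon) and `seed`.
#' @export
project_species <- function(records, table,
                            sampling = list(fst_mean = 0.270, fst_sd = 0.211,
                                            fst_range = c(0.01, 0.99),
                                            z_range = c(0.01, 0.8)),
                            seed = 1L) {
  stopifnot(is.data.frame(records), inherits(table, "gd_loss_table"))
  need <- c("species_id", "source")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  n <- nrow(records)
  set.seed(seed)
  # area-loss bounds per record
  lo <- mid <- hi <- numeric(n)
  for (i in seq_len(n)) {
    src <- records$source[i]
    if (src == "redlist") {
      r <- category_to_area_loss(records$category[i])
      lo[i] <- r$min; mid[i] <- r$mid; hi[i] <- r$max
    } else if (src == "lpi") {
      d <- records$decline_fraction[i]
      if (is.na(d)) stop("lpi record without decline_fraction: row ", i)
      lo[i] <- mid[i] <- hi[i] <- d
    } else if (src == "gbf") {
      d <- as.numeric(combine_gbf_indicators(records$pops_lost[i],
                                             records$frac_below_ne500[i]))
      lo[i] <- records$pops_lost[i]       # already-lost populations only
      mid[i] <- hi[i] <- d                # plus those below the Ne threshold
    } else stop("unknown source: ", src)
  }
  draw_trunc_norm <- function(k, mean, sd, range) {
    out <- numeric(k)
    todo <- seq_len(k)
    while (length(todo)) {
      cand <- stats::rnorm(length(todo), mean, sd)
      ok <- cand >= range[1] & cand <= range[2]
      out[todo[ok]] <- cand[ok]
      todo <- todo[!ok]
    }
    out
  }
  fst <- if ("fst" %in% names(records)) records$fst else rep(NA_real_, n)
  z_mar <- if ("z_mar" %in% names(records)) records$z_mar else rep(NA_real_, n)
  miss_f <- is.na(fst); miss_z <- is.na(z_mar)
  fst[miss_f] <- draw_trunc_norm(sum(miss_f), sampling$fst_mean,
                                 sampling$fst_sd, sampling$fst_range)
  z_mar[miss_z] <- stats::runif(sum(miss_z), sampling$z_range[1],
                                sampling$z_range[2])
  per <- list()
  for (h in table$horizons) {
    per[[length(per) + 1L]] <- data.frame(
      species_id = records$species_id, source = records$source,
      metric = paste0("pi_", table$metric), horizon = h,
      loss_min = loss_lookup(table, fst, lo, h),
      loss_mid = loss_lookup(table, fst, mid, h),
      loss_max = loss_lookup(table, fst, hi, h),
      fst = fst, z = NA_real_
    )
  }
  per[[length(per) + 1L]] <- data.frame(
    species_id = records$species_id, source = records$source,
    metric = "richness_mar", horizon = "short",
    loss_min = predict_loss(z_mar, 1 - lo),
    loss_mid = predict_loss(z_mar, 1 - mid),
    loss_max = predict_loss(z_mar, 1 - hi),
    fst = NA_real_, z = z_mar
  )
  per <- do.call(rbind, per)
  # min <= mid <= max even where the table is locally non-monotone
  swap <- per$loss_min > per$loss_max
  tmp <- per$loss_min[swap]
  per$loss_min[swap] <- per$loss_max[swap]; per$loss_max[swap] <- tmp
  agg <- do.call(rbind, lapply(
    split(per, list(per$source, per$metric, per$horizon), drop = TRUE),
    function(d) data.frame(
      source = d$source[1], metric = d$metric[1], horizon = d$horizon[1],
      n = nrow(d), mean_loss = mean(d$loss_mid),
      q25 = unname(stats::quantile(d$loss_mid, 0.25)),
      q75 = unname(stats::quantile(d$loss_mid, 0.75))
    )))
  rownames(agg) <- NULL
  structure(list(per_species = per, aggregates = agg, seed = seed,
                 metadata = table$metadata["area_loss_proxy"]),
            class = "gd_projection")
}

#' @export
print.gd_projection <- function(x, ...) {
  cat(sprintf("Diversity-loss projection for %d species records\n",
              length(unique(x$per_species$species_id))))
  a <- x$aggregates
  a$mean_loss <- sprintf("%.1f%%", 100 * a$mean_loss)
  a$q25 <- sprintf("%.1f%%", 100 * a$q25)
  a$q75 <- sprintf("%.1f%%", 100 * a$q75)
  print(a)
  invisible(x)
}

#' Generate a synthetic species-indicator table
#'
#' Stands in for Red List / Living Planet Index / GBF-indicator downloads:
#' Red List records with requested per-category counts (defaults mirror the
#' A2-4c tallies 2240 VU / 1621 EN / 916 CR / 1688 LC), LPI records with
#' Beta-distributed declines calibrated to a 64% mean and a 40-93%
#' interquartile range, and GBF records with zero-inflated Beta indicator
#' pairs calibrated to means of roughly 18% populations lost and 24% of the
#' remainder below Ne = 500.
#'
#' @param counts_by_category Named integer vector of Red List counts
#'   (names among LC/NT/VU/EN/CR/EX).
#' @param n_lpi Number of LPI species records.
#' @param n_gbf Number of GBF species records.
#' @param lpi_params List `(shape1, shape2)` of the decline Beta.
#' @param gbf_params List `(p0_lost, lost_shape, p0_below, below_shape)`
#'   with two-element shape vectors.
#' @param seed RNG seed.
#' @return Data frame with the record schema of [project_species()].
#' @export
synth_species_table <- function(counts_by_category = c(VU = 2240, EN = 1621,
                                                       CR = 916, LC = 1688),
                                n_lpi = 500, n_gbf = 200,
                                lpi_params = list(shape1 = 0.926,
                                                  shape2 = 0.510),
                                gbf_params = list(p0_lost = 0.3,
                                                  lost_shape = c(0.5, 1.5),
                                                  p0_below = 0.25,
                                                  below_shape = c(1.16, 2.46)),
                                seed = 1L) {
  stopifnot(all(counts_by_category >= 0), n_lpi >= 0, n_gbf >= 0)
  set.seed(seed)
  empty <- data.frame(species_id = character(0), source = character(0),
                      category = character(0), criterion = character(0),
                      decline_fraction = numeric(0), pops_lost = numeric(0),
                      frac_below_ne500 = numeric(0), fst = numeric(0),
                      z_mar = numeric(0), z_gdar = numeric(0))
  out <- list(empty)
  if (sum(counts_by_category) > 0) {
    cats <- rep(names(counts_by_category), counts_by_category)
    out[[length(out) + 1L]] <- data.frame(
      species_id = sprintf("rl_%05d", seq_along(cats)), source = "redlist",
      category = cats,
      criterion = sample(c("A2c", "A2bc", "A4c", "A3c"), length(cats),
                         replace = TRUE),
      decline_fraction = NA_real_, pops_lost = NA_real_,
      frac_below_ne500 = NA_real_, fst = NA_real_, z_mar = NA_real_,
      z_gdar = NA_real_
    )
  }
  if (n_lpi > 0) {
    out[[length(out) + 1L]] <- data.frame(
      species_id = sprintf("lpi_%05d", seq_len(n_lpi)), source = "lpi",
      category = NA_character_, criterion = NA_character_,
      decline_fraction = stats::rbeta(n_lpi, lpi_params$shape1,
                                      lpi_params$shape2),
      pops_lost = NA_real_, frac_below_ne500 = NA_real_, fst = NA_real_,
      z_mar = NA_real_, z_gdar = NA_real_
    )
  }
  if (n_gbf > 0) {
    lost <- ifelse(stats::runif(n_gbf) < gbf_params$p0_lost, 0,
                   stats::rbeta(n_gbf, gbf_params$lost_shape[1],
                                gbf_params$lost_shape[2]))
    below <- ifelse(stats::runif(n_gbf) < gbf_params$p0_below, 0,
                    stats::rbeta(n_gbf, gbf_params$below_shape[1],
                                 gbf_params$below_shape[2]))
    out[[length(out) + 1L]] <- data.frame(
      species_id = sprintf("gbf_%05d", seq_len(n_gbf)), source = "gbf",
      category = NA_character_, criterion = NA_character_,
      decline_fraction = NA_real_, pops_lost = lost,
      frac_below_ne500 = below, fst = NA_real_, z_mar = NA_real_,
      z_gdar = NA_real_
    )
  }
  do.call(rbind, out)
}
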