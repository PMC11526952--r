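#' Habitat-destruction scenario specification
#'
#' Bundles the knobs of a habitat-loss (or restoration) experiment: which
#' spatial pattern of loss, how much habitat is removed, at what cadence, and
#' the three reporting horizons in generations after the loss event.
#'
#' @param scenario One of `"edge_contraction"`, `"fragmentation"`,
#'   `"gradual"`, `"restoration"`.
#' @param loss_fraction Fraction of occupied cells removed (in `[0, 1)`); for
#'   restoration, the fraction of the landscape currently missing.
#' @param cell_block Fragmentation resolution as a fraction of the landscape
#'   area per removed block (default 1/100, i.e. single cells on a 10 x 10
#'   grid; 1/400 and 1/12 are supported on grids where the implied square
#'   block fits).
#' @param rate For gradual scenarios: fraction of the original habitat
#'   removed per removal step (default 0.01).
#' @param rate_interval Generations between gradual removal steps (default 1;
#'   set to 11 for a 1%-per-11-generations cadence).
#' @param seed Integer seed for stochastic removal patterns.
#' @param horizons Named numeric vector `c(short=, medium=, long=)` of
#'   generations after the loss event; must be non-decreasing. Defaults to
#'   0, 2200 and 13800 generations.
#' @param mode Restoration mode, `"natural"` or `"translocation"`.
#' @return An object of class `gd_scenario`.
#' @export
gd_scenario <- function(scenario = c("edge_contraction", "fragmentation",
                                     "gradual", "restoration"),
                        loss_fraction,
                        cell_block = 1 / 100,
                        rate = 0.01,
                        rate_interval = 1,
                        seed = 1L,
                        horizons = c(short = 0, medium = 2200, long = 13800),
                        mode = c("natural", "translocation")) {
  scenario <- match.arg(scenario)
  mode <- match.arg(mode)
  stopifnot(loss_fraction >= 0, loss_fraction < 1)
  stopifnot(length(horizons) == 3L, !is.unsorted(horizons))
  if (is.null(names(horizons))) names(horizons) <- c("short", "medium", "long")
  structure(
    list(scenario = scenario, loss_fraction = loss_fraction,
         cell_block = cell_block, rate = rate, rate_interval = rate_interval,
         seed = as.integer(seed), horizons = horizons, mode = mode),
    class = "gd_scenario"
  )
}

#' Demes removed by edge contraction
#'
#' Deterministic removal of habitat from the western edge of the range:
#' whole columns are removed west to east until `floor(loss_fraction * D)`
#' cells are gone, completing a partial final column from the top down.
#'
#' @param landscape A `gd_landscape`.
#' @param loss_fraction Fraction in `[0, 1)` of occupied cells to remove.
#' @param edge Which edge retreats: `"west"` (default), `"east"`, `"north"`
#'   or `"south"`.
#' @return Integer cell ids of the removed demes (possibly empty).
#' @export
edge_contraction_demes <- function(landscape, loss_fraction, edge = "west") {
  stopifnot(loss_fraction >= 0, loss_fraction < 1)
  n <- floor(loss_fraction * length(landscape$demes))
  if (n == 0L) return(integer(0))
  rc <- landscape$coords
  ord <- switch(edge,
    west  = order(rc[, "col"], rc[, "row"]),
    east  = order(-rc[, "col"], rc[, "row"]),
    north = order(rc[, "row"], rc[, "col"]),
    south = order(-rc[, "row"], rc[, "col"]),
    stop("unknown edge: ", edge)
  )
  landscape$demes[ord[seq_len(n)]]
}

#' Random-fragmentation occupancy mask
#'
#' Removes square blocks of cells uniformly at random (without replacement)
#' until at least `loss_fraction` of the occupied cells are gone. The block
#' side is `round(sqrt(cell_block * rows * cols))` cells (minimum 1); blocks
#' tile the grid from the top-left corner and cells outside complete blocks
#' are never removed. Because blocks are removed whole, the realized loss can
#' differ from the target; it is recorded in the `realized_loss` attribute.
#'
#' @param landscape A `gd_landscape`.
#' @param loss_fraction Target fraction of occupied cells to remove.
#' @param cell_block Block area as a fraction of the landscape (default
#'   1/100).
#' @param seed Integer RNG seed (removals are reproducible given the seed).
#' @return A logical occupancy mask (same shape as `landscape$mask`) with
#'   attributes `realized_loss`, `removed_cells` and `block_side`.
#' @export
fragmentation_mask <- function(landscape, loss_fraction, cell_block = 1 / 100,
                               seed = 1L) {
  stopifnot(loss_fraction >= 0, loss_fraction < 1)
  rows <- landscape$rows; cols <- landscape$cols
  b <- max(1L, as.integer(round(sqrt(cell_block * rows * cols))))
  if (b > rows || b > cols)
    stop(sprintf("block side %d exceeds grid dimensions %d x %d", b, rows, cols))
  n_occ <- length(landscape$demes)
  target <- floor(loss_fraction * n_occ)
  mask <- landscape$mask
  if (target == 0L) {
    return(structure(mask, realized_loss = 0, removed_cells = integer(0),
                     block_side = b))
  }
  tiles <- expand.grid(br = seq_len(rows %/% b), bc = seq_len(cols %/% b))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  ord <- sample(nrow(tiles))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  removed <- integer(0)
  for (k in ord) {
    rr <- (tiles$br[k] - 1L) * b + seq_len(b)
    cc <- (tiles$bc[k] - 1L) * b + seq_len(b)
    cells <- as.integer(outer(rr, (cc - 1L) * rows, "+"))
    cells <- cells[mask[cells]]
    if (length(cells) == 0L) next
    if (sum(mask) - length(cells) < 1L) next      # keep at least one deme
    mask[cells] <- FALSE
    removed <- c(removed, cells)
    if (length(removed) >= target) break
  }
  structure(mask, realized_loss = length(removed) / n_occ,
            removed_cells = removed, block_side = b)
}

#' Run a habitat-destruction scenario on the moment system
#'
#' Equilibrates the landscape, applies the scenario's habitat-loss event and
#' summarizes the diversity trajectory at the short, medium and long
#' horizons. The short-term state is the instantaneous post-removal
#' restriction; the medium term integrates the moment system to
#' `horizons["medium"]` generations; the long term is the reduced system's
#' exact equilibrium when the surviving landscape is a single connected
#' component, and otherwise the state integrated to `horizons["long"]`
#' generations (under infinite-sites mutation, diversity between isolated
#' fragments grows without bound, so no equilibrium exists). Gradual
#' scenarios interleave removal steps with evolution; restoration scenarios
#' start from the contracted landscape's equilibrium, add the missing cells
#' back via [restore_habitat()] and report the remaining deficit relative to
#' the full landscape's equilibrium.
#'
#' @param spec A [gd_scenario()].
#' @param landscape A `gd_landscape` (the pre-loss landscape).
#' @param params A [gd_params()].
#' @return An object of class `gd_trajectory`: list with `times`,
#'   `species_pi`, `local_pi` (series over the recorded times), `summaries`
#'   (data frame of fractional losses per horizon and metric),
#'   `n_components`, `realized_loss` and the pre-loss reference values.
#' @export
run_scenario <- function(spec, landscape, params) {
  stopifnot(inherits(spec, "gd_scenario"))
  if (spec$scenario == "restoration") {
    return(run_restoration(spec, landscape, params))
  }
  eq0 <- equilibrium_diversity(landscape, params)
  sp0 <- species_pi(eq0); lp0 <- local_pi(eq0)
  realized <- spec$loss_fraction
  if (spec$scenario == "edge_contraction") {
    removed <- edge_contraction_demes(landscape, spec$loss_fraction)
    red <- apply_habitat_loss(eq0, landscape, removed)
  } else if (spec$scenario == "fragmentation") {
    mask <- fragmentation_mask(landscape, spec$loss_fraction, spec$cell_block,
                               spec$seed)
    removed <- attr(mask, "removed_cells")
    realized <- attr(mask, "realized_loss")
    red <- apply_habitat_loss(eq0, landscape, removed)
  } else {                                # gradual
    red <- run_gradual_loss(spec, landscape, params, eq0)
  }
  st_short <- red$state; lsc <- red$landscape
  comp <- landscape_components(lsc)
  n_comp <- max(comp)
  h <- spec$horizons
  st_med <- evolve_diversity(st_short, lsc, params, h[["medium"]])
  if (n_comp == 1L) {
    st_long <- equilibrium_diversity(lsc, params)
  } else {
    st_long <- evolve_diversity(st_med, lsc, params,
                                h[["long"]] - h[["medium"]])
  }
  times <- unname(h)
  sp <- c(species_pi(st_short), species_pi(st_med), species_pi(st_long))
  lp <- c(local_pi(st_short), local_pi(st_med), local_pi(st_long))
  summaries <- data.frame(
    horizon = c("short", "medium", "long"),
    time = times,
    species_loss = 1 - sp / sp0,
    local_loss = 1 - lp / lp0,
    row.names = NULL
  )
  structure(
    list(times = times, species_pi = sp, local_pi = lp,
         summaries = summaries, n_components = n_comp,
         realized_loss = realized, species_pi0 = sp0, local_pi0 = lp0,
         scenario = spec$scenario),
    class = "gd_trajectory"
  )
}

# Gradual loss: remove `rate * D0` west-edge cells per `rate_interval`
# generations (in edge-contraction order), evolving between steps, until the
# target count is reached. Returns the state/landscape at the end of loss.
run_gradual_loss <- function(spec, landscape, params, eq0) {
  D0 <- length(landscape$demes)
  target <- floor(spec$loss_fraction * D0)
  order_all <- edge_contraction_demes(landscape,
                                      loss_fraction = (D0 - 1) / D0)
  per_step <- max(1L, round(spec$rate * D0))
  st <- eq0; lsc <- landscape
  removed_so_far <- 0L
  while (removed_so_far < target) {
    k <- min(per_step, target - removed_so_far)
    chunk <- order_all[removed_so_far + seq_len(k)]
    red <- apply_habitat_loss(st, lsc, chunk)
    st <- red$state; lsc <- red$landscape
    removed_so_far <- removed_so_far + k
    if (removed_so_far < target)
      st <- evolve_diversity(st, lsc, params, spec$rate_interval)
  }
  list(state = st, landscape = lsc)
}

run_restoration <- function(spec, landscape, params) {
  removed <- edge_contraction_demes(landscape, spec$loss_fraction)
  keep_mask <- landscape$mask
  keep_mask[removed] <- FALSE
  contracted <- landscape_from_mask(keep_mask)
  contracted$params <- landscape$params
  eq_red <- equilibrium_diversity(contracted, params)
  eq_full <- equilibrium_diversity(landscape, params)
  sp_ref <- species_pi(eq_full); lp_ref <- local_pi(eq_full)
  res <- restore_habitat(eq_red, contracted, removed, mode = spec$mode)
  st0 <- res$state; lsc <- res$landscape
  h <- spec$horizons
  st_med <- evolve_diversity(st0, lsc, params, h[["medium"]])
  st_long <- equilibrium_diversity(lsc, params)
  sp <- c(species_pi(st0), species_pi(st_med), species_pi(st_long))
  lp <- c(local_pi(st0), local_pi(st_med), local_pi(st_long))
  summaries <- data.frame(
    horizon = c("short", "medium", "long"),
    time = unname(h),
    species_loss = 1 - sp / sp_ref,
    local_loss = 1 - lp / lp_ref,
    row.names = NULL
  )
  structure(
    list(times = unname(h), species_pi = sp, local_pi = lp,
         summaries = summaries, n_components = max(landscape_components(lsc)),
         realized_loss = -spec$loss_fraction, species_pi0 = sp_ref,
         local_pi0 = lp_ref, scenario = "restoration"),
    class = "gd_trajectory"
  )
}

#' @export
print.gd_trajectory <- function(x, ...) {
  cat(sprintf("Scenario trajectory (%s, realized loss %.1f%%, %d component%s)\n",
              x$scenario, 100 * x$realized_loss, x$n_components,
              if (x$n_components > 1) "s" else ""))
  print(transform(x$summaries,
                  species_loss = sprintf("%.2f%%", 100 * species_loss),
                  local_loss = sprintf("%.2f%%", 100 * local_loss)))
  invisible(x)
}

#' Restore habitat cells to a landscape
#'
#' Adds currently unoccupied cells back to the landscape and initializes
#' their expected-diversity rows. In `"natural"` mode each new deme is
#' founded from its nearest occupied deme and copies that deme's diversity
#' relationships; in `"translocation"` mode founders are drawn uniformly
#' across the whole landscape, so the new deme's within diversity equals the
#' current species-wide diversity and its between rows equal the mean of the
#' existing rows.
#'
#' @param state A [gd_diversity()] on `landscape`.
#' @param landscape A `gd_landscape`.
#' @param new_cells Integer cell ids to occupy (must be unoccupied).
#' @param mode `"natural"` or `"translocation"`.
#' @return List with elements `state` and `landscape` (both enlarged).
#' @export
restore_habitat <- function(state, landscape, new_cells,
                            mode = c("natural", "translocation")) {
  mode <- match.arg(mode)
  new_cells <- as.integer(new_cells)
  if (any(new_cells %in% landscape$demes))
    stop("some cells to restore are already occupied")
  if (any(new_cells < 1L | new_cells > landscape$rows * landscape$cols))
    stop("cell ids outside the grid")
  mask <- landscape$mask
  mask[new_cells] <- TRUE
  lsc2 <- landscape_from_mask(mask)
  lsc2$params <- landscape$params
  old <- landscape$demes
  D2 <- length(lsc2$demes)
  P2 <- matrix(NA_real_, D2, D2)
  old_pos <- match(old, lsc2$demes)
  new_pos <- match(new_cells, lsc2$demes)
  P2[old_pos, old_pos] <- state$pi
  if (mode == "natural") {
    rows <- landscape$rows
    rc_new <- cbind((new_cells - 1L) %% rows + 1L, (new_cells - 1L) %/% rows + 1L)
    src <- vapply(seq_along(new_cells), function(k) {
      d2 <- (landscape$coords[, 1] - rc_new[k, 1])^2 +
        (landscape$coords[, 2] - rc_new[k, 2])^2
      which.min(d2)                       # index into old demes; ties -> first
    }, integer(1))
    P2[new_pos, old_pos] <- state$pi[src, , drop = FALSE]
    P2[old_pos, new_pos] <- t(state$pi[src, , drop = FALSE])
    P2[new_pos, new_pos] <- state$pi[src, src, drop = FALSE]
  } else {
    sp <- species_pi(state)
    colm <- colMeans(state$pi)
    P2[new_pos, old_pos] <- matrix(colm, length(new_pos), length(old_pos),
                                   byrow = TRUE)
    P2[old_pos, new_pos] <- t(P2[new_pos, old_pos, drop = FALSE])
    P2[new_pos, new_pos] <- sp
  }
  list(state = gd_diversity((P2 + t(P2)) / 2, lsc2$demes), landscape = lsc2)
}

#' Binary-landscape fragmentation metrics
#'
#' Standard patch metrics on an occupancy mask under the 4-neighbour patch
#' definition: patch count and mean size (flood fill), total core area
#' (occupied cells whose four neighbours are all occupied), total patch
#' perimeter (unit edges between an occupied cell and grid boundary or
#' unoccupied cell), edge density (occupied-occupied adjacencies per grid
#' cell), patch density, and connectedness (fraction of occupied-occupied
#' adjacencies among all grid adjacencies touching at least one occupied
#' cell).
#'
#' @param mask Logical occupancy matrix (or a `gd_landscape`, whose mask is
#'   used).
#' @return A list of class `gd_fragmetrics` with fields `patch_count`,
#'   `mean_patch_size`, `core_area_total`, `perimeter_total`, `edge_density`,
#'   `patch_density`, `connectedness`, `occupied`.
#' @export
landscape_metrics <- function(mask) {
  if (inherits(mask, "gd_landscape")) mask <- mask$mask
  stopifnot(is.matrix(mask), is.logical(mask))
  rows <- nrow(mask); cols <- ncol(mask)
  n_occ <- sum(mask)
  if (n_occ == 0L) {
    return(structure(list(patch_count = 0L, mean_patch_size = 0,
                          core_area_total = 0L, perimeter_total = 0L,
                          edge_density = 0, patch_density = 0,
                          connectedness = NA_real_, occupied = 0L),
                     class = "gd_fragmetrics"))
  }
  lsc <- landscape_from_mask(mask)
  comp <- landscape_components(lsc)
  occ_edges <- sum(lsc$adjacency) / 2
  # neighbour counts per occupied cell
  deg <- Matrix::rowSums(lsc$adjacency)
  core <- sum(deg == 4L)
  perimeter <- sum(4L - deg)
  # grid adjacencies touching at least one occupied cell
  horiz <- mask[, -cols, drop = FALSE] | mask[, -1, drop = FALSE]
  vert <- mask[-rows, , drop = FALSE] | mask[-1, , drop = FALSE]
  touching <- sum(horiz) + sum(vert)
  structure(
    list(patch_count = max(comp),
         mean_patch_size = n_occ / max(comp),
         core_area_total = core,
         perimeter_total = perimeter,
         edge_density = occ_edges / (rows * cols),
         patch_density = max(comp) / (rows * cols),
         connectedness = if (touching > 0) occ_edges / touching else NA_real_,
         occupied = n_occ),
    class = "gd_fragmetrics"
  )
}

#' @export
print.gd_fragmetrics <- function(x, ...) {
  cat("Fragmentation metrics:\n")
  cat(sprintf("  patches: %d (mean size %.2f), occupied cells: %d\n",
              x$patch_count, x$mean_patch_size, x$occupied))
  cat(sprintf("  core area: %d, perimeter: %d, connectedness: %.3f\n",
              x$core_area_total, x$perimeter_total, x$connectedness))
  invisible(x)
}
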