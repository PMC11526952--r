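#' Read a run configuration
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON (`.json`) configuration file into a
#' named list. Configurations round-trip unchanged through
#' [write_run_config()].
#'
#' @param path File path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be .yaml/.yml or .json, got: ", path)
}

#' Write a run configuration
#'
#' @param config Named list.
#' @param path Destination (`.yaml`, `.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::write_yaml(config, path)
  } else if (ext == "json") {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else stop("config must be .yaml/.yml or .json, got: ", path)
  invisible(path)
}

#' Write / read a diversity matrix as CSV
#'
#' The CSV carries deme ids as header and row names, so the matrix
#' round-trips exactly (up to numeric formatting).
#'
#' @param state A [gd_diversity()].
#' @param path Destination CSV.
#' @return `path` invisibly, or the re-read `gd_diversity`.
#' @export
write_diversity_csv <- function(state, path) {
  stopifnot(inherits(state, "gd_diversity"))
  df <- as.data.frame(state$pi)
  names(df) <- state$demes
  utils::write.csv(cbind(deme = state$demes, df), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_diversity_csv
#' @export
read_diversity_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  demes <- as.integer(df$deme)
  P <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(as.integer(colnames(P)), demes))
    stop("malformed diversity CSV (header/deme mismatch): ", path)
  gd_diversity(unname(P), demes)
}

#' Write / read an occupancy mask as a 0/1 text grid
#'
#' @param mask Logical matrix (or `gd_landscape`).
#' @param path Destination text file (one row per line, digits `0`/`1`
#'   separated by spaces).
#' @return `path` invisibly, or the re-read logical matrix.
#' @export
write_mask_txt <- function(mask, path) {
  if (inherits(mask, "gd_landscape")) mask <- mask$mask
  writeLines(apply(mask * 1L, 1, paste, collapse = " "), path)
  invisible(path)
}

#' @rdname write_mask_txt
#' @export
read_mask_txt <- function(path) {
  lines <- readLines(path)
  rows <- lapply(seq_along(lines), function(i) {
    v <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (!all(v %in% c("0", "1")))
      stop(sprintf("%s:%d: mask entries must be 0 or 1", path, i))
    as.integer(v)
  })
  if (length(unique(lengths(rows))) != 1)
    stop(path, ": ragged mask rows")
  matrix(unlist(rows) == 1L, nrow = length(rows), byrow = TRUE)
}

#' Write a trajectory as tidy CSV plus a JSON summary
#'
#' @param traj A `gd_trajectory` from [run_scenario()].
#' @param csv_path Tidy series CSV (time, metric, value).
#' @param json_path Optional JSON file with the per-horizon loss summaries.
#' @return `csv_path`, invisibly.
#' @export
write_trajectory <- function(traj, csv_path, json_path = NULL) {
  stopifnot(inherits(traj, "gd_trajectory"))
  tidy <- rbind(
    data.frame(time = traj$times, metric = "species_pi",
               value = traj$species_pi),
    data.frame(time = traj$times, metric = "local_pi", value = traj$local_pi)
  )
  utils::write.csv(tidy, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(scenario = traj$scenario, realized_loss = traj$realized_loss,
           n_components = traj$n_components, summaries = traj$summaries),
      json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(csv_path)
}

# ---- command implementations ----------------------------------------------

landscape_from_config <- function(config) {
  lc <- config$landscape
  if (is.null(lc)) stop("config is missing the `landscape` block")
  if (!is.null(lc$mask_file)) {
    landscape_from_mask(read_mask_txt(lc$mask_file))
  } else {
    if (is.null(lc$rows) || is.null(lc$cols))
      stop("config landscape block needs `rows` and `cols` (or `mask_file`)")
    build_lattice(lc$rows, lc$cols)
  }
}

params_from_config <- function(config, landscape) {
  pc <- config$params
  if (is.null(pc)) stop("config is missing the `params` block")
  if (is.null(pc$deme_size)) stop("config params block needs `deme_size`")
  mu <- if (!is.null(pc$mu)) pc$mu else if (!is.null(pc$theta)) {
    mu_for_theta(pc$theta, pc$deme_size, length(landscape$demes))
  } else stop("config params block needs `mu` or `theta`")
  p <- gd_params(mu = mu, deme_size = pc$deme_size,
                 mig = if (!is.null(pc$mig)) pc$mig else 0)
  if (is.null(pc$mig) && !is.null(pc$target_fst)) {
    p$mig <- as.numeric(suppressWarnings(
      tune_migration(landscape, p, pc$target_fst)))
  }
  p
}

write_manifest <- function(out_dir, command, config, seed, started) {
  jsonlite::write_json(
    list(command = command, config = config, seed = seed,
         package = "gdforecast",
         version = as.character(utils::packageVersion("gdforecast")),
         r_version = R.version.string,
         runtime_seconds = as.numeric(difftime(Sys.time(), started,
                                               units = "secs"))),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the `solve` command: equilibrium diversity report
#'
#' Builds the configured landscape and parameters, solves the equilibrium
#' moment system and writes `diversity.csv` (the pairwise matrix) and
#' `summary.json` (species-wide pi, mean local pi, average pairwise F_ST)
#' plus a reproducibility manifest into `out_dir`.
#'
#' @param config Named list (see [read_run_config()]) with blocks
#'   `landscape` (`rows`, `cols` or `mask_file`) and `params` (`deme_size`,
#'   `mu` or `theta`, `mig` or `target_fst`).
#' @param out_dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest (solve is deterministic).
#' @return Invisibly, the summary list.
#' @export
cmd_solve <- function(config, out_dir, seed = 1L) {
  started <- Sys.time()
  lsc <- landscape_from_config(config)
  p <- params_from_config(config, lsc)
  eq <- equilibrium_diversity(lsc, p)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_diversity_csv(eq, file.path(out_dir, "diversity.csv"))
  summary <- list(
    species_pi = species_pi(eq), local_pi = local_pi(eq),
    fst = if (length(lsc$demes) > 1) pairwise_fst(eq) else NA,
    theta = theta(p, lsc), mig = p$mig, n_demes = length(lsc$demes))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(out_dir, "solve", config, seed, started)
  invisible(summary)
}

#' Run the `scenario` command
#'
#' @inheritParams cmd_solve
#' @return Invisibly, the `gd_trajectory`.
#' @export
cmd_scenario <- function(config, out_dir, seed = 1L) {
  started <- Sys.time()
  lsc <- landscape_from_config(config)
  p <- params_from_config(config, lsc)
  sc <- config$scenario
  if (is.null(sc)) stop("config is missing the `scenario` block")
  args <- sc[intersect(names(sc), names(formals(gd_scenario)))]
  if (is.null(args$seed)) args$seed <- seed
  if (!is.null(args$horizons)) args$horizons <- unlist(args$horizons)
  spec <- do.call(gd_scenario, args)
  traj <- run_scenario(spec, lsc, p)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_trajectory(traj, file.path(out_dir, "trajectory.csv"),
                   file.path(out_dir, "summary.json"))
  write_manifest(out_dir, "scenario", config, seed, started)
  invisible(traj)
}

#' Run the `table` command: precompute a loss table
#'
#' Writes `loss_table.csv` (tidy: fst, loss, horizon, value) and a JSON
#' sidecar with the axes and metadata.
#'
#' @inheritParams cmd_solve
#' @return Invisibly, the `gd_loss_table`.
#' @export
cmd_table <- function(config, out_dir, seed = 1L) {
  started <- Sys.time()
  lsc <- landscape_from_config(config)
  p <- params_from_config(config, lsc)
  tc <- config$table
  if (is.null(tc)) stop("config is missing the `table` block")
  tab <- build_loss_table(
    fst_grid = unlist(tc$fst_grid), loss_grid = unlist(tc$loss_grid),
    landscape = lsc, params = p,
    horizons = if (!is.null(tc$horizons)) unlist(tc$horizons)
               else c("short", "medium", "long"),
    scenario = if (!is.null(tc$scenario)) tc$scenario else "edge_contraction",
    seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tidy <- expand.grid(fst = tab$fst_grid, loss = tab$loss_grid,
                      horizon = tab$horizons, stringsAsFactors = FALSE)
  tidy$value <- as.vector(tab$values)
  utils::write.csv(tidy, file.path(out_dir, "loss_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(fst_grid = tab$fst_grid, loss_grid = tab$loss_grid,
         horizons = tab$horizons, metric = tab$metric,
         scenario = tab$scenario, mig = tab$metadata$mig,
         unreachable = tab$metadata$unreachable),
    file.path(out_dir, "loss_table_axes.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(out_dir, "table", config, seed, started)
  invisible(tab)
}

# Rebuild a gd_loss_table from cmd_table outputs.
read_loss_table <- function(csv_path, json_path) {
  tidy <- utils::read.csv(csv_path)
  axes <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  vals <- array(NA_real_, dim = c(length(axes$fst_grid),
                                  length(axes$loss_grid),
                                  length(axes$horizons)),
                dimnames = list(fst = axes$fst_grid, loss = axes$loss_grid,
                                horizon = axes$horizons))
  for (k in seq_len(nrow(tidy))) {
    vals[match(tidy$fst[k], axes$fst_grid),
         match(tidy$loss[k], axes$loss_grid),
         match(tidy$horizon[k], axes$horizons)] <- tidy$value[k]
  }
  structure(list(fst_grid = axes$fst_grid, loss_grid = axes$loss_grid,
                 horizons = axes$horizons, values = vals,
                 metric = axes$metric, scenario = axes$scenario,
                 metadata = list(mig = axes$mig,
                                 unreachable = axes$unreachable)),
            class = "gd_loss_table")
}

#' Run the `synth` command: synthetic species-indicator table
#'
#' @inheritParams cmd_solve
#' @return Invisibly, the records data frame.
#' @export
cmd_synth <- function(config, out_dir, seed = 1L) {
  started <- Sys.time()
  sc <- config$synth
  args <- if (is.null(sc)) list() else
    sc[intersect(names(sc), names(formals(synth_species_table)))]
  if (!is.null(args$counts_by_category))
    args$counts_by_category <- unlist(args$counts_by_category)
  args$seed <- seed
  records <- do.call(synth_species_table, args)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(records, file.path(out_dir, "species_records.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, "synth", config, seed, started)
  invisible(records)
}

#' Run the `project` command
#'
#' Expects `config$project$records` (CSV path) and either
#' `config$project$table_dir` (a `cmd_table` output directory) or a
#' `table` block to build one.
#'
#' @inheritParams cmd_solve
#' @return Invisibly, the `gd_projection`.
#' @export
cmd_project <- function(config, out_dir, seed = 1L) {
  started <- Sys.time()
  pc <- config$project
  if (is.null(pc) || is.null(pc$records))
    stop("config needs a `project` block with a `records` CSV path")
  records <- utils::read.csv(pc$records)
  tab <- if (!is.null(pc$table_dir)) {
    read_loss_table(file.path(pc$table_dir, "loss_table.csv"),
                    file.path(pc$table_dir, "loss_table_axes.json"))
  } else {
    cmd_table(config, file.path(out_dir, "table"), seed = seed)
  }
  proj <- project_species(records, tab, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(proj$per_species,
                   file.path(out_dir, "projection_species.csv"),
                   row.names = FALSE)
  utils::write.csv(proj$aggregates,
                   file.path(out_dir, "projection_aggregates.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, aggregates = proj$aggregates,
         note = proj$metadata$area_loss_proxy),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
  write_manifest(out_dir, "project", config, seed, started)
  invisible(proj)
}

#' Run the `powerlaw` command
#'
#' Reads a genotype panel (VCF + coordinates CSV, or PLINK text), runs the
#' configured extinction scheme and writes the extinction curve and the
#' fitted MAR/GDAR power laws.
#'
#' @inheritParams cmd_solve
#' @return Invisibly, a list with the curve and the fits.
#' @export
cmd_powerlaw <- function(config, out_dir, seed = 1L) {
  started <- Sys.time()
  pc <- config$powerlaw
  if (is.null(pc)) stop("config is missing the `powerlaw` block")
  panel <- if (!is.null(pc$vcf)) {
    read_vcf_panel(pc$vcf, pc$coords)
  } else if (!is.null(pc$ped)) {
    read_plink_panel(pc$ped, pc$map, pc$coords)
  } else stop("powerlaw block needs `vcf` or `ped`/`map` input")
  curve <- extinction_curve(
    panel, scheme = if (!is.null(pc$scheme)) pc$scheme else "random",
    resolution = pc$resolution,
    reps = if (!is.null(pc$reps)) pc$reps else 20, seed = seed)
  ok <- !is.na(curve$pi)
  fit_mar <- fit_powerlaw(curve$area_fraction_remaining,
                          curve$segregating_sites)
  fit_gdar <- fit_powerlaw(curve$area_fraction_remaining[ok], curve$pi[ok])
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(curve, file.path(out_dir, "extinction_curve.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(mar = unclass(fit_mar), gdar = unclass(fit_gdar),
         resolution = attr(curve, "resolution")),
    file.path(out_dir, "powerlaw.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(out_dir, "powerlaw", config, seed, started)
  invisible(list(curve = curve, mar = fit_mar, gdar = fit_gdar))
}

#' Run the `oracle` command
#'
#' @inheritParams cmd_solve
#' @return Invisibly, the comparison table from [run_oracle_scenario()].
#' @export
cmd_oracle <- function(config, out_dir, seed = 1L) {
  started <- Sys.time()
  lsc <- landscape_from_config(config)
  p <- params_from_config(config, lsc)
  oc <- if (is.null(config$oracle)) list() else config$oracle
  tab <- run_oracle_scenario(
    lsc, p,
    loci = if (!is.null(oc$loci)) oc$loci else 2000,
    reps = if (!is.null(oc$reps)) oc$reps else 9,
    loss_levels = if (!is.null(oc$loss_levels)) unlist(oc$loss_levels)
                  else seq(0.1, 0.9, by = 0.1),
    medium = if (!is.null(oc$medium)) oc$medium else 2200,
    sample_n = if (!is.null(oc$sample_n)) oc$sample_n else 30,
    burnin = oc$burnin, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(tab, file.path(out_dir, "oracle_comparison.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, "oracle", config, seed, started)
  invisible(tab)
}

#' Command-line entry point
#'
#' Dispatches `gdforecast <command> --config <file> [--seed S] [--out DIR]`
#' with command one of `solve`, `scenario`, `table`, `project`, `synth`,
#' `powerlaw`, `oracle`. Installed as the executable script
#' `exec/gdforecast`; this function contains the full logic so it can be
#' driven programmatically.
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return Exit status, invisibly (0 on success).
#' @export
gdf_cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: gdforecast <solve|scenario|table|project|synth|powerlaw|oracle>",
    "--config <file> [--seed S] [--out DIR]")
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- list(config = NULL, seed = 1L, out = "gdforecast_out")
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opts) || i == length(args)) {
      message("unknown or incomplete option: ", args[i], "\n", usage)
      return(invisible(1L))
    }
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  fns <- list(solve = cmd_solve, scenario = cmd_scenario, table = cmd_table,
              project = cmd_project, synth = cmd_synth,
              powerlaw = cmd_powerlaw, oracle = cmd_oracle)
  if (!cmd %in% names(fns)) { message(usage); return(invisible(1L)) }
  if (is.null(opts$config)) { message("--config is required\n", usage)
    return(invisible(1L)) }
  res <- tryCatch({
    config <- read_run_config(opts$config)
    fns[[cmd]](config, opts$out, seed = as.integer(opts$seed))
    0L
  }, error = function(e) {
    message("gdforecast ", cmd, " failed: ", conditionMessage(e))
    1L
  })
  invisible(res)
}
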