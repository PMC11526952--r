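#' Initialize a forward Wright-Fisher simulation state
#'
#' Creates the allele-frequency array (occupied demes x loci) of a
#' discrete-deme, multi-locus Wright-Fisher simulator with symmetric
#' recurrent mutation. The simulator tracks biallelic loci as an
#' approximation to infinite sites (valid while the per-locus scaled
#' mutation rate is much below 1).
#'
#' @param landscape A `gd_landscape`.
#' @param params A [gd_params()]; `mu` is the per-locus symmetric mutation
#'   rate and `deme_size` the diploid count per deme.
#' @param loci Number of independent loci (>= 1).
#' @param seed Integer RNG seed.
#' @param init `"stationary"` draws each locus's shared starting frequency
#'   from the panmictic mutation-drift stationary law Beta(theta, theta)
#'   with theta = 4 N_total mu (all demes start identical, as if recently
#'   well mixed); `"half"` starts every locus at frequency 0.5; `"fixed"`
#'   starts at 0.
#' @return An object of class `gd_simstate` with fields `freqs`, `loci`,
#'   `generation`, `landscape`, `params`.
#' @export
sim_init <- function(landscape, params, loci, seed = 1L,
                     init = c("stationary", "half", "fixed")) {
  init <- match.arg(init)
  stopifnot(loci >= 1)
  check_migration(landscape, params)
  D <- length(landscape$demes)
  set.seed(seed)
  p0 <- switch(init,
    stationary = {
      a <- theta(params, landscape)
      stats::rbeta(loci, a, a)
    },
    half = rep(0.5, loci),
    fixed = rep(0, loci)
  )
  structure(
    list(freqs = matrix(p0, D, loci, byrow = TRUE), loci = as.integer(loci),
         generation = 0L, landscape = landscape, params = params),
    class = "gd_simstate"
  )
}

# The sample-frequency diversity estimator shared by all oracle metrics:
# pi = (n/(n-1)) (1/L) sum_l 2 p_l (1 - p_l), n diploid individuals.
pi_estimator <- function(phat, n) {
  (n / (n - 1)) * mean(2 * phat * (1 - phat))
}

# Row-stochastic backward migration matrix: probability m per occupied
# neighbour; mass aimed at unoccupied cells stays in place.
migration_matrix <- function(landscape, params) {
  M <- params$mig * landscape$adjacency
  Matrix::diag(M) <- 1 - params$mig * Matrix::rowSums(landscape$adjacency)
  M
}

#' Advance a Wright-Fisher simulation
#'
#' Iterates `generations` steps of: deterministic migration mixing of deme
#' frequencies by the backward-migration matrix, symmetric mutation at rate
#' `mu` per gamete, and binomial resampling of 2N gametes per deme.
#'
#' @param state A `gd_simstate`.
#' @param generations Number of generations (>= 0).
#' @return The advanced `gd_simstate`.
#' @export
sim_step <- function(state, generations) {
  stopifnot(generations >= 0)
  if (generations == 0) return(state)
  P <- state$freqs
  M <- migration_matrix(state$landscape, state$params)
  mu <- state$params$mu
  n2 <- 2L * state$params$deme_size
  DL <- length(P)
  for (g in seq_len(generations)) {
    P <- as.matrix(M %*% P)
    P <- P * (1 - mu) + (1 - P) * mu
    P <- matrix(stats::rbinom(DL, n2, P) / n2, nrow(P), ncol(P))
  }
  state$freqs <- P
  state$generation <- state$generation + as.integer(generations)
  state
}

#' Restrict a simulation to surviving demes
#'
#' @param state A `gd_simstate`.
#' @param removed Integer cell ids to remove (allele frequencies of
#'   survivors are unchanged).
#' @return The reduced `gd_simstate`.
#' @export
sim_remove_demes <- function(state, removed) {
  keep <- which(!(state$landscape$demes %in% as.integer(removed)))
  if (length(keep) == 0L) stop("cannot remove every deme")
  state$landscape <- landscape_keep(state$landscape, keep)
  state$freqs <- state$freqs[keep, , drop = FALSE]
  state
}

#' Sample-based nucleotide diversity from a simulation state
#'
#' Draws `sample_n` diploid individuals (species-wide: uniformly across
#' demes; local: within each deme, averaging the per-deme values) and
#' computes the bias-corrected estimator
#' `pi = (n/(n-1)) (1/L) sum_l 2 p_l (1 - p_l)` on the sample allele
#' frequencies.
#'
#' @param state A `gd_simstate`.
#' @param scope `"species"` or `"local"`.
#' @param sample_n Number of diploid individuals per sample (>= 2; must not
#'   exceed the available individuals).
#' @return Numeric scalar.
#' @export
sim_pi <- function(state, scope = c("species", "local"), sample_n) {
  scope <- match.arg(scope)
  stopifnot(sample_n >= 2)
  D <- nrow(state$freqs); N <- state$params$deme_size
  if (scope == "species") {
    if (sample_n > D * N) stop("sample_n exceeds available individuals")
    alloc <- as.integer(stats::rmultinom(1, sample_n, rep(1 / D, D)))
    counts <- rep(0L, state$loci)
    for (d in which(alloc > 0)) {
      counts <- counts + stats::rbinom(state$loci, 2L * alloc[d],
                                       state$freqs[d, ])
    }
    pi_estimator(counts / (2 * sample_n), sample_n)
  } else {
    if (sample_n > N) stop("sample_n exceeds deme size")
    vals <- vapply(seq_len(D), function(d) {
      phat <- stats::rbinom(state$loci, 2L * sample_n, state$freqs[d, ]) /
        (2 * sample_n)
      pi_estimator(phat, sample_n)
    }, numeric(1))
    mean(vals)
  }
}

#' Segregating sites in a sample
#'
#' Number of loci polymorphic (sample frequency strictly between 0 and 1)
#' in a sample of `sample_n` diploids, drawn species-wide or restricted to a
#' subset of demes (e.g. a surviving area for mutations-area curves).
#'
#' @param state A `gd_simstate`.
#' @param sample_n Diploid sample size (>= 2).
#' @param demes Optional integer cell ids restricting the sampled area.
#' @return Integer count (<= `state$loci`).
#' @export
sim_segregating_sites <- function(state, sample_n, demes = NULL) {
  stopifnot(sample_n >= 2)
  freqs <- state$freqs
  if (!is.null(demes)) {
    idx <- which(state$landscape$demes %in% as.integer(demes))
    if (length(idx) == 0L) stop("no sampled demes available")
    freqs <- freqs[idx, , drop = FALSE]
  }
  D <- nrow(freqs)
  if (sample_n > D * state$params$deme_size)
    stop("sample_n exceeds available individuals")
  alloc <- as.integer(stats::rmultinom(1, sample_n, rep(1 / D, D)))
  counts <- rep(0L, state$loci)
  for (d in which(alloc > 0)) {
    counts <- counts + stats::rbinom(state$loci, 2L * alloc[d], freqs[d, ])
  }
  sum(counts > 0L & counts < 2L * sample_n)
}

#' Forward simulation with burn-in, sampling times and removal events
#'
#' Runs the Wright-Fisher simulator to mutation-drift-migration
#' stationarity, then through an optional habitat-removal event, recording
#' species-wide and mean local diversity and segregating sites at requested
#' times.
#'
#' @param landscape A `gd_landscape`.
#' @param params A [gd_params()] (per-locus `mu`).
#' @param loci Number of loci.
#' @param generations Post-burn-in generations to simulate.
#' @param seed RNG seed.
#' @param burnin Burn-in generations before time 0 (default
#'   `20 * 2 * N_total`).
#' @param sample_times Generations (since time 0) at which to record
#'   metrics; defaults to `c(0, generations)`.
#' @param sample_n Diploid sample size for the recorded metrics.
#' @param removed Optional integer cell ids removed at `remove_at`.
#' @param remove_at Generation (since time 0) of the removal event.
#' @param init Initial-frequency scheme, see [sim_init()].
#' @return A list of class `gd_oraclerun`: `table` (data frame with columns
#'   generation, species_pi, local_pi, segregating_sites) and `state` (the
#'   final `gd_simstate`).
#' @export
simulate_forward <- function(landscape, params, loci, generations, seed = 1L,
                             burnin = NULL, sample_times = NULL,
                             sample_n = 20, removed = NULL, remove_at = 0,
                             init = "stationary") {
  if (is.null(burnin))
    burnin <- 20 * 2 * params$deme_size * length(landscape$demes)
  if (is.null(sample_times)) sample_times <- unique(c(0, generations))
  sample_times <- sort(unique(sample_times))
  stopifnot(all(sample_times >= 0), all(sample_times <= generations))
  st <- sim_init(landscape, params, loci, seed = seed, init = init)
  st <- sim_step(st, burnin)
  st$generation <- 0L
  events <- data.frame(time = sample_times, what = "sample")
  if (!is.null(removed) && length(removed) > 0) {
    events <- rbind(events, data.frame(time = remove_at, what = "remove"))
  }
  events <- events[order(events$time, events$what == "sample"), ]
  out <- data.frame()
  cur <- 0
  for (k in seq_len(nrow(events))) {
    st <- sim_step(st, events$time[k] - cur)
    cur <- events$time[k]
    if (events$what[k] == "remove") {
      st <- sim_remove_demes(st, removed)
    } else {
      out <- rbind(out, data.frame(
        generation = cur,
        species_pi = sim_pi(st, "species", sample_n),
        local_pi = sim_pi(st, "local", min(sample_n, params$deme_size)),
        segregating_sites = sim_segregating_sites(st, sample_n)
      ))
    }
  }
  structure(list(table = out, state = st), class = "gd_oraclerun")
}

#' Replicated oracle runs across a habitat-loss sweep
#'
#' For each replicate, burns one landscape in to stationarity and then
#' applies every loss level of an edge-contraction sweep to that shared
#' pre-loss state, recording simulated species-wide diversity immediately
#' after removal and after the medium horizon, together with the matched
#' moment-system predictions for the same landscapes.
#'
#' @param landscape A `gd_landscape`.
#' @param params A [gd_params()] (per-locus mutation rate).
#' @param loci Loci per replicate.
#' @param reps Number of replicates (>= 1).
#' @param loss_levels Fractions of habitat removed (default 10%-90%).
#' @param medium Generations of the medium horizon (default 2200).
#' @param sample_n Diploid sample size for simulated metrics.
#' @param burnin Burn-in generations (default `4 * 2 * N_total` from a
#'   stationary-law start).
#' @param seed Base RNG seed; replicate r uses `seed + r`.
#' @return Data frame with one row per (loss level, replicate): columns
#'   `loss`, `rep`, `pi0_sim`, `pi_short_sim`, `pi_medium_sim`, `S0_sim`,
#'   `S_short_sim`, `pi0_mom`, `pi_short_mom`, `pi_medium_mom` and the
#'   fractional losses `loss_short_sim`, `loss_medium_sim`,
#'   `loss_short_mom`, `loss_medium_mom`.
#' @export
run_oracle_scenario <- function(landscape, params, loci = 2000, reps = 9,
                                loss_levels = seq(0.1, 0.9, by = 0.1),
                                medium = 2200, sample_n = 30,
                                burnin = NULL, seed = 1L) {
  stopifnot(reps >= 1)
  if (is.null(burnin))
    burnin <- 4 * 2 * params$deme_size * length(landscape$demes)
  # moment predictions, once per loss level
  eq0 <- equilibrium_diversity(landscape, params)
  pi0_mom <- species_pi(eq0)
  mom <- lapply(loss_levels, function(fr) {
    removed <- edge_contraction_demes(landscape, fr)
    red <- apply_habitat_loss(eq0, landscape, removed)
    med <- evolve_diversity(red$state, red$landscape, params, medium)
    list(removed = removed, short = species_pi(red$state),
         medium = species_pi(med))
  })
  rows <- list()
  for (r in seq_len(reps)) {
    st0 <- sim_init(landscape, params, loci, seed = seed + r)
    st0 <- sim_step(st0, burnin)
    pi0_sim <- sim_pi(st0, "species", sample_n)
    s0 <- sim_segregating_sites(st0, sample_n)
    for (li in seq_along(loss_levels)) {
      red <- sim_remove_demes(st0, mom[[li]]$removed)
      pi_s <- sim_pi(red, "species", sample_n)
      s_s <- sim_segregating_sites(red, sample_n)
      red <- sim_step(red, medium)
      pi_m <- sim_pi(red, "species", sample_n)
      rows[[length(rows) + 1L]] <- data.frame(
        loss = loss_levels[li], rep = r,
        pi0_sim = pi0_sim, pi_short_sim = pi_s, pi_medium_sim = pi_m,
        S0_sim = s0, S_short_sim = s_s,
        pi0_mom = pi0_mom, pi_short_mom = mom[[li]]$short,
        pi_medium_mom = mom[[li]]$medium
      )
    }
  }
  out <- do.call(rbind, rows)
  out$loss_short_sim <- 1 - out$pi_short_sim / out$pi0_sim
  out$loss_medium_sim <- 1 - out$pi_medium_sim / out$pi0_sim
  out$loss_short_mom <- 1 - out$pi_short_mom / out$pi0_mom
  out$loss_medium_mom <- 1 - out$pi_medium_mom / out$pi0_mom
  out
}
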