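#' Demographic parameters of a lattice metapopulation
#'
#' Bundles the per-site per-generation mutation rate, the number of diploid
#' individuals per occupied deme, and the per-neighbour backward migration
#' rate. Time is measured in generations throughout the package.
#'
#' @param mu Per-site, per-generation mutation rate (> 0).
#' @param deme_size Diploid individuals per occupied deme, N (>= 1).
#' @param mig Per-generation probability that a lineage's parent lived in a
#'   given adjacent deme (one rate per neighbour). The total emigration
#'   probability of a deme, `mig * degree`, must not exceed 1.
#' @param time_scale Multiplier converting user time units to model
#'   generations. Defaults to 1 (times are already generations); exposed so
#'   that calibrations against external simulators can rescale time without
#'   touching the model.
#'
#' @return An object of class `gd_params`.
#' @examples
#' p <- gd_params(mu = 5e-9, deme_size = 50, mig = 0.05)
#' p
#' @seealso [theta()] for the population-scaled mutation rate 4*N_total*mu.
#' @export
gd_params <- function(mu, deme_size, mig = 0, time_scale = 1) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu), mu > 0)
  stopifnot(is.numeric(deme_size), length(deme_size) == 1L, deme_size >= 1)
  stopifnot(is.numeric(mig), length(mig) == 1L, mig >= 0)
  stopifnot(is.numeric(time_scale), length(time_scale) == 1L, time_scale > 0)
  structure(
    list(mu = mu, deme_size = deme_size, mig = mig, time_scale = time_scale),
    class = "gd_params"
  )
}

#' @export
print.gd_params <- function(x, ...) {
  cat("Metapopulation parameters\n")
  cat(sprintf("  mu (per site per generation): %g\n", x$mu))
  cat(sprintf("  deme size N (diploids):       %g\n", x$deme_size))
  cat(sprintf("  migration rate m/neighbour:   %g\n", x$mig))
  invisible(x)
}

#' Population-scaled mutation rate
#'
#' Computes theta = 4 * N_total * mu, where N_total is the summed diploid
#' size over occupied demes. For a panmictic population theta equals the
#' equilibrium nucleotide diversity under infinite sites.
#'
#' @param params A [gd_params()] object.
#' @param landscape A [build_lattice()] landscape (used for the occupied-deme
#'   count); if missing, a single deme is assumed.
#' @return Numeric scalar, 4*N_total*mu.
#' @export
theta <- function(params, landscape = NULL) {
  n_demes <- if (is.null(landscape)) 1L else length(landscape$demes)
  4 * params$deme_size * n_demes * params$mu
}

#' Choose a mutation rate that realizes a target theta
#'
#' Convenience inverse of [theta()]: given a landscape and deme size, returns
#' the per-site mutation rate such that 4*N_total*mu equals `target_theta`.
#'
#' @param target_theta Desired population-scaled mutation rate.
#' @param deme_size Diploid individuals per deme.
#' @param n_demes Number of occupied demes.
#' @return Numeric mutation rate.
#' @export
mu_for_theta <- function(target_theta, deme_size, n_demes) {
  stopifnot(target_theta > 0, deme_size >= 1, n_demes >= 1)
  target_theta / (4 * deme_size * n_demes)
}

#' Effective size from census size
#'
#' Applies the conventional conservation-genetics conversion N_e = ratio *
#' N_c (default ratio 0.1). The ratio is exposed because N_e/N_c varies by
#' orders of magnitude across taxa.
#'
#' @param nc Census size(s).
#' @param ratio N_e/N_c ratio (default 0.1).
#' @return Effective size(s).
#' @export
ne_from_census <- function(nc, ratio = 0.1) {
  stopifnot(all(nc >= 0), ratio > 0)
  ratio * nc
}

# Validate that migration mass leaving any deme stays within [0, 1].
check_migration <- function(landscape, params) {
  deg <- max(Matrix::rowSums(landscape$adjacency))
  if (deg * params$mig > 1 + 1e-12) {
    stop(sprintf(
      "migration rate %g times maximum degree %d exceeds 1; reduce `mig`",
      params$mig, deg
    ), call. = FALSE)
  }
  invisible(TRUE)
}
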