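#' Expected pairwise-diversity matrix
#'
#' Container for the matrix of expected per-site pairwise nucleotide
#' diversity pi_ij between a lineage sampled in deme i and one sampled in
#' deme j. Diagonal entries are the within-deme expectations.
#'
#' @param pi Symmetric numeric matrix (demes x demes), entries >= 0.
#' @param demes Integer ids of the demes (cell indices); defaults to
#'   `1:nrow(pi)`.
#' @return An object of class `gd_diversity`.
#' @export
gd_diversity <- function(pi, demes = seq_len(nrow(pi))) {
  stopifnot(is.matrix(pi), nrow(pi) == ncol(pi), length(demes) == nrow(pi))
  if (any(pi < 0, na.rm = TRUE)) stop("diversity entries must be non-negative")
  if (max(abs(pi - t(pi)), na.rm = TRUE) > 1e-8 * max(1, max(abs(pi), na.rm = TRUE)))
    stop("diversity matrix must be symmetric")
  pi <- (pi + t(pi)) / 2
  dimnames(pi) <- list(demes, demes)
  structure(list(demes = as.integer(demes), pi = pi), class = "gd_diversity")
}

#' @export
print.gd_diversity <- function(x, ...) {
  cat(sprintf("Pairwise diversity over %d demes\n", length(x$demes)))
  cat(sprintf("  mean within-deme pi : %g\n", local_pi(x)))
  cat(sprintf("  species-wide pi     : %g\n", species_pi(x)))
  invisible(x)
}

# --- generator of the linear moment system ---------------------------------
#
# The expected pairwise diversities obey, in continuous time (units of
# generations, infinite-sites mutation influx 2*mu):
#
#   d pi_ij / dt = 2 mu
#                  - delta_ij * pi_ii / (2 N_i)
#                  + sum_k m_ik (pi_kj - pi_ij)
#                  + sum_k m_jk (pi_ik - pi_ij)
#
# with m_ik the backward migration rate from deme i to adjacent occupied
# deme k. In matrix form dP/dt = 2 mu J + L P + P L' - drift(diag), i.e. a
# linear system A x + b on x = vec(P), with A = I (x) L + L (x) I minus the
# drift terms on diagonal-pair coordinates.

migration_generator <- function(landscape, params) {
  check_migration(landscape, params)
  L <- params$mig * landscape$adjacency
  Matrix::diag(L) <- -params$mig * Matrix::rowSums(landscape$adjacency)
  L
}

pair_generator <- function(landscape, params) {
  D <- length(landscape$demes)
  L <- migration_generator(landscape, params)
  I <- Matrix::Diagonal(D)
  A <- kronecker(I, L) + kronecker(L, I)
  di <- (seq_len(D) - 1L) * D + seq_len(D)   # vec indices of diagonal pairs
  A <- A + Matrix::sparseMatrix(i = di, j = di,
                                x = rep(-1 / (2 * params$deme_size), D),
                                dims = c(D^2, D^2))
  methods::as(A, "CsparseMatrix")
}

#' Equilibrium of the pairwise-diversity moment system
#'
#' Solves the stationary condition of the linear moment ODE for expected
#' pairwise diversity on the occupied demes of a landscape. The system is
#' solved exactly (sparse direct solve) per connected component; under
#' infinite-sites mutation, diversity between demes in different components
#' grows without bound, so those entries are returned as `Inf`.
#'
#' For a single deme the solution is the classical mutation-drift balance
#' `4 N mu`; for two demes exchanging migrants at rate m it is
#' `pi_within = 8 N mu` and `pi_between = 8 N mu + mu / m`.
#'
#' @param landscape A [build_lattice()] landscape.
#' @param params A [gd_params()] with positive `mu` and, for more than one
#'   deme per component, the migration rate `mig`.
#' @return A [gd_diversity()] over the landscape's occupied demes.
#' @examples
#' p <- gd_params(mu = 1e-8, deme_size = 250000)
#' eq <- equilibrium_diversity(build_lattice(1, 1), p)
#' eq$pi[1, 1]    # 0.01 = 4 N mu
#' @export
equilibrium_diversity <- function(landscape, params) {
  D <- length(landscape$demes)
  comp <- landscape_components(landscape)
  A <- pair_generator(landscape, params)
  b <- rep(2 * params$mu, D^2)
  x <- rep(Inf, D^2)
  same <- outer(comp, comp, "==")          # column-major == vec ordering
  idx <- which(same)
  # -A restricted to within-component pairs is symmetric positive definite
  # (drift provides strict diagonal decay), so a sparse Cholesky applies.
  S <- Matrix::forceSymmetric(-A[idx, idx, drop = FALSE])
  sol <- tryCatch(
    as.numeric(Matrix::solve(Matrix::Cholesky(S), b[idx], system = "A")),
    error = function(e) {
      stop(sprintf(
        "singular moment system (%d demes in %d components): %s",
        D, max(comp), conditionMessage(e)), call. = FALSE)
    }
  )
  x[idx] <- sol
  P <- matrix(x, D, D)
  P <- (P + t(P)) / 2
  gd_diversity(P, landscape$demes)
}

#' Integrate the moment system forward in time
#'
#' Propagates a pairwise-diversity state t generations forward under the
#' linear moment ODE, using the action of the matrix exponential computed by
#' uniformization (scaled truncated series on the non-negative propagator;
#' no cancellation, tolerance-controlled).
#'
#' @param state A [gd_diversity()] defined on `landscape`'s occupied demes.
#' @param landscape A `gd_landscape`.
#' @param params A [gd_params()].
#' @param t Non-negative time in generations (scaled by `params$time_scale`).
#' @param tol Relative series-truncation tolerance.
#' @return The propagated [gd_diversity()].
#' @export
evolve_diversity <- function(state, landscape, params, t, tol = 1e-10) {
  stopifnot(inherits(state, "gd_diversity"))
  if (t < 0) stop("t must be non-negative")
  if (!identical(as.integer(state$demes), as.integer(landscape$demes)))
    stop("state and landscape are defined on different deme sets")
  if (!all(is.finite(state$pi)))
    stop("cannot evolve a state with non-finite entries")
  if (t == 0) return(state)
  D <- length(landscape$demes)
  A <- pair_generator(landscape, params)
  b <- rep(2 * params$mu, D^2)
  # inhomogeneous term folded in by augmenting the system with a constant 1
  Ab <- rbind(cbind(A, b), Matrix::sparseMatrix(
    i = integer(0), j = integer(0), x = numeric(0), dims = c(1L, D^2 + 1L)))
  v <- c(as.numeric(state$pi), 1)
  w <- expmv_uniform(methods::as(Ab, "CsparseMatrix"), v,
                     t * params$time_scale, tol = tol)
  P <- matrix(w[seq_len(D^2)], D, D)
  P <- (P + t(P)) / 2
  P[P < 0] <- 0                          # clip tiny negative round-off
  gd_diversity(P, landscape$demes)
}

# Action of expm(A * t) on v for an essentially non-negative (Metzler) A,
# by uniformization: A = alpha (P - I) with P >= 0, so
# expm(A t) v = sum_k Pois(alpha t)_k P^k v, evaluated in scaled steps.
expmv_uniform <- function(A, v, t, tol = 1e-10, theta = 40) {
  if (t <= 0) return(v)
  d <- Matrix::diag(A)
  alpha <- max(-d, 0)
  if (alpha == 0) {                      # A has no diagonal decay: pure influx
    # fall back to plain truncated Taylor (A is tiny in this case)
    term <- v; out <- v
    k <- 1
    repeat {
      term <- as.numeric(A %*% term) * (t / k)
      out <- out + term
      if (sum(abs(term)) <= tol * max(sum(abs(out)), 1e-300) || k > 100) break
      k <- k + 1
    }
    return(out)
  }
  P <- A / alpha
  Matrix::diag(P) <- Matrix::diag(P) + 1
  s <- max(1L, ceiling(alpha * t / theta))
  lam <- alpha * t / s
  kmax <- ceiling(lam + 8 * sqrt(lam) + 30)
  for (step in seq_len(s)) {
    term <- v
    out <- exp(-lam) * v
    for (k in seq_len(kmax)) {
      term <- as.numeric(P %*% term)
      coef <- exp(-lam + k * log(lam) - lgamma(k + 1))
      out <- out + coef * term
      if (k > lam && coef * sum(abs(term)) <= tol * max(sum(abs(out)), 1e-300))
        break
    }
    v <- out
  }
  v
}

#' Instantaneous habitat removal
#'
#' Removes a set of demes from the landscape and restricts the diversity
#' state to the survivors. Allele frequencies of surviving demes are
#' unchanged by the removal, so the short-term state is exactly the
#' submatrix of pi on surviving demes. Migration mass formerly directed at
#' removed cells stays in place (the backward-migration rows are rebuilt
#' from the surviving adjacency without renormalization).
#'
#' @param state A [gd_diversity()] on `landscape`.
#' @param landscape A `gd_landscape`.
#' @param removed Integer cell ids (values of `landscape$demes`) to remove.
#'   May be empty.
#' @return A list with elements `state` (restricted [gd_diversity()]) and
#'   `landscape` (the reduced `gd_landscape`).
#' @export
apply_habitat_loss <- function(state, landscape, removed) {
  stopifnot(inherits(state, "gd_diversity"))
  removed <- as.integer(removed)
  if (length(removed) == 0L) return(list(state = state, landscape = landscape))
  if (!all(removed %in% landscape$demes))
    stop("removed cells must be occupied demes")
  keep <- which(!(landscape$demes %in% removed))
  if (length(keep) == 0L) stop("cannot remove every deme")
  lsc2 <- landscape_keep(landscape, keep)
  st2 <- gd_diversity(state$pi[keep, keep, drop = FALSE], lsc2$demes)
  list(state = st2, landscape = lsc2)
}

#' Species-wide expected diversity
#'
#' The expectation of the average pairwise difference between two individuals
#' sampled from the whole landscape: `sum_ij w_i w_j pi_ij` with per-deme
#' sampling weights `w` (uniform over occupied demes by default).
#'
#' @param state A [gd_diversity()].
#' @param weights Optional non-negative per-deme weights summing to 1.
#' @return Numeric scalar.
#' @export
species_pi <- function(state, weights = NULL) {
  D <- length(state$demes)
  if (is.null(weights)) weights <- rep(1 / D, D)
  if (length(weights) != D) stop("one weight per deme is required")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  as.numeric(t(weights) %*% state$pi %*% weights)
}

#' Mean within-deme expected diversity
#'
#' Average of the diagonal of the pairwise-diversity matrix, i.e. the
#' expected diversity of a sample drawn within a single deme, averaged over
#' demes.
#'
#' @param state A [gd_diversity()].
#' @return Numeric scalar.
#' @export
local_pi <- function(state) {
  mean(diag(state$pi))
}

#' Average pairwise Hudson-style F_ST
#'
#' For each pair of demes i < j computes
#' `1 - ((pi_ii + pi_jj) / 2) / pi_ij` and averages over pairs. Pairs with
#' `pi_ij == 0` are excluded (undefined).
#'
#' @param state A [gd_diversity()] with at least two demes.
#' @return Numeric scalar in (-Inf, 1].
#' @export
pairwise_fst <- function(state) {
  D <- length(state$demes)
  if (D < 2L) stop("F_ST requires at least two demes")
  P <- state$pi
  within <- outer(diag(P), diag(P), "+") / 2
  ut <- upper.tri(P)
  pij <- P[ut]; wij <- within[ut]
  keep <- pij > 0                        # pairs with pi_ij = 0 are undefined
  # diverging between-component pairs (pi_ij = Inf) have F_ST = 1
  f <- ifelse(is.infinite(pij), 1, 1 - wij / pij)
  mean(f[keep])
}

#' Tune the migration rate to a target F_ST
#'
#' Bisection on log10(m) such that the average pairwise F_ST of the
#' equilibrium diversity matches `target_fst`. The search bracket is
#' `[1e-8, 1/max_degree]` (the upper bound keeps total emigration <= 1).
#' If the target is unreachable on the bracket, the bracketing bound is
#' returned with a warning and the attribute `unreachable = TRUE`.
#'
#' @param landscape A `gd_landscape` with >= 2 demes (single component).
#' @param params A [gd_params()]; its `mig` field is ignored.
#' @param target_fst Target in `[0, 1)`.
#' @param tol Absolute tolerance on the achieved F_ST (default 1e-3).
#' @return The migration rate (numeric scalar) with attributes
#'   `achieved_fst` and `unreachable`.
#' @export
tune_migration <- function(landscape, params, target_fst, tol = 1e-3) {
  if (target_fst < 0 || target_fst >= 1) stop("target_fst must be in [0, 1)")
  deg <- max(Matrix::rowSums(landscape$adjacency))
  if (deg == 0) stop("landscape has no adjacency; F_ST is not tunable")
  m_hi <- 1 / deg
  m_lo <- 1e-8
  fst_at <- function(m) {
    p <- params; p$mig <- m
    pairwise_fst(equilibrium_diversity(landscape, p))
  }
  f_hi <- fst_at(m_hi)                   # lowest achievable F_ST
  f_lo <- fst_at(m_lo)                   # highest achievable F_ST
  wrap <- function(m, achieved, unreachable) {
    if (unreachable)
      warning(sprintf(
        "target F_ST %.4g unreachable on bracket; returning bound m = %g (F_ST = %.4g)",
        target_fst, m, achieved), call. = FALSE)
    structure(m, achieved_fst = achieved, unreachable = unreachable)
  }
  if (target_fst <= f_hi) {
    # panmictic-side target: report the upper bound; reached if within tol
    return(wrap(m_hi, f_hi, unreachable = f_hi - target_fst > tol))
  }
  if (target_fst >= f_lo) {
    return(wrap(m_lo, f_lo, unreachable = target_fst - f_lo > tol))
  }
  lo <- log10(m_lo); hi <- log10(m_hi)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    f_mid <- fst_at(10^mid)
    if (abs(f_mid - target_fst) <= tol * 0.5) break
    if (f_mid > target_fst) lo <- mid else hi <- mid
  }
  wrap(10^mid, f_mid, unreachable = abs(f_mid - target_fst) > tol)
}
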