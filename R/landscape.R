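#' Build a fully occupied lattice landscape
#'
#' Creates a `rows` x `cols` grid of demes with 4-neighbour (rook) adjacency.
#' Cells are identified by their column-major index in the grid; the occupancy
#' mask can later be modified by habitat-loss operators.
#'
#' @param rows,cols Grid dimensions (>= 1).
#' @param params Optional [gd_params()] attached to the landscape for
#'   convenience (not required by the structural operators).
#' @return An object of class `gd_landscape`: a list with elements
#'   `rows`, `cols`, `mask` (logical `rows` x `cols` occupancy matrix),
#'   `demes` (integer cell indices of occupied cells), `coords` (two-column
#'   matrix of row/col positions per occupied deme) and `adjacency`
#'   (sparse symmetric 0/1 matrix between occupied demes).
#' @examples
#' L <- build_lattice(10, 10)
#' length(L$demes)                     # 100 demes
#' sum(L$adjacency) / 2                # 180 rook edges
#' @export
build_lattice <- function(rows, cols, params = NULL) {
  stopifnot(rows >= 1, cols >= 1)
  rows <- as.integer(rows); cols <- as.integer(cols)
  mask <- matrix(TRUE, rows, cols)
  lsc <- landscape_from_mask(mask)
  lsc$params <- params
  lsc
}

#' Build a landscape from an occupancy mask
#'
#' @param mask Logical matrix; `TRUE` cells are occupied demes. At least one
#'   cell must be occupied.
#' @return A `gd_landscape` (see [build_lattice()]).
#' @export
landscape_from_mask <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("landscape must contain at least one occupied cell")
  rows <- nrow(mask); cols <- ncol(mask)
  demes <- which(mask)                      # column-major cell ids
  rc <- cbind(row = (demes - 1L) %% rows + 1L,
              col = (demes - 1L) %/% rows + 1L)
  adjacency <- lattice_adjacency(mask, demes, rc)
  structure(
    list(rows = rows, cols = cols, mask = mask, demes = demes,
         coords = rc, adjacency = adjacency),
    class = "gd_landscape"
  )
}

# Sparse symmetric adjacency among occupied cells, 4-neighbour rule.
lattice_adjacency <- function(mask, demes, rc) {
  rows <- nrow(mask); cols <- ncol(mask)
  D <- length(demes)
  pos <- integer(rows * cols)               # cell id -> deme index
  pos[demes] <- seq_len(D)
  ii <- integer(0); jj <- integer(0)
  for (shift in list(c(1L, 0L), c(0L, 1L))) {
    r2 <- rc[, 1L] + shift[1L]; c2 <- rc[, 2L] + shift[2L]
    ok <- r2 >= 1L & r2 <= rows & c2 >= 1L & c2 <= cols
    nb <- (c2[ok] - 1L) * rows + r2[ok]
    occ <- mask[nb]
    from <- seq_len(D)[ok][occ]
    to <- pos[nb[occ]]
    ii <- c(ii, from, to); jj <- c(jj, to, from)
  }
  if (length(ii) == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(D, D)))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(D, D))
}

#' @export
print.gd_landscape <- function(x, ...) {
  cat(sprintf("Lattice landscape: %d x %d grid, %d occupied demes, %d edges\n",
              x$rows, x$cols, length(x$demes), sum(x$adjacency) / 2))
  invisible(x)
}

#' Connected components of a landscape
#'
#' Labels occupied demes by connected component under 4-neighbour adjacency,
#' using an iterative flood fill.
#'
#' @param landscape A `gd_landscape`.
#' @return Integer vector of component labels (1-based), one per occupied deme.
#' @export
landscape_components <- function(landscape) {
  adj <- landscape$adjacency
  D <- nrow(adj)
  comp <- integer(D)
  nb <- lapply(seq_len(D), function(i) which(adj[i, ] != 0))
  cur <- 0L
  for (s in seq_len(D)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    comp[s] <- cur
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      for (w in nb[[v]]) {
        if (comp[w] == 0L) {
          comp[w] <- cur
          stack <- c(stack, w)
        }
      }
    }
  }
  comp
}

# Restrict a landscape to a subset of its occupied demes (indices into
# landscape$demes). Used by habitat-loss operators.
landscape_keep <- function(landscape, keep_idx) {
  mask <- landscape$mask
  drop_cells <- landscape$demes[setdiff(seq_along(landscape$demes), keep_idx)]
  mask[drop_cells] <- FALSE
  out <- landscape_from_mask(mask)
  out$params <- landscape$params
  out
}
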