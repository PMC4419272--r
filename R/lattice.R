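## Regular reference lattice.
##
## The deformation map is represented by a regular, axis-aligned lattice of
## nodes laid over the organ before deformation; estimation moves the nodes
## to their deformed positions.  Node (r, c) sits at
## origin + spacing * (c-1, r-1); rows run along the AP axis, columns along
## the PD axis; nodes are stored row-major.

#' Build a regular lattice enveloping the landmark data
#'
#' Lays an axis-aligned square lattice over the bounding box of the
#' before-deformation positions `X`, padded by `margin_cells` cells on every
#' side so that every landmark is strictly inside the grid.
#'
#' @param data A landmark table (see [landmarks()]).
#' @param spacing Lattice spacing in micrometres (default 200).
#' @param margin_cells Number of padding cells around the data bounding box.
#' @return An object of class `lattice_grid`: origin, spacing, `n_rows`,
#'   `n_cols`, and the reference node positions.
#' @examples
#' lm <- tibble::tibble(embryo_id = "e1", interval_id = "st22-23",
#'                      X_pd = c(0, 1000, 0, 1000), X_ap = c(0, 0, 500, 500),
#'                      x_pd = c(0, 1200, 0, 1200), x_ap = c(0, 0, 600, 600))
#' build_lattice(lm, spacing = 200)
#' @export
build_lattice <- function(data, spacing = 200, margin_cells = 1) {
  data <- landmarks(data)
  if (spacing <= 0) abort("`spacing` must be positive", class = "morphomapr_input")
  if (margin_cells < 1) abort("`margin_cells` must be >= 1", class = "morphomapr_input")
  if (nrow(data) < 4) {
    abort("need at least 4 landmarks to anchor a lattice", class = "morphomapr_input")
  }
  rng_pd <- range(data$X_pd)
  rng_ap <- range(data$X_ap)
  if (diff(rng_pd) == 0 && diff(rng_ap) == 0) {
    abort("landmarks have degenerate span (all X identical)",
          class = "morphomapr_degenerate")
  }
  origin <- c(rng_pd[1] - margin_cells * spacing,
              rng_ap[1] - margin_cells * spacing)
  n_cols <- ceiling(diff(rng_pd) / spacing) + 2 * margin_cells + 1
  n_rows <- ceiling(diff(rng_ap) / spacing) + 2 * margin_cells + 1
  new_lattice(origin, spacing, n_rows, n_cols)
}

new_lattice <- function(origin, spacing, n_rows, n_cols) {
  structure(
    list(origin = as.numeric(origin), spacing = spacing,
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
    class = "lattice_grid"
  )
}

#' @export
print.lattice_grid <- function(x, ...) {
  cat(sprintf("<lattice_grid> %d x %d nodes (%d x %d cells), spacing %g um, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$n_rows - 1L, x$n_cols - 1L,
              x$spacing, x$origin[1], x$origin[2]))
  invisible(x)
}

## Reference node positions, row-major (m x 2 matrix).
lattice_nodes <- function(lat) {
  pd <- lat$origin[1] + (seq_len(lat$n_cols) - 1) * lat$spacing
  ap <- lat$origin[2] + (seq_len(lat$n_rows) - 1) * lat$spacing
  cbind(rep(pd, times = lat$n_rows), rep(ap, each = lat$n_cols))
}

lattice_node_index <- function(lat, row, col) (row - 1L) * lat$n_cols + col

## Bilinear design matrix: n x m weights of each point on the 4 nodes of its
## cell.  Points must lie inside the lattice (boundary inclusive).
lattice_design <- function(lat, P) {
  gx <- (P[, 1] - lat$origin[1]) / lat$spacing
  gy <- (P[, 2] - lat$origin[2]) / lat$spacing
  eps <- 1e-9
  out_of <- gx < -eps | gx > lat$n_cols - 1 + eps |
            gy < -eps | gy > lat$n_rows - 1 + eps
  if (any(out_of)) {
    abort(sprintf("%d point(s) fall outside the lattice (no extrapolation)",
                  sum(out_of)), class = "morphomapr_domain")
  }
  cc <- pmin(pmax(floor(gx), 0), lat$n_cols - 2) # 0-based cell col
  rr <- pmin(pmax(floor(gy), 0), lat$n_rows - 2)
  u <- gx - cc
  v <- gy - rr
  n <- nrow(P); m <- lat$n_rows * lat$n_cols
  W <- matrix(0, n, m)
  i00 <- rr * lat$n_cols + cc + 1
  idx <- cbind(i00, i00 + 1, i00 + lat$n_cols, i00 + lat$n_cols + 1)
  wgt <- cbind((1 - u) * (1 - v), u * (1 - v), (1 - u) * v, u * v)
  for (k in 1:4) W[cbind(seq_len(n), idx[, k])] <- W[cbind(seq_len(n), idx[, k])] + wgt[, k]
  W
}

## Thin-plate-type second-difference penalty matrix: one row per interior
## node along each grid line (along-PD differences within rows, along-AP
## within columns) plus sqrt(2)-weighted mixed differences per cell.  Its
## null space is exactly the affine fields a + b*c + g*r, so affine
## deformation is unpenalised while pure shear wiggles are not free.
lattice_penalty <- function(lat) {
  nr <- lat$n_rows; nc <- lat$n_cols; m <- nr * nc
  k <- 0L
  n_pen <- nr * max(nc - 2, 0) + nc * max(nr - 2, 0) + (nr - 1) * (nc - 1)
  L <- matrix(0, n_pen, m)
  for (r in seq_len(nr)) {
    if (nc >= 3) for (c in 2:(nc - 1)) {
      k <- k + 1L
      i <- lattice_node_index(lat, r, c)
      L[k, i - 1L] <- 1; L[k, i] <- -2; L[k, i + 1L] <- 1
    }
  }
  for (c in seq_len(nc)) {
    if (nr >= 3) for (r in 2:(nr - 1)) {
      k <- k + 1L
      i <- lattice_node_index(lat, r, c)
      L[k, i - nc] <- 1; L[k, i] <- -2; L[k, i + nc] <- 1
    }
  }
  s2 <- sqrt(2)
  for (r in seq_len(nr - 1)) {
    for (c in seq_len(nc - 1)) {
      k <- k + 1L
      i <- lattice_node_index(lat, r, c)
      L[k, i] <- s2; L[k, i + 1L] <- -s2
      L[k, i + nc] <- -s2; L[k, i + nc + 1L] <- s2
    }
  }
  L
}
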