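## Geometric vertex-model simulation of tissue outlines.
##
## The tissue is a fixed-topology polygonal cell mesh (mesenchymal packing:
## no neighbour rearrangements).  Each cell carries a target area and a
## target shape tensor; vertices follow overdamped descent on the purely
## geometric energy
##   E = sum_c [ K_A (A_c / A_c^target - 1)^2
##             + K_S || S_c/tr(S_c) - T_c/tr(T_c) ||_F^2 ],
## where S_c is the cell's area-normalised second-moment (gyration) tensor
## about its centroid and T_c its target.  No line tensions or elastic
## moduli enter: growth and anisotropy are prescribed, not emergent.

#' Initialise a polygonal cell tissue inside an outline
#'
#' Tiles a simple polygon with a hexagonal (centroidal-Voronoi-like)
#' packing, clipping boundary cells to the outline, and sets every cell's
#' target area and target shape tensor to its initial geometry (so the
#' initial state is an energy minimum).
#'
#' @param outline Two-column matrix or data frame (pd, ap) of a simple
#'   polygon, in micrometres (counter-clockwise; reversed automatically).
#' @param target_cell_area Intended cell area in um^2.
#' @param K_A,K_S Weights of the area and shape energy terms.
#' @param step Descent step, as a fraction of sqrt(mean target area) moved
#'   by the steepest vertex per iteration.
#' @param max_iter Maximum descent iterations per growth step.
#' @return An object of class `vertex_tissue`.
#' @export
init_tissue <- function(outline, target_cell_area, K_A = 1, K_S = 1,
                        step = 0.05, max_iter = 500) {
  outline <- as_pd_ap_matrix(outline)
  if (nrow(outline) < 3) abort("outline needs >= 3 vertices", class = "morphomapr_input")
  if (abs(polygon_area(outline)) < 1e-9) {
    abort("outline polygon is degenerate (zero area)", class = "morphomapr_degenerate")
  }
  if (polygon_area(outline) < 0) outline <- outline[rev(seq_len(nrow(outline))), ]
  if (target_cell_area <= 0) abort("`target_cell_area` must be positive",
                                   class = "morphomapr_input")
  s <- sqrt(2 * target_cell_area / (3 * sqrt(3)))   # hexagon side
  w <- sqrt(3) * s
  bb <- apply(outline, 2, range)
  xs <- seq(bb[1, 1] - w, bb[2, 1] + w, by = w)
  ys <- seq(bb[1, 2] - 1.5 * s, bb[2, 2] + 1.5 * s, by = 1.5 * s)
  polys <- list()
  ang <- pi / 6 + (0:5) * pi / 3                     # pointy-top hexagon
  hx <- s * cos(ang); hy <- s * sin(ang)
  for (j in seq_along(ys)) {
    off <- if (j %% 2 == 0) w / 2 else 0
    for (x0 in xs + off) {
      hex <- cbind(x0 + hx, ys[j] + hy)
      clip <- clip_polygon(outline, hex)
      if (!is.null(clip) && nrow(clip) >= 3 &&
          polygon_area(clip) > 1e-3 * target_cell_area) {
        polys[[length(polys) + 1]] <- clip
      }
    }
  }
  if (length(polys) == 0) {
    abort("no cells fit inside the outline at this target area",
          class = "morphomapr_degenerate")
  }
  # merge shared vertices by coordinate (1e-6 um resolution)
  allv <- do.call(rbind, polys)
  key <- paste(round(allv[, 1], 6), round(allv[, 2], 6))
  uid <- match(key, unique(key))
  V <- allv[!duplicated(uid), , drop = FALSE]
  counts <- vapply(polys, nrow, integer(1))
  cells <- split(uid, rep(seq_along(polys), counts))
  cells <- lapply(cells, function(ix) ix[!duplicated(ix)])  # drop merged dups
  keep <- vapply(cells, length, integer(1)) >= 3
  cells <- cells[keep]
  tis <- structure(
    list(V = V, cells = unname(cells),
         params = list(K_A = K_A, K_S = K_S, step = step,
                       max_iter = max_iter)),
    class = "vertex_tissue"
  )
  tis$flat <- flatten_cells(tis$cells)
  geo <- tissue_geometry(tis$V, tis$flat)
  if (any(geo$A <= 0)) abort("degenerate cell produced during tiling",
                             class = "morphomapr_degenerate")
  tis$target_area <- geo$A
  tis$target_shape <- cbind(Txx = geo$Sxx, Txy = geo$Sxy, Tyy = geo$Syy)
  tis
}

#' @export
print.vertex_tissue <- function(x, ...) {
  geo <- tissue_geometry(x$V, x$flat)
  cat(sprintf("<vertex_tissue> %d cells, %d vertices, total area %.4g um^2\n",
              length(x$cells), nrow(x$V), sum(geo$A)))
  invisible(x)
}

#' @rdname init_tissue
#' @param x A `vertex_tissue`.
#' @param ... Unused.
#' @export
tidy.vertex_tissue <- function(x, ...) {
  geo <- tissue_geometry(x$V, x$flat)
  tibble::tibble(
    cell = seq_along(x$cells),
    centroid_pd = geo$Cx, centroid_ap = geo$Cy,
    area = geo$A, target_area = x$target_area,
    n_vertices = lengths(x$cells)
  )
}

## ---- flat topology ----------------------------------------------------------

flatten_cells <- function(cells) {
  v <- unlist(cells, use.names = FALSE)
  lens <- lengths(cells)
  cell <- rep(seq_along(cells), lens)
  start <- cumsum(c(1L, lens[-length(lens)]))
  pos <- sequence(lens)
  nxt <- seq_along(v) + 1L
  prv <- seq_along(v) - 1L
  ends <- cumsum(lens)
  nxt[ends] <- start
  prv[start] <- ends
  list(v = v, cell = cell, nxt = nxt, prv = prv, n_cells = length(cells))
}

## Areas, centroids and central second moments of all cells at once.
tissue_geometry <- function(V, flat) {
  xi <- V[flat$v, 1]; yi <- V[flat$v, 2]
  xn <- xi[flat$nxt]; yn <- yi[flat$nxt]
  cr <- xi * yn - xn * yi
  cl <- flat$cell
  A <- rowsum_vec(cr, cl, flat$n_cells) / 2
  Cx <- rowsum_vec((xi + xn) * cr, cl, flat$n_cells) / (6 * A)
  Cy <- rowsum_vec((yi + yn) * cr, cl, flat$n_cells) / (6 * A)
  Jxx <- rowsum_vec(cr * (xi^2 + xi * xn + xn^2), cl, flat$n_cells) / 12
  Jyy <- rowsum_vec(cr * (yi^2 + yi * yn + yn^2), cl, flat$n_cells) / 12
  Jxy <- rowsum_vec(cr * (2 * xi * yi + xi * yn + xn * yi + 2 * xn * yn),
                    cl, flat$n_cells) / 24
  list(A = A, Cx = Cx, Cy = Cy,
       Sxx = Jxx / A - Cx^2, Syy = Jyy / A - Cy^2, Sxy = Jxy / A - Cx * Cy,
       Jxx = Jxx, Jyy = Jyy, Jxy = Jxy)
}

rowsum_vec <- function(x, g, n) {
  out <- numeric(n)
  r <- rowsum(x, g)
  out[as.integer(rownames(r))] <- r[, 1]
  out
}

## Total energy of a vertex configuration.
tissue_energy <- function(V, tissue) {
  geo <- tissue_geometry(V, tissue$flat)
  if (any(geo$A <= 0)) return(Inf)
  p <- tissue$params
  trS <- geo$Sxx + geo$Syy
  T <- tissue$target_shape
  trT <- T[, "Txx"] + T[, "Tyy"]
  Nxx <- geo$Sxx / trS; Nyy <- geo$Syy / trS; Nxy <- geo$Sxy / trS
  Mxx <- T[, "Txx"] / trT; Myy <- T[, "Tyy"] / trT; Mxy <- T[, "Txy"] / trT
  e_shape <- (Nxx - Mxx)^2 + 2 * (Nxy - Mxy)^2 + (Nyy - Myy)^2
  sum(p$K_A * (geo$A / tissue$target_area - 1)^2 + p$K_S * e_shape)
}

## Analytic gradient of tissue_energy with respect to every vertex
## coordinate; returns an n_vertices x 2 matrix.  Verified against finite
## differences in the test suite.
tissue_gradient <- function(V, tissue) {
  flat <- tissue$flat
  p <- tissue$params
  xi <- V[flat$v, 1]; yi <- V[flat$v, 2]
  xn <- xi[flat$nxt]; yn <- yi[flat$nxt]
  xp <- xi[flat$prv]; yp <- yi[flat$prv]
  cr <- xi * yn - xn * yi
  crp <- cr[flat$prv]
  cl <- flat$cell
  geo <- tissue_geometry(V, flat)
  A <- geo$A[cl]; Cx <- geo$Cx[cl]; Cy <- geo$Cy[cl]
  Jxx <- geo$Jxx[cl]; Jyy <- geo$Jyy[cl]; Jxy <- geo$Jxy[cl]

  dA_x <- (yn - yp) / 2
  dA_y <- (xp - xn) / 2
  dPx_x <- cr + (xi + xn) * yn + crp - (xp + xi) * yp
  dPx_y <- -(xi + xn) * xn + (xp + xi) * xp
  dPy_x <- (yi + yn) * yn - (yp + yi) * yp
  dPy_y <- cr - (yi + yn) * xn + crp + (yp + yi) * xp
  q <- xi^2 + xi * xn + xn^2
  qp <- q[flat$prv]
  dJxx_x <- (yn * q + cr * (2 * xi + xn) - yp * qp + crp * (xp + 2 * xi)) / 12
  dJxx_y <- (-xn * q + xp * qp) / 12
  rr <- yi^2 + yi * yn + yn^2
  rrp <- rr[flat$prv]
  dJyy_y <- (-xn * rr + cr * (2 * yi + yn) + xp * rrp + crp * (yp + 2 * yi)) / 12
  dJyy_x <- (yn * rr - yp * rrp) / 12
  ss <- 2 * xi * yi + xi * yn + xn * yi + 2 * xn * yn
  ssp <- ss[flat$prv]
  dJxy_x <- (yn * ss + cr * (2 * yi + yn) - yp * ssp + crp * (yp + 2 * yi)) / 24
  dJxy_y <- (-xn * ss + cr * (2 * xi + xn) + xp * ssp + crp * (xp + 2 * xi)) / 24

  dCx_x <- dPx_x / (6 * A) - Cx * dA_x / A
  dCx_y <- dPx_y / (6 * A) - Cx * dA_y / A
  dCy_x <- dPy_x / (6 * A) - Cy * dA_x / A
  dCy_y <- dPy_y / (6 * A) - Cy * dA_y / A

  dSxx_x <- dJxx_x / A - Jxx * dA_x / A^2 - 2 * Cx * dCx_x
  dSxx_y <- dJxx_y / A - Jxx * dA_y / A^2 - 2 * Cx * dCx_y
  dSyy_x <- dJyy_x / A - Jyy * dA_x / A^2 - 2 * Cy * dCy_x
  dSyy_y <- dJyy_y / A - Jyy * dA_y / A^2 - 2 * Cy * dCy_y
  dSxy_x <- dJxy_x / A - Jxy * dA_x / A^2 - (dCx_x * Cy + Cx * dCy_x)
  dSxy_y <- dJxy_y / A - Jxy * dA_y / A^2 - (dCx_y * Cy + Cx * dCy_y)

  trS <- geo$Sxx + geo$Syy
  T <- tissue$target_shape
  trT <- T[, "Txx"] + T[, "Tyy"]
  Nxx <- geo$Sxx / trS; Nyy <- geo$Syy / trS; Nxy <- geo$Sxy / trS
  Dxx <- Nxx - T[, "Txx"] / trT
  Dyy <- Nyy - T[, "Tyy"] / trT
  Dxy <- Nxy - T[, "Txy"] / trT
  dn <- Dxx * Nxx + 2 * Dxy * Nxy + Dyy * Nyy   # <N - M, N>_F
  Gxx <- (Dxx - dn)[cl]; Gyy <- (Dyy - dn)[cl]; Gxy <- Dxy[cl]
  itr <- (1 / trS)[cl]

  area_pref <- (2 * p$K_A * (geo$A / tissue$target_area - 1) / tissue$target_area)[cl]
  gx <- area_pref * dA_x +
    p$K_S * 2 * itr * (Gxx * dSxx_x + 2 * Gxy * dSxy_x + Gyy * dSyy_x)
  gy <- area_pref * dA_y +
    p$K_S * 2 * itr * (Gxx * dSxx_y + 2 * Gxy * dSxy_y + Gyy * dSyy_y)

  grad <- matrix(0, nrow(V), 2)
  grad[, 1] <- rowsum_vec(gx, flat$v, nrow(V))
  grad[, 2] <- rowsum_vec(gy, flat$v, nrow(V))
  grad
}

## ---- growth step ------------------------------------------------------------

#' Advance the tissue by one growth step
#'
#' Updates each cell's targets — area multiplied by the local growth factor
#' `g`, shape tensor transformed by the stretch
#' `B = R(theta) diag(sqrt(g a), sqrt(g/a)) R(theta)^T` (so target
#' anisotropy compounds multiplicatively) — then relaxes the vertices by
#' backtracking gradient descent on the geometric energy.  The descent is
#' initialised by a uniform scaling of the tissue about its centroid by the
#' square root of the mean prescribed area growth.
#'
#' @param tissue A `vertex_tissue`.
#' @param g Per-cell area growth factor(s) for this step (scalar or vector).
#' @param a Per-cell anisotropy factor(s) for this step (>= 1; 1 = isotropic).
#' @param theta Anisotropy axis (radians from the PD axis), scalar or vector.
#' @return The relaxed `vertex_tissue` (attributes `energy` and
#'   `descent_iter` record the final energy and iteration count).
#' @export
tissue_step <- function(tissue, g, a = 1, theta = 0) {
  nc <- length(tissue$cells)
  g <- rep_len(g, nc); a <- rep_len(a, nc); theta <- rep_len(theta, nc)
  if (any(g <= 0) || any(a < 1)) {
    abort("growth factors must be positive and anisotropy >= 1",
          class = "morphomapr_input")
  }
  tissue$target_area <- tissue$target_area * g
  # compound the target shape: T <- B T B', B the prescribed local stretch
  s1 <- sqrt(g * a); s2 <- sqrt(g / a)
  ct <- cos(theta); st <- sin(theta)
  B11 <- ct^2 * s1 + st^2 * s2
  B22 <- st^2 * s1 + ct^2 * s2
  B12 <- ct * st * (s1 - s2)
  Txx <- tissue$target_shape[, "Txx"]
  Txy <- tissue$target_shape[, "Txy"]
  Tyy <- tissue$target_shape[, "Tyy"]
  nTxx <- B11 * (B11 * Txx + B12 * Txy) + B12 * (B11 * Txy + B12 * Tyy)
  nTxy <- B11 * (B12 * Txx + B22 * Txy) + B12 * (B12 * Txy + B22 * Tyy)
  nTyy <- B12 * (B12 * Txx + B22 * Txy) + B22 * (B12 * Txy + B22 * Tyy)
  tissue$target_shape <- cbind(Txx = nTxx, Txy = nTxy, Tyy = nTyy)

  V <- tissue$V
  geo <- tissue_geometry(V, tissue$flat)
  ctr <- c(sum(geo$Cx * geo$A), sum(geo$Cy * geo$A)) / sum(geo$A)
  scale0 <- sqrt(sum(tissue$target_area) / sum(geo$A))
  V <- sweep(sweep(V, 2, ctr) * scale0, 2, ctr, `+`)

  p <- tissue$params
  eta0 <- NULL
  E <- tissue_energy(V, tissue)
  iter <- 0L
  while (iter < p$max_iter) {
    iter <- iter + 1L
    Gr <- tissue_gradient(V, tissue)
    gmax <- max(sqrt(rowSums(Gr^2)))
    if (gmax < 1e-12) break
    if (is.null(eta0)) eta0 <- p$step * sqrt(mean(tissue$target_area)) / gmax
    eta <- eta0
    accepted <- FALSE
    for (bt in 1:40) {
      Vt <- V - eta * Gr
      Et <- tissue_energy(Vt, tissue)   # Inf on polygon flip
      if (is.finite(Et) && Et < E) {
        accepted <- TRUE
        break
      }
      eta <- eta / 2
    }
    if (!accepted) {
      if (!is.finite(tissue_energy(V - 1e-12 * Gr, tissue))) {
        abort("persistent polygon flip during descent", class = "morphomapr_degenerate")
      }
      break   # no further descent possible at numeric precision
    }
    dE <- E - Et
    V <- Vt; E <- Et
    eta0 <- min(eta * 1.5, p$step * sqrt(mean(tissue$target_area)) /
                  max(gmax, 1e-12))
    if (dE < 1e-12 * max(E, 1e-9)) break
  }
  tissue$V <- V
  attr(tissue, "energy") <- E
  attr(tissue, "descent_iter") <- iter
  tissue
}

## ---- scenarios --------------------------------------------------------------

#' Run a morphogenetic scenario
#'
#' Simulates limb-bud outline deformation over `steps` growth steps under
#' prescribed full-interval growth-rate and anisotropy fields, optionally
#' replaced by their virtual-mutant counterparts:
#' \describe{
#'   \item{WT}{fields as given;}
#'   \item{vMT_I}{same growth pattern, anisotropy flattened to 1 everywhere;}
#'   \item{vMT_II}{same anisotropy pattern, growth replaced by its (initial
#'     area-weighted) spatial mean, so net prescribed growth is conserved.}
#' }
#' Fields are sampled once at the initial cell centroids (material/Lagrangian
#' assignment) and compounded as the `steps`-th root per step.
#'
#' @param tissue A `vertex_tissue`.
#' @param growth Full-interval area growth: a scalar, a function of an
#'   `n x 2` point matrix, or a `deformation_field` (its `growth_rate`).
#' @param aniso Full-interval anisotropy magnitude (same forms; field uses
#'   `aniso_mag`).
#' @param theta Anisotropy axis in radians (scalar or function; a
#'   `deformation_field` in `aniso` supplies its own axis).
#' @param steps Number of growth steps.
#' @param scenario `"WT"`, `"vMT_I"` or `"vMT_II"`.
#' @return An object of class `tissue_trajectory`: per-step metrics
#'   (`total_area`, bounding-box `aspect_ratio`, `energy`), the outline
#'   polygon of every step, and the final tissue.
#' @export
run_scenario <- function(tissue, growth, aniso = 1, theta = 0, steps = 4,
                         scenario = c("WT", "vMT_I", "vMT_II")) {
  scenario <- match.arg(scenario)
  geo <- tissue_geometry(tissue$V, tissue$flat)
  cent <- cbind(geo$Cx, geo$Cy)
  g_full <- eval_cell_field(growth, cent, "growth_rate")
  if (inherits(aniso, "deformation_field")) {
    a_full <- eval_cell_field(aniso, cent, "aniso_mag")
    th <- eval_cell_field(aniso, cent, "aniso_angle_deg") * pi / 180
  } else {
    a_full <- eval_cell_field(aniso, cent, NULL)
    th <- if (is.function(theta)) theta(cent) else rep_len(theta, nrow(cent))
  }
  a_full[!is.finite(a_full)] <- 1
  if (scenario == "vMT_I") a_full <- rep(1, length(a_full))
  if (scenario == "vMT_II") {
    g_full <- rep(stats::weighted.mean(g_full, geo$A), length(g_full))
  }
  if (steps < 0) abort("`steps` must be >= 0", class = "morphomapr_input")
  g_step <- g_full^(1 / max(steps, 1))
  a_step <- pmax(a_full, 1)^(1 / max(steps, 1))

  metrics <- list(trajectory_metrics(tissue, 0))
  outlines <- list(tissue_outline(tissue))
  if (steps > 0) {
    for (k in seq_len(steps)) {
      tissue <- tissue_step(tissue, g_step, a_step, th)
      metrics[[k + 1]] <- trajectory_metrics(tissue, k)
      outlines[[k + 1]] <- tissue_outline(tissue)
    }
  }
  structure(
    list(metrics = dplyr::bind_rows(metrics), outlines = outlines,
         tissue = tissue, scenario = scenario),
    class = "tissue_trajectory"
  )
}

eval_cell_field <- function(f, points, column) {
  if (inherits(f, "deformation_field")) {
    return(interp_field(f, points, column))
  }
  if (is.function(f)) return(f(points))
  rep_len(as.numeric(f), nrow(points))
}

## Bilinear interpolation of a per-cell field column over its cell-centre
## grid; queries outside the field (or on unsupported cells) take the value
## of the nearest valid cell.
interp_field <- function(field, points, column) {
  sp <- attr(field, "spacing"); org <- attr(field, "origin")
  fl <- tibble::as_tibble(field)
  nr <- max(fl$cell_i); nc <- max(fl$cell_j)
  M <- matrix(NA_real_, nr, nc)
  vals <- fl[[column]]
  vals[!fl$supported | !fl$ok] <- NA_real_
  M[cbind(fl$cell_i, fl$cell_j)] <- vals
  tf <- list(values = M, origin = org + sp / 2, spacing = sp)
  class(tf) <- "thickness_field"
  gx <- pmin(pmax((points[, 1] - tf$origin[1]) / sp, 0), nc - 1)
  gy <- pmin(pmax((points[, 2] - tf$origin[2]) / sp, 0), nr - 1)
  P <- cbind(tf$origin[1] + gx * sp, tf$origin[2] + gy * sp)
  out <- interp_thickness(tf, P)
  if (any(is.na(out))) {
    # fall back to nearest valid cell centre
    valid <- fl[!is.na(vals), ]
    for (i in which(is.na(out))) {
      d <- (valid$center_pd - points[i, 1])^2 + (valid$center_ap - points[i, 2])^2
      out[i] <- vals[!is.na(vals)][which.min(d)]
    }
  }
  out
}

trajectory_metrics <- function(tissue, step) {
  geo <- tissue_geometry(tissue$V, tissue$flat)
  used <- unique(tissue$flat$v)
  bb <- apply(tissue$V[used, , drop = FALSE], 2, range)
  tibble::tibble(
    step = step,
    total_area = sum(geo$A),
    aspect_ratio = (bb[2, 1] - bb[1, 1]) / (bb[2, 2] - bb[1, 2]),
    energy = attr(tissue, "energy") %||% tissue_energy(tissue$V, tissue)
  )
}

#' Boundary outline of a vertex tissue
#'
#' Chains the edges used by exactly one cell into the tissue boundary
#' polygon.
#'
#' @param tissue A `vertex_tissue`.
#' @return Two-column matrix of boundary vertex positions in order.
#' @export
tissue_outline <- function(tissue) {
  flat <- tissue$flat
  from <- flat$v
  to <- flat$v[flat$nxt]
  key <- paste(pmin(from, to), pmax(from, to))
  boundary <- !(key %in% key[duplicated(key)])
  bf <- from[boundary]; bt <- to[boundary]
  nxt_of <- setNames(bt, bf)
  loop <- integer(length(bf))
  loop[1] <- bf[1]
  for (i in seq_len(length(bf) - 1)) loop[i + 1] <- nxt_of[[as.character(loop[i])]]
  tissue$V[loop, , drop = FALSE]
}

#' @export
print.tissue_trajectory <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<tissue_trajectory> scenario %s, %d steps\n",
              x$scenario, max(m$step)))
  cat(sprintf("  area %.4g -> %.4g um^2, aspect ratio %.3f -> %.3f\n",
              m$total_area[1], m$total_area[nrow(m)],
              m$aspect_ratio[1], m$aspect_ratio[nrow(m)]))
  invisible(x)
}

#' @rdname run_scenario
#' @param x A `tissue_trajectory`.
#' @param ... Unused.
#' @export
tidy.tissue_trajectory <- function(x, ...) x$metrics

#' Write per-step trajectory metrics as TSV
#'
#' Columns `step total_area aspect_ratio energy`.
#'
#' @param trajectory A `tissue_trajectory`.
#' @param path Output file.
#' @export
write_trajectory <- function(trajectory, path) {
  readr::write_tsv(trajectory$metrics, path, progress = FALSE)
  invisible(path)
}

## ---- polygon helpers --------------------------------------------------------

polygon_area <- function(P) {
  x <- P[, 1]; y <- P[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

## Sutherland-Hodgman: intersection of `subject` (simple polygon) with the
## convex polygon `clip` (both CCW).  Returns NULL when empty.
clip_polygon <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) < 3) return(NULL)
    a <- clip[i, ]; b <- clip[if (i == nc) 1 else i + 1, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    side <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])  # >0 = inside (left)
    n <- nrow(out)
    nxt <- c(2:n, 1)
    res <- list()
    for (k in seq_len(n)) {
      kp <- nxt[k]
      cur_in <- side[k] >= -1e-12
      nxt_in <- side[kp] >= -1e-12
      if (cur_in) res[[length(res) + 1]] <- out[k, ]
      if (xor(cur_in, nxt_in)) {
        t <- side[k] / (side[k] - side[kp])
        res[[length(res) + 1]] <- out[k, ] + t * (out[kp, ] - out[k, ])
      }
    }
    out <- if (length(res) >= 3) do.call(rbind, res) else NULL
  }
  out
}
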