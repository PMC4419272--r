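## Per-cell deformation fields and derived statistics.

## Raw per-cell deformation gradients from the bilinear shape-function
## gradient at each cell centre.  For cell (r, c) with deformed corner nodes
## y00 (r,c), y10 (r,c+1), y01 (r+1,c), y11 (r+1,c+1):
##   dphi/dX_pd = ((y10 + y11) - (y00 + y01)) / (2 s)
##   dphi/dX_ap = ((y01 + y11) - (y00 + y10)) / (2 s)
cell_tensors <- function(map) {
  lat <- map$lattice
  s <- lat$spacing
  nr <- lat$n_rows - 1L; nc <- lat$n_cols - 1L  # cells
  rr <- rep(seq_len(nr), each = nc)
  cc <- rep(seq_len(nc), times = nr)
  i00 <- lattice_node_index(lat, rr, cc)
  i10 <- i00 + 1L
  i01 <- i00 + lat$n_cols
  i11 <- i01 + 1L
  E <- map$est_nodes
  dpd <- (E[i10, , drop = FALSE] + E[i11, , drop = FALSE] -
          E[i00, , drop = FALSE] - E[i01, , drop = FALSE]) / (2 * s)
  dap <- (E[i01, , drop = FALSE] + E[i11, , drop = FALSE] -
          E[i00, , drop = FALSE] - E[i10, , drop = FALSE]) / (2 * s)
  F11 <- dpd[, 1]; F21 <- dpd[, 2]; F12 <- dap[, 1]; F22 <- dap[, 2]
  tibble::tibble(
    cell_i = rr, cell_j = cc,
    center_pd = lat$origin[1] + (cc - 0.5) * s,
    center_ap = lat$origin[2] + (rr - 0.5) * s,
    F11 = F11, F12 = F12, F21 = F21, F22 = F22,
    detF = F11 * F22 - F12 * F21
  )
}

#' Per-cell deformation field of an estimated map
#'
#' Evaluates the deformation gradient tensor F at every lattice cell centre
#' (one tensor per cell, from the bilinear shape-function gradient of the
#' cell's four nodes) and decomposes it into tissue growth rate `det F` and
#' deformation anisotropy (magnitude `lambda1/lambda2` and axis, reference
#' frame).  Cells whose centre lies inside the convex hull of the landmark
#' `X` positions are marked `supported`; cells with `det F <= 0` are flagged
#' (`ok = FALSE`), not fatal.
#'
#' @param map A `deformation_map`.
#' @return A tibble of class `deformation_field` with one row per lattice
#'   cell: indices, centre position, `F11..F22`, `growth_rate`, `aniso_mag`,
#'   `aniso_pd`, `aniso_ap`, `aniso_angle_deg`, `n_landmarks`, `supported`,
#'   `ok`.
#' @export
compute_field <- function(map) {
  ct <- cell_tensors(map)
  n <- nrow(ct)
  aniso_mag <- rep(NA_real_, n)
  aniso_pd <- rep(NA_real_, n); aniso_ap <- rep(NA_real_, n)
  ok <- ct$detF > 0
  for (i in which(ok)) {
    an <- anisotropy(matrix(c(ct$F11[i], ct$F21[i], ct$F12[i], ct$F22[i]), 2, 2))
    aniso_mag[i] <- an$mag
    aniso_pd[i] <- an$dir[1]; aniso_ap[i] <- an$dir[2]
  }
  X <- as.matrix(map$landmarks[, c("X_pd", "X_ap")])
  hull <- X[grDevices::chull(X), , drop = FALSE]
  centers <- as.matrix(ct[, c("center_pd", "center_ap")])
  supported <- mgcv::in.out(rbind(hull, hull[1, ]), centers)
  # landmarks per cell
  lat <- map$lattice
  ci <- floor((X[, 2] - lat$origin[2]) / lat$spacing) + 1
  cj <- floor((X[, 1] - lat$origin[1]) / lat$spacing) + 1
  cnt <- table(factor(paste(ci, cj), levels = paste(ct$cell_i, ct$cell_j)))
  out <- tibble::tibble(
    ct[, c("cell_i", "cell_j", "center_pd", "center_ap",
           "F11", "F12", "F21", "F22")],
    growth_rate = ct$detF,
    aniso_mag = aniso_mag,
    aniso_pd = aniso_pd, aniso_ap = aniso_ap,
    aniso_angle_deg = atan2(aniso_ap, aniso_pd) * 180 / pi,
    n_landmarks = as.integer(cnt),
    supported = supported,
    ok = ok
  )
  structure(out,
            class = c("deformation_field", class(out)),
            interval_id = map$interval_id,
            spacing = lat$spacing, origin = lat$origin)
}

#' Export a per-cell deformation field as TSV
#'
#' Columns: `cell_i cell_j center_pd center_ap F11 F12 F21 F22 growth_rate
#' aniso_mag aniso_angle_deg` (plus support flags).
#'
#' @param field A `deformation_field`.
#' @param path Output file.
#' @export
write_field <- function(field, path) {
  readr::write_tsv(tibble::as_tibble(field), path, progress = FALSE)
  invisible(path)
}

#' Dorso-ventral growth rate from paired thickness fields
#'
#' The growth rate along the D-V axis at a reference position `X` is
#' `h(phi(X)) / H(X)`: the thickness after deformation at the mapped
#' position over the thickness before deformation at `X`.  Points outside
#' either thickness support (or the lattice) are returned as `NA` (masked).
#'
#' @param map A `deformation_map`.
#' @param H Thickness field before deformation (frame `"before"`).
#' @param h Thickness field after deformation (frame `"after"`).
#' @param points Data frame with columns `pd`, `ap` (or `X_pd`/`X_ap`,
#'   `center_pd`/`center_ap`) of reference positions; default: supported
#'   cell centres of `compute_field(map)`.
#' @return The `points` tibble with columns `H`, `h_mapped` and `dv_growth`
#'   appended.
#' @export
dv_growth <- function(map, H, h, points = NULL) {
  if (is.null(points)) {
    fl <- compute_field(map)
    points <- tibble::tibble(pd = fl$center_pd, ap = fl$center_ap)[fl$supported, ]
  }
  P <- as_pd_ap_matrix(points)
  H_val <- interp_thickness(H, P)
  mapped <- tryCatch(
    predict(map, tibble::tibble(X_pd = P[, 1], X_ap = P[, 2])),
    error = function(e) NULL
  )
  if (is.null(mapped)) {   # some points outside the lattice: map one by one
    mapped <- purrr::map_dfr(seq_len(nrow(P)), function(i) {
      tryCatch(predict(map, tibble::tibble(X_pd = P[i, 1], X_ap = P[i, 2])),
               error = function(e) tibble::tibble(pd = NA_real_, ap = NA_real_))
    })
  }
  h_val <- interp_thickness(h, mapped)
  bad_H <- !is.na(H_val) & H_val <= 0
  if (any(bad_H)) abort("H(X) <= 0 at some points", class = "morphomapr_input")
  tibble::tibble(pd = P[, 1], ap = P[, 2], H = H_val, h_mapped = h_val,
                 dv_growth = h_val / H_val)
}

#' Volumetric growth rate
#'
#' The 3D volume growth rate at a position is the product of the 2D area
#' growth rate (`det F`) and the D-V growth rate at that position.
#'
#' @param area_growth Area growth rate(s), `det F`; must be positive.
#' @param dv D-V growth rate(s); must be positive (`NA` propagates).
#' @return `area_growth * dv`.
#' @export
volume_growth <- function(area_growth, dv) {
  if (any(area_growth <= 0, na.rm = TRUE) || any(dv <= 0, na.rm = TRUE)) {
    abort("growth rates must be positive", class = "morphomapr_input")
  }
  area_growth * dv
}

#' Correlation between two per-cell fields
#'
#' Pearson correlation over cells with full data support in both fields
#' (pairwise-complete, no imputation).
#'
#' @param f1,f2 Numeric vectors of per-cell values over the same cells.
#' @return Pearson correlation coefficient.
#' @export
field_correlation <- function(f1, f2) {
  if (length(f1) != length(f2)) {
    abort("fields must be over the same cells", class = "morphomapr_input")
  }
  keep <- is.finite(f1) & is.finite(f2)
  if (sum(keep) < 3) abort("need at least 3 complete cells", class = "morphomapr_input")
  if (sd(f1[keep]) == 0 || sd(f2[keep]) == 0) {
    abort("correlation undefined for a constant field", class = "morphomapr_degenerate")
  }
  cor(f1[keep], f2[keep])
}

#' Local field change around an implanted bead
#'
#' Mean treated-minus-control difference of growth rate and anisotropy
#' magnitude over lattice cells whose centres lie within `radius` of the
#' bead centre (reference frame).
#'
#' @param field_treated,field_control `deformation_field` objects on the
#'   same lattice.
#' @param center Length-2 bead centre (pd, ap), um.
#' @param radius Disc radius in um (default 200).
#' @return One-row tibble with `n_cells`, `d_growth`, `d_aniso`.
#' @export
region_change <- function(field_treated, field_control, center, radius = 200) {
  ft <- tibble::as_tibble(field_treated)
  fc <- tibble::as_tibble(field_control)
  j <- dplyr::inner_join(
    ft[, c("cell_i", "cell_j", "center_pd", "center_ap", "growth_rate", "aniso_mag")],
    fc[, c("cell_i", "cell_j", "growth_rate", "aniso_mag")],
    by = c("cell_i", "cell_j"), suffix = c("_t", "_c")
  )
  d <- sqrt((j$center_pd - center[1])^2 + (j$center_ap - center[2])^2)
  j <- j[d <= radius & is.finite(j$growth_rate_t) & is.finite(j$growth_rate_c), ]
  if (nrow(j) == 0) {
    abort("no cells within the bead region in both fields",
          class = "morphomapr_input")
  }
  tibble::tibble(
    n_cells = nrow(j),
    d_growth = mean(j$growth_rate_t - j$growth_rate_c),
    d_aniso = mean(j$aniso_mag_t - j$aniso_mag_c)
  )
}

#' Deformation anisotropy from a few markers (affine fit)
#'
#' Fits the least-squares affine map `x = A X + b` to a small set of paired
#' markers (e.g. four DiI crystals tracked over 24 h) and returns the
#' anisotropy magnitude of `A`.  The translation absorbs any common drift,
#' so only relative positional changes matter.
#'
#' @param data A landmark-style data frame with columns `X_pd`, `X_ap`,
#'   `x_pd`, `x_ap`; at least 3 non-collinear `X` positions.
#' @return Anisotropy magnitude (`lambda1/lambda2` of the fitted stretch).
#' @export
affine_anisotropy <- function(data) {
  data <- tibble::as_tibble(data)
  X <- as.matrix(data[, c("X_pd", "X_ap")])
  x <- as.matrix(data[, c("x_pd", "x_ap")])
  if (nrow(X) < 3 || qr(cbind(1, X))$rank < 3) {
    abort("need >= 3 non-collinear markers for an affine fit",
          class = "morphomapr_degenerate")
  }
  A <- affine_fit(X, x)$A
  anisotropy(A)$mag
}
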