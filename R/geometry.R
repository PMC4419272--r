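## Tensor description of local tissue deformation.
##
## A local linear deformation is a 2x2 tensor F with det F > 0.  Its polar
## decomposition F = R U splits it into a rotation R (SO(2)) and a symmetric
## positive-definite right stretch U.  Tissue growth rate is det F (local area
## expansion factor); deformation anisotropy has magnitude lambda1/lambda2
## (eigenvalues of U, lambda1 >= lambda2) and axis given by the lambda1
## eigenvector, expressed in the reference frame.

#' Polar decomposition of a 2x2 deformation gradient tensor
#'
#' Splits an orientation-preserving tensor `F` into `F = R %*% U`, with `R` a
#' proper rotation and `U` the symmetric positive-definite right stretch
#' tensor.  Uses the exact closed form for 2x2 tensors,
#' `R = [[a+d, b-c], [c-b, a+d]] / sqrt((a+d)^2 + (b-c)^2)`, which is
#' well-defined whenever `det(F) > 0`.
#'
#' @param F A 2x2 numeric matrix with positive determinant.
#' @return A list with elements `R` (rotation) and `U` (right stretch).
#' @examples
#' th <- pi / 5
#' Rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
#' polar_decompose(Rot %*% diag(c(2, 1)))
#' @export
polar_decompose <- function(F) {
  F <- check_tensor(F)
  a <- F[1, 1]; b <- F[1, 2]; c <- F[2, 1]; d <- F[2, 2]
  r <- sqrt((a + d)^2 + (b - c)^2)
  # r > 0 is guaranteed: a+d = 0 and b = c would force det F = -a^2 - b^2 < 0
  R <- matrix(c(a + d, c - b, b - c, a + d), 2, 2) / r
  U <- crossprod(R, F)
  U <- (U + t(U)) / 2   # symmetrize away rounding
  list(R = R, U = U)
}

#' Local deformation summary of an affine map
#'
#' Builds the full local-deformation record of the affine map
#' `x = A %*% X + b`: deformation gradient `F = A`, polar factors, tissue
#' growth rate `det(F)`, and deformation anisotropy (magnitude and axis).
#'
#' @param A 2x2 linear part; must have positive determinant
#'   (orientation-preserving).
#' @param b Length-2 translation (ignored by all derived quantities).
#' @return An object of class `local_deformation`: a list with `F`, `R`, `U`,
#'   `growth_rate`, `aniso_mag`, `aniso_dir` (unit vector, or `c(NA, NA)` when
#'   the stretch is isotropic), and `aniso_defined`.
#' @examples
#' deformation_tensor(diag(c(3, 1)))
#' @export
deformation_tensor <- function(A, b = c(0, 0)) {
  A <- check_tensor(A)
  pol <- polar_decompose(A)
  an <- anisotropy_of_stretch(pol$U)
  structure(
    list(
      F = A, R = pol$R, U = pol$U,
      growth_rate = det2(A),
      aniso_mag = an$mag,
      aniso_dir = an$dir,
      aniso_defined = an$defined
    ),
    class = "local_deformation"
  )
}

#' Deformation anisotropy of a tensor
#'
#' Magnitude `lambda1/lambda2` (eigenvalue ratio of the right stretch `U`,
#' always >= 1; equal to 1 for isotropic deformation) and axis (the `lambda1`
#' eigenvector, sign-normalised to non-negative pd component, then
#' non-negative ap component on ties).  When `lambda1 == lambda2` the axis is
#' undefined: the magnitude is returned as exactly 1 and the direction as
#' `c(NA, NA)`.
#'
#' @inheritParams polar_decompose
#' @return A list with `mag`, `dir` (unit vector or `c(NA, NA)`) and
#'   `defined` (logical; `FALSE` for isotropic deformation).
#' @examples
#' anisotropy(diag(c(2, 0.5)))  # mag 4, axis along pd
#' @export
anisotropy <- function(F) {
  F <- check_tensor(F)
  anisotropy_of_stretch(polar_decompose(F)$U)
}

## Eigen-analysis of a 2x2 SPD stretch tensor; shared by anisotropy() and
## deformation_tensor().
anisotropy_of_stretch <- function(U, iso_tol = 1e-12) {
  e <- eigen(U, symmetric = TRUE)
  lam <- e$values            # decreasing
  if (lam[2] <= 0) {
    abort("stretch tensor is not positive definite", class = "morphomapr_degenerate")
  }
  if (lam[1] / lam[2] > 1e12) {
    abort("near-singular deformation (condition number > 1e12)",
          class = "morphomapr_degenerate")
  }
  if ((lam[1] - lam[2]) <= iso_tol * lam[1]) {
    return(list(mag = 1, dir = c(NA_real_, NA_real_), defined = FALSE))
  }
  v <- e$vectors[, 1]
  v <- v / sqrt(sum(v^2))
  # anisotropy is an axis, not a vector: pick the representative with
  # non-negative pd component (non-negative ap on exact ties)
  if (v[1] < 0 || (v[1] == 0 && v[2] < 0)) v <- -v
  list(mag = lam[1] / lam[2], dir = v, defined = TRUE)
}

#' @export
print.local_deformation <- function(x, ...) {
  cat("<local_deformation>\n")
  cat(sprintf("  growth rate (det F): %.6g\n", x$growth_rate))
  if (x$aniso_defined) {
    cat(sprintf("  anisotropy: %.6g along (%.4f, %.4f)\n",
                x$aniso_mag, x$aniso_dir[1], x$aniso_dir[2]))
  } else {
    cat("  anisotropy: 1 (isotropic; axis undefined)\n")
  }
  invisible(x)
}

#' @rdname deformation_tensor
#' @param x A `local_deformation` object.
#' @param ... Unused.
#' @export
tidy.local_deformation <- function(x, ...) {
  tibble::tibble(
    F11 = x$F[1, 1], F12 = x$F[1, 2], F21 = x$F[2, 1], F22 = x$F[2, 2],
    growth_rate = x$growth_rate,
    aniso_mag = x$aniso_mag,
    aniso_pd = x$aniso_dir[1],
    aniso_ap = x$aniso_dir[2],
    aniso_angle_deg = if (x$aniso_defined)
      atan2(x$aniso_dir[2], x$aniso_dir[1]) * 180 / pi else NA_real_
  )
}

## ---- internal helpers -------------------------------------------------------

det2 <- function(M) M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]

rotation2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

check_tensor <- function(F, arg = "F") {
  F <- as.matrix(F)
  if (!all(dim(F) == c(2L, 2L)) || !all(is.finite(F))) {
    abort(sprintf("`%s` must be a finite 2x2 matrix", arg),
          class = "morphomapr_input")
  }
  if (det2(F) <= 0) {
    abort(sprintf("`%s` must be orientation-preserving (det > 0)", arg),
          class = "morphomapr_orientation")
  }
  F
}
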