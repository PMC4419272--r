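## Gridded dorso-ventral thickness fields.
##
## Thickness is measured on a regular grid (e.g. from OPT scans): H(X) before
## deformation, h(x) after.  Values are micrometres; rows run along the AP
## axis, columns along the PD axis, matching the lattice convention.

#' Construct a gridded thickness field
#'
#' @param values Numeric matrix of thickness values (um); rows index the AP
#'   axis, columns the PD axis.  `NA` marks points outside the measured
#'   support.
#' @param origin Length-2 position (pd, ap) of `values[1, 1]`, in um.
#' @param spacing Grid spacing in um.
#' @param frame `"before"` (field H over X) or `"after"` (field h over x).
#' @return An object of class `thickness_field`.
#' @export
thickness_field <- function(values, origin, spacing, frame = c("before", "after")) {
  frame <- match.arg(frame)
  values <- as.matrix(values)
  if (spacing <= 0) abort("`spacing` must be positive", class = "morphomapr_input")
  if (any(values <= 0, na.rm = TRUE)) {
    abort("thickness values must be positive where defined",
          class = "morphomapr_input")
  }
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = spacing, frame = frame),
            class = "thickness_field")
}

#' @export
print.thickness_field <- function(x, ...) {
  cat(sprintf("<thickness_field> (%s frame) %d x %d grid, spacing %g um, origin (%g, %g)\n",
              x$frame, nrow(x$values), ncol(x$values), x$spacing,
              x$origin[1], x$origin[2]))
  invisible(x)
}

#' Interpolate a thickness field
#'
#' Bilinear interpolation inside the grid support; queries outside the grid
#' (or touching an `NA` corner) return `NA`.
#'
#' @param field A `thickness_field`.
#' @param points Data frame or matrix with columns `pd`, `ap` (um).
#' @return Numeric vector of interpolated thickness (um), `NA` when masked.
#' @export
interp_thickness <- function(field, points) {
  P <- as_pd_ap_matrix(points)
  gx <- (P[, 1] - field$origin[1]) / field$spacing   # column coordinate
  gy <- (P[, 2] - field$origin[2]) / field$spacing   # row coordinate
  nr <- nrow(field$values); nc <- ncol(field$values)
  out <- rep(NA_real_, nrow(P))
  ok <- is.finite(gx) & is.finite(gy) &
    gx >= 0 & gx <= nc - 1 & gy >= 0 & gy <= nr - 1
  if (!any(ok)) return(out)
  cc <- pmin(pmax(floor(gx[ok]), 0), nc - 2)
  rr <- pmin(pmax(floor(gy[ok]), 0), nr - 2)
  u <- gx[ok] - cc; v <- gy[ok] - rr
  V <- field$values
  v00 <- V[cbind(rr + 1, cc + 1)]; v01 <- V[cbind(rr + 1, cc + 2)]
  v10 <- V[cbind(rr + 2, cc + 1)]; v11 <- V[cbind(rr + 2, cc + 2)]
  out[ok] <- (1 - u) * (1 - v) * v00 + u * (1 - v) * v01 +
    (1 - u) * v * v10 + u * v * v11
  out
}

#' Read / write a thickness field (TSV)
#'
#' Header comment lines `#origin_pd <um>`, `#origin_ap <um>`, `#spacing <um>`,
#' `#frame before|after`, followed by the tab-separated value matrix (rows =
#' AP axis).
#'
#' @param path File path.
#' @param field A `thickness_field` (for writing).
#' @return `read_thickness()` returns a `thickness_field`;
#'   `write_thickness()` returns `path` invisibly.
#' @export
read_thickness <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key, default = NULL) {
    ln <- grep(paste0("^#", key, "\\b"), hdr, value = TRUE)
    if (length(ln) == 0) return(default)
    strsplit(trimws(ln[1]), "[\t ]+")[[1]][2]
  }
  vals <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t")
  thickness_field(
    as.matrix(vals),
    origin = c(as.numeric(get("origin_pd")), as.numeric(get("origin_ap"))),
    spacing = as.numeric(get("spacing")),
    frame = get("frame", "before")
  )
}

#' @rdname read_thickness
#' @export
write_thickness <- function(field, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("#origin_pd\t%.10g", field$origin[1]),
    sprintf("#origin_ap\t%.10g", field$origin[2]),
    sprintf("#spacing\t%.10g", field$spacing),
    sprintf("#frame\t%s", field$frame)
  ), con)
  utils::write.table(field$values, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

as_pd_ap_matrix <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 2)
    return(points)
  }
  points <- tibble::as_tibble(points)
  nm <- if (all(c("pd", "ap") %in% names(points))) c("pd", "ap")
        else if (all(c("X_pd", "X_ap") %in% names(points))) c("X_pd", "X_ap")
        else if (all(c("center_pd", "center_ap") %in% names(points)))
          c("center_pd", "center_ap")
        else abort("points need pd/ap coordinate columns", class = "morphomapr_input")
  as.matrix(points[, nm])
}
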