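## Landmark tables.
##
## A landmark table records, per dye mark, its position before (X_pd, X_ap)
## and after (x_pd, x_ap) a developmental time interval, in micrometres in
## the frontal (AP-PD) plane, together with embryo and interval labels.

landmark_cols <- c("embryo_id", "interval_id", "X_pd", "X_ap", "x_pd", "x_ap")

#' Assemble a landmark-pair table
#'
#' Validates and normalises a data frame of paired landmark positions.
#'
#' @param data A data frame with columns `embryo_id`, `interval_id`, `X_pd`,
#'   `X_ap`, `x_pd`, `x_ap` (positions in micrometres; `X` before, `x` after
#'   deformation).
#' @return A tibble with the six landmark columns, coordinates as doubles.
#' @export
landmarks <- function(data) {
  data <- tibble::as_tibble(data)
  missing <- setdiff(landmark_cols, names(data))
  if (length(missing) > 0) {
    abort(paste0("landmark table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "morphomapr_input")
  }
  out <- dplyr::mutate(
    data[landmark_cols],
    embryo_id = as.character(.data$embryo_id),
    interval_id = as.character(.data$interval_id),
    dplyr::across(dplyr::all_of(c("X_pd", "X_ap", "x_pd", "x_ap")), as.numeric)
  )
  if (nrow(out) == 0) {
    abort("landmark table is empty", class = "morphomapr_input")
  }
  coords <- as.matrix(out[c("X_pd", "X_ap", "x_pd", "x_ap")])
  if (!all(is.finite(coords))) {
    abort("landmark coordinates must be finite", class = "morphomapr_input")
  }
  if (any(!nzchar(out$embryo_id))) {
    abort("embryo_id must be nonempty", class = "morphomapr_input")
  }
  out
}

#' Read / write a landmark table (TSV)
#'
#' Tab-separated, UTF-8, '.' decimal, header
#' `embryo_id interval_id X_pd X_ap x_pd x_ap`, coordinates in micrometres.
#'
#' @param path File path.
#' @return `read_landmarks()` returns a validated landmark tibble;
#'   `write_landmarks()` returns `path` invisibly.
#' @export
read_landmarks <- function(path) {
  landmarks(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}

#' @rdname read_landmarks
#' @param data A landmark table.
#' @export
write_landmarks <- function(data, path) {
  readr::write_tsv(landmarks(data), path, progress = FALSE)
  invisible(path)
}

#' Rigidly align embryos to a common frame
#'
#' Pools embryos imaged in slightly different frames by aligning each
#' embryo's outline to the consensus outline with a rigid (rotation +
#' translation, no scaling) Procrustes fit, then applying the fitted
#' transform to that embryo's landmark positions (both `X` and `x`).
#' Scaling is deliberately excluded: inter-embryo size differences are
#' biology, not measurement nuisance.
#'
#' Outlines must share vertex correspondence across embryos (the same
#' outline traced with the same vertex order), as produced by
#' [sample_landmarks()].  The consensus is the vertex-wise mean outline,
#' refined by one realignment pass (generalized Procrustes).
#'
#' @param data A landmark table.
#' @param outlines A data frame with columns `embryo_id`, `vertex`, `pd`,
#'   `ap`: one outline polygon per embryo, vertices in corresponding order.
#' @param reference Optional reference outline (two-column matrix, same
#'   vertex correspondence) fixing the common frame, e.g. the interval's
#'   mean or atlas limb outline; `NULL` uses the consensus of the embryos.
#' @return The landmark table with `X` and `x` mapped into the common
#'   frame; the per-embryo fitted transforms are attached as attribute
#'   `"frames"` (tibble with `embryo_id`, `theta`, `t_pd`, `t_ap`).
#' @export
register_embryos <- function(data, outlines, reference = NULL) {
  data <- landmarks(data)
  outlines <- tibble::as_tibble(outlines)
  ids <- unique(data$embryo_id)
  if (!all(ids %in% outlines$embryo_id)) {
    abort("every embryo in the landmark table needs an outline",
          class = "morphomapr_input")
  }
  polys <- lapply(ids, function(id) {
    o <- dplyr::arrange(outlines[outlines$embryo_id == id, ], .data$vertex)
    as.matrix(o[, c("pd", "ap")])
  })
  nv <- vapply(polys, nrow, integer(1))
  if (length(unique(nv)) != 1) {
    abort("outlines must have the same number of vertices (corresponding order)",
          class = "morphomapr_input")
  }
  if (is.null(reference)) {
    # generalized rigid Procrustes: align to first, average, realign to mean
    target <- polys[[1]]
    for (pass in 1:2) {
      fits <- lapply(polys, kabsch_rigid, target = target)
      aligned <- lapply(seq_along(polys), function(i) {
        apply_rigid(polys[[i]], fits[[i]])
      })
      target <- Reduce(`+`, aligned) / length(aligned)
    }
  } else {
    target <- as_pd_ap_matrix(reference)
    if (nrow(target) != nv[1]) {
      abort("`reference` outline must share the embryos' vertex correspondence",
            class = "morphomapr_input")
    }
  }
  fits <- lapply(polys, kabsch_rigid, target = target)
  frames <- tibble::tibble(
    embryo_id = ids,
    theta = vapply(fits, function(f) atan2(f$R[2, 1], f$R[1, 1]), numeric(1)),
    t_pd = vapply(fits, function(f) f$t[1], numeric(1)),
    t_ap = vapply(fits, function(f) f$t[2], numeric(1))
  )
  out <- data
  for (i in seq_along(ids)) {
    sel <- out$embryo_id == ids[i]
    Xn <- apply_rigid(as.matrix(out[sel, c("X_pd", "X_ap")]), fits[[i]])
    xn <- apply_rigid(as.matrix(out[sel, c("x_pd", "x_ap")]), fits[[i]])
    out[sel, c("X_pd", "X_ap")] <- as.data.frame(Xn)
    out[sel, c("x_pd", "x_ap")] <- as.data.frame(xn)
  }
  attr(out, "frames") <- frames
  out
}

## Rigid Kabsch fit: rotation + translation (no scaling, no reflection)
## minimizing ||R P + t - target||.
kabsch_rigid <- function(P, target) {
  cp <- colMeans(P); ct <- colMeans(target)
  H <- crossprod(sweep(P, 2, cp), sweep(target, 2, ct))
  sv <- svd(H)
  d <- sign(det2(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  list(R = R, t = as.numeric(ct - R %*% cp))
}

apply_rigid <- function(P, fit) {
  sweep(P %*% t(fit$R), 2, fit$t, `+`)
}
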