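## Cross-validation of estimated deformation maps.

#' Cross-validate a deformation map estimate
#'
#' Evaluates the out-of-sample prediction error of the lattice map: for each
#' fold, the map is re-estimated on the training pairs and the held-out
#' before-positions are mapped and compared with their observed
#' after-positions.  Default scheme is leave-one-embryo-out, matching the
#' pooled multi-embryo design; seeded k-fold over landmarks is available for
#' single-embryo data.  Held-out points outside the training lattice are
#' skipped and counted; folds with fewer than 6 training pairs are skipped
#' with a warning.
#'
#' @param data A landmark table for one interval.
#' @param scheme `"loeo"` (leave-one-embryo-out) or `"kfold"`.
#' @param k Number of folds for `scheme = "kfold"` (default 5).
#' @param seed Integer seed for the k-fold shuffle.
#' @param spacing,margin_cells,alpha,sigma2 Passed to [estimate_map()].
#' @return An object of class `cv_report`: per-fold and pooled mean/median
#'   absolute errors along the PD and AP axes and the Euclidean error, all
#'   in micrometres.
#' @export
cross_validate <- function(data, scheme = c("loeo", "kfold"), k = 5, seed = 1,
                           spacing = 200, margin_cells = 1,
                           alpha = NULL, sigma2 = NULL) {
  scheme <- match.arg(scheme)
  data <- landmarks(data)
  if (length(unique(data$interval_id)) != 1) {
    abort("cross_validate() works on one time interval", class = "morphomapr_input")
  }
  n <- nrow(data)
  if (scheme == "loeo") {
    ids <- unique(data$embryo_id)
    if (length(ids) < 2) {
      abort("leave-one-embryo-out needs at least 2 embryos",
            class = "morphomapr_input")
    }
    fold_of <- match(data$embryo_id, ids)
    n_folds <- length(ids)
  } else {
    if (k < 2 || k > n) abort("invalid `k`", class = "morphomapr_input")
    set.seed(seed)
    fold_of <- sample(rep(seq_len(k), length.out = n))
    n_folds <- k
  }

  per_fold <- list()
  errs <- list()
  n_skipped_points <- 0L
  for (f in seq_len(n_folds)) {
    train <- data[fold_of != f, ]
    test <- data[fold_of == f, ]
    if (nrow(train) < 6) {
      warn(sprintf("fold %d skipped: fewer than 6 training pairs", f))
      next
    }
    map <- estimate_map(train, spacing = spacing, margin_cells = margin_cells,
                        alpha = alpha, sigma2 = sigma2)
    inside <- points_in_lattice(map$lattice, as.matrix(test[, c("X_pd", "X_ap")]))
    n_skipped_points <- n_skipped_points + sum(!inside)
    test <- test[inside, ]
    if (nrow(test) == 0) {
      warn(sprintf("fold %d: all held-out points outside the training lattice", f))
      next
    }
    pred <- predict(map, test)
    e <- tibble::tibble(
      fold = f,
      d_pd = abs(pred$pd - test$x_pd),
      d_ap = abs(pred$ap - test$x_ap),
      d_euclid = sqrt((pred$pd - test$x_pd)^2 + (pred$ap - test$x_ap)^2)
    )
    errs[[length(errs) + 1]] <- e
    per_fold[[length(per_fold) + 1]] <- tibble::tibble(
      fold = f, n_test = nrow(test),
      err_pd = mean(e$d_pd), err_ap = mean(e$d_ap), err_euclid = mean(e$d_euclid)
    )
  }
  if (length(errs) == 0) {
    abort("all folds were skipped; cannot cross-validate", class = "morphomapr_degenerate")
  }
  all_e <- dplyr::bind_rows(errs)
  structure(
    list(
      interval_id = data$interval_id[1],
      scheme = scheme,
      n_folds = length(per_fold),
      n_skipped_points = n_skipped_points,
      err_pd = mean(all_e$d_pd),
      err_ap = mean(all_e$d_ap),
      err_euclid = mean(all_e$d_euclid),
      med_pd = median(all_e$d_pd),
      med_ap = median(all_e$d_ap),
      med_euclid = median(all_e$d_euclid),
      per_fold = dplyr::bind_rows(per_fold),
      pointwise = all_e
    ),
    class = "cv_report"
  )
}

points_in_lattice <- function(lat, P) {
  gx <- (P[, 1] - lat$origin[1]) / lat$spacing
  gy <- (P[, 2] - lat$origin[2]) / lat$spacing
  gx >= 0 & gx <= lat$n_cols - 1 & gy >= 0 & gy <= lat$n_rows - 1
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> interval %s, scheme %s, %d folds (%d held-out points skipped)\n",
              x$interval_id, x$scheme, x$n_folds, x$n_skipped_points))
  cat(sprintf("  mean prediction error: PD %.2f um, AP %.2f um, Euclidean %.2f um\n",
              x$err_pd, x$err_ap, x$err_euclid))
  cat(sprintf("  median prediction error: PD %.2f um, AP %.2f um, Euclidean %.2f um\n",
              x$med_pd, x$med_ap, x$med_euclid))
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `cv_report`.
#' @param ... Unused.
#' @export
tidy.cv_report <- function(x, ...) x$per_fold

#' @rdname cross_validate
#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(
    interval_id = x$interval_id, scheme = x$scheme, n_folds = x$n_folds,
    n_skipped_points = x$n_skipped_points,
    err_pd = x$err_pd, err_ap = x$err_ap, err_euclid = x$err_euclid,
    med_pd = x$med_pd, med_ap = x$med_ap, med_euclid = x$med_euclid
  )
}

#' Serialize a cross-validation report to JSON
#'
#' @param report A `cv_report`.
#' @param path Output file.
#' @export
write_cv_report <- function(report, path) {
  obj <- report
  class(obj) <- NULL
  obj$pointwise <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
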