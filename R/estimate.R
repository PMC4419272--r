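## Bayesian estimation of the deformation map.
##
## Model: each observed after-position x_i is the bilinear interpolation of
## the unknown deformed node positions y_j at X_i, plus isotropic Gaussian
## noise.  Prior: Gaussian smoothness penalty lambda * ||L d||^2 on the node
## displacements d = y - ref, with L the stacked second-difference operator
## (lattice_penalty); its null space is the bilinear fields, so affine
## deformation is unpenalised.  The posterior mean solves, per coordinate,
##     (W'W + lambda L'L) d = W'(x - W ref),        lambda = alpha * sigma^2.
## Hyperparameters are chosen by empirical Bayes: the type-II (marginal)
## log-likelihood is maximised over a 25-point log-spaced grid of the
## smoothing parameter, with sigma^2 profiled in closed form and the penalty
## null space treated as diffuse.

#' Estimate a smooth deformation map from landmark pairs
#'
#' Fits the lattice deformation map by penalised (Bayesian) least squares
#' with a smoothness prior, pooling all landmarks of one time interval.
#' With `alpha = NULL` the smoothness weight and observation variance are
#' selected by empirical Bayes (marginal-likelihood maximisation).
#'
#' @param data A landmark table for a single interval (see [landmarks()]).
#' @param lattice A `lattice_grid`, or `NULL` to build one from the data.
#' @param spacing,margin_cells Passed to [build_lattice()] when `lattice`
#'   is `NULL`.
#' @param alpha Smoothness weight (prior precision scale, 1/um^2); `NULL`
#'   selects it by empirical Bayes.
#' @param sigma2 Observation variance in um^2; `NULL` profiles it from the
#'   marginal likelihood.
#' @return An object of class `deformation_map` with the lattice, the
#'   posterior-mean deformed node positions, fitted hyperparameters, and the
#'   (possibly replicate-averaged) landmark table used.
#' @seealso [predict.deformation_map()], [residual_error()],
#'   [cross_validate()], [compute_field()]
#' @export
estimate_map <- function(data, lattice = NULL, spacing = 200, margin_cells = 1,
                         alpha = NULL, sigma2 = NULL) {
  data <- landmarks(data)
  if (length(unique(data$interval_id)) != 1) {
    abort("estimate_map() fits one time interval; filter `interval_id` first",
          class = "morphomapr_input")
  }
  if (!is.null(alpha) && alpha <= 0) {
    abort("`alpha` must be positive", class = "morphomapr_input")
  }
  data <- average_replicates(data)
  if (nrow(data) < 6) {
    abort("need at least 6 landmark pairs (affine component identifiable)",
          class = "morphomapr_input")
  }
  X <- as.matrix(data[, c("X_pd", "X_ap")])
  x <- as.matrix(data[, c("x_pd", "x_ap")])
  if (qr(cbind(1, X))$rank < 3) {
    abort("landmarks are collinear; the map is not identifiable",
          class = "morphomapr_degenerate")
  }
  if (is.null(lattice)) {
    lattice <- build_lattice(data, spacing = spacing, margin_cells = margin_cells)
  }
  ref <- lattice_nodes(lattice)
  W <- lattice_design(lattice, X)
  L <- lattice_penalty(lattice)
  K <- crossprod(L)
  r <- x - W %*% ref              # n x 2 working response (displacements)
  n <- nrow(X); m <- nrow(ref)

  ek <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  null_dim <- sum(ek < max(ek) * 1e-10)          # affine null space (3)
  logpdet_K <- sum(log(ek[ek >= max(ek) * 1e-10]))
  supported <- colSums(abs(W)) > 0

  # posterior-mean solve as augmented least squares on [W; sqrt(lambda) L]:
  # backward-stable for any smoothing weight, and the R factor supplies
  # log det(W'W + lambda K) for the marginal likelihood
  zero_pad <- matrix(0, nrow(L), 2)
  fit_at <- function(lambda) {
    Aug <- rbind(W, sqrt(lambda) * L)
    rhs <- rbind(r, zero_pad)
    qd <- qr(Aug)
    if (qd$rank < m) {
      # degenerate support: tiny ridge on unsupported nodes for solvability
      ridge <- diag(ifelse(supported, 0, 1e-4), m)   # sqrt(1e-8)
      Aug <- rbind(Aug, ridge[!supported, , drop = FALSE])
      rhs <- rbind(rhs, matrix(0, sum(!supported), 2))
      qd <- qr(Aug)
      if (qd$rank < m) {
        Aug <- rbind(Aug, diag(1e-4, m))
        rhs <- rbind(rhs, matrix(0, m, 2))
        qd <- qr(Aug)
      }
    }
    d <- qr.coef(qd, rhs)
    d[is.na(d)] <- 0
    dimnames(d) <- NULL
    resid <- r - W %*% d
    rss <- colSums(resid^2)
    quad <- colSums((rhs - Aug %*% d)^2)           # RSS + lambda d'Kd
    list(d = d, rss = rss, quad = quad,
         logdet_M = 2 * sum(log(abs(diag(qr.R(qd))))))
  }

  ## -2 x type-II log-likelihood (both coordinates, shared hyperparameters),
  ## penalty null space diffuse, up to an additive constant
  neg2_logml <- function(lambda, f, s2) {
    2 * (n - null_dim) * log(s2) + sum(f$quad) / s2 +
      2 * (f$logdet_M - (m - null_dim) * log(lambda) - logpdet_K)
  }

  if (!is.null(alpha) && !is.null(sigma2)) {
    lambda <- alpha * sigma2
    f <- fit_at(lambda)
    eb <- NULL
  } else {
    # initial noise scale from an affine pre-fit (floor keeps the grid proper
    # for noiseless data)
    aff <- affine_fit(X, x)
    s2_0 <- max(mean(colSums((x - cbind(1, X) %*% aff$beta)^2)) /
                  max(n - 3, 1), 1e-8)
    if (is.null(alpha)) {
      lam_grid <- 10^seq(log10(1e-6 * s2_0), log10(1e2 * s2_0), length.out = 25)
      score <- numeric(length(lam_grid))
      fits <- vector("list", length(lam_grid))
      for (i in seq_along(lam_grid)) {
        f <- fits[[i]] <- fit_at(lam_grid[i])
        s2 <- if (is.null(sigma2)) sum(f$quad) / (2 * (n - null_dim)) else sigma2
        score[i] <- neg2_logml(lam_grid[i], f, max(s2, 1e-12))
      }
      best <- which.min(score)
      lambda <- lam_grid[best]
      f <- fits[[best]]
      eb <- tibble::tibble(lambda = lam_grid, neg2_logml = score)
    } else {
      # fixed alpha, unknown sigma2: short fixed-point iteration
      s2 <- s2_0
      for (it in 1:3) {
        f <- fit_at(alpha * s2)
        s2 <- max(sum(f$quad) / (2 * (n - null_dim)), 1e-12)
      }
      lambda <- alpha * s2
      eb <- NULL
    }
    if (is.null(sigma2)) sigma2 <- max(sum(f$quad) / (2 * (n - null_dim)), 1e-12)
    if (is.null(alpha)) alpha <- lambda / sigma2
  }

  est <- ref + f$d
  map <- structure(
    list(lattice = lattice, ref_nodes = ref, est_nodes = est,
         hyperparams = list(alpha = alpha, sigma2 = sigma2, lambda = lambda),
         eb_grid = eb, interval_id = data$interval_id[1],
         landmarks = data, node_supported = supported),
    class = "deformation_map"
  )
  map$fold_free <- all(cell_tensors(map)$detF > 0)
  if (!map$fold_free) {
    warn("estimated map contains folded cells (det F <= 0); inspect tidy(compute_field(map))")
  }
  map
}

## exact-duplicate X positions are measurement replicates: average their x
average_replicates <- function(data) {
  key <- paste(data$interval_id, data$X_pd, data$X_ap, sep = "\r")
  if (!anyDuplicated(key)) return(data)
  warn("duplicate X positions found; averaging their deformed positions")
  out <- dplyr::summarise(
    dplyr::group_by(data, .data$interval_id, .data$X_pd, .data$X_ap),
    embryo_id = .data$embryo_id[1],
    x_pd = mean(.data$x_pd), x_ap = mean(.data$x_ap), .groups = "drop"
  )
  landmarks(out)
}

affine_fit <- function(X, x) {
  B <- cbind(1, X)
  beta <- qr.solve(B, x)           # 3 x 2: intercepts + linear part
  list(beta = beta, A = t(beta[2:3, ]), b = beta[1, ])
}

#' Evaluate an estimated deformation map
#'
#' Bilinear interpolation of the estimated node positions at new
#' before-deformation positions.  No extrapolation: points outside the
#' lattice raise an error.
#'
#' @param object A `deformation_map`.
#' @param newdata A data frame with columns `X_pd`, `X_ap` (micrometres).
#' @param ... Unused.
#' @return A tibble with the mapped positions `pd`, `ap`.
#' @export
predict.deformation_map <- function(object, newdata, ...) {
  P <- as.matrix(tibble::as_tibble(newdata)[, c("X_pd", "X_ap")])
  W <- lattice_design(object$lattice, P)
  out <- W %*% object$est_nodes
  tibble::tibble(pd = out[, 1], ap = out[, 2])
}

#' Residual error of an estimated map
#'
#' Mean Euclidean distance (micrometres) between mapped and observed
#' after-positions.
#'
#' @param map A `deformation_map`.
#' @param data Landmark table to evaluate on; defaults to the fitting data.
#' @return Mean residual in micrometres.
#' @export
residual_error <- function(map, data = NULL) {
  data <- if (is.null(data)) map$landmarks else landmarks(data)
  if (nrow(data) == 0) abort("no landmarks to evaluate", class = "morphomapr_input")
  pred <- predict(map, data)
  mean(sqrt((pred$pd - data$x_pd)^2 + (pred$ap - data$x_ap)^2))
}

#' @export
print.deformation_map <- function(x, ...) {
  cat(sprintf("<deformation_map> interval %s: %d landmarks on a %dx%d-node lattice (spacing %g um)\n",
              x$interval_id, nrow(x$landmarks),
              x$lattice$n_rows, x$lattice$n_cols, x$lattice$spacing))
  cat(sprintf("  alpha %.3g, sigma2 %.3g um^2, residual %.2f um%s\n",
              x$hyperparams$alpha, x$hyperparams$sigma2, residual_error(x),
              if (x$fold_free) "" else "  [folded cells!]"))
  invisible(x)
}

#' @rdname estimate_map
#' @param x A `deformation_map`.
#' @param ... Unused.
#' @export
tidy.deformation_map <- function(x, ...) {
  lat <- x$lattice
  tibble::tibble(
    row = rep(seq_len(lat$n_rows), each = lat$n_cols),
    col = rep(seq_len(lat$n_cols), times = lat$n_rows),
    ref_pd = x$ref_nodes[, 1], ref_ap = x$ref_nodes[, 2],
    est_pd = x$est_nodes[, 1], est_ap = x$est_nodes[, 2],
    supported = x$node_supported
  )
}

#' @rdname estimate_map
#' @export
glance.deformation_map <- function(x, ...) {
  tibble::tibble(
    interval_id = x$interval_id,
    n_landmarks = nrow(x$landmarks),
    n_rows = x$lattice$n_rows, n_cols = x$lattice$n_cols,
    spacing = x$lattice$spacing,
    alpha = x$hyperparams$alpha,
    sigma2 = x$hyperparams$sigma2,
    lambda = x$hyperparams$lambda,
    residual_um = residual_error(x),
    fold_free = x$fold_free
  )
}

#' Serialize a deformation map to JSON
#'
#' Writes origin, spacing, grid shape, reference and estimated node arrays
#' (row-major), hyperparameters, and a provenance block (landmark digest,
#' package version).
#'
#' @param map A `deformation_map`.
#' @param path Output file.
#' @return `path`, invisibly (`read_map()` returns the `deformation_map`).
#' @export
write_map <- function(map, path) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  readr::write_tsv(map$landmarks, tmp, progress = FALSE)
  obj <- list(
    origin = map$lattice$origin,
    spacing = map$lattice$spacing,
    shape = c(map$lattice$n_rows, map$lattice$n_cols),
    ref_nodes = map$ref_nodes,
    est_nodes = map$est_nodes,
    hyperparams = map$hyperparams[c("alpha", "sigma2", "lambda")],
    interval_id = map$interval_id,
    landmarks = map$landmarks,
    provenance = list(
      landmark_md5 = unname(tools::md5sum(tmp)),
      n_landmarks = nrow(map$landmarks),
      package = as.character(utils::packageVersion("morphomapr"))
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lat <- new_lattice(obj$origin, obj$spacing, obj$shape[1], obj$shape[2])
  data <- landmarks(obj$landmarks)
  map <- structure(
    list(lattice = lat, ref_nodes = lattice_nodes(lat),
         est_nodes = matrix(as.numeric(obj$est_nodes), ncol = 2),
         hyperparams = obj$hyperparams, eb_grid = NULL,
         interval_id = obj$interval_id, landmarks = data,
         node_supported = colSums(abs(lattice_design(
           lat, as.matrix(data[, c("X_pd", "X_ap")])))) > 0),
    class = "deformation_map"
  )
  map$fold_free <- all(cell_tensors(map)$detF > 0)
  map
}
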