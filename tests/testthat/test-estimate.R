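test_that("noiseless affine data is reproduced exactly for any smoothness weight", {
  A <- matrix(c(1.3, 0.1, -0.05, 1.15), 2, 2); b <- c(30, -20)
  lm <- affine_landmarks(A, b, n = 20)
  for (alpha in c(1e-6, 1e-2, 1, 1e2)) {
    map <- estimate_map(lm, alpha = alpha, sigma2 = 400)
    target <- cbind(1, map$ref_nodes) %*% rbind(b, t(A))
    expect_lt(max(abs(map$est_nodes - target)), 1e-6)
  }
  # empirical-Bayes path is exact too
  map <- estimate_map(lm)
  target <- cbind(1, map$ref_nodes) %*% rbind(b, t(A))
  expect_lt(max(abs(map$est_nodes - target)), 1e-6)
  expect_lt(residual_error(map), 1e-8)
})

test_that("the identity map is recovered when nothing moves", {
  lm <- affine_landmarks(diag(2), c(0, 0), n = 15)
  map <- estimate_map(lm)
  expect_equal(map$est_nodes, map$ref_nodes, tolerance = 1e-8)
})

test_that("the posterior mean is equivariant to rigid motions of the target data", {
  lm <- affine_landmarks(n = 25, sigma = 15, seed = 3)
  map0 <- estimate_map(lm, alpha = 0.01, sigma2 = 225)
  # translate all x by t: the solution translates
  t_sh <- c(130, -70)
  lm_t <- dplyr::mutate(lm, x_pd = x_pd + t_sh[1], x_ap = x_ap + t_sh[2])
  map_t <- estimate_map(lm_t, alpha = 0.01, sigma2 = 225)
  expect_equal(map_t$est_nodes, sweep(map0$est_nodes, 2, t_sh, `+`),
               tolerance = 1e-5)
  # rotate all x by Q: the solution rotates (isotropic prior)
  Q <- rot2(0.4)
  xr <- as.matrix(lm[, c("x_pd", "x_ap")]) %*% t(Q)
  lm_r <- dplyr::mutate(lm, x_pd = xr[, 1], x_ap = xr[, 2])
  map_r <- estimate_map(lm_r, alpha = 0.01, sigma2 = 225)
  expect_equal(map_r$est_nodes, map0$est_nodes %*% t(Q), tolerance = 1e-5)
})

test_that("infinite smoothing converges to the best-fit affine map", {
  lm <- affine_landmarks(n = 40, sigma = 25, seed = 5)
  # oracle: per-coordinate least squares on {1, X_pd, X_ap}
  fit <- lm(cbind(x_pd, x_ap) ~ X_pd + X_ap, data = lm)
  for (alpha in c(1e7, 1e9)) {
    map <- estimate_map(lm, alpha = alpha, sigma2 = 625)
    target <- cbind(1, map$ref_nodes) %*% coef(fit)
    expect_lt(max(abs(map$est_nodes - target)), 1e-3)
  }
})

test_that("degenerate inputs are rejected or repaired", {
  lm <- affine_landmarks(n = 12)
  expect_error(estimate_map(lm[1:5, ]), class = "morphomapr_input")
  col <- lm
  col$X_ap <- 2 * col$X_pd + 1      # collinear
  expect_error(estimate_map(col), class = "morphomapr_degenerate")
  dup <- dplyr::bind_rows(lm, dplyr::mutate(lm[1, ], x_pd = x_pd + 10))
  expect_warning(map <- estimate_map(dup, alpha = 1, sigma2 = 1),
                 "duplicate")
  expect_equal(nrow(map$landmarks), nrow(lm))
  expect_error(estimate_map(lm, alpha = -1), class = "morphomapr_input")
})

test_that("the default synthetic scenario is recovered within tolerance", {
  rec <- default_recovery()
  sup <- dplyr::filter(rec$field, supported, ok)
  truth <- rec$gt$detF(cbind(sup$center_pd, sup$center_ap))
  rel <- abs(sup$growth_rate - truth) / truth
  expect_gte(mean(rel <= 0.10), 0.90)
  # anisotropy field recovers too
  ta <- rec$gt$aniso_mag(cbind(sup$center_pd, sup$center_ap))
  expect_gte(mean(abs(sup$aniso_mag - ta) / ta <= 0.10), 0.90)
  # residual sits at the noise floor, well under the mesh size
  expect_gt(residual_error(rec$map), 10)
  expect_lt(residual_error(rec$map), 40)
  # estimated noise close to the generating sigma^2 = 400 um^2
  expect_gt(rec$map$hyperparams$sigma2, 150)
  expect_lt(rec$map$hyperparams$sigma2, 900)
  # fold-free
  expect_true(all(sup$growth_rate > 0))
})

test_that("registration removes per-embryo rigid frame jitter", {
  rec <- default_recovery()
  truth <- attr(rec$lmk, "truth")
  # registered X equals the canonical X up to numerical Procrustes error
  expect_lt(max(abs(rec$reg$X_pd - truth$X_pd)), 1e-6)
  expect_lt(max(abs(rec$reg$X_ap - truth$X_ap)), 1e-6)
  frames <- attr(rec$reg, "frames")
  jit <- attr(rec$lmk, "frames")
  # fitted rotations undo the applied ones
  expect_equal(sort(frames$theta), sort(-jit$theta), tolerance = 1e-8)
})

test_that("maps survive a JSON round trip", {
  rec <- default_recovery()
  path <- withr::local_tempfile(fileext = ".json")
  write_map(rec$map, path)
  back <- read_map(path)
  expect_equal(back$est_nodes, rec$map$est_nodes, tolerance = 1e-12)
  expect_equal(back$lattice$spacing, rec$map$lattice$spacing)
  expect_equal(residual_error(back), residual_error(rec$map), tolerance = 1e-10)
})
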