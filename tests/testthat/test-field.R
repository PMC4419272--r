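test_that("identity and affine maps give spatially constant fields", {
  lm <- affine_landmarks(diag(2), c(0, 0), n = 15)
  fl <- compute_field(estimate_map(lm, alpha = 1, sigma2 = 1))
  expect_true(all(abs(fl$growth_rate - 1) < 1e-8))
  expect_true(all(abs(fl$aniso_mag - 1) < 1e-6))

  A <- matrix(c(1.4, 0.08, -0.1, 1.1), 2, 2)
  lm <- affine_landmarks(A, c(50, 10), n = 25)
  fl <- compute_field(estimate_map(lm, alpha = 1, sigma2 = 400))
  # F equals A exactly in every cell (bilinear gradient of an affine field)
  expect_lt(max(abs(fl$F11 - A[1, 1])), 1e-8)
  expect_lt(max(abs(fl$F12 - A[1, 2])), 1e-8)
  expect_lt(max(abs(fl$F21 - A[2, 1])), 1e-8)
  expect_lt(max(abs(fl$F22 - A[2, 2])), 1e-8)
  expect_lt(max(abs(fl$growth_rate - det(A))), 1e-8)
})

test_that("the recovered growth field correlates strongly with the truth", {
  rec <- default_recovery()
  sup <- dplyr::filter(rec$field, supported, ok)
  truth <- rec$gt$detF(cbind(sup$center_pd, sup$center_ap))
  expect_gte(field_correlation(sup$growth_rate, truth), 0.9)
})

test_that("D-V growth is the thickness ratio along the map", {
  # constant fields: H = 200, h = 300 -> ratio 1.5 everywhere
  H <- thickness_field(matrix(200, 30, 40), origin = c(-2000, -2000),
                       spacing = 200, frame = "before")
  h <- thickness_field(matrix(300, 30, 40), origin = c(-2000, -2000),
                       spacing = 200, frame = "after")
  lm <- affine_landmarks(n = 20)
  map <- estimate_map(lm, alpha = 1, sigma2 = 400)
  dv <- dv_growth(map, H, h, points = tibble::tibble(pd = c(200, 500),
                                                     ap = c(100, 300)))
  expect_equal(dv$dv_growth, c(1.5, 1.5))
  # identity map with h = H: ratio 1 everywhere
  lm_id <- affine_landmarks(diag(2), c(0, 0), n = 15)
  dv <- dv_growth(estimate_map(lm_id, alpha = 1, sigma2 = 1), H, H,
                  points = tibble::tibble(pd = 300, ap = 200))
  expect_equal(dv$dv_growth, 1, tolerance = 1e-8)
})

test_that("synthetic thickness pairs reproduce their known ratio field", {
  rec <- default_recovery()
  tp <- make_thickness_pair(rec$spec, rec$gt, target_correlation = 0.2)
  sup <- dplyr::filter(rec$field, supported, ok)
  pts <- tibble::tibble(pd = sup$center_pd, ap = sup$center_ap)
  dv <- dv_growth(rec$map, tp$H, tp$h, points = pts)
  truth <- tp$ratio(cbind(dv$pd, dv$ap))
  ok <- !is.na(dv$dv_growth)
  expect_gt(mean(ok), 0.9)
  expect_lt(max(abs(dv$dv_growth[ok] - truth[ok]) / truth[ok]), 0.02)
  # the engineered correlation with area growth lands near its target
  r <- field_correlation(dv$dv_growth, sup$growth_rate)
  expect_lt(abs(r - 0.2), 0.1)
})

test_that("volume growth is the exact area x D-V product", {
  expect_equal(volume_growth(1, 1), 1)
  expect_equal(volume_growth(1.3, 1.2), 1.56)
  set.seed(11)
  a <- runif(50, 0.5, 2); d <- runif(50, 0.5, 2)
  looped <- vapply(1:50, function(i) a[i] * d[i], numeric(1))
  expect_equal(volume_growth(a, d), looped)
  expect_error(volume_growth(-1, 1), class = "morphomapr_input")
})

test_that("field correlation behaves like Pearson r with masking", {
  set.seed(5)
  f <- rnorm(100)
  expect_equal(field_correlation(f, f), 1)
  expect_equal(field_correlation(f, -f), -1)
  g <- rnorm(100)                      # independent noise fields
  expect_lt(abs(field_correlation(f, g)), 0.3)
  expect_error(field_correlation(f, rep(1, 100)),
               class = "morphomapr_degenerate")
  expect_error(field_correlation(f[1:2], g[1:2]), class = "morphomapr_input")
})

test_that("bead-region change averages cells within the disc", {
  rec <- default_recovery()
  fl <- rec$field
  expect_equal(region_change(fl, fl, c(1000, 500))$d_growth, 0)
  expect_equal(region_change(fl, fl, c(1000, 500))$d_aniso, 0)
  # uniform offset fields
  fl2 <- fl
  fl2$growth_rate <- fl$growth_rate - 0.3
  rc <- region_change(fl2, fl, c(1000, 500))
  expect_equal(rc$d_growth, -0.3, tolerance = 1e-12)
  # manual 3-cell oracle at a 200 um disc around a cell centre
  ctr <- c(fl$center_pd[30], fl$center_ap[30])
  d <- sqrt((fl$center_pd - ctr[1])^2 + (fl$center_ap - ctr[2])^2)
  manual <- mean(fl2$growth_rate[d <= 200] - fl$growth_rate[d <= 200])
  expect_equal(region_change(fl2, fl, ctr)$d_growth, manual)
  # antisymmetry under swapping treated and control
  a <- region_change(fl2, fl, ctr); b <- region_change(fl, fl2, ctr)
  expect_equal(a$d_growth, -b$d_growth)
  expect_equal(a$d_aniso, -b$d_aniso)
  expect_error(region_change(fl, fl, c(1e6, 1e6)), class = "morphomapr_input")
})

test_that("affine anisotropy recovers the stretch of a small marker set", {
  # four markers mapped by diag(1.74, 1): the DiI-crystal statistic
  X <- rbind(c(0, 0), c(300, 0), c(300, 300), c(0, 300))
  x <- X %*% diag(c(1.74, 1))
  df <- tibble::tibble(X_pd = X[, 1], X_ap = X[, 2],
                       x_pd = x[, 1], x_ap = x[, 2])
  expect_equal(affine_anisotropy(df), 1.74, tolerance = 1e-10)
  # a rigid motion has anisotropy 1, and the statistic is invariant to
  # rigid motions of both point sets
  Q <- rot2(0.7)
  xr <- X %*% t(Q)
  expect_equal(affine_anisotropy(tibble::tibble(
    X_pd = X[, 1], X_ap = X[, 2], x_pd = xr[, 1], x_ap = xr[, 2])), 1,
    tolerance = 1e-9)
  Xr <- sweep(X %*% t(Q), 2, c(100, -50), `+`)
  xrr <- sweep(x %*% t(Q), 2, c(-20, 80), `+`)
  expect_equal(affine_anisotropy(tibble::tibble(
    X_pd = Xr[, 1], X_ap = Xr[, 2], x_pd = xrr[, 1], x_ap = xrr[, 2])),
    1.74, tolerance = 1e-9)
  # exactly three markers determine the affine map exactly
  A <- matrix(c(1.5, 0.2, -0.1, 0.9), 2, 2)
  X3 <- rbind(c(0, 0), c(200, 50), c(80, 260))
  x3 <- X3 %*% t(A) + 25
  a3 <- affine_anisotropy(tibble::tibble(X_pd = X3[, 1], X_ap = X3[, 2],
                                         x_pd = x3[, 1], x_ap = x3[, 2]))
  expect_equal(a3, anisotropy(A)$mag, tolerance = 1e-10)
  # collinear markers are unidentifiable
  Xc <- rbind(c(0, 0), c(100, 100), c(200, 200), c(300, 300))
  expect_error(affine_anisotropy(tibble::tibble(
    X_pd = Xc[, 1], X_ap = Xc[, 2], x_pd = Xc[, 1], x_ap = Xc[, 2])),
    class = "morphomapr_degenerate")
})

test_that("field TSV export carries the per-cell tensor columns", {
  rec <- default_recovery()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_field(rec$field, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_true(all(c("cell_i", "cell_j", "center_pd", "center_ap", "F11",
                    "F22", "growth_rate", "aniso_mag", "aniso_angle_deg")
                  %in% names(back)))
  expect_equal(back$growth_rate, rec$field$growth_rate, tolerance = 1e-9)
})
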