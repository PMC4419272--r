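# Coarse tissues (large target cell area) keep the descent cheap while
# leaving enough cells for collective behaviour.

test_that("hexagonal tiling fills simple outlines to high accuracy", {
  rect <- rbind(c(0, 0), c(1000, 0), c(1000, 500), c(0, 500))
  tis <- init_tissue(rect, 5000)
  areas <- tidy(tis)$area
  expect_gt(length(tis$cells), 75)
  expect_lt(length(tis$cells), 135)
  expect_equal(sum(areas), 5e5, tolerance = 0.01)

  th <- seq(0, 2 * pi, length.out = 60)[-60]
  circle <- cbind(500 * cos(th), 500 * sin(th))
  tis <- init_tissue(circle, 5000)
  expect_equal(sum(tidy(tis)$area), pi * 500^2, tolerance = 0.01)

  expect_error(init_tissue(rbind(c(0, 0), c(1, 0), c(2, 0)), 10),
               class = "morphomapr_degenerate")
})

test_that("the analytic energy gradient matches finite differences", {
  tis <- init_tissue(limb_outline(1200, 700), 20000)
  # perturb targets so the state is off-minimum
  set.seed(8)
  tis$target_area <- tis$target_area * runif(length(tis$cells), 0.8, 1.2)
  th <- runif(length(tis$cells), 0, pi)
  s1 <- sqrt(1.2); s2 <- sqrt(1 / 1.2)
  tis$target_shape[, "Txx"] <- tis$target_shape[, "Txx"] * runif(length(tis$cells), 0.9, 1.4)
  V <- tis$V
  g <- morphomapr:::tissue_gradient(V, tis)
  h <- 1e-5
  gscale <- max(abs(g))
  idx <- sample(nrow(V), 15)
  for (i in idx) {
    for (j in 1:2) {
      Vp <- V; Vp[i, j] <- Vp[i, j] + h
      Vm <- V; Vm[i, j] <- Vm[i, j] - h
      fd <- (morphomapr:::tissue_energy(Vp, tis) -
               morphomapr:::tissue_energy(Vm, tis)) / (2 * h)
      expect_lt(abs(g[i, j] - fd), 1e-5 * gscale)
    }
  }
})

test_that("a tissue at its targets is a fixed point", {
  tis <- init_tissue(limb_outline(1200, 700), 20000)
  st <- tissue_step(tis, 1, 1, 0)
  expect_lt(max(abs(st$V - tis$V)), 1e-9)
  expect_lt(attr(st, "energy"), 1e-12)
})

test_that("uniform isotropic growth scales the tissue self-similarly", {
  tis <- init_tissue(limb_outline(1500, 800), 15000)
  g <- 1.25
  tr <- run_scenario(tis, growth = g^3, aniso = 1, steps = 3)
  m <- tr$metrics
  # area multiplies by the prescribed factor each step, within 2%
  step_ratio <- m$total_area[-1] / m$total_area[-4]
  expect_true(all(abs(step_ratio - g) / g < 0.02))
  # outline shape similarity: aspect-ratio drift below 2% per step
  ar_drift <- abs(diff(m$aspect_ratio)) / m$aspect_ratio[-4]
  expect_true(all(ar_drift < 0.02))
})

test_that("uniform P-D anisotropy elongates the tissue monotonically", {
  tis <- init_tissue(limb_outline(1500, 800), 15000)
  tr <- run_scenario(tis, growth = 1.5, aniso = 1.3^10, theta = 0,
                     steps = 10, scenario = "WT")
  expect_true(all(diff(tr$metrics$aspect_ratio) > 0))
})

test_that("virtual mutants separate anisotropy from biased growth", {
  spec <- scenario_spec("distal_biased")
  gt <- ground_truth_map(spec)
  tis <- init_tissue(spec$domain, 20000)
  v1 <- run_scenario(tis, gt$detF, gt$aniso_mag, gt$aniso_theta,
                     steps = 3, scenario = "vMT_I")
  v2 <- run_scenario(tis, gt$detF, gt$aniso_mag, gt$aniso_theta,
                     steps = 3, scenario = "vMT_II")
  wt <- run_scenario(tis, gt$detF, gt$aniso_mag, gt$aniso_theta,
                     steps = 3, scenario = "WT")
  # aligned anisotropy, not biased growth, drives directional elongation
  expect_gt(tail(v2$metrics$aspect_ratio, 1), tail(v1$metrics$aspect_ratio, 1))
  expect_true(all(diff(v2$metrics$aspect_ratio) > 0))
  # the mean-growth construction conserves net prescribed growth
  expect_equal(tail(v2$metrics$total_area, 1), tail(wt$metrics$total_area, 1),
               tolerance = 0.03)
  # energy is relaxed at every recorded step
  expect_true(all(is.finite(wt$metrics$energy)))
  # zero steps returns the initial tissue
  tr0 <- run_scenario(tis, gt$detF, gt$aniso_mag, gt$aniso_theta, steps = 0)
  expect_equal(tr0$tissue$V, tis$V)
})

test_that("rotating the tissue and its fields rotates the trajectory", {
  out <- limb_outline(1200, 700)
  tis <- init_tissue(out, 25000)
  tr <- run_scenario(tis, growth = 1.4, aniso = 1.3, theta = 0, steps = 2)
  Q <- rot2(pi / 6)
  # same tiling rotated: rotate vertices and the target shape tensors
  tis_r <- tis
  tis_r$V <- tis$V %*% t(Q)
  Ts <- tis$target_shape
  rotT <- t(apply(Ts, 1, function(tt) {
    M <- Q %*% matrix(c(tt[1], tt[2], tt[2], tt[3]), 2, 2) %*% t(Q)
    c(M[1, 1], M[1, 2], M[2, 2])
  }))
  tis_r$target_shape <- cbind(Txx = rotT[, 1], Txy = rotT[, 2], Tyy = rotT[, 3])
  tr_r <- run_scenario(tis_r, growth = 1.4, aniso = 1.3, theta = pi / 6,
                       steps = 2)
  expect_lt(max(abs(tr_r$tissue$V - tr$tissue$V %*% t(Q))), 0.05)
})

test_that("boundary outline extraction returns a closed loop of used vertices", {
  tis <- init_tissue(limb_outline(1200, 700), 20000)
  o <- tissue_outline(tis)
  expect_gt(nrow(o), 8)
  expect_true(abs(morphomapr:::polygon_area(o)) > 0.9 * sum(tidy(tis)$area))
})
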