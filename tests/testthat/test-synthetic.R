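test_that("generators are reproducible given the spec", {
  spec <- scenario_spec("posterior_biased", seed = 11)
  a <- sample_landmarks(spec)
  b <- sample_landmarks(spec)
  expect_identical(a, b)
})

test_that("noise-free, jitter-free samples lie exactly on the ground-truth map", {
  spec <- scenario_spec("distal_biased", noise_sigma = 0,
                        jitter_translation = 0, jitter_rotation_deg = 0,
                        seed = 2)
  gt <- ground_truth_map(spec)
  lmk <- sample_landmarks(spec, gt)
  expect_equal(nrow(lmk), spec$n_embryos * spec$markers_per_embryo)
  mapped <- gt$phi(cbind(lmk$X_pd, lmk$X_ap))
  expect_lt(max(abs(mapped$pd - lmk$x_pd)), 1e-9)
  expect_lt(max(abs(mapped$ap - lmk$x_ap)), 1e-9)
})

test_that("marker displacement noise follows the half-normal mean", {
  spec <- scenario_spec("affine", noise_sigma = 20, n_embryos = 1,
                        markers_per_embryo = 4000,
                        jitter_translation = 0, jitter_rotation_deg = 0,
                        seed = 6)
  gt <- ground_truth_map(spec)
  lmk <- sample_landmarks(spec, gt)
  truth <- attr(lmk, "truth")
  d <- sqrt((lmk$x_pd - truth$x_pd)^2 + (lmk$x_ap - truth$x_ap)^2)
  # mean of a 2D isotropic Gaussian radius: sigma * sqrt(pi/2)
  expect_equal(mean(d), 20 * sqrt(pi / 2), tolerance = 0.03)
})

test_that("growth modes place their contrast where the mode says", {
  spec <- scenario_spec("distal_biased")
  gt <- ground_truth_map(spec)
  distal <- gt$detF(cbind(1900, 500))
  proximal <- gt$detF(cbind(100, 500))
  expect_equal(distal / proximal, spec$growth_contrast, tolerance = 1e-9)

  spec_p <- scenario_spec("posterior_biased")
  gt_p <- ground_truth_map(spec_p)
  expect_equal(gt_p$detF(cbind(1000, 990)) / gt_p$detF(cbind(1000, 10)),
               spec_p$growth_contrast, tolerance = 1e-9)

  spec_x <- scenario_spec("proximal_biased")
  gt_x <- ground_truth_map(spec_x)
  expect_equal(gt_x$detF(cbind(100, 500)) / gt_x$detF(cbind(1900, 500)),
               spec_x$growth_contrast, tolerance = 1e-9)

  # affine mode: constant growth and anisotropy everywhere
  spec_a <- scenario_spec("affine")
  gt_a <- ground_truth_map(spec_a)
  pts <- cbind(runif(20, 0, 2000), runif(20, 0, 1000))
  expect_true(all(abs(gt_a$detF(pts) - spec_a$base_growth) < 1e-12))
  expect_true(all(abs(gt_a$aniso_mag(pts) - spec_a$aniso) < 1e-12))

  expect_error(scenario_spec("distal_biased", growth_contrast = 0.5),
               class = "morphomapr_input")
})

test_that("the analytic map inverts and differentiates consistently", {
  spec <- scenario_spec("distal_biased")
  gt <- ground_truth_map(spec)
  set.seed(3)
  P <- cbind(runif(30, 0, 2000), runif(30, 0, 1000))
  fwd <- as.matrix(gt$phi(P))
  back <- as.matrix(gt$inverse(fwd))
  expect_lt(max(abs(back - P)), 1e-6)
  # closed-form F agrees with numerical differentiation of phi
  h <- 1e-4
  for (i in c(4, 17)) {
    Fnum <- cbind(
      (as.numeric(gt$phi(rbind(P[i, ] + c(h, 0)))) -
         as.numeric(gt$phi(rbind(P[i, ] - c(h, 0))))) / (2 * h),
      (as.numeric(gt$phi(rbind(P[i, ] + c(0, h)))) -
         as.numeric(gt$phi(rbind(P[i, ] - c(0, h))))) / (2 * h))
    expect_equal(gt$F_at(rbind(P[i, ]))[[1]], Fnum, tolerance = 1e-6)
    expect_equal(gt$detF(rbind(P[i, ])), det(Fnum), tolerance = 1e-6)
  }
})

test_that("velocity profiles depend on the camera frame, the gradient does not", {
  k <- 0.05; L0 <- 1000
  left <- velocity_profile(k, L0, "left")
  right <- velocity_profile(k, L0, "right")
  center <- velocity_profile(k, L0, "center")
  expect_equal(left$v[1], 0)
  expect_true(all(diff(left$v) > 0))                     # faster farther right
  expect_equal(right$v[nrow(right)], 0)
  expect_true(all(right$v[-nrow(right)] < 0))
  # centre frame: |v| maximal at the two ends
  expect_equal(which.max(abs(center$v[c(1, 51, 101)])) %in% c(1, 3), TRUE)
  expect_equal(max(abs(center$v)), k * L0 / 2)
  # identical velocity gradient k in every frame
  for (p in list(left, right, center)) {
    grads <- diff(p$v) / diff(p$x)
    expect_true(all(abs(grads - k) < 1e-12))
    expect_equal(attr(p, "velocity_gradient"), k)
  }
  expect_error(velocity_profile(-1, 10), class = "morphomapr_input")
})
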