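## Synthetic study generator.
##
## Emulates the dye-injection study design with known ground truth: an
## analytic, orientation-preserving deformation map over a paddle-shaped
## limb-bud domain, multi-embryo landmark samples with measurement noise and
## per-embryo rigid frame jitter, paired thickness fields with a controlled
## D-V/area growth correlation, and the camera-frame velocity demonstration.

#' Paddle-shaped limb-bud outline
#'
#' A capsule polygon (rectangle with a semicircular distal cap) echoing a
#' stage-22 hindlimb bud, proximal edge at pd = 0.
#'
#' @param length Total PD extent in um.
#' @param width AP extent in um.
#' @param n_arc Number of vertices on the distal cap.
#' @return Two-column matrix (pd, ap), counter-clockwise.
#' @export
limb_outline <- function(length = 2000, width = 1000, n_arc = 15) {
  r <- width / 2
  lr <- length - r
  th <- seq(-pi / 2, pi / 2, length.out = n_arc)
  cap <- cbind(lr + r * cos(th), r + r * sin(th))
  rbind(c(0, 0), cap, c(0, width))
}

#' Specify a synthetic deformation scenario
#'
#' Fixes the study conditions for one synthetic 12-h interval: the spatial
#' growth mode, growth scale and contrast, P-D-aligned anisotropy, marker
#' noise, and the sampling design (embryos x markers).
#'
#' @param mode Growth mode: `"distal_biased"`, `"posterior_biased"`,
#'   `"proximal_biased"` or `"affine"` (spatially uniform).
#' @param domain Reference outline polygon (two columns, um).
#' @param base_growth Baseline area growth factor (det F) per interval.
#' @param growth_contrast Max/min growth ratio across the domain (>= 1).
#' @param aniso P-D-aligned anisotropy magnitude (>= 1).
#' @param noise_sigma Marker measurement noise sd in um.
#' @param n_embryos,markers_per_embryo Sampling design.
#' @param jitter_translation Per-embryo frame translation sd (um).
#' @param jitter_rotation_deg Per-embryo frame rotation sd (degrees).
#' @param interval_id Label for the interval.
#' @param seed Integer seed; every generator output is reproducible given
#'   the spec.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(mode = c("distal_biased", "posterior_biased",
                                   "proximal_biased", "affine"),
                          domain = limb_outline(),
                          base_growth = 1.4, growth_contrast = 2,
                          aniso = 1.3, noise_sigma = 20,
                          n_embryos = 8, markers_per_embryo = 30,
                          jitter_translation = 25, jitter_rotation_deg = 2,
                          interval_id = "st22-23", seed = 7) {
  mode <- match.arg(mode)
  if (base_growth <= 0) abort("`base_growth` must be positive", class = "morphomapr_input")
  if (growth_contrast < 1) abort("`growth_contrast` must be >= 1", class = "morphomapr_input")
  if (aniso < 1) abort("`aniso` must be >= 1", class = "morphomapr_input")
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0", class = "morphomapr_input")
  structure(
    list(mode = mode, domain = as_pd_ap_matrix(domain),
         base_growth = base_growth, growth_contrast = growth_contrast,
         aniso = aniso, noise_sigma = noise_sigma,
         n_embryos = n_embryos, markers_per_embryo = markers_per_embryo,
         jitter_translation = jitter_translation,
         jitter_rotation_deg = jitter_rotation_deg,
         interval_id = interval_id, seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %s: growth %g (contrast %g), aniso %g, sigma %g um, %d embryos x %d markers, seed %d\n",
              x$mode, x$base_growth, x$growth_contrast, x$aniso,
              x$noise_sigma, x$n_embryos, x$markers_per_embryo, x$seed))
  invisible(x)
}

## Cosine-tapered rise from 0 to 1 over [t1, t2], C1 everywhere.
taper <- function(t, t1, t2) {
  s <- pmin(pmax((t - t1) / (t2 - t1), 0), 1)
  (1 - cos(pi * s)) / 2
}

## Closed-form antiderivative of taper() with taper(t1) as origin.
taper_int <- function(t, t1, t2) {
  w <- t2 - t1
  s <- pmin(pmax((t - t1) / w, 0), 1)
  core <- w * (s / 2 - sin(pi * s) / (2 * pi))
  core + pmax(t - t2, 0)
}

#' Analytic ground-truth deformation map of a scenario
#'
#' Constructs a separable, strictly monotone C1 map
#' `phi(X) = (phi_pd(X_pd), phi_ap(X_ap))` whose diagonal deformation
#' gradient realises the scenario's growth mode (cosine-tapered spatial
#' bump in det F) and its P-D-aligned anisotropy.  `det F` and the
#' anisotropy field are available in closed form everywhere.
#'
#' @param spec A `scenario_spec`.
#' @return An object of class `ground_truth_map`: a list of vectorised
#'   functions `phi(points)`, `inverse(points)`, `detF(points)`,
#'   `aniso_mag(points)`, `aniso_theta(points)` (axis angle in radians) and
#'   `F_at(points)` (list of 2x2 tensors).
#' @export
ground_truth_map <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  bb <- apply(spec$domain, 2, range)
  Lx <- bb[2, 1] - bb[1, 1]; Ly <- bb[2, 2] - bb[1, 2]
  g0 <- spec$base_growth; cg <- spec$growth_contrast; a <- spec$aniso
  sa <- sqrt(a)

  # growth modulation m(t) with int M(t), axis: "pd" or "ap"
  mk_mod <- function(t1, t2, rising) {
    if (rising) {
      list(m = function(t) 1 + (cg - 1) * taper(t, t1, t2),
           M = function(t) (t - t1) + (cg - 1) * taper_int(t, t1, t2))
    } else {
      list(m = function(t) cg - (cg - 1) * taper(t, t1, t2),
           M = function(t) cg * (t - t1) - (cg - 1) * taper_int(t, t1, t2))
    }
  }
  mode_axis <- switch(spec$mode,
    distal_biased = "pd", proximal_biased = "pd",
    posterior_biased = "ap", affine = "none")
  mod <- switch(spec$mode,
    distal_biased = mk_mod(bb[1, 1] + 0.4 * Lx, bb[1, 1] + 0.8 * Lx, TRUE),
    proximal_biased = mk_mod(bb[1, 1] + 0.2 * Lx, bb[1, 1] + 0.6 * Lx, FALSE),
    posterior_biased = mk_mod(bb[1, 2] + 0.4 * Ly, bb[1, 2] + 0.9 * Ly, TRUE),
    affine = list(m = function(t) rep(1, length(t)), M = function(t) t)
  )
  # diagonal F components as functions of (pd, ap)
  f11 <- function(P) {
    base <- sqrt(g0) * sa
    if (mode_axis == "pd") base * mod$m(P[, 1]) else rep(base, nrow(P))
  }
  f22 <- function(P) {
    base <- sqrt(g0) / sa
    if (mode_axis == "ap") base * mod$m(P[, 2]) else rep(base, nrow(P))
  }
  phi <- function(points) {
    P <- as_pd_ap_matrix(points)
    pd <- if (mode_axis == "pd") sqrt(g0) * sa * (mod$M(P[, 1]) - mod$M(bb[1, 1]))
          else sqrt(g0) * sa * (P[, 1] - bb[1, 1])
    ap <- if (mode_axis == "ap") sqrt(g0) / sa * (mod$M(P[, 2]) - mod$M(bb[1, 2]))
          else sqrt(g0) / sa * (P[, 2] - bb[1, 2])
    tibble::tibble(pd = pd + bb[1, 1], ap = ap + bb[1, 2])
  }
  inverse <- function(points) {
    P <- as_pd_ap_matrix(points)
    inv1 <- function(target, fwd, lo, hi) {
      vapply(target, function(v) {
        stats::uniroot(function(t) fwd(t) - v, lower = lo, upper = hi,
                       extendInt = "upX", tol = 1e-10)$root
      }, numeric(1))
    }
    fwd_pd <- function(t) phi(cbind(t, bb[1, 2]))$pd
    fwd_ap <- function(t) phi(cbind(bb[1, 1], t))$ap
    tibble::tibble(
      X_pd = inv1(P[, 1], fwd_pd, bb[1, 1] - 2 * Lx, bb[2, 1] + 2 * Lx),
      X_ap = inv1(P[, 2], fwd_ap, bb[1, 2] - 2 * Ly, bb[2, 2] + 2 * Ly)
    )
  }
  detF <- function(points) {
    P <- as_pd_ap_matrix(points)
    f11(P) * f22(P)
  }
  aniso_mag <- function(points) {
    P <- as_pd_ap_matrix(points)
    v1 <- f11(P); v2 <- f22(P)
    pmax(v1, v2) / pmin(v1, v2)
  }
  aniso_theta <- function(points) {
    P <- as_pd_ap_matrix(points)
    ifelse(f11(P) >= f22(P), 0, pi / 2)
  }
  F_at <- function(points) {
    P <- as_pd_ap_matrix(points)
    v1 <- f11(P); v2 <- f22(P)
    lapply(seq_len(nrow(P)), function(i) diag(c(v1[i], v2[i])))
  }
  probe <- phi(spec$domain)
  if (any(!is.finite(c(probe$pd, probe$ap))) || any(detF(spec$domain) <= 0)) {
    abort("scenario parameters yield a degenerate map (det F <= 0)",
          class = "morphomapr_degenerate")
  }
  structure(list(spec = spec, phi = phi, inverse = inverse, detF = detF,
                 aniso_mag = aniso_mag, aniso_theta = aniso_theta,
                 F_at = F_at, bbox = bb),
            class = "ground_truth_map")
}

#' Sample a multi-embryo landmark dataset from a scenario
#'
#' For each embryo, draws `markers_per_embryo` uniform positions inside the
#' domain, maps them through the ground-truth map, adds isotropic Gaussian
#' measurement noise, and applies an embryo-specific rigid frame jitter
#' (recorded, together with each embryo's jittered outline, so that
#' [register_embryos()] can be exercised).
#'
#' @param spec A `scenario_spec`.
#' @param gt Optional pre-built [ground_truth_map()] for `spec`.
#' @return A landmark tibble with attributes `"outlines"` (per-embryo
#'   outline polygons, corresponding vertex order), `"frames"` (the applied
#'   rigid jitters) and `"truth"` (noise-free canonical-frame positions).
#' @export
sample_landmarks <- function(spec, gt = ground_truth_map(spec)) {
  set.seed(spec$seed)
  bb <- gt$bbox
  dom <- rbind(spec$domain, spec$domain[1, ])
  draw_in_domain <- function(n) {
    out <- matrix(numeric(0), 0, 2)
    while (nrow(out) < n) {
      cand <- cbind(runif(4 * n, bb[1, 1], bb[2, 1]),
                    runif(4 * n, bb[1, 2], bb[2, 2]))
      out <- rbind(out, cand[mgcv::in.out(dom, cand), , drop = FALSE])
    }
    out[seq_len(n), , drop = FALSE]
  }
  ctr <- colMeans(spec$domain)
  rows <- list(); outl <- list(); frames <- list(); truth <- list()
  for (e in seq_len(spec$n_embryos)) {
    id <- sprintf("e%02d", e)
    X <- draw_in_domain(spec$markers_per_embryo)
    x_true <- as.matrix(phi_points(gt, X))
    x <- x_true + matrix(rnorm(2 * nrow(X), 0, spec$noise_sigma), ncol = 2)
    theta <- rnorm(1, 0, spec$jitter_rotation_deg * pi / 180)
    tr <- rnorm(2, 0, spec$jitter_translation)
    R <- rotation2(theta)
    jit <- function(P) sweep(sweep(P, 2, ctr) %*% t(R), 2, ctr + tr, `+`)
    Xr <- jit(X); xr <- jit(x)
    rows[[e]] <- tibble::tibble(
      embryo_id = id, interval_id = spec$interval_id,
      X_pd = Xr[, 1], X_ap = Xr[, 2], x_pd = xr[, 1], x_ap = xr[, 2])
    oj <- jit(spec$domain)
    outl[[e]] <- tibble::tibble(embryo_id = id,
                                vertex = seq_len(nrow(oj)),
                                pd = oj[, 1], ap = oj[, 2])
    frames[[e]] <- tibble::tibble(embryo_id = id, theta = theta,
                                  t_pd = tr[1], t_ap = tr[2])
    truth[[e]] <- tibble::tibble(embryo_id = id,
                                 X_pd = X[, 1], X_ap = X[, 2],
                                 x_pd = x_true[, 1], x_ap = x_true[, 2])
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "outlines") <- dplyr::bind_rows(outl)
  attr(out, "frames") <- dplyr::bind_rows(frames)
  attr(out, "truth") <- dplyr::bind_rows(truth)
  out
}

phi_points <- function(gt, P) gt$phi(P)

#' Paired thickness fields with a controlled D-V/area growth correlation
#'
#' Builds a before-field H over the reference domain and an after-field h
#' over the deformed domain such that the implied D-V growth
#' `h(phi(X))/H(X)` equals a known closed-form ratio field.  When
#' `target_correlation` is given, the ratio field is calibrated so that its
#' Pearson correlation with the area growth field `det F` over interior
#' calibration points equals the target exactly (the standardised
#' independent component is residualised against the growth field).
#'
#' @param spec A `scenario_spec`.
#' @param gt Optional pre-built ground-truth map.
#' @param grid_spacing Thickness grid spacing (um).
#' @param H0 Baseline D-V thickness (um).
#' @param base_dv Baseline D-V growth ratio.
#' @param amplitude Relative modulation amplitude of the ratio field.
#' @param target_correlation Desired correlation with det F, or `NULL` for
#'   an independent smooth pattern.
#' @return List with `H`, `h` (thickness_field objects), the closed-form
#'   `ratio` function of reference positions, and the calibration points.
#' @export
make_thickness_pair <- function(spec, gt = ground_truth_map(spec),
                                grid_spacing = 100, H0 = 200,
                                base_dv = 1.2, amplitude = 0.12,
                                target_correlation = NULL) {
  bb <- gt$bbox
  Lx <- bb[2, 1] - bb[1, 1]; Ly <- bb[2, 2] - bb[1, 2]
  H_fun <- function(P) H0 * (1 + 0.1 * cos(pi * (P[, 1] - bb[1, 1]) / Lx))
  w_fun <- function(P) sin(2 * pi * (P[, 2] - bb[1, 2]) / Ly) *
    cos(pi * (P[, 1] - bb[1, 1]) / Lx)
  # interior calibration points
  gx <- seq(bb[1, 1] + 0.05 * Lx, bb[2, 1] - 0.05 * Lx, length.out = 24)
  gy <- seq(bb[1, 2] + 0.05 * Ly, bb[2, 2] - 0.05 * Ly, length.out = 12)
  cal <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  cal <- cal[mgcv::in.out(rbind(spec$domain, spec$domain[1, ]), cal), , drop = FALSE]
  g_cal <- gt$detF(cal)
  if (is.null(target_correlation)) {
    ratio <- function(P) {
      P <- as_pd_ap_matrix(P)
      base_dv * (1 + amplitude * w_fun(P))
    }
  } else {
    rho <- target_correlation
    mu_g <- mean(g_cal); sd_g <- sd(g_cal)
    if (sd_g == 0) abort("det F is constant; cannot target a correlation",
                         class = "morphomapr_degenerate")
    w_cal <- w_fun(cal)
    co <- coef(lm(w_cal ~ g_cal))
    res_sd <- sd(w_cal - co[1] - co[2] * g_cal)
    ratio <- function(P) {
      P <- as_pd_ap_matrix(P)
      g <- gt$detF(P)
      gz <- (g - mu_g) / sd_g
      wz <- (w_fun(P) - co[1] - co[2] * g) / res_sd
      base_dv * (1 + amplitude * (rho * gz + sqrt(1 - rho^2) * wz))
    }
  }
  pad <- 2 * grid_spacing
  Hg <- grid_points(bb[1, ] - pad, bb[2, ] + pad, grid_spacing)
  H <- thickness_field(matrix(H_fun(Hg$P), Hg$nr, Hg$nc, byrow = TRUE),
                       origin = Hg$origin, spacing = grid_spacing,
                       frame = "before")
  dbb <- apply(as.matrix(gt$phi(spec$domain)), 2, range)
  hg <- grid_points(dbb[1, ] - pad, dbb[2, ] + pad, grid_spacing)
  Xh <- as.matrix(gt$inverse(hg$P))
  h_vals <- ratio(Xh) * H_fun(Xh)
  h <- thickness_field(matrix(h_vals, hg$nr, hg$nc, byrow = TRUE),
                       origin = hg$origin, spacing = grid_spacing,
                       frame = "after")
  list(H = H, h = h, ratio = ratio,
       calibration = tibble::tibble(pd = cal[, 1], ap = cal[, 2],
                                    detF = g_cal))
}

grid_points <- function(lo, hi, spacing) {
  pd <- seq(lo[1], hi[1], by = spacing)
  ap <- seq(lo[2], hi[2], by = spacing)
  list(P = cbind(rep(pd, times = length(ap)), rep(ap, each = length(pd))),
       nr = length(ap), nc = length(pd), origin = lo)
}

#' Camera-frame dependence of velocity in a uniformly growing tissue
#'
#' For one-dimensional tissue of initial length `L0` growing uniformly and
#' exponentially at rate `k`, the instantaneous velocity profile is
#' `v(x) = k (x - x_anchor)`, where the anchor is the point the camera is
#' fixed on: the left (proximal) end, the right (distal) end, or the centre.
#' The profiles differ between frames while the velocity gradient `dv/dx`
#' is `k` everywhere in every frame — only the gradient reflects tissue
#' deformation.
#'
#' @param k Growth rate per hour (> 0).
#' @param L0 Tissue length in um (> 0).
#' @param frame `"left"`, `"right"` or `"center"`.
#' @param n Number of sample positions.
#' @return Tibble with `x`, `v` and `frame`; attribute
#'   `"velocity_gradient"` holds the constant `dv/dx = k`.
#' @export
velocity_profile <- function(k, L0, frame = c("left", "right", "center"),
                             n = 101) {
  frame <- match.arg(frame)
  if (k <= 0 || L0 <= 0) abort("`k` and `L0` must be positive", class = "morphomapr_input")
  anchor <- switch(frame, left = 0, right = L0, center = L0 / 2)
  x <- seq(0, L0, length.out = n)
  out <- tibble::tibble(x = x, v = k * (x - anchor), frame = frame)
  attr(out, "velocity_gradient") <- k
  out
}

#' Synthetic dual-label counts for a known cell cycle
#'
#' Draws classified-cell counts (S-phase, left-S, other) multinomially from
#' the steady-state fractions `T_s/T_c` and `interval_h/T_c`.
#'
#' @param T_s,T_c True S-phase and cycle times (hours).
#' @param n_total Cells counted.
#' @param interval_h Hours between the two label pulses.
#' @param seed Integer seed.
#' @param region,stage Optional labels carried into the output.
#' @return A one-row counts tibble suitable for [cell_cycle_time()].
#' @export
make_dual_label_counts <- function(T_s, T_c, n_total, interval_h, seed = 1,
                                   region = "distal", stage = "st23") {
  if (T_c < T_s) abort("T_c must be >= T_s", class = "morphomapr_input")
  if (interval_h >= T_c - T_s) {
    warn("interval approaches T_c - T_s; leaving-fraction assumption strained")
  }
  set.seed(seed)
  p <- c(T_s / T_c, interval_h / T_c)
  draw <- stats::rmultinom(1, n_total, c(p, 1 - sum(p)))
  tibble::tibble(region = region, stage = stage, n_total = n_total,
                 n_s = draw[1], n_leaving = draw[2], interval_h = interval_h)
}
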