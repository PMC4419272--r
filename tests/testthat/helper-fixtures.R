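# Shared fixtures, built in code.  The default-scenario recovery experiment
# is memoised because several files probe different aspects of the same run.

.fixture_cache <- new.env(parent = emptyenv())

default_recovery <- function() {
  if (is.null(.fixture_cache$rec)) {
    spec <- scenario_spec("distal_biased")
    gt <- ground_truth_map(spec)
    lmk <- sample_landmarks(spec, gt)
    reg <- register_embryos(lmk, attr(lmk, "outlines"), reference = spec$domain)
    map <- estimate_map(reg)
    .fixture_cache$rec <- list(spec = spec, gt = gt, lmk = lmk, reg = reg,
                               map = map, field = compute_field(map))
  }
  .fixture_cache$rec
}

default_cv <- function() {
  if (is.null(.fixture_cache$cv)) {
    .fixture_cache$cv <- cross_validate(default_recovery()$reg)
  }
  .fixture_cache$cv
}

# random orientation-preserving 2x2 tensor
random_tensor <- function(max_tries = 50) {
  for (i in seq_len(max_tries)) {
    F <- matrix(rnorm(4), 2, 2)
    if (F[1, 1] * F[2, 2] - F[1, 2] * F[2, 1] > 0) return(F)
  }
  diag(2)
}

rot2 <- function(theta) matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)

# landmark table generated by an exact affine map x = A X + b
affine_landmarks <- function(A = matrix(c(1.3, 0.1, -0.05, 1.15), 2, 2),
                             b = c(30, -20), n = 20, seed = 1,
                             n_embryos = 2, sigma = 0) {
  set.seed(seed)
  X <- cbind(runif(n, 0, 1000), runif(n, 0, 500))
  x <- t(A %*% t(X) + b) + matrix(rnorm(2 * n, 0, sigma), ncol = 2)
  tibble::tibble(
    embryo_id = rep_len(sprintf("e%d", seq_len(n_embryos)), n),
    interval_id = "st22-23",
    X_pd = X[, 1], X_ap = X[, 2], x_pd = x[, 1], x_ap = x[, 2]
  )
}

# SVD construction of the polar decomposition: the independent oracle
svd_polar <- function(F) {
  sv <- svd(F)
  R <- sv$u %*% t(sv$v)
  U <- sv$v %*% diag(sv$d) %*% t(sv$v)
  list(R = R, U = U)
}
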