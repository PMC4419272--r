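## Dual-label (IddU then BrdU) pulse-chase cell-cycle estimation.
##
## Two thymidine analogues are given `interval` hours apart.  At fixation,
## cells positive for the second label are in S phase (n_s); cells positive
## for the first label only left S phase during the interval (n_leaving).
## Under steady-state asynchronous cycling the flux out of S is constant, so
##   T_s = interval * n_s / n_leaving        (S-phase duration)
##   T_c = T_s * n_total / n_s               (total cycle time)
## since the S-phase fraction n_s / n_total equals T_s / T_c.

#' Estimate S-phase and total cell-cycle time from dual-label counts
#'
#' @param counts A data frame with columns `n_total`, `n_s`, `n_leaving`,
#'   `interval_h` (hours between pulses); optional grouping columns such as
#'   `region` and `stage` are carried through.
#' @return The input tibble with `T_s` and `T_c` (hours) and the
#'   proliferation rate `1/T_c` (per hour) appended.
#' @examples
#' cell_cycle_time(tibble::tibble(n_total = 2000, n_s = 500,
#'                                n_leaving = 100, interval_h = 2))
#' @export
cell_cycle_time <- function(counts) {
  counts <- tibble::as_tibble(counts)
  need <- c("n_total", "n_s", "n_leaving", "interval_h")
  if (!all(need %in% names(counts))) {
    abort(paste("counts need columns:", paste(need, collapse = ", ")),
          class = "morphomapr_input")
  }
  with(counts, {
    if (any(interval_h <= 0)) abort("`interval_h` must be positive",
                                    class = "morphomapr_input")
    if (any(c(n_total, n_s, n_leaving) < 0)) {
      abort("counts must be non-negative", class = "morphomapr_input")
    }
    if (any(n_s + n_leaving > n_total)) {
      # tolerated (warning only) so algebraic boundary cases remain computable
      warn("n_s + n_leaving exceeds n_total; check the count classification")
    }
    if (any(n_s == 0)) abort("no S-phase cells (n_s = 0)", class = "morphomapr_degenerate")
    if (any(n_leaving == 0)) {
      abort("no cells left S phase (n_leaving = 0); interval too short to estimate",
            class = "morphomapr_degenerate")
    }
  })
  dplyr::mutate(
    counts,
    T_s = .data$interval_h * .data$n_s / .data$n_leaving,
    T_c = .data$T_s * .data$n_total / .data$n_s,
    proliferation_rate = 1 / .data$T_c
  )
}

#' Bootstrap confidence intervals for cell-cycle times
#'
#' Resamples the classified cells (S-phase / leaving / other) multinomially
#' within each row of `counts` and returns percentile intervals for `T_s`
#' and `T_c`.
#'
#' @inheritParams cell_cycle_time
#' @param n_boot Number of bootstrap replicates.
#' @param level Interval coverage (default 0.95).
#' @param seed Integer seed.
#' @return `cell_cycle_time(counts)` with columns `T_s_lo`, `T_s_hi`,
#'   `T_c_lo`, `T_c_hi` appended.
#' @export
cell_cycle_boot <- function(counts, n_boot = 1000, level = 0.95, seed = 1) {
  est <- cell_cycle_time(counts)
  set.seed(seed)
  p <- (1 - level) / 2
  ci <- purrr::map_dfr(seq_len(nrow(est)), function(i) {
    n <- est$n_total[i]
    probs <- c(est$n_s[i], est$n_leaving[i], n - est$n_s[i] - est$n_leaving[i]) / n
    draws <- stats::rmultinom(n_boot, n, probs)
    keep <- draws[1, ] > 0 & draws[2, ] > 0
    ts <- est$interval_h[i] * draws[1, keep] / draws[2, keep]
    tc <- ts * n / draws[1, keep]
    tibble::tibble(
      T_s_lo = quantile(ts, p, names = FALSE),
      T_s_hi = quantile(ts, 1 - p, names = FALSE),
      T_c_lo = quantile(tc, p, names = FALSE),
      T_c_hi = quantile(tc, 1 - p, names = FALSE)
    )
  })
  dplyr::bind_cols(est, ci)
}

#' Read dual-label counts (TSV)
#'
#' Columns `region stage n_total n_s n_leaving interval_h`.
#'
#' @param path File path.
#' @export
read_cell_counts <- function(path) {
  tibble::as_tibble(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}
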