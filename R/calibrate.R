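## Closed-form correlation structure of the generative model, and the
## calibration of its coupling parameters to target correlations.

## Gains implied by a completed boundary-BW table, pigs x periods.
boundary_gain_matrix <- function(boundary, schedule) {
  p <- schedule$periods
  pigs <- unique(boundary$pig_id)
  B <- matrix(NA_real_, length(pigs), nrow(p) + 1L)
  i <- match(boundary$pig_id, pigs)
  j <- match(boundary$day, c(p$start_day[1], p$end_day))
  ok <- !is.na(j)
  B[cbind(i[ok], j[ok])] <- boundary$bw_kg[ok]
  g <- (B[, -1, drop = FALSE] - B[, -ncol(B), drop = FALSE]) /
    rep(p$span, each = length(pigs))
  dimnames(g) <- list(pigs, p$label)
  g
}

#' Linear response of derived period gains to weighing errors
#'
#' The sequential boundary fill is affine in the measured body weights, so
#' a unit error on any single weighing propagates linearly into every
#' derived period gain. This returns that exact linear map, computed by
#' pushing unit errors through [estimate_boundary_bw()] itself.
#'
#' @param schedule an `hs_schedule`.
#' @return matrix (periods x BW days): entry `[k, d]` is the change of the
#'   period-`k` gain (kg/d) per kg of error on the day-`d` weighing.
#' @export
bwg_noise_map <- function(schedule) {
  days <- schedule$bw_days
  bw <- data.frame(
    pig_id = rep(paste0("u", seq_along(days)), each = length(days)),
    day = rep(days, times = length(days)),
    bw_kg = as.vector(diag(length(days))))
  g <- boundary_gain_matrix(estimate_boundary_bw(bw, schedule), schedule)
  ## rows of g are pigs u1..uK in sorted-unique order; restore day order
  g <- g[match(paste0("u", seq_along(days)), rownames(g)), , drop = FALSE]
  out <- t(g)
  colnames(out) <- days
  out
}

#' Implied trade-off and repeatability correlations of the generator
#'
#' Computes, in closed form, the population correlations among derived
#' phenotypes implied by a generator configuration: the per-cycle and
#' pooled (cycle-adjusted) correlation between TN-period gain and the
#' following cycle's gain drop, and the cycle-to-cycle repeatability of
#' the drop. The computation combines the latent linear model (animal +
#' litter TN-gain deviation, trade-off slope, persistent robustness,
#' transient HS noise) with the exact propagation of weighing error
#' through the boundary fill ([bwg_noise_map()]); it is the calibration
#' target function of [calibrate_tradeoff()] and is verified against
#' simulation in the package tests.
#'
#' @param config a [cohort_config()].
#' @param schedule an `hs_schedule`.
#' @return list: `pooled_r`, `cycle_r` (first-to-second cycle loss
#'   correlation), `per_cycle_r` (TN gain vs same-cycle loss, by cycle),
#'   `loss_cor` (loss correlation matrix), `gain_cov` (covariance of the
#'   derived period gains).
#' @export
implied_tradeoff_corr <- function(config, schedule = default_schedule()) {
  p <- schedule$periods
  nP <- nrow(p)
  hs_idx <- which(p$climate == "HS")
  nC <- length(hs_idx)
  if (nC < 1) stop("schedule has no HS period")
  hr <- config$hs_response

  u <- ifelse(p$climate == "HS", 1 + hr$tradeoff_slope, 1)
  v <- as.numeric(p$climate == "HS")
  sig_g2 <- config$animal_sd^2 + config$litter_sd^2
  C <- bwg_noise_map(schedule)
  S <- sig_g2 * tcrossprod(u) + hr$robustness_sd^2 * tcrossprod(v) +
    config$bw_measurement_sd^2 * tcrossprod(C)
  for (c in seq_len(nC)) {
    w <- numeric(nP); w[hs_idx[c]] <- 1
    S <- S + hr$residual_sd_bwg^2 * tcrossprod(w)
  }
  dimnames(S) <- list(p$label, p$label)

  tn_idx <- hs_idx - 1L
  A <- matrix(0, nC, nP)   # losses
  for (c in seq_len(nC)) {
    A[c, hs_idx[c]] <- 1
    A[c, tn_idx[c]] <- -1
  }
  T_ <- matrix(0, nC, nP)  # same-cycle TN gains
  for (c in seq_len(nC)) T_[c, tn_idx[c]] <- 1

  S_loss <- A %*% S %*% t(A)
  S_tn <- T_ %*% S %*% t(T_)
  S_cross <- T_ %*% S %*% t(A)   # cov(TN_c, Loss_c') at [c, c']

  per_cycle <- diag(S_cross) / sqrt(diag(S_tn) * diag(S_loss))
  pooled <- sum(diag(S_cross)) / sqrt(sum(diag(S_tn)) * sum(diag(S_loss)))
  loss_cor <- stats::cov2cor(S_loss)
  list(pooled_r = pooled,
       cycle_r = if (nC >= 2) loss_cor[1, 2] else NA_real_,
       per_cycle_r = per_cycle,
       loss_cor = loss_cor,
       gain_cov = S)
}

#' Calibrate the TN-performance / HS-robustness trade-off
#'
#' Chooses `tradeoff_slope`, `robustness_sd` and `residual_sd_bwg` so that
#' the implied pooled correlation between TN gain and the next cycle's
#' gain drop equals `target_pooled_r` and the implied first-to-second
#' cycle drop correlation equals `target_cycle_r`, using the closed-form
#' correlations of [implied_tradeoff_corr()]. One degree of freedom is
#' left over; it is resolved by keeping `residual_sd_bwg` close to its
#' incoming value.
#'
#' A zero target pair switches both coupling mechanisms off exactly
#' (`tradeoff_slope = 0`, `robustness_sd = 0`); with weighing error the
#' implied pooled correlation is then slightly negative (shared errors in
#' the boundary fill), which is the generative model's honest value.
#'
#' @param target_pooled_r,target_cycle_r target correlations in (-1, 1).
#' @param config a [cohort_config()] supplying all other parameters.
#' @param schedule an `hs_schedule`.
#' @param tol maximum acceptable absolute deviation from the targets.
#' @return the updated `cohort_config`.
#' @export
calibrate_tradeoff <- function(target_pooled_r, target_cycle_r,
                               config = cohort_config(),
                               schedule = default_schedule(),
                               tol = 1e-6) {
  if (abs(target_pooled_r) >= 1 || abs(target_cycle_r) >= 1)
    stop("targets must lie in (-1, 1)")
  if (target_pooled_r == 0 && target_cycle_r == 0) {
    config$hs_response$tradeoff_slope <- 0
    config$hs_response$robustness_sd <- 0
    return(config)
  }
  sde0 <- max(config$hs_response$residual_sd_bwg, 1e-3)
  obj <- function(par) {
    cfg <- config
    cfg$hs_response$tradeoff_slope <- par[1]
    cfg$hs_response$robustness_sd <- exp(par[2])
    cfg$hs_response$residual_sd_bwg <- exp(par[3])
    im <- implied_tradeoff_corr(cfg, schedule)
    (im$pooled_r - target_pooled_r)^2 + (im$cycle_r - target_cycle_r)^2 +
      1e-6 * (par[3] - log(sde0))^2
  }
  start <- c(config$hs_response$tradeoff_slope %||% -1,
             log(max(config$hs_response$robustness_sd, 1e-3)),
             log(sde0))
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  fit <- stats::optim(fit$par, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  cfg <- config
  cfg$hs_response$tradeoff_slope <- fit$par[1]
  cfg$hs_response$robustness_sd <- exp(fit$par[2])
  cfg$hs_response$residual_sd_bwg <- exp(fit$par[3])
  im <- implied_tradeoff_corr(cfg, schedule)
  err <- max(abs(im$pooled_r - target_pooled_r),
             abs(im$cycle_r - target_cycle_r))
  if (!is.finite(err) || err > tol)
    stop(sprintf(paste0("calibration error: no non-negative variance ",
                        "solution reaches the targets (residual %.2g)"), err))
  cfg
}
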