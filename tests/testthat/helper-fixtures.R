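## Shared fixtures: configurations and simulated repeated-measures data.

## all noise off, all coupling off: phenotypes must equal configured means
noiseless_config <- function(n_per_cell = 2) {
  cohort_config(
    n_per_cell = n_per_cell, litter_sd = 0, animal_sd = 0,
    rfi_animal_sd = 0, daily_fi_cv = 0, bw_measurement_sd = 0,
    lean_residual_sd = 0, hcw_sd = 0,
    hs_response = hs_response_params(tradeoff_slope = 0, robustness_sd = 0,
                                     residual_sd_bwg = 0,
                                     residual_sd_fi = 0,
                                     loss_bwg_line_effect = c(
                                       commercial = 0, lowRFI = 0,
                                       highRFI = 0)))
}

## calibrated study-condition cohort (n = 12 * n_per_cell pigs)
calibrated_config <- function(n_per_cell = 8) {
  calibrate_tradeoff(-0.70, 0.36, cohort_config(n_per_cell = n_per_cell))
}

## balanced repeated-measures data with known covariance structure
sim_repeated <- function(n_subj, T_, Sigma, beta = c(1, 0.5), seed = 1,
                         groups = 2) {
  set.seed(seed)
  subj <- rep(sprintf("s%04d", seq_len(n_subj)), each = T_)
  ord <- rep(seq_len(T_), n_subj)
  x <- stats::rnorm(n_subj * T_)
  grp <- factor(rep(rep(letters[seq_len(groups)], length.out = n_subj),
                    each = T_))
  E <- matrix(stats::rnorm(n_subj * T_), n_subj, T_) %*% chol(Sigma)
  y <- beta[1] + beta[2] * x + as.numeric(grp != "a") * 0.7 + as.vector(t(E))
  data.frame(y = y, x = x, grp = grp, subj = subj, ord = ord)
}

ar1_cov <- function(T_, sigma2 = 1, rho = 0.5)
  sigma2 * rho^abs(outer(seq_len(T_), seq_len(T_), "-"))

cs_cov <- function(T_, sigma2 = 1, rho = 0.4)
  sigma2 * ((1 - rho) * diag(T_) + rho)

## pooled TN-gain-vs-next-loss and first-to-second-cycle loss partial
## correlations, adjusted as in the study (line, diet, room; cycle for
## the pooled one), computed directly from derived tables
tradeoff_corrs <- function(der) {
  P <- der$phenotypes; L <- der$losses
  tn <- P[P$period %in% c("TN1", "TN2", "TN3"),
          c("pig_id", "period", "bwg")]
  tn$cycle <- sub("TN", "HS", tn$period)
  m <- merge(tn, L, by = c("pig_id", "cycle"))
  m$room <- factor(m$room)
  pooled <- partial_corr("bwg", "loss_bwg",
                         c("line", "diet", "room", "cycle"), m)$r
  w <- merge(L[L$cycle == "HS1", c("pig_id", "loss_bwg", "line", "diet",
                                   "room")],
             L[L$cycle == "HS2", c("pig_id", "loss_bwg")], by = "pig_id")
  w$room <- factor(w$room)
  cyc <- partial_corr("loss_bwg.x", "loss_bwg.y",
                      c("line", "diet", "room"), w)$r
  c(pooled = pooled, cycle = cyc)
}
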