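fast <- hslmm_control(n_starts = 1)

test_that("compound symmetry equals a random subject intercept", {
  d <- sim_repeated(40, 5, cs_cov(5, 1, 0.4), seed = 7)
  f_cs <- hslmm(y ~ x + grp, d, subject = "subj", order = "ord",
                structure = "cs", control = fast)
  f_ri <- hslmm(y ~ x + grp, d, subject = "subj", order = "ord",
                structure = "iid", random = "subj", control = fast)
  expect_lt(abs(f_cs$m2ll - f_ri$m2ll), 1e-6)
  expect_equal(f_cs$beta, f_ri$beta, tolerance = 1e-6)
})

test_that("AR1 with correlation pinned at zero is the IID model", {
  d <- sim_repeated(30, 4, ar1_cov(4, 1, 0.5), seed = 8)
  f_iid <- hslmm(y ~ x, d, subject = "subj", order = "ord",
                 structure = "iid", control = fast)
  f_ar0 <- hslmm(y ~ x, d, subject = "subj", order = "ord",
                 structure = "ar1", fix = list(rho = 0), control = fast)
  expect_lt(abs(f_ar0$m2ll - f_iid$m2ll), 1e-8)
})

test_that("spatial power on equally spaced times equals AR1", {
  d <- sim_repeated(35, 5, ar1_cov(5, 1.2, 0.45), seed = 9)
  f_ar <- hslmm(y ~ x, d, subject = "subj", order = "ord",
                structure = "ar1", control = fast)
  f_sp <- hslmm(y ~ x, d, subject = "subj", order = "ord",
                structure = "sppow", control = fast)
  expect_lt(abs(f_ar$m2ll - f_sp$m2ll), 1e-6)
})

test_that("the unstructured family dominates every nested structure", {
  d <- sim_repeated(45, 4, ar1_cov(4, 1, 0.4) + cs_cov(4, 0.3, 0.9),
                    seed = 10)
  fits <- lapply(c("iid", "cs", "ar1", "arh1", "toep", "un"), function(s)
    hslmm(y ~ x + grp, d, subject = "subj", order = "ord",
          structure = s, control = fast))
  un <- fits[[6]]
  for (f in fits[1:5]) {
    expect_lte(un$m2ll, f$m2ll + 1e-6)
    ## implied covariance is symmetric positive definite
    expect_equal(f$Sigma, t(f$Sigma))
    expect_gt(min(eigen(f$Sigma, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }
})

test_that("REML matches the reference implementation (nlme/lme4)", {
  skip_if_not_installed("nlme")
  skip_if_not_installed("lme4")
  d <- sim_repeated(40, 5, cs_cov(5, 1, 0.5), seed = 11)
  f_ar <- hslmm(y ~ x + grp, d, subject = "subj", order = "ord",
                structure = "ar1", control = fast)
  g <- nlme::gls(y ~ x + grp, d,
                 correlation = nlme::corAR1(form = ~ord | subj),
                 method = "REML")
  expect_equal(unname(f_ar$beta), unname(coef(g)), tolerance = 1e-5)
  expect_equal(tanh(f_ar$theta[["z_rho"]]),
               unname(coef(g$modelStruct$corStruct,
                           unconstrained = FALSE)), tolerance = 1e-4)
  expect_equal(f_ar$reml_loglik, as.numeric(logLik(g)), tolerance = 1e-5)
  f_ri <- hslmm(y ~ x + grp, d, subject = "subj", order = "ord",
                structure = "iid", random = "subj", control = fast)
  lm4 <- lme4::lmer(y ~ x + grp + (1 | subj), d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lm4))
  expect_equal(unname(f_ri$random_var), vc$vcov[1], tolerance = 1e-3)
  expect_equal(unname(f_ri$beta), unname(lme4::fixef(lm4)),
               tolerance = 1e-5)
})

test_that("an IID optimum reproduces ordinary least squares", {
  d <- sim_repeated(30, 3, diag(3), seed = 12)
  f <- hslmm(y ~ x + grp, d, subject = "subj", order = "ord",
             structure = "iid", control = fast)
  ols <- lm(y ~ x + grp, d)
  expect_equal(unname(f$beta), unname(coef(ols)), tolerance = 1e-8)
  ## single-column Wald F equals the squared OLS t statistic
  tt <- summary(ols)$coefficients["x", "t value"]
  expect_equal(f$anova$F[f$anova$term == "x"], tt^2, tolerance = 1e-6)
})

test_that("unstructured covariance is recovered from balanced data", {
  S <- matrix(c(1.0, 0.5, 0.2, 0.1,
                0.5, 1.3, 0.6, 0.3,
                0.2, 0.6, 0.9, 0.4,
                0.1, 0.3, 0.4, 1.1), 4, 4)
  d <- sim_repeated(500, 4, S, seed = 13)
  f <- hslmm(y ~ x + grp, d, subject = "subj", order = "ord",
             structure = "un", control = fast)
  expect_lt(norm(f$Sigma - S, "F") / norm(S, "F"), 0.10)
  ## GLS with the true covariance as closed-form oracle
  Xl <- model.matrix(y ~ x + grp, d)
  W <- kronecker(diag(500), solve(S))
  XtWX <- t(Xl) %*% W %*% Xl
  beta_or <- solve(XtWX, t(Xl) %*% W %*% d$y)[, 1]
  se_or <- sqrt(diag(solve(XtWX)))
  expect_lt(max(abs(f$beta - beta_or) / se_or), 2)
})

test_that("subjects with missing levels or one observation are handled", {
  d <- sim_repeated(30, 4, ar1_cov(4, 1, 0.5), seed = 14)
  drop <- c(which(d$subj == "s0001" & d$ord > 1),
            which(d$subj == "s0002" & d$ord %in% c(2, 4)))
  d2 <- d[-drop, ]
  f <- hslmm(y ~ x, d2, subject = "subj", order = "ord",
             structure = "ar1", control = fast)
  expect_true(f$converged)
  expect_equal(f$n_obs, nrow(d2))
  expect_equal(dim(f$Sigma), c(4, 4))
})

test_that("within-climate FCE on gain slopes and their contrast", {
  set.seed(15)
  ph <- data.frame(climate = rep(c("TN", "HS"), each = 60),
                   bwg = runif(120, 0.2, 1.2))
  ph$fce <- ifelse(ph$climate == "TN", 0.1 + 0.3 * ph$bwg,
                   0.05 + 0.5 * ph$bwg)
  s <- suppressWarnings(fce_bwg_slopes(ph))
  expect_equal(s$slopes$slope[s$slopes$climate == "TN"], 0.3,
               tolerance = 1e-10)
  expect_equal(s$slopes$slope[s$slopes$climate == "HS"], 0.5,
               tolerance = 1e-10)
  expect_equal(s$difference$estimate, 0.2, tolerance = 1e-10)
  ## OLS slope equals the covariance ratio oracle
  ph$fce <- ph$fce + rnorm(120, 0, 0.05)
  s2 <- fce_bwg_slopes(ph)
  tn <- ph[ph$climate == "TN", ]
  expect_equal(s2$slopes$slope[s2$slopes$climate == "TN"],
               cov(tn$fce, tn$bwg) / var(tn$bwg), tolerance = 1e-12)
  expect_error(fce_bwg_slopes(ph[1:2, ]), "fewer than 3")
})

test_that("heat stress steepens the efficiency-gain slope", {
  sch <- default_schedule()
  cfg <- calibrated_config(6)
  dir <- vapply(1:8, function(s) {
    ph <- derive_phenotypes(generate_cohort(cfg, sch, seed = 300 + s),
                            sch)$phenotypes
    sl <- fce_bwg_slopes(ph)$slopes
    sl$slope[sl$climate == "HS"] > sl$slope[sl$climate == "TN"]
  }, logical(1))
  expect_gte(sum(dir), 7)
})
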