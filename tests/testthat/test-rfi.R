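sch <- default_schedule()

make_tn_rows <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(pig_id = sprintf("p%03d", seq_len(n)), period = "TN1",
             climate = "TN",
             mbw = runif(n, 20, 32), bwg = runif(n, 0.4, 1.4),
             bft = runif(n, 10, 22))
}

test_that("the anchor regression matches the normal-equations oracle", {
  d <- make_tn_rows(50)
  d$fi <- 2.4 + 0.01 * d$mbw + 0.45 * d$bwg + 0.005 * d$bft +
    rnorm(50, 0, 0.2)
  fit <- rfi_fit(d)
  X <- cbind(1, d$mbw, d$bwg, d$bft)
  beta_or <- solve(t(X) %*% X, t(X) %*% d$fi)[, 1]
  expect_equal(unname(coef(fit)), unname(beta_or), tolerance = 1e-10)
  r <- d$fi - X %*% beta_or
  s2 <- sum(r^2) / (50 - 4)
  expect_equal(unname(vcov(fit)), unname(s2 * solve(t(X) %*% X)),
               tolerance = 1e-8)
  ## OLS identities: residuals sum to zero, orthogonal to each regressor
  expect_lt(abs(sum(residuals(fit))), 1e-10)
  for (j in 2:4) expect_lt(abs(sum(residuals(fit) * X[, j])), 1e-8)
})

test_that("noiseless gain-only intake recovers the printed truth exactly", {
  d <- make_tn_rows(40, seed = 2)
  d$fi <- 2.42 + 0.480 * d$bwg
  fit <- suppressWarnings(rfi_fit(d))
  expect_equal(coef(fit)[["b0"]], 2.42, tolerance = 1e-10)
  expect_equal(coef(fit)[["b2"]], 0.480, tolerance = 1e-10)
  expect_equal(coef(fit)[["b1"]], 0, tolerance = 1e-10)
  expect_equal(coef(fit)[["b3"]], 0, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)
})

test_that("RFI applied with TN coefficients reproduces TN residuals", {
  coh <- generate_cohort(cohort_config(n_per_cell = 3), sch, seed = 31)
  ph <- derive_phenotypes(coh, sch)$phenotypes
  fit <- rfi_fit(ph)
  ph2 <- apply_rfi(fit, ph)
  tn <- ph2[ph2$climate == "TN", ]
  expect_equal(unname(tn$rfi),
               unname(residuals(fit)[paste(tn$pig_id, tn$period,
                                           sep = ".")]),
               tolerance = 1e-12)
  ## mean TN RFI of the fitted cohort is exactly zero
  expect_lt(abs(mean(tn$rfi)), 1e-10)
  ## HS RFI is unconstrained (and negative here: intake drops more than
  ## its thermoneutral expectation)
  expect_lt(mean(ph2$rfi[ph2$climate == "HS"]), 0)
})

test_that("a constant intake shift moves only the intercept", {
  d <- make_tn_rows(30, seed = 3)
  d$fi <- 2.4 + 0.45 * d$bwg + rnorm(30, 0, 0.1)
  f1 <- rfi_fit(d)
  d2 <- d; d2$fi <- d$fi + 0.5
  f2 <- rfi_fit(d2)
  expect_equal(coef(f2)[["b0"]], coef(f1)[["b0"]] + 0.5,
               tolerance = 1e-10)
  expect_equal(coef(f2)[-1], coef(f1)[-1], tolerance = 1e-10)
  expect_equal(residuals(f2), residuals(f1), tolerance = 1e-10)
})

test_that("hand-computed RFI from fixed coefficients", {
  d <- make_tn_rows(10, seed = 4)
  d$fi <- 2.0 + 0.5 * d$bwg
  fit <- suppressWarnings(rfi_fit(d))   # recovers b0 = 2, b2 = 0.5 exactly
  row <- data.frame(pig_id = "z", period = "HS1", climate = "HS",
                    fi = 2.1, mbw = mean(d$mbw), bwg = 0.4,
                    bft = mean(d$bft))
  row$mbw <- 0; row$bft <- 0   # b1 = b3 = 0 so values are irrelevant
  out <- apply_rfi(fit, row)
  expect_equal(out$rfi, 2.1 - (2.0 + 0.5 * 0.4), tolerance = 1e-8)
})

test_that("degenerate designs raise a singular-fit error naming columns", {
  d <- make_tn_rows(20, seed = 5)
  d$fi <- 2 + 0.4 * d$bwg
  d$mbw <- 2 * d$bwg + 1   # collinear with bwg and the intercept
  expect_error(rfi_fit(d), "collinear")
  d2 <- make_tn_rows(20, seed = 6)
  d2$fi <- 2 + 0.4 * d2$bwg
  d2$bft <- 14
  expect_error(rfi_fit(d2), "fewer than 2 distinct")
})

test_that("residual growth mirrors the swapped regression", {
  d <- make_tn_rows(40, seed = 7)
  d$fi <- runif(40, 1.8, 3.4)
  d$bwg <- 0.3 + 0.2 * d$fi
  rg <- suppressWarnings(residual_growth(d))
  expect_equal(unname(rg$fit["fi", "Estimate"]), 0.2, tolerance = 1e-10)
  expect_lt(abs(sum(rg$phenotypes$residual_bwg)), 1e-10)
  ## calibrated cohort: commercial pigs out-grow their TN expectation and
  ## under-grow it in HS (their intake stays relatively high while gain
  ## collapses)
  coh <- generate_cohort(calibrated_config(6), sch, seed = 41)
  ph <- derive_phenotypes(coh, sch)$phenotypes
  rg2 <- residual_growth(ph)$phenotypes
  comm <- rg2[rg2$line == "commercial", ]
  expect_gt(mean(comm$residual_bwg[comm$climate == "TN"]), 0)
  expect_lt(mean(comm$residual_bwg[comm$climate == "HS"]), 0)
})

test_that("feed requirements recover constructed line x climate slopes", {
  coh <- generate_cohort(noiseless_config(4), sch, seed = 3)
  ph <- derive_phenotypes(coh, sch)$phenotypes
  ## overwrite intake with an exact linear model carrying the six slopes
  slopes <- c(commercial_TN = 0.18, lowRFI_TN = 0.25, highRFI_TN = 0.21,
              commercial_HS = 0.21, lowRFI_HS = 0.07, highRFI_HS = 0.07)
  ## give pigs distinct gains so the slopes are identifiable
  set.seed(9)
  ph$bwg <- ph$bwg + rnorm(nrow(ph), 0, 0.1)
  key <- paste(ph$line, ph$climate, sep = "_")
  ph$fi <- 1.95 + 0.69 * (ph$climate == "TN") +
    0.07 * (ph$diet == "high_fiber") + 0.16 * (ph$room == 1) -
    0.02 * ph$age_at_start + 0.006 * ph$mbw + 0.01 * ph$bft +
    slopes[key] * ph$bwg
  fr <- suppressWarnings(
    fit_feed_requirements(ph, control = hslmm_control(n_starts = 1)))
  got <- fr$slopes$estimate
  names(got) <- paste(fr$slopes$line, fr$slopes$climate, sep = "_")
  expect_equal(got[names(slopes)], slopes, tolerance = 1e-6)
  tab <- fr$table
  expect_equal(tab$estimate[tab$effect == "Intercept"], 1.95,
               tolerance = 1e-6)
  expect_equal(tab$estimate[tab$effect == "Climate" & tab$climate == "TN"],
               0.69, tolerance = 1e-6)
  ## reference rows are pinned at zero (HS, low fiber, highRFI, room 2)
  expect_equal(tab$estimate[tab$effect == "Climate" & tab$climate == "HS"], 0)
  expect_equal(tab$estimate[tab$effect == "Line" & tab$line == "highRFI"], 0)
})

test_that("anchor fit explains more intake variation in TN than in HS", {
  cfg <- calibrated_config(6)
  r2 <- vapply(1:20, function(s) {
    ph <- derive_phenotypes(generate_cohort(cfg, sch, seed = 200 + s),
                            sch)$phenotypes
    c(rfi_fit(ph, "TN")$r_squared, rfi_fit(ph, "HS")$r_squared)
  }, numeric(2))
  expect_gt(mean(r2[1, ]), mean(r2[2, ]))
})
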