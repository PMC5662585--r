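sch <- default_schedule()

test_that("identical configuration and seed give identical cohorts", {
  cfg <- cohort_config(n_per_cell = 3)
  a <- generate_cohort(cfg, sch, seed = 21)
  b <- generate_cohort(cfg, sch, seed = 21)
  for (nm in c("pigs", "bw", "daily_fi", "scans", "slaughter", "climate"))
    expect_identical(a[[nm]], b[[nm]])
  c2 <- generate_cohort(cfg, sch, seed = 22)
  expect_false(identical(a$bw$bw_kg, c2$bw$bw_kg))
})

test_that("adding pigs never perturbs existing pigs' draws", {
  small <- generate_cohort(cohort_config(n_per_cell = 2), sch, seed = 21)
  big <- generate_cohort(cohort_config(n_per_cell = 4), sch, seed = 21)
  common <- small$pigs$pig_id
  expect_true(all(common %in% big$pigs$pig_id))
  a <- small$bw[small$bw$pig_id %in% common, ]
  b <- big$bw[big$bw$pig_id %in% common, ]
  expect_equal(a[order(a$pig_id, a$day), "bw_kg"],
               b[order(b$pig_id, b$day), "bw_kg"])
})

test_that("the noiseless limit reproduces configured means exactly", {
  coh <- generate_cohort(noiseless_config(), sch, seed = 1)
  g <- coh$truth$gain
  means <- c(commercial = 1.22, lowRFI = 0.720, highRFI = 0.657)
  for (ln in names(means)) {
    rows <- coh$pigs$line == ln
    expect_equal(unique(g[rows, "TN1"]), means[[ln]])
    expect_equal(unique(g[rows, "HS2"]), means[[ln]] - 0.294,
                 tolerance = 1e-12)
  }
})

test_that("daily intake aggregates exactly to the period means", {
  coh <- generate_cohort(cohort_config(n_per_cell = 2), sch, seed = 3)
  ph <- derive_period_phenotypes(coh$bw, coh$daily_fi, coh$scans, sch)
  fi <- coh$daily_fi
  fi$period <- period_of_day(fi$day, sch)
  agg <- aggregate(fi_kg ~ pig_id + period, fi[!is.na(fi$period), ], sum)
  m <- merge(ph, agg, by.x = c("pig_id", "period"),
             by.y = c("pig_id", "period"))
  expect_equal(m$fi * m$span, m$fi_kg, tolerance = 1e-10)
})

test_that("intake deviations and lean noise match their configuration", {
  ## commercial-only cohort (singleton litters, so deviations are iid):
  ## 4 cells x 2500 = 10^4 pigs
  cfg <- cohort_config(n_per_cell = 2500,
                       lines = default_lines()[1], seed = 77)
  coh <- generate_cohort(cfg, sch)
  dev <- coh$truth$latent$rfi_dev
  n <- length(dev)
  ## true RFI deviations centre on zero
  expect_lt(abs(mean(dev)), 3 * sd(dev) / sqrt(n))
  ## slaughter lean equals the carcass equation plus configured noise
  b2 <- coh$scans$bft_mm[coh$scans$day == 52]
  resid <- coh$slaughter$lean_pct -
    pct_lean(b2, coh$slaughter$loind_mm)
  expect_equal(sd(resid), cfg$lean_residual_sd, tolerance = 0.1)
})

test_that("cycle-1 intake drop is calibrated to the study conditions", {
  cfg <- calibrated_config(n_per_cell = 8)
  m <- vapply(1:20, function(s) {
    der <- derive_phenotypes(generate_cohort(cfg, sch, seed = 100 + s), sch)
    mean(der$losses$loss_fi[der$losses$cycle == "HS1"])
  }, numeric(1))
  ## 3 SE of the 20-seed mean around the configured -0.662 kg/d
  expect_lt(abs(mean(m) + 0.662), 3 * sd(m) / sqrt(20))
})

test_that("infeasible intake configurations fail loudly", {
  bad <- cohort_config(n_per_cell = 1,
                       lines = list(line_params("lowRFI", 0.7, 0.01, 81,
                                                0, bft_mean = 18,
                                                n_litters = 2)),
                       rfi_animal_sd = 0,
                       hs_response = hs_response_params(
                         loss_fi_mean = c(-2, -2, -2),
                         loss_bwg_line_effect = c(lowRFI = 0)))
  expect_error(generate_cohort(bad, sch, seed = 1), "non-positive")
})

test_that("cohorts round-trip through the delimited-table layout", {
  coh <- generate_cohort(cohort_config(n_per_cell = 2), sch, seed = 8)
  d <- file.path(tempdir(), "cohort_rt")
  write_cohort(coh, d)
  back <- read_cohort(d)
  expect_equal(back$pigs, coh$pigs, ignore_attr = TRUE)
  expect_equal(back$bw$bw_kg, coh$bw$bw_kg, tolerance = 1e-12)
  expect_equal(back$slaughter$lean_pct, coh$slaughter$lean_pct,
               tolerance = 1e-12)
  unlink(d, recursive = TRUE)
})
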