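sch <- default_schedule()

test_that("sequential boundary fill reproduces hand arithmetic", {
  bw <- data.frame(pig_id = "p1", day = c(8, 19, 23),
                   bw_kg = c(60, 71, 73))
  b <- estimate_boundary_bw(bw, sch)
  expect_equal(b$bw_kg[b$day == 20], 72)                # 71 + 11/11
  expect_equal(b$bw_kg[b$day == 24], 73 + 1 / 3, tolerance = 1e-12)
  expect_equal((b$bw_kg[b$day == 24] - b$bw_kg[b$day == 20]) / 4,
               1 / 3, tolerance = 1e-12)
  ## and the HS1 gain equals the measured-interval rate algebraically
  expect_equal((b$bw_kg[b$day == 24] - b$bw_kg[b$day == 20]) / 4,
               (73 - b$bw_kg[b$day == 20]) / 3, tolerance = 1e-12)
})

test_that("the fill is exact on constant and linear trajectories", {
  days <- sch$bw_days
  flat <- data.frame(pig_id = "c", day = days, bw_kg = 80)
  b <- estimate_boundary_bw(flat, sch)
  expect_true(all(b$bw_kg == 80))
  lin <- data.frame(pig_id = "l", day = days, bw_kg = 50 + days)
  bl <- estimate_boundary_bw(lin, sch)
  expect_equal(bl$bw_kg, 50 + bl$day, tolerance = 1e-12)
})

test_that("a missing weighing excludes only the affected periods", {
  days <- setdiff(sch$bw_days, 30)   # lose the TN2-end weighing
  bw <- data.frame(pig_id = "m", day = days, bw_kg = 50 + days)
  b <- estimate_boundary_bw(bw, sch)
  expect_true(is.na(b$bw_kg[b$day == 31]))
  expect_false(anyNA(b$bw_kg[b$day %in% c(8, 20, 24)]))
  expect_false(anyNA(b$bw_kg[b$day %in% c(42, 46, 53)]))
})

test_that("derived phenotypes follow their definitions", {
  coh <- generate_cohort(noiseless_config(), sch, seed = 2)
  ph <- derive_period_phenotypes(coh$bw, coh$daily_fi, coh$scans, sch)
  ## metabolic BW definition
  expect_equal(unique(ph$mbw[ph$pig_id == ph$pig_id[1]]),
               ((coh$truth$boundary_bw[1, -1] +
                 coh$truth$boundary_bw[1, -8]) / 2)^0.75,
               ignore_attr = TRUE)
  expect_equal(16^0.75, 8)
  expect_equal(((59 + 63) / 2)^0.75, 61^0.75)
  ## FCE = BWG/FI exactly, FCR undefined at zero gain
  expect_equal(ph$fce, ph$bwg / ph$fi)
  ## BFT assignment rule: scan1 for first two periods, scan2 for last
  ## two, mean otherwise
  sc <- coh$scans
  p1 <- ph[ph$pig_id == sc$pig_id[1], ]
  b1 <- sc$bft_mm[sc$pig_id == sc$pig_id[1] & sc$day == 19]
  b2 <- sc$bft_mm[sc$pig_id == sc$pig_id[1] & sc$day == 52]
  expect_equal(p1$bft[p1$period %in% c("TN1", "HS1")], rep(b1, 2))
  expect_equal(p1$bft[p1$period %in% c("HS3", "TN4")], rep(b2, 2))
  expect_equal(p1$bft[p1$period %in% c("TN2", "HS2", "TN3")],
               rep((b1 + b2) / 2, 3))
})

test_that("negative gain gives negative FCE and undefined FCE at fi <= 0", {
  ph <- data.frame(pig_id = "x", period = "TN1", climate = "TN",
                   bwg = -0.2, fi = 2.0)
  expect_equal(-0.2 / 2.0, -0.1)
  coh <- generate_cohort(noiseless_config(), sch, seed = 4)
  fi0 <- coh$daily_fi
  fi0$fi_kg[fi0$pig_id == fi0$pig_id[1]] <- 0
  expect_warning(
    ph2 <- derive_period_phenotypes(coh$bw, fi0, coh$scans, sch),
    "non-positive FI")
  expect_true(all(is.na(ph2$fce[ph2$pig_id == fi0$pig_id[1]])))
})

test_that("one missing intake day is imputed, two are not", {
  coh <- generate_cohort(noiseless_config(), sch, seed = 5)
  pid <- coh$pigs$pig_id[1]
  fi <- coh$daily_fi
  full <- derive_period_phenotypes(coh$bw, fi, coh$scans, sch)
  fi1 <- fi[!(fi$pig_id == pid & fi$day == 25), ]         # 1 day of TN2
  ph1 <- derive_period_phenotypes(coh$bw, fi1, coh$scans, sch)
  expect_equal(ph1$fi[ph1$pig_id == pid & ph1$period == "TN2"],
               full$fi[full$pig_id == pid & full$period == "TN2"],
               tolerance = 1e-12)   # noiseless: mean unchanged
  fi2 <- fi[!(fi$pig_id == pid & fi$day %in% c(25, 26)), ]
  ph2 <- derive_period_phenotypes(coh$bw, fi2, coh$scans, sch)
  expect_true(is.na(ph2$fi[ph2$pig_id == pid & ph2$period == "TN2"]))
})

test_that("period gains telescope to the total weight change", {
  cfg <- cohort_config(n_per_cell = 2)
  coh <- generate_cohort(cfg, sch, seed = 9)
  b <- estimate_boundary_bw(coh$bw, sch)
  ph <- derive_period_phenotypes(b, coh$daily_fi, coh$scans, sch)
  for (pid in unique(ph$pig_id)) {
    tot <- sum(ph$bwg[ph$pig_id == pid] * ph$span[ph$pig_id == pid])
    expect_equal(tot, b$bw_kg[b$pig_id == pid & b$day == 53] -
                   b$bw_kg[b$pig_id == pid & b$day == 8],
                 tolerance = 1e-10)
  }
})

test_that("losses are TN-to-HS differences with drop sign convention", {
  ph <- data.frame(
    pig_id = rep(c("a", "b"), each = 4),
    period = rep(c("TN1", "HS1", "TN2", "HS2"), 2),
    climate = rep(c("TN", "HS"), 4),
    bwg = c(1.0, 0.5, 0.9, 0.9, 0.7, 0.7, 0.8, 0.6),
    fi = c(3, 2.5, 3, 3, 2, 2, 2.2, 1.9))
  l <- compute_losses(ph)
  expect_equal(l$loss_bwg[l$pig_id == "a" & l$cycle == "HS1"], -0.5)
  expect_equal(l$loss_bwg[l$pig_id == "a" & l$cycle == "HS2"], 0)
  expect_equal(l$loss_fi[l$pig_id == "b" & l$cycle == "HS2"],
               -0.3, tolerance = 1e-12)
  ## missing member drops the pair
  ph_miss <- ph[!(ph$pig_id == "a" & ph$period == "TN1"), ]
  ph_miss <- rbind(ph_miss,
                   data.frame(pig_id = "a", period = "TN1", climate = "TN",
                              bwg = NA, fi = NA))
  l2 <- suppressMessages(compute_losses(ph_miss))
  expect_equal(nrow(l2[l2$pig_id == "a" &
                         !is.na(l2$loss_bwg), ]), 1)
})

test_that("the carcass lean equation is linear with printed constants", {
  expect_identical(pct_lean(0, 0), 58.86)
  expect_equal(pct_lean(10, 50), 58.76)
  expect_equal(pct_lean(11, 50) - pct_lean(10, 50), -0.61)
  expect_equal(pct_lean(10, 51) - pct_lean(10, 50), 0.12)
  expect_error(pct_lean(-1, 10), "non-negative")
})

test_that("noiseless cohorts reproduce generator truth to machine precision", {
  coh <- generate_cohort(noiseless_config(), sch, seed = 11)
  der <- derive_phenotypes(coh, sch)
  ph <- der$phenotypes
  g <- coh$truth$gain
  idx <- cbind(match(ph$pig_id, rownames(g)), match(ph$period, colnames(g)))
  expect_equal(ph$bwg, g[idx], tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(ph$fi, coh$truth$fi[idx], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(ph$mbw, coh$truth$mbw[idx], tolerance = 1e-12,
               ignore_attr = TRUE)
  ## losses equal the configured cycle means exactly
  l <- der$losses
  expect_equal(unique(round(l$loss_bwg[l$cycle == "HS1"], 12)), -0.529)
  expect_equal(unique(round(l$loss_fi[l$cycle == "HS1"], 12)), -0.662)
  expect_equal(unique(round(l$loss_bwg[l$cycle == "HS3"], 12)), -0.245)
})
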