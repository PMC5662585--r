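#' Line-specific generator parameters
#'
#' Defaults emulate the study conditions the package is built around: a
#' fast-growing commercial line starting at 59 kg (SD 5.9) with TN gain
#' 1.22 kg/d and TN intake 3.22 kg/d, and two slower lines divergently
#' selected for residual feed intake starting at 81 kg (TN gains 0.720 and
#' 0.657 kg/d, TN intakes 2.63 and 2.77 kg/d). Backfat and loin-eye-area
#' means are first-scan values; `bft_gain`/`lea_gain` are the mean change
#' between the two scans. Commercial pigs are genetically unrelated and get
#' singleton litters (`n_litters = NA`).
#'
#' @param label line name.
#' @param bwg_tn_mean,fi_tn_mean TN-period gain and intake means, kg/d.
#' @param start_bw_mean,start_bw_sd day-1 body weight, kg.
#' @param bft_mean,bft_sd,bft_gain first-scan backfat (mm) and scan-to-scan
#'   gain.
#' @param lea_mean,lea_sd,lea_gain first-scan loin eye area (cm^2) and gain.
#' @param loind_mean,loind_sd slaughter loin depth (mm).
#' @param n_litters litters per line (`NA` = one litter per pig).
#' @return list of class `line_params`.
#' @export
line_params <- function(label, bwg_tn_mean, fi_tn_mean, start_bw_mean,
                        start_bw_sd, bft_mean, bft_sd = 2.5, bft_gain = 1,
                        lea_mean = 36, lea_sd = 3.5, lea_gain = 3,
                        loind_mean = 56, loind_sd = 3, n_litters = NA) {
  stopifnot(bwg_tn_mean > 0, fi_tn_mean > 0, start_bw_mean > 0)
  structure(list(label = label, bwg_tn_mean = bwg_tn_mean,
                 fi_tn_mean = fi_tn_mean, start_bw_mean = start_bw_mean,
                 start_bw_sd = start_bw_sd, bft_mean = bft_mean,
                 bft_sd = bft_sd, bft_gain = bft_gain, lea_mean = lea_mean,
                 lea_sd = lea_sd, lea_gain = lea_gain,
                 loind_mean = loind_mean, loind_sd = loind_sd,
                 n_litters = n_litters), class = "line_params")
}

#' @details `default_lines()` returns the three default lines
#'   (commercial, lowRFI, highRFI) with the study-condition means.
#' @rdname line_params
#' @export
default_lines <- function() list(
  line_params("commercial", 1.22, 3.22, 59, 5.9, bft_mean = 13.5,
              bft_gain = 0.5, lea_mean = 33.3, lea_gain = 4.9,
              loind_mean = 55.6, n_litters = NA),
  line_params("lowRFI", 0.720, 2.63, 81, 11.0, bft_mean = 17.6,
              bft_gain = 2.4, lea_mean = 36.6, lea_gain = 2.4,
              loind_mean = 59.0, n_litters = 13),
  line_params("highRFI", 0.657, 2.77, 81, 8.7, bft_mean = 19.3,
              bft_gain = 0.6, lea_mean = 37.3, lea_gain = 0.8,
              loind_mean = 54.8, n_litters = 10)
)

#' Heat-stress response parameters
#'
#' The per-pig HS gain in cycle `c` is
#' `tn_bwg_i + loss_bwg_mean[c] + tradeoff_slope * (tn_bwg_i - line mean)
#'  + robustness_i + eps_ic`:
#' a cycle fixed effect, a trade-off making TN-superior pigs drop more, a
#' persistent animal robustness effect (`robustness_i ~ N(0,
#' robustness_sd^2)`), and transient noise. The HS intake is the pig's
#' same-cycle TN intake plus `loss_fi_mean[c]` plus transient noise.
#' Cycle means default to the attenuating sequence observed under repeated
#' 4-day heat episodes (first cycle hits hardest); the coupling parameters
#' default to values calibrated so the pooled TN-gain vs next-cycle-loss
#' partial correlation is about -0.70 while cycle-to-cycle loss
#' repeatability stays near 0.36 (see [calibrate_tradeoff()]).
#'
#' @param loss_bwg_mean,loss_fi_mean per-cycle mean drops, kg/d (<= 0).
#' @param loss_bwg_line_effect named per-line deviations of the gain drop
#'   (mean ~ 0 across lines): fast lean lines drop hardest, so the lines'
#'   TN ranking compresses under HS. Adjusted away in the trade-off
#'   correlations (which correct for line).
#' @param tradeoff_slope (kg/d extra drop) per (kg/d TN gain above the
#'   line mean).
#' @param robustness_sd SD of the persistent animal-level HS effect, kg/d.
#' @param residual_sd_bwg,residual_sd_fi transient HS noise SDs, kg/d.
#' @return list of class `hs_response_params`.
#' @export
hs_response_params <- function(loss_bwg_mean = c(-0.529, -0.294, -0.245),
                               loss_fi_mean = c(-0.662, -0.506, -0.439),
                               loss_bwg_line_effect = c(commercial = -0.418,
                                                        lowRFI = 0.050,
                                                        highRFI = 0.368),
                               tradeoff_slope = -1.5,
                               robustness_sd = 0.05,
                               residual_sd_bwg = 0.21,
                               residual_sd_fi = 0.15) {
  stopifnot(all(loss_bwg_mean <= 0), all(loss_fi_mean <= 0),
            robustness_sd >= 0, residual_sd_bwg >= 0, residual_sd_fi >= 0)
  structure(list(loss_bwg_mean = loss_bwg_mean, loss_fi_mean = loss_fi_mean,
                 loss_bwg_line_effect = loss_bwg_line_effect,
                 tradeoff_slope = tradeoff_slope,
                 robustness_sd = robustness_sd,
                 residual_sd_bwg = residual_sd_bwg,
                 residual_sd_fi = residual_sd_fi),
            class = "hs_response_params")
}

#' Cohort generator configuration
#'
#' @param n_per_cell pigs per line x diet x room cell.
#' @param lines list of [line_params()].
#' @param hs_response an [hs_response_params()].
#' @param diet_fi_effect intake shift (kg/d) for high-fiber-fed pigs of the
#'   lines named in `diet_fi_lines`; no diet effect on gain or efficiency.
#' @param diet_fi_lines lines whose intake responds to the high-fiber diet.
#' @param litter_sd,animal_sd SDs of the litter and animal deviations of
#'   the latent TN gain, kg/d (litters also get an independent intake
#'   deviation with SD `litter_sd`).
#' @param rfi_animal_sd SD of the persistent animal intake deviation (the
#'   true residual feed intake), kg/d.
#' @param daily_fi_cv day-to-day lognormal CV of feed intake.
#' @param bw_measurement_sd weighing error SD, kg.
#' @param rfi_truth named vector `b0`, `b1`, `b2`, `b3` of the true TN
#'   feed-requirement coefficients (intercept kg/d; kg/d per kg^0.75; kg
#'   feed per kg gain; kg/d per mm backfat).
#' @param lean_residual_sd SD of slaughter lean percentage around the
#'   carcass lean equation, percentage points.
#' @param hcw_dressing,hcw_sd hot-carcass dressing fraction and noise SD.
#' @param mean_age,age_sd age at day 1 (d); commercial pigs are pinned at
#'   `mean_age`.
#' @param seed default master seed used by [generate_cohort()].
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_cell = 8,
                          lines = default_lines(),
                          hs_response = hs_response_params(),
                          diet_fi_effect = -0.26,
                          diet_fi_lines = "commercial",
                          litter_sd = 0.05,
                          animal_sd = 0.10,
                          rfi_animal_sd = 0.15,
                          daily_fi_cv = 0.10,
                          bw_measurement_sd = 0.5,
                          rfi_truth = c(b0 = 2.42, b1 = -0.01,
                                        b2 = 0.480, b3 = 0.00),
                          lean_residual_sd = 1.0,
                          hcw_dressing = 0.73, hcw_sd = 1.5,
                          mean_age = 147, age_sd = 7,
                          seed = 20170155L) {
  stopifnot(n_per_cell >= 1, litter_sd >= 0, animal_sd >= 0,
            rfi_animal_sd >= 0, daily_fi_cv >= 0, bw_measurement_sd >= 0,
            lean_residual_sd >= 0,
            all(c("b0", "b1", "b2", "b3") %in% names(rfi_truth)))
  structure(list(n_per_cell = n_per_cell, lines = lines,
                 hs_response = hs_response, diet_fi_effect = diet_fi_effect,
                 diet_fi_lines = diet_fi_lines, litter_sd = litter_sd,
                 animal_sd = animal_sd, rfi_animal_sd = rfi_animal_sd,
                 daily_fi_cv = daily_fi_cv,
                 bw_measurement_sd = bw_measurement_sd,
                 rfi_truth = rfi_truth, lean_residual_sd = lean_residual_sd,
                 hcw_dressing = hcw_dressing, hcw_sd = hcw_sd,
                 mean_age = mean_age, age_sd = age_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

## per-pig standard-normal draw layout (fixed so substreams are stable)
.pig_draw_names <- function(schedule) {
  nC <- sum(schedule$periods$climate == "HS")
  n_days <- schedule$periods$end_day[nrow(schedule$periods)] - 1L
  c("start_bw", "g", "robustness", "rfi_dev", "age",
    paste0("eps_bwg", seq_len(max(nC, 1))),
    paste0("eps_fi", seq_len(max(nC, 1))),
    "bft1", "bft2", "lea1", "lea2", "loind", "hcw", "lean",
    paste0("w", schedule$bw_days),
    paste0("d", seq_len(n_days)))
}

#' Generate a synthetic cohort
#'
#' Simulates a full cohort under the episodic TN/HS design: per-pig latent
#' TN gain (line mean + litter + animal deviations), piecewise-linear true
#' body weight with cycle-specific HS gain drops (see
#' [hs_response_params()]), noisy weighings at the scheduled BW days,
#' daily feed intake driven by the true TN feed-requirement coefficients
#' (`rfi_truth`) plus a persistent animal RFI deviation and lognormal
#' day-to-day noise, ultrasound scans, slaughter traits consistent with the
#' carcass lean equation, and a room climate log.
#'
#' All randomness flows from `seed` through named substreams (one per pig,
#' per litter, and per ancillary stage), so identical configurations are
#' byte-identical and adding pigs never perturbs existing ones.
#'
#' @param config a [cohort_config()].
#' @param schedule an [hs_schedule()].
#' @param seed master seed; defaults to `config$seed`.
#' @return list of class `hs_cohort`: `pigs`, `bw`, `daily_fi`, `scans`,
#'   `slaughter`, `climate`, and a `truth` list with the latent values and
#'   true per-period gains/intakes (for testing and calibration work).
#' @export
generate_cohort <- function(config, schedule = default_schedule(),
                            seed = config$seed) {
  p <- schedule$periods
  nP <- nrow(p)
  hs_idx <- which(p$climate == "HS")
  nC <- length(hs_idx)
  hr <- config$hs_response
  if (nC > length(hr$loss_bwg_mean))
    stop("hs_response has fewer cycle means than the schedule has HS periods")
  rt <- config$rfi_truth
  draw_names <- .pig_draw_names(schedule)
  n_days <- p$end_day[nP] - 1L

  ## ---- pig roster -------------------------------------------------------
  abbr <- c(commercial = "C", lowRFI = "L", highRFI = "H")
  ## pig ids and litter assignment depend only on (line, diet, room, k),
  ## never on n_per_cell, so growing a cohort preserves existing pigs
  roster <- do.call(rbind, lapply(config$lines, function(ln) {
    cells <- expand.grid(diet = c("low_fiber", "high_fiber"), room = c(1L, 2L),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    cells <- cells[order(cells$diet, cells$room), ]
    grid <- merge(cells, data.frame(k = seq_len(config$n_per_cell)))
    grid$cellpos <- match(paste(grid$diet, grid$room),
                          paste(cells$diet, cells$room))
    grid <- grid[order(grid$k, grid$cellpos), ]
    ab <- abbr[ln$label] %||% substr(ln$label, 1, 1)
    data.frame(pig_id = sprintf("%s_%s_R%d_%03d", ab,
                                ifelse(grid$diet == "low_fiber", "lf", "hf"),
                                grid$room, grid$k),
               line = ln$label, diet = grid$diet, room = grid$room,
               pig_index = (grid$k - 1L) * nrow(cells) + grid$cellpos,
               stringsAsFactors = FALSE)
  }))

  ## litters: round-robin by pig index within line; singleton when NA
  roster$litter_id <- NA_character_
  for (ln in config$lines) {
    sel <- roster$line == ln$label
    if (is.na(ln$n_litters)) {
      roster$litter_id[sel] <- paste0("lit_", roster$pig_id[sel])
    } else {
      roster$litter_id[sel] <- sprintf("lit_%s_%02d",
                                       abbr[ln$label] %||% ln$label,
                                       (roster$pig_index[sel] - 1L) %%
                                         ln$n_litters + 1L)
    }
  }

  ## ---- per-litter and per-pig draws ------------------------------------
  rs <- local_seed(seed)
  on.exit(rs())
  lit_ids <- unique(roster$litter_id)
  lit_eff <- matrix(0, length(lit_ids), 2,
                    dimnames = list(lit_ids, c("bwg", "fi")))
  for (l in lit_ids) {
    set.seed(substream_seed(seed, paste0("litter/", l)))
    lit_eff[l, ] <- stats::rnorm(2) * config$litter_sd
  }
  Z <- matrix(NA_real_, nrow(roster), length(draw_names),
              dimnames = list(roster$pig_id, draw_names))
  for (i in seq_len(nrow(roster))) {
    set.seed(substream_seed(seed, paste0("pig/", roster$pig_id[i])))
    Z[i, ] <- stats::rnorm(length(draw_names))
  }

  line_of <- match(roster$line, vapply(config$lines, `[[`, "", "label"))
  lp <- function(field) vapply(config$lines, `[[`, numeric(1), field)[line_of]

  start_bw <- lp("start_bw_mean") + Z[, "start_bw"] * lp("start_bw_sd")
  tn_bwg <- lp("bwg_tn_mean") + lit_eff[roster$litter_id, "bwg"] +
    Z[, "g"] * config$animal_sd
  robustness <- Z[, "robustness"] * hr$robustness_sd
  rfi_dev <- Z[, "rfi_dev"] * config$rfi_animal_sd +
    lit_eff[roster$litter_id, "fi"]
  age <- ifelse(roster$line == "commercial", config$mean_age,
                round(config$mean_age + Z[, "age"] * config$age_sd))

  ## ---- true per-period gains and boundary BW ---------------------------
  n <- nrow(roster)
  gain <- matrix(tn_bwg, n, nP)
  line_loss <- hr$loss_bwg_line_effect[roster$line]
  line_loss[is.na(line_loss)] <- 0
  for (c in seq_len(nC)) {
    k <- hs_idx[c]
    gain[, k] <- tn_bwg + hr$loss_bwg_mean[c] + line_loss +
      hr$tradeoff_slope * (tn_bwg - lp("bwg_tn_mean")) +
      robustness + Z[, paste0("eps_bwg", c)] * hr$residual_sd_bwg
  }
  bw8 <- start_bw + tn_bwg * (p$start_day[1] - schedule$adaptation_span[1])
  Btrue <- matrix(NA_real_, n, nP + 1L)
  Btrue[, 1] <- bw8
  for (k in seq_len(nP)) Btrue[, k + 1] <- Btrue[, k] + gain[, k] * p$span[k]
  mbw_true <- ((Btrue[, -1, drop = FALSE] +
                Btrue[, -(nP + 1), drop = FALSE]) / 2)^0.75

  ## measured BW at scheduled days (truth is piecewise linear)
  true_bw_at <- function(day) {
    out <- numeric(n)
    before <- day < p$start_day[1]
    out[before] <- (start_bw + tn_bwg * (day - schedule$adaptation_span[1]))[before]
    if (any(!before)) {
      k <- findInterval(day, p$start_day)
      out[!before] <- (Btrue[, k] + gain[, k] * (day - p$start_day[k]))[!before]
    }
    out
  }
  bw_tab <- do.call(rbind, lapply(schedule$bw_days, function(d)
    data.frame(pig_id = roster$pig_id, day = d,
               bw_kg = true_bw_at(d) +
                 Z[, paste0("w", d)] * config$bw_measurement_sd)))

  ## ---- scans and slaughter ---------------------------------------------
  bft1 <- pmax(2, lp("bft_mean") + Z[, "bft1"] * lp("bft_sd"))
  bft2 <- pmax(2, bft1 + lp("bft_gain") + Z[, "bft2"] * 0.8)
  lea1 <- pmax(15, lp("lea_mean") + Z[, "lea1"] * lp("lea_sd"))
  lea2 <- pmax(15, lea1 + lp("lea_gain") + Z[, "lea2"] * 1.2)
  scans <- rbind(
    data.frame(pig_id = roster$pig_id, day = schedule$scan_days[1],
               bft_mm = bft1, lea_cm2 = lea1),
    data.frame(pig_id = roster$pig_id, day = schedule$scan_days[2],
               bft_mm = bft2, lea_cm2 = lea2))
  bw_sl <- Btrue[, nP + 1] +
    gain[, nP] * (schedule$slaughter_day - p$end_day[nP])
  loind <- pmax(20, lp("loind_mean") + Z[, "loind"] * lp("loind_sd"))
  slaughter <- data.frame(
    pig_id = roster$pig_id,
    hcw_kg = config$hcw_dressing * bw_sl + Z[, "hcw"] * config$hcw_sd,
    loind_mm = loind,
    lean_pct = pct_lean(bft2, loind) + Z[, "lean"] * config$lean_residual_sd)

  ## ---- feed intake ------------------------------------------------------
  ## true BFT under the period assignment rule
  bft_assigned <- matrix(NA_real_, n, nP)
  for (k in seq_len(nP))
    bft_assigned[, k] <- if (k <= 2) bft1 else if (k >= nP - 1) bft2
                         else (bft1 + bft2) / 2
  ## line intake anchor: offset so mean TN intake hits fi_tn_mean
  mbw_ref <- vapply(config$lines, function(ln) {
    b8 <- ln$start_bw_mean + ln$bwg_tn_mean *
      (p$start_day[1] - schedule$adaptation_span[1])
    bnd <- b8
    m <- 0
    tn <- which(p$climate == "TN")
    mb <- numeric(nP)
    for (k in seq_len(nP)) {
      gk <- ln$bwg_tn_mean
      if (p$climate[k] == "HS") {
        c <- match(k, hs_idx)
        gk <- gk + hr$loss_bwg_mean[c] +
          (hr$loss_bwg_line_effect[ln$label] %|na|% 0)
      }
      nxt <- bnd + gk * p$span[k]
      mb[k] <- ((bnd + nxt) / 2)^0.75
      bnd <- nxt
    }
    mean(mb[tn])
  }, numeric(1))
  line_offset <- vapply(seq_along(config$lines), function(i) {
    ln <- config$lines[[i]]
    ln$fi_tn_mean - (rt["b0"] + rt["b1"] * mbw_ref[i] +
                     rt["b2"] * ln$bwg_tn_mean + rt["b3"] * ln$bft_mean)
  }, numeric(1))[line_of]
  diet_shift <- ifelse(roster$diet == "high_fiber" &
                         roster$line %in% config$diet_fi_lines,
                       config$diet_fi_effect, 0)

  fi_true <- matrix(NA_real_, n, nP)
  tn_of_cycle <- hs_idx - 1L   # TN period immediately preceding each HS
  for (k in seq_len(nP)) {
    if (p$climate[k] == "TN") {
      fi_true[, k] <- rt["b0"] + rt["b1"] * mbw_true[, k] +
        rt["b2"] * tn_bwg + rt["b3"] * bft_assigned[, k] +
        line_offset + diet_shift + rfi_dev
    }
  }
  for (c in seq_len(nC)) {
    k <- hs_idx[c]
    fi_true[, k] <- fi_true[, tn_of_cycle[c]] + hr$loss_fi_mean[c] +
      Z[, paste0("eps_fi", c)] * hr$residual_sd_fi
  }
  ## non-positive intakes: resample transient parts from fresh substreams
  attempt <- 0
  repeat {
    bad <- which(fi_true <= 0, arr.ind = TRUE)
    if (!nrow(bad)) break
    attempt <- attempt + 1
    if (attempt > 100) stop("generator error: feed intake stayed non-positive ",
                            "after 100 resampling attempts")
    for (r in seq_len(nrow(bad))) {
      i <- bad[r, 1]; k <- bad[r, 2]
      set.seed(substream_seed(seed, sprintf("resample/%s/%d/%d",
                                            roster$pig_id[i], k, attempt)))
      if (p$climate[k] == "HS") {
        c <- match(k, hs_idx)
        fi_true[i, k] <- fi_true[i, tn_of_cycle[c]] + hr$loss_fi_mean[c] +
          stats::rnorm(1) * hr$residual_sd_fi
      } else {
        fi_true[i, k] <- abs(fi_true[i, k]) + stats::runif(1, 0.05, 0.2)
      }
    }
  }

  sln <- sqrt(log(1 + config$daily_fi_cv^2))
  days <- seq_len(n_days)
  day_k <- findInterval(days, p$start_day)   # 0 => adaptation
  mu_day <- matrix(NA_real_, n, n_days)
  for (d in days)
    mu_day[, d] <- if (day_k[d] == 0) fi_true[, 1] else fi_true[, day_k[d]]
  noise <- exp(Z[, paste0("d", days), drop = FALSE] * sln - sln^2 / 2)
  fi_day <- mu_day * noise
  daily_fi <- data.frame(
    pig_id = rep(roster$pig_id, times = n_days),
    day = rep(days, each = n),
    fi_kg = as.vector(fi_day))

  pigs <- roster[c("pig_id", "line", "litter_id", "diet", "room")]
  pigs$age_at_start <- age
  structure(list(
    pigs = pigs,
    bw = bw_tab[order(match(bw_tab$pig_id, roster$pig_id), bw_tab$day), ],
    daily_fi = daily_fi,
    scans = scans[order(match(scans$pig_id, roster$pig_id), scans$day), ],
    slaughter = slaughter,
    climate = simulate_climate_log(schedule,
                                   substream_seed(seed, "climate")),
    truth = list(
      latent = data.frame(pig_id = roster$pig_id, tn_bwg = tn_bwg,
                          robustness = robustness, rfi_dev = rfi_dev),
      gain = `dimnames<-`(gain, list(roster$pig_id, p$label)),
      fi = `dimnames<-`(fi_true, list(roster$pig_id, p$label)),
      mbw = `dimnames<-`(mbw_true, list(roster$pig_id, p$label)),
      boundary_bw = Btrue),
    seed = as.integer(seed)
  ), class = "hs_cohort")
}

#' @export
print.hs_cohort <- function(x, ...) {
  cat("Synthetic TN/HS cohort:", nrow(x$pigs), "pigs,",
      length(unique(x$pigs$litter_id)), "litters, seed", x$seed, "\n")
  print(table(line = x$pigs$line, diet = x$pigs$diet))
  invisible(x)
}

#' Write / read a cohort as delimited tables
#'
#' Writes `pigs.csv`, `bw.csv`, `daily_fi.csv`, `scans.csv`,
#' `slaughter.csv` and `climate.csv` with fixed headers into `dir`.
#' `read_cohort` reads them back (without the generator truth).
#'
#' @param cohort an `hs_cohort` (or a compatible list of tables).
#' @param dir directory path (created if needed).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` a list of
#'   tables of class `hs_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("pigs", "bw", "daily_fi", "scans", "slaughter", "climate")) {
    if (!is.null(cohort[[nm]]))
      utils::write.csv(cohort[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  rd <- function(nm) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(f)) utils::read.csv(f, stringsAsFactors = FALSE) else NULL
  }
  structure(list(pigs = rd("pigs"), bw = rd("bw"), daily_fi = rd("daily_fi"),
                 scans = rd("scans"), slaughter = rd("slaughter"),
                 climate = rd("climate")), class = "hs_cohort")
}
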