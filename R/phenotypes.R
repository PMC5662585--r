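#' Complete body weights at period boundaries
#'
#' Body weight is weighed one day before each period boundary, so the BW at
#' each boundary day is estimated by a sequential forward fill: processed in
#' chronological order, the gain rate of the period ending at boundary `b`
#' is computed from the latest available BWs bracketing that period (the
#' already-completed start BW and the measurement one day before `b`), and
#' the boundary BW is the measurement plus one day of that rate. With the
#' default schedule this makes, e.g., `BW20 = BW19 + (BW19 - BW8)/11` and
#' the HS1 gain identically `(BW23 - BW20)/3`.
#'
#' A missing measurement leaves the affected boundary `NA` (the adjacent
#' periods are thereby excluded downstream) and the fill resumes from the
#' latest available anchor; the whole pig is never dropped.
#'
#' @param bw data frame with columns `pig_id`, `day`, `bw_kg`.
#' @param schedule an `hs_schedule`.
#' @return data frame with columns `pig_id`, `day`, `bw_kg`, `estimated`
#'   (TRUE for boundary days that were filled rather than weighed), one row
#'   per pig per boundary day (period starts and ends).
#' @examples
#' sch <- default_schedule()
#' bw <- data.frame(pig_id = "p1", day = c(1, 8, 19, 23, 30, 34, 41, 45, 52),
#'                  bw_kg = 60 + c(0, 7, 18, 22, 29, 33, 40, 44, 51))
#' estimate_boundary_bw(bw, sch)  # exact 1 kg/d line is preserved
#' @export
estimate_boundary_bw <- function(bw, schedule) {
  stopifnot(all(c("pig_id", "day", "bw_kg") %in% names(bw)))
  p <- schedule$periods
  bounds <- c(p$start_day[1], p$end_day)
  pigs <- unique(bw$pig_id)
  ## wide matrix of measured BW: pigs x bw_days
  W <- matrix(NA_real_, length(pigs), length(schedule$bw_days),
              dimnames = list(NULL, schedule$bw_days))
  i <- match(bw$pig_id, pigs)
  j <- match(bw$day, schedule$bw_days)
  ok <- !is.na(j)
  W[cbind(i[ok], j[ok])] <- bw$bw_kg[ok]

  B <- matrix(NA_real_, length(pigs), length(bounds),
              dimnames = list(NULL, bounds))
  meas_day <- vapply(bounds, function(b) {
    cand <- schedule$bw_days[abs(schedule$bw_days - b) <= 1]
    if (!length(cand)) NA_integer_ else as.integer(cand[which.max(cand)])
  }, integer(1))
  estim <- meas_day != bounds

  ## first boundary: measured on the day itself (or 1 before, then no rate
  ## is available yet and it stays NA until an anchor exists)
  anchor_day <- rep(NA_real_, length(pigs))
  anchor_val <- rep(NA_real_, length(pigs))
  first <- W[, as.character(meas_day[1])]
  if (!estim[1]) {
    B[, 1] <- first
    anchor_day <- ifelse(is.na(first), NA_real_, bounds[1])
    anchor_val <- first
  }
  for (k in 2:length(bounds)) {
    wk <- W[, as.character(meas_day[k])]
    have <- !is.na(wk) & !is.na(anchor_val) & (meas_day[k] > anchor_day)
    rate <- (wk - anchor_val) / (meas_day[k] - anchor_day)
    Bk <- wk + rate * (bounds[k] - meas_day[k])
    Bk[!have] <- NA_real_
    B[, k] <- Bk
    ## advance the anchor: completed boundary if available, else the raw
    ## measurement so later periods can still be bracketed
    adv <- !is.na(Bk)
    anchor_day[adv] <- bounds[k]
    anchor_val[adv] <- Bk[adv]
    raw_only <- !adv & !is.na(wk)
    anchor_day[raw_only] <- meas_day[k]
    anchor_val[raw_only] <- wk[raw_only]
  }
  out <- data.frame(
    pig_id = rep(pigs, times = length(bounds)),
    day = rep(bounds, each = length(pigs)),
    bw_kg = as.vector(B),
    estimated = rep(estim, each = length(pigs))
  )
  out <- out[order(match(out$pig_id, pigs), out$day), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive per-pig per-period phenotypes
#'
#' Computes, for every pig and period: average daily body weight gain
#' `bwg = (BW_end - BW_start)/span` (kg/d), average daily feed intake `fi`
#' over the period's days (kg/d), metabolic body weight
#' `mbw = ((BW_start + BW_end)/2)^0.75`, the assigned ultrasound backfat
#' `bft` (first scan for the first two periods, last scan for the final
#' two, the mean of both for the middle periods), feed conversion
#' efficiency `fce = bwg/fi` (negative gain gives negative FCE; FCE is
#' undefined when `fi <= 0`), and its inverse `fcr` (undefined at zero
#' gain). The `rfi` column is initialised to `NA` and filled by
#' [apply_rfi()].
#'
#' At most one missing feed-intake day per period is imputed by the period
#' mean; with more missing days the period's `fi` is `NA`.
#'
#' @param bw raw BW table (`pig_id`, `day`, `bw_kg`) or the output of
#'   [estimate_boundary_bw()].
#' @param daily_fi data frame `pig_id`, `day`, `fi_kg`.
#' @param scans data frame `pig_id`, `day`, `bft_mm` (and optionally
#'   `lea_cm2`).
#' @param schedule an `hs_schedule`.
#' @return data frame of class `period_phenotypes` with columns `pig_id`,
#'   `period`, `climate`, `span`, `bwg`, `fi`, `mbw`, `bft`, `fce`, `fcr`,
#'   `rfi`.
#' @export
derive_period_phenotypes <- function(bw, daily_fi, scans, schedule) {
  p <- schedule$periods
  boundary <- if ("estimated" %in% names(bw)) bw
              else estimate_boundary_bw(bw, schedule)
  pigs <- unique(boundary$pig_id)
  nP <- nrow(p)

  Bw <- matrix(NA_real_, length(pigs), nP + 1L)
  i <- match(boundary$pig_id, pigs)
  j <- match(boundary$day, c(p$start_day[1], p$end_day))
  ok <- !is.na(j)
  Bw[cbind(i[ok], j[ok])] <- boundary$bw_kg[ok]

  bwg <- (Bw[, -1, drop = FALSE] - Bw[, -(nP + 1), drop = FALSE]) /
    rep(p$span, each = length(pigs))
  mbw <- ((Bw[, -1, drop = FALSE] + Bw[, -(nP + 1), drop = FALSE]) / 2)^0.75

  ## period mean FI with <=1-day-per-period imputation by period mean
  day_period <- period_of_day(daily_fi$day, schedule)
  keep <- !is.na(day_period) & !is.na(daily_fi$fi_kg)
  g <- factor(paste(daily_fi$pig_id[keep], day_period[keep], sep = "\r"),
              levels = paste(rep(pigs, each = nP), rep(p$label, length(pigs)),
                             sep = "\r"))
  fi_sum <- rowsum(daily_fi$fi_kg[keep], g)[, 1]
  fi_n <- rowsum(rep(1, sum(keep)), g)[, 1]
  fi_sum[is.na(fi_sum)] <- 0; fi_n[is.na(fi_n)] <- 0
  span_full <- rep(p$span, length(pigs))
  fi_mean <- ifelse(fi_n >= span_full - 1 & fi_n > 0, fi_sum / fi_n, NA_real_)
  FI <- matrix(fi_mean, length(pigs), nP, byrow = TRUE)

  ## BFT assignment
  sc1 <- scans[scans$day == schedule$scan_days[1], ]
  sc2 <- scans[scans$day == schedule$scan_days[2], ]
  b1 <- sc1$bft_mm[match(pigs, sc1$pig_id)]
  b2 <- sc2$bft_mm[match(pigs, sc2$pig_id)]
  idx <- seq_len(nP)
  BFT <- matrix(NA_real_, length(pigs), nP)
  for (k in idx) {
    BFT[, k] <- if (k <= 2) b1
    else if (k >= nP - 1) b2
    else (b1 + b2) / 2
  }

  out <- data.frame(
    pig_id = rep(pigs, times = nP),
    period = rep(p$label, each = length(pigs)),
    climate = rep(p$climate, each = length(pigs)),
    span = rep(p$span, each = length(pigs)),
    bwg = as.vector(bwg),
    fi = as.vector(FI),
    mbw = as.vector(mbw),
    bft = as.vector(BFT)
  )
  bad_fi <- !is.na(out$fi) & out$fi <= 0
  if (any(bad_fi))
    warning(sprintf("%d pig-period(s) with non-positive FI: FCE undefined",
                    sum(bad_fi)))
  out$fce <- ifelse(bad_fi, NA_real_, out$bwg / out$fi)
  out$fcr <- ifelse(!is.na(out$bwg) & out$bwg == 0, NA_real_,
                    out$fi / out$bwg)
  out$rfi <- NA_real_
  out <- out[order(match(out$pig_id, pigs), match(out$period, p$label)), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("period_phenotypes", "data.frame")
  out
}

#' Within-pig drops of gain and intake from TN to the following HS period
#'
#' For each HS cycle `c`, `loss_bwg = bwg(HSc) - bwg(TNc)` and
#' `loss_fi = fi(HSc) - fi(TNc)`, where TNc is the TN period immediately
#' preceding HSc; negative values are drops. Pairs with a missing member
#' are omitted with a message.
#'
#' @param phenotypes output of [derive_period_phenotypes()].
#' @return data frame `pig_id`, `cycle` (HS1, HS2, ...), `loss_bwg`,
#'   `loss_fi`.
#' @export
compute_losses <- function(phenotypes) {
  ph <- phenotypes
  hs <- sort(unique(ph$period[ph$climate == "HS"]))
  out <- do.call(rbind, lapply(hs, function(h) {
    cyc <- as.integer(sub("HS", "", h))
    tn <- paste0("TN", cyc)
    a <- ph[ph$period == h, c("pig_id", "bwg", "fi")]
    b <- ph[ph$period == tn, c("pig_id", "bwg", "fi")]
    m <- merge(a, b, by = "pig_id", suffixes = c("_hs", "_tn"))
    data.frame(pig_id = m$pig_id, cycle = h,
               loss_bwg = m$bwg_hs - m$bwg_tn,
               loss_fi = m$fi_hs - m$fi_tn)
  }))
  drop <- is.na(out$loss_bwg) & is.na(out$loss_fi)
  if (any(drop))
    message(sprintf("omitting %d pig-cycle(s) with both losses missing",
                    sum(drop)))
  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Carcass lean percentage (Fat-O-Meater equation)
#'
#' `%Lean = 58.86 - 0.61 * BFT + 0.12 * LoinD`, with backfat thickness in
#' mm and loin depth in mm.
#'
#' @param bft backfat thickness, mm (>= 0).
#' @param loin_depth loin depth, mm (>= 0).
#' @return lean percentage.
#' @examples
#' pct_lean(0, 0)    # 58.86
#' pct_lean(10, 50)  # 58.76
#' @export
pct_lean <- function(bft, loin_depth) {
  if (any(bft < 0, na.rm = TRUE) || any(loin_depth < 0, na.rm = TRUE))
    stop("'bft' and 'loin_depth' must be non-negative")
  58.86 - 0.61 * bft + 0.12 * loin_depth
}

#' Adaptation-phase body weight gain
#'
#' Average gain over the adaptation days before the first period (days 1-8
#' by default). Exposed for descriptive use; it enters no model by default.
#'
#' @param bw raw BW table (`pig_id`, `day`, `bw_kg`).
#' @param schedule an `hs_schedule`.
#' @return data frame `pig_id`, `bwg_adapt`.
#' @export
adaptation_bwg <- function(bw, schedule) {
  a <- schedule$adaptation_span
  w1 <- bw[bw$day == a[1], c("pig_id", "bw_kg")]
  w2 <- bw[bw$day == a[2], c("pig_id", "bw_kg")]
  m <- merge(w1, w2, by = "pig_id", suffixes = c("_start", "_end"))
  data.frame(pig_id = m$pig_id,
             bwg_adapt = (m$bw_kg_end - m$bw_kg_start) / (a[2] - a[1]))
}

#' Derive the full phenotype bundle from a simulated or imported cohort
#'
#' Convenience wrapper: completes boundary BWs, derives period phenotypes
#' and TN-to-HS losses, and merges pig metadata (line, litter, diet, room,
#' age) onto both tables so they are ready for model fitting.
#'
#' @param cohort a list with elements `pigs`, `bw`, `daily_fi`, `scans`
#'   (as produced by [generate_cohort()] or [read_cohort()]).
#' @param schedule an `hs_schedule`.
#' @return list with elements `phenotypes` and `losses`.
#' @export
derive_phenotypes <- function(cohort, schedule) {
  ph <- derive_period_phenotypes(cohort$bw, cohort$daily_fi, cohort$scans,
                                 schedule)
  losses <- compute_losses(ph)
  meta <- cohort$pigs[c("pig_id", "line", "litter_id", "diet", "room",
                        "age_at_start")]
  ph <- merge(ph, meta, by = "pig_id", sort = FALSE)
  class(ph) <- c("period_phenotypes", "data.frame")
  losses <- merge(losses, meta, by = "pig_id", sort = FALSE)
  list(phenotypes = ph, losses = losses)
}
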