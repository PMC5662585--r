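#' Thermoneutral-anchored residual feed intake regression
#'
#' Fits, by ordinary least squares pooled over all TN pig-periods (periods
#' are unweighted, so 4-day and 7-day periods count equally), the
#' population feed-requirement relationship
#' \deqn{FI = b0 + b1 MBW + b2 BWG + b3 BFT + e,}
#' with intake and gain in kg/d, metabolic body weight in kg^0.75 and
#' backfat in mm. The residual `e` of a TN row is the pig's TN residual
#' feed intake; negative values mean the pig ate less than predicted from
#' its size, gain and fatness (more efficient than the population
#' average). Coefficients estimated in TN are subsequently applied to HS
#' rows by [apply_rfi()], so HS RFI measures intake relative to the
#' thermoneutral expectation.
#'
#' @param phenotypes a `period_phenotypes` data frame (see
#'   [derive_period_phenotypes()]); only rows with `climate == climate`
#'   argument enter the fit.
#' @param climate climate whose rows anchor the regression (default
#'   `"TN"`).
#' @return object of class `rfi_fit`: coefficients `b0..b3`, `vcov`,
#'   `r_squared`, `adj_r_squared`, `sigma`, `n_obs`, `residuals` (named by
#'   row), plus the `lm` machinery needed by `predict`.
#' @examples
#' ph <- data.frame(pig_id = letters[1:6], period = "TN1", climate = "TN",
#'                  mbw = c(20, 22, 24, 26, 28, 30),
#'                  bwg = c(.6, .8, 1, 1.1, .9, .7),
#'                  bft = c(12, 14, 13, 15, 16, 12))
#' ph$fi <- 2.42 + 0.48 * ph$bwg
#' coef(rfi_fit(ph))  # recovers b0 = 2.42, b2 = 0.48, b1 = b3 = 0
#' @export
rfi_fit <- function(phenotypes, climate = "TN") {
  d <- phenotypes[phenotypes$climate == climate &
                    stats::complete.cases(
                      phenotypes[c("fi", "mbw", "bwg", "bft")]), ]
  if (nrow(d) < 5) stop("need at least 5 complete ", climate, " rows")
  for (v in c("mbw", "bwg", "bft"))
    if (length(unique(d[[v]])) < 2)
      stop("covariate '", v, "' has fewer than 2 distinct values")
  X <- cbind(1, d$mbw, d$bwg, d$bft)
  colnames(X) <- c("b0", "b1", "b2", "b3")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)),
                               qx$pivot[seq_len(qx$rank)])]
    stop("singular fit: collinear column(s) ", paste(bad, collapse = ", "))
  }
  fit <- stats::lm(fi ~ mbw + bwg + bft, data = d)
  cf <- stats::setNames(stats::coef(fit), c("b0", "b1", "b2", "b3"))
  vc <- stats::vcov(fit)
  dimnames(vc) <- list(names(cf), names(cf))
  sm <- summary(fit)
  structure(list(
    coefficients = cf, vcov = vc,
    se = stats::setNames(sqrt(diag(vc)), names(cf)),
    r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
    sigma = sm$sigma, n_obs = nrow(d), climate = climate,
    residuals = stats::setNames(stats::resid(fit),
                                paste(d$pig_id, d$period, sep = ".")),
    lm = fit
  ), class = "rfi_fit")
}

#' @export
print.rfi_fit <- function(x, ...) {
  cat("Feed-requirement OLS anchored in", x$climate,
      sprintf("(n = %d pig-periods)\n", x$n_obs))
  tab <- cbind(estimate = x$coefficients, se = x$se)
  rownames(tab) <- c("intercept (kg/d)", "MBW (kg/d per kg^0.75)",
                     "BWG (kg feed per kg gain)", "BFT (kg/d per mm)")
  print(round(tab, 4))
  cat(sprintf("R2 = %.3f (adjusted %.3f), residual SD = %.3f kg/d\n",
              x$r_squared, x$adj_r_squared, x$sigma))
  invisible(x)
}

#' @export
coef.rfi_fit <- function(object, ...) object$coefficients

#' @export
vcov.rfi_fit <- function(object, ...) object$vcov

#' @export
residuals.rfi_fit <- function(object, ...) object$residuals

#' @export
summary.rfi_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @describeIn rfi_fit predicted feed intake for new pig-period rows
#'   (columns `mbw`, `bwg`, `bft`).
#' @param object an `rfi_fit`.
#' @param newdata data frame of pig-period rows.
#' @param ... unused.
#' @export
predict.rfi_fit <- function(object, newdata, ...) {
  b <- object$coefficients
  b[["b0"]] + b[["b1"]] * newdata$mbw + b[["b2"]] * newdata$bwg +
    b[["b3"]] * newdata$bft
}

#' Fill per-period RFI from the thermoneutral anchor fit
#'
#' Computes `rfi = fi - (b0 + b1 mbw + b2 bwg + b3 bft)` for every row
#' (TN and HS) using the TN-estimated coefficients. On the TN rows that
#' entered the fit this reproduces the OLS residuals exactly, so the mean
#' TN RFI of the fitted cohort is 0; HS RFI is unconstrained and measures
#' intake below/above the thermoneutral expectation for the pig's HS-period
#' size, gain and fatness. Rows with missing backfat (or other inputs) are
#' skipped with a message and keep `rfi = NA`.
#'
#' @param fit an [rfi_fit()].
#' @param phenotypes a `period_phenotypes` data frame.
#' @return `phenotypes` with the `rfi` column filled.
#' @export
apply_rfi <- function(fit, phenotypes) {
  need <- c("fi", "mbw", "bwg", "bft")
  ok <- stats::complete.cases(phenotypes[need])
  if (any(!ok))
    message("apply_rfi: skipping ", sum(!ok),
            " row(s) with missing inputs")
  phenotypes$rfi <- NA_real_
  phenotypes$rfi[ok] <- phenotypes$fi[ok] -
    predict(fit, phenotypes[ok, , drop = FALSE])
  phenotypes
}

#' Residual growth: the anchor regression with intake and gain swapped
#'
#' OLS of BWG on `{1, MBW, FI, BFT}` over the TN rows; residuals are
#' reported for all rows (TN coefficients applied to HS rows), giving a
#' "growth relative to thermoneutral expectation" measure: pigs robust to
#' heat grow more than expected from their depressed HS intake.
#'
#' @param phenotypes a `period_phenotypes` data frame.
#' @return list: `fit` (lm-style coefficient summary), `phenotypes` (input
#'   with a `residual_bwg` column).
#' @export
residual_growth <- function(phenotypes) {
  d <- phenotypes[phenotypes$climate == "TN" &
                    stats::complete.cases(
                      phenotypes[c("fi", "mbw", "bwg", "bft")]), ]
  if (nrow(d) < 5) stop("need at least 5 complete TN rows")
  fit <- stats::lm(bwg ~ mbw + fi + bft, data = d)
  cf <- stats::coef(fit)
  ok <- stats::complete.cases(phenotypes[c("fi", "mbw", "bwg", "bft")])
  phenotypes$residual_bwg <- NA_real_
  phenotypes$residual_bwg[ok] <- phenotypes$bwg[ok] -
    (cf[[1]] + cf[["mbw"]] * phenotypes$mbw[ok] +
       cf[["fi"]] * phenotypes$fi[ok] + cf[["bft"]] * phenotypes$bft[ok])
  list(fit = summary(fit)$coefficients, phenotypes = phenotypes)
}

#' Line- and climate-specific feed requirements for gain
#'
#' Mixed model for per-period feed intake over all TN and HS pig-periods:
#' fixed effects of line, climate, diet, room, the age and metabolic-BW
#' and backfat covariates, and a separate BWG slope for every line x
#' climate cell; random litter intercept (litters are nested in line by
#' construction of the litter identifiers); independent residuals.
#' Reference levels are HS, low fiber, highRFI and room 2, so the
#' reported contrasts are "TN", "high fiber", "commercial", "lowRFI" and
#' "room 1" against zero reference rows.
#'
#' @param phenotypes a `period_phenotypes` data frame; if it lacks the
#'   pig metadata columns, supply `pigs` to merge them.
#' @param pigs optional pig metadata (`pig_id`, `line`, `litter_id`,
#'   `diet`, `room`, `age_at_start`).
#' @param control a [hslmm_control()].
#' @return list of class `feed_requirements`: `table` (effect-layout data
#'   frame with estimates, SEs and zero reference rows), `slopes` (the six
#'   line x climate BWG slopes), `fit` (the underlying `hslmm`).
#' @export
fit_feed_requirements <- function(phenotypes, pigs = NULL,
                                  control = hslmm_control()) {
  d <- as.data.frame(phenotypes)
  if (!is.null(pigs))
    d <- merge(d, pigs, by = "pig_id", sort = FALSE,
               suffixes = c("", ".pig"))
  need <- c("line", "litter_id", "diet", "room", "age_at_start")
  if (!all(need %in% names(d)))
    stop("phenotypes lack metadata columns; supply 'pigs'")
  d <- d[stats::complete.cases(d[c("fi", "bwg", "mbw", "bft",
                                   "age_at_start")]), ]
  d$line <- factor(d$line)
  if ("highRFI" %in% levels(d$line))
    d$line <- stats::relevel(d$line, "highRFI")
  d$climate <- factor(d$climate, levels = c("HS", "TN"))
  d$diet <- factor(d$diet)
  if ("low_fiber" %in% levels(d$diet))
    d$diet <- stats::relevel(d$diet, "low_fiber")
  d$room <- factor(d$room, levels = rev(sort(unique(d$room))))
  d$period_idx <- as.integer(factor(d$period))

  fit <- hslmm(fi ~ line + climate + diet + room + age_at_start + mbw +
                 bft + line:climate:bwg,
               d, subject = "pig_id", order = "period_idx",
               structure = "iid", random = "litter_id", control = control)
  cf <- fit$beta
  se <- sqrt(diag(fit$vcov))

  grab <- function(pattern) {
    i <- grep(pattern, names(cf))
    if (length(i) != 1) c(NA_real_, NA_real_) else c(cf[i], se[i])
  }
  lines_nonref <- setdiff(levels(d$line), levels(d$line)[1])
  rows <- list(
    c(effect = "Intercept", climate = "", diet = "", line = "", room = ""))
  tab <- data.frame(effect = "Intercept", climate = "", diet = "",
                    line = "", room = "", estimate = cf[["(Intercept)"]],
                    se = se[["(Intercept)"]])
  add <- function(tab, effect, climate = "", diet = "", line = "",
                  room = "", est = NA_real_, s = NA_real_)
    rbind(tab, data.frame(effect = effect, climate = climate, diet = diet,
                          line = line, room = room, estimate = est, se = s))
  g <- grab("^climateTN$")
  tab <- add(tab, "Climate", climate = "TN", est = g[1], s = g[2])
  tab <- add(tab, "Climate", climate = "HS", est = 0, s = NA)
  for (dl in setdiff(levels(d$diet), "low_fiber")) {
    g <- grab(paste0("^diet", dl, "$"))
    tab <- add(tab, "Diet", diet = dl, est = g[1], s = g[2])
  }
  tab <- add(tab, "Diet", diet = "low_fiber", est = 0, s = NA)
  for (ln in lines_nonref) {
    g <- grab(paste0("^line", ln, "$"))
    tab <- add(tab, "Line", line = ln, est = g[1], s = g[2])
  }
  tab <- add(tab, "Line", line = levels(d$line)[1], est = 0, s = NA)
  g <- grab(paste0("^room", levels(d$room)[2], "$"))
  tab <- add(tab, "Room", room = levels(d$room)[2], est = g[1], s = g[2])
  tab <- add(tab, "Room", room = levels(d$room)[1], est = 0, s = NA)
  g <- grab("^age_at_start$")
  tab <- add(tab, "Age", est = g[1], s = g[2])
  g <- grab("^mbw$")
  tab <- add(tab, "MBW", est = g[1], s = g[2])
  slopes <- do.call(rbind, lapply(levels(d$line), function(ln)
    do.call(rbind, lapply(c("TN", "HS"), function(cl) {
      nm <- paste0("line", ln, ":climate", cl, ":bwg")
      i <- match(nm, names(cf))
      data.frame(climate = cl, line = ln,
                 estimate = if (is.na(i)) NA_real_ else cf[i],
                 se = if (is.na(i)) NA_real_ else se[i])
    }))))
  slopes <- slopes[order(slopes$climate == "HS", slopes$line), ]
  rownames(slopes) <- NULL
  for (i in seq_len(nrow(slopes)))
    tab <- add(tab, "BWG x C x L", climate = slopes$climate[i],
               line = slopes$line[i], est = slopes$estimate[i],
               s = slopes$se[i])
  g <- grab("^bft$")
  tab <- add(tab, "BackFat", est = g[1], s = g[2])
  rownames(tab) <- NULL
  structure(list(table = tab, slopes = slopes, fit = fit),
            class = "feed_requirements")
}

#' @export
print.feed_requirements <- function(x, ...) {
  cat("Feed requirements for gain (intake model over TN and HS periods)\n")
  t2 <- x$table
  t2$estimate <- round(t2$estimate, 3)
  t2$se <- round(t2$se, 3)
  print(t2, row.names = FALSE, na.print = "-")
  if (length(x$fit$random_var))
    cat(sprintf("litter variance: %.4g\n", x$fit$random_var[[1]]))
  invisible(x)
}
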