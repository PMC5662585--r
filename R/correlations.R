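#' Partial (covariate-adjusted) correlation
#'
#' Residualizes `x` and `y` on the adjuster design (factors dummy-coded,
#' covariates linear, plus an intercept) by OLS and Pearson-correlates the
#' residuals. With an empty adjuster set this is the plain Pearson
#' correlation. The test statistic is `t = r sqrt(df / (1 - r^2))` with
#' `df = n - 2 - k`, `k` the number of adjuster design columns beyond the
#' intercept.
#'
#' @param x,y column names in `data`.
#' @param adjusters character vector of adjuster column names (possibly
#'   empty).
#' @param data data frame.
#' @return data frame of class `partial_corr`: `x`, `y`, `adjusters`, `n`,
#'   `r`, `df`, `p`.
#' @export
partial_corr <- function(x, y, adjusters = character(0), data) {
  d <- data[stats::complete.cases(data[c(x, y, adjusters)]),
            c(x, y, adjusters), drop = FALSE]
  n <- nrow(d)
  if (!length(adjusters)) {
    Z <- matrix(1, n, 1)
  } else {
    for (v in adjusters)
      if (is.character(d[[v]])) d[[v]] <- factor(d[[v]])
    Z <- drop_aliased(stats::model.matrix(
      stats::reformulate(adjusters), d))
  }
  k <- ncol(Z) - 1
  if (n <= k + 2) stop("too few observations for the adjuster set")
  rx <- stats::lm.fit(Z, d[[x]])$residuals
  ry <- stats::lm.fit(Z, d[[y]])$residuals
  tolx <- 1e-10 * (stats::sd(d[[x]]) + abs(mean(d[[x]])) + 1)
  toly <- 1e-10 * (stats::sd(d[[y]]) + abs(mean(d[[y]])) + 1)
  if (stats::sd(rx) <= tolx || stats::sd(ry) <= toly)
    stop("zero residual variance: correlation undefined")
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  t <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  structure(data.frame(
    x = x, y = y, adjusters = paste(adjusters, collapse = "+"),
    n = n, r = r, df = df,
    p = 2 * stats::pt(abs(t), df, lower.tail = FALSE)),
    class = c("partial_corr", "data.frame"))
}

## one row per period, columns = trait by period
.wide_by_period <- function(phenotypes, trait) {
  periods <- unique(phenotypes$period)
  out <- unique(phenotypes[c("pig_id", "line", "diet", "room")])
  for (p in periods) {
    sub <- phenotypes[phenotypes$period == p, ]
    out[[paste0(trait, "_", p)]] <- sub[[trait]][match(out$pig_id,
                                                       sub$pig_id)]
  }
  out
}

#' Adjusted correlation report across derived traits
#'
#' Computes the correlation families of interest for the episodic TN/HS
#' design, each adjusted for line, diet and room (the pooled trade-off
#' correlation is additionally adjusted for cycle):
#' \itemize{
#'   \item gain across TN periods and across HS periods,
#'   \item gain in consecutive periods,
#'   \item repeatability of the gain and intake drops across HS cycles,
#'   \item TN gain vs the following cycle's gain drop, per cycle and
#'     pooled over cycles,
#'   \item mean intake/gain drop vs carcass traits (backfat at each scan,
#'     lean percentage, loin depth, hot carcass weight, and loin eye area
#'     when scans are supplied).
#' }
#'
#' @param phenotypes `period_phenotypes` merged with pig metadata (as from
#'   [derive_phenotypes()]).
#' @param losses loss table merged with metadata.
#' @param slaughter optional slaughter table (`pig_id`, `hcw_kg`,
#'   `loind_mm`, `lean_pct`).
#' @param scans optional scan table (`pig_id`, `day`, `bft_mm`,
#'   `lea_cm2`).
#' @param trait trait whose cross-period correlations are reported
#'   (default `bwg`).
#' @return data frame: `family`, `x`, `y`, `adjusters`, `n`, `r`, `df`,
#'   `p`.
#' @export
trait_correlation_report <- function(phenotypes, losses, slaughter = NULL,
                                     scans = NULL, trait = "bwg") {
  adj <- c("line", "diet", "room")
  phenotypes$period <- as.character(phenotypes$period)
  losses$cycle <- as.character(losses$cycle)
  w <- .wide_by_period(phenotypes, trait)
  w$room <- factor(w$room)
  periods <- unique(phenotypes$period)
  tn <- periods[startsWith(periods, "TN")]
  hs <- periods[startsWith(periods, "HS")]
  out <- list()
  pc <- function(family, x, y, adjusters, data) {
    res <- tryCatch(partial_corr(x, y, adjusters, data),
                    error = function(e) NULL)
    if (!is.null(res)) {
      res <- cbind(family = family, as.data.frame(res))
      out[[length(out) + 1]] <<- res
    }
  }
  for (i in seq_along(tn)) for (j in seq_along(tn)) if (i < j)
    pc("tn_gain", paste0(trait, "_", tn[i]), paste0(trait, "_", tn[j]),
       adj, w)
  for (i in seq_along(hs)) for (j in seq_along(hs)) if (i < j)
    pc("hs_gain", paste0(trait, "_", hs[i]), paste0(trait, "_", hs[j]),
       adj, w)
  for (i in seq_len(length(periods) - 1))
    pc("consecutive", paste0(trait, "_", periods[i]),
       paste0(trait, "_", periods[i + 1]), adj, w)

  ## losses wide
  lw <- unique(losses[c("pig_id", "line", "diet", "room")])
  lw$room <- factor(lw$room)
  cycles <- sort(unique(losses$cycle))
  for (cc in cycles) for (v in c("loss_bwg", "loss_fi")) {
    sub <- losses[losses$cycle == cc, ]
    lw[[paste0(v, "_", cc)]] <- sub[[v]][match(lw$pig_id, sub$pig_id)]
  }
  for (v in c("loss_bwg", "loss_fi"))
    for (i in seq_along(cycles)) for (j in seq_along(cycles)) if (i < j)
      pc(paste0(v, "_repeatability"), paste0(v, "_", cycles[i]),
         paste0(v, "_", cycles[j]), adj, lw)

  ## TN gain vs next-cycle loss, per cycle and pooled over cycles
  m <- merge(lw, w[c("pig_id", paste0(trait, "_", tn))], by = "pig_id")
  for (cc in cycles) {
    tn_p <- sub("HS", "TN", cc)
    if (paste0(trait, "_", tn_p) %in% names(m))
      pc(paste0("tradeoff_", cc), paste0(trait, "_", tn_p),
         paste0("loss_bwg_", cc), adj, m)
  }
  pooled <- do.call(rbind, lapply(cycles, function(cc) {
    tn_p <- paste0(trait, "_", sub("HS", "TN", cc))
    if (!tn_p %in% names(m)) return(NULL)
    data.frame(pig_id = m$pig_id, line = m$line, diet = m$diet,
               room = m$room, cycle = cc, tn_gain = m[[tn_p]],
               loss = m[[paste0("loss_bwg_", cc)]])
  }))
  if (!is.null(pooled) && nrow(pooled)) {
    res <- tryCatch(partial_corr("tn_gain", "loss", c(adj, "cycle"),
                                 pooled), error = function(e) NULL)
    if (!is.null(res))
      out[[length(out) + 1]] <- cbind(family = "tradeoff_pooled",
                                      as.data.frame(res))
  }

  ## mean losses vs carcass traits
  if (!is.null(slaughter)) {
    agg <- stats::aggregate(losses[c("loss_bwg", "loss_fi")],
                            by = list(pig_id = losses$pig_id), mean)
    carc <- merge(merge(agg, unique(losses[c("pig_id", adj)]),
                        by = "pig_id"),
                  slaughter, by = "pig_id")
    carc$room <- factor(carc$room)
    if (!is.null(scans)) {
      for (d in sort(unique(scans$day))) {
        sub <- scans[scans$day == d, ]
        carc[[paste0("bft_d", d)]] <- sub$bft_mm[match(carc$pig_id,
                                                       sub$pig_id)]
        carc[[paste0("lea_d", d)]] <- sub$lea_cm2[match(carc$pig_id,
                                                        sub$pig_id)]
      }
    }
    targets <- intersect(c(grep("^bft_d|^lea_d", names(carc), value = TRUE),
                           "lean_pct", "loind_mm", "hcw_kg"), names(carc))
    for (v in c("loss_fi", "loss_bwg")) for (tg in targets)
      pc("loss_vs_carcass", v, tg, adj, carc)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
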