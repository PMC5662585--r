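## Covariance-structure selection, interaction pruning, LS means.

## which structures are special cases of which (same random terms)
.nesting <- list(
  iid = c("cs", "ar1", "arh1", "toep", "un", "sppow"),
  ar1 = c("arh1", "toep", "un"),
  cs = c("toep", "un"),
  arh1 = "un", toep = "un", sppow = "un")

is_nested_structure <- function(a, b, random_a = NULL, random_b = NULL) {
  same_rand <- setequal(random_a %||% character(0), random_b %||% character(0))
  if (same_rand && a %in% names(.nesting) && b %in% .nesting[[a]]) return(TRUE)
  ## compound symmetry is AR1-plus-subject-intercept at rho = 0
  if (a == "cs" && b %in% c("ar1", "arh1") &&
      length(setdiff(random_b, random_a)) == 1) return(TRUE)
  FALSE
}

#' Screen residual covariance structures and choose one
#'
#' Fits the model under each candidate structure, ranks converged fits by
#' the corrected Akaike criterion (AICc), and, when the two best-ranked
#' fits are nested, compares them with a REML likelihood ratio test on the
#' difference in -2 log-likelihood with degrees of freedom equal to the
#' difference in covariance-parameter counts; the simpler structure is
#' kept when that test is non-significant at `lrt_alpha`.
#'
#' AR1 and heterogeneous-AR1 candidates additionally receive a random
#' subject intercept (`add_subject_intercept`), mirroring the convention
#' that banded correlation structures are combined with an animal effect.
#'
#' @inheritParams hslmm
#' @param candidates character vector of structure names.
#' @param add_subject_intercept structures that get an extra random
#'   intercept on the subject.
#' @param lrt_alpha significance level of the nested comparison.
#' @return list of class `structure_selection`: `ranking` (data frame),
#'   `fits`, `chosen` (structure name), `fit` (the chosen `hslmm`),
#'   `lrt` (data frame or NULL).
#' @export
select_structure <- function(fixed, data, subject, order,
                             candidates = c("cs", "ar1", "arh1", "toep",
                                            "un"),
                             random = NULL, times = NULL,
                             add_subject_intercept = c("ar1", "arh1"),
                             lrt_alpha = 0.05,
                             control = hslmm_control()) {
  fits <- list()
  for (kind in candidates) {
    rnd <- random
    if (kind %in% add_subject_intercept) rnd <- unique(c(rnd, subject))
    fits[[kind]] <- tryCatch(
      hslmm(fixed, data, subject = subject, order = order, structure = kind,
            random = rnd, times = times, control = control),
      error = function(e) {
        warning("structure ", kind, " failed: ", conditionMessage(e))
        NULL
      })
  }
  ok <- !vapply(fits, is.null, logical(1))
  ok[ok] <- vapply(fits[ok], `[[`, logical(1), "converged")
  if (sum(ok) < 1) stop("no candidate structure converged")
  ranking <- do.call(rbind, lapply(names(fits)[ok], function(k) {
    f <- fits[[k]]
    data.frame(structure = k, q = f$q, m2ll = f$m2ll, aic = f$aic,
               aicc = f$aicc, bic = f$bic,
               random = paste(f$random %||% "", collapse = "+"))
  }))
  ranking <- ranking[order(ranking$aicc), ]
  rownames(ranking) <- NULL
  chosen <- ranking$structure[1]
  lrt <- NULL
  if (nrow(ranking) >= 2) {
    a <- ranking$structure[1]; b <- ranking$structure[2]
    fa <- fits[[a]]; fb <- fits[[b]]
    simple <- NULL; complexf <- NULL
    if (is_nested_structure(a, b, fa$random, fb$random)) {
      simple <- fa; complexf <- fb
    } else if (is_nested_structure(b, a, fb$random, fa$random)) {
      simple <- fb; complexf <- fa
    }
    if (!is.null(simple)) {
      stat <- simple$m2ll - complexf$m2ll
      df <- complexf$q - simple$q
      p <- stats::pchisq(max(stat, 0), df, lower.tail = FALSE)
      lrt <- data.frame(simple = simple$structure,
                        complex = complexf$structure,
                        stat = stat, df = df, p = p)
      chosen <- if (p >= lrt_alpha) simple$structure else complexf$structure
    }
  }
  structure(list(ranking = ranking, fits = fits, chosen = chosen,
                 fit = fits[[chosen]], lrt = lrt),
            class = "structure_selection")
}

#' @export
print.structure_selection <- function(x, ...) {
  cat("Covariance-structure screening (ranked by AICc):\n")
  print(x$ranking, row.names = FALSE)
  if (!is.null(x$lrt)) {
    cat(sprintf("LRT %s vs %s: chi2 = %.3f, df = %d, p = %.4g\n",
                x$lrt$simple, x$lrt$complex, x$lrt$stat, x$lrt$df, x$lrt$p))
  }
  cat("Chosen:", toupper(x$chosen), "\n")
  invisible(x)
}

#' Stepwise removal of non-significant interaction terms
#'
#' Starting from the full fixed-effect specification, repeatedly refits
#' the model and removes the single interaction term with the largest
#' Wald p-value at or above `alpha`, until every remaining interaction
#' has p below `alpha`. Main effects are never removed. `alpha = 1`
#' removes all interactions (boundary case).
#'
#' @inheritParams hslmm
#' @param alpha removal threshold (default 0.10).
#' @return list: `fit` (final `hslmm`), `formula`, `trail` (data frame of
#'   removed terms and their p-values, in removal order).
#' @export
prune_interactions <- function(fixed, data, subject, order,
                               structure = "un", random = NULL,
                               times = NULL, alpha = 0.10,
                               control = hslmm_control()) {
  response <- deparse(fixed[[2]])
  labels <- attr(stats::terms(fixed), "term.labels")
  trail <- data.frame(step = integer(0), dropped = character(0),
                      p = numeric(0))
  if (alpha >= 1) {
    drop_all <- grepl(":", labels)
    trail <- data.frame(step = seq_len(sum(drop_all)),
                        dropped = labels[drop_all],
                        p = NA_real_)
    labels <- labels[!drop_all]
  }
  ## interaction labels are matched with their variables sorted, because
  ## terms() may reorder variables within a label between refits
  canon <- function(x) vapply(strsplit(x, ":", fixed = TRUE),
                              function(v) paste(sort(v), collapse = ":"),
                              character(1))
  step <- nrow(trail)
  max_steps <- sum(grepl(":", labels)) + 1L
  repeat {
    fml <- stats::reformulate(if (length(labels)) labels else "1",
                              response = response)
    fit <- hslmm(fml, data, subject = subject, order = order,
                 structure = structure, random = random, times = times,
                 control = control)
    inter <- fit$anova[grepl(":", fit$anova$term), , drop = FALSE]
    if (!nrow(inter) || max_steps < 1) break
    worst <- inter[which.max(inter$p), ]
    if (is.na(worst$p) || worst$p < alpha) break
    step <- step + 1
    max_steps <- max_steps - 1L
    trail <- rbind(trail, data.frame(step = step, dropped = worst$term,
                                     p = worst$p))
    labels <- labels[canon(labels) != canon(worst$term)]
  }
  list(fit = fit, formula = fml, trail = trail)
}

#' Least-squares (model-adjusted marginal) means
#'
#' Predicted margins for the levels of `factor` (a single factor name or
#' several joined by `:`), averaging with equal weight over the observed
#' level combinations of the other factors in the model and holding
#' covariates at their observed means. Standard errors come from the
#' fixed-effect covariance; pairwise comparisons are Wald t tests on the
#' contrast of two margins, with letter groupings at `alpha`.
#'
#' @param fit an `hslmm` fit.
#' @param factor character: factor name(s), e.g. `"line"` or
#'   `"line:climate"`.
#' @param alpha significance level for the letter display.
#' @return list of class `ls_means`: `means` (level, estimate, se, df,
#'   lower, upper, group), `pairs` (level1, level2, diff, se, t, p).
#' @export
ls_means <- function(fit, factor, alpha = 0.05) {
  stopifnot(inherits(fit, "hslmm"))
  fvars <- strsplit(factor, ":", fixed = TRUE)[[1]]
  dat <- fit$model_data
  mf_vars <- all.vars(stats::delete.response(fit$terms))
  is_fac <- vapply(mf_vars, function(v) is.factor(dat[[v]]) ||
                     is.character(dat[[v]]), logical(1))
  fac_vars <- mf_vars[is_fac]
  num_vars <- mf_vars[!is_fac]
  if (!all(fvars %in% fac_vars))
    stop("'factor' must name factor variables of the model")

  ## observed combinations of all model factors (keeps nested factors
  ## consistent); covariates at their observed means
  grid <- unique(dat[fac_vars])
  for (v in num_vars) grid[[v]] <- mean(dat[[v]], na.rm = TRUE)
  Xg <- stats::model.matrix(stats::delete.response(fit$terms), grid,
                            contrasts.arg = fit$contrasts,
                            xlev = fit$xlevels)
  Xg <- Xg[, fit$x_cols, drop = FALSE]

  key <- interaction(grid[fvars], drop = TRUE, sep = ":")
  lev <- levels(key)
  L <- t(vapply(lev, function(l) colMeans(Xg[key == l, , drop = FALSE]),
                numeric(ncol(Xg))))
  ## levels of the target factor never observed -> NA with a warning
  full_lev <- levels(interaction(lapply(fvars, function(v)
    if (is.factor(dat[[v]])) dat[[v]] else factor(dat[[v]])),
    drop = FALSE, sep = ":"))
  missing_lev <- setdiff(full_lev, lev)
  if (length(missing_lev))
    warning("non-estimable (empty) level(s): ",
            paste(missing_lev, collapse = ", "))

  est <- drop(L %*% fit$beta)
  Vm <- L %*% fit$vcov %*% t(L)
  se <- sqrt(pmax(diag(Vm), 0))
  df <- fit$n_obs - fit$rank_X
  tcrit <- stats::qt(1 - alpha / 2, df)
  means <- data.frame(level = lev, estimate = est, se = se, df = df,
                      lower = est - tcrit * se, upper = est + tcrit * se)

  cmb <- utils::combn(seq_along(lev), 2)
  pairs <- data.frame(
    level1 = lev[cmb[1, ]], level2 = lev[cmb[2, ]],
    diff = est[cmb[1, ]] - est[cmb[2, ]],
    se = sqrt(pmax(Vm[cbind(cmb[1, ], cmb[1, ])] +
                   Vm[cbind(cmb[2, ], cmb[2, ])] -
                   2 * Vm[cbind(cmb[1, ], cmb[2, ])], 0)))
  pairs$t <- pairs$diff / pairs$se
  pairs$p <- 2 * stats::pt(abs(pairs$t), df, lower.tail = FALSE)
  ord <- order(-est)
  grp <- letter_groups(lev[ord], pairs, alpha)
  means$group <- grp[means$level]
  structure(list(means = means, pairs = pairs, factor = factor,
                 alpha = alpha), class = "ls_means")
}

#' @export
print.ls_means <- function(x, ...) {
  cat("LS means for", x$factor, "\n")
  m <- x$means
  m$estimate <- round(m$estimate, 4); m$se <- round(m$se, 4)
  m$lower <- round(m$lower, 4); m$upper <- round(m$upper, 4)
  print(m, row.names = FALSE)
  invisible(x)
}

#' Within-climate regression of feed conversion efficiency on gain
#'
#' Ordinary least squares of FCE on body weight gain separately within the
#' TN and HS rows, with the TN-vs-HS slope difference tested through the
#' gain-by-climate interaction of the pooled model. Faster-growing pigs
#' are more efficient; the slope is steeper under heat stress because
#' intake is depressed there.
#'
#' @param phenotypes a `period_phenotypes` data frame (rows with undefined
#'   FCE are dropped).
#' @return list: `slopes` (climate, slope, se, n), `difference` (estimate,
#'   se, t, p for HS minus TN).
#' @export
fce_bwg_slopes <- function(phenotypes) {
  ph <- phenotypes[!is.na(phenotypes$fce) & !is.na(phenotypes$bwg), ]
  slopes <- do.call(rbind, lapply(c("TN", "HS"), function(cl) {
    d <- ph[ph$climate == cl, ]
    if (nrow(d) < 3) stop("fewer than 3 usable rows in climate ", cl)
    f <- stats::lm(fce ~ bwg, d)
    data.frame(climate = cl, slope = stats::coef(f)[["bwg"]],
               se = sqrt(diag(stats::vcov(f)))[["bwg"]], n = nrow(d))
  }))
  ph$climate <- stats::relevel(factor(ph$climate), "TN")
  f2 <- stats::lm(fce ~ bwg * climate, ph)
  sm <- summary(f2)$coefficients
  iname <- grep("^bwg:climate", rownames(sm), value = TRUE)
  difference <- data.frame(estimate = sm[iname, 1], se = sm[iname, 2],
                           t = sm[iname, 3], p = sm[iname, 4])
  list(slopes = slopes, difference = difference)
}
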