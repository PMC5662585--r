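#' Configuration of a full analysis run
#'
#' Bundles everything a reproducible run needs: the cohort generator
#' configuration, the schedule, the trade-off calibration targets, the
#' traits to model, the candidate residual covariance structures, and the
#' master seed. A run is reproducible from its archived configuration
#' alone (see [write_run_config()]).
#'
#' @param cohort a [cohort_config()].
#' @param schedule an [hs_schedule()].
#' @param calibrate logical: calibrate the trade-off parameters to
#'   `calibrate_targets` before simulating.
#' @param calibrate_targets pooled and cycle-to-cycle target correlations.
#' @param traits period traits fitted with the repeated-measures model.
#' @param loss_traits per-cycle loss traits (same model without climate).
#' @param carcass_traits slaughter traits (between-animal model).
#' @param structures candidate covariance structures for screening.
#' @param prune_alpha interaction-removal threshold.
#' @param lmm_control optimizer control for all model fits.
#' @param seed master seed.
#' @export
run_config <- function(cohort = cohort_config(),
                       schedule = default_schedule(),
                       calibrate = TRUE,
                       calibrate_targets = c(-0.70, 0.36),
                       traits = c("bwg", "fi"),
                       loss_traits = c("loss_bwg", "loss_fi"),
                       carcass_traits = c("lean_pct", "loind_mm", "hcw_kg"),
                       structures = c("cs", "ar1", "arh1"),
                       prune_alpha = 0.10,
                       lmm_control = hslmm_control(n_starts = 1),
                       seed = cohort$seed) {
  structure(list(cohort = cohort, schedule = schedule,
                 calibrate = calibrate,
                 calibrate_targets = calibrate_targets, traits = traits,
                 loss_traits = loss_traits,
                 carcass_traits = carcass_traits, structures = structures,
                 prune_alpha = prune_alpha, lmm_control = lmm_control,
                 seed = as.integer(seed)),
            class = "run_config")
}

## model-4-style fixed formula for a period trait
model4_formula <- function(trait) {
  stats::reformulate(c("line", "climate", "climate:period", "diet", "room",
                       "age_at_start", "line:climate",
                       "line:climate:period", "line:room", "line:diet",
                       "diet:climate", "diet:climate:period", "diet:room",
                       "room:climate", "room:climate:period"),
                     response = trait)
}

## same model without climate, for per-cycle losses
loss_formula <- function(trait) {
  stats::reformulate(c("line", "cycle", "diet", "room", "age_at_start",
                       "line:cycle", "line:room", "line:diet",
                       "diet:cycle", "diet:room", "room:cycle"),
                     response = trait)
}

## between-animal model for carcass traits (BW-adjusted unless lean)
model5_formula <- function(trait, with_bw = TRUE) {
  stats::reformulate(c("line", "diet", "room", "age_at_start",
                       if (with_bw) "bw_final",
                       "line:diet", "line:room", "diet:room"),
                     response = trait)
}

#' Run the full pipeline: simulate, derive, RFI, mixed models, correlations
#'
#' Executes all stages in order on a synthetic cohort: (1) calibrate the
#' generator trade-off, (2) simulate the cohort, (3) derive period
#' phenotypes and TN-to-HS losses, (4) fit the TN-anchored RFI regression
#' and fill RFI for all periods, (5) fit the line x climate
#' feed-requirement model, (6) for each period trait screen residual
#' covariance structures and prune non-significant interactions, with LS
#' means for line x climate, (7) the same for loss traits (without
#' climate) and carcass traits (between-animal model), and (8) the
#' adjusted correlation report. Every stage draws from a named substream
#' of the master seed, so two runs with the same configuration are
#' identical; degenerate model stages (e.g. one pig per cell) warn and
#' return `NULL` instead of aborting the run.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, all tables are written
#'   as comma-delimited UTF-8 files plus `run.log` and the archived
#'   configuration.
#' @param seed master seed override.
#' @return list of class `hs_report`: `cohort`, `phenotypes`, `losses`,
#'   `rfi`, `feed_requirements`, `models` (per trait: selection, pruning
#'   trail, LS means), `correlations`, `climate_summary`, `log`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         seed = config$seed) {
  log_lines <- character(0)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- expr
    el <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    nr <- if (is.data.frame(res)) nrow(res) else NA
    log_lines <<- c(log_lines,
                    sprintf("stage=%s elapsed=%.2fs rows=%s seed=%d",
                            name, el, ifelse(is.na(nr), "-", nr), seed))
    res
  }
  soft <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      warning("stage '", name, "' degraded: ", conditionMessage(e))
      log_lines <<- c(log_lines, sprintf("stage=%s status=failed msg=%s",
                                         name, conditionMessage(e)))
      NULL
    })
  }
  sch <- config$schedule
  cfg <- config$cohort
  if (isTRUE(config$calibrate))
    cfg <- stage("calibrate",
                 calibrate_tradeoff(config$calibrate_targets[1],
                                    config$calibrate_targets[2], cfg, sch))
  cohort <- stage("simulate",
                  generate_cohort(cfg, sch,
                                  seed = substream_seed(seed, "cohort")))
  der <- stage("derive", derive_phenotypes(cohort, sch))
  ph <- der$phenotypes; losses <- der$losses
  climate_summary <- soft("climate", summarize_climate(cohort$climate, sch))

  rfi <- stage("rfi", rfi_fit(ph))
  ph <- apply_rfi(rfi, ph)
  rg <- soft("residual_growth", residual_growth(ph))
  if (!is.null(rg)) ph <- rg$phenotypes

  feed_req <- soft("feed_requirements",
                   fit_feed_requirements(ph, control = config$lmm_control))

  ph$room <- factor(ph$room)
  ph$period <- factor(ph$period, levels = sch$periods$label)
  ph$climate <- factor(ph$climate, levels = c("TN", "HS"))
  ph$period_idx <- as.integer(ph$period)
  losses$room <- factor(losses$room)
  losses$cycle <- factor(losses$cycle)
  losses$cycle_idx <- as.integer(losses$cycle)

  models <- list()
  for (tr in config$traits) {
    models[[tr]] <- soft(paste0("lmm_", tr), {
      sel <- select_structure(model4_formula(tr), ph, subject = "pig_id",
                              order = "period_idx",
                              candidates = config$structures,
                              random = "litter_id",
                              control = config$lmm_control)
      pr <- prune_interactions(model4_formula(tr), ph, subject = "pig_id",
                               order = "period_idx",
                               structure = sel$chosen,
                               random = unique(c("litter_id",
                                                 sel$fit$random)),
                               alpha = config$prune_alpha,
                               control = config$lmm_control)
      lsm <- soft(paste0("lsmeans_", tr),
                  ls_means(pr$fit, "line:climate"))
      list(selection = sel, pruned = pr, ls_means = lsm)
    })
  }
  for (tr in config$loss_traits) {
    models[[tr]] <- soft(paste0("lmm_", tr), {
      sel <- select_structure(loss_formula(tr), losses,
                              subject = "pig_id", order = "cycle_idx",
                              candidates = intersect(config$structures,
                                                     c("cs", "ar1", "arh1",
                                                       "toep", "un")),
                              random = "litter_id",
                              control = config$lmm_control)
      pr <- prune_interactions(loss_formula(tr), losses,
                               subject = "pig_id", order = "cycle_idx",
                               structure = sel$chosen,
                               random = unique(c("litter_id",
                                                 sel$fit$random)),
                               alpha = config$prune_alpha,
                               control = config$lmm_control)
      lsm <- soft(paste0("lsmeans_", tr), ls_means(pr$fit, "line"))
      list(selection = sel, pruned = pr, ls_means = lsm)
    })
  }
  ## carcass traits: one record per pig
  bw52 <- cohort$bw[cohort$bw$day == max(cohort$bw$day), ]
  carc <- merge(cohort$slaughter, cohort$pigs, by = "pig_id")
  carc$bw_final <- bw52$bw_kg[match(carc$pig_id, bw52$pig_id)]
  carc$room <- factor(carc$room)
  carc$one <- 1L
  for (tr in config$carcass_traits) {
    models[[tr]] <- soft(paste0("lmm_", tr), {
      fml <- model5_formula(tr, with_bw = tr != "lean_pct")
      pr <- prune_interactions(fml, carc, subject = "pig_id",
                               order = "one", structure = "iid",
                               random = "litter_id",
                               alpha = config$prune_alpha,
                               control = config$lmm_control)
      lsm <- soft(paste0("lsmeans_", tr), ls_means(pr$fit, "line"))
      list(selection = NULL, pruned = pr, ls_means = lsm)
    })
  }

  correlations <- soft("correlate",
                       trait_correlation_report(ph, losses,
                                                cohort$slaughter,
                                                cohort$scans))
  report <- structure(list(
    config = config, cohort_config = cfg, cohort = cohort,
    phenotypes = ph, losses = losses, rfi = rfi,
    feed_requirements = feed_req, models = models,
    correlations = correlations, climate_summary = climate_summary,
    log = log_lines, seed = as.integer(seed)
  ), class = "hs_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.hs_report <- function(x, ...) {
  cat("Episodic TN/HS analysis report (seed", x$seed, ")\n\n")
  print(x$rfi)
  if (!is.null(x$feed_requirements)) {
    cat("\n"); print(x$feed_requirements)
  }
  for (tr in names(x$models)) {
    m <- x$models[[tr]]
    if (is.null(m)) next
    cat("\n== trait:", tr, "==\n")
    if (!is.null(m$selection))
      cat("chosen structure:", toupper(m$selection$chosen), "\n")
    if (nrow(m$pruned$trail))
      cat("removed interactions:",
          paste(m$pruned$trail$dropped, collapse = ", "), "\n")
    if (!is.null(m$ls_means)) print(m$ls_means)
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits the cohort tables, `period_phenotypes.csv`, `losses.csv`,
#' `rfi_fit.json`, `feed_requirements.csv`, per-trait structure rankings,
#' pruning trails and LS means, `correlations.csv`, `run.log`, and the
#' archived run configuration. All tables are UTF-8, comma-delimited,
#' with a header row, `.` decimal mark and `NA` for missing.
#'
#' @param report an `hs_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(report$cohort, file.path(dir, "cohort"))
  wcsv <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                          row.names = FALSE, quote = FALSE)
  ph <- report$phenotypes
  out_ph <- data.frame(pig_id = ph$pig_id, period = ph$period,
                       climate = ph$climate, bwg_kgd = ph$bwg,
                       fi_kgd = ph$fi, mbw_kg075 = ph$mbw,
                       bft_mm = ph$bft, fce = ph$fce, rfi_kgd = ph$rfi)
  wcsv(out_ph, "period_phenotypes.csv")
  lo <- report$losses
  wcsv(data.frame(pig_id = lo$pig_id, cycle = lo$cycle,
                  loss_bwg_kgd = lo$loss_bwg, loss_fi_kgd = lo$loss_fi),
       "losses.csv")
  r <- report$rfi
  jsonlite::write_json(list(coefficients = as.list(r$coefficients),
                            se = as.list(r$se), r_squared = r$r_squared,
                            adj_r_squared = r$adj_r_squared,
                            n_obs = r$n_obs),
                       file.path(dir, "rfi_fit.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(report$feed_requirements))
    wcsv(report$feed_requirements$table, "feed_requirements.csv")
  for (tr in names(report$models)) {
    m <- report$models[[tr]]
    if (is.null(m)) next
    if (!is.null(m$selection))
      wcsv(m$selection$ranking, paste0("structure_ranking_", tr, ".csv"))
    if (!is.null(m$pruned) && nrow(m$pruned$trail))
      wcsv(m$pruned$trail, paste0("pruning_trail_", tr, ".csv"))
    if (!is.null(m$ls_means))
      wcsv(m$ls_means$means, paste0("ls_means_", tr, ".csv"))
  }
  if (!is.null(report$correlations))
    wcsv(report$correlations, "correlations.csv")
  if (!is.null(report$climate_summary))
    wcsv(report$climate_summary, "climate_summary.csv")
  writeLines(report$log, file.path(dir, "run.log"))
  write_run_config(report$config, file.path(dir, "run_config.yaml"))
  invisible(dir)
}

#' Archive / restore a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  cc <- config$cohort
  lst <- list(
    seed = config$seed,
    calibrate = config$calibrate,
    calibrate_targets = config$calibrate_targets,
    traits = config$traits, loss_traits = config$loss_traits,
    carcass_traits = config$carcass_traits,
    structures = config$structures, prune_alpha = config$prune_alpha,
    lmm_control = config$lmm_control,
    schedule = list(
      n_cycles = sum(config$schedule$periods$climate == "HS"),
      tn_span = config$schedule$periods$span[nrow(config$schedule$periods)],
      hs_span = config$schedule$periods$span[2] %||% 4,
      tn1_span = config$schedule$periods$span[1],
      start_day = config$schedule$periods$start_day[1]),
    cohort = c(cc[setdiff(names(cc), c("lines", "hs_response",
                                       "rfi_truth"))],
               list(rfi_truth = as.list(cc$rfi_truth),
                    lines = lapply(cc$lines, unclass),
                    hs_response = lapply(unclass(cc$hs_response),
                                         function(v)
                                           if (!is.null(names(v)))
                                             as.list(v) else v))))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  lines <- lapply(y$cohort$lines, function(l) {
    l$n_litters <- l$n_litters %||% NA
    do.call(line_params, l)
  })
  hsr <- do.call(hs_response_params, lapply(y$cohort$hs_response, unlist))
  cc_args <- y$cohort[setdiff(names(y$cohort),
                              c("lines", "hs_response"))]
  cc_args$rfi_truth <- unlist(cc_args$rfi_truth)
  cc <- do.call(cohort_config,
                c(cc_args, list(lines = lines, hs_response = hsr)))
  sch <- do.call(hs_schedule, y$schedule)
  run_config(cohort = cc, schedule = sch, calibrate = y$calibrate,
             calibrate_targets = unlist(y$calibrate_targets),
             traits = unlist(y$traits),
             loss_traits = unlist(y$loss_traits),
             carcass_traits = unlist(y$carcass_traits),
             structures = unlist(y$structures),
             prune_alpha = y$prune_alpha,
             lmm_control = do.call(hslmm_control, y$lmm_control),
             seed = y$seed)
}
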