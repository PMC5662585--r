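#' Episodic thermoneutral / heat-stress experiment schedules
#'
#' The experiment alternates thermoneutral (TN) and heat-stress (HS) periods
#' over a fixed timeline. Day coordinates are 1-based experiment days and
#' periods are half-open intervals `[start_day, end_day)`, so the span of a
#' period is `end_day - start_day`. The default timeline has an adaptation
#' phase (days 1-8), a long first TN period, and three 4-day HS episodes
#' each followed by 7 days of TN recovery, for 45 period-covered days.
#'
#' Body weight is weighed one day before each period boundary (plus days 1
#' and 8), so boundary body weights are later completed by the phenotype
#' module (see [estimate_boundary_bw()]).
#'
#' @param n_cycles number of HS episodes (>= 0).
#' @param tn_span length in days of each TN recovery period after an HS
#'   episode.
#' @param hs_span length in days of each HS episode.
#' @param tn1_span length in days of the first TN period (after adaptation).
#' @param start_day first day of TN1; days before it are the adaptation
#'   phase.
#'
#' @return An object of class `hs_schedule`: a list with elements
#'   `periods` (data frame with columns `label`, `climate`, `start_day`,
#'   `end_day`, `span`), `bw_days`, `scan_days`, `slaughter_day` and
#'   `adaptation_span`.
#' @examples
#' sch <- default_schedule()
#' sch$periods
#' @export
hs_schedule <- function(n_cycles = 3, tn_span = 7, hs_span = 4,
                        tn1_span = 12, start_day = 8) {
  if (n_cycles < 0 || n_cycles != round(n_cycles))
    stop("'n_cycles' must be a non-negative integer")
  if (tn_span < 1 || hs_span < 1 || tn1_span < 1)
    stop("all period spans must be >= 1 day")
  if (start_day < 2) stop("'start_day' must leave at least one adaptation day")

  label <- "TN1"
  climate <- "TN"
  span <- tn1_span
  for (c in seq_len(n_cycles)) {
    label <- c(label, paste0("HS", c), paste0("TN", c + 1L))
    climate <- c(climate, "HS", "TN")
    span <- c(span, hs_span, tn_span)
  }
  end_day <- start_day + cumsum(span)
  periods <- data.frame(
    label = label,
    climate = climate,
    start_day = c(start_day, end_day[-length(end_day)]),
    end_day = end_day,
    span = span,
    stringsAsFactors = FALSE
  )
  # BW is weighed 1 day before every boundary except the very first, which
  # is weighed on the day itself; day 1 anchors the adaptation phase.
  bw_days <- sort(unique(c(1L, as.integer(start_day), as.integer(end_day) - 1L)))
  scan_days <- c(periods$end_day[1] - 1L, periods$end_day[nrow(periods)] - 1L)
  out <- structure(list(
    periods = periods,
    bw_days = bw_days,
    scan_days = as.integer(scan_days),
    slaughter_day = as.integer(periods$end_day[nrow(periods)] + 2L),
    adaptation_span = c(1L, as.integer(start_day))
  ), class = "hs_schedule")
  validate_schedule(out)
  out
}

#' @rdname hs_schedule
#' @export
default_schedule <- function() hs_schedule(3, 7, 4, 12, start_day = 8)

#' Validate an `hs_schedule`
#'
#' Asserts the schedule invariants: periods tile a single interval with no
#' gaps or overlaps, climates alternate starting from TN, and every period
#' boundary has a measured body-weight day within one day.
#'
#' @param schedule an `hs_schedule`.
#' @return `schedule`, invisibly; errors on violation.
#' @export
validate_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "hs_schedule"))
  p <- schedule$periods
  if (any(p$end_day <= p$start_day)) stop("period with non-positive span")
  if (nrow(p) > 1) {
    if (any(p$start_day[-1] != p$end_day[-nrow(p)]))
      stop("periods must be contiguous and non-overlapping")
    if (any(p$climate[-1] == p$climate[-nrow(p)]))
      stop("climates must alternate")
  }
  if (p$climate[1] != "TN") stop("first period must be TN")
  bounds <- unique(c(p$start_day, p$end_day))
  near <- vapply(bounds, function(b) any(abs(schedule$bw_days - b) <= 1),
                 logical(1))
  if (!all(near))
    stop("every period boundary needs a BW day within 1 day")
  invisible(schedule)
}

#' @export
print.hs_schedule <- function(x, ...) {
  p <- x$periods
  cat("Episodic TN/HS schedule: ", nrow(p), " periods, days [",
      p$start_day[1], ", ", p$end_day[nrow(p)], ")\n", sep = "")
  cat(paste0("  ", format(p$label, width = 4), " ", p$climate, " [",
             p$start_day, ",", p$end_day, ")  ", p$span, " d"), sep = "\n")
  cat("BW days:", paste(x$bw_days, collapse = ", "), "\n")
  cat("Scan days:", paste(x$scan_days, collapse = ", "),
      " slaughter day:", x$slaughter_day, "\n")
  invisible(x)
}

#' Map experiment days to periods
#'
#' @param days integer vector of experiment days.
#' @param schedule an `hs_schedule`.
#' @return character vector of period labels (`NA` for days outside all
#'   periods, e.g. the adaptation phase).
#' @export
period_of_day <- function(days, schedule) {
  p <- schedule$periods
  idx <- findInterval(days, p$start_day)
  lab <- rep(NA_character_, length(days))
  ok <- idx >= 1 & days < p$end_day[pmax(idx, 1)]
  lab[ok] <- p$label[idx[ok]]
  lab
}

#' Summarise a climate log by room and climate condition
#'
#' Averages daily room temperature and relative humidity over the TN days
#' and the HS days of the schedule, per room. Days outside the period
#' timeline (the adaptation phase) are ignored. A room-day that is missing
#' from the log raises a warning and is excluded from the summary.
#'
#' @param log data frame with columns `room`, `day`, `temperature_c`,
#'   `rh_pct` (one row per room-day).
#' @param schedule an `hs_schedule`.
#' @return data frame with columns `room`, `climate`, `n_days`, `t_mean`,
#'   `t_sd`, `rh_mean`, `rh_sd` (sample SDs).
#' @export
summarize_climate <- function(log, schedule) {
  stopifnot(all(c("room", "day", "temperature_c", "rh_pct") %in% names(log)))
  if (any(log$rh_pct < 0 | log$rh_pct > 100, na.rm = TRUE))
    stop("relative humidity must lie in [0, 100]")
  if (anyDuplicated(log[c("room", "day")]))
    stop("climate log must have one record per room-day")
  p <- schedule$periods
  period_days <- seq.int(p$start_day[1], p$end_day[nrow(p)] - 1L)
  lab <- period_of_day(log$day, schedule)
  keep <- !is.na(lab)
  log <- log[keep, , drop = FALSE]
  log$climate <- p$climate[match(lab[keep], p$label)]
  for (r in unique(log$room)) {
    miss <- setdiff(period_days, log$day[log$room == r])
    if (length(miss))
      warning(sprintf("room %s: %d period day(s) missing from climate log",
                      r, length(miss)))
  }
  agg <- function(v) {
    s <- stats::aggregate(log[[v]], by = list(room = log$room,
                                              climate = log$climate),
                          FUN = function(z) c(mean(z), stats::sd(z), length(z)))
    cbind(s[1:2], mean = s$x[, 1], sd = s$x[, 2], n = s$x[, 3])
  }
  t <- agg("temperature_c"); rh <- agg("rh_pct")
  out <- data.frame(room = t$room, climate = t$climate, n_days = t$n,
                    t_mean = t$mean, t_sd = t$sd,
                    rh_mean = rh$mean, rh_sd = rh$sd)
  out[order(out$room, out$climate, decreasing = c(FALSE, TRUE),
            method = "radix"), , drop = FALSE]
}

#' Simulate a daily climate log for a schedule
#'
#' Draws one temperature and relative-humidity record per room-day with
#' room- and climate-specific means and day-to-day SDs matching the study
#' conditions the package emulates (TN about 22-23 degC at 71-73% RH, HS
#' about 32 degC at 56-61% RH).
#'
#' @param schedule an `hs_schedule`.
#' @param seed integer seed.
#' @param params optional data frame overriding the per room x climate
#'   means/SDs; columns `room`, `climate`, `t_mean`, `t_sd`, `rh_mean`,
#'   `rh_sd`.
#' @return climate log data frame (`room`, `day`, `temperature_c`,
#'   `rh_pct`).
#' @export
simulate_climate_log <- function(schedule, seed = 1L, params = NULL) {
  if (is.null(params)) {
    params <- data.frame(
      room = c(1, 1, 2, 2), climate = c("TN", "HS", "TN", "HS"),
      t_mean = c(21.9, 31.8, 23.3, 31.8), t_sd = c(1.1, 2.1, 1.1, 1.8),
      rh_mean = c(71.1, 55.6, 73.1, 61.3), rh_sd = c(6.1, 8.6, 5.5, 7.5))
  }
  p <- schedule$periods
  days <- seq.int(p$start_day[1], p$end_day[nrow(p)] - 1L)
  climate <- p$climate[match(period_of_day(days, schedule), p$label)]
  rs <- local_seed(seed)
  on.exit(rs())
  out <- do.call(rbind, lapply(unique(params$room), function(r) {
    i <- match(paste(r, climate), paste(params$room, params$climate))
    data.frame(room = r, day = days,
               temperature_c = stats::rnorm(length(days), params$t_mean[i],
                                            params$t_sd[i]),
               rh_pct = pmin(100, pmax(0, stats::rnorm(
                 length(days), params$rh_mean[i], params$rh_sd[i]))))
  }))
  rownames(out) <- NULL
  out
}

#' Read / write a schedule as a YAML configuration
#'
#' @param schedule an `hs_schedule`.
#' @param path file path.
#' @return `read_schedule` returns an `hs_schedule`; `write_schedule`
#'   returns `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  validate_schedule(schedule)
  yaml::write_yaml(list(
    periods = lapply(seq_len(nrow(schedule$periods)), function(i)
      as.list(schedule$periods[i, c("label", "climate", "start_day",
                                    "end_day")])),
    bw_days = schedule$bw_days,
    scan_days = schedule$scan_days,
    slaughter_day = schedule$slaughter_day,
    adaptation_span = schedule$adaptation_span
  ), path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  y <- yaml::read_yaml(path)
  periods <- do.call(rbind, lapply(y$periods, function(p)
    data.frame(label = p$label, climate = p$climate,
               start_day = as.integer(p$start_day),
               end_day = as.integer(p$end_day))))
  periods$span <- periods$end_day - periods$start_day
  out <- structure(list(
    periods = periods,
    bw_days = as.integer(y$bw_days),
    scan_days = as.integer(y$scan_days),
    slaughter_day = as.integer(y$slaughter_day),
    adaptation_span = as.integer(y$adaptation_span)
  ), class = "hs_schedule")
  validate_schedule(out)
  out
}
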