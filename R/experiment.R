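#' Run paired baseline and augmented network scenarios
#'
#' Fits and predicts every day twice: a baseline scenario using only the
#' urban network, and an augmented scenario adding the remote network.
#' Both scenarios share the grid, CTM field, configuration and per-day
#' seeds, so the extra observations are the only difference between them;
#' on days when no remote site reports, the augmented surface is the
#' baseline surface, bit for bit.
#'
#' @param sites Scheduled site tibble (both networks).
#' @param obs Observation tibble for all sites.
#' @param ctm Gridded CTM field tibble.
#' @param grid The grid.
#' @param config A [ds_config()].
#' @param verbose Print one line per fitted day.
#' @return List with `baseline` and `augmented` daily-surface tibbles
#'   (rows stacked over days), and `days`: a per-day log tibble
#'   (`date, n_baseline, n_remote, fitted, identical`).
#' @export
run_scenario_pair <- function(sites, obs, ctm, grid, config = ds_config(),
                              verbose = FALSE) {
  urban <- sites[sites$network == "urban", , drop = FALSE]
  if (!all(urban$site_id %in% sites$site_id))
    stop("baseline site set must nest in the augmented set", call. = FALSE)
  dates <- sort(unique(ctm$date))
  origin <- min(dates)
  obs_u <- obs[obs$site_id %in% urban$site_id, , drop = FALSE]

  base_out <- list(); aug_out <- list(); log <- list()
  for (k in seq_along(dates)) {
    d <- dates[k]
    n_rem <- sum(obs$date == d & !obs$site_id %in% urban$site_id)
    n_base <- sum(obs_u$date == d)
    fitted <- FALSE; ident <- NA
    if (n_base >= 3) {
      fb <- fit_day(obs_u, urban, ctm, grid, d, config,
                    origin_date = origin)
      sb <- predict_day(fb, ctm, grid)
      base_out[[length(base_out) + 1]] <- sb
      if (n_rem == 0) {
        # identical inputs and seeds: reuse the baseline surface outright
        aug_out[[length(aug_out) + 1]] <- sb
        ident <- TRUE
      } else {
        fa <- fit_day(obs, sites, ctm, grid, d, config, origin_date = origin)
        aug_out[[length(aug_out) + 1]] <- predict_day(fa, ctm, grid)
        ident <- FALSE
      }
      fitted <- TRUE
    }
    if (verbose)
      message(sprintf("%s: n_urban=%d n_remote=%d %s", format(d), n_base,
                      n_rem, if (fitted) "fitted" else "skipped (<3 obs)"))
    log[[k]] <- tibble::tibble(date = d, n_baseline = n_base,
                               n_remote = n_rem, fitted = fitted,
                               identical = ident)
  }
  list(baseline = dplyr::bind_rows(base_out),
       augmented = dplyr::bind_rows(aug_out),
       days = dplyr::bind_rows(log))
}

#' Remote-network sample dates
#'
#' The days on which at least one remote site is scheduled to report.
#'
#' @param sites Scheduled site tibble.
#' @param dates Candidate dates (the simulation period).
#' @return Subset of `dates`.
#' @export
sample_dates <- function(sites, dates) {
  rem <- sites[sites$network == "remote", , drop = FALSE]
  if (nrow(rem) == 0) return(as.Date(character(0)))
  out <- as.Date(character(0))
  for (i in seq_len(nrow(rem)))
    out <- union(out, scheduled_dates(rem$schedule[i], rem$offset[i],
                                      as.Date(dates)))
  sort(as.Date(out))
}

#' Aggregate daily surfaces to annual, quarterly and 98th percentile
#'
#' Per-cell summaries over the selected days: the period (annual) mean,
#' the 98th percentile of daily values (approximating the averaging time
#' of the daily PM2.5 standard), calendar-quarter means (Q1 = Jan-Mar,
#' ..., Q4 = Oct-Dec), and the mean prediction standard error.
#'
#' @param surfaces Daily `ds_surface` rows from [run_scenario_pair()].
#' @param mode `"entire_period"` (all fitted days) or `"sample_dates"`
#'   (restrict to `dates`, typically [sample_dates()]).
#' @param dates Dates to keep when `mode = "sample_dates"`.
#' @param pctl_method `"linear"` (interpolation between order statistics)
#'   or `"nearest_rank"`.
#' @return Tibble with one row per cell: `cell_x, cell_y, x, y,
#'   annual_mean, p98, q1, q2, q3, q4, se_mean`, with the mode recorded in
#'   attribute `"mode"`.
#' @export
aggregate_surfaces <- function(surfaces,
                               mode = c("entire_period", "sample_dates"),
                               dates = NULL,
                               pctl_method = c("linear", "nearest_rank")) {
  mode <- match.arg(mode)
  pctl_method <- match.arg(pctl_method)
  if (mode == "sample_dates") {
    if (is.null(dates)) stop("sample_dates mode needs `dates`", call. = FALSE)
    surfaces <- surfaces[surfaces$date %in% as.Date(dates), , drop = FALSE]
  }
  if (nrow(surfaces) == 0) stop("no days selected", call. = FALSE)
  p98f <- if (pctl_method == "linear") {
    function(v) unname(stats::quantile(v, 0.98, type = 7))
  } else {
    function(v) sort(v)[ceiling(0.98 * length(v))]
  }
  qtr <- function(d) (as.integer(format(d, "%m")) - 1L) %/% 3L + 1L
  out <- surfaces |>
    dplyr::mutate(quarter = qtr(.data$date)) |>
    dplyr::group_by(.data$cell_x, .data$cell_y, .data$x, .data$y) |>
    dplyr::summarise(
      annual_mean = mean(.data$pm25_mean),
      p98 = p98f(.data$pm25_mean),
      q1 = mean(.data$pm25_mean[.data$quarter == 1L]),
      q2 = mean(.data$pm25_mean[.data$quarter == 2L]),
      q3 = mean(.data$pm25_mean[.data$quarter == 3L]),
      q4 = mean(.data$pm25_mean[.data$quarter == 4L]),
      se_mean = mean(.data$pm25_se),
      .groups = "drop") |>
    dplyr::arrange(.data$cell_y, .data$cell_x)
  attr(out, "mode") <- mode
  out
}

#' Cellwise difference between two aggregate surfaces
#'
#' Augmented minus baseline, for every aggregate statistic including the
#' mean standard error; positive values mean the augmented scenario
#' predicts higher (or is less certain, for `se_mean`).
#'
#' @param augmented,baseline Aggregates from [aggregate_surfaces()] on the
#'   same grid and date-selection mode.
#' @return Tibble of per-cell differences with the same statistic columns.
#' @export
difference_surface <- function(augmented, baseline) {
  if (!identical(attr(augmented, "mode"), attr(baseline, "mode")))
    stop("aggregates use different date-selection modes", call. = FALSE)
  if (!identical(augmented[c("cell_x", "cell_y")],
                 baseline[c("cell_x", "cell_y")]))
    stop("aggregates are on different grids", call. = FALSE)
  stats <- c("annual_mean", "p98", "q1", "q2", "q3", "q4", "se_mean")
  out <- augmented
  for (s in stats) out[[s]] <- augmented[[s]] - baseline[[s]]
  attr(out, "mode") <- attr(augmented, "mode")
  out
}

#' Extract a spatial window and per-site time series for a case study
#'
#' Crops both scenarios' daily surfaces to a rectangular window and builds
#' aligned observed/baseline/augmented daily time series at named focus
#' sites (prediction taken at the site's containing grid cell), for
#' inspecting urban-remote gradients the way a two-site case study would.
#'
#' @param scenario Result of [run_scenario_pair()].
#' @param obs Observation tibble.
#' @param sites Site tibble.
#' @param grid The grid.
#' @param window List with `xmin, xmax, ymin, ymax` (km).
#' @param focus_sites Character vector of `site_id`s inside the window.
#' @return List with `baseline`, `augmented` (cropped surface tibbles) and
#'   `series` (tibble `site_id, date, observed, baseline, augmented`).
#' @export
extract_case_study <- function(scenario, obs, sites, grid, window,
                               focus_sites) {
  stopifnot(all(c("xmin", "xmax", "ymin", "ymax") %in% names(window)))
  crop <- function(s) s[s$x >= window$xmin & s$x <= window$xmax &
                        s$y >= window$ymin & s$y <= window$ymax, ,
                        drop = FALSE]
  cb <- crop(scenario$baseline)
  if (nrow(cb) == 0) stop("window contains no grid cells", call. = FALSE)
  fs <- sites[sites$site_id %in% focus_sites, , drop = FALSE]
  if (nrow(fs) < length(unique(focus_sites)))
    stop("unknown focus site id", call. = FALSE)
  if (!all(fs$x >= window$xmin & fs$x <= window$xmax &
           fs$y >= window$ymin & fs$y <= window$ymax))
    stop("focus sites must lie inside the window", call. = FALSE)
  cc <- containing_cell(grid, fs$x, fs$y)
  cells <- tibble::tibble(site_id = fs$site_id, cell_x = cc$cell_x,
                          cell_y = cc$cell_y)
  pick <- function(s, nm) {
    dplyr::inner_join(cells, s, by = c("cell_x", "cell_y")) |>
      dplyr::select("site_id", "date", !!nm := "pm25_mean")
  }
  series <- obs[obs$site_id %in% focus_sites, c("site_id", "date", "pm25")] |>
    dplyr::rename(observed = "pm25") |>
    dplyr::left_join(pick(scenario$baseline, "baseline"),
                     by = c("site_id", "date")) |>
    dplyr::left_join(pick(scenario$augmented, "augmented"),
                     by = c("site_id", "date")) |>
    dplyr::arrange(.data$site_id, .data$date)
  list(baseline = cb, augmented = crop(scenario$augmented), series = series)
}
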