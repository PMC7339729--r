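#' Per-site mean bias of the two scenarios
#'
#' Treating the prediction at a site's containing grid centroid as the
#' grid-cell value, computes each site's mean (predicted - observed) bias
#' under both scenarios over the days the site reported, and the
#' absolute-mean-bias difference
#' `delta = |bias_augmented| - |bias_baseline|`; negative `delta` marks a
#' site whose prediction improved when the remote network was added.
#'
#' @param scenario Result of [run_scenario_pair()].
#' @param obs Observation tibble.
#' @param sites Site tibble.
#' @param grid The grid.
#' @return Tibble `site_id, network, n_days, bias_baseline,
#'   bias_augmented, abs_bias_diff`.
#' @export
site_mean_bias <- function(scenario, obs, sites, grid) {
  cc <- containing_cell(grid, sites$x, sites$y)
  keyed <- tibble::tibble(site_id = sites$site_id, network = sites$network,
                          cell_x = cc$cell_x, cell_y = cc$cell_y)
  pred <- function(s, nm) {
    dplyr::inner_join(keyed, s[, c("date", "cell_x", "cell_y", "pm25_mean")],
                      by = c("cell_x", "cell_y")) |>
      dplyr::select("site_id", "date", !!nm := "pm25_mean")
  }
  joined <- obs |>
    dplyr::inner_join(pred(scenario$baseline, "pred_base"),
                      by = c("site_id", "date")) |>
    dplyr::inner_join(pred(scenario$augmented, "pred_aug"),
                      by = c("site_id", "date"))
  if (nrow(joined) == 0)
    stop("no site-days with both a prediction and an observation",
         call. = FALSE)
  joined |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      n_days = dplyr::n(),
      bias_baseline = mean(.data$pred_base - .data$pm25),
      bias_augmented = mean(.data$pred_aug - .data$pm25),
      .groups = "drop") |>
    dplyr::mutate(abs_bias_diff = abs(.data$bias_augmented) -
                    abs(.data$bias_baseline)) |>
    dplyr::left_join(keyed[, c("site_id", "network")], by = "site_id") |>
    dplyr::relocate("network", .after = "site_id")
}

#' Compare two collocated observation series
#'
#' For monitors of two networks sharing a location (same grid cell), on
#' their shared sample days: percent bias of the mean of series `b`
#' relative to series `a`, a two-sided paired t test on the daily
#' differences, the Pearson correlation, and the least-squares slope of
#' `b` on `a`.
#'
#' @param obs_a,obs_b Tibbles with `date` and `pm25`; records are paired
#'   by date.
#' @return One-row tibble `n, percent_bias, p_value, correlation, slope,
#'   degenerate` (degenerate flags a zero-variance series, for which the
#'   correlation and p-value are undefined and returned as `NA`).
#' @export
collocation_stats <- function(obs_a, obs_b) {
  p <- dplyr::inner_join(obs_a[, c("date", "pm25")],
                         obs_b[, c("date", "pm25")],
                         by = "date", suffix = c("_a", "_b"))
  if (nrow(p) < 3) stop("need >= 3 shared site-days", call. = FALSE)
  a <- p$pm25_a; b <- p$pm25_b
  degen <- stats::var(a) == 0 || stats::var(b) == 0
  dvar <- stats::var(b - a) > 0
  tibble::tibble(
    n = nrow(p),
    percent_bias = (mean(b) - mean(a)) / mean(a) * 100,
    p_value = if (dvar) stats::t.test(b, a, paired = TRUE)$p.value else
      NA_real_,
    correlation = if (degen) NA_real_ else stats::cor(a, b),
    slope = if (stats::var(a) == 0) NA_real_ else
      sum((a - mean(a)) * (b - mean(b))) / sum((a - mean(a))^2),
    degenerate = degen || !dvar)
}

#' Validation statistics for a set of scored records
#'
#' The cross-validation summary: number of site-days, mean bias
#' (predicted - observed), mean squared error, and coverage (fraction of
#' observations inside their 95% predictive intervals), each with a 90%
#' confidence interval (normal approximation for bias and MSE, Wilson
#' score for coverage).
#'
#' @param records Tibble with `obs`, `pred_mean`, `pred_lo`, `pred_hi`.
#' @param level CI level for the reported intervals.
#' @return One-row tibble with each statistic and its `_lo` / `_hi` bounds.
#' @export
cv_stats <- function(records, level = 0.90) {
  n <- nrow(records)
  if (n < 1) {
    return(tibble::tibble(n = 0L, bias = NA_real_, bias_lo = NA_real_,
                          bias_hi = NA_real_, mse = NA_real_,
                          mse_lo = NA_real_, mse_hi = NA_real_,
                          coverage = NA_real_, coverage_lo = NA_real_,
                          coverage_hi = NA_real_))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  err <- records$pred_mean - records$obs
  bias <- mean(err); bias_se <- stats::sd(err) / sqrt(n)
  sq <- err^2
  mse <- mean(sq); mse_se <- stats::sd(sq) / sqrt(n)
  inside <- records$obs >= records$pred_lo & records$obs <= records$pred_hi
  phat <- mean(inside)
  # Wilson score interval
  den <- 1 + z^2 / n
  ctr <- (phat + z^2 / (2 * n)) / den
  hw <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / den
  tibble::tibble(
    n = n,
    bias = bias, bias_lo = bias - z * bias_se, bias_hi = bias + z * bias_se,
    mse = mse, mse_lo = mse - z * mse_se, mse_hi = mse + z * mse_se,
    coverage = phat, coverage_lo = max(ctr - hw, 0),
    coverage_hi = min(ctr + hw, 1))
}

#' Withholding cross-validation of the downscaler
#'
#' Randomly withholds a fraction of the observed site-days, refits each
#' day's model without them, and scores the withheld observations against
#' their 95% posterior predictive intervals (which include the observation
#' noise, since a withheld observation contains it). Days left with fewer
#' than 3 observations are skipped and logged.
#'
#' @param obs Observation tibble.
#' @param sites Site tibble (the network(s) to fit).
#' @param ctm Gridded CTM field tibble.
#' @param grid The grid.
#' @param config A [ds_config()].
#' @param withhold_frac Fraction of site-days withheld, in (0, 0.5].
#' @param seed Seed for the withholding draw.
#' @param unit `"site_day"` (default) withholds individual records;
#'   `"site"` withholds whole sites.
#' @return A `ds_cv` list: `records` (withheld records with `site_id,
#'   date, network, obs, pred_mean, pred_lo, pred_hi`), `stats` (overall
#'   and by-network [cv_stats()] rows), `skipped_days`.
#' @export
cross_validate <- function(obs, sites, ctm, grid, config = ds_config(),
                           withhold_frac = 0.10, seed = config$seed,
                           unit = c("site_day", "site")) {
  unit <- match.arg(unit)
  if (withhold_frac <= 0 || withhold_frac > 0.5)
    stop("withhold_frac must be in (0, 0.5]", call. = FALSE)
  obs <- obs[obs$site_id %in% sites$site_id, , drop = FALSE]
  n <- nrow(obs)
  held_idx <- with_seed(seed, {
    if (unit == "site_day") {
      sort(sample.int(n, round(withhold_frac * n)))
    } else {
      ids <- unique(obs$site_id)
      held_sites <- sample(ids, max(1, round(withhold_frac * length(ids))))
      which(obs$site_id %in% held_sites)
    }
  })
  held <- obs[held_idx, , drop = FALSE]
  kept <- obs[-held_idx, , drop = FALSE]
  origin <- min(ctm$date)

  recs <- list(); skipped <- as.Date(character(0))
  held_dates <- sort(unique(held$date))
  for (di in seq_along(held_dates)) {
    d <- held_dates[di]
    if (sum(kept$date == d) < 3) {
      skipped <- c(skipped, d)
      next
    }
    fit <- fit_day(kept, sites, ctm, grid, d, config, origin_date = origin)
    hd <- dplyr::inner_join(held[held$date == d, , drop = FALSE],
                            sites[, c("site_id", "x", "y", "network")],
                            by = "site_id")
    pp <- predict_points(fit, hd, ctm, grid, include_noise = TRUE,
                         level = 0.95)
    recs[[length(recs) + 1]] <- tibble::tibble(
      site_id = hd$site_id, date = d, network = hd$network,
      obs = hd$pm25, pred_mean = pp$pred_mean,
      pred_lo = pp$pred_lo, pred_hi = pp$pred_hi)
  }
  records <- dplyr::bind_rows(recs)
  stats <- dplyr::bind_rows(
    dplyr::mutate(cv_stats(records), selection = "all", .before = 1),
    records |>
      dplyr::group_by(.data$network) |>
      dplyr::group_modify(~cv_stats(.x)) |>
      dplyr::ungroup() |>
      dplyr::rename(selection = "network"))
  structure(list(records = records, stats = stats, skipped_days = skipped,
                 withhold_frac = withhold_frac, seed = seed),
            class = "ds_cv")
}

#' @export
print.ds_cv <- function(x, ...) {
  cat(sprintf("<ds_cv> %d withheld site-days (%d days skipped)\n",
              nrow(x$records), length(x$skipped_days)))
  print(x$stats)
  invisible(x)
}

#' Restrict two cross-validation runs to their common site-days
#'
#' Intersects the withheld (site, day) keys of two [cross_validate()]
#' runs (e.g. baseline and augmented scenarios) and recomputes the
#' validation statistics of each run on that shared set, so the two
#' scenarios are compared on identical records.
#'
#' @param cv_a,cv_b `ds_cv` objects.
#' @param labels Length-2 names for the two runs.
#' @return List with `records_a`, `records_b` (the common records) and
#'   `stats` (one [cv_stats()] row per run, labelled by `simulation`).
#'   An empty intersection returns zero-row tibbles.
#' @export
common_sitedays <- function(cv_a, cv_b, labels = c("a", "b")) {
  key <- function(r) paste(r$site_id, r$date)
  shared <- intersect(key(cv_a$records), key(cv_b$records))
  ra <- cv_a$records[key(cv_a$records) %in% shared, , drop = FALSE]
  rb <- cv_b$records[key(cv_b$records) %in% shared, , drop = FALSE]
  stats <- dplyr::bind_rows(
    dplyr::mutate(cv_stats(ra), simulation = labels[1], .before = 1),
    dplyr::mutate(cv_stats(rb), simulation = labels[2], .before = 1))
  list(records_a = ra, records_b = rb, stats = stats)
}
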