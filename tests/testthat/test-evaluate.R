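surface_from <- function(cent, dates, value_fun) {
  dplyr::bind_rows(lapply(dates, function(d)
    dplyr::mutate(cent, date = d, pm25_mean = value_fun(d, cent),
                  pm25_se = 0.5)))
}

test_that("site mean bias is zero when predictions equal observations", {
  grid <- make_grid(4, 4, 10)
  cent <- grid_centroids(grid)
  dates <- as.Date("2014-01-01") + 0:3
  sites <- tibble::tibble(site_id = c("A", "B"), x = c(1, 22), y = c(2, 31),
                          network = c("urban", "remote"))
  surf <- surface_from(cent, dates, function(d, ct) 6)
  obs <- tidyr::expand_grid(site_id = sites$site_id, date = dates)
  obs$pm25 <- 6
  sb <- site_mean_bias(list(baseline = surf, augmented = surf), obs, sites,
                       grid)
  expect_true(all(sb$bias_baseline == 0))
  expect_true(all(sb$bias_augmented == 0))
  expect_true(all(sb$abs_bias_diff == 0))
})

test_that("site mean bias matches hand arithmetic and sign convention", {
  grid <- make_grid(4, 4, 10)
  cent <- grid_centroids(grid)
  dates <- as.Date("2014-01-01") + 0:1
  sites <- tibble::tibble(site_id = "A", x = 1, y = 2, network = "urban")
  obs <- tibble::tibble(site_id = "A", date = dates, pm25 = c(10, 12))
  base <- surface_from(cent, dates, function(d, ct)
    if (d == dates[1]) 11 else 13)          # preds (11, 13): bias +1
  aug <- surface_from(cent, dates, function(d, ct)
    if (d == dates[1]) 10.5 else 12.5)      # preds (10.5, 12.5): bias +0.5
  sb <- site_mean_bias(list(baseline = base, augmented = aug), obs, sites,
                       grid)
  expect_equal(sb$bias_baseline, 1)
  expect_equal(sb$bias_augmented, 0.5)
  # delta < 0 marks improvement
  expect_equal(sb$abs_bias_diff, -0.5)
  swapped <- site_mean_bias(list(baseline = aug, augmented = base), obs,
                            sites, grid)
  expect_equal(swapped$abs_bias_diff, 0.5)
})

test_that("collocation statistics on identical and scaled series", {
  dates <- as.Date("2014-01-01") + 0:5
  a <- tibble::tibble(date = dates, pm25 = c(8, 10, 12, 9, 11, 13))
  same <- collocation_stats(a, a)
  expect_equal(same$percent_bias, 0)
  expect_equal(same$correlation, 1)
  expect_equal(same$slope, 1)
  expect_true(same$degenerate)  # zero-variance differences: no paired test

  b <- dplyr::mutate(a, pm25 = 0.85 * pm25)
  sc <- collocation_stats(a, b)
  expect_equal(sc$percent_bias, -15)
  expect_equal(sc$slope, 0.85)
  expect_equal(sc$correlation, 1)
})

test_that("collocation statistics match direct formula evaluation", {
  dates <- as.Date("2014-01-01") + 0:5
  a <- tibble::tibble(date = dates, pm25 = c(5, 8, 11, 7, 9, 14))
  b <- tibble::tibble(date = dates, pm25 = c(4.5, 8.2, 10.1, 6.3, 9.4, 12.8))
  st <- collocation_stats(a, b)
  expect_equal(st$n, 6)
  expect_equal(st$percent_bias,
               (mean(b$pm25) - mean(a$pm25)) / mean(a$pm25) * 100)
  expect_equal(st$correlation, cor(a$pm25, b$pm25))
  expect_equal(st$slope, unname(coef(lm(b$pm25 ~ a$pm25))[2]))
  expect_equal(st$p_value, t.test(b$pm25 - a$pm25)$p.value)
  expect_error(collocation_stats(a[1:2, ], b[1:2, ]), ">= 3")
})

test_that("validation statistics match hand computation on a toy list", {
  rec <- tibble::tibble(
    obs = c(10, 12, 9, 15, 11, 8, 13, 10, 14, 9),
    pred_mean = c(11, 11.5, 10, 14, 12, 8.5, 12, 10.5, 15, 8),
    pred_lo = pred_mean - 2, pred_hi = pred_mean + 2)
  st <- cv_stats(rec)
  err <- rec$pred_mean - rec$obs
  expect_equal(st$n, 10)
  expect_equal(st$bias, mean(err))
  expect_equal(st$mse, mean(err^2))
  expect_equal(st$coverage, mean(abs(err) <= 2))
  z <- qnorm(0.95)
  expect_equal(st$bias_lo, mean(err) - z * sd(err) / sqrt(10))
  expect_equal(st$mse_hi, mean(err^2) + z * sd(err^2) / sqrt(10))
  # MSE decomposition: population variance + squared bias
  expect_equal(st$mse, mean((err - mean(err))^2) + mean(err)^2)
  # Wilson interval bounds stay in [0, 1] and bracket the point estimate
  expect_true(st$coverage_lo <= st$coverage &&
                st$coverage <= st$coverage_hi)
})

test_that("widening intervals never decreases coverage", {
  with_test_seed(4, {
    rec <- tibble::tibble(obs = rnorm(50, 10, 3), pred_mean = rnorm(50, 10, 1))
    cov_prev <- -1
    for (hw in c(0.5, 1, 2, 4, 8)) {
      st <- cv_stats(dplyr::mutate(rec, pred_lo = pred_mean - hw,
                                   pred_hi = pred_mean + hw))
      expect_gte(st$coverage, cov_prev)
      cov_prev <- st$coverage
    }
  })
})

test_that("withholding partitions site-days reproducibly", {
  w <- tiny_world(n_sites = 12, n_days = 6,
                  truth = list(beta0 = 1, beta1 = 1, tau2 = 0.5, rho = 30,
                               sigma2 = 0.3))
  cfg <- ds_config(n_iter = 300, n_burn = 100, seed = 3)
  cv1 <- cross_validate(w$obs, w$sites, w$ctm, w$grid, cfg, seed = 21)
  cv2 <- cross_validate(w$obs, w$sites, w$ctm, w$grid, cfg, seed = 21)
  expect_identical(cv1$records, cv2$records)
  expect_equal(nrow(cv1$records), round(0.1 * nrow(w$obs)))
  # withheld records carry their original observed values
  m <- dplyr::inner_join(cv1$records, w$obs, by = c("site_id", "date"))
  expect_equal(m$obs, m$pm25)
  expect_error(cross_validate(w$obs, w$sites, w$ctm, w$grid, cfg,
                              withhold_frac = 0.6), "0.5")
})

test_that("common site-days intersect withheld sets correctly", {
  mk_cv <- function(keys) list(records = tibble::tibble(
    site_id = sub("/.*", "", keys), date = as.Date(sub(".*/", "", keys)),
    obs = 1, pred_mean = 1, pred_lo = 0, pred_hi = 2))
  k1 <- c("A/2014-01-01", "B/2014-01-02", "C/2014-01-03")
  same <- common_sitedays(mk_cv(k1), mk_cv(k1))
  expect_equal(nrow(same$records_a), 3)
  disj <- common_sitedays(mk_cv(k1), mk_cv("D/2014-01-04"))
  expect_equal(nrow(disj$records_a), 0)
  expect_equal(disj$stats$n, c(0L, 0L))
})

test_that("independent 10% draws intersect in about 1% of site-days", {
  n <- 4000
  keys <- paste0("S", seq_len(n))
  fr <- with_test_seed(12, vapply(1:50, function(i) {
    a <- sample(keys, 400); b <- sample(keys, 400)
    length(intersect(a, b)) / n
  }, numeric(1)))
  expect_lt(abs(mean(fr) - 0.01), 0.002)
})
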