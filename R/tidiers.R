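#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of a daily downscaler fit
#'
#' One row per scalar parameter (global intercept, slope, error variance,
#' GP sill, GP range, kernel decay) with posterior mean, standard
#' deviation and central 95% credible bounds. Local intercepts are
#' summarised with `tidy(x, pars = "local")`, one row per fitted site.
#'
#' @param x A `ds_fit`.
#' @param pars `"global"` (default) or `"local"`.
#' @param ... Unused.
#' @return A tibble with columns `term, estimate, std.error, conf.low,
#'   conf.high`.
#' @method tidy ds_fit
#' @export
tidy.ds_fit <- function(x, pars = c("global", "local"), ...) {
  pars <- match.arg(pars)
  summ <- function(v, term) {
    q <- unname(stats::quantile(v, c(0.025, 0.975)))
    tibble::tibble(term = term, estimate = mean(v),
                   std.error = stats::sd(v), conf.low = q[1],
                   conf.high = q[2])
  }
  if (pars == "global") {
    dplyr::bind_rows(
      summ(x$draws$beta0, "beta0"),
      summ(x$draws$beta1, "beta1"),
      summ(x$draws$sigma2, "sigma2"),
      summ(x$draws$tau2, "tau2"),
      summ(x$draws$rho, "rho"),
      summ(x$draws$kernel_decay, "kernel_decay"))
  } else {
    dplyr::bind_rows(lapply(seq_len(ncol(x$draws$w)), function(i)
      summ(x$draws$w[, i], paste0("w_", x$sites$site_id[i]))))
  }
}

#' One-row fit summary
#'
#' @param x A `ds_fit`.
#' @param ... Unused.
#' @return Tibble with the date, data size, draw count, posterior modal
#'   GP range and kernel decay, and posterior mean variances.
#' @method glance ds_fit
#' @export
glance.ds_fit <- function(x, ...) {
  mode_of <- function(v) as.numeric(names(which.max(table(v))))
  tibble::tibble(
    date = x$date,
    n_obs = nrow(x$sites),
    n_draws = length(x$draws$beta0),
    beta0 = mean(x$draws$beta0),
    beta1 = mean(x$draws$beta1),
    sigma2 = mean(x$draws$sigma2),
    tau2 = mean(x$draws$tau2),
    rho_mode = mode_of(x$draws$rho),
    kernel_decay_mode = mode_of(x$draws$kernel_decay))
}

#' Tidy cross-validation statistics
#'
#' @param x A `ds_cv` from [cross_validate()].
#' @param ... Unused.
#' @return The per-selection statistics tibble (overall and by network).
#' @method tidy ds_cv
#' @export
tidy.ds_cv <- function(x, ...) x$stats

#' One-row cross-validation summary
#'
#' @param x A `ds_cv`.
#' @param ... Unused.
#' @return Tibble with `n`, `bias`, `mse`, `coverage` over all withheld
#'   site-days.
#' @method glance ds_cv
#' @export
glance.ds_cv <- function(x, ...) {
  s <- x$stats[x$stats$selection == "all", , drop = FALSE]
  tibble::tibble(n = s$n, bias = s$bias, mse = s$mse, coverage = s$coverage,
                 n_skipped_days = length(x$skipped_days))
}
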