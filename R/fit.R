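#' MCMC and prior configuration for the downscaler fit
#'
#' Conjugate, weakly informative defaults: normal priors on the global
#' intercept and slope, inverse-gamma priors on the error variance and the
#' GP partial sill. The GP range rho is given discrete uniform prior mass
#' on fractions of the maximum inter-site distance
#' ([decay_candidates()]); the kernel decay of the weighted regressor is
#' likewise sampled over a discrete candidate grid.
#'
#' @param n_iter Total Gibbs iterations.
#' @param n_burn Burn-in iterations discarded (`n_iter > n_burn >= 0`);
#'   `n_iter - n_burn` must be divisible by `thin`.
#' @param thin Thinning interval.
#' @param decay_grid_fracs Fractions of max inter-site distance defining
#'   the rho candidates, each in (0, 1].
#' @param kernel_decay_grid Candidate kernel decays, 1/km.
#' @param prior_beta_mean,prior_beta_var Normal prior moments for
#'   (beta0, beta1).
#' @param prior_sigma2,prior_tau2 Inverse-gamma (shape, rate) for the error
#'   variance and GP sill.
#' @param seed Master seed; each day's sampler seed is derived from it and
#'   the day index, so results do not depend on how a run is partitioned.
#' @return A validated `ds_config` list.
#' @export
ds_config <- function(n_iter = 2000, n_burn = 500, thin = 1,
                      decay_grid_fracs = c(0.05, 0.1, 0.15, 0.2, 0.3, 0.5),
                      kernel_decay_grid = c(0.05, 0.1, 0.2, 0.5),
                      prior_beta_mean = c(0, 0),
                      prior_beta_var = c(1e4, 1e4),
                      prior_sigma2 = c(0.1, 0.1),
                      prior_tau2 = c(0.1, 0.1),
                      seed = 1L) {
  cfg <- list(n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
              thin = as.integer(thin),
              decay_grid_fracs = as.numeric(decay_grid_fracs),
              kernel_decay_grid = as.numeric(kernel_decay_grid),
              prior_beta_mean = as.numeric(prior_beta_mean),
              prior_beta_var = as.numeric(prior_beta_var),
              prior_sigma2 = as.numeric(prior_sigma2),
              prior_tau2 = as.numeric(prior_tau2),
              seed = as.integer(seed))
  errs <- validate_ds_config(cfg)
  if (length(errs) > 0)
    stop("invalid ds_config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  structure(cfg, class = "ds_config")
}

validate_ds_config <- function(cfg) {
  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(cfg$n_iter > cfg$n_burn && cfg$n_burn >= 0,
      sprintf("need n_iter (%s) > n_burn (%s) >= 0", cfg$n_iter, cfg$n_burn))
  chk(cfg$thin >= 1, "thin must be >= 1")
  chk((cfg$n_iter - cfg$n_burn) %% cfg$thin == 0,
      "n_iter - n_burn must be divisible by thin")
  chk(all(cfg$decay_grid_fracs > 0 & cfg$decay_grid_fracs <= 1),
      "decay_grid_fracs must lie in (0, 1]")
  chk(all(cfg$kernel_decay_grid > 0), "kernel_decay_grid must be > 0")
  chk(length(cfg$prior_beta_mean) == 2 && length(cfg$prior_beta_var) == 2 &&
        all(cfg$prior_beta_var > 0), "beta priors must be length-2, var > 0")
  chk(all(cfg$prior_sigma2 > 0) && all(cfg$prior_tau2 > 0),
      "variance priors must have positive shape and rate")
  errs
}

# Precompute, for one day's site set, the inverse exponential correlation
# matrix and its log determinant for every rho candidate.
rho_precision_list <- function(coords, rho_candidates, jitter = 1e-8) {
  lapply(rho_candidates, function(rho) {
    R <- exp_corr(pair_dist(coords), rho) + diag(jitter, nrow(coords))
    U <- chol(R)
    Q <- chol2inv(U)
    attr(Q, "logdetQ") <- -2 * sum(log(diag(U)))
    Q
  })
}

#' Fit the downscaler model for one day
#'
#' Regresses the day's monitor observations on the kernel-weighted CTM
#' regressor with a spatially varying intercept,
#' `Y(s) = beta0 + beta0(s) + beta1 * x~(s) + eps(s)`, by Gibbs sampling
#' with conjugate updates. The local intercept `beta0(s)` is a mean-zero
#' Gaussian process with covariance `tau2 * exp(-d / rho)`; `rho` and the
#' regressor's kernel decay are drawn over discrete candidate grids. The
#' model is fit separately for each day of data.
#'
#' @param obs Observation tibble (`site_id, date, pm25`), any dates.
#' @param sites Site tibble (`site_id, x, y`, ...); used both for the
#'   fitted day's coordinates and for the rho candidate grid.
#' @param ctm Gridded field tibble covering `date`.
#' @param grid The grid.
#' @param date The day to fit.
#' @param config A [ds_config()].
#' @param rho_candidates Optional explicit rho candidates (km); default
#'   derived from `sites` and `config$decay_grid_fracs`.
#' @param fixed Optional named list pinning parameters for diagnostics and
#'   oracle checks: any of `sigma2`, `tau2`, `rho` (a candidate value),
#'   `kernel_decay` (a candidate value).
#' @param origin_date First date of the simulation period (day index 0);
#'   defaults to the earliest CTM date. Determines the per-day seed.
#' @return A `ds_fit` object holding posterior draws.
#' @export
fit_day <- function(obs, sites, ctm, grid, date, config = ds_config(),
                    rho_candidates = NULL, fixed = list(),
                    origin_date = min(ctm$date)) {
  date <- as.Date(date)
  od <- dplyr::inner_join(obs[obs$date == date, , drop = FALSE],
                          sites, by = "site_id")
  n <- nrow(od)
  if (n < 3)
    stop("day ", format(date), " has ", n,
         " observations (< 3); skipping", call. = FALSE)
  if (!all(is.finite(od$pm25))) stop("non-finite observations", call. = FALSE)
  if (!date %in% ctm$date) stop("CTM field missing date ", format(date),
                                call. = FALSE)
  if (is.null(rho_candidates))
    rho_candidates <- decay_candidates(sites, config$decay_grid_fracs)

  v <- field_day_values(ctm, grid, date)
  coords <- cbind(od$x, od$y)
  kd_grid <- config$kernel_decay_grid
  X <- regressor_matrix(coords, v, grid, kd_grid)

  fixed_rho_idx <- 0L; fixed_dec_idx <- 0L
  if (!is.null(fixed$rho)) {
    fixed_rho_idx <- which.min(abs(rho_candidates - fixed$rho))
    rho_candidates[fixed_rho_idx] <- fixed$rho
  }
  if (!is.null(fixed$kernel_decay)) {
    fixed_dec_idx <- which.min(abs(kd_grid - fixed$kernel_decay))
    kd_grid[fixed_dec_idx] <- fixed$kernel_decay
    X[, fixed_dec_idx] <- regressor_matrix(coords, v, grid,
                                           fixed$kernel_decay)
  }

  Qs <- rho_precision_list(coords, rho_candidates)
  logdetQ <- vapply(Qs, attr, numeric(1), "logdetQ")

  seed <- day_seed(config$seed, day_index(date, origin_date))
  draws <- with_seed(seed, ds_gibbs_cpp(
    y = od$pm25, X = X, Qs = Qs, logdetQ = logdetQ,
    prior_beta_mean = config$prior_beta_mean,
    prior_beta_var = config$prior_beta_var,
    a_sigma = config$prior_sigma2[1], b_sigma = config$prior_sigma2[2],
    a_tau = config$prior_tau2[1], b_tau = config$prior_tau2[2],
    n_iter = config$n_iter, n_burn = config$n_burn, thin = config$thin,
    fixed_sigma2 = fixed$sigma2 %||% -1, fixed_tau2 = fixed$tau2 %||% -1,
    fixed_rho = fixed_rho_idx, fixed_decay = fixed_dec_idx,
    init_sigma2 = stats::var(od$pm25) %||% 1,
    init_tau2 = max(stats::var(od$pm25) / 2, 0.1)))

  structure(list(
    date = date,
    sites = od[, c("site_id", "x", "y")],
    y = od$pm25,
    draws = list(
      beta0 = draws$beta[, 1], beta1 = draws$beta[, 2],
      sigma2 = draws$sigma2, tau2 = draws$tau2,
      rho = rho_candidates[draws$rho_idx],
      kernel_decay = kd_grid[draws$decay_idx],
      rho_idx = draws$rho_idx, decay_idx = draws$decay_idx,
      w = draws$w),
    rho_candidates = rho_candidates,
    kernel_decay_grid = kd_grid,
    config = config,
    seed = seed
  ), class = "ds_fit")
}

#' @export
print.ds_fit <- function(x, ...) {
  cat(sprintf("<ds_fit> %s: %d sites, %d draws\n", format(x$date),
              nrow(x$sites), length(x$draws$beta0)))
  print(tidy(x))
  invisible(x)
}

#' Exact conjugate posterior for small instances
#'
#' With the variances, GP range and kernel decay held fixed, the joint
#' posterior of `(beta0, beta1, beta0(s_1..n))` is Gaussian and available
#' in closed form by dense linear algebra. Used as an oracle to validate
#' the Gibbs sampler on instances of at most 10 sites.
#'
#' @inheritParams fit_day
#' @param sigma2,tau2,rho,kernel_decay Fixed parameter values.
#' @return List with `mean` (named length n+2 vector: beta0, beta1, then
#'   one local intercept per site) and `cov` (the posterior covariance).
#' @export
exact_small_posterior <- function(obs, sites, ctm, grid, date,
                                  sigma2, tau2, rho, kernel_decay,
                                  config = ds_config()) {
  date <- as.Date(date)
  od <- dplyr::inner_join(obs[obs$date == date, , drop = FALSE],
                          sites, by = "site_id")
  n <- nrow(od)
  if (n > 10) stop("exact posterior restricted to <= 10 sites", call. = FALSE)
  if (n < 1) stop("no observations on ", format(date), call. = FALSE)
  v <- field_day_values(ctm, grid, date)
  xt <- vapply(seq_len(n), function(i)
    build_weighted_regressor(od$x[i], od$y[i], v, grid, kernel_decay),
    numeric(1))
  H <- cbind(1, xt, diag(n))
  Rw <- tau2 * exp_corr(pair_dist(cbind(od$x, od$y)), rho) + diag(1e-8, n)
  Vprior <- matrix(0, n + 2, n + 2)
  Vprior[1, 1] <- config$prior_beta_var[1]
  Vprior[2, 2] <- config$prior_beta_var[2]
  Vprior[3:(n + 2), 3:(n + 2)] <- Rw
  mprior <- c(config$prior_beta_mean, rep(0, n))
  # covariance (Woodbury) form: stable for sigma2 -> 0 and tight priors
  VHt <- Vprior %*% t(H)
  G <- H %*% VHt + diag(sigma2, n)
  K <- VHt %*% solve(G)
  mu <- drop(mprior + K %*% (od$pm25 - H %*% mprior))
  Sigma <- Vprior - K %*% t(VHt)
  names(mu) <- c("beta0", "beta1", paste0("w_", od$site_id))
  list(mean = mu, cov = Sigma, regressor = xt)
}

#' Conditional Gaussian-process distribution at new locations
#'
#' Given local-intercept values at observed sites, returns the mean and
#' marginal variance of the GP at target locations under covariance
#' `tau2 * exp(-d / rho)` (simple kriging from the mean-zero process).
#'
#' @param site_coords n x 2 matrix of observed locations (km).
#' @param target_coords m x 2 matrix of target locations.
#' @param w Length-n vector (or draws x n matrix) of values at the sites.
#' @param tau2 GP partial sill (scalar, or length-draws vector).
#' @param rho GP range, km.
#' @return List with `mean` (m vector or draws x m matrix) and `var`
#'   (length-m marginal conditional variances).
#' @export
gp_conditional <- function(site_coords, target_coords, w, tau2, rho) {
  site_coords <- as.matrix(site_coords)
  target_coords <- as.matrix(target_coords)
  R <- exp_corr(pair_dist(site_coords), rho) +
    diag(1e-8, nrow(site_coords))
  r <- exp_corr(pair_dist(target_coords, site_coords), rho) # m x n
  A <- r %*% chol2inv(chol(R))                              # m x n
  condvar_unit <- pmax(1 - rowSums(A * r), 0)               # m, per unit sill
  if (is.matrix(w)) {
    mean <- w %*% t(A)                                      # draws x m
  } else {
    mean <- drop(A %*% w)
  }
  list(mean = mean, var = outer_var(tau2, condvar_unit))
}

# tau2 may be a scalar or one value per draw
outer_var <- function(tau2, unit) {
  if (length(tau2) == 1) tau2 * unit else outer(tau2, unit)
}
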