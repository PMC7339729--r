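#' Build, load, save and validate a full run configuration
#'
#' A run configuration drives the whole pipeline: grid, simulation period,
#' network design, generative truth parameters, CTM surrogate settings,
#' MCMC controls and cross-validation settings. Configurations are stored
#' as YAML; validation aggregates every violation into one report and
#' rejects unknown keys.
#'
#' @param ... Named top-level sections overriding the defaults shown in
#'   [default_run_config()].
#' @return A validated `ds_run_config` list.
#' @export
run_config <- function(...) {
  user <- list(...)
  cfg <- modify_config(default_run_config(), user)
  errs <- validate_run_config(cfg)
  if (length(errs) > 0)
    stop("invalid run config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  structure(cfg, class = "ds_run_config")
}

#' Default run configuration
#'
#' A small but complete experiment: a 15 x 15 grid of 12-km cells, 30
#' days, 30 urban + 10 remote sites, truth parameters of realistic
#' magnitude for daily PM2.5 (background ~8 ug/m3, slope 1, GP sill 1,
#' error variance 0.5), and short MCMC chains suitable for pipeline runs.
#'
#' @return A named list of configuration sections.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    grid = list(nx = 15L, ny = 15L, cell_size = 12, origin = c(0, 0)),
    dates = list(start = "2014-01-01", n_days = 30L),
    networks = list(n_urban = 30L, n_remote = 10L,
                    urban_fracs = c(0.13, 0.47, 0.40), remote_bias = 1.0),
    ctm = list(base_level = 8, day_sd = 2, range_km = 60),
    truth = list(beta0 = 1, beta1 = 1, tau2 = 1, rho_frac = 0.15,
                 sigma2 = 0.5, kernel_decay = 0.1),
    fit = list(n_iter = 1000L, n_burn = 250L, thin = 1L,
               decay_grid_fracs = c(0.05, 0.1, 0.15, 0.2, 0.3, 0.5),
               kernel_decay_grid = c(0.05, 0.1, 0.2, 0.5),
               prior_beta_mean = c(0, 0), prior_beta_var = c(1e4, 1e4),
               prior_sigma2 = c(0.1, 0.1), prior_tau2 = c(0.1, 0.1)),
    cv = list(withhold_frac = 0.10)
  )
}

# Recursive override keeping the default structure; unknown keys surface
# later in validation (they are carried through, not silently dropped).
modify_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- modify_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

validate_run_config <- function(cfg) {
  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  def <- default_run_config()
  extra <- setdiff(names(cfg), names(def))
  if (length(extra) > 0)
    chk(FALSE, paste("unknown top-level keys:", paste(extra, collapse = ", ")))
  for (sec in intersect(names(def), names(cfg))) {
    if (!is.list(def[[sec]])) next
    bad <- setdiff(names(cfg[[sec]]), names(def[[sec]]))
    if (length(bad) > 0)
      chk(FALSE, paste0("unknown keys in '", sec, "': ",
                        paste(bad, collapse = ", ")))
  }
  g <- cfg$grid
  chk(is.numeric(g$nx) && g$nx >= 1 && is.numeric(g$ny) && g$ny >= 1,
      "grid$nx and grid$ny must be >= 1")
  chk(is.numeric(g$cell_size) && g$cell_size > 0, "grid$cell_size must be > 0")
  d <- cfg$dates
  chk(!inherits(try(as.Date(d$start), silent = TRUE), "try-error") &&
        !is.na(as.Date(d$start)), "dates$start must be an ISO date")
  chk(is.numeric(d$n_days) && d$n_days >= 1, "dates$n_days must be >= 1")
  nw <- cfg$networks
  chk(is.numeric(nw$n_urban) && nw$n_urban >= 0 &&
        is.numeric(nw$n_remote) && nw$n_remote >= 0 &&
        nw$n_urban + nw$n_remote >= 1,
      "networks: need n_urban + n_remote >= 1")
  chk(length(nw$urban_fracs) == 3 && all(nw$urban_fracs >= 0) &&
        abs(sum(nw$urban_fracs) - 1) < 1e-8,
      "networks$urban_fracs must be 3 nonnegative numbers summing to 1")
  chk(is.numeric(nw$remote_bias) && nw$remote_bias > 0,
      "networks$remote_bias must be > 0")
  tr <- cfg$truth
  chk(is.numeric(tr$tau2) && tr$tau2 >= 0 && is.numeric(tr$sigma2) &&
        tr$sigma2 >= 0, "truth$tau2 and truth$sigma2 must be >= 0")
  chk(is.numeric(tr$rho_frac) && tr$rho_frac > 0 && tr$rho_frac <= 1,
      "truth$rho_frac must be in (0, 1]")
  chk(is.numeric(tr$kernel_decay) && tr$kernel_decay > 0,
      "truth$kernel_decay must be > 0")
  f <- cfg$fit
  chk(is.numeric(f$n_iter) && is.numeric(f$n_burn) && f$n_iter > f$n_burn &&
        f$n_burn >= 0,
      sprintf("fit: need n_iter (%s) > n_burn (%s) >= 0",
              toString(f$n_iter), toString(f$n_burn)))
  errs_fit <- tryCatch({
    do.call(ds_config, c(f, list(seed = cfg$seed))); character(0)
  }, error = function(e) conditionMessage(e))
  if (length(errs_fit) > 0 && !any(grepl("n_iter", errs)))
    chk(FALSE, paste("fit section:", errs_fit[1]))
  chk(is.numeric(cfg$cv$withhold_frac) && cfg$cv$withhold_frac > 0 &&
        cfg$cv$withhold_frac <= 0.5, "cv$withhold_frac must be in (0, 0.5]")
  errs
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param config A `ds_run_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.ds_run_config <- function(x, ...) {
  cat("<ds_run_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

# The ds_config embedded in a run config
fit_config <- function(config) {
  do.call(ds_config, c(config$fit, list(seed = config$seed)))
}

run_dates <- function(config) {
  as.Date(config$dates$start) + seq_len(config$dates$n_days) - 1L
}

run_grid <- function(config) {
  make_grid(config$grid$nx, config$grid$ny, config$grid$cell_size,
            config$grid$origin)
}
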