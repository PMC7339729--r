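# On-disk formats: plain CSV schemas.
# sites:        site_id,x_km,y_km,network,schedule,offset
# observations: site_id,date,pm25_ugm3          (dates ISO-8601)
# fields:       date,cell_x,cell_y,x_km,y_km,pm25_ugm3[,pm25_se_ugm3]

#' Write / read a site table
#'
#' @param sites Site tibble (`site_id, x, y, network[, schedule, offset]`).
#' @param path CSV path.
#' @return `write_sites_csv` returns `path` invisibly; `read_sites_csv`
#'   returns the site tibble.
#' @export
write_sites_csv <- function(sites, path) {
  out <- data.frame(site_id = sites$site_id, x_km = sites$x, y_km = sites$y,
                    network = sites$network,
                    schedule = sites$schedule %||% rep(NA, nrow(sites)),
                    offset = sites$offset %||% rep(NA, nrow(sites)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sites_csv
#' @param path CSV path.
#' @export
read_sites_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "x_km", "y_km", "network")
  if (!all(need %in% names(d)))
    stop("sites file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- tibble::tibble(site_id = as.character(d$site_id), x = d$x_km,
                        y = d$y_km, network = d$network)
  if ("schedule" %in% names(d) && !all(is.na(d$schedule))) {
    out$schedule <- d$schedule
    out$offset <- as.integer(d$offset)
  }
  out
}

#' Write / read an observation table
#'
#' @param obs Observation tibble (`site_id, date, pm25`).
#' @param path CSV path.
#' @return `write_observations_csv` returns `path` invisibly;
#'   `read_observations_csv` returns the observation tibble.
#' @export
write_observations_csv <- function(obs, path) {
  out <- data.frame(site_id = obs$site_id, date = format(obs$date),
                    pm25_ugm3 = obs$pm25)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_observations_csv
#' @export
read_observations_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "date", "pm25_ugm3")
  if (!all(need %in% names(d)))
    stop("observations file must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  tibble::tibble(site_id = as.character(d$site_id),
                 date = as.Date(d$date), pm25 = d$pm25_ugm3)
}

#' Write / read a gridded daily field
#'
#' Long-format CSV, one row per (date, cell); prediction surfaces carry an
#' extra `pm25_se_ugm3` column.
#'
#' @param field Field tibble (`date, cell_x, cell_y, x, y, pm25` or a
#'   `ds_surface` with `pm25_mean, pm25_se`).
#' @param path CSV path.
#' @return `write_field_csv` returns `path` invisibly; `read_field_csv`
#'   returns the field tibble.
#' @export
write_field_csv <- function(field, path) {
  if ("pm25_mean" %in% names(field)) {
    out <- data.frame(date = format(field$date), cell_x = field$cell_x,
                      cell_y = field$cell_y, x_km = field$x, y_km = field$y,
                      pm25_ugm3 = field$pm25_mean,
                      pm25_se_ugm3 = field$pm25_se)
  } else {
    out <- data.frame(date = format(field$date), cell_x = field$cell_x,
                      cell_y = field$cell_y, x_km = field$x, y_km = field$y,
                      pm25_ugm3 = field$pm25)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- tibble::tibble(date = as.Date(d$date),
                        cell_x = as.integer(d$cell_x),
                        cell_y = as.integer(d$cell_y),
                        x = d$x_km, y = d$y_km)
  if ("pm25_se_ugm3" %in% names(d)) {
    out$pm25_mean <- d$pm25_ugm3
    out$pm25_se <- d$pm25_se_ugm3
    class(out) <- c("ds_surface", class(out))
  } else {
    out$pm25 <- d$pm25_ugm3
  }
  out
}
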