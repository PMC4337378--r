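# Builders for hand-crafted animal-days and stop tables used across tests.

day_fixes <- function(x, y, speed = NULL, minutes = NULL,
                      date = as.Date("2010-03-01"), start_h = 6,
                      alt = 300, animal_id = "V01",
                      interpolated = FALSE) {
  n <- length(x)
  if (is.null(speed)) speed <- rep(10, n)
  if (is.null(minutes)) minutes <- (seq_len(n) - 1) * 10
  t0 <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC")
  tibble::tibble(
    animal_id = animal_id,
    timestamp = t0 + start_h * 3600 + minutes * 60,
    x_m = x, y_m = y,
    altitude_m = rep_len(alt, n),
    ground_speed_ms = speed,
    interpolated = rep_len(interpolated, n))
}

sunrise_at <- function(date = as.Date("2010-03-01"), time = "05:42") {
  as.POSIXct(paste(format(date), time), tz = "UTC")
}

# Minimal classified-stop row for feedscan tests.
stop_row <- function(animal_id, date, x = 0, y = 0, start_h = 10,
                     dur_min = 60, eating = 0, running = 0,
                     stop_id = 1L) {
  t0 <- as.POSIXct(paste(format(as.Date(date)), "00:00:00"), tz = "UTC")
  out <- tibble::tibble(
    animal_id = animal_id, date = as.Date(date),
    start = t0 + start_h * 3600,
    end = t0 + start_h * 3600 + dur_min * 60,
    duration_min = dur_min, x_m = x, y_m = y, n_fixes = 5L,
    stop_id = stop_id)
  for (lb in c("active_flight", "passive_flight", "standing", "lying",
               "preening", "running", "eating")) {
    out[[paste0("n_", lb)]] <- 0L
  }
  out$n_eating <- as.integer(eating)
  out$n_running <- as.integer(running)
  out$is_last <- FALSE
  out$classification <- "none"
  out
}

empty_sites <- function() {
  tibble::tibble(site_id = character(), kind = character(),
                 x_m = numeric(), y_m = numeric(), radius_m = numeric())
}

roost_site <- function(x = 0, y = 0, r = 500, id = "R01") {
  tibble::tibble(site_id = id, kind = "roost", x_m = x, y_m = y,
                 radius_m = r)
}

sfs_site <- function(x, y, r = 400, id = "S01") {
  tibble::tibble(site_id = id, kind = "sfs", x_m = x, y_m = y,
                 radius_m = r)
}

# Metric rows for compute_fdp / sequence tests: one complete row per day.
metric_days <- function(animal_id, dates, travel = 40,
                        missing = FALSE) {
  tibble::tibble(
    animal_id = animal_id, date = as.Date(dates),
    active = TRUE, departure_offset = 3, departure_censored = FALSE,
    travel_distance = rep_len(travel, length(dates)),
    max_displacement = rep_len(travel, length(dates)) / 2 / 1.62,
    straightness = 0.62, mean_speed = 10, flight_elevation = 450,
    prop_active_flight = 0.15, n_fixes = 70L, n_interpolated = 3L,
    missing_day = rep_len(missing, length(dates)))
}

# Small simulated population shared by round-trip style tests.
small_sim <- function(seed = 11, n_vultures = 5, n_days = 80, ...) {
  sim_config(n_vultures = n_vultures, n_days = n_days, seed = seed, ...)
}
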