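#' @importFrom stats approx
NULL

BEHAVIOR_LABELS <- c("active_flight", "passive_flight", "standing",
                     "lying", "preening", "running", "eating")

#' Fill missing fixes on the duty-cycle grid by linear interpolation
#'
#' Every scheduled slot lacking a real fix within half a sampling interval
#' receives a position linearly interpolated in time between the bracketing
#' real fixes; no extrapolation occurs beyond the first or last real fix of
#' the day. Interpolated fixes carry the chord speed between their
#' bracketing real fixes, so the speed field stays consistent with the
#' interpolated positions.
#'
#' @param fixes data frame of one animal-day with columns `timestamp`,
#'   `x_m`, `y_m`, `altitude_m`, `ground_speed_ms`, `interpolated`.
#' @param schedule POSIXct vector of expected fix times.
#' @return `fixes` with gap rows added, sorted by time; fewer than two real
#'   fixes returns the input unchanged (the day is handled as missing).
#' @export
interpolate_missing_fixes <- function(fixes, schedule) {
  if (nrow(fixes) < 2) return(fixes)
  fixes <- fixes[order(fixes$timestamp), ]
  tt <- as.numeric(fixes$timestamp)
  ss <- as.numeric(schedule)
  half <- if (length(ss) > 1) min(diff(ss)) / 2 else 300
  covered <- vapply(ss, function(s) any(abs(tt - s) <= half), logical(1))
  want <- ss[!covered & ss > tt[1] & ss < tt[length(tt)]]
  if (!length(want)) return(fixes)
  ix <- findInterval(want, tt)
  chord <- sqrt((fixes$x_m[ix + 1] - fixes$x_m[ix])^2 +
                (fixes$y_m[ix + 1] - fixes$y_m[ix])^2)
  new <- fixes[rep(1, length(want)), ]
  new$timestamp <- as.POSIXct(want, tz = "UTC",
                              origin = "1970-01-01")
  new$x_m <- approx(tt, fixes$x_m, xout = want)$y
  new$y_m <- approx(tt, fixes$y_m, xout = want)$y
  new$altitude_m <- approx(tt, fixes$altitude_m, xout = want)$y
  new$ground_speed_ms <- chord / (tt[ix + 1] - tt[ix])
  new$interpolated <- TRUE
  out <- rbind(fixes, new)
  out[order(out$timestamp), ]
}

dist_from_first <- function(x, y) {
  sqrt((x - x[1])^2 + (y - y[1])^2)
}

#' Classify an animal-day as active or inactive
#'
#' A day is active iff the animal moved strictly more than the activity
#' radius (default 2 km) from its initial location (the roost).
#'
#' @param fixes one animal-day of fixes.
#' @param config a [run_config()].
#' @return logical flag; `NA` for an empty day.
#' @export
classify_active_day <- function(fixes, config = run_config()) {
  if (nrow(fixes) == 0) return(NA)
  max(dist_from_first(fixes$x_m, fixes$y_m)) > config$activity_km * 1000
}

#' Daily travelled distance
#'
#' Sum of planar distances between successive fixes of the day, km;
#' 0 for fewer than two fixes.
#'
#' @inheritParams classify_active_day
#' @export
daily_travel_distance <- function(fixes) {
  n <- nrow(fixes)
  if (n < 2) return(0)
  sum(sqrt(diff(fixes$x_m)^2 + diff(fixes$y_m)^2)) / 1000
}

#' Maximal daily displacement
#'
#' Euclidean distance from the day's initial location to its farthest
#' location, km; distance ties are broken toward the earliest fix.
#'
#' @inheritParams classify_active_day
#' @export
max_displacement <- function(fixes) {
  if (nrow(fixes) == 0) stop("no fixes", call. = FALSE)
  max(dist_from_first(fixes$x_m, fixes$y_m)) / 1000
}

#' Daily path straightness
#'
#' Path-efficiency ratio in `[0, 1]`. Under the default out-and-back
#' convention it is twice the maximal displacement over the total travel
#' distance, clipped at 1 (exact for a straight flight to the farthest
#' point and back); the alternative convention divides the maximal
#' displacement by the distance travelled up to the farthest point.
#'
#' @inheritParams classify_active_day
#' @return ratio in `[0, 1]`; `NA` when travel distance is zero.
#' @export
straightness <- function(fixes, config = run_config()) {
  L <- daily_travel_distance(fixes)
  if (L <= 0) return(NA_real_)
  d <- dist_from_first(fixes$x_m, fixes$y_m)
  if (config$straightness_convention == "out_and_back") {
    min(1, 2 * max(d) / 1000 / L)
  } else {
    k <- which.max(d)
    if (k < 2) return(NA_real_)
    upto <- sum(sqrt(diff(fixes$x_m[1:k])^2 + diff(fixes$y_m[1:k])^2))
    min(1, max(d) / upto)
  }
}

#' Roost-departure time after sunrise
#'
#' Hours from sunrise to the first non-static fix (ground speed strictly
#' above the static threshold). If that fix is the first sample of the
#' day the true departure happened earlier, and the value is
#' left-censored.
#'
#' @param fixes one animal-day of fixes, time-sorted.
#' @param sunrise POSIXct sunrise instant of that day.
#' @param config a [run_config()].
#' @return list with `offset_h` (hours, `NA` when censored or when no
#'   non-static fix exists) and `censored` flag.
#' @export
roost_departure_time <- function(fixes, sunrise, config = run_config()) {
  k <- which(fixes$ground_speed_ms > config$static_ms)[1]
  if (is.na(k)) {
    warning("active day without any non-static fix; departure undefined")
    return(list(offset_h = NA_real_, censored = FALSE))
  }
  if (k == 1) return(list(offset_h = NA_real_, censored = TRUE))
  list(offset_h = as.numeric(difftime(fixes$timestamp[k], sunrise,
                                      units = "hours")),
       censored = FALSE)
}

#' Detect day-stops in one animal-day
#'
#' Greedy left-to-right scan: a stop opens at the first static fix (ground
#' speed at or below the static threshold) and extends while every member
#' fix lies within the stop radius of the running centroid; it is emitted
#' if its time span strictly exceeds the minimum stop duration. Behaviour
#' bursts timestamped within the stop are tallied into per-label counts.
#'
#' @param fixes one animal-day of (interpolated) fixes, time-sorted.
#' @param behaviors behaviour records of the same animal-day (may be
#'   empty).
#' @param config a [run_config()].
#' @return tibble of stops: `start`, `end`, `duration_min`, centroid
#'   `x_m`/`y_m`, `n_fixes`, one count column per behaviour label, and
#'   `is_last` tagging the final (evening roost candidate) stop.
#' @export
detect_day_stops <- function(fixes, behaviors = NULL,
                             config = run_config()) {
  n <- nrow(fixes)
  res <- list()
  i <- 1
  while (i <= n) {
    if (fixes$ground_speed_ms[i] > config$static_ms) {
      i <- i + 1
      next
    }
    cx <- fixes$x_m[i]
    cy <- fixes$y_m[i]
    members <- i
    j <- i + 1
    while (j <= n) {
      if (sqrt((fixes$x_m[j] - cx)^2 + (fixes$y_m[j] - cy)^2) >
          config$stop_radius_m) break
      members <- c(members, j)
      cx <- mean(fixes$x_m[members])
      cy <- mean(fixes$y_m[members])
      j <- j + 1
    }
    span <- as.numeric(difftime(fixes$timestamp[members[length(members)]],
                                fixes$timestamp[members[1]],
                                units = "mins"))
    if (span > config$stop_min_minutes) {
      res[[length(res) + 1]] <- data.frame(
        start = fixes$timestamp[members[1]],
        end = fixes$timestamp[members[length(members)]],
        duration_min = span, x_m = cx, y_m = cy,
        n_fixes = length(members), stringsAsFactors = FALSE)
    }
    i <- j
  }
  if (!length(res)) {
    out <- tibble::tibble(start = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC"),
                          duration_min = numeric(), x_m = numeric(),
                          y_m = numeric(), n_fixes = integer())
    for (lb in BEHAVIOR_LABELS) out[[paste0("n_", lb)]] <- integer()
    out$is_last <- logical()
    return(out)
  }
  out <- tibble::as_tibble(dplyr::bind_rows(res))
  for (lb in BEHAVIOR_LABELS) out[[paste0("n_", lb)]] <- 0L
  if (!is.null(behaviors) && nrow(behaviors)) {
    for (r in seq_len(nrow(out))) {
      inwin <- behaviors$timestamp >= out$start[r] &
        behaviors$timestamp <= out$end[r]
      tab <- table(behaviors$label[inwin])
      for (lb in names(tab)) {
        out[[paste0("n_", lb)]][r] <- as.integer(tab[[lb]])
      }
    }
  }
  out$is_last <- seq_len(nrow(out)) == nrow(out)
  out
}

#' Daily movement characteristics of one animal-day
#'
#' Aggregates the per-day metrics: activity flag, roost-departure offset
#' (with left-censoring), travelled distance, maximal displacement,
#' straightness, mean ground speed and mean flight altitude over
#' non-static fixes, proportion of flapping among flight-labelled
#' behaviour bursts, and fix bookkeeping. A day with fewer than two real
#' fixes is flagged `missing_day` with all metrics `NA`.
#'
#' @param fixes one animal-day of (interpolated) fixes.
#' @param behaviors behaviour records of the same animal-day.
#' @param sunrise POSIXct sunrise instant of the day.
#' @param config a [run_config()].
#' @return one-row tibble.
#' @export
compute_daily_metrics <- function(fixes, behaviors, sunrise,
                                  config = run_config()) {
  n_real <- sum(!fixes$interpolated)
  base <- tibble::tibble(
    active = NA, departure_offset = NA_real_, departure_censored = FALSE,
    travel_distance = NA_real_, max_displacement = NA_real_,
    straightness = NA_real_, mean_speed = NA_real_,
    flight_elevation = NA_real_, prop_active_flight = NA_real_,
    n_fixes = n_real, n_interpolated = sum(fixes$interpolated),
    missing_day = n_real < 2)
  if (base$missing_day) return(base)

  base$active <- classify_active_day(fixes, config)
  base$travel_distance <- daily_travel_distance(fixes)
  base$max_displacement <- max_displacement(fixes)
  base$straightness <- straightness(fixes, config)
  nonstatic <- fixes$ground_speed_ms > config$static_ms
  if (any(nonstatic)) {
    base$mean_speed <- mean(fixes$ground_speed_ms[nonstatic])
    base$flight_elevation <- mean(fixes$altitude_m[nonstatic])
  }
  if (isTRUE(base$active)) {
    dep <- roost_departure_time(fixes, sunrise, config)
    base$departure_offset <- dep$offset_h
    base$departure_censored <- dep$censored
  }
  if (!is.null(behaviors) && nrow(behaviors)) {
    nf <- sum(behaviors$label == "active_flight")
    np <- sum(behaviors$label == "passive_flight")
    if (nf + np > 0) base$prop_active_flight <- nf / (nf + np)
  }
  base
}

#' Process a full track table into daily metrics and day-stops
#'
#' Splits the fix and behaviour tables into animal-days, interpolates
#' missing fixes on the duty-cycle grid inferred per day, and computes
#' [compute_daily_metrics()] and [detect_day_stops()] for every
#' animal-day.
#'
#' @param fixes fix table (all animals).
#' @param behaviors behaviour table (all animals).
#' @param sunrise tibble with columns `date`, `time` ("HH:MM").
#' @param config a [run_config()].
#' @param fix_interval sampling interval in minutes used to build the
#'   interpolation grid.
#' @return list with tibbles `metrics` (one row per animal-day) and
#'   `stops` (one row per detected stop, keyed by `animal_id`, `date`).
#' @export
process_tracks <- function(fixes, behaviors, sunrise,
                           config = run_config(), fix_interval = 10) {
  fixes$date <- as.Date(fixes$timestamp)
  behaviors$date <- as.Date(behaviors$timestamp)
  key_f <- paste(fixes$animal_id, fixes$date)
  key_b <- paste(behaviors$animal_id, behaviors$date)
  fsp <- split(fixes, key_f)
  bsp <- split(behaviors, key_b)
  sunrise_at <- as.POSIXct(paste(format(sunrise$date), sunrise$time),
                           tz = "UTC")
  names(sunrise_at) <- format(sunrise$date)

  mrows <- vector("list", length(fsp))
  srows <- vector("list", length(fsp))
  for (k in seq_along(fsp)) {
    day <- fsp[[k]]
    day <- day[order(day$timestamp), ]
    aid <- day$animal_id[1]
    dt <- day$date[1]
    beh <- bsp[[names(fsp)[k]]]
    grid <- seq(min(day$timestamp), max(day$timestamp),
                by = fix_interval * 60)
    day_i <- interpolate_missing_fixes(day, grid)
    sr <- sunrise_at[[format(dt)]]
    if (is.null(sr)) sr <- as.POSIXct(paste(format(dt), "05:42"),
                                      tz = "UTC")
    m <- compute_daily_metrics(day_i, beh, sr, config)
    m$animal_id <- aid
    m$date <- dt
    mrows[[k]] <- m
    st <- detect_day_stops(day_i, beh, config)
    if (nrow(st)) {
      st$animal_id <- aid
      st$date <- dt
      srows[[k]] <- st
    }
  }
  metrics <- dplyr::bind_rows(mrows)
  metrics <- metrics[order(metrics$animal_id, metrics$date),
                     c("animal_id", "date",
                       setdiff(names(metrics), c("animal_id", "date")))]
  stops <- dplyr::bind_rows(srows)
  if (nrow(stops)) {
    stops <- stops[order(stops$animal_id, stops$start),
                   c("animal_id", "date",
                     setdiff(names(stops), c("animal_id", "date")))]
    stops$stop_id <- seq_len(nrow(stops))
  }
  list(metrics = tibble::as_tibble(metrics),
       stops = tibble::as_tibble(stops))
}
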