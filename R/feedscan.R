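point_in_sites <- function(x, y, sites, kind, fallback_radius) {
  sel <- sites[sites$kind == kind, , drop = FALSE]
  if (nrow(sel) == 0) return(rep(NA_character_, length(x)))
  rad <- if ("radius_m" %in% names(sel)) sel$radius_m else
    rep(fallback_radius, nrow(sel))
  out <- rep(NA_character_, length(x))
  for (i in seq_along(x)) {
    d <- sqrt((sel$x_m - x[i])^2 + (sel$y_m - y[i])^2)
    k <- which(d <= rad)
    if (length(k)) out[i] <- sel$site_id[k[which.min(d[k])]]
  }
  out
}

#' Classify day-stops as feeding, undecided or none
#'
#' Applies the conservative feeding filters to every detected stop, in two
#' passes. A stop inside a major roost site is never feeding. Otherwise:
#' two or more `eating` bursts is a feeding stop (rule i); a single
#' `eating` with two or more `running` is a feeding stop (rule ii); a
#' single `eating` with a single `running` is "undecided"; a single
#' `eating` with no `running` is feeding only if another animal's
#' rule-i/ii feeding stop overlaps it in time within the co-feeding radius
#' (rule iii, resolved in a second pass against first-pass feeders only,
#' which makes the result independent of animal processing order); no
#' `eating` is not a feeding stop.
#'
#' @param stops stop table from [process_tracks()] (all animals).
#' @param sites site table with `site_id`, `kind` (`"roost"`/`"sfs"`),
#'   `x_m`, `y_m`, `radius_m`.
#' @param config a [run_config()].
#' @return `stops` with added columns `in_roost`, `at_sfs_site`,
#'   `classification` in `{feeding, undecided, none}` and `feeding_rule`
#'   in `{i, ii, iii, NA}`.
#' @export
classify_stops <- function(stops, sites, config = run_config()) {
  if (nrow(stops) == 0) {
    stops$in_roost <- logical(0)
    stops$at_sfs_site <- character(0)
    stops$classification <- character(0)
    stops$feeding_rule <- character(0)
    return(stops)
  }
  roost_id <- point_in_sites(stops$x_m, stops$y_m, sites, "roost",
                             config$site_radius_m)
  sfs_id <- point_in_sites(stops$x_m, stops$y_m, sites, "sfs",
                           config$site_radius_m)
  stops$in_roost <- !is.na(roost_id)
  stops$at_sfs_site <- sfs_id

  eat <- stops$n_eating
  run <- stops$n_running
  cls <- rep("none", nrow(stops))
  rule <- rep(NA_character_, nrow(stops))
  cls[eat >= 2] <- "feeding"
  rule[eat >= 2] <- "i"
  cls[eat == 1 & run >= 2] <- "feeding"
  rule[eat == 1 & run >= 2] <- "ii"
  cls[eat == 1 & run == 1] <- "undecided"
  lone <- eat == 1 & run == 0
  cls[stops$in_roost] <- "none"
  rule[stops$in_roost] <- NA_character_

  # pass 2: co-feeding rescue of lone-eating stops, against pass-1 feeders
  feeders <- which(cls == "feeding")
  for (i in which(lone & !stops$in_roost)) {
    if (!length(feeders)) break
    cand <- feeders[stops$animal_id[feeders] != stops$animal_id[i]]
    if (!length(cand)) next
    overlap <- stops$start[cand] <= stops$end[i] &
      stops$end[cand] >= stops$start[i]
    near <- sqrt((stops$x_m[cand] - stops$x_m[i])^2 +
                 (stops$y_m[cand] - stops$y_m[i])^2) <=
      config$rule3_radius_m
    if (any(overlap & near)) {
      cls[i] <- "feeding"
      rule[i] <- "iii"
    }
  }
  stops$classification <- cls
  stops$feeding_rule <- rule
  stops
}

#' Collapse feeding stops into day-level feeding events
#'
#' Any feeding-classified stop makes its animal-day a feeding day; at most
#' one event per animal-day is emitted, referencing the earliest feeding
#' stop. `at_sfs` is set by point-in-radius of that stop against the
#' station table.
#'
#' @param stops classified stop table from [classify_stops()].
#' @return tibble of events: `animal_id`, `date`, `stop_id`, `at_sfs`,
#'   `site_id`, `feeding_rule`.
#' @export
build_feeding_events <- function(stops) {
  fs <- stops[stops$classification == "feeding", , drop = FALSE]
  if (nrow(fs) == 0) {
    return(tibble::tibble(animal_id = character(), date = as.Date(character()),
                          stop_id = integer(), at_sfs = logical(),
                          site_id = character(), feeding_rule = character()))
  }
  fs <- fs[order(fs$animal_id, fs$date, fs$start), ]
  first <- !duplicated(paste(fs$animal_id, fs$date))
  fs <- fs[first, ]
  tibble::tibble(animal_id = fs$animal_id, date = fs$date,
                 stop_id = fs$stop_id, at_sfs = !is.na(fs$at_sfs_site),
                 site_id = fs$at_sfs_site, feeding_rule = fs$feeding_rule)
}

#' Attach food-deprivation periods and validity to feeding events
#'
#' The FDP of an event is the number of whole non-feeding days between it
#' and the animal's previous feeding event (feeding days themselves are
#' not counted). An event is excluded when its history is unknown (first
#' event of the animal), when any day strictly inside the gap is missing
#' or carries an "undecided" stop, or when the FDP exceeds the validity
#' cap (default 14 days).
#'
#' @param events event table from [build_feeding_events()].
#' @param metrics daily-metrics table from [process_tracks()].
#' @param stops classified stop table (for undecided days).
#' @param config a [run_config()].
#' @return `events` with added `fdp`, `valid`, `exclusion_reason`.
#' @export
compute_fdp <- function(events, metrics, stops, config = run_config()) {
  events <- events[order(events$animal_id, events$date), ]
  n <- nrow(events)
  events$fdp <- NA_integer_
  events$valid <- FALSE
  events$exclusion_reason <- "unknown_history"
  if (n == 0) return(events)

  ok_days <- metrics[!metrics$missing_day, c("animal_id", "date")]
  ok_key <- paste(ok_days$animal_id, ok_days$date)
  und <- stops[stops$classification == "undecided", c("animal_id", "date")]
  und_key <- unique(paste(und$animal_id, und$date))

  for (i in seq_len(n)) {
    if (i == 1 || events$animal_id[i] != events$animal_id[i - 1]) next
    gap_days <- as.integer(events$date[i] - events$date[i - 1]) - 1L
    events$fdp[i] <- gap_days
    inner_key <- if (gap_days > 0) {
      paste(events$animal_id[i], events$date[i - 1] + seq_len(gap_days))
    } else character(0)
    if (length(inner_key) && !all(inner_key %in% ok_key)) {
      events$exclusion_reason[i] <- "missing_day_in_gap"
    } else if (length(inner_key) && any(inner_key %in% und_key)) {
      events$exclusion_reason[i] <- "undecided_in_gap"
    } else if (gap_days > config$fdp_cap) {
      events$exclusion_reason[i] <- "fdp_over_14"
    } else {
      events$exclusion_reason[i] <- "none"
      events$valid[i] <- TRUE
    }
  }
  events
}

seq_category <- function(fdp, config) {
  ifelse(fdp >= config$long_min, "long",
         ifelse(fdp >= config$short_range[1] &
                fdp <= config$short_range[2], "short",
                ifelse(fdp == 0, "zero", "mid")))
}

#' Build FDP sequences with per-day metric rows
#'
#' One sequence per valid event: day `d = 0` is the feeding day opening
#' the sequence (the previous feeding event) and days `1..fdp` are the
#' non-feeding days before the terminal event. Daily metrics are joined
#' per day; sequences touching a day with no metric row are dropped with
#' a warning. Categories: short (FDP within `short_range`), long
#' (`>= long_min`), mid (between), zero (FDP 0).
#'
#' @param events validated events from [compute_fdp()].
#' @param metrics daily-metrics table.
#' @param config a [run_config()].
#' @return tidy long tibble: `animal_id`, `event_id`, `fdp`, `category`,
#'   `day_index`, `date` plus the metric columns.
#' @export
build_sequences <- function(events, metrics, config = run_config()) {
  ev <- events[events$valid & !is.na(events$fdp), , drop = FALSE]
  out <- vector("list", nrow(ev))
  mkey <- paste(metrics$animal_id, metrics$date)
  dropped <- 0
  for (i in seq_len(nrow(ev))) {
    f <- ev$fdp[i]
    dates <- ev$date[i] - f - 1 + 0:f
    keys <- paste(ev$animal_id[i], dates)
    rows <- match(keys, mkey)
    if (anyNA(rows)) {
      dropped <- dropped + 1
      next
    }
    m <- metrics[rows, ]
    m$event_id <- i
    m$fdp <- f
    m$day_index <- 0:f
    out[[i]] <- m
  }
  if (dropped > 0) {
    warning(sprintf("%d sequences dropped for absent metric rows", dropped))
  }
  seqs <- dplyr::bind_rows(out)
  if (nrow(seqs) == 0) return(seqs)
  seqs$category <- seq_category(seqs$fdp, config)
  cols <- c("animal_id", "event_id", "fdp", "category", "day_index", "date")
  seqs[, c(cols, setdiff(names(seqs), cols))]
}

#' FDP histogram and monthly long-FDP proportions
#'
#' Counts valid events by FDP value from 0 up to the validity cap, and the
#' monthly proportion of events with FDP at or above the long-sequence
#' threshold (using the terminal event's calendar month).
#'
#' @param events validated events from [compute_fdp()].
#' @param config a [run_config()].
#' @return list with tibbles `counts` (`fdp`, `n`) and `monthly`
#'   (`month`, `n_events`, `prop_long`).
#' @export
fdp_histogram <- function(events, config = run_config()) {
  ev <- events[events$valid & !is.na(events$fdp), , drop = FALSE]
  counts <- tibble::tibble(
    fdp = 0:config$fdp_cap,
    n = vapply(0:config$fdp_cap, function(k) sum(ev$fdp == k), integer(1)))
  month <- as.integer(format(ev$date, "%m"))
  monthly <- tibble::tibble(month = 1:12)
  monthly$n_events <- vapply(1:12, function(m) sum(month == m), integer(1))
  monthly$prop_long <- vapply(1:12, function(m) {
    idx <- month == m
    if (!any(idx)) return(NA_real_)
    mean(ev$fdp[idx] >= config$long_min)
  }, numeric(1))
  list(counts = counts, monthly = monthly)
}

#' Restrict events to an analysis subset
#'
#' `"all"` keeps every event; `"sfs"` keeps events at a supplementary
#' feeding station; `"occasional"` keeps events at occasional carcasses.
#'
#' @param events event table.
#' @param subset subset selector.
#' @return filtered events.
#' @export
apply_event_subset <- function(events, subset = c("all", "sfs",
                                                  "occasional")) {
  subset <- match.arg(subset)
  switch(subset,
         all = events,
         sfs = events[events$at_sfs, , drop = FALSE],
         occasional = events[!events$at_sfs, , drop = FALSE])
}
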