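#' @importFrom stats rnorm runif rgeom rpois rgamma rbinom
NULL

#' Hump-shaped expected displacement profile
#'
#' Expected maximal displacement (km) of an active day as a function of the
#' day-within-FDP: a truncated quadratic rising from `hump_base` to
#' `hump_base + hump_gain` at `hump_peak_day` and falling back symmetrically,
#' constant at `hump_base` beyond twice the peak day.
#'
#' @param d day-within-FDP (0 = feeding day), vectorised.
#' @param config a [sim_config()].
#' @return expected displacement, km.
#' @export
hump_profile <- function(d, config) {
  config$hump_base + config$hump_gain * hump_fraction(d, config)
}

hump_fraction <- function(d, config) {
  pk <- config$hump_peak_day
  pmax(0, 1 - ((d - pk) / pk)^2)
}

#' Per-month feeding probability
#'
#' The population simulator models feeding as a memoryless daily process:
#' each day an animal feeds with probability p, so FDPs are geometric with
#' zero-fraction p. Under the seasonal calibration p varies by calendar
#' month and is derived from the target monthly proportion of long
#' (>= 6 day) FDPs, p(m) = 1 - prop(m)^(1/6); with seasonality off it is
#' the flat `fdp_p0`.
#'
#' @param month calendar month 1-12, vectorised.
#' @param config a [sim_config()].
#' @return feeding probability per day.
#' @export
monthly_feed_prob <- function(month, config) {
  if (isTRUE(config$seasonal)) {
    1 - config$monthly_long_prop[month]^(1 / 6)
  } else {
    rep(config$fdp_p0, length(month))
  }
}

#' Sample food-deprivation-period durations
#'
#' Draws i.i.d. FDP durations from a geometric law on \{0, 1, 2, ...\} with
#' success probability `p0` — the maximum-entropy model for a memoryless
#' day-to-day feeding process, whose histogram decays exponentially with
#' rate -log(1 - p0) and whose zero fraction equals `p0`.
#'
#' @param n number of events to draw.
#' @param p0 per-day feeding probability in (0, 1].
#' @return integer vector of `n` non-negative day counts.
#' @export
sample_fdp_durations <- function(n, p0) {
  if (!is.numeric(p0) || length(p0) != 1 || p0 <= 0 || p0 > 1) {
    stop("`p0` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  rgeom(n, p0)
}

GROUND_LABELS <- c("standing", "lying", "preening")
FILLER_PROBS <- c(standing = 0.45, lying = 0.2, preening = 0.25,
                  passive_flight = 0.1)

#' Behaviour-label composition of one day-stop
#'
#' Emits the multiset of ACC behaviour labels recorded during a ground
#' stop, by stop kind: `"feeding"` satisfies one of the feeding rules
#' (usually two or more `eating` bursts; occasionally one `eating` with two
#' or more `running`), `"feeding_single"` is a genuine feeding stop emitted
#' with a single `eating` burst and no `running` (recoverable only through
#' the co-feeding rule), `"ambiguous"` carries exactly one `eating` and one
#' `running` (classified "undecided" downstream), and `"loafing"` carries
#' no `eating`. Remaining slots are filled with resting labels.
#'
#' @param stop_kind one of `"feeding"`, `"feeding_single"`, `"ambiguous"`,
#'   `"loafing"`.
#' @param config a [sim_config()].
#' @param n_slots number of ACC bursts recorded during the stop; extended
#'   if smaller than the core label count.
#' @return character vector of labels, in randomised order.
#' @export
emit_stop_behaviors <- function(stop_kind, config, n_slots = 12) {
  counts <- switch(stop_kind,
    feeding = {
      if (runif(1) < config$p_rule2_comp) {
        c(eating = 1, running = 2 + rpois(1, 1))
      } else {
        c(eating = 2 + rpois(1, max(0, config$eating_burst_rate - 2)),
          running = rpois(1, config$running_burst_rate))
      }
    },
    feeding_single = c(eating = 1, running = 0),
    ambiguous = c(eating = 1, running = 1),
    loafing = c(eating = 0, running = rbinom(1, 1, 0.2)),
    stop(sprintf("unknown stop kind '%s'", stop_kind), call. = FALSE)
  )
  core <- rep(names(counts), counts)
  n_slots <- max(n_slots, length(core))
  out <- sample(names(FILLER_PROBS), n_slots, replace = TRUE,
                prob = FILLER_PROBS)
  # eating/running bursts happen in the early-to-mid part of the stop
  # (birds feed soon after landing), keeping them clear of the stop edges
  lo <- max(2, ceiling(0.2 * n_slots))
  hi <- max(floor(0.75 * n_slots), lo)
  if (hi - lo + 1 < length(core)) {
    lo <- 1
    hi <- n_slots
  }
  if (length(core)) {
    pos <- if (hi > lo) sample(lo:hi, length(core)) else lo
    out[pos] <- core[sample.int(length(core))]
  }
  out
}

parse_clock <- function(x) {
  p <- as.integer(strsplit(x, ":", fixed = TRUE)[[1]])
  p[1] + p[2] / 60
}

duty_slots <- function(config) {
  seq(config$duty_start, config$duty_end, by = config$fix_interval / 60)
}

trunc_norm_pos <- function(n, mean, sd) pmax(0, rnorm(n, mean, sd))

draw_displacement <- function(d, config) {
  mu <- hump_profile(d, config)
  cv <- config$displacement_cv
  # 5-km floor keeps apparent flight speeds above the static threshold at
  # the fix-interval resolution
  max(5, rgamma(1, shape = 1 / cv^2, scale = mu * cv^2))
}

# Builds one out-or-inbound flight leg as a zigzag of fix-interval steps
# whose headings alternate bearing +/- alpha with cos(alpha) =
# 1/tortuosity, then rotates and rescales the whole leg so its endpoint
# lands exactly `dist_m` along `bearing`. Path length is therefore about
# tortuosity * dist_m (exact when the step count is even), and recorded
# instantaneous speeds equal step length / interval, so positions and the
# speed field stay mutually consistent.
flight_leg <- function(from, bearing, dist_m, config) {
  alpha <- acos(1 / config$tortuosity)
  dt <- config$fix_interval * 60
  n <- max(2, round(config$tortuosity * dist_m / (config$speed_mean * dt)))
  v <- pmax(5, rnorm(n, config$speed_mean, config$speed_sd))
  head0 <- rep_len(c(alpha, -alpha), n)
  dx <- v * dt * cos(head0)
  dy <- v * dt * sin(head0)
  ex <- sum(dx)
  ey <- sum(dy)
  sc <- dist_m / sqrt(ex^2 + ey^2)
  rot <- bearing - atan2(ey, ex)
  dx2 <- sc * (dx * cos(rot) - dy * sin(rot))
  dy2 <- sc * (dx * sin(rot) + dy * cos(rot))
  list(x = from[1] + cumsum(dx2), y = from[2] + cumsum(dy2),
       speed = v * sc)
}

roost_walk <- function(n, roost, sd_step = 25, max_r = 250) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  x <- y <- numeric(n)
  cx <- cy <- 0
  for (i in seq_len(n)) {
    cx <- cx + rnorm(1, 0, sd_step)
    cy <- cy + rnorm(1, 0, sd_step)
    r <- sqrt(cx^2 + cy^2)
    if (r > max_r) {
      cx <- cx * max_r / r
      cy <- cy * max_r / r
    }
    x[i] <- roost[1] + cx
    y[i] <- roost[2] + cy
  }
  cbind(x = x, y = y)
}

ground_filler <- function(n) {
  sample(GROUND_LABELS, n, replace = TRUE, prob = c(0.45, 0.2, 0.35))
}

#' Simulate one animal-day of GPS fixes and behaviour bursts
#'
#' Realises the measurement design for a single animal-day: fixes on the
#' duty-cycle grid with independent dropout; an inactive day stays within
#' a few hundred metres of the roost at ground speeds below the static
#' threshold; an active day departs the roost at a truncated-Normal offset
#' after sunrise, flies an out-and-back path whose farthest point sits at
#' the displacement drawn from the hump profile for the given
#' day-within-FDP and whose length is `tortuosity` times the round-trip
#' displacement, pauses at Poisson-drawn ground stops, and on feeding days
#' carries exactly one stop with a feeding behaviour composition.
#'
#' @param day_state list with at least `date`, `day_in_fdp`, `active`,
#'   `feeding`; optional elements `animal_id`, `month`, `roost` (x/y, m),
#'   `ground_alt` (m), `feed_comp` (`"feeding"` or `"feeding_single"`),
#'   `feed_site` (list with `x`, `y`, `site_id`), `ambiguous`,
#'   `t_dep_h` (departure clock hour), `displacement_km`,
#'   `feed_slots` (feeding-stop length in fix slots).
#' @param config a [sim_config()].
#' @return list with data frames `fixes`, `behaviors`, `stops` (generator
#'   truth descriptors of emitted non-roost stops).
#' @export
simulate_vulture_day <- function(day_state, config) {
  s <- day_state
  if (is.null(s$animal_id)) s$animal_id <- "V01"
  if (is.null(s$roost)) s$roost <- c(0, 0)
  if (is.null(s$ground_alt)) s$ground_alt <- 300
  if (s$day_in_fdp < 0) stop("day_in_fdp must be >= 0", call. = FALSE)
  slots <- duty_slots(config)
  n_slot <- length(slots)
  date <- as.Date(s$date)
  t0 <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC")
  stamps <- t0 + slots * 3600

  stop_rec <- list()
  if (!isTRUE(s$active)) {
    xy <- roost_walk(n_slot, s$roost)
    speed <- runif(n_slot, 0.1, 1.2)
    alt <- s$ground_alt + rnorm(n_slot, 0, 3)
    labels <- ground_filler(n_slot)
  } else {
    sunrise_h <- parse_clock(config$sunrise_time)
    t_dep <- if (!is.null(s$t_dep_h)) s$t_dep_h else
      sunrise_h + trunc_norm_pos(1, config$departure_mean,
                                 config$departure_sd)
    D_km <- if (!is.null(s$displacement_km)) s$displacement_km else
      draw_displacement(s$day_in_fdp, config)
    if (!is.null(s$feed_site)) {
      dx <- s$feed_site$x - s$roost[1]
      dy <- s$feed_site$y - s$roost[2]
      bearing <- atan2(dy, dx)
      D_km <- sqrt(dx^2 + dy^2) / 1000
    } else {
      bearing <- runif(1, 0, 2 * pi)
    }
    k_dep <- if (t_dep <= slots[1]) 1L else
      which(slots >= t_dep)[1]
    if (is.na(k_dep)) k_dep <- n_slot  # departure after duty end: stay put

    feeding <- isTRUE(s$feeding)
    feed_slots <- if (feeding) {
      if (!is.null(s$feed_slots)) s$feed_slots else
        max(4, round(60 * min(4, max(1, rnorm(1, config$feeding_stop_hours,
                                              0.5))) / config$fix_interval))
    } else 0L
    n_loaf <- min(rpois(1, config$stop_rate), 4)
    if (isTRUE(s$ambiguous) && n_loaf == 0) n_loaf <- 1
    loaf_slots <- if (n_loaf > 0) {
      sample(3:9, n_loaf, replace = TRUE)
    } else integer(0)

    for (try in 1:4) {
      out <- flight_leg(s$roost, bearing, D_km * 1000, config)
      turn <- c(s$roost[1] + D_km * 1000 * cos(bearing),
                s$roost[2] + D_km * 1000 * sin(bearing))
      inb <- flight_leg(turn, bearing + pi, D_km * 1000, config)
      n_fly <- length(out$speed) + length(inb$speed)
      need <- (k_dep - 1) + n_fly + feed_slots + sum(loaf_slots)
      if (need <= n_slot - 1) break
      if (length(loaf_slots)) loaf_slots <- integer(0)
      else if (feed_slots > 4) feed_slots <- 4L
      else D_km <- D_km * 0.7
    }
    # place loafing stops after random flight vertices; on feeding days
    # only on the inbound leg, so the arrival time at the feeding site
    # stays at its planned slot (the co-feeding windows rely on it)
    vert_ids <- seq_len(n_fly)
    feed_vert <- length(out$speed)
    cand <- if (feeding) {
      vert_ids[vert_ids > feed_vert & vert_ids < n_fly]
    } else {
      vert_ids[-length(vert_ids)]
    }
    loaf_at <- if (length(loaf_slots) && length(cand)) {
      sort(sample(cand, min(n_loaf, length(cand))))
    } else integer(0)
    loaf_slots <- loaf_slots[seq_along(loaf_at)]
    amb_idx <- if (isTRUE(s$ambiguous) && length(loaf_at)) {
      sample(length(loaf_at), 1)
    } else 0L

    vx <- c(out$x, inb$x)
    vy <- c(out$y, inb$y)
    vx[n_fly] <- s$roost[1]
    vy[n_fly] <- s$roost[2]
    vspeed <- c(out$speed, inb$speed)

    x <- y <- speed <- alt <- numeric(0)
    labels <- character(0)
    add_static <- function(n, px, py, lab) {
      x <<- c(x, px + rnorm(n, 0, 10))
      y <<- c(y, py + rnorm(n, 0, 10))
      speed <<- c(speed, runif(n, 0.1, 1.2))
      alt <<- c(alt, s$ground_alt + rnorm(n, 0, 3))
      labels <<- c(labels, lab)
    }
    add_static(k_dep - 1, s$roost[1], s$roost[2], ground_filler(k_dep - 1))
    alt_mu <- config$elevation_base +
      config$elevation_gain * hump_fraction(s$day_in_fdp, config)
    for (j in seq_len(n_fly)) {
      x <- c(x, vx[j]); y <- c(y, vy[j])
      speed <- c(speed, vspeed[j])
      alt <- c(alt, rnorm(1, alt_mu, 50))
      labels <- c(labels,
                  if (runif(1) < config$p_active_flight) "active_flight"
                  else "passive_flight")
      is_feed_here <- feeding && j == feed_vert
      is_loaf_here <- j %in% loaf_at
      if (is_feed_here || is_loaf_here) {
        if (is_feed_here) {
          ns <- feed_slots
          kind <- if (!is.null(s$feed_comp)) s$feed_comp else "feeding"
        } else {
          ns <- loaf_slots[match(j, loaf_at)]
          kind <- if (amb_idx == match(j, loaf_at)) "ambiguous" else "loafing"
        }
        st_start <- length(x)  # slot index of first stop fix = current fix
        add_static(ns, vx[j], vy[j], emit_stop_behaviors(kind, config, ns))
        stop_rec[[length(stop_rec) + 1]] <- data.frame(
          animal_id = s$animal_id, date = date, kind = kind,
          x_m = vx[j], y_m = vy[j],
          site_id = if (is_feed_here && !is.null(s$feed_site))
            s$feed_site$site_id else NA_character_,
          start = stamps[min(st_start, n_slot)],
          end = stamps[min(st_start + ns, n_slot)],
          stringsAsFactors = FALSE)
      }
    }
    n_rest <- max(0, n_slot - length(x))
    add_static(n_rest, s$roost[1], s$roost[2], ground_filler(n_rest))
    xy <- cbind(x = x[seq_len(n_slot)], y = y[seq_len(n_slot)])
    speed <- speed[seq_len(n_slot)]
    alt <- alt[seq_len(n_slot)]
    labels <- labels[seq_len(n_slot)]
  }

  xy[, 1] <- xy[, 1] + rnorm(n_slot, 0, config$gps_noise_m)
  xy[, 2] <- xy[, 2] + rnorm(n_slot, 0, config$gps_noise_m)
  keep <- runif(n_slot) >= config$p_missing_fix
  if (sum(keep) < 2) keep[1:2] <- TRUE

  fixes <- data.frame(
    animal_id = s$animal_id, timestamp = stamps[keep],
    x_m = xy[keep, 1], y_m = xy[keep, 2], altitude_m = alt[keep],
    ground_speed_ms = speed[keep], interpolated = FALSE,
    stringsAsFactors = FALSE)
  behaviors <- data.frame(
    animal_id = s$animal_id, timestamp = stamps, label = labels,
    stringsAsFactors = FALSE)
  stops <- if (length(stop_rec)) do.call(rbind, stop_rec) else NULL
  list(fixes = fixes, behaviors = behaviors, stops = stops)
}

#' Simulate a tracked population
#'
#' Generates a complete multi-animal GPS/behaviour dataset: roost colonies
#' and supplementary feeding stations are placed in a planar study region;
#' each animal feeds day-to-day under a memoryless (optionally seasonal)
#' feeding process; feeding days are always active, other days are active
#' with the probability that keeps the overall active fraction at
#' `p_active_day`; each day is realised by [simulate_vulture_day()].
#' Feeding stops land at an SFS with probability `p_feed_at_sfs` (the
#' station nearest the drawn displacement), otherwise at an occasional
#' carcass at the turnaround point. When two or more animals feed at the
#' same station on the same day with overlapping stop windows, all but the
#' first may be emitted with a single-eating composition, exercising the
#' co-feeding classification rule.
#'
#' The result is deterministic given `config$seed`. The `truth` ledger
#' (true feeding days, day-within-FDP, activity) is for recovery tests
#' only and is never consumed by the analysis path.
#'
#' @param config a [sim_config()].
#' @return object of class `fdp_track_dataset`: list with tibbles `fixes`,
#'   `behaviors`, `sites`, `sunrise`, `truth`, plus the `config`.
#' @export
simulate_population <- function(config) {
  config <- validate_sim_config(config)
  withr::with_seed(config$seed, simulate_population_impl(config))
}

simulate_population_impl <- function(config) {
  nv <- config$n_vultures
  nd <- config$n_days
  dates <- config$start_date + seq_len(nd) - 1
  months <- as.integer(format(dates, "%m"))
  p_feed <- monthly_feed_prob(months, config)
  # feeding days are always active; the remainder are active with the
  # probability that restores the marginal active fraction
  q_act <- pmin(1, pmax(0, (config$p_active_day - p_feed) / (1 - p_feed)))

  half <- config$region_km * 1000 / 2
  colonies <- cbind(runif(config$n_colonies, -half, half),
                    runif(config$n_colonies, -half, half))
  sfs <- cbind(runif(config$n_sfs, -half * 2, half * 2),
               runif(config$n_sfs, -half * 2, half * 2))
  sites <- tibble::tibble(
    site_id = c(sprintf("R%02d", seq_len(config$n_colonies)),
                sprintf("S%02d", seq_len(config$n_sfs))),
    kind = c(rep("roost", config$n_colonies), rep("sfs", config$n_sfs)),
    x_m = c(colonies[, 1], sfs[, 1]),
    y_m = c(colonies[, 2], sfs[, 2]),
    radius_m = c(rep(500, config$n_colonies), rep(400, config$n_sfs)))

  ids <- sprintf("V%02d", seq_len(nv))
  colony_of <- rep_len(seq_len(config$n_colonies), nv)
  roost_x <- colonies[colony_of, 1] + runif(nv, -50, 50)
  roost_y <- colonies[colony_of, 2] + runif(nv, -50, 50)

  sunrise_h <- parse_clock(config$sunrise_time)

  # --- plan stage: feeding calendar, activity, feeding-site assignments ---
  plans <- vector("list", nv)
  feed_plan <- list()
  for (a in seq_len(nv)) {
    feeding <- runif(nd) < p_feed
    active <- feeding | (runif(nd) < q_act)
    d_in <- integer(nd)
    last <- 0L
    for (i in seq_len(nd)) {
      d_in[i] <- if (feeding[i]) 0L else i - last
      if (feeding[i]) last <- i
    }
    ambiguous <- !feeding & active & runif(nd) < config$p_ambiguous_day
    plans[[a]] <- list(feeding = feeding, active = active, d_in = d_in,
                       ambiguous = ambiguous)
    for (i in which(feeding)) {
      D <- draw_displacement(d_in[i], config)
      at_sfs <- runif(1) < config$p_feed_at_sfs
      site_id <- NA_character_
      if (at_sfs) {
        dist_km <- sqrt((sfs[, 1] - roost_x[a])^2 +
                        (sfs[, 2] - roost_y[a])^2) / 1000
        k <- which.min(abs(dist_km - D))
        D <- dist_km[k]
        site_id <- sprintf("S%02d", k)
      }
      t_dep <- sunrise_h + trunc_norm_pos(1, config$departure_mean,
                                          config$departure_sd)
      feed_slots <- max(4, round(60 * min(4, max(1,
        rnorm(1, config$feeding_stop_hours, 0.5))) / config$fix_interval))
      t_arr <- t_dep + D * 1000 * config$tortuosity / config$speed_mean / 3600
      feed_plan[[length(feed_plan) + 1]] <- data.frame(
        a = a, i = i, site_id = site_id, D = D, t_dep = t_dep,
        feed_slots = feed_slots, t_arr = t_arr,
        t_end = t_arr + feed_slots * config$fix_interval / 60,
        comp = "feeding", stringsAsFactors = FALSE)
    }
  }
  fp <- if (length(feed_plan)) do.call(rbind, feed_plan) else
    data.frame(a = integer(0))

  # co-feeding: within each station-day, later-arriving overlapping
  # feeders may carry a single-eating composition (rule-iii fodder).
  # A downgrade needs a generous planned overlap and a slack slot budget
  # on both sides, so the realised stop windows still overlap after grid
  # quantisation and cannot be shortened by the day-length guard.
  if (nrow(fp) > 0) {
    dt <- config$fix_interval * 60
    n_slot <- length(duty_slots(config))
    leg_steps <- pmax(2, round(config$tortuosity * fp$D * 1000 /
                                 (config$speed_mean * dt)))
    need_est <- ceiling(pmax(0, fp$t_dep - config$duty_start) * 60 /
                          config$fix_interval) +
      2 * leg_steps + fp$feed_slots + 4 * 9
    safe <- need_est <= n_slot - 1
    key <- paste(fp$i, fp$site_id)
    for (g in split(seq_len(nrow(fp)), key)) {
      if (length(g) < 2 || is.na(fp$site_id[g[1]])) next
      g <- g[order(fp$t_arr[g])]
      anchor <- g[1]
      for (j in g[-1]) {
        overlap <- min(fp$t_end[anchor], fp$t_end[j]) -
          max(fp$t_arr[anchor], fp$t_arr[j])
        if (overlap >= 1 && safe[anchor] && safe[j] &&
            runif(1) < config$p_rule3_downgrade) {
          fp$comp[j] <- "feeding_single"
        }
      }
    }
  }

  # --- generation stage ---
  fx <- bh <- st <- vector("list", nv * nd)
  truth <- vector("list", nv)
  k <- 0
  for (a in seq_len(nv)) {
    pl <- plans[[a]]
    fpa <- fp[fp$a == a, , drop = FALSE]
    for (i in seq_len(nd)) {
      k <- k + 1
      state <- list(animal_id = ids[a], date = dates[i],
                    day_in_fdp = pl$d_in[i], month = months[i],
                    active = pl$active[i], feeding = pl$feeding[i],
                    ambiguous = pl$ambiguous[i],
                    roost = c(roost_x[a], roost_y[a]), ground_alt = 300)
      if (pl$feeding[i]) {
        row <- fpa[fpa$i == i, ]
        state$t_dep_h <- row$t_dep
        state$displacement_km <- row$D
        state$feed_slots <- row$feed_slots
        state$feed_comp <- row$comp
        if (!is.na(row$site_id)) {
          sr <- sites[sites$site_id == row$site_id, ]
          state$feed_site <- list(x = sr$x_m, y = sr$y_m,
                                  site_id = row$site_id)
        }
      }
      day <- simulate_vulture_day(state, config)
      fx[[k]] <- day$fixes
      bh[[k]] <- day$behaviors
      st[[k]] <- day$stops
    }
    site_by_day <- rep(NA_character_, nd)
    site_by_day[fpa$i] <- fpa$site_id
    comp_by_day <- rep(NA_character_, nd)
    comp_by_day[fpa$i] <- fpa$comp
    truth[[a]] <- data.frame(
      animal_id = ids[a], date = dates, feeding = pl$feeding,
      active = pl$active, day_in_fdp = pl$d_in,
      ambiguous = pl$ambiguous, site_id = site_by_day,
      at_sfs = pl$feeding & !is.na(site_by_day),
      feed_comp = comp_by_day, stringsAsFactors = FALSE)
  }

  structure(list(
    fixes = tibble::as_tibble(dplyr::bind_rows(fx)),
    behaviors = tibble::as_tibble(dplyr::bind_rows(bh)),
    sites = sites,
    sunrise = tibble::tibble(date = dates, time = config$sunrise_time),
    truth = tibble::as_tibble(dplyr::bind_rows(truth)),
    truth_stops = tibble::as_tibble(dplyr::bind_rows(st)),
    config = config), class = "fdp_track_dataset")
}

#' @export
print.fdp_track_dataset <- function(x, ...) {
  cat(sprintf(
    "<fdp_track_dataset> %d animals, %d days, %d fixes, %d behaviour bursts\n",
    length(unique(x$truth$animal_id)), length(unique(x$truth$date)),
    nrow(x$fixes), nrow(x$behaviors)))
  invisible(x)
}
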