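#' Simulation configuration for the synthetic biologging generator
#'
#' Builds and validates the parameter set driving [simulate_population()].
#' The defaults are the packaged "field calibration": a supplementary-fed
#' griffon vulture population sampled at 10-min GPS/ACC intervals over a
#' 12-h diurnal duty cycle, with roughly 10% dropped fixes, 90% active
#' days, a memoryless day-to-day feeding process whose zero-day
#' food-deprivation-period (FDP) fraction is 52%, a hump-shaped dependence
#' of daily movement on day-within-FDP peaking at day 5, path tortuosity
#' 1.62 (mean daily straightness 1/1.62 = 0.617), roost departure on
#' average 3 h after sunrise, and 71.4% of feeding stops at supplementary
#' feeding stations (SFS).
#'
#' @param n_vultures number of tracked animals.
#' @param n_days number of tracking days per animal.
#' @param start_date first tracking day (`Date` or coercible).
#' @param fix_interval GPS/ACC sampling interval, minutes; must divide the
#'   duty window.
#' @param duty_start,duty_end local clock hours bounding the diurnal duty
#'   cycle during which the tag samples.
#' @param p_missing_fix probability that any scheduled fix is dropped.
#' @param p_active_day probability that an animal-day is active (leaves the
#'   roost beyond the 2-km activity radius).
#' @param fdp_p0 per-day feeding probability of the memoryless feeding
#'   process when seasonality is off; equals the expected fraction of
#'   zero-day FDPs.
#' @param seasonal logical; if `TRUE`, the per-day feeding probability is
#'   derived per calendar month from `monthly_long_prop`.
#' @param monthly_long_prop length-12 vector of target monthly proportions
#'   of feeding events with FDP >= 6 days (winter maximum, early-summer
#'   minimum, secondary autumn bump); converted to monthly feeding
#'   probability via p(m) = 1 - prop^(1/6).
#' @param hump_peak_day day-within-FDP at which expected displacement
#'   peaks, days.
#' @param hump_base,hump_gain baseline and peak-added expected maximal
#'   displacement of an active day, km.
#' @param displacement_cv coefficient of variation of the per-day
#'   displacement draw around its hump mean.
#' @param tortuosity path-length inflation factor (>= 1); daily travel
#'   distance of an active day is about `tortuosity * 2 * displacement`,
#'   so expected straightness is `1/tortuosity`.
#' @param departure_mean,departure_sd roost-departure offset after sunrise,
#'   hours (Normal, truncated at 0).
#' @param speed_mean,speed_sd cross-country ground speed of flight fixes,
#'   m/s.
#' @param elevation_base,elevation_gain baseline and peak-added mean flight
#'   altitude (a.s.l.), m, following the same hump profile.
#' @param stop_rate expected number of non-roost day-stops per active day
#'   (Poisson, truncated at 4).
#' @param p_feed_at_sfs probability a feeding stop is at an SFS.
#' @param p_rule2_comp probability a feeding stop carries the
#'   single-eating-plus-running composition instead of two or more eating
#'   bursts.
#' @param p_rule3_downgrade probability that a feeding stop sharing an SFS
#'   (with temporal overlap) with another feeder is emitted with a single
#'   eating burst and no running, so that it is only recoverable through
#'   the co-feeding rule.
#' @param p_ambiguous_day probability a non-feeding animal-day contains an
#'   "undecided" stop composition (one eating, one running).
#' @param eating_burst_rate,running_burst_rate expected eating/running
#'   burst counts of a feeding stop.
#' @param feeding_stop_hours mean duration of a feeding stop, hours.
#' @param n_sfs number of supplementary feeding stations.
#' @param n_colonies number of roost colonies animals are assigned to.
#' @param region_km half-width of the square study region, km.
#' @param gps_noise_m s.d. of isotropic GPS position noise, m.
#' @param sunrise_time fixed local sunrise clock time, "HH:MM".
#' @param p_active_flight probability a flight fix is flapping (active)
#'   rather than soaring (passive) flight.
#' @param seed integer seed making the whole dataset reproducible.
#'
#' @return A validated list of class `fdp_sim_config`.
#' @export
sim_config <- function(n_vultures = 20,
                       n_days = 200,
                       start_date = as.Date("2010-01-01"),
                       fix_interval = 10,
                       duty_start = 6,
                       duty_end = 18,
                       p_missing_fix = 0.10,
                       p_active_day = 0.90,
                       fdp_p0 = 0.52,
                       seasonal = TRUE,
                       monthly_long_prop = c(0.15, 0.15, 0.11, 0.08,
                                             0.05, 0.05, 0.06, 0.07,
                                             0.10, 0.10, 0.12, 0.14),
                       hump_peak_day = 5,
                       hump_base = 12,
                       hump_gain = 8,
                       displacement_cv = 0.25,
                       tortuosity = 1.62,
                       departure_mean = 3.0,
                       departure_sd = 1.0,
                       speed_mean = 10,
                       speed_sd = 1.5,
                       elevation_base = 400,
                       elevation_gain = 200,
                       stop_rate = 1.5,
                       p_feed_at_sfs = 0.714,
                       p_rule2_comp = 0.02,
                       p_rule3_downgrade = 0.5,
                       p_ambiguous_day = 0.02,
                       eating_burst_rate = 4,
                       running_burst_rate = 1,
                       feeding_stop_hours = 2.75,
                       n_sfs = 25,
                       n_colonies = 4,
                       region_km = 60,
                       gps_noise_m = 15,
                       sunrise_time = "05:42",
                       p_active_flight = 0.15,
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$start_date <- as.Date(start_date)
  class(cfg) <- "fdp_sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "fdp_sim_config"))
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
      stop(sprintf("`%s` must be a probability in [0, 1]", nm), call. = FALSE)
    }
  }
  for (nm in c("p_missing_fix", "p_active_day", "p_feed_at_sfs",
               "p_rule2_comp", "p_rule3_downgrade", "p_ambiguous_day",
               "p_active_flight", "monthly_long_prop")) {
    chk_prob(cfg[[nm]], nm)
  }
  if (!is.numeric(cfg$fdp_p0) || cfg$fdp_p0 <= 0 || cfg$fdp_p0 > 1) {
    stop("`fdp_p0` must lie in (0, 1]", call. = FALSE)
  }
  if (length(cfg$monthly_long_prop) != 12) {
    stop("`monthly_long_prop` must have one value per calendar month",
         call. = FALSE)
  }
  if (cfg$tortuosity < 1) stop("`tortuosity` must be >= 1", call. = FALSE)
  if (cfg$hump_peak_day < 1) stop("`hump_peak_day` must be >= 1", call. = FALSE)
  if (cfg$n_vultures < 1) stop("`n_vultures` must be >= 1", call. = FALSE)
  if (cfg$n_days < 2) stop("`n_days` must be >= 2", call. = FALSE)
  duty_min <- (cfg$duty_end - cfg$duty_start) * 60
  if (duty_min <= 0) stop("duty window must have positive length", call. = FALSE)
  if (duty_min %% cfg$fix_interval != 0) {
    stop("`fix_interval` must divide the duty window", call. = FALSE)
  }
  cfg
}

#' Analysis thresholds and run options
#'
#' Collects every named threshold of the processing pipeline so that the
#' computational functions carry no literal cut-offs: the 2-km activity
#' radius, the 4 m/s static/non-static ground-speed boundary, the 400-m /
#' 20-min day-stop rule, the 14-day FDP validity cap, the 10-day cap on
#' sequences entering model fits, the short (1-4) / long (>= 6) sequence
#' categories, and the co-feeding (rule-iii) spatio-temporal window.
#'
#' @param activity_km displacement radius (km) beyond which a day is active
#'   (strict inequality).
#' @param static_ms ground speed (m/s) at or below which a fix is static
#'   (non-static requires speed strictly above).
#' @param stop_radius_m maximal distance (m) of a member fix from the
#'   running stop centroid.
#' @param stop_min_minutes minimal stop span, minutes (strict inequality).
#' @param fdp_cap FDPs longer than this many days are discarded as
#'   unrealistic.
#' @param model_max_fdp sequences longer than this are excluded from the
#'   day-within-FDP model fits.
#' @param short_range inclusive FDP range defining short sequences.
#' @param long_min minimal FDP of a long sequence.
#' @param rule3_radius_m centroid separation (m) within which two
#'   temporally overlapping stops count as co-located for the co-feeding
#'   rule.
#' @param site_radius_m fallback point-in-radius distance (m) for site
#'   membership when the site table has no radius column.
#' @param subset which feeding events enter the analysis: all events, only
#'   those at an SFS, or only those at occasional carcasses.
#' @param fit_grand_means logical; fit response models to per-day grand
#'   means instead of vulture-by-day mean cells.
#' @param straightness_convention `"out_and_back"` (2 * Dmax / L, clipped
#'   to 1) or `"to_farthest"` (Dmax over the distance travelled up to the
#'   farthest point).
#'
#' @return A validated list of class `fdp_run_config`.
#' @export
run_config <- function(activity_km = 2,
                       static_ms = 4,
                       stop_radius_m = 400,
                       stop_min_minutes = 20,
                       fdp_cap = 14,
                       model_max_fdp = 10,
                       short_range = c(1, 4),
                       long_min = 6,
                       rule3_radius_m = 400,
                       site_radius_m = 400,
                       subset = c("all", "sfs", "occasional"),
                       fit_grand_means = FALSE,
                       straightness_convention = c("out_and_back",
                                                   "to_farthest")) {
  subset <- match.arg(subset)
  straightness_convention <- match.arg(straightness_convention)
  cfg <- list(activity_km = activity_km, static_ms = static_ms,
              stop_radius_m = stop_radius_m,
              stop_min_minutes = stop_min_minutes,
              fdp_cap = fdp_cap, model_max_fdp = model_max_fdp,
              short_range = short_range, long_min = long_min,
              rule3_radius_m = rule3_radius_m,
              site_radius_m = site_radius_m,
              subset = subset, fit_grand_means = fit_grand_means,
              straightness_convention = straightness_convention)
  class(cfg) <- "fdp_run_config"
  pos <- c("activity_km", "static_ms", "stop_radius_m", "stop_min_minutes",
           "fdp_cap", "model_max_fdp", "rule3_radius_m", "site_radius_m")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop(sprintf("`%s` must be positive", nm), call. = FALSE)
    }
  }
  if (length(short_range) != 2 || short_range[1] > short_range[2]) {
    stop("`short_range` must be an increasing length-2 range", call. = FALSE)
  }
  if (short_range[2] >= long_min) {
    stop("short upper bound must fall below `long_min`", call. = FALSE)
  }
  cfg
}
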