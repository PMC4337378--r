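test_that("stop classification applies the feeding rules", {
  d <- "2010-03-01"
  stops <- dplyr::bind_rows(
    stop_row("V01", d, x = 5000, eating = 3, stop_id = 1L),
    stop_row("V02", d, x = 5000, eating = 1, running = 2, stop_id = 2L),
    stop_row("V03", d, x = 5000, eating = 1, running = 1, stop_id = 3L),
    stop_row("V04", d, x = 9000, eating = 0, running = 1, stop_id = 4L),
    stop_row("V05", d, x = 0, eating = 3, stop_id = 5L))  # inside roost
  cls <- classify_stops(stops, roost_site(0, 0))
  expect_equal(cls$classification,
               c("feeding", "feeding", "undecided", "none", "none"))
  expect_equal(cls$feeding_rule[1:2], c("i", "ii"))
  expect_true(cls$in_roost[5])
})

test_that("co-feeding rescues lone eating stops near active feeders", {
  d <- "2010-03-01"
  base <- dplyr::bind_rows(
    stop_row("V01", d, x = 5000, start_h = 10, eating = 3, stop_id = 1L),
    stop_row("V02", d, x = 5100, start_h = 10.5, eating = 1, stop_id = 2L))
  cls <- classify_stops(base, empty_sites())
  expect_equal(cls$classification[2], "feeding")
  expect_equal(cls$feeding_rule[2], "iii")

  # too far away
  far <- base
  far$x_m[2] <- 7000
  expect_equal(classify_stops(far, empty_sites())$classification[2],
               "none")
  # no temporal overlap
  late <- base
  late$start[2] <- late$start[2] + 6 * 3600
  late$end[2] <- late$end[2] + 6 * 3600
  expect_equal(classify_stops(late, empty_sites())$classification[2],
               "none")
  # a lone eater cannot rescue another lone eater
  lone2 <- base
  lone2$n_eating[1] <- 1L
  expect_equal(classify_stops(lone2, empty_sites())$classification,
               c("none", "none"))
})

test_that("co-feeding resolution is independent of row order", {
  d <- "2010-03-01"
  stops <- dplyr::bind_rows(
    stop_row("V01", d, x = 5000, start_h = 10, eating = 3, stop_id = 1L),
    stop_row("V02", d, x = 5050, start_h = 11, eating = 1, stop_id = 2L),
    stop_row("V03", d, x = 5100, start_h = 10.2, eating = 1, stop_id = 3L),
    stop_row("V04", d, x = 20000, start_h = 10, eating = 1, stop_id = 4L))
  ref <- classify_stops(stops, empty_sites())
  withr::with_seed(31, {
    for (i in 1:10) {
      perm <- sample(nrow(stops))
      got <- classify_stops(stops[perm, ], empty_sites())
      expect_equal(got$classification[order(got$stop_id)],
                   ref$classification[order(ref$stop_id)])
    }
  })
})

test_that("feeding events collapse to one per animal-day with SFS flags", {
  d <- "2010-03-01"
  stops <- dplyr::bind_rows(
    stop_row("V01", d, x = 5000, start_h = 9, eating = 2, stop_id = 1L),
    stop_row("V01", d, x = 9000, start_h = 14, eating = 4, stop_id = 2L),
    stop_row("V02", d, x = 9020, start_h = 14, eating = 0, stop_id = 3L))
  cls <- classify_stops(stops, sfs_site(9000, 0))
  ev <- build_feeding_events(cls)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$animal_id, "V01")
  expect_equal(ev$stop_id, 1L)        # earliest feeding stop referenced
  expect_false(ev$at_sfs)             # that stop is away from the station
})

test_that("FDP computation counts whole gap days and applies exclusions", {
  mk_ev <- function(dates, id = "V01") {
    tibble::tibble(animal_id = id, date = as.Date(dates),
                   stop_id = seq_along(dates), at_sfs = TRUE,
                   site_id = "S01", feeding_rule = "i")
  }
  days <- metric_days("V01", as.Date("2010-03-01") + 0:40)
  nostops <- stop_row("V09", "2010-01-01", eating = 0)[0, ]

  ev <- compute_fdp(mk_ev(c("2010-03-01", "2010-03-02", "2010-03-06",
                            "2010-03-23")), days, nostops)
  expect_true(is.na(ev$fdp[1]))
  expect_equal(ev$exclusion_reason[1], "unknown_history")
  expect_equal(ev$fdp[2:4], c(0L, 3L, 16L))
  expect_equal(ev$valid[2:4], c(TRUE, TRUE, FALSE))
  expect_equal(ev$exclusion_reason[4], "fdp_over_14")

  # missing day strictly inside the gap invalidates
  days2 <- metric_days("V01", as.Date("2010-03-01") + 0:40)
  days2$missing_day[days2$date == as.Date("2010-03-04")] <- TRUE
  ev2 <- compute_fdp(mk_ev(c("2010-03-01", "2010-03-06")), days2, nostops)
  expect_equal(ev2$exclusion_reason[2], "missing_day_in_gap")

  # undecided stop inside the gap invalidates; on the feeding day it
  # does not
  und <- stop_row("V01", "2010-03-04", x = 5000, eating = 1, running = 1)
  und$classification <- "undecided"
  ev3 <- compute_fdp(mk_ev(c("2010-03-01", "2010-03-06")), days, und)
  expect_equal(ev3$exclusion_reason[2], "undecided_in_gap")
  und_on_feed <- stop_row("V01", "2010-03-06", x = 5000, eating = 1,
                          running = 1)
  und_on_feed$classification <- "undecided"
  ev4 <- compute_fdp(mk_ev(c("2010-03-01", "2010-03-06")), days,
                     und_on_feed)
  expect_true(ev4$valid[2])
})

test_that("sequences carry day rows 0..fdp and category labels", {
  ev <- tibble::tibble(
    animal_id = "V01",
    date = as.Date(c("2010-03-05", "2010-03-10", "2010-03-16",
                     "2010-03-22")),
    stop_id = 1:4, at_sfs = TRUE, site_id = "S01", feeding_rule = "i",
    fdp = c(4L, 4L, 5L, 5L), valid = TRUE, exclusion_reason = "none")
  days <- metric_days("V01", as.Date("2010-02-25") + 0:30)
  sq <- build_sequences(ev, days)
  expect_equal(unique(sq$category[sq$fdp == 4]), "short")
  expect_equal(unique(sq$category[sq$fdp == 5]), "mid")
  s1 <- sq[sq$event_id == 1, ]
  expect_equal(s1$day_index, 0:4)
  expect_equal(s1$date, as.Date("2010-02-28") + 0:4)

  ev$fdp <- c(0L, 6L, 2L, 12L)
  sq2 <- build_sequences(ev, days)
  expect_equal(unique(sq2$category[sq2$fdp == 0]), "zero")
  expect_equal(unique(sq2$category[sq2$fdp == 6]), "long")
  expect_equal(nrow(sq2[sq2$fdp == 0, ]), 1)

  # a day without metrics drops the sequence with a warning
  expect_warning(
    sq3 <- build_sequences(ev, days[days$date > as.Date("2010-03-06"), ]),
    "dropped")
  expect_false(2 %in% sq3$event_id)
})

test_that("FDP histogram counts events and monthly long shares", {
  ev <- tibble::tibble(
    animal_id = "V01",
    date = as.Date(c("2010-01-03", "2010-01-10", "2010-01-15",
                     "2010-01-20", "2010-02-05")),
    fdp = c(0L, 0L, 1L, 6L, 3L), valid = TRUE,
    exclusion_reason = "none", at_sfs = TRUE)
  h <- fdp_histogram(ev)
  expect_equal(h$counts$n[h$counts$fdp %in% 0:6],
               c(2L, 1L, 0L, 1L, 0L, 0L, 1L))
  expect_equal(h$monthly$prop_long[1], 0.25)
  expect_equal(h$monthly$n_events[2], 1L)
  empty <- fdp_histogram(ev[0, ])
  expect_true(all(empty$counts$n == 0))
})

test_that("event subsets split SFS from occasional carcasses", {
  ev <- tibble::tibble(animal_id = "V01", date = as.Date("2010-03-01"),
                       at_sfs = c(TRUE, FALSE))
  expect_equal(nrow(apply_event_subset(ev, "all")), 2)
  expect_true(all(apply_event_subset(ev, "sfs")$at_sfs))
  expect_false(any(apply_event_subset(ev, "occasional")$at_sfs))
})

test_that("detected feeding days and FDPs round-trip the generator truth", {
  cfg <- small_sim(seed = 13, n_vultures = 5, n_days = 90,
                   p_ambiguous_day = 0)
  rep <- run_synthetic_pipeline(cfg)
  tr <- rep$dataset$truth

  det <- sort(paste(rep$events$animal_id, rep$events$date))
  tru <- sort(paste(tr$animal_id, tr$date)[tr$feeding])
  expect_identical(det, tru)

  # recovered FDP equals the truth gap for every non-first event
  truth_fdp <- do.call(rbind, lapply(split(tr, tr$animal_id), function(t) {
    f <- which(t$feeding)
    if (length(f) < 2) return(NULL)
    data.frame(animal_id = t$animal_id[1], date = t$date[f[-1]],
               fdp = diff(f) - 1L)
  }))
  got <- rep$events[!is.na(rep$events$fdp), c("animal_id", "date", "fdp")]
  mg <- merge(truth_fdp, got, by = c("animal_id", "date"))
  expect_equal(nrow(mg), nrow(got))
  expect_equal(mg$fdp.x, mg$fdp.y)
})

test_that("tightening the co-feeding window never adds events", {
  cfg <- small_sim(seed = 14, n_vultures = 6, n_days = 60,
                   p_rule3_downgrade = 1)
  ds <- simulate_population(cfg)
  rep_loose <- run_pipeline(ds$fixes, ds$behaviors, ds$sites, ds$sunrise,
                            run_config(rule3_radius_m = 400))
  rep_tight <- run_pipeline(ds$fixes, ds$behaviors, ds$sites, ds$sunrise,
                            run_config(rule3_radius_m = 1))
  expect_lte(nrow(rep_tight$events), nrow(rep_loose$events))
})
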