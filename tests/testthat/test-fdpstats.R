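seq_table <- function(rows) {
  # rows: list of c(animal, event, fdp, day, value)
  df <- do.call(rbind, lapply(rows, function(r) {
    tibble::tibble(animal_id = r[[1]], event_id = as.integer(r[[2]]),
                   fdp = as.integer(r[[3]]), day_index = as.integer(r[[4]]),
                   travel_distance = as.numeric(r[[5]]))
  }))
  df$category <- ifelse(df$fdp >= 6, "long",
                        ifelse(df$fdp >= 1 & df$fdp <= 4, "short",
                               ifelse(df$fdp == 0, "zero", "mid")))
  df$date <- as.Date("2010-03-01") + df$day_index
  df
}

test_that("per-vulture day means average within individuals first", {
  one <- seq_table(list(c("V01", 1, 2, 0, 10), c("V01", 1, 2, 1, 20),
                        c("V01", 1, 2, 2, 30)))
  pvm <- per_vulture_day_means(one, "travel_distance")
  expect_equal(pvm$cells$value, c(10, 20, 30))

  two <- seq_table(list(c("V01", 1, 1, 1, 10), c("V01", 2, 1, 1, 20),
                        c("V01", 1, 1, 0, 5), c("V01", 2, 1, 0, 5)))
  pvm2 <- per_vulture_day_means(two, "travel_distance")
  expect_equal(pvm2$cells$value[pvm2$cells$day_index == 1], 15)

  long <- seq_table(lapply(0:12, function(d) c("V01", 1, 12, d, 99)))
  pvm3 <- per_vulture_day_means(long, "travel_distance")
  expect_equal(nrow(pvm3$cells), 0)

  expect_error(per_vulture_day_means(one, "no_such_metric"), "unknown")
})

test_that("AICc follows the corrected least-squares formula", {
  expect_equal(aicc(10, 11, 2), 11 * log(10 / 11) + 4 + 1.5,
               tolerance = 1e-12)
  expect_gt(aicc(10, 20, 4), aicc(10, 20, 2))
  expect_true(is.na(aicc(5, 3, 2)))
  expect_error(aicc(-1, 10, 2), "rss")
})

test_that("model selection recovers the generating shape", {
  mk <- function(f, vultures = 5, noise = 0, seed = 1) {
    withr::with_seed(seed, {
      cells <- expand.grid(animal_id = sprintf("V%02d", 1:vultures),
                           day_index = 0:10)
      cells$value <- f(cells$day_index) + rnorm(nrow(cells), 0, noise)
      list(cells = tibble::as_tibble(cells),
           summary = NULL)
    })
  }
  quad <- fit_response_models(mk(function(d) 30 - (d - 5)^2))
  expect_equal(quad$model[quad$selected], "quadratic")
  expect_equal(quad$vertex[3], 5, tolerance = 1e-6)

  flat <- fit_response_models(mk(function(d) rep(10, length(d)),
                                 noise = 0.01))
  expect_equal(flat$model[flat$selected], "constant")

  lin <- fit_response_models(mk(function(d) 2 * d))
  expect_equal(lin$model[lin$selected], "linear")

  expect_true(all(quad$delta >= 0))
  expect_equal(sum(quad$selected), 1)
})

test_that("AICc selection is consistent over seeded replicates", {
  # day-profile scale: 10 vultures contribute noisy cells, the profile is
  # fit to the 11 per-day grand means
  run_case <- function(f, noise, seed) {
    withr::with_seed(seed, {
      cells <- expand.grid(animal_id = sprintf("V%02d", 1:10),
                           day_index = 0:10)
      cells$value <- f(cells$day_index) + rnorm(nrow(cells), 0, noise)
    })
    sm <- aggregate(value ~ day_index, data = cells, FUN = mean)
    dm <- list(cells = cells,
               summary = data.frame(day_index = sm$day_index,
                                    mean = sm$value))
    fits <- fit_response_models(dm, use_grand_means = TRUE)
    fits$model[fits$selected]
  }
  # quadratic signal amplitude 3x the per-cell residual sd
  hump <- vapply(1:100, function(s) {
    run_case(function(d) 12 * pmax(0, 1 - ((d - 5) / 5)^2), 4, s)
  }, character(1))
  expect_gte(sum(hump == "quadratic"), 95)

  flat <- vapply(1:100, function(s) {
    run_case(function(d) rep(50, length(d)), 4, 1000 + s)
  }, character(1))
  expect_gte(sum(flat == "constant"), 90)
})

test_that("Benjamini-Yekutieli matches brute force and p.adjust", {
  expect_equal(benjamini_yekutieli(0.04, 0.05), 1L)
  expect_equal(benjamini_yekutieli(0.06, 0.05), integer(0))
  expect_equal(benjamini_yekutieli(c(0.005, 0.02, 0.5)), 1L)
  expect_equal(benjamini_yekutieli(rep(1, 5)), integer(0))
  expect_equal(benjamini_yekutieli(numeric(0)), integer(0))

  brute_by <- function(p, alpha) {
    m <- length(p)
    cm <- sum(1 / seq_len(m))
    ps <- sort(p)
    k <- 0
    for (i in seq_len(m)) {
      if (ps[i] <= i * alpha / (m * cm)) k <- i
    }
    if (k == 0) return(integer(0))
    sort(which(p <= ps[k] + 1e-15))
  }
  withr::with_seed(41, {
    for (i in 1:1000) {
      m <- sample(1:20, 1)
      p <- runif(m)^sample(1:3, 1)
      alpha <- runif(1, 0.01, 0.2)
      mine <- benjamini_yekutieli(p, alpha)
      expect_identical(mine, brute_by(p, alpha))
      expect_identical(mine,
                       sort(which(stats::p.adjust(p, "BY") <= alpha)))
    }
  })
})

test_that("hungry-vs-satiated contrast pairs flanking days per vulture", {
  dates <- as.Date("2010-03-01") + 0:20
  met <- dplyr::bind_rows(
    metric_days("V01", dates, travel = 10),
    metric_days("V02", dates, travel = 12),
    metric_days("V03", dates, travel = 14))
  # after-day travel lower: set day 11 (after events on day 10)
  met$travel_distance[met$date == dates[12]] <-
    c(7, 8, 9)[match(met$animal_id[met$date == dates[12]],
                     c("V01", "V02", "V03"))]
  ev <- tibble::tibble(animal_id = c("V01", "V02", "V03"),
                       date = dates[11], valid = TRUE,
                       at_sfs = TRUE)
  out <- hungry_vs_satiated(met, ev, metrics_family = "travel_distance")
  expect_equal(out$n_vultures, 3)
  expect_equal(out$mean_diff, 4)
  expect_equal(out$statistic, 4 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(out$direction, "higher_when_hungry")

  # identical flanking days: p = 1, nothing rejected
  met2 <- met
  met2$travel_distance <- 10
  out2 <- hungry_vs_satiated(met2, ev, metrics_family = "travel_distance")
  expect_equal(out2$p, 1)
  expect_false(out2$significant)

  # a missing before-day drops the pair
  met3 <- met
  met3$missing_day[met3$animal_id == "V03" &
                     met3$date == dates[10]] <- TRUE
  out3 <- hungry_vs_satiated(met3, ev, metrics_family = "travel_distance")
  expect_equal(out3$n_vultures, 2)

  # flanking feeding days exclude the event
  ev4 <- dplyr::bind_rows(ev,
    tibble::tibble(animal_id = "V01", date = dates[12], valid = TRUE,
                   at_sfs = TRUE))
  out4 <- hungry_vs_satiated(met, ev4, metrics_family = "travel_distance")
  expect_equal(out4$n_vultures[1], 2)

  # sign-permutation alternative agrees on direction
  out5 <- hungry_vs_satiated(met, ev, metrics_family = "travel_distance",
                             test = "sign_permutation")
  expect_lt(out5$p, 0.3)
})

test_that("balanced repeated-measures decomposition matches hand sums", {
  y <- c(1, 2, 3, 4, 2, 3, 4, 5)
  tab <- fdpscan:::balanced_rm_anova(
    y,
    subject = rep(c("S1", "S2"), each = 4),
    f1 = rep(rep(c("a", "b"), each = 2), 2),
    f2 = rep(c("d1", "d2"), 4))
  gs <- function(e) tab$ss[tab$effect == e]
  expect_equal(gs("type"), 8)
  expect_equal(gs("day"), 2)
  expect_equal(gs("subject"), 2)
  expect_equal(gs("type:day"), 0)
  expect_equal(gs("subject:type") + gs("subject:day") + gs("residual"), 0)
  expect_true(attr(tab, "degenerate"))
  expect_equal(sum(tab$ss), sum((y - mean(y))^2))

  zero <- fdpscan:::balanced_rm_anova(
    rep(3, 8),
    subject = rep(c("S1", "S2"), each = 4),
    f1 = rep(rep(c("a", "b"), each = 2), 2),
    f2 = rep(c("d1", "d2"), 4))
  expect_true(all(zero$ss == 0))
})

test_that("repeated-measures ANOVA agrees with the aov error strata", {
  withr::with_seed(42, {
    cells <- expand.grid(subject = sprintf("S%d", 1:6),
                         type = c("short", "long"), day = 1:4,
                         stringsAsFactors = FALSE)
    cells$y <- rnorm(nrow(cells), 40, 5) +
      ifelse(cells$type == "long", 6, 0) + cells$day
  })
  mine <- fdpscan:::balanced_rm_anova(cells$y, cells$subject, cells$type,
                                      cells$day)
  ref <- summary(stats::aov(
    y ~ type * factor(day) + Error(factor(subject) / (type * factor(day))),
    data = cells))
  get <- function(stratum, row) {
    tb <- ref[[stratum]][[1]]
    tb[grep(row, rownames(tb), fixed = TRUE)[1], ]
  }
  expect_equal(mine$F[mine$effect == "type"],
               get("Error: factor(subject):type", "type")$`F value`,
               tolerance = 1e-8)
  expect_equal(mine$p[mine$effect == "day"],
               get("Error: factor(subject):factor(day)",
                   "factor(day)")$`Pr(>F)`,
               tolerance = 1e-8)
  expect_equal(mine$F[mine$effect == "type:day"],
               get("Error: factor(subject):type:factor(day)",
                   "type:factor(day)")$`F value`,
               tolerance = 1e-8)
  # SS conservation at 1e-9 relative tolerance
  expect_equal(sum(mine$ss), sum((cells$y - mean(cells$y))^2),
               tolerance = 1e-9)
})

test_that("short-vs-long ANOVA applies the inclusion rule", {
  rows <- list()
  mkseq <- function(animal, event, fdp, amp) {
    lapply(1:min(fdp, 4), function(d) {
      c(animal, event, fdp, d, amp + 2 * d)
    })
  }
  ev <- 0
  for (v in c("V01", "V02", "V03")) {
    for (i in 1:3) {
      ev <- ev + 1
      rows <- c(rows, mkseq(v, ev, 4, 40))
      ev <- ev + 1
      rows <- c(rows, mkseq(v, ev, 7, 52))
    }
  }
  # V04 has long sequences only: excluded by the inclusion rule
  for (i in 1:3) {
    ev <- ev + 1
    rows <- c(rows, mkseq("V04", ev, 7, 70))
  }
  sq <- seq_table(rows)
  withr::with_seed(43, {
    sq$travel_distance <- sq$travel_distance + rnorm(nrow(sq), 0, 0.5)
  })
  tab <- rm_anova_short_long(sq, "travel_distance")
  expect_false("V04" %in% attr(tab, "subjects"))
  expect_equal(sort(attr(tab, "subjects")), c("V01", "V02", "V03"))
  expect_gt(tab$F[tab$effect == "type"], 10)
  expect_lt(tab$p[tab$effect == "type"], 0.05)

  sq_short_only <- sq[sq$fdp == 4, ]
  expect_error(rm_anova_short_long(sq_short_only, "travel_distance"),
               "inclusion")
})

test_that("exponential histogram fit recovers decay parameters", {
  exact <- 100 * exp(-0.5 * 0:6)
  f <- fit_exponential_fdp(exact)
  expect_equal(f$A, 100, tolerance = 1e-9)
  expect_equal(f$b, 0.5, tolerance = 1e-9)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)

  counts <- c(2257, 1014, 456, 205, 92, 41, 19, 8, 4, 2, 1)
  f2 <- fit_exponential_fdp(counts)
  expect_lt(abs(f2$b - 0.8), 0.02)
  expect_gte(f2$r_squared, 0.99)

  f3 <- fit_exponential_fdp(rep(7, 5))
  expect_equal(f3$b, 0, tolerance = 1e-12)

  expect_error(fit_exponential_fdp(c(5, 0, 0, 3)), "nonzero")
})
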