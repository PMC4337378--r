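#' @importFrom stats lm coef resid pf pt t.test aggregate complete.cases
NULL

#' Per-vulture means of a metric along the day-within-FDP axis
#'
#' Averages the metric at each day index `d` over all of a vulture's FDP
#' sequences (one value per vulture-day cell), which controls
#' pseudo-replication among events of the same individual. Sequences
#' longer than `max_fdp` days are excluded. Also returns the per-day grand
#' mean with the standard error between individual means (the error bars
#' of the day-profile figures).
#'
#' @param sequences tidy sequence table from [build_sequences()].
#' @param metric name of the metric column.
#' @param max_fdp longest sequence admitted, days.
#' @return list with `cells` (tibble `animal_id`, `day_index`, `value`,
#'   `n_seqs`) and `summary` (tibble `day_index`, `mean`, `se`,
#'   `n_vultures`).
#' @export
per_vulture_day_means <- function(sequences, metric, max_fdp = 10) {
  if (!metric %in% names(sequences)) {
    stop(sprintf("unknown metric '%s'", metric), call. = FALSE)
  }
  sq <- sequences[sequences$fdp <= max_fdp, , drop = FALSE]
  sq$value <- as.numeric(sq[[metric]])
  sq <- sq[!is.na(sq$value), , drop = FALSE]
  cells <- dplyr::summarise(
    dplyr::group_by(sq, .data$animal_id, .data$day_index),
    value = mean(.data$value), n_seqs = dplyr::n(), .groups = "drop")
  summary <- dplyr::summarise(
    dplyr::group_by(cells, .data$day_index),
    mean = mean(.data$value),
    se = stats::sd(.data$value) / sqrt(dplyr::n()),
    n_vultures = dplyr::n(), .groups = "drop")
  list(cells = cells, summary = summary)
}

#' Small-sample corrected Akaike information criterion for least squares
#'
#' `n * log(rss/n) + 2k + 2k(k+1)/(n-k-1)`, with `k` counting the residual
#' variance as a parameter and an epsilon floor on the RSS guarding exact
#' fits. Inadmissible when `n <= k + 1`.
#'
#' @param rss residual sum of squares.
#' @param n number of observations.
#' @param k parameter count including the residual variance.
#' @return AICc score, or `NA` when inadmissible.
#' @export
aicc <- function(rss, n, k) {
  if (rss < 0) stop("`rss` must be non-negative", call. = FALSE)
  if (n <= k + 1) return(NA_real_)
  n * log(max(rss, 1e-12) / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit and select among constant, linear and quadratic response models
#'
#' Fits `Y = C`, `Y = a + bX` and `Y = a + bX + cX^2` by ordinary least
#' squares to the day-profile observations and selects the model with the
#' smallest AICc (ties broken toward fewer parameters). By default the
#' observations are the vulture-by-day mean cells, weighting each vulture
#' equally; `use_grand_means = TRUE` fits the per-day grand means instead.
#'
#' @param day_means result of [per_vulture_day_means()].
#' @param use_grand_means fit grand means rather than vulture-level cells.
#' @return tibble with one row per model: `model`, coefficients `c0`,
#'   `c1`, `c2` (intercept, slope, curvature), `rss`, `n`, `k`, `aicc`,
#'   `delta`, `selected`, and `vertex` (`-b/2a`, quadratic only).
#' @export
fit_response_models <- function(day_means, use_grand_means = FALSE) {
  obs <- if (use_grand_means) {
    data.frame(x = day_means$summary$day_index, y = day_means$summary$mean)
  } else {
    data.frame(x = day_means$cells$day_index, y = day_means$cells$value)
  }
  obs <- obs[complete.cases(obs), ]
  if (length(unique(obs$x)) < 3) {
    stop("need at least 3 distinct day indices to fit response models",
         call. = FALSE)
  }
  n <- nrow(obs)
  fits <- list(
    constant = lm(y ~ 1, data = obs),
    linear = lm(y ~ x, data = obs),
    quadratic = lm(y ~ x + I(x^2), data = obs))
  ks <- c(constant = 2, linear = 3, quadratic = 4)
  out <- tibble::tibble(
    model = names(fits),
    c0 = NA_real_, c1 = NA_real_, c2 = NA_real_,
    rss = NA_real_, n = n, k = unname(ks),
    aicc = NA_real_, delta = NA_real_, selected = FALSE,
    vertex = NA_real_)
  for (i in seq_along(fits)) {
    cf <- coef(fits[[i]])
    out$c0[i] <- cf[1]
    if (length(cf) > 1) out$c1[i] <- cf[2]
    if (length(cf) > 2) out$c2[i] <- cf[3]
    out$rss[i] <- sum(resid(fits[[i]])^2)
    out$aicc[i] <- aicc(out$rss[i], n, out$k[i])
  }
  out$vertex[3] <- if (!is.na(out$c2[3]) && out$c2[3] != 0) {
    -out$c1[3] / (2 * out$c2[3])
  } else NA_real_
  adm <- which(!is.na(out$aicc))
  if (!length(adm)) stop("no admissible model at this sample size",
                         call. = FALSE)
  best <- min(out$aicc[adm])
  out$delta <- out$aicc - best
  # tie-break toward fewer parameters: rows are ordered by k
  out$selected[adm[which(out$aicc[adm] <= best + 1e-9)[1]]] <- TRUE
  out
}

#' Benjamini-Yekutieli step-up false-discovery-rate control
#'
#' Step-up procedure valid under arbitrary dependence: with `m` p-values
#' sorted increasingly, find the largest `i` with
#' `p_(i) <= i * alpha / (m * c(m))`, `c(m) = sum_{j=1}^m 1/j`, and reject
#' all hypotheses with p-values up to `p_(i)`.
#'
#' @param p_values vector of p-values in `[0, 1]`.
#' @param alpha target FDR level.
#' @return integer indices (into `p_values`) of rejected hypotheses.
#' @export
benjamini_yekutieli <- function(p_values, alpha = 0.05) {
  m <- length(p_values)
  if (m == 0) return(integer(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  cm <- sum(1 / seq_len(m))
  ord <- order(p_values)
  ps <- p_values[ord]
  thr <- seq_len(m) * alpha / (m * cm)
  k <- suppressWarnings(max(which(ps <= thr)))
  if (!is.finite(k)) return(integer(0))
  sort(ord[seq_len(k)])
}

HUNGRY_METRICS <- c("travel_distance", "max_displacement",
                    "flight_elevation", "straightness", "mean_speed",
                    "prop_active_flight", "departure_offset", "active")

#' Hungry-versus-satiated paired contrast around feeding events
#'
#' Compares movement characteristics on the day before a feeding event
#' (hungry) with the day after it (satiated). Flanking days must be
#' present, not missing, and not themselves feeding days. Values are
#' averaged per vulture on each side, the across-vulture difference is
#' tested with a paired t-test (or a sign-permutation test), and the
#' p-value family is corrected with [benjamini_yekutieli()].
#'
#' @param metrics daily-metrics table.
#' @param events feeding-event table.
#' @param metrics_family metric columns to contrast.
#' @param test `"t"` or `"sign_permutation"`.
#' @param alpha FDR level of the BY correction.
#' @param n_perm Monte-Carlo draws when permutation is not enumerable.
#' @return tibble per metric: `n_vultures`, `mean_hungry`,
#'   `mean_satiated`, `mean_diff`, `statistic`, `p`, `significant`
#'   (BY-adjusted), `direction`.
#' @export
hungry_vs_satiated <- function(metrics, events,
                               metrics_family = HUNGRY_METRICS,
                               test = c("t", "sign_permutation"),
                               alpha = 0.05, n_perm = 2000) {
  test <- match.arg(test)
  metrics_family <- intersect(metrics_family, names(metrics))
  feed_key <- paste(events$animal_id, events$date)
  mkey <- paste(metrics$animal_id, metrics$date)

  before <- match(paste(events$animal_id, events$date - 1), mkey)
  after <- match(paste(events$animal_id, events$date + 1), mkey)
  usable <- !is.na(before) & !is.na(after) &
    !metrics$missing_day[before] & !metrics$missing_day[after] &
    !(paste(events$animal_id, events$date - 1) %in% feed_key) &
    !(paste(events$animal_id, events$date + 1) %in% feed_key)

  rows <- list()
  for (met in metrics_family) {
    b <- as.numeric(metrics[[met]][before[usable]])
    a <- as.numeric(metrics[[met]][after[usable]])
    id <- events$animal_id[usable]
    ok <- !is.na(b) & !is.na(a)
    if (!any(ok)) next
    bm <- tapply(b[ok], id[ok], mean)
    am <- tapply(a[ok], id[ok], mean)
    d <- bm - am
    nv <- length(d)
    if (nv < 3 || stats::sd(d) == 0 && test == "t") {
      rows[[met]] <- tibble::tibble(
        metric = met, n_vultures = nv, mean_hungry = mean(bm),
        mean_satiated = mean(am), mean_diff = mean(d),
        statistic = NA_real_,
        p = if (nv >= 3 && stats::sd(d) == 0 && all(d == 0)) 1 else NA_real_)
      next
    }
    if (test == "t") {
      tt <- t.test(bm, am, paired = TRUE)
      stat <- unname(tt$statistic)
      p <- tt$p.value
    } else {
      obs <- mean(d)
      if (nv <= 14) {
        signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), nv)))
        perm <- signs %*% d / nv
      } else {
        perm <- replicate(n_perm,
                          mean(d * sample(c(-1, 1), nv, replace = TRUE)))
      }
      stat <- obs
      p <- mean(abs(perm) >= abs(obs) - 1e-12)
    }
    rows[[met]] <- tibble::tibble(
      metric = met, n_vultures = nv, mean_hungry = mean(bm),
      mean_satiated = mean(am), mean_diff = mean(d), statistic = stat,
      p = p)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  rej <- benjamini_yekutieli(out$p, alpha)
  out$significant <- seq_len(nrow(out)) %in% rej
  out$direction <- ifelse(out$mean_diff > 0, "higher_when_hungry",
                          ifelse(out$mean_diff < 0,
                                 "lower_when_hungry", "none"))
  out
}

#' Two-way repeated-measures ANOVA of short versus long FDP sequences
#'
#' Compares a movement metric between short FDP sequences and the
#' corresponding early days of long sequences, with vultures as subjects
#' and sequence type and day as within-subject factors. Only vultures
#' with at least `min_sequences` long sequences and `min_sequences`
#' sequences of FDP exactly equal to the short upper bound enter; cell
#' means over that vulture's qualifying sequences balance the design.
#' Classical balanced sums-of-squares decomposition; each factor is
#' tested against its interaction with subjects.
#'
#' @param sequences tidy sequence table from [build_sequences()].
#' @param metric metric column name.
#' @param days day indices compared (default 1-4).
#' @param min_sequences inclusion threshold per type.
#' @param config a [run_config()].
#' @return tibble ANOVA table (`effect`, `ss`, `df`, `ms`, `F`, `p`) with
#'   attributes `degenerate` (logical) and `subjects` (ids used).
#' @export
rm_anova_short_long <- function(sequences, metric, days = 1:4,
                                min_sequences = 3,
                                config = run_config()) {
  short_len <- config$short_range[2]
  sq <- sequences
  sq$value <- as.numeric(sq[[metric]])
  ev <- unique(sq[, c("animal_id", "event_id", "fdp")])
  n_long <- table(ev$animal_id[ev$fdp >= config$long_min])
  n_short <- table(ev$animal_id[ev$fdp == short_len])
  subjects <- intersect(names(n_long)[n_long >= min_sequences],
                        names(n_short)[n_short >= min_sequences])
  if (!length(subjects)) {
    stop("no subject satisfies the sequence-count inclusion rule",
         call. = FALSE)
  }
  use <- sq$animal_id %in% subjects & sq$day_index %in% days &
    (sq$fdp == short_len | sq$fdp >= config$long_min) & !is.na(sq$value)
  sq <- sq[use, , drop = FALSE]
  sq$type <- ifelse(sq$fdp >= config$long_min, "long", "short")
  cells <- aggregate(value ~ animal_id + type + day_index, data = sq,
                     FUN = mean)
  full <- expand.grid(animal_id = subjects, type = c("short", "long"),
                      day_index = days, stringsAsFactors = FALSE)
  cells <- merge(full, cells, all.x = TRUE)
  if (anyNA(cells$value)) {
    drop <- unique(cells$animal_id[is.na(cells$value)])
    warning(sprintf("dropping %d subjects with empty cells", length(drop)))
    cells <- cells[!cells$animal_id %in% drop, ]
    subjects <- setdiff(subjects, drop)
    if (!length(subjects)) stop("no complete subject remains", call. = FALSE)
  }
  balanced_rm_anova(cells$value,
                    subject = cells$animal_id,
                    f1 = cells$type, f2 = cells$day_index)
}

# Classical balanced two-within-factor repeated-measures decomposition.
balanced_rm_anova <- function(y, subject, f1, f2) {
  subject <- factor(subject)
  f1 <- factor(f1)
  f2 <- factor(f2)
  S <- nlevels(subject)
  A <- nlevels(f1)
  B <- nlevels(f2)
  g <- mean(y)
  eff <- function(index) tapply(y, index, mean)
  ms <- eff(subject)
  ma <- eff(f1)
  mb <- eff(f2)
  mab <- tapply(y, list(f1, f2), mean)
  msa <- tapply(y, list(subject, f1), mean)
  msb <- tapply(y, list(subject, f2), mean)

  ss_s <- A * B * sum((ms - g)^2)
  ss_a <- S * B * sum((ma - g)^2)
  ss_b <- S * A * sum((mb - g)^2)
  ss_ab <- S * sum((sweep(sweep(mab, 1, ma), 2, mb) + g)^2)
  ss_sa <- B * sum((sweep(sweep(msa, 1, ms), 2, ma) + g)^2)
  ss_sb <- A * sum((sweep(sweep(msb, 1, ms), 2, mb) + g)^2)
  ss_tot <- sum((y - g)^2)
  ss_sab <- ss_tot - ss_s - ss_a - ss_b - ss_ab - ss_sa - ss_sb

  df <- c(S - 1, A - 1, B - 1, (A - 1) * (B - 1),
          (S - 1) * (A - 1), (S - 1) * (B - 1),
          (S - 1) * (A - 1) * (B - 1))
  ss <- c(ss_s, ss_a, ss_b, ss_ab, ss_sa, ss_sb, max(0, ss_sab))
  msq <- ifelse(df > 0, ss / df, NA_real_)
  effect <- c("subject", "type", "day", "type:day",
              "subject:type", "subject:day", "residual")
  Fv <- rep(NA_real_, 7)
  pv <- rep(NA_real_, 7)
  err_for <- c(type = 5, day = 6, `type:day` = 7)
  for (nm in names(err_for)) {
    i <- match(nm, effect)
    e <- err_for[[nm]]
    if (df[e] > 0 && msq[e] > 0) {
      Fv[i] <- msq[i] / msq[e]
      pv[i] <- pf(Fv[i], df[i], df[e], lower.tail = FALSE)
    }
  }
  degenerate <- any(df[5:7] > 0 & ss[5:7] <= 1e-12) ||
    all(ss[5:7] <= 1e-12)
  out <- tibble::tibble(effect = effect, ss = ss, df = df, ms = msq,
                        F = Fv, p = pv)
  attr(out, "degenerate") <- degenerate
  attr(out, "subjects") <- levels(subject)
  out
}

#' Negative-exponential fit to the FDP histogram
#'
#' Fits `Y = A * exp(-b * x)` to histogram counts by least squares of
#' `log(counts)` on `x` over the nonzero bins, weighting each bin by its
#' count (the variance-stabilising weight for Poisson-like counts on the
#' log scale, which keeps near-empty tail bins from dominating the
#' slope), then computes the coefficient of determination on the count
#' scale against the fitted curve.
#'
#' @param counts integer counts by FDP value, or the `counts` tibble of
#'   [fdp_histogram()].
#' @param x FDP values of the bins (defaults to `0:(length-1)`).
#' @return list with `A`, `b`, `r_squared`, `n_bins`.
#' @export
fit_exponential_fdp <- function(counts, x = NULL) {
  if (is.data.frame(counts)) {
    x <- counts$fdp
    counts <- counts$n
  }
  if (is.null(x)) x <- seq_along(counts) - 1
  keep <- counts > 0
  if (sum(keep) < 3) {
    stop("need at least 3 nonzero histogram bins", call. = FALSE)
  }
  xx <- x[keep]
  yy <- counts[keep]
  fit <- lm(log(yy) ~ xx, weights = yy)
  A <- exp(coef(fit)[[1]])
  b <- -coef(fit)[[2]]
  pred <- A * exp(-b * xx)
  r2 <- 1 - sum((yy - pred)^2) / sum((yy - mean(yy))^2)
  list(A = A, b = b, r_squared = r2, n_bins = sum(keep))
}
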