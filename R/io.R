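#' @importFrom utils read.csv write.csv
NULL

WGS84_A <- 6378137
WGS84_E2 <- (1 / 298.257223563) * (2 - 1 / 298.257223563)

parse_timestamps <- function(x) {
  x <- gsub("T", " ", x, fixed = TRUE)
  x <- sub("Z$", "", x)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%d %H:%M"))
  if (anyNA(out)) {
    stop(sprintf("unparseable timestamp at row %d",
                 which(is.na(out))[1]), call. = FALSE)
  }
  out
}

#' Convert geographic to local planar coordinates
#'
#' Local flat-earth projection about the dataset centroid, using the
#' WGS84 meridional and normal curvature radii at the reference latitude
#' and each point's own latitude cosine for the east-west scale:
#' `x = N(lat0) * cos(lat) * (lon - lon0)`, `y = M(lat0) * (lat - lat0)`
#' (radians). Adequate at the ~100-km extent of a regional tracking
#' study, where the length distortion stays well below 0.1%.
#'
#' @param lon,lat geographic coordinates, degrees.
#' @param ref optional `c(lon0, lat0)` reference; defaults to the
#'   centroid.
#' @return data frame with `x_m`, `y_m` and the reference as an attribute.
#' @export
lonlat_to_planar <- function(lon, lat, ref = NULL) {
  if (is.null(ref)) ref <- c(mean(lon), mean(lat))
  rad <- pi / 180
  s2 <- sin(ref[2] * rad)^2
  n_rad <- WGS84_A / sqrt(1 - WGS84_E2 * s2)
  m_rad <- WGS84_A * (1 - WGS84_E2) / (1 - WGS84_E2 * s2)^1.5
  out <- data.frame(
    x_m = n_rad * cos(lat * rad) * (lon - ref[1]) * rad,
    y_m = m_rad * (lat - ref[2]) * rad)
  attr(out, "ref") <- ref
  out
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing columns: %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
}

maybe_project <- function(df) {
  if (!all(c("x_m", "y_m") %in% names(df)) &&
      all(c("lon", "lat") %in% names(df))) {
    pl <- lonlat_to_planar(df$lon, df$lat)
    df$x_m <- pl$x_m
    df$y_m <- pl$y_m
  }
  df
}

#' Read a GPS-fix table
#'
#' CSV with columns `animal_id`, `timestamp` (ISO-8601 UTC), planar
#' `x_m`/`y_m` (or `lon`/`lat`, converted through
#' [lonlat_to_planar()]), `altitude_m`, `ground_speed_ms` and optionally
#' `interpolated`. Timestamps must be strictly increasing per animal.
#'
#' @param path CSV file path.
#' @return validated, sorted tibble of fixes.
#' @export
read_fix_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("animal_id", "timestamp"), "fix table")
  if (nrow(df) == 0) {
    return(tibble::tibble(animal_id = character(),
                          timestamp = as.POSIXct(character(), tz = "UTC"),
                          x_m = numeric(), y_m = numeric(),
                          altitude_m = numeric(),
                          ground_speed_ms = numeric(),
                          interpolated = logical()))
  }
  df$timestamp <- parse_timestamps(df$timestamp)
  df <- maybe_project(df)
  require_columns(df, c("x_m", "y_m", "altitude_m", "ground_speed_ms"),
                  "fix table")
  if (is.null(df$interpolated)) df$interpolated <- FALSE
  # timestamps must already be strictly increasing per animal in file
  # order; silently sorting would mask corrupt exports
  for (id in unique(df$animal_id)) {
    rows <- which(df$animal_id == id)
    bad <- rows[which(diff(as.numeric(df$timestamp[rows])) <= 0)]
    if (length(bad)) {
      stop(sprintf(
        "non-increasing timestamps for animal %s near row %d",
        id, bad[1] + 1L), call. = FALSE)
    }
  }
  df <- df[order(df$animal_id, df$timestamp), ]
  if (any(df$ground_speed_ms < 0, na.rm = TRUE)) {
    stop("negative ground speeds in fix table", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Read a behaviour-label table
#'
#' CSV with columns `animal_id`, `timestamp`, `label`; labels must come
#' from the seven-class vocabulary.
#'
#' @param path CSV file path.
#' @return tibble of behaviour records.
#' @export
read_behavior_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("animal_id", "timestamp", "label"),
                  "behavior table")
  if (nrow(df) == 0) {
    return(tibble::tibble(animal_id = character(),
                          timestamp = as.POSIXct(character(), tz = "UTC"),
                          label = character()))
  }
  df$timestamp <- parse_timestamps(df$timestamp)
  bad <- setdiff(unique(df$label), BEHAVIOR_LABELS)
  if (length(bad)) {
    stop(sprintf("unknown behaviour labels: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  tibble::as_tibble(df[order(df$animal_id, df$timestamp), ])
}

#' Read a site table
#'
#' CSV with columns `site_id`, `kind` (`"sfs"` or `"roost"`), `x_m`,
#' `y_m` (or `lon`/`lat`) and `radius_m`.
#'
#' @param path CSV file path.
#' @return tibble of sites.
#' @export
read_site_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("site_id", "kind"), "site table")
  df <- maybe_project(df)
  if (nrow(df)) {
    require_columns(df, c("x_m", "y_m", "radius_m"), "site table")
    bad <- setdiff(unique(df$kind), c("sfs", "roost"))
    if (length(bad)) {
      stop(sprintf("unknown site kinds: %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    }
  }
  tibble::as_tibble(df)
}

#' Read a sunrise table
#'
#' CSV with columns `date` (ISO) and `time` ("HH:MM" local sunrise).
#'
#' @param path CSV file path.
#' @return tibble with `date` (Date) and `time`.
#' @export
read_sunrise_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  require_columns(df, c("date", "time"), "sunrise table")
  tibble::tibble(date = as.Date(df$date), time = df$time)
}

#' Write a synthetic track dataset as CSV files
#'
#' Emits `fixes.csv`, `behaviors.csv`, `sites.csv` and `sunrise.csv` into
#' `dir` using the schemas the readers expect; the truth ledger is only
#' written on request (it must never feed the analysis path).
#'
#' @param dataset an `fdp_track_dataset` from [simulate_population()].
#' @param dir output directory (created if absent).
#' @param include_truth also write `truth.csv`.
#' @return `dir`, invisibly.
#' @export
write_track_dataset <- function(dataset, dir, include_truth = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fx <- dataset$fixes
  fx$timestamp <- format(fx$timestamp, "%Y-%m-%dT%H:%M:%SZ")
  write.csv(fx, file.path(dir, "fixes.csv"), row.names = FALSE)
  bh <- dataset$behaviors
  bh$timestamp <- format(bh$timestamp, "%Y-%m-%dT%H:%M:%SZ")
  write.csv(bh, file.path(dir, "behaviors.csv"), row.names = FALSE)
  write.csv(dataset$sites, file.path(dir, "sites.csv"), row.names = FALSE)
  write.csv(dataset$sunrise, file.path(dir, "sunrise.csv"),
            row.names = FALSE)
  if (include_truth) {
    write.csv(dataset$truth, file.path(dir, "truth.csv"),
              row.names = FALSE)
  }
  invisible(dir)
}
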