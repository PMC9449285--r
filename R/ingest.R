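# Log ingestion: reading, accuracy filtering, active-user selection, and
# collapsing duplicate-minute logs into representative points.

#' Read a GPS log table
#'
#' Reads a delimited log table with columns `uuid, year, month, day, hour,
#' minute, lat, lon, accuracy_m` and optional `sex, age_group, daily_steps`.
#' Timestamps have minute resolution; rows whose coordinates or timestamp
#' components fail to parse are dropped with a warning stating the count.
#'
#' @param path Path to a delimited text file (comma- or tab-separated, with
#'   header).
#' @return A tibble of logs with columns `uuid`, `timestamp` (minute
#'   resolution), `lat`, `lon`, `accuracy_m`, `sex`, `age_group`,
#'   `daily_steps`.
#' @export
read_gps_logs <- function(path) {
  required <- c("uuid", "year", "month", "day", "hour", "minute",
                "lat", "lon", "accuracy_m")
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    rlang::abort(paste0("log table is missing required column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "stepscape_schema_error")
  }
  for (col in c("sex", "age_group", "daily_steps")) {
    if (!col %in% names(raw)) raw[[col]] <- NA_character_
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  parsed <- tibble::tibble(
    uuid = raw$uuid,
    year = num(raw$year), month = num(raw$month), day = num(raw$day),
    hour = num(raw$hour), minute = num(raw$minute),
    lat = num(raw$lat), lon = num(raw$lon),
    accuracy_m = num(raw$accuracy_m),
    sex = dplyr::coalesce(raw$sex, "unknown"),
    age_group = dplyr::coalesce(raw$age_group, "unknown"),
    daily_steps = num(raw$daily_steps)
  )
  ok <- stats::complete.cases(parsed[c("year", "month", "day", "hour", "minute",
                                       "lat", "lon")]) &
    is.finite(parsed$lat) & is.finite(parsed$lon)
  if (any(!ok)) {
    rlang::warn(paste0("dropped ", sum(!ok), " row(s) with unparseable coordinates or timestamps"))
  }
  parsed <- parsed[ok, ]
  parsed$timestamp <- lubridate::make_datetime(
    parsed$year, parsed$month, parsed$day, parsed$hour, parsed$minute, 0
  )
  dplyr::select(parsed, "uuid", "timestamp", "lat", "lon", "accuracy_m",
                "sex", "age_group", "daily_steps")
}

#' Filter logs by horizontal GPS accuracy
#'
#' Retains logs whose horizontal positioning error is strictly less than
#' `max_error_m` and whose user identifier is non-empty.
#'
#' @param logs A log tibble (see [read_gps_logs()]).
#' @param max_error_m Accuracy cut-off in metres; default 200. The boundary
#'   is excluded (`accuracy_m < max_error_m`).
#' @return The filtered log tibble.
#' @export
filter_accuracy <- function(logs, max_error_m = 200) {
  dplyr::filter(
    logs,
    !is.na(.data$accuracy_m), .data$accuracy_m < max_error_m,
    !is.na(.data$uuid), .data$uuid != ""
  )
}

#' Index valid user-days and active users
#'
#' A date is valid for a user when that user has at least `min_logs` logs on
#' the date (at least one log per 30 minutes over a 12-hour activity
#' window); a user is active when they have more than `min_valid_days - 1`
#' valid days.
#'
#' @param logs Accuracy-filtered log tibble.
#' @param min_logs Minimum logs per valid day; default 24.
#' @param min_valid_days Minimum number of valid days for an active user;
#'   default 11 ("more than 10").
#' @return A tibble with one row per observed user-day: `uuid`, `date`,
#'   `n_logs`, `valid`, `active`.
#' @export
index_valid_days <- function(logs, min_logs = 24, min_valid_days = 11) {
  logs |>
    dplyr::mutate(date = .log_date(.data$timestamp)) |>
    dplyr::count(.data$uuid, .data$date, name = "n_logs") |>
    dplyr::mutate(valid = .data$n_logs >= min_logs) |>
    dplyr::group_by(.data$uuid) |>
    dplyr::mutate(active = sum(.data$valid) >= min_valid_days) |>
    dplyr::ungroup()
}

#' Keep logs of active users on their valid days
#'
#' @param logs Accuracy-filtered log tibble.
#' @param index A user-day index from [index_valid_days()] built from these
#'   logs.
#' @return The log tibble restricted to active users' valid days.
#' @export
select_active <- function(logs, index) {
  keep <- dplyr::filter(index, .data$valid, .data$active)
  logs |>
    dplyr::mutate(date = .log_date(.data$timestamp)) |>
    dplyr::semi_join(keep, by = c("uuid", "date")) |>
    dplyr::select(-"date")
}

#' Collapse duplicate-minute logs into representative points
#'
#' The minimum time unit of the logs is one minute, so a user can have
#' several logs at the same minute. The representative location is the
#' unweighted arithmetic mean of latitude and of longitude over the
#' duplicates.
#'
#' @param logs Log tibble of active users.
#' @return A trajectory-point tibble with columns `uuid`, `timestamp`,
#'   `lat`, `lon`, `origin` (`"observed"`), one row per (uuid, minute),
#'   time-ordered within user.
#' @export
dedupe_minute <- function(logs) {
  logs |>
    dplyr::summarise(
      lat = mean(.data$lat), lon = mean(.data$lon),
      .by = c("uuid", "timestamp")
    ) |>
    dplyr::arrange(.data$uuid, .data$timestamp) |>
    dplyr::mutate(origin = "observed")
}
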