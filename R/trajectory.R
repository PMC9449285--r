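# Trajectory reconstruction: straight-line interpolation between
# consecutive observed points at one-minute resolution, followed by removal
# of interpolated points landing on invalid days (create-then-delete).

#' Interpolate between two consecutive trajectory points
#'
#' For a time gap of `dt` whole minutes, emits exactly `dt - 1` points at
#' equally spaced positions on the straight segment between the pair in
#' longitude/latitude degree space (planar, not geodesic); point `i` lies at
#' fraction `i / dt` along the segment with timestamp `t(a) + i` minutes.
#' Endpoints are not emitted: a 5-minute gap yields 4 points at the four
#' intermediate minutes, a 2-minute gap yields the midpoint, and a 1-minute
#' gap yields nothing.
#'
#' @param a,b One-row trajectory-point data frames (`uuid`, `timestamp`,
#'   `lat`, `lon`) with the same `uuid` and `timestamp(b) > timestamp(a)`.
#' @return A tibble of interpolated points (`uuid`, `timestamp`, `lat`,
#'   `lon`, `origin = "interpolated"`), possibly empty.
#' @export
interpolate_pair <- function(a, b) {
  if (!identical(a$uuid, b$uuid)) {
    rlang::abort("cannot interpolate between points of different users",
      class = "stepscape_identity_error")
  }
  dt <- as.numeric(difftime(b$timestamp, a$timestamp, units = "mins"))
  if (!isTRUE(dt > 0)) {
    rlang::abort("points must be strictly ordered in time",
      class = "stepscape_ordering_error")
  }
  dt <- as.integer(round(dt))
  if (dt <= 1L) {
    return(tibble::tibble(
      uuid = character(), timestamp = a$timestamp[0], lat = numeric(),
      lon = numeric(), origin = character()
    ))
  }
  i <- seq_len(dt - 1L)
  frac <- i / dt
  tibble::tibble(
    uuid = a$uuid,
    timestamp = a$timestamp + 60 * i,
    lat = a$lat + frac * (b$lat - a$lat),
    lon = a$lon + frac * (b$lon - a$lon),
    origin = "interpolated"
  )
}

#' Interpolate all users' trajectories and purge invalid days
#'
#' Generates interpolated points between every pair of consecutive observed
#' points of each user -- including pairs spanning midnight or multi-day
#' gaps -- and then deletes every interpolated point whose calendar date is
#' not a valid day for that user. Observed points pass through unchanged.
#'
#' @param points Observed trajectory points ([dedupe_minute()] output).
#' @param index User-day index from [index_valid_days()].
#' @param max_gap_minutes Optional guard: gaps longer than this are not
#'   interpolated. `Inf` (default) applies no cap.
#' @return Time-sorted trajectory tibble (`uuid`, `timestamp`, `lat`,
#'   `lon`, `origin`).
#' @export
interpolate_points <- function(points, index, max_gap_minutes = Inf) {
  pts <- dplyr::arrange(points, .data$uuid, .data$timestamp)
  n <- nrow(pts)
  if (n == 0L) return(dplyr::mutate(pts, origin = character(0)))
  same_user <- c(pts$uuid[-1] == pts$uuid[-n], FALSE)
  dt <- c(as.numeric(difftime(pts$timestamp[-1], pts$timestamp[-n], units = "mins")), NA)
  dt <- as.integer(round(dt))
  gap <- which(same_user & dt >= 2L & dt <= max_gap_minutes)
  if (length(gap)) {
    n_new <- dt[gap] - 1L
    src <- rep.int(gap, n_new)
    step <- sequence(n_new)
    frac <- step / rep.int(dt[gap], n_new)
    interp <- tibble::tibble(
      uuid = pts$uuid[src],
      timestamp = pts$timestamp[src] + 60 * step,
      lat = pts$lat[src] + frac * (pts$lat[src + 1L] - pts$lat[src]),
      lon = pts$lon[src] + frac * (pts$lon[src + 1L] - pts$lon[src]),
      origin = "interpolated"
    )
    valid_days <- index |>
      dplyr::filter(.data$valid) |>
      dplyr::select("uuid", "date")
    interp <- interp |>
      dplyr::mutate(date = .log_date(.data$timestamp)) |>
      dplyr::semi_join(valid_days, by = c("uuid", "date")) |>
      dplyr::select(-"date")
    out <- dplyr::bind_rows(pts, interp)
  } else {
    out <- pts
  }
  dplyr::arrange(out, .data$uuid, .data$timestamp)
}
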