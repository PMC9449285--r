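# Spatial aggregation of predicted steps: day-type classification,
# per-user means, and 500 m residence-grid summaries with a disclosure
# rule.

#' Default holiday calendar for the October 2019 study window
#'
#' @return A Date vector (Health-Sports Day Oct 14 and the enthronement
#'   ceremony holiday Oct 22, 2019).
#' @export
default_holidays <- function() as.Date(c("2019-10-14", "2019-10-22"))

#' Default weekend pairs of October 2019
#'
#' @return Named list of Date vectors, one per weekend of the study month.
#' @export
default_weekend_pairs <- function() {
  list(
    weekend_1 = as.Date(c("2019-10-05", "2019-10-06")),
    weekend_2 = as.Date(c("2019-10-12", "2019-10-13")),
    weekend_3 = as.Date(c("2019-10-19", "2019-10-20")),
    weekend_4 = as.Date(c("2019-10-26", "2019-10-27"))
  )
}

#' Classify dates as weekday or weekend/holiday
#'
#' @param date Date vector.
#' @param holidays Date vector of public holidays; default
#'   [default_holidays()].
#' @return Character vector, `"weekday"` or `"weekend_holiday"`.
#' @export
classify_day <- function(date, holidays = default_holidays()) {
  wd <- lubridate::wday(date, week_start = 1)
  ifelse(wd >= 6 | date %in% holidays, "weekend_holiday", "weekday")
}

#' Per-user mean predicted steps by day type
#'
#' Computes each user's mean predicted daily steps over (a) weekdays, (b)
#' weekends and holidays pooled, and (c) each listed weekend pair
#' separately. A user with no dates in a cell contributes no row for it.
#'
#' @param predictions Tibble `uuid`, `date`, `predicted_steps`.
#' @param holidays Holiday calendar; default [default_holidays()].
#' @param weekend_pairs Named list of per-weekend date sets; default
#'   [default_weekend_pairs()].
#' @return A tibble `uuid`, `day_type`, `mean_steps`, `n_days`.
#' @export
user_day_means <- function(predictions, holidays = default_holidays(),
                           weekend_pairs = default_weekend_pairs()) {
  base <- predictions |>
    dplyr::mutate(day_type = classify_day(.data$date, holidays))
  per_weekend <- purrr::imap_dfr(weekend_pairs, function(dates, name) {
    predictions |>
      dplyr::filter(.data$date %in% dates) |>
      dplyr::mutate(day_type = name)
  })
  dplyr::bind_rows(base, per_weekend) |>
    dplyr::summarise(
      mean_steps = mean(.data$predicted_steps),
      n_days = dplyr::n(),
      .by = c("uuid", "day_type")
    ) |>
    dplyr::arrange(.data$uuid, .data$day_type)
}

#' 500 m residence-grid summaries of mean predicted steps
#'
#' Assigns each user to the 500 m grid square containing their residence
#' point and reports, per grid and day type, the number of resident users
#' and the unweighted mean of the users' mean steps. Grids with fewer than
#' `min_users` resident users are suppressed as non-assessable.
#'
#' @param user_means Output of [user_day_means()].
#' @param residences Valid-residence tibble ([estimate_residences()]).
#' @param min_users Disclosure threshold; default 5.
#' @return A tibble `grid_500m`, `day_type`, `n_users`, `mean_steps`.
#' @export
grid_summaries <- function(user_means, residences, min_users = 5) {
  res <- residences |>
    dplyr::filter(.data$status == "valid") |>
    dplyr::mutate(grid_500m = mesh_code(.data$residence_lat, .data$residence_lon, "500m")) |>
    dplyr::select("uuid", "grid_500m")
  user_means |>
    dplyr::inner_join(res, by = "uuid") |>
    dplyr::summarise(
      n_users = dplyr::n_distinct(.data$uuid),
      mean_steps = mean(.data$mean_steps),
      .by = c("grid_500m", "day_type")
    ) |>
    dplyr::filter(.data$n_users >= min_users) |>
    dplyr::arrange(.data$grid_500m, .data$day_type)
}

#' Write grid summaries as GeoJSON polygons
#'
#' @param summaries Output of [grid_summaries()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_grid_geojson <- function(summaries, path) {
  b <- mesh_bounds(summaries$grid_500m, "500m")
  features <- purrr::map(seq_len(nrow(summaries)), function(i) {
    ring <- list(
      c(b$west[i], b$south[i]), c(b$east[i], b$south[i]),
      c(b$east[i], b$north[i]), c(b$west[i], b$north[i]),
      c(b$west[i], b$south[i])
    )
    list(
      type = "Feature",
      geometry = list(type = "Polygon", coordinates = list(ring)),
      properties = list(
        grid_500m = summaries$grid_500m[i],
        day_type = summaries$day_type[i],
        n_users = summaries$n_users[i],
        mean_steps = summaries$mean_steps[i]
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Map grid summaries as a tile plot
#'
#' @param summaries Output of [grid_summaries()].
#' @param day_types Day types to facet; default all present.
#' @return A ggplot of 500 m cells coloured by mean predicted steps.
#' @export
plot_grid_summaries <- function(summaries, day_types = unique(summaries$day_type)) {
  dat <- dplyr::filter(summaries, .data$day_type %in% day_types)
  ctr <- mesh_centroid(dat$grid_500m, "500m")
  dat$lat <- ctr$lat
  dat$lon <- ctr$lon
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$lon, y = .data$lat,
                                    fill = .data$mean_steps)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~day_type) +
    ggplot2::coord_fixed(ratio = 1 / cos(mean(dat$lat) * pi / 180)) +
    ggplot2::scale_fill_viridis_c(name = "mean daily steps") +
    ggplot2::labs(x = "longitude", y = "latitude")
}
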