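# Residence estimation from daily first/last log clusters: 5% log sets,
# daily modal 250 m grids, merging of co-resident candidate grids, residence
# centroid, and removal of residential-grid points.

# per-group head/tail selector: first k and last k of n, whole set if 2k >= n
.five_percent_k <- function(n) pmax(1L, as.integer(ceiling(0.05 * n)))

#' First and last 5% of a day's points
#'
#' The "5% log set" of one user-date: the first `k` and last `k` points in
#' time order where `k = max(1, ceiling(0.05 n))`; when `2k >= n` the whole
#' day is returned.
#'
#' @param points Time-sorted trajectory points of a single user-date.
#' @return The subset tibble.
#' @export
five_percent_set <- function(points) {
  n <- nrow(points)
  if (n == 0L) return(points)
  k <- .five_percent_k(n)
  if (2L * k >= n) return(points)
  points[c(seq_len(k), seq.int(n - k + 1L, n)), ]
}

# 5% sets for all user-dates at once
.five_percent_all <- function(points) {
  points |>
    dplyr::mutate(date = .log_date(.data$timestamp)) |>
    dplyr::arrange(.data$uuid, .data$timestamp) |>
    dplyr::group_by(.data$uuid, .data$date) |>
    dplyr::filter({
      n <- dplyr::n()
      k <- .five_percent_k(n)
      rn <- dplyr::row_number()
      2L * k >= n | rn <= k | rn > n - k
    }) |>
    dplyr::ungroup()
}

#' Modal 250 m grid of a day's 5% log set
#'
#' @param points The 5% log set of one user-date.
#' @return The 250 m mesh code containing the most points; ties broken by
#'   the lexicographically smallest code.
#' @export
daily_modal_grid <- function(points) {
  codes <- mesh_code(points$lat, points$lon, "250m")
  tab <- table(codes)
  min(names(tab)[tab == max(tab)])
}

#' Estimate users' residence locations
#'
#' For each user: take the daily 5% log sets, find each date's modal 250 m
#' grid (one grid per day), and define the most frequent grid(s) across days
#' as the residential grid(s). Several tied grids are retained together only
#' when mutually co-resident (adjacent to each other or sharing a common
#' adjacent grid, [mesh_coresident()]); otherwise the user is residence
#' undefinable. The residence point is the arithmetic mean of all 5%-set
#' points falling inside the residential grid(s).
#'
#' @param points Trajectory points of active users (observed, or observed
#'   plus interpolated).
#' @param adjacency Contiguity rule for merging tied grids, `"queen"`
#'   (default) or `"rook"`.
#' @return A tibble with one row per user: `uuid`, `status` (`"valid"` or
#'   `"undefinable"`), `residential_grids` (list-column of 250 m codes),
#'   `residence_lat`, `residence_lon` (NA when undefinable).
#' @export
estimate_residences <- function(points, adjacency = c("queen", "rook")) {
  adjacency <- match.arg(adjacency)
  sets <- .five_percent_all(points)
  sets$code <- mesh_code(sets$lat, sets$lon, "250m")

  daily_modal <- sets |>
    dplyr::count(.data$uuid, .data$date, .data$code) |>
    dplyr::group_by(.data$uuid, .data$date) |>
    dplyr::filter(.data$n == max(.data$n)) |>
    dplyr::summarise(code = min(.data$code), .groups = "drop")

  res_grids <- daily_modal |>
    dplyr::count(.data$uuid, .data$code) |>
    dplyr::group_by(.data$uuid) |>
    dplyr::filter(.data$n == max(.data$n)) |>
    dplyr::summarise(residential_grids = list(sort(.data$code)), .groups = "drop") |>
    dplyr::mutate(status = purrr::map_chr(.data$residential_grids, function(g) {
      if (length(g) == 1L || mesh_coresident(g, adjacency)) "valid" else "undefinable"
    }))

  grid_long <- res_grids |>
    dplyr::filter(.data$status == "valid") |>
    dplyr::select("uuid", "residential_grids") |>
    tidyr::unnest("residential_grids") |>
    dplyr::rename(code = "residential_grids")

  centroids <- sets |>
    dplyr::semi_join(grid_long, by = c("uuid", "code")) |>
    dplyr::summarise(
      residence_lat = mean(.data$lat), residence_lon = mean(.data$lon),
      .by = "uuid"
    )

  res_grids |>
    dplyr::left_join(centroids, by = "uuid") |>
    dplyr::select("uuid", "status", "residential_grids",
                  "residence_lat", "residence_lon") |>
    dplyr::arrange(.data$uuid)
}

#' Remove points in users' residential grids
#'
#' Drops every trajectory point (observed or interpolated) whose 250 m grid
#' square is one of the user's residential grids. Points of users without a
#' row in `residences` pass through untouched.
#'
#' @param points Trajectory points.
#' @param residences Residence tibble from [estimate_residences()]; all rows
#'   must have `status == "valid"`.
#' @return The filtered trajectory tibble.
#' @export
filter_residential <- function(points, residences) {
  if (any(residences$status != "valid")) {
    rlang::abort("filter_residential applied to an undefinable residence; drop those users first",
      class = "stepscape_state_error")
  }
  grid_long <- residences |>
    dplyr::select("uuid", "residential_grids") |>
    tidyr::unnest("residential_grids") |>
    dplyr::rename(code = "residential_grids")
  gidx <- .mesh_indices(grid_long$code, "250m")
  grid_keys <- tibble::tibble(uuid = grid_long$uuid,
                              .key = gidx$row * 1e5 + gidx$col)
  pidx <- .mesh_point_indices(points$lat, points$lon, "250m")
  points$.key <- pidx$row * 1e5 + pidx$col
  out <- dplyr::anti_join(points, grid_keys, by = c("uuid", ".key"))
  dplyr::select(out, -".key")
}

# even-odd ray casting; ring is a data frame / matrix with lon, lat columns
.point_in_ring <- function(lat, lon, ring) {
  rx <- ring[, 1]; ry <- ring[, 2]
  m <- length(rx)
  inside <- rep(FALSE, length(lat))
  j <- m
  for (i in seq_len(m)) {
    crosses <- ((ry[i] > lat) != (ry[j] > lat)) &
      (lon < (rx[j] - rx[i]) * (lat - ry[i]) / (ry[j] - ry[i]) + rx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Restrict residences to a study region
#'
#' Keeps users whose residence point falls inside the region of interest
#' (e.g. the administrative area under study).
#'
#' @param residences Residence tibble with valid residence points.
#' @param region `NULL` or `"none"` for no restriction; a named vector/list
#'   with `west`, `east`, `south`, `north` (degrees) for a bounding box; or
#'   a two-column matrix/data frame of `lon`, `lat` ring vertices for a
#'   polygon.
#' @return The filtered residence tibble.
#' @export
restrict_region <- function(residences, region = NULL) {
  if (is.null(region) || identical(region, "none")) return(residences)
  lat <- residences$residence_lat
  lon <- residences$residence_lon
  if ((is.list(region) && !is.data.frame(region)) ||
      (is.numeric(region) && !is.null(names(region)))) {
    need <- c("west", "east", "south", "north")
    if (!all(need %in% names(region))) {
      rlang::abort("bounding-box region needs west, east, south, north",
        class = "stepscape_config_error")
    }
    keep <- lat >= region[["south"]] & lat < region[["north"]] &
      lon >= region[["west"]] & lon < region[["east"]]
  } else if ((is.matrix(region) || is.data.frame(region)) && ncol(region) == 2) {
    keep <- .point_in_ring(lat, lon, as.matrix(region))
  } else {
    rlang::abort("malformed region specification", class = "stepscape_config_error")
  }
  residences[which(keep), ]
}
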