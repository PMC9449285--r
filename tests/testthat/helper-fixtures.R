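# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except temporary files the tests write themselves.

# a raw-log tibble from compact arguments
make_logs <- function(uuid, timestamp, lat, lon, accuracy_m = 10,
                      sex = "unknown", age_group = "unknown",
                      daily_steps = NA_real_) {
  tibble::tibble(
    uuid = uuid,
    timestamp = as.POSIXct(timestamp, tz = "UTC"),
    lat = lat, lon = lon, accuracy_m = accuracy_m,
    sex = sex, age_group = age_group, daily_steps = daily_steps
  )
}

# n logs for one user on one date, minutes evenly spread from 08:00
day_of_logs <- function(uuid, date, n, lat = 38.26, lon = 140.87,
                        accuracy_m = 10) {
  make_logs(
    uuid = uuid,
    timestamp = as.POSIXct(paste(date, "08:00:00"), tz = "UTC") + 60 * seq_len(n),
    lat = lat, lon = lon, accuracy_m = accuracy_m
  )
}

# observed trajectory points (dedupe_minute output shape)
make_points <- function(uuid, timestamp, lat, lon, origin = "observed") {
  tibble::tibble(
    uuid = uuid,
    timestamp = as.POSIXct(timestamp, tz = "UTC"),
    lat = lat, lon = lon, origin = origin
  )
}

# a small rectangular land-use table of 100 m cells centred near Sendai;
# types cycle through all 8 classes deterministically
tiny_landscape <- function(n_rows = 30, n_cols = 30,
                           south = 38.25, west = 140.85) {
  r0 <- floor(south * 1200)
  c0 <- floor(west * 800)
  rows <- rep(r0:(r0 + n_rows - 1L), times = n_cols)
  cols <- rep(c0:(c0 + n_cols - 1L), each = n_rows)
  code <- stepscape:::.mesh_from_indices(rows, cols, "100m")
  types <- landuse_types()[(seq_along(code) - 1L) %% 8L + 1L]
  tibble::tibble(
    mesh_code_100m = code,
    reclassified_type = types,
    lat = (rows + 0.5) / 1200,
    lon = (cols + 0.5) / 800
  )
}

# independent O(N) buffer oracle: brute-force haversine scan over all cells
brute_force_buffer <- function(lat, lon, cells, radius_m = 100) {
  d <- if (requireNamespace("geosphere", quietly = TRUE)) {
    geosphere::distHaversine(cbind(lon, lat), cbind(cells$lon, cells$lat),
                             r = 6371000)
  } else {
    haversine_m(lat, lon, cells$lat, cells$lon)
  }
  cells[d <= radius_m, ]
}

# user-day index marking the given dates valid for a user
make_index <- function(uuid, dates, n_logs = 30) {
  tibble::tibble(
    uuid = uuid, date = as.Date(dates), n_logs = n_logs,
    valid = TRUE, active = TRUE
  )
}
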