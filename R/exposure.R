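# Land-use exposure: reclassification of the 17 original land-use
# categories into 8 types, buffer queries against 100 m grid-cell
# centroids, and per user-day visit-frequency counts.

.LANDUSE_RECLASS <- c(
  "High-rise buildings"      = "high_rise",
  "Dense low-rise buildings" = "dense_low_rise",
  "Low-rise buildings"       = "low_rise",
  "Factories"                = "factories",
  "Public facilities"        = "parks_public",
  "Parks and green spaces"   = "parks_public",
  "Roads"                    = "roads",
  "Railways"                 = "railways",
  "Forests"                  = "other",
  "Wastelands"               = "other",
  "Vacant lands"             = "other",
  "Rivers and lakes"         = "other",
  "Sea"                      = "other",
  "Seashores"                = "other",
  "Golf courses"             = "other",
  "Rice fields"              = "other",
  "Other fields"             = "other"
)

#' Reclassification table for land-use categories
#'
#' @return A tibble mapping the 17 original land-use categories to the 8
#'   reclassified types; public facilities and parks/green spaces are
#'   combined into `parks_public`, non-urban categories into `other`.
#' @export
landuse_reclass_table <- function() {
  tibble::tibble(
    original_type = names(.LANDUSE_RECLASS),
    reclassified_type = unname(.LANDUSE_RECLASS)
  )
}

#' Reclassify original land-use categories
#'
#' Cells with no land-use information (missing category) are classified as
#' `"other"`; an unknown label is a schema error.
#'
#' @param original_type Character vector of original category labels (or
#'   `NA`).
#' @return Character vector of reclassified types ([landuse_types()]).
#' @export
reclassify_landuse <- function(original_type) {
  out <- unname(.LANDUSE_RECLASS[original_type])
  out[is.na(original_type)] <- "other"
  unknown <- !is.na(original_type) & is.na(out)
  if (any(unknown)) {
    rlang::abort(paste0("unknown land-use label: '", original_type[which(unknown)[1]], "'"),
      class = "stepscape_schema_error")
  }
  out
}

#' Read a land-use table
#'
#' @param path Delimited text with columns `mesh_code_100m`,
#'   `original_type`.
#' @return A tibble with `mesh_code_100m`, `original_type`,
#'   `reclassified_type`.
#' @export
read_landuse <- function(path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  cells <- readr::read_delim(path, delim = delim,
                             col_types = readr::cols(.default = readr::col_character()),
                             progress = FALSE)
  if (!all(c("mesh_code_100m", "original_type") %in% names(cells))) {
    rlang::abort("land-use table needs columns mesh_code_100m, original_type",
      class = "stepscape_schema_error")
  }
  cells$original_type[cells$original_type == ""] <- NA_character_
  cells$reclassified_type <- reclassify_landuse(cells$original_type)
  cells
}

#' Build a spatial index over 100 m land-use cells
#'
#' Indexes cells by their integer grid position so that buffer queries only
#' examine the handful of cells whose centroid can possibly lie within the
#' query radius.
#'
#' @param cells Land-use tibble with `mesh_code_100m` and
#'   `reclassified_type` (see [read_landuse()]).
#' @return A `landuse_index` object.
#' @export
build_cell_index <- function(cells) {
  idx <- .mesh_indices(cells$mesh_code_100m, "100m")
  type <- factor(cells$reclassified_type, levels = landuse_types())
  if (anyNA(type)) {
    rlang::abort("reclassified_type contains values outside landuse_types()",
      class = "stepscape_schema_error")
  }
  structure(
    list(row = idx$row, col = idx$col,
         key = idx$row * 1e5 + idx$col,
         type_int = as.integer(type),
         n = length(idx$row)),
    class = "landuse_index"
  )
}

#' @export
print.landuse_index <- function(x, ...) {
  cat("<landuse_index> of", x$n, "100 m cells\n")
  invisible(x)
}

# candidate window half-widths (in cells) for a radius at given latitudes
.buffer_window <- function(radius_m, lat_range) {
  arcsec_m <- pi / 180 / 3600 * .EARTH_RADIUS_M
  lat_cell_m <- 3 * arcsec_m
  lon_cell_m <- 4.5 * arcsec_m * min(cos(lat_range * pi / 180))
  c(
    lat = as.integer(ceiling(radius_m / lat_cell_m + 0.5)),
    lon = as.integer(ceiling(radius_m / lon_cell_m + 0.5))
  )
}

#' Land-use cells within a buffer of a point
#'
#' Returns the indexed cells whose centroid lies within `radius_m` metres
#' (great-circle, boundary inclusive) of the query point -- equivalent to
#' intersecting centroids with a circular buffer around the point.
#'
#' @param lat,lon Query point, WGS84 degrees.
#' @param index A [build_cell_index()] object.
#' @param radius_m Buffer radius in metres; default 100.
#' @return A tibble of hit cells: `mesh_code_100m`, `reclassified_type`,
#'   `dist_m`.
#' @export
cells_in_buffer <- function(lat, lon, index, radius_m = 100) {
  stopifnot(inherits(index, "landuse_index"), length(lat) == 1L, length(lon) == 1L)
  win <- .buffer_window(radius_m, lat)
  p <- .mesh_point_indices(lat, lon, "100m")
  off <- expand.grid(dr = -win[["lat"]]:win[["lat"]], dc = -win[["lon"]]:win[["lon"]])
  rows <- p$row + off$dr
  cols <- p$col + off$dc
  pos <- match(rows * 1e5 + cols, index$key)
  hit <- !is.na(pos)
  rows <- rows[hit]; cols <- cols[hit]; pos <- pos[hit]
  d <- haversine_m(lat, lon, (rows + 0.5) / 1200, (cols + 0.5) / 800)
  keep <- d <= radius_m
  tibble::tibble(
    mesh_code_100m = .mesh_from_indices(rows[keep], cols[keep], "100m"),
    reclassified_type = landuse_types()[index$type_int[pos[keep]]],
    dist_m = d[keep]
  )
}

# visit-frequency counts for many points at once: n_points x 8 matrix
.buffer_counts <- function(lat, lon, index, radius_m) {
  n <- length(lat)
  counts <- matrix(0L, nrow = n, ncol = 8L)
  if (n == 0L) return(counts)
  win <- .buffer_window(radius_m, range(lat))
  p <- .mesh_point_indices(lat, lon, "100m")
  for (dr in -win[["lat"]]:win[["lat"]]) {
    for (dc in -win[["lon"]]:win[["lon"]]) {
      rows <- p$row + dr
      cols <- p$col + dc
      pos <- match(rows * 1e5 + cols, index$key)
      hit <- which(!is.na(pos))
      if (!length(hit)) next
      d <- haversine_m(lat[hit], lon[hit],
                       (rows[hit] + 0.5) / 1200, (cols[hit] + 0.5) / 800)
      ok <- hit[d <= radius_m]
      if (!length(ok)) next
      at <- cbind(ok, index$type_int[pos[ok]])
      counts[at] <- counts[at] + 1L
    }
  }
  counts
}

#' Daily land-use exposure counts
#'
#' For every trajectory point, counts the 100 m land-use cells whose
#' centroid falls within the buffer, by reclassified type, and sums the
#' counts per user-day. A cell hit by m points on a day contributes m
#' (visit-frequency semantics).
#'
#' @param points Residence-filtered trajectory points.
#' @param index A [build_cell_index()] object.
#' @param radius_m Buffer radius in metres; default 100.
#' @return A tibble with `uuid`, `date` and the 8 count columns in the
#'   order given by [landuse_types()]. User-days with no surviving points
#'   yield no row.
#' @export
compute_exposure <- function(points, index, radius_m = 100) {
  counts <- .buffer_counts(points$lat, points$lon, index, radius_m)
  colnames(counts) <- landuse_types()
  out <- dplyr::bind_cols(
    tibble::tibble(uuid = points$uuid, date = .log_date(points$timestamp)),
    tibble::as_tibble(counts)
  )
  out |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(landuse_types()), sum),
      .by = c("uuid", "date")
    ) |>
    dplyr::arrange(.data$uuid, .data$date)
}

# numeric AGE codes (10..60); 70plus and unknown are NA
.age_code <- function(age_group) {
  codes <- c("10s" = 10, "20s" = 20, "30s" = 30, "40s" = 40, "50s" = 50, "60s" = 60)
  unname(codes[age_group])
}

# SEX: 1 female, 0 male, NA unknown
.sex_code <- function(sex) {
  dplyr::case_match(sex, "female" ~ 1, "male" ~ 0, .default = NA_real_)
}

#' Assemble per user-day exposure records
#'
#' Joins exposure counts with daily step counts (from the raw logs of that
#' user-day) and user attributes (sex/age from the oldest log of each
#' user).
#'
#' @param counts Output of [compute_exposure()].
#' @param logs The accuracy-filtered raw logs carrying `daily_steps`,
#'   `sex`, `age_group`.
#' @return Exposure-record tibble: `uuid`, `date`, `steps`, `sex`,
#'   `age_group`, then the 8 count columns.
#' @export
exposure_records <- function(counts, logs) {
  steps <- logs |>
    dplyr::mutate(date = .log_date(.data$timestamp)) |>
    dplyr::filter(!is.na(.data$daily_steps)) |>
    dplyr::summarise(steps = max(.data$daily_steps), .by = c("uuid", "date"))
  attrs <- logs |>
    dplyr::arrange(.data$timestamp) |>
    dplyr::distinct(.data$uuid, .keep_all = TRUE) |>
    dplyr::select("uuid", "sex", "age_group")
  counts |>
    dplyr::left_join(steps, by = c("uuid", "date")) |>
    dplyr::left_join(attrs, by = "uuid") |>
    dplyr::select("uuid", "date", "steps", "sex", "age_group",
                  dplyr::all_of(landuse_types()))
}

#' Split exposure records into model-building and prediction sets
#'
#' The model set holds records with observed daily steps and complete sex
#' and age, excluding users aged 70 years and over. The prediction set
#' holds records without step counts.
#'
#' @param records Exposure-record tibble ([exposure_records()]).
#' @return A list with elements `with_steps` and `without_steps`.
#' @export
split_model_data <- function(records) {
  list(
    with_steps = dplyr::filter(
      records,
      !is.na(.data$steps),
      .data$sex %in% c("male", "female"),
      !is.na(.age_code(.data$age_group))
    ),
    without_steps = dplyr::filter(records, is.na(.data$steps))
  )
}
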