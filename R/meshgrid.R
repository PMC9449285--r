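# Japanese standardized grid-square (mesh code) codec.
#
# The national standard tiles Japan with a Basic Grid Square of 30" latitude
# by 45" longitude (ca. 1 km x 1 km), subdivided 2x2 into 500 m and 250 m
# Half/Quarter squares and 10x10 into 100 m squares. Codes are plain digit
# strings: 8 digits at 1 km, one appended quadrant digit (SW=1, SE=2, NW=3,
# NE=4) per halving step, and two appended 0-9 digits (latitude row then
# longitude column) at 100 m. Cell membership is half-open,
# [south, north) x [west, east), so every point maps to exactly one cell
# per level.

#' Supported grid-square levels
#'
#' @return Character vector of the four supported mesh levels.
#' @export
mesh_levels <- function() c("1km", "500m", "250m", "100m")

# cells per degree at each level (latitude, longitude)
.mesh_div <- function(level) {
  switch(level,
    "1km"  = c(lat = 120,  lon = 80),
    "500m" = c(lat = 240,  lon = 160),
    "250m" = c(lat = 480,  lon = 320),
    "100m" = c(lat = 1200, lon = 800),
    rlang::abort(paste0("unknown mesh level: '", level, "'"), class = "stepscape_level_error")
  )
}

.mesh_nchar <- function(level) {
  switch(level, "1km" = 8L, "500m" = 9L, "250m" = 10L, "100m" = 10L)
}

#' Cell extent of a mesh level in arcseconds
#'
#' @param level One of `"1km"`, `"500m"`, `"250m"`, `"100m"`.
#' @return Named numeric vector `c(lat = , lon = )` in arcseconds.
#' @export
mesh_extent_arcsec <- function(level) {
  div <- .mesh_div(match.arg(level, mesh_levels()))
  c(lat = 3600 / div[["lat"]], lon = 3600 / div[["lon"]])
}

# index-space epsilon: ~1e-7 of a cell, far above double rounding error for
# lat*div (~5e-12) and far below any physical distance, so exact cell
# corners encode into their own cell.
.MESH_EPS <- 1e-7

# global (row, col) cell indices at a level; row = floor(lat * latdiv)
.mesh_point_indices <- function(lat, lon, level) {
  div <- .mesh_div(level)
  list(
    row = floor(lat * div[["lat"]] + .MESH_EPS),
    col = floor(lon * div[["lon"]] + .MESH_EPS)
  )
}

# build digit-string codes from global cell indices (vectorized)
.mesh_from_indices <- function(row, col, level) {
  if (level == "1km") {
    r1 <- row; c1 <- col
    suffix <- ""
  } else if (level == "500m") {
    r1 <- row %/% 2L; c1 <- col %/% 2L
    suffix <- as.character(2L * (row %% 2L) + (col %% 2L) + 1L)
  } else if (level == "250m") {
    r5 <- row %/% 2L; c5 <- col %/% 2L
    q2 <- 2L * (row %% 2L) + (col %% 2L) + 1L
    r1 <- r5 %/% 2L; c1 <- c5 %/% 2L
    q1 <- 2L * (r5 %% 2L) + (c5 %% 2L) + 1L
    suffix <- paste0(q1, q2)
  } else { # 100m
    r1 <- row %/% 10L; c1 <- col %/% 10L
    suffix <- paste0(row %% 10L, col %% 10L)
  }
  p <- r1 %/% 80L
  s <- (r1 %% 80L) %/% 10L
  x <- r1 %% 10L
  u <- c1 %/% 80L - 100L
  t <- (c1 %% 80L) %/% 10L
  y <- c1 %% 10L
  paste0(sprintf("%02d%02d", p, u), s, t, x, y, suffix)
}

.mesh_check_code <- function(code, level) {
  n <- .mesh_nchar(level)
  bad <- is.na(code) | nchar(code) != n | !grepl("^[0-9]+$", code)
  if (level %in% c("500m", "250m")) {
    q <- substr(code, 9L, n)
    bad <- bad | grepl("[05-9]", q)
  }
  if (any(bad)) {
    rlang::abort(
      paste0("malformed ", level, " mesh code: '", code[which(bad)[1]], "'"),
      class = "stepscape_parse_error"
    )
  }
  invisible(code)
}

# global cell indices of codes at their own level (vectorized)
.mesh_indices <- function(code, level) {
  .mesh_check_code(code, level)
  dig <- function(i) as.integer(substr(code, i, i))
  p <- as.integer(substr(code, 1L, 2L))
  u <- as.integer(substr(code, 3L, 4L))
  r1 <- p * 80L + dig(5L) * 10L + dig(7L)
  c1 <- (u + 100L) * 80L + dig(6L) * 10L + dig(8L)
  if (level == "1km") {
    list(row = r1, col = c1)
  } else if (level == "500m") {
    q <- dig(9L) - 1L
    list(row = r1 * 2L + q %/% 2L, col = c1 * 2L + q %% 2L)
  } else if (level == "250m") {
    q1 <- dig(9L) - 1L
    q2 <- dig(10L) - 1L
    list(
      row = (r1 * 2L + q1 %/% 2L) * 2L + q2 %/% 2L,
      col = (c1 * 2L + q1 %% 2L) * 2L + q2 %% 2L
    )
  } else {
    list(row = r1 * 10L + dig(9L), col = c1 * 10L + dig(10L))
  }
}

.mesh_check_domain <- function(lat, lon) {
  bad_lat <- which(!is.finite(lat) | lat < 20 | lat >= 46)
  if (length(bad_lat)) {
    rlang::abort(
      paste0("latitude ", lat[bad_lat[1]], " outside the standard-mesh domain [20, 46)"),
      class = "stepscape_domain_error"
    )
  }
  bad_lon <- which(!is.finite(lon) | lon < 122 | lon >= 154)
  if (length(bad_lon)) {
    rlang::abort(
      paste0("longitude ", lon[bad_lon[1]], " outside the standard-mesh domain [122, 154)"),
      class = "stepscape_domain_error"
    )
  }
  invisible(NULL)
}

#' Encode coordinates to a grid-square code
#'
#' Maps WGS84 coordinates to the Japanese standardized grid-square code at
#' the requested level. Membership is half-open, `[south, north) x
#' [west, east)`, so a point on a shared edge belongs to the cell to its
#' north/east.
#'
#' @param lat,lon Numeric vectors of WGS84 degrees, within the standard-mesh
#'   domain (latitude `[20, 46)`, longitude `[122, 154)`).
#' @param level Mesh level, one of [mesh_levels()].
#' @return Character vector of digit-string codes.
#' @examples
#' mesh_code(38.2682, 140.8694, "1km")
#' @export
mesh_code <- function(lat, lon, level = c("1km", "500m", "250m", "100m")) {
  level <- match.arg(level)
  .mesh_check_domain(lat, lon)
  idx <- .mesh_point_indices(lat, lon, level)
  .mesh_from_indices(idx$row, idx$col, level)
}

#' Geographic bounds of grid-square codes
#'
#' @param code Character vector of mesh codes, all at `level`.
#' @param level Mesh level of the codes.
#' @return A tibble with columns `code`, `south`, `west`, `north`, `east`
#'   (degrees).
#' @export
mesh_bounds <- function(code, level = c("1km", "500m", "250m", "100m")) {
  level <- match.arg(level)
  div <- .mesh_div(level)
  idx <- .mesh_indices(code, level)
  tibble::tibble(
    code = code,
    south = idx$row / div[["lat"]],
    west = idx$col / div[["lon"]],
    north = (idx$row + 1) / div[["lat"]],
    east = (idx$col + 1) / div[["lon"]]
  )
}

#' Centroid of grid-square codes
#'
#' @inheritParams mesh_bounds
#' @return A tibble with columns `code`, `lat`, `lon` (degrees).
#' @export
mesh_centroid <- function(code, level = c("1km", "500m", "250m", "100m")) {
  level <- match.arg(level)
  div <- .mesh_div(level)
  idx <- .mesh_indices(code, level)
  tibble::tibble(
    code = code,
    lat = (idx$row + 0.5) / div[["lat"]],
    lon = (idx$col + 0.5) / div[["lon"]]
  )
}

#' Eight-neighborhood of a 250 m grid square
#'
#' Returns the eight surrounding 250 m cells (queen contiguity), correctly
#' crossing parent-cell boundaries. Used when merging candidate residential
#' grids.
#'
#' @param code A single 250 m mesh code.
#' @param level Must be `"250m"`; any other level is an error.
#' @return Character vector of the 8 neighboring codes.
#' @export
mesh_neighbors <- function(code, level = "250m") {
  if (!identical(level, "250m")) {
    rlang::abort("mesh_neighbors is defined for 250m codes only",
      class = "stepscape_level_error")
  }
  if (length(code) != 1L) {
    rlang::abort("mesh_neighbors takes a single code", class = "stepscape_level_error")
  }
  idx <- .mesh_indices(code, "250m")
  off <- expand.grid(dr = -1L:1L, dc = -1L:1L)
  off <- off[!(off$dr == 0L & off$dc == 0L), ]
  .mesh_from_indices(idx$row + off$dr, idx$col + off$dc, "250m")
}

#' Are a set of 250 m grid squares mutually co-resident?
#'
#' Candidate residential grids are merged when they are adjacent to each
#' other or share a common adjacent grid. Under queen contiguity this is a
#' pairwise Chebyshev distance of at most 2 in cell-index space; under rook
#' contiguity, a pairwise Manhattan distance of at most 2.
#'
#' @param codes Character vector of 250 m mesh codes (non-empty).
#' @param adjacency `"queen"` (default) or `"rook"`.
#' @return Single logical; singletons are trivially `TRUE`.
#' @export
mesh_coresident <- function(codes, adjacency = c("queen", "rook")) {
  adjacency <- match.arg(adjacency)
  if (length(codes) == 0L) {
    rlang::abort("empty code set", class = "stepscape_level_error")
  }
  idx <- .mesh_indices(codes, "250m")
  if (length(codes) == 1L) return(TRUE)
  if (adjacency == "queen") {
    diff(range(idx$row)) <= 2L && diff(range(idx$col)) <= 2L
  } else {
    dr <- outer(idx$row, idx$row, "-")
    dc <- outer(idx$col, idx$col, "-")
    all(abs(dr) + abs(dc) <= 2L)
  }
}
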