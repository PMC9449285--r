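#' @importFrom rlang .data
#' @importFrom stats coef predict rnorm runif rbinom rnbinom sd var
NULL

# Earth radius used throughout, metres
.EARTH_RADIUS_M <- 6371000

#' Great-circle (haversine) distance
#'
#' Vectorized haversine distance on a sphere of radius 6,371,000 m.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in WGS84 degrees; vectors are
#'   recycled.
#' @return Distances in metres.
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad / 2
  dlon <- (lon2 - lon1) * rad / 2
  a <- sin(dlat)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon)^2
  2 * .EARTH_RADIUS_M * asin(pmin(1, sqrt(a)))
}

# calendar date of a minute timestamp (timestamps are a single local
# timezone stored as UTC; JST has no DST so this is safe)
.log_date <- function(t) lubridate::as_date(t)

.canonical_landuse_types <- c(
  "high_rise", "dense_low_rise", "low_rise", "factories",
  "parks_public", "roads", "railways", "other"
)

#' The eight reclassified land-use types, in canonical column order
#'
#' @return Character vector of length 8.
#' @export
landuse_types <- function() .canonical_landuse_types
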