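# Distances are reported in miles. Geodesic distances use the great-circle
# (haversine) formula on a spherical earth of radius 3958.8 miles; planar
# distances assume both layers share a projected CRS with mile units.

EARTH_RADIUS_MILES <- 3958.8

#' Pairwise distance between points
#'
#' @param x1,y1 coordinates of the first point(s): lon/lat degrees under the
#'   geodesic metric, planar miles under the planar metric.
#' @param x2,y2 coordinates of the second point(s); recycled against the first.
#' @param metric `"geodesic"` or `"planar"`.
#' @return distance(s) in miles. Symmetric, non-negative, zero iff the
#'   coordinates are identical.
#' @examples
#' pairwise_distance(0, 0, 3, 4, metric = "planar") # 5
#' pairwise_distance(0, 0, 1, 0)                    # ~69.09 miles
#' @export
pairwise_distance <- function(x1, y1, x2, y2,
                              metric = c("geodesic", "planar")) {
  metric <- match.arg(metric)
  if (metric == "planar") return(sqrt((x1 - x2)^2 + (y1 - y2)^2))
  check_lonlat(x1, y1)
  check_lonlat(x2, y2)
  haversine_miles(x1, y1, x2, y2)
}

check_lonlat <- function(lon, lat) {
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("non-finite coordinates under geodesic metric", call. = FALSE)
  if (any(lat < -90 | lat > 90))
    stop("latitude outside [-90, 90] under geodesic metric", call. = FALSE)
  invisible(NULL)
}

haversine_miles <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  dphi <- (lat2 - lat1) * rad / 2
  dlam <- (lon2 - lon1) * rad / 2
  h <- sin(dphi)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlam)^2
  2 * EARTH_RADIUS_MILES * asin(pmin(1, sqrt(h)))
}

# Embed lon/lat degrees on a sphere of radius EARTH_RADIUS_MILES so that
# chord-length ordering equals great-circle ordering (chord is a monotone
# function of central angle).
lonlat_to_xyz <- function(lon, lat) {
  rad <- pi / 180
  cbind(EARTH_RADIUS_MILES * cos(lat * rad) * cos(lon * rad),
        EARTH_RADIUS_MILES * cos(lat * rad) * sin(lon * rad),
        EARTH_RADIUS_MILES * sin(lat * rad))
}

chord_to_greatcircle <- function(chord) {
  2 * EARTH_RADIUS_MILES * asin(pmin(1, chord / (2 * EARTH_RADIUS_MILES)))
}
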