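# CSV is the canonical interchange. Documented schemas:
#   blocks: block_id, x, y, pop_total [, pop_<group>...] [, stratum columns]
#   parks:  park_id, x, y, size            (size in square miles after read)
# GeoJSON (RFC 7946) is accepted for geometry convenience: Point features for
# blocks, Polygon/Point features for parks (polygons yield a planar centroid
# and shoelace area, which require a projected mile-unit CRS).

#' Read a block table
#'
#' Rows failing validation (non-numeric or negative population, missing
#' coordinates) are rejected with a message naming their line numbers;
#' duplicate `block_id`s are an error.
#'
#' @param path CSV file (header as documented above) or GeoJSON Point
#'   features whose properties carry the non-geometry columns.
#' @param metric declared CRS interpretation: `"geodesic"` (lon/lat degrees,
#'   validated) or `"planar"` (projected miles).
#' @return validated block table.
#' @export
read_blocks <- function(path, metric = c("geodesic", "planar")) {
  metric <- match.arg(metric)
  dat <- if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    geojson_table(path)
  } else {
    read.csv(path, stringsAsFactors = FALSE, colClasses = c(block_id = "character"))
  }
  need <- c("block_id", "x", "y", "pop_total")
  miss <- setdiff(need, names(dat))
  if (length(miss))
    stop("block file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in c("x", "y", grep("^pop_", names(dat), value = TRUE)))
    dat[[col]] <- suppressWarnings(as.numeric(dat[[col]]))
  bad <- !is.finite(dat$x) | !is.finite(dat$y) |
    is.na(dat$pop_total) | dat$pop_total < 0
  if (any(bad)) {
    message("rejected ", sum(bad), " invalid block row(s) at line(s): ",
            paste(which(bad) + 1L, collapse = ", "))
    dat <- dat[!bad, , drop = FALSE]
  }
  if (nrow(dat) == 0L) stop("no valid block rows in ", path, call. = FALSE)
  if (metric == "geodesic") check_lonlat(dat$x, dat$y)
  rownames(dat) <- NULL
  validate_blocks(dat)
  dat$block_id <- as.character(dat$block_id)
  dat
}

#' Read a park table
#'
#' @param path CSV (`park_id, x, y, size`) or GeoJSON. GeoJSON Polygon
#'   features yield a planar centroid and shoelace area in squared CRS units
#'   (a warning reminds that degree-based areas require a projected CRS);
#'   Point features must carry a `size` property.
#' @param metric declared CRS interpretation, as in [read_blocks()].
#' @param area_unit unit of the size column / computed area: `"sqmi"`,
#'   `"acres"` or `"sqft"`; converted to square miles.
#' @return validated park table, sizes in square miles.
#' @export
read_parks <- function(path, metric = c("geodesic", "planar"),
                       area_unit = c("sqmi", "acres", "sqft")) {
  metric <- match.arg(metric)
  area_unit <- match.arg(area_unit)
  dat <- if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    if (metric == "geodesic")
      warning("polygon areas/centroids are computed on the plane; ",
              "degree coordinates need a projected CRS for meaningful areas")
    geojson_table(path)
  } else {
    read.csv(path, stringsAsFactors = FALSE, colClasses = c(park_id = "character"))
  }
  need <- c("park_id", "x", "y", "size")
  miss <- setdiff(need, names(dat))
  if (length(miss))
    stop("park file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  dat$size <- to_square_miles(suppressWarnings(as.numeric(dat$size)),
                              area_unit)
  bad <- !is.finite(dat$x) | !is.finite(dat$y) |
    is.na(dat$size) | dat$size <= 0
  if (any(bad)) {
    message("rejected ", sum(bad), " invalid park row(s) at line(s): ",
            paste(which(bad) + 1L, collapse = ", "))
    dat <- dat[!bad, , drop = FALSE]
  }
  if (nrow(dat) == 0L) stop("no valid park rows in ", path, call. = FALSE)
  if (metric == "geodesic") check_lonlat(dat$x, dat$y)
  rownames(dat) <- NULL
  validate_parks(dat)
  dat$park_id <- as.character(dat$park_id)
  dat
}

# GeoJSON FeatureCollection -> data.frame of properties + x, y (+ size for
# polygons, in squared CRS units). Point and Polygon geometries supported.
geojson_table <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection" ||
      is.null(gj$features))
    stop("expected a GeoJSON FeatureCollection in ", path, call. = FALSE)
  rows <- lapply(gj$features, function(f) {
    g <- f$geometry
    if (is.null(g) || is.null(g$type))
      stop("feature without geometry in ", path, call. = FALSE)
    props <- lapply(f$properties, function(p) if (is.null(p)) NA else p)
    if (g$type == "Point") {
      props$x <- g$coordinates[[1]]
      props$y <- g$coordinates[[2]]
    } else if (g$type == "Polygon") {
      pc <- polygon_area_centroid(g$coordinates)
      props$x <- pc$x; props$y <- pc$y; props$size <- pc$area
    } else {
      stop("unsupported geometry type '", g$type, "' in ", path,
           call. = FALSE)
    }
    props
  })
  cols <- unique(unlist(lapply(rows, names)))
  out <- lapply(cols, function(cn)
    unlist(lapply(rows, function(r) if (is.null(r[[cn]])) NA else r[[cn]])))
  names(out) <- cols
  data.frame(out, stringsAsFactors = FALSE)
}

# Shoelace area and centroid of a GeoJSON polygon (list of rings, first
# exterior, rest holes; holes subtract by their ring orientation handling).
polygon_area_centroid <- function(rings) {
  acc_a <- 0; acc_x <- 0; acc_y <- 0
  for (ri in seq_along(rings)) {
    ring <- rings[[ri]]
    xs <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
    ys <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    n <- length(xs)
    if (n < 4 || xs[1] != xs[n] || ys[1] != ys[n])
      stop("invalid polygon ring: must be closed with >= 4 positions",
           call. = FALSE)
    cross <- xs[-n] * ys[-1] - xs[-1] * ys[-n]
    a <- sum(cross) / 2
    if (a == 0) next
    # exterior ring counts positive, holes negative, whatever the winding
    signed <- if (ri == 1) abs(a) else -abs(a)
    scale <- signed / a
    acc_a <- acc_a + signed
    acc_x <- acc_x + scale * sum((xs[-n] + xs[-1]) * cross) / 6
    acc_y <- acc_y + scale * sum((ys[-n] + ys[-1]) * cross) / 6
  }
  if (acc_a <= 0) stop("polygon has non-positive area", call. = FALSE)
  list(area = acc_a, x = acc_x / acc_a, y = acc_y / acc_a)
}

#' Write block / park tables
#'
#' Plain CSV in the documented schemas, no row names; byte-stable across
#' repeated runs.
#'
#' @param x table to write.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = TRUE, eol = "\n")
  invisible(path)
}
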