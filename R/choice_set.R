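#' Remove parks below the minimum-size floor
#'
#' Very small parks (below 0.1 acres by default, the resolution floor of
#' national park layers) are excluded before any accessibility computation.
#'
#' @param parks park table (see [validate_parks()]), sizes in square miles.
#' @param min_size floor in square miles; `0` keeps every park.
#' @param quiet suppress the message reporting how many parks were removed.
#' @return the filtered park table.
#' @export
filter_parks <- function(parks, min_size = default_min_park_size(),
                         quiet = FALSE) {
  parks <- validate_parks(parks)
  stopifnot(is.numeric(min_size), length(min_size) == 1L, min_size >= 0)
  keep <- parks$size >= min_size
  if (!quiet)
    message(sum(!keep), " of ", nrow(parks),
            " parks below the size floor (", signif(min_size, 6),
            " sq mi) removed")
  out <- parks[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("no parks remain after applying the size floor", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Build a spatial index over parks
#'
#' Wraps an Rcpp k-d tree supporting k-nearest queries. Under the geodesic
#' metric, lon/lat points are embedded on a 3-D sphere so that chord-length
#' ordering equals great-circle ordering; under the planar metric the tree
#' holds the 2-D coordinates directly. Parks are stored sorted by `park_id`
#' (byte order), so equal-distance ties resolve to the smaller `park_id`.
#'
#' @param parks park table; at least one park.
#' @param metric `"geodesic"` or `"planar"`.
#' @return a `park_index` object.
#' @export
build_spatial_index <- function(parks, metric = c("geodesic", "planar")) {
  metric <- match.arg(metric)
  parks <- validate_parks(parks)
  if (nrow(parks) == 0L) stop("cannot index an empty park set", call. = FALSE)
  parks <- parks[order(parks$park_id, method = "radix"), , drop = FALSE]
  rownames(parks) <- NULL
  pts <- if (metric == "geodesic") {
    check_lonlat(parks$x, parks$y)
    lonlat_to_xyz(parks$x, parks$y)
  } else {
    cbind(parks$x, parks$y)
  }
  structure(
    list(tree = .kdtree_build(pts), parks = parks, metric = metric),
    class = "park_index"
  )
}

#' @export
print.park_index <- function(x, ...) {
  cat(sprintf("Park spatial index: %d parks, %s metric\n",
              nrow(x$parks), x$metric))
  invisible(x)
}

#' Destination choice sets: the k nearest parks per block
#'
#' For each block, selects the `k` nearest parks (all parks when fewer than
#' `k` exist), sorted ascending by distance with exact ties broken by
#' ascending `park_id`. Selection ranks use true distances; the returned
#' `distance` column is then clamped below at `d_floor` so the distance-decay
#' term stays finite for blocks sitting on a park centroid (the true distance
#' is kept in `distance_true`).
#'
#' @param blocks block table (or any data.frame with `block_id`, `x`, `y`).
#' @param index a `park_index` from [build_spatial_index()].
#' @param k choice-set size.
#' @param d_floor minimum distance in miles applied after selection.
#' @return data.frame with columns `block_id`, `park_id`, `rank`,
#'   `distance` (clamped, miles), `distance_true` (miles), in block order,
#'   `min(k, n_parks)` rows per block.
#' @export
nearest_k <- function(blocks, index, k = 7, d_floor = 0.05) {
  stopifnot(inherits(index, "park_index"), k >= 1, d_floor > 0)
  blocks$block_id <- as.character(blocks$block_id)
  pts <- if (index$metric == "geodesic") {
    check_lonlat(blocks$x, blocks$y)
    lonlat_to_xyz(blocks$x, blocks$y)
  } else {
    cbind(blocks$x, blocks$y)
  }
  res <- .kdtree_query(index$tree, pts, as.integer(k))
  kk <- ncol(res$idx)
  dist_true <- if (index$metric == "geodesic") {
    matrix(chord_to_greatcircle(sqrt(as.vector(res$dist2))),
           nrow = nrow(res$dist2))
  } else {
    sqrt(res$dist2)
  }
  # row-major flatten: per block, ranks 1..kk contiguous
  data.frame(
    block_id = rep(blocks$block_id, each = kk),
    park_id = index$parks$park_id[as.vector(t(res$idx))],
    rank = rep.int(seq_len(kk), nrow(blocks)),
    distance = pmax(as.vector(t(dist_true)), d_floor),
    distance_true = as.vector(t(dist_true)),
    stringsAsFactors = FALSE
  )
}

#' Choice sets straight from block and park tables
#'
#' Convenience wrapper: filters nothing, builds the index with the metric in
#' `params` and runs [nearest_k()] with `params$k` and `params$d_floor`.
#'
#' @param blocks block table.
#' @param parks park table (already size-filtered if desired).
#' @param params an [access_params()] object.
#' @return a choice-set data.frame (see [nearest_k()]).
#' @export
choice_sets <- function(blocks, parks, params = access_params()) {
  params <- as_access_params(params)
  index <- build_spatial_index(parks, metric = params$metric)
  nearest_k(blocks, index, k = params$k, d_floor = params$d_floor)
}
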