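#' Model parameters for park accessibility
#'
#' Bundles the tunable parameters of the gravity/Huff accessibility model:
#' the park-size exponent `alpha`, the distance-decay (friction) exponent
#' `beta`, the choice-set size `k`, the minimum distance `d_floor` substituted
#' for smaller computed distances, and the distance metric.
#'
#' The defaults are the empirical values for public open space: size exponent
#' 0.85, distance decay 1.91, and a choice set of the seven nearest parks
#' (the information-processing limit of roughly seven alternatives).
#' `d_floor` (default 0.05 miles) keeps the distance-decay term finite when a
#' block centroid coincides with, or sits practically on top of, a park
#' centroid; it is applied after nearest-neighbour selection, so rankings use
#' true distances.
#'
#' @param alpha dimensionless exponent on park size (square miles). Must be
#'   finite.
#' @param beta dimensionless distance-decay exponent; must satisfy
#'   `0 <= beta <= 50` (the upper guard rejects regimes where `d^-beta`
#'   overflows double precision at sub-mile distances).
#' @param k choice-set size, an integer `>= 1`.
#' @param d_floor minimum distance in miles, `> 0`.
#' @param metric `"geodesic"` (great-circle on a sphere of radius 3958.8
#'   miles; coordinates are lon/lat degrees) or `"planar"` (straight-line;
#'   coordinates are in a projected CRS with mile units).
#' @return an object of class `access_params`.
#' @examples
#' access_params()
#' access_params(beta = 2, metric = "planar")
#' @export
access_params <- function(alpha = 0.85, beta = 1.91, k = 7, d_floor = 0.05,
                          metric = c("geodesic", "planar")) {
  metric <- match.arg(metric)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta < 0)
    stop("`beta` must be a single finite number >= 0", call. = FALSE)
  if (beta > 50)
    stop("`beta` > 50 rejected: d^-beta overflows double precision ",
         "at sub-mile distances", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != as.integer(k))
    stop("`k` must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(d_floor) || length(d_floor) != 1L || d_floor <= 0)
    stop("`d_floor` must be a single number > 0 (miles)", call. = FALSE)
  structure(
    list(alpha = alpha, beta = beta, k = as.integer(k),
         d_floor = d_floor, metric = metric),
    class = "access_params"
  )
}

#' @export
print.access_params <- function(x, ...) {
  cat("Park accessibility model parameters\n")
  cat(sprintf("  alpha (size exponent):     %g\n", x$alpha))
  cat(sprintf("  beta (distance decay):     %g\n", x$beta))
  cat(sprintf("  k (choice-set size):       %d\n", x$k))
  cat(sprintf("  d_floor (miles):           %g\n", x$d_floor))
  cat(sprintf("  metric:                    %s\n", x$metric))
  invisible(x)
}

as_access_params <- function(x) {
  if (inherits(x, "access_params")) return(x)
  if (is.list(x)) return(do.call(access_params, x))
  stop("expected an `access_params` object", call. = FALSE)
}

#' Default minimum park size
#'
#' Parks smaller than 0.1 acres (4000 square feet) are excluded, mirroring
#' the resolution floor of national park layers.
#'
#' @return the floor in square miles (0.1/640).
#' @export
default_min_park_size <- function() 0.1 * SQMI_PER_ACRE
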