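# Nearest-park shortest-distance baseline and its comparison with the PWD.
# The nearest park is always in the choice set and the PWD is a convex
# combination of choice-set distances, so PWD >= nearest distance for every
# block, with equality when the choice set has a single park.

#' Population-weighted nearest-park distance per unit
#'
#' The classic shortest-distance baseline, aggregated exactly like the PWD:
#' a population-weighted mean of each block's distance to its closest park.
#'
#' @inheritParams aggregate_pwd
#' @return as [aggregate_pwd()], with `pwd` holding the aggregated nearest
#'   distance (renamed `nearest` by [compare_measures()] outputs).
#' @export
nearest_distance_measure <- function(access, blocks, level = "nation",
                                     hierarchy = fips_hierarchy()) {
  if (!"nearest_distance" %in% names(access))
    stop("access results lack a nearest_distance column", call. = FALSE)
  aggregate_pwd(access, blocks, level, hierarchy, value = "nearest_distance")
}

#' Compare the PWD with the nearest-park baseline
#'
#' @param nearest numeric vector of per-unit nearest-park distances (miles).
#' @param pwd numeric vector of per-unit PWDs (miles), same order.
#' @param weights optional population weights for the mean difference
#'   (default: equal weights).
#' @return list with `mean_difference` (weighted mean of `pwd - nearest`,
#'   miles), `pearson_r` (`NA` when either measure has zero variance) and
#'   `flag` (`""` or `"zero_variance"`).
#' @export
compare_measures <- function(nearest, pwd, weights = NULL) {
  stopifnot(length(nearest) == length(pwd))
  ok <- is.finite(nearest) & is.finite(pwd)
  nearest <- nearest[ok]; pwd <- pwd[ok]
  if (length(nearest) < 3)
    stop("need at least 3 units with both measures defined", call. = FALSE)
  w <- if (is.null(weights)) rep(1, length(nearest)) else weights[ok]
  diffs <- pwd - nearest
  md <- sum(w * diffs) / sum(w)
  if (var(nearest) == 0 || var(pwd) == 0) {
    list(mean_difference = md, pearson_r = NA_real_, flag = "zero_variance")
  } else {
    list(mean_difference = md, pearson_r = cor(nearest, pwd), flag = "")
  }
}

#' Nearest-park vs PWD comparison report
#'
#' One row per category of an optional stratum (plus an overall row):
#' population-weighted nearest-park distance, population-weighted PWD, their
#' difference, and the Pearson correlation between the two measures across
#' observations. The correlation is computed over unweighted block-level
#' values by default; set `r_level` to correlate aggregated units at that
#' level instead.
#'
#' @inheritParams aggregate_pwd
#' @param stratum optional stratum column of `blocks` (e.g. `"urban_rural"`)
#'   to break the comparison down by.
#' @param r_level `"block"` (default) or a hierarchy level name at which the
#'   correlation is computed (equal unit weights).
#' @return data.frame: `geography`, `nearest_miles`, `pwd_miles`,
#'   `difference_miles`, `pearson_r`, `flag` (`""`, `"zero_variance"`, or
#'   `"too_few_units"` when a cell has fewer than 3 observations).
#' @export
comparison_report <- function(access, blocks, stratum = NULL,
                              hierarchy = fips_hierarchy(),
                              r_level = "block") {
  dat <- join_access(access, blocks)
  if (!is.null(stratum) && !stratum %in% names(dat))
    stop("unknown stratum column: ", stratum, call. = FALSE)
  cats <- if (is.null(stratum)) character(0)
          else sort(unique(as.character(dat[[stratum]])))

  one <- function(label, sel) {
    d <- dat[sel, , drop = FALSE]
    w <- d$pop_total
    wp <- if (sum(w) > 0) w else rep(1, nrow(d))
    near_agg <- sum(wp * d$nearest_distance) / sum(wp)
    pwd_agg <- sum(wp * d$pwd) / sum(wp)
    if (r_level == "block") {
      nvec <- d$nearest_distance; pvec <- d$pwd
    } else {
      agg_n <- rollup(d$nearest_distance, w,
                      list(unit_id = unit_ids_at(d$block_id, hierarchy,
                                                 r_level)))
      agg_p <- rollup(d$pwd, w,
                      list(unit_id = unit_ids_at(d$block_id, hierarchy,
                                                 r_level)))
      nvec <- agg_n$pwd; pvec <- agg_p$pwd
    }
    cmp <- if (sum(is.finite(nvec) & is.finite(pvec)) >= 3) {
      compare_measures(nvec, pvec)
    } else {
      list(pearson_r = NA_real_, flag = "too_few_units")
    }
    data.frame(geography = label, nearest_miles = near_agg,
               pwd_miles = pwd_agg, difference_miles = pwd_agg - near_agg,
               pearson_r = cmp$pearson_r, flag = cmp$flag,
               stringsAsFactors = FALSE)
  }
  rows <- c(list(one("ALL", rep(TRUE, nrow(dat)))),
            lapply(cats, function(g) one(g, dat[[stratum]] == g)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
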