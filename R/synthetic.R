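# Seeded generator of synthetic landscapes: spatially clustered blocks along
# an urban-rural density gradient, right-skewed park sizes with a minimum
# floor, FIPS-like hierarchical IDs, block-group poverty and per-band
# subgroup composition. Everything the pipeline consumes, without any
# download. Coordinates are planar miles by default.

NCHS_BANDS <- c("1_large_central_metro", "2_large_fringe_metro",
                "3_medium_metro", "4_small_metro", "5_micropolitan",
                "6_noncore")

SUBGROUPS <- c("white", "black", "asian", "hispanic", "other")

#' Configuration of a synthetic landscape
#'
#' Defaults describe a stylised three-city region on a 160x160-mile square:
#' blocks scatter around urban cores with exponentially decaying density plus
#' a uniform rural background; parks follow the same radial process (denser
#' near cores) with lognormal sizes that grow toward rural bands, truncated
#' below at the minimum park-size floor; block populations are lognormal;
#' poverty rates are Beta-distributed at the block-group level; subgroup
#' shares are Dirichlet draws whose concentration shifts from diverse (urban)
#' to homogeneous (rural). Urban-rural labels follow the six ordered
#' metro-to-noncore bands, assigned by distance to the nearest core.
#'
#' @param seed integer seed; identical seed + config give a bit-identical
#'   landscape.
#' @param extent bounding box `c(xmin, xmax, ymin, ymax)` in planar miles.
#' @param n_centers number of urban cores.
#' @param blocks_per_center clustered blocks per core.
#' @param n_background_blocks uniform rural blocks.
#' @param block_radial_mean mean (miles) of the exponential radial scatter of
#'   clustered blocks.
#' @param pop_meanlog,pop_sdlog lognormal block-population parameters.
#' @param n_parks number of parks.
#' @param park_center_frac fraction of parks placed by the radial process
#'   (rest uniform).
#' @param park_radial_mean mean (miles) of the park radial scatter.
#' @param park_size_meanlog,park_size_sdlog lognormal park-size parameters
#'   (square miles) in the most urban band.
#' @param park_size_band_step added to `park_size_meanlog` per band step
#'   toward rural (rural parks run larger).
#' @param min_park_size truncation floor for park sizes (square miles).
#' @param urban_rural_breaks 5 increasing distances (miles) cutting the 6
#'   urban-rural bands.
#' @param poverty_shape1,poverty_shape2 Beta parameters of block-group
#'   poverty rates.
#' @param include_edge_cases append a block coincident with a park centroid
#'   and a zero-population block, so degenerate paths are exercised.
#' @return a `landscape_config` object (a validated list).
#' @export
landscape_config <- function(seed = 1L,
                             extent = c(0, 160, 0, 160),
                             n_centers = 3L,
                             blocks_per_center = 180L,
                             n_background_blocks = 120L,
                             block_radial_mean = 12,
                             pop_meanlog = 4, pop_sdlog = 1,
                             n_parks = 150L,
                             park_center_frac = 0.85,
                             park_radial_mean = 8,
                             park_size_meanlog = log(0.03),
                             park_size_sdlog = 1.2,
                             park_size_band_step = 0.5,
                             min_park_size = default_min_park_size(),
                             urban_rural_breaks = c(4, 10, 18, 30, 48),
                             poverty_shape1 = 2, poverty_shape2 = 8,
                             include_edge_cases = TRUE) {
  cfg <- as.list(environment())
  stopifnot(length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3],
            n_centers >= 1, blocks_per_center >= 0,
            n_background_blocks >= 0,
            blocks_per_center * n_centers + n_background_blocks > 0,
            block_radial_mean > 0, pop_sdlog > 0,
            n_parks >= 1, park_center_frac >= 0, park_center_frac <= 1,
            park_radial_mean > 0, park_size_sdlog > 0,
            min_park_size >= 0,
            length(urban_rural_breaks) == 5,
            all(diff(urban_rural_breaks) > 0),
            poverty_shape1 > 0, poverty_shape2 > 0)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "landscape_config")
}

# ordered urban-rural band (1..6) from distance to the nearest core
ur_band <- function(dist, breaks) {
  findInterval(dist, breaks) + 1L
}

# Dirichlet draw via independent gammas; concentration interpolated between
# a diverse urban profile and a homogeneous rural one
subgroup_shares <- function(band) {
  urban <- c(4, 3, 2, 3, 1)
  rural <- c(12, 1, 0.4, 1, 0.6)
  t(vapply(band, function(b) {
    wconc <- urban + (rural - urban) * (b - 1) / 5
    g <- rgamma(length(wconc), shape = wconc)
    g / sum(g)
  }, numeric(length(SUBGROUPS))))
}

# FIPS-like 15-character IDs from nested spatial tiles:
# state (2 chars, 2x2 grid) / county (3, 3x3) / tract (6, 4x4) /
# block group digit (2x2) / block sequence (3)
tile_ids <- function(x, y, extent) {
  rel <- function(v, lo, hi, n) pmin(n - 1L, floor((v - lo) / (hi - lo) * n))
  sx <- rel(x, extent[1], extent[2], 2L); sy <- rel(y, extent[3], extent[4], 2L)
  state <- sprintf("%02d", sx * 2L + sy + 1L)
  w <- (extent[2] - extent[1]) / 2; h <- (extent[4] - extent[3]) / 2
  x1 <- x - extent[1] - sx * w; y1 <- y - extent[3] - sy * h
  cx <- rel(x1, 0, w, 3L); cy <- rel(y1, 0, h, 3L)
  county <- sprintf("%03d", cx * 3L + cy + 1L)
  x2 <- x1 - cx * w / 3; y2 <- y1 - cy * h / 3
  tx <- rel(x2, 0, w / 3, 4L); ty <- rel(y2, 0, h / 3, 4L)
  tract <- sprintf("%06d", tx * 4L + ty + 1L)
  x3 <- x2 - tx * w / 12; y3 <- y2 - ty * h / 12
  gx <- rel(x3, 0, w / 12, 2L); gy <- rel(y3, 0, h / 12, 2L)
  bg <- as.character(gx * 2L + gy + 1L)
  prefix <- paste0(state, county, tract, bg)
  seq_in <- ave(seq_along(prefix), prefix, FUN = seq_along)
  paste0(prefix, sprintf("%03d", seq_in))
}

#' Generate a synthetic landscape
#'
#' @param config a [landscape_config()].
#' @return a list of class `landscape` with elements `blocks` (block table
#'   with `pop_<group>` counts, `urban_rural` and `poverty` strata and the
#'   underlying `poverty_rate`), `parks` (park table) and `config`. All
#'   coordinates are planar miles; use `access_params(metric = "planar")`.
#' @examples
#' land <- generate_landscape(landscape_config(seed = 42))
#' nrow(land$blocks); nrow(land$parks)
#' @export
generate_landscape <- function(config = landscape_config()) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(config$seed)
  ext <- config$extent

  centers <- cbind(
    runif(config$n_centers, ext[1] + 0.2 * (ext[2] - ext[1]),
          ext[1] + 0.8 * (ext[2] - ext[1])),
    runif(config$n_centers, ext[3] + 0.2 * (ext[4] - ext[3]),
          ext[3] + 0.8 * (ext[4] - ext[3]))
  )

  radial_points <- function(n, mean_r) {
    ctr <- centers[sample.int(config$n_centers, n, replace = TRUE), ,
                   drop = FALSE]
    r <- rexp(n, rate = 1 / mean_r)
    theta <- runif(n, 0, 2 * pi)
    cbind(pmin(pmax(ctr[, 1] + r * cos(theta), ext[1]), ext[2]),
          pmin(pmax(ctr[, 2] + r * sin(theta), ext[3]), ext[4]))
  }
  uniform_points <- function(n) {
    cbind(runif(n, ext[1], ext[2]), runif(n, ext[3], ext[4]))
  }
  dist_to_core <- function(pts) {
    d <- outer(seq_len(nrow(pts)), seq_len(config$n_centers),
               function(i, j) sqrt((pts[i, 1] - centers[j, 1])^2 +
                                   (pts[i, 2] - centers[j, 2])^2))
    apply(d, 1, min)
  }

  # blocks
  n_clu <- config$n_centers * config$blocks_per_center
  bpts <- rbind(radial_points(n_clu, config$block_radial_mean),
                uniform_points(config$n_background_blocks))
  pop <- round(rlnorm(nrow(bpts), config$pop_meanlog, config$pop_sdlog))
  band <- ur_band(dist_to_core(bpts), config$urban_rural_breaks)

  # parks: radial (urban-dense) plus uniform background
  n_rad <- round(config$n_parks * config$park_center_frac)
  ppts <- rbind(radial_points(n_rad, config$park_radial_mean),
                uniform_points(config$n_parks - n_rad))
  pband <- ur_band(dist_to_core(ppts), config$urban_rural_breaks)
  meanlog <- config$park_size_meanlog +
    config$park_size_band_step * (pband - 1)
  size <- rlnorm(nrow(ppts), meanlog, config$park_size_sdlog)
  while (any(size < config$min_park_size)) { # truncation by redraw
    low <- size < config$min_park_size
    size[low] <- rlnorm(sum(low), meanlog[low], config$park_size_sdlog)
  }
  parks <- data.frame(
    park_id = sprintf("P%04d", seq_len(nrow(ppts))),
    x = ppts[, 1], y = ppts[, 2], size = size,
    stringsAsFactors = FALSE
  )

  shares <- subgroup_shares(band)
  counts <- t(vapply(seq_len(nrow(bpts)), function(i) {
    if (pop[i] == 0) return(integer(length(SUBGROUPS)))
    as.integer(rmultinom(1, pop[i], shares[i, ]))
  }, integer(length(SUBGROUPS))))
  colnames(counts) <- paste0("pop_", SUBGROUPS)

  blocks <- data.frame(
    block_id = tile_ids(bpts[, 1], bpts[, 2], ext),
    x = bpts[, 1], y = bpts[, 2], pop_total = pop,
    counts,
    urban_rural = NCHS_BANDS[band],
    stringsAsFactors = FALSE
  )

  # poverty is a block-group attribute: one Beta draw per block group,
  # inherited by member blocks
  bg_id <- substr(blocks$block_id, 1, 12)
  bgs <- sort(unique(bg_id))
  bg_rate <- setNames(rbeta(length(bgs), config$poverty_shape1,
                            config$poverty_shape2), bgs)
  blocks$poverty_rate <- as.vector(bg_rate[bg_id])
  blocks$poverty <- as.character(classify_poverty(blocks$poverty_rate))

  if (config$include_edge_cases && nrow(blocks) >= 2) {
    # a block sitting exactly on a park centroid (zero-distance path) and a
    # zero-population block
    blocks$x[1] <- parks$x[1]; blocks$y[1] <- parks$y[1]
    blocks$pop_total[nrow(blocks)] <- 0
    blocks[nrow(blocks), paste0("pop_", SUBGROUPS)] <- 0L
  }

  structure(list(blocks = validate_blocks(blocks), parks = parks,
                 config = config),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("Synthetic landscape: %d blocks, %d parks (seed %d)\n",
              nrow(x$blocks), nrow(x$parks), x$config$seed))
  invisible(x)
}

#' Tiny fixed worked-example landscape
#'
#' One block with two unit-size (1 sq mi) parks at exactly 1 and 2 miles on a
#' planar CRS — the hand-checkable fixture behind the documentation examples.
#' With the default parameters its Huff probabilities are (0.78983, 0.21017)
#' and its PWD is 1.21017 miles.
#'
#' @return list with `blocks` and `parks` tables (planar miles).
#' @export
worked_example_fixture <- function() {
  blocks <- data.frame(
    block_id = "010010001001001",
    x = 0, y = 0, pop_total = 100,
    stringsAsFactors = FALSE
  )
  parks <- data.frame(
    park_id = c("PARK_A", "PARK_B"),
    x = c(1, 2), y = c(0, 0), size = c(1, 1),
    stringsAsFactors = FALSE
  )
  list(blocks = blocks, parks = parks)
}
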