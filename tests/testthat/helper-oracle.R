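# Frozen expected values, computed with an independent 40-digit evaluator
# (mpmath) before the model code was written:
#   2^0.85 / 3^1.91
ORACLE_GRAVITY_2_3 <- 0.22109244364718113
#   1 + 2^-1.91
ORACLE_ATOTAL_11_12 <- 1.2660925456133400
#   Huff probabilities for sizes (1,1) sq mi at distances (1,2) miles,
#   alpha = 0.85, beta = 1.91
ORACLE_PROBS_11_12 <- c(0.78983167815395727, 0.21016832184604273)
#   expected distance sum(P * d) for the same instance
ORACLE_PWD_11_12 <- 1.21016832184604273
#   great-circle distance of 1 degree of longitude at the equator on a
#   sphere of radius 3958.8 miles: 3958.8 * pi / 180
ORACLE_ONE_DEGREE_MILES <- 69.0940944279515193

# Exhaustive k-nearest oracle with the stated tie rule: ascending distance,
# exact ties broken by ascending park_id (byte order). Deliberately naive --
# full pairwise scan, no index.
brute_force_knn <- function(blocks, parks, k, metric) {
  rows <- lapply(seq_len(nrow(blocks)), function(i) {
    d <- pairwise_distance(blocks$x[i], blocks$y[i], parks$x, parks$y,
                           metric = metric)
    ord <- order(d, parks$park_id, method = "radix")
    ord <- ord[seq_len(min(k, nrow(parks)))]
    data.frame(block_id = blocks$block_id[i], park_id = parks$park_id[ord],
               rank = seq_along(ord), distance_true = d[ord],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# random point landscape (planar miles or lon/lat degrees)
random_landscape <- function(n_blocks, n_parks, metric = "planar",
                             span = if (metric == "planar") 100 else 2) {
  if (metric == "planar") {
    bx <- runif(n_blocks, 0, span); by <- runif(n_blocks, 0, span)
    px <- runif(n_parks, 0, span); py <- runif(n_parks, 0, span)
  } else {
    bx <- runif(n_blocks, -span, span); by <- runif(n_blocks, 30, 30 + span)
    px <- runif(n_parks, -span, span); py <- runif(n_parks, 30, 30 + span)
  }
  list(
    blocks = data.frame(block_id = sprintf("B%04d", seq_len(n_blocks)),
                        x = bx, y = by,
                        pop_total = rpois(n_blocks, 50),
                        stringsAsFactors = FALSE),
    parks = data.frame(park_id = sprintf("P%04d", seq_len(n_parks)),
                       x = px, y = py,
                       size = rlnorm(n_parks, log(0.05), 1),
                       stringsAsFactors = FALSE)
  )
}

# a random single-block choice set plus park table, for property sweeps
random_choice_instance <- function(max_k = 9) {
  n <- sample(1:max_k, 1)
  parks <- data.frame(park_id = sprintf("P%02d", 1:n),
                      x = 0, y = 0,
                      size = rlnorm(n, log(0.1), 1.5),
                      stringsAsFactors = FALSE)
  d <- sort(runif(n, 0.05, 50))
  cs <- data.frame(block_id = "B1", park_id = parks$park_id,
                   rank = 1:n, distance = d, distance_true = d,
                   stringsAsFactors = FALSE)
  list(choice_set = cs, parks = parks)
}
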