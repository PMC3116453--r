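# Core gravity/Huff model. For block i and park j with size S_j (sq mi) and
# distance d_ij (miles):
#   accessibility  A_ij = S_j^alpha / d_ij^beta
#   total          A_i  = sum_j A_ij over the k nearest parks
#   Huff prob      P_ij = A_ij / A_i
#   block PWD      B_i  = sum_j P_ij * d_ij   (expected travel distance)

#' Gravity accessibility score of one park from one block
#'
#' `size^alpha / distance^beta`, the spatial-interaction weight of a park of
#' the given size at the given distance. Strictly increasing in size and, for
#' `beta > 0`, strictly decreasing in distance. Distances smaller than
#' `params$d_floor` are clamped up to it before use, so a zero distance never
#' reaches the formula. The optional `weight` is a forward-compatible
#' multiplicative attractiveness hook (default 1, unused by the shipped
#' pipeline).
#'
#' @param size park size(s) in square miles, `> 0`.
#' @param distance distance(s) in miles.
#' @param params an [access_params()] object.
#' @param weight optional per-park multiplicative weight.
#' @return numeric accessibility score(s); treated as dimensionless weights.
#' @examples
#' gravity_accessibility(1, 1)              # 1
#' gravity_accessibility(4, 2, access_params(alpha = 0.5, beta = 1)) # 1
#' @export
gravity_accessibility <- function(size, distance, params = access_params(),
                                  weight = 1) {
  params <- as_access_params(params)
  if (any(!is.finite(size)) || any(size <= 0))
    stop("park size must be > 0 (square miles)", call. = FALSE)
  if (any(!is.finite(distance)) || any(distance < 0))
    stop("distance must be finite and >= 0 (miles)", call. = FALSE)
  d <- pmax(distance, params$d_floor)
  weight * size^params$alpha / d^params$beta
}

# Resolve park sizes for a choice set, failing loudly on unknown IDs, and
# attach per-entry accessibility scores.
score_choice_set <- function(choice_set, parks, params) {
  stopifnot(is.data.frame(choice_set),
            all(c("block_id", "park_id", "distance") %in% names(choice_set)))
  if (nrow(choice_set) == 0L)
    stop("empty choice set: no parks to score", call. = FALSE)
  parks <- validate_parks(parks)
  pos <- match(choice_set$park_id, parks$park_id)
  if (anyNA(pos))
    stop("choice set references unknown park_id: ",
         paste(unique(choice_set$park_id[is.na(pos)]), collapse = ", "),
         call. = FALSE)
  choice_set$accessibility <- gravity_accessibility(
    parks$size[pos], choice_set$distance, params
  )
  choice_set
}

#' Total potential accessibility of each block
#'
#' Sums the gravity scores of every park in the block's choice set.
#'
#' @param choice_set choice-set data.frame from [nearest_k()] (one or many
#'   blocks).
#' @param parks park table resolving every `park_id` in the choice set.
#' @param params an [access_params()] object.
#' @return named numeric vector of `A_i` keyed by `block_id`, in first-
#'   appearance order; every value `> 0`.
#' @export
total_accessibility <- function(choice_set, parks, params = access_params()) {
  params <- as_access_params(params)
  cs <- score_choice_set(choice_set, parks, params)
  ids <- unique(cs$block_id)
  tot <- rowsum(cs$accessibility, factor(cs$block_id, levels = ids))
  setNames(as.vector(tot), ids)
}

#' Huff visit probabilities over each block's choice set
#'
#' Normalizes the gravity scores within each block:
#' `P_ij = A_ij / sum_j A_ij`. Probabilities are positive, sum to 1 per
#' block, and are returned in entry order.
#'
#' @inheritParams total_accessibility
#' @return the choice set with columns `accessibility` and `prob` appended.
#' @export
huff_probabilities <- function(choice_set, parks, params = access_params()) {
  params <- as_access_params(params)
  cs <- score_choice_set(choice_set, parks, params)
  ids <- unique(cs$block_id)
  f <- factor(cs$block_id, levels = ids)
  tot <- rowsum(cs$accessibility, f)
  cs$prob <- cs$accessibility / tot[as.integer(f)]
  cs
}

#' Block-level population-weighted distance (PWD)
#'
#' The expected travel distance from each block to its nearby parks:
#' `B_i = sum_j P_ij * d_ij`, a convex combination of the choice-set
#' distances, so always within their min-max envelope. With a single park in the
#' choice set it equals that park's distance.
#'
#' @inheritParams total_accessibility
#' @return data.frame with one row per block, in first-appearance order:
#'   `block_id`, `a_total` (total accessibility `A_i`), `pwd` (miles),
#'   `nearest_distance` (miles, clamped like the model distances).
#' @export
block_pwd <- function(choice_set, parks, params = access_params()) {
  params <- as_access_params(params)
  cs <- huff_probabilities(choice_set, parks, params)
  ids <- unique(cs$block_id)
  f <- factor(cs$block_id, levels = ids)
  data.frame(
    block_id = ids,
    a_total = as.vector(rowsum(cs$accessibility, f)),
    pwd = as.vector(rowsum(cs$prob * cs$distance, f)),
    nearest_distance = as.vector(tapply(cs$distance, f, min)),
    stringsAsFactors = FALSE
  )
}

#' Full access computation from block and park tables
#'
#' Builds the choice sets ([choice_sets()]) and evaluates the gravity/Huff
#' model ([block_pwd()]) in one step.
#'
#' @param blocks block table.
#' @param parks park table (apply [filter_parks()] first if a size floor is
#'   wanted).
#' @param params an [access_params()] object.
#' @return per-block access results as in [block_pwd()], in block-table order.
#' @examples
#' ex <- worked_example_fixture()
#' compute_access(ex$blocks, ex$parks, access_params(metric = "planar"))
#' @export
compute_access <- function(blocks, parks, params = access_params()) {
  params <- as_access_params(params)
  blocks <- validate_blocks(blocks)
  cs <- choice_sets(blocks, parks, params)
  block_pwd(cs, parks, params)
}
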