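# Population-weighted roll-up of block PWDs over a prefix-coded nesting
# hierarchy. For an aggregated unit k with member blocks i:
#   T_k = sum_i(Pop_i * B_i) / Pop_k,   Pop_k = sum_i Pop_i
# i.e. a population-weighted mean, so roll-ups are consistent across levels
# and every T_k lies within [min, max] of its member block PWDs.

#' Prefix-coded geographic hierarchy
#'
#' Levels are defined by prefix lengths of `block_id`, deepest first and
#' strictly decreasing — the FIPS pattern: 15-character block IDs nest into
#' block group (12), tract (11), county (5), state (2) and nation (0).
#'
#' @param levels named integer vector of prefix lengths, strictly decreasing.
#' @return a `hierarchy` object (named integer vector).
#' @examples
#' fips_hierarchy()
#' hierarchy_levels(c(block = 8, region = 4, nation = 0))
#' @export
hierarchy_levels <- function(levels) {
  stopifnot(is.numeric(levels), length(levels) >= 1,
            !is.null(names(levels)), all(nzchar(names(levels))))
  if (any(levels < 0) || any(diff(levels) >= 0))
    stop("prefix lengths must be non-negative and strictly decreasing",
         call. = FALSE)
  structure(setNames(as.integer(levels), names(levels)), class = "hierarchy")
}

#' @rdname hierarchy_levels
#' @export
fips_hierarchy <- function() {
  hierarchy_levels(c(block = 15, block_group = 12, tract = 11,
                     county = 5, state = 2, nation = 0))
}

# unit_id of every block at `level`; nation-style prefix 0 maps to "ALL"
unit_ids_at <- function(block_id, hierarchy, level) {
  if (!level %in% names(hierarchy))
    stop("unknown hierarchy level: ", level, call. = FALSE)
  n <- hierarchy[[level]]
  if (any(nchar(block_id) < n))
    stop("block_id shorter than the ", level, " prefix (", n, " characters)",
         call. = FALSE)
  if (n == 0L) rep("ALL", length(block_id)) else substr(block_id, 1L, n)
}

# Weighted-mean roll-up shared by all reporting functions. `groups` is a list
# of grouping vectors (unit ids first); zero-weight cells get an NA mean and
# a "zero_population" flag instead of being dropped.
rollup <- function(value, weight, groups) {
  key <- interaction(groups, drop = TRUE, sep = "\r", lex.order = TRUE)
  wsum <- rowsum(weight, key)
  vsum <- rowsum(weight * value, key)
  n <- as.vector(rowsum(rep(1L, length(value)), key))
  lev <- levels(key)
  parts <- strsplit(lev, "\r", fixed = TRUE)
  out <- data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- names(groups)
  out$n_blocks <- n
  out$pop <- as.vector(wsum)
  out$pwd <- ifelse(out$pop > 0, as.vector(vsum) / out$pop, NA_real_)
  out$flag <- ifelse(out$pop > 0, "", "zero_population")
  rownames(out) <- NULL
  out
}

# join access results to block attributes, failing on unmatched blocks
join_access <- function(access, blocks) {
  blocks <- validate_blocks(blocks)
  pos <- match(access$block_id, blocks$block_id)
  if (anyNA(pos))
    stop("access results reference unknown block_id: ",
         paste(unique(access$block_id[is.na(pos)]), collapse = ", "),
         call. = FALSE)
  cbind(access, blocks[pos, setdiff(names(blocks), names(access)),
                       drop = FALSE])
}

#' Aggregate block PWDs to a hierarchy level
#'
#' Population-weighted mean of the block-level PWD over every unit at the
#' requested level. Units whose total population is zero are reported with an
#' undefined (`NA`) PWD and a `"zero_population"` flag rather than dropped.
#'
#' @param access per-block results from [compute_access()] (needs `block_id`
#'   and the `value` column).
#' @param blocks block table carrying populations (and `block_id`).
#' @param level level name in `hierarchy`.
#' @param hierarchy a [hierarchy_levels()] object; FIPS-style by default.
#' @param value column of `access` to aggregate (`"pwd"` or
#'   `"nearest_distance"`).
#' @param weight column of `blocks` giving the weights (default
#'   `"pop_total"`).
#' @return data.frame: `level`, `unit_id`, `n_blocks`, `pop`, `pwd`, `flag`.
#' @export
aggregate_pwd <- function(access, blocks, level = "nation",
                          hierarchy = fips_hierarchy(), value = "pwd",
                          weight = "pop_total") {
  stopifnot(value %in% names(access))
  dat <- join_access(access, blocks)
  if (!weight %in% names(dat))
    stop("unknown weight column: ", weight, call. = FALSE)
  w <- dat[[weight]]
  if (anyNA(w)) {
    message(sum(is.na(w)), " blocks with missing ", weight,
            " counts treated as 0")
    w[is.na(w)] <- 0
  }
  out <- rollup(dat[[value]], w,
                list(unit_id = unit_ids_at(dat$block_id, hierarchy, level)))
  cbind(level = level, out, stringsAsFactors = FALSE)
}

#' Subgroup PWD at a hierarchy level
#'
#' Re-weights the block PWDs by a subgroup's population counts
#' (`pop_<subgroup>` column). The block-level PWD is shared across subgroups
#' — only the weights differ — so a subgroup present in a single block
#' reports that block's PWD.
#'
#' @inheritParams aggregate_pwd
#' @param subgroup subgroup label; the block table must carry
#'   `pop_<subgroup>`.
#' @return as [aggregate_pwd()], plus a `subgroup` column.
#' @export
subgroup_pwd <- function(access, blocks, subgroup, level = "nation",
                         hierarchy = fips_hierarchy()) {
  col <- paste0("pop_", subgroup)
  if (!col %in% names(blocks))
    stop("unknown subgroup '", subgroup, "': no column ", col, call. = FALSE)
  out <- aggregate_pwd(access, blocks, level, hierarchy, weight = col)
  cbind(out[1], subgroup = subgroup, out[-1], stringsAsFactors = FALSE)
}

#' Classify poverty rates into three classes
#'
#' Low: rate below 10%; medium: at least 10% and below 20%; high: 20% or
#' more.
#'
#' @param rate poverty rate(s) as fractions in `[0, 1]`.
#' @return factor with ordered levels `low < medium < high`.
#' @examples
#' classify_poverty(c(0.09, 0.10, 0.20))
#' @export
classify_poverty <- function(rate) {
  if (any(!is.finite(rate)) || any(rate < 0 | rate > 1))
    stop("poverty rate must lie in [0, 1]", call. = FALSE)
  cut(rate, breaks = c(-Inf, 0.10, 0.20, Inf), right = FALSE,
      labels = c("low", "medium", "high"), ordered_result = TRUE)
}

#' Stratified PWD report
#'
#' Cross-tabulated population-weighted PWD: one row per (unit, stratum-cell,
#' subgroup), the analog of a by-urban-rural-by-poverty access table. Cells
#' of the full cross-product with no member blocks are emitted with an
#' `"empty"` flag; zero-population cells with `"zero_population"`.
#'
#' @inheritParams aggregate_pwd
#' @param strata character vector of stratum column names in `blocks` (e.g.
#'   `c("urban_rural", "poverty")`). Missing labels become category
#'   `"missing"`.
#' @param subgroups optional subgroup labels to add re-weighted rows for;
#'   the pseudo-subgroup `"all"` (total population) is always included.
#' @return data.frame: `level`, `unit_id`, one column per stratum,
#'   `subgroup`, `n_blocks`, `pop`, `pwd`, `flag`.
#' @export
stratified_report <- function(access, blocks, strata, level = "nation",
                              hierarchy = fips_hierarchy(),
                              subgroups = NULL) {
  dat <- join_access(access, blocks)
  missing_strata <- setdiff(strata, names(dat))
  if (length(missing_strata))
    stop("undeclared stratum column(s): ",
         paste(missing_strata, collapse = ", "), call. = FALSE)
  cats <- lapply(strata, function(s) {
    v <- as.character(dat[[s]])
    if (anyNA(v)) {
      message(sum(is.na(v)), " blocks with missing '", s,
              "' label assigned category 'missing'")
      v[is.na(v)] <- "missing"
    }
    v
  })
  names(cats) <- strata
  bad <- setdiff(subgroups, subgroup_names(dat))
  if (length(bad))
    stop("unknown subgroup(s): ", paste(bad, collapse = ", "), call. = FALSE)
  unit <- unit_ids_at(dat$block_id, hierarchy, level)
  groups <- c(list(unit_id = unit), cats)

  one <- function(label, w) {
    if (anyNA(w)) w[is.na(w)] <- 0
    res <- rollup(dat$pwd, w, groups)
    cbind(level = level, res[seq_along(groups)], subgroup = label,
          res[-seq_along(groups)], stringsAsFactors = FALSE)
  }
  pieces <- c(list(one("all", dat$pop_total)),
              lapply(subgroups, function(g) one(g, dat[[paste0("pop_", g)]])))
  out <- do.call(rbind, pieces)

  # complete the cross-product so structurally empty cells are visible
  grid <- expand.grid(c(list(unit_id = sort(unique(unit))),
                        lapply(cats, function(v) sort(unique(v))),
                        list(subgroup = unique(out$subgroup))),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(d) do.call(paste, c(d[c("unit_id", strata, "subgroup")],
                                      sep = "\r"))
  pos <- match(key(grid), key(out))
  res <- cbind(level = level, grid, stringsAsFactors = FALSE)
  res$n_blocks <- ifelse(is.na(pos), 0L, out$n_blocks[pos])
  res$pop <- ifelse(is.na(pos), 0, out$pop[pos])
  res$pwd <- out$pwd[pos]
  res$flag <- ifelse(is.na(pos), "empty", out$flag[pos])
  rownames(res) <- NULL
  res
}

#' Within-stratum quintile classification of unit PWDs
#'
#' Ranks units by PWD within each stratum and cuts at the 20/40/60/80th
#' percentiles (linear-interpolation quantiles, `type = 7`). Class 1 is the
#' smallest PWD (best access); a value equal to a boundary takes the lower
#' class, so identical PWDs all land in class 1. Strata with fewer than 5
#' units with a defined PWD are flagged (`"too_few_units"`) and left
#' unclassified.
#'
#' @param units data.frame of aggregated units with a PWD column.
#' @param value name of the PWD column (default `"pwd"`).
#' @param stratum optional name of a stratum column; `NULL` classifies all
#'   units together.
#' @return `units` with `quintile` (integer 1–5 or `NA`) and
#'   `quintile_flag` columns appended.
#' @export
quintile_classify <- function(units, value = "pwd", stratum = NULL) {
  stopifnot(is.data.frame(units), value %in% names(units))
  if (!is.null(stratum) && !stratum %in% names(units))
    stop("unknown stratum column: ", stratum, call. = FALSE)
  grp <- if (is.null(stratum)) rep("all", nrow(units))
         else as.character(units[[stratum]])
  units$quintile <- NA_integer_
  units$quintile_flag <- ""
  for (g in unique(grp)) {
    sel <- which(grp == g)
    x <- units[[value]][sel]
    ok <- is.finite(x)
    if (sum(ok) < 5) {
      units$quintile_flag[sel] <- "too_few_units"
      next
    }
    breaks <- quantile(x[ok], probs = c(0.2, 0.4, 0.6, 0.8),
                       type = 7, names = FALSE)
    cls <- 1L + rowSums(outer(x[ok], breaks, ">"))
    units$quintile[sel[ok]] <- as.integer(cls)
    units$quintile_flag[sel[!ok]] <- "undefined_pwd"
  }
  units
}
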