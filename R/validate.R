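# Table contracts shared by the readers, the generator and the model:
#   blocks: block_id (unique, non-empty, hierarchical prefix-coded), x, y,
#           pop_total >= 0, optional pop_<group> columns >= 0, optional
#           stratum label columns.
#   parks:  park_id (unique), x, y, size in square miles > 0.

#' Validate a block table
#'
#' Checks the block-table contract: unique non-empty `block_id`, numeric
#' coordinates, non-negative `pop_total` and non-negative subgroup counts in
#' any `pop_<group>` column. Subgroup counts are not required to sum to
#' `pop_total` (groups may overlap); an exact partition is only enforced when
#' the caller declares one (see [subgroup_pwd()]).
#'
#' @param blocks data.frame with at least `block_id`, `x`, `y`, `pop_total`.
#' @return `blocks`, invisibly, with `block_id` coerced to character.
#' @export
validate_blocks <- function(blocks) {
  stopifnot(is.data.frame(blocks))
  need <- c("block_id", "x", "y", "pop_total")
  miss <- setdiff(need, names(blocks))
  if (length(miss))
    stop("block table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  blocks$block_id <- as.character(blocks$block_id)
  if (anyNA(blocks$block_id) || any(!nzchar(blocks$block_id)))
    stop("block_id must be non-empty", call. = FALSE)
  dup <- blocks$block_id[duplicated(blocks$block_id)]
  if (length(dup))
    stop("duplicate block_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (!is.numeric(blocks$x) || !is.numeric(blocks$y))
    stop("block coordinates must be numeric", call. = FALSE)
  if (!is.numeric(blocks$pop_total) || anyNA(blocks$pop_total) ||
      any(blocks$pop_total < 0))
    stop("pop_total must be numeric and >= 0", call. = FALSE)
  for (col in grep("^pop_", names(blocks), value = TRUE)) {
    if (col == "pop_total") next
    bad <- !is.na(blocks[[col]]) & blocks[[col]] < 0
    if (any(bad))
      stop("negative subgroup count in column ", col, call. = FALSE)
  }
  invisible(blocks)
}

#' Validate a park table
#'
#' @param parks data.frame with `park_id`, `x`, `y`, `size` (square miles).
#' @return `parks`, invisibly, with `park_id` coerced to character.
#' @export
validate_parks <- function(parks) {
  stopifnot(is.data.frame(parks))
  need <- c("park_id", "x", "y", "size")
  miss <- setdiff(need, names(parks))
  if (length(miss))
    stop("park table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  parks$park_id <- as.character(parks$park_id)
  dup <- parks$park_id[duplicated(parks$park_id)]
  if (length(dup))
    stop("duplicate park_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (!is.numeric(parks$size) || anyNA(parks$size) || any(parks$size <= 0))
    stop("park size must be numeric and > 0 (square miles)", call. = FALSE)
  invisible(parks)
}

# names of subgroup count columns ("pop_white" -> "white")
subgroup_names <- function(blocks) {
  cols <- setdiff(grep("^pop_", names(blocks), value = TRUE), "pop_total")
  sub("^pop_", "", cols)
}
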