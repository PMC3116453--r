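#' Run the full accessibility pipeline
#'
#' Orchestrates: park size-filter -> choice sets -> gravity/Huff PWD ->
#' population-weighted aggregation per level -> stratified report ->
#' nearest-park comparison -> within-stratum quintile classification, and
#' writes one CSV per product plus a `manifest.json` recording every
#' parameter and input checksum (the manifest fully determines the outputs).
#' On any stage error, partially written outputs are removed.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{input}{`list(blocks=, parks=, area_unit=)` file paths, or}
#'     \item{simulate}{arguments for [landscape_config()] to generate the
#'       landscape instead of reading files}
#'     \item{params}{arguments for [access_params()]}
#'     \item{min_park_size}{square miles; default [default_min_park_size()]}
#'     \item{levels}{hierarchy levels to aggregate to; default
#'       `c("tract", "county", "state", "nation")`}
#'     \item{strata}{stratum columns for the stratified report (those present
#'       in the block table are used; default
#'       `c("urban_rural", "poverty")`)}
#'     \item{subgroups}{subgroup labels; default: all `pop_<group>` columns}
#'     \item{r_level}{observation level of the comparison correlation;
#'       default `"block"`}
#'     \item{quintile_level}{unit level for quintile classification; default
#'       `"tract"`}
#'     \item{quintile_stratum}{stratum for within-stratum quintiles; default
#'       `"urban_rural"` when present}
#'     \item{output_dir}{directory for the outputs (required)}
#'   }
#' @param quiet suppress per-stage log messages.
#' @return invisibly, a list with the in-memory products (`access`,
#'   `aggregates`, `stratified`, `comparison`, `quintiles`, `manifest`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$output_dir))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok && length(written)) unlink(written), add = TRUE)
  log <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(x, file) {
    path <- file.path(out_dir, file)
    write_table_csv(x, path)
    written <<- c(written, path)
    path
  }

  params <- do.call(access_params, as.list(config$params))
  min_park_size <- config$min_park_size %||% default_min_park_size()

  inputs <- stage("read", {
    if (!is.null(config$simulate)) {
      land <- generate_landscape(do.call(landscape_config,
                                         as.list(config$simulate)))
      list(blocks = land$blocks, parks = land$parks, checksums = NULL,
           seed = land$config$seed)
    } else {
      if (is.null(config$input$blocks) || is.null(config$input$parks))
        stop("config$input must name blocks and parks files")
      blocks <- read_blocks(config$input$blocks, metric = params$metric)
      parks <- read_parks(config$input$parks, metric = params$metric,
                          area_unit = config$input$area_unit %||% "sqmi")
      list(blocks = blocks, parks = parks,
           checksums = as.list(tools::md5sum(c(config$input$blocks,
                                               config$input$parks))),
           seed = NULL)
    }
  })
  blocks <- inputs$blocks
  log("read ", nrow(blocks), " blocks, ", nrow(inputs$parks), " parks")

  parks <- stage("filter_parks",
                 filter_parks(inputs$parks, min_park_size, quiet = quiet))

  access <- stage("access", compute_access(blocks, parks, params))
  log("computed access for ", nrow(access), " blocks")
  emit(access, "access.csv")

  levels <- config$levels %||% c("tract", "county", "state", "nation")
  hierarchy <- fips_hierarchy()
  aggregates <- stage("aggregate", {
    res <- lapply(levels, function(lv)
      aggregate_pwd(access, blocks, lv, hierarchy))
    names(res) <- levels
    res
  })
  for (lv in levels) emit(aggregates[[lv]], paste0("aggregate_", lv, ".csv"))

  strata <- intersect(config$strata %||% c("urban_rural", "poverty"),
                      names(blocks))
  subgroups <- config$subgroups %||% subgroup_names(blocks)
  stratified <- if (length(strata)) {
    stage("stratify",
          stratified_report(access, blocks, strata, level = "nation",
                            hierarchy = hierarchy, subgroups = subgroups))
  } else NULL
  if (!is.null(stratified)) emit(stratified, "stratified_nation.csv")

  comparison <- stage("compare",
    comparison_report(access, blocks,
                      stratum = if ("urban_rural" %in% names(blocks))
                        "urban_rural" else NULL,
                      hierarchy = hierarchy,
                      r_level = config$r_level %||% "block"))
  emit(comparison, "comparison.csv")

  q_level <- config$quintile_level %||% "tract"
  q_stratum <- config$quintile_stratum %||%
    (if ("urban_rural" %in% names(blocks)) "urban_rural" else NULL)
  quintiles <- stage("classify", {
    units <- aggregate_pwd(access, blocks, q_level, hierarchy)
    if (!is.null(q_stratum)) {
      # a unit inherits the stratum of the bulk (population-majority) of its
      # member blocks
      uid <- unit_ids_at(blocks$block_id, hierarchy, q_level)
      lab <- vapply(split(seq_len(nrow(blocks)), uid), function(ix) {
        v <- blocks[[q_stratum]][ix]
        w <- blocks$pop_total[ix]
        names(which.max(rowsum(w + 1e-9, v)[, 1]))
      }, character(1))
      units[[q_stratum]] <- as.vector(lab[units$unit_id])
      quintile_classify(units, stratum = q_stratum)
    } else {
      quintile_classify(units)
    }
  })
  emit(quintiles, paste0("quintiles_", q_level, ".csv"))

  manifest <- list(
    parameters = list(alpha = params$alpha, beta = params$beta,
                      k = params$k, d_floor = params$d_floor,
                      metric = params$metric,
                      min_park_size = min_park_size),
    seed = inputs$seed,
    inputs = inputs$checksums,
    levels = levels, strata = strata, subgroups = subgroups,
    r_level = config$r_level %||% "block",
    quintile_level = q_level, quintile_stratum = q_stratum,
    n_blocks = nrow(blocks), n_parks = nrow(parks)
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  written <- c(written, manifest_path)
  ok <- TRUE
  log("pipeline complete: ", length(written), " files in ", out_dir)
  invisible(list(access = access, aggregates = aggregates,
                 stratified = stratified, comparison = comparison,
                 quintiles = quintiles, manifest = manifest,
                 files = written))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
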