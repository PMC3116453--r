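mk_access <- function(ids, pwd, nearest = pwd) {
  data.frame(block_id = ids, a_total = 1, pwd = pwd,
             nearest_distance = nearest, stringsAsFactors = FALSE)
}
mk_blocks <- function(ids, pop, ...) {
  data.frame(block_id = ids, x = 0, y = 0, pop_total = pop, ...,
             stringsAsFactors = FALSE)
}

test_that("hierarchies validate prefix structure", {
  h <- fips_hierarchy()
  expect_identical(names(h), c("block", "block_group", "tract", "county",
                               "state", "nation"))
  expect_error(hierarchy_levels(c(a = 3, b = 5)), "decreasing")
  expect_error(hierarchy_levels(c(3, 2)))
  acc <- mk_access("AB", 1)
  expect_error(aggregate_pwd(acc, mk_blocks("AB", 1), "county"),
               "shorter than")
  expect_error(aggregate_pwd(acc, mk_blocks("AB", 1), "continent"),
               "unknown hierarchy level")
})

test_that("population-weighted aggregation matches hand computations", {
  ids <- c("010010001001001", "010010001001002")
  acc <- mk_access(ids, c(2, 4))
  out <- aggregate_pwd(acc, mk_blocks(ids, c(100, 300)), "tract")
  expect_equal(out$pwd, 3.5) # (100*2 + 300*4) / 400
  expect_equal(out$pop, 400)
  expect_equal(out$n_blocks, 2L)

  single <- aggregate_pwd(mk_access(ids[1], 2.25),
                          mk_blocks(ids[1], 10), "county")
  expect_equal(single$pwd, 2.25)

  # zero-population unit: flagged, not dropped
  zero <- aggregate_pwd(acc, mk_blocks(ids, c(0, 0)), "nation")
  expect_true(is.na(zero$pwd))
  expect_identical(zero$flag, "zero_population")
  expect_equal(zero$n_blocks, 2L)
})

test_that("roll-ups are consistent across every adjacent pair of levels", {
  land <- generate_landscape(landscape_config(seed = 3))
  prm <- access_params(metric = "planar")
  acc <- compute_access(land$blocks, filter_parks(land$parks, quiet = TRUE),
                        prm)
  h <- fips_hierarchy()
  lv <- c("block_group", "tract", "county", "state", "nation")
  direct <- lapply(lv, function(l) aggregate_pwd(acc, land$blocks, l, h))
  names(direct) <- lv
  # weighted mean of any level's units == the next level up, and == nation
  for (i in seq_len(length(lv) - 1)) {
    lower <- direct[[lv[i]]]
    lower <- lower[lower$pop > 0, ] # zero-population units carry no weight
    upper <- direct[[lv[i + 1]]]
    upper <- upper[upper$pop > 0, ]
    n_up <- h[[lv[i + 1]]]
    parent <- if (n_up == 0) rep("ALL", nrow(lower))
              else substr(lower$unit_id, 1, n_up)
    recomb <- rowsum(lower$pop * lower$pwd, parent) / rowsum(lower$pop, parent)
    expect_equal(as.vector(recomb[upper$unit_id, ]), upper$pwd,
                 tolerance = 1e-9)
  }
  # convexity: every unit PWD inside its member blocks' envelope
  cty <- direct$county
  uid <- substr(acc$block_id, 1, 5)
  for (u in cty$unit_id) {
    member <- acc$pwd[uid == u]
    expect_gte(cty$pwd[cty$unit_id == u], min(member) - 1e-12)
    expect_lte(cty$pwd[cty$unit_id == u], max(member) + 1e-12)
  }
})

test_that("subgroup re-weighting shares block PWDs and recombines exactly", {
  ids <- c("010010001001001", "010010001001002")
  acc <- mk_access(ids, c(1, 5))
  blocks <- mk_blocks(ids, c(40, 60), pop_a = c(10, 30), pop_b = c(30, 30))
  out <- subgroup_pwd(acc, blocks, "a", "tract")
  expect_equal(out$pwd, 4.0) # (10*1 + 30*5) / 40
  expect_identical(out$subgroup, "a")
  expect_error(subgroup_pwd(acc, blocks, "nope"), "unknown subgroup")

  # counts equal to the total population reproduce the overall PWD
  blocks_eq <- mk_blocks(ids, c(40, 60), pop_a = c(40, 60))
  expect_equal(subgroup_pwd(acc, blocks_eq, "a", "tract")$pwd,
               aggregate_pwd(acc, blocks_eq, "tract")$pwd)

  # subgroup present in a single block reports that block's PWD
  blocks_one <- mk_blocks(ids, c(40, 60), pop_a = c(0, 7))
  expect_equal(subgroup_pwd(acc, blocks_one, "a", "tract")$pwd, 5)

  # declared exact partition recombines to the overall PWD
  land <- generate_landscape(landscape_config(seed = 9))
  prm <- access_params(metric = "planar")
  acc2 <- compute_access(land$blocks, filter_parks(land$parks, quiet = TRUE),
                         prm)
  groups <- c("white", "black", "asian", "hispanic", "other")
  gcols <- paste0("pop_", groups)
  expect_true(all(rowSums(land$blocks[gcols]) == land$blocks$pop_total))
  per <- vapply(groups, function(g)
    subgroup_pwd(acc2, land$blocks, g, "nation")$pwd, numeric(1))
  gpop <- colSums(land$blocks[gcols])
  overall <- aggregate_pwd(acc2, land$blocks, "nation")
  expect_equal(sum(gpop * per) / sum(gpop), overall$pwd, tolerance = 1e-9)
})

test_that("poverty rates classify at the documented thresholds", {
  got <- classify_poverty(c(0, 0.09, 0.0999, 0.10, 0.15, 0.1999, 0.20, 0.5, 1))
  expect_identical(as.character(got),
                   c("low", "low", "low", "medium", "medium", "medium",
                     "high", "high", "high"))
  expect_true(is.ordered(got))
  expect_error(classify_poverty(1.2), "\\[0, 1\\]")
  expect_error(classify_poverty(-0.1), "\\[0, 1\\]")
})

test_that("stratified reports cross-tabulate cells and flag empties", {
  ids <- sprintf("01001000100100%d", 1:4)
  acc <- mk_access(ids, c(2, 6, 2, 6))
  blocks <- mk_blocks(ids, c(10, 10, 10, 10),
                      grp = c("u", "u", "r", "r"))
  # one stratum with one category reduces to plain aggregation
  blocks1 <- mk_blocks(ids, rep(10, 4), grp = "u")
  one <- stratified_report(acc, blocks1, "grp")
  expect_equal(one$pwd, aggregate_pwd(acc, blocks1, "nation")$pwd)

  # even split into 2 categories: cell PWDs 2 and 6, overall 4
  blocks2 <- mk_blocks(ids, rep(10, 4), grp = c("a", "b", "a", "b"))
  acc2 <- mk_access(ids, c(2, 2, 2, 6))
  acc_even <- mk_access(ids, c(2, 6, 2, 6))
  rep2 <- stratified_report(acc_even, blocks2, "grp")
  expect_equal(rep2$pwd[rep2$grp == "a"], 2)
  expect_equal(rep2$pwd[rep2$grp == "b"], 6)
  expect_equal(aggregate_pwd(acc_even, blocks2, "nation")$pwd, 4)

  # 6 urban-rural x 3 poverty categories -> 18 national cells
  n <- 18
  ids18 <- sprintf("0100100010010%02d", 1:n)
  combos <- expand.grid(ur = paste0("band", 1:6),
                        pov = c("low", "medium", "high"),
                        stringsAsFactors = FALSE)
  blocks18 <- mk_blocks(ids18, rep(5, n), urban_rural = combos$ur,
                        poverty = combos$pov)
  rep18 <- stratified_report(mk_access(ids18, runif(n)), blocks18,
                             c("urban_rural", "poverty"))
  expect_equal(nrow(rep18), 18)
  expect_true(all(rep18$flag == ""))

  # an unpopulated combination is emitted and flagged empty
  blocks_gap <- blocks18[combos$ur != "band6" | combos$pov != "high", ]
  acc_gap <- mk_access(blocks_gap$block_id, runif(nrow(blocks_gap)))
  rep_gap <- stratified_report(acc_gap, blocks_gap,
                               c("urban_rural", "poverty"))
  gap <- rep_gap[rep_gap$urban_rural == "band6" & rep_gap$poverty == "high", ]
  expect_identical(gap$flag, "empty")
  expect_true(is.na(gap$pwd))

  expect_error(stratified_report(acc, blocks, "not_a_stratum"),
               "undeclared stratum")
  expect_error(stratified_report(acc, blocks, "grp", subgroups = "ghost"),
               "unknown subgroup")
})

test_that("quintile classes follow linear-interpolation quantiles with low ties", {
  u5 <- data.frame(unit_id = letters[1:5], pwd = c(5, 3, 1, 4, 2))
  got <- quintile_classify(u5)
  expect_identical(got$quintile, as.integer(c(5, 3, 1, 4, 2)))

  same <- data.frame(unit_id = letters[1:6], pwd = rep(2.2, 6))
  expect_true(all(quintile_classify(same)$quintile == 1L))

  set.seed(40)
  u100 <- data.frame(unit_id = sprintf("u%03d", 1:100), pwd = runif(100))
  got <- quintile_classify(u100)
  expect_identical(as.vector(table(got$quintile)), rep(20L, 5))
  # independent check: classes agree with rank-based quantile membership
  breaks <- quantile(u100$pwd, c(0.2, 0.4, 0.6, 0.8), type = 7)
  ref <- 1L + (u100$pwd > breaks[1]) + (u100$pwd > breaks[2]) +
    (u100$pwd > breaks[3]) + (u100$pwd > breaks[4])
  expect_identical(got$quintile, as.integer(ref))

  # strata with < 5 defined units are flagged, not classified
  small <- data.frame(unit_id = letters[1:7],
                      pwd = c(1, 2, 3, NA, 5, 6, 7),
                      band = c(rep("a", 4), rep("b", 3)))
  got <- quintile_classify(small, stratum = "band")
  expect_true(all(is.na(got$quintile)))
  expect_true(all(got$quintile_flag == "too_few_units"))
})
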