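params_planar <- access_params(metric = "planar")

test_that("gravity accessibility matches closed forms and rejects bad input", {
  expect_equal(gravity_accessibility(1, 1), 1.0)
  expect_equal(gravity_accessibility(4, 2, access_params(alpha = 0.5, beta = 1)), 1.0)
  expect_equal(gravity_accessibility(2, 3), ORACLE_GRAVITY_2_3,
               tolerance = 1e-12)
  # distance 0 is clamped to d_floor, never reaching the singular formula
  expect_equal(gravity_accessibility(1, 0, access_params(d_floor = 0.05)),
               1 / 0.05^1.91)
  expect_error(gravity_accessibility(0, 1), "size")
  expect_error(gravity_accessibility(-2, 1), "size")
  expect_error(access_params(beta = 51), "beta")
  expect_error(access_params(beta = -1), "beta")
  # monotone in size, antitone in distance
  expect_true(gravity_accessibility(2, 1) > gravity_accessibility(1, 1))
  expect_true(gravity_accessibility(1, 2) < gravity_accessibility(1, 1))
})

test_that("total accessibility sums gravity scores over the choice set", {
  one <- data.frame(block_id = "B1", park_id = "P1", rank = 1,
                    distance = 1, stringsAsFactors = FALSE)
  parks1 <- data.frame(park_id = "P1", x = 0, y = 0, size = 1)
  expect_equal(unname(total_accessibility(one, parks1)), 1.0)

  two_same <- data.frame(block_id = "B1", park_id = c("P1", "P2"),
                         rank = 1:2, distance = c(3, 3),
                         stringsAsFactors = FALSE)
  parks2 <- data.frame(park_id = c("P1", "P2"), x = 0, y = 0, size = c(2, 2))
  expect_equal(unname(total_accessibility(two_same, parks2)),
               2 * gravity_accessibility(2, 3))

  ex <- data.frame(block_id = "B1", park_id = c("P1", "P2"), rank = 1:2,
                   distance = c(1, 2), stringsAsFactors = FALSE)
  parksu <- data.frame(park_id = c("P1", "P2"), x = 0, y = 0, size = c(1, 1))
  expect_equal(unname(total_accessibility(ex, parksu)), ORACLE_ATOTAL_11_12,
               tolerance = 1e-12)

  badcs <- transform(ex, park_id = c("P1", "GHOST"))
  expect_error(total_accessibility(badcs, parksu), "GHOST")
  expect_error(total_accessibility(ex[0, ], parksu), "empty")
})

test_that("Huff probabilities normalize and preserve entry order", {
  parks1 <- data.frame(park_id = "P1", x = 0, y = 0, size = 1)
  one <- data.frame(block_id = "B1", park_id = "P1", rank = 1, distance = 5)
  expect_equal(huff_probabilities(one, parks1)$prob, 1.0)

  # scores 3 and 1 (alpha = 1, beta = 0) -> probabilities 0.75 / 0.25
  p10 <- access_params(alpha = 1, beta = 0)
  cs <- data.frame(block_id = "B1", park_id = c("P1", "P2"), rank = 1:2,
                   distance = c(1, 2))
  parks31 <- data.frame(park_id = c("P1", "P2"), x = 0, y = 0, size = c(3, 1))
  expect_equal(huff_probabilities(cs, parks31, p10)$prob, c(0.75, 0.25))

  # seven identical parks -> uniform 1/7
  cs7 <- data.frame(block_id = "B1", park_id = sprintf("P%d", 1:7),
                    rank = 1:7, distance = rep(2, 7))
  parks7 <- data.frame(park_id = sprintf("P%d", 1:7), x = 0, y = 0, size = 1)
  expect_equal(huff_probabilities(cs7, parks7)$prob, rep(1 / 7, 7))

  ex <- data.frame(block_id = "B1", park_id = c("P1", "P2"), rank = 1:2,
                   distance = c(1, 2))
  parksu <- data.frame(park_id = c("P1", "P2"), x = 0, y = 0, size = c(1, 1))
  expect_equal(huff_probabilities(ex, parksu)$prob, ORACLE_PROBS_11_12,
               tolerance = 1e-9)
})

test_that("block PWD is the Huff-weighted expected distance", {
  parks1 <- data.frame(park_id = "P1", x = 0, y = 0, size = 1)
  one <- data.frame(block_id = "B1", park_id = "P1", rank = 1, distance = 5)
  res <- block_pwd(one, parks1)
  expect_equal(res$pwd, 5.0)
  expect_equal(res$nearest_distance, 5.0)

  # equal accessibility scores at 2 and 4 miles -> midpoint 3.0
  p00 <- access_params(alpha = 0, beta = 0)
  cs <- data.frame(block_id = "B1", park_id = c("P1", "P2"), rank = 1:2,
                   distance = c(2, 4))
  parks2 <- data.frame(park_id = c("P1", "P2"), x = 0, y = 0, size = c(1, 9))
  expect_equal(block_pwd(cs, parks2, p00)$pwd, 3.0)

  ex <- data.frame(block_id = "B1", park_id = c("P1", "P2"), rank = 1:2,
                   distance = c(1, 2))
  parksu <- data.frame(park_id = c("P1", "P2"), x = 0, y = 0, size = c(1, 1))
  res <- block_pwd(ex, parksu)
  expect_equal(res$pwd, ORACLE_PWD_11_12, tolerance = 1e-9)
  expect_equal(res$a_total, ORACLE_ATOTAL_11_12, tolerance = 1e-9)
  expect_equal(res$nearest_distance, 1.0)
})

test_that("probabilities sum to one and PWD stays inside the distance envelope", {
  set.seed(101)
  for (i in 1:200) {
    inst <- random_choice_instance()
    prm <- access_params(alpha = runif(1, 0, 2), beta = runif(1, 0, 4))
    hp <- huff_probabilities(inst$choice_set, inst$parks, prm)
    tot <- sum(hp$prob)
    expect_lt(abs(tot - 1), 1e-9)
    expect_true(all(hp$prob > 0 & hp$prob <= 1))
    res <- block_pwd(inst$choice_set, inst$parks, prm)
    expect_gte(res$pwd, min(inst$choice_set$distance) - 1e-12)
    expect_lte(res$pwd, max(inst$choice_set$distance) + 1e-12)
    expect_gt(res$a_total, 0)
  }
})

test_that("PWD is strictly decreasing in beta and hits the closed-form limits", {
  cs <- data.frame(block_id = "B1", park_id = c("P1", "P2", "P3"),
                   rank = 1:3, distance = c(1, 2.5, 6))
  parks <- data.frame(park_id = c("P1", "P2", "P3"), x = 0, y = 0,
                      size = c(0.5, 2, 1))
  betas <- c(0, 0.5, 1, 1.91, 3)
  pwds <- vapply(betas, function(b)
    block_pwd(cs, parks, access_params(beta = b))$pwd, numeric(1))
  expect_true(all(diff(pwds) < 0))

  # alpha = 0, beta = 0: uniform probabilities, PWD = arithmetic mean
  res <- block_pwd(cs, parks, access_params(alpha = 0, beta = 0))
  expect_equal(res$pwd, mean(cs$distance), tolerance = 1e-12)
})

test_that("growing one park pulls probability and PWD toward it", {
  prm <- params_planar
  cs <- data.frame(block_id = "B1", park_id = c("P1", "P2"), rank = 1:2,
                   distance = c(1, 3))
  mk <- function(s2) data.frame(park_id = c("P1", "P2"), x = 0, y = 0,
                                size = c(1, s2))
  p_small <- huff_probabilities(cs, mk(1), prm)$prob
  p_big <- huff_probabilities(cs, mk(5), prm)$prob
  expect_gt(p_big[2], p_small[2])
  pwd_small <- block_pwd(cs, mk(1), prm)$pwd
  pwd_big <- block_pwd(cs, mk(5), prm)$pwd
  expect_gt(pwd_big, pwd_small) # moves toward the (farther) enlarged park
})

test_that("PWD scales linearly under uniform distance scaling away from the floor", {
  set.seed(7)
  prm <- access_params(d_floor = 1e-6)
  for (i in 1:25) {
    inst <- random_choice_instance()
    cc <- runif(1, 0.5, 4)
    scaled <- transform(inst$choice_set, distance = distance * cc)
    p1 <- huff_probabilities(inst$choice_set, inst$parks, prm)$prob
    p2 <- huff_probabilities(scaled, inst$parks, prm)$prob
    expect_equal(p2, p1, tolerance = 1e-9)
    expect_equal(block_pwd(scaled, inst$parks, prm)$pwd,
                 cc * block_pwd(inst$choice_set, inst$parks, prm)$pwd,
                 tolerance = 1e-9)
  }
})

test_that("compute_access reproduces the worked example end to end", {
  ex <- worked_example_fixture()
  res <- compute_access(ex$blocks, ex$parks, params_planar)
  expect_equal(res$pwd, ORACLE_PWD_11_12, tolerance = 1e-9)
  expect_equal(res$nearest_distance, 1.0)
})
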