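test_that("age-group classification uses an inclusive 55-year threshold", {
  expect_equal(classify_age_group(c(54, 55, 60)), c("YAG", "OAG", "OAG"))
  expect_error(classify_age_group(NA_real_), "data error")
})

test_that("belief update is the stated convex combination", {
  expect_equal(update_belief(0.2, 0.6, 1), 0.6)    # full replacement
  expect_equal(update_belief(0.2, 0.6, 0), 0.2)    # identity
  expect_equal(update_belief(0.2, 0.6, 0.5), 0.4)
  expect_error(update_belief(0.2, 0.6, 1.2), "invalid parameter")
})

test_that("pattern importance is the revenue-weighted share of use", {
  expect_equal(as.vector(pattern_importance(c(2, 1), c(3, 4))$importance),
               c(0.6, 0.4))
  expect_equal(as.vector(pattern_importance(c(1, 2), c(2, 1))$importance),
               c(0.5, 0.5))
  expect_equal(as.vector(pattern_importance(c(0, 5), c(10, 2))$importance),
               c(0, 1))
  res <- pattern_importance(c(0, 0), c(3, 4))
  expect_true(res$no_utilization)
  expect_equal(as.vector(res$importance), c(0, 0))
  expect_error(pattern_importance(c(-1, 1), c(1, 1)), "data error")
})

test_that("importance rows sum to one whenever any product is positive", {
  set.seed(21)
  for (i in 1:200) {
    UA <- matrix(rexp(8), 4, 2) * rbinom(8, 1, 0.8)
    I <- matrix(rexp(8), 4, 2)
    res <- pattern_importance(UA, I)
    sums <- rowSums(res$importance)
    expect_true(all(abs(sums[!res$no_utilization] - 1) < 1e-12))
    expect_true(all(sums[res$no_utilization] == 0))
  }
})

test_that("factor scores hit their rescaling anchors", {
  h <- data.frame(
    perception_planting_regulation = c(5, 1, 3),
    perception_fuelwood_regulation = c(5, 1, 3),
    soil_quality = 2, land_fragmentation = 0.5, fuel_slope = 2,
    fuel_restriction = 1, fuel_distance_km = 8,
    education_level = c(2, 1, 3), health_level = c(2, 1, 3))
  sc <- factor_scores(h, belief = 0.5)
  expect_equal(sc$social_pressure, c(1, 0, 0.5))
  expect_equal(sc$labor_literacy, c(0.5, 0, 1))
  expect_equal(sc$ecological_value_identity, rep(0.5, 3))
  expect_true(all(as.matrix(sc) >= 0 & as.matrix(sc) <= 1))
})

test_that("factor weights normalize salience coefficients", {
  expect_equal(factor_weights(c(1, 3, 0, 0)), c(0.25, 0.75, 0, 0))
  expect_equal(sum(factor_weights(runif(4, 0.1, 5))), 1)
  expect_error(factor_weights(c(0, 0, 0, 0)), "invalid salience")
  expect_error(factor_weights(c(1, -1, 1, 1)), "invalid salience")
})

test_that("final decision reduces to importance when all modulations are one", {
  imp <- rbind(c(0.6, 0.4), c(0.2, 0.8))
  ones <- matrix(1, 2, 4)
  out <- final_decision(imp, ones, salience = c(2, 1, 4, 3),
                        modulation = "identity")
  expect_equal(out, imp)
})

test_that("final decision matches the hand-evaluated weighted modulation", {
  m <- matrix(c(0.2, 0.6, 0.9, 0.1), 1)
  out <- final_decision(rbind(c(1, 1)), m, salience = c(1, 3, 0, 0),
                        modulation = "identity")
  expect_equal(as.vector(out), c(0.5, 0.5))
  # zero importance propagates
  out0 <- final_decision(rbind(c(0, 0)), m, salience = c(1, 3, 0, 0),
                         modulation = "identity")
  expect_equal(as.vector(out0), c(0, 0))
})

test_that("weaker modulation weakly decreases every final intensity", {
  set.seed(31)
  for (i in 1:50) {
    imp <- pattern_importance(matrix(rexp(6), 3, 2),
                              matrix(rexp(6), 3, 2))$importance
    m <- matrix(runif(12), 3, 4)
    a <- runif(4, 0.1, 2)
    base <- final_decision(imp, m, a, modulation = "identity")
    m2 <- m
    j <- sample(4, 1)
    m2[, j] <- m2[, j] * runif(1)
    lower <- final_decision(imp, m2, a, modulation = "identity")
    expect_true(all(lower <= base + 1e-12))
  }
})

test_that("aggregation to community level is a group-wise mean", {
  d <- data.frame(
    community_id = c("C1", "C1", "C2"),
    age_group = c("OAG", "OAG", "YAG"),
    final_cropland = c(0.4, 0.6, 0.3),
    final_fuelwood = c(0.2, 0.2, 0.9))
  agg <- aggregate_to_community(d)
  c1 <- agg[agg$community_id == "C1" & agg$age_group == "OAG", ]
  expect_equal(c1$x1, 0.5)
  expect_equal(c1$x2, 0.2)
  expect_equal(c1$n_households, 2L)
  # single household keeps its own value
  c2 <- agg[agg$community_id == "C2" & agg$age_group == "YAG", ]
  expect_equal(c2$x1, 0.3)
  # cells with no members are missing
  expect_true(is.na(agg$x1[agg$community_id == "C2" & agg$age_group == "OAG"]))
  expect_error(aggregate_to_community(d[0, ]), "data error")
})

test_that("aggregation matches an explicit double-loop oracle", {
  set.seed(41)
  d <- data.frame(
    community_id = sample(paste0("C", 1:3), 40, replace = TRUE),
    age_group = sample(c("OAG", "YAG"), 40, replace = TRUE),
    final_cropland = runif(40),
    final_fuelwood = runif(40))
  agg <- aggregate_to_community(d)
  for (i in seq_len(nrow(agg))) {
    vals <- c()
    for (r in seq_len(nrow(d))) {
      if (d$community_id[r] == agg$community_id[i] &&
          d$age_group[r] == agg$age_group[i]) {
        vals <- c(vals, d$final_cropland[r])
      }
    }
    if (length(vals) == 0) {
      expect_true(is.na(agg$x1[i]))
    } else {
      expect_equal(agg$x1[i], mean(vals))
    }
  }
})

test_that("decide_households produces bounded, group-labelled intensities", {
  hh <- generate_households(tiny_config(seed = 13))
  dec <- decide_households(hh)
  expect_equal(nrow(dec), nrow(hh))
  expect_true(all(dec$age_group %in% c("OAG", "YAG")))
  num <- c("importance_cropland", "importance_fuelwood", "final_cropland",
           "final_fuelwood", "intensity_state_cropland",
           "intensity_next_fuelwood")
  for (v in num) expect_true(all(dec[[v]] >= 0 & dec[[v]] <= 1), label = v)
  # the factor gate never amplifies the importance
  expect_true(all(dec$final_cropland <= dec$importance_cropland + 1e-12))
  # next-period intensity never exceeds the current state
  expect_true(all(dec$intensity_next_cropland <=
                  dec$intensity_state_cropland + 1e-12))
})
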