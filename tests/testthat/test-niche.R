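test_that("index matrix applies the stated ratio formulas", {
  cd <- data.frame(
    community_id = c("C1", "C1", "C2", "C2"),
    age_group = c("OAG", "YAG", "OAG", "YAG"),
    x1_state = c(0.4, 0.5, 0.3, 0.6), x1_next = c(0.3, 0.45, 0.25, 0.5),
    x2_state = c(0.2, 0.3, 0.1, 0.4), x2_next = c(0.15, 0.25, 0.08, 0.35),
    n_households = 5L)
  cm <- data.frame(
    community_id = c("C1", "C2"), reserve_id = "R1", inside_reserve = 1L,
    TACL_2013 = c(100, 80), AACL_2013 = c(60, 40),
    TACL_2018 = c(90, 75), AACL_2018 = c(45, 30),
    TAFL_2013 = c(400, 300), AAFL_2013 = c(100, 90),
    TAFL_2018 = c(410, 310), AAFL_2018 = c(95, 93),
    TPR_2013 = c(1000, 800), LFQH_2013 = c(450, 400),
    TPR_2018 = c(950, 780), LFQH_2018 = c(420, 390),
    x8_2013 = c(0.2, 0.3), x8_2018 = c(0.25, 0.35),
    x9_2013 = c(0.1, 0.2), x9_2018 = c(0.15, 0.2),
    x10_2013 = c(0.2, 0.2), x10_2018 = c(0.3, 0.25))
  ps <- data.frame(reserve_id = "R1", AGPH3rd = 100, AGPH4th = 120,
                   PGPH3rd = 20, PGPH4th = 25, ANR = 200, ASFB = 50)
  pc <- expand.grid(community_id = c("C1", "C2"),
                    age_group = c("OAG", "YAG"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pc$x6 <- c(3.2, 3.4, 3.0, 3.6)
  pc$x7 <- c(2.8, 3.1, 2.9, 3.3)

  im <- build_index_matrix(cd, cm, ps, pc)
  expect_equal(nrow(im$state), 4)
  r <- which(im$rows$community_id == "C1" & im$rows$age_group == "OAG")
  expect_equal(unname(im$state[r, "x3"]), 0.6)                  # AACL/TACL
  expect_equal(unname(im$potential[r, "x3"]), 45 / 90 - 0.6)
  expect_equal(unname(im$state[r, "x5"]), 0.45)                 # LFQH/TPR
  expect_equal(unname(im$state[, "x11"]), rep(0.2, 4))  # habitat change rate
  expect_equal(unname(im$state[, "x12"]), rep(0.25, 4))
  expect_equal(unname(im$state[, "x13"]), rep(0.25, 4)) # ASFB/ANR
  expect_equal(unname(im$state[, "x14"]), rep(2, 4))    # ASFB/PGPH4th
  expect_equal(unname(im$potential[, "x11"]), rep(0, 4))
  expect_equal(unname(im$state[r, "x1"]), 0.4)
  expect_equal(unname(im$potential[r, "x1"]), -0.1)

  # zero denominators are reported with the index and unit
  ps_bad <- ps
  ps_bad$AGPH3rd <- 0
  expect_error(build_index_matrix(cd, cm, ps_bad, pc), "x11")
  cm_bad <- cm
  cm_bad$TACL_2013[2] <- 0
  expect_error(build_index_matrix(cd, cm_bad, ps, pc), "x3.*C2")
})

test_that("z-score standardization centers and scales with sample sd", {
  out <- standardize_indexes(cbind(a = c(2, 4, 6)))
  expect_equal(as.vector(out), c(-1, 0, 1))
  set.seed(8)
  m <- matrix(rnorm(60, 5, 2), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  z <- standardize_indexes(m)
  expect_true(all(abs(colMeans(z)) < 1e-12))
  expect_equal(unname(apply(z, 2, sd)), rep(1, 3))
  expect_error(standardize_indexes(cbind(a = rep(2, 5))), "degenerate")
})

test_that("coefficient-of-variation weights normalize as stated", {
  x <- cbind(a = c(0.8, 1, 1.2), b = c(0.7, 1, 1.3))  # CVs 0.2 and 0.3
  w <- compute_weights(x)
  expect_equal(unname(w$W), c(0.4, 0.6))
  expect_equal(sum(w$W), 1)
  w1 <- compute_weights(cbind(a = c(1, 2, 3)))
  expect_equal(unname(w1$W), 1)
  # identical CVs give equal weights
  weq <- compute_weights(cbind(a = c(0.8, 1, 1.2), b = 2 * c(0.8, 1, 1.2)))
  expect_equal(unname(weq$W), c(0.5, 0.5))
  expect_error(compute_weights(cbind(a = c(-1, 0, 1))), "weight undefined")
})

test_that("dimension weights are sums of member-index weights", {
  im <- toy_index_matrix(n = 5)
  adj <- adjusted_values(im)
  w <- compute_weights(adj$raw, meta = im$meta)
  expect_equal(sum(w$w_d), 1)
  expect_equal(unname(w$w_d["X1"]), unname(sum(w$W[c("x1", "x2")])))
})

test_that("adjusted values combine state and annualized potential", {
  im <- list(state = cbind(x1 = c(0.4, 0.6)),
             potential = cbind(x1 = c(0.1, 0)), meta = NULL)
  out <- adjusted_values(im, A = 1, period_years = 5, rescale = "none")
  expect_equal(as.vector(out$raw), c(0.42, 0.6))
  # A = 0 ignores the potential entirely
  out0 <- adjusted_values(im, A = 0, rescale = "none")
  expect_equal(as.vector(out0$raw), c(0.4, 0.6))
})

test_that("min-max rescaling is strictly positive and order-preserving", {
  im <- toy_index_matrix(n = 6)
  im$potential[] <- 0
  adj <- adjusted_values(im)
  expect_true(all(adj$scaled > 0 & adj$scaled <= 1))
  # positive-direction columns keep the state ordering when potential is 0
  expect_equal(order(adj$scaled[, "x5"]), order(im$state[, "x5"]))
  # negative-direction columns reverse it
  expect_equal(order(adj$scaled[, "x1"]), rev(order(im$state[, "x1"])))
  # without direction handling the utilization orientation is kept
  prof <- adjusted_values(im, apply_direction = FALSE)
  expect_equal(order(prof$scaled[, "x1"]), order(im$state[, "x1"]))
  # constant columns raise a degenerate-column error by default
  im$state[, "x3"] <- 0.5
  im$potential[, "x3"] <- 0
  expect_error(adjusted_values(im), "degenerate")
  expect_silent(adjusted_values(im, on_constant = "uniform"))
})

test_that("relative niche widths are community shares of weighted resources", {
  meta <- data.frame(index = "x1", dimension = "X1", direction = 1)
  scaled <- cbind(x1 = c(1, 1, 2))
  w <- list(W = c(x1 = 1))
  expect_equal(relative_niche_width(scaled, w, "X1", meta),
               c(0.25, 0.25, 0.5))
  # a single unit owns the whole dimension
  expect_equal(relative_niche_width(cbind(x1 = 3), w, "X1", meta), 1)
  # equal resources split evenly
  expect_equal(relative_niche_width(cbind(x1 = rep(2, 4)), w, "X1", meta),
               rep(0.25, 4))
  expect_error(relative_niche_width(scaled, w, "X9", meta), "spec error")
})

test_that("comprehensive niche width is the dimension-weighted aggregate", {
  expect_equal(
    comprehensive_niche(rbind(c(0.1, 0.2, 0.3, 0.4)), rep(0.25, 4)), 0.25)
  N <- cbind(X1 = c(0.3, 0.7), X2 = c(0.3, 0.7))
  expect_equal(comprehensive_niche(N, c(X1 = 0.4, X2 = 0.6)), c(0.3, 0.7))
  expect_error(comprehensive_niche(N, c(X1 = 0.4, X3 = 0.6)), "data error")
})

test_that("niche overlap is the cosine of ownership profiles", {
  expect_equal(niche_overlap(c(0.3, 0.3, 0.4), c(0.3, 0.3, 0.4)), 1)
  expect_equal(niche_overlap(c(1, 0), c(0, 1)), 0)
  expect_equal(niche_overlap(c(1, 0), c(0.5, 0.5)), 1 / sqrt(2),
               tolerance = 1e-12)
  expect_true(is.na(niche_overlap(c(0, 0), c(1, 1))))
  # scale invariance of the shares
  expect_equal(niche_overlap(c(2, 1, 1), c(3, 1, 2)),
               niche_overlap(c(2, 1, 1) * 10, c(3, 1, 2) / 7))
})

test_that("overlap matrices are symmetric with unit diagonal on [0, 1]", {
  set.seed(17)
  for (i in 1:100) {
    P <- matrix(rexp(6 * 14), 6, 14)
    O <- overlap_matrix(P)
    expect_true(all(abs(O - t(O)) < 1e-14))
    expect_equal(unname(diag(O)), rep(1, 6))
    expect_true(all(O >= 0 & O <= 1))
  }
})

test_that("widths and overlaps match the brute-force oracle to 1e-12", {
  # 3 communities x 4 indexes in two dimensions
  set.seed(23)
  meta <- data.frame(index = c("a", "b", "c", "d"),
                     dimension = c("D1", "D1", "D2", "D2"),
                     direction = 1)
  raw <- matrix(runif(12, 0.5, 2), 3, 4,
                dimnames = list(NULL, meta$index))
  w <- compute_weights(raw, meta = meta)
  scaled <- raw  # already positive; widths operate on any positive matrix
  N <- sapply(c("D1", "D2"), function(d) {
    relative_niche_width(scaled, w, d, meta = meta)
  })
  M <- comprehensive_niche(N, w$w_d)
  oracle <- bruteforce_widths(scaled, as.list(w$W), meta)
  expect_equal(unname(N), unname(oracle$N), tolerance = 1e-12)
  expect_equal(M, oracle$M, tolerance = 1e-12)
  O <- overlap_matrix(scaled)
  for (j in 1:3) {
    for (k in 1:3) {
      expect_equal(O[j, k], bruteforce_overlap(scaled[j, ], scaled[k, ]),
                   tolerance = 1e-12)
    }
  }
})

test_that("widths conserve to one and respond monotonically to resources", {
  set.seed(29)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    im <- toy_index_matrix(n = n, seed = i)
    adj <- adjusted_values(im)
    w <- compute_weights(adj$raw, meta = im$meta)
    dims <- unique(im$meta$dimension)
    N <- sapply(dims, function(d) {
      relative_niche_width(adj$scaled, w, d, meta = im$meta)
    })
    expect_true(all(abs(colSums(N) - 1) < 1e-9))
    M <- comprehensive_niche(N, w$w_d)
    expect_lt(abs(sum(M) - 1), 1e-9)

    # raising one unit's resource on one index: zero-sum share shift
    scaled2 <- adj$scaled
    scaled2[1, "x5"] <- scaled2[1, "x5"] * 2
    N2 <- relative_niche_width(scaled2, w, "X2", meta = im$meta)
    N1 <- relative_niche_width(adj$scaled, w, "X2", meta = im$meta)
    expect_gte(N2[1], N1[1] - 1e-12)
    expect_true(all(N2[-1] <= N1[-1] + 1e-12))
  }
})

test_that("overlap ratios classify positive and negative differences", {
  r <- overlap_ratio(0.4, 0.5)
  expect_equal(r$ratio, 0.8)
  expect_equal(r$classification, "positive")
  r2 <- overlap_ratio(0.6, 0.4)
  expect_equal(r2$ratio, 1.5)
  expect_equal(r2$classification, "negative")
  expect_equal(overlap_ratio(0.5, 0.5)$classification, "undefined")
  expect_equal(overlap_ratio(0.5, 0)$classification, "undefined")
  expect_true(is.na(overlap_ratio(0.5, 0)$ratio))
})

test_that("evaluate_niche returns coherent widths and pair overlaps", {
  cfg <- tiny_config(seed = 19)
  res <- run_all(cfg)
  widths <- res$niche$widths
  expect_lt(abs(sum(widths$M) - 1), 1e-9)
  for (d in c("N_X1", "N_X2", "N_X3", "N_X4")) {
    expect_lt(abs(sum(widths[[d]]) - 1), 1e-9)
  }
  ov <- res$niche$overlaps
  expect_true(all(ov$O_OAG >= 0 & ov$O_OAG <= 1, na.rm = TRUE))
  expect_true(all(ov$classification %in%
                  c("positive", "negative", "undefined")))
})
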