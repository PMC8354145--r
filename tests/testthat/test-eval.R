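test_that("auc matches pair enumeration and handles ties", {
  # enumerate the 4 pairs: (0.9 beats both) + (0.4 beats 0.1) = 3/4
  expect_equal(auc(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  expect_equal(auc(c(5, 6), c(1, 2)), 1)
  expect_equal(auc(rep(0.3, 4), rep(0.3, 9)), 0.5)
  # invariant under strictly monotone transforms
  withr::with_seed(3, {
    p <- runif(40); b <- runif(70)
  })
  expect_equal(auc(p, b), auc(qlogis(p), qlogis(b)))
  expect_equal(auc(p, b), auc(p^3, b^3))
  expect_error(auc(numeric(0), b), "non-empty")
})

test_that("max_sss_threshold maximizes sensitivity + specificity", {
  # exhaustive scan of the worked example: t = 0.8 is the unique argmax
  expect_equal(max_sss_threshold(c(0.9, 0.8, 0.2), c(0.7, 0.3, 0.1)), 0.8)
  # perfectly separated sets: the smallest presence score
  expect_equal(max_sss_threshold(c(0.8, 0.9), c(0.1, 0.2)), 0.8)
  # identical distributions: sens + spec = 1 everywhere, lowest score wins
  expect_equal(max_sss_threshold(c(0.2, 0.5), c(0.2, 0.5)), 0.2)
  # property: the returned threshold beats every other candidate (by scan)
  for (s in 1:5) {
    withr::with_seed(s, {
      pr <- runif(30, 0.3, 1); bg <- runif(60, 0, 0.7)
    })
    t_star <- max_sss_threshold(pr, bg)
    val <- function(t) mean(pr >= t) + mean(bg < t)
    cand <- sort(unique(c(pr, bg)))
    expect_true(all(val(t_star) >= vapply(cand, val, numeric(1)) - 1e-12))
  }
})

test_that("pe_curve reproduces analytic window masses for an ideal model", {
  # background quasi-uniform on [0, 1]; all test presences uniform on [0.5, 1]
  bgs <- seq(0, 1, length.out = 10001)
  tst <- seq(0.5, 1, length.out = 2000)
  curve <- pe_curve(tst, bgs)
  w <- 0.1
  mids <- curve$windows$midpoint
  # analytic expected and presence masses of each closed window
  e_an <- pmin(mids + w / 2, 1) - pmax(mids - w / 2, 0)
  p_an <- (pmin(mids + w / 2, 1) - pmax(pmax(mids - w / 2, 0), 0.5)) / 0.5
  f_an <- pmax(p_an, 0) / e_an
  expect_equal(curve$windows$f_mean, f_an, tolerance = 0.01)
  # F ~ 0 below 0.4, ~ 2 well above 0.6
  expect_true(all(curve$windows$f_mean[mids < 0.44] == 0))
  expect_equal(curve$windows$f_mean[mids > 0.6 & mids < 0.94],
               rep(2, sum(mids > 0.6 & mids < 0.94)), tolerance = 0.02)
  # Boyce equals an independent enumeration of the same definition: counted
  # window masses, ratios, and rank correlation computed from ranks directly
  e_cnt <- vapply(mids, function(m) {
    sum(bgs >= m - w / 2 & bgs <= m + w / 2) / length(bgs)
  }, numeric(1))
  p_cnt <- vapply(mids, function(m) {
    sum(tst >= m - w / 2 & tst <= m + w / 2) / length(tst)
  }, numeric(1))
  f_cnt <- p_cnt[e_cnt > 0] / e_cnt[e_cnt > 0]
  boyce_oracle <- cor(rank(f_cnt), rank(mids[e_cnt > 0]))
  expect_equal(curve$boyce, boyce_oracle, tolerance = 1e-10)
  # the monotone shape keeps the index high (ties among the flat segments
  # hold the rank correlation below the tie-free value of 1)
  expect_gt(curve$boyce, 0.8)
})

test_that("pe_curve null behavior and degenerate inputs", {
  withr::with_seed(17, {
    bgs <- runif(3000)
    reps <- lapply(1:10, function(r) sample(bgs, 500))
  })
  curve <- pe_curve(reps, bgs)
  expect_true(all(abs(curve$windows$f_mean - 1) <= 0.25))
  expect_true(all(curve$f_matrix >= 0))
  # bands from >= 2 replicates straddle the mean
  expect_true(all(curve$windows$lo <= curve$windows$f_mean + 1e-12))
  expect_true(all(curve$windows$hi >= curve$windows$f_mean - 1e-12))
  # a constant prediction surface cannot support a curve
  expect_error(suppressWarnings(pe_curve(rep(0.4, 50), rep(0.4, 200))),
               "window")
})

test_that("ideal-model Boyce exceeds every null Boyce", {
  b <- fixture_bundle()
  p <- as.vector(b$truth$values)
  eta <- log(p / (1 - p))                       # recover q up to a constant
  q <- exp(eta) / sum(exp(eta))
  withr::with_seed(71, bg <- sample(length(p), 2000))
  ideal <- vapply(1:10, function(s) {
    withr::with_seed(1000 + s,
      pe_curve(p[sample(length(p), 300, prob = q)], p[bg])$boyce)
  }, numeric(1))
  null <- vapply(1:10, function(s) {
    withr::with_seed(2000 + s,
      pe_curve(p[sample(length(p), 300)], p[bg])$boyce)
  }, numeric(1))
  expect_true(all(ideal >= 0.8))
  expect_gt(min(ideal), max(null))
})

test_that("classify_suitability finds the random-chance crossing and median split", {
  bgs <- seq(0, 1, length.out = 10001)
  tst <- seq(0.5, 1, length.out = 2000)
  curve <- pe_curve(tst, bgs)
  cls <- classify_suitability(curve, tst, mode = "methods_text")
  # F crosses 1 where presences start (0.5), up to window resolution
  expect_equal(cls$t_unsuitable, 0.5, tolerance = 0.03)
  # median of uniform-[0.5, 1] presences above the threshold ~ 0.75
  expect_equal(cls$t_high, 0.75, tolerance = 0.01)
  expect_false(cls$all_unsuitable)
  expect_lt(cls$t_unsuitable, cls$t_high)
  # F identically 1 never rises above chance: everything unsuitable
  null_curve <- pe_curve(bgs, bgs)
  expect_warning(cls0 <- classify_suitability(null_curve, bgs), "unsuitable")
  expect_true(cls0$all_unsuitable)
})

test_that("figure4 mode requires the lower band to clear the reference", {
  bgs <- seq(0, 1, length.out = 5001)
  withr::with_seed(23, reps <- lapply(1:10, function(r) runif(400, 0.5, 1)))
  curve <- pe_curve(reps, bgs)
  m_text <- classify_suitability(curve, reps, mode = "methods_text")
  fig4 <- classify_suitability(curve, reps, mode = "figure4")
  # the band crossing cannot precede the mean crossing
  expect_gte(fig4$t_unsuitable, m_text$t_unsuitable - 1e-9)
})

test_that("classification thresholds move up when test scores shift up", {
  bgs <- seq(0, 1, length.out = 5001)
  withr::with_seed(29, base <- runif(600, 0.4, 1))
  up <- pmin(base + 0.15, 1)
  c1 <- classify_suitability(pe_curve(base, bgs), base)
  c2 <- classify_suitability(pe_curve(up, bgs), up)
  expect_gte(c2$t_unsuitable, c1$t_unsuitable)
  expect_gte(c2$t_high, c1$t_high)
})

test_that("classify_raster partitions the map and counts rook components", {
  # constant-zero raster: one unsuitable component covering everything
  flat <- grid_layer(matrix(0, 4, 5), cell_size = 10)
  out <- classify_raster(flat, c(0.14, 0.30))
  expect_equal(nrow(out$components), 1)
  expect_equal(out$components$class, 1)
  expect_equal(out$components$area, 20 * 100)
  # its exterior ring encloses exactly the full area
  ring <- out$rings[["1"]][[1]]
  shoelace <- function(r) {
    n <- nrow(r); j <- c(n, 1:(n - 1))
    sum(r[j, 1] * r[, 2] - r[, 1] * r[j, 2]) / 2
  }
  expect_equal(abs(shoelace(ring)), 20 * 100)

  # checkerboard split around the upper threshold: every cell is its own
  # rook component
  v <- matrix(0.95, 6, 6)
  v[(row(v) + col(v)) %% 2 == 0] <- 0.2
  cb <- classify_raster(grid_layer(v, 1), c(0.5, 0.9))
  expect_equal(nrow(cb$components), 36)
  expect_setequal(unique(cb$components$class), c(1, 3))
  # class areas partition the unmasked region
  expect_equal(sum(cb$components$area), 36)

  # nodata cells are excluded from every class
  v[2, 2] <- NA
  cb2 <- classify_raster(grid_layer(v, 1), c(0.5, 0.9))
  expect_equal(sum(cb2$components$area), 35)
  expect_true(is.na(cb2$class_layer$values[2, 2]))
})

test_that("suitability classes use half-open threshold bins", {
  gl <- grid_layer(matrix(c(0.139, 0.14, 0.299, 0.30, 0.9, 0), 2, 3),
                   cell_size = 1)
  out <- classify_raster(gl, c(0.14, 0.30))
  expect_equal(as.vector(out$class_layer$values), c(1, 2, 2, 3, 3, 1))
})
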