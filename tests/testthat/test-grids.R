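test_that("focal_mean matches a brute-force neighborhood oracle", {
  # hand example: 3x3 values 1..9 (column-major), cell 100 m, radius 100 m;
  # the center cell's inclusive neighborhood is the von Neumann cross
  gl <- grid_layer(matrix(1:9, 3, 3), cell_size = 100)
  fm <- focal_mean(gl, 100)
  expect_equal(fm$values[2, 2], mean(c(2, 4, 5, 6, 8)))

  # randomized grid with nodata, checked against a double-loop oracle
  withr::with_seed(7, {
    v <- matrix(rnorm(12 * 10), 12, 10)
    v[sample(120, 15)] <- NA
  })
  gl <- grid_layer(v, cell_size = 100)
  radius <- 250
  fm <- focal_mean(gl, radius)
  oracle <- matrix(NA_real_, 12, 10)
  for (i in 1:12) for (j in 1:10) {
    if (is.na(v[i, j])) next
    acc <- c()
    for (ii in 1:12) for (jj in 1:10) {
      if (!is.na(v[ii, jj]) &&
          sqrt((ii - i)^2 + (jj - j)^2) * 100 <= radius + 1e-9) {
        acc <- c(acc, v[ii, jj])
      }
    }
    oracle[i, j] <- mean(acc)
  }
  expect_equal(fm$values, oracle, tolerance = 1e-10)
})

test_that("focal_mean trivial contracts: constants, identity radius, errors", {
  const <- grid_layer(matrix(7, 9, 9), cell_size = 30)
  expect_equal(focal_mean(const, 1170)$values, matrix(7, 9, 9))
  gl <- grid_layer(matrix(rnorm(25), 5, 5), cell_size = 100)
  expect_equal(focal_mean(gl, 49)$values, gl$values)
  expect_error(focal_mean(gl, -1), "non-negative")
})

test_that("focal_mean is linear and bounded by the neighborhood extremes", {
  withr::with_seed(11, {
    x <- grid_layer(matrix(rnorm(400), 20, 20), cell_size = 50, name = "x")
    y <- grid_layer(matrix(rnorm(400), 20, 20), cell_size = 50, name = "y")
  })
  for (r in c(60, 130)) {
    lhs <- focal_mean(grid_layer(2 * x$values + 3 * y$values, 50), r)$values
    rhs <- 2 * focal_mean(x, r)$values + 3 * focal_mean(y, r)$values
    expect_equal(lhs, rhs, tolerance = 1e-10)
    sm <- focal_mean(x, r)$values
    expect_true(all(sm <= max(x$values) + 1e-12))
    expect_true(all(sm >= min(x$values) - 1e-12))
  }
})

test_that("focal_mean drops nodata neighbours without propagating them", {
  v <- matrix(1, 3, 3); v[1, 1] <- NA
  fm <- focal_mean(grid_layer(v, 100), 100)
  expect_true(is.na(fm$values[1, 1]))          # nodata stays nodata
  expect_equal(fm$values[2, 2], 1)             # neighbours unaffected
  # fully masked neighborhood -> nodata
  v2 <- matrix(NA_real_, 3, 3); v2[1, 1] <- 5
  fm2 <- focal_mean(grid_layer(v2, 100), 100)
  expect_equal(fm2$values[1, 1], 5)
  expect_true(all(is.na(fm2$values[-1])))
})

test_that("mcp_buffer obeys the Minkowski-sum area formula", {
  tri <- data.frame(x = c(0, 1, 0), y = c(0, 0, 1))
  expect_equal(region_area(mcp_buffer(tri, 0)), 0.5)
  for (b in c(0.5, 2)) {
    reg <- mcp_buffer(tri, b)
    expect_equal(region_area(reg), 0.5 + (2 + sqrt(2)) * b + pi * b^2,
                 tolerance = 1e-4)
    expect_true(all(in_region(reg, tri$x, tri$y)))
  }
  # monotone in buffer
  areas <- vapply(c(0, 1, 2, 5), function(b) region_area(mcp_buffer(tri, b)),
                  numeric(1))
  expect_true(all(diff(areas) > 0))
  # interior points do not become hull vertices
  quad <- data.frame(x = c(0, 4, 0, 1), y = c(0, 0, 4, 1))
  expect_equal(nrow(mcp_buffer(quad, 0)$polygon), 3)
  # degenerate geometry
  expect_error(mcp_buffer(data.frame(x = 1:3, y = 1:3), 1), "collinear")
  expect_error(mcp_buffer(data.frame(x = 1:2, y = 1:2), 1), ">= 3")
})

test_that("sample_background is exhaustive, reproducible and mask-aware", {
  v <- matrix(rnorm(100), 10, 10)
  v[, 1:5] <- NA                       # half the grid masked
  st <- covariate_stack(list(grid_layer(v, 10, name = "a")))
  # exhaustive draw returns every eligible cell center
  all50 <- sample_background(st, NULL, 50, seed = 3)
  expect_equal(nrow(dplyr::distinct(all50, x, y)), 50)
  expect_true(all(all50$x > 50))       # masked (low-x) half untouched
  # bit-reproducible
  expect_identical(sample_background(st, NULL, 20, seed = 42),
                   sample_background(st, NULL, 20, seed = 42))
  # capacity error names both counts
  expect_error(sample_background(st, NULL, 51, seed = 1), "51.*50")
  # exclusion removes occupied cells
  ex <- all50[1:10, c("x", "y")]
  rest <- sample_background(st, NULL, 40, seed = 5, exclude = ex)
  expect_equal(nrow(dplyr::inner_join(rest, ex, by = c("x", "y"))), 0)
})

test_that("background occupancy is uniform across quadrants", {
  v <- matrix(0, 40, 40)
  v[, 1:20] <- NA
  st <- covariate_stack(list(grid_layer(v, 10, name = "a")))
  pts <- purrr::map_dfr(1:13, function(s)
    sample_background(st, NULL, 770, seed = s))  # ~10^4 draws in total
  expect_true(all(pts$x > 200))
  # unmasked half has 800 cells; top/bottom quadrant counts ~ Binomial(n, 1/2)
  n <- nrow(pts)
  top <- sum(pts$y > 200)
  bound <- 2.576 * sqrt(n * 0.25)
  expect_lt(abs(top - n / 2), bound)
})

test_that("extract_values uses half-open cell intervals", {
  gl <- grid_layer(matrix(1:4, 2, 2), cell_size = 1, name = "v")
  st <- covariate_stack(list(gl))
  # exact center
  expect_equal(extract_values(st, data.frame(x = 0.5, y = 0.5))$v, 1)
  # point on the shared vertical edge belongs to the right-hand cell
  expect_equal(extract_values(st, data.frame(x = 1, y = 0.5))$v, 3)
  # point on the shared horizontal edge belongs to the upper cell
  expect_equal(extract_values(st, data.frame(x = 0.5, y = 1))$v, 2)
  # constant layer extracts constant
  cst <- covariate_stack(list(grid_layer(matrix(2, 3, 3), 1, name = "c")))
  ev <- extract_values(cst, data.frame(x = runif(5, 0, 3), y = runif(5, 0, 3)))
  expect_true(all(ev$c == 2))
  # outside the extent: flagged invalid with a warning
  expect_warning(out <- extract_values(st, data.frame(x = 5, y = 5)),
                 "outside")
  expect_false(out$valid[1])
  expect_true(is.na(out$v[1]))
})

test_that("ESRI ASCII grids round-trip", {
  withr::with_seed(9, v <- matrix(round(rnorm(30), 4), 5, 6))
  v[2, 3] <- NA
  gl <- grid_layer(v, cell_size = 25, origin = c(100, 200), name = "cov")
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(gl, path)
  back <- read_ascii_grid(path, name = "cov")
  expect_equal(back$values, gl$values)
  expect_equal(back$cell_size, 25)
  expect_equal(back$origin, c(100, 200))
})

test_that("regions serialize to parseable GeoJSON", {
  reg <- mcp_buffer(data.frame(x = c(0, 10, 0), y = c(0, 0, 10)), 2)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_region_geojson(reg, path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  ring <- gj$features[[1]]$geometry$coordinates[[1]]
  expect_equal(ring[[1]], ring[[length(ring)]])  # closed
})

test_that("covariate stacks enforce shared geometry and unique names", {
  a <- grid_layer(matrix(0, 2, 2), 10, name = "a")
  b <- grid_layer(matrix(0, 2, 2), 10, name = "b")
  expect_s3_class(covariate_stack(a, b), "covariate_stack")
  expect_error(covariate_stack(a, grid_layer(matrix(0, 3, 2), 10, name = "b")),
               "geometry")
  expect_error(covariate_stack(a, a), "unique")
})
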