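test_that("fit_binomial_glm recovers the closed-form logit difference", {
  # grouped 2x2 table: P(y=1|x=0) = 0.2 (50/250), P(y=1|x=1) = 0.8 (200/250);
  # slope on raw x is logit(0.8) - logit(0.2) = 2 ln 4
  x <- rep(c(0, 1), each = 250)
  y <- c(rep(1, 50), rep(0, 200), rep(1, 200), rep(0, 50))
  fit <- fit_binomial_glm(y, x)
  expect_equal(fit$coefficient_raw, 2 * log(4), tolerance = 1e-6)
  expect_false(fit$separated)
  # AIC = -2 logLik + 2k with k = 2
  ll <- sum(stats::dbinom(y, 1, stats::plogis(fit$intercept +
    fit$coefficient * scale(x)[, 1]), log = TRUE))
  expect_equal(fit$aic, -2 * ll + 4, tolerance = 1e-6)
})

test_that("fit_binomial_glm matches a brute-force likelihood grid search", {
  nll <- function(a, b, y, z) {
    -sum(stats::dbinom(y, 1, stats::plogis(a + b * z), log = TRUE))
  }
  for (s in 1:5) {
    withr::with_seed(s, {
      x <- rnorm(20)
      y <- rbinom(20, 1, stats::plogis(0.3 * x))
    })
    if (length(unique(y)) < 2) next
    fit <- fit_binomial_glm(y, x)
    z <- scale(x)[, 1]
    # coarse-to-fine grid search around 0
    ctr <- c(0, 0); width <- 8
    for (lvl in 1:8) {
      as <- seq(ctr[1] - width, ctr[1] + width, length.out = 41)
      bs <- seq(ctr[2] - width, ctr[2] + width, length.out = 41)
      grid <- expand.grid(a = as, b = bs)
      vals <- mapply(nll, grid$a, grid$b, MoreArgs = list(y = y, z = z))
      ctr <- unlist(grid[which.min(vals), ])
      width <- width / 8
    }
    expect_equal(fit$coefficient, unname(ctr[2]), tolerance = 1e-3)
  }
})

test_that("fit_binomial_glm flags independence and separation sensibly", {
  withr::with_seed(3, {
    x <- rnorm(400)
    y <- rbinom(400, 1, 0.5)
  })
  fit <- fit_binomial_glm(y, x)
  expect_lt(abs(fit$z), 3)
  # complete separation is a flagged result, not an exception
  xs <- c(rnorm(20, -3), rnorm(20, 3))
  ys <- rep(c(0, 1), each = 20)
  expect_true(fit_binomial_glm(ys, xs)$separated)
  expect_error(fit_binomial_glm(rep(1, 10), rnorm(10)), "both classes")
})

make_scale_fixture <- function(transform = identity) {
  withr::with_seed(21, base <- matrix(runif(900, 0, 100), 30, 30))
  l50 <- grid_layer(transform(base), 30, name = "v")
  sm <- focal_mean(grid_layer(base, 30, name = "v"), 300)
  l270 <- grid_layer(transform(sm$values), 30, name = "v")
  list("50" = covariate_stack(list(l50)), "270" = covariate_stack(list(l270)))
}

test_that("optimize_scale selects by AIC with a smallest-radius tie-break", {
  withr::with_seed(22, base <- matrix(runif(900, 0, 100), 30, 30))
  st <- covariate_stack(list(grid_layer(base, 30, name = "v")))
  stacks <- list("50" = st, "270" = st, "742" = st)  # identical across radii
  withr::with_seed(23, {
    pres <- tibble::tibble(x = runif(60, 0, 900), y = runif(60, 0, 900))
    bg <- tibble::tibble(x = runif(600, 0, 900), y = runif(600, 0, 900))
  })
  sel <- optimize_scale(pres, bg, stacks, "v")
  expect_equal(attr(sel, "selected_radius"), 50)
  expect_true(all(sel$selected == (sel$radius == 50)))
})

test_that("optimize_scale is invariant to affine rescaling of the covariate", {
  withr::with_seed(24, {
    pres <- tibble::tibble(x = runif(80, 0, 900), y = runif(80, 0, 900))
    bg <- tibble::tibble(x = runif(800, 0, 900), y = runif(800, 0, 900))
  })
  s1 <- optimize_scale(pres, bg, make_scale_fixture(), "v")
  s2 <- optimize_scale(pres, bg, make_scale_fixture(function(v) 3 * v - 40), "v")
  expect_equal(attr(s1, "selected_radius"), attr(s2, "selected_radius"))
  expect_equal(s1$coefficient, s2$coefficient, tolerance = 1e-6)
  expect_equal(s1$aic, s2$aic, tolerance = 1e-6)
})

test_that("pearson_screen drops the lower-preference member of each hot pair", {
  withr::with_seed(31, {
    canopy_cover <- rnorm(200)
    e <- rnorm(200)
  })
  e <- residuals(lm(e ~ canopy_cover))
  diameter_diversity <- 0.9 * scale(canopy_cover)[, 1] +
    sqrt(1 - 0.81) * scale(e)[, 1]
  tab <- tibble::tibble(canopy_cover, diameter_diversity,
                        other = rnorm(200))
  rep <- pearson_screen(tab, threshold = 0.6,
                        preference = c("canopy_cover", "diameter_diversity"))
  expect_true("canopy_cover" %in% rep$retained)
  expect_equal(rep$dropped$variable, "diameter_diversity")
  expect_equal(rep$dropped$partner, "canopy_cover")
  # duplicated column: exactly one of the pair goes
  tab2 <- tibble::tibble(a = rnorm(50), b = rnorm(50))
  tab2$a_copy <- tab2$a
  rep2 <- pearson_screen(tab2, preference = c("a", "a_copy"))
  expect_setequal(rep2$retained, c("a", "b"))
  # nothing dropped when all |r| <= threshold
  withr::with_seed(32, tab3 <- tibble::as_tibble(matrix(rnorm(300), 100, 3,
    dimnames = list(NULL, c("p", "q", "r")))))
  expect_length(pearson_screen(tab3)$dropped$variable, 0)
})

test_that("pearson_screen output never contains a hot pair (property)", {
  for (s in 1:5) {
    withr::with_seed(s, {
      z <- matrix(rnorm(120 * 3), 120, 3)
      mix <- matrix(runif(3 * 6, -1, 1), 3, 6)
      tab <- tibble::as_tibble(as.data.frame(z %*% mix))
    })
    rep <- pearson_screen(tab, threshold = 0.6)
    if (length(rep$retained) >= 2) {
      cm <- abs(stats::cor(tab[, rep$retained]))
      expect_true(all(cm[upper.tri(cm)] <= 0.6))
    }
  }
})

test_that("pearson_screen drops constant columns with a warning", {
  tab <- tibble::tibble(a = rnorm(30), b = rnorm(30), c = rep(1, 30))
  expect_warning(rep <- pearson_screen(tab), "constant")
  expect_false("c" %in% rep$retained)
})

test_that("vif matches closed forms and is order-invariant", {
  # mutually orthogonal columns -> all VIF = 1
  po <- stats::poly(1:40, 3)
  tab <- tibble::tibble(a = po[, 1], b = po[, 2], c = po[, 3])
  expect_equal(vif(tab)$vif, rep(1, 3), tolerance = 1e-10)
  # exact empirical r = 0.6 -> both VIF = 1 / (1 - 0.36) = 1.5625
  withr::with_seed(41, z <- matrix(rnorm(200), 100, 2))
  q <- qr.Q(qr(cbind(1, z)))[, 2:3]     # orthonormal, mean zero
  x1 <- q[, 1]; x2 <- 0.6 * q[, 1] + 0.8 * q[, 2]
  v <- vif(tibble::tibble(x1 = x1, x2 = x2))
  expect_equal(v$vif, c(1.5625, 1.5625), tolerance = 1e-9)
  # exact collinearity -> infinite
  v2 <- vif(tibble::tibble(x1 = x1, x2 = x2, x3 = x1))
  expect_true(any(!is.finite(v2$vif)))
  # column order does not change values
  tab4 <- tibble::tibble(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  v_abc <- vif(tab4)
  v_cba <- vif(tab4[, c("c", "b", "a")])
  expect_equal(v_abc$vif[v_abc$variable == "b"],
               v_cba$vif[v_cba$variable == "b"])
})
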