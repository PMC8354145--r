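# Independent oracles used to freeze expected values.

# Penalized maxent objective, written independently of the package solver.
or_objective <- function(lambda, Fp, Fb, beta) {
  eta <- as.vector(Fb %*% lambda)
  mx <- max(eta)
  log_z <- mx + log(sum(exp(eta - mx)))
  -sum(colMeans(Fp) * lambda) + log_z + sum(beta * abs(lambda))
}

# Golden-section minimizer of a unimodal 1-D function on [lo, hi].
golden_min <- function(f, lo, hi, tol = 1e-10) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c <- b - phi * (b - a); d <- a + phi * (b - a)
  fc <- f(c); fd <- f(d)
  while (abs(b - a) > tol) {
    if (fc < fd) {
      b <- d; d <- c; fd <- fc
      c <- b - phi * (b - a); fc <- f(c)
    } else {
      a <- c; c <- d; fc <- fd
      d <- a + phi * (b - a); fd <- f(d)
    }
  }
  (a + b) / 2
}

# Coordinate-wise golden-section minimization of the penalized objective;
# convex => coordinate minimization converges to the optimum.
oracle_cd <- function(Fp, Fb, beta, span = 25, sweeps = 300) {
  J <- ncol(Fb)
  lambda <- numeric(J)
  for (s in seq_len(sweeps)) {
    old <- lambda
    for (j in seq_len(J)) {
      f1 <- function(v) {
        l <- lambda; l[j] <- v
        or_objective(l, Fp, Fb, beta)
      }
      lambda[j] <- golden_min(f1, lambda[j] - span, lambda[j] + span)
      # snap to the kink if it is at least as good (golden section cannot
      # land exactly on the nondifferentiable point)
      l0 <- lambda; l0[j] <- 0
      if (or_objective(l0, Fp, Fb, beta) <= f1(lambda[j])) lambda[j] <- 0
    }
    if (max(abs(lambda - old)) < 1e-9) break
  }
  lambda
}

# Random tiny presence/background instance on raw covariate tables.
tiny_instance <- function(seed) {
  withr::with_seed(seed, {
    n_bg <- sample(20:100, 1)
    j <- sample(1:3, 1)
    m <- sample(5:25, 1)
    bg <- tibble::as_tibble(stats::setNames(
      lapply(seq_len(j), function(i) stats::runif(n_bg, 0, 10)),
      paste0("v", seq_len(j))))
    # presences oversample high-v1 cells so the signal is real but not separable
    w <- exp(0.4 * scale(bg$v1)[, 1])
    pres <- bg[sample(n_bg, m, replace = TRUE, prob = w), , drop = FALSE]
    list(pres = pres, bg = bg, rm = stats::runif(1, 0.5, 2))
  })
}

# Shared mid-size synthetic bundle for selection/evaluation tests (built once).
.fixture_cache <- new.env(parent = emptyenv())
fixture_bundle <- function() {
  if (!is.null(.fixture_cache$bundle)) return(.fixture_cache$bundle)
  vars <- tibble::tibble(name = c("info", "noise"),
                         range = c(500, 400), min = c(0, 0), max = c(100, 100))
  st <- simulate_landscape(c(100, 100), 30, vars, seed = 31)
  coefs <- c(info = 3)
  occ <- simulate_occurrences(st, coefs, n_presence = 300, seed = 32,
                              clustering = function(n) rep(1L, n))
  pres <- attr(occ, "presence_cells")
  bg <- sample_background(st, NULL, 3000, seed = 33)
  .fixture_cache$bundle <- list(
    stack = st, coefs = coefs,
    pres_tab = extract_values(st, pres)[, vars$name],
    bg_tab = extract_values(st, bg)[, vars$name],
    truth = truth_suitability(st, coefs)
  )
  .fixture_cache$bundle
}

# Regularization-multiplier sweep over the fixture, fitted once.
fixture_sweep <- function() {
  if (is.null(.fixture_cache$sweep)) {
    b <- fixture_bundle()
    .fixture_cache$sweep <- rm_sweep(b$pres_tab, b$bg_tab)
  }
  .fixture_cache$sweep
}
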