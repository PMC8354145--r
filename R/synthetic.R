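## Synthetic landscapes and occurrences with known truth.
##
## Landscapes are Gaussian random fields with exponential covariance
## (circulant embedding on a doubled torus, so the cost is one FFT),
## optionally cross-correlated between variables and rank-mapped to each
## variable's marginal bounds. Occurrences are drawn from the same Gibbs
## (log-linear) form the model fits, then duplicated and jittered to emulate
## the sampling redundancy of real survey databases (GPS bursts, repeat
## visits), giving the thinning stage real work to do.

#' Default synthetic covariates
#'
#' A six-variable set shaped like coastal forest-structure and climate
#' layers: percentage-scaled vegetation covariates with sub-kilometer
#' autocorrelation ranges, plus smoother climate-like surfaces.
#'
#' @return tibble with `name`, `range` (exponential-covariance range
#'   parameter, m), `min`, `max`.
#' @export
default_variables <- function() {
  tibble::tibble(
    name = c("canopy_cover", "salal", "ogsi", "pine", "precipitation",
             "temperature"),
    range = c(400, 800, 250, 600, 2000, 2000),
    min = c(2, 0, 0, 0, 13, 8),
    max = c(99, 100, 100, 94, 198, 24)
  )
}

# One standardized exponential-covariance Gaussian random field via
# circulant embedding; consumes RNG state (caller controls the seed).
grf_exp <- function(nr, nc, cell_size, range) {
  M <- 2L * nr; N <- 2L * nc
  dr <- pmin(0:(M - 1), M - (0:(M - 1))) * cell_size
  dc <- pmin(0:(N - 1), N - (0:(N - 1))) * cell_size
  D <- sqrt(outer(dr^2, dc^2, "+"))
  lam <- Re(stats::fft(exp(-D / range)))
  lam[lam < 0] <- 0                      # embedding may be slightly indefinite
  z <- matrix(stats::rnorm(M * N), M, N) + 1i * matrix(stats::rnorm(M * N), M, N)
  f <- Re(stats::fft(sqrt(lam) * z) / sqrt(M * N))[seq_len(nr), seq_len(nc)]
  # standardize: eigenvalue clamping inflates the variance slightly, and the
  # cross-correlation mixing downstream assumes unit-variance inputs
  (f - mean(f)) / stats::sd(f)
}

#' Simulate a stack of spatially autocorrelated covariates
#'
#' Each variable is a Gaussian random field with exponential covariance at
#' its own range parameter; fields are mixed through the Cholesky factor of
#' `cross_correlation` so same-cell correlations match the requested matrix,
#' then rank-mapped to the variable's marginal bounds (so mins and maxes are
#' honored exactly and marginals are uniform on them). Optional
#' `gradient_variables` are monotone in x — stand-ins for coast-distance or
#' advection-driven climate gradients. An optional contiguous nodata blob
#' emulates masked urban/water cells.
#'
#' @param n_cells `(rows, cols)` of the grid.
#' @param cell_size cell edge in meters (default 30, the resolution of the
#'   vegetation products this mimics).
#' @param variables tibble with `name`, `range`, `min`, `max`; default
#'   [default_variables()].
#' @param cross_correlation square correlation matrix across `variables`
#'   (positive semi-definite); default identity.
#' @param gradient_variables optional tibble `name`, `min`, `max` of
#'   variables linear in x.
#' @param mask_fraction fraction of cells masked as nodata, carved as the
#'   low end of an auxiliary smooth field so the mask is contiguous blobs
#'   (default 0).
#' @param seed integer seed; output is bit-reproducible.
#' @param origin grid origin, default (0, 0).
#' @return A `covariate_stack`.
#' @export
simulate_landscape <- function(n_cells, cell_size = 30,
                               variables = default_variables(),
                               cross_correlation = NULL,
                               gradient_variables = NULL,
                               mask_fraction = 0, seed = 1L,
                               origin = c(0, 0)) {
  nr <- n_cells[1]; nc <- n_cells[2]
  k <- nrow(variables)
  if (is.null(cross_correlation)) cross_correlation <- diag(k)
  ev <- eigen(cross_correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("cross_correlation is not positive semi-definite", call. = FALSE)
  }
  L <- t(chol(cross_correlation + diag(1e-10, k)))

  withr::with_seed(as.integer(seed), {
    fields <- lapply(seq_len(k), function(i) {
      grf_exp(nr, nc, cell_size, variables$range[i])
    })
    mask <- NULL
    if (mask_fraction > 0) {
      aux <- grf_exp(nr, nc, cell_size, 10 * cell_size)
      mask <- aux <= stats::quantile(aux, mask_fraction)
    }
    layers <- lapply(seq_len(k), function(i) {
      mixed <- Reduce(`+`, Map(`*`, L[i, seq_len(k)], fields))
      u <- rank(mixed, ties.method = "average") / (nr * nc + 1)
      vals <- matrix(variables$min[i] + u * (variables$max[i] - variables$min[i]),
                     nr, nc)
      if (!is.null(mask)) vals[mask] <- NA_real_
      grid_layer(vals, cell_size = cell_size, origin = origin,
                 name = variables$name[i])
    })
    if (!is.null(gradient_variables)) {
      gx <- matrix(rep(seq_len(nc), each = nr), nr, nc)
      u <- (gx - 1) / (nc - 1)
      for (i in seq_len(nrow(gradient_variables))) {
        vals <- gradient_variables$min[i] +
          u * (gradient_variables$max[i] - gradient_variables$min[i])
        if (!is.null(mask)) vals[mask] <- NA_real_
        layers[[length(layers) + 1L]] <-
          grid_layer(vals, cell_size = cell_size, origin = origin,
                     name = gradient_variables$name[i])
      }
    }
    covariate_stack(layers)
  })
}

# Scaled ([0,1] by unmasked min/max) covariates and the Gibbs linear
# predictor over all cells (NA where masked).
truth_eta <- function(stack, coefficients) {
  bad <- setdiff(names(coefficients), stack_names(stack))
  if (length(bad)) {
    stop("coefficients reference unknown variables: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  eta <- 0
  for (v in names(coefficients)) {
    vals <- stack$layers[[v]]$values
    r <- range(vals, na.rm = TRUE)
    eta <- eta + coefficients[[v]] * (vals - r[1]) / (r[2] - r[1])
  }
  eta
}

#' Simulate occurrence records from a known log-linear suitability
#'
#' Presence cells are drawn without replacement with probability
#' proportional to `exp(sum_v beta_v * v_scaled)` — the same Gibbs form the
#' model fits, so fitted coefficients and surfaces can be checked against
#' truth. Each presence cell is then reported `clustering(n)` times with a
#' small coordinate jitter and a detection type drawn from `detection_mix`,
#' emulating the redundancy (GPS bursts, repeat surveys) that spatial
#' thinning exists to remove.
#'
#' @param stack a `covariate_stack`.
#' @param coefficients named numeric vector of generating coefficients on the
#'   \[0, 1\]-scaled variables.
#' @param n_presence number of distinct presence cells.
#' @param detection_mix named probabilities over source types; the default
#'   mirrors a telemetry-dominated survey database.
#' @param clustering `function(n)` returning per-presence duplication counts
#'   (>= 1); the default is heavy-tailed with mean ~26 so a few hundred
#'   presence cells yield ~10,000 records.
#' @param jitter maximum absolute coordinate jitter in meters (uniform;
#'   default 200, under half a conventional 500-m thinning cell).
#' @param years detection years to sample from.
#' @param seed integer seed.
#' @return `occurrence_records` with attribute `presence_cells` (tibble of
#'   the true presence cell centers).
#' @export
simulate_occurrences <- function(stack, coefficients, n_presence,
                                 detection_mix = c(den_rest = 0.05,
                                                   scat_dog = 0.026,
                                                   station = 0.053,
                                                   telemetry = 0.863,
                                                   roadkill = 0.002,
                                                   other = 0.006),
                                 clustering = function(n)
                                   1L + stats::rnbinom(n, size = 0.25, mu = 25),
                                 jitter = 200, years = 1996:2020, seed = 1L) {
  eta <- as.vector(truth_eta(stack, coefficients))
  eligible <- which(!as.vector(stack_mask(stack)))
  if (n_presence > length(eligible)) {
    stop(sprintf("n_presence (%d) exceeds eligible cells (%d)",
                 n_presence, length(eligible)), call. = FALSE)
  }
  cc <- cell_centers(stack)
  withr::with_seed(as.integer(seed), {
    w <- exp(eta[eligible] - max(eta[eligible], na.rm = TRUE))
    cells <- sample(eligible, n_presence, prob = w)
    dup <- clustering(n_presence)
    dup <- pmax(as.integer(dup), 1L)
    idx <- rep(cells, dup)
    n_rec <- length(idx)
    recs <- occurrence_records(
      x = cc$x[idx] + stats::runif(n_rec, -jitter, jitter),
      y = cc$y[idx] + stats::runif(n_rec, -jitter, jitter),
      year = sample(years, n_rec, replace = TRUE),
      source_type = sample(names(detection_mix), n_rec, replace = TRUE,
                           prob = detection_mix)
    )
    attr(recs, "presence_cells") <- tibble::tibble(x = cc$x[cells],
                                                   y = cc$y[cells])
    recs
  })
}

#' True logistic suitability surface of a synthetic landscape
#'
#' Computes the generating Gibbs density over all unmasked cells, its entropy
#' H, and the logistic transform `e^H q / (1 + e^H q)` — the surface a
#' perfectly recovered model would predict, used as the reference in
#' parameter-recovery tests. Zero coefficients give a constant 0.5 surface.
#'
#' @inheritParams simulate_occurrences
#' @return A `grid_layer` named `"truth"` with values in (0, 1).
#' @export
truth_suitability <- function(stack, coefficients) {
  eta <- truth_eta(stack, coefficients)
  ok <- !is.na(eta)
  lz <- log_sum_exp(eta[ok])
  q <- exp(eta - lz)
  h <- -sum(q[ok] * log(q[ok]))
  p <- exp(h) * q / (1 + exp(h) * q)
  grid_layer(p, cell_size = stack$layers[[1]]$cell_size,
             origin = stack$layers[[1]]$origin, name = "truth")
}
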