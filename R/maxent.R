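## Maximum-entropy (Gibbs density) presence-only model.
##
## The model estimates a density q_lambda(x) = exp(lambda . f(x)) / Z over a
## background sample, chosen to minimize the L1-penalized negative
## log-likelihood of the presences:
##
##   NLL(lambda) = -(1/m) sum_presences log q(x) + sum_j beta_j |lambda_j|
##
## which is convex. Fitting is cyclic coordinate descent with per-coordinate
## Newton steps, soft-thresholding for the L1 part, and backtracking so the
## regularized training gain is non-decreasing along the update trace.

# Published default regularization schedule rho(class, m), interpolated
# piecewise-linearly in the presence count m and held constant beyond the
# endpoints.
.rho_schedule <- list(
  linear    = list(m = c(10, 30, 100), rho = c(1.0, 0.2, 0.05)),
  quadratic = list(m = c(0, 10, 17),   rho = c(1.3, 0.8, 0.05)),
  product   = list(m = c(0, 10, 30, 80), rho = c(2.6, 1.6, 1.0, 0.05))
)

#' Per-class regularization weight at a given presence count
#' @param class feature class: `"linear"`, `"quadratic"` or `"product"`.
#' @param m presence count.
#' @return interpolated default regularization weight.
#' @export
reg_rho <- function(class, m) {
  s <- .rho_schedule[[class]]
  if (is.null(s)) stop("unknown feature class: ", class, call. = FALSE)
  stats::approx(s$m, s$rho, xout = m, rule = 2)$y
}

# Feature classes admitted by "auto features" at presence count m: a class is
# used only when the sample is large enough to estimate it stably.
auto_classes <- function(m) {
  cl <- "linear"
  if (m >= 10) cl <- c(cl, "quadratic")
  if (m >= 80) cl <- c(cl, "product")
  cl
}

#' Expand raw covariates into model features
#'
#' Scales each variable to \[0, 1\] by its background minimum and maximum and
#' expands the requested feature classes: `linear` (the scaled value),
#' `quadratic` (its square) and `product` (all unordered pairs). When
#' predicting outside the training bounds, scaled values are clamped to
#' \[0, 1\] so responses are never extrapolated. Variables that are constant
#' over the background are excluded with a warning.
#'
#' @param table data frame of raw covariate values; the coordinate columns
#'   `x`, `y`, `valid`, `label` are ignored if present.
#' @param classes subset of `c("linear", "quadratic", "product")`.
#' @param bounds optional tibble (`variable`, `min`, `max`) computed on the
#'   background table; if `NULL`, computed from `table`.
#' @return list with `features` (numeric matrix), `specs` (tibble: `feature`,
#'   `class`, `var1`, `var2`), `bounds`.
#' @export
build_features <- function(table, classes = c("linear", "quadratic", "product"),
                           bounds = NULL) {
  classes <- match.arg(classes, c("linear", "quadratic", "product"),
                       several.ok = TRUE)
  tab <- dplyr::select(tibble::as_tibble(table), dplyr::where(is.numeric))
  tab <- tab[, setdiff(names(tab), c("x", "y", "valid")), drop = FALSE]
  if (ncol(tab) == 0L) stop("no covariate columns found", call. = FALSE)
  if (is.null(bounds)) {
    bounds <- tibble::tibble(
      variable = names(tab),
      min = vapply(tab, min, numeric(1)),
      max = vapply(tab, max, numeric(1))
    )
  }
  bad <- bounds$variable[bounds$max <= bounds$min]
  if (length(bad)) {
    warning("constant variable(s) excluded: ", paste(bad, collapse = ", "),
            call. = FALSE)
    bounds <- bounds[!bounds$variable %in% bad, , drop = FALSE]
  }
  vars <- intersect(bounds$variable, names(tab))
  if (length(vars) == 0L) stop("no usable (non-constant) variables", call. = FALSE)

  scaled <- vapply(vars, function(v) {
    b <- bounds[bounds$variable == v, ]
    pmin(pmax((tab[[v]] - b$min) / (b$max - b$min), 0), 1)
  }, numeric(nrow(tab)))
  scaled <- matrix(scaled, nrow = nrow(tab),
                   dimnames = list(NULL, vars))

  specs <- tibble::tibble(feature = character(), class = character(),
                          var1 = character(), var2 = character())
  cols <- list()
  if ("linear" %in% classes) {
    for (v in vars) {
      specs <- dplyr::bind_rows(specs, tibble::tibble(
        feature = v, class = "linear", var1 = v, var2 = NA_character_))
      cols[[length(cols) + 1L]] <- scaled[, v]
    }
  }
  if ("quadratic" %in% classes) {
    for (v in vars) {
      specs <- dplyr::bind_rows(specs, tibble::tibble(
        feature = paste0(v, "^2"), class = "quadratic", var1 = v,
        var2 = NA_character_))
      cols[[length(cols) + 1L]] <- scaled[, v]^2
    }
  }
  if ("product" %in% classes && length(vars) >= 2L) {
    pairs <- utils::combn(vars, 2)
    for (k in seq_len(ncol(pairs))) {
      v1 <- pairs[1, k]; v2 <- pairs[2, k]
      specs <- dplyr::bind_rows(specs, tibble::tibble(
        feature = paste0(v1, "*", v2), class = "product", var1 = v1,
        var2 = v2))
      cols[[length(cols) + 1L]] <- scaled[, v1] * scaled[, v2]
    }
  }
  features <- do.call(cbind, cols)
  colnames(features) <- specs$feature
  list(features = features, specs = specs, bounds = bounds)
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Fit an L1-regularized maximum-entropy model
#'
#' Estimates the Gibbs density over the background sample whose feature
#' expectations match the presence sample, subject to per-feature L1
#' penalties `beta_j = rm * rho(class_j, m) * sd_j / sqrt(m)` where `sd_j` is
#' the presence-sample standard deviation of feature j (floored at
#' `sd_floor` so degenerate features keep a positive penalty) and `rho` the
#' default per-class schedule (see [reg_rho()]). The solver is cyclic
#' coordinate descent with Newton steps, soft-thresholding and backtracking;
#' the objective is convex so the algorithm is a means to the optimum, not
#' part of the contract.
#'
#' @param presence,background data frames of raw covariate values at presence
#'   and background locations (coordinate columns are ignored).
#' @param classes feature classes, or `"auto"` to let the presence count
#'   decide (linear always; quadratic from 10 presences; product from 80).
#' @param rm regularization multiplier (>= 0); larger values give sparser
#'   models.
#' @param max_iter maximum number of full coordinate sweeps (default 500).
#' @param tol relative objective-change convergence tolerance per sweep.
#' @param sd_floor lower bound applied to the presence-sample feature sd in
#'   the penalty (numerical guard; features live in \[0, 1\]).
#' @param keep_data if `TRUE` (default) the raw training tables are stored on
#'   the model for downstream evaluation (jackknife, permutation importance,
#'   response curves).
#' @return A `maxent_model`: feature `specs` (with penalties), `lambda`,
#'   `log_z` and `entropy` over the training background, the gain `trace`,
#'   convergence information, and the scaling `bounds`.
#' @export
fit_maxent <- function(presence, background, classes = "auto", rm = 1,
                       max_iter = 500, tol = 1e-5, sd_floor = 0.05,
                       keep_data = TRUE) {
  m <- nrow(tibble::as_tibble(presence))
  if (m < 2L) stop("need at least 2 presences", call. = FALSE)
  if (rm < 0) stop("`rm` must be >= 0", call. = FALSE)
  if (identical(classes, "auto")) classes <- auto_classes(m)

  bg <- build_features(background, classes = classes)
  pr <- build_features(presence, classes = classes, bounds = bg$bounds)
  Fb <- bg$features
  Fp <- pr$features
  n <- nrow(Fb)
  if (n < 10 * m) {
    warning(sprintf(
      "background (%d) is smaller than 10x presences (%d); estimates may be unstable",
      n, m), call. = FALSE)
  }

  sd_j <- pmax(apply(Fp, 2, stats::sd), sd_floor)
  rho_j <- vapply(bg$specs$class, reg_rho, numeric(1), m = m)
  beta <- rm * rho_j * sd_j / sqrt(m)

  fit <- maxent_cd(Fp, Fb, beta, max_iter = max_iter, tol = tol)

  specs <- dplyr::mutate(bg$specs,
                         beta = unname(beta),
                         lambda = unname(fit$lambda),
                         f_min = apply(Fb, 2, min),
                         f_max = apply(Fb, 2, max))
  structure(
    list(specs = specs, lambda = fit$lambda, beta = beta,
         log_z = fit$log_z, entropy = fit$entropy, rm = rm, m = m,
         n_background = n, bounds = bg$bounds, classes = classes,
         converged = fit$converged, iterations = fit$iterations,
         objective = fit$objective, trace = fit$trace,
         presence_means = colMeans(Fp),
         train = if (keep_data) list(
           presence = tibble::as_tibble(presence),
           background = tibble::as_tibble(background)) else NULL),
    class = "maxent_model"
  )
}

# Core coordinate-descent solver on prebuilt feature matrices.
maxent_cd <- function(Fp, Fb, beta, max_iter = 500, tol = 1e-5) {
  J <- ncol(Fb); n <- nrow(Fb)
  pbar <- colMeans(Fp)
  lambda <- numeric(J)
  eta <- numeric(n)
  log_z <- log(n)
  obj <- log_z                                     # -lambda.pbar + logZ + penalty
  gain0 <- log(n)
  trace_feat <- integer(0); trace_gain <- numeric(0)

  objective_at <- function(eta, lambda) {
    log_sum_exp(eta) - sum(lambda * pbar) + sum(beta * abs(lambda))
  }

  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iterations <- it
    obj_sweep_start <- obj
    for (j in seq_len(J)) {
      q <- exp(eta - log_sum_exp(eta))
      fj <- Fb[, j]
      ef <- sum(q * fj)
      ef2 <- sum(q * fj^2)
      g <- ef - pbar[j]
      h <- max(ef2 - ef^2, 1e-12)
      u <- h * lambda[j] - g
      lam_new <- sign(u) * max(abs(u) - beta[j], 0) / h
      d <- lam_new - lambda[j]
      if (abs(d) < 1e-14) next
      d <- max(min(d, 10), -10)                    # trust region; features in [0,1]
      accepted <- FALSE
      for (bt in 1:40) {
        eta_new <- eta + d * fj
        lam_try <- lambda
        lam_try[j] <- lambda[j] + d
        obj_new <- objective_at(eta_new, lam_try)
        if (obj_new <= obj + 1e-13) { accepted <- TRUE; break }
        d <- d / 2
      }
      if (accepted && obj_new < obj - 1e-15) {
        lambda[j] <- lambda[j] + d
        eta <- eta_new
        obj <- obj_new
        trace_feat <- c(trace_feat, j)
        trace_gain <- c(trace_gain, gain0 - obj)
      }
    }
    if (abs(obj_sweep_start - obj) < tol * (abs(obj_sweep_start) + 1e-10)) {
      converged <- TRUE
      break
    }
  }

  log_z <- log_sum_exp(eta)
  q <- exp(eta - log_z)
  list(lambda = lambda, log_z = log_z,
       entropy = -sum(q * log(q)),
       objective = obj, converged = converged, iterations = iterations,
       trace = tibble::tibble(feature = trace_feat, gain = trace_gain))
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> RM %.2g, %d presences vs %d background\n",
              x$rm, x$m, x$n_background))
  cat(sprintf("  %d/%d nonzero features, gain %.4f, entropy %.4f, %s in %d sweeps\n",
              sum(x$lambda != 0), length(x$lambda), training_gain(x),
              x$entropy, if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

# Rebuild the feature matrix for new raw data using a fitted model's specs
# and training bounds (with clamping).
features_for <- function(model, newdata) {
  build_features(newdata, classes = model$classes,
                 bounds = model$bounds)$features[, model$specs$feature,
                                                 drop = FALSE]
}

#' Predict from a fitted maximum-entropy model
#'
#' `type = "raw"` returns the Gibbs density `q(x) = exp(lambda . f(x) -
#' log Z)`, normalized so the values over the training background sum to 1.
#' `type = "logistic"` returns `e^H q / (1 + e^H q)` with `H` the model
#' entropy — the conventional suitability index in (0, 1) with indifference
#' value 0.5 under the default prevalence assumption.
#'
#' @param object a `maxent_model`.
#' @param newdata data frame of raw covariates (or a `covariate_stack`; then
#'   a `grid_layer` is returned).
#' @param type `"logistic"` (default) or `"raw"`.
#' @param ... unused.
#' @return numeric vector, or a `grid_layer` when `newdata` is a stack.
#' @export
predict.maxent_model <- function(object, newdata,
                                 type = c("logistic", "raw"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "covariate_stack")) {
    return(predict_layer(object, newdata, type = type))
  }
  f <- features_for(object, newdata)
  q <- exp(as.vector(f %*% object$lambda) - object$log_z)
  if (type == "raw") return(q)
  eh <- exp(object$entropy)
  eh * q / (1 + eh * q)
}

#' @rdname predict.maxent_model
#' @param model a `maxent_model`.
#' @export
predict_raw <- function(model, newdata) predict(model, newdata, type = "raw")

#' @rdname predict.maxent_model
#' @export
predict_logistic <- function(model, newdata) {
  predict(model, newdata, type = "logistic")
}

# Predict over every unmasked cell of a stack.
predict_layer <- function(model, stack, type = "logistic") {
  cc <- cell_centers(stack)
  mask <- as.vector(stack_mask(stack))
  tab <- tibble::as_tibble(
    lapply(stack$layers, function(l) as.vector(l$values)))[!mask, , drop = FALSE]
  p <- predict(model, tab, type = type)
  d <- grid_dim(stack)
  vals <- rep(NA_real_, nrow(cc))
  vals[!mask] <- p
  grid_layer(matrix(vals, d[1], d[2]),
             cell_size = stack$layers[[1]]$cell_size,
             origin = stack$layers[[1]]$origin,
             name = paste0("predicted_", type))
}

#' Regularized training gain of a fitted model
#'
#' `gain = ln(n_background) + mean presence log-density - penalty`; zero for
#' the uniform model, non-negative at the fitted optimum.
#'
#' @param model a `maxent_model`.
#' @return scalar gain.
#' @export
training_gain <- function(model) {
  log(model$n_background) - model$objective
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a maximum-entropy model's coefficients
#' @param x a `maxent_model`.
#' @param ... unused.
#' @return tibble with one row per feature: `feature`, `class`, `var1`,
#'   `var2`, `lambda`, `beta`.
#' @export
tidy.maxent_model <- function(x, ...) {
  dplyr::select(x$specs, "feature", "class", "var1", "var2", "lambda", "beta")
}

#' One-row summary of a maximum-entropy model
#' @param x a `maxent_model`.
#' @param ... unused.
#' @return tibble: presence/background counts, `rm`, nonzero-feature count
#'   `k`, `log_z`, `entropy`, `gain`, `converged`, `iterations`.
#' @export
glance.maxent_model <- function(x, ...) {
  tibble::tibble(
    m = x$m, n_background = x$n_background, rm = x$rm,
    k = sum(x$lambda != 0), log_z = x$log_z, entropy = x$entropy,
    gain = training_gain(x), converged = x$converged,
    iterations = x$iterations
  )
}

#' Serialize a model to JSON
#' @param model a `maxent_model`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_maxent_json <- function(model, path) {
  jsonlite::write_json(list(
    specs = model$specs, bounds = model$bounds, rm = model$rm, m = model$m,
    n_background = model$n_background, log_z = model$log_z,
    entropy = model$entropy, converged = model$converged,
    iterations = model$iterations, classes = model$classes
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a Maxent-style .lambdas text file
#'
#' One line per feature (`name, lambda, min, max` of the feature over the
#' training background) followed by the `linearPredictorNormalizer`,
#' `densityNormalizer`, `numBackgroundPoints` and `entropy` lines that
#' downstream tooling expects.
#'
#' @param model a `maxent_model`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_lambdas <- function(model, path) {
  s <- model$specs
  lpn <- model$log_z - log(model$n_background)   # shift so uniform -> 0
  lines <- c(
    sprintf("%s, %.10g, %.10g, %.10g", s$feature, s$lambda, s$f_min, s$f_max),
    sprintf("linearPredictorNormalizer, %.10g", lpn),
    sprintf("densityNormalizer, %.10g", exp(model$log_z - lpn)),
    sprintf("numBackgroundPoints, %d", model$n_background),
    sprintf("entropy, %.10g", model$entropy)
  )
  writeLines(lines, path)
  invisible(path)
}
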