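#' Fit a sweep of candidate models over a regularization-multiplier grid
#'
#' Fits one maximum-entropy model per regularization multiplier on the *full*
#' presence set (model selection uses all presences; replicate splits are for
#' evaluation). The default grid is 0.5 to 4 in 0.5 steps.
#'
#' @param presence,background raw covariate tables (see [fit_maxent()]).
#' @param rms regularization multipliers.
#' @param classes feature classes or `"auto"`.
#' @param ... passed to [fit_maxent()].
#' @return tibble with one row per candidate: `rm`, `k`, `gain`, `converged`
#'   and a `model` list-column.
#' @export
rm_sweep <- function(presence, background, rms = seq(0.5, 4, by = 0.5),
                     classes = "auto", ...) {
  purrr::map_dfr(rms, function(r) {
    fit <- fit_maxent(presence, background, classes = classes, rm = r, ...)
    if (!fit$converged) {
      warning(sprintf("candidate RM = %g did not converge; still ranked", r),
              call. = FALSE)
    }
    tibble::tibble(rm = r, k = sum(fit$lambda != 0), gain = training_gain(fit),
                   converged = fit$converged, model = list(fit))
  })
}

#' Rank candidate models by small-sample-corrected AIC
#'
#' For each candidate, raw predictions are re-normalized to sum to 1 over the
#' normalization background (by default the candidate's own training
#' background), the presence log-likelihood is computed from those
#' densities, `k` counts nonzero coefficients, and
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)` with `n` the presence
#' count. Candidates with `k >= n - 1` are flagged invalid (the correction
#' denominator vanishes); `delta_aicc` is relative to the best valid
#' candidate. The model with the lowest AICc is the top model; candidates
#' within `delta_aicc < 2` are conventionally competitive.
#'
#' @param candidates a sweep tibble from [rm_sweep()] or a list of
#'   `maxent_model`s.
#' @param background optional data frame of raw covariates to use as the
#'   normalization background (e.g. all landscape cells) instead of each
#'   model's training background.
#' @return A `candidate_ranking` tibble sorted by AICc: `rm`, `k`, `log_lik`,
#'   `aicc`, `delta_aicc`, `invalid`, `model` (list-column).
#' @export
aicc_rank <- function(candidates, background = NULL) {
  models <- if (is.data.frame(candidates)) candidates$model else candidates
  rows <- purrr::map_dfr(models, function(mod) {
    n <- mod$m
    if (is.null(mod$train)) {
      stop("candidates must be fitted with keep_data = TRUE", call. = FALSE)
    }
    bg <- if (is.null(background)) mod$train$background else background
    fb <- features_for(mod, bg)
    fp <- features_for(mod, mod$train$presence)
    log_z <- log_sum_exp(as.vector(fb %*% mod$lambda))
    ll <- sum(as.vector(fp %*% mod$lambda)) - n * log_z
    k <- sum(mod$lambda != 0)
    invalid <- k >= n - 1
    aicc <- if (invalid) NA_real_ else -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
    tibble::tibble(rm = mod$rm, k = k, log_lik = ll, aicc = aicc,
                   invalid = invalid, model = list(mod))
  })
  if (all(rows$invalid)) {
    stop("all candidates have k >= n - 1; increase presences or RM",
         call. = FALSE)
  }
  rows$delta_aicc <- rows$aicc - min(rows$aicc, na.rm = TRUE)
  rows <- dplyr::arrange(rows, dplyr::desc(!.data$invalid), .data$aicc)
  out <- dplyr::select(rows, "rm", "k", "log_lik", "aicc", "delta_aicc",
                       "invalid", "model")
  class(out) <- c("candidate_ranking", class(out))
  out
}

#' Per-variable percent contribution from the fitting trace
#'
#' Each positive increment of the regularized training gain recorded during
#' coordinate descent is credited to the parent variable(s) of the updated
#' feature (product features split 50/50 between their two parents);
#' accumulated credits are normalized to sum to 100. Contribution is
#' path-dependent by construction and is most informative when variables are
#' not strongly correlated.
#'
#' @param model a `maxent_model`.
#' @return tibble with `variable`, `contribution` (percent).
#' @export
percent_contribution <- function(model) {
  vars <- model$bounds$variable
  credit <- stats::setNames(numeric(length(vars)), vars)
  tr <- model$trace
  if (nrow(tr) == 0L || sum(model$lambda != 0) == 0L) {
    warning("empty gain trace (k = 0); contributions are all zero",
            call. = FALSE)
    return(tibble::tibble(variable = vars, contribution = 0))
  }
  inc <- pmax(diff(c(0, tr$gain)), 0)
  for (i in seq_len(nrow(tr))) {
    s <- model$specs[tr$feature[i], ]
    if (!is.na(s$var2)) {
      credit[s$var1] <- credit[s$var1] + inc[i] / 2
      credit[s$var2] <- credit[s$var2] + inc[i] / 2
    } else {
      credit[s$var1] <- credit[s$var1] + inc[i]
    }
  }
  tot <- sum(credit)
  tibble::tibble(variable = vars,
                 contribution = if (tot > 0) 100 * unname(credit) / tot
                                else unname(credit) * 0)
}

#' Permutation importance of each variable
#'
#' For each variable, its raw values are permuted jointly across the training
#' presences and background, features are rebuilt with the model's scaling
#' and clamping, and the drop in training AUC is recorded; drops are floored
#' at zero and normalized to sum to 100. The single-permutation default
#' mirrors common practice; `n_perm > 1` averages repeats for stability.
#'
#' @param model a `maxent_model` fitted with `keep_data = TRUE`.
#' @param seed integer seed for the permutations.
#' @param n_perm permutations per variable (default 1).
#' @param perm_fun permutation generator `function(n)` returning an index
#'   vector; the default draws a uniform random permutation. Exposed for
#'   diagnostics (e.g. the identity permutation must yield zero drop).
#' @return tibble with `variable`, `importance` (percent), `auc_drop`.
#' @export
permutation_importance <- function(model, seed = 1L, n_perm = 1,
                                   perm_fun = NULL) {
  if (is.null(model$train)) {
    stop("model must be fitted with keep_data = TRUE", call. = FALSE)
  }
  pres <- model$train$presence
  bg <- model$train$background
  np <- nrow(pres)
  combined <- dplyr::bind_rows(pres[, model$bounds$variable],
                               bg[, model$bounds$variable])
  scores <- predict(model, combined, type = "raw")
  auc0 <- auc(scores[seq_len(np)], scores[-seq_len(np)])
  vars <- model$bounds$variable
  if (auc0 <= 0.5) {
    warning("training AUC <= 0.5; permutation importances set to 0",
            call. = FALSE)
    return(tibble::tibble(variable = vars, importance = 0, auc_drop = 0))
  }
  drops <- withr::with_seed(as.integer(seed), {
    vapply(vars, function(v) {
      mean(vapply(seq_len(n_perm), function(rep) {
        perm <- if (is.null(perm_fun)) sample.int(nrow(combined))
                else perm_fun(nrow(combined))
        tab <- combined
        tab[[v]] <- tab[[v]][perm]
        s <- predict(model, tab, type = "raw")
        max(0, auc0 - auc(s[seq_len(np)], s[-seq_len(np)]))
      }, numeric(1)))
    }, numeric(1))
  })
  tot <- sum(drops)
  tibble::tibble(variable = vars,
                 importance = if (tot > 0) 100 * unname(drops) / tot else drops * 0,
                 auc_drop = unname(drops))
}

#' Jackknife of per-variable training gain
#'
#' Refits the model twice per variable — once with only that variable's
#' features, once with every feature except that variable's — and reports
#' the regularized training gain of each alongside the full model's gain.
#'
#' @param model a `maxent_model` fitted with `keep_data = TRUE`.
#' @param variables variables to jackknife; default all.
#' @return tibble: `variable`, `gain_with_only`, `gain_without`, `gain_full`.
#' @export
jackknife_gain <- function(model, variables = NULL) {
  if (is.null(model$train)) {
    stop("model must be fitted with keep_data = TRUE", call. = FALSE)
  }
  vars <- model$bounds$variable
  if (length(vars) < 2L) stop("need at least 2 variables", call. = FALSE)
  if (is.null(variables)) variables <- vars
  pres <- model$train$presence
  bg <- model$train$background
  refit <- function(vs) {
    fit_maxent(pres[, vs, drop = FALSE], bg[, vs, drop = FALSE],
               classes = model$classes, rm = model$rm, keep_data = FALSE)
  }
  full_gain <- training_gain(model)
  purrr::map_dfr(variables, function(v) {
    tibble::tibble(
      variable = v,
      gain_with_only = training_gain(refit(v)),
      gain_without = training_gain(refit(setdiff(vars, v))),
      gain_full = full_gain
    )
  })
}

#' Response curve of one variable
#'
#' `mode = "marginal"`: the variable sweeps its background range on a grid
#' while every other variable is held at its background mean, and the fitted
#' model's logistic output is evaluated. `mode = "univariate"`: the model is
#' refit using only that variable's features and the refit is evaluated
#' across the range — the curve free of the influence of correlated
#' variables.
#'
#' @param model a `maxent_model` fitted with `keep_data = TRUE`.
#' @param variable variable name.
#' @param mode `"marginal"` or `"univariate"`.
#' @param n_grid number of grid values (default 101).
#' @return tibble: `variable`, `value` (raw scale), `p` (logistic output),
#'   `mode`.
#' @export
response_curve <- function(model, variable, mode = c("marginal", "univariate"),
                           n_grid = 101) {
  mode <- match.arg(mode)
  if (!variable %in% model$bounds$variable) {
    stop("variable not in model: ", variable, call. = FALSE)
  }
  b <- model$bounds[model$bounds$variable == variable, ]
  grid <- seq(b$min, b$max, length.out = n_grid)
  if (mode == "marginal") {
    bg <- model$train$background
    base <- lapply(model$bounds$variable, function(v) mean(bg[[v]]))
    names(base) <- model$bounds$variable
    newdata <- tibble::as_tibble(base)[rep(1, n_grid), ]
    newdata[[variable]] <- grid
    p <- predict(model, newdata, type = "logistic")
  } else {
    sub <- fit_maxent(model$train$presence[, variable, drop = FALSE],
                      model$train$background[, variable, drop = FALSE],
                      classes = setdiff(model$classes, "product"),
                      rm = model$rm, keep_data = FALSE)
    p <- predict(sub, tibble::as_tibble(stats::setNames(list(grid), variable)),
                 type = "logistic")
  }
  tibble::tibble(variable = variable, value = grid, p = p, mode = mode)
}

#' Response curves for several variables
#' @inheritParams response_curve
#' @param variables variables to plot; default all in the model.
#' @return tibble stacking [response_curve()] results.
#' @export
response_curves <- function(model, variables = NULL,
                            mode = c("marginal", "univariate"), n_grid = 101) {
  mode <- match.arg(mode)
  if (is.null(variables)) variables <- model$bounds$variable
  purrr::map_dfr(variables, response_curve, model = model, mode = mode,
                 n_grid = n_grid)
}
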