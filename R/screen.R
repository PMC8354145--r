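#' Univariate binomial GLM of presence vs background
#'
#' Fits a maximum-likelihood logistic regression of the presence indicator on
#' a single covariate, standardized internally (mean 0, sd 1) so coefficient
#' magnitudes are comparable across variables and scales. Both the
#' standardized and raw-scale slope are reported, with AIC = -2 logLik + 2k
#' (k = 2). Complete separation is flagged rather than raised.
#'
#' @param y binary 0/1 vector (1 = presence).
#' @param x covariate values.
#' @return one-row tibble: `intercept`, `coefficient` (standardized),
#'   `coefficient_raw`, `std_error`, `z`, `aic`, `separated`.
#' @export
fit_binomial_glm <- function(y, x) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("`y` must contain both classes", call. = FALSE)
  if (any(!is.finite(x))) stop("`x` must be finite", call. = FALSE)
  s <- stats::sd(x)
  z <- if (s > 0) (x - mean(x)) / s else x * 0
  fit <- suppressWarnings(stats::glm(y ~ z, family = stats::binomial()))
  co <- summary(fit)$coefficients
  sep <- !fit$converged || abs(co["z", "Estimate"]) > 25 ||
    co["z", "Std. Error"] > 1e3
  tibble::tibble(
    intercept = co["(Intercept)", "Estimate"],
    coefficient = co["z", "Estimate"],
    coefficient_raw = if (s > 0) co["z", "Estimate"] / s else 0,
    std_error = co["z", "Std. Error"],
    z = co["z", "z value"],
    aic = stats::AIC(fit),
    separated = sep
  )
}

#' Choose the focal-smoothing radius of one covariate
#'
#' For each candidate radius, extracts the covariate (smoothed at that
#' radius) at the presence locations and at a dedicated GLM background sample
#' (conventionally 25 background points per presence, drawn at different
#' locations than the maximum-entropy background), fits the univariate
#' binomial GLM, and selects the radius with the lowest AIC. The radius with
#' the most extreme standardized coefficient is reported alongside; when the
#' two criteria disagree, AIC wins and `disagreement` is set. Exact AIC ties
#' go to the smallest radius (parsimony). Radii whose GLM is flagged as
#' separated are excluded from selection with a warning.
#'
#' @param presences data frame with `x`, `y` of presence locations.
#' @param glm_background data frame with `x`, `y` of background points.
#' @param smoothed_stacks named list of `covariate_stack`s, one per candidate
#'   radius; names are the radii in meters (e.g. `"50"`, `"270"`, ...).
#' @param variable layer name to optimize.
#' @return A `scale_selection`: tibble with one row per radius (`radius`,
#'   `coefficient`, `std_error`, `aic`, `separated`, `selected`) and
#'   attributes `variable`, `selected_radius`, `disagreement`.
#' @export
optimize_scale <- function(presences, glm_background, smoothed_stacks,
                           variable) {
  radii <- as.numeric(names(smoothed_stacks))
  if (anyNA(radii)) stop("`smoothed_stacks` must be named by radius", call. = FALSE)
  y <- c(rep(1, nrow(presences)), rep(0, nrow(glm_background)))
  rows <- purrr::map2_dfr(smoothed_stacks, radii, function(st, r) {
    v <- c(extract_values(st, presences)[[variable]],
           extract_values(st, glm_background)[[variable]])
    ok <- is.finite(v)
    dplyr::mutate(fit_binomial_glm(y[ok], v[ok]), radius = r, .before = 1)
  })
  rows <- dplyr::arrange(rows, radius)
  usable <- !rows$separated
  if (!any(usable)) stop("all candidate radii flagged as separated", call. = FALSE)
  if (any(!usable)) {
    warning(sprintf("optimize_scale(%s): %d radius(es) separated, excluded",
                    variable, sum(!usable)), call. = FALSE)
  }
  aic_pick <- rows$radius[usable][which.min(rows$aic[usable])]
  coef_pick <- rows$radius[usable][which.max(abs(rows$coefficient[usable]))]
  rows$selected <- rows$radius == aic_pick
  structure(
    rows,
    class = c("scale_selection", class(rows)),
    variable = variable,
    selected_radius = aic_pick,
    most_extreme_radius = coef_pick,
    disagreement = !isTRUE(all.equal(aic_pick, coef_pick))
  )
}

#' Optimize the scale of every layer in one pass
#'
#' @inheritParams optimize_scale
#' @param variables layer names; default all layers.
#' @return tibble with one row per variable: `variable`, `selected_radius`,
#'   `most_extreme_radius`, `disagreement`, and a `table` list-column of the
#'   per-radius GLM tables.
#' @export
optimize_scales <- function(presences, glm_background, smoothed_stacks,
                            variables = NULL) {
  if (is.null(variables)) variables <- stack_names(smoothed_stacks[[1]])
  purrr::map_dfr(variables, function(v) {
    sel <- optimize_scale(presences, glm_background, smoothed_stacks, v)
    tibble::tibble(
      variable = v,
      selected_radius = attr(sel, "selected_radius"),
      most_extreme_radius = attr(sel, "most_extreme_radius"),
      disagreement = attr(sel, "disagreement"),
      table = list(tibble::as_tibble(sel))
    )
  })
}

#' Pairwise-correlation screen with an interpretability order
#'
#' Iterates over variable pairs whose |Pearson r| exceeds `threshold` in
#' decreasing |r|; at each step the member ranked lower in `preference` (the
#' user's interpretability order; unlisted variables rank below listed ones,
#' ties broken by column order) is dropped and eligibility is recomputed.
#' Constant columns, whose correlation is undefined, are dropped up front
#' with a warning.
#'
#' @param table data frame of covariate values (rows = points).
#' @param threshold absolute-correlation cutoff; default 0.6.
#' @param preference character vector, most interpretable first.
#' @return A `screen_report` list: `retained`, `dropped` (tibble with
#'   `variable`, `partner`, `r`), `cor_matrix`, `vif` (tibble, computed on the
#'   retained set), `threshold`.
#' @export
pearson_screen <- function(table, threshold = 0.6, preference = character()) {
  tab <- dplyr::select(tibble::as_tibble(table), dplyr::where(is.numeric))
  if (ncol(tab) < 2L) stop("need at least 2 numeric variables", call. = FALSE)
  if (nrow(tab) < 3L) stop("need at least 3 rows", call. = FALSE)

  const <- vapply(tab, function(v) stats::sd(v) == 0 || !is.finite(stats::sd(v)),
                  logical(1))
  dropped <- tibble::tibble(variable = character(), partner = character(),
                            r = numeric())
  if (any(const)) {
    warning("constant column(s) dropped: ",
            paste(names(tab)[const], collapse = ", "), call. = FALSE)
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      variable = names(tab)[const], partner = NA_character_, r = NA_real_))
    tab <- tab[, !const, drop = FALSE]
  }

  full_cor <- stats::cor(tab)
  rank_of <- function(v) {
    i <- match(v, preference)
    ifelse(is.na(i), length(preference) + match(v, names(tab)), i)
  }
  keep <- names(tab)
  repeat {
    cm <- full_cor[keep, keep, drop = FALSE]
    cm[upper.tri(cm, diag = TRUE)] <- NA
    idx <- which(abs(cm) > threshold, arr.ind = TRUE)
    if (nrow(idx) == 0L) break
    worst <- idx[which.max(abs(cm[idx])), ]
    pair <- c(keep[worst[1]], keep[worst[2]])
    loser <- pair[which.max(rank_of(pair))]
    winner <- setdiff(pair, loser)
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      variable = loser, partner = winner,
      r = full_cor[pair[1], pair[2]]))
    keep <- setdiff(keep, loser)
  }

  structure(
    list(retained = keep, dropped = dropped, cor_matrix = full_cor,
         vif = if (length(keep) >= 2L && nrow(tab) > length(keep))
           vif(tab[, keep, drop = FALSE]) else NULL,
         threshold = threshold),
    class = "screen_report"
  )
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> |r| threshold %.2f: %d retained, %d dropped\n",
              x$threshold, length(x$retained), nrow(x$dropped)))
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$dropped)) {
    for (i in seq_len(nrow(x$dropped))) {
      cat(sprintf("  dropped %s (r = %.3f with %s)\n",
                  x$dropped$variable[i], x$dropped$r[i], x$dropped$partner[i]))
    }
  }
  invisible(x)
}

#' Variance inflation factors
#'
#' For each variable i, regresses it (OLS) on all the others and reports
#' VIF_i = 1 / (1 - R_i^2). Values of 1 mean no multicollinearity; values
#' above ~5 flag a highly correlated variable. Exact collinearity yields
#' `Inf`.
#'
#' @param table data frame of numeric covariates, more rows than columns, no
#'   constant column.
#' @return tibble with `variable`, `vif`.
#' @export
vif <- function(table) {
  tab <- as.data.frame(table)
  if (nrow(tab) <= ncol(tab)) stop("need more rows than variables", call. = FALSE)
  if (any(vapply(tab, function(v) stats::sd(v) == 0, logical(1)))) {
    stop("constant column; VIF undefined", call. = FALSE)
  }
  X <- scale(as.matrix(tab))
  vifs <- vapply(seq_len(ncol(X)), function(i) {
    fit <- stats::lm.fit(cbind(1, X[, -i, drop = FALSE]), X[, i])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, i] - mean(X[, i]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble::tibble(variable = names(tab), vif = vifs)
}
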