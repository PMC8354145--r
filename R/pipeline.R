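#' Assemble a pipeline run configuration
#'
#' Collects every tunable of the analysis with defaults set to the
#' conventional study settings: 500-m thinning, candidate radii
#' 50/270/742/1170 m, 10,000 maximum-entropy background points and a
#' 25-per-presence GLM background at distinct locations, |r| > 0.6 Pearson
#' screen, RM grid 0.5-4 by 0.5, 10 replicates with a 75/25 split.
#' Configurations round-trip through YAML ([write_config()] /
#' [read_config()]).
#'
#' @param occurrences occurrence CSV path or `occurrence_records` tibble.
#' @param rasters named character vector of ASCII-grid paths, or a
#'   `covariate_stack`.
#' @param disturbance_mask optional disturbance-year raster path or
#'   `grid_layer`.
#' @param vintage vegetation vintage year for the exclusion filter.
#' @param buffer MCP buffer in meters defining the modeling region.
#' @param thin_cell thinning grid cell in meters.
#' @param thin_anchor optional thinning grid anchor `(x, y)`.
#' @param radii candidate smoothing radii in meters.
#' @param n_background maximum-entropy background size.
#' @param glm_multiplier GLM background points per presence.
#' @param classes feature classes or `"auto"`.
#' @param rm_grid regularization multipliers to sweep.
#' @param n_replicates,train_frac evaluation replicates and training
#'   fraction.
#' @param pearson_threshold collinearity cutoff on |r|.
#' @param preference interpretability order for the Pearson screen.
#' @param eval_mode `"methods_text"` or `"figure4"` threshold rule.
#' @param n_windows,window_frac P/E window scheme.
#' @param seed master seed; stage seeds are derived from it.
#' @return A `run_config` (named list).
#' @export
run_config <- function(occurrences, rasters, disturbance_mask = NULL,
                       vintage = 2016, buffer = 10000, thin_cell = 500,
                       thin_anchor = NULL, radii = c(50, 270, 742, 1170),
                       n_background = 10000, glm_multiplier = 25,
                       classes = "auto", rm_grid = seq(0.5, 4, by = 0.5),
                       n_replicates = 10, train_frac = 0.75,
                       pearson_threshold = 0.6, preference = character(),
                       eval_mode = c("methods_text", "figure4"),
                       n_windows = 101, window_frac = 0.1, seed = 1L) {
  eval_mode <- match.arg(eval_mode)
  cfg <- list(
    occurrences = occurrences, rasters = rasters,
    disturbance_mask = disturbance_mask, vintage = vintage, buffer = buffer,
    thin_cell = thin_cell, thin_anchor = thin_anchor, radii = radii,
    n_background = n_background, glm_multiplier = glm_multiplier,
    classes = classes, rm_grid = rm_grid, n_replicates = n_replicates,
    train_frac = train_frac, pearson_threshold = pearson_threshold,
    preference = preference, eval_mode = eval_mode, n_windows = n_windows,
    window_frac = window_frac, seed = as.integer(seed)
  )
  structure(cfg, class = "run_config")
}

#' Write / read a configuration as YAML
#'
#' Only path-valued inputs survive serialization; in-memory stacks or record
#' tables are noted and must be re-supplied on read.
#'
#' @param config a `run_config`.
#' @param path YAML file.
#' @return `path` / a `run_config`.
#' @export
write_config <- function(config, path) {
  ser <- unclass(config)
  for (f in c("occurrences", "rasters", "disturbance_mask")) {
    if (!is.null(ser[[f]]) && !is.character(ser[[f]])) {
      ser[[f]] <- paste0("<in-memory ", class(ser[[f]])[1], ">")
    }
  }
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  if (!is.null(cfg$radii)) cfg$radii <- as.numeric(cfg$radii)
  if (!is.null(cfg$rm_grid)) cfg$rm_grid <- as.numeric(cfg$rm_grid)
  if (!is.null(cfg$preference)) cfg$preference <- as.character(cfg$preference)
  structure(cfg, class = "run_config")
}

load_stack <- function(rasters) {
  if (inherits(rasters, "covariate_stack")) return(rasters)
  layers <- lapply(seq_along(rasters), function(i) {
    read_ascii_grid(rasters[[i]],
                    name = if (!is.null(names(rasters))) names(rasters)[i])
  })
  covariate_stack(layers)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: exclusion filter, priority thinning, MCP-buffer region
#' construction, multi-scale smoothing and per-variable scale optimization
#' (against a dedicated GLM background disjoint from the maximum-entropy
#' background), Pearson/VIF screening, the regularization-multiplier sweep
#' with AICc ranking, replicate train/test evaluation (AUC, P/E curve,
#' continuous Boyce index), threshold classification, and the classified
#' suitability map. All artifacts and a manifest recording seeds, settings
#' and derived thresholds are written under `out_dir`; a second run with the
#' same config is bit-identical for all deterministic stages.
#'
#' @param config a `run_config`.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the main results: `thinned`, `region`,
#'   `scales`, `screen`, `ranking`, `top_model`, `replicates` (per-replicate
#'   AUC), `curve`, `classification`, `classified`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed

  stage <- "load inputs"
  res <- tryCatch({
    stack <- load_stack(config$rasters)
    occ <- if (is.character(config$occurrences)) {
      read_occurrences_csv(config$occurrences)
    } else config$occurrences
    dist_mask <- config$disturbance_mask
    if (is.character(dist_mask)) dist_mask <- read_ascii_grid(dist_mask)

    stage <- "filter"
    say("filter: %d records in", nrow(occ))
    occ <- filter_excluded(occ, dist_mask, vintage = config$vintage)

    stage <- "thin"
    thinned <- thin_by_grid(occ, cell = config$thin_cell, seed = seed,
                            anchor = config$thin_anchor)
    say("thin: %d records -> %d thinned", nrow(occ), nrow(thinned))
    readr::write_csv(tibble::as_tibble(thinned),
                     file.path(out_dir, "thinned.csv"))

    stage <- "region"
    region <- mcp_buffer(thinned, buffer = config$buffer)
    write_region_geojson(region, file.path(out_dir, "region.geojson"))

    stage <- "background"
    bg_pts <- sample_background(stack, region, config$n_background,
                                seed = seed + 1L)
    n_glm <- config$glm_multiplier * nrow(thinned)
    glm_pts <- sample_background(stack, region, n_glm, seed = seed + 2L,
                                 exclude = dplyr::bind_rows(
                                   bg_pts[, c("x", "y")],
                                   thinned[, c("x", "y")]))
    say("background: %d maxent + %d glm points", nrow(bg_pts), nrow(glm_pts))

    stage <- "smooth / scale optimization"
    smoothed <- lapply(config$radii, function(r) smooth_stack(stack, r))
    names(smoothed) <- config$radii
    scales <- optimize_scales(thinned, glm_pts, smoothed)
    readr::write_csv(dplyr::select(scales, -"table"),
                     file.path(out_dir, "scale_selection.csv"))
    say("scales: %s", paste(scales$variable, scales$selected_radius,
                            sep = "@", collapse = ", "))

    # one stack with each layer at its selected radius
    sel_layers <- lapply(seq_len(nrow(scales)), function(i) {
      smoothed[[as.character(scales$selected_radius[i])]]$layers[[scales$variable[i]]]
    })
    sel_stack <- covariate_stack(sel_layers)

    stage <- "screen"
    pres_tab <- extract_values(sel_stack, thinned)
    bg_tab <- extract_values(sel_stack, bg_pts)
    covars <- function(tab) tab[tab$valid & stats::complete.cases(tab),
                                stack_names(sel_stack), drop = FALSE]
    screen <- pearson_screen(covars(bg_tab),
                             threshold = config$pearson_threshold,
                             preference = config$preference)
    say("screen: retained %s", paste(screen$retained, collapse = ", "))
    # drop presences without usable covariates (masked cells) and keep the
    # record table aligned with the covariate table for the replicate splits
    ok_p <- pres_tab$valid & stats::complete.cases(pres_tab)
    pres_used <- thinned[ok_p, , drop = FALSE]
    pres_cov <- pres_tab[ok_p, screen$retained, drop = FALSE]
    bg_cov <- covars(bg_tab)[, screen$retained, drop = FALSE]

    stage <- "rm sweep / aicc"
    sweep <- rm_sweep(pres_cov, bg_cov, rms = config$rm_grid,
                      classes = config$classes)
    ranking <- aicc_rank(sweep)
    readr::write_csv(dplyr::select(ranking, -"model"),
                     file.path(out_dir, "ranking.csv"))
    top <- ranking$model[[1]]
    say("top model: RM %.2g (k = %d, AICc %.2f)", top$rm,
        sum(top$lambda != 0), ranking$aicc[1])
    write_maxent_json(top, file.path(out_dir, "top_model.json"))
    write_lambdas(top, file.path(out_dir, "top_model.lambdas"))

    contrib <- percent_contribution(top)
    perm <- permutation_importance(top, seed = seed + 3L)
    readr::write_csv(dplyr::left_join(contrib, perm, by = "variable"),
                     file.path(out_dir, "importance.csv"))

    stage <- "replicate evaluation"
    splits <- make_replicates(pres_used, n_rep = config$n_replicates,
                              train_frac = config$train_frac,
                              seed = seed + 4L)
    bg_scores <- predict(top, bg_cov, type = "logistic")
    rep_rows <- purrr::map_dfr(seq_len(nrow(splits)), function(r) {
      tr <- splits$train[[r]]; te <- splits$test[[r]]
      mod <- fit_maxent(pres_cov[tr, , drop = FALSE], bg_cov,
                        classes = config$classes, rm = top$rm,
                        keep_data = FALSE)
      test_scores <- predict(mod, pres_cov[te, , drop = FALSE],
                             type = "logistic")
      bg_s <- predict(mod, bg_cov, type = "logistic")
      tibble::tibble(replicate = r, n_train = length(tr), n_test = length(te),
                     test_auc = auc(test_scores, bg_s),
                     scores = list(test_scores))
    })
    readr::write_csv(dplyr::select(rep_rows, -"scores"),
                     file.path(out_dir, "replicates.csv"))
    say("replicates: mean test AUC %.3f", mean(rep_rows$test_auc))

    stage <- "P/E curve / classification"
    curve <- pe_curve(rep_rows$scores, bg_scores,
                      n_windows = config$n_windows,
                      window_frac = config$window_frac)
    readr::write_csv(curve$windows, file.path(out_dir, "pe_curve.csv"))
    classification <- classify_suitability(curve, rep_rows$scores,
                                           mode = config$eval_mode)
    say("thresholds: unsuitable < %.3f, highly suitable >= %.3f (Boyce %.3f)",
        classification$t_unsuitable, classification$t_high, curve$boyce)

    stage <- "map"
    prediction <- predict(top, sel_stack, type = "logistic")
    write_ascii_grid(prediction, file.path(out_dir, "prediction.asc"))
    classified <- classify_raster(prediction, classification)
    write_ascii_grid(classified$class_layer, file.path(out_dir, "classes.asc"))
    write_classes_geojson(classified, file.path(out_dir, "classes.geojson"))
    readr::write_csv(classified$components,
                     file.path(out_dir, "class_components.csv"))

    stage <- "summaries / manifest"
    mcp <- mcp_buffer(thinned, buffer = 0)
    summary_tab <- summarize_variables(sel_stack, region, mcp, thinned)
    readr::write_csv(summary_tab, file.path(out_dir, "variable_summary.csv"))

    manifest <- list(
      package_version = as.character(utils::packageVersion("maxsdm")),
      r_version = R.version.string,
      seed = seed,
      stage_seeds = list(thin = seed, background = seed + 1L,
                         glm_background = seed + 2L, permutation = seed + 3L,
                         replicates = seed + 4L),
      settings = unclass(write_config_list(config)),
      n_records_in = nrow(occ), n_thinned = nrow(thinned),
      n_candidates = nrow(ranking), n_replicates = config$n_replicates,
      top_rm = top$rm, top_k = sum(top$lambda != 0),
      top_aicc = ranking$aicc[1],
      mean_test_auc = mean(rep_rows$test_auc),
      boyce = curve$boyce,
      t_unsuitable = classification$t_unsuitable,
      t_high = classification$t_high,
      outputs = c(list.files(out_dir), "manifest.json")
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)

    list(thinned = thinned, region = region, scales = scales,
         screen = screen, ranking = ranking, top_model = top,
         replicates = rep_rows, curve = curve,
         classification = classification, classified = classified,
         summary = summary_tab, manifest = manifest)
  }, error = function(e) {
    stop(sprintf("pipeline halted at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

# Serializable view of a config (paths only).
write_config_list <- function(config) {
  ser <- unclass(config)
  for (f in c("occurrences", "rasters", "disturbance_mask")) {
    if (!is.null(ser[[f]]) && !is.character(ser[[f]])) {
      ser[[f]] <- paste0("<in-memory ", class(ser[[f]])[1], ">")
    }
  }
  ser
}

#' Per-variable summary over region, MCP and presence locations
#'
#' Range, mean and standard deviation of every layer (at its selected scale)
#' over (a) the cells of the modeling region, (b) the cells of the MCP, and
#' (c) the presence locations.
#'
#' @param stack covariate stack at selected scales.
#' @param region modeling region.
#' @param mcp minimum convex polygon region.
#' @param presences data frame of presence locations (`x`, `y`).
#' @return tibble: `variable`, `context`, `min`, `max`, `mean`, `sd`, `n`.
#' @export
summarize_variables <- function(stack, region, mcp, presences) {
  cc <- cell_centers(stack)
  unmasked <- !as.vector(stack_mask(stack))
  in_reg <- unmasked & in_region(region, cc$x, cc$y)
  in_mcp <- unmasked & in_region(mcp, cc$x, cc$y)
  pres_tab <- extract_values(stack, presences)
  stat_rows <- function(vals, context, nm) {
    vals <- vals[is.finite(vals)]
    tibble::tibble(variable = nm, context = context,
                   min = min(vals), max = max(vals),
                   mean = mean(vals), sd = stats::sd(vals), n = length(vals))
  }
  purrr::map_dfr(stack_names(stack), function(nm) {
    v <- as.vector(stack$layers[[nm]]$values)
    dplyr::bind_rows(
      stat_rows(v[in_reg], "model_region", nm),
      stat_rows(v[in_mcp], "mcp", nm),
      stat_rows(pres_tab[[nm]], "presence", nm)
    )
  })
}
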