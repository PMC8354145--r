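#' Rank-based AUC of presence vs background scores
#'
#' The Mann-Whitney statistic: the probability that a randomly chosen
#' presence outscores a randomly chosen background point, ties counting one
#' half. Invariant under any strictly monotone transform of the scores.
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (np == 0L || nb == 0L) stop("both score sets must be non-empty", call. = FALSE)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Maximum sensitivity-plus-specificity threshold
#'
#' Scans the distinct observed scores as candidate thresholds `t`, with
#' sensitivity the fraction of presences `>= t` and specificity the fraction
#' of background `< t`, and returns the `t` maximizing their sum (the usual
#' presence-only binarization rule, minimizing false negatives plus false
#' positives). Ties go to the lowest threshold.
#'
#' @inheritParams auc
#' @return the selected threshold.
#' @export
max_sss_threshold <- function(presence_scores, background_scores) {
  if (length(presence_scores) == 0L || length(background_scores) == 0L) {
    stop("both score sets must be non-empty", call. = FALSE)
  }
  cand <- sort(unique(c(presence_scores, background_scores)))
  ss <- vapply(cand, function(t) {
    mean(presence_scores >= t) + mean(background_scores < t)
  }, numeric(1))
  cand[which.max(ss)]   # which.max returns the first (lowest) maximizer
}

#' Predicted-to-expected (P/E) ratio curve with replicate bands
#'
#' Slides `n_windows` overlapping windows (width `window_frac` of the
#' background score range, midpoints evenly spanning that range) across the
#' logistic score axis. Within window i, the expected fraction `E_i` is the
#' share of background scores falling in the window and, per replicate r,
#' `F_ri = P_ri / E_i` with `P_ri` the share of that replicate's test
#' presences. A model no better than chance has F near 1 everywhere; good
#' models have F increasing in the score. The continuous Boyce index is the
#' Spearman rank correlation between the mean F and the window midpoints.
#' Windows with zero background mass are dropped and recorded.
#'
#' @param test_scores numeric vector of test-presence scores, or a list of
#'   vectors (one per replicate; >= 2 replicates give percentile bands).
#' @param background_scores background scores defining availability.
#' @param n_windows number of window midpoints (default 101).
#' @param window_frac window width as a fraction of the background score
#'   range (default 0.1).
#' @return A `pe_curve`: list with `windows` (tibble `midpoint`, `expected`,
#'   `f_mean`, `lo`, `hi`), the per-replicate `f_matrix`, `boyce`,
#'   `spearman_p`, `dropped_midpoints`, `window_width`, `n_replicates`.
#' @export
pe_curve <- function(test_scores, background_scores, n_windows = 101,
                     window_frac = 0.1) {
  reps <- if (is.list(test_scores)) test_scores else list(test_scores)
  if (length(background_scores) < 100) {
    warning("fewer than 100 background scores; P/E windows will be noisy",
            call. = FALSE)
  }
  rng <- range(background_scores)
  if (diff(rng) <= 0) {
    stop("background scores are constant: only a single window is possible, ",
         "fewer than the 3 needed for a P/E curve", call. = FALSE)
  }
  width <- window_frac * diff(rng)
  mids <- seq(rng[1], rng[2], length.out = n_windows)
  expected <- vapply(mids, function(m) {
    mean(background_scores >= m - width / 2 & background_scores <= m + width / 2)
  }, numeric(1))
  keep <- expected > 0
  if (sum(keep) < 3L) {
    stop("fewer than 3 windows carry background mass; prediction surface ",
         "too narrow for a P/E curve", call. = FALSE)
  }
  f_matrix <- do.call(rbind, lapply(reps, function(s) {
    p <- vapply(mids[keep], function(m) {
      mean(s >= m - width / 2 & s <= m + width / 2)
    }, numeric(1))
    p / expected[keep]
  }))
  f_mean <- colMeans(f_matrix)
  if (length(reps) >= 2L) {
    qs <- apply(f_matrix, 2, stats::quantile, probs = c(0.025, 0.975))
    lo <- qs[1, ]; hi <- qs[2, ]
  } else {
    lo <- rep(NA_real_, sum(keep)); hi <- rep(NA_real_, sum(keep))
  }
  boyce <- suppressWarnings(
    stats::cor(f_mean, mids[keep], method = "spearman"))
  sp <- suppressWarnings(
    stats::cor.test(f_mean, mids[keep], method = "spearman", exact = FALSE))
  structure(
    list(
      windows = tibble::tibble(midpoint = mids[keep],
                               expected = expected[keep],
                               f_mean = f_mean, lo = lo, hi = hi),
      f_matrix = f_matrix,
      boyce = boyce,
      spearman_p = unname(sp$p.value),
      dropped_midpoints = mids[!keep],
      window_width = width,
      n_replicates = length(reps)
    ),
    class = "pe_curve"
  )
}

#' @export
print.pe_curve <- function(x, ...) {
  cat(sprintf("<pe_curve> %d windows (width %.4g), %d replicate(s)\n",
              nrow(x$windows), x$window_width, x$n_replicates))
  cat(sprintf("  continuous Boyce index %.3f (Spearman p = %.3g)\n",
              x$boyce, x$spearman_p))
  if (length(x$dropped_midpoints)) {
    cat(sprintf("  %d empty window(s) dropped\n", length(x$dropped_midpoints)))
  }
  invisible(x)
}

#' Derive suitability thresholds from a P/E curve
#'
#' The lower threshold marks where the model starts beating random chance:
#' the midpoint of the first window whose mean F rises above 1 *and stays at
#' or above 1* in every higher window. Below it the map is unsuitable (or
#' marginal). The upper threshold splits the remaining scores: the median of
#' the test-presence scores above the lower threshold (`mode =
#' "methods_text"`), so the lower half is "suitable" and the upper half
#' "highly suitable". `mode = "figure4"` instead requires the *lower 95%
#' band* to clear the reference before suitability starts (windows where
#' only the mean clears it are marginal and fold into the bottom class).
#'
#' @param curve a `pe_curve`.
#' @param test_scores test-presence scores (vector or per-replicate list);
#'   pooled for the median split.
#' @param mode `"methods_text"` (default) or `"figure4"`.
#' @param reference the random-chance line the curve must clear; default 1
#'   (P/E = 1). A literal reading of "confidence interval overlapping 0" is
#'   available by setting `reference = 0` with `mode = "figure4"`.
#' @return A `suitability_classification`: list with `t_unsuitable`,
#'   `t_high`, `mode`, `reference`, `all_unsuitable`.
#' @export
classify_suitability <- function(curve, test_scores,
                                 mode = c("methods_text", "figure4"),
                                 reference = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(curve, "pe_curve"))
  w <- curve$windows
  series <- if (mode == "figure4") w$lo else w$f_mean
  if (mode == "figure4" && all(is.na(series))) {
    stop("figure4 mode needs replicate bands (>= 2 replicates)", call. = FALSE)
  }
  n <- length(series)
  # first window strictly above the reference whose tail never dips below it
  ok_tail <- rev(cumprod(rev(series >= reference))) == 1
  cross <- which(series > reference & ok_tail)
  scores <- unlist(test_scores)
  if (length(cross) == 0L) {
    warning("P/E never rises above the reference; everything classified ",
            "unsuitable", call. = FALSE)
    return(structure(list(t_unsuitable = 1, t_high = 1, mode = mode,
                          reference = reference, all_unsuitable = TRUE),
                     class = "suitability_classification"))
  }
  t_un <- w$midpoint[cross[1]]
  above <- scores[scores > t_un]
  t_high <- if (length(above)) stats::median(above) else t_un
  structure(list(t_unsuitable = t_un, t_high = t_high, mode = mode,
                 reference = reference, all_unsuitable = FALSE),
            class = "suitability_classification")
}

#' @export
print.suitability_classification <- function(x, ...) {
  cat(sprintf(
    "<suitability_classification> (%s) unsuitable < %.4g <= suitable < %.4g <= highly suitable\n",
    x$mode, x$t_unsuitable, x$t_high))
  invisible(x)
}

#' Classify a prediction raster into three suitability classes
#'
#' Applies half-open threshold bins to the logistic prediction —
#' `[0, t_unsuitable)` unsuitable/marginal (class 1), `[t_unsuitable,
#' t_high)` suitable (class 2), `[t_high, 1]` highly suitable (class 3) —
#' then dissolves contiguous same-class cells (rook adjacency) into polygon
#' components.
#'
#' @param prediction a `grid_layer` with values in \[0, 1\].
#' @param classification a `suitability_classification` (or a numeric vector
#'   `c(t_unsuitable, t_high)`).
#' @return list: `class_layer` (a `grid_layer` of 1/2/3), `components`
#'   (tibble `component`, `class`, `n_cells`, `area`), `rings` (per
#'   component, a list of closed ring matrices; the largest-area ring is the
#'   exterior, the rest are holes).
#' @export
classify_raster <- function(prediction, classification) {
  th <- if (inherits(classification, "suitability_classification")) {
    c(classification$t_unsuitable, classification$t_high)
  } else as.numeric(classification)
  v <- prediction$values
  cls <- ifelse(is.na(v), NA_integer_,
                ifelse(v < th[1], 1L, ifelse(v < th[2], 2L, 3L)))
  cls <- matrix(cls, nrow(v), ncol(v))
  lab <- label_components(cls)
  ids <- sort(unique(lab[!is.na(lab)]))
  cell_area <- prediction$cell_size^2
  components <- purrr::map_dfr(ids, function(id) {
    cells <- which(lab == id)
    tibble::tibble(component = id, class = cls[cells[1]],
                   n_cells = length(cells),
                   area = length(cells) * cell_area)
  })
  rings <- lapply(ids, function(id) {
    trace_rings(lab == id, prediction$cell_size, prediction$origin)
  })
  names(rings) <- as.character(ids)
  out <- prediction
  out$values <- cls * 1.0
  out$name <- "suitability_class"
  list(class_layer = out, components = components, rings = rings)
}

# Label rook-connected components of equal value; NA stays NA.
label_components <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(NA_integer_, nr, nc)
  nxt <- 0L
  for (start in which(!is.na(m))) {
    if (!is.na(lab[start])) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    val <- m[start]
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (cur - 1L) %% nr + 1L
      j <- (cur - 1L) %/% nr + 1L
      for (nb in c(if (i > 1L) cur - 1L, if (i < nr) cur + 1L,
                   if (j > 1L) cur - nr, if (j < nc) cur + nr)) {
        if (is.na(lab[nb]) && !is.na(m[nb]) && m[nb] == val) {
          lab[nb] <- nxt
          queue <- c(queue, nb)
        }
      }
    }
  }
  lab
}

# Trace the boundary rings of a logical cell mask as closed polygons.
# Directed cell edges keep the component interior on the left; rings are
# assembled by walking, preferring the sharpest left turn at shared corners.
trace_rings <- function(mask, cell_size, origin) {
  mask[is.na(mask)] <- FALSE
  idx <- which(mask)
  if (!length(idx)) return(list())
  nr <- nrow(mask); nc <- ncol(mask)
  i <- (idx - 1L) %% nr + 1L
  j <- (idx - 1L) %/% nr + 1L
  inm <- function(ii, jj) ii >= 1L & ii <= nr & jj >= 1L & jj <= nc &
    mask[cbind(pmax(pmin(ii, nr), 1L), pmax(pmin(jj, nc), 1L))]
  # vertex coordinates in cell units: cell (i, j) spans (j-1, i-1)..(j, i)
  edges <- list()
  add_edge <- function(x1, y1, x2, y2) {
    edges[[length(edges) + 1L]] <<- c(x1, y1, x2, y2)
  }
  for (k in seq_along(idx)) {
    ii <- i[k]; jj <- j[k]
    x0 <- jj - 1L; x1 <- jj; y0 <- ii - 1L; y1 <- ii
    if (!inm(ii - 1L, jj)) add_edge(x0, y0, x1, y0)   # bottom
    if (!inm(ii, jj + 1L)) add_edge(x1, y0, x1, y1)   # right
    if (!inm(ii + 1L, jj)) add_edge(x1, y1, x0, y1)   # top
    if (!inm(ii, jj - 1L)) add_edge(x0, y1, x0, y0)   # left
  }
  E <- do.call(rbind, edges)
  used <- rep(FALSE, nrow(E))
  start_key <- paste(E[, 1], E[, 2])
  by_start <- split(seq_len(nrow(E)), start_key)
  rings <- list()
  for (e0 in seq_len(nrow(E))) {
    if (used[e0]) next
    path <- E[e0, 1:2, drop = FALSE]
    cur <- e0
    repeat {
      used[cur] <- TRUE
      to <- E[cur, 3:4]
      path <- rbind(path, to)
      if (all(to == E[e0, 1:2])) break
      cand <- by_start[[paste(to[1], to[2])]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) break   # defensive; closed by construction
      if (length(cand) > 1L) {
        din <- E[cur, 3:4] - E[cur, 1:2]
        turn <- vapply(cand, function(e) {
          dout <- E[e, 3:4] - E[e, 1:2]
          atan2(din[1] * dout[2] - din[2] * dout[1],
                din[1] * dout[1] + din[2] * dout[2])
        }, numeric(1))
        cand <- cand[which.max(turn)]   # sharpest left turn
      }
      cur <- cand
    }
    ring <- cbind(x = origin[1] + path[, 1] * cell_size,
                  y = origin[2] + path[, 2] * cell_size)
    rings[[length(rings) + 1L]] <- ring
  }
  rings
}

#' Write classified components as GeoJSON
#' @param classified result of [classify_raster()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_classes_geojson <- function(classified, path) {
  feats <- purrr::map(seq_len(nrow(classified$components)), function(r) {
    row <- classified$components[r, ]
    rings <- classified$rings[[as.character(row$component)]]
    coords <- lapply(rings, function(rr) {
      lapply(seq_len(nrow(rr)), function(i) c(rr[i, 1], rr[i, 2]))
    })
    list(type = "Feature",
         properties = list(class = row$class, component = row$component,
                           n_cells = row$n_cells, area = row$area),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
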