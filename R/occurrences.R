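#' Occurrence records
#'
#' Builds the tibble of georeferenced detections the pipeline consumes. Each
#' record carries a detection `source_type` that maps to a retention
#' priority used during spatial thinning: telemetry-verified den and rest
#' structures are the most reliable evidence of residency, scat-detection-dog
#' finds next, baited camera / track-plate stations next, and everything else
#' (roadkill, incidental) last.
#'
#' @param x,y coordinates in projected meters.
#' @param year detection year.
#' @param source_type one of `"den_rest"`, `"scat_dog"`, `"station"`,
#'   `"telemetry"`, `"roadkill"`, `"other"`.
#' @param excluded_flag logical; `TRUE` marks records known to sit in areas
#'   disturbed after the detection (dropped by [filter_excluded()]).
#' @return tibble with class `occurrence_records`.
#' @export
occurrence_records <- function(x, y, year, source_type,
                               excluded_flag = FALSE) {
  source_type <- as.character(source_type)
  bad <- setdiff(unique(source_type), names(.priority_map))
  if (length(bad)) {
    stop("unknown source_type: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    x = as.numeric(x), y = as.numeric(y), year = as.integer(year),
    source_type = source_type,
    excluded_flag = rep_len(as.logical(excluded_flag), length(x))
  )
  class(out) <- c("occurrence_records", class(out))
  out
}

.priority_map <- c(den_rest = 1L, scat_dog = 2L, station = 3L,
                   telemetry = 4L, roadkill = 4L, other = 4L)

#' Retention priority rank of a detection type
#'
#' Rank 1 (highest priority) = den/rest, 2 = scat dog, 3 = station, 4 = all
#' other types.
#'
#' @param source_type character vector of detection types.
#' @return integer ranks.
#' @export
priority_rank <- function(source_type) {
  unname(.priority_map[as.character(source_type)])
}

#' Read occurrence records from CSV
#'
#' Expects columns `x,y,year,source_type` and optionally `excluded_flag`.
#'
#' @param path CSV file.
#' @return `occurrence_records` tibble.
#' @export
read_occurrences_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  occurrence_records(
    d$x, d$y, d$year, d$source_type,
    excluded_flag = if ("excluded_flag" %in% names(d)) d$excluded_flag else FALSE
  )
}

#' Drop records invalidated by later disturbance
#'
#' Removes records whose location burned or was harvested *after* the
#' detection but before the vegetation layers' vintage year, because the
#' covariates there no longer describe the conditions the animal used.
#' A record is dropped when its `excluded_flag` is set, or, if a
#' `disturbance_mask` holding per-cell disturbance years is supplied, when
#' `record year < cell disturbance year <= vintage`.
#'
#' @param records `occurrence_records`.
#' @param disturbance_mask optional `grid_layer` whose values are disturbance
#'   years (`NA` = never disturbed).
#' @param vintage vegetation-data vintage year; disturbances after it are
#'   irrelevant (they postdate the covariates too). Default 2016.
#' @return filtered records; the number dropped is reported via `message()`.
#' @export
filter_excluded <- function(records, disturbance_mask = NULL, vintage = 2016) {
  drop <- records$excluded_flag
  if (!is.null(disturbance_mask)) {
    ev <- extract_values(disturbance_mask, records)
    dist_year <- ev[[4]]
    drop <- drop | (!is.na(dist_year) &
                      dist_year > records$year & dist_year <= vintage)
  }
  if (any(drop)) {
    message(sprintf("filter_excluded: dropped %d of %d records",
                    sum(drop), length(drop)))
  }
  records[!drop, , drop = FALSE]
}

#' Priority-aware spatial thinning on a square grid
#'
#' Overlays a `cell` x `cell` grid (default 500 m, anchored at the records'
#' bounding-box lower-left corner unless `anchor` is given) and keeps exactly
#' one record per occupied cell: among the records of the best (lowest)
#' priority rank present in a cell, one is chosen uniformly at random under
#' `seed`. Thinning a thinned set returns it unchanged.
#'
#' @param records `occurrence_records`.
#' @param cell thinning cell edge in meters (> 0); default 500.
#' @param seed integer seed for the within-cell draw.
#' @param anchor optional `(x, y)` grid anchor.
#' @return A `thinned_set`: the retained records plus a `cell_index` column;
#'   attributes `cell`, `anchor`, `seed`.
#' @export
thin_by_grid <- function(records, cell = 500, seed = 1L, anchor = NULL) {
  if (!is.numeric(cell) || length(cell) != 1L || cell <= 0) {
    stop("`cell` must be a single positive number", call. = FALSE)
  }
  if (nrow(records) == 0L) stop("no records to thin", call. = FALSE)
  if (is.null(anchor)) {
    # reuse the grid anchor of an already-thinned set so thinning is idempotent
    anchor <- attr(records, "anchor", exact = TRUE)
    if (is.null(anchor)) anchor <- c(min(records$x), min(records$y))
  }
  ci <- floor((records$x - anchor[1]) / cell)
  ri <- floor((records$y - anchor[2]) / cell)
  key <- paste(ci, ri, sep = ":")
  rank <- priority_rank(records$source_type)

  keep <- withr::with_seed(as.integer(seed), {
    vapply(split(seq_len(nrow(records)), key), function(idx) {
      best <- idx[rank[idx] == min(rank[idx])]
      if (length(best) == 1L) best else sample(best, 1L)
    }, integer(1))
  })
  keep <- sort(unname(keep))

  out <- records[keep, , drop = FALSE]
  out$cell_index <- key[keep]
  class(out) <- c("thinned_set", setdiff(class(out), "thinned_set"))
  attr(out, "cell") <- cell
  attr(out, "anchor") <- anchor
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Replicate train/test partitions of a thinned set
#'
#' Produces `n_rep` independent random partitions of the presences into a
#' training fraction and its complement (the Maxent-style "bootstrap with
#' random test percentage" scheme: the partition is redrawn per replicate;
#' records are never resampled with replacement within a split).
#'
#' @param thinned a `thinned_set` (or any data frame of presences).
#' @param n_rep number of replicates (default 10).
#' @param train_frac training fraction in (0, 1); default 0.75. The training
#'   size is `round(train_frac * n)`.
#' @param seed integer seed.
#' @return tibble with one row per replicate: `replicate`, list-columns
#'   `train` and `test` holding integer row indices into `thinned`.
#' @export
make_replicates <- function(thinned, n_rep = 10, train_frac = 0.75, seed = 1L) {
  n <- nrow(thinned)
  if (train_frac <= 0 || train_frac >= 1) {
    stop("`train_frac` must be strictly between 0 and 1", call. = FALSE)
  }
  if (n < 4L) stop("need at least 4 presences to split", call. = FALSE)
  n_train <- round(train_frac * n)
  splits <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_rep), function(r) sort(sample(n, n_train)))
  })
  tibble::tibble(
    replicate = seq_len(n_rep),
    train = splits,
    test = lapply(splits, function(tr) setdiff(seq_len(n), tr))
  )
}
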