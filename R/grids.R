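#' Create a single-covariate grid layer
#'
#' A `grid_layer` is the package's raster primitive: one covariate on a
#' regular grid in projected (metric) coordinates. Cells are addressed by
#' half-open intervals, so a point at `x` falls in column
#' `floor((x - origin_x) / cell_size) + 1`, and every statistic computed on
#' the layer ignores nodata cells, which are stored as `NA`.
#'
#' Row 1 of `values` is the *bottom* row of the grid (smallest y); this keeps
#' the index arithmetic `y = origin_y + (row - 0.5) * cell_size` free of
#' flips. [read_ascii_grid()] and [write_ascii_grid()] perform the reordering
#' that the ESRI ASCII format (top row first) requires.
#'
#' @param values numeric matrix; `NA` marks nodata cells.
#' @param cell_size cell edge length in meters (> 0).
#' @param origin numeric length-2, (x, y) of the grid's lower-left corner.
#' @param name layer name.
#' @param crs free-text tag describing the projected CRS; never interpreted.
#' @return An object of class `grid_layer`.
#' @export
#' @examples
#' gl <- grid_layer(matrix(1:9, 3, 3), cell_size = 100)
#' grid_dim(gl)
grid_layer <- function(values, cell_size, origin = c(0, 0), name = "layer",
                       crs = "") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("`cell_size` must be a single positive number", call. = FALSE)
  }
  if (length(origin) != 2L || !is.numeric(origin)) {
    stop("`origin` must be numeric of length 2", call. = FALSE)
  }
  structure(
    list(name = as.character(name), values = values,
         cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), crs = as.character(crs)),
    class = "grid_layer"
  )
}

#' @export
print.grid_layer <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<grid_layer '%s'> %d x %d cells @ %g m, origin (%g, %g), %d nodata\n",
              x$name, d[1], d[2], x$cell_size, x$origin[1], x$origin[2],
              sum(is.na(x$values))))
  invisible(x)
}

#' Grid dimensions (rows, cols)
#' @param layer a `grid_layer` or `covariate_stack`.
#' @return integer vector (rows, cols).
#' @export
grid_dim <- function(layer) {
  if (inherits(layer, "covariate_stack")) layer <- layer$layers[[1]]
  dim(layer$values)
}

#' Nodata mask of a layer
#' @param layer a `grid_layer`.
#' @return logical matrix, `TRUE` where the cell is nodata.
#' @export
nodata_mask <- function(layer) is.na(layer$values)

#' Cell-center coordinates of every cell
#'
#' @param layer a `grid_layer` or `covariate_stack`.
#' @return tibble with columns `row`, `col`, `x`, `y` (one row per cell,
#'   column-major order matching `as.vector(values)`).
#' @export
cell_centers <- function(layer) {
  if (inherits(layer, "covariate_stack")) layer <- layer$layers[[1]]
  d <- dim(layer$values)
  rows <- rep(seq_len(d[1]), times = d[2])
  cols <- rep(seq_len(d[2]), each = d[1])
  tibble::tibble(
    row = rows, col = cols,
    x = layer$origin[1] + (cols - 0.5) * layer$cell_size,
    y = layer$origin[2] + (rows - 0.5) * layer$cell_size
  )
}

#' @export
as_tibble.grid_layer <- function(x, ...) {
  dplyr::mutate(cell_centers(x), value = as.vector(x$values))
}

#' Locate points on the grid (half-open cell convention)
#'
#' Maps each point to the cell whose half-open interval
#' `[x0, x0 + cell_size)` contains it, so a point on a shared edge belongs to
#' exactly one cell (the upper/right neighbour).
#'
#' @param layer a `grid_layer` or `covariate_stack`.
#' @param x,y point coordinates in projected meters.
#' @return tibble with `row`, `col` (NA when the point is outside the extent)
#'   and logical `inside`.
#' @export
locate_cells <- function(layer, x, y) {
  if (inherits(layer, "covariate_stack")) layer <- layer$layers[[1]]
  d <- dim(layer$values)
  col <- floor((x - layer$origin[1]) / layer$cell_size) + 1
  row <- floor((y - layer$origin[2]) / layer$cell_size) + 1
  inside <- col >= 1 & col <= d[2] & row >= 1 & row <= d[1] &
    !is.na(col) & !is.na(row)
  tibble::tibble(row = ifelse(inside, row, NA_integer_),
                 col = ifelse(inside, col, NA_integer_),
                 inside = inside)
}

#' Bundle co-registered layers into a covariate stack
#'
#' All layers must share geometry (dimensions, cell size, origin) exactly and
#' carry unique names.
#'
#' @param ... `grid_layer` objects, or a single list of them.
#' @return A `covariate_stack`.
#' @export
covariate_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && !inherits(layers[[1]], "grid_layer")) {
    layers <- layers[[1]]
  }
  if (length(layers) == 0L) stop("need at least one layer", call. = FALSE)
  ref <- layers[[1]]
  for (l in layers) {
    stopifnot(inherits(l, "grid_layer"))
    if (!identical(dim(l$values), dim(ref$values)) ||
        l$cell_size != ref$cell_size ||
        !isTRUE(all.equal(l$origin, ref$origin))) {
      stop("all layers must share geometry exactly", call. = FALSE)
    }
  }
  nms <- vapply(layers, function(l) l$name, character(1))
  if (anyDuplicated(nms)) stop("layer names must be unique", call. = FALSE)
  names(layers) <- nms
  structure(list(layers = layers), class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  d <- grid_dim(x)
  cat(sprintf("<covariate_stack> %d layers, %d x %d cells @ %g m\n",
              length(x$layers), d[1], d[2], x$layers[[1]]$cell_size))
  cat(" ", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Layer names of a stack
#' @param stack a `covariate_stack`.
#' @return character vector.
#' @export
stack_names <- function(stack) names(stack$layers)

# Combined nodata mask across a stack: a cell is unusable if any layer is NA.
stack_mask <- function(stack) {
  m <- nodata_mask(stack$layers[[1]])
  for (l in stack$layers[-1]) m <- m | nodata_mask(l)
  m
}

#' Focal (moving-window circular) mean of a layer
#'
#' Each unmasked cell receives the mean of unmasked cell values whose centers
#' lie within `radius` meters of that cell's center; the cell itself is
#' always included. Nodata cells stay nodata, and nodata neighbours are
#' simply excluded from the mean (they do not propagate), so coastline cells
#' keep large-radius values. Should the whole neighbourhood be masked the
#' cell becomes nodata.
#'
#' Implemented as an FFT convolution of the masked values and of the mask
#' itself, which keeps the cost near `O(n log n)` even for home-range-sized
#' radii (for a 30 m grid, the 1,170 m radius spans a 79 x 79 cell window).
#'
#' @param layer a `grid_layer`.
#' @param radius neighbourhood radius in meters (>= 0). A radius smaller
#'   than half a cell returns the layer unchanged.
#' @return A `grid_layer` with the smoothed values, named
#'   `<name>_r<radius>`.
#' @export
focal_mean <- function(layer, radius) {
  stopifnot(inherits(layer, "grid_layer"))
  if (!is.numeric(radius) || length(radius) != 1L || is.na(radius) || radius < 0) {
    stop("`radius` must be a single non-negative number", call. = FALSE)
  }
  cs <- layer$cell_size
  r_cells <- floor(radius / cs + 1e-9)
  out <- layer
  out$name <- sprintf("%s_r%g", layer$name, radius)
  if (r_cells == 0L) return(out)

  # circular kernel on cell-center distances, inclusive boundary
  off <- seq(-r_cells, r_cells)
  dist <- sqrt(outer(off^2, off^2, "+")) * cs
  kernel <- (dist <= radius + 1e-9) * 1

  vals <- layer$values
  ok <- !is.na(vals)
  v0 <- ifelse(ok, vals, 0)

  num <- conv2d_same(v0, kernel)
  cnt <- round(conv2d_same(ok * 1, kernel))

  sm <- ifelse(cnt > 0, num / pmax(cnt, 1), NA_real_)
  sm[!ok] <- NA_real_
  out$values <- sm
  out
}

# 2-D "same"-size convolution via zero-padded FFT. kernel must have odd dims.
conv2d_same <- function(x, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  nr <- nrow(x); nc <- ncol(x)
  pr <- nr + kr - 1L; pc <- nc + kc - 1L
  X <- matrix(0, pr, pc); X[1:nr, 1:nc] <- x
  K <- matrix(0, pr, pc); K[1:kr, 1:kc] <- kernel
  full <- Re(stats::fft(stats::fft(X) * stats::fft(K), inverse = TRUE)) / (pr * pc)
  hr <- (kr - 1L) %/% 2L; hc <- (kc - 1L) %/% 2L
  full[(hr + 1L):(hr + nr), (hc + 1L):(hc + nc)]
}

#' Smooth every layer of a stack at one radius
#' @param stack a `covariate_stack`.
#' @param radius radius in meters.
#' @param keep_names if `TRUE` (default) layers keep their original names so
#'   stacks at different radii are directly comparable.
#' @return A `covariate_stack` of smoothed layers.
#' @export
smooth_stack <- function(stack, radius, keep_names = TRUE) {
  layers <- lapply(stack$layers, function(l) {
    s <- focal_mean(l, radius)
    if (keep_names) s$name <- l$name
    s
  })
  covariate_stack(layers)
}

## ---- regions -------------------------------------------------------------

#' Build a modeling region as a buffered minimum convex polygon
#'
#' Computes the convex hull (MCP) of the points and dilates it by `buffer`
#' meters (Minkowski sum with a disc, arcs discretized). A 10-km buffer
#' around all occurrence locations is the conventional way to delimit the
#' available environment for background sampling.
#'
#' @param points a data frame with columns `x`, `y`, or a 2-column matrix.
#' @param buffer dilation distance in meters (>= 0).
#' @param arc_step arc discretization step in radians for the rounded
#'   corners; the default (pi/180) keeps the polygonal area within ~1e-4 of
#'   the exact disc.
#' @return A `region` object: list with `polygon` (counter-clockwise matrix
#'   of vertices), `source = "mcp_buffer"`, `buffer`.
#' @export
mcp_buffer <- function(points, buffer, arc_step = pi / 180) {
  pts <- as.matrix(as.data.frame(points)[, c("x", "y")])
  storage.mode(pts) <- "double"
  pts <- unique(pts)
  if (nrow(pts) < 3L) stop("need >= 3 distinct points for an MCP", call. = FALSE)
  if (buffer < 0) stop("`buffer` must be >= 0", call. = FALSE)
  h <- grDevices::chull(pts)            # clockwise indices
  hull <- pts[rev(h), , drop = FALSE]   # counter-clockwise
  if (polygon_area(hull) <= 0) stop("points are collinear; MCP is degenerate",
                                    call. = FALSE)
  poly <- if (buffer == 0) hull else buffer_convex(hull, buffer, arc_step)
  structure(list(polygon = poly, source = "mcp_buffer", buffer = buffer),
            class = "region")
}

#' Wrap a user polygon as a region
#' @param polygon 2-column matrix or data frame of vertices (one ring).
#' @return A `region`.
#' @export
region_from_polygon <- function(polygon) {
  poly <- as.matrix(as.data.frame(polygon)[, 1:2])
  colnames(poly) <- c("x", "y")
  a <- polygon_area(poly)
  if (abs(a) <= 0) stop("polygon has zero area", call. = FALSE)
  if (a < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  structure(list(polygon = poly, source = "user", buffer = 0),
            class = "region")
}

# Signed shoelace area; > 0 for counter-clockwise rings.
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Area of a region in square meters
#' @param region a `region`.
#' @export
region_area <- function(region) abs(polygon_area(region$polygon))

# Minkowski sum of a CCW convex polygon with a disc of radius b.
buffer_convex <- function(hull, b, arc_step) {
  n <- nrow(hull)
  out_x <- numeric(0); out_y <- numeric(0)
  for (i in seq_len(n)) {
    p_prev <- hull[if (i == 1L) n else i - 1L, ]
    p <- hull[i, ]
    p_next <- hull[if (i == n) 1L else i + 1L, ]
    a_in <- atan2(p[2] - p_prev[2], p[1] - p_prev[1]) - pi / 2   # inbound edge normal
    a_out <- atan2(p_next[2] - p[2], p_next[1] - p[1]) - pi / 2  # outbound edge normal
    sweep <- (a_out - a_in) %% (2 * pi)
    k <- max(1L, ceiling(sweep / arc_step))
    ang <- a_in + sweep * (0:k) / k
    out_x <- c(out_x, p[1] + b * cos(ang))
    out_y <- c(out_y, p[2] + b * sin(ang))
  }
  cbind(x = out_x, y = out_y)
}

#' Test points for region membership
#' @param region a `region`.
#' @param x,y coordinates.
#' @return logical vector (`TRUE` also on the boundary).
#' @export
in_region <- function(region, x, y) {
  poly <- region$polygon
  pracma::inpolygon(x, y, poly[, 1], poly[, 2], boundary = TRUE)
}

## ---- background sampling & extraction -------------------------------------

#' Sample background (pseudo-absence) cell centers
#'
#' Draws a uniform, seed-reproducible sample of distinct eligible cell
#' centers: cells that are unmasked in every layer, whose center falls inside
#' the region, and that are not occupied by `exclude` points (so the
#' GLM background used for scale optimization can be kept disjoint from the
#' maximum-entropy background).
#'
#' @param stack a `covariate_stack`.
#' @param region a `region`, or `NULL` for the whole grid.
#' @param n number of points.
#' @param seed integer seed; the draw is bit-reproducible for a fixed seed.
#' @param exclude optional data frame with `x`, `y`: cells containing these
#'   points are ineligible.
#' @return tibble with columns `x`, `y`, `label = "background"`.
#' @export
sample_background <- function(stack, region, n, seed, exclude = NULL) {
  cc <- cell_centers(stack)
  eligible <- !as.vector(stack_mask(stack))
  if (!is.null(region)) {
    eligible <- eligible & in_region(region, cc$x, cc$y)
  }
  if (!is.null(exclude) && nrow(as.data.frame(exclude)) > 0) {
    ex <- as.data.frame(exclude)
    loc <- locate_cells(stack, ex$x, ex$y)
    d <- grid_dim(stack)
    occupied <- unique((loc$col[loc$inside] - 1L) * d[1] + loc$row[loc$inside])
    eligible[occupied] <- FALSE
  }
  idx <- which(eligible)
  if (n > length(idx)) {
    stop(sprintf("requested %d background points but only %d eligible cells",
                 n, length(idx)), call. = FALSE)
  }
  take <- withr::with_seed(as.integer(seed), sample(idx, n))
  tibble::tibble(x = cc$x[take], y = cc$y[take], label = "background")
}

#' Extract covariate values at points
#'
#' Each point is mapped to its containing cell (half-open intervals, see
#' [locate_cells()]) and that cell's value is read from every layer. Points
#' outside the grid extent are flagged invalid with a warning and carry `NA`
#' values.
#'
#' @param stack a `covariate_stack` (or single `grid_layer`).
#' @param points data frame with columns `x`, `y`.
#' @return tibble: `x`, `y`, `valid`, then one column per layer.
#' @export
extract_values <- function(stack, points) {
  if (inherits(stack, "grid_layer")) stack <- covariate_stack(list(stack))
  pts <- as.data.frame(points)
  loc <- locate_cells(stack, pts$x, pts$y)
  if (any(!loc$inside)) {
    warning(sprintf("%d point(s) outside grid extent; rows flagged invalid",
                    sum(!loc$inside)), call. = FALSE)
  }
  d <- grid_dim(stack)
  lin <- (loc$col - 1L) * d[1] + loc$row
  out <- tibble::tibble(x = pts$x, y = pts$y, valid = loc$inside)
  for (nm in stack_names(stack)) {
    v <- rep(NA_real_, nrow(pts))
    v[loc$inside] <- stack$layers[[nm]]$values[lin[loc$inside]]
    out[[nm]] <- v
  }
  out
}

## ---- file formats ----------------------------------------------------------

#' Read an ESRI ASCII grid
#'
#' Single-band plain-text raster: a 6-line header (`ncols`, `nrows`,
#' `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`, `cellsize`,
#' `nodata_value`) followed by rows top-first. Nodata cells become `NA`.
#'
#' @param path file path.
#' @param name layer name; default the file stem.
#' @param crs optional CRS tag to attach.
#' @return A `grid_layer`.
#' @export
read_ascii_grid <- function(path, name = NULL, crs = "") {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (grepl("^\\s*[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  ox <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cs / 2
  oy <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cs / 2
  body <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(body) != nr * nc) {
    stop("ASCII grid body does not match header dimensions", call. = FALSE)
  }
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)   # top row first
  m[m == nodata] <- NA_real_
  m <- m[nr:1, , drop = FALSE]                            # bottom row first
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  grid_layer(m, cell_size = cs, origin = c(ox, oy), name = name, crs = crs)
}

#' Write an ESRI ASCII grid
#' @param layer a `grid_layer`.
#' @param path destination file.
#' @param nodata value used for `NA` cells (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(layer, path, nodata = -9999) {
  m <- layer$values
  nr <- nrow(m)
  m <- m[nr:1, , drop = FALSE]
  m[is.na(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", layer$origin[1]),
    sprintf("yllcorner %.10g", layer$origin[2]),
    sprintf("cellsize %.10g", layer$cell_size),
    sprintf("nodata_value %.10g", nodata)
  )
  rows <- apply(m, 1, function(r) paste(format(r, trim = TRUE, digits = 10),
                                        collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write a region (or raw rings) as GeoJSON
#' @param region a `region` object or a list of ring matrices.
#' @param path destination file.
#' @param properties named list of feature properties.
#' @return `path`, invisibly.
#' @export
write_region_geojson <- function(region, path, properties = list()) {
  rings <- if (inherits(region, "region")) list(region$polygon) else region
  coords <- lapply(rings, function(r) {
    r <- rbind(r, r[1, ])  # close ring
    lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
  })
  gj <- list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature",
      properties = properties,
      geometry = list(type = "Polygon", coordinates = coords)
    ))
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
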