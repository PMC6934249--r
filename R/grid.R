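#' Create a regular single-band grid
#'
#' The universal raster carrier of the package: a numeric matrix with an
#' axis-aligned, square-cell georeference in a projected metric CRS. Row 1
#' is the northernmost row (the usual raster convention); `NA` marks nodata
#' cells, which are excluded from every statistic in the package.
#'
#' @param values Numeric matrix. Rows run north to south, columns west to
#'   east. Use `NA` for nodata.
#' @param xmin x coordinate (metres) of the west edge.
#' @param ymax y coordinate (metres) of the north edge.
#' @param cell_size_m Cell edge length in metres. The nominal working
#'   resolution of the pipeline is 100 m, so one cell is 1 ha.
#' @param crs Label of the projected metric CRS the coordinates live in.
#'   Purely a consistency tag: operations refuse to mix grids or zones
#'   whose labels differ.
#' @param nodata Sentinel written for `NA` cells on file output.
#'
#' @return An object of class `mg_grid`.
#' @export
#' @examples
#' g <- mg_grid(matrix(1:12, 3, 4))
#' g
#' cell_area_ha(g)
mg_grid <- function(values, xmin = 0, ymax = nrow(values) * cell_size_m,
                    cell_size_m = 100, crs = "local-metric",
                    nodata = -9999) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (!is.numeric(cell_size_m) || length(cell_size_m) != 1 || cell_size_m <= 0) {
    stop("`cell_size_m` must be a single positive number", call. = FALSE)
  }
  if (is.null(crs) || is.na(crs) || !nzchar(crs)) stop("missing CRS", call. = FALSE)
  structure(
    list(values = values, xmin = xmin, ymax = ymax,
         cell_size_m = cell_size_m, crs = crs, nodata = nodata),
    class = "mg_grid"
  )
}

#' @export
print.mg_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<mg_grid> %d x %d cells, %g m resolution (%g ha/cell), crs \"%s\"\n",
              nrow(v), ncol(v), x$cell_size_m, cell_area_ha(x), x$crs))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              x$xmin, grid_xmax(x), grid_ymin(x), x$ymax))
  ok <- !is.na(v)
  if (any(ok)) {
    cat(sprintf("  values: min %g, max %g, nodata cells %d\n",
                min(v[ok]), max(v[ok]), sum(!ok)))
  } else {
    cat("  values: all nodata\n")
  }
  invisible(x)
}

#' Grid geometry helpers
#'
#' @param g An `mg_grid`.
#' @return `cell_area_ha()` the area of one cell in hectares;
#'   `grid_xmax()`/`grid_ymin()` the east/south extent edges;
#'   `cell_centres()` a tibble of cell centres.
#' @export
cell_area_ha <- function(g) g$cell_size_m^2 / 1e4

#' @rdname cell_area_ha
#' @export
grid_xmax <- function(g) g$xmin + ncol(g$values) * g$cell_size_m

#' @rdname cell_area_ha
#' @export
grid_ymin <- function(g) g$ymax - nrow(g$values) * g$cell_size_m

# x of column centres / y of row centres
col_x <- function(g, cols = seq_len(ncol(g$values))) {
  g$xmin + (cols - 0.5) * g$cell_size_m
}
row_y <- function(g, rows = seq_len(nrow(g$values))) {
  g$ymax - (rows - 0.5) * g$cell_size_m
}

#' @rdname cell_area_ha
#' @export
cell_centres <- function(g) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    x = rep(col_x(g), each = nr),
    y = rep(row_y(g), times = nc),
    value = as.vector(g$values)
  )
}

# two grids share a georeference (shape, transform, crs)
same_georef <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol &&
    abs(a$cell_size_m - b$cell_size_m) < tol && identical(a$crs, b$crs)
}

stop_if_misaligned <- function(a, b, what = "grids") {
  if (!same_georef(a, b)) {
    stop(sprintf("%s do not share a georeference (shape/transform/crs)", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

# new grid with same georeference, different values
grid_like <- function(template, values) {
  mg_grid(values, xmin = template$xmin, ymax = template$ymax,
          cell_size_m = template$cell_size_m, crs = template$crs,
          nodata = template$nodata)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Turn a grid into a long tibble of cell centres
#'
#' @param x An `mg_grid`.
#' @param ... Unused.
#' @return A tibble with `row`, `col`, `x`, `y`, `value`.
#' @export
as_tibble.mg_grid <- function(x, ...) cell_centres(x)

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Plot a grid as a raster heat map
#'
#' @param object An `mg_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mg_grid <- function(object, ...) {
  df <- cell_centres(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}

#' Align a covariate grid to a target georeference by nearest neighbour
#'
#' Each output cell takes the value of the source cell containing the
#' output cell's centre; nodata propagates, and output cells whose centres
#' fall outside the source extent are nodata. Centres that land exactly on
#' a source cell boundary are assigned to the cell to the east/south of the
#' boundary, a fixed deterministic convention.
#'
#' @param src Source `mg_grid`.
#' @param template An `mg_grid` supplying the target shape, transform and
#'   CRS (its values are ignored).
#' @return An `mg_grid` on the template georeference.
#' @export
resample_nearest <- function(src, template) {
  stopifnot(inherits(src, "mg_grid"), inherits(template, "mg_grid"))
  if (!identical(src$crs, template$crs)) {
    stop("missing or mismatched CRS: source and target differ", call. = FALSE)
  }
  if (grid_xmax(src) <= template$xmin || src$xmin >= grid_xmax(template) ||
      src$ymax <= grid_ymin(template) || grid_ymin(src) >= template$ymax) {
    stop("no spatial overlap", call. = FALSE)
  }
  nr <- nrow(template$values); nc <- ncol(template$values)
  tx <- col_x(template); ty <- row_y(template)
  src_col <- floor((tx - src$xmin) / src$cell_size_m) + 1L
  src_row <- floor((src$ymax - ty) / src$cell_size_m) + 1L
  ok_c <- src_col >= 1L & src_col <= ncol(src$values)
  ok_r <- src_row >= 1L & src_row <= nrow(src$values)
  out <- matrix(NA_real_, nr, nc)
  if (any(ok_r) && any(ok_c)) {
    out[ok_r, ok_c] <- src$values[src_row[ok_r], src_col[ok_c], drop = FALSE]
  }
  grid_like(template, out)
}
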