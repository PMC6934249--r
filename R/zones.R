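#' Build a zone set (census units with polygon geometries)
#'
#' A zone set is a tibble with one row per census zone: a stable character
#' `zone_id`, a polygon/multipolygon `geometry` (see [geom_area_ha()] for
#' the representation) and the derived `area_ha`. Zone ids must be unique;
#' geometries are assumed valid and mutually non-overlapping.
#'
#' @param zone_id Character vector of unique zone identifiers.
#' @param geometry List of geometries, one per zone.
#' @param crs CRS label; must match the grids the zones are used with.
#' @return A tibble of class `zone_set` with attribute `crs`.
#' @export
zone_set <- function(zone_id, geometry, crs = "local-metric") {
  zone_id <- as.character(zone_id)
  if (length(zone_id) == 0) stop("empty zone set", call. = FALSE)
  if (anyDuplicated(zone_id)) stop("zone ids must be unique", call. = FALSE)
  if (length(geometry) != length(zone_id)) {
    stop("`geometry` must have one element per zone", call. = FALSE)
  }
  area <- vapply(geometry, geom_area_ha, numeric(1))
  if (any(area <= 0)) {
    stop("every zone must have positive area", call. = FALSE)
  }
  out <- tibble::tibble(zone_id = zone_id, geometry = geometry,
                        area_ha = area)
  attr(out, "crs") <- crs
  class(out) <- c("zone_set", class(out))
  out
}

zone_crs <- function(zones) attr(zones, "crs") %||% "local-metric"

check_zone_grid <- function(zones, grid) {
  if (!identical(zone_crs(zones), grid$crs)) {
    stop("zones and grid are in different CRS", call. = FALSE)
  }
  invisible(TRUE)
}

#' Rasterize zones onto a grid by the cell-centre rule
#'
#' Each cell is assigned to the zone whose polygon contains the cell's
#' centre. Membership is boundary-inclusive; a centre lying exactly on a
#' shared boundary goes to the zone with the lexicographically smallest
#' `zone_id` (a deterministic tie-break). Cells inside no zone get `NA`.
#'
#' @param zones A [zone_set()].
#' @param grid An `mg_grid` supplying the cell geometry.
#' @return An integer matrix of row indices into `zones` (NA = no zone).
#' @export
rasterize_zones <- function(zones, grid) {
  check_zone_grid(zones, grid)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cx <- col_x(grid); cy <- row_y(grid)
  lab <- matrix(NA_integer_, nr, nc)
  cs <- grid$cell_size_m
  for (zi in order(zones$zone_id, method = "radix")) {
    geom <- zones$geometry[[zi]]
    bb <- geom_bbox(geom)
    cols <- which(cx >= bb["xmin"] - cs & cx <= bb["xmax"] + cs)
    rows <- which(cy >= bb["ymin"] - cs & cy <= bb["ymax"] + cs)
    if (!length(cols) || !length(rows)) next
    sub <- lab[rows, cols, drop = FALSE]
    open <- which(is.na(sub))
    if (!length(open)) next
    pr <- rows[(open - 1L) %% length(rows) + 1L]
    pc <- cols[(open - 1L) %/% length(rows) + 1L]
    hit <- point_in_geom(cx[pc], cy[pr], geom)
    if (any(hit)) lab[cbind(pr[hit], pc[hit])] <- zi
  }
  lab
}

#' Zonal mean of a grid over polygons
#'
#' For each zone, the arithmetic mean of grid values at cells whose
#' centres fall inside the zone polygon (cell-centre rule), excluding
#' nodata cells. Zones containing no valid cell centre get `NA`.
#'
#' @param grid An `mg_grid`.
#' @param zones A [zone_set()] in the same CRS.
#' @param labels Optional precomputed [rasterize_zones()] matrix, to reuse
#'   one rasterization across several layers.
#' @return A tibble with `zone_id` and `value`.
#' @export
zonal_mean <- function(grid, zones, labels = NULL) {
  if (is.null(zones) || nrow(zones) == 0) stop("empty zone set", call. = FALSE)
  if (is.null(labels)) labels <- rasterize_zones(zones, grid)
  v <- as.vector(grid$values)
  l <- as.vector(labels)
  ok <- !is.na(v) & !is.na(l)
  sums <- rep(0, nrow(zones)); cnts <- rep(0L, nrow(zones))
  if (any(ok)) {
    t_s <- tapply(v[ok], l[ok], sum)
    t_n <- tapply(v[ok], l[ok], length)
    idx <- as.integer(names(t_s))
    sums[idx] <- t_s; cnts[idx] <- t_n
  }
  tibble::tibble(zone_id = zones$zone_id,
                 value = ifelse(cnts > 0, sums / cnts, NA_real_))
}

# per-zone sum of grid values (nodata excluded); shares the label matrix
zonal_sum <- function(grid, zones, labels = NULL) {
  if (is.null(labels)) labels <- rasterize_zones(zones, grid)
  v <- as.vector(grid$values)
  l <- as.vector(labels)
  ok <- !is.na(v) & !is.na(l)
  sums <- rep(0, nrow(zones))
  if (any(ok)) {
    t_s <- tapply(v[ok], l[ok], sum)
    sums[as.integer(names(t_s))] <- t_s
  }
  tibble::tibble(zone_id = zones$zone_id, value = sums)
}

#' Create an aligned covariate stack
#'
#' An ordered, named collection of grids sharing one georeference.
#'
#' @param ... Named `mg_grid` layers, or a single named list of them.
#' @return A list of class `mg_stack`.
#' @export
grid_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1 && is.list(layers[[1]]) &&
      !inherits(layers[[1]], "mg_grid")) {
    layers <- layers[[1]]
  }
  if (length(layers) == 0) stop("empty covariate stack", call. = FALSE)
  nm <- names(layers)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm)) {
    stop("layers must have unique, non-empty names", call. = FALSE)
  }
  for (l in layers) stopifnot(inherits(l, "mg_grid"))
  for (l in layers[-1]) stop_if_misaligned(layers[[1]], l, "stack layers")
  structure(layers, class = "mg_stack")
}

#' @export
print.mg_stack <- function(x, ...) {
  g <- x[[1]]
  cat(sprintf("<mg_stack> %d layers, %d x %d cells @ %g m: %s\n",
              length(x), nrow(g$values), ncol(g$values), g$cell_size_m,
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Zonal means for every layer of a stack
#'
#' @param stack An [grid_stack()].
#' @param zones A [zone_set()].
#' @return A tibble with `zone_id` and one column per layer.
#' @export
zonal_means_stack <- function(stack, zones) {
  labels <- rasterize_zones(zones, stack[[1]])
  out <- tibble::tibble(zone_id = zones$zone_id)
  for (nm in names(stack)) {
    out[[nm]] <- zonal_mean(stack[[nm]], zones, labels = labels)$value
  }
  out
}
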