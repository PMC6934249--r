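# Plain-text I/O: ESRI ASCII grids, GeoJSON zones, counts CSV.

#' Read and write single-band rasters as ESRI ASCII grids
#'
#' The ESRI ASCII grid (`.asc`) is a plain-text single-band raster format
#' with an explicit NODATA tag; cells are written row by row from the
#' north. Only square-cell, axis-aligned grids are supported.
#'
#' @param path File path.
#' @param crs CRS label to attach on read (the format itself carries none).
#' @param g An `mg_grid` to write.
#' @return `read_ascii_grid()` returns an `mg_grid`;
#'   `write_ascii_grid()` returns `path` invisibly.
#' @export
read_ascii_grid <- function(path, crs = "local-metric") {
  lines <- readLines(path, n = 6)
  hdr <- list()
  for (l in lines) {
    kv <- strsplit(trimws(l), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("not an ESRI ASCII grid: missing header fields", call. = FALSE)
  }
  nodata <- hdr[["nodata_value"]] %||% -9999
  body <- scan(path, skip = length(hdr), quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(body) != nr * nc) stop("corrupt ASCII grid body", call. = FALSE)
  vals <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  vals[vals == nodata] <- NA_real_
  mg_grid(vals, xmin = hdr$xllcorner,
          ymax = hdr$yllcorner + nr * hdr$cellsize,
          cell_size_m = hdr$cellsize, crs = crs, nodata = nodata)
}

#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(g, path) {
  stopifnot(inherits(g, "mg_grid"))
  v <- g$values
  v[is.na(v)] <- g$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", g$xmin),
    sprintf("yllcorner %.10g", grid_ymin(g)),
    sprintf("cellsize %.10g", g$cell_size_m),
    sprintf("NODATA_value %.10g", g$nodata)
  )
  body <- apply(v, 1, function(r) paste(format(r, trim = TRUE, digits = 15),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

ring_to_coords <- function(ring) {
  closed <- rbind(ring, ring[1, , drop = FALSE])
  lapply(seq_len(nrow(closed)), function(i) as.numeric(closed[i, ]))
}

coords_to_ring <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(p) as.numeric(p[1:2])))
  # drop the closing vertex GeoJSON requires
  if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  m
}

geom_to_geojson <- function(geom) {
  parts <- lapply(geom, function(part) lapply(part, ring_to_coords))
  if (length(parts) == 1) {
    list(type = "Polygon", coordinates = parts[[1]])
  } else {
    list(type = "MultiPolygon", coordinates = parts)
  }
}

geojson_to_geom <- function(gj) {
  if (gj$type == "Polygon") {
    list(lapply(gj$coordinates, coords_to_ring))
  } else if (gj$type == "MultiPolygon") {
    lapply(gj$coordinates, function(part) lapply(part, coords_to_ring))
  } else {
    stop("unsupported geometry type: ", gj$type, call. = FALSE)
  }
}

#' Read and write zone polygons as GeoJSON
#'
#' Zones are stored as a FeatureCollection of Polygon/MultiPolygon
#' features with a `zone_id` property. Coordinates are taken verbatim (no
#' reprojection); attach the CRS label through `crs`.
#'
#' @param path File path.
#' @param crs CRS label to attach on read.
#' @param zones A [zone_set()] to write.
#' @return `read_zones_geojson()` returns a [zone_set()].
#' @export
read_zones_geojson <- function(path, crs = "local-metric") {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(fc$features)) stop("not a GeoJSON FeatureCollection", call. = FALSE)
  ids <- vapply(fc$features, function(f) {
    as.character(f$properties$zone_id %||% f$properties[[1]])
  }, character(1))
  geoms <- lapply(fc$features, function(f) geojson_to_geom(f$geometry))
  zone_set(ids, geoms, crs = crs)
}

#' @rdname read_zones_geojson
#' @export
write_zones_geojson <- function(zones, path) {
  feats <- lapply(seq_len(nrow(zones)), function(i) {
    list(type = "Feature",
         properties = list(zone_id = zones$zone_id[i],
                           area_ha = zones$area_ha[i]),
         geometry = geom_to_geojson(zones$geometry[[i]]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write settlements or agglomerations as GeoJSON
#'
#' Settlement features carry `settlement_id`, `area_ha`, `population` and
#' `cell_count`; agglomeration features carry `ma_id`, `population`,
#' `area_ha`, `density_per_ha`, `size_class` and member settlement ids.
#'
#' @param x A settlement or agglomeration tibble with a `geometry`
#'   list-column.
#' @param path File path.
#' @export
write_features_geojson <- function(x, path) {
  keep <- setdiff(names(x), c("geometry", "cells", "members"))
  feats <- lapply(seq_len(nrow(x)), function(i) {
    props <- lapply(keep, function(nm) {
      v <- x[[nm]][i]
      if (is.factor(v)) as.character(v) else v
    })
    names(props) <- keep
    if ("members" %in% names(x)) props$members <- x$members[[i]]
    list(type = "Feature", properties = props,
         geometry = geom_to_geojson(x$geometry[[i]]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read zone population counts from CSV
#'
#' Accepts either long form (`zone_id, year, count`) or wide form
#' (`zone_id` plus one column per year, e.g. `2001, 2011`); returns the
#' long form used throughout the package.
#'
#' @param path CSV file path.
#' @return A tibble with `zone_id` (character), `year` (integer) and
#'   `count` (numeric, nonnegative).
#' @export
read_counts_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (all(c("zone_id", "year", "count") %in% names(df))) {
    out <- dplyr::transmute(df, zone_id = as.character(.data$zone_id),
                            year = as.integer(.data$year),
                            count = as.numeric(.data$count))
  } else {
    out <- tidyr::pivot_longer(df, -"zone_id", names_to = "year",
                               values_to = "count")
    out <- dplyr::transmute(out, zone_id = as.character(.data$zone_id),
                            year = as.integer(.data$year),
                            count = as.numeric(.data$count))
  }
  if (any(is.na(out$count)) || any(out$count < 0)) {
    stop("counts must be nonnegative and complete", call. = FALSE)
  }
  out
}

# counts for one year as a vector aligned with zones; errors if missing
counts_for_year <- function(counts, zones, year) {
  cc <- counts[counts$year == year, , drop = FALSE]
  m <- match(zones$zone_id, cc$zone_id)
  if (anyNA(m)) {
    stop("missing counts for year ", year, " in zones: ",
         paste(utils::head(zones$zone_id[is.na(m)], 5), collapse = ", "),
         call. = FALSE)
  }
  n <- cc$count[m]
  if (any(n < 0)) stop("negative census count", call. = FALSE)
  n
}

#' Write a proximity graph as an edge-list CSV
#'
#' @param graph A [build_proximity_graph()] result.
#' @param path File path.
#' @export
write_graph_csv <- function(graph, path) {
  readr::write_csv(graph$edges, path)
  invisible(path)
}
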