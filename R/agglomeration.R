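#' Select cells above the urban density threshold
#'
#' Marks cells whose population density (persons/ha) reaches the
#' threshold. The comparison is `>=` by default (the threshold is read as
#' a minimum density); set `strict = TRUE` for a strictly-above rule.
#' Nodata cells are never selected.
#'
#' @param pop A `population_grid` of persons per cell (or any `mg_grid`
#'   already in persons/ha if `is_density = TRUE`).
#' @param tau_per_ha Density threshold in persons per hectare; the
#'   pipeline default is 7.5, with 5 and 10 as sensitivity settings.
#' @param strict Use `>` instead of `>=`.
#' @param is_density Treat `pop` values as persons/ha directly.
#' @return A binary `mg_grid` (1 = selected, 0 = not).
#' @export
threshold_cells <- function(pop, tau_per_ha, strict = FALSE,
                            is_density = FALSE) {
  stopifnot(tau_per_ha > 0)
  dens <- if (is_density) pop$values else pop$values / cell_area_ha(pop)
  sel <- if (strict) dens > tau_per_ha else dens >= tau_per_ha
  sel[is.na(sel)] <- FALSE
  grid_like(pop, matrix(as.numeric(sel), nrow(dens), ncol(dens)))
}

# neighbour offsets (row, col) for rook/queen adjacency
conn_offsets <- function(connectivity) {
  if (connectivity == 4) {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  } else if (connectivity == 8) {
    cbind(dr = rep(c(-1L, 0L, 1L), times = 3),
          dc = rep(c(-1L, 0L, 1L), each = 3))[-5, ]
  } else {
    stop("connectivity must be 4 or 8", call. = FALSE)
  }
}

#' Label connected regions of a binary grid
#'
#' Maximal connected components of selected cells under rook (4) or queen
#' (8) adjacency. Labels are assigned in row-major order of each region's
#' first (top-left) cell, a deterministic convention.
#'
#' @param binary A binary `mg_grid` (nonzero = selected).
#' @param connectivity 4 (rook, the default) or 8 (queen).
#' @return List: `labels` (integer matrix, `NA` outside regions), `n`
#'   (number of regions), `grid` (the input georeference).
#' @export
label_regions <- function(binary, connectivity = 4) {
  v <- binary$values
  nr <- nrow(v); nc <- ncol(v)
  sel <- !is.na(v) & v != 0
  offs <- conn_offsets(connectivity)
  lab <- matrix(NA_integer_, nr, nc)
  nlab <- 0L
  # row-major scan of seeds
  seeds <- which(t(sel))
  seeds <- (seeds - 1L) %/% nc + 1L + ((seeds - 1L) %% nc) * nr
  for (k0 in seeds) {
    if (!is.na(lab[k0])) next
    nlab <- nlab + 1L
    lab[k0] <- nlab
    frontier <- k0
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      c <- (frontier - 1L) %/% nr + 1L
      nxt <- integer(0)
      for (i in seq_len(nrow(offs))) {
        rr <- r + offs[i, 1L]; cc <- c + offs[i, 2L]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        if (!any(ok)) next
        kk <- rr[ok] + (cc[ok] - 1L) * nr
        kk <- kk[sel[kk] & is.na(lab[kk])]
        if (length(kk)) {
          kk <- unique(kk)
          lab[kk] <- nlab
          nxt <- c(nxt, kk)
        }
      }
      frontier <- nxt
    }
  }
  list(labels = lab, n = nlab, grid = binary)
}

# Trace the boundary rings of a cell set (linear matrix indices) on a
# grid. Returns a list of rings (n x 2 coordinate matrices); the exterior
# ring is the one with the largest absolute area, interior rings are
# holes. Edges are oriented with the region on the left, so the exterior
# comes out counter-clockwise.
trace_rings <- function(cells, grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cs <- grid$cell_size_m
  inset <- matrix(FALSE, nr, nc)
  inset[cells] <- TRUE
  r <- (cells - 1L) %% nr + 1L
  c <- (cells - 1L) %/% nr + 1L
  inb <- function(rr, cc) rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
  nbr_out <- function(rr, cc) {
    ok <- inb(rr, cc)
    out <- rep(TRUE, length(rr))
    out[ok] <- !inset[cbind(rr[ok], cc[ok])]
    out
  }
  # corner key for corner-row cr in 0..nr, corner-col cc in 0..nc
  ckey <- function(cr, cc) cr * (nc + 1L) + cc + 1L
  # directed boundary edges, region on the left (exterior CCW in x/y)
  from <- integer(0); to <- integer(0)
  add <- function(f, t) { from <<- c(from, f); to <<- c(to, t) }
  b <- nbr_out(r + 1L, c); add(ckey(r[b], c[b] - 1L), ckey(r[b], c[b]))        # bottom: BL->BR
  b <- nbr_out(r, c + 1L); add(ckey(r[b], c[b]), ckey(r[b] - 1L, c[b]))        # right:  BR->TR
  b <- nbr_out(r - 1L, c); add(ckey(r[b] - 1L, c[b]), ckey(r[b] - 1L, c[b] - 1L)) # top: TR->TL
  b <- nbr_out(r, c - 1L); add(ckey(r[b] - 1L, c[b] - 1L), ckey(r[b], c[b] - 1L)) # left: TL->BL
  m <- length(from)
  used <- rep(FALSE, m)
  # out-edges indexed by start vertex
  ord <- order(from)
  starts <- from[ord]
  first <- match(unique(starts), starts)
  outidx <- split(ord, from[ord])
  key_xy <- function(k) {
    k0 <- k - 1L
    cc <- k0 %% (nc + 1L); cr <- k0 %/% (nc + 1L)
    cbind(x = grid$xmin + cc * cs, y = grid$ymax - cr * cs)
  }
  dir_of <- function(e) {
    a <- key_xy(from[e]); b <- key_xy(to[e])
    cbind(b[, 1] - a[, 1], b[, 2] - a[, 2])
  }
  rings <- list()
  for (e0 in seq_len(m)) {
    if (used[e0]) next
    ring_keys <- integer(0)
    e <- e0
    repeat {
      used[e] <- TRUE
      ring_keys <- c(ring_keys, from[e])
      v <- to[e]
      cand <- outidx[[as.character(v)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      if (length(cand) == 1L) {
        e <- cand
      } else {
        # pinch vertex: take the sharpest left turn to keep rings simple
        d_in <- dir_of(e)
        d_out <- dir_of(cand)
        cross <- d_in[1] * d_out[, 2] - d_in[2] * d_out[, 1]
        dot <- d_in[1] * d_out[, 1] + d_in[2] * d_out[, 2]
        ang <- atan2(cross, dot)
        e <- cand[which.max(ang)]
      }
    }
    rings[[length(rings) + 1L]] <- key_xy(ring_keys)
  }
  rings
}

# Collapse collinear runs in a ring (cell tracing emits unit steps)
simplify_ring <- function(ring) {
  n <- nrow(ring)
  if (n <= 4) return(ring)
  prev <- rbind(ring[n, ], ring[-n, ])
  nxt <- rbind(ring[-1, ], ring[1, ])
  cross <- (ring[, 1] - prev[, 1]) * (nxt[, 2] - ring[, 2]) -
    (ring[, 2] - prev[, 2]) * (nxt[, 1] - ring[, 1])
  keep <- abs(cross) > 1e-9
  if (!any(keep)) return(ring)
  ring[keep, , drop = FALSE]
}

#' Delineate settlements from a population grid
#'
#' The first stages of the agglomeration pipeline: threshold the density
#' surface, group contiguous selected cells into regions, fill each
#' region's holes (every cell whose centre lies inside the region's
#' exterior ring belongs to it; regions completely enclosed in another
#' region's hole are absorbed by it), drop regions smaller than the
#' minimum area, and integrate population over the filled extent —
#' including below-threshold cells inside former holes.
#'
#' @param pop A `population_grid`.
#' @param tau_per_ha Density threshold (persons/ha), default 7.5.
#' @param min_area_ha Minimum settlement area after hole filling; regions
#'   strictly below it are removed. Default 2 ha (about two cells).
#' @param connectivity Region-grouping adjacency, 4 (default) or 8.
#' @param strict_threshold Use `>` instead of `>=` at the threshold.
#' @return A tibble of settlements: `settlement_id`, `cell_count`,
#'   `area_ha`, `population`, plus list-columns `cells` (linear cell
#'   indices of the filled extent) and `geometry` (hole-free polygon).
#' @export
delineate_settlements <- function(pop, tau_per_ha = 7.5, min_area_ha = 2,
                                  connectivity = 4,
                                  strict_threshold = FALSE) {
  binary <- threshold_cells(pop, tau_per_ha, strict = strict_threshold)
  lab <- label_regions(binary, connectivity = connectivity)
  nr <- nrow(pop$values); nc <- ncol(pop$values)
  if (lab$n == 0) {
    return(tibble::tibble(settlement_id = integer(0), cell_count = integer(0),
                          area_ha = numeric(0), population = numeric(0),
                          cells = list(), geometry = list()))
  }
  regions <- split(which(!is.na(lab$labels)),
                   lab$labels[!is.na(lab$labels)])
  # exterior ring and filled cell set per region
  ext <- vector("list", lab$n)
  filled <- vector("list", lab$n)
  for (i in seq_len(lab$n)) {
    cells <- regions[[i]]
    rings <- trace_rings(cells, pop)
    areas <- vapply(rings, function(rg) abs(ring_area_signed(rg)), numeric(1))
    ring <- simplify_ring(rings[[which.max(areas)]])
    ext[[i]] <- ring
    if (length(rings) == 1L) {
      filled[[i]] <- cells
    } else {
      bb <- geom_bbox(list(list(ring)))
      cols <- which(col_x(pop) > bb["xmin"] & col_x(pop) < bb["xmax"])
      rows <- which(row_y(pop) > bb["ymin"] & row_y(pop) < bb["ymax"])
      pr <- rep(rows, times = length(cols))
      pc <- rep(cols, each = length(rows))
      hit <- pip_ring(col_x(pop, pc), row_y(pop, pr), ring)$inside
      filled[[i]] <- sort(pr[hit] + (pc[hit] - 1L) * nr)
    }
  }
  # ownership: largest regions claim first; a region whose selected cells
  # were all claimed by an encloser is absorbed into it
  sizes <- lengths(regions)
  ord <- order(-sizes, seq_along(sizes))
  owner <- integer(nr * nc)
  keep <- logical(lab$n)
  for (i in ord) {
    if (all(owner[regions[[i]]] != 0L)) next   # absorbed
    keep[i] <- TRUE
    cl <- filled[[i]]
    cl <- cl[owner[cl] == 0L]
    owner[cl] <- i
    filled[[i]] <- cl
  }
  idx <- which(keep)
  persons <- as.vector(pop$values)
  persons[is.na(persons)] <- 0
  out <- tibble::tibble(
    cells = filled[idx],
    geometry = lapply(ext[idx], function(rg) list(list(rg)))
  )
  out$cell_count <- lengths(out$cells)
  out$area_ha <- out$cell_count * cell_area_ha(pop)
  out$population <- vapply(out$cells, function(cl) sum(persons[cl]),
                           numeric(1))
  out <- filter_min_area(out, min_area_ha)
  # ids in row-major order of each region's top-left cell
  top_left <- vapply(out$cells, function(cl) {
    r <- (cl - 1L) %% nr + 1L; c <- (cl - 1L) %/% nr + 1L
    min(r) * (nc + 1) + min(c[r == min(r)])
  }, numeric(1))
  out <- out[order(top_left), ]
  out$settlement_id <- seq_len(nrow(out))
  out[, c("settlement_id", "cell_count", "area_ha", "population",
          "cells", "geometry")]
}

#' Drop settlements below the minimum area
#'
#' Keeps polygons whose hole-filled area reaches `min_area_ha`; strictly
#' smaller ones are removed as gridding noise.
#'
#' @param settlements A settlement tibble with an `area_ha` column.
#' @param min_area_ha Minimum area in hectares (default 2).
#' @return The filtered tibble.
#' @export
filter_min_area <- function(settlements, min_area_ha = 2) {
  settlements[settlements$area_ha >= min_area_ha, , drop = FALSE]
}

#' Integrate population over polygons
#'
#' Sums persons at cells whose centres fall inside each geometry
#' (boundary-inclusive cell-centre rule). For pipeline settlements the
#' stored filled cell set is used directly, which is identical to the
#' point-in-polygon evaluation of the hole-free geometry.
#'
#' @param x A settlement tibble (with `cells` or `geometry` list-column)
#'   or a bare list of geometries.
#' @param pop A `population_grid`.
#' @return For tibbles, the tibble with a refreshed `population` column;
#'   for geometry lists, a numeric vector of populations.
#' @export
integrate_population <- function(x, pop) {
  persons <- as.vector(pop$values)
  persons[is.na(persons)] <- 0
  nr <- nrow(pop$values)
  geom_pop <- function(geom) {
    bb <- geom_bbox(geom)
    cols <- which(col_x(pop) > bb["xmin"] & col_x(pop) < bb["xmax"])
    rows <- which(row_y(pop) > bb["ymin"] & row_y(pop) < bb["ymax"])
    if (!length(cols) || !length(rows)) return(0)
    pr <- rep(rows, times = length(cols))
    pc <- rep(cols, each = length(rows))
    hit <- point_in_geom(col_x(pop, pc), row_y(pop, pr), geom)
    sum(persons[pr[hit] + (pc[hit] - 1L) * nr])
  }
  if (is.data.frame(x)) {
    if (!is.null(x$cells)) {
      x$population <- vapply(x$cells, function(cl) sum(persons[cl]),
                             numeric(1))
    } else {
      x$population <- vapply(x$geometry, geom_pop, numeric(1))
    }
    x
  } else {
    vapply(x, geom_pop, numeric(1))
  }
}

# boundary cells of a settlement: at least one rook neighbour outside
boundary_cells <- function(cells, nr, nc) {
  inset <- logical(nr * nc)
  inset[cells] <- TRUE
  r <- (cells - 1L) %% nr + 1L
  c <- (cells - 1L) %/% nr + 1L
  on_b <- r == 1L | r == nr | c == 1L | c == nc
  for (off in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    rr <- pmin(pmax(r + off[1], 1L), nr)
    cc <- pmin(pmax(c + off[2], 1L), nc)
    on_b <- on_b | !inset[rr + (cc - 1L) * nr]
  }
  cells[on_b]
}

# minimum distance between two sets of cell squares (exact for unions of
# closed axis-aligned squares)
min_cell_distance <- function(cells_a, cells_b, nr, cs) {
  ra <- (cells_a - 1L) %% nr + 1L; ca <- (cells_a - 1L) %/% nr + 1L
  rb <- (cells_b - 1L) %% nr + 1L; cb <- (cells_b - 1L) %/% nr + 1L
  dx <- pmax(abs(outer(ca, cb, "-")) - 1L, 0) * cs
  dy <- pmax(abs(outer(ra, rb, "-")) - 1L, 0) * cs
  sqrt(min(dx * dx + dy * dy))
}

#' Build the settlement proximity graph
#'
#' One vertex per settlement; an undirected edge joins two settlements
#' when the minimum Euclidean distance between their boundaries is
#' strictly below `d_max_m`. Touching settlements (distance 0) are always
#' connected. The default 150 m is roughly one cell diagonal, so the
#' graph approximates queen contiguity with one cell skipped over.
#'
#' @param settlements A [delineate_settlements()] tibble.
#' @param pop The `population_grid` (or any aligned `mg_grid`) the
#'   settlements were delineated on, supplying the cell geometry.
#' @param d_max_m Distance threshold in metres (default 150, strict `<`).
#' @return A `proximity_graph`: list with `vertices` (settlement ids),
#'   `edges` (tibble `from`, `to`, `distance_m`) and `d_max_m`.
#' @export
build_proximity_graph <- function(settlements, pop, d_max_m = 150) {
  nr <- nrow(pop$values); nc <- ncol(pop$values)
  cs <- pop$cell_size_m
  n <- nrow(settlements)
  bnd <- lapply(settlements$cells, boundary_cells, nr = nr, nc = nc)
  bbox <- lapply(settlements$cells, function(cl) {
    r <- (cl - 1L) %% nr + 1L; c <- (cl - 1L) %/% nr + 1L
    c(min(r), max(r), min(c), max(c))
  })
  from <- integer(0); to <- integer(0); dist <- numeric(0)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        bi <- bbox[[i]]; bj <- bbox[[j]]
        gap_r <- max(0L, max(bi[1], bj[1]) - min(bi[2], bj[2]) - 1L)
        gap_c <- max(0L, max(bi[3], bj[3]) - min(bi[4], bj[4]) - 1L)
        if (sqrt(sum((c(gap_r, gap_c) * cs)^2)) >= d_max_m) next
        d <- min_cell_distance(bnd[[i]], bnd[[j]], nr, cs)
        if (d < d_max_m) {
          from <- c(from, settlements$settlement_id[i])
          to <- c(to, settlements$settlement_id[j])
          dist <- c(dist, d)
        }
      }
    }
  }
  proximity_graph(settlements$settlement_id,
                  tibble::tibble(from = from, to = to, distance_m = dist),
                  d_max_m = d_max_m)
}

#' Construct a proximity graph from vertices and edges
#'
#' @param vertices Integer vertex ids.
#' @param edges Tibble/data frame with `from` and `to` columns (and
#'   optionally `distance_m`); self-loops and duplicate edges are
#'   rejected.
#' @param d_max_m Distance threshold recorded on the object.
#' @return A `proximity_graph`.
#' @export
proximity_graph <- function(vertices, edges, d_max_m = NA_real_) {
  vertices <- as.integer(vertices)
  edges <- tibble::as_tibble(edges)
  if (nrow(edges)) {
    if (any(edges$from == edges$to)) stop("self-loops not allowed", call. = FALSE)
    if (!all(edges$from %in% vertices) || !all(edges$to %in% vertices)) {
      stop("edge endpoints must be vertices", call. = FALSE)
    }
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    if (anyDuplicated(key)) stop("duplicate edges", call. = FALSE)
  }
  structure(list(vertices = vertices, edges = edges, d_max_m = d_max_m),
            class = "proximity_graph")
}

#' @export
print.proximity_graph <- function(x, ...) {
  cat(sprintf("<proximity_graph> %d vertices, %d edges (d_max %g m)\n",
              length(x$vertices), nrow(x$edges), x$d_max_m))
  invisible(x)
}
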