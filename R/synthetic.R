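#' Specify a synthetic landscape
#'
#' Parameters of the fully synthetic scenes used to exercise the whole
#' pipeline without external data: a density surface built from Gaussian
#' settlement kernels over a low rural background, covariates correlated
#' with the true surface, a random uninhabitable mask, and a recursive
#' rectangle tessellation of census districts whose integer counts
#' integrate the true surface exactly.
#'
#' Defaults describe a landscape in the pipeline's working units: 100 m
#' cells (1 ha), a rural background of 0.2 persons/ha, settlement peaks of
#' 20-60 persons/ha (well above the 7.5 pp/ha urban threshold) with decay
#' lengths of 200-500 m, 5% uninhabitable cells, and moderate covariate
#' noise. Overlapping medium kernels emulate coalescent settlement belts;
#' isolated tall kernels emulate concentrated urban cores.
#'
#' @param n_rows,n_cols Grid shape in cells.
#' @param cell_size_m Cell edge (metres).
#' @param n_districts Number of census districts.
#' @param settlements Optional tibble `x`, `y`, `peak`, `decay_m`
#'   (persons/ha and metres); when `NULL`, `n_settlements` kernels are
#'   drawn uniformly over the grid at generation time.
#' @param n_settlements Number of kernels drawn when `settlements` is
#'   `NULL`.
#' @param peak_range,decay_range Ranges the kernel peaks (persons/ha) and
#'   decay lengths (m) are drawn from.
#' @param background_density Rural background density (persons/ha).
#' @param covariate_noise_sd SD of the noise on the noisy covariate.
#' @param mask_fraction Fraction of cells made uninhabitable.
#' @param seed Integer seed; the spec plus seed fully determine the scene.
#' @param year Census year label attached to the counts.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(n_rows = 80, n_cols = 80, cell_size_m = 100,
                       n_districts = 16, settlements = NULL,
                       n_settlements = 10, peak_range = c(20, 60),
                       decay_range = c(200, 500),
                       background_density = 0.2,
                       covariate_noise_sd = 0.3, mask_fraction = 0.05,
                       seed = 1L, year = 2011L) {
  if (background_density < 0) stop("background density must be >= 0", call. = FALSE)
  if (min(peak_range) <= background_density) {
    stop("peak densities must exceed the background", call. = FALSE)
  }
  structure(list(n_rows = n_rows, n_cols = n_cols, cell_size_m = cell_size_m,
                 n_districts = n_districts, settlements = settlements,
                 n_settlements = n_settlements, peak_range = peak_range,
                 decay_range = decay_range,
                 background_density = background_density,
                 covariate_noise_sd = covariate_noise_sd,
                 mask_fraction = mask_fraction, seed = as.integer(seed),
                 year = as.integer(year)),
            class = "scene_spec")
}

# recursive rectangle tessellation: repeatedly split the largest rectangle
# along its longer axis at a random interior fraction
split_rects <- function(n, xmin, xmax, ymin, ymax) {
  rects <- list(c(xmin, xmax, ymin, ymax))
  while (length(rects) < n) {
    areas <- vapply(rects, function(r) (r[2] - r[1]) * (r[4] - r[3]),
                    numeric(1))
    i <- which.max(areas)
    r <- rects[[i]]
    f <- stats::runif(1, 0.35, 0.65)
    if (r[2] - r[1] >= r[4] - r[3]) {
      cut <- r[1] + f * (r[2] - r[1])
      new <- list(c(r[1], cut, r[3], r[4]), c(cut, r[2], r[3], r[4]))
    } else {
      cut <- r[3] + f * (r[4] - r[3])
      new <- list(c(r[1], r[2], r[3], cut), c(r[1], r[2], cut, r[4]))
    }
    rects <- c(rects[-i], new)
  }
  rects
}

# integer counts by the largest-remainder rule: totals match round(sum)
largest_remainder <- function(raw) {
  fl <- floor(raw)
  rem <- round(sum(raw)) - sum(fl)
  if (rem > 0) {
    top <- order(raw - fl, decreasing = TRUE)[seq_len(rem)]
    fl[top] <- fl[top] + 1
  }
  fl
}

district_zone_set <- function(n_districts, grid) {
  rects <- split_rects(n_districts, grid$xmin, grid_xmax(grid),
                       grid_ymin(grid), grid$ymax)
  zone_set(sprintf("D%03d", seq_along(rects)),
           lapply(rects, function(r) list(list(rect_ring(r[1], r[3],
                                                         r[2], r[4])))),
           crs = grid$crs)
}

finish_scene <- function(spec, grid, density, habitable, extra = list()) {
  density[!habitable] <- 0
  dens_grid <- grid_like(grid, density)
  persons <- density * cell_area_ha(grid)
  pop <- grid_like(grid, persons)
  class(pop) <- c("population_grid", class(pop))
  mask <- grid_like(grid, matrix(as.numeric(habitable), nrow(density),
                                 ncol(density)))
  zones <- district_zone_set(spec$n_districts, grid)
  labels <- rasterize_zones(zones, grid)
  sums <- zonal_sum(pop, zones, labels = labels)$value
  counts <- tibble::tibble(zone_id = zones$zone_id, year = spec$year,
                           count = largest_remainder(sums))
  eps0 <- 0.01
  noiseless <- log(density + eps0)
  noisy <- noiseless + stats::rnorm(length(density),
                                    sd = spec$covariate_noise_sd)
  irrelevant <- stats::rnorm(length(density), mean = 300, sd = 50)
  stack <- grid_stack(
    settlement_index = grid_like(grid, noiseless),
    lights = grid_like(grid, matrix(noisy, nrow(density), ncol(density))),
    elevation = grid_like(grid, matrix(irrelevant, nrow(density),
                                       ncol(density)))
  )
  out <- c(list(spec = spec, density = dens_grid, population = pop,
                mask = mask, stack = stack, zones = zones,
                counts = counts, district_labels = labels),
           extra)
  class(out) <- "synthetic_scene"
  out
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %d x %d cells, %d districts, total population %d\n",
    x$spec$n_rows, x$spec$n_cols, nrow(x$zones), sum(x$counts$count)))
  invisible(x)
}

#' Generate a synthetic landscape
#'
#' Builds the full set of pipeline inputs from a [scene_spec()]: the true
#' density surface (background plus Gaussian settlement kernels, zero on
#' uninhabitable cells), the true population grid, a three-layer
#' covariate stack (a noiseless transform of true log density, a noisy
#' correlate, and an irrelevant layer), the habitability mask, district
#' polygons, and integer census counts that integrate the true surface
#' (largest-remainder rounding, so the counts sum to the rounded total
#' exactly).
#'
#' @param spec A [scene_spec()].
#' @return A `synthetic_scene`: `spec`, `density`, `population`, `mask`,
#'   `stack`, `zones`, `counts`, `district_labels`, `settlements`.
#' @export
generate_landscape <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  nr <- spec$n_rows; nc <- spec$n_cols; cs <- spec$cell_size_m
  grid <- mg_grid(matrix(0, nr, nc), cell_size_m = cs)
  st <- spec$settlements
  if (is.null(st)) {
    st <- tibble::tibble(
      x = stats::runif(spec$n_settlements, 0, grid_xmax(grid)),
      y = stats::runif(spec$n_settlements, 0, grid$ymax),
      peak = stats::runif(spec$n_settlements, spec$peak_range[1],
                          spec$peak_range[2]),
      decay_m = stats::runif(spec$n_settlements, spec$decay_range[1],
                             spec$decay_range[2])
    )
  }
  if (any(st$x < grid$xmin | st$x > grid_xmax(grid) |
          st$y < grid_ymin(grid) | st$y > grid$ymax)) {
    stop("settlement centre outside grid", call. = FALSE)
  }
  cx <- col_x(grid); cy <- row_y(grid)
  density <- matrix(spec$background_density, nr, nc)
  for (i in seq_len(nrow(st))) {
    d2 <- outer((cy - st$y[i])^2, (cx - st$x[i])^2, "+")
    density <- density + st$peak[i] * exp(-d2 / (2 * st$decay_m[i]^2))
  }
  habitable <- matrix(stats::runif(nr * nc) >= spec$mask_fraction, nr, nc)
  finish_scene(spec, grid, density, habitable,
               extra = list(settlements = st))
}

#' Generate a planted-cluster scene with known agglomeration truth
#'
#' Plants `k_clusters` groups of dense rectangular settlement blobs on a
#' quiet background. Within a cluster, consecutive blobs are separated by
#' exactly one empty cell (100 m at the default resolution, under the
#' 150 m graph threshold), so the proximity graph chains them together;
#' clusters are separated by more than `gap_m`, so no edge can cross
#' between clusters. Clusters hold at most three blobs by default: a
#' chain of two or three vertices admits no modularity-increasing split,
#' so each planted cluster is guaranteed to survive community detection
#' as one unit (longer chains are exactly the tendrils the method is
#' designed to cut). Running the full delineation at the default
#' parameters therefore recovers the planted membership exactly.
#'
#' @param spec A [scene_spec()]; its grid shape, cell size, districts and
#'   seed are used. Blob densities are drawn from 15-40 persons/ha over a
#'   0.5 persons/ha background.
#' @param k_clusters Number of planted clusters.
#' @param gap_m Minimum separation between clusters (metres); must exceed
#'   the 150 m graph threshold.
#' @param blobs_per_cluster Range of blobs per cluster.
#' @param d_max_m The graph threshold the scene is built against.
#' @return A `synthetic_scene` with a `planted` tibble: `blob_id`,
#'   `cluster_id`, `cells`.
#' @export
generate_planted_clusters <- function(spec = scene_spec(), k_clusters = 3,
                                      gap_m = 600,
                                      blobs_per_cluster = c(2, 3),
                                      d_max_m = 150) {
  stopifnot(inherits(spec, "scene_spec"))
  if (gap_m <= d_max_m) {
    stop("cluster gap must exceed the graph distance threshold", call. = FALSE)
  }
  set.seed(spec$seed)
  nr <- spec$n_rows; nc <- spec$n_cols; cs <- spec$cell_size_m
  grid <- mg_grid(matrix(0, nr, nc), cell_size_m = cs)
  max_blob <- 4L
  max_blobs <- max(blobs_per_cluster)
  slot_w <- max_blobs * max_blob + (max_blobs - 1L) + 2L  # cells, with margin
  slot_h <- max_blob + 2L
  gap_cells <- as.integer(ceiling(gap_m / cs)) + 1L
  per_row <- (nc + gap_cells) %/% (slot_w + gap_cells)
  n_rows_slots <- (nr + gap_cells) %/% (slot_h + gap_cells)
  if (per_row < 1 || per_row * n_rows_slots < k_clusters) {
    stop("infeasible packing: grid too small for the requested clusters",
         call. = FALSE)
  }
  density <- matrix(0.5, nr, nc)
  blob_id <- integer(0); cluster_id <- integer(0); cells <- list()
  for (k in seq_len(k_clusters)) {
    slot_r <- (k - 1L) %/% per_row
    slot_c <- (k - 1L) %% per_row
    r0 <- 1L + slot_r * (slot_h + gap_cells) + sample.int(2L, 1) - 1L
    c0 <- 1L + slot_c * (slot_w + gap_cells) + sample.int(2L, 1) - 1L
    n_blobs <- sample(seq(blobs_per_cluster[1], blobs_per_cluster[2]), 1)
    cc <- c0
    for (b in seq_len(n_blobs)) {
      side <- sample(2:max_blob, 1)
      rows <- r0:(r0 + side - 1L)
      cols <- cc:(cc + side - 1L)
      density[rows, cols] <- stats::runif(1, 15, 40)
      cl <- as.vector(outer(rows, (cols - 1L) * nr, "+"))
      blob_id <- c(blob_id, length(blob_id) + 1L)
      cluster_id <- c(cluster_id, k)
      cells <- c(cells, list(sort(cl)))
      cc <- cc + side + 1L   # one empty cell between consecutive blobs
    }
  }
  habitable <- matrix(TRUE, nr, nc)
  finish_scene(spec, grid, density, habitable,
               extra = list(planted = tibble::tibble(
                 blob_id = blob_id, cluster_id = cluster_id,
                 cells = cells)))
}

#' Match planted blobs to delineated agglomerations
#'
#' For each planted blob, the agglomeration owning the majority of its
#' cells (`NA` if none). Comparing `cluster_id` with `ma_id` (e.g., by
#' adjusted Rand index) measures end-to-end recovery of the planted
#' structure.
#'
#' @param scene A [generate_planted_clusters()] scene.
#' @param delineation A [delineate_agglomerations()] result on the
#'   scene's population grid.
#' @return The scene's `planted` tibble with an `ma_id` column.
#' @export
planted_recovery <- function(scene, delineation) {
  mas <- delineation$agglomerations
  owner <- integer(length(scene$population$values))
  for (i in seq_len(nrow(mas))) owner[mas$cells[[i]]] <- mas$ma_id[i]
  out <- scene$planted
  out$ma_id <- vapply(out$cells, function(cl) {
    o <- owner[cl]
    o <- o[o != 0L]
    if (!length(o)) return(NA_integer_)
    as.integer(names(sort(table(o), decreasing = TRUE))[1])
  }, integer(1))
  out
}
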