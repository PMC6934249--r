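# Independent brute-force oracles used across the suite. These are
# deliberately naive re-derivations (scans, double loops, exhaustive
# enumeration) that share no code path with the package implementation.

# population grid from a density matrix (persons/ha)
pop_from_density <- function(dens, cell_size_m = 100) {
  g <- mg_grid(dens * cell_size_m^2 / 1e4, cell_size_m = cell_size_m)
  class(g) <- c("population_grid", class(g))
  g
}

# --- connected components: stack-based flood fill -----------------------
oracle_flood_components <- function(sel, connectivity = 4) {
  nr <- nrow(sel); nc <- ncol(sel)
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
         c(1, -1), c(1, 0), c(1, 1))
  }
  lab <- matrix(0L, nr, nc)
  nlab <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!sel[r0, c0] || lab[r0, c0] != 0L) next
    nlab <- nlab + 1L
    stack <- list(c(r0, c0))
    lab[r0, c0] <- nlab
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in offs) {
        r <- p[1] + o[1]; c <- p[2] + o[2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            sel[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nlab
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  list(labels = lab, n = nlab)
}

# two labelings describe the same partition of selected cells
same_partition <- function(lab_a, lab_b) {
  sel <- !is.na(lab_a) & lab_a != 0
  if (!identical(sel, !is.na(lab_b) & lab_b != 0)) return(FALSE)
  a <- lab_a[sel]; b <- lab_b[sel]
  !anyDuplicated(unique(cbind(a, b))[, 1]) &&
    !anyDuplicated(unique(cbind(a, b))[, 2])
}

# --- point in polygon: crossing number, written independently -----------
oracle_point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if (((yi > py) != (yj > py)) &&
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

oracle_point_in_geom <- function(px, py, geom) {
  inside <- FALSE
  for (part in geom) for (ring in part) {
    if (oracle_point_in_ring(px, py, ring)) inside <- !inside
  }
  inside
}

# zonal mean by scanning every cell centre against every zone polygon
oracle_zonal_mean <- function(grid, zones) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  sums <- numeric(nrow(zones)); cnt <- integer(nrow(zones))
  for (c in seq_len(nc)) for (r in seq_len(nr)) {
    v <- grid$values[r, c]
    if (is.na(v)) next
    x <- grid$xmin + (c - 0.5) * grid$cell_size_m
    y <- grid$ymax - (r - 0.5) * grid$cell_size_m
    for (z in seq_len(nrow(zones))) {
      if (oracle_point_in_geom(x, y, zones$geometry[[z]])) {
        sums[z] <- sums[z] + v
        cnt[z] <- cnt[z] + 1L
        break
      }
    }
  }
  ifelse(cnt > 0, sums / cnt, NA_real_)
}

# --- signed distance: all-pairs nearest-opposite scan -------------------
oracle_signed_distance <- function(values, target_class, cell_size_m) {
  nr <- nrow(values); nc <- ncol(values)
  valid <- !is.na(values)
  tgt <- valid & values == target_class
  out <- matrix(NA_real_, nr, nc)
  coords <- function(mask) which(mask, arr.ind = TRUE)
  tc <- coords(tgt); oc <- coords(valid & !tgt)
  for (c in seq_len(nc)) for (r in seq_len(nr)) {
    if (!valid[r, c]) next
    opp <- if (tgt[r, c]) oc else tc
    d <- sqrt(min((opp[, 1] - r)^2 + (opp[, 2] - c)^2)) * cell_size_m
    out[r, c] <- if (tgt[r, c]) -d else d
  }
  out
}

# --- nearest-neighbour resampling by per-cell containment search --------
oracle_resample <- function(src, template) {
  nr <- nrow(template$values); nc <- ncol(template$values)
  out <- matrix(NA_real_, nr, nc)
  css <- src$cell_size_m
  for (c in seq_len(nc)) for (r in seq_len(nr)) {
    x <- template$xmin + (c - 0.5) * template$cell_size_m
    y <- template$ymax - (r - 0.5) * template$cell_size_m
    for (sc in seq_len(ncol(src$values))) for (sr in seq_len(nrow(src$values))) {
      x0 <- src$xmin + (sc - 1) * css
      y1 <- src$ymax - (sr - 1) * css
      if (x >= x0 && x < x0 + css && y <= y1 && y > y1 - css) {
        out[r, c] <- src$values[sr, sc]
      }
    }
  }
  out
}

# --- minimum boundary distance: all-pairs over full cell sets -----------
oracle_min_distance <- function(cells_a, cells_b, nr, cell_size_m) {
  ra <- (cells_a - 1) %% nr + 1; ca <- (cells_a - 1) %/% nr + 1
  rb <- (cells_b - 1) %% nr + 1; cb <- (cells_b - 1) %/% nr + 1
  best <- Inf
  for (i in seq_along(cells_a)) {
    dx <- pmax(abs(ca[i] - cb) - 1, 0) * cell_size_m
    dy <- pmax(abs(ra[i] - rb) - 1, 0) * cell_size_m
    best <- min(best, min(sqrt(dx^2 + dy^2)))
  }
  best
}

# --- modularity: literal double-loop over the formula -------------------
oracle_modularity <- function(adj, membership) {
  n <- nrow(adj)
  m <- sum(adj) / 2
  k <- rowSums(adj)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (membership[i] == membership[j]) {
      q <- q + adj[i, j] - k[i] * k[j] / (2 * m)
    }
  }
  q / (2 * m)
}

# --- exhaustive maximum modularity over all set partitions --------------
# restricted-growth-string enumeration, memoised per n
.partition_cache <- new.env(parent = emptyenv())
partitions_of <- function(n) {
  key <- as.character(n)
  if (!is.null(.partition_cache[[key]])) return(.partition_cache[[key]])
  res <- if (n == 1) list(1L) else {
    out <- list()
    for (p in partitions_of(n - 1)) {
      for (v in seq_len(max(p) + 1L)) out[[length(out) + 1L]] <- c(p, v)
    }
    out
  }
  .partition_cache[[key]] <- res
  res
}

# P x n^2 matrix of vectorised same-community masks, memoised per n
partition_masks <- function(n) {
  key <- paste0("mask", n)
  if (!is.null(.partition_cache[[key]])) return(.partition_cache[[key]])
  parts <- partitions_of(n)
  m <- t(vapply(parts, function(p) as.numeric(outer(p, p, "==")),
                numeric(n * n)))
  .partition_cache[[key]] <- m
  m
}

oracle_max_modularity <- function(adj) {
  n <- nrow(adj)
  m <- sum(adj) / 2
  k <- rowSums(adj)
  b <- adj - outer(k, k) / (2 * m)
  qs <- partition_masks(n) %*% as.vector(b) / (2 * m)
  list(q_max = max(qs),
       best = partitions_of(n)[[which.max(qs)]])
}

# --- random graphs ------------------------------------------------------
random_connected_graph <- function(n, p = 0.4) {
  repeat {
    adj <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1
    }
    # connectivity by reachability scan
    seen <- c(1L)
    repeat {
      nb <- which(colSums(adj[seen, , drop = FALSE]) > 0)
      nb <- setdiff(nb, seen)
      if (!length(nb)) break
      seen <- c(seen, nb)
    }
    if (length(seen) == n && sum(adj) > 0) return(adj)
  }
}

graph_from_adjacency <- function(adj) {
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  proximity_graph(seq_len(nrow(adj)),
                  tibble::tibble(from = idx[, 1], to = idx[, 2]))
}
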