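# Leading-eigenvector modularity community detection on the settlement
# proximity graph, and merging of communities into agglomerations.

# adjacency matrix (dense, 0/1) in vertex order of graph$vertices
graph_adjacency <- function(graph) {
  n <- length(graph$vertices)
  a <- matrix(0, n, n)
  if (nrow(graph$edges)) {
    i <- match(graph$edges$from, graph$vertices)
    j <- match(graph$edges$to, graph$vertices)
    a[cbind(i, j)] <- 1
    a[cbind(j, i)] <- 1
  }
  a
}

membership_vector <- function(graph, partition) {
  if (inherits(partition, "graph_partition")) partition <- partition$membership
  if (is.data.frame(partition)) {
    m <- partition$community[match(graph$vertices, partition$vertex)]
  } else if (!is.null(names(partition))) {
    m <- partition[as.character(graph$vertices)]
  } else if (length(partition) == length(graph$vertices)) {
    m <- partition
  } else {
    stop("partition must cover every vertex", call. = FALSE)
  }
  if (anyNA(m)) stop("partition must cover every vertex", call. = FALSE)
  m
}

#' Modularity of a partition
#'
#' Newman's Q for an unweighted simple graph:
#' `Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) * [c_i == c_j]`,
#' the fraction of within-community edges minus its degree-preserving
#' random expectation.
#'
#' @param graph A [proximity_graph()].
#' @param partition A `graph_partition`, a tibble (`vertex`, `community`),
#'   a named vector keyed by vertex id, or a vector in vertex order.
#' @return The modularity Q.
#' @export
modularity <- function(graph, partition) {
  m <- nrow(graph$edges)
  if (m == 0) stop("modularity undefined for m=0", call. = FALSE)
  comm <- membership_vector(graph, partition)
  i <- match(graph$edges$from, graph$vertices)
  j <- match(graph$edges$to, graph$vertices)
  deg <- tabulate(c(i, j), nbins = length(graph$vertices))
  internal <- sum(comm[i] == comm[j])
  dc <- tapply(deg, comm, sum)
  internal / m - sum((dc / (2 * m))^2)
}

# Kernighan-Lin-style refinement of a bisection sign vector: per round,
# greedily move each vertex exactly once (largest gain in s'Bs first),
# keep the best intermediate state, and repeat while rounds improve.
# Flipping s_i changes s'Bs by 4 * (B_ii - s_i * (B s)_i).
kl_refine <- function(bg, s) {
  q_of <- function(x) as.numeric(t(x) %*% bg %*% x)
  repeat {
    cur <- s
    bs <- as.numeric(bg %*% cur)
    moved <- rep(FALSE, length(s))
    best_q <- q_of(s); best <- s
    run_q <- best_q
    for (step in seq_along(s)) {
      gain <- 4 * (diag(bg) - cur * bs)
      gain[moved] <- -Inf
      i <- which.max(gain)
      run_q <- run_q + gain[i]
      bs <- bs - 2 * cur[i] * bg[, i]
      cur[i] <- -cur[i]
      moved[i] <- TRUE
      if (run_q > best_q + 1e-12) {
        best_q <- run_q
        best <- cur
      }
    }
    if (best_q > q_of(s) + 1e-12) s <- best else return(s)
  }
}

#' Detect communities by the leading-eigenvector method
#'
#' Per connected component, recursive spectral bisection of the
#' (generalized) modularity matrix: split vertices by the sign of the
#' leading eigenvector, accept the split only when the leading eigenvalue
#' is positive (above tolerance) *and* the split strictly increases Q,
#' and recurse on both sides. Entries within tolerance of zero join the
#' positive side, and the eigenvector's sign is fixed so its
#' largest-magnitude entry is positive — both deterministic tie-breaks.
#' Singleton and edgeless components each form their own community.
#' Communities never span two components.
#'
#' @param graph A [proximity_graph()].
#' @param tol Numerical tolerance for the eigenvalue/entry tests.
#' @param fine_tune Apply a Kernighan-Lin single-vertex refinement to each
#'   proposed bisection before the acceptance test (on by default; the
#'   refinement is deterministic and only ever increases Q).
#' @return A `graph_partition`: list with `membership` (tibble `vertex`,
#'   `community`) and `Q` (`NA` for an edgeless graph).
#' @export
detect_communities <- function(graph, tol = 1e-10, fine_tune = TRUE) {
  n <- length(graph$vertices)
  a <- graph_adjacency(graph)
  deg <- rowSums(a)
  m <- nrow(graph$edges)
  comm <- integer(n)
  next_comm <- 0L
  # connected components by BFS
  comp <- integer(n)
  nc <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    nc <- nc + 1L
    frontier <- s
    comp[s] <- nc
    while (length(frontier)) {
      nb <- which(colSums(a[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nb] <- nc
      frontier <- nb
    }
  }
  if (m > 0) {
    b <- a - outer(deg, deg) / (2 * m)
  }
  bisect <- function(g) {
    if (length(g) == 1L) {
      next_comm <<- next_comm + 1L
      comm[g] <<- next_comm
      return(invisible())
    }
    bg <- b[g, g, drop = FALSE]
    diag(bg) <- diag(bg) - rowSums(bg)
    eig <- eigen(bg, symmetric = TRUE)
    lambda <- eig$values[1]
    v <- eig$vectors[, 1]
    imax <- which.max(abs(v))
    if (v[imax] < 0) v <- -v
    s <- ifelse(v < -tol, -1, 1)   # near-zero entries join the positive side
    if (fine_tune) s <- kl_refine(bg, s)
    dq <- as.numeric(t(s) %*% bg %*% s) / (4 * m)
    if (lambda > tol && dq > tol && any(s > 0) && any(s < 0)) {
      bisect(g[s > 0])
      bisect(g[s < 0])
    } else {
      next_comm <<- next_comm + 1L
      comm[g] <<- next_comm
    }
  }
  for (k in seq_len(nc)) bisect(which(comp == k))
  # relabel deterministically by smallest member vertex position
  first <- tapply(seq_len(n), comm, min)
  relab <- match(comm, as.integer(names(sort(first))))
  out <- structure(
    list(membership = tibble::tibble(vertex = graph$vertices,
                                     community = relab),
         Q = NA_real_),
    class = "graph_partition"
  )
  out$Q <- if (m > 0) modularity(graph, out) else NA_real_
  out
}

#' @export
print.graph_partition <- function(x, ...) {
  cat(sprintf("<graph_partition> %d vertices in %d communities, Q = %s\n",
              nrow(x$membership), length(unique(x$membership$community)),
              format(x$Q, digits = 4)))
  invisible(x)
}

#' Merge settlement communities into metropolitan agglomerations
#'
#' One agglomeration per community: geometry is the union (multipolygon)
#' of member settlements, population and area are sums, and
#' `density_per_ha = population / area_ha`. Agglomeration ids are
#' assigned by descending population with ties broken on the smallest
#' member settlement id. Each agglomeration gets its [classify_size()]
#' size class.
#'
#' @param settlements A [delineate_settlements()] tibble.
#' @param partition A `graph_partition` (or anything
#'   [modularity()] accepts) over the settlement ids.
#' @return A tibble of agglomerations: `ma_id`, `population`, `area_ha`,
#'   `density_per_ha`, `size_class`, `n_settlements`, plus list-columns
#'   `members` (settlement ids), `cells` and `geometry`.
#' @export
merge_into_agglomerations <- function(settlements, partition) {
  if (inherits(partition, "graph_partition")) partition <- partition$membership
  partition <- tibble::as_tibble(partition)
  unknown <- setdiff(partition$vertex, settlements$settlement_id)
  if (length(unknown)) {
    stop("unknown settlement_id in partition: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  comm <- partition$community[match(settlements$settlement_id,
                                    partition$vertex)]
  if (anyNA(comm)) stop("partition must cover all settlement_ids", call. = FALSE)
  if (nrow(settlements) == 0) {
    return(tibble::tibble(ma_id = integer(0), population = numeric(0),
                          area_ha = numeric(0), density_per_ha = numeric(0),
                          size_class = classify_size(numeric(0)),
                          n_settlements = integer(0), members = list(),
                          cells = list(), geometry = list()))
  }
  groups <- split(seq_len(nrow(settlements)), comm)
  rows <- lapply(groups, function(idx) {
    tibble::tibble(
      population = sum(settlements$population[idx]),
      area_ha = sum(settlements$area_ha[idx]),
      n_settlements = length(idx),
      min_member = min(settlements$settlement_id[idx]),
      members = list(sort(settlements$settlement_id[idx])),
      cells = list(sort(unlist(settlements$cells[idx]))),
      geometry = list(unlist(lapply(settlements$geometry[idx],
                                    function(g) g), recursive = FALSE))
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(-out$population, out$min_member), ]
  out$ma_id <- seq_len(nrow(out))
  out$density_per_ha <- out$population / out$area_ha
  out$size_class <- classify_size(out$population)
  out[, c("ma_id", "population", "area_ha", "density_per_ha", "size_class",
          "n_settlements", "members", "cells", "geometry")]
}

#' Full agglomeration delineation pipeline
#'
#' Chains [delineate_settlements()], [build_proximity_graph()],
#' [detect_communities()] and [merge_into_agglomerations()].
#'
#' @inheritParams delineate_settlements
#' @inheritParams build_proximity_graph
#' @return A list of class `ma_delineation`: `settlements`, `graph`,
#'   `partition`, `agglomerations`, `parameters`.
#' @export
delineate_agglomerations <- function(pop, tau_per_ha = 7.5, d_max_m = 150,
                                     min_area_ha = 2, connectivity = 4,
                                     strict_threshold = FALSE) {
  settlements <- delineate_settlements(pop, tau_per_ha = tau_per_ha,
                                       min_area_ha = min_area_ha,
                                       connectivity = connectivity,
                                       strict_threshold = strict_threshold)
  graph <- build_proximity_graph(settlements, pop, d_max_m = d_max_m)
  partition <- detect_communities(graph)
  mas <- merge_into_agglomerations(settlements, partition)
  structure(list(settlements = settlements, graph = graph,
                 partition = partition, agglomerations = mas,
                 parameters = list(tau_per_ha = tau_per_ha,
                                   d_max_m = d_max_m,
                                   min_area_ha = min_area_ha,
                                   connectivity = connectivity,
                                   strict_threshold = strict_threshold)),
            class = "ma_delineation")
}

#' @export
print.ma_delineation <- function(x, ...) {
  p <- x$parameters
  cat(sprintf(
    "<ma_delineation> tau %g pp/ha, d_max %g m, min area %g ha\n",
    p$tau_per_ha, p$d_max_m, p$min_area_ha))
  cat(sprintf("  %d settlements -> %d agglomerations, urban population %.0f\n",
              nrow(x$settlements), nrow(x$agglomerations),
              sum(x$agglomerations$population)))
  invisible(x)
}

#' Plot delineated agglomerations over the population surface
#'
#' @param object An `ma_delineation`.
#' @param pop The population grid used for delineation (for the backdrop).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ma_delineation <- function(object, pop = NULL, ...) {
  mas <- object$agglomerations
  poly_df <- dplyr::bind_rows(lapply(seq_len(nrow(mas)), function(i) {
    parts <- mas$geometry[[i]]
    dplyr::bind_rows(lapply(seq_along(parts), function(k) {
      ring <- parts[[k]][[1]]
      tibble::tibble(x = ring[, 1], y = ring[, 2],
                     grp = paste(mas$ma_id[i], k),
                     ma_id = factor(mas$ma_id[i]))
    }))
  }))
  p <- ggplot2::ggplot()
  if (!is.null(pop)) {
    p <- p + ggplot2::geom_raster(
      data = cell_centres(density_view(pop)),
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
      ggplot2::scale_fill_viridis_c(name = "pp/ha", na.value = "grey90")
  }
  p + ggplot2::geom_polygon(
    data = poly_df,
    ggplot2::aes(x = .data$x, y = .data$y, group = .data$grp,
                 colour = .data$ma_id),
    fill = NA, linewidth = 0.4) +
    ggplot2::coord_equal() +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}
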