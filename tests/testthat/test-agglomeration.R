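# Thresholding, region grouping, hole filling, area filtering,
# population integration and the proximity graph.

test_that("density threshold is lower-inclusive by default, strict on request", {
  pop <- pop_from_density(matrix(c(7.5, 7.49, 10, 2), 2, 2))
  sel <- threshold_cells(pop, 7.5)
  expect_equal(sel$values, matrix(c(1, 0, 1, 0), 2, 2))
  strict <- threshold_cells(pop, 7.5, strict = TRUE)
  expect_equal(strict$values, matrix(c(0, 0, 1, 0), 2, 2))
  nodata <- pop_from_density(matrix(c(NA, 9), 1, 2))
  expect_equal(threshold_cells(nodata, 7.5)$values, matrix(c(0, 1), 1, 2))
})

test_that("threshold selections nest as tau rises", {
  set.seed(14)
  for (rep in 1:5) {
    pop <- pop_from_density(matrix(runif(400, 0, 15), 20, 20))
    s5 <- threshold_cells(pop, 5)$values
    s75 <- threshold_cells(pop, 7.5)$values
    s10 <- threshold_cells(pop, 10)$values
    expect_true(all(s10 <= s75))
    expect_true(all(s75 <= s5))
  }
})

test_that("region grouping distinguishes rook and queen adjacency", {
  diag2 <- mg_grid(matrix(c(1, 0, 0, 1), 2, 2))
  expect_equal(label_regions(diag2, connectivity = 4)$n, 2)
  expect_equal(label_regions(diag2, connectivity = 8)$n, 1)
})

test_that("region grouping matches the flood-fill oracle on random binary grids", {
  set.seed(33)
  for (rep in 1:6) {
    sel <- matrix(runif(2500) < 0.35, 50, 50)
    bin <- mg_grid(matrix(as.numeric(sel), 50, 50))
    for (conn in c(4, 8)) {
      got <- label_regions(bin, connectivity = conn)
      ora <- oracle_flood_components(sel, connectivity = conn)
      expect_equal(got$n, ora$n)
      expect_true(same_partition(got$labels, ora$labels))
    }
  }
})

test_that("hole filling keeps exterior rings only and never shrinks an area", {
  ring <- rect_ring(0, 0, 500, 500)
  hole <- rect_ring(100, 100, 200, 200)
  filled <- fill_holes(list(list(list(ring, hole))))
  expect_equal(filled, list(list(list(ring))))
  expect_equal(geom_area_ha(filled[[1]]), 25)
  expect_gt(geom_area_ha(filled[[1]]),
            geom_area_ha(list(list(ring, hole))))

  # hole-free polygons unchanged, and the operation is idempotent
  plain <- list(list(list(ring)))
  expect_equal(fill_holes(plain), plain)
  expect_equal(fill_holes(fill_holes(filled)), filled)

  # nested multi-ring polygon: area equals the shoelace of the exterior
  nested <- list(list(list(rect_ring(0, 0, 900, 400),
                           rect_ring(100, 100, 300, 300),
                           rect_ring(500, 100, 800, 300))))
  expect_equal(geom_area_ha(fill_holes(nested)[[1]]), 900 * 400 / 1e4)

  expect_error(fill_holes(list(list(list(cbind(1, 2))))), "invalid geometry")
})

test_that("a ring of selected cells becomes a 9-cell square settlement", {
  dens <- matrix(10, 3, 3)
  dens[2, 2] <- 0
  pop <- pop_from_density(dens)
  pop$values[2, 2] <- 2 * cell_area_ha(pop)  # 2 persons in the hole
  s <- delineate_settlements(pop, tau_per_ha = 7.5)
  expect_equal(nrow(s), 1)
  expect_equal(s$area_ha, 9)
  expect_equal(s$cell_count, 9L)
  # former hole population included
  expect_equal(s$population, 8 * 10 + 2)
  # geometry is the hole-free 300 m square
  expect_equal(geom_area_ha(s$geometry[[1]]), 9)
})

test_that("the minimum-area filter removes settlements strictly below 2 ha", {
  dens <- matrix(0, 6, 6)
  dens[2, 2] <- 20           # 1 cell = 1 ha -> removed
  dens[4, 4:5] <- 20         # 2 cells = 2 ha -> kept
  pop <- pop_from_density(dens)
  s <- delineate_settlements(pop, tau_per_ha = 7.5, min_area_ha = 2)
  expect_equal(nrow(s), 1)
  expect_equal(s$area_ha, 2)
  expect_equal(nrow(filter_min_area(tibble::tibble(area_ha = numeric(0)))), 0)
})

test_that("population integration equals the cell-centre brute force", {
  set.seed(8)
  dens <- matrix(runif(400, 0, 20), 20, 20)
  pop <- pop_from_density(dens)
  # whole-grid polygon integrates everything
  whole <- list(list(rect_ring(0, 0, 2000, 2000)))
  expect_equal(integrate_population(list(whole), pop), sum(pop$values))

  s <- delineate_settlements(pop, tau_per_ha = 10)
  for (i in seq_len(min(nrow(s), 5))) {
    geom <- s$geometry[[i]]
    brute <- 0
    for (c in 1:20) for (r in 1:20) {
      x <- (c - 0.5) * 100; y <- 2000 - (r - 0.5) * 100
      if (oracle_point_in_geom(x, y, geom)) {
        brute <- brute + pop$values[r, c]
      }
    }
    expect_equal(s$population[i], brute)
  }
})

test_that("proximity edges require boundary distance strictly below the threshold", {
  dens <- matrix(0, 3, 7)
  dens[2, 1] <- 20; dens[2, 3] <- 20   # one empty cell between: gap 100 m
  dens[2, 6] <- 20                     # two empty cells: gap 200 m
  pop <- pop_from_density(dens)
  s <- delineate_settlements(pop, tau_per_ha = 7.5, min_area_ha = 0)
  g <- build_proximity_graph(s, pop, d_max_m = 150)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$distance_m, 100)

  # separation of exactly 150 m yields no edge
  g150 <- build_proximity_graph(s, pop, d_max_m = 100)
  expect_equal(nrow(g150$edges), 0)

  # touching settlements are always connected: two cells diagonal under
  # rook grouping are distinct settlements at distance 0
  dd <- matrix(0, 2, 2); dd[1, 1] <- 20; dd[2, 2] <- 20
  pd <- pop_from_density(dd)
  sd <- delineate_settlements(pd, tau_per_ha = 7.5, min_area_ha = 0,
                              connectivity = 4)
  gd <- build_proximity_graph(sd, pd, d_max_m = 150)
  expect_equal(nrow(sd), 2)
  expect_equal(gd$edges$distance_m, 0)
})

test_that("proximity graph matches the all-pairs boundary-distance brute force", {
  set.seed(55)
  for (rep in 1:4) {
    dens <- matrix(0, 40, 40)
    for (b in 1:12) {
      r0 <- sample(1:36, 1); c0 <- sample(1:36, 1)
      dens[r0:(r0 + sample(1:4, 1)), c0:(c0 + sample(1:4, 1))] <- 20
    }
    pop <- pop_from_density(dens)
    s <- delineate_settlements(pop, tau_per_ha = 7.5, min_area_ha = 0)
    g <- build_proximity_graph(s, pop, d_max_m = 250)
    want <- list()
    for (i in seq_len(nrow(s) - 1)) for (j in seq(i + 1, nrow(s))) {
      d <- oracle_min_distance(s$cells[[i]], s$cells[[j]], 40, 100)
      if (d < 250) want[[length(want) + 1]] <- c(s$settlement_id[i],
                                                 s$settlement_id[j], d)
    }
    want <- do.call(rbind, want)
    got <- as.matrix(g$edges)
    expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                 want[order(want[, 1], want[, 2]), , drop = FALSE],
                 ignore_attr = TRUE)
  }
})

test_that("delineation is deterministic and labels settlements top-left first", {
  set.seed(71)
  dens <- matrix(runif(900, 0, 12), 30, 30)
  pop <- pop_from_density(dens)
  s1 <- delineate_settlements(pop, tau_per_ha = 7.5)
  s2 <- delineate_settlements(pop, tau_per_ha = 7.5)
  expect_identical(s1, s2)
  expect_equal(s1$settlement_id, seq_len(nrow(s1)))
})

test_that("total selected area and urban population fall as tau rises", {
  set.seed(90)
  for (rep in 1:4) {
    sc <- generate_landscape(scene_spec(n_rows = 40, n_cols = 40,
                                        n_districts = 12, n_settlements = 6,
                                        seed = 900 + rep))
    res <- lapply(c(5, 7.5, 10), function(tau) {
      s <- delineate_settlements(sc$population, tau_per_ha = tau)
      c(area = sum(s$area_ha), pop = sum(s$population), n = nrow(s))
    })
    areas <- vapply(res, `[[`, numeric(1), "area")
    pops <- vapply(res, `[[`, numeric(1), "pop")
    expect_true(all(diff(areas) <= 0))
    expect_true(all(diff(pops) <= 0))
  }
})
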