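#' Build the zone-level model table
#'
#' One row per census zone: the response `log_density` (natural log of
#' persons per hectare, `log(count / area_ha)`) and the zonal mean of
#' every covariate layer (cell-centre rule, nodata excluded). Zones with a
#' zero count get `log(eps_persons / area_ha)` so the support stays
#' complete; the pseudo-count default is half a person.
#'
#' @param zones A [zone_set()].
#' @param counts Long counts tibble (`zone_id`, `year`, `count`).
#' @param year Census year to model.
#' @param stack A [grid_stack()] of covariates.
#' @param eps_persons Pseudo-count for zero-count zones.
#' @return A tibble with `zone_id`, `area_ha`, `count`, `log_density` and
#'   one column per covariate; covariate names are kept in the
#'   `"covariates"` attribute.
#' @export
build_feature_table <- function(zones, counts, year, stack,
                                eps_persons = 0.5) {
  n <- counts_for_year(counts, zones, year)
  if (any(zones$area_ha <= 0)) stop("zone with zero area", call. = FALSE)
  covs <- zonal_means_stack(stack, zones)
  eff <- ifelse(n > 0, n, eps_persons)
  out <- tibble::tibble(zone_id = zones$zone_id,
                        area_ha = zones$area_ha,
                        count = n,
                        log_density = log(eff / zones$area_ha))
  out <- dplyr::left_join(out, covs, by = "zone_id")
  attr(out, "covariates") <- names(stack)
  out
}

#' Fit the random-forest log-density model
#'
#' A regression random forest of `n_trees` trees predicting natural-log
#' population density from zone-level covariate means, with out-of-bag
#' (OOB) diagnostics: `oob_mse`, and `oob_pseudo_r2 = 1 - oob_mse /
#' mean((y - mean(y))^2)`. Features per split default to the regression
#' convention of a third of the covariates. A constant response cannot be
#' modelled by trees; it warns and returns a degenerate model that always
#' predicts the constant.
#'
#' @param table A [build_feature_table()] result.
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed; fixing it makes the fit deterministic.
#' @param covariates Covariate columns to use; defaults to the table's
#'   `"covariates"` attribute.
#' @param mtry Features tried per split; default `ceiling(p / 3)`.
#' @return An object of class `density_model`.
#' @export
fit_density_model <- function(table, n_trees = 500, seed = 1L,
                              covariates = NULL, mtry = NULL) {
  covariates <- covariates %||% attr(table, "covariates") %||%
    setdiff(names(table), c("zone_id", "area_ha", "count", "log_density"))
  if (nrow(table) < 10) stop("need at least 10 zones to fit", call. = FALSE)
  x <- as.data.frame(table[, covariates, drop = FALSE])
  y <- table$log_density
  if (anyNA(x) || anyNA(y)) {
    stop("missing covariate or response values in feature table", call. = FALSE)
  }
  out <- list(covariate_names = covariates, n_trees = as.integer(n_trees),
              seed = as.integer(seed), n_zones = nrow(table),
              response_range = range(y))
  if (diff(range(y)) == 0) {
    warning("constant response; model predicts the constant", call. = FALSE)
    out$constant <- y[1]
    out$rf <- NULL
    out$oob_mse <- 0
    out$oob_pseudo_r2 <- NA_real_
    class(out) <- "density_model"
    return(out)
  }
  mtry <- mtry %||% max(1L, ceiling(length(covariates) / 3))
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                   mtry = mtry, importance = TRUE)
  oob_mse <- mean((y - rf$predicted)^2)
  out$rf <- rf
  out$mtry <- mtry
  out$oob_mse <- oob_mse
  out$oob_pseudo_r2 <- 1 - oob_mse / mean((y - mean(y))^2)
  class(out) <- "density_model"
  out
}

#' @export
print.density_model <- function(x, ...) {
  cat(sprintf("<density_model> %d trees on %d zones, %d covariates\n",
              x$n_trees, x$n_zones, length(x$covariate_names)))
  cat(sprintf("  OOB MSE %.4g, OOB pseudo-R2 %.3f\n",
              x$oob_mse, x$oob_pseudo_r2))
  invisible(x)
}

#' Predict log density for new covariate rows
#'
#' @param object A `density_model`.
#' @param newdata Data frame with the model's covariate columns.
#' @param ... Unused.
#' @return Numeric vector of predicted natural-log densities.
#' @export
predict.density_model <- function(object, newdata, ...) {
  missing <- setdiff(object$covariate_names, names(newdata))
  if (length(missing)) {
    stop("missing covariate layer: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(object$rf)) {
    return(rep(object$constant, nrow(newdata)))
  }
  as.numeric(predict(object$rf,
                     as.data.frame(newdata[, object$covariate_names,
                                           drop = FALSE])))
}

#' @export
tidy.density_model <- function(x, ...) {
  if (is.null(x$rf)) {
    return(tibble::tibble(term = x$covariate_names,
                          importance_mse = NA_real_,
                          importance_purity = NA_real_))
  }
  imp <- randomForest::importance(x$rf)
  tibble::tibble(term = rownames(imp),
                 importance_mse = imp[, "%IncMSE"],
                 importance_purity = imp[, "IncNodePurity"])
}

#' @export
glance.density_model <- function(x, ...) {
  tibble::tibble(n_zones = x$n_zones, n_trees = x$n_trees,
                 mtry = x$mtry %||% NA_integer_,
                 oob_mse = x$oob_mse, oob_pseudo_r2 = x$oob_pseudo_r2)
}

#' Predict the per-cell dasymetric weight surface
#'
#' Evaluates the fitted model at every habitable cell of the covariate
#' stack and exponentiates, giving a strictly positive relative weight;
#' masked (uninhabitable/protected) cells and cells with any nodata
#' covariate get weight exactly 0.
#'
#' @param model A [fit_density_model()] result.
#' @param stack A [grid_stack()] covering the model's covariates.
#' @param mask Optional `mg_grid`, 1 = habitable, 0/nodata = not; `NULL`
#'   means everything is habitable.
#' @return A `weight_surface`: list with `weights` (`mg_grid`),
#'   `habitable` (logical matrix) and a `provenance` note.
#' @export
predict_weight_surface <- function(model, stack, mask = NULL) {
  g0 <- stack[[1]]
  missing <- setdiff(model$covariate_names, names(stack))
  if (length(missing)) {
    stop("missing covariate layer: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(mask)) {
    stop_if_misaligned(g0, mask, "stack and mask")
    habitable <- !is.na(mask$values) & mask$values != 0
  } else {
    habitable <- matrix(TRUE, nrow(g0$values), ncol(g0$values))
  }
  complete <- habitable
  for (nm in model$covariate_names) complete <- complete & !is.na(stack[[nm]]$values)
  w <- matrix(0, nrow(g0$values), ncol(g0$values))
  idx <- which(complete)
  if (length(idx)) {
    newdata <- as.data.frame(lapply(stack[model$covariate_names],
                                    function(l) l$values[idx]))
    names(newdata) <- model$covariate_names
    w[idx] <- exp(predict(model, newdata))
  }
  structure(
    list(weights = grid_like(g0, w), habitable = complete,
         provenance = sprintf(
           "exp(RF log-density), %d trees; %d of %d cells masked to 0",
           model$n_trees, sum(!complete), length(complete))),
    class = "weight_surface"
  )
}

#' @export
print.weight_surface <- function(x, ...) {
  cat("<weight_surface> ", x$provenance, "\n", sep = "")
  invisible(x)
}

as_weight_surface <- function(weights) {
  if (inherits(weights, "weight_surface")) return(weights)
  stopifnot(inherits(weights, "mg_grid"))
  v <- weights$values
  structure(list(weights = weights, habitable = !is.na(v) & v > 0,
                 provenance = "user-supplied weight grid"),
            class = "weight_surface")
}

#' Dasymetric redistribution of census counts
#'
#' Allocates each zone's count over its cells proportionally to the
#' weight surface: `persons_i = N_z * w_i / sum(w_j, j in z)`. A zone
#' whose weights sum to zero falls back to uniform allocation over its
#' habitable cells (or over all its cells if none is habitable), so that
#' every zone's total is conserved exactly.
#'
#' @param weights A [predict_weight_surface()] result (or a bare weight
#'   `mg_grid`, in which case cells with positive weight count as
#'   habitable).
#' @param zones A [zone_set()].
#' @param counts Long counts tibble.
#' @param year Census year to redistribute.
#' @return A `population_grid` (an `mg_grid` subclass) of persons per
#'   cell; cells outside every zone are 0.
#' @export
redistribute <- function(weights, zones, counts, year) {
  ws <- as_weight_surface(weights)
  g <- ws$weights
  n <- counts_for_year(counts, zones, year)
  lab <- rasterize_zones(zones, g)
  labv <- as.vector(lab)
  wv <- as.vector(g$values)
  wv[is.na(wv)] <- 0
  hab <- as.vector(ws$habitable)
  persons <- numeric(length(wv))
  cells_by_zone <- split(seq_along(labv), labv)
  missing <- setdiff(as.character(seq_len(nrow(zones))), names(cells_by_zone))
  if (length(missing)) {
    stop("zone(s) with no grid cells: ",
         paste(zones$zone_id[as.integer(missing)], collapse = ", "),
         call. = FALSE)
  }
  for (zi in seq_len(nrow(zones))) {
    cells <- cells_by_zone[[as.character(zi)]]
    w <- wv[cells]
    tot <- sum(w)
    if (tot > 0) {
      persons[cells] <- n[zi] * w / tot
    } else {
      habc <- cells[hab[cells]]
      if (!length(habc)) habc <- cells
      persons[habc] <- n[zi] / length(habc)
    }
  }
  out <- grid_like(g, matrix(persons, nrow(g$values), ncol(g$values)))
  class(out) <- c("population_grid", class(out))
  attr(out, "year") <- year
  out
}

#' Person-per-hectare view of a population grid
#'
#' @param pop A `population_grid` of persons per cell.
#' @return An `mg_grid` of densities (persons/ha).
#' @export
density_view <- function(pop) {
  grid_like(pop, pop$values / cell_area_ha(pop))
}

#' Re-aggregate a population grid to check zones
#'
#' Validation device: sum the gridded population over an independent set
#' of polygons (cell-centre rule) and correlate with reference counts.
#' Over the fitting zones themselves the correlation is 1 by conservation;
#' over independent finer zones it measures how well the disaggregation
#' located people.
#'
#' @param pop A `population_grid`.
#' @param check_zones A [zone_set()] (may differ from the fitting zones).
#' @param counts Reference counts tibble.
#' @param year Year of the reference counts.
#' @return List with `by_zone` (tibble: `zone_id`, `count`, `estimated`)
#'   and `pearson_r`.
#' @export
reaggregate_check <- function(pop, check_zones, counts, year) {
  if (nrow(check_zones) < 3) {
    stop("need at least 3 zones for a correlation", call. = FALSE)
  }
  ref <- counts_for_year(counts, check_zones, year)
  est <- zonal_sum(pop, check_zones)$value
  list(by_zone = tibble::tibble(zone_id = check_zones$zone_id,
                                count = ref, estimated = est),
       pearson_r = stats::cor(est, ref))
}

#' One-call dasymetric disaggregation
#'
#' Chains [build_feature_table()], [fit_density_model()],
#' [predict_weight_surface()] and [redistribute()].
#'
#' @inheritParams build_feature_table
#' @inheritParams fit_density_model
#' @param mask Optional habitability mask grid (1 = habitable).
#' @return List of class `disaggregation`: `feature_table`, `model`,
#'   `weights`, `population`.
#' @export
disaggregate_population <- function(zones, counts, year, stack, mask = NULL,
                                    n_trees = 500, eps_persons = 0.5,
                                    seed = 1L) {
  ft <- build_feature_table(zones, counts, year, stack,
                            eps_persons = eps_persons)
  model <- fit_density_model(ft, n_trees = n_trees, seed = seed)
  ws <- predict_weight_surface(model, stack, mask = mask)
  pop <- redistribute(ws, zones, counts, year)
  structure(list(feature_table = ft, model = model, weights = ws,
                 population = pop),
            class = "disaggregation")
}

#' @export
print.disaggregation <- function(x, ...) {
  print(x$model)
  cat(sprintf("  total redistributed population: %.0f persons\n",
              sum(x$population$values, na.rm = TRUE)))
  invisible(x)
}
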