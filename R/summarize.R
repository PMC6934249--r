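# Urban hierarchy classification and urbanization shares.

size_class_breaks <- c(0, 5e3, 2e4, 1e5, 1e6, 1e7, 4e7, Inf)
size_class_labels <- c("<5k town", "5-20k town", "20-100k town",
                       "Class 1 (100k-1M)", "Million+ (1-10M)",
                       "Megacity (10-40M)", "Megalopolis (>40M)")

#' The urban size-class hierarchy
#'
#' Seven ordered classes partitioning `[0, Inf)` at 5,000 / 20,000 /
#' 100,000 / 1 million / 10 million / 40 million persons. Every interval
#' is half-open `[lo, hi)` — the lower bound is inclusive, one fixed
#' convention for boundaries the source tabulations describe with mixed
#' range notation.
#'
#' @return A tibble with `size_class`, `lower`, `upper`.
#' @export
size_classes <- function() {
  k <- length(size_class_labels)
  tibble::tibble(
    size_class = factor(size_class_labels, levels = size_class_labels,
                        ordered = TRUE),
    lower = size_class_breaks[seq_len(k)],
    upper = size_class_breaks[seq_len(k) + 1]
  )
}

#' Classify agglomeration populations into the size hierarchy
#'
#' @param population Numeric vector of populations (persons), `>= 0`.
#' @return An ordered factor over the seven size classes.
#' @export
classify_size <- function(population) {
  if (any(is.na(population)) || any(population < 0)) {
    stop("population must be nonnegative", call. = FALSE)
  }
  cut(population, breaks = size_class_breaks, labels = size_class_labels,
      right = FALSE, ordered_result = TRUE)
}

#' Tabulate the urban hierarchy and urbanization share
#'
#' Counts and total populations of agglomerations per size class, plus
#' the total urban population and the percent urban, computed against the
#' supplied total (census) population.
#'
#' @param mas A [merge_into_agglomerations()] tibble (only `population`
#'   is required).
#' @param total_population Total population of the study area (the census
#'   total for the modelled year).
#' @return A list of class `urban_summary`: `by_class` (tibble
#'   `size_class`, `n`, `population`), `urban_population`,
#'   `total_population`, `percent_urban`.
#' @export
tabulate_hierarchy <- function(mas, total_population) {
  if (!is.numeric(total_population) || total_population <= 0) {
    stop("total_population must be positive", call. = FALSE)
  }
  pops <- if (is.data.frame(mas)) mas$population else as.numeric(mas)
  urban <- sum(pops)
  if (urban > total_population) {
    warning("urban population exceeds the supplied total", call. = FALSE)
  }
  cls <- classify_size(pops)
  by_class <- tibble::tibble(
    size_class = size_classes()$size_class,
    n = as.integer(table(cls)),
    population = as.numeric(tapply(pops, cls, sum, default = 0))
  )
  structure(list(by_class = by_class, urban_population = urban,
                 total_population = total_population,
                 percent_urban = 100 * urban / total_population),
            class = "urban_summary")
}

#' @export
print.urban_summary <- function(x, ...) {
  print(x$by_class, n = Inf)
  cat(sprintf("urban %.0f of %.0f persons (%.2f%% urban)\n",
              x$urban_population, x$total_population, x$percent_urban))
  invisible(x)
}

#' @export
glance.urban_summary <- function(x, ...) {
  tibble::tibble(n_agglomerations = sum(x$by_class$n),
                 urban_population = x$urban_population,
                 total_population = x$total_population,
                 percent_urban = x$percent_urban)
}

#' @export
tidy.urban_summary <- function(x, ...) x$by_class

#' Plot the urban hierarchy tabulation
#'
#' @param object An `urban_summary`.
#' @param ... Unused.
#' @return A ggplot bar chart of population per size class.
#' @export
autoplot.urban_summary <- function(object, ...) {
  ggplot2::ggplot(object$by_class,
                  ggplot2::aes(x = .data$size_class,
                               y = .data$population)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "population") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Urbanization share per administrative zone
#'
#' For each overlay zone (e.g., a state), the urban population is the sum
#' of gridded persons at cells whose centres lie inside the zone *and*
#' inside any agglomeration; the share divides by the zone's census
#' count. Because the denominator is the census count while the numerator
#' is grid-integrated over agglomeration extents, shares can exceed 100%
#' where agglomeration geometries spill across zone edges; such zones are
#' flagged rather than clipped.
#'
#' @param mas A [merge_into_agglomerations()] tibble (its `cells`
#'   list-column defines the urban extent).
#' @param admin_zones A [zone_set()] of overlay zones.
#' @param pop The `population_grid` the agglomerations came from.
#' @param counts Census counts tibble for the overlay zones.
#' @param year Census year.
#' @return A tibble: `zone_id`, `urban_population`, `total_population`,
#'   `share_pct`, `exceeds_census`.
#' @export
admin_overlay_share <- function(mas, admin_zones, pop, counts, year) {
  n <- counts_for_year(counts, admin_zones, year)
  urban <- logical(length(pop$values))
  for (cl in mas$cells) urban[cl] <- TRUE
  persons <- as.vector(pop$values)
  persons[is.na(persons)] <- 0
  lab <- as.vector(rasterize_zones(admin_zones, pop))
  ok <- urban & !is.na(lab)
  sums <- rep(0, nrow(admin_zones))
  if (any(ok)) {
    t_s <- tapply(persons[ok], lab[ok], sum)
    sums[as.integer(names(t_s))] <- t_s
  }
  share <- ifelse(n > 0, 100 * sums / n, NA_real_)
  tibble::tibble(zone_id = admin_zones$zone_id,
                 urban_population = sums,
                 total_population = n,
                 share_pct = share,
                 exceeds_census = !is.na(share) & share > 100)
}
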