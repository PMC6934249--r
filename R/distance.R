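#' Signed distance to the edge of a land-cover class
#'
#' For every cell, the Euclidean centre-to-centre distance (metres) to the
#' nearest cell of the opposite membership (target class vs. everything
#' else). The sign is negative inside the target class and positive
#' outside, the convention used for distance-to-built-edge covariates.
#' Nodata cells belong to neither side: they are excluded as distance
#' targets and are nodata in the output.
#'
#' @param class_grid An `mg_grid` of integer class codes.
#' @param target_class The class whose edge is measured.
#' @return An `mg_grid` of signed distances in metres.
#' @export
signed_distance_to_class_edge <- function(class_grid, target_class) {
  stopifnot(inherits(class_grid, "mg_grid"))
  v <- class_grid$values
  valid <- !is.na(v)
  tgt <- valid & v == target_class
  oth <- valid & v != target_class
  if (!any(tgt) || !any(oth)) stop("no class edge present", call. = FALSE)
  # distmap gives, for each non-background pixel, the exact Euclidean
  # distance (in cell units) to the nearest background pixel
  d_to_tgt <- EBImage::distmap(matrix(as.numeric(!tgt), nrow(v), ncol(v)))
  d_to_oth <- EBImage::distmap(matrix(as.numeric(!oth), nrow(v), ncol(v)))
  d_to_tgt <- as.matrix(d_to_tgt); d_to_oth <- as.matrix(d_to_oth)
  out <- ifelse(tgt, -d_to_oth, d_to_tgt) * class_grid$cell_size_m
  out[!valid] <- NA_real_
  grid_like(class_grid, out)
}
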