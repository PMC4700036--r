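## Clark-Evans order index.
##
## R = 2 * nbar * D^(1/d), with nbar the mean nearest-neighbour distance,
## D the intensity (points per unit length or area) and d the dimension.
## Anchor values: 2.0 (perfectly even 1-D spacing), 2/sqrt(2/sqrt(3)) =
## 2.149 (hexagonal packing), 1.0 (complete spatial randomness), -> 0
## (clustering). No edge correction by default, matching uncorrected field
## practice; a Donnelly-style correction is available behind a flag.

#' Clark-Evans R index from summary quantities
#'
#' @param mean_nn mean nearest-neighbour distance (um).
#' @param n_points number of points.
#' @param extent total length (um, `dims = 1`) or area (um^2, `dims = 2`).
#' @param dims 1 or 2.
#' @return An object of class `"order_index"` with fields `r_value`,
#'   `mean_nn`, `density`, `dims`, `n_points`.
#' @export
#' @examples
#' # ring of eudicot stem bundles: 18 bundles, mean spacing 9.6 mm,
#' # circumference 53.5*pi mm
#' clark_evans_r(9.6, 18, 53.5 * pi, dims = 1)   # R = 2.06 -> ordered
clark_evans_r <- function(mean_nn, n_points, extent, dims) {
  if (!dims %in% c(1, 2)) stop("`dims` must be 1 or 2", call. = FALSE)
  if (!is.numeric(mean_nn) || mean_nn <= 0 || !is.finite(mean_nn)) {
    stop("`mean_nn` must be a positive number", call. = FALSE)
  }
  if (n_points < 2) stop("need at least 2 points", call. = FALSE)
  if (!is.numeric(extent) || extent <= 0 || !is.finite(extent)) {
    stop("`extent` must be positive", call. = FALSE)
  }
  density <- n_points / extent
  structure(list(r_value = 2 * mean_nn * density^(1 / dims),
                 mean_nn = mean_nn, density = density,
                 dims = as.integer(dims), n_points = as.integer(n_points)),
            class = "order_index")
}

#' @export
print.order_index <- function(x, ...) {
  cat(sprintf("<order_index> R = %.3f (%s), %d-D, n = %d, mean NN = %.4g, density = %.4g\n",
              x$r_value, classify_order(x), x$dims, x$n_points,
              x$mean_nn, x$density))
  invisible(x)
}

#' R index of a 1-D transect
#'
#' @param t a [transect()].
#' @return `"order_index"` (dims = 1).
#' @export
r_index_from_transect <- function(t) {
  stopifnot(inherits(t, "transect"))
  clark_evans_r(mean(nn_distances_1d(t)), length(t$positions), t$length,
                dims = 1)
}

#' R index of a 2-D pattern
#'
#' Mean Delaunay nearest-neighbour distance against the intensity from the
#' declared area (or the convex hull, with a warning).
#'
#' @param p a [point_pattern()].
#' @param adj optional precomputed [delaunay_adjacency()].
#' @param correction `"none"` (default) or `"donnelly"`; the latter divides
#'   the observed mean by the edge-corrected CSR expectation instead of
#'   using the raw `2 * nbar * sqrt(D)` form and needs `perimeter`.
#' @param perimeter region perimeter (um), used only by the correction.
#' @return `"order_index"` (dims = 2).
#' @export
r_index_from_pattern <- function(p, adj = NULL,
                                 correction = c("none", "donnelly"),
                                 perimeter = NULL) {
  stopifnot(inherits(p, "point_pattern"))
  correction <- match.arg(correction)
  if (is.null(adj)) adj <- delaunay_adjacency(p)
  nbar <- mean(nn_distances_2d(p, adj))
  n <- n_points(p)
  a <- region_area(p)
  res <- clark_evans_r(nbar, n, a, dims = 2)
  if (correction == "donnelly") {
    if (is.null(perimeter)) {
      stop("the Donnelly correction needs the region `perimeter`",
           call. = FALSE)
    }
    expected <- 0.5 * sqrt(a / n) + (0.0514 + 0.041 / sqrt(n)) * perimeter / n
    res$r_value <- nbar / expected
  }
  res
}

#' Classify an order index
#'
#' Bands around the CSR anchor: clustered below `thresholds[1]`, random up
#' to `thresholds[2]`, ordered above.
#'
#' @param r an `"order_index"` or a bare R value.
#' @param thresholds length-2 numeric, default `c(0.9, 1.1)`.
#' @return `"ordered"`, `"random"` or `"clustered"`.
#' @export
classify_order <- function(r, thresholds = c(0.9, 1.1)) {
  v <- if (inherits(r, "order_index")) r$r_value else r
  stopifnot(is.numeric(v), length(v) == 1L, length(thresholds) == 2L,
            thresholds[1] <= thresholds[2])
  if (v < thresholds[1]) "clustered"
  else if (v <= thresholds[2]) "random"
  else "ordered"
}

#' Dispersal-gradient correlation
#'
#' Pearson correlation of per-bundle nearest-neighbour distance against
#' depth from the organ periphery: near zero for a uniform dispersal,
#' clearly positive when spacing widens with depth (a gradient profile).
#'
#' @param values nearest-neighbour distances (um).
#' @param depths depths from the periphery (um), same length.
#' @return Pearson correlation coefficient.
#' @export
gradient_correlation <- function(values, depths) {
  if (length(values) != length(depths)) {
    stop("`values` and `depths` must have equal length", call. = FALSE)
  }
  if (length(values) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(values) == 0 || stats::sd(depths) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(values, depths)
}
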