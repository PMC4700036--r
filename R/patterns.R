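## Core pattern containers and neighbour geometry.
##
## Two measurement frames coexist in sectioned material: 1-D transects
## (ordered vein centres along a line or around a ring, e.g. leaf veins,
## peripheral bundles, sclerenchyma strands) and 2-D point patterns
## (medullary bundle centres in the stem plate). Coordinates are
## micrometres; transect positions are vein CENTRES, with edge-to-edge gaps
## derived from the optional width column.

#' One-dimensional transect of vein centres
#'
#' @param positions numeric vector of centre coordinates (um), strictly
#'   increasing, all within `[0, length]`.
#' @param length total extent of the transect (um): the line length, or the
#'   ring circumference for `topology = "ring"`.
#' @param topology `"line"` or `"ring"`; on a ring, distances wrap modulo
#'   `length`.
#' @param widths optional per-vein diameters (um), positive, one per
#'   position.
#' @return An object of class `"transect"`.
#' @export
#' @examples
#' transect(c(0, 1, 3), length = 4)
transect <- function(positions, length, topology = c("line", "ring"),
                     widths = NULL) {
  topology <- match.arg(topology)
  if (!is.numeric(positions) || anyNA(positions)) {
    stop("`positions` must be numeric with no missing values", call. = FALSE)
  }
  if (!is.numeric(length) || length(length) != 1L || !is.finite(length) ||
      length <= 0) {
    stop("`length` must be a single positive number", call. = FALSE)
  }
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("`positions` must be strictly increasing", call. = FALSE)
  }
  if (any(positions < 0) || any(positions > length)) {
    bad <- which(positions < 0 | positions > length)
    stop(sprintf("position %g (row %d) lies outside [0, %g]",
                 positions[bad[1L]], bad[1L], length), call. = FALSE)
  }
  if (!is.null(widths)) {
    if (!is.numeric(widths) || length(widths) != length(positions)) {
      stop("`widths` must be numeric, one per position", call. = FALSE)
    }
    if (anyNA(widths) || any(widths <= 0)) {
      stop("`widths` must all be positive", call. = FALSE)
    }
  }
  structure(list(positions = as.numeric(positions),
                 length = as.numeric(length),
                 topology = topology,
                 widths = if (!is.null(widths)) as.numeric(widths)),
            class = "transect")
}

#' @export
print.transect <- function(x, ...) {
  cat(sprintf("<transect> %d veins on a %s of %g um%s\n",
              length(x$positions), x$topology, x$length,
              if (is.null(x$widths)) "" else " (with widths)"))
  invisible(x)
}

#' Two-dimensional point pattern of bundle centres
#'
#' @param x,y numeric coordinate vectors (um).
#' @param area declared region area (um^2), or `NULL` to fall back on the
#'   convex-hull area when a density is needed.
#' @param labels optional per-point tags (e.g. depth from the stem
#'   periphery, um).
#' @return An object of class `"point_pattern"`.
#' @export
point_pattern <- function(x, y, area = NULL, labels = NULL) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y) ||
      anyNA(x) || anyNA(y)) {
    stop("`x` and `y` must be numeric vectors of equal length", call. = FALSE)
  }
  if (length(x) < 2L) stop("a pattern needs at least 2 points", call. = FALSE)
  if (anyDuplicated(cbind(x, y))) {
    dup <- which(duplicated(cbind(x, y)))[1L]
    stop(sprintf("duplicate point at row %d (%g, %g); coincident centres are digitisation errors",
                 dup, x[dup], y[dup]), call. = FALSE)
  }
  if (!is.null(area)) {
    if (!is.numeric(area) || length(area) != 1L || !is.finite(area) || area <= 0) {
      stop("declared `area` must be a single positive number", call. = FALSE)
    }
  }
  if (!is.null(labels) && length(labels) != length(x)) {
    stop("`labels` must have one entry per point", call. = FALSE)
  }
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 area = if (!is.null(area)) as.numeric(area),
                 labels = labels),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("<point_pattern> %d points, area %s\n", length(x$x),
              if (is.null(x$area)) "convex hull (on demand)"
              else sprintf("%g um^2", x$area)))
  invisible(x)
}

n_points <- function(p) length(p$x)

#' Region area of a point pattern
#'
#' Declared area when one was given, otherwise the convex-hull area of the
#' points (with a warning, since a hull underestimates the sampled region).
#'
#' @param p a [point_pattern()].
#' @return area in um^2.
#' @export
region_area <- function(p) {
  stopifnot(inherits(p, "point_pattern"))
  if (!is.null(p$area)) return(p$area)
  h <- grDevices::chull(p$x, p$y)
  xs <- p$x[h]; ys <- p$y[h]
  a <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  if (a <= 0) stop("convex hull of the pattern is degenerate", call. = FALSE)
  warning("no declared area; using the convex-hull area", call. = FALSE)
  a
}

#' Read a transect or 2-D pattern from a delimited file
#'
#' Accepts comma- or tab-separated files with a header. Transect files carry
#' columns `id, pos[, width]`; planar files carry `id, x, y[, width][, depth]`.
#' Geometry not present in the file (extent, topology, area) is supplied via
#' arguments.
#'
#' @param path file path.
#' @param dialect `"transect"` or `"pattern2d"`.
#' @param topology,length transect geometry (see [transect()]).
#' @param area declared region area for planar patterns (um^2; optional).
#' @return A [transect()] or [point_pattern()]; transect rows are sorted by
#'   position.
#' @export
read_pattern <- function(path, dialect = c("transect", "pattern2d"),
                         topology = "line", length = NULL, area = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- if (dialect == "transect") c("id", "pos") else c("id", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  num_cols <- setdiff(names(df), "id")
  for (cl in num_cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn)) {
        bad <- which(is.na(vn))[1L]
        stop(sprintf("non-numeric value '%s' in column '%s', row id %s",
                     v[bad], cl, df$id[bad]), call. = FALSE)
      }
      df[[cl]] <- vn
    }
  }
  if (dialect == "transect") {
    if (anyDuplicated(df$pos)) {
      dup <- df$id[duplicated(df$pos)][1L]
      stop(sprintf("duplicate position for id %s", dup), call. = FALSE)
    }
    if (is.null(length)) {
      stop("transect files need a total `length`", call. = FALSE)
    }
    ord <- order(df$pos)
    df <- df[ord, , drop = FALSE]
    tryCatch(
      transect(df$pos, length = length, topology = topology,
               widths = if ("width" %in% names(df)) df$width),
      error = function(e) {
        stop(sprintf("%s (ids: %s)", conditionMessage(e),
                     paste(utils::head(df$id, 3), collapse = ", ")),
             call. = FALSE)
      })
  } else {
    if (anyDuplicated(cbind(df$x, df$y))) {
      dup <- df$id[duplicated(cbind(df$x, df$y))][1L]
      stop(sprintf("duplicate (x, y) for id %s", dup), call. = FALSE)
    }
    point_pattern(df$x, df$y, area = area,
                  labels = if ("depth" %in% names(df)) df$depth)
  }
}

#' Nearest-neighbour distances along a transect
#'
#' Centre-to-centre distance from each vein to its closer flanking
#' neighbour. On a line the two end veins have a single neighbour; on a
#' ring the gap wraps modulo the circumference.
#'
#' @param t a [transect()].
#' @return numeric vector, one distance per vein (um).
#' @export
#' @examples
#' nn_distances_1d(transect(c(0, 1, 3), length = 4))        # 1 1 2
nn_distances_1d <- function(t) {
  stopifnot(inherits(t, "transect"))
  n <- length(t$positions)
  if (n < 2L) stop("need at least 2 positions", call. = FALSE)
  gaps <- diff(t$positions)
  if (t$topology == "ring") {
    wrap <- t$length - t$positions[n] + t$positions[1L]
    left <- c(wrap, gaps)          # gap to the left of vein i
    right <- c(gaps, wrap)         # gap to the right
    pmin(left, right)
  } else {
    pmin(c(Inf, gaps), c(gaps, Inf))
  }
}

#' Edge-to-edge gap distances along a transect
#'
#' The free space between consecutive veins: centre spacing minus the two
#' half-widths. This is the quantity the vein-insertion model works in.
#'
#' @param t a [transect()] with widths.
#' @return numeric vector of gaps (um); `n` gaps on a ring, `n - 1` on a
#'   line.
#' @export
edge_gap_distances <- function(t) {
  stopifnot(inherits(t, "transect"))
  if (is.null(t$widths)) stop("transect has no widths", call. = FALSE)
  n <- length(t$positions)
  if (n < 2L) stop("need at least 2 positions", call. = FALSE)
  centre <- diff(t$positions)
  halfw <- (t$widths[-n] + t$widths[-1L]) / 2
  gaps <- centre - halfw
  if (t$topology == "ring") {
    wrap <- (t$length - t$positions[n] + t$positions[1L]) -
      (t$widths[n] + t$widths[1L]) / 2
    gaps <- c(gaps, wrap)
  }
  if (any(gaps <= 0)) {
    stop(sprintf("overlapping veins: gap %d is %g um",
                 which(gaps <= 0)[1L], min(gaps)), call. = FALSE)
  }
  gaps
}

#' Delaunay adjacency of a planar pattern
#'
#' Neighbours are the endpoints of Delaunay triangulation edges, found by an
#' exhaustive empty-circumcircle scan (compiled; suitable for the few
#' hundred bundles of a section, guarded by `max_points`). Co-circular
#' quadruples (lattice data) are broken by a deterministic, tolerance-scaled
#' perturbation indexed by point order; when that happens the result carries
#' `attr(, "jittered") = TRUE`.
#'
#' @param p a [point_pattern()] with at least 3 non-collinear points.
#' @param max_points size guard for the cubic scan.
#' @return An object of class `"adjacency"`: a list of integer neighbour
#'   vectors, symmetric, no self-loops.
#' @export
delaunay_adjacency <- function(p, max_points = 400L) {
  stopifnot(inherits(p, "point_pattern"))
  n <- n_points(p)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  if (n > max_points) {
    stop(sprintf("pattern has %d points; the exhaustive scan is guarded at %d",
                 n, max_points), call. = FALSE)
  }
  xy <- cbind(p$x, p$y)
  if (.collinear(xy)) {
    stop("all points are collinear; analyse this pattern as a 1-D transect",
         call. = FALSE)
  }
  res <- .delaunay_scan(xy)
  jittered <- FALSE
  if (isTRUE(res$degenerate)) {
    # golden-angle offsets: deterministic, irrational direction per index,
    # magnitude far below any inter-point distance
    span <- max(diff(range(p$x)), diff(range(p$y)))
    eps <- 1e-8 * span
    ang <- (seq_len(n)) * 2.399963229728653
    res <- .delaunay_scan(xy + eps * cbind(cos(ang), sin(ang)))
    jittered <- TRUE
  }
  adj <- lapply(seq_len(n), function(i) which(res$adj[i, ]))
  if (any(lengths(adj) == 0L)) {
    stop("triangulation left an isolated point; pattern may be degenerate",
         call. = FALSE)
  }
  structure(adj, class = "adjacency", jittered = jittered)
}

.collinear <- function(xy) {
  v <- sweep(xy, 2, xy[1L, ])
  span <- max(abs(v))
  if (span == 0) return(TRUE)
  # reference direction: the point farthest from p1 (robust when p2 ~ p1)
  ref <- which.max(rowSums(v^2))
  cr <- v[ref, 1] * v[, 2] - v[ref, 2] * v[, 1]
  all(abs(cr) < 1e-9 * span^2)
}

#' @export
print.adjacency <- function(x, ...) {
  cat(sprintf("<adjacency> %d points, %d edges, mean degree %.2f%s\n",
              length(x), sum(lengths(x)) / 2, mean(lengths(x)),
              if (isTRUE(attr(x, "jittered"))) " (degeneracy broken by jitter)"
              else ""))
  invisible(x)
}

#' Edge list of an adjacency map
#'
#' @param adj an `"adjacency"` object.
#' @return two-column integer matrix of edges (`from < to`), ready for TSV
#'   export.
#' @export
adjacency_edges <- function(adj) {
  stopifnot(inherits(adj, "adjacency"))
  from <- rep.int(seq_along(adj), lengths(adj))
  to <- unlist(adj, use.names = FALSE)
  keep <- from < to
  cbind(from = from[keep], to = to[keep])
}

#' Nearest-neighbour distances of a planar pattern
#'
#' Per point, the minimum Euclidean distance among its Delaunay neighbours.
#' Because a point's true nearest neighbour is always a Delaunay neighbour,
#' this equals the global nearest-neighbour distance.
#'
#' @param p a [point_pattern()].
#' @param adj its adjacency from [delaunay_adjacency()].
#' @return numeric vector, one distance per point (um).
#' @export
nn_distances_2d <- function(p, adj) {
  stopifnot(inherits(p, "point_pattern"), inherits(adj, "adjacency"))
  if (length(adj) != n_points(p)) {
    stop("adjacency does not match the pattern", call. = FALSE)
  }
  vapply(seq_along(adj), function(i) {
    nb <- adj[[i]]
    if (length(nb) == 0L) stop("point ", i, " has no neighbours", call. = FALSE)
    sqrt(min((p$x[nb] - p$x[i])^2 + (p$y[nb] - p$y[i])^2))
  }, numeric(1))
}

#' Subset a pattern by Delaunay degree
#'
#' Retains the points whose number of Delaunay neighbours is at least
#' `min_degree` (used to separate well-embedded medullary bundles from
#' marginal ones).
#'
#' @inheritParams nn_distances_2d
#' @param min_degree minimum neighbour count to keep.
#' @return A `"point_pattern"` subset (possibly with fewer than 2 points);
#'   attributes `retained` and `discarded` carry the counts.
#' @export
filter_by_degree <- function(p, adj, min_degree) {
  stopifnot(inherits(p, "point_pattern"), inherits(adj, "adjacency"))
  keep <- lengths(adj) >= min_degree
  if (!any(keep)) {
    warning("no point has degree >= ", min_degree, "; returning empty subset",
            call. = FALSE)
  }
  out <- structure(list(x = p$x[keep], y = p$y[keep], area = p$area,
                        labels = if (!is.null(p$labels)) p$labels[keep]),
                   class = "point_pattern")
  attr(out, "retained") <- sum(keep)
  attr(out, "discarded") <- sum(!keep)
  message(sprintf("filter_by_degree: retained %d, discarded %d",
                  sum(keep), sum(!keep)))
  out
}
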