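## Seeded generators for every input class the analysis consumes.
##
## Each generator is a pure function of its arguments including a mandatory
## seed (one RNG stream per call, restored afterwards), and every emitted
## object passes its own class validation.

#' Generate a 1-D transect
#'
#' * `uniform`: perfectly even spacing (midpoint lattice on a line, so the
#'   R index is exactly 2 for both topologies);
#' * `jittered`: uniform plus truncated-Gaussian displacement (`sigma`,
#'   truncated at +/- 0.49 spacing so order is preserved);
#' * `poisson`: order statistics of `n` uniform draws (1-D CSR);
#' * `clustered`: pairs separated by `eps`, pair centres evenly spaced.
#'
#' @param kind generator kind.
#' @param n number of veins.
#' @param length transect extent (um).
#' @param seed RNG seed (mandatory).
#' @param topology `"line"` or `"ring"`.
#' @param sigma jitter standard deviation (um), `jittered` only.
#' @param eps within-pair separation (um), `clustered` only.
#' @param widths optional constant vein width to attach (um); rejected if
#'   the generated spacing cannot accommodate it.
#' @return A [transect()].
#' @export
gen_transect <- function(kind = c("uniform", "jittered", "poisson", "clustered"),
                         n, length, seed, topology = "line",
                         sigma = NULL, eps = NULL, widths = NULL) {
  kind <- match.arg(kind)
  stopifnot(n >= 2, length > 0)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  pos <- withr::with_seed(seed, {
    spacing <- length / n
    switch(kind,
      uniform = (seq_len(n) - 0.5) * spacing,
      jittered = {
        if (is.null(sigma)) sigma <- 0.1 * spacing
        base <- (seq_len(n) - 0.5) * spacing
        lim <- 0.49 * spacing
        jit <- rnorm(n, 0, sigma)
        while (any(abs(jit) > lim)) {           # truncated Gaussian
          redo <- abs(jit) > lim
          jit[redo] <- rnorm(sum(redo), 0, sigma)
        }
        base + jit
      },
      poisson = sort(runif(n, 0, length)),
      clustered = {
        if (is.null(eps)) eps <- spacing / 100
        n_pairs <- ceiling(n / 2)
        centres <- (seq_len(n_pairs) - 0.5) * (length / n_pairs)
        p <- sort(c(centres - eps / 2, centres + eps / 2))[seq_len(n)]
        p
      })
  })
  pos <- sort(pos)
  if (anyDuplicated(pos)) pos <- pos + seq_along(pos) * 1e-9  # CSR ties
  w <- NULL
  if (!is.null(widths)) {
    w <- rep_len(widths, n)
    if (any(diff(pos) <= (w[-n] + w[-1]) / 2)) {
      stop("generated spacing cannot accommodate the requested widths",
           call. = FALSE)
    }
  }
  transect(pos, length = length, topology = topology, widths = w)
}

#' Generate a 2-D point pattern
#'
#' * `poisson`: `n` uniform points in a square of the requested area (CSR);
#' * `hexagonal`: rows of a triangular lattice with spacing `s`; the
#'   declared area is `n * s^2 * sqrt(3)/2` (the lattice cell area), so the
#'   R index of the emitted pattern is the closed-form 2.149;
#' * `hardcore`: simple sequential inhibition (dart throwing with minimum
#'   distance `r_min`) in a disc or square;
#' * `gradient`: rows whose spacing grows linearly with depth (slope
#'   `slope` per um of depth) plus Gaussian jitter `noise_sd`; depth labels
#'   attached.
#'
#' @param kind generator kind.
#' @param n target point count.
#' @param seed RNG seed (mandatory).
#' @param area region area (um^2) for `poisson`/`hardcore` (square side
#'   `sqrt(area)`; `hardcore` uses a disc of that area when
#'   `region = "disc"`).
#' @param s lattice spacing (um), `hexagonal` only.
#' @param r_min inhibition distance (um), `hardcore` only; default 0.7 of
#'   the hexagonal spacing for `n` in `area` (moderate inhibition).
#' @param region `"square"` or `"disc"`, `hardcore` only.
#' @param max_tries placement attempts per point before giving up.
#' @param slope,noise_sd gradient parameters (`gradient` only): base row
#'   spacing grows as `s0 * (1 + slope * depth)` with jitter `noise_sd`.
#' @param s0 base spacing for `gradient` (um).
#' @return A [point_pattern()]; `gradient` carries depth labels.
#' @export
gen_pattern2d <- function(kind = c("poisson", "hexagonal", "hardcore", "gradient"),
                          n, seed, area = NULL, s = NULL, r_min = NULL,
                          region = c("square", "disc"), max_tries = 200L,
                          slope = 0, noise_sd = NULL, s0 = 10) {
  kind <- match.arg(kind)
  region <- match.arg(region)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(n >= 2)
  withr::with_seed(seed, {
    switch(kind,
      poisson = {
        if (is.null(area)) stop("`area` needed for poisson", call. = FALSE)
        side <- sqrt(area)
        point_pattern(runif(n, 0, side), runif(n, 0, side), area = area)
      },
      hexagonal = {
        if (is.null(s)) stop("`s` (spacing) needed for hexagonal", call. = FALSE)
        ncol <- ceiling(sqrt(n))
        rows <- ceiling(n / ncol)
        ij <- expand.grid(i = seq_len(ncol), j = seq_len(rows))
        x <- (ij$i - 1) * s + ifelse(ij$j %% 2 == 0, s / 2, 0)
        y <- (ij$j - 1) * s * sqrt(3) / 2
        keep <- seq_len(n)
        point_pattern(x[keep], y[keep], area = n * s^2 * sqrt(3) / 2)
      },
      hardcore = {
        if (is.null(area)) stop("`area` needed for hardcore", call. = FALSE)
        if (is.null(r_min)) r_min <- 0.7 * sqrt(2 * area / (sqrt(3) * n))
        side <- sqrt(area)
        R <- sqrt(area / pi)
        xs <- numeric(0); ys <- numeric(0)
        for (i in seq_len(n)) {
          placed <- FALSE
          for (try in seq_len(max_tries)) {
            if (region == "disc") {
              r <- R * sqrt(runif(1)); th <- runif(1, 0, 2 * pi)
              px <- r * cos(th); py <- r * sin(th)
            } else {
              px <- runif(1, 0, side); py <- runif(1, 0, side)
            }
            if (!length(xs) || all((xs - px)^2 + (ys - py)^2 >= r_min^2)) {
              xs <- c(xs, px); ys <- c(ys, py); placed <- TRUE; break
            }
          }
          if (!placed) {
            stop(sprintf("hardcore saturation: placed %d of %d points (r_min = %g)",
                         length(xs), n, r_min), call. = FALSE)
          }
        }
        point_pattern(xs, ys, area = area)
      },
      gradient = {
        if (is.null(noise_sd)) noise_sd <- 0.05 * s0
        ncol <- ceiling(sqrt(n))
        xs <- numeric(0); ys <- numeric(0); depth <- 0
        while (length(xs) < n) {
          local_s <- s0 * (1 + slope * depth)   # spacing grows with depth
          depth <- depth + local_s
          row_x <- (seq_len(ncol) - 0.5) * local_s + rnorm(ncol, 0, noise_sd)
          xs <- c(xs, row_x)
          ys <- c(ys, rep(depth, ncol) + rnorm(ncol, 0, noise_sd))
        }
        keep <- seq_len(n)
        point_pattern(xs[keep], ys[keep],
                      area = ncol * s0 * max(ys[keep]),
                      labels = ys[keep])
      })
  })
}

#' Simulate leaf gap growth and vein insertion
#'
#' Gaps grow synchronously by the factor `gp$a` per tick; a gap reaching
#' the doubling threshold `2 * d0 * m` is split by an [insertion_event()]
#' (larger daughter on a fair-coin side) into two daughters plus the new
#' vein width. Simulation starts from `n_init` gaps with log-uniform random
#' phases and stops once `n_events` insertions have occurred; the standing
#' gaps are emitted as a line transect of vein centres with constant
#' widths, so [edge_gap_distances()] recovers the simulated gaps exactly.
#'
#' @param gp a [growth_params()]; `d0 * m` is the post-split gap scale in
#'   um.
#' @param asymmetry larger-daughter fraction (see [insertion_event()]).
#' @param vein_width inserted vein width 2v, in the same units as
#'   `d0 * m`; the default 0 is the proliferating-cell analogue ("v is
#'   dropped"), while the measured bract configuration is `m = 11.41`
#'   (so `2d = 228.2` um) with `vein_width = 28`.
#' @param n_events number of insertions to simulate (>= 10).
#' @param seed RNG seed (mandatory).
#' @param n_init initial gap count.
#' @return A [transect()] with widths (`vein_width`, or a nominal 1e-6 um
#'   when `vein_width = 0` so the width bookkeeping stays valid).
#' @export
gen_growth_insertion <- function(gp, asymmetry = 114.3 / 200.2,
                                 vein_width = 0, n_events, seed,
                                 n_init = 64L) {
  stopifnot(inherits(gp, "growth_params"))
  if (n_events < 10) stop("`n_events` must be >= 10", call. = FALSE)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  d_min <- gp$d0 * gp$m
  trigger <- 2 * d_min
  if (vein_width >= trigger) {
    stop("`vein_width` must be below the doubling threshold", call. = FALSE)
  }
  gaps <- withr::with_seed(seed, {
    g <- d_min * exp(runif(n_init) * log(2))   # log-uniform phases
    events <- 0L
    while (events < n_events) {
      g <- g * gp$a
      hit <- which(g >= trigger)
      if (length(hit)) {
        big <- asymmetry * (g[hit] - vein_width)
        small <- (g[hit] - vein_width) - big
        side <- stats::rbinom(length(hit), 1L, 0.5) == 1L
        first <- ifelse(side, big, small)
        second <- ifelse(side, small, big)
        daughters <- as.vector(rbind(first, second))
        g <- c(g[-hit], daughters)
        events <- events + length(hit)
      }
    }
    g
  })
  w <- max(vein_width, 1e-6)
  centres <- w / 2 + cumsum(c(0, gaps[-length(gaps)] + w))
  transect(centres, length = centres[length(centres)] + w / 2 + gaps[length(gaps)],
           topology = "line", widths = rep(w, length(centres)))
}

#' Generate a reproducible batch of completed cell rows
#'
#' Wraps [simulate_row()] under one seeded RNG stream: identical arguments
#' give byte-identical rows.
#'
#' @param n_free free cells per row.
#' @param n_rows number of rows.
#' @param seed RNG seed (mandatory).
#' @return list of completed [cell_row()] objects.
#' @export
gen_cell_rows <- function(n_free, n_rows, seed) {
  if (n_rows < 1) stop("`n_rows` must be >= 1", call. = FALSE)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  withr::with_seed(seed, {
    lapply(seq_len(n_rows), function(i) simulate_row(n_free))
  })
}
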