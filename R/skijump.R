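## The leaf intervein-distance ("ski-jump") model.
##
## A gap between adjacent veins grows exponentially, d_t = d0 * a^t, until
## it doubles (a^T = 2); a new vein of width 2v is then inserted, splitting
## the parent gap 2d into a larger and a smaller daughter (2d -> dv + dv +
## 2v). Because the gap population doubles once per growth period, the
## frequency of a gap class decays as the reciprocal of its size:
## f_t = f0 * h^t with h = 1/a. Plotting f against d over one doubling gives
## a doubly-truncated negative exponential whose mass at 2d is half that at
## d -- the ski-jump shape.

#' Growth/decay parameters of the intervein model
#'
#' @param d0 smallest gap (arbitrary units or um).
#' @param a per-interval growth multiplier (growth rate + 1); must exceed 1.
#' @param T number of growth intervals per doubling (integer >= 1).
#' @param f0 initial frequency at `t = 0`.
#' @param h frequency decay multiplier; must equal `1/a` within `1e-4`
#'   (the growth/decay duality), and defaults to exactly `1/a`.
#' @param m scale factor from model units to um.
#' @return An object of class `"growth_params"`.
#' @export
#' @examples
#' growth_params()  # the worked bract example: 10 -> 20 units in 10 steps
growth_params <- function(d0 = 10, a = 1.07177, T = 10, f0 = 0.1145,
                          h = 1 / a, m = 1) {
  if (a <= 1) stop("`a` must exceed 1", call. = FALSE)
  if (abs(h - 1 / a) > 1e-4) {
    stop("`h` must be the reciprocal of `a` (within 1e-4)", call. = FALSE)
  }
  if (T < 1 || T != round(T)) stop("`T` must be a positive integer",
                                   call. = FALSE)
  if (d0 <= 0 || f0 <= 0 || m <= 0) {
    stop("`d0`, `f0` and `m` must be positive", call. = FALSE)
  }
  structure(list(d0 = d0, a = a, h = h, T = as.integer(T), f0 = f0, m = m),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("<growth_params> d0 = %g, a = %g, h = %g, T = %d, f0 = %g, m = %g\n",
              x$d0, x$a, x$h, x$T, x$f0, x$m))
  invisible(x)
}

#' Gap-size series d_t = d0 * a^t
#'
#' @param gp a [growth_params()].
#' @return numeric vector of length `T + 1` (t = 0..T), in model units.
#' @export
distance_series <- function(gp) {
  stopifnot(inherits(gp, "growth_params"))
  gp$d0 * gp$a^(0:gp$T)
}

#' Frequency series f_t = f0 * h^t
#'
#' @param gp a [growth_params()].
#' @return numeric vector of length `T + 1`.
#' @export
frequency_series <- function(gp) {
  stopifnot(inherits(gp, "growth_params"))
  gp$f0 * gp$h^(0:gp$T)
}

#' Binned distance distribution
#'
#' The shared output container of the distance models and of data
#' histograms: an ordered support with a normalised mass per class.
#'
#' @param support strictly increasing distance values (um or cell units).
#' @param mass non-negative weights, renormalised to sum to 1.
#' @return An object of class `"interval_distribution"`.
#' @export
interval_distribution <- function(support, mass) {
  if (length(support) != length(mass)) {
    stop("`support` and `mass` must have equal length", call. = FALSE)
  }
  if (is.unsorted(support, strictly = TRUE)) {
    stop("`support` must be strictly increasing", call. = FALSE)
  }
  if (any(mass < 0) || all(mass == 0)) {
    stop("`mass` must be non-negative with positive total", call. = FALSE)
  }
  structure(list(support = as.numeric(support),
                 mass = as.numeric(mass / sum(mass))),
            class = "interval_distribution")
}

#' @export
print.interval_distribution <- function(x, ...) {
  cat(sprintf("<interval_distribution> %d classes on [%g, %g]\n",
              length(x$support), min(x$support), max(x$support)))
  invisible(x)
}

#' The ski-jump intervein-distance pdf
#'
#' Support `d0 * a^t * m` for t = 0..T with mass proportional to
#' `f0 * h^t`. With `a^T = 2` the support spans exactly one doubling
#' `[d0*m, 2*d0*m]` and the raw mass at the top class is half that at the
#' bottom class.
#'
#' @param gp a [growth_params()].
#' @return An [interval_distribution()].
#' @export
skijump_pdf <- function(gp) {
  stopifnot(inherits(gp, "growth_params"))
  interval_distribution(distance_series(gp) * gp$m, frequency_series(gp))
}

#' Binomial smoothing of a distance distribution
#'
#' Replaces each class mass by the three-tap binomial kernel
#' `[q^2, 2pq, p^2]` gathered over the classes `t - 1, t, t + 1`
#' (the distance acquired at insertion is itself binomially dispersed, so
#' each nominal class leaks into its neighbours). Kernel taps that fall
#' outside the support are redirected to the nearest valid class; the
#' result is renormalised.
#'
#' @param dist an [interval_distribution()] with at least 3 classes.
#' @param p kernel probability in (0, 1); `p = q = 0.5` by default.
#' @return A smoothed [interval_distribution()].
#' @export
binomial_smooth <- function(dist, p = 0.5) {
  stopifnot(inherits(dist, "interval_distribution"))
  n <- length(dist$support)
  if (n < 3L) stop("need at least 3 support classes", call. = FALSE)
  if (p <= 0 || p >= 1) stop("`p` must lie in (0, 1)", call. = FALSE)
  q <- 1 - p
  w <- c(q^2, 2 * p * q, p^2)      # taps for source classes t-1, t, t+1
  idx <- function(i) pmin(pmax(i, 1L), n)   # reflect onto nearest valid class
  m <- dist$mass
  out <- w[1] * m[idx(seq_len(n) - 1L)] +
    w[2] * m +
    w[3] * m[idx(seq_len(n) + 1L)]
  interval_distribution(dist$support, out)
}

#' A vein-insertion event
#'
#' Bookkeeping of `2d -> dv + dv + 2v`: the parent gap is consumed by two
#' daughter gaps plus the width of the new vein, conserved exactly.
#'
#' @param parent_gap parent edge-to-edge gap 2d (um).
#' @param asymmetry fraction of the free space (`parent_gap - vein_width`)
#'   taken by the larger daughter, in `[0.5, 1)`.
#' @param vein_width width 2v of the inserted vein (um); `0` gives the pure
#'   bisection bookkeeping of proliferating cells.
#' @return An object of class `"insertion_event"` with fields `parent_gap`,
#'   `d_large`, `d_small`, `vein_width`.
#' @export
#' @examples
#' # the measured bract event: 228.2 -> 114.3 + 85.9 + 28
#' insertion_event(228.2, asymmetry = 114.3 / 200.2, vein_width = 28)
insertion_event <- function(parent_gap, asymmetry = 0.5, vein_width = 0) {
  if (vein_width < 0) stop("`vein_width` must be non-negative", call. = FALSE)
  if (vein_width >= parent_gap) {
    stop("`vein_width` must be smaller than the parent gap", call. = FALSE)
  }
  if (asymmetry < 0.5 || asymmetry >= 1) {
    stop("`asymmetry` must lie in [0.5, 1)", call. = FALSE)
  }
  free <- parent_gap - vein_width
  d_large <- asymmetry * free
  d_small <- free - d_large        # remainder: conservation is exact
  structure(list(parent_gap = parent_gap, d_large = d_large,
                 d_small = d_small, vein_width = vein_width),
            class = "insertion_event")
}

#' @export
print.insertion_event <- function(x, ...) {
  cat(sprintf("<insertion_event> %g -> %g + %g + %g\n",
              x$parent_gap, x$d_large, x$d_small, x$vein_width))
  invisible(x)
}

#' Goodness of fit of gap data to a model distribution
#'
#' Assigns each observed gap to the nearest model support class and
#' compares the empirical class masses with the model masses. Reports the
#' sum of squared mass differences (the `discrepancy`) and the maximum
#' absolute difference; no sampling distribution is claimed.
#'
#' @param data observed gap distances (um), at least 10.
#' @param model an [interval_distribution()].
#' @return An object of class `"gap_fit"` with fields `discrepancy` (sum of
#'   squared mass differences), `max_abs`, `n`, `empirical`, `model`.
#' @export
fit_distribution <- function(data, model) {
  stopifnot(inherits(model, "interval_distribution"))
  if (length(data) < 10L) stop("need at least 10 observations", call. = FALSE)
  s <- model$support
  cuts <- (s[-length(s)] + s[-1L]) / 2       # nearest-class boundaries
  cls <- findInterval(data, cuts) + 1L
  emp <- tabulate(cls, nbins = length(s)) / length(data)
  d <- emp - model$mass
  structure(list(discrepancy = sum(d^2), max_abs = max(abs(d)),
                 n = length(data), empirical = emp, model = model$mass,
                 support = s),
            class = "gap_fit")
}

#' @export
print.gap_fit <- function(x, ...) {
  cat(sprintf("<gap_fit> n = %d, discrepancy (SSE) = %.5f, max |diff| = %.4f\n",
              x$n, x$discrepancy, x$max_abs))
  invisible(x)
}
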