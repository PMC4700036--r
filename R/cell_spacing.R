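## The preprocambium cell-spacing (P/S/F) model.
##
## A file of undetermined cells flanked by P S ... S P: a free cell (F)
## spontaneously becomes a preprocambial cell (P) and converts its F
## neighbours to spacer cells (S). When no F remains, every pair of
## adjacent P is separated by exactly one or two S -- the one-celled and
## two-celled spacings whose relative frequency drives the "children's
## slide" distance distribution.

# ---- row representation -----------------------------------------------

#' A row of P/S/F cells
#'
#' @param cells character vector over `{"P", "S", "F"}`, beginning `P S`
#'   and ending `S P` (the fixed flank).
#' @return An object of class `"cell_row"`.
#' @export
cell_row <- function(cells) {
  if (!all(cells %in% c("P", "S", "F"))) {
    stop("cells must be 'P', 'S' or 'F'", call. = FALSE)
  }
  n <- length(cells)
  if (n < 4L || cells[1L] != "P" || cells[2L] != "S" ||
      cells[n - 1L] != "S" || cells[n] != "P") {
    stop("a row is flanked by P S ... S P", call. = FALSE)
  }
  structure(cells, class = "cell_row")
}

#' @export
print.cell_row <- function(x, ...) {
  cat("<cell_row> ", paste(unclass(x), collapse = ""), "\n", sep = "")
  invisible(x)
}

# interior coding used by the simulators/enumerators: 0 = F, 1 = P, 2 = S
.row_from_interior <- function(state) {
  cell_row(c("P", "S", c("F", "P", "S")[state + 1L], "S", "P"))
}

# counts of (one-celled, total) separations for an interior state with no F
.tally_interior <- function(state) {
  full <- c(1L, 2L, state, 2L, 1L)
  ppos <- which(full == 1L)
  runs <- diff(ppos) - 1L
  c(one = sum(runs == 1L), total = length(runs))
}

#' Tally one- and two-celled separations of a completed row
#'
#' Counts the maximal S-runs between adjacent P cells, including the runs
#' against the flanking P.
#'
#' @param row a completed [cell_row()] (no F remaining).
#' @return An object of class `"spacing_tally"`: `one_celled`,
#'   `two_celled`, `frequency` (one-celled share of all separations).
#' @export
#' @examples
#' tally(cell_row(c("P", "S", "P", "S", "P")))   # 2 one-celled
tally <- function(row) {
  stopifnot(inherits(row, "cell_row"))
  if (any(row == "F")) {
    stop("row still contains free cells; complete it first", call. = FALSE)
  }
  ppos <- which(unclass(row) == "P")
  runs <- diff(ppos) - 1L
  if (any(runs < 1L | runs > 2L)) {
    stop("invalid completed row: S-runs must have length 1 or 2",
         call. = FALSE)
  }
  spacing_tally(sum(runs == 1L), sum(runs == 2L))
}

spacing_tally <- function(one_celled, two_celled) {
  stopifnot(one_celled >= 0, two_celled >= 0, one_celled + two_celled > 0)
  structure(list(one_celled = one_celled, two_celled = two_celled,
                 frequency = one_celled / (one_celled + two_celled)),
            class = "spacing_tally")
}

#' @export
print.spacing_tally <- function(x, ...) {
  cat(sprintf("<spacing_tally> one-celled %g, two-celled %g, frequency %.4f\n",
              x$one_celled, x$two_celled, x$frequency))
  invisible(x)
}

# ---- stochastic model --------------------------------------------------

#' Simulate one row to completion
#'
#' Starting from `P S F^n S P`, repeatedly picks one remaining free cell
#' uniformly at random, converts it to P and its free neighbours to S,
#' until no F remains.
#'
#' @param n_free number of initial free cells (>= 1).
#' @param seed optional seed; when `NULL` the current RNG stream is used
#'   (callers such as [gen_cell_rows()] seed once for a whole batch).
#' @return A completed [cell_row()].
#' @export
simulate_row <- function(n_free, seed = NULL) {
  if (n_free < 1) stop("`n_free` must be >= 1", call. = FALSE)
  run <- function() .row_from_interior(.simulate_interior(n_free))
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

.simulate_interior <- function(n_free) {
  state <- integer(n_free)                 # all F
  repeat {
    pool <- which(state == 0L)
    if (!length(pool)) return(state)
    i <- pool[sample.int(length(pool), 1L)]
    state[i] <- 1L
    if (i > 1L && state[i - 1L] == 0L) state[i - 1L] <- 2L
    if (i < n_free && state[i + 1L] == 0L) state[i + 1L] <- 2L
  }
}

#' Pooled Monte Carlo spacing frequency
#'
#' Simulates `n_reps` independent rows and pools the separation counts
#' (sum of one-celled over sum of all separations across rows -- not a mean
#' of per-row ratios).
#'
#' @param n_free free cells per row.
#' @param n_reps number of rows.
#' @param seed RNG seed (mandatory; one stream for the whole batch).
#' @return A `"spacing_tally"`; attribute `per_row` holds the per-row count
#'   matrix, attribute `n_reps` the replicate count.
#' @export
monte_carlo_frequency <- function(n_free, n_reps, seed) {
  if (n_reps < 1) stop("`n_reps` must be >= 1", call. = FALSE)
  rows <- gen_cell_rows(n_free, n_reps, seed)
  counts <- t(vapply(rows, function(r) {
    tl <- tally(r)
    c(tl$one_celled, tl$one_celled + tl$two_celled)
  }, numeric(2)))
  out <- spacing_tally(sum(counts[, 1]), sum(counts[, 2] - counts[, 1]))
  attr(out, "per_row") <- counts
  attr(out, "n_reps") <- n_reps
  out
}

# ---- exact enumeration -------------------------------------------------

enumeration_result <- function(favorable, total, n_cases) {
  structure(list(favorable = favorable, total = total,
                 frequency = favorable / total, n_cases = n_cases),
            class = "enumeration_result")
}

#' @export
print.enumeration_result <- function(x, ...) {
  cat(sprintf("<enumeration_result> %g/%g = %.4f over %g cases\n",
              x$favorable, x$total, x$frequency, x$n_cases))
  invisible(x)
}

.check_guard <- function(n_free, guard) {
  if (n_free < 1) stop("`n_free` must be >= 1", call. = FALSE)
  if (n_free > guard) {
    stop(sprintf("n_free = %d exceeds the enumeration guard (%d); use monte_carlo_frequency()",
                 n_free, guard), call. = FALSE)
  }
}

#' Exact enumeration over conversion orders
#'
#' Depth-first enumeration of every feasible sequence of F-to-P choices
#' (cells turned S leave the pool), each order weighted equally; separation
#' counts are pooled over orders with exact integer arithmetic.
#'
#' @param n_free free cells (guarded: enumeration cost grows
#'   super-exponentially).
#' @param guard upper bound on `n_free`.
#' @return An `"enumeration_result"`: `favorable` (one-celled), `total`
#'   (all separations), `frequency`, `n_cases` (number of orders).
#' @export
#' @examples
#' enumerate_permutations(3)   # 6/8
enumerate_permutations <- function(n_free, guard = 12L) {
  .check_guard(n_free, guard)
  acc <- new.env(parent = emptyenv())
  acc$fav <- 0; acc$tot <- 0; acc$orders <- 0
  rec <- function(state) {
    pool <- which(state == 0L)
    if (!length(pool)) {
      tl <- .tally_interior(state)
      acc$fav <- acc$fav + tl[["one"]]
      acc$tot <- acc$tot + tl[["total"]]
      acc$orders <- acc$orders + 1
      return(invisible())
    }
    for (i in pool) {
      ns <- state
      ns[i] <- 1L
      if (i > 1L && ns[i - 1L] == 0L) ns[i - 1L] <- 2L
      if (i < length(ns) && ns[i + 1L] == 0L) ns[i + 1L] <- 2L
      rec(ns)
    }
  }
  rec(integer(n_free))
  enumeration_result(acc$fav, acc$tot, acc$orders)
}

#' Exact enumeration over distinct final configurations
#'
#' Enumerates the distinct completed P/S rows reachable from
#' `P S F^n S P`, weighting each configuration equally (the "combinations
#' not permutations" variant).
#'
#' @inheritParams enumerate_permutations
#' @return An `"enumeration_result"`; `n_cases` is the number of distinct
#'   configurations.
#' @export
#' @examples
#' enumerate_combinations(3)   # 3/5
enumerate_combinations <- function(n_free, guard = 12L) {
  .check_guard(n_free, guard)
  seen <- new.env(parent = emptyenv())
  rec <- function(state) {
    pool <- which(state == 0L)
    if (!length(pool)) {
      assign(paste(state, collapse = ""), state, envir = seen)
      return(invisible())
    }
    for (i in pool) {
      ns <- state
      ns[i] <- 1L
      if (i > 1L && ns[i - 1L] == 0L) ns[i - 1L] <- 2L
      if (i < length(ns) && ns[i + 1L] == 0L) ns[i + 1L] <- 2L
      rec(ns)
    }
  }
  rec(integer(n_free))
  configs <- as.list(seen)
  counts <- vapply(configs, .tally_interior, c(one = 0, total = 0))
  enumeration_result(sum(counts["one", ]), sum(counts["total", ]),
                     length(configs))
}

#' Dynamics-exact expected spacing frequency
#'
#' The probability-weighted counterpart of [enumerate_permutations()]:
#' each conversion order carries the product of `1 / |remaining F|` at
#' every step (the law of the stochastic model), and the result is the
#' ratio of expected pooled counts. This is the exact value that
#' [monte_carlo_frequency()] converges to, and it differs from the
#' equal-weight order enumeration from `n_free = 4` upward.
#'
#' @inheritParams enumerate_permutations
#' @return An `"enumeration_result"` whose `favorable`/`total` are expected
#'   counts (not integers); `n_cases` counts the orders visited.
#' @export
dynamics_exact_frequency <- function(n_free, guard = 12L) {
  .check_guard(n_free, guard)
  acc <- new.env(parent = emptyenv())
  acc$fav <- 0; acc$tot <- 0; acc$orders <- 0
  rec <- function(state, prob) {
    pool <- which(state == 0L)
    if (!length(pool)) {
      tl <- .tally_interior(state)
      acc$fav <- acc$fav + prob * tl[["one"]]
      acc$tot <- acc$tot + prob * tl[["total"]]
      acc$orders <- acc$orders + 1
      return(invisible())
    }
    p <- prob / length(pool)
    for (i in pool) {
      ns <- state
      ns[i] <- 1L
      if (i > 1L && ns[i - 1L] == 0L) ns[i - 1L] <- 2L
      if (i < length(ns) && ns[i + 1L] == 0L) ns[i + 1L] <- 2L
      rec(ns, p)
    }
  }
  rec(integer(n_free), 1)
  enumeration_result(acc$fav, acc$tot, acc$orders)
}

# ---- distance conversion and the slide pdf -----------------------------

#' Convert a spacer count to a centre-to-centre distance
#'
#' A one-celled separation spans one spacer plus two half preprocambial
#' cells (1 + 1/2 + 1/2 = 2 cells); a two-celled separation spans 3 cells.
#'
#' @param cell_count 1 or 2.
#' @return distance in cell units (`cell_count + 1`).
#' @export
spacing_to_distance <- function(cell_count) {
  if (!all(cell_count %in% c(1, 2))) {
    stop("the model only produces 1- or 2-celled separations", call. = FALSE)
  }
  cell_count + 1
}

#' The "children's slide" binomial spacing pdf
#'
#' Cell-counted centre-to-centre spacings compose `k` binomial choices
#' between the small (two-cell) and large (three-cell) unit:
#' mass `C(k, c) * p_small^(k - c) * (1 - p_small)^c` at distance
#' `(2 + c) * m` for `c = 0..k`. Unlike the ski jump, the frequency at the
#' longest distance is near zero.
#'
#' @param k number of binomial classes minus 1 (>= 1).
#' @param p_small probability of the small spacing (the one-celled
#'   frequency, ~0.69 in the model's own dynamics).
#' @param m micrometres per cell unit.
#' @return An [interval_distribution()] on `(2:(2 + k)) * m`.
#' @export
#' @examples
#' slide_pdf(1, p_small = 0.69, m = 1)   # masses 0.69, 0.31
slide_pdf <- function(k, p_small = 0.685, m = 1) {
  if (k < 1 || k != round(k)) stop("`k` must be a positive integer",
                                   call. = FALSE)
  if (p_small <= 0 || p_small >= 1) stop("`p_small` must lie in (0, 1)",
                                         call. = FALSE)
  if (m <= 0) stop("`m` must be positive", call. = FALSE)
  cc <- 0:k
  interval_distribution((2 + cc) * m, stats::dbinom(cc, k, 1 - p_small))
}
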