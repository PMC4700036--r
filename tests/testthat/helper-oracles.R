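# Independent oracles used to freeze expected values. Each reimplements the
# target quantity by a different route than the package code.

# all-pairs nearest-neighbour distances (oracle for the Delaunay route)
brute_nn <- function(p) {
  n <- length(p$x)
  d <- as.matrix(stats::dist(cbind(p$x, p$y)))
  diag(d) <- Inf
  unname(apply(d, 1, min))
}

# brute-force Delaunay edges in plain R: a triangle is kept iff its
# circumcircle holds no other point strictly inside (tiny patterns only)
brute_delaunay_edges <- function(x, y) {
  n <- length(x)
  edges <- matrix(integer(0), ncol = 2)
  for (tri in utils::combn(n, 3, simplify = FALSE)) {
    i <- tri[1]; j <- tri[2]; k <- tri[3]
    abx <- x[j] - x[i]; aby <- y[j] - y[i]
    acx <- x[k] - x[i]; acy <- y[k] - y[i]
    d <- 2 * (abx * acy - aby * acx)
    if (abs(d) < 1e-12) next
    ab2 <- abx^2 + aby^2; ac2 <- acx^2 + acy^2
    ux <- (acy * ab2 - aby * ac2) / d
    uy <- (abx * ac2 - acx * ab2) / d
    r2 <- ux^2 + uy^2
    cx <- x[i] + ux; cy <- y[i] + uy
    others <- setdiff(seq_len(n), tri)
    if (all((x[others] - cx)^2 + (y[others] - cy)^2 >= r2 * (1 - 1e-9))) {
      edges <- rbind(edges, rbind(sort(c(i, j)), sort(c(j, k)), sort(c(i, k))))
    }
  }
  unique(edges)
}

# Closed-form oracle for the equal-weight order enumeration: the feasible
# conversion orders are exactly the orderings of maximal independent
# (dominating) subsets of the path graph on n free cells, so the pooled
# counts are sum over such subsets of k! times the subset's run tallies.
mis_enumeration_oracle <- function(n_free) {
  fav <- 0; tot <- 0
  for (k in seq_len(ceiling(n_free / 2))) {
    sets <- utils::combn(n_free, k, simplify = FALSE)
    for (S in sets) {
      if (k > 1 && any(diff(S) == 1)) next           # independence
      covered <- unique(c(S, S - 1L, S + 1L))
      if (!all(seq_len(n_free) %in% covered)) next   # domination
      ppos <- c(-1L, S, n_free + 2L)                 # flank P at -1, n+2
      runs <- diff(ppos) - 1L
      w <- factorial(k)
      fav <- fav + w * sum(runs == 1L)
      tot <- tot + w * length(runs)
    }
  }
  c(favorable = fav, total = tot)
}

# ratio-estimator standard error of a pooled frequency from per-row counts
pooled_freq_se <- function(per_row) {
  ones <- per_row[, 1]; tots <- per_row[, 2]
  R <- sum(ones) / sum(tots)
  n <- nrow(per_row)
  resid <- ones - R * tots
  sqrt(n / (n - 1) * sum(resid^2)) / sum(tots)
}
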