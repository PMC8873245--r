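# Independent brute-force oracles. These recompute, by enumeration or
# direct formula, the quantities the package computes algorithmically;
# they share no code path with the implementation they check.

# total within-segment SSE of a tiling, on the SAME per-element
# standardisation the segmenter uses (z-scores over the whole series)
oracle_tiling_cost <- function(x, breaks) {
  z <- scale(x)
  z[!is.finite(z)] <- 0
  bounds <- c(0, breaks, nrow(x))
  cost <- 0
  for (s in seq_len(length(bounds) - 1)) {
    seg <- z[(bounds[s] + 1):bounds[s + 1], , drop = FALSE]
    cost <- cost + sum(sweep(seg, 2, colMeans(seg))^2)
  }
  cost
}

# exhaustive optimum over all tilings into k segments with min_seg_len;
# returns 0-based breakpoints of the minimal-cost tiling (ties: first in
# lexicographic order, matching the smallest-index tie rule)
oracle_exhaustive_segmentation <- function(x, k, min_seg_len) {
  n <- nrow(x)
  if (k == 1) return(integer(0))
  cand <- seq(min_seg_len, n - min_seg_len)
  combs <- utils::combn(cand, k - 1, simplify = FALSE)
  ok <- vapply(combs, function(b) all(diff(c(0, b, n)) >= min_seg_len),
               logical(1))
  combs <- combs[ok]
  costs <- vapply(combs, function(b) oracle_tiling_cost(x, b), numeric(1))
  combs[[which.min(costs)]]
}

# pseudo-F computed directly from group centroids in coordinate space
# (for Euclidean distances the distance-based and centroid-based
# partitionings coincide)
oracle_pseudo_f <- function(x, g) {
  x <- as.matrix(x)
  g <- factor(g)
  grand <- colMeans(x)
  ss_within <- 0
  ss_among <- 0
  for (lv in levels(g)) {
    xs <- x[g == lv, , drop = FALSE]
    ctr <- colMeans(xs)
    ss_within <- ss_within + sum(sweep(xs, 2, ctr)^2)
    ss_among <- ss_among + nrow(xs) * sum((ctr - grand)^2)
  }
  a <- nlevels(g)
  (ss_among / (a - 1)) / (ss_within / (nrow(x) - a))
}

# exact permutation p-value for two groups by enumerating all assignments
# of group labels (combn over which rows carry label A)
oracle_exact_permanova_p <- function(x, g) {
  g <- factor(g)
  stopifnot(nlevels(g) == 2)
  n <- length(g)
  na <- sum(g == levels(g)[1])
  f_obs <- oracle_pseudo_f(x, g)
  sets <- utils::combn(n, na, simplify = FALSE)
  f_all <- vapply(sets, function(idx) {
    gp <- factor(ifelse(seq_len(n) %in% idx, levels(g)[1], levels(g)[2]))
    oracle_pseudo_f(x, gp)
  }, numeric(1))
  mean(f_all >= f_obs - 1e-12)
}

# moving-median smoothing + interior argmax, written independently
oracle_core_index <- function(mn, k, edge_frac) {
  n <- length(mn)
  half <- (k - 1) / 2
  sm <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    stats::median(mn[lo:hi])
  }, numeric(1))
  drop_n <- floor(edge_frac * n)
  interior <- (drop_n + 1):(n - drop_n)
  interior[which.max(sm[interior])]
}
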