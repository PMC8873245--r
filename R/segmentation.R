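#' Chronological segmentation of a multivariate transect
#'
#' Splits an oriented (core-to-edge) multivariate concentration series into
#' contiguous partitions at elemental-signature discontinuities, by greedy
#' recursive binary partitioning: at each step the breakpoint minimising the
#' total within-segment sum of squared Euclidean deviations from segment
#' means is taken, and splitting stops when the best split's relative cost
#' reduction falls below `penalty`, when `max_partitions` is reached, or
#' when no admissible split respects `min_seg_len`.
#'
#' The split cost is computed on per-element z-scores (each element centred
#' and scaled by its own mean and standard deviation over the fish's
#' series), so that elements spanning different orders of magnitude
#' contribute comparably; partition fingerprints are averaged on the
#' original, unstandardised concentrations. Equal-cost breakpoints are
#' broken toward the smallest index. Partitions use the half-open, 0-based
#' index convention `[start, end)` and tile the series exactly: the first
#' partition starts directly after the core, the last ends at capture.
#'
#' @param transect an oriented [elemental_transect()], or a plain numeric
#'   matrix (points x elements) already restricted to the working element
#'   subset.
#' @param elements optional element subset to segment on; fingerprints are
#'   still reported for all columns present.
#' @param min_seg_len minimum points per partition (>= 2).
#' @param max_partitions cap on the number of partitions.
#' @param penalty minimum relative cost reduction for a split to be
#'   accepted.
#' @return An object of class `partition_set`: `fish_id`, `partitions`
#'   (data frame with 0-based `start`, `end`, `n_points` and, when position
#'   data are available, `start_um`/`end_um`), `fingerprints` (partition x
#'   element matrix of means on the original scale), `cost` (final total
#'   within-segment cost on the standardised series), `breakpoints`
#'   (0-based interior cut indices) and the parameters used.
#' @export
segment_transect <- function(transect, elements = NULL, min_seg_len = 5L,
                             max_partitions = 6L, penalty = 0.05) {
  if (inherits(transect, "elemental_transect")) {
    if (transect$orientation != "core_to_edge")
      stop("transect of fish ", transect$fish_id,
           " must be oriented core_to_edge before segmentation",
           call. = FALSE)
    full <- transect$concentrations
    fish_id <- transect$fish_id
    positions <- transect$positions
  } else {
    full <- as.matrix(transect)
    fish_id <- NA_character_
    positions <- NULL
  }
  if (is.null(elements)) elements <- colnames(full)
  if (is.null(elements)) elements <- seq_len(ncol(full))
  if (!length(elements)) stop("empty element subset", call. = FALSE)
  x <- full[, elements, drop = FALSE]
  n <- nrow(x)
  min_seg_len <- max(2L, as.integer(min_seg_len))

  z <- scale(x)
  z[!is.finite(z)] <- 0  # constant (sd = 0) or single-point columns

  # prefix sums for O(1) segment cost: cost[a,b) = sum z^2 - sum(z)^2/n
  cs <- apply(z, 2, cumsum)
  cs2 <- apply(z * z, 2, cumsum)
  cs <- rbind(0, cs); cs2 <- rbind(0, cs2)
  seg_cost <- function(a, b) {  # 0-based half-open [a, b)
    s <- cs[b + 1L, ] - cs[a + 1L, ]
    s2 <- cs2[b + 1L, ] - cs2[a + 1L, ]
    sum(s2 - s * s / (b - a))
  }
  best_split <- function(a, b) {  # best interior cut k in (a, b)
    if (b - a < 2L * min_seg_len) return(NULL)
    ks <- seq(a + min_seg_len, b - min_seg_len)
    costs <- vapply(ks, function(k) seg_cost(a, k) + seg_cost(k, b),
                    numeric(1))
    k <- ks[which.min(costs)]  # which.min: first minimum = smallest index
    list(k = k, cost = min(costs))
  }

  segs <- list(c(0L, n))  # half-open [start, end)
  repeat {
    if (length(segs) >= max_partitions) break
    total <- sum(vapply(segs, function(s) seg_cost(s[1], s[2]), numeric(1)))
    cand <- lapply(segs, function(s) best_split(s[1], s[2]))
    gains <- vapply(seq_along(segs), function(i) {
      if (is.null(cand[[i]])) return(-Inf)
      seg_cost(segs[[i]][1], segs[[i]][2]) - cand[[i]]$cost
    }, numeric(1))
    if (all(!is.finite(gains)) || max(gains) <= 0) break
    rel <- if (total > 0) max(gains) / total else 0
    if (total == 0 || rel < penalty) break
    i <- which.max(gains)
    k <- cand[[i]]$k
    segs <- append(segs[-i],
                   list(c(segs[[i]][1], k), c(k, segs[[i]][2])), after = i - 1L)
  }
  starts <- vapply(segs, `[`, 0L, 1)
  ord <- order(starts)
  segs <- segs[ord]

  part <- data.frame(
    start = vapply(segs, `[`, 0L, 1),
    end = vapply(segs, `[`, 0L, 2))
  part$n_points <- part$end - part$start
  if (!is.null(positions)) {
    part$start_um <- positions[part$start + 1L]
    part$end_um <- positions[part$end]
  }
  fp <- do.call(rbind, lapply(segs, function(s)
    colMeans(full[(s[1] + 1L):s[2], , drop = FALSE])))
  colnames(fp) <- colnames(full)
  cost <- sum(vapply(segs, function(s) seg_cost(s[1], s[2]), numeric(1)))
  structure(
    list(fish_id = fish_id, partitions = part, fingerprints = fp,
         cost = cost,
         breakpoints = part$start[-1],
         params = list(elements = elements, min_seg_len = min_seg_len,
                       max_partitions = max_partitions, penalty = penalty),
         scaled_center = attr(z, "scaled:center"),
         scaled_scale = attr(z, "scaled:scale")),
    class = "partition_set")
}

#' @export
print.partition_set <- function(x, ...) {
  cat("<partition_set> fish ", x$fish_id, ": ", nrow(x$partitions),
      " partition(s), cost ", signif(x$cost, 4), "\n", sep = "")
  print(x$partitions)
  invisible(x)
}

#' Partition fingerprints
#'
#' Per-partition arithmetic means of the original concentrations. The
#' point-count-weighted mean of the rows reconstructs the whole-series mean
#' exactly (conservation identity).
#'
#' @param partition_set a [segment_transect()] result.
#' @param series optional matrix to average over (defaults to the one the
#'   partition set was built from, whose fingerprints are stored).
#' @return Matrix (partition x element).
#' @export
partition_fingerprints <- function(partition_set, series = NULL) {
  if (is.null(series)) return(partition_set$fingerprints)
  series <- as.matrix(series)
  part <- partition_set$partitions
  fp <- do.call(rbind, lapply(seq_len(nrow(part)), function(i)
    colMeans(series[(part$start[i] + 1L):part$end[i], , drop = FALSE])))
  colnames(fp) <- colnames(series)
  fp
}
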