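#' One-way PERMANOVA on elemental fingerprints
#'
#' Permutational multivariate analysis of variance on the Euclidean
#' distance matrix of edge fingerprints. The pseudo-F follows the
#' distance-based partitioning of total sum of squares into among- and
#' within-group components; significance is obtained by freely permuting
#' the group labels. When the number of distinct label arrangements does
#' not exceed `n_permutations`, all of them are enumerated and the p-value
#' is exact (`#\{F_perm >= F_obs\} / N_arrangements`, identity included);
#' otherwise `n_permutations` random permutations are drawn and
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_permutations)`.
#'
#' @param fingerprints numeric matrix or data frame (observations x
#'   elements).
#' @param groups group labels, length `nrow(fingerprints)`.
#' @param n_permutations number of random permutations (default 9999,
#'   giving p-value resolution 1e-4).
#' @param seed integer seed for the permutation stream.
#' @return Object of class `permanova_result`: `pseudo_F`, `p_value`,
#'   `n_permutations` (actually used), `exact` (enumeration used),
#'   `group_sizes`, `df_among`, `df_within`, `ss_among`, `ss_within`.
#' @export
permanova <- function(fingerprints, groups, n_permutations = 9999L,
                      seed = 1L) {
  x <- as.matrix(as.data.frame(fingerprints))
  storage.mode(x) <- "double"
  g <- factor(groups)
  n <- nrow(x)
  stopifnot(length(g) == n)
  if (nlevels(g) < 2) stop("need at least two groups", call. = FALSE)
  sizes <- table(g)
  if (any(sizes < 2))
    stop("group(s) of size 1: ", paste(names(sizes)[sizes < 2],
                                       collapse = ", "), call. = FALSE)
  d2 <- as.matrix(stats::dist(x))^2
  a <- nlevels(g)
  g0 <- as.integer(g) - 1L

  n_distinct <- multiset_perm_count(as.integer(sizes))
  if (!is.na(n_distinct) && n_distinct <= n_permutations) {
    perms <- multiset_permutations(g0)
    f_all <- permanova_f_cpp(d2, perms, a)
    f_obs <- permanova_f_cpp(d2, matrix(g0, ncol = 1), a)[1]
    p <- mean(f_all >= f_obs - 1e-12)
    n_used <- ncol(perms)
    exact <- TRUE
  } else {
    set.seed(as.integer(seed))
    perms <- vapply(seq_len(n_permutations), function(i) sample(g0),
                    integer(n))
    f_obs <- permanova_f_cpp(d2, matrix(g0, ncol = 1), a)[1]
    f_all <- permanova_f_cpp(d2, perms, a)
    p <- (1 + sum(f_all >= f_obs - 1e-12)) / (1 + n_permutations)
    n_used <- n_permutations
    exact <- FALSE
  }
  ss_tot <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (lv in levels(g)) {
    idx <- which(g == lv)
    ss_within <- ss_within +
      sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  structure(
    list(pseudo_F = f_obs, p_value = p, n_permutations = n_used,
         exact = exact, group_sizes = as.integer(sizes),
         groups = levels(g), df_among = a - 1L, df_within = n - a,
         ss_among = ss_tot - ss_within, ss_within = ss_within),
    class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA (Euclidean): pseudo-F = ", signif(x$pseudo_F, 6),
      ", p = ", format(x$p_value, digits = 4),
      if (x$exact) " (exact enumeration)" else
        paste0(" (", x$n_permutations, " permutations)"),
      "\n", sep = "")
  invisible(x)
}

#' Pairwise post hoc PERMANOVA comparisons
#'
#' Runs a two-group PERMANOVA for every unordered pair of groups and
#' reports `t = sqrt(pseudo-F)` with the permutation p-value. The
#' significance flag is keyed to the unadjusted p-value at `alpha`
#' (matching the usual presentation of post hoc PERMANOVA tables);
#' Holm-adjusted p-values are reported alongside.
#'
#' @inheritParams permanova
#' @param alpha significance level for the flag.
#' @return Data frame of class `pairwise_permanova`: `group_a`, `group_b`,
#'   `t`, `p_perm`, `p_holm`, `significant`.
#' @export
pairwise_permanova <- function(fingerprints, groups,
                               n_permutations = 9999L, seed = 1L,
                               alpha = 0.05) {
  g <- factor(groups)
  lv <- levels(g)
  prs <- utils::combn(lv, 2)
  x <- as.data.frame(fingerprints)
  rows <- lapply(seq_len(ncol(prs)), function(i) {
    sel <- g %in% prs[, i]
    r <- permanova(x[sel, , drop = FALSE], droplevels(g[sel]),
                   n_permutations = n_permutations,
                   seed = as.integer(seed) + i)
    data.frame(group_a = prs[1, i], group_b = prs[2, i],
               t = sqrt(r$pseudo_F), p_perm = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p_perm, "holm")
  out$significant <- out$p_perm < alpha
  class(out) <- c("pairwise_permanova", "data.frame")
  out
}

#' Per-element habitat comparisons
#'
#' Rank-based (Kruskal-Wallis) test of each element's concentration across
#' habitat groups, with pairwise Wilcoxon follow-ups (Holm-adjusted) and a
#' directional summary naming the group with the highest median.
#'
#' @param fingerprints data frame (observations x elements).
#' @param groups habitat labels.
#' @param alpha significance level.
#' @return Data frame: `element`, `chi_sq`, `df`, `p_value`, `significant`,
#'   `highest_group`, `direction`; attribute `pairwise` (per-element list
#'   of Holm-adjusted Wilcoxon p matrices).
#' @export
per_element_tests <- function(fingerprints, groups, alpha = 0.05) {
  x <- as.data.frame(fingerprints)
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least two groups", call. = FALSE)
  pw <- list()
  rows <- lapply(names(x), function(e) {
    kt <- stats::kruskal.test(x[[e]], g)
    med <- tapply(x[[e]], g, stats::median)
    hi <- names(med)[which.max(med)]
    lo <- names(med)[which.min(med)]
    pw[[e]] <<- suppressWarnings(
      stats::pairwise.wilcox.test(x[[e]], g, p.adjust.method = "holm",
                                  exact = FALSE)$p.value)
    data.frame(element = e, chi_sq = unname(kt$statistic),
               df = unname(kt$parameter), p_value = kt$p.value,
               significant = kt$p.value < alpha,
               highest_group = hi,
               direction = paste(hi, ">", lo),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "pairwise") <- pw
  out
}

#' Seasonal-effect check per location
#'
#' One PERMANOVA per sampling location with season as the grouping term,
#' to verify that within-location elemental signatures are stable across
#' the sampling campaign. Locations with fewer than two seasons, or with
#' any season represented by fewer than two fish, are skipped with a
#' warning.
#'
#' @param edges edge-signature table with `site_id`, `season` and element
#'   columns.
#' @param elements element columns; default all present.
#' @inheritParams permanova
#' @return Data frame: `site_id`, `pseudo_F`, `p_value`, `n_fish`,
#'   `n_seasons`, `significant`.
#' @export
season_effect_test <- function(edges, elements = NULL,
                               n_permutations = 9999L, seed = 1L,
                               alpha = 0.05) {
  if (is.null(elements)) elements <- element_columns(edges)
  rows <- list()
  for (s in unique(edges$site_id)) {
    sub <- edges[edges$site_id == s, , drop = FALSE]
    tab <- table(sub$season)
    tab <- tab[!is.na(names(tab))]
    if (length(tab) < 2 || any(tab < 2)) {
      warning("site ", s, " under-replicated across seasons; skipped",
              call. = FALSE)
      next
    }
    r <- permanova(sub[elements], sub$season,
                   n_permutations = n_permutations, seed = seed)
    rows[[s]] <- data.frame(site_id = s, pseudo_F = r$pseudo_F,
                            p_value = r$p_value, n_fish = nrow(sub),
                            n_seasons = length(tab),
                            significant = r$p_value < alpha,
                            stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(site_id = character(), pseudo_F = numeric(),
                      p_value = numeric(), n_fish = integer(),
                      n_seasons = integer(), significant = logical()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# number of distinct arrangements of a label multiset; NA on overflow
multiset_perm_count <- function(sizes) {
  lg <- lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1))
  if (lg > log(.Machine$integer.max)) return(NA_real_)
  round(exp(lg))
}

# all distinct arrangements of the label vector g0 (0-based integers),
# returned as an n x N matrix (each column one arrangement)
multiset_permutations <- function(g0) {
  n <- length(g0)
  counts <- tabulate(g0 + 1L)
  res <- list()
  rec <- function(prefix, counts) {
    if (length(prefix) == n) {
      res[[length(res) + 1L]] <<- prefix
      return(invisible())
    }
    for (k in seq_along(counts)) {
      if (counts[k] > 0L) {
        counts[k] <- counts[k] - 1L
        rec(c(prefix, k - 1L), counts)
        counts[k] <- counts[k] + 1L
      }
    }
  }
  rec(integer(0), counts)
  matrix(unlist(res), nrow = n)
}
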