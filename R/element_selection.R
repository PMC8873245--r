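#' Rank elements by site-discrimination importance within a river system
#'
#' Fits an ensemble classifier predicting capture site from otolith-edge
#' fingerprints within one river system, and scores each element by its
#' permutation importance (percent mean decrease in accuracy), averaged
#' over `n_repeats` independently seeded fits.
#'
#' @param edges data frame of edge signatures for one river system:
#'   `site_id` plus one numeric column per element (see
#'   [edge_signature_table()]).
#' @param river_system label recorded in the output.
#' @param elements element columns to score; defaults to all numeric
#'   non-metadata columns.
#' @param n_repeats independently seeded ensemble fits to average over.
#' @param ntree trees per fit.
#' @param seed integer seed; repeats use `seed + 1, ..., seed + n_repeats`.
#' @return Object of class `importance_table`: data frame with
#'   `river_system`, `element`, `mean_decrease_accuracy` (percent, averaged
#'   over repeats) and `sd` (dispersion over repeats), sorted by decreasing
#'   importance.
#' @export
rank_element_importance <- function(edges, river_system = NA_character_,
                                    elements = NULL, n_repeats = 10L,
                                    ntree = 500L, seed = 1L) {
  if (is.null(elements)) elements <- element_columns(edges)
  sites <- factor(edges$site_id)
  if (nlevels(sites) < 2)
    stop("importance is undefined for a single-site river system",
         call. = FALSE)
  if (min(table(sites)) < 2)
    stop("need at least two fish per site", call. = FALSE)
  x <- edges[elements]
  scores <- matrix(NA_real_, n_repeats, length(elements),
                   dimnames = list(NULL, elements))
  for (r in seq_len(n_repeats)) {
    set.seed(as.integer(seed) + r)
    fit <- oto_rf(x, sites, ntree = ntree, importance = TRUE)
    scores[r, ] <- fit$importance$mean_decrease_accuracy
  }
  out <- data.frame(river_system = river_system, element = elements,
                    mean_decrease_accuracy = colMeans(scores),
                    sd = apply(scores, 2, stats::sd),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$mean_decrease_accuracy), ]
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Select the working element subset across river systems
#'
#' An element is excluded only when its mean-decrease-in-accuracy score
#' falls below `threshold` percent in *every* river system; an element
#' informative anywhere is kept everywhere.
#'
#' @param importance_tables list of [rank_element_importance()] results,
#'   one per river system, covering identical element sets.
#' @param threshold percent mean decrease in accuracy (default 5).
#' @return List with `retained` and `excluded` element character vectors
#'   and `scores` (element x river system matrix).
#' @export
select_elements <- function(importance_tables, threshold = 5) {
  stopifnot(length(importance_tables) >= 1)
  elems <- sort(importance_tables[[1]]$element)
  scores <- vapply(importance_tables, function(tb) {
    if (!setequal(tb$element, elems))
      stop("importance tables cover different element lists", call. = FALSE)
    tb$mean_decrease_accuracy[match(elems, tb$element)]
  }, numeric(length(elems)))
  scores <- matrix(scores, nrow = length(elems),
                   dimnames = list(elems,
                                   vapply(importance_tables, function(tb)
                                     as.character(tb$river_system[1]), "")))
  excluded <- apply(scores < threshold, 1, all)
  retained <- elems[!excluded]
  if (!length(retained))
    stop("element selection removed every element", call. = FALSE)
  list(retained = retained, excluded = elems[excluded], scores = scores)
}

element_columns <- function(df) {
  meta <- c("fish_id", "site_id", "season", "n_points", "river_system",
            "partition_rank", "source", "habitat", "section", "river_km")
  cand <- setdiff(names(df), meta)
  cand[vapply(df[cand], is.numeric, logical(1))]
}
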