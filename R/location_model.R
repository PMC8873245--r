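#' Assemble a per-river training set under the independence rule
#'
#' The classifier that assigns transect partitions to sampling locations is
#' trained on two pools of fingerprints, both reflecting the habitat just
#' before capture: (i) the last partition of every cored fish, and (ii) the
#' edge signature of every fish without an identifiable core. Because last
#' partitions are themselves evaluated during movement reconstruction, the
#' last partitions of fish in `holdout_fish` are removed from the training
#' pool so that training and prediction data stay strictly independent.
#' Coreless edge signatures are never evaluated and are therefore never
#' held out.
#'
#' @param last_partitions data frame of last-partition fingerprints of
#'   cored fish: `fish_id`, `site_id` plus element columns.
#' @param coreless_edges data frame of edge signatures of coreless fish,
#'   same layout (may be `NULL` or empty).
#' @param holdout_fish fish ids whose last partitions are excluded.
#' @param river_system label carried into the model.
#' @return Object of class `training_set`: a data frame with `fish_id`,
#'   `site_id`, `source` (`"last_partition"` / `"coreless_edge"`) and
#'   element columns; attribute `river_system`.
#' @export
build_training_set <- function(last_partitions, coreless_edges = NULL,
                               holdout_fish = character(),
                               river_system = NA_character_) {
  keep <- !(last_partitions$fish_id %in% holdout_fish)
  lp <- last_partitions[keep, , drop = FALSE]
  lp$source <- rep_len("last_partition", nrow(lp))
  if (!is.null(coreless_edges) && nrow(coreless_edges)) {
    ce <- coreless_edges
    ce$source <- "coreless_edge"
    common <- intersect(names(lp), names(ce))
    out <- rbind(lp[common], ce[common])
  } else {
    out <- lp
  }
  rownames(out) <- NULL
  counts <- table(out$site_id)
  if (length(counts) == 0)
    stop("training set has no classes", call. = FALSE)
  if (any(counts < 2))
    warning("training class(es) with fewer than 2 rows: ",
            paste(names(counts)[counts < 2], collapse = ", "),
            call. = FALSE)
  attr(out, "river_system") <- river_system
  class(out) <- c("training_set", "data.frame")
  out
}

#' Train a per-river location classifier with repeated OOB evaluation
#'
#' Fits `n_runs` independently seeded ensemble classifiers predicting site
#' from fingerprint, records the out-of-bag accuracy of each, and deploys
#' the fit whose OOB accuracy is closest to the median of the distribution
#' (ties toward the earlier run).
#'
#' @param training a [build_training_set()] result (or any data frame with
#'   `site_id` and element columns).
#' @param elements element columns to train on; defaults to all numeric
#'   element columns present.
#' @param n_runs number of evaluation fits (default 100).
#' @param ntree trees per fit.
#' @param seed integer; run r uses seed `seed + r`.
#' @return Object of class `location_model`: `river_system`, `classes`,
#'   `elements`, `oob_accuracy` (vector of length `n_runs`), `oob_mean`,
#'   `oob_sd`, per-class OOB recall of the deployed fit, the deployed
#'   [oto_rf()] `fit`, and `training_fish` (fish ids whose last partitions
#'   were trained on, for the independence audit).
#' @export
train_location_model <- function(training, elements = NULL, n_runs = 100L,
                                 ntree = 500L, seed = 1L) {
  if (is.null(elements)) elements <- element_columns(training)
  y <- factor(training$site_id)
  if (nlevels(y) < 2)
    stop("cannot train a location model on a single class", call. = FALSE)
  x <- training[elements]
  acc <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(as.integer(seed) + r)
    acc[r] <- oto_rf(x, y, ntree = ntree, importance = FALSE)$oob_accuracy
  }
  deploy <- which.min(abs(acc - stats::median(acc)))
  set.seed(as.integer(seed) + deploy)
  fit <- oto_rf(x, y, ntree = ntree, importance = FALSE)
  conf <- fit$oob_confusion
  recall <- diag(conf) / pmax(1, rowSums(conf))
  src <- if ("source" %in% names(training)) training$source
         else rep("last_partition", nrow(training))
  structure(
    list(river_system = attr(training, "river_system"),
         classes = levels(y), elements = elements,
         oob_accuracy = acc, oob_mean = mean(acc), oob_sd = stats::sd(acc),
         oob_recall = recall, deployed_run = deploy, fit = fit,
         training_fish = unique(training$fish_id[src == "last_partition"])),
    class = "location_model")
}

#' @export
print.location_model <- function(x, ...) {
  cat("<location_model> ", x$river_system, ": ", length(x$classes),
      " sites, OOB accuracy ", signif(x$oob_mean, 3), " +/- ",
      signif(x$oob_sd, 2), " over ", length(x$oob_accuracy), " runs\n",
      sep = "")
  invisible(x)
}

#' Predict the location of transect partitions
#'
#' Each partition fingerprint is assigned the site most voted by the
#' deployed ensemble. Vote proportions over all sites are returned so the
#' caller can apply any confidence policy; exact ties are broken toward
#' the site earlier in canonical (alphabetical) order and flagged.
#'
#' @param model a [train_location_model()] result.
#' @param fingerprints data frame with the model's element columns and
#'   optionally `fish_id` and `partition_rank`.
#' @param audit_fish fish ids being evaluated; when given, the independence
#'   audit asserts that none of them contributed last-partition training
#'   rows to this model.
#' @return Data frame: `fish_id`, `partition_rank`, `predicted_site`,
#'   `vote_max`, `tie` plus one `vote_<site>` column per class.
#' @export
predict_partition_location <- function(model, fingerprints,
                                       audit_fish = NULL) {
  if (!is.null(audit_fish)) {
    leak <- intersect(model$training_fish, audit_fish)
    if (length(leak))
      stop("independence violation: fish trained on and evaluated: ",
           paste(leak, collapse = ", "), call. = FALSE)
  }
  prob <- predict(model$fit, fingerprints, type = "prob")
  pred <- model$classes[apply(prob, 1, which.max)]
  tie <- apply(prob, 1, function(p) sum(p == max(p)) > 1)
  out <- data.frame(
    fish_id = if ("fish_id" %in% names(fingerprints))
      fingerprints$fish_id else NA_character_,
    partition_rank = if ("partition_rank" %in% names(fingerprints))
      fingerprints$partition_rank else seq_len(nrow(prob)),
    predicted_site = pred,
    vote_max = apply(prob, 1, max),
    tie = tie,
    stringsAsFactors = FALSE)
  votes <- as.data.frame(prob)
  names(votes) <- paste0("vote_", colnames(prob))
  cbind(out, votes)
}

#' Compare OOB performance across river systems
#'
#' Summarises each model's OOB error distribution, tests for differences
#' among rivers with a one-way ANOVA on the per-run error values, and
#' groups rivers sharing statistical indistinguishability with compact
#' letters (Tukey HSD at `alpha`).
#'
#' @param models named list of [train_location_model()] results (names =
#'   river systems).
#' @param alpha significance level for the letter grouping.
#' @return List with `summary` (per-river mean/sd OOB error + letters),
#'   `anova` (data frame with F and p) and `tukey` (pairwise table).
#' @export
summarize_oob <- function(models, alpha = 0.05) {
  stopifnot(length(models) >= 2)
  rivers <- names(models)
  if (is.null(rivers))
    rivers <- vapply(models, function(m) as.character(m$river_system), "")
  err <- lapply(models, function(m) 1 - m$oob_accuracy)
  df <- data.frame(
    river = factor(rep(rivers, lengths(err)), levels = rivers),
    error = unlist(err, use.names = FALSE))
  fit <- stats::aov(error ~ river, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$river
  # significance matrix for letter grouping
  k <- length(rivers)
  sig <- matrix(FALSE, k, k, dimnames = list(rivers, rivers))
  prs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(prs)) {
    a <- prs[[i]][1]; b <- prs[[i]][2]
    s <- tk[i, "p adj"] < alpha
    sig[a, b] <- sig[b, a] <- s
  }
  means <- vapply(err, mean, numeric(1))
  letters_out <- cld_letters(rivers[order(means)], sig)
  summary_df <- data.frame(
    river_system = rivers,
    oob_error_mean = means,
    oob_error_sd = vapply(err, stats::sd, numeric(1)),
    letters = letters_out[rivers],
    stringsAsFactors = FALSE, row.names = NULL)
  list(summary = summary_df,
       anova = data.frame(F = an[["F value"]][1], p = an[["Pr(>F)"]][1]),
       tukey = as.data.frame(tk))
}

# compact-letter display by insert-and-absorb over a significance matrix;
# `groups` ordered (letters follow that order), sig[a, b] TRUE if different
cld_letters <- function(groups, sig) {
  sets <- list(groups)
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (si in seq_along(sets)) {
      s <- sets[[si]]
      done <- FALSE
      for (a in s) {
        for (b in s) {
          if (a < b && sig[a, b]) {
            sets[[si]] <- setdiff(s, a)
            sets <- append(sets, list(setdiff(s, b)))
            changed <- TRUE; done <- TRUE
            break
          }
        }
        if (done) break
      }
      if (done) break
    }
    # absorb sets fully contained in another
    keep <- rep(TRUE, length(sets))
    for (i in seq_along(sets))
      for (j in seq_along(sets))
        if (i != j && keep[i] && keep[j] &&
            all(sets[[i]] %in% sets[[j]]) &&
            length(sets[[i]]) < length(sets[[j]]))
          keep[i] <- FALSE
    # drop duplicates
    sets <- sets[keep]
    sets <- sets[!duplicated(lapply(sets, sort))]
  }
  # order sets by the earliest group they contain, assign letters
  first_idx <- vapply(sets, function(s) min(match(s, groups)), numeric(1))
  sets <- sets[order(first_idx)]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets))
    out[sets[[i]]] <- paste0(out[sets[[i]]], letters[i])
  out
}
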