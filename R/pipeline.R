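#' Pipeline parameter set
#'
#' Every tunable stage parameter of [run_pipeline()], with the package
#' defaults. All of them are recorded verbatim in the run report for
#' auditability.
#'
#' @param dl_threshold detection-limit exclusion fraction.
#' @param edge_window sub-surface edge window, um.
#' @param smooth_window,min_prominence,edge_exclusion_fraction core
#'   detection (see [detect_core()]).
#' @param limb_rule limb kept when orienting (see [orient_core_to_edge()]).
#' @param min_seg_len,max_partitions,penalty segmentation (see
#'   [segment_transect()]).
#' @param importance_threshold,importance_repeats element selection
#'   (percent mean decrease in accuracy; repeats per river).
#' @param ntree trees per ensemble fit.
#' @param oob_runs repeated fits for the OOB distribution.
#' @param estuary_threshold estuarine decision vote proportion.
#' @param n_permutations PERMANOVA permutations.
#' @param prediction_batches number of holdout folds used when predicting
#'   partition locations: the cored fish of each river are split into this
#'   many batches, and each batch is predicted by a model whose training
#'   set excludes that batch's last partitions (independence rule) while
#'   keeping the other batches' last partitions and all coreless edges.
#' @param run_stats run the habitat-statistics stage.
#' @return Named list of class `pipeline_params`.
#' @export
pipeline_params <- function(dl_threshold = 0.25, edge_window = c(2, 7),
                            smooth_window = 5L, min_prominence = 3,
                            edge_exclusion_fraction = 0.1,
                            limb_rule = "longer", min_seg_len = 5L,
                            max_partitions = 6L, penalty = 0.05,
                            importance_threshold = 5,
                            importance_repeats = 10L, ntree = 500L,
                            oob_runs = 100L, estuary_threshold = 0.5,
                            n_permutations = 9999L,
                            prediction_batches = 2L, run_stats = TRUE) {
  structure(as.list(environment()), class = "pipeline_params")
}

# rbind data frames whose column sets may differ (vote columns vary with
# the class set of each model); absent numeric columns fill with 0
rbind_fill <- function(dfs) {
  dfs <- Filter(Negate(is.null), dfs)
  if (!length(dfs)) return(NULL)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (cc in setdiff(cols, names(d)))
      d[[cc]] <- if (startsWith(cc, "vote_")) 0 else NA
    d[cols]
  }))
}

# deterministic per-stage seed derived from the global seed, so adding or
# reordering stages does not shift the random streams of the others
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 100003 + h) %% 2147483629)
}

#' Run the full movement-reconstruction pipeline
#'
#' Sequences ingestion, detection-limit filtering, core detection,
#' chronological segmentation, element selection, per-river location
#' modelling, partition prediction under the independence rule, movement
#' and life-history reconstruction, and habitat statistics. Fully
#' deterministic given `seed`.
#'
#' All cored fish are evaluated, so their last partitions are withheld
#' from classifier training; the per-river training sets then consist of
#' the edge signatures of coreless fish (plus last partitions of any
#' non-evaluated cored fish).
#'
#' @param transects list of raw [elemental_transect()]s, or a path/data
#'   frame accepted by [read_transects()].
#' @param sites a [read_sites()] table or path.
#' @param params a [pipeline_params()] list.
#' @param seed global integer seed.
#' @return A run report (list of class `pipeline_report`): per-stage
#'   outputs (`element_filter`, `core_table`, `importance`,
#'   `selected_elements`, `models`, `oob_comparison`, `predictions`,
#'   `histories`, `recruitment`, `stats`) plus `params_used` and `seed`.
#' @export
run_pipeline <- function(transects, sites, params = pipeline_params(),
                         seed = 1L) {
  if (!is.list(transects) || is.data.frame(transects))
    transects <- read_transects(transects)
  if (!inherits(sites, "sampling_sites")) sites <- read_sites(sites)

  ## ingest + detection-limit filter
  flt <- filter_elements(transects, params$dl_threshold)
  transects <- flt$transects

  ## core detection and cohort split
  calls <- lapply(transects, detect_core,
                  smooth_window = params$smooth_window,
                  min_prominence = params$min_prominence,
                  edge_exclusion_fraction = params$edge_exclusion_fraction)
  split <- split_cohort_by_core(transects, calls)

  ## edge signatures (all fish, raw surface end)
  edges <- edge_signature_table(transects, window = params$edge_window)
  edges$river_system <- sites$river_system[match(edges$site_id,
                                                 sites$site_id)]
  edges$habitat <- sites$habitat[match(edges$site_id, sites$site_id)]

  ## element selection per river system
  rivers <- unique(edges$river_system)
  imp <- lapply(rivers, function(rv)
    rank_element_importance(edges[edges$river_system == rv, , drop = FALSE],
                            river_system = rv,
                            n_repeats = params$importance_repeats,
                            ntree = params$ntree,
                            seed = stage_seed(seed, paste0("importance_", rv))))
  names(imp) <- rivers
  sel <- select_elements(imp, threshold = params$importance_threshold)

  ## orient + segment cored fish on the selected subset
  oriented <- mapply(function(tr, cc)
    orient_core_to_edge(tr, cc, limb_rule = params$limb_rule),
    split$with_core, split$core_calls, SIMPLIFY = FALSE)
  psets <- lapply(oriented, segment_transect, elements = sel$retained,
                  min_seg_len = params$min_seg_len,
                  max_partitions = params$max_partitions,
                  penalty = params$penalty)

  partition_table <- do.call(rbind, lapply(psets, function(ps) {
    fp <- as.data.frame(ps$fingerprints)
    cbind(data.frame(fish_id = ps$fish_id,
                     partition_rank = seq_len(nrow(fp)),
                     n_partitions = nrow(fp), stringsAsFactors = FALSE),
          fp)
  }))
  rownames(partition_table) <- NULL
  site_of <- vapply(transects, `[[`, "", "capture_site_id")
  partition_table$site_id <- site_of[partition_table$fish_id]
  partition_table$river_system <-
    sites$river_system[match(partition_table$site_id, sites$site_id)]

  ## per-river location models. OOB reporting uses a model trained on the
  ## full training pool (all last partitions + coreless edges); partition
  ## prediction uses batch-holdout models so that no fish's last partition
  ## is in the training set of the model that evaluates it.
  coreless_ids <- vapply(split$without_core, `[[`, "", "fish_id")
  models <- list()
  predictions <- list()
  for (rv in rivers) {
    pt <- partition_table[partition_table$river_system == rv, , drop = FALSE]
    last <- pt[pt$partition_rank == pt$n_partitions, , drop = FALSE]
    ce <- edges[edges$river_system == rv &
                  edges$fish_id %in% coreless_ids, , drop = FALSE]
    full_training <- build_training_set(last, ce, river_system = rv)
    models[[rv]] <- train_location_model(
      full_training, elements = sel$retained, n_runs = params$oob_runs,
      ntree = params$ntree, seed = stage_seed(seed, paste0("locate_", rv)))
    eval_fish <- unique(pt$fish_id)
    nb <- max(1L, as.integer(params$prediction_batches))
    batch_of <- stats::setNames(rep_len(seq_len(nb), length(eval_fish)),
                                sort(eval_fish))
    preds_rv <- list()
    for (b in seq_len(nb)) {
      batch <- names(batch_of)[batch_of == b]
      if (!length(batch)) next
      training <- suppressWarnings(
        build_training_set(last, ce, holdout_fish = batch,
                           river_system = rv))
      bm <- train_location_model(
        training, elements = sel$retained, n_runs = 1L,
        ntree = params$ntree,
        seed = stage_seed(seed, paste0("locate_", rv, "_batch", b)))
      ptb <- pt[pt$fish_id %in% batch, , drop = FALSE]
      preds_rv[[b]] <- predict_partition_location(bm, ptb,
                                                  audit_fish = batch)
    }
    predictions[[rv]] <- rbind_fill(preds_rv)
  }
  pred_all <- rbind_fill(predictions)
  rownames(pred_all) <- NULL

  ## estuarine-signature model (pooled estuaries vs freshwater ends)
  certain <- grepl("estuary|upper|lake", edges$habitat, ignore.case = TRUE)
  est_model <- NULL
  if (any(grepl("estuary", edges$habitat[certain], ignore.case = TRUE)) &&
      any(!grepl("estuary", edges$habitat[certain], ignore.case = TRUE)))
    est_model <- {
      set.seed(stage_seed(seed, "estuary_model"))
      train_estuary_model(edges[certain, , drop = FALSE],
                          elements = sel$retained, ntree = params$ntree,
                          seed = stage_seed(seed, "estuary_model"))
    }

  ## movement reconstruction + life-history classification
  histories <- list()
  for (fid in unique(pred_all$fish_id)) {
    pf <- pred_all[pred_all$fish_id == fid, , drop = FALSE]
    hist <- reconstruct_movement(pf, sites)
    if (!is.null(est_model)) {
      fp <- partition_table[partition_table$fish_id == fid, , drop = FALSE]
      est <- detect_estuarine_signature(fp, est_model,
                                        threshold = params$estuary_threshold)
      cap_hab <- sites$habitat[match(site_of[fid], sites$site_id)]
      hist <- classify_life_history(hist, est$partition_flags, cap_hab)
    }
    histories[[fid]] <- hist
  }
  recruitment <- if (!is.null(est_model)) summarize_recruitment(histories)
                 else NULL

  ## habitat statistics on edge fingerprints
  stats_out <- NULL
  if (isTRUE(params$run_stats)) {
    fp <- edges[sel$retained]
    stats_out <- list(
      permanova = permanova(fp, edges$habitat,
                            n_permutations = params$n_permutations,
                            seed = stage_seed(seed, "permanova")),
      pairwise = pairwise_permanova(fp, edges$habitat,
                                    n_permutations = params$n_permutations,
                                    seed = stage_seed(seed, "pairwise")),
      per_element = per_element_tests(fp, edges$habitat))
  }

  oob_cmp <- if (length(models) >= 2) summarize_oob(models) else NULL

  structure(
    list(element_filter = flt$report,
         core_table = split$table,
         n_with_core = length(split$with_core),
         n_without_core = length(split$without_core),
         importance = imp,
         selected_elements = sel$retained,
         excluded_elements = sel$excluded,
         partition_table = partition_table,
         models = models,
         oob_comparison = oob_cmp,
         predictions = pred_all,
         histories = histories,
         recruitment = recruitment,
         stats = stats_out,
         params_used = params,
         seed = seed),
    class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> seed ", x$seed, "\n", sep = "")
  cat("  fish: ", x$n_with_core, " cored + ", x$n_without_core,
      " coreless\n", sep = "")
  cat("  elements retained: ", paste(x$selected_elements, collapse = ", "),
      "\n", sep = "")
  for (rv in names(x$models))
    cat("  ", rv, ": OOB accuracy ", signif(x$models[[rv]]$oob_mean, 3),
        " +/- ", signif(x$models[[rv]]$oob_sd, 2), "\n", sep = "")
  if (!is.null(x$recruitment)) {
    cat("  recruitment:\n")
    print(x$recruitment)
  }
  if (!is.null(x$stats)) print(x$stats$permanova)
  invisible(x)
}
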