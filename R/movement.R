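#' Reconstruct a fish's movement history from partition predictions
#'
#' Converts the chronological sequence of predicted partition locations
#' (first = earliest recorded, last = just before capture) into movement
#' events. Each change of predicted site between adjacent partitions is one
#' event, with direction derived from along-river kilometres: moving to a
#' site farther from the river mouth is `"upstream"`, nearer is
#' `"downstream"`, equal distance is `"lateral"` (e.g. lake-river
#' transitions at the same river kilometre).
#'
#' @param predictions data frame for one fish, ordered by
#'   `partition_rank`, with columns `fish_id`, `partition_rank`,
#'   `predicted_site` (see [predict_partition_location()]).
#' @param sites a [read_sites()] table covering every predicted site.
#' @return Object of class `movement_history`: `fish_id`, `sequence`
#'   (chronological predicted sites), `events` (data frame `from_site`,
#'   `to_site`, `direction`, `distance_km`), `max_displacement_km`.
#'   Estuarine flags and the life-history label are added by
#'   [detect_estuarine_signature()] and [classify_life_history()].
#' @export
reconstruct_movement <- function(predictions, sites) {
  stopifnot(nrow(predictions) >= 1)
  ord <- order(predictions$partition_rank)
  seq_sites <- as.character(predictions$predicted_site[ord])
  km <- sites$river_km[match(seq_sites, sites$site_id)]
  if (any(is.na(km)))
    stop("predicted site(s) missing river_km: ",
         paste(unique(seq_sites[is.na(km)]), collapse = ", "),
         call. = FALSE)
  changes <- which(seq_sites[-1] != seq_sites[-length(seq_sites)])
  events <- data.frame(
    from_site = seq_sites[changes], to_site = seq_sites[changes + 1L],
    stringsAsFactors = FALSE)
  if (nrow(events)) {
    d <- km[changes + 1L] - km[changes]
    events$direction <- ifelse(d > 0, "upstream",
                               ifelse(d < 0, "downstream", "lateral"))
    events$distance_km <- abs(d)
  } else {
    events$direction <- character(0)
    events$distance_km <- numeric(0)
  }
  visited_km <- km[!duplicated(seq_sites)]
  structure(
    list(fish_id = as.character(predictions$fish_id[1]),
         sequence = seq_sites,
         events = events,
         max_displacement_km = max_displacement_km(seq_sites, sites),
         estuarine_flags = NULL,
         life_history = NA_character_),
    class = "movement_history")
}

#' @export
print.movement_history <- function(x, ...) {
  cat("<movement_history> fish ", x$fish_id, ": ",
      paste(x$sequence, collapse = " -> "), "\n", sep = "")
  cat(nrow(x$events), " movement event(s), max displacement ",
      x$max_displacement_km, " km",
      if (!is.na(x$life_history)) paste0(", life history: ", x$life_history),
      "\n", sep = "")
  invisible(x)
}

#' Maximum along-river displacement
#'
#' Largest absolute difference in river kilometres between any two sites
#' visited in a movement history; 0 when only one site is visited.
#'
#' @param history a [reconstruct_movement()] result, or a character vector
#'   of visited site ids.
#' @param sites a [read_sites()] table.
#' @return Displacement in km.
#' @export
max_displacement <- function(history, sites) {
  seq_sites <- if (inherits(history, "movement_history")) history$sequence
               else as.character(history)
  max_displacement_km(seq_sites, sites)
}

max_displacement_km <- function(seq_sites, sites) {
  km <- sites$river_km[match(unique(seq_sites), sites$site_id)]
  if (any(is.na(km)))
    stop("site(s) missing river_km", call. = FALSE)
  if (length(km) < 2) return(0)
  max(km) - min(km)
}

#' Train the pooled estuarine-signature detector
#'
#' For river systems without sampled estuaries, estuarine residence can
#' still be recognised chemically: a binary ensemble classifier is trained
#' on edge signatures pooled from all sampled estuaries against edge
#' signatures from freshwater habitats (fish captured in upper sections and
#' lakes), exploiting the strong Sr (estuary-high) / Rb (freshwater-high)
#' contrast.
#'
#' @param edges edge-signature table covering both habitat classes, with a
#'   `habitat` column (values containing `"estuary"` are the estuarine
#'   class).
#' @param elements element columns; default all present.
#' @param ntree,seed ensemble parameters.
#' @return Object of class `estuary_model` wrapping an [oto_rf()] fit.
#' @export
train_estuary_model <- function(edges, elements = NULL, ntree = 500L,
                                seed = 1L) {
  if (is.null(elements)) elements <- element_columns(edges)
  cls <- ifelse(grepl("estuary", edges$habitat, ignore.case = TRUE),
                "estuarine", "freshwater")
  if (length(unique(cls)) < 2)
    stop("need both estuarine and freshwater edge signatures", call. = FALSE)
  set.seed(as.integer(seed))
  fit <- oto_rf(edges[elements], cls, ntree = ntree, importance = FALSE)
  structure(list(fit = fit, elements = elements), class = "estuary_model")
}

#' Flag partitions carrying an estuarine elemental signature
#'
#' Each partition fingerprint is scored by the pooled estuary model; a
#' partition is flagged estuarine when the ensemble's vote proportion for
#' the estuarine class reaches `threshold`. The fish-level flag is `TRUE`
#' when any partition is flagged: one or more estuarine partitions is
#' evidence in favour of an amphidromous (or estuarine-resident) history.
#'
#' @param fingerprints data frame of partition fingerprints (rows in
#'   chronological order) with the model's element columns.
#' @param estuary_model a [train_estuary_model()] result.
#' @param threshold decision vote proportion (default 0.5).
#' @return List with `partition_flags` (logical vector), `fish_flag`
#'   (any partition flagged) and `votes` (estuarine vote proportions).
#' @export
detect_estuarine_signature <- function(fingerprints, estuary_model,
                                       threshold = 0.5) {
  prob <- predict(estuary_model$fit, fingerprints, type = "prob")
  v <- prob[, "estuarine"]
  flags <- v >= threshold
  list(partition_flags = unname(flags), fish_flag = any(flags),
       votes = unname(v))
}

#' Classify a fish's life history
#'
#' Applies the residence rules to the per-partition estuarine flags:
#' \itemize{
#'   \item amphidromous: at least one estuarine and at least one
#'     non-estuarine partition (movement across the estuary-freshwater
#'     divide during the lifespan);
#'   \item estuarine_resident: every partition estuarine and the fish was
#'     captured in an estuary;
#'   \item freshwater_resident: no partition estuarine;
#'   \item undetermined: contradictory evidence (e.g. a uniformly
#'     estuarine signal in a fish captured in fresh water).
#' }
#'
#' @param history a [reconstruct_movement()] result.
#' @param estuarine_flags per-partition logical flags (from
#'   [detect_estuarine_signature()]).
#' @param capture_habitat habitat class of the capture site.
#' @return The `movement_history` with `estuarine_flags` and
#'   `life_history` filled in.
#' @export
classify_life_history <- function(history, estuarine_flags,
                                  capture_habitat) {
  stopifnot(length(estuarine_flags) == length(history$sequence))
  any_est <- any(estuarine_flags)
  any_fresh <- any(!estuarine_flags)
  label <- if (any_est && any_fresh) {
    "amphidromous"
  } else if (any_est) {
    if (grepl("estuary", capture_habitat, ignore.case = TRUE))
      "estuarine_resident" else "undetermined"
  } else {
    "freshwater_resident"
  }
  history$estuarine_flags <- estuarine_flags
  history$life_history <- label
  history
}

#' Summarise recruitment strategies over a cohort
#'
#' @param histories list of labelled `movement_history` objects.
#' @return Data frame with `life_history`, `n`, `proportion` and `percent`
#'   (rounded to integer percent for reporting).
#' @export
summarize_recruitment <- function(histories) {
  labels <- vapply(histories, `[[`, "", "life_history")
  if (anyNA(labels)) stop("all fish must be labelled first", call. = FALSE)
  lv <- c("freshwater_resident", "estuarine_resident", "amphidromous",
          "undetermined")
  counts <- table(factor(labels, levels = lv))
  data.frame(life_history = lv, n = as.integer(counts),
             proportion = as.numeric(counts) / length(labels),
             percent = as.integer(round(100 * as.numeric(counts) /
                                          length(labels))),
             stringsAsFactors = FALSE, row.names = NULL)
}
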