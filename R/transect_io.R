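#' Construct an elemental transect
#'
#' One fish's ordered series of elemental concentrations along the ablation
#' path. Positions are micrometres along the path and must be strictly
#' increasing after sorting; the concentration and below-detection-limit
#' matrices are congruent (position x element).
#'
#' @param fish_id,capture_site_id identifiers.
#' @param positions numeric vector, um along the ablation path.
#' @param concentrations numeric matrix (position x element), molar ratio to
#'   Ca, non-negative; column names are element symbols.
#' @param below_dl logical matrix, same shape as `concentrations`; `TRUE`
#'   marks a reading below the instrument detection limit. Defaults to all
#'   `FALSE`.
#' @param season optional season label.
#' @param orientation `"raw"` (as ablated) or `"core_to_edge"`
#'   (chronological, position 0 at the core).
#' @return An object of class `elemental_transect`.
#' @seealso [read_transects()], [orient_core_to_edge()]
#' @export
elemental_transect <- function(fish_id, capture_site_id, positions,
                               concentrations, below_dl = NULL,
                               season = NA_character_,
                               orientation = c("raw", "core_to_edge")) {
  orientation <- match.arg(orientation)
  positions <- as.numeric(positions)
  concentrations <- as.matrix(concentrations)
  storage.mode(concentrations) <- "double"
  if (is.null(below_dl))
    below_dl <- matrix(FALSE, nrow(concentrations), ncol(concentrations),
                       dimnames = dimnames(concentrations))
  below_dl <- as.matrix(below_dl)
  if (length(positions) != nrow(concentrations) ||
      !identical(dim(concentrations), dim(below_dl)))
    stop("positions, concentrations and below_dl are not congruent for fish ",
         fish_id, call. = FALSE)
  ord <- order(positions)
  positions <- positions[ord]
  concentrations <- concentrations[ord, , drop = FALSE]
  below_dl <- below_dl[ord, , drop = FALSE]
  if (anyDuplicated(positions))
    stop("duplicate (fish, position) rows for fish ", fish_id, call. = FALSE)
  if (any(!is.finite(concentrations)) || any(concentrations < 0))
    stop("concentrations must be finite and non-negative for fish ", fish_id,
         call. = FALSE)
  structure(
    list(fish_id = as.character(fish_id),
         capture_site_id = as.character(capture_site_id),
         season = as.character(season),
         positions = positions,
         concentrations = concentrations,
         below_dl = below_dl,
         orientation = orientation),
    class = "elemental_transect")
}

#' @export
print.elemental_transect <- function(x, ...) {
  cat("<elemental_transect> fish ", x$fish_id, " @ ", x$capture_site_id,
      ": ", length(x$positions), " points x ", ncol(x$concentrations),
      " elements [", x$orientation, "]\n", sep = "")
  invisible(x)
}

#' @export
length.elemental_transect <- function(x) length(x$positions)

transect_elements <- function(x) colnames(x$concentrations)

#' Read otolith transect tables
#'
#' Reads a transect table into a list of [elemental_transect()] objects.
#' Two dialects are accepted: wide (one column per element symbol, optional
#' `<symbol>_bdl` logical columns for below-detection-limit flags) and long
#' (columns `element`, `value` and optional `below_dl`). CSV and TSV files
#' are sniffed by delimiter; a data frame may be passed directly.
#'
#' Rows with unparseable (non-finite) concentration values are rejected and
#' reported via the `"rejected"` attribute of the result rather than
#' aborting the run.
#'
#' @param table a data frame or path to a CSV/TSV file with columns
#'   `fish_id`, `site_id`, `position`, optional `season`, and element data
#'   in either dialect.
#' @param registry an [element_registry()]; element columns must be a subset
#'   of its symbols.
#' @return A named list of `elemental_transect` objects (one per fish, in
#'   first-appearance order), with attribute `rejected` (data frame of
#'   dropped rows and reasons).
#' @export
read_transects <- function(table, registry = default_element_registry()) {
  df <- read_delim_sniff(table)
  need <- c("fish_id", "site_id", "position")
  if (!all(need %in% names(df)))
    stop("transect table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  long <- "element" %in% names(df)
  rejected <- data.frame(fish_id = character(), position = numeric(),
                         reason = character(), stringsAsFactors = FALSE)

  if (long) {
    if (!"value" %in% names(df))
      stop("long-format table requires a `value` column", call. = FALSE)
    unknown <- setdiff(unique(df$element), registry$symbol)
    if (length(unknown))
      stop("unknown element(s) ", paste(unknown, collapse = ", "),
           "; registry has: ", paste(registry$symbol, collapse = ", "),
           call. = FALSE)
    df$value <- suppressWarnings(as.numeric(df$value))
    bad <- !is.finite(df$value)
    if (any(bad)) {
      rejected <- data.frame(fish_id = df$fish_id[bad],
                             position = df$position[bad],
                             reason = "unparseable value",
                             stringsAsFactors = FALSE)
      df <- df[!bad, , drop = FALSE]
    }
    if (!"below_dl" %in% names(df)) df$below_dl <- FALSE
    elems <- registry$symbol[registry$symbol %in% df$element]
    split_fish <- split(df, factor(df$fish_id, levels = unique(df$fish_id)))
    out <- lapply(split_fish, function(d) {
      pos <- sort(unique(d$position))
      conc <- matrix(NA_real_, length(pos), length(elems),
                     dimnames = list(NULL, elems))
      bdl <- matrix(FALSE, length(pos), length(elems),
                    dimnames = list(NULL, elems))
      pi <- match(d$position, pos)
      ei <- match(d$element, elems)
      if (anyDuplicated(cbind(pi, ei)))
        stop("duplicate (fish, position) rows for fish ", d$fish_id[1],
             call. = FALSE)
      conc[cbind(pi, ei)] <- d$value
      bdl[cbind(pi, ei)] <- as.logical(d$below_dl)
      if (any(is.na(conc)))
        stop("missing element values at some positions for fish ",
             d$fish_id[1], call. = FALSE)
      elemental_transect(d$fish_id[1], d$site_id[1], pos, conc, bdl,
                         season = if ("season" %in% names(d)) d$season[1]
                                  else NA_character_)
    })
  } else {
    meta <- c("fish_id", "site_id", "position", "season", "orientation")
    elem_cols <- setdiff(names(df), c(meta, paste0(registry$symbol, "_bdl")))
    unknown <- setdiff(elem_cols, registry$symbol)
    if (length(unknown))
      stop("unknown element column(s) ", paste(unknown, collapse = ", "),
           "; registry has: ", paste(registry$symbol, collapse = ", "),
           call. = FALSE)
    elems <- registry$symbol[registry$symbol %in% elem_cols]
    for (e in elems) df[[e]] <- suppressWarnings(as.numeric(df[[e]]))
    bad <- !stats::complete.cases(df[elems]) |
      rowSums(!is.finite(as.matrix(df[elems]))) > 0
    if (any(bad)) {
      rejected <- data.frame(fish_id = df$fish_id[bad],
                             position = df$position[bad],
                             reason = "unparseable value",
                             stringsAsFactors = FALSE)
      df <- df[!bad, , drop = FALSE]
    }
    split_fish <- split(df, factor(df$fish_id, levels = unique(df$fish_id)))
    out <- lapply(split_fish, function(d) {
      conc <- as.matrix(d[elems])
      bdl_cols <- paste0(elems, "_bdl")
      bdl <- matrix(FALSE, nrow(d), length(elems),
                    dimnames = list(NULL, elems))
      have <- bdl_cols %in% names(d)
      if (any(have))
        bdl[, have] <- as.matrix(
          as.data.frame(lapply(d[bdl_cols[have]], as.logical)))
      elemental_transect(d$fish_id[1], d$site_id[1], d$position, conc, bdl,
                         season = if ("season" %in% names(d)) d$season[1]
                                  else NA_character_)
    })
  }
  attr(out, "rejected") <- rejected
  out
}

#' Write transects as a wide CSV
#'
#' Inverse of [read_transects()] for the wide dialect. Concentrations are
#' written with 17 significant digits so a write/read round trip reproduces
#' them bit-exactly.
#'
#' @param transects list of [elemental_transect()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_transects <- function(transects, path) {
  rows <- lapply(transects, function(tr) {
    d <- data.frame(fish_id = tr$fish_id, site_id = tr$capture_site_id,
                    season = tr$season, position = tr$positions,
                    stringsAsFactors = FALSE)
    conc <- as.data.frame(tr$concentrations)
    d <- cbind(d, conc)
    bdl <- as.data.frame(tr$below_dl)
    names(bdl) <- paste0(colnames(tr$concentrations), "_bdl")
    cbind(d, bdl)
  })
  df <- do.call(rbind, rows)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the sampling-site metadata table
#'
#' @param table data frame or CSV/TSV path with columns `site_id`,
#'   `river_system`, `section`, `habitat`, `river_km` (along-river distance
#'   from the river mouth, km).
#' @return A validated data frame of class `sampling_sites`.
#' @export
read_sites <- function(table) {
  df <- read_delim_sniff(table)
  need <- c("site_id", "river_system", "section", "habitat", "river_km")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("site table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df[c("river_system", "site_id")]))
    stop("duplicate (river_system, site_id) rows in site table",
         call. = FALSE)
  df$river_km <- as.numeric(df$river_km)
  if (any(is.na(df$river_km)) || any(df$river_km < 0))
    stop("river_km must be non-negative for all sites", call. = FALSE)
  class(df) <- c("sampling_sites", "data.frame")
  df
}

read_delim_sniff <- function(table) {
  if (is.data.frame(table)) return(as.data.frame(table))
  if (!is.character(table) || !file.exists(table))
    stop("input is neither a data frame nor an existing file: ", table,
         call. = FALSE)
  first <- readLines(table, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(table, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Detection-limit element filter
#'
#' Excludes every element whose pooled fraction of below-detection-limit
#' readings, over all fish in the collection, is strictly greater than
#' `dl_fraction_threshold` (default 0.25, i.e. "> 25%"). Readings below the
#' detection limit that belong to a retained element keep their reported
#' concentration; only whole elements are dropped.
#'
#' @param transects list of [elemental_transect()] objects.
#' @param dl_fraction_threshold fraction in (0, 1).
#' @return A list with `transects` (re-projected onto the retained
#'   elements), `retained` (character vector) and `report` (per-element
#'   data frame: counts, pooled fraction, decision).
#' @export
filter_elements <- function(transects, dl_fraction_threshold = 0.25) {
  stopifnot(length(transects) > 0)
  if (dl_fraction_threshold <= 0 || dl_fraction_threshold >= 1)
    stop("dl_fraction_threshold must lie in (0, 1)", call. = FALSE)
  elems <- transect_elements(transects[[1]])
  n_bdl <- n_tot <- stats::setNames(numeric(length(elems)), elems)
  for (tr in transects) {
    if (!identical(transect_elements(tr), elems))
      stop("transects disagree on element columns", call. = FALSE)
    n_bdl <- n_bdl + colSums(tr$below_dl)
    n_tot <- n_tot + nrow(tr$below_dl)
  }
  frac <- n_bdl / n_tot
  excluded <- frac > dl_fraction_threshold
  report <- data.frame(element = elems, n_below_dl = as.integer(n_bdl),
                       n_total = as.integer(n_tot), fraction_below_dl = frac,
                       excluded = excluded, row.names = NULL,
                       stringsAsFactors = FALSE)
  retained <- elems[!excluded]
  if (!length(retained))
    stop("all elements excluded by the detection-limit filter; no usable signal",
         call. = FALSE)
  out <- lapply(transects, function(tr) {
    tr$concentrations <- tr$concentrations[, retained, drop = FALSE]
    tr$below_dl <- tr$below_dl[, retained, drop = FALSE]
    tr
  })
  list(transects = out, retained = retained, report = report)
}

#' Extract the otolith-edge elemental signature
#'
#' Averages each element over the sub-surface window (default 2-7 um from
#' the otolith surface, both bounds inclusive). Readings closer than the
#' lower bound to the surface are never included: they are considered
#' unreliable due to surface contamination and irregularity. The surface is
#' taken to be the outer end of the series: the last (highest-position)
#' point of a raw transect, or the far-from-core end of an oriented one.
#'
#' @param transect an [elemental_transect()].
#' @param window numeric length-2, um from the surface, inclusive.
#' @param surface_end `"last"` (default: the surface is at `max(positions)`)
#'   or `"first"`.
#' @return An object of class `edge_signature`: `fish_id`, `site_id`,
#'   `season`, `fingerprint` (named per-element means) and `n_points`.
#' @export
extract_edge_signature <- function(transect, window = c(2, 7),
                                   surface_end = c("last", "first")) {
  surface_end <- match.arg(surface_end)
  stopifnot(length(window) == 2, window[1] <= window[2], window[1] >= 0)
  pos <- transect$positions
  dist_surface <- if (surface_end == "last") max(pos) - pos else pos - min(pos)
  in_win <- dist_surface >= window[1] & dist_surface <= window[2]
  if (!any(in_win))
    stop("no measurements within ", window[1], "-", window[2],
         " um of the surface for fish ", transect$fish_id, call. = FALSE)
  fp <- colMeans(transect$concentrations[in_win, , drop = FALSE])
  structure(
    list(fish_id = transect$fish_id, site_id = transect$capture_site_id,
         season = transect$season, fingerprint = fp,
         n_points = sum(in_win)),
    class = "edge_signature")
}

#' @export
print.edge_signature <- function(x, ...) {
  cat("<edge_signature> fish ", x$fish_id, " @ ", x$site_id, " (",
      x$n_points, " points)\n", sep = "")
  print(signif(x$fingerprint, 4))
  invisible(x)
}

#' Tabulate edge signatures for a transect collection
#'
#' @param transects list of [elemental_transect()] objects.
#' @inheritParams extract_edge_signature
#' @return Data frame with `fish_id`, `site_id`, `season`, `n_points` and
#'   one column per element.
#' @export
edge_signature_table <- function(transects, window = c(2, 7),
                                 surface_end = "last") {
  sigs <- lapply(transects, extract_edge_signature, window = window,
                 surface_end = surface_end)
  fp <- do.call(rbind, lapply(sigs, function(s) s$fingerprint))
  out <- data.frame(fish_id = vapply(sigs, `[[`, "", "fish_id"),
                    site_id = vapply(sigs, `[[`, "", "site_id"),
                    season = vapply(sigs, `[[`, "", "season"),
                    n_points = vapply(sigs, `[[`, 0L, "n_points"),
                    stringsAsFactors = FALSE, row.names = NULL)
  cbind(out, as.data.frame(fp))
}
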