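#' Default site fingerprint template for a synthetic river system
#'
#' Builds per-site multivariate elemental fingerprints along an
#' estuary-to-upstream gradient: strontium decreases upstream and rubidium
#' increases, reflecting the dominant chemical contrast between estuarine
#' and freshwater otolith material; remaining elements differ among sites
#' only by a small seeded jitter. Adjacent site centroids are separated by
#' at least `separation_sd` pooled standard deviations in the multivariate
#' space (the Sr and Rb axes each contribute `separation_sd / sqrt(2)` per
#' step), so `separation_sd = 0` collapses all sites onto one centroid.
#'
#' The gradient is deliberately non-linear: the estuary-freshwater step in
#' both Sr and Rb is `estuary_sr_boost` times larger than the steps among
#' freshwater sites, mirroring the empirical pattern that the
#' estuary-freshwater contrast (Sr-enriched estuarine material, Rb-enriched
#' freshwater material) is far stronger than any difference among
#' freshwater sites.
#'
#' @param n_sites number of sites (>= 2); site 1 is the estuary, the last
#'   site the upper reach.
#' @param separation_sd centroid separation between adjacent sites, in
#'   pooled-sd units.
#' @param registry an [element_registry()].
#' @param river_system label for the site table.
#' @param river_km along-river km of each site; default evenly spaced
#'   over 0-149 km.
#' @param relative_sd per-element sd as a fraction of the base mean.
#' @param estuary_sr_boost multiplier on the Sr step between the estuary
#'   and the first freshwater site.
#' @param seed seed for the non-gradient element jitter.
#' @return Object of class `site_fingerprint_spec`: list with `sites` (a
#'   [read_sites()]-compatible table), `means` (site x element matrix),
#'   `sds` (named per-element vector).
#' @export
default_river_template <- function(n_sites = 3L, separation_sd = 5,
                                   registry = default_element_registry(),
                                   river_system = "synthetic",
                                   river_km = NULL, relative_sd = 0.08,
                                   estuary_sr_boost = 5, seed = 1L) {
  stopifnot(n_sites >= 2)
  base <- c(Li = 2e-6, B = 1e-5, Mg = 1.5e-4, P = 3e-4, K = 2e-4,
            Mn = 5e-6, Rb = 1e-6, Sr = 1.5e-3, Ba = 5e-6)
  elems <- registry$symbol
  miss <- setdiff(elems, names(base))
  if (length(miss)) base[miss] <- 1e-5
  base <- base[elems]
  sds <- base * relative_sd

  section <- c("estuary",
               if (n_sites > 2) paste0("middle",
                                       if (n_sites > 3) seq_len(n_sites - 2)
                                       else ""),
               "upper")
  habitat <- c("estuary", rep("middle river", n_sites - 2), "upper river")
  site_id <- paste0(river_system, "_", section)
  if (is.null(river_km)) river_km <- seq(0, 149, length.out = n_sites)

  means <- matrix(rep(base, each = n_sites), n_sites, length(elems),
                  dimnames = list(site_id, elems))
  step <- separation_sd / sqrt(2)
  # steps upstream in sd units: the estuary -> first freshwater step is
  # boosted (the marine influence dominates both Sr and Rb), steps among
  # freshwater sites are unit-sized
  steps <- c(estuary_sr_boost * step, rep(step, max(0, n_sites - 2)))
  down_level <- rev(cumsum(c(0, rev(steps))))[seq_len(n_sites)]  # high at estuary
  up_level <- cumsum(c(0, steps))                                # high upstream
  means[, "Sr"] <- base["Sr"] + sds["Sr"] * down_level
  means[, "Rb"] <- base["Rb"] + sds["Rb"] * up_level
  other <- setdiff(elems, c("Sr", "Rb"))
  set.seed(as.integer(seed))
  jitter <- matrix(stats::rnorm(n_sites * length(other), 0, 0.1 * step),
                   n_sites, length(other))
  means[, other] <- means[, other] + sweep(jitter, 2, sds[other], `*`)
  means[means <= 0] <- min(base) * 1e-3

  sites <- data.frame(site_id = site_id, river_system = river_system,
                      section = section, habitat = habitat,
                      river_km = river_km, stringsAsFactors = FALSE)
  class(sites) <- c("sampling_sites", "data.frame")
  structure(list(sites = sites, means = means, sds = sds),
            class = "site_fingerprint_spec")
}

#' Define a movement scenario
#'
#' An ordered sequence of residence segments (site, number of measurement
#' points); the capture site is the last segment's site, and `label` is the
#' ground-truth life-history class the scenario embodies.
#'
#' @param scenario_id identifier.
#' @param site_ids ordered visited sites (chronological, first = natal).
#' @param lengths residence length of each segment, in measurement points.
#' @param label true life-history class.
#' @return Object of class `movement_scenario`.
#' @export
movement_scenario <- function(scenario_id, site_ids, lengths, label) {
  stopifnot(length(site_ids) == length(lengths), length(site_ids) >= 1,
            all(lengths >= 2))
  structure(list(scenario_id = scenario_id,
                 site_ids = as.character(site_ids),
                 lengths = as.integer(lengths),
                 capture_site = as.character(site_ids[length(site_ids)]),
                 label = label),
            class = "movement_scenario")
}

#' Canonical scenario set for a three-site template
#'
#' Four archetypes: freshwater residence in the upper reach, estuarine
#' residence, a downstream move within fresh water, and amphidromy (early
#' life in the estuary followed by upstream movement to the upper reach).
#'
#' @param template a [default_river_template()] with >= 3 sites.
#' @param segment_points residence points per segment.
#' @return Named list of [movement_scenario()] objects.
#' @export
default_scenarios <- function(template, segment_points = 40L) {
  s <- template$sites$site_id
  n <- length(s)
  est <- s[1]; mid <- s[min(2, n)]; up <- s[n]
  list(
    freshwater_resident = movement_scenario(
      "freshwater_resident", up, 3L * segment_points,
      "freshwater_resident"),
    estuarine_resident = movement_scenario(
      "estuarine_resident", est, 3L * segment_points,
      "estuarine_resident"),
    downstream_move = movement_scenario(
      "downstream_move", c(up, mid), c(2L * segment_points, segment_points),
      "freshwater_resident"),
    amphidromous = movement_scenario(
      "amphidromous", c(est, mid, up),
      rep(segment_points, 3L), "amphidromous"))
}

#' Cohort simulation configuration
#'
#' @param template a [default_river_template()].
#' @param scenarios list of [movement_scenario()] objects.
#' @param n_fish_per_scenario fish simulated per scenario.
#' @param noise_sd_multiplier scales the per-element residual sd.
#' @param ar_phi AR(1) coefficient of the within-fish residuals; adjacent
#'   ablation points on real otoliths are positively correlated.
#' @param mn_peak_mult core Mn peak height as a multiple of the baseline
#'   Mn mean.
#' @param mn_peak_width Gaussian width (sd) of the core peak, in points.
#' @param coreless_fraction fraction of fish simulated without a core
#'   peak.
#' @param spacing_um distance between measurement points.
#' @param stub_fraction length of the discarded-limb stub ahead of the
#'   core, as a fraction of the chronological length (the through-core
#'   ablation records part of the opposite limb before the core).
#' @param below_dl_rate optional named per-element probability that a
#'   reading is flagged below the detection limit.
#' @param conc_floor positive clipping floor for concentrations.
#' @param seed mandatory integer seed.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(template, scenarios, n_fish_per_scenario = 20L,
                          noise_sd_multiplier = 1, ar_phi = 0.3,
                          mn_peak_mult = 8, mn_peak_width = 2.5,
                          coreless_fraction = 0.2, spacing_um = 1,
                          stub_fraction = 0.15, below_dl_rate = NULL,
                          conc_floor = 1e-12, seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(coreless_fraction >= 0, coreless_fraction <= 1,
            stub_fraction >= 0, abs(ar_phi) < 1)
  structure(list(template = template, scenarios = scenarios,
                 n_fish_per_scenario = as.integer(n_fish_per_scenario),
                 noise_sd_multiplier = noise_sd_multiplier, ar_phi = ar_phi,
                 mn_peak_mult = mn_peak_mult,
                 mn_peak_width = mn_peak_width,
                 coreless_fraction = coreless_fraction,
                 spacing_um = spacing_um, stub_fraction = stub_fraction,
                 below_dl_rate = below_dl_rate, conc_floor = conc_floor,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# stationary AR(1) residual series, sd `s`, length n
ar1_noise <- function(n, phi, s) {
  if (n == 0) return(numeric(0))
  e <- numeric(n)
  e[1] <- stats::rnorm(1, 0, s)
  if (n > 1) {
    innov <- stats::rnorm(n - 1, 0, s * sqrt(1 - phi^2))
    for (i in 2:n) e[i] <- phi * e[i - 1] + innov[i - 1]
  }
  e
}

#' Simulate one fish's transect
#'
#' Generates the chronological (core-to-edge) concentration series as the
#' concatenation of residence segments (site mean + AR(1) noise per
#' element), prepends a short opposite-limb stub, adds the Gaussian Mn
#' core peak (unless the fish is coreless), and returns the raw transect
#' together with its ground truth. Uses R's RNG; seed before calling for
#' reproducibility.
#'
#' @param scenario a [movement_scenario()].
#' @param config a [cohort_config()].
#' @param fish_id identifier.
#' @param coreless simulate without a core peak.
#' @param season season label recorded on the transect.
#' @return List with `transect` (an [elemental_transect()], orientation
#'   `"raw"`) and `truth` (list: `core_index` raw 1-based or `NA`,
#'   `stub_points`, `sites` per chronological point, `breakpoints`
#'   (0-based, chronological), `label`, `capture_site`, `clipped`).
#' @export
simulate_fish <- function(scenario, config, fish_id, coreless = FALSE,
                          season = NA_character_) {
  tpl <- config$template
  unknown <- setdiff(scenario$site_ids, rownames(tpl$means))
  if (length(unknown))
    stop("scenario references unknown site(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  elems <- colnames(tpl$means)
  n_chrono <- sum(scenario$lengths)
  site_per_point <- rep(scenario$site_ids, scenario$lengths)
  mean_mat <- tpl$means[site_per_point, , drop = FALSE]

  m <- max(3L, round(config$stub_fraction * n_chrono))
  stub_mean <- matrix(rep(tpl$means[scenario$site_ids[1], ], each = m),
                      m, length(elems), dimnames = list(NULL, elems))
  full_mean <- rbind(stub_mean, mean_mat)
  n <- nrow(full_mean)

  noise <- vapply(seq_along(elems), function(j)
    ar1_noise(n, config$ar_phi,
              tpl$sds[elems[j]] * config$noise_sd_multiplier),
    numeric(n))
  conc <- full_mean + noise

  core_raw <- m + 1L
  if (!coreless) {
    peak <- config$mn_peak_mult * tpl$means[scenario$site_ids[1], "Mn"] *
      exp(-0.5 * ((seq_len(n) - core_raw) / config$mn_peak_width)^2)
    conc[, "Mn"] <- conc[, "Mn"] + peak
  }
  clipped <- sum(conc < config$conc_floor)
  conc[conc < config$conc_floor] <- config$conc_floor

  bdl <- matrix(FALSE, n, length(elems), dimnames = list(NULL, elems))
  if (!is.null(config$below_dl_rate)) {
    for (e in names(config$below_dl_rate))
      bdl[, e] <- stats::runif(n) < config$below_dl_rate[[e]]
  }
  tr <- elemental_transect(
    fish_id, scenario$capture_site,
    positions = config$spacing_um * (seq_len(n) - 1),
    concentrations = conc, below_dl = bdl, season = season,
    orientation = "raw")
  list(transect = tr,
       truth = list(core_index = if (coreless) NA_integer_ else core_raw,
                    stub_points = m,
                    sites = site_per_point,
                    breakpoints = cumsum(scenario$lengths)[
                      -length(scenario$lengths)],
                    label = scenario$label,
                    capture_site = scenario$capture_site,
                    clipped = clipped))
}

#' Simulate a cohort of transects with ground truth
#'
#' Draws `n_fish_per_scenario` fish per scenario, each coreless with
#' probability `coreless_fraction`, with seasons rotated over the sampling
#' campaign. Fully deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param out optional directory; when given, `transects.csv`,
#'   `sites.csv` and `truth.csv` are written there in the dialects
#'   [read_transects()] / [read_sites()] accept.
#' @return List of class `synthetic_cohort`: `transects` (list of raw
#'   [elemental_transect()]s), `sites`, `truth` (per-fish data frame),
#'   `truth_points` (per-point site table), `config`.
#' @export
simulate_cohort <- function(config, out = NULL) {
  set.seed(config$seed)
  seasons <- c("March", "May", "August", "November")
  transects <- list()
  truth_rows <- list()
  pts_rows <- list()
  i <- 0L
  for (sc in config$scenarios) {
    for (f in seq_len(config$n_fish_per_scenario)) {
      i <- i + 1L
      fid <- sprintf("%s_%03d", sc$scenario_id, f)
      coreless <- stats::runif(1) < config$coreless_fraction
      fish <- simulate_fish(sc, config, fid, coreless = coreless,
                            season = seasons[1L + (i %% 4L)])
      transects[[fid]] <- fish$transect
      truth_rows[[fid]] <- data.frame(
        fish_id = fid, scenario = sc$scenario_id, label = fish$truth$label,
        capture_site = fish$truth$capture_site, coreless = coreless,
        core_index = fish$truth$core_index,
        stub_points = fish$truth$stub_points,
        n_segments = length(sc$lengths),
        stringsAsFactors = FALSE)
      pts_rows[[fid]] <- data.frame(
        fish_id = fid, chrono_index = seq_along(fish$truth$sites),
        site_id = fish$truth$sites, stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth_rows); rownames(truth) <- NULL
  pts <- do.call(rbind, pts_rows); rownames(pts) <- NULL
  out_obj <- structure(
    list(transects = transects, sites = config$template$sites,
         truth = truth, truth_points = pts, config = config),
    class = "synthetic_cohort")
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_transects(transects, file.path(out, "transects.csv"))
    utils::write.csv(config$template$sites, file.path(out, "sites.csv"),
                     row.names = FALSE)
    utils::write.csv(truth, file.path(out, "truth.csv"), row.names = FALSE)
    utils::write.csv(pts, file.path(out, "truth_points.csv"),
                     row.names = FALSE)
  }
  out_obj
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", length(x$transects), " fish, ",
      nrow(x$sites), " sites, seed ", x$config$seed, "\n", sep = "")
  print(table(x$truth$label))
  invisible(x)
}
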