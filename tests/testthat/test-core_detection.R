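test_that("detect_core finds clear peaks and rejects flat series", {
  flat <- toy_transect(matrix(1, 101, 3,
                              dimnames = list(NULL, c("Mn", "Sr", "Rb"))))
  cc <- detect_core(flat)
  expect_true(is.na(cc$core_index))

  # single spike, no smoothing: unique-peak case
  spike1 <- matrix(1, 101, 3, dimnames = list(NULL, c("Mn", "Sr", "Rb")))
  spike1[50, "Mn"] <- 10
  cc1 <- detect_core(toy_transect(spike1), smooth_window = 1,
                     min_prominence = 3)
  expect_equal(cc1$core_index, 50L)

  # wide spike under the default moving median: the smoothed maximum is a
  # plateau and the first index wins (tie convention); must agree with the
  # brute-force oracle and stay within the plateau
  spike <- spike1
  spike[49:51, "Mn"] <- 10
  cc2 <- detect_core(toy_transect(spike), min_prominence = 3)
  expect_equal(cc2$core_index,
               oracle_core_index(spike[, "Mn"], 5, 0.1))
  expect_lte(abs(cc2$core_index - 50L), 1L)
  expect_gte(cc2$peak_prominence, 3)

  expect_error(detect_core(flat, mn_element = "Zn"), "Zn")
  tiny <- toy_transect(matrix(1, 3, 3,
                              dimnames = list(NULL, c("Mn", "Sr", "Rb"))))
  expect_error(detect_core(tiny, smooth_window = 5), "smooth_window")
  expect_error(detect_core(flat, smooth_window = 4), "odd")
})

test_that("detect_core matches the brute-force smoothing oracle", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(60:120, 1)
    core <- sample(seq(round(0.2 * n), round(0.8 * n)), 1)
    tr <- mn_peak_transect(n, core, height = 8, width = 2.5,
                           noise_sd = 0.08)
    for (k in c(3L, 5L, 7L)) {
      cc <- detect_core(tr, smooth_window = k)
      expect_equal(cc$core_index,
                   oracle_core_index(tr$concentrations[, "Mn"], k, 0.1))
    }
  }
})

test_that("core detection is scale-invariant and translation-equivariant", {
  set.seed(7)
  tr <- mn_peak_transect(90, 40)
  cc <- detect_core(tr)
  # positive scaling of Mn leaves the call unchanged (prominence is a ratio)
  tr_scaled <- tr
  tr_scaled$concentrations[, "Mn"] <- tr$concentrations[, "Mn"] * 137
  cc2 <- detect_core(tr_scaled)
  expect_equal(cc2$core_index, cc$core_index)
  expect_equal(cc2$peak_prominence, cc$peak_prominence)

  # prepending a constant left pad shifts the index by the pad length
  pad <- 10L
  padded <- rbind(matrix(rep(tr$concentrations[1, ], each = pad), pad, 3,
                         dimnames = list(NULL, colnames(tr$concentrations))),
                  tr$concentrations)
  tr_pad <- toy_transect(padded)
  cc3 <- detect_core(tr_pad)
  expect_equal(cc3$core_index, cc$core_index + pad)
})

mk_core_call <- function(idx, fish = "f1")
  structure(list(fish_id = fish, core_index = idx, core_position = NA_real_,
                 peak_prominence = 10, chosen_limb = "n/a"),
            class = "core_call")

test_that("orient_core_to_edge keeps the right limb and is idempotent", {
  # asymmetric: core at index 21 of 61 -> second limb longer
  conc <- matrix(1, 61, 3, dimnames = list(NULL, c("Mn", "Sr", "Rb")))
  conc[, "Sr"] <- seq_len(61)
  tr <- toy_transect(conc, positions = seq(0, 120, by = 2))
  cc <- mk_core_call(21L)
  ot <- orient_core_to_edge(tr, cc)
  expect_equal(ot$orientation, "core_to_edge")
  expect_equal(ot$positions[1], 0)                       # origin at the core
  expect_equal(length(ot), 61 - 21 + 1)                  # longer (second) limb
  expect_equal(unname(ot$concentrations[, "Sr"]), 21:61) # chronological order
  expect_equal(attr(ot, "discarded_limb"), "first")

  # idempotence: an oriented transect passes through unchanged
  expect_identical(orient_core_to_edge(ot, cc), ot)

  # equal limbs: tie broken toward the limb ending at the declared surface
  conc2 <- matrix(1, 41, 3, dimnames = list(NULL, c("Mn", "Sr", "Rb")))
  conc2[, "Sr"] <- seq_len(41)
  tr2 <- toy_transect(conc2)
  cc2 <- mk_core_call(21L)
  ot2 <- orient_core_to_edge(tr2, cc2, surface_end = "last")
  expect_equal(unname(ot2$concentrations[, "Sr"]), 21:41)  # second limb
  ot2f <- orient_core_to_edge(tr2, cc2, surface_end = "first")
  expect_equal(unname(ot2f$concentrations[, "Sr"]), 21:1)  # first limb

  # core at an end -> no usable limb
  cc_end <- cc2; cc_end$core_index <- 1L
  expect_error(orient_core_to_edge(tr2, cc_end), "limb")
})

test_that("split_cohort_by_core partitions and tabulates per site", {
  set.seed(21)
  trs <- c(lapply(1:3, function(i) {
    tr <- mn_peak_transect(60, 30); tr$fish_id <- paste0("c", i)
    tr$capture_site_id <- "sA"; tr
  }), lapply(1:2, function(i) {
    tr <- mn_peak_transect(60, NA); tr$fish_id <- paste0("n", i)
    tr$capture_site_id <- "sB"; tr
  }))
  calls <- lapply(trs, detect_core)
  sp <- split_cohort_by_core(trs, calls)
  expect_length(sp$with_core, 3)
  expect_length(sp$without_core, 2)
  expect_equal(sum(sp$table$n_core_identified,
                   sp$table$n_core_not_identified), 5)
  expect_equal(sp$table$n_core_identified[sp$table$site_id == "sA"], 3L)

  all_core <- split_cohort_by_core(trs[1:3], calls[1:3])
  expect_length(all_core$without_core, 0)
})

test_that("coreless fraction is recovered on a simulated cohort", {
  tpl <- default_river_template(3, separation_sd = 5, seed = 2)
  cfg <- cohort_config(tpl, default_scenarios(tpl, 25L),
                       n_fish_per_scenario = 25L, coreless_fraction = 0.3,
                       seed = 314L)
  coh <- simulate_cohort(cfg)
  calls <- lapply(coh$transects, detect_core)
  n <- length(coh$transects)
  n_missing <- sum(vapply(calls, function(cc) is.na(cc$core_index),
                          logical(1)))
  # detection matches the generated coreless flags exactly at high prominence
  expect_equal(n_missing, sum(coh$truth$coreless))
  # and the generated fraction sits inside the binomial 95% band around 0.3
  band <- stats::qbinom(c(0.025, 0.975), n, 0.3)
  expect_gte(n_missing, band[1])
  expect_lte(n_missing, band[2])
})
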