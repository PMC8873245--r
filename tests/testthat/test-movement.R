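mk_sites <- function(km = c(estuary = 10, middle = 89, upper = 159)) {
  df <- data.frame(site_id = names(km), river_system = "r",
                   section = names(km),
                   habitat = c("estuary", "middle river", "upper river")[
                     seq_along(km)],
                   river_km = unname(km), stringsAsFactors = FALSE)
  read_sites(df)
}

mk_pred <- function(sites_seq, fish = "f1")
  data.frame(fish_id = fish, partition_rank = seq_along(sites_seq),
             predicted_site = sites_seq, stringsAsFactors = FALSE)

test_that("reconstruct_movement derives events and directions", {
  sites <- mk_sites()
  # resident: no events
  h0 <- reconstruct_movement(mk_pred(rep("middle", 3)), sites)
  expect_equal(nrow(h0$events), 0)
  expect_equal(h0$max_displacement_km, 0)

  # downstream move late in life
  h1 <- reconstruct_movement(mk_pred(c("upper", "upper", "middle")), sites)
  expect_equal(nrow(h1$events), 1)
  expect_equal(h1$events$direction, "downstream")

  # estuary -> middle -> upper: two upstream events
  h2 <- reconstruct_movement(mk_pred(c("estuary", "middle", "upper")), sites)
  expect_equal(h2$events$direction, c("upstream", "upstream"))

  # unknown site km -> error
  bad <- mk_pred(c("middle", "nowhere"))
  expect_error(reconstruct_movement(bad, sites), "nowhere")

  # lateral transition at equal km (lake beside river)
  sites_lat <- read_sites(data.frame(
    site_id = c("lake", "riv"), river_system = "r",
    section = c("lake", "upper"), habitat = c("lake", "upper river"),
    river_km = c(50, 50)))
  hl <- reconstruct_movement(mk_pred(c("lake", "riv")), sites_lat)
  expect_equal(hl$events$direction, "lateral")
})

test_that("max displacement uses visited-site km extremes", {
  sites <- mk_sites(c(estuary = 10, middle = 89, upper = 159))
  h <- reconstruct_movement(mk_pred(c("estuary", "middle", "estuary")), sites)
  expect_equal(h$max_displacement_km, 79)   # km 10 vs 89
  expect_equal(max_displacement(c("estuary", "middle"), sites), 79)

  sites3 <- mk_sites(c(estuary = 0, middle = 80, upper = 149))
  expect_equal(max_displacement(c("estuary", "middle", "upper"), sites3), 149)
  expect_equal(max_displacement("middle", sites3), 0)

  # invariant to event ordering; zero iff a single site visited
  expect_equal(max_displacement(c("upper", "estuary", "middle"), sites3), 149)
  expect_equal(max_displacement(rep("upper", 5), sites3), 0)
})

test_that("estuarine signature detection separates habitats", {
  set.seed(81)
  n <- 25
  est <- data.frame(Sr = stats::rnorm(n, 10), Rb = stats::rnorm(n, 0),
                    habitat = "estuary")
  fw <- data.frame(Sr = stats::rnorm(n, 0), Rb = stats::rnorm(n, 10),
                   habitat = "upper river")
  em <- train_estuary_model(rbind(est, fw), elements = c("Sr", "Rb"),
                            ntree = 300, seed = 3)
  est_fp <- data.frame(Sr = stats::rnorm(5, 10), Rb = stats::rnorm(5, 0))
  fw_fp <- data.frame(Sr = stats::rnorm(5, 0), Rb = stats::rnorm(5, 10))
  d_est <- detect_estuarine_signature(est_fp, em)
  d_fw <- detect_estuarine_signature(fw_fp, em)
  expect_true(all(d_est$partition_flags))
  expect_true(d_est$fish_flag)
  expect_false(any(d_fw$partition_flags))
  expect_false(d_fw$fish_flag)

  # threshold 1.0 flags only unanimous votes
  d_strict <- detect_estuarine_signature(est_fp, em, threshold = 1.0)
  expect_equal(d_strict$partition_flags, d_strict$votes == 1)

  expect_error(train_estuary_model(est, elements = c("Sr", "Rb")),
               "both estuarine and freshwater")
})

test_that("life-history rules cover all label combinations", {
  sites <- mk_sites()
  h_est <- reconstruct_movement(mk_pred(rep("estuary", 3)), sites)
  expect_equal(classify_life_history(h_est, rep(TRUE, 3),
                                     "estuary")$life_history,
               "estuarine_resident")

  h_fw <- reconstruct_movement(mk_pred(c("upper", "middle", "middle")), sites)
  expect_equal(classify_life_history(h_fw, rep(FALSE, 3),
                                     "middle river")$life_history,
               "freshwater_resident")

  h_am <- reconstruct_movement(mk_pred(c("estuary", "middle", "upper")), sites)
  expect_equal(classify_life_history(h_am, c(TRUE, FALSE, FALSE),
                                     "upper river")$life_history,
               "amphidromous")

  # contradictory: uniformly estuarine but captured in fresh water
  h_ud <- reconstruct_movement(mk_pred(rep("upper", 2)), sites)
  expect_equal(classify_life_history(h_ud, rep(TRUE, 2),
                                     "upper river")$life_history,
               "undetermined")

  # labels are existential: duplicating a partition changes nothing
  h_dup <- reconstruct_movement(
    mk_pred(c("estuary", "middle", "middle", "upper")), sites)
  expect_equal(classify_life_history(h_dup, c(TRUE, FALSE, FALSE, FALSE),
                                     "upper river")$life_history,
               "amphidromous")
})

test_that("summarize_recruitment reports counts and integer percents", {
  mk_h <- function(lab) structure(list(life_history = lab),
                                  class = "movement_history")
  hs <- c(replicate(71, mk_h("freshwater_resident"), simplify = FALSE),
          replicate(24, mk_h("estuarine_resident"), simplify = FALSE),
          replicate(5, mk_h("amphidromous"), simplify = FALSE))
  s <- summarize_recruitment(hs)
  expect_equal(s$percent[match(c("freshwater_resident", "estuarine_resident",
                                 "amphidromous"), s$life_history)],
               c(71L, 24L, 5L))
  s2 <- summarize_recruitment(replicate(10, mk_h("freshwater_resident"),
                                        simplify = FALSE))
  expect_equal(s2$percent[s2$life_history == "freshwater_resident"], 100L)
  expect_equal(sum(s2$n), 10L)
})
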