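test_that("read_transects round-trips toy tables in both dialects", {
  reg <- toy_registry()
  wide <- data.frame(fish_id = "f1", site_id = "s1", position = c(1, 2, 3),
                     Mn = c(1, 2, 3), Sr = c(4, 5, 6), Rb = c(7, 8, 9))
  trs <- read_transects(wide, reg)
  expect_length(trs, 1)
  expect_equal(length(trs[["f1"]]), 3)
  expect_equal(unname(trs[["f1"]]$concentrations[, "Sr"]), c(4, 5, 6))

  # unsorted positions are reordered
  shuffled <- wide[c(3, 1, 2), ]
  shuffled$position <- c(3, 1, 2)
  tr2 <- read_transects(shuffled, reg)[["f1"]]
  expect_equal(tr2$positions, c(1, 2, 3))
  expect_equal(unname(tr2$concentrations[, "Mn"]), c(1, 2, 3))

  # two fish interleaved in long format
  long <- expand.grid(position = 1:4, element = c("Mn", "Sr", "Rb"),
                      fish_id = c("a", "b"), stringsAsFactors = FALSE)
  long <- long[sample(nrow(long)), ]
  long$site_id <- ifelse(long$fish_id == "a", "s1", "s2")
  long$value <- seq_len(nrow(long))
  trs2 <- read_transects(long, reg)
  expect_setequal(names(trs2), c("a", "b"))
  expect_equal(length(trs2[["a"]]), 4)
  expect_equal(length(trs2[["b"]]), 4)
  # values land at the right (fish, position, element) cells
  for (i in seq_len(nrow(long))) {
    r <- long[i, ]
    expect_equal(
      trs2[[r$fish_id]]$concentrations[
        match(r$position, trs2[[r$fish_id]]$positions), r$element],
      r$value, ignore_attr = TRUE)
  }
})

test_that("read_transects rejects duplicates and unknown elements", {
  reg <- toy_registry()
  dup <- data.frame(fish_id = "f1", site_id = "s1", position = c(1, 1),
                    Mn = 1:2, Sr = 1:2, Rb = 1:2)
  expect_error(read_transects(dup, reg), "f1")
  unk <- data.frame(fish_id = "f1", site_id = "s1", position = 1,
                    Mn = 1, Sr = 1, Rb = 1, Zz = 1)
  expect_error(read_transects(unk, reg), "Zz")
  expect_error(read_transects(unk, reg), "Mn")  # error lists the registry
})

test_that("unparseable rows are dropped and reported, not fatal", {
  reg <- toy_registry()
  tab <- data.frame(fish_id = "f1", site_id = "s1", position = 1:3,
                    Mn = c("1", "oops", "3"), Sr = c(1, 2, 3),
                    Rb = c(1, 2, 3), stringsAsFactors = FALSE)
  trs <- read_transects(tab, reg)
  expect_equal(length(trs[["f1"]]), 2)
  expect_equal(nrow(attr(trs, "rejected")), 1)
  expect_equal(attr(trs, "rejected")$position, 2)
})

test_that("write/read round trip is bit-exact (CSV and TSV sniffing)", {
  reg <- toy_registry()
  set.seed(11)
  trs <- lapply(1:3, function(i)
    toy_transect(matrix(stats::rexp(30) * 1e-5, 10, 3,
                        dimnames = list(NULL, reg$symbol)),
                 fish_id = paste0("f", i), positions = seq(0.5, 5, by = 0.5)))
  names(trs) <- paste0("f", 1:3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_transects(trs, path)
  back <- read_transects(path, reg)
  for (i in 1:3) {
    expect_identical(back[[i]]$positions, trs[[i]]$positions)
    expect_identical(unname(back[[i]]$concentrations),
                     unname(trs[[i]]$concentrations))
  }
  # TSV dialect
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(gsub(",", "\t", readLines(path)), tsv)
  back2 <- read_transects(tsv, reg)
  expect_identical(unname(back2[["f2"]]$concentrations),
                   unname(trs[["f2"]]$concentrations))
})

test_that("filter_elements applies the strict > threshold rule, pooled", {
  reg <- toy_registry()
  # 100 pooled points across 2 fish; Mn 26 below DL, Sr 25, Rb 0
  make_bdl <- function(n_true, n) c(rep(TRUE, n_true), rep(FALSE, n - n_true))
  bdl <- cbind(Mn = make_bdl(26, 100), Sr = make_bdl(25, 100),
               Rb = rep(FALSE, 100))
  conc <- matrix(1, 100, 3, dimnames = list(NULL, reg$symbol))
  trs <- list(
    toy_transect(conc[1:60, ], fish_id = "a", below_dl = bdl[1:60, ]),
    toy_transect(conc[61:100, ], fish_id = "b", below_dl = bdl[61:100, ]))
  res <- filter_elements(trs)
  expect_setequal(res$retained, c("Sr", "Rb"))   # 25/100 retained (strict >)
  expect_true(res$report$excluded[res$report$element == "Mn"])  # 26/100
  expect_equal(colnames(res$transects[[1]]$concentrations), c("Sr", "Rb"))

  # idempotent and order-independent over fish
  res2 <- filter_elements(res$transects)
  expect_equal(res2$retained, res$retained)
  res3 <- filter_elements(trs[c(2, 1)])
  expect_setequal(res3$retained, res$retained)

  # all excluded -> error
  all_bdl <- matrix(TRUE, 10, 3, dimnames = list(NULL, reg$symbol))
  expect_error(filter_elements(list(toy_transect(conc[1:10, ],
                                                 below_dl = all_bdl))),
               "no usable signal")
})

test_that("edge signature averages the inclusive 2-7 um window", {
  # positions 0..10, surface at 10; element value = position
  conc <- cbind(Mn = 0:10, Sr = 0:10, Rb = 0:10)
  tr <- toy_transect(conc, positions = 0:10)
  sig <- extract_edge_signature(tr)
  # distances 2..7 from surface are positions 3..8 -> mean 5.5
  expect_equal(unname(sig$fingerprint), rep(5.5, 3))
  expect_equal(sig$n_points, 6L)

  # constant transect
  sigc <- extract_edge_signature(toy_transect(matrix(5, 11, 3), positions = 0:10))
  expect_equal(unname(sigc$fingerprint), rep(5, 3))

  # truncated transect: only part of the window present
  trunc <- toy_transect(cbind(Mn = 1:4, Sr = 1:4, Rb = 1:4), positions = 0:3)
  sigt <- extract_edge_signature(trunc)
  expect_true(sigt$n_points < 6)
  expect_equal(sigt$n_points, 2L)  # distances 2 and 3

  # window values permuted -> unchanged fingerprint (mean invariance)
  perm <- conc
  perm[4:9, ] <- perm[sample(4:9), ]
  sigp <- extract_edge_signature(toy_transect(perm, positions = 0:10))
  expect_equal(sigp$fingerprint, sig$fingerprint)

  # no points in window -> error naming the fish
  short <- toy_transect(cbind(Mn = 1:2, Sr = 1:2, Rb = 1:2),
                        positions = c(0, 1), fish_id = "shorty")
  expect_error(extract_edge_signature(short), "shorty")
})
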