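# Small in-code fixtures shared across test files.

# minimal registry used by toy transects
toy_registry <- function() element_registry(c("Mn", "Sr", "Rb"), c(55, 88, 85))

# one-fish transect with given element matrix
toy_transect <- function(conc, fish_id = "f1", site_id = "s1",
                         positions = NULL, below_dl = NULL,
                         orientation = "raw") {
  conc <- as.matrix(conc)
  if (is.null(positions)) positions <- seq_len(nrow(conc))
  elemental_transect(fish_id, site_id, positions, conc, below_dl,
                     orientation = orientation)
}

# transect whose Mn series is flat baseline + optional Gaussian peak
mn_peak_transect <- function(n = 80, core_idx = 40, height = 8,
                             width = 2.5, noise_sd = 0.05,
                             baseline = 1) {
  mn <- baseline + stats::rnorm(n, 0, noise_sd * baseline)
  if (!is.na(core_idx))
    mn <- mn + height * baseline *
      exp(-0.5 * ((seq_len(n) - core_idx) / width)^2)
  conc <- cbind(Mn = pmax(mn, 1e-9),
                Sr = pmax(stats::rnorm(n, 1, 0.05), 1e-9),
                Rb = pmax(stats::rnorm(n, 1, 0.05), 1e-9))
  toy_transect(conc)
}

# edge-signature table with site-separated Gaussian clusters:
# k sites, n fish per site, p elements, centroid separation `sep` pooled sd
separable_edges <- function(n_per_site = 15, k = 2, p = 4, sep = 10,
                            sd = 1, site_prefix = "site") {
  sites <- paste0(site_prefix, seq_len(k))
  rows <- lapply(seq_len(k), function(i) {
    mu <- rep(0, p)
    mu[1] <- sep * sd * (i - 1) / sqrt(1)  # separation along element 1
    fp <- matrix(stats::rnorm(n_per_site * p, 0, sd), n_per_site, p)
    fp <- sweep(fp, 2, mu, `+`)
    data.frame(fish_id = sprintf("%s_f%02d", sites[i], seq_len(n_per_site)),
               site_id = sites[i], fp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[-(1:2)] <- paste0("E", seq_len(p))
  rownames(out) <- NULL
  out
}

# piecewise-constant multivariate series with Gaussian noise;
# breaks: 0-based interior breakpoints; shift: mean shift in sd units
piecewise_series <- function(n, breaks, p = 3, shift_sd = 5, noise_sd = 1) {
  bounds <- c(0, sort(breaks), n)
  k <- length(bounds) - 1
  mu <- matrix(stats::rnorm(k * p, 0, 1e-9), k, p)
  for (j in seq_len(p)) mu[, j] <- shift_sd * noise_sd * seq_len(k) *
      rep_len(c(1, -1), k)[seq_len(k)]  # alternate direction, distinct means
  x <- matrix(NA_real_, n, p)
  for (s in seq_len(k)) {
    idx <- (bounds[s] + 1):bounds[s + 1]
    x[idx, ] <- matrix(rep(mu[s, ], each = length(idx)), length(idx), p) +
      matrix(stats::rnorm(length(idx) * p, 0, noise_sd), length(idx), p)
  }
  x
}
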