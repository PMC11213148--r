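test_that("histogram bins conserve counts and honor the auto rule", {
  p <- c(rep(0.5, 100))
  h <- pr_histogram(p, 10)
  expect_equal(sum(h$counts), 100)
  expect_equal(sum(h$counts == 100), 1)  # one bin holds everything

  set.seed(2)
  p2 <- runif(4096, 0.01, 0.9)
  h2 <- pr_histogram(p2, "auto")
  expect_equal(length(h2$counts), 64)    # ceiling(sqrt(4096))
  expect_equal(sum(h2$counts), 4096)
  expect_true(all(diff(h2$bin_edges) > 0))

  expect_error(pr_histogram(numeric(0)), "empty")
  expect_error(pr_histogram(c(0.5, 1.5)), "\\(0, 1\\]")
})

test_that("Lorentzian fit recovers exact model parameters", {
  centers_n <- 40
  edges <- seq(0.1, 0.9, length.out = centers_n + 1)
  centers <- (edges[-1] + edges[-(centers_n + 1)]) / 2
  counts <- 100 * 0.05^2 / ((centers - 0.6)^2 + 0.05^2)
  h <- structure(list(bin_edges = edges, bin_centers = centers,
                      counts = counts, bin_rule = "fixed"),
                 class = "pr_histogram")
  fit <- fit_lorentzian(h)
  expect_true(fit$converged)
  expect_equal(fit$lambda0, 0.6, tolerance = 1e-6)
  expect_equal(fit$gamma, 0.05, tolerance = 1e-6)
  expect_equal(fit$amplitude, 100, tolerance = 1e-4)
})

test_that("Lorentzian fit recovers parameters from sampled data", {
  # samples from a Cauchy(0.55, 0.04) truncated to [0, 1]
  set.seed(77)
  draws <- stats::rcauchy(40000, location = 0.55, scale = 0.04)
  draws <- draws[draws > 0 & draws <= 1][1:10000]
  h <- pr_histogram(draws, 64)
  fit <- fit_lorentzian(h)
  # oracle: exhaustive grid search minimizing the same residual
  oracle <- qldenoise:::lorentzian_grid_search(h$bin_centers,
                                               as.numeric(h$counts))
  expect_lt(abs(fit$lambda0 - 0.55), 0.01)
  expect_lt(abs(fit$gamma - 0.04), 0.3 * 0.04)
  expect_lt(abs(fit$lambda0 - oracle$lambda0), 0.01)
  expect_lte(fit$residual_norm, oracle$residual_norm * 1.001)
})

test_that("symmetric triangular histogram peaks within one bin of center", {
  centers_n <- 21
  edges <- seq(0.2, 0.8, length.out = centers_n + 1)
  centers <- (edges[-1] + edges[-(centers_n + 1)]) / 2
  counts <- 100 - 300 * abs(centers - 0.5)
  h <- structure(list(bin_edges = edges, bin_centers = centers,
                      counts = pmax(counts, 0), bin_rule = "fixed"),
                 class = "pr_histogram")
  fit <- fit_lorentzian(h)
  bin_w <- mean(diff(edges))
  expect_lt(abs(fit$lambda0 - 0.5), bin_w)
  # brute-force fit agrees on the peak location
  oracle <- qldenoise:::lorentzian_grid_search(centers, pmax(counts, 0))
  expect_lt(abs(oracle$lambda0 - 0.5), bin_w)
})

test_that("degenerate histograms are rejected with guidance", {
  h <- pr_histogram(rep(0.3, 50), 10)
  expect_error(fit_lorentzian(h), "non-empty bins")
})

test_that("mode selection reproduces the constructed three-block spectrum", {
  # 100 localized + 800 delocalized + 100 localized modes
  p <- c(rep(0.05, 100), rep(0.6, 800), rep(0.05, 100))
  sp <- mode_spectrum(seq_len(1000) * 0.01, normalized_participation = p)
  fit <- structure(list(amplitude = 800, lambda0 = 0.6, gamma = 0.05,
                        converged = TRUE, residual_norm = 0, method = "exact"),
                   class = "lorentzian_fit")
  sel <- select_modes(sp, fit, k = 1)
  expect_equal(sel$p_star, 0.55)
  expect_equal(sel$n_kept, 200)
  expect_equal(sel$compression_fraction, 0.8)
  expect_equal(sel$E_low, 100 * 0.01)
  expect_equal(sel$E_high, 901 * 0.01)
  expect_false(sel$warning_flag)
  expect_equal(sum(sel$keep_mask), sel$n_kept)
  expect_equal(sel$compression_fraction + sel$n_kept / 1000, 1)
})

test_that("uninformative thresholds keep everything and raise the flag", {
  p <- rep(0.1, 50)
  sp <- mode_spectrum(seq_len(50), normalized_participation = p)
  fit <- structure(list(amplitude = 1, lambda0 = 0.5, gamma = 0.1,
                        converged = TRUE, residual_norm = 0, method = "exact"),
                   class = "lorentzian_fit")
  expect_warning(sel <- select_modes(sp, fit), "uninformative")
  expect_true(sel$warning_flag)
  expect_equal(sel$n_kept, 50)
  expect_equal(sel$compression_fraction, 0)
})

test_that("k = 0 limit matches a brute-force recomputation", {
  set.seed(13)
  p <- pmin(pmax(c(stats::rbeta(30, 1, 8), stats::rbeta(40, 20, 8),
                   stats::rbeta(30, 1, 8)), 1e-4), 1)
  ev <- sort(stats::runif(100))
  sp <- mode_spectrum(ev, normalized_participation = p)
  fit <- structure(list(amplitude = 1, lambda0 = 0.7, gamma = 1e-9,
                        converged = TRUE, residual_norm = 0, method = "exact"),
                   class = "lorentzian_fit")
  sel_k0 <- suppressWarnings(select_modes(sp, fit, k = 0))
  # brute force: same rule evaluated directly at p* = lambda0
  sm <- as.numeric(stats::runmed(p, 5))
  below <- sm < 0.7
  nl <- if (below[1]) rle(below)$lengths[1] else 0L
  rb <- rev(below)
  nh <- if (rb[1]) rle(rb)$lengths[1] else 0L
  keep <- seq_along(ev) <= nl | seq_along(ev) > 100 - nh
  expect_equal(sel_k0$keep_mask, keep)
})

test_that("selection keep count is monotone nonincreasing in k", {
  set.seed(31)
  p <- pmin(pmax(c(stats::rbeta(50, 2, 10), stats::rbeta(100, 15, 6),
                   stats::rbeta(50, 2, 10)), 1e-4), 1)
  sp <- mode_spectrum(seq_len(200), normalized_participation = p)
  fit <- structure(list(amplitude = 1, lambda0 = 0.65, gamma = 0.08,
                        converged = TRUE, residual_norm = 0, method = "exact"),
                   class = "lorentzian_fit")
  kept <- vapply(c(0, 0.5, 1, 1.5, 2), function(k) {
    suppressWarnings(select_modes(sp, fit, k = k)$n_kept)
  }, numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("selection depends only on eigenvalue order and p values", {
  set.seed(41)
  p <- pmin(pmax(c(stats::rbeta(30, 2, 12), stats::rbeta(60, 16, 7),
                   stats::rbeta(30, 2, 12)), 1e-4), 1)
  ev <- sort(stats::runif(120))
  fit <- structure(list(amplitude = 1, lambda0 = 0.65, gamma = 0.07,
                        converged = TRUE, residual_norm = 0, method = "exact"),
                   class = "lorentzian_fit")
  sel <- suppressWarnings(
    select_modes(mode_spectrum(ev, normalized_participation = p), fit))
  # permute, then rebuild in sorted order: identical mask
  perm <- sample(120)
  ord <- order(ev[perm])
  sel2 <- suppressWarnings(select_modes(
    mode_spectrum(ev[perm][ord], normalized_participation = p[perm][ord]),
    fit))
  expect_identical(sel$keep_mask, sel2$keep_mask)
})

test_that("selection CSV export has the documented layout", {
  p <- c(rep(0.05, 10), rep(0.6, 30), rep(0.05, 10))
  sp <- mode_spectrum(seq_len(50), normalized_participation = p)
  fit <- structure(list(amplitude = 1, lambda0 = 0.6, gamma = 0.05,
                        converged = TRUE, residual_norm = 0, method = "exact"),
                   class = "lorentzian_fit")
  sel <- select_modes(sp, fit)
  path <- withr::local_tempfile(fileext = ".csv")
  write_selection_csv(sp, sel, path)
  back <- utils::read.csv(path)
  expect_named(back, c("mode_index", "eigenvalue",
                       "normalized_participation", "kept"))
  expect_equal(sum(back$kept), sel$n_kept)
})
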