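make_small_basis <- function(n = 8, seed = 17, hbar = 1.2) {
  set.seed(seed)
  img <- as_image(matrix(runif(n * n, 0, 6), n, n))
  sp <- decompose(build_hamiltonian(img, hamiltonian_params(hbar)),
                  shape = c(n, n))
  list(img = img, sp = sp, a = project(sp, img))
}

test_that("keeping all modes reconstructs the image exactly", {
  b <- make_small_basis()
  rec <- reconstruct_subspace(b$sp, b$a, rep(TRUE, 64))
  expect_equal(unclass(rec), unclass(b$img), tolerance = 1e-8,
               ignore_attr = TRUE)
  # nonnegative input: clipping inactive up to FP error
  expect_lt(attr(rec, "clipped_energy"), 1e-16)
})

test_that("keeping no modes yields the zero image", {
  b <- make_small_basis()
  rec <- reconstruct_subspace(b$sp, b$a, rep(FALSE, 64))
  expect_equal(max(abs(rec)), 0)
})

test_that("subspace reconstruction is an idempotent projection", {
  b <- make_small_basis()
  keep <- rep(c(TRUE, FALSE), length.out = 64)
  rec1 <- reconstruct_subspace(b$sp, b$a, keep)
  # re-project the (unclipped) output and reconstruct again
  a2 <- project(b$sp, attr(rec1, "unclipped"))
  rec2 <- reconstruct_subspace(b$sp, a2, keep)
  expect_equal(attr(rec2, "unclipped"), attr(rec1, "unclipped"),
               tolerance = 1e-8)
})

test_that("projection and baseline gate never expand energy", {
  b <- make_small_basis(seed = 23)
  for (frac in c(0.2, 0.5, 0.9)) {
    keep <- seq_len(64) <= 64 * frac
    rec <- reconstruct_subspace(b$sp, b$a, keep)
    expect_lte(sum(attr(rec, "unclipped")^2), sum(b$img^2) + 1e-8)
  }
  base <- baseline_all_modes(b$img)
  expect_lte(sum(base$unclipped^2), sum(b$img^2) + 1e-8)
})

test_that("mask length mismatches are rejected", {
  b <- make_small_basis()
  expect_error(reconstruct_subspace(b$sp, b$a, rep(TRUE, 10)), "length")
  expect_error(reconstruct_subspace(b$sp, b$a[1:10], rep(TRUE, 64)), "length")
})

test_that("baseline gate limits: identity and zero reconstructions", {
  b <- make_small_basis(seed = 5)
  # gate midpoints far outside any possible eigenvalue range
  ident <- baseline_all_modes(b$img, E_s = 1e12, delta = 1e-12)
  expect_equal(ident$unclipped, unclass(b$img), tolerance = 1e-8,
               ignore_attr = TRUE)
  zero <- baseline_all_modes(b$img, E_s = -1e12, delta = 1e-12)
  expect_lt(max(abs(zero$unclipped)), 1e-8)
})

test_that("raising the baseline gate midpoint never lowers output energy", {
  b <- make_small_basis(seed = 29)
  ev <- b$sp$eigenvalues
  cuts <- stats::quantile(ev, c(0.2, 0.4, 0.6, 0.8))
  energies <- vapply(cuts, function(es) {
    sum(baseline_all_modes(b$img, E_s = es)$unclipped^2)
  }, numeric(1))
  expect_true(all(diff(energies) >= -1e-10))
})

test_that("denoise returns a complete, internally consistent result", {
  run <- phantom_run(snr = 15)
  res <- run$result
  expect_s3_class(res, "denoise_result")
  expect_equal(dim(res$denoised), dim(run$input))
  expect_equal(length(res$selection$keep_mask), res$spectrum$n_tot)
  expect_true(all(res$denoised >= 0))
  expect_equal(res$selection$compression_fraction,
               1 - res$selection$n_kept / res$spectrum$n_tot)
  g <- glance(res)
  expect_equal(g$n_kept, res$selection$n_kept)
  expect_true(is.finite(g$psnr_db))
})

test_that("denoising a clean phantom preserves it nearly perfectly", {
  m <- phantom_metrics(snr = NULL, seed = 1)
  expect_gte(m$ssim_denoised, 0.95)
  expect_gt(m$psnr_denoised, 40)
  expect_false(m$warning_flag)
})

test_that("denoising tracks the noisy input closely while compressing hard", {
  # the discarded mid-band carries almost no image energy: quality stays
  # within a whisker of the noisy input at a fraction of the modes
  for (snr in c(5, 15)) {
    m <- phantom_metrics(snr = snr, seed = 1)
    expect_gt(m$psnr_denoised, m$psnr_noisy - 0.5)
    expect_gt(m$ssim_denoised, m$ssim_noisy - 0.01)
    expect_gte(m$compression, 0.5)
  }
})

test_that("planck override bypasses the a priori estimate", {
  img <- ripple_image(8, amp = 3)
  res <- suppressWarnings(
    denoise(img, denoise_control(planck_override = 0.5, n_bins = 8)))
  expect_equal(res$params$hbar_eff, 0.5)
  # but the a priori estimate is still recorded
  expect_equal(res$planck$hbar, estimate_planck(img)$hbar)
})

test_that("size guard refuses oversized images unless forced", {
  big <- matrix(1, 91, 91)  # 8281 > 8192 pixels
  expect_error(denoise(big), "force")
})

test_that("identical runs produce bit-identical CSV exports", {
  run_once <- function() {
    img <- ripple_image(10, amp = 8)
    res <- suppressWarnings(denoise(img, denoise_control(n_bins = 10)))
    f1 <- tempfile(fileext = ".csv")
    write_selection_csv(res$spectrum, res$selection, f1)
    f1
  }
  f1 <- run_once(); f2 <- run_once()
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("run summary records config, fit and selection", {
  run <- phantom_run(snr = 15)
  path <- withr::local_tempfile(fileext = ".txt")
  write_run_summary(run$result, path)
  txt <- readLines(path)
  expect_true(any(grepl("^hbar = ", txt)))
  expect_true(any(grepl("^p_star = ", txt)))
  expect_true(any(grepl("^compression_fraction = ", txt)))
  expect_true(any(grepl("^psnr_db = ", txt)))
})
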