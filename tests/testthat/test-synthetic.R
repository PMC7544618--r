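test_that("cluster layouts encode mirror-symmetric sector maps", {
  lay <- cluster_layout()
  expect_equal(designed_reversals(lay), 4L)
  expect_equal(designed_reversals(cluster_layout(
    n_sectors = 6, sector_style = "flat")), 6L)
  expect_equal(designed_reversals(cluster_layout(
    n_sectors = 1, sector_style = "flat")), 0L)
  # gradients alternate in sign between adjacent sectors
  g <- vapply(lay$polar_maps, function(m) sign(diff(m)), numeric(1))
  expect_true(all(g[-1] != g[-length(g)]))
  expect_error(cluster_layout(ecc_gradient_deg_mm = 0), "degenerate")
})

test_that("sheets follow the layout's eccentricity and size laws", {
  lay <- cluster_layout()
  sheet <- make_cluster_sheet(lay, 300, seed = 3)
  r <- sqrt(sheet$flat_x^2 + sheet$flat_y^2)
  ecc <- sqrt(sheet$x0^2 + sheet$y0^2)
  # eccentricity strictly linear in distance from the confluence
  expect_equal(ecc, lay$ecc_gradient_deg_mm * r, tolerance = 1e-12)
  expect_lt(min(ecc), 5)            # near-zero at the confluence
  # monotone along any radial spoke
  phi <- atan2(sheet$flat_y, sheet$flat_x)
  spoke <- which(abs(phi - phi[1]) < 0.05)
  o <- order(r[spoke])
  expect_true(all(diff(ecc[spoke][o]) >= 0))
  # sigma laws per sector style
  sloped <- grepl("sloped", sheet$area)
  expect_equal(sheet$sigma[sloped],
               lay$sigma_intercept + lay$sigma_slope * ecc[sloped])
  expect_true(all(sheet$sigma[!sloped] == lay$sigma_flat))
  # all pRFs contralateral for a left-hemisphere sheet
  expect_true(all(sheet$x0 >= 0))
  expect_true(all(sheet$sigma > 0))
  expect_false(anyDuplicated(sheet$node_id) > 0)
})

test_that("node ground truth round-trips through sheet TSV files", {
  sheet <- test_sheet(20)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_sheet_tsv(sheet, p)
  back <- read_sheet_tsv(p)
  expect_equal(as.data.frame(back), as.data.frame(sheet),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("simulated responses behave like Gaussian-overlap drives", {
  movies <- test_movies()
  # a pRF far outside the stimulated field is silent
  far <- simulate_node_bold(c(80, 80, 3), movies$cw)
  expect_lt(max(abs(attr(far, "clean"))), 1e-8)
  # doubling the amplitude doubles the clean response exactly
  a1 <- simulate_node_bold(c(10, 5, 4), movies$cw, amp = 1)
  a2 <- simulate_node_bold(c(10, 5, 4), movies$cw, amp = 2)
  expect_equal(attr(a2, "clean"), 2 * attr(a1, "clean"))
  # a stimulated pRF responds periodically at the cycle frequency
  resp <- attr(a1, "clean")[-(1:5)]
  cyc <- matrix(resp, nrow = 22)
  expect_gt(stats::cor(cyc[, 1], rowMeans(cyc)), 0.99)
  expect_error(simulate_node_bold(c(0, 0, 0), movies$cw), "sigma")
  empty <- movies$cw
  empty$frames[] <- FALSE
  expect_error(simulate_node_bold(c(0, 0, 3), empty), "empty")
})

test_that("HRF kernel peaks where asked and convolution is causal", {
  k <- hrf_kernel(hrf_double_gamma(), dt = 0.5)
  t_axis <- seq(0, 30, by = 0.5)
  expect_equal(t_axis[which.max(k)], 4)
  expect_equal(max(k), 1)
  expect_lt(min(k), 0)  # undershoot present
  x <- c(1, rep(0, 99))
  expect_equal(convolve_causal(x, k)[seq_along(k)], k, tolerance = 1e-12)
  # matrix form agrees with FFT convolution
  set.seed(1)
  z <- rnorm(100)
  expect_equal(drop(prfmapr:::.conv_matrix(k, 100) %*% z),
               convolve_causal(z, k), tolerance = 1e-10)
})

test_that("volume embedding separates brain and out-of-brain voxels", {
  sheet <- test_sheet(25, seed = 4)
  sim <- simulate_sheet_bold(sheet, test_movies()$cw, amp = 1)
  clean <- attr(sim, "clean")
  nuis <- make_nuisance_courses(ncol(clean), k = 4, seed = 2)
  run <- suppressWarnings(   # node collisions in voxels are summed
    embed_runs_in_volume(sheet, clean, nuisance = nuis, seed = 5))
  flat <- matrix(run$volume, prod(dim(run$volume)[1:3]),
                 dim(run$volume)[4])
  v <- apply(flat, 1, stats::var)
  expect_gt(stats::median(v[!as.vector(run$brain_mask)]),
            stats::median(v[as.vector(run$brain_mask)]))

  # denoising with known nuisance brings node series closer to truth
  ntc <- sample_to_nodes(run, sheet, run_type = "cw", leadin_TRs = 5)
  nr <- extract_noise_regressors(run, k = 4)
  den <- regress_out(ntc$data, nr)
  r_raw <- vapply(seq_len(nrow(clean)), function(i)
    stats::cor(ntc$data[i, ], clean[i, ]), numeric(1))
  r_den <- vapply(seq_len(nrow(clean)), function(i)
    stats::cor(den[i, ], clean[i, ]), numeric(1))
  expect_gt(stats::median(r_den), stats::median(r_raw))
  expect_gt(stats::median(r_den), 0.85)
})

test_that("without nuisance, denoising removes only its projection", {
  sheet <- test_sheet(10, seed = 8)
  sim <- simulate_sheet_bold(sheet, test_movies()$cw, amp = 1)
  clean <- attr(sim, "clean")
  run <- embed_runs_in_volume(sheet, clean, nuisance = NULL,
                              white_sd = 0.05, seed = 6)
  ntc <- sample_to_nodes(run, sheet, run_type = "cw", leadin_TRs = 5)
  k <- 4
  nr <- extract_noise_regressors(run, k = k)
  den <- regress_out(ntc$data, nr)
  # regressors are then white-noise PCs: they can remove at most ~k/T of
  # the signal variance, so pre/post series stay highly correlated
  rr <- vapply(seq_len(nrow(den)), function(i)
    stats::cor(den[i, ], ntc$data[i, ]), numeric(1))
  expect_gt(min(rr), sqrt(1 - 3 * k / ncol(den)))
  expect_gt(stats::median(rr), 0.97)
})

test_that("volumes round-trip through NIfTI", {
  arr <- array(rnorm(4 * 5 * 3 * 6), c(4, 5, 3, 6))
  p <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume_nifti(arr, p)
  back <- read_volume_nifti(p)
  expect_equal(dim(back), dim(arr))
  expect_equal(back, arr, tolerance = 1e-6, ignore_attr = TRUE)
})
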