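# small synthetic volume: out-of-brain voxels share one sinusoid
sinusoid_volume <- function(n_t = 60, n_out_sin = 40, seed = 1) {
  dims <- c(6, 6, 4)
  mask <- array(FALSE, dims)
  mask[3:4, 3:4, 2:3] <- TRUE
  with_seed(seed, {
    flat <- matrix(rnorm(prod(dims) * n_t, 100, 0.01), prod(dims), n_t)
    s <- sin(2 * pi * seq_len(n_t) / 12)
    out_idx <- which(!as.vector(mask))[seq_len(n_out_sin)]
    flat[out_idx, ] <- flat[out_idx, ] +
      outer(runif(n_out_sin, 2, 4), s)
    list(volume = array(flat, c(dims, n_t)), mask = mask, s = s)
  })
}

test_that("PCA noise regressors recover a shared out-of-brain source", {
  v <- sinusoid_volume()
  nr <- extract_noise_regressors(v$volume, v$mask, fraction = 0.5, k = 3)
  expect_gt(abs(stats::cor(nr[, 1], v$s)), 0.99)
  expect_equal(crossprod(nr), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_identical(formals(extract_noise_regressors)$k, 18)
  expect_identical(formals(extract_noise_regressors)$fraction, 0.10)
})

test_that("degenerate nuisance inputs are rejected", {
  v <- sinusoid_volume()
  const <- v$volume
  flat <- matrix(const, prod(dim(const)[1:3]), dim(const)[4])
  flat[!as.vector(v$mask), ] <- 7  # constant out-of-brain series
  const <- array(flat, dim(const))
  expect_error(extract_noise_regressors(const, v$mask, fraction = 0.5,
                                        k = 3), "z-score")
  expect_error(extract_noise_regressors(v$volume, v$mask,
                                        fraction = 0.01, k = 18),
               "fewer eligible")
})

test_that("nuisance regression removes exactly the fitted projection", {
  set.seed(2)
  reg <- matrix(rnorm(200), 100, 2)
  # a series equal to a regressor vanishes
  expect_lt(max(abs(regress_out(reg[, 1], reg))), 1e-10)
  # residuals are uncorrelated with every regressor
  y <- rnorm(100)
  res <- regress_out(y, reg)
  expect_lt(max(abs(stats::cor(res, reg))), 1e-10)
  # a series orthogonal to the regressors is returned demeaned
  q <- qr.Q(qr(cbind(1, reg)))
  y_orth <- y - q %*% crossprod(q, y)
  expect_equal(drop(regress_out(drop(y_orth), reg)), drop(y_orth),
               tolerance = 1e-10)
  # mixture: removing known nuisance improves similarity to the truth
  truth <- sin(seq_len(100) / 5)
  mixed <- truth + reg %*% c(2, -1)
  expect_gt(stats::cor(regress_out(drop(mixed), reg), truth),
            stats::cor(drop(mixed), truth))
  # collinear columns are dropped with a warning
  expect_warning(regress_out(y, cbind(reg, reg[, 1])), "collinear")
})

test_that("surface sampling converts to PSC and averages 7 points", {
  sheet <- data.frame(node_id = 1:2, vol_x = c(3, 5.5), vol_y = c(3, 4),
                      vol_z = c(3, 3), nx = 0, ny = 0, nz = 1)
  # uniform volume: PSC is identically zero
  vol <- array(50, c(8, 8, 6, 10))
  ntc <- sample_to_nodes(vol, sheet)
  expect_true(all(abs(ntc$data) < 1e-12))
  # multiplicative gradient along the normal: every sampling point has
  # the same PSC profile, so the node equals the mid-point series
  # (trilinear interpolation is linear and the offsets are symmetric)
  base <- 100 + sin(1:10)
  grad <- array(0, c(8, 8, 6, 10))
  for (z in 1:6) grad[, , z, ] <- z * outer(rep(1, 64), base)
  ntc2 <- sample_to_nodes(grad, sheet)
  expect_equal(ntc2$data[1, ], (base / mean(base) - 1) * 100,
               tolerance = 1e-9, ignore_attr = TRUE)
  # nodes outside the volume are excluded with a warning
  out_sheet <- rbind(sheet, data.frame(node_id = 3, vol_x = 50,
                                       vol_y = 3, vol_z = 3, nx = 0,
                                       ny = 0, nz = 1))
  expect_warning(ntc3 <- sample_to_nodes(vol, out_sheet), "outside")
  expect_equal(nrow(ntc3$data), 2)
})

test_that("embedded node signals are recovered with high fidelity", {
  sheet <- test_sheet(15, seed = 9)
  sim <- simulate_sheet_bold(sheet, test_movies()$cw, amp = 1)
  clean <- attr(sim, "clean")
  run <- suppressWarnings(   # node collisions in voxels are summed
    embed_runs_in_volume(sheet, clean, nuisance = NULL,
                         white_sd = 1e-4, seed = 2))
  ntc <- sample_to_nodes(run, sheet, run_type = "cw", leadin_TRs = 5)
  rr <- vapply(seq_len(nrow(clean)), function(i)
    stats::cor(ntc$data[i, ], clean[i, ]), numeric(1))
  expect_gt(min(rr), 0.95)
})

test_that("run averaging pools runs of one type only", {
  m <- matrix(rnorm(40), 4, 10)
  ntc <- node_timecourses(m, run_type = "cw")
  expect_equal(average_runs(list(ntc, ntc))$data, m)
  expect_equal(average_runs(list(ntc, ntc))$n_runs_averaged, 2)
  # averaging two noisy runs halves the noise variance
  set.seed(3)
  sig <- matrix(rep(sin(1:200 / 7), 50), 50, 200, byrow = TRUE)
  r1 <- node_timecourses(sig + matrix(rnorm(10000), 50), run_type = "cw")
  r2 <- node_timecourses(sig + matrix(rnorm(10000), 50), run_type = "cw")
  avg <- average_runs(list(r1, r2))
  v1 <- mean(apply(r1$data - sig, 1, stats::var))
  va <- mean(apply(avg$data - sig, 1, stats::var))
  expect_equal(va / v1, 0.5, tolerance = 0.1)
  r3 <- node_timecourses(m, run_type = "ccw")
  expect_error(average_runs(list(ntc, r3)), "mixed")
  expect_error(average_runs(list()), "no runs")
})

test_that("harmonic filtering keeps exactly the cycle-locked content", {
  n_cyc <- 5; cyc <- 22; n <- n_cyc * cyc
  t_idx <- seq_len(n)
  # a pure sinusoid at f0 passes unchanged
  s <- cos(2 * pi * t_idx / cyc + 0.4)
  out <- harmonic_filter_and_collapse(matrix(s, 1), cyc, 0)
  expect_equal(drop(out), s[seq_len(cyc)], tolerance = 1e-10,
               ignore_attr = TRUE)
  # broadband content orthogonal to the harmonic bins is annihilated
  set.seed(4)
  noise <- rnorm(n)
  periodic <- rep(colMeans(matrix(noise, n_cyc, cyc, byrow = TRUE)),
                  n_cyc)
  resid <- noise - periodic        # no cycle-locked component left
  out2 <- harmonic_filter_and_collapse(matrix(resid, 1), cyc, 0)
  expect_lt(max(abs(out2 - mean(resid) * 0)), 1e-10)
  expect_error(harmonic_filter_and_collapse(matrix(rnorm(100), 1), 22, 0),
               "integer number of cycles")
})

test_that("filter + collapse equals cycle averaging of demeaned series", {
  set.seed(5)
  x <- matrix(rnorm(10 * 115), 10, 115)
  got <- harmonic_filter_and_collapse(x, cycle_TRs = 22, leadin_TRs = 5)
  xx <- x[, -(1:5)]
  xx <- xx - rowMeans(xx)
  direct <- t(apply(xx, 1, function(v)
    rowMeans(matrix(v, nrow = 22))))
  expect_equal(got, direct, tolerance = 1e-10, ignore_attr = TRUE)
  # idempotence: re-filtering the tiled cycle average changes nothing
  tiled <- got[, rep(seq_len(22), 5)]
  again <- harmonic_filter_and_collapse(tiled, 22, 0)
  expect_equal(again, got, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("averaging runs and filtering commute", {
  set.seed(6)
  r1 <- node_timecourses(matrix(rnorm(5 * 115), 5), run_type = "cw",
                         leadin_TRs = 5)
  r2 <- node_timecourses(matrix(rnorm(5 * 115), 5), run_type = "cw",
                         leadin_TRs = 5)
  a <- harmonic_filter_and_collapse(average_runs(list(r1, r2)))
  b <- (harmonic_filter_and_collapse(r1) +
          harmonic_filter_and_collapse(r2)) / 2
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("condition concatenation builds 88-sample vectors", {
  parts <- lapply(1:4, function(i) matrix(rnorm(3 * 22), 3))
  out <- concat_conditions(parts[[1]], parts[[2]], parts[[3]], parts[[4]])
  expect_equal(dim(out), c(3L, 88L))
  expect_equal(out[, 23:44], parts[[2]], ignore_attr = TRUE)
  expect_error(concat_conditions(parts[[1]], parts[[2]], parts[[3]],
                                 NULL), "required")
})

test_that("volume smoothing has the requested FWHM and conserves mass", {
  vol <- array(0, c(21, 21, 21))
  vol[11, 11, 11] <- 1
  sm <- smooth_volume(vol, fwhm_mm = 2)
  expect_equal(sum(sm), 1, tolerance = 1e-3)
  prof <- sm[, 11, 11]
  half <- max(prof) / 2
  fwhm <- sum(prof >= half)  # voxels above half maximum
  expect_lt(abs(fwhm - 2), 1.01)
  expect_equal(smooth_volume(array(3, c(5, 5, 5)), 2),
               array(3, c(5, 5, 5)), tolerance = 1e-10)
  expect_identical(smooth_volume(vol, 0), vol)
  expect_error(smooth_volume(vol, -1), "non-negative")
})

test_that("node time courses round-trip through TSV", {
  ntc <- node_timecourses(matrix(rnorm(20), 4, 5,
                                 dimnames = list(1:4, NULL)),
                          TR = 2, run_type = "exp", cycle_TRs = 22,
                          leadin_TRs = 5, n_runs_averaged = 3L)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_ntc_tsv(ntc, p)
  back <- read_ntc_tsv(p)
  expect_equal(back$data, ntc$data, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(back$run_type, "exp")
  expect_equal(back$n_runs_averaged, 3L)
  expect_equal(back$leadin_TRs, 5L)
})
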