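#' Search-grid specification for pRF fitting
#'
#' The position lattice is a square grid of `n_side x n_side` centres
#' spanning `xlim` (and the same range vertically); sigma candidates
#' are log-spaced over `sigma_range` (log spacing resolves small pRFs
#' better; linear spacing is available via `log_sigma = FALSE`). The
#' full-scale default (`n_side = 201` over +/-40 deg, 55 sigmas from
#' 0.25 to 35 deg) yields 40401 positions and 2,222,055 candidate time
#' courses; [reduced_grid_spec()] gives a desk-scale 41 x 41 x 10 grid
#' for demos and tests.
#'
#' @param xlim Position range (deg) in both dimensions.
#' @param n_side Lattice points per side.
#' @param sigma_range Range of Gaussian SD candidates (deg).
#' @param n_sigma Number of sigma candidates.
#' @param log_sigma Log-spaced sigmas if `TRUE`.
#' @return An object of class `"prf_grid_spec"`.
#' @export
prf_grid_spec <- function(xlim = c(-40, 40), n_side = 201,
                          sigma_range = c(0.25, 35), n_sigma = 55,
                          log_sigma = TRUE) {
  stopifnot(n_side >= 2, n_sigma >= 1, sigma_range[1] > 0,
            diff(sigma_range) >= 0)
  structure(list(xlim = xlim, n_side = n_side,
                 sigma_range = sigma_range, n_sigma = n_sigma,
                 log_sigma = log_sigma),
            class = "prf_grid_spec")
}

#' Desk-scale search grid
#'
#' @param n_side,n_sigma Reduced lattice sizes (default 41 and 10).
#' @inheritParams prf_grid_spec
#' @return A `prf_grid_spec`.
#' @export
reduced_grid_spec <- function(n_side = 41, n_sigma = 10,
                              xlim = c(-40, 40),
                              sigma_range = c(0.25, 35)) {
  prf_grid_spec(xlim = xlim, n_side = n_side, sigma_range = sigma_range,
                n_sigma = n_sigma)
}

#' Candidate positions of a grid spec
#'
#' @param spec A `prf_grid_spec`.
#' @return Data frame `x0`, `y0` with `n_side^2` rows (x varying
#'   fastest).
#' @export
grid_positions <- function(spec) {
  ax <- seq(spec$xlim[1], spec$xlim[2], length.out = spec$n_side)
  expand.grid(x0 = ax, y0 = ax, KEEP.OUT.ATTRS = FALSE)
}

#' Candidate sigmas of a grid spec
#'
#' @param spec A `prf_grid_spec`.
#' @return Numeric vector of length `n_sigma`.
#' @export
grid_sigmas <- function(spec) {
  r <- spec$sigma_range
  if (spec$n_sigma == 1) return(r[1])
  if (spec$log_sigma) exp(seq(log(r[1]), log(r[2]),
                              length.out = spec$n_sigma))
  else seq(r[1], r[2], length.out = spec$n_sigma)
}

#' Number of candidates of a grid spec
#'
#' @param spec A `prf_grid_spec`.
#' @return `n_side^2 * n_sigma`.
#' @export
n_candidates <- function(spec) as.numeric(spec$n_side)^2 * spec$n_sigma

## 22 x n_TR operator: drop lead-in, demean, average cycles. Equals the
## harmonic filter + collapse for cycle-periodic designs (tested).
.collapse_operator <- function(n_tr, cycle_TRs, leadin_TRs) {
  n <- n_tr - leadin_TRs
  n_cyc <- n / cycle_TRs
  stopifnot(abs(n_cyc - round(n_cyc)) < 1e-9)
  sel <- cbind(matrix(0, n, leadin_TRs), diag(n))
  dm <- diag(n) - matrix(1 / n, n, n)
  avg <- matrix(0, cycle_TRs, n)
  avg[cbind(rep(seq_len(cycle_TRs), round(n_cyc)), seq_len(n))] <- 1 / n_cyc
  avg %*% dm %*% sel
}

#' Build the repertory of theoretical pRF time courses
#'
#' For every candidate (position, sigma), the unit-mass Gaussian is
#' overlapped with each aperture movie, convolved with the HRF, sampled
#' at the TR, passed through the identical harmonic filter + cycle
#' collapse applied to the data, and the four run-type cycles are
#' concatenated into an 88-sample prediction. Candidates are processed
#' in position blocks to bound memory; predictions are stored
#' standardised (zero mean, unit norm) so fitting reduces to a matrix
#' product.
#'
#' @param movies Named list of `aperture_movie`s with elements `cw`,
#'   `ccw`, `exp`, `con` sharing one raster.
#' @param hrf An [hrf_double_gamma()].
#' @param TR Repetition time (s).
#' @param spec A [prf_grid_spec()].
#' @param block_positions Positions per processing block.
#' @return A `prf_grid`: standardised `pred` (88 x N), candidate
#'   `params` (x0, y0, sigma, ecc), `spec` and a design fingerprint.
#' @export
build_grid <- function(movies, hrf = hrf_double_gamma(), TR = 2,
                       spec = reduced_grid_spec(),
                       block_positions = 2000L) {
  need <- c("cw", "ccw", "exp", "con")
  if (!all(need %in% names(movies)))
    stop("movies must contain cw, ccw, exp and con")
  movies <- movies[need]
  geom <- vapply(movies, function(m) c(m$deg_per_px, m$h, m$w),
                 numeric(3))
  if (any(geom != geom[, 1]))
    stop("all movies must share one raster geometry ",
         "(same raster_px and deg_per_px)")
  k <- hrf_kernel(hrf, TR)
  bs <- lapply(movies, function(mv) {
    trm <- bin_movie_to_tr(mv, TR)
    cop <- .collapse_operator(nrow(trm), attr(trm, "cycle_TRs"),
                              attr(trm, "leadin_TRs"))
    hmat <- .conv_matrix(k, nrow(trm))
    (cop %*% hmat) %*% trm            # cycle_TRs x pixels
  })
  b <- do.call(rbind, bs)             # 88 x pixels
  mv1 <- movies[[1]]
  co <- movie_pixel_coords(mv1)
  cell <- mv1$deg_per_px^2
  pos <- grid_positions(spec)
  sig <- grid_sigmas(spec)
  n_pos <- nrow(pos)
  n_samp <- nrow(b)
  pred <- matrix(0, n_samp, n_pos * length(sig))
  blocks <- split(seq_len(n_pos),
                  ceiling(seq_len(n_pos) / block_positions))
  for (blk in blocks) {
    d2 <- outer(co$x, pos$x0[blk], `-`)^2 +
      outer(co$y, pos$y0[blk], `-`)^2
    for (si in seq_along(sig)) {
      s <- sig[si]
      g <- exp(-d2 / (2 * s^2)) * (cell / (2 * pi * s^2))
      cols <- (si - 1L) * n_pos + blk
      pred[, cols] <- b %*% g
    }
  }
  params <- data.frame(
    x0 = rep(pos$x0, times = length(sig)),
    y0 = rep(pos$y0, times = length(sig)),
    sigma = rep(sig, each = n_pos))
  params$ecc <- sqrt(params$x0^2 + params$y0^2)
  mu <- colMeans(pred)
  pred <- sweep(pred, 2, mu, "-")
  nrm <- sqrt(colSums(pred^2))
  valid <- nrm > 1e-12 * max(nrm, 1)
  pred[, valid] <- sweep(pred[, valid, drop = FALSE], 2, nrm[valid], "/")
  pred[, !valid] <- 0
  structure(list(pred = pred, params = params, valid = valid,
                 spec = spec, n_samples = n_samp, TR = TR,
                 fingerprint = grid_fingerprint(movies, hrf, TR, spec)),
            class = "prf_grid")
}

#' Fingerprint of a grid's design inputs
#'
#' Used to detect stale cached grids: the fingerprint covers the
#' aperture designs, HRF, TR and grid spec.
#'
#' @param movies,hrf,TR,spec As in [build_grid()].
#' @return MD5 string.
#' @export
grid_fingerprint <- function(movies, hrf, TR, spec) {
  desc <- c(vapply(movies, function(m)
    paste(deparse(m$design), collapse = ""), character(1)),
    paste(deparse(unclass(hrf)), collapse = ""), format(TR),
    paste(deparse(unclass(spec)), collapse = ""))
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(desc, f)
  unname(tools::md5sum(f))
}

#' @export
print.prf_grid <- function(x, ...) {
  cat(sprintf("<prf_grid> %d candidates (%d positions x %d sigmas), %d-sample predictions\n",
              ncol(x$pred), x$spec$n_side^2, x$spec$n_sigma, x$n_samples))
  invisible(x)
}

## Tie-break: among equal-r candidates prefer smallest sigma, then
## smallest eccentricity, then lowest index.
.better <- function(params, i, j) {
  if (params$sigma[i] != params$sigma[j])
    return(params$sigma[i] < params$sigma[j])
  if (params$ecc[i] != params$ecc[j])
    return(params$ecc[i] < params$ecc[j])
  i < j
}

#' Fit pRFs to many node series by exhaustive grid search
#'
#' Each node's series is standardised and correlated with every stored
#' candidate prediction; the candidate with the highest Pearson r wins,
#' with ties broken by smallest sigma, then smallest eccentricity.
#' Candidates are scanned in blocks (the blocked scan is bit-identical
#' to a single-pass argmax). Constant series give an invalid fit with
#' an `NA` correlation.
#'
#' @param series `node x n_samples` matrix (e.g. 88-sample vectors from
#'   [concat_conditions()]), or a vector for one node.
#' @param grid A `prf_grid`.
#' @param block_candidates Candidates per scan block.
#' @param r_thresh Goodness-of-fit threshold recorded in
#'   `passed_threshold`.
#' @return A `prf_fits` data frame: `node_id`, `x0`, `y0`, `sigma`,
#'   `r`, `ecc`, `valid`, `passed_threshold`.
#' @export
fit_nodes <- function(series, grid, block_candidates = 100000L,
                      r_thresh = 0.5) {
  if (is.null(dim(series))) series <- matrix(series, nrow = 1)
  stopifnot(inherits(grid, "prf_grid"),
            ncol(series) == grid$n_samples)
  n <- nrow(series)
  s <- series - rowMeans(series)
  nrm <- sqrt(rowSums(s^2))
  ok <- nrm > 0
  s[ok, ] <- s[ok, , drop = FALSE] / nrm[ok]
  n_cand <- ncol(grid$pred)
  best_r <- rep(-Inf, n)
  best_i <- rep(NA_integer_, n)
  starts <- seq(1L, n_cand, by = block_candidates)
  for (st in starts) {
    en <- min(st + block_candidates - 1L, n_cand)
    rb <- s %*% grid$pred[, st:en, drop = FALSE]
    inv <- !grid$valid[st:en]
    if (any(inv)) rb[, inv] <- -Inf
    for (i in which(ok)) {
      m <- max(rb[i, ])
      if (m < best_r[i] || m == -Inf) next
      cand <- st - 1L + which(rb[i, ] == m)
      pick <- cand[1]
      for (cc in cand[-1]) if (.better(grid$params, cc, pick)) pick <- cc
      if (m > best_r[i] || is.na(best_i[i]) ||
          .better(grid$params, pick, best_i[i])) {
        best_r[i] <- m
        best_i[i] <- pick
      }
    }
  }
  p <- grid$params
  ids <- rownames(series)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  out <- data.frame(
    node_id = ids,
    x0 = ifelse(ok, p$x0[best_i], NA_real_),
    y0 = ifelse(ok, p$y0[best_i], NA_real_),
    sigma = ifelse(ok, p$sigma[best_i], NA_real_),
    r = ifelse(ok, best_r, NA_real_),
    valid = ok, stringsAsFactors = FALSE)
  out$ecc <- sqrt(out$x0^2 + out$y0^2)
  out$passed_threshold <- !is.na(out$r) & out$r > r_thresh
  class(out) <- c("prf_fits", "data.frame")
  out
}

#' Fit a single node series
#'
#' @param series88 Numeric vector matching the grid's sample count.
#' @inheritParams fit_nodes
#' @return One-row `prf_fits` data frame.
#' @export
fit_node <- function(series88, grid, r_thresh = 0.5) {
  fit_nodes(matrix(series88, nrow = 1), grid, r_thresh = r_thresh)
}

#' Snap ground-truth pRFs to a search lattice
#'
#' Replaces each node's true `(x0, y0, sigma)` by the nearest grid
#' candidate (nearest position coordinate per axis; nearest sigma in
#' log space for log-spaced grids). Used by recovery oracles that
#' validate the fitter at grid resolution: with on-lattice truth and
#' noiseless simulation the grid search must recover every node
#' exactly.
#'
#' @param sheet A `cortical_sheet`.
#' @param spec A `prf_grid_spec`.
#' @return The sheet with snapped `x0`, `y0`, `sigma`.
#' @export
snap_sheet_to_grid <- function(sheet, spec) {
  ax <- seq(spec$xlim[1], spec$xlim[2], length.out = spec$n_side)
  sg <- grid_sigmas(spec)
  snap <- function(v, g, log_space = FALSE) {
    gg <- if (log_space) log(g) else g
    vv <- if (log_space) log(v) else v
    g[vapply(vv, function(x) which.min(abs(gg - x)), integer(1))]
  }
  sheet$x0 <- snap(sheet$x0, ax)
  sheet$y0 <- snap(sheet$y0, ax)
  sheet$sigma <- snap(sheet$sigma, sg, log_space = spec$log_sigma)
  sheet
}

#' t statistic and one-tailed p for a correlation threshold
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with `n - 2` degrees of
#' freedom. At the conventional threshold r = 0.5 with 88 samples this
#' gives t = 5.35 and a one-tailed p below 1e-6.
#'
#' @param r_thresh Correlation threshold (|r| < 1).
#' @param n Number of samples (> 2).
#' @return List with `t`, `df` and `one_tailed_p`.
#' @export
r_threshold_stats <- function(r_thresh = 0.5, n = 88) {
  if (n <= 2) stop("n must exceed 2")
  if (abs(r_thresh) >= 1) stop("|r| must be below 1")
  df <- n - 2
  t <- r_thresh * sqrt(df) / sqrt(1 - r_thresh^2)
  list(t = t, df = df, one_tailed_p = stats::pt(t, df, lower.tail = FALSE))
}

#' Retain pRFs in (or near) the contralateral hemifield
#'
#' A fit is retained iff its centre lies in the hemifield contralateral
#' to `hemisphere`, or within 5 degrees of the vertical meridian in
#' polar angle, or within 2 degrees of the centre of gaze. The
#' near-meridian tolerance is measured as the angular distance of the
#' centre's direction from the vertical meridian.
#'
#' @param fits A `prf_fits` data frame.
#' @param hemisphere `"left"` or `"right"` (cortical hemisphere).
#' @param polar_tol_deg,ecc_tol_deg Tolerances for the near-meridian
#'   and near-fovea rules.
#' @param keep_all If `TRUE`, return all rows with a `retained_contra`
#'   flag; otherwise return the retained subset (flag included).
#' @return A `prf_fits` data frame.
#' @export
contralateral_filter <- function(fits, hemisphere = c("left", "right"),
                                 polar_tol_deg = 5, ecc_tol_deg = 2,
                                 keep_all = FALSE) {
  hemisphere <- match.arg(hemisphere)
  contra_sign <- if (hemisphere == "left") 1 else -1
  theta <- atan2(fits$y0, fits$x0) * 180 / pi
  dvm <- pmin(abs(((theta - 90 + 180) %% 360) - 180),
              abs(((theta + 90 + 180) %% 360) - 180))
  keep <- sign(fits$x0) == contra_sign | dvm < polar_tol_deg |
    fits$ecc < ecc_tol_deg
  keep[is.na(keep)] <- FALSE
  fits$retained_contra <- keep
  if (keep_all) fits else fits[keep, , drop = FALSE]
}

#' Write pRF fits to TSV
#'
#' @param fits A `prf_fits` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fits_tsv <- function(fits, path) {
  utils::write.table(as.data.frame(fits), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pRF fits from TSV
#'
#' @param path Path written by [write_fits_tsv()].
#' @return A `prf_fits` data frame.
#' @export
read_fits_tsv <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  class(out) <- c("prf_fits", "data.frame")
  out
}
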