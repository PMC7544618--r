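#' Node time-course container
#'
#' @param data `node x sample` numeric matrix (percent signal change).
#' @param TR Repetition time (s).
#' @param run_type Run label (`"cw"`, `"ccw"`, `"exp"`, `"con"`,
#'   `"localizer"`, ...).
#' @param cycle_TRs Samples per stimulus cycle.
#' @param leadin_TRs Lead-in samples still present at the start of
#'   `data` (0 once discarded).
#' @param n_runs_averaged Number of runs averaged into `data`.
#' @return An object of class `"node_timecourses"`.
#' @export
node_timecourses <- function(data, TR = 2, run_type = "cw",
                             cycle_TRs = 22, leadin_TRs = 0,
                             n_runs_averaged = 1L) {
  stopifnot(is.matrix(data), all(is.finite(data)))
  structure(list(data = data, TR = TR, run_type = run_type,
                 cycle_TRs = cycle_TRs, leadin_TRs = leadin_TRs,
                 n_runs_averaged = n_runs_averaged),
            class = "node_timecourses")
}

#' @export
print.node_timecourses <- function(x, ...) {
  cat(sprintf("<node_timecourses> %d nodes x %d samples, TR %gs, type %s, %d run(s) averaged\n",
              nrow(x$data), ncol(x$data), x$TR, x$run_type,
              x$n_runs_averaged))
  invisible(x)
}

#' PCA nuisance regressors from high-variance out-of-brain voxels
#'
#' Out-of-brain voxel series (muscles, eyes, ...) capture global
#' artefacts such as postural motion. The `fraction` of out-of-brain
#' voxels with the highest temporal variance are z-scored and submitted
#' to PCA; the first `k` component time courses (orthonormal columns)
#' are returned for nuisance regression.
#'
#' @param volume 4D array (X x Y x Z x T) or a `sim_run`.
#' @param brain_mask 3D logical array (`TRUE` = brain); ignored when a
#'   `sim_run` is given.
#' @param fraction Fraction of out-of-brain voxels retained by
#'   temporal variance.
#' @param k Number of PCA components (default 18).
#' @return `T x k` matrix with orthonormal columns and attribute
#'   `n_source_voxels`.
#' @export
extract_noise_regressors <- function(volume, brain_mask = NULL,
                                     fraction = 0.10, k = 18) {
  if (inherits(volume, "sim_run")) {
    brain_mask <- volume$brain_mask
    volume <- volume$volume
  }
  stopifnot(length(dim(volume)) == 4, !is.null(brain_mask))
  n_t <- dim(volume)[4]
  flat <- matrix(volume, prod(dim(volume)[1:3]), n_t)
  out_idx <- which(!as.vector(brain_mask))
  v <- flat[out_idx, , drop = FALSE]
  vars <- apply(v, 1, stats::var)
  n_keep <- max(1L, ceiling(fraction * nrow(v)))
  keep <- order(vars, decreasing = TRUE)[seq_len(n_keep)]
  if (n_keep < k)
    stop("fewer eligible out-of-brain voxels (", n_keep,
         ") than requested components (", k, ")")
  sel <- v[keep, , drop = FALSE]
  sds <- apply(sel, 1, stats::sd)
  if (any(sds == 0))
    stop("constant out-of-brain voxel series: z-score undefined")
  z <- (sel - rowMeans(sel)) / sds
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  # prcomp on voxels x time: rotation columns are component time courses
  comp <- pc$rotation[, seq_len(k), drop = FALSE]
  comp <- sweep(comp, 2, sqrt(colSums(comp^2)), "/")
  colnames(comp) <- paste0("PC", seq_len(k))
  attr(comp, "n_source_voxels") <- n_keep
  comp
}

#' Regress nuisance components out of time series
#'
#' Least-squares projection of each series onto `[intercept,
#' regressors]`; the residual (uncorrelated with every regressor) is
#' returned. Collinear regressor columns are dropped with a warning.
#'
#' @param series Numeric vector (length T) or `node x T` matrix.
#' @param regressors `T x k` matrix.
#' @return Residual series, same shape as `series`.
#' @export
regress_out <- function(series, regressors) {
  vec <- is.null(dim(series))
  m <- if (vec) matrix(series, nrow = 1) else series
  stopifnot(ncol(m) == nrow(regressors))
  x <- cbind(1, regressors)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    warning("rank-deficient nuisance design: dropping ",
            ncol(x) - qx$rank, " collinear column(s)")
    x <- x[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(x)
  }
  res <- t(qr.resid(qx, t(m)))
  if (vec) drop(res) else res
}

## Trilinear interpolation of a 4D volume at one mm-space point
## (1 mm isotropic voxels, centres at integer coordinates).
.trilinear_series <- function(flat, dims, pt) {
  f <- floor(pt)
  w <- pt - f
  ser <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wx <- if (dx) w[1] else 1 - w[1]
    wy <- if (dy) w[2] else 1 - w[2]
    wz <- if (dz) w[3] else 1 - w[3]
    wt <- wx * wy * wz
    if (wt == 0) next
    i <- f + c(dx, dy, dz)
    lin <- (i[3] - 1) * dims[1] * dims[2] + (i[2] - 1) * dims[1] + i[1]
    ser <- ser + wt * flat[lin, ]
  }
  ser
}

#' Project a 4D volume onto cortical-sheet nodes
#'
#' For each node, 7 sampling points are placed along the surface normal
#' from -0.75 to +0.75 mm (accounting for cortical thickness); series
#' are extracted by trilinear interpolation, converted individually to
#' percent signal change, and averaged into a single node series.
#' Nodes whose sampling points leave the volume are excluded with a
#' warning.
#'
#' @param volume 4D array or `sim_run`.
#' @param sheet A `cortical_sheet`.
#' @param offsets_mm Sampling offsets along the normal (mm).
#' @param TR,run_type,cycle_TRs,leadin_TRs Metadata passed to
#'   [node_timecourses()].
#' @return A `node_timecourses` object (percent signal change).
#' @export
sample_to_nodes <- function(volume, sheet,
                            offsets_mm = seq(-0.75, 0.75, length.out = 7),
                            TR = 2, run_type = "cw", cycle_TRs = 22,
                            leadin_TRs = 0) {
  if (inherits(volume, "sim_run")) {
    TR <- volume$TR
    volume <- volume$volume
  }
  dims <- dim(volume)
  stopifnot(length(dims) == 4)
  n_t <- dims[4]
  flat <- matrix(volume, prod(dims[1:3]), n_t)
  n <- nrow(sheet)
  out <- matrix(NA_real_, n, n_t)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    acc <- 0
    for (o in offsets_mm) {
      pt <- c(sheet$vol_x[i] + o * sheet$nx[i],
              sheet$vol_y[i] + o * sheet$ny[i],
              sheet$vol_z[i] + o * sheet$nz[i])
      if (any(pt < 1) || any(pt > dims[1:3] - 1e-9)) { ok[i] <- FALSE; break }
      ser <- .trilinear_series(flat, dims, pt)
      mu <- mean(ser)
      if (mu <= 0) stop("non-positive mean series: PSC undefined")
      acc <- acc + (ser / mu - 1) * 100
    }
    if (ok[i]) out[i, ] <- acc / length(offsets_mm)
  }
  if (!all(ok)) {
    warning(sum(!ok), " node(s) outside the volume excluded")
    out <- out[ok, , drop = FALSE]
  }
  rownames(out) <- sheet$node_id[ok]
  node_timecourses(out, TR = TR, run_type = run_type,
                   cycle_TRs = cycle_TRs, leadin_TRs = leadin_TRs)
}

#' Average runs of the same type
#'
#' @param runs List of `node_timecourses` with identical type, node set
#'   and length.
#' @return A `node_timecourses` with the element-wise mean and
#'   `n_runs_averaged` updated.
#' @export
average_runs <- function(runs) {
  if (length(runs) == 0) stop("no runs to average")
  stopifnot(all(vapply(runs, inherits, logical(1), "node_timecourses")))
  types <- vapply(runs, function(r) r$run_type, character(1))
  if (length(unique(types)) != 1)
    stop("cannot average runs of mixed types: ",
         paste(unique(types), collapse = ", "))
  dims <- vapply(runs, function(r) dim(r$data), integer(2))
  if (any(dims != dims[, 1])) stop("runs differ in dimensions")
  acc <- Reduce(`+`, lapply(runs, function(r) r$data)) / length(runs)
  r1 <- runs[[1]]
  node_timecourses(acc, TR = r1$TR, run_type = r1$run_type,
                   cycle_TRs = r1$cycle_TRs, leadin_TRs = r1$leadin_TRs,
                   n_runs_averaged = sum(vapply(runs, function(r)
                     r$n_runs_averaged, numeric(1))))
}

#' Harmonic frequency-domain filter and cycle collapse
#'
#' After discarding the lead-in, the series (an integer number of
#' stimulus cycles) is Fourier transformed; only the bins at the
#' fundamental cycle frequency and its harmonics are retained (DC
#' excluded, harmonics up to Nyquist), the series is inverse
#' transformed, and the cycles are averaged into one `cycle_TRs`-sample
#' cycle. Because the harmonic bins carry exactly the cycle-periodic
#' content, this equals direct cycle averaging of the demeaned series;
#' the explicit frequency-domain route is kept as the reference
#' implementation and the identity is asserted in the test suite.
#'
#' @param ntc A `node_timecourses` (or plain `node x T` matrix).
#' @param cycle_TRs Samples per cycle (default from the object, else
#'   22).
#' @param leadin_TRs Lead-in samples to discard (default from the
#'   object, else 0).
#' @return `node x cycle_TRs` matrix of cycle-averaged responses.
#' @export
harmonic_filter_and_collapse <- function(ntc, cycle_TRs = NULL,
                                         leadin_TRs = NULL) {
  if (inherits(ntc, "node_timecourses")) {
    if (is.null(cycle_TRs)) cycle_TRs <- ntc$cycle_TRs
    if (is.null(leadin_TRs)) leadin_TRs <- ntc$leadin_TRs
    x <- ntc$data
  } else {
    x <- ntc
    if (is.null(cycle_TRs)) cycle_TRs <- 22L
    if (is.null(leadin_TRs)) leadin_TRs <- 0L
  }
  if (leadin_TRs > 0) x <- x[, -seq_len(leadin_TRs), drop = FALSE]
  n <- ncol(x)
  n_cyc <- n / cycle_TRs
  if (abs(n_cyc - round(n_cyc)) > 1e-9)
    stop("series length (", n, ") is not an integer number of cycles")
  n_cyc <- as.integer(round(n_cyc))
  xf <- stats::mvfft(t(x))                     # T x nodes
  bins0 <- seq_len(n) - 1L                     # 0-based frequencies
  keep <- bins0 %% n_cyc == 0 & bins0 != 0     # harmonics of f0, no DC
  xf[!keep, ] <- 0
  filt <- Re(stats::mvfft(xf, inverse = TRUE)) / n   # T x nodes
  grp <- rep(seq_len(cycle_TRs), times = n_cyc)
  collapsed <- rowsum(filt, grp) / n_cyc       # cycle_TRs x nodes
  out <- t(collapsed)
  rownames(out) <- rownames(x)
  out
}

#' Concatenate the four run-type cycle averages
#'
#' Fixed order clockwise wedge, counterclockwise wedge, expanding ring,
#' contracting ring; with 22-sample cycles this yields the 88-sample
#' vectors used for pRF fitting.
#'
#' @param cw,ccw,exp,con `node x cycle_TRs` matrices with matching
#'   rows.
#' @return `node x (4 * cycle_TRs)` matrix.
#' @export
concat_conditions <- function(cw, ccw, exp, con) {
  parts <- list(cw = cw, ccw = ccw, exp = exp, con = con)
  if (any(vapply(parts, is.null, logical(1))))
    stop("all four conditions (cw, ccw, exp, con) are required")
  dims <- vapply(parts, dim, integer(2))
  if (any(dims != dims[, 1])) stop("conditions differ in dimensions")
  do.call(cbind, parts)
}

#' Gaussian spatial smoothing of a volume
#'
#' Separable Gaussian kernel applied along x, y and z (and to each
#' frame of a 4D volume). The kernel is normalised so the image sum is
#' conserved away from the borders. `fwhm_mm = 0` is the identity.
#'
#' @param volume 3D or 4D numeric array (isotropic voxels).
#' @param fwhm_mm Full width at half maximum of the kernel (mm).
#' @param voxel_mm Voxel size (mm).
#' @return Smoothed array of the same shape.
#' @export
smooth_volume <- function(volume, fwhm_mm = 2, voxel_mm = 1) {
  if (fwhm_mm < 0) stop("FWHM must be non-negative")
  if (fwhm_mm == 0) return(volume)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  rad <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-rad, rad), sd = sigma)
  k <- k / sum(k)
  smooth1 <- function(v) {                 # along first margin of a matrix
    n <- nrow(v)
    out <- matrix(0, n, ncol(v))
    for (j in seq_along(k)) {
      off <- j - rad - 1L
      src <- pmin(pmax(seq_len(n) + off, 1L), n)   # replicate borders
      out <- out + k[j] * v[src, , drop = FALSE]
    }
    out
  }
  d <- dim(volume)
  if (length(d) == 4) {
    for (t in seq_len(d[4]))
      volume[, , , t] <- smooth_volume(volume[, , , t], fwhm_mm, voxel_mm)
    return(volume)
  }
  stopifnot(length(d) == 3)
  x <- matrix(volume, d[1], d[2] * d[3])
  x <- smooth1(x)
  x <- array(x, d)
  x <- aperm(x, c(2, 1, 3))
  x <- array(smooth1(matrix(x, d[2], d[1] * d[3])), c(d[2], d[1], d[3]))
  x <- aperm(x, c(2, 1, 3))
  x <- aperm(x, c(3, 2, 1))
  x <- array(smooth1(matrix(x, d[3], d[2] * d[1])), c(d[3], d[2], d[1]))
  aperm(x, c(3, 2, 1))
}

#' Write node time courses to TSV
#'
#' Header comment lines carry the sampling metadata; rows are nodes.
#'
#' @param ntc A `node_timecourses`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ntc_tsv <- function(ntc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# TR_s=%g run_type=%s cycle_TRs=%d leadin_TRs=%d n_runs_averaged=%d",
                     ntc$TR, ntc$run_type, ntc$cycle_TRs, ntc$leadin_TRs,
                     ntc$n_runs_averaged), con)
  ids <- rownames(ntc$data)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(ntc$data)))
  df <- data.frame(node_id = ids, ntc$data, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read node time courses from TSV
#'
#' @param path Path written by [write_ntc_tsv()].
#' @return A `node_timecourses`.
#' @export
read_ntc_tsv <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- strsplit(sub("^# ", "", hdr), " ")[[1]]
  meta <- stats::setNames(
    lapply(strsplit(kv, "="), `[`, 2),
    vapply(strsplit(kv, "="), `[`, character(1), 1))
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$node_id
  node_timecourses(m, TR = as.numeric(meta$TR_s),
                   run_type = meta$run_type,
                   cycle_TRs = as.integer(meta$cycle_TRs),
                   leadin_TRs = as.integer(meta$leadin_TRs),
                   n_runs_averaged = as.integer(meta$n_runs_averaged))
}
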