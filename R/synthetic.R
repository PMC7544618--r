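#' Cloverleaf cluster layout
#'
#' Parameterises a synthetic visuotopic cluster: a disc of cortex whose
#' sectors each hold a mirror-symmetric map of the contralateral visual
#' field, all sharing a foveal confluence at the disc centre.
#' Eccentricity grows linearly with distance from the centre
#' (`ecc_gradient_deg_mm`), and the polar-angle gradient flips sign at
#' every sector border, as in the cloverleaf clusters described for
#' extrastriate and parietal cortex. Sector "styles" control the pRF
#' size law: `"sloped"` sectors have sigma increasing linearly with
#' eccentricity (CIP-like), `"flat"` sectors have a constant sigma
#' (PIP-like).
#'
#' @param n_sectors Number of sectors (>= 1; mirror symmetry requires an
#'   even count for a seamless circular map).
#' @param radius_mm Cluster radius on the flattened sheet (mm).
#' @param ecc_gradient_deg_mm Eccentricity gradient (deg of visual angle
#'   per mm of cortex); must be positive.
#' @param polar_range Polar-angle range (deg) covered by each sector;
#'   `c(-90, 90)` gives hemifield maps, `c(0, 90)` upper-quadrant maps.
#' @param sector_style Character vector (recycled) of `"sloped"` /
#'   `"flat"` pRF-size laws per sector.
#' @param sigma_intercept,sigma_slope Sigma law for sloped sectors:
#'   `sigma = intercept + slope * ecc` (deg).
#' @param sigma_flat Constant sigma (deg) for flat sectors.
#' @param hemisphere Cortical hemisphere the sheet belongs to; pRF
#'   centres are placed in the contralateral visual hemifield.
#' @param start_deg Cortical angle (deg) of the first sector border.
#' @return An object of class `"cluster_layout"`.
#' @export
cluster_layout <- function(n_sectors = 4, radius_mm = 10,
                           ecc_gradient_deg_mm = 4,
                           polar_range = c(-90, 90),
                           sector_style = c("sloped", "sloped",
                                            "flat", "flat"),
                           sigma_intercept = 2, sigma_slope = 0.25,
                           sigma_flat = 8,
                           hemisphere = c("left", "right"),
                           start_deg = 0) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(n_sectors >= 1, radius_mm > 0, length(polar_range) == 2)
  if (ecc_gradient_deg_mm <= 0)
    stop("degenerate layout: eccentricity gradient must be positive")
  if (diff(polar_range) == 0)
    stop("degenerate layout: polar-angle range must be non-zero")
  style <- rep_len(sector_style, n_sectors)
  # mirror alternation: odd sectors run polar_range forward, even ones
  # reversed, so the gradient flips sign at every border
  maps <- lapply(seq_len(n_sectors), function(k)
    if (k %% 2 == 1) polar_range else rev(polar_range))
  structure(list(n_sectors = n_sectors, radius_mm = radius_mm,
                 ecc_gradient_deg_mm = ecc_gradient_deg_mm,
                 polar_maps = maps, sector_style = style,
                 sigma_intercept = sigma_intercept,
                 sigma_slope = sigma_slope, sigma_flat = sigma_flat,
                 hemisphere = hemisphere, start_deg = start_deg),
            class = "cluster_layout")
}

#' Number of polar-angle gradient reversals a layout prescribes
#'
#' Counts sign changes of the per-sector polar-angle gradient around the
#' full circle (including the wrap from last to first sector).
#'
#' @param layout A [cluster_layout()].
#' @return Integer reversal count.
#' @export
designed_reversals <- function(layout) {
  g <- vapply(layout$polar_maps, function(m) sign(diff(m)), numeric(1))
  if (length(g) == 1) return(0L)
  sum(g != c(g[-1], g[1]))
}

#' Generate a ground-truth cortical sheet from a cluster layout
#'
#' Scatters `n_nodes` uniformly over the layout disc and assigns each
#' node a ground-truth pRF from its sector's mirror map: polar angle
#' linear in the within-sector cortical angle, eccentricity linear in
#' the distance from the foveal confluence, and sigma from the sector's
#' size law. Volume coordinates place the sheet on a flat plane (unit
#' normals along +z) for the volume-embedding stage.
#'
#' @param layout A [cluster_layout()].
#' @param n_nodes Number of surface nodes.
#' @param seed RNG seed for node placement.
#' @return A `cortical_sheet` data frame with columns `node_id`,
#'   `flat_x`/`flat_y` (mm), `vol_x`/`vol_y`/`vol_z` (mm),
#'   `nx`/`ny`/`nz`, ground-truth `x0`/`y0`/`sigma` (deg) and the
#'   sector label `area`.
#' @export
make_cluster_sheet <- function(layout, n_nodes = 200, seed = 1L) {
  stopifnot(inherits(layout, "cluster_layout"), n_nodes >= 1)
  r_mm <- with_seed(seed, {
    r <- layout$radius_mm * sqrt(stats::runif(n_nodes))
    phi <- stats::runif(n_nodes, 0, 360)
    list(r = r, phi = phi)
  })
  r <- r_mm$r; phi <- r_mm$phi
  width <- 360 / layout$n_sectors
  rel <- (phi - layout$start_deg) %% 360
  sector <- pmin(floor(rel / width) + 1L, layout$n_sectors)
  u <- rel / width - (sector - 1L)
  pa <- vapply(seq_along(sector), function(i) {
    m <- layout$polar_maps[[sector[i]]]
    m[1] + u[i] * (m[2] - m[1])
  }, numeric(1))
  ecc <- layout$ecc_gradient_deg_mm * r
  sigma <- ifelse(layout$sector_style[sector] == "flat",
                  layout$sigma_flat,
                  layout$sigma_intercept + layout$sigma_slope * ecc)
  side <- if (layout$hemisphere == "left") 1 else -1
  flat_x <- r * cospi(phi / 180)
  flat_y <- r * sinpi(phi / 180)
  pad <- 4
  out <- data.frame(
    node_id = seq_len(n_nodes),
    flat_x = flat_x, flat_y = flat_y,
    vol_x = flat_x + layout$radius_mm + pad,
    vol_y = flat_y + layout$radius_mm + pad,
    vol_z = rep(5, n_nodes),
    nx = 0, ny = 0, nz = 1,
    x0 = side * ecc * cospi(pa / 180),
    y0 = ecc * sinpi(pa / 180),
    sigma = sigma,
    area = paste0("S", sector, "_", layout$sector_style[sector]),
    stringsAsFactors = FALSE)
  class(out) <- c("cortical_sheet", "data.frame")
  attr(out, "layout") <- layout
  out
}

#' Noise specification for simulated BOLD
#'
#' @param white_sd SD of additive white Gaussian noise (same units as
#'   the signal, i.e. percent signal change).
#' @param drift_sd SD of the random coefficients of a low-order cosine
#'   drift (orders `1..drift_orders` over the run).
#' @param drift_orders Number of cosine drift terms.
#' @param nuisance_sd SD of the per-node weights applied to shared
#'   nuisance time courses.
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(white_sd = 0, drift_sd = 0, drift_orders = 3,
                       nuisance_sd = 0) {
  stopifnot(white_sd >= 0, drift_sd >= 0, drift_orders >= 0,
            nuisance_sd >= 0)
  structure(list(white_sd = white_sd, drift_sd = drift_sd,
                 drift_orders = drift_orders, nuisance_sd = nuisance_sd),
            class = "noise_spec")
}

#' Shared nuisance time courses
#'
#' Smooth random series (sums of low-order cosines with random
#' coefficients, normalised to unit SD) shared between brain and
#' out-of-brain voxels, emulating global artefacts such as postural
#' motion.
#'
#' @param n_samples Series length (TRs).
#' @param k Number of components.
#' @param seed RNG seed.
#' @param orders Highest cosine order used.
#' @return `n_samples x k` matrix.
#' @export
make_nuisance_courses <- function(n_samples, k = 6, seed = 1L, orders = 10) {
  with_seed(seed, {
    tt <- (seq_len(n_samples) - 0.5) / n_samples
    basis <- sapply(seq_len(orders), function(j) cospi(j * tt))
    m <- basis %*% matrix(stats::rnorm(orders * k), orders, k)
    scale(m, center = TRUE, scale = apply(m, 2, stats::sd))[, , drop = FALSE]
  })
}

## Cosine drift with random coefficients (seeded by the caller's RNG).
.drift <- function(n, sd, orders) {
  if (sd == 0 || orders == 0) return(numeric(n))
  tt <- (seq_len(n) - 0.5) / n
  basis <- sapply(seq_len(orders), function(j) cospi(j * tt))
  drop(basis %*% stats::rnorm(orders, sd = sd))
}

#' Bin an aperture movie to the TR grid
#'
#' Averages the binary frames within each TR, giving the fractional
#' aperture occupancy per pixel per TR. Overlap with a pRF is linear in
#' the frames, so computing overlaps on the TR-binned movie equals
#' TR-averaging the per-frame overlaps.
#'
#' @param movie An `aperture_movie`.
#' @param TR Repetition time (s); `frame_rate_hz * TR` must be integer.
#' @return `n_TR x n_pixels` numeric matrix with attributes
#'   `leadin_TRs`, `cycle_TRs` and `n_full_cycles`.
#' @export
bin_movie_to_tr <- function(movie, TR = 2) {
  fpt <- movie$frame_rate_hz * TR
  if (abs(fpt - round(fpt)) > 1e-9)
    stop("TR must hold an integer number of frames")
  fpt <- as.integer(round(fpt))
  n_frames <- nrow(movie$frames)
  n_tr <- n_frames %/% fpt
  if (n_tr * fpt != n_frames)
    stop("movie duration must be an integer number of TRs")
  grp <- rep(seq_len(n_tr), each = fpt)
  m <- rowsum(movie$frames + 0, grp) / fpt
  attr(m, "leadin_TRs") <- as.integer(round(movie$leadin_s / TR))
  attr(m, "cycle_TRs") <- as.integer(round(movie$cycle_s / TR))
  attr(m, "n_full_cycles") <- movie$n_full_cycles
  m
}

#' Unit-mass Gaussian pRF image on a movie raster
#'
#' @param x0,y0,sigma pRF centre and SD in degrees (`sigma > 0`).
#' @param movie An `aperture_movie` (supplies pixel coordinates).
#' @return Numeric vector of pixel weights summing to ~1 (unit mass,
#'   truncated at the raster).
#' @export
gaussian_prf_image <- function(x0, y0, sigma, movie) {
  stopifnot(sigma > 0)
  co <- movie_pixel_coords(movie)
  cell <- movie$deg_per_px^2
  exp(-((co$x - x0)^2 + (co$y - y0)^2) / (2 * sigma^2)) *
    cell / (2 * pi * sigma^2)
}

#' Simulate BOLD time courses for a sheet of pRFs
#'
#' Neural drive = per-frame overlap of each node's unit-mass Gaussian
#' with the aperture (computed on the TR-binned movie), convolved with
#' the HRF sampled at the TR and scaled by `amp` (percent signal change
#' per unit overlap). Noise (white + cosine drift + weighted shared
#' nuisance components) is added per node.
#'
#' @param sheet A `cortical_sheet` with ground-truth pRFs.
#' @param movie An `aperture_movie` (or a pre-binned matrix from
#'   [bin_movie_to_tr()] passed via `tr_frames`).
#' @param hrf An [hrf_double_gamma()] object.
#' @param TR Repetition time (s).
#' @param amp Response amplitude (PSC per unit Gaussian-aperture
#'   overlap).
#' @param noise A [noise_spec()].
#' @param nuisance Optional `n_TR x k` matrix of shared nuisance
#'   courses.
#' @param seed RNG seed for the noise draw.
#' @param tr_frames Optional precomputed [bin_movie_to_tr()] output.
#' @return `node x n_TR` matrix with attribute `clean` holding the
#'   noise-free signal, plus `TR`, `leadin_TRs`, `cycle_TRs`.
#' @export
simulate_sheet_bold <- function(sheet, movie, hrf = hrf_double_gamma(),
                                TR = 2, amp = 1, noise = noise_spec(),
                                nuisance = NULL, seed = NULL,
                                tr_frames = NULL) {
  stopifnot(all(sheet$sigma > 0))
  if (is.null(tr_frames)) tr_frames <- bin_movie_to_tr(movie, TR)
  if (all(tr_frames == 0)) stop("aperture movie is empty")
  co <- movie_pixel_coords(movie)
  cell <- movie$deg_per_px^2
  g <- sapply(seq_len(nrow(sheet)), function(i) {
    s <- sheet$sigma[i]
    exp(-((co$x - sheet$x0[i])^2 + (co$y - sheet$y0[i])^2) / (2 * s^2)) *
      cell / (2 * pi * s^2)
  })
  drive <- tr_frames %*% g                       # n_TR x nodes
  k <- hrf_kernel(hrf, TR)
  clean <- amp * apply(drive, 2, convolve_causal, kernel = k)
  n_tr <- nrow(clean)
  noisy <- with_seed(seed, {
    out <- clean
    for (i in seq_len(ncol(out))) {
      e <- stats::rnorm(n_tr, sd = noise$white_sd) +
        .drift(n_tr, noise$drift_sd, noise$drift_orders)
      if (!is.null(nuisance) && noise$nuisance_sd > 0)
        e <- e + drop(nuisance %*%
                        stats::rnorm(ncol(nuisance), sd = noise$nuisance_sd))
      out[, i] <- out[, i] + e
    }
    out
  })
  res <- t(noisy)
  rownames(res) <- sheet$node_id
  cl <- t(clean)
  rownames(cl) <- sheet$node_id
  attr(res, "clean") <- cl
  attr(res, "TR") <- TR
  attr(res, "leadin_TRs") <- attr(tr_frames, "leadin_TRs")
  attr(res, "cycle_TRs") <- attr(tr_frames, "cycle_TRs")
  res
}

#' Simulate the BOLD response of a single pRF
#'
#' Single-node convenience wrapper around [simulate_sheet_bold()].
#'
#' @param prf Numeric `(x0, y0, sigma)` in degrees.
#' @inheritParams simulate_sheet_bold
#' @return Numeric time course (one value per TR) with a `clean`
#'   attribute.
#' @export
simulate_node_bold <- function(prf, movie, hrf = hrf_double_gamma(),
                               TR = 2, amp = 1, noise = noise_spec(),
                               nuisance = NULL, seed = NULL,
                               tr_frames = NULL) {
  stopifnot(length(prf) == 3)
  if (prf[3] <= 0) stop("sigma must be positive")
  sheet <- data.frame(node_id = 1L, x0 = prf[1], y0 = prf[2],
                      sigma = prf[3])
  m <- simulate_sheet_bold(sheet, movie, hrf, TR, amp, noise, nuisance,
                           seed, tr_frames)
  out <- drop(m[1, ])
  attr(out, "clean") <- drop(attr(m, "clean")[1, ])
  attr(out, "TR") <- attr(m, "TR")
  out
}

#' Embed node time courses into a simulated 4D volume
#'
#' Deposits each node's percent-signal-change series into the voxels
#' nearest its 7 sampling points along the surface normal (within
#' +/- 0.75 mm), on top of a constant baseline. Out-of-brain voxels
#' carry high-variance shared nuisance components plus white noise;
#' brain voxels carry the signal, a weaker leak of the same nuisance
#' components, and white noise. Nodes that collide in a voxel are
#' summed with a warning.
#'
#' @param sheet A `cortical_sheet` (volume coordinates in mm; 1 mm
#'   isotropic voxels with centres at integer coordinates).
#' @param psc `node x T` matrix of percent-signal-change series.
#' @param TR Repetition time (s).
#' @param baseline Raw baseline intensity of brain voxels.
#' @param nuisance Optional `T x k` matrix of shared nuisance courses
#'   (`NULL` for none).
#' @param nuisance_sd_out,nuisance_sd_brain SD of the random nuisance
#'   weights for out-of-brain and brain voxels.
#' @param white_sd SD of white voxel noise (raw units).
#' @param pad Padding (voxels) around the sheet bounding box.
#' @param seed RNG seed for voxel noise.
#' @return A `sim_run` list: `volume` (X x Y x Z x T array),
#'   `brain_mask` (3D logical), `TR`, `nuisance`, `voxel_mm`, and the
#'   node-to-voxel `deposit` table.
#' @export
embed_runs_in_volume <- function(sheet, psc, TR = 2, baseline = 100,
                                 nuisance = NULL, nuisance_sd_out = 5,
                                 nuisance_sd_brain = 0.5, white_sd = 0.2,
                                 pad = 3, seed = 1L) {
  stopifnot(nrow(psc) == nrow(sheet))
  n_t <- ncol(psc)
  offs <- seq(-0.75, 0.75, length.out = 7)
  pts <- do.call(rbind, lapply(offs, function(o)
    cbind(sheet$vol_x + o * sheet$nx, sheet$vol_y + o * sheet$ny,
          sheet$vol_z + o * sheet$nz)))
  dims <- ceiling(apply(pts, 2, max)) + pad
  if (any(pts < 1 + 1e-9) )
    stop("sheet volume coordinates must lie inside the volume (>= 1 mm)")
  dims <- pmax(dims, 4)
  vox <- round(pts)
  node_of <- rep(seq_len(nrow(sheet)), times = 7)
  key <- paste(vox[, 1], vox[, 2], vox[, 3], sep = ",")
  dep <- data.frame(node = node_of, x = vox[, 1], y = vox[, 2],
                    z = vox[, 3], key = key, stringsAsFactors = FALSE)
  dep <- unique(dep)
  if (anyDuplicated(dep$key))
    warning("nodes overlap in ", sum(duplicated(dep$key)),
            " voxel(s); signals summed")
  brain_mask <- array(FALSE, dims)
  brain_mask[as.matrix(dep[, c("x", "y", "z")])] <- TRUE
  n_vox <- prod(dims)
  vol <- with_seed(seed, {
    v <- array(stats::rnorm(n_vox * n_t, mean = baseline, sd = white_sd),
               c(dims, n_t))
    flat <- matrix(v, n_vox, n_t)
    if (!is.null(nuisance)) {
      stopifnot(nrow(nuisance) == n_t)
      k <- ncol(nuisance)
      w <- matrix(stats::rnorm(n_vox * k), n_vox, k)
      sd_vox <- ifelse(as.vector(brain_mask), nuisance_sd_brain,
                       nuisance_sd_out)
      flat <- flat + (w * sd_vox) %*% t(nuisance)
    }
    array(flat, c(dims, n_t))
  })
  # deposit signal: brain voxel value = baseline * (1 + psc/100)
  sig <- matrix(0, n_vox, n_t)
  lin <- (dep$z - 1) * dims[1] * dims[2] + (dep$y - 1) * dims[1] + dep$x
  for (i in seq_len(nrow(dep)))
    sig[lin[i], ] <- sig[lin[i], ] + psc[dep$node[i], ]
  flat <- matrix(vol, n_vox, n_t)
  flat <- flat + baseline * sig / 100
  structure(list(volume = array(flat, c(dims, n_t)),
                 brain_mask = brain_mask, TR = TR, baseline = baseline,
                 nuisance = nuisance, voxel_mm = 1,
                 deposit = dep[, c("node", "x", "y", "z")]),
            class = "sim_run")
}

#' Write a 4D volume (or 3D mask) to NIfTI
#'
#' @param x Numeric/logical array (3D or 4D) or a `sim_run` (its
#'   `volume` is written).
#' @param path Output file path (`.nii` / `.nii.gz`).
#' @param voxel_mm Isotropic voxel size (mm).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(x, path, voxel_mm = 1) {
  if (inherits(x, "sim_run")) x <- x$volume
  img <- RNifti::asNifti(x + 0)
  RNifti::pixdim(img) <- rep(voxel_mm, min(3, length(dim(x))))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file path.
#' @return Numeric array.
#' @export
read_volume_nifti <- function(path) {
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim = dim(arr))
}

#' Write a cortical sheet to TSV
#'
#' @param sheet A `cortical_sheet`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sheet_tsv <- function(sheet, path) {
  utils::write.table(as.data.frame(sheet), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cortical sheet from TSV
#'
#' @param path TSV path written by [write_sheet_tsv()].
#' @return A `cortical_sheet` data frame.
#' @export
read_sheet_tsv <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  class(out) <- c("cortical_sheet", "data.frame")
  out
}
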