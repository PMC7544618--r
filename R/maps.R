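#' Convert pRF fits to a retinotopic map
#'
#' Polar angle uses the hemifield convention: 0 at the horizontal
#' meridian, +90 at the upper vertical meridian, -90 at the lower
#' vertical meridian, with the hemifield recorded separately as the
#' sign of `x0`. The conversion round-trips exactly:
#' `x0 = hemifield * ecc * cos(angle)`, `y0 = ecc * sin(angle)`.
#'
#' @param fits A `prf_fits` data frame (typically thresholded).
#' @return A `retinotopic_map` data frame: `node_id`,
#'   `polar_angle_deg`, `hemifield`, `eccentricity_deg`, `size_deg`,
#'   `r`, `mask`.
#' @export
to_map <- function(fits) {
  pa <- atan2(fits$y0, abs(fits$x0)) * 180 / pi
  out <- data.frame(
    node_id = fits$node_id,
    polar_angle_deg = pa,
    hemifield = sign(fits$x0),
    eccentricity_deg = sqrt(fits$x0^2 + fits$y0^2),
    size_deg = fits$sigma,
    r = fits$r,
    mask = if (!is.null(fits$passed_threshold)) fits$passed_threshold
           else rep(TRUE, nrow(fits)),
    stringsAsFactors = FALSE)
  class(out) <- c("retinotopic_map", "data.frame")
  out
}

#' Recover pRF centres from a retinotopic map
#'
#' Inverse of [to_map()].
#'
#' @param map A `retinotopic_map`.
#' @return Data frame with `x0`, `y0`.
#' @export
map_to_centers <- function(map) {
  data.frame(
    x0 = map$hemifield * map$eccentricity_deg *
      cospi(map$polar_angle_deg / 180),
    y0 = map$eccentricity_deg * sinpi(map$polar_angle_deg / 180))
}

## match map values to sheet rows by node_id
.values_for_sheet <- function(sheet, map, column) {
  idx <- match(as.character(sheet$node_id), as.character(map$node_id))
  map[[column]][idx]
}

#' Profile of map values along a path on the cortical sheet
#'
#' For each segment of the polyline, the nodes within `halfwidth_mm`
#' of the segment are averaged; segments are ordered along the path.
#' With `halfwidth_mm = 0` the single nearest node per segment is
#' used. Geometry (the sheet and path) and values (the map) are
#' independent arguments so coordinates can be drawn on one data half
#' and values read from the other.
#'
#' @param sheet A `cortical_sheet` (flat coordinates, mm).
#' @param map A `retinotopic_map` providing values by `node_id`.
#' @param path `k x 2` matrix of polyline vertices (mm), `k >= 2`.
#' @param halfwidth_mm Capture half-width around each segment.
#' @param value Map column to profile.
#' @return A `profile` data frame: `position`, `value`, `n`, `empty`.
#' @export
path_profile <- function(sheet, map, path, halfwidth_mm = 1,
                         value = "polar_angle_deg") {
  path <- as.matrix(path)
  stopifnot(ncol(path) == 2, nrow(path) >= 2)
  vals <- .values_for_sheet(sheet, map, value)
  px <- sheet$flat_x; py <- sheet$flat_y
  n_seg <- nrow(path) - 1L
  out <- data.frame(position = seq_len(n_seg), value = NA_real_,
                    n = 0L, empty = TRUE)
  for (s in seq_len(n_seg)) {
    a <- path[s, ]; b <- path[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) rep(0, length(px))
         else pmin(1, pmax(0, ((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / len2))
    d <- sqrt((px - (a[1] + t * ab[1]))^2 + (py - (a[2] + t * ab[2]))^2)
    sel <- if (halfwidth_mm > 0) which(d <= halfwidth_mm & !is.na(vals))
           else {
             cand <- which(!is.na(vals))
             cand[which.min(d[cand])]
           }
    if (length(sel) > 0) {
      out$value[s] <- mean(vals[sel])
      out$n[s] <- length(sel)
      out$empty[s] <- FALSE
    }
  }
  class(out) <- c("profile", "data.frame")
  out
}

#' Circular spoke profile around a cluster centre
#'
#' Subdivides the disc of radius `radius_mm` around `center` into
#' `n_sectors` equal angular sectors and averages the map values of the
#' nodes falling in each sector, ordered by sector angle. Used with
#' polar-angle values, the mirror maps of a cloverleaf cluster appear
#' as gradient reversals along the profile.
#'
#' @param sheet A `cortical_sheet`.
#' @param map A `retinotopic_map`.
#' @param center Length-2 centre on the flat sheet (mm).
#' @param radius_mm Disc radius (mm).
#' @param n_sectors Number of sectors (default 24).
#' @param start_deg Angle of the first sector border; `clockwise`
#'   reverses the ordering. Defaults traverse counterclockwise from the
#'   +x axis.
#' @param clockwise Traverse clockwise if `TRUE`.
#' @param value Map column to average.
#' @return A `profile` data frame: `position`, `angle_deg` (sector
#'   centre), `value`, `n`, `empty`.
#' @export
spoke_profile <- function(sheet, map, center = c(0, 0), radius_mm = 10,
                          n_sectors = 24, start_deg = 0,
                          clockwise = FALSE,
                          value = "polar_angle_deg") {
  vals <- .values_for_sheet(sheet, map, value)
  dx <- sheet$flat_x - center[1]
  dy <- sheet$flat_y - center[2]
  r <- sqrt(dx^2 + dy^2)
  ang <- (atan2(dy, dx) * 180 / pi - start_deg) %% 360
  if (clockwise) ang <- (360 - ang) %% 360
  width <- 360 / n_sectors
  sec <- pmin(floor(ang / width) + 1L, n_sectors)
  out <- data.frame(position = seq_len(n_sectors),
                    angle_deg = (seq_len(n_sectors) - 0.5) * width +
                      start_deg,
                    value = NA_real_, n = 0L, empty = TRUE)
  for (s in seq_len(n_sectors)) {
    sel <- which(sec == s & r <= radius_mm & !is.na(vals))
    if (length(sel) > 0) {
      out$value[s] <- mean(vals[sel])
      out$n[s] <- length(sel)
      out$empty[s] <- FALSE
    }
  }
  class(out) <- c("profile", "data.frame")
  out
}

#' Eccentric-ring profile around a foveal confluence
#'
#' Splits the disc around `center` into `n_rings` equal-width
#' concentric rings and, separately for the two sides of a split axis
#' (e.g. medial vs lateral), averages pRF eccentricity per ring. On a
#' cloverleaf cluster centred on its foveal confluence both sides show
#' eccentricity increasing with ring index.
#'
#' @param sheet A `cortical_sheet`.
#' @param map A `retinotopic_map`.
#' @param center Length-2 centre on the flat sheet (mm).
#' @param radius_mm Outer radius (mm).
#' @param n_rings Number of rings (default 5).
#' @param split_axis `"x"` or `"y"`: nodes with coordinate above the
#'   centre on that axis form the `"lateral"` side, the rest
#'   `"medial"`.
#' @param value Map column to average.
#' @return A `profile` data frame: `position` (ring), `side`, `value`,
#'   `n`, `empty` (2 * n_rings rows).
#' @export
ring_profile <- function(sheet, map, center = c(0, 0), radius_mm = 10,
                         n_rings = 5, split_axis = c("x", "y"),
                         value = "eccentricity_deg") {
  split_axis <- match.arg(split_axis)
  vals <- .values_for_sheet(sheet, map, value)
  dx <- sheet$flat_x - center[1]
  dy <- sheet$flat_y - center[2]
  r <- sqrt(dx^2 + dy^2)
  side <- ifelse((if (split_axis == "x") dx else dy) >= 0,
                 "lateral", "medial")
  edges <- seq(0, radius_mm, length.out = n_rings + 1)
  ring <- pmin(findInterval(r, edges, rightmost.closed = TRUE), n_rings)
  out <- expand.grid(position = seq_len(n_rings),
                     side = c("medial", "lateral"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$value <- NA_real_; out$n <- 0L; out$empty <- TRUE
  for (i in seq_len(nrow(out))) {
    sel <- which(ring == out$position[i] & side == out$side[i] &
                   r <= radius_mm & !is.na(vals))
    if (length(sel) > 0) {
      out$value[i] <- mean(vals[sel])
      out$n[i] <- length(sel)
      out$empty[i] <- FALSE
    }
  }
  class(out) <- c("profile", "data.frame")
  out
}

#' Detect gradient reversals along a profile
#'
#' After moving-average smoothing, indices where the sign of the
#' discrete gradient changes and the new sign persists for at least
#' `min_run` steps are reported (zero gradients inherit the preceding
#' sign). With `circular = TRUE` the profile is treated as a closed
#' loop, as appropriate for spoke profiles.
#'
#' @param values Numeric profile values (>= 5 positions), or a
#'   `profile` data frame (its `value` column is used; empty bins must
#'   be absent or interpolated first).
#' @param smooth_window Moving-average window (odd; 1 = no smoothing).
#' @param min_run Minimum persistence (gradient steps) of the new sign.
#' @param circular Treat the profile as circular.
#' @return Integer vector of extremum positions (empty if none).
#' @export
detect_reversals <- function(values, smooth_window = 1, min_run = 2,
                             circular = FALSE) {
  if (is.data.frame(values)) values <- values$value
  if (anyNA(values)) stop("profile contains empty bins")
  n <- length(values)
  if (n < 5) stop("profile too short (need >= 5 positions)")
  if (smooth_window > 1) {
    k <- rep(1 / smooth_window, smooth_window)
    pad <- (smooth_window - 1) %/% 2
    ext <- if (circular)
      c(utils::tail(values, pad), values, utils::head(values, pad))
    else c(rep(values[1], pad), values, rep(values[n], pad))
    values <- stats::filter(ext, k, sides = 2)[pad + seq_len(n)]
  }
  d <- if (circular) diff(c(values, values[1])) else diff(values)
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) == 0) return(integer(0))     # flat profile
  # zero gradients inherit the preceding (or, leading, the first) sign
  s[seq_len(nz[1] - 1L)] <- s[nz[1]]
  for (i in seq_along(s)) if (s[i] == 0) s[i] <- s[i - 1]
  if (all(s == s[1])) return(integer(0))
  n_d <- length(s)
  # circular profiles: scan two laps so wrap-spanning runs are merged,
  # then fold reversal positions back into the first lap
  ss <- if (circular) c(s, s) else s
  runs <- rle(as.vector(ss))
  ends <- cumsum(runs$lengths)
  rev_pos <- integer(0)
  for (j in seq_len(length(runs$lengths) - 1)) {
    if (runs$values[j + 1] != runs$values[j] &&
        runs$lengths[j + 1] >= min_run)
      rev_pos <- c(rev_pos, ends[j] + 1L)
  }
  if (circular) rev_pos <- rev_pos[rev_pos <= 2L * n_d]
  sort(unique(((rev_pos - 1L) %% n_d) + 1L))
}

#' Split-half agreement of pRF parameters
#'
#' Compares fits obtained independently from odd and even run averages
#' on the common node set: Pearson correlations and median absolute
#' differences per parameter (polar-angle differences wrapped to
#' +/-180).
#'
#' @param fits_odd,fits_even `prf_fits` data frames.
#' @param valid_only Restrict to nodes valid in both halves.
#' @return List with `n`, per-parameter `r`
#'   (`x0`, `y0`, `sigma`, `polar_angle`, `eccentricity`) and `mad`
#'   (median absolute differences; angle wrapped).
#' @export
split_half <- function(fits_odd, fits_even, valid_only = TRUE) {
  m <- merge(as.data.frame(fits_odd), as.data.frame(fits_even),
             by = "node_id", suffixes = c("_odd", "_even"))
  if (valid_only) m <- m[m$valid_odd & m$valid_even, , drop = FALSE]
  if (nrow(m) < 10) stop("fewer than 10 common nodes")
  ang <- function(x0, y0) atan2(y0, abs(x0)) * 180 / pi
  pa_o <- ang(m$x0_odd, m$y0_odd); pa_e <- ang(m$x0_even, m$y0_even)
  ec_o <- sqrt(m$x0_odd^2 + m$y0_odd^2)
  ec_e <- sqrt(m$x0_even^2 + m$y0_even^2)
  wrap <- function(d) ((d + 180) %% 360) - 180
  safe_cor <- function(a, b)
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
    else stats::cor(a, b)
  list(
    n = nrow(m),
    r = c(x0 = safe_cor(m$x0_odd, m$x0_even),
          y0 = safe_cor(m$y0_odd, m$y0_even),
          sigma = safe_cor(m$sigma_odd, m$sigma_even),
          polar_angle = safe_cor(pa_o, pa_e),
          eccentricity = safe_cor(ec_o, ec_e)),
    mad = c(x0 = stats::median(abs(m$x0_odd - m$x0_even)),
            y0 = stats::median(abs(m$y0_odd - m$y0_even)),
            sigma = stats::median(abs(m$sigma_odd - m$sigma_even)),
            polar_angle = stats::median(abs(wrap(pa_o - pa_e))),
            eccentricity = stats::median(abs(ec_o - ec_e))))
}

#' Write a retinotopic map to TSV
#'
#' @param map A `retinotopic_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map_tsv <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
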