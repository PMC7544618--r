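#' Rotating-wedge stimulus design
#'
#' Describes a wedge aperture rotating over the visual field for
#' polar-angle mapping. The default parameters reproduce a wide-field
#' design: a wedge of ~40 degrees radius and 49 degrees angular extent
#' completing a rotation in 44 s, shown for 5 full cycles after a 10 s
#' lead-in, so every covered point of the field is stimulated for
#' 49/360 x 44 s (about 6 s) per cycle.
#'
#' @param radius_deg Wedge radius in degrees of visual angle.
#' @param angular_extent_deg Angular extent of the wedge in degrees
#'   (0 < extent <= 360).
#' @param cycle_s Duration of one full rotation in seconds.
#' @param n_full_cycles Number of full cycles after the lead-in.
#' @param leadin_s Lead-in duration in seconds; the lead-in replays the
#'   final `leadin_s` seconds of a cycle so the periodic steady state is
#'   reached before the first analysed cycle.
#' @param direction `"clockwise"` or `"counterclockwise"` (as seen by
#'   the viewer; counterclockwise increases the mathematical angle).
#' @param start_angle_deg Polar angle (degrees, 0 = right horizontal,
#'   90 = upper vertical) of the wedge centre at the start of a cycle.
#' @param frame_rate_hz Display frame rate in Hz.
#' @param raster_px Raster width/height in pixels. Aperture geometry is
#'   resolution independent (it is defined in degrees via
#'   `deg_per_px`), so smaller rasters can be used for analysis.
#' @param deg_per_px Degrees of visual angle per pixel; defaults to
#'   `2 * radius_deg / raster_px` so the field just fills the raster.
#' @return An object of class `c("wedge_design", "aperture_design")`.
#' @seealso [make_wedge_movie()], [ring_design()]
#' @export
wedge_design <- function(radius_deg = 40, angular_extent_deg = 49,
                         cycle_s = 44, n_full_cycles = 5, leadin_s = 10,
                         direction = c("clockwise", "counterclockwise"),
                         start_angle_deg = 90, frame_rate_hz = 16,
                         raster_px = 700, deg_per_px = NULL) {
  direction <- match.arg(direction)
  stopifnot(radius_deg > 0, cycle_s > 0, n_full_cycles >= 0, leadin_s >= 0,
            raster_px >= 2)
  if (angular_extent_deg <= 0 || angular_extent_deg > 360)
    stop("angular_extent_deg must lie in (0, 360]")
  if (frame_rate_hz <= 0) stop("frame_rate_hz must be positive")
  if (is.null(deg_per_px)) deg_per_px <- 2 * radius_deg / raster_px
  structure(list(type = "wedge", radius_deg = radius_deg,
                 angular_extent_deg = angular_extent_deg,
                 cycle_s = cycle_s, n_full_cycles = n_full_cycles,
                 leadin_s = leadin_s, direction = direction,
                 start_angle_deg = start_angle_deg,
                 frame_rate_hz = frame_rate_hz, raster_px = raster_px,
                 deg_per_px = deg_per_px),
            class = c("wedge_design", "aperture_design"))
}

#' Expanding/contracting-ring stimulus design
#'
#' Describes an annular aperture whose mean eccentricity sweeps linearly
#' between `ecc_min_deg` and `ecc_max_deg` over one cycle, used for
#' eccentricity mapping. The annulus has constant width; its inner
#' border is clipped at 0 degrees near the centre of gaze.
#'
#' @param ecc_min_deg,ecc_max_deg Range of the mean eccentricity sweep
#'   in degrees (`ecc_max_deg > ecc_min_deg`).
#' @param width_deg Annulus width (outer minus inner border) in degrees.
#' @param direction `"expanding"` or `"contracting"`.
#' @inheritParams wedge_design
#' @return An object of class `c("ring_design", "aperture_design")`.
#' @export
ring_design <- function(ecc_min_deg = 0, ecc_max_deg = 40, width_deg = 11,
                        cycle_s = 44, n_full_cycles = 5, leadin_s = 10,
                        direction = c("expanding", "contracting"),
                        frame_rate_hz = 16, raster_px = 700,
                        deg_per_px = NULL) {
  direction <- match.arg(direction)
  stopifnot(width_deg > 0, cycle_s > 0, n_full_cycles >= 0, leadin_s >= 0,
            raster_px >= 2)
  if (ecc_max_deg <= ecc_min_deg) stop("ecc_max_deg must exceed ecc_min_deg")
  if (frame_rate_hz <= 0) stop("frame_rate_hz must be positive")
  if (is.null(deg_per_px))
    deg_per_px <- 2 * (ecc_max_deg + width_deg / 2) / raster_px
  structure(list(type = "ring", ecc_min_deg = ecc_min_deg,
                 ecc_max_deg = ecc_max_deg, width_deg = width_deg,
                 cycle_s = cycle_s, n_full_cycles = n_full_cycles,
                 leadin_s = leadin_s, direction = direction,
                 frame_rate_hz = frame_rate_hz, raster_px = raster_px,
                 deg_per_px = deg_per_px),
            class = c("ring_design", "aperture_design"))
}

#' Block-design motion localizer
#'
#' Four visual conditions (central/peripheral crossed with
#' motion/static, split at `central_ecc_deg`) presented in 6 s blocks,
#' each repeated `n_repeats` times and separated (and flanked) by blank
#' baselines, so a run holds `n_blocks + 1` baselines.
#'
#' @param block_s Condition block duration (s).
#' @param baseline_s Blank baseline duration (s).
#' @param n_repeats Repetitions of each condition per run.
#' @param conditions Character vector of condition labels.
#' @param central_ecc_deg Eccentricity (deg) separating central from
#'   peripheral apertures.
#' @return An object of class `"localizer_design"`.
#' @export
localizer_design <- function(block_s = 6, baseline_s = 10, n_repeats = 3,
                             conditions = c("Central-Motion", "Central-Static",
                                            "Peripheral-Motion",
                                            "Peripheral-Static"),
                             central_ecc_deg = 3) {
  stopifnot(block_s > 0, baseline_s > 0, n_repeats >= 0,
            length(conditions) >= 1)
  structure(list(block_s = block_s, baseline_s = baseline_s,
                 n_repeats = n_repeats, conditions = conditions,
                 central_ecc_deg = central_ecc_deg),
            class = "localizer_design")
}

#' Total duration of an aperture design
#'
#' `leadin_s + n_full_cycles * cycle_s` for wedge/ring designs; blocks
#' plus flanking baselines for the localizer.
#'
#' @param design A design object.
#' @return Duration in seconds.
#' @export
design_duration <- function(design) {
  if (inherits(design, "aperture_design"))
    return(design$leadin_s + design$n_full_cycles * design$cycle_s)
  if (inherits(design, "localizer_design")) {
    n_blocks <- design$n_repeats * length(design$conditions)
    return(n_blocks * design$block_s + (n_blocks + 1) * design$baseline_s)
  }
  stop("unknown design class")
}

## Phase within the cycle at time t (s from movie onset). The stimulus
## starts with the last `leadin_s` seconds of a cycle, so cycle starts
## fall at t = leadin_s + k * cycle_s.
.cycle_phase <- function(design, t) (t - design$leadin_s) %% design$cycle_s

#' Aperture indicator function
#'
#' Evaluates, without rasterising, whether visual-field positions are
#' inside the aperture at time `t`. This is the geometric primitive
#' shared by the movie generators and is resolution free.
#'
#' @param design A wedge or ring design.
#' @param t Time in seconds from movie onset (scalar).
#' @param x,y Visual-field coordinates in degrees (vectors of equal
#'   length); x increases rightward, y upward.
#' @return Logical vector.
#' @export
aperture_indicator <- function(design, t, x, y) {
  stopifnot(length(t) == 1L)
  phase <- .cycle_phase(design, t)
  ecc <- sqrt(x^2 + y^2)
  if (design$type == "wedge") {
    sgn <- if (design$direction == "counterclockwise") 1 else -1
    centre <- design$start_angle_deg +
      sgn * 360 * phase / design$cycle_s
    ang <- atan2(y, x) * 180 / pi
    d <- ((ang - centre + 180) %% 360) - 180
    abs(d) <= design$angular_extent_deg / 2 & ecc <= design$radius_deg
  } else {
    frac <- phase / design$cycle_s
    if (design$direction == "contracting") frac <- 1 - frac
    m <- design$ecc_min_deg + (design$ecc_max_deg - design$ecc_min_deg) * frac
    lo <- max(0, m - design$width_deg / 2)
    hi <- m + design$width_deg / 2
    ecc >= lo & ecc <= hi
  }
}

## Pixel-centre coordinates of the raster, centred on (0, 0) deg.
.raster_coords <- function(raster_px, deg_per_px) {
  ax <- (seq_len(raster_px) - (raster_px + 1) / 2) * deg_per_px
  list(x = ax, y = ax)
}

.movie_frames_n <- function(design) {
  n <- design_duration(design) * design$frame_rate_hz
  if (abs(n - round(n)) > 1e-9)
    stop("duration times frame rate must be an integer frame count")
  as.integer(round(n))
}

.make_aperture_movie <- function(design) {
  n_frames <- .movie_frames_n(design)
  px <- design$raster_px
  p <- as.numeric(px)^2
  if (n_frames * p > 3e8)
    stop("raster/frame-rate combination too large to hold in memory; ",
         "reduce raster_px (aperture geometry is resolution independent)")
  co <- .raster_coords(px, design$deg_per_px)
  xx <- rep(co$x, each = px)   # column-major: y varies fastest
  yy <- rep(co$y, times = px)
  frames <- matrix(FALSE, n_frames, px * px)
  times <- (seq_len(n_frames) - 0.5) / design$frame_rate_hz
  for (i in seq_len(n_frames))
    frames[i, ] <- aperture_indicator(design, times[i], xx, yy)
  structure(list(frames = frames, h = px, w = px,
                 deg_per_px = design$deg_per_px,
                 frame_rate_hz = design$frame_rate_hz,
                 t0_s = 0, leadin_s = design$leadin_s,
                 cycle_s = design$cycle_s,
                 n_full_cycles = design$n_full_cycles,
                 field_radius_deg = max(abs(co$x)) + design$deg_per_px / 2,
                 design = design),
            class = "aperture_movie")
}

#' Rasterise a wedge design into an aperture movie
#'
#' A frame has a pixel on iff the pixel centre lies within the wedge
#' radius and within half the angular extent of the wedge centre, which
#' rotates by 360 degrees per cycle. The lead-in replays the last
#' `leadin_s` seconds of a cycle; lead-in frames are generated and can
#' be identified from the movie's `leadin_s` field so preprocessing can
#' discard them.
#'
#' @param design A [wedge_design()].
#' @return An `aperture_movie`: a frames-by-pixels logical matrix plus
#'   raster metadata (`deg_per_px`, frame rate, cycle structure).
#' @export
make_wedge_movie <- function(design) {
  stopifnot(inherits(design, "wedge_design"))
  # arc width at mid-eccentricity must be resolvable on the raster
  arc_mid <- 2 * (design$radius_deg / 2) *
    sin(pi * min(design$angular_extent_deg, 180) / 360)
  if (design$deg_per_px > arc_mid / 2)
    stop("raster too coarse to resolve the wedge; increase raster_px")
  .make_aperture_movie(design)
}

#' Rasterise a ring design into an aperture movie
#'
#' A frame has a pixel on iff its eccentricity lies in
#' `[max(0, m(t) - width/2), m(t) + width/2]` where the mean
#' eccentricity `m(t)` varies linearly over the cycle (reversed for
#' contracting rings). The outer border may exceed the raster and is
#' clipped at the raster bounds.
#'
#' @param design A [ring_design()].
#' @return An `aperture_movie`.
#' @export
make_ring_movie <- function(design) {
  stopifnot(inherits(design, "ring_design"))
  if (design$deg_per_px > design$width_deg / 2)
    stop("raster too coarse to resolve the ring width; increase raster_px")
  .make_aperture_movie(design)
}

#' @export
print.aperture_movie <- function(x, ...) {
  cat(sprintf("<aperture_movie> %s: %d frames (%.0f s at %g Hz), %dx%d px, %.3f deg/px\n",
              x$design$type, nrow(x$frames),
              nrow(x$frames) / x$frame_rate_hz, x$frame_rate_hz,
              x$h, x$w, x$deg_per_px))
  invisible(x)
}

#' Pixel-centre coordinates of a movie raster
#'
#' @param movie An `aperture_movie`.
#' @return A list with vectors `x` and `y` of length `h * w`
#'   (column-major, y varying fastest) in degrees.
#' @export
movie_pixel_coords <- function(movie) {
  co <- .raster_coords(movie$w, movie$deg_per_px)
  list(x = rep(co$x, each = movie$h), y = rep(co$y, times = movie$w))
}

#' Per-cycle stimulation time of a visual-field point
#'
#' Counts the frames during the full cycles (lead-in excluded) in which
#' the raster pixel nearest to `point_deg` is inside the aperture and
#' converts the per-cycle count to seconds. For the default wedge this
#' is `angular_extent/360 * cycle_s` (about 6 s); for a ring it is
#' `width / sweep rate` of the mean eccentricity.
#'
#' @param movie An `aperture_movie` with at least one full cycle.
#' @param point_deg Numeric length-2 vector `(x, y)` in degrees.
#' @return Seconds of stimulation per cycle.
#' @export
dwell_time <- function(movie, point_deg) {
  stopifnot(inherits(movie, "aperture_movie"), length(point_deg) == 2)
  half <- movie$w / 2 * movie$deg_per_px
  if (any(abs(point_deg) > half)) stop("point outside the raster")
  if (movie$n_full_cycles < 1) stop("movie holds no full cycle")
  co <- .raster_coords(movie$w, movie$deg_per_px)
  ix <- which.min(abs(co$x - point_deg[1]))
  iy <- which.min(abs(co$y - point_deg[2]))
  p <- (ix - 1L) * movie$h + iy
  times <- (seq_len(nrow(movie$frames)) - 0.5) / movie$frame_rate_hz
  full <- times > movie$leadin_s
  sum(movie$frames[full, p]) / movie$frame_rate_hz / movie$n_full_cycles
}

#' Randomised block schedule for the motion localizer
#'
#' Blocks are ordered by a seeded permutation of
#' `rep(conditions, n_repeats)` and interleaved with baselines so that
#' every block is flanked by baselines.
#'
#' @param design A [localizer_design()].
#' @param seed Integer seed for the block permutation.
#' @return A data frame `(condition, onset_s, duration_s)` including
#'   `"Baseline"` rows, with a `total_duration_s` attribute.
#' @export
make_localizer_schedule <- function(design, seed = 1L) {
  stopifnot(inherits(design, "localizer_design"))
  blocks <- rep(design$conditions, design$n_repeats)
  blocks <- with_seed(seed, sample(blocks))
  cond <- character(0); onset <- numeric(0); dur <- numeric(0)
  t <- 0
  add <- function(cnd, d) {
    cond <<- c(cond, cnd); onset <<- c(onset, t); dur <<- c(dur, d)
    t <<- t + d
  }
  add("Baseline", design$baseline_s)
  for (b in blocks) {
    add(b, design$block_s)
    add("Baseline", design$baseline_s)
  }
  out <- data.frame(condition = cond, onset_s = onset, duration_s = dur,
                    stringsAsFactors = FALSE)
  attr(out, "total_duration_s") <- t
  out
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Seeds the global RNG, evaluates `expr`, and restores the previous
#' RNG state, so seeded helpers do not perturb the caller's stream.
#'
#' @param seed Integer seed (or `NULL` to use the current stream).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
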