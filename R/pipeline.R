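#' Noise presets for simulated sessions
#'
#' `"none"` gives noiseless signals. `"moderate"` is calibrated so
#' that, under the default session (24 runs per type averaged before
#' fitting), the median goodness of fit across nodes lands near
#' r = 0.7, a realistic regime for parietal data; `"high"` doubles
#' every noise SD.
#'
#' @param name Preset name.
#' @return A [noise_spec()].
#' @export
noise_preset <- function(name = c("none", "moderate", "high")) {
  name <- match.arg(name)
  switch(name,
         none = noise_spec(),
         moderate = noise_spec(white_sd = 5, drift_sd = 1.5,
                               drift_orders = 3, nuisance_sd = 1),
         high = noise_spec(white_sd = 10, drift_sd = 3,
                           drift_orders = 3, nuisance_sd = 2))
}

#' Simulate repeated runs of one stimulus type
#'
#' The noiseless node response to the movie is computed once and
#' reused; each run adds an independent noise draw (white + drift +
#' that run's shared nuisance components).
#'
#' @param sheet A `cortical_sheet`.
#' @param movie An `aperture_movie`.
#' @param run_type Label stored on the runs.
#' @param n_runs Number of runs.
#' @param hrf,TR,amp As in [simulate_sheet_bold()].
#' @param noise A [noise_spec()].
#' @param n_nuisance Shared nuisance components per run.
#' @param seed Base seed; run j uses `seed + j`.
#' @param tr_frames Optional precomputed [bin_movie_to_tr()] output.
#' @return List of `node_timecourses` (one per run) with attribute
#'   `clean` (the shared noiseless `node_timecourses`).
#' @export
simulate_runs <- function(sheet, movie, run_type, n_runs = 24,
                          hrf = hrf_double_gamma(), TR = 2, amp = 1,
                          noise = noise_spec(), n_nuisance = 6,
                          seed = 1L, tr_frames = NULL) {
  sim <- simulate_sheet_bold(sheet, movie, hrf, TR, amp,
                             noise = noise_spec(), seed = NULL,
                             tr_frames = tr_frames)
  clean <- attr(sim, "clean")
  n_tr <- ncol(clean)
  meta <- list(cycle_TRs = attr(sim, "cycle_TRs"),
               leadin_TRs = attr(sim, "leadin_TRs"))
  runs <- lapply(seq_len(n_runs), function(j) {
    nuis <- make_nuisance_courses(n_tr, k = n_nuisance,
                                  seed = seed + 7919L * j)
    noisy <- with_seed(seed + j, {
      out <- clean
      for (i in seq_len(nrow(out))) {
        e <- stats::rnorm(n_tr, sd = noise$white_sd) +
          .drift(n_tr, noise$drift_sd, noise$drift_orders)
        if (noise$nuisance_sd > 0)
          e <- e + drop(nuis %*% stats::rnorm(ncol(nuis),
                                              sd = noise$nuisance_sd))
        out[i, ] <- out[i, ] + e
      }
      out
    })
    node_timecourses(noisy, TR = TR, run_type = run_type,
                     cycle_TRs = meta$cycle_TRs,
                     leadin_TRs = meta$leadin_TRs)
  })
  attr(runs, "clean") <- node_timecourses(
    clean, TR = TR, run_type = run_type, cycle_TRs = meta$cycle_TRs,
    leadin_TRs = meta$leadin_TRs)
  runs
}

#' Build the four retinotopy aperture movies
#'
#' Clockwise/counterclockwise wedges and expanding/contracting rings
#' sharing one raster.
#'
#' @param raster_px Raster size in pixels (analysis rasters can be much
#'   smaller than the display raster; geometry is resolution free).
#' @param frame_rate_hz Frame rate (Hz).
#' @param radius_deg Field radius (deg).
#' @return Named list `cw`, `ccw`, `exp`, `con`.
#' @export
make_session_movies <- function(raster_px = 61, frame_rate_hz = 16,
                                radius_deg = 40) {
  list(
    cw = make_wedge_movie(wedge_design(radius_deg = radius_deg,
                                       direction = "clockwise",
                                       raster_px = raster_px,
                                       frame_rate_hz = frame_rate_hz)),
    ccw = make_wedge_movie(wedge_design(radius_deg = radius_deg,
                                        direction = "counterclockwise",
                                        raster_px = raster_px,
                                        frame_rate_hz = frame_rate_hz)),
    exp = make_ring_movie(ring_design(ecc_max_deg = radius_deg,
                                      direction = "expanding",
                                      raster_px = raster_px,
                                      frame_rate_hz = frame_rate_hz,
                                      deg_per_px = 2 * radius_deg / raster_px)),
    con = make_ring_movie(ring_design(ecc_max_deg = radius_deg,
                                      direction = "contracting",
                                      raster_px = raster_px,
                                      frame_rate_hz = frame_rate_hz,
                                      deg_per_px = 2 * radius_deg / raster_px)))
}

#' Preprocess simulated runs into 88-sample fit vectors
#'
#' Averages the runs of each type (optionally a subset, e.g. odd or
#' even runs), applies the harmonic filter + cycle collapse, and
#' concatenates the four conditions.
#'
#' @param runs_by_type Named list (`cw`, `ccw`, `exp`, `con`) of lists
#'   of `node_timecourses`.
#' @param run_subset Optional function mapping a run count to the
#'   indices to keep (e.g. odd runs: `function(n) seq(1, n, by = 2)`).
#' @return `node x 88` matrix.
#' @export
collapse_session <- function(runs_by_type, run_subset = NULL) {
  cycles <- lapply(runs_by_type, function(runs) {
    if (!is.null(run_subset)) runs <- runs[run_subset(length(runs))]
    harmonic_filter_and_collapse(average_runs(runs))
  })
  concat_conditions(cycles$cw, cycles$ccw, cycles$exp, cycles$con)
}

#' Configuration for a reproducible simulated session
#'
#' Collects every tunable of the simulate -> preprocess -> fit -> maps
#' -> coverage chain; all stochastic stages derive their seeds from
#' `seed`. The configuration serialises to JSON and reads back
#' identically.
#'
#' @param seed Master seed.
#' @param n_nodes Sheet size.
#' @param n_runs_per_type Runs per stimulus type.
#' @param raster_px,frame_rate_hz Analysis raster for the movies.
#' @param TR Repetition time (s).
#' @param amp Response amplitude (PSC per unit overlap).
#' @param noise Noise preset name.
#' @param grid_n_side,grid_n_sigma Search-grid size.
#' @param r_thresh Goodness-of-fit threshold.
#' @param hemisphere Simulated hemisphere.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, n_nodes = 200, n_runs_per_type = 24,
                       raster_px = 61, frame_rate_hz = 16, TR = 2,
                       amp = 1, noise = "moderate", grid_n_side = 41,
                       grid_n_sigma = 10, r_thresh = 0.5,
                       hemisphere = "left") {
  structure(list(seed = as.integer(seed), n_nodes = as.integer(n_nodes),
                 n_runs_per_type = as.integer(n_runs_per_type),
                 raster_px = as.integer(raster_px),
                 frame_rate_hz = frame_rate_hz, TR = TR, amp = amp,
                 noise = noise, grid_n_side = as.integer(grid_n_side),
                 grid_n_sigma = as.integer(grid_n_sigma),
                 r_thresh = r_thresh, hemisphere = hemisphere),
            class = "run_config")
}

#' Write / read a run configuration
#'
#' @param config A `run_config`.
#' @param path JSON path.
#' @return `path` (write) or the `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  int_fields <- c("seed", "n_nodes", "n_runs_per_type", "raster_px",
                  "grid_n_side", "grid_n_sigma")
  num_fields <- c("frame_rate_hz", "TR", "amp", "r_thresh")
  for (f in intersect(int_fields, names(x))) x[[f]] <- as.integer(x[[f]])
  for (f in intersect(num_fields, names(x))) x[[f]] <- as.numeric(x[[f]])
  structure(x, class = "run_config")
}

.manifest_path <- function(out_dir, stage)
  file.path(out_dir, paste0("manifest_", stage, ".json"))

.write_manifest <- function(out_dir, stage, config, files) {
  md5 <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(md5) <- files
  jsonlite::write_json(
    list(stage = stage, config = unclass(config), files = md5,
         package_version = as.character(utils::packageVersion("prfmapr"))),
    .manifest_path(out_dir, stage), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
}

.check_manifest <- function(out_dir, stage) {
  mp <- .manifest_path(out_dir, stage)
  if (!file.exists(mp))
    stop("upstream stage '", stage, "' has not been run in ", out_dir)
  m <- jsonlite::read_json(mp, simplifyVector = TRUE)
  files <- names(m$files)
  actual <- tools::md5sum(file.path(out_dir, files))
  if (anyNA(actual) || any(unname(actual) != unlist(m$files)))
    stop("artifacts of stage '", stage,
         "' are missing or do not match their manifest; rerun it")
  invisible(m)
}

.session_env <- new.env(parent = emptyenv())

.config_objects <- function(config) {
  key <- paste(deparse(unclass(config)), collapse = "")
  if (!is.null(.session_env$key) && identical(.session_env$key, key))
    return(.session_env$obj)
  movies <- make_session_movies(config$raster_px, config$frame_rate_hz)
  obj <- list(movies = movies,
              hrf = hrf_double_gamma(),
              grid = NULL)
  .session_env$key <- key
  .session_env$obj <- obj
  obj
}

#' Run one pipeline stage
#'
#' Stages: `"simulate"` (sheet + per-run node time courses),
#' `"preprocess"` (run averaging, harmonic filter, 88-sample vectors),
#' `"fit"` (grid-search pRF fits), `"maps"` (retinotopic map, spoke and
#' ring profiles, reversal indices), `"coverage"` (coverage extents and
#' per-area statistics). Each stage writes its artifacts plus a JSON
#' manifest (config echo + artifact checksums) into `out_dir`, checks
#' its upstream manifest before running, and is deterministic given the
#' configuration.
#'
#' @param stage Stage name.
#' @param config A [run_config()].
#' @param out_dir Artifact directory (created if needed).
#' @return Character vector of artifact filenames, invisibly.
#' @export
run_stage <- function(stage = c("simulate", "preprocess", "fit", "maps",
                                "coverage"),
                      config = run_config(), out_dir = ".") {
  stage <- match.arg(stage)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  obj <- .config_objects(config)
  files <- switch(stage,
    simulate = {
      layout <- cluster_layout(hemisphere = config$hemisphere)
      sheet <- make_cluster_sheet(layout, config$n_nodes,
                                  seed = config$seed)
      write_sheet_tsv(sheet, file.path(out_dir, "sheet.tsv"))
      fs <- "sheet.tsv"
      noise <- noise_preset(config$noise)
      for (tt in names(obj$movies)) {
        runs <- simulate_runs(sheet, obj$movies[[tt]], tt,
                              n_runs = config$n_runs_per_type,
                              hrf = obj$hrf, TR = config$TR,
                              amp = config$amp, noise = noise,
                              seed = config$seed * 1000L +
                                match(tt, names(obj$movies)) * 100L)
        for (j in seq_along(runs)) {
          fn <- sprintf("ntc_%s_run%02d.tsv", tt, j)
          write_ntc_tsv(runs[[j]], file.path(out_dir, fn))
          fs <- c(fs, fn)
        }
      }
      fs
    },
    preprocess = {
      .check_manifest(out_dir, "simulate")
      series <- collapse_session(lapply(
        c(cw = "cw", ccw = "ccw", exp = "exp", con = "con"),
        function(tt) {
          fns <- sort(list.files(out_dir,
                                 sprintf("^ntc_%s_run\\d+\\.tsv$", tt)))
          lapply(file.path(out_dir, fns), read_ntc_tsv)
        }))
      df <- data.frame(node_id = rownames(series), series,
                       check.names = FALSE)
      utils::write.table(df, file.path(out_dir, "series88.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      "series88.tsv"
    },
    fit = {
      .check_manifest(out_dir, "preprocess")
      df <- utils::read.table(file.path(out_dir, "series88.tsv"),
                              sep = "\t", header = TRUE,
                              check.names = FALSE)
      series <- as.matrix(df[, -1])
      rownames(series) <- df$node_id
      spec <- reduced_grid_spec(config$grid_n_side, config$grid_n_sigma)
      grid <- build_grid(obj$movies, obj$hrf, config$TR, spec)
      fits <- fit_nodes(series, grid, r_thresh = config$r_thresh)
      fits <- contralateral_filter(fits, config$hemisphere,
                                   keep_all = TRUE)
      write_fits_tsv(fits, file.path(out_dir, "fits.tsv"))
      "fits.tsv"
    },
    maps = {
      .check_manifest(out_dir, "fit")
      .check_manifest(out_dir, "simulate")
      fits <- read_fits_tsv(file.path(out_dir, "fits.tsv"))
      sheet <- read_sheet_tsv(file.path(out_dir, "sheet.tsv"))
      map <- to_map(fits)
      write_map_tsv(map, file.path(out_dir, "map.tsv"))
      sp <- spoke_profile(sheet, map)
      rp <- ring_profile(sheet, map)
      utils::write.csv(sp, file.path(out_dir, "spoke_profile.csv"),
                       row.names = FALSE)
      utils::write.csv(rp, file.path(out_dir, "ring_profile.csv"),
                       row.names = FALSE)
      vals <- sp$value[!sp$empty]   # empty sectors carry no gradient
      rev_idx <- if (length(vals) >= 5)
        detect_reversals(vals, circular = TRUE) else integer(0)
      jsonlite::write_json(list(reversal_positions = rev_idx,
                                n_reversals = length(rev_idx)),
                           file.path(out_dir, "reversals.json"),
                           auto_unbox = TRUE, digits = NA)
      c("map.tsv", "spoke_profile.csv", "ring_profile.csv",
        "reversals.json")
    },
    coverage = {
      .check_manifest(out_dir, "fit")
      .check_manifest(out_dir, "simulate")
      fits <- read_fits_tsv(file.path(out_dir, "fits.tsv"))
      sheet <- read_sheet_tsv(file.path(out_dir, "sheet.tsv"))
      fits$area <- sheet$area[match(fits$node_id, sheet$node_id)]
      keep <- fits$passed_threshold & fits$retained_contra
      cov <- field_coverage(fits[keep, , drop = FALSE])
      ecc <- sqrt(fits$x0[keep]^2 + fits$y0[keep]^2)
      kw_ok <- length(unique(fits$area[keep])) >= 2 &&
        all(table(fits$area[keep]) >= 2)
      na_kw <- list(H = NA, df = NA, p = NA)
      kw_e <- if (kw_ok) group_compare(ecc, fits$area[keep]) else na_kw
      kw_s <- if (kw_ok) group_compare(fits$sigma[keep], fits$area[keep])
              else na_kw
      secc <- size_ecc_correlation(fits[keep, , drop = FALSE])
      utils::write.csv(secc,
                       file.path(out_dir, "size_ecc_correlation.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(extent = as.list(cov$extent),
             region_mass = cov$region_mass,
             kruskal_wallis = list(
               eccentricity = kw_e[c("H", "df", "p")],
               size = kw_s[c("H", "df", "p")])),
        file.path(out_dir, "coverage_summary.json"),
        auto_unbox = TRUE, digits = NA)
      c("size_ecc_correlation.csv", "coverage_summary.json")
    })
  .write_manifest(out_dir, stage, config, files)
  invisible(files)
}
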