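# Shared fixtures, memoised so expensive aperture movies and search
# grids are built once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

run_types <- c(cw = "cw", ccw = "ccw", exp = "exp", con = "con")

# small analysis raster: geometry is resolution free
test_movies <- function() memo("movies41", make_session_movies(raster_px = 41))

# small search grid matched to the small movies
test_grid_spec <- function() reduced_grid_spec(n_side = 21, n_sigma = 6)

test_grid <- function() memo("grid21x6", build_grid(test_movies(),
                                                    spec = test_grid_spec()))

test_sheet <- function(n = 60, seed = 7)
  make_cluster_sheet(cluster_layout(), n, seed = seed)

# noiseless 88-sample vectors for a sheet
noiseless_series <- function(sheet, movies = test_movies()) {
  collapse_session(lapply(run_types, function(tt)
    simulate_runs(sheet, movies[[tt]], tt, n_runs = 1,
                  noise = noise_spec(), seed = 1)))
}

noisy_session <- function(sheet, noise, n_runs = 4, seed = 11,
                          movies = test_movies()) {
  lapply(run_types, function(tt)
    simulate_runs(sheet, movies[[tt]], tt, n_runs = n_runs,
                  noise = noise, seed = seed))
}
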