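#' Visual-field coverage from summed Gaussian pRFs
#'
#' Sums unit-mass Gaussians on a regular visual-field grid and finds
#' the highest-density region (smallest superlevel set) containing
#' `mass` of the total density, together with its horizontal and
#' vertical extents. The grid extends `3 * max(sigma)` beyond the most
#' eccentric centre so that truncated mass is negligible. For a single
#' pRF of SD sigma the 95% region is a disc of radius
#' `sigma * sqrt(2 * log(20))` (about 12.24 deg for sigma = 5).
#'
#' @param fits A `prf_fits` data frame (>= 1 row with finite
#'   parameters).
#' @param grid_step Grid spacing (deg).
#' @param mass Density mass the region must contain (default 0.95).
#' @return A `coverage_density` list: `x`, `y` grid axes, `density`
#'   matrix (x by y), logical `region`, `level`, `region_mass`
#'   (fraction), `total_mass` (units of pRF count), and `extent`
#'   (`xmin`, `xmax`, `ymin`, `ymax` of the region).
#' @export
field_coverage <- function(fits, grid_step = 0.25, mass = 0.95) {
  f <- as.data.frame(fits)
  f <- f[is.finite(f$x0) & is.finite(f$y0) & is.finite(f$sigma), ,
         drop = FALSE]
  if (nrow(f) == 0) stop("no valid fits to cover")
  stopifnot(mass > 0, mass < 1)
  lim <- max(sqrt(f$x0^2 + f$y0^2)) + 3 * max(f$sigma)
  ax <- seq(-lim, lim, by = grid_step)
  dens <- matrix(0, length(ax), length(ax))
  for (i in seq_len(nrow(f))) {
    gx <- stats::dnorm(ax, f$x0[i], f$sigma[i])
    gy <- stats::dnorm(ax, f$y0[i], f$sigma[i])
    dens <- dens + outer(gx, gy)
  }
  cellmass <- dens * grid_step^2
  total <- sum(cellmass)
  ord <- order(dens, decreasing = TRUE)
  cum <- cumsum(cellmass[ord])
  cut <- which(cum >= mass * total)[1]
  level <- dens[ord[cut]]
  region <- dens >= level
  idx <- which(region, arr.ind = TRUE)
  structure(list(x = ax, y = ax, density = dens, region = region,
                 level = level,
                 region_mass = sum(cellmass[region]) / total,
                 total_mass = total,
                 extent = c(xmin = min(ax[idx[, 1]]),
                            xmax = max(ax[idx[, 1]]),
                            ymin = min(ax[idx[, 2]]),
                            ymax = max(ax[idx[, 2]])),
                 grid_step = grid_step, mass = mass),
            class = "coverage_density")
}

#' @export
print.coverage_density <- function(x, ...) {
  cat(sprintf("<coverage_density> %.0f%% region: x [%.1f, %.1f] deg, y [%.1f, %.1f] deg (step %.2f)\n",
              100 * x$mass, x$extent["xmin"], x$extent["xmax"],
              x$extent["ymin"], x$extent["ymax"], x$grid_step))
  invisible(x)
}

#' Kruskal-Wallis comparison of a quantity across areas
#'
#' Rank-based H statistic with tie correction and a chi-square p value
#' on `k - 1` degrees of freedom (via [stats::kruskal.test()]).
#'
#' @param values Numeric vector.
#' @param groups Group labels (same length).
#' @return List with `H`, `df`, `p` and per-group `n`.
#' @export
group_compare <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2)
  if (any(table(groups) < 2)) stop("each group needs at least 2 values")
  if (stats::var(values) == 0)
    return(list(H = 0, df = nlevels(groups) - 1, p = 1,
                n = as.vector(table(groups))))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, n = as.vector(table(groups)))
}

#' Size-eccentricity correlation per area
#'
#' Pearson correlation between pRF eccentricity and sigma within each
#' area; areas with fewer than 3 fits or zero variance are flagged
#' with `NA`.
#'
#' @param fits A `prf_fits` data frame with an `area` column (or
#'   supply `areas`).
#' @param areas Optional area labels overriding `fits$area`.
#' @return Data frame `area`, `r`, `n`.
#' @export
size_ecc_correlation <- function(fits, areas = fits$area) {
  if (is.null(areas)) stop("area labels required")
  f <- as.data.frame(fits)
  ecc <- sqrt(f$x0^2 + f$y0^2)
  out <- do.call(rbind, lapply(split(seq_len(nrow(f)), areas),
                               function(ix) {
    r <- if (length(ix) < 3 || stats::sd(ecc[ix]) == 0 ||
             stats::sd(f$sigma[ix]) == 0) NA_real_
         else stats::cor(ecc[ix], f$sigma[ix])
    data.frame(r = r, n = length(ix))
  }))
  data.frame(area = rownames(out), r = out$r, n = out$n,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a coverage grid to CSV
#'
#' @param cov A `coverage_density`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_csv <- function(cov, path) {
  df <- data.frame(x = rep(cov$x, times = length(cov$y)),
                   y = rep(cov$y, each = length(cov$x)),
                   density = as.vector(cov$density),
                   in_region = as.vector(cov$region))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
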