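#' Design matrix for the block-design localizer GLM
#'
#' Condition boxcars (baseline modelled implicitly) are built at the TR
#' grid with fractional occupancy, convolved with the HRF, and combined
#' with optional noise regressors and an intercept. Collinear columns
#' are pruned with a warning so the returned matrix has full column
#' rank.
#'
#' @param schedule Data frame from [make_localizer_schedule()].
#' @param hrf An [hrf_double_gamma()].
#' @param TR Repetition time (s).
#' @param noise_regressors Optional `T x k` matrix appended to the
#'   design.
#' @return `T x P` design matrix with column names; attribute
#'   `conditions` lists the condition columns.
#' @export
build_design <- function(schedule, hrf = hrf_double_gamma(), TR = 2,
                         noise_regressors = NULL) {
  total <- attr(schedule, "total_duration_s")
  if (is.null(total)) total <- max(schedule$onset_s + schedule$duration_s)
  n_tr <- round(total / TR)
  if (abs(n_tr - total / TR) > 1e-9)
    stop("run duration must be an integer number of TRs")
  blocks <- schedule[schedule$condition != "Baseline", , drop = FALSE]
  if (nrow(blocks) > 1) {
    o <- order(blocks$onset_s)
    ends <- blocks$onset_s[o] + blocks$duration_s[o]
    if (any(blocks$onset_s[o][-1] < ends[-length(ends)] - 1e-9))
      stop("overlapping blocks in schedule")
  }
  conds <- unique(blocks$condition)
  k <- hrf_kernel(hrf, TR)
  tr_edges <- seq(0, by = TR, length.out = n_tr + 1)
  x <- matrix(0, n_tr, length(conds))
  colnames(x) <- conds
  for (ci in seq_along(conds)) {
    box <- numeric(n_tr)
    bl <- blocks[blocks$condition == conds[ci], , drop = FALSE]
    for (b in seq_len(nrow(bl))) {
      on <- bl$onset_s[b]; off <- on + bl$duration_s[b]
      overlap <- pmax(0, pmin(off, tr_edges[-1]) - pmax(on, tr_edges[-(n_tr + 1)]))
      box <- box + overlap / TR
    }
    x[, ci] <- convolve_causal(box, k)
  }
  if (!is.null(noise_regressors)) {
    stopifnot(nrow(noise_regressors) == n_tr)
    nr <- as.matrix(noise_regressors)
    if (is.null(colnames(nr))) colnames(nr) <- paste0("noise", seq_len(ncol(nr)))
    x <- cbind(x, nr)
  }
  x <- cbind(x, intercept = 1)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    drop_n <- ncol(x) - qx$rank
    warning("design rank deficient: dropping ", drop_n, " column(s)")
    keep <- qx$pivot[seq_len(qx$rank)]
    x <- x[, sort(keep), drop = FALSE]
  }
  attr(x, "conditions") <- intersect(conds, colnames(x))
  x
}

#' Ordinary least-squares GLM fit
#'
#' @param series Numeric vector (length T).
#' @param design `T x P` design matrix from [build_design()].
#' @return A `glm_fit` list: `betas`, `sigma2` (residual variance),
#'   `df` (T - rank), `xtx_inv`, `residuals`, `design_cols`.
#' @export
fit_glm <- function(series, design) {
  stopifnot(length(series) == nrow(design))
  qx <- qr(design)
  if (qx$rank < ncol(design))
    stop("design matrix is rank deficient; prune it first")
  betas <- qr.coef(qx, series)
  res <- qr.resid(qx, series)
  df <- length(series) - qx$rank
  sigma2 <- sum(res^2) / df
  structure(list(betas = betas, sigma2 = sigma2, df = df,
                 xtx_inv = chol2inv(qr.R(qx)),
                 residuals = res, design_cols = colnames(design),
                 conditions = attr(design, "conditions")),
            class = "glm_fit")
}

#' Contrast t statistic
#'
#' `t = c'beta / sqrt(sigma2 * c' (X'X)^-1 c)`. A zero standard error
#' is flagged with `NA`.
#'
#' @param fit A `glm_fit`.
#' @param contrast_vec Numeric contrast of length P, or a named vector
#'   whose names match design columns (others zero).
#' @return List with `estimate`, `se`, `t`, `df`.
#' @export
contrast <- function(fit, contrast_vec) {
  p <- length(fit$betas)
  if (!is.null(names(contrast_vec))) {
    cv <- numeric(p)
    names(cv) <- fit$design_cols
    cv[names(contrast_vec)] <- contrast_vec
  } else {
    stopifnot(length(contrast_vec) == p)
    cv <- contrast_vec
  }
  est <- sum(cv * fit$betas)
  v <- fit$sigma2 * drop(t(cv) %*% fit$xtx_inv %*% cv)
  se <- sqrt(max(v, 0))
  t <- if (se == 0) NA_real_ else est / se
  list(estimate = est, se = se, t = t, df = fit$df)
}

#' Visual-activation contrast (all conditions vs implicit baseline)
#'
#' With the baseline modelled implicitly, "conditions > baseline" is
#' the mean of the condition betas against zero.
#'
#' @param fit A `glm_fit` whose design carried a `conditions`
#'   attribute.
#' @return As [contrast()].
#' @export
visual_activation_contrast <- function(fit) {
  conds <- fit$conditions
  if (is.null(conds) || length(conds) == 0)
    stop("fit carries no condition columns")
  cv <- stats::setNames(rep(1 / length(conds), length(conds)), conds)
  contrast(fit, cv)
}
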