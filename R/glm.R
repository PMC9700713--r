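# First-level (within-subject) mass-univariate GLM: trial-wise amplitude at
# every scalp x time voxel regressed on one z-scored learning-trajectory
# regressor.

#' Build a single-regressor trial design matrix
#'
#' One intercept plus one regressor column taken from the HGF trajectories
#' (or the binary tone sequence), restricted to kept trials and z-scored so
#' that first-level slopes are comparable across subjects.
#'
#' @param trajectories a `trajectory_set` (or NULL for the `"tone"` regressor).
#' @param regressor regressor name (see [effect_spec()]).
#' @param kept logical/integer index of kept trials.
#' @param tones optional `tone_sequence` (for `"tone"`).
#' @param standardise z-score the regressor over kept trials (default TRUE).
#' @return object of class `trial_design`: list with `X` (n x 2 matrix),
#'   `regressor`, `trials`.
#' @export
trial_design <- function(trajectories, regressor, kept, tones = NULL,
                         standardise = TRUE) {
  r <- regressor_values(regressor, trajectories, tones)
  idx <- if (is.logical(kept)) which(kept) else as.integer(kept)
  r <- r[idx]
  if (stats::sd(r) == 0)
    stop(sprintf("regressor '%s' has zero variance over kept trials", regressor),
         call. = FALSE)
  if (standardise) r <- (r - mean(r)) / stats::sd(r)
  X <- cbind(intercept = 1, slope = r)
  structure(list(X = X, regressor = regressor, trials = idx),
            class = "trial_design")
}

#' Fit the first-level GLM at every voxel
#'
#' Ordinary least squares of trial amplitude on `[1, regressor]` at each
#' masked voxel and time bin: slope estimate, residual variance, and
#' degrees of freedom `n - 2`.
#'
#' @param sts a `scalp_time_set` of per-trial volumes (rows must align with
#'   `design$trials`).
#' @param design a [trial_design()].
#' @return object of class `beta_map`: list with `beta` (slope per masked
#'   voxel-time), `se`, `sigma2` (residual variance), `df`, `regressor`,
#'   `mask`, `grid`, `n_times`, `n_voxels`.
#' @export
first_level_fit <- function(sts, design) {
  stopifnot(inherits(sts, "scalp_time_set"), inherits(design, "trial_design"))
  X <- design$X
  n <- nrow(X)
  if (n < 10) stop("need at least 10 kept trials", call. = FALSE)
  if (ncol(sts$data) != n)
    stop("design and trial volumes are misaligned", call. = FALSE)
  XtXi <- solve(crossprod(X))
  XtY <- sts$data %*% X                       # voxels x 2  (= t(X'Y))
  B <- tcrossprod(XtXi, XtY)                  # 2 x voxels
  # rss = y'y - b' X'y, avoiding the full fitted-value matrix
  rss <- rowSums(sts$data^2) - rowSums((XtY %*% XtXi) * XtY)
  rss[rss < 0] <- 0
  df <- n - 2L
  sigma2 <- rss / df
  se <- sqrt(sigma2 * XtXi[2, 2])
  structure(list(beta = as.numeric(B[2, ]), intercept = as.numeric(B[1, ]),
                 se = se, sigma2 = sigma2, df = df,
                 regressor = design$regressor, mask = sts$mask,
                 grid = sts$grid, n_times = sts$n_times,
                 n_voxels = sts$n_voxels),
            class = "beta_map")
}

#' Full first-level pass for one subject
#'
#' Convenience wrapper: project kept epochs to the grid, smooth, and fit one
#' GLM per requested regressor.
#'
#' @param epochs a cleaned `epoch_set`.
#' @param trajectories the subject's `trajectory_set`.
#' @param regressors character vector of regressor names.
#' @param grid a [grid_spec()].
#' @param fwhm spatial smoothing FWHM, mm.
#' @param projector,smoother optional precomputed operators.
#' @param tones optional `tone_sequence` for the `"tone"` regressor.
#' @return named list of `beta_map` objects.
#' @export
subject_first_level <- function(epochs, trajectories, regressors, grid,
                                fwhm = c(16, 16), projector = NULL,
                                smoother = NULL, tones = NULL) {
  sts <- project_to_grid(epochs, grid, projector)
  sts <- smooth_volumes(sts, fwhm, smoother)
  out <- lapply(regressors, function(rg) {
    d <- trial_design(trajectories, rg, sts$trials, tones)
    first_level_fit(sts, d)
  })
  stats::setNames(out, regressors)
}
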