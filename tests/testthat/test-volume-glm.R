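# Scalp x time projection, smoothing, and the first-level GLM.

test_that("projection reproduces constants and channel values", {
  m <- montage_1020()
  m$bad <- FALSE
  g <- grid_spec(m)
  pr <- build_projector(m, g)
  expect_true(sum(pr$mask) > 0)
  # constant field -> constant everywhere inside the hull
  const <- pr$P %*% rep(3.7, ncol(pr$P))
  expect_equal(as.numeric(const), rep(3.7, nrow(pr$P)), tolerance = 1e-8)
  # values at (grid nodes nearest to) channel locations: evaluate the
  # interpolant exactly at channel positions via a grid that contains them
  sc <- m[m$role == "scalp", ]
  for (ch in c("Cz", "F3", "P8")) {
    i <- which(sc$name == ch)
    gi <- interp::interp(sc$x, sc$y, z = as.numeric(seq_len(nrow(sc)) == i),
                         xo = sc$x[i], yo = sc$y[i], method = "linear",
                         output = "points")
    expect_equal(gi$z, 1, tolerance = 1e-6)
  }
  # locality: single nonzero channel peaks at its own location
  z <- as.numeric(sc$name == "Cz")
  v <- pr$P %*% z
  arr <- matrix(0, g$nx, g$ny)
  arr[pr$mask] <- v
  pk <- which(arr == max(arr), arr.ind = TRUE)[1, ]
  czx <- sc$x[sc$name == "Cz"]; czy <- sc$y[sc$name == "Cz"]
  expect_lt(abs(g$xs[pk[1]] - czx), 2 * g$voxel[1])
  expect_lt(abs(g$ys[pk[2]] - czy), 2 * g$voxel[2])
  # degenerate montage
  bad <- data.frame(name = letters[1:5], x = 1:5, y = 2 * (1:5) + 1,
                    role = "scalp", bad = FALSE)
  expect_error(build_projector(bad, g), "collinear")
})

test_that("smoothing preserves constants, masked means, and kernel width", {
  m <- montage_1020()
  g <- grid_spec(m)
  pr <- build_projector(m, g)
  S <- build_smoother(g, pr$mask, fwhm = c(16, 16))
  nv <- nrow(S)
  expect_equal(as.numeric(S %*% rep(2.5, nv)), rep(2.5, nv), tolerance = 1e-10)

  sts <- structure(list(data = matrix(rnorm(nv * 3), nv * 1, 3) , mask = pr$mask,
                        grid = g, trials = 1:3, n_voxels = nv, n_times = 1),
                   class = "scalp_time_set")
  sm <- smooth_volumes(sts, smoother = S)
  for (i in 1:3)
    expect_equal(mean(sm$data[, i]), mean(sts$data[, i]), tolerance = 1e-9)

  # impulse response width: fit on an interior voxel, away from mask edges
  midx <- which(pr$mask, arr.ind = TRUE)
  ctr <- midx[which.min((g$xs[midx[, 1]] - mean(g$xs))^2 +
                        (g$ys[midx[, 2]] - mean(g$ys))^2), ]
  imp <- numeric(nv)
  lin <- which(pr$mask)
  imp[lin == ((ctr[2] - 1) * g$nx + ctr[1])] <- 1
  resp <- as.numeric(S %*% imp)
  arr <- matrix(NA_real_, g$nx, g$ny)
  arr[pr$mask] <- resp
  # profile along x through the impulse; fitted Gaussian FWHM ~ 16 mm
  prof <- arr[, ctr[2]]
  xs <- g$xs
  ok <- !is.na(prof) & prof > max(prof, na.rm = TRUE) * 1e-6
  fit <- lm(log(prof[ok]) ~ xs[ok] + I(xs[ok]^2))
  sigma <- sqrt(-1 / (2 * unname(coef(fit)[3])))
  expect_equal(sigma * 2 * sqrt(2 * log(2)), 16, tolerance = 0.05)
})

test_that("first-level OLS matches the normal-equations oracle", {
  set.seed(101)
  n <- 200; nvox <- 300
  X <- cbind(1, rnorm(n))
  Y <- matrix(rnorm(n * nvox), n, nvox)
  g <- small_grid()
  sts <- structure(list(data = t(Y), mask = matrix(TRUE, 1, 1), grid = g,
                        trials = 1:n, n_voxels = nvox, n_times = 1),
                   class = "scalp_time_set")
  des <- structure(list(X = X, regressor = "eps2", trials = 1:n),
                   class = "trial_design")
  bm <- first_level_fit(sts, des)
  Bo <- solve(t(X) %*% X) %*% t(X) %*% Y
  resid <- Y - X %*% Bo
  s2o <- colSums(resid^2) / (n - 2)
  expect_equal(bm$beta, as.numeric(Bo[2, ]), tolerance = 1e-8)
  expect_equal(bm$intercept, as.numeric(Bo[1, ]), tolerance = 1e-8)
  expect_equal(as.numeric(bm$sigma2), s2o, tolerance = 1e-8)
  expect_equal(bm$df, n - 2)
})

test_that("planted slope is recovered within 3 standard errors", {
  spec <- small_paradigm(n_trials = 1000)
  tones <- gen_tone_sequence(spec, 55)
  traj <- hgf_filter(tones)
  eff <- list(effect_spec("eps2", c("Fz", "FC1", "FC2", "Cz"), c(100, 228), 5))
  nz <- noise_spec(trial_sd = 1, ar1 = 0.3, blink_rate = 0, drift_sd = 0)
  ep <- gen_subject_eeg(tones, traj, eff, nz, spec, seed = 56)
  g <- small_grid()
  bm <- local({
    pr <- build_projector(ep$channels, g)
    sts <- smooth_volumes(project_to_grid(ep, g, pr),
                          smoother = build_smoother(g, pr$mask))
    first_level_fit(sts, trial_design(traj, "eps2", sts$trials))
  })
  # at the voxel nearest Fz inside the planted window the slope should be
  # near 5 (slightly shrunk by smoothing against unplanted neighbours)
  i <- which.max(bm$beta)
  expect_lt(abs(bm$beta[i] - 5), max(3 * bm$se[i], 0.8))
  expect_gt(bm$beta[i] / bm$se[i], 10)
})

test_that("zero-variance regressor and misalignment raise design errors", {
  traj <- hgf_filter(gen_tone_sequence(small_paradigm(50), 1))
  tones0 <- structure(list(u = rep(0L, 50)), class = "tone_sequence")
  expect_error(trial_design(NULL, "tone", rep(TRUE, 50), tones0), "variance")
  g <- small_grid()
  sts <- structure(list(data = matrix(0, 5, 40), mask = matrix(TRUE, 1, 1),
                        grid = g, trials = 1:40, n_voxels = 5, n_times = 1),
                   class = "scalp_time_set")
  expect_error(first_level_fit(sts, trial_design(traj, "eps2", 1:50)),
               "misaligned")
  sts$data <- matrix(0, 5, 5); sts$trials <- 1:5
  expect_error(first_level_fit(sts, trial_design(traj, "eps2", 1:5)), "10")
})

test_that("affine equivariance of the first-level fit", {
  set.seed(7)
  n <- 60; nvox <- 50
  X <- cbind(1, rnorm(n))
  Y <- matrix(rnorm(n * nvox), n, nvox)
  g <- small_grid()
  mk <- function(Y) structure(list(data = t(Y), mask = matrix(TRUE, 1, 1),
                                   grid = g, trials = 1:n, n_voxels = nvox,
                                   n_times = 1), class = "scalp_time_set")
  des <- structure(list(X = X, regressor = "eps2", trials = 1:n),
                   class = "trial_design")
  b0 <- first_level_fit(mk(Y), des)
  b_scaled <- first_level_fit(mk(3 * Y), des)
  expect_equal(b_scaled$beta, 3 * b0$beta, tolerance = 1e-10)
  b_shift <- first_level_fit(mk(Y + 7), des)
  expect_equal(b_shift$beta, b0$beta, tolerance = 1e-8)
  expect_equal(b_shift$intercept, b0$intercept + 7, tolerance = 1e-8)
})

test_that("projection and smoothing commute with trial averaging", {
  spec <- small_paradigm(n_trials = 30)
  tones <- gen_tone_sequence(spec, 5)
  ep <- gen_subject_eeg(tones, NULL, list(), noise_spec(blink_rate = 0),
                        spec, seed = 2)
  g <- small_grid()
  pr <- build_projector(ep$channels, g)
  S <- build_smoother(g, pr$mask)
  sts <- smooth_volumes(project_to_grid(ep, g, pr), smoother = S)
  mean_of_proc <- rowMeans(sts$data)
  ep_mean <- ep
  ep_mean$data <- array(rep(apply(ep$data, c(2, 3), mean), each = 1),
                        dim = c(1, dim(ep$data)[2], dim(ep$data)[3]))
  ep_mean$kept <- TRUE; ep_mean$reject_reason <- "none"; ep_mean$tone <- 0L
  sts_m <- smooth_volumes(project_to_grid(ep_mean, g, pr, trials = 1),
                          smoother = S)
  expect_equal(mean_of_proc, as.numeric(sts_m$data), tolerance = 1e-8)
})

test_that("rejected trials have no influence on betas", {
  spec <- small_paradigm(n_trials = 120)
  tones <- gen_tone_sequence(spec, 6)
  traj <- hgf_filter(tones)
  ep <- gen_subject_eeg(tones, traj, list(), noise_spec(blink_rate = 0),
                        spec, seed = 3)
  ep$kept[1:20] <- FALSE
  ep$reject_reason[1:20] <- "amplitude"
  g <- small_grid()
  pr <- build_projector(ep$channels, g)
  S <- build_smoother(g, pr$mask)
  sts <- smooth_volumes(project_to_grid(ep, g, pr), smoother = S)
  b1 <- first_level_fit(sts, trial_design(traj, "eps2", sts$trials))
  # physically delete the rejected trials and refit
  ep2 <- ep
  keep <- which(ep$kept)
  ep2$data <- ep$data[keep, , , drop = FALSE]
  ep2$tone <- ep$tone[keep]
  ep2$kept <- rep(TRUE, length(keep))
  ep2$reject_reason <- rep("none", length(keep))
  traj2 <- lapply(unclass(traj), function(v) v[keep])
  class(traj2) <- "trajectory_set"
  sts2 <- smooth_volumes(project_to_grid(ep2, g, pr), smoother = S)
  b2 <- first_level_fit(sts2, trial_design(traj2, "eps2", sts2$trials))
  expect_equal(b1$beta, b2$beta, tolerance = 1e-8)
})

test_that("volumes unmask and round-trip to NIfTI", {
  m <- montage_1020()
  g <- small_grid(m)
  pr <- build_projector(m, g)
  nv <- sum(pr$mask)
  vals <- rnorm(nv * 3)
  arr <- unmask_volume(vals, list(mask = pr$mask, grid = g))
  expect_equal(dim(arr), c(g$nx, g$ny, 3))
  expect_equal(sum(!is.na(arr)), nv * 3)
  f <- tempfile(fileext = ".nii")
  write_volume_nifti(arr, g, f)
  back <- RNifti::readNifti(f)
  expect_equal(dim(back), dim(arr))
  av <- arr; av[is.na(av)] <- 0
  expect_equal(as.numeric(back), as.numeric(av), tolerance = 1e-6)
})
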