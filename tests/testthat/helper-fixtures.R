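# Shared fixtures: small paradigms, reduced analysis grids, and handmade
# epoch sets, all built in code at test time.

small_paradigm <- function(n_trials = 200, ...) {
  paradigm_spec(n_trials = n_trials, ...)
}

# reduced analysis grid covering the whole scalp with coarser voxels
small_grid <- function(montage = montage_1020(), nx = 12, ny = 12,
                       voxel = c(12, 15, 4), time_window = c(100, 400)) {
  grid_spec(montage, nx = nx, ny = ny, voxel = voxel,
            time_window = time_window)
}

# hand-built epoch set: trials x channels x samples filled with `fill`,
# standard montage, 500 Hz, -100..400 ms window
make_epochs <- function(n_trials = 10, fill = 0, srate = 500,
                        window = c(-100, 400), tone = NULL,
                        montage = montage_1020()) {
  times <- seq(window[1], window[2], by = 1000 / srate)
  n_ch <- nrow(montage)
  chan <- montage
  chan$bad <- FALSE
  if (is.null(tone)) tone <- rep(c(0, 0, 0, 0, 1), length.out = n_trials)
  structure(list(
    data = array(fill, dim = c(n_trials, n_ch, length(times))),
    times = times, channels = chan, srate = srate, tone = tone,
    kept = rep(TRUE, n_trials),
    reject_reason = rep("none", n_trials),
    blink_trials = integer(0)),
    class = "epoch_set")
}

# fake per-subject beta map on a given grid (for group-level tests)
fake_beta_map <- function(values, grid, mask, regressor = "eps2", df = 100) {
  nv <- sum(mask)
  nt <- length(values) / nv
  structure(list(beta = values, intercept = rep(0, length(values)),
                 se = rep(1, length(values)), sigma2 = rep(1, length(values)),
                 df = df, regressor = regressor, mask = mask, grid = grid,
                 n_times = nt, n_voxels = nv),
            class = "beta_map")
}

# full-mask rectangular grid for distribution-level tests
rect_grid_mask <- function(nx = 8, ny = 8, nt = 30) {
  g <- structure(list(nx = nx, ny = ny, voxel = c(10, 10, 10),
                      xs = seq_len(nx) * 10, ys = seq_len(ny) * 10,
                      ts = 100 + (seq_len(nt) - 1) * 10,
                      time_window = c(100, 100 + (nt - 1) * 10)),
                 class = "grid_spec")
  list(grid = g, mask = matrix(TRUE, nx, ny), nt = nt)
}

# quick subject simulation through first level on a reduced grid
simulate_subject_betas <- function(seed, spec, grid, effects, noise,
                                   regressor = "eps2", subject_scale = 1,
                                   projector = NULL, smoother = NULL,
                                   params = hgf_params()) {
  tones <- gen_tone_sequence(spec, seed)
  traj <- hgf_filter(tones, params)
  ep <- gen_subject_eeg(tones, traj, effects, noise, spec,
                        subject_scale = subject_scale, seed = seed + 1)
  if (is.null(projector)) projector <- build_projector(ep$channels, grid)
  if (is.null(smoother)) smoother <- build_smoother(grid, projector$mask)
  sts <- project_to_grid(ep, grid, projector)
  sts <- smooth_volumes(sts, smoother = smoother)
  d <- trial_design(traj, regressor, sts$trials, tones)
  first_level_fit(sts, d)
}
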