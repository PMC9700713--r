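# Scalp x time volumes: projection of channel amplitudes onto a 2D scalp
# lattice, spatial Gaussian smoothing inside the scalp mask, and NIfTI export.

#' Scalp-by-time grid specification
#'
#' Defines the (x, y, t) lattice used for sensor-space statistical maps. The
#' default spatial voxel is 4.25 mm x 5.38 mm on a 32 x 32 grid centred on
#' the montage, with 2 ms time bins over the 100-400 ms analysis window.
#'
#' @param montage channel layout (scalp channels give the grid centre/extent).
#' @param nx,ny number of voxels along the left-right and
#'   posterior-anterior axes.
#' @param voxel c(dx, dy, dt): mm, mm, ms.
#' @param time_window analysis window, ms (default c(100, 400)).
#' @return object of class `grid_spec` with voxel-centre coordinates `xs`,
#'   `ys`, `ts`.
#' @export
grid_spec <- function(montage, nx = 32, ny = 32, voxel = c(4.25, 5.38, 2),
                      time_window = c(100, 400)) {
  sc <- montage[montage$role == "scalp", ]
  cx <- mean(range(sc$x)); cy <- mean(range(sc$y))
  xs <- cx + (seq_len(nx) - (nx + 1) / 2) * voxel[1]
  ys <- cy + (seq_len(ny) - (ny + 1) / 2) * voxel[2]
  ts <- seq(time_window[1], time_window[2], by = voxel[3])
  structure(list(nx = nx, ny = ny, voxel = voxel, xs = xs, ys = ys, ts = ts,
                 time_window = time_window),
            class = "grid_spec")
}

#' Build the channel-to-grid linear projector
#'
#' Piecewise-linear (Delaunay) interpolation of scattered channel positions
#' onto the grid is a linear map of the channel values; this precomputes the
#' corresponding (n_voxels x n_channels) matrix by interpolating each
#' channel's indicator, plus the in-hull scalp mask.
#'
#' @param channels montage data.frame (only good scalp channels are used).
#' @param grid a [grid_spec()].
#' @return list with `P` (matrix, masked voxels x channels), `mask`
#'   (nx x ny logical), `channel_names`.
#' @export
build_projector <- function(channels, grid) {
  bad <- channels$bad %||% rep(FALSE, nrow(channels))
  sc <- channels[channels$role == "scalp" & !bad, ]
  if (nrow(sc) < 4) stop("need at least 4 good scalp channels", call. = FALSE)
  if (qr(cbind(1, sc$x, sc$y))$rank < 3)
    stop("degenerate montage: channel positions are collinear", call. = FALSE)
  n_ch <- nrow(sc)
  cols <- vector("list", n_ch)
  mask <- NULL
  for (i in seq_len(n_ch)) {
    z <- numeric(n_ch); z[i] <- 1
    g <- interp::interp(x = sc$x, y = sc$y, z = z, xo = grid$xs, yo = grid$ys,
                        method = "linear", output = "grid", extrap = FALSE)
    if (is.null(mask)) mask <- !is.na(g$z)
    zi <- g$z; zi[is.na(zi)] <- 0
    cols[[i]] <- as.numeric(zi)
  }
  P <- do.call(cbind, cols)          # (nx*ny) x n_ch
  P <- P[as.numeric(mask) > 0, , drop = FALSE]
  list(P = P, mask = mask, channel_names = sc$name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Project epochs onto the scalp-by-time grid
#'
#' For each kept trial, channel amplitudes at every time bin inside the
#' analysis window are linearly interpolated onto the 2D scalp grid;
#' out-of-hull voxels are masked. Returns the per-trial volumes flattened
#' over masked voxels for efficient GLM fitting.
#'
#' @param epochs an `epoch_set` (bad channels must already be interpolated).
#' @param grid a [grid_spec()].
#' @param projector optional precomputed [build_projector()] result.
#' @param trials which trials to project (default: kept trials).
#' @return object of class `scalp_time_set`: list with `data`
#'   ((masked voxels * time bins) x trials matrix, voxel-major), `mask`,
#'   `grid`, `trials`, `n_voxels` (masked spatial voxels), `n_times`.
#' @export
project_to_grid <- function(epochs, grid, projector = NULL,
                            trials = which(epochs$kept)) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(grid, "grid_spec"))
  if (is.null(projector)) projector <- build_projector(epochs$channels, grid)
  sc_idx <- match(projector$channel_names, epochs$channels$name)
  t_idx <- vapply(grid$ts, function(t) which.min(abs(epochs$times - t)), 0L)
  if (max(abs(epochs$times[t_idx] - grid$ts)) > grid$voxel[3] / 2 + 1e-9)
    warning("grid time bins do not align with epoch samples; nearest used")
  n_vox <- nrow(projector$P)
  n_t <- length(t_idx)
  # one multiply for all trials: channels x (times, trials)
  C <- epochs$data[trials, sc_idx, t_idx, drop = FALSE]  # trials x ch x t
  C <- aperm(C, c(2, 3, 1))
  dim(C) <- c(length(sc_idx), n_t * length(trials))
  out <- projector$P %*% C                               # vox x (t, trial)
  dim(out) <- c(n_vox * n_t, length(trials))
  structure(list(data = out, mask = projector$mask, grid = grid,
                 trials = trials, n_voxels = n_vox, n_times = n_t),
            class = "scalp_time_set")
}

# 1-D Gaussian kernel, FWHM in voxel units
gauss_kernel <- function(fwhm_vox) {
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

#' Build the spatial smoothing operator on the masked grid
#'
#' Separable Gaussian smoothing (FWHM in mm per spatial axis, no smoothing
#' along time), renormalised inside the scalp mask so the kernel weights of
#' out-of-mask voxels are redistributed. Returned as a masked-voxel x
#' masked-voxel matrix so smoothing a trial is one multiply.
#'
#' @param grid a [grid_spec()].
#' @param mask nx x ny logical scalp mask.
#' @param fwhm c(fwhm_x, fwhm_y), mm (default c(16, 16)).
#' @return smoothing matrix S (rows sum to 1 over the mask).
#' @export
build_smoother <- function(grid, mask, fwhm = c(16, 16)) {
  kx <- gauss_kernel(fwhm[1] / grid$voxel[1])
  ky <- gauss_kernel(fwhm[2] / grid$voxel[2])
  nx <- grid$nx; ny <- grid$ny
  # dense separable operator restricted to the mask
  Kx <- matrix(0, nx, nx)
  rx <- (length(kx) - 1) / 2
  for (i in seq_len(nx)) {
    j <- (i - rx):(i + rx)
    ok <- j >= 1 & j <= nx
    Kx[i, j[ok]] <- kx[ok]
  }
  Ky <- matrix(0, ny, ny)
  ry <- (length(ky) - 1) / 2
  for (i in seq_len(ny)) {
    j <- (i - ry):(i + ry)
    ok <- j >= 1 & j <= ny
    Ky[i, j[ok]] <- ky[ok]
  }
  # full 2D operator via Kronecker structure on (x fastest) vectorised grid
  S_full <- kronecker(Ky, Kx)
  midx <- which(as.logical(mask))
  S <- S_full[midx, midx, drop = FALSE]
  rs <- rowSums(S)
  S / rs
}

#' Smooth a projected trial set spatially
#'
#' Applies the mask-renormalised Gaussian smoother to every trial and time
#' bin; an additive correction restores each volume's masked mean exactly.
#'
#' @param sts a `scalp_time_set` from [project_to_grid()].
#' @param fwhm c(fwhm_x, fwhm_y) mm (default c(16, 16)).
#' @param smoother optional precomputed [build_smoother()] matrix.
#' @return smoothed `scalp_time_set`.
#' @export
smooth_volumes <- function(sts, fwhm = c(16, 16), smoother = NULL) {
  stopifnot(inherits(sts, "scalp_time_set"))
  if (is.null(smoother)) smoother <- build_smoother(sts$grid, sts$mask, fwhm)
  nv <- sts$n_voxels; nt <- sts$n_times
  n_tr <- ncol(sts$data)
  M <- sts$data
  dim(M) <- c(nv, nt * n_tr)                  # columns are (time, trial) pairs
  SV <- smoother %*% M
  SV <- SV - rep(colMeans(SV) - colMeans(M), each = nv)  # restore masked mean
  dim(SV) <- c(nv * nt, n_tr)
  sts$data <- SV
  sts
}

#' Reshape a masked statistic vector to the full (x, y, t) array
#'
#' @param values masked-voxel-major vector (voxels x times).
#' @param sts_or_mask a `scalp_time_set`, or a list with `mask` and `grid`.
#' @param fill value for out-of-mask voxels (default NA).
#' @return nx x ny x nt array.
#' @export
unmask_volume <- function(values, sts_or_mask, fill = NA_real_) {
  mask <- sts_or_mask$mask
  grid <- sts_or_mask$grid
  nt <- length(values) / sum(mask)
  arr <- array(fill, dim = c(grid$nx, grid$ny, nt))
  midx <- which(as.logical(mask))
  m <- matrix(values, sum(mask), nt)
  for (k in seq_len(nt)) {
    slice <- array(fill, dim = c(grid$nx, grid$ny))
    slice[midx] <- m[, k]
    arr[, , k] <- slice
  }
  arr
}

#' Export a scalp-by-time array as NIfTI
#'
#' Writes the (x, y, t) lattice as a 3-D NIfTI image with the voxel sizes in
#' the header (mm, mm, ms), for interoperability with neuroimaging viewers.
#' Requires the RNifti package.
#'
#' @param arr nx x ny x nt array (e.g. from [unmask_volume()]).
#' @param grid the [grid_spec()].
#' @param path output `.nii` path.
#' @export
write_volume_nifti <- function(arr, grid, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI export", call. = FALSE)
  arr[is.na(arr)] <- 0
  img <- RNifti::asNifti(arr, pixdim = grid$voxel)
  RNifti::writeNifti(img, path)
  invisible(path)
}
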