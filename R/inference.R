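# Random-effects group inference on first-level beta maps: one-sample and
# two-sample F maps, ANCOVA against clinical covariates, permutation-based
# family-wise error control at peak and cluster level, effect sizes, and
# figure-level ERP summaries.

stack_betas <- function(betas) {
  B <- do.call(rbind, lapply(betas, function(b) b$beta))
  ref <- betas[[1]]
  list(B = B, mask = ref$mask, grid = ref$grid,
       n_voxels = ref$n_voxels, n_times = ref$n_times,
       regressor = ref$regressor)
}

new_stat_map <- function(stat, df, type, contrast, perm, meta, provenance = NULL) {
  structure(list(stat = stat, df = df, type = type, contrast = contrast,
                 perm = perm, mask = meta$mask, grid = meta$grid,
                 n_voxels = meta$n_voxels, n_times = meta$n_times,
                 regressor = meta$regressor, provenance = provenance),
            class = "stat_map")
}

#' One-sample random-effects F map
#'
#' At each voxel, t = mean(beta) / SE(beta) across subjects and F = t^2 with
#' df (1, n - 1): the test that the group-mean regression slope is zero.
#' Voxels with zero between-subject variance receive a `+Inf` sentinel
#' (counted in the returned map's `provenance$n_infinite`).
#'
#' @param betas list of `beta_map` objects (one per subject, same grid).
#' @return object of class `stat_map` (permutation scheme: sign flipping).
#' @export
one_sample_F <- function(betas) {
  if (length(betas) < 3) stop("need at least 3 subjects", call. = FALSE)
  s <- stack_betas(betas)
  n <- nrow(s$B)
  m <- colMeans(s$B)
  v <- (colSums(s$B^2) - n * m^2) / (n - 1)
  Fv <- ifelse(v > 0, n * m^2 / v, ifelse(m == 0, 0, Inf))
  n_inf <- sum(is.infinite(Fv))
  new_stat_map(Fv, c(1, n - 1), "F", sprintf("mean(%s) = 0", s$regressor),
               list(scheme = "sign_flip", B = s$B), s,
               provenance = list(n_subjects = n, n_infinite = n_inf))
}

#' Two-sample group-difference map
#'
#' Unpaired pooled-variance two-sample t at each voxel, returned as F = t^2
#' with df (1, nA + nB - 2). Group sizes may differ. (The source analysis
#' protocol describes a "paired t-test", which is not computable for unequal
#' group sizes; the unpaired test is used and the wording is recorded in the
#' map's provenance.)
#'
#' @param betas_a,betas_b lists of `beta_map` objects for the two groups.
#' @return `stat_map` with the signed t map in `$t` (permutation scheme:
#'   group-label permutation).
#' @export
group_difference <- function(betas_a, betas_b) {
  if (length(betas_a) < 2 || length(betas_b) < 2)
    stop("each group needs at least 2 subjects", call. = FALSE)
  sa <- stack_betas(betas_a); sb <- stack_betas(betas_b)
  na <- nrow(sa$B); nb <- nrow(sb$B)
  ma <- colMeans(sa$B); mb <- colMeans(sb$B)
  ssa <- colSums(sa$B^2) - na * ma^2
  ssb <- colSums(sb$B^2) - nb * mb^2
  sp2 <- (ssa + ssb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tv <- ifelse(se > 0, (ma - mb) / se, ifelse(ma == mb, 0, Inf))
  map <- new_stat_map(tv^2, c(1, na + nb - 2), "F",
                      sprintf("group difference in %s", sa$regressor),
                      list(scheme = "two_sample",
                           B = rbind(sa$B, sb$B), n_a = na),
                      sa,
                      provenance = list(
                        test = "unpaired pooled-variance two-sample t",
                        protocol_wording = "paired t-test",
                        n = c(na, nb)))
  map$t <- tv
  map
}

#' ANCOVA map against a clinical covariate
#'
#' At each voxel, fits `beta ~ intercept + covariate (+ nuisance)` across
#' subjects and returns the F test (df 1, n - p) on the covariate slope,
#' e.g. first-level pwPE effects against SIPS positive-subscale totals.
#'
#' @param betas list of `beta_map` objects, aligned with `design` rows.
#' @param design data.frame of per-subject covariates (complete cases only).
#' @param covariate name of the column of interest.
#' @param nuisance character vector of additional adjustment columns.
#' @return `stat_map` with the signed covariate slope in `$slope` and t in
#'   `$t` (permutation scheme: Freedman-Lane residual permutation).
#' @export
ancova_map <- function(betas, design, covariate, nuisance = character(0)) {
  s <- stack_betas(betas)
  n <- nrow(s$B)
  if (nrow(design) != n) stop("design rows must align with subjects", call. = FALSE)
  cols <- c(covariate, nuisance)
  if (any(!cols %in% names(design)))
    stop("missing design columns: ", paste(setdiff(cols, names(design)), collapse = ", "),
         call. = FALSE)
  if (anyNA(design[, cols])) stop("design contains missing values; supply complete cases",
                                  call. = FALSE)
  x <- as.numeric(design[[covariate]])
  if (stats::sd(x) == 0) stop("covariate has zero variance", call. = FALSE)
  Z <- cbind(intercept = rep(1, n))
  for (nu in nuisance) {
    v <- design[[nu]]
    if (!is.numeric(v)) v <- as.numeric(factor(v))
    Z <- cbind(Z, v)
    colnames(Z)[ncol(Z)] <- nu
  }
  X <- cbind(Z, covariate = x)
  if (qr(X)$rank < ncol(X))
    stop("collinear design (columns: ", paste(colnames(X), collapse = ", "), ")",
         call. = FALSE)
  fit <- glm_f_stats(X, s$B, ncol(X))
  map <- new_stat_map(fit$F, c(1, n - ncol(X)), "F",
                      sprintf("%s slope on %s", covariate, s$regressor),
                      list(scheme = "freedman_lane", Y = s$B, X = X,
                           Z = Z, coef_index = ncol(X)),
                      s,
                      provenance = list(covariate = covariate,
                                        nuisance = nuisance, n = n))
  map$slope <- fit$b
  map$t <- fit$t
  map
}

# vectorised per-voxel OLS F statistic for one coefficient
glm_f_stats <- function(X, Y, j) {
  n <- nrow(X); p <- ncol(X)
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)
  rss <- colSums((Y - X %*% B)^2)
  sigma2 <- rss / (n - p)
  se <- sqrt(sigma2 * XtXi[j, j])
  tv <- ifelse(se > 0, B[j, ] / se, ifelse(B[j, ] == 0, 0, Inf))
  list(b = as.numeric(B[j, ]), t = as.numeric(tv), F = as.numeric(tv^2))
}

perm_stat <- function(map, idx_or_signs) {
  pm <- map$perm
  if (pm$scheme == "sign_flip") {
    B <- pm$B; n <- nrow(B)
    m <- as.numeric(crossprod(idx_or_signs, B)) / n
    v <- (colSums(B^2) - n * m^2) / (n - 1)
    ifelse(v > 0, n * m^2 / v, ifelse(m == 0, 0, Inf))
  } else if (pm$scheme == "two_sample") {
    B <- pm$B; n <- nrow(B); na <- pm$n_a; nb <- n - na
    ia <- idx_or_signs[seq_len(na)]
    Ba <- B[ia, , drop = FALSE]; Bb <- B[-ia, , drop = FALSE]
    ma <- colMeans(Ba); mb <- colMeans(Bb)
    sp2 <- (colSums(Ba^2) - na * ma^2 + colSums(Bb^2) - nb * mb^2) / (n - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    ifelse(se > 0, ((ma - mb) / se)^2, 0)
  } else if (pm$scheme == "freedman_lane") {
    # permute reduced-model residuals, add back nuisance fit, refit full model
    Z <- pm$Z; Y <- pm$Y
    Hz <- Z %*% solve(crossprod(Z)) %*% t(Z)
    Yr <- Y - Hz %*% Y
    Ystar <- Hz %*% Y + Yr[idx_or_signs, , drop = FALSE]
    glm_f_stats(pm$X, Ystar, pm$coef_index)$F
  } else stop("unknown permutation scheme", call. = FALSE)
}

#' Permutation-based cluster and peak inference on a statistic map
#'
#' Thresholds the F map at the value whose upper-tail probability is `cdt_p`
#' (cluster-defining threshold), labels face-connected suprathreshold
#' components on the (x, y, t) lattice, and compares each cluster's extent
#' and peak statistic with max-statistic permutation null distributions:
#' sign flipping for one-sample maps, group-label permutation for two-sample
#' maps, and Freedman-Lane residual permutation for ANCOVA maps. Family-wise
#' error corrected p-values are `(1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param map a `stat_map`.
#' @param cdt_p cluster-defining threshold, uncorrected p (default 0.001).
#' @param alpha significance level recorded against each cluster
#'   (default 0.05).
#' @param n_perm number of permutations (default 1000; < 100 warns).
#' @param seed RNG seed (permutations deterministic given seed).
#' @param connectivity 6 (faces, default), 18, or 26.
#' @return data.frame of class `cluster_result`: one row per suprathreshold
#'   cluster with `cluster`, `extent`, `peak_stat`, `peak_x`, `peak_y`
#'   (mm), `peak_ms`, `t_start_ms`, `t_end_ms`, `p_cluster_fwe`,
#'   `p_peak_fwe`, `significant` (cluster- or peak-level at `alpha`).
#'   Zero rows when nothing survives the threshold (a valid outcome).
#' @export
cluster_inference <- function(map, cdt_p = 0.001, alpha = 0.05,
                              n_perm = 1000, seed = 1, connectivity = 6) {
  stopifnot(inherits(map, "stat_map"))
  if (n_perm < 100) warning("n_perm < 100 gives coarse FWE p-values")
  thr <- stats::qf(1 - cdt_p, map$df[1], map$df[2])
  grid <- map$grid
  dims <- c(grid$nx, grid$ny, map$n_times)

  full <- function(statvec) {
    arr <- array(0, dim = dims)
    midx <- which(as.logical(map$mask))
    m <- matrix(statvec, map$n_voxels, map$n_times)
    off <- (seq_len(map$n_times) - 1L) * (grid$nx * grid$ny)
    for (k in seq_len(map$n_times)) arr[midx + off[k]] <- m[, k]
    arr
  }

  obs <- full(map$stat)
  supra <- !is.nan(obs) & obs > thr
  labels <- .label_components_3d(as.logical(supra), dims, connectivity)
  n_cl <- max(labels)

  empty <- data.frame(cluster = integer(0), extent = integer(0),
                      peak_stat = numeric(0), peak_x = numeric(0),
                      peak_y = numeric(0), peak_ms = numeric(0),
                      t_start_ms = numeric(0), t_end_ms = numeric(0),
                      p_cluster_fwe = numeric(0), p_peak_fwe = numeric(0),
                      significant = logical(0))
  class(empty) <- c("cluster_result", "data.frame")
  if (n_cl == 0) return(empty)

  # permutation null of max extent / max peak
  null_ext <- numeric(n_perm); null_peak <- numeric(n_perm)
  with_seed(seed, {
    pm <- map$perm
    for (b in seq_len(n_perm)) {
      draw <- if (pm$scheme == "sign_flip") {
        sample(c(-1, 1), nrow(pm$B), replace = TRUE)
      } else if (pm$scheme == "two_sample") {
        sample.int(nrow(pm$B))
      } else {
        sample.int(nrow(pm$Y))
      }
      ms <- .max_cluster_stats(as.numeric(full(perm_stat(map, draw))),
                               dims, thr, connectivity)
      null_ext[b] <- ms[1]; null_peak[b] <- ms[2]
    }
  })

  lab_arr <- array(labels, dim = dims)
  rows <- lapply(seq_len(n_cl), function(cl) {
    vox <- which(lab_arr == cl, arr.ind = TRUE)
    vals <- obs[lab_arr == cl]
    pk <- which.max(vals)
    pkv <- vox[pk, ]
    data.frame(cluster = cl, extent = nrow(vox),
               peak_stat = max(vals),
               peak_x = grid$xs[pkv[1]], peak_y = grid$ys[pkv[2]],
               peak_ms = grid$ts[pkv[3]],
               t_start_ms = grid$ts[min(vox[, 3])],
               t_end_ms = grid$ts[max(vox[, 3])],
               p_cluster_fwe = (1 + sum(null_ext >= nrow(vox))) / (n_perm + 1),
               p_peak_fwe = (1 + sum(null_peak >= max(vals))) / (n_perm + 1))
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_cluster_fwe < alpha | out$p_peak_fwe < alpha
  out <- out[order(-out$extent), ]
  rownames(out) <- NULL
  class(out) <- c("cluster_result", "data.frame")
  attr(out, "cdt_threshold") <- thr
  attr(out, "n_perm") <- n_perm
  out
}

#' Cohen's f-squared from an F statistic
#'
#' Standard conversion via partial eta-squared:
#' `eta2 = F * df1 / (F * df1 + df2)`, `f2 = eta2 / (1 - eta2)`.
#'
#' @param F F statistic (>= 0).
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return list with `eta2_p` and `f2`.
#' @export
cohen_f2 <- function(F, df1, df2) {
  if (df2 <= 0) stop("df2 must be positive", call. = FALSE)
  if (any(F < 0)) stop("F must be non-negative", call. = FALSE)
  eta2 <- F * df1 / (F * df1 + df2)
  list(eta2_p = eta2, f2 = eta2 / (1 - eta2))
}

#' Quantile-split ERP averages
#'
#' Mean ERP over the trials with the top and bottom `q` fraction of the
#' regressor values (ties broken by trial order), at the named electrodes:
#' the standard figure showing how single-trial amplitudes differ between
#' high and low precision-weighted prediction errors.
#'
#' @param epochs an `epoch_set`.
#' @param regressor numeric per-trial vector aligned with all trials of
#'   `epochs` (only kept trials enter the split).
#' @param q quantile fraction per side (default 0.15).
#' @param electrodes channel names to average over (default: all scalp).
#' @return list with `high` / `low` (mean ERP, electrodes x time), `times`,
#'   `n_side`, `high_trials`, `low_trials`.
#' @export
quantile_split_erp <- function(epochs, regressor, q = 0.15,
                               electrodes = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (length(regressor) != length(epochs$kept))
    stop("regressor must align with all trials", call. = FALSE)
  if (is.null(electrodes))
    electrodes <- epochs$channels$name[epochs$channels$role == "scalp"]
  ci <- match(electrodes, epochs$channels$name)
  if (anyNA(ci)) stop("unknown electrode name", call. = FALSE)
  kept <- which(epochs$kept)
  n <- length(kept)
  n_side <- round(q * n)
  if (n_side < 5) warning("fewer than 5 trials per side of the split")
  ord <- kept[order(regressor[kept], seq_along(kept))]   # stable tie-break
  lo <- ord[seq_len(n_side)]
  hi <- ord[seq.int(n - n_side + 1L, n)]
  avg <- function(idx) {
    m <- apply(epochs$data[idx, ci, , drop = FALSE], c(2, 3), mean)
    rownames(m) <- electrodes
    m
  }
  list(high = avg(hi), low = avg(lo), times = epochs$times,
       n_side = n_side, high_trials = hi, low_trials = lo)
}

#' Classical mismatch-negativity difference wave
#'
#' Mean ERP to standards minus mean ERP to deviants (kept trials), per
#' channel and time point.
#'
#' @param epochs an `epoch_set` with both tone classes among kept trials.
#' @return list with `difference` (channels x time), `standard`, `deviant`,
#'   `times`, `channels`.
#' @export
classic_mmn <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  kept <- which(epochs$kept)
  st <- kept[epochs$tone[kept] == 0]
  dv <- kept[epochs$tone[kept] == 1]
  if (length(st) == 0 || length(dv) == 0)
    stop("both standards and deviants must be present", call. = FALSE)
  m <- function(idx) apply(epochs$data[idx, , , drop = FALSE], c(2, 3), mean)
  ms <- m(st); md <- m(dv)
  list(difference = ms - md, standard = ms, deviant = md,
       times = epochs$times, channels = epochs$channels$name)
}

#' Maximum-intensity projection of a statistic map
#'
#' Collapses one spatial axis by taking the per-cell maximum, producing the
#' standard 2-D summary image (default: collapse left-right, retaining
#' anterior-posterior position by peristimulus time).
#'
#' @param map a `stat_map`, or an nx x ny x nt array.
#' @param axis `"x"` (collapse left-right, default) or `"y"`.
#' @return matrix (retained spatial axis x time), NA where the whole line is
#'   out of mask.
#' @export
max_intensity_projection <- function(map, axis = c("x", "y")) {
  axis <- match.arg(axis)
  arr <- if (inherits(map, "stat_map")) unmask_volume(map$stat, map) else map
  drop_dim <- if (axis == "x") 1 else 2
  apply(arr, setdiff(1:3, drop_dim), function(v) {
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  })
}

#' Write a cluster table to TSV
#' @param clusters a `cluster_result` data.frame.
#' @param path output path.
#' @export
write_cluster_table <- function(clusters, path) {
  utils::write.table(as.data.frame(clusters), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
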