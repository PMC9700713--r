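# Three-level binary hierarchical Gaussian filter (HGF).
#
# Level 1: binary outcome u (deviant vs standard); level 2: continuous
# tendency x2 whose logistic transform is the deviant probability; level 3:
# log-volatility x3 modulating the step size of x2. Updates are the standard
# closed-form one-step equations: each posterior mean moves by the prediction
# error from the level below weighted by a ratio of precisions.

#' HGF parameter set
#'
#' @param kappa coupling strength between levels 2 and 3 (fixed at 1 by
#'   convention; must be > 0).
#' @param omega2 tonic log-volatility at level 2.
#' @param omega3 tonic log-volatility at level 3 (theta = exp(omega3)).
#' @param mu2_0,sigma2_0 level-2 prior mean and variance.
#' @param mu3_0,sigma3_0 level-3 prior mean and variance.
#' @return object of class `hgf_params`.
#' @export
hgf_params <- function(kappa = 1, omega2 = -3, omega3 = -6,
                       mu2_0 = 0, sigma2_0 = 1, mu3_0 = 1, sigma3_0 = 1) {
  if (sigma2_0 <= 0 || sigma3_0 <= 0) stop("prior variances must be positive", call. = FALSE)
  if (kappa <= 0) stop("kappa must be positive", call. = FALSE)
  structure(list(kappa = kappa, omega2 = omega2, omega3 = omega3,
                 mu2_0 = mu2_0, sigma2_0 = sigma2_0,
                 mu3_0 = mu3_0, sigma3_0 = sigma3_0),
            class = "hgf_params")
}

hgf_error <- function(msg, ...) {
  stop(structure(class = c("hgf_numerical_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = NULL)))
}

#' One HGF prediction step
#'
#' Maps the posterior belief after trial k-1 to the prediction for trial k:
#' predicted deviant probability `muhat1 = plogis(mu2)`, irreducible
#' uncertainty `sigma1 = muhat1 * (1 - muhat1)`, and predicted precisions
#' `pihat2 = 1 / (sigma2 + exp(kappa * mu3 + omega2))`,
#' `pihat3 = 1 / (sigma3 + exp(omega3))`.
#'
#' @param prev list/belief with `mu2`, `sigma2`, `mu3`, `sigma3`.
#' @param params an [hgf_params()].
#' @return list with `muhat1`, `sigma1`, `pihat1`, `pihat2`, `pihat3`, `v2`.
#' @export
hgf_predict <- function(prev, params) {
  muhat1 <- stats::plogis(prev$mu2)
  sigma1 <- muhat1 * (1 - muhat1)
  v2 <- exp(params$kappa * prev$mu3 + params$omega2)
  if (!is.finite(v2)) hgf_error("exp(kappa*mu3 + omega2) overflowed (mu3 = %g)", prev$mu3)
  v3 <- exp(params$omega3)
  if (!is.finite(v3)) hgf_error("exp(omega3) overflowed (omega3 = %g)", params$omega3)
  pihat2 <- 1 / (prev$sigma2 + v2)
  pihat3 <- 1 / (prev$sigma3 + v3)
  if (!is.finite(pihat2) || pihat2 <= 0) hgf_error("predicted level-2 precision not positive")
  if (!is.finite(pihat3) || pihat3 <= 0) hgf_error("predicted level-3 precision not positive")
  list(muhat1 = muhat1, sigma1 = sigma1, pihat1 = 1 / sigma1,
       pihat2 = pihat2, pihat3 = pihat3, v2 = v2)
}

#' One HGF update step
#'
#' Given the prediction for trial k and the observed outcome `u`, computes
#' the sensory prediction error `delta1 = u - muhat1`, the level-2 posterior
#' (`pi2 = pihat2 + sigma1`, `mu2 += delta1 / pi2`), the volatility
#' prediction error `delta2`, and the level-3 posterior. The belief shifts
#' `eps2 = delta1 / pi2` and `eps3 = kappa / (2 * pi3) * w2 * delta2` are the
#' precision-weighted prediction errors used as EEG regressors.
#'
#' @param pred output of [hgf_predict()].
#' @param prev previous belief (`mu2`, `sigma2`, `mu3`, `sigma3`).
#' @param u observed outcome, 0 or 1.
#' @param params an [hgf_params()].
#' @return list with the new belief (`mu2`, `sigma2`, `mu3`, `sigma3`, `pi2`,
#'   `pi3`) and trial quantities `delta1`, `eps2`, `delta2`, `eps3`.
#' @export
hgf_update <- function(pred, prev, u, params) {
  stopifnot(u %in% c(0, 1))
  k <- params$kappa
  delta1 <- u - pred$muhat1

  pi2 <- pred$pihat2 + pred$sigma1
  eps2 <- delta1 / pi2
  mu2 <- prev$mu2 + eps2
  sigma2 <- 1 / pi2

  denom <- prev$sigma2 + pred$v2            # = 1 / pihat2
  delta2 <- (sigma2 + (mu2 - prev$mu2)^2) / denom - 1
  w2 <- pred$v2 / denom
  r2 <- (pred$v2 - prev$sigma2) / (pred$v2 + prev$sigma2)
  pi3 <- pred$pihat3 + (k^2 / 2) * w2 * (w2 + r2 * delta2)
  if (!is.finite(pi3) || pi3 <= 0)
    hgf_error("negative posterior precision at level 3 (pi3 = %g)", pi3)
  eps3 <- (k / (2 * pi3)) * w2 * delta2
  mu3 <- prev$mu3 + eps3
  sigma3 <- 1 / pi3

  list(mu2 = mu2, sigma2 = sigma2, mu3 = mu3, sigma3 = sigma3,
       pi2 = pi2, pi3 = pi3,
       delta1 = delta1, eps2 = eps2, delta2 = delta2, eps3 = eps3)
}

#' Filter a tone sequence through the HGF
#'
#' Applies [hgf_predict()] / [hgf_update()] sequentially from the priors.
#' Row k of the output holds the prediction made before observing trial k's
#' tone and the prediction errors / posteriors computed after observing it.
#'
#' @param tones a `tone_sequence` (or plain 0/1 vector).
#' @param params an [hgf_params()].
#' @param rectify_pwpe if TRUE, export `eps2`/`eps3` as absolute magnitudes
#'   instead of signed values (off by default).
#' @return object of class `trajectory_set`: data.frame-like list of
#'   per-trial vectors `u`, `muhat1`, `sigma1`, `delta1`, `eps2`, `sigma2`,
#'   `delta2`, `eps3`, `sigma3`, `pi2`, `pi3`, `mu2`, `mu3`.
#' @export
hgf_filter <- function(tones, params = hgf_params(), rectify_pwpe = FALSE) {
  u <- if (inherits(tones, "tone_sequence")) tones$u else as.integer(tones)
  n <- length(u)
  if (n == 0) stop("empty tone sequence", call. = FALSE)
  cols <- c("u", "muhat1", "sigma1", "delta1", "eps2", "sigma2",
            "delta2", "eps3", "sigma3", "pi2", "pi3", "mu2", "mu3")
  out <- stats::setNames(replicate(length(cols), numeric(n), simplify = FALSE), cols)
  state <- list(mu2 = params$mu2_0, sigma2 = params$sigma2_0,
                mu3 = params$mu3_0, sigma3 = params$sigma3_0)
  for (k in seq_len(n)) {
    res <- tryCatch({
      pred <- hgf_predict(state, params)
      upd <- hgf_update(pred, state, u[k], params)
      list(pred = pred, upd = upd)
    }, hgf_numerical_error = function(e) {
      hgf_error("trial %d: %s", k, conditionMessage(e))
    })
    pred <- res$pred; upd <- res$upd
    out$u[k] <- u[k]
    out$muhat1[k] <- pred$muhat1; out$sigma1[k] <- pred$sigma1
    out$delta1[k] <- upd$delta1; out$eps2[k] <- upd$eps2
    out$sigma2[k] <- upd$sigma2; out$delta2[k] <- upd$delta2
    out$eps3[k] <- upd$eps3; out$sigma3[k] <- upd$sigma3
    out$pi2[k] <- upd$pi2; out$pi3[k] <- upd$pi3
    out$mu2[k] <- upd$mu2; out$mu3[k] <- upd$mu3
    state <- upd[c("mu2", "sigma2", "mu3", "sigma3")]
  }
  if (rectify_pwpe) { out$eps2 <- abs(out$eps2); out$eps3 <- abs(out$eps3) }
  structure(out, class = "trajectory_set", params = params,
            rectified = rectify_pwpe)
}

#' Cumulative surprise of a tone sequence under the HGF
#'
#' Negative log predictive probability summed over trials,
#' `S = -sum(log(u * muhat1 + (1 - u) * (1 - muhat1)))`. Inadmissible
#' parameter sets (any trial raising a numerical-domain error) return `Inf`.
#'
#' @param tones tone sequence or 0/1 vector.
#' @param params an [hgf_params()].
#' @param base `"nats"` (natural log, default) or `"bits"`.
#' @return scalar surprise (`Inf` for inadmissible parameters).
#' @export
hgf_surprise <- function(tones, params, base = c("nats", "bits")) {
  base <- match.arg(base)
  traj <- tryCatch(hgf_filter(tones, params),
                   hgf_numerical_error = function(e) NULL)
  if (is.null(traj)) return(Inf)
  p <- ifelse(traj$u == 1, traj$muhat1, 1 - traj$muhat1)
  if (any(p <= 0)) return(Inf)
  s <- -sum(log(p))
  if (base == "bits") s <- s / log(2)
  s
}

#' Fit Bayes-optimal HGF parameters to a tone sequence
#'
#' Finds the tonic volatilities (omega2, omega3) minimising cumulative
#' surprise plus Gaussian prior penalties (a MAP estimate of the
#' "Bayes-optimal learner"): the parameterisation under which the sequence
#' would have been least surprising. kappa and the level-2/3 priors stay
#' fixed. Derivative-free Nelder-Mead from five fixed starting points;
#' inadmissible proposals receive `Inf` and are counted.
#'
#' @param tones tone sequence with both outcome types present.
#' @param prior_config list with `omega2_prior` / `omega3_prior`
#'   (each c(mean, variance)) and `fixed` ([hgf_params()] supplying kappa
#'   and level priors). Defaults: omega2 ~ N(-3, 16), omega3 ~ N(-6, 16).
#' @return list with `params` (fitted [hgf_params()]), `surprise` (at the
#'   optimum, penalty excluded), `objective`, `convergence`,
#'   `n_inadmissible`, and `starts` (per-start objective values).
#' @export
hgf_fit_bayes_optimal <- function(tones, prior_config = list()) {
  u <- if (inherits(tones, "tone_sequence")) tones$u else as.integer(tones)
  if (length(unique(u)) < 2)
    stop("sequence must contain both standards and deviants", call. = FALSE)
  pc <- utils::modifyList(list(omega2_prior = c(-3, 16),
                               omega3_prior = c(-6, 16),
                               fixed = hgf_params()), prior_config)
  n_bad <- 0L
  obj <- function(th) {
    p <- pc$fixed; p$omega2 <- th[1]; p$omega3 <- th[2]
    s <- hgf_surprise(u, p)
    if (!is.finite(s)) { n_bad <<- n_bad + 1L; return(Inf) }
    s + (th[1] - pc$omega2_prior[1])^2 / (2 * pc$omega2_prior[2]) +
        (th[2] - pc$omega3_prior[1])^2 / (2 * pc$omega3_prior[2])
  }
  starts <- list(c(-3, -6), c(-2, -4), c(-4, -7), c(-5, -8), c(-1.5, -3))
  fits <- lapply(starts, function(s0) {
    if (!is.finite(obj(s0))) return(NULL)
    stats::optim(s0, obj, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-10))
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop(sprintf(paste0("all %d starting points are inadmissible ",
                        "(omega2 in [%g, %g], omega3 in [%g, %g])"),
                 length(starts),
                 min(vapply(starts, `[`, 0, 1)), max(vapply(starts, `[`, 0, 1)),
                 min(vapply(starts, `[`, 0, 2)), max(vapply(starts, `[`, 0, 2))),
         call. = FALSE)
  vals <- vapply(fits, function(f) if (is.null(f)) Inf else f$value, numeric(1))
  best <- fits[[which.min(vals)]]
  params <- pc$fixed
  params$omega2 <- best$par[1]; params$omega3 <- best$par[2]
  list(params = params,
       surprise = hgf_surprise(u, params),
       objective = best$value,
       convergence = best$convergence == 0,
       n_inadmissible = n_bad,
       starts = vals)
}

#' Write a trajectory set to TSV (one row per trial)
#' @param traj a `trajectory_set`.
#' @param path output path.
#' @export
write_trajectories <- function(traj, path) {
  utils::write.table(as.data.frame(unclass(traj)), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
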