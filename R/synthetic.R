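# Synthetic oddball cohorts: tone sequences, clinical tables, and
# trajectory-locked multichannel EEG epochs.

#' Evaluate an expression with a temporarily seeded RNG
#'
#' Restores (or removes) the global `.Random.seed` afterwards so that seeded
#' generator calls never perturb the caller's RNG stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed
#'
#' Deterministic integer mix used to give each subject, permutation or stage
#' its own reproducible stream; results stay below 2^31 - 1.
#' @param seed master seed (integer).
#' @param k child index (integer >= 0).
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 10007 + as.numeric(k)) %% 2147483647)
}

#' Oddball paradigm specification
#'
#' Describes the auditory oddball paradigm: standard (50 ms) and deviant
#' (100 ms) tones delivered at a fixed interstimulus interval while EEG is
#' recorded from a 32-channel modified 10-20 cap.
#'
#' @param n_trials number of tones per session (default 1830).
#' @param p_deviant per-trial deviant probability (default 0.10).
#' @param isi interstimulus interval, ms (default 500).
#' @param srate sampling rate, Hz (default 500).
#' @param epoch_window epoch limits around tone onset, ms (default -100..400).
#' @param montage channel layout data.frame (default [montage_1020()]).
#' @return An object of class `paradigm_spec`.
#' @export
paradigm_spec <- function(n_trials = 1830, p_deviant = 0.10, isi = 500,
                          srate = 500, epoch_window = c(-100, 400),
                          montage = montage_1020()) {
  # p_deviant = 0 is allowed as a degenerate all-standard sequence
  if (p_deviant < 0 || p_deviant >= 1)
    stop("p_deviant must lie in [0, 1)", call. = FALSE)
  if (srate <= 0) stop("srate must be positive", call. = FALSE)
  if (!(epoch_window[1] < 0 && epoch_window[2] > 0))
    stop("epoch window must straddle tone onset", call. = FALSE)
  if (anyDuplicated(montage$name)) stop("channel names must be unique", call. = FALSE)
  structure(list(n_trials = as.integer(n_trials), p_deviant = p_deviant,
                 isi = isi, srate = srate, epoch_window = epoch_window,
                 montage = montage,
                 n_channels = sum(montage$role == "scalp")),
            class = "paradigm_spec")
}

#' Cohort specification
#'
#' Describes a simulated cohort of healthy controls (HC) and clinical
#' high-risk (CHR) participants. CHR subjects carry SIPS subscale totals;
#' the positive-subscale distribution defaults to mean 10.5, SD 3.6.
#' `effect_link` is the slope tying a subject's EEG effect amplitude to
#' their z-scored SIPS positive total (0 = no clinical coupling).
#'
#' @param n_hc,n_chr group sizes.
#' @param sips_positive c(mean, sd) of the SIPS positive-subscale total.
#' @param sips_negative,sips_disorganised,sips_general c(mean, sd) for the
#'   remaining subscales.
#' @param effect_link slope: per-subject effect scale = 1 + effect_link *
#'   z(SIPS positive); HC subjects have scale 1.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_hc = 23, n_chr = 31,
                        sips_positive = c(10.5, 3.6),
                        sips_negative = c(12.8, 4.9),
                        sips_disorganised = c(5.6, 3.2),
                        sips_general = c(9.6, 4.0),
                        effect_link = 0) {
  if (n_hc < 1 || n_chr < 1) stop("group sizes must be >= 1", call. = FALSE)
  if (sips_positive[2] < 0) stop("sd must be >= 0", call. = FALSE)
  structure(list(n_hc = as.integer(n_hc), n_chr = as.integer(n_chr),
                 sips_positive = sips_positive, sips_negative = sips_negative,
                 sips_disorganised = sips_disorganised,
                 sips_general = sips_general, effect_link = effect_link),
            class = "cohort_spec")
}

#' Planted-effect specification
#'
#' One planted linear coupling between a learning-trajectory regressor and
#' epoch amplitude: inside `window` at the listed `channels`, amplitude gains
#' `amplitude * subject_scale * z(regressor)` microvolts per trial.
#'
#' @param regressor_name one of `"eps2"`, `"eps3"`, `"sigma1"`, `"sigma2"`,
#'   `"sigma3"`, `"delta1"`, `"delta2"`, `"tone"`.
#' @param channels channel names receiving the effect.
#' @param window c(start, end) ms, inside the epoch window.
#' @param amplitude microvolts per unit of z-scored regressor.
#' @export
effect_spec <- function(regressor_name, channels, window, amplitude) {
  regs <- c("eps2", "eps3", "sigma1", "sigma2", "sigma3",
            "delta1", "delta2", "tone")
  regressor_name <- match.arg(regressor_name, regs)
  structure(list(regressor_name = regressor_name, channels = channels,
                 window = window, amplitude = amplitude),
            class = "effect_spec")
}

#' Noise specification for synthetic epochs
#'
#' Trial noise is an AR(1) process in time whose innovations are spatially
#' correlated across channels with a Gaussian kernel; a fraction of trials
#' additionally carry a large blink transient on the EOG channel (partially
#' volume-conducted to Fp1/Fp2).
#'
#' @param trial_sd stationary noise SD, microvolts.
#' @param ar1 temporal AR(1) coefficient in `[0, 1)`.
#' @param spatial_scale spatial correlation length, mm.
#' @param blink_rate per-trial blink probability.
#' @param blink_amplitude blink peak amplitude on the EOG channel, microvolts.
#' @param drift_sd SD of the per-trial DC offset (removed by baseline
#'   correction), microvolts.
#' @export
noise_spec <- function(trial_sd = 5, ar1 = 0.8, spatial_scale = 40,
                       blink_rate = 0.05, blink_amplitude = 400,
                       drift_sd = 2) {
  if (trial_sd <= 0) stop("trial_sd must be positive", call. = FALSE)
  if (ar1 < 0 || ar1 >= 1) stop("ar1 must lie in [0, 1)", call. = FALSE)
  structure(list(trial_sd = trial_sd, ar1 = ar1, spatial_scale = spatial_scale,
                 blink_rate = blink_rate, blink_amplitude = blink_amplitude,
                 drift_sd = drift_sd),
            class = "noise_spec")
}

#' Generate an oddball tone sequence
#'
#' Draws a binary sequence (0 = standard, 1 = deviant) of `n_trials` tones,
#' each trial independently deviant with probability `p_deviant`
#' ("pseudorandom" placement). An optional `min_gap` forces at least that
#' many standards after every deviant.
#'
#' @param spec a [paradigm_spec()].
#' @param seed RNG seed.
#' @param min_gap minimum number of standards following each deviant
#'   (0 = unconstrained i.i.d. placement, the default).
#' @return An object of class `tone_sequence`: list with `u` (integer 0/1),
#'   and the paradigm metadata.
#' @export
gen_tone_sequence <- function(spec, seed, min_gap = 0) {
  stopifnot(inherits(spec, "paradigm_spec"))
  u <- with_seed(seed, {
    u <- as.integer(stats::runif(spec$n_trials) < spec$p_deviant)
    if (min_gap > 0 && any(u == 1)) {
      gap <- 0L
      for (k in seq_along(u)) {
        if (gap > 0L) { u[k] <- 0L; gap <- gap - 1L }
        else if (u[k] == 1L) gap <- as.integer(min_gap)
      }
    }
    u
  })
  structure(list(u = u, n_trials = spec$n_trials, p_deviant = spec$p_deviant,
                 isi = spec$isi, seed = as.integer(seed), min_gap = min_gap),
            class = "tone_sequence")
}

#' Generate a simulated clinical cohort table
#'
#' One row per subject: group label (HC first, then CHR), age, sex, and for
#' CHR subjects the four SIPS subscale totals (clipped at zero). Each
#' subject's `effect_scale` column carries the multiplier later applied to
#' planted EEG effects: 1 for HC, `1 + effect_link * z(SIPS positive)` for
#' CHR, so symptom-linked amplitude modulation is recoverable by ANCOVA.
#'
#' @param spec a [cohort_spec()].
#' @param seed RNG seed.
#' @return data.frame with columns `subject`, `group`, `age`, `sex`,
#'   `sips_positive`, `sips_negative`, `sips_disorganised`, `sips_general`,
#'   `effect_scale`.
#' @export
gen_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    n <- spec$n_hc + spec$n_chr
    group <- c(rep("HC", spec$n_hc), rep("CHR", spec$n_chr))
    age <- c(stats::rnorm(spec$n_hc, 21.5, 2.8), stats::rnorm(spec$n_chr, 20.7, 2.4))
    sex <- sample(c("F", "M"), n, replace = TRUE)
    draw <- function(ms, n) pmax(0, stats::rnorm(n, ms[1], ms[2]))
    sp <- draw(spec$sips_positive, spec$n_chr)
    out <- data.frame(
      subject = sprintf("sub-%02d", seq_len(n)),
      group = group, age = round(age, 1), sex = sex,
      sips_positive = c(rep(NA_real_, spec$n_hc), sp),
      sips_negative = c(rep(NA_real_, spec$n_hc), draw(spec$sips_negative, spec$n_chr)),
      sips_disorganised = c(rep(NA_real_, spec$n_hc), draw(spec$sips_disorganised, spec$n_chr)),
      sips_general = c(rep(NA_real_, spec$n_hc), draw(spec$sips_general, spec$n_chr)),
      stringsAsFactors = FALSE
    )
    z <- if (spec$n_chr > 1 && stats::sd(sp) > 0) (sp - mean(sp)) / stats::sd(sp) else rep(0, spec$n_chr)
    out$effect_scale <- c(rep(1, spec$n_hc), 1 + spec$effect_link * z)
    out
  })
}

#' Look up a regressor vector by name
#'
#' @param name regressor name (see [effect_spec()]).
#' @param trajectories a `trajectory_set` from [hgf_filter()].
#' @param tones a `tone_sequence` (needed only for `"tone"`).
#' @return numeric per-trial vector.
#' @export
regressor_values <- function(name, trajectories = NULL, tones = NULL) {
  if (name == "tone") {
    if (is.null(tones)) stop("tone regressor needs the tone sequence", call. = FALSE)
    return(as.numeric(tones$u))
  }
  if (is.null(trajectories)) stop("trajectory regressor needs trajectories", call. = FALSE)
  if (!name %in% names(trajectories))
    stop(sprintf("unknown regressor '%s'", name), call. = FALSE)
  trajectories[[name]]
}

#' Generate single-subject oddball EEG epochs
#'
#' Builds a trials x channels x samples epoch array: per-trial DC offset
#' (baseline drift), planted trajectory-locked effects, spatially correlated
#' AR(1) noise, and blink transients on the EOG channel in a random fraction
#' of trials. Fully deterministic given `seed`.
#'
#' @param tones a `tone_sequence`.
#' @param trajectories a `trajectory_set` aligned with `tones` (may be NULL
#'   when all effects use the `"tone"` regressor).
#' @param effects list of [effect_spec()] objects (may be empty).
#' @param noise a [noise_spec()].
#' @param spec the [paradigm_spec()] (montage, epoch window, srate).
#' @param subject_scale per-subject multiplier on all effect amplitudes.
#' @param seed RNG seed.
#' @return An object of class `epoch_set`: list with `data`
#'   (trials x channels x samples array, microvolts), `times` (ms),
#'   `channels` (montage data.frame with `bad` flags), `srate`, `tone`
#'   (0/1 per trial), `kept`, `reject_reason`, and `blink_trials`
#'   (the generator's ground-truth blink log).
#' @export
gen_subject_eeg <- function(tones, trajectories, effects, noise, spec,
                            subject_scale = 1, seed = 1) {
  stopifnot(inherits(tones, "tone_sequence"), inherits(noise, "noise_spec"),
            inherits(spec, "paradigm_spec"))
  n_tr <- tones$n_trials
  if (!is.null(trajectories) && length(trajectories$u) != n_tr)
    stop("trajectories are not aligned with the tone sequence", call. = FALSE)
  mont <- spec$montage
  n_ch <- nrow(mont)
  times <- seq(spec$epoch_window[1], spec$epoch_window[2], by = 1000 / spec$srate)
  n_t <- length(times)

  with_seed(seed, {
    # spatially correlated innovations: Gaussian kernel over channel distance
    d <- as.matrix(stats::dist(mont[, c("x", "y")]))
    K <- exp(-0.5 * (d / noise$spatial_scale)^2)
    L <- t(chol(K + diag(1e-8, n_ch)))
    # innovations scaled for stationary marginal SD = trial_sd
    innov_sd <- noise$trial_sd * sqrt(1 - noise$ar1^2)
    z <- matrix(stats::rnorm(n_ch * n_t * n_tr), nrow = n_ch)
    z <- innov_sd * (L %*% z)                 # channels x (samples, trials)
    # AR(1) along time, vectorised over (channel, trial); stationary start
    dim(z) <- c(n_ch, n_t, n_tr)
    z <- aperm(z, c(1, 3, 2))                 # channels x trials x samples
    dim(z) <- c(n_ch * n_tr, n_t)
    z[, 1] <- as.numeric(L %*% matrix(stats::rnorm(n_ch * n_tr, 0, noise$trial_sd), n_ch))
    for (s in 2:n_t) z[, s] <- noise$ar1 * z[, s - 1] + z[, s]
    dim(z) <- c(n_ch, n_tr, n_t)
    data <- aperm(z, c(2, 1, 3))              # trials x channels x samples

    # per-trial, per-channel DC offset (slow drift surrogate)
    if (noise$drift_sd > 0) {
      offs <- matrix(stats::rnorm(n_tr * n_ch, 0, noise$drift_sd), n_tr, n_ch)
      data <- data + array(rep(offs, n_t), dim = c(n_tr, n_ch, n_t))
    }

    # planted effects
    for (ef in effects) {
      stopifnot(inherits(ef, "effect_spec"))
      if (!all(ef$channels %in% mont$name))
        stop("effect channels not in montage", call. = FALSE)
      if (ef$window[1] < spec$epoch_window[1] || ef$window[2] > spec$epoch_window[2])
        stop("effect window outside epoch window", call. = FALSE)
      r <- regressor_values(ef$regressor_name, trajectories, tones)
      zr <- if (stats::sd(r) > 0) (r - mean(r)) / stats::sd(r) else r * 0
      ci <- match(ef$channels, mont$name)
      ti <- which(times >= ef$window[1] & times <= ef$window[2])
      bump <- ef$amplitude * subject_scale * zr      # per trial
      block <- data[, ci, ti, drop = FALSE]
      data[, ci, ti] <- block + array(rep(bump, length(ci) * length(ti)),
                                      dim = dim(block))
    }

    # blinks: half-cosine transient on vEOG, partially on Fp1/Fp2
    blink_trials <- integer(0)
    if (noise$blink_rate > 0) {
      blink_trials <- which(stats::runif(n_tr) < noise$blink_rate)
      eog <- which(mont$role == "eog")
      fp <- match(intersect(c("Fp1", "Fp2"), mont$name), mont$name)
      blink_len <- max(3L, round(0.150 * spec$srate))   # 150 ms
      shape <- noise$blink_amplitude * (1 - cos(2 * pi * seq_len(blink_len) / (blink_len + 1))) / 2
      for (tr in blink_trials) {
        start <- sample.int(max(1L, n_t - blink_len), 1)
        idx <- start:(start + blink_len - 1L)
        data[tr, eog, idx] <- data[tr, eog, idx] + shape
        for (f in fp) data[tr, f, idx] <- data[tr, f, idx] + 0.4 * shape
      }
    }

    chan <- mont
    chan$bad <- FALSE
    structure(list(data = data, times = times, channels = chan,
                   srate = spec$srate, tone = tones$u,
                   kept = rep(TRUE, n_tr),
                   reject_reason = rep("none", n_tr),
                   blink_trials = blink_trials),
              class = "epoch_set")
  })
}

#' Write a tone sequence to a two-column TSV
#' @param tones a `tone_sequence`.
#' @param path output path.
#' @export
write_tone_sequence <- function(tones, path) {
  utils::write.table(data.frame(trial = seq_along(tones$u), u = tones$u),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tone sequence from a two-column TSV
#' @param path TSV with columns `trial`, `u`.
#' @param isi,p_deviant optional paradigm metadata to attach.
#' @export
read_tone_sequence <- function(path, isi = 500, p_deviant = NA_real_) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  structure(list(u = as.integer(d$u), n_trials = nrow(d),
                 p_deviant = p_deviant, isi = isi, seed = NA_integer_,
                 min_gap = 0),
            class = "tone_sequence")
}
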