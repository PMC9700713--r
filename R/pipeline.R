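# End-to-end orchestration: config handling, simulation of a full cohort,
# the staged analysis (HGF -> preprocessing -> first level -> group), and a
# figure/table report. All stages are deterministic given the master seed.

#' Default pipeline configuration
#'
#' Returns the full default configuration: the oddball paradigm (1830 trials,
#' 10% deviants, 500 ms ISI, 500 Hz, 32-channel modified 10-20 montage), a
#' 23 HC + 31 CHR cohort with SIPS positive totals ~ N(10.5, 3.6^2), one
#' planted frontocentral sensory-pwPE effect at 100-228 ms, AR(1) noise with
#' blinks, Bayes-optimal HGF fitting, the stated preprocessing thresholds
#' (0.5-30 Hz band, 100 uV rejection, 20% channel rule, 250 uV EOG blink
#' threshold), the 32 x 32 x 2 ms analysis grid over 100-400 ms with
#' 16 x 16 mm smoothing, and permutation FWE inference (CDT p < 0.001,
#' alpha 0.05, 1000 permutations).
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    paradigm = list(n_trials = 1830, p_deviant = 0.10, isi = 500, srate = 500,
                    epoch_window = c(-100, 400)),
    cohort = list(n_hc = 23, n_chr = 31, sips_positive = c(10.5, 3.6),
                  effect_link = 0.5),
    effects = list(list(regressor = "eps2",
                        channels = c("Fz", "FC1", "FC2", "F3", "F4", "Cz"),
                        window = c(100, 228), amplitude = 1)),
    noise = list(trial_sd = 5, ar1 = 0.8, spatial_scale = 40,
                 blink_rate = 0.05, blink_amplitude = 400, drift_sd = 2),
    hgf = list(fit = TRUE, omega2 = -3, omega3 = -6,
               omega2_prior = c(-3, 16), omega3_prior = c(-6, 16)),
    preprocess = list(blink_threshold = 250, amplitude_threshold = 100,
                      channel_max_fraction = 0.20),
    glm = list(regressors = c("eps2", "eps3", "sigma1", "sigma2", "sigma3",
                              "delta1", "delta2", "tone"),
               fwhm = c(16, 16),
               grid = list(nx = 32, ny = 32, voxel = c(4.25, 5.38, 2),
                           time_window = c(100, 400))),
    inference = list(cdt_p = 0.001, alpha = 0.05, n_perm = 1000,
                     connectivity = 6)
  )
}

known_config_keys <- function() names(default_config())

#' Read a pipeline configuration from YAML or JSON
#'
#' Unknown top-level keys are rejected; missing keys take their defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), known_config_keys())
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  out <- utils::modifyList(default_config(), cfg)
  validate_config(out)
  out
}

validate_config <- function(cfg) {
  stopifnot(cfg$paradigm$n_trials >= 1,
            cfg$paradigm$p_deviant > 0, cfg$paradigm$p_deviant < 1,
            cfg$inference$cdt_p > 0, cfg$inference$cdt_p < 1,
            cfg$inference$n_perm >= 1,
            cfg$preprocess$amplitude_threshold > 0)
  invisible(cfg)
}

config_objects <- function(cfg) {
  par_spec <- paradigm_spec(n_trials = cfg$paradigm$n_trials,
                            p_deviant = cfg$paradigm$p_deviant,
                            isi = cfg$paradigm$isi, srate = cfg$paradigm$srate,
                            epoch_window = cfg$paradigm$epoch_window)
  coh_spec <- cohort_spec(n_hc = cfg$cohort$n_hc, n_chr = cfg$cohort$n_chr,
                          sips_positive = cfg$cohort$sips_positive,
                          effect_link = cfg$cohort$effect_link)
  effects <- lapply(cfg$effects, function(e)
    effect_spec(e$regressor, e$channels, e$window, e$amplitude))
  noise <- noise_spec(trial_sd = cfg$noise$trial_sd, ar1 = cfg$noise$ar1,
                      spatial_scale = cfg$noise$spatial_scale,
                      blink_rate = cfg$noise$blink_rate,
                      blink_amplitude = cfg$noise$blink_amplitude,
                      drift_sd = cfg$noise$drift_sd)
  grid <- grid_spec(par_spec$montage, nx = cfg$glm$grid$nx,
                    ny = cfg$glm$grid$ny, voxel = cfg$glm$grid$voxel,
                    time_window = cfg$glm$grid$time_window)
  list(paradigm = par_spec, cohort = coh_spec, effects = effects,
       noise = noise, grid = grid)
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

write_manifest <- function(out_dir, cfg, stage, files, warnings = character(0)) {
  man <- list(stage = stage,
              config = cfg,
              config_hash = config_hash(cfg),
              package_version = as.character(utils::packageVersion("hgfmmn")),
              seed = cfg$seed,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              warnings = warnings,
              files = as.list(tools::md5sum(files)))
  jsonlite::write_json(man, file.path(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(man)
}

#' Simulate a full synthetic cohort to disk
#'
#' Writes, for every subject: the tone sequence (TSV) and the epoch set
#' (serialized `.rds`, a run-time artifact); plus the clinical table (TSV),
#' the ground-truth effect log (JSON), and a stage manifest with file
#' digests.
#'
#' @param cfg configuration list (see [default_config()]).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
pipeline_simulate <- function(cfg = default_config(), out_dir) {
  validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  obj <- config_objects(cfg)
  cohort <- gen_cohort(obj$cohort, derive_seed(cfg$seed, 0))
  ct_path <- file.path(out_dir, "cohort.tsv")
  utils::write.table(cohort, ct_path, sep = "\t", row.names = FALSE, quote = FALSE)
  files <- ct_path
  truth <- list()
  for (i in seq_len(nrow(cohort))) {
    tones <- gen_tone_sequence(obj$paradigm, derive_seed(cfg$seed, i))
    traj <- hgf_filter(tones, hgf_params(omega2 = cfg$hgf$omega2,
                                         omega3 = cfg$hgf$omega3))
    epochs <- gen_subject_eeg(tones, traj, obj$effects, obj$noise,
                              obj$paradigm,
                              subject_scale = cohort$effect_scale[i],
                              seed = derive_seed(cfg$seed, 1000 + i))
    tp <- file.path(out_dir, sprintf("%s_tones.tsv", cohort$subject[i]))
    write_tone_sequence(tones, tp)
    ep <- file.path(out_dir, sprintf("%s_epochs.rds", cohort$subject[i]))
    saveRDS(epochs, ep)
    files <- c(files, tp, ep)
    truth[[cohort$subject[i]]] <- list(effect_scale = cohort$effect_scale[i],
                                       blink_trials = epochs$blink_trials)
  }
  truth_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(list(effects = cfg$effects, subjects = truth),
                       truth_path, auto_unbox = TRUE, digits = NA)
  files <- c(files, truth_path)
  invisible(write_manifest(out_dir, cfg, "simulate", files))
}

preprocess_epochs <- function(epochs, pp) {
  epochs <- reject_blinks(epochs, pp$blink_threshold)
  epochs <- reject_amplitude(epochs, pp$amplitude_threshold)
  flag_and_interpolate_channels(epochs, pp$channel_max_fraction,
                                pp$amplitude_threshold)
}

#' Run the staged analysis on a simulated (or prepared) dataset
#'
#' Executes, per subject: Bayes-optimal HGF fit (or fixed parameters) on the
#' tone sequence, blink/amplitude/bad-channel preprocessing, and first-level
#' GLMs for every configured regressor. Then, per group and regressor:
#' one-sample F maps with permutation cluster inference; group-difference
#' maps; and the CHR ANCOVA of the sensory-pwPE betas against SIPS positive
#' totals. Cluster tables (TSV), trajectories (TSV) and a manifest are
#' written to `out_dir`.
#'
#' @param cfg configuration list.
#' @param data_dir directory produced by [pipeline_simulate()].
#' @param out_dir results directory.
#' @param group_regressors regressors taken to group level (default: first
#'   configured GLM regressor; keep small for speed).
#' @return invisibly, a list with `betas` (per regressor/group), `clusters`,
#'   `ancova`, `cohort`.
#' @export
pipeline_run <- function(cfg = default_config(), data_dir, out_dir,
                         group_regressors = cfg$glm$regressors[1]) {
  validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  obj <- config_objects(cfg)
  cohort <- utils::read.table(file.path(data_dir, "cohort.tsv"),
                              header = TRUE, sep = "\t")
  projector <- NULL; smoother <- NULL
  betas <- list()
  files <- character(0)
  for (i in seq_len(nrow(cohort))) {
    sub <- cohort$subject[i]
    tones <- read_tone_sequence(file.path(data_dir, sprintf("%s_tones.tsv", sub)),
                                isi = cfg$paradigm$isi,
                                p_deviant = cfg$paradigm$p_deviant)
    params <- if (isTRUE(cfg$hgf$fit)) {
      hgf_fit_bayes_optimal(tones,
        list(omega2_prior = cfg$hgf$omega2_prior,
             omega3_prior = cfg$hgf$omega3_prior))$params
    } else hgf_params(omega2 = cfg$hgf$omega2, omega3 = cfg$hgf$omega3)
    traj <- tryCatch(hgf_filter(tones, params), error = function(e)
      stop(sprintf("stage hgf, subject %s: %s", sub, conditionMessage(e)),
           call. = FALSE))
    tj <- file.path(out_dir, sprintf("%s_trajectories.tsv", sub))
    write_trajectories(traj, tj); files <- c(files, tj)
    epochs <- readRDS(file.path(data_dir, sprintf("%s_epochs.rds", sub)))
    epochs <- tryCatch(preprocess_epochs(epochs, cfg$preprocess),
                       error = function(e)
      stop(sprintf("stage preprocess, subject %s: %s", sub, conditionMessage(e)),
           call. = FALSE))
    if (is.null(projector)) {
      projector <- build_projector(epochs$channels, obj$grid)
      smoother <- build_smoother(obj$grid, projector$mask, cfg$glm$fwhm)
    }
    betas[[sub]] <- tryCatch(
      subject_first_level(epochs, traj, group_regressors, obj$grid,
                          cfg$glm$fwhm, projector, smoother, tones),
      error = function(e)
        stop(sprintf("stage first-level, subject %s: %s", sub,
                     conditionMessage(e)), call. = FALSE))
  }
  hc <- cohort$subject[cohort$group == "HC"]
  chr <- cohort$subject[cohort$group == "CHR"]
  clusters <- list()
  for (rg in group_regressors) {
    for (gname in c("HC", "CHR")) {
      subs <- if (gname == "HC") hc else chr
      if (length(subs) < 3) next
      map <- one_sample_F(lapply(subs, function(s) betas[[s]][[rg]]))
      cl <- cluster_inference(map, cfg$inference$cdt_p, cfg$inference$alpha,
                              cfg$inference$n_perm,
                              seed = derive_seed(cfg$seed, 5000),
                              connectivity = cfg$inference$connectivity)
      key <- sprintf("%s_%s", rg, gname)
      clusters[[key]] <- cl
      p <- file.path(out_dir, sprintf("clusters_%s.tsv", key))
      write_cluster_table(cl, p); files <- c(files, p)
    }
    if (length(hc) >= 2 && length(chr) >= 2) {
      dmap <- group_difference(lapply(hc, function(s) betas[[s]][[rg]]),
                               lapply(chr, function(s) betas[[s]][[rg]]))
      cl <- cluster_inference(dmap, cfg$inference$cdt_p, cfg$inference$alpha,
                              cfg$inference$n_perm,
                              seed = derive_seed(cfg$seed, 6000),
                              connectivity = cfg$inference$connectivity)
      key <- sprintf("%s_groupdiff", rg)
      clusters[[key]] <- cl
      p <- file.path(out_dir, sprintf("clusters_%s.tsv", key))
      write_cluster_table(cl, p); files <- c(files, p)
    }
  }
  # ANCOVA: CHR betas on the first group regressor vs SIPS positive totals
  anc <- NULL
  if (length(chr) >= 4) {
    rg <- group_regressors[1]
    des <- cohort[cohort$group == "CHR", c("subject", "sips_positive")]
    amap <- ancova_map(lapply(chr, function(s) betas[[s]][[rg]]),
                       des, "sips_positive")
    acl <- cluster_inference(amap, cfg$inference$cdt_p, cfg$inference$alpha,
                             cfg$inference$n_perm,
                             seed = derive_seed(cfg$seed, 7000),
                             connectivity = cfg$inference$connectivity)
    key <- sprintf("%s_ancova", rg)
    p <- file.path(out_dir, sprintf("clusters_%s.tsv", key))
    write_cluster_table(acl, p); files <- c(files, p)
    anc <- list(map = amap, clusters = acl)
    clusters[[key]] <- acl
  }
  man <- write_manifest(out_dir, cfg, "run", files,
                        warnings = paste("group difference computed as unpaired",
                                         "two-sample t (protocol wording: paired)"))
  invisible(list(betas = betas, clusters = clusters, ancova = anc,
                 cohort = cohort, manifest = man))
}

#' Re-run the ANCOVA excluding named subjects
#'
#' Stability harness mirroring a converter-exclusion re-analysis: drops the
#' listed subjects (by default the three CHR with the highest covariate
#' values), refits the covariate map and cluster table, and returns both.
#'
#' @param betas named list of per-subject `beta_map` lists (from
#'   [pipeline_run()]'s return value), one regressor selected via `regressor`.
#' @param design data.frame with `subject` and the covariate column.
#' @param covariate covariate column name.
#' @param regressor which regressor's betas to use.
#' @param exclude subject ids to drop (default: 3 highest covariate values).
#' @param ... passed to [cluster_inference()].
#' @return list with `map`, `clusters`, `excluded`.
#' @export
ancova_excluding <- function(betas, design, covariate, regressor,
                             exclude = NULL, ...) {
  if (is.null(exclude)) {
    ord <- order(-design[[covariate]])
    exclude <- design$subject[ord[seq_len(min(3, nrow(design) - 4))]]
  }
  keep <- !design$subject %in% exclude
  des <- design[keep, , drop = FALSE]
  map <- ancova_map(lapply(des$subject, function(s) betas[[s]][[regressor]]),
                    des, covariate)
  cl <- cluster_inference(map, ...)
  list(map = map, clusters = cl, excluded = exclude)
}

#' Render a plain-figure report from a results directory
#'
#' Writes PNG maximum-intensity projections for every cluster table's
#' statistic map when available, and a markdown summary of all cluster
#' tables (including explicit "no significant clusters" sections for empty
#' tables).
#'
#' @param results a [pipeline_run()] return value.
#' @param out_dir directory for the report files.
#' @return invisibly, the path of the markdown summary.
#' @export
pipeline_report <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  md <- file.path(out_dir, "report.md")
  con <- file(md, "w")
  on.exit(close(con))
  writeLines("# Group-level cluster report", con)
  for (key in names(results$clusters)) {
    cl <- results$clusters[[key]]
    writeLines(sprintf("\n## %s", key), con)
    if (nrow(cl) == 0 || !any(cl$significant)) {
      writeLines("No significant clusters.", con)
    } else {
      sig <- cl[cl$significant, , drop = FALSE]
      for (i in seq_len(nrow(sig)))
        writeLines(sprintf(
          "- cluster %d: extent %d voxels, peak stat %.2f at (%.1f, %.1f) mm, %d ms; window %d-%d ms; p_cluster(FWE) = %.4f, p_peak(FWE) = %.4f",
          sig$cluster[i], sig$extent[i], sig$peak_stat[i], sig$peak_x[i],
          sig$peak_y[i], round(sig$peak_ms[i]), round(sig$t_start_ms[i]),
          round(sig$t_end_ms[i]), sig$p_cluster_fwe[i], sig$p_peak_fwe[i]), con)
    }
  }
  if (!is.null(results$ancova)) {
    png_path <- file.path(out_dir, "mip_ancova.png")
    grDevices::png(png_path, width = 700, height = 400)
    mip <- max_intensity_projection(results$ancova$map)
    graphics::image(x = results$ancova$map$grid$ts,
                    y = results$ancova$map$grid$ys,
                    z = t(mip), xlab = "peristimulus time (ms)",
                    ylab = "posterior-anterior (mm)",
                    main = "ANCOVA F, maximum-intensity projection",
                    useRaster = TRUE)
    grDevices::dev.off()
  }
  invisible(md)
}
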