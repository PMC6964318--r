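#' Default run configuration
#'
#' Fully serialisable configuration for a complete synthetic-cohort run:
#' phantom geometry, acquisition, cold-effect response, composition
#' constants, analysis thresholds and clustering settings. Every pipeline
#' run writes its resolved configuration beside its outputs.
#'
#' @param seed Base seed; per-subject and per-stage seeds derive from it.
#' @return Plain nested list, directly serialisable to JSON.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    phantom = list(shape = c(64, 64, 16), voxel_volume = 0.548,
                   n_subjects = 9),
    acquisition = list(te_first = 1.98e-3, delta_te = 1.75e-3, n_echoes = 6,
                       field_strength = 3, noise_sd = 0),
    cold = unclass(cold_effect_params()),
    constants = unclass(composition_constants()),
    analysis = list(lower_min = 30, sweep_step = 1, hist_bin = 0.5,
                    change_bin = 10,
                    ranges = list(c(30, 100), c(50, 100), c(70, 100)),
                    sat_range = c(70, 100)),
    smoothing = list(k = 3, three_d = FALSE),
    clustering = list(k_max = 8, variance_cutoff = 0.95, n_restarts = 10),
    simulate = list(use_recon = FALSE, ff_noise_sd = 0.003,
                    t2_noise_sd = 0.2))
}

#' Simulate a pre/post-cooling cohort
#'
#' Generates one phantom per subject, applies the cold effect, and returns
#' per-subject FF and T2* maps at both time points together with the depot
#' and subcutaneous-control ROIs. With `use_recon = TRUE` each time point is
#' pushed through the full acquisition simulation and water-fat
#' reconstruction; otherwise the truth maps are used with additive Gaussian
#' measurement noise at the level the reconstruction delivers, which
#' exercises the analysis stages at a fraction of the cost.
#'
#' @param config Configuration list as produced by `default_config`.
#' @return List of subjects; each has `ff_pre`, `ff_post`, `t2_pre`,
#'   `t2_post`, `roi_pre`, `roi_post`, `sat_roi` and the phantom pair.
#' @export
simulate_cohort <- function(config = default_config()) {
  n <- config$phantom$n_subjects
  acq <- do.call(acquisition_params, config$acquisition)
  cold <- do.call(cold_effect_params, config$cold)
  lapply(seq_len(n), function(s) {
    seed_s <- config$seed + 1000L * s
    ph_pre <- generate_phantom(config$phantom$shape, seed = seed_s,
                               voxel_volume = config$phantom$voxel_volume)
    ph_post <- apply_cold_effect(ph_pre, cold, seed = seed_s + 1L)
    vv <- config$phantom$voxel_volume
    if (isTRUE(config$simulate$use_recon)) {
      maps_pre <- reconstruct_maps(simulate_echo_series(ph_pre, acq,
                                                        seed = seed_s + 2L))
      maps_post <- reconstruct_maps(simulate_echo_series(ph_post, acq,
                                                         seed = seed_s + 3L))
      ff_pre <- zero_na(maps_pre$ff); ff_post <- zero_na(maps_post$ff)
      t2_pre <- zero_na(maps_pre$t2star); t2_post <- zero_na(maps_post$t2star)
    } else {
      set.seed(seed_s + 4L)
      nsd <- config$simulate$ff_noise_sd
      tsd <- config$simulate$t2_noise_sd
      addn <- function(m, sd) if (sd > 0)
        clamp(m + stats::rnorm(length(m), sd = sd), 0, Inf) else m
      ff_pre <- clamp(addn(ph_pre$ff_true, nsd), 0, 1)
      ff_post <- clamp(addn(ph_post$ff_true, nsd), 0, 1)
      t2_pre <- addn(ph_pre$t2s_true, tsd)
      t2_post <- addn(ph_post$t2s_true, tsd)
    }
    list(subject = s,
         ff_pre = ff_pre, ff_post = ff_post,
         t2_pre = t2_pre, t2_post = t2_post,
         roi_pre = roi_mask(ph_pre$roi, vv, "supraclavicular"),
         roi_post = roi_mask(ph_post$roi, vv, "supraclavicular"),
         sat_roi = roi_mask(ph_pre$sat_roi, vv, "deltoid SAT"),
         phantom_pre = ph_pre, phantom_post = ph_post)
  })
}

## ---- NIfTI / JSON glue -----------------------------------------------

#' Write a 3-D map as NIfTI
#'
#' @param arr 3-D array.
#' @param path Output path (.nii or .nii.gz).
#' @param spacing Voxel spacing in mm (isotropic 1.1 mm default).
#' @export
write_map_nifti <- function(arr, path, spacing = c(1.1, 1.1, 1.1)) {
  img <- RNifti::asNifti(arr * 1)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI map as a plain array
#' @param path NIfTI file.
#' @return Numeric array.
#' @export
read_map_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  attributes(arr) <- list(dim = dim(arr))
  arr
}

#' Write an echo series as 4-D NIfTI plus JSON sidecar
#'
#' The complex series is stored as a real/imaginary file pair; the sidecar
#' records echo times, field strength, fat spectrum, noise level, seed and
#' voxel volume, sufficient to reconstruct without the originating R
#' session.
#'
#' @param echoes A `bat_echoes`.
#' @param prefix Path prefix; writes `<prefix>_real.nii.gz`,
#'   `<prefix>_imag.nii.gz`, `<prefix>.json`.
#' @export
write_echo_series <- function(echoes, prefix) {
  RNifti::writeNifti(RNifti::asNifti(Re(echoes$data)),
                     paste0(prefix, "_real.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(Im(echoes$data)),
                     paste0(prefix, "_imag.nii.gz"))
  side <- list(te = echoes$te,
               field_strength = echoes$acq$field_strength,
               fat_peaks = echoes$acq$fat_peaks,
               noise_sd = echoes$acq$noise_sd,
               voxel_volume = echoes$voxel_volume,
               seed = echoes$seed)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read an echo series written by `write_echo_series`
#' @param prefix Path prefix used when writing.
#' @return A `bat_echoes`.
#' @export
read_echo_series <- function(prefix) {
  re <- as.array(RNifti::readNifti(paste0(prefix, "_real.nii.gz")))
  im <- as.array(RNifti::readNifti(paste0(prefix, "_imag.nii.gz")))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  te <- side$te
  acq <- acquisition_params(te_first = te[1], delta_te = te[2] - te[1],
                            n_echoes = length(te),
                            field_strength = side$field_strength,
                            fat_peaks = as.data.frame(side$fat_peaks),
                            noise_sd = side$noise_sd)
  dat <- array(complex(real = re, imaginary = im), dim = dim(re))
  structure(list(data = dat, te = te, acq = acq,
                 voxel_volume = side$voxel_volume, seed = side$seed),
            class = "bat_echoes")
}

## ---- pipeline ---------------------------------------------------------

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the requested stages in order — simulate, reconstruct (folded
#' into simulate when `use_recon` is set), global, mass_energy, local —
#' writing the declared artifacts (CSV tables, sweep grids, cluster report,
#' resolved configuration) under `out_dir`. Reruns with the same
#' configuration regenerate identical outputs. A stage whose inputs are
#' missing fails with an error naming the stage to rerun.
#'
#' @param config Configuration list from `default_config`.
#' @param stages Character subset of
#'   `c("simulate", "global", "mass_energy", "local")`.
#' @param out_dir Output directory (created if needed); NULL for no files.
#' @param state Optional state list from a previous partial run.
#' @return Invisibly, the run report: a list with the cohort summaries,
#'   sweep grids, composition tables, cluster result and file manifest.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("simulate", "global", "mass_energy",
                                    "local"),
                         out_dir = NULL, state = list()) {
  t_start <- Sys.time()
  allowed <- c("simulate", "global", "mass_energy", "local")
  stopifnot(all(stages %in% allowed))
  report <- list(config = config, timings = list())
  need_cohort <- function() {
    if (is.null(state$cohort))
      stop("missing cohort maps: rerun stage 'simulate' first")
    state$cohort
  }
  emit <- function(df, name) {
    if (!is.null(out_dir))
      utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)

  if ("simulate" %in% stages) {
    t0 <- Sys.time()
    state$cohort <- simulate_cohort(config)
    report$timings$simulate <- as.numeric(Sys.time() - t0, units = "secs")
  }

  constants <- do.call(composition_constants, config$constants)

  if ("global" %in% stages) {
    t0 <- Sys.time()
    cohort <- need_cohort()
    ranges <- lapply(config$analysis$ranges,
                     function(r) threshold_range(r[1], r[2]))
    summaries <- do.call(rbind, lapply(cohort, function(sub) {
      do.call(rbind, lapply(ranges, function(rng) {
        rbind(cbind(subject = sub$subject,
                    depot_summary(sub$ff_pre, sub$t2_pre, sub$roi_pre, rng,
                                  "thermoneutral")),
              cbind(subject = sub$subject,
                    depot_summary(sub$ff_post, sub$t2_post, sub$roi_post,
                                  rng, "post_cooling")))
      }))
    }))
    sat_rng <- threshold_range(config$analysis$sat_range[1],
                               config$analysis$sat_range[2])
    sat <- do.call(rbind, lapply(cohort, function(sub) {
      rbind(cbind(subject = sub$subject,
                  depot_summary(sub$ff_pre, sub$t2_pre, sub$sat_roi,
                                sat_rng, "thermoneutral")),
            cbind(subject = sub$subject,
                  depot_summary(sub$ff_post, sub$t2_post, sub$sat_roi,
                                sat_rng, "post_cooling")))
    }))
    tests <- do.call(rbind, lapply(ranges, function(rng) {
      per <- lapply(c("volume", "ff", "t2star"), function(q) {
        pg <- paired_global_change(cohort, rng, q)
        st <- pg$stats
        data.frame(quantity = q, lower = rng$lower, upper = rng$upper,
                   mean_pre = st$mean_pre, mean_post = st$mean_post,
                   mean_diff = st$mean_diff, p = st$p,
                   significant = st$significant)
      })
      do.call(rbind, per)
    }))
    sat_stats <- paired_stats(
      sat$ff_glob[sat$timepoint == "thermoneutral"],
      sat$ff_glob[sat$timepoint == "post_cooling"])
    hist_pre <- volume_histogram(cohort[[1]]$ff_pre, cohort[[1]]$roi_pre,
                                 config$analysis$hist_bin,
                                 threshold_range(config$analysis$lower_min,
                                                 100))
    binned <- binned_volume_change(cohort, config$analysis$change_bin,
                                   threshold_range(config$analysis$lower_min,
                                                   100))
    sweeps <- lapply(c("volume", "ff", "t2star"), function(q)
      threshold_sweep(cohort, q, step = config$analysis$sweep_step,
                      lower_min = config$analysis$lower_min))
    names(sweeps) <- c("volume", "ff", "t2star")
    emit(summaries, "depot_summaries")
    emit(sat, "sat_summaries")
    emit(tests, "paired_tests")
    emit(binned, "binned_volume_change")
    emit(hist_pre, "volume_histogram_subject1_pre")
    if (!is.null(out_dir))
      for (q in names(sweeps))
        emit(as.data.frame(sweeps[[q]]$delta), paste0("sweep_", q))
    report$global <- list(summaries = summaries, sat = sat, tests = tests,
                          sat_stats = sat_stats, binned = binned,
                          sweeps = sweeps)
    state$global <- report$global
    report$timings$global <- as.numeric(Sys.time() - t0, units = "secs")
  }

  if ("mass_energy" %in% stages) {
    t0 <- Sys.time()
    cohort <- need_cohort()
    rng <- threshold_range(config$analysis$lower_min, 100)
    comp <- do.call(rbind, lapply(cohort, function(sub) {
      rbind(cbind(subject = sub$subject, timepoint = "thermoneutral",
                  depot_totals(sub$ff_pre, sub$roi_pre, rng,
                               constants)$totals),
            cbind(subject = sub$subject, timepoint = "post_cooling",
                  depot_totals(sub$ff_post, sub$roi_post, rng,
                               constants)$totals))
    }))
    egrid <- energy_threshold_grid(cohort, constants,
                                   step = config$analysis$sweep_step,
                                   lower_min = config$analysis$lower_min)
    pre <- comp[comp$timepoint == "thermoneutral", ]
    r2 <- if (nrow(pre) >= 3) list(
      fat = mass_volume_r2(pre$tissue_volume_ml, pre$fat_mass_g),
      lean = mass_volume_r2(pre$tissue_volume_ml, pre$lean_mass_g))
    else NULL
    energy_stats <- paired_stats(
      comp$total_energy_kcal[comp$timepoint == "thermoneutral"],
      comp$total_energy_kcal[comp$timepoint == "post_cooling"])
    emit(comp, "composition_totals")
    if (!is.null(out_dir)) {
      emit(as.data.frame(egrid$delta), "sweep_energy")
      jsonlite::write_json(list(constants = unclass(constants), r2 = r2),
                           file.path(out_dir, "mass_energy_meta.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    report$mass_energy <- list(composition = comp, energy_grid = egrid,
                               r2 = r2, energy_stats = energy_stats)
    report$timings$mass_energy <- as.numeric(Sys.time() - t0,
                                             units = "secs")
  }

  if ("local" %in% stages) {
    t0 <- Sys.time()
    cohort <- need_cohort()
    tabs <- lapply(cohort, function(sub) {
      voxel_deltas(list(ff = sub$ff_pre, t2star = sub$t2_pre),
                   list(ff = sub$ff_post, t2star = sub$t2_post),
                   sub$roi_pre, field = NULL, k = config$smoothing$k,
                   three_d = config$smoothing$three_d)
    })
    pooled <- do.call(rbind, tabs)
    jh <- joint_histogram(pooled$ff_pre, pooled$dff)
    clus <- cluster_elbow(pooled, columns = c("ff_pre", "dff"),
                          k_max = config$clustering$k_max,
                          variance_cutoff = config$clustering$variance_cutoff,
                          seed = config$seed,
                          n_restarts = config$clustering$n_restarts)
    emit(pooled, "voxel_pairs")
    if (!is.null(out_dir)) {
      emit(as.data.frame(jh$counts), "joint_histogram_ffpre_dff")
      jsonlite::write_json(
        list(k_selected = clus$k_selected,
             explained_variance = clus$explained_variance_curve,
             centroids = as.data.frame(clus$centroids),
             summary = clus$summary, seed = clus$seed,
             n_restarts = clus$n_restarts),
        file.path(out_dir, "cluster_report.json"),
        auto_unbox = TRUE, digits = NA)
    }
    report$local <- list(pooled = pooled, joint_histogram = jh,
                         clusters = clus)
    report$timings$local <- as.numeric(Sys.time() - t0, units = "secs")
  }

  report$elapsed <- as.numeric(Sys.time() - t_start, units = "secs")
  if (!is.null(out_dir))
    jsonlite::write_json(list(seed = config$seed, stages = stages,
                              config = config,
                              timings = report$timings,
                              r_version = R.version.string),
                         file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA)
  attr(report, "state") <- state
  invisible(report)
}
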