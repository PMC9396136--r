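# End-to-end pipeline: generate (or load) -> scale -> IK -> ID -> static
# optimization -> knee contact -> EMG validation -> tables + SPM, with a
# results bundle on disk and a machine-readable run manifest.

#' Pipeline configuration
#'
#' @param mode `"synthetic"` (generate a cohort from `spec`) or
#'   `"directory"` (read a cohort written by [generate_cohort()] from
#'   `data_dir`).  Exactly one input mode must be active.
#' @param spec A `cohort_spec` (synthetic mode).
#' @param data_dir Cohort directory (directory mode).
#' @param out_dir Output directory for the results bundle.
#' @param seed Integer seed recorded in the manifest and used for every
#'   stochastic stage.
#' @param alpha Significance level for tables and SPM.
#' @param welch Use Welch t-tests.
#' @param spm_method `"rft"` or `"perm"`.
#' @param strict_emg_band Error when the EMG band edge reaches Nyquist.
#' @param marker_filter_hz,angle_filter_hz Zero-lag low-pass cutoffs.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "directory"),
                            spec = cohort_spec(), data_dir = NULL,
                            out_dir = tempfile("squatmech_run_"),
                            seed = 1, alpha = 0.05, welch = FALSE,
                            spm_method = "rft", strict_emg_band = FALSE,
                            marker_filter_hz = 6, angle_filter_hz = 6) {
  mode <- match.arg(mode)
  if (mode == "synthetic" && !is.null(data_dir)) {
    stop_squatmech("exactly one input mode: synthetic spec OR data_dir",
                   "config_error")
  }
  if (mode == "directory" && is.null(data_dir)) {
    stop_squatmech("directory mode requires data_dir", "config_error")
  }
  structure(list(mode = mode, spec = spec, data_dir = data_dir,
                 out_dir = out_dir, seed = as.integer(seed), alpha = alpha,
                 welch = welch, spm_method = spm_method,
                 strict_emg_band = strict_emg_band,
                 marker_filter_hz = marker_filter_hz,
                 angle_filter_hz = angle_filter_hz),
            class = "pipeline_config")
}

# Normalize an envelope sampled at the EMG rate onto the squat cycle
# segmented at the marker rate.
.emg_to_cycle <- function(env, emg_rate, seg, marker_rate) {
  to_emg <- function(i) {
    max(1L, min(length(env), round((i - 1) / marker_rate * emg_rate) + 1L))
  }
  seg_e <- structure(list(start = to_emg(seg$start),
                          deepest = to_emg(seg$deepest),
                          end = to_emg(seg$end)),
                     class = "phase_segmentation")
  time_normalize(env, seg_e)
}

#' Process one squat trial through the full analysis chain
#'
#' IK, cycle segmentation, inverse dynamics, static optimization, knee
#' contact decomposition, EMG envelope extraction and model validation,
#' all time-normalized to the 101-point cycle.
#'
#' @param model The participant's scaled `squat_model`.
#' @param trial A `squat_trial`.
#' @param config A `pipeline_config` (filter/EMG settings).
#' @return List of cycle curves (`angles`, `moments` N m/kg, `contact`
#'   N/kg, `activations`, `emg`), the `validation` table, the raw-time
#'   results and a named `metrics` vector.
#' @export
process_trial <- function(model, trial, config = pipeline_config()) {
  angles <- inverse_kinematics(model, trial,
                               filter_cutoff_hz = config$marker_filter_hz)
  seg <- segment_cycle(angles[, "knee_flexion"])
  id <- inverse_dynamics(model, angles, trial$grf, trial$load$barbell_kg,
                         filter_cutoff_hz = config$angle_filter_hz)
  act <- static_optimization(model, id$moments, id$angles_filtered)
  contact <- contact_force_curves(model, id, act, id$angles_filtered,
                                  trial$load$barbell_kg)
  mass <- model$participant$mass_kg
  angles_cycle <- time_normalize(angles, seg, units = "deg",
                                 quantity = "joint angles")
  moments_cycle <- time_normalize(
    normalize_load(id$moments, mass, trial$load$barbell_kg), seg,
    units = "N m/kg", quantity = "joint moments")
  contact_cycle <- time_normalize(attr(contact, "normalized"), seg,
                                  units = "N/kg",
                                  quantity = "knee contact forces")
  act_cycle <- time_normalize(act$activations, seg, units = "0-1",
                              quantity = "muscle activations")

  emg_cycle <- NULL
  validation <- NULL
  # EMG validation needs both the squat EMG and the MVC reference bout
  if (!is.null(trial$emg) && !is.null(trial$mvc)) {
    emg_mus <- setdiff(names(trial$emg), "time")
    env <- matrix(0, 101, length(emg_mus),
                  dimnames = list(NULL, emg_mus))
    for (mu in emg_mus) {
      filt <- emg_bandpass(trial$emg[[mu]], trial$emg_rate,
                           strict = config$strict_emg_band)
      rms <- emg_rms_envelope(filt, trial$emg_rate)
      mvc_rms <- sqrt(mean(emg_bandpass(trial$mvc[[mu]], trial$emg_rate,
                                        strict = config$strict_emg_band)^2))
      act_n <- normalize_mvc(rms, mvc_rms)
      env[, mu] <- .emg_to_cycle(act_n, trial$emg_rate, seg,
                                 trial$marker_rate)
    }
    emg_cycle <- env
    validation <- validate_activations(env, act_cycle)
  }

  metrics <- c(peak_angles(angles_cycle),
               range_of_motion(angles_cycle),
               peak_moments(moments_cycle),
               peak_contact_forces(contact_cycle))
  list(angles = angles_cycle, moments = moments_cycle,
       contact = contact_cycle, activations = act_cycle,
       emg = emg_cycle, validation = validation,
       segmentation = seg, metrics = metrics,
       raw = list(angles = angles, id = id, act = act, contact = contact))
}

# Assemble the in-memory cohort (participants + true models + trials)
# for synthetic mode, mirroring generate_cohort() seed-for-seed.
.synthetic_cohort <- function(spec) {
  out <- list()
  for (gi in seq_along(c("valgus", "normal"))) {
    group <- c("valgus", "normal")[gi]
    for (i in seq_len(spec$n_per_group)) {
      pseed <- derive_seed(spec$seed, gi, i)
      p <- generate_participant(
        group, pseed,
        id = sprintf("%s%02d", toupper(substr(group, 1, 1)), i),
        spec = spec)
      model <- build_true_model(p)
      static <- generate_static_trial(p, model, spec,
                                      seed = derive_seed(pseed, 9L))
      trials <- list()
      for (li in seq_along(spec$loads)) {
        load <- load_condition(spec$loads[li], p$onerm_kg)
        for (tr in seq_len(spec$trials)) {
          trials[[length(trials) + 1L]] <- generate_squat_trial(
            p, load, model, spec, seed = derive_seed(pseed, li, tr))
        }
      }
      out[[p$id]] <- list(participant = p, static = static, trials = trials)
    }
  }
  out
}

# Load a cohort written by generate_cohort().
.directory_cohort <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) {
    stop_squatmech(sprintf("no manifest.json in '%s'", dir), "io_error")
  }
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  tab <- man$trials_table
  out <- list()
  for (pid in unique(tab$participant)) {
    rows <- tab[tab$participant == pid, ]
    p <- participant(pid, rows$mass_kg[1], rows$height_m[1],
                     rows$valgus_deg[1], rows$onerm_kg[1])
    mk_static <- read_trc(file.path(dir, rows$static_trc[1]))
    static <- structure(list(markers = mk_static,
                             marker_rate = attr(mk_static, "rate_hz"),
                             participant_id = pid),
                        class = "squat_trial")
    trials <- lapply(seq_len(nrow(rows)), function(k) {
      mk <- read_trc(file.path(dir, rows$trc[k]))
      structure(list(
        markers = mk, marker_rate = attr(mk, "rate_hz"),
        grf = utils::read.csv(file.path(dir, rows$grf[k])),
        grf_rate = attr(mk, "rate_hz"),
        emg = utils::read.csv(file.path(dir, rows$emg[k])),
        emg_rate = 1000, mvc = NULL,
        load = list(fraction = rows$load[k],
                    barbell_kg = rows$load[k] * rows$onerm_kg[k]),
        participant_id = pid), class = "squat_trial")
    })
    out[[pid]] <- list(participant = p, static = static, trials = trials)
  }
  out
}

#' Run the full analysis pipeline
#'
#' Generates (or reads) the cohort, scales each participant's model
#' against their static trial (enforcing the marker-residual gates),
#' processes every trial, and writes the results bundle: scaling
#' reports, per-participant mean cycle curves, the EMG-vs-optimization
#' validation table, the four group-comparison metrics tables, SPM
#' results for the angle/moment/contact curve families, and a JSON run
#' manifest echoing the seed and configuration.
#'
#' @param config A `pipeline_config`.
#' @return Results bundle (list), invisibly: `tables`, `spm`,
#'   `scaling`, `validation`, `metrics`, `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    stop_squatmech("config must be a pipeline_config", "config_error")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- if (config$mode == "synthetic") {
    .synthetic_cohort(config$spec)
  } else {
    .directory_cohort(config$data_dir)
  }

  scaling_rows <- list()
  metric_rows <- list()
  validation_rows <- list()
  curve_store <- list()  # curve_store[[family]][[dof]][[load]][[group]] row-bound

  for (pid in names(cohort)) {
    entry <- cohort[[pid]]
    p <- entry$participant
    base <- build_default_model(p)
    sc <- scale_model(base, entry$static)
    model <- sc$model
    model$participant <- p
    scaling_rows[[pid]] <- data.frame(
      participant = pid, group = p$group,
      rms_m = sc$report$marker_rms_m, max_m = sc$report$marker_max_m,
      pass = sc$report$pass, stringsAsFactors = FALSE)

    by_load <- split(entry$trials,
                     vapply(entry$trials, function(tr) tr$load$fraction,
                            numeric(1)))
    for (ld in names(by_load)) {
      res <- lapply(by_load[[ld]], process_trial, model = model,
                    config = config)
      mm <- rowMeans(vapply(res, function(r) r$metrics,
                            numeric(length(res[[1]]$metrics))))
      metric_rows[[length(metric_rows) + 1L]] <- data.frame(
        participant = pid, group = p$group, load = as.numeric(ld),
        metric = names(mm), value = unname(mm), stringsAsFactors = FALSE)
      for (r in res) {
        if (!is.null(r$validation)) {
          v <- r$validation
          v$participant <- pid
          v$load <- as.numeric(ld)
          validation_rows[[length(validation_rows) + 1L]] <- v
        }
      }
      for (fam in c("angles", "moments", "contact")) {
        mean_curves <- Reduce(`+`, lapply(res, `[[`, fam)) / length(res)
        for (dof in colnames(mean_curves)) {
          curve_store[[fam]][[dof]][[ld]][[p$group]] <- rbind(
            curve_store[[fam]][[dof]][[ld]][[p$group]],
            mean_curves[, dof])
        }
      }
    }
  }

  metrics <- do.call(rbind, metric_rows)
  tables <- build_tables(metrics, alpha = config$alpha,
                         welch = config$welch)

  spm_results <- list()
  can_spm <- length(unique(metrics$participant[metrics$group == "valgus"])) >= 2 &&
    length(unique(metrics$participant[metrics$group == "normal"])) >= 2
  if (can_spm) {
    for (fam in names(curve_store)) {
      for (dof in names(curve_store[[fam]])) {
        for (ld in names(curve_store[[fam]][[dof]])) {
          gs <- curve_store[[fam]][[dof]][[ld]]
          if (is.null(gs$valgus) || is.null(gs$normal)) next
          key <- sprintf("%s.%s.load%s", fam, dof, ld)
          spm_results[[key]] <- spm_ttest_curves(
            gs$valgus, gs$normal, alpha = config$alpha,
            method = config$spm_method,
            seed = derive_seed(config$seed, 77L))
        }
      }
    }
  }

  scaling <- do.call(rbind, scaling_rows)
  validation <- if (length(validation_rows)) {
    do.call(rbind, validation_rows)
  } else NULL

  od <- config$out_dir
  write_unit_csv <- function(df, path, unit_note) {
    con <- file(path, "w")
    writeLines(paste0("# ", unit_note), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  write_unit_csv(scaling, file.path(od, "scaling_reports.csv"),
                 "units: m (marker residuals)")
  write_unit_csv(metrics, file.path(od, "participant_metrics.csv"),
                 "units: deg (angles/ROM), N m/kg (moments), N/kg (contact)")
  write_unit_csv(as.data.frame(tables), file.path(od, "metrics_tables.csv"),
                 "units: deg (angles/ROM), N m/kg (moments), N/kg (contact)")
  if (!is.null(validation)) {
    write_unit_csv(validation, file.path(od, "validation.csv"),
                   "units: dimensionless (Pearson r, RMSE on 0-1 activation)")
  }
  spm_json <- lapply(spm_results, function(s) {
    list(t_crit = s$t_crit, alpha = s$alpha, fwhm = s$fwhm,
         method = s$method, df = s$df,
         clusters = lapply(s$clusters, as.list))
  })
  jsonlite::write_json(spm_json, file.path(od, "spm_results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (length(spm_results)) {
    tcurves <- as.data.frame(lapply(spm_results, `[[`, "t"))
    names(tcurves) <- names(spm_results)
    tcurves <- cbind(pct = 0:100, tcurves)
    write_unit_csv(tcurves, file.path(od, "spm_t_curves.csv"),
                   "units: t-statistic per % cycle")
  }
  manifest <- list(
    package = "squatmech",
    version = as.character(utils::packageVersion("squatmech")),
    r_version = R.version.string,
    seed = config$seed,
    mode = config$mode,
    alpha = config$alpha,
    spm_method = config$spm_method,
    n_participants = length(cohort),
    scaling_gates = list(rms_m = 0.02, max_m = 0.04,
                         all_pass = all(scaling$pass))
  )
  jsonlite::write_json(manifest, file.path(od, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(tables = tables, spm = spm_results, scaling = scaling,
                 validation = validation, metrics = metrics,
                 out_dir = od))
}
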