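#' Run configuration registry
#'
#' Collects every numeric default of the two analysis pipelines in one
#' place; each run serializes its effective configuration next to its
#' outputs. Defaults: E-field threshold 0.2 V/mm, conductivity 0.14 S/m,
#' coverage fraction 0.2, FD threshold 0.5 mm in > 50\% of volumes,
#' smoothing FWHM 6 mm, passband 0.01-0.08 Hz, 1000 permutations.
#'
#' @param seed master seed of the run.
#' @param n_patients,noise_sd,max_improvement synthetic cohort settings
#'   (see [cohort_spec()]).
#' @param efield_threshold,conductivity,mode stimulation-volume model
#'   settings.
#' @param min_coverage sweetspot coverage gate.
#' @param fd_threshold,fd_fraction motion QC settings.
#' @param fwhm,band,gsr connectome preprocessing settings.
#' @param n_subjects,n_violators,n_volumes,tr synthetic connectome
#'   settings (see [connectome_spec()]).
#' @param n_perm permutations for both validations.
#' @param volumes_dir,cohort_table optional paths to user-supplied
#'   stimulation volumes and cohort table; when `NULL` the synthetic
#'   generator is used.
#' @param improvement_model `"overlap"` (planted-sweetspot coverage) or
#'   `"network"` (connectivity to the first planted network) for the
#'   synthetic cohort of the network pipeline.
#' @return A `"run_config"` list.
#' @export
run_config <- function(seed = 42L, n_patients = 20L, noise_sd = 10,
                       max_improvement = 60, efield_threshold = 0.2,
                       conductivity = 0.14, mode = "voltage",
                       min_coverage = 0.2, fd_threshold = 0.5,
                       fd_fraction = 0.5, fwhm = 6, band = c(0.01, 0.08),
                       gsr = TRUE, n_subjects = 12L, n_violators = 2L,
                       n_volumes = 60L, tr = 2, n_perm = 1000L,
                       volumes_dir = NULL, cohort_table = NULL,
                       improvement_model = c("overlap", "network")) {
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 noise_sd = noise_sd, max_improvement = max_improvement,
                 efield_threshold = efield_threshold,
                 conductivity = conductivity, mode = mode,
                 min_coverage = min_coverage, fd_threshold = fd_threshold,
                 fd_fraction = fd_fraction, fwhm = fwhm, band = band,
                 gsr = gsr, n_subjects = as.integer(n_subjects),
                 n_violators = as.integer(n_violators),
                 n_volumes = as.integer(n_volumes), tr = tr,
                 n_perm = as.integer(n_perm), volumes_dir = volumes_dir,
                 cohort_table = cohort_table,
                 improvement_model = match.arg(improvement_model)),
            class = "run_config")
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

stage_msg <- function(...) message(format(Sys.time(), "[%H:%M:%S] "), ...)

## load cohort volumes + improvements either from disk or the generator
pipeline_inputs <- function(config) {
  if (!is.null(config$volumes_dir)) {
    dat <- read_cohort(config$volumes_dir)
    imp <- if ("improvement_pct" %in% names(dat$cohort)) {
      dat$cohort$improvement_pct
    } else {
      percent_improvement(dat$cohort$pre_score, dat$cohort$post_score)
    }
    list(volumes = dat$volumes, improvements = imp, cohort = dat$cohort,
         sim = NULL)
  } else {
    spec <- cohort_spec(n_patients = config$n_patients,
                        noise_sd = config$noise_sd,
                        max_improvement = config$max_improvement,
                        seed = config$seed, mode = config$mode)
    sim <- simulate_cohort(spec, efield_threshold = config$efield_threshold,
                           conductivity = config$conductivity)
    list(volumes = sim$volumes, improvements = sim$cohort$improvement_pct,
         cohort = sim$cohort, sim = sim)
  }
}

#' Run the sweetspot analysis end to end
#'
#' Obtains stimulation volumes and improvements (from `config$volumes_dir`
#' or the synthetic generator), fits the T-model, validates it by
#' permutation, computes the centre of gravity, and writes the T-model
#' maps plus a JSON report and a config snapshot into `out_dir`. Reports
#' are a deterministic function of the configuration.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with `model`, `validation`, `cog`, `report`
#'   and `out_dir`.
#' @export
run_sweetspot_pipeline <- function(config = run_config(),
                                   out_dir = tempfile("sweetspot_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_json_report(config[!vapply(config, is.null, TRUE)],
                    file.path(out_dir, "config.json"))
  stage_msg("loading stimulation volumes")
  inp <- pipeline_inputs(config)
  stage_msg("fitting T-model on ", length(inp$volumes), " volumes")
  model <- sweetspot_fit(inp$volumes, inp$improvements,
                         min_coverage = config$min_coverage)
  stage_msg("permutation validation (", config$n_perm, " permutations)")
  val <- validate_sweetspot(model, inp$volumes, inp$improvements,
                            n_perm = config$n_perm, seed = config$seed)
  cog <- sweetspot_cog(model)
  stage_msg("writing outputs to ", out_dir)
  tm <- model$t_map
  tm$data[is.na(tm$data)] <- 0
  write_volume(tm, file.path(out_dir, "t_map.nii.gz"))
  write_volume(model$coverage, file.path(out_dir, "coverage.nii.gz"))
  write_volume(model$included, file.path(out_dir, "included.nii.gz"))
  if (!is.null(inp$sim)) write_cohort(inp$sim, file.path(out_dir, "cohort"))
  report <- c(permutation_report(val),
              list(cog_mm = as.list(cog), n_patients = length(inp$volumes),
                   n_included_voxels = sum(model$included$data)))
  write_json_report(report, file.path(out_dir, "report.json"))
  invisible(list(model = model, validation = val, cog = cog,
                 report = report, out_dir = out_dir))
}

#' Run the network-mapping analysis end to end
#'
#' Simulates (or loads) the cohort, simulates the synthetic connectome
#' cohort, applies motion QC, preprocesses the retained subjects, computes
#' per-patient connectivity fingerprints, fits the R-map, validates it by
#' permutation, and writes the R-map, a QC report and a JSON report into
#' `out_dir`.
#'
#' @inheritParams run_sweetspot_pipeline
#' @return Invisibly, a list with `model`, `validation`, `qc`,
#'   `fingerprints`, `report` and `out_dir`.
#' @export
run_network_pipeline <- function(config = run_config(),
                                 out_dir = tempfile("network_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_json_report(config[!vapply(config, is.null, TRUE)],
                    file.path(out_dir, "config.json"))
  stage_msg("loading stimulation volumes")
  inp <- pipeline_inputs(config)

  cspec <- connectome_spec(n_subjects = config$n_subjects,
                           n_violators = config$n_violators,
                           n_volumes = config$n_volumes, tr = config$tr,
                           seed = config$seed)
  stage_msg("simulating ", cspec$n_subjects, " connectome subjects")
  subjects <- simulate_connectome(cspec)
  qc <- qc_filter(subjects, fd_threshold = config$fd_threshold,
                  volume_fraction = config$fd_fraction)
  stage_msg(length(qc$retained), " subjects retained, ",
            length(qc$excluded), " excluded by motion QC")
  if (!length(qc$retained))
    stop("all connectome subjects were excluded by motion QC ",
         "(FD > ", config$fd_threshold, " mm in > ",
         100 * config$fd_fraction, "% of volumes)")
  stage_msg("preprocessing retained subjects")
  cmats <- lapply(qc$retained, preprocess_subject, fwhm = config$fwhm,
                  band = config$band, global_signal = config$gsr)

  stage_msg("resampling seeds to the connectome grid")
  seeds <- lapply(inp$volumes, function(v)
    resample_to_grid(v$mask, cspec$affine, cspec$shape, method = "nearest"))
  ok <- vapply(seeds, function(s) any(s$data == 1), logical(1))
  if (!all(ok))
    stop("stimulation volume(s) ", paste(which(!ok), collapse = ", "),
         " do not reach the connectome grid")

  improvements <- inp$improvements
  if (is.null(config$volumes_dir) &&
      config$improvement_model == "network") {
    improvements <- network_improvements(
      lapply(seeds, stimulation_volume),
      planted_networks(cspec)[[1]],
      max_improvement = config$max_improvement,
      noise_sd = config$noise_sd, seed = config$seed + 1L)
  }

  stage_msg("computing connectivity fingerprints")
  fingerprints <- lapply(seq_along(seeds), function(i) {
    maps <- lapply(cmats, function(cm) seed_fingerprint(seeds[[i]], cm))
    group_fingerprint(maps, patient_id = inp$cohort$patient_id[i])
  })
  stage_msg("fitting and validating the R-map")
  val <- validate_network_model(fingerprints, improvements,
                                n_perm = config$n_perm, seed = config$seed)
  model <- attr(val, "model")
  stage_msg("writing outputs to ", out_dir)
  rm_out <- model$rmap; rm_out$data[is.na(rm_out$data)] <- 0
  write_volume(rm_out, file.path(out_dir, "rmap.nii.gz"))
  write_json_report(qc$summary, file.path(out_dir, "qc_report.json"))
  report <- c(permutation_report(val),
              list(n_patients = length(fingerprints),
                   n_connectome_subjects = length(cmats),
                   n_excluded_subjects = length(qc$excluded),
                   n_included_voxels = sum(model$included$data)))
  write_json_report(report, file.path(out_dir, "report.json"))
  invisible(list(model = model, validation = val, qc = qc,
                 fingerprints = fingerprints, report = report,
                 out_dir = out_dir))
}
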