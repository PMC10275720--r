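#' Phantom atlas with bilateral pallidal stand-ins
#'
#' Builds a deterministic label volume holding two mirror-symmetric
#' ellipsoidal "pallidal" target structures and two lateral neighbour
#' structures (stand-ins for GPi and GPe), used as the spatial scaffold of
#' the synthetic DBS cohort. Labels: 0 background, 1 target-left,
#' 2 target-right, 3 neighbour-left, 4 neighbour-right (left = negative
#' world x).
#'
#' @param affine 4x4 voxel-to-world affine; default: 2 mm isotropic grid
#'   centred on world origin.
#' @param shape integer 3-vector; at least 40 voxels per axis, spacing at
#'   most 2 mm.
#' @return A `"phantom_atlas"`: list with `labels` ([image_volume()]) and
#'   `structure_names`.
#' @export
make_phantom_atlas <- function(affine = NULL, shape = c(48L, 56L, 48L)) {
  if (is.null(affine)) {
    g <- centered_grid(shape, 2)
    affine <- g$affine; shape <- g$shape
  }
  check_affine(affine)
  shape <- as.integer(shape)
  if (any(shape < 40L))
    stop("phantom atlas grid needs at least 40 voxels per axis")
  if (any(voxel_spacing(affine) > 2 + 1e-9))
    stop("phantom atlas grid needs spacing of at most 2 mm")

  w <- grid_world_coords(affine, shape)
  in_ellipsoid <- function(center, semi) {
    rowSums(sweep(sweep(w, 2, center), 2, semi, "/")^2) <= 1
  }
  target_r <- in_ellipsoid(c(21, -7, -5), c(6, 9, 7))
  target_l <- in_ellipsoid(c(-21, -7, -5), c(6, 9, 7))
  neigh_r <- in_ellipsoid(c(27, -4, -1), c(5, 10, 8)) & !target_r
  neigh_l <- in_ellipsoid(c(-27, -4, -1), c(5, 10, 8)) & !target_l

  lab <- numeric(nrow(w))
  lab[target_l] <- 1; lab[target_r] <- 2
  lab[neigh_l] <- 3; lab[neigh_r] <- 4
  if (!all(1:4 %in% lab))
    stop("grid too small to hold the phantom structures")
  structure(list(
    labels = image_volume(array(lab, dim = shape), affine, "synthetic-mni"),
    structure_names = c("1" = "target_left", "2" = "target_right",
                        "3" = "neighbour_left", "4" = "neighbour_right")),
    class = "phantom_atlas")
}

#' Specification of a synthetic DBS cohort
#'
#' The cohort generator plants a spherical "sweetspot" and derives each
#' patient's clinical improvement from how much of that sphere their
#' bilateral stimulation volume covers:
#' `improvement_i = max_improvement * coverage_i + N(0, noise_sd)`.
#' Improvements may be negative once noise is added (real cohorts contain
#' worseners); they are not clipped.
#'
#' @param n_patients cohort size (>= 5); default 20.
#' @param planted_center world mm centre of the planted sphere; must lie
#'   inside a target structure of the atlas.
#' @param planted_radius sphere radius in mm (> 0).
#' @param max_improvement improvement (%) when the sphere is fully covered.
#' @param noise_sd standard deviation (%) of additive Gaussian noise.
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of the spec.
#' @param mode stimulation mode for the simulated electrodes.
#' @return A `"cohort_spec"` list.
#' @export
cohort_spec <- function(n_patients = 20L, planted_center = c(21, -7, -5),
                        planted_radius = 4, max_improvement = 60,
                        noise_sd = 10, seed = 42L,
                        mode = c("voltage", "current")) {
  mode <- match.arg(mode)
  if (n_patients < 5L) stop("'n_patients' must be at least 5")
  if (planted_radius <= 0) stop("'planted_radius' must be positive")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  structure(list(n_patients = as.integer(n_patients),
                 planted_center = planted_center,
                 planted_radius = planted_radius,
                 max_improvement = max_improvement,
                 noise_sd = noise_sd, seed = as.integer(seed), mode = mode),
            class = "cohort_spec")
}

#' Simulate a DBS cohort with a planted sweetspot
#'
#' Places a 4-contact electrode in each hemisphere (contacts stacked
#' 3 mm apart along z, targeting centres jittered per patient), selects one
#' active contact and amplitude per side, models the stimulation volumes
#' with [compute_efield()] + [binarize_efield()], and generates the
#' improvement score of every patient from the fraction of the planted
#' sphere covered by the combined bilateral stimulation volume (see
#' [cohort_spec()]). Pre/post clinical scores consistent with each
#' improvement are drawn around a realistic severity distribution.
#'
#' @param spec a [cohort_spec()].
#' @param atlas a [make_phantom_atlas()] result; its grid is the cohort's
#'   analysis grid.
#' @param efield_threshold activation threshold in V/mm.
#' @param conductivity medium conductivity in S/m (current mode).
#' @return A `"cohort_sim"` list: `cohort` (data.frame with patient_id,
#'   pre_score, post_score, improvement_pct, coverage), `electrodes`
#'   (per-patient left/right [electrode_model()]s), `volumes` (combined
#'   bilateral `stimulation_volume`s), `sphere` (planted mask), `spec`.
#' @export
simulate_cohort <- function(spec, atlas = make_phantom_atlas(),
                            efield_threshold = 0.2, conductivity = 0.14) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(atlas, "phantom_atlas"))
  affine <- atlas$labels$affine
  shape <- dim(atlas$labels$data)
  ctr_vox <- round(voxel_world_transform(affine, spec$planted_center,
                                         "world_to_voxel"))
  lab_at_ctr <- atlas$labels$data[matrix(ctr_vox + 1, 1)]
  if (!lab_at_ctr %in% c(1, 2))
    stop("'planted_center' must lie inside an atlas target structure")

  w <- grid_world_coords(affine, shape)
  sphere <- as.numeric(
    rowSums(sweep(w, 2, spec$planted_center)^2) <= spec$planted_radius^2)
  sphere_vol <- image_volume(array(sphere, dim = shape), affine,
                             atlas$labels$space)
  ## coverage is measured on a fine 1 mm sub-grid of the planted sphere so
  ## the covered volume fraction is effectively continuous (no ties from
  ## the coarser analysis voxels)
  rr <- spec$planted_radius
  off <- as.matrix(expand.grid(x = seq(-rr, rr, by = 1),
                               y = seq(-rr, rr, by = 1),
                               z = seq(-rr, rr, by = 1)))
  off <- off[rowSums(off^2) <= rr^2, , drop = FALSE]
  sphere_pts <- sweep(off, 2, spec$planted_center, "+")

  ## the planted side carries all outcome-relevant placement variability
  ## (targeting jitter, amplitude, active contact); the contralateral
  ## electrode is held at fixed cohort-standard settings (middle contact,
  ## 3 V), so its contribution to any overlap statistic is constant across
  ## patients and the planted association stays unilateral and identifiable
  mirror <- c(-1, 1, 1)
  planted_side <- if (spec$planted_center[1] >= 0) "right" else "left"
  other_side <- if (planted_side == "right") "left" else "right"
  target_var <- c(21 * sign(spec$planted_center[1] + 1e-12), -7, -5)
  target_ref <- target_var * mirror
  zoff <- cbind(0, 0, c(-3, -1, 1, 3))  # 2 mm contact pitch

  out <- with_seed(spec$seed, {
    em_ref <- electrode_model(sweep(zoff, 2, target_ref, "+"),
                              data.frame(contact = 2, polarity = -1,
                                         amplitude = 3),
                              mode = spec$mode)
    sv_ref <- suppressWarnings(
      binarize_efield(compute_efield(em_ref, affine, shape, conductivity),
                      efield_threshold, side = other_side))
    electrodes <- volumes <- vector("list", spec$n_patients)
    coverage <- amplitude <- active_contact <- numeric(spec$n_patients)
    for (i in seq_len(spec$n_patients)) {
      jit <- stats::rnorm(3, 0, 2)
      centers <- sweep(zoff, 2, target_var + jit, "+")
      amp <- stats::runif(1, 2, 5)
      act <- sample.int(4, 1)
      em <- electrode_model(centers,
                            data.frame(contact = act, polarity = -1,
                                       amplitude = amp),
                            mode = spec$mode)
      ef <- compute_efield(em, affine, shape, conductivity)
      sv <- suppressWarnings(
        binarize_efield(ef, efield_threshold,
                        patient_id = sprintf("pt-%02d", i),
                        side = planted_side))
      electrodes[[i]] <- if (planted_side == "right")
        list(left = em_ref, right = em) else list(left = em, right = em_ref)
      volumes[[i]] <- combine_bilateral(sv_ref, sv)
      volumes[[i]]$patient_id <- sprintf("pt-%02d", i)
      above <- rep(FALSE, nrow(sphere_pts))
      for (e in list(em, em_ref)) {
        ev <- efield_vectors(e, sphere_pts, conductivity)
        above <- above | sqrt(rowSums(ev^2)) > efield_threshold
      }
      coverage[i] <- mean(above)
      amplitude[i] <- amp
      active_contact[i] <- act
    }
    improvement <- spec$max_improvement * coverage +
      stats::rnorm(spec$n_patients, 0, spec$noise_sd)
    ## post kept at full precision so improvement == 100*(pre-post)/pre
    ## exactly AND equals the coverage model exactly at noise_sd = 0
    pre <- pmax(10, round(stats::rnorm(spec$n_patients, 71.68, 26.51), 1))
    post <- pre * (1 - improvement / 100)
    list(electrodes = electrodes, volumes = volumes, coverage = coverage,
         improvement = improvement, pre = pre, post = post)
  })
  if (all(out$coverage == 0) && spec$noise_sd == 0)
    warning("degenerate cohort: no stimulation volume touches the planted sphere and noise_sd = 0")

  cohort <- data.frame(
    patient_id = sprintf("pt-%02d", seq_len(spec$n_patients)),
    pre_score = out$pre, post_score = out$post,
    improvement_pct = out$improvement, coverage = out$coverage,
    stringsAsFactors = FALSE)
  structure(list(cohort = cohort, electrodes = out$electrodes,
                 volumes = out$volumes, sphere = sphere_vol, atlas = atlas,
                 spec = spec),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("<cohort_sim> %d patients, improvement %.1f +/- %.1f %%, planted sphere r = %g mm at (%s) mm\n",
              nrow(x$cohort), mean(x$cohort$improvement_pct),
              stats::sd(x$cohort$improvement_pct), x$spec$planted_radius,
              paste(x$spec$planted_center, collapse = ", ")))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes the cohort table as TSV and each combined stimulation volume as
#' binary NIfTI (`<patient_id>_stim.nii.gz`) into `dir`.
#'
#' @param sim a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "cohort_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- sim$cohort
  tab$volume_file <- sprintf("%s_stim.nii.gz", tab$patient_id)
  utils::write.table(tab, file.path(dir, "cohort.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (i in seq_len(nrow(tab)))
    write_volume(sim$volumes[[i]]$mask, file.path(dir, tab$volume_file[i]))
  invisible(dir)
}

#' Read a cohort table and its stimulation volumes
#'
#' @param dir directory holding `cohort.tsv` and the referenced NIfTIs.
#' @return list with `cohort` data.frame and `volumes` (list of
#'   `stimulation_volume`s).
#' @export
read_cohort <- function(dir) {
  path <- file.path(dir, "cohort.tsv")
  if (!file.exists(path)) stop("no cohort.tsv in ", dir)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  volumes <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    f <- file.path(dir, tab$volume_file[i])
    if (!file.exists(f))
      stop("stimulation volume missing for patient ", tab$patient_id[i],
           ": ", f)
    volumes[[i]] <- stimulation_volume(read_volume(f),
                                       patient_id = tab$patient_id[i])
  }
  list(cohort = tab, volumes = volumes)
}
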