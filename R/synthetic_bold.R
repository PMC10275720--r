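#' Specification of a synthetic rs-fMRI connectome cohort
#'
#' Describes a multi-subject synthetic BOLD dataset with planted spatial
#' networks, CSF/white-matter/global nuisance signals, motion-coupled
#' artifacts, and a configurable number of deliberate motion-QC violators.
#' Network time courses are smooth (temporally low-pass) so band-pass
#' filtering retains them while the additive voxel noise is white.
#'
#' @param n_subjects number of subjects.
#' @param n_violators subjects constructed to fail the framewise
#'   displacement criterion (FD > 0.5 mm in > 50\% of volumes); subjects
#'   with 0-based index `< n_violators` are the violators, all others keep
#'   FD at or below 0.2 mm throughout.
#' @param n_volumes BOLD volumes per subject (>= 30).
#' @param tr repetition time in seconds.
#' @param shape,spacing connectome grid (isotropic, centred on the world
#'   origin; default 24 x 28 x 24 at 3 mm).
#' @param n_networks number of planted networks.
#' @param network_amplitude BOLD amplitude of the network signal.
#' @param noise_sd standard deviation of the additive white voxel noise.
#' @param seed integer master seed; networks and masks depend only on the
#'   spec, each subject on `seed` and its index.
#' @return A `"connectome_spec"` list (includes the grid `affine`).
#' @export
connectome_spec <- function(n_subjects = 20L, n_violators = 2L,
                            n_volumes = 120L, tr = 2,
                            shape = c(24L, 28L, 24L), spacing = 3,
                            n_networks = 3L, network_amplitude = 3,
                            noise_sd = 1, seed = 7L) {
  if (n_violators > n_subjects) stop("'n_violators' cannot exceed 'n_subjects'")
  if (n_volumes < 30L) stop("'n_volumes' must be at least 30")
  if (tr <= 0) stop("'tr' must be positive")
  g <- centered_grid(shape, spacing)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_violators = as.integer(n_violators),
                 n_volumes = as.integer(n_volumes), tr = tr,
                 affine = g$affine, shape = g$shape,
                 n_networks = as.integer(n_networks),
                 network_amplitude = network_amplitude,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "connectome_spec")
}

## deterministic tissue masks on the spec grid: concentric ellipsoidal
## zones standing in for CSF (core), white matter (shell) and gray matter
connectome_masks <- function(spec) {
  w <- grid_world_coords(spec$affine, spec$shape)
  semi <- spec$shape * voxel_spacing(spec$affine) / 2 * 0.92
  rn <- sqrt(rowSums(sweep(w, 2, semi, "/")^2))
  brain <- rn < 1
  csf <- rn < 0.22
  wm <- rn >= 0.55 & rn < 0.8
  gray <- brain & !csf & !wm
  as_vol <- function(v) image_volume(array(as.numeric(v), dim = spec$shape),
                                     spec$affine, "synthetic-mni")
  list(brain = as_vol(brain), gray = as_vol(gray), wm = as_vol(wm),
       csf = as_vol(csf))
}

## planted network spatial maps (shared across subjects): each network is a
## pair of Gaussian blobs on gray matter; network 1 sits on the bilateral
## "pallidal" region so stimulation-volume seeds engage it
planted_networks <- function(spec) {
  w <- grid_world_coords(spec$affine, spec$shape)
  masks <- connectome_masks(spec)
  gray_idx <- which(masks$gray$data == 1)
  blob <- function(center, sd) exp(-rowSums(sweep(w, 2, center)^2) / (2 * sd^2))
  centers <- with_seed(spec$seed, {
    ## network 1: bilateral pallidal stand-in; others: random gray locations
    first <- list(rbind(c(21, -7, -5), c(-21, -7, -5)))
    more <- lapply(seq_len(max(0, spec$n_networks - 1L)), function(k) {
      pick <- sample(gray_idx, 2)
      w[pick, , drop = FALSE]
    })
    c(first, more)
  })
  lapply(seq_len(spec$n_networks), function(k) {
    m <- rowSums(vapply(seq_len(nrow(centers[[k]])),
                        function(j) blob(centers[[k]][j, ], 9),
                        numeric(nrow(w))))
    m <- m / max(m) * masks$gray$data  # networks live in gray matter
    image_volume(array(m, dim = spec$shape), spec$affine, "synthetic-mni")
  })
}

## temporally smooth unit-variance latent time course (Gaussian-smoothed
## white noise, sd in volumes)
smooth_tc <- function(n, sd_vol = 3) {
  x <- stats::rnorm(n + 8 * sd_vol)
  k <- stats::dnorm(seq(-4 * sd_vol, 4 * sd_vol), sd = sd_vol)
  y <- stats::filter(x, k / sum(k), sides = 2)
  y <- y[!is.na(y)][seq_len(n)]
  as.numeric(scale(y))
}

#' Simulate one synthetic connectome subject
#'
#' Generates a 4-D BOLD series as the sum of planted-network signals
#' (shared spatial maps times smooth latent time courses), white voxel
#' noise, CSF/WM/global nuisance time courses injected into their tissue
#' regions, and a motion-coupled artifact, plus a 6-column motion trace
#' (3 translations in mm, 3 rotations in rad). Subjects with
#' `subject_index < n_violators` have framewise displacement > 0.5 mm in
#' 70\% of their volumes; all others stay at or below 0.2 mm.
#'
#' @param spec a [connectome_spec()].
#' @param subject_index 0-based subject index (`< n_subjects`).
#' @return A `"connectome_subject"`: list with `bold`
#'   ([time_series_image()]), `motion` (matrix), `masks` (brain/gray/wm/csf
#'   [image_volume()]s), `networks` (planted spatial maps), `subject_id`.
#' @export
simulate_connectome_subject <- function(spec, subject_index) {
  stopifnot(inherits(spec, "connectome_spec"))
  if (subject_index < 0 || subject_index >= spec$n_subjects)
    stop("'subject_index' must be in [0, n_subjects)")
  masks <- connectome_masks(spec)
  nets <- planted_networks(spec)
  nvox <- prod(spec$shape)
  nt <- spec$n_volumes
  subj_seed <- (spec$seed + 104729L * (subject_index + 1L)) %% 2147483647L

  sim <- with_seed(subj_seed, {
    ## latent network signals
    V <- matrix(0, nvox, nt)
    for (k in seq_along(nets)) {
      tc <- smooth_tc(nt)
      V <- V + spec$network_amplitude * (as.numeric(nets[[k]]$data) %o% tc)
    }
    ## nuisance signals in their tissue regions, global over the brain
    csf_tc <- smooth_tc(nt, 2); wm_tc <- smooth_tc(nt, 2)
    glob_tc <- smooth_tc(nt, 2)
    V <- V + 2.0 * (as.numeric(masks$csf$data) %o% csf_tc) +
             2.0 * (as.numeric(masks$wm$data) %o% wm_tc) +
             1.5 * (as.numeric(masks$brain$data) %o% glob_tc)
    ## motion trace
    violator <- subject_index < spec$n_violators
    dtr <- matrix(stats::rnorm(3 * (nt - 1), 0, 0.01), nt - 1, 3)
    dro <- matrix(stats::rnorm(3 * (nt - 1), 0, 2e-4), nt - 1, 3)
    fd0 <- rowSums(abs(dtr)) + 50 * rowSums(abs(dro))
    sc <- 0.15 / max(fd0)
    dtr <- dtr * sc; dro <- dro * sc
    if (violator) {
      nbig <- ceiling(0.7 * (nt - 1))
      big <- sample.int(nt - 1, nbig)
      dtr[big, ] <- dtr[big, ] +
        matrix(sample(c(-0.3, 0.3), 3 * nbig, TRUE), nbig, 3)
    }
    motion <- rbind(0, cbind(apply(dtr, 2, cumsum), apply(dro, 2, cumsum)))
    colnames(motion) <- c("tx_mm", "ty_mm", "tz_mm",
                          "rx_rad", "ry_rad", "rz_rad")
    ## motion-coupled artifact: two motion regressors times spatial patterns
    mstd <- scale(motion[, c(1, 4)])
    mstd[is.nan(mstd)] <- 0
    pat <- matrix(stats::rnorm(2 * nvox, 0, 0.4), nvox, 2) *
      as.numeric(masks$brain$data)
    V <- V + pat %*% t(mstd)
    ## white noise + baseline
    V <- V + matrix(stats::rnorm(nvox * nt, 0, spec$noise_sd), nvox, nt)
    V <- V + 100 * as.numeric(masks$brain$data)
    list(V = V, motion = motion)
  })
  bold <- time_series_image(array(sim$V, dim = c(spec$shape, nt)),
                            spec$affine, tr = spec$tr, space = "synthetic-mni")
  structure(list(bold = bold, motion = sim$motion, masks = masks,
                 networks = nets,
                 subject_id = sprintf("sub-%03d", subject_index + 1)),
            class = "connectome_subject")
}

#' @rdname simulate_connectome_subject
#' @param indices which 0-based subject indices to generate (default all).
#' @export
simulate_connectome <- function(spec, indices = seq_len(spec$n_subjects) - 1L) {
  lapply(indices, function(i) simulate_connectome_subject(spec, i))
}

#' Improvements generated from connectivity to a planted network
#'
#' Alternative ground truth for the network-mapping analysis: each
#' patient's improvement is proportional to how strongly their seed volume
#' engages the designated planted network (mean network-map value inside
#' the seed), plus Gaussian noise.
#'
#' @param volumes list of `stimulation_volume`s on the connectome grid.
#' @param network_map planted network spatial map ([image_volume()]).
#' @param max_improvement improvement (%) at the strongest attainable
#'   engagement (seed fully inside the network peak).
#' @param noise_sd additive noise sd in %.
#' @param seed RNG seed.
#' @return Numeric vector of improvements (%).
#' @export
network_improvements <- function(volumes, network_map, max_improvement = 60,
                                 noise_sd = 5, seed = 1L) {
  engage <- vapply(volumes, function(v) {
    idx <- v$mask$data == 1
    if (!any(idx)) return(0)
    mean(network_map$data[idx]) / max(network_map$data)
  }, numeric(1))
  noise <- with_seed(seed, stats::rnorm(length(volumes), 0, noise_sd))
  max_improvement * engage + noise
}
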