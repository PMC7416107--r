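#' Effect specification for the synthetic cohort simulator
#'
#' Controls the statistical structure the simulator injects: per-region
#' multivoxel discriminability `d` (separation of condition-specific pattern
#' increments, in units of the voxel noise SD), a condition-common univariate
#' response amplitude (percent signal change for sound versus rest), and the
#' noise model (AR(1) plus white noise, slow cosine drift).
#'
#' Condition patterns are zero-mean across conditions within each voxel, so
#' the univariate sound-versus-rest response is condition-equal by
#' construction; all decodable signal lives in the spatial pattern.
#'
#' The defaults emulate the blind-like cohort of the study design this
#' package models: an eccentricity gradient of discriminability in early
#' visual cortex (fovea < periphery < far periphery), near-ceiling
#' discriminability in auditory cortex, and none in motor cortex.
#'
#' @param d Named numeric vector of discriminability values for the keys
#'   `fovea`, `periphery`, `far_periphery` (applied to all three visual
#'   areas), `AC` and `MC`.
#' @param amplitude Named numeric vector of percent-signal-change response
#'   amplitudes for `EVC`, `AC`, `MC` (common to all conditions).
#' @param noise_sd Marginal SD of the voxel noise.
#' @param ar1 AR(1) coefficient of the noise, in `[0, 1)`.
#' @param drift_amplitude SD of the random per-voxel weights on the slow
#'   cosine drift basis.
#' @param d_overrides Optional named vector of per-region discriminability
#'   overriding the band-level values (names from [atlas_region_names()]).
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(d = c(fovea = 0.03, periphery = 0.048,
                              far_periphery = 0.066, AC = 0.25, MC = 0),
                        amplitude = c(EVC = 0.2, AC = 2, MC = 0),
                        noise_sd = 1, ar1 = 0.3, drift_amplitude = 1,
                        d_overrides = NULL) {
  stopifnot(noise_sd >= 0, ar1 >= 0, ar1 < 1, drift_amplitude >= 0,
            all(d >= 0))
  need <- c("fovea", "periphery", "far_periphery", "AC", "MC")
  stopifnot(all(need %in% names(d)), all(c("EVC", "AC", "MC") %in% names(amplitude)))
  structure(list(d = d, amplitude = amplitude, noise_sd = noise_sd,
                 ar1 = ar1, drift_amplitude = drift_amplitude,
                 d_overrides = d_overrides),
            class = "effect_spec")
}

# Per-region discriminability / amplitude vectors over atlas_region_names().
region_effects <- function(effect) {
  regions <- atlas_region_names()
  d <- numeric(length(regions)); names(d) <- regions
  a <- numeric(length(regions)); names(a) <- regions
  for (rg in regions) {
    if (rg %in% c("AC", "MC")) {
      d[rg] <- effect$d[[rg]]; a[rg] <- effect$amplitude[[rg]]
    } else {
      band <- sub("^V[123]_", "", rg)
      d[rg] <- effect$d[[band]]; a[rg] <- effect$amplitude[["EVC"]]
    }
  }
  if (!is.null(effect$d_overrides)) {
    stopifnot(all(names(effect$d_overrides) %in% regions))
    d[names(effect$d_overrides)] <- effect$d_overrides
  }
  list(d = d, amplitude = a)
}

#' Simulate one subject's multi-run BOLD data
#'
#' Per voxel the signal is baseline (100) plus a condition-common boxcar
#' response, plus a condition-specific pattern increment (drawn once per
#' subject, fixed across runs, scaled by the voxel's region discriminability
#' and the noise SD, centred across conditions), all convolved with the
#' canonical double-gamma HRF, plus low-frequency cosine drift and AR(1)
#' noise. Identical seeds give bit-identical output.
#'
#' @param schedules List of [build_schedule()] results, one per run; all must
#'   share the atlas grid and TR.
#' @param atlas A [make_roi_atlas()] atlas.
#' @param effect An [effect_spec()].
#' @param seed Integer seed.
#' @param hrf An [hrf_config()].
#' @return List of class `subject_data`: `bold` (list of 4-D arrays),
#'   `schedules`, `patterns` (labelled-voxel x condition matrix of ground-truth
#'   increments), `pattern_voxels` (linear indices), `effect`, `seed`.
#' @export
simulate_subject <- function(schedules, atlas, effect = effect_spec(),
                             seed = 1L, hrf = hrf_config()) {
  stopifnot(inherits(atlas, "roi_atlas"), inherits(effect, "effect_spec"))
  for (s in schedules)
    if (!identical(s$acquisition$grid_shape, atlas$grid_shape))
      stop("mismatched grid shapes between schedule and atlas")
  g <- atlas$grid_shape
  nvox <- prod(g)
  conds <- sound_conditions()
  eff <- region_effects(effect)

  lab_idx <- which(atlas$labels != 0)
  lab_region <- names(atlas$lut)[match(atlas$labels[lab_idx], atlas$lut)]
  d_vox <- eff$d[lab_region]
  a_vox <- eff$amplitude[lab_region]

  with_seed(seed, {
  # condition pattern increments: zero-mean across conditions per voxel
  z <- matrix(stats::rnorm(length(lab_idx) * 3), ncol = 3)
  z <- z - rowMeans(z)
  patterns <- z * (d_vox * effect$noise_sd)
  colnames(patterns) <- conds

  bold <- vector("list", length(schedules))
  for (r in seq_along(schedules)) {
    sched <- schedules[[r]]
    nv <- sched$acquisition$n_volumes
    tr <- sched$acquisition$tr_seconds
    X_cond <- vapply(conds, function(cn) {
      b <- sched$blocks[sched$blocks$condition == cn, , drop = FALSE]
      if (nrow(b) == 0) numeric(nv)
      else convolve_blocks(b$onset, b$duration, nv, tr, hrf)
    }, numeric(nv))
    X_all <- rowSums(X_cond)

    Y <- matrix(100, nrow = nv, ncol = nvox)
    if (length(lab_idx) > 0) {
      Y[, lab_idx] <- Y[, lab_idx] + outer(X_all, a_vox) +
        X_cond %*% t(patterns)
    }
    if (effect$drift_amplitude > 0) {
      i <- seq_len(nv)
      B <- vapply(1:3, function(k) cos(pi * k * (i - 0.5) / nv), numeric(nv))
      W <- matrix(stats::rnorm(nvox * 3, sd = effect$drift_amplitude), nrow = 3)
      Y <- Y + B %*% W
    }
    if (effect$noise_sd > 0) {
      innov_sd <- effect$noise_sd * sqrt(1 - effect$ar1^2)
      eps <- matrix(stats::rnorm(nv * nvox, sd = innov_sd), nrow = nv)
      if (effect$ar1 > 0)
        eps <- unclass(stats::filter(eps, effect$ar1, method = "recursive"))
      Y <- Y + eps
    }
    bold[[r]] <- array(t(Y), dim = c(g, nv))
  }
  structure(list(bold = bold, schedules = schedules, patterns = patterns,
                 pattern_voxels = lab_idx, effect = effect, seed = seed),
            class = "subject_data")
  })
}

#' Cohort specification
#'
#' @param name Group name (e.g. `"blind"`).
#' @param n_subjects Number of subjects.
#' @param n_runs Runs per subject (>= 2; leave-one-run-out needs at least 2).
#' @param effect An [effect_spec()] shared by the cohort.
#' @param short_subject Optional index of one subject scanned with the short
#'   (6 s / 6 s, 117-volume) design variant; all others use the long design.
#' @param acquisition Base [acquisition_spec()].
#' @param seed Master seed; per-subject seeds are derived deterministically.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(name, n_subjects, n_runs = 4, effect = effect_spec(),
                        short_subject = NULL,
                        acquisition = acquisition_spec(), seed = 1L) {
  stopifnot(n_subjects >= 0, n_runs >= 2)
  if (!is.null(short_subject))
    stopifnot(short_subject >= 1, short_subject <= n_subjects)
  structure(list(name = name, n_subjects = as.integer(n_subjects),
                 n_runs = as.integer(n_runs), effect = effect,
                 short_subject = short_subject, acquisition = acquisition,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Blind-like cohort preset (8 subjects, strong EVC signal with gradient)
#' @param seed Master seed.
#' @param acquisition Base [acquisition_spec()].
#' @export
cohort_blind_like <- function(seed = 1L, acquisition = acquisition_spec()) {
  cohort_spec("blind", 8, effect = effect_spec(), short_subject = 1L,
              acquisition = acquisition, seed = seed)
}

#' Sighted-like cohort preset (10 subjects, weaker EVC signal, stronger AC)
#' @param seed Master seed.
#' @param acquisition Base [acquisition_spec()].
#' @export
cohort_sighted_like <- function(seed = 2L, acquisition = acquisition_spec()) {
  cohort_spec("sighted", 10,
              effect = effect_spec(d = c(fovea = 0.015, periphery = 0.025,
                                         far_periphery = 0.036, AC = 0.35,
                                         MC = 0)),
              acquisition = acquisition, seed = seed)
}

# Deterministic per-subject seed derivation, kept below 2^31.
subject_seed <- function(master, i) (as.integer(master) + 7919L * as.integer(i)) %% 2147483647L

#' Simulate a subject of a cohort in memory
#'
#' @param cohort A [cohort_spec()].
#' @param i Subject index.
#' @param atlas Atlas shared by the cohort.
#' @return A `subject_data` (see [simulate_subject()]).
#' @export
simulate_cohort_subject <- function(cohort, i, atlas) {
  design <- if (!is.null(cohort$short_subject) && i == cohort$short_subject)
    "short" else "long"
  acq <- cohort$acquisition
  acq$grid_shape <- atlas$grid_shape
  scheds <- session_schedules(cohort$n_runs, design, acq,
                              seed = subject_seed(cohort$seed, i))
  simulate_subject(scheds, atlas, cohort$effect,
                   seed = subject_seed(cohort$seed, i) + 1L)
}

#' Simulate a cohort to disk
#'
#' Writes one directory per subject (`sub-01`, ...) containing per-run NIfTI
#' BOLD volumes and BIDS-style events tables, the shared atlas volume with a
#' JSON label lookup, and a JSON manifest recording seeds and the ground-truth
#' effect structure. The manifest is written last, so an interrupted write
#' leaves no dataset that parses as complete.
#'
#' @param cohort A [cohort_spec()].
#' @param atlas A [make_roi_atlas()] atlas.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
simulate_cohort <- function(cohort, atlas, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0) stop("out_dir not writable: ", out_dir)
  write_atlas(atlas, file.path(out_dir, "atlas.nii"),
              file.path(out_dir, "atlas_lut.json"))
  subjects <- list()
  for (i in seq_len(cohort$n_subjects)) {
    sub_id <- sprintf("sub-%02d", i)
    sub_dir <- file.path(out_dir, sub_id)
    dir.create(sub_dir, showWarnings = FALSE)
    sd <- simulate_cohort_subject(cohort, i, atlas)
    for (r in seq_along(sd$bold)) {
      write_volume(sd$bold[[r]],
                   file.path(sub_dir, sprintf("run-%02d_bold.nii", r)),
                   voxel_size_mm = cohort$acquisition$voxel_size_mm)
      write_events(sd$schedules[[r]],
                   file.path(sub_dir, sprintf("run-%02d_events.tsv", r)))
    }
    subjects[[sub_id]] <- list(
      seed = subject_seed(cohort$seed, i),
      design = if (!is.null(cohort$short_subject) && i == cohort$short_subject)
        "short" else "long",
      n_runs = cohort$n_runs)
  }
  eff <- region_effects(cohort$effect)
  manifest <- list(group = cohort$name, seed = cohort$seed,
                   n_subjects = cohort$n_subjects,
                   tr_seconds = cohort$acquisition$tr_seconds,
                   grid_shape = atlas$grid_shape,
                   ground_truth = list(discriminability = as.list(eff$d),
                                       amplitude = as.list(eff$amplitude),
                                       noise_sd = cohort$effect$noise_sd,
                                       ar1 = cohort$effect$ar1),
                   subjects = subjects)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
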