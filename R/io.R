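#' Read a 4-D BOLD volume
#'
#' @param path NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param expect_volumes Optional expected volume count; a mismatch raises an
#'   error before any computation.
#' @return 4-D numeric array with attribute `voxel_size_mm`.
#' @export
read_bold <- function(path, expect_volumes = NULL) {
  if (!file.exists(path)) stop("BOLD file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4)
    stop("not a 4-D BOLD volume: ", path)
  if (!is.null(expect_volumes) && dim(arr)[4] != expect_volumes)
    stop("volume count mismatch in ", path, ": found ", dim(arr)[4],
         ", expected ", expect_volumes)
  attr(arr, "voxel_size_mm") <- RNifti::pixdim(img)[1]
  arr
}

#' Write a volume as NIfTI-1
#'
#' Volumes are written with an identity-scaled affine (voxel size on the
#' diagonal); integer arrays are stored as integer data.
#'
#' @param volume 3-D or 4-D array.
#' @param path Output path.
#' @param voxel_size_mm Isotropic voxel size.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, voxel_size_mm = 3) {
  pd8 <- c(-1, rep(voxel_size_mm, 3), 1, 0, 0, 0)
  img <- RNifti::asNifti(volume, reference = list(pixdim = pd8),
                         datatype = if (is.integer(volume)) "int32" else "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a BIDS-style events table
#'
#' Columns `onset`, `duration`, `trial_type` (seconds from the first retained
#' volume), tab-separated.
#'
#' @param schedule A `stimulus_schedule`.
#' @param path Output `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_events <- function(schedule, path) {
  b <- schedule$blocks
  df <- data.frame(onset = b$onset, duration = b$duration,
                   trial_type = b$condition)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an events table into a stimulus schedule
#'
#' @param path Tab-separated file with columns `onset`, `duration`,
#'   `trial_type` (seconds).
#' @param acquisition An [acquisition_spec()] with `n_volumes` set (events
#'   files do not carry scan geometry).
#' @param run_id Run identifier.
#' @return A `stimulus_schedule`.
#' @export
read_events <- function(path, acquisition, run_id = 1L) {
  if (!file.exists(path)) stop("events file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("events file ", path, " missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!is.numeric(df$onset) || !is.numeric(df$duration))
    stop("events file ", path, ": onset/duration must be numeric seconds")
  if (is.na(acquisition$n_volumes))
    stop("acquisition must specify n_volumes to validate ", path)
  sched <- structure(list(
    blocks = data.frame(onset = df$onset, duration = df$duration,
                        condition = df$trial_type, stringsAsFactors = FALSE),
    run_id = as.integer(run_id), acquisition = acquisition),
    class = "stimulus_schedule")
  validate_schedule(sched)
  sched
}

#' Write an atlas volume and its JSON label lookup
#'
#' @param atlas A `roi_atlas`.
#' @param nii_path,lut_path Output paths.
#' @return Invisibly, `nii_path`.
#' @export
write_atlas <- function(atlas, nii_path, lut_path) {
  labs <- atlas$labels
  storage.mode(labs) <- "integer"
  write_volume(labs, nii_path)
  jsonlite::write_json(list(lut = as.list(atlas$lut),
                            bands = as.list(atlas$bands)),
                       lut_path, auto_unbox = TRUE, digits = NA)
  invisible(nii_path)
}

#' Read an atlas volume and its label lookup
#'
#' @param nii_path Integer NIfTI label volume.
#' @param lut_path JSON lookup written by [write_atlas()].
#' @return A `roi_atlas`.
#' @export
read_atlas <- function(nii_path, lut_path) {
  if (!file.exists(nii_path)) stop("atlas volume not found: ", nii_path)
  if (!file.exists(lut_path)) stop("atlas lookup not found: ", lut_path)
  arr <- as.array(RNifti::readNifti(nii_path))
  if (length(dim(arr)) != 3) stop("atlas must be a 3-D label volume: ", nii_path)
  meta <- jsonlite::read_json(lut_path, simplifyVector = TRUE)
  labels <- array(as.integer(round(arr)), dim = dim(arr))
  lut <- unlist(meta$lut)
  structure(list(labels = labels, lut = lut,
                 bands = unlist(meta$bands), grid_shape = dim(arr)),
            class = "roi_atlas")
}

#' Pipeline configuration
#'
#' All inference defaults equal the study settings this package models:
#' 1000 label permutations, 10 000 bootstrap samples, side-7 searchlight,
#' voxelwise p 0.001 with cluster-extent correction, sign-permutation model
#' at voxelwise p 0.005 with 2 mm FWHM variance smoothing.
#'
#' @param data_dir Dataset directory ([simulate_cohort()] layout).
#' @param out_dir Results directory.
#' @param rois ROI list for decoding.
#' @param n_perm,n_boot,alpha,fdr_q Inference settings.
#' @param highpass_cutoff_s GLM high-pass cutoff.
#' @param svm_cost SVM cost parameter.
#' @param searchlight Logical: run the searchlight stage.
#' @param searchlight_side Cube side.
#' @param searchlight_voxel_p,snpm_voxel_p Voxelwise thresholds.
#' @param variance_smoothing_fwhm_mm SnPM variance smoothing FWHM (mm).
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(data_dir, out_dir, rois = default_roi_list(),
                            n_perm = 1000, n_boot = 10000, alpha = 0.05,
                            fdr_q = 0.05, highpass_cutoff_s = 128,
                            svm_cost = 1, searchlight = FALSE,
                            searchlight_side = 7,
                            searchlight_voxel_p = 0.001,
                            snpm_voxel_p = 0.005,
                            variance_smoothing_fwhm_mm = 2, seed = 1L) {
  structure(list(data_dir = data_dir, out_dir = out_dir, rois = rois,
                 n_perm = n_perm, n_boot = n_boot, alpha = alpha,
                 fdr_q = fdr_q, highpass_cutoff_s = highpass_cutoff_s,
                 svm_cost = svm_cost, searchlight = searchlight,
                 searchlight_side = searchlight_side,
                 searchlight_voxel_p = searchlight_voxel_p,
                 snpm_voxel_p = snpm_voxel_p,
                 variance_smoothing_fwhm_mm = variance_smoothing_fwhm_mm,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read or write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
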