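#' Build a single-block design matrix
#'
#' One HRF-convolved boxcar regressor per stimulus block (least-squares-all
#' beta-series scheme), plus a discrete-cosine high-pass nuisance basis and an
#' intercept. The standard long run yields 18 stimulus columns (3 conditions
#' x 6 blocks).
#'
#' @param schedule A [build_schedule()] result.
#' @param hrf An [hrf_config()].
#' @param highpass_cutoff_s High-pass cutoff in seconds (cosine basis up to
#'   this period); default 128 s.
#' @return List of class `design_matrix`: `X` (volumes x columns),
#'   `block_cols` (indices of stimulus columns), `block_condition`,
#'   `nuisance_cols`, `schedule`.
#' @export
build_design <- function(schedule, hrf = hrf_config(), highpass_cutoff_s = 128) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  nv <- schedule$acquisition$n_volumes
  tr <- schedule$acquisition$tr_seconds
  b <- schedule$blocks
  n_blocks <- nrow(b)
  Xs <- if (n_blocks > 0) {
    vapply(seq_len(n_blocks), function(i)
      convolve_blocks(b$onset[i], b$duration[i], nv, tr, hrf), numeric(nv))
  } else matrix(numeric(0), nrow = nv, ncol = 0)
  if (n_blocks > 0)
    colnames(Xs) <- sprintf("block%02d_%s", seq_len(n_blocks), b$condition)
  hp <- dct_highpass_basis(nv, tr, highpass_cutoff_s)
  X <- cbind(Xs, hp, intercept = rep(1, nv))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(X = X,
                 block_cols = seq_len(n_blocks),
                 block_condition = if (n_blocks > 0) b$condition else character(0),
                 nuisance_cols = if (ncol(X) > n_blocks)
                   (n_blocks + 1L):ncol(X) else integer(0),
                 schedule = schedule),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix: %d volumes, %d stimulus + %d nuisance columns\n",
              nrow(x$X), length(x$block_cols), length(x$nuisance_cols)))
  invisible(x)
}

# 4-D array (or voxels-in-columns matrix) -> volumes x voxels matrix over mask
bold_to_matrix <- function(bold, mask = NULL) {
  if (is.matrix(bold)) return(list(Y = bold, voxels = seq_len(ncol(bold))))
  d <- dim(bold)
  stopifnot(length(d) == 4)
  nvox <- prod(d[1:3])
  voxels <- if (is.null(mask)) seq_len(nvox) else which(mask)
  Y <- t(matrix(bold, nrow = nvox, ncol = d[4])[voxels, , drop = FALSE])
  list(Y = Y, voxels = voxels)
}

#' Estimate single-block beta weights
#'
#' Ordinary least squares per voxel; only the stimulus-block betas are
#' returned, labelled with block condition and run id. Voxels whose time
#' series is identically zero yield zero betas with a warning.
#'
#' @param bold_run 4-D BOLD array (x, y, z, t) or a volumes x voxels matrix.
#' @param design A [build_design()] design matrix for the same run.
#' @param mask Optional logical 3-D array restricting the voxels analysed.
#' @return List of class `beta_set`: `betas` (blocks x voxels), `condition`,
#'   `run_id`, `voxels` (linear voxel indices of the columns).
#' @export
estimate_block_betas <- function(bold_run, design, mask = NULL) {
  stopifnot(inherits(design, "design_matrix"))
  bm <- bold_to_matrix(bold_run, mask)
  Y <- bm$Y
  if (nrow(Y) != nrow(design$X))
    stop("BOLD volume count (", nrow(Y), ") does not match design rows (",
         nrow(design$X), ")")
  zero <- which(colSums(Y != 0) == 0)
  if (length(zero) > 0)
    warning(length(zero), " all-zero voxel time series; betas set to 0")
  fit <- qr.coef(qr(design$X), Y)
  fit[is.na(fit)] <- 0
  betas <- fit[design$block_cols, , drop = FALSE]
  if (anyNA(betas)) stop("missing values in estimated betas")
  structure(list(betas = betas, condition = design$block_condition,
                 run_id = design$schedule$run_id, voxels = bm$voxels),
            class = "beta_set")
}

#' @export
print.beta_set <- function(x, ...) {
  cat(sprintf("beta_set: run %d, %d blocks x %d voxels\n",
              x$run_id, nrow(x$betas), ncol(x$betas)))
  invisible(x)
}

#' Separable 3-D Gaussian smoothing
#'
#' Kernel truncated at 3 SD and renormalised at the edges, so constant images
#' are preserved exactly; FWHM of 0 is the identity.
#'
#' @param vol 3-D numeric array.
#' @param fwhm_vox Kernel FWHM in voxel units.
#' @return Smoothed array of the same dimensions.
#' @export
gaussian_smooth_3d <- function(vol, fwhm_vox) {
  stopifnot(fwhm_vox >= 0)
  if (fwhm_vox == 0) return(vol)
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-half:half, sd = sigma)
  w <- w / sum(w)
  d <- dim(vol)
  smooth_dim <- function(a, dim_i) {
    n <- d[dim_i]
    if (2 * half + 1 > 2 * n) stop("smoothing kernel larger than grid")
    S <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - half):(i + half)
      keep <- j >= 1 & j <= n
      S[i, j[keep]] <- w[keep] / sum(w[keep])
    }
    m <- matrix(aperm(a, c(dim_i, setdiff(1:3, dim_i))), nrow = n)
    out <- S %*% m
    aperm(array(out, dim = d[c(dim_i, setdiff(1:3, dim_i))]),
          order(c(dim_i, setdiff(1:3, dim_i))))
  }
  for (k in 1:3) vol <- smooth_dim(vol, k)
  vol
}

#' Univariate sound-versus-rest contrast
#'
#' Optional isotropic Gaussian smoothing (FWHM in mm, converted via the voxel
#' size) is applied to every volume before estimation — this is the only path
#' on which spatial smoothing occurs. A condition-level GLM (one regressor per
#' condition, pooling its blocks, plus nuisance) is fit per run; per-condition
#' and pooled sound-versus-rest contrasts are averaged across runs.
#'
#' @param bold_runs List of 4-D BOLD arrays.
#' @param designs List of matching [build_design()] designs.
#' @param smoothing_fwhm_mm Smoothing FWHM in millimetres (0 disables).
#' @param voxel_size_mm Isotropic voxel size in millimetres.
#' @param atlas Optional `roi_atlas`; when given, a per-ROI mean table is
#'   returned for the regions in `rois`.
#' @param rois Regions for the mean table.
#' @return List of class `univariate_contrast`: `condition_maps` (list of 3-D
#'   arrays), `pooled_map`, and if an atlas was given `roi_means`
#'   (data.frame: roi, condition, mean).
#' @export
univariate_contrast <- function(bold_runs, designs, smoothing_fwhm_mm = 6,
                                voxel_size_mm = 3, atlas = NULL,
                                rois = c("EVC", "AC", "MC")) {
  if (smoothing_fwhm_mm < 0) stop("smoothing FWHM must be >= 0")
  stopifnot(length(bold_runs) == length(designs))
  conds <- sound_conditions()
  fwhm_vox <- smoothing_fwhm_mm / voxel_size_mm
  acc <- NULL
  for (r in seq_along(bold_runs)) {
    bold <- bold_runs[[r]]
    d <- dim(bold)
    if (fwhm_vox > 0)
      for (t in seq_len(d[4]))
        bold[, , , t] <- gaussian_smooth_3d(bold[, , , t], fwhm_vox)
    des <- designs[[r]]
    # condition-level design: sum block columns per condition
    Xc <- vapply(conds, function(cn) {
      cols <- des$block_cols[des$block_condition == cn]
      if (length(cols) == 0) numeric(nrow(des$X))
      else rowSums(des$X[, cols, drop = FALSE])
    }, numeric(nrow(des$X)))
    X <- cbind(Xc, des$X[, des$nuisance_cols, drop = FALSE])
    Y <- t(matrix(bold, nrow = prod(d[1:3]), ncol = d[4]))
    fit <- qr.coef(qr(X), Y)
    fit[is.na(fit)] <- 0
    cond_betas <- fit[seq_along(conds), , drop = FALSE]
    acc <- if (is.null(acc)) cond_betas else acc + cond_betas
  }
  acc <- acc / length(bold_runs)
  g <- dim(bold_runs[[1]])[1:3]
  condition_maps <- lapply(seq_along(conds), function(i) array(acc[i, ], dim = g))
  names(condition_maps) <- conds
  pooled <- array(colMeans(acc), dim = g)
  out <- list(condition_maps = condition_maps, pooled_map = pooled)
  if (!is.null(atlas)) {
    rows <- do.call(rbind, lapply(rois, function(rg) {
      m <- roi_mask(atlas, rg)
      data.frame(roi = rg, condition = conds,
                 mean = vapply(condition_maps, function(v) mean(v[m]),
                               numeric(1)),
                 stringsAsFactors = FALSE)
    }))
    rownames(rows) <- NULL
    out$roi_means <- rows
  }
  structure(out, class = "univariate_contrast")
}
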