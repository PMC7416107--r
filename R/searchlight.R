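#' Cube neighbourhood offsets
#'
#' @param side Odd cube side length (7 gives 343 voxels).
#' @return Integer matrix (side^3 x 3) of voxel offsets.
#' @export
cube_offsets <- function(side = 7) {
  stopifnot(side >= 1, side %% 2 == 1)
  h <- (side - 1) / 2
  as.matrix(expand.grid(dx = -h:h, dy = -h:h, dz = -h:h))
}

#' Whole-volume cubic searchlight decoding
#'
#' At every in-mask centre, the decoding features are the in-mask voxels of
#' the side^3 cube around it, clipped at the volume borders. Decoding uses
#' exactly the ROI scheme (train-set z-scoring, one-vs-one linear SVM,
#' leave-one-run-out), so a searchlight accuracy equals [decode_loro()] run
#' on that neighbourhood's mask. Per-voxel z-scoring is neighbourhood
#' independent, so fold normalisation is computed once over the whole mask.
#'
#' @param beta_runs List of per-run `beta_set`s covering the mask voxels.
#' @param brain_mask Logical 3-D array of voxels to analyse.
#' @param side Odd cube side (default 7).
#' @param cost SVM cost.
#' @param centers Optional logical array restricting searchlight centres
#'   (defaults to `brain_mask`).
#' @return List of class `searchlight_map`: `accuracy` (3-D array, `NA`
#'   outside centres), `side`, `mask`.
#' @export
run_searchlight <- function(beta_runs, brain_mask, side = 7, cost = 1,
                            centers = NULL) {
  stopifnot(side %% 2 == 1, side >= 1)
  g <- dim(brain_mask)
  if (any(g < side))
    warning("grid smaller than the searchlight side; cubes are clipped")
  if (is.null(centers)) centers <- brain_mask
  cols <- mask_to_cols(beta_runs, brain_mask)
  mask_idx <- which(brain_mask)
  col_of_voxel <- array(NA_integer_, dim = g)
  col_of_voxel[mask_idx] <- seq_along(mask_idx)

  labels <- lapply(beta_runs, function(b) b$condition)
  folds <- loro_folds(beta_runs, cols)

  off <- cube_offsets(side)
  acc <- array(NA_real_, dim = g)
  ctr <- which(centers & brain_mask, arr.ind = TRUE)
  for (i in seq_len(nrow(ctr))) {
    nb <- sweep(off, 2, ctr[i, ], "+")
    keep <- nb[, 1] >= 1 & nb[, 1] <= g[1] & nb[, 2] >= 1 & nb[, 2] <= g[2] &
      nb[, 3] >= 1 & nb[, 3] <= g[3]
    nb <- nb[keep, , drop = FALSE]
    sub <- col_of_voxel[cbind(nb[, 1], nb[, 2], nb[, 3])]
    sub <- sub[!is.na(sub)]
    if (length(sub) == 0) next
    sub_folds <- lapply(folds, function(f)
      list(ztrain = f$ztrain[, sub, drop = FALSE],
           ztest = f$ztest[, sub, drop = FALSE],
           train_runs = f$train_runs, test_run = f$test_run))
    acc[ctr[i, 1], ctr[i, 2], ctr[i, 3]] <-
      mean(cv_accuracy(sub_folds, labels, cost = cost)$accuracy_3class)
  }
  structure(list(accuracy = acc, side = side, mask = brain_mask),
            class = "searchlight_map")
}

#' @export
print.searchlight_map <- function(x, ...) {
  v <- x$accuracy[!is.na(x$accuracy)]
  cat(sprintf("searchlight_map: side %d, %d centres, accuracy %.3f-%.3f\n",
              x$side, length(v), min(v), max(v)))
  invisible(x)
}

# connectivity offsets for 3-D cluster labelling
connectivity_offsets <- function(connectivity = 6) {
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(off != 0)
  switch(as.character(connectivity),
         "6" = off[nz == 1, , drop = FALSE],
         "18" = off[nz >= 1 & nz <= 2, , drop = FALSE],
         "26" = off[nz >= 1, , drop = FALSE],
         stop("connectivity must be 6, 18 or 26"))
}

#' Label connected clusters in a logical volume
#'
#' Flood fill with 6- (faces, default), 18- or 26-connectivity.
#'
#' @param supra Logical 3-D array.
#' @param connectivity 6, 18 or 26.
#' @return List: `labels` (integer array, 0 = background), `sizes` (voxel
#'   counts per cluster, descending label order follows discovery).
#' @export
label_clusters <- function(supra, connectivity = 6) {
  g <- dim(supra)
  off <- connectivity_offsets(connectivity)
  labels <- array(0L, dim = g)
  idx <- which(supra, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list(labels = labels, sizes = integer(0)))
  lin <- which(supra)
  in_cluster <- array(FALSE, dim = g)
  sizes <- integer(0)
  lab <- 0L
  for (s in seq_along(lin)) {
    if (labels[lin[s]] != 0L) next
    lab <- lab + 1L
    queue <- matrix(idx[s, ], ncol = 3)
    labels[lin[s]] <- lab
    size <- 1L
    while (nrow(queue) > 0) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      nb <- sweep(off, 2, cur, "+")
      keep <- nb[, 1] >= 1 & nb[, 1] <= g[1] & nb[, 2] >= 1 & nb[, 2] <= g[2] &
        nb[, 3] >= 1 & nb[, 3] <= g[3]
      nb <- nb[keep, , drop = FALSE]
      for (q in seq_len(nrow(nb))) {
        if (supra[nb[q, 1], nb[q, 2], nb[q, 3]] &&
            labels[nb[q, 1], nb[q, 2], nb[q, 3]] == 0L) {
          labels[nb[q, 1], nb[q, 2], nb[q, 3]] <- lab
          size <- size + 1L
          queue <- rbind(queue, nb[q, , drop = FALSE])
        }
      }
    }
    sizes <- c(sizes, size)
  }
  list(labels = labels, sizes = sizes)
}

# cluster table from a statistic volume and suprathreshold mask; peak
# coordinates reported 0-based
cluster_table <- function(stat_vol, supra, k_min, connectivity = 6,
                          sign = 1) {
  cl <- label_clusters(supra, connectivity)
  if (length(cl$sizes) == 0)
    return(data.frame(cluster = integer(0), size = integer(0),
                      peak_x = integer(0), peak_y = integer(0),
                      peak_z = integer(0), peak_stat = numeric(0),
                      sign = character(0), significant = logical(0)))
  rows <- lapply(seq_along(cl$sizes), function(l) {
    vox <- which(cl$labels == l, arr.ind = TRUE)
    vals <- sign * stat_vol[cl$labels == l]
    peak <- vox[which.max(vals), ]
    data.frame(cluster = l, size = cl$sizes[l],
               peak_x = peak[1] - 1L, peak_y = peak[2] - 1L,
               peak_z = peak[3] - 1L,
               peak_stat = sign * max(vals),
               sign = if (sign >= 0) "positive" else "negative",
               significant = cl$sizes[l] >= k_min)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Monte-Carlo cluster-extent threshold
#'
#' Simulates smoothness-matched Gaussian noise volumes, thresholds each at
#' the voxelwise p (upper tail after global standardisation), and records the
#' maximum cluster size. `k_min` is the smallest extent whose familywise rate
#' of occurrence under the null is at most `alpha`. A functional
#' re-implementation of cluster-level threshold estimation; no
#' bit-compatibility with any particular tool is claimed.
#'
#' @param voxel_threshold_p Voxelwise threshold (upper-tail p).
#' @param grid Integer vector of length 3.
#' @param smoothness_fwhm Noise smoothness FWHM in voxels (0 = independent).
#' @param alpha Familywise alpha.
#' @param n_mc Number of Monte-Carlo volumes (>= 1000 recommended).
#' @param seed Integer seed.
#' @param connectivity Cluster connectivity.
#' @return List of class `cluster_threshold`: `k_min`, `max_sizes`, `alpha`.
#' @export
cluster_extent_mc <- function(voxel_threshold_p, grid, smoothness_fwhm = 0,
                              alpha = 0.05, n_mc = 1000, seed = 1L,
                              connectivity = 6) {
  stopifnot(alpha > 0, alpha <= 1, n_mc >= 1,
            voxel_threshold_p > 0, voxel_threshold_p < 1)
  if (smoothness_fwhm > min(grid))
    stop("smoothness FWHM exceeds the grid extent")
  zthr <- stats::qnorm(1 - voxel_threshold_p)
  max_sizes <- with_seed(seed, vapply(seq_len(n_mc), function(m) {
    vol <- array(stats::rnorm(prod(grid)), dim = grid)
    if (smoothness_fwhm > 0) {
      vol <- gaussian_smooth_3d(vol, smoothness_fwhm)
      vol <- vol / stats::sd(vol)
    }
    cl <- label_clusters(vol > zthr, connectivity)
    if (length(cl$sizes) == 0) 0L else max(cl$sizes)
  }, integer(1)))
  k_min <- 1L
  while (mean(max_sizes >= k_min) > alpha) k_min <- k_min + 1L
  structure(list(k_min = k_min, max_sizes = max_sizes, alpha = alpha,
                 voxel_threshold_p = voxel_threshold_p),
            class = "cluster_threshold")
}

# one-sample t per voxel across subject maps; returns list(t, p, n, mean, sd)
voxelwise_one_sample_t <- function(maps, mu = 0) {
  X <- do.call(rbind, lapply(maps, as.vector))
  n <- nrow(X)
  mn <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  t <- (mn - mu) / (sdv / sqrt(n))
  t[sdv == 0] <- NA_real_  # degenerate: zero variance, flagged not infinite
  p <- stats::pt(t, n - 1, lower.tail = FALSE)
  g <- dim(maps[[1]])
  list(t = array(t, g), p = array(p, g), n = n,
       mean = array(mn, g), sd = array(sdv, g))
}

#' Group searchlight map versus chance
#'
#' Per-voxel one-sample t of accuracy minus chance across subjects,
#' thresholded voxelwise, with surviving clusters (face connectivity by
#' default) flagged against a Monte-Carlo cluster-extent threshold. Voxels
#' with zero between-subject variance are flagged degenerate (`NA`), never
#' emitted as infinite statistics.
#'
#' @param maps List (>= 3) of subject accuracy volumes on a shared grid.
#' @param chance Chance accuracy (1/3).
#' @param voxel_p Voxelwise threshold p.
#' @param alpha Cluster familywise alpha.
#' @param smoothness_fwhm Noise smoothness (voxels) for the extent threshold;
#'   `NULL` estimates it from the residual maps.
#' @param n_mc,seed Monte-Carlo settings.
#' @param connectivity Cluster connectivity.
#' @return List of class `group_map`: `t` (array), `clusters` (data.frame),
#'   `k_min`, `n_degenerate`.
#' @export
group_vs_chance_map <- function(maps, chance = 1/3, voxel_p = 0.001,
                                alpha = 0.05, smoothness_fwhm = NULL,
                                n_mc = 1000, seed = 1L, connectivity = 6) {
  if (length(maps) < 3) stop("group map requires >= 3 subjects")
  g <- dim(maps[[1]])
  for (m in maps) if (!identical(dim(m), g)) stop("maps are not co-registered")
  ts <- voxelwise_one_sample_t(maps, mu = chance)
  if (is.null(smoothness_fwhm)) {
    resid <- lapply(maps, function(m) m - ts$mean)
    smoothness_fwhm <- estimate_smoothness_fwhm(resid)
  }
  supra <- !is.na(ts$p) & ts$p < voxel_p
  kt <- cluster_extent_mc(voxel_p, g, smoothness_fwhm, alpha, n_mc, seed,
                          connectivity)
  clusters <- cluster_table(ts$t, supra, kt$k_min, connectivity)
  structure(list(t = ts$t, clusters = clusters, k_min = kt$k_min,
                 voxel_p = voxel_p,
                 n_degenerate = sum(is.na(ts$t) & !is.na(ts$sd) & ts$sd == 0)),
            class = "group_map")
}

#' Estimate noise smoothness from residual maps
#'
#' Classic gradient-based FWHM estimate: per axis,
#' `FWHM = sqrt(-2 log 2 / log(1 - var(diff) / (2 var)))`, geometric mean over
#' axes, computed from voxelwise residual maps.
#'
#' @param resid_maps List of residual volumes.
#' @return FWHM in voxels (0 if residuals are spatially independent or
#'   rougher).
#' @export
estimate_smoothness_fwhm <- function(resid_maps) {
  per_axis <- vapply(1:3, function(ax) {
    num <- 0; den <- 0
    for (r in resid_maps) {
      d <- apply(r, setdiff(1:3, ax), diff)
      num <- num + stats::var(as.vector(d), na.rm = TRUE)
      den <- den + stats::var(as.vector(r), na.rm = TRUE)
    }
    ratio <- num / (2 * den)
    if (!is.finite(ratio) || ratio >= 1) return(0)
    sqrt(-2 * log(2) / log(1 - ratio))
  }, numeric(1))
  per_axis <- per_axis[per_axis > 0]
  if (length(per_axis) == 0) return(0)
  exp(mean(log(per_axis)))
}

#' Between-group searchlight difference map
#'
#' Per-voxel two-sample t (or covariate-adjusted linear model with group plus
#' covariate when a covariate is supplied), signed so positive means group A
#' exceeds group B. Positive and negative suprathreshold clusters are
#' corrected by cluster extent as in [group_vs_chance_map()].
#'
#' @param mapsA,mapsB Lists of subject accuracy volumes (each n >= 2).
#' @param covariate Optional numeric vector, one value per subject
#'   (A then B), e.g. mean univariate response.
#' @param voxel_p,alpha,smoothness_fwhm,n_mc,seed,connectivity As in
#'   [group_vs_chance_map()].
#' @return List of class `group_diff_map`: `t` (signed array), `clusters`
#'   (positive and negative rows), `k_min`.
#' @export
group_difference_map <- function(mapsA, mapsB, covariate = NULL,
                                 voxel_p = 0.001, alpha = 0.05,
                                 smoothness_fwhm = 0, n_mc = 1000, seed = 1L,
                                 connectivity = 6) {
  stopifnot(length(mapsA) >= 2, length(mapsB) >= 2)
  g <- dim(mapsA[[1]])
  XA <- do.call(rbind, lapply(mapsA, as.vector))
  XB <- do.call(rbind, lapply(mapsB, as.vector))
  nA <- nrow(XA); nB <- nrow(XB)
  if (!is.null(covariate) && length(covariate) != nA + nB)
    stop("covariate length must equal the total number of subjects")
  if (is.null(covariate)) {
    mA <- colMeans(XA); mB <- colMeans(XB)
    vA <- apply(XA, 2, stats::var); vB <- apply(XB, 2, stats::var)
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    tval <- (mA - mB) / sqrt(sp2 * (1 / nA + 1 / nB))
    df <- nA + nB - 2
  } else {
    grp <- c(rep(1, nA), rep(0, nB))
    X <- cbind(1, grp, covariate)
    Y <- rbind(XA, XB)
    qx <- qr(X)
    coefs <- qr.coef(qx, Y)
    res <- Y - X %*% coefs
    df <- nA + nB - ncol(X)
    sigma2 <- colSums(res^2) / df
    xtxi <- chol2inv(qr.R(qx))
    tval <- coefs[2, ] / sqrt(sigma2 * xtxi[2, 2])
  }
  tval[!is.finite(tval)] <- NA_real_
  p_pos <- stats::pt(tval, df, lower.tail = FALSE)
  p_neg <- stats::pt(tval, df, lower.tail = TRUE)
  kt <- cluster_extent_mc(voxel_p, g, smoothness_fwhm, alpha, n_mc, seed,
                          connectivity)
  t_arr <- array(tval, g)
  clusters <- rbind(
    cluster_table(t_arr, array(!is.na(p_pos) & p_pos < voxel_p, g),
                  kt$k_min, connectivity, sign = 1),
    cluster_table(t_arr, array(!is.na(p_neg) & p_neg < voxel_p, g),
                  kt$k_min, connectivity, sign = -1))
  structure(list(t = t_arr, clusters = clusters, k_min = kt$k_min, df = df),
            class = "group_diff_map")
}

#' Sign-permutation (pseudo-t) group inference
#'
#' Non-parametric one-sample group model for accuracy-minus-chance maps: the
#' pseudo-t uses a variance volume Gaussian-smoothed at the stated FWHM
#' before forming the standard error; the null is built by random sign flips
#' of the subject maps (exhaustive enumeration of all 2^n patterns when that
#' is fewer than `n_perm`, with a message). The voxelwise cluster-forming
#' threshold is the upper `voxel_p` quantile of the pooled permutation
#' pseudo-t distribution; cluster familywise error comes from the permutation
#' distribution of maximum cluster size.
#'
#' @param maps List of subject accuracy-minus-chance volumes (n >= 4).
#' @param n_perm Requested permutations (default 10000).
#' @param variance_smoothing_fwhm Variance smoothing FWHM in voxels
#'   (0 reduces the pseudo-t to the ordinary t).
#' @param voxel_p Voxelwise threshold (default 0.005).
#' @param alpha_cluster Cluster FWE level.
#' @param seed Integer seed.
#' @param connectivity Cluster connectivity.
#' @param mask Optional logical array restricting the analysis.
#' @return List of class `snpm_result`: `pseudo_t` (array), `clusters`,
#'   `u_threshold`, `n_perm_used`, `exhaustive`.
#' @export
snpm_group <- function(maps, n_perm = 10000, variance_smoothing_fwhm = 0,
                       voxel_p = 0.005, alpha_cluster = 0.05, seed = 1L,
                       connectivity = 6, mask = NULL) {
  n <- length(maps)
  if (n < 4) stop("sign permutation needs >= 4 subjects to be meaningful")
  g <- dim(maps[[1]])
  if (is.null(mask)) mask <- array(TRUE, g)
  X <- do.call(rbind, lapply(maps, as.vector))
  X[, !mask] <- NA

  smooth_var <- function(v) {
    if (variance_smoothing_fwhm == 0) return(v)
    vol <- array(ifelse(is.na(v), 0, v), g)
    w <- array(as.numeric(mask), g)
    num <- gaussian_smooth_3d(vol * w, variance_smoothing_fwhm)
    den <- gaussian_smooth_3d(w, variance_smoothing_fwhm)
    out <- as.vector(num / den)
    out[!mask] <- NA
    out
  }
  pseudo_t_for <- function(signs) {
    mn <- as.vector(crossprod(signs, X)) / n
    v <- pmax((colSums(X^2) - n * mn^2) / (n - 1), 0)
    vs <- smooth_var(v)
    pt_ <- mn / sqrt(vs / n)
    pt_[vs == 0] <- NA_real_
    pt_
  }

  exhaustive <- 2^n <= n_perm
  if (exhaustive) {
    message("exhaustive sign enumeration: 2^", n, " = ", 2^n,
            " patterns (< requested ", n_perm, ")")
    signs_mat <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    signs_mat <- with_seed(seed,
      matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), ncol = n))
  }
  n_used <- nrow(signs_mat)

  obs <- pseudo_t_for(rep(1, n))
  perm_t <- matrix(NA_real_, n_used, sum(mask))
  perm_max_size <- integer(n_used)
  mask_lin <- which(as.vector(mask))
  all_vals <- numeric(0)
  for (i in seq_len(n_used)) {
    pt_i <- pseudo_t_for(signs_mat[i, ])
    perm_t[i, ] <- pt_i[mask_lin]
  }
  u <- stats::quantile(perm_t, 1 - voxel_p, na.rm = TRUE, names = FALSE)
  for (i in seq_len(n_used)) {
    vol_i <- array(NA_real_, g)
    vol_i[mask_lin] <- perm_t[i, ]
    cl <- label_clusters(!is.na(vol_i) & vol_i >= u, connectivity)
    perm_max_size[i] <- if (length(cl$sizes) == 0) 0L else max(cl$sizes)
  }
  obs_arr <- array(obs, g)
  supra <- !is.na(obs_arr) & obs_arr >= u
  cl <- label_clusters(supra, connectivity)
  clusters <- cluster_table(obs_arr, supra, k_min = Inf, connectivity)
  if (nrow(clusters) > 0) {
    clusters$p_fwe <- vapply(clusters$size, function(s)
      max(sum(perm_max_size >= s), 1) / n_used, numeric(1))
    clusters$significant <- clusters$p_fwe <= alpha_cluster
  } else clusters$p_fwe <- numeric(0)
  structure(list(pseudo_t = obs_arr, clusters = clusters, u_threshold = u,
                 n_perm_used = n_used, exhaustive = exhaustive),
            class = "snpm_result")
}
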