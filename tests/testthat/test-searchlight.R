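test_that("cube neighbourhoods have the expected sizes", {
  expect_equal(nrow(cube_offsets(7)), 343)
  expect_equal(nrow(cube_offsets(1)), 1)
  expect_error(cube_offsets(4))
  # side-7 cube fully inside a mask keeps all 343 voxels
  mask <- array(TRUE, dim = c(9, 9, 9))
  br <- synth_beta_runs(2, 2, prod(dim(mask)), d = 0, seed = 1,
                        voxels = seq_len(prod(dim(mask))))
  centers <- array(FALSE, dim = dim(mask)); centers[5, 5, 5] <- TRUE
  # count via the internal neighbourhood logic: accuracy defined at centre
  sl <- run_searchlight(br, mask, side = 7, centers = centers)
  expect_equal(sum(!is.na(sl$accuracy)), 1)
})

test_that("searchlight accuracy equals ROI decoding on the same neighbourhood", {
  g <- c(7, 7, 7)
  mask <- array(TRUE, dim = g)
  br <- synth_beta_runs(3, 3, prod(g), d = 0.4, n_informative = prod(g),
                        seed = 5)
  centers <- array(FALSE, dim = g)
  pts <- rbind(c(2, 2, 2), c(4, 4, 4), c(6, 3, 5))
  centers[pts] <- TRUE
  sl <- run_searchlight(br, mask, side = 3, centers = centers)
  off <- cube_offsets(3)
  for (i in seq_len(nrow(pts))) {
    nb <- sweep(off, 2, pts[i, ], "+")
    keep <- apply(nb, 1, function(v) all(v >= 1 & v <= g))
    vox <- apply(nb[keep, , drop = FALSE], 1, function(v)
      v[1] + (v[2] - 1) * g[1] + (v[3] - 1) * g[1] * g[2])
    ref <- decode_loro(br, sort(vox))
    expect_equal(sl$accuracy[pts[i, 1], pts[i, 2], pts[i, 3]],
                 ref$mean_accuracy)
  }
  # side 1 is single-voxel decoding
  sl1 <- run_searchlight(br, mask, side = 1, centers = centers)
  ref1 <- decode_loro(br, pts[1, 1] + (pts[1, 2] - 1) * g[1] +
                        (pts[1, 3] - 1) * g[1] * g[2])
  expect_equal(sl1$accuracy[pts[1, 1], pts[1, 2], pts[1, 3]],
               ref1$mean_accuracy)
})

test_that("an embedded informative cluster is localised by the searchlight", {
  g <- c(8, 8, 8)
  nvox <- prod(g)
  sig <- array(FALSE, dim = g); sig[3:7, 3:7, 3:7] <- TRUE  # 5^3 cluster
  set.seed(31)
  conds <- sound_conditions()
  mu <- matrix(rnorm(3 * sum(sig)), 3)
  mu <- 1.2 * (mu - rep(colMeans(mu), each = 3))
  br <- lapply(1:4, function(r) {
    cond <- rep(conds, 4)[sample.int(12)]
    betas <- matrix(rnorm(12 * nvox), ncol = nvox)
    betas[, which(sig)] <- betas[, which(sig)] +
      mu[match(cond, conds), , drop = FALSE]
    structure(list(betas = betas, condition = cond, run_id = r,
                   voxels = seq_len(nvox)), class = "beta_set")
  })
  sl <- run_searchlight(br, array(TRUE, dim = g), side = 3)
  peak <- which(sl$accuracy == max(sl$accuracy, na.rm = TRUE), arr.ind = TRUE)[1, ]
  # peak centre within the cluster dilated by the searchlight radius
  expect_true(all(peak >= 2 & peak <= 8))
  expect_gt(max(sl$accuracy, na.rm = TRUE), 0.8)
  # far-field centres (no informative voxel in reach) stay near chance
  far <- sl$accuracy[1, 1, 1]
  expect_lt(far, 0.7)
})

test_that("cluster labelling respects connectivity", {
  supra <- array(FALSE, dim = c(5, 5, 5))
  supra[1:2, 1, 1] <- TRUE          # blob of 2
  supra[4:5, 5, 5] <- TRUE          # separate blob of 2
  cl <- label_clusters(supra, 6)
  expect_equal(sort(cl$sizes), c(2L, 2L))
  # diagonal touch: separate under 6-connectivity, merged under 26
  supra2 <- array(FALSE, dim = c(4, 4, 4))
  supra2[2, 2, 2] <- TRUE; supra2[3, 3, 3] <- TRUE
  expect_length(label_clusters(supra2, 6)$sizes, 2)
  expect_length(label_clusters(supra2, 26)$sizes, 1)
  expect_length(label_clusters(array(FALSE, c(3, 3, 3)))$sizes, 0)
})

test_that("Monte-Carlo extent threshold matches analytic values on a toy grid", {
  # independent voxels on 3x3x3: P(any suprathreshold) = 1-(1-p)^27
  # p = 0.001 -> 0.027 < alpha -> k_min = 1
  k1 <- cluster_extent_mc(0.001, c(3, 3, 3), 0, alpha = 0.05, n_mc = 3000,
                          seed = 1)
  expect_equal(k1$k_min, 1L)
  # p = 0.01 -> P(any) = 0.238 > alpha, but P(adjacent pair) ~ 54*1e-4 << alpha
  k2 <- cluster_extent_mc(0.01, c(3, 3, 3), 0, alpha = 0.05, n_mc = 3000,
                          seed = 2)
  expect_equal(k2$k_min, 2L)
  # alpha -> 1: no correction
  k3 <- cluster_extent_mc(0.01, c(4, 4, 4), 0, alpha = 1, n_mc = 500, seed = 3)
  expect_equal(k3$k_min, 1L)
  # stricter voxel thresholds can only shrink the required extent
  ks <- vapply(c(0.05, 0.01, 0.001), function(p)
    cluster_extent_mc(p, c(6, 6, 6), 0, alpha = 0.05, n_mc = 800,
                      seed = 4)$k_min, integer(1))
  expect_true(all(diff(ks) <= 0))
  expect_error(cluster_extent_mc(0.01, c(5, 5, 5), 10, n_mc = 10),
               "exceeds the grid")
})

test_that("group map machinery: nulls, degenerate guards, identical groups", {
  g <- c(6, 6, 6)
  set.seed(41)
  # null maps: suprathreshold voxel rate matches the nominal threshold
  maps <- lapply(1:12, function(i) array(rnorm(prod(g), 1/3, 0.05), dim = g))
  gm <- group_vs_chance_map(maps, voxel_p = 0.01, n_mc = 200, seed = 2,
                            smoothness_fwhm = 0)
  ts <- soundmvpa:::voxelwise_one_sample_t(maps, mu = 1/3)
  rate <- mean(ts$p < 0.01, na.rm = TRUE)
  expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / prod(g)))
  # constant above-chance maps: degenerate flag, no infinities
  const <- lapply(1:5, function(i) array(0.6, dim = g))
  gm2 <- group_vs_chance_map(const, n_mc = 50, seed = 1, smoothness_fwhm = 0)
  expect_equal(gm2$n_degenerate, prod(g))
  expect_false(any(is.infinite(gm2$t)))
  expect_error(group_vs_chance_map(maps[1:2]), ">= 3")
  # identical groups: difference statistic collapses to zero
  gd <- group_difference_map(maps[1:6], maps[1:6], n_mc = 50, seed = 1)
  expect_lt(max(abs(gd$t), na.rm = TRUE), 1e-8)
  expect_equal(nrow(gd$clusters), 0)
  expect_error(group_difference_map(maps[1:4], maps[5:8],
                                    covariate = c(1, 2)), "covariate length")
})

test_that("embedded group signal is recovered as a significant cluster", {
  g <- c(8, 8, 8)
  region <- array(FALSE, dim = g); region[3:5, 3:5, 3:5] <- TRUE
  set.seed(47)
  hits <- 0
  for (s in 1:20) {
    maps <- lapply(1:10, function(i) {
      m <- array(rnorm(prod(g), 1/3, 0.04), dim = g)
      m[region] <- m[region] + 0.15
      m
    })
    gm <- group_vs_chance_map(maps, voxel_p = 0.001, n_mc = 200,
                              seed = 100 + s, smoothness_fwhm = 0)
    sig <- gm$clusters[gm$clusters$significant, , drop = FALSE]
    ok <- nrow(sig) >= 1 &&
      all(region[cbind(sig$peak_x + 1, sig$peak_y + 1, sig$peak_z + 1)])
    hits <- hits + ok
  }
  expect_gte(hits, 16)  # >= 80% of 20 simulations
})

test_that("covariates uncorrelated with group leave difference maps stable", {
  g <- c(5, 5, 5)
  set.seed(53)
  mapsA <- lapply(1:8, function(i) array(rnorm(prod(g), 0.5, 0.05), dim = g))
  mapsB <- lapply(1:8, function(i) array(rnorm(prod(g), 0.4, 0.05), dim = g))
  plain <- group_difference_map(mapsA, mapsB, n_mc = 50, seed = 1)
  cov <- rnorm(16)
  adj <- group_difference_map(mapsA, mapsB, covariate = cov, n_mc = 50,
                              seed = 1)
  expect_gt(cor(as.vector(plain$t), as.vector(adj$t)), 0.95)
  expect_lt(mean(abs(plain$t - adj$t)), 0.5)
})

test_that("sign-permutation pseudo-t reduces to t and controls its threshold", {
  g <- c(5, 5, 5)
  set.seed(59)
  maps <- lapply(1:8, function(i) array(rnorm(prod(g), 0, 0.05), dim = g))
  expect_message(res <- snpm_group(maps, n_perm = 10000,
                                   variance_smoothing_fwhm = 0,
                                   voxel_p = 0.005, seed = 1),
                 "exhaustive")
  expect_true(res$exhaustive)
  expect_equal(res$n_perm_used, 256)
  # FWHM 0: pseudo-t equals the ordinary one-sample t
  ts <- soundmvpa:::voxelwise_one_sample_t(maps, mu = 0)
  expect_equal(res$pseudo_t, ts$t, tolerance = 1e-10)
  # variance smoothing changes the statistic but keeps strong means strong
  maps2 <- lapply(maps, function(m) m + 0.3)
  res2 <- snpm_group(maps2, n_perm = 300, variance_smoothing_fwhm = 2,
                     voxel_p = 0.005, seed = 2)
  expect_true(all(res2$pseudo_t > 0))
  expect_error(snpm_group(maps[1:3]), ">= 4")
})

test_that("blind-like vs sighted-like cohorts give spatially specific clusters", {
  # synthetic twin of the between-group searchlight comparison: positive
  # clusters only in early visual labels, negative only in auditory labels,
  # none in motor cortex; reduced settings (short design, 2 runs, small atlas)
  atl <- make_roi_atlas(c(12, 12, 12))
  acq <- acquisition_spec(grid_shape = c(12, 12, 12))
  mask <- atl$labels != 0
  evc <- roi_mask(atl, "EVC"); ac <- roi_mask(atl, "AC"); mc <- roi_mask(atl, "MC")
  eff_blind <- effect_spec(d = c(fovea = 0.6, periphery = 0.6,
                                 far_periphery = 0.6, AC = 0.05, MC = 0))
  eff_sighted <- effect_spec(d = c(fovea = 0.05, periphery = 0.05,
                                   far_periphery = 0.05, AC = 0.6, MC = 0))
  # centres restricted to two representative coronal planes (one through the
  # visual slabs, one through the control boxes) to keep the 20-simulation
  # loop at desk scale; features still come from the full 3-D neighbourhood
  centers <- mask
  keep_y <- c(4, unique(which(ac, arr.ind = TRUE)[, 2])[2])
  centers[, setdiff(seq_len(dim(mask)[2]), keep_y), ] <- FALSE
  one_subject_map <- function(eff, seed) {
    sch <- lapply(1:2, function(r)
      build_schedule(6, 6, reps_per_condition = 4, acquisition = acq,
                     lead_in_volumes = 3, run_id = r, seed = seed + r))
    sd1 <- simulate_subject(sch, atl, eff, seed = seed + 11)
    betas <- subject_betas(sd1, atl)
    run_searchlight(betas, mask, side = 3, centers = centers)$accuracy
  }
  ok <- 0
  for (s in 1:20) {
    mapsA <- lapply(1:4, function(i) one_subject_map(eff_blind, 5000 + 97 * (20 * s + i)))
    mapsB <- lapply(1:4, function(i) one_subject_map(eff_sighted, 6000 + 89 * (20 * s + i)))
    gd <- group_difference_map(mapsA, mapsB, voxel_p = 0.01, alpha = 0.05,
                               n_mc = 300, seed = s)
    sig <- gd$clusters[gd$clusters$significant, , drop = FALSE]
    pos <- sig[sig$sign == "positive", , drop = FALSE]
    neg <- sig[sig$sign == "negative", , drop = FALSE]
    peaks_in <- function(tab, region)
      nrow(tab) > 0 && all(region[cbind(tab$peak_x + 1, tab$peak_y + 1,
                                        tab$peak_z + 1)])
    no_peaks_in <- function(tab, region)
      nrow(tab) == 0 || !any(region[cbind(tab$peak_x + 1, tab$peak_y + 1,
                                          tab$peak_z + 1)])
    ok <- ok + (peaks_in(pos, evc) && peaks_in(neg, ac) &&
                  no_peaks_in(sig, mc))
  }
  expect_gte(ok, 16)  # >= 80% of 20 simulations
})
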