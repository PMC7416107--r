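#' Train-set z-scoring
#'
#' Per-voxel mean and SD (denominator n-1) are computed on the training rows
#' only and applied to both sets, so no test information enters the
#' normalisation. Zero-variance training voxels have their SD replaced by 1
#' (with a warning), preserving feature dimensionality across folds.
#'
#' @param train,test Numeric matrices with identical columns (voxels).
#' @return List with `train`, `test`, `center`, `scale`.
#' @export
zscore_fit_apply <- function(train, test) {
  stopifnot(is.matrix(train), is.matrix(test), ncol(train) == ncol(test))
  center <- colMeans(train)
  scale <- apply(train, 2, stats::sd)
  zero <- !is.finite(scale) | scale == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance training voxel(s); sd set to 1")
    scale[zero] <- 1
  }
  list(train = sweep(sweep(train, 2, center), 2, scale, "/"),
       test = sweep(sweep(test, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

# Linear SVM fit + decision values on test rows. Positive decision values
# correspond to the class of the first training row (libsvm orders classes by
# first appearance); returns predicted labels.
svm_pair_predict <- function(xtr, ytr, xte, cost = 1) {
  # beta sets are complete by invariant, so NA screening is skipped (na.pass
  # avoids the costly data.frame round trip inside svm; model is identical)
  m <- e1071::svm(xtr, factor(ytr), kernel = "linear", cost = cost,
                  scale = FALSE, fitted = FALSE, na.action = stats::na.pass)
  w <- crossprod(m$SV, m$coefs)
  dec <- drop(xte %*% w) - m$rho
  pos <- as.character(ytr[1])
  neg <- setdiff(unique(as.character(ytr)), pos)
  ifelse(dec > 0, pos, neg)
}

# Assemble per-fold z-scored feature matrices for leave-one-run-out CV.
# Normalisation is label-independent, so folds can be reused across label
# permutations. `cols` indexes columns of each beta matrix.
loro_folds <- function(beta_runs, cols) {
  n_runs <- length(beta_runs)
  mats <- lapply(beta_runs, function(b) b$betas[, cols, drop = FALSE])
  labels <- lapply(beta_runs, function(b) b$condition)
  folds <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    train <- do.call(rbind, mats[-r])
    z <- withCallingHandlers(
      zscore_fit_apply(train, mats[[r]]),
      warning = function(w) invokeRestart("muffleWarning"))
    folds[[r]] <- list(ztrain = z$train, ztest = z$test,
                       train_runs = rep(seq_len(n_runs)[-r],
                                        vapply(mats[-r], nrow, integer(1))),
                       test_run = r)
  }
  attr(folds, "labels_by_run") <- labels
  folds
}

# Core CV for a given label assignment (`labels_by_run` may be permuted).
# Returns the fold x pair binary accuracy table (chance 0.5), the per-fold
# three-class accuracy from one-vs-one voting over all held-out exemplars
# (chance 1/3; ties among the pairwise decisions receive fractional credit,
# the expectation of a random tie-break), and the raw votes when requested.
cv_accuracy <- function(folds, labels_by_run, cost = 1, votes = FALSE) {
  conds <- sort(unique(unlist(labels_by_run)))
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  n_folds <- length(folds)
  acc <- matrix(NA_real_, n_folds, length(pairs),
                dimnames = list(NULL, vapply(pairs, paste, "", collapse = "|")))
  acc3 <- numeric(n_folds)
  vote_list <- if (votes) vector("list", n_folds) else NULL
  for (f in seq_len(n_folds)) {
    fold <- folds[[f]]
    # rebuild the training label vector in the same row order as ztrain
    ytr_all <- unlist(labels_by_run[unique(fold$train_runs)], use.names = FALSE)
    yte_all <- labels_by_run[[fold$test_run]]
    fold_votes <- matrix(NA_character_, length(yte_all), length(pairs))
    for (p in seq_along(pairs)) {
      pr <- pairs[[p]]
      tr_sel <- ytr_all %in% pr
      pred_all <- svm_pair_predict(fold$ztrain[tr_sel, , drop = FALSE],
                                   ytr_all[tr_sel], fold$ztest, cost)
      te_sel <- yte_all %in% pr
      acc[f, p] <- mean(pred_all[te_sel] == yte_all[te_sel])
      fold_votes[, p] <- pred_all
    }
    counts <- vapply(conds, function(cn) rowSums(fold_votes == cn),
                     numeric(length(yte_all)))
    counts <- matrix(counts, nrow = length(yte_all))
    maxc <- apply(counts, 1, max)
    n_tied <- rowSums(counts == maxc)
    true_count <- counts[cbind(seq_along(yte_all), match(yte_all, conds))]
    acc3[f] <- mean(ifelse(true_count == maxc, 1 / n_tied, 0))
    if (votes) vote_list[[f]] <- list(votes = fold_votes, truth = yte_all)
  }
  list(accuracy = acc, accuracy_3class = acc3, votes = vote_list,
       conditions = conds)
}

# One-vs-one majority voting with seeded random tie-break.
votes_to_confusion <- function(cv, seed = 1L) {
  conds <- cv$conditions
  confusion <- matrix(0L, length(conds), length(conds),
                      dimnames = list(true = conds, predicted = conds))
  with_seed(seed, for (fv in cv$votes) {
    for (i in seq_len(nrow(fv$votes))) {
      tab <- table(factor(fv$votes[i, ], levels = conds))
      winners <- names(tab)[tab == max(tab)]
      pred <- if (length(winners) == 1) winners
              else winners[sample.int(length(winners), 1)]
      confusion[fv$truth[i], pred] <- confusion[fv$truth[i], pred] + 1L
    }
  })
  confusion
}

# Map a logical mask (or voxel indices) to beta-matrix columns.
mask_to_cols <- function(beta_runs, mask) {
  vox <- if (is.logical(mask) || is.array(mask)) which(mask) else as.integer(mask)
  cols <- match(vox, beta_runs[[1]]$voxels)
  if (anyNA(cols))
    stop("mask contains voxels without estimated betas")
  cols
}

#' Leave-one-run-out one-versus-one SVM decoding within an ROI
#'
#' For each held-out run and each unordered condition pair, a linear SVM
#' (cost 1, no scaling beyond the train-set z-scoring) is trained on the
#' remaining runs' block betas of that pair and scored on the held-out run's
#' exemplars of that pair, giving the fold x pair accuracy table (binary
#' chance 0.5) whose grand mean is `mean_pairwise_accuracy`. The primary
#' `mean_accuracy` is the three-class accuracy (chance one-out-of-three)
#' obtained by one-vs-one voting over all held-out exemplars, averaged over
#' folds; voting ties receive fractional credit (the expectation of a random
#' tie-break). The confusion matrix uses majority voting with a seeded
#' random tie-break.
#'
#' @param beta_runs List of [estimate_block_betas()] results, one per run
#'   (>= 2), all with identical voxel columns.
#' @param mask Logical 3-D array (or voxel indices) selecting the ROI.
#' @param cost SVM cost parameter.
#' @param seed Seed for the confusion tie-break.
#' @param subject,roi Optional identifiers stored in the result.
#' @return List of class `decoding_result`: `fold_pair_accuracy` (folds x
#'   pairs), `mean_pairwise_accuracy`, `mean_accuracy` (three-class),
#'   `fold_accuracy` (per-fold three-class), `confusion`, `n_features`,
#'   `subject`, `roi`.
#' @export
decode_loro <- function(beta_runs, mask, cost = 1, seed = 1L,
                        subject = NA_character_, roi = NA_character_) {
  if (length(beta_runs) < 2) stop("leave-one-run-out requires >= 2 runs")
  cols <- mask_to_cols(beta_runs, mask)
  if (length(cols) < 1) stop("ROI mask selects no voxels")
  labels <- lapply(beta_runs, function(b) b$condition)
  counts <- lapply(labels, table)
  if (any(unlist(counts) < 1)) stop("each run needs >= 1 exemplar per condition")
  folds <- loro_folds(beta_runs, cols)
  cv <- cv_accuracy(folds, labels, cost = cost, votes = TRUE)
  structure(list(fold_pair_accuracy = cv$accuracy,
                 mean_pairwise_accuracy = mean(cv$accuracy),
                 mean_accuracy = mean(cv$accuracy_3class),
                 fold_accuracy = cv$accuracy_3class,
                 confusion = votes_to_confusion(cv, seed = seed),
                 n_features = length(cols),
                 subject = subject, roi = roi),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("decoding_result%s%s: mean accuracy %.3f (%d folds x %d pairs, %d voxels)\n",
              if (!is.na(x$subject)) paste0(" ", x$subject) else "",
              if (!is.na(x$roi)) paste0(" [", x$roi, "]") else "",
              x$mean_accuracy, nrow(x$fold_pair_accuracy),
              ncol(x$fold_pair_accuracy), x$n_features))
  invisible(x)
}

#' Decode every requested ROI of a subject
#'
#' The EVC result is computed on the union mask of the nine early-visual
#' sub-regions (not averaged from sub-ROI results); likewise V1, V2, V3 are
#' decoded on their three-band unions.
#'
#' @param beta_runs List of per-run `beta_set`s covering at least the atlas
#'   voxels.
#' @param atlas A `roi_atlas`.
#' @param rois Character vector of ROI names (default: the 15 standard ROIs).
#' @param cost,seed Passed to [decode_loro()].
#' @param subject Subject identifier.
#' @return List with `results` (named list of `decoding_result`) and `table`
#'   (data.frame: subject, roi, n_features, mean_accuracy).
#' @export
decode_all_rois <- function(beta_runs, atlas, rois = default_roi_list(),
                            cost = 1, seed = 1L, subject = NA_character_) {
  results <- lapply(rois, function(rg)
    decode_loro(beta_runs, roi_mask(atlas, rg), cost = cost, seed = seed,
                subject = subject, roi = rg))
  names(results) <- rois
  table <- data.frame(subject = subject, roi = rois,
                      n_features = vapply(results, function(r) r$n_features,
                                          numeric(1)),
                      mean_accuracy = vapply(results, function(r)
                        r$mean_accuracy, numeric(1)),
                      stringsAsFactors = FALSE)
  rownames(table) <- NULL
  list(results = results, table = table)
}

#' Betas for every run of a simulated subject
#'
#' Convenience wrapper chaining [build_design()] and
#' [estimate_block_betas()] over a subject's runs, restricted to a mask
#' (default: all labelled atlas voxels).
#'
#' @param subject_data A [simulate_subject()] result.
#' @param atlas The atlas (for the default mask).
#' @param mask Optional logical array.
#' @param highpass_cutoff_s High-pass cutoff.
#' @return List of `beta_set`, one per run.
#' @export
subject_betas <- function(subject_data, atlas, mask = NULL,
                          highpass_cutoff_s = 128) {
  if (is.null(mask)) mask <- atlas$labels != 0
  lapply(seq_along(subject_data$bold), function(r) {
    des <- build_design(subject_data$schedules[[r]],
                        highpass_cutoff_s = highpass_cutoff_s)
    estimate_block_betas(subject_data$bold[[r]], des, mask = mask)
  })
}
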