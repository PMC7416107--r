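#' Permute condition labels within runs
#'
#' Labels are shuffled independently within each run, preserving per-run
#' condition counts; no label moves across runs. This respects the run
#' structure under which the leave-one-run-out scheme is exchangeable.
#'
#' @param labels_by_run List of per-run condition label vectors.
#' @return List of permuted label vectors (same shape).
#' @export
permute_labels <- function(labels_by_run) {
  lapply(labels_by_run, function(l) sample(l))
}

#' Shared permutation schedule
#'
#' Generates `n_perm` within-run label shuffles from one seed. Using the same
#' schedule across ROIs of a subject gives the shared permutation indexing
#' required by the group-level mean null and the max-statistic correction.
#'
#' @param labels_by_run List of per-run label vectors.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List of class `perm_schedule` of length `n_perm`; attributes
#'   `seed` and `n_perm`.
#' @export
perm_schedule <- function(labels_by_run, n_perm = 1000, seed = 1L) {
  out <- with_seed(seed,
    lapply(seq_len(n_perm), function(i) permute_labels(labels_by_run)))
  structure(out, class = "perm_schedule", seed = seed, n_perm = n_perm)
}

# permutation p with the 1/n floor: p = max(#{null >= real}, 1) / n_perm
perm_p <- function(real, null) max(sum(null >= real), 1) / length(null)

#' Subject-level permutation null distribution and p-value
#'
#' The full cross-validation (fold assembly, train-set z-scoring, one-vs-one
#' SVMs) is re-run for every permuted label assignment; only operations that
#' are label-independent (the z-scored fold matrices) are computed once. The
#' p-value is `max(#{null >= real}, 1) / n_perm`, reproducing the floor of
#' exactly 0.001 at 1000 permutations.
#'
#' @param beta_runs List of per-run `beta_set`s.
#' @param mask ROI mask (logical array or voxel indices).
#' @param schedule A [perm_schedule()]; built from `n_perm` and `seed` when
#'   `NULL`.
#' @param n_perm,seed Used when `schedule` is `NULL`.
#' @param cost SVM cost.
#' @param subject,roi Identifiers stored in the result.
#' @return List of class `null_distribution`: `null` (length `n_perm`),
#'   `real_accuracy`, `p`, `n_perm`, `seed`, `scheme`, `subject`, `roi`.
#' @export
subject_null <- function(beta_runs, mask, schedule = NULL, n_perm = 1000,
                         seed = 1L, cost = 1,
                         subject = NA_character_, roi = NA_character_) {
  labels <- lapply(beta_runs, function(b) b$condition)
  if (is.null(schedule)) schedule <- perm_schedule(labels, n_perm, seed)
  n_perm <- attr(schedule, "n_perm")
  if (n_perm < 100) warning("n_perm < 100: permutation p granularity is coarse")
  cols <- mask_to_cols(beta_runs, mask)
  folds <- loro_folds(beta_runs, cols)
  real <- mean(cv_accuracy(folds, labels, cost = cost)$accuracy_3class)
  null <- vapply(schedule, function(perm)
    mean(cv_accuracy(folds, perm, cost = cost)$accuracy_3class), numeric(1))
  structure(list(null = null, real_accuracy = real, p = perm_p(real, null),
                 n_perm = n_perm, seed = attr(schedule, "seed"),
                 scheme = "within-run label shuffle",
                 subject = subject, roi = roi),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null_distribution%s%s: real %.3f, p = %.4g (%d permutations)\n",
              if (!is.na(x$subject)) paste0(" ", x$subject) else "",
              if (!is.na(x$roi)) paste0(" [", x$roi, "]") else "",
              x$real_accuracy, x$p, x$n_perm))
  invisible(x)
}

#' Group-level permutation p from the mean null distribution
#'
#' Permutation index `i` of the group null is the mean over subjects of their
#' `i`-th permutation accuracy (subjects must share a permutation schedule
#' length); the group p compares the mean real accuracy to that mean null
#' with the same `max(count, 1)/n_perm` convention as the subject level.
#'
#' @param subject_nulls List of [subject_null()] results (one per subject) for
#'   one ROI.
#' @param roi Optional ROI name stored in the result.
#' @return List of class `group_permutation_result`: `mean_real`, `mean_null`
#'   (length n_perm), `p_uncorrected`, `n_perm`, `roi`, `scheme`.
#' @export
group_permutation_p <- function(subject_nulls, roi = NA_character_) {
  stopifnot(length(subject_nulls) >= 1)
  n_perm <- unique(vapply(subject_nulls, function(s) s$n_perm, numeric(1)))
  if (length(n_perm) != 1)
    stop("subjects have mismatched n_perm; group null undefined")
  scheme <- unique(vapply(subject_nulls, function(s) s$scheme, character(1)))
  if (length(scheme) != 1)
    stop("subjects have mismatched permutation schemes")
  null_mat <- do.call(rbind, lapply(subject_nulls, function(s) s$null))
  mean_null <- colMeans(null_mat)
  mean_real <- mean(vapply(subject_nulls, function(s) s$real_accuracy,
                           numeric(1)))
  structure(list(mean_real = mean_real, mean_null = mean_null,
                 p_uncorrected = perm_p(mean_real, mean_null),
                 n_perm = n_perm, roi = roi, scheme = scheme),
            class = "group_permutation_result")
}

#' @export
print.group_permutation_result <- function(x, ...) {
  cat(sprintf("group_permutation_result%s: mean real %.3f, p = %.4g (%d perms)\n",
              if (!is.na(x$roi)) paste0(" [", x$roi, "]") else "",
              x$mean_real, x$p_uncorrected, x$n_perm))
  invisible(x)
}

#' Single-threshold (max-statistic) multiple-comparison correction
#'
#' For a family of ROIs sharing one permutation stream, the corrected p of an
#' ROI compares its mean real accuracy against the distribution of the
#' per-permutation maximum of the mean null accuracy across the family.
#'
#' @param group_results Named list of [group_permutation_p()] results (e.g.
#'   V1, V2, V3) computed from the same shared permutation schedule.
#' @return data.frame: roi, p_uncorrected, p_corrected.
#' @export
single_threshold_correct <- function(group_results) {
  stopifnot(length(group_results) >= 1)
  n_perm <- unique(vapply(group_results, function(g) g$n_perm, numeric(1)))
  if (length(n_perm) != 1)
    stop("ROIs with different permutation streams; correction invalid")
  null_mat <- do.call(rbind, lapply(group_results, function(g) g$mean_null))
  max_null <- apply(null_mat, 2, max)
  out <- data.frame(
    roi = names(group_results),
    p_uncorrected = vapply(group_results, function(g) g$p_uncorrected,
                           numeric(1)),
    p_corrected = vapply(group_results, function(g)
      perm_p(g$mean_real, max_null), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up BH adjustment (via [stats::p.adjust()]) with the rejection set at
#' level `q`.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param q FDR level.
#' @return List: `adjusted` (same length/names), `rejected` (logical).
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (length(p_values) == 0)
    return(list(adjusted = numeric(0), rejected = logical(0)))
  stopifnot(all(p_values > 0), all(p_values <= 1))
  adjusted <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adjusted, rejected = adjusted <= q)
}

#' Bootstrap test of group mean accuracy against chance
#'
#' Subjects are resampled with replacement `n_boot` times; the percentile CI
#' of the mean accuracy and a one-sided p (proportion of bootstrap means at
#' or below chance, floored at `1/n_boot`) are returned.
#'
#' @param subject_accuracies Numeric vector (>= 2 subjects).
#' @param n_boot Number of bootstrap samples (default 10000).
#' @param seed Integer seed.
#' @param chance Chance level (default 1/3 for three classes).
#' @param conf Confidence level of the percentile interval.
#' @return List of class `bootstrap_result`: `mean`, `ci`, `p`, `n_boot`.
#' @export
bootstrap_vs_chance <- function(subject_accuracies, n_boot = 10000, seed = 1L,
                                chance = 1/3, conf = 0.95) {
  n <- length(subject_accuracies)
  stopifnot(n >= 2)
  idx <- with_seed(seed,
    matrix(sample.int(n, n * n_boot, replace = TRUE), ncol = n_boot))
  boot_means <- colMeans(matrix(subject_accuracies[idx], ncol = n_boot))
  alpha <- 1 - conf
  structure(list(mean = mean(subject_accuracies),
                 ci = stats::quantile(boot_means,
                                      c(alpha / 2, 1 - alpha / 2), names = FALSE),
                 p = max(sum(boot_means <= chance), 1) / n_boot,
                 n_boot = n_boot, conf = conf),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap_result: mean %.3f, %g%% CI [%.3f, %.3f], p = %.4g\n",
              x$mean, 100 * x$conf, x$ci[1], x$ci[2], x$p))
  invisible(x)
}
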