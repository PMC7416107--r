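#' Group test result container
#'
#' @param test Test name.
#' @param statistic Named statistic value (U, F, chi-square, V, ...).
#' @param df Degrees of freedom (length 0, 1 or 2).
#' @param p p-value.
#' @param effect_size Optional effect size (partial eta squared).
#' @param degenerate Logical flag for zero-error degenerate fits.
#' @return List of class `group_test_result`.
#' @export
group_test_result <- function(test, statistic, df = numeric(0), p = NA_real_,
                              effect_size = NA_real_, degenerate = FALSE) {
  structure(list(test = test, statistic = statistic, df = df, p = p,
                 effect_size = effect_size, degenerate = degenerate),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  dftxt <- if (length(x$df) == 2) sprintf("(%g,%g)", x$df[1], x$df[2])
           else if (length(x$df) == 1) sprintf("(df=%g)", x$df) else ""
  cat(sprintf("%s: %s%s = %.4g, p = %.4g%s%s\n", x$test,
              names(x$statistic)[1], dftxt, x$statistic[1], x$p,
              if (!is.na(x$effect_size))
                sprintf(", partial eta^2 = %.3f", x$effect_size) else "",
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

# U statistic of group A from midranks
u_stat <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Mann-Whitney U test
#'
#' Midrank tie handling; the reported `U` is `min(U_A, U_B)`. The p-value is
#' exact by full enumeration of group assignments when `min(nA, nB) <= 8` and
#' there are no ties, otherwise a normal approximation with tie correction is
#' used. Two-sided.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @param exact_when_small Use exact enumeration when feasible.
#' @return A [group_test_result()] with statistic `U`.
#' @export
mann_whitney <- function(a, b, exact_when_small = TRUE) {
  nA <- length(a); nB <- length(b)
  if (nA == 0 || nB == 0) stop("both groups must be non-empty")
  uA <- u_stat(a, b)
  u <- min(uA, nA * nB - uA)
  ties <- anyDuplicated(c(a, b)) > 0
  if (exact_when_small && !ties && min(nA, nB) <= 8) {
    pooled <- c(a, b)
    combs <- utils::combn(nA + nB, nA)
    r <- rank(pooled)
    uAll <- colSums(matrix(r[combs], nrow = nA)) - nA * (nA + 1) / 2
    centre <- nA * nB / 2
    p <- mean(abs(uAll - centre) >= abs(uA - centre))
  } else {
    n <- nA + nB
    tie_tab <- table(c(a, b))
    sigma2 <- nA * nB / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (uA - nA * nB / 2) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  group_test_result("Mann-Whitney", c(U = u), p = min(p, 1))
}

# cell-mean helper: complete balanced table as a 3-d array [subject, f1, f2]
table_to_array <- function(df, dv, subject, f1, f2) {
  s <- factor(df[[subject]]); A <- factor(df[[f1]]); E <- factor(df[[f2]])
  arr <- tapply(df[[dv]], list(s, A, E), mean)
  if (anyNA(arr)) stop("missing cells in the design table; no imputation")
  counts <- table(s, A, E)
  if (any(counts != 1)) stop("design table must have exactly one value per cell")
  arr
}

#' Two-way repeated-measures ANOVA with a linear eccentricity contrast
#'
#' Full within-subject decomposition of a subject x area x eccentricity table
#' (main effects, interaction, each tested against its effect-by-subject
#' error stratum, no sphericity correction) with partial eta squared
#' `SS_effect / (SS_effect + SS_error)`. The linear contrast applies weights
#' (-1, 0, +1) to each subject's eccentricity means (averaged over areas) and
#' tests the contrast scores against zero as a one-sample F with `(1, n - 1)`
#' degrees of freedom.
#'
#' @param df Long data.frame.
#' @param dv,subject,f1,f2 Column names (dependent variable, subject id, the
#'   two within factors; `f2` is the factor receiving the linear contrast).
#' @param contrast_weights Contrast weights over the levels of `f2`
#'   (default: evenly spaced linear weights, (-1, 0, +1) for three levels).
#' @return Named list of [group_test_result()]: one per effect (`f1`, `f2`,
#'   interaction) plus `linear_contrast`.
#' @export
rm_anova <- function(df, dv = "accuracy", subject = "subject", f1 = "area",
                     f2 = "eccentricity", contrast_weights = NULL) {
  y <- table_to_array(df, dv, subject, f1, f2)
  S <- dim(y)[1]; a <- dim(y)[2]; e <- dim(y)[3]
  m <- mean(y)
  m_i <- apply(y, 1, mean); m_j <- apply(y, 2, mean); m_k <- apply(y, 3, mean)
  m_ij <- apply(y, c(1, 2), mean); m_ik <- apply(y, c(1, 3), mean)
  m_jk <- apply(y, c(2, 3), mean)

  ss_A <- S * e * sum((m_j - m)^2)
  ss_E <- S * a * sum((m_k - m)^2)
  ss_AE <- S * sum((m_jk - outer(m_j, rep(1, e)) -
                      outer(rep(1, a), m_k) + m)^2)
  ss_AS <- e * sum((m_ij - outer(m_i, rep(1, a)) -
                      outer(rep(1, S), m_j) + m)^2)
  ss_ES <- a * sum((m_ik - outer(m_i, rep(1, e)) -
                      outer(rep(1, S), m_k) + m)^2)
  ss_S <- a * e * sum((m_i - m)^2)
  ss_tot <- sum((y - m)^2)
  ss_AES <- ss_tot - ss_A - ss_E - ss_AE - ss_S - ss_AS - ss_ES

  f_test <- function(name, ss_eff, df_eff, ss_err, df_err) {
    if (ss_err <= 1e-12 * max(ss_tot, 1e-300)) {
      return(group_test_result(name, c(F = if (ss_eff > 0) Inf else 0),
                               df = c(df_eff, df_err), p = NA_real_,
                               effect_size = if (ss_eff + ss_err > 0)
                                 ss_eff / (ss_eff + ss_err) else 0,
                               degenerate = TRUE))
    }
    F <- (ss_eff / df_eff) / (ss_err / df_err)
    group_test_result(name, c(F = F), df = c(df_eff, df_err),
                      p = stats::pf(F, df_eff, df_err, lower.tail = FALSE),
                      effect_size = ss_eff / (ss_eff + ss_err))
  }
  out <- list(
    f_test(f1, ss_A, a - 1, ss_AS, (a - 1) * (S - 1)),
    f_test(f2, ss_E, e - 1, ss_ES, (e - 1) * (S - 1)),
    f_test(paste0(f1, ":", f2), ss_AE, (a - 1) * (e - 1), ss_AES,
           (a - 1) * (e - 1) * (S - 1)))
  names(out) <- c(f1, f2, paste0(f1, ":", f2))

  if (is.null(contrast_weights)) contrast_weights <- seq(-1, 1, length.out = e)
  stopifnot(length(contrast_weights) == e)
  L <- as.numeric(m_ik %*% contrast_weights)
  vL <- stats::var(L)
  out$linear_contrast <- if (vL <= 1e-12 * max(mean(L)^2, 1e-300) || S < 2) {
    group_test_result("linear_contrast", c(F = if (mean(L) != 0) Inf else 0),
                      df = c(1, S - 1), p = NA_real_, degenerate = TRUE)
  } else {
    F <- mean(L)^2 / (vL / S)
    group_test_result("linear_contrast", c(F = F), df = c(1, S - 1),
                      p = stats::pf(F, 1, S - 1, lower.tail = FALSE),
                      effect_size = F / (F + (S - 1)))
  }
  out$ss <- c(ss_A, ss_E, ss_AE, ss_S, ss_AS, ss_ES, ss_AES, total = ss_tot)
  out
}

#' Mixed-design ANOVA (one between-subject factor, two within)
#'
#' Sequential decomposition matching `aov` with an
#' `Error(subject/(f1*f2))` stratum structure: the group effect is tested
#' against between-subject error; each within effect and its group
#' interaction against the corresponding effect-by-subject-within-group
#' error. Balanced within-subject design required; group sizes may differ.
#'
#' @param df Long data.frame.
#' @param dv,subject,group,f1,f2 Column names.
#' @param contrast_weights Linear contrast weights over the levels of `f2`.
#' @return Named list of [group_test_result()] (group, f1, f1:group, f2,
#'   f2:group, f1:f2, f1:f2:group, linear_contrast) plus `ss`.
#' @export
mixed_anova <- function(df, dv = "accuracy", subject = "subject",
                        group = "group", f1 = "area", f2 = "eccentricity",
                        contrast_weights = NULL) {
  y <- table_to_array(df, dv, subject, f1, f2)
  subj_group <- tapply(as.character(df[[group]]), factor(df[[subject]]),
                       function(v) unique(v))
  if (any(lengths(subj_group) != 1)) stop("each subject must be in one group")
  grp <- factor(unlist(subj_group))
  S <- dim(y)[1]; a <- dim(y)[2]; e <- dim(y)[3]
  ng <- table(grp); G <- length(ng)
  ss_tot <- sum((y - mean(y))^2)

  f_test <- function(name, ss_eff, df_eff, ss_err, df_err) {
    if (ss_err <= 1e-12 * max(ss_tot, 1e-300))
      return(group_test_result(name, c(F = if (ss_eff > 0) Inf else 0),
                               df = c(df_eff, df_err), p = NA_real_,
                               degenerate = TRUE))
    F <- (ss_eff / df_eff) / (ss_err / df_err)
    group_test_result(name, c(F = F), df = c(df_eff, df_err),
                      p = stats::pf(F, df_eff, df_err, lower.tail = FALSE),
                      effect_size = ss_eff / (ss_eff + ss_err))
  }

  # between stratum: one-way ANOVA on subject means, scaled by cells/subject
  m_i <- apply(y, 1, mean)
  m_g <- tapply(m_i, grp, mean)
  mm <- mean(m_i)
  ss_G <- a * e * sum(ng * (m_g - mm)^2)
  ss_SG <- a * e * sum((m_i - m_g[grp])^2)

  # within strata: subject-centred profiles
  m_ij <- apply(y, c(1, 2), mean) - m_i   # S x a, subject-centred
  m_ik <- apply(y, c(1, 3), mean) - m_i   # S x e
  d_ijk <- y - array(rep(apply(y, c(1, 2), mean), e), dim = dim(y)) -
    aperm(array(rep(apply(y, c(1, 3), mean), a), dim = c(S, e, a)), c(1, 3, 2)) +
    array(m_i, dim = dim(y))

  within_ss <- function(prof, mult) {
    cbar <- colMeans(prof)
    cg <- apply(prof, 2, function(col) tapply(col, grp, mean))
    cg <- matrix(cg, nrow = G)
    ss_main <- mult * S * sum(cbar^2)
    ss_int <- mult * sum(as.vector(ng) * (cg - matrix(cbar, G, ncol(prof),
                                                      byrow = TRUE))^2)
    fitted <- cg[as.integer(grp), , drop = FALSE]
    ss_err <- mult * sum((prof - fitted)^2)
    c(main = ss_main, int = ss_int, err = ss_err)
  }
  ssA <- within_ss(m_ij, e)
  ssE <- within_ss(m_ik, a)
  ssAE <- within_ss(matrix(d_ijk, nrow = S), 1)

  out <- list(
    group = f_test(group, ss_G, G - 1, ss_SG, S - G),
    f1 = f_test(f1, ssA["main"], a - 1, ssA["err"], (a - 1) * (S - G)),
    f1_group = f_test(paste0(f1, ":", group), ssA["int"], (a - 1) * (G - 1),
                      ssA["err"], (a - 1) * (S - G)),
    f2 = f_test(f2, ssE["main"], e - 1, ssE["err"], (e - 1) * (S - G)),
    f2_group = f_test(paste0(f2, ":", group), ssE["int"], (e - 1) * (G - 1),
                      ssE["err"], (e - 1) * (S - G)),
    f1_f2 = f_test(paste0(f1, ":", f2), ssAE["main"], (a - 1) * (e - 1),
                   ssAE["err"], (a - 1) * (e - 1) * (S - G)),
    f1_f2_group = f_test(paste0(f1, ":", f2, ":", group), ssAE["int"],
                         (a - 1) * (e - 1) * (G - 1), ssAE["err"],
                         (a - 1) * (e - 1) * (S - G)))
  names(out) <- c(group, f1, paste0(f1, ":", group), f2,
                  paste0(f2, ":", group), paste0(f1, ":", f2),
                  paste0(f1, ":", f2, ":", group))

  if (is.null(contrast_weights)) contrast_weights <- seq(-1, 1, length.out = e)
  stopifnot(length(contrast_weights) == e)
  Lc <- as.numeric((m_ik + m_i) %*% contrast_weights)
  # pooled within-group one-sample contrast F (grand contrast mean vs zero,
  # error from within-group variability)
  Lg <- tapply(Lc, grp, mean)
  ss_c_err <- sum((Lc - Lg[grp])^2)
  if (ss_c_err <= 1e-12 * max(mean(Lc)^2, 1e-300)) {
    out$linear_contrast <- group_test_result("linear_contrast",
                                             c(F = if (mean(Lc) != 0) Inf else 0),
                                             df = c(1, S - G), p = NA_real_,
                                             degenerate = TRUE)
  } else {
    F <- S * mean(Lc)^2 / (ss_c_err / (S - G))
    out$linear_contrast <- group_test_result(
      "linear_contrast", c(F = F), df = c(1, S - G),
      p = stats::pf(F, 1, S - G, lower.tail = FALSE),
      effect_size = F / (F + (S - G)))
  }
  out$ss <- c(group = ss_G, subj_within = ss_SG,
              ssA, ssE, ssAE, total = ss_tot)
  out
}

#' Friedman rank test
#'
#' Rank-based non-parametric counterpart of the one-way repeated-measures
#' ANOVA, with midranks for ties and the standard tie correction;
#' `chi-square` has `k - 1` degrees of freedom.
#'
#' @param mat Numeric matrix, subjects in rows, conditions in columns.
#' @return A [group_test_result()] with statistic `chi-square`.
#' @export
friedman <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  stopifnot(n >= 2, k >= 2)
  ranks <- t(apply(mat, 1, rank))
  Rj <- colSums(ranks)
  chi <- 12 * sum((Rj - n * (k + 1) / 2)^2) / (n * k * (k + 1))
  ties <- apply(mat, 1, function(row) {
    tt <- table(row); sum(tt^3 - tt)
  })
  C <- 1 - sum(ties) / (n * k * (k^2 - 1))
  if (C > 0) chi <- chi / C
  group_test_result("Friedman", c(`chi-square` = chi), df = k - 1,
                    p = stats::pchisq(chi, k - 1, lower.tail = FALSE))
}

#' Non-parametric region-by-group interaction test
#'
#' Per subject the difference between auditory-cortex and early-visual-cortex
#' decoding accuracy is computed; the difference scores are compared between
#' groups with the Mann-Whitney test. Robust to ceiling effects that preclude
#' a parametric interaction.
#'
#' @param acc_ac,acc_evc Per-subject accuracies (same order).
#' @param groups Factor/character vector of group membership.
#' @return A [group_test_result()] with statistic `U`.
#' @export
interaction_nonparam <- function(acc_ac, acc_evc, groups) {
  stopifnot(length(acc_ac) == length(acc_evc),
            length(acc_ac) == length(groups))
  diffs <- acc_ac - acc_evc
  keep <- !is.na(diffs)
  if (any(!keep)) warning(sum(!keep), " subject(s) dropped (missing ROI accuracy)")
  diffs <- diffs[keep]; groups <- factor(groups[keep])
  stopifnot(nlevels(groups) == 2)
  mann_whitney(diffs[groups == levels(groups)[1]],
               diffs[groups == levels(groups)[2]])
}

#' Wilcoxon signed-rank test
#'
#' Zero differences are dropped (Wilcoxon's original convention); `V` is the
#' sum of ranks of positive differences (midranks for tied magnitudes). Exact
#' p by enumeration of all sign patterns for `n <= 15` retained pairs,
#' normal approximation with tie correction otherwise. Two-sided by default.
#'
#' @param x,y Paired numeric vectors, or `y = NULL` to test `x` against zero.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return A [group_test_result()] with statistic `V`.
#' @export
wilcoxon_signed <- function(x, y = NULL,
                            alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x else x - y
  stopifnot(length(d) >= 2)
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all differences are zero")
    return(group_test_result("Wilcoxon signed-rank", c(V = 0), p = 1))
  }
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  centre <- n * (n + 1) / 4
  if (n <= 15) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vAll <- as.numeric(signs %*% r)
    p <- switch(alternative,
                two.sided = mean(abs(vAll - centre) >= abs(v - centre)),
                greater = mean(vAll >= v),
                less = mean(vAll <= v))
  } else {
    tie_tab <- table(abs(d))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (v - centre) / sqrt(sigma2)
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
  }
  group_test_result("Wilcoxon signed-rank", c(V = v), p = min(p, 1))
}
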