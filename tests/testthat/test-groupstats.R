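test_that("Mann-Whitney handles separation, symmetry and ties", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$statistic), 0)
  # identical singletons: midranks put U at its centre nA*nB/2
  r2 <- mann_whitney(2, 2)
  expect_equal(unname(r2$statistic), 0.5)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("exact Mann-Whitney p matches the enumeration oracle (nA=nB=4)", {
  # oracle: stats::wilcox.test computes the exact null by a different route
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(4); b <- rnorm(4, mean = i %% 3)
    ours <- mann_whitney(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    expect_equal(unname(ours$statistic),
                 min(ref$statistic, 16 - ref$statistic))
  }
  # all 70 assignments enumerated: p values live on the exact support
  p_grid <- unique(vapply(1:8, function(u)
    mann_whitney(1:4 + u * 0.01 + 0.001, 2:5)$p, numeric(1)))
  expect_true(all(abs(p_grid * 70 - round(p_grid * 70)) < 1e-9))
})

test_that("repeated-measures ANOVA agrees with the aov oracle", {
  set.seed(11)
  for (i in 1:25) {
    df <- expand.grid(subject = paste0("s", 1:8), area = c("V1", "V2", "V3"),
                      eccentricity = c("fovea", "periphery", "far_periphery"))
    df$eccentricity <- factor(df$eccentricity,
                              levels = c("fovea", "periphery", "far_periphery"))
    df$accuracy <- runif(nrow(df))
    ours <- rm_anova(df)
    oracle <- summary(aov(accuracy ~ area * eccentricity +
                            Error(subject / (area * eccentricity)), data = df))
    get_row <- function(stratum, term) {
      tab <- oracle[[stratum]][[1]]
      tab[trimws(rownames(tab)) == term, ]
    }
    o_area <- get_row("Error: subject:area", "area")
    expect_equal(unname(ours$area$statistic), o_area$`F value`, tolerance = 1e-8)
    expect_equal(ours$area$p, o_area$`Pr(>F)`, tolerance = 1e-8)
    o_ecc <- get_row("Error: subject:eccentricity", "eccentricity")
    expect_equal(unname(ours$eccentricity$statistic), o_ecc$`F value`,
                 tolerance = 1e-8)
    o_int <- get_row("Error: subject:area:eccentricity", "area:eccentricity")
    expect_equal(unname(ours$`area:eccentricity`$statistic),
                 o_int$`F value`, tolerance = 1e-8)
    # partial eta squared from the oracle's own SS
    err <- get_row("Error: subject:eccentricity", "Residuals")
    expect_equal(ours$eccentricity$effect_size,
                 o_ecc$`Sum Sq` / (o_ecc$`Sum Sq` + err$`Sum Sq`),
                 tolerance = 1e-8)
    # SS partition identity
    expect_equal(sum(ours$ss[1:7]), unname(ours$ss["total"]), tolerance = 1e-8)
  }
})

test_that("rm ANOVA degenerate limits behave", {
  df <- expand.grid(subject = paste0("s", 1:6), area = c("V1", "V2", "V3"),
                    eccentricity = c("fovea", "periphery", "far_periphery"))
  base <- rnorm(6)[as.integer(factor(df$subject))]
  df$accuracy <- base + as.integer(factor(df$area)) * 0.1
  out <- rm_anova(df)
  expect_lt(abs(unname(out$eccentricity$statistic)), 1e-6)
  expect_lt(abs(unname(out$linear_contrast$statistic)), 1e-6)
  # noiseless additive gradient: contrast F flagged degenerate, not infinite p
  df$accuracy <- base + c(fovea = 0, periphery = 0.1,
                          far_periphery = 0.2)[as.character(df$eccentricity)]
  out2 <- rm_anova(df)
  expect_true(out2$linear_contrast$degenerate)
})

test_that("linear eccentricity contrast detects an induced gradient", {
  set.seed(13)
  df <- expand.grid(subject = paste0("s", 1:8), area = c("V1", "V2", "V3"),
                    eccentricity = c("fovea", "periphery", "far_periphery"))
  df$eccentricity <- factor(df$eccentricity,
                            levels = c("fovea", "periphery", "far_periphery"))
  slope <- c(fovea = 0, periphery = 0.1, far_periphery = 0.2)
  df$accuracy <- 0.4 + slope[as.character(df$eccentricity)] +
    rnorm(nrow(df), sd = 0.05)
  out <- rm_anova(df)
  expect_lt(out$linear_contrast$p, 0.05)
  expect_equal(length(out$linear_contrast$df), 2)
  expect_equal(out$linear_contrast$df, c(1, 7))
})

test_that("mixed ANOVA matches aov and satisfies the SS partition", {
  set.seed(17)
  for (i in 1:10) {
    ns <- c(blind = 4, sighted = 5)
    df <- do.call(rbind, lapply(names(ns), function(g)
      expand.grid(subject = paste0(g, 1:ns[[g]]), group = g,
                  area = c("V1", "V2", "V3"),
                  eccentricity = c("fovea", "periphery", "far_periphery"))))
    df$accuracy <- runif(nrow(df))
    ours <- mixed_anova(df)
    oracle <- summary(aov(accuracy ~ group * area * eccentricity +
                            Error(subject / (area * eccentricity)), data = df))
    g_tab <- oracle[["Error: subject"]][[1]]
    expect_equal(unname(ours$group$statistic),
                 g_tab[trimws(rownames(g_tab)) == "group", "F value"],
                 tolerance = 1e-8)
    a_tab <- oracle[["Error: subject:area"]][[1]]
    expect_equal(unname(ours$area$statistic),
                 a_tab[trimws(rownames(a_tab)) == "area", "F value"],
                 tolerance = 1e-8)
    expect_equal(unname(ours$`area:group`$statistic),
                 a_tab[trimws(rownames(a_tab)) == "group:area", "F value"],
                 tolerance = 1e-8)
    e_tab <- oracle[["Error: subject:eccentricity"]][[1]]
    expect_equal(unname(ours$`eccentricity:group`$statistic),
                 e_tab[trimws(rownames(e_tab)) == "group:eccentricity",
                       "F value"],
                 tolerance = 1e-8)
    ae_tab <- oracle[["Error: subject:area:eccentricity"]][[1]]
    expect_equal(unname(ours$`area:eccentricity:group`$statistic),
                 ae_tab[trimws(rownames(ae_tab)) == "group:area:eccentricity",
                        "F value"],
                 tolerance = 1e-8)
    expect_equal(unname(sum(ours$ss[names(ours$ss) != "total"])),
                 unname(ours$ss["total"]), tolerance = 1e-8)
  }
})

test_that("mixed ANOVA recovers an injected group offset specifically", {
  set.seed(23)
  hits_group <- 0; hits_other <- 0
  for (i in 1:20) {
    df <- do.call(rbind, lapply(c("blind", "sighted"), function(g)
      expand.grid(subject = paste0(g, 1:6), group = g,
                  area = c("V1", "V2", "V3"),
                  eccentricity = c("fovea", "periphery", "far_periphery"))))
    df$accuracy <- 0.5 + 0.15 * (df$group == "blind") +
      rnorm(nrow(df), sd = 0.08)
    out <- mixed_anova(df)
    hits_group <- hits_group + (out$group$p < 0.05)
    hits_other <- hits_other + (out$`area:group`$p < 0.05)
  }
  expect_gte(hits_group, 16)
  expect_lte(hits_other, 4)
  # two identical groups: group F is (numerically) zero
  cells <- expand.grid(subject = 1:4, area = c("V1", "V2"),
                       eccentricity = c("fovea", "periphery"))
  vals <- runif(nrow(cells))
  df2 <- rbind(
    data.frame(cells, group = "a", accuracy = vals),
    data.frame(cells, group = "b", accuracy = vals))
  df2$subject <- paste0(df2$group, df2$subject)
  expect_lt(abs(unname(mixed_anova(df2)$group$statistic)), 1e-10)
})

test_that("Friedman test: closed form, ties, and the null moment", {
  # all subjects rank the three conditions identically: chi-square = 16
  m <- matrix(rep(c(1, 2, 3), each = 8), 8)
  expect_equal(unname(friedman(m)$statistic), 16)
  # identical columns: zero
  m0 <- matrix(rep(rnorm(8), 3), 8)
  expect_equal(unname(friedman(m0)$statistic), 0)
  # agreement with the stats oracle on untied data
  set.seed(29)
  for (i in 1:10) {
    mm <- matrix(rnorm(24), 8)
    ref <- friedman.test(mm)
    ours <- friedman(mm)
    expect_equal(unname(ours$statistic), unname(ref$statistic),
                 tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
  # exchangeable null: mean chi-square ~ k - 1 = 2
  set.seed(31)
  chis <- replicate(2000, unname(friedman(matrix(rnorm(24), 8))$statistic))
  expect_lt(abs(mean(chis) - 2), 3 * sd(chis) / sqrt(2000))
})

test_that("Wilcoxon signed-rank: exact enumeration and limits", {
  set.seed(37)
  x <- rnorm(6); y <- rnorm(6)
  ours <- wilcoxon_signed(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  expect_equal(unname(ours$statistic), unname(ref$statistic))
  # monotone increase in every pair: minimal one-sided p = 1 / 2^n
  inc <- wilcoxon_signed(1:6 + 0.5, 1:6, alternative = "greater")
  expect_equal(inc$p, 1 / 64)
  expect_warning(z <- wilcoxon_signed(rep(1, 5), rep(1, 5)), "zero")
  expect_equal(z$p, 1)
  # antisymmetric differences sit at the null centre
  anti <- wilcoxon_signed(c(-3, -2, -1, 1, 2, 3))
  expect_equal(anti$p, 1)
})

test_that("the AC-EVC interaction test is rank-invariant and calibrated", {
  set.seed(41)
  g <- rep(c("blind", "sighted"), each = 8)
  ac <- runif(16, 0.9, 1); evc <- runif(16, 0.3, 0.7)
  r1 <- interaction_nonparam(ac, evc, g)
  # common monotone transform of the differences leaves U unchanged
  d <- ac - evc
  r2 <- mann_whitney(exp(d[g == "blind"]), exp(d[g == "sighted"]))
  expect_equal(r1$statistic, r2$statistic)
  # missing accuracies drop the subject with a warning
  ac2 <- ac; ac2[3] <- NA
  expect_warning(interaction_nonparam(ac2, evc, g), "dropped")
})

test_that("distribution-shift cohorts yield a significant interaction", {
  # blind-like: higher EVC accuracy, AC at ceiling in both groups
  set.seed(43)
  hits <- 0
  for (i in 1:100) {
    evc_b <- pmin(rnorm(8, 0.66, 0.08), 1); evc_s <- pmin(rnorm(10, 0.41, 0.08), 1)
    ac_b <- pmin(rnorm(8, 0.93, 0.05), 1); ac_s <- pmin(rnorm(10, 0.97, 0.03), 1)
    r <- interaction_nonparam(c(ac_b, ac_s), c(evc_b, evc_s),
                              rep(c("blind", "sighted"), c(8, 10)))
    hits <- hits + (r$p < 0.05)
  }
  expect_gte(hits, 80)
})
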