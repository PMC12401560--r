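test_that("Cohen's d matches its textbook definition", {
  x <- c(1, 2, 3, 4)
  y <- c(2, 3, 4, 5)
  sp <- sqrt((3 * var(x) + 3 * var(y)) / 6)
  expect_equal(cohens_d(x, y), (mean(x) - mean(y)) / sp)
  expect_equal(cohens_d(y, x), -cohens_d(x, y))
  expect_equal(cohens_d(x, x), 0)
})

test_that("type-III ANCOVA agrees with a single-term-deletion oracle", {
  set.seed(10)
  n <- 30
  tbl <- expand.grid(subject_id = sprintf("s%02d", seq_len(n)),
                     electrode = c("O1", "Pz"), stringsAsFactors = FALSE)
  tbl$group <- rep(rep(c("HOA", "aMCI", "naMCI"), each = n / 3), 2)
  tbl$F_snr <- rnorm(2 * n, 10, 2)
  tbl$f_plus <- 2 + (tbl$group == "HOA") * 1.5 + 0.1 * tbl$F_snr +
    rnorm(2 * n, sd = 0.8)
  res <- ancova_group_by_electrode(tbl)
  expect_setequal(res$anova$term, c("group", "electrode", "group:electrode",
                                    "F_snr"))
  # oracle: drop1 on the same sum-contrast fit reproduces type-III F
  d1 <- drop1(res$fit, . ~ ., test = "F")
  for (trm in c("group", "electrode", "group:electrode")) {
    i <- match(trm, res$anova$term)
    expect_equal(res$anova$F[i], d1[trm, "F value"], tolerance = 1e-10)
    expect_equal(res$anova$p[i], d1[trm, "Pr(>F)"], tolerance = 1e-10)
  }
  # partial eta^2 = SS_term / (SS_term + SS_error)
  sse <- sum(residuals(res$fit)^2)
  ss_g <- d1["group", "Sum of Sq"]
  expect_equal(res$anova$partial_eta_sq[match("group", res$anova$term)],
               ss_g / (ss_g + sse), tolerance = 1e-10)
  # planted group effect is detected
  expect_lt(res$anova$p[match("group", res$anova$term)], 0.01)
  # pairwise d: 3 contrasts, HOA above both MCI groups
  expect_equal(nrow(res$pairwise_d), 3)
  d_ha <- res$pairwise_d$d[res$pairwise_d$group1 == "HOA" &
                             res$pairwise_d$group2 == "aMCI"]
  expect_gt(d_ha, 0.5)
})

test_that("the max-electrode design and null data behave as expected", {
  set.seed(11)
  tbl <- data.frame(subject_id = sprintf("s%02d", 1:36),
                    group = rep(c("HOA", "aMCI", "naMCI"), each = 12),
                    electrode = "max",
                    F_snr = rnorm(36, 10, 2))
  tbl$f_plus_max <- 3 + rnorm(36)
  res <- ancova_group_by_electrode(tbl, outcome = "f_plus_max",
                                   design = "max")
  expect_setequal(res$anova$term, c("group", "F_snr"))
  expect_gt(res$anova$p[res$anova$term == "group"], 0.05)
  # dropping the covariate gives a plain one-way ANOVA matching aov
  res0 <- ancova_group_by_electrode(tbl, outcome = "f_plus_max",
                                    covariate = NULL, design = "max")
  ref <- summary(aov(f_plus_max ~ group, tbl))[[1]]
  expect_equal(res0$anova$F[1], ref["group", "F value"], tolerance = 1e-10)
  # constant outcome is rejected as singular? no - constant covariate is
  tbl$F_snr <- 5
  expect_error(ancova_group_by_electrode(tbl, outcome = "f_plus_max",
                                         design = "max"), "aliased")
})

test_that("Mann-Whitney matches wilcox.test and a counting oracle", {
  x <- c(1.2, 3.4, 2.2, 5.0, 4.1)
  y <- c(2.0, 2.2, 6.1, 0.5, 3.3, 4.4)
  mw <- mann_whitney_z(x, y)
  # counting oracle for U1 (ties count 1/2)
  u1 <- sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(mw$U, min(u1, length(x) * length(y) - u1))
  expect_lte(mw$Z, 0)
  # p agrees with the tie-corrected normal approximation of wilcox.test
  ref <- suppressWarnings(wilcox.test(x, y, correct = FALSE, exact = FALSE))
  expect_equal(mw$p, ref$p.value, tolerance = 1e-10)
  # identical samples: Z = 0, p = 1
  mw0 <- mann_whitney_z(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw0$Z, 0)
  expect_equal(mw0$p, 1)
  # a complete separation is highly significant
  mws <- mann_whitney_z(1:10, 101:110)
  expect_lt(mws$p, 0.001)
})

test_that("Kruskal-Wallis post hocs carry the Bonferroni factor", {
  set.seed(12)
  tbl <- data.frame(group = rep(c("A", "B", "C"), each = 15),
                    y = c(rnorm(15), rnorm(15, 3), rnorm(15)))
  res <- kruskal_wallis_posthoc(tbl, "y")
  ref <- kruskal.test(tbl$y, factor(tbl$group))
  expect_equal(res$kruskal$H, unname(ref$statistic))
  expect_equal(res$kruskal$p, ref$p.value)
  expect_equal(nrow(res$pairwise), 3)
  expect_equal(res$pairwise$p_bonferroni, pmin(1, res$pairwise$p * 3))
  # the planted A-B difference survives correction; A-C does not reach it
  pab <- res$pairwise$p_bonferroni[res$pairwise$group1 == "A" &
                                     res$pairwise$group2 == "B"]
  pac <- res$pairwise$p_bonferroni[res$pairwise$group1 == "A" &
                                     res$pairwise$group2 == "C"]
  expect_lt(pab, 0.01)
  expect_gt(pac, 0.05)
  # NA outcomes are dropped, not propagated
  tbl$y[1] <- NA
  expect_false(anyNA(kruskal_wallis_posthoc(tbl, "y")$pairwise$p))
})

test_that("bootstrap regression is exact on noiseless data and deterministic", {
  d <- data.frame(x = seq_len(20), y = 2 * seq_len(20) + 5)
  res <- bootstrap_regression(d, y ~ x, B = 200, seed = 3)
  co <- res$coefficients
  expect_equal(co$estimate[co$term == "x"], 2, tolerance = 1e-10)
  expect_equal(co$ci_lower[co$term == "x"], 2, tolerance = 1e-10)
  expect_equal(co$ci_upper[co$term == "x"], 2, tolerance = 1e-10)
  expect_equal(co$p_boot[co$term == "x"], 2 / 201, tolerance = 1e-12)
  # determinism
  res2 <- bootstrap_regression(d, y ~ x, B = 200, seed = 3)
  expect_identical(res$coefficients, res2$coefficients)
  res3 <- bootstrap_regression(d, y ~ x, B = 200, seed = 4)
  expect_false(identical(res$coefficients$ci_lower, res3$coefficients$ci_lower))
  # a pure-noise predictor keeps 0 inside its interval
  set.seed(5)
  dn <- data.frame(x = rnorm(60), z = rnorm(60))
  dn$y <- 1 + 3 * dn$x + rnorm(60)
  rn <- bootstrap_regression(dn, y ~ x + z, B = 500, seed = 6)$coefficients
  expect_lt(rn$ci_lower[rn$term == "z"], 0)
  expect_gt(rn$ci_upper[rn$term == "z"], 0)
  expect_lt(rn$ci_lower[rn$term == "x"], 3)
  expect_gt(rn$ci_upper[rn$term == "x"], 3)
  # standardized slope of a standardized problem equals the correlation
  ds <- data.frame(x = scale(rnorm(50))[, 1])
  ds$y <- 0.5 * ds$x + rnorm(50, sd = 0.5)
  rs <- bootstrap_regression(ds, y ~ x, B = 100, seed = 7)$coefficients
  expect_equal(rs$std_estimate[rs$term == "x"], cor(ds$x, ds$y),
               tolerance = 1e-10)
  # guardrails
  dd <- data.frame(x = 1:10); dd$w <- 2 * dd$x; dd$y <- rnorm(10)
  expect_error(bootstrap_regression(dd, y ~ x + w, B = 100, seed = 1),
               "collinear")
  expect_warning(bootstrap_regression(d, y ~ x, B = 50, seed = 1), "B < 100")
})

test_that("ICC mean squares match an aov oracle", {
  set.seed(20)
  n <- 25; k <- 2
  subj <- rnorm(n, 10, 2)
  m <- cbind(s1 = subj + rnorm(n), s2 = subj + 0.5 + rnorm(n))
  res <- icc_two_way(m)
  long <- data.frame(y = c(m), subject = factor(rep(seq_len(n), k)),
                     session = factor(rep(seq_len(k), each = n)))
  av <- summary(aov(y ~ subject + session, long))[[1]]
  expect_equal(res$MSR, av["subject", "Mean Sq"], tolerance = 1e-10)
  expect_equal(res$MSC, av["session", "Mean Sq"], tolerance = 1e-10)
  expect_equal(res$MSE, av["Residuals", "Mean Sq"], tolerance = 1e-10)
  # point estimates from the standard mean-square formulas
  expect_equal(res$icc$est[res$icc$type == "ICC(C,1)"],
               (res$MSR - res$MSE) / (res$MSR + (k - 1) * res$MSE))
  expect_equal(res$icc$est[res$icc$type == "ICC(C,k)"],
               1 - res$MSE / res$MSR)
  # session-bias F is MSC/MSE with the aov p value
  expect_equal(res$bias_F$statistic, res$MSC / res$MSE)
  expect_equal(res$bias_F$p, av["session", "Pr(>F)"], tolerance = 1e-10)
})

test_that("ICC respects ordering and shift invariances", {
  set.seed(21)
  n <- 40
  subj <- rnorm(n, 5, 1.5)
  base <- cbind(subj + rnorm(n, sd = 0.8), subj + rnorm(n, sd = 0.8))
  res <- icc_two_way(base)
  est <- setNames(res$icc$est, res$icc$type)
  expect_gte(est["ICC(C,k)"], est["ICC(C,1)"] - 1e-12)
  # with a genuine session offset, agreement falls below consistency
  rb <- icc_two_way(cbind(base[, 1], base[, 2] + 1))
  eb <- setNames(rb$icc$est, rb$icc$type)
  expect_lt(eb["ICC(A,1)"], eb["ICC(C,1)"])
  expect_lt(eb["ICC(A,k)"], eb["ICC(C,k)"])
  expect_equal(unname(eb["ICC(C,1)"]), unname(est["ICC(C,1)"]),
               tolerance = 1e-12)   # consistency ignores the offset
  # CIs bracket their estimates
  expect_true(all(res$icc$ci_lower <= res$icc$est + 1e-9))
  expect_true(all(res$icc$ci_upper >= res$icc$est - 1e-9))
  # a constant session shift leaves consistency at 1 but drags agreement down
  shifted <- cbind(subj, subj + 2)
  rs <- icc_two_way(shifted)
  es <- setNames(rs$icc$est, rs$icc$type)
  expect_equal(unname(es["ICC(C,1)"]), 1, tolerance = 1e-9)
  expect_lt(es["ICC(A,1)"], 0.9)
  expect_lt(rs$bias_F$p, 1e-6)
  # incomplete rows are dropped and counted
  base[3, 2] <- NA
  rd <- icc_two_way(base)
  expect_equal(rd$n_dropped, 1)
  expect_equal(rd$n, n - 1)
  expect_error(icc_two_way(matrix(rnorm(4), 2, 2)), ">= 3")
})

test_that("reliability bands use left-closed boundaries", {
  expect_identical(icc_band(c(-0.2, 0.39, 0.40, 0.59, 0.60, 0.74, 0.75, 0.95)),
                   c("poor", "poor", "moderate", "moderate",
                     "good", "good", "excellent", "excellent"))
})
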