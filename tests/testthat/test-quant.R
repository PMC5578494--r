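test_that("standard-curve fitting is exact on exact data", {
  amounts <- 10^(0:5)
  ct <- 40 - 3.3219 * log10(amounts)
  curve <- fit_standard_curve(amounts, ct)
  expect_equal(curve$slope, -3.3219)
  expect_equal(curve$intercept, 40)
  expect_equal(curve$r2, 1)
  expect_equal(curve$efficiency, 10^(1 / 3.3219) - 1, tolerance = 1e-9)
  # rescaling all amounts x1000 shifts the intercept by slope * 3 only
  curve2 <- fit_standard_curve(amounts * 1000, ct)
  expect_equal(curve2$slope, curve$slope)
  expect_equal(curve2$intercept, curve$intercept + 3.3219 * 3)
  expect_error(fit_standard_curve(c(1, 10), c(40, 36)), ">= 3")
  expect_error(fit_standard_curve(c(-1, 1, 10), c(1, 2, 3)), "positive")
})

test_that("noisy plates recover the true slope within its standard error", {
  true_curve <- list(slope = -3.3219, intercept = 40)
  plate <- gen_qpcr(true_curve, true_amounts = 2, replicates = 3,
                    noise_sd = 0.2, seed = 7)
  curve <- fit_standard_curve(plate[plate$role == "standard", ])
  se <- coef(summary(curve$fit))[2, 2]
  expect_lt(abs(curve$slope - true_curve$slope), 3 * se)
})

test_that("absolute quantification inverts the curve exactly", {
  curve <- fit_standard_curve(10^(0:3), 38 - 3.4 * log10(10^(0:3)))
  expect_equal(absolute_quant(curve$intercept, curve), 1)
  # noiseless round trip: true amounts recovered to numerical precision
  plate <- gen_qpcr(curve, true_amounts = c(0.05, 0.7, 12), noise_sd = 0,
                    seed = 1, replicates = 1)
  unk <- plate[plate$role == "unknown", ]
  expect_equal(absolute_quant(unk$ct, curve), unk$true_amount,
               tolerance = 1e-9)
  # the two normalization denominators differ by exactly their ratio
  a_rna <- absolute_quant(30, curve, denominator = 1)     # per ug RNA
  a_mass <- absolute_quant(30, curve, denominator = 2.5)  # per g sample
  expect_equal(a_rna / a_mass, 2.5)
  flat <- curve; flat$slope <- 0
  expect_error(absolute_quant(30, flat), "slope")
})

test_that("delta-delta-Ct identities hold exactly", {
  plate <- data.frame(
    sample = rep(sprintf("s%d", 1:4), 2),
    arm = rep(c("control", "control", "treated", "treated"), 2),
    gene = rep(c("amTOR", "amActin"), each = 4),
    ct = c(24, 24, 24, 24, 18, 18, 18, 18))
  r <- relative_ddct(plate, "amTOR", "amActin")
  expect_equal(r$fold, rep(1, 4))
  # treated dCt exactly one cycle higher halves the fold
  plate2 <- plate
  plate2$ct[plate2$gene == "amTOR" & plate2$arm == "treated"] <- 25
  r2 <- relative_ddct(plate2, "amTOR", "amActin")
  expect_equal(as.numeric(attr(r2, "arm_means")), c(1, 0.5))
  # control-arm mean fold is 1 by construction even with noise
  plate3 <- gen_qpcr_relative(true_fold = 0.4, n_per_arm = 6,
                              noise_sd = 0.3, seed = 3)
  r3 <- relative_ddct(plate3, "amTOR", "amActin")
  ctl <- r3$fold[r3$arm == "control"]
  expect_equal(exp(mean(log(ctl))), 1, tolerance = 1e-12)  # geometric mean
  expect_error(relative_ddct(plate[plate$gene == "amTOR", ],
                             "amTOR", "amActin"), "missing")
})

test_that("simulated knockdown plates recover the configured fold change", {
  folds <- vapply(1:60, function(s) {
    plate <- gen_qpcr_relative(true_fold = 0.4, n_per_arm = 6,
                               noise_sd = 0.15, seed = s)
    r <- relative_ddct(plate, "amTOR", "amActin")
    mean(r$fold[r$arm == "treated"])
  }, numeric(1))
  se <- sd(folds) / sqrt(length(folds))
  expect_lt(abs(mean(folds) - 0.4), 3 * se + 0.01)
})

test_that("group comparison reproduces classical identities", {
  set.seed(2)
  tab <- data.frame(arm = rep(c("control", "treated"), each = 12),
                    weight = rnorm(24, 100, 10))
  gt <- compare_groups(tab, "weight", test = "t")
  ga <- compare_groups(tab, "weight", test = "anova")
  expect_equal(ga$statistic, gt$statistic^2, tolerance = 1e-9)  # F = t^2
  expect_equal(ga$p, gt$p, tolerance = 1e-9)
  # identical arms: zero effect, p = 1
  tab2 <- data.frame(arm = rep(c("control", "treated"), each = 5),
                     weight = rep(c(10, 11, 12, 13, 14), 2))
  g0 <- compare_groups(tab2, "weight")
  expect_equal(g0$effect_abs, 0)
  expect_equal(g0$p, 1, tolerance = 1e-9)
  # three arms dispatch to one-way ANOVA
  tab3 <- data.frame(arm = rep(c("control", "scrambled", "mir162a"),
                               each = 8),
                     weight = rnorm(24, 100, 10))
  g3 <- compare_groups(tab3, "weight")
  expect_equal(g3$test, "anova")
  expect_error(compare_groups(tab3[tab3$arm == "control", ], "weight"),
               "two arms")
  # percent effect is relative to the control mean
  tab4 <- data.frame(arm = rep(c("control", "treated"), each = 3),
                     w = c(99, 100, 101, 79, 80, 81))
  g4 <- compare_groups(tab4, "w")
  expect_equal(g4$effect_pct, -20)
})

test_that("type-I error of the phenotype test sits at the nominal level", {
  set.seed(123)
  ps <- vapply(1:2000, function(i) {
    x <- rnorm(20, 100, 10)
    arm <- rep(c("control", "treated"), each = 10)
    compare_groups(data.frame(arm = arm, w = x), "w")$p
  }, numeric(1))
  rate <- mean(ps < 0.05)
  tol <- 3 * sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(rate - 0.05), tol)
})
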