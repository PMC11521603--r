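test_that("simulation is deterministic under a fixed seed", {
  cfg <- small_panel_config(n_samples = 15, seed = 5, segment = TRUE,
                            multiallelic = TRUE)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$true_cn, b$true_cn)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$expression, b$expression)
  expect_identical(a$wells, b$wells)

  cfg2 <- small_panel_config(n_samples = 15, seed = 6, segment = TRUE,
                             multiallelic = TRUE)
  expect_false(identical(simulate_cohort(cfg2)$true_cn, a$true_cn))

  cfg_noseed <- small_panel_config(n_samples = 15, seed = NULL)
  expect_error(simulate_cohort(cfg_noseed), "seed")
})

test_that("boundary allele frequencies give degenerate copy numbers", {
  set.seed(81)
  cfg0 <- small_panel_config(n_samples = 25, seed = 1, del_freq = 0,
                             dup_freq = 0)
  cn0 <- simulate_true_cn(cfg0)
  expect_true(all(cn0 == 2L))

  cfg1 <- small_panel_config(n_samples = 25, seed = 1, del_freq = 1,
                             dup_freq = 0)
  expect_true(all(simulate_true_cn(cfg1) == 0L))
})

test_that("diploid genotypes follow Hardy-Weinberg proportions", {
  cfg <- small_panel_config(n_samples = 10000, seed = 82, n_single = 1,
                            del_freq = 0.1, dup_freq = 0.1)
  set.seed(82)
  cn <- simulate_true_cn(cfg)[, 1L]
  n <- length(cn)
  # haploid allele: 0 wp 0.1, 1 wp 0.8, 2 wp 0.1; diploid CN = sum
  probs <- c(`0` = 0.01, `1` = 0.16, `2` = 0.66, `3` = 0.16, `4` = 0.01)
  for (k in names(probs)) {
    p <- probs[[k]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(cn == as.integer(k)) - p), 3 * se)
  }
})

test_that("segment members share one identical CN perturbation", {
  cfg <- small_panel_config(n_samples = 200, seed = 83, segment = TRUE,
                            seg_freq = 0.2)
  set.seed(83)
  cn <- simulate_true_cn(cfg)
  expect_identical(cn[, "SEGA"], cn[, "SEGB"])
  expect_identical(cn[, "SEGA"], cn[, "SEGC"])
  expect_gt(stats::var(cn[, "SEGA"]), 0)
})

test_that("read counts are depth- and copy-proportional Poisson draws", {
  cfg <- small_panel_config(n_samples = 10000, seed = 84, n_single = 2,
                            depth_sd = 0, depth_mean = 30)
  # fixed truth: gene 1 at CN 1, gene 2 at CN 2 for every sample
  true_cn <- matrix(rep(c(1L, 2L), each = 10000), ncol = 2,
                    dimnames = list(sprintf("S%05d", 1:10000),
                                    c("GEN01", "GEN02")))
  set.seed(84)
  rcm <- simulate_read_counts(true_cn, cfg)
  mu1 <- 30 * 2000 * 1 / (2 * 150)   # 200
  m1 <- mean(rcm$counts[, "GEN01"])
  m2 <- mean(rcm$counts[, "GEN02"])
  expect_lt(abs(m1 - mu1), 3 * sqrt(mu1 / 10000))
  expect_lt(abs(m2 - 2 * mu1), 3 * sqrt(2 * mu1 / 10000))
  expect_equal(unname(rcm$mean_coverage), rep(30, 10000))

  # CN 0 -> count 0 always
  zero_cn <- true_cn; zero_cn[, 1L] <- 0L
  set.seed(85)
  expect_true(all(simulate_read_counts(zero_cn, cfg)$counts[, "GEN01"]
                  == 0L))
})

test_that("multi-allelic gene spans a wide diploid range", {
  cfg <- small_panel_config(n_samples = 2000, seed = 86,
                            multiallelic = TRUE)
  set.seed(86)
  cn <- simulate_true_cn(cfg)[, "MULTI"]
  expect_gte(max(cn), 12)   # far beyond bi-allelic 0-4
  expect_gte(diff(range(cn)), 8)
  expect_true(all(cn >= 0 & cn <= 30))
})

test_that("expression follows the planted dosage model", {
  genes <- data.frame(assay_group = c("NULLG", "POSG", "NEGG"),
                      expected_cn = 2, del_freq = 0.2, dup_freq = 0.2,
                      region_length = 2000, stringsAsFactors = FALSE)
  dosage <- data.frame(assay_group = genes$assay_group,
                       beta0 = c(50, 20, 100),
                       beta = c(0, 10, -10),
                       sd = c(0, 0, 0), stringsAsFactors = FALSE)
  cfg <- cohort_config(n_samples = 50, genes = genes,
                       multiallelic = NULL, segments = list(),
                       dosage = dosage, seed = 87)
  set.seed(87)
  cn <- simulate_true_cn(cfg)
  expr <- simulate_expression(cn, cfg)
  expect_equal(unname(expr[, "NULLG"]), rep(50, 50))
  expect_equal(stats::cor(cn[, "POSG"], expr[, "POSG"]), 1)
  expect_equal(stats::cor(cn[, "NEGG"], expr[, "NEGG"]), -1)
  expect_true(all(expr >= 0))
})

test_that("planted r-squared shows its derived sampling spread at n = 94", {
  # population r2 = 0.10; oracle-computed coverage: ~70% within +-0.06,
  # >=90% within +-0.10 (sd of sample r2 is about 0.06 at this n)
  set.seed(88)
  sd_noise <- 15
  reps <- 500
  r2 <- replicate(reps, {
    cn <- sample(0:2, 94, TRUE, c(.3, .4, .3)) +
      sample(0:2, 94, TRUE, c(.3, .4, .3))
    beta <- dosage_slope_for_r2(0.10, sd(cn), sd_noise)
    y <- 50 + beta * cn + rnorm(94, 0, sd_noise)
    cor(cn, y)^2
  })
  cov06 <- mean(abs(r2 - 0.10) <= 0.06)
  expect_gt(cov06, 0.60)
  expect_lt(cov06, 0.80)
  expect_gte(mean(abs(r2 - 0.10) <= 0.10), 0.90)
})

test_that("ddPCR wells reflect true copy number through the lambda ratio", {
  cfg <- small_panel_config(n_samples = 60, seed = 89, n_single = 1,
                            del_freq = 0.25, dup_freq = 0.25)
  set.seed(89)
  cn <- simulate_true_cn(cfg)
  wells <- simulate_ddpcr_wells(cn, cfg)
  expect_setequal(unique(wells$role), c("target", "reference"))
  res <- ddpcr_copy_number(wells)
  truth <- cn[res$sample, "GEN01"]
  expect_lt(max(abs(res$cn - truth)), 0.5)
  expect_equal(unname(round(res$cn)[truth == 2]),
               unname(truth[truth == 2]))

  # CN 0 gives zero positives deterministically
  cn0 <- cn; cn0[, 1L] <- 0L
  set.seed(90)
  w0 <- simulate_ddpcr_wells(cn0, cfg)
  expect_true(all(w0$droplets_positive[w0$role == "target"] == 0L))

  # saturation warning when lambda leaves the dynamic range
  cfg_hot <- small_panel_config(n_samples = 5, seed = 91, n_single = 1,
                                lambda_ref = 8)
  set.seed(91)
  cn_hot <- simulate_true_cn(cfg_hot)
  expect_warning(simulate_ddpcr_wells(cn_hot, cfg_hot), "saturation")
})

test_that("default configuration exposes the study-structure panel", {
  cfg <- cohort_config(n_samples = 10, seed = 92)
  expect_equal(cfg$multiallelic$assay_group, "DEFB103")
  expect_equal(sum(abs(cfg$multiallelic$hap_probs)), 1, tolerance = 1e-8)
  expect_setequal(cfg$segments[[1L]]$members,
                  c("DEFB110-1", "DEFB110-2", "DEFB112", "DEFB113"))
  expect_true(all(c("DEFB10", "DEFB127") %in% cfg$dosage$assay_group))
  expect_equal(cfg$dosage$beta[cfg$dosage$assay_group == "DEFB10"], 10)
  expect_equal(cfg$dosage$beta[cfg$dosage$assay_group == "DEFB103"], -5)
  coh <- simulate_cohort(cfg)
  expect_equal(ncol(coh$true_cn), 53)  # 54 regions, two share one group
  expect_true("TP53" %in% colnames(coh$counts$counts))
  expect_false("TP53" %in% colnames(coh$true_cn))
})
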