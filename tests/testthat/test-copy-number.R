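# Catalogue with one single-copy gene and one three-copy group.
cn_catalogue <- function() {
  make_catalogue(c("SINGLE", "TRIPLEa", "TRIPLEb"), "chr1",
                 c(1000L, 3000L, 5000L), c(1999L, 3999L, 5999L),
                 reference_copies = c(1L, 3L, 3L),
                 assay_group = c("SINGLE", "TRIPLE", "TRIPLE"))
}

test_that("estimator reproduces the hand-evaluated reference formula", {
  # ratios per sample: 0.5, 1.0, 1.5 of the reference; mean ratio 1.0
  counts <- matrix(
    c(50L, 100L, 150L,      # SINGLE
      300L, 600L, 900L,     # TRIPLE
      100L, 100L, 100L),    # TP53
    nrow = 3,
    dimnames = list(c("s1", "s2", "s3"), c("SINGLE", "TRIPLE", "TP53")))
  cn <- estimate_copy_number(read_count_matrix(counts), cn_catalogue())

  # sample at the cohort-mean ratio: expected copy number exactly
  expect_equal(cn$estimates["s2", "SINGLE"], 2.0)
  expect_equal(cn$estimates["s2", "TRIPLE"], 6.0)
  # ratio 1.5x the cohort mean, singleton group -> 3.0
  expect_equal(cn$estimates["s3", "SINGLE"], 3.0)
  expect_equal(cn$estimates["s1", "SINGLE"], 1.0)
  expect_equal(unname(cn$expected_cn), c(2, 6))
})

test_that("zero counts, zero references and tiny cohorts are handled", {
  counts <- matrix(c(0L, 100L, 50L, 60L, 100L, 100L), nrow = 2,
                   dimnames = list(c("s1", "s2"),
                                   c("SINGLE", "TRIPLE", "TP53")))
  cn <- estimate_copy_number(read_count_matrix(counts), cn_catalogue())
  expect_equal(cn$estimates["s1", "SINGLE"], 0)

  bad_ref <- counts; bad_ref[1L, "TP53"] <- 0L
  expect_error(estimate_copy_number(read_count_matrix(bad_ref),
                                    cn_catalogue()), "s1")

  one <- counts[1L, , drop = FALSE]
  expect_error(estimate_copy_number(read_count_matrix(one),
                                    cn_catalogue()), ">= 2 samples")

  all_zero <- counts; all_zero[, "SINGLE"] <- 0L
  expect_warning(
    cn0 <- estimate_copy_number(read_count_matrix(all_zero),
                                cn_catalogue()),
    "zero cohort-centre")
  expect_true(all(is.na(cn0$estimates[, "SINGLE"])))
})

test_that("normalization identity: cohort mean equals expected CN exactly", {
  set.seed(101)
  for (rep in 1:5) {
    n <- sample(5:40, 1)
    counts <- matrix(rpois(n * 3, lambda = c(150, 900, 300)) + 1L,
                     nrow = n, byrow = TRUE,
                     dimnames = list(paste0("s", 1:n),
                                     c("SINGLE", "TRIPLE", "TP53")))
    cn <- estimate_copy_number(read_count_matrix(counts), cn_catalogue())
    expect_equal(unname(colMeans(cn$estimates)), c(2, 6),
                 tolerance = 1e-12)
  }
})

test_that("estimates are invariant to rescaling one sample's counts", {
  set.seed(202)
  counts <- matrix(rpois(8 * 3, 500) + 1L, nrow = 8,
                   dimnames = list(paste0("s", 1:8),
                                   c("SINGLE", "TRIPLE", "TP53")))
  cn1 <- estimate_copy_number(read_count_matrix(counts), cn_catalogue())
  scaled <- counts
  scaled[3L, ] <- scaled[3L, ] * 7L
  cn2 <- estimate_copy_number(read_count_matrix(scaled), cn_catalogue())
  expect_equal(cn1$estimates, cn2$estimates, tolerance = 1e-12)
})

test_that("median centring is available and differs under skew", {
  counts <- matrix(c(100L, 100L, 100L, 400L,   # duplication-heavy gene
                     100L, 100L, 100L, 100L),
                   nrow = 4,
                   dimnames = list(paste0("s", 1:4), c("SINGLE", "TP53")))
  ctl <- make_catalogue("SINGLE", "chr1", 1000L, 1999L)
  cn_mean <- estimate_copy_number(read_count_matrix(counts), ctl)
  cn_med <- estimate_copy_number(read_count_matrix(counts), ctl,
                                 centre = "median")
  # median centre anchors the unvaried samples at 2
  expect_equal(unname(cn_med$estimates[1:3, "SINGLE"]), rep(2, 3))
  expect_true(all(cn_mean$estimates[1:3, "SINGLE"] < 2))
})

test_that("threshold calls match a brute-force re-evaluation", {
  rule <- threshold_rule(0.25)
  ctl <- cn_catalogue()
  for (expected in c(2, 6)) {
    grid <- seq(0, 2 * expected, length.out = 10000)
    est <- matrix(grid, ncol = 1,
                  dimnames = list(paste0("s", seq_along(grid)),
                                  if (expected == 2) "SINGLE" else
                                    "TRIPLE"))
    cnm <- structure(list(estimates = est,
                          expected_cn = stats::setNames(expected,
                                                        colnames(est)),
                          centre = "mean", breed = NULL),
                     class = "copy_number_matrix")
    calls <- call_cnv(cnm, rule)
    oracle <- ifelse(grid < expected * 0.75, "deletion",
                     ifelse(grid > expected * 1.25, "duplication",
                            "normal"))
    expect_identical(calls$call, oracle)
  }
})

test_that("worked threshold examples at expected CN 2 and 6", {
  est <- matrix(c(1.2, 1.5, 2.0, 2.6, 4.0, 6.0, 8.1, 7.5),
                ncol = 1, dimnames = list(paste0("s", 1:8), "G"))
  for (expected in c(2, 6)) {
    cnm <- structure(list(estimates = est,
                          expected_cn = c(G = expected),
                          centre = "mean", breed = NULL),
                     class = "copy_number_matrix")
    calls <- call_cnv(cnm)
    got <- stats::setNames(calls$call, calls$sample)
    if (expected == 2) {
      expect_equal(unname(got[c("s1", "s2", "s3", "s4")]),
                   c("deletion", "normal", "normal", "duplication"))
    } else {
      # bands are 4.5 / 7.5: boundary values are normal (strict)
      expect_equal(unname(got[c("s5", "s6", "s7", "s8")]),
                   c("deletion", "normal", "duplication", "normal"))
    }
  }
  expect_error(threshold_rule(0), "fraction")
  expect_error(threshold_rule(1), "fraction")
})

test_that("cohort summary reports per-breed CNV and per-gene ranges", {
  est <- matrix(c(2.0, 2.1, 0.9,    # GEN1: one deletion (sample c)
                  2.0, 1.9, 2.1),   # GEN2: quiet
                nrow = 3,
                dimnames = list(c("a", "b", "c"), c("GEN1", "GEN2")))
  cnm <- structure(list(estimates = est, expected_cn = c(GEN1 = 2,
                                                         GEN2 = 2),
                        centre = "mean", breed = NULL),
                   class = "copy_number_matrix")
  calls <- call_cnv(cnm)
  summ <- summarize_cohort(calls,
                           breed = c(a = "X", b = "X", c = "Y"))
  bs <- summ$breed_summary
  expect_equal(bs$n_groups_no_cnv[bs$breed == "X"], 2L)
  expect_equal(bs$n_groups_cnv[bs$breed == "Y"], 1L)
  gr <- summ$gene_ranges
  expect_equal(gr$n_deletion[gr$assay_group == "GEN1"], 1L)
  expect_equal(gr$min_estimate[gr$assay_group == "GEN1"], 0.9)
  expect_equal(gr$max_estimate[gr$assay_group == "GEN2"], 2.1)

  expect_error(summarize_cohort(calls, breed = c(a = "X")),
               "missing from breed map")
})

test_that("copy-number TSV round-trips estimates and expected CN", {
  est <- matrix(c(1.25, 2.5, 6.0, 5.5), nrow = 2,
                dimnames = list(c("s1", "s2"), c("A", "B")))
  cnm <- structure(list(estimates = est, expected_cn = c(A = 2, B = 6),
                        centre = "mean",
                        breed = c(s1 = "X", s2 = "Y")),
                   class = "copy_number_matrix")
  tsv <- tempfile(fileext = ".tsv")
  write_cn_tsv(cnm, tsv)
  back <- read_cn_tsv(tsv)
  expect_equal(back$estimates, est)
  expect_equal(back$expected_cn, cnm$expected_cn)
  expect_equal(back$breed, cnm$breed)
})
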