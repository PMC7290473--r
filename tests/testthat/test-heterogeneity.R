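# Wald chi-square comparisons between strata and tissues.

test_that("wald_chisq_diff matches the closed forms and is symmetric", {
  eq <- wald_chisq_diff(0.4, 0.1, 0.4, 0.2)
  expect_equal(eq$chi2, 0)
  expect_equal(eq$p, 1)
  w <- wald_chisq_diff(0.5, 0.1, 0.1, 0.1)
  expect_equal(w$chi2, 8)
  expect_equal(w$p, 4.677735e-3, tolerance = 1e-6)
  expect_equal(w, wald_chisq_diff(0.1, 0.1, 0.5, 0.1))
  expect_error(wald_chisq_diff(0.1, 0, 0.2, 0.1), "positive")
})

test_that("the blood-vs-brain worked comparison evaluates as expected", {
  # printed effect pairs for the same probe in two tissues
  w <- wald_chisq_diff(0.723, 0.125, 0.272, 0.043)
  expect_equal(w$chi2, 11.64, tolerance = 1e-3)
  expect_equal(w$p, 6.45e-4, tolerance = 1e-3)
  # not significant once adjusted for a methylome-wide family of shared probes
  expect_gt(w$p, 0.05 / 90000)
})

test_that("the statistic is chi-square(1) under equal group effects", {
  set.seed(17)
  n <- 1000
  b <- runif(n, -0.5, 0.5); s1 <- runif(n, 0.05, 0.3); s2 <- runif(n, 0.05, 0.3)
  chi2 <- wald_chisq_diff(rnorm(n, b, s1), s1, rnorm(n, b, s2), s2)$chi2
  expect_gt(ks.test(chi2, pchisq, df = 1)$p.value, 0.01)
})

mk_results <- function(ids, b, se, sig) {
  data.frame(probe_id = ids, b_smr = b, se_smr = se,
             passes_smr = sig, passes_heidi = sig, stringsAsFactors = FALSE)
}

test_that("group_specific_scan flags by the 0.05/m rule on a hand-set fixture", {
  # four candidates significant in A only; two have clearly different effects
  a <- mk_results(paste0("cg", 1:4), c(1.0, 0.5, 0.8, 0.3),
                  c(0.1, 0.1, 0.15, 0.2), rep(TRUE, 4))
  b <- mk_results(paste0("cg", 1:4), c(0.0, 0.45, 0.1, 0.2),
                  c(0.1, 0.1, 0.15, 0.2), rep(FALSE, 4))
  scan <- group_specific_scan(a, b)
  expect_equal(nrow(scan), 4L)
  expect_equal(scan$m, rep(4L, 4))
  expect_equal(scan$threshold, rep(0.0125, 4))
  expect_equal(sum(scan$group_specific), 2L)
  expect_setequal(scan$probe_id[scan$group_specific], c("cg1", "cg3"))
})

test_that("candidates are probes significant in exactly one group", {
  a <- mk_results(paste0("cg", 1:3), c(1, 1, 1), 0.1, c(TRUE, TRUE, FALSE))
  b <- mk_results(paste0("cg", 1:3), c(1, 0, 0), 0.1, c(TRUE, FALSE, TRUE))
  scan <- group_specific_scan(a, b)
  expect_setequal(scan$probe_id, c("cg2", "cg3"))   # cg1 significant in both
  # a candidate absent from the other group's tested set is skipped
  scan2 <- group_specific_scan(a[1:2, ], b[c(1, 3), ])
  expect_true("cg2" %in% attr(scan2, "skipped"))
  # identical result sets give no candidates
  expect_equal(nrow(group_specific_scan(a, a)), 0L)
})

test_that("cross-tissue concordance counts signs and significant differences", {
  a <- mk_results(paste0("cg", 1:4), c(0.5, -0.3, 0.2, 0.4), 0.1, TRUE)
  expect_equal(cross_tissue_concordance(a, a)$sign_concordance, 1.0)
  expect_equal(cross_tissue_concordance(a, a)$frac_different, 0.0)
  b <- a; b$b_smr[2] <- 0.3                       # one sign flip
  expect_equal(cross_tissue_concordance(a, b)$sign_concordance, 0.75)
  expect_warning(cc <- cross_tissue_concordance(a, mk_results("cgX", 1, 0.1, TRUE)),
                 "no shared")
  expect_equal(cc$n_shared, 0L)
})

test_that("a shared causal architecture keeps tissues concordant", {
  # same causal structure, independent seeds standing in for two tissues
  sizes <- list(c(1500, 1500))
  f1 <- fit_toy(sim_mwas_study(scenario_config("pleiotropy", n_probes = 4,
                                               seed = 61, cohort_sizes = sizes,
                                               beta_zx = 0.7, b_xy = 0.5)))
  f2 <- fit_toy(sim_mwas_study(scenario_config("pleiotropy", n_probes = 4,
                                               seed = 61, n_mqtl = 1500,
                                               cohort_sizes = sizes,
                                               beta_zx = 0.7, b_xy = 0.5)))
  cc <- cross_tissue_concordance(f1, f2)
  expect_equal(cc$sign_concordance, 1.0)
  expect_lt(cc$frac_different, 0.05 + 1e-9)
})

test_that("an effect absent in one group is flagged more often than under no contrast", {
  sizes <- list(c(1500, 1500))
  base <- scenario_config("pleiotropy", n_probes = 3, seed = 71,
                          cohort_sizes = sizes, beta_zx = 0.8, b_xy = 0.6)
  fitA <- fit_toy(sim_mwas_study(base))
  null_cfg <- base; null_cfg$scenario <- "null"
  null_cfg$b_xy <- 0
  fitB <- fit_toy(sim_mwas_study(null_cfg))
  scan <- group_specific_scan(fitA, fitB)
  expect_gt(sum(scan$group_specific), 0L)
  same <- group_specific_scan(fitA, fitA)
  expect_equal(nrow(same), 0L)
})
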