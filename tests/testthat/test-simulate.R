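# The synthetic-data generator: seed determinism, LD structure of the
# latent AR(1) model, and distributional properties of the simulated
# summary statistics.

test_that("generation is reproducible from the seed", {
  cfg <- scenario_config("pleiotropy", n_probes = 2, seed = 42,
                         cohort_sizes = list(c(500, 500)))
  s1 <- sim_mwas_study(cfg)
  s2 <- sim_mwas_study(cfg)
  expect_identical(s1$panel$X, s2$panel$X)
  expect_identical(s1$mqtl, s2$mqtl)
  expect_identical(s1$gwas, s2$gwas)
  s3 <- sim_mwas_study(scenario_config("pleiotropy", n_probes = 2, seed = 43,
                                       cohort_sizes = list(c(500, 500))))
  expect_false(identical(s1$panel$X, s3$panel$X))
})

test_that("adjacent-SNP dosage correlation tracks the AR(1) parameter", {
  adj_cor <- function(rho, seed) {
    cfg <- scenario_config("null", n_ref = 2000, m_snps = 40, ld_rho = rho,
                           seed = seed)
    X <- gen_reference_panel(cfg)$X
    sapply(seq_len(ncol(X) - 1), function(j) cor(X[, j], X[, j + 1]))
  }
  expect_lt(mean(abs(adj_cor(0, 1))), 0.05)
  # thresholding plus MAF heterogeneity attenuates the latent 0.9; the band
  # is frozen from a direct Monte-Carlo oracle of the model (mean ~0.60)
  r9 <- mean(adj_cor(0.9, 2))
  expect_gt(r9, 0.50)
  expect_lt(r9, 0.70)
  expect_gt(r9, mean(adj_cor(0.5, 2)))
})

test_that("panel invariants hold: polymorphic SNPs, increasing positions", {
  cfg <- scenario_config("null", n_ref = 100, m_snps = 30,
                         maf_range = c(0.05, 0.45), seed = 3)
  pan <- gen_reference_panel(cfg)
  expect_true(all(apply(pan$X, 2, var) > 0))
  expect_true(all(diff(pan$snps$pos) > 0))
  expect_false(anyDuplicated(pan$snps$snp) > 0)
  expect_true(all(pan$X %in% 0:2))
})

test_that("config validation rejects bad parameters", {
  expect_error(scenario_config(ld_rho = 1.2), "ld_rho")
  expect_error(scenario_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(scenario_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(scenario_config(cohort_sizes = list(c(1, 5))), "cohort_sizes")
})

test_that("mQTL p-values are uniform when the probe has no genetic effect", {
  cfg <- scenario_config("null", n_mqtl = 1000, m_snps = 200, ld_rho = 0,
                         beta_zx = 0, seed = 5)
  pan <- gen_reference_panel(cfg)
  sim <- gen_mqtl_summary(pan, cfg)
  expect_gt(ks.test(sim$records$p, "punif")$p.value, 0.01)
})

test_that("the causal SNP attains the minimum mQTL p in most replicates", {
  hits <- vapply(1:100, function(s) {
    cfg <- scenario_config("pleiotropy", n_mqtl = 2000, m_snps = 20,
                           ld_rho = 0.8, beta_zx = 0.5, seed = 1000 + s)
    pan <- gen_reference_panel(cfg)
    sim <- gen_mqtl_summary(pan, cfg)
    sim$records$snp[which.min(sim$records$p)] == sim$truth$causal_snp
  }, TRUE)
  expect_gte(mean(hits), 0.90)
})

test_that("GWAS p-values are uniform under the null scenario", {
  cfg <- scenario_config("null", m_snps = 200, ld_rho = 0, seed = 6,
                         cohort_sizes = list(c(1000, 1000)))
  pan <- gen_reference_panel(cfg)
  sim <- gen_mqtl_summary(pan, cfg)
  g <- gen_gwas_cohorts(pan, cfg, sim$truth)[[1]]
  expect_gt(ks.test(g$p, "punif")$p.value, 0.01)
  # rejection fraction at 0.05 within 3 binomial SDs (pooled over this and
  # a second independent draw to reach ~1000 SNPs in total)
  cfg2 <- scenario_config("null", m_snps = 200, ld_rho = 0, seed = 60,
                          cohort_sizes = list(c(1000, 1000)))
  pan2 <- gen_reference_panel(cfg2)
  g2 <- gen_gwas_cohorts(pan2, cfg2, gen_mqtl_summary(pan2, cfg2)$truth)[[1]]
  frac <- mean(c(g$p, g2$p) < 0.05)
  n <- length(c(g$p, g2$p))
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("the causal SNP carries the strongest GWAS signal under pleiotropy", {
  zs <- sapply(1:50, function(s) {
    cfg <- scenario_config("pleiotropy", m_snps = 10, ld_rho = 0.8,
                           beta_zx = 0.5, b_xy = 0.4, seed = 2000 + s,
                           cohort_sizes = list(c(1000, 1000)))
    pan <- gen_reference_panel(cfg)
    sim <- gen_mqtl_summary(pan, cfg)
    g <- gen_gwas_cohorts(pan, cfg, sim$truth)[[1]]
    ic <- match(sim$truth$causal_snp, g$snp)
    idist <- which.max(abs(g$pos - g$pos[ic]))
    c(causal = abs(g$b[ic] / g$se[ic]), distant = abs(g$b[idist] / g$se[idist]))
  })
  expect_gt(median(zs["causal", ]), median(zs["distant", ]))
})

test_that("summary tables keep consistent alleles and plausible frequencies", {
  sim <- sim_mwas_study(scenario_config("pleiotropy", n_probes = 2, seed = 9,
                                        cohort_sizes = list(c(800, 800))))
  g <- sim$gwas[[1]]
  expect_true(all(g$freq > 0.01 & g$freq < 0.99))
  i <- match(g$snp, sim$mqtl$snp)
  expect_identical(g$a1, sim$mqtl$a1[i])
  expect_identical(g$a2, sim$mqtl$a2[i])
  j <- match(g$snp, sim$panel$snps$snp)
  expect_identical(g$a1, sim$panel$snps$a1[j])
})

test_that("the marginal GWAS/mQTL effect ratio at the causal SNP approaches b_xy", {
  # moderate-n version of the convergence property (the acceptance suite
  # runs the full n = 5000 / 200-replicate version)
  ratios <- sapply(1:40, function(s) {
    cfg <- scenario_config("pleiotropy", n_mqtl = 4000, m_snps = 8,
                           ld_rho = 0.6, beta_zx = 0.5, b_xy = 0.4,
                           seed = 3000 + s, cohort_sizes = list(c(2000, 2000)))
    pan <- gen_reference_panel(cfg)
    sim <- gen_mqtl_summary(pan, cfg)
    g <- gen_gwas_cohorts(pan, cfg, sim$truth)[[1]]
    ic <- match(sim$truth$causal_snp, g$snp)
    im <- match(sim$truth$causal_snp, sim$records$snp)
    g$b[ic] / sim$records$b[im]
  })
  expect_lt(abs(mean(ratios) - 0.4), 0.1 * 0.4)
})
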