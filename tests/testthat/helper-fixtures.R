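# Fixture builders shared across test files. Everything is generated in
# code; nothing binary is stored.

# A minimal well-formed GWAS table.
toy_gwas <- function(n = 3L, snp = paste0("rs", seq_len(n)), chr = "1",
                     pos = seq_len(n) * 1000L, a1 = "A", a2 = "G",
                     freq = 0.3, b = 0.1, se = 0.05, nn = 5000) {
  p <- 2 * pnorm(-abs(b / se))
  data.frame(snp = snp, chr = chr, pos = pos, a1 = a1, a2 = a2,
             freq = freq, b = b, se = se, p = p, n = nn,
             stringsAsFactors = FALSE)
}

# mQTL records for one probe (same dialect as the generator).
toy_mqtl_records <- function(probe_id = "cg1", snp = paste0("rs", 1:3),
                             pos = seq_along(snp) * 1000L, b = 0.5,
                             se = 0.05, p = NULL, chr = "1") {
  if (is.null(p)) p <- 2 * pnorm(-abs(b / se))
  data.frame(probe_id = probe_id, snp = snp, chr = chr, pos = pos,
             a1 = "A", a2 = "G", freq = 0.3, b = b, se = se, p = p,
             n = 2000, stringsAsFactors = FALSE)
}

toy_probes <- function(probe_id = "cg1", chr = "1", pos = 2000L, gene = "") {
  data.frame(probe_id = probe_id, chr = chr, pos = pos, gene = gene,
             band = NA_character_, orientation = "+", stringsAsFactors = FALSE)
}

# Merge studies simulated under different scenarios (distinct labels and
# chromosomes keep ids and positions disjoint).
merge_studies <- function(...) {
  sims <- list(...)
  panel <- list(snps = do.call(rbind, lapply(sims, function(s) s$panel$snps)),
                X = do.call(cbind, lapply(sims, function(s) s$panel$X)),
                rho = sims[[1]]$panel$rho)
  class(panel) <- "ld_panel"
  k <- length(sims[[1]]$gwas)
  list(panel = panel,
       probes = do.call(rbind, lapply(sims, `[[`, "probes")),
       mqtl = do.call(rbind, lapply(sims, `[[`, "mqtl")),
       gwas = lapply(seq_len(k), function(j)
         do.call(rbind, lapply(sims, function(s) s$gwas[[j]]))),
       truth = do.call(rbind, lapply(sims, `[[`, "truth")))
}

# The mixed toy study used by the end-to-end checks: two pleiotropy probes
# with strong effects, one linkage probe, two null probes; fixed seed.
toy_mixed_study <- function(seed = 7L) {
  sizes <- list(c(2000L, 2000L), c(2000L, 2000L))
  pl <- sim_mwas_study(scenario_config("pleiotropy", n_probes = 2, seed = seed,
                                       m_snps = 20, n_mqtl = 3000,
                                       cohort_sizes = sizes, ld_rho = 0.85,
                                       beta_zx = 0.8, b_xy = 0.6),
                       chr = "1", label = "P")
  lk <- sim_mwas_study(scenario_config("linkage", n_probes = 1, seed = seed + 1L,
                                       m_snps = 20, n_mqtl = 3000,
                                       cohort_sizes = sizes, ld_rho = 0.85,
                                       beta_zx = 0.8, b_xy = 0.6),
                       chr = "2", label = "L")
  nu <- sim_mwas_study(scenario_config("null", n_probes = 2, seed = seed + 2L,
                                       m_snps = 20, n_mqtl = 3000,
                                       cohort_sizes = sizes, ld_rho = 0.85,
                                       beta_zx = 0.8),
                       chr = "3", label = "N")
  merge_studies(pl, lk, nu)
}

# Direct Monte-Carlo tail of a weighted sum of 1-df chi-squares.
mc_wchisq_tail <- function(q, lambda, n = 2e5) {
  mean(colSums(lambda * matrix(rnorm(length(lambda) * n)^2,
                               length(lambda))) > q)
}

fit_toy <- function(sim, ...) {
  gwas <- meta_analyse(sim$gwas)
  mwas(gwas, list(probes = sim$probes, records = sim$mqtl), sim$panel, ...)
}
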