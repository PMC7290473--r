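# Synthetic-data generator: LD-structured reference panels and matched
# cis-mQTL + multi-cohort case-control GWAS summary statistics under
# scenarios with known truth (null, pleiotropy, linkage, group heterogeneity).
#
# The LD model is a latent-Gaussian AR(1): each haplotype is a first-order
# autoregressive Gaussian vector with adjacent correlation ld_rho, thresholded
# at the quantile matching each SNP's minor-allele frequency, which yields
# Hardy-Weinberg genotype frequencies and a one-parameter LD decay. The
# thresholding attenuates the latent correlation on the dosage scale, so an
# ld_rho of 0.9 produces empirical adjacent-pair dosage correlations of
# roughly 0.8-0.9.

#' Scenario configuration for the synthetic-data generator
#'
#' Bundles every parameter of a simulated summary-data study: the reference
#' panel, the mQTL study, the GWAS cohorts, and the causal scenario that links
#' methylation to disease.
#'
#' @param scenario one of `"null"`, `"pleiotropy"`, `"linkage"`,
#'   `"group_heterogeneity"`. Under `"pleiotropy"` a single causal SNP drives
#'   methylation, and methylation in turn shifts disease risk by `b_xy`; under
#'   `"linkage"` a second SNP in LD with the methylation SNP affects disease
#'   directly; under `"null"` disease is independent of genotype.
#' @param n_ref individuals in the LD reference panel.
#' @param n_mqtl mQTL-study sample size.
#' @param cohort_sizes list of `c(n_cases, n_controls)` pairs, one per GWAS
#'   cohort.
#' @param m_snps number of cis SNPs per probe.
#' @param ld_rho adjacent-SNP latent correlation of the AR(1) LD model, in
#'   `[0, 0.99]`.
#' @param maf_range minor-allele-frequency range; MAFs are drawn uniformly.
#' @param beta_zx causal SNP effect on methylation (methylation units per
#'   effect allele).
#' @param b_xy methylation effect on disease (log-odds per methylation unit).
#' @param group_ratio multiplier applied to `b_xy` in cohorts labelled group
#'   `"B"` under the group-heterogeneity scenario.
#' @param cohort_groups character vector of `"A"`/`"B"` labels, one per
#'   cohort; defaults to all `"A"`.
#' @param n_probes number of probes to simulate.
#' @param seed integer seed; all randomness flows from it through a fixed
#'   stage-offset splitting scheme.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("null", "pleiotropy", "linkage",
                                         "group_heterogeneity"),
                            n_ref = 500L, n_mqtl = 2000L,
                            cohort_sizes = list(c(1000L, 1000L)),
                            m_snps = 20L, ld_rho = 0.8,
                            maf_range = c(0.05, 0.45),
                            beta_zx = 0.5, b_xy = 0.4,
                            group_ratio = 1, cohort_groups = NULL,
                            n_probes = 1L, seed = 1L) {
  scenario <- match.arg(scenario)
  check_number(ld_rho, "ld_rho", 0, 0.99)
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop_cfg("maf_range must be an increasing pair within (0, 0.5]")
  for (nm in c("n_ref", "n_mqtl"))
    check_number(get(nm), nm, lower = 2)
  if (!is.list(cohort_sizes) || !length(cohort_sizes) ||
      !all(vapply(cohort_sizes, function(s) length(s) == 2L && all(s >= 2), TRUE)))
    stop_cfg("cohort_sizes must be a list of (n_cases, n_controls) pairs, all >= 2")
  check_number(m_snps, "m_snps", lower = 2)
  if (is.null(cohort_groups)) cohort_groups <- rep("A", length(cohort_sizes))
  if (length(cohort_groups) != length(cohort_sizes) ||
      !all(cohort_groups %in% c("A", "B")))
    stop_cfg("cohort_groups must be 'A'/'B' labels, one per cohort")
  structure(list(scenario = scenario, n_ref = as.integer(n_ref),
                 n_mqtl = as.integer(n_mqtl), cohort_sizes = cohort_sizes,
                 m_snps = as.integer(m_snps), ld_rho = ld_rho,
                 maf_range = maf_range, beta_zx = beta_zx, b_xy = b_xy,
                 group_ratio = group_ratio, cohort_groups = cohort_groups,
                 n_probes = as.integer(n_probes), seed = as.integer(seed)),
            class = "scenario_config")
}

# Dosage matrix (n x m, values 0/1/2) from the latent AR(1) haplotype model.
sim_dosages <- function(n, maf, rho) {
  m <- length(maf)
  thr <- stats::qnorm(1 - maf)
  one_hap <- function() {
    Z <- matrix(stats::rnorm(n * m), n, m)
    if (rho > 0 && m > 1) {
      s <- sqrt(1 - rho^2)
      for (j in 2:m) Z[, j] <- rho * Z[, j - 1] + s * Z[, j]
    }
    t(t(Z) > thr) * 1
  }
  one_hap() + one_hap()
}

#' Generate an LD reference panel
#'
#' Draws a genotype-dosage matrix from the latent-Gaussian AR(1) LD model at
#' MAFs sampled uniformly from `config$maf_range`. Monomorphic draws are
#' redrawn up to 10 times; any still-monomorphic SNPs are excluded.
#'
#' @param config a [scenario_config()].
#' @param chr chromosome label for the simulated cis region.
#' @param pos_offset base-pair offset of the region (positions are strictly
#'   increasing from `pos_offset + 1000`).
#' @param id_prefix prefix for SNP identifiers.
#' @return an object of class `ld_panel`: a list with `snps` (SNP metadata:
#'   id, chr, pos, a1 effect allele, a2, maf) and `X` (dosage matrix, one
#'   column per SNP, counting copies of a1).
#' @export
gen_reference_panel <- function(config, chr = "1", pos_offset = 0L,
                                id_prefix = "rs") {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(stage_seed(config$seed, "panel"))
  m <- config$m_snps
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  X <- sim_dosages(config$n_ref, maf, config$ld_rho)
  for (i in seq_len(10L)) {
    mono <- apply(X, 2, stats::var) == 0
    if (!any(mono)) break
    X[, mono] <- sim_dosages(config$n_ref, maf[mono], 0)
  }
  keep <- apply(X, 2, stats::var) > 0
  # non-palindromic allele pairs so harmonization never drops simulated SNPs
  pairs <- cbind(c("A", "A", "C", "C", "G", "G", "T", "T"),
                 c("C", "G", "A", "T", "A", "T", "C", "G"))
  pick <- sample(nrow(pairs), m, replace = TRUE)
  snps <- data.frame(snp = paste0(id_prefix, seq_len(m)), chr = chr,
                     pos = pos_offset + 1000L + (seq_len(m) - 1L) * 2000L,
                     a1 = pairs[pick, 1], a2 = pairs[pick, 2],
                     maf = maf, stringsAsFactors = FALSE)
  panel <- list(snps = snps[keep, , drop = FALSE],
                X = X[, keep, drop = FALSE], rho = config$ld_rho)
  colnames(panel$X) <- panel$snps$snp
  class(panel) <- "ld_panel"
  panel
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("LD reference panel: %d individuals x %d SNPs (AR(1) rho = %.2f)\n",
              nrow(x$X), ncol(x$X), x$rho))
  invisible(x)
}

# Vectorized marginal least-squares summary statistics (one SNP at a time
# against a quantitative trait), as an mQTL study reports them.
marginal_lm <- function(X, y) {
  n <- length(y)
  xm <- colMeans(X)
  Sxx <- colSums(X^2) - n * xm^2
  ym <- mean(y)
  Syy <- sum(y^2) - n * ym^2
  Sxy <- colSums(X * y) - n * xm * ym
  beta <- Sxy / Sxx
  rss <- pmax(Syy - beta * Sxy, 0)
  se <- sqrt(rss / ((n - 2) * Sxx))
  # z-based p, the convention of large-sample summary resources (and the
  # only choice consistent with the (b/se)^2 chi-square identity validated
  # on read)
  data.frame(b = beta, se = se, p = z_to_p(beta / se), row.names = NULL)
}

#' Generate cis-mQTL summary statistics for one probe
#'
#' Simulates a methylation trait `y = beta_zx * g_causal + N(0,1)` for
#' `config$n_mqtl` individuals drawn from the same LD model as the panel, and
#' reports the marginal least-squares beta, SE and p for every SNP.
#'
#' @param panel an `ld_panel` from [gen_reference_panel()].
#' @param config the matching [scenario_config()].
#' @param probe_id probe identifier.
#' @param probe_index index used to split the seed so probes are independent.
#' @param causal index (into panel SNPs) of the causal SNP; defaults to the
#'   middle SNP. Ignored when `beta_zx = 0`.
#' @return list with `records` (data.frame in the mQTL summary dialect:
#'   probe_id, snp, chr, pos, a1, a2, freq, b, se, p, n), `probe`
#'   (probe metadata row) and `truth` (the truth record).
#' @export
gen_mqtl_summary <- function(panel, config, probe_id = "cg000001",
                             probe_index = 0L, causal = NULL) {
  stopifnot(inherits(panel, "ld_panel"))
  set.seed(stage_seed(config$seed, "mqtl", probe_index))
  m <- nrow(panel$snps)
  if (is.null(causal)) causal <- (m + 1L) %/% 2L
  X <- sim_dosages(config$n_mqtl, panel$snps$maf, panel$rho)
  y <- config$beta_zx * X[, causal] + stats::rnorm(config$n_mqtl)
  keep <- apply(X, 2, stats::var) > 0
  if (any(!keep))
    message(sprintf("gen_mqtl_summary: dropped %d monomorphic SNP(s) for %s",
                    sum(!keep), probe_id))
  st <- marginal_lm(X[, keep, drop = FALSE], y)
  sn <- panel$snps[keep, , drop = FALSE]
  records <- data.frame(probe_id = probe_id, snp = sn$snp, chr = sn$chr,
                        pos = sn$pos, a1 = sn$a1, a2 = sn$a2,
                        freq = colMeans(X[, keep, drop = FALSE]) / 2,
                        b = st$b, se = st$se, p = st$p, n = config$n_mqtl,
                        stringsAsFactors = FALSE, row.names = NULL)
  probe <- data.frame(probe_id = probe_id, chr = sn$chr[1],
                      pos = as.integer(round(mean(range(sn$pos)))),
                      gene = "", band = NA_character_, orientation = "+",
                      stringsAsFactors = FALSE)
  truth <- data.frame(probe_id = probe_id, scenario = config$scenario,
                      causal_snp = panel$snps$snp[causal],
                      causal_snp2 = NA_character_,
                      beta_zx = config$beta_zx,
                      b_xy_groupA = if (config$scenario %in% c("null", "linkage")) 0 else config$b_xy,
                      b_xy_groupB = if (config$scenario %in% c("null", "linkage")) 0 else
                        config$b_xy * if (config$scenario == "group_heterogeneity") config$group_ratio else 1,
                      stringsAsFactors = FALSE)
  list(records = records, probe = probe, truth = truth)
}

# Single-SNP logistic association via IRLS (glm.fit); returns NULL on
# separation / non-convergence so callers can drop the SNP.
logistic_assoc <- function(g, y) {
  X <- cbind(1, g)
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  if (!fit$converged || any(abs(fit$coefficients) > 15)) return(NULL)
  V <- tryCatch(solve(crossprod(X, fit$weights * X)), error = function(e) NULL)
  if (is.null(V) || V[2, 2] <= 0) return(NULL)
  b <- unname(fit$coefficients[2])
  se <- sqrt(V[2, 2])
  c(b = b, se = se, p = z_to_p(b / se))
}

#' Generate per-cohort case-control GWAS summary statistics
#'
#' For each cohort, case-control status is simulated from a logistic model
#' whose linear predictor depends on the scenario: `b_xy` times the
#' methylation trait (its genetic component plus fresh environmental noise)
#' under pleiotropy and group heterogeneity, a direct effect of a second
#' linked SNP under linkage, and zero under the null. Per-SNP logistic Wald
#' statistics are then computed by iteratively reweighted least squares.
#' SNPs with complete separation in a cohort are dropped from that cohort's
#' table.
#'
#' @param panel an `ld_panel`.
#' @param config the matching [scenario_config()].
#' @param truth truth record from [gen_mqtl_summary()] (identifies the causal
#'   SNP or SNP pair).
#' @param probe_index seed-splitting index.
#' @return list of per-cohort data.frames in the GWAS summary dialect
#'   (snp, chr, pos, a1, a2, freq, b, se, p, n).
#' @export
gen_gwas_cohorts <- function(panel, config, truth, probe_index = 0L) {
  stopifnot(inherits(panel, "ld_panel"))
  set.seed(stage_seed(config$seed, "gwas", probe_index))
  i1 <- match(truth$causal_snp, panel$snps$snp)
  i2 <- if (!is.na(truth$causal_snp2)) match(truth$causal_snp2, panel$snps$snp) else NA
  out <- vector("list", length(config$cohort_sizes))
  for (k in seq_along(config$cohort_sizes)) {
    sz <- config$cohort_sizes[[k]]
    b_xy_k <- if (config$cohort_groups[k] == "B") truth$b_xy_groupB else truth$b_xy_groupA
    n_need <- sum(sz)
    cases <- controls <- NULL
    tries <- 0L
    while ((length(cases) < sz[1] || length(controls) < sz[2]) && tries < 20L) {
      tries <- tries + 1L
      n_pool <- max(4L * n_need, 2000L)
      G <- sim_dosages(n_pool, panel$snps$maf, panel$rho)
      eta <- switch(config$scenario,
        null = rep(0, n_pool),
        pleiotropy = ,
        group_heterogeneity =
          b_xy_k * (truth$beta_zx * G[, i1] + stats::rnorm(n_pool)),
        linkage = config$b_xy * config$beta_zx * G[, i2])
      yy <- stats::rbinom(n_pool, 1L, stats::plogis(eta))
      idx_case <- which(yy == 1L)
      idx_ctrl <- which(yy == 0L)
      if (length(idx_case) >= sz[1] && length(idx_ctrl) >= sz[2]) {
        sel <- c(idx_case[seq_len(sz[1])], idx_ctrl[seq_len(sz[2])])
        cases <- idx_case[seq_len(sz[1])]
        controls <- idx_ctrl[seq_len(sz[2])]
        G <- G[sel, , drop = FALSE]
        y <- c(rep(1L, sz[1]), rep(0L, sz[2]))
      }
    }
    if (length(cases) < sz[1]) stop_cfg("could not fill cohort %d", k)
    st <- lapply(seq_len(ncol(G)), function(j) {
      if (stats::var(G[, j]) == 0) return(NULL)
      logistic_assoc(G[, j], y)
    })
    ok <- !vapply(st, is.null, TRUE)
    if (any(!ok))
      message(sprintf("gen_gwas_cohorts: cohort %d dropped %d SNP(s) (separation/monomorphic)",
                      k, sum(!ok)))
    stm <- do.call(rbind, st[ok])
    sn <- panel$snps[ok, , drop = FALSE]
    out[[k]] <- data.frame(snp = sn$snp, chr = sn$chr, pos = sn$pos,
                           a1 = sn$a1, a2 = sn$a2,
                           freq = colMeans(G[, ok, drop = FALSE]) / 2,
                           b = stm[, "b"], se = stm[, "se"], p = stm[, "p"],
                           n = n_need, stringsAsFactors = FALSE,
                           row.names = NULL)
  }
  names(out) <- paste0("cohort", seq_along(out))
  out
}

#' Simulate a complete summary-data study
#'
#' Convenience wrapper that builds, for `config$n_probes` probes, a combined
#' reference panel, the mQTL summary table, per-cohort GWAS tables and the
#' truth table. Each probe occupies its own well-separated cis region (10 Mb
#' apart on one chromosome), so probes are independent.
#'
#' Under the linkage scenario two causal SNPs are recorded: the methylation
#' SNP and a second SNP `linkage_gap` positions away that affects disease
#' directly.
#'
#' @param config a [scenario_config()].
#' @param linkage_gap index separation between the two causal SNPs under the
#'   linkage scenario (the AR(1) model makes their dosage correlation roughly
#'   `attenuated(ld_rho^gap)`).
#' @param chr chromosome label for the whole study.
#' @param label prefix distinguishing the study's probe and SNP ids, so
#'   studies simulated under different scenarios can be merged.
#' @return list with `panel`, `probes`, `mqtl` (records), `gwas` (list of
#'   per-cohort tables), `truth`.
#' @export
sim_mwas_study <- function(config, linkage_gap = 2L, chr = "1", label = "") {
  stopifnot(inherits(config, "scenario_config"))
  panels <- probes <- mqtls <- truths <- vector("list", config$n_probes)
  gwas <- replicate(length(config$cohort_sizes), list())
  for (i in seq_len(config$n_probes)) {
    cfg_i <- config
    cfg_i$seed <- stage_seed(config$seed, "probe", i)
    # 100 probes per chromosome, regions 4 Mb apart: cis windows stay
    # disjoint and positions stay inside integer range for large studies
    block <- (i - 1L) %/% 100L
    chr_i <- if (block == 0L) chr else paste0(chr, letters[block + 1L])
    pan <- gen_reference_panel(cfg_i, chr = chr_i,
                               pos_offset = ((i - 1L) %% 100L) * 4000000L,
                               id_prefix = sprintf("rs%s%03d_", label, i))
    m <- nrow(pan$snps)
    causal <- max(1L, (m + 1L) %/% 2L - linkage_gap %/% 2L)
    sim <- gen_mqtl_summary(pan, cfg_i, probe_id = sprintf("cg%s%06d", label, i),
                            probe_index = i, causal = causal)
    if (config$scenario == "linkage") {
      c2 <- min(m, causal + linkage_gap)
      sim$truth$causal_snp2 <- pan$snps$snp[c2]
    }
    g <- gen_gwas_cohorts(pan, cfg_i, sim$truth, probe_index = i)
    for (k in seq_along(g)) gwas[[k]] <- c(gwas[[k]], list(g[[k]]))
    panels[[i]] <- pan
    probes[[i]] <- sim$probe
    mqtls[[i]] <- sim$records
    truths[[i]] <- sim$truth
  }
  panel <- list(snps = do.call(rbind, lapply(panels, `[[`, "snps")),
                X = do.call(cbind, lapply(panels, `[[`, "X")),
                rho = config$ld_rho)
  class(panel) <- "ld_panel"
  list(panel = panel,
       probes = do.call(rbind, probes),
       mqtl = do.call(rbind, mqtls),
       gwas = lapply(gwas, function(g) do.call(rbind, g)),
       truth = do.call(rbind, truths))
}
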