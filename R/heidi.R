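# HEIDI: heterogeneity in dependent instruments. If a single causal variant
# drives both methylation and disease, the ratio estimate b_smr is the same
# (up to sampling noise) at every SNP in LD with the top instrument; under
# linkage between distinct causal variants the ratios disagree. HEIDI tests
# the null of a homogeneous ratio across the instrument's LD neighbourhood,
# accounting for the correlation between SNP estimators induced by LD.

#' Upper tail of a weighted sum of 1-df chi-squares
#'
#' Evaluates `P(sum_k lambda_k X_k > q)` for independent 1-df chi-square
#' variables by numerical inversion of the characteristic function (Imhof's
#' integral). Falls back to a Satterthwaite moment-matching approximation if
#' the quadrature fails.
#'
#' @param q observed statistic.
#' @param lambda non-negative weights (eigenvalues).
#' @return tail probability in [0, 1].
#' @export
wchisq_tail <- function(q, lambda) {
  lambda <- lambda[lambda > 1e-10]
  if (!length(lambda) || q <= 0) return(1)
  if (length(lambda) == 1L)
    return(chisq1_tail(q / lambda))
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(lambda %o% u)) - 0.5 * q * u
    lrho <- 0.25 * colSums(log1p((lambda^2) %o% (u^2)))
    sin(theta) / (u * exp(lrho))
  }
  val <- tryCatch(
    stats::integrate(integrand, 0, Inf, subdivisions = 1000L,
                     rel.tol = 1e-9, abs.tol = 1e-12,
                     stop.on.error = FALSE)$value,
    error = function(e) NA_real_)
  if (is.na(val)) {
    scale <- sum(lambda^2) / sum(lambda)
    df <- sum(lambda)^2 / sum(lambda^2)
    return(stats::pchisq(q / scale, df = df, lower.tail = FALSE))
  }
  min(max(0.5 + val / pi, 0), 1)
}

# Allelic (dosage) correlation between the top SNP and the others, and among
# the others, from the reference panel. Dosages must already be aligned to
# the harmonized effect alleles, so the sign of r tracks the effect coding.
panel_ld <- function(panel, snps) {
  i <- match(snps, colnames(panel$X))
  if (anyNA(i)) stop_cfg("panel does not cover SNP(s): %s",
                         paste(snps[is.na(i)], collapse = ", "))
  stats::cor(panel$X[, i, drop = FALSE])
}

#' HEIDI test for one probe
#'
#' Candidate SNPs are the probe's cis SNPs with mQTL `p < p_candidate`, LD
#' r-squared to the top instrument inside `r2_window`, greedily pruned (by
#' descending mQTL |z|) so no retained pair exceeds the upper r-squared
#' bound, and capped at `max_snps` SNPs including the top. For each retained
#' SNP the deviation `d_i = b_smr(i) - b_smr(top)` is computed; the
#' covariance of the `d` vector follows from first-order error propagation
#' with GWAS and mQTL z-statistics of two SNPs correlating as their allelic
#' correlation within each study. The statistic is the sum of squared
#' standardized deviations, and its null distribution is the eigen-weighted
#' sum of 1-df chi-squares evaluated by [wchisq_tail()].
#'
#' @param probe_records the probe's cis-mQTL records (harmonized to the GWAS
#'   allele coding).
#' @param gwas meta-analysed GWAS table.
#' @param panel `ld_panel` whose dosages are aligned to the same coding.
#' @param top the top mQTL record ([pick_top_mqtl()]).
#' @param p_candidate mQTL p-value ceiling for candidate SNPs (default
#'   1.6e-3, i.e. roughly z^2 > 10).
#' @param r2_window admissible r-squared range to the top SNP.
#' @param max_snps maximum SNPs used, including the top (default 20).
#' @param min_snps minimum SNPs (including the top) needed to evaluate the
#'   test; below this `p_heidi` is NA.
#' @return list with p_heidi (NA when not evaluable) and n_heidi (SNPs used,
#'   including the top).
#' @export
heidi_test <- function(probe_records, gwas, panel, top,
                       p_candidate = 1.6e-3, r2_window = c(0.05, 0.9),
                       max_snps = 20L, min_snps = 3L) {
  r <- probe_records[probe_records$snp %in% gwas$snp &
                       probe_records$snp %in% colnames(panel$X), , drop = FALSE]
  r <- r[r$snp != top$snp, , drop = FALSE]
  if (nrow(r)) {
    ld_top <- as.vector(stats::cor(panel$X[, match(top$snp, colnames(panel$X))],
                                   panel$X[, match(r$snp, colnames(panel$X)),
                                           drop = FALSE]))
    ok <- r$p < p_candidate & ld_top^2 >= r2_window[1] & ld_top^2 <= r2_window[2]
    r <- r[ok, , drop = FALSE]
  }
  if (nrow(r) > 1L) {            # prune pairs above the upper r2 bound
    r <- r[order(-abs(r$b / r$se)), , drop = FALSE]
    R <- panel_ld(panel, r$snp)
    keep <- logical(nrow(r))
    for (i in seq_len(nrow(r)))
      keep[i] <- !any(keep & R[i, ]^2 > r2_window[2] & seq_len(nrow(r)) != i)
    r <- r[keep, , drop = FALSE]
  }
  if (nrow(r) > max_snps - 1L) r <- r[seq_len(max_snps - 1L), , drop = FALSE]
  n_heidi <- nrow(r) + 1L
  if (n_heidi < min_snps) return(list(p_heidi = NA_real_, n_heidi = n_heidi))

  snps <- c(top$snp, r$snp)
  gi <- match(snps, gwas$snp)
  bzx <- c(top$b, r$b);  se_zx <- c(top$se, r$se)
  bgw <- gwas$b[gi];     se_gw <- gwas$se[gi]
  bxy <- bgw / bzx
  R <- panel_ld(panel, snps)
  # cov(bxy_i, bxy_j) by first-order propagation; GWAS and mQTL errors are
  # independent across studies but correlate as R within each study
  C <- R * (tcrossprod(se_gw) / tcrossprod(bzx) +
              tcrossprod(bxy) * tcrossprod(se_zx) / tcrossprod(bzx))
  k <- length(snps)
  D <- C[-1, -1, drop = FALSE] - matrix(C[1, -1], k - 1L, k - 1L) -
    t(matrix(C[1, -1], k - 1L, k - 1L)) + C[1, 1]
  d <- bxy[-1] - bxy[1]
  v <- pmax(diag(D), 1e-12)
  z_d <- d / sqrt(v)
  Corr <- D / sqrt(tcrossprod(v))
  lambda <- eigen(Corr, symmetric = TRUE, only.values = TRUE)$values
  list(p_heidi = wchisq_tail(sum(z_d^2), lambda), n_heidi = n_heidi)
}
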