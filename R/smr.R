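# The SMR ratio test and its per-probe plumbing (probe eligibility and
# instrument selection).
#
# The test treats the top cis-mQTL as an instrument: the ratio
# b_smr = b_gwas / b_mqtl estimates the effect of methylation on disease,
# and its chi-square statistic T = z_gwas^2 z_mqtl^2 / (z_gwas^2 + z_mqtl^2)
# is bounded above by the weaker of the two component chi-squares, so the
# SMR p-value can never be smaller than either component p-value.

#' SMR ratio test from two summary effects
#'
#' @param b_gwas,se_gwas disease (log-odds) effect and SE of the instrument
#'   SNP in the GWAS.
#' @param b_mqtl,se_mqtl methylation effect and SE of the same SNP in the
#'   mQTL study (must be nonzero).
#' @return list with b_smr, se_smr, p_smr and the chi-square statistic t_smr.
#'   `se_smr` is the first-order (delta-method) SE, defined so that
#'   `(b_smr/se_smr)^2` reproduces `t_smr` exactly.
#' @examples
#' smr_test(0.1, 0.02, 0.5, 0.05)  # b_smr = 0.2, T = 20
#' @export
smr_test <- function(b_gwas, se_gwas, b_mqtl, se_mqtl) {
  if (se_gwas <= 0 || se_mqtl <= 0) stop_cfg("smr_test: SEs must be positive")
  if (b_mqtl == 0) stop_cfg("smr_test: b_mqtl is zero, ratio undefined")
  z_g2 <- (b_gwas / se_gwas)^2
  z_m2 <- (b_mqtl / se_mqtl)^2
  t_smr <- if (z_g2 == 0) 0 else z_g2 * z_m2 / (z_g2 + z_m2)
  b_smr <- b_gwas / b_mqtl
  # equals |b_smr|/sqrt(T) when b_gwas != 0, and stays finite at b_gwas = 0
  se_smr <- sqrt((se_gwas^2 + b_smr^2 * se_mqtl^2) / b_mqtl^2)
  list(b_smr = b_smr, se_smr = se_smr, p_smr = chisq1_tail(t_smr),
       t_smr = t_smr)
}

#' Select probes eligible for the SMR scan
#'
#' A probe is retained iff it has at least one cis-mQTL with
#' `p < p_mqtl_threshold` whose SNP is also present in the GWAS table.
#'
#' @param probes probe table (`probe_id`, ...).
#' @param records cis-mQTL records (probe_id, snp, p, ...).
#' @param gwas meta-analysed GWAS table.
#' @param p_mqtl_threshold instrument significance threshold (default 5e-8).
#' @return character vector of eligible probe ids.
#' @export
select_eligible_probes <- function(probes, records, gwas,
                                   p_mqtl_threshold = 5e-8) {
  hit <- records$p < p_mqtl_threshold & records$snp %in% gwas$snp
  intersect(probes$probe_id, unique(records$probe_id[hit]))
}

#' Pick a probe's top mQTL instrument
#'
#' Among the probe's cis SNPs present in both tables, returns the record with
#' the smallest mQTL p; ties are broken by larger mQTL |z|, then by smaller
#' position.
#'
#' @param probe_id probe identifier.
#' @param records cis-mQTL records.
#' @param gwas meta-analysed GWAS table.
#' @return the winning mQTL record (one-row data.frame).
#' @export
pick_top_mqtl <- function(probe_id, records, gwas) {
  r <- records[records$probe_id == probe_id & records$snp %in% gwas$snp, ,
               drop = FALSE]
  if (!nrow(r)) stop_cfg("pick_top_mqtl: no SNP of %s shared with GWAS", probe_id)
  r <- r[order(r$p, -abs(r$b / r$se), r$pos), , drop = FALSE]
  r[1, , drop = FALSE]
}
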