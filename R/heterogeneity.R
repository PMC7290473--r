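# Wald chi-square comparisons of SMR effects between strata (males vs
# females, hypertensive vs non-hypertensive) and between tissues.

#' Wald chi-square for the difference of two effects
#'
#' `chi2 = (b1 - b2)^2 / (se1^2 + se2^2)` with a 1-df chi-square p-value;
#' symmetric in its arguments.
#'
#' @param b1,se1 effect and SE in group 1.
#' @param b2,se2 effect and SE in group 2.
#' @return list with chi2 and p.
#' @export
wald_chisq_diff <- function(b1, se1, b2, se2) {
  if (any(se1 <= 0) || any(se2 <= 0))
    stop_cfg("wald_chisq_diff: SEs must be positive")
  chi2 <- (b1 - b2)^2 / (se1^2 + se2^2)
  list(chi2 = chi2, p = chisq1_tail(chi2))
}

results_of <- function(x) if (inherits(x, "mwas")) x$results else x

#' Scan for group-specific probes between two stratified analyses
#'
#' Candidates are probes that pass both the SMR and HEIDI filters in exactly
#' one of the two groups. Each candidate's effect is compared with its
#' (possibly non-significant) estimate in the other group by
#' [wald_chisq_diff()]; the family size `m` is the candidate count and a
#' probe is flagged group-specific when `p < alpha/m`. Candidates absent
#' from the other group's tested set are skipped and reported.
#'
#' @param resultsA,resultsB `mwas` objects or their results tables for the
#'   two groups (same tissue and plan family).
#' @param alpha family-wise error target.
#' @return data.frame of class `group_scan` with one row per compared
#'   candidate: probe_id, detected_in, b/se in both groups, chi2, p, m,
#'   threshold, group_specific; skipped probes in attribute `skipped`.
#' @export
group_specific_scan <- function(resultsA, resultsB, alpha = 0.05) {
  a <- results_of(resultsA); b <- results_of(resultsB)
  sigA <- a$probe_id[a$passes_smr & a$passes_heidi]
  sigB <- b$probe_id[b$passes_smr & b$passes_heidi]
  cand <- union(setdiff(sigA, sigB), setdiff(sigB, sigA))
  m <- length(cand)
  rows <- list(); skipped <- character()
  for (pid in cand) {
    ia <- match(pid, a$probe_id); ib <- match(pid, b$probe_id)
    if (is.na(ia) || is.na(ib)) { skipped <- c(skipped, pid); next }
    w <- wald_chisq_diff(a$b_smr[ia], a$se_smr[ia], b$b_smr[ib], b$se_smr[ib])
    rows[[length(rows) + 1L]] <- data.frame(
      probe_id = pid, detected_in = if (pid %in% sigA) "A" else "B",
      b1 = a$b_smr[ia], se1 = a$se_smr[ia],
      b2 = b$b_smr[ib], se2 = b$se_smr[ib],
      chi2 = w$chi2, p = w$p, m = m, threshold = alpha / max(m, 1L),
      group_specific = w$p < alpha / max(m, 1L), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(probe_id = character(), detected_in = character(),
               b1 = numeric(), se1 = numeric(), b2 = numeric(),
               se2 = numeric(), chi2 = numeric(), p = numeric(),
               m = integer(), threshold = numeric(),
               group_specific = logical(), stringsAsFactors = FALSE)
  if (length(skipped))
    message(sprintf("group_specific_scan: skipped %d candidate(s) absent from the other group: %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  attr(out, "skipped") <- skipped
  class(out) <- c("group_scan", class(out))
  out
}

#' Cross-tissue concordance of SMR effects
#'
#' Over probes present in both analyses, reports the fraction with the same
#' effect direction and the fraction whose effects differ significantly at
#' the family-adjusted level `alpha/m` (by default `m` is the shared-probe
#' count).
#'
#' @param blood,brain `mwas` objects or results tables.
#' @param m family size for the Bonferroni adjustment; defaults to the
#'   number of shared probes.
#' @param alpha family-wise error target.
#' @return list with n_shared, sign_concordance, frac_different, threshold,
#'   and the per-probe comparison table.
#' @export
cross_tissue_concordance <- function(blood, brain, m = NULL, alpha = 0.05) {
  a <- results_of(blood); b <- results_of(brain)
  shared <- intersect(a$probe_id, b$probe_id)
  if (!length(shared)) {
    warning("cross_tissue_concordance: no shared probes", call. = FALSE)
    return(list(n_shared = 0L, sign_concordance = NA_real_,
                frac_different = NA_real_, threshold = NA_real_,
                table = NULL))
  }
  ia <- match(shared, a$probe_id); ib <- match(shared, b$probe_id)
  if (is.null(m)) m <- length(shared)
  w <- wald_chisq_diff(a$b_smr[ia], a$se_smr[ia], b$b_smr[ib], b$se_smr[ib])
  tab <- data.frame(probe_id = shared,
                    b_blood = a$b_smr[ia], se_blood = a$se_smr[ia],
                    b_brain = b$b_smr[ib], se_brain = b$se_smr[ib],
                    chi2 = w$chi2, p = w$p,
                    same_sign = sign(a$b_smr[ia]) == sign(b$b_smr[ib]),
                    different = w$p < alpha / m, stringsAsFactors = FALSE)
  list(n_shared = length(shared),
       sign_concordance = mean(tab$same_sign),
       frac_different = mean(tab$different),
       threshold = alpha / m, table = tab)
}
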