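# Allele harmonization across summary tables and fixed-effects
# inverse-variance meta-analysis of per-cohort GWAS effects.

.palindromic <- function(a1, a2) {
  paste0(a1, a2) %in% c("AT", "TA", "CG", "GC")
}

#' Harmonize one SNP record to a reference allele coding
#'
#' If the other record's alleles are the reference's swapped, its beta is
#' negated and its frequency replaced by 1 - freq; identical codings pass
#' through unchanged. Strand-palindromic SNPs (A/T, C/G) whose frequency
#' falls in the ambiguity window are dropped (returned as NULL), since their
#' strand cannot be resolved from summary data.
#'
#' @param reference,other single-row SNP association records (lists or
#'   one-row data.frames with a1, a2, freq, b fields) for the same snp_id.
#' @param drop_palindromic_window frequency window inside which palindromic
#'   SNPs are considered unresolvable.
#' @return the harmonized `other` record, or NULL for a dropped palindromic
#'   SNP.
#' @export
harmonize_alleles <- function(reference, other,
                              drop_palindromic_window = c(0.4, 0.6)) {
  if (.palindromic(other$a1, other$a2) &&
      other$freq >= drop_palindromic_window[1] &&
      other$freq <= drop_palindromic_window[2])
    return(NULL)
  if (reference$a1 == other$a1 && reference$a2 == other$a2) return(other)
  if (reference$a1 == other$a2 && reference$a2 == other$a1) {
    other$b <- -other$b
    other$freq <- 1 - other$freq
    tmp <- other$a1; other$a1 <- other$a2; other$a2 <- tmp
    return(other)
  }
  stop_cfg("harmonize_alleles: incompatible allele pairs (%s/%s vs %s/%s)",
           reference$a1, reference$a2, other$a1, other$a2)
}

# Vectorized table-level harmonization: align `tab` (by snp) to the allele
# coding of `ref`. Returns tab with flipped rows fixed; palindromic-ambiguous
# and incompatible rows removed (counts reported via attributes).
harmonize_table <- function(ref, tab, drop_palindromic_window = c(0.4, 0.6)) {
  i <- match(tab$snp, ref$snp)
  has <- !is.na(i)
  r1 <- ref$a1[i]; r2 <- ref$a2[i]
  same <- has & tab$a1 == r1 & tab$a2 == r2
  swap <- has & tab$a1 == r2 & tab$a2 == r1
  pal <- .palindromic(tab$a1, tab$a2) &
    tab$freq >= drop_palindromic_window[1] &
    tab$freq <= drop_palindromic_window[2]
  keep <- (!has) | ((same | swap) & !pal)
  n_bad <- sum(has & !(same | swap))
  if (any(swap & keep)) {
    j <- which(swap & keep)
    tab$b[j] <- -tab$b[j]
    tab$freq[j] <- 1 - tab$freq[j]
    a <- tab$a1[j]; tab$a1[j] <- tab$a2[j]; tab$a2[j] <- a
  }
  out <- tab[keep, , drop = FALSE]
  attr(out, "n_palindromic_dropped") <- sum(pal & has)
  attr(out, "n_incompatible_dropped") <- n_bad
  out
}

#' Fixed-effects inverse-variance meta-analysis of one SNP
#'
#' Pools effects with weights `1/se^2`: pooled beta is the weighted mean,
#' pooled SE is `1/sqrt(sum of weights)`, and p is the two-sided normal tail
#' of `beta/se`.
#'
#' @param beta,se numeric vectors of per-cohort effects and standard errors
#'   (all `se > 0`, at least one effect).
#' @return list with beta, se, z, p, k (cohorts used).
#' @export
meta_fixed <- function(beta, se) {
  if (!length(beta)) stop_cfg("meta_fixed: empty input")
  if (length(beta) != length(se) || any(se <= 0) || anyNA(beta) || anyNA(se))
    stop_cfg("meta_fixed: beta/se must be equal-length with all se > 0")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  list(beta = b, se = s, z = b / s, p = z_to_p(b / s), k = length(beta))
}

#' Meta-analyse per-cohort GWAS summary tables
#'
#' Harmonizes every cohort to the first table's allele coding, then pools
#' each SNP over the cohorts that report it.
#'
#' @param cohorts list of GWAS tables (as from [read_gwas_table()] or
#'   [gen_gwas_cohorts()]).
#' @param drop_palindromic_window passed to the harmonization step.
#' @return GWAS-dialect data.frame (snp, chr, pos, a1, a2, freq, b, se, p, n)
#'   with an extra `k` column counting the cohorts pooled per SNP.
#' @export
meta_analyse <- function(cohorts, drop_palindromic_window = c(0.4, 0.6)) {
  stopifnot(is.list(cohorts), length(cohorts) >= 1L)
  ref <- cohorts[[1]]
  tabs <- c(list(harmonize_table(ref, ref, drop_palindromic_window)),
            lapply(cohorts[-1], harmonize_table, ref = ref,
                   drop_palindromic_window = drop_palindromic_window))
  all_rec <- do.call(rbind, tabs)
  split_idx <- split(seq_len(nrow(all_rec)), all_rec$snp)
  rows <- lapply(split_idx, function(ii) {
    m <- meta_fixed(all_rec$b[ii], all_rec$se[ii])
    first <- ii[1]
    data.frame(snp = all_rec$snp[first], chr = all_rec$chr[first],
               pos = all_rec$pos[first], a1 = all_rec$a1[first],
               a2 = all_rec$a2[first],
               freq = stats::weighted.mean(all_rec$freq[ii], all_rec$n[ii]),
               b = m$beta, se = m$se, p = m$p, n = sum(all_rec$n[ii]),
               k = m$k, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chr, out$pos, out$snp), , drop = FALSE]
  rownames(out) <- NULL
  out
}
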