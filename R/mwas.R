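# The central fitting function: a methylome-wide SMR + HEIDI scan.

#' Methylome-wide SMR association scan
#'
#' Fits the summary-data-based Mendelian randomization model probe by probe:
#' harmonizes the mQTL study and the LD reference panel to the GWAS allele
#' coding, selects probes with at least one genome-wide-significant cis-mQTL
#' shared with the GWAS, computes the SMR ratio test at each probe's top
#' instrument, and applies the HEIDI filter to separate single-locus
#' pleiotropy from linkage.
#'
#' A probe `passes_smr` when `p_smr < alpha / denominator`, where the
#' Bonferroni denominator defaults to the realized number of eligible probes
#' and may be overridden (e.g. a fixed study-wide probe count). It
#' `passes_heidi` when `p_heidi >= heidi_retain`; probes with too few HEIDI
#' SNPs have undefined `p_heidi` and count as not passing unless
#' `keep_unevaluable = TRUE`.
#'
#' @param gwas meta-analysed GWAS summary table ([meta_analyse()] or
#'   [read_gwas_table()]).
#' @param mqtl list with `probes` and `records` ([read_mqtl_table()] or the
#'   generator).
#' @param panel `ld_panel` covering the cis SNPs.
#' @param alpha family-wise error target (default 0.05).
#' @param bonferroni_denominator `"auto"` (eligible-probe count) or a fixed
#'   integer.
#' @param p_mqtl_threshold instrument eligibility threshold (default 5e-8).
#' @param heidi_retain retain probes with `p_heidi` at or above this level
#'   (default 0.05).
#' @param keep_unevaluable treat probes whose HEIDI test could not be
#'   evaluated as passing the filter.
#' @param heidi_args list of overrides passed to [heidi_test()]
#'   (`p_candidate`, `r2_window`, `max_snps`, `min_snps`).
#' @param plan free-text label for the analysis plan (kept in the object).
#' @return an object of class `mwas`: list with `results` (one row per
#'   eligible probe), `counts` (records at each filter), `threshold`,
#'   `alpha`, `denominator`, `plan`.
#' @seealso [smr_test()], [heidi_test()], [write_mwas_results()]
#' @export
mwas <- function(gwas, mqtl, panel, alpha = 0.05,
                 bonferroni_denominator = "auto",
                 p_mqtl_threshold = 5e-8, heidi_retain = 0.05,
                 keep_unevaluable = FALSE, heidi_args = list(),
                 plan = "all") {
  stopifnot(is.list(mqtl), !is.null(mqtl$probes), !is.null(mqtl$records),
            inherits(panel, "ld_panel"))
  records <- harmonize_table(gwas, mqtl$records)
  # align panel dosages to the GWAS effect-allele coding so LD r keeps sign
  pi_ <- match(panel$snps$snp, gwas$snp)
  flip <- !is.na(pi_) & panel$snps$a1 == gwas$a2[pi_] & panel$snps$a2 == gwas$a1[pi_]
  if (any(flip)) {
    panel$X[, flip] <- 2 - panel$X[, flip]
    a <- panel$snps$a1[flip]
    panel$snps$a1[flip] <- panel$snps$a2[flip]
    panel$snps$a2[flip] <- a
  }
  eligible <- select_eligible_probes(mqtl$probes, records, gwas,
                                     p_mqtl_threshold)
  counts <- c(probes_in = nrow(mqtl$probes), eligible = length(eligible))
  denom <- if (identical(bonferroni_denominator, "auto"))
    max(length(eligible), 1L) else as.integer(bonferroni_denominator)
  threshold <- alpha / denom
  rows <- vector("list", length(eligible))
  for (i in seq_along(eligible)) {
    pid <- eligible[i]
    pr <- mqtl$probes[mqtl$probes$probe_id == pid, , drop = FALSE]
    rec <- records[records$probe_id == pid, , drop = FALSE]
    top <- pick_top_mqtl(pid, rec, gwas)
    g <- gwas[match(top$snp, gwas$snp), , drop = FALSE]
    s <- smr_test(g$b, g$se, top$b, top$se)
    h <- tryCatch(
      do.call(heidi_test, c(list(probe_records = rec, gwas = gwas,
                                 panel = panel, top = top), heidi_args)),
      error = function(e) list(p_heidi = NA_real_, n_heidi = NA_integer_))
    rows[[i]] <- data.frame(
      probe_id = pid, chr = pr$chr, probe_pos = pr$pos, gene = pr$gene,
      top_snp = top$snp, top_pos = top$pos, top_a1 = top$a1,
      top_freq = top$freq, p_gwas = g$p, p_mqtl = top$p,
      b_smr = s$b_smr, se_smr = s$se_smr, p_smr = s$p_smr,
      p_heidi = h$p_heidi, n_heidi = h$n_heidi,
      passes_smr = s$p_smr < threshold,
      passes_heidi = if (is.na(h$p_heidi)) keep_unevaluable
                     else h$p_heidi >= heidi_retain,
      heidi_evaluable = !is.na(h$p_heidi),
      stringsAsFactors = FALSE)
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    utils::read.table(text = "", col.names = c(
      "probe_id", "chr", "probe_pos", "gene", "top_snp", "top_pos", "top_a1",
      "top_freq", "p_gwas", "p_mqtl", "b_smr", "se_smr", "p_smr", "p_heidi",
      "n_heidi", "passes_smr", "passes_heidi", "heidi_evaluable"))
  if (!nrow(results)) warning("mwas: no eligible probes", call. = FALSE)
  results <- results[order(results$p_smr), , drop = FALSE]
  rownames(results) <- NULL
  counts <- c(counts,
              smr_significant = sum(results$passes_smr),
              heidi_retained = sum(results$passes_smr & results$passes_heidi),
              heidi_not_evaluable = sum(!results$heidi_evaluable))
  structure(list(results = results, counts = counts, threshold = threshold,
                 alpha = alpha, denominator = denom,
                 heidi_retain = heidi_retain, plan = plan),
            class = "mwas")
}

#' @export
print.mwas <- function(x, ...) {
  cat(sprintf("Methylome-wide SMR scan (plan '%s')\n", x$plan))
  cat(sprintf("  eligible probes: %d   SMR threshold: %.3g (= %.2g/%d)\n",
              x$counts[["eligible"]], x$threshold, x$alpha, x$denominator))
  cat(sprintf("  SMR-significant: %d   retained after HEIDI (p >= %.2g): %d\n",
              x$counts[["smr_significant"]], x$heidi_retain,
              x$counts[["heidi_retained"]]))
  invisible(x)
}

#' @export
summary.mwas <- function(object, ...) {
  sig <- object$results[object$results$passes_smr &
                          object$results$passes_heidi, , drop = FALSE]
  structure(list(object = object, significant = sig), class = "summary.mwas")
}

#' @export
print.summary.mwas <- function(x, ...) {
  print(x$object)
  if (nrow(x$significant)) {
    cat("\nSignificant probes (pass SMR and HEIDI):\n")
    print(x$significant[, c("probe_id", "gene", "top_snp", "b_smr", "se_smr",
                            "p_smr", "p_heidi", "n_heidi")],
          row.names = FALSE, digits = 4)
  } else cat("\nNo probe passes both filters.\n")
  invisible(x)
}

#' @export
coef.mwas <- function(object, ...) {
  stats::setNames(object$results$b_smr, object$results$probe_id)
}

#' @export
#' @importFrom graphics abline legend points
plot.mwas <- function(x, ...) {
  r <- x$results
  if (!nrow(r)) { warning("nothing to plot"); return(invisible(x)) }
  col <- ifelse(r$passes_smr & r$passes_heidi, "firebrick",
                ifelse(r$passes_smr, "orange", "grey40"))
  plot(r$b_smr, -log10(r$p_smr), pch = 19, col = col,
       xlab = expression(b[SMR]), ylab = expression(-log[10](P[SMR])), ...)
  abline(h = -log10(x$threshold), lty = 2)
  legend("topleft", bty = "n", pch = 19,
         col = c("firebrick", "orange", "grey40"),
         legend = c("SMR + HEIDI", "SMR only", "not significant"))
  invisible(x)
}

#' Extract the results table of an `mwas` fit
#' @param x an `mwas` object.
#' @param ... unused.
#' @export
as.data.frame.mwas <- function(x, ...) x$results
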