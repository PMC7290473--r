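# Competitive gene-set enrichment of per-gene scores from a methylome-wide
# scan, with Benjamini-Hochberg q-values and the "< 1 expected false
# positive" FDR-level selection rule.

#' Per-gene scores from SMR results
#'
#' Each gene's score is the maximum of `-log10(p_smr)` over its probes, so a
#' gene is represented by its best probe.
#'
#' @param results `mwas` object or results table (probes without a gene
#'   assignment are ignored).
#' @return named numeric vector of gene scores.
#' @export
gene_score <- function(results) {
  r <- results_of(results)
  r <- r[nzchar(r$gene) & !is.na(r$gene), , drop = FALSE]
  s <- tapply(-log10(pmax(r$p_smr, 1e-300)), norm_gene(r$gene), max)
  stats::setNames(as.numeric(s), names(s))
}

#' Competitive z-score for one gene set
#'
#' `z = (mean score in set - mean score overall) / (population SD overall /
#' sqrt(count))` with a one-sided upper-tail normal p-value; `count` is the
#' number of scored genes in the set.
#'
#' @param scores named gene-score vector ([gene_score()]).
#' @param set_genes character vector of the set's gene symbols.
#' @return list with size (genes in set), count, z, p; z is NA (flagged)
#'   when the overall score SD is zero.
#' @export
pathway_z <- function(scores, set_genes) {
  if (length(scores) < 2L) stop_cfg("pathway_z: need >= 2 scored genes")
  in_set <- names(scores) %in% norm_gene(set_genes)
  count <- sum(in_set)
  if (!count) return(list(size = length(set_genes), count = 0L,
                          z = NA_real_, p = NA_real_))
  sd_pop <- sqrt(mean((scores - mean(scores))^2))
  if (sd_pop == 0)   # all genes share one score: no evidence either way
    return(list(size = length(set_genes), count = count, z = 0, p = 0.5,
                degenerate = TRUE))
  z <- (mean(scores[in_set]) - mean(scores)) / (sd_pop / sqrt(count))
  list(size = length(set_genes), count = count, z = z,
       p = stats::pnorm(z, lower.tail = FALSE))
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up q-values (monotone non-decreasing after sorting).
#'
#' @param p vector of p-values in (0, 1].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p) | p <= 0 | p > 1)) stop_cfg("bh_fdr: p must be in (0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Enrich a collection of gene sets
#'
#' @param scores named gene-score vector.
#' @param sets gene-set table from [read_gene_sets()].
#' @return data.frame with pathway, source, size, count, z, p, q — one row
#'   per set with at least one scored gene.
#' @export
enrich_pathways <- function(scores, sets) {
  rows <- lapply(seq_len(nrow(sets)), function(i) {
    r <- pathway_z(scores, sets$genes[[i]])
    data.frame(pathway = sets$name[i], source = sets$source[i],
               size = r$size, count = r$count, z = r$z, p = r$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$p), , drop = FALSE]
  out$q <- if (nrow(out)) bh_fdr(out$p) else numeric()
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select an FDR level with fewer than one expected false positive
#'
#' For each level in `grid`, with `counts(q)` pathways at q-value <= level,
#' the expected number of false positives is `level * counts`. Admissible
#' levels keep that product below 1; the chosen level is the largest
#' admissible one.
#'
#' @param q q-values of the tested pathways (or precomputed `counts`).
#' @param grid candidate FDR levels.
#' @param counts optional precomputed counts per level (overrides `q`).
#' @return list with chosen level (NA when no level is admissible),
#'   admissible levels, and the per-level table.
#' @export
select_fdr_level <- function(q = NULL, grid = c(0.05, 0.1, 0.15, 0.2, 0.25),
                             counts = NULL) {
  if (is.null(counts)) {
    if (is.null(q)) stop_cfg("select_fdr_level: give q or counts")
    counts <- vapply(grid, function(l) sum(q <= l), 0L)
  }
  if (length(counts) != length(grid))
    stop_cfg("select_fdr_level: counts must match grid")
  if (is.unsorted(counts)) stop_cfg("select_fdr_level: counts must be non-decreasing in the level")
  expected_fp <- grid * counts
  admissible <- grid[expected_fp < 1]
  list(chosen = if (length(admissible)) max(admissible) else NA_real_,
       admissible = admissible,
       table = data.frame(level = grid, count = counts,
                          expected_false_positives = expected_fp,
                          admissible = expected_fp < 1))
}
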