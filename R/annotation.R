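# Probe-to-gene assignment, +/- 1 Mb association-catalog classification,
# and overlap of gene lists across analyses.

gene_tss <- function(models) ifelse(models$strand == "+", models$start, models$end)

#' Assign a probe to a gene
#'
#' A probe inside a gene body, or within `tss_margin` bp of a transcription
#' start site, is assigned to that gene (the closest TSS wins when several
#' genes qualify); otherwise it is annotated to the nearest gene, by TSS
#' distance, with class `igr_nearest`.
#'
#' @param probe one-row probe record (chr, pos).
#' @param models gene-model table ([read_gene_models()]).
#' @param tss_margin promoter margin in bp (default 1500).
#' @param metric `"tss"` (distance probe to TSS, the default) or
#'   `"boundary"` (distance to the nearest gene edge) for the nearest-gene
#'   fallback.
#' @return list with gene, class in {gene_body, tss1500, igr_nearest,
#'   unassigned} and the distance used.
#' @export
assign_probe_gene <- function(probe, models, tss_margin = 1500,
                              metric = c("tss", "boundary")) {
  metric <- match.arg(metric)
  g <- models[models$chr == probe$chr, , drop = FALSE]
  if (!nrow(g)) return(list(gene = NA_character_, class = "unassigned",
                            distance = NA_real_))
  tss <- gene_tss(g)
  d_tss <- abs(probe$pos - tss)
  in_body <- probe$pos >= g$start & probe$pos <= g$end
  near_tss <- d_tss <= tss_margin
  hit <- in_body | near_tss
  if (any(hit)) {
    i <- which(hit)[which.min(d_tss[hit])]
    return(list(gene = g$gene[i],
                class = if (in_body[i]) "gene_body" else "tss1500",
                distance = d_tss[i]))
  }
  d <- if (metric == "tss") d_tss else
    pmax(g$start - probe$pos, probe$pos - g$end, 0)
  i <- which.min(d)
  list(gene = g$gene[i], class = "igr_nearest", distance = d[i])
}

#' Classify the locus around a probe against an association catalog
#'
#' Scans catalog entries within `window` bp of the probe: class `"G"` if any
#' entry has `p < 5e-8`, else `"S"` if any has `5e-8 <= p < 5e-6`, else
#' `"N"` (boundaries exactly as printed: p equal to 5e-8 is suggestive, p
#' equal to 5e-6 is neither).
#'
#' @param probe one-row probe record (chr, pos).
#' @param catalog catalog table ([read_catalog()]).
#' @param window half-width in bp (default 1 Mb).
#' @return list with class and the supporting catalog entries.
#' @export
classify_locus <- function(probe, catalog, window = 1e6) {
  k <- catalog[catalog$chr == probe$chr &
                 abs(catalog$pos - probe$pos) <= window, , drop = FALSE]
  cls <- if (any(k$p < 5e-8)) "G"
         else if (any(k$p >= 5e-8 & k$p < 5e-6)) "S"
         else "N"
  list(class = cls,
       support = k[k$p < 5e-6, , drop = FALSE])
}

norm_gene <- function(g) toupper(trimws(g))

#' Overlap of significant genes between two analyses
#'
#' Intersects gene symbols (normalized for case and whitespace) from a
#' methylome-wide scan with an external gene list, keeping the provenance of
#' each hit.
#'
#' @param mwa_results `mwas` object or results table; only probes passing
#'   both filters contribute their genes.
#' @param other_genes character vector (or data.frame with `gene` and
#'   optional `provenance` columns) of comparison genes.
#' @return data.frame with one row per overlapping gene.
#' @export
overlap_genes <- function(mwa_results, other_genes) {
  r <- results_of(mwa_results)
  r <- r[r$passes_smr & r$passes_heidi & nzchar(r$gene), , drop = FALSE]
  if (is.data.frame(other_genes)) {
    og <- norm_gene(other_genes$gene)
    oprov <- if (!is.null(other_genes$provenance)) other_genes$provenance
             else rep(NA_character_, nrow(other_genes))
  } else {
    og <- norm_gene(other_genes)
    oprov <- rep(NA_character_, length(og))
  }
  mg <- norm_gene(r$gene)
  shared <- intersect(unique(mg), unique(og))
  if (!length(shared))
    return(data.frame(gene = character(), mwa_probes = character(),
                      other_provenance = character(), stringsAsFactors = FALSE))
  data.frame(gene = shared,
             mwa_probes = vapply(shared, function(g)
               paste(r$probe_id[mg == g], collapse = ","), ""),
             other_provenance = vapply(shared, function(g)
               paste(unique(stats::na.omit(oprov[og == g])), collapse = ","), ""),
             stringsAsFactors = FALSE, row.names = NULL)
}
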