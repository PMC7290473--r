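# End-to-end orchestration of one analysis plan: meta-analysis -> SMR/HEIDI
# scan -> annotation -> enrichment -> report, from files on disk to a result
# bundle on disk, with per-stage record counts and an input-checksum
# manifest so reruns are verifiably deterministic.

#' Specify an analysis plan
#'
#' @param plan plan label, e.g. one of `"all"`, `"males"`, `"females"`,
#'   `"htn"`, `"no_htn"`.
#' @param cohort_files character vector of per-cohort GWAS summary files.
#' @param mqtl_file flat cis-mQTL summary file.
#' @param panel_file whitespace-delimited panel file: SNP metadata columns
#'   (SNP Chr Pos A1 A2) followed by one dosage column per individual — or
#'   an `ld_panel` object passed directly to [run_plan()].
#' @param tissue mQTL study label, `"blood"` or `"brain"`.
#' @param out_dir output directory for the result bundle.
#' @param alpha,p_mqtl_threshold,heidi_retain,bonferroni_denominator
#'   thresholds forwarded to [mwas()].
#' @param gene_models_file optional BED file for probe-gene annotation.
#' @param catalog_file optional catalog TSV for locus classification.
#' @param gene_sets_file optional GMT file for pathway enrichment.
#' @return a `plan_spec` list.
#' @export
plan_spec <- function(plan, cohort_files, mqtl_file, panel_file,
                      tissue = c("blood", "brain"), out_dir = tempfile("mwas_"),
                      alpha = 0.05, p_mqtl_threshold = 5e-8,
                      heidi_retain = 0.05, bonferroni_denominator = "auto",
                      gene_models_file = NULL, catalog_file = NULL,
                      gene_sets_file = NULL) {
  structure(list(plan = plan, cohort_files = cohort_files,
                 mqtl_file = mqtl_file, panel_file = panel_file,
                 tissue = match.arg(tissue), out_dir = out_dir,
                 alpha = alpha, p_mqtl_threshold = p_mqtl_threshold,
                 heidi_retain = heidi_retain,
                 bonferroni_denominator = bonferroni_denominator,
                 gene_models_file = gene_models_file,
                 catalog_file = catalog_file,
                 gene_sets_file = gene_sets_file),
            class = "plan_spec")
}

#' Read a panel file written by [write_panel()]
#' @param path panel file path.
#' @return an `ld_panel`.
#' @export
read_panel <- function(path) {
  d <- read_table_checked(path, c("SNP", "Chr", "Pos", "A1", "A2"), "panel")
  meta <- data.frame(snp = as.character(d$SNP), chr = as.character(d$Chr),
                     pos = as.integer(d$Pos), a1 = as.character(d$A1),
                     a2 = as.character(d$A2), stringsAsFactors = FALSE)
  if (anyDuplicated(meta$snp)) stop_cfg("read_panel: duplicate SNP ids")
  X <- t(as.matrix(d[, setdiff(names(d), c("SNP", "Chr", "Pos", "A1", "A2")),
                     drop = FALSE]))
  colnames(X) <- meta$snp
  rownames(X) <- NULL
  poly <- apply(X, 2, stats::var) > 0
  structure(list(snps = meta[poly, , drop = FALSE],
                 X = X[, poly, drop = FALSE], rho = NA_real_),
            class = "ld_panel")
}

#' @rdname read_panel
#' @param panel an `ld_panel`.
#' @export
write_panel <- function(panel, path) {
  d <- data.frame(SNP = panel$snps$snp, Chr = panel$snps$chr,
                  Pos = panel$snps$pos, A1 = panel$snps$a1,
                  A2 = panel$snps$a2, t(panel$X))
  names(d)[-(1:5)] <- paste0("id", seq_len(nrow(panel$X)))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the truth table of a simulated study
#' @param truth truth table from [sim_mwas_study()].
#' @param path file path.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run one analysis plan end to end
#'
#' Reads the cohort GWAS tables, meta-analyses them, runs the SMR + HEIDI
#' scan, optionally annotates probes and enriches pathways, and writes the
#' result bundle (results TSV, filter-count log, optional annotation and
#' enrichment TSVs, input-checksum manifest) under `spec$out_dir`.
#'
#' @param spec a [plan_spec()].
#' @param panel optional `ld_panel` object overriding `spec$panel_file`.
#' @return the fitted `mwas` object, invisibly, with the bundle paths in
#'   attribute `"bundle"`.
#' @export
run_plan <- function(spec, panel = NULL) {
  stopifnot(inherits(spec, "plan_spec"))
  missing_files <- spec$cohort_files[!file.exists(spec$cohort_files)]
  if (length(missing_files))
    stop_cfg("run_plan: missing cohort file(s): %s",
             paste(missing_files, collapse = ", "))
  cohorts <- lapply(spec$cohort_files, read_gwas_table)
  gwas <- meta_analyse(cohorts)
  mqtl <- read_mqtl_table(spec$mqtl_file)
  if (is.null(panel)) panel <- read_panel(spec$panel_file)
  fit <- mwas(gwas, mqtl, panel, alpha = spec$alpha,
              bonferroni_denominator = spec$bonferroni_denominator,
              p_mqtl_threshold = spec$p_mqtl_threshold,
              heidi_retain = spec$heidi_retain, plan = spec$plan)
  dir.create(spec$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(results = file.path(spec$out_dir, "results.tsv"),
                log = file.path(spec$out_dir, "counts.log"),
                manifest = file.path(spec$out_dir, "manifest.tsv"))
  write_mwas_results(fit$results, paths$results)
  writeLines(c(sprintf("plan\t%s", spec$plan),
               sprintf("tissue\t%s", spec$tissue),
               sprintf("smr_threshold\t%.6g", fit$threshold),
               sprintf("%s\t%d", names(fit$counts), fit$counts)),
             paths$log)
  if (!is.null(spec$gene_models_file)) {
    models <- read_gene_models(spec$gene_models_file)
    catalog <- if (!is.null(spec$catalog_file)) read_catalog(spec$catalog_file)
    ann <- annotate_results(fit$results, mqtl$probes, models, catalog)
    paths$annotation <- file.path(spec$out_dir, "annotation.tsv")
    utils::write.table(ann, paths$annotation, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    fit$results$gene <- ann$gene[match(fit$results$probe_id, ann$probe_id)]
  }
  if (!is.null(spec$gene_sets_file) && nrow(fit$results) > 1L) {
    sets <- read_gene_sets(spec$gene_sets_file)
    sc <- gene_score(fit$results)
    if (length(sc) >= 2L) {
      enr <- enrich_pathways(sc, sets)
      paths$enrichment <- file.path(spec$out_dir, "enrichment.tsv")
      utils::write.table(enr, paths$enrichment, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  }
  inputs <- c(spec$cohort_files, spec$mqtl_file,
              if (is.character(spec$panel_file)) spec$panel_file,
              spec$gene_models_file, spec$catalog_file, spec$gene_sets_file)
  inputs <- inputs[file.exists(inputs)]
  utils::write.table(data.frame(file = inputs, md5 = tools::md5sum(inputs)),
                     paths$manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  attr(fit, "bundle") <- paths
  invisible(fit)
}

# Annotate every probe in a results table with its gene and catalog classes.
annotate_results <- function(results, probes, models, catalog = NULL) {
  rows <- lapply(seq_len(nrow(results)), function(i) {
    pr <- probes[match(results$probe_id[i], probes$probe_id), , drop = FALSE]
    a <- assign_probe_gene(pr, models)
    cls <- if (!is.null(catalog)) classify_locus(pr, catalog)$class else NA_character_
    data.frame(probe_id = results$probe_id[i], gene = a$gene,
               gene_class = a$class, tss_distance = a$distance,
               catalog_class = cls, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Contrast two completed plans for group-specific effects
#'
#' Delegates to [group_specific_scan()] and writes the comparison TSV with a
#' summary header recording the family size `m` and the adjusted threshold.
#'
#' @param fitA,fitB `mwas` objects (or results tables) for the contrasting
#'   plans; they must come from the same tissue.
#' @param tissueA,tissueB tissue labels (checked for equality).
#' @param out optional output TSV path.
#' @param alpha family-wise error target.
#' @return the `group_scan` table.
#' @export
run_contrast <- function(fitA, fitB, tissueA = "blood", tissueB = "blood",
                         out = NULL, alpha = 0.05) {
  if (!identical(tissueA, tissueB))
    stop_cfg("run_contrast: mismatched tissue labels ('%s' vs '%s')",
             tissueA, tissueB)
  scan <- group_specific_scan(fitA, fitB, alpha = alpha)
  if (!is.null(out)) {
    m <- if (nrow(scan)) scan$m[1] else 0L
    con <- file(out, "w")
    writeLines(sprintf("# m=%d threshold=%.6g", m, alpha / max(m, 1L)), con)
    utils::write.table(scan, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  scan
}
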