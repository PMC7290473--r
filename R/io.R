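# Readers and writers for every tabular dialect the pipeline touches.
# All coordinates inside the pipeline are 1-based inclusive; the BED
# converters are the only place 0-based half-open coordinates appear.
# Malformed rows are rejected and logged, never fatal unless strict = TRUE.

.gwas_cols <- c("SNP", "Chr", "Pos", "A1", "A2", "freq", "b", "se", "p", "n")
.mqtl_cols <- c("ProbeID", "ProbeChr", "ProbeBp", "Gene", "Orientation",
                "SNP", "SnpChr", "SnpBp", "A1", "A2", "Freq", "b", "se", "p", "n")
.results_cols <- c("ProbeID", "Chr", "ProbePos", "Gene", "SNP", "Pos", "A1",
                   "Freq", "P_GWAS", "P_mQTL", "b_SMR", "SE_SMR", "P_SMR",
                   "P_HEIDI", "N_HEIDI", "passes_SMR", "passes_HEIDI")

read_table_checked <- function(path, required, what) {
  if (!file.exists(path)) stop_cfg("%s file not found: %s", what, path)
  d <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                         check.names = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop_cfg("%s file %s is missing column(s): %s", what, path,
             paste(missing, collapse = ", "))
  d
}

reject <- function(keep, why, strict, what) {
  bad <- which(!keep)
  if (length(bad)) {
    msg <- sprintf("%s: rejected %d row(s) [%s] at line(s) %s", what,
                   length(bad), why, paste(utils::head(bad + 1L, 10L), collapse = ","))
    if (strict) stop_cfg("%s", msg) else message(msg)
  }
  keep
}

# Row-level validation shared by the GWAS and mQTL roles of a SNP
# association record.
validate_snp_assoc <- function(d, strict, what) {
  num <- !is.na(d$freq) & !is.na(d$b) & !is.na(d$se) & !is.na(d$p) & !is.na(d$n)
  keep <- reject(num, "non-numeric field", strict, what)
  keep <- keep & reject(!keep | d$a1 != d$a2, "a1 == a2", strict, what)
  ok <- !keep | (d$freq > 0 & d$freq < 1 & d$se > 0 & d$p > 0 & d$p <= 1 & d$n >= 1)
  keep <- keep & reject(ok, "field out of range", strict, what)
  # p should agree with the Wald chi-square (b/se)^2 within a factor of 2
  with_p <- which(keep)
  if (length(with_p)) {
    pw <- chisq1_tail((d$b[with_p] / d$se[with_p])^2)
    bad <- pmax(pw, 1e-300) / pmax(d$p[with_p], 1e-300)
    bad <- bad > 2 | bad < 0.5
    if (any(bad & pw > 1e-290))
      warning(sprintf("%s: %d row(s) have p inconsistent with (b/se)^2 by > factor 2",
                      what, sum(bad & pw > 1e-290)), call. = FALSE)
  }
  keep
}

#' Read / write a GWAS summary-statistics table
#'
#' The `"full"` dialect has columns SNP Chr Pos A1 A2 freq b se p n; the
#' `"ma"` dialect is the conventional 8-column SNP A1 A2 freq b se p n
#' layout (chromosome and position are then NA). Rows violating the record
#' invariants (a1 != a2, freq in (0,1), se > 0, p in (0,1]) are rejected and
#' logged with their line numbers.
#'
#' @param path file path.
#' @param dialect `"full"` or `"ma"`.
#' @param strict escalate rejected rows to errors.
#' @return data.frame with columns snp, chr, pos, a1, a2, freq, b, se, p, n.
#' @export
read_gwas_table <- function(path, dialect = c("full", "ma"), strict = FALSE) {
  dialect <- match.arg(dialect)
  required <- if (dialect == "ma") setdiff(.gwas_cols, c("Chr", "Pos")) else .gwas_cols
  d <- read_table_checked(path, required, "GWAS")
  out <- data.frame(snp = as.character(d$SNP),
                    chr = if (dialect == "ma") NA_character_ else as.character(d$Chr),
                    pos = if (dialect == "ma") NA_integer_ else as.integer(d$Pos),
                    a1 = as.character(d$A1), a2 = as.character(d$A2),
                    freq = suppressWarnings(as.numeric(d$freq)),
                    b = suppressWarnings(as.numeric(d$b)),
                    se = suppressWarnings(as.numeric(d$se)),
                    p = suppressWarnings(as.numeric(d$p)),
                    n = suppressWarnings(as.numeric(d$n)),
                    stringsAsFactors = FALSE)
  out[validate_snp_assoc(out, strict, "read_gwas_table"), , drop = FALSE]
}

#' @rdname read_gwas_table
#' @param x table as returned by [read_gwas_table()].
#' @export
write_gwas_table <- function(x, path, dialect = c("full", "ma")) {
  dialect <- match.arg(dialect)
  d <- data.frame(SNP = x$snp, Chr = x$chr, Pos = x$pos, A1 = x$a1, A2 = x$a2,
                  freq = x$freq, b = x$b, se = x$se, p = x$p, n = x$n)
  if (dialect == "ma") d$Chr <- d$Pos <- NULL
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a flat cis-mQTL summary table
#'
#' One row per probe-SNP pair with columns ProbeID ProbeChr ProbeBp Gene
#' Orientation SNP SnpChr SnpBp A1 A2 Freq b se p n. Records whose SNP lies
#' on a different chromosome than the probe, or outside the cis window, are
#' rejected with reason "non-cis".
#'
#' @param path file path.
#' @param cis_window maximum probe-SNP distance in bp (default 2 Mb).
#' @param strict escalate rejected rows to errors.
#' @return list with `probes` (probe_id, chr, pos, gene, band, orientation)
#'   and `records` (probe_id plus the SNP association fields).
#' @export
read_mqtl_table <- function(path, cis_window = 2e6, strict = FALSE) {
  d <- read_table_checked(path, .mqtl_cols, "mQTL")
  rec <- data.frame(probe_id = as.character(d$ProbeID),
                    snp = as.character(d$SNP),
                    chr = as.character(d$SnpChr), pos = as.integer(d$SnpBp),
                    a1 = as.character(d$A1), a2 = as.character(d$A2),
                    freq = suppressWarnings(as.numeric(d$Freq)),
                    b = suppressWarnings(as.numeric(d$b)),
                    se = suppressWarnings(as.numeric(d$se)),
                    p = suppressWarnings(as.numeric(d$p)),
                    n = suppressWarnings(as.numeric(d$n)),
                    stringsAsFactors = FALSE)
  keep <- validate_snp_assoc(rec, strict, "read_mqtl_table")
  cis <- as.character(d$ProbeChr) == rec$chr &
    abs(as.integer(d$ProbeBp) - rec$pos) <= cis_window
  keep <- keep & reject(!keep | cis, "non-cis", strict, "read_mqtl_table")
  gene <- as.character(d$Gene)
  gene[gene == "."] <- ""
  probes <- unique(data.frame(probe_id = as.character(d$ProbeID),
                              chr = as.character(d$ProbeChr),
                              pos = as.integer(d$ProbeBp),
                              gene = gene,
                              band = NA_character_,
                              orientation = as.character(d$Orientation),
                              stringsAsFactors = FALSE))
  if (anyDuplicated(probes$probe_id))
    stop_cfg("read_mqtl_table: probe(s) with inconsistent metadata: %s",
             paste(unique(probes$probe_id[duplicated(probes$probe_id)]), collapse = ", "))
  list(probes = probes, records = rec[keep, , drop = FALSE])
}

#' @rdname read_mqtl_table
#' @param probes,records the two tables returned by [read_mqtl_table()].
#' @export
write_mqtl_table <- function(probes, records, path) {
  i <- match(records$probe_id, probes$probe_id)
  d <- data.frame(ProbeID = records$probe_id, ProbeChr = probes$chr[i],
                  ProbeBp = probes$pos[i], Gene = probes$gene[i],
                  Orientation = probes$orientation[i],
                  SNP = records$snp, SnpChr = records$chr, SnpBp = records$pos,
                  A1 = records$a1, A2 = records$a2, Freq = records$freq,
                  b = records$b, se = records$se, p = records$p, n = records$n)
  # "." placeholder keeps the column count stable under whitespace splitting
  d$Gene[is.na(d$Gene) | d$Gene == ""] <- "."
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene models in BED format
#'
#' BED is 0-based half-open; on read the coordinates are converted to the
#' pipeline's 1-based inclusive convention (start + 1, end unchanged), and
#' the conversion is inverted on write. Both 5-column (name, strand) and
#' 6-column (name, score, strand) layouts are accepted.
#'
#' @param path file path.
#' @param strict escalate rejected rows to errors.
#' @return data.frame with gene, chr, start, end (1-based inclusive), strand.
#' @export
read_gene_models <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop_cfg("BED file not found: %s", path)
  d <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 5) stop_cfg("BED needs >= 5 columns (chr start end name [score] strand)")
  strand <- if (ncol(d) >= 6) as.character(d[[6]]) else as.character(d[[5]])
  out <- data.frame(gene = as.character(d[[4]]), chr = as.character(d[[1]]),
                    start = as.integer(d[[2]]) + 1L, end = as.integer(d[[3]]),
                    strand = strand, stringsAsFactors = FALSE)
  keep <- reject(out$end >= out$start, "end <= start", strict, "read_gene_models") &
    reject(out$strand %in% c("+", "-"), "bad strand", strict, "read_gene_models")
  out[keep, , drop = FALSE]
}

#' @rdname read_gene_models
#' @param x gene-model table as returned by [read_gene_models()].
#' @export
write_gene_models <- function(x, path) {
  d <- data.frame(x$chr, x$start - 1L, x$end, x$gene, 0L, x$strand)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line is: set name, source/description, then tab-separated gene
#' symbols. Empty sets are kept with a warning.
#'
#' @param path file path.
#' @return data.frame with name, source, and a list-column `genes`.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop_cfg("GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 1L) < 2L
  if (any(short)) stop_cfg("GMT line(s) with < 2 fields: %s",
                           paste(which(short), collapse = ","))
  genes <- lapply(parts, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  if (any(!lengths(genes)))
    warning(sprintf("read_gene_sets: %d empty gene set(s) kept", sum(!lengths(genes))),
            call. = FALSE)
  out <- data.frame(name = vapply(parts, `[[`, "", 1L),
                    source = vapply(parts, `[[`, "", 2L),
                    stringsAsFactors = FALSE)
  out$genes <- genes
  out
}

#' Read an association-catalog extract
#'
#' Tab-separated columns SNP Chr Pos p Source, used for the +/- 1 Mb locus
#' classification around probes.
#'
#' @param path file path.
#' @param strict escalate rejected rows to errors.
#' @return data.frame with snp, chr, pos, p, source.
#' @export
read_catalog <- function(path, strict = FALSE) {
  d <- read_table_checked(path, c("SNP", "Chr", "Pos", "p", "Source"), "catalog")
  out <- data.frame(snp = as.character(d$SNP), chr = as.character(d$Chr),
                    pos = as.integer(d$Pos),
                    p = suppressWarnings(as.numeric(d$p)),
                    source = as.character(d$Source), stringsAsFactors = FALSE)
  keep <- reject(!is.na(out$p) & out$p > 0 & out$p <= 1, "p out of range",
                 strict, "read_catalog")
  out[keep, , drop = FALSE]
}

#' Write / read an SMR results table
#'
#' Columns follow the conventional per-probe result layout: ProbeID, Chr,
#' ProbePos, Gene, SNP (top mQTL), Pos, A1, Freq, P_GWAS, P_mQTL, b_SMR,
#' SE_SMR, P_SMR, P_HEIDI, N_HEIDI, plus the two pass flags.
#'
#' @param x results data.frame from [mwas()] (component `results`).
#' @param path file path.
#' @export
write_mwas_results <- function(x, path) {
  d <- data.frame(ProbeID = x$probe_id, Chr = x$chr, ProbePos = x$probe_pos,
                  Gene = ifelse(is.na(x$gene) | x$gene == "", ".", x$gene),
                  SNP = x$top_snp, Pos = x$top_pos, A1 = x$top_a1,
                  Freq = x$top_freq, P_GWAS = x$p_gwas, P_mQTL = x$p_mqtl,
                  b_SMR = x$b_smr, SE_SMR = x$se_smr, P_SMR = x$p_smr,
                  P_HEIDI = x$p_heidi, N_HEIDI = x$n_heidi,
                  passes_SMR = x$passes_smr, passes_HEIDI = x$passes_heidi)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mwas_results
#' @export
read_mwas_results <- function(path) {
  d <- read_table_checked(path, .results_cols, "results")
  data.frame(probe_id = d$ProbeID, chr = as.character(d$Chr),
             probe_pos = d$ProbePos, gene = ifelse(d$Gene == ".", "", d$Gene),
             top_snp = d$SNP, top_pos = d$Pos, top_a1 = d$A1,
             top_freq = d$Freq, p_gwas = d$P_GWAS, p_mqtl = d$P_mQTL,
             b_smr = d$b_SMR, se_smr = d$SE_SMR, p_smr = d$P_SMR,
             p_heidi = suppressWarnings(as.numeric(d$P_HEIDI)),
             n_heidi = d$N_HEIDI, passes_smr = as.logical(d$passes_SMR),
             passes_heidi = as.logical(d$passes_HEIDI),
             stringsAsFactors = FALSE)
}
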