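# Probe-gene assignment, catalog-based locus classification, overlaps.

models <- data.frame(
  gene = c("GENEA", "GENEB"), chr = "1",
  start = c(10000L, 60000L), end = c(20000L, 70000L),
  strand = c("+", "+"), stringsAsFactors = FALSE)

probe_at <- function(pos, chr = "1") list(chr = chr, pos = pos)

test_that("probes inside a gene body are assigned to it", {
  a <- assign_probe_gene(probe_at(15000), models)
  expect_equal(a$gene, "GENEA")
  expect_equal(a$class, "gene_body")
})

test_that("probes within 1.5 kb of a TSS get the promoter class", {
  a <- assign_probe_gene(probe_at(9000), models)   # 1000 bp upstream of TSS
  expect_equal(a$gene, "GENEA")
  expect_equal(a$class, "tss1500")
  # just beyond the margin falls through to nearest-gene
  b <- assign_probe_gene(probe_at(8400), models)
  expect_equal(b$class, "igr_nearest")
})

test_that("intergenic probes go to the nearest gene by TSS distance", {
  a <- assign_probe_gene(probe_at(30000), models)  # 20 kb vs 30 kb
  expect_equal(a$gene, "GENEA")
  expect_equal(a$class, "igr_nearest")
  b <- assign_probe_gene(probe_at(50000), models)  # 40 kb vs 10 kb
  expect_equal(b$gene, "GENEB")
  # closest TSS wins when a probe hits several genes
  overlapping <- rbind(models,
                       data.frame(gene = "GENEC", chr = "1", start = 14000L,
                                  end = 16000L, strand = "+"))
  c1 <- assign_probe_gene(probe_at(15000), overlapping)
  expect_equal(c1$gene, "GENEC")
  # negative strand: the TSS is the end coordinate
  minus <- data.frame(gene = "GENED", chr = "1", start = 100000L,
                      end = 110000L, strand = "-")
  d <- assign_probe_gene(probe_at(111000), minus)
  expect_equal(d$class, "tss1500")
})

test_that("probes on an unmodelled chromosome stay unassigned", {
  a <- assign_probe_gene(probe_at(100, chr = "9"), models)
  expect_equal(a$class, "unassigned")
  expect_true(is.na(a$gene))
})

test_that("locus classification follows the strict G/S/N boundaries", {
  cat0 <- data.frame(snp = character(), chr = character(), pos = integer(),
                     p = numeric(), source = character())
  expect_equal(classify_locus(probe_at(5e6), cat0)$class, "N")
  cat1 <- data.frame(snp = "rs1", chr = "1", pos = 55e5, p = 1e-9, source = "x")
  expect_equal(classify_locus(probe_at(5e6), cat1)$class, "G")
  cat1$p <- 1e-7
  expect_equal(classify_locus(probe_at(5e6), cat1)$class, "S")
  cat1$p <- 1e-5
  expect_equal(classify_locus(probe_at(5e6), cat1)$class, "N")
  # boundary p-values: exactly 5e-8 is suggestive, exactly 5e-6 is neither
  cat1$p <- 5e-8
  expect_equal(classify_locus(probe_at(5e6), cat1)$class, "S")
  cat1$p <- 5e-6
  expect_equal(classify_locus(probe_at(5e6), cat1)$class, "N")
  # outside the +/- 1 Mb window entries are ignored
  cat1$p <- 1e-9; cat1$pos <- 5e6 + 1.5e6
  expect_equal(classify_locus(probe_at(5e6), cat1)$class, "N")
})

test_that("adding catalog entries never demotes a classification", {
  set.seed(23)
  cat_a <- data.frame(snp = paste0("rs", 1:10), chr = "1",
                      pos = round(runif(10, 4e6, 6e6)),
                      p = 10^runif(10, -9, -4), source = "x")
  rank_of <- c(N = 1, S = 2, G = 3)
  for (i in 1:10) {
    sub <- cat_a[sample(10, sample(0:9, 1)), ]
    cls_sub <- classify_locus(probe_at(5e6), sub)$class
    cls_all <- classify_locus(probe_at(5e6), cat_a)$class
    expect_gte(rank_of[[cls_all]], rank_of[[cls_sub]])
  }
})

test_that("gene-overlap reporting intersects normalized symbols", {
  r <- data.frame(probe_id = paste0("cg", 1:5),
                  gene = c("AIM2", "DGUOK", "ST14", "C16orf80", "OTHERX"),
                  passes_smr = TRUE, passes_heidi = TRUE,
                  stringsAsFactors = FALSE)
  twa <- c("AIM2", "DGUOK", "ST14", "C16orf80", "OTHERY")
  ov <- overlap_genes(r, twa)
  expect_setequal(ov$gene, c("AIM2", "DGUOK", "ST14", "C16ORF80"))
  expect_equal(nrow(ov), 4L)
  # disjoint lists give an empty table
  expect_equal(nrow(overlap_genes(r, c("NOPE"))), 0L)
  # case and whitespace differences are normalized away
  ov2 <- overlap_genes(r, c(" aim2 "))
  expect_equal(ov2$gene, "AIM2")
  # only probes passing both filters contribute
  r$passes_heidi <- FALSE
  expect_equal(nrow(overlap_genes(r, twa)), 0L)
})
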