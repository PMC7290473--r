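# Gene scoring, the competitive z, BH q-values, FDR-level selection.

test_that("gene scores take the best probe per gene", {
  r <- data.frame(probe_id = paste0("cg", 1:3),
                  gene = c("G1", "G1", "G2"),
                  p_smr = c(1e-4, 1e-2, 0.5), stringsAsFactors = FALSE)
  s <- gene_score(r)
  expect_equal(unname(s["G1"]), 4)
  expect_equal(unname(s["G2"]), -log10(0.5), tolerance = 1e-9)
  # invariant under probe order
  expect_equal(gene_score(r[3:1, ]), s)
})

test_that("pathway_z matches the hand-worked example", {
  scores <- c(A = 1, B = 2, C = 3, D = 4)
  r <- pathway_z(scores, c("C", "D"))
  expect_equal(r$z, 1.264911, tolerance = 1e-5)
  expect_equal(r$p, 0.1029516, tolerance = 1e-5)
  expect_equal(r$count, 2L)
  # the whole population as a set is its own mean
  expect_equal(pathway_z(scores, names(scores))$z, 0)
  # all-equal scores carry no information
  flat <- pathway_z(c(A = 1, B = 1, C = 1), c("A"))
  expect_equal(flat$z, 0)
  expect_equal(flat$p, 0.5)
})

test_that("z-scores are invariant to a constant shift of all scores", {
  set.seed(19)
  scores <- setNames(rnorm(50), paste0("G", 1:50))
  set_genes <- paste0("G", 1:10)
  z1 <- pathway_z(scores, set_genes)$z
  z2 <- pathway_z(scores + 3.7, set_genes)$z
  expect_equal(z1, z2, tolerance = 1e-9)
})

test_that("bh_fdr equals the brute-force step-up definition", {
  brute_bh <- function(p) {
    n <- length(p); o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  set.seed(29)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), brute_bh(p), tolerance = 1e-12)
  }
  # permutation equivariance
  p <- runif(10); o <- sample(10)
  expect_equal(bh_fdr(p)[o], bh_fdr(p[o]))
  expect_error(bh_fdr(c(0.5, 0)), "p must be")
})

test_that("FDR-level selection keeps expected false positives below one", {
  sel <- select_fdr_level(grid = c(0.05, 0.10, 0.15, 0.20, 0.25),
                          counts = c(3, 7, 9, 12, 20))
  expect_equal(sel$admissible, c(0.05, 0.10))
  expect_equal(sel$chosen, 0.10)
  # zero discoveries at every level: everything admissible
  sel0 <- select_fdr_level(grid = c(0.05, 0.10, 0.15, 0.20, 0.25),
                           counts = rep(0, 5))
  expect_equal(sel0$chosen, 0.25)
  # a 7-pathway result set is admissible at the 0.1 level (0.1 * 7 < 1)
  sel7 <- select_fdr_level(q = rep(0.05, 7), grid = c(0.05, 0.1))
  expect_true(0.1 %in% sel7$admissible)
  expect_lt(0.1 * 7, 1)
  expect_error(select_fdr_level(counts = c(5, 3), grid = c(0.05, 0.1)),
               "non-decreasing")
})

test_that("an inflated pathway rises to the top of the ranking", {
  top_hit <- vapply(1:100, function(s) {
    set.seed(400 + s)
    scores <- setNames(abs(rnorm(200, 1, 0.8)), paste0("G", 1:200))
    sets <- data.frame(name = paste0("S", 1:10), source = "sim",
                       stringsAsFactors = FALSE)
    sets$genes <- lapply(1:10, function(i) paste0("G", ((i - 1) * 20 + 1):(i * 20)))
    scores[sets$genes[[4]]] <- scores[sets$genes[[4]]] + 1.5
    enr <- enrich_pathways(scores, sets)
    enr$pathway[which.max(enr$z)] == "S4"
  }, TRUE)
  expect_gte(mean(top_hit), 0.90)
})

test_that("enrich_pathways returns the full column contract with q >= p", {
  set.seed(31)
  scores <- setNames(abs(rnorm(100)), paste0("G", 1:100))
  sets <- data.frame(name = c("S1", "S2"), source = "db",
                     stringsAsFactors = FALSE)
  sets$genes <- list(paste0("G", 1:15), paste0("G", 50:70))
  enr <- enrich_pathways(scores, sets)
  expect_named(enr, c("pathway", "source", "size", "count", "z", "p", "q"))
  expect_true(all(enr$q >= enr$p - 1e-12))
  expect_true(all(enr$count <= enr$size))
})
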