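test_that("exact two-sided Fisher matches closed forms and fisher.test", {
  r1 <- fisher_exact_2x2(matrix(c(1, 9, 11, 3), 2, byrow = TRUE))
  expect_equal(r1$p_value,
               stats::fisher.test(matrix(c(1, 9, 11, 3), 2,
                                         byrow = TRUE))$p.value,
               tolerance = 1e-10)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  # both extreme tables: closed form 2 / C(20, 10)
  r3 <- fisher_exact_2x2(matrix(c(0, 10, 10, 0), 2, byrow = TRUE))
  expect_equal(r3$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  # zero margin
  expect_identical(fisher_exact_2x2(c(0, 0, 5, 7))$p_value, 1)
  # cross-product odds ratio
  expect_equal(fisher_exact_2x2(c(4, 2, 1, 8))$odds_ratio, 16)
  expect_error(fisher_exact_2x2(c(1, -1, 2, 2)), "non-negative")

  set.seed(16)
  for (i in 1:50) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-8)
  }
})

test_that("TE flank overlap uses half-open 4-kb windows", {
  genes <- data.frame(gene_id = "g1", scaffold = "s1", start = 10000L,
                      end = 12000L, strand = "+", stringsAsFactors = FALSE)
  tes <- data.frame(scaffold = "s1",
                    start = c(10500L, 5500L, 5000L, 13000L, 13500L),
                    end = c(10900L, 6000L, 6000L, 13400L, 13900L),
                    family = c("LTR/Gypsy", "LTR/Gypsy", "DNA/MuDR",
                               "LTR/Gypsy", "LTR/Gypsy"),
                    stringsAsFactors = FALSE)
  # window = [6000, 16000): the TE ending exactly at 6000 does not count
  pres <- te_flank_presence(genes, tes, flank = 4000L)
  expect_identical(pres$per_gene$n_te, 3L)
  expect_true(pres$per_gene$presence)
  fam <- pres$per_family
  expect_identical(fam$count[fam$family == "LTR/Gypsy"], 3L)
  expect_false("DNA/MuDR" %in% fam$family)
  # excluding the body drops the TE fully inside it
  pres2 <- te_flank_presence(genes, tes, flank = 4000L,
                             include_body = FALSE)
  expect_identical(pres2$per_gene$n_te, 2L)
})

test_that("family-enriched TEs near MEGs are detected against background", {
  # sparse gene spacing so MEG 4-kb flank zones cover a minority of the
  # genome, leaving room for genuine enrichment contrast
  cfg <- sim_config(seed = 111, n_scaffolds = 2, scaffold_len = 500000,
                    n_genes = 100, gene_len = 600, snp_rate = 2e-4,
                    frac_meg = 0.2, frac_peg = 0, frac_accession_biased = 0,
                    te_families = data.frame(
                      family = c("LTR/Gypsy", "DNA/MuDR"),
                      n = c(120L, 80L), meg_multiplier = c(6, 1)))
  truth <- gen_parental_genomes(cfg)
  meg <- truth$genes$gene_id[truth$genes$class == "MEG"]
  bg <- truth$genes$gene_id[truth$genes$class != "MEG"]
  enr <- te_enrichment(meg, bg, truth$genes, truth$tes)
  gy <- enr[enr$contrast == "LTR/Gypsy", ]
  expect_lt(gy$p_value, 0.01)
  expect_gt(gy$odds_ratio, 1)
  # the flat family should not be strongly enriched
  mu <- enr[enr$contrast == "DNA/MuDR", ]
  expect_gt(mu$p_value, 0.01)
  # empty imprinted set: empty result, no error
  expect_identical(nrow(te_enrichment(character(0), bg, truth$genes,
                                      truth$tes)), 0L)
})

test_that("adjacent imprinted genes give a significant cluster test", {
  genes <- data.frame(gene_id = sprintf("g%04d", 1:1000), scaffold = "s1",
                      start = seq(0L, by = 5000L, length.out = 1000),
                      end = seq(2000L, by = 5000L, length.out = 1000),
                      strand = "+", stringsAsFactors = FALSE)
  res <- cluster_test(c("g0101", "g0102", "g0103"), genes, n_perm = 1000,
                      seed = 42)
  expect_lte(res$p_value, 0.01)
  expect_identical(res$mini_clusters$n_genes, 3L)
  # reproducible under the seed; add-one smoothing keeps P positive
  res2 <- cluster_test(c("g0101", "g0102", "g0103"), genes, n_perm = 1000,
                       seed = 42)
  expect_identical(res$p_value, res2$p_value)
  expect_gt(res$p_value, 0)
  expect_error(cluster_test(c("g0101", "g0102"), genes, n_perm = 0), "n_perm")
  expect_error(cluster_test("g0101", genes, n_perm = 10),
               "fewer than two")
})

test_that("cluster-test P is roughly uniform for random imprinted sets", {
  genes <- data.frame(gene_id = sprintf("g%03d", 1:300), scaffold = "s1",
                      start = seq(0L, by = 4000L, length.out = 300),
                      end = seq(1500L, by = 4000L, length.out = 300),
                      strand = "+", stringsAsFactors = FALSE)
  set.seed(17)
  ps <- vapply(1:40, function(i) {
    ids <- sample(genes$gene_id, 12)
    cluster_test(ids, genes, n_perm = 199, seed = i)$p_value
  }, numeric(1))
  # permutation P-values are discrete, so ties are expected
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})
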