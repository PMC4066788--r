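test_that("exact binomial tails match closed forms and the pbinom oracle", {
  expect_equal(binom_onesided(20, 20, 2 / 3, "greater"), (2 / 3)^20,
               tolerance = 1e-12)
  expect_equal(binom_onesided(0, 10, 2 / 3, "greater"), 1.0)
  expect_equal(binom_onesided(10, 10, 1 / 3, "greater"), (1 / 3)^10,
               tolerance = 1e-12)
  expect_equal(binom_onesided(0, 12, 0.25, "less"), 0.75^12,
               tolerance = 1e-12)
  # spot-check the vectorised path against stats::pbinom
  set.seed(2)
  n <- sample(1:200, 50, replace = TRUE)
  k <- vapply(n, function(x) sample(0:x, 1), integer(1))
  expect_equal(binom_onesided(k, n, 2 / 3, "greater"),
               stats::pbinom(k - 1, n, 2 / 3, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(binom_onesided(k, n, 0.4, "less"),
               stats::pbinom(k, n, 0.4), tolerance = 1e-12)
  expect_error(binom_onesided(1, 0, 0.5), "n must be")
  expect_error(binom_onesided(5, 4, 0.5), "k must")
  expect_error(binom_onesided(1, 2, 1.2), "p0")
})

test_that("joint reciprocal P is the squared maximum and stays uniform", {
  expect_equal(joint_p(0.02, 0.01), 4e-4)
  expect_equal(joint_p(1, 0.37), 1)
  expect_equal(joint_p(0, 0), 0)
  expect_error(joint_p(-0.1, 0.5), "\\[0, 1\\]")
  # distribution of the second-order statistic: max(U1,U2)^2 ~ Uniform
  set.seed(3)
  u <- joint_p(stats::runif(20000), stats::runif(20000))
  ks <- stats::ks.test(u, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("rank FDR follows P*n/i, with BH as the monotone variant", {
  expect_equal(fdr_rank(c(1e-4, 0.01, 0.2)), c(3e-4, 0.015, 0.2))
  q <- 0.02
  expect_equal(sort(fdr_rank(rep(q, 3))), c(q, 1.5 * q, 3 * q))
  # unsorted input maps back to input order
  p <- c(0.2, 1e-4, 0.01)
  expect_equal(fdr_rank(p), c(0.2, 3e-4, 0.015))
  # monotone pass reproduces Benjamini-Hochberg (p.adjust caps at 1)
  set.seed(4)
  pp <- stats::runif(200)^2
  expect_equal(pmin(fdr_rank(pp, monotone = TRUE), 1),
               stats::p.adjust(pp, method = "BH"))
  expect_identical(fdr_rank(numeric(0)), numeric(0))
})

test_that("locus classification honours FDR and the 90% filter jointly", {
  counts <- make_counts(mat_AxB = c(95L, 67L, 95L, 5L),
                        n_AxB = 100L,
                        mat_BxA = c(92L, 66L, 85L, 8L),
                        n_BxA = 100L)
  res <- classify_loci(counts)
  expect_identical(res$class, c("MEG", "biallelic", "biallelic", "PEG"))
  expect_identical(res$completeness[1], "partial")
  expect_true(all(res$joint_P_maternal ==
                    pmax(res$p1_mat, res$p2_mat)^2))
  expect_true(all(res$fdr_mat >= res$joint_P_maternal - 1e-15))
  # one-sided Ps are extreme for the genuine MEG
  expect_lt(res$p1_mat[1], 1e-8)
  expect_lt(res$p2_mat[1], 1e-8)

  # zero-read loci are excluded with a message
  z <- make_counts(c(95L, 0L), c(100L, 0L), c(95L, 0L), c(100L, 0L))
  expect_message(rz <- classify_loci(z), "zero reads")
  expect_identical(nrow(rz), 1L)

  # complete imprinting annotated when the minor parent has zero reads
  comp <- make_counts(100L, 100L, 100L, 100L)
  expect_identical(classify_loci(comp)$completeness, "complete")
})

test_that("relabelling the parents swaps MEG and PEG calls exactly", {
  set.seed(5)
  counts <- make_counts(
    mat_AxB = stats::rbinom(60, 50, c(rep(0.95, 10), rep(2 / 3, 40),
                                      rep(0.05, 10))),
    n_AxB = 50L,
    mat_BxA = stats::rbinom(60, 50, c(rep(0.95, 10), rep(2 / 3, 40),
                                      rep(0.05, 10))),
    n_BxA = 50L)
  res <- classify_loci(counts)
  swapped <- counts
  swapped$mat_AxB <- counts$n_AxB - counts$mat_AxB
  swapped$pat_AxB <- counts$mat_AxB
  swapped$mat_BxA <- counts$n_BxA - counts$mat_BxA
  swapped$pat_BxA <- counts$mat_BxA
  res_sw <- classify_loci(swapped)
  map <- c(MEG = "PEG", PEG = "MEG", biallelic = "biallelic")
  expect_identical(unname(map[res$class]), res_sw$class)
})

test_that("accession bias is line-consistent, not parent-of-origin", {
  counts <- make_counts(mat_AxB = c(95L, 95L, 91L),
                        n_AxB = 100L,
                        mat_BxA = c(7L, 95L, 11L),
                        n_BxA = 100L)
  # locus 1: line-1 fractions 0.95 / 0.93 -> accession biased toward p1
  # locus 2: maternal in both crosses -> imprinted pattern, not line bias
  # locus 3: 0.91 / 0.89 -> one cross below the threshold
  acc <- detect_accession_bias(counts)
  expect_identical(acc$acc_class, c("accession_biased_p1", "none", "none"))
})

test_that("type-I control: null dosage tables produce almost no calls", {
  set.seed(6)
  n <- 3000L
  counts <- make_counts(mat_AxB = stats::rbinom(n, 30, 2 / 3), n_AxB = 30L,
                        mat_BxA = stats::rbinom(n, 30, 2 / 3), n_BxA = 30L)
  res <- classify_loci(counts)
  expect_lt(mean(res$class != "biallelic"), 0.001)
})

test_that("gene aggregation: unanimity, discordance, intergenic distance", {
  genes <- data.frame(gene_id = c("g1", "g2"), scaffold = "s1",
                      start = c(1000L, 5000L), end = c(2000L, 6000L),
                      strand = c("+", "+"), stringsAsFactors = FALSE)
  loci <- make_counts(mat_AxB = c(95L, 96L, 97L, 95L, 5L, 96L),
                      n_AxB = 100L,
                      mat_BxA = c(95L, 96L, 97L, 95L, 5L, 96L),
                      n_BxA = 100L)
  loci <- classify_loci(loci)
  loci$pos <- c(1100L, 1500L, 1900L, 5100L, 5900L, 6300L)
  loci$scaffold <- "s1"
  agg <- aggregate_to_genes(loci, genes)
  g1 <- agg$genes[agg$genes$gene_id == "g1", ]
  expect_identical(g1$class, "MEG")
  expect_identical(g1$supporting_loci, 3L)
  # g2 holds one MEG and one PEG locus -> discordant
  expect_identical(agg$genes$class[agg$genes$gene_id == "g2"], "discordant")
  # the locus 300 bp after g2's end is intergenic MEG-like
  expect_identical(nrow(agg$intergenic), 1L)
  expect_identical(agg$intergenic$class, "intergenic_MEG_like")
  expect_identical(agg$intergenic$nearest_gene, "g2")
  expect_identical(agg$intergenic$distance, 300L)
  expect_identical(agg$intergenic$side, "downstream")
})
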