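test_that("degenerate SNP rate gives identical haplotypes", {
  cfg <- sim_config(seed = 1, n_scaffolds = 1, scaffold_len = 5000,
                    n_genes = 2, gene_len = 400, snp_rate = 0,
                    ensure_gene_snp = FALSE)
  truth <- gen_parental_genomes(cfg)
  expect_equal(nrow(truth$snps), 0L)
  expect_identical(truth$genomes$parent1, truth$genomes$parent2)
})

test_that("SNP count follows the Poisson rate and matches the truth table", {
  cfg <- sim_config(seed = 1, n_scaffolds = 1, scaffold_len = 100000,
                    n_genes = 4, gene_len = 600, snp_rate = 0.001,
                    ensure_gene_snp = FALSE)
  truth <- gen_parental_genomes(cfg)
  # ~100 expected; 4 sd of a Poisson(100) is +/- 40
  expect_gt(nrow(truth$snps), 60)
  expect_lt(nrow(truth$snps), 140)
  # haplotypes differ exactly at the recorded SNP positions with the
  # recorded alleles
  h1 <- seq_to_int(truth$genomes$parent1[[1]])
  h2 <- seq_to_int(truth$genomes$parent2[[1]])
  diffs <- which(h1 != h2)
  expect_identical(diffs, sort(truth$snps$pos))
  bases <- c("A", "C", "G", "T")
  expect_identical(bases[h1[truth$snps$pos]], truth$snps$allele_p1)
  expect_identical(bases[h2[truth$snps$pos]], truth$snps$allele_p2)
  # SNPs stay a read length away from scaffold edges
  expect_true(all(truth$snps$pos > cfg$read_len))
  expect_true(all(truth$snps$pos <= cfg$scaffold_len - cfg$read_len))
})

test_that("generation is deterministic in the seed and varies across seeds", {
  t1a <- gen_parental_genomes(small_cfg(seed = 5))
  t1b <- gen_parental_genomes(small_cfg(seed = 5))
  t2 <- gen_parental_genomes(small_cfg(seed = 6))
  expect_identical(t1a$genomes, t1b$genomes)
  expect_identical(t1a$snps, t1b$snps)
  expect_false(identical(t1a$snps$pos, t2$snps$pos))
  r1a <- gen_endosperm_reads(small_cfg(seed = 5), "AxB", t1a)
  r1b <- gen_endosperm_reads(small_cfg(seed = 5), "AxB", t1b)
  expect_identical(r1a, r1b)
  b1a <- gen_bisulfite_reads(small_cfg(seed = 5), "endosperm", t1a)
  b1b <- gen_bisulfite_reads(small_cfg(seed = 5), "endosperm", t1b)
  expect_identical(b1a, b1b)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(frac_meg = 0.7, frac_peg = 0.4), "<= 1")
  expect_error(sim_config(imprint_strength = 0.4), "imprint_strength")
  expect_error(sim_config(scaffold_len = 50, n_genes = 1, gene_len = 40),
               "read_len")
  expect_error(gen_endosperm_reads(small_cfg(), "AxC", small_truth()),
               "cross")
})

test_that("endosperm dosage: biallelic maternal fraction is 2/3", {
  cfg <- sim_config(seed = 21, n_scaffolds = 1, scaffold_len = 40000,
                    n_genes = 10, gene_len = 600, snp_rate = 0.002,
                    frac_meg = 0, frac_peg = 0, frac_accession_biased = 0,
                    coverage_rna = 200)
  truth <- gen_parental_genomes(cfg)
  er <- gen_endosperm_reads(cfg, "AxB", truth)
  n <- nrow(er$origin)
  frac <- mean(er$origin$parent == "maternal")
  se <- sqrt((2 / 3) * (1 / 3) / n)
  expect_gt(n, 2000)
  expect_lt(abs(frac - 2 / 3), 3 * se)
})

test_that("forced imprinting and accession bias shape the origin log", {
  cfg <- small_cfg(seed = 31, imprint_strength = 1.0,
                   accession_strength = 0.97, coverage_rna = 60)
  truth <- gen_parental_genomes(cfg)
  megs <- truth$genes$gene_id[truth$genes$class == "MEG"]
  accs <- truth$genes[truth$genes$class == "accession_biased", ]
  for (cross in c("AxB", "BxA")) {
    o <- gen_endosperm_reads(cfg, cross, truth)$origin
    # complete imprinting: zero paternal reads at MEGs in both directions
    expect_identical(unique(o$parent[o$gene_id %in% megs]), "maternal")
    # accession bias follows the line, not the cross direction
    for (r in seq_len(nrow(accs))) {
      ofg <- o[o$gene_id == accs$gene_id[r], ]
      expect_gt(mean(ofg$line == accs$biased_line[r]), 0.9)
    }
  }
})

test_that("every emitted read id appears exactly once in the origin log", {
  cfg <- small_cfg(seed = 41)
  truth <- gen_parental_genomes(cfg)
  for (x in list(gen_endosperm_reads(cfg, "AxB", truth),
                 gen_bisulfite_reads(cfg, "endosperm", truth))) {
    expect_identical(x$reads$id, x$origin$id)
    expect_false(anyDuplicated(x$reads$id) > 0)
  }
})

test_that("bisulfite conversion chemistry follows the truth levels", {
  base_cfg <- function(me, conv) {
    sim_config(seed = 51, n_scaffolds = 1, scaffold_len = 20000,
               n_genes = 4, gene_len = 600, snp_rate = 0,
               ensure_gene_snp = FALSE, coverage_bs = 20,
               meth_embryo = me, bisulfite_conversion_rate = conv,
               frac_hypo_meg = 0, frac_hypo_background = 0,
               frac_allele_dmr = 0)
  }
  check_cpg_fraction <- function(cfg, expected, tol_se = TRUE) {
    truth <- gen_parental_genomes(cfg)
    bs <- gen_bisulfite_reads(cfg, "embryo", truth)
    h <- seq_to_int(truth$genomes$parent1[[1]])
    cpg_plus <- which(h == 2L & c(h[-1], 0L) == 3L)
    n_c <- 0L; n_t <- 0L
    plus <- bs$origin$strand == "+"
    rmat <- reads_to_int_matrix(bs$reads$seq[plus])
    st <- bs$origin$start0[plus]
    for (j in seq_len(ncol(rmat))) {
      at_cpg <- (st + j) %in% cpg_plus
      n_c <- n_c + sum(at_cpg & rmat[, j] == 2L)
      n_t <- n_t + sum(at_cpg & rmat[, j] == 4L)
    }
    frac <- n_c / (n_c + n_t)
    if (tol_se) {
      se <- sqrt(expected * (1 - expected) / (n_c + n_t))
      expect_lt(abs(frac - expected), 3 * se)
    } else {
      expect_equal(frac, expected)
    }
    n_c + n_t
  }
  # full conversion of an unmethylated genome: every CpG C reads as T
  check_cpg_fraction(base_cfg(0, 1), 0, tol_se = FALSE)
  # full methylation: every CpG C survives as C
  check_cpg_fraction(base_cfg(1, 1), 1, tol_se = FALSE)
  # intermediate level: observed C fraction within 3 s.e. of truth
  n_obs <- check_cpg_fraction(base_cfg(0.5, 1), 0.5)
  expect_gt(n_obs, 5000)
})

test_that("paired mode emits consistent mates from the same fragment", {
  cfg <- small_cfg(seed = 63, paired = TRUE)
  truth <- gen_parental_genomes(cfg)
  x <- gen_endosperm_reads(cfg, "AxB", truth)
  ids1 <- sub("/1$", "", x$reads$id[grepl("/1$", x$reads$id)])
  ids2 <- sub("/2$", "", x$reads$id[grepl("/2$", x$reads$id)])
  expect_identical(ids1, ids2)
  expect_identical(nrow(x$reads), 2L * length(ids1))
  # every read (either mate) reconstructs from its origin record
  o <- merge(x$origin, x$reads, by = "id")
  idx <- sample(nrow(o), 50)
  for (i in idx) {
    hap <- truth$genomes[[o$line[i]]][o$scaffold[i]]
    seg <- unname(substr(hap, o$start0[i] + 1L, o$start0[i] + cfg$read_len))
    want <- if (o$strand[i] == "-") revcomp(seg) else seg
    expect_identical(o$seq[i], want)
  }
})

test_that("maternal contamination inflates the maternal fraction", {
  cfg <- small_cfg(seed = 61, frac_meg = 0, frac_peg = 0,
                   frac_accession_biased = 0, maternal_contamination = 0.5,
                   coverage_rna = 100)
  truth <- gen_parental_genomes(cfg)
  o <- gen_endosperm_reads(cfg, "AxB", truth)$origin
  # 2/3 baseline plus a third more purely maternal reads: (2/3+1/2)/1.5
  expect_gt(mean(o$parent == "maternal"), 0.72)
})
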