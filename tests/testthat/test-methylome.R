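# hand-crafted placements over a genome with known CpGs, plus simulated
# end-to-end checks of the methylome stack

test_that("cytosine calling counts C/T read bases at reference cytosines", {
  # genome with a CpG at positions 11-12 on the plus strand
  genome <- c(s1 = paste0(strrep("A", 10), "CG", strrep("A", 20),
                          "C", strrep("A", 27)))
  L <- 40L
  seg <- substr(genome[[1]], 5, 5 + L - 1)     # covers the CpG at offset 7
  # ... and the lone non-CpG C at offset 29 (genomic position 33)
  mk <- function(base_at_c) {
    s <- seg
    substr(s, 7, 7) <- base_at_c
    s
  }
  reads <- data.frame(id = sprintf("r%02d", 1:10),
                      seq = c(rep(mk("C"), 4), rep(mk("T"), 5), mk("G")),
                      qual = strrep("I", L), stringsAsFactors = FALSE)
  pl <- data.frame(read_id = reads$id, scaffold = "s1", pos0 = 4L,
                   strand = "+", mismatches = 0L, stringsAsFactors = FALSE)
  calls <- call_cytosines(pl, reads, genome)
  cg <- calls[calls$pos == 11, ]
  expect_identical(cg$c_count, 4L)   # 4 C reads
  expect_identical(cg$t_count, 5L)   # 5 T reads; the G read is ignored
  expect_equal(cg$level, 4 / 9)
  expect_identical(cg$context, "CpG")
  # the isolated non-CpG cytosine is not reported with cpg_only = TRUE
  expect_false(33 %in% calls$pos)
  all_calls <- call_cytosines(pl, reads, genome, cpg_only = FALSE)
  expect_true(33 %in% all_calls$pos)
})

test_that("fully methylated and unmethylated inputs give levels 1 and 0", {
  cfg <- sim_config(seed = 91, n_scaffolds = 1, scaffold_len = 15000,
                    n_genes = 3, gene_len = 600, snp_rate = 0,
                    ensure_gene_snp = FALSE, coverage_bs = 15,
                    meth_embryo = 1, bisulfite_conversion_rate = 1,
                    frac_hypo_meg = 0, frac_hypo_background = 0,
                    frac_allele_dmr = 0)
  truth <- gen_parental_genomes(cfg)
  ref <- truth$genomes$parent1
  bs <- gen_bisulfite_reads(cfg, "embryo", truth)
  calls <- call_cytosines(map_bisulfite_reads(bs$reads, ref), bs$reads, ref)
  expect_gt(nrow(calls), 500)
  expect_true(all(calls$level == 1))

  cfg0 <- sim_config(seed = 91, n_scaffolds = 1, scaffold_len = 15000,
                     n_genes = 3, gene_len = 600, snp_rate = 0,
                     ensure_gene_snp = FALSE, coverage_bs = 15,
                     meth_embryo = 0, bisulfite_conversion_rate = 1,
                     frac_hypo_meg = 0, frac_hypo_background = 0,
                     frac_allele_dmr = 0)
  truth0 <- gen_parental_genomes(cfg0)
  bs0 <- gen_bisulfite_reads(cfg0, "embryo", truth0)
  calls0 <- call_cytosines(map_bisulfite_reads(bs0$reads, ref), bs0$reads,
                           truth0$genomes$parent1)
  # every C read as T: covered cytosines all have level exactly 0
  expect_gt(nrow(calls0), 500)
  expect_true(all(calls0$c_count == 0L))
  expect_true(all(calls0$level == 0))
})

test_that("bisulfite caller recovers truth levels within 0.02 at 50x", {
  cfg <- sim_config(seed = 95, n_scaffolds = 1, scaffold_len = 20000,
                    n_genes = 4, gene_len = 600, snp_rate = 0.001,
                    coverage_bs = 50, frac_meg = 0.5, frac_hypo_meg = 1,
                    frac_allele_dmr = 0)
  truth <- gen_parental_genomes(cfg)
  ref <- truth$genomes$parent1
  for (sample in c("endosperm", "embryo")) {
    bs <- gen_bisulfite_reads(cfg, sample, truth)
    calls <- call_cytosines(map_bisulfite_reads(bs$reads, ref), bs$reads,
                            ref)
    lev_col <- if (sample == "embryo") "level_embryo" else "level_endosperm"
    for (r in seq_len(nrow(truth$meth_regions))) {
      reg <- truth$meth_regions[r, ]
      inside <- calls$pos > reg$start & calls$pos <= reg$end
      if (reg$type == "background") {
        # background = scaffold minus special regions
        sp <- truth$meth_regions[truth$meth_regions$type != "background", ]
        for (q in seq_len(nrow(sp)))
          inside <- inside & !(calls$pos > sp$start[q] &
                                 calls$pos <= sp$end[q])
      }
      obs <- mean(calls$level[inside])
      expect_lt(abs(obs - reg[[lev_col]]), 0.02)
    }
  }
})

test_that("DMR segmentation obeys the five criteria", {
  # 6 CpGs across 120 bp, levels 0.1 vs 0.9 at 20 reads
  pos <- as.integer(seq(1001, 1120, length.out = 6))
  a <- make_calls("s1", pos, c_count = 2L, t_count = 18L)
  b <- make_calls("s1", pos, c_count = 18L, t_count = 2L)
  d <- call_dmrs(a, b)
  expect_identical(nrow(d), 1L)
  expect_equal(d$diff, -0.8)
  expect_identical(d$n_sites, 6L)
  expect_identical(d$length, d$end - d$start)
  chi_oracle <- stats::chisq.test(matrix(c(12, 108, 108, 12), 2,
                                         byrow = TRUE),
                                  correct = FALSE)$p.value
  expect_equal(d$chi2_p, chi_oracle)

  # the same contrast squeezed into 35 bp fails the length criterion
  pos35 <- as.integer(seq(1001, 1035, length.out = 6))
  expect_identical(nrow(call_dmrs(make_calls("s1", pos35, 2L, 18L),
                                  make_calls("s1", pos35, 18L, 2L))), 0L)

  # swapping samples negates the difference, nothing else
  d_sw <- call_dmrs(b, a)
  expect_equal(d_sw$diff, 0.8)
  expect_identical(d_sw[c("start", "end", "n_sites")],
                   d[c("start", "end", "n_sites")])

  # sites further than 200 bp apart never chain
  pos_far <- c(1001L, 1300L, 1600L, 1900L, 2200L, 2500L)
  expect_identical(nrow(call_dmrs(make_calls("s1", pos_far, 2L, 18L),
                                  make_calls("s1", pos_far, 18L, 2L))), 0L)

  # identical samples yield zero segments
  expect_identical(nrow(call_dmrs(a, a)), 0L)

  # low coverage is ignored entirely
  a10 <- make_calls("s1", pos, 1L, 9L)
  b10 <- make_calls("s1", pos, 9L, 1L)
  expect_identical(nrow(call_dmrs(a10, b10)), 0L)
})

test_that("reported DMRs pass an independent re-audit", {
  cfg <- sim_config(seed = 97, n_scaffolds = 1, scaffold_len = 30000,
                    n_genes = 8, gene_len = 600, snp_rate = 0.002,
                    coverage_bs = 30, frac_meg = 0.4, frac_hypo_meg = 1,
                    frac_allele_dmr = 0)
  truth <- gen_parental_genomes(cfg)
  ref <- truth$genomes$parent1
  bs_a <- gen_bisulfite_reads(cfg, "endosperm", truth)
  bs_b <- gen_bisulfite_reads(cfg, "embryo", truth)
  ca <- call_cytosines(map_bisulfite_reads(bs_a$reads, ref), bs_a$reads, ref)
  cb <- call_cytosines(map_bisulfite_reads(bs_b$reads, ref), bs_b$reads, ref)
  d <- call_dmrs(ca, cb)
  expect_gt(nrow(d), 0L)
  aud <- audit_dmrs(d, ca, cb)
  expect_true(all(aud$ok))
  # every called DMR overlaps a truth hypomethylated region
  hypo <- truth$meth_regions[truth$meth_regions$type == "hypo", ]
  for (i in seq_len(nrow(d)))
    expect_true(any(d$start[i] < hypo$end & d$end[i] > hypo$start))
})

test_that("metagene profile is strand-aware and tracks the truth levels", {
  # uniformly methylated calls -> every covered bin is exactly 1
  set.seed(15)
  pos <- sort(sample(1:10000, 600))
  calls <- make_calls("s1", pos, 10L, 0L)
  feats <- data.frame(scaffold = "s1", start = 4000L, end = 6000L,
                      strand = "+", stringsAsFactors = FALSE)
  prof <- metagene_profile(calls, feats)
  expect_true(all(prof$mean_level[!is.na(prof$mean_level)] == 1))

  # mirrored bin assignment when the strand flips
  calls2 <- calls
  calls2$c_count <- ifelse(pos < 4000, 10L, 0L)
  calls2$t_count <- 10L - calls2$c_count
  calls2$level <- calls2$c_count / 10
  p_plus <- metagene_profile(calls2, feats)
  feats_m <- feats; feats_m$strand <- "-"
  p_minus <- metagene_profile(calls2, feats_m)
  up_plus <- p_plus$mean_level[p_plus$rel_start < 0]
  # upstream of the + gene is < 4000: fully methylated there
  expect_true(all(up_plus[!is.na(up_plus)] == 1))
  up_minus <- p_minus$mean_level[p_minus$rel_start < 0]
  # upstream of the - gene is > 6000: unmethylated
  expect_true(all(up_minus[!is.na(up_minus)] == 0))
})

test_that("endosperm metagene profile sits below the embryo profile", {
  cfg <- sim_config(seed = 99, n_scaffolds = 1, scaffold_len = 30000,
                    n_genes = 6, gene_len = 600, snp_rate = 0.001,
                    coverage_bs = 25, meth_endosperm = 0.3,
                    meth_embryo = 0.8, frac_hypo_meg = 0,
                    frac_hypo_background = 0, frac_allele_dmr = 0)
  truth <- gen_parental_genomes(cfg)
  ref <- truth$genomes$parent1
  bs_en <- gen_bisulfite_reads(cfg, "endosperm", truth)
  bs_em <- gen_bisulfite_reads(cfg, "embryo", truth)
  cy_en <- call_cytosines(map_bisulfite_reads(bs_en$reads, ref),
                          bs_en$reads, ref)
  cy_em <- call_cytosines(map_bisulfite_reads(bs_em$reads, ref),
                          bs_em$reads, ref)
  for (anchor in c("five_prime", "three_prime")) {
    p_en <- metagene_profile(cy_en, truth$genes, anchor = anchor)
    p_em <- metagene_profile(cy_em, truth$genes, anchor = anchor)
    covered <- !is.na(p_en$mean_level) & !is.na(p_em$mean_level)
    expect_gt(sum(covered), 10)
    expect_true(all(p_en$mean_level[covered] < p_em$mean_level[covered]))
  }
})

test_that("DMR-gene linking labels by midpoint within the 2-kb flank", {
  genes <- data.frame(gene_id = "g1", scaffold = "s1", start = 10000L,
                      end = 12000L, strand = "+", stringsAsFactors = FALSE)
  dmrs <- data.frame(scaffold = "s1",
                     start = c(9400L, 11000L, 12500L, 14600L, 9950L),
                     end = c(9600L, 11200L, 12700L, 14800L, 10050L),
                     diff = -0.7)
  ln <- dmr_gene_overlap(dmrs, genes)
  expect_identical(ln$dmr, c(1L, 2L, 3L, 5L))  # 2.5 kb away: not linked
  expect_identical(ln$region, c("upstream", "gene_body", "downstream",
                                "gene_body"))  # TSS-spanning: by midpoint
  expect_identical(hypomethylated_genes(dmrs, genes), "g1")
})

test_that("the 40/70 allele rule gates allele-specific DMR windows", {
  gene <- data.frame(gene_id = "g1", scaffold = "s1", start = 1000L,
                     end = 1600L, strand = "+", stringsAsFactors = FALSE)
  pos <- as.integer(seq(1210, 1390, by = 30))  # 7 CpGs in one window
  run_case <- function(mat_pct, pat_pct) {
    depth <- 12L
    cm <- make_calls("s1", pos, as.integer(round(depth * mat_pct / 100)),
                     depth - as.integer(round(depth * mat_pct / 100)))
    cp <- make_calls("s1", pos, as.integer(round(depth * pat_pct / 100)),
                     depth - as.integer(round(depth * pat_pct / 100)))
    call_allele_dmrs(cm, cp, gene)
  }
  hit <- run_case(33, 100)
  expect_gt(nrow(hit), 0L)
  expect_identical(unique(hit$region), "gene_body")
  expect_true(all(hit$length == hit$end - hit$start))
  expect_true(all(hit$length == hit$rel_end - hit$rel_start))
  expect_identical(nrow(run_case(45, 80)), 0L)  # fails the < 40% arm
  hit2 <- run_case(0, 71)
  expect_gt(nrow(hit2), 0L)
  expect_identical(nrow(run_case(0, 69)), 0L)   # fails the > 70% arm
})

test_that("parent-of-origin splitting recovers allele methylation truth", {
  cfg <- sim_config(seed = 101, n_scaffolds = 1, scaffold_len = 30000,
                    n_genes = 8, gene_len = 600, snp_rate = 0.002,
                    coverage_bs = 60, frac_meg = 0.4, frac_allele_dmr = 0.8,
                    frac_hypo_meg = 0, frac_hypo_background = 0)
  truth <- gen_parental_genomes(cfg)
  ref <- truth$genomes$parent1
  bs <- gen_bisulfite_reads(cfg, "endosperm", truth)
  pl <- map_bisulfite_reads(bs$reads, ref)
  spl <- split_bisulfite_by_parent(pl, bs$reads, truth$snps, "AxB")
  # labels agree exactly with the generator's parent-of-origin log
  m <- merge(spl[spl$parent != "unknown", ], bs$origin, by.x = "read_id",
             by.y = "id")
  expect_gt(nrow(m), 500)
  expect_true(all(m$parent.x == m$parent.y))
  # allele-specific DMRs are recovered at the truth regions
  cy_m <- call_cytosines(spl[spl$parent == "maternal", ], bs$reads, ref)
  cy_p <- call_cytosines(spl[spl$parent == "paternal", ], bs$reads, ref)
  tg <- truth$genes[truth$genes$has_allele_dmr, ]
  adm <- call_allele_dmrs(cy_m, cy_p, tg)
  regs <- truth$meth_regions[truth$meth_regions$type == "allele_dmr", ]
  expect_gt(nrow(regs), 0L)
  found <- vapply(seq_len(nrow(regs)), function(i)
    any(adm$gene_id == regs$gene_id[i] & adm$start < regs$end[i] &
          adm$end > regs$start[i]), logical(1))
  expect_true(all(found))
  # maternal hypomethylated, paternal hypermethylated, as simulated
  expect_true(all(adm$meth_maternal_pct < 40))
  expect_true(all(adm$meth_paternal_pct > 70))
})

test_that("hypomethylation association reproduces the exact Fisher P", {
  tab <- matrix(c(20L, 189L, 100L, 9800L), 2, byrow = TRUE)
  res <- hypomethylation_association(
    imprinted_genes = sprintf("i%04d", 1:209),
    informative_genes = c(sprintf("i%04d", 1:209), sprintf("b%04d", 1:9900)),
    hypo_genes = c(sprintf("i%04d", 1:20), sprintf("b%04d", 1:100)))
  expect_identical(unname(res$table), tab)
  expect_equal(res$p_value, stats::fisher.test(tab)$p.value,
               tolerance = 1e-10)
  # degenerate margin
  res0 <- hypomethylation_association("i1", c("i1", "b1"), character(0))
  expect_identical(res0$p_value, 1)
})
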