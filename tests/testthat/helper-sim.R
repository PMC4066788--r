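# shared small simulation fixtures, built once per test run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# a small mixed-class genome: 12 genes on 2 scaffolds, 3 MEG / 1 PEG /
# 1 accession-biased
small_cfg <- function(seed = 11L, ...) {
  args <- list(seed = seed, n_scaffolds = 2L, scaffold_len = 30000L,
               n_genes = 12L, gene_len = 600L, snp_rate = 0.002,
               coverage_rna = 40, coverage_bs = 25, frac_meg = 0.25,
               frac_peg = 1 / 12, frac_accession_biased = 1 / 12,
               imprint_strength = 0.97)
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}

small_truth <- function() cached("small_truth", {
  gen_parental_genomes(small_cfg())
})

# cytosine-call table builder for hand-crafted methylome tests
make_calls <- function(scaffold, pos, c_count, t_count, strand = "+") {
  data.frame(scaffold = scaffold, pos = pos, strand = strand,
             context = "CpG", c_count = c_count, t_count = t_count,
             level = c_count / (c_count + t_count),
             stringsAsFactors = FALSE)
}

# joint locus count table builder for imprinting tests
make_counts <- function(mat_AxB, n_AxB, mat_BxA, n_BxA,
                        snp_id = sprintf("locus_%03d", seq_along(mat_AxB))) {
  data.frame(snp_id = snp_id,
             scaffold = "scaffold_01", pos = seq_along(mat_AxB) * 100L,
             p1_AxB = mat_AxB, p2_AxB = n_AxB - mat_AxB,
             p1_BxA = n_BxA - mat_BxA, p2_BxA = mat_BxA,
             mat_AxB = mat_AxB, pat_AxB = n_AxB - mat_AxB,
             mat_BxA = mat_BxA, pat_BxA = n_BxA - mat_BxA,
             n_AxB = n_AxB, n_BxA = n_BxA,
             stringsAsFactors = FALSE)
}
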