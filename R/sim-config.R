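#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator: two inbred
#' parental haplotypes differing at biallelic SNPs, reciprocal F1 endosperm
#' transcriptomes with 2 maternal : 1 paternal genomic dosage, and CpG
#' bisulfite reads with endosperm hypomethylation and allele-differential
#' methylation at a subset of imprinted genes.
#'
#' @param seed integer seed; identical seed + config give byte-identical
#'   outputs.
#' @param n_scaffolds number of scaffolds.
#' @param scaffold_len scaffold length in bp.
#' @param snp_rate expected SNPs per bp between the parental lines.
#' @param n_genes number of (unspliced) gene models.
#' @param gene_len gene length in bp (must be >= `read_len`).
#' @param frac_meg,frac_peg,frac_accession_biased proportions of genes that
#'   are maternally expressed, paternally expressed, or biased toward one
#'   parental line in both cross directions; the rest are biallelic.
#' @param imprint_strength maternal read fraction for MEGs (and paternal
#'   fraction for PEGs); must be in (0.5, 1].
#' @param accession_strength fraction of reads drawn from the favoured line
#'   for accession-biased genes, in both cross directions.
#' @param read_len read length in bp.
#' @param coverage_rna mean endosperm reads per SNP per cross direction.
#' @param coverage_parental mean per-base depth of parental (SNP-discovery)
#'   reads over gene bodies.
#' @param coverage_bs mean bisulfite reads per cytosine.
#' @param meth_endosperm,meth_embryo baseline CpG methylation probability in
#'   endosperm and embryo. The endosperm baseline sits below the embryo one
#'   (global hypomethylation) but above the DMR detection contrast.
#' @param meth_hypo CpG methylation level inside endosperm-hypomethylated
#'   regions (strong local demethylation, the DMR signal).
#' @param meth_allele_low,meth_allele_high maternal/paternal CpG methylation
#'   levels inside allele-differential regions of endosperm.
#' @param frac_hypo_meg,frac_hypo_background probability that a MEG (resp.
#'   any other gene) carries an endosperm-hypomethylated region in its body
#'   or 2-kb flanks.
#' @param hypo_len length of endosperm-hypomethylated regions (bp).
#' @param frac_allele_dmr fraction of MEGs carrying an allele-differential
#'   methylation region in the gene body.
#' @param te_families data.frame with columns `family`, `n`,
#'   `meg_multiplier`: TE counts per family and the enrichment multiplier
#'   for placement near MEGs (within 4-kb flanks).
#' @param bisulfite_conversion_rate probability that an unmethylated C is
#'   read as T.
#' @param bs_maternal_prob_endosperm,bs_maternal_prob_embryo probability
#'   that a bisulfite read is drawn from the maternal haplotype (2/3 in the
#'   triploid endosperm, 1/2 in the diploid embryo).
#' @param error_rate per-base sequencing error rate for RNA reads (default
#'   0: the statistics are exercised on clean reads; set to e.g. 0.001 for
#'   robustness experiments).
#' @param maternal_contamination extra purely maternal reads added per gene,
#'   as a fraction of the gene's read count (models seed-coat/maternal RNA
#'   carry-over, which mimics MEGs).
#' @param paired emit read pairs (`/1`, `/2` mates from opposite fragment
#'   ends) for the endosperm libraries; off by default since pairing adds
#'   nothing to allele counting.
#' @param ensure_gene_snp guarantee at least one diagnostic SNP inside every
#'   gene body so every gene is informative.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_scaffolds = 2L,
                       scaffold_len = 100000L,
                       snp_rate = 0.001,
                       n_genes = 40L,
                       gene_len = 600L,
                       frac_meg = 0.10,
                       frac_peg = 0.05,
                       frac_accession_biased = 0.05,
                       imprint_strength = 0.95,
                       accession_strength = 0.95,
                       read_len = 90L,
                       coverage_rna = 30,
                       coverage_parental = 15,
                       coverage_bs = 20,
                       meth_endosperm = 0.45,
                       meth_embryo = 0.80,
                       meth_hypo = 0.05,
                       meth_allele_low = 0.05,
                       meth_allele_high = 0.90,
                       frac_hypo_meg = 0.5,
                       frac_hypo_background = 0.05,
                       hypo_len = 500L,
                       frac_allele_dmr = 0.3,
                       te_families = default_te_families(),
                       bisulfite_conversion_rate = 0.995,
                       bs_maternal_prob_endosperm = 2 / 3,
                       bs_maternal_prob_embryo = 0.5,
                       error_rate = 0,
                       maternal_contamination = 0,
                       paired = FALSE,
                       ensure_gene_snp = TRUE) {
  cfg <- list(seed = as.integer(seed), n_scaffolds = as.integer(n_scaffolds),
              scaffold_len = as.integer(scaffold_len), snp_rate = snp_rate,
              n_genes = as.integer(n_genes), gene_len = as.integer(gene_len),
              frac_meg = frac_meg, frac_peg = frac_peg,
              frac_accession_biased = frac_accession_biased,
              imprint_strength = imprint_strength,
              accession_strength = accession_strength,
              read_len = as.integer(read_len),
              coverage_rna = coverage_rna,
              coverage_parental = coverage_parental,
              coverage_bs = coverage_bs,
              meth_endosperm = meth_endosperm, meth_embryo = meth_embryo,
              meth_hypo = meth_hypo,
              meth_allele_low = meth_allele_low,
              meth_allele_high = meth_allele_high,
              frac_hypo_meg = frac_hypo_meg,
              frac_hypo_background = frac_hypo_background,
              hypo_len = as.integer(hypo_len),
              frac_allele_dmr = frac_allele_dmr,
              te_families = te_families,
              bisulfite_conversion_rate = bisulfite_conversion_rate,
              bs_maternal_prob_endosperm = bs_maternal_prob_endosperm,
              bs_maternal_prob_embryo = bs_maternal_prob_embryo,
              error_rate = error_rate,
              maternal_contamination = maternal_contamination,
              paired = isTRUE(paired),
              ensure_gene_snp = isTRUE(ensure_gene_snp))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default transposable-element family table for the generator
#' @return data.frame with columns `family`, `n`, `meg_multiplier`.
#' @export
default_te_families <- function() {
  data.frame(family = c("LTR/Gypsy", "LTR/Copia", "DNA/MuDR", "DNA/CACTA"),
             n = c(60L, 40L, 30L, 20L),
             meg_multiplier = c(5, 1, 1, 1),
             stringsAsFactors = FALSE)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with(cfg, {
    if (frac_meg + frac_peg + frac_accession_biased > 1)
      stop("frac_meg + frac_peg + frac_accession_biased must be <= 1")
    if (!(imprint_strength > 0.5 && imprint_strength <= 1))
      stop("imprint_strength must be in (0.5, 1]")
    probs <- c(frac_meg, frac_peg, frac_accession_biased,
               accession_strength, meth_endosperm, meth_embryo, meth_hypo,
               meth_allele_low, meth_allele_high, frac_hypo_meg,
               frac_hypo_background, frac_allele_dmr,
               bisulfite_conversion_rate, bs_maternal_prob_endosperm,
               bs_maternal_prob_embryo, error_rate, snp_rate)
    if (any(probs < 0 | probs > 1))
      stop("all rates and probabilities must lie in [0, 1]")
    if (scaffold_len < read_len)
      stop("scaffold_len must be >= read_len")
    if (gene_len < read_len)
      stop("gene_len must be >= read_len")
    if (!is.data.frame(te_families) ||
        !all(c("family", "n", "meg_multiplier") %in% names(te_families)))
      stop("te_families must have columns family, n, meg_multiplier")
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome : %d scaffold(s) x %d bp, SNP rate %g\n",
              x$n_scaffolds, x$scaffold_len, x$snp_rate))
  cat(sprintf("  genes  : %d x %d bp (MEG %.0f%%, PEG %.0f%%, accession %.0f%%)\n",
              x$n_genes, x$gene_len, 100 * x$frac_meg, 100 * x$frac_peg,
              100 * x$frac_accession_biased))
  cat(sprintf("  reads  : %d bp, RNA %g per SNP per cross, BS %g per C\n",
              x$read_len, x$coverage_rna, x$coverage_bs))
  cat(sprintf("  imprint strength %.2f, seed %d\n",
              x$imprint_strength, x$seed))
  invisible(x)
}
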