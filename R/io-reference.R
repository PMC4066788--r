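#' Reference allele-specific DMR table
#'
#' Loads the published summary of allele-specific differentially methylated
#' regions at imprinted castor bean endosperm genes that ships with the
#' package (six genes, eight regions; maternal alleles hypomethylated,
#' paternal alleles hypermethylated). Coordinates are gene-relative for
#' upstream regions (negative values) and scaffold coordinates otherwise;
#' in both frames the printed length equals `end - start`.
#'
#' @return data.frame with columns `gene`, `type`, `start`, `end`,
#'   `length`, `meth_paternal_pct`, `meth_maternal_pct`, `region`.
#' @export
reference_allele_dmrs <- function() {
  read_tsv_file(system.file("extdata", "reference_allele_dmrs.tsv",
                            package = "imprintseq", mustWork = TRUE))
}

#' Apply the 40%/70% allele-methylation rule to a summary table
#'
#' Keeps rows where one allele's percent methylation is below `low_pct`
#' and the other's is above `high_pct` -- the selection rule for
#' allele-specific DMRs.
#'
#' @param tab data.frame with `meth_maternal_pct` and `meth_paternal_pct`.
#' @param low_pct,high_pct thresholds in percent.
#' @return the qualifying subset of `tab`.
#' @export
filter_allele_dmr_table <- function(tab, low_pct = 40, high_pct = 70) {
  lo <- pmin(tab$meth_maternal_pct, tab$meth_paternal_pct)
  hi <- pmax(tab$meth_maternal_pct, tab$meth_paternal_pct)
  tab[lo < low_pct & hi > high_pct, , drop = FALSE]
}
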