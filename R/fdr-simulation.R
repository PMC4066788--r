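#' False-discovery control simulation for the locus selection procedure
#'
#' Simulates count tables at the study's dosage conditions -- null loci
#' draw maternal counts from Binomial(coverage, 2/3) in each cross,
#' imprinted loci from Binomial(coverage, `imprint_maternal`) -- runs the
#' full selection procedure ([classify_loci()]: exact one-sided binomial
#' tests, joint reciprocal P, rank FDR, uniparental filter) and measures
#' the false-discovery proportion among selected (MEG or PEG) loci,
#' averaged over replicates. A replicate with no selected locus contributes
#' a false-discovery proportion of 0.
#'
#' @param n_null number of null (biallelic) loci per replicate.
#' @param n_imprinted number of truly imprinted (maternal-biased) loci.
#' @param coverage reads per locus per cross.
#' @param imprint_maternal maternal fraction of imprinted loci.
#' @param n_rep replicates.
#' @param seed base seed; replicate r uses `seed + r`.
#' @param ... further arguments passed to [classify_loci()].
#' @return list with `mean_fdp`, `fdp` (per replicate), `mean_selected`,
#'   `mean_true_positive_rate`.
#' @export
simulate_fdr_control <- function(n_null = 5000L, n_imprinted = 500L,
                                 coverage = 50L, imprint_maternal = 0.95,
                                 n_rep = 50L, seed = 1L, ...) {
  fdp <- numeric(n_rep)
  n_sel <- numeric(n_rep)
  tpr <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    res <- .with_seed(seed + r, {
      n <- n_null + n_imprinted
      p <- c(rep(2 / 3, n_null), rep(imprint_maternal, n_imprinted))
      counts <- data.frame(
        snp_id = sprintf("locus_%05d", seq_len(n)),
        mat_AxB = stats::rbinom(n, coverage, p),
        n_AxB = coverage,
        mat_BxA = stats::rbinom(n, coverage, p),
        n_BxA = coverage,
        truly_null = c(rep(TRUE, n_null), rep(FALSE, n_imprinted)))
      classify_loci(counts, ...)
    })
    sel <- res$class != "biallelic"
    n_sel[r] <- sum(sel)
    fdp[r] <- if (any(sel)) mean(res$truly_null[sel]) else 0
    tpr[r] <- sum(sel & !res$truly_null) / n_imprinted
  }
  list(mean_fdp = mean(fdp), fdp = fdp, mean_selected = mean(n_sel),
       mean_true_positive_rate = mean(tpr))
}
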