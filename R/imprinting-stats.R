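# The core imprinting statistic: per-locus exact one-sided binomial tests
# against the 2 maternal : 1 paternal dosage null, a joint reciprocal
# P-value from the distribution of the second-order statistic
# P = max(p1, p2)^2, a literal rank-based FDR (P * n / i), uniparental
# filtering, and locus -> gene aggregation.

#' Exact one-sided binomial tail probability
#'
#' Computes the exact tail sum of the binomial mass function (no normal
#' approximation): `P(X >= k)` for `direction = "greater"` or `P(X <= k)`
#' for `"less"`, with `X ~ Binomial(n, p0)`. Vectorised over `k` and `n`.
#'
#' @param k observed successes (vector).
#' @param n trials (vector, recycled against `k`); must be >= 1.
#' @param p0 null success probability, in (0, 1).
#' @param direction tail: `"greater"` or `"less"`.
#' @return vector of exact tail probabilities.
#' @export
binom_onesided <- function(k, n, p0, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(p0) != 1L || is.na(p0) || p0 <= 0 || p0 >= 1)
    stop("p0 must be a single value in (0, 1)")
  kk <- as.integer(k); nn <- as.integer(rep_len(n, length(kk)))
  if (any(nn < 1L)) stop("n must be >= 1")
  if (any(kk < 0L | kk > nn)) stop("k must lie in [0, n]")
  out <- numeric(length(kk))
  lp <- log(p0); lq <- log1p(-p0)
  for (nu in unique(nn)) {
    jj <- 0:nu
    lmass <- lchoose(nu, jj) + jj * lp + (nu - jj) * lq
    mass <- exp(lmass)
    # accumulate each tail from its small end to limit rounding
    upper <- rev(cumsum(rev(mass)))   # upper[j+1] = P(X >= j)
    lower <- cumsum(mass)             # lower[j+1] = P(X <= j)
    sel <- nn == nu
    out[sel] <- if (direction == "greater") pmin(upper[kk[sel] + 1L], 1)
    else pmin(lower[kk[sel] + 1L], 1)
  }
  out
}

#' Joint reciprocal P-value (second-order statistic)
#'
#' Combines the two one-sided P-values from the reciprocal crosses into
#' `P = max(p1, p2)^2` -- the probability that the larger of two independent
#' uniform variables falls below `max(p1, p2)` -- so the joint P-value is
#' itself uniform under the null.
#'
#' @param p1,p2 P-values in `[0, 1]` (vectorised).
#' @return joint P-values.
#' @export
joint_p <- function(p1, p2) {
  if (any(is.na(p1) | is.na(p2) | p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1))
    stop("p1 and p2 must lie in [0, 1]")
  pmax(p1, p2)^2
}

#' Rank-based false-discovery rate
#'
#' Sorts the joint P-values ascending and computes `FDR_i = P_(i) * n / i`
#' (`n` = list length, `i` = rank), mapped back to input order. This is the
#' raw rank formula; the Benjamini-Hochberg step-up monotonicity pass
#' (`FDR_i <- min_{j >= i} FDR_j` in sorted order) is available via
#' `monotone = TRUE` but off by default.
#'
#' @param p vector of P-values in `[0, 1]`.
#' @param monotone apply the step-up monotonicity pass.
#' @return FDR values aligned with `p` (may exceed 1 when `monotone`
#'   is off).
#' @export
fdr_rank <- function(p, monotone = FALSE) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p) | p < 0 | p > 1)) stop("P-values must lie in [0, 1]")
  n <- length(p)
  o <- order(p)
  fdr_sorted <- p[o] * n / seq_len(n)
  if (monotone) fdr_sorted <- rev(cummin(rev(fdr_sorted)))
  out <- numeric(n)
  out[o] <- fdr_sorted
  out
}

#' Classify loci as MEG / PEG / biallelic
#'
#' For each locus, tests the maternal read count in each cross against the
#' dosage null (maternal fraction `null_maternal` = 2/3) with an exact
#' one-sided binomial test, combines the reciprocal P-values with
#' [joint_p()], ranks the maternal and paternal joint lists *separately*
#' with [fdr_rank()], and calls a locus maternally expressed iff its
#' maternal FDR is at or below `fdr_threshold` *and* the maternal fraction
#' reaches `uniparental_fraction` in **both** crosses (paternal calls are
#' symmetric). Imprinting is annotated `complete` when the minor parent has
#' zero reads in both crosses, else `partial`.
#'
#' @param counts joint locus table from [counts_by_cross()] (or any
#'   data.frame with `mat_AxB`, `n_AxB`, `mat_BxA`, `n_BxA`).
#' @param fdr_threshold FDR selection cutoff.
#' @param uniparental_fraction minimum uniparental read fraction required
#'   in both crosses.
#' @param null_maternal null maternal fraction (2/3 for triploid
#'   endosperm).
#' @param monotone_fdr apply the step-up pass in [fdr_rank()].
#' @return data.frame with per-locus test results (`p1_mat`, `p2_mat`,
#'   `joint_P_maternal`, `joint_P_paternal`, `fdr_mat`, `fdr_pat`,
#'   fractions, totals, `class`, `completeness`).
#' @export
classify_loci <- function(counts, fdr_threshold = 0.05,
                          uniparental_fraction = 0.90,
                          null_maternal = 2 / 3, monotone_fdr = FALSE) {
  x <- as.data.frame(counts)
  need <- c("mat_AxB", "n_AxB", "mat_BxA", "n_BxA")
  stopifnot(all(need %in% names(x)))
  drop <- x$n_AxB == 0L | x$n_BxA == 0L
  if (any(drop)) {
    message(sum(drop), " locus/loci with zero reads in a cross excluded")
    x <- x[!drop, , drop = FALSE]
  }
  if (nrow(x) == 0L) return(x)

  x$mat_frac_AxB <- x$mat_AxB / x$n_AxB
  x$mat_frac_BxA <- x$mat_BxA / x$n_BxA
  x$p1_mat <- binom_onesided(x$mat_AxB, x$n_AxB, null_maternal, "greater")
  x$p2_mat <- binom_onesided(x$mat_BxA, x$n_BxA, null_maternal, "greater")
  pat_null <- 1 - null_maternal
  x$p1_pat <- binom_onesided(x$n_AxB - x$mat_AxB, x$n_AxB, pat_null,
                             "greater")
  x$p2_pat <- binom_onesided(x$n_BxA - x$mat_BxA, x$n_BxA, pat_null,
                             "greater")
  x$joint_P_maternal <- joint_p(x$p1_mat, x$p2_mat)
  x$joint_P_paternal <- joint_p(x$p1_pat, x$p2_pat)
  x$fdr_mat <- fdr_rank(x$joint_P_maternal, monotone = monotone_fdr)
  x$fdr_pat <- fdr_rank(x$joint_P_paternal, monotone = monotone_fdr)

  meg <- x$fdr_mat <= fdr_threshold &
    x$mat_frac_AxB >= uniparental_fraction &
    x$mat_frac_BxA >= uniparental_fraction
  peg <- x$fdr_pat <= fdr_threshold &
    (1 - x$mat_frac_AxB) >= uniparental_fraction &
    (1 - x$mat_frac_BxA) >= uniparental_fraction
  x$class <- ifelse(meg, "MEG", ifelse(peg, "PEG", "biallelic"))
  x$completeness <- NA_character_
  minor_mat <- (x$n_AxB - x$mat_AxB) + (x$n_BxA - x$mat_BxA)
  minor_pat <- x$mat_AxB + x$mat_BxA
  x$completeness[meg] <- ifelse(minor_mat[meg] == 0L, "complete", "partial")
  x$completeness[peg] <- ifelse(minor_pat[peg] == 0L, "complete", "partial")
  rownames(x) <- NULL
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect accession-biased (line-biased, non-imprinted) loci
#'
#' A locus is biased toward parental line X iff the line-X read fraction
#' exceeds `bias_fraction` in *both* cross directions -- i.e. the bias
#' follows the line, not the parent of origin -- and the deviation from the
#' dosage null (2/3 when X is the mother, 1/3 when X is the father) is
#' FDR-significant on the joint reciprocal P-value. Disjoint from MEG/PEG
#' by construction.
#'
#' @param counts joint locus table from [counts_by_cross()].
#' @param bias_fraction line-fraction threshold (strictly greater than).
#' @param fdr_threshold FDR cutoff on the per-line joint P-value lists.
#' @param null_maternal dosage null for the maternal parent.
#' @return `counts` with added per-line fractions, joint P-values, FDRs and
#'   an `acc_class` column (`accession_biased_p1`, `accession_biased_p2`,
#'   or `none`).
#' @export
detect_accession_bias <- function(counts, bias_fraction = 0.90,
                                  fdr_threshold = 0.05,
                                  null_maternal = 2 / 3) {
  x <- as.data.frame(counts)
  stopifnot(all(c("p1_AxB", "p2_AxB", "p1_BxA", "p2_BxA") %in% names(x)))
  x <- x[(x$p1_AxB + x$p2_AxB) > 0L & (x$p1_BxA + x$p2_BxA) > 0L, ,
         drop = FALSE]
  if (nrow(x) == 0L) {
    x$acc_class <- character(0)
    return(x)
  }
  nA <- x$p1_AxB + x$p2_AxB
  nB <- x$p1_BxA + x$p2_BxA
  x$frac_p1_AxB <- x$p1_AxB / nA
  x$frac_p1_BxA <- x$p1_BxA / nB
  pat_null <- 1 - null_maternal
  # line 1 is the mother in AxB and the father in BxA
  p1_ax <- binom_onesided(x$p1_AxB, nA, null_maternal, "greater")
  p1_bx <- binom_onesided(x$p1_BxA, nB, pat_null, "greater")
  p2_ax <- binom_onesided(x$p2_AxB, nA, pat_null, "greater")
  p2_bx <- binom_onesided(x$p2_BxA, nB, null_maternal, "greater")
  x$joint_P_line1 <- joint_p(p1_ax, p1_bx)
  x$joint_P_line2 <- joint_p(p2_ax, p2_bx)
  x$fdr_line1 <- fdr_rank(x$joint_P_line1)
  x$fdr_line2 <- fdr_rank(x$joint_P_line2)
  b1 <- x$frac_p1_AxB > bias_fraction & x$frac_p1_BxA > bias_fraction &
    x$fdr_line1 <= fdr_threshold
  b2 <- (1 - x$frac_p1_AxB) > bias_fraction &
    (1 - x$frac_p1_BxA) > bias_fraction & x$fdr_line2 <= fdr_threshold
  x$acc_class <- ifelse(b1, "accession_biased_p1",
                        ifelse(b2, "accession_biased_p2", "none"))
  rownames(x) <- NULL
  x
}

#' Aggregate locus calls to gene calls
#'
#' A locus inside a gene body supports that gene; a gene's class is the
#' unanimous class of its significant (non-biallelic) loci, genes whose
#' significant loci disagree are flagged `discordant`, and significant loci
#' outside all gene bodies are reported as intergenic with the distance and
#' side of the nearest gene (e.g. `intergenic_MEG_like`).
#'
#' @param loci data.frame from [classify_loci()] (optionally carrying an
#'   `acc_class` column from [detect_accession_bias()]).
#' @param genes gene models: `gene_id`, `scaffold`, `start`, `end` (0-based
#'   half-open), `strand`.
#' @return list with `genes` (one row per informative gene: class, number
#'   of supporting significant loci, pooled counts) and `intergenic` (one
#'   row per significant locus outside all gene bodies).
#' @export
aggregate_to_genes <- function(loci, genes) {
  x <- as.data.frame(loci)
  if (!nrow(x)) return(list(genes = data.frame(), intergenic = data.frame()))
  cls <- x$class
  if (!is.null(x$acc_class))
    cls <- ifelse(cls == "biallelic" & x$acc_class != "none", x$acc_class,
                  cls)
  gr_loc <- GenomicRanges::GRanges(
    x$scaffold, IRanges::IRanges(start = x$pos, width = 1L))
  gr_gen <- GenomicRanges::GRanges(
    genes$scaffold, IRanges::IRanges(start = genes$start + 1L,
                                     end = genes$end))
  hits <- GenomicRanges::findOverlaps(gr_loc, gr_gen)
  gene_of <- rep(NA_character_, nrow(x))
  gene_of[S4Vectors::queryHits(hits)] <- genes$gene_id[S4Vectors::subjectHits(hits)]

  inside <- !is.na(gene_of)
  gtab <- data.table::data.table(
    gene_id = gene_of[inside], class = cls[inside],
    mat_AxB = x$mat_AxB[inside], n_AxB = x$n_AxB[inside],
    mat_BxA = x$mat_BxA[inside], n_BxA = x$n_BxA[inside])
  gcall <- gtab[, {
    sig <- class[class != "biallelic"]
    cl <- if (length(sig) == 0L) "biallelic"
    else if (length(unique(sig)) == 1L) sig[1] else "discordant"
    .(class = cl, supporting_loci = max(1L, length(sig)),
      n_loci = .N,
      mat_AxB = sum(mat_AxB), n_AxB = sum(n_AxB),
      mat_BxA = sum(mat_BxA), n_BxA = sum(n_BxA))
  }, by = gene_id]
  gmeta <- genes[match(gcall$gene_id, genes$gene_id),
                 c("scaffold", "start", "end", "strand")]
  gcalls <- cbind(as.data.frame(gcall), gmeta)
  gcalls$location <- "genic"
  rownames(gcalls) <- NULL

  ## significant loci outside gene bodies -> intergenic report
  inter_idx <- which(!inside & cls != "biallelic")
  inter <- data.frame()
  if (length(inter_idx)) {
    rows <- lapply(inter_idx, function(i) {
      same <- genes[genes$scaffold == x$scaffold[i], , drop = FALSE]
      pos0 <- x$pos[i] - 1L
      if (!nrow(same)) {
        return(data.frame(snp_id = x$snp_id[i], scaffold = x$scaffold[i],
                          pos = x$pos[i],
                          class = paste0("intergenic_", cls[i], "_like"),
                          nearest_gene = NA_character_,
                          distance = NA_integer_, side = NA_character_,
                          stringsAsFactors = FALSE))
      }
      d_up <- same$start - pos0         # locus before gene start
      d_dn <- pos0 - same$end + 1L      # locus after gene end
      dist <- pmax(d_up, d_dn)          # one of them is positive outside
      k <- which.min(dist)
      side_abs <- if (d_up[k] > 0) "before" else "after"
      side <- if (same$strand[k] == "+") {
        if (side_abs == "before") "upstream" else "downstream"
      } else {
        if (side_abs == "before") "downstream" else "upstream"
      }
      data.frame(snp_id = x$snp_id[i], scaffold = x$scaffold[i],
                 pos = x$pos[i],
                 class = paste0("intergenic_", cls[i], "_like"),
                 nearest_gene = same$gene_id[k],
                 distance = as.integer(dist[k]), side = side,
                 stringsAsFactors = FALSE)
    })
    inter <- do.call(rbind, rows)
  }
  list(genes = gcalls, intergenic = inter)
}

#' Export log2 maternal-vs-paternal scatter data
#'
#' Per-locus log2 read counts (with a 0.5 pseudo-count) for the classic
#' maternal-versus-paternal scatter of both reciprocal crosses.
#'
#' @param loci data.frame from [classify_loci()].
#' @return data.frame with one row per locus and cross.
#' @export
export_scatter <- function(loci) {
  x <- as.data.frame(loci)
  rbind(
    data.frame(snp_id = x$snp_id, cross = "AxB",
               log2_maternal = log2(x$mat_AxB + 0.5),
               log2_paternal = log2(x$n_AxB - x$mat_AxB + 0.5),
               class = x$class, stringsAsFactors = FALSE),
    data.frame(snp_id = x$snp_id, cross = "BxA",
               log2_maternal = log2(x$mat_BxA + 0.5),
               log2_paternal = log2(x$n_BxA - x$mat_BxA + 0.5),
               class = x$class, stringsAsFactors = FALSE))
}
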