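# Association of imprinting with genomic features: TE proximity enrichment
# (overall and per family), imprinted-gene mini-cluster testing, and the
# shared exact 2x2 machinery.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided P by the probability-mass rule: the sum of
#' hypergeometric probabilities (computed with fixed margins) not exceeding
#' the observed table's probability (no doubling of the one-sided tail).
#' The odds ratio is the cross-product estimate.
#'
#' @param table 2x2 matrix (or length-4 vector, row-wise) of non-negative
#'   counts.
#' @return list with `p_value` and `odds_ratio`. A zero margin gives
#'   `p_value = 1`.
#' @export
fisher_exact_2x2 <- function(table) {
  x <- as.vector(t(as.matrix(table)))
  if (length(x) != 4L || any(is.na(x)) || any(x < 0))
    stop("table must be a 2x2 of non-negative counts")
  a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
  m <- a + b; n2 <- cc + d; k <- a + cc; N <- m + n2
  or <- (a * d) / (b * cc)
  if (m == 0 || n2 == 0 || k == 0 || k == N)
    return(list(p_value = 1, odds_ratio = or))
  lo <- max(0, k - n2); hi <- min(k, m)
  supp <- lo:hi
  lp <- lchoose(m, supp) + lchoose(n2, k - supp) - lchoose(N, k)
  p_obs <- exp(lp[supp == a])
  # relative tolerance absorbs floating-point ties in the mass comparison
  p <- sum(exp(lp)[exp(lp) <= p_obs * (1 + 1e-7)])
  list(p_value = min(p, 1), odds_ratio = or)
}

#' TE presence and family counts in gene flanks
#'
#' A TE counts for a gene iff it overlaps the gene body extended by
#' `flank` bp on each side (0-based half-open intervals; a TE ending
#' exactly at the window start does not overlap). Setting
#' `include_body = FALSE` restricts to the flanks proper.
#'
#' @param genes gene models (`gene_id`, `scaffold`, `start`, `end`).
#' @param tes TE annotations (`scaffold`, `start`, `end`, `family`).
#' @param flank flank size in bp.
#' @param include_body count TEs overlapping only the gene body as well.
#' @return list with `per_gene` (gene_id, `n_te`, `presence`) and
#'   `per_family` (long table gene_id x family counts).
#' @export
te_flank_presence <- function(genes, tes, flank = 4000L,
                              include_body = TRUE) {
  per_gene <- data.frame(gene_id = genes$gene_id, n_te = 0L,
                         presence = FALSE, stringsAsFactors = FALSE)
  empty_fam <- data.frame(gene_id = character(0), family = character(0),
                          count = integer(0), stringsAsFactors = FALSE)
  if (nrow(tes) == 0L || nrow(genes) == 0L)
    return(list(per_gene = per_gene, per_family = empty_fam))
  win_start <- pmax(genes$start - flank, 0L)
  win_end <- genes$end + flank
  gr_g <- GenomicRanges::GRanges(
    genes$scaffold, IRanges::IRanges(start = win_start + 1L, end = win_end))
  gr_t <- GenomicRanges::GRanges(
    tes$scaffold, IRanges::IRanges(start = tes$start + 1L, end = tes$end))
  h <- GenomicRanges::findOverlaps(gr_g, gr_t)
  gi <- S4Vectors::queryHits(h); ti <- S4Vectors::subjectHits(h)
  if (!include_body && length(gi)) {
    # drop TEs entirely inside the gene body
    inside <- tes$start[ti] >= genes$start[gi] & tes$end[ti] <= genes$end[gi]
    gi <- gi[!inside]; ti <- ti[!inside]
  }
  if (!length(gi))
    return(list(per_gene = per_gene, per_family = empty_fam))
  tab <- table(factor(gi, levels = seq_len(nrow(genes))))
  per_gene$n_te <- as.integer(tab)
  per_gene$presence <- per_gene$n_te > 0L
  fam <- data.table::data.table(gene_id = genes$gene_id[gi],
                                family = tes$family[ti])
  per_family <- as.data.frame(fam[, .(count = .N), by = .(gene_id, family)])
  list(per_gene = per_gene, per_family = per_family)
}

#' TE enrichment around imprinted genes
#'
#' Compares TE presence within `flank` bp of imprinted genes against a
#' background of non-imprinted informative genes: one overall
#' presence/absence Fisher test plus one per TE family, with raw and
#' BH-adjusted P-values.
#'
#' @param imprinted_ids,background_ids disjoint gene-id sets (background =
#'   non-imprinted genes informative in both crosses).
#' @param genes gene models covering both sets.
#' @param tes TE annotations.
#' @param flank flank size in bp.
#' @param per_family also test each family separately.
#' @return data.frame of enrichment results: `contrast`, the 2x2 counts
#'   (`imp_with`, `imp_without`, `bg_with`, `bg_without`), `p_value`,
#'   `odds_ratio`, `p_adj` (BH over the family tests).
#' @export
te_enrichment <- function(imprinted_ids, background_ids, genes, tes,
                          flank = 4000L, per_family = TRUE) {
  empty <- data.frame(contrast = character(0), imp_with = integer(0),
                      imp_without = integer(0), bg_with = integer(0),
                      bg_without = integer(0), p_value = numeric(0),
                      odds_ratio = numeric(0), p_adj = numeric(0),
                      stringsAsFactors = FALSE)
  imprinted_ids <- unique(imprinted_ids)
  background_ids <- setdiff(unique(background_ids), imprinted_ids)
  if (!length(imprinted_ids)) return(empty)
  use <- genes[genes$gene_id %in% c(imprinted_ids, background_ids), ,
               drop = FALSE]
  pres <- te_flank_presence(use, tes, flank = flank)
  is_imp <- pres$per_gene$gene_id %in% imprinted_ids
  one_test <- function(with_gene_ids, contrast) {
    w <- pres$per_gene$gene_id %in% with_gene_ids
    tab <- c(sum(is_imp & w), sum(is_imp & !w),
             sum(!is_imp & w), sum(!is_imp & !w))
    ft <- fisher_exact_2x2(tab)
    data.frame(contrast = contrast, imp_with = tab[1], imp_without = tab[2],
               bg_with = tab[3], bg_without = tab[4], p_value = ft$p_value,
               odds_ratio = ft$odds_ratio, stringsAsFactors = FALSE)
  }
  res <- one_test(pres$per_gene$gene_id[pres$per_gene$presence], "any_TE")
  if (per_family && nrow(pres$per_family)) {
    fams <- sort(unique(pres$per_family$family))
    fam_res <- do.call(rbind, lapply(fams, function(f) {
      ids <- pres$per_family$gene_id[pres$per_family$family == f]
      one_test(ids, f)
    }))
    fam_res$p_adj <- stats::p.adjust(fam_res$p_value, method = "BH")
    res$p_adj <- NA_real_
    res <- rbind(res, fam_res)
  } else {
    res$p_adj <- NA_real_
  }
  rownames(res) <- NULL
  res
}

# run a block of code under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Permutation test for clustering of imprinted genes
#'
#' Statistic: mean genomic distance (midpoint to midpoint) between
#' consecutive imprinted genes along each scaffold. The null distribution
#' draws the same number of genes uniformly without replacement from the
#' informative gene set `n_perm` times;
#' `P = (1 + #\{null <= observed\}) / (n_perm + 1)`. Also reports
#' mini-clusters: runs of two or more imprinted genes with no intervening
#' informative gene.
#'
#' @param imprinted_ids imprinted gene ids.
#' @param genes informative gene models (`gene_id`, `scaffold`, `start`,
#'   `end`).
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed (required for reproducibility).
#' @return list with `observed` (mean consecutive distance), `p_value`,
#'   `n_pairs`, `mini_clusters` (data.frame of runs), `null` (permutation
#'   statistics).
#' @export
cluster_test <- function(imprinted_ids, genes, n_perm = 1000L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  g <- genes[order(genes$scaffold, genes$start), , drop = FALSE]
  g$mid <- (g$start + g$end) / 2
  is_imp <- g$gene_id %in% imprinted_ids
  stat <- function(flag) {
    d <- unlist(lapply(split(seq_len(nrow(g)), g$scaffold), function(ii) {
      mm <- g$mid[ii][flag[ii]]
      if (length(mm) >= 2L) diff(sort(mm)) else numeric(0)
    }), use.names = FALSE)
    if (!length(d)) return(NA_real_)
    mean(d)
  }
  obs <- stat(is_imp)
  if (is.na(obs))
    stop("fewer than two imprinted genes on every scaffold: ",
         "statistic undefined")
  n_imp <- sum(is_imp)
  null <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      flag <- logical(nrow(g))
      flag[sample.int(nrow(g), n_imp)] <- TRUE
      stat(flag)
    }, numeric(1))
  })
  p <- (1 + sum(null <= obs, na.rm = TRUE)) / (n_perm + 1)

  # maximal runs of adjacent imprinted genes in the informative gene order
  runs <- list()
  for (sc in unique(g$scaffold)) {
    ii <- which(g$scaffold == sc)
    r <- rle(is_imp[ii])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= 2L)) {
      sel <- ii[starts[j]:ends[j]]
      runs[[length(runs) + 1L]] <- data.frame(
        scaffold = sc, n_genes = length(sel),
        gene_ids = paste(g$gene_id[sel], collapse = ","),
        start = min(g$start[sel]), end = max(g$end[sel]),
        stringsAsFactors = FALSE)
    }
  }
  mini <- if (length(runs)) do.call(rbind, runs) else
    data.frame(scaffold = character(0), n_genes = integer(0),
               gene_ids = character(0), start = integer(0),
               end = integer(0), stringsAsFactors = FALSE)
  list(observed = obs, p_value = p, n_pairs = sum(is_imp),
       mini_clusters = mini, null = null)
}
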