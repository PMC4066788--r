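# CpG methylome analysis: bisulfite-aware read placement, per-cytosine
# methylation calls, metagene profiles, endosperm-vs-embryo DMR
# segmentation under five criteria, and allele-specific DMRs under the
# 40% / 70% rule.

#' Map bisulfite reads to a genome
#'
#' Bisulfite-aware ungapped placement: a read T opposite a genomic C
#' (forward sense) or a read A opposite a genomic G (reverse-complement
#' sense) does not count as a mismatch, so fully converted reads from
#' unmethylated regions place with zero mismatches. Reads whose best
#' placement is not unique are removed when `unique_only` is set.
#'
#' @param reads data.frame with `id`, `seq`.
#' @param genome named character vector of scaffolds.
#' @param max_mismatch maximum (conversion-aware) mismatches.
#' @param unique_only drop multi-mapping reads.
#' @return placements data.frame (`read_id`, `scaffold`, `pos0`, `strand`,
#'   `mismatches`).
#' @export
map_bisulfite_reads <- function(reads, genome, max_mismatch = 2L,
                                unique_only = TRUE) {
  place_reads(reads, genome, max_mismatch = max_mismatch,
              unique_only = unique_only, mode = "bisulfite")
}

# genome-space base matrix for placed reads (rows follow `placements`)
.placed_base_matrix <- function(placements, reads) {
  ri <- match(placements$read_id, reads$id)
  rmat <- reads_to_int_matrix(reads$seq)
  L <- ncol(rmat)
  bmat <- rmat[ri, , drop = FALSE]
  neg <- placements$strand == "-"
  if (any(neg)) {
    flip <- .INT_COMP[bmat[neg, rev(seq_len(L)), drop = FALSE] + 1L]
    dim(flip) <- c(sum(neg), L)
    bmat[neg, ] <- flip
  }
  bmat
}

#' Call per-cytosine methylation from placed bisulfite reads
#'
#' For each genomic cytosine on the strand a read derives from, a read base
#' C increments the methylated count and T the unmethylated count (other
#' bases are ignored). Context is determined from the reference; only
#' CpG-context cytosines are reported unless `cpg_only = FALSE`. Symmetric
#' CpG strand merging (summing the minus-strand call into its plus-strand
#' partner) is off by default.
#'
#' @param placements from [map_bisulfite_reads()].
#' @param reads the reads data.frame the placements refer to.
#' @param genome named character vector of scaffolds.
#' @param cpg_only report CpG-context cytosines only.
#' @param merge_strands merge symmetric CpG calls onto the plus strand.
#' @return data.frame: `scaffold`, `pos` (1-based), `strand`, `context`,
#'   `c_count`, `t_count`, `level`.
#' @export
call_cytosines <- function(placements, reads, genome, cpg_only = TRUE,
                           merge_strands = FALSE) {
  empty <- data.frame(scaffold = character(0), pos = integer(0),
                      strand = character(0), context = character(0),
                      c_count = integer(0), t_count = integer(0),
                      level = numeric(0), stringsAsFactors = FALSE)
  if (is.null(placements) || nrow(placements) == 0L) return(empty)
  bmat <- .placed_base_matrix(placements, reads)
  L <- ncol(bmat)
  n <- nrow(placements)
  dt <- data.table::data.table(
    scaffold = rep(placements$scaffold, L),
    pos = rep(placements$pos0, L) + rep(seq_len(L), each = n),
    sense = rep(placements$strand, L),
    base = as.vector(bmat))
  ref_int <- lapply(genome, function(s) c(0L, seq_to_int(s), 0L))  # padded
  dt[, ref := 0L]
  dt[, nxt := 0L]
  dt[, prv := 0L]
  for (s in unique(dt$scaffold)) {
    sel <- which(dt$scaffold == s)
    rp <- ref_int[[s]]
    data.table::set(dt, sel, "ref", rp[dt$pos[sel] + 1L])
    data.table::set(dt, sel, "nxt", rp[dt$pos[sel] + 2L])
    data.table::set(dt, sel, "prv", rp[dt$pos[sel]])
  }
  plus <- dt[sense == "+" & ref == 2L,
             .(scaffold, pos, strand = "+",
               cpg = nxt == 3L, c_obs = base == 2L, t_obs = base == 4L)]
  minus <- dt[sense == "-" & ref == 3L,
              .(scaffold, pos, strand = "-",
                cpg = prv == 2L, c_obs = base == 3L, t_obs = base == 1L)]
  obs <- rbind(plus, minus)
  if (nrow(obs) == 0L) return(empty)
  agg <- obs[, .(context = ifelse(cpg[1], "CpG", "CpH"),
                 c_count = sum(c_obs), t_count = sum(t_obs)),
             by = .(scaffold, pos, strand)]
  if (cpg_only) agg <- agg[context == "CpG"]
  if (merge_strands) {
    agg[strand == "-", pos := pos - 1L]
    agg <- agg[, .(context = context[1], c_count = sum(c_count),
                   t_count = sum(t_count)),
               by = .(scaffold, pos)][, strand := "+"]
  }
  agg <- agg[c_count + t_count > 0L]
  agg[, level := c_count / (c_count + t_count)]
  data.table::setorder(agg, scaffold, pos, strand)
  out <- as.data.frame(agg[, .(scaffold, pos, strand, context, c_count,
                               t_count, level)])
  out
}

#' Metagene methylation profile
#'
#' Averages per-cytosine methylation levels in fixed-width bins around the
#' 5' or 3' end of a feature set (genes or TEs), strand-oriented: bins
#' cover the `flank` outside the anchor and the proximal feature body. The
#' per-bin value is the unweighted mean of per-cytosine levels within each
#' feature, averaged over features with data in the bin.
#'
#' @param calls cytosine calls from [call_cytosines()].
#' @param features data.frame: `scaffold`, `start`, `end` (0-based
#'   half-open), `strand`.
#' @param flank flank size (bp).
#' @param bin bin width (bp).
#' @param anchor `"five_prime"` or `"three_prime"`.
#' @return data.frame per bin: `rel_start`, `rel_end` (bp relative to the
#'   anchor, 5'->3' axis), `mean_level`, `n_features`.
#' @export
metagene_profile <- function(calls, features, flank = 2000L, bin = 200L,
                             anchor = c("five_prime", "three_prime")) {
  anchor <- match.arg(anchor)
  ca <- data.table::as.data.table(calls)
  nb <- flank %/% bin
  bins <- data.frame(rel_start = seq(-nb, nb - 1L) * bin,
                     rel_end = seq(-nb + 1L, nb) * bin)
  acc <- matrix(NA_real_, nrow(features), nrow(bins))
  for (f in seq_len(nrow(features))) {
    ft <- features[f, ]
    len <- ft$end - ft$start
    sub <- ca[scaffold == ft$scaffold & pos > ft$start - flank &
                pos <= ft$end + flank]
    if (nrow(sub) == 0L) next
    pos0 <- sub$pos - 1L
    along <- if (ft$strand == "+") pos0 - ft$start else (ft$end - 1L) - pos0
    rel <- if (anchor == "five_prime") along else along - (len - 1L)
    # flank window around the anchor, not running past the far feature end
    keep <- rel >= -flank & rel < flank &
      (if (anchor == "five_prime") along < len else along >= 0L)
    if (!any(keep)) next
    bi <- (rel[keep] %/% bin) + nb + 1L
    lv <- sub$level[keep]
    m <- tapply(lv, bi, mean)
    acc[f, as.integer(names(m))] <- m
  }
  bins$mean_level <- colMeans(acc, na.rm = TRUE)
  bins$mean_level[is.nan(bins$mean_level)] <- NA_real_
  bins$n_features <- colSums(!is.na(acc))
  bins
}

#' Call differentially methylated regions between two samples
#'
#' Seed-and-chain segmentation under five criteria: (1) only CpGs with more
#' than `min_reads` coverage in both samples are considered; (2) sites with
#' a per-site level difference of at least `min_diff` seed segments;
#' (3) consecutive seeds closer than `max_gap` bp are chained -- an
#' intervening covered CpG that fails the difference criterion breaks the
#' chain, so sporadic noise sites cannot glue unrelated regions together;
#' (4) a chained segment is kept iff its span exceeds `min_len` bp, it
#' contains more than `min_meth_sites` methylated CpGs in at least one
#' sample, and its mean level difference is at least `min_diff`; and (5) a
#' Pearson chi-squared test (2x2 on summed methylated/unmethylated counts,
#' no continuity correction) gives P at or below `alpha`.
#'
#' @param calls_a,calls_b cytosine calls for the two samples (e.g.
#'   endosperm and embryo) on the same reference.
#' @param min_meth_sites,min_reads,min_len,max_gap,min_diff,alpha the five
#'   criteria's parameters.
#' @return data.frame of segments: `scaffold`, `start`, `end` (0-based
#'   half-open), `length`, `n_sites`, `meth_a`, `meth_b`,
#'   `diff` (= `meth_a - meth_b`), `chi2_p`.
#' @export
call_dmrs <- function(calls_a, calls_b, min_meth_sites = 5L,
                      min_reads = 10L, min_len = 40L, max_gap = 200L,
                      min_diff = 0.5, alpha = 0.05) {
  a <- data.table::as.data.table(calls_a)
  b <- data.table::as.data.table(calls_b)
  m <- merge(a[, .(scaffold, pos, strand, c_a = c_count, t_a = t_count)],
             b[, .(scaffold, pos, strand, c_b = c_count, t_b = t_count)],
             by = c("scaffold", "pos", "strand"))
  empty <- data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      n_sites = integer(0), meth_a = numeric(0),
                      meth_b = numeric(0), diff = numeric(0),
                      chi2_p = numeric(0), stringsAsFactors = FALSE)
  if (nrow(m) == 0L) return(empty)
  m <- m[c_a + t_a > min_reads & c_b + t_b > min_reads]
  m[, lev_a := c_a / (c_a + t_a)]
  m[, lev_b := c_b / (c_b + t_b)]
  if (nrow(m) == 0L) return(empty)
  data.table::setorder(m, scaffold, pos)
  # a segment is a maximal run of *consecutive* covered CpGs that each
  # pass the per-site difference criterion and sit < max_gap apart; an
  # intervening covered non-differential site breaks the run, so segment
  # statistics cover every covered CpG inside the reported span
  seed <- abs(m$lev_a - m$lev_b) >= min_diff
  if (!any(seed)) return(empty)
  n <- nrow(m)
  brk <- c(TRUE, m$scaffold[-1L] != m$scaffold[-n] |
             diff(m$pos) >= max_gap | !seed[-n])
  m[, grp := cumsum(brk)]
  seg <- m[seed, .(scaffold = scaffold[1], start = min(pos) - 1L,
                   end = max(pos), n_sites = .N,
                   meth_a = mean(lev_a), meth_b = mean(lev_b),
                   n_meth_a = sum(c_a >= 1L), n_meth_b = sum(c_b >= 1L),
                   sc_a = sum(c_a), st_a = sum(t_a),
                   sc_b = sum(c_b), st_b = sum(t_b)), by = grp]
  seg[, length := end - start]
  seg <- seg[length > min_len &
               (n_meth_a > min_meth_sites | n_meth_b > min_meth_sites) &
               abs(meth_a - meth_b) >= min_diff]
  if (nrow(seg) == 0L) return(empty)
  seg[, chi2_p := vapply(seq_len(.N), function(i) {
    tab <- matrix(c(sc_a[i], st_a[i], sc_b[i], st_b[i]), nrow = 2,
                  byrow = TRUE)
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }, numeric(1))]
  seg <- seg[chi2_p <= alpha]
  if (nrow(seg) == 0L) return(empty)
  seg[, diff := meth_a - meth_b]
  as.data.frame(seg[, .(scaffold, start, end, length, n_sites, meth_a,
                        meth_b, diff, chi2_p)])
}

#' Re-audit reported DMR segments against all five criteria
#'
#' Independently re-checks every segment of a [call_dmrs()] result from the
#' raw cytosine calls. Used by [validate_outputs()] and in tests.
#'
#' @inheritParams call_dmrs
#' @param dmrs segment table from [call_dmrs()].
#' @return data.frame with one row per segment and logical columns for each
#'   criterion plus `ok` (all criteria hold).
#' @export
audit_dmrs <- function(dmrs, calls_a, calls_b, min_meth_sites = 5L,
                       min_reads = 10L, min_len = 40L, max_gap = 200L,
                       min_diff = 0.5, alpha = 0.05) {
  if (nrow(dmrs) == 0L)
    return(data.frame(ok = logical(0)))
  a <- data.table::as.data.table(calls_a)
  b <- data.table::as.data.table(calls_b)
  m <- merge(a[, .(scaffold, pos, strand, c_a = c_count, t_a = t_count)],
             b[, .(scaffold, pos, strand, c_b = c_count, t_b = t_count)],
             by = c("scaffold", "pos", "strand"))
  m <- m[c_a + t_a > min_reads & c_b + t_b > min_reads]
  m[, lev_a := c_a / (c_a + t_a)]
  m[, lev_b := c_b / (c_b + t_b)]
  res <- lapply(seq_len(nrow(dmrs)), function(i) {
    d <- dmrs[i, ]
    s <- m[scaffold == d$scaffold & pos > d$start & pos <= d$end]
    seed <- s[abs(lev_a - lev_b) >= min_diff]
    data.table::setorder(seed, pos)
    len_ok <- (d$end - d$start) > min_len && d$length == d$end - d$start
    gap_ok <- nrow(seed) > 0L &&
      (nrow(seed) == 1L || max(diff(seed$pos)) < max_gap)
    meth_ok <- nrow(s) > 0L &&
      (sum(s$c_a >= 1L) > min_meth_sites || sum(s$c_b >= 1L) > min_meth_sites)
    diff_ok <- nrow(s) > 0L &&
      abs(mean(s$lev_a) - mean(s$lev_b)) >= min_diff
    chi_ok <- if (nrow(s) == 0L) FALSE else {
      tab <- matrix(c(sum(s$c_a), sum(s$t_a), sum(s$c_b), sum(s$t_b)),
                    nrow = 2, byrow = TRUE)
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value) <=
        alpha
    }
    data.frame(segment = i, len_ok = len_ok, gap_ok = gap_ok,
               meth_sites_ok = meth_ok, mean_diff_ok = diff_ok,
               chi2_ok = chi_ok,
               ok = len_ok && gap_ok && meth_ok && diff_ok && chi_ok)
  })
  do.call(rbind, res)
}

#' Link DMRs to genes within a flank
#'
#' A DMR is linked to a gene iff it overlaps the gene body extended by
#' `flank` bp on both sides; the link is labelled upstream / gene_body /
#' downstream by the strand-oriented position of the DMR midpoint.
#'
#' @param dmrs segment table from [call_dmrs()].
#' @param genes gene models (`gene_id`, `scaffold`, `start`, `end`,
#'   `strand`).
#' @param flank linking distance in bp.
#' @return data.frame: one row per (DMR, gene) link with a `region` label.
#' @export
dmr_gene_overlap <- function(dmrs, genes, flank = 2000L) {
  empty <- data.frame(dmr = integer(0), gene_id = character(0),
                      scaffold = character(0), start = integer(0),
                      end = integer(0), region = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(dmrs) == 0L || nrow(genes) == 0L) return(empty)
  gr_d <- GenomicRanges::GRanges(
    dmrs$scaffold, IRanges::IRanges(start = dmrs$start + 1L, end = dmrs$end))
  gr_g <- GenomicRanges::GRanges(
    genes$scaffold,
    IRanges::IRanges(start = pmax(genes$start - flank, 0L) + 1L,
                     end = genes$end + flank))
  h <- GenomicRanges::findOverlaps(gr_d, gr_g)
  if (length(h) == 0L) return(empty)
  di <- S4Vectors::queryHits(h); gi <- S4Vectors::subjectHits(h)
  mid <- (dmrs$start[di] + dmrs$end[di]) %/% 2L
  before <- mid < genes$start[gi]
  after <- mid >= genes$end[gi]
  plus <- genes$strand[gi] == "+"
  region <- ifelse(!before & !after, "gene_body",
                   ifelse(before == plus, "upstream", "downstream"))
  data.frame(dmr = di, gene_id = genes$gene_id[gi],
             scaffold = dmrs$scaffold[di], start = dmrs$start[di],
             end = dmrs$end[di], region = region, stringsAsFactors = FALSE)
}

#' Genes with an endosperm-hypomethylated DMR nearby
#'
#' Convenience selector: gene ids linked (via [dmr_gene_overlap()]) to a
#' DMR where sample A (endosperm) is the hypomethylated one
#' (`diff = meth_a - meth_b < 0`).
#'
#' @inheritParams dmr_gene_overlap
#' @return character vector of gene ids.
#' @export
hypomethylated_genes <- function(dmrs, genes, flank = 2000L) {
  if (nrow(dmrs) == 0L) return(character(0))
  hypo <- dmrs[dmrs$diff < 0, , drop = FALSE]
  unique(dmr_gene_overlap(hypo, genes, flank)$gene_id)
}

#' Split bisulfite placements by parent of origin
#'
#' Labels each placed read `maternal`, `paternal` or `unknown` from the
#' read bases at the SNPs it covers, with bisulfite-aware allele matching:
#' on the forward sense a read T also matches a C allele, on the reverse
#' sense a read A also matches a G allele; a read matching both alleles at
#' a SNP, or different lines at different SNPs, stays `unknown`.
#'
#' @param placements from [map_bisulfite_reads()].
#' @param reads the reads data.frame.
#' @param snps SNP table (`scaffold`, `pos`, `allele_p1`, `allele_p2`).
#' @param cross cross direction of the sample (`"AxB"`: parent1 is the
#'   mother).
#' @return `placements` with an added `parent` column.
#' @export
split_bisulfite_by_parent <- function(placements, reads, snps,
                                      cross = "AxB") {
  if (!cross %in% c("AxB", "BxA")) stop("unknown cross direction: ", cross)
  mother <- if (cross == "AxB") "parent1" else "parent2"
  placements$parent <- "unknown"
  if (nrow(placements) == 0L || nrow(snps) == 0L) return(placements)
  bmat <- .placed_base_matrix(placements, reads)
  L <- ncol(bmat)
  pl <- data.table::data.table(idx = seq_len(nrow(placements)),
                               scaffold = placements$scaffold,
                               pos0 = placements$pos0,
                               sense = placements$strand)
  sn <- data.table::data.table(scaffold = snps$scaffold, spos = snps$pos,
                               a1 = snps$allele_p1, a2 = snps$allele_p2)
  pl[, start := pos0 + 1L][, end := pos0 + L]
  hits <- sn[pl, on = .(scaffold, spos >= start, spos <= end), nomatch = NULL,
             .(idx, scaffold, spos = x.spos, a1, a2, pos0, sense)]
  if (nrow(hits) == 0L) return(placements)
  b <- c("N", "A", "C", "G", "T")[
    bmat[cbind(hits$idx, hits$spos - hits$pos0)] + 1L]
  match_allele <- function(base, allele, sense) {
    base == allele |
      (sense == "+" & allele == "C" & base == "T") |
      (sense == "-" & allele == "G" & base == "A")
  }
  m1 <- match_allele(b, hits$a1, hits$sense)
  m2 <- match_allele(b, hits$a2, hits$sense)
  hits[, line := ifelse(m1 & !m2, "parent1",
                        ifelse(m2 & !m1, "parent2", NA_character_))]
  vote <- hits[!is.na(line),
               .(n_lines = data.table::uniqueN(line), line = line[1]),
               by = idx]
  vote <- vote[n_lines == 1L]
  placements$parent[vote$idx] <- ifelse(vote$line == mother, "maternal",
                                        "paternal")
  placements
}

#' Call allele-specific DMRs around imprinted genes
#'
#' Slides `window`-bp windows (step `step`) over each gene body plus
#' `flank` bp either side and compares maternal vs paternal CpG
#' methylation. A window qualifies iff each allele has at least
#' `min_informative` informative (covered) methylcytosines and more than
#' `min_reads` mean read depth, and one allele's percent methylation is
#' below `low_pct` while the other's is above `high_pct`. Overlapping
#' qualifying windows are merged into maximal runs and re-summarised;
#' merged regions are reported in both scaffold-absolute and gene-relative
#' (TSS = 0, upstream negative) coordinates.
#'
#' @param calls_mat,calls_pat allele-resolved cytosine calls (from
#'   [call_cytosines()] on maternal / paternal read subsets).
#' @param genes gene models for the genes of interest.
#' @param window,step window geometry in bp.
#' @param min_informative minimum covered methylcytosines per allele.
#' @param min_reads minimum mean per-site depth per allele (strictly
#'   greater than).
#' @param low_pct,high_pct the percent thresholds (one allele `<
#'   low_pct`, the other `> high_pct`).
#' @param flank region examined either side of the gene body.
#' @return data.frame: `gene_id`, `region` (upstream / gene_body /
#'   downstream by midpoint), `start`, `end`, `rel_start`, `rel_end`,
#'   `length`, `meth_maternal_pct`, `meth_paternal_pct`, `n_informative`.
#' @export
call_allele_dmrs <- function(calls_mat, calls_pat, genes, window = 200L,
                             step = 100L, min_informative = 5L,
                             min_reads = 5L, low_pct = 40, high_pct = 70,
                             flank = 2000L) {
  cm <- data.table::as.data.table(calls_mat)
  cp <- data.table::as.data.table(calls_pat)
  out <- list()
  for (g in seq_len(nrow(genes))) {
    gn <- genes[g, ]
    lo <- max(gn$start - flank, 0L)
    hi <- gn$end + flank
    sm <- cm[scaffold == gn$scaffold & pos > lo & pos <= hi]
    sp <- cp[scaffold == gn$scaffold & pos > lo & pos <= hi]
    if (nrow(sm) == 0L || nrow(sp) == 0L) next
    starts <- seq(lo, hi - window, by = step)
    wstat <- function(calls, w0) {
      s <- calls[pos > w0 & pos <= w0 + window]
      s <- s[c_count + t_count > 0L]
      if (nrow(s) == 0L)
        return(c(n = 0, depth = 0, pct = NA_real_))
      c(n = nrow(s), depth = mean(s$c_count + s$t_count),
        pct = 100 * sum(s$c_count) / sum(s$c_count + s$t_count))
    }
    qual <- logical(length(starts))
    for (i in seq_along(starts)) {
      a <- wstat(sm, starts[i]); b <- wstat(sp, starts[i])
      qual[i] <- a["n"] >= min_informative && b["n"] >= min_informative &&
        a["depth"] > min_reads && b["depth"] > min_reads &&
        min(a["pct"], b["pct"]) < low_pct &&
        max(a["pct"], b["pct"]) > high_pct
    }
    if (!any(qual)) next
    runs <- rle(qual)
    ends_i <- cumsum(runs$lengths)
    starts_i <- ends_i - runs$lengths + 1L
    for (r in which(runs$values)) {
      r0 <- starts[starts_i[r]]
      r1 <- starts[ends_i[r]] + window
      a <- { s <- sm[pos > r0 & pos <= r1 & c_count + t_count > 0L]
             c(n = nrow(s), pct = if (nrow(s)) 100 * sum(s$c_count) /
                 sum(s$c_count + s$t_count) else NA_real_) }
      b <- { s <- sp[pos > r0 & pos <= r1 & c_count + t_count > 0L]
             c(n = nrow(s), pct = if (nrow(s)) 100 * sum(s$c_count) /
                 sum(s$c_count + s$t_count) else NA_real_) }
      if (!(min(a["pct"], b["pct"]) < low_pct &&
            max(a["pct"], b["pct"]) > high_pct)) next
      mid <- (r0 + r1) %/% 2L
      before <- mid < gn$start; after <- mid >= gn$end
      region <- if (!before && !after) "gene_body"
      else if ((gn$strand == "+") == before) "upstream" else "downstream"
      if (gn$strand == "+") {
        rel_start <- r0 - gn$start; rel_end <- r1 - gn$start
      } else {
        rel_start <- gn$end - r1; rel_end <- gn$end - r0
      }
      out[[length(out) + 1L]] <- data.frame(
        gene_id = gn$gene_id, region = region, start = r0, end = r1,
        rel_start = rel_start, rel_end = rel_end, length = r1 - r0,
        meth_maternal_pct = unname(a["pct"]),
        meth_paternal_pct = unname(b["pct"]),
        n_informative = as.integer(min(a["n"], b["n"])),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(0), region = character(0),
                      start = integer(0), end = integer(0),
                      rel_start = integer(0), rel_end = integer(0),
                      length = integer(0), meth_maternal_pct = numeric(0),
                      meth_paternal_pct = numeric(0),
                      n_informative = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Test association between imprinting and endosperm hypomethylation
#'
#' Two-sided Fisher exact test on the 2x2 table {imprinted, not-imprinted}
#' x {has an endosperm-hypomethylated DMR within gene body +/- 2 kb, has
#' none}, over a shared universe of informative genes.
#'
#' @param imprinted_genes character vector of imprinted gene ids.
#' @param informative_genes the gene universe (ids).
#' @param hypo_genes gene ids with an endosperm-hypo DMR (e.g. from
#'   [hypomethylated_genes()]).
#' @return list with `table` (2x2 matrix), `p_value`, `odds_ratio`.
#' @export
hypomethylation_association <- function(imprinted_genes, informative_genes,
                                        hypo_genes) {
  uni <- unique(informative_genes)
  imp <- intersect(unique(imprinted_genes), uni)
  hyp <- intersect(unique(hypo_genes), uni)
  a <- length(intersect(imp, hyp))
  b <- length(setdiff(imp, hyp))
  cc <- length(setdiff(hyp, imp))
  d <- length(uni) - a - b - cc
  tab <- matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("imprinted", "not_imprinted"),
                                c("hypo_dmr", "no_hypo_dmr")))
  ft <- fisher_exact_2x2(tab)
  list(table = tab, p_value = ft$p_value, odds_ratio = ft$odds_ratio)
}

#' Write cytosine calls as bedGraph-like TSV
#' @param calls from [call_cytosines()].
#' @param path output path.
#' @export
write_cytosines_bedgraph <- function(calls, path) {
  out <- data.frame(scaffold = calls$scaffold, start = calls$pos - 1L,
                    end = calls$pos, level = calls$level,
                    c_count = calls$c_count, t_count = calls$t_count,
                    strand = calls$strand)
  write_tsv_file(out, path)
}

#' Write DMR segments as BED6 plus extended columns
#' @param dmrs from [call_dmrs()].
#' @param path output path.
#' @export
write_dmrs_bed <- function(dmrs, path) {
  out <- data.frame(scaffold = dmrs$scaffold, start = dmrs$start,
                    end = dmrs$end,
                    name = sprintf("dmr_%04d", seq_len(nrow(dmrs))),
                    score = rep(0L, nrow(dmrs)),
                    strand = rep(".", nrow(dmrs)), meth_a = dmrs$meth_a,
                    meth_b = dmrs$meth_b, diff = dmrs$diff,
                    chi2_p = dmrs$chi2_p, n_sites = dmrs$n_sites)
  write_tsv_file(out, path)
}

#' Write allele-specific DMRs as TSV
#'
#' Columns mirror the field's summary-table convention: the printed length
#' always equals `end - start` in both coordinate frames.
#'
#' @param adm from [call_allele_dmrs()].
#' @param path output path.
#' @export
write_allele_dmrs <- function(adm, path) {
  out <- data.frame(gene = adm$gene_id,
                    type = rep("MEG_assoc", nrow(adm)),
                    start = adm$rel_start, end = adm$rel_end,
                    length = adm$length,
                    abs_start = adm$start, abs_end = adm$end,
                    meth_paternal_pct = adm$meth_paternal_pct,
                    meth_maternal_pct = adm$meth_maternal_pct,
                    region = adm$region)
  write_tsv_file(out, path)
}
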