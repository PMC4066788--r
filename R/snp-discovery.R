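# SNP discovery between the two parental lines from per-site pileup
# summaries. Four filters gate a call: per-base quality, minimum coverage,
# exclusion of bases near read ends, and homozygosity of each parent.

#' Build per-site pileup summaries from placed parental reads
#'
#' Tallies per-parent base counts at every candidate site (any position
#' where a placed read base disagrees with the reference). Bases with
#' quality at or below `min_quality`, and bases within `end_margin` bp of
#' either end of their read, are excluded from the A/C/G/T counts and
#' reported separately.
#'
#' @param placements_p1,placements_p2 placements from [place_reads()] for
#'   each parental read set.
#' @param reads_p1,reads_p2 the corresponding reads data.frames.
#' @param genome named character vector (reference scaffolds).
#' @param min_quality Phred threshold; only bases with Q > `min_quality`
#'   are counted.
#' @param end_margin bases within this distance of a read end are ignored.
#' @return data.frame with one row per (site, parent): `scaffold`, `pos`
#'   (1-based), `parent`, `nA`, `nC`, `nG`, `nT`, `n_lowq`, `n_margin`.
#' @export
build_pileups <- function(placements_p1, reads_p1, placements_p2, reads_p2,
                          genome, min_quality = 20L, end_margin = 5L) {
  ref_int <- lapply(genome, seq_to_int)
  obs <- list()
  for (p in 1:2) {
    pl <- if (p == 1) placements_p1 else placements_p2
    rd <- if (p == 1) reads_p1 else reads_p2
    if (is.null(pl) || nrow(pl) == 0L) next
    ri <- match(pl$read_id, rd$id)
    rmat <- reads_to_int_matrix(rd$seq)
    qmat <- matrix(utf8ToInt(paste(rd$qual, collapse = "")) - 33L,
                   nrow = nrow(rd), byrow = TRUE)
    L <- ncol(rmat)
    neg <- pl$strand == "-"
    n <- nrow(pl)
    # genome-space base/quality matrices for the placed reads
    bmat <- rmat[ri, , drop = FALSE]
    qm <- qmat[ri, , drop = FALSE]
    if (any(neg)) {
      bmat[neg, ] <- .INT_COMP[bmat[neg, rev(seq_len(L)), drop = FALSE] + 1L]
      qm[neg, ] <- qm[neg, rev(seq_len(L)), drop = FALSE]
    }
    dt <- data.table::data.table(
      scaffold = rep(pl$scaffold, L),
      pos = rep(pl$pos0, L) + rep(seq_len(L), each = n),
      base = as.vector(bmat),
      qok = as.vector(qm) > min_quality,
      margin = rep(seq_len(L), each = n) <= end_margin |
        rep(seq_len(L), each = n) > L - end_margin,
      parent = paste0("parent", p))
    dt[, ref := 0L]
    for (s in unique(dt$scaffold)) {
      sel <- dt$scaffold == s
      data.table::set(dt, which(sel), "ref", ref_int[[s]][dt$pos[sel]])
    }
    obs[[p]] <- dt
  }
  obs <- data.table::rbindlist(obs)
  if (nrow(obs) == 0L) {
    return(data.frame(scaffold = character(0), pos = integer(0),
                      parent = character(0), nA = integer(0), nC = integer(0),
                      nG = integer(0), nT = integer(0), n_lowq = integer(0),
                      n_margin = integer(0)))
  }
  cand <- unique(obs[base != ref & qok & !margin, .(scaffold, pos)])
  obs <- obs[cand, on = c("scaffold", "pos")]
  agg <- obs[, .(
    nA = sum(base == 1L & qok & !margin),
    nC = sum(base == 2L & qok & !margin),
    nG = sum(base == 3L & qok & !margin),
    nT = sum(base == 4L & qok & !margin),
    n_lowq = sum(!qok),
    n_margin = sum(margin)), by = .(scaffold, pos, parent)]
  data.table::setorder(agg, scaffold, pos, parent)
  as.data.frame(agg)
}

#' Call homozygous SNP differences between the parental lines
#'
#' A site becomes a SNP iff, after the quality and read-end filters applied
#' during pileup construction, (a) each parent retains at least
#' `min_coverage` bases, (b) each parent is homozygous -- a site is deemed
#' heterozygous only when the minor-allele fraction exceeds
#' `max_minor_fraction` *and* the minor allele is seen on at least
#' `min_minor_count` reads (a single discordant read is treated as error) --
#' and (c) the two parental consensus bases differ.
#'
#' @param pileups data.frame from [build_pileups()].
#' @param min_coverage minimum filtered coverage per parent.
#' @param max_minor_fraction homozygosity threshold on the minor-allele
#'   fraction.
#' @param min_minor_count minimum minor-allele reads for heterozygosity.
#' @return data.frame of SNPs: `snp_id`, `scaffold`, `pos`, `allele_p1`,
#'   `allele_p2`, `cov_p1`, `cov_p2`. Zero qualifying sites give an empty
#'   (valid) result.
#' @export
call_snps <- function(pileups, min_coverage = 5L, max_minor_fraction = 0.1,
                      min_minor_count = 2L) {
  empty <- data.frame(snp_id = character(0), scaffold = character(0),
                      pos = integer(0), allele_p1 = character(0),
                      allele_p2 = character(0), cov_p1 = integer(0),
                      cov_p2 = integer(0), stringsAsFactors = FALSE)
  if (is.null(pileups) || nrow(pileups) == 0L) return(empty)
  need <- c("scaffold", "pos", "parent", "nA", "nC", "nG", "nT")
  if (!all(need %in% names(pileups))) stop("malformed pileup table")
  cnt <- as.matrix(pileups[, c("nA", "nC", "nG", "nT")])
  bad <- apply(cnt, 1L, function(x) anyNA(x) || any(x < 0))
  bad <- bad | is.na(pileups$pos) | is.na(pileups$scaffold)
  if (any(bad)) {
    warning(sum(bad), " malformed pileup row(s) skipped")
    pileups <- pileups[!bad, , drop = FALSE]
    cnt <- cnt[!bad, , drop = FALSE]
  }
  if (nrow(pileups) == 0L) return(empty)
  bases <- c("A", "C", "G", "T")
  cov <- rowSums(cnt)
  cons_i <- max.col(cnt, ties.method = "first")
  major <- cnt[cbind(seq_len(nrow(cnt)), cons_i)]
  minor <- cov - major
  het <- cov > 0 & (minor / pmax(cov, 1L)) > max_minor_fraction &
    minor >= min_minor_count
  ok <- cov >= min_coverage & !het

  dt <- data.table::data.table(scaffold = pileups$scaffold,
                               pos = pileups$pos,
                               parent = pileups$parent,
                               cons = bases[cons_i], cov = cov, ok = ok)
  w <- data.table::dcast(dt, scaffold + pos ~ parent,
                         value.var = c("cons", "cov", "ok"))
  need2 <- c("cons_parent1", "cons_parent2", "ok_parent1", "ok_parent2")
  if (!all(need2 %in% names(w))) return(empty)
  w <- w[!is.na(ok_parent1) & !is.na(ok_parent2) &
           ok_parent1 & ok_parent2 & cons_parent1 != cons_parent2]
  if (nrow(w) == 0L) return(empty)
  data.table::setorder(w, scaffold, pos)
  data.frame(snp_id = sprintf("%s:%d", w$scaffold, w$pos),
             scaffold = w$scaffold, pos = w$pos,
             allele_p1 = w$cons_parent1, allele_p2 = w$cons_parent2,
             cov_p1 = as.integer(w$cov_parent1),
             cov_p2 = as.integer(w$cov_parent2),
             stringsAsFactors = FALSE)
}

#' Write a SNP table as TSV
#' @param snps data.frame from [call_snps()].
#' @param path output path.
#' @export
write_snps_tsv <- function(snps, path) {
  out <- data.frame(scaffold = snps$scaffold, pos_1based = snps$pos,
                    allele_p1 = snps$allele_p1, allele_p2 = snps$allele_p2,
                    cov_p1 = snps$cov_p1, cov_p2 = snps$cov_p2)
  write_tsv_file(out, path)
}

#' Write SNPs as a minimal VCF 4.2 (parent2 allele as ALT)
#' @param snps data.frame from [call_snps()].
#' @param path output path.
#' @export
write_snps_vcf <- function(snps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=imprintseq",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(snps)) {
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.", snps$scaffold,
                       snps$pos, snps$snp_id, snps$allele_p1,
                       snps$allele_p2), con)
  }
  invisible(path)
}
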