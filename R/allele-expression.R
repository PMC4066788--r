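# Allele-specific expression: 191-nt allele windows around each diagnostic
# SNP, bounded-mismatch read assignment, and maternal/paternal count tables
# per reciprocal cross.

#' Build allele windows around SNPs
#'
#' Extracts a 191-nt reference window around each SNP (90 bp of left flank,
#' the SNP base at 0-based offset 90, and the remainder of the window to
#' its right) and substitutes the SNP base with each parental allele,
#' yielding one window pair per SNP. Windows are truncated at scaffold
#' edges, with `snp_offset` adjusted.
#'
#' @param genome named character vector of reference scaffolds (the
#'   parent-1 haplotype).
#' @param snps SNP data.frame (`snp_id`, `scaffold`, `pos`, `allele_p1`,
#'   `allele_p2`).
#' @param flank left-flank size in bp (the SNP's 0-based offset in an
#'   untruncated window).
#' @param win_len total window length for interior SNPs.
#' @return data.frame with `snp_id`, `scaffold`, `pos`, `start0` (0-based
#'   window start), `snp_offset` (0-based SNP position within the window),
#'   `seq_p1`, `seq_p2` (upper case).
#' @export
build_windows <- function(genome, snps, flank = 90L, win_len = 191L) {
  if (nrow(snps) == 0L) {
    return(data.frame(snp_id = character(0), scaffold = character(0),
                      pos = integer(0), start0 = integer(0),
                      snp_offset = integer(0), seq_p1 = character(0),
                      seq_p2 = character(0), stringsAsFactors = FALSE))
  }
  slen <- nchar(genome)
  if (!all(snps$scaffold %in% names(genome)))
    stop("SNP scaffold not present in genome")
  if (any(snps$pos < 1L | snps$pos > slen[snps$scaffold]))
    stop("SNP position outside scaffold")
  start1 <- pmax(snps$pos - flank, 1L)
  end1 <- pmin(snps$pos + (win_len - flank - 1L), slen[snps$scaffold])
  base <- toupper(substring(genome[snps$scaffold], start1, end1))
  off <- snps$pos - start1
  sub_at <- function(s, i, a) {
    substr(s, i, i) <- a
    s
  }
  seq_p1 <- mapply(sub_at, base, off + 1L, snps$allele_p1, USE.NAMES = FALSE)
  seq_p2 <- mapply(sub_at, base, off + 1L, snps$allele_p2, USE.NAMES = FALSE)
  data.frame(snp_id = snps$snp_id, scaffold = snps$scaffold, pos = snps$pos,
             start0 = start1 - 1L, snp_offset = as.integer(off),
             seq_p1 = seq_p1, seq_p2 = seq_p2, stringsAsFactors = FALSE)
}

#' Assign reads to parental alleles at SNP windows
#'
#' A read is assigned to allele X at a window iff it aligns ungapped, fully
#' contained in the window, in forward or reverse-complement orientation,
#' with at most `max_mismatch` mismatches, its alignment covers the SNP
#' position, and its base at the SNP equals allele X's base. Among candidate
#' placements the minimal-mismatch one is kept, ties broken by leftmost
#' position (forward orientation first). Reads not overlapping the SNP are
#' unassigned. A read assignable at several distinct SNPs is counted at each
#' locus; reads whose SNP bases imply *conflicting* parental lines at
#' different loci are discarded everywhere (chimera/error guard).
#'
#' @param reads data.frame with `id`, `seq` (equal-length reads).
#' @param windows window table from [build_windows()].
#' @param max_mismatch maximum mismatches per placement.
#' @return list with `counts` (per SNP: `snp_id`, `scaffold`, `pos`,
#'   `count_p1`, `count_p2`), `assignments` (per read-locus assignment),
#'   `n_unassigned` and `n_conflict` tallies.
#' @export
assign_reads <- function(reads, windows, max_mismatch = 4L) {
  empty_counts <- data.frame(snp_id = character(0), scaffold = character(0),
                             pos = integer(0), count_p1 = integer(0),
                             count_p2 = integer(0), stringsAsFactors = FALSE)
  if (nrow(reads) == 0L || nrow(windows) == 0L) {
    return(list(counts = empty_counts, assignments = data.frame(),
                n_unassigned = nrow(reads), n_conflict = 0L))
  }
  L <- unique(nchar(reads$seq))
  if (length(L) != 1L) stop("reads must have equal length")
  wlen <- nchar(windows$seq_p1)
  if (any(L > wlen))
    message("reads longer than ", sum(L > wlen), " truncated window(s); ",
            "those windows cannot receive assignments")

  subjects <- as.vector(rbind(windows$seq_p1, windows$seq_p2))
  m <- match_reads(reads$seq, subjects, max_mismatch = max_mismatch,
                   orientation = "both", mode = "plain")
  if (nrow(m) == 0L) {
    return(list(counts = cbind(windows[c("snp_id", "scaffold", "pos")],
                               count_p1 = 0L, count_p2 = 0L),
                assignments = data.frame(),
                n_unassigned = nrow(reads), n_conflict = 0L))
  }
  m[, win := (subject + 1L) %/% 2L]
  m[, allele := ifelse(subject %% 2L == 1L, "p1", "p2")]
  m[, snp_off := windows$snp_offset[win]]
  m <- m[pos0 <= snp_off & snp_off <= pos0 + L - 1L]
  if (nrow(m) == 0L) {
    return(list(counts = cbind(windows[c("snp_id", "scaffold", "pos")],
                               count_p1 = 0L, count_p2 = 0L),
                assignments = data.frame(),
                n_unassigned = nrow(reads), n_conflict = 0L))
  }

  # base the read shows at the SNP position (window-forward space)
  rmat_f <- reads_to_int_matrix(reads$seq)
  rmat_r <- .INT_COMP[rmat_f[, rev(seq_len(L)), drop = FALSE] + 1L]
  dim(rmat_r) <- dim(rmat_f)
  j <- m$snp_off - m$pos0 + 1L
  bint <- ifelse(m$strand == "+", rmat_f[cbind(m$read, j)],
                 rmat_r[cbind(m$read, j)])
  m[, snp_base := c("A", "C", "G", "T")[bint]]
  a1 <- substr(windows$seq_p1, windows$snp_offset + 1L,
               windows$snp_offset + 1L)
  a2 <- substr(windows$seq_p2, windows$snp_offset + 1L,
               windows$snp_offset + 1L)
  m[, win_allele := ifelse(allele == "p1", a1[win], a2[win])]
  m <- m[snp_base == win_allele]
  if (nrow(m) == 0L) {
    return(list(counts = cbind(windows[c("snp_id", "scaffold", "pos")],
                               count_p1 = 0L, count_p2 = 0L),
                assignments = data.frame(),
                n_unassigned = nrow(reads), n_conflict = 0L))
  }

  # minimal-mismatch placement per (read, window); leftmost, "+" first
  data.table::setorder(m, read, win, mismatches, pos0, strand)
  m <- m[, .SD[1L], by = .(read, win)]

  # conflicting parental lines across loci -> discard the read everywhere
  m[, n_alleles := data.table::uniqueN(allele), by = read]
  n_conflict <- length(unique(m$read[m$n_alleles > 1L]))
  m <- m[n_alleles == 1L]

  cnt <- m[, .(count_p1 = sum(allele == "p1"),
               count_p2 = sum(allele == "p2")), by = win]
  counts <- cbind(windows[c("snp_id", "scaffold", "pos")],
                  count_p1 = 0L, count_p2 = 0L)
  counts$count_p1[cnt$win] <- cnt$count_p1
  counts$count_p2[cnt$win] <- cnt$count_p2

  assignments <- data.frame(id = reads$id[m$read],
                            snp_id = windows$snp_id[m$win],
                            allele = m$allele, mismatches = m$mismatches,
                            pos0 = m$pos0, strand = m$strand,
                            stringsAsFactors = FALSE)
  list(counts = counts, assignments = assignments,
       n_unassigned = nrow(reads) - length(unique(m$read)),
       n_conflict = n_conflict)
}

#' Combine reciprocal-cross allele counts into a joint locus table
#'
#' Applies the maternal/paternal orientation map (in AxB parent1 is the
#' mother; in BxA parent2 is) and restricts to loci informative (at least
#' one assigned read) in both cross directions. Loci with more than
#' `min_reads` reads in both crosses are flagged high-quality.
#'
#' @param counts_axb,counts_bxa per-cross count tables from
#'   [assign_reads()]`$counts`.
#' @param min_reads high-quality coverage threshold (strictly greater
#'   than).
#' @return data.frame with one row per joint locus; loci seen in only one
#'   cross are attached as the `"excluded"` attribute.
#' @export
counts_by_cross <- function(counts_axb, counts_bxa, min_reads = 10L) {
  a <- data.table::as.data.table(counts_axb)
  b <- data.table::as.data.table(counts_bxa)
  a <- a[count_p1 + count_p2 > 0L]
  b <- b[count_p1 + count_p2 > 0L]
  j <- merge(a, b, by = c("snp_id", "scaffold", "pos"),
             suffixes = c("_AxB", "_BxA"))
  excluded <- rbind(
    cbind(a[!j, on = "snp_id"], cross = if (nrow(a[!j, on = "snp_id"])) "AxB"
          else character(0)),
    cbind(b[!j, on = "snp_id"], cross = if (nrow(b[!j, on = "snp_id"])) "BxA"
          else character(0)),
    fill = TRUE)
  out <- data.frame(
    snp_id = j$snp_id, scaffold = j$scaffold, pos = j$pos,
    p1_AxB = j$count_p1_AxB, p2_AxB = j$count_p2_AxB,
    p1_BxA = j$count_p1_BxA, p2_BxA = j$count_p2_BxA,
    stringsAsFactors = FALSE)
  out$mat_AxB <- out$p1_AxB; out$pat_AxB <- out$p2_AxB
  out$mat_BxA <- out$p2_BxA; out$pat_BxA <- out$p1_BxA
  out$n_AxB <- out$p1_AxB + out$p2_AxB
  out$n_BxA <- out$p1_BxA + out$p2_BxA
  out$high_quality <- out$n_AxB > min_reads & out$n_BxA > min_reads
  out <- out[order(out$scaffold, out$pos), ]
  rownames(out) <- NULL
  attr(out, "excluded") <- as.data.frame(excluded)
  out
}
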