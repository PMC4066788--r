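# Deterministic ungapped read matcher.
#
# All read placement in the package (parental RNA reads onto the reference
# for pileups, endosperm reads onto 191-nt allele windows, bisulfite reads
# onto the genome) goes through one seeded exact-substring engine: reads are
# split into max_mismatch + 1 disjoint seed k-mers so that any ungapped
# placement with at most max_mismatch mismatches is guaranteed to share at
# least one exact seed with the subject (pigeonhole), candidates are then
# verified column-by-column. Bisulfite mode collapses the alphabet
# (C -> T on the forward sense, G -> A on the reverse sense) on both sides so
# that unmethylated-converted bases never count as mismatches.

.KMAX <- 15L  # 4^15 < 2^31, so seed codes stay in integer range

# rolling 2-bit codes of all k-mers of an integer-encoded sequence;
# windows containing an invalid base (0) get NA
.kmer_codes <- function(iv, k) {
  n <- length(iv) - k + 1L
  if (n < 1L) return(integer(0))
  code <- iv[1:n] - 1L
  for (j in 2:k) code <- code * 4L + (iv[j:(j + n - 1L)] - 1L)
  cz <- c(0L, cumsum(iv == 0L))
  bad <- (cz[(1:n) + k] - cz[1:n]) > 0L
  code[bad] <- NA_integer_
  code
}

.collapse_ct <- function(iv) { iv[iv == 2L] <- 4L; iv }  # C -> T
.collapse_ga <- function(iv) { iv[iv == 3L] <- 1L; iv }  # G -> A

# concatenate subject integer vectors with k zero separators;
# returns list(big = int vector, offset = 0-based start of each subject,
#              len = subject lengths)
.concat_subjects <- function(subj_int, sep = .KMAX) {
  lens <- vapply(subj_int, length, integer(1))
  offs <- cumsum(c(0L, head(lens + sep, -1L)))
  big <- integer(sum(lens) + sep * length(lens))
  for (i in seq_along(subj_int)) {
    big[(offs[i] + 1L):(offs[i] + lens[i])] <- subj_int[[i]]
  }
  list(big = big, offset = offs, len = lens)
}

# index of seed codes -> absolute position (1-based in concatenated vector)
.build_index <- function(big, k) {
  code <- .kmer_codes(big, k)
  keep <- !is.na(code)
  data.table::data.table(code = code[keep], apos = which(keep), key = "code")
}

#' Ungapped read matching with bounded mismatches
#'
#' Places each read onto each subject sequence wherever a full-length
#' ungapped alignment with at most `max_mismatch` mismatches exists, in
#' forward and (optionally) reverse-complement orientation. In bisulfite
#' mode a read T opposite a subject C (forward sense) or a read A opposite a
#' subject G (reverse-complement sense) is not counted as a mismatch.
#'
#' @param seqs character vector of reads (all the same length).
#' @param subjects character vector of subject sequences (scaffolds or
#'   allele windows).
#' @param max_mismatch maximum number of mismatches tolerated.
#' @param orientation `"both"` (default) or `"forward"`.
#' @param mode `"plain"` or `"bisulfite"`.
#' @return a `data.table` with one row per placement: `read` (index into
#'   `seqs`), `subject` (index into `subjects`), `pos0` (0-based alignment
#'   start on the subject's forward strand), `strand` (`"+"`/`"-"`),
#'   `mismatches`.
#' @export
match_reads <- function(seqs, subjects, max_mismatch = 4L,
                        orientation = c("both", "forward"),
                        mode = c("plain", "bisulfite")) {
  orientation <- match.arg(orientation)
  mode <- match.arg(mode)
  empty <- data.table::data.table(read = integer(0), subject = integer(0),
                                  pos0 = integer(0), strand = character(0),
                                  mismatches = integer(0))
  if (length(seqs) == 0L || length(subjects) == 0L) return(empty)

  rmat_f <- reads_to_int_matrix(seqs)
  L <- ncol(rmat_f)
  n_chunk <- max_mismatch + 1L
  k <- min(L %/% n_chunk, .KMAX)
  if (k < 8L)
    stop("reads too short for ", max_mismatch, "-mismatch seeding")
  chunk_starts <- as.integer(floor((0:(n_chunk - 1L)) * L / n_chunk))

  subj_int <- lapply(subjects, seq_to_int)
  cc <- .concat_subjects(subj_int)
  too_short <- cc$len < L

  # reverse-complemented read matrix (rows aligned with seqs)
  rmat_r <- NULL
  if (orientation == "both") {
    rmat_r <- .INT_COMP[rmat_f[, rev(seq_len(L)), drop = FALSE] + 1L]
    dim(rmat_r) <- dim(rmat_f)
  }

  # per-sense subject vectors, indexes, and read matrices
  senses <- list()
  if (mode == "plain") {
    idx <- .build_index(cc$big, k)
    senses[["+"]] <- list(sub = cc$big, idx = idx, rmat = rmat_f)
    if (orientation == "both")
      senses[["-"]] <- list(sub = cc$big, idx = idx, rmat = rmat_r)
  } else {
    sub_ct <- .collapse_ct(cc$big)
    senses[["+"]] <- list(sub = sub_ct, idx = .build_index(sub_ct, k),
                          rmat = .collapse_ct(rmat_f))
    if (orientation == "both") {
      sub_ga <- .collapse_ga(cc$big)
      senses[["-"]] <- list(sub = sub_ga, idx = .build_index(sub_ga, k),
                            rmat = .collapse_ga(rmat_r))
    }
  }

  out <- list()
  for (strand in names(senses)) {
    sn <- senses[[strand]]
    cand <- list()
    for (cs in chunk_starts) {
      sub_cols <- sn$rmat[, (cs + 1L):(cs + k), drop = FALSE]
      code <- sub_cols[, 1L] - 1L
      bad <- sub_cols[, 1L] == 0L
      for (j in 2:k) {
        code <- code * 4L + (sub_cols[, j] - 1L)
        bad <- bad | sub_cols[, j] == 0L
      }
      code[bad] <- NA_integer_
      qdt <- data.table::data.table(code = code, read = seq_along(code))
      qdt <- qdt[!is.na(code)]
      if (nrow(qdt) == 0L) next
      hits <- sn$idx[qdt, on = "code", allow.cartesian = TRUE, nomatch = NULL]
      if (nrow(hits) == 0L) next
      hits[, astart := apos - cs]
      cand[[length(cand) + 1L]] <- hits[, .(read, astart)]
    }
    if (length(cand) == 0L) next
    cand <- unique(data.table::rbindlist(cand))

    # containment within a single subject
    si <- findInterval(cand$astart, cc$offset + 1L)
    sic <- pmax(si, 1L)
    ok <- si >= 1L & !too_short[sic] &
      cand$astart >= cc$offset[sic] + 1L &
      cand$astart + L - 1L <= cc$offset[sic] + cc$len[sic]
    cand <- cand[ok]; si <- si[ok]
    if (nrow(cand) == 0L) next

    mm <- integer(nrow(cand))
    sub <- sn$sub; rmat <- sn$rmat; ast <- cand$astart; rd <- cand$read
    for (j in seq_len(L)) {
      mm <- mm + (sub[ast + (j - 1L)] != rmat[cbind(rd, j)])
    }
    keep <- mm <= max_mismatch
    if (!any(keep)) next
    out[[strand]] <- data.table::data.table(
      read = rd[keep],
      subject = si[keep],
      pos0 = ast[keep] - cc$offset[si[keep]] - 1L,
      strand = strand,
      mismatches = mm[keep])
  }
  if (length(out) == 0L) return(empty)
  res <- data.table::rbindlist(out)
  data.table::setorder(res, read, subject, pos0, strand)
  res[]
}

#' Place reads on a genome, keeping best placements
#'
#' Thin wrapper around [match_reads()] that keeps, per read, only the
#' placements with the minimal mismatch count, and optionally drops reads
#' whose best placement is not unique.
#'
#' @param reads data.frame with columns `id`, `seq` (equal-length reads).
#' @param genome named character vector of scaffold sequences.
#' @param max_mismatch maximum mismatches.
#' @param unique_only drop reads with more than one best placement.
#' @param mode `"plain"` or `"bisulfite"`.
#' @return data.frame of placements: `read_id`, `scaffold`, `pos0`, `strand`,
#'   `mismatches`.
#' @export
place_reads <- function(reads, genome, max_mismatch = 4L, unique_only = TRUE,
                        mode = "plain") {
  m <- match_reads(reads$seq, unname(genome), max_mismatch = max_mismatch,
                   orientation = "both", mode = mode)
  if (nrow(m) == 0L) {
    return(data.frame(read_id = character(0), scaffold = character(0),
                      pos0 = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  m[, best := min(mismatches), by = read]
  m <- m[mismatches == best]
  if (unique_only) {
    m[, nbest := .N, by = read]
    m <- m[nbest == 1L]
  } else {
    # deterministic single placement: leftmost on the first scaffold, "+" first
    data.table::setorder(m, read, subject, pos0, strand)
    m <- m[, .SD[1L], by = read]
  }
  data.frame(read_id = reads$id[m$read],
             scaffold = names(genome)[m$subject],
             pos0 = m$pos0,
             strand = m$strand,
             mismatches = m$mismatches,
             stringsAsFactors = FALSE)
}
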