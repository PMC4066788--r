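# Read emission helpers shared by the RNA and bisulfite generators.

.new_read_id <- function(prefix, n) sprintf("%s_%07d", prefix, seq_len(n))

.revcomp_subset <- function(seqs, idx) {
  if (length(idx)) seqs[idx] <- revcomp(seqs[idx])
  seqs
}

.apply_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0L) return(seqs)
  L <- nchar(seqs[1])
  nerr <- stats::rbinom(length(seqs), L, error_rate)
  hit <- which(nerr > 0L)
  for (i in hit) {
    v <- seq_to_int(seqs[i])
    pos <- sample.int(L, nerr[i])
    v[pos] <- vapply(v[pos], function(b) sample(setdiff(1:4, b), 1L),
                     integer(1))
    seqs[i] <- int_to_seq(v)
  }
  seqs
}

#' Simulate reciprocal-cross endosperm RNA reads with known origin
#'
#' Emits single-end reads covering the diagnostic SNPs of every gene. In the
#' triploid endosperm a read from a biallelic gene is maternal with
#' probability 2/3 (the genomic dosage); MEG reads are maternal with
#' probability `imprint_strength`, PEG reads with `1 - imprint_strength`;
#' accession-biased genes draw reads from the favoured parental line with
#' probability `accession_strength` in *both* cross directions. Each read is
#' logged with its parent-of-origin, parental line, gene, SNP and placement,
#' so downstream accuracy can be scored exactly. With `config$paired` a
#' second mate is emitted from the opposite end of a fragment extending
#' within the gene body (ids suffixed `/1`, `/2`).
#'
#' @param config a [sim_config()] object.
#' @param cross `"AxB"` (parent1 is the mother) or `"BxA"`.
#' @param truth a `sim_truth` object from [gen_parental_genomes()].
#' @return list with `reads` (data.frame `id`, `seq`, `qual`) and `origin`
#'   (one row per read: `id`, `gene_id`, `snp_id`, `cross`, `line`,
#'   `parent`, `scaffold`, `start0`, `strand`).
#' @export
gen_endosperm_reads <- function(config, cross, truth) {
  if (!cross %in% c("AxB", "BxA")) stop("unknown cross direction: ", cross)
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(config$seed + if (cross == "AxB") 104729L else 224737L)
  mother <- if (cross == "AxB") "parent1" else "parent2"
  father <- if (cross == "AxB") "parent2" else "parent1"
  L <- config$read_len

  snps <- truth$snps[!is.na(truth$snps$gene_id), ]
  genes <- truth$genes
  if (nrow(snps) == 0L) {
    empty <- data.frame(id = character(0), seq = character(0),
                        qual = character(0), stringsAsFactors = FALSE)
    return(list(reads = empty, origin = data.frame()))
  }
  gidx <- match(snps$gene_id, genes$gene_id)

  n_per_snp <- stats::rpois(nrow(snps), config$coverage_rna)
  si <- rep.int(seq_len(nrow(snps)), n_per_snp)

  ## maternal-contamination reads: purely maternal extras per gene
  if (config$maternal_contamination > 0) {
    n_cont <- stats::rpois(nrow(snps),
                           config$maternal_contamination * config$coverage_rna)
    ci <- rep.int(seq_len(nrow(snps)), n_cont)
  } else ci <- integer(0)

  n <- length(si)
  cls <- genes$class[gidx][si]
  p_mat <- ifelse(cls == "MEG", config$imprint_strength,
                  ifelse(cls == "PEG", 1 - config$imprint_strength, 2 / 3))
  parent <- ifelse(stats::runif(n) < p_mat, "maternal", "paternal")
  line <- ifelse(parent == "maternal", mother, father)
  isacc <- cls == "accession_biased"
  if (any(isacc)) {
    fav <- genes$biased_line[gidx][si][isacc]
    oth <- ifelse(fav == "parent1", "parent2", "parent1")
    line[isacc] <- ifelse(stats::runif(sum(isacc)) < config$accession_strength,
                          fav, oth)
    parent[isacc] <- ifelse(line[isacc] == mother, "maternal", "paternal")
  }

  if (length(ci)) {
    si <- c(si, ci)
    parent <- c(parent, rep("maternal", length(ci)))
    line <- c(line, rep(mother, length(ci)))
    n <- length(si)
  }

  pos <- snps$pos[si]
  gs <- genes$start[gidx][si]; ge <- genes$end[gidx][si]
  lo <- pmax(gs + 1L, pos - L + 1L)
  hi <- pmin(pos, ge - L + 1L)
  start1 <- lo + as.integer(floor(stats::runif(n) * (hi - lo + 1L)))
  scaff <- snps$scaffold[si]

  seqs <- character(n)
  for (ln in c("parent1", "parent2")) {
    for (s in unique(scaff)) {
      sel <- which(line == ln & scaff == s)
      if (!length(sel)) next
      seqs[sel] <- substring(truth$genomes[[ln]][s], start1[sel],
                             start1[sel] + L - 1L)
    }
  }
  seqs <- .apply_errors(seqs, config$error_rate)
  strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
  seqs <- .revcomp_subset(seqs, which(strand == "-"))

  ids <- .new_read_id(cross, n)
  origin <- data.frame(id = ids, gene_id = snps$gene_id[si],
                       snp_id = snps$snp_id[si], cross = cross,
                       line = line, parent = parent, scaffold = scaff,
                       start0 = start1 - 1L, strand = strand,
                       stringsAsFactors = FALSE)
  reads <- data.frame(id = ids, seq = seqs, qual = strrep("I", L),
                      stringsAsFactors = FALSE)

  if (config$paired) {
    # mate 2: the opposite end of a fragment extending 3' of read 1 within
    # the gene body, reverse-complemented relative to it
    flen <- pmin(2L * L + 60L, ge - gs)
    f1 <- pmin(start1, ge - flen + 1L)
    m2_start <- f1 + flen - L
    seq2 <- character(n)
    for (ln in c("parent1", "parent2")) {
      for (s in unique(scaff)) {
        sel <- which(line == ln & scaff == s)
        if (!length(sel)) next
        seq2[sel] <- substring(truth$genomes[[ln]][s], m2_start[sel],
                               m2_start[sel] + L - 1L)
      }
    }
    seq2 <- .apply_errors(seq2, config$error_rate)
    # mate 2 points the other way along the fragment
    flip <- strand == "+"
    seq2 <- .revcomp_subset(seq2, which(flip))
    reads$id <- paste0(ids, "/1")
    origin$id <- reads$id
    mate2 <- data.frame(id = paste0(ids, "/2"), seq = seq2,
                        qual = strrep("I", L), stringsAsFactors = FALSE)
    origin2 <- origin
    origin2$id <- mate2$id
    origin2$start0 <- m2_start - 1L
    origin2$strand <- ifelse(flip, "-", "+")
    reads <- rbind(reads, mate2)
    origin <- rbind(origin, origin2)
  }
  list(reads = reads, origin = origin)
}

#' Simulate parental-line RNA reads for SNP discovery
#'
#' Uniform error-free coverage over every gene body of one parental
#' haplotype; these reads feed the pileup builder and SNP caller.
#'
#' @param config a [sim_config()] object.
#' @param parent `"parent1"` or `"parent2"`.
#' @param truth a `sim_truth` object.
#' @param coverage mean per-base depth (defaults to
#'   `config$coverage_parental`).
#' @return list with `reads` and `origin` as in [gen_endosperm_reads()].
#' @export
gen_parental_reads <- function(config, parent = c("parent1", "parent2"),
                               truth, coverage = NULL) {
  parent <- match.arg(parent)
  stopifnot(inherits(truth, "sim_truth"))
  if (is.null(coverage)) coverage <- config$coverage_parental
  set.seed(config$seed + if (parent == "parent1") 312343L else 414977L)
  L <- config$read_len
  genes <- truth$genes
  n_per_gene <- stats::rpois(nrow(genes),
                             coverage * (genes$end - genes$start) / L)
  gi <- rep.int(seq_len(nrow(genes)), n_per_gene)
  n <- length(gi)
  lo <- genes$start[gi] + 1L
  hi <- genes$end[gi] - L + 1L
  start1 <- lo + as.integer(floor(stats::runif(n) * (hi - lo + 1L)))
  scaff <- genes$scaffold[gi]
  seqs <- character(n)
  for (s in unique(scaff)) {
    sel <- which(scaff == s)
    seqs[sel] <- substring(truth$genomes[[parent]][s], start1[sel],
                           start1[sel] + L - 1L)
  }
  seqs <- .apply_errors(seqs, config$error_rate)
  strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
  seqs <- .revcomp_subset(seqs, which(strand == "-"))
  ids <- .new_read_id(parent, n)
  list(reads = data.frame(id = ids, seq = seqs, qual = strrep("I", L),
                          stringsAsFactors = FALSE),
       origin = data.frame(id = ids, gene_id = genes$gene_id[gi],
                           line = parent, scaffold = scaff,
                           start0 = start1 - 1L, strand = strand,
                           stringsAsFactors = FALSE))
}
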