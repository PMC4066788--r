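#' Generate parental haplotypes, gene models, TEs and methylation truth
#'
#' Builds the complete ground truth for one simulated experiment: two inbred
#' parental haplotypes (`parent1`, `parent2`) identical except at biallelic
#' SNPs, non-overlapping unspliced gene models with imprinting class labels
#' (MEG / PEG / biallelic / accession-biased), transposable-element
#' annotations with configurable enrichment near MEGs, and a piecewise
#' methylation map (embryo baseline, globally hypomethylated endosperm,
#' strongly demethylated endosperm regions, and allele-differential regions
#' inside a subset of MEG bodies).
#'
#' SNPs are placed at least `read_len` bp from scaffold edges so that every
#' SNP supports a full allele window. Allele-differential methylation
#' regions are seeded with three diagnostic A/C SNPs (distinguishable under
#' bisulfite conversion on both strands) so parent-of-origin read splitting
#' is possible there.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `sim_truth` with elements `genomes` (named
#'   list `parent1`, `parent2` of named character vectors), `snps`, `genes`,
#'   `tes`, `meth_regions` (data.frames) and `config`. Gene and TE
#'   coordinates are 0-based half-open; SNP positions are 1-based.
#' @export
gen_parental_genomes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  L <- config$scaffold_len
  margin <- config$read_len
  scaffolds <- sprintf("scaffold_%02d", seq_len(config$n_scaffolds))

  hap1 <- lapply(scaffolds, function(s) sample.int(4L, L, replace = TRUE))
  names(hap1) <- scaffolds

  ## gene models: evenly slotted with random jitter, never overlapping
  n_per <- diff(round(seq(0, config$n_genes, length.out =
                            config$n_scaffolds + 1L)))
  usable <- L - 2L * margin
  genes <- list()
  gi <- 0L
  for (si in seq_along(scaffolds)) {
    k <- n_per[si]
    if (k == 0L) next
    slot <- usable %/% k
    if (slot < config$gene_len + 40L)
      stop("scaffold_len too small for n_genes of this gene_len")
    jit_max <- slot - config$gene_len - 20L
    for (j in seq_len(k)) {
      gi <- gi + 1L
      start0 <- margin + (j - 1L) * slot + 10L + sample.int(jit_max, 1L)
      genes[[gi]] <- data.frame(
        gene_id = sprintf("gene_%04d", gi),
        scaffold = scaffolds[si],
        start = start0, end = start0 + config$gene_len,
        strand = sample(c("+", "-"), 1L),
        stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, genes)

  ## imprinting class labels
  ng <- nrow(genes)
  n_meg <- round(config$frac_meg * ng)
  n_peg <- round(config$frac_peg * ng)
  n_acc <- round(config$frac_accession_biased * ng)
  labels <- c(rep("MEG", n_meg), rep("PEG", n_peg),
              rep("accession_biased", n_acc),
              rep("biallelic", ng - n_meg - n_peg - n_acc))
  genes$class <- sample(labels)
  genes$biased_line <- NA_character_
  acc <- genes$class == "accession_biased"
  genes$biased_line[acc] <- sample(c("parent1", "parent2"), sum(acc),
                                   replace = TRUE)

  ## random SNPs (Poisson process away from scaffold edges)
  snps <- list()
  for (si in seq_along(scaffolds)) {
    hit <- which(stats::runif(usable) < config$snp_rate) + margin
    if (length(hit))
      snps[[si]] <- data.frame(scaffold = scaffolds[si], pos = hit,
                               forced = FALSE, stringsAsFactors = FALSE)
  }
  snps <- if (length(snps)) do.call(rbind, snps) else
    data.frame(scaffold = character(0), pos = integer(0), forced = logical(0))

  ## guarantee every gene body carries at least one SNP
  if (config$ensure_gene_snp && nrow(genes)) {
    for (r in seq_len(nrow(genes))) {
      g <- genes[r, ]
      inside <- snps$scaffold == g$scaffold & snps$pos > g$start &
        snps$pos <= g$end
      if (!any(inside)) {
        snps <- rbind(snps, data.frame(
          scaffold = g$scaffold, pos = as.integer((g$start + g$end) %/% 2),
          forced = FALSE, stringsAsFactors = FALSE))
      }
    }
  }

  ## allele-differential methylation regions inside MEG bodies,
  ## seeded with diagnostic A/C SNPs
  adm_len <- min(300L, config$gene_len)
  genes$has_allele_dmr <- FALSE
  megs <- which(genes$class == "MEG")
  adm_rows <- list()
  if (length(megs)) {
    chosen <- megs[stats::runif(length(megs)) < config$frac_allele_dmr]
    for (r in chosen) {
      g <- genes[r, ]
      off_max <- config$gene_len - adm_len
      a0 <- g$start + (if (off_max > 0) sample.int(off_max, 1L) else 0L)
      genes$has_allele_dmr[r] <- TRUE
      adm_rows[[length(adm_rows) + 1L]] <- data.frame(
        scaffold = g$scaffold, start = a0, end = a0 + adm_len,
        gene_id = g$gene_id, stringsAsFactors = FALSE)
      # dense diagnostic SNPs: nearly every read in the region covers one,
      # so both alleles retain usable labelled depth
      forced_pos <- a0 + as.integer(round(adm_len * c(0.1, 0.37, 0.63, 0.9)))
      snps <- snps[!(snps$scaffold == g$scaffold & snps$pos %in% forced_pos), ]
      snps <- rbind(snps, data.frame(scaffold = g$scaffold, pos = forced_pos,
                                     forced = TRUE, stringsAsFactors = FALSE))
    }
  }
  snps <- snps[order(snps$scaffold, snps$pos), ]
  snps <- snps[!duplicated(snps[c("scaffold", "pos")]), ]

  ## alleles: parent1 keeps (or, for forced SNPs, is set to) the reference
  ## base; parent2 receives a different base
  hap2 <- hap1
  snps$allele_p1 <- rep(NA_character_, nrow(snps))
  snps$allele_p2 <- rep(NA_character_, nrow(snps))
  bases <- c("A", "C", "G", "T")
  for (s in scaffolds) {
    idx <- which(snps$scaffold == s)
    if (!length(idx)) next
    pos <- snps$pos[idx]
    forced <- snps$forced[idx]
    hap1[[s]][pos[forced]] <- 1L                      # A
    a1 <- hap1[[s]][pos]
    a2 <- integer(length(pos))
    a2[forced] <- 2L                                  # C
    if (any(!forced)) {
      a2[!forced] <- vapply(a1[!forced], function(b)
        sample(setdiff(1:4, b), 1L), integer(1))
    }
    hap2[[s]][pos] <- a2
    snps$allele_p1[idx] <- bases[a1]
    snps$allele_p2[idx] <- bases[a2]
  }

  ## map SNPs to gene bodies
  snps$gene_id <- rep(NA_character_, nrow(snps))
  for (r in seq_len(nrow(genes))) {
    g <- genes[r, ]
    inside <- snps$scaffold == g$scaffold & snps$pos > g$start &
      snps$pos <= g$end
    snps$gene_id[inside] <- g$gene_id
  }
  snps$snp_id <- sprintf("%s:%d", snps$scaffold, snps$pos)

  ## transposable elements, enriched near MEGs per family multiplier
  te_zone <- genes[genes$class == "MEG", c("scaffold", "start", "end")]
  genome_len <- as.numeric(config$n_scaffolds) * L
  zone_len <- if (nrow(te_zone))
    sum(pmin(te_zone$end + 4000, L) - pmax(te_zone$start - 4000, 0)) else 0
  zone_frac <- zone_len / genome_len
  tes <- list()
  for (f in seq_len(nrow(config$te_families))) {
    fam <- config$te_families[f, ]
    if (fam$n == 0L) next
    p_near <- min(0.95, fam$meg_multiplier * zone_frac)
    te_len <- sample(200:1500, fam$n, replace = TRUE)
    near <- stats::runif(fam$n) < p_near & nrow(te_zone) > 0
    sc <- character(fam$n); st <- integer(fam$n)
    for (i in seq_len(fam$n)) {
      if (near[i]) {
        z <- te_zone[sample.int(nrow(te_zone), 1L), ]
        lo <- max(z$start - 4000L, 0L)
        hi <- min(z$end + 4000L, L) - te_len[i]
        sc[i] <- z$scaffold
        st[i] <- if (hi > lo) lo + sample.int(hi - lo, 1L) else lo
      } else {
        sc[i] <- sample(scaffolds, 1L)
        st[i] <- sample.int(L - te_len[i], 1L)
      }
    }
    tes[[f]] <- data.frame(scaffold = sc, start = st, end = st + te_len,
                           family = fam$family, stringsAsFactors = FALSE)
  }
  tes <- if (length(tes)) do.call(rbind, tes) else
    data.frame(scaffold = character(0), start = integer(0), end = integer(0),
               family = character(0), stringsAsFactors = FALSE)
  tes <- tes[order(tes$scaffold, tes$start), ]
  rownames(tes) <- NULL

  ## endosperm-hypomethylated regions in gene bodies / 2-kb flanks
  genes$has_hypo <- FALSE
  hypo_rows <- list()
  occupied <- adm_rows  # avoid stacking special regions on one another
  overlaps_any <- function(s, a, b) {
    if (!length(occupied)) return(FALSE)
    any(vapply(occupied, function(r)
      r$scaffold == s && a < r$end && b > r$start, logical(1)))
  }
  for (r in seq_len(nrow(genes))) {
    g <- genes[r, ]
    p <- if (g$class == "MEG") config$frac_hypo_meg else
      config$frac_hypo_background
    if (stats::runif(1) >= p) next
    lo <- max(g$start - 2000L, 0L)
    hi <- min(g$end + 2000L, L) - config$hypo_len
    if (hi <= lo) next
    h0 <- lo + sample.int(hi - lo, 1L)
    if (overlaps_any(g$scaffold, h0, h0 + config$hypo_len)) next
    genes$has_hypo[r] <- TRUE
    row <- data.frame(scaffold = g$scaffold, start = h0,
                      end = h0 + config$hypo_len, gene_id = g$gene_id,
                      stringsAsFactors = FALSE)
    hypo_rows[[length(hypo_rows) + 1L]] <- row
    occupied[[length(occupied) + 1L]] <- row
  }

  ## piecewise methylation map: background + special regions
  meth <- data.frame(scaffold = scaffolds, start = 0L, end = L,
                     type = "background",
                     gene_id = NA_character_,
                     level_embryo = config$meth_embryo,
                     level_endosperm = config$meth_endosperm,
                     level_endosperm_maternal = config$meth_endosperm,
                     level_endosperm_paternal = config$meth_endosperm,
                     stringsAsFactors = FALSE)
  if (length(hypo_rows)) {
    h <- do.call(rbind, hypo_rows)
    meth <- rbind(meth, data.frame(
      scaffold = h$scaffold, start = h$start, end = h$end, type = "hypo",
      gene_id = h$gene_id,
      level_embryo = config$meth_embryo,
      level_endosperm = config$meth_hypo,
      level_endosperm_maternal = config$meth_hypo,
      level_endosperm_paternal = config$meth_hypo,
      stringsAsFactors = FALSE))
  }
  if (length(adm_rows)) {
    a <- do.call(rbind, adm_rows)
    mixed <- (2 * config$meth_allele_low + config$meth_allele_high) / 3
    meth <- rbind(meth, data.frame(
      scaffold = a$scaffold, start = a$start, end = a$end,
      type = "allele_dmr", gene_id = a$gene_id,
      level_embryo = config$meth_embryo,
      level_endosperm = mixed,
      level_endosperm_maternal = config$meth_allele_low,
      level_endosperm_paternal = config$meth_allele_high,
      stringsAsFactors = FALSE))
  }
  rownames(meth) <- NULL
  rownames(genes) <- NULL
  rownames(snps) <- NULL

  genomes <- list(parent1 = vapply(hap1, int_to_seq, character(1)),
                  parent2 = vapply(hap2, int_to_seq, character(1)))
  out <- list(config = config, genomes = genomes,
              snps = snps[c("snp_id", "scaffold", "pos", "allele_p1",
                            "allele_p2", "gene_id", "forced")],
              genes = genes, tes = tes, meth_regions = meth)
  class(out) <- "sim_truth"
  out
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>\n")
  cat(sprintf("  %d scaffold(s), %d SNPs, %d genes (%s), %d TEs\n",
              length(x$genomes$parent1), nrow(x$snps), nrow(x$genes),
              paste(names(table(x$genes$class)),
                    table(x$genes$class), sep = ":", collapse = " "),
              nrow(x$tes)))
  cat(sprintf("  methylation regions: %s\n",
              paste(names(table(x$meth_regions$type)),
                    table(x$meth_regions$type), sep = ":", collapse = " ")))
  invisible(x)
}

#' Export truth annotations as plain-text files
#'
#' Writes the haplotypes (FASTA), gene and TE annotations (BED, 0-based
#' half-open), SNP table and methylation-region table (TSV) of a
#' `sim_truth` object into a directory.
#'
#' @param truth a `sim_truth` object.
#' @param dir output directory (created if missing).
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(truth$genomes$parent1, file.path(dir, "parent1.fa"))
  write_fasta(truth$genomes$parent2, file.path(dir, "parent2.fa"))
  g <- truth$genes
  write_bed_file(data.frame(g$scaffold, g$start, g$end, g$gene_id, 0L,
                            g$strand),
                 file.path(dir, "genes.bed"))
  if (nrow(truth$tes))
    write_bed_file(data.frame(truth$tes$scaffold, truth$tes$start,
                              truth$tes$end, truth$tes$family),
                   file.path(dir, "tes.bed"))
  write_tsv_file(truth$snps, file.path(dir, "snps_truth.tsv"))
  write_tsv_file(truth$genes, file.path(dir, "genes_truth.tsv"))
  write_tsv_file(truth$meth_regions, file.path(dir, "meth_regions.tsv"))
  invisible(dir)
}
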