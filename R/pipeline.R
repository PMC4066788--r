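# End-to-end pipeline: simulate -> SNPs -> allele windows/counts ->
# imprinting calls -> methylome -> feature association, with plain-text
# outputs and a machine-readable funnel summary.

#' Pipeline configuration
#'
#' Bundles a [sim_config()] (or paths to pre-existing inputs) with one
#' parameter block per stage. The defaults reproduce the canonical
#' settings: base quality > 20 and coverage >= 5 for SNP calls, 191-nt
#' (+/- 90 bp) allele windows, up to 4 mismatches for allele assignment,
#' the 2:1 dosage null with FDR 0.05 and the 90% uniparental filter, the
#' five DMR criteria, 200-bp allele-methylation windows with the 40%/70%
#' rule, and 4-kb TE flanks.
#'
#' @param sim a [sim_config()] describing the synthetic inputs.
#' @param outdir output directory for the run.
#' @param snp,windows,assign,counts,imprinting,accession,bs,dmr,allele_dmr,te,cluster
#'   named lists overriding individual stage parameters.
#' @param write_reads write FASTQ files for all simulated reads.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), outdir = tempfile("ipsrun"),
                            snp = list(), windows = list(), assign = list(),
                            counts = list(), imprinting = list(),
                            accession = list(), bs = list(), dmr = list(),
                            allele_dmr = list(), te = list(),
                            cluster = list(), write_reads = TRUE) {
  defaults <- list(
    snp = list(min_quality = 20L, end_margin = 5L, min_coverage = 5L,
               max_minor_fraction = 0.1, min_minor_count = 2L),
    windows = list(flank = 90L),
    assign = list(max_mismatch = 4L),
    counts = list(min_reads = 10L),
    imprinting = list(fdr_threshold = 0.05, uniparental_fraction = 0.90,
                      null_maternal = 2 / 3, monotone_fdr = FALSE),
    accession = list(bias_fraction = 0.90, fdr_threshold = 0.05),
    bs = list(max_mismatch = 2L, unique_only = TRUE),
    dmr = list(min_meth_sites = 5L, min_reads = 10L, min_len = 40L,
               max_gap = 200L, min_diff = 0.5, alpha = 0.05),
    allele_dmr = list(window = 200L, step = 100L, min_informative = 5L,
                      min_reads = 5L, low_pct = 40, high_pct = 70,
                      flank = 2000L),
    te = list(flank = 4000L),
    cluster = list(n_perm = 1000L))
  user <- list(snp = snp, windows = windows, assign = assign,
               counts = counts, imprinting = imprinting,
               accession = accession, bs = bs, dmr = dmr,
               allele_dmr = allele_dmr, te = te, cluster = cluster)
  for (blk in names(user)) defaults[[blk]][names(user[[blk]])] <- user[[blk]]
  cfg <- list(sim = sim, outdir = outdir, params = defaults,
              write_reads = isTRUE(write_reads))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order (simulate, SNP discovery,
#' allele windows and counts, imprinting classification, methylome,
#' feature association), writes plain-text outputs into the run directory,
#' and records a funnel summary (counts surviving each filter step) plus a
#' parameter echo in `summary.json`. Reruns with an identical
#' configuration are byte-identical. When `sim$coverage_bs` is zero the
#' methylome stages are skipped with an explicit notice.
#'
#' @param config a [pipeline_config()] object.
#' @return (invisibly) a list with the main in-memory results and the
#'   summary.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  pr <- config$params
  summary <- list(seed = config$sim$seed)
  notices <- character(0)

  ## stage 1: simulate
  truth <- gen_parental_genomes(config$sim)
  write_truth(truth, file.path(out, "truth"))
  summary$n_true_snps <- nrow(truth$snps)
  summary$n_genes <- nrow(truth$genes)

  ## stage 2: SNP discovery from parental reads
  rp1 <- gen_parental_reads(config$sim, "parent1", truth)
  rp2 <- gen_parental_reads(config$sim, "parent2", truth)
  ref <- truth$genomes$parent1
  pl1 <- place_reads(rp1$reads, ref, max_mismatch = 4L, unique_only = TRUE)
  pl2 <- place_reads(rp2$reads, ref, max_mismatch = 4L, unique_only = TRUE)
  pile <- build_pileups(pl1, rp1$reads, pl2, rp2$reads, ref,
                        min_quality = pr$snp$min_quality,
                        end_margin = pr$snp$end_margin)
  snps <- call_snps(pile, min_coverage = pr$snp$min_coverage,
                    max_minor_fraction = pr$snp$max_minor_fraction,
                    min_minor_count = pr$snp$min_minor_count)
  write_snps_tsv(snps, file.path(out, "snps.tsv"))
  write_snps_vcf(snps, file.path(out, "snps.vcf"))
  summary$n_called_snps <- nrow(snps)

  ## stage 3: allele windows and reciprocal read counts
  win <- build_windows(ref, snps, flank = pr$windows$flank)
  ends <- list()
  counts_per_cross <- list()
  for (cross in c("AxB", "BxA")) {
    er <- gen_endosperm_reads(config$sim, cross, truth)
    ends[[cross]] <- er
    asn <- assign_reads(er$reads, win, max_mismatch = pr$assign$max_mismatch)
    counts_per_cross[[cross]] <- asn$counts
    summary[[paste0("n_reads_", cross)]] <- nrow(er$reads)
    summary[[paste0("n_assigned_", cross)]] <-
      sum(asn$counts$count_p1 + asn$counts$count_p2)
  }
  counts <- counts_by_cross(counts_per_cross$AxB, counts_per_cross$BxA,
                            min_reads = pr$counts$min_reads)
  long <- rbind(
    data.frame(scaffold = counts$scaffold, pos_1based = counts$pos,
               cross = "AxB", mat_count = counts$mat_AxB,
               pat_count = counts$pat_AxB, p1_count = counts$p1_AxB,
               p2_count = counts$p2_AxB, high_quality = counts$high_quality),
    data.frame(scaffold = counts$scaffold, pos_1based = counts$pos,
               cross = "BxA", mat_count = counts$mat_BxA,
               pat_count = counts$pat_BxA, p1_count = counts$p1_BxA,
               p2_count = counts$p2_BxA, high_quality = counts$high_quality))
  write_tsv_file(long[order(long$scaffold, long$pos_1based), ],
                 file.path(out, "allele_counts.tsv"))
  write_tsv_file(counts, file.path(out, "allele_counts_joint.tsv"))
  summary$n_loci_both_crosses <- nrow(counts)
  summary$n_loci_high_quality <- sum(counts$high_quality)

  ## stage 4: imprinting classification
  loci <- classify_loci(counts,
                        fdr_threshold = pr$imprinting$fdr_threshold,
                        uniparental_fraction =
                          pr$imprinting$uniparental_fraction,
                        null_maternal = pr$imprinting$null_maternal,
                        monotone_fdr = pr$imprinting$monotone_fdr)
  acc <- detect_accession_bias(counts,
                               bias_fraction = pr$accession$bias_fraction,
                               fdr_threshold = pr$accession$fdr_threshold,
                               null_maternal = pr$imprinting$null_maternal)
  loci$acc_class <- acc$acc_class[match(loci$snp_id, acc$snp_id)]
  loci$acc_class[is.na(loci$acc_class)] <- "none"
  write_tsv_file(loci, file.path(out, "imprinting_loci.tsv"))
  write_tsv_file(export_scatter(loci), file.path(out, "scatter_log2.tsv"))
  agg <- aggregate_to_genes(loci, truth$genes)
  write_tsv_file(agg$genes, file.path(out, "gene_calls.tsv"))
  if (nrow(agg$intergenic))
    write_tsv_file(agg$intergenic, file.path(out, "intergenic_loci.tsv"))
  summary$n_meg_loci <- sum(loci$class == "MEG")
  summary$n_peg_loci <- sum(loci$class == "PEG")
  summary$n_accession_loci <- sum(loci$acc_class != "none" &
                                    loci$class == "biallelic")
  meg_genes <- agg$genes$gene_id[agg$genes$class == "MEG"]
  peg_genes <- agg$genes$gene_id[agg$genes$class == "PEG"]
  imprinted <- c(meg_genes, peg_genes)
  informative <- agg$genes$gene_id
  summary$n_meg_genes <- length(meg_genes)
  summary$n_peg_genes <- length(peg_genes)

  if (config$write_reads) {
    rdir <- file.path(out, "reads")
    dir.create(rdir, showWarnings = FALSE)
    write_fastq(rp1$reads, file.path(rdir, "parent1.fastq.gz"))
    write_fastq(rp2$reads, file.path(rdir, "parent2.fastq.gz"))
    write_fastq(ends$AxB$reads, file.path(rdir, "endosperm_AxB.fastq.gz"))
    write_fastq(ends$BxA$reads, file.path(rdir, "endosperm_BxA.fastq.gz"))
  }

  ## stage 5: methylome
  results <- list(truth = truth, snps = snps, counts = counts, loci = loci,
                  gene_calls = agg$genes)
  if (config$sim$coverage_bs > 0) {
    bs_en <- gen_bisulfite_reads(config$sim, "endosperm", truth)
    bs_em <- gen_bisulfite_reads(config$sim, "embryo", truth)
    if (config$write_reads) {
      write_fastq(bs_en$reads, file.path(out, "reads",
                                         "bisulfite_endosperm.fastq.gz"))
      write_fastq(bs_em$reads, file.path(out, "reads",
                                         "bisulfite_embryo.fastq.gz"))
    }
    pl_en <- map_bisulfite_reads(bs_en$reads, ref,
                                 max_mismatch = pr$bs$max_mismatch,
                                 unique_only = pr$bs$unique_only)
    pl_em <- map_bisulfite_reads(bs_em$reads, ref,
                                 max_mismatch = pr$bs$max_mismatch,
                                 unique_only = pr$bs$unique_only)
    cy_en <- call_cytosines(pl_en, bs_en$reads, ref)
    cy_em <- call_cytosines(pl_em, bs_em$reads, ref)
    write_cytosines_bedgraph(cy_en, file.path(out,
                                              "cytosines_endosperm.tsv"))
    write_cytosines_bedgraph(cy_em, file.path(out, "cytosines_embryo.tsv"))
    dmrs <- do.call(call_dmrs, c(list(cy_en, cy_em), pr$dmr))
    write_dmrs_bed(dmrs, file.path(out, "dmrs.tsv"))
    links <- dmr_gene_overlap(dmrs, truth$genes,
                              flank = pr$allele_dmr$flank)
    write_tsv_file(links, file.path(out, "dmr_gene_links.tsv"))
    hypo <- hypomethylated_genes(dmrs, truth$genes,
                                 flank = pr$allele_dmr$flank)
    summary$n_dmrs <- nrow(dmrs)
    summary$n_hypo_genes <- length(hypo)

    ## allele-specific methylation at imprinted genes
    pl_split <- split_bisulfite_by_parent(pl_en, bs_en$reads, snps,
                                          cross = "AxB")
    cy_mat <- call_cytosines(pl_split[pl_split$parent == "maternal", ],
                             bs_en$reads, ref)
    cy_pat <- call_cytosines(pl_split[pl_split$parent == "paternal", ],
                             bs_en$reads, ref)
    target_genes <- truth$genes[truth$genes$gene_id %in% imprinted, ,
                                drop = FALSE]
    adm <- call_allele_dmrs(cy_mat, cy_pat, target_genes,
                            window = pr$allele_dmr$window,
                            step = pr$allele_dmr$step,
                            min_informative = pr$allele_dmr$min_informative,
                            min_reads = pr$allele_dmr$min_reads,
                            low_pct = pr$allele_dmr$low_pct,
                            high_pct = pr$allele_dmr$high_pct,
                            flank = pr$allele_dmr$flank)
    write_allele_dmrs(adm, file.path(out, "allele_dmrs.tsv"))
    summary$n_allele_dmrs <- nrow(adm)
    summary$n_allele_dmr_genes <- length(unique(adm$gene_id))

    hm <- hypomethylation_association(imprinted, informative, hypo)
    summary$hypomethylation_fisher_p <- hm$p_value
    results <- c(results, list(dmrs = dmrs, allele_dmrs = adm,
                               hypomethylation = hm))
  } else {
    notices <- c(notices,
                 "bisulfite coverage is 0: methylome stages skipped")
  }

  ## stage 6: feature association
  background <- setdiff(informative, imprinted)
  if (length(imprinted) && nrow(truth$tes)) {
    enr <- te_enrichment(imprinted, background, truth$genes, truth$tes,
                         flank = pr$te$flank)
    write_tsv_file(enr, file.path(out, "te_enrichment.tsv"))
    summary$te_overall_p <- enr$p_value[enr$contrast == "any_TE"]
    results$te_enrichment <- enr
  } else {
    notices <- c(notices, "no imprinted genes or no TEs: ",
                 "TE enrichment skipped")
  }
  cl <- tryCatch(
    cluster_test(imprinted, truth$genes,
                 n_perm = pr$cluster$n_perm, seed = config$sim$seed),
    error = function(e) NULL)
  if (!is.null(cl)) {
    summary$cluster_observed_distance <- cl$observed
    summary$cluster_p <- cl$p_value
    summary$n_mini_clusters <- nrow(cl$mini_clusters)
    results$cluster <- cl
  } else {
    notices <- c(notices, "cluster test undefined (fewer than two ",
                 "imprinted genes per scaffold)")
  }

  summary$notices <- notices
  report <- list(summary = summary, parameters = pr,
                 sim = unclass(config$sim)[setdiff(names(config$sim),
                                                   "te_families")])
  jsonlite::write_json(report, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (msg in notices) message(msg)
  results$summary <- summary
  invisible(results)
}

#' Audit a completed pipeline run
#'
#' Re-checks every emitted DMR against the five segmentation criteria
#' (from the written cytosine tables), every MEG/PEG locus against the FDR
#' and uniparental-fraction rules, and every allele-specific DMR against
#' the 40%/70% rule and the length arithmetic. Missing files are reported
#' per file.
#'
#' @param outdir a directory written by [run_pipeline()].
#' @return data.frame audit report (one row per check) with attribute
#'   `ok`; any violation or missing file sets `ok` to `FALSE`.
#' @export
validate_outputs <- function(outdir) {
  checks <- list()
  add <- function(stage, check, ok, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      stage = stage, check = check, ok = ok, detail = detail,
      stringsAsFactors = FALSE)
  }
  need <- c("summary.json", "snps.tsv", "allele_counts.tsv",
            "imprinting_loci.tsv", "gene_calls.tsv")
  for (f in need) {
    ok <- file.exists(file.path(outdir, f))
    add("files", f, ok, if (!ok) "missing" else "")
  }
  if (!file.exists(file.path(outdir, "summary.json"))) {
    rep <- do.call(rbind, checks)
    attr(rep, "ok") <- FALSE
    return(rep)
  }
  pars <- jsonlite::read_json(file.path(outdir, "summary.json"),
                              simplifyVector = TRUE)$parameters

  ## imprinting calls obey the selection rules
  fl <- file.path(outdir, "imprinting_loci.tsv")
  if (file.exists(fl)) {
    loci <- read_tsv_file(fl)
    thr <- pars$imprinting$fdr_threshold
    uf <- pars$imprinting$uniparental_fraction
    meg <- loci$class == "MEG"
    peg <- loci$class == "PEG"
    add("imprinting", "MEG_rules",
        all(loci$fdr_mat[meg] <= thr & loci$mat_frac_AxB[meg] >= uf &
              loci$mat_frac_BxA[meg] >= uf),
        sprintf("%d MEG loci", sum(meg)))
    add("imprinting", "PEG_rules",
        all(loci$fdr_pat[peg] <= thr & (1 - loci$mat_frac_AxB[peg]) >= uf &
              (1 - loci$mat_frac_BxA[peg]) >= uf),
        sprintf("%d PEG loci", sum(peg)))
  }

  ## DMRs obey the five criteria
  fd <- file.path(outdir, "dmrs.tsv")
  fe <- file.path(outdir, "cytosines_endosperm.tsv")
  fm <- file.path(outdir, "cytosines_embryo.tsv")
  if (file.exists(fd) && file.exists(fe) && file.exists(fm)) {
    dmrs <- read_tsv_file(fd)
    names(dmrs)[names(dmrs) == "name"] <- "name"
    dmrs$length <- dmrs$end - dmrs$start
    bg2calls <- function(path) {
      x <- read_tsv_file(path)
      data.frame(scaffold = x$scaffold, pos = x$end, strand = x$strand,
                 c_count = x$c_count, t_count = x$t_count,
                 level = x$level, stringsAsFactors = FALSE)
    }
    if (nrow(dmrs)) {
      aud <- do.call(audit_dmrs,
                     c(list(dmrs, bg2calls(fe), bg2calls(fm)), pars$dmr))
      add("dmrs", "five_criteria", all(aud$ok),
          sprintf("%d/%d segments pass", sum(aud$ok), nrow(aud)))
    } else add("dmrs", "five_criteria", TRUE, "no segments")
  }

  ## allele-specific DMRs obey the 40/70 rule and length arithmetic
  fa <- file.path(outdir, "allele_dmrs.tsv")
  if (file.exists(fa)) {
    adm <- read_tsv_file(fa)
    if (nrow(adm)) {
      lo <- pars$allele_dmr$low_pct; hi <- pars$allele_dmr$high_pct
      add("allele_dmrs", "length_arithmetic",
          all(adm$length == adm$end - adm$start) &&
            all(adm$length == adm$abs_end - adm$abs_start), "")
      add("allele_dmrs", "threshold_40_70",
          all(pmin(adm$meth_maternal_pct, adm$meth_paternal_pct) < lo &
                pmax(adm$meth_maternal_pct, adm$meth_paternal_pct) > hi),
          sprintf("%d regions", nrow(adm)))
    } else add("allele_dmrs", "threshold_40_70", TRUE, "no regions")
  }

  rep <- do.call(rbind, checks)
  attr(rep, "ok") <- all(rep$ok)
  rep
}
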