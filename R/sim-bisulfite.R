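# Bisulfite read simulation: emits reads in which each cytosine on the read
# strand survives as C with probability
#   level + (1 - level) * (1 - conversion_rate)
# where `level` is the true CpG methylation of its region (non-CpG cytosines
# have level 0 in this CpG-only model).

# per-base methylation level vector for one scaffold / sample / parental role
.meth_level_vector <- function(truth, scaffold, sample, role) {
  mr <- truth$meth_regions[truth$meth_regions$scaffold == scaffold, ]
  col <- if (sample == "embryo") "level_embryo"
  else if (role == "maternal") "level_endosperm_maternal"
  else "level_endosperm_paternal"
  bg <- mr[mr$type == "background", ]
  v <- rep(bg[[col]][1], bg$end[1])
  sp <- mr[mr$type != "background", ]
  for (r in seq_len(nrow(sp)))
    v[(sp$start[r] + 1L):sp$end[r]] <- sp[[col]][r]
  v
}

#' Simulate bisulfite reads with known methylation truth
#'
#' Reads are drawn uniformly over the genome from the maternal haplotype
#' with probability `bs_maternal_prob_endosperm` (2/3 by default, the
#' triploid dosage) in endosperm and `bs_maternal_prob_embryo` (1/2) in
#' embryo, on either strand. Unmethylated cytosines on the read strand are
#' converted to T with probability `bisulfite_conversion_rate`; methylated
#' cytosines always survive as C. CpG context is determined from the
#' emitting haplotype's own sequence.
#'
#' @param config a [sim_config()] object.
#' @param sample `"endosperm"` or `"embryo"`.
#' @param truth a `sim_truth` object.
#' @param cross cross direction of the assayed tissue (determines which
#'   line is maternal); default `"AxB"` (parent1 is the mother).
#' @return list with `reads` (data.frame `id`, `seq`, `qual`) and `origin`
#'   (per-read `id`, `scaffold`, `start0`, `strand`, `line`, `parent`,
#'   `sample`).
#' @export
gen_bisulfite_reads <- function(config, sample = c("endosperm", "embryo"),
                                truth, cross = "AxB") {
  sample <- match.arg(sample)
  stopifnot(inherits(truth, "sim_truth"))
  if (!cross %in% c("AxB", "BxA")) stop("unknown cross direction: ", cross)
  set.seed(config$seed + if (sample == "endosperm") 512927L else 611953L)
  mother <- if (cross == "AxB") "parent1" else "parent2"
  father <- if (cross == "AxB") "parent2" else "parent1"
  p_mat <- if (sample == "endosperm") config$bs_maternal_prob_endosperm
  else config$bs_maternal_prob_embryo
  conv <- config$bisulfite_conversion_rate
  L <- config$read_len

  scaffolds <- names(truth$genomes$parent1)
  slen <- nchar(truth$genomes$parent1)
  n_total <- as.integer(round(config$coverage_bs * sum(slen) / L))
  if (n_total == 0L)
    return(list(reads = data.frame(id = character(0), seq = character(0),
                                   qual = character(0)),
                origin = data.frame()))

  scaff <- sample(scaffolds, n_total, replace = TRUE, prob = slen)
  start0 <- as.integer(floor(stats::runif(n_total) *
                               (slen[scaff] - L + 1L)))
  role <- ifelse(stats::runif(n_total) < p_mat, "maternal", "paternal")
  line <- ifelse(role == "maternal", mother, father)
  strand <- ifelse(stats::runif(n_total) < 0.5, "+", "-")

  seqs <- character(n_total)
  hap_int <- lapply(c(parent1 = "parent1", parent2 = "parent2"), function(p)
    lapply(truth$genomes[[p]], seq_to_int))

  for (s in scaffolds) {
    lev <- list(maternal = .meth_level_vector(truth, s, sample, "maternal"),
                paternal = .meth_level_vector(truth, s, sample, "paternal"))
    for (ln in c("parent1", "parent2")) {
      H <- hap_int[[ln]][[s]]
      Hpad <- c(0L, H, 0L)  # 1-shifted, sentinel at both ends
      for (st in c("+", "-")) {
        sel <- which(scaff == s & line == ln & strand == st)
        if (!length(sel)) next
        rl <- ifelse(line[sel][1] == mother, "maternal", "paternal")
        V <- lev[[rl]]
        M <- outer(start0[sel] + 1L, 0:(L - 1L), "+")  # 1-based positions
        B <- H[M]; dim(B) <- dim(M)
        if (st == "+") {
          cyt <- B == 2L
          cpg <- cyt & (Hpad[M + 2L] == 3L)   # next base G
          to <- 4L                            # unconverted C -> T
        } else {
          cyt <- B == 3L                      # plus-strand G = minus-strand C
          cpg <- cyt & (Hpad[M] == 2L)        # previous base C
          to <- 1L                            # minus-strand T = plus-strand A
        }
        lvl <- matrix(0, nrow(M), ncol(M))
        lvl[cpg] <- V[M[cpg]]
        p_c <- lvl + (1 - lvl) * (1 - conv)
        convert <- cyt & (stats::runif(length(B)) >= p_c)
        B[convert] <- to
        if (st == "-") {
          B <- .INT_COMP[B[, ncol(B):1, drop = FALSE] + 1L]
          dim(B) <- dim(M)
        }
        seqs[sel] <- int_matrix_to_seqs(B)
      }
    }
  }

  ids <- .new_read_id(paste0("bs_", substr(sample, 1, 3)), n_total)
  list(reads = data.frame(id = ids, seq = seqs, qual = strrep("I", L),
                          stringsAsFactors = FALSE),
       origin = data.frame(id = ids, scaffold = scaff, start0 = start0,
                           strand = strand, line = line, parent = role,
                           sample = sample, stringsAsFactors = FALSE))
}
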