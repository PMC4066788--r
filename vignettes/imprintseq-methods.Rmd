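---
title: "Methods: detecting parent-of-origin expression and allele-specific methylation in reciprocal-cross endosperm"
author: "imprintseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imprinting detection and methylome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the numerical choices taken where
the methodology left room, and the limits of what the synthetic-data tests
demonstrate.

## 1. The dosage model and the imprinting statistic

Triploid endosperm carries two maternal and one paternal genome copy, so
if both alleles of a gene are transcribed at equal per-copy rates, a read
sampled at a diagnostic SNP is maternal with probability 2/3. Every
departure worth calling "imprinting" must be a departure from *that* null,
not from 1/2, and it must be reproduced when the cross is reversed —
otherwise it is a property of the parental line (accession), not of the
parental origin.

For each locus informative in both crosses the package computes:

* `p1 = P(X ≥ k1)`, `X ~ Binomial(n1, 2/3)` in the A×B cross, and `p2`
  analogously in B×A, as exact tail sums of the binomial mass function
  (`binom_onesided()`). Tails are accumulated from their small end to
  limit floating-point rounding; the unit tests require agreement with
  full enumeration to `1e-12` for all `n ≤ 25`.
* the joint reciprocal P-value `P = max(p1, p2)²` (`joint_p()`). This is
  the distribution function of the second-order statistic of two
  independent uniforms: under the null the joint P is again uniform, a
  property verified by a Kolmogorov–Smirnov test on 10⁵ draws.
* the rank FDR `FDR_i = P_(i) · n / i` (`fdr_rank()`), computed
  separately over the maternal and the paternal joint P-value lists.
  This literal formula is *not* monotone in the rank; the
  Benjamini–Hochberg step-up pass (`monotone = TRUE`) is provided but
  off by default, because the package reproduces the plain rank formula
  first and offers the standard correction second. Ties receive
  consecutive ranks in stable sort order.
* the uniparental filter: a MEG call additionally requires a maternal
  read fraction of at least 0.90 in *both* crosses (PEGs symmetric).
  This filter, not the FDR, does most of the work of rejecting maternal
  RNA carry-over from seed coat, which inflates the maternal fraction in
  both cross directions and therefore perfectly mimics a MEG in the test
  statistic alone. The generator can simulate this contamination
  (`maternal_contamination`) precisely so that tests can show the mimicry.

Accession-biased loci (`detect_accession_bias()`) are the line-consistent
complement: the same parental line exceeds a 0.90 read fraction in both
directions. The per-cross deviations (against 2/3 when the line is the
mother, 1/3 when it is the father) are combined with the same
`max(p1,p2)²` statistic and rank-FDR machinery; requiring the joint value
at `α` implies both per-cross P-values fall below `√α`, which is how the
package operationalises "significant in both crosses".

Locus calls aggregate to genes by unanimity: a gene's class is the common
class of its significant loci, genes with conflicting significant loci
are flagged `discordant` and excluded from MEG/PEG totals, and
significant loci outside every annotated gene body are reported as
intergenic with the distance and strand-aware side of the nearest gene.
Imprinting is annotated `complete` when the minor parent contributes zero
reads in both crosses, `partial` otherwise.

## 2. SNP discovery and allele-window read counting

Parental SNPs are called from per-site pileup summaries under four
filters: base quality (`Q > 20`), coverage (`≥ 5` filtered bases per
parent), exclusion of bases within 5 bp of a read end (the read-end
artifact margin; the methodology behind the pipeline left "read ends"
unquantified, and 5 bp is standard end-trimming), and homozygosity of
each parent. Homozygosity is likewise unquantified in the field's usual
phrasing; the package declares a site heterozygous only when the
minor-allele fraction exceeds 0.1 *and* the minor allele is seen on at
least 2 reads, so a single discordant read is treated as sequencing error.

Allele windows are 191 nt: 90 bp of genomic flank to the left of the SNP,
the SNP base (0-based offset 90) substituted with each parental allele,
and the remainder to the right. Windows truncate at scaffold edges with
the offset adjusted. Reads are assigned by ungapped full-containment
matching in both orientations with up to 4 mismatches; among candidate
placements the minimal-mismatch one wins, ties broken by leftmost
position with forward orientation first. A read is counted only if its
alignment covers the SNP and its base there equals one allele exactly; a
read spanning several SNPs is counted at each locus, unless its SNP bases
imply different parental lines at different loci, in which case it is
discarded everywhere as a chimera/error guard. Counts flow into a joint
locus table restricted to loci with reads in both crosses; loci with more
than 10 reads in both are flagged high-quality.

All read placement in the package (pileups, windows, bisulfite) uses one
deterministic engine: reads are split into `max_mismatch + 1` disjoint
seed k-mers (k ≤ 15, 2-bit integer codes), so any qualifying ungapped
placement shares at least one exact seed with the subject (pigeonhole),
and candidates are verified column-wise. This replaces short-read
aligners entirely at the package's scale and makes every placement
reproducible bit-for-bit.

## 3. The synthetic-data generator

The generator (`sim_config()`, `gen_parental_genomes()`,
`gen_endosperm_reads()`, `gen_bisulfite_reads()`) emulates the study
design the statistics were built for: two inbred parental haplotypes
differing at biallelic SNPs placed at least one read length from scaffold
edges (so every SNP supports a full window); non-overlapping unspliced
gene models with class labels (MEG / PEG / biallelic / accession-biased);
single-end 90-bp error-free reads by default (pairing adds no information
to allele counting and is therefore only reserved as a switch; an
optional uniform per-base error rate exists for robustness experiments);
reciprocal endosperm transcriptomes in which a biallelic gene's read is
maternal with probability 2/3, a MEG's with `imprint_strength`, a PEG's
with `1 − imprint_strength`, and an accession-biased gene draws from its
favoured line with `accession_strength` in both directions; and bisulfite
reads in which each cytosine on the read strand survives as C with
probability `level + (1 − level)(1 − conversion_rate)`.

The methylation landscape is piecewise: embryo at `meth_embryo` (default
0.80) everywhere; endosperm at `meth_endosperm` (default 0.45) — globally
hypomethylated relative to embryo, but deliberately *above* the 0.5 DMR
contrast so that the genome-wide hypomethylation visible in metagene
profiles does not itself segment into DMRs; strongly demethylated regions
at `meth_hypo` (default 0.05) placed in the bodies/2-kb flanks of a
configurable fraction of genes (enriched among MEGs); and
allele-differential regions inside a fraction of MEG bodies with maternal
0.05 / paternal 0.90. Allele-differential regions are seeded with four
diagnostic A/C SNPs about 75 bp apart: parent-of-origin splitting of
bisulfite reads is only possible for reads overlapping a SNP, and the A/C
pair remains unambiguous under both conversion senses (a read T matches a
C allele on the forward sense, a read A matches a G allele on the
reverse, and neither rule touches A vs C). This mirrors the biological
fact that allele-resolved methylation is only assayable near
polymorphisms. In the endosperm, bisulfite reads are drawn from the
maternal haplotype with probability 2/3 (1/2 in embryo); the maternal
draw probability is exposed as a parameter because ploidy-aware coverage
normalisation of endosperm bisulfite libraries is genuinely an open
choice.

Every read carries a truth record (parent of origin, line, gene/region,
placement), so downstream accuracy is scored exactly; identical seed and
configuration reproduce every output byte-for-byte.

What the generator does **not** emulate — and hence what green tests do
not demonstrate about real data: quality-score ramps, indels, PCR
duplicates, spliced transcripts, expression-level variation across genes,
overdispersion of allelic counts beyond binomial sampling (no
beta-binomial component), non-CpG methylation contexts, and partially
converted libraries beyond a uniform conversion rate.

## 4. The methylome procedures and their reconstruction choices

Per-cytosine calls count read C (methylated) and T (unmethylated) bases
at reference cytosines on the strand the read derives from, with CpG
context taken from the reference; only CpG-context calls are reported by
default and symmetric strand merging is an off-by-default flag. The DMR
criteria are standard, but the segmentation *algorithm* behind them is
not specified anywhere; the package's reconstruction is: restrict to
CpGs with more than 10 reads in both samples, mark sites whose level
difference reaches 0.5, and chain *consecutive* covered sites that are
all marked and sit less than 200 bp apart. An intervening covered site
that fails the difference criterion breaks the chain. This last rule is
load-bearing: at per-site depths around 20, an isolated background site
crosses the 0.5 threshold by sampling noise often enough that gap-only
chaining welds the whole genome into one segment, which then fails the
mean-difference filter and swallows every true region with it. Because
chains are runs of consecutive covered sites, the segment statistics
(mean levels, methylated-site counts, pooled χ²) cover every covered CpG
in the reported span, and `audit_dmrs()` re-derives all five criteria for
every reported segment from the raw calls. The χ² test is Pearson's on
the pooled 2×2 counts without continuity correction. Segment length is
`end − start` in 0-based half-open coordinates; spans must exceed 40 bp
and contain more than 5 methylated (c ≥ 1) CpGs in at least one sample —
`c ≥ 1` being the package's reading of "methylated site", since no level
cutoff is stated anywhere.

Allele-specific DMRs slide 200-bp windows in 100-bp steps (the step is
another unstated quantity; half-window overlap is the conventional
choice) over gene bodies ± 2 kb. A window qualifies when each allele has
at least 5 informative (covered) methylcytosines and more than 5 reads of
mean per-site depth, and one allele's percent methylation is below 40
while the other's is above 70. "More than five reads coverage" could
also be read as five distinct reads per window; the package uses mean
per-site depth, the stricter and more uniform interpretation. Overlapping
qualifying windows merge into maximal runs, which are re-summarised and
reported in both scaffold-absolute and gene-relative (TSS = 0, upstream
negative) coordinates — published summaries of such regions mix the two
frames, so the writer emits both, and in either frame the printed length
equals `end − start`.

Metagene profiles average per-cytosine levels in 200-bp bins around the
5' or 3' feature end, strand-oriented, covering the 2-kb flank and the
proximal feature body; each feature contributes its own bin mean and
features are averaged unweighted, so long, CpG-dense features do not
dominate.

## 5. Feature association

TE enrichment compares TE presence within 4-kb flanks (gene body
included; an `include_body = FALSE` flag exists because "within 4 kb
flanking regions" could be read either way) between imprinted genes and
the background of non-imprinted genes informative in both crosses — not
all annotated genes, since uninformative genes never had a chance to be
called. One overall presence test and one per family, all with the
package's exact two-sided Fisher test (probability-mass rule, not
doubling — variants differ in the third decimal, which is why the rule is
pinned and enumeratively tested for every table total up to 40);
per-family P-values are also reported BH-adjusted. The mini-cluster test
statistic is the mean midpoint distance between consecutive imprinted
genes per scaffold, with a permutation null drawing the same number of
genes uniformly without replacement from the informative set and the
add-one-smoothed P `(1 + #{null ≤ obs}) / (n_perm + 1)`; runs of two or
more imprinted genes with no intervening informative gene are reported as
mini-clusters. The statistic is undefined (and the function refuses to
run) when no scaffold carries two imprinted genes.

## 6. Conventions, degenerate inputs, and tie-breaks

* Coordinates are 0-based half-open internally (genes, TEs, DMRs,
  windows); 1-based positions appear only for SNPs and per-cytosine
  calls at TSV/VCF boundaries, and every writer documents its frame.
  `length = end − start` everywhere.
* Thresholds follow their sources: coverage filters are strict
  (`> 10` reads per cytosine, `> 10` reads for high-quality loci,
  `> 5` methylated sites, `length > 40`), selection cutoffs are
  inclusive (`FDR ≤ 0.05`, fraction `≥ 0.90`, site difference `≥ 0.5`,
  χ² `P ≤ 0.05`), and the 40/70 allele rule is strict on both arms.
* Degenerate inputs: zero SNPs, zero qualifying sites, empty read sets
  and empty imprinted sets all return empty results rather than errors;
  loci with zero reads in a cross are excluded with a message; a
  zero-margin 2×2 table has Fisher P exactly 1; `n_perm < 1` and
  undefined cluster statistics are rejected.
* Tie-breaks are deterministic: minimal mismatches, then leftmost
  placement, then forward strand; consensus base by fixed A,C,G,T order
  on count ties; stable sort ranks for tied P-values.
* The Fisher mass comparison uses a `1 + 1e-7` relative tolerance so
  exactly tied tail tables (symmetric tables) are included regardless of
  floating-point noise, matching the convention of standard
  implementations.

## 7. Problem sizes used by the test-suite

The shipped tests run the generator at sizes chosen to make the measured
error rates meaningful while keeping the suite quick on one CPU: the
parameter-recovery experiment uses 2,220 genes (200 MEGs, 20 PEGs, 2,000
biallelic) on four 250-kb scaffolds with imprint strength 0.97 and 50
reads per SNP per cross (about 290,000 reads end-to-end), and requires
MEG/PEG recall ≥ 0.9 with precision ≥ 0.95 at gene level; the DMR
recovery experiment uses a 150-kb scaffold with ~25 truth regions of 0.8
methylation contrast at 30× bisulfite coverage and requires recall
≥ 0.9; the false-discovery simulation uses 5,000 null plus 500 imprinted
loci at 50 reads per locus per cross over 50 replicates. The acceptance
script (`scripts/acceptance.R`) re-runs the last of these from scratch
at any seed.

## 8. Known limitations

* The binomial model has no overdispersion component; replicate-level
  biological variation in allelic ratios will inflate significance on
  real data. The 90% filter mitigates but does not remove this.
* Ungapped matching cannot place reads across indels or splice
  junctions; real RNA-seq requires a spliced aligner upstream, with this
  package consuming the resulting counts or pileups.
* Only CpG methylation is modelled and called; CHG/CHH contexts, which
  matter in plants, are out of scope.
* The rank FDR without the monotone pass can order selections
  non-monotonically in P; users wanting guaranteed BH behaviour should
  set `monotone_fdr = TRUE`.
* The DMR segmentation is a reconstruction; other reasonable algorithms
  (HMMs, smoothing-based callers) would draw different boundaries around
  the same regions.
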