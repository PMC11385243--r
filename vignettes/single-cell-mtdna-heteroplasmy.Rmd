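---
title: "Quantifying somatic mtDNA heteroplasmy in single cells"
author: "scMitoHet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying somatic mtDNA heteroplasmy in single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scMitoHet)
```

## The problem

Human mitochondrial DNA (mtDNA) is polyploid: a single cell carries on the
order of hundreds of genome copies, and a variant may sit on all of them
(homoplasmy) or on a fraction (heteroplasmy). Somatic heteroplasmies arise
in stem-cell compartments, drift in fraction through replication and cell
division, and can reach phenotypically relevant levels. Measuring them in
single cells requires deep sequencing of the 16,569 bp circular genome and
a filtering strategy that separates genuine cell-private variation from
germline haplotype, shared (sample-level) heteroplasmy, sequencing error
and cross-cell contamination.

scMitoHet implements that strategy starting from per-position allele
counts, one table per single cell plus one per *consensus* sample (a bulk
lysate of the same tissue aliquot that serves as the per-individual
germline reference). Read-level processing (alignment, duplicate marking,
base-quality filtering) is upstream of this package: its effect is
summarized by the per-base error rate parameter.

## The genome model

Coordinates are 1-based and inclusive ("m.N" convention) and position
arithmetic is modular on the 16,569 bp circle, so `wrapPosition(16570)` is
position 1. The packaged locus annotation carries the genuine NC_012920.1
feature coordinates: the D-loop/control region (m.16024–576, wrapping the
origin), 2 rRNAs, 22 tRNAs and 13 protein-coding genes, with MT-ND6 and
eight tRNAs on the light strand.

Two details deserve care:

* **Overlapping genes.** MT-ATP8/MT-ATP6, MT-ND4L/MT-ND4 and
  MT-ATP6/MT-CO3 overlap. For *burden counting* every position must belong
  to at most one class, so overlaps resolve by first-in-genome-order
  precedence. For *consequence annotation* all overlapping frames are
  evaluated and the most severe consequence is reported.
* **Normalization constants.** Burden normalization divides per-cell
  counts by fixed locus-class lengths — D-loop 1124, rRNA 2511, tRNA 1486,
  protein-coding 11,382 bp — rather than lengths recomputed from the
  interval table. The arithmetic lengths differ slightly (the D-loop
  interval spans 1122 bp, the summed tRNAs 1508 bp, the summed
  protein-coding genes 11,395 bp); `computedLocusLengths()` exposes both,
  and a regression test freezes the residuals so any annotation edit that
  changes them is caught. The constants are kept for comparability, since
  normalized burdens are only ever compared to each other.

Low-complexity regions are excluded from comparative analysis via a
`MaskSet` (defaults m.66–71, m.300–316, m.513–525, m.3106–3107,
m.12418–12425, m.16181–16194; inclusive ends). One listed region is
sometimes printed with an end coordinate beyond the genome length
(21,425); the packaged default reads it as 12,418–12,425, the only
physically possible interpretation, and the whole set is user-overridable
— except the rCRS placeholder positions 3,106–3,107, which are masked
under every configuration because the reference itself is undefined there.

The packaged FASTA is a **synthetic stand-in sequence** (rCRS-like base
composition, fixed generation seed): the genuine NC_012920.1 sequence is
not redistributed with the package. Every sequence-dependent computation
(codon context, consequence calling) is defined relative to whichever
reference the user loads, and all tests verify consistency between two
independent routes over the same sequence, so supplying the real rCRS
FASTA to `mtReference()` is sufficient to work on real data.

## Calling and thresholds

The heteroplasmic fraction of a substitution is

$$\mathrm{HF} = \frac{d_{alt}}{d_{alt} + d_{ref}},$$

the variant allele depth relative to the reference allele depth. Reads
supporting other alternate bases do not enter the denominator; an
`alt/depth` variant is available via the `denominator` option. Zygosity
follows the strict printed thresholds: homoplasmic iff HF > 0.98,
sub-threshold iff HF ≤ 0.02, heteroplasmic otherwise — so HF = 0.98 is
heteroplasmic and HF = 0.02 sub-threshold.

`callVariants()` emits *every* non-reference base with read support, so
the sub-threshold tail is available for HF histograms; the 0.02 analysis
floor acts later as a filter, not at emission. Each call carries a
binomial error p-value (observed alt count versus
$\mathrm{Bin}(d, e)$ at the assumed error rate $e$) and a low-confidence
flag for sites under `minSiteDepth` (default 100×, an in-package choice:
deep amplicon data rarely goes lower except in dropout regions, where HF
estimates are meaningless anyway).

Coverage QC keeps a cell when at least 99% of the genome is covered at
≥ 1500×, evaluated as exact threshold arithmetic on the 16,569 positions.

## Somatic identification

A variant (position, alt) in cell $c$ is **somatic** when

1. it is heteroplasmic in $c$ with 0.02 < HF < 0.98 (strict);
2. it is *absent* from the consensus; and
3. it is *absent* from every other cell of the same sample.

"Absent" is operationalized as HF below the 0.02 detection floor in the
comparator, not as zero alt reads — zero-read absence is unattainable
under sequencing error. Only cells passing QC participate in the privacy
comparison (a failed cell cannot veto a variant), and cells failing the
homology check are dropped before somatic identification. With a single
cell the privacy criterion degenerates and only (1)–(2) apply, with a
warning.

Two numerical guards matter at near-homoplasmic sites, where the
reference allele depth is itself error-level:

* a lone miscalled read can reach HF ≈ 1 under the alt/(alt+ref)
  definition, so *homoplasmy sharing* additionally requires the allele to
  carry the majority of all reads at the site;
* somatic candidacy requires the binomial error p-value to fall below
  `errorAlpha` (default 10⁻³), so calls explainable by sequencing error
  never enter somatic sets however their HF lands.

The homology check itself mirrors haplogroup comparison without naming
haplogroups: the fraction of the consensus homoplasmic set also
homoplasmic in the cell must exceed 0.99; a contaminating cell carrying a
different germline haplotype fails it decisively.

`identifySomatic()` also retains the *pre-floor* list (HF > 0, same
consensus/privacy criteria, no error-p filter) so the full distribution —
dominated by error-level calls below 0.02 — can be plotted against the
detection floor with `plotHFHistogram()`.

## Consequence annotation

Protein-level consequences are computed in-house: only substitution
synonymy on a fixed, fully known 13-gene annotation is needed, and the
vertebrate mitochondrial genetic code (translation table 2: AGA/AGG stop,
ATA Met, TGA Trp) is hard-coded. For a variant in a coding gene the
reference codon is located from the gene's frame anchor, read 5'→3' on
the coding strand (reverse-complemented for light-strand genes), mutated,
and both codons translated; stop gain/loss is sub-flagged. Genes whose
length is not a multiple of three end in an incomplete stop completed by
polyadenylation; their trailing codon is translated with poly-A padding
and the affected 1–2 positions carry an `incompleteStopCaveat` flag.
The test suite checks 100% agreement against an independent brute-force
oracle that rebuilds the entire mutated coding sequence and compares
whole-protein translations through the Biostrings machinery, including
light-strand and code-idiosyncrasy cases.

Pathogenicity is classification, not computation: MutPred and APOGEE 2
scores are consumed as lookup tables with strict thresholds (> 0.50 and
> 0.38). Variants absent from a table are *unscored* (`NA`), never given
a default, and are excluded from pathogenic-fraction denominators while
their count is always reported alongside.

## Statistics

* **Burdens** (counts per cell per locus class, normalized by the printed
  constants) are compared by one-way ANOVA plus Dunnett's many-to-one
  comparisons against a reference group — the first sample for
  between-sample comparisons, the D-loop for between-locus comparisons.
  Counts are treated as continuous, matching how such data are usually
  plotted and tested; a Kruskal–Wallis alternative is one option away.
* **HF distributions** use variants as the observational unit (a cell
  without variants has no HF); with exactly two groups (non-synonymous
  versus synonymous) the two-sided Mann–Whitney U test with normal
  approximation is used instead.
* **Dunnett's test** is implemented in-package as the single-step
  many-to-one multivariate-t procedure, with correlation
  $\rho_{ij} = \sqrt{n_i n_j / ((n_i+n_0)(n_j+n_0))}$ and the Genz–Bretz
  integration at absolute tolerance 10⁻⁶ by default. It is cross-checked
  against an independent implementation in the tests, and its family-wise
  type-I error is verified by null simulation.
* **Score shapes** report kurtosis in *both* conventions, labelled
  `kurtosisExcess` (normal = 0) and `kurtosisPearson` (normal = 3),
  because a bare "kurtosis" value is ambiguous between them; tests use
  the excess convention. Shapiro–Wilk requires 8 ≤ n ≤ 5000 (larger
  samples are truncated to the first 5000 with the count reported).
* All p-values are two-sided and reported unadjusted across analyses, a
  deliberate choice for discovery-style questions with non-independent
  variables; only Dunnett's single-step adjustment (internal to the
  procedure) is applied.

## The simulator

`simulateSample()` generates data with the statistical structure the
analysis assumes, plus ground truth for recovery testing. Per sample:

* a homoplasmic **germline haplotype** (default 25 variants, in the range
  of a typical European-lineage divergence from the reference);
* 1–7 **shared heteroplasmies** with sample-level fractions uniform in
  [0.02, 0.94]; each cell's copy drifts independently;
* **private somatic variants** per cell (Poisson, default mean 40),
  placed without replacement across the sample's cells on unmasked
  annotated positions, D-loop positions upweighted (default ×6) to
  emulate the control-region hotspot; initial fractions follow
  0.97·Beta(1, 30) + 0.03·U(0.3, 0.9) — mostly below 0.25 with rare
  high-fraction variants — and then undergo Wright–Fisher drift.

Drift resamples the variant copy count as Binomial(N, f) per generation
at N = 800 copies (the mtDNA content scale of bone-marrow mesenchymal
stem cells) over a default 20 generations; the closed-form variance
$f_0(1-f_0)(1-(1-1/N)^t)$ is the test oracle. Discrete Wright–Fisher
steps were chosen over a Moran process for exactly that closed form.

Counts are multinomial per position: depth from a negative binomial
(default mean 3000, size 150 — deep amplicon sequencing with mild
overdispersion, keeping genuine coverage QC passes at the 1500× rule),
alt probability $h(1-e) + (1-h)e/3$, symmetric error $e/3$ to each other
base (default e = 0.001, the residual error after upstream Q30
filtering). The consensus is generated from pooled truth: germline at
1.0, shared heteroplasmies at the sample fraction, private somatics
diluted to $h/n_{cells}$. A configurable number of cells receive a
low-coverage window spanning 5% of the genome to exercise the QC failure
path. All randomness flows from one mandatory seed; identical seeds yield
byte-identical output files.

**Ground truth and recoverability.** The truth table flags a private
variant `expectedSomatic` when its cell fraction lies strictly inside
(0.02, 0.98) *and* its diluted consensus fraction is below the 0.02
detection floor. The second clause is part of the somatic definition
itself: a variant at fraction 0.30 in one of ten cells sits at 0.03 in
the pooled consensus and is, by definition, not consensus-absent. Recall
is therefore measured against recoverable truth; precision counts any
called variant matching a true private somatic variant of that cell.

**What the simulator does not model**: read-level artifacts (strand
bias, context-dependent error, alignment slippage around homopolymers),
NUMT contamination, indels and structural variants, amplicon coverage
periodicity, and selection during drift. Passing recovery tests on
simulated data therefore demonstrates the correctness of the filtering
logic under the stated error model, not robustness to every failure mode
of real amplicon sequencing — the mask set exists precisely because some
of those failure modes are positional and known.

**Fabricated score tables** (`simulateScoreTables()`) draw
MutPred-like scores from 0.8·Beta(6, 2) + 0.2·Beta(2, 6) and more
conservative APOGEE2-like scores from 0.5·Beta(5, 3) + 0.5·Beta(1.5, 5),
emulating predictor distributions skewed toward pathogenicity with
APOGEE 2 the stricter of the two; 5% of variants are left unscored to
exercise the unscored contract. These are stand-ins for testing shape
statistics, not models of the predictors.

## Problem sizes and tolerances

The shipped tests run at sizes chosen to make binomial/sampling noise
negligible relative to the asserted tolerances: cohort recovery uses 13
samples × 8 cells at 2000× (about 900 recoverable truth variants);
drift uses 10,000 trajectories (variance within 10% of closed form);
consequence agreement uses 1000 random coding substitutions (exact
agreement required); test calibration uses 1000 null replicates per
procedure (empirical size within three binomial standard errors of
0.05). The Dunnett cross-check tolerates 2×10⁻³ on p-values — the
quasi-Monte-Carlo integration error of the reference implementation —
and 10⁻⁸ on the t-statistics.

## Known limitations

* The caller is count-based and single-sample; it does not reproduce
  caller-arbitration schemes that reconcile two independent callers, nor
  strand-bias filters (strand information is absent from count tables).
* The homology check is a proxy for ancestry comparison, not a formal
  contamination deconvolution; a low-level mixture below the homoplasmy
  threshold will not be flagged.
* Cells are treated as independent within samples; no mixed-effects
  structure (cells nested in individuals) is modelled, mirroring the
  analysis this package reproduces.
* tRNA/rRNA variants receive locus annotation but no pathogenicity
  scoring: the consumed predictors score protein-coding variants only.
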