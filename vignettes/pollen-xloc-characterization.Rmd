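---
title: "Characterizing pollen-expressed intergenic loci: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing pollen-expressed intergenic loci: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

RNA-seq of the male gametophyte routinely assembles transcriptional units
that no reference annotation contains: the pollen transcriptome is
enriched for young, lineage-specific, highly tissue-restricted genes,
most of them long noncoding RNAs (lncRNAs) and some carrying small ORFs
with micropeptide potential. Characterizing such a cohort means answering
a fixed battery of questions per locus — is it really unannotated, what
biotype is it, where and how strongly is it expressed, is it
stress-responsive, how old is it phylogenetically, is it a miRNA target,
and is it translated? `pollenxloc` implements that battery as composable,
individually tested operations plus an orchestrating pipeline, and pairs
it with a synthetic-data generator whose ground truth exercises every
decision rule.

## Data model

Coordinates are 1-based and closed throughout, the IRanges/GenomicRanges
convention, which also matches GTF/GFF3 so no conversion happens at I/O.
All interval algebra (overlap, nearest-distance) is delegated to
GenomicRanges; "overlap" always means at least one shared base pair.
Transcript models are exon tables (`tcons_id`, `chrom`, `start`, `end`,
`strand`), with `"*"` denoting the unknown strand of non-strand-specific
libraries. Annotations are `GRanges` tagged `protein_coding`,
`other_gene` or `TE`.

## Locus grouping

Two transcripts belong to one locus iff they are connected by a chain of
pairwise exonic overlaps on the same chromosome (`group_into_loci`,
implemented as union-find over the exon overlap graph). A `+` and a `-`
transcript never merge directly; an unknown-strand transcript merges with
either. Locus identifiers are assigned by leftmost genomic coordinate, so
regrouping is idempotent and deterministic.

## Novelty and biotype rules

* **Novelty.** Any exonic base shared with a gene body of the primary
  reference makes a locus `known` (such loci are not part of an XLOC
  cohort); otherwise overlap with the updated reference makes it
  `recent`, else `novel`. Gene bodies (not exons of the neighbours) are
  used — the conservative reading of "intergenic".
* **Class.** With spliced length $L$ and longest ORF $p$ (aa):
  $L < 200$ nt → `short`; else $p \ge 100$ aa → `orf_coding`; else
  `lncRNA`, refined to `lincRNA` iff the locus lies $\ge 500$ bp from the
  nearest protein-coding gene **and** no exon overlaps a transposable
  element. A locus is classified by its longest transcript.
* **Boundary decisions** (the definitions quoted in the field leave gaps,
  so the package fixes them explicitly):
  * exactly 200 nt is *not* short — the long-RNA criterion is "longer
    than 200", the short criterion "shorter than 200", and the tie goes
    to lncRNA;
  * exactly 500 bp away satisfies the lincRNA distance test ("500 or
    more bp away");
  * an ORF requires both an ATG and an in-frame stop inside the
    transcript; `peptide_length` excludes the stop codon, so a 100-aa
    smORF spans 303 nt;
  * unknown-strand transcripts are scanned on both strands and the
    maximal ORF is used; stranded transcripts are scanned forward only;
  * protein-homology identity bins close the published 96/97 gap at 97:
    `full` at identity ≥ 97, `partial` in [50, 97), `none` below 50 or
    when the best hit fails E ≤ 1e−7. The best hit is the lowest
    E-value, ties broken by identity.

## Expression statistics

RPM uses the *declared* library size from the sample sheet (total
sequenced reads), not the column sum, matching "reads per million reads".
All threshold calls operate on arithmetic condition means of replicate
RPM. PEX means mean RPM > 1 in at least one condition of a pollen dataset
(the published rule is ambiguous between "either" and "both" conditions;
"either" is chosen and fixed here). hPEX uses > 10, presence ≥ 0.05. PSX
requires PEX somewhere in pollen and mean RPM below `rpm_sporo_max`
(default 1, the published cutoff) in *every* condition of *every*
sporophytic dataset. The sporophytic cutoff is deliberately a separate
parameter: were it tied to `rpm_pex`, raising the PEX threshold would
loosen the silence test and the monotonicity property (stricter
thresholds never enlarge called sets) would fail.

### The NB Wald test

The published analysis used an external DE package; `pollenxloc`
re-implements a minimal, self-contained negative-binomial Wald test with
the same decision rule and no LFC shrinkage, outlier refitting or
independent filtering:

1. filter loci with < 10 counts in all samples;
2. median-of-ratios size factors (median over all-positive loci of
   count/row-geometric-mean; an informative error suggests a
   pseudo-reference when no such locus exists);
3. per locus, a dispersion $\alpha$ shared across conditions by the
   method of moments on normalized counts. Raw per-locus moment
   estimates are extremely noisy at $n = 3$ and produced an inflated
   null type-I error in development, so each estimate is floored at the
   cohort *median* dispersion (a deliberately simple analogue of the
   empirical-Bayes shrinkage mature DE packages use) and at $10^{-8}$;
4. $\mathrm{LFC} = \log_2\frac{\bar x_{HS} + 1/2}{\bar x_{ctl} + 1/2}$,
   with the delta-method standard error
   $SE^2 = \frac{1}{\ln^2 2}\sum_c \frac{\mu_c + \alpha\mu_c^2}{n_c(\mu_c + 1/2)^2}$,
   a two-sided normal p-value, and BH adjustment per dataset
   ("correction within each comparison"). Loci with all-zero counts in
   both conditions get NA statistics and are excluded from BH;
5. DEX ⟺ $|\mathrm{LFC}| \ge 1$ and adjusted $p < 0.05$ (strict
   inequality, so $p_{adj} = 0.05$ is not called).

The acceptance suite verifies calibration (empirical type-I error within
[0.025, 0.10] at nominal 0.05 on a 2,000-locus null with dispersion 0.05
and $n=3$) and power (≥ 0.8 for planted $|\mathrm{LFC}| = 2$ at base mean
100), and one test cross-checks fold changes and calls against an
established NB DE implementation on the same counts.

## Phylostrata

Lineages are semicolon-joined root-to-tip node lists; the lineage file is
authoritative and compared positionally, with no taxonomy
reconciliation. After excluding self-species hits and hits with
E > 1e−5, each hit maps to the LCA of its subject lineage with the focal
lineage, and the locus stratum is the root-most such node — the oldest
node at which a homolog is detectable. No passing hits ⇒ species-specific.
Adding hits can only move a stratum root-ward (tested as a property). The
published two-pass search (within-family minus focal species; outside the
family) is merged into one pass-agnostic hit table, which yields the same
assignment. The node set of the x-axis is data-driven from the lineage
file rather than hard-coded.

## miRNA target scoring

Only the tool name and the ≤ 3 expectation cutoff are fixed by the
published analysis; the scoring constants here are the normative ones for
this artifact: per aligned position, 0 for a Watson–Crick match, 0.5 for
G:U, 1.0 for a mismatch, 2.0 for a gap, doubled when the miRNA position
(from its 5′ end) lies in the seed span 2–13. The search covers every
ungapped window plus every window with a single one-base bulge on either
side of the duplex (at most one gap, the bounded-band simplification);
a bulged target base is charged at the seed status of the miRNA position
3′ of the gap, a bulged miRNA base at its own position. The best site per
(miRNA, transcript) is reported, ties broken by the 5′-most site, only at
expectation ≤ 3. Any non-match among miRNA positions 9–11 — the cleavage
site — calls `translational_inhibition`, otherwise `cleavage`. The
vectorized scanner is verified against an exhaustive window oracle, and
lowering the cutoff can only remove hits (monotone filtering).

## Translation likelihood

P-sites are read 5′ ends shifted by a read-length-specific offset; reads
with unknown lengths are dropped and counted. The published pipeline's
wavelet denoising is replaced by a documented, configurable threshold: a
position with count ≥ `pf_min_count` (default 1) is a periodic-footprint
(PF) P-site, and PF *positions* (not reads) are tallied per frame
relative to an anchor (default the transcript 5′ end; the ORF start can
be supplied when one is annotated — frame identity shifts, but the
translated/untranslated decision does not). A transcript is considered at
RPF abundance ≥ 1 RPM in at least one condition and called translated at
≥ 5 PF P-sites in one frame ("positions" resolves the published
wording's ambiguity between positions and reads, consistent with
footprint plots); two frames at ≥ 5 flag `multi_frame`, the signature of
retained introns. An optional exact binomial enrichment p-value is
provided: $p = \min(1,\ 3\,P(X \ge \max F))$ with
$X \sim \mathrm{Bin}(\sum F, 1/3)$ — the factor 3 adjusts for selecting
the maximal frame, and a uniform (3,3,3) profile gives $p = 1$; an empty
profile returns NA ("no signal").

## The synthetic study generator

`simulate_xloc_study()` emulates the motivating study design, which is
also its default configuration: 312 intergenic loci; class mix in the
published proportions 3 : 248 : 38 : 29 (short : lncRNA : lincRNA :
ORF-coding — these tallies over-count the cohort slightly, so they are
used as normalized proportions); 246/312 recently annotated; 41
multi-isoform loci; four datasets (MP_HS, MP_Hot/Cold, GP_HS pollen;
CL_HS cauline leaf) at the reported mean depths of 63.7, 30.7, 101.6 and
60.7 million reads; three replicates per condition; 230/312
pollen-specific; 61/312 expressed in germinating pollen; NB dispersion
0.05 and planted |log₂FC| = 2 on a 15% DE fraction per pollen dataset
(independent draws across three datasets give a ~39% union, matching the
reported ~42% responsive loci). Library sizes are jittered ±10% so size
factors differ from 1. Where the study reports no value (per-replicate
depth distributions, baseline RPM spread, P-site rates), defaults were
chosen once as field-plausible and are documented in `?sim_config`.

Design points worth knowing:

* **Single RNG stream, fixed order.** One seed; layout/classes, genome
  bases, transcript sequences, counts per dataset, P-site tracks,
  homology and protein tables draw in that order, so outputs are
  reproducible and later stages never perturb earlier ones.
* **Sequence construction.** Chromosomes are i.i.d. uniform A/C/G/T;
  planted content (ORFs, miRNA sites) is written explicitly into the
  spliced sequences and spliced back into the genome across exons.
  Non-coding loci are rejection-sampled until no ORF ≥ 100 aa exists on
  either strand, and ORF-coding loci until the planted ORF is the unique
  one at or above the threshold — ground truth is guaranteed, not merely
  probable. Extra isoforms are truncations of the primary transcript, so
  they can never introduce new ORFs.
* **Placement.** Features are laid out left to right with randomized
  gaps: lincRNA loci get ≥ 600 bp clearance on both sides; near-gene
  lncRNA violators are placed 80–400 bp behind a partner gene; TE-class
  violators get a TE overlapping one exon; remaining TEs are intergenic
  blocks. An undersized genome raises a sizing error. TE-overlap
  violations are capped by the TE budget (`n_te = 0` forces all lncRNA
  violations to gene proximity).
* **Guard bands.** Planted expression means avoid a ±1.4× band around
  the 1- and 10-RPM thresholds, so threshold calls on simulated data have
  a well-defined truth; the noiseless preset (`sim_config_noiseless`)
  additionally uses near-Poisson counts (dispersion $10^{-6}$), zero
  off-frame P-site noise and a strong in-frame signal, making exact
  (0-error) ground-truth recovery a meaningful requirement rather than a
  probabilistic one.
* **Homology tables.** Passing hits (E ≤ 1e−5) come only from taxa whose
  LCA with the focal species equals the planted stratum; decoy rows with
  failing E-values (possibly from older nodes) and self-species hits
  exercise the filters.

What the generator does **not** emulate: read-level noise (no FASTQ,
alignment or assembly artifacts), splice-graph realism, sequence
evolution, expression correlation across datasets, multi-mapping and
counting ambiguity, or annotation errors. Passing the recovery tests
therefore demonstrates that the decision rules are implemented exactly
as specified — not that the rules themselves are robust to upstream
noise in real data.

## Problem sizes and runtime choices

The recovery layer of the acceptance suite uses a 500-locus noiseless
cohort; DE calibration and power use 2,000-locus simulations at $n = 3$;
oracle-equivalence properties use 300 random instances per primitive.
These sizes give stable empirical rates while keeping a full validation
run in the minutes range on a single core.

## Known limitations

* The NB test is intentionally minimal; for small effects near the
  detection boundary a mature DE package with dispersion-trend shrinkage
  will be better calibrated locus-by-locus.
* Antisense (NAT) classification is out of scope — with
  non-strand-specific pollen libraries it cannot be called, matching the
  cohort definition this package targets.
* The miRNA search allows at most one single-base bulge and no
  target-site accessibility term.
* PF P-site calling replaces wavelet denoising with plain count
  thresholding; with noisy RPF data, `pf_min_count` should be raised
  (the published decision rule consumes only per-frame PF counts, which
  this preserves).
* `recount_from_supplementary()` recomputes headline counts from any
  per-locus table through a user-editable column schema; published
  supplementary tables must be exported to TSV first, and columns absent
  from a table simply yield no corresponding count.
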