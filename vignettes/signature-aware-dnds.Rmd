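---
title: "Methods: signature-aware dN/dS for somatic mutation catalogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature-aware dN/dS for somatic mutation catalogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigdnds)
```

## The estimand and the three estimators

For a gene with `n` observed non-synonymous and `s` synonymous coding
point mutations across samples, `N` non-synonymous and `S` synonymous
sites, the **basic** estimator is

$$\mathrm{dN/dS} = \frac{n/N}{s/S} = \frac{n}{s}\cdot\frac{S}{N}.$$

Sites are counted by simulating all three possible point mutations at
every CDS position, so `N + S = 9 L` for a gene of `L` codons with
defined context everywhere. The basic form assumes uniform substitution
probabilities. The **corrected** estimator replaces the site counts by
signature-expected mutation counts,

$$\mathrm{corrected\ dN/dS} = \frac{n/s}{N_{MS}/S_{MS}}, \qquad
N_{MS} = \sum_i N_i P_i,\quad S_{MS} = \sum_i S_i P_i,$$

where $i$ runs over the 96 trinucleotide substitution classes, $N_i$ and
$S_i$ are the gene's per-class counts of possible non-synonymous and
synonymous changes, and $P_i$ is the signature probability of class $i$.
The **simulated** dN/dS, $(N_{MS}/S_{MS})/(N/S)$, isolates the bias: it
is the dN/dS a gene is expected to display under the signature alone,
with no selection, and the three quantities factor exactly as
`corrected = basic / simulated` wherever all are defined. Under a uniform
profile $P_i = 1/96$ the weights cancel and the corrected estimator
reduces to the basic one identically.

### Assumptions

* Mutations are independent point substitutions; indels, dinucleotide
  events and copy number are out of scope.
* Synonymous mutations are selectively neutral (the usual dN/dS premise).
* The signature estimated from the catalog reflects the mutational
  process, i.e. selection does not materially distort the observed class
  frequencies. This matters: see *Selection recovery* below.

## Substitution classes and strand normalization

Classes follow the conventional pyrimidine-referenced taxonomy: 6 base
substitutions (C>A, C>G, C>T, T>A, T>C, T>G) times 16 combinations of the
immediate 5' and 3' bases, labelled `A[C>A]A` … `T[T>G]T`. A
purine-referenced record is converted to its complementary-base
representation; because the strand flip reverses 5' and 3', the flanking
bases are complemented **and swapped**. The class order is fixed
lexicographically (class, then upstream `A<C<G<T`, then downstream) so
that profile vectors are reproducible run to run; no ordering is implied
by the science, only by the need for stable serialization.

Context at the CDS termini is the transcript-adjacent base supplied with
the sequence (`flank5=`/`flank3=` tokens in the FASTA header), not the
genomic intronic base; the package is deliberately self-contained in
transcript coordinates and carries no genome build. Positions whose
context contains `N` are excluded from the site spectrum *and* their
mutations are rejected during annotation, keeping numerator and
denominator on the same site set. A genomic-coordinate adapter
(`maf_to_mutations()`) is the documented extension point for users coming
from standard MAF files.

## Consequence annotation

Each single-base codon change is classified as synonymous, missense,
stopgain or stoploss under the standard genetic code (NCBI table 1; no
mitochondrial or alternative codes, this being a human nuclear-exome
method). All dN/dS tallies use the binary split: stopgain and stoploss
count as non-synonymous — they alter the protein — and stop-to-stop
counts as synonymous. This binary fold is a package decision (annotation
tools report finer categories); it is exposed in `consequence_impact()`
rather than buried in the counting code.

The hydrophobic amino-acid set used for the membrane-protein mechanism is
Ala, Gly, Ile, Leu, Phe, Val, Pro, Met, Trp. Gly and Pro are included
deliberately even though some hydrophobicity scales disagree; the set is
the one relevant to the transmembrane-composition argument. All 16 NTN
codons (T at the second position) encode residues from this set, against
13 of the other 48 codons:

```{r census}
hydrophobic_codon_census()
```

Combined with the concentration of the genetic code's redundancy in the
C>T and T>C classes —

```{r syndist}
synonymous_class_distribution()
```

— this is the whole mechanism by which a C>T-dominated signature mimics
purifying selection preferentially in hydrophobic (membrane) proteins.

## Statistical testing

Purifying selection is tested per gene with a one-tailed binomial test:
with $n+s$ coding mutations and null non-synonymous proportion $\pi$, the
p-value is $P(X \le n)$, $X \sim \mathrm{Bin}(n+s, \pi)$. The null
proportion matches the metric under test: $N/(N+S)$ for the basic metric,
$N_{MS}/(N_{MS}+S_{MS})$ for the corrected one (the default). An upper
tail is available behind `alternative = "greater"` for positive
selection, but the package's validation focuses on the lower tail.
Q-values are Benjamini–Hochberg across the analyzed genes; gene inclusion
requires at least 10 coding point mutations (inclusive), applied before
any ratio computation. Undefined ratios ($s = 0$ or $S_{MS} = 0$) are
reported as `NA`, excluded from medians, and counted in the `glance()`
summary — silent infinities would corrupt cohort medians.

Gene-set enrichment uses a two-sided Fisher's exact test on the 2×2
hit/in-set table over the user-supplied background, BH-corrected across
sets. The reported odds ratio is the sample odds ratio $ad/bc$; the
p-value comes from the exact test.

## The probability sweep

`signature_sweep()` varies one of the six class probabilities over a grid
while the other five classes share the remaining mass. "Keeping the other
classes constant" is ambiguous between an equal split and a proportional
rescaling of a base profile; the default is the equal split $(1-p)/5$,
with `renormalization = "proportional"` exposing the alternative. At
$p = 1/6$ the equal split reproduces the uniform profile exactly, which
pins the sweep to 1 at that point and makes the two conventions directly
comparable.

## The synthetic-cohort generator

`simulate_genes()` draws in-frame CDSs with no internal stop codons. The
number of NTN codons per gene is the rounded target fraction, placed at
random positions, so the realized composition matches the target to
within rounding. `simulate_mutations()` draws a per-gene mutation count
(Poisson by default, negative binomial via `dispersion`), then assigns
each mutation to one of the gene's possible single-base changes with
**sampling weight equal to the signature probability of that change's
class**. This site-level weighting is the generator's defining choice: it
makes the expected non-synonymous fraction of a neutral gene exactly
$N_{MS}/(N_{MS}+S_{MS})$, so the corrected dN/dS of a neutral cohort is
centered at 1 by construction and the simulated dN/dS is the exact
neutral expectation. (The alternative — drawing the class first from
$P_i$ and then a site uniformly within the class — weights classes by
$1/M_i$, where $M_i$ is the gene's class site count, and does not have
this property.) Purifying selection of strength $f$ then discards each
non-synonymous event independently with probability $f$, giving an
expected corrected dN/dS of $1-f$. Sample barcodes are drawn from a pool
of 400 synthetic samples and duplicate (sample, gene, position) records
are dropped, mirroring the deduplication applied to real catalogs.

Default study conditions, fixed once: 200 genes of 100–300 codons, 250
mean mutations per gene, the stylized 96-class melanoma-like signature
(below) and NTN fractions 0.6 ("membrane-like") versus 0.2
("soluble-like") for the mechanism contrast. These are chosen to be
large enough for the cohort medians to stabilize while remaining
desk-scale; the vignette's and test suite's simulations use these sizes
or smaller.

### The melanoma-like signature

`melanoma_like_signature()` reconstructs a UV-like profile from published
marginal proportions of cutaneous melanoma exomes: 6-class masses
2.5/1.5/87.6/2.3/4.1/2.0% (so 91.6% of mutations hit a cytosine and 8.4%
a thymine, on the pyrimidine-referenced strand); in the 96-class version
53.1% of all mutations sit at `T[C>T]N` contexts with 23.3% at
`T[C>T]C`, and the remaining mass of each class is spread uniformly over
its other contexts. It is a stylized reconstruction for simulation — a
real fitted signature has structure in every context.

### What the generator does and does not emulate

It emulates: signature-driven mutagenesis with per-class site weighting,
gene-to-gene composition differences (NTN content), cohort-scale mutation
counts, barcode-level deduplication, and tunable purifying selection.
It does **not** emulate: real human gene-length and composition
distributions, genome-wide trinucleotide frequency skews, clonal or
subclonal structure, regional mutation-rate covariates, or positive
selection hotspots. Passing the recovery tests therefore demonstrates the
estimators' internal consistency under the stated generative model, not
their robustness to everything real exomes do.

## Selection recovery and the signature-estimation caveat

On neutral cohorts the default pipeline — signature estimated from the
same catalog being tested — recovers a corrected median of 1, and this is
how the package's neutral-cohort validation runs. Under strong selection,
however, estimating the signature from the *selected* catalog is subtly
circular: classes rich in non-synonymous opportunity are depleted by
selection, which tilts the estimated $P_i$ and biases the corrected ratio
upward at large $f$. The recovery validation (medians within ±0.05 of
$1-f$ for $f \in \{0.2, 0.5, 0.8\}$) therefore supplies the generating
signature explicitly, which is also the recommended practice on real data
when an external profile (e.g. from whole-genome, non-exonic regions) is
available. The assumption is stated rather than hidden: it is the same
one any same-catalog correction makes.

## Numerical choices

* Signature vectors are validated to sum to 1 within `1e-6` and otherwise
  renormalized with a warning; zero or negative total mass is an error.
* 6-class profiles are expanded to 96 by spreading each class mass
  uniformly over its 16 contexts; *all* expected-count computation
  happens in 96-class space, so the two modes agree exactly on
  context-balanced genes.
* Undefined ratios are `NA`, never `Inf`; medians use `na.rm = TRUE` and
  the count of undefined genes is reported.
* Internal stop codons in input CDSs warn by default
  (`stop_handling = "error"` upgrades); the generator never produces
  them.
* Gene tables, spectra and results are ordered by `gene_id` and class
  order is fixed, so reruns are byte-identical (output timestamps are
  off by default).

## Known limitations

* No normalization against genome-wide trinucleotide frequencies: $P_i$
  is a mutation-class probability, not a per-context rate. This matches
  the corrected estimator's definition but means signatures from
  differently composed regions are not interchangeable without care.
* No signature deconvolution (NMF) or codon-model likelihoods
  (Goldman–Yang); the correction is deliberately a reweighting of
  Nei–Gojobori-style counts.
* Per-gene, cohort-aggregated inference only: no per-sample dN/dS, no
  subclonal structure.
* Transcript-coordinate only; splice-region effects and
  transcribed-strand asymmetry are not modelled.
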