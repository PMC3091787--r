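---
title: "Estimating CNV frequencies from SNP-array genotypes: methods and design"
author: "hweCNV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating CNV frequencies from SNP-array genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hweCNV)
```

## The problem

Dense SNP genotyping chips are designed to call biallelic genotypes,
but a marker sitting inside a common copy-number variant does not
behave like a biallelic locus. A segregating **deletion (null)
allele** silences one chromosomal copy: heterozygous carriers present
as homozygotes of their remaining allele, and deletion homozygotes
produce no signal at all and land in the no-call class. A segregating
**duplication** whose extra haplotype carries both SNP alleles makes
every carrier look heterozygous. In a large homogeneous population
sample — the design case is 912 artificial-insemination sires from a
single dairy-cattle breed genotyped on a ~54,000-SNP chip — these
distortions are large enough to estimate the CNV allele frequency at
every marker directly from genotype-class counts, without touching
the raw intensities.

The package combines this Hardy-Weinberg (HWE) evidence with an
independent signal-intensity (SI) arm: per-sample CNV calls (such as
PennCNV `rawcnv` output) tallied into per-marker loss/gain
frequencies. The two arms have complementary error profiles, and
their intersection is the detection rule.

## The HWE model

Let `p` and `q` be the frequencies of the two SNP alleles and `r` the
frequency of a third, silent allele. Under random mating, genotype
frequencies follow the trinomial expansion `(p + q + r)^2 = 1`. The
observable phenotype classes are:

| genotype | phenotype class |
|----------|-----------------|
| pp, pr   | A-like homozygote (`p_o`) |
| qq, qr   | B-like homozygote (`q_o`) |
| pq       | heterozygote-like (`pq_o`) |
| rr       | no-call |

Substituting `p_o = p^2 + 2pr`, `q_o = q^2 + 2qr`, `pq_o = 2pq` and
eliminating `p` and `q` yields the closed-form loss estimator

$$r_l = \sqrt{0.25 - 0.25\,pq_o + p_o q_o / pq_o} - 0.5 .$$

The radicand is a sum of non-negative terms
(`0.25(1 - pq_o) + p_o q_o / pq_o`), so `r_l` is always finite when
any heterozygotes are observed. For the gain model (every carrier of
the duplication allele `g` heterozygote-like, `p_o = p^2`,
`q_o = q^2`, `pq_o = 1 - p^2 - q^2`):

$$r_g = \sqrt{p_o + q_o + pq_o} - \sqrt{p_o} - \sqrt{q_o} .$$

Both inversions are exact: on model-expected fractions they return
the planted frequency to machine precision, which the test suite
asserts over a 0.05-step simplex grid. Two consequences of applying
each formula outside its own model are used rather than suppressed:

* On a deletion locus `r_g` is *negative* with magnitude close to
  `r_l`, and symmetrically for `r_l` on a duplication locus. Negative
  estimates are therefore retained everywhere except in the no-call
  expectation; they carry information and produce the strong negative
  correlation between the two estimators that is expected when the
  method works.
* On a locus with no heterozygotes at all but both homozygote classes
  present — the signature of a hemizygous, effectively X-linked
  marker typed in males — `r_l` diverges (`pq_o -> 0` gives `+Inf`,
  reported as such rather than as an error). More generally any
  `r_l > 1` (100%) is impossible for a true autosomal marker;
  `hweScan()` flags such markers and `flagNonAutosomal()` groups them
  into positional runs, because a run of flagged markers is the
  classic signature of a sex-chromosome segment misplaced onto an
  autosome in the genome assembly.

### Denominator choice

Fractions can be computed over successfully called individuals (the
default) or over all genotyped individuals. Technical no-calls hit
every class uniformly and do not bias the called-only fractions, but
a frequent null allele inflates the no-call class specifically, so
the called-only denominator gives a slightly *larger* `r_l` at
high-loss markers (the package exposes both; the tests assert the
direction of the difference). Since the technical no-call rate on
modern chips is small (~1%), the difference is second-order at the
planted frequencies used in validation.

### Ancillary screens

* **Chi-square HWE test** (`hweChisq()`): the standard biallelic 1-df
  goodness-of-fit test on called genotypes, no continuity correction.
  It is used descriptively (an excess of low p-values among selected
  markers corroborates CNV activity), so raw p-values are reported
  and no multiple-testing correction is applied.
* **No-call expectation** (`expectedNoCalls()`): a null allele at
  frequency `r_l` predicts at least `n r_l^2` no-calls; negative
  `r_l` is clamped to zero here (losses only), and non-finite
  estimates propagate `NA`.
* **Polymorphism filter**: a marker is polymorphic iff at least two
  of the three called classes are observed; monomorphic markers get
  `NA` metrics and never enter threshold calibration or selection.

## The SI arm

`parseRawcnv()` reads the one-call-per-line `rawcnv` dialect
(1-based, fully closed coordinates; copy numbers 0, 1, 3, 4, 5; copy
number 2 rejected; thousands-commas tolerated in the length token;
single-marker calls allowed, matching a minimum-SNP setting of 1).
`markerSiFrequencies()` places a marker inside a call when the
chromosome matches and `start <= position <= end` — endpoints
included, consistent with the format's startsnp/endsnp fields — and
counts copies lost `L = sum max(0, 2 - cn)` and gained
`G = sum max(0, cn - 2)` over samples, with absent samples
contributing two copies. Percent frequencies are `100 L / 2n` and
`100 G / 2n`. On pure-loss or pure-gain loci this equals the single
absolute-value statistic `100 |1 - N_t / 2n|` on the total copy count
exactly (asserted to 1e-12); splitting loss from gain keeps mixed
loci from cancelling to zero. Two calls from the same sample covering
the same marker are an error (ambiguous copy state), not a silent
overwrite.

## Combining, clustering, confirming

Thresholds are calibrated per metric as mean + 1 population SD over
eligible markers (polymorphic, unflagged, finite); population rather
than sample SD because the marker panels involved are large enough
that the distinction is negligible, and the multiplier is a
parameter. Selection is a strict AND — a marker must exceed both its
HWE and its SI threshold of the same type — with an OR mode available
for sensitivity analyses. Loss and gain pipelines run independently,
so a locus can legitimately appear once as a loss and once as a gain
region.

Selected markers are chained into regions by single-linkage: markers
of the same type at most `clusterDistance` apart merge. The default
is 500 bp. That default is deliberately conservative relative to a
~50 kb-spaced chip — at 500 bp essentially only markers inside the
same planted event merge, and most regions are single markers, which
on such a chip may represent indels below the chip's resolution. A
user working with clustered custom content or wanting CNVR-scale
aggregation should raise it (it is an exposed parameter everywhere,
including the CLI); the default is kept small rather than silently
"corrected" because the region span is only ever the span of member
markers — actual CNV breakpoints cannot be assigned from chip data.

Catalog confirmation is gap-based: a region is confirmed when a
documented interval on the same chromosome overlaps it or lies within
`proximity` bp edge-to-edge (gap measured as `start2 - end1`,
implemented by padding the catalog interval by `proximity` on each
side — padding only one of the two sides of the comparison, since
padding both would double the allowance). The symmetric catalog-side
confirmation rate is reported too.

## The simulator

`scenarioSpec()` describes a panel marker by marker: model (`hwe`,
`null_allele`, `gain_allele`, `hemizygous_x`), allele frequencies,
planted CNV frequency, and cluster membership; markers sharing a
cluster share one CNV event per individual, emulating a deletion or
duplication haplotype spanning the cluster. Defaults are the design
conditions: 912 individuals; technical no-call rate 0.01 (applied
uniformly and independently after the genetic model — on real chips
observed missing calls mix technical failure with true deletion
homozygotes, and the uniform-technical component is about 1%); SI
detection rate 0.3 per carrier (per-sample intensity-based calling is
conservative, with moderate power and a low false-positive rate —
accordingly the default false-positive rate is 0, with a parameter to
raise it). Duplication homozygotes are emitted as copy number 4,
heterozygous carriers as 3; deletion carriers as 1 and 0.

What the simulator does *not* emulate — and therefore what passing
tests do not establish about real data: linkage disequilibrium
between markers (irrelevant to single-marker estimators but not to
region statistics on real panels), raw intensity noise and
batch/plate effects, genotype-calling artifacts correlated across
samples, population structure and selection, and real PennCNV
behaviour (its HMM is out of scope; only its output format is
consumed). The simulator validates the estimators and the pipeline
logic under their own model assumptions, not the upstream calling
chain.

Determinism: every simulation entry point takes a seed, and identical
spec + seed give byte-identical output files.

## Validation statistics

For a deletion validated by an orthogonal assay (e.g. qPCR), the
package estimates the allele frequency from the count of
deletion-homozygous individuals: `sqrt(k/n)` under HWE, so 2 of 132
gives 12% at whole-percent rounding. The count is modelled as
Poisson, and the exact (Garwood) interval is used:
`lower = qchisq(alpha/2, 2k)/2`, `upper = qchisq(1-alpha/2, 2k+2)/2`,
verified in the tests against direct inversion of the Poisson CDF to
1e-8. The interval maps monotonically to the allele scale via
`sqrt(lambda/n)`; for k = 2, n = 132 the 95% upper limits are 7.22
homozygotes and 23.4%. Published analyses of this design quote a
higher lower limit than the Garwood one (0.6 homozygotes where the
exact limit is 0.24); the provenance of such lower bounds is
method-dependent (different exact or approximate constructions differ
most at the lower end for tiny counts), so this package documents and
reports only the exact interval and treats upper limits as the
reproducible quantity.

## Numerical and design choices

* `pq_o = 0` with both homozygote classes present returns `+Inf` and
  sets the non-autosomal flag — these markers are diagnostic
  evidence, not errors. Monomorphic markers return `NA`.
* The loss radicand is clamped at zero before the square root purely
  as floating-point protection; analytically it cannot be negative.
* Heterozygote identity in genotype files is by unordered allele
  pair; a half-call (one missing allele) is conservatively a
  no-call; homozygote orientation is lexicographic, which the HWE
  math is invariant to (`p_o` and `q_o` enter symmetrically).
* Markers present in a genotype report but absent from the map are
  counted but excluded from position-dependent steps, with a warning.
* Test and validation problem sizes are chosen to exercise the study
  scale where it matters statistically (n = 912 throughout; 500
  replicate markers for estimator recovery; 10,000 markers for
  chi-square calibration; 5,000 background markers with 20 planted
  5-marker clusters for end-to-end recovery) while keeping the whole
  suite around a minute.

## Known limitations

Only the two simplified single-event models are inverted — one copy
lost, or one gained carrying both alleles. Loci combining loss and
gain, multi-copy expansions, and duplications whose extra copy is
identical to the source allele (invisible to HWE) are outside the
model, as is X-chromosome inheritance (X-like markers are flagged,
not modelled). Region spans are marker spans, not breakpoints. The
HWE arm needs a large sample from a reasonably panmictic population;
inbreeding or strong substructure mimics heterozygote deficit and
will inflate loss estimates.
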