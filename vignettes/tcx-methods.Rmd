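---
title: "Methods: time- and age-dependent differential expression after status epilepticus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time- and age-dependent differential expression after status epilepticus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcx)
options(tcx.verbose = FALSE)
```

## The scientific problem

Kainic-acid-induced status epilepticus (KA-SE) is the standard rat model of
mesial temporal lobe epilepsy. A central observation in this model is that
the consequence of the same insult depends on age: immature animals
(postnatal day 15, P15) rarely become epileptic, while mature animals (P30)
frequently do. One window into this difference is the hippocampal
transcriptional response over the latent period — which genes change, how
strongly, and for how long, at each age.

`tcx` implements the full computational path of such a study as a reusable,
tested pipeline: a 2 ages x 2 treatments (PBS vehicle vs KA) x 5 time
points (1, 6, 24, 72, 240 h) x 3 replicate design (60 expression profiles);
per-contrast differential-expression selection combining fold change, an
unpaired t-test and a permutation-based false-discovery-rate estimate;
integration of multi-source gene-ontology annotation into a composite
database; reduction of MAPK signalling into 13 component pathways with
co-annotation "array plots" and regulator-polarity classification; and
delta-delta-Ct qRT-PCR concordance accounting. Because the original arrays
and circa-2008 annotation snapshots are not reproducible at desk scale, the
package ships a first-class synthetic-data generator that emulates the
design, and every stage is validated against the generator's ground truth.

## The synthetic-data generator

`generate_study()` draws per-gene baselines b_g ~ N(6, 1.5) on the log2
scale and models each observed signal as

    log2 signal = b_g + effect(gene, age, time, treatment) + N(0, sigma)

with sigma = 0.3 log2 units by default — a replicate noise level typical of
oligonucleotide arrays after normalization. Signals are therefore
log-normal and strictly positive. Injected treatment effects apply only to
the KA arm at the (age, time) cells listed in the effect table; when the
table is auto-generated, the P30-like age group receives larger magnitudes
(|log2 FC| ~ U(1.5, 5) vs U(1.2, 3)) over longer durations (up to all five
time points vs at most three), mirroring the qualitative age asymmetry of
the seizure response. These defaults are configuration, not claims about
any particular dataset.

Detection calls are generated by thresholding a logistic function of the
log2 signal (midpoint 4, slope 1.2) with uniform randomness, plus a small
Marginal band (5%). This emulates the intensity dependence of
Present/Marginal/Absent calls; the probe-level detection algorithm itself
is out of scope — calls are an input contract, consumed, never computed
from probe intensities.

One global integer seed drives every generator through independent derived
streams (`derive_seed()`), so adding a generator never perturbs another's
draws, and identical seeds give byte-identical studies.

What the generator does *not* emulate: probe-level PM/MM structure,
cross-hybridization, batch effects, RNA-pooling covariance (a `pooling`
flag shrinks replicate noise by sqrt(4) to mimic four-animal pools, off by
default since the marginal variance is what the test statistics see), or
correlated biological pathway dynamics. Passing tests therefore demonstrate
the correctness of the *analysis machinery* under the stated noise model,
not robustness to every artefact of real arrays.

## Differential expression

**Presence filter.** A gene enters a contrast only if it is called Present
in at least two of three replicates in either the control or the treated
group (rat rule), or in all samples (human case-control rule). This removes
genes too close to background for the statistics to be meaningful.

**Normalization.** The original analysis used a commercial package whose
normalization method is not stated; we use per-sample median scaling to 1 —
the simplest method of that era's practice — and it is the one
normalization whose result is scale-equivariant per sample. Statistics are
computed on log2 normalized values; fold changes on the linear scale, with
downregulation reported as fc < 1 so that fc(A,B) x fc(B,A) = 1 exactly.

**t-test.** Two-sided unpaired Student's t-test (pooled variance) on log2
signals, vectorized over genes. Whether the original test ran on linear or
log signals is unstated; log2 is chosen because the noise model is
multiplicative. Zero pooled variance is degenerate: p is defined as 1 when
the means are equal and the smallest representable positive value
otherwise, and the event is logged.

**Permutation q-values.** The FDR machinery follows the
significance-analysis-of-microarrays (SAM) skeleton:

* moderated score d_g = (mean treated − mean control) / (s_g + s0), with
  the fudge factor s0 selected among 5%-step percentiles of the s_g
  distribution to minimize the coefficient of variation of d's spread
  (median absolute deviation) across bins of s_g; median of s is the
  fallback when the search degenerates;
* group-label permutations — exhaustive over all C(n1+n2, n1) distinct
  assignments when feasible (a 3v3 contrast has exactly 20), otherwise a
  sampled set of distinct assignments that always includes the observed
  labelling;
* FDR at each gene's |d|: pi0 x median over permutations of the count of
  permuted scores at or beyond that threshold, divided by the observed
  count; counting is inclusive on both tails, the conservative tie-break;
* pi0 estimated as #{d in (q25, q75 of permuted scores)} / (m/2), capped
  at 1;
* monotonicity enforced so a larger |d| never gets a larger q (cumulative
  maximum down the |d| ordering — the conservative direction).

Since every published knob of the method is a parameter here, the
calibration properties are tested rather than assumed: on all-null studies
(1000 genes, 3v3, 20 seeds) the q <= 0.05 call proportion stays far below
nominal, and with 50 strong injected effects the realized FDR averages
under 0.10 with sensitivity 1.0. Whether q-values should be computed per
time point or jointly is unstated in the source analysis; per time point is
chosen because the selection rule is "significant at >= 1 time point".

**Selection.** A gene is significant for an age group iff fold change > 2
(or < 0.5), p < 0.05 and q < 0.05 hold jointly at at least one time point.
(The source prints the q inequality both ways in different places; q < 0.05
is the only reading consistent with q being a false-discovery rate, and is
used throughout.) The human variant uses fold 1.5 and the t-test only.
Selection is monotone: loosening any threshold can only grow the set — a
tested invariant.

**Baseline contrast.** To separate developmental from seizure-response
differences, the same machinery runs with age as the grouping factor on
PBS-only samples (P30 controls vs P15 controls per time point); the overlap
of that baseline DE set with the KA-responsive sets is the confound report.

## Composite ontology database

`build_composite()` pools any number of symbol/description sources,
resolves aliases (case-insensitive; one-step mappings only — chains and
one-alias-to-two-canonicals are errors), and keeps, per gene, the
case-insensitive union of unique descriptions after whitespace
normalization. The result is provably independent of source order.

Term counting treats whole (whitespace-normalized) description strings as
terms — the least-interpretation reading of counting "ontological terms"
without a defined tokenization. Keyword grouping is case-insensitive
substring matching, configurable per group; the shipped group keyword sets
(MAPK signalling, inflammation/immune, cell cycle, transcription, synaptic,
calcium, apoptosis, mitochondrial, glial) are explicitly heuristic
starting points.

## Pathway mapping

The 13 component pathways are fixed vocabulary, ordered by family:
Classical (ERK1/2, Growth Factor, Ras/Rab), SAPK (p38, Rho/Cdc42/Rac, JNK,
p53, TGF-beta, TNF-alpha), Other (NF-kappaB, Wnt, JAK/STAT, PI3K/AKT).
Assignment is phrase matching against an editable lexicon
(`default_pathway_lexicon()`); matching is performed on normalized text, so
Greek letters (TGF-β / TGF-beta), hyphens and slashes are interchangeable.
Genes matching no phrase are excluded from pathway analyses but reported in
a sidecar list.

The array plot is the pair-combinatorics device: a 13 x 13 matrix where an
upregulated gene annotated with n pathways increments each of its C(n, 2)
unordered pathway pairs in the upper triangle (downregulated: lower
triangle). Matrices are additive over genes, stratified by age and time,
and split at four pathways of breadth because a single 5–7-pathway gene
alone fills 10–21 squares.

Regulator polarity parses the grammar "positive regulation of X" /
"negative regulation of X" / "regulation of X", mapping X through the same
lexicon. A gene carrying both signed phrases for one pathway is a *general*
regulator of it, as is a gene with only the unsigned phrase; a signed
phrase alongside an unsigned one keeps the sign (the unsigned phrase is
less specific). Enzyme classification flags kinase, phosphatase,
dual-specificity phosphatase (which implies phosphatase) and
MAPKKK-association by keyword lexicon, with regulation-of-kinase/
phosphatase polarity handled by the same grammar.

## qRT-PCR

dCt = Ct(gene) − Ct(housekeeping) per sample; when both beta-actin and
GAPDH are flagged the default policy is the arithmetic mean of their Ct
(the source's "and/or" is ambiguous; a single-gene policy is available).
ddCt = mean dCt(treated) − mean dCt(control), fold = 2^(−ddCt). Whether the
original fold changes used per-sample or per-group-mean ddCt is unstated;
we use per-group means for the fold and the per-sample dCt values for the
unpaired t-test, which keeps the fold estimate and the inference consistent
with each other. Concordance against the array is a chain of nested
filters: shared genes → array-significant → same trend → qPCR-significant
(p < 0.05) → fold beyond 2.

## Reporting

Time-course figures use second-order (piecewise quadratic) interpolation
through consecutive point triples — purely cosmetic smoothing that passes
exactly through every observed point and reduces to a straight segment for
two points; it is never used in statistics. Time is drawn on a log axis to
discriminate 1 h from 6 h. Figure rendering never changes tabular output (a
tested invariant), and identical configuration + seed gives byte-identical
tables.

## Problem sizes and numerical choices

The package's default pipeline configuration runs the full 60-profile
factorial layout with a 1200-gene panel and 80 injected DE genes; the
calibration suites use 1000-gene single-contrast studies over 20 seeds, and
the ontology round trip uses 200 genes across 3 sources with aliasing on.
These sizes give stable statistics while keeping a full run in seconds; the
machinery is size-agnostic and the full 8799-gene panel is the
`design_spec()` default for study generation.

Tolerances: fold-change and ddCt identities are exact (floating point);
noisy qPCR recovery is asserted within ±25% at Ct noise 0.1 and n = 6 per
group; FDR and sensitivity bounds are means over 20 seeds. Tie-breaks in
permutation counting are inclusive on both tails (conservative); q
monotonicity uses the cumulative maximum (conservative). Degenerate inputs
(zero-variance samples, empty groups, missing time points, empty keyword
lists, genes with fewer than two pathways passed to the array plot) are
explicit errors rather than silent coercions.

## Known limitations

* Phrase lexicons are heuristics; on real annotation exports they would
  need curation, and the round-trip guarantees shown here hold for the
  generator's template grammar, not for arbitrary free text.
* The q-value implementation is one published default skeleton of the SAM
  family; other variants (asymmetric cutoffs, local FDR) are not provided.
* The human case-control arm reuses the factorial machinery with a
  different rule; with 3–4 samples per group its power is intrinsically
  limited, as in the original design.
* No probe-set-to-gene collapsing across platforms: gene symbols are
  assumed already harmonized up to aliasing.
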