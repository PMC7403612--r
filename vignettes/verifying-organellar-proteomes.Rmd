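---
title: "Verifying an organellar proteome from fraction-level proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying an organellar proteome from fraction-level proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitosieve)
```

## The verification model

A density-gradient mitochondrial fraction from a plastid-bearing
protist contains four kinds of protein: genuine mitochondrial
residents, chloroplast material from the adjacent band, cytosolic
contaminants that co-sediment with the organelle pellet, and
dual-localized proteins. No single measurement separates these classes:
enrichment ratios misclassify dual-targeted and weakly expressed
proteins, import-signal prediction fails on 5'-truncated transcripts,
and orthology against reference mitoproteomes covers only the conserved
core of a divergent lineage. The pipeline therefore accepts a candidate
into the verified proteome when **any one** of three strategies
supports it:

* **Orthology** — an ortholog in at least one of the reference
  mitoproteomes (four by default). "At least one" reflects that each
  reference is itself incomplete and phylogenetically distant; demanding
  agreement across references would discard most of the conserved core.
* **Enrichment** — mean Mt intensity exceeding both the chloroplast and
  the whole-cell mean (`Mt/Cp > 1` *and* `Mt/WC > 1`). Requiring both
  guards against proteins that are merely depleted from one comparison
  fraction.
* **Targeting consensus** — an ORF starting with methionine and
  predicted mitochondrial in the majority of the surveyed transcriptome
  variants. The majority denominator is all surveyed transcriptomes
  (three), not only those containing the transcript, so a transcript
  present once can never reach the required two votes. This is the
  conservative reading of "majority": a single prediction on a single
  assembly is weak evidence precisely because the other assemblies are
  silent.

Union-then-curation, rather than a stricter 2-of-3 vote, is the primary
rule because the three strategies have largely disjoint failure modes;
a majority rule would discard the many genuine residents supported by
exactly one line of evidence. A `rule = "majority"` switch is provided
for sensitivity analysis. Curation then corrects the union in both
directions, each requiring a conjunction:

* **Removal**: clearly non-mitochondrial functional annotation *and* no
  ortholog in any reference. Annotation alone is not sufficient — an
  annotated protein with a reference ortholog is more plausibly a
  genuine resident with a misleading annotation.
* **Reintegration**: predicted mitoproteome membership *and*
  mitochondrial functional annotation, for candidates that failed all
  three strategies (in practice: insufficient enrichment).

The invariant `final = union - removed + reintegrated` is asserted at
assembly time on every run. Final members whose Mt/Cp ratio is below 1
("greater chloroplast enrichment") are by construction retained through
orthology and/or targeting; the summary counts them separately because
they are the natural candidates for dual localization.

## Identification layer

Peptides are canonicalised by collapsing isoleucine to leucine (the two
are isobaric and indistinguishable by the instrument; the collapse
direction is arbitrary but fixed) and dropping peptides shorter than
six residues. Protein grouping follows peptide-set subsumption: protein
B joins protein A's group when B's peptide set is contained in A's.
Subsumption is closed through the leading protein only — if B and C are
both subsets of A, all three share a group even if B and C are
incomparable — because containment chains through intermediate members
are not well defined when the leader already covers every member.
Proteins are visited in order of decreasing peptide-set size with
lexicographic tie-breaks, which makes the grouping deterministic and
invariant under permutation of the input. A peptide mapping to members
of more than one group is a razor peptide: excluded from unique-peptide
counts and from quantification.

The FDR filter sorts identification scores decreasingly and estimates
FDR as `decoys / targets` within each prefix (the plain
reversed-database count, without the +1 correction). Among prefixes
whose estimate stays at or below the requested level, the threshold is
placed at the last accepted *target* of the prefix maximising the
target count: extending a qualifying prefix into a trailing run of pure
decoys would add no identifications while inflating the estimate. An
all-decoy qualifying prefix yields an empty acceptance with FDR defined
as 0.

## Quantification choices

* Group intensity per sample = **sum** of unique-peptide intensities.
  The full pairwise-ratio label-free algorithm used by instrument
  software is deliberately out of scope; summation is the simplest
  aggregation that preserves the ratio statistics the pipeline
  consumes, and the substitution is documented here.
* Ratios use means over replicates with **no pseudocount**; a zero
  denominator with Mt signal is an explicit `infinite` category, not a
  large sentinel. Both-zero is undefined and never counts as enriched.
* `log10(Mt/Cp) = 1` (exactly 10x) falls in the `0.0-1.0` bin: the
  interval is closed on the right so the bins read "1-10x", "10-100x".
* Welch's unequal-variance t-test on log10 intensities; with zero
  variance on both sides the p-value is 1 for equal means and the
  smallest representable positive double otherwise, so volcano plots
  never receive a literal zero.
* Molecular weights use average (not monoisotopic) residue masses plus
  one water, in kDa.

## What the generator emulates

`simulation_config()` fixes the study conditions; its defaults are
chosen once and are not tuned per analysis:

| parameter | default | rationale |
|---|---|---|
| localization proportions | mito .35 / chloro .25 / cytosol .35 / dual .05 | a photosynthetic protist fraction experiment: both organelles abundant, a small dual-targeted cohort |
| `enrichment_fold` | 8 | strong but realistic one-step gradient purification |
| `intensity_log_sd` | 0.2 | typical spread of label-free intensities between replicates |
| `n_replicates_per_fraction` | 3 | standard design |
| `detectability` | 0.5 | roughly half of tryptic peptides fly and fragment well |
| `missing_rate` | 0.1 | sporadic per-sample dropout |
| `truncation_prob` | 0.8 | most assembled transcripts of the motivating lineage lack the 5' end carrying the targeting signal, so only a minority of true residents can ever reach the 2-of-3 consensus |
| `reference_coverage` | 0.2 | each reference mitoproteome covers only the conserved core of a divergent protist; with four references, roughly half of true residents carry orthology evidence |
| `ortholog_fp_rate` / `targeting_fp_rate` | 0.01 / 0.02 | low, nonzero error rates of orthology inference and signal prediction |
| `contaminant_rate` | 0.05 | fraction of cytosolic proteins that co-sediment |
| `leak_factor` | 0.1 | median mito-band abundance of a contaminant relative to the fold |
| `id_score_separation` | 5 | well-resolved target/decoy scores: the 1% FDR filter costs well under 1% of true identifications |

The fraction-composition model: organellar bands cross-contaminate each
other at base level (a mitochondrial protein appears in the chloroplast
band with effect 1, and vice versa), soluble cytosolic proteins are
washed out of both organellar bands, and the whole-cell fraction
contains every protein at its base abundance — the simplest realisation
of the whole cell as the mixture of all compartments. Consequently a
mitochondrial protein's noise-free Mt/Cp ratio equals the configured
fold exactly, which the tests assert. Dual proteins carry the fold in
both organellar bands (Mt/Cp near 1), so they are recovered through
orthology and targeting rather than enrichment — the same reason the
retention rule exists for real data.

Contaminant co-sedimentation is heterogeneous: each contaminant's
mito-band abundance is the fold times a lognormal multiplier centred on
`leak_factor` (sd 0.5 log10 units). Heterogeneity matters because
per-group ratios average noise over tens of peptide observations; a
constant sub-unity leak would never look enriched, whereas in a real
gradient a minority of contaminants (vesicle-associated, aggregated)
co-purify strongly. Those are exactly the members the annotation-based
removal step exists to catch.

What the generator does **not** emulate: spectra (no m/z, retention
time, or fragmentation — intensities are abstract), shared peptides
between homologous proteins (sequences are random, so subsumption
groups are almost always singletons; the grouping logic is instead
exercised by dedicated constructed instances and a brute-force oracle),
between-run normalisation drift, and correlated missingness. Passing
end-to-end tests therefore demonstrates the decision logic and its
statistics, not robustness to instrument artefacts.

## Numerical and degenerate-input conventions

* All generators are deterministic given the config seed; sub-seeds are
  derived by fixed offsets so the generators can be called in any
  order. The RNG state of the caller is saved and restored.
* Tryptic digestion cleaves after K/R except before P, with 0 (default)
  to 2 missed cleavages; with no length filter the fragments
  concatenate back to the input, which is property-tested.
* Localization counts follow the configured proportions by
  largest-remainder allocation, exact to within rounding.
* An empty observation table (e.g. `missing_rate = 1`) flows through
  every stage and produces an empty proteome with a consistent summary,
  not an error. A fraction with no surviving observation contributes
  zero intensity.
* Proteins are reported in groups; evidence is evaluated per protein,
  with group-level enrichment inherited by every member.

## Problem sizes

The shipped analysis and the test suite run the full pipeline at 2,000
proteins (the scale at which recall and precision are evaluated),
grouping-oracle comparisons on 200 random instances of up to 20
proteins and 50 peptides, and FDR calibration on 20 simulations of
10,000 targets plus 10,000 decoys at 3-sd separation. These sizes keep
a complete run in tens of seconds while leaving Monte-Carlo error well
below the margins being tested.

## Known limitations

* The union rule's precision depends on the false-positive rates of the
  weaker strategies; with heavily inflated orthology error the curation
  step cannot compensate, since removal requires an annotation signal.
* Razor-peptide accounting is minimal: shared peptides are excluded
  from unique counts and quantification, with no largest-group razor
  assignment.
* "Weak homology" for the `PUTATIVE` presence status has no numeric
  definition here; it is a caller-supplied flag.
* The generator's placeholder fold separation (8x) is not an estimate
  of any real fractionation; conclusions about real-data recall or
  precision do not transfer.
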