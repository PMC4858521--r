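---
title: "Methods: the T4PCensus neighborhood census, feature heuristics and architecture models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the T4PCensus neighborhood census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: what the census
computes, which parameters matter and why they default as they do, what the
synthetic-data generator does and does not emulate, and where the design was
genuinely open.

## The census model

Type IV pili (T4P) systems and the archaellum are multi-gene machines whose
components — pilins above all — diverge too fast for annotation transfer, but
whose genes cluster around a conserved marker, the VirB11/FlaI-family
secretion ATPase. The census therefore works on *gene order*, not sequence
similarity: protein-family labels (arCOG-like) are taken as input, and
membership in the T4P gene complement is inferred from recurrent genomic
context.

`expandOnce()` implements one step of guilt-by-association expansion: a
family joins the set when it occurs within `window` genes up- or downstream
of a current-set gene in at least `min_genomes` distinct genomes.
Multiplicity within a genome counts once — the threshold is about
reproducibility of the association across genomes, not abundance.
`runCensus()` iterates this a fixed number of times, then hands sub-threshold
candidates to an automated curation step and finally removes excluded roles
(S-layer families) into a "potential components" side list rather than
dropping them.

Key parameter defaults, all exposed on `CensusConfig`:

| parameter | default | rationale |
|---|---|---|
| `window` | 3 genes | neighborhood = three genes up- and downstream; measured in genes, not bp, because operon structure — not physical distance — carries the signal |
| `minGenomes` | 5 genomes | an association seen in five genomes is very unlikely to be a lineage-private rearrangement |
| `iterations` | 3 | chains of association (ATPase → platform → pilins) are short; three hops reach every component of the largest known loci |
| `exclusionRoles` | `s_layer` | S-layer proteins associate with T4P loci in some genomes but not others; they are reported separately, not asserted as components |
| `contextExclusivityMin` | 1.0 | curation surrogate for "never occurs in a different gene context": every member of a curated family must sit inside a candidate locus |
| `localizationMin` | 0.8 | curated components must be (predicted) secreted or membrane proteins; 80% tolerates occasional truncated members |

Curation replaces manual inspection with three explicit clauses (localization,
context exclusivity, operon sharing); each decision carries a reason code so
that the audit trail manual inspection would provide is preserved.

Two semantics were open and are decided as follows. First, the genome
threshold is re-applied to *candidates* at each iteration; families once
accepted persist (the accepted chain is non-decreasing by construction, and a
fixed point exists). Second, per-genome T4P counts (`countT4pPerGenome()`)
count ATPase *genes*, not families: duplicated ATPase genes mark duplicated
systems, e.g. paralogous loci after lineage-specific duplication. A
`distinct_families` flag provides the other reading.

Neighborhoods never cross contig boundaries and contigs are linear — the
conservative choice for draft genomes; circular replicons would add at most
one junction neighborhood per contig and can be supported later without
changing the contract.

## Sequence-feature heuristics

The census needs three per-protein calls; all are deliberately simple,
threshold-exposed rules rather than probabilistic topology models.

**Hydropathy and TM segments.** `kdProfile()` computes sliding-window mean
Kyte–Doolittle hydropathy (window 19, the classical TM helix span). Windows
with mean ≥ 1.6 are merged when overlapping or separated by < 5 residues;
merged runs ≥ 15 residues are reported as TM segments. These are standard
hydropathy-plot conventions. Unknown residue letters score 0.0 with a
warning, so `X` in real proteomes degrades gracefully instead of erroring.

**Class III (prepilin) signal peptides.** The A24-family peptidase removes
only the positively charged N-terminus, cleaving at a \[K/R\]G motif and
leaving a hydrophobic domain of about 20 amino acids on the mature protein.
`detectClass3()` encodes exactly that: scan leader positions 2..35 for K/R
followed by G; accept the first position where the prefix net charge (K/R =
+1, D/E = −1) is ≥ +1 and the mean hydropathy of the 20 residues after the G
is ≥ 1.0. The published archaellin-signature tools' exact patterns are not
public, so this documented rule *is* the package's contract; leftmost
acceptable motif wins, which makes ties deterministic. A Sec-like fallback
(8-residue core of mean hydropathy ≥ 1.5 within the first 40 residues) feeds
the secreted/membrane localization call; its nominal cleavage position — the
rule only needs a position to exist — is set 5 residues after the core.

**Localization.** Membrane iff ≥ 1 TM segment, except that a single segment
starting at or before residue 45 is discounted when a signal peptide was
detected: that segment is the signal's own hydrophobic domain (this is what
makes prepilins *secreted*, not membrane). Secreted iff any signal peptide
and not membrane; otherwise cytoplasmic; unknown without a sequence.

## Pilin calling

Major pilins are small (mature length ~70 aa for the methanococcal majors,
up to ~160 aa for PilA-family majors), class III positive, and
characteristically encoded by stand-alone genes, often in tandem-duplicated
paralog groups. Minor pilins are the remaining class III proteins in T4P
loci, often much longer (~250–550 aa). The classifier gates on class III
fraction ≥ 0.8, then separates major from minor by median mature length
≤ 160 aa *and* (stand-alone fraction ≥ 0.5 *or* ≥ 2 paralogs in some
genome). The 160 aa bound is a surrogate — the literature gives no numeric
major/minor boundary — chosen to bisect the ~70 aa and 250–550 aa regimes;
it is config-exposed and the call is monotone in it (raising the bound never
demotes a major). Mature length is length after the class III cleavage
position when detected, else full length.

## Locus assembly and architecture templates

`buildLoci()` merges census-family genes separated by ≤ 2 non-census genes
(`max_intervening`) into runs; runs with ≥ 2 distinct census families are
loci, single-family runs (singletons or tandem copies) are flagged
stand-alone — precisely the pattern major pilins produce. This distinction is
a package design choice: the field's locus lists include single-gene entries,
but treating them as "loci" would make the stand-alone fraction — a major
diagnostic for major pilins — vacuously zero.

Each locus is scored against 11 declarative templates (`builtinTemplates()`,
editable as YAML): score = satisfied required-role ranges / total required
roles, minus 1.0 (floored at 0) if a forbidden role is present. A required
major pilin with zero in-locus copies is satisfied when the genome carries
stand-alone majors — ATPase/TadC modules demonstrably operate with pilins
encoded in trans. Ties go to the template with more required roles (subset
architectures otherwise shadow their supersets), then lexicographically; best
score < 0.6 is `unclassified`. The archaellum template requires the seven
core components (FlaI, FlaH, FlaJ, FlaF, FlaG, 1–9 archaellins, 1–3
FlaC/D/E); fused DE/CDE genes count once per gene.
`checkArchaellumCompleteness()` additionally counts stand-alone archaellins
encoded outside the locus.

Only three template compositions are fixed by the underlying models
(archaellum; the complex clade-1 system with two TadC genes, ≥ 5 minor
pilins and the 9-TM peptidase EppA; the two-component pilin-free 4D system).
The other eight required/optional splits are this package's design, grounded
in the described figures: the clade-2 signature minor pilin (arCOG02911-like)
for the two euryarchaeal variants, an adhesin for 4C and 4B, a coiled-coil
cytoplasmic component for 4F, the membrane + cytoplasmic accessory pair for
4E, and the FleN/MinD ATPase plus two cytoplasmic components for the complex
4G system. S-layer proteins are *optional everywhere*: the census excludes
them from the final set, so a template requiring one could never be satisfied
from census loci. The role vocabulary distinguishes `flaF`, `flaG` and
`flaCDE` from generic minor pilins so the archaellum's one-copy-each
constraints are expressible.

## Alignment column filter

`columnStats()`/`filterAlignment()` remove, by default, columns with gap
fraction > 0.5 **or** homogeneity < 0.1 (union). Homogeneity statistics in
the literature vary in formulation; the package uses mean pairwise
identity among non-gap characters — bounded in [0, 1], 1.0 for a single
distinct character, 0.0 by convention for an all-gap column — and accepts a
plug-in replacement (`hom_fun`) for substitution-matrix-weighted variants.
The union reading matches standard trimming practice (remove gappy columns
*and* remove heterogeneous columns); an `intersection` mode implements the
literal conjunctive reading. Filtering is idempotent and monotone in both
thresholds.

## The synthetic-data generator

`generateCollection()` builds genome collections in which every downstream
claim is checkable against planted truth. The default parameters are the
study conditions: 30 genomes, each of the 11 templates planted in 5 genomes
(55 systems), system counts per genome spanning every value from 1 to 7
(ATPase genes as proxy), stand-alone major-pilin probability 0.5 per system,
archaellin paralog counts drawn from 1–9 (the observed ceiling), and a
fixed seed (17).

Construction guarantees worth stating explicitly:

* **Sequences are composition-coded, not evolved.** Prepilins get a charged
  leader, \[K/R\]G motif and 21-residue hydrophobic tract; membrane proteins
  get hydrophobic 21-mers at fixed spacing; background proteins draw only
  hydrophilic residues. The detectors are therefore *exactly* separable on
  generator output — the tests assert sensitivity 1.0 and false-positive
  rate 0.0, which validates the construction/detection contract, **not**
  detector performance on real proteomes, where leaders are noisier and
  hydrophobicity is continuous.
* **Background label structure stresses the genome threshold.** Interior
  background families are drawn Zipf-like (exponent 1.5) from a shared pool,
  so they recur across genomes — but never inside seed neighborhoods. The
  margins flanking each planted locus (and each stand-alone pilin gene) draw
  from a "rare" pool capped at 4 genomes per family: these families *do*
  appear in census neighborhoods, in just under the acceptance threshold,
  so the min-genomes rule is load-bearing in every run. Without the cap a
  high-frequency background family would sit next to loci in ≥ 5 genomes and
  the zero-background-acceptance property would be unattainable by any
  correct implementation.
* **Operon signal.** Locus genes share a strand with 1–50 bp gaps;
  everything else is spaced 200–800 bp, so the 100 bp operon gap threshold
  recovers the generator's operon plan exactly.
* **In-trans majors.** With probability `standalone_major_pilin_rate` a
  system's major-pilin genes are planted as stand-alone tandem runs elsewhere
  in the genome. Major families planted *only* in trans are invisible to
  neighborhood expansion — as in real data, where stand-alone majors were
  identified from prior knowledge rather than context — so recovery recall
  is defined over families that occur inside planted loci in ≥ 5 genomes.
* **Horizontal transfer** is modeled as copying a planted system (with fresh
  flanks) into another genome, recorded in truth. The default rate is 0: the
  default collection models vertical inheritance only, keeping the planted
  per-genome counts exactly on the 1–7 ramp; HGT behavior is exercised by its
  own tests at rate 0.5.

What the generator does **not** emulate: sequence evolution and family
divergence (labels are exact), annotation noise and mislabeled families,
draft-genome fragmentation (one contig per genome), circular replicons,
pseudogenes, and the continuous gradation between major and minor pilins.
Green tests on synthetic data therefore demonstrate algorithmic correctness
under the stated contracts, not robustness to real-world label noise.

## Problem sizes and determinism

The shipped test suite runs the full pipeline on the 30-genome default
collection (~3,000 genes) and the template-confusion analysis on a 70-genome
collection with 220 planted loci; census-oracle equivalence is checked on 50
random instances of ≤ 8 genomes × ≤ 60 genes against a brute-force pair
enumeration. These sizes give every statistic a non-trivial denominator while
keeping a full run in well under a minute of compute. All randomness flows
from explicit seeds; `generateCollection()` restores the caller's RNG state,
and `runPipeline()` reruns are byte-identical given the same seed.

## Known limitations

* Family labels are trusted input; the census cannot rescue mis-assigned or
  missing family labels (profile searches are out of scope).
* The feature heuristics are hydropathy rules, not HMMs; on real proteomes
  they will miss atypical leaders and split long TM helices. All thresholds
  are exposed precisely so they can be recalibrated.
* Template scoring treats roles as exchangeable within a multiplicity range;
  gene order within the locus is not scored.
* Clade labels on families are carried as metadata; no tree inference is
  performed.
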