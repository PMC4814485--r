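---
title: "Methods: aquaporin family annotation with aqpscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aquaporin family annotation with aqpscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqpscan)
```

## The problem and the model

Plant aquaporins (AQPs, the major intrinsic protein superfamily) are
channel proteins whose substrate range — water, urea, boric and silicic
acid, NH3, CO2, H2O2, glycerol — is largely encoded by a handful of
conserved residue positions on an otherwise divergent six-transmembrane
fold. A genome-wide family study therefore reduces to a small set of
reusable computations: curate a gene catalog and check its gene-model
arithmetic; align every protein to a structure-anchored reference and read
off the diagnostic residues (the dual NPA motifs on loops B and E, the
aromatic/arginine constriction H2/H5/LE1/LE2, Froger's positions P1–P5,
and nine specificity-determining positions, SDPs, per substrate class);
compare those residues to degenerate "typical transporter" profiles;
classify proteins into the five plant subfamilies (PIP, TIP, NIP, SIP,
XIP) and their subgroups; type duplicate gene pairs and book-keep
ancestral family sizes; and summarize tissue expression as FPKM.

`aqpscan` implements that pipeline with each stage exposed as a plain
function, plus a seeded generator that produces AQP-like families with
*known planted truth* so the whole chain is testable without any
downloads.

## The reference topology

Residue extraction is anchored on a single reference with annotated
alignment columns (`default_topology()`). The anchor is a **synthetic**
plant-PIP-like backbone built in code — hydrophobic 21-residue blocks at
the six TM spans, polar filler in loops — with the canonical PIP residues
planted at the annotated columns (F-H-T-R ar/R filter, NPA/NPA motifs
spaced 108 residues apart, E-S-A-F-W Froger residues, and the typical
boric acid/CO2/H2O2/urea SDP vectors). Using a constructed anchor rather
than a natural structure-resolved sequence keeps the package
self-contained; because every extractor is alignment-relative, any
annotated natural anchor could be substituted without code changes. The
backbone is a fixed point of the extractors: annotating the reference
returns exactly its planted residues, which is asserted in the tests.

Each substrate class gets its own nine annotated SDP columns. In natural
proteins some SDP positions coincide across classes; keeping them disjoint
in the synthetic topology lets the generator plant and the tests verify
each class vector independently.

## Alignment and extraction choices

* **Alignment**: global (Needleman–Wunsch) with BLOSUM62 and affine gaps,
  open 10, extend 0.5 — the standard regime for intra-family protein
  alignment. Queries scoring at or below 0 against the reference are
  rejected as not MIP-like; queries shorter than 100 residues are rejected
  outright.
* **NPA motifs**: searched in a ±10-column window around the annotated
  motif columns, accepting any x-P-x triplet, preferring Asn then Ser at
  the first position, and reporting the literal triplet (NPA, NPV, NPS,
  NPT, NPL, SPI all occur in real families). The inter-motif spacing
  counts residues strictly *between* the two motif start positions; with
  this convention the backbone's spacing is 108, the value diagnostic of
  silicon transporters. Whether published spacing figures count inclusive
  or exclusive of the motif residues is not standardized; this package's
  convention is fixed and documented here.
* **Missing residues**: a gapped annotated column yields the marker `.`,
  which always counts as an SDP mismatch — conservative prediction, never
  a wildcard.
* **Hydropathy TM finder**: Kyte–Doolittle, window 19, threshold 1.6,
  runs merged when separated by fewer than 3 positions. This is a
  deliberately simple substitute for a full topology predictor; it is
  used only for the TM-count column of annotation reports.
* **Molecular weight / pI**: average residue masses plus one water;
  isoelectric point by bisection (tolerance 1e-4 pH) of the
  Henderson–Hasselbalch net charge under the EMBOSS pKa set. Published
  tables computed with other pKa sets can differ by roughly ±0.2 pH
  units.

## Substrate prediction

The six degenerate profiles (typical NH3, boric acid, CO2, H2O2, silicic
acid and urea transporters) ship as a fixture. A substrate is predicted
only on a **zero-mismatch** match by default: published analyses treat
single-position deviations as "novel SDPs", not matches, so near misses
are reported separately rather than folded into the call. The three
evidence channels — SDP matching, the Froger AqpZ/GlpF discrimination
(exemplar identity first, the aquaglyceroporin chemical rule as fallback),
and the ar/R water call (high only for exactly F-H-T-R) — are never
combined into a composite score, because no principled weighting exists;
reports keep them separate.

## Classification and trees

Percent similarity is `100 × positive-scoring aligned pairs / alignment
length` (terminal gaps excluded), a reproducible proxy for the
percent-similarity outputs of classic multiple-alignment suites whose
exact definition is rarely stated. Subfamily assignment is
nearest-reference under this similarity with a 25% floor ("unclassified"
below it), ties broken by a subgroup vote among the top three, then
lexicographic reference id.

The support tree is neighbor joining on `d = 1 − similarity/100`,
implemented in-package so that negative branch lengths are clamped to
zero with the deficit shifted to the sister edge (total pair length
preserved). NJ replaces a maximum-likelihood bootstrap tree by design:
the tree is classification support, not a published-figure reproduction.
On additive matrices the implementation reproduces all pairwise path
lengths to < 1e-9, which the tests assert against an independent NJ
implementation (ape).

## Duplicates and ancestral bookkeeping

A pair is **tandem** when both genes lie on the same scaffold, in the
same orientation (foot-to-head order), with no other family gene between
them; **dispersed** when on different chromosomes; otherwise a
**WGD-candidate**. Minus-strand genes are recognized from descending
catalog coordinate pairs and normalized to an explicit strand flag.

Ancestral family sizes use a documented default rule (no standard rule
exists): a subgroup is ancestral when present in the outgroup or in at
least two ingroup species; its count is the maximum ingroup count after
collapsing annotated lineage-specific duplicate pairs and removing
annotated pseudogenes. The packaged per-subgroup ancestral list for the
Euphorbiaceae family (total 31) is a transcribed fixture, so the headline
total is checked on the list itself, not on the rule's output — the rule
is a tool for new datasets, not a claim about how the published list was
derived.

## Expression

FPKM is `count × 1e9 / (eff_len × total_mapped)` with the CDS as
effective length (reads are mapped to coding sequences) and library-wide
totals (whether published figures used family-restricted totals is
unknowable from the text; library-wide is the standard choice). A gene is
"expressed" when more than one fragment maps (count ≥ 2). Log2 transforms
use a pseudocount of 1. Subfamily shares are member percentages of the
subfamily total FPKM per tissue, undefined over a zero total; duplicate
pair divergence is the per-tissue log2 ratio with a preference-switch
flag when the sign changes across tissues.

## The synthetic generator and what passing tests mean

`simulate_family()` plants subgroup-typical residues (ar/R, Froger, NPA
variants, substrate-typical SDP vectors) at the annotated backbone
columns, then mutates *outside* them at configured substitution/indel
rates; CDS are back-translated with a fixed codon table and laid out with
subfamily-typical intron counts (PIP 3, TIP 2, NIP 4, SIP1 0, SIP2 2,
XIP1 1, XIP2 2, NIP5 3). The default composition is 9 PIP / 9 TIP / 8
NIP / 4 SIP / 2 XIP with the physic nut subgroup split. True FPKM values
follow the subfamily abundance ordering PIP > TIP > SIP > NIP > XIP with
lognormal gene and tissue effects; counts are Poisson around
`FPKM × len × total / 1e9`. Everything is a pure function of (config,
seed).

What the generator does **not** emulate: phylogenetic site-rate
variation, codon usage, alternative isoforms, sequencing error, and
overdispersed counts. Planted-truth recovery therefore demonstrates that
the extraction and classification machinery is correct *given* the MIP
fold and divergence regime, not that it would annotate an arbitrary
proteome; similarly, unbiased FPKM recovery is shown under the Poisson
ideal.

Problem sizes used by the packaged checks: planted-truth recovery on 200
simulated proteins (substitution rate 0.05; indel rate 0 and 0.01),
subfamily recovery over 100 seeded replicates at 30% divergence against
a two-per-subfamily panel, NJ exactness on ten random additive matrices,
and Poisson recovery at expected count 50 over 2000 draws.

## Degenerate inputs and numerical conventions

Empty catalogs summarize to zeros; all-missing SDP vectors predict
nothing; zero subfamily totals yield undefined shares; span
inconsistencies (e.g. a catalog genomic span that disagrees with its
stated transcriptional region) are *reported*, never raised, since
published tables contain exactly such conflicts. Pseudogene calls require
both an ORF disruption (frameshifting indel or premature stop, located
against a subgroup consensus) and absence of expression evidence —
either alone is insufficient. pI bisection brackets are asserted (net
charge positive at pH 0, negative at 14). Fixture loading is
deterministic; the inventory fixture always parses to exactly 32 rows.

## Known limitations

* Percent similarity is alignment-parameter-dependent; published
  similarity ranges computed with other tools will differ in detail.
* The ar/R water call recognizes only the F-H-T-R filter; divergent
  filters with experimentally proven water permeability are "unknown".
* The tandem test uses adjacency within the inventory, not physical
  distance; two same-strand family genes megabases apart on one scaffold
  with nothing between them would still be called tandem.
* The ancestral-count rule is a reasonable default, not an inference
  method; it has no error model.
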