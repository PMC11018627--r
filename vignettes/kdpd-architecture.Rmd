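---
title: "Classifying KdpD architectures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying KdpD architectures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdparch)
```

## Scientific background

KdpD, the sensor kinase of the KdpDE two-component system, regulates the
bacterial K⁺ pump KdpFABC on two levels. Its C-terminal transmitter — the
DHp and CA domains, residues 663–894 in *E. coli* numbering, with the
catalytic histidine H673 — is a classical histidine kinase (HK) that
controls *kdpFABC* transcription through the response regulator KdpE. Its
N-terminal KdpD domain (residues 1–230) is an atypical serine kinase
(ASK) that inhibits the assembled pump post-translationally by
phosphorylating a serine on the KdpB subunit. The ASK active site is a
nucleotide-binding module rather than a kinase fold: an atypical Walker A
motif G-X₅-G-K-T (triad G36/K37/T38, one spacer more than the classical
G-X₄-G-K-T), a Walker B D109/E110 pair, and an adenine-coordinating
W39/R190 pair.

Because the two activities live on separable modules, genomes carry many
versions of the system: full-length chains; short KdpD/Usp chains (ASK
only, typically controlled by c-di-AMP binding to the Usp domain); split
systems with a KdpD/Usp ASK chain and a TM/GAF/DHpCA HK chain;
HK-truncated chains; and bare KdpD-domain chains. `kdparch` classifies
candidate chains into this taxonomy and correlates the species-level
version with the presence of KdpE and of a diadenylate cyclase (the
c-di-AMP source).

## The classification procedure

Every candidate chain is aligned globally to an annotated reference, and
all domain and anchor decisions are made by projecting reference
coordinates through the alignment. The assumptions are therefore: (i)
candidate chains are homologous to the reference over the regions they
share, (ii) domain content can be read off alignment coverage rather
than profile models, and (iii) the reference's anchor residues occupy
homologous columns in capable chains.

### Alignment

Needleman–Wunsch/Gotoh global alignment with affine gaps, implemented in
C++ for speed. A gap run of length $L$ costs $g_{open} + L\,g_{ext}$;
transitions between the two gap states re-open, so every maximal run
pays its opening penalty. Defaults: BLOSUM62, $g_{open} = 10$,
$g_{ext} = 1$ (matrix units). The wildcard X scores 0 against
everything; letters outside BLOSUM62 score 0. Traceback tie-break is
fixed — diagonal over up over left — so results are bit-reproducible. A
didactic unit scheme (match +1, mismatch −1, linear −2 per gapped
residue) exists for worked examples and oracle tests.

Two identity statistics are computed. The *column-local* identity
(matches / columns where both sequences hold a residue) is robust to
length differences and is what the per-domain presence call uses
locally. The *global* identity (matches / all alignment columns, gaps
included) drives curation. The distinction matters: under affine gaps
the optimizer aligns an unrelated 300-mer to the scattered best-matching
reference columns, which inflates column-local identity to roughly 0.3,
while the gap-inclusive measure stays near the 0.10 random baseline.
An intact single-domain chain scores about 0.26 globally (230 of 894
reference columns), so the curation threshold of 0.15 keeps genuine
short versions and drops junk; chains mutated past the threshold are
still rescued when any reference domain is detected. The tests verify
both behaviours on generated cases.

### Domains, motifs, anchors

A reference domain is called present in a chain when, over the
reference-domain columns, alignment coverage ≥ 0.6 **and** local
identity ≥ 0.2. The thresholds are deliberately loose — domain presence
is a coarse architectural statement, and the synthetic benchmarks mutate
10% of residues — and they are monotone by construction: tightening them
can only turn calls off (a property test asserts this).

Walker motifs are scanned as literal patterns: `G-X{5}-GKT`
(atypical), `G-X{4}-GKT` (classical), and for Walker B at least three
consecutive hydrophobic residues (A/V/I/L/M/F/C) immediately followed by
`DE` — the canonical Walker B consensus, adopted because the motif is
defined in the literature only by its D/E pair. Spacer positions match
the 20 canonical residues only; X, B, Z and U never satisfy any motif
position, keeping calls conservative on dirty sequences. All overlapping
hits are reported; the scanner is verified against a naive
every-substring oracle.

Capability calls combine the two mechanisms:

- **ASK-capable**: KdpD domain present, an atypical Walker A hit inside
  the query region homologous to the N-terminal domain (an incidental
  G-X₅-GKT elsewhere does not count), and a positive Walker B signal.
  The Walker B signal is primarily anchor conservation — D and E in the
  columns homologous to 109/110 — with the pattern scan as fallback only
  when the alignment gaps those columns out; projection is the closest
  automated counterpart to expert curation, and the GKT is required
  literally (a permissive switch admits GKS for exploration).
- **HK-capable**: DHpCA domain present and H in the column homologous
  to position 673.

### Chain and species classes

The chain class is a deterministic function of the domain-presence
vector with fixed precedence (FULL_LENGTH, HK_TRUNCATED, SHORT_KDPD_USP,
KDPD_ONLY, HK_ONLY_TM_GAF_DHPCA, OTHER); OTHER is a reported catch-all,
never silently dropped. Species aggregation mirrors how multi-variant
species are treated in comparative surveys: a full-length chain
dominates (it alone fulfils both activities, so additional variants are
not counted separately); otherwise an ASK chain lacking DHpCA plus an
HK-capable chain make a SPLIT_ASK_HK species; otherwise the species
takes the class of its single most capable chain, with ties broken by
number of domains and then accession for determinism. Species capability
flags are the OR over retained chains — a split system is jointly
functional. Metadata species without any surviving chain are ABSENT, a
category of their own in all distributions (with re-based proportions
also reported).

### Co-occurrence summaries

`version_distribution()` gives counts and proportions per group;
`crosstab_binary()` cross-tabulates any boolean outcome against a
boolean split, reporting an empty group as *n* = 0 with NA percentages —
an explicit null, never a silent zero that would corrupt a comparison.
No hypothesis tests are attached (the scientific claims here are
percentages); optional Wilson 95% intervals can be switched on. Because
"percentage of KdpD versions in species without KdpE" admits both a
per-species and a per-chain denominator, both tables are produced
(`hk_by_kdpe_species`, the default reading, and `hk_by_kdpe_chains`).

## The synthetic proteome generator

The generator is first-class, tested code: it emulates the statistical
structure of a curated multi-species KdpD panel so every pipeline stage
has a known truth. Per species it samples an architecture class, builds
each chain by concatenating the reference's domain segments joined by
5-residue G-rich linkers (G-rich because glycine is in no motif's
residue set, so a junction cannot complete a Walker pattern; an internal
assertion re-scans every template), optionally ablates motifs
(GKT→AAC echoing the G36A/K37A/T38C knockout, D109/E110→AA, H673→A),
mutates unprotected positions independently with a configurable rate,
and samples metadata conditionally on the planted capabilities.

Default study conditions: class mix FULL_LENGTH 0.74, SHORT_KDPD_USP
0.12, SPLIT_ASK_HK 0.05, HK_TRUNCATED 0.05, KDPD_ONLY 0.04 — roughly
three quarters full-length with the remainder spread over the shorter
versions, the regime the comparative survey reports; mutation rate 0.1
with anchors/motif spans protected; P(KdpE | HK-capable) = 0.95,
P(KdpE | not) = 0.05; P(cyclase | TM/GAF-less class) = 0.9,
P(cyclase | otherwise) = 0.5. Metadata is conditioned on planted
capability (not on raw class), so the Bayes-implied conditionals the
cross-tabs should recover are well defined from the config. The
mandatory seed makes outputs byte-identical across runs.

Species-level truth is derived by applying the species aggregation rule
to the per-chain truth labels — a pure function of labels, independent
of sequences — so recovery stays well defined even when ablations change
what a species can do (a split species whose ASK chain lost Walker A is
planted, and should be recovered, as HK-only).

What the generator does **not** emulate: phylogenetic covariance between
species (phylum labels are decorative and sampled independently of
class), annotation noise such as truncated or chimeric database entries,
compositional bias, and real inter-species divergence (point mutations
at a uniform rate are a crude stand-in). Passing the recovery benchmarks
therefore demonstrates that the pipeline's logic is correct and robust
to moderate sequence noise — not that its thresholds are optimal for any
particular real proteome set.

## The reference

The shipped default reference is **synthetic**: an 894-residue sequence
constructed to satisfy every annotation invariant (GKT at 36–38 with the
motif glycine at 30, W39, a hydrophobic run before D109/E110, R190,
H673), then sanitized so the Walker A GKT at 36–38 is the only GKT in
the molecule and the only N-terminal Walker B pattern ends at E110. The
sanitation is what makes planted-motif bookkeeping exact for the
generator — an ablated chain cannot be rescued by an accidental second
motif. Domain boundaries KdpD 1–230 and DHpCA 663–894 follow the
residue numbering above; the Usp (231–395), TM (396–500) and GAF
(501–662) boundaries are reconstructions that tile the remainder, since
only the two kinase modules have published residue ranges. A real
curated record can be dropped in as a YAML/JSON document via
`read_reference()`, which validates all anchors and intervals on load.

## Numerical and interface choices

- Coordinates are 1-based inclusive everywhere, matching residue
  numbering such as H673.
- Report TSVs serialize doubles with 17 significant digits so re-reading
  reproduces values exactly; JSON sidecars carry config hash, seed and
  version.
- Degenerate inputs are first-class: empty FASTA and empty species sets
  flow through every stage and produce valid empty outputs; the pipeline
  asserts record-count conservation (read = curated + rejected) and
  maps failures to stable exit codes (2 missing input, 3 validation,
  4 internal).
- All thresholds live in one configuration object
  (`classify_config()` / the YAML pipeline config); unknown config keys
  are rejected rather than ignored.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` use: 200 random pairs of
length ≤ 8 against a brute-force enumeration of all global alignments
(both scoring schemes), 500 random sequences of length ≤ 200 against the
naive motif oracle, 200-species panels for zero-noise (expected exact)
and 10%-mutation recovery, a 200-species panel with 25% ablation rates
for capability-flip checks, 2000-species panels for co-occurrence
recovery at three fixed seeds (3-binomial-SE agreement with the
Bayes-implied conditionals), and a 5000-species draw for class-frequency
calibration. These sizes give the binomial checks enough resolution
while keeping a full run on one CPU in the minutes range.

## Known limitations

- Domain presence is alignment-based; profile HMMs would be more
  sensitive for remote homologs and are deliberately out of scope.
- No transmembrane-helix prediction: the TM domain is called like any
  other interval, which a real membrane-protein survey might refine.
- The fifth-class taxonomy (which short variants are distinguished) is
  configurable in code but the class definitions themselves are fixed;
  OTHER absorbs anything unanticipated.
- Curation thresholds were chosen for the synthetic study conditions;
  real UniProt-derived sets have annotation artifacts (fragments,
  fusions) that may need stricter settings, which is why every
  intermediate quantity is written to the audit tables.
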