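# kdparch

Domain-architecture classification of KdpD sensor kinases across
prokaryotic species.

## The problem

KdpD is the sensor kinase that controls the high-affinity bacterial K⁺
pump KdpFABC. It is a *tandem serine histidine kinase*: besides the
canonical C-terminal histidine-kinase (HK) transmitter — the DHp/CA
domains (residues 663–894 in *E. coli*, catalytic histidine H673) that
phosphorylate the response regulator KdpE for transcriptional control —
its N-terminal KdpD domain (residues 1–230) acts as an atypical serine
kinase (ASK) that phosphorylates KdpB S162 to inhibit the pump
post-translationally. The ASK active site is built from nucleotide-binding
motifs, not a kinase fold:

- an atypical Walker A, **G-X₅-G-K-T** (one spacer residue more than the
  classical G-X₄-G-K-T), with the triad at G36/K37/T38;
- a Walker B **D109/E110** pair that polarizes the γ-phosphate and the
  substrate serine;
- an adenine-coordinating **W39/R190** pair.

Across species, KdpD comes in strikingly different versions: full-length
chains with all five domains (KdpD–Usp–TM–GAF–DHpCA), short KdpD/Usp
chains that keep only the ASK (regulated by c-di-AMP via the Usp domain
instead of by direct K⁺ sensing), split systems with ASK and HK on
separate polypeptides, HK-truncated chains, and bare KdpD-domain chains.
Which version a species carries co-varies with whether it encodes the
response regulator KdpE (needed only for HK signalling) and a
diadenylate cyclase (the c-di-AMP source).

`kdparch` automates this comparative analysis for anyone with a FASTA of
candidate KdpD chains and a species table:

1. **Curation** — global affine-gap alignment (Needleman–Wunsch/Gotoh,
   BLOSUM62, gap open 10 / extend 1, Rcpp core) of every chain to an
   annotated reference; chains are kept when their gap-inclusive global
   identity reaches 0.15 or at least one reference domain is detected.
2. **Domain and motif calls** — reference domain intervals and anchor
   residues are projected through the alignment column map; Walker
   motifs are scanned with conservative patterns (ambiguity letters
   X/B/Z/U never match).
3. **Classification** — each chain gets a domain-presence vector,
   ASK/HK capability flags and an architecture class; chains aggregate
   into species-level version calls (full-length precedence, split
   ASK+HK detection).
4. **Co-occurrence summaries** — version distributions (overall, per
   phylum) and cross-tabulations of HK capability against KdpE presence
   and of TM/GAF-less architectures against diadenylate-cyclase
   presence.
5. **Synthetic proteomes** — a generator plants architectures, motif
   ablations (GKT→AAC, DE→AA, H→A) and metadata correlations with a
   truth table, so every stage is testable without downloads.

The package ships a constructed (synthetic) 894-residue reference that
satisfies every annotation invariant; a real curated KdpD record (e.g.
UniProt P21865) can be supplied via `read_reference()`.

## Worked example

```r
library(kdparch)

chains  <- read_fasta(system.file("extdata", "example_chains.fasta",  package = "kdparch"))
species <- read_species_table(system.file("extdata", "example_species.tsv", package = "kdparch"))
fit <- kdpd_classify(chains, species)
fit
```

```
KdpD architecture classification
  reference: KdpD_reference_synthetic
  chains: 8 read, 8 curated, 0 rejected
  species: 8
  species classes:
    FULL_LENGTH                7 ( 87.5%)
    SHORT_KDPD_USP             1 ( 12.5%)
```

Seven of the eight example species carry a full-length KdpD (both ASK
and HK capable); one carries the short KdpD/Usp version, which keeps the
serine-kinase function but cannot signal to KdpE. `summary(fit)` adds
the co-occurrence tables:

```
ASK-capable species: 8 / 8; HK-capable: 7 / 8

HK capability by KdpE presence:
Cross-tabulation of 'hk_capable' by 'has_kdpE'
 split_value n n_true n_false pct_true pct_false
        TRUE 7      7       0      100         0
       FALSE 1      0       1        0       100
```

i.e. every KdpE-carrying species in this toy set has an HK-capable KdpD
system, and the single KdpE-less species lacks one — the association the
full-scale comparative analysis quantifies on thousands of species.

The same pipeline is scriptable from the shell
(`inst/scripts/kdparch {simulate|classify|summarize} --config cfg.yaml`)
with machine-readable manifests and stable exit codes.

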