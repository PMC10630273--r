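---
title: "Mining lytic cassettes and detecting gene/domain shuffling in phage genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining lytic cassettes and detecting gene/domain shuffling in phage genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lyticmine)
```

## The biological problem

Tailed bacteriophages end their lytic cycle by destroying the host cell
wall. In phages of gram-positive bacteria such as *Enterococcus*, the
machinery is encoded in a compact *lytic cassette*: a holin (a small
membrane protein that times lysis and lets the hydrolase through the
inner membrane), an endolysin (the peptidoglycan hydrolase), and in some
cassettes accessory genes such as an XhlA hemolysin-like holin-associated
protein. Gram-positive endolysins are modular: an N-terminal catalytic
domain (Amidase_2, CHAP, Glyco_hydro_25, Amidase_5, ...) is joined to a
C-terminal cell-wall-binding (CWB) domain (SH3_5, SH3_3, ZoocinA, LysM)
by a short flexible linker rich in proline and lysine, with the consensus
`KPTKPPSKPPPKP`. Because the modules are interchangeable in principle,
comparative genomics of many phage genomes can reveal *gene shuffling*
(replacement of a whole holin gene in an otherwise conserved cassette)
and *domain shuffling* (exchange of a catalytic or CWB module between
endolysins that are otherwise near-identical) — natural experiments that
inform the engineering of chimeric endolysins as antimicrobials.

`lyticmine` packages this comparative analysis as a reproducible,
testable pipeline: parse annotated genomes, classify proteins into lytic
roles, extract cassettes, stratify genomes by size, tabulate domain
combinations, segment endolysins around the interdomain linker, infer
putative unknown CWB (UCWB) regions, and call shuffling events from
explicit identity thresholds.

## Annotation model

Proteins are classified by two complementary evidence streams:

* **Keywords** on the GenBank `product` string (case-insensitive
  substrings): "N-acetylmuramoyl-L-alanine amidase", "endolysin",
  "phage lysin" and "lysin" mark endolysins; "holin" marks holins.
* **Domains** from an InterProScan-style scan, mapped through a
  controlled vocabulary of Pfam accessions covering seven holin families,
  six catalytic families, four CWB families and XhlA
  (see `default_vocabulary()`).

Domain evidence outranks the keyword on conflict, with precedence
holin-family domain > XhlA > catalytic domain > CWB-only > keyword. This
encodes the curation practice of confirming keyword hits with a domain
scan, and it rescues lysis genes annotated as "hypothetical protein" or
"tail fiber protein" — a real failure mode for XhlA genes. Overlapping
hits of the same domain merge to their envelope; repeated domains at
different positions (e.g. tandem LysM) survive.

## Cassette extraction and tabulation

A cassette is a gene neighbourhood seeded on any holin or endolysin and
extended over neighbouring annotated lytic genes on either strand; at
most `max_gap_genes` (default 2) consecutive unknown-role genes are
bridged, and unknown-role genes are trimmed from the ends. The rule is
deliberately gene-count based rather than base-pair based: it is robust
to annotation density, and the neighbourhoods it recovers match what a
curator would assemble by eye. When a genome yields several candidate
neighbourhoods, tabulation keeps one *primary* cassette per genome (most
members, ties to the leftmost), so n genomes contribute n cassettes;
`all_cassettes = TRUE` disables the reduction.

Genomes are stratified into five size groups — <20, 20–50, 50–65,
65–100 and ≥100 kbp — with half-open, lower-inclusive boundaries (a
genome of exactly 20,000 bp is Group 2; no published genome sits exactly
on a boundary, so the convention is ours). Combination tables count
cassettes by catalytic × CWB domain (Table-1 style) or holin ×
catalytic × CWB (Table-2 style); percentages are rounded
half-away-from-zero to two decimals, the convention that reproduces every
published table value exactly (e.g. 56/171 → 32.75). Endolysins without
an annotated CWB domain are tabulated as "Unknown"; multiple CWB domains
are joined N→C ("SH3_5 + SH3_3"). XhlA presence is kept as a separate
boolean on the cassette type key rather than folded into the
holin column, because the published holin–endolysin table omits it.

## Alignment and identity

All sequence comparisons reduce to pairwise global Needleman–Wunsch
alignment (BLOSUM62, affine gaps: a gap of length L costs
`10 + 0.5·L`, end gaps penalised). This replaces the by-eye multiple
alignments of a manual analysis with an explicit, reproducible statistic.
Identity is defined as identical aligned residue pairs divided by the
*full* alignment length, so gaps count against identity — a deliberate
choice, because length differences between endolysin variants (e.g. a
289 aa versus a 416 aa Amidase_2 endolysin) are themselves evidence of
module exchange. Because co-optimal alignments can differ in match count
depending on which sequence is the pattern, the implementation always
aligns the lexicographically smaller sequence as pattern; identity is
therefore exactly symmetric. Non-standard residues are scored as X.
Alignment scores are verified in the test suite against an exhaustive
enumeration of all gapped alignments for short sequences.

## Linker detection and endolysin segmentation

`detect_linker()` scans windows whose start lies within 80 residues
downstream of the catalytic domain and applies two criteria:

* **composition** — windows of 12–16 residues with P+K fraction ≥ 0.5,
  the best window extended through contiguous P/K flanks (extension
  never absorbs non-P/K residues, so the call cannot dilute into the
  neighbouring domain);
* **motif** — any substring of length 10–16 within edit distance ≤ 3 of
  the consensus `KPTKPPSKPPPKP`.

Each criterion scores its candidate (the P/K fraction, respectively
`(13 − distance)/13`) and the higher-scoring call wins, the motif
winning ties as the more specific evidence. An exact planted consensus is
therefore always reported at its exact coordinates with
`motif_distance = 0`.

`segment_endolysin()` anchors on the first catalytic domain, searches
the linker downstream, and assigns the CWB region: the annotated CWB
span when one exists, otherwise the unannotated stretch from the linker
end to the sequence end, labelled a *putative UCWB candidate* when at
least `min_ucwb_len` (default 40) residues long. When an annotated CWB
domain sits ≥ 40 residues downstream of the linker, the intervening
stretch is additionally reported as a UCWB candidate — the situation
seen in SH3_5 endolysins that are longer than the domain model explains.
Endolysins with neither a catalytic domain nor a linker yield a
segmentation-failed marker rather than an error. UCWB calls are flagged
putative in all outputs; this package deliberately replaces structure
prediction with sequence-composition segmentation, so a UCWB label is a
hypothesis about a region, not a structural assignment.

## Calling shuffling events

For every endolysin pair, the catalytic-region identity and the
CWB-region identity (the region C-terminal of the linker end, or of the
catalytic end when no linker is found) are computed. With defaults
`high_id = 0.9` and `low_id = 0.5`:

* catalytic ≥ 0.9 and CWB ≤ 0.5 → **CWB-domain swap**;
* catalytic ≤ 0.5 and CWB ≥ 0.9 → **catalytic-domain swap**.

The deadband between 0.5 and 0.9 is intentional: pairs in it are
ambiguous and produce no call, which keeps the detector conservative and
monotone (raising `high_id` or lowering `low_id` can only remove
events). Gene shuffling is called by clustering cassettes on full-length
endolysin identity ≥ 0.9 (single linkage) and, within every cluster of
at least three cassettes, flagging each cassette whose holin differs
from the cluster's modal holin family. Putative UCWB regions are
clustered the same way at identity ≥ 0.8 and labelled `UCWB-1`,
`UCWB-2`, ... by descending cluster size (ties by smallest member id),
so labels are deterministic and permutation-stable. Single linkage can
in principle chain intermediate sequences into one cluster; at the
conservative default thresholds and with the deadband this was never
observed on simulated data, but it is the known trade-off of the choice.

## The synthetic population generator

Because the pipeline's correctness claims are behavioural (does it find
what is there, and nothing else?), the package ships a generator that
produces GenBank records, domain-scan tables and protein FASTA together
with a ground-truth ledger of every planted event.

* A **block library** (`build_library()`) holds unrelated random
  amino-acid blocks for catalytic domains (including four mutually
  unrelated Amidase_2 variants, mirroring the observation that one
  family name covers several sequence lineages), CWB domains (including
  three UCWB families that the emulated scanner never annotates), holin
  genes, and linkers including the exact consensus. Distinct blocks are
  kept below 0.3 pairwise identity by construction checks.
* Each size group has a cassette **template** (holin family, endolysin
  recipe, XhlA presence) modelled on the group-specific cassette types
  of enterococcal phages; every genome receives a length drawn uniformly
  from its group's bp range, neutral filler genes (including the
  "tail fiber protein" decoy), and one cassette built from mutated block
  copies. Nucleotide sequences are produced by uniform reverse
  translation under genetic code table 11.
* **Divergence** (default 0.03) mutates every planted block copy at
  exactly `round(rate × length)` positions. The deterministic count
  bounds within-family copy identity below by construction
  (≥ 1 − 2·rate), which makes the planted truth unambiguous at the
  default thresholds. Substitutions only — no indels — at the default,
  so recovery failures are always diagnosable as detector faults rather
  than generator noise. Linkers are planted unmutated, mirroring their
  strong conservation in real endolysins and keeping the linker-recovery
  property exact.
* **Swaps** replace a recipient genome's holin gene or its endolysin's
  CWB/catalytic block with a spare block that no template uses
  (acquisition from an outside lineage). The truth ledger enumerates the
  implied pairwise events from block identities: two endolysins sharing
  a catalytic block but not a CWB block are a planted CWB-swap pair, and
  conversely. Gene swaps are placed in distinct groups and domain swaps
  capped at two per group so that every endolysin cluster keeps an
  unambiguous holin majority.

The default simulation — 30 genomes (6 per group), divergence 0.03,
three planted swaps of each class — is the study condition under which
the pipeline is validated: across 20 seeds the test suite requires
precision = recall = 1.0 for every event class, zero called events when
zero are planted, and planted linkers recovered within ±2 residues.
These are also the problem sizes used by `scripts/acceptance.R`.

What the generator does **not** emulate: realistic gene content, codon
usage or GC composition; indel divergence (available via higher-level
options only as a robustness probe); partially annotated real records;
or the curation judgement calls of the published dataset. Passing tests
therefore demonstrate the pipeline's internal correctness and
calibration, not that it reproduces a curator's decisions on real
GenBank material.

## Numerical and degenerate-input conventions

* Internal coordinates are 0-based half-open everywhere; GenBank I/O
  converts at the boundary. Joined CDS concatenate intervals in feature
  order; the strand applies to the whole feature.
* Records without sequences are accepted; CDS without a translation are
  translated from the nucleotide sequence (table 11) when possible,
  otherwise kept with an empty translation and flagged. A CDS span that
  is not a multiple of three is flagged, never silently fixed.
* Table rounding is half-away-from-zero with a 1e-9 representation
  guard; percentages must sum to 100 within 0.01 per row or the report
  step fails with an internal-invariant status.
* Empty cassette sets, empty domain scans, singleton cluster inputs and
  empty truth/called event lists all have defined behaviour (errors
  where the operation is meaningless, identity conventions where it is
  not: empty-vs-empty recovery scores 1.0).

## Limitations

* Identity thresholds formalise the qualitative "almost identical"
  versus "different" distinction of manual analyses; 0.9/0.5 are
  conventions, exposed in `run_config()`, not fitted quantities.
* The similarity measure penalises indels; a domain insertion inside an
  otherwise identical region lowers identity even though a curator might
  still call the flanks "the same".
* UCWB inference is sequence-based only and cannot distinguish a true
  cell-wall-binding module from any other unannotated C-terminal region
  of sufficient length.
* On real data the one-primary-cassette-per-genome reduction mirrors a
  one-cassette-per-phage accounting; genomes with two genuinely distinct
  cassettes require `all_cassettes = TRUE` and manual review.
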