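---
title: "Annotating modular PKS assembly lines and predicting their products"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating modular PKS assembly lines and predicting their products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pksline)
```

## The model

Modular type I polyketide synthases are enzymatic assembly lines: a
loading module primes a starter unit, each extension module performs
one decarboxylative condensation with a CoA-linked extender unit, and a
terminal thioesterase (TE) releases and macrocyclizes the chain. The
*colinearity rule* states that the order and domain content of the
modules map one-to-one onto the chemical structure of the product. This
package operationalizes that rule end to end for the domain repertoire
of polyene macrolide PKSs: KS (ketosynthase; KSq denotes the
loading-module variant with the catalytic Cys replaced by Gln, which
decarboxylates rather than condenses), AT (acyltransferase, selecting
malonyl-CoA or methylmalonyl-CoA), DH (dehydratase), ER
(enoylreductase), KR (ketoreductase), ACP (acyl carrier protein) and
TE.

With C1 the carbonyl carbon delivered to the TE and N extension
modules, the backbone has `2(N+1)` carbons and module `m` (1..N)
contributes the carbon pair `C(2N+2-2m)` (alpha) / `C(2N+3-2m)` (beta).
Its reductive loop sets the beta-carbon state:

* no (active) KR: ketone;
* A-type KR: *S*-configured hydroxyl; B-type: *R*-configured;
  signature-less KR: hydroxyl of unknown configuration (the package
  never guesses a configuration without a signature);
* functional DH: syn elimination of water from the *R*-configured
  hydroxyl, giving an E-configured double bond at `Δ(2N+2-2m)`. A DH
  over a non-R (S or unknown) hydroxyl is chemically inconsistent with
  syn elimination, so it is flagged and no bond is drawn; a DH without
  a KR is likewise flagged and the carbon stays keto;
* DH plus ER: reduction through to a methylene.

A methylmalonyl-specific AT at module `m` adds a methyl branch at the
alpha carbon `2N+2-2m`; the loading KSq decarboxylates its unit in
situ, so a malonyl loading AT yields an acetate starter and a
methylmalonyl one propionate. Z-configured double bonds are outside
the model (in polyene products they arise by post-assembly
isomerization, not by the DH).

These closed-form positions are verified in the test suite against an
independent oracle that grows the chain unit by unit and renumbers at
the end, for every architecture up to N = 20.

## Domain detection

Domain assignment by sequence homology is made concrete in two steps:

1. **Window anchoring.** One exemplar sequence per domain type is
   locally aligned (affine-gap Smith-Waterman over BLOSUM62, gap open
   10, extension 1) against the protein, iterating with masking until
   the score drops below `window_threshold` × the exemplar self-score.
   The default threshold 0.35 is deliberately permissive: windows are
   cheap, and validation is done by motifs. Overlapping windows are
   resolved greedily by descending score, ties to the leftmost start,
   so output is deterministic.
2. **Motif validation.** Each window is scanned for the catalytic
   motifs of its type with a degenerate-pattern matcher (fixed
   residues, `x` wildcards, `A/B` alternatives, `(x)` optional
   positions, `max_mismatch` substitutions at fixed positions). The
   positions read out by variant callers — the KS triad Cys/Gln and the
   ACP phosphopantetheine Ser — are wildcarded in the pattern so that
   substituted variants still anchor and the observed residue decides
   the call. Defaults: 0 mismatches for triads and short motifs
   (binary, per their catalytic role), 1 for the long ER consensus,
   which tolerates drift.

The scanner is checked against an exhaustive position-by-position
oracle on inputs up to 300 residues. Domain boundaries are operational
(alignment-derived); no claim is made that they match structural domain
boundaries, which the underlying study does not report either.

## AT and KR classification

**Residue route.** The AT region is aligned to the panel anchor and the
residues at annotated specificity-determining columns are read; the
call is the majority vote and the confidence the fraction of columns
agreeing (ties: unknown; more than half the columns in gaps: unknown).
The columns are shipped as editable sidecar data
(`inst/extdata/domain_sites.tsv`) rather than hard-coded offsets,
because published column conventions vary; the packaged residues are
synthetic, modeled on the malonyl/methylmalonyl fingerprint convention.

**Phylogenetic route.** The query is aligned together with the
reference panel, a neighbor-joining tree is built, and the call is the
class of the smallest bipartition side containing the query whose panel
members are all of one class, with the bootstrap support of the
subtending branch. When two minimal sides of different classes tie —
the query sits on the edge between the class clades — the nearer class
by mean p-distance wins, and an exactly equidistant query is reported
unknown (basal placement). This tie rule matters in practice: a noisy
query can attach at the root trifurcation of the unrooted tree.

When the two routes disagree, the call follows the configurable
precedence (`residues` by default, matching the convention of trusting
structure-consistent residue evidence) and the result is flagged
discordant with both lines of evidence retained — the loading-module
AT of the packaged fixture is exactly such a case.

**KR stereo-typing** reads two diagnostic regions mapped through the
alignment to the KR reference: the B-type window (LDD, or the LED
variant) and the A-type Trp position. The mapping is
alignment-relative, not offset-based, for robustness to indels. The
invariants are strict: a configuration is only ever emitted together
with its signature; both signatures at once give `unassigned` with a
conflict flag.

## Phylogenetic machinery

The package carries its own small, fully deterministic stack:

* pairwise global/local alignment in one compiled affine-gap kernel
  (gap of length k costs `open + k*ext`; traceback ties resolve
  diagonal > up > left);
* progressive multiple alignment: guide distances are one minus
  fractional identity from pairwise global alignments, the guide tree
  is average-linkage (UPGMA), and profiles are merged with the same
  kernel using column-frequency cross-scores;
* distances: p-distance over pairwise gap-deleted columns. No
  substitution model is imposed — the simplest defensible default for
  closely related domain sequences, and configurable by supplying your
  own matrix to `nj_tree`;
* neighbor joining with Q-matrix minimization; ties are broken by the
  lexicographically smallest joined label pair, so topologies are
  reproducible. Negative NJ branch lengths are clamped to zero for
  display with raw values retained in `attr(tree, "raw_lengths")`;
* nonparametric bootstrap: columns resampled with replacement, one NJ
  tree per replicate, supports as the percentage of replicates
  containing each original bipartition. A single caller-supplied seed
  makes replicate sets identical across runs. The default replicate
  count in `run_config()` is 1000.

NJ correctness is tested by recovery of the generating topology from
additive matrices of random trees (up to 8 leaves) and against an
independent NJ implementation; the alignment kernel is tested against
a textbook dynamic-programming oracle and an independent
implementation.

## The simulator and the fixture

`generate_proteins()` concatenates per-module domain scaffolds with
short linkers, writes the class-determining residues (AT columns, KR
LDD/LED/Trp, the loading KSq Gln), and applies seeded per-residue
substitution noise that avoids annotated diagnostic sites — so label
recovery degrades with noise through the *alignment* signal, not by
destroying the diagnostics themselves. `corrupt_diagnostics` exists
precisely to break named sites on purpose (e.g. one ACP serine).

Design points worth knowing:

* The scaffolds are miniature (~40–90 aa) synthetic consensus-like
  sequences carrying the real catalytic motifs; real domains are
  300–450 aa. This keeps simulations fast without changing any logic
  under test, but it means passing tests demonstrate correctness of
  the procedure, not sensitivity/specificity on real proteins, where
  domain similarity structure is far richer.
* Module AT domains are drawn from per-class ancestor sequences (~12%
  mutual divergence) so that phylogenetic placement carries class
  signal beyond the few diagnostic columns, mirroring how real AT
  clades are separated by overall sequence, not only by fingerprint
  residues. Panel leaves sit at ~8% divergence from their ancestor,
  far enough apart that no two leaves are near-identical.
* All generators take an explicit seed; identical seeds give
  byte-identical FASTA.

`make_rdm_fixture()` transcribes the reedsmycin organization: 17
modules over four ORFs, methylmalonyl ATs at modules 0–2 (AT0 flagged
discordant), malonyl at 3–16, B-type KRs at 1–3/12–16 (LED variant in
15–16), A-type at 6–7/9–11, unassigned at 4–5/8, functional DHs at
1–3/12–16, the single ER at module 1, and a terminal TE.
`make_observed_rdma()` encodes the elucidated RDM A chemotype: 34
carbons, acetate starter, S-hydroxyls at C-13/15/17/21/23,
unknown-configuration hydroxyls at C-19/25/27/31, E bonds at Δ2–Δ10
and Δ28, methyls at C-30/32. The C-31 hydroxyl configuration is
encoded unknown deliberately: if module 2's DH is skipped, its B-type
KR would predict *R*, but the structure determination does not state
it, and unknowns match anything during reconciliation.

## Reconciliation order

`reconcile()` never infers a DH skip de novo. The pipeline predicts
from sequence first, compares with the observed chemotype second, and
only then applies the resulting overrides (`apply_reconciliation`) to
regenerate the final chemotype — mirroring how assembly-line proposals
are actually argued. On the fixture this yields exactly two
discrepancies: the loading AT specificity (propionate predicted,
acetate observed) and the module-2 DH skip (Δ30 predicted, hydroxyl at
C-31 observed). The macrolactone ring-closure position is left unset
by default (`ring_closure = NA`): the lactonization hydroxyl is a
structural fact the module string does not determine.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; conversion to
  1-based inclusive happens once, at the GFF3 boundary.
* Proteins shorter than the smallest exemplar give an empty hit table
  with a warning; a hit set without any KS is a hard error ("no
  modules detectable"); orphan domains before the first KS attach to
  the loading module with a logged grammar violation.
* `scan_motif` on an empty sequence returns an empty table; motif
  patterns must have at least 3 positions and fewer mismatches than
  fixed letters.
* Distance matrices must be symmetric, non-negative, zero-diagonal;
  triangle violations are permitted (NJ does not require metricity).
* `titer_fold_change` rejects non-positive means and reports two
  decimals.

## Problem sizes in the test suite

The suite runs the full fixture pipeline (4 ORFs, 17 modules, ~6 kaa
total) several times, the motif-scanner oracle on sequences up to 300
aa, NJ recovery on random trees up to 8 leaves, chain-growth oracle
comparisons up to N = 20 extension modules, 100 seeded replicates of
AT placement at 10% noise, and a 1000-replicate bootstrap on a
20-taxon, 300-column alignment; the whole suite completes in well
under a minute on one CPU.

## Known limitations

* No profile-HMM machinery: detection rests on single exemplars plus
  motifs. For real clusters this is weaker than pHMM search; the
  module surface (`reference` argument) accepts richer exemplars.
* Domains outside the polyene repertoire (MT, Cy, Ox) are not modeled.
* ORF calling and database homology search are out of scope; inputs
  are deduced proteins (FASTA or GenBank translations).
* The AT diagnostic columns and KR signature positions are shipped as
  editable data and defined on synthetic anchors; applying the package
  to real sequences requires swapping in curated reference panels.
* Stereochemistry is predicted only where a signature licenses it;
  the package deliberately returns "unknown" otherwise.
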