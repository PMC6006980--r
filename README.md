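# pksline

Annotation of modular type I polyketide synthases (PKSs) and
colinearity-based prediction of the polyketide product, built around the
assembly line of the reedsmycins (RDMs) — non-glycosylated polyene
macrolide antifungals from a marine-derived *Streptomyces*.

## What it does, and for whom

Natural-product researchers who have the protein sequences of a modular
PKS cluster routinely ask three questions: which catalytic domains does
each protein carry, what does each module select and do chemically, and
what backbone does the whole line therefore make? `pksline` answers all
three with a self-contained, fully testable pipeline:

1. **Domain detection** (`detect_domains`): candidate windows are
   anchored by local alignment of one exemplar per domain type
   (KS, AT, DH, ER, KR, ACP, TE) and validated by the catalytic motifs of
   the field — the KS Cys-His-His/Asn triad (Gln replacing Cys in the
   decarboxylating loading-module KSq), the ACP `L/IG(x)DS`
   phosphopantetheine motif with its essential serine, the KR NADP(H)
   motif and KSY triad, the DH consensus `HxxxGxxxP`, and the ER
   consensus `LxHxxxGGVGxxAxxxA`.
2. **Functional classification**: AT extender-unit specificity
   (malonyl-CoA vs methylmalonyl-CoA) by specificity-determining
   residues and, independently, by neighbor-joining placement against a
   reference panel with bootstrap support (`classify_at_residues`,
   `classify_at_phylo`); KR stereo-type by signature (`classify_kr`):
   B-type (LDD/LED motif) KRs give *R*-configured alcohols, A-type (a
   diagnostic Trp) give *S*-configured ones, and signature-less KRs stay
   unassigned; DH/ER functionality flags.
3. **Colinearity prediction** (`build_assembly_line`,
   `predict_chemotype`): with C1 the carbonyl delivered to the
   thioesterase and N extension modules, the backbone has 2(N+1)
   carbons; module m installs its hydroxyl at carbon `2N+3-2m`, a
   methylmalonyl AT at module m puts a methyl branch at `2N+2-2m`, and a
   functional DH (syn elimination on the R-configured product of a
   B-type KR) draws an E double bond at Δ(`2N+2-2m`). `reconcile`
   compares the prediction with an observed structure and maps every
   mismatch back to the responsible module (AT specificity conflicts,
   DH "skips", KR configuration disagreements).

A seeded simulator (`architecture_spec`, `generate_proteins`) builds
synthetic multi-ORF PKS proteins with known ground truth, and
`make_rdm_fixture()` hard-codes the RDM organization: 17 modules over
RdmG (loading + 1–2), RdmH (3–6), RdmI (7–12) and RdmJ (13–16 + TE).

## Worked example

```r
library(pksline)

truth <- generate_proteins(make_rdm_fixture())
hits  <- lapply(truth$records, detect_domains)
names(hits) <- vapply(truth$records, function(r) r$id, character(1))
line  <- annotate_assembly_line(build_assembly_line(hits), truth$records)

ct <- predict_chemotype(line)
print(ct)
#> <chemotype_table> C34 backbone, starter propionate
#>   hydroxyls: C13(S) C15(S) C17(S) C19(unknown) C21(S) C23(S) C25(unknown) C27(unknown)
#>   E double bonds: Δ2 Δ4 Δ6 Δ8 Δ10 Δ28 Δ30
#>   methyl branches: C30 C32
```

The raw prediction has 34 backbone carbons (16 condensation rounds),
S-configured hydroxyls at C-13/15/17/21/23 from the A-type KRs of
modules 11/10/9/7/6, and unknown-configuration hydroxyls at C-19/25/27
from the unassigned KRs 8/5/4. Reconciling it against the elucidated
RDM A structure finds exactly two inconsistencies:

```r
disc <- reconcile(ct, make_observed_rdma())
disc
#>   module_index       category      predicted  observed
#> 1            0 at_specificity     propionate   acetate
#> 2            2        dh_skip enoyl_E at Δ30 OH at C31
```

(i) the loading AT is classified methylmalonyl-specific although the
structure demands a malonyl-derived acetate starter, and (ii) module
2's DH is active in sequence but "skipped" in the product. Applying the
overrides regenerates the structure-consistent chemotype:

```r
final <- predict_chemotype(apply_reconciliation(line, disc))
print(final)
#> <chemotype_table> C34 backbone, starter acetate
#>   hydroxyls: C13(S) C15(S) C17(S) C19(unknown) C21(S) C23(S) C25(unknown) C27(unknown) C31(R)
#>   E double bonds: Δ2 Δ4 Δ6 Δ8 Δ10 Δ28
#>   methyl branches: C30 C32
```

— six E double bonds (Δ2–Δ10 and Δ28) and the full polyol region, in
agreement with the observed 34-carbon macrolactone.

The same workflow is available from a shell via
`inst/scripts/pks-cli.R` (`scan`, `classify`, `tree`, `predict`,
`simulate` subcommands), e.g.

```sh
Rscript inst/scripts/pks-cli.R predict --fasta cluster.faa --out rdm --seed 1
```

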