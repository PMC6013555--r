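---
title: "Screening neuropsychiatric-disorder gene sets in brain expression data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening neuropsychiatric-disorder gene sets in brain expression data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npscreen)
```

## The screening problem

Alzheimer's-disease (AD) patients frequently present neuropsychiatric
symptoms — mood swings, hallucinations, depression — that overlap the
symptomatology of bipolar disorder (BIP), schizophrenia (SCZ) and major
depressive disorder (MDD). One way to ask whether an AD model shows
molecular signatures of these disorders is to screen its brain
transcriptome *through disorder-associated gene pools*: take Gene Ontology
(GO) terms that genome-wide association work has linked to each disorder,
collect the genes annotated to those terms, and ask how many of them are
differentially expressed between the AD model and wild-type animals, per
brain region and age.

`npscreen` implements that screen as a tested pipeline for a 2 × 2 × 2
design: genotype (wild type vs forebrain presenilin double knockout),
region (cortex, hippocampus) and age (7, 18 months), with intensities from
a probe-level microarray where several probes may interrogate one gene.
The stages are:

1. **Pool construction** (`parse_gaf()`, `filter_annotations()`,
   `expand_term()`, `build_term_gene_sets()`, `build_disorder_pool()`):
   annotations are read from GAF 2.2, kept when they match the target taxon
   (mouse, 10090), carry no `NOT` qualifier, and have at least one
   qualifier among *part_of, involved_in, enables, contributes_to,
   colocalizes_with*; each configured term is expanded to itself plus all
   is_a descendants before gene sets are collected. A disorder's pool is
   the deduplicated union of its terms' sets; the overlap is reported as
   *redundant memberships* (sum of set sizes minus union size).
2. **DEG calling** (`call_degs()`, `collapse_probes()`): per condition, a
   two-sided Welch t-test on log2 intensities plus a linear-scale fold
   change FC = mean(KO)/mean(WT); a probe is significant when
   p < 0.05 **and** max(FC, 1/FC) > 1.3, both strict. A gene is significant
   when any of its probes is.
3. **Disorder statistics** (`count_degs_per_term()`, `disorder_totals()`,
   `rank_disorders()`): per-term counts and percentages, per-disorder
   unique totals, share of all DEGs, and rankings by *number* or by
   *percentage* of pool.
4. **Cross-age classification** (`venn_partition()`,
   `classify_direction()`, `find_common_genes()`, `region_specificity()`):
   genes significant at both ages are *common*; a common gene with fold
   changes on opposite sides of 1 at the two ages is *contra-regulated*;
   a common gene that is common in exactly one region is
   *region-specific*.

`run_pipeline()` chains the stages and writes every report as TSV plus a
JSON manifest; all randomness derives from one seed.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | significance level on the (raw, by default) p-value |
| `fc_threshold` | 1.3 | symmetric fold-change bound, linear scale |
| `correction` | `"none"` | which p-value feeds the significance flag; Bonferroni/BH columns are always reported |
| `pooled` | `FALSE` | switch the Welch test to Student's pooled-variance test |
| `taxon` | `"10090"` | annotation taxon filter |
| `allowed_qualifiers` | the five-qualifier set above | annotation qualifier filter |

The default criterion reports raw-p significance because in this design a
family-wise or FDR correction across a few thousand GO-pool probes at
n = 2 arrays/group removes essentially everything; the corrected columns
are emitted alongside so that choice is always visible.

## Choices the data could not make for us

Several details of the analysis this package systematises are not pinned
down by any public description, so the package fixes them explicitly:

- **Test statistic.** The screen's p-values come from a spreadsheet-style
  analysis whose underlying test is unspecified. We default to the Welch
  two-sample t-test on log2 intensities — the defensible default for tiny,
  possibly unequal groups — and expose `pooled = TRUE` for sensitivity
  analysis with the Student test.
- **Fold-change symmetry.** "Fold change of 1.3" is applied symmetrically
  (max(FC, 1/FC) > 1.3): down-regulated genes with FC ≈ 0.7 are bona fide
  calls, which matches published examples of starred sub-unity fold
  changes.
- **Strict inequalities.** A probe at exactly p = 0.05 or FC = 1.3 fails.
- **Probe collapse.** A gene is significant iff ≥ 1 probe is; the reported
  p and fold change come from the minimum-p probe (ties: smallest probe id
  lexicographically). This rule is our own — probe multiplicity is a fact
  of the array, but no collapse rule is published — and it changes gene
  counts, so it is stated prominently here.
- **Fold change as mean ratio.** KO/WT ratio of group means (not medians)
  on the linear scale.
- **Rounding.** Percentages round half-up: two decimals for per-term and
  total percentages, one decimal for the DEG share. Because a share of
  3.05% may be displayed as "3" in integer-style reporting, totals carry
  both a one-decimal and an integer-rounded column.
- **Direction of FC exactly 1.** Classified `flat`, a class unreachable
  for significant genes under the FC criterion but defined for totality.
- **Ranking tie-breaks.** Descending by the chosen key, then by the other
  key, then alphabetically.
- **Ontology traversal.** Only is_a edges are followed; `part_of`
  relationships are parsed and counted but not traversed (a notice is
  emitted). Gene identity is the case-sensitive symbol string — users of
  real data must pre-map aliases.
- **Snapshot pool sizes.** Published per-term set sizes come from a 2017
  GO snapshot that cannot be regenerated from the live ontology; they are
  treated as fixture parameters of the synthetic generator, never as
  values to validate against current GO. Similarly, the disorder preset
  has 14 term slots over 13 distinct terms (one histone-methylation term
  is shared by BIP and SCZ); pool reports surface both numbers.

## The synthetic-data generator

Downstream correctness is established on generated data with known ground
truth (`simulation_design()`, `generate_expression()`,
`generate_annotations()`, `generate_scenario()`).

**Intensity model.** Log-normal: per-probe baseline log2 intensity drawn
N(8, 1.5), knockout effects added on the log2 scale to all probes of the
affected gene in the matching (region, age), Gaussian noise of SD 0.15
log2 units added per measurement, then exponentiated. This is the standard
first-order approximation of normalised microarray intensities. It does
**not** model probe-specific affinity, intensity-dependent variance,
background, batch or normalisation artefacts — so passing tests certify
the screening logic, not robustness to raw-array pathology. Inputs to the
pipeline are assumed normalised.

**Probe multiplicity.** Each gene gets a uniform 1–4 probes (the array
this emulates averages ≈ 2.1 probes per gene).

**Annotation fixtures.** `go_fixture_spec()` takes per-term set sizes and
an exact count of redundant memberships; the generator fills terms largest
first, reusing already-used genes against the redundancy budget, and the
identity *sum(sizes) − |union| = redundancy* holds exactly for every
satisfiable specification (infeasible ones are rejected with the violated
bound). With `ontology_depth > 0`, a fraction of memberships is attached
to generated is_a children so that parsing without descendant expansion
cannot recover the configured sets.

**Presets.**

- `null` — no effects; 5000 genes (≈ 12.5k probes) and **10** arrays per
  group. Ten, not the pooled design's two, because the Welch approximation
  is conservative at n = 2 (measured raw rejection ≈ 0.024 at α = 0.05),
  which would invalidate calibration of the caller rather than measure it;
  at n = 10 the raw rate sits within 3 binomial SEs of 0.05 over ≥ 10,000
  probes.
- `paper_like` — the 13-term configuration with snapshot sizes (union
  1207 genes); 2 arrays per group, mirroring the pooled design. Per
  condition it plants 16 SCZ, 6 BIP and 4 MDD pool-exclusive genes at
  log2 effect 1.5. The preset's contract is qualitative — SCZ first by DEG
  number in every condition — and at n = 2 the per-gene power of the joint
  criterion is only ≈ 0.78 even at a strong ~2.8-fold effect, with
  pool-wide false positives adding noise of a few genes per disorder, so
  the planted margins are sized for the ordering to hold dependably rather
  than to mimic published magnitudes. Five further SCZ genes are planted
  as cross-age common genes (cortex: one up, one down at both ages;
  hippocampus: three, one contra-regulated).
- `contra_demo` — one gene at +0.7/−0.7 log2 across the two ages in the
  hippocampus, 10 arrays per group (pilot power for the common + contra
  call ≥ 0.95 at that n).

Ground-truth tables accompany every bundle so tests never reach into
generator internals.

## Problem sizes and verification

The test suite and the acceptance report run the worked-example pool
arithmetic (union sizes 448/556/335 from the configured term sizes and
overlaps; DEG shares 4.1/4.9/3 from 93/111/69 over 2261; the 9.26 = 5/54
per-term cell) exactly; calibrate the caller on ≈ 12.5k null probes;
check ontology expansion against brute-force reachability on 200-node
random DAGs; check BH/Bonferroni against a longhand step-up computation;
verify planted-effect recovery ≥ 95% at 10 arrays/group (measured ≈ 100%
at log2 effect 1.5, noise SD 0.15); and confirm the SCZ-first ordering and
the cross-age common-gene pattern (including the two contra-regulated
genes) on fixtures. These sizes keep a full run in well under a minute on
one core while leaving each statistical check adequately powered.

## Known limitations

- No normalisation, background correction or batch adjustment; the
  pipeline begins at a normalised probe matrix.
- Enrichment statistics (hypergeometric tests, pathway analysis) are out
  of scope: rankings are by raw counts and percentages of pool, as in the
  screen this systematises.
- The GAF/OBO readers accept the common tab-separated dialects described
  above, not every historical variant; QuickGO TSV exports should be
  converted to GAF columns first.
- At n = 2 arrays per group, p-values from any t-family test are fragile;
  results at that depth are screening signals, not inference.
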