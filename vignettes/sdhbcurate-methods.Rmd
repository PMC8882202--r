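---
title: "Methods: dual-framework SDHB variant classification and consensus curation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-framework SDHB variant classification and consensus curation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdhbcurate)
```

## Scientific model

Germline *SDHB* variants cause hereditary paraganglioma/pheochromocytoma
(PPGL) through loss of function of the succinate dehydrogenase complex; the
tumour typically loses the remaining wild-type allele. This biology makes
tumour-derived evidence unusually informative: loss of the *wild-type*
allele, negative SDHB immunohistochemistry (with retained SDHA staining),
lost SDH enzymatic activity, an SDHx-type transcriptomic profile
(cluster 1A), reduced SDHB protein on western blot, or aberrant cDNA
splicing all argue that the variant disables the complex — while loss of
the *variant* allele in the tumour, or assays showing preserved function,
argue against it.

The package models the complete curation workflow for a multicentric cohort
of index cases:

1. parse and normalize submitted HGVS c. descriptions, collapse cases to
   distinct variants with recurrence counts;
2. classify every variant independently under (a) an SDHB-adapted ACMG/AMP
   rule engine and (b) a PPGL-specific decision tree;
3. measure concordance and resolve the pairs through a deterministic
   two-round consensus stage with an expert override ledger;
4. summarize the cohort (clinical table, recurrence bins, type and class
   distributions) and export the finalized classifications.

All stages are pure functions of their inputs plus explicit configuration
objects, and every report embeds an MD5 hash of the resolved configuration.

## Variant model

Descriptions are coding-DNA HGVS on NM_003000.2, taken as submitted (no
3'-shifting, no genomic liftover). Twelve mutually exclusive types split
into seven substitution types and five deletion/duplication types. The
typing rules:

- intronic offset within ±2 of a junction → splice site; deeper →
  mid-intronic; protein annotations contradicting an intronic position are
  a consistency error, not silently fixed;
- `-` prefix → 5'UTR; coding positions 1–3 → initiation codon;
- coding substitutions follow the protein consequence (Ter → nonsense,
  `=` → synonymous, default missense);
- indels: `?` breakpoints denote whole-exon scale events
  (large rearrangement); a breakpoint pair straddling a junction is a
  splice-site indel; fully intronic indels split at the ±2 boundary;
  coding indels follow the protein (`fs`) or net length change modulo 3.

Deduplication keys on the normalized cDNA string, so case and whitespace
differences collapse; `sum(count)` always equals the number of input cases.

## In silico module

Predictors are never executed; their pre-computed outputs arrive as table
columns. The conservation ratio is the fraction of 14 ortholog residues
identical to the human residue (gaps count as non-matching). Missense
outputs aggregate to `supports_pathogenic` / `supports_benign` only when at
least two tools agree and none opposes; any opposition is `conflicting`,
anything thinner is `insufficient`. Splice outputs compare reference and
alternate MaxEntScan / NNSplice scores: a relative drop ≥ 15% (or an
NNSplice site detected in the reference but lost in the alternate) supports
pathogenicity unless another tool shows essentially no change; all-tools
no-change supports a benign call.

All cutoffs live in `insilico_config()` and are **package defaults**, not
values fixed by any particular study: the original supplementary threshold
tables were not available to this implementation, so conventional published
per-tool cutoffs are used and everything is configurable.

## Adapted ACMG engine

Criteria never evaluated for *SDHB*: PS4, BP1, PP2, PM1, PM3, PM6, PS2
(de novo events are rare and penetrance is incomplete) and PP4 (the PPGL
phenotype is not gene-specific). Tumour-assay evidence maps onto six
adapted tiers:

| tier | code | trigger |
|---|---|---|
| benign strong | `FA_BS` | variant-carrying allele lost in tumour |
| benign supporting | `FA_BP` | no LOH, or assay not in favour of loss of function |
| pathogenic supporting | `FA_PP` | wild-type allele lost (LOH) |
| pathogenic moderate | `FA_PM` | assay in favour of SDH loss of function, SDHx genes not all analysed |
| pathogenic strong | `FA_PS` | SDH loss of function and no additional SDHx variant |
| pathogenic very strong | `FA_PVS` | SDHB-specific loss of function: SDHB IHC−, SDHA IHC+, other SDHx excluded |

`FA_PVS` supersedes `FA_PS`/`FA_PM`; simultaneous benign- and
pathogenic-direction assays return all triggered criteria flagged as a
conflict. Combining follows the canonical ACMG/AMP table verbatim
(`combine_strength_counts()` is exhaustively tested against an independent
brute-force oracle); note this means a rare null variant carrying only
{PVS1, PM2} is *likely* pathogenic, not pathogenic. A configurable
"reputation" ladder converts net published assertions into one criterion
between benign-strong and pathogenic-strong. Allele-frequency cutoffs
(BA1 0.005, BS1 5e-4, PM2 1e-5) are package defaults for a rare,
incompletely penetrant dominant tumour syndrome.

## PPGL decision tree

The gene-specific framework is implemented as a versioned, JSON-serializable
decision tree (`ngsnppgl_default_tree()`, shipped at
`inst/extdata/ngsnppgl_tree.json`) so the topology can be revised without
code changes. Node order encodes the framework's factor precedence:

1. frequency gate — common variants are benign/likely benign outright, and
   frequency leaves accept **no** adjustment (no assay rescues a common
   variant);
2. rare truncating (null) variants are likely pathogenic;
3. otherwise in silico verdicts, then co-segregation (≥ 3 informative
   meioses), then a default VUS fall-through;
4. at every non-frequency leaf, evidence axes move the class by exactly one,
   saturating at 1 and 5: SDHB-specific loss of function, SDH loss of
   function with other SDHx excluded, or strong published evidence
   (net ≥ 5 assertions) promote; a benign-direction assay demotes;
   opposing axes cancel; recurrence (≥ 10 index cases) promotes truncating
   leaves.

Classification returns a complete audit trace (node, observed value, branch
taken) and is a pure function of (profile, tree).

## Consensus stage

Expert judgment is not simulatable, so it is externalized: an **override
ledger** (TSV of `cdna`, `final_class`, `citation`) takes absolute
precedence in both rounds, and a ledger entry naming an unknown variant is
an error. The deterministic policy underneath:

- **Round 1** — concordant pairs are retained; a concordant likely
  pathogenic call seen in ≥ 10 index cases with strong functional evidence
  is promoted to pathogenic. Discordant pairs resolve toward the
  functional-evidence direction; failing that, a one-class gap around VUS
  resolves to the non-VUS class when non-functional evidence (in silico,
  segregation, priors) is directional. Everything else goes to round 2.
- **Round 2** — functional direction wins; with none, the tie-break policy
  applies (default: the *less* pathogenic candidate, the conservative
  clinical choice since predictive testing of relatives requires an LPV/PV
  call).

Every variant receives exactly one final class; the output records round,
source (`policy`/`override`) and rationale per variant.

## Reference fixtures and cohort summaries

`fixture_reference_tables()` transcribes the printed breakdowns of the curated
reference cohort (737 index cases, 223 distinct variants): the clinical
table, the pre-curation class-pair concordance (161/62), the first-round
outcome (91 + 9 + 48 decided, 75 unresolved), recurrence bins
(122/75/12/9/5), variant types (162 substitutions / 61 indels) and final
classes (2/21/51/83/66 → merged 23/51/149). These are data, not
computations, and anchor desk-scale arithmetic tests. Percentages use the
known-denominator convention (unknowns excluded), one decimal for clinical
rows, integers for type rows, rounding half away from zero. A variant seen
exactly 20 times falls in the open top recurrence bin.

## Synthetic cohort generator

`generate_cohort()` draws a cohort with exact marginal quotas
(largest-remainder scaling) for variant types, recurrence bins and
ground-truth classes, then writes **class-consistent** evidence: truncating
types carry (likely) pathogenic truth; pathogenic truth gets ultra-rare
frequency, published assertions and — at the transcribed availability rates
— confirmatory tumour assays; likely benign truth gets an elevated (BS1
band) frequency plus benign-direction predictions or assays; VUS truth gets
deliberately thin data. Recurrent counts land preferentially on pathogenic
founder alleles. At the default zero noise rate no assay contradicts truth,
and the full pipeline recovers the ground-truth class for 100% of variants
at the tested seeds (the acceptance criterion requires ≥ 90%). The
generator emulates cohort *structure* for benchmarking, not the joint
clinical distribution: clinical fields are independent categorical draws.

## Determinism and audit

Generation is a pure function of the seed; classification is a pure
function of (input, config); reports are written as canonical TSV (UTF-8,
LF, unquoted) and are byte-identical across runs. Every report row carries
the criteria met, the decision-tree trace, the consensus round, source and
rationale, and the configuration hash. LOVD export refuses tables with
unresolved final classes.

## Limitations

- Threshold values (frequency cutoffs, predictor cutoffs, reputation
  ladder, recurrence threshold) are documented package defaults, replaceable
  via the config objects; they were not calibrated against unavailable
  supplementary material.
- The consensus policy is a deterministic interpretation of a human process;
  real expert decisions should enter through the override ledger, which is
  why it has absolute precedence.
- HGVS support covers the coding-DNA forms used for this gene (no 3'UTR
  substitutions, no inversions, no mosaic/allele syntax), and descriptions
  are not 3'-shifted.
- The generator's clinical fields match marginal frequencies only; it is
  not a model of genotype–phenotype correlation.
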