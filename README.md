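# sdhbcurate

Dual-framework classification and expert-style consensus curation of germline
**SDHB** variants.

Heterozygous germline variants in *SDHB* (the iron-sulfur subunit of
succinate dehydrogenase) predispose to hereditary paraganglioma and
pheochromocytoma (PPGL) with a high risk of metastatic disease, so the
pathogenicity call on a single variant drives predictive testing and
surveillance for whole families. Two classification practices coexist:
the generic ACMG/AMP criteria and a PPGL-specific decision framework built
on frequency, variant type, in silico predictions, segregation and tumour
assays. The two frequently disagree, and a large fraction of variants land
in the clinically unusable "unknown significance" class until experts
weigh the tumour-based evidence.

`sdhbcurate` implements that entire workflow as a deterministic, auditable
pipeline:

- **Variant model** — hand-rolled HGVS-c parser and typer for the
  NM_003000.2 transcript (substitutions, indels, intronic offsets, 5'UTR,
  whole-exon events with `?` breakpoints), plus case deduplication into
  distinct variants with recurrence counts.
- **In silico module** — amino-acid conservation across 14 orthologs and
  aggregation of pre-computed predictor outputs (PolyPhen-2, SIFT,
  Align-GVGD, MutationTaster, MaxEntScan, NNSplice) into categorical
  verdicts. Predictors are never executed; their outputs arrive as columns.
- **Adapted ACMG engine** — the standard combining rules with SDHB-specific
  exclusions (PS4, BP1, PP2, PM1, PM3, PM6, PS2, PP4 are never evaluated)
  and six adapted tumour-assay tiers from benign-strong (variant allele lost
  in tumour) up to pathogenic-very-strong (SDHB-negative / SDHA-positive
  immunohistochemistry with other SDHx genes excluded).
- **PPGL decision tree** — the gene-specific framework as a configurable,
  JSON-serializable decision tree returning a full audit trace; a frequency
  gate dominates, and assay/recurrence evidence moves leaf classes by one.
- **Consensus stage** — a deterministic two-round arbitration between the
  two engines with an expert **override ledger** (TSV of documented
  decisions) taking absolute precedence.
- **Cohort summaries** — clinical presentation table with the
  known-denominator convention, recurrence bins, variant-type and class
  distributions.
- **Synthetic cohort generator** — quota-sampled cohorts with known ground
  truth (by default 737 index cases over 223 distinct variants) for
  benchmarking the full pipeline.
- **IO / CLI** — TSV evidence tables, minimal VCF import, aligned-FASTA
  conservation, LOVD-style export, and a thin command-line front end.

## Worked example

A rare nonsense variant reported in 14 independent index cases, with
SDHB-negative / SDHA-positive tumour immunohistochemistry and the other SDHx
genes excluded:

```r
library(sdhbcurate)

v <- parse_variant("c.268C>T", "p.Arg90Ter")
print(v)
#> c.268C>T (p.Arg90Ter) [nonsense]

e <- evidence_profile(v, shdb_ihc = "negative", sdha_ihc = "positive",
                      other_sdhx_excluded = TRUE, case_count = 14)
res <- classify_both(e)
res$criteria[, c("code", "strength")]
#>     code               strength
#> 1   PVS1 pathogenic_very_strong
#> 2    PM2    pathogenic_moderate
#> 3 FA_PVS pathogenic_very_strong

res$trace
#>                node             value  branch
#> 1   freq_standalone              <NA>      no
#> 2       freq_benign              <NA>      no
#> 3        truncating              TRUE     yes
#> 4   rare_truncating               LPV    leaf
#> 5      adjust_assay sdhb_specific_lof promote
#> 6 adjust_recurrence                14 promote

tier_label(c(res$acmg, res$ngs))
#> [1] "PV" "PV"
```

Both engines call the variant pathogenic independently; `curate()` then
retains the concordant class:

```r
curate(data.frame(cdna = v$cdna, acmg = res$acmg, ngs = res$ngs,
                  case_count = 14),
       criteria = setNames(list(res$criteria), v$cdna))
#>       cdna acmg ngs final_class round                          rationale
#> 1 c.268C>T    5   5           5     1 concordant classification retained
```

The same pipeline runs on whole tables (`classify_table()`), files
(`read_evidence_table()`, `write_tsv()`, `read_vcf_variants()`,
`export_lovd()`), and from the shell:

```sh
Rscript inst/cli/sdhbcurate.R simulate --seed 2 \
    --out-cases cases.tsv --out-profiles profiles.tsv
Rscript inst/cli/sdhbcurate.R classify --in profiles.tsv --out report.tsv
Rscript inst/cli/sdhbcurate.R export-lovd --in report.tsv --out lovd.tsv
```

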