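# The per-variant evidence container consumed by both classification
# engines. Tumour-assay fields default to "not_done"; clinical and molecular
# evidence fields are optional (NA).

#' Build a per-variant evidence profile
#'
#' Collects all machine-readable evidence for one variant: population
#' frequency, index-case recurrence, co-segregation, in silico verdicts, and
#' tumour-assay results (LOH, SDHB/SDHA immunohistochemistry, SDH enzymatic
#' activity, transcriptomic cluster, western blot, cDNA splicing analysis),
#' plus prior published assertions. Assay fields default to `"not_done"`.
#'
#' @param variant an `sdhb_variant` (see [parse_variant()]).
#' @param max_population_af highest allele frequency observed in reference
#'   populations (gnomAD/ESP); `NA` when the variant is absent from controls.
#' @param af_source label for the frequency source.
#' @param case_count number of independent index cases reported with the
#'   variant (>= 1).
#' @param coseg_meioses number of informative meioses observed in families.
#' @param coseg_segregates logical: does the variant segregate with disease?
#' @param de_novo logical; de novo occurrence (expected rare for SDHB).
#' @param insilico_missense,insilico_splice categorical verdicts from
#'   [missense_verdict()] / [splice_verdict()]; `NA` if not assessed.
#' @param cdna_splicing `"aberrant"`, `"normal"` or `"not_done"`.
#' @param loh `"variant_allele_retained_wt_lost"` (loss of the wild-type
#'   allele in tumour DNA), `"variant_allele_lost"`, `"no_loh"` or
#'   `"not_done"`.
#' @param shdb_ihc,sdha_ihc SDHB / SDHA tumour immunohistochemistry:
#'   `"negative"`, `"positive"` or `"not_done"`.
#' @param sdh_activity `"lost"`, `"preserved"` or `"not_done"`.
#' @param transcriptomic_cluster `"cluster_1A"` (SDHx-related), `"cluster_1B"`
#'   (VHL-related), `"cluster_2A"` (RET/NF1/sporadic) or `"not_done"`.
#' @param western SDHB western blot: `"reduced_absent"`, `"normal"` or
#'   `"not_done"`.
#' @param other_sdhx_excluded logical: SDHA/SDHC/SDHD genotyping performed
#'   and negative.
#' @param prior_pathogenic,prior_benign counts of published pathogenic /
#'   benign assertions for the variant.
#' @param prior_same_aa_pathogenic logical: the same amino-acid change was
#'   previously established as pathogenic (via a different nucleotide change).
#' @param prior_same_codon_pathogenic logical: a different missense change at
#'   the same codon was previously established as pathogenic.
#' @return an object of class `evidence_profile`.
#' @export
evidence_profile <- function(variant,
                             max_population_af = NA_real_,
                             af_source = "gnomAD",
                             case_count = 1L,
                             coseg_meioses = NA_integer_,
                             coseg_segregates = NA,
                             de_novo = FALSE,
                             insilico_missense = NA_character_,
                             insilico_splice = NA_character_,
                             cdna_splicing = "not_done",
                             loh = "not_done",
                             shdb_ihc = "not_done",
                             sdha_ihc = "not_done",
                             sdh_activity = "not_done",
                             transcriptomic_cluster = "not_done",
                             western = "not_done",
                             other_sdhx_excluded = FALSE,
                             prior_pathogenic = 0L,
                             prior_benign = 0L,
                             prior_same_aa_pathogenic = FALSE,
                             prior_same_codon_pathogenic = FALSE) {
  stopifnot(inherits(variant, "sdhb_variant"))
  if (!is.na(max_population_af)) {
    stopifnot(max_population_af >= 0, max_population_af <= 1)
  }
  case_count <- as.integer(case_count)
  stopifnot(case_count >= 1L)
  ok <- function(x, levels) is.na(x) || x %in% levels
  stopifnot(
    ok(insilico_missense, c("supports_pathogenic", "supports_benign",
                            "conflicting", "insufficient")),
    ok(insilico_splice, c("supports_pathogenic", "supports_benign",
                          "insufficient")),
    cdna_splicing %in% c("aberrant", "normal", "not_done"),
    loh %in% c("variant_allele_retained_wt_lost", "variant_allele_lost",
               "no_loh", "not_done"),
    shdb_ihc %in% c("negative", "positive", "not_done"),
    sdha_ihc %in% c("negative", "positive", "not_done"),
    sdh_activity %in% c("lost", "preserved", "not_done"),
    transcriptomic_cluster %in% c("cluster_1A", "cluster_1B", "cluster_2A",
                                  "not_done"),
    western %in% c("reduced_absent", "normal", "not_done"),
    is.logical(other_sdhx_excluded)
  )
  structure(
    list(variant = variant,
         max_population_af = max_population_af,
         af_source = af_source,
         case_count = case_count,
         coseg_meioses = coseg_meioses,
         coseg_segregates = coseg_segregates,
         de_novo = isTRUE(de_novo),
         insilico_missense = insilico_missense,
         insilico_splice = insilico_splice,
         cdna_splicing = cdna_splicing,
         loh = loh,
         shdb_ihc = shdb_ihc,
         sdha_ihc = sdha_ihc,
         sdh_activity = sdh_activity,
         transcriptomic_cluster = transcriptomic_cluster,
         western = western,
         other_sdhx_excluded = isTRUE(other_sdhx_excluded),
         prior_pathogenic = as.integer(prior_pathogenic),
         prior_benign = as.integer(prior_benign),
         prior_same_aa_pathogenic = isTRUE(prior_same_aa_pathogenic),
         prior_same_codon_pathogenic = isTRUE(prior_same_codon_pathogenic)),
    class = "evidence_profile")
}

#' @export
print.evidence_profile <- function(x, ...) {
  cat("Evidence profile for ", x$variant$cdna, " [", x$variant$vtype, "]\n",
      "  AF: ", if (is.na(x$max_population_af)) "absent from controls"
      else format(x$max_population_af), " (", x$af_source, ")",
      "; index cases: ", x$case_count, "\n", sep = "")
  assays <- c(loh = x$loh, shdb_ihc = x$shdb_ihc, sdha_ihc = x$sdha_ihc,
              activity = x$sdh_activity, cluster = x$transcriptomic_cluster,
              western = x$western, cdna = x$cdna_splicing)
  done <- assays[assays != "not_done"]
  cat("  assays: ", if (length(done)) paste(names(done), done, sep = "=",
                                            collapse = ", ") else "none", "\n",
      sep = "")
  invisible(x)
}
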