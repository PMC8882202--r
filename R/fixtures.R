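# Reference tallies transcribed from the published expert-curated SDHB
# cohort (737 index cases collapsing to 223 distinct variants). These are
# printed breakdowns, transcribed as data -- not computed here -- and used as
# desk-scale worked examples for the accounting functions.

#' Transcribed reference-cohort tallies
#'
#' Returns the printed breakdowns of the expert-curated SDHB study cohort as
#' in-memory fixtures:
#' \describe{
#'   \item{table1}{clinical presentation counts for all 737 index cases and
#'     for the 614 carriers of (likely) pathogenic variants.}
#'   \item{concordance_pairs}{one row per distinct variant (223) with the
#'     framework classes assigned before curation: 161 concordant (6 LBV,
#'     61 VUS, 70 LPV, 24 PV) and 62 discordant (4 BV/LBV, 1 VUS/BV,
#'     17 VUS/LBV, 23 LPV/VUS, 6 VUS/PV, 11 LPV/PV).}
#'   \item{round1}{first-round curation outcome counts: 91 concordant calls
#'     retained, 9 likely pathogenic calls promoted to pathogenic, 48
#'     discordant variants resolved, 75 left unresolved (5 VUS/LBV,
#'     5 VUS/PV, 36 VUS/LPV, 29 LPV/PV).}
#'   \item{occurrence_bins}{recurrence bins of the 223 distinct variants.}
#'   \item{vtype_counts}{variant-type counts of the 223 distinct variants.}
#'   \item{class_counts}{final consensus class counts (2 BV, 21 LBV, 51 VUS,
#'     83 LPV, 66 PV).}
#'   \item{evidence_counts}{number of distinct variants with each tumour
#'     assay reported.}
#' }
#'
#' @return named list of fixtures; each element carries a `source` attribute
#'   describing what it transcribes.
#' @export
fixture_reference_tables <- function() {
  src <- function(x, what) {
    attr(x, "source") <- paste("transcribed from the published curated SDHB",
                               "cohort breakdown:", what)
    x
  }

  table1 <- data.frame(
    field = c(rep("tumours", 9), rep("metastatic", 3), rep("family_history", 3)),
    stratum = c("single_ppgl", "single_hn_pgl", "single_tap_pgl", "single_pcc",
                "single_site_not_specified", "multiple_ppgl", "rcc_only",
                "gist_only", "not_specified",
                "yes", "no", "not_specified",
                "yes", "no", "not_specified"),
    all_cases = c(618L, 213L, 184L, 78L, 143L, 103L, 8L, 2L, 6L,
                  133L, 238L, 366L,
                  159L, 374L, 204L),
    lp_p_cases = c(514L, 171L, 166L, 47L, 130L, 89L, 5L, 2L, 4L,
                   122L, 183L, 309L,
                   142L, 287L, 185L),
    stringsAsFactors = FALSE)
  attr(table1, "n_all") <- 737L
  attr(table1, "n_lp_p") <- 614L

  expand_pairs <- function(acmg, ngs, n) {
    data.frame(acmg = rep(as_tier(acmg), n), ngs = rep(as_tier(ngs), n))
  }
  concordance_pairs <- rbind(
    expand_pairs("LBV", "LBV", 6), expand_pairs("VUS", "VUS", 61),
    expand_pairs("LPV", "LPV", 70), expand_pairs("PV", "PV", 24),
    # discordant pairs; within each pair the first label is taken as the
    # ACMG-side class and the second as the PPGL-framework class
    expand_pairs("BV", "LBV", 4), expand_pairs("VUS", "BV", 1),
    expand_pairs("VUS", "LBV", 17), expand_pairs("LPV", "VUS", 23),
    expand_pairs("VUS", "PV", 6), expand_pairs("LPV", "PV", 11))
  concordance_pairs$cdna <- sprintf("ref_variant_%03d",
                                    seq_len(nrow(concordance_pairs)))

  round1 <- list(
    unchanged = 91L,
    unchanged_breakdown = c(LBV = 5L, VUS = 28L, LPV = 35L, PV = 23L),
    promoted_lpv_to_pv = 9L,
    discordant_resolved = 48L,
    resolved_breakdown = c(BV = 2L, LBV = 12L, VUS = 12L, LPV = 8L, PV = 14L),
    unresolved_breakdown = c("VUS/LBV" = 5L, "VUS/PV" = 5L,
                             "VUS/LPV" = 36L, "LPV/PV" = 29L))

  occurrence <- c("1" = 122L, "2-5" = 75L, "6-10" = 12L, "11-20" = 9L,
                  ">=20" = 5L)

  vtype_counts <- c(
    missense = 98L, nonsense = 21L, splice_site_substitution = 20L,
    mid_intronic = 12L, synonymous = 6L, utr5 = 3L, initiation_codon = 2L,
    frameshift_indel = 38L, large_rearrangement = 14L, inframe_indel = 4L,
    noncoding_indel = 3L, splice_site_indel = 2L)

  class_counts <- c(BV = 2L, LBV = 21L, VUS = 51L, LPV = 83L, PV = 66L)

  evidence_counts <- c(ihc = 75L, loh = 26L, cluster = 24L, cdna = 15L,
                       western = 7L, activity = 6L)

  list(
    table1 = src(table1, "clinical presentation table"),
    concordance_pairs = src(concordance_pairs,
                            "pre-curation framework concordance"),
    round1 = src(round1, "first-round curation outcomes"),
    occurrence_bins = src(occurrence, "variant recurrence bins"),
    vtype_counts = src(vtype_counts, "variant-type distribution"),
    class_counts = src(class_counts, "final consensus class distribution"),
    evidence_counts = src(evidence_counts, "tumour-assay availability"))
}

#' Expand the clinical table fixture into per-case rows
#'
#' Reconstructs a cohort of index-case rows whose marginal tallies equal the
#' transcribed clinical table. Fields are filled independently (the joint
#' distribution across fields was not printed), which leaves every marginal
#' statistic computed by [clinical_table()] exact.
#'
#' @param which `"all"` for the full cohort (737 rows) or `"lp_p"` for the
#'   (likely) pathogenic carrier subcohort (614 rows).
#' @return data frame with columns `case_id`, `presentation`, `metastatic`,
#'   `family_history`, `carrier_group`.
#' @export
fixture_cohort_cases <- function(which = c("all", "lp_p")) {
  which <- match.arg(which)
  fx <- fixture_reference_tables()$table1
  col <- if (which == "all") fx$all_cases else fx$lp_p_cases
  n <- if (which == "all") attr(fx, "n_all") else attr(fx, "n_lp_p")
  get <- function(field, stratum) col[fx$field == field & fx$stratum == stratum]

  pres <- rep(c("single_hn_pgl", "single_tap_pgl", "single_pcc",
                "single_ppgl_site_unspecified", "multiple_ppgl", "rcc_only",
                "gist_only", NA),
              c(get("tumours", "single_hn_pgl"),
                get("tumours", "single_tap_pgl"),
                get("tumours", "single_pcc"),
                get("tumours", "single_site_not_specified"),
                get("tumours", "multiple_ppgl"),
                get("tumours", "rcc_only"),
                get("tumours", "gist_only"),
                get("tumours", "not_specified")))
  met <- rep(c("yes", "no", NA),
             c(get("metastatic", "yes"), get("metastatic", "no"),
               get("metastatic", "not_specified")))
  fam <- rep(c("yes", "no", NA),
             c(get("family_history", "yes"), get("family_history", "no"),
               get("family_history", "not_specified")))
  stopifnot(length(pres) == n, length(met) == n, length(fam) == n)
  n_lp_p <- attr(fx, "n_lp_p")
  data.frame(
    case_id = sprintf("case_%03d", seq_len(n)),
    presentation = pres,
    metastatic = met,
    family_history = fam,
    carrier_group = if (which == "all") {
      rep(c("lp_p", "other"), c(n_lp_p, n - n_lp_p))
    } else rep("lp_p", n),
    stringsAsFactors = FALSE)
}
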