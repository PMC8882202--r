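# SDHB/PPGL-adapted ACMG/AMP rule engine.
#
# The standard criteria that are not applicable to SDHB are never evaluated:
# PS4, BP1, PP2, PM1, PM3, PM6, PS2 (de novo cases are very rare and the
# disease has low penetrance) and PP4 (multiple PPGL susceptibility genes
# make the phenotype non-specific). Tumour-assay ("additional data")
# evidence is mapped onto six adapted strengths ranging from benign strong
# to pathogenic very strong.

#' Criterion strength vocabulary
#' @format Character vector of the seven evidence strengths.
#' @export
STRENGTH_LEVELS <- c("stand_alone_benign", "benign_strong", "benign_supporting",
                     "pathogenic_supporting", "pathogenic_moderate",
                     "pathogenic_strong", "pathogenic_very_strong")

#' ACMG criteria excluded for SDHB
#' @format Character vector of codes never emitted by [assign_criteria()].
#' @export
EXCLUDED_CRITERIA <- c("PS4", "BP1", "PP2", "PM1", "PM3", "PM6", "PS2", "PP4")

criterion <- function(code, strength, rationale) {
  strength <- match.arg(strength, STRENGTH_LEVELS)
  data.frame(code = code, strength = strength, rationale = rationale,
             stringsAsFactors = FALSE)
}

empty_criteria <- function() {
  data.frame(code = character(), strength = character(),
             rationale = character(), stringsAsFactors = FALSE)
}

#' Default configuration of the ACMG engine
#'
#' Allele-frequency cutoffs are package defaults chosen for a rare,
#' incompletely penetrant dominant tumour syndrome; the reported-evidence
#' ("reputation") ladder converts the net count of published pathogenic minus
#' benign assertions into a criterion strength. All values are configurable
#' and a hash of the resolved configuration is embedded in every report.
#'
#' @param af_ba1 stand-alone benign allele-frequency cutoff.
#' @param af_bs1 strong benign allele-frequency cutoff.
#' @param af_pm2 frequency at or below which a variant counts as
#'   absent/ultra-rare in controls (PM2).
#' @param min_meioses minimum informative meioses for co-segregation
#'   criteria (PP1/BS4).
#' @param init_codon_strength strength granted to initiation-codon variants
#'   under the null-variant criterion (decremented from very strong by
#'   default, reflecting common practice).
#' @param rep_strong,rep_moderate,rep_supporting,rep_benign_strong cutoffs on
#'   the net published assertion count for the reputation criterion.
#' @return named list.
#' @export
acmg_config <- function(af_ba1 = 0.005,
                        af_bs1 = 5e-4,
                        af_pm2 = 1e-5,
                        min_meioses = 3L,
                        init_codon_strength = "pathogenic_strong",
                        rep_strong = 5L, rep_moderate = 2L,
                        rep_supporting = 1L, rep_benign_strong = -2L) {
  init_codon_strength <- match.arg(init_codon_strength, STRENGTH_LEVELS)
  as.list(environment())
}

# true when any tumour assay indicates SDH loss of function
assay_lof <- function(e) {
  e$shdb_ihc == "negative" || e$sdh_activity == "lost" ||
    e$transcriptomic_cluster == "cluster_1A" ||
    e$western == "reduced_absent" || e$cdna_splicing == "aberrant"
}

# true when some assay was performed and argues against SDHB loss of function
assay_not_lof <- function(e) {
  e$shdb_ihc == "positive" || e$sdh_activity == "preserved" ||
    e$transcriptomic_cluster %in% c("cluster_1B", "cluster_2A") ||
    e$western == "normal" || e$cdna_splicing == "normal"
}

#' Map tumour-assay evidence to adapted criterion strengths
#'
#' Implements the six SDHB-adapted additional-data tiers:
#' \itemize{
#'   \item benign strong (`FA_BS`): loss of the allele carrying the SDHB
#'     variant in tumour DNA;
#'   \item benign supporting (`FA_BP`): no LOH at the SDHB locus, or an assay
#'     not in favour of SDHB loss of function;
#'   \item pathogenic supporting (`FA_PP`): LOH at the SDHB locus (wild-type
#'     allele lost);
#'   \item pathogenic moderate (`FA_PM`): an assay in favour of SDH loss of
#'     function without all SDHx genes analysed;
#'   \item pathogenic strong (`FA_PS`): evidence for SDH loss of function and
#'     no additional variant found in the other SDHx genes;
#'   \item pathogenic very strong (`FA_PVS`): evidence for SDHB-specific loss
#'     of function (negative SDHB with positive SDHA immunohistochemistry and
#'     other SDHx genes excluded); supersedes `FA_PS`/`FA_PM`.
#' }
#' When benign-direction and pathogenic-direction assays are simultaneously
#' triggered, all criteria are returned and the result carries a
#' `conflict = TRUE` attribute.
#'
#' @param e an [evidence_profile()].
#' @return data frame with columns `code`, `strength`, `rationale`; attribute
#'   `conflict` flags contradictory assays.
#' @export
assign_functional_criteria <- function(e) {
  stopifnot(inherits(e, "evidence_profile"))
  out <- empty_criteria()
  if (e$loh == "variant_allele_lost") {
    out <- rbind(out, criterion("FA_BS", "benign_strong",
      "variant-carrying allele lost in tumour DNA"))
  }
  if (e$loh == "no_loh" || assay_not_lof(e)) {
    out <- rbind(out, criterion("FA_BP", "benign_supporting",
      "no LOH at the SDHB locus and/or assay not in favour of SDHB loss of function"))
  }
  if (e$loh == "variant_allele_retained_wt_lost") {
    out <- rbind(out, criterion("FA_PP", "pathogenic_supporting",
      "LOH at the SDHB locus (wild-type allele lost in tumour)"))
  }
  if (assay_lof(e)) {
    sdhb_specific <- e$shdb_ihc == "negative" && e$sdha_ihc == "positive" &&
      e$other_sdhx_excluded
    if (sdhb_specific) {
      out <- rbind(out, criterion("FA_PVS", "pathogenic_very_strong",
        "SDHB-specific loss of function (SDHB IHC negative, SDHA IHC positive, other SDHx excluded)"))
    } else if (e$other_sdhx_excluded) {
      out <- rbind(out, criterion("FA_PS", "pathogenic_strong",
        "SDH loss of function with no additional variant in SDHx genes"))
    } else {
      out <- rbind(out, criterion("FA_PM", "pathogenic_moderate",
        "assay in favour of SDH loss of function, SDHx genes not all analysed"))
    }
  }
  benign_dir <- any(out$code %in% c("FA_BS", "FA_BP"))
  path_dir <- any(out$code %in% c("FA_PP", "FA_PM", "FA_PS", "FA_PVS"))
  conflict <- benign_dir && path_dir
  if (conflict) {
    out$rationale <- paste0(out$rationale, " [conflicting-evidence]")
  }
  attr(out, "conflict") <- conflict
  out
}

#' Assign all evaluable ACMG criteria for a variant
#'
#' Unions the standard criteria computable from the evidence profile --
#' PVS1 (null variant), PM2 (absent/ultra-rare in controls), PM4 (in-frame
#' length change), PP1/BS4 (co-segregation), PP3/BP4 (in silico verdicts),
#' PS1/PM5 (prior reports of the same change / same codon), BA1/BS1
#' (population frequency), BP7 (synonymous without predicted splice impact)
#' and the reputation criterion `REP` -- with the adapted functional criteria
#' from [assign_functional_criteria()]. The SDHB-excluded codes (PS4, BP1,
#' PP2, PM1, PM3, PM6, PS2, PP4) are never evaluated.
#'
#' @param e an [evidence_profile()].
#' @param config engine configuration, see [acmg_config()].
#' @return data frame of (code, strength, rationale), one row per criterion;
#'   each code appears at most once.
#' @export
assign_criteria <- function(e, config = acmg_config()) {
  stopifnot(inherits(e, "evidence_profile"))
  out <- empty_criteria()
  vt <- e$variant$vtype
  af <- e$max_population_af

  # PVS1: null variant in a gene where loss of function causes disease.
  # Large rearrangements qualify when they are deletions (a whole-gene
  # duplication is not presumed null).
  if (vt %in% NULL_VTYPES) {
    is_large_dup <- vt == "large_rearrangement" && grepl("dup", e$variant$cdna)
    if (!is_large_dup) {
      strength <- if (vt == "initiation_codon") config$init_codon_strength
      else "pathogenic_very_strong"
      out <- rbind(out, criterion("PVS1", strength,
        paste0("null variant (", vt, ")")))
    }
  }
  # population frequency
  if (!is.na(af) && af >= config$af_ba1) {
    out <- rbind(out, criterion("BA1", "stand_alone_benign",
      sprintf("allele frequency %.4g >= %.4g in %s", af, config$af_ba1, e$af_source)))
  } else if (!is.na(af) && af >= config$af_bs1) {
    out <- rbind(out, criterion("BS1", "benign_strong",
      sprintf("allele frequency %.4g >= %.4g in %s", af, config$af_bs1, e$af_source)))
  } else if (is.na(af) || af <= config$af_pm2) {
    out <- rbind(out, criterion("PM2", "pathogenic_moderate",
      if (is.na(af)) paste0("absent from controls (", e$af_source, ")")
      else sprintf("allele frequency %.4g <= %.4g", af, config$af_pm2)))
  }
  # protein length change
  if (vt == "inframe_indel") {
    out <- rbind(out, criterion("PM4", "pathogenic_moderate",
      "in-frame deletion/insertion changes protein length"))
  }
  # co-segregation
  if (!is.na(e$coseg_segregates) && !is.na(e$coseg_meioses) &&
      e$coseg_meioses >= config$min_meioses) {
    if (isTRUE(e$coseg_segregates)) {
      out <- rbind(out, criterion("PP1", "pathogenic_supporting",
        sprintf("co-segregation with disease over %d informative meioses",
                e$coseg_meioses)))
    } else {
      out <- rbind(out, criterion("BS4", "benign_strong",
        sprintf("lack of segregation over %d informative meioses",
                e$coseg_meioses)))
    }
  }
  # in silico
  verdicts <- c(e$insilico_missense, e$insilico_splice)
  verdicts <- verdicts[!is.na(verdicts)]
  if (any(verdicts == "supports_pathogenic")) {
    out <- rbind(out, criterion("PP3", "pathogenic_supporting",
      "computational evidence supports a deleterious effect"))
  } else if (length(verdicts) > 0 && all(verdicts == "supports_benign")) {
    out <- rbind(out, criterion("BP4", "benign_supporting",
      "computational evidence suggests no impact"))
  }
  # prior reports at same residue
  if (e$prior_same_aa_pathogenic) {
    out <- rbind(out, criterion("PS1", "pathogenic_strong",
      "same amino-acid change previously established as pathogenic"))
  } else if (e$prior_same_codon_pathogenic && vt == "missense") {
    out <- rbind(out, criterion("PM5", "pathogenic_moderate",
      "different missense change at a codon with an established pathogenic variant"))
  }
  # synonymous with no predicted splice impact
  if (vt == "synonymous" && !is.na(e$insilico_splice) &&
      e$insilico_splice == "supports_benign") {
    out <- rbind(out, criterion("BP7", "benign_supporting",
      "synonymous variant with no predicted splice impact"))
  }
  # reputation: net published assertions, calibrated between benign strong
  # and pathogenic strong
  net <- e$prior_pathogenic - e$prior_benign
  if (net >= config$rep_strong) {
    out <- rbind(out, criterion("REP", "pathogenic_strong",
      sprintf("net %d published pathogenic assertions", net)))
  } else if (net >= config$rep_moderate) {
    out <- rbind(out, criterion("REP", "pathogenic_moderate",
      sprintf("net %d published pathogenic assertions", net)))
  } else if (net >= config$rep_supporting) {
    out <- rbind(out, criterion("REP", "pathogenic_supporting",
      sprintf("net %d published pathogenic assertions", net)))
  } else if (net <= config$rep_benign_strong) {
    out <- rbind(out, criterion("REP", "benign_strong",
      sprintf("net %d published benign assertions", -net)))
  }

  func <- assign_functional_criteria(e)
  res <- rbind(out, func)
  attr(res, "conflict") <- isTRUE(attr(func, "conflict"))
  stopifnot(!any(res$code %in% EXCLUDED_CRITERIA), !anyDuplicated(res$code))
  rownames(res) <- NULL
  res
}

#' Combine assigned criteria into a 5-tier class
#'
#' Applies the standard ACMG/AMP combining rules over the counts of
#' very-strong/strong/moderate/supporting pathogenic and
#' stand-alone/strong/supporting benign criteria; the adapted functional
#' strengths slot into the same algebra. Satisfying both a pathogenic and a
#' benign rule, or no rule at all, yields VUS.
#'
#' @param criteria data frame from [assign_criteria()] (columns `code`,
#'   `strength`).
#' @return integer tier in 1..5 (see [TIER_LEVELS]).
#' @export
combine_criteria <- function(criteria) {
  stopifnot(is.data.frame(criteria), all(c("code", "strength") %in% names(criteria)
                                         | nrow(criteria) == 0))
  n <- function(s) if (nrow(criteria) == 0) 0L else sum(criteria$strength == s)
  combine_strength_counts(
    pvs = n("pathogenic_very_strong"), ps = n("pathogenic_strong"),
    pm = n("pathogenic_moderate"), pp = n("pathogenic_supporting"),
    ba = n("stand_alone_benign"), bs = n("benign_strong"),
    bp = n("benign_supporting"))
}

#' Combine evidence-strength counts into a 5-tier class
#'
#' The count-level form of [combine_criteria()], useful for exhaustive
#' checks.
#'
#' @param pvs,ps,pm,pp counts of pathogenic very-strong/strong/moderate/
#'   supporting criteria.
#' @param ba,bs,bp counts of stand-alone/strong/supporting benign criteria.
#' @return integer tier in 1..5.
#' @export
combine_strength_counts <- function(pvs = 0, ps = 0, pm = 0, pp = 0,
                                    ba = 0, bs = 0, bp = 0) {
  pathogenic <-
    (pvs >= 2) ||
    (pvs >= 1 && (ps >= 1 || pm >= 2 || (pm == 1 && pp >= 1) || pp >= 2)) ||
    (ps >= 2) ||
    (ps == 1 && (pm >= 3 || (pm == 2 && pp >= 2) || (pm == 1 && pp >= 4)))
  likely_pathogenic <-
    (pvs >= 1 && pm == 1) ||
    (ps == 1 && pm >= 1 && pm <= 2) ||
    (ps == 1 && pp >= 2) ||
    (pm >= 3) ||
    (pm == 2 && pp >= 2) ||
    (pm == 1 && pp >= 4)
  benign <- (ba >= 1) || (bs >= 2)
  likely_benign <- (bs == 1 && bp >= 1) || (bp >= 2)

  path_side <- pathogenic || likely_pathogenic
  benign_side <- benign || likely_benign
  if (path_side && benign_side) return(TIER_LEVELS[["VUS"]])
  if (pathogenic) return(TIER_LEVELS[["PV"]])
  if (likely_pathogenic) return(TIER_LEVELS[["LPV"]])
  if (benign) return(TIER_LEVELS[["BV"]])
  if (likely_benign) return(TIER_LEVELS[["LBV"]])
  TIER_LEVELS[["VUS"]]
}

#' Classify a variant with the adapted ACMG engine
#'
#' Convenience wrapper: [assign_criteria()] followed by
#' [combine_criteria()].
#'
#' @inheritParams assign_criteria
#' @return list with `class` (integer tier), `label`, and `criteria` (the
#'   criterion data frame).
#' @export
classify_acmg <- function(e, config = acmg_config()) {
  crit <- assign_criteria(e, config)
  cls <- combine_criteria(crit)
  list(class = cls, label = tier_label(cls), criteria = crit)
}
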