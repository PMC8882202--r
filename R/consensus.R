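# Two-round consensus stage. Expert judgment is not simulatable, so it is
# externalized as an override ledger (TSV: cdna, final_class, citation) that
# takes absolute precedence over a deterministic arbitration policy.

#' Consensus policy configuration
#'
#' @param recurrence_threshold number of independent index cases at or above
#'   which a concordant likely pathogenic call with strong functional
#'   evidence is promoted to pathogenic in round 1.
#' @param tie_break round-2 fallback when no functional evidence points
#'   either way: `"less_pathogenic"` (conservative clinical default, since
#'   predictive testing of relatives requires an LPV/PV call) or
#'   `"more_pathogenic"`.
#' @return named list.
#' @export
consensus_policy <- function(recurrence_threshold = 10L,
                             tie_break = c("less_pathogenic",
                                           "more_pathogenic")) {
  tie_break <- match.arg(tie_break)
  list(recurrence_threshold = as.integer(recurrence_threshold),
       tie_break = tie_break)
}

#' Read an expert override ledger
#'
#' A TSV with columns `cdna`, `final_class` (1-5 or BV/LBV/VUS/LPV/PV) and
#' `citation`. Ledger entries take absolute precedence over the policy in
#' both curation rounds.
#'
#' @param path TSV file path.
#' @return data frame with columns `cdna`, `final_class` (integer tier),
#'   `citation`.
#' @export
read_override_ledger <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("cdna", "final_class")
  if (!all(req %in% names(df))) {
    stop("override ledger must have columns: ", paste(req, collapse = ", "))
  }
  if (!"citation" %in% names(df)) df$citation <- NA_character_
  # the class column may mix integer codes and labels
  fc <- as.character(df$final_class)
  num <- suppressWarnings(as.integer(fc))
  out <- integer(length(fc))
  out[!is.na(num)] <- as_tier(num[!is.na(num)])
  if (any(is.na(num))) out[is.na(num)] <- as_tier(fc[is.na(num)])
  df$final_class <- out
  df$cdna <- vapply(df$cdna, function(x) parse_variant(x)$cdna, character(1))
  df
}

#' Concordance summary of dual framework classifications
#'
#' @param pairs data frame with columns `acmg` and `ngs` (integer tiers or
#'   labels), one row per variant.
#' @return list with `n_concordant`, `n_discordant`, and `breakdown`: a named
#'   integer vector keyed by unordered class pair (e.g. `"VUS/LPV"`), where
#'   concordant keys are single labels.
#' @export
concordance <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0) stop("pairs must be non-empty")
  acmg <- as_tier(pairs$acmg)
  ngs <- as_tier(pairs$ngs)
  conc <- acmg == ngs
  key <- ifelse(conc, tier_label(acmg),
                paste(tier_label(pmin(acmg, ngs)),
                      tier_label(pmax(acmg, ngs)), sep = "/"))
  breakdown <- table(key)
  out <- list(n_concordant = sum(conc), n_discordant = sum(!conc),
              breakdown = stats::setNames(as.integer(breakdown),
                                          names(breakdown)))
  stopifnot(out$n_concordant + out$n_discordant == nrow(pairs),
            sum(out$breakdown) == nrow(pairs))
  out
}

ledger_class_for <- function(cdna, overrides) {
  if (is.null(overrides) || nrow(overrides) == 0) return(NA_integer_)
  hit <- overrides$final_class[overrides$cdna == cdna]
  if (length(hit) == 0) NA_integer_ else hit[[1]]
}

# direction of the adapted functional (tumour-assay) criteria for a variant
functional_direction <- function(criteria) {
  if (is.null(criteria) || nrow(criteria) == 0) return("none")
  path <- any(criteria$code %in% c("FA_PP", "FA_PM", "FA_PS", "FA_PVS"))
  ben <- any(criteria$code %in% c("FA_BS", "FA_BP"))
  direction_label(path, ben)
}

direction_label <- function(path, ben) {
  if (path && ben) {
    "conflict"
  } else if (path) {
    "pathogenic"
  } else if (ben) {
    "benign"
  } else {
    "none"
  }
}

has_strong_functional <- function(criteria) {
  !is.null(criteria) && nrow(criteria) > 0 &&
    any(criteria$code %in% c("FA_PS", "FA_PVS"))
}

# non-functional directional evidence (in silico, segregation, reputation,
# prior reports) used for the one-class-gap rule on discordant pairs
nonfunctional_direction <- function(criteria) {
  if (is.null(criteria) || nrow(criteria) == 0) return("none")
  path_codes <- c("PP1", "PP3", "PS1", "PM5")
  ben_codes <- c("BP4", "BS4", "BP7")
  path <- any(criteria$code %in% path_codes) ||
    any(criteria$code == "REP" & grepl("^pathogenic", criteria$strength))
  ben <- any(criteria$code %in% ben_codes) ||
    any(criteria$code == "REP" & grepl("^benign", criteria$strength))
  direction_label(path, ben)
}

decision_row <- function(cdna, round, pre, post, source, rationale) {
  data.frame(cdna = cdna, round = round, pre_class = pre,
             post_class = post, source = source, rationale = rationale,
             stringsAsFactors = FALSE)
}

#' First round of curation
#'
#' Deterministic emulation of the first expert review. Override-ledger
#' entries win outright. Concordant pairs keep their class unless the
#' recurrence-promotion rule fires (a concordant likely pathogenic call
#' observed in at least `recurrence_threshold` independent index cases and
#' backed by at least one strong/very-strong functional criterion becomes
#' pathogenic). Discordant pairs resolve to the class on the side supported
#' by functional (tumour-assay) evidence; failing that, to the non-VUS class
#' when the gap is a single class and non-functional evidence is directional;
#' anything else is passed to round 2.
#'
#' @param pairs data frame with columns `cdna`, `acmg`, `ngs` and optionally
#'   `case_count`; one row per variant.
#' @param criteria named list (by cdna) of criterion data frames from
#'   [assign_criteria()]; may be empty, in which case no evidence-based rule
#'   fires.
#' @param overrides override ledger (see [read_override_ledger()]) or `NULL`.
#' @param policy see [consensus_policy()].
#' @return list with `decisions` (data frame of round-1 decisions) and
#'   `unresolved` (data frame `cdna`, `cand_lo`, `cand_hi`).
#' @export
curate_round1 <- function(pairs, criteria = list(), overrides = NULL,
                          policy = consensus_policy()) {
  pairs <- as.data.frame(pairs)
  if (anyDuplicated(pairs$cdna)) stop("each variant must appear once")
  if (!is.null(overrides) && nrow(overrides) > 0) {
    unknown <- setdiff(overrides$cdna, pairs$cdna)
    if (length(unknown) > 0) {
      stop("override ledger references unknown variant(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  acmg <- as_tier(pairs$acmg)
  ngs <- as_tier(pairs$ngs)
  cc <- if ("case_count" %in% names(pairs)) pairs$case_count else
    rep(NA_integer_, nrow(pairs))

  decisions <- list()
  unresolved <- list()
  for (i in seq_len(nrow(pairs))) {
    cdna <- pairs$cdna[i]
    crit <- criteria[[cdna]]
    pre <- if (acmg[i] == ngs[i]) tier_label(acmg[i]) else
      paste(tier_label(acmg[i]), tier_label(ngs[i]), sep = "|")
    ov <- ledger_class_for(cdna, overrides)
    if (!is.na(ov)) {
      decisions[[length(decisions) + 1]] <- decision_row(
        cdna, 1L, pre, ov, "override", "expert override ledger")
      next
    }
    if (acmg[i] == ngs[i]) {
      cls <- acmg[i]
      if (cls == TIER_LEVELS[["LPV"]] && !is.na(cc[i]) &&
          cc[i] >= policy$recurrence_threshold && has_strong_functional(crit)) {
        decisions[[length(decisions) + 1]] <- decision_row(
          cdna, 1L, pre, TIER_LEVELS[["PV"]], "policy",
          sprintf("recurrence promotion: %d index cases with strong functional evidence",
                  cc[i]))
      } else {
        decisions[[length(decisions) + 1]] <- decision_row(
          cdna, 1L, pre, cls, "policy", "concordant classification retained")
      }
      next
    }
    lo <- min(acmg[i], ngs[i]); hi <- max(acmg[i], ngs[i])
    dir <- functional_direction(crit)
    if (dir == "pathogenic") {
      decisions[[length(decisions) + 1]] <- decision_row(
        cdna, 1L, pre, hi, "policy",
        "discordant pair resolved toward functional evidence (pathogenic direction)")
      next
    }
    if (dir == "benign") {
      decisions[[length(decisions) + 1]] <- decision_row(
        cdna, 1L, pre, lo, "policy",
        "discordant pair resolved toward functional evidence (benign direction)")
      next
    }
    vus <- TIER_LEVELS[["VUS"]]
    if (hi - lo == 1L && (lo == vus || hi == vus)) {
      non_vus <- if (lo == vus) hi else lo
      ndir <- nonfunctional_direction(crit)
      if ((non_vus > vus && ndir == "pathogenic") ||
          (non_vus < vus && ndir == "benign")) {
        decisions[[length(decisions) + 1]] <- decision_row(
          cdna, 1L, pre, non_vus, "policy",
          "one-class gap resolved to the non-VUS class on directional evidence")
        next
      }
    }
    unresolved[[length(unresolved) + 1]] <- data.frame(
      cdna = cdna, cand_lo = lo, cand_hi = hi, stringsAsFactors = FALSE)
  }
  list(
    decisions = if (length(decisions)) do.call(rbind, decisions) else
      decision_row(character(), integer(), character(), integer(),
                   character(), character()),
    unresolved = if (length(unresolved)) do.call(rbind, unresolved) else
      data.frame(cdna = character(), cand_lo = integer(),
                 cand_hi = integer(), stringsAsFactors = FALSE))
}

#' Second round of curation
#'
#' Resolves every variant left open by round 1: an override-ledger entry
#' wins; otherwise the more pathogenic candidate is adopted when any
#' pathogenic-direction functional criterion exists, and the less pathogenic
#' candidate otherwise (conservative clinical default).
#'
#' @param unresolved data frame from [curate_round1()] (`cdna`, `cand_lo`,
#'   `cand_hi`).
#' @inheritParams curate_round1
#' @return data frame of round-2 decisions covering the full unresolved set.
#' @export
curate_round2 <- function(unresolved, criteria = list(), overrides = NULL,
                          policy = consensus_policy()) {
  unresolved <- as.data.frame(unresolved)
  decisions <- list()
  for (i in seq_len(nrow(unresolved))) {
    cdna <- unresolved$cdna[i]
    lo <- unresolved$cand_lo[i]; hi <- unresolved$cand_hi[i]
    pre <- paste(tier_label(lo), tier_label(hi), sep = "|")
    ov <- ledger_class_for(cdna, overrides)
    if (!is.na(ov)) {
      decisions[[length(decisions) + 1]] <- decision_row(
        cdna, 2L, pre, ov, "override", "expert override ledger")
      next
    }
    dir <- functional_direction(criteria[[cdna]])
    if (dir == "pathogenic") {
      decisions[[length(decisions) + 1]] <- decision_row(
        cdna, 2L, pre, hi, "policy",
        "pathogenic-direction functional evidence: more pathogenic candidate adopted")
    } else if (dir == "benign") {
      decisions[[length(decisions) + 1]] <- decision_row(
        cdna, 2L, pre, lo, "policy",
        "benign-direction functional evidence: less pathogenic candidate adopted")
    } else {
      post <- if (policy$tie_break == "less_pathogenic") lo else hi
      decisions[[length(decisions) + 1]] <- decision_row(
        cdna, 2L, pre, post, "policy",
        paste0("no functional evidence: ", gsub("_", " ", policy$tie_break),
               " candidate adopted"))
    }
  }
  if (length(decisions)) do.call(rbind, decisions) else
    decision_row(character(), integer(), character(), integer(),
                 character(), character())
}

#' Run the full two-round consensus stage
#'
#' @inheritParams curate_round1
#' @return data frame with one row per variant: `cdna`, `acmg`, `ngs`,
#'   `round1_class` (`NA` when the variant went to round 2), `final_class`,
#'   `round`, `source`, `rationale`. Every input variant receives exactly one
#'   final class.
#' @export
curate <- function(pairs, criteria = list(), overrides = NULL,
                   policy = consensus_policy()) {
  pairs <- as.data.frame(pairs)
  r1 <- curate_round1(pairs, criteria, overrides, policy)
  r2 <- curate_round2(r1$unresolved, criteria, overrides, policy)
  all_dec <- rbind(r1$decisions, r2)
  stopifnot(setequal(all_dec$cdna, pairs$cdna),
            !anyDuplicated(all_dec$cdna))
  idx <- match(pairs$cdna, all_dec$cdna)
  out <- data.frame(
    cdna = pairs$cdna,
    acmg = as_tier(pairs$acmg),
    ngs = as_tier(pairs$ngs),
    round1_class = ifelse(all_dec$round[idx] == 1L,
                          all_dec$post_class[idx], NA_integer_),
    final_class = all_dec$post_class[idx],
    round = all_dec$round[idx],
    source = all_dec$source[idx],
    rationale = all_dec$rationale[idx],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
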