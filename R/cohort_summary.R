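# Cohort summary statistics: clinical presentation table, occurrence bins,
# variant-type distribution and 5-tier class distribution. Percentages
# follow the reporting convention of clinical cohort tables: denominators
# exclude cases where the field is not specified, clinical percentages are
# printed to one decimal and variant-type percentages to the nearest
# integer, rounding half away from zero.

#' Round half away from zero
#' @param x numeric.
#' @param digits decimal places.
#' @return numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

PRESENTATION_LEVELS <- c("single_hn_pgl", "single_tap_pgl", "single_pcc",
                         "single_ppgl_site_unspecified", "multiple_ppgl",
                         "rcc_only", "gist_only")

pct_of <- function(count, denom, digits = 1) {
  if (denom == 0) return(NA_real_)
  round_half_up(100 * count / denom, digits)
}

#' Clinical presentation table
#'
#' Tallies tumour presentation, metastatic status and family history for a
#' cohort of index cases, with percentages computed over the denominator of
#' cases where the field is specified (unknowns are reported as their own
#' strata but excluded from percentages). The site split of single PPGL uses
#' only single-PPGL cases with a known location.
#'
#' @param cases data frame of index cases with columns `presentation` (one of
#'   `single_hn_pgl`, `single_tap_pgl`, `single_pcc`,
#'   `single_ppgl_site_unspecified`, `multiple_ppgl`, `rcc_only`,
#'   `gist_only`, or `NA` when not specified), `metastatic` (`"yes"`,
#'   `"no"`, `NA`) and `family_history` (`"yes"`, `"no"`, `NA`).
#' @param subset optional logical vector (or vector of row indices)
#'   restricting the cohort, e.g. to carriers of (likely) pathogenic
#'   variants.
#' @return data frame with columns `field`, `stratum`, `count`, `denominator`,
#'   `pct`; attribute `n` holds the cohort size. Strata with denominator 0
#'   carry `pct = NA`.
#' @export
clinical_table <- function(cases, subset = NULL) {
  cases <- as.data.frame(cases)
  if (!is.null(subset)) cases <- cases[subset, , drop = FALSE]
  if (nrow(cases) == 0) stop("empty cohort", call. = FALSE)
  pres <- as.character(cases$presentation)
  bad <- !is.na(pres) & !pres %in% PRESENTATION_LEVELS
  if (any(bad)) stop("unknown presentation value(s): ",
                     paste(unique(pres[bad]), collapse = ", "))
  known_pres <- sum(!is.na(pres))
  is_single <- !is.na(pres) & startsWith(pres, "single")
  single_known_site <- !is.na(pres) &
    pres %in% c("single_hn_pgl", "single_tap_pgl", "single_pcc")
  n_site <- sum(single_known_site)

  rows <- list()
  add <- function(field, stratum, count, denom, digits = 1) {
    rows[[length(rows) + 1]] <<- data.frame(
      field = field, stratum = stratum, count = as.integer(count),
      denominator = as.integer(denom),
      pct = pct_of(count, denom, digits), stringsAsFactors = FALSE)
  }
  add("tumours", "single_ppgl", sum(is_single), known_pres)
  add("tumours", "single_hn_pgl", sum(pres == "single_hn_pgl", na.rm = TRUE), n_site)
  add("tumours", "single_tap_pgl", sum(pres == "single_tap_pgl", na.rm = TRUE), n_site)
  add("tumours", "single_pcc", sum(pres == "single_pcc", na.rm = TRUE), n_site)
  add("tumours", "single_site_not_specified",
      sum(pres == "single_ppgl_site_unspecified", na.rm = TRUE), 0)
  add("tumours", "multiple_ppgl", sum(pres == "multiple_ppgl", na.rm = TRUE), known_pres)
  add("tumours", "rcc_only", sum(pres == "rcc_only", na.rm = TRUE), known_pres)
  add("tumours", "gist_only", sum(pres == "gist_only", na.rm = TRUE), known_pres)
  add("tumours", "not_specified", sum(is.na(pres)), 0)

  met <- as.character(cases$metastatic)
  known_met <- sum(!is.na(met))
  add("metastatic", "yes", sum(met == "yes", na.rm = TRUE), known_met)
  add("metastatic", "no", sum(met == "no", na.rm = TRUE), known_met)
  add("metastatic", "not_specified", sum(is.na(met)), 0)

  fam <- as.character(cases$family_history)
  known_fam <- sum(!is.na(fam))
  add("family_history", "yes", sum(fam == "yes", na.rm = TRUE), known_fam)
  add("family_history", "no", sum(fam == "no", na.rm = TRUE), known_fam)
  add("family_history", "not_specified", sum(is.na(fam)), 0)

  if ("age_at_diagnosis" %in% names(cases) && any(!is.na(cases$age_at_diagnosis))) {
    age <- cases$age_at_diagnosis
    add("age", "fourth_decade",
        sum(!is.na(age) & age >= 30 & age <= 39), sum(!is.na(age)))
  }

  out <- do.call(rbind, rows)
  # self-audit: every printed percentage equals count/denominator to rounding
  ok <- is.na(out$pct) |
    abs(out$pct - 100 * out$count / pmax(out$denominator, 1)) <= 0.05 + 1e-9
  stopifnot(all(ok))
  attr(out, "n") <- nrow(cases)
  out
}

#' Bin variant occurrence counts
#'
#' Bins the number of independent index cases per distinct variant into the
#' conventional recurrence bins 1, 2-5, 6-10, 11-20 and >= 20 (a variant seen
#' exactly 20 times falls in the open top bin).
#'
#' @param dedup output of [deduplicate()], or a bare integer vector of
#'   occurrence counts.
#' @return named integer vector of bin counts summing to the number of
#'   distinct variants.
#' @export
occurrence_bins <- function(dedup) {
  counts <- if (is.data.frame(dedup)) dedup$count else as.integer(dedup)
  if (length(counts) > 0) stopifnot(all(counts >= 1))
  bins <- c("1" = sum(counts == 1),
            "2-5" = sum(counts >= 2 & counts <= 5),
            "6-10" = sum(counts >= 6 & counts <= 10),
            "11-20" = sum(counts >= 11 & counts < 20),
            ">=20" = sum(counts >= 20))
  stopifnot(sum(bins) == length(counts))
  bins
}

#' Variant-type distribution
#'
#' Counts and integer percentages per variant type, grouped into nucleotide
#' substitutions versus deletions/duplications.
#'
#' @param vtypes character vector of variant types (see [VTYPE_LEVELS]), one
#'   per distinct variant.
#' @return data frame with columns `vtype`, `group`, `count`, `pct`;
#'   attribute `groups` holds the two group totals and percentages.
#' @export
type_distribution <- function(vtypes) {
  vtypes <- as.character(vtypes)
  bad <- !vtypes %in% VTYPE_LEVELS
  if (any(bad)) stop("unknown variant type(s): ",
                     paste(unique(vtypes[bad]), collapse = ", "))
  total <- length(vtypes)
  counts <- vapply(VTYPE_LEVELS, function(v) sum(vtypes == v), integer(1))
  out <- data.frame(
    vtype = VTYPE_LEVELS,
    group = ifelse(VTYPE_LEVELS %in% VTYPE_SUBSTITUTIONS,
                   "substitution", "deletion_duplication"),
    count = counts,
    pct = if (total == 0) rep(0, length(counts)) else
      round_half_up(100 * counts / total, 0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  g <- c(substitution = sum(out$count[out$group == "substitution"]),
         deletion_duplication = sum(out$count[out$group == "deletion_duplication"]))
  attr(out, "groups") <- data.frame(
    group = names(g), count = as.integer(g),
    pct = if (total == 0) c(0, 0) else round_half_up(100 * g / total, 0),
    stringsAsFactors = FALSE)
  out
}

#' Five-tier class distribution with merged groups
#'
#' @param finals integer tiers (1-5) or labels, one final class per distinct
#'   variant.
#' @param cdna optional vector of variant keys used to reject duplicates.
#' @return list with `per_class` (named counts BV..PV) and `merged` (named
#'   counts `benign_group` = BV+LBV, `vus` = VUS, `pathogenic_group` =
#'   LPV+PV).
#' @export
class_distribution <- function(finals, cdna = NULL) {
  if (!is.null(cdna) && anyDuplicated(cdna)) {
    stop("duplicate variant(s) in final classification: ",
         paste(unique(cdna[duplicated(cdna)]), collapse = ", "))
  }
  tiers <- if (length(finals) == 0) integer() else as_tier(finals)
  per_class <- vapply(1:5, function(k) sum(tiers == k), integer(1))
  names(per_class) <- names(TIER_LEVELS)
  merged <- c(benign_group = per_class[["BV"]] + per_class[["LBV"]],
              vus = per_class[["VUS"]],
              pathogenic_group = per_class[["LPV"]] + per_class[["PV"]])
  stopifnot(sum(merged) == sum(per_class), sum(per_class) == length(tiers))
  list(per_class = per_class, merged = merged)
}
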