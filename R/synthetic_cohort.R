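# Synthetic cohort generator: index cases and per-variant evidence profiles
# with the structure of the study cohort (737 cases over 223 distinct
# variants by default) and known ground-truth classes, so every pipeline
# stage is testable without any external data. Occurrence and variant-type
# margins use quota (exact-count) sampling; clinical fields are independent
# categorical draws.

#' Synthetic cohort generator configuration
#'
#' Defaults reproduce the reference cohort's marginal structure: 737 index
#' cases collapsing to 223 distinct variants, the printed recurrence bins,
#' variant-type counts, final class counts, tumour-assay availability rates
#' and the clinical composition of the cohort table. Custom `n_distinct`
#' values rescale the count quotas proportionally (largest remainder).
#'
#' @param seed integer seed; fully determines the output.
#' @param n_cases number of index cases.
#' @param n_distinct number of distinct variants (`<= n_cases`).
#' @param occurrence_bins named counts over bins `1`, `2-5`, `6-10`, `11-20`,
#'   `>=20`.
#' @param vtype_counts named counts over [VTYPE_LEVELS].
#' @param class_counts named counts over `BV`..`PV` (ground-truth classes).
#' @param evidence_availability per-assay probabilities that the assay is
#'   reported for a variant whose truth class can carry it.
#' @param noise_rate probability that a reported assay contradicts the truth
#'   class (default 0: assays are never fabricated against truth).
#' @return named list (class `generator_config`).
#' @export
generator_config <- function(seed = 1L,
                             n_cases = 737L,
                             n_distinct = 223L,
                             occurrence_bins = NULL,
                             vtype_counts = NULL,
                             class_counts = NULL,
                             evidence_availability = NULL,
                             noise_rate = 0) {
  fx <- fixture_reference_tables()
  if (is.null(occurrence_bins)) occurrence_bins <- fx$occurrence_bins
  if (is.null(vtype_counts)) vtype_counts <- fx$vtype_counts
  if (is.null(class_counts)) class_counts <- fx$class_counts
  if (is.null(evidence_availability)) {
    evidence_availability <- fx$evidence_counts / 223
  }
  n_cases <- as.integer(n_cases); n_distinct <- as.integer(n_distinct)
  if (any(occurrence_bins < 0) || any(vtype_counts < 0) || any(class_counts < 0)) {
    stop("distribution counts must be non-negative")
  }
  if (n_distinct > n_cases) stop("n_distinct must not exceed n_cases")
  if (noise_rate < 0 || noise_rate > 1) stop("noise_rate must be in [0, 1]")
  structure(list(seed = as.integer(seed), n_cases = n_cases,
                 n_distinct = n_distinct, occurrence_bins = occurrence_bins,
                 vtype_counts = vtype_counts, class_counts = class_counts,
                 evidence_availability = evidence_availability,
                 noise_rate = noise_rate),
            class = "generator_config")
}

# length-safe shuffle (sample(x) on a length-1 integer means sample.int)
shuffle <- function(x) if (length(x) <= 1L) x else sample(x)

# proportional rescale to a new total, largest-remainder method
scale_quota <- function(counts, n) {
  if (sum(counts) == 0) stop("quota weights sum to zero")
  raw <- counts * n / sum(counts)
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(counts))
}

BIN_MIN <- c("1" = 1L, "2-5" = 2L, "6-10" = 6L, "11-20" = 11L, ">=20" = 20L)
BIN_MAX <- c("1" = 1L, "2-5" = 5L, "6-10" = 10L, "11-20" = 19L,
             ">=20" = .Machine$integer.max)

# exact-total occurrence counts honouring the bin quotas
draw_occurrence_counts <- function(bins, n_distinct, n_cases) {
  if (n_cases == n_distinct) return(rep(1L, n_distinct))
  bins <- scale_quota(bins, n_distinct)
  counts <- rep(BIN_MIN[rep(names(bins), bins)], 1)
  caps <- BIN_MAX[rep(names(bins), bins)]
  extra <- n_cases - sum(counts)
  if (extra < 0) {
    stop("infeasible quotas: bin minima exceed n_cases", call. = FALSE)
  }
  while (extra > 0) {
    open <- which(counts < caps)
    if (length(open) == 0) {
      stop("infeasible quotas: bin maxima below n_cases", call. = FALSE)
    }
    i <- open[sample.int(length(open), 1)]
    counts[i] <- counts[i] + 1L
    extra <- extra - 1L
  }
  unname(shuffle(counts))
}

AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
         "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
         "Tyr", "Val")
BASES <- c("A", "C", "G", "T")
# illustrative exon-boundary anchor positions on the coding sequence used to
# build intronic descriptions (donor sites after these cDNA positions)
DONOR_ANCHORS <- c(72L, 166L, 287L, 423L, 540L, 642L, 765L)
CDS_LEN <- 846L  # 281 codons plus stop

draw_base_pair <- function() sample(BASES, 2)

# one plausible HGVS description of the requested type
random_hgvs <- function(vtype) {
  sub_at <- function(pos) {
    b <- draw_base_pair()
    paste0("c.", pos, b[1], ">", b[2])
  }
  switch(vtype,
    missense = {
      codon <- sample(2:280, 1)
      pos <- 3L * (codon - 1L) + sample(1:3, 1)
      aa <- sample(AA3, 2)
      list(cdna = sub_at(pos), protein = paste0("p.", aa[1], codon, aa[2]))
    },
    nonsense = {
      codon <- sample(2:280, 1)
      pos <- 3L * (codon - 1L) + sample(1:3, 1)
      list(cdna = sub_at(pos),
           protein = paste0("p.", sample(AA3, 1), codon, "Ter"))
    },
    synonymous = {
      codon <- sample(2:280, 1)
      pos <- 3L * (codon - 1L) + 3L
      list(cdna = sub_at(pos), protein = paste0("p.", sample(AA3, 1), codon, "="))
    },
    splice_site_substitution = {
      e <- sample(DONOR_ANCHORS, 1)
      form <- sample(c("donor", "acceptor"), 1)
      pos <- if (form == "donor") paste0(e, "+", sample(1:2, 1)) else
        paste0(e + 1L, "-", sample(1:2, 1))
      b <- draw_base_pair()
      list(cdna = paste0("c.", pos, b[1], ">", b[2]), protein = NA_character_)
    },
    mid_intronic = {
      e <- sample(DONOR_ANCHORS, 1)
      b <- draw_base_pair()
      list(cdna = paste0("c.", e, "+", sample(10:80, 1), b[1], ">", b[2]),
           protein = NA_character_)
    },
    utr5 = {
      b <- draw_base_pair()
      list(cdna = paste0("c.-", sample(1:60, 1), b[1], ">", b[2]),
           protein = NA_character_)
    },
    initiation_codon = {
      pos <- sample(1:3, 1)
      ref <- c("A", "T", "G")[pos]
      alt <- sample(setdiff(BASES, ref), 1)
      list(cdna = paste0("c.", pos, ref, ">", alt),
           protein = "p.Met1?")
    },
    frameshift_indel = {
      s <- sample(4:800, 1)
      len <- sample(c(1L, 2L, 4L, 5L), 1)
      cdna <- if (len == 1L) {
        paste0("c.", s, sample(c("del", "dup"), 1))
      } else paste0("c.", s, "_", s + len - 1L, "del")
      list(cdna = cdna, protein = NA_character_)
    },
    inframe_indel = {
      s <- sample(4:800, 1)
      len <- sample(c(3L, 6L, 9L), 1)
      list(cdna = paste0("c.", s, "_", s + len - 1L, "del"),
           protein = NA_character_)
    },
    large_rearrangement = {
      k <- sort(sample(seq_along(DONOR_ANCHORS), 2))
      a <- if (k[1] == 1) 1L else DONOR_ANCHORS[k[1] - 1] + 1L
      b <- DONOR_ANCHORS[k[2]]
      start <- if (a == 1L) paste0(a, "-?") else paste0(a, "-?")
      list(cdna = paste0("c.", start, "_", b, "+?del"),
           protein = NA_character_)
    },
    noncoding_indel = {
      e <- sample(DONOR_ANCHORS, 1)
      o <- sample(15:60, 1)
      list(cdna = paste0("c.", e, "+", o, "_", e, "+", o + sample(1:5, 1), "del"),
           protein = NA_character_)
    },
    splice_site_indel = {
      e <- sample(DONOR_ANCHORS, 1)
      list(cdna = paste0("c.", e, "+1_", e, "+", sample(2:5, 1), "del"),
           protein = NA_character_)
    },
    stop("unknown vtype: ", vtype))
}

# couple ground-truth classes to variant types: truncating variants carry
# (likely) pathogenic truth, benign/VUS truth goes to non-truncating types
assign_truth <- function(vtypes, class_counts) {
  n <- length(vtypes)
  pool <- scale_quota(class_counts, n)
  truth <- integer(n)
  take <- function(label) {
    if (pool[[label]] > 0L) {
      pool[[label]] <<- pool[[label]] - 1L
      TIER_LEVELS[[label]]
    } else NA_integer_
  }
  trunc_hard <- vtypes %in% setdiff(NULL_VTYPES, "initiation_codon") &
    !(vtypes == "large_rearrangement")  # keep order stable below
  trunc_hard <- vtypes %in% setdiff(NULL_VTYPES, "initiation_codon")
  # pathogenic truth to truncating variants first
  for (i in shuffle(which(trunc_hard))) {
    truth[i] <- take("PV")
    if (is.na(truth[i])) truth[i] <- take("LPV")
    if (is.na(truth[i])) truth[i] <- take("VUS")
    if (is.na(truth[i])) truth[i] <- TIER_LEVELS[["VUS"]]
  }
  for (i in which(vtypes == "initiation_codon")) {
    truth[i] <- take("LPV")
    if (is.na(truth[i])) truth[i] <- take("PV")
    if (is.na(truth[i])) truth[i] <- TIER_LEVELS[["VUS"]]
  }
  # remaining likely pathogenic truth to missense variants
  miss <- shuffle(which(vtypes == "missense" & truth == 0L))
  for (i in miss) {
    if (pool[["LPV"]] > 0L) truth[i] <- take("LPV")
  }
  # benign truth preferentially to non-missense non-truncating types
  rest <- which(truth == 0L)
  non_miss <- shuffle(rest[vtypes[rest] != "missense"])
  for (i in non_miss) {
    if (pool[["BV"]] > 0L) {
      truth[i] <- take("BV")
    } else if (pool[["LBV"]] > 0L) {
      truth[i] <- take("LBV")
    }
  }
  # everything left: fill from the remaining pool (VUS first)
  for (i in shuffle(which(truth == 0L))) {
    for (label in c("VUS", "LBV", "BV", "LPV", "PV")) {
      truth[i] <- take(label)
      if (!is.na(truth[i])) break
    }
    if (is.na(truth[i])) truth[i] <- TIER_LEVELS[["VUS"]]
  }
  truth
}

# evidence fields consistent with the drawn truth class; returns a one-row
# list of evidence-table columns
draw_evidence <- function(vtype, cdna, truth, case_count, avail, noise_rate,
                          cfg = acmg_config()) {
  e <- list(
    max_af = NA_real_, af_source = "gnomAD",
    coseg_meioses = NA_integer_, coseg_segregates = NA,
    cons_ratio = NA_real_, phylop = NA_real_, grantham = NA_real_,
    polyphen2 = NA_character_, sift = NA_character_,
    align_gvgd = NA_character_, mutation_taster = NA_character_,
    mes_ref = NA_real_, mes_alt = NA_real_,
    nns_ref = NA_real_, nns_alt = NA_real_,
    cdna_splicing = "not_done", loh = "not_done",
    shdb_ihc = "not_done", sdha_ihc = "not_done",
    sdh_activity = "not_done", cluster = "not_done", western = "not_done",
    other_sdhx_excluded = FALSE,
    prior_pathogenic = 0L, prior_benign = 0L,
    prior_same_aa_pathogenic = FALSE, prior_same_codon_pathogenic = FALSE)
  truncating <- vtype %in% NULL_VTYPES
  splice_candidate <- vtype %in% c("synonymous", "mid_intronic",
                                   "noncoding_indel")
  set_insilico_path <- function(e) {
    e$cons_ratio <- 1.0
    e$polyphen2 <- "probably_damaging"
    e$sift <- "deleterious"
    e$grantham <- sample(150:215, 1)
    e
  }
  set_insilico_benign <- function(e) {
    if (vtype == "missense") {
      e$cons_ratio <- round(sample(1:7, 1) / 14, 6)
      e$polyphen2 <- "benign"
      e$sift <- "tolerated"
    } else {
      e$mes_ref <- round(stats::runif(1, 6, 10), 2)
      e$mes_alt <- e$mes_ref
      e$nns_ref <- round(stats::runif(1, 0.6, 0.95), 2)
      e$nns_alt <- e$nns_ref
    }
    e
  }
  label <- tier_label(truth)
  if (label == "BV") {
    e$max_af <- stats::runif(1, cfg$af_ba1 * 1.2, 0.05)
  } else if (label == "LBV") {
    e$max_af <- stats::runif(1, cfg$af_bs1, cfg$af_ba1 * 0.9)
    if (vtype == "missense" || splice_candidate) {
      e <- set_insilico_benign(e)
    } else {
      e$shdb_ihc <- "positive"  # assay not in favour of loss of function
    }
  } else if (label == "VUS") {
    # limited data: ultra-rare, no informative predictions or assays
  } else if (label == "LPV") {
    if (!truncating) {
      e <- set_insilico_path(e)
      e$prior_same_codon_pathogenic <- TRUE
      e$coseg_meioses <- sample(3:6, 1)
      e$coseg_segregates <- TRUE
      if (stats::runif(1) < avail[["cluster"]]) e$cluster <- "cluster_1A"
    }
  } else if (label == "PV") {
    e$prior_pathogenic <- sample(5:30, 1)
    if (!truncating) {
      e <- set_insilico_path(e)
      e$prior_same_aa_pathogenic <- TRUE
    }
    if (stats::runif(1) < avail[["ihc"]]) {
      e$shdb_ihc <- "negative"
      e$sdha_ihc <- "positive"
      e$other_sdhx_excluded <- TRUE
    }
    if (stats::runif(1) < avail[["loh"]]) {
      e$loh <- "variant_allele_retained_wt_lost"
    }
    if (stats::runif(1) < avail[["activity"]]) {
      e$sdh_activity <- "lost"
      e$other_sdhx_excluded <- TRUE
    }
  }
  if (noise_rate > 0 && stats::runif(1) < noise_rate) {
    # a contradicting assay result (measurement noise)
    if (truth >= 4L) {
      e$shdb_ihc <- "positive"
    } else {
      e$loh <- "variant_allele_retained_wt_lost"
    }
  }
  e
}

CLINICAL_PRES_PROBS <- c(single_hn_pgl = 213, single_tap_pgl = 184,
                         single_pcc = 78, single_ppgl_site_unspecified = 143,
                         multiple_ppgl = 103, rcc_only = 8, gist_only = 2,
                         not_specified = 6) / 737
CLINICAL_MET_PROBS <- c(yes = 133, no = 238, not_specified = 366) / 737
CLINICAL_FAM_PROBS <- c(yes = 159, no = 374, not_specified = 204) / 737

draw_clinical <- function(n) {
  pres <- sample(names(CLINICAL_PRES_PROBS), n, replace = TRUE,
                 prob = CLINICAL_PRES_PROBS)
  met <- sample(names(CLINICAL_MET_PROBS), n, replace = TRUE,
                prob = CLINICAL_MET_PROBS)
  fam <- sample(names(CLINICAL_FAM_PROBS), n, replace = TRUE,
                prob = CLINICAL_FAM_PROBS)
  age <- pmin(pmax(round(stats::rnorm(n, 36, 13)), 6), 83)
  data.frame(
    presentation = ifelse(pres == "not_specified", NA_character_, pres),
    metastatic = ifelse(met == "not_specified", NA_character_, met),
    family_history = ifelse(fam == "not_specified", NA_character_, fam),
    age_at_diagnosis = age,
    n_tumours = ifelse(is.na(pres) | pres == "not_specified", NA_integer_,
                       ifelse(pres == "multiple_ppgl", sample(2:7, n, TRUE), 1L)),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws `n_distinct` distinct variants (types by exact quota), couples each
#' to a ground-truth 5-tier class (truncating types carry pathogenic truth),
#' draws occurrence counts by exact bin quota summing to `n_cases`, and
#' populates each variant's evidence profile consistently with its truth
#' class: pathogenic truth gets ultra-rare frequency plus deleterious
#' predictions, published evidence and (at the configured availability
#' rates) confirmatory tumour assays; benign truth gets elevated population
#' frequency and benign-direction evidence; VUS truth gets deliberately
#' limited data. At the default zero noise rate no assay ever contradicts
#' truth.
#'
#' @param config a [generator_config()].
#' @return list with `cases` (one row per index case: `case_id`, `cdna`,
#'   `protein`, `vtype`, clinical columns), `profiles` (one row per distinct
#'   variant in the evidence-table dialect), and `truth` (named integer
#'   vector of ground-truth tiers keyed by cdna).
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_distinct

  vtypes <- sample(rep(names(config$vtype_counts),
                       scale_quota(config$vtype_counts, n)))
  truth <- assign_truth(vtypes, config$class_counts)
  counts <- draw_occurrence_counts(config$occurrence_bins, n, config$n_cases)
  # recurrent variants are predominantly (likely) pathogenic founder alleles
  ord <- order(-counts)
  slot <- c(shuffle(which(truth >= 4L)), shuffle(which(truth < 4L)))
  counts_assigned <- integer(n)
  counts_assigned[slot] <- counts[ord]
  counts <- counts_assigned

  seen <- character(0)
  hgvs <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      h <- random_hgvs(vtypes[i])
      key <- parse_variant(h$cdna, h$protein)$cdna
      if (!key %in% seen) {
        seen <- c(seen, key)
        h$cdna <- key
        hgvs[[i]] <- h
        break
      }
    }
  }
  cdna <- vapply(hgvs, `[[`, character(1), "cdna")
  protein <- vapply(hgvs, `[[`, character(1), "protein")

  ev <- lapply(seq_len(n), function(i) {
    draw_evidence(vtypes[i], cdna[i], truth[i], counts[i],
                  config$evidence_availability, config$noise_rate)
  })
  profiles <- cbind(
    data.frame(cdna = cdna, protein = protein, vtype = vtypes,
               case_count = counts, stringsAsFactors = FALSE),
    do.call(rbind, lapply(ev, function(x) {
      as.data.frame(x, stringsAsFactors = FALSE)
    })))

  case_rows <- rep(seq_len(n), counts)
  clin <- draw_clinical(length(case_rows))
  cases <- cbind(
    data.frame(case_id = sprintf("case_%04d", seq_along(case_rows)),
               cdna = cdna[case_rows], protein = protein[case_rows],
               vtype = vtypes[case_rows], stringsAsFactors = FALSE),
    clin)

  list(cases = cases, profiles = profiles,
       truth = stats::setNames(truth, cdna))
}
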