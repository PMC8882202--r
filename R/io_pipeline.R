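# Readers, writers and the end-to-end pipeline binding parsing, in silico
# verdicts, both classifiers and the consensus stage. The canonical dialect
# is TSV (UTF-8, LF): HGVS strings never contain tabs but may contain commas
# or semicolons.

#' Hash a resolved run configuration
#'
#' A content hash of the configuration (thresholds, tree, policy) embedded in
#' every report so outputs are traceable to the exact settings that produced
#' them.
#'
#' @param ... configuration objects (lists).
#' @return character MD5 hex digest.
#' @export
config_hash <- function(...) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  # hash the deparsed content rather than a binary serialization so the
  # digest is stable across R versions
  writeLines(deparse(list(...)), tmp)
  unname(tools::md5sum(tmp))
}

#' Read a per-variant evidence table
#'
#' Tab-separated, UTF-8, one header row; required column `cdna`. All other
#' columns of the evidence-table dialect are optional. A `vtype` column
#' overrides type inference (with a warning when it differs).
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_evidence_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!"cdna" %in% names(df)) {
    stop("evidence table is missing required column: cdna", call. = FALSE)
  }
  df
}

col_or_na <- function(row, name, default = NA) {
  if (name %in% names(row)) row[[name]] else default
}

#' Build an evidence profile from one evidence-table row
#'
#' Parses the variant, computes the missense and splice in silico verdicts
#' from the predictor columns (`cons_ratio`, `phylop`, `grantham`,
#' `polyphen2`, `sift`, `align_gvgd`, `mutation_taster`, `mes_ref`,
#' `mes_alt`, `nns_ref`, `nns_alt`) and assembles the assay and prior-report
#' fields.
#'
#' @param row one-row data frame (or named list) in the evidence-table
#'   dialect.
#' @param insilico_cfg thresholds, see [insilico_config()].
#' @return an [evidence_profile()].
#' @export
profile_from_row <- function(row, insilico_cfg = insilico_config()) {
  v <- parse_variant(row[["cdna"]],
                     protein = col_or_na(row, "protein", NULL),
                     vtype = col_or_na(row, "vtype", NULL))
  miss_pred <- list(
    conservation_ratio = col_or_na(row, "cons_ratio"),
    phylop = col_or_na(row, "phylop"),
    grantham = col_or_na(row, "grantham"),
    polyphen2 = col_or_na(row, "polyphen2"),
    sift = col_or_na(row, "sift"),
    align_gvgd = col_or_na(row, "align_gvgd"),
    mutation_taster = col_or_na(row, "mutation_taster"))
  any_miss <- any(!vapply(miss_pred, function(x) is.null(x) || is.na(x), logical(1)))
  splice_pred <- list(
    maxentscan_ref = col_or_na(row, "mes_ref"),
    maxentscan_alt = col_or_na(row, "mes_alt"),
    nnsplice_ref = col_or_na(row, "nns_ref"),
    nnsplice_alt = col_or_na(row, "nns_alt"))
  any_splice <- any(!vapply(splice_pred, function(x) is.null(x) || is.na(x), logical(1)))
  assay <- function(name) {
    x <- col_or_na(row, name, "not_done")
    if (is.na(x)) "not_done" else x
  }
  evidence_profile(
    v,
    max_population_af = as.numeric(col_or_na(row, "max_af")),
    af_source = {
      s <- col_or_na(row, "af_source", "gnomAD")
      if (is.na(s)) "gnomAD" else s
    },
    case_count = {
      cc <- col_or_na(row, "case_count", 1L)
      if (is.na(cc)) 1L else as.integer(cc)
    },
    coseg_meioses = as.integer(col_or_na(row, "coseg_meioses")),
    coseg_segregates = as.logical(col_or_na(row, "coseg_segregates")),
    insilico_missense = if (v$vtype == "missense" && any_miss) {
      missense_verdict(miss_pred, insilico_cfg)
    } else NA_character_,
    insilico_splice = if (any_splice) {
      splice_verdict(splice_pred, insilico_cfg)
    } else NA_character_,
    cdna_splicing = assay("cdna_splicing"),
    loh = assay("loh"),
    shdb_ihc = assay("shdb_ihc"),
    sdha_ihc = assay("sdha_ihc"),
    sdh_activity = assay("sdh_activity"),
    transcriptomic_cluster = assay("cluster"),
    western = assay("western"),
    other_sdhx_excluded = isTRUE(as.logical(col_or_na(row, "other_sdhx_excluded",
                                                      FALSE))),
    prior_pathogenic = {
      x <- col_or_na(row, "prior_pathogenic", 0L)
      if (is.na(x)) 0L else as.integer(x)
    },
    prior_benign = {
      x <- col_or_na(row, "prior_benign", 0L)
      if (is.na(x)) 0L else as.integer(x)
    },
    prior_same_aa_pathogenic = isTRUE(as.logical(
      col_or_na(row, "prior_same_aa_pathogenic", FALSE))),
    prior_same_codon_pathogenic = isTRUE(as.logical(
      col_or_na(row, "prior_same_codon_pathogenic", FALSE))))
}

#' Classify an evidence table end to end
#'
#' Runs the full pipeline on a per-variant evidence table: parse and
#' normalize each variant, compute in silico verdicts, classify under both
#' frameworks, and resolve each variant through the two-round consensus
#' stage. Rows that fail to parse are collected into an error report rather
#' than aborting the run.
#'
#' @param evidence data frame (see [read_evidence_table()]) with one row per
#'   distinct variant.
#' @param acmg_cfg see [acmg_config()].
#' @param insilico_cfg see [insilico_config()].
#' @param tree see [ngsnppgl_default_tree()].
#' @param overrides optional override ledger (see [read_override_ledger()]).
#' @param policy see [consensus_policy()].
#' @return list with `report` (data frame: `cdna`, `acmg_class`,
#'   `criteria_met`, `ngsnppgl_class`, `trace`, `round1_class`,
#'   `final_class`, `source`, `rationale`, `config_hash`) and `errors` (data
#'   frame `row`, `cdna`, `message`).
#' @export
classify_table <- function(evidence,
                           acmg_cfg = acmg_config(),
                           insilico_cfg = insilico_config(),
                           tree = ngsnppgl_default_tree(),
                           overrides = NULL,
                           policy = consensus_policy()) {
  evidence <- as.data.frame(evidence)
  hash <- config_hash(acmg_cfg, insilico_cfg, tree, policy)
  profiles <- list()
  errors <- list()
  for (i in seq_len(nrow(evidence))) {
    row <- evidence[i, , drop = FALSE]
    p <- tryCatch(profile_from_row(row, insilico_cfg), error = function(e) e)
    if (inherits(p, "error")) {
      errors[[length(errors) + 1]] <- data.frame(
        row = i, cdna = as.character(row[["cdna"]]),
        message = conditionMessage(p), stringsAsFactors = FALSE)
    } else {
      profiles[[length(profiles) + 1]] <- p
    }
  }
  err_df <- if (length(errors)) do.call(rbind, errors) else
    data.frame(row = integer(), cdna = character(), message = character(),
               stringsAsFactors = FALSE)
  if (length(profiles) == 0) {
    return(list(report = data.frame(), errors = err_df))
  }
  cdna <- vapply(profiles, function(p) p$variant$cdna, character(1))
  if (anyDuplicated(cdna)) {
    stop("evidence table contains duplicate variants: ",
         paste(unique(cdna[duplicated(cdna)]), collapse = ", "))
  }
  both <- lapply(profiles, classify_both, acmg_cfg = acmg_cfg, tree = tree)
  criteria <- stats::setNames(lapply(both, `[[`, "criteria"), cdna)
  pairs <- data.frame(
    cdna = cdna,
    acmg = vapply(both, `[[`, integer(1), "acmg"),
    ngs = vapply(both, `[[`, integer(1), "ngs"),
    case_count = vapply(profiles, `[[`, integer(1), "case_count"),
    stringsAsFactors = FALSE)
  final <- curate(pairs, criteria, overrides, policy)
  report <- data.frame(
    cdna = cdna,
    vtype = vapply(profiles, function(p) p$variant$vtype, character(1)),
    acmg_class = pairs$acmg,
    criteria_met = vapply(criteria, function(cr) {
      if (nrow(cr) == 0) "" else
        paste(paste0(cr$code, "(", cr$strength, ")"), collapse = ";")
    }, character(1)),
    ngsnppgl_class = pairs$ngs,
    trace = vapply(both, function(b) {
      paste(paste0(b$trace$node, "=", b$trace$value, ":", b$trace$branch),
            collapse = ";")
    }, character(1)),
    round1_class = final$round1_class,
    final_class = final$final_class,
    source = final$source,
    rationale = final$rationale,
    config_hash = hash,
    stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(report = report, errors = err_df)
}

#' Write a report (or any table) as canonical TSV
#'
#' UTF-8, LF line endings, tab-separated, no quoting; deterministic for a
#' given input.
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df) > 0) do.call(paste, c(lapply(df, as.character),
                                                sep = "\t")))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read SDHB variants from a minimal VCF
#'
#' Accepts a VCF 4.2 restricted to the SDHB locus whose records carry an
#' HGVS coding annotation in the INFO field `HGVSC`. Records without the
#' annotation are rejected into a per-row error report rather than aborting.
#'
#' @param path VCF file (plain text or bgzipped).
#' @return list with `variants` (data frame `cdna`, `protein`, `vtype`) and
#'   `errors` (data frame `record`, `message`).
#' @export
read_vcf_variants <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("the VariantAnnotation package is required to read VCF", call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(path)
  info <- VariantAnnotation::info(vcf)
  n <- nrow(info)
  hgvs <- if ("HGVSC" %in% names(info)) as.character(info$HGVSC) else
    rep(NA_character_, n)
  prot <- if ("HGVSP" %in% names(info)) as.character(info$HGVSP) else
    rep(NA_character_, n)
  variants <- list()
  errors <- list()
  for (i in seq_len(n)) {
    if (is.na(hgvs[i]) || !nzchar(hgvs[i])) {
      errors[[length(errors) + 1]] <- data.frame(
        record = i, message = "missing HGVSC annotation in INFO",
        stringsAsFactors = FALSE)
      next
    }
    v <- tryCatch(parse_variant(hgvs[i], protein = prot[i]),
                  error = function(e) e)
    if (inherits(v, "error")) {
      errors[[length(errors) + 1]] <- data.frame(
        record = i, message = conditionMessage(v), stringsAsFactors = FALSE)
    } else {
      variants[[length(variants) + 1]] <- data.frame(
        cdna = v$cdna, protein = v$protein, vtype = v$vtype,
        stringsAsFactors = FALSE)
    }
  }
  list(
    variants = if (length(variants)) do.call(rbind, variants) else
      data.frame(cdna = character(), protein = character(),
                 vtype = character(), stringsAsFactors = FALSE),
    errors = if (length(errors)) do.call(rbind, errors) else
      data.frame(record = integer(), message = character(),
                 stringsAsFactors = FALSE))
}

LOVD_REMARK <- "variant classified by experts from the NGSnPPGL study group (ENS@T/PRESSOR)"

#' Export a finalized consensus report in LOVD submission layout
#'
#' Produces a generic LOVD shared-instance submission table (gene symbol,
#' transcript, cDNA and protein change, classification label, remarks). The
#' export is refused when any variant lacks a final class.
#'
#' @param report report data frame from [classify_table()] (needs columns
#'   `cdna`, `final_class`; `protein` is used when present).
#' @return data frame ready for [write_tsv()].
#' @export
export_lovd <- function(report) {
  report <- as.data.frame(report)
  if (nrow(report) > 0 &&
      (!"final_class" %in% names(report) || anyNA(report$final_class))) {
    stop("export refused: unresolved variants present", call. = FALSE)
  }
  hash <- if ("config_hash" %in% names(report) && nrow(report) > 0) {
    report$config_hash[1]
  } else ""
  data.frame(
    gene = rep("SDHB", nrow(report)),
    transcript = rep("NM_003000.2", nrow(report)),
    cdna = report$cdna,
    protein = if ("protein" %in% names(report)) report$protein else
      rep(NA_character_, nrow(report)),
    classification = if (nrow(report) > 0) tier_label(report$final_class) else
      character(0),
    remarks = rep(paste0(LOVD_REMARK, " [config ", hash, "]"), nrow(report)),
    stringsAsFactors = FALSE)
}
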