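# In silico evidence: ortholog conservation and aggregation of pre-computed
# predictor outputs into categorical verdicts consumed by both classifiers.
# External predictors (PolyPhen2, SIFT, Align-GVGD, MutationTaster,
# MaxEntScan, NNSplice) are never executed here; their outputs arrive as
# table columns.

N_ORTHOLOGS <- 14L

#' Default thresholds for in silico verdict aggregation
#'
#' Every cutoff used to turn predictor outputs into categorical verdicts
#' lives here and can be replaced wholesale. Defaults follow each tool's
#' conventional published cutoffs (e.g. SIFT calls below 0.05 arrive already
#' encoded as the categorical verdict "deleterious"); they are package
#' defaults, not values fixed by any particular study.
#'
#' @param min_tools minimum number of reporting predictors for a
#'   non-`insufficient` missense verdict.
#' @param min_agree minimum number of predictors on the pathogenic (resp.
#'   benign) side, with none on the other side, for a directional verdict.
#' @param cons_path,cons_benign conservation-ratio cutoffs (fraction of 14
#'   orthologs sharing the human residue).
#' @param phylop_path,phylop_benign PhyloP nucleotide-conservation cutoffs.
#' @param grantham_path,grantham_benign Grantham distance cutoffs (0-215).
#' @param gvgd_path,gvgd_benign Align-GVGD classes counted as
#'   pathogenic-supporting / benign-supporting.
#' @param mes_path_drop relative MaxEntScan score drop (ref-alt)/ref at or
#'   above which a splice-site loss is supported.
#' @param mes_benign_drop relative drop below which a tool is counted as
#'   showing no change.
#' @param nns_detect NNSplice detection cutoff: a site scored at or above it
#'   in the reference but below it in the alternate is a predicted site loss.
#' @return named list of thresholds.
#' @export
insilico_config <- function(min_tools = 2L,
                            min_agree = 2L,
                            cons_path = 0.9, cons_benign = 0.5,
                            phylop_path = 2.0, phylop_benign = 0.0,
                            grantham_path = 150, grantham_benign = 50,
                            gvgd_path = c("C55", "C65"), gvgd_benign = "C0",
                            mes_path_drop = 0.15, mes_benign_drop = 0.05,
                            nns_detect = 0.4) {
  as.list(environment())
}

#' Amino-acid conservation ratio across 14 orthologs
#'
#' The fraction of 14 ortholog residues at the variant position that are
#' identical to the human residue, expressed as a ratio in `[0, 1]` (x
#' orthologs sharing the same amino acid / 14). Alignment gaps count as
#' non-matching: absence of the residue is not conservation.
#'
#' @param residues character vector of exactly 14 single-letter amino acids
#'   (or `-` for a gap), one per ortholog.
#' @param human_residue single-letter human amino acid at the position.
#' @return numeric scalar, always a multiple of 1/14.
#' @examples
#' conservation_ratio(rep("R", 14), "R")  # 1
#' conservation_ratio(c(rep("R", 7), rep("K", 7)), "R")  # 0.5
#' @export
conservation_ratio <- function(residues, human_residue) {
  residues <- toupper(as.character(residues))
  if (length(residues) != N_ORTHOLOGS) {
    stop(sprintf("ortholog column must have exactly %d residues (got %d)",
                 N_ORTHOLOGS, length(residues)), call. = FALSE)
  }
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWY*X-]$", residues)
  if (!all(ok)) {
    stop("invalid residue letter(s): ",
         paste(unique(residues[!ok]), collapse = ", "), call. = FALSE)
  }
  human_residue <- toupper(human_residue)
  stopifnot(length(human_residue) == 1, grepl("^[ACDEFGHIKLMNPQRSTVWY]$", human_residue))
  sum(residues == human_residue) / N_ORTHOLOGS
}

#' Conservation ratios from an aligned ortholog FASTA
#'
#' Reads an aligned FASTA of the human SDHB protein (first sequence) plus 14
#' orthologs and computes the conservation ratio at one or more alignment
#' columns.
#'
#' @param path aligned FASTA file; the human sequence must come first and be
#'   followed by exactly 14 ortholog sequences of equal alignment width.
#' @param positions integer vector of alignment column positions.
#' @return numeric vector of conservation ratios, one per position.
#' @export
alignment_conservation <- function(path, positions) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("the Biostrings package is required to read alignments", call. = FALSE)
  }
  aln <- Biostrings::readAAStringSet(path)
  if (length(aln) != N_ORTHOLOGS + 1L) {
    stop(sprintf("alignment must contain the human sequence plus %d orthologs",
                 N_ORTHOLOGS), call. = FALSE)
  }
  widths <- Biostrings::width(aln)
  if (length(unique(widths)) != 1) stop("sequences are not aligned (unequal widths)")
  mat <- as.matrix(aln)
  vapply(positions, function(p) {
    if (p < 1 || p > ncol(mat)) stop("alignment position out of range: ", p)
    conservation_ratio(mat[-1, p], mat[1, p])
  }, numeric(1))
}

# per-tool direction calls: +1 pathogenic-supporting, -1 benign-supporting,
# 0 reporting but neutral, NA not reporting
missense_tool_calls <- function(p, cfg) {
  num_call <- function(x, hi, lo) {
    if (is.null(x) || is.na(x)) return(NA_real_)
    if (x >= hi) 1 else if (x <= lo) -1 else 0
  }
  cat_call <- function(x, path_levels, benign_levels) {
    if (is.null(x) || is.na(x)) return(NA_real_)
    if (x %in% path_levels) 1 else if (x %in% benign_levels) -1 else 0
  }
  c(
    conservation = num_call(p$conservation_ratio, cfg$cons_path, cfg$cons_benign),
    phylop = num_call(p$phylop, cfg$phylop_path, cfg$phylop_benign),
    grantham = num_call(p$grantham, cfg$grantham_path, cfg$grantham_benign),
    polyphen2 = cat_call(p$polyphen2, "probably_damaging", "benign"),
    sift = cat_call(p$sift, "deleterious", "tolerated"),
    align_gvgd = cat_call(p$align_gvgd, cfg$gvgd_path, cfg$gvgd_benign),
    mutation_taster = cat_call(p$mutation_taster, "disease_causing", "polymorphism")
  )
}

#' Aggregate missense predictor outputs into a verdict
#'
#' Combines the conservation ratio and up to six pre-computed predictor
#' outputs into one of four categorical verdicts. A verdict is
#' `insufficient` when fewer than `min_tools` predictors report;
#' `conflicting` when at least one reporting tool is at/above its
#' pathogenic-supporting cutoff while another is at/below its
#' benign-supporting cutoff; `supports_pathogenic` (resp. `supports_benign`)
#' when at least `min_agree` tools are on that side and none on the other;
#' otherwise `insufficient`.
#'
#' @param p named list with any of `conservation_ratio`, `phylop`,
#'   `grantham`, `polyphen2` (`benign`/`possibly_damaging`/
#'   `probably_damaging`), `sift` (`tolerated`/`deleterious`), `align_gvgd`
#'   (`C0`..`C65`), `mutation_taster` (`polymorphism`/`disease_causing`).
#' @param config thresholds, see [insilico_config()].
#' @return one of `"supports_pathogenic"`, `"supports_benign"`,
#'   `"conflicting"`, `"insufficient"`.
#' @export
missense_verdict <- function(p, config = insilico_config()) {
  if (!is.null(p$grantham) && !is.na(p$grantham) &&
      (p$grantham < 0 || p$grantham > 215)) {
    stop("grantham distance must be in [0, 215]", call. = FALSE)
  }
  calls <- missense_tool_calls(p, config)
  reporting <- calls[!is.na(calls)]
  if (length(reporting) < config$min_tools) return("insufficient")
  n_path <- sum(reporting > 0)
  n_ben <- sum(reporting < 0)
  if (n_path >= 1 && n_ben >= 1) return("conflicting")
  if (n_path >= config$min_agree && n_ben == 0) return("supports_pathogenic")
  if (n_ben >= config$min_agree && n_path == 0) return("supports_benign")
  "insufficient"
}

#' Aggregate splice-site predictor scores into a verdict
#'
#' For splice candidates (splice-site, synonymous and intronic variants)
#' MaxEntScan and NNSplice reference/alternate scores are compared. The
#' verdict is `supports_pathogenic` when at least one tool predicts a site
#' loss -- a MaxEntScan relative score drop `(ref - alt) / ref` at or above
#' `mes_path_drop`, or an NNSplice site detected in the reference
#' (`ref >= nns_detect`) but lost in the alternate (`alt < nns_detect`) --
#' and no reporting tool shows essentially no change; `supports_benign` when
#' all reporting tools show a relative drop below `mes_benign_drop`;
#' otherwise `insufficient`.
#'
#' @param p named list with any of `maxentscan_ref`, `maxentscan_alt`,
#'   `nnsplice_ref`, `nnsplice_alt`. Alternate scores are only considered
#'   when the matching reference score is present.
#' @param config thresholds, see [insilico_config()].
#' @return one of `"supports_pathogenic"`, `"supports_benign"`,
#'   `"insufficient"`.
#' @export
splice_verdict <- function(p, config = insilico_config()) {
  has <- function(x) !is.null(x) && !is.na(x)
  loss <- logical(0)
  nochange <- logical(0)
  if (has(p$maxentscan_ref) && has(p$maxentscan_alt)) {
    if (p$maxentscan_ref == 0) {
      stop("MaxEntScan reference score of 0: relative drop undefined",
           call. = FALSE)
    }
    drop <- (p$maxentscan_ref - p$maxentscan_alt) / p$maxentscan_ref
    loss <- c(loss, drop >= config$mes_path_drop)
    nochange <- c(nochange, drop < config$mes_benign_drop)
  }
  if (has(p$nnsplice_ref) && has(p$nnsplice_alt)) {
    site_lost <- p$nnsplice_ref >= config$nns_detect &&
      p$nnsplice_alt < config$nns_detect
    rel_drop <- if (p$nnsplice_ref > 0) {
      (p$nnsplice_ref - p$nnsplice_alt) / p$nnsplice_ref
    } else 0
    loss <- c(loss, site_lost)
    nochange <- c(nochange, !site_lost && rel_drop < config$mes_benign_drop)
  }
  if (length(loss) == 0) return("insufficient")
  if (any(loss) && !any(nochange)) return("supports_pathogenic")
  if (all(nochange)) return("supports_benign")
  "insufficient"
}
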