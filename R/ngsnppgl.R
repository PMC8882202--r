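# PPGL-specific (NGSnPPGL study group style) classifier: a configurable
# decision tree over population frequency, variant type, in silico verdicts,
# co-segregation and tumour-assay / published additional information. The
# tree ships as a versioned, human-readable nested config so the topology
# can be revised without code changes; classification is a pure function of
# (profile, tree) and returns a full audit trace.

#' Default NGSnPPGL-style decision tree
#'
#' Node order follows the framework's factor list: (1) a frequency gate
#' (common variants are benign / likely benign regardless of any assay),
#' (2) a truncating-type gate (a rare null variant is likely pathogenic,
#' promoted to pathogenic by confirmatory evidence or recurrence), (3) an
#' evidence-adjustment step at each non-frequency leaf (SDHB-specific loss
#' of function or strong published pathogenic evidence promotes one class;
#' a benign-direction assay demotes one class), (4) an in silico +
#' co-segregation gate for missense and splice candidates, and (5) a default
#' VUS fall-through. Promotion/demotion moves exactly one class per evidence
#' axis, saturating at 1 and 5.
#'
#' @param af_standalone allele frequency at or above which a variant is
#'   benign outright.
#' @param af_benign allele frequency at or above which a variant is likely
#'   benign.
#' @param recurrence_threshold number of independent index cases at or above
#'   which a rare truncating variant is promoted one class.
#' @return nested list of nodes; each internal node is
#'   `list(label, kind = "test", factor, op, value, yes, no)` and each leaf
#'   `list(label, kind = "leaf", class, adjust)` where `adjust` is a subset
#'   of `c("assay", "recurrence")`.
#' @export
ngsnppgl_default_tree <- function(af_standalone = 0.005,
                                  af_benign = 5e-4,
                                  recurrence_threshold = 10L) {
  leaf <- function(label, class, adjust = character()) {
    list(label = label, kind = "leaf", class = as.integer(class),
         adjust = adjust)
  }
  test <- function(label, factor, op, value, yes, no) {
    list(label = label, kind = "test", factor = factor, op = op,
         value = value, yes = yes, no = no)
  }
  tree <- test("freq_standalone", "af", "ge", af_standalone,
    yes = leaf("common_benign", TIER_LEVELS[["BV"]]),
    no = test("freq_benign", "af", "ge", af_benign,
      yes = leaf("frequent_likely_benign", TIER_LEVELS[["LBV"]]),
      no = test("truncating", "null_type", "eq", TRUE,
        yes = leaf("rare_truncating", TIER_LEVELS[["LPV"]],
                   adjust = c("assay", "recurrence")),
        no = test("insilico_pathogenic", "insilico", "eq", "supports_pathogenic",
          yes = leaf("predicted_deleterious", TIER_LEVELS[["LPV"]],
                     adjust = "assay"),
          no = test("insilico_benign", "insilico", "eq", "supports_benign",
            yes = leaf("predicted_neutral", TIER_LEVELS[["LBV"]],
                       adjust = "assay"),
            no = test("segregation", "segregation", "eq", "segregates",
              yes = leaf("cosegregating", TIER_LEVELS[["LPV"]],
                         adjust = "assay"),
              no = test("non_segregation", "segregation", "eq",
                        "non_segregating",
                yes = leaf("non_segregating", TIER_LEVELS[["LBV"]],
                           adjust = "assay"),
                no = leaf("default_vus", TIER_LEVELS[["VUS"]],
                          adjust = "assay"))))))))
  attr(tree, "recurrence_threshold") <- as.integer(recurrence_threshold)
  attr(tree, "version") <- "1"
  tree
}

#' Write / read a decision tree as JSON
#'
#' @param tree a tree as returned by [ngsnppgl_default_tree()].
#' @param path file path.
#' @return `read_ngsnppgl_tree` returns the tree list.
#' @export
write_ngsnppgl_tree <- function(tree, path) {
  payload <- list(recurrence_threshold = attr(tree, "recurrence_threshold"),
                  version = attr(tree, "version"), root = tree)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_ngsnppgl_tree
#' @export
read_ngsnppgl_tree <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  fix <- function(node) {
    node$class <- if (!is.null(node$class)) as.integer(node$class)
    node$adjust <- as.character(unlist(node$adjust))
    if (!is.null(node$yes)) node$yes <- fix(node$yes)
    if (!is.null(node$no)) node$no <- fix(node$no)
    node
  }
  tree <- fix(payload$root)
  attr(tree, "recurrence_threshold") <- as.integer(payload$recurrence_threshold)
  attr(tree, "version") <- payload$version
  tree
}

tree_config_error <- function(msg, path) {
  stop(errorCondition(
    paste0("malformed tree config at node path [", paste(path, collapse = " > "),
           "]: ", msg),
    class = c("sdhb_tree_config_error", "error", "condition")))
}

resolve_factor <- function(e, factor, path) {
  switch(factor,
    af = e$max_population_af,
    null_type = e$variant$vtype %in% NULL_VTYPES &&
      !(e$variant$vtype == "large_rearrangement" && grepl("dup", e$variant$cdna)),
    vtype = e$variant$vtype,
    insilico = {
      v <- c(e$insilico_missense, e$insilico_splice)
      v <- v[!is.na(v)]
      if (any(v == "supports_pathogenic")) "supports_pathogenic"
      else if (length(v) > 0 && all(v == "supports_benign")) "supports_benign"
      else if (any(v == "conflicting")) "conflicting"
      else "insufficient"
    },
    segregation = {
      if (is.na(e$coseg_segregates) || is.na(e$coseg_meioses) ||
          e$coseg_meioses < 3L) "none"
      else if (isTRUE(e$coseg_segregates)) "segregates"
      else "non_segregating"
    },
    case_count = e$case_count,
    tree_config_error(paste0("unknown factor '", factor, "'"), path))
}

apply_op <- function(value, op, ref, path) {
  if (length(value) == 0 || (length(value) == 1 && is.na(value))) return(FALSE)
  switch(op,
    ge = value >= ref,
    le = value <= ref,
    gt = value > ref,
    lt = value < ref,
    eq = identical(value, ref) || (is.logical(ref) && isTRUE(value) == ref) ||
      (is.character(ref) && identical(as.character(value), ref)),
    "in" = as.character(value) %in% as.character(ref),
    tree_config_error(paste0("unknown op '", op, "'"), path))
}

# evidence-axis adjustments applied at a leaf; each axis moves the class by
# at most one, saturating at the tier bounds
leaf_adjust <- function(class, adjust, e, recurrence_threshold, trace) {
  clamp <- function(x) max(1L, min(5L, x))
  if ("assay" %in% adjust) {
    sdhb_specific <- e$shdb_ihc == "negative" && e$sdha_ihc == "positive" &&
      e$other_sdhx_excluded
    strong_lof <- assay_lof(e) && e$other_sdhx_excluded
    strong_published <- (e$prior_pathogenic - e$prior_benign) >= 5L
    promote <- sdhb_specific || strong_lof || strong_published
    demote <- e$loh == "variant_allele_lost" || e$loh == "no_loh" ||
      assay_not_lof(e)
    if (promote && demote) {
      trace <- add_trace(trace, "adjust_assay", "conflicting", "none")
    } else if (promote) {
      class <- clamp(class + 1L)
      trace <- add_trace(trace, "adjust_assay",
                         if (sdhb_specific) "sdhb_specific_lof"
                         else if (strong_lof) "sdh_lof_sdhx_excluded"
                         else "strong_published_evidence", "promote")
    } else if (demote) {
      class <- clamp(class - 1L)
      trace <- add_trace(trace, "adjust_assay", "benign_direction_assay",
                         "demote")
    }
  }
  if ("recurrence" %in% adjust && e$case_count >= recurrence_threshold) {
    class <- clamp(class + 1L)
    trace <- add_trace(trace, "adjust_recurrence",
                       as.character(e$case_count), "promote")
  }
  list(class = class, trace = trace)
}

add_trace <- function(trace, node, value, branch) {
  rbind(trace, data.frame(node = node, value = as.character(value),
                          branch = branch, stringsAsFactors = FALSE))
}

#' Classify a variant with the PPGL-specific decision tree
#'
#' Walks the (configurable) decision tree over the evidence profile and
#' returns the class together with a complete audit trace of every node
#' visited, the input value observed there and the branch taken.
#'
#' @param e an [evidence_profile()].
#' @param tree decision tree, see [ngsnppgl_default_tree()].
#' @return list with `class` (integer tier), `label`, and `trace` (data frame
#'   with columns `node`, `value`, `branch`).
#' @export
classify_ngsnppgl <- function(e, tree = ngsnppgl_default_tree()) {
  stopifnot(inherits(e, "evidence_profile"))
  rec <- attr(tree, "recurrence_threshold")
  if (is.null(rec) || is.na(rec)) rec <- 10L
  trace <- data.frame(node = character(), value = character(),
                      branch = character(), stringsAsFactors = FALSE)
  node <- tree
  path <- character()
  repeat {
    if (is.null(node$kind)) tree_config_error("node lacks 'kind'", path)
    path <- c(path, node$label %||% "?")
    if (node$kind == "leaf") {
      if (is.null(node$class) || is.na(node$class) ||
          node$class < 1L || node$class > 5L) {
        tree_config_error("leaf lacks a valid class", path)
      }
      trace <- add_trace(trace, node$label, tier_label(node$class), "leaf")
      adj <- leaf_adjust(node$class, node$adjust %||% character(), e, rec, trace)
      return(list(class = adj$class, label = tier_label(adj$class),
                  trace = adj$trace))
    }
    if (node$kind != "test" || is.null(node$factor) || is.null(node$op) ||
        is.null(node$yes) || is.null(node$no)) {
      tree_config_error("test node needs factor/op/value/yes/no", path)
    }
    value <- resolve_factor(e, node$factor, path)
    taken <- apply_op(value, node$op, node$value, path)
    trace <- add_trace(trace, node$label,
                       if (length(value) == 1) as.character(value) else "?",
                       if (taken) "yes" else "no")
    node <- if (taken) node$yes else node$no
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify a variant independently under both frameworks
#'
#' Runs the adapted ACMG engine and the PPGL decision tree on the same
#' evidence profile; neither engine reads the other's output.
#'
#' @param e an [evidence_profile()].
#' @param acmg_cfg see [acmg_config()].
#' @param tree see [ngsnppgl_default_tree()].
#' @return list with integer tiers `acmg` and `ngs`, plus `criteria` (ACMG
#'   criterion data frame) and `trace` (decision-tree audit trace).
#' @export
classify_both <- function(e, acmg_cfg = acmg_config(),
                          tree = ngsnppgl_default_tree()) {
  a <- classify_acmg(e, acmg_cfg)
  n <- classify_ngsnppgl(e, tree)
  list(acmg = a$class, ngs = n$class, criteria = a$criteria, trace = n$trace)
}
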