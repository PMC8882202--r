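# Variant parsing, typing and deduplication. All coordinates are HGVS
# coding-DNA positions on the NM_003000.2 reference transcript; no genomic
# liftover is performed and descriptions are taken as submitted (no 3'
# shifting).

#' Variant type vocabulary
#'
#' The twelve mutually exclusive variant-type categories used for typing and
#' for cohort summaries, split between nucleotide substitutions and
#' deletion/duplication (indel) alterations.
#'
#' @format Character vector of length 12.
#' @export
VTYPE_LEVELS <- c(
  # substitutions
  "missense", "nonsense", "splice_site_substitution", "mid_intronic",
  "synonymous", "utr5", "initiation_codon",
  # deletions / duplications / insertions
  "frameshift_indel", "large_rearrangement", "inframe_indel",
  "noncoding_indel", "splice_site_indel"
)

#' Substitution-group variant types
#' @rdname VTYPE_LEVELS
#' @export
VTYPE_SUBSTITUTIONS <- VTYPE_LEVELS[1:7]

#' Indel-group variant types
#' @rdname VTYPE_LEVELS
#' @export
VTYPE_INDELS <- VTYPE_LEVELS[8:12]

# variant types predicted to abolish protein function (null variants)
NULL_VTYPES <- c("nonsense", "frameshift_indel", "splice_site_substitution",
                 "splice_site_indel", "initiation_codon", "large_rearrangement")

parse_error <- function(msg, token = NULL) {
  if (!is.null(token)) msg <- paste0(msg, " [offending token: '", token, "']")
  stop(errorCondition(msg, class = c("sdhb_parse_error", "error", "condition")))
}

consistency_error <- function(msg) {
  stop(errorCondition(msg,
    class = c("sdhb_consistency_error", "error", "condition")))
}

# -- position tokens ---------------------------------------------------------

# An HGVS-c position: optional 5'UTR "-" or 3'UTR "*" prefix, a base position,
# and an optional intronic offset ("+12", "-2") which may be uncertain ("+?").
POS_RE <- "([*-]?)(\\d+)(?:([+-])(\\d+|\\?))?"

parse_pos <- function(tok) {
  m <- regmatches(tok, regexec(paste0("^", POS_RE, "$"), tok))[[1]]
  if (length(m) == 0) parse_error("invalid position", tok)
  prefix <- m[2]
  base <- as.integer(m[3])
  off_sign <- m[4]
  off_raw <- m[5]
  uncertain <- identical(off_raw, "?")
  offset <- if (nzchar(off_sign) && !uncertain) {
    as.integer(off_raw) * if (off_sign == "-") -1L else 1L
  } else if (nzchar(off_sign)) NA_integer_ else 0L
  list(prefix = prefix, base = base, offset = offset,
       intronic = nzchar(off_sign), uncertain = uncertain, text = tok)
}

format_pos <- function(p) p$text

# -- protein descriptions ----------------------------------------------------

parse_protein <- function(protein) {
  s <- gsub("\\s+", "", protein)
  if (!nzchar(s)) return(NULL)
  if (grepl("fs", s)) return(list(kind = "frameshift", text = s))
  m <- regmatches(s, regexec(
    "^p\\.\\(?([A-Z][a-z]{2}|\\*)(\\d+)(=|\\?|Ter|\\*|[A-Z][a-z]{2})\\)?", s))[[1]]
  if (length(m) == 0) parse_error("invalid protein description", protein)
  ref <- m[2]; pos <- as.integer(m[3]); alt <- m[4]
  kind <- if (alt %in% c("Ter", "*")) "nonsense"
  else if (alt == "=") "synonymous"
  else if (pos == 1L) "initiation"
  else if (alt == "?") "unknown_effect"
  else "missense"
  list(kind = kind, ref = ref, pos = pos, alt = alt, text = s)
}

# -- typing rules ------------------------------------------------------------

# Substitution typing precedence: intronic offset |1..2| -> splice site,
# deeper intronic -> mid-intronic; 5'UTR -> utr5; coding position 1..3 ->
# initiation codon; otherwise the protein consequence decides (Ter ->
# nonsense, "=" -> synonymous, default missense).
type_substitution <- function(pos, prot) {
  if (pos$intronic) {
    off <- abs(pos$offset)
    vt <- if (!is.na(off) && off <= 2L) "splice_site_substitution" else "mid_intronic"
    if (!is.null(prot) && prot$kind %in% c("missense", "nonsense", "synonymous")) {
      consistency_error(paste0(
        "protein consequence '", prot$text, "' contradicts intronic position"))
    }
    return(vt)
  }
  if (pos$prefix == "-") return("utr5")
  if (pos$prefix == "*") parse_error("3'UTR substitutions are not supported", pos$text)
  if (pos$base <= 3L) return("initiation_codon")
  if (!is.null(prot)) {
    switch(prot$kind,
      nonsense = "nonsense",
      synonymous = "synonymous",
      initiation = "initiation_codon",
      missense = "missense",
      frameshift = consistency_error(
        "frameshift protein consequence contradicts a substitution"),
      "missense")
  } else {
    # without protein annotation a coding substitution defaults to missense
    "missense"
  }
}

type_indel <- function(p1, p2, kind, seq, prot) {
  if (p1$uncertain || (!is.null(p2) && p2$uncertain)) {
    # uncertain ("?") breakpoints denote whole-exon scale events
    return("large_rearrangement")
  }
  intr1 <- p1$intronic || p1$prefix != ""
  intr2 <- if (is.null(p2)) intr1 else (p2$intronic || p2$prefix != "")
  off1 <- if (p1$intronic) abs(p1$offset) else NA_integer_
  off2 <- if (!is.null(p2) && p2$intronic) abs(p2$offset) else NA_integer_
  if (intr1 && intr2) {
    near <- (!is.na(off1) && off1 <= 2L) || (!is.na(off2) && off2 <= 2L)
    return(if (near) "splice_site_indel" else "noncoding_indel")
  }
  if (intr1 || intr2) {
    # one breakpoint in the intron, one in the exon: the junction is hit
    return("splice_site_indel")
  }
  if (!is.null(prot) && prot$kind == "frameshift") return("frameshift_indel")
  span <- if (is.null(p2)) 1L else p2$base - p1$base + 1L
  len_change <- switch(kind,
    del = span,
    dup = span,
    ins = nchar(seq),
    delins = abs(nchar(seq) - span))
  if (len_change %% 3L == 0L) "inframe_indel" else "frameshift_indel"
}

# -- parser ------------------------------------------------------------------

#' Parse an HGVS coding-DNA variant description
#'
#' Parses, normalizes and types an SDHB variant given as an HGVS c.
#' description (substitutions, deletions, duplications, insertions, delins,
#' intronic offsets, 5'UTR positions and whole-exon scale events with
#' uncertain `?` breakpoints). Typing rules: intronic substitutions with
#' offset within +/-2 of the junction are splice-site, deeper ones
#' mid-intronic; positions `c.1`..`c.3` hit the initiation codon; coding
#' indels without protein annotation are frameshift vs in-frame by length
#' modulo 3; `?` breakpoints denote large rearrangements.
#'
#' @param description HGVS c. string, e.g. `"c.137G>A"`, `"c.72+1A>G"`,
#'   `"c.166_170del"`.
#' @param protein optional HGVS p. string, e.g. `"p.Arg46Gln"`. When present
#'   it decides the consequence of coding substitutions and flags
#'   frameshifts.
#' @param vtype optional explicit variant type overriding inference (one of
#'   [VTYPE_LEVELS]); a differing override is applied with a warning.
#' @return An object of class `sdhb_variant`: a list with elements `cdna`
#'   (normalized description), `protein`, `vtype` and `exon` (`NA` unless
#'   supplied downstream).
#' @examples
#' parse_variant("c.137G>A", "p.Arg46Gln")$vtype  # "missense"
#' parse_variant("c.423+1G>C")$vtype              # "splice_site_substitution"
#' parse_variant("c.1A>G")$vtype                  # "initiation_codon"
#' @export
parse_variant <- function(description, protein = NULL, vtype = NULL) {
  if (is.null(description) || is.na(description) || !nzchar(trimws(description))) {
    parse_error("empty variant description", description)
  }
  s <- gsub("\\s+", "", description)
  if (!grepl("^[Cc]\\.", s)) parse_error("description must start with 'c.'", s)
  body <- sub("^[Cc]\\.", "", s)

  prot <- if (!is.null(protein) && !is.na(protein) && nzchar(trimws(protein))) {
    parse_protein(protein)
  } else NULL

  sub_re <- paste0("^(", POS_RE, ")([ACGTacgt])>([ACGTacgt])$")
  ind_re <- paste0("^(", POS_RE, ")(?:_(", POS_RE, "))?",
                   "(delins|del|dup|ins)([ACGTacgt]*)$")

  m <- regmatches(body, regexec(sub_re, body))[[1]]
  if (length(m) > 0) {
    pos <- parse_pos(m[2])
    ref <- toupper(m[7]); alt <- toupper(m[8])
    if (ref == alt) parse_error("reference and alternate base are identical", body)
    vt <- type_substitution(pos, prot)
    cdna <- paste0("c.", format_pos(pos), ref, ">", alt)
    return(new_variant(cdna, prot, vt, vtype))
  }

  m <- regmatches(body, regexec(ind_re, body))[[1]]
  if (length(m) > 0) {
    p1 <- parse_pos(m[2])
    p2 <- if (nzchar(m[7])) parse_pos(m[7]) else NULL
    kind <- m[12]; seq <- toupper(m[13])
    if (kind == "ins" && !nzchar(seq)) {
      parse_error("insertion without inserted sequence", body)
    }
    if (!is.null(p2) && !p1$uncertain && !p2$uncertain &&
        p1$prefix == "" && p2$prefix == "" && p2$base < p1$base) {
      parse_error("range end precedes range start", body)
    }
    vt <- type_indel(p1, p2, kind, seq, prot)
    cdna <- paste0("c.", format_pos(p1),
                   if (!is.null(p2)) paste0("_", format_pos(p2)) else "",
                   kind, seq)
    return(new_variant(cdna, prot, vt, vtype))
  }

  parse_error("unrecognized HGVS c. syntax", body)
}

new_variant <- function(cdna, prot, inferred_vtype, vtype_override) {
  vt <- inferred_vtype
  if (!is.null(vtype_override) && !is.na(vtype_override)) {
    vtype_override <- match.arg(vtype_override, VTYPE_LEVELS)
    if (!identical(vtype_override, inferred_vtype)) {
      warning(sprintf("vtype override '%s' differs from inferred '%s' for %s",
                      vtype_override, inferred_vtype, cdna), call. = FALSE)
    }
    vt <- vtype_override
  }
  structure(
    list(cdna = cdna,
         protein = if (is.null(prot)) NA_character_ else prot$text,
         vtype = vt, exon = NA_integer_),
    class = "sdhb_variant")
}

#' Format a variant back to its normalized HGVS c. description
#' @param v an `sdhb_variant`.
#' @return character scalar.
#' @export
format_variant <- function(v) {
  stopifnot(inherits(v, "sdhb_variant"))
  v$cdna
}

#' @export
print.sdhb_variant <- function(x, ...) {
  cat(x$cdna,
      if (!is.na(x$protein)) paste0(" (", x$protein, ")") else "",
      " [", x$vtype, "]\n", sep = "")
  invisible(x)
}

#' @export
`==.sdhb_variant` <- function(e1, e2) {
  identical(e1$cdna, e2$cdna)
}

#' Deduplicate index cases into distinct variants with occurrence counts
#'
#' Collapses a table of index cases (one row per reported case) to the
#' distinct variants it contains, counting the number of independent index
#' cases per variant. Equality is by normalized cDNA description, so
#' whitespace or case differences in submitted strings collapse to one key.
#'
#' @param cases data frame with at least a `cdna` column; optional `protein`
#'   and `vtype` columns are carried through (first occurrence wins).
#' @return data frame with columns `cdna`, `protein`, `vtype`, `count`,
#'   ordered by decreasing count then cDNA; `sum(count) == nrow(cases)`.
#' @export
deduplicate <- function(cases) {
  if (is.null(cases) || nrow(as.data.frame(cases)) == 0) {
    return(data.frame(cdna = character(), protein = character(),
                      vtype = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  cases <- as.data.frame(cases)
  if (!"cdna" %in% names(cases)) stop("cases must have a 'cdna' column")
  parsed <- lapply(seq_len(nrow(cases)), function(i) {
    parse_variant(cases$cdna[i],
                  protein = if ("protein" %in% names(cases)) cases$protein[i] else NULL,
                  vtype = if ("vtype" %in% names(cases)) cases$vtype[i] else NULL)
  })
  key <- vapply(parsed, function(v) v$cdna, character(1))
  first <- !duplicated(key)
  tab <- table(key)
  out <- data.frame(
    cdna = key[first],
    protein = vapply(parsed[first], function(v) v$protein, character(1)),
    vtype = vapply(parsed[first], function(v) v$vtype, character(1)),
    stringsAsFactors = FALSE)
  out$count <- as.integer(tab[out$cdna])
  out <- out[order(-out$count, out$cdna), , drop = FALSE]
  rownames(out) <- NULL
  out
}
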