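test_that("substitutions are parsed and typed from position and protein", {
  expect_identical(parse_variant("c.137G>A", "p.Arg46Gln")$vtype, "missense")
  expect_identical(parse_variant("c.268C>T", "p.Arg90Ter")$vtype, "nonsense")
  expect_identical(parse_variant("c.600T>C", "p.Gly200=")$vtype, "synonymous")
  expect_identical(parse_variant("c.423+1G>C")$vtype, "splice_site_substitution")
  expect_identical(parse_variant("c.166-2A>G")$vtype, "splice_site_substitution")
  expect_identical(parse_variant("c.72+33G>A")$vtype, "mid_intronic")
  expect_identical(parse_variant("c.-20C>T")$vtype, "utr5")
  expect_identical(parse_variant("c.1A>G", "p.Met1?")$vtype, "initiation_codon")
  expect_identical(parse_variant("c.3G>A")$vtype, "initiation_codon")
  # a coding substitution without protein annotation defaults to missense
  expect_identical(parse_variant("c.137G>A")$vtype, "missense")
})

test_that("indels are typed by breakpoints, protein and length modulo 3", {
  expect_identical(parse_variant("c.166_170del")$vtype, "frameshift_indel")
  expect_identical(parse_variant("c.200del")$vtype, "frameshift_indel")
  expect_identical(parse_variant("c.300_305del")$vtype, "inframe_indel")
  expect_identical(parse_variant("c.300_302dup")$vtype, "inframe_indel")
  expect_identical(parse_variant("c.100_101insTGA")$vtype, "inframe_indel")
  # delins length change is |inserted - removed|: 4 out, 1 in -> net 3
  expect_identical(parse_variant("c.100_103delinsA")$vtype, "inframe_indel")
  expect_identical(parse_variant("c.100_103delinsAG")$vtype, "frameshift_indel")
  # protein-level frameshift overrides the length rule
  expect_identical(parse_variant("c.300_305del", "p.Ile100MetfsTer5")$vtype,
                   "frameshift_indel")
  # uncertain breakpoints denote whole-exon scale events
  expect_identical(parse_variant("c.73-?_287+?del")$vtype, "large_rearrangement")
  expect_identical(parse_variant("c.1-?_72+?dup")$vtype, "large_rearrangement")
  # intronic breakpoints
  expect_identical(parse_variant("c.72+1_72+4del")$vtype, "splice_site_indel")
  expect_identical(parse_variant("c.70_72+4del")$vtype, "splice_site_indel")
  expect_identical(parse_variant("c.72+20_72+25del")$vtype, "noncoding_indel")
  expect_identical(parse_variant("c.-40_-38del")$vtype, "noncoding_indel")
})

test_that("parser normalizes whitespace and case, round-trips, and errors cleanly", {
  v <- parse_variant(" c.137 G>A ", "p.Arg46Gln")
  expect_identical(v$cdna, "c.137G>A")
  expect_identical(format_variant(v), "c.137G>A")
  expect_true(v == parse_variant("C.137g>a"))

  expect_error(parse_variant("c.137G>G"), class = "sdhb_parse_error")
  expect_error(parse_variant("137G>A"), class = "sdhb_parse_error")
  expect_error(parse_variant("c.xyz"), class = "sdhb_parse_error")
  expect_error(parse_variant("c.200_100del"), class = "sdhb_parse_error")
  expect_error(parse_variant("c.100_101ins"), class = "sdhb_parse_error")
  expect_error(parse_variant(""), class = "sdhb_parse_error")
  expect_error(parse_variant("c.*12A>G"), class = "sdhb_parse_error")
  # contradictory protein annotation is a consistency error, not a silent fix
  expect_error(parse_variant("c.72+33G>A", "p.Arg25Gln"),
               class = "sdhb_consistency_error")
  expect_error(parse_variant("c.137G>A", "p.Arg46LeufsTer3"),
               class = "sdhb_consistency_error")
  # explicit vtype override differing from inference warns
  expect_warning(parse_variant("c.137G>A", "p.Arg46Gln", vtype = "synonymous"),
                 "differs from inferred")
})

test_that("substitution consequences agree with the standard genetic code", {
  # oracle: translate ref/alt codons with Biostrings' genetic code and derive
  # the expected type, then feed the parser the equivalent protein string
  gc <- Biostrings::GENETIC_CODE
  one_to_three <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
                    Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
                    L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
                    S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")
  cases <- list(
    list(codon = 46L, ref = "CGG", alt = "CAG", off = 2L),   # Arg -> Gln
    list(codon = 90L, ref = "CGA", alt = "TGA", off = 1L),   # Arg -> stop
    list(codon = 200L, ref = "GGT", alt = "GGC", off = 3L))  # Gly -> Gly
  for (cs in cases) {
    aa_ref <- gc[[cs$ref]]
    aa_alt <- gc[[cs$alt]]
    expected <- if (aa_alt == "*") "nonsense"
    else if (aa_alt == aa_ref) "synonymous" else "missense"
    prot <- paste0("p.", one_to_three[[aa_ref]], cs$codon,
                   if (aa_alt == "*") "Ter"
                   else if (aa_alt == aa_ref) "="
                   else one_to_three[[aa_alt]])
    pos <- 3L * (cs$codon - 1L) + cs$off
    cdna <- paste0("c.", pos, substr(cs$ref, cs$off, cs$off), ">",
                   substr(cs$alt, cs$off, cs$off))
    expect_identical(parse_variant(cdna, prot)$vtype, expected, info = cdna)
  }
})

test_that("deduplication counts index cases and is order invariant", {
  cases <- data.frame(
    cdna = c("c.137G>A", "C.137g>A", "c.268C>T", " c.137G>A", "c.72+1G>T"),
    protein = c("p.Arg46Gln", "p.Arg46Gln", "p.Arg90Ter", "p.Arg46Gln", NA),
    stringsAsFactors = FALSE)
  d <- deduplicate(cases)
  expect_identical(nrow(d), 2L + 1L)
  expect_identical(sum(d$count), nrow(cases))
  expect_identical(d$count[d$cdna == "c.137G>A"], 3L)
  expect_identical(d$vtype[d$cdna == "c.72+1G>T"], "splice_site_substitution")

  set.seed(11)
  perm <- sample(nrow(cases))
  d2 <- deduplicate(cases[perm, , drop = FALSE])
  expect_identical(d, d2)

  empty <- deduplicate(data.frame(cdna = character()))
  expect_identical(nrow(empty), 0L)
})
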