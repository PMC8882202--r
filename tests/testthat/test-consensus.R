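fa <- function(code, strength) {
  data.frame(code = code, strength = strength, rationale = "test",
             stringsAsFactors = FALSE)
}

test_that("concordance reproduces the transcribed class-pair breakdown", {
  fx <- fixture_reference_tables()
  cc <- concordance(fx$concordance_pairs)
  expect_identical(cc$n_concordant, 161L)
  expect_identical(cc$n_discordant, 62L)
  expect_identical(cc$breakdown[["VUS"]], 61L)
  expect_identical(cc$breakdown[["LPV"]], 70L)
  expect_identical(cc$breakdown[["PV"]], 24L)
  expect_identical(cc$breakdown[["LBV"]], 6L)
  # unordered pairs
  expect_identical(cc$breakdown[["BV/LBV"]], 4L)
  expect_identical(cc$breakdown[["BV/VUS"]], 1L)
  expect_identical(cc$breakdown[["LBV/VUS"]], 17L)
  expect_identical(cc$breakdown[["VUS/LPV"]], 23L)
  expect_identical(cc$breakdown[["VUS/PV"]], 6L)
  expect_identical(cc$breakdown[["LPV/PV"]], 11L)
  expect_identical(sum(cc$breakdown), 223L)
})

test_that("round 1 applies retention, promotion and functional resolution", {
  pairs <- data.frame(
    cdna = c("v_keep", "v_promote", "v_func_path", "v_func_ben",
             "v_gap", "v_open"),
    acmg = c("VUS", "LPV", "LPV", "VUS", "VUS", "LPV"),
    ngs = c("VUS", "LPV", "VUS", "BV", "LPV", "PV"),
    case_count = c(1L, 12L, 2L, 1L, 1L, 3L),
    stringsAsFactors = FALSE)
  criteria <- list(
    v_promote = fa("FA_PVS", "pathogenic_very_strong"),
    v_func_path = fa("FA_PM", "pathogenic_moderate"),
    v_func_ben = fa("FA_BS", "benign_strong"),
    v_gap = fa("PP3", "pathogenic_supporting"))
  r1 <- curate_round1(pairs, criteria)
  dec <- r1$decisions
  post <- function(id) dec$post_class[dec$cdna == id]
  expect_identical(post("v_keep"), as_tier("VUS"))
  # concordant LPV, >= 10 index cases, strong functional evidence -> PV
  expect_identical(post("v_promote"), as_tier("PV"))
  # discordant pairs resolve toward the functional-evidence direction
  expect_identical(post("v_func_path"), as_tier("LPV"))
  expect_identical(post("v_func_ben"), as_tier("BV"))
  # one-class gap around VUS with directional non-functional evidence
  expect_identical(post("v_gap"), as_tier("LPV"))
  # everything else stays open for round 2
  expect_identical(r1$unresolved$cdna, "v_open")
  expect_identical(r1$unresolved$cand_lo, as_tier("LPV"))
  expect_identical(r1$unresolved$cand_hi, as_tier("PV"))

  # without strong functional evidence recurrence alone does not promote
  r1b <- curate_round1(pairs[pairs$cdna == "v_promote", , drop = FALSE],
                       criteria = list(v_promote = fa("FA_PP",
                                                      "pathogenic_supporting")))
  expect_identical(r1b$decisions$post_class, as_tier("LPV"))
})

test_that("round 2 resolves everything left open", {
  unresolved <- data.frame(
    cdna = c("u_path", "u_ben", "u_tie"),
    cand_lo = as_tier(c("VUS", "VUS", "LPV")),
    cand_hi = as_tier(c("PV", "LPV", "PV")),
    stringsAsFactors = FALSE)
  criteria <- list(u_path = fa("FA_PS", "pathogenic_strong"),
                   u_ben = fa("FA_BP", "benign_supporting"))
  r2 <- curate_round2(unresolved, criteria)
  expect_identical(r2$post_class,
                   as_tier(c("PV", "VUS", "LPV")))  # tie -> less pathogenic
  r2b <- curate_round2(unresolved, criteria,
                       policy = consensus_policy(tie_break = "more_pathogenic"))
  expect_identical(r2b$post_class[3], as_tier("PV"))
})

test_that("the override ledger takes absolute precedence in both rounds", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("cdna\tfinal_class\tcitation",
               "c.137G>A\tLPV\tdoi:10.0000/example",
               "c.268C>T\t3\tpanel decision 2019"), tmp)
  ov <- read_override_ledger(tmp)
  expect_identical(ov$final_class, as_tier(c("LPV", "VUS")))

  pairs <- data.frame(cdna = c("c.137G>A", "c.268C>T"),
                      acmg = c("BV", "PV"), ngs = c("BV", "PV"),
                      stringsAsFactors = FALSE)
  out <- curate(pairs, overrides = ov)
  expect_identical(out$final_class, as_tier(c("LPV", "VUS")))
  expect_identical(out$source, c("override", "override"))

  # an override naming an unknown variant is an error, not a silent no-op
  pairs2 <- data.frame(cdna = "c.600T>C", acmg = "VUS", ngs = "VUS",
                       stringsAsFactors = FALSE)
  expect_error(curate(pairs2, overrides = ov), "unknown variant")
  expect_error(read_override_ledger({
    t2 <- tempfile(); writeLines("cdna\tnote\nx\ty", t2); t2
  }), "must have columns")
})

test_that("curation is total: every variant gets exactly one final class", {
  fx <- fixture_reference_tables()
  pairs <- fx$concordance_pairs
  out <- curate(pairs)
  expect_identical(nrow(out), 223L)
  expect_identical(sort(out$cdna), sort(pairs$cdna))
  expect_false(anyDuplicated(out$cdna) > 0)
  expect_true(all(out$final_class %in% 1:5))
  expect_true(all(out$round %in% 1:2))
  # with no criteria and no overrides, every discordant pair reaches round 2
  expect_identical(sum(out$round == 2L), 62L)
  expect_true(all(is.na(out$round1_class[out$round == 2L])))
  expect_true(all(!is.na(out$round1_class[out$round == 1L])))
  # duplicate variants are rejected
  expect_error(curate(rbind(pairs, pairs[1, ])), "once")
})
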