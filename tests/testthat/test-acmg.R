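test_that("tumour-assay evidence maps onto the six adapted tiers", {
  v <- "c.137G>A"; p <- "p.Arg46Gln"
  tier <- function(...) {
    crit <- assign_functional_criteria(profile_of(v, p, ...))
    crit$code
  }
  expect_identical(tier(loh = "variant_allele_lost"), "FA_BS")
  expect_identical(tier(loh = "no_loh"), "FA_BP")
  expect_identical(tier(shdb_ihc = "positive"), "FA_BP")
  expect_identical(tier(loh = "variant_allele_retained_wt_lost"), "FA_PP")
  expect_identical(tier(sdh_activity = "lost"), "FA_PM")
  expect_identical(tier(sdh_activity = "lost", other_sdhx_excluded = TRUE),
                   "FA_PS")
  expect_identical(tier(transcriptomic_cluster = "cluster_1A",
                        other_sdhx_excluded = TRUE), "FA_PS")
  # SDHB-specific loss of function: the very-strong tier supersedes FA_PS
  expect_identical(tier(shdb_ihc = "negative", sdha_ihc = "positive",
                        other_sdhx_excluded = TRUE), "FA_PVS")
  # without SDHA staining the same IHC stays at strong
  expect_identical(tier(shdb_ihc = "negative", other_sdhx_excluded = TRUE),
                   "FA_PS")

  # contradictory assays: both directions returned and flagged
  crit <- assign_functional_criteria(profile_of(
    v, p, loh = "variant_allele_lost", sdh_activity = "lost"))
  expect_setequal(crit$code, c("FA_BS", "FA_PM"))
  expect_true(attr(crit, "conflict"))
  expect_true(all(grepl("conflicting-evidence", crit$rationale)))
})

test_that("standard criteria fire from the evidence profile", {
  cfg <- acmg_config()
  # rare nonsense variant: PVS1 + PM2 -> likely pathogenic
  res <- classify_acmg(profile_of("c.268C>T", "p.Arg90Ter"), cfg)
  expect_setequal(res$criteria$code, c("PVS1", "PM2"))
  expect_identical(res$class, as_tier("LPV"))

  # common variant: BA1 stands alone
  res <- classify_acmg(profile_of("c.137G>A", "p.Arg46Gln",
                                  max_population_af = 0.06), cfg)
  expect_true("BA1" %in% res$criteria$code)
  expect_identical(res$class, as_tier("BV"))

  # BS1 band
  crit <- assign_criteria(profile_of("c.137G>A", "p.Arg46Gln",
                                     max_population_af = 1e-3), cfg)
  expect_true("BS1" %in% crit$code)
  expect_false(any(c("BA1", "PM2") %in% crit$code))

  # initiation codon at the configured (strong) level
  crit <- assign_criteria(profile_of("c.1A>G", "p.Met1?"), cfg)
  expect_identical(crit$strength[crit$code == "PVS1"], "pathogenic_strong")
  # a whole-gene duplication is not presumed null
  crit <- assign_criteria(profile_of("c.1-?_765+?dup"), cfg)
  expect_false("PVS1" %in% crit$code)
  # a multi-exon deletion is
  crit <- assign_criteria(profile_of("c.73-?_287+?del"), cfg)
  expect_true("PVS1" %in% crit$code)

  # PM4, PP1/BS4, PP3/BP4, PS1 over PM5, BP7, REP ladder
  expect_true("PM4" %in% assign_criteria(profile_of("c.300_305del"), cfg)$code)
  crit <- assign_criteria(profile_of(
    "c.137G>A", "p.Arg46Gln", coseg_meioses = 4, coseg_segregates = TRUE), cfg)
  expect_true("PP1" %in% crit$code)
  crit <- assign_criteria(profile_of(
    "c.137G>A", "p.Arg46Gln", coseg_meioses = 5, coseg_segregates = FALSE), cfg)
  expect_true("BS4" %in% crit$code)
  # too few meioses: neither fires
  crit <- assign_criteria(profile_of(
    "c.137G>A", "p.Arg46Gln", coseg_meioses = 2, coseg_segregates = TRUE), cfg)
  expect_false(any(c("PP1", "BS4") %in% crit$code))
  crit <- assign_criteria(profile_of(
    "c.137G>A", "p.Arg46Gln", insilico_missense = "supports_pathogenic"), cfg)
  expect_true("PP3" %in% crit$code)
  crit <- assign_criteria(profile_of(
    "c.137G>A", "p.Arg46Gln", prior_same_aa_pathogenic = TRUE,
    prior_same_codon_pathogenic = TRUE), cfg)
  expect_true("PS1" %in% crit$code)
  expect_false("PM5" %in% crit$code)
  crit <- assign_criteria(profile_of(
    "c.137G>A", "p.Arg46Gln", prior_same_codon_pathogenic = TRUE), cfg)
  expect_true("PM5" %in% crit$code)
  crit <- assign_criteria(profile_of(
    "c.600T>C", "p.Gly200=", max_population_af = 1e-4,
    insilico_splice = "supports_benign"), cfg)
  expect_true(all(c("BP7", "BP4") %in% crit$code))
  rep_strength <- function(p, b) {
    crit <- assign_criteria(profile_of("c.137G>A", "p.Arg46Gln",
                                       prior_pathogenic = p, prior_benign = b),
                            cfg)
    if ("REP" %in% crit$code) crit$strength[crit$code == "REP"] else NA
  }
  expect_identical(rep_strength(6, 0), "pathogenic_strong")
  expect_identical(rep_strength(3, 1), "pathogenic_moderate")
  expect_identical(rep_strength(1, 0), "pathogenic_supporting")
  expect_identical(rep_strength(0, 3), "benign_strong")
  expect_true(is.na(rep_strength(0, 0)))
})

test_that("combine matches an exhaustive brute-force oracle", {
  grid <- oracle_grid(3L)
  expect_identical(nrow(grid), 16384L)  # 4^7 combinations
  got <- mapply(combine_strength_counts, grid$pvs, grid$ps, grid$pm, grid$pp,
                grid$ba, grid$bs, grid$bp)
  want <- mapply(oracle_combine, grid$pvs, grid$ps, grid$pm, grid$pp,
                 grid$ba, grid$bs, grid$bp)
  expect_identical(as.integer(got), as.integer(want))
})

test_that("combine is monotone under added pathogenic evidence", {
  grid <- oracle_grid(2L)
  base <- mapply(combine_strength_counts, grid$pvs, grid$ps, grid$pm, grid$pp,
                 grid$ba, grid$bs, grid$bp)
  for (col in c("pvs", "ps", "pm", "pp")) {
    bumped <- grid
    bumped[[col]] <- bumped[[col]] + 1L
    after <- mapply(combine_strength_counts, bumped$pvs, bumped$ps, bumped$pm,
                    bumped$pp, bumped$ba, bumped$bs, bumped$bp)
    expect_true(all(after >= base), info = col)
  }
})

test_that("excluded criteria are never emitted over randomized profiles", {
  set.seed(41)
  cfg <- acmg_config()
  for (i in 1:250) {
    crit <- suppressWarnings(assign_criteria(random_profile(), cfg))
    expect_false(any(crit$code %in% EXCLUDED_CRITERIA))
    expect_false(anyDuplicated(crit$code) > 0)
    cls <- combine_criteria(crit)
    expect_true(cls %in% 1:5)
  }
})
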