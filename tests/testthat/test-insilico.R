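test_that("conservation ratio counts matching orthologs out of 14", {
  expect_identical(conservation_ratio(rep("R", 14), "R"), 1)
  expect_identical(conservation_ratio(c(rep("R", 7), rep("K", 7)), "R"), 0.5)
  expect_identical(conservation_ratio(rep("K", 14), "R"), 0)
  # gaps are non-matching: absence of the residue is not conservation
  expect_identical(conservation_ratio(c(rep("R", 10), rep("-", 4)), "R"),
                   10 / 14)
  # permutation invariance and granularity
  set.seed(21)
  res <- sample(c(rep("R", 9), rep("H", 3), rep("-", 2)))
  r <- conservation_ratio(res, "R")
  expect_identical(r, conservation_ratio(rev(res), "R"))
  expect_identical(r * 14, round(r * 14))
  expect_identical(conservation_ratio(tolower(res), "r"), r)

  expect_error(conservation_ratio(rep("R", 13), "R"), "exactly 14")
  expect_error(conservation_ratio(c(rep("R", 13), "Z"), "R"), "invalid residue")
})

test_that("alignment-based conservation matches the direct computation", {
  tmp <- tempfile(fileext = ".fasta")
  human <- "MRAKL"
  orth <- c(rep("MRAKL", 10), rep("MKAKL", 3), "M-AKL")
  writeLines(c(">human", human,
               unlist(lapply(seq_along(orth), function(i) {
                 c(paste0(">orth", i), orth[i])
               }))), tmp)
  got <- alignment_conservation(tmp, c(1, 2, 5))
  expect_identical(got, c(1, 10 / 14, 1))
  expect_error(alignment_conservation(tmp, 6), "out of range")
})

test_that("missense verdicts aggregate tool directions", {
  cfg <- insilico_config()
  expect_identical(missense_verdict(list(polyphen2 = "probably_damaging"), cfg),
                   "insufficient")
  expect_identical(
    missense_verdict(list(polyphen2 = "probably_damaging",
                          sift = "deleterious"), cfg),
    "supports_pathogenic")
  expect_identical(
    missense_verdict(list(conservation_ratio = 1.0, grantham = 180,
                          mutation_taster = "disease_causing"), cfg),
    "supports_pathogenic")
  expect_identical(
    missense_verdict(list(polyphen2 = "benign", sift = "tolerated",
                          conservation_ratio = 0.2), cfg),
    "supports_benign")
  # one tool on each side is a conflict, whatever else reports
  expect_identical(
    missense_verdict(list(polyphen2 = "benign",
                          mutation_taster = "disease_causing"), cfg),
    "conflicting")
  # two tools reporting but neither decisive
  expect_identical(
    missense_verdict(list(conservation_ratio = 0.7, grantham = 100), cfg),
    "insufficient")
  expect_error(missense_verdict(list(grantham = 300, sift = "deleterious"), cfg),
               "215")
})

test_that("splice verdicts follow relative score drops", {
  cfg <- insilico_config()
  # clear site loss
  expect_identical(
    splice_verdict(list(maxentscan_ref = 9.4, maxentscan_alt = 0.8), cfg),
    "supports_pathogenic")
  # essentially unchanged scores across all reporting tools
  expect_identical(
    splice_verdict(list(maxentscan_ref = 8.0, maxentscan_alt = 7.9,
                        nnsplice_ref = 0.9, nnsplice_alt = 0.89), cfg),
    "supports_benign")
  # NNSplice-detected site lost in the alternate
  expect_identical(
    splice_verdict(list(nnsplice_ref = 0.85, nnsplice_alt = 0.2), cfg),
    "supports_pathogenic")
  # disagreement between tools is not called either way
  expect_identical(
    splice_verdict(list(maxentscan_ref = 9.0, maxentscan_alt = 2.0,
                        nnsplice_ref = 0.9, nnsplice_alt = 0.9), cfg),
    "insufficient")
  expect_identical(splice_verdict(list(), cfg), "insufficient")
  expect_error(splice_verdict(list(maxentscan_ref = 0, maxentscan_alt = 2), cfg),
               "undefined")
})

test_that("splice verdict is monotone in the alternate score", {
  cfg <- insilico_config()
  rank <- c(supports_benign = 1L, insufficient = 2L, supports_pathogenic = 3L)
  set.seed(31)
  for (i in 1:50) {
    ref <- runif(1, 4, 11)
    alts <- sort(runif(2, 0, ref))
    v_low <- splice_verdict(list(maxentscan_ref = ref,
                                 maxentscan_alt = alts[1]), cfg)
    v_high <- splice_verdict(list(maxentscan_ref = ref,
                                  maxentscan_alt = alts[2]), cfg)
    expect_gte(rank[[v_low]], rank[[v_high]])
  }
})
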