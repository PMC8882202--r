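test_that("the default tree reproduces the framework's worked examples", {
  tree <- ngsnppgl_default_tree()
  # rare frameshift -> likely pathogenic
  res <- classify_ngsnppgl(profile_of("c.166_170del"), tree)
  expect_identical(res$class, as_tier("LPV"))
  expect_identical(res$trace$node[res$trace$branch == "leaf"], "rare_truncating")
  # bare rare missense -> VUS via the fall-through leaf
  res <- classify_ngsnppgl(profile_of("c.137G>A", "p.Arg46Gln"), tree)
  expect_identical(res$class, as_tier("VUS"))
  expect_identical(res$trace$node[res$trace$branch == "leaf"], "default_vus")
  # common variant -> benign
  res <- classify_ngsnppgl(profile_of("c.137G>A", "p.Arg46Gln",
                                      max_population_af = 0.06), tree)
  expect_identical(res$class, as_tier("BV"))
})

test_that("the frequency gate dominates every assay", {
  tree <- ngsnppgl_default_tree()
  # even a truncating variant with a confirmatory SDHB-specific assay stays
  # benign once the standalone frequency threshold is crossed
  res <- classify_ngsnppgl(profile_of(
    "c.268C>T", "p.Arg90Ter", max_population_af = 0.02,
    shdb_ihc = "negative", sdha_ihc = "positive",
    other_sdhx_excluded = TRUE), tree)
  expect_identical(res$class, as_tier("BV"))
  expect_identical(res$trace$node[1], "freq_standalone")
  expect_false(any(grepl("adjust", res$trace$node)))
})

test_that("leaf adjustments move one class per axis and saturate", {
  tree <- ngsnppgl_default_tree()
  # truncating + SDHB-specific assay: promoted to pathogenic
  res <- classify_ngsnppgl(profile_of(
    "c.268C>T", "p.Arg90Ter", shdb_ihc = "negative", sdha_ihc = "positive",
    other_sdhx_excluded = TRUE), tree)
  expect_identical(res$class, as_tier("PV"))
  expect_true("adjust_assay" %in% res$trace$node)
  # truncating + recurrence: promoted to pathogenic
  res <- classify_ngsnppgl(profile_of("c.268C>T", "p.Arg90Ter",
                                      case_count = 12), tree)
  expect_identical(res$class, as_tier("PV"))
  expect_true("adjust_recurrence" %in% res$trace$node)
  # both axes together saturate at class 5
  res <- classify_ngsnppgl(profile_of(
    "c.268C>T", "p.Arg90Ter", case_count = 25, shdb_ihc = "negative",
    sdha_ihc = "positive", other_sdhx_excluded = TRUE), tree)
  expect_identical(res$class, as_tier("PV"))
  # strong published evidence promotes a predicted-deleterious missense
  res <- classify_ngsnppgl(profile_of(
    "c.137G>A", "p.Arg46Gln", insilico_missense = "supports_pathogenic",
    prior_pathogenic = 8), tree)
  expect_identical(res$class, as_tier("PV"))
  # a benign-direction assay demotes
  res <- classify_ngsnppgl(profile_of(
    "c.137G>A", "p.Arg46Gln", insilico_missense = "supports_pathogenic",
    loh = "variant_allele_lost"), tree)
  expect_identical(res$class, as_tier("VUS"))
  # conflicting evidence axes cancel
  res <- classify_ngsnppgl(profile_of(
    "c.137G>A", "p.Arg46Gln", insilico_missense = "supports_pathogenic",
    loh = "variant_allele_lost", prior_pathogenic = 8), tree)
  expect_identical(res$class, as_tier("LPV"))
  expect_true(any(res$trace$node == "adjust_assay" &
                    res$trace$branch == "none"))
})

test_that("every leaf of the default tree is reachable", {
  tree <- ngsnppgl_default_tree()
  profiles <- list(
    common_benign = profile_of("c.137G>A", "p.Arg46Gln",
                               max_population_af = 0.01),
    frequent_likely_benign = profile_of("c.137G>A", "p.Arg46Gln",
                                        max_population_af = 1e-3),
    rare_truncating = profile_of("c.268C>T", "p.Arg90Ter"),
    predicted_deleterious = profile_of(
      "c.137G>A", "p.Arg46Gln", insilico_missense = "supports_pathogenic"),
    predicted_neutral = profile_of(
      "c.137G>A", "p.Arg46Gln", insilico_missense = "supports_benign"),
    cosegregating = profile_of("c.137G>A", "p.Arg46Gln",
                               coseg_meioses = 4, coseg_segregates = TRUE),
    non_segregating = profile_of("c.137G>A", "p.Arg46Gln",
                                 coseg_meioses = 4, coseg_segregates = FALSE),
    default_vus = profile_of("c.137G>A", "p.Arg46Gln"))
  for (leaf in names(profiles)) {
    res <- classify_ngsnppgl(profiles[[leaf]], tree)
    expect_identical(res$trace$node[res$trace$branch == "leaf"], leaf)
  }
})

test_that("classification is deterministic and survives a JSON round trip", {
  tree <- ngsnppgl_default_tree()
  set.seed(51)
  profiles <- replicate(20, random_profile(), simplify = FALSE)
  res1 <- lapply(profiles, classify_ngsnppgl, tree = tree)
  res2 <- lapply(profiles, classify_ngsnppgl, tree = tree)
  expect_identical(res1, res2)

  tmp <- tempfile(fileext = ".json")
  write_ngsnppgl_tree(tree, tmp)
  tree2 <- read_ngsnppgl_tree(tmp)
  res3 <- lapply(profiles, classify_ngsnppgl, tree = tree2)
  expect_identical(lapply(res1, `[[`, "class"), lapply(res3, `[[`, "class"))
  expect_identical(lapply(res1, `[[`, "trace"), lapply(res3, `[[`, "trace"))
})

test_that("a reconfigured tree changes behaviour without code changes", {
  strict <- ngsnppgl_default_tree(af_standalone = 0.05, af_benign = 0.01,
                                  recurrence_threshold = 3L)
  p <- profile_of("c.137G>A", "p.Arg46Gln", max_population_af = 0.02)
  expect_identical(classify_ngsnppgl(p, ngsnppgl_default_tree())$class,
                   as_tier("BV"))
  expect_identical(classify_ngsnppgl(p, strict)$class, as_tier("LBV"))
  p <- profile_of("c.268C>T", "p.Arg90Ter", case_count = 4)
  expect_identical(classify_ngsnppgl(p, strict)$class, as_tier("PV"))
  # malformed trees are rejected with a config error
  bad <- ngsnppgl_default_tree()
  bad$factor <- "no_such_factor"
  expect_error(classify_ngsnppgl(profile_of("c.137G>A"), bad),
               class = "sdhb_tree_config_error")
})
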