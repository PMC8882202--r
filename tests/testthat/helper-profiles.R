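# Randomized but always-valid evidence profiles used for property tests.
random_profile <- function() {
  pool <- list(
    list("c.137G>A", "p.Arg46Gln"), list("c.268C>T", "p.Arg90Ter"),
    list("c.72+1G>T", NULL), list("c.600T>C", "p.Gly200="),
    list("c.166_170del", NULL), list("c.72+40A>G", NULL),
    list("c.300_305del", NULL), list("c.1A>G", "p.Met1?"),
    list("c.-30C>T", NULL), list("c.73-?_287+?del", NULL))
  pick <- pool[[sample(length(pool), 1)]]
  v <- parse_variant(pick[[1]], protein = pick[[2]])
  af <- if (runif(1) < 0.4) NA_real_ else runif(1, 0, 0.02)
  meioses <- if (runif(1) < 0.5) NA_integer_ else sample(1:8, 1)
  evidence_profile(
    v,
    max_population_af = af,
    case_count = sample(1:25, 1),
    coseg_meioses = meioses,
    coseg_segregates = if (is.na(meioses)) NA else runif(1) < 0.5,
    insilico_missense = sample(c(NA, "supports_pathogenic", "supports_benign",
                                 "conflicting", "insufficient"), 1),
    insilico_splice = sample(c(NA, "supports_pathogenic", "supports_benign",
                               "insufficient"), 1),
    cdna_splicing = sample(c("aberrant", "normal", "not_done"), 1),
    loh = sample(c("variant_allele_retained_wt_lost", "variant_allele_lost",
                   "no_loh", "not_done"), 1),
    shdb_ihc = sample(c("negative", "positive", "not_done"), 1),
    sdha_ihc = sample(c("negative", "positive", "not_done"), 1),
    sdh_activity = sample(c("lost", "preserved", "not_done"), 1),
    transcriptomic_cluster = sample(c("cluster_1A", "cluster_1B",
                                      "cluster_2A", "not_done"), 1),
    western = sample(c("reduced_absent", "normal", "not_done"), 1),
    other_sdhx_excluded = runif(1) < 0.5,
    prior_pathogenic = sample(0:10, 1),
    prior_benign = sample(0:10, 1),
    prior_same_aa_pathogenic = runif(1) < 0.2,
    prior_same_codon_pathogenic = runif(1) < 0.2)
}

# minimal profile for a parsed variant with chosen evidence fields
profile_of <- function(cdna, protein = NULL, ...) {
  evidence_profile(parse_variant(cdna, protein = protein), ...)
}
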