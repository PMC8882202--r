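# Brute-force oracle for the ACMG/AMP combining table, typed out
# independently of the package implementation as a direct transcription of
# the published rule list (one predicate per published rule).
oracle_combine <- function(pvs, ps, pm, pp, ba, bs, bp) {
  pathogenic_rules <- c(
    pvs >= 2,                                  # two very-strong criteria
    pvs >= 1 && ps >= 1,                       # Ia
    pvs >= 1 && pm >= 2,                       # Ib
    pvs >= 1 && pm >= 1 && pp >= 1,            # Ic
    pvs >= 1 && pp >= 2,                       # Id
    ps >= 2,                                   # II
    ps >= 1 && pm >= 3,                        # IIIa
    ps >= 1 && pm >= 2 && pp >= 2,             # IIIb
    ps >= 1 && pm >= 1 && pp >= 4)             # IIIc
  likely_pathogenic_rules <- c(
    pvs >= 1 && pm >= 1,                       # i
    ps >= 1 && pm >= 1,                        # ii
    ps >= 1 && pp >= 2,                        # iii
    pm >= 3,                                   # iv
    pm >= 2 && pp >= 2,                        # v
    pm >= 1 && pp >= 4)                        # vi
  benign <- ba >= 1 || bs >= 2
  likely_benign <- (bs >= 1 && bp >= 1) || bp >= 2

  path_side <- any(pathogenic_rules) || any(likely_pathogenic_rules)
  benign_side <- benign || likely_benign
  if (path_side && benign_side) return(3L)  # contradictory -> VUS
  if (any(pathogenic_rules)) return(5L)
  if (any(likely_pathogenic_rules)) return(4L)
  if (benign) return(1L)
  if (likely_benign) return(2L)
  3L
}

# all strength-count combinations with at most `max_per` criteria per strength
oracle_grid <- function(max_per = 3L) {
  expand.grid(pvs = 0:max_per, ps = 0:max_per, pm = 0:max_per,
              pp = 0:max_per, ba = 0:max_per, bs = 0:max_per,
              bp = 0:max_per)
}
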