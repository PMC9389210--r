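test_that("canonical TNF profile matches brute-force counting and is strand-invariant", {
  set.seed(7)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE), collapse = "")
    asm <- genome_assembly("x", c(c1 = s))
    prof <- tetranucleotide_profile(asm)
    expect_equal(sum(prof), 1)
    expect_equal(unname(prof), unname(oracle_tnf(s)[names(prof)]), tolerance = 1e-12)
    rc_asm <- genome_assembly("y", c(c1 = rc_string(s)))
    expect_identical(unname(prof), unname(tetranucleotide_profile(rc_asm)))
  }
  # degenerate composition: poly-A puts all mass on the AAAA/TTTT bin
  polya <- genome_assembly("p", c(c1 = strrep("A", 6000)))
  pp <- tetranucleotide_profile(polya)
  expect_equal(unname(pp["AAAA"]), 1)
  expect_equal(sum(pp[names(pp) != "AAAA"]), 0)
  # too-short assembly: undefined profile, undefined correlation
  short <- genome_assembly("s", c(c1 = strrep("ACGT", 100)))
  expect_true(anyNA(tetranucleotide_profile(short)))
  expect_true(is.na(tnf_correlation(tetranucleotide_profile(short), pp)))
})

test_that("TNF correlation separates same-genome from composition-divergent pairs", {
  g <- simulate_ancestor(60000, 0.5, 31)
  cfg <- simulation_config(genome_length = 60000, n_markers = 30,
                           mean_depth = 0, seed = 32)
  s1 <- simulate_sag(g, cfg, 33, target_completeness = 0.6)$assembly
  s2 <- simulate_sag(g, cfg, 34, target_completeness = 0.6)$assembly
  p1 <- tetranucleotide_profile(s1); p2 <- tetranucleotide_profile(s2)
  expect_equal(tnf_correlation(p1, p1), 1.0)
  expect_gt(tnf_correlation(p1, p2), 0.90)
  lo_gc <- simulate_ancestor(60000, 0.30, 35)
  hi_gc <- simulate_ancestor(60000, 0.65, 36)
  expect_lt(tnf_correlation(tetranucleotide_profile(lo_gc),
                            tetranucleotide_profile(hi_gc)), 0.90)
})

test_that("fragment ANI is exact on self and calibrated on derived pairs", {
  g <- simulate_ancestor(60000, 0.5, 41)
  self <- two_way_ani(g, g)
  expect_equal(self$ani, 100.0)
  expect_equal(self$fragments_used, 2 * 60)

  b <- mutate_to_ani(g, 0.97, 42)
  truth <- 100 * hamming_identity(g, b)
  est <- two_way_ani(g, b)
  expect_lt(abs(est$ani - truth), 0.3)

  # symmetry by construction
  p <- ani_params()
  ab <- fragment_ani(g, b, p); ba <- fragment_ani(b, g, p)
  expect_equal(two_way_ani(g, b, p)$ani, (ab$ani + ba$ani) / 2)
  expect_equal(two_way_ani(b, g, p)$ani, two_way_ani(g, b, p)$ani)

  # unrelated genomes: nothing qualifies
  u <- simulate_ancestor(60000, 0.5, 43)
  expect_true(is.na(two_way_ani(g, u)$ani))
})

test_that("estimated ANI is stable under contig fragmentation of the target", {
  g <- simulate_ancestor(60000, 0.5, 44)
  b <- mutate_to_ani(g, 0.98, 45)
  base_ani <- two_way_ani(g, b)$ani
  set.seed(46)
  seq_b <- b$contigs[[1]]
  cuts <- sort(sample(2000:58000, 10))
  bounds <- c(0, cuts, nchar(seq_b))
  pieces <- substring(seq_b, bounds[-length(bounds)] + 1, bounds[-1])
  b_frag <- genome_assembly("bf", setNames(pieces, paste0("c", seq_along(pieces))))
  b_frag <- filter_contigs(b_frag)
  frag_ani_val <- two_way_ani(g, b_frag)$ani
  expect_lt(abs(frag_ani_val - base_ani), 0.2)
})

test_that("marker homology reflects per-site divergence of planted markers", {
  pl <- plant_markers(simulate_ancestor(80000, 0.5, 51), 40, 900, 0.5, 52)
  g <- pl$assembly
  self <- marker_homology(g, g, pl$markers)
  expect_equal(self$homology, 100.0)
  expect_equal(self$markers_compared, 40)

  near <- mutate_to_ani(g, 0.999, 53)
  far <- mutate_to_ani(g, 0.97, 54)
  h_near <- marker_homology(g, near, pl$markers)$homology
  h_far <- marker_homology(g, far, pl$markers)$homology
  expect_gt(h_near, 99.7)
  expect_lt(abs(h_near - 99.9), 0.15)
  expect_lt(abs(h_far - 97), 0.5)

  # insufficient shared markers -> undefined
  few <- genome_assembly("few", c(c1 = substr(g$contigs[[1]], 1, 6000)))
  expect_true(is.na(marker_homology(g, few, pl$markers)$homology))
})

test_that("similarity records are complete and symmetric in construction", {
  coh <- clustering_fixture(seed = 61, n_strains = 2, sags_per_strain = 2,
                            between_ani = 0.97, genome_length = 60000,
                            n_markers = 30, completeness = c(0.8, 1))
  asms <- cohort_assemblies(coh)
  recs <- similarity_records(asms, coh$markers)
  expect_equal(nrow(recs), choose(length(asms), 2))
  expect_true(all(recs$sag_a < recs$sag_b))
  truth <- setNames(coh$truth$strain_id, coh$truth$sag_id)
  same <- truth[recs$sag_a] == truth[recs$sag_b]
  expect_true(all(recs$ani[same] > 99))
  expect_true(all(recs$ani[!same] < 99))
  expect_true(all(recs$tnf_corr[same] > 0.9))
  expect_true(all(recs$marker_homology[same] > 99, na.rm = TRUE))
  expect_true(all(recs$marker_homology[!same] < 99, na.rm = TRUE))
})
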