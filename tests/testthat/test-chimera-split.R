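test_that("read mapping finds verbatim copies and rejects foreign reads", {
  g <- simulate_ancestor(40000, 0.5, 101)
  read <- substr(g$contigs[[1]], 5001, 5150)
  segs <- map_read(read, g)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$qstart, 0)
  expect_equal(segs$qend, 150)
  expect_equal(segs$identity, 1.0)
  expect_equal(segs$tstart, 5000)

  foreign <- substr(simulate_ancestor(10000, 0.5, 102)$contigs[[1]], 1, 150)
  expect_equal(nrow(map_read(foreign, g)), 0)
})

test_that("chimeric junctions are located within seed resolution", {
  g <- simulate_ancestor(40000, 0.5, 103)
  seq_g <- g$contigs[[1]]
  for (case in list(c(1001, 60, 20001, 90), c(8001, 75, 30001, 75))) {
    left <- substr(seq_g, case[1], case[1] + case[2] - 1)
    right <- substr(seq_g, case[3], case[3] + case[4] - 1)
    chim <- paste0(left, rc_string(right))
    segs <- map_read(chim, g)
    expect_equal(nrow(segs), 2)
    boundary <- sort(c(segs$qend[1], segs$qstart[2]))
    expect_lte(abs(segs$qend[1] - case[2]), 14)
    expect_lte(abs(segs$qstart[2] - case[2]), 14)
    expect_setequal(segs$strand, c("+", "-"))
  }
})

test_that("classification and splitting follow interval arithmetic exactly", {
  p <- split_params()
  seqc <- strrep("ACGTT", 30)  # 150 bp
  qual <- q_string(30, 150)
  seg <- function(qs, qe) data.frame(query = 1L, qstart = qs, qend = qe,
                                     contig = "c", tstart = qs, tend = qe,
                                     strand = "+", matches = qe - qs,
                                     identity = 1, stringsAsFactors = FALSE)
  # fully aligned: unsplit
  full <- classify_and_split(seqc, qual, seg(0, 150), p)
  expect_equal(full$status, "clean")
  expect_equal(full$fragments$sequence, seqc)
  # unmapped: returned whole
  um <- classify_and_split(seqc, qual, seg(0, 0)[0, ], p)
  expect_equal(um$status, "unmapped")
  expect_equal(um$fragments$sequence, seqc)
  # one 100-bp aligned segment: two fragments, both >= 20 bp
  sp <- classify_and_split(seqc, qual, seg(0, 100), p)
  expect_equal(sp$status, "split")
  expect_equal(sp$fragments$start, c(0, 100))
  expect_equal(sp$fragments$end, c(100, 150))
  expect_equal(sp$fragments$sequence,
               c(substr(seqc, 1, 100), substr(seqc, 101, 150)))
  expect_equal(nchar(sp$fragments$quality), nchar(sp$fragments$sequence))
  # trailing 10-bp fragment discarded by the 20-bp floor
  sp2 <- classify_and_split(seqc, qual, seg(0, 140), p)
  expect_equal(sp2$status, "split")
  expect_equal(nrow(sp2$fragments), 1)
  expect_equal(sp2$fragments$end, 140)
  # two overlapping segments: boundary resolved at the overlap midpoint
  two <- rbind(seg(0, 80), seg(72, 150))
  sp3 <- classify_and_split(seqc, qual, two, p)
  expect_equal(sp3$status, "split")
  expect_equal(sp3$fragments$end[1], sp3$fragments$start[2])
  expect_gte(sp3$fragments$end[1], 72)
  expect_lte(sp3$fragments$end[1], 80)
})

test_that("a chimera-free group is a fixpoint of read cleaning", {
  cfg <- simulation_config(genome_length = 40000, n_markers = 20, n_strains = 1,
                           sags_per_strain = 2, chimera_rate = 0, contam_rate = 0,
                           host_decoy_rate = 0, error_rate = 0.005,
                           target_completeness = c(0.9, 1), mean_depth = 6, seed = 111)
  coh <- simulate_cohort(cfg, n_hosts = 1)
  sags <- coh$hosts$H01$sags
  res <- clean_group_reads(names(sags), lapply(sags, `[[`, "reads"),
                           lapply(sags, function(s) filter_contigs(s$assembly)))
  expect_equal(sum(res$report$reads_split), 0)
  expect_equal(res$report$cycles, c(1L, 1L))
  in_seqs <- sort(unname(unlist(lapply(sags, function(s) s$reads$sequence))))
  expect_equal(sort(res$reads$sequence), in_seqs)
})

test_that("singleton groups pass reads through unchanged", {
  cfg <- simulation_config(genome_length = 30000, n_markers = 15, n_strains = 1,
                           sags_per_strain = 1, mean_depth = 4, seed = 115)
  coh <- simulate_cohort(cfg, n_hosts = 1)
  s <- coh$hosts$H01$sags[[1]]
  res <- clean_group_reads(names(coh$hosts$H01$sags),
                           list(H01_S01 = s$reads),
                           list(H01_S01 = filter_contigs(s$assembly)))
  expect_equal(nrow(res$reads), nrow(s$reads))
  expect_equal(res$reads$sequence, s$reads$sequence)
})

test_that("chimera cleaning meets recall and precision bounds on manifest truth", {
  for (seed in c(7, 8, 9)) {
    cfg <- simulation_config(genome_length = 50000, n_markers = 25, n_strains = 1,
                             sags_per_strain = 3, target_completeness = c(0.8, 1),
                             chimera_rate = 0.05, error_rate = 0.005,
                             contam_rate = 0, host_decoy_rate = 0,
                             mean_depth = 8, seed = seed)
    coh <- simulate_cohort(cfg, n_hosts = 1)
    sags <- coh$hosts$H01$sags
    res <- clean_group_reads(names(sags), lapply(sags, `[[`, "reads"),
                             lapply(sags, function(s) filter_contigs(s$assembly)))
    log <- merge(res$read_log, coh$manifest[, c("read_id", "is_chimeric")],
                 by = "read_id")
    expect_gte(mean(log$split[log$is_chimeric]), 0.95)
    expect_lte(mean(log$split[!log$is_chimeric]), 0.01)
    expect_gte(min(nchar(res$reads$sequence)), 20)
    expect_equal(sum(res$report$bases_in),
                 sum(res$report$bases_out) + sum(res$report$bases_discarded))
    expect_lte(max(res$report$cycles), 5)
    # fixpoint stability: cleaning the cleaned pool changes nothing
    by_src <- split(seq_len(nrow(res$reads)), res$reads$source_sag)
    readsets2 <- lapply(by_src, function(ix)
      read_set(res$reads$read_id[ix], res$reads$sequence[ix],
               res$reads$quality[ix], sag_id = res$reads$source_sag[ix[1]]))
    res2 <- clean_group_reads(names(sags), readsets2,
                              lapply(sags, function(s) filter_contigs(s$assembly)))
    expect_equal(sum(res2$report$reads_split), 0)
    expect_equal(sort(res2$reads$sequence), sort(res$reads$sequence))
  }
})
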