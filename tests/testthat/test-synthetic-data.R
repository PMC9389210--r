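test_that("ancestor simulation honors length, composition and determinism", {
  a <- simulate_ancestor(100000, 0.5, 1)
  expect_equal(nchar(a$contigs[[1]]), 100000)
  expect_false(grepl("[^ACGT]", a$contigs[[1]]))
  gc <- assembly_stats(a)$gc
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.5 * 0.5 / 100000))

  b1 <- simulate_ancestor(100000, 0.40, 7)
  b2 <- simulate_ancestor(100000, 0.40, 7)
  expect_identical(b1$contigs, b2$contigs)
  gc40 <- assembly_stats(b1)$gc
  expect_lt(abs(gc40 - 0.40), 3 * sqrt(0.4 * 0.6 / 100000))

  expect_error(simulate_ancestor(5000, 0.5, 1), "10,000")
  expect_error(simulate_ancestor(100000, 1.5, 1), "gc")
})

test_that("mutation to a target identity is calibrated and seed-stable", {
  a <- simulate_ancestor(100000, 0.5, 2)
  expect_identical(mutate_to_ani(a, 1.0, 5)$contigs, a$contigs)

  b <- mutate_to_ani(a, 0.97, 5)
  id <- hamming_identity(a, b)
  expect_lt(abs(id - 0.97), 3 * sqrt(0.03 * 0.97 / 100000))
  expect_identical(b$contigs, mutate_to_ani(a, 0.97, 5)$contigs)
  expect_error(mutate_to_ani(a, 0.85, 1), "target_identity")
})

test_that("derived identity bands are separable by the estimated ANI", {
  a <- simulate_ancestor(60000, 0.5, 3)
  near <- mutate_to_ani(a, 0.999, 4)
  far <- mutate_to_ani(a, 0.97, 5)
  ani_near <- two_way_ani(a, near)$ani
  ani_far <- two_way_ani(a, far)$ani
  expect_gt(ani_near, 99.5)
  expect_lt(ani_far, 98)
})

test_that("a noise-free SAG reproduces its strain genome and maps back", {
  cfg <- simulation_config(genome_length = 40000, n_markers = 20,
                           target_completeness = 1, chimera_rate = 0,
                           contam_rate = 0, host_decoy_rate = 0,
                           error_rate = 0, mean_depth = 5, seed = 9)
  strain <- plant_markers(simulate_ancestor(40000, 0.5, 9), 20, 900, 0.5, 10)$assembly
  sim <- simulate_sag(strain, cfg, 11, sag_id = "s1", target_completeness = 1)
  expect_equal(paste(sim$assembly$contigs, collapse = ""), strain$contigs[[1]])
  expect_equal(sim$true_completeness, 1)
  genome <- strain$contigs[[1]]
  extracted <- substring(genome, sim$manifest$origin_start + 1L, sim$manifest$origin_end)
  expect_identical(unname(extracted), sim$reads$sequence)
})

test_that("truth manifest is consistent with the emitted reads", {
  cfg <- simulation_config(genome_length = 40000, n_markers = 20,
                           chimera_rate = 0.05, contam_rate = 0.02,
                           host_decoy_rate = 0.02, mean_depth = 8, seed = 13)
  strain <- simulate_ancestor(40000, 0.5, 13)
  contaminant <- simulate_ancestor(20000, 0.6, 14)
  decoy <- simulate_ancestor(20000, 0.41, 15)
  sim <- simulate_sag(strain, cfg, 16, sag_id = "s1", target_completeness = 0.8,
                      contaminant = contaminant, decoy = decoy)
  expect_false(anyDuplicated(sim$manifest$read_id) > 0)
  expect_setequal(sim$manifest$read_id, sim$reads$read_id)
  expect_true(all(!is.na(sim$manifest$junction_pos[sim$manifest$is_chimeric])))
  expect_true(all(is.na(sim$manifest$junction_pos[!sim$manifest$is_chimeric])))
  expect_false(any(sim$manifest$is_host & sim$manifest$is_contaminant))
})

test_that("chimera counts follow the configured binomial rate", {
  cfg <- simulation_config(genome_length = 100000, n_markers = 40,
                           chimera_rate = 0.05, contam_rate = 0,
                           host_decoy_rate = 0, mean_depth = 15, seed = 17)
  strain <- simulate_ancestor(100000, 0.5, 17)
  sim <- simulate_sag(strain, cfg, 18, target_completeness = 1)
  n <- nrow(sim$manifest)
  expect_gt(n, 5000)
  k <- sum(sim$manifest$is_chimeric)
  expect_lt(abs(k - 0.05 * n), 3 * sqrt(n * 0.05 * 0.95))
})

test_that("coverage dispersion grows with the lognormal sigma", {
  strain <- simulate_ancestor(200000, 0.5, 19)
  disp <- vapply(c(0.2, 0.8, 1.5), function(sg) {
    cfg <- simulation_config(genome_length = 200000, n_markers = 40,
                             lognormal_sigma = sg, chimera_rate = 0,
                             contam_rate = 0, host_decoy_rate = 0,
                             target_completeness = 1, mean_depth = 15, seed = 19)
    mean(vapply(1:5, function(r) {
      sim <- simulate_sag(strain, cfg, 23 + r, target_completeness = 1)
      win <- sim$manifest$origin_start %/% cfg$dropout_window
      counts <- tabulate(win + 1L, nbins = 40)
      stats::var(counts) / mean(counts)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(disp) > 0))
})

test_that("simulation output is byte-identical across reruns", {
  cfg <- simulation_config(genome_length = 30000, n_markers = 15, n_strains = 2,
                           sags_per_strain = 2, mean_depth = 4, seed = 31)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_simulation(simulate_cohort(cfg, n_hosts = 1), d1)
  write_simulation(simulate_cohort(cfg, n_hosts = 1), d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  m1 <- tools::md5sum(file.path(d1, f1)); m2 <- tools::md5sum(file.path(d2, f2))
  expect_identical(unname(m1), unname(m2))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("simulated strain pairs at 97% reproduce the target ANI on average", {
  anis <- vapply(1:10, function(i) {
    a <- simulate_ancestor(100000, 0.5, 100 + i)
    b <- mutate_to_ani(a, 0.97, 200 + i)
    two_way_ani(a, b)$ani
  }, numeric(1))
  expect_lt(abs(mean(anis) - 97.0), 0.3)
})
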