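fake_records <- function(pairs) {
  do.call(rbind, lapply(pairs, function(p)
    data.frame(sag_a = p[[1]], sag_b = p[[2]], ani = p[[3]],
               ani_fragments_used = 10L, tnf_corr = p[[4]],
               marker_homology = p[[5]], markers_compared = 20L,
               stringsAsFactors = FALSE)))
}

fake_quality <- function(ids, completeness = 90, contamination = 1) {
  data.frame(sag_id = ids, completeness = completeness,
             contamination = contamination,
             total_bp = seq(100000, by = 1000, length.out = length(ids)),
             host_id = "H1", stringsAsFactors = FALSE)
}

test_that("grouping uses connected components over the three-way threshold graph", {
  # chain: A-B pass, B-C pass, A-C fail -> one group {A,B,C}
  recs <- fake_records(list(
    list("A", "B", 99.5, 0.99, 99.95), list("B", "C", 99.4, 0.99, 99.96),
    list("A", "C", 98.5, 0.99, 99.95)))
  g <- build_strain_groups(recs, fake_quality(c("A", "B", "C")))
  expect_equal(length(unique(g$group_id)), 1)
  expect_setequal(g$sag_id, c("A", "B", "C"))

  # nothing passes ANI -> all singletons
  recs2 <- fake_records(list(
    list("A", "B", 98.5, 0.99, 99.95), list("B", "C", 98.5, 0.99, 99.95),
    list("A", "C", 98.5, 0.99, 99.95)))
  g2 <- build_strain_groups(recs2, fake_quality(c("A", "B", "C")))
  expect_equal(length(unique(g2$group_id)), 3)

  # an edge requires ALL three criteria strictly
  recs3 <- fake_records(list(list("A", "B", 99.5, 0.89, 99.95)))
  g3 <- build_strain_groups(recs3, fake_quality(c("A", "B")))
  expect_equal(length(unique(g3$group_id)), 2)
  recs4 <- fake_records(list(list("A", "B", 99.5, 0.95, 99.9)))
  g4 <- build_strain_groups(recs4, fake_quality(c("A", "B")))
  expect_equal(length(unique(g4$group_id)), 2)  # 99.9 not > 99.9
})

test_that("groups partition the selected SAGs and respect selection", {
  q <- fake_quality(c("A", "B", "C", "D"))
  q$completeness[q$sag_id == "D"] <- 15  # below the 20% selection floor
  recs <- fake_records(list(
    list("A", "B", 99.5, 0.99, 99.95), list("A", "C", 98, 0.99, 99.95),
    list("B", "C", 98, 0.99, 99.95), list("A", "D", 99.9, 0.99, 99.99),
    list("B", "D", 98, 0.99, 99.95), list("C", "D", 98, 0.99, 99.95)))
  g <- build_strain_groups(recs, q)
  expect_setequal(g$sag_id, c("A", "B", "C"))
  expect_equal(anyDuplicated(g$sag_id), 0)
  expect_equal(sum(table(g$group_id)), 3)
  expect_equal(sum(g$is_representative), length(unique(g$group_id)))
})

test_that("raising any threshold only refines the partition", {
  set.seed(71)
  ids <- sprintf("S%02d", 1:8)
  pairs <- t(combn(ids, 2))
  recs <- data.frame(sag_a = pairs[, 1], sag_b = pairs[, 2],
                     ani = runif(nrow(pairs), 98.5, 100),
                     ani_fragments_used = 10L,
                     tnf_corr = runif(nrow(pairs), 0.85, 1),
                     marker_homology = runif(nrow(pairs), 98.5, 100),
                     markers_compared = 20L, stringsAsFactors = FALSE)
  q <- fake_quality(ids)
  loose <- build_strain_groups(recs, q, strain_grouping_params(99, 0.90, 99.0))
  for (p in list(strain_grouping_params(99.5, 0.90, 99.0),
                 strain_grouping_params(99, 0.95, 99.0),
                 strain_grouping_params(99, 0.90, 99.5))) {
    strict <- build_strain_groups(recs, q, p)
    loose_of <- setNames(loose$group_id, loose$sag_id)
    # every strict group is contained in one loose group
    for (gid in unique(strict$group_id)) {
      mem <- strict$sag_id[strict$group_id == gid]
      expect_equal(length(unique(loose_of[mem])), 1)
    }
  }
})

test_that("grouping recovers the simulated strain partition", {
  coh <- clustering_fixture(seed = 81, n_strains = 3, sags_per_strain = 3,
                            between_ani = 0.97, completeness = c(0.6, 1))
  part <- inferred_partition(coh, marker_threshold = 99.0)
  truth <- setNames(coh$truth$strain_id, coh$truth$sag_id)
  expect_equal(adjusted_rand(part[names(truth)], truth), 1.0)
})

test_that("cross-host grouping links exactly the shared strain", {
  coh <- clustering_fixture(seed = 83, n_strains = 2, sags_per_strain = 3,
                            between_ani = 0.97, completeness = c(0.7, 1),
                            n_hosts = 2, shared_strains = 1)
  truth <- setNames(coh$truth$strain_id, coh$truth$sag_id)
  hosts <- setNames(coh$truth$host_id, coh$truth$sag_id)
  # per-host: no group spans hosts
  part_ph <- inferred_partition(coh, marker_threshold = 99.0)
  for (gid in unique(part_ph))
    expect_equal(length(unique(hosts[names(part_ph)[part_ph == gid]])), 1)
  # cross-host: exactly the shared strain's SAGs form the spanning group
  part_ch <- inferred_partition(coh, marker_threshold = 99.0, cross_host = TRUE)
  spanning <- unique(part_ch)[vapply(unique(part_ch), function(gid)
    length(unique(hosts[names(part_ch)[part_ch == gid]])) > 1, logical(1))]
  expect_equal(length(spanning), 1)
  expect_setequal(names(part_ch)[part_ch == spanning],
                  names(truth)[truth == "strain01"])
})

test_that("dereplication keeps the best-scoring genome per ANI cluster", {
  g <- simulate_ancestor(20000, 0.5, 91)
  twin <- g; twin$sag_id <- "twin"
  other <- simulate_ancestor(20000, 0.5, 92)
  asms <- list(a = g, b = twin, c = other)
  q <- data.frame(sag_id = c("a", "b", "c"),
                  completeness = c(95, 80, 70), contamination = c(1, 1, 1),
                  stringsAsFactors = FALSE)
  out <- dereplicate(asms, q)
  expect_true(out$kept[out$sag_id == "a"])
  expect_false(out$kept[out$sag_id == "b"])
  expect_true(out$kept[out$sag_id == "c"])  # unrelated: own cluster
  expect_equal(out$cluster_id[out$sag_id == "a"], out$cluster_id[out$sag_id == "b"])

  # the two-term score dominates raw completeness
  q2 <- data.frame(sag_id = c("a", "b"),
                   completeness = c(90, 92), contamination = c(4, 8),
                   stringsAsFactors = FALSE)
  out2 <- dereplicate(list(a = g, b = twin), q2)
  expect_equal(out2$score, c(70, 52))
  expect_true(out2$kept[out2$sag_id == "a"])

  # genomes below the ANI threshold both survive
  near <- mutate_to_ani(g, 0.98, 93)
  out3 <- dereplicate(list(a = g, b = near),
                      data.frame(sag_id = c("a", "b"), completeness = c(90, 50),
                                 contamination = c(0, 0), stringsAsFactors = FALSE))
  expect_true(all(out3$kept))
})
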