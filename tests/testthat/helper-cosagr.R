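# shared fixture builders and independent oracles

q_string <- function(q, n) strrep(intToUtf8(q + 33L), n)

rc_string <- function(x) {
  vapply(strsplit(chartr("ACGTN", "TGCAN", x), ""), function(ch)
    paste(rev(ch), collapse = ""), character(1))
}

# brute-force canonical tetranucleotide counting, independent of the package
oracle_tnf_levels <- local({
  bases <- c("A", "C", "G", "T")
  kmers <- apply(expand.grid(bases, bases, bases, bases,
                             stringsAsFactors = FALSE), 1, function(r)
    paste(r, collapse = ""))
  canon <- pmin(kmers, rc_string(kmers))
  list(map = setNames(canon, kmers), levels = sort(unique(canon)))
})

oracle_tnf <- function(seqs) {
  cnt <- setNames(numeric(length(oracle_tnf_levels$levels)), oracle_tnf_levels$levels)
  for (s in seqs) {
    L <- nchar(s)
    if (L < 4) next
    for (i in seq_len(L - 3)) {
      km <- substr(s, i, i + 3)
      if (grepl("[^ACGT]", km)) next
      cnt[oracle_tnf_levels$map[km]] <- cnt[oracle_tnf_levels$map[km]] + 1
    }
  }
  cnt / sum(cnt)
}

# enumeration oracle for the right-end quality trim: try every cut point,
# maximize sum(trimq - Q) over the removed suffix, trim least on ties
oracle_trim_keep <- function(q, trimq) {
  L <- length(q)
  objs <- vapply(0:L, function(keep)
    if (keep == L) 0 else sum(trimq - q[(keep + 1):L]), numeric(1))
  max(which(objs == max(objs))) - 1L
}

# Hamming identity between two equal-length single-contig genomes
hamming_identity <- function(a, b) {
  sa <- strsplit(a$contigs[[1]], "")[[1]]
  sb <- strsplit(b$contigs[[1]], "")[[1]]
  mean(sa == sb)
}

# small assembly-only cohort for clustering fixtures
clustering_fixture <- function(seed, n_strains, sags_per_strain, between_ani,
                               genome_length = 80000, n_markers = 40,
                               completeness = c(0.5, 1), n_hosts = 1,
                               shared_strains = 0) {
  cfg <- simulation_config(genome_length = genome_length, n_markers = n_markers,
                           n_strains = n_strains, sags_per_strain = sags_per_strain,
                           between_strain_ani = between_ani,
                           target_completeness = completeness,
                           mean_depth = 0, seed = seed)
  simulate_cohort(cfg, n_hosts = n_hosts, shared_strains = shared_strains)
}

cohort_assemblies <- function(cohort) {
  out <- list()
  for (h in cohort$hosts)
    for (sid in names(h$sags))
      out[[sid]] <- filter_contigs(h$sags[[sid]]$assembly)
  out
}

cohort_quality <- function(cohort) {
  asms <- list()
  for (h in cohort$hosts)
    for (sid in names(h$sags)) asms[[sid]] <- h$sags[[sid]]$assembly
  qt <- quality_table(asms, cohort$markers)
  qt$host_id <- cohort$truth$host_id[match(qt$sag_id, cohort$truth$sag_id)]
  qt
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# partition recovered by the pipeline, as a named vector sag_id -> group_id
inferred_partition <- function(cohort, marker_threshold = 99.0, cross_host = FALSE) {
  asms <- cohort_assemblies(cohort)
  recs <- similarity_records(asms, cohort$markers)
  qt <- cohort_quality(cohort)
  g <- build_strain_groups(recs, qt,
                           strain_grouping_params(marker_threshold = marker_threshold),
                           cross_host = cross_host)
  setNames(g$group_id, g$sag_id)
}
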