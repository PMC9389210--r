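#' Strain-grouping thresholds
#'
#' A pair of SAGs is same-strain when it strictly exceeds all three
#' thresholds: two-way ANI, tetranucleotide-frequency correlation, and
#' single-copy marker homology. The marker default of 99.9 follows the
#' operative strain-clustering rule; 99.0 is the common looser variant and
#' is reachable here by configuration.
#'
#' @param ani_threshold Percent (default 99.0).
#' @param tnf_threshold Correlation (default 0.90).
#' @param marker_threshold Percent (default 99.9).
#' @return A list of class `strain_grouping_params`.
#' @export
strain_grouping_params <- function(ani_threshold = 99.0, tnf_threshold = 0.90,
                                   marker_threshold = 99.9) {
  if (ani_threshold < 0 || ani_threshold > 100) stop("ani_threshold out of range")
  if (tnf_threshold < -1 || tnf_threshold > 1) stop("tnf_threshold out of range")
  if (marker_threshold < 0 || marker_threshold > 100) stop("marker_threshold out of range")
  structure(list(ani_threshold = ani_threshold, tnf_threshold = tnf_threshold,
                 marker_threshold = marker_threshold),
            class = "strain_grouping_params")
}

derep_score <- function(completeness, contamination) completeness - 5 * contamination

#' Group SAGs into same-strain clusters
#'
#' Builds a graph with an edge for every pair strictly exceeding all three
#' thresholds (undefined similarities count as below threshold) and returns
#' its connected components as strain groups; singletons are groups of one.
#' Grouping is restricted to SAGs passing [select_for_grouping()] and, by
#' default, to pairs from the same host.
#'
#' @param records Data frame from [similarity_records()].
#' @param qualities Data frame from [quality_table()] (needs sag_id,
#'   completeness, contamination, total_bp; host_id optional).
#' @param p A [strain_grouping_params()].
#' @param hosts Optional named character vector sag_id -> host_id.
#' @param cross_host Allow edges across hosts (default `FALSE`).
#' @return Data frame: group_id, host_id, sag_id, is_representative. Groups
#'   are ordered lexicographically by their smallest member id; the
#'   representative maximizes `completeness - 5 * contamination` (ties:
#'   larger assembly, then lexicographic id).
#' @export
build_strain_groups <- function(records, qualities, p = strain_grouping_params(),
                                hosts = NULL, cross_host = FALSE) {
  sel <- qualities[select_for_grouping(qualities$completeness, qualities$contamination), ,
                   drop = FALSE]
  ids <- sort(sel$sag_id)
  if (is.null(hosts)) {
    hosts <- if ("host_id" %in% names(qualities))
      setNames(qualities$host_id, qualities$sag_id)
    else setNames(rep("all", nrow(qualities)), qualities$sag_id)
  }
  if (length(ids) == 0) {
    return(data.frame(group_id = character(0), host_id = character(0),
                      sag_id = character(0), is_representative = logical(0),
                      stringsAsFactors = FALSE))
  }
  rec <- records[records$sag_a %in% ids & records$sag_b %in% ids, , drop = FALSE]
  n_expected <- choose(length(ids), 2)
  have <- if (!cross_host) {
    same <- hosts[rec$sag_a] == hosts[rec$sag_b]
    n_same_expected <- sum(vapply(split(ids, hosts[ids]), function(x)
      choose(length(x), 2), numeric(1)))
    if (sum(same) < n_same_expected)
      warning("missing pair records among selected SAGs; treating as no-edge")
    rec
  } else {
    if (nrow(rec) < n_expected)
      warning("missing pair records among selected SAGs; treating as no-edge")
    rec
  }
  pass <- !is.na(have$ani) & have$ani > p$ani_threshold &
    !is.na(have$tnf_corr) & have$tnf_corr > p$tnf_threshold &
    !is.na(have$marker_homology) & have$marker_homology > p$marker_threshold
  if (!cross_host) pass <- pass & hosts[have$sag_a] == hosts[have$sag_b]
  edges <- have[pass, c("sag_a", "sag_b"), drop = FALSE]

  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(ids)
  if (nrow(edges) > 0)
    g <- igraph::add_edges(g, rbind(match(edges$sag_a, ids), match(edges$sag_b, ids)))
  comp <- igraph::components(g)$membership
  members <- split(ids, comp)
  members <- members[order(vapply(members, min, character(1)))]

  out <- list()
  for (gi in seq_along(members)) {
    mem <- sort(members[[gi]])
    q <- sel[match(mem, sel$sag_id), , drop = FALSE]
    score <- derep_score(q$completeness, q$contamination)
    size <- if ("total_bp" %in% names(q)) q$total_bp else rep(0, length(mem))
    ord <- order(-score, -size, mem)
    rep_id <- mem[ord[1]]
    host_id <- paste(sort(unique(hosts[mem])), collapse = "+")
    out[[gi]] <- data.frame(group_id = sprintf("g%03d", gi), host_id = host_id,
                            sag_id = mem, is_representative = mem == rep_id,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Dereplicate assemblies at an ANI threshold
#'
#' Clusters genomes whose two-way ANI strictly exceeds `ani_threshold`
#' (connected components) and keeps, per cluster, the genome maximizing
#' `completeness - 5 * contamination`; ties broken by larger total assembly
#' length, then lexicographic id.
#'
#' @param assemblies Named list of contig-filtered `genome_assembly`.
#' @param qualities Data frame with sag_id, completeness, contamination.
#' @param ani_threshold Percent (default 99.0).
#' @param p An [ani_params()].
#' @param records Optional precomputed [similarity_records()] (must cover
#'   all pairs); when given, ANI is not recomputed.
#' @return Data frame: cluster_id, sag_id, score, kept.
#' @export
dereplicate <- function(assemblies, qualities, ani_threshold = 99.0,
                        p = ani_params(), records = NULL) {
  ids <- sort(names(assemblies))
  if (any(!ids %in% qualities$sag_id))
    stop("qualities must cover all assemblies")
  edges <- matrix(integer(0), nrow = 2)
  if (length(ids) > 1) {
    if (is.null(records)) {
      idxs <- lapply(assemblies[ids], assembly_index)
      for (i in seq_along(ids)[-length(ids)]) {
        for (j in seq(i + 1, length(ids))) {
          ab <- frag_ani_with_index(assemblies[[ids[i]]], idxs[[ids[j]]], p)
          ba <- frag_ani_with_index(assemblies[[ids[j]]], idxs[[ids[i]]], p)
          ani <- if (is.na(ab$ani) || is.na(ba$ani)) NA_real_ else (ab$ani + ba$ani) / 2
          if (!is.na(ani) && ani > ani_threshold)
            edges <- cbind(edges, c(i, j))
        }
      }
    } else {
      rec <- records[records$sag_a %in% ids & records$sag_b %in% ids, , drop = FALSE]
      pass <- !is.na(rec$ani) & rec$ani > ani_threshold
      edges <- rbind(match(rec$sag_a[pass], ids), match(rec$sag_b[pass], ids))
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(ids)
  if (ncol(edges) > 0) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  q <- qualities[match(ids, qualities$sag_id), , drop = FALSE]
  score <- derep_score(q$completeness, q$contamination)
  size <- vapply(assemblies[ids], function(a) sum(nchar(a$contigs)), numeric(1))
  rows <- list()
  members <- split(seq_along(ids), comp)
  members <- members[order(vapply(members, function(ix) min(ids[ix]), character(1)))]
  for (ci in seq_along(members)) {
    ix <- members[[ci]]
    ord <- ix[order(-score[ix], -size[ix], ids[ix])]
    rows[[ci]] <- data.frame(cluster_id = sprintf("c%03d", ci), sag_id = ids[ix],
                             score = score[ix], kept = ids[ix] == ids[ord[1]],
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
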