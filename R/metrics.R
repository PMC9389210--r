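#' Locate single-copy markers in an assembly
#'
#' A marker counts as found when it has a local alignment to the assembly
#' with identity >= `min_identity` over >= `min_coverage` of the marker
#' length; each extra disjoint qualifying hit (disjoint on the assembly)
#' counts as a duplication.
#'
#' @param asm A [genome_assembly()].
#' @param markers Named character vector of marker sequences.
#' @param min_identity Identity floor (default 0.90).
#' @param min_coverage Marker-length coverage floor (default 0.80).
#' @return Data frame with one row per qualifying hit: `marker`, `contig`,
#'   `tstart`, `tend`, `qstart`, `qend`, `strand`, `identity`.
#' @export
find_markers <- function(asm, markers, min_identity = 0.90, min_coverage = 0.80) {
  if (length(markers) == 0) stop("marker set must be non-empty")
  if (length(asm$contigs) == 0) stop("assembly must be non-empty")
  idx <- assembly_index(asm)
  segs <- cpp_map_batch(unname(markers), idx,
                        min_identity = min_identity, min_seg_len = 15L,
                        xdrop = 20L, max_diag_gap = 3L, max_seed_gap = 300L,
                        max_overlap = 14L, nonoverlap_on_target = TRUE,
                        max_segments = 8L, seed_step = 2L)
  if (nrow(segs) == 0) return(empty_marker_hits())
  mlen <- nchar(markers)[segs$query]
  keep <- (segs$qend - segs$qstart) >= min_coverage * mlen
  segs <- segs[keep, , drop = FALSE]
  if (nrow(segs) == 0) return(empty_marker_hits())
  data.frame(marker = names(markers)[segs$query], contig = segs$contig,
             tstart = segs$tstart, tend = segs$tend,
             qstart = segs$qstart, qend = segs$qend,
             strand = segs$strand, identity = segs$identity,
             stringsAsFactors = FALSE)
}

empty_marker_hits <- function() {
  data.frame(marker = character(0), contig = character(0), tstart = integer(0),
              tend = integer(0), qstart = integer(0), qend = integer(0),
              strand = character(0), identity = numeric(0), stringsAsFactors = FALSE)
}

#' Marker-based genome quality estimate
#'
#' Completeness is the percentage of markers found; contamination is the
#' percentage of expected markers with extra (duplicated) qualifying hits —
#' the fraction-found / fraction-duplicated semantics that single-copy
#' marker quality tiers depend on.
#'
#' @param asm A [genome_assembly()] (apply [filter_contigs()] first).
#' @param markers Named character vector of marker sequences.
#' @param min_identity,min_coverage Hit qualification thresholds, see
#'   [find_markers()].
#' @return A list of class `genome_quality`: `sag_id`, `completeness`,
#'   `contamination` (percent), `tier`, `markers_found`,
#'   `markers_duplicated`, `markers_expected`.
#' @export
estimate_quality <- function(asm, markers, min_identity = 0.90, min_coverage = 0.80) {
  hits <- find_markers(asm, markers, min_identity, min_coverage)
  per <- table(factor(hits$marker, levels = names(markers)))
  found <- sum(per >= 1)
  dup <- sum(pmax(0L, as.integer(per) - 1L))
  completeness <- 100 * found / length(markers)
  contamination <- 100 * dup / length(markers)
  structure(list(sag_id = asm$sag_id, completeness = completeness,
                 contamination = contamination,
                 tier = assign_tier(completeness, contamination),
                 markers_found = found, markers_duplicated = dup,
                 markers_expected = length(markers)),
            class = "genome_quality")
}

#' @export
print.genome_quality <- function(x, ...) {
  cat(sprintf("<genome_quality> %s: completeness %.1f%%, contamination %.1f%% [%s]\n",
              x$sag_id, x$completeness, x$contamination, x$tier))
  invisible(x)
}

#' Assign a genome quality tier
#'
#' Tiers follow the printed single-copy-marker definitions: HQ requires
#' completeness > 90 and contamination < 5; MQ completeness >= 50 and
#' contamination < 10; LQ completeness < 50 and contamination < 10;
#' anything with contamination >= 10 is excluded. Total over
#' `[0,100] x [0,100]` and vectorized.
#'
#' @param completeness,contamination Percentages in `[0,100]`.
#' @return Character vector over `{"HQ","MQ","LQ","excluded"}`.
#' @export
assign_tier <- function(completeness, contamination) {
  ifelse(completeness > 90 & contamination < 5, "HQ",
    ifelse(completeness >= 50 & contamination < 10, "MQ",
      ifelse(completeness < 50 & contamination < 10, "LQ", "excluded")))
}

#' Is a SAG eligible for strain grouping?
#'
#' Eligibility requires completeness >= 20 percent and contamination < 10
#' percent.
#'
#' @param completeness,contamination Percentages, or a `genome_quality` as
#'   first argument.
#' @return Logical vector.
#' @export
select_for_grouping <- function(completeness, contamination = NULL) {
  if (inherits(completeness, "genome_quality")) {
    contamination <- completeness$contamination
    completeness <- completeness$completeness
  }
  completeness >= 20 & contamination < 10
}

#' Quality table for a set of assemblies
#'
#' @param assemblies Named list of `genome_assembly` (names = sag ids).
#' @param markers Marker sequences.
#' @param min_contig_len Contig filter applied before estimation.
#' @return Data frame: sag_id, completeness, contamination, tier,
#'   markers_found, markers_duplicated, markers_expected, n_contigs,
#'   total_bp, n50, gc, selected.
#' @export
quality_table <- function(assemblies, markers, min_contig_len = 1000) {
  rows <- lapply(names(assemblies), function(id) {
    asm <- filter_contigs(assemblies[[id]], min_contig_len)
    st <- assembly_stats(asm)
    if (st$n_contigs == 0) {
      return(data.frame(sag_id = id, completeness = 0, contamination = 0,
                        tier = "LQ", markers_found = 0L, markers_duplicated = 0L,
                        markers_expected = length(markers), n_contigs = 0L,
                        total_bp = 0L, n50 = 0L, gc = NA_real_, selected = FALSE,
                        stringsAsFactors = FALSE))
    }
    q <- estimate_quality(asm, markers)
    data.frame(sag_id = id, completeness = q$completeness,
               contamination = q$contamination, tier = q$tier,
               markers_found = q$markers_found,
               markers_duplicated = q$markers_duplicated,
               markers_expected = q$markers_expected,
               n_contigs = st$n_contigs, total_bp = st$total_bp,
               n50 = st$n50, gc = st$gc,
               selected = select_for_grouping(q$completeness, q$contamination),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
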