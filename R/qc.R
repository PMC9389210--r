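#' Read QC parameters
#'
#' Defaults reproduce the standard BBDuk-style bounds for single-cell read
#' QC: right-end quality trimming at Q10, minimum length 40 bp, at most one
#' N, minimum mean quality Q15, and host-decoy removal at 95% identity.
#'
#' @param trim_quality Phred threshold for right-end trimming.
#' @param min_length Minimum read length after trimming (bp).
#' @param max_ns Maximum number of N bases.
#' @param min_avg_quality Minimum mean Phred quality.
#' @param decoy_min_identity Minimum alignment identity for host removal.
#' @param decoy_min_coverage Minimum fraction of the read aligned to the
#'   decoy for host removal.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(trim_quality = 10, min_length = 40, max_ns = 1,
                      min_avg_quality = 15, decoy_min_identity = 0.95,
                      decoy_min_coverage = 0.60) {
  if (any(c(trim_quality, min_length, max_ns, min_avg_quality) < 0))
    stop("qc parameters must be non-negative")
  if (decoy_min_identity < 0 || decoy_min_identity > 1)
    stop("decoy_min_identity must be in [0,1]")
  structure(list(trim_quality = trim_quality, min_length = min_length,
                 max_ns = max_ns, min_avg_quality = min_avg_quality,
                 decoy_min_identity = decoy_min_identity,
                 decoy_min_coverage = decoy_min_coverage),
            class = "qc_params")
}

# Number of bases to keep for one quality vector: remove the suffix
# maximizing sum(trimq - Q) over the removed bases (classic Phred-style
# trimming objective); ties resolved toward trimming least.
trim_keep_length <- function(q, trimq) {
  L <- length(q)
  if (L == 0) return(0L)
  # suffix_score[i] = sum over bases i..L of (trimq - Q)
  suffix <- rev(cumsum(rev(trimq - q)))
  best <- max(suffix)
  if (best <= 0) return(L)
  # keep bases before the best cut; latest argmax = least trimmed on ties
  max(which(suffix == best)) - 1L
}

#' Right-end quality trimming
#'
#' Trims each read's 3' end at the cut point maximizing the Phred-style
#' trimming objective `sum(trim_quality - Q)` over the removed suffix.
#' Bases before the cut are untouched; a read entirely below the threshold
#' becomes empty (and is then removed by the length filter).
#'
#' @param rs A [read_set()].
#' @param trim_quality Phred threshold (default 10).
#' @return The trimmed `read_set`.
#' @export
quality_trim_right <- function(rs, trim_quality = 10) {
  if (nrow(rs) == 0) return(rs)
  qs <- phred_to_int(rs$quality)
  keep <- vapply(qs, trim_keep_length, integer(1), trimq = trim_quality)
  out <- rs
  out$sequence <- substr(rs$sequence, 1L, keep)
  out$quality <- substr(rs$quality, 1L, keep)
  out
}

#' Length / N-count / mean-quality read filter
#'
#' Keeps exactly the reads with length >= `min_length`, at most `max_ns`
#' N bases, and mean Phred quality >= `min_avg_quality`; order preserved.
#' For paired reads (mate `"1"`/`"2"` with a shared id stem), both mates are
#' dropped if either fails, keeping the pool assembler-ready.
#'
#' @param rs A [read_set()].
#' @param p A [qc_params()].
#' @return The filtered `read_set`.
#' @export
filter_reads <- function(rs, p = qc_params()) {
  if (nrow(rs) == 0) return(rs)
  len <- nchar(rs$sequence)
  ns <- nchar(rs$sequence) - nchar(gsub("N", "", rs$sequence, fixed = TRUE))
  meanq <- vapply(phred_to_int(rs$quality), function(q)
    if (length(q) == 0) 0 else mean(q), numeric(1))
  ok <- len >= p$min_length & ns <= p$max_ns & meanq >= p$min_avg_quality
  paired <- rs$mate %in% c("1", "2")
  if (any(paired)) {
    stem <- sub("/[12]$", "", rs$read_id)
    bad_stems <- unique(stem[paired & !ok])
    ok[paired & stem %in% bad_stems] <- FALSE
  }
  out <- rs[ok, , drop = FALSE]
  attr(out, "sag_id") <- attr(rs, "sag_id")
  class(out) <- class(rs)
  out
}

#' Remove host-derived reads by decoy mapping
#'
#' Reads whose best local alignment to the decoy genome covers at least
#' `decoy_min_coverage` of the read at identity >= `decoy_min_identity`
#' are removed; all other reads are retained.
#'
#' @param rs A [read_set()].
#' @param decoy A non-empty [genome_assembly()] (the host decoy).
#' @param p A [qc_params()].
#' @return The `read_set` with host reads removed; the removed ids are in
#'   attribute `"host_read_ids"`.
#' @export
remove_host_reads <- function(rs, decoy, p = qc_params()) {
  if (is.null(decoy) || length(decoy$contigs) == 0)
    stop("decoy genome must be non-empty")
  if (nrow(rs) == 0) return(rs)
  idx <- assembly_index(decoy)
  segs <- cpp_map_batch(rs$sequence, idx,
                        min_identity = p$decoy_min_identity, min_seg_len = 15L,
                        xdrop = 20L, max_diag_gap = 3L, max_seed_gap = 300L,
                        max_overlap = 14L, nonoverlap_on_target = FALSE,
                        max_segments = 4L, seed_step = 2L)
  host <- rep(FALSE, nrow(rs))
  if (nrow(segs) > 0) {
    cov <- (segs$qend - segs$qstart) / nchar(rs$sequence)[segs$query]
    flag <- segs$identity >= p$decoy_min_identity & cov >= p$decoy_min_coverage
    host[unique(segs$query[flag])] <- TRUE
  }
  out <- rs[!host, , drop = FALSE]
  attr(out, "sag_id") <- attr(rs, "sag_id")
  attr(out, "host_read_ids") <- rs$read_id[host]
  class(out) <- class(rs)
  out
}

#' Full read QC: trim, filter, and host removal
#'
#' @param rs A [read_set()].
#' @param p A [qc_params()].
#' @param decoy Optional host decoy `genome_assembly`; when `NULL` the host
#'   removal step is skipped.
#' @return A list with `reads` (the clean `read_set`) and `report` (one-row
#'   data frame: input, trimmed, removed-by-filter, removed-as-host, output
#'   counts).
#' @export
qc_reads <- function(rs, p = qc_params(), decoy = NULL) {
  n_in <- nrow(rs)
  trimmed <- quality_trim_right(rs, p$trim_quality)
  n_trimmed <- sum(nchar(trimmed$sequence) < nchar(rs$sequence))
  filtered <- filter_reads(trimmed, p)
  n_filtered_out <- nrow(trimmed) - nrow(filtered)
  host_ids <- character(0)
  out <- filtered
  if (!is.null(decoy)) {
    out <- remove_host_reads(filtered, decoy, p)
    host_ids <- attr(out, "host_read_ids")
  }
  list(reads = out,
       report = data.frame(sag_id = attr(rs, "sag_id") %||% NA_character_,
                           reads_in = n_in, reads_trimmed = n_trimmed,
                           removed_by_filter = n_filtered_out,
                           removed_as_host = length(host_ids),
                           reads_out = nrow(out), stringsAsFactors = FALSE))
}
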