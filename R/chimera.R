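#' Chimera-splitting parameters
#'
#' @param min_fragment Minimum fragment length kept after splitting, bp
#'   (default 20; shorter fragments are discarded).
#' @param full_align_fraction A read with one alignment segment covering at
#'   least this fraction of its length is clean (default 0.95).
#' @param min_identity Minimum alignment identity for a segment (default 0.90).
#' @param max_cycles Maximum cross-reference mapping/splitting cycles
#'   (default 5; cycling stops early at the fixpoint).
#' @return A list of class `split_params`.
#' @export
split_params <- function(min_fragment = 20, full_align_fraction = 0.95,
                         min_identity = 0.90, max_cycles = 5) {
  if (min_fragment < 1) stop("min_fragment must be >= 1")
  if (full_align_fraction <= 0 || full_align_fraction > 1)
    stop("full_align_fraction must be in (0,1]")
  if (min_identity <= 0 || min_identity > 1) stop("min_identity must be in (0,1]")
  structure(list(min_fragment = as.integer(min_fragment),
                 full_align_fraction = full_align_fraction,
                 min_identity = min_identity, max_cycles = as.integer(max_cycles)),
            class = "split_params")
}

#' Map a single read against a target assembly
#'
#' Maximal non-overlapping high-identity local alignments of the read to
#' the target, by exact 15-mer seeding, diagonal clustering and X-drop
#' extension; segments shorter than two seed lengths (30 bp) are dropped as
#' spurious-match noise. Deterministic for fixed inputs.
#'
#' @param sequence Read sequence (character scalar).
#' @param target A [genome_assembly()] passing the contig filter, or a
#'   prebuilt seed index.
#' @param p A [split_params()].
#' @return Data frame of alignment segments (`qstart`/`qend` 0-based
#'   half-open on the read, `contig`, `tstart`/`tend`, `strand`,
#'   `identity`); zero rows for an unaligned read.
#' @export
map_read <- function(sequence, target, p = split_params()) {
  idx <- if (inherits(target, "genome_assembly")) assembly_index(target) else target
  segs <- cpp_map_batch(sequence, idx,
                        min_identity = p$min_identity, min_seg_len = 30L,
                        xdrop = 20L, max_diag_gap = 3L, max_seed_gap = 300L,
                        max_overlap = 14L, nonoverlap_on_target = FALSE,
                        max_segments = 8L, seed_step = 2L)
  segs[order(segs$qstart), , drop = FALSE]
}

# resolve residual query overlaps (<= k bp, seed-edge ambiguity) at the
# overlap midpoint, tie broken toward the longer segment
resolve_overlaps <- function(segs) {
  segs <- segs[order(segs$qstart, -(segs$qend - segs$qstart)), , drop = FALSE]
  if (nrow(segs) < 2) return(segs)
  for (i in seq_len(nrow(segs) - 1)) {
    a_end <- segs$qend[i]; b_start <- segs$qstart[i + 1]
    if (b_start < a_end) {
      len_a <- segs$qend[i] - segs$qstart[i]
      len_b <- segs$qend[i + 1] - segs$qstart[i + 1]
      mid <- (b_start + a_end) / 2
      cut <- if (len_a >= len_b) ceiling(mid) else floor(mid)
      segs$qend[i] <- cut
      segs$qstart[i + 1] <- cut
    }
  }
  segs[segs$qend > segs$qstart, , drop = FALSE]
}

#' Classify a read and split it at alignment boundaries
#'
#' A read with one segment covering at least `full_align_fraction` of its
#' length is returned whole (clean); a read with no segments is returned
#' whole (unmapped is not evidence of chimerism); otherwise the read is cut
#' at segment boundaries into aligned and interstitial unaligned fragments,
#' qualities sliced in register, and fragments shorter than `min_fragment`
#' are discarded.
#'
#' @param sequence,quality The read and its Phred+33 quality string.
#' @param segments Segments from [map_read()] for this read.
#' @param p A [split_params()].
#' @return List with `status` (`"clean"`, `"unmapped"` or `"split"`) and
#'   `fragments` (data frame `start`, `end`, `sequence`, `quality`,
#'   `aligned`; the whole read when unsplit).
#' @export
classify_and_split <- function(sequence, quality, segments, p = split_params()) {
  L <- nchar(sequence)
  whole <- data.frame(start = 0L, end = L, sequence = sequence, quality = quality,
                      aligned = NA, stringsAsFactors = FALSE)
  if (is.null(segments) || nrow(segments) == 0)
    return(list(status = "unmapped", fragments = whole))
  cov <- (segments$qend - segments$qstart) / L
  if (any(cov >= p$full_align_fraction))
    return(list(status = "clean", fragments = whole))
  segs <- resolve_overlaps(segments)
  bounds <- sort(unique(c(0L, segs$qstart, segs$qend, L)))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1]
  aligned <- vapply(seq_along(starts), function(i)
    any(segs$qstart <= starts[i] & segs$qend >= ends[i]), logical(1))
  keep <- (ends - starts) >= p$min_fragment
  fr <- data.frame(start = starts[keep], end = ends[keep],
                   sequence = substr(rep(sequence, sum(keep)), starts[keep] + 1L, ends[keep]),
                   quality = substr(rep(quality, sum(keep)), starts[keep] + 1L, ends[keep]),
                   aligned = aligned[keep], stringsAsFactors = FALSE)
  list(status = "split", fragments = fr)
}

# per-read candidate decision against one partner, vectorized over a pool
decide_against_partner <- function(seqs, idx, p) {
  segs <- cpp_map_batch(seqs, idx,
                        min_identity = p$min_identity, min_seg_len = 30L,
                        xdrop = 20L, max_diag_gap = 3L, max_seed_gap = 300L,
                        max_overlap = 14L, nonoverlap_on_target = FALSE,
                        max_segments = 8L, seed_step = 2L)
  n <- length(seqs)
  status <- rep("unmapped", n)
  if (nrow(segs) > 0) {
    cov <- (segs$qend - segs$qstart) / nchar(seqs)[segs$query]
    mx <- tapply(cov, segs$query, max)
    qidx <- as.integer(names(mx))
    status[qidx] <- ifelse(mx >= p$full_align_fraction, "clean", "partial")
  }
  list(status = status, segments = segs)
}

#' Clean and pool the reads of a strain group
#'
#' Runs cycles of cross-reference mapping: every member's current reads are
#' mapped against every other member's assembly; a read partially aligned
#' to any partner is split (applying the most fragmenting partner's split),
#' sub-`min_fragment` pieces are discarded, and cycles repeat until no read
#' is split or `max_cycles` is reached. Unmapped reads are retained whole —
#' they may come from genuine regions absent in partner SAGs. Singleton
#' groups pass through unchanged.
#'
#' @param members Character vector of member sag ids.
#' @param readsets Named list of [read_set()] (per member).
#' @param assemblies Named list of contig-filtered `genome_assembly`.
#' @param p A [split_params()].
#' @return List with `reads` (pooled `read_set`, ids prefixed by source
#'   sag), `report` (per-member data frame: reads in/clean/split, fragments
#'   out, bases in/out/discarded, cycles), and `read_log` (original read id,
#'   sag, split flag, fragments surviving).
#' @export
clean_group_reads <- function(members, readsets, assemblies, p = split_params()) {
  members <- sort(members)
  with_asm <- members[members %in% names(assemblies)]
  if (length(setdiff(members, with_asm)) > 0)
    message("members without assemblies excluded as mapping targets: ",
            paste(setdiff(members, with_asm), collapse = ", "))

  pools <- lapply(members, function(m) {
    rs <- readsets[[m]]
    data.frame(read_id = rs$read_id, sequence = rs$sequence, quality = rs$quality,
               orig_id = rs$read_id, fresh = TRUE, stringsAsFactors = FALSE)
  })
  names(pools) <- members
  bases_in <- vapply(pools, function(pl) sum(nchar(pl$sequence)), numeric(1))
  split_flag <- lapply(pools, function(pl) setNames(rep(FALSE, nrow(pl)), pl$read_id))
  bases_discarded <- setNames(rep(0, length(members)), members)
  cycles <- 0L

  if (length(members) >= 2 && length(with_asm) >= 2) {
    idxs <- lapply(assemblies[with_asm], assembly_index)
    repeat {
      cycles <- cycles + 1L
      any_split <- FALSE
      for (m in members) {
        pool <- pools[[m]]
        act <- which(pool$fresh)
        if (length(act) == 0) next
        partners <- setdiff(with_asm, m)
        if (length(partners) == 0) next
        seqs <- pool$sequence[act]
        decisions <- lapply(partners, function(pt)
          decide_against_partner(seqs, idxs[[pt]], p))
        names(decisions) <- partners
        status_mat <- vapply(decisions, `[[`, character(length(act)), "status")
        if (length(act) == 1) status_mat <- matrix(status_mat, nrow = 1,
                                                   dimnames = list(NULL, partners))
        is_partial <- apply(status_mat == "partial", 1, any)
        new_rows <- list(); drop_rows <- integer(0)
        for (ii in which(is_partial)) {
          i <- act[ii]
          best <- NULL; best_n <- -1L; best_partner <- NULL
          for (pt in partners) {
            if (status_mat[ii, pt] != "partial") next
            segs <- decisions[[pt]]$segments
            segs <- segs[segs$query == ii, , drop = FALSE]
            cand <- classify_and_split(pool$sequence[i], pool$quality[i], segs, p)
            if (cand$status != "split") next
            if (nrow(cand$fragments) > best_n) {
              best <- cand$fragments; best_n <- nrow(cand$fragments); best_partner <- pt
            }
          }
          if (is.null(best)) next
          any_split <- TRUE
          drop_rows <- c(drop_rows, i)
          split_flag[[m]][pool$orig_id[i]] <- TRUE
          bases_discarded[m] <- bases_discarded[m] +
            nchar(pool$sequence[i]) - sum(nchar(best$sequence))
          if (nrow(best) > 0) {
            new_rows[[length(new_rows) + 1L]] <- data.frame(
              read_id = sprintf("%s:f%d", pool$read_id[i], seq_len(nrow(best))),
              sequence = best$sequence, quality = best$quality,
              orig_id = pool$orig_id[i], fresh = TRUE, stringsAsFactors = FALSE)
          }
        }
        pool$fresh <- FALSE
        if (length(drop_rows) > 0) pool <- pool[-drop_rows, , drop = FALSE]
        if (length(new_rows) > 0) pool <- rbind(pool, do.call(rbind, new_rows))
        pools[[m]] <- pool
      }
      if (!any_split || cycles >= p$max_cycles) break
    }
  }

  pooled <- do.call(rbind, lapply(members, function(m) {
    pl <- pools[[m]]
    if (nrow(pl) == 0) return(NULL)
    data.frame(read_id = paste0(m, "|", pl$read_id), sequence = pl$sequence,
               quality = pl$quality, source_sag = m, orig_id = pl$orig_id,
               stringsAsFactors = FALSE)
  }))
  out_rs <- if (is.null(pooled)) {
    read_set(character(0), character(0), character(0), sag_id = "pooled")
  } else {
    rs <- read_set(pooled$read_id, pooled$sequence, pooled$quality, sag_id = "pooled")
    rs$source_sag <- pooled$source_sag
    rs
  }
  report <- do.call(rbind, lapply(members, function(m) {
    pl <- pools[[m]]
    data.frame(sag_id = m, reads_in = length(split_flag[[m]]),
               reads_split = sum(split_flag[[m]]),
               reads_clean = sum(!split_flag[[m]]),
               fragments_out = sum(pl$orig_id %in%
                                     names(which(split_flag[[m]]))),
               reads_out = nrow(pl),
               bases_in = bases_in[[m]], bases_out = sum(nchar(pl$sequence)),
               bases_discarded = bases_discarded[[m]],
               cycles = cycles, stringsAsFactors = FALSE)
  }))
  read_log <- do.call(rbind, lapply(members, function(m) {
    pl <- pools[[m]]
    surv <- table(factor(pl$orig_id, levels = names(split_flag[[m]])))
    data.frame(sag_id = m, read_id = names(split_flag[[m]]),
               split = unname(split_flag[[m]]),
               fragments_surviving = as.integer(surv), stringsAsFactors = FALSE)
  }))
  list(reads = out_rs, report = report, read_log = read_log)
}
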