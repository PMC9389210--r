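#' Fragment-ANI parameters
#'
#' Defaults follow the classic fragment-based ANI convention: 1,000-bp
#' non-overlapping fragments, 70% identity and 70% fragment-coverage floors,
#' and a minimum of 5 qualifying fragments for a defined estimate.
#'
#' @param fragment_length Fragment length in bp (>= 200).
#' @param min_fragment_identity Identity floor in `[0,1]`.
#' @param min_fragment_coverage Fragment coverage floor in `[0,1]`.
#' @param min_fragments Minimum qualifying fragments.
#' @return A list of class `ani_params`.
#' @export
ani_params <- function(fragment_length = 1000, min_fragment_identity = 0.70,
                       min_fragment_coverage = 0.70, min_fragments = 5) {
  if (fragment_length < 200) stop("fragment_length must be >= 200 bp")
  fr <- c(min_fragment_identity, min_fragment_coverage)
  if (any(fr < 0 | fr > 1)) stop("identity/coverage floors must be in [0,1]")
  structure(list(fragment_length = as.integer(fragment_length),
                 min_fragment_identity = min_fragment_identity,
                 min_fragment_coverage = min_fragment_coverage,
                 min_fragments = as.integer(min_fragments)),
            class = "ani_params")
}

# canonical (strand-symmetric) tetranucleotide bins: 136 of them
tnf_bins <- local({
  bases <- c("A", "C", "G", "T")
  kmers <- apply(expand.grid(bases, bases, bases, bases,
                             stringsAsFactors = FALSE)[, 4:1], 1, paste, collapse = "")
  rc <- vapply(strsplit(chartr("ACGT", "TGCA", kmers), ""), function(x)
    paste(rev(x), collapse = ""), character(1))
  canon <- pmin(kmers, rc)
  list(kmers = kmers, canon = canon, levels = sort(unique(canon)))
})

#' Canonical tetranucleotide frequency profile
#'
#' Counts every 4-mer together with its reverse complement over all contigs
#' (windows never span contig boundaries; windows containing N are skipped),
#' collapsed to the 136 strand-symmetric canonical bins and normalized to
#' sum to one. Profiles of a sequence and of its reverse complement are
#' identical by construction.
#'
#' @param asm A [genome_assembly()] with total length >= `min_length`.
#' @param min_length Minimum assembly length for a defined profile
#'   (default 5,000 bp; shorter assemblies give composition estimates too
#'   noisy for strain grouping).
#' @return Named numeric vector of 136 canonical 4-mer frequencies, or a
#'   vector of `NA` when the assembly is too short (undefined profile).
#' @export
tetranucleotide_profile <- function(asm, min_length = 5000) {
  undef <- setNames(rep(NA_real_, length(tnf_bins$levels)), tnf_bins$levels)
  if (length(asm$contigs) == 0 || sum(nchar(asm$contigs)) < min_length) return(undef)
  counts <- colSums(Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(asm$contigs), width = 4))
  canon <- tapply(counts[tnf_bins$kmers], tnf_bins$canon, sum)
  v <- as.numeric(canon)[match(tnf_bins$levels, names(canon))]
  names(v) <- tnf_bins$levels
  tot <- sum(v)
  if (tot == 0) return(undef)
  v / tot
}

#' Pearson correlation of two tetranucleotide profiles
#'
#' @param p,q Profiles from [tetranucleotide_profile()].
#' @return Correlation in `[-1,1]`, or `NA` when either profile is
#'   undefined or has zero variance.
#' @export
tnf_correlation <- function(p, q) {
  if (anyNA(p) || anyNA(q)) return(NA_real_)
  if (stats::sd(p) == 0 || stats::sd(q) == 0) return(NA_real_)
  cor(p, q)
}

# chop filtered contigs of `asm` into full-length non-overlapping fragments
ani_fragments <- function(asm, fragment_length) {
  frags <- character(0)
  for (ct in asm$contigs) {
    n_full <- nchar(ct) %/% fragment_length
    if (n_full == 0) next
    starts <- (seq_len(n_full) - 1L) * fragment_length + 1L
    frags <- c(frags, substring(ct, starts, starts + fragment_length - 1L))
  }
  frags
}

frag_ani_with_index <- function(asm_a, idx_b, p) {
  frags <- ani_fragments(asm_a, p$fragment_length)
  if (length(frags) == 0) return(list(ani = NA_real_, fragments_used = 0L))
  segs <- cpp_map_batch(frags, idx_b,
                        min_identity = p$min_fragment_identity, min_seg_len = 100L,
                        xdrop = 30L, max_diag_gap = 3L, max_seed_gap = 300L,
                        max_overlap = 14L, nonoverlap_on_target = FALSE,
                        max_segments = 2L, seed_step = 4L)
  if (nrow(segs) == 0) return(list(ani = NA_real_, fragments_used = 0L))
  best <- segs[!duplicated(segs$query), , drop = FALSE]  # best segment first per query
  cov <- (best$qend - best$qstart) / p$fragment_length
  ok <- best$identity >= p$min_fragment_identity & cov >= p$min_fragment_coverage
  used <- sum(ok)
  if (used < p$min_fragments) return(list(ani = NA_real_, fragments_used = as.integer(used)))
  list(ani = 100 * mean(best$identity[ok]), fragments_used = as.integer(used))
}

#' One-way fragment-based ANI
#'
#' Chops `a` into non-overlapping fragments, finds the best local alignment
#' of each fragment in `b`, and averages percent identity over fragments
#' passing the identity and coverage floors. Undefined (`NA`) when fewer
#' than `min_fragments` qualify (insufficient homologous fraction).
#'
#' @param a,b [genome_assembly()] objects (contig-filtered).
#' @param p An [ani_params()].
#' @return List with `ani` (percent or `NA`) and `fragments_used`.
#' @export
fragment_ani <- function(a, b, p = ani_params()) {
  frag_ani_with_index(a, assembly_index(b), p)
}

#' Two-way average nucleotide identity
#'
#' Mean of the one-way fragment ANIs in both directions; undefined when
#' either direction is undefined. Symmetric under argument swap.
#'
#' @inheritParams fragment_ani
#' @return List with `ani` (percent or `NA`) and `fragments_used`
#'   (total over both directions).
#' @export
two_way_ani <- function(a, b, p = ani_params()) {
  ab <- fragment_ani(a, b, p)
  ba <- fragment_ani(b, a, p)
  if (is.na(ab$ani) || is.na(ba$ani))
    return(list(ani = NA_real_, fragments_used = ab$fragments_used + ba$fragments_used))
  list(ani = (ab$ani + ba$ani) / 2,
       fragments_used = ab$fragments_used + ba$fragments_used)
}

# single-copy marker extractions for one assembly: marker-oriented sequence
# plus the marker interval covered
marker_extractions <- function(asm, markers, min_identity = 0.90, min_coverage = 0.80) {
  hits <- find_markers(asm, markers, min_identity, min_coverage)
  if (nrow(hits) == 0) return(hits[0, ])
  single <- names(which(table(hits$marker) == 1))
  hits <- hits[hits$marker %in% single, , drop = FALSE]
  if (nrow(hits) == 0) return(hits)
  seqs <- substr(asm$contigs[hits$contig], hits$tstart + 1L, hits$tend)
  flip <- hits$strand == "-"
  if (any(flip)) seqs[flip] <- revcomp(seqs[flip])
  hits$sequence <- unname(seqs)
  hits
}

marker_homology_from_extractions <- function(ex_a, ex_b, min_shared = 10,
                                             min_overlap = 200, band = 16) {
  shared <- intersect(ex_a$marker, ex_b$marker)
  idents <- numeric(0)
  for (m in shared) {
    ra <- ex_a[ex_a$marker == m, ]
    rb <- ex_b[ex_b$marker == m, ]
    lo <- max(ra$qstart, rb$qstart)
    hi <- min(ra$qend, rb$qend)
    if (hi - lo < min_overlap) next
    sa <- substr(ra$sequence, lo - ra$qstart + 1L, hi - ra$qstart)
    sb <- substr(rb$sequence, lo - rb$qstart + 1L, hi - rb$qstart)
    idents <- c(idents, cpp_global_identity(sa, sb, band))
  }
  idents <- idents[!is.na(idents)]
  if (length(idents) < min_shared)
    return(list(homology = NA_real_, markers_compared = length(idents)))
  list(homology = 100 * mean(idents), markers_compared = length(idents))
}

#' Single-copy marker homology between two assemblies
#'
#' For every marker found single-copy in both assemblies, the two extracted
#' marker sequences are globally aligned over their common marker interval;
#' homology is the mean percent identity. Undefined when fewer than
#' `min_shared` markers are comparable.
#'
#' @param a,b [genome_assembly()] objects.
#' @param markers Named character vector of marker sequences.
#' @param min_shared Minimum shared single-copy markers (default 10).
#' @return List with `homology` (percent or `NA`) and `markers_compared`.
#' @export
marker_homology <- function(a, b, markers, min_shared = 10) {
  marker_homology_from_extractions(marker_extractions(a, markers),
                                   marker_extractions(b, markers),
                                   min_shared = min_shared)
}

#' Pairwise similarity records for a set of assemblies
#'
#' Computes, for every unordered pair, the three grouping measures:
#' two-way fragment ANI, canonical tetranucleotide-frequency correlation,
#' and single-copy marker homology. Per-assembly work (seed index, TNF
#' profile, marker extraction) is done once.
#'
#' @param assemblies Named list of contig-filtered `genome_assembly`.
#' @param markers Named character vector of marker sequences.
#' @param p An [ani_params()].
#' @param min_shared_markers Minimum shared single-copy markers.
#' @return Data frame: sag_a, sag_b, ani, ani_fragments_used, tnf_corr,
#'   marker_homology, markers_compared.
#' @export
similarity_records <- function(assemblies, markers, p = ani_params(),
                               min_shared_markers = 10) {
  ids <- names(assemblies)
  if (length(ids) < 2) {
    return(data.frame(sag_a = character(0), sag_b = character(0),
                      ani = numeric(0), ani_fragments_used = integer(0),
                      tnf_corr = numeric(0), marker_homology = numeric(0),
                      markers_compared = integer(0), stringsAsFactors = FALSE))
  }
  idxs <- lapply(assemblies, assembly_index)
  profs <- lapply(assemblies, tetranucleotide_profile)
  exts <- lapply(assemblies, marker_extractions, markers = markers)
  rows <- list()
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in seq((i + 1), length(ids))) {
      a <- ids[i]; b <- ids[j]
      ab <- frag_ani_with_index(assemblies[[a]], idxs[[b]], p)
      ba <- frag_ani_with_index(assemblies[[b]], idxs[[a]], p)
      ani <- if (is.na(ab$ani) || is.na(ba$ani)) NA_real_ else (ab$ani + ba$ani) / 2
      mh <- marker_homology_from_extractions(exts[[a]], exts[[b]],
                                             min_shared = min_shared_markers)
      rows[[length(rows) + 1L]] <- data.frame(
        sag_a = a, sag_b = b, ani = ani,
        ani_fragments_used = ab$fragments_used + ba$fragments_used,
        tnf_corr = tnf_correlation(profs[[a]], profs[[b]]),
        marker_homology = mh$homology, markers_compared = mh$markers_compared,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
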