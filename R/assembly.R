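#' Construct a genome assembly object
#'
#' A `genome_assembly` holds the contigs of one single-amplified genome (SAG),
#' co-assembly, or reference as a named character vector of DNA sequences.
#'
#' @param sag_id Identifier of the genome.
#' @param contigs Named character vector of contig sequences (names are contig
#'   ids; sequences over `A`, `C`, `G`, `T`, `N`).
#' @param source One of `"sag"`, `"cosag"`, `"reference"`, `"mag"`.
#' @return An object of class `genome_assembly`.
#' @export
genome_assembly <- function(sag_id, contigs, source = c("sag", "cosag", "reference", "mag")) {
  source <- match.arg(source)
  contigs <- unlist(contigs)
  if (length(contigs) > 0) {
    if (is.null(names(contigs)) || anyDuplicated(names(contigs)))
      stop("contigs must have unique names")
    bad <- grepl("[^ACGTNacgtn]", contigs)
    if (any(bad)) stop("contig sequences must be over {A,C,G,T,N}")
    contigs <- toupper(contigs)
  }
  structure(list(sag_id = as.character(sag_id), contigs = contigs, source = source),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  st <- assembly_stats(x)
  cat(sprintf("<genome_assembly> %s (%s): %d contig(s), %s bp, N50 %s, GC %.1f%%\n",
              x$sag_id, x$source, st$n_contigs,
              format(st$total_bp, big.mark = ","),
              format(st$n50, big.mark = ","), 100 * st$gc))
  invisible(x)
}

#' Assembly summary statistics
#'
#' @param asm A [genome_assembly()].
#' @return A list with `n_contigs`, `total_bp`, `n50`, `gc`.
#' @export
assembly_stats <- function(asm) {
  len <- nchar(asm$contigs)
  total <- sum(len)
  n50 <- if (total == 0) 0L else {
    sl <- sort(len, decreasing = TRUE)
    sl[which(cumsum(sl) >= total / 2)[1]]
  }
  gc <- if (total == 0) NA_real_ else {
    counts <- rowSums(vapply(asm$contigs, function(s) {
      c(gc = nchar(gsub("[^GC]", "", s)), acgt = nchar(gsub("[^ACGT]", "", s)))
    }, numeric(2)))
    unname(counts["gc"] / max(counts["acgt"], 1))
  }
  list(n_contigs = length(asm$contigs), total_bp = total, n50 = n50, gc = gc)
}

#' Drop short contigs from an assembly
#'
#' Contigs below `min_len` are removed before any downstream analysis; the
#' default reproduces the standard 1,000-bp cutoff for single-cell assemblies.
#'
#' @param asm A [genome_assembly()].
#' @param min_len Minimum contig length in bp (default 1000).
#' @return The filtered `genome_assembly`, order preserved.
#' @export
filter_contigs <- function(asm, min_len = 1000) {
  keep <- nchar(asm$contigs) >= min_len
  out <- asm
  out$contigs <- asm$contigs[keep]
  if (length(asm$contigs) > 0 && length(out$contigs) == 0)
    warning(sprintf("all contigs of %s removed by the %d bp filter", asm$sag_id, min_len))
  out
}

#' Read an assembly from a FASTA file
#' @param path FASTA file.
#' @param sag_id Genome id; defaults to the file name without extension.
#' @param source Passed to [genome_assembly()].
#' @return A `genome_assembly`.
#' @export
read_assembly_fasta <- function(path, sag_id = NULL, source = "sag") {
  x <- Biostrings::readDNAStringSet(path)
  sag_id <- sag_id %||% sub("\\.(fa|fasta|fna)$", "", basename(path))
  genome_assembly(sag_id, setNames(as.character(x), names(x)), source = source)
}

#' Write an assembly to a FASTA file
#' @param asm A `genome_assembly`.
#' @param path Output path.
#' @export
write_assembly_fasta <- function(asm, path) {
  x <- Biostrings::DNAStringSet(asm$contigs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# Seed index over an assembly's contigs, cached inside the object environment
# of the call site; rebuilt on demand.
assembly_index <- function(asm, k = 15L) {
  if (length(asm$contigs) == 0) stop("cannot index an empty assembly")
  cpp_build_index(unname(asm$contigs), names(asm$contigs), as.integer(k))
}
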