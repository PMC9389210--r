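#' Construct a read set
#'
#' A `read_set` is a data frame of reads (id, sequence, Phred+33 quality
#' string, mate) carrying the SAG of origin as an attribute.
#'
#' @param read_id Character vector of unique read ids.
#' @param sequence DNA sequences.
#' @param quality Phred+33 quality strings, same lengths as `sequence`.
#' @param mate `"1"`, `"2"` or `"unpaired"` per read.
#' @param sag_id Provenance tag for the whole set.
#' @return A data frame of class `read_set`.
#' @export
read_set <- function(read_id, sequence, quality, mate = "unpaired", sag_id = NA_character_) {
  read_id <- as.character(read_id)
  if (anyDuplicated(read_id)) stop("read ids must be unique within a set")
  if (length(sequence) != length(read_id) || length(quality) != length(read_id))
    stop("read_id, sequence and quality must have equal length")
  if (any(nchar(sequence) != nchar(quality)))
    stop("sequence and quality lengths must match per read")
  df <- data.frame(read_id = read_id, sequence = as.character(sequence),
                   quality = as.character(quality),
                   mate = rep_len(as.character(mate), length(read_id)),
                   stringsAsFactors = FALSE)
  attr(df, "sag_id") <- sag_id
  class(df) <- c("read_set", "data.frame")
  df
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %s: %d reads, %s bases\n",
              attr(x, "sag_id"), nrow(x), format(sum(nchar(x$sequence)), big.mark = ",")))
  invisible(x)
}

as_read_set <- function(df, sag_id = NA_character_) {
  read_set(df$read_id, df$sequence, df$quality,
           mate = if ("mate" %in% names(df)) df$mate else "unpaired",
           sag_id = sag_id)
}

#' Read a FASTQ file into a read set
#' @param path FASTQ file (Phred+33).
#' @param sag_id Provenance tag.
#' @return A `read_set`.
#' @export
read_fastq <- function(path, sag_id = NULL) {
  # readQualityScaledDNAStringSet warns about dropping its own mcols
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ids <- sub("\\s.*$", "", names(x))
  read_set(ids, as.character(x), as.character(Biostrings::quality(x)),
           sag_id = sag_id %||% sub("\\.(fq|fastq)$", "", basename(path)))
}

#' Write a read set to a FASTQ file
#' @param rs A `read_set`.
#' @param path Output path.
#' @export
write_fastq <- function(rs, path) {
  if (nrow(rs) == 0) {
    file.create(path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(rs$sequence)
  names(x) <- rs$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(rs$quality))
  invisible(path)
}
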