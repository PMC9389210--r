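#' Run the full CoSAG construction pipeline
#'
#' Orchestrates read QC, contig filtering, marker-based quality estimation
#' and tier assignment, SAG selection, the three pairwise similarity
#' measures, same-strain grouping, and iterative chimera splitting, ending
#' at co-assembly-ready pooled reads per strain group. The external
#' assembler is not invoked; a ready-to-run command line per group is
#' written into the report instead.
#'
#' @param samples A [simulate_cohort()] result, or a data frame manifest
#'   with columns `host_id`, `sag_id`, `reads` (FASTQ path), `assembly`
#'   (FASTA path).
#' @param markers Named character vector of marker sequences, or a marker
#'   FASTA path.
#' @param decoy Optional host decoy `genome_assembly` or FASTA path.
#' @param qc,ani,grouping,split Parameter blocks ([qc_params()],
#'   [ani_params()], [strain_grouping_params()], [split_params()]).
#' @param cross_host Allow strain groups to span hosts (default `FALSE`;
#'   enable for cohabiting-host comparisons).
#' @param min_contig_len Contig filter in bp (default 1000).
#' @param min_shared_markers Minimum shared single-copy markers for a
#'   defined marker homology.
#' @param outdir Optional output directory; when given, all tables, pooled
#'   FASTQ files, a JSON report and a provenance manifest are written, and
#'   a completed run with the same configuration is returned from cache
#'   without recomputation.
#' @return A list of class `cosag_report`.
#' @export
run_pipeline <- function(samples, markers, decoy = NULL,
                         qc = qc_params(), ani = ani_params(),
                         grouping = strain_grouping_params(),
                         split = split_params(), cross_host = FALSE,
                         min_contig_len = 1000, min_shared_markers = 10,
                         outdir = NULL) {
  inp <- load_pipeline_inputs(samples, markers, decoy)
  if (length(inp$sag_ids) == 0) stop("empty sample manifest: nothing to run")
  cfg_hash <- pipeline_config_hash(inp, qc, ani, grouping, split, cross_host,
                                   min_contig_len, min_shared_markers)
  if (!is.null(outdir)) {
    cached <- read_cached_report(outdir, cfg_hash)
    if (!is.null(cached)) return(cached)
  }

  stage <- function(name, sid, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed for %s: %s", name, sid,
                   conditionMessage(e)), call. = FALSE))
  }

  # stage 1: read QC
  qc_rows <- list(); clean_reads <- list()
  for (sid in inp$sag_ids) {
    res <- stage("qc_reads", sid, qc_reads(inp$readsets[[sid]], qc, inp$decoy))
    clean_reads[[sid]] <- res$reads
    qc_rows[[sid]] <- res$report
  }
  qc_report <- do.call(rbind, c(qc_rows, list(make.row.names = FALSE)))

  # stage 2: contig filter + marker-based quality
  assemblies <- lapply(inp$assemblies, filter_contigs, min_len = min_contig_len)
  quality <- stage("genome_metrics", "all",
                   quality_table(inp$assemblies, inp$markers, min_contig_len))
  quality$host_id <- inp$hosts[quality$sag_id]
  tier_counts <- as.data.frame(table(host_id = quality$host_id, tier = quality$tier),
                               stringsAsFactors = FALSE)

  # stage 3: similarity among selected SAGs
  selected <- quality$sag_id[quality$selected]
  sims <- stage("similarity", "selected",
                similarity_records(assemblies[selected], inp$markers, ani,
                                   min_shared_markers))

  # stage 4: strain grouping
  groups <- stage("strain_clustering", "selected",
                  build_strain_groups(sims, quality, grouping,
                                      hosts = inp$hosts, cross_host = cross_host))

  # stage 5: chimera splitting and read pooling per group
  pooled <- list(); cleaning <- list()
  for (gid in unique(groups$group_id)) {
    mem <- groups$sag_id[groups$group_id == gid]
    res <- stage("chimera_split", gid,
                 clean_group_reads(mem, clean_reads, assemblies, split))
    pooled[[gid]] <- res$reads
    rep_g <- res$report
    rep_g$group_id <- gid
    cleaning[[gid]] <- rep_g
  }
  cleaning <- do.call(rbind, c(cleaning, list(make.row.names = FALSE)))

  bands <- summarize_ani_bands(sims, groups)

  report <- structure(list(
    config_hash = cfg_hash, n_sags = length(inp$sag_ids),
    qc = qc_report, quality = quality, tier_counts = tier_counts,
    similarity = sims, groups = groups, cleaning = cleaning,
    ani_bands = bands, pooled = pooled,
    assembler_cmds = vapply(names(pooled), function(g)
      sprintf("spades.py --sc --careful -s pooled/%s.fastq -o assembly/%s", g, g),
      character(1))), class = "cosag_report")
  if (!is.null(outdir)) write_pipeline_outputs(report, inp, outdir)
  report
}

#' @export
print.cosag_report <- function(x, ...) {
  cat(sprintf("<cosag_report> %d SAGs, %d selected, %d strain group(s)\n",
              x$n_sags, sum(x$quality$selected), length(unique(x$groups$group_id))))
  tl <- table(x$quality$tier)
  cat("  tiers:", paste(sprintf("%s=%d", names(tl), tl), collapse = ", "), "\n")
  if (nrow(x$ani_bands) > 0) {
    for (i in seq_len(nrow(x$ani_bands)))
      cat(sprintf("  ANI %s-group: n=%d, %.2f-%.2f (mean %.2f)\n",
                  x$ani_bands$band[i], x$ani_bands$n[i], x$ani_bands$min[i],
                  x$ani_bands$max[i], x$ani_bands$mean[i]))
  }
  invisible(x)
}

#' Within- versus between-group ANI summary
#'
#' @param records [similarity_records()] data frame.
#' @param groups [build_strain_groups()] data frame.
#' @return Data frame with one row per band (`within`, `between`): n, min,
#'   mean, max. A warning is emitted when the two bands' ranges intersect.
#' @export
summarize_ani_bands <- function(records, groups) {
  grp <- setNames(groups$group_id, groups$sag_id)
  rec <- records[records$sag_a %in% names(grp) & records$sag_b %in% names(grp) &
                   !is.na(records$ani), , drop = FALSE]
  if (nrow(rec) == 0) {
    return(data.frame(band = character(0), n = integer(0), min = numeric(0),
                      mean = numeric(0), max = numeric(0), stringsAsFactors = FALSE))
  }
  within <- grp[rec$sag_a] == grp[rec$sag_b]
  mk <- function(v, nm) if (length(v) == 0) NULL else
    data.frame(band = nm, n = length(v), min = min(v), mean = mean(v), max = max(v),
               stringsAsFactors = FALSE)
  out <- rbind(mk(rec$ani[within], "within"), mk(rec$ani[!within], "between"))
  if (!is.null(out) && nrow(out) == 2 && out$max[out$band == "between"] >=
        out$min[out$band == "within"])
    warning("within-group and between-group ANI ranges intersect")
  out %||% data.frame(band = character(0), n = integer(0), min = numeric(0),
                      mean = numeric(0), max = numeric(0), stringsAsFactors = FALSE)
}

# ---- input loading and provenance ------------------------------------------

load_pipeline_inputs <- function(samples, markers, decoy) {
  if (is.character(markers) && length(markers) == 1 && file.exists(markers)) {
    m <- Biostrings::readDNAStringSet(markers)
    markers <- setNames(as.character(m), names(m))
  }
  if (is.character(decoy)) decoy <- read_assembly_fasta(decoy, "decoy", "reference")
  if (inherits(samples, "sag_cohort")) {
    assemblies <- list(); readsets <- list(); hosts <- character(0)
    for (h in samples$hosts) {
      for (sid in names(h$sags)) {
        assemblies[[sid]] <- h$sags[[sid]]$assembly
        readsets[[sid]] <- h$sags[[sid]]$reads
        hosts[sid] <- h$host_id
      }
    }
    return(list(sag_ids = names(assemblies), hosts = hosts,
                assemblies = assemblies, readsets = readsets,
                markers = markers %||% samples$markers,
                decoy = decoy %||% samples$decoy))
  }
  df <- as.data.frame(samples)
  if (nrow(df) == 0) return(list(sag_ids = character(0)))
  need <- c("host_id", "sag_id", "reads", "assembly")
  if (!all(need %in% names(df)))
    stop("sample manifest needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sag_id)) stop("sag_ids must be unique")
  missing <- c(df$reads[!file.exists(df$reads)], df$assembly[!file.exists(df$assembly)])
  if (length(missing) > 0)
    stop("referenced paths do not exist: ", paste(missing, collapse = ", "))
  assemblies <- lapply(seq_len(nrow(df)), function(i)
    read_assembly_fasta(df$assembly[i], df$sag_id[i]))
  readsets <- lapply(seq_len(nrow(df)), function(i)
    read_fastq(df$reads[i], df$sag_id[i]))
  names(assemblies) <- names(readsets) <- df$sag_id
  list(sag_ids = df$sag_id, hosts = setNames(df$host_id, df$sag_id),
       assemblies = assemblies, readsets = readsets, markers = markers,
       decoy = decoy)
}

pipeline_config_hash <- function(inp, qc, ani, grouping, split, cross_host,
                                 min_contig_len, min_shared_markers) {
  cfg <- list(sags = inp$sag_ids, hosts = unname(inp$hosts[inp$sag_ids]),
              n_markers = length(inp$markers), has_decoy = !is.null(inp$decoy),
              qc = unclass(qc), ani = unclass(ani), grouping = unclass(grouping),
              split = unclass(split), cross_host = cross_host,
              min_contig_len = min_contig_len,
              min_shared_markers = min_shared_markers)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(cfg), f)
  unname(tools::md5sum(f))
}

read_cached_report <- function(outdir, cfg_hash) {
  mf <- file.path(outdir, "MANIFEST.tsv")
  rj <- file.path(outdir, "report.json")
  if (!file.exists(mf) || !file.exists(rj)) return(NULL)
  man <- read.table(mf, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!identical(attr_row(man, "config_hash"), cfg_hash)) return(NULL)
  if (!identical(attr_row(man, "status"), "complete")) return(NULL)
  rep <- jsonlite::fromJSON(rj, simplifyDataFrame = TRUE)
  rep$pooled <- NULL
  rep$cached <- TRUE
  class(rep) <- "cosag_report"
  rep
}

attr_row <- function(man, key) {
  v <- man$value[man$key == key]
  if (length(v) == 1) v else NA_character_
}

write_pipeline_outputs <- function(report, inp, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "pooled"), showWarnings = FALSE)
  wt <- function(df, name) {
    write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
    name
  }
  files <- c(wt(report$qc, "qc.tsv"), wt(report$quality, "quality.tsv"),
             wt(report$similarity, "similarity.tsv"), wt(report$groups, "groups.tsv"),
             wt(report$cleaning, "cleaning.tsv"))
  for (gid in names(report$pooled)) {
    path <- file.path("pooled", paste0(gid, ".fastq"))
    write_fastq(report$pooled[[gid]], file.path(outdir, path))
    files <- c(files, path)
  }
  json <- report
  json$pooled <- NULL
  jsonlite::write_json(unclass(json), file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  files <- c(files, "report.json")
  md5 <- tools::md5sum(file.path(outdir, files))
  man <- rbind(data.frame(key = "config_hash", value = report$config_hash,
                          stringsAsFactors = FALSE),
               data.frame(key = paste0("file:", files), value = unname(md5),
                          stringsAsFactors = FALSE),
               data.frame(key = "status", value = "complete", stringsAsFactors = FALSE))
  write.table(man, file.path(outdir, "MANIFEST.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(outdir)
}
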