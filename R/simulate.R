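#' Simulation configuration for synthetic SAG data
#'
#' Defines the generative model for ground-truthed single-amplified genome
#' (SAG) data: an ancestral genome with planted single-copy marker tags,
#' strains derived at controlled nucleotide identity, and per-SAG
#' MDA-style artifacts (lognormal coverage bias, locus dropout, read
#' errors, chimeric reads, cross-species and host contamination).
#'
#' @param genome_length Ancestor length in bp (>= 10,000).
#' @param gc_content Expected G+C fraction in `[0,1]`.
#' @param n_strains Strains per host.
#' @param between_strain_ani Target pairwise identity between strains, either
#'   a scalar in `[0.90, 1]` or a symmetric unit-diagonal matrix.
#' @param within_strain_identity Target pairwise identity between SAG genomes
#'   of the same strain (cell-to-cell microdiversity).
#' @param sags_per_strain SAGs simulated per strain.
#' @param target_completeness Retained genome fraction per SAG: a scalar, a
#'   `c(lo, hi)` range sampled uniformly per SAG, or one value per SAG.
#' @param read_length Read length in bp (>= 50).
#' @param mean_depth Mean fold-coverage over retained loci.
#' @param lognormal_sigma Sigma of the lognormal per-window depth (MDA
#'   amplification bias; 0 = uniform coverage).
#' @param error_rate Per-base substitution error rate of reads.
#' @param chimera_rate Fraction of genomic reads that are chimeric junctions.
#' @param contam_rate Fraction of reads drawn from an unrelated species.
#' @param host_decoy_rate Fraction of reads drawn from the host decoy genome.
#' @param n_markers Number of planted 900-bp single-copy marker tags.
#' @param marker_length Marker tag length in bp.
#' @param dropout_window Dropout window length in bp (the MDA locus unit).
#' @param degraded_fraction Fraction of reads given a low-quality (Q2) tail,
#'   to exercise read QC.
#' @param seed Base RNG seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(genome_length = 200000, gc_content = 0.5,
                              n_strains = 3, between_strain_ani = 0.97,
                              within_strain_identity = 0.999,
                              sags_per_strain = 4,
                              target_completeness = c(0.5, 1.0),
                              read_length = 150, mean_depth = 20,
                              lognormal_sigma = 0.8, error_rate = 0.005,
                              chimera_rate = 0.02, contam_rate = 0.01,
                              host_decoy_rate = 0.01, n_markers = 100,
                              marker_length = 900, dropout_window = 5000,
                              degraded_fraction = 0, seed = 1) {
  cfg <- list(genome_length = as.integer(genome_length), gc_content = gc_content,
              n_strains = as.integer(n_strains),
              between_strain_ani = between_strain_ani,
              within_strain_identity = within_strain_identity,
              sags_per_strain = as.integer(sags_per_strain),
              target_completeness = target_completeness,
              read_length = as.integer(read_length), mean_depth = mean_depth,
              lognormal_sigma = lognormal_sigma, error_rate = error_rate,
              chimera_rate = chimera_rate, contam_rate = contam_rate,
              host_decoy_rate = host_decoy_rate, n_markers = as.integer(n_markers),
              marker_length = as.integer(marker_length),
              dropout_window = as.integer(dropout_window),
              degraded_fraction = degraded_fraction, seed = as.integer(seed))
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid simulation config: ", msg, call. = FALSE)
  if (cfg$genome_length < 10000) stop_cfg("genome_length must be >= 10,000 bp")
  if (cfg$read_length < 50) stop_cfg("read_length must be >= 50 bp")
  if (cfg$gc_content < 0 || cfg$gc_content > 1) stop_cfg("gc_content must be in [0,1]")
  if (cfg$mean_depth < 0) stop_cfg("mean_depth must be >= 0")
  rates <- c(cfg$error_rate, cfg$chimera_rate, cfg$contam_rate,
             cfg$host_decoy_rate, cfg$degraded_fraction, cfg$target_completeness)
  if (any(rates < 0 | rates > 1)) stop_cfg("all rates/fractions must be in [0,1]")
  if (is.matrix(cfg$between_strain_ani)) {
    m <- cfg$between_strain_ani
    if (!isSymmetric(m) || any(diag(m) != 1))
      stop_cfg("target ANI matrix must be symmetric with unit diagonal")
    if (any(m < 0.90)) stop_cfg("target ANI must be >= 0.90")
  } else if (cfg$between_strain_ani < 0.90 || cfg$between_strain_ani > 1) {
    stop_cfg("between_strain_ani must be in [0.90, 1]")
  }
  if (cfg$within_strain_identity < 0.99 || cfg$within_strain_identity > 1)
    stop_cfg("within_strain_identity must be in [0.99, 1]")
  if (cfg$n_markers * cfg$marker_length > 0.8 * cfg$genome_length)
    stop_cfg("markers would occupy > 80% of the genome; reduce n_markers")
  invisible(cfg)
}

#' Simulate an ancestral genome
#'
#' @param length Genome length in bp (>= 10,000).
#' @param gc Expected G+C fraction.
#' @param seed RNG seed; fixed seed gives a byte-identical genome.
#' @return A single-contig [genome_assembly()].
#' @export
simulate_ancestor <- function(length, gc, seed) {
  if (length < 10000) stop("invalid simulation config: length must be >= 10,000 bp")
  if (gc < 0 || gc > 1) stop("invalid simulation config: gc must be in [0,1]")
  seq <- with_seed(seed, random_dna(length, gc))
  genome_assembly("ancestor", c(genome = seq), source = "reference")
}

# Substitute each selected site with a uniformly chosen different base.
mutate_sequence <- function(seq, rate) {
  L <- nchar(seq)
  n <- rbinom(1, L, rate)
  if (n == 0) return(seq)
  pos <- sort(sample.int(L, n))
  cur <- substring(seq, pos, pos)
  alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                nrow = 3, dimnames = list(NULL, c("A","C","G","T")))
  new <- alt[cbind(sample.int(3, n, replace = TRUE), match(cur, c("A","C","G","T")))]
  cpp_substitute(seq, rep.int(1L, n), as.integer(pos), new)[[1]]
}

#' Derive a genome at a target nucleotide identity
#'
#' Substitutions are placed uniformly at per-site rate `1 - target_identity`
#' (no indels), so alignment-free site identity equals the target up to
#' binomial error.
#'
#' @param base A [genome_assembly()].
#' @param target_identity Fraction in `[0.90, 1]`.
#' @param seed RNG seed.
#' @return The derived `genome_assembly`.
#' @export
mutate_to_ani <- function(base, target_identity, seed) {
  if (target_identity < 0.90 || target_identity > 1)
    stop("target_identity must be in [0.90, 1]")
  if (target_identity == 1) return(base)
  out <- base
  out$contigs <- with_seed(seed, {
    setNames(vapply(base$contigs, mutate_sequence, character(1),
                    rate = 1 - target_identity), names(base$contigs))
  })
  out
}

#' Plant single-copy marker tags into a genome
#'
#' Writes `n_markers` random unique tags of `marker_length` bp at uniformly
#' placed non-overlapping loci of the (single-contig) genome. The tags play
#' the role of universal single-copy marker genes: the marker FASTA plus the
#' recorded loci give downstream completeness/contamination estimation a
#' fully known truth.
#'
#' @param asm Single-contig `genome_assembly`.
#' @param n_markers,marker_length Number and length of tags.
#' @param gc G+C fraction of the tags (match the genome's to keep
#'   composition signatures undisturbed).
#' @param seed RNG seed.
#' @return List with `assembly` (tags planted), `markers` (named character
#'   vector `marker001`...), `positions` (data frame of 1-based loci).
#' @export
plant_markers <- function(asm, n_markers = 100, marker_length = 900, gc = 0.5, seed = 1) {
  if (length(asm$contigs) != 1) stop("marker planting expects a single-contig genome")
  L <- nchar(asm$contigs[[1]])
  if (n_markers * marker_length > 0.8 * L) stop("markers would occupy > 80% of the genome")
  with_seed(seed, {
    free <- L - n_markers * marker_length
    gaps <- sort(sample.int(free, n_markers))
    starts <- gaps + (seq_len(n_markers) - 1L) * marker_length
    tags <- vapply(seq_len(n_markers), function(i) random_dna(marker_length, gc),
                   character(1))
    names(tags) <- sprintf("marker%03d", seq_len(n_markers))
    seq <- asm$contigs[[1]]
    seq <- substitute_blocks(seq, starts, tags)
    out <- asm
    out$contigs[[1]] <- seq
    list(assembly = out, markers = tags,
         positions = data.frame(marker = names(tags), start = starts,
                                end = starts + marker_length - 1L))
  })
}

# Replace blocks of `seq` starting at 1-based `starts` with `tags`.
substitute_blocks <- function(seq, starts, tags) {
  for (i in seq_along(starts)) {
    substr(seq, starts[i], starts[i] + nchar(tags[i]) - 1L) <- tags[i]
  }
  seq
}

# Per-SAG dropout plan: drop whole windows until the retained fraction
# approximates the target; adjacent retained windows merge into contigs.
plan_dropout <- function(L, window, target_completeness) {
  starts <- seq(1L, L, by = window)
  ends <- pmin(starts + window - 1L, L)
  n <- length(starts)
  n_drop <- round((1 - target_completeness) * n)
  dropped <- if (n_drop > 0) sort(sample.int(n, n_drop)) else integer(0)
  keep <- setdiff(seq_len(n), dropped)
  list(win_start = starts, win_end = ends, kept = keep, dropped = dropped)
}

#' Simulate one SAG from a strain genome
#'
#' Emulates MDA single-cell artifacts: (i) whole dropout windows are removed
#' until the retained fraction matches the target completeness (the truth);
#' (ii) per-window depth is lognormal with mean `mean_depth`; (iii) reads get
#' uniform substitution errors; (iv) a `chimera_rate` fraction of genomic
#' reads are junctions of two loci (second segment from a random retained
#' locus and strand, junction recorded); (v) a `contam_rate` /
#' `host_decoy_rate` fraction of reads is replaced by reads from the
#' contaminant / host decoy genome. The SAG assembly is the retained windows
#' merged into contigs (assembly from reads is out of scope), so true
#' completeness is exact.
#'
#' @param strain Single-contig strain (or SAG) genome.
#' @param cfg A [simulation_config()].
#' @param sag_seed RNG seed for this SAG.
#' @param sag_id,strain_id Identifiers recorded in the truth manifest.
#' @param target_completeness Retained fraction for this SAG.
#' @param contaminant,decoy Optional `genome_assembly` sources of
#'   contaminant / host reads.
#' @return List with `assembly`, `reads` (a [read_set()]), `manifest` (truth
#'   data frame), `dropped` (dropped window intervals), `true_completeness`.
#' @export
simulate_sag <- function(strain, cfg, sag_seed, sag_id = "sag1",
                         strain_id = "strain1",
                         target_completeness = 0.8,
                         contaminant = NULL, decoy = NULL) {
  validate_simulation_config(unclass(cfg))
  genome <- strain$contigs[[1]]
  L <- nchar(genome)
  RL <- cfg$read_length
  with_seed(sag_seed, {
    plan <- plan_dropout(L, cfg$dropout_window, target_completeness)
    kept <- plan$kept
    true_comp <- sum(plan$win_end[kept] - plan$win_start[kept] + 1) / L

    # contigs: merge runs of adjacent kept windows
    contigs <- character(0); offsets <- integer(0)
    if (length(kept) > 0) {
      runs <- split(kept, cumsum(c(1, diff(kept) != 1)))
      contigs <- vapply(runs, function(r)
        substr(genome, plan$win_start[r[1]], plan$win_end[r[length(r)]]), character(1))
      offsets <- vapply(runs, function(r) plan$win_start[r[1]], integer(1))
      names(contigs) <- sprintf("%s_c%03d", sag_id, seq_along(contigs))
    }
    asm <- genome_assembly(sag_id, contigs, source = "sag")
    attr(asm, "offsets") <- data.frame(contig = names(contigs), genome_start = offsets)

    # reads per kept window: lognormal depth, positions uniform inside the window
    # mean_depth = 0 requests an assembly-only SAG (no reads)
    mu <- if (cfg$mean_depth > 0) log(cfg$mean_depth) - cfg$lognormal_sigma^2 / 2 else -Inf
    rstart <- integer(0)
    for (w in if (cfg$mean_depth > 0) kept else integer(0)) {
      wlen <- plan$win_end[w] - plan$win_start[w] + 1L
      if (wlen < RL) next
      depth <- rlnorm(1, meanlog = mu, sdlog = cfg$lognormal_sigma)
      nr <- round(depth * wlen / RL)
      if (nr <= 0) next
      rstart <- c(rstart, plan$win_start[w] + sample.int(wlen - RL + 1L, nr, replace = TRUE) - 1L)
    }
    n <- length(rstart)
    if (n == 0) {
      list(assembly = asm,
           reads = read_set(character(0), character(0), character(0),
                            sag_id = sag_id),
           manifest = empty_manifest(), dropped = dropped_df(plan, sag_id),
           true_completeness = true_comp)
    } else {
    seqs <- substring(genome, rstart, rstart + RL - 1L)
    man <- data.frame(read_id = sprintf("%s_r%06d", sag_id, seq_len(n)),
                      sag_id = sag_id, strain_id = strain_id,
                      origin_contig = "genome",
                      origin_start = rstart - 1L, origin_end = rstart + RL - 1L,
                      is_chimeric = FALSE, junction_pos = NA_integer_,
                      is_contaminant = FALSE, is_host = FALSE,
                      stringsAsFactors = FALSE)

    # chimeras: junction uniform in [0.25, 0.75] of the read; second segment
    # from a uniformly chosen retained locus and strand
    chim <- which(runif(n) < cfg$chimera_rate)
    kept_long <- kept[plan$win_end[kept] - plan$win_start[kept] + 1L >= RL]
    if (length(chim) > 0 && length(kept_long) > 0) {
      for (i in chim) {
        j <- round(runif(1, 0.25, 0.75) * RL)          # second segment starts at j (0-based)
        seg_len <- RL - j
        w2 <- kept_long[sample.int(length(kept_long), 1)]
        wlen2 <- plan$win_end[w2] - plan$win_start[w2] + 1L
        s2 <- plan$win_start[w2] + sample.int(wlen2 - seg_len + 1L, 1) - 1L
        frag <- substr(genome, s2, s2 + seg_len - 1L)
        if (runif(1) < 0.5) frag <- revcomp(frag)
        seqs[i] <- paste0(substr(seqs[i], 1L, j), frag)
        man$is_chimeric[i] <- TRUE
        man$junction_pos[i] <- j
        man$origin_end[i] <- man$origin_start[i] + j
      }
    }

    # contaminant / host replacement reads
    repl <- runif(n)
    host_idx <- which(repl < cfg$host_decoy_rate)
    contam_idx <- which(repl >= cfg$host_decoy_rate &
                        repl < cfg$host_decoy_rate + cfg$contam_rate)
    replace_from <- function(idx, src, label, flag) {
      if (length(idx) == 0 || is.null(src)) return()
      g <- src$contigs[[1]]
      gl <- nchar(g)
      st <- sample.int(gl - RL + 1L, length(idx), replace = TRUE)
      seqs[idx] <<- substring(g, st, st + RL - 1L)
      man$origin_contig[idx] <<- label
      man$origin_start[idx] <<- st - 1L
      man$origin_end[idx] <<- st + RL - 1L
      man$is_chimeric[idx] <<- FALSE
      man$junction_pos[idx] <<- NA_integer_
      man[[flag]][idx] <<- TRUE
    }
    replace_from(host_idx, decoy, "host", "is_host")
    replace_from(contam_idx, contaminant, "contaminant", "is_contaminant")

    # substitution errors
    nerr <- rbinom(n, nchar(seqs), cfg$error_rate)
    has <- which(nerr > 0)
    if (length(has) > 0) {
      idx <- rep.int(has, nerr[has])
      pos <- unlist(lapply(has, function(i) sample.int(nchar(seqs[i]), nerr[i])))
      cur <- substring(seqs[idx], pos, pos)
      alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                    nrow = 3, dimnames = list(NULL, c("A","C","G","T")))
      new <- alt[cbind(sample.int(3, length(idx), replace = TRUE),
                       match(cur, c("A","C","G","T")))]
      seqs <- cpp_substitute(seqs, as.integer(idx), as.integer(pos), new)
    }

    # qualities: constant Q30, with an optional degraded low-quality tail
    qual <- strrep(rawToChar(as.raw(30 + 33)), nchar(seqs))
    if (cfg$degraded_fraction > 0) {
      deg <- which(runif(n) < cfg$degraded_fraction)
      for (i in deg) {
        tl <- sample(10:max(10, nchar(seqs[i]) %/% 2), 1)
        keep <- nchar(seqs[i]) - tl
        qual[i] <- paste0(strrep(rawToChar(as.raw(30 + 33)), keep),
                          strrep(rawToChar(as.raw(2 + 33)), tl))
      }
    }

    list(assembly = asm,
         reads = read_set(man$read_id, seqs, qual, sag_id = sag_id),
         manifest = man, dropped = dropped_df(plan, sag_id),
         true_completeness = true_comp)
    }
  })
}

empty_manifest <- function() {
  data.frame(read_id = character(0), sag_id = character(0), strain_id = character(0),
             origin_contig = character(0), origin_start = integer(0),
             origin_end = integer(0), is_chimeric = logical(0),
             junction_pos = integer(0), is_contaminant = logical(0),
             is_host = logical(0), stringsAsFactors = FALSE)
}

dropped_df <- function(plan, sag_id) {
  d <- plan$dropped
  data.frame(sag_id = rep(sag_id, length(d)),
             start = plan$win_start[d] - 1L, end = plan$win_end[d],
             stringsAsFactors = FALSE)
}

sample_completeness <- function(x, n) {
  if (length(x) == 1) rep(x, n)
  else if (length(x) == 2) runif(n, x[1], x[2])
  else if (length(x) == n) x
  else stop("target_completeness must be a scalar, a range, or one value per SAG")
}

#' Simulate a cohort of hosts with strain-structured SAGs
#'
#' All strains descend from one ancestral species genome with planted marker
#' tags; each host carries `n_strains` strains at the configured
#' between-strain identity, and `shared_strains` strain(s) are carried by the
#' first two hosts (the cohabiting-host scenario). Each strain yields
#' `sags_per_strain` SAGs with independent dropout, coverage bias, errors,
#' chimeras and contamination.
#'
#' @param cfg A [simulation_config()].
#' @param n_hosts Number of hosts.
#' @param shared_strains Number of strains shared between hosts 1 and 2.
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return A list of class `sag_cohort`: `cfg`, `markers`, `marker_positions`,
#'   `decoy`, `contaminant`, `hosts` (per host: list of SAG simulations),
#'   `truth` (sag_id, host_id, strain_id, true_completeness), `manifest`.
#' @export
simulate_cohort <- function(cfg = simulation_config(), n_hosts = 2,
                            shared_strains = 0, seed = cfg$seed) {
  validate_simulation_config(unclass(cfg))
  if (shared_strains > 0 && n_hosts < 2) stop("shared strains need >= 2 hosts")
  if (shared_strains > cfg$n_strains) stop("shared_strains must be <= n_strains")
  anc <- simulate_ancestor(cfg$genome_length, cfg$gc_content, derive_seed(seed, 1))
  pl <- plant_markers(anc, cfg$n_markers, cfg$marker_length, cfg$gc_content,
                      derive_seed(seed, 2))
  contaminant <- simulate_ancestor(50000, 0.60, derive_seed(seed, 3))
  decoy <- simulate_ancestor(50000, 0.41, derive_seed(seed, 4))

  n_distinct <- n_hosts * cfg$n_strains - shared_strains
  d <- (1 - scalar_ani(cfg$between_strain_ani)) / 2
  strain_genomes <- lapply(seq_len(n_distinct), function(i) {
    g <- mutate_to_ani(pl$assembly, 1 - d, derive_seed(seed, 10 + i))
    g$sag_id <- sprintf("strain%02d", i)
    g
  })
  names(strain_genomes) <- sprintf("strain%02d", seq_len(n_distinct))

  # host -> strain assignment; shared strains go to hosts 1 and 2
  assign <- vector("list", n_hosts)
  nxt <- shared_strains + 1L
  for (h in seq_len(n_hosts)) {
    own <- cfg$n_strains - if (h <= 2) shared_strains else 0L
    ids <- integer(0)
    if (h <= 2 && shared_strains > 0) ids <- seq_len(shared_strains)
    if (own > 0) { ids <- c(ids, seq(nxt, nxt + own - 1L)); nxt <- nxt + own }
    assign[[h]] <- sprintf("strain%02d", ids)
  }

  hosts <- list(); truth <- list(); manifest <- list()
  ctr <- 100L
  d_within <- (1 - cfg$within_strain_identity) / 2
  for (h in seq_len(n_hosts)) {
    host_id <- sprintf("H%02d", h)
    sags <- list()
    comp <- with_seed(derive_seed(seed, 50 + h),
                      sample_completeness(cfg$target_completeness,
                                          cfg$n_strains * cfg$sags_per_strain))
    k <- 0L
    for (st in assign[[h]]) {
      for (r in seq_len(cfg$sags_per_strain)) {
        k <- k + 1L; ctr <- ctr + 1L
        sag_id <- sprintf("%s_S%02d", host_id, k)
        cell <- mutate_to_ani(strain_genomes[[st]], 1 - d_within,
                              derive_seed(seed, ctr))
        ctr <- ctr + 1L
        sim <- simulate_sag(cell, cfg, derive_seed(seed, ctr), sag_id = sag_id,
                            strain_id = st, target_completeness = comp[k],
                            contaminant = contaminant, decoy = decoy)
        sags[[sag_id]] <- sim
        truth[[sag_id]] <- data.frame(sag_id = sag_id, host_id = host_id,
                                      strain_id = st,
                                      true_completeness = sim$true_completeness,
                                      stringsAsFactors = FALSE)
        manifest[[sag_id]] <- sim$manifest
      }
    }
    hosts[[host_id]] <- list(host_id = host_id, sags = sags)
  }
  structure(list(cfg = cfg, markers = pl$markers, marker_positions = pl$positions,
                 strains = strain_genomes, decoy = decoy, contaminant = contaminant,
                 hosts = hosts, truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
                 manifest = do.call(rbind, c(manifest, list(make.row.names = FALSE)))),
            class = "sag_cohort")
}

scalar_ani <- function(x) if (is.matrix(x)) mean(x[upper.tri(x)]) else x

#' @export
print.sag_cohort <- function(x, ...) {
  cat(sprintf("<sag_cohort> %d host(s), %d SAG(s), %d strain genome(s), %d marker tags\n",
              length(x$hosts), nrow(x$truth), length(x$strains), length(x$markers)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits per-SAG assembly FASTA and read FASTQ, the marker and decoy FASTA,
#' the truth manifest TSV and a YAML echo of the configuration.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (h in cohort$hosts) {
    for (sag_id in names(h$sags)) {
      sim <- h$sags[[sag_id]]
      write_assembly_fasta(sim$assembly, file.path(outdir, paste0(sag_id, ".fa")))
      write_fastq(sim$reads, file.path(outdir, paste0(sag_id, ".fastq")))
    }
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cohort$markers),
                              file.path(outdir, "markers.fa"))
  write_assembly_fasta(cohort$decoy, file.path(outdir, "decoy.fa"))
  man <- cohort$manifest
  man$junction_pos[is.na(man$junction_pos)] <- ""
  write.table(man, file.path(outdir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(cohort$cfg), file.path(outdir, "config.yaml"))
  invisible(outdir)
}
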