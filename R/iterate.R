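# Iterative separation: Hamming rates between reads and tentative
# haplotypes drive the decision whether another diploid separation round
# is worthwhile, globally and per sequence.

#' Hamming records of reads against phased haplotypes
#'
#' For every read whose alignment overlaps a phaseset interval by at least
#' `min_overlap` bp and that shares at least one phased SNV position, the
#' Hamming rate is the number of mismatching shared positions divided by
#' the number of shared positions, taken against the closer of the two
#' haplotypes.
#'
#' @param phasesets [extract_phasesets()] result for one contig.
#' @param matrix The matching `read_snv_matrix`.
#' @param min_overlap Minimum read/phaseset overlap in bp (default 3000;
#'   strictly smaller overlaps are excluded).
#' @return Data frame: `read_id`, `sequence_id`, `shared_sites`,
#'   `mismatch_h1`, `mismatch_h2`, `rate`.
#' @export
hamming_records <- function(phasesets, matrix, min_overlap = 3000) {
  empty <- data.frame(read_id = character(0), sequence_id = character(0),
                      shared_sites = integer(0), mismatch_h1 = integer(0),
                      mismatch_h2 = integer(0), rate = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(phasesets) == 0) return(empty)
  reads <- matrix$reads
  out <- list()
  for (i in seq_len(nrow(phasesets))) {
    ps <- phasesets[i, ]
    ov <- pmin(reads$end, ps$e + 1L) - pmax(reads$start, ps$s)
    sel <- which(ov >= min_overlap)
    if (!length(sel)) next
    site_idx <- which(matrix$sites$pos >= ps$s & matrix$sites$pos <= ps$e)
    ent <- matrix$entries[matrix$entries$site %in% site_idx &
                            matrix$entries$read %in% sel, ]
    if (!nrow(ent)) next
    h <- ps$h1[[1]]
    mism <- as.integer(ent$allele != h[match(ent$site, site_idx)])
    d1 <- rowsum(mism, ent$read)
    tot <- rowsum(rep(1L, nrow(ent)), ent$read)
    ridx <- as.integer(rownames(d1))
    out[[length(out) + 1]] <- data.frame(
      read_id = reads$read_id[ridx], sequence_id = ps$contig,
      shared_sites = tot[, 1], mismatch_h1 = d1[, 1],
      mismatch_h2 = tot[, 1] - d1[, 1],
      rate = pmin(d1[, 1], tot[, 1] - d1[, 1]) / tot[, 1],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Decide whether another separation round should run
#'
#' @param previous Global mean Hamming rate of the previous round, or
#'   `NULL`/`NA` on the first round.
#' @param current Global mean Hamming rate of the tentative phasing.
#' @param improvement_frac Required relative improvement (default 0.01:
#'   the current rate must be at most 99% of the previous one).
#' @return `TRUE` to iterate again.
#' @export
should_iterate <- function(previous, current,
                           improvement_frac = 0.01) {
  if (is.null(previous) || is.na(previous)) return(TRUE)
  if (is.na(current)) return(FALSE)
  current <= previous * (1 - improvement_frac)
}

#' Select sequences whose Hamming rate improves locally
#'
#' Applies the same relative-improvement rule per sequence; sequences
#' absent from the previous round (newly created scaffolds) are eligible
#' by convention, others pass through unchanged.
#'
#' @param previous Named numeric vector of per-sequence mean rates from
#'   the previous round (or `NULL`).
#' @param current Named numeric vector for the current tentative phasing.
#' @param improvement_frac See [should_iterate()].
#' @return Character vector of sequence ids to re-separate.
#' @export
select_sequences <- function(previous, current,
                             improvement_frac = 0.01) {
  if (is.null(previous)) return(names(current))
  keep <- vapply(names(current), function(id) {
    if (!id %in% names(previous)) return(TRUE)
    should_iterate(previous[[id]], current[[id]], improvement_frac)
  }, TRUE)
  names(current)[keep]
}

# One tentative phasing pass over an assembly: SNVs, matrices, phasesets
# and Hamming summaries per contig.
phase_assembly <- function(assembly, alignments, config) {
  phasesets <- list()
  matrices <- list()
  ham <- list()
  for (contig in names(assembly)) {
    sites <- detect_snvs(alignments, assembly, contig,
                         min_depth = config$min_depth,
                         min_alt_frac = config$min_alt_frac,
                         min_per_allele = config$min_per_allele)
    mat <- snv_matrix(alignments, sites, contig)
    blocks <- phase_diploid(mat)
    ps <- extract_phasesets(blocks, min_dens = config$min_dens)
    phasesets[[contig]] <- ps
    matrices[[contig]] <- mat
    ham[[contig]] <- hamming_records(ps, mat,
                                     min_overlap = config$hamming_min_overlap)
  }
  records <- do.call(rbind, ham)
  per_seq <- if (!is.null(records) && nrow(records)) {
    tapply(records$rate, records$sequence_id, mean)
  } else numeric(0)
  list(phasesets = phasesets, matrices = matrices,
       hamming = records,
       global_rate = if (!is.null(records) && nrow(records)) {
         mean(records$rate)
       } else NA_real_,
       per_sequence_rate = setNames(as.numeric(per_seq), names(per_seq)))
}

# Separation + scaffolding of one assembly given its tentative phasing.
separate_and_scaffold <- function(assembly, alignments, phased, reads_fa,
                                  config, sequences = names(assembly)) {
  phasesets <- phased$phasesets
  # untouched sequences pass through unchanged (no phasesets)
  for (contig in setdiff(names(assembly), sequences)) {
    phasesets[[contig]] <- phasesets[[contig]][0, , drop = FALSE]
  }
  contigs <- build_contig_set(assembly, phasesets, phased$matrices,
                              alignments, min_cov = config$min_cov,
                              min_len = config$min_unphased_len,
                              external_cmd = config$external_assembler)
  paf <- align_reads(reads_fa, contigs$seqs, preset = config$preset,
                     format = "paf", threads = config$threads)
  dov <- filter_dovetails(paf, min_mapq = config$min_mapq,
                          max_overhang = config$max_overhang,
                          overhang_frac = config$overhang_frac)
  graph <- build_graph(dov, contigs,
                       setNames(nchar(assembly), names(assembly)),
                       end_window = config$end_window)
  graph <- remove_transitive_edges(graph)
  graph <- remove_weak_edges(graph, min_reads = config$weak_edge_min_reads,
                             frac = config$weak_edge_frac)
  scaf <- traverse_paths(graph, contigs$seqs)
  # singleton pass-through scaffolds keep their backbone contig id, so
  # per-sequence Hamming comparison across rounds stays meaningful
  lay <- scaf$layout
  singles <- names(which(table(lay$scaffold) == 1))
  for (sc in singles) {
    ctg <- lay$contig[lay$scaffold == sc]
    inf <- contigs$info[contigs$info$id == ctg, ]
    if (inf$kind == "unphased-backbone" && inf$origin_start == 0 &&
          inf$origin_end == nchar(assembly[[inf$origin_contig]]) &&
          !inf$origin_contig %in% lay$scaffold) {
      names(scaf$seqs)[names(scaf$seqs) == sc] <- inf$origin_contig
      lay$scaffold[lay$scaffold == sc] <- inf$origin_contig
    }
  }
  scaf$layout <- lay
  list(contigs = contigs, graph = graph, scaffolds = scaf)
}

#' Run the full iterative strain-separation pipeline
#'
#' Executes phase -> separate -> assemble -> scaffold, then re-aligns the
#' reads to the current scaffolds, re-phases tentatively and repeats while
#' the global mean Hamming rate improves by at least
#' `config$improvement_frac` (relative) and fewer than `max_strains - 1`
#' rounds have run.  Later rounds re-separate only sequences whose local
#' mean Hamming rate improves.
#'
#' @param assembly Strain-oblivious assembly: named character vector or a
#'   FASTA path.
#' @param alignments Position-sorted read alignments against `assembly`:
#'   alignment records, or a SAM/indexed-BAM path.
#' @param max_strains Maximal number of conspecific strains n; the
#'   pipeline performs at most n - 1 separation rounds (default 5).
#' @param seed Integer seed (the core is deterministic; the seed also
#'   feeds any downstream randomized hooks).
#' @param config A [pipeline_config()] list.
#' @param out_dir Optional output directory; when given, per-iteration
#'   subdirectories with FASTA/VCF/AGP/GFA dumps, the resolved config, a
#'   summary TSV and a log are written.
#' @return List with `assembly` (final named character vector),
#'   `scaffolds`, `contigs`, `iterations` (per-round summaries) and
#'   `config`.
#' @export
run_pipeline <- function(assembly, alignments, max_strains = 5, seed = 1,
                         config = pipeline_config(), out_dir = NULL) {
  if (max_strains < 2) stop("max_strains must be at least 2")
  if (is.character(assembly) && length(assembly) == 1 &&
        file.exists(assembly)) {
    assembly <- read_fasta(assembly)
  }
  if (is.character(alignments) && length(alignments) == 1) {
    alignments <- read_alignments(alignments)  # errors early if unindexed
  }
  config$max_strains <- max_strains
  config$seed <- seed
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(config, file.path(out_dir, "config.txt"))
  }
  log_lines <- character(0)
  logmsg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    paste0(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  # reads (as sequenced) recovered from the primary input alignments
  prim <- alignments[alignments$primary, ]
  reads <- setNames(ifelse(prim$strand == "-", revcomp(prim$seq),
                           prim$seq), prim$read_id)
  reads_fa <- tempfile(fileext = ".fasta")
  write_fasta(reads, reads_fa)
  on.exit(unlink(reads_fa))

  cur_assembly <- assembly
  cur_alignments <- alignments
  prev_rate <- NULL
  prev_per_seq <- NULL
  iterations <- list()
  result <- NULL
  iter <- 0
  with_seed(seed, repeat {
    phased <- phase_assembly(cur_assembly, cur_alignments, config)
    n_ps <- sum(vapply(phased$phasesets, nrow, 0L))
    logmsg("iteration ", iter + 1, ": ", n_ps, " phaseset(s), ",
           "mean Hamming rate ",
           formatC(phased$global_rate, digits = 4, format = "f"))
    if (!should_iterate(prev_rate, phased$global_rate,
                        config$improvement_frac)) {
      logmsg("Hamming rate no longer improves by ",
             100 * config$improvement_frac, "%; stopping")
      break
    }
    sequences <- select_sequences(prev_per_seq, phased$per_sequence_rate,
                                  config$improvement_frac)
    active <- names(cur_assembly)[names(cur_assembly) %in% sequences]
    has_ps <- vapply(phased$phasesets[active], nrow, 0L) > 0
    if (n_ps == 0 || !any(has_ps)) {
      logmsg("no separable sequence; output equals current assembly")
      break
    }
    step <- separate_and_scaffold(cur_assembly, cur_alignments, phased,
                                  reads_fa, config, sequences = active)
    iter <- iter + 1
    iterations[[iter]] <- list(
      iteration = iter, phasesets = n_ps,
      hamming_rate = phased$global_rate,
      n_contigs = nrow(step$contigs$info),
      n_scaffolds = length(step$scaffolds$seqs),
      total_bp = sum(nchar(step$scaffolds$seqs)))
    result <- step
    if (!is.null(out_dir)) {
      idir <- file.path(out_dir, sprintf("iteration_%d", iter))
      dir.create(idir, showWarnings = FALSE)
      write_fasta(step$scaffolds$seqs, file.path(idir, "scaffolds.fasta"))
      write_agp(step$scaffolds, step$contigs$seqs,
                file.path(idir, "scaffolds.agp"))
      write_gfa(step$graph, NULL, file.path(idir, "graph.gfa"))
      for (contig in names(phased$phasesets)) {
        ps <- phased$phasesets[[contig]]
        if (nrow(ps)) {
          write_phased_vcf(ps, phased$matrices[[contig]]$sites,
                           file.path(idir, paste0(contig, ".phased.vcf")))
        }
      }
    }
    prev_rate <- phased$global_rate
    prev_per_seq <- phased$per_sequence_rate
    if (iter >= max_strains - 1) {
      logmsg("reached the maximum of ", max_strains - 1, " iteration(s)")
      break
    }
    cur_assembly <- step$scaffolds$seqs
    cur_alignments <- align_reads(reads_fa, cur_assembly,
                                  preset = config$preset, format = "sam",
                                  threads = config$threads)
    logmsg("re-aligned ", sum(cur_alignments$primary),
           " reads to ", length(cur_assembly), " scaffold(s)")
  })
  final <- if (is.null(result)) assembly else result$scaffolds$seqs
  out <- list(assembly = final,
              scaffolds = if (is.null(result)) NULL else result$scaffolds,
              contigs = if (is.null(result)) NULL else result$contigs,
              iterations = iterations, config = config)
  if (!is.null(out_dir)) {
    write_fasta(final, file.path(out_dir, "assembly.fasta"))
    summ <- do.call(rbind, lapply(iterations, as.data.frame))
    if (is.null(summ)) {
      summ <- data.frame(iteration = integer(0), phasesets = integer(0),
                         hamming_rate = numeric(0), n_contigs = integer(0),
                         n_scaffolds = integer(0), total_bp = integer(0))
    }
    write.table(summ, file.path(out_dir, "summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  }
  out
}
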