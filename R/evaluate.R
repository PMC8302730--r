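# Reference-based assembly evaluation: best-reference assignment,
# reference coverage, ANI, NG50 and duplication ratio.
#
# The metrics mirror the standard strain-aware reading of assembly
# statistics: a duplication ratio near k over a single reference simply
# indicates k resolved strains, and identity against a consensus
# reference is expected to drop when strains are separated.  Alignments
# come from minimap2 (`-x asm20`, one run per reference so every
# contig/reference pair is chained independently) or can be ingested as a
# pre-computed mapping table.

#' Assign contigs to their closest reference
#'
#' A contig is assignable to a reference when the union of its aligned
#' bases covers at least half of its length; among assignable references
#' the one maximising score = alignedBases x averageIdentity wins (ties
#' broken by lexicographically smaller reference id).
#'
#' @param alignments Mapping table ([read_paf] layout) of contigs
#'   (queries) against references (targets).
#' @param contig_lengths Named integer vector of contig lengths.
#' @param min_aligned_frac Assignment threshold (default 0.5).
#' @return Data frame: `contig_id`, `reference_id` (NA when unassigned),
#'   `aligned_bases`, `average_identity`, `score`.
#' @export
assign_to_reference <- function(alignments, contig_lengths,
                                min_aligned_frac = 0.5) {
  out <- data.frame(contig_id = names(contig_lengths),
                    reference_id = NA_character_,
                    aligned_bases = 0L, average_identity = NA_real_,
                    score = NA_real_, stringsAsFactors = FALSE)
  if (nrow(alignments) == 0) return(out)
  key <- paste(alignments$query, alignments$target, sep = "\r")
  for (k in unique(key)) {
    sel <- alignments[key == k, ]
    q <- sel$query[1]
    if (!q %in% names(contig_lengths)) next
    aligned <- interval_union_length(sel$qstart, sel$qend)
    if (aligned < min_aligned_frac * contig_lengths[[q]]) next
    identity <- sum(sel$nmatch) / sum(sel$blocklen)
    score <- aligned * identity
    i <- match(q, out$contig_id)
    better <- is.na(out$score[i]) || score > out$score[i] ||
      (score == out$score[i] && sel$target[1] < out$reference_id[i])
    if (better) {
      out$reference_id[i] <- sel$target[1]
      out$aligned_bases[i] <- aligned
      out$average_identity[i] <- identity
      out$score[i] <- score
    }
  }
  out
}

#' NG50 of a contig length set
#'
#' The largest length L such that contigs of length at least L together
#' cover at least half of the genome size.  With `genome_size` equal to
#' the total assembly length this is the ordinary N50.
#'
#' @param contig_lengths Integer vector of contig lengths (bp).
#' @param genome_size Known genome length (bp).
#' @return NG50 in bp; 0 with a warning when the contigs sum to less than
#'   half the genome.
#' @export
ng50 <- function(contig_lengths, genome_size) {
  stopifnot(genome_size > 0)
  lens <- sort(as.numeric(contig_lengths), decreasing = TRUE)
  cum <- cumsum(lens)
  hit <- which(cum >= genome_size / 2)
  if (!length(hit)) {
    warning("assembly covers less than half of the genome size; NG50 = 0")
    return(0)
  }
  lens[hit[1]]
}

#' Duplication ratio of an alignment set
#'
#' Total assembly bases in alignments (with multiplicity) divided by the
#' number of distinct reference bases covered at least once.  Roughly k
#' when k strains are resolved against a single reference.
#'
#' @param alignments Mapping table of (assigned) contigs against one
#'   reference.
#' @return The ratio, or `NA` with a warning when no reference base is
#'   covered.
#' @export
duplication_ratio <- function(alignments) {
  if (nrow(alignments) == 0 ||
        interval_union_length(alignments$tstart, alignments$tend) == 0) {
    warning("no reference bases covered; duplication ratio undefined")
    return(NA_real_)
  }
  sum(alignments$qend - alignments$qstart) /
    interval_union_length(alignments$tstart, alignments$tend)
}

#' Per-reference evaluation report
#'
#' For every reference: reference coverage (percent of reference bases in
#' the union of alignments of its assigned contigs), ANI
#' (alignment-length-weighted mean identity, percent), NG50 of the
#' assigned contigs against the reference length, duplication ratio and
#' assigned contig count; plus the overall unaligned assembly fraction.
#'
#' @param assignments [assign_to_reference()] result.
#' @param alignments The mapping table used for assignment.
#' @param ref_lengths Named integer vector of reference lengths.
#' @param contig_lengths Named integer vector of contig lengths.
#' @return List with `per_reference` (data frame) and
#'   `unaligned_assembly_frac`.
#' @export
reference_metrics <- function(assignments, alignments, ref_lengths,
                              contig_lengths) {
  rows <- lapply(names(ref_lengths), function(ref) {
    ctg <- assignments$contig_id[!is.na(assignments$reference_id) &
                                   assignments$reference_id == ref]
    aln <- alignments[alignments$target == ref &
                        alignments$query %in% ctg, , drop = FALSE]
    if (nrow(aln) == 0) {
      return(data.frame(reference_id = ref, coverage = 0, ani = NA_real_,
                        ng50 = 0, duplication_ratio = NA_real_,
                        assigned_contigs = 0L, stringsAsFactors = FALSE))
    }
    cov <- 100 * interval_union_length(aln$tstart, aln$tend) /
      ref_lengths[[ref]]
    ani <- 100 * sum(aln$nmatch) / sum(aln$blocklen)
    n50 <- suppressWarnings(ng50(contig_lengths[ctg], ref_lengths[[ref]]))
    dup <- suppressWarnings(duplication_ratio(aln))
    data.frame(reference_id = ref, coverage = cov, ani = ani, ng50 = n50,
               duplication_ratio = dup, assigned_contigs = length(ctg),
               stringsAsFactors = FALSE)
  })
  per_ref <- do.call(rbind, rows)
  aligned_per_contig <- vapply(names(contig_lengths), function(q) {
    sel <- alignments[alignments$query == q, , drop = FALSE]
    if (nrow(sel) == 0) return(0)
    min(interval_union_length(sel$qstart, sel$qend), contig_lengths[[q]])
  }, 0)
  unaligned <- 1 - sum(aligned_per_contig) / sum(contig_lengths)
  list(per_reference = per_ref, unaligned_assembly_frac = unaligned)
}

#' Evaluate an assembly against reference genomes
#'
#' Aligns contigs/scaffolds to every reference (minimap2 `-x asm20`, one
#' run per reference), assigns each contig to its closest reference and
#' computes the per-reference report.
#'
#' @param contigs Named character vector of assembly sequences, or a
#'   FASTA path.
#' @param references Named character vector of reference genomes, or a
#'   FASTA path.
#' @param preset minimap2 preset (default "asm20", suited to the up-to-5%
#'   divergence this pipeline targets).
#' @param alignments Optional pre-computed mapping table (skips the
#'   aligner; use [read_paf] layout).
#' @return List with `assignments`, `report` (see [reference_metrics()])
#'   and `alignments`.
#' @export
evaluate_assembly <- function(contigs, references, preset = "asm20",
                              alignments = NULL) {
  if (is.character(contigs) && length(contigs) == 1 &&
        file.exists(contigs)) {
    contigs <- read_fasta(contigs)
  }
  if (is.character(references) && length(references) == 1 &&
        file.exists(references)) {
    references <- read_fasta(references)
  }
  if (is.null(alignments)) {
    qf <- tempfile(fileext = ".fasta")
    write_fasta(contigs, qf)
    on.exit(unlink(qf))
    alignments <- do.call(rbind, lapply(names(references), function(ref) {
      tf <- tempfile(fileext = ".fasta")
      write_fasta(references[ref], tf)
      on.exit(unlink(tf), add = TRUE)
      minimap2_paf(qf, tf, preset = preset)
    }))
  }
  contig_lengths <- setNames(nchar(contigs), names(contigs))
  ref_lengths <- setNames(nchar(references), names(references))
  assignments <- assign_to_reference(alignments, contig_lengths)
  report <- reference_metrics(assignments, alignments, ref_lengths,
                              contig_lengths)
  list(assignments = assignments, report = report,
       alignments = alignments)
}

#' Write an evaluation report as TSV
#'
#' @param evaluation [evaluate_assembly()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(evaluation, path) {
  write.table(evaluation$report$per_reference, path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Ingest MUMmer show-coords-style tab output as a mapping table
#'
#' Expects `show-coords -T -l -c` column order: S1 E1 S2 E2 LEN1 LEN2
#' %IDY LENR LENQ COVR COVQ [tags] ref query.  Converted to the
#' [read_paf] layout (contigs as queries) so the evaluation operations
#' can run on externally produced whole-genome alignments.
#'
#' @param path show-coords tab output (no header lines).
#' @return Mapping table ([read_paf] layout).
#' @export
read_coords <- function(path) {
  lines <- readLines(path)
  lines <- lines[grepl("^[0-9]", lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  grab <- function(i) vapply(f, `[`, "", i)
  s1 <- as.integer(grab(1)); e1 <- as.integer(grab(2))
  s2 <- as.integer(grab(3)); e2 <- as.integer(grab(4))
  len1 <- as.integer(grab(5)); len2 <- as.integer(grab(6))
  idy <- as.numeric(grab(7))
  lenr <- as.integer(grab(8)); lenq <- as.integer(grab(9))
  ncol <- length(f[[1]])
  refid <- grab(ncol - 1); qid <- grab(ncol)
  strand <- ifelse(s2 <= e2, "+", "-")
  qs <- pmin(s2, e2) - 1L; qe <- pmax(s2, e2)
  data.frame(query = qid, qlen = lenq, qstart = qs, qend = qe,
             strand = strand, target = refid, tlen = lenr,
             tstart = s1 - 1L, tend = e1,
             nmatch = as.integer(round(len1 * idy / 100)),
             blocklen = pmax(len1, len2), mapq = 60L, primary = TRUE,
             stringsAsFactors = FALSE)
}
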