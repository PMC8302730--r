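# File formats: FASTA/FASTQ, SAM/BAM alignment records, PAF mappings.
#
# Alignment records are held in a plain data frame (class "sb_alignments")
# with columns: read_id, contig, pos (0-based leftmost reference position),
# strand ("+"/"-"), mapq, primary (logical), cigar, seq.  `seq` is always
# reference-oriented (reverse-complemented relative to the sequencer output
# for minus-strand records), which makes pileup and consensus independent of
# strand.

#' Read a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences (case preserved).
#' @export
read_fasta <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  setNames(as.character(x), ids)
}

#' Write sequences to FASTA (80-column wrapped)
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids")
  x <- Biostrings::BStringSet(unname(as.character(seqs)))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Write reads to FASTQ
#'
#' Qualities are constant placeholders; base qualities are not modelled by
#' the simulator.
#'
#' @param seqs Named character vector of read sequences (as sequenced).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0("@", names(seqs)[i]), seqs[[i]], "+",
                 strrep("I", nchar(seqs[[i]]))), con)
  }
  invisible(path)
}

new_alignments <- function(df) {
  need <- c("read_id", "contig", "pos", "strand", "mapq", "primary",
            "cigar", "seq")
  stopifnot(all(need %in% names(df)))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  class(df) <- c("sb_alignments", "data.frame")
  df
}

#' @export
print.sb_alignments <- function(x, ...) {
  cat("<sb_alignments> ", nrow(x), " records on ",
      length(unique(x$contig)), " contig(s)\n", sep = "")
  invisible(x)
}

#' Read alignments from a SAM/BAM file
#'
#' BAM files must be position-sorted and indexed (use `samtools sort` and
#' `samtools index`); SAM text files are parsed directly.  Secondary and
#' supplementary records are kept but flagged `primary = FALSE`; unmapped
#' records are dropped.
#'
#' @param path SAM or BAM file.
#' @param region Optional region as `list(contig =, start =, end =)`
#'   (0-based half-open), BAM only.
#' @return An alignment record data frame (see [new_alignments]).
#' @export
read_alignments <- function(path, region = NULL) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    if (!is.null(region)) stop("region queries require an indexed BAM file")
    return(read_sam(path))
  }
  bai <- paste0(path, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", path))) {
    stop("BAM index not found for ", path,
         "; create it with: samtools index ", path)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "mapq", "flag", "cigar", "seq"),
    which = if (is.null(region)) {
      GenomicRanges::GRanges()
    } else {
      GenomicRanges::GRanges(region$contig,
                             IRanges::IRanges(region$start + 1, region$end))
    })
  res <- Rsamtools::scanBam(path, param = param)
  recs <- do.call(rbind, lapply(res, function(r) {
    keep <- !is.na(r$pos)
    data.frame(read_id = r$qname[keep],
               contig = as.character(r$rname)[keep],
               pos = r$pos[keep] - 1L,
               strand = as.character(r$strand)[keep],
               mapq = r$mapq[keep],
               primary = bitwAnd(r$flag[keep], 0x900L) == 0L,
               cigar = r$cigar[keep],
               seq = as.character(r$seq)[keep],
               stringsAsFactors = FALSE)
  }))
  new_alignments(recs)
}

# Minimal SAM text parser (primary + secondary/supplementary, mapped only).
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) {
    return(new_alignments(data.frame(
      read_id = character(0), contig = character(0), pos = integer(0),
      strand = character(0), mapq = integer(0), primary = logical(0),
      cigar = character(0), seq = character(0), stringsAsFactors = FALSE)))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  keep <- bitwAnd(flag, 0x4L) == 0L
  f <- f[keep]; flag <- flag[keep]
  new_alignments(data.frame(
    read_id = vapply(f, `[`, "", 1),
    contig = vapply(f, `[`, "", 3),
    pos = vapply(f, function(x) as.integer(x[4]), integer(1)) - 1L,
    strand = ifelse(bitwAnd(flag, 0x10L) != 0L, "-", "+"),
    mapq = vapply(f, function(x) as.integer(x[5]), integer(1)),
    primary = bitwAnd(flag, 0x900L) == 0L,
    cigar = vapply(f, `[`, "", 6),
    seq = vapply(f, `[`, "", 10),
    stringsAsFactors = FALSE))
}

#' Write alignment records to a SAM file
#'
#' Records are position-sorted per contig before writing.  Use
#' `samtools view -b` / `samtools index` to produce an indexed BAM.
#'
#' @param aln Alignment records ([new_alignments] layout).
#' @param ref_lengths Named integer vector of reference sequence lengths
#'   (for the `@SQ` header).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, ref_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (i in seq_along(ref_lengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths)[i],
                       as.integer(ref_lengths[i])), con)
  }
  aln <- aln[order(match(aln$contig, names(ref_lengths)), aln$pos), ]
  flag <- ifelse(aln$strand == "-", 16L, 0L) +
    ifelse(aln$primary, 0L, 256L)
  writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                     aln$read_id, flag, aln$contig, aln$pos + 1L,
                     as.integer(aln$mapq), aln$cigar, aln$seq), con)
  invisible(path)
}

# Parse minimap2 PAF (with -c, so cg/tp tags are present) into a mapping
# table used by the scaffolder and the evaluation module.  Coordinates are
# 0-based half-open; query coordinates refer to the original read strand.
read_paf <- function(path) {
  empty <- data.frame(
    query = character(0), qlen = integer(0), qstart = integer(0),
    qend = integer(0), strand = character(0), target = character(0),
    tlen = integer(0), tstart = integer(0), tend = integer(0),
    nmatch = integer(0), blocklen = integer(0), mapq = integer(0),
    primary = logical(0), stringsAsFactors = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0) return(empty)
  f <- strsplit(lines, "\t", fixed = TRUE)
  tp <- vapply(f, function(x) {
    hit <- grep("^tp:A:", x, value = TRUE)
    if (length(hit)) sub("^tp:A:", "", hit[1]) else "P"
  }, "")
  data.frame(
    query = vapply(f, `[`, "", 1),
    qlen = as.integer(vapply(f, `[`, "", 2)),
    qstart = as.integer(vapply(f, `[`, "", 3)),
    qend = as.integer(vapply(f, `[`, "", 4)),
    strand = vapply(f, `[`, "", 5),
    target = vapply(f, `[`, "", 6),
    tlen = as.integer(vapply(f, `[`, "", 7)),
    tstart = as.integer(vapply(f, `[`, "", 8)),
    tend = as.integer(vapply(f, `[`, "", 9)),
    nmatch = as.integer(vapply(f, `[`, "", 10)),
    blocklen = as.integer(vapply(f, `[`, "", 11)),
    mapq = as.integer(vapply(f, `[`, "", 12)),
    primary = tp == "P",
    stringsAsFactors = FALSE)
}
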