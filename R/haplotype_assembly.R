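# Assembly of separated read sets into haplotype contigs, trimming to
# phaseset intervals, and assembly of the strain-aware contig set.
#
# The default assembler is an internal coordinate-anchored column-wise
# consensus over the read-to-backbone alignments (majority base; deletion
# when >50% of covering reads delete; most frequent insertion when >50%
# insert; contigs split where coverage < 3 since majority vote is
# meaningless below that).  Users reproducing the published pipeline can
# instead run an external assembler on the per-haplotype FASTQ via
# `external_cmd` (the reference setup used wtdbg2 with flags
# `-e 5 -l 1000 -L 3000 -S 1 -R`).

#' Assemble one separated read set into haplotype contigs
#'
#' @param read_ids Character vector of separated read ids.
#' @param alignments Alignment records of all reads against the backbone.
#' @param phaseset One row of a [extract_phasesets()] result.
#' @param backbone Named character vector of backbone sequences.
#' @param min_cov Coverage below which contigs are split (default 3).
#' @param flank Backbone bases beyond [s, e] included in the consensus
#'   window before trimming (default 10000).
#' @param external_cmd Optional command template with placeholders
#'   `{reads}` (FASTQ path written for the read set) and `{out}` (FASTA the
#'   command must produce); when set, the internal consensus is bypassed
#'   and the resulting contigs carry no coordinate anchors (they are
#'   trimmed by alignment instead).
#' @return List of raw haplotype contigs, each a list with `seq` and
#'   `anchor` (backbone position per base; `NULL` for external contigs).
#' @export
assemble_haplotype <- function(read_ids, alignments, phaseset, backbone,
                               min_cov = 3, flank = 10000,
                               external_cmd = NULL) {
  if (length(read_ids) == 0) {
    warning("empty read set for phaseset [", phaseset$s, ",", phaseset$e,
            "] on ", phaseset$contig, "; no contig assembled")
    return(list())
  }
  aln <- alignments[alignments$primary &
                      alignments$contig == phaseset$contig &
                      alignments$read_id %in% read_ids, ]
  if (!is.null(external_cmd)) {
    fq <- tempfile(fileext = ".fastq")
    out <- tempfile(fileext = ".fasta")
    seqs <- setNames(ifelse(aln$strand == "-", revcomp(aln$seq), aln$seq),
                     aln$read_id)
    write_fastq(seqs, fq)
    cmd <- gsub("{reads}", fq, gsub("{out}", out, external_cmd,
                                    fixed = TRUE), fixed = TRUE)
    status <- system(cmd)
    if (status != 0 || !file.exists(out)) {
      stop("external assembler failed: ", cmd)
    }
    ctg <- read_fasta(out)
    return(lapply(unname(ctg), function(s) list(seq = s, anchor = NULL)))
  }
  L <- nchar(backbone[[phaseset$contig]])
  a <- max(0L, phaseset$s - as.integer(flank))
  b <- min(L, phaseset$e + 1L + as.integer(flank))
  cpp_consensus(aln$seq, aln$cigar, aln$pos, a, b, as.integer(min_cov))
}

#' Trim a haplotype contig to its phaseset interval
#'
#' Read coverage of a separated set decays outside the phaseset, so
#' consensus quality does too; only the part of the contig whose alignment
#' to the backbone projects inside `[s, e]` is kept.  Contigs from the
#' internal assembler carry per-base backbone anchors and are trimmed by
#' coordinate; external contigs are aligned (global-local) against the
#' backbone window `[s - 10 kbp, e + 10 kbp]` and dropped with a warning if
#' fewer than half their bases align.
#'
#' @param hap_contig One contig from [assemble_haplotype()].
#' @param backbone Named character vector of backbone sequences.
#' @param phaseset One row of a [extract_phasesets()] result.
#' @param haplotype "h1" or "h2" (provenance only).
#' @return A one-row strain-aware contig data frame (see
#'   [build_contig_set()]) plus its sequence in `attr(, "seq")`, or `NULL`
#'   when the trimmed contig is empty or unalignable.
#' @export
trim_to_phaseset <- function(hap_contig, backbone, phaseset,
                             haplotype = "h1") {
  s <- phaseset$s; e <- phaseset$e
  if (!is.null(hap_contig$anchor)) {
    keep <- hap_contig$anchor >= s & hap_contig$anchor <= e
    if (!any(keep)) return(NULL)
    seq <- substr(hap_contig$seq, which(keep)[1], tail(which(keep), 1))
    interval <- c(min(hap_contig$anchor[keep]),
                  max(hap_contig$anchor[keep]) + 1L)
  } else {
    L <- nchar(backbone[[phaseset$contig]])
    wa <- max(0L, s - 10000L); wb <- min(L, e + 1L + 10000L)
    window <- substr(backbone[[phaseset$contig]], wa + 1L, wb)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(hap_contig$seq), Biostrings::DNAString(window),
      type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -4),
      gapOpening = 4, gapExtension = 2)
    aligned_len <- Biostrings::end(Biostrings::pattern(pa)) -
      Biostrings::start(Biostrings::pattern(pa)) + 1L
    if (aligned_len < 0.5 * nchar(hap_contig$seq)) {
      warning("haplotype contig aligns for <50% of its length; dropped")
      return(NULL)
    }
    # project [s, e] through the alignment
    tstart <- wa + Biostrings::start(Biostrings::subject(pa)) - 1L
    tend <- wa + Biostrings::end(Biostrings::subject(pa))  # half-open
    qs <- Biostrings::start(Biostrings::pattern(pa))
    qe <- Biostrings::end(Biostrings::pattern(pa))
    # approximate per-base projection by linear interpolation over the
    # aligned block (adequate: external contigs are near-collinear)
    if (tend <= s || tstart > e) return(NULL)
    scale <- (qe - qs + 1) / max(1L, tend - tstart)
    q_lo <- qs + as.integer(round(max(0, s - tstart) * scale))
    q_hi <- qe - as.integer(round(max(0, tend - (e + 1L)) * scale))
    if (q_hi < q_lo) return(NULL)
    seq <- substr(hap_contig$seq, q_lo, q_hi)
    interval <- c(max(tstart, s), min(tend, e + 1L))
  }
  if (nchar(seq) == 0) return(NULL)
  out <- data.frame(
    id = sprintf("%s_%d_%d_%s", phaseset$contig, interval[1], interval[2],
                 haplotype),
    origin_contig = phaseset$contig, origin_start = interval[1],
    origin_end = interval[2], kind = "haplotype-assembled",
    haplotype = haplotype, stringsAsFactors = FALSE)
  attr(out, "seq") <- seq
  out
}

#' Retain unphased backbone subsequences
#'
#' The complement of the phaseset intervals on a backbone contig; pieces
#' strictly longer than `min_len` are kept as shared (non-separated)
#' contigs.
#'
#' @param backbone Named character vector of backbone sequences.
#' @param contig Backbone contig id.
#' @param phasesets [extract_phasesets()] result for that contig.
#' @param min_len Minimum retained length in bp (default 500; strictly
#'   greater than `min_len` is kept).
#' @return List of one-row contig data frames with sequence attributes, as
#'   in [trim_to_phaseset()].
#' @export
collect_unphased <- function(backbone, contig, phasesets, min_len = 500) {
  L <- nchar(backbone[[contig]])
  ps <- phasesets[phasesets$contig == contig, , drop = FALSE]
  # phaseset intervals as half-open [s, e+1)
  starts <- ps$s; ends <- ps$e + 1L
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  gaps_lo <- c(0L, ends)
  gaps_hi <- c(starts, L)
  out <- list()
  for (i in seq_along(gaps_lo)) {
    lo <- gaps_lo[i]; hi <- gaps_hi[i]
    if (hi - lo <= min_len) next
    row <- data.frame(
      id = sprintf("%s_%d_%d_un", contig, as.integer(lo), as.integer(hi)),
      origin_contig = contig, origin_start = as.integer(lo),
      origin_end = as.integer(hi), kind = "unphased-backbone",
      haplotype = "none", stringsAsFactors = FALSE)
    attr(row, "seq") <- substr(backbone[[contig]], lo + 1L, hi)
    out[[length(out) + 1]] <- row
  }
  out
}

#' Assemble the strain-aware contig set for one or more backbone contigs
#'
#' Runs read separation, haplotype consensus, trimming and unphased
#' collection for every retained phaseset of every backbone contig, and
#' binds the results into a single provenance-stamped contig set.
#'
#' @param backbone Named character vector of backbone sequences.
#' @param phasesets_by_contig Named list of [extract_phasesets()] results.
#' @param matrices Named list of `read_snv_matrix` objects (same names).
#' @param alignments Alignment records of reads against the backbone.
#' @param min_cov,min_len,external_cmd See [assemble_haplotype()] and
#'   [collect_unphased()].
#' @return A `strain_contigs` object: list with `info` (data frame: `id`,
#'   `origin_contig`, `origin_start`, `origin_end`, `kind`, `haplotype`)
#'   and `seqs` (named character vector), ordered by backbone then
#'   interval; also records per-phaseset read separations in
#'   `separations`.
#' @export
build_contig_set <- function(backbone, phasesets_by_contig, matrices,
                             alignments, min_cov = 3, min_len = 500,
                             external_cmd = NULL) {
  rows <- list()
  seq_list <- list()
  separations <- list()
  for (contig in names(backbone)) {
    ps <- phasesets_by_contig[[contig]]
    if (is.null(ps)) {
      ps <- extract_phasesets(
        structure(list(contig = contig, sites = data.frame(pos = integer(0)),
                       blocks = list()), class = "phase_blocks"))
    }
    for (i in seq_len(nrow(ps))) {
      sep <- separate_reads(ps[i, ], matrices[[contig]])
      separations[[sprintf("%s_%d_%d", contig, ps$s[i], ps$e[i])]] <- sep
      for (hap in c("h1", "h2")) {
        raw <- assemble_haplotype(sep[[hap]], alignments, ps[i, ], backbone,
                                  min_cov = min_cov,
                                  external_cmd = external_cmd)
        for (ctg in raw) {
          trimmed <- trim_to_phaseset(ctg, backbone, ps[i, ], haplotype = hap)
          if (is.null(trimmed)) next
          rows[[length(rows) + 1]] <- trimmed
          seq_list[[length(seq_list) + 1]] <- attr(trimmed, "seq")
        }
      }
    }
    for (row in collect_unphased(backbone, contig, ps, min_len = min_len)) {
      rows[[length(rows) + 1]] <- row
      seq_list[[length(seq_list) + 1]] <- attr(row, "seq")
    }
  }
  info <- if (length(rows)) {
    do.call(rbind, lapply(rows, function(r) { attr(r, "seq") <- NULL; r }))
  } else {
    data.frame(id = character(0), origin_contig = character(0),
               origin_start = integer(0), origin_end = integer(0),
               kind = character(0), haplotype = character(0),
               stringsAsFactors = FALSE)
  }
  # de-duplicate ids of split consensus pieces sharing an interval
  if (anyDuplicated(info$id)) {
    dup <- duplicated(info$id) | duplicated(info$id, fromLast = TRUE)
    info$id[dup] <- paste0(info$id[dup], "_p",
                           stats::ave(seq_len(nrow(info)), info$id,
                                      FUN = seq_along)[dup])
  }
  if (anyDuplicated(info$id)) stop("duplicate strain-aware contig ids")
  seqs <- setNames(unlist(seq_list) %||% character(0), info$id)
  o <- order(match(info$origin_contig, names(backbone)), info$origin_start,
             info$origin_end, info$id)
  info <- info[o, , drop = FALSE]
  rownames(info) <- NULL
  structure(list(info = info, seqs = seqs[info$id],
                 separations = separations),
            class = "strain_contigs")
}

#' @export
print.strain_contigs <- function(x, ...) {
  cat("<strain_contigs> ", nrow(x$info), " contig(s), ",
      sum(x$info$kind == "haplotype-assembled"), " haplotype-assembled, ",
      sum(nchar(x$seqs)), " bp total\n", sep = "")
  invisible(x)
}
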