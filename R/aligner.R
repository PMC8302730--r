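# External aligner hook (minimap2 by default).
#
# All pipeline stages consume alignment tables, so any aligner producing
# PAF (mappings) or SAM (base-level records) can be substituted; minimap2
# is the default because it is the standard long-read mapper and the one
# the reference protocol uses (presets map-pb / map-ont for reads,
# asm5/asm20 for assembly-to-reference comparison).

minimap2_available <- function() nzchar(Sys.which("minimap2"))

require_minimap2 <- function() {
  if (!minimap2_available()) {
    stop("minimap2 not found on PATH; install it or supply pre-computed ",
         "alignments")
  }
}

# Run minimap2 and return a PAF mapping table (base-level, -c).
minimap2_paf <- function(query_fa, target_fa, preset = "map-pb",
                         threads = 1) {
  require_minimap2()
  out <- tempfile(fileext = ".paf")
  status <- system2("minimap2",
                    c("-c", "-x", preset, "-t", as.character(threads),
                      "--secondary=no", shQuote(target_fa),
                      shQuote(query_fa)),
                    stdout = out, stderr = FALSE)
  if (status != 0) stop("minimap2 failed (exit ", status, ")")
  on.exit(unlink(out))
  read_paf(out)
}

# Run minimap2 with SAM output and return alignment records.
minimap2_sam <- function(query_fa, target_fa, preset = "map-pb",
                         threads = 1) {
  require_minimap2()
  out <- tempfile(fileext = ".sam")
  status <- system2("minimap2",
                    c("-a", "-x", preset, "-t", as.character(threads),
                      "--secondary=no", shQuote(target_fa),
                      shQuote(query_fa)),
                    stdout = out, stderr = FALSE)
  if (status != 0) stop("minimap2 failed (exit ", status, ")")
  on.exit(unlink(out))
  read_sam(out)
}

#' Align reads against an assembly
#'
#' Thin wrapper around the configured aligner (minimap2).  Returns either a
#' PAF-style mapping table (`format = "paf"`, used by the scaffolder) or
#' base-level alignment records (`format = "sam"`, used by SNV calling).
#'
#' @param reads Named character vector of read sequences, or a FASTA/FASTQ
#'   path.
#' @param assembly Named character vector of target sequences, or a FASTA
#'   path.
#' @param preset minimap2 preset (default "map-pb").
#' @param format "paf" or "sam".
#' @param threads Number of aligner threads.
#' @return A mapping table ([read_paf] layout) or alignment records.
#' @export
align_reads <- function(reads, assembly, preset = "map-pb",
                        format = c("paf", "sam"), threads = 1) {
  format <- match.arg(format)
  qf <- if (is.character(reads) && length(reads) == 1 &&
              file.exists(reads)) {
    reads
  } else {
    f <- tempfile(fileext = ".fasta")
    write_fasta(reads, f)
    f
  }
  tf <- if (is.character(assembly) && length(assembly) == 1 &&
              file.exists(assembly)) {
    assembly
  } else {
    f <- tempfile(fileext = ".fasta")
    write_fasta(assembly, f)
    f
  }
  if (format == "paf") minimap2_paf(qf, tf, preset, threads)
  else minimap2_sam(qf, tf, preset, threads)
}
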