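# Synthetic strain-community generator with planted truth.

# Per-read identity: beta distribution scaled to max_identity with the
# requested mean and standard deviation (degenerate cases fall back to a
# constant mean identity).
draw_identity <- function(n, mean_identity, max_identity, sd_identity) {
  if (sd_identity <= 0 || max_identity <= mean_identity) {
    return(rep(mean_identity, n))
  }
  mu <- mean_identity / max_identity
  v <- (sd_identity / max_identity)^2
  if (v >= mu * (1 - mu)) return(rep(mean_identity, n))
  a <- mu * (mu * (1 - mu) / v - 1)
  b <- (1 - mu) * (mu * (1 - mu) / v - 1)
  max_identity * stats::rbeta(n, a, b)
}
#
# The generator emulates the study conditions used to benchmark the
# pipeline: 2--5 conspecific strain genomes at a chosen pairwise divergence,
# PacBio-like long reads (gamma-distributed lengths, mean identity ~0.90
# with errors split 60/20/20 substitution/insertion/deletion), per-strain
# fold-coverage, and truth outputs (variant lists, read origins, exact
# read-to-backbone alignments) so every downstream stage can be tested
# without an external aligner.  The "backbone" standing in for a
# strain-oblivious assembly is strain 1's genome: with substitution-only
# divergence all strains share its coordinate system, exactly as conspecific
# strains collapse onto one consensus contig.

#' Derive a strain genome by random mutation
#'
#' Substitutions are placed uniformly at random so that the expected
#' substitution rate equals `divergence`; the planted variants are recorded
#' in backbone (input) coordinates.  Small indels can additionally be
#' requested, but the community generator keeps `indel_rate = 0` so that all
#' strains stay on the backbone coordinate system.
#'
#' @param base_genome Character scalar, the backbone genome.
#' @param divergence Expected substitution rate, in `[0, 0.05]`.
#' @param indel_rate Expected indel rate (single-base events), default 0.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param strain_id Label for the derived strain.
#' @return A `strain_truth` object: list with `strain_id`, `genome`,
#'   `variants` (data frame `pos` 0-based / `ref` / `alt`), `coverage`
#'   (filled in later by [simulate_reads()]), and `indels`.
#' @export
mutate_genome <- function(base_genome, divergence, indel_rate = 0,
                          seed = NULL, strain_id = "strain") {
  if (!is.numeric(divergence) || divergence < 0 || divergence > 0.05) {
    stop("divergence must be in [0, 0.05]")
  }
  if (nchar(base_genome) == 0) stop("base genome must be non-empty")
  with_seed(seed, {
    chars <- strsplit(base_genome, "", fixed = TRUE)[[1]]
    L <- length(chars)
    hit <- which(runif(L) < divergence)
    variants <- data.frame(pos = integer(0), ref = character(0),
                           alt = character(0), stringsAsFactors = FALSE)
    if (length(hit)) {
      ref <- chars[hit]
      alt <- vapply(ref, function(b) {
        sample(setdiff(c("A", "C", "G", "T"), toupper(b)), 1)
      }, "", USE.NAMES = FALSE)
      chars[hit] <- alt
      variants <- data.frame(pos = hit - 1L, ref = ref, alt = alt,
                             stringsAsFactors = FALSE)
    }
    indels <- data.frame(pos = integer(0), type = character(0),
                         seq = character(0), stringsAsFactors = FALSE)
    if (indel_rate > 0) {
      ih <- which(runif(L) < indel_rate)
      ih <- setdiff(ih, hit)
      if (length(ih)) {
        type <- sample(c("ins", "del"), length(ih), replace = TRUE)
        insseq <- vapply(seq_along(ih), function(i) {
          if (type[i] == "ins") sample(c("A", "C", "G", "T"), 1) else ""
        }, "")
        # apply right-to-left so earlier positions stay valid
        o <- order(ih, decreasing = TRUE)
        for (i in o) {
          if (type[i] == "ins") {
            chars <- append(chars, insseq[i], after = ih[i])
          } else {
            chars <- chars[-ih[i]]
          }
        }
        indels <- data.frame(pos = ih - 1L, type = type, seq = insseq,
                             stringsAsFactors = FALSE)
      }
    }
    structure(list(strain_id = strain_id,
                   genome = paste(chars, collapse = ""),
                   variants = variants, indels = indels,
                   coverage = NA_real_),
              class = "strain_truth")
  })
}

#' @export
print.strain_truth <- function(x, ...) {
  cat("<strain_truth> ", x$strain_id, ": ", nchar(x$genome), " bp, ",
      nrow(x$variants), " planted SNVs, coverage ",
      x$coverage, "x\n", sep = "")
  invisible(x)
}

#' Simulate long reads from strain genomes
#'
#' Read lengths follow a gamma distribution matched to `mean_len`/`sd_len`,
#' truncated at 500 bp (and at the genome length).  Reads are drawn
#' uniformly along each genome until the requested fold-coverage is
#' reached, and reverse-complemented with probability 0.5.  Each read gets
#' an identity drawn from a beta distribution scaled to `max_identity`
#' with mean `mean_identity` and standard deviation `sd_identity`
#' (PacBio-like; set `sd_identity = 0` for a constant rate); sequencing
#' errors are injected at rate `1 - identity`, split 60/20/20 between
#' substitutions, single-base insertions and single-base deletions.  True
#' origin coordinates and the exact error CIGAR are recorded per read.
#'
#' @param strains List of `strain_truth` objects with `coverage` set (or
#'   pass `coverage` here).
#' @param coverage Optional numeric vector of per-strain fold-coverages.
#' @param mean_len,sd_len Read length distribution (bp); defaults 6100/3700.
#' @param mean_identity Mean read identity in (0, 1]; default 0.90.
#' @param max_identity Upper bound of the identity distribution (default
#'   0.97).
#' @param sd_identity Standard deviation of read identity (default 0.03).
#' @param seed Integer seed.
#' @return Data frame of reads with columns `read_id`, `sequence` (as
#'   sequenced), `source_strain`, `true_start`, `true_end` (0-based
#'   half-open on the source genome), `strand`, `cigar`, `aln_seq`
#'   (reference-oriented sequence).
#' @export
simulate_reads <- function(strains, coverage = NULL, mean_len = 6100,
                           sd_len = 3700, mean_identity = 0.90,
                           max_identity = 0.97, sd_identity = 0.03,
                           seed = NULL) {
  if (length(strains) == 0) stop("empty strain list")
  if (!is.null(coverage)) {
    stopifnot(length(coverage) == length(strains))
    for (i in seq_along(strains)) strains[[i]]$coverage <- coverage[i]
  }
  covs <- vapply(strains, function(s) s$coverage, 0)
  if (any(is.na(covs)) || any(covs <= 0)) {
    stop("every strain needs a positive coverage")
  }
  stopifnot(mean_identity > 0, mean_identity <= 1, sd_identity >= 0)
  shape <- (mean_len / sd_len)^2
  rate <- mean_len / sd_len^2
  with_seed(seed, {
    out <- vector("list", length(strains))
    for (i in seq_along(strains)) {
      st <- strains[[i]]
      L <- nchar(st$genome)
      if (mean_len >= L) stop("mean_len must be smaller than the genome")
      target <- st$coverage * L
      lens <- integer(0)
      while (sum(lens) < target) {
        k <- max(32L, ceiling((target - sum(lens)) / mean_len))
        draw <- pmin(L, pmax(500L, as.integer(round(
          rgamma(k, shape = shape, rate = rate)))))
        need <- which(cumsum(as.numeric(draw)) >= target - sum(lens))
        if (length(need)) draw <- draw[seq_len(need[1])]
        lens <- c(lens, draw)
      }
      n <- length(lens)
      starts <- as.integer(floor(runif(n) * (L - lens + 1)))
      strand <- ifelse(runif(n) < 0.5, "-", "+")
      identity <- draw_identity(n, mean_identity, max_identity, sd_identity)
      sim <- cpp_simulate_read_errors(st$genome, starts, lens,
                                      1 - identity, 0.6, 0.2)
      ids <- sprintf("%s_read%06d", st$strain_id, seq_len(n))
      seqs <- sim$seq
      as_sequenced <- ifelse(strand == "-", revcomp(seqs), seqs)
      out[[i]] <- data.frame(
        read_id = ids, sequence = as_sequenced, source_strain = st$strain_id,
        true_start = starts, true_end = starts + lens, strand = strand,
        cigar = sim$cigar, aln_seq = seqs, stringsAsFactors = FALSE)
    }
    reads <- do.call(rbind, out)
    rownames(reads) <- NULL
    reads
  })
}

#' Emit exact truth alignments of simulated reads against the backbone
#'
#' One primary record per read, with the planted position, strand and the
#' CIGAR implied by the injected sequencing errors.  Valid only when strain
#' divergence is substitution-only (the community generator default), so
#' that every strain shares the backbone coordinate system; planted strain
#' SNVs appear as mismatches inside M runs.
#'
#' @param reads Read data frame from [simulate_reads()].
#' @param backbone_id Name of the backbone contig.
#' @return Position-sorted alignment records ([new_alignments] layout).
#' @export
emit_truth_alignments <- function(reads, backbone_id = "backbone") {
  if (is.null(reads$true_start) || any(is.na(reads$true_start))) {
    stop("reads are missing truth coordinates")
  }
  aln <- new_alignments(data.frame(
    read_id = reads$read_id, contig = backbone_id, pos = reads$true_start,
    strand = reads$strand, mapq = 60L, primary = TRUE,
    cigar = reads$cigar, seq = reads$aln_seq, stringsAsFactors = FALSE))
  aln[order(aln$pos), ]
}

#' Generate a synthetic strain community with planted truth
#'
#' Builds `n_strains` conspecific genomes (strain 1 is the backbone; the
#' others are derived by [mutate_genome()] at the given pairwise
#' divergence), simulates reads and truth alignments, and returns
#' everything needed to run and score the pipeline.
#'
#' @param genome_length Backbone genome length (bp).
#' @param n_strains Number of strains (2--5).
#' @param divergence Substitution divergence of each derived strain from the
#'   backbone (so also the approximate pairwise divergence).
#' @param coverage Per-strain fold-coverage, recycled to `n_strains`.
#' @param mean_len,sd_len,mean_identity Read model, see [simulate_reads()].
#' @param seed Integer seed driving all randomness.
#' @return List with `strains` (list of `strain_truth`), `backbone` (named
#'   character vector of length 1), `reads`, `alignments`, and `genomes`
#'   (named character vector of all strain genomes).
#' @export
simulate_community <- function(genome_length = 1e6, n_strains = 2,
                               divergence = 0.01, coverage = 50,
                               mean_len = 6100, sd_len = 3700,
                               mean_identity = 0.90, max_identity = 0.97,
                               sd_identity = 0.03, seed = 1) {
  stopifnot(n_strains >= 2, n_strains <= 5)
  coverage <- rep_len(coverage, n_strains)
  with_seed(seed, {
    base <- random_genome(genome_length)
    strains <- vector("list", n_strains)
    strains[[1]] <- structure(
      list(strain_id = "strainA", genome = base,
           variants = data.frame(pos = integer(0), ref = character(0),
                                 alt = character(0)),
           indels = data.frame(pos = integer(0), type = character(0),
                               seq = character(0)),
           coverage = coverage[1]),
      class = "strain_truth")
    for (i in seq_len(n_strains - 1)) {
      strains[[i + 1]] <- mutate_genome(
        base, divergence, strain_id = paste0("strain", LETTERS[i + 1]))
      strains[[i + 1]]$coverage <- coverage[i + 1]
    }
    reads <- simulate_reads(strains, mean_len = mean_len, sd_len = sd_len,
                            mean_identity = mean_identity,
                            max_identity = max_identity,
                            sd_identity = sd_identity)
    aln <- emit_truth_alignments(reads, backbone_id = "backbone")
    genomes <- setNames(vapply(strains, function(s) s$genome, ""),
                        vapply(strains, function(s) s$strain_id, ""))
    list(strains = strains,
         backbone = c(backbone = base),
         reads = reads, alignments = aln, genomes = genomes)
  })
}

#' Write community truth tables and sequence files
#'
#' Emits genomes (FASTA), reads (FASTQ), truth alignments (SAM), a read
#' truth table (TSV: read_id, strain, start, end, strand) and per-strain
#' variant lists (TSV).
#'
#' @param community Result of [simulate_community()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(community$genomes, file.path(dir, "strains.fasta"))
  write_fasta(community$backbone, file.path(dir, "backbone.fasta"))
  write_fastq(setNames(community$reads$sequence, community$reads$read_id),
              file.path(dir, "reads.fastq"))
  write_sam(community$alignments,
            setNames(nchar(community$backbone), names(community$backbone)),
            file.path(dir, "truth.sam"))
  write.table(community$reads[, c("read_id", "source_strain", "true_start",
                                  "true_end", "strand")],
              file.path(dir, "read_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  vars <- do.call(rbind, lapply(community$strains, function(s) {
    if (nrow(s$variants) == 0) return(NULL)
    cbind(strain = s$strain_id, s$variants)
  }))
  if (is.null(vars)) {
    vars <- data.frame(strain = character(0), pos = integer(0),
                       ref = character(0), alt = character(0))
  }
  write.table(vars, file.path(dir, "variant_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
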