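# Shared fixtures built in code.  Communities are cached per session so
# several test files can reuse the same simulation.

.fixture_cache <- new.env(parent = emptyenv())

cached_community <- function(key, ...) {
  if (!exists(key, .fixture_cache)) {
    assign(key, simulate_community(...), .fixture_cache)
  }
  get(key, .fixture_cache)
}

# standard small two-strain mixture used across phasing/assembly tests
small_community <- function() {
  cached_community("small2", genome_length = 100000, n_strains = 2,
                   divergence = 0.01, coverage = 40, seed = 7)
}

# Hand-built alignment records: error-free reads tiling a reference.
tiling_alignments <- function(ref, read_len = 60, step = 15,
                              prefix = "r") {
  starts <- seq(0, nchar(ref) - read_len, by = step)
  new_alignments(data.frame(
    read_id = sprintf("%s%03d", prefix, seq_along(starts)),
    contig = "ctg", pos = as.integer(starts), strand = "+", mapq = 60L,
    primary = TRUE, cigar = paste0(read_len, "M"),
    seq = vapply(starts, function(s) substr(ref, s + 1, s + read_len), ""),
    stringsAsFactors = FALSE))
}

# Read/SNV matrix built directly from an allele matrix (rows = reads,
# columns = sites, entries 0/1/NA), with site positions `pos`.
matrix_from_alleles <- function(m, pos = seq_len(ncol(m)) * 100,
                                contig = "ctg") {
  sites <- data.frame(contig = contig, pos = as.integer(pos), ref = "A",
                      alt = "G", depth = nrow(m), alt_count = 1L,
                      stringsAsFactors = FALSE)
  idx <- which(!is.na(m), arr.ind = TRUE)
  entries <- data.frame(read = idx[, 1], site = idx[, 2],
                        allele = m[idx])
  entries <- entries[order(entries$read, entries$site), ]
  reads <- data.frame(
    read_id = sprintf("read%02d", seq_len(nrow(m))),
    start = 0L, end = as.integer(max(pos) + 100),
    stringsAsFactors = FALSE)
  structure(list(contig = contig, reads = reads, sites = sites,
                 entries = entries),
            class = "read_snv_matrix")
}

# label-switch-invariant read partition accuracy against planted truth,
# over SNV-covering reads of all phasesets
partition_accuracy <- function(phasesets, matrix, truth) {
  n <- 0; correct <- 0
  for (i in seq_len(nrow(phasesets))) {
    sep <- separate_reads(phasesets[i, ], matrix)
    covered <- unique(matrix$reads$read_id[matrix$entries$read])
    h1 <- intersect(sep$h1, covered)
    h2 <- intersect(sep$h2, covered)
    un <- intersect(sep$untagged, covered)
    t1 <- table(factor(truth[h1], levels = unique(truth)))
    t2 <- table(factor(truth[h2], levels = unique(truth)))
    best <- 0
    strains <- unique(truth)
    for (a in strains) for (b in setdiff(strains, a)) {
      best <- max(best, t1[[a]] + t2[[b]])
    }
    correct <- correct + best
    n <- n + length(h1) + length(h2) + length(un)
  }
  correct / n
}
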