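# Independent oracles used to check the implementation's results.

# Exhaustive MEC over all bipartitions of reads.  `entries` is a data
# frame (read, site, allele) with 1-based indices; per-group consensus is
# the per-site majority over the group's non-missing entries, ties cost
# the same either way.
brute_force_mec <- function(entries, n_reads, n_sites) {
  cost_of_group <- function(rows) {
    if (!nrow(rows)) return(0L)
    total <- 0L
    for (s in unique(rows$site)) {
      al <- rows$allele[rows$site == s]
      total <- total + min(sum(al == 0), sum(al == 1))
    }
    total
  }
  best <- Inf
  for (mask in 0:(2^(n_reads - 1) - 1)) {
    grp <- c(TRUE, as.logical(bitwAnd(mask, 2^(0:(n_reads - 2)))))
    cost <- cost_of_group(entries[grp[entries$read], , drop = FALSE]) +
      cost_of_group(entries[!grp[entries$read], , drop = FALSE])
    best <- min(best, cost)
  }
  best
}

# MEC of a phase_blocks result (sum over blocks).
phased_mec <- function(blocks) {
  sum(vapply(blocks$blocks, function(b) b$mec, 0L))
}

# Literal application of the transitive-edge definition: for each edge
# e = (i, j, ei, ej), look for any pair of other edges forming a
# pass-through path i -> z -> j with matching outer ends and opposite
# ends at z.
brute_force_transitive <- function(edges) {
  ends_at <- function(k, v) {
    if (edges$v1[k] == v) c(edges$end1[k], edges$v2[k], edges$end2[k])
    else c(edges$end2[k], edges$v1[k], edges$end1[k])
  }
  drop <- logical(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    i <- edges$v1[k]; j <- edges$v2[k]
    ei <- edges$end1[k]; ej <- edges$end2[k]
    for (k1 in seq_len(nrow(edges))) {
      if (k1 == k) next
      if (!(edges$v1[k1] == i || edges$v2[k1] == i)) next
      a <- ends_at(k1, i)
      if (a[1] != ei) next
      z <- a[2]; z_in <- a[3]
      if (z == j) next
      for (k2 in seq_len(nrow(edges))) {
        if (k2 == k || k2 == k1) next
        if (!(edges$v1[k2] == j || edges$v2[k2] == j)) next
        b <- ends_at(k2, j)
        if (b[1] != ej || b[2] != z) next
        if (b[3] != z_in) { drop[k] <- TRUE; break }
      }
      if (drop[k]) break
    }
  }
  edges[!drop, , drop = FALSE]
}

# Random bi-directed graph as a scaffolding_graph (no parallel identical
# side-pairs, no self loops).
random_bigraph <- function(n_vertices, n_edges) {
  ids <- sprintf("v%02d", seq_len(n_vertices))
  rows <- list()
  seen <- character(0)
  tries <- 0
  while (length(rows) < n_edges && tries < 200) {
    tries <- tries + 1
    vs <- sort(sample(ids, 2))
    ends <- sample(c("prefix", "suffix"), 2, replace = TRUE)
    key <- paste(vs[1], vs[2], ends[1], ends[2])
    if (key %in% seen) next
    seen <- c(seen, key)
    rows[[length(rows) + 1]] <- data.frame(
      v1 = vs[1], v2 = vs[2], end1 = ends[1], end2 = ends[2],
      weight = sample(1:30, 1), stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, rows)
  edges$dist <- replicate(nrow(edges), sample(-50:200, 3), simplify = FALSE)
  info <- data.frame(id = ids, origin_contig = "bb", origin_start = 0L,
                     origin_end = 1000L, kind = "unphased-backbone",
                     haplotype = "none", length = 1000L,
                     stringsAsFactors = FALSE)
  structure(list(vertices = info, edges = edges),
            class = "scaffolding_graph")
}

# Exhaustive-scan NG50: try every candidate length.
brute_force_ng50 <- function(lengths, genome_size) {
  best <- 0
  for (L in sort(unique(lengths))) {
    if (sum(lengths[lengths >= L]) >= genome_size / 2) best <- max(best, L)
  }
  best
}

# Position-marking duplication ratio oracle.
brute_force_duplication <- function(tstart, tend, qstart, qend, tlen) {
  covered <- logical(tlen)
  for (i in seq_along(tstart)) {
    if (tend[i] > tstart[i]) covered[(tstart[i] + 1):tend[i]] <- TRUE
  }
  sum(qend - qstart) / sum(covered)
}
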