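# Strain-aware scaffolding: dovetail filtering, bi-directed scaffolding
# graph, transitive/weak edge removal, and maximal unambiguous path
# traversal.
#
# Bi-directed convention: an edge records which contig end (prefix/suffix)
# each endpoint contributes.  A suffix end means the arrow points away from
# the vertex (the contig is left forward when exiting through it); a prefix
# end means the arrow points toward the vertex.  Entering a vertex through
# one end forces exiting through the other.

#' Filter read-to-contig mappings down to dovetail alignments
#'
#' Keeps primary records with mapping quality strictly greater than
#' `min_mapq` whose shape joins a contig end to a read end, allowing an
#' unaligned overhang of at most `min(max_overhang, overhang_frac *
#' match length)` on both the contig side and the read side of the
#' junction.  A record may yield two dovetails when the read spans the
#' whole contig.
#'
#' @param paf Mapping table ([read_paf] layout; base-level alignments so
#'   the overhang is knowable).
#' @param min_mapq Strict lower bound on mapping quality (default 40).
#' @param max_overhang Maximum junction overhang in bp (default 50).
#' @param overhang_frac Maximum junction overhang as a fraction of the
#'   match length (default 0.10).
#' @return Data frame of dovetails: `read_id`, `contig`, `contig_end`,
#'   `read_end` (prefix/suffix of the original-orientation read),
#'   `strand`, `match_len`, `mapq`, `read_lo`, `read_hi` (alignment
#'   interval on the read, original orientation).
#' @export
filter_dovetails <- function(paf, min_mapq = 40, max_overhang = 50,
                             overhang_frac = 0.10) {
  if (is.null(paf$blocklen)) {
    stop("alignments lack base-level extent; cannot measure overhangs")
  }
  paf <- paf[paf$primary & paf$mapq > min_mapq, , drop = FALSE]
  out <- list()
  if (nrow(paf)) {
    allow <- pmin(max_overhang, overhang_frac * paf$blocklen)
    # oriented read coordinates (read as it aligns forward to the contig)
    r_lo <- ifelse(paf$strand == "+", paf$qstart, paf$qlen - paf$qend)
    r_hi <- ifelse(paf$strand == "+", paf$qend, paf$qlen - paf$qstart)
    # contig suffix joined to oriented-read prefix
    caseA <- (paf$tlen - paf$tend) <= allow & r_lo <= allow
    # contig prefix joined to oriented-read suffix
    caseB <- paf$tstart <= allow & (paf$qlen - r_hi) <= allow
    mk <- function(sel, contig_end, oriented_prefix) {
      p <- paf[sel, , drop = FALSE]
      if (!nrow(p)) return(NULL)
      read_end <- ifelse((p$strand == "+") == oriented_prefix,
                         "prefix", "suffix")
      data.frame(read_id = p$query, contig = p$target,
                 contig_end = contig_end, read_end = read_end,
                 strand = p$strand, match_len = p$blocklen,
                 mapq = p$mapq, read_lo = p$qstart, read_hi = p$qend,
                 stringsAsFactors = FALSE)
    }
    out <- list(mk(caseA, "suffix", TRUE), mk(caseB, "prefix", FALSE))
    out <- out[!vapply(out, is.null, TRUE)]
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(read_id = character(0), contig = character(0),
               contig_end = character(0), read_end = character(0),
               strand = character(0), match_len = integer(0),
               mapq = integer(0), read_lo = integer(0),
               read_hi = integer(0), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

# Is there a contig strictly between intervals a and b on the backbone?
# Candidates with intervals identical to a's or b's do not count.
interval_between <- function(mids, a_mid, b_mid, exclude) {
  lo <- min(a_mid, b_mid); hi <- max(a_mid, b_mid)
  any(mids > lo & mids < hi & !exclude)
}

#' Build the bi-directed scaffolding graph
#'
#' An edge joins two strain-aware contigs when at least one read has two
#' dovetail alignments, one involving the read's prefix and one its
#' suffix, the contigs differ, and the pair satisfies one of the
#' admission rules: (i) consecutive contigs on the same backbone contig;
#' (ii) adjacent haplotype-assembled contigs (no other phaseset between
#' them); (iii) a non-separated backbone piece and a haplotype-assembled
#' contig linked by the read; (iv) two contigs both mapping on a backbone
#' contig extremity (within `end_window` bp of an end).  Edge weight is
#' the number of supporting reads; each read also contributes a signed
#' distance sample (read bases strictly between the two alignments;
#' negative when they overlap on the read).
#'
#' @param dovetails [filter_dovetails()] result.
#' @param contigs A `strain_contigs` object (or its `info` data frame with
#'   a `length` column).
#' @param backbone_lengths Named integer vector of backbone contig
#'   lengths.
#' @param end_window Size of the terminal window defining a backbone
#'   "extremity" (default 1000 bp).
#' @return A `scaffolding_graph`: list with `vertices` (contig info) and
#'   `edges` (data frame `v1`, `v2`, `end1`, `end2`, `weight`, list column
#'   `dist`).
#' @export
build_graph <- function(dovetails, contigs, backbone_lengths,
                        end_window = 1000) {
  info <- if (inherits(contigs, "strain_contigs")) contigs$info else contigs
  if (inherits(contigs, "strain_contigs")) {
    info$length <- nchar(contigs$seqs[info$id])
  }
  mids <- (info$origin_start + info$origin_end) / 2
  names(mids) <- info$id
  # candidate links: per read, best dovetail per read end
  links <- list()
  if (nrow(dovetails)) {
    o <- order(dovetails$read_id, dovetails$read_end,
               -dovetails$match_len, dovetails$contig, dovetails$contig_end)
    dt <- dovetails[o, ]
    keep <- !duplicated(dt[, c("read_id", "read_end")])
    dt <- dt[keep, ]
    pre <- dt[dt$read_end == "prefix", ]
    suf <- dt[dt$read_end == "suffix", ]
    m <- match(pre$read_id, suf$read_id)
    ok <- !is.na(m)
    pre <- pre[ok, ]; suf <- suf[m[ok], ]
    diffc <- pre$contig != suf$contig
    pre <- pre[diffc, ]; suf <- suf[diffc, ]
    if (nrow(pre)) {
      links <- data.frame(
        read_id = pre$read_id,
        v1 = pre$contig, end1 = pre$contig_end,
        v2 = suf$contig, end2 = suf$contig_end,
        gap = suf$read_lo - pre$read_hi,
        stringsAsFactors = FALSE)
    }
  }
  edges <- data.frame(v1 = character(0), v2 = character(0),
                      end1 = character(0), end2 = character(0),
                      weight = integer(0), stringsAsFactors = FALSE)
  edges$dist <- list()
  if (length(links) && nrow(links)) {
    # admission rules
    ia <- match(links$v1, info$id); ib <- match(links$v2, info$id)
    bad <- is.na(ia) | is.na(ib)
    links <- links[!bad, ]; ia <- ia[!bad]; ib <- ib[!bad]
    admit <- logical(nrow(links))
    for (k in seq_len(nrow(links))) {
      a <- info[ia[k], ]; b <- info[ib[k], ]
      same_bb <- a$origin_contig == b$origin_contig
      same_interval <- same_bb && a$origin_start == b$origin_start &&
        a$origin_end == b$origin_end
      # (i) consecutive contigs on the same backbone
      if (same_bb && !same_interval) {
        on_bb <- info$origin_contig == a$origin_contig
        excl <- (info$origin_start == a$origin_start &
                   info$origin_end == a$origin_end) |
          (info$origin_start == b$origin_start &
             info$origin_end == b$origin_end)
        if (!interval_between(mids[info$id[on_bb]],
                              mids[[a$id]], mids[[b$id]],
                              excl[on_bb])) {
          admit[k] <- TRUE
        }
      }
      # (ii) adjacent haplotype-assembled contigs
      if (!admit[k] && same_bb && !same_interval &&
            a$kind == "haplotype-assembled" &&
            b$kind == "haplotype-assembled") {
        hap <- info$origin_contig == a$origin_contig &
          info$kind == "haplotype-assembled"
        excl <- (info$origin_start == a$origin_start &
                   info$origin_end == a$origin_end) |
          (info$origin_start == b$origin_start &
             info$origin_end == b$origin_end)
        if (!interval_between(mids[info$id[hap]],
                              mids[[a$id]], mids[[b$id]],
                              excl[hap])) {
          admit[k] <- TRUE
        }
      }
      # (iii) unphased backbone piece + haplotype contig, read-linked
      if (!admit[k] &&
            ((a$kind == "unphased-backbone" &&
                b$kind == "haplotype-assembled") ||
               (b$kind == "unphased-backbone" &&
                  a$kind == "haplotype-assembled"))) {
        admit[k] <- TRUE
      }
      # (iv) both contigs on a backbone extremity
      if (!admit[k]) {
        at_end <- function(x) {
          bl <- backbone_lengths[[x$origin_contig]]
          !is.null(bl) && (x$origin_start <= end_window ||
                             x$origin_end >= bl - end_window)
        }
        if (at_end(a) && at_end(b)) admit[k] <- TRUE
      }
    }
    links <- links[admit, , drop = FALSE]
    if (nrow(links)) {
      # canonical edge orientation: v1 <= v2 lexicographically
      swap <- links$v1 > links$v2
      tmp <- links$v1[swap]; links$v1[swap] <- links$v2[swap]
      links$v2[swap] <- tmp
      tmp <- links$end1[swap]; links$end1[swap] <- links$end2[swap]
      links$end2[swap] <- tmp
      key <- paste(links$v1, links$v2, links$end1, links$end2, sep = "\r")
      grp <- split(seq_len(nrow(links)), key)
      edges <- do.call(rbind, lapply(grp, function(idx) {
        data.frame(v1 = links$v1[idx[1]], v2 = links$v2[idx[1]],
                   end1 = links$end1[idx[1]], end2 = links$end2[idx[1]],
                   weight = length(idx), stringsAsFactors = FALSE)
      }))
      edges$dist <- unname(lapply(grp, function(idx) links$gap[idx]))
      edges <- edges[order(edges$v1, edges$v2, edges$end1, edges$end2), ]
      rownames(edges) <- NULL
    }
  }
  structure(list(vertices = info, edges = edges),
            class = "scaffolding_graph")
}

#' @export
print.scaffolding_graph <- function(x, ...) {
  cat("<scaffolding_graph> ", nrow(x$vertices), " vertices, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

# incident edge view: one row per (vertex, side) occurrence
incident_sides <- function(edges) {
  rbind(data.frame(edge = seq_len(nrow(edges)), v = edges$v1,
                   end = edges$end1, other = edges$v2,
                   other_end = edges$end2, stringsAsFactors = FALSE),
        data.frame(edge = seq_len(nrow(edges)), v = edges$v2,
                   end = edges$end2, other = edges$v1,
                   other_end = edges$end1, stringsAsFactors = FALSE))
}

#' Remove transitive edges from the scaffolding graph
#'
#' An edge (S_i, S_j) is transitive when a two-edge path S_i -> S_z -> S_j
#' exists whose arrows at S_i and S_j match the edge's, and whose two
#' arrows at S_z use opposite ends (a traversable pass-through).  All
#' removals are evaluated against the original edge set, so the result
#' does not depend on edge iteration order.
#'
#' @param graph A `scaffolding_graph`.
#' @return The graph with transitive edges removed.
#' @export
remove_transitive_edges <- function(graph) {
  edges <- graph$edges
  if (nrow(edges) <= 1) return(graph)
  inc <- incident_sides(edges)
  drop <- logical(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    i <- edges$v1[k]; j <- edges$v2[k]
    ei <- edges$end1[k]; ej <- edges$end2[k]
    # edges leaving i through the same end, to some z != j
    e1 <- inc[inc$v == i & inc$end == ei & inc$other != j &
                inc$edge != k, , drop = FALSE]
    if (!nrow(e1)) next
    e2 <- inc[inc$v == j & inc$end == ej & inc$other != i &
                inc$edge != k, , drop = FALSE]
    if (!nrow(e2)) next
    for (z in intersect(e1$other, e2$other)) {
      z_in <- e1$other_end[e1$other == z]
      z_out <- e2$other_end[e2$other == z]
      # pass-through at z: enter through one end, leave through the other
      if (any(outer(z_in, z_out, FUN = "!="))) {
        drop[k] <- TRUE
        break
      }
    }
  }
  graph$edges <- edges[!drop, , drop = FALSE]
  rownames(graph$edges) <- NULL
  graph
}

#' Remove weak edges from the scaffolding graph
#'
#' An edge is weak at a vertex side when it is supported by fewer than
#' `min_reads` reads, or by less than `frac` of the total read support of
#' all edges leaving that vertex side (the edge itself included).  Weak
#' edges are identified simultaneously on the input graph and removed.
#'
#' @param graph A `scaffolding_graph`.
#' @param min_reads Minimum supporting reads (default 10).
#' @param frac Fraction of the side's total support required (default
#'   0.9).
#' @return The graph with weak edges removed.
#' @export
remove_weak_edges <- function(graph, min_reads = 10, frac = 0.9) {
  edges <- graph$edges
  if (!nrow(edges)) return(graph)
  inc <- incident_sides(edges)
  inc$w <- edges$weight[inc$edge]
  side_tot <- tapply(inc$w, paste(inc$v, inc$end, sep = "\r"), sum)
  tot <- side_tot[paste(inc$v, inc$end, sep = "\r")]
  weak_at_side <- inc$w < min_reads | inc$w < frac * tot
  drop <- tapply(weak_at_side, inc$edge, any)
  graph$edges <- edges[!drop[as.character(seq_len(nrow(edges)))], ,
                       drop = FALSE]
  rownames(graph$edges) <- NULL
  graph
}

#' Traverse maximal unambiguous paths into scaffolds
#'
#' Edges usable for scaffolding are those that are the unique edge at both
#' of their endpoint sides; the usable subgraph decomposes into simple
#' paths (cycles are broken at their lowest-weight edge with a warning).
#' Each path becomes one scaffold: orientations follow the bi-directed
#' arrows, and the gap between consecutive contigs is the lower median of
#' the edge's distance samples when positive, otherwise a direct join.
#' Isolated contigs are emitted as singleton scaffolds; every contig
#' appears in exactly one scaffold.
#'
#' @param graph A simplified `scaffolding_graph`.
#' @param seqs Named character vector of contig sequences.
#' @return A `scaffolds` object: list with `layout` (data frame
#'   `scaffold`, `part`, `contig`, `orientation`, `gap_after`) and `seqs`
#'   (named character vector of scaffold sequences, gaps as N runs).
#' @export
traverse_paths <- function(graph, seqs) {
  edges <- graph$edges
  ids <- graph$vertices$id
  usable <- logical(nrow(edges))
  if (nrow(edges)) {
    inc <- incident_sides(edges)
    deg <- table(paste(inc$v, inc$end, sep = "\r"))
    d1 <- deg[paste(edges$v1, edges$end1, sep = "\r")]
    d2 <- deg[paste(edges$v2, edges$end2, sep = "\r")]
    usable <- d1 == 1 & d2 == 1
  }
  E <- edges[usable, , drop = FALSE]
  rownames(E) <- NULL
  # break cycles: a usable-subgraph component is a cycle iff none of its
  # vertices has a free side; drop its lowest-weight edge
  repeat {
    if (!nrow(E)) break
    comp <- edge_components(E)
    side_key <- c(paste(E$v1, E$end1, sep = "\r"),
                  paste(E$v2, E$end2, sep = "\r"))
    vfree <- function(v) {
      !(paste(v, "prefix", sep = "\r") %in% side_key) ||
        !(paste(v, "suffix", sep = "\r") %in% side_key)
    }
    broke <- FALSE
    for (cc in unique(comp)) {
      ek <- which(comp == cc)
      vs <- unique(c(E$v1[ek], E$v2[ek]))
      if (!any(vapply(vs, vfree, TRUE))) {
        k <- ek[order(E$weight[ek], E$v1[ek], E$v2[ek])[1]]
        warning("cycle in scaffolding graph; broken at edge ",
                E$v1[k], " -- ", E$v2[k], " (weight ", E$weight[k], ")")
        E <- E[-k, , drop = FALSE]
        rownames(E) <- NULL
        broke <- TRUE
        break
      }
    }
    if (!broke) break
  }
  side_of <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(E))) {
    assign(paste(E$v1[k], E$end1[k], sep = "\r"), k, side_of)
    assign(paste(E$v2[k], E$end2[k], sep = "\r"), k, side_of)
  }
  endpoints <- unique(c(E$v1, E$v2))
  free <- vapply(endpoints, function(v) {
    !exists(paste(v, "prefix", sep = "\r"), side_of) ||
      !exists(paste(v, "suffix", sep = "\r"), side_of)
  }, TRUE)
  starts <- endpoints[free]
  # prefer starting through a suffix side (forward orientation); this
  # makes orientation-flipped inputs traverse paths in reverse, so their
  # scaffolds come out reverse-complemented
  exit_suffix <- vapply(starts, function(v) {
    !exists(paste(v, "prefix", sep = "\r"), side_of)
  }, TRUE)
  starts <- starts[order(!exit_suffix, starts)]
  visited_e <- logical(nrow(E))
  used_v <- character(0)
  layout <- list()
  scaf_n <- 0
  for (v0 in starts) {
    if (v0 %in% used_v) next
    scaf_n <- scaf_n + 1
    v <- v0
    # start by exiting through the side that has an edge
    has_pre <- exists(paste(v, "prefix", sep = "\r"), side_of)
    exit_end <- if (has_pre) "prefix" else "suffix"
    orient <- if (exit_end == "suffix") "+" else "-"
    part <- 1
    rows <- list()
    repeat {
      key <- paste(v, exit_end, sep = "\r")
      k <- if (exists(key, side_of)) get(key, side_of) else NA
      more <- !is.na(k) && !visited_e[k]
      gap <- NA_integer_
      if (more) {
        med <- lower_median(E$dist[[k]])
        gap <- if (!is.na(med) && med > 0) as.integer(med) else 0L
      }
      rows[[part]] <- data.frame(
        scaffold = paste0("scaffold_", scaf_n), part = part,
        contig = v, orientation = orient, gap_after = gap,
        stringsAsFactors = FALSE)
      used_v <- c(used_v, v)
      if (!more) break
      visited_e[k] <- TRUE
      nxt <- if (E$v1[k] == v && E$end1[k] == exit_end) {
        c(E$v2[k], E$end2[k])
      } else {
        c(E$v1[k], E$end1[k])
      }
      v <- nxt[1]
      enter_end <- nxt[2]
      orient <- if (enter_end == "prefix") "+" else "-"
      exit_end <- if (enter_end == "prefix") "suffix" else "prefix"
      part <- part + 1
    }
    layout[[scaf_n]] <- do.call(rbind, rows)
  }
  for (v in sort(setdiff(ids, used_v))) {
    scaf_n <- scaf_n + 1
    layout[[scaf_n]] <- data.frame(
      scaffold = paste0("scaffold_", scaf_n), part = 1, contig = v,
      orientation = "+", gap_after = NA_integer_, stringsAsFactors = FALSE)
  }
  layout <- if (length(layout)) do.call(rbind, layout) else {
    data.frame(scaffold = character(0), part = integer(0),
               contig = character(0), orientation = character(0),
               gap_after = integer(0), stringsAsFactors = FALSE)
  }
  rownames(layout) <- NULL
  build_scaffold_seqs(layout, seqs)
}

# connected components over the edges of a scaffolding graph (edge ids ->
# component label), ignoring bi-directed side information
edge_components <- function(E) {
  vs <- unique(c(E$v1, E$v2))
  parent <- setNames(seq_along(vs), vs)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(E))) {
    a <- find(match(E$v1[k], vs)); b <- find(match(E$v2[k], vs))
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(nrow(E)), function(k) find(match(E$v1[k], vs)), 0L)
}

build_scaffold_seqs <- function(layout, seqs) {
  out <- character(0)
  for (sc in unique(layout$scaffold)) {
    part <- layout[layout$scaffold == sc, ]
    part <- part[order(part$part), ]
    pieces <- character(0)
    for (i in seq_len(nrow(part))) {
      s <- seqs[[part$contig[i]]]
      if (part$orientation[i] == "-") s <- revcomp(s)
      pieces <- c(pieces, s)
      if (i < nrow(part)) {
        pieces <- c(pieces, strrep("N", part$gap_after[i]))
      }
    }
    out[[sc]] <- paste(pieces, collapse = "")
  }
  structure(list(layout = layout, seqs = out), class = "scaffolds")
}

#' @export
print.scaffolds <- function(x, ...) {
  cat("<scaffolds> ", length(x$seqs), " scaffold(s) from ",
      nrow(x$layout), " contig(s), ", sum(nchar(x$seqs)), " bp\n", sep = "")
  invisible(x)
}

#' Write scaffolds as AGP v2.1
#'
#' @param scaffolds A `scaffolds` object.
#' @param contig_seqs Named character vector of component contig
#'   sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(scaffolds, contig_seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  for (sc in unique(scaffolds$layout$scaffold)) {
    part <- scaffolds$layout[scaffolds$layout$scaffold == sc, ]
    part <- part[order(part$part), ]
    beg <- 1L; n <- 0L
    for (i in seq_len(nrow(part))) {
      len <- nchar(contig_seqs[[part$contig[i]]])
      n <- n + 1L
      writeLines(sprintf("%s\t%d\t%d\t%d\tW\t%s\t1\t%d\t%s",
                         sc, beg, beg + len - 1L, n, part$contig[i], len,
                         part$orientation[i]), con)
      beg <- beg + len
      if (i < nrow(part) && part$gap_after[i] > 0) {
        n <- n + 1L
        writeLines(sprintf("%s\t%d\t%d\t%d\tN\t%d\tscaffold\tyes\talign_genus",
                           sc, beg, beg + part$gap_after[i] - 1L, n,
                           part$gap_after[i]), con)
        beg <- beg + part$gap_after[i]
      }
    }
  }
  invisible(path)
}

#' Dump a scaffolding graph as GFA 1.0
#'
#' @param graph A `scaffolding_graph`.
#' @param seqs Optional named character vector of contig sequences (else
#'   segments are written without sequence).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(graph, seqs = NULL, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  for (v in graph$vertices$id) {
    s <- if (!is.null(seqs)) seqs[[v]] else "*"
    writeLines(sprintf("S\t%s\t%s", v, s), con)
  }
  e <- graph$edges
  for (k in seq_len(nrow(e))) {
    writeLines(sprintf("L\t%s\t%s\t%s\t%s\t0M\tRC:i:%d",
                       e$v1[k], if (e$end1[k] == "suffix") "+" else "-",
                       e$v2[k], if (e$end2[k] == "prefix") "+" else "-",
                       e$weight[k]), con)
  }
  invisible(path)
}
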