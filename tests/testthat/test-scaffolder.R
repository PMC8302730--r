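# Dovetail filtering, graph construction/simplification, path traversal.

paf_row <- function(query = "r1", qlen = 6000L, qstart = 0L, qend = 300L,
                    strand = "+", target = "c1", tlen = 10000L,
                    tstart = 9700L, tend = 10000L, nmatch = 280L,
                    blocklen = 300L, mapq = 60L, primary = TRUE) {
  data.frame(query = query, qlen = qlen, qstart = qstart, qend = qend,
             strand = strand, target = target, tlen = tlen,
             tstart = tstart, tend = tend, nmatch = nmatch,
             blocklen = blocklen, mapq = mapq, primary = primary,
             stringsAsFactors = FALSE)
}

test_that("dovetail filter enforces mapq, shape and overhang rules", {
  # perfect contig-suffix / read-prefix join
  ok <- paf_row()
  expect_identical(nrow(filter_dovetails(ok)), 1L)
  d <- filter_dovetails(ok)
  expect_identical(d$contig_end, "suffix")
  expect_identical(d$read_end, "prefix")

  # mapq exactly 40 rejected, 41 accepted (strictly greater)
  expect_identical(nrow(filter_dovetails(paf_row(mapq = 40L))), 0L)
  expect_identical(nrow(filter_dovetails(paf_row(mapq = 41L))), 1L)
  # secondary alignments rejected
  expect_identical(nrow(filter_dovetails(paf_row(primary = FALSE))), 0L)

  # overhang bound is min(50, 10% of match length): match 300 -> 30
  # read-side overhang 31 rejected, 30 accepted
  expect_identical(nrow(filter_dovetails(
    paf_row(qstart = 31L, qend = 331L))), 0L)
  expect_identical(nrow(filter_dovetails(
    paf_row(qstart = 30L, qend = 330L))), 1L)
  # contig-side overhang: alignment stopping 31 bp before the contig end
  expect_identical(nrow(filter_dovetails(
    paf_row(tstart = 9669L, tend = 9969L))), 0L)
  expect_identical(nrow(filter_dovetails(
    paf_row(tstart = 9670L, tend = 9970L))), 1L)
  # long match: cap at 50 bp
  expect_identical(nrow(filter_dovetails(
    paf_row(qstart = 50L, qend = 1050L, nmatch = 950L,
            blocklen = 1000L))), 1L)
  expect_identical(nrow(filter_dovetails(
    paf_row(qstart = 51L, qend = 1051L, nmatch = 950L,
            blocklen = 1000L))), 0L)

  # mid-read alignments are not dovetails
  expect_identical(nrow(filter_dovetails(
    paf_row(qstart = 2000L, qend = 2300L))), 0L)
  # mid-contig alignments are not dovetails
  expect_identical(nrow(filter_dovetails(
    paf_row(tstart = 4000L, tend = 4300L))), 0L)
  # minus-strand: read suffix joins the contig suffix
  d2 <- filter_dovetails(paf_row(strand = "-", qstart = 5700L,
                                 qend = 6000L))
  expect_identical(nrow(d2), 1L)
  expect_identical(d2$contig_end, "suffix")
  expect_identical(d2$read_end, "suffix")
  # mappings without base-level extent are refused
  expect_error(filter_dovetails(data.frame(query = "r")), "base-level")
})

contig_table <- function(ids, kinds, starts, ends, bb = "bb1") {
  data.frame(id = ids, origin_contig = bb, origin_start = starts,
             origin_end = ends, kind = kinds,
             haplotype = ifelse(kinds == "haplotype-assembled", "h1",
                                "none"),
             length = ends - starts, stringsAsFactors = FALSE)
}

bridge_paf <- function(read, c_from, c_to, tlen_from, tlen_to,
                       gap = 100L, qlen = 4000L) {
  # read prefix aligns to the suffix of c_from, read suffix to the
  # prefix of c_to, `gap` read bases in between
  half <- (qlen - gap) %/% 2L
  rbind(
    paf_row(query = read, qlen = qlen, qstart = 0L, qend = half,
            target = c_from, tlen = tlen_from,
            tstart = tlen_from - half, tend = tlen_from,
            nmatch = half - 50L, blocklen = half),
    paf_row(query = read, qlen = qlen, qstart = half + gap, qend = qlen,
            target = c_to, tlen = tlen_to, tstart = 0L,
            tend = qlen - half - gap, nmatch = qlen - half - gap - 50L,
            blocklen = qlen - half - gap))
}

test_that("edges require one read-prefix and one read-suffix dovetail", {
  info <- contig_table(c("c1", "c2"), rep("haplotype-assembled", 2),
                       c(0L, 5000L), c(4000L, 9000L))
  paf <- do.call(rbind, lapply(sprintf("r%02d", 1:12), function(r) {
    bridge_paf(r, "c1", "c2", 4000L, 4000L)
  }))
  dov <- filter_dovetails(paf)
  g <- build_graph(dov, info, c(bb1 = 9000L))
  expect_identical(nrow(g$edges), 1L)
  expect_identical(g$edges$weight, 12L)
  expect_identical(g$edges$end1, "suffix")  # c1 suffix
  expect_identical(g$edges$end2, "prefix")  # c2 prefix

  # both dovetails on the read prefix: no edge
  both_pre <- rbind(
    paf_row(query = "rp", qlen = 9000L, qstart = 0L, qend = 2000L,
            target = "c1", tlen = 4000L, tstart = 2000L, tend = 4000L,
            nmatch = 1900L, blocklen = 2000L),
    paf_row(query = "rp", qlen = 9000L, qstart = 10L, qend = 2010L,
            target = "c2", tlen = 4000L, tstart = 2000L, tend = 4000L,
            nmatch = 1900L, blocklen = 2000L))
  g2 <- build_graph(filter_dovetails(both_pre), info, c(bb1 = 9000L))
  expect_identical(nrow(g2$edges), 0L)
})

test_that("admission rules gate edges by backbone position and kind", {
  # two haplotype contigs on DIFFERENT backbones, away from extremities:
  # all rules fail
  info <- contig_table(c("c1", "c2"), rep("haplotype-assembled", 2),
                       c(5000L, 5000L), c(9000L, 9000L))
  info$origin_contig <- c("bb1", "bb2")
  paf <- do.call(rbind, lapply(sprintf("r%02d", 1:12), function(r) {
    bridge_paf(r, "c1", "c2", 4000L, 4000L)
  }))
  dov <- filter_dovetails(paf)
  g <- build_graph(dov, info, c(bb1 = 50000L, bb2 = 50000L))
  expect_identical(nrow(g$edges), 0L)

  # same pair at backbone extremities: rule (iv) admits
  info_iv <- info
  info_iv$origin_start <- c(46000L, 0L)
  info_iv$origin_end <- c(50000L, 4000L)
  g_iv <- build_graph(dov, info_iv, c(bb1 = 50000L, bb2 = 50000L))
  expect_identical(nrow(g_iv$edges), 1L)

  # unphased + haplotype pair: rule (iii) admits even mid-backbone
  info_iii <- info
  info_iii$origin_contig <- c("bb1", "bb1")
  info_iii$kind <- c("unphased-backbone", "haplotype-assembled")
  # put a third contig between them so rule (i) cannot apply
  info_iii <- rbind(info_iii,
                    contig_table("mid", "unphased-backbone", 4200L, 4800L))
  g_iii <- build_graph(dov, info_iii, c(bb1 = 50000L))
  expect_identical(nrow(g_iii$edges), 1L)

  # two parallel haplotype contigs of the SAME phaseset never join
  info_par <- contig_table(c("c1", "c2"), rep("haplotype-assembled", 2),
                           c(5000L, 5000L), c(9000L, 9000L))
  g_par <- build_graph(dov, info_par, c(bb1 = 50000L))
  expect_identical(nrow(g_par$edges), 0L)
})

test_that("transitive edges are removed per the path definition", {
  mk_graph <- function(edges) {
    ids <- unique(c(edges$v1, edges$v2))
    info <- contig_table(ids, rep("unphased-backbone", length(ids)),
                         rep(0L, length(ids)), rep(1000L, length(ids)))
    edges$dist <- replicate(nrow(edges), 10L, simplify = FALSE)
    structure(list(vertices = info, edges = edges),
              class = "scaffolding_graph")
  }
  # consistent triangle: A->B->C plus direct A->C with matching arrows
  tri <- data.frame(
    v1 = c("A", "B", "A"), v2 = c("B", "C", "C"),
    end1 = c("suffix", "suffix", "suffix"),
    end2 = c("prefix", "prefix", "prefix"),
    weight = c(20L, 20L, 5L), stringsAsFactors = FALSE)
  g <- remove_transitive_edges(mk_graph(tri))
  expect_identical(nrow(g$edges), 2L)
  expect_false(any(g$edges$v1 == "A" & g$edges$v2 == "C"))

  # arrow at A differs from the path's: kept
  tri2 <- tri
  tri2$end1[3] <- "prefix"
  g2 <- remove_transitive_edges(mk_graph(tri2))
  expect_identical(nrow(g2$edges), 3L)

  # pass-through at the middle vertex must use opposite ends
  tri3 <- tri
  tri3$end1[2] <- "prefix"  # B enters and leaves through its prefix
  g3 <- remove_transitive_edges(mk_graph(tri3))
  expect_identical(nrow(g3$edges), 3L)

  # 50 random bi-directed graphs match the brute-force definition, and
  # the result is invariant to edge order
  set.seed(77)
  for (i in 1:50) {
    g <- random_bigraph(sample(4:8, 1), sample(3:10, 1))
    got <- remove_transitive_edges(g)$edges
    want <- brute_force_transitive(g$edges)
    expect_identical(got[order(got$v1, got$v2, got$end1, got$end2),
                         c("v1", "v2", "end1", "end2")],
                     want[order(want$v1, want$v2, want$end1, want$end2),
                          c("v1", "v2", "end1", "end2")],
                     ignore_attr = TRUE)
    perm <- sample(nrow(g$edges))
    g_perm <- g
    g_perm$edges <- g$edges[perm, ]
    got2 <- remove_transitive_edges(g_perm)$edges
    expect_identical(sort(paste(got2$v1, got2$v2, got2$end1, got2$end2)),
                     sort(paste(got$v1, got$v2, got$end1, got$end2)))
  }
})

test_that("weak edges are removed by count and side-fraction rules", {
  mk <- function(v1, v2, end1, end2, w) {
    edges <- data.frame(v1 = v1, v2 = v2, end1 = end1, end2 = end2,
                        weight = w, stringsAsFactors = FALSE)
    edges$dist <- replicate(nrow(edges), 10L, simplify = FALSE)
    ids <- unique(c(v1, v2))
    info <- contig_table(ids, rep("unphased-backbone", length(ids)),
                         rep(0L, length(ids)), rep(1000L, length(ids)))
    structure(list(vertices = info, edges = edges),
              class = "scaffolding_graph")
  }
  # single edge with weight 9: below the 10-read floor
  g <- remove_weak_edges(mk("A", "B", "suffix", "prefix", 9L))
  expect_identical(nrow(g$edges), 0L)
  expect_identical(nrow(remove_weak_edges(
    mk("A", "B", "suffix", "prefix", 10L))$edges), 1L)

  # side with weights 100 and 5: the 5 goes (5 < 10), the 100 stays
  g2 <- remove_weak_edges(mk(c("A", "A"), c("B", "C"),
                             c("suffix", "suffix"),
                             c("prefix", "prefix"), c(100L, 5L)))
  expect_identical(g2$edges$v2, "B")
  # side with weights 100 and 12: both below 90% of 112, both removed
  g3 <- remove_weak_edges(mk(c("A", "A"), c("B", "C"),
                             c("suffix", "suffix"),
                             c("prefix", "prefix"), c(100L, 12L)))
  expect_identical(nrow(g3$edges), 0L)
  # opposite sides of one vertex are independent pools
  g4 <- remove_weak_edges(mk(c("A", "A"), c("B", "C"),
                             c("suffix", "prefix"),
                             c("prefix", "suffix"), c(100L, 12L)))
  expect_identical(nrow(g4$edges), 2L)
})

chain_graph <- function(dists = list(10L, 10L)) {
  edges <- data.frame(
    v1 = c("A", "B"), v2 = c("B", "C"),
    end1 = c("suffix", "suffix"), end2 = c("prefix", "prefix"),
    weight = c(20L, 20L), stringsAsFactors = FALSE)
  edges$dist <- dists
  ids <- c("A", "B", "C")
  info <- contig_table(ids, rep("unphased-backbone", 3), rep(0L, 3),
                       rep(1000L, 3))
  structure(list(vertices = info, edges = edges),
            class = "scaffolding_graph")
}

test_that("path traversal joins chains with median gaps", {
  seqs <- c(A = random_genome(300, seed = 41),
            B = random_genome(200, seed = 42),
            C = random_genome(250, seed = 43))
  scaf <- traverse_paths(chain_graph(list(c(120L, 140L, 260L), -15L)),
                         seqs)
  expect_length(scaf$seqs, 1)
  # gap = median 140 between A and B; negative median -> direct join
  expect_identical(scaf$seqs[[1]],
                   paste0(seqs[["A"]], strrep("N", 140), seqs[["B"]],
                          seqs[["C"]]))
  lay <- scaf$layout
  expect_identical(lay$contig, c("A", "B", "C"))
  expect_identical(lay$orientation, c("+", "+", "+"))
  expect_identical(lay$gap_after, c(140L, 0L, NA_integer_))

  # zero median is a direct join too
  scaf0 <- traverse_paths(chain_graph(list(0L, 5L)), seqs)
  expect_identical(scaf0$seqs[[1]],
                   paste0(seqs[["A"]], seqs[["B"]], strrep("N", 5),
                          seqs[["C"]]))

  # flipping every contig orientation reverse-complements the scaffold
  g_rc <- chain_graph(list(c(120L, 140L, 260L), -15L))
  g_rc$edges$end1 <- c("prefix", "prefix")
  g_rc$edges$end2 <- c("suffix", "suffix")
  scaf_rc <- traverse_paths(g_rc, setNames(revcomp(seqs), names(seqs)))
  expect_identical(scaf_rc$seqs[[1]], revcomp(scaf$seqs[[1]]))
})

test_that("orientation follows the bi-directed arrows", {
  # A suffix -> B suffix: B must be reverse-complemented
  edges <- data.frame(v1 = "A", v2 = "B", end1 = "suffix",
                      end2 = "suffix", weight = 20L,
                      stringsAsFactors = FALSE)
  edges$dist <- list(10L)
  info <- contig_table(c("A", "B"), rep("unphased-backbone", 2),
                       c(0L, 0L), c(300L, 200L))
  g <- structure(list(vertices = info, edges = edges),
                 class = "scaffolding_graph")
  seqs <- c(A = random_genome(300, seed = 44),
            B = random_genome(200, seed = 45))
  scaf <- traverse_paths(g, seqs)
  expect_length(scaf$seqs, 1)
  expect_identical(scaf$seqs[[1]],
                   paste0(seqs[["A"]], strrep("N", 10),
                          revcomp(seqs[["B"]])))
})

test_that("traversal conserves contigs and respects RC symmetry", {
  set.seed(88)
  for (i in 1:10) {
    g <- random_bigraph(sample(4:8, 1), sample(2:8, 1))
    g <- remove_transitive_edges(g)
    seqs <- setNames(vapply(seq_len(nrow(g$vertices)), function(k) {
      random_genome(sample(100:300, 1))
    }, ""), g$vertices$id)
    scaf <- suppressWarnings(traverse_paths(g, seqs))
    # every contig exactly once
    expect_identical(sort(scaf$layout$contig), sort(g$vertices$id))
    # non-N base conservation
    expect_identical(
      sum(nchar(gsub("N", "", scaf$seqs, fixed = TRUE))),
      sum(nchar(seqs)))
    # flipping every contig end and sequence yields the same molecules
    # (each scaffold equal to the original or its reverse complement)
    g_rc <- g
    flip <- function(x) ifelse(x == "prefix", "suffix", "prefix")
    g_rc$edges$end1 <- flip(g$edges$end1)
    g_rc$edges$end2 <- flip(g$edges$end2)
    seqs_rc <- setNames(revcomp(seqs), names(seqs))
    scaf_rc <- suppressWarnings(traverse_paths(g_rc, seqs_rc))
    canon <- function(x) pmin(x, revcomp(x))
    expect_setequal(canon(unname(scaf_rc$seqs)),
                    canon(unname(scaf$seqs)))
  }
})

test_that("cycles are broken at the lowest-weight edge", {
  edges <- data.frame(
    v1 = c("A", "B", "A"), v2 = c("B", "C", "C"),
    end1 = c("suffix", "suffix", "prefix"),
    end2 = c("prefix", "prefix", "suffix"),
    weight = c(20L, 30L, 11L), stringsAsFactors = FALSE)
  edges$dist <- replicate(3, 10L, simplify = FALSE)
  info <- contig_table(c("A", "B", "C"), rep("unphased-backbone", 3),
                       rep(0L, 3), rep(1000L, 3))
  g <- structure(list(vertices = info, edges = edges),
                 class = "scaffolding_graph")
  seqs <- c(A = random_genome(100, seed = 1),
            B = random_genome(100, seed = 2),
            C = random_genome(100, seed = 3))
  expect_warning(scaf <- traverse_paths(g, seqs), "cycle")
  expect_length(scaf$seqs, 1)
  expect_identical(sort(scaf$layout$contig), c("A", "B", "C"))
  # the weight-11 edge was dropped: C--A join is absent, A starts a path
  expect_identical(scaf$layout$contig[1], "A")
})

test_that("AGP and GFA outputs describe the scaffolds", {
  seqs <- c(A = random_genome(300, seed = 41),
            B = random_genome(200, seed = 42),
            C = random_genome(250, seed = 43))
  g <- chain_graph(list(c(120L, 140L, 260L), -15L))
  scaf <- traverse_paths(g, seqs)
  agp <- withr::local_tempfile(fileext = ".agp")
  write_agp(scaf, seqs, agp)
  lines <- readLines(agp)
  expect_identical(lines[1], "##agp-version\t2.1")
  w <- strsplit(grep("\tW\t", lines, value = TRUE), "\t")
  expect_identical(vapply(w, `[`, "", 6), c("A", "B", "C"))
  n <- strsplit(grep("\tN\t", lines, value = TRUE), "\t")
  expect_identical(vapply(n, `[`, "", 6), "140")
  gfa <- withr::local_tempfile(fileext = ".gfa")
  write_gfa(g, seqs, gfa)
  glines <- readLines(gfa)
  expect_identical(sum(startsWith(glines, "S")), 3L)
  expect_identical(sum(startsWith(glines, "L")), 2L)
})
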