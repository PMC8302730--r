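# Consensus assembly of separated reads, trimming, unphased retention.

fake_phaseset <- function(contig = "ctg", s, e) {
  data.frame(contig = contig, s = s, e = e, n_snv = 2L, dens = 1,
             positions = I(list(c(s, e))), h1 = I(list(c(0L, 1L))),
             read_tags = I(list(character(0))), stringsAsFactors = FALSE)
}

test_that("error-free tiling reads give back the exact truth sequence", {
  truth <- random_genome(20000, seed = 31)
  aln <- tiling_alignments(truth, read_len = 1000, step = 250)
  ps <- fake_phaseset(s = 0, e = 19999)
  raw <- assemble_haplotype(aln$read_id, aln, ps,
                            c(ctg = truth), min_cov = 1)
  expect_length(raw, 1)
  expect_identical(raw[[1]]$seq, truth)
  expect_identical(raw[[1]]$anchor[1], 0L)
})

test_that("noisy 30x consensus is >= 99.9% identical to the planted truth", {
  st <- mutate_genome(random_genome(30000, seed = 32), 0, seed = 1,
                      strain_id = "s1")
  st$coverage <- 30
  reads <- simulate_reads(list(st), mean_len = 3000, sd_len = 1000,
                          seed = 33)
  aln <- emit_truth_alignments(reads, "ctg")
  ps <- fake_phaseset(s = 0, e = 29999)
  raw <- assemble_haplotype(aln$read_id, aln, ps, c(ctg = st$genome))
  # compare each piece against the truth window it is anchored to
  total <- 0; matched <- 0
  for (ctg in raw) {
    window <- substr(st$genome, ctg$anchor[1] + 1,
                     ctg$anchor[length(ctg$anchor)] + 1)
    pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(ctg$seq),
                                        Biostrings::DNAString(window))
    total <- total + nchar(window)
    matched <- matched + nchar(window) * Biostrings::pid(pa) / 100
  }
  expect_gte(100 * matched / total, 99.9)
  # nearly the whole phaseset is assembled
  expect_gte(sum(vapply(raw, function(x) nchar(x$seq), 0)), 28000)
})

full_span_alignments <- function(seqs, cigars, pos = NULL, contig = "ctg") {
  n <- length(seqs)
  new_alignments(data.frame(
    read_id = sprintf("r%03d", seq_len(n)), contig = contig,
    pos = if (is.null(pos)) rep(0L, n) else as.integer(pos),
    strand = "+", mapq = 60L, primary = TRUE, cigar = cigars,
    seq = seqs, stringsAsFactors = FALSE))
}

test_that("a zero-coverage gap splits the consensus in two", {
  truth <- random_genome(2000, seed = 34)
  left <- substr(truth, 1, 800); right <- substr(truth, 1201, 2000)
  aln <- full_span_alignments(c(rep(left, 3), rep(right, 3)),
                              c(rep("800M", 3), rep("800M", 3)),
                              pos = c(0, 0, 0, 1200, 1200, 1200))
  ps <- fake_phaseset(s = 0, e = 1999)
  raw <- assemble_haplotype(aln$read_id, aln, ps, c(ctg = truth))
  expect_length(raw, 2)
  expect_identical(raw[[1]]$seq, left)
  expect_identical(raw[[2]]$seq, right)
  expect_identical(raw[[2]]$anchor[1], 1200L)
  # empty read set: warning, no contig
  expect_warning(out <- assemble_haplotype(character(0), aln, ps,
                                           c(ctg = truth)), "empty")
  expect_length(out, 0)
})

test_that("majority indels are reflected in the consensus", {
  truth <- random_genome(400, seed = 35)
  with_del <- paste0(substr(truth, 1, 100), substr(truth, 103, 400))
  aln <- full_span_alignments(c(truth, rep(with_del, 3)),
                              c("400M", rep("100M2D298M", 3)))
  ps <- fake_phaseset(s = 0, e = 399)
  raw <- assemble_haplotype(aln$read_id, aln, ps, c(ctg = truth))
  expect_length(raw, 1)
  expect_identical(raw[[1]]$seq, with_del)
  # majority insertion of 2 bp after position 199 (0-based)
  with_ins <- paste0(substr(truth, 1, 200), "CA", substr(truth, 201, 400))
  aln2 <- full_span_alignments(c(truth, rep(with_ins, 3)),
                               c("400M", rep("200M2I200M", 3)))
  raw2 <- assemble_haplotype(aln2$read_id, aln2, ps, c(ctg = truth))
  expect_identical(raw2[[1]]$seq, with_ins)
})

test_that("trimming keeps exactly the [s, e] projection", {
  truth <- random_genome(5000, seed = 36)
  aln <- tiling_alignments(truth, 500, 100)
  ps <- fake_phaseset(s = 1000, e = 3999)
  raw <- assemble_haplotype(aln$read_id, aln, ps, c(ctg = truth))
  # consensus extends beyond [s, e] (reads cover the whole contig)
  expect_gt(nchar(raw[[1]]$seq), 3000)
  trimmed <- trim_to_phaseset(raw[[1]], c(ctg = truth), ps, "h1")
  expect_identical(attr(trimmed, "seq"), substr(truth, 1001, 4000))
  expect_identical(trimmed$origin_start, 1000L)
  expect_identical(trimmed$origin_end, 4000L)
  expect_identical(trimmed$kind, "haplotype-assembled")
  # contig already inside [s, e]: unchanged
  inner <- list(seq = substr(truth, 1501, 2500), anchor = 1500:2499)
  trimmed2 <- trim_to_phaseset(inner, c(ctg = truth), ps, "h2")
  expect_identical(attr(trimmed2, "seq"), inner$seq)
  # trimmed length never exceeds the raw length
  expect_lte(nchar(attr(trimmed, "seq")), nchar(raw[[1]]$seq))
})

test_that("unanchored contigs are trimmed by alignment or dropped", {
  truth <- random_genome(8000, seed = 37)
  ps <- fake_phaseset(s = 2000, e = 5999)
  # external-assembler style contig covering [1500, 6500) of the backbone
  ctg <- list(seq = substr(truth, 1501, 6500), anchor = NULL)
  trimmed <- trim_to_phaseset(ctg, c(ctg = truth), ps, "h1")
  expect_false(is.null(trimmed))
  got <- attr(trimmed, "seq")
  expect_gt(nchar(got), 3900)
  expect_lt(nchar(got), 4100)
  expect_true(grepl(substr(got, 100, 300), substr(truth, 2001, 6000),
                    fixed = TRUE))
  # unalignable contig: dropped with a warning
  junk <- list(seq = random_genome(3000, seed = 38), anchor = NULL)
  expect_warning(res <- trim_to_phaseset(junk, c(ctg = truth), ps, "h1"),
                 "dropped")
  expect_null(res)
})

test_that("unphased retention follows the strict > 500 bp rule", {
  bb <- c(ctg = random_genome(10000, seed = 39))
  ps <- rbind(fake_phaseset(s = 400, e = 4999),
              fake_phaseset(s = 5400, e = 9599))
  class(ps) <- c("phasesets", "data.frame")
  # gaps: [0,400) = 400 bp dropped; [5000,5400) = 400 dropped;
  # [9600,10000) = 400 dropped
  out <- collect_unphased(bb, "ctg", ps)
  expect_length(out, 0)
  # 501 bp head gap is retained
  ps2 <- rbind(fake_phaseset(s = 501, e = 4999),
               fake_phaseset(s = 5400, e = 9599))
  out2 <- collect_unphased(bb, "ctg", ps2)
  expect_length(out2, 1)
  expect_identical(out2[[1]]$origin_start, 0L)
  expect_identical(out2[[1]]$origin_end, 501L)
  expect_identical(attr(out2[[1]], "seq"), substr(bb[[1]], 1, 501))
  # exactly 500: dropped
  ps3 <- fake_phaseset(s = 500, e = 9999)
  expect_length(collect_unphased(bb, "ctg", ps3), 0)
  # no phasesets: the whole contig is retained
  ps0 <- ps[0, , drop = FALSE]
  out0 <- collect_unphased(bb, "ctg", ps0)
  expect_length(out0, 1)
  expect_identical(attr(out0[[1]], "seq"), bb[[1]])
  expect_identical(out0[[1]]$kind, "unphased-backbone")
})

test_that("the contig set partitions the backbone with unique ids", {
  comm <- small_community()
  sites <- detect_snvs(comm$alignments, comm$backbone, "backbone")
  mat <- snv_matrix(comm$alignments, sites, "backbone")
  ps <- extract_phasesets(phase_diploid(mat))
  ctgs <- build_contig_set(comm$backbone, list(backbone = ps),
                           list(backbone = mat), comm$alignments)
  info <- ctgs$info
  expect_false(anyDuplicated(info$id) > 0)
  # 1 phaseset, both haplotypes + flanks
  expect_identical(sum(info$kind == "haplotype-assembled"), 2L)
  # phaseset + unphased intervals are mutually disjoint and fit in the
  # backbone
  un <- info[info$kind == "unphased-backbone", ]
  iv <- rbind(data.frame(s = ps$s, e = ps$e + 1L),
              data.frame(s = un$origin_start, e = un$origin_end))
  iv <- iv[order(iv$s), ]
  expect_true(all(iv$s[-1] >= iv$e[-nrow(iv)]))
  expect_lte(sum(iv$e - iv$s), nchar(comm$backbone[[1]]))
  # haplotype contigs resolve their true strain (closest reference)
  ev <- evaluate_assembly(ctgs$seqs[info$id[info$kind ==
                                              "haplotype-assembled"]],
                          comm$genomes)
  hap_assign <- ev$assignments
  expect_identical(sort(hap_assign$reference_id),
                   c("strainA", "strainB"))
  # no phasesets anywhere: output equals input
  ps0 <- ps[0, , drop = FALSE]
  ctgs0 <- build_contig_set(comm$backbone, list(backbone = ps0),
                            list(backbone = mat), comm$alignments)
  expect_identical(unname(ctgs0$seqs), unname(comm$backbone))
})
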