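# SNV detection, diploid phasing, phasesets and read separation.
#
# This is the internal stand-in for the external variant-caller/phaser pair
# (Longshot + HapCUT2) the published pipeline delegates to; an externally
# produced phased VCF plus haplotag table can be ingested instead via
# `phasesets_from_vcf()`.

#' Detect biallelic SNV sites on a backbone contig
#'
#' Columns of the read pileup are reported as SNVs when the backbone base
#' and the most frequent non-backbone base both reach `min_per_allele`
#' reads, the alternate fraction reaches `min_alt_frac`, and total depth
#' reaches `min_depth`.  Only substitution sites are considered; the
#' per-allele minimum guards against long-read error pileups.
#'
#' @param alignments Alignment records ([new_alignments] layout).
#' @param backbone Named character vector of backbone contig sequences.
#' @param contig Contig to scan; must be a name of `backbone`.
#' @param min_depth Minimum total base depth (default 10).
#' @param min_alt_frac Minimum alternate allele fraction (default 0.2).
#' @param min_per_allele Minimum read count per allele (default 5).
#' @return Data frame of sites: `contig`, `pos` (0-based), `ref`, `alt`,
#'   `depth`, `alt_count`, sorted by position.
#' @export
detect_snvs <- function(alignments, backbone, contig,
                        min_depth = 10, min_alt_frac = 0.2,
                        min_per_allele = 5) {
  if (!contig %in% names(backbone)) {
    stop("contig ", contig, " not found in the backbone assembly")
  }
  empty <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      depth = integer(0), alt_count = integer(0),
                      stringsAsFactors = FALSE)
  aln <- alignments[alignments$primary & alignments$contig == contig, ]
  if (nrow(aln) == 0) return(empty)
  L <- nchar(backbone[[contig]])
  cnt <- cpp_pileup(aln$seq, aln$cigar, aln$pos, 0L, L)
  tot <- cnt[1, ] + cnt[2, ] + cnt[3, ] + cnt[4, ]
  bases <- c("A", "C", "G", "T")
  refb <- match(strsplit(toupper(backbone[[contig]]), "")[[1]], bases)
  cand <- which(tot >= min_depth & !is.na(refb))
  if (length(cand) == 0) return(empty)
  sub <- cnt[, cand, drop = FALSE]
  ref_idx <- refb[cand]
  ref_cnt <- sub[cbind(ref_idx, seq_along(cand))]
  # most frequent non-reference base (ties: A < C < G < T)
  sub[cbind(ref_idx, seq_along(cand))] <- -1L
  alt_idx <- max.col(t(sub), ties.method = "first")
  alt_cnt <- sub[cbind(alt_idx, seq_along(cand))]
  keep <- ref_cnt >= min_per_allele & alt_cnt >= min_per_allele &
    alt_cnt / tot[cand] >= min_alt_frac
  if (!any(keep)) return(empty)
  data.frame(contig = contig, pos = cand[keep] - 1L,
             ref = bases[ref_idx[keep]], alt = bases[alt_idx[keep]],
             depth = tot[cand][keep], alt_count = alt_cnt[keep],
             stringsAsFactors = FALSE)
}

#' Build the read x SNV allele matrix for one contig
#'
#' Sparse container of per-read alleles at called SNV sites; an entry
#' exists only where the read's alignment spans the site and shows the ref
#' or alt allele (third bases and deletions are missing).
#'
#' @param alignments Alignment records.
#' @param sites SNV table from [detect_snvs()].
#' @param contig Contig label.
#' @return A `read_snv_matrix`: list with `contig`, `reads` (data frame
#'   `read_id`, `start`, `end` 0-based half-open alignment spans), `sites`,
#'   and `entries` (data frame `read`, `site` 1-based indices, `allele`
#'   0 = ref / 1 = alt).
#' @export
snv_matrix <- function(alignments, sites, contig) {
  aln <- alignments[alignments$primary & alignments$contig == contig, ]
  sites <- sites[sites$contig == contig, , drop = FALSE]
  sites <- sites[order(sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  span <- if (nrow(aln)) cpp_cigar_ref_span(aln$cigar) else integer(0)
  reads <- data.frame(read_id = aln$read_id, start = aln$pos,
                      end = aln$pos + span, stringsAsFactors = FALSE)
  ent <- if (nrow(aln) && nrow(sites)) {
    cpp_read_alleles(aln$seq, aln$cigar, aln$pos,
                     sites$pos, sites$ref, sites$alt)
  } else {
    list(read = integer(0), site = integer(0), allele = integer(0))
  }
  structure(list(contig = contig, reads = reads, sites = sites,
                 entries = data.frame(read = ent$read, site = ent$site,
                                      allele = ent$allele)),
            class = "read_snv_matrix")
}

#' @export
print.read_snv_matrix <- function(x, ...) {
  cat("<read_snv_matrix> ", x$contig, ": ", nrow(x$reads), " reads x ",
      nrow(x$sites), " sites, ", nrow(x$entries), " entries\n", sep = "")
  invisible(x)
}

# majority haplotype vector from net votes; undefined sites default to ref
votes_to_h <- function(votes) as.integer(votes > 0)

# Hamming distances of one read's entries to h1 (h) and h2 (1 - h),
# counting only sites where the haplotype is defined.
read_distances <- function(sidx, allele, h, defined) {
  use <- defined[sidx]
  d1 <- sum(allele[use] != h[sidx[use]])
  list(d1 = d1, d2 = sum(use) - d1, shared = sum(use))
}

#' Phase SNVs into two haplotypes (greedy MEC heuristic)
#'
#' Blocks break wherever no read links two consecutive SNV sites.  Within a
#' block, a greedy seed-and-extend heuristic minimises the mismatch error
#' count (MEC): the read covering most sites seeds haplotype 1, remaining
#' reads are assigned to the nearer haplotype in order of decreasing site
#' overlap, and two refinement sweeps reassign every read against the
#' current majority haplotypes.  Exactly two haplotypes are produced per
#' block (the iterative outer loop handles additional strains).  All ties
#' are broken deterministically (lexicographic read id; tied reads are left
#' untagged; tied site votes default to the reference allele), so the
#' result is reproducible irrespective of `seed`.
#'
#' @param matrix A `read_snv_matrix`.
#' @param seed Accepted for interface stability; the heuristic is
#'   deterministic.
#' @return A `phase_blocks` object: list with `contig`, `sites`, and
#'   `blocks`, each block holding `site_idx`, `positions`, `h1` (0/1 allele
#'   vector of haplotype 1; haplotype 2 is its complement), `read_tags`
#'   (named "h1"/"h2"/"untagged"), and `mec`.
#' @export
phase_diploid <- function(matrix, seed = 0) {
  sites <- matrix$sites
  ent <- matrix$entries
  blocks <- list()
  if (nrow(sites) > 0 && nrow(ent) > 0) {
    # adjacency: site j linked to j+1 if one read holds alleles at both
    o <- order(ent$read, ent$site)
    r <- ent$read[o]; s <- ent$site[o]
    link <- logical(max(nrow(sites) - 1, 0))
    adj <- which(r[-1] == r[-length(r)] & s[-1] == s[-length(s)] + 1L)
    link[s[adj]] <- TRUE
    block_id <- cumsum(c(1L, !link))  # per site
    for (b in unique(block_id)) {
      site_idx <- which(block_id == b)
      sel <- ent$site %in% site_idx
      if (!any(sel)) next
      e <- ent[sel, ]
      # block-local site indices
      loc <- match(e$site, site_idx)
      by_read <- split(seq_len(nrow(e)), e$read)
      read_ids <- matrix$reads$read_id[as.integer(names(by_read))]
      cover <- lengths(by_read)
      lo <- vapply(by_read, function(idx) min(loc[idx]), 0L)
      hi <- vapply(by_read, function(idx) max(loc[idx]), 0L)
      nb <- length(site_idx)
      votes <- numeric(nb)
      assign <- rep(NA_integer_, length(by_read))  # 1, 2 or NA
      # seed with the read covering most sites, then extend outward from
      # the seed so every read is scored against already-phased sites:
      # rightward by increasing start, then leftward by decreasing end
      seed <- order(-cover, read_ids)[1]
      right <- setdiff(which(lo >= lo[seed]), seed)
      right <- right[order(lo[right], read_ids[right])]
      left <- which(lo < lo[seed])
      left <- left[order(-hi[left], read_ids[left])]
      ord <- c(seed, right, left)
      first <- TRUE
      for (k in ord) {
        idx <- by_read[[k]]
        sidx <- loc[idx]; al <- e$allele[idx]
        if (first) {
          votes[sidx] <- votes[sidx] + (2 * al - 1)
          assign[k] <- 1L
          first <- FALSE
          next
        }
        def <- votes[sidx] != 0
        d1 <- sum(al[def] != (votes[sidx][def] > 0))
        d2 <- sum(def) - d1
        if (d1 < d2) {
          assign[k] <- 1L
          votes[sidx] <- votes[sidx] + (2 * al - 1)
        } else if (d2 < d1) {
          assign[k] <- 2L
          votes[sidx] <- votes[sidx] - (2 * al - 1)
        } # tie (including zero defined sites): untagged, no vote
      }
      # refinement sweeps against fixed majority haplotypes
      for (sweep in 1:2) {
        h <- votes_to_h(votes)
        newassign <- rep(NA_integer_, length(by_read))
        for (k in seq_along(by_read)) {
          idx <- by_read[[k]]
          sidx <- loc[idx]; al <- e$allele[idx]
          d1 <- sum(al != h[sidx])
          d2 <- length(idx) - d1
          if (d1 < d2) newassign[k] <- 1L
          else if (d2 < d1) newassign[k] <- 2L
        }
        assign <- newassign
        votes <- numeric(nb)
        for (k in seq_along(by_read)) {
          if (is.na(assign[k])) next
          idx <- by_read[[k]]
          sgn <- if (assign[k] == 1L) 1 else -1
          votes[loc[idx]] <- votes[loc[idx]] + sgn * (2 * e$allele[idx] - 1)
        }
      }
      h <- votes_to_h(votes)
      # MEC: every read contributes its distance to the nearer haplotype
      mec <- 0L
      tags <- character(length(by_read))
      for (k in seq_along(by_read)) {
        idx <- by_read[[k]]
        d1 <- sum(e$allele[idx] != h[loc[idx]])
        d2 <- length(idx) - d1
        mec <- mec + min(d1, d2)
        tags[k] <- if (is.na(assign[k])) "untagged"
                   else if (assign[k] == 1L) "h1" else "h2"
      }
      blocks[[length(blocks) + 1]] <- list(
        site_idx = site_idx,
        positions = sites$pos[site_idx],
        h1 = h,
        read_tags = setNames(tags, read_ids),
        read_cover = setNames(as.integer(cover), read_ids),
        mec = mec)
    }
  }
  structure(list(contig = matrix$contig, sites = sites, blocks = blocks),
            class = "phase_blocks")
}

#' @export
print.phase_blocks <- function(x, ...) {
  cat("<phase_blocks> ", x$contig, ": ", length(x$blocks), " block(s), ",
      nrow(x$sites), " phased site(s)\n", sep = "")
  invisible(x)
}

#' Global per-read haplotype tags
#'
#' A read spanning several blocks takes its tag from the block where it
#' covers most sites (lexicographically first block on ties).
#'
#' @param blocks A `phase_blocks` object.
#' @return Named character vector, values "h1"/"h2"/"untagged".
#' @export
read_tags <- function(blocks) {
  tags <- new.env(parent = emptyenv())
  best <- new.env(parent = emptyenv())
  for (b in blocks$blocks) {
    ids <- names(b$read_tags)
    for (i in seq_along(ids)) {
      id <- ids[i]
      cov <- b$read_cover[[i]]
      prev <- if (exists(id, best)) get(id, best) else -1L
      if (cov > prev) {
        assign(id, cov, best)
        assign(id, b$read_tags[[i]], tags)
      }
    }
  }
  ids <- sort(ls(tags))
  setNames(vapply(ids, function(id) get(id, tags), ""), ids)
}

#' Extract phasesets from phased blocks
#'
#' A phaseset is the interval of a backbone contig from the first to the
#' last phased SNV of one block, with dens(PS) = 100 * #SNVs / interval
#' length.  Blocks whose density falls strictly below `min_dens` percent
#' are discarded: separating strains of identity above ~99.9% is not
#' attempted, and sporadic false-positive SNVs cannot split a contig.
#'
#' @param blocks A `phase_blocks` object.
#' @param min_dens Minimum SNV density in percent (default 0.1; discard is
#'   strict `<`, a block at exactly `min_dens` is retained).
#' @return A `phasesets` data frame: `contig`, `s`, `e` (0-based inclusive
#'   positions of first/last SNV), `n_snv`, `dens`, plus list columns
#'   `positions`, `h1` (allele vector), `read_tags`.
#' @export
extract_phasesets <- function(blocks, min_dens = 0.1) {
  rows <- lapply(blocks$blocks, function(b) {
    s <- min(b$positions); e <- max(b$positions)
    dens <- 100 * length(b$positions) / (e - s + 1)
    if (dens < min_dens) return(NULL)
    data.frame(contig = blocks$contig, s = s, e = e,
               n_snv = length(b$positions), dens = dens,
               positions = I(list(b$positions)), h1 = I(list(b$h1)),
               read_tags = I(list(b$read_tags)),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(contig = character(0), s = integer(0), e = integer(0),
               n_snv = integer(0), dens = numeric(0),
               positions = I(list()), h1 = I(list()), read_tags = I(list()))
  }
  out <- out[order(out$s), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("phasesets", "data.frame")
  out
}

#' Separate reads of a phaseset by closest haplotype
#'
#' All reads whose alignment overlaps the phaseset interval `[s, e]` are
#' partitioned into three disjoint sets: assigned to haplotype 1 or 2 by
#' minimum Hamming distance to the phased allele vectors, or untagged when
#' the distances tie or the read covers no phased site.
#'
#' @param phaseset One row of a [extract_phasesets()] result.
#' @param matrix The `read_snv_matrix` the phasing was computed from.
#' @return List with character vectors `h1`, `h2`, `untagged` of read ids.
#' @export
separate_reads <- function(phaseset, matrix) {
  s <- phaseset$s; e <- phaseset$e
  reads <- matrix$reads
  overlapping <- which(reads$start <= e & reads$end > s)
  site_idx <- which(matrix$sites$pos >= s & matrix$sites$pos <= e)
  h <- phaseset$h1[[1]]
  names(h) <- as.character(site_idx)
  ent <- matrix$entries[matrix$entries$site %in% site_idx, ]
  res <- rep("untagged", length(overlapping))
  if (nrow(ent)) {
    loc <- match(ent$site, site_idx)
    mism <- as.integer(ent$allele != h[loc])
    d1 <- rowsum(mism, ent$read)
    tot <- rowsum(rep(1L, nrow(ent)), ent$read)
    ridx <- as.integer(rownames(d1))
    d2 <- tot[, 1] - d1[, 1]
    tag <- ifelse(d1[, 1] < d2, "h1", ifelse(d2 < d1[, 1], "h2", "untagged"))
    m <- match(ridx, overlapping)
    ok <- !is.na(m)
    res[m[ok]] <- tag[ok]
  }
  ids <- reads$read_id[overlapping]
  list(h1 = ids[res == "h1"],
       h2 = ids[res == "h2"],
       untagged = ids[res == "untagged"])
}

#' Write phased SNVs as VCF 4.2
#'
#' Phased genotypes `0|1` with a `PS` tag equal to the 1-based phaseset
#' start position.
#'
#' @param phasesets A [extract_phasesets()] result.
#' @param sites The SNV table the phasing was computed from.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(phasesets, sites, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsample"),
             con)
  for (i in seq_len(nrow(phasesets))) {
    ps <- phasesets[i, ]
    pos <- ps$positions[[1]]
    h <- ps$h1[[1]]
    sidx <- match(pos, sites$pos)
    gt <- ifelse(h == 0, "0|1", "1|0")
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:PS\t%s:%d",
                       ps$contig, pos + 1L, sites$ref[sidx],
                       sites$alt[sidx], gt, ps$s + 1L), con)
  }
  invisible(path)
}
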