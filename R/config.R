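# Pipeline configuration: every tunable with its default.

#' Pipeline configuration
#'
#' Collects all tunables of the separation pipeline.  Defaults: SNV
#' calling at `min_depth` 10, `min_alt_frac` 0.2, `min_per_allele` 5;
#' phaseset density floor `min_dens` 0.1% (strict `<` discards); unphased
#' retention above `min_unphased_len` 500 bp; dovetail filter `min_mapq`
#' 40 (strict `>`), overhang at most `min(max_overhang` 50 bp`,
#' overhang_frac` 10%`)` of the match length; weak edges below
#' `weak_edge_min_reads` 10 reads or `weak_edge_frac` 90% of their side
#' support; Hamming records require `hamming_min_overlap` 3000 bp; a new
#' round needs a relative rate improvement of `improvement_frac` 1%; at
#' most `max_strains` - 1 = 4 rounds by default.
#'
#' @param min_depth,min_alt_frac,min_per_allele SNV calling thresholds.
#' @param min_dens Phaseset SNV density floor (percent).
#' @param min_unphased_len Minimum retained unphased length (bp).
#' @param min_cov Consensus coverage split threshold.
#' @param min_mapq,max_overhang,overhang_frac Dovetail filter.
#' @param weak_edge_min_reads,weak_edge_frac Weak edge removal.
#' @param end_window Backbone extremity window (bp) for edge admission.
#' @param hamming_min_overlap Minimum read/phaseset overlap (bp).
#' @param improvement_frac Relative Hamming improvement required.
#' @param max_strains Maximal number of conspecific strains n.
#' @param preset Aligner preset ("map-pb" or "map-ont").
#' @param threads Aligner threads.
#' @param seed Integer seed.
#' @param external_phaser,external_assembler Optional external tool
#'   command templates (see [assemble_haplotype()]).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_depth = 10, min_alt_frac = 0.2,
                            min_per_allele = 5, min_dens = 0.1,
                            min_unphased_len = 500, min_cov = 3,
                            min_mapq = 40, max_overhang = 50,
                            overhang_frac = 0.1,
                            weak_edge_min_reads = 10,
                            weak_edge_frac = 0.9, end_window = 1000,
                            hamming_min_overlap = 3000,
                            improvement_frac = 0.01, max_strains = 5,
                            preset = "map-pb", threads = 1, seed = 1,
                            external_phaser = NULL,
                            external_assembler = NULL) {
  cfg <- list(min_depth = min_depth, min_alt_frac = min_alt_frac,
              min_per_allele = min_per_allele, min_dens = min_dens,
              min_unphased_len = min_unphased_len, min_cov = min_cov,
              min_mapq = min_mapq, max_overhang = max_overhang,
              overhang_frac = overhang_frac,
              weak_edge_min_reads = weak_edge_min_reads,
              weak_edge_frac = weak_edge_frac, end_window = end_window,
              hamming_min_overlap = hamming_min_overlap,
              improvement_frac = improvement_frac,
              max_strains = max_strains, preset = preset,
              threads = threads, seed = seed,
              external_phaser = external_phaser,
              external_assembler = external_assembler)
  stopifnot(cfg$min_dens >= 0, cfg$min_unphased_len >= 0,
            cfg$min_mapq >= 0, cfg$overhang_frac >= 0,
            cfg$overhang_frac <= 1, cfg$weak_edge_frac >= 0,
            cfg$weak_edge_frac <= 1, cfg$improvement_frac >= 0,
            cfg$improvement_frac < 1, cfg$max_strains >= 2)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write a configuration as a flat key=value file
#' @param config A [pipeline_config()] list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  keep <- !vapply(config, is.null, TRUE)
  writeLines(paste0(names(config)[keep], "=",
                    vapply(config[keep], as.character, "")), path)
  invisible(path)
}

#' Read a flat key=value configuration file
#' @param path File path.
#' @return A `pipeline_config` with the file's overrides applied.
#' @export
read_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    v <- paste(x[-1], collapse = "=")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- vapply(kv, `[`, "", 1)
  do.call(pipeline_config, vals)
}
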