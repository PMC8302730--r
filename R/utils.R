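# Small shared helpers.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N, any case).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate a random genome sequence
#'
#' Uniform i.i.d. bases; used to seed synthetic strain communities.
#'
#' @param length Genome length in bp.
#' @param seed Optional integer seed.
#' @return A single character string.
#' @export
random_genome <- function(length, seed = NULL) {
  stopifnot(length >= 1)
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                        collapse = ""))
}

# Lower median of an integer sample (no interpolation): element at position
# ceiling(n/2) of the sorted vector.  Gap lengths are integer base counts.
lower_median <- function(x) {
  if (length(x) == 0) return(NA_integer_)
  sort(x)[ceiling(length(x) / 2)]
}

# union length of a set of half-open intervals [start, end)
interval_union_length <- function(start, end) {
  if (length(start) == 0) return(0)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  total <- 0
  cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] > cur_e) {
      total <- total + (cur_e - cur_s)
      cur_s <- start[i]; cur_e <- end[i]
    } else {
      cur_e <- max(cur_e, end[i])
    }
  }
  total + (cur_e - cur_s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
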