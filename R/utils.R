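#' @keywords internal
"_PACKAGE"

## Shared low-level helpers. Sequence strings are plain uppercase character
## vectors over {A,C,G,T}; positions are 1-based unless a function says
## otherwise (interval masks are 0-based half-open, BED-style).

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
## seed = NULL means "use the current RNG stream" (no restore).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    stop(sprintf("'%s' must be a single number >= %s", name, min), call. = FALSE)
  }
  invisible(x)
}

## Variant class from allele strings (VCF-style, anchored indels).
variant_class <- function(ref, alt) {
  lr <- nchar(ref)
  la <- nchar(alt)
  ifelse(lr == 1L & la == 1L, "SNV", ifelse(la > lr, "insertion", "deletion"))
}
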