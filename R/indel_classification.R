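## Tandem-repeat context and breakpoint microhomology for small indels.
##
## Indels in long tandem repeats are error-prone calls and are excluded by
## run-length thresholds (mononucleotide > 7 units, dinucleotide > 4,
## trinucleotide-or-longer > 2). Deletions of >= 3 nt outside repeats are
## scored for 2-4 nt microhomology between the deleted sequence and the
## flanks, a hallmark of end-joining repair of double-strand breaks.

#' Repeat-based indel exclusion thresholds
#'
#' @param max_mono_units Maximum allowed reference run length (units) for
#'   mononucleotide-repeat indels. Default 7.
#' @param max_di_units Same for dinucleotide repeats. Default 4.
#' @param max_tri_plus_units Same for unit length >= 3. Default 2.
#' @return Object of class `repeat_exclusion_params`.
#' @export
repeat_exclusion_params <- function(max_mono_units = 7L, max_di_units = 4L,
                                    max_tri_plus_units = 2L) {
  p <- list(max_mono_units = as.integer(max_mono_units),
            max_di_units = as.integer(max_di_units),
            max_tri_plus_units = as.integer(max_tri_plus_units))
  if (any(unlist(p) < 1L)) stop("all unit thresholds must be >= 1", call. = FALSE)
  structure(p, class = "repeat_exclusion_params")
}

## Smallest period that tiles `s` exactly, among lengths 1..max_unit;
## NA if none (then the whole string is the only candidate unit).
tiling_units <- function(s, max_unit = 6L) {
  n <- nchar(s)
  ls <- seq_len(min(max_unit, n))
  ls[vapply(ls, function(l) {
    n %% l == 0L && identical(strrep(substr(s, 1L, l), n %/% l), s)
  }, logical(1))]
}

## Count tandem copies of `unit` in `seq` covering/adjacent to the run that
## starts at 1-based position `at` (the first base of the indel allele).
count_tandem_copies <- function(seq, unit, at) {
  l <- nchar(unit)
  n <- nchar(seq)
  count <- 0L
  p <- at
  while (p + l - 1L <= n && substr(seq, p, p + l - 1L) == unit) {
    count <- count + 1L
    p <- p + l
  }
  p <- at - l
  while (p >= 1L && substr(seq, p, p + l - 1L) == unit) {
    count <- count + 1L
    p <- p - l
  }
  count
}

## Core repeat annotation on raw sequence context. `pos` is the 1-based
## position of the anchor base (VCF convention: ref and alt share the anchor).
annotate_repeat_one <- function(seq, pos, ref, alt, max_unit = 6L) {
  lr <- nchar(ref)
  la <- nchar(alt)
  if (lr == la) stop("not an indel", call. = FALSE)
  if (substr(ref, 1L, 1L) != substr(alt, 1L, 1L)) {
    stop("indel alleles must share the anchor base (left-aligned VCF style)",
         call. = FALSE)
  }
  indel_seq <- if (lr > la) substr(ref, la + 1L, lr) else substr(alt, lr + 1L, la)
  at <- pos + 1L  # first inserted/deleted base (for insertions: first ref base right of anchor)
  units <- tiling_units(indel_seq, max_unit)
  if (length(units) == 0L) units <- nchar(indel_seq)
  best <- NULL
  for (l in units) {
    unit <- substr(indel_seq, 1L, l)
    cnt <- count_tandem_copies(seq, unit, at)
    if (is.null(best)) best <- list(unit = unit, count = cnt)
    if (cnt >= 2L) { best <- list(unit = unit, count = cnt); break }
  }
  list(unit = best$unit,
       unit_length = nchar(best$unit),
       unit_count = max(1L, best$count),
       is_repeat_indel = best$count >= 2L)
}

#' Annotate indels with their tandem-repeat context
#'
#' For each indel the smallest sequence unit whose tandem copy number is
#' changed by the indel is located, and its reference copy number at the locus
#' counted (copies spanning plus flanking the indel). An indel is a "repeat
#' indel" iff that copy number is at least 2; `unit_count` is floored at 1 for
#' insertions whose unit does not occur in the reference.
#'
#' @param calls Data frame of indel calls with columns `chrom`, `pos`
#'   (1-based anchor), `ref`, `alt` (left-aligned, anchored).
#' @param reference Named character vector of chromosome sequences.
#' @param max_unit Longest repeat unit searched. Default 6.
#' @param min_flank Minimum available flank either side; shorter context is an
#'   error. Default 50.
#' @return `calls` with columns `unit`, `unit_length`, `unit_count`,
#'   `is_repeat_indel` appended.
#' @export
annotate_repeat <- function(calls, reference, max_unit = 6L, min_flank = 50L) {
  n <- nrow(calls)
  unit <- character(n); ulen <- integer(n); ucnt <- integer(n); isrep <- logical(n)
  for (i in seq_len(n)) {
    seq <- reference[[calls$chrom[i]]]
    if (is.null(seq)) stop("chromosome not in reference: ", calls$chrom[i], call. = FALSE)
    span <- max(nchar(calls$ref[i]), nchar(calls$alt[i]))
    if (calls$pos[i] <= min_flank ||
        calls$pos[i] + span - 1L + min_flank > nchar(seq)) {
      stop("flank too short for indel at ", calls$chrom[i], ":", calls$pos[i],
           call. = FALSE)
    }
    a <- annotate_repeat_one(seq, calls$pos[i], calls$ref[i], calls$alt[i], max_unit)
    unit[i] <- a$unit; ulen[i] <- a$unit_length
    ucnt[i] <- a$unit_count; isrep[i] <- a$is_repeat_indel
  }
  calls$unit <- unit
  calls$unit_length <- ulen
  calls$unit_count <- ucnt
  calls$is_repeat_indel <- isrep
  calls
}

#' Apply the repeat-based exclusion rule
#'
#' Excludes an annotated indel iff it lies in a mononucleotide run of more
#' than `max_mono_units` units, a dinucleotide run of more than `max_di_units`
#' units, or a trinucleotide-or-longer run of more than `max_tri_plus_units`
#' units.
#'
#' @param ann Data frame with `unit_length` and `unit_count` columns (as from
#'   [annotate_repeat()]), or a single annotation list.
#' @param params [repeat_exclusion_params()].
#' @return Logical vector: `TRUE` = exclude.
#' @export
apply_repeat_exclusion <- function(ann, params = repeat_exclusion_params()) {
  if (!is.data.frame(ann)) ann <- as.data.frame(ann[c("unit_length", "unit_count")])
  (ann$unit_length == 1L & ann$unit_count > params$max_mono_units) |
    (ann$unit_length == 2L & ann$unit_count > params$max_di_units) |
    (ann$unit_length >= 3L & ann$unit_count > params$max_tri_plus_units)
}

## Core microhomology test on raw sequences. A deletion shows breakpoint
## microhomology iff it is >= 3 nt long and at least the first 2 deleted bases
## equal the start of the downstream flank, or the last 2 deleted bases equal
## the end of the upstream flank. The reported length is the longest such
## match, capped at min(4, deletion length - 1): a full-length match would
## make the locus a tandem repeat, which is classified separately.
microhomology_core <- function(deleted, upstream, downstream) {
  d <- nchar(deleted)
  cap <- min(4L, d - 1L, nchar(upstream), nchar(downstream))
  if (d < 3L || cap < 2L) {
    return(list(has_mh = FALSE, mh_length = 0L, side = NA_character_))
  }
  for (k in seq(cap, 2L)) {
    if (substr(deleted, 1L, k) == substr(downstream, 1L, k)) {
      return(list(has_mh = TRUE, mh_length = k, side = "downstream"))
    }
    up_n <- nchar(upstream)
    if (substr(deleted, d - k + 1L, d) == substr(upstream, up_n - k + 1L, up_n)) {
      return(list(has_mh = TRUE, mh_length = k, side = "upstream"))
    }
  }
  list(has_mh = FALSE, mh_length = 0L, side = NA_character_)
}

#' Detect breakpoint microhomology in deletions
#'
#' @param calls Data frame of deletion calls (`chrom`, `pos`, `ref`, `alt`;
#'   anchored VCF style, `nchar(ref) > nchar(alt)`). Non-deletions are an
#'   error.
#' @param reference Named character vector of chromosome sequences.
#' @param flank Flank length examined either side. Default 50.
#' @return `calls` with columns `has_mh` (logical), `mh_length` (0 if none)
#'   and `mh_side` appended.
#' @export
detect_microhomology <- function(calls, reference, flank = 50L) {
  n <- nrow(calls)
  has <- logical(n); len <- integer(n); side <- character(n)
  for (i in seq_len(n)) {
    if (variant_class(calls$ref[i], calls$alt[i]) != "deletion") {
      stop("microhomology is defined for deletions only", call. = FALSE)
    }
    seq <- reference[[calls$chrom[i]]]
    la <- nchar(calls$alt[i])
    del <- substr(calls$ref[i], la + 1L, nchar(calls$ref[i]))
    d0 <- calls$pos[i] + la  # first deleted base, 1-based
    up <- substr(seq, max(1L, d0 - flank), d0 - 1L)
    dn <- substr(seq, d0 + nchar(del), min(nchar(seq), d0 + nchar(del) + flank - 1L))
    mh <- microhomology_core(del, up, dn)
    has[i] <- mh$has_mh; len[i] <- mh$mh_length; side[i] <- mh$side
  }
  calls$has_mh <- has
  calls$mh_length <- len
  calls$mh_side <- side
  calls
}

#' Breakdown of single-nucleotide indels by mononucleotide-run length
#'
#' Tabulates retained single-nucleotide insertions and deletions by the length
#' of the reference mononucleotide run in which they occur: non-repeat
#' (run length 1), 2, 3, and 4-7 units. Runs longer than 7 units are assumed
#' excluded upstream; any remaining are dropped with a warning.
#'
#' @param calls Annotated calls (from [annotate_repeat()]) already filtered to
#'   retained indels; only single-nucleotide indels are tabulated.
#' @return Integer matrix, rows `non-repeat`, `2`, `3`, `4-7`; columns
#'   `deletion`, `insertion`.
#' @export
mononucleotide_indel_breakdown <- function(calls) {
  classes <- c("non-repeat", "2", "3", "4-7")
  out <- matrix(0L, nrow = 4L, ncol = 2L,
                dimnames = list(classes, c("deletion", "insertion")))
  if (nrow(calls) == 0L) return(out)
  mclass <- variant_class(calls$ref, calls$alt)
  single <- abs(nchar(calls$ref) - nchar(calls$alt)) == 1L & mclass != "SNV"
  calls <- calls[single, , drop = FALSE]
  mclass <- mclass[single]
  run <- ifelse(calls$unit_length == 1L, calls$unit_count, 1L)
  over <- run > 7L
  if (any(over)) {
    warning("dropping ", sum(over), " single-nt indel(s) in runs > 7 units")
    calls <- calls[!over, , drop = FALSE]
    mclass <- mclass[!over]
    run <- run[!over]
  }
  cls <- ifelse(run <= 1L, "non-repeat",
                ifelse(run == 2L, "2", ifelse(run == 3L, "3", "4-7")))
  for (i in seq_along(cls)) {
    out[cls[i], mclass[i]] <- out[cls[i], mclass[i]] + 1L
  }
  out
}
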