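## Effective whole-genome coverage (EWC) region: the autosomal positions where
## every sample has (i) high-mapping-quality depth within a band around its
## coverage peak and (ii) a sufficient fraction of high-MQ reads. The size of
## the intersected mask is the denominator of every mutation rate.

#' Parameters for EWC mask construction
#'
#' @param lower_frac Lower coverage bound as a fraction of the per-sample peak
#'   high-MQ depth. Default 0.5 (i.e. 50% of peak).
#' @param upper_frac Upper coverage bound as a fraction of peak. Default 3.0.
#' @param min_mq_ratio Minimum ratio of high-MQ depth to total depth at a
#'   position. Default 0.8.
#' @return An object of class `ewc_params`.
#' @export
ewc_params <- function(lower_frac = 0.5, upper_frac = 3.0, min_mq_ratio = 0.8) {
  if (!(lower_frac > 0 && lower_frac < upper_frac)) {
    stop("need 0 < lower_frac < upper_frac", call. = FALSE)
  }
  if (!(min_mq_ratio > 0 && min_mq_ratio <= 1)) {
    stop("need 0 < min_mq_ratio <= 1", call. = FALSE)
  }
  structure(list(lower_frac = lower_frac, upper_frac = upper_frac,
                 min_mq_ratio = min_mq_ratio),
            class = "ewc_params")
}

#' Modal depth of a coverage histogram
#'
#' The "peak coverage" of a sample is the mode of its high-MQ depth histogram
#' over depths >= 1 (uncovered positions carry no information about typical
#' coverage). Ties are broken toward the lower depth so the result is
#' deterministic.
#'
#' @param depth_histogram Named numeric vector of position counts, names being
#'   integer depths; or an unnamed vector where element `i` is the count of
#'   positions at depth `i - 1`.
#' @return Integer modal depth.
#' @export
peak_coverage <- function(depth_histogram) {
  if (length(depth_histogram) == 0L) stop("empty histogram", call. = FALSE)
  depths <- if (!is.null(names(depth_histogram))) {
    as.integer(names(depth_histogram))
  } else {
    seq_along(depth_histogram) - 1L
  }
  keep <- depths >= 1L & depth_histogram > 0
  if (!any(keep)) stop("no covered positions", call. = FALSE)
  depths <- depths[keep]
  counts <- depth_histogram[keep]
  o <- order(depths)
  depths <- depths[o]
  counts <- counts[o]
  depths[which.max(counts)]  # which.max takes the first = lowest depth on ties
}

## depth tracks: named list (per chromosome) of integer vectors, element i =
## depth at 1-based position i.
depth_histogram_from_track <- function(track) {
  v <- unlist(track, use.names = FALSE)
  tab <- table(v)
  counts <- as.numeric(tab)
  names(counts) <- names(tab)
  counts
}

new_ewc_mask <- function(intervals, samples = character()) {
  intervals <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
  rownames(intervals) <- NULL
  structure(list(intervals = intervals,
                 total_bp = sum(intervals$end - intervals$start),
                 samples = samples),
            class = "ewc_mask")
}

#' @export
print.ewc_mask <- function(x, ...) {
  cat(sprintf("EWC mask: %d interval(s) on %d chromosome(s), %s bp",
              nrow(x$intervals), length(unique(x$intervals$chrom)),
              format(x$total_bp, big.mark = ",")))
  if (length(x$samples)) cat(sprintf(" [%s]", paste(x$samples, collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Per-sample callable mask from depth tracks
#'
#' A position qualifies iff `lower_frac * peak <= hq <= upper_frac * peak` and
#' `hq / total >= min_mq_ratio`. The peak is computed from the pooled high-MQ
#' histogram across all chromosomes of this sample. Positions with total depth
#' zero are excluded before the ratio test. Qualifying positions are merged
#' into 0-based half-open intervals.
#'
#' @param hq_depth_track,total_depth_track Named lists of per-base integer
#'   depth vectors, one element per chromosome, identical names and lengths.
#' @param params An [ewc_params()] object.
#' @param sample Optional sample identifier recorded in the mask.
#' @return An `ewc_mask`.
#' @export
sample_mask <- function(hq_depth_track, total_depth_track,
                        params = ewc_params(), sample = NA_character_) {
  if (!identical(names(hq_depth_track), names(total_depth_track))) {
    stop("track chromosome names differ", call. = FALSE)
  }
  if (!identical(lengths(hq_depth_track), lengths(total_depth_track))) {
    stop("track lengths differ", call. = FALSE)
  }
  peak <- peak_coverage(depth_histogram_from_track(hq_depth_track))
  lo <- params$lower_frac * peak
  hi <- params$upper_frac * peak
  iv <- lapply(names(hq_depth_track), function(chrom) {
    hq <- hq_depth_track[[chrom]]
    tot <- total_depth_track[[chrom]]
    ok <- tot > 0 & hq >= lo & hq <= hi & hq / pmax(tot, 1L) >= params$min_mq_ratio
    r <- IRanges::reduce(IRanges::IRanges(which(ok), width = 1L))
    data.frame(chrom = rep(chrom, length(r)),
               start = IRanges::start(r) - 1L,   # to 0-based half-open
               end = IRanges::end(r))
  })
  m <- new_ewc_mask(do.call(rbind, iv), samples = stats::na.omit(sample))
  m$peak <- peak
  m
}

mask_to_irl <- function(mask, chroms) {
  out <- lapply(chroms, function(ch) {
    sub <- mask$intervals[mask$intervals$chrom == ch, , drop = FALSE]
    IRanges::IRanges(start = sub$start + 1L, end = sub$end)
  })
  names(out) <- chroms
  out
}

#' Intersect callable masks across samples
#'
#' The EWC region is the set of positions callable in every sample of the
#' study (all offspring and parents of both experiments).
#'
#' @param masks List of `ewc_mask` objects (length >= 1).
#' @return An `ewc_mask` whose intervals are the position-wise intersection.
#' @export
intersect_masks <- function(masks) {
  if (length(masks) == 0L) stop("need at least one mask", call. = FALSE)
  if (length(masks) == 1L) return(masks[[1L]])
  chroms <- sort(unique(unlist(lapply(masks, function(m) m$intervals$chrom))))
  iv <- lapply(chroms, function(ch) {
    irs <- lapply(masks, function(m) mask_to_irl(m, ch)[[1L]])
    r <- Reduce(IRanges::intersect, irs)
    data.frame(chrom = rep(ch, length(r)),
               start = IRanges::start(r) - 1L,
               end = IRanges::end(r))
  })
  samples <- unique(unlist(lapply(masks, function(m) m$samples)))
  new_ewc_mask(do.call(rbind, iv), samples = samples)
}

#' Mask construction for a whole cohort
#'
#' Convenience wrapper: per-sample masks from a cohort's depth tracks,
#' intersected across all samples.
#'
#' @param depth Named list: per sample, a list with elements `hq` and `total`
#'   (depth tracks as in [sample_mask()]).
#' @param params An [ewc_params()] object.
#' @return The intersected `ewc_mask`.
#' @export
cohort_mask <- function(depth, params = ewc_params()) {
  masks <- lapply(names(depth), function(s) {
    sample_mask(depth[[s]]$hq, depth[[s]]$total, params, sample = s)
  })
  intersect_masks(masks)
}

#' Test 1-based positions for mask membership
#'
#' @param mask An `ewc_mask`.
#' @param chrom,pos Vectors of chromosome names and 1-based positions.
#' @return Logical vector.
#' @export
in_mask <- function(mask, chrom, pos) {
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    sub <- mask$intervals[mask$intervals$chrom == ch, , drop = FALSE]
    sel <- chrom == ch
    if (nrow(sub) == 0L) { out[sel] <- FALSE; next }
    ir <- IRanges::IRanges(sub$start + 1L, sub$end)
    out[sel] <- IRanges::overlapsAny(IRanges::IRanges(pos[sel], width = 1L), ir)
  }
  out
}

#' Write / read an EWC mask as BED3
#'
#' @param mask An `ewc_mask`.
#' @param path Output BED path.
#' @return `write_mask_bed` returns `path` invisibly; `read_mask_bed` returns
#'   an `ewc_mask`.
#' @export
write_mask_bed <- function(mask, path) {
  gr <- GenomicRanges::GRanges(mask$intervals$chrom,
                               IRanges::IRanges(mask$intervals$start + 1L,
                                                mask$intervals$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_mask_bed
#' @export
read_mask_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  new_ewc_mask(data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                          start = GenomicRanges::start(gr) - 1L,
                          end = GenomicRanges::end(gr)))
}
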