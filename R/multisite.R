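## Multisite mutations: >= 2 alterations (SNVs/indels) within 100 bp on the
## same haplotype in one offspring, counted as a single mutational event.
## Their internal substitution spectrum is compared with the spontaneous SNV
## spectrum over seven collapsed categories with Bonferroni-corrected Fisher
## tests.

SPECTRUM_CATEGORIES <- c("C>A", "C>G", "C>T at CpG", "C>T at non-CpG",
                         "T>A", "T>C", "T>G")

## Haplotype compatibility of two calls: identical phase tags, or (when a tag
## is missing on either side) identical, determined parental origin.
hap_compatible <- function(tag1, tag2, origin1, origin2) {
  if (!is.na(tag1) && !is.na(tag2)) return(tag1 == tag2)
  !is.na(origin1) && !is.na(origin2) &&
    origin1 != "undetermined" && origin2 != "undetermined" &&
    origin1 == origin2
}

#' Cluster alterations into multisite mutations
#'
#' Single-linkage clustering within each (child, chromosome): two alterations
#' are linked iff their positions are at most `window` bp apart and they carry
#' compatible haplotype evidence (shared phase tag, or matching determined
#' parental origin when tags are absent). Clusters are the connected
#' components with at least two members; chains may span more than `window`
#' bp end to end because the rule is pairwise.
#'
#' @param dnms Data frame of accepted calls with columns `chrom`, `pos`,
#'   `child`, and optionally `haplotype_tag` and `parental_origin`.
#' @param window Maximum pairwise distance in bp. Default 100.
#' @return Data frame, one row per clustered alteration, with columns of
#'   `dnms` plus `cluster_id` (e.g. `"ms1"`), `cluster_size`, `span`.
#'   Unclustered alterations are absent. Zero-row input gives a zero-row
#'   result.
#' @export
cluster_multisite <- function(dnms, window = 100L) {
  empty <- cbind(dnms[0, , drop = FALSE],
                 data.frame(cluster_id = character(), cluster_size = integer(),
                            span = integer()))
  if (nrow(dnms) == 0L) return(empty)
  if (is.null(dnms$haplotype_tag)) dnms$haplotype_tag <- NA_character_
  if (is.null(dnms$parental_origin)) dnms$parental_origin <- NA_character_
  n <- nrow(dnms)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }
  key <- paste(dnms$child, dnms$chrom)
  o <- order(key, dnms$pos)
  for (a in seq_len(n - 1L)) {
    i <- o[a]
    for (b in seq((a + 1L), n)) {
      if (b > n) break
      j <- o[b]
      if (key[j] != key[i]) break
      if (dnms$pos[j] - dnms$pos[i] > window) break
      if (hap_compatible(dnms$haplotype_tag[i], dnms$haplotype_tag[j],
                         dnms$parental_origin[i], dnms$parental_origin[j])) {
        union_(i, j)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  sizes <- table(comp)
  keep <- comp %in% as.integer(names(sizes)[sizes >= 2L])
  if (!any(keep)) return(empty)
  out <- dnms[keep, , drop = FALSE]
  comp <- comp[keep]
  ids <- match(comp, unique(comp))
  out$cluster_id <- paste0("ms", ids)
  out$cluster_size <- as.integer(table(ids)[as.character(ids)])
  out$span <- stats::ave(out$pos, ids, FUN = function(p) diff(range(p)))
  out <- out[order(out$child, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a single-base substitution into the 7-category spectrum
#'
#' Substitutions are collapsed onto the pyrimidine strand (a G or A reference
#' is reverse-complemented together with its context), giving six base
#' changes, with C>T split by CpG context (is the base 3' of the pyrimidine C
#' a G?) for seven categories in total.
#'
#' @param ref,alt Single reference/alternate bases.
#' @param context Trinucleotide reference context centred on the substituted
#'   base.
#' @return One of `r paste(sprintf('"%s"', SPECTRUM_CATEGORIES), collapse = ", ")`.
#' @export
classify_substitution <- function(ref, alt, context) {
  if (nchar(ref) != 1L || nchar(alt) != 1L || ref == alt) {
    stop("not a single-base substitution", call. = FALSE)
  }
  if (nchar(context) != 3L || substr(context, 2L, 2L) != ref) {
    stop("context must be 3 nt with the substituted base in the middle",
         call. = FALSE)
  }
  if (ref %in% c("G", "A")) {
    ref <- revcomp(ref); alt <- revcomp(alt); context <- revcomp(context)
  }
  change <- paste0(ref, ">", alt)
  if (change == "C>T") {
    if (substr(context, 3L, 3L) == "G") "C>T at CpG" else "C>T at non-CpG"
  } else {
    change
  }
}

#' Tally substitutions into a spectrum table
#'
#' @param calls Data frame of SNV calls with `chrom`, `pos`, `ref`, `alt`.
#' @param reference Named character vector of chromosome sequences (source of
#'   trinucleotide context).
#' @return Named integer vector over the 7 spectrum categories.
#' @export
spectrum_table <- function(calls, reference) {
  counts <- stats::setNames(integer(length(SPECTRUM_CATEGORIES)),
                            SPECTRUM_CATEGORIES)
  for (i in seq_len(nrow(calls))) {
    seq <- reference[[calls$chrom[i]]]
    ctx <- substr(seq, calls$pos[i] - 1L, calls$pos[i] + 1L)
    cat_i <- classify_substitution(calls$ref[i], calls$alt[i], ctx)
    counts[cat_i] <- counts[cat_i] + 1L
  }
  counts
}

#' Compare two substitution spectra
#'
#' First a global Fisher exact test on the 2 x 7 contingency table asks
#' whether the two spectra differ at all; then each category is tested with a
#' two-tailed Fisher exact test on the 2 x 2 table (category vs rest, spectrum
#' a vs b), and the per-category P values are Bonferroni-corrected by the
#' number of categories (7).
#'
#' @param a,b Named count vectors over the 7 categories (as from
#'   [spectrum_table()]).
#' @return List with `global_p`, and a data frame `per_category` holding
#'   counts, odds ratios (conditional MLE), raw and corrected P values.
#' @export
compare_spectra <- function(a, b) {
  a <- a[SPECTRUM_CATEGORIES]; b <- b[SPECTRUM_CATEGORIES]
  if (any(is.na(a)) || any(is.na(b))) stop("spectra must cover all 7 categories", call. = FALSE)
  if (sum(a) == 0 || sum(b) == 0) stop("zero-total spectrum", call. = FALSE)
  tab <- rbind(a = a, b = b)
  global_p <- tryCatch(
    stats::fisher.test(tab, workspace = 2e7)$p.value,
    error = function(e) stats::fisher.test(tab, simulate.p.value = TRUE,
                                           B = 1e5)$p.value)
  per <- lapply(SPECTRUM_CATEGORIES, function(cat_i) {
    t2 <- matrix(c(a[cat_i], sum(a) - a[cat_i],
                   b[cat_i], sum(b) - b[cat_i]), nrow = 2L)
    ft <- stats::fisher.test(t2)
    data.frame(category = cat_i, count_a = unname(a[cat_i]),
               count_b = unname(b[cat_i]),
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               p_bonferroni = min(1, length(SPECTRUM_CATEGORIES) * ft$p.value))
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  list(global_p = global_p, per_category = per)
}

#' Flag known error-prone-polymerase dinucleotide signatures
#'
#' Tests whether a cluster contains an adjacent substituted dinucleotide
#' matching GC>AA or GA>TT on either strand (i.e. also GC>TT and TC>TA read
#' on the minus strand). These signatures are attributed to error-prone
#' translesion polymerases, not radiation.
#'
#' @param cluster Data frame of one cluster's members (`pos`, `ref`, `alt`);
#'   only single-base substitutions at adjacent positions are considered.
#' @return Named logical vector `c(gc_aa = , ga_tt = )`.
#' @export
flag_dinucleotide_signatures <- function(cluster) {
  flags <- c(gc_aa = FALSE, ga_tt = FALSE)
  snv <- cluster[nchar(cluster$ref) == 1L & nchar(cluster$alt) == 1L, , drop = FALSE]
  if (nrow(snv) < 2L) return(flags)
  snv <- snv[order(snv$pos), , drop = FALSE]
  for (i in seq_len(nrow(snv) - 1L)) {
    if (snv$pos[i + 1L] != snv$pos[i] + 1L) next
    din_ref <- paste0(snv$ref[i], snv$ref[i + 1L])
    din_alt <- paste0(snv$alt[i], snv$alt[i + 1L])
    for (variant in list(c(din_ref, din_alt),
                         c(revcomp(din_ref), revcomp(din_alt)))) {
      if (variant[1] == "GC" && variant[2] == "AA") flags["gc_aa"] <- TRUE
      if (variant[1] == "GA" && variant[2] == "TT") flags["ga_tt"] <- TRUE
    }
  }
  flags
}
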