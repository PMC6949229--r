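## Trio DNM filtering. A candidate de novo mutation is a variant with low
## variant allele frequency (VAF) in both parents, substantial VAF in the
## offspring, adequate depth in all three samples, and a position inside the
## callable (EWC) mask. Parental origin is assigned from phased
## strain-informative polymorphisms nearby.

#' Trio DNM filter thresholds
#'
#' @param max_parent_vaf Parental VAF must be strictly below this. Default 0.1.
#' @param min_child_vaf Offspring VAF must be at least this. Default 0.25.
#' @param min_parent_depth,min_child_depth Depth floors (high-quality reads).
#'   Default 10.
#' @return Object of class `filter_params`.
#' @export
filter_params <- function(max_parent_vaf = 0.1, min_child_vaf = 0.25,
                          min_parent_depth = 10L, min_child_depth = 10L) {
  if (!(max_parent_vaf >= 0 && max_parent_vaf < min_child_vaf &&
        min_child_vaf <= 1)) {
    stop("need 0 <= max_parent_vaf < min_child_vaf <= 1", call. = FALSE)
  }
  structure(list(max_parent_vaf = max_parent_vaf,
                 min_child_vaf = min_child_vaf,
                 min_parent_depth = as.integer(min_parent_depth),
                 min_child_depth = as.integer(min_child_depth)),
            class = "filter_params")
}

sample_vaf <- function(variants, sample) {
  dp <- variants[[paste0(sample, "_dp")]]
  ad <- variants[[paste0(sample, "_ad")]]
  if (is.null(dp) || is.null(ad)) {
    stop("missing depth columns for sample '", sample, "'", call. = FALSE)
  }
  ifelse(dp > 0, ad / dp, 0)
}

#' Call de novo mutation candidates for one offspring
#'
#' Applies, in order: parental VAF < `max_parent_vaf` in *both* parents,
#' offspring VAF >= `min_child_vaf`, depth floors in all three samples, and
#' membership in the EWC mask. VAFs are computed from the high-quality read
#' counts (`<sample>_ad` / `<sample>_dp` columns).
#'
#' @param variants Joint variant table: columns `chrom`, `pos`, `ref`, `alt`
#'   plus `<sample>_dp` / `<sample>_ad` pairs for every sample.
#' @param roles Named character vector with elements `father`, `mother`,
#'   `child` giving the sample names.
#' @param params [filter_params()].
#' @param mask An `ewc_mask`, or `NULL` to skip the region filter.
#' @param phase Optional phase table (`chrom`, `pos`, `child`, `tag`) used to
#'   attach read-backed haplotype tags to accepted calls.
#' @return Data frame of accepted calls with columns `chrom`, `pos`, `ref`,
#'   `alt`, `child`, `mclass`, `father_vaf`, `mother_vaf`, `child_vaf`,
#'   `child_dp`, `in_ewc`, `haplotype_tag`. Rejected variants (offspring
#'   carries the allele but a filter failed) are recorded with a reason in
#'   `attr(, "rejected")`.
#' @export
call_dnm_candidates <- function(variants, roles, params = filter_params(),
                                mask = NULL, phase = NULL) {
  for (r in c("father", "mother", "child")) {
    if (!r %in% names(roles)) stop("roles must name a '", r, "' sample", call. = FALSE)
  }
  fv <- sample_vaf(variants, roles[["father"]])
  mv <- sample_vaf(variants, roles[["mother"]])
  cv <- sample_vaf(variants, roles[["child"]])
  fd <- variants[[paste0(roles[["father"]], "_dp")]]
  md <- variants[[paste0(roles[["mother"]], "_dp")]]
  cd <- variants[[paste0(roles[["child"]], "_dp")]]
  in_ewc <- if (is.null(mask)) rep(TRUE, nrow(variants)) else {
    in_mask(mask, variants$chrom, variants$pos)
  }
  reason <- rep(NA_character_, nrow(variants))
  reason[!in_ewc] <- "outside-mask"
  reason[is.na(reason) & (fd < params$min_parent_depth |
                          md < params$min_parent_depth |
                          cd < params$min_child_depth)] <- "low-depth"
  reason[is.na(reason) & cv < params$min_child_vaf] <- "child-vaf"
  reason[is.na(reason) & (fv >= params$max_parent_vaf |
                          mv >= params$max_parent_vaf)] <- "parent-vaf"
  pass <- is.na(reason)
  ## only variants the offspring actually carries are candidates at all;
  ## allele-free rows are uninformative, not "rejected"
  carries <- variants[[paste0(roles[["child"]], "_ad")]] > 0
  out <- data.frame(chrom = variants$chrom, pos = variants$pos,
                    ref = variants$ref, alt = variants$alt,
                    child = roles[["child"]],
                    mclass = variant_class(variants$ref, variants$alt),
                    father_vaf = fv, mother_vaf = mv, child_vaf = cv,
                    child_dp = cd, in_ewc = in_ewc)
  accepted <- out[pass, , drop = FALSE]
  accepted$haplotype_tag <- rep(NA_character_, nrow(accepted))
  if (!is.null(phase) && nrow(accepted) > 0L) {
    idx <- match(paste(accepted$chrom, accepted$pos, roles[["child"]]),
                 paste(phase$chrom, phase$pos, phase$child))
    accepted$haplotype_tag <- phase$tag[idx]
  }
  rejected <- out[!pass & carries, , drop = FALSE]
  rejected$reason <- reason[!pass & carries]
  rownames(accepted) <- rownames(rejected) <- NULL
  attr(accepted, "rejected") <- rejected
  accepted
}

#' Assign parental origin from linked informative polymorphisms
#'
#' Informative sites are variants where one parent is homozygous for the
#' alternate allele and the other homozygous reference (strain differences
#' between the parental lines), judged from parental VAFs. A DNM is assigned
#' to a parent when it shares a read-backed haplotype tag with at least one
#' informative site within `max_distance` bp in the same offspring, the
#' offspring is heterozygous there, and all such linked sites agree on the
#' parent; disagreeing sites give `"undetermined"` with a conflict flag.
#'
#' @param dnms Accepted calls from [call_dnm_candidates()] (needs
#'   `haplotype_tag`).
#' @param variants The joint variant table.
#' @param roles Named vector with `father`, `mother` (and `child`, matching
#'   `dnms$child`) sample names.
#' @param phase Phase table (`chrom`, `pos`, `child`, `tag`).
#' @param max_distance Maximum distance to an informative site. Default 500.
#' @param hom_vaf,ref_vaf VAF thresholds calling a parent homozygous
#'   alternate (>=) or homozygous reference (<=). Defaults 0.9 and 0.1.
#' @return `dnms` with columns `parental_origin` (`"paternal"`, `"maternal"`,
#'   `"undetermined"`) and `origin_conflict` (logical) appended.
#' @export
assign_parental_origin <- function(dnms, variants, roles, phase,
                                   max_distance = 500L,
                                   hom_vaf = 0.9, ref_vaf = 0.1) {
  fv <- sample_vaf(variants, roles[["father"]])
  mv <- sample_vaf(variants, roles[["mother"]])
  pat_marker <- fv >= hom_vaf & mv <= ref_vaf   # alt allele is the father's
  mat_marker <- mv >= hom_vaf & fv <= ref_vaf
  info <- variants[pat_marker | mat_marker, c("chrom", "pos"), drop = FALSE]
  info$marker_parent <- ifelse(pat_marker[pat_marker | mat_marker],
                               "paternal", "maternal")
  origin <- rep("undetermined", nrow(dnms))
  conflict <- logical(nrow(dnms))
  for (i in seq_len(nrow(dnms))) {
    tag <- dnms$haplotype_tag[i]
    if (is.na(tag)) next
    near <- info[info$chrom == dnms$chrom[i] &
                 abs(info$pos - dnms$pos[i]) <= max_distance &
                 info$pos != dnms$pos[i], , drop = FALSE]
    if (nrow(near) == 0L) next
    ptag <- phase$tag[match(paste(near$chrom, near$pos, dnms$child[i]),
                            paste(phase$chrom, phase$pos, phase$child))]
    linked <- !is.na(ptag) & ptag == tag
    parents <- unique(near$marker_parent[linked])
    if (length(parents) == 1L) {
      origin[i] <- parents
    } else if (length(parents) > 1L) {
      conflict[i] <- TRUE
    }
  }
  dnms$parental_origin <- origin
  dnms$origin_conflict <- conflict
  dnms
}

#' Summarise mutation counts by group
#'
#' Multisite clusters are counted as single mutations separate from SNVs and
#' indels: clustered alterations leave the SNV/indel tallies and each cluster
#' contributes one multisite mutation. Indels flagged `excluded` (repeat
#' rule) are omitted entirely and reported in the `excluded` column.
#'
#' @param dnms Accepted calls; an optional logical column `excluded` marks
#'   repeat-excluded indels.
#' @param clusters Output of [cluster_multisite()] run on the retained calls.
#' @param groups Named character vector mapping child sample name to group
#'   label; `NULL` puts everyone in group `"all"`.
#' @return Data frame with columns `group`, `snv`, `indel`, `multisite`,
#'   `excluded`. Counts satisfy
#'   `snv + indel + sum(cluster sizes) + excluded == nrow(dnms)` per group.
#' @export
summarize_counts <- function(dnms, clusters, groups = NULL) {
  if (is.null(groups)) {
    groups <- stats::setNames(rep("all", length(unique(dnms$child))),
                              unique(dnms$child))
  }
  if (nrow(clusters) > 0L) {
    dup <- duplicated(paste(clusters$child, clusters$chrom, clusters$pos,
                            clusters$ref, clusters$alt))
    if (any(dup)) stop("alteration assigned to more than one cluster", call. = FALSE)
  }
  excl <- if (is.null(dnms$excluded)) rep(FALSE, nrow(dnms)) else dnms$excluded
  keyd <- paste(dnms$child, dnms$chrom, dnms$pos, dnms$ref, dnms$alt)
  keyc <- paste(clusters$child, clusters$chrom, clusters$pos, clusters$ref,
                clusters$alt)
  clustered <- keyd %in% keyc
  glab <- sort(unique(unname(groups)))
  if (length(glab) == 0L) {
    return(data.frame(group = character(), snv = integer(), indel = integer(),
                      multisite = integer(), excluded = integer()))
  }
  out <- lapply(glab, function(g) {
    kids <- names(groups)[groups == g]
    sel <- dnms$child %in% kids
    free <- sel & !clustered & !excl
    mcls <- variant_class(dnms$ref[free], dnms$alt[free])
    ncl <- if (nrow(clusters)) length(unique(clusters$cluster_id[clusters$child %in% kids])) else 0L
    data.frame(group = g,
               snv = sum(mcls == "SNV"),
               indel = sum(mcls != "SNV"),
               multisite = ncl,
               excluded = sum(sel & excl))
  })
  do.call(rbind, out)
}
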