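## End-to-end analysis of a trio cohort: EWC mask from depth tracks, DNM
## calling per offspring, indel repeat annotation and exclusion,
## microhomology scoring, multisite clustering, parental origin, group
## counts and rate estimates with before/after tests.

#' Run the full DNM analysis on a trio cohort
#'
#' @param cohort A `trio_cohort` (or a compatible list with `variants`,
#'   `depth`, `reference`, `phase`, `roles`, `groups` elements).
#' @param filter [filter_params()].
#' @param ewc [ewc_params()].
#' @param repeat_rules [repeat_exclusion_params()].
#' @param window Multisite clustering window in bp. Default 100.
#' @param max_phase_distance Phasing search distance in bp. Default 500.
#' @param test_reps Replicates for the before/after Poisson tests.
#' @param test_seed Seed for those tests.
#' @return List with elements `mask`, `calls` (annotated accepted calls),
#'   `clusters`, `counts` (per group: snv / indel / multisite / excluded),
#'   `rates` (per group and mutation type), `tests` (before-vs-after
#'   `poisson_test_result` per type).
#' @export
analyze_trio_cohort <- function(cohort,
                                filter = filter_params(),
                                ewc = ewc_params(),
                                repeat_rules = repeat_exclusion_params(),
                                window = 100L,
                                max_phase_distance = 500L,
                                test_reps = 1e5,
                                test_seed = 1L) {
  mask <- cohort_mask(cohort$depth, ewc)
  calls <- lapply(names(cohort$roles), function(child) {
    cc <- call_dnm_candidates(cohort$variants, cohort$roles[[child]], filter,
                              mask, phase = cohort$phase)
    assign_parental_origin(cc, cohort$variants, cohort$roles[[child]],
                           cohort$phase, max_distance = max_phase_distance)
  })
  calls <- do.call(rbind, calls)
  ## strain markers pass no trio filter (parents carry them), so accepted
  ## calls are DNM candidates only
  is_indel <- calls$mclass != "SNV"
  calls$excluded <- FALSE
  if (any(is_indel)) {
    ann <- annotate_repeat(calls[is_indel, , drop = FALSE], cohort$reference)
    calls$unit <- NA_character_; calls$unit_length <- NA_integer_
    calls$unit_count <- NA_integer_; calls$is_repeat_indel <- NA
    calls[is_indel, c("unit", "unit_length", "unit_count", "is_repeat_indel")] <-
      ann[, c("unit", "unit_length", "unit_count", "is_repeat_indel")]
    calls$excluded[is_indel] <- apply_repeat_exclusion(ann, repeat_rules)
    is_del <- is_indel & calls$mclass == "deletion"
    calls$has_mh <- NA; calls$mh_length <- NA_integer_
    if (any(is_del)) {
      mh <- detect_microhomology(calls[is_del, , drop = FALSE], cohort$reference)
      calls[is_del, c("has_mh", "mh_length")] <- mh[, c("has_mh", "mh_length")]
    }
  }
  retained <- calls[!calls$excluded, , drop = FALSE]
  clusters <- cluster_multisite(retained, window = window)
  counts <- summarize_counts(calls, clusters, groups = cohort$groups)

  G <- 2 * mask$total_bp
  n_off <- as.integer(table(cohort$groups)[counts$group])
  rates <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    do.call(rbind, lapply(c("snv", "indel", "multisite"), function(type) {
      r <- mutation_rate(counts[[type]][i], n_off[i], G)
      data.frame(group = counts$group[i], type = type, m = r$m,
                 mu = r$mu, ci_low = r$ci_low, ci_high = r$ci_high)
    }))
  }))

  tests <- NULL
  if (all(c("before", "after") %in% counts$group)) {
    b <- counts[counts$group == "before", ]
    a <- counts[counts$group == "after", ]
    tests <- lapply(stats::setNames(nm = c("snv", "indel", "multisite")),
                    function(type) {
      poisson_difference_test(b[[type]], a[[type]], reps = test_reps,
                              seed = test_seed)
    })
  }
  list(mask = mask, calls = calls, clusters = clusters, counts = counts,
       rates = rates, tests = tests)
}
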