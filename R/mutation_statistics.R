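## Rate estimators and tests: per-generation mutation rate with exact Poisson
## (Garwood) confidence intervals, linear parental-aging model and
## age-adjusted counts, two-tailed Monte-Carlo Poisson tests for before/after
## count differences, genome-wide extrapolation beyond the callable region,
## and a chi-square test of the regional distribution of mutations.

#' Per-generation mutation rate with exact Poisson CI
#'
#' The rate is `mu = m / (n * G)` where `m` is the mutation count, `n` the
#' number of offspring and `G` the analysed genome size in bp — twice the EWC
#' size, since each offspring contributes a diploid genome. The 95% CI is the
#' exact Poisson (Garwood) interval for the mean of `m`, rescaled by
#' `1 / (n * G)`; it is defined at `m = 0` (lower bound 0).
#'
#' @param m Mutation count (non-negative integer).
#' @param n Number of offspring.
#' @param G Analysed genome size in bp per offspring (diploid).
#' @param conf_level Confidence level. Default 0.95.
#' @return Object of class `rate_estimate`: list with `m`, `n`, `G`, `mu`,
#'   `ci_low`, `ci_high`, `conf_level`.
#' @export
mutation_rate <- function(m, n, G, conf_level = 0.95) {
  stopifnot_scalar_number(m, "m", min = 0)
  stopifnot_scalar_number(n, "n", min = 1)
  stopifnot_scalar_number(G, "G", min = .Machine$double.eps)
  ci <- stats::poisson.test(m, conf.level = conf_level)$conf.int / (n * G)
  structure(list(m = m, n = n, G = G, mu = m / (n * G),
                 ci_low = ci[1], ci_high = ci[2], conf_level = conf_level),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("mutation rate: %s per nt per generation (%d%% CI %s-%s; m=%d, n=%d)\n",
              signif(x$mu, 2), round(100 * x$conf_level),
              signif(x$ci_low, 2), signif(x$ci_high, 2), x$m, x$n))
  invisible(x)
}

#' Linear parental-aging model
#'
#' Weekly fractional increments of the total spontaneous de novo SNV count
#' per week of parental age beyond a reference age, attributed separately to
#' the father and the mother. The defaults (4.5%/week paternal, 2.3%/week
#' maternal, reference 8 weeks) are the phased-count estimates for laboratory
#' mice; the same fractions are conventionally reused for indels, whose
#' SNV-relative abundance is approximately age-invariant.
#'
#' @param r_paternal,r_maternal Fraction of the baseline count added per week
#'   of paternal / maternal age.
#' @param reference_age_weeks Age at which the baseline counts were observed.
#' @param delta_weeks_paternal,delta_weeks_maternal Age offsets (weeks beyond
#'   reference) of the comparison group.
#' @return Object of class `aging_model`.
#' @export
aging_model <- function(r_paternal = 0.045, r_maternal = 0.023,
                        reference_age_weeks = 8,
                        delta_weeks_paternal = 0, delta_weeks_maternal = 0) {
  if (r_paternal < 0 || r_maternal < 0) stop("aging rates must be >= 0", call. = FALSE)
  if (delta_weeks_paternal < 0 || delta_weeks_maternal < 0) {
    stop("delta weeks must be >= 0", call. = FALSE)
  }
  structure(list(r_paternal = r_paternal, r_maternal = r_maternal,
                 reference_age_weeks = reference_age_weeks,
                 delta_weeks_paternal = delta_weeks_paternal,
                 delta_weeks_maternal = delta_weeks_maternal),
            class = "aging_model")
}

#' Weekly aging rate from phased before/after counts
#'
#' For one parent, compares the number of mutations phased to that parent's
#' (unexposed) allele in offspring conceived at the reference age
#' (`count_before`) and `delta_weeks` later (`count_after`). The fractional
#' increase is scaled by the parent's share of the total baseline count so
#' the result is expressed per total de novo SNV count:
#' `r = (count_after / count_before - 1) * baseline_share / delta_weeks`.
#'
#' @param count_before,count_after Phased counts on this parent's allele.
#' @param delta_weeks Age difference in weeks (> 0).
#' @param baseline_share This parent's share of the total baseline count
#'   (default 0.5, the approximate phased paternal:maternal balance at the
#'   reference age).
#' @return Weekly fractional increase (scalar).
#' @export
aging_rate_from_phased_counts <- function(count_before, count_after,
                                          delta_weeks, baseline_share = 0.5) {
  if (delta_weeks <= 0) stop("delta_weeks must be > 0", call. = FALSE)
  if (count_before <= 0) {
    stop("zero baseline phased count: aging rate undefined", call. = FALSE)
  }
  (count_after / count_before - 1) * baseline_share / delta_weeks
}

#' Weekly aging rate from two rate estimates at different parental ages
#'
#' Cross-estimate from two studies (or cohorts) of the spontaneous SNV rate
#' at different mean parental ages at conception:
#' `r = (mu2 / mu1 - 1) / (age2 - age1)` per week.
#'
#' @param mu1,mu2 Rates at `age1` and `age2` (same units).
#' @param age1,age2 Parental ages at conception in weeks, `age2 > age1`.
#' @return Weekly fractional increase.
#' @export
aging_rate_from_two_studies <- function(mu1, mu2, age1, age2) {
  if (age2 <= age1) stop("age2 must exceed age1", call. = FALSE)
  if (mu1 <= 0) stop("mu1 must be > 0", call. = FALSE)
  (mu2 / mu1 - 1) / (age2 - age1)
}

## Expected number of age-added mutations given a baseline count and model.
aging_expected_addition <- function(baseline_before, model) {
  baseline_before * (model$r_paternal * model$delta_weeks_paternal +
                     model$r_maternal * model$delta_weeks_maternal)
}

#' Age-adjust an observed mutation count
#'
#' Subtracts the expected aging-related addition from the count observed
#' after exposure:
#' `adjusted = observed_after - baseline_before * (r_p * dw_p + r_m * dw_m)`.
#' The result is real-valued and may be negative (returned as-is with a
#' warning).
#'
#' @param observed_after Count observed in the post-exposure group.
#' @param baseline_before Count observed in the reference-age group.
#' @param model An [aging_model()] with the comparison's delta weeks set.
#' @return Adjusted count (numeric scalar).
#' @export
adjust_count_for_age <- function(observed_after, baseline_before, model) {
  adj <- observed_after - aging_expected_addition(baseline_before, model)
  if (adj < 0) warning("age-adjusted count is negative (", signif(adj, 3), ")")
  adj
}

#' Two-tailed Monte-Carlo Poisson test for a count difference
#'
#' Under the null that the before and after counts share a common mean, pairs
#' `(X, Y)` are drawn i.i.d. Poisson with mean `(m1 + m2) / 2` and the
#' two-tailed P value is the proportion of pairs at least as extreme as the
#' observation: `P(|X - Y| >= |m1 - m2|)`. With `aging_uncertainty`
#' supplied, the aging subtraction applied to `m2` is itself re-drawn each
#' replicate — the expected addition is Poisson-distributed and split between
#' parents binomially — so its sampling uncertainty propagates into the test.
#'
#' @param m1,m2 Observed counts (before, after). When aging uncertainty is
#'   used, `m2` is the *raw* post-exposure count.
#' @param reps Number of simulation replicates. Default 100000.
#' @param seed Optional integer seed; fixed seed gives an identical P value.
#' @param aging_uncertainty Optional list with `baseline` (the pre-exposure
#'   count the aging addition is proportional to) and `model` (an
#'   [aging_model()]).
#' @return Object of class `poisson_test_result`: `p`, `reps`, `seed`,
#'   `observed` counts, `aging_propagated`.
#' @export
poisson_difference_test <- function(m1, m2, reps = 1e5, seed = NULL,
                                    aging_uncertainty = NULL) {
  if (reps < 1e4) stop("reps must be >= 10000", call. = FALSE)
  p <- with_seed(seed, {
    if (is.null(aging_uncertainty)) {
      lam <- (m1 + m2) / 2
      x <- stats::rpois(reps, lam)
      y <- stats::rpois(reps, lam)
      mean(abs(x - y) >= abs(m1 - m2))
    } else {
      model <- aging_uncertainty$model
      mu_add <- aging_expected_addition(aging_uncertainty$baseline, model)
      m2_adj <- m2 - mu_add
      lam <- max((m1 + m2_adj) / 2, 0)
      ## the raw after-count includes the aging addition; the adjustment
      ## subtracts a noisy estimate of it, re-drawn each replicate (the
      ## paternal/maternal components are drawn separately, equivalent to a
      ## binomially split Poisson total)
      wp <- model$r_paternal * model$delta_weeks_paternal
      wm <- model$r_maternal * model$delta_weeks_maternal
      share_p <- if (wp + wm > 0) wp / (wp + wm) else 0.5
      x <- stats::rpois(reps, lam)
      y_raw <- stats::rpois(reps, lam + mu_add)
      a_star <- stats::rpois(reps, mu_add * share_p) +
        stats::rpois(reps, mu_add * (1 - share_p))
      y <- y_raw - a_star
      mean(abs(x - y) >= abs(m1 - m2_adj))
    }
  })
  structure(list(p = p, reps = reps, seed = seed, observed = c(m1 = m1, m2 = m2),
                 aging_propagated = !is.null(aging_uncertainty)),
            class = "poisson_test_result")
}

#' @export
print.poisson_test_result <- function(x, ...) {
  cat(sprintf("two-tailed Poisson simulation test: p = %s (m1=%s, m2=%s, %s reps%s)\n",
              signif(x$p, 2), x$observed["m1"], x$observed["m2"],
              format(x$reps, big.mark = ","),
              if (x$aging_propagated) ", aging uncertainty propagated" else ""))
  invisible(x)
}

#' Exact Skellam two-tail probability
#'
#' Closed form for the quantity the simulation test estimates: if `X` and `Y`
#' are i.i.d. Poisson with mean `(m1 + m2) / 2`, returns
#' `P(|X - Y| >= |m1 - m2|)`. Exposed as an analytic cross-check for
#' [poisson_difference_test()].
#'
#' @param m1,m2 Observed counts.
#' @return Exact two-tail probability.
#' @export
skellam_two_tail <- function(m1, m2) {
  lam <- (m1 + m2) / 2
  d <- abs(m1 - m2)
  if (d == 0) return(1)
  kmax <- stats::qpois(1 - 1e-15, lam) + d
  k <- 0:kmax
  pk <- stats::dpois(k, lam)
  diff_mat <- abs(outer(k, k, "-")) >= d
  sum(outer(pk, pk)[diff_mat])
}

#' Extrapolate counts to the whole autosomal genome per offspring
#'
#' Scales a count observed inside the callable (EWC) region to the whole
#' autosomal genome: `estimate = m / (n * ewc_fraction)`. By default the CI
#' is the exact Poisson interval on `m` rescaled identically; with
#' `method = "simulation"` it is taken from quantiles of `reps` Poisson
#' re-draws of `m` (used when aging uncertainty makes the exact interval
#' unavailable).
#'
#' @param m Count in the EWC region across `n` offspring.
#' @param n Number of offspring.
#' @param ewc_fraction Fraction of the autosomal genome covered by the EWC
#'   region. Default 0.539.
#' @param method `"exact"` (default) or `"simulation"`.
#' @param reps Simulation replicates. Default 1000.
#' @param seed Optional seed for the simulation method.
#' @param conf_level Confidence level. Default 0.95.
#' @return List with `estimate`, `ci_low`, `ci_high`, `method`.
#' @export
extrapolate_per_offspring <- function(m, n, ewc_fraction = 0.539,
                                      method = c("exact", "simulation"),
                                      reps = 1000, seed = NULL,
                                      conf_level = 0.95) {
  if (!(ewc_fraction > 0 && ewc_fraction <= 1)) {
    stop("ewc_fraction must be in (0, 1]", call. = FALSE)
  }
  method <- match.arg(method)
  scale <- 1 / (n * ewc_fraction)
  est <- m * scale
  if (method == "exact") {
    ci <- stats::poisson.test(m, conf.level = conf_level)$conf.int * scale
  } else {
    sims <- with_seed(seed, stats::rpois(reps, m)) * scale
    ci <- unname(stats::quantile(sims, c((1 - conf_level) / 2,
                                         1 - (1 - conf_level) / 2)))
  }
  list(estimate = est, ci_low = ci[1], ci_high = ci[2], method = method)
}

#' Chi-square test of mutation counts across genomic region classes
#'
#' Compares observed counts in region classes (e.g. exonic / intronic /
#' intergenic) against expectations proportional to each class's share of the
#' callable region.
#'
#' @param counts Observed counts per class (length >= 2).
#' @param fractions Region-class fractions of the EWC region; normalised to
#'   sum to 1 internally.
#' @return List with `p`, `statistic`, `df`, `expected`.
#' @export
region_distribution_test <- function(counts, fractions) {
  if (length(counts) < 2L) stop("need at least two region classes", call. = FALSE)
  if (length(counts) != length(fractions)) stop("length mismatch", call. = FALSE)
  pr <- fractions / sum(fractions)
  expected <- sum(counts) * pr
  if (any(expected == 0)) stop("expected count of zero in a class", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(counts, p = pr))
  list(p = ct$p.value, statistic = unname(ct$statistic),
       df = unname(ct$parameter), expected = expected)
}
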