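## Synthetic trio cohorts with known truth. The generator emulates the
## structure the downstream analysis assumes: two litters of offspring (one
## conceived with parents at a reference age, one later, after one parent's
## exposure), strain-informative polymorphisms between the parental lines,
## spontaneous DNMs scaled linearly with parental age, and radiation-induced
## signature mutations (non-repeat deletions with breakpoint microhomology,
## single-nucleotide deletions in mononucleotide runs, multisite clusters).
## Every planted DNM carries a truth record; seeds make output reproducible.

#' Configuration for the synthetic trio cohort generator
#'
#' Defaults encode the study conditions the package targets: six offspring
#' per group, spontaneous SNV rate 4.0e-9 and indel rate 3.9e-10 per nt per
#' generation over a diploid callable genome, linear parental-age scaling
#' (4.5%/week paternal, 2.3%/week maternal beyond 8 weeks), and a
#' post-exposure radiation signature in which 60% of induced non-repeat
#' deletions of >= 3 nt carry 2-4 nt breakpoint microhomology. Chromosome
#' length defaults to a desk-scale 1e5 bp; per-nt rates stay at their
#' biological values, so planted spontaneous counts are proportionally small
#' unless `genome_length` or the rates are raised.
#'
#' @param genome_length Bases per synthetic chromosome (>= 1e4).
#' @param n_chromosomes Number of chromosomes.
#' @param n_offspring_per_group Offspring per group (before / after).
#' @param snv_rate,indel_rate,multisite_rate Spontaneous per-nt
#'   per-generation rates (diploid genome). The multisite default derives
#'   from 2 clusters observed in 12 offspring over a diploid callable genome
#'   of 2 x 1.29e9 nt.
#' @param paternal_age_weeks,maternal_age_weeks Length-2 named vectors
#'   (`before`, `after`) of parental ages at conception.
#' @param exposed_parent `"father"`, `"mother"`, or `"none"`.
#' @param induced_deletion_count_mean,induced_multisite_count_mean Poisson
#'   means of induced events per post-exposure offspring.
#' @param microhomology_fraction Fraction of induced non-repeat deletions of
#'   >= 3 nt planted with 2-4 nt breakpoint microhomology.
#' @param mononucleotide_deletion_fraction Fraction of induced deletions that
#'   are single-nt deletions in mononucleotide runs.
#' @param strain_polymorphism_rate Per-nt density of informative parental
#'   marker sites.
#' @param mean_depth,depth_dispersion Negative-binomial per-base coverage
#'   model (mean and size).
#' @param vaf_concentration Concentration of the Beta distribution (centred
#'   at 0.5) from which heterozygous offspring VAFs are drawn.
#' @param parent_noise_vaf Per-read probability of a spurious alternate read
#'   in allele-free samples.
#' @param run_density Fraction of reference positions placed inside planted
#'   tandem runs (unit lengths 1-4, 2-10 copies).
#' @param phase_block_bp Size of read-backed phasing blocks; haplotype tags
#'   only link alterations within a block.
#' @param aging_r_paternal,aging_r_maternal,reference_age_weeks Linear aging
#'   model planted into the spontaneous counts.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(genome_length = 1e5,
                              n_chromosomes = 2L,
                              n_offspring_per_group = 6L,
                              snv_rate = 4.0e-9,
                              indel_rate = 3.9e-10,
                              multisite_rate = 2 / (12 * 2 * 1.29e9),
                              paternal_age_weeks = c(before = 8, after = 26),
                              maternal_age_weeks = c(before = 8, after = 17),
                              exposed_parent = c("father", "mother", "none"),
                              induced_deletion_count_mean = 5,
                              induced_multisite_count_mean = 1.7,
                              microhomology_fraction = 0.6,
                              mononucleotide_deletion_fraction = 0.45,
                              strain_polymorphism_rate = 1 / 200,
                              mean_depth = 40,
                              depth_dispersion = 8,
                              vaf_concentration = 40,
                              parent_noise_vaf = 0.002,
                              run_density = 0.015,
                              phase_block_bp = 500L,
                              aging_r_paternal = 0.045,
                              aging_r_maternal = 0.023,
                              reference_age_weeks = 8,
                              seed = 1L) {
  exposed_parent <- match.arg(exposed_parent)
  cfg <- list(genome_length = as.integer(genome_length),
              n_chromosomes = as.integer(n_chromosomes),
              n_offspring_per_group = as.integer(n_offspring_per_group),
              snv_rate = snv_rate, indel_rate = indel_rate,
              multisite_rate = multisite_rate,
              paternal_age_weeks = paternal_age_weeks,
              maternal_age_weeks = maternal_age_weeks,
              exposed_parent = exposed_parent,
              induced_deletion_count_mean = induced_deletion_count_mean,
              induced_multisite_count_mean = induced_multisite_count_mean,
              microhomology_fraction = microhomology_fraction,
              mononucleotide_deletion_fraction = mononucleotide_deletion_fraction,
              strain_polymorphism_rate = strain_polymorphism_rate,
              mean_depth = mean_depth, depth_dispersion = depth_dispersion,
              vaf_concentration = vaf_concentration,
              parent_noise_vaf = parent_noise_vaf,
              run_density = run_density,
              phase_block_bp = as.integer(phase_block_bp),
              aging_r_paternal = aging_r_paternal,
              aging_r_maternal = aging_r_maternal,
              reference_age_weeks = reference_age_weeks,
              seed = as.integer(seed))
  rates <- c(cfg$snv_rate, cfg$indel_rate, cfg$multisite_rate,
             cfg$strain_polymorphism_rate, cfg$induced_deletion_count_mean,
             cfg$induced_multisite_count_mean, cfg$aging_r_paternal,
             cfg$aging_r_maternal, cfg$run_density)
  if (any(rates < 0)) stop("rates must be >= 0", call. = FALSE)
  fracs <- c(cfg$microhomology_fraction, cfg$mononucleotide_deletion_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must be in [0, 1]", call. = FALSE)
  if (cfg$genome_length <= 0) stop("genome_length must be positive", call. = FALSE)
  for (v in c("paternal_age_weeks", "maternal_age_weeks")) {
    if (!all(c("before", "after") %in% names(cfg[[v]]))) {
      stop(v, " needs named elements 'before' and 'after'", call. = FALSE)
    }
  }
  structure(cfg, class = "simulation_config")
}

## ---- reference generation ------------------------------------------------

reference_impl <- function(config) {
  L <- config$genome_length
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  runs <- list()
  seqs <- lapply(chroms, function(ch) {
    s <- sample(DNA_BASES, L, replace = TRUE)
    planted <- 0L
    target <- ceiling(config$run_density * L)
    rr <- list()
    guard <- 0L
    while (planted < target && guard < 10 * L) {
      guard <- guard + 1L
      ul <- sample(1:4, 1L)
      uc <- sample(2:10, 1L)
      w <- ul * uc
      p <- sample.int(L - w - 2L, 1L) + 1L
      unit <- paste(sample(DNA_BASES, ul, replace = TRUE), collapse = "")
      s[p:(p + w - 1L)] <- strsplit(strrep(unit, uc), "")[[1L]]
      planted <- planted + w
      rr[[length(rr) + 1L]] <- data.frame(chrom = ch, start = p, unit = unit,
                                          count = uc)
    }
    if (target > 0L) {
      ## guarantee a mononucleotide run of exactly 8 units (flanked by
      ## non-matching bases) so the >7-unit exclusion is exercised
      p <- floor(L / 2)
      s[p:(p + 7L)] <- "A"
      s[p - 1L] <- "C"; s[p + 8L] <- "G"
      rr[[length(rr) + 1L]] <- data.frame(chrom = ch, start = p, unit = "A",
                                          count = 8L)
    }
    runs[[ch]] <<- if (length(rr)) do.call(rbind, rr) else NULL
    s
  })
  names(seqs) <- chroms
  attr(seqs, "runs") <- do.call(rbind, runs)
  seqs  # list of per-base character vectors; collapse with collapse_reference()
}

collapse_reference <- function(ref_chars) {
  out <- vapply(ref_chars, paste, character(1), collapse = "")
  attr(out, "runs") <- attr(ref_chars, "runs")
  out
}

#' Generate a synthetic reference genome
#'
#' Random i.i.d. bases with planted tandem runs (unit lengths 1-4, 2-10
#' copies, density `run_density`), including one mononucleotide run of
#' exactly 8 units per chromosome. The planted runs are recorded in
#' `attr(, "runs")`.
#'
#' @param config A [simulation_config()]. `genome_length` must be >= 1e4.
#' @return Named character vector of chromosome sequences.
#' @export
generate_reference <- function(config = simulation_config()) {
  if (config$genome_length < 1e4) {
    stop("genome_length must be >= 1e4", call. = FALSE)
  }
  with_seed(config$seed, collapse_reference(reference_impl(config)))
}

## ---- engineered signature loci -------------------------------------------

## Construct a deletion locus (up, deleted, down) whose classification under
## microhomology_core / annotate_repeat_one matches the request exactly:
## want_mh = TRUE plants a 2-4 nt junction homology; want_mh = FALSE
## rejection-samples until no homology is detected; both reject repeat-indel
## contexts. Returns NULL after `tries` failures.
engineer_deletion_locus <- function(d, want_mh, flank = 50L, tries = 200L) {
  for (t in seq_len(tries)) {
    up <- sample(DNA_BASES, flank, replace = TRUE)
    del <- sample(DNA_BASES, d, replace = TRUE)
    dn <- sample(DNA_BASES, flank, replace = TRUE)
    if (want_mh) {
      k <- sample(2:min(4L, d - 1L), 1L)
      if (stats::runif(1) < 0.5) {
        dn[seq_len(k)] <- del[seq_len(k)]
      } else {
        up[(flank - k + 1L):flank] <- del[(d - k + 1L):d]
      }
    }
    seq <- paste(c(up, del, dn), collapse = "")
    mh <- microhomology_core(paste(del, collapse = ""),
                             paste(up, collapse = ""),
                             paste(dn, collapse = ""))
    if (mh$has_mh != want_mh) next
    ref_allele <- paste(c(up[flank], del), collapse = "")
    ann <- annotate_repeat_one(seq, flank, ref_allele, up[flank])
    if (ann$is_repeat_indel) next
    return(list(up = up, del = del, down = dn, has_mh = mh$has_mh,
                mh_length = mh$mh_length))
  }
  NULL
}

## Mononucleotide-run deletion locus: a run of `run_len` copies of one base,
## flanked by non-matching bases; the deletion removes one unit.
engineer_mono_run_locus <- function(run_len, flank = 50L) {
  base <- sample(DNA_BASES, 1L)
  up <- sample(DNA_BASES, flank, replace = TRUE)
  dn <- sample(DNA_BASES, flank, replace = TRUE)
  up[flank] <- sample(setdiff(DNA_BASES, base), 1L)
  dn[1L] <- sample(setdiff(DNA_BASES, base), 1L)
  list(up = up, del = rep(base, run_len), down = dn, keep_units = run_len)
}

#' Simulate induced non-repeat deletions with the microhomology signature
#'
#' Stand-alone generator for the radiation deletion signature: `n` deletions
#' with lengths drawn from `lengths`, each planted with 2-4 nt breakpoint
#' microhomology with probability `microhomology_fraction` (and verified free
#' of it otherwise), in non-repeat context. Each deletion sits on its own
#' mini-chromosome so the set can be fed directly to
#' [detect_microhomology()].
#'
#' @param n Number of deletions.
#' @param lengths Candidate deletion lengths (>= 3 for the microhomology
#'   definition to apply); sampled with geometric-decay weights.
#' @param microhomology_fraction Planting probability.
#' @param flank Flank length either side. Default 60 (enough context for the
#'   repeat and microhomology annotators).
#' @param seed Optional seed.
#' @return List with `reference` (named character vector), `calls` (data
#'   frame `chrom`, `pos`, `ref`, `alt`) and `truth` (data frame with
#'   `planted_mh`, `planted_mh_length`, `del_length`).
#' @export
simulate_induced_deletions <- function(n = 200L, lengths = 3:35,
                                       microhomology_fraction = 0.6,
                                       flank = 60L, seed = NULL) {
  with_seed(seed, {
    w <- 0.8 ^ (lengths - min(lengths))
    refs <- character(n); calls <- vector("list", n); truth <- vector("list", n)
    for (i in seq_len(n)) {
      d <- sample(lengths, 1L, prob = w)
      want <- d >= 3L && stats::runif(1) < microhomology_fraction
      loc <- NULL
      while (is.null(loc)) loc <- engineer_deletion_locus(d, want, flank)
      chrom <- sprintf("del%04d", i)
      refs[i] <- paste(c(loc$up, loc$del, loc$down), collapse = "")
      calls[[i]] <- data.frame(chrom = chrom, pos = flank,
                               ref = paste(c(loc$up[flank], loc$del), collapse = ""),
                               alt = loc$up[flank])
      truth[[i]] <- data.frame(chrom = chrom, planted_mh = want,
                               planted_mh_length = loc$mh_length,
                               del_length = d)
      names(refs)[i] <- chrom
    }
    list(reference = refs, calls = do.call(rbind, calls),
         truth = do.call(rbind, truth))
  })
}

## ---- depth model ----------------------------------------------------------

running_mean <- function(x, w) {
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- w %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## Per-chromosome depth pair (total, hq) with planted artifact segments:
## low-coverage, high-coverage and low-mapping-quality stretches, smoothed
## over 100 bp windows for realistic callable-region boundaries.
simulate_depth_chrom <- function(L, mean_depth, dispersion) {
  raw <- stats::rnbinom(L, mu = mean_depth, size = dispersion)
  tot <- running_mean(raw, 100L)
  ## artifact segments total a few percent of the chromosome per sample, so
  ## the intersected mask across a whole cohort retains most of the genome
  seg <- function() {
    len <- max(50L, as.integer(L * stats::runif(1, 0.002, 0.008)))
    p <- sample.int(L - len, 1L)
    p:(p + len - 1L)
  }
  for (i in 1:2) {
    idx <- seg()
    tot[idx] <- tot[idx] * stats::runif(1, 0.05, 0.3)
  }
  idx <- seg()
  tot[idx] <- tot[idx] * stats::runif(1, 4, 6)
  tot <- as.integer(round(tot))
  q <- rep(0.97, L)
  for (i in 1:2) q[seg()] <- stats::runif(1, 0.3, 0.6)
  hq <- stats::rbinom(L, tot, q)
  list(total = tot, hq = hq)
}

## ---- cohort generation ----------------------------------------------------

new_locus_registry <- function(n_chrom, L) {
  reg <- new.env(parent = emptyenv())
  reg$occ <- lapply(seq_len(n_chrom), function(i) logical(L))
  reg
}

## Reserve [pos - pad, pos + span + pad]; returns FALSE if already taken.
reserve_locus <- function(reg, chrom_i, pos, span, pad = 60L, L) {
  lo <- max(1L, pos - pad)
  hi <- min(L, pos + span + pad)
  if (any(reg$occ[[chrom_i]][lo:hi])) return(FALSE)
  reg$occ[[chrom_i]][lo:hi] <- TRUE
  TRUE
}

#' Generate a synthetic trio cohort with truth labels
#'
#' Builds a reference genome, per-sample depth tracks, a joint variant table
#' (strain markers plus planted DNMs with realistic allele depths), a phase
#' table of read-backed haplotype tags, and a truth record per planted DNM.
#' Spontaneous DNM counts per offspring are Poisson with mean
#' `rate * 2 * genome size`, scaled by the linear aging model for the
#' post-exposure group; post-exposure offspring additionally carry induced
#' deletions and multisite clusters with the configured signature mix.
#'
#' @param config A [simulation_config()].
#' @return Object of class `trio_cohort`: list with elements `config`,
#'   `reference`, `variants`, `depth`, `truth`, `phase`, `samples`, `groups`,
#'   `roles` (per-child named role vectors).
#' @export
generate_trio_cohort <- function(config = simulation_config()) {
  with_seed(config$seed, generate_trio_cohort_impl(config))
}

generate_trio_cohort_impl <- function(config) {
  L <- config$genome_length
  nchrom <- config$n_chromosomes
  chroms <- paste0("chr", seq_len(nchrom))
  ref <- reference_impl(config)

  n_off <- config$n_offspring_per_group
  kids_before <- sprintf("F1_B%d", seq_len(n_off))
  kids_after <- sprintf("F1_A%d", seq_len(n_off))
  samples <- c("father", "mother", kids_before, kids_after)
  groups <- stats::setNames(rep(c("before", "after"), each = n_off),
                            c(kids_before, kids_after))

  depth <- lapply(samples, function(s) {
    per <- lapply(chroms, function(ch) {
      simulate_depth_chrom(L, config$mean_depth, config$depth_dispersion)
    })
    list(hq = stats::setNames(lapply(per, `[[`, "hq"), chroms),
         total = stats::setNames(lapply(per, `[[`, "total"), chroms))
  })
  names(depth) <- samples

  registry <- new_locus_registry(nchrom, L)
  ## phasing-block label permutation, memoised per (child, chrom, block)
  flips <- new.env(parent = emptyenv())
  tag_of <- function(child, chrom, pos, parent) {
    block <- pos %/% config$phase_block_bp
    key <- paste(child, chrom, block, sep = "|")
    if (is.null(flips[[key]])) flips[[key]] <- stats::runif(1) < 0.5
    hap <- if (parent == "paternal") 1L else 2L
    if (flips[[key]]) hap <- 3L - hap
    sprintf("%s:%s:b%d:h%d", child, chrom, block, hap)
  }

  age_factor <- function(group) {
    dp <- config$paternal_age_weeks[[group]] - config$reference_age_weeks
    dm <- config$maternal_age_weeks[[group]] - config$reference_age_weeks
    1 + config$aging_r_paternal * dp + config$aging_r_maternal * dm
  }
  p_paternal <- function(group) {
    dp <- config$paternal_age_weeks[[group]] - config$reference_age_weeks
    dm <- config$maternal_age_weeks[[group]] - config$reference_age_weeks
    (0.5 + config$aging_r_paternal * dp) / age_factor(group)
  }

  variants <- list()   # rows: chrom, pos, ref, alt, carrier, origin
  truth <- list()
  phase <- list()
  min_flank <- 55L

  free_position <- function(span, pad = 60L) {
    for (t in 1:500) {
      ci <- sample.int(nchrom, 1L)
      p <- sample((min_flank + 1L):(L - span - min_flank), 1L)
      if (reserve_locus(registry, ci, p, span, pad, L)) {
        return(list(chrom_i = ci, pos = p))
      }
    }
    stop("could not place locus: genome too crowded", call. = FALSE)
  }

  add_dnm <- function(chrom_i, pos, ref_allele, alt_allele, child, origin,
                      class, signature, tag = NA_character_) {
    chrom <- chroms[chrom_i]
    variants[[length(variants) + 1L]] <<- data.frame(
      chrom = chrom, pos = pos, ref = ref_allele, alt = alt_allele,
      carrier = child, stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <<- data.frame(
      chrom = chrom, pos = pos, ref = ref_allele, alt = alt_allele,
      child = child, planted_class = class, planted_signature = signature,
      parental_origin = origin, stringsAsFactors = FALSE)
    if (is.na(tag)) tag <- tag_of(child, chrom, pos, origin)
    phase[[length(phase) + 1L]] <<- data.frame(
      chrom = chrom, pos = pos, child = child, tag = tag,
      stringsAsFactors = FALSE)
    invisible(tag)
  }

  paste_locus <- function(chrom_i, pos, up, mid, down) {
    ## overwrite reference around the anchor: up ends at `pos`
    flank <- length(up)
    lo <- pos - flank + 1L
    hi <- pos + length(mid) + length(down)
    ref[[chrom_i]][lo:hi] <<- c(up, mid, down)
  }

  plant_snv <- function(child, origin, class, signature = "none",
                        at = NULL, tag = NA_character_) {
    loc <- if (is.null(at)) free_position(1L) else at
    rb <- ref[[loc$chrom_i]][loc$pos]
    ab <- sample(setdiff(DNA_BASES, rb), 1L)
    add_dnm(loc$chrom_i, loc$pos, rb, ab, child, origin, class, signature, tag)
    loc
  }

  plant_spontaneous_indel <- function(child, origin, class) {
    del <- stats::runif(1) < 0.5
    len <- min(1L + stats::rgeom(1L, 0.5), 10L)
    loc <- free_position(len + 1L)
    anchor <- ref[[loc$chrom_i]][loc$pos]
    if (del) {
      ref_allele <- paste(ref[[loc$chrom_i]][loc$pos:(loc$pos + len)], collapse = "")
      add_dnm(loc$chrom_i, loc$pos, ref_allele, anchor, child, origin, class, "none")
    } else {
      ins <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
      add_dnm(loc$chrom_i, loc$pos, anchor, paste0(anchor, ins),
              child, origin, class, "none")
    }
  }

  plant_induced_deletion <- function(child, origin) {
    if (stats::runif(1) < config$mononucleotide_deletion_fraction) {
      run_len <- sample(2:7, 1L, prob = c(0.55, 0.2, 0.1, 0.08, 0.04, 0.03))
      loc <- free_position(run_len + 1L, pad = 80L)
      eng <- engineer_mono_run_locus(run_len)
      paste_locus(loc$chrom_i, loc$pos, eng$up, eng$del, eng$down)
      ref_allele <- paste(c(eng$up[length(eng$up)], eng$del[1L]), collapse = "")
      add_dnm(loc$chrom_i, loc$pos, ref_allele, eng$up[length(eng$up)],
              child, origin, "induced", "mono_run_deletion")
    } else {
      d <- min(1L + stats::rgeom(1L, 0.25), 35L)
      want <- d >= 3L && stats::runif(1) < config$microhomology_fraction
      eng <- NULL
      while (is.null(eng)) eng <- engineer_deletion_locus(d, want)
      loc <- free_position(d + 1L, pad = 80L)
      paste_locus(loc$chrom_i, loc$pos, eng$up, eng$del, eng$down)
      ref_allele <- paste(c(eng$up[length(eng$up)], eng$del), collapse = "")
      add_dnm(loc$chrom_i, loc$pos, ref_allele, eng$up[length(eng$up)],
              child, origin, "induced",
              if (want) "microhomology_deletion" else "none")
    }
  }

  ms_blocks <- new.env(parent = emptyenv())
  plant_multisite <- function(child, origin, class) {
    k <- sample(2:3, 1L, prob = c(0.8, 0.2))
    gaps <- sample(1:15, k - 1L, replace = TRUE)
    span <- sum(gaps) + 1L
    ## one planted cluster per (child, chrom, phasing block), so each cluster
    ## has an unambiguous haplotype tag
    for (try in 1:50) {
      loc <- free_position(span, pad = 120L)
      bkey <- paste(child, loc$chrom_i, loc$pos %/% config$phase_block_bp)
      if (is.null(ms_blocks[[bkey]])) break
    }
    ms_blocks[[bkey]] <- TRUE
    tag <- tag_of(child, chroms[loc$chrom_i], loc$pos, origin)
    p <- loc$pos
    for (i in seq_len(k)) {
      plant_snv(child, origin, class, "multisite",
                at = list(chrom_i = loc$chrom_i, pos = p), tag = tag)
      if (i < k) p <- p + gaps[i]
    }
  }

  ## ---- induced signature loci first (they rewrite reference segments) ----
  exposed_origin <- switch(config$exposed_parent,
                           father = "paternal", mother = "maternal", NA)
  if (!is.na(exposed_origin)) {
    for (child in kids_after) {
      for (i in seq_len(stats::rpois(1L, config$induced_deletion_count_mean))) {
        plant_induced_deletion(child, exposed_origin)
      }
      for (i in seq_len(stats::rpois(1L, config$induced_multisite_count_mean))) {
        plant_multisite(child, exposed_origin, "induced")
      }
    }
  }

  ## ---- spontaneous / aging DNMs -----------------------------------------
  Gdip <- 2 * nchrom * L
  for (child in c(kids_before, kids_after)) {
    g <- groups[[child]]
    af <- age_factor(g)
    pp <- p_paternal(g)
    draw_origin <- function() if (stats::runif(1) < pp) "paternal" else "maternal"
    draw_class <- function() {
      if (af > 1 && stats::runif(1) < (af - 1) / af) "aging" else "spontaneous"
    }
    for (i in seq_len(stats::rpois(1L, config$snv_rate * Gdip * af))) {
      plant_snv(child, draw_origin(), draw_class())
    }
    for (i in seq_len(stats::rpois(1L, config$indel_rate * Gdip * af))) {
      plant_spontaneous_indel(child, draw_origin(), draw_class())
    }
    for (i in seq_len(stats::rpois(1L, config$multisite_rate * Gdip))) {
      plant_multisite(child, draw_origin(), "spontaneous")
    }
  }

  ## ---- strain markers (after all reference rewriting) --------------------
  for (ci in seq_len(nchrom)) {
    hits <- which(stats::runif(L) < config$strain_polymorphism_rate)
    hits <- hits[hits > min_flank & hits < L - min_flank]
    hits <- hits[!registry$occ[[ci]][hits]]
    for (p in hits) {
      rb <- ref[[ci]][p]
      ab <- sample(setdiff(DNA_BASES, rb), 1L)
      alt_parent <- sample(c("father", "mother"), 1L)
      origin <- if (alt_parent == "father") "paternal" else "maternal"
      variants[[length(variants) + 1L]] <- data.frame(
        chrom = chroms[ci], pos = p, ref = rb, alt = ab,
        carrier = paste0("marker:", alt_parent), stringsAsFactors = FALSE)
      for (child in c(kids_before, kids_after)) {
        phase[[length(phase) + 1L]] <- data.frame(
          chrom = chroms[ci], pos = p, child = child,
          tag = tag_of(child, chroms[ci], p, origin), stringsAsFactors = FALSE)
      }
    }
  }

  variants <- if (length(variants)) do.call(rbind, variants) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), carrier = character())
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), child = character(),
               planted_class = character(), planted_signature = character(),
               parental_origin = character())
  phase <- if (length(phase)) do.call(rbind, phase) else
    data.frame(chrom = character(), pos = integer(), child = character(),
               tag = character())

  ## ---- allele depths ------------------------------------------------------
  if (nrow(variants) == 0L) variants$carrier <- NULL
  if (nrow(variants) > 0L) {
    chrom_i <- match(variants$chrom, chroms)
    for (s in samples) {
      dp <- vapply(seq_len(nrow(variants)), function(i) {
        depth[[s]]$hq[[chrom_i[i]]][variants$pos[i]]
      }, numeric(1))
      dp <- as.integer(dp)
      vaf <- numeric(nrow(variants))
      is_marker <- startsWith(variants$carrier, "marker:")
      alt_parent <- sub("marker:", "", variants$carrier)
      half <- 0.5 * config$vaf_concentration
      het_vaf <- function(n) stats::rbeta(n, half, half)
      if (s %in% c("father", "mother")) {
        vaf[is_marker & alt_parent == s] <- 0.995
        vaf[is_marker & alt_parent != s] <- config$parent_noise_vaf
        vaf[!is_marker] <- config$parent_noise_vaf
      } else {
        vaf[is_marker] <- het_vaf(sum(is_marker))
        own <- !is_marker & variants$carrier == s
        vaf[own] <- het_vaf(sum(own))
        vaf[!is_marker & variants$carrier != s] <- config$parent_noise_vaf
      }
      variants[[paste0(s, "_dp")]] <- dp
      variants[[paste0(s, "_ad")]] <- stats::rbinom(nrow(variants), dp, vaf)
    }
    variants$carrier <- NULL
    o <- order(variants$chrom, variants$pos)
    variants <- variants[o, , drop = FALSE]
    rownames(variants) <- NULL
  }
  o <- order(truth$chrom, truth$pos); truth <- truth[o, , drop = FALSE]
  rownames(truth) <- NULL

  roles <- lapply(c(kids_before, kids_after), function(k) {
    c(father = "father", mother = "mother", child = k)
  })
  names(roles) <- c(kids_before, kids_after)

  structure(list(config = config,
                 reference = collapse_reference(ref),
                 variants = variants, depth = depth, truth = truth,
                 phase = phase, samples = samples, groups = groups,
                 roles = roles),
            class = "trio_cohort")
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic trio cohort: %d chromosome(s) x %s bp, ",
                     "%d offspring per group\n  %d variant rows, %d planted DNMs\n"),
              x$config$n_chromosomes,
              format(x$config$genome_length, big.mark = ","),
              x$config$n_offspring_per_group,
              if (is.null(x$variants)) 0L else nrow(x$variants), nrow(x$truth)))
  invisible(x)
}
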