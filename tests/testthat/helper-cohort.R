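## Shared fixtures. Rates are inflated relative to the biological defaults so
## that desk-scale genomes carry enough planted events to test against; the
## cohort is generated once and reused.

fixture_config <- function(seed = 7, ...) {
  simulation_config(genome_length = 2e4, n_chromosomes = 2L,
                    snv_rate = 5e-6, indel_rate = 1e-6, multisite_rate = 2e-7,
                    induced_deletion_count_mean = 8,
                    induced_multisite_count_mean = 2,
                    seed = seed, ...)
}

.fixture_env <- new.env()

fixture_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_trio_cohort(fixture_config())
  }
  .fixture_env$cohort
}

fixture_analysis <- function() {
  if (is.null(.fixture_env$analysis)) {
    .fixture_env$analysis <- analyze_trio_cohort(fixture_cohort(),
                                                 test_reps = 1e4,
                                                 test_seed = 11)
  }
  .fixture_env$analysis
}

## Key identifying one alteration in one offspring.
call_key <- function(df) paste(df$chrom, df$pos, df$child)

## Build a minimal one-variant trio table for filter tests.
trio_variant_row <- function(father_vaf, mother_vaf, child_vaf, dp = 40L,
                             pos = 500L, ref = "A", alt = "T") {
  data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
             dad_dp = dp, dad_ad = as.integer(round(dp * father_vaf)),
             mum_dp = dp, mum_ad = as.integer(round(dp * mother_vaf)),
             kid_dp = dp, kid_ad = as.integer(round(dp * child_vaf)))
}

trio_roles <- c(father = "dad", mother = "mum", child = "kid")

## Uniform-depth tracks for handcrafted mask scenarios.
flat_track <- function(depth, L = 100L, chrom = "chr1") {
  stats::setNames(list(rep(as.integer(depth), L)), chrom)
}
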