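## A locus string with the indel at a known anchor; reference is a one-entry
## named vector so the annotators can be driven directly.
locus_ref <- function(up, mid, down, chrom = "c") {
  stats::setNames(paste0(up, mid, down), chrom)
}
del_call <- function(up, deleted, down) {
  ref <- locus_ref(up, deleted, down)
  anchor <- substr(up, nchar(up), nchar(up))
  list(reference = ref,
       calls = data.frame(chrom = "c", pos = nchar(up),
                          ref = paste0(anchor, deleted), alt = anchor))
}

test_that("repeat annotation finds the smallest changed tandem unit", {
  pad <- strrep("CTGACTTG", 13)  # repeat-free 104 nt padding

  # deletion of one A in ...C AA G...: unit A, 2 copies, repeat indel
  x <- del_call(paste0(pad, "C"), "A", paste0("AG", pad))
  ann <- annotate_repeat(x$calls, x$reference)
  expect_equal(ann$unit, "A")
  expect_equal(ann$unit_count, 2L)
  expect_true(ann$is_repeat_indel)

  # deletion of ACG in non-repetitive context: not a repeat indel
  y <- del_call(paste0(pad, "T"), "ACG", paste0("TT", pad))
  anny <- annotate_repeat(y$calls, y$reference)
  expect_false(anny$is_repeat_indel)
  expect_equal(anny$unit_count, 1L)

  # deletion of AC from (AC)5: unit AC, 5 copies
  z <- del_call(paste0(pad, "T"), "AC", paste0(strrep("AC", 4), "TT", pad))
  annz <- annotate_repeat(z$calls, z$reference)
  expect_equal(annz$unit, "AC")
  expect_equal(annz$unit_count, 5L)
  expect_true(annz$is_repeat_indel)

  # insertion of one A next to AAA: unit A, reference has 3 copies
  ins <- data.frame(chrom = "c", pos = nchar(pad) + 1L, ref = "G", alt = "GA")
  refseq <- locus_ref(paste0(pad, "G"), "AAA", paste0("C", pad))
  anni <- annotate_repeat(ins, refseq)
  expect_equal(anni$unit, "A")
  expect_equal(anni$unit_count, 3L)
  expect_true(anni$is_repeat_indel)

  expect_error(annotate_repeat(data.frame(chrom = "c", pos = 3L,
                                          ref = "AT", alt = "A"),
                               stats::setNames("ATATATAT", "c")),
               "flank too short")
})

test_that("repeat annotation agrees with a brute-force tandem scan on random loci", {
  ## independent oracle: for each candidate unit length, count copies by
  ## vectorised substring comparison over the whole locus
  brute_count <- function(seq, unit, at) {
    l <- nchar(unit)
    n <- nchar(seq)
    starts_right <- seq(at, n - l + 1L, by = l)
    hits_r <- cumprod(substring(seq, starts_right, starts_right + l - 1L) == unit)
    starts_left <- rev(seq(at - l, 1L, by = -l))
    hits_l <- if (length(starts_left)) {
      rev(cumprod(rev(substring(seq, starts_left, starts_left + l - 1L) == unit)))
    } else numeric(0)
    sum(hits_r) + sum(hits_l)
  }
  set.seed(99)
  cfg <- simulation_config(genome_length = 1e4, n_chromosomes = 1L, seed = 5)
  ref <- generate_reference(cfg)
  seq <- ref[["chr1"]]
  n_checked <- 0L
  while (n_checked < 400L) {
    pos <- sample(60:(nchar(seq) - 120), 1L)
    d <- sample(1:6, 1L)
    anchor <- substr(seq, pos, pos)
    deleted <- substr(seq, pos + 1L, pos + d)
    calls <- data.frame(chrom = "chr1", pos = pos,
                        ref = paste0(anchor, deleted), alt = anchor)
    ann <- annotate_repeat(calls, ref)
    # oracle: smallest tiling unit with >= 2 reference copies wins
    units <- Filter(function(l) d %% l == 0L &&
                      strrep(substr(deleted, 1, l), d %/% l) == deleted, 1:d)
    if (length(units) == 0L) units <- d
    counts <- vapply(units, function(l) {
      brute_count(seq, substr(deleted, 1, l), pos + 1L)
    }, numeric(1))
    hit <- which(counts >= 2L)
    expected_count <- if (length(hit)) counts[hit[1L]] else max(1L, counts[1L])
    expected_rep <- length(hit) > 0L
    expect_equal(ann$unit_count, as.integer(expected_count))
    expect_equal(ann$is_repeat_indel, expected_rep)
    n_checked <- n_checked + 1L
  }
})

test_that("repeat exclusion matches the three-clause rule over an exhaustive grid", {
  grid <- expand.grid(unit_length = 1:4, unit_count = 1:10)
  got <- apply_repeat_exclusion(grid)
  oracle <- with(grid, (unit_length == 1 & unit_count > 7) |
                       (unit_length == 2 & unit_count > 4) |
                       (unit_length >= 3 & unit_count > 2))
  expect_identical(got, oracle)
  # the boundary cases called out by the rule
  expect_true(apply_repeat_exclusion(data.frame(unit_length = 1, unit_count = 8)))
  expect_false(apply_repeat_exclusion(data.frame(unit_length = 2, unit_count = 4)))
  expect_true(apply_repeat_exclusion(data.frame(unit_length = 2, unit_count = 5)))
  expect_false(apply_repeat_exclusion(data.frame(unit_length = 3, unit_count = 1)))
})

test_that("microhomology requires length >= 3 and a >= 2 nt junction match", {
  pad <- strrep("GACTGTTC", 13)

  # deleted TACG with downstream flank starting TA...
  x <- del_call(paste0(pad, "C"), "TACG", paste0("TAGG", pad))
  mh <- detect_microhomology(x$calls, x$reference)
  expect_true(mh$has_mh)
  expect_gte(mh$mh_length, 2L)
  expect_equal(mh$mh_side, "downstream")

  # upstream-side match: deleted ends CT, upstream flank ends CT
  y <- del_call(paste0(pad, "GCT"), "AGCT", paste0("GGAA", pad))
  mhy <- detect_microhomology(y$calls, y$reference)
  expect_true(mhy$has_mh)

  # deletions shorter than 3 nt never qualify
  z <- del_call(paste0(pad, "C"), "TA", paste0("TAGG", pad))
  expect_false(detect_microhomology(z$calls, z$reference)$has_mh)

  # no junction identity at all
  w <- del_call(paste0(pad, "AACC"), "GGGG", paste0("CATT", pad))
  mw <- detect_microhomology(w$calls, w$reference)
  expect_false(mw$has_mh)
  expect_equal(mw$mh_length, 0L)

  expect_error(detect_microhomology(data.frame(chrom = "c", pos = 10L,
                                               ref = "A", alt = "T"),
                                    stats::setNames(strrep("A", 100), "c")),
               "deletions only")
})

test_that("microhomology detection matches a direct substring oracle on random loci", {
  set.seed(123)
  for (i in 1:300) {
    d <- sample(3:20, 1L)
    up <- random_str <- function(n) paste(sample(c("A","C","G","T"), n, TRUE),
                                          collapse = "")
    up <- random_str(60); deleted <- random_str(d); down <- random_str(60)
    x <- del_call(up, deleted, down)
    got <- detect_microhomology(x$calls, x$reference)
    cap <- min(4L, d - 1L)
    oracle_len <- 0L
    for (k in cap:2) {
      if (substr(deleted, 1, k) == substr(down, 1, k) ||
          substr(deleted, d - k + 1L, d) == substr(up, 60 - k + 1L, 60)) {
        oracle_len <- k
        break
      }
    }
    expect_equal(got$has_mh, oracle_len >= 2L)
    expect_equal(got$mh_length, oracle_len)
  }
})

test_that("single-nt indel breakdown places planted deletions in their run class", {
  res <- fixture_analysis()
  co <- fixture_cohort()
  bd <- mononucleotide_indel_breakdown(res$calls[!res$calls$excluded, ])
  expect_equal(dim(bd), c(4L, 2L))
  # every retained single-nt indel appears in exactly one cell
  retained <- res$calls[!res$calls$excluded, ]
  n_single <- sum(abs(nchar(retained$ref) - nchar(retained$alt)) == 1L &
                  retained$mclass != "SNV")
  expect_equal(sum(bd), n_single)
  # planted mono-run deletions recovered in the run-length cells (class >= 2)
  truth_mono <- co$truth[co$truth$planted_signature == "mono_run_deletion", ]
  tin <- in_mask(res$mask, truth_mono$chrom, truth_mono$pos)
  recovered <- call_key(retained)[which(retained$mclass == "deletion" &
                                        retained$unit_length == 1L &
                                        retained$unit_count >= 2L)]
  expect_gte(mean(call_key(truth_mono)[tin] %in% recovered), 0.9)

  expect_equal(sum(mononucleotide_indel_breakdown(res$calls[0, ])), 0L)
})
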