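ms_calls <- function(pos, tag = "H1", child = "kid", chrom = "chr1",
                     ref = "A", alt = "T", origin = NULL) {
  df <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                   child = child, haplotype_tag = tag)
  if (!is.null(origin)) df$parental_origin <- origin
  df
}

test_that("multisite clustering follows the pairwise 100 bp haplotype rule", {
  # two SNVs 10 bp apart on one haplotype: one cluster of two
  c1 <- cluster_multisite(ms_calls(c(1000, 1010)))
  expect_equal(nrow(c1), 2L)
  expect_equal(unique(c1$cluster_size), 2L)

  # 150 bp apart: no cluster
  expect_equal(nrow(cluster_multisite(ms_calls(c(1000, 1150)))), 0L)

  # chain 0/80/160: pairwise gaps 80 <= 100 so one cluster of three,
  # even though the end-to-end span is 160
  c3 <- cluster_multisite(ms_calls(c(1000, 1080, 1160)))
  expect_equal(unique(c3$cluster_size), 3L)
  expect_equal(unique(c3$span), 160)

  # different haplotype tags: no shared-haplotype evidence
  expect_equal(nrow(cluster_multisite(ms_calls(c(1000, 1010),
                                               tag = c("H1", "H2")))), 0L)

  # tags absent: matching determined parental origin is the fallback
  noTag <- ms_calls(c(1000, 1010), tag = NA_character_,
                    origin = c("paternal", "paternal"))
  expect_equal(nrow(cluster_multisite(noTag)), 2L)
  und <- ms_calls(c(1000, 1010), tag = NA_character_,
                  origin = c("undetermined", "undetermined"))
  expect_equal(nrow(cluster_multisite(und)), 0L)

  # different children never cluster together
  expect_equal(nrow(cluster_multisite(ms_calls(c(1000, 1010),
                                               child = c("k1", "k2")))), 0L)
})

test_that("clustering equals connected components of the proximity graph", {
  skip_if_not_installed("igraph")
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(2:20, 1L)
    calls <- data.frame(chrom = sample(c("c1", "c2"), n, TRUE),
                        pos = sample(1:600, n),
                        ref = "A", alt = "G",
                        child = sample(c("k1", "k2"), n, TRUE),
                        haplotype_tag = sample(c("H1", "H2", NA), n, TRUE))
    calls$parental_origin <- sample(c("paternal", "maternal", "undetermined"),
                                    n, TRUE)
    calls <- calls[sample(n), ]  # permutation invariance
    got <- cluster_multisite(calls, window = 100L)
    ## oracle: explicit graph, components of size >= 2
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      compat <- radtrio:::hap_compatible(calls$haplotype_tag[i],
                                         calls$haplotype_tag[j],
                                         calls$parental_origin[i],
                                         calls$parental_origin[j])
      if (calls$chrom[i] == calls$chrom[j] && calls$child[i] == calls$child[j] &&
          abs(calls$pos[i] - calls$pos[j]) <= 100L && compat) {
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    keep <- comp %in% which(table(comp) >= 2)
    oracle_members <- sort(paste(calls$child, calls$chrom, calls$pos)[keep])
    got_members <- sort(paste(got$child, got$chrom, got$pos))
    expect_identical(got_members, oracle_members)
    ## partition must match: members sharing an oracle component share a
    ## cluster id and vice versa
    if (nrow(got)) {
      key <- paste(got$child, got$chrom, got$pos)
      oracle_part <- comp[keep][match(key, paste(calls$child, calls$chrom,
                                                 calls$pos)[keep])]
      expect_equal(length(unique(paste(oracle_part, got$cluster_id))),
                   length(unique(got$cluster_id)))
    }
  }
})

test_that("substitutions collapse to the pyrimidine strand over 7 categories", {
  expect_equal(classify_substitution("C", "T", "ACG"), "C>T at CpG")
  expect_equal(classify_substitution("C", "T", "ACT"), "C>T at non-CpG")
  # purine reference: G>A in CGT context is C>T at CpG on the other strand
  expect_equal(classify_substitution("G", "A", "CGT"), "C>T at CpG")
  expect_equal(classify_substitution("C", "A", "TCT"), "C>A")
  expect_equal(classify_substitution("T", "G", "ATA"), "T>G")
  expect_equal(classify_substitution("A", "C", "TAT"), "T>G")
  expect_error(classify_substitution("A", "A", "TAT"), "substitution")
  expect_error(classify_substitution("C", "T", "AAG"), "context")
})

test_that("spectrum counts are invariant under reverse-complementing the genome", {
  set.seed(5)
  L <- 500L
  seq <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  ref <- stats::setNames(seq, "c")
  pos <- sample(2:(L - 1L), 60L)
  refb <- substring(seq, pos, pos)
  alt <- vapply(refb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                character(1))
  calls <- data.frame(chrom = "c", pos = pos, ref = refb, alt = alt)
  fwd <- spectrum_table(calls, ref)
  rc <- stats::setNames(revcomp(seq), "c")
  calls_rc <- data.frame(chrom = "c", pos = L + 1L - pos,
                         ref = revcomp(refb), alt = revcomp(alt))
  expect_identical(spectrum_table(calls_rc, rc), fwd)
  expect_equal(sum(fwd), nrow(calls))
})

test_that("spectrum comparison matches a hypergeometric enumeration oracle", {
  ## independent oracle: two-tailed Fisher P by full enumeration of the
  ## 2x2 tables with the observed margins
  fisher_enum <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    xs <- max(0, k - n):min(k, m)
    probs <- dhyper(xs, m, n, k)
    p_obs <- dhyper(a, m, n, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  a <- c(`C>A` = 3, `C>G` = 2, `C>T at CpG` = 0, `C>T at non-CpG` = 10,
         `T>A` = 4, `T>C` = 6, `T>G` = 3)          # total 28
  b <- c(`C>A` = 20, `C>G` = 25, `C>T at CpG` = 40, `C>T at non-CpG` = 70,
         `T>A` = 30, `T>C` = 40, `T>G` = 25)        # total 250
  res <- compare_spectra(a, b)
  cpg <- res$per_category[res$per_category$category == "C>T at CpG", ]
  expect_equal(cpg$p, fisher_enum(0, 28, 40, 210), tolerance = 1e-10)
  for (i in seq_len(nrow(res$per_category))) {
    row <- res$per_category[i, ]
    expect_equal(row$p,
                 fisher_enum(row$count_a, sum(a) - row$count_a,
                             row$count_b, sum(b) - row$count_b),
                 tolerance = 1e-10)
    expect_gte(row$p_bonferroni, row$p)
    expect_lte(row$p_bonferroni, 1)
    expect_equal(row$p_bonferroni, min(1, 7 * row$p))
  }
  # identical spectra: all corrected P = 1, OR = 1 where defined
  same <- compare_spectra(b, b)
  expect_true(all(same$per_category$p_bonferroni == 1))
  expect_gt(same$global_p, 0.9)
  expect_error(compare_spectra(a * 0, b), "zero-total")
})

test_that("known dinucleotide signatures are flagged on either strand", {
  mk <- function(refs, alts, pos = c(100L, 101L)) {
    data.frame(chrom = "c", pos = pos, ref = refs, alt = alts)
  }
  f1 <- flag_dinucleotide_signatures(mk(c("G", "C"), c("A", "A")))
  expect_true(f1[["gc_aa"]])
  f2 <- flag_dinucleotide_signatures(mk(c("G", "A"), c("T", "T")))
  expect_true(f2[["ga_tt"]])
  # GC>AA read on the minus strand is GC>TT
  f3 <- flag_dinucleotide_signatures(mk(c("G", "C"), c("T", "T")))
  expect_true(f3[["gc_aa"]])
  # TC>TT on the minus strand is GA>AA: not a signature
  f4 <- flag_dinucleotide_signatures(mk(c("T", "C"), c("T", "T")))
  expect_false(any(f4))
  expect_false(any(flag_dinucleotide_signatures(mk(c("A", "T"), c("G", "C")))))
  # non-adjacent substitutions never count
  expect_false(any(flag_dinucleotide_signatures(
    mk(c("G", "C"), c("A", "A"), pos = c(100L, 103L)))))
})
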