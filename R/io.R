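## File interchange: FASTA via Biostrings, bedGraph/BED via rtracklayer,
## multi-sample VCF (GT-less; DP/AD per sample) written as plain text and
## read back with vcfR. The in-memory data frames remain the working
## representation throughout the package.

#' Write a reference genome to FASTA
#'
#' @param reference Named character vector of chromosome sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(unlist(reference)), path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write / read per-base depth tracks as bedGraph
#'
#' Consecutive equal-depth positions are collapsed into intervals on write
#' and expanded on read.
#'
#' @param track Named list of per-base integer depth vectors.
#' @param path bedGraph path.
#' @param chrom_lengths Named integer vector of chromosome lengths (needed on
#'   read to restore zero-depth tails).
#' @return `path` invisibly, or the track on read.
#' @export
write_depth_bedgraph <- function(track, path) {
  parts <- lapply(names(track), function(ch) {
    r <- rle(track[[ch]])
    ends <- cumsum(r$lengths)
    data.frame(chrom = ch, start = ends - r$lengths + 1L, end = ends,
               score = r$values)
  })
  df <- do.call(rbind, parts)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               score = df$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_depth_bedgraph
#' @export
read_depth_bedgraph <- function(path, chrom_lengths) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- lapply(names(chrom_lengths), function(ch) {
    v <- integer(chrom_lengths[[ch]])
    sub <- gr[GenomicRanges::seqnames(gr) == ch]
    for (i in seq_along(sub)) {
      v[GenomicRanges::start(sub)[i]:GenomicRanges::end(sub)[i]] <-
        sub$score[i]
    }
    v
  })
  stats::setNames(out, names(chrom_lengths))
}

#' Write a joint variant table as a multi-sample VCF
#'
#' Emits a minimal VCF 4.2 with per-sample `DP` and `AD` (ref,alt) FORMAT
#' fields and genotypes left as `./.` (genotype calls are not part of the
#' table model; filtering runs on allele fractions).
#'
#' @param variants Variant table (`chrom`, `pos`, `ref`, `alt`,
#'   `<sample>_dp`, `<sample>_ad`).
#' @param samples Sample names, in column order.
#' @param path Output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, samples, path) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"High-quality read depth\">",
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  geno <- sapply(samples, function(s) {
    dp <- variants[[paste0(s, "_dp")]]
    ad <- variants[[paste0(s, "_ad")]]
    sprintf("./.:%d:%d,%d", dp, dp - ad, ad)
  })
  if (nrow(variants) == 1L) geno <- matrix(geno, nrow = 1L)
  body <- paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
                ".", "PASS", ".", "GT:DP:AD",
                apply(geno, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a multi-sample trio VCF into a variant table
#'
#' Uses `vcfR`; multi-allelic records must be split upstream. `DP` and the
#' alternate `AD` component become `<sample>_dp` / `<sample>_ad` columns.
#'
#' @param path VCF path.
#' @return Variant table data frame.
#' @export
read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    stop("multi-allelic records must be split before reading", call. = FALSE)
  }
  out <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT)
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, element = "AD")
  for (s in colnames(dp)) {
    out[[paste0(s, "_dp")]] <- as.integer(dp[, s])
    out[[paste0(s, "_ad")]] <- as.integer(sub("^[0-9]+,", "", ad[, s]))
  }
  rownames(out) <- NULL
  out
}

#' Write a whole synthetic cohort to disk
#'
#' Writes the reference FASTA, the joint VCF, one high-MQ and one total-depth
#' bedGraph per sample, and TSVs for the truth and phase tables.
#'
#' @param cohort A `trio_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_reference_fasta(cohort$reference, file.path(dir, "reference.fa"))
  write_variants_vcf(cohort$variants, cohort$samples, file.path(dir, "cohort.vcf"))
  for (s in cohort$samples) {
    write_depth_bedgraph(cohort$depth[[s]]$hq,
                         file.path(dir, paste0(s, ".hq.bedgraph")))
    write_depth_bedgraph(cohort$depth[[s]]$total,
                         file.path(dir, paste0(s, ".total.bedgraph")))
  }
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$phase, file.path(dir, "phase.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
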