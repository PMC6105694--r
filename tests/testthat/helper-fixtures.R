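# Small in-code fixtures shared across the suite.

make_transcript <- function(cds, id = "T1", chrom = "chr1", strand = "+",
                            exon_start = 100L, exons = NULL) {
  if (is.null(exons)) {
    exons <- cbind(exon_start, exon_start + nchar(cds))
  }
  reference_transcript(id, chrom, strand, exons, cds)
}

# cohort from explicit per-sample genotype strings "a|b"
make_cohort <- function(variants, gt) {
  samples <- names(gt)
  hapA <- hapB <- matrix(0L, nrow(variants), length(samples),
                         dimnames = list(variants$variant_id, samples))
  for (s in samples) {
    parts <- strsplit(gt[[s]], "|", fixed = TRUE)
    hapA[, s] <- vapply(parts, function(p) as.integer(p[[1]]), 1L)
    hapB[, s] <- vapply(parts, function(p) as.integer(p[[2]]), 1L)
  }
  list(variants = variants, hapA = hapA, hapB = hapB, samples = samples)
}

# variants on a single-exon "+" strand transcript, specified by 0-based
# CDS offset (== genomic offset from the exon start)
cds_variants <- function(tr, cds_offset, ref, alt, f,
                         id = sprintf("tv%02d", seq_along(cds_offset))) {
  stopifnot(tr$strand == "+", nrow(tr$exons) == 1L)
  variant_table(id, rep(tr$chromosome, length(cds_offset)),
                tr$exons[1, 1] + cds_offset + 1L,
                ref, as.list(alt), as.list(f))
}

# a CDS of n_codon codons (including start and terminal stop) built from
# a repeating non-degenerate codon so single-base edits are easy to reason
# about: ATG + (GAT)* + TAA translates to M D D D ... D
poly_asp_cds <- function(n_codon) {
  paste0("ATG", strrep("GAT", n_codon - 2L), "TAA")
}

# find a single-base missense edit in the given codon of a transcript;
# returns a one-row variant_table
missense_at <- function(tr, codon, f = 0.5, id = "tv01") {
  cds <- tr$cds_sequence
  for (p in 0:2) {
    off <- 3L * (codon - 1L) + p
    base <- substr(cds, off + 1L, off + 1L)
    for (b in setdiff(c("A", "C", "G", "T"), base)) {
      v <- cds_variants(tr, off, base, b, f, id = id)
      if (classify_variant(tr, v, 1) == "missense") return(v)
    }
  }
  stop("no missense edit found in codon ", codon)
}

# a deterministic varied CDS (no internal stop) whose k-mer windows are
# essentially all distinct — needed when the test relies on window
# uniqueness along the protein
varied_cds <- function(n_codon, seed = 99L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(sense, n_codon - 2L, replace = TRUE),
                      collapse = ""), "TAA")
}
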