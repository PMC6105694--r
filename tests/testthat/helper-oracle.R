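# Independent brute-force oracles. Deliberately naive: the proteome
# oracle rebuilds the whole genomic sequence, applies variants by genomic
# position, re-splices with shifted exon boundaries and translates codon
# by codon — a different computational path from the package's
# CDS-projection implementation.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

oracle_translate <- function(seq) {
  n <- nchar(seq) %/% 3L
  prot <- character(0)
  for (i in seq_len(n)) {
    aa <- Biostrings::GENETIC_CODE[[substr(seq, 3L * i - 2L, 3L * i)]]
    if (aa == "*") break
    prot <- c(prot, aa)
  }
  paste(prot, collapse = "")
}

oracle_haplotype_protein <- function(tr, variants, alleles) {
  ex <- tr$exons
  glen <- max(ex[, 2]) + 200L
  genome <- rep("A", glen)
  plus_seq <- if (tr$strand == "+") tr$cds_sequence
              else oracle_revcomp(tr$cds_sequence)
  off <- 0L
  for (i in seq_len(nrow(ex))) {
    w <- ex[i, 2] - ex[i, 1]
    genome[(ex[i, 1] + 1L):ex[i, 2]] <-
      strsplit(substr(plus_seq, off + 1L, off + w), "", fixed = TRUE)[[1]]
    off <- off + w
  }
  genome <- paste(genome, collapse = "")

  idx <- which(alleles > 0L & variants$chrom == tr$chromosome)
  ed <- list()
  for (i in idx) {
    start0 <- variants$pos[i] - 1L
    w <- nchar(variants$ref[i])
    if (!any(start0 >= ex[, 1] & start0 + w <= ex[, 2])) next
    ed[[length(ed) + 1L]] <- list(pos0 = start0, ref = variants$ref[i],
                                  alt = variants$alt[[i]][[alleles[[i]]]])
  }
  if (length(ed)) {
    ed <- ed[order(vapply(ed, `[[`, 0L, "pos0"), decreasing = TRUE)]
    for (e in ed) {
      stopifnot(identical(substr(genome, e$pos0 + 1L, e$pos0 + nchar(e$ref)),
                          e$ref))
      genome <- paste0(substr(genome, 1L, e$pos0), e$alt,
                       substr(genome, e$pos0 + nchar(e$ref) + 1L,
                              nchar(genome)))
    }
    ed <- ed[order(vapply(ed, `[[`, 0L, "pos0"))]
  }
  shift_at <- function(coord) {
    s <- 0L
    for (e in ed) if (e$pos0 < coord) s <- s + nchar(e$alt) - nchar(e$ref)
    s
  }
  spliced <- paste(vapply(seq_len(nrow(ex)), function(i) {
    s <- ex[i, 1] + shift_at(ex[i, 1])
    e2 <- ex[i, 2] + shift_at(ex[i, 2])
    substr(genome, s + 1L, e2)
  }, ""), collapse = "")
  if (tr$strand == "-") spliced <- oracle_revcomp(spliced)
  oracle_translate(spliced)
}

# brute-force URP oracle: enumerate all k-mer windows of both samples'
# haplotype proteins and take the plain set difference
oracle_urps <- function(rec_prots, don_prots, k = 9L) {
  kmers <- function(prots) {
    out <- character(0)
    for (p in prots) {
      L <- nchar(p)
      if (L >= k) {
        out <- c(out, substring(p, seq_len(L - k + 1L),
                                seq_len(L - k + 1L) + k - 1L))
      }
    }
    unique(out)
  }
  setdiff(kmers(rec_prots), kmers(don_prots))
}

# HWE genotype-pair enumeration: probability that the recipient carries
# >= 1 copy of the allele while an unrelated donor carries none
oracle_pmm_unrelated <- function(f) {
  gp <- c(`0` = (1 - f)^2, `1` = 2 * f * (1 - f), `2` = f^2)
  p <- 0
  for (gr in 0:2) for (gd in 0:2) {
    if (gr >= 1L && gd == 0L) {
      p <- p + gp[[as.character(gr)]] * gp[[as.character(gd)]]
    }
  }
  p
}

# parental-genotype x Mendelian-transmission enumeration for siblings
oracle_pmm_sibling <- function(f) {
  hap_p <- c(`0` = 1 - f, `1` = f)
  p <- 0
  for (m1 in 0:1) for (m2 in 0:1) for (d1 in 0:1) for (d2 in 0:1) {
    w_par <- hap_p[[as.character(m1)]] * hap_p[[as.character(m2)]] *
             hap_p[[as.character(d1)]] * hap_p[[as.character(d2)]]
    mom <- c(m1, m2); dad <- c(d1, d2)
    for (tm_r in 1:2) for (td_r in 1:2) for (tm_d in 1:2) for (td_d in 1:2) {
      rec <- c(mom[tm_r], dad[td_r])
      don <- c(mom[tm_d], dad[td_d])
      if (sum(rec) >= 1L && sum(don) == 0L) {
        p <- p + w_par / 16
      }
    }
  }
  p
}
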