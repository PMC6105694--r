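# Variant-aware proteome construction: apply a sample's phased alleles to
# each transcript CDS per haplotype, translate, and record per-variant
# provenance (which protein residues each applied allele altered, and
# which reference residues it removed or replaced). The provenance
# intervals drive URP causal-variant attribution downstream; they are
# deliberately generous at indel junctions (one extra flanking codon) —
# over-covering is harmless because covering variants are only consulted
# for peptides already proven unique by set subtraction.

# Project one alternate allele of one variant row onto a transcript.
# Returns NULL when the REF span is not contained in a single exon of
# this transcript; list(mismatch = TRUE) when the transcript sequence
# disagrees with the REF allele; else list(cds_off, ref_cds, alt_cds).
project_allele <- function(transcript, variants, i, allele_index) {
  if (variants$chrom[i] != transcript$chromosome) return(NULL)
  ref <- variants$ref[i]
  alt <- variants$alt[[i]][[allele_index]]
  start0 <- variants$pos[i] - 1L
  off <- project_span(transcript, start0, nchar(ref))
  if (is.na(off)) return(NULL)
  if (transcript$strand == "+") {
    ref_cds <- ref; alt_cds <- alt
  } else {
    ref_cds <- revcomp(ref); alt_cds <- revcomp(alt)
  }
  expected <- substr(transcript$cds_sequence, off + 1L, off + nchar(ref_cds))
  if (!identical(expected, ref_cds)) return(list(mismatch = TRUE))
  list(cds_off = off, ref_cds = ref_cds, alt_cds = alt_cds)
}

#' Classify a variant allele relative to a transcript
#'
#' Applies the single allele to the reference CDS and compares
#' translations. Classification is transcript-relative: the same site can
#' be coding for one transcript and not projectable onto another.
#'
#' @param transcript a `reference_transcript`.
#' @param variants a [variant_table()].
#' @param i row index into `variants`.
#' @param allele_index alternate allele index (>= 1).
#' @return one of `"missense"`, `"synonymous"`, `"nonsense"`,
#'   `"stop_lost"`, `"inframe_insertion"`, `"inframe_deletion"`,
#'   `"frameshift_insertion"`, `"frameshift_deletion"`,
#'   `"not_projectable"`, `"ref_mismatch"`.
#' @export
classify_variant <- function(transcript, variants, i, allele_index = 1L) {
  p <- project_allele(transcript, variants, i, allele_index)
  if (is.null(p)) return("not_projectable")
  if (isTRUE(p$mismatch)) return("ref_mismatch")
  wr <- nchar(p$ref_cds); wa <- nchar(p$alt_cds)
  delta <- wa - wr
  if (delta %% 3L != 0L) {
    return(if (delta < 0L) "frameshift_deletion" else "frameshift_insertion")
  }
  if (delta != 0L) {
    return(if (delta < 0L) "inframe_deletion" else "inframe_insertion")
  }
  cds <- transcript$cds_sequence
  mut <- paste0(substr(cds, 1L, p$cds_off), p$alt_cds,
                substr(cds, p$cds_off + wr + 1L, nchar(cds)))
  ref_tr <- translate_cds(cds)
  mut_tr <- translate_cds(mut)
  if (identical(mut_tr$protein, ref_tr$protein)) return("synonymous")
  if (nchar(mut_tr$protein) < nchar(ref_tr$protein)) return("nonsense")
  if (nchar(mut_tr$protein) > nchar(ref_tr$protein)) return("stop_lost")
  "missense"
}

#' Apply one haplotype's alleles to a transcript CDS
#'
#' Alleles are applied right-to-left in CDS coordinates so earlier
#' offsets stay valid; the returned offsets locate each applied allele in
#' the final mutated CDS. When two alleles on the same haplotype have
#' overlapping REF spans, the downstream-most (largest CDS offset) is
#' applied and the other skipped (`overlap_conflict` in the log) — a
#' deterministic tie-break.
#'
#' @param transcript a `reference_transcript`.
#' @param variants a [variant_table()].
#' @param alleles integer vector of allele indices for this haplotype,
#'   one per variant row (0 = reference).
#' @return list with `cds` (mutated CDS string), `applied` (data.frame:
#'   `vi`, `variant_id`, `allele_index`, `ref_off`, `wr`, `wa`,
#'   `mut_offset`), `log`.
#' @export
apply_haplotype <- function(transcript, variants, alleles) {
  stopifnot(length(alleles) == nrow(variants))
  log <- new_log()
  rows <- list()
  for (i in which(alleles > 0L)) {
    a <- alleles[[i]]
    p <- project_allele(transcript, variants, i, a)
    if (is.null(p)) next
    if (isTRUE(p$mismatch)) {
      log <- bump(log, "ref_mismatch")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      vi = i, variant_id = variants$variant_id[i], allele_index = a,
      ref_off = p$cds_off, wr = nchar(p$ref_cds), wa = nchar(p$alt_cds),
      ref_cds = p$ref_cds, alt_cds = p$alt_cds, stringsAsFactors = FALSE)
  }
  cds <- transcript$cds_sequence
  if (!length(rows)) {
    return(list(cds = cds,
                applied = data.frame(vi = integer(0),
                                     variant_id = character(0),
                                     allele_index = integer(0),
                                     ref_off = integer(0), wr = integer(0),
                                     wa = integer(0), mut_offset = integer(0),
                                     stringsAsFactors = FALSE),
                log = log))
  }
  ed <- do.call(rbind, rows)
  ed <- ed[order(ed$ref_off, decreasing = TRUE), , drop = FALSE]
  keep <- logical(nrow(ed))
  last_kept_off <- Inf
  for (r in seq_len(nrow(ed))) {
    if (ed$ref_off[r] + ed$wr[r] > last_kept_off) {
      log <- bump(log, "overlap_conflict")
      next
    }
    keep[r] <- TRUE
    last_kept_off <- ed$ref_off[r]
    cds <- paste0(substr(cds, 1L, ed$ref_off[r]), ed$alt_cds[r],
                  substr(cds, ed$ref_off[r] + ed$wr[r] + 1L, nchar(cds)))
  }
  ed <- ed[keep, , drop = FALSE]
  ed <- ed[order(ed$ref_off), , drop = FALSE]
  delta <- ed$wa - ed$wr
  shift <- c(0L, cumsum(delta))[seq_len(nrow(ed))]
  ed$mut_offset <- ed$ref_off + as.integer(shift)
  list(cds = cds,
       applied = ed[, c("vi", "variant_id", "allele_index", "ref_off",
                        "wr", "wa", "mut_offset")],
       log = log)
}

#' Build one haplotype protein
#'
#' Applies the haplotype's alleles, translates, and computes per-variant
#' provenance intervals: `prot_start`/`prot_end` are the 1-based residue
#' range the allele altered in the *mutated* protein (frameshift alleles
#' cover everything downstream; donor-side classification also uses
#' `ref_start`/`ref_end`, the reference-protein residue range the allele
#' altered or removed). A start-codon-disrupting allele yields an empty
#' protein (`start_lost`); a destroyed stop codon reads through to the
#' end of the provided CDS (`stop_lost`).
#'
#' @inheritParams apply_haplotype
#' @param sample_id,haplotype identifiers stored on the result
#'   (haplotype is `"A"` or `"B"`).
#' @return object of class `haplotype_protein`.
#' @export
build_haplotype_protein <- function(transcript, variants, alleles,
                                    sample_id = "sample", haplotype = "A") {
  ah <- apply_haplotype(transcript, variants, alleles)
  ed <- ah$applied
  ref_tr <- translate_cds(transcript$cds_sequence)
  rplen <- nchar(ref_tr$protein)

  start_lost <- nrow(ed) > 0L &&
    substr(transcript$cds_sequence, 1L, 3L) == "ATG" &&
    substr(ah$cds, 1L, 3L) != "ATG"
  if (start_lost) {
    protein <- ""
    truncated <- TRUE
    plen <- 0L
  } else {
    tl <- translate_cds(ah$cds)
    protein <- tl$protein
    truncated <- tl$truncated
    plen <- nchar(protein)
  }

  n <- nrow(ed)
  type <- character(n)
  prot_start <- prot_end <- ref_start <- ref_end <- rep(NA_integer_, n)
  expressed <- rep(FALSE, n)
  frameshift <- truncating <- rep(FALSE, n)
  codon_delta <- rep(0L, n)
  stop_lost <- FALSE
  for (r in seq_len(n)) {
    ty <- classify_variant(transcript, variants, ed$vi[r], ed$allele_index[r])
    type[r] <- ty
    mo <- ed$mut_offset[r]; ro <- ed$ref_off[r]
    wa <- ed$wa[r]; wr <- ed$wr[r]
    c1 <- mo %/% 3L + 1L
    c2 <- (mo + max(wa, 1L) - 1L) %/% 3L + 1L
    rc1 <- ro %/% 3L + 1L
    rc2 <- (ro + max(wr, 1L) - 1L) %/% 3L + 1L
    if (start_lost) next
    if (ty %in% c("missense", "synonymous")) {
      if (c1 <= plen) {
        expressed[r] <- TRUE
        prot_start[r] <- c1; prot_end[r] <- min(c2, plen)
        ref_start[r] <- rc1; ref_end[r] <- min(rc2, rplen)
      }
    } else if (ty == "nonsense") {
      # no altered residues in the mutated protein; the carrier loses
      # reference residues rc1..end
      if (c1 == plen + 1L) {
        expressed[r] <- TRUE
        truncating[r] <- TRUE
        ref_start[r] <- rc1; ref_end[r] <- rplen
      }
    } else if (ty == "stop_lost") {
      if (c1 <= plen) {
        expressed[r] <- TRUE
        stop_lost <- TRUE
        prot_start[r] <- c1; prot_end[r] <- plen
        ref_start[r] <- rplen; ref_end[r] <- rplen
      }
    } else if (ty %in% c("inframe_insertion", "inframe_deletion")) {
      if (c1 - 1L <= plen) {
        expressed[r] <- TRUE
        codon_delta[r] <- as.integer((wa - wr) / 3L)
        prot_start[r] <- max(1L, c1 - 1L)
        prot_end[r] <- min(plen, c2 + 1L)
        ref_start[r] <- max(1L, rc1 - 1L)
        ref_end[r] <- min(rplen, rc2 + 1L)
      }
    } else if (ty %in% c("frameshift_insertion", "frameshift_deletion")) {
      if (c1 - 1L <= plen) {
        expressed[r] <- TRUE
        frameshift[r] <- TRUE
        truncating[r] <- TRUE
        prot_start[r] <- max(1L, c1 - 1L)
        prot_end[r] <- plen
        ref_start[r] <- max(1L, rc1 - 1L)
        ref_end[r] <- rplen
      }
    }
  }

  vdf <- data.frame(variant_id = ed$variant_id,
                    allele_index = ed$allele_index,
                    cds_offset = ed$mut_offset,
                    type = type,
                    expressed = expressed,
                    frameshift = frameshift,
                    truncating = truncating,
                    prot_start = prot_start, prot_end = prot_end,
                    ref_start = ref_start, ref_end = ref_end,
                    codon_delta = codon_delta,
                    stringsAsFactors = FALSE)

  structure(list(sample_id = sample_id,
                 transcript_id = transcript$transcript_id,
                 haplotype = haplotype,
                 protein = protein,
                 truncated = truncated,
                 start_lost = start_lost,
                 stop_lost = stop_lost,
                 variants = vdf,
                 log = ah$log),
            class = "haplotype_protein")
}

#' @export
print.haplotype_protein <- function(x, ...) {
  cat(sprintf("<haplotype_protein %s %s/%s: %d aa, %d variant(s)%s>\n",
              x$sample_id, x$transcript_id, x$haplotype, nchar(x$protein),
              nrow(x$variants),
              if (x$truncated) ", truncated" else ""))
  invisible(x)
}

#' Build an individual's diploid proteome
#'
#' Translates both haplotypes of every transcript for one sample.
#' Homozygous-reference transcripts are still emitted: they contribute
#' reference peptides to the sample's peptidome (and so to donor-side
#' subtraction).
#'
#' @param sample_id a column of the haplotype matrices.
#' @param transcripts list of `reference_transcript`.
#' @param cohort list with `variants`, `hapA`, `hapB` (as returned by
#'   [read_variants()] or [generate_cohort()]).
#' @return object of class `individual_proteome`: a deterministic,
#'   named list of `haplotype_protein` (`"<transcript>|A"`, `"...|B"`).
#' @export
build_proteome <- function(sample_id, transcripts, cohort) {
  if (!sample_id %in% colnames(cohort$hapA)) {
    stop("sample not genotyped: ", sample_id)
  }
  av <- cohort$hapA[, sample_id]
  bv <- cohort$hapB[, sample_id]
  proteins <- list()
  for (tr in transcripts) {
    proteins[[paste0(tr$transcript_id, "|A")]] <-
      build_haplotype_protein(tr, cohort$variants, av, sample_id, "A")
    proteins[[paste0(tr$transcript_id, "|B")]] <-
      build_haplotype_protein(tr, cohort$variants, bv, sample_id, "B")
  }
  structure(list(sample_id = sample_id, proteins = proteins),
            class = "individual_proteome")
}

#' @export
print.individual_proteome <- function(x, ...) {
  cat(sprintf("<individual_proteome %s: %d haplotype proteins>\n",
              x$sample_id, length(x$proteins)))
  invisible(x)
}
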