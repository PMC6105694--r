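# Synthetic-data generators: reference transcripts, coding variant sets
# with a configurable type mixture and allele-frequency spectrum,
# Hardy-Weinberg cohorts, sibling pairs by Mendelian transmission, and
# synthetic PSSMs with class-I-like anchor motifs. Every generator is
# fully determined by the config seed, and every output is readable by
# the corresponding package reader (round-trip property).

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                        c("TAA", "TAG", "TGA"))

#' Simulation configuration
#'
#' Defaults emulate the statistical structure of a phased population
#' cohort at desk scale: a cohort of 200 samples (enough for 100
#' disjoint virtual pairs), mostly-missense coding variation, and a
#' uniform allele-frequency spectrum.
#'
#' @param seed integer; fully determines all generator output.
#' @param n_transcripts number of coding transcripts.
#' @param transcript_length_range codon range (including start and stop).
#' @param n_variants total coding variants.
#' @param variant_type_mixture named proportions over `missense`,
#'   `adjacent_missense` (a linked pair of missense SNVs in neighbouring
#'   codons), `inframe_indel`, `frameshift`, `nonsense`; must sum to 1.
#' @param frequency_spectrum `"uniform"`, `list(kind = "point", f = )`,
#'   or `list(kind = "truncated_1_over_f", f_min = , f_max = )`.
#' @param n_samples cohort size for [generate_cohort()].
#' @param relationship_structure `"unrelated"` or `"sibling_families"`.
#' @param k peptide length used downstream.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_transcripts = 30L,
                              transcript_length_range = c(100L, 300L),
                              n_variants = 150L,
                              variant_type_mixture = c(
                                missense = 0.85, adjacent_missense = 0.03,
                                inframe_indel = 0.04, frameshift = 0.05,
                                nonsense = 0.03),
                              frequency_spectrum = "uniform",
                              n_samples = 200L,
                              relationship_structure = c("unrelated",
                                                         "sibling_families"),
                              k = 9L) {
  mix_names <- c("missense", "adjacent_missense", "inframe_indel",
                 "frameshift", "nonsense")
  stopifnot(setequal(names(variant_type_mixture), mix_names),
            abs(sum(variant_type_mixture) - 1) < 1e-8,
            all(variant_type_mixture >= 0),
            length(transcript_length_range) == 2,
            transcript_length_range[1] >= 20,
            seed == floor(seed), abs(seed) < 2^31 - 10)
  structure(list(seed = as.integer(seed),
                 n_transcripts = as.integer(n_transcripts),
                 transcript_length_range = as.integer(transcript_length_range),
                 n_variants = as.integer(n_variants),
                 variant_type_mixture = variant_type_mixture[mix_names],
                 frequency_spectrum = frequency_spectrum,
                 n_samples = as.integer(n_samples),
                 relationship_structure = match.arg(relationship_structure),
                 k = as.integer(k)),
            class = "simulation_config")
}

# draw one frequency from the configured spectrum
draw_f <- function(spectrum, n = 1L) {
  sp <- if (is.character(spectrum)) list(kind = spectrum) else spectrum
  if (sp$kind == "uniform") return(runif(n))
  if (sp$kind == "point") return(rep(sp$f, n))
  if (sp$kind == "truncated_1_over_f") {
    f_min <- if (is.null(sp$f_min)) 0.001 else sp$f_min
    f_max <- if (is.null(sp$f_max)) 0.999 else sp$f_max
    return(f_min * (f_max / f_min)^runif(n))
  }
  stop("unknown frequency spectrum: ", sp$kind)
}

#' Generate reference transcripts
#'
#' Each transcript starts with ATG, ends with a stop codon, has no
#' internal in-frame stop, uses uniform sense-codon composition, lives
#' on its own chromosome with 1-3 exons, and has a random strand.
#'
#' @param config a [simulation_config()].
#' @param fasta_path,annotation_path optional output paths; when given,
#'   the transcripts are also written via [write_transcripts()].
#' @return list of `reference_transcript`.
#' @export
generate_reference <- function(config, fasta_path = NULL,
                               annotation_path = NULL) {
  set.seed(config$seed)
  out <- vector("list", config$n_transcripts)
  lens <- seq.int(config$transcript_length_range[1],
                  config$transcript_length_range[2])
  for (i in seq_len(config$n_transcripts)) {
    n_codon <- lens[[sample.int(length(lens), 1L)]]
    body <- sample(SENSE_CODONS, n_codon - 2L, replace = TRUE)
    cds <- paste0("ATG", paste(body, collapse = ""),
                  sample(STOP_CODONS, 1L))
    L <- nchar(cds)
    n_ex <- sample(1:3, 1L)
    cuts <- if (n_ex > 1L) sort(sample(seq_len(L - 1L), n_ex - 1L)) else integer(0)
    widths <- diff(c(0L, cuts, L))
    starts <- 100L + c(0L, cumsum(widths[-n_ex] + 100L))
    exons <- cbind(starts, starts + widths)
    out[[i]] <- reference_transcript(
      sprintf("TX%03d", i), sprintf("chr%d", i),
      sample(c("+", "-"), 1L), exons, cds)
  }
  if (!is.null(fasta_path)) {
    write_transcripts(out, fasta_path, annotation_path)
  }
  out
}

# cds-level edit constructors; each returns list(offset0, ref, alt) in
# CDS coordinates or NULL to signal "resample"
edit_missense <- function(cds, c) {
  codon <- substr(cds, 3L * c - 2L, 3L * c)
  aa <- Biostrings::GENETIC_CODE[[codon]]
  for (try in seq_len(20L)) {
    p <- sample(1:3, 1L)
    new_base <- sample(setdiff(c("A", "C", "G", "T"),
                               substr(codon, p, p)), 1L)
    new_codon <- codon
    substr(new_codon, p, p) <- new_base
    new_aa <- Biostrings::GENETIC_CODE[[new_codon]]
    if (new_aa != "*" && new_aa != aa) {
      return(list(offset0 = 3L * (c - 1L) + p - 1L,
                  ref = substr(codon, p, p), alt = new_base))
    }
  }
  NULL
}

edit_nonsense <- function(cds, c) {
  codon <- substr(cds, 3L * c - 2L, 3L * c)
  cands <- list()
  for (p in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
      new_codon <- codon
      substr(new_codon, p, p) <- b
      if (new_codon %in% STOP_CODONS) {
        cands[[length(cands) + 1L]] <- list(
          offset0 = 3L * (c - 1L) + p - 1L,
          ref = substr(codon, p, p), alt = b)
      }
    }
  }
  if (!length(cands)) return(NULL)
  cands[[sample(length(cands), 1L)]]
}

edit_inframe_indel <- function(cds, c) {
  anchor_pos <- 3L * c - 3L  # last base of codon c-1 (1-based), c >= 2
  anchor <- substr(cds, anchor_pos, anchor_pos)
  if (runif(1) < 0.5) {  # delete codon c
    list(offset0 = anchor_pos - 1L,
         ref = substr(cds, anchor_pos, 3L * c), alt = anchor)
  } else {               # insert a sense codon before codon c
    list(offset0 = anchor_pos - 1L, ref = anchor,
         alt = paste0(anchor, sample(SENSE_CODONS, 1L)))
  }
}

edit_frameshift <- function(cds, c) {
  p <- 3L * c - 2L + sample(0:1, 1L)  # inside codon c, anchor has successor
  anchor <- substr(cds, p, p)
  if (runif(1) < 0.5) {  # 1-bp deletion of the base after the anchor
    list(offset0 = p - 1L, ref = substr(cds, p, p + 1L), alt = anchor)
  } else {               # 1-bp insertion after the anchor
    list(offset0 = p - 1L, ref = anchor,
         alt = paste0(anchor, sample(c("A", "C", "G", "T"), 1L)))
  }
}

#' Generate a coding variant set
#'
#' Variant positions are uniform over coding positions excluding the
#' start and stop codons; missense variants are nonsynonymous by
#' construction (candidate substitutions are resampled until the amino
#' acid changes), so generator type labels are exact ground truth for
#' classifier tests. `adjacent_missense` draws emit a perfectly linked
#' pair of missense SNVs in neighbouring codons (one `link_group`, one
#' frequency) so that adjacent-nsSNP URPs actually co-occur on a
#' haplotype. Each variant records its true frequency drawn from the
#' configured spectrum.
#'
#' @param config a [simulation_config()].
#' @param transcripts output of [generate_reference()].
#' @return list of class `variant_set`: `variants` (a
#'   [variant_table()]) and `meta` (data.frame: `variant_id`,
#'   `type_label`, `link_group`, `true_f`, `transcript_id`, `codon`).
#' @export
generate_variant_set <- function(config, transcripts) {
  set.seed(config$seed + 1L)
  n_codons <- vapply(transcripts, function(tr) nchar(tr$cds_sequence) %/% 3L, 1L)
  capacity <- sum(n_codons - 2L)
  if (config$n_variants > capacity %/% 2L) {
    stop("requested variant count exceeds available coding positions (",
         capacity, ")")
  }
  occupied <- lapply(seq_along(transcripts), function(i) logical(n_codons[i]))

  pick_codons <- function(width) {
    # sample a transcript (length-weighted) and `width` free neighbouring
    # codons in [2, n_codon - 1]; NULL if the draw collides
    ti <- sample(seq_along(transcripts), 1L, prob = n_codons - 2L)
    nc <- n_codons[ti]
    c0 <- sample(2L:(nc - width), 1L)
    cods <- c0:(c0 + width - 1L)
    if (any(occupied[[ti]][pmax(1L, min(cods) - 1L):
                             pmin(nc, max(cods) + 1L)])) return(NULL)
    list(ti = ti, codons = cods)
  }

  mix <- config$variant_type_mixture
  rows <- list()
  meta <- list()
  vnum <- 0L
  gnum <- 0L
  add_variant <- function(ti, edit, type_label, group, f) {
    tr <- transcripts[[ti]]
    wr <- nchar(edit$ref)
    g0 <- unproject_span(tr, edit$offset0, wr)
    if (is.na(g0)) return(FALSE)  # span crosses exon junction: resample
    if (tr$strand == "+") {
      ref_g <- edit$ref; alt_g <- edit$alt
    } else {
      ref_g <- revcomp(edit$ref); alt_g <- revcomp(edit$alt)
    }
    vnum <<- vnum + 1L
    vid <- sprintf("v%04d", vnum)
    rows[[vnum]] <<- data.frame(variant_id = vid, chrom = tr$chromosome,
                                pos = g0 + 1L, ref = ref_g, alt = alt_g,
                                af = f, stringsAsFactors = FALSE)
    meta[[vnum]] <<- data.frame(variant_id = vid, type_label = type_label,
                                link_group = group, true_f = f,
                                transcript_id = tr$transcript_id,
                                codon = edit$offset0 %/% 3L + 1L,
                                stringsAsFactors = FALSE)
    TRUE
  }

  guard <- 0L
  while (vnum < config$n_variants) {
    guard <- guard + 1L
    if (guard > 200L * config$n_variants) {
      stop("variant placement did not converge; lower n_variants")
    }
    type <- sample(names(mix), 1L, prob = mix)
    width <- if (type == "adjacent_missense") 2L else 1L
    if (type == "adjacent_missense" && vnum == config$n_variants - 1L) {
      type <- "missense"; width <- 1L  # keep the exact total
    }
    loc <- pick_codons(width)
    if (is.null(loc)) next
    tr <- transcripts[[loc$ti]]
    cds <- tr$cds_sequence
    f <- draw_f(config$frequency_spectrum)
    gnum <- gnum + 1L
    ok <- switch(type,
      missense = {
        e <- edit_missense(cds, loc$codons[1L])
        !is.null(e) && add_variant(loc$ti, e, "missense", gnum, f)
      },
      adjacent_missense = {
        e1 <- edit_missense(cds, loc$codons[1L])
        e2 <- edit_missense(cds, loc$codons[2L])
        !is.null(e1) && !is.null(e2) &&
          add_variant(loc$ti, e1, "adjacent_missense", gnum, f) &&
          add_variant(loc$ti, e2, "adjacent_missense", gnum, f)
      },
      inframe_indel = {
        e <- edit_inframe_indel(cds, loc$codons[1L])
        add_variant(loc$ti, e, "inframe_indel", gnum, f)
      },
      frameshift = {
        e <- edit_frameshift(cds, loc$codons[1L])
        add_variant(loc$ti, e, "frameshift", gnum, f)
      },
      nonsense = {
        e <- edit_nonsense(cds, loc$codons[1L])
        !is.null(e) && add_variant(loc$ti, e, "nonsense", gnum, f)
      })
    if (ok) {
      nc <- n_codons[loc$ti]
      occupied[[loc$ti]][pmax(1L, min(loc$codons) - 1L):
                           pmin(nc, max(loc$codons) + 1L)] <- TRUE
    }
  }

  rows <- do.call(rbind, rows)
  meta <- do.call(rbind, meta)
  ord <- order(rows$chrom, rows$pos)
  rows <- rows[ord, , drop = FALSE]
  meta <- meta[ord, , drop = FALSE]
  variants <- variant_table(rows$variant_id, rows$chrom, rows$pos, rows$ref,
                            as.list(rows$alt), as.list(rows$af))
  structure(list(variants = variants, meta = meta), class = "variant_set")
}

#' Generate a phased cohort under Hardy-Weinberg equilibrium
#'
#' Each haplotype carries the alternate allele independently with
#' probability equal to the variant's true frequency; linked variants
#' (one `link_group`) are co-inherited perfectly. Independent across
#' samples and across link groups.
#'
#' @param config a [simulation_config()].
#' @param varset a `variant_set` from [generate_variant_set()].
#' @param n_samples overrides `config$n_samples` when given.
#' @param sample_prefix prefix for generated sample ids.
#' @return list of class `cohort`: `variants`, `meta`, `hapA`, `hapB`,
#'   `samples`.
#' @export
generate_cohort <- function(config, varset, n_samples = config$n_samples,
                            sample_prefix = "S") {
  set.seed(config$seed + 2L)
  meta <- varset$meta
  groups <- unique(meta$link_group)
  g_idx <- match(meta$link_group, groups)
  g_f <- meta$true_f[match(groups, meta$link_group)]
  n_g <- length(groups)
  samples <- sprintf("%s%04d", sample_prefix, seq_len(n_samples))
  draw <- function() {
    m <- matrix(rbinom(n_g * n_samples, 1L, g_f), n_g, n_samples)
    m[g_idx, , drop = FALSE]
  }
  hapA <- draw(); hapB <- draw()
  dimnames(hapA) <- dimnames(hapB) <- list(meta$variant_id, samples)
  structure(list(variants = varset$variants, meta = meta,
                 hapA = hapA, hapB = hapB, samples = samples),
            class = "cohort")
}

#' Generate sibling pairs by Mendelian transmission
#'
#' For each family, two parents are drawn under Hardy-Weinberg
#' equilibrium; each sibling receives one uniformly chosen haplotype
#' from each parent, independently per chromosome (single-chromosome
#' model: one transmission draw per parent per child per chromosome, no
#' recombination).
#'
#' @param config a [simulation_config()].
#' @param varset a `variant_set`.
#' @param n_pairs number of sibling pairs (families).
#' @return list of class `cohort` with the sibling samples
#'   (`"F<i>.1"`, `"F<i>.2"`) plus a `pairs` data.frame.
#' @export
generate_sibling_cohort <- function(config, varset, n_pairs) {
  set.seed(config$seed + 3L)
  meta <- varset$meta
  groups <- unique(meta$link_group)
  g_idx <- match(meta$link_group, groups)
  g_f <- meta$true_f[match(groups, meta$link_group)]
  n_g <- length(groups)
  chroms <- unique(varset$variants$chrom)
  g_chrom <- match(varset$variants$chrom, chroms)[
    match(groups, meta$link_group)]
  n_c <- length(chroms)

  par_hap <- function() matrix(rbinom(n_g * n_pairs, 1L, g_f), n_g, n_pairs)
  p1a <- par_hap(); p1b <- par_hap(); p2a <- par_hap(); p2b <- par_hap()
  # transmission choices: chromosome x family, one per (parent, child)
  tchoice <- function() matrix(sample(c(TRUE, FALSE), n_c * n_pairs,
                                      replace = TRUE), n_c, n_pairs)
  t11 <- tchoice(); t21 <- tchoice()  # parent1/2 -> child1
  t12 <- tchoice(); t22 <- tchoice()  # parent1/2 -> child2
  pick <- function(t, a, b) {
    sel <- t[g_chrom, , drop = FALSE]
    out <- b
    out[sel] <- a[sel]
    out
  }
  c1A <- pick(t11, p1a, p1b); c1B <- pick(t21, p2a, p2b)
  c2A <- pick(t12, p1a, p1b); c2B <- pick(t22, p2a, p2b)

  samples <- c(sprintf("F%04d.1", seq_len(n_pairs)),
               sprintf("F%04d.2", seq_len(n_pairs)))
  expand <- function(c1, c2) {
    m <- cbind(c1[g_idx, , drop = FALSE], c2[g_idx, , drop = FALSE])
    dimnames(m) <- list(meta$variant_id, samples)
    m
  }
  pairs <- data.frame(recipient_id = samples[seq_len(n_pairs)],
                      donor_id = samples[n_pairs + seq_len(n_pairs)],
                      relationship = "sibling", stringsAsFactors = FALSE)
  structure(list(variants = varset$variants, meta = meta,
                 hapA = expand(c1A, c2A), hapB = expand(c1B, c2B),
                 samples = samples, pairs = pairs),
            class = "cohort")
}

#' Generate a synthetic class-I-like PSSM
#'
#' Anchor positions (2 and k by default, mimicking MHC class I binding
#' motifs) receive a strong preference for one randomly chosen residue;
#' all other weights are small noise. `anchor_weight = 0` gives a
#' maximal-entropy (motif-free) matrix whose binder set is an arbitrary
#' p-fraction of any background.
#'
#' @param config a [simulation_config()].
#' @param allele_name label for the matrix.
#' @param anchor_positions positions carrying the motif.
#' @param anchor_weight score bonus of the preferred anchor residue;
#'   controls motif entropy (larger = lower entropy = more promiscuous
#'   separation between motif and background).
#' @param seed_offset stream offset so several alleles from one config
#'   differ.
#' @return a [pssm()].
#' @export
generate_pssm <- function(config, allele_name = "HLA-SYN*01:01",
                          anchor_positions = c(2L, config$k),
                          anchor_weight = 3, seed_offset = 4L) {
  set.seed(config$seed + seed_offset)
  k <- config$k
  w <- matrix(stats::rnorm(k * 20, 0, 0.3), k, 20,
              dimnames = list(NULL, AA_ALPHABET))
  for (p in anchor_positions) {
    pref <- sample(AA_ALPHABET, 1L)
    w[p, pref] <- w[p, pref] + anchor_weight
  }
  pssm(allele_name, w, provenance = "synthetic")
}

#' Sample background peptides from the reference proteome
#'
#' Uniform k-mer windows over the reference proteins of the generated
#' transcripts — the "randomly selected from the genome" background used
#' for percentile threshold calibration.
#'
#' @param transcripts list of `reference_transcript`.
#' @param n number of peptides.
#' @param k peptide length.
#' @param seed RNG seed.
#' @return character vector of `n` k-mers.
#' @export
generate_background <- function(transcripts, n, k = 9L, seed = 1L) {
  set.seed(seed)
  prots <- vapply(transcripts, reference_protein, "")
  n_win <- pmax(0L, nchar(prots) - k + 1L)
  stopifnot(sum(n_win) > 0)
  ti <- sample(seq_along(prots), n, replace = TRUE, prob = n_win)
  starts <- vapply(ti, function(i) sample.int(n_win[i], 1L), 1L)
  substring(prots[ti], starts, starts + k - 1L)
}
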