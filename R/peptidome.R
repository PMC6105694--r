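# Peptidome: 9-mer extraction, donor-subtracted unique recipient peptide
# (URP) computation with causal-variant provenance, polymorphism-class
# assignment, frequency profiling, saturation curves, and intersection
# with external peptide lists (e.g. MS-identified immunopeptidomes).
#
# Distinct-peptide semantics throughout: a peptide string occurring in
# two transcripts is one URP with merged provenance.

# allele-frequency bins used for nsSNP URP profiling
F_BIN_LABELS <- c("f<0.01", "0.01<=f<0.1", "0.1<=f<=0.9", "f>0.9")

f_bin_of <- function(f) {
  ifelse(f < 0.01, F_BIN_LABELS[1],
    ifelse(f < 0.1, F_BIN_LABELS[2],
      ifelse(f <= 0.9, F_BIN_LABELS[3], F_BIN_LABELS[4])))
}

#' Extract the k-mer peptidome of an individual proteome
#'
#' Every haplotype protein of length `L` contributes `max(0, L - k + 1)`
#' peptide occurrences; the sample's peptidome-as-set is the union of
#' distinct peptide strings over both haplotypes and all transcripts.
#'
#' @param proteome an `individual_proteome`.
#' @param k peptide length (default 9, the dominant MHC class I ligand
#'   length).
#' @return object of class `peptidome`: list with `sample_id`, `k`,
#'   `peptides` (distinct strings) and `occurrences` (data.frame:
#'   `peptide`, `transcript_id`, `haplotype`, `start` — 1-based start in
#'   the haplotype protein).
#' @export
extract_peptides <- function(proteome, k = 9L) {
  stopifnot(k >= 1L)
  k <- as.integer(k)
  occs <- vector("list", length(proteome$proteins))
  for (j in seq_along(proteome$proteins)) {
    hp <- proteome$proteins[[j]]
    L <- nchar(hp$protein)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    occs[[j]] <- data.frame(
      peptide = substring(hp$protein, starts, starts + k - 1L),
      transcript_id = hp$transcript_id,
      haplotype = hp$haplotype,
      start = starts,
      stringsAsFactors = FALSE)
  }
  occurrences <- do.call(rbind, occs)
  if (is.null(occurrences)) {
    occurrences <- data.frame(peptide = character(0),
                              transcript_id = character(0),
                              haplotype = character(0), start = integer(0),
                              stringsAsFactors = FALSE)
  }
  structure(list(sample_id = proteome$sample_id, k = k,
                 peptides = unique(occurrences$peptide),
                 occurrences = occurrences),
            class = "peptidome")
}

#' @export
print.peptidome <- function(x, ...) {
  cat(sprintf("<peptidome %s: %d distinct %d-mers (%d occurrences)>\n",
              x$sample_id, length(x$peptides), x$k, nrow(x$occurrences)))
  invisible(x)
}

#' Subtract the donor peptidome from the recipient peptidome
#'
#' A peptide is a URP iff its string occurs somewhere in the recipient's
#' peptidome and nowhere in the donor's whole peptidome (all transcripts,
#' both haplotypes). Recipient occurrences of each URP are kept as
#' provenance; classes are assigned later by [classify_urps()].
#'
#' @param recipient_peptidome,donor_peptidome `peptidome` objects built
#'   with the same `k` and transcript set.
#' @return object of class `urp_set`: list with `peptides`,
#'   `occurrences`, `k`, `recipient_id`, `donor_id`.
#' @export
subtract_peptidomes <- function(recipient_peptidome, donor_peptidome) {
  if (recipient_peptidome$k != donor_peptidome$k) {
    stop("mismatched k: ", recipient_peptidome$k, " vs ", donor_peptidome$k)
  }
  urp <- setdiff(recipient_peptidome$peptides, donor_peptidome$peptides)
  occ <- recipient_peptidome$occurrences
  occ <- occ[occ$peptide %in% urp, , drop = FALSE]
  structure(list(peptides = urp, occurrences = occ,
                 k = recipient_peptidome$k,
                 recipient_id = recipient_peptidome$sample_id,
                 donor_id = donor_peptidome$sample_id),
            class = "urp_set")
}

#' @export
print.urp_set <- function(x, ...) {
  cat(sprintf("<urp_set %s minus %s: %d distinct %d-mers>\n",
              x$recipient_id, x$donor_id, length(x$peptides), x$k))
  invisible(x)
}

#' Classify URPs by causal polymorphism
#'
#' Assigns each URP its polymorphism class, causal variants and encoding
#' allele frequency. Causal variants are the recipient-side alleles whose
#' altered residues overlap the peptide window, minus alleles shared by
#' the donor. URPs with no recipient-side causal allele are
#' reference-encoded and explained on the donor side: a donor homozygous
#' for a truncating allele removes reference peptides
#' (`homozygous_frameshift_donor` / `homozygous_nonsense_donor`), and a
#' donor homozygous for a missense allele makes the recipient's
#' reference-encoded peptides unique (`single_nsSNP`/`adjacent_nsSNPs`
#' with the *reference* allele as the encoding allele, frequency
#' `1 - sum(f_alt)`). Anything unresolvable is `combination`, never
#' silently dropped.
#'
#' @param urps a `urp_set` from [subtract_peptidomes()].
#' @param recipient_proteome,donor_proteome the `individual_proteome`s
#'   the peptidomes came from.
#' @param cohort list with `variants`, `hapA`, `hapB`.
#' @return data.frame (class `urp_records`): `peptide`,
#'   `polymorphism_class`, `causal_variants` (comma-separated
#'   `id:allele`), `encoding_allele_frequency`.
#' @export
classify_urps <- function(urps, recipient_proteome, donor_proteome, cohort) {
  variants <- cohort$variants
  donor <- donor_proteome$sample_id
  don_a <- cohort$hapA[, donor, drop = FALSE]  # keeps variant rownames
  don_b <- cohort$hapB[, donor, drop = FALSE]
  vrow <- setNames(seq_len(nrow(variants)), variants$variant_id)
  k <- urps$k
  occ <- urps$occurrences
  occ_by_pep <- split(seq_len(nrow(occ)), occ$peptide)

  causal_types <- c("missense", "inframe_insertion", "inframe_deletion",
                    "frameshift_insertion", "frameshift_deletion",
                    "stop_lost")

  out <- vector("list", length(urps$peptides))
  for (p in seq_along(urps$peptides)) {
    pep <- urps$peptides[[p]]
    rows <- occ[occ_by_pep[[pep]], , drop = FALSE]
    causal <- list()      # keyed "id:allele"
    covering <- character(0)  # all covering alleles, incl. donor-shared
    donor_fallback <- NULL
    for (r in seq_len(nrow(rows))) {
      hp <- recipient_proteome$proteins[[
        paste0(rows$transcript_id[r], "|", rows$haplotype[r])]]
      s <- rows$start[r]
      vd <- hp$variants
      cov <- which(vd$expressed & !is.na(vd$prot_start) &
                   vd$prot_start <= s + k - 1L & vd$prot_end >= s &
                   vd$type %in% causal_types)
      if (length(cov)) {
        for (ci in cov) {
          vid <- vd$variant_id[ci]; ai <- vd$allele_index[ci]
          covering <- union(covering, paste0(vid, ":", ai))
          if (don_a[vid, 1L] == ai || don_b[vid, 1L] == ai) next  # shared
          causal[[paste0(vid, ":", ai)]] <-
            list(variant_id = vid, allele_index = ai, type = vd$type[ci],
                 f = variants$af[[vrow[[vid]]]][[ai]])
        }
      } else if (is.null(donor_fallback)) {
        # reference-encoded window: map to reference coordinates
        up <- vd$expressed & !is.na(vd$prot_end) & vd$prot_end < s
        rs <- s - sum(vd$codon_delta[up])
        donor_fallback <- donor_side_class(
          rows$transcript_id[r], rs, k, donor_proteome, variants, vrow)
      }
    }

    if (length(causal)) {
      types <- vapply(causal, `[[`, "", "type")
      fs <- vapply(causal, `[[`, 0, "f")
      n_var <- length(unique(vapply(causal, `[[`, "", "variant_id")))
      cls <-
        if (all(types == "missense")) {
          if (n_var >= 2L) "adjacent_nsSNPs" else "single_nsSNP"
        } else if (all(types %in% c("inframe_insertion", "inframe_deletion"))) {
          "inframe_indel"
        } else if (all(types %in% c("frameshift_insertion",
                                    "frameshift_deletion"))) {
          "frameshift_recipient"
        } else {
          "combination"
        }
      out[[p]] <- data.frame(
        peptide = pep, polymorphism_class = cls,
        causal_variants = paste(names(causal), collapse = ","),
        encoding_allele_frequency = min(fs),
        stringsAsFactors = FALSE)
    } else if (!is.null(donor_fallback)) {
      out[[p]] <- data.frame(
        peptide = pep, polymorphism_class = donor_fallback$class,
        causal_variants = donor_fallback$causal,
        encoding_allele_frequency = donor_fallback$f,
        stringsAsFactors = FALSE)
    } else {
      # e.g. a donor-shared allele whose donor copy is disrupted by a
      # second polymorphism: a genuine combination of causes; keep the
      # covering alleles as diagnostic provenance
      out[[p]] <- data.frame(
        peptide = pep, polymorphism_class = "combination",
        causal_variants = paste(covering, collapse = ","),
        encoding_allele_frequency = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(peptide = character(0),
                      polymorphism_class = character(0),
                      causal_variants = character(0),
                      encoding_allele_frequency = numeric(0),
                      stringsAsFactors = FALSE)
  }
  class(res) <- c("urp_records", "data.frame")
  res
}

# Donor-side explanation of a reference-encoded URP: examine the donor's
# two haplotype proteins of the transcript for expressed alleles whose
# reference-residue footprint overlaps the window [rs, rs + k - 1].
donor_side_class <- function(transcript_id, rs, k, donor_proteome,
                             variants, vrow) {
  hits <- list()
  both <- TRUE
  for (h in c("A", "B")) {
    hp <- donor_proteome$proteins[[paste0(transcript_id, "|", h)]]
    vd <- hp$variants
    ov <- which(vd$expressed & !is.na(vd$ref_start) &
                vd$ref_start <= rs + k - 1L & vd$ref_end >= rs)
    if (!length(ov)) { both <- FALSE; next }
    for (ci in ov) {
      hits[[paste0(vd$variant_id[ci], ":", vd$allele_index[ci])]] <-
        list(variant_id = vd$variant_id[ci], type = vd$type[ci])
    }
  }
  if (!both || !length(hits)) {
    return(list(class = "combination", causal = "", f = NA_real_))
  }
  types <- vapply(hits, `[[`, "", "type")
  vids <- unique(vapply(hits, `[[`, "", "variant_id"))
  causal <- paste(names(hits), collapse = ",")
  # the peptide is reference-encoded on every donor-side path, so the
  # encoding allele is always the reference allele
  if (all(types %in% c("frameshift_insertion", "frameshift_deletion"))) {
    cls <- "homozygous_frameshift_donor"
    f <- min(vapply(vids, function(v) 1 - sum(variants$af[[vrow[[v]]]]), 0))
  } else if (all(types == "nonsense")) {
    cls <- "homozygous_nonsense_donor"
    f <- min(vapply(vids, function(v) 1 - sum(variants$af[[vrow[[v]]]]), 0))
  } else if (all(types == "missense")) {
    cls <- if (length(vids) >= 2L) "adjacent_nsSNPs" else "single_nsSNP"
    # encoding allele is the reference allele
    f <- min(vapply(vids, function(v) 1 - sum(variants$af[[vrow[[v]]]]), 0))
  } else if (all(types %in% c("inframe_insertion", "inframe_deletion"))) {
    # donor homozygous in-frame indel: the reference-encoded junction
    # region is absent from the donor
    cls <- "inframe_indel"
    f <- min(vapply(vids, function(v) 1 - sum(variants$af[[vrow[[v]]]]), 0))
  } else {
    cls <- "combination"
    f <- NA_real_
  }
  list(class = cls, causal = causal, f = f)
}

#' Polymorphism-class and frequency profile of a pair's URPs
#'
#' Per-class URP counts/shares plus the allele-frequency bin shares of
#' nsSNP-encoded URPs (bins: f < 0.01, 0.01-0.1, 0.1-0.9, > 0.9).
#'
#' @param urp_records output of [classify_urps()].
#' @return object of class `polymorphism_profile`: list with `n`,
#'   `class_counts`, `class_shares`, `f_bin_counts`, `f_bin_shares`.
#' @export
profile_pair <- function(urp_records) {
  n <- nrow(urp_records)
  if (n == 0L) {
    warning("empty URP set: all shares reported as zero")
    zero_cls <- setNames(numeric(0), character(0))
    zero_bin <- setNames(rep(0, length(F_BIN_LABELS)), F_BIN_LABELS)
    return(structure(list(n = 0L, class_counts = zero_cls,
                          class_shares = zero_cls,
                          f_bin_counts = zero_bin, f_bin_shares = zero_bin),
                     class = "polymorphism_profile"))
  }
  cls <- table(urp_records$polymorphism_class)
  class_counts <- setNames(as.integer(cls), names(cls))
  ns <- urp_records[urp_records$polymorphism_class %in%
                      c("single_nsSNP", "adjacent_nsSNPs") &
                      !is.na(urp_records$encoding_allele_frequency), ,
                    drop = FALSE]
  bins <- factor(f_bin_of(ns$encoding_allele_frequency),
                 levels = F_BIN_LABELS)
  f_bin_counts <- setNames(as.integer(table(bins)), F_BIN_LABELS)
  structure(list(
    n = n,
    class_counts = class_counts,
    class_shares = class_counts / n,
    f_bin_counts = f_bin_counts,
    f_bin_shares = if (nrow(ns)) f_bin_counts / nrow(ns)
                   else setNames(rep(0, length(F_BIN_LABELS)), F_BIN_LABELS)),
    class = "polymorphism_profile")
}

#' @export
print.polymorphism_profile <- function(x, ...) {
  cat(sprintf("<polymorphism_profile: %d URPs>\n", x$n))
  if (x$n > 0L) {
    cat("  class shares:\n")
    for (nm in names(x$class_shares)) {
      cat(sprintf("    %-28s %5.1f%%\n", nm, 100 * x$class_shares[[nm]]))
    }
    cat("  nsSNP allele-frequency bins:\n")
    for (nm in names(x$f_bin_shares)) {
      cat(sprintf("    %-28s %5.1f%%\n", nm, 100 * x$f_bin_shares[[nm]]))
    }
  }
  invisible(x)
}

#' Saturation of the distinct-URP union over pairs
#'
#' For n = 1..N pairs (in the given order), the number of distinct URP
#' strings in the union of the first n pairs, overall and stratified by
#' encoding-allele frequency bin. Shuffle the input (under a seed) and
#' average externally for smoothed curves.
#'
#' @param urp_tables list of [classify_urps()] outputs (one per pair).
#' @return data.frame: `n_pairs`, `distinct_urps`, one column per
#'   frequency bin.
#' @export
saturation_curve <- function(urp_tables) {
  stopifnot(length(urp_tables) >= 1L)
  seen <- character(0)
  seen_bin <- setNames(vector("list", length(F_BIN_LABELS)), F_BIN_LABELS)
  for (b in F_BIN_LABELS) seen_bin[[b]] <- character(0)
  rows <- vector("list", length(urp_tables))
  for (i in seq_along(urp_tables)) {
    tab <- urp_tables[[i]]
    seen <- union(seen, tab$peptide)
    keep <- !is.na(tab$encoding_allele_frequency)
    bins <- f_bin_of(tab$encoding_allele_frequency[keep])
    peps <- tab$peptide[keep]
    for (b in F_BIN_LABELS) {
      seen_bin[[b]] <- union(seen_bin[[b]], peps[bins == b])
    }
    rows[[i]] <- c(n_pairs = i, distinct_urps = length(seen),
                   setNames(vapply(seen_bin, length, 1L), F_BIN_LABELS))
  }
  as.data.frame(do.call(rbind, rows))
}

#' Intersect URPs with an external peptide list
#'
#' Exact string intersection with, e.g., an MS-identified peptide list;
#' matched records keep their provenance, and an encoding-allele
#' frequency histogram of the matches is attached.
#'
#' @param urp_records output of [classify_urps()].
#' @param peptide_list character vector of k-mers (entries of the wrong
#'   length are skipped and counted).
#' @param k expected peptide length.
#' @return list with `matches` (subset of `urp_records`),
#'   `f_histogram` (counts per frequency bin), `n_skipped`.
#' @export
intersect_with_peptide_list <- function(urp_records, peptide_list, k = 9L) {
  ok <- nchar(peptide_list) == k
  n_skipped <- sum(!ok)
  lst <- unique(peptide_list[ok])
  matches <- urp_records[urp_records$peptide %in% lst, , drop = FALSE]
  keep <- !is.na(matches$encoding_allele_frequency)
  bins <- factor(f_bin_of(matches$encoding_allele_frequency[keep]),
                 levels = F_BIN_LABELS)
  list(matches = matches,
       f_histogram = setNames(as.integer(table(bins)), F_BIN_LABELS),
       n_skipped = n_skipped)
}
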