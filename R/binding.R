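# PSSM-based MHC class I binding: additive position-specific scoring,
# background-percentile threshold calibration (strong = top 0.5%, weak =
# top 2% of a random background by default), two-predictor consensus
# filtering, and the co-dominant/dominant nsSNP statistic.
#
# The published neural-network predictors are not reimplemented: any
# predictor exposing peptide -> score can be plugged in; the additive
# PSSM scorer shipped here is the reference implementation.

#' Construct a position-specific scoring matrix
#'
#' @param allele_name HLA-style allele label (e.g. `"HLA-A*02:01"`).
#' @param weights numeric k x 20 matrix; columns must be named by the 20
#'   standard amino acids (any order; stored in canonical order).
#' @param provenance free-text origin note.
#' @return object of class `pssm`.
#' @export
pssm <- function(allele_name, weights, provenance = "synthetic") {
  stopifnot(is.matrix(weights), ncol(weights) == 20)
  if (!setequal(colnames(weights), AA_ALPHABET)) {
    stop("weights must cover all 20 standard residues")
  }
  weights <- weights[, AA_ALPHABET, drop = FALSE]
  structure(list(allele_name = as.character(allele_name),
                 weights = weights,
                 k = nrow(weights),
                 provenance = provenance),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm %s: k=%d (%s)>\n", x$allele_name, x$k, x$provenance))
  invisible(x)
}

#' Write a PSSM to a plain-text matrix file
#'
#' Format: `# allele <name>` comment line, then a tab-separated table
#' with a `pos` column and one column per residue.
#'
#' @param x a [pssm()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_pssm <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# allele ", x$allele_name), con)
  df <- data.frame(pos = seq_len(x$k), x$weights, check.names = FALSE)
  write.table(format(df, digits = 10), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a PSSM from a plain-text matrix file
#'
#' @param path file written by [write_pssm()] (or any matrix in the same
#'   layout).
#' @return a [pssm()].
#' @export
read_pssm <- function(path) {
  lines <- readLines(path)
  allele <- "unknown"
  hdr <- grep("^# allele ", lines, value = TRUE)
  if (length(hdr)) allele <- sub("^# allele ", "", hdr[[1L]])
  df <- read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                   sep = "\t", check.names = FALSE)
  w <- as.matrix(df[, setdiff(names(df), "pos"), drop = FALSE])
  pssm(allele, w, provenance = path)
}

#' Score peptides against a PSSM
#'
#' Additive position-specific score: the sum over positions of the
#' weight of the residue observed at that position.
#'
#' @param x a [pssm()].
#' @param peptides character vector of k-mers over the 20 standard
#'   residues.
#' @return numeric scores, one per peptide.
#' @export
score_peptides <- function(x, peptides) {
  if (!length(peptides)) return(numeric(0))
  if (any(nchar(peptides) != x$k)) {
    stop("peptide length must equal the PSSM length k = ", x$k)
  }
  scores <- numeric(length(peptides))
  for (pos in seq_len(x$k)) {
    res <- substr(peptides, pos, pos)
    bad <- which(!res %in% AA_ALPHABET)
    if (length(bad)) {
      stop(sprintf("nonstandard residue '%s' at position %d of peptide %d",
                   res[bad[[1L]]], pos, bad[[1L]]))
    }
    scores <- scores + x$weights[pos, res]
  }
  unname(scores)
}

#' Calibrate strong/weak binder score cutoffs on a background
#'
#' Percentile calibration against peptides randomly drawn from the
#' reference proteome: the strong cutoff is the score of the
#' `ceiling(p_strong * N)`-th highest background peptide (analogously for
#' weak), so the fraction of background at or above the cutoff never
#' exceeds `p + 1/N`. A peptide tied with the cutoff counts as a binder.
#'
#' @param x a [pssm()].
#' @param background_peptides character vector of background k-mers;
#'   must contain at least `1/p_strong` peptides.
#' @param p_strong,p_weak target background fractions for strong and
#'   weak binders (defaults 0.005 and 0.02).
#' @return object of class `threshold_calibration`.
#' @export
calibrate_thresholds <- function(x, background_peptides, p_strong = 0.005,
                                 p_weak = 0.02) {
  stopifnot(p_strong < p_weak, p_strong > 0, p_weak < 1)
  n <- length(background_peptides)
  if (n < 1 / p_strong) {
    stop("background too small: need at least ", ceiling(1 / p_strong),
         " peptides, have ", n)
  }
  sc <- sort(score_peptides(x, background_peptides), decreasing = TRUE)
  # the m-th highest background score; when a tie block straddles rank m,
  # move up to the next distinct score (stricter) so the at-or-above
  # fraction never exceeds p + 1/n
  cut_at <- function(p) {
    m <- ceiling(p * n)
    v <- sc[[m]]
    if (sum(sc >= v) > m) {
      higher <- sc[sc > v]
      v <- if (length(higher)) min(higher) else Inf
    }
    v
  }
  strong_cutoff <- cut_at(p_strong)
  weak_cutoff <- cut_at(p_weak)
  structure(list(allele_name = x$allele_name,
                 strong_cutoff = strong_cutoff,
                 weak_cutoff = weak_cutoff,
                 background_size = n,
                 p_strong = p_strong, p_weak = p_weak),
            class = "threshold_calibration")
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf(
    "<threshold_calibration %s: SB >= %.4g (top %.3g), WB >= %.4g (top %.3g), N=%d>\n",
    x$allele_name, x$strong_cutoff, x$p_strong, x$weak_cutoff, x$p_weak,
    x$background_size))
  invisible(x)
}

#' Classify peptides as strong/weak/non-binders
#'
#' Pure function of (score, calibration): `SB` when score is at or above
#' the strong cutoff, else `WB` at or above the weak cutoff, else
#' `non-binder`. By convention SB is a subset of WB: use
#' `category != "non-binder"` for the weak-or-better set.
#'
#' @param peptides character vector of k-mers.
#' @param x a [pssm()].
#' @param calibration a matching [calibrate_thresholds()] result.
#' @return data.frame (class `binding_calls`): `peptide`, `allele_name`,
#'   `score`, `category`.
#' @export
classify_binders <- function(peptides, x, calibration) {
  if (!identical(calibration$allele_name, x$allele_name)) {
    stop("calibration allele does not match PSSM allele")
  }
  score <- score_peptides(x, peptides)
  category <- ifelse(score >= calibration$strong_cutoff, "SB",
                     ifelse(score >= calibration$weak_cutoff, "WB",
                            "non-binder"))
  out <- data.frame(peptide = peptides, allele_name = x$allele_name,
                    score = score, category = category,
                    stringsAsFactors = FALSE)
  class(out) <- c("binding_calls", "data.frame")
  out
}

# peptides meeting a stringency level in one call set
calls_at_level <- function(calls, level = c("SB", "WB")) {
  level <- match.arg(level)
  if (level == "SB") calls$peptide[calls$category == "SB"]
  else calls$peptide[calls$category != "non-binder"]
}

#' Consensus of two predictors
#'
#' Peptides called at the requested stringency by BOTH predictors (weak
#' includes strong, so the SB overlap is a subset of the WB overlap).
#' Both call sets must cover the same peptide universe.
#'
#' @param calls1,calls2 `binding_calls` over identical peptide sets.
#' @param level `"SB"` or `"WB"`.
#' @return character vector of consensus peptides.
#' @export
consensus_filter <- function(calls1, calls2, level = c("SB", "WB")) {
  level <- match.arg(level)
  d <- length(union(setdiff(calls1$peptide, calls2$peptide),
                    setdiff(calls2$peptide, calls1$peptide)))
  if (d > 0) {
    stop("call sets cover different peptide universes (symmetric difference: ",
         d, " peptides)")
  }
  intersect(calls_at_level(calls1, level), calls_at_level(calls2, level))
}

#' Allelic counterpart peptides of a biallelic nsSNP
#'
#' Builds, on an otherwise reference background, the k-mer windows
#' covering the substituted residue for each allele of one missense SNV:
#' the reference-encoded and alternate-encoded peptide sets whose joint
#' presentation defines co-dominance.
#'
#' @param transcript a `reference_transcript`.
#' @param variants a [variant_table()].
#' @param i row index of the missense SNV.
#' @param allele_index alternate allele index.
#' @param k peptide length.
#' @return list with `ref` and `alt` character vectors.
#' @export
allelic_peptides <- function(transcript, variants, i, allele_index = 1L,
                             k = 9L) {
  ty <- classify_variant(transcript, variants, i, allele_index)
  if (ty != "missense") stop("variant is not missense on this transcript: ", ty)
  p <- project_allele(transcript, variants, i, allele_index)
  ref_prot <- reference_protein(transcript)
  alleles <- integer(nrow(variants))
  alleles[[i]] <- allele_index
  hp <- build_haplotype_protein(transcript, variants, alleles)
  alt_prot <- hp$protein
  codon <- p$cds_off %/% 3L + 1L
  windows <- function(prot) {
    L <- nchar(prot)
    if (L < k) return(character(0))
    lo <- max(1L, codon - k + 1L)
    hi <- min(codon, L - k + 1L)
    if (hi < lo) return(character(0))
    starts <- lo:hi
    unique(substring(prot, starts, starts + k - 1L))
  }
  list(ref = windows(ref_prot), alt = windows(alt_prot))
}

#' Co-dominant to dominant nsSNP ratio
#'
#' An nsSNP is *co-dominant* when at least one peptide from EACH allelic
#' variant passes the binding level, *dominant* when only one side
#' passes. Optionally removes peptides containing arginine or lysine
#' before counting (substitutions to R/K alter proteasomal cleavage and
#' inflate one-sided presentation).
#'
#' @param allelic_sets list (one entry per nsSNP) of lists with `ref`
#'   and `alt` peptide vectors, e.g. from [allelic_peptides()].
#' @param binder_peptides character vector of peptides passing the
#'   binding level under consideration.
#' @param exclude_RK drop peptides containing R or K before counting.
#' @return list with `ratio` (`Inf` when no dominant nsSNP exists),
#'   `n_codominant`, `n_dominant`, `n_silent` (neither side presented).
#' @export
codominance_ratio <- function(allelic_sets, binder_peptides,
                              exclude_RK = FALSE) {
  n_co <- n_dom <- n_sil <- 0L
  for (s in allelic_sets) {
    ref <- s$ref; alt <- s$alt
    if (exclude_RK) {
      ref <- ref[!grepl("[RK]", ref)]
      alt <- alt[!grepl("[RK]", alt)]
    }
    ref_hit <- any(ref %in% binder_peptides)
    alt_hit <- any(alt %in% binder_peptides)
    if (ref_hit && alt_hit) n_co <- n_co + 1L
    else if (ref_hit || alt_hit) n_dom <- n_dom + 1L
    else n_sil <- n_sil + 1L
  }
  list(ratio = if (n_dom == 0L) Inf else n_co / n_dom,
       n_codominant = n_co, n_dominant = n_dom, n_silent = n_sil)
}
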