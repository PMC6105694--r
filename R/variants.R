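# Variant + phased genotype model. Variants are kept in a data.frame with
# list columns for alternate alleles and their population frequencies
# (multiallelic sites stay one row, decomposed per alternate allele for
# frequency and URP attribution). Phased genotypes are two integer
# matrices (variant x sample): haplotype A and haplotype B allele indices,
# 0 = reference.

#' Construct a variant table
#'
#' @param variant_id character vector.
#' @param chrom character vector.
#' @param pos 1-based genomic position of the first REF base (VCF
#'   convention); the 0-based internal coordinate is `pos - 1`.
#' @param ref REF allele strings.
#' @param alt list of character vectors (alternate alleles per site).
#' @param af list of numeric vectors (per-alternate-allele population
#'   frequency, each in `[0, 1]`).
#' @return data.frame of class `variant_table` with list columns
#'   `alt` and `af`, row names = `variant_id`.
#' @export
variant_table <- function(variant_id, chrom, pos, ref, alt, af) {
  if (!is.list(alt)) alt <- as.list(alt)
  if (!is.list(af)) af <- as.list(af)
  stopifnot(length(variant_id) == length(chrom),
            length(chrom) == length(pos),
            length(pos) == length(ref),
            length(ref) == length(alt),
            length(alt) == length(af))
  if (any(!nzchar(ref)) || any(vapply(alt, function(a) any(!nzchar(a)), TRUE))) {
    stop("empty REF or ALT allele")
  }
  fs <- unlist(af)
  if (length(fs) && (any(fs < 0) || any(fs > 1))) {
    stop("allele frequency outside [0, 1]")
  }
  df <- data.frame(variant_id = as.character(variant_id),
                   chrom = as.character(chrom),
                   pos = as.integer(pos),
                   ref = toupper(as.character(ref)),
                   stringsAsFactors = FALSE)
  df$alt <- lapply(alt, toupper)
  df$af <- lapply(af, as.numeric)
  rownames(df) <- df$variant_id
  class(df) <- c("variant_table", "data.frame")
  df
}

# frequency of one alternate allele (index >= 1) of one variant row
allele_frequency <- function(variants, variant_id, allele_index) {
  variants$af[[match(variant_id, variants$variant_id)]][[allele_index]]
}

#' Read phased variants and genotypes from a VCF
#'
#' Reads a VCF 4.x with phased `GT` fields, applies the coding-region
#' input filters, and returns the variant table plus phased haplotype
#' matrices. Filters applied (counts recorded in the attached log):
#' * structural/symbolic alternate alleles are excluded;
#' * variants whose REF span is not fully contained within a single exon
#'   of at least one supplied transcript are dropped (`beyond_exon`).
#'
#' Allele frequency precedence: the INFO key named by `af_key` when
#' present, otherwise computed from the cohort's genotype columns; the
#' source used is recorded in the log.
#'
#' @param vcf_path path to the VCF (plain text or bgzipped).
#' @param transcripts list of `reference_transcript` used for the exon
#'   containment filter.
#' @param af_key INFO key carrying per-alternate allele frequencies.
#' @param unphased `"error"` (default) rejects a file with unphased
#'   genotypes; `"assign"` assigns phase arbitrarily with a warning.
#' @return list with `variants` (a [variant_table()]), `hapA`, `hapB`
#'   (integer matrices, variant x sample), `samples`, and `log`.
#' @export
read_variants <- function(vcf_path, transcripts, af_key = "AF",
                          unphased = c("error", "assign")) {
  unphased <- match.arg(unphased)
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcf@fix  # keep the INFO column (getFIX drops it)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt_raw)
  n <- nrow(fix)
  log <- new_log()

  keep <- logical(n)
  ids <- character(n)
  alt_list <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    if (any(grepl("[<>\\[\\]]", alts))) {
      log <- bump(log, "structural")
      next
    }
    ref <- fix[i, "REF"]
    start0 <- as.integer(fix[i, "POS"]) - 1L
    contained <- any(vapply(transcripts, function(tr) {
      tr$chromosome == fix[i, "CHROM"] &&
        !is.na(project_span(tr, start0, nchar(ref)))
    }, TRUE))
    if (!contained) {
      log <- bump(log, "beyond_exon")
      next
    }
    keep[i] <- TRUE
    alt_list[[i]] <- alts
    ids[i] <- if (!is.na(fix[i, "ID"]) && fix[i, "ID"] != ".") fix[i, "ID"]
              else paste0(fix[i, "CHROM"], "_", fix[i, "POS"])
  }

  idx <- which(keep)
  if (anyDuplicated(ids[idx])) {
    ids[idx] <- make.unique(ids[idx], sep = "_dup")
  }

  # phased genotype parsing
  parse_gt <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(c(0L, 0L))
    if (grepl("/", g, fixed = TRUE)) {
      if (unphased == "error") {
        stop("unphased genotype encountered: '", g,
             "' (set unphased = \"assign\" to phase arbitrarily)")
      }
      g <- sub("/", "|", g, fixed = TRUE)
    }
    as.integer(strsplit(g, "|", fixed = TRUE)[[1L]][1:2])
  }
  had_unphased <- any(grepl("/", gt_raw[idx, , drop = FALSE], fixed = TRUE))
  if (had_unphased && unphased == "assign") {
    warning("unphased genotypes present: phase assigned arbitrarily")
    log <- bump(log, "unphased_assigned")
  }

  hapA <- matrix(0L, length(idx), length(samples),
                 dimnames = list(ids[idx], samples))
  hapB <- hapA
  for (j in seq_along(idx)) {
    for (s in seq_along(samples)) {
      ab <- parse_gt(gt_raw[idx[j], s])
      hapA[j, s] <- ab[[1L]]
      hapB[j, s] <- ab[[2L]]
    }
  }

  # allele frequencies: INFO af_key, else cohort-computed
  info <- fix[, "INFO"]
  af_from_info <- function(i, n_alt) {
    m <- regmatches(info[i],
                    regexpr(paste0("(^|;)", af_key, "=[^;]+"), info[i]))
    if (!length(m)) return(NULL)
    vals <- as.numeric(strsplit(sub(paste0(".*", af_key, "="), "", m),
                                ",", fixed = TRUE)[[1L]])
    if (length(vals) != n_alt) return(NULL)
    vals
  }
  af_list <- vector("list", length(idx))
  used_info <- FALSE
  used_cohort <- FALSE
  for (j in seq_along(idx)) {
    i <- idx[j]
    n_alt <- length(alt_list[[i]])
    vals <- af_from_info(i, n_alt)
    if (!is.null(vals)) {
      used_info <- TRUE
    } else {
      used_cohort <- TRUE
      n_chr <- 2L * length(samples)
      vals <- vapply(seq_len(n_alt), function(a) {
        (sum(hapA[j, ] == a) + sum(hapB[j, ] == a)) / n_chr
      }, numeric(1))
    }
    af_list[[j]] <- vals
  }
  if (used_info) log <- bump(log, "af_from_info")
  if (used_cohort) log <- bump(log, "af_from_cohort")
  log <- bump(log, "retained", length(idx))

  variants <- variant_table(ids[idx], fix[idx, "CHROM"],
                            as.integer(fix[idx, "POS"]), fix[idx, "REF"],
                            alt_list[idx], af_list)
  list(variants = variants, hapA = hapA, hapB = hapB,
       samples = samples, log = log)
}

#' Write a phased multi-sample VCF
#'
#' Emits a minimal VCF 4.2 with phased `GT` columns and per-alternate
#' `AF` INFO values; [read_variants()] round-trips the result.
#'
#' @param variants a [variant_table()].
#' @param hapA,hapB integer matrices (variant x sample), allele indices.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(variants, hapA, hapB, path) {
  stopifnot(nrow(variants) == nrow(hapA), identical(dim(hapA), dim(hapB)))
  samples <- colnames(hapA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  for (i in seq_len(nrow(variants))) {
    gts <- paste0(hapA[i, ], "|", hapB[i, ])
    line <- paste(c(variants$chrom[i], variants$pos[i],
                    variants$variant_id[i], variants$ref[i],
                    paste(variants$alt[[i]], collapse = ","), ".", ".",
                    paste0("AF=", paste(signif(variants$af[[i]], 8),
                                        collapse = ",")),
                    "GT", gts), collapse = "\t")
    writeLines(line, con)
  }
  invisible(path)
}

#' Count alternate alleles unique to the recipient
#'
#' Number of alternate alleles present on at least one recipient
#' haplotype and absent from both donor haplotypes — the variant-level
#' disparity between the two genomes of a pair.
#'
#' @param recipient,donor sample ids (columns of the haplotype matrices).
#' @param variants a [variant_table()].
#' @param hapA,hapB phased haplotype matrices from [read_variants()] or
#'   the cohort simulator.
#' @return integer count.
#' @export
count_unique_recipient_variants <- function(recipient, donor, variants,
                                            hapA, hapB) {
  for (s in c(recipient, donor)) {
    if (!s %in% colnames(hapA)) stop("sample not genotyped: ", s)
  }
  ra <- hapA[, recipient]; rb <- hapB[, recipient]
  da <- hapA[, donor];     db <- hapB[, donor]
  max_alt <- max(vapply(variants$alt, length, 1L))
  total <- 0L
  for (a in seq_len(max_alt)) {
    valid <- vapply(variants$alt, length, 1L) >= a
    total <- total + sum(valid & (ra == a | rb == a) & da != a & db != a)
  }
  total
}

#' Randomly pair cohort samples
#'
#' Assigns each sample to at most one (recipient, donor) pair, mirroring
#' a random virtual-pairing design over a cohort.
#'
#' @param sample_ids character vector of available samples.
#' @param n_pairs number of pairs (requires `2 * n_pairs` samples).
#' @param relationship tag attached to every pair.
#' @return data.frame with columns `recipient_id`, `donor_id`,
#'   `relationship`.
#' @export
make_pairs <- function(sample_ids, n_pairs,
                       relationship = c("unrelated", "sibling")) {
  relationship <- match.arg(relationship)
  if (length(sample_ids) < 2L * n_pairs) {
    stop("need ", 2L * n_pairs, " samples for ", n_pairs,
         " disjoint pairs, have ", length(sample_ids))
  }
  chosen <- sample(sample_ids, 2L * n_pairs)
  data.frame(recipient_id = chosen[seq_len(n_pairs)],
             donor_id = chosen[n_pairs + seq_len(n_pairs)],
             relationship = relationship,
             stringsAsFactors = FALSE)
}
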