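# Shared low-level helpers: nucleotide/protein alphabets, reverse
# complement, CDS translation. These back every downstream module.

#' @importFrom stats integrate optimize rbinom runif setNames uniroot sd
#' @importFrom utils read.table write.table
NULL

# 20 standard amino acids, fixed column order used by all PSSMs.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse complement of nucleotide strings
#'
#' @param x character vector of A/C/G/T strings.
#' @return character vector of the same length.
#' @keywords internal
revcomp <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Translate a coding sequence
#'
#' Translates `cds` with the standard genetic code, starting at offset 0.
#' Translation stops at the first in-frame stop codon; the stop symbol is
#' never included. A trailing incomplete codon is discarded.
#'
#' @param cds nucleotide string (A/C/G/T), assumed to start at the start
#'   codon position of the (possibly mutated) transcript.
#' @return list with `protein` (amino-acid string) and `truncated`
#'   (`TRUE` when the first stop precedes the end of the sequence, or when
#'   the reading frame ran off the end without reaching a stop codon).
#' @examples
#' translate_cds("ATGGATTGCTAA")  # MDC, truncated = FALSE
#' translate_cds("ATGGATTGATGC")  # MD,  truncated = TRUE (internal TGA)
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1)
  if (!nzchar(cds)) stop("empty CDS")
  bad <- regexpr("[^ACGT]", cds)
  if (bad > 0) {
    stop(sprintf("non-ACGT character '%s' at offset %d",
                 substr(cds, bad, bad), bad - 1L))
  }
  n_codon <- nchar(cds) %/% 3L
  if (n_codon == 0L) return(list(protein = "", truncated = TRUE))
  starts <- seq(1L, by = 3L, length.out = n_codon)
  codons <- substring(cds, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stop_i <- which(aa == "*")
  if (length(stop_i)) {
    first <- stop_i[[1L]]
    protein <- paste(aa[seq_len(first - 1L)], collapse = "")
    # truncated unless the stop codon is the final complete codon and the
    # sequence ends exactly there
    truncated <- (first < n_codon) || (nchar(cds) %% 3L != 0L)
  } else {
    protein <- paste(aa, collapse = "")
    truncated <- TRUE  # frame ran off the end without a stop
  }
  list(protein = protein, truncated = truncated)
}

# internal: named counter bookkeeping used by readers/filters
new_log <- function() integer(0)
bump <- function(log, key, by = 1L) {
  if (is.null(log[key]) || is.na(log[key])) log[key] <- 0L
  log[key] <- log[key] + as.integer(by)
  log
}

#' Write a run log as key-value text
#'
#' @param counters named integer/numeric vector.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_run_log <- function(counters, path) {
  lines <- sprintf("%s\t%s", names(counters), as.character(counters))
  writeLines(lines, path)
  invisible(path)
}
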