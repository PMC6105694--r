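# Reference transcript model: coding sequences with genomic exon
# coordinates and strand, plus the input-filtering rules applied when
# reading them (internal-stop exclusion, frame checks).
#
# Coordinate convention: annotation files and all internal arithmetic use
# 0-based half-open genomic intervals; VCF positions (1-based) are
# converted exactly once, at the VCF reader boundary.

#' Construct a reference transcript
#'
#' @param transcript_id character scalar.
#' @param chromosome character scalar.
#' @param strand `"+"` or `"-"`.
#' @param exons integer matrix with columns `start`, `end` (0-based
#'   half-open, sorted by genomic position, non-overlapping).
#' @param cds_sequence spliced coding sequence in coding-strand
#'   orientation, starting at the annotated start codon. May include the
#'   terminal stop codon.
#' @param validate check invariants (length divisible by 3, A/C/G/T only,
#'   no internal in-frame stop codon, exon widths summing to the CDS
#'   length).
#' @return an object of class `reference_transcript`.
#' @export
reference_transcript <- function(transcript_id, chromosome, strand, exons,
                                 cds_sequence, validate = TRUE) {
  if (is.null(dim(exons))) exons <- matrix(exons, ncol = 2, byrow = TRUE)
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  tr <- structure(
    list(transcript_id = as.character(transcript_id),
         chromosome = as.character(chromosome),
         strand = match.arg(strand, c("+", "-")),
         exons = exons,
         cds_sequence = toupper(as.character(cds_sequence))),
    class = "reference_transcript")
  if (validate) {
    reason <- transcript_invalid_reason(tr)
    if (!is.null(reason)) {
      stop(sprintf("invalid transcript %s: %s", transcript_id, reason))
    }
  }
  tr
}

# Returns NULL for a valid transcript, else a short reason code.
transcript_invalid_reason <- function(tr) {
  cds <- tr$cds_sequence
  if (nchar(cds) < 3L) return("short_cds")
  if (nchar(cds) %% 3L != 0L) return("not_multiple_of_3")
  if (grepl("[^ACGT]", cds)) return("bad_alphabet")
  ex <- tr$exons
  if (nrow(ex) > 1L) {
    if (is.unsorted(ex[, 1L])) return("unsorted_exons")
    if (any(ex[-1L, 1L] < ex[-nrow(ex), 2L])) return("overlapping_exons")
  }
  if (any(ex[, 2L] <= ex[, 1L])) return("empty_exon")
  if (sum(ex[, 2L] - ex[, 1L]) != nchar(cds)) return("exon_length_mismatch")
  n_codon <- nchar(cds) %/% 3L
  starts <- seq(1L, by = 3L, length.out = n_codon)
  codons <- substring(cds, starts, starts + 2L)
  stops <- which(codons %in% STOP_CODONS)
  if (any(stops < n_codon)) return("internal_stop")
  NULL
}

#' @export
print.reference_transcript <- function(x, ...) {
  cat(sprintf("<reference_transcript %s: %s%s, %d exon(s), CDS %d nt>\n",
              x$transcript_id, x$chromosome, x$strand, nrow(x$exons),
              nchar(x$cds_sequence)))
  invisible(x)
}

#' Reference protein of a transcript
#'
#' Translation of the CDS up to (and excluding) the terminal stop codon.
#'
#' @param transcript a `reference_transcript`.
#' @return amino-acid string.
#' @export
reference_protein <- function(transcript) {
  translate_cds(transcript$cds_sequence)$protein
}

#' Project a genomic span onto a transcript CDS
#'
#' Maps the 0-based half-open genomic span `[start0, start0 + width)` to a
#' 0-based offset in the spliced CDS (transcription order). The span must
#' be fully contained within a single exon; spans crossing an exon
#' boundary (or outside all exons) return `NA`, mirroring the "beyond
#' exon boundaries" input filter.
#'
#' @param transcript a `reference_transcript`.
#' @param start0 0-based genomic start.
#' @param width span width in bases (>= 1).
#' @return integer CDS offset, or `NA_integer_`.
#' @export
project_span <- function(transcript, start0, width) {
  ex <- transcript$exons
  hit <- which(start0 >= ex[, 1L] & (start0 + width) <= ex[, 2L])
  if (!length(hit)) return(NA_integer_)
  i <- hit[[1L]]
  before <- if (i > 1L) sum(ex[seq_len(i - 1L), 2L] - ex[seq_len(i - 1L), 1L]) else 0L
  plus_off <- before + (start0 - ex[i, 1L])
  total <- sum(ex[, 2L] - ex[, 1L])
  if (transcript$strand == "+") as.integer(plus_off)
  else as.integer(total - plus_off - width)
}

# Inverse of project_span: map a CDS span [cds_off, cds_off + width) back
# to a 0-based genomic start, or NA if the span crosses an exon junction.
unproject_span <- function(transcript, cds_off, width) {
  ex <- transcript$exons
  total <- sum(ex[, 2L] - ex[, 1L])
  plus_off <- if (transcript$strand == "+") cds_off else total - cds_off - width
  cum <- cumsum(ex[, 2L] - ex[, 1L])
  before <- c(0L, cum[-length(cum)])
  i <- which(plus_off >= before & plus_off + width <= cum)
  if (!length(i)) return(NA_integer_)
  i <- i[[1L]]
  as.integer(ex[i, 1L] + (plus_off - before[i]))
}

#' Read reference transcripts from FASTA + annotation
#'
#' The annotation is a tab-separated table with header columns
#' `transcript_id`, `chromosome`, `strand`, `exon_start`, `exon_end`
#' (one row per exon, 0-based half-open genomic coordinates). Sequences
#' are read from the FASTA by transcript id.
#'
#' Transcripts failing the invariants (in particular, any with an
#' internal in-frame stop codon) are dropped and recorded in the
#' attached log, as are transcripts present in the annotation but absent
#' from the FASTA.
#'
#' @param fasta_path path to the CDS FASTA.
#' @param annotation_path path to the exon annotation table.
#' @return list of `reference_transcript` objects, with attributes
#'   `log` (named drop counters) and `dropped` (data.frame id/reason).
#' @export
read_transcripts <- function(fasta_path, annotation_path) {
  if (!file.exists(fasta_path)) stop("FASTA not found: ", fasta_path)
  if (!file.exists(annotation_path)) stop("annotation not found: ", annotation_path)
  ann <- read.table(annotation_path, header = TRUE, sep = "\t",
                    colClasses = c("character", "character", "character",
                                   "integer", "integer"),
                    stringsAsFactors = FALSE)
  need <- c("transcript_id", "chromosome", "strand", "exon_start", "exon_end")
  if (!all(need %in% names(ann))) {
    stop("malformed annotation: expected columns ",
         paste(need, collapse = ", "))
  }
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  seq_map <- setNames(as.character(seqs), names(seqs))

  log <- new_log()
  dropped <- list()
  out <- list()
  if (nrow(ann) == 0L) {
    warning("empty annotation: no transcripts read")
  }
  for (id in unique(ann$transcript_id)) {
    rows <- ann[ann$transcript_id == id, , drop = FALSE]
    if (!id %in% names(seq_map)) {
      log <- bump(log, "missing_sequence")
      dropped[[length(dropped) + 1L]] <- c(id, "missing_sequence")
      next
    }
    ex <- cbind(rows$exon_start, rows$exon_end)
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    tr <- reference_transcript(id, rows$chromosome[[1L]], rows$strand[[1L]],
                               ex, seq_map[[id]], validate = FALSE)
    reason <- transcript_invalid_reason(tr)
    if (!is.null(reason)) {
      log <- bump(log, reason)
      dropped[[length(dropped) + 1L]] <- c(id, reason)
      next
    }
    out[[length(out) + 1L]] <- tr
  }
  log <- bump(log, "retained", length(out))
  dropped <- if (length(dropped)) {
    as.data.frame(do.call(rbind, dropped), stringsAsFactors = FALSE) |>
      setNames(c("transcript_id", "reason"))
  } else {
    data.frame(transcript_id = character(0), reason = character(0))
  }
  structure(out, log = log, dropped = dropped)
}

#' Write transcripts to FASTA + annotation
#'
#' Inverse of [read_transcripts()]; a round trip preserves all fields.
#'
#' @param transcripts list of `reference_transcript`.
#' @param fasta_path,annotation_path output paths.
#' @return invisibly, the two paths.
#' @export
write_transcripts <- function(transcripts, fasta_path, annotation_path) {
  seqs <- Biostrings::DNAStringSet(
    setNames(vapply(transcripts, `[[`, "", "cds_sequence"),
             vapply(transcripts, `[[`, "", "transcript_id")))
  Biostrings::writeXStringSet(seqs, fasta_path)
  rows <- do.call(rbind, lapply(transcripts, function(tr) {
    data.frame(transcript_id = tr$transcript_id,
               chromosome = tr$chromosome,
               strand = tr$strand,
               exon_start = tr$exons[, 1L],
               exon_end = tr$exons[, 2L],
               stringsAsFactors = FALSE)
  }))
  write.table(rows, annotation_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fasta_path, annotation_path))
}
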