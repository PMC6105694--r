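# End-to-end orchestration: per-pair URP analysis (proteomes ->
# peptidomes -> subtraction -> classification -> mismatch model ->
# optional binding panel) and cohort-level aggregation (means, distinct
# union, saturation, observed-vs-model mismatch fractions, sibling fold
# comparison). Tables are written tab-separated with a header row and
# "." for missing values.

#' Analyse one donor-recipient pair
#'
#' Runs the whole prediction chain for one virtual transplantation pair:
#' both diploid proteomes, k-mer peptidomes, donor subtraction, URP
#' classification with encoding-allele frequencies, mismatch
#' probabilities, and (optionally) MHC-binding calls for a panel of
#' HLA alleles.
#'
#' @param transcripts list of `reference_transcript`.
#' @param cohort list with `variants`, `hapA`, `hapB` (from
#'   [read_variants()], [generate_cohort()] or
#'   [generate_sibling_cohort()]).
#' @param recipient,donor sample ids.
#' @param relationship `"unrelated"` or `"sibling"` — selects the
#'   mismatch model.
#' @param k peptide length.
#' @param pmm_thresholds therapeutic mismatch-probability tiers.
#' @param panel optional named list (one entry per HLA allele) of lists
#'   of predictors, each `list(pssm = , calibration = )`; two predictors
#'   per allele enable the consensus columns.
#' @return object of class `pair_analysis`.
#' @export
run_pair_analysis <- function(transcripts, cohort, recipient, donor,
                              relationship = c("unrelated", "sibling"),
                              k = 9L, pmm_thresholds = c(0.1, 0.2),
                              panel = NULL) {
  relationship <- match.arg(relationship)
  if (identical(recipient, donor)) stop("recipient and donor must differ")
  rp <- build_proteome(recipient, transcripts, cohort)
  dp <- build_proteome(donor, transcripts, cohort)
  rpep <- extract_peptides(rp, k)
  dpep <- extract_peptides(dp, k)
  urps <- subtract_peptidomes(rpep, dpep)
  rec <- classify_urps(urps, rp, dp, cohort)
  rec <- assign_pmm(rec, relationship, pmm_thresholds)
  prof <- if (nrow(rec)) profile_pair(rec)
          else suppressWarnings(profile_pair(rec))
  n_uv <- count_unique_recipient_variants(recipient, donor, cohort$variants,
                                          cohort$hapA, cohort$hapB)
  binding <- NULL
  if (!is.null(panel) && nrow(rec)) {
    binding <- lapply(panel, function(preds) {
      calls <- lapply(preds, function(pr) {
        classify_binders(rec$peptide, pr$pssm, pr$calibration)
      })
      tab <- data.frame(peptide = rec$peptide, stringsAsFactors = FALSE)
      for (j in seq_along(calls)) {
        tab[[paste0("score_", j)]] <- calls[[j]]$score
        tab[[paste0("category_", j)]] <- calls[[j]]$category
      }
      if (length(calls) >= 2L) {
        tab$consensus_SB <- tab$peptide %in%
          consensus_filter(calls[[1L]], calls[[2L]], "SB")
        tab$consensus_WB <- tab$peptide %in%
          consensus_filter(calls[[1L]], calls[[2L]], "WB")
      } else {
        tab$consensus_SB <- calls[[1L]]$category == "SB"
        tab$consensus_WB <- calls[[1L]]$category != "non-binder"
      }
      tab
    })
  }
  structure(list(recipient_id = recipient, donor_id = donor,
                 relationship = relationship, k = k,
                 urps = rec, profile = prof,
                 n_urp = nrow(rec),
                 n_recipient_peptides = length(rpep$peptides),
                 urp_fraction = if (length(rpep$peptides))
                   nrow(rec) / length(rpep$peptides) else 0,
                 n_unique_variants = n_uv,
                 binding = binding),
            class = "pair_analysis")
}

#' @export
print.pair_analysis <- function(x, ...) {
  cat(sprintf("<pair_analysis %s (recipient) vs %s (donor), %s>\n",
              x$recipient_id, x$donor_id, x$relationship))
  cat(sprintf("  unique recipient variants: %d\n", x$n_unique_variants))
  cat(sprintf("  URPs: %d (%.3f%% of the recipient %d-mer peptidome)\n",
              x$n_urp, 100 * x$urp_fraction, x$k))
  if (!is.null(x$binding)) {
    for (al in names(x$binding)) {
      b <- x$binding[[al]]
      cat(sprintf("  %s: %d consensus SB, %d consensus WB URiPs\n",
                  al, sum(b$consensus_SB), sum(b$consensus_WB)))
    }
  }
  invisible(x)
}

#' Analyse a cohort of donor-recipient pairs
#'
#' Runs [run_pair_analysis()] for every pair and aggregates: per-pair
#' counts with mean and SD per relationship group, the distinct-URP
#' union, saturation curves per frequency bin, the observed per-variant
#' mismatch fraction against the model prediction, and the
#' sibling-vs-unrelated fold comparison when both groups are present.
#'
#' @inheritParams run_pair_analysis
#' @param pairs data.frame with `recipient_id`, `donor_id`,
#'   `relationship` (e.g. from [make_pairs()]).
#' @return object of class `cohort_analysis`.
#' @export
run_cohort_analysis <- function(transcripts, cohort, pairs, k = 9L,
                                pmm_thresholds = c(0.1, 0.2), panel = NULL) {
  stopifnot(nrow(pairs) >= 1L)
  analyses <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    analyses[[i]] <- run_pair_analysis(
      transcripts, cohort, pairs$recipient_id[i], pairs$donor_id[i],
      pairs$relationship[i], k, pmm_thresholds, panel)
  }
  per_pair <- do.call(rbind, lapply(analyses, function(a) {
    data.frame(recipient_id = a$recipient_id, donor_id = a$donor_id,
               relationship = a$relationship, n_urp = a$n_urp,
               n_unique_variants = a$n_unique_variants,
               urp_fraction = a$urp_fraction, stringsAsFactors = FALSE)
  }))
  rels <- unique(per_pair$relationship)
  summary <- do.call(rbind, lapply(rels, function(rl) {
    v <- per_pair$n_urp[per_pair$relationship == rl]
    data.frame(relationship = rl, n_pairs = length(v),
               mean_urp = mean(v), sd_urp = if (length(v) > 1) sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  distinct_urps <- unique(unlist(lapply(analyses,
                                        function(a) a$urps$peptide)))
  saturation <- saturation_curve(lapply(analyses, `[[`, "urps"))

  # observed per-variant mismatch fraction (first alternate allele) per
  # relationship group, against the closed-form model
  variant_mismatch <- NULL
  f1 <- vapply(cohort$variants$af, `[[`, 0, 1L)
  for (rl in rels) {
    idx <- which(per_pair$relationship == rl)
    rs <- per_pair$recipient_id[idx]; ds <- per_pair$donor_id[idx]
    mm <- (cohort$hapA[, rs, drop = FALSE] == 1L |
             cohort$hapB[, rs, drop = FALSE] == 1L) &
          (cohort$hapA[, ds, drop = FALSE] != 1L &
             cohort$hapB[, ds, drop = FALSE] != 1L)
    fn <- pmm_fun(rl)
    tab <- data.frame(variant_id = cohort$variants$variant_id,
                      f = f1, relationship = rl,
                      observed = rowMeans(mm), expected = fn(f1),
                      stringsAsFactors = FALSE)
    variant_mismatch <- rbind(variant_mismatch, tab)
  }

  fold_observed <- NA_real_
  if (all(c("unrelated", "sibling") %in% rels)) {
    fold_observed <-
      summary$mean_urp[summary$relationship == "unrelated"] /
      summary$mean_urp[summary$relationship == "sibling"]
  }

  structure(list(per_pair = per_pair, summary = summary,
                 n_distinct_urps = length(distinct_urps),
                 distinct_urps = distinct_urps,
                 saturation = saturation,
                 variant_mismatch = variant_mismatch,
                 fold_observed = fold_observed,
                 analyses = analyses),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("<cohort_analysis: %d pairs, %d distinct URPs>\n",
              nrow(x$per_pair), x$n_distinct_urps))
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("  %s: %d pairs, URPs per pair %.1f +/- %.1f\n",
                s$relationship, s$n_pairs, s$mean_urp,
                ifelse(is.na(s$sd_urp), 0, s$sd_urp)))
  }
  if (!is.na(x$fold_observed)) {
    cat(sprintf("  unrelated / sibling URP fold: %.2f\n", x$fold_observed))
  }
  invisible(x)
}

write_tsv <- function(df, path) {
  df[] <- lapply(df, function(col) {
    col[is.na(col)] <- "."
    col
  })
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-pair result tables
#'
#' Emits `urps.tsv` (peptide, class, causal variants, frequency, pmm,
#' tier), `profile.tsv`, one `urip_<allele>.tsv` per panel allele, and
#' `summary.tsv` into `dir`.
#'
#' @param pa a `pair_analysis`.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_pair_tables <- function(pa, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(pa$urps, file.path(dir, "urps.tsv"))
  prof <- data.frame(
    key = c(paste0("class_share:", names(pa$profile$class_shares)),
            paste0("f_bin_share:", names(pa$profile$f_bin_shares))),
    value = c(pa$profile$class_shares, pa$profile$f_bin_shares),
    stringsAsFactors = FALSE)
  write_tsv(prof, file.path(dir, "profile.tsv"))
  if (!is.null(pa$binding)) {
    for (al in names(pa$binding)) {
      safe <- gsub("[^A-Za-z0-9]+", "_", al)
      write_tsv(pa$binding[[al]], file.path(dir, paste0("urip_", safe, ".tsv")))
    }
  }
  smry <- data.frame(
    key = c("recipient", "donor", "relationship", "k", "n_unique_variants",
            "n_urp", "n_recipient_peptides", "urp_fraction"),
    value = c(pa$recipient_id, pa$donor_id, pa$relationship, pa$k,
              pa$n_unique_variants, pa$n_urp, pa$n_recipient_peptides,
              signif(pa$urp_fraction, 6)),
    stringsAsFactors = FALSE)
  write_tsv(smry, file.path(dir, "summary.tsv"))
  invisible(dir)
}

#' Write cohort result tables
#'
#' Emits `per_pair.tsv`, `summary.tsv`, `saturation.tsv` and
#' `variant_mismatch.tsv` into `dir`.
#'
#' @param ca a `cohort_analysis`.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_cohort_tables <- function(ca, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(ca$per_pair, file.path(dir, "per_pair.tsv"))
  write_tsv(ca$summary, file.path(dir, "summary.tsv"))
  write_tsv(ca$saturation, file.path(dir, "saturation.tsv"))
  write_tsv(ca$variant_mismatch, file.path(dir, "variant_mismatch.tsv"))
  invisible(dir)
}

#' Write a run manifest
#'
#' Key-value text capturing the run configuration, seed and package
#' version so a run can be reproduced byte-identically.
#'
#' @param config named list of settings (seeds, thresholds, paths).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_manifest <- function(config, path) {
  config$mihascan_version <-
    as.character(utils::packageVersion("mihascan"))
  lines <- vapply(names(config), function(nm) {
    paste0(nm, "\t", paste(as.character(config[[nm]]), collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
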