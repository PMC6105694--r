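# Closed-form mismatch-probability model. For a peptide encoded by an
# allele at population frequency f, the probability that a random
# donor-recipient pair is mismatched (recipient carries the encoding
# allele, donor lacks it) is, under Hardy-Weinberg equilibrium,
#
#   unrelated pairs:  P(f) = f (1-f)^2 (2-f)  =  (1 - (1-f)^2) (1-f)^2
#   sibling pairs:    P(f) = (1-f)^2 f (4-f) / 4
#
# Both vanish at f = 0 and f = 1; the unrelated maximum is 1/4 at
# f = 1 - 1/sqrt(2) ~ 0.293, the sibling maximum ~0.136 at
# f = (7 - sqrt(33))/4 ~ 0.314.

check_f <- function(f) {
  if (any(is.na(f)) || any(f < 0) || any(f > 1)) {
    stop("allele frequency outside [0, 1]")
  }
  f
}

#' Mismatch probability for unrelated pairs
#'
#' `f (1-f)^2 (2-f)`: the probability that the recipient carries the
#' encoding allele times the probability that an unrelated donor lacks
#' it, both under Hardy-Weinberg equilibrium.
#'
#' @param f encoding-allele frequency, vectorised over `[0, 1]`.
#' @return mismatch probabilities in `[0, 0.25]`.
#' @export
pmm_unrelated <- function(f) {
  check_f(f)
  f * (1 - f)^2 * (2 - f)
}

#' Mismatch probability for sibling pairs
#'
#' `(1-f)^2 f (4-f) / 4`: accounts for the Mendelian co-transmission of
#' parental haplotypes, which makes siblings share more alleles than
#' unrelated pairs.
#'
#' @inheritParams pmm_unrelated
#' @return mismatch probabilities in `[0, ~0.136]`.
#' @export
pmm_sibling <- function(f) {
  check_f(f)
  (1 - f)^2 * f * (4 - f) / 4
}

pmm_fun <- function(model = c("unrelated", "sibling")) {
  switch(match.arg(model), unrelated = pmm_unrelated, sibling = pmm_sibling)
}

#' Maximum of a mismatch-probability model
#'
#' Numeric maximisation on `[0, 1]` (tolerance well below 1e-6; the
#' unrelated model also has the closed form `f* = 1 - 1/sqrt(2)`, used as
#' a cross-check in the test-suite).
#'
#' @param model `"unrelated"` or `"sibling"`.
#' @return named numeric vector `c(f_star, p_max)`.
#' @export
pmm_extremum <- function(model = c("unrelated", "sibling")) {
  fn <- pmm_fun(model)
  opt <- optimize(fn, c(0, 1), maximum = TRUE, tol = 1e-12)
  c(f_star = opt$maximum, p_max = opt$objective)
}

#' Allele-frequency window above a mismatch-probability threshold
#'
#' The two roots of `P(f) = threshold` bracketing the model's maximum:
#' alleles inside `(f_low, f_high)` have mismatch probability above the
#' threshold. Root finding by bisection on each side of the argmax
#' (tolerance 1e-10).
#'
#' @param model `"unrelated"` or `"sibling"`.
#' @param threshold mismatch probability, `0 < threshold < p_max`.
#' @return named numeric vector `c(f_low, f_high)`.
#' @export
pmm_frequency_window <- function(model = c("unrelated", "sibling"),
                                 threshold) {
  fn <- pmm_fun(model)
  ext <- pmm_extremum(model)
  if (threshold <= 0 || threshold >= ext[["p_max"]]) {
    stop("empty window: threshold must be in (0, ",
         signif(ext[["p_max"]], 6), ")")
  }
  g <- function(f) fn(f) - threshold
  lo <- uniroot(g, c(0, ext[["f_star"]]), tol = 1e-12)$root
  hi <- uniroot(g, c(ext[["f_star"]], 1), tol = 1e-12)$root
  c(f_low = lo, f_high = hi)
}

#' Probability of observing a URP in at least one of n pairs
#'
#' `1 - (1 - p)^n` for a peptide with per-pair mismatch probability `p`
#' across `n` independent pairs — the analytic form of the URP
#' saturation curve.
#'
#' @param p per-pair mismatch probability in `[0, 1]`, vectorised.
#' @param n number of pairs (non-negative integer), vectorised.
#' @return probabilities.
#' @export
saturation_probability <- function(p, n) {
  stopifnot(all(p >= 0), all(p <= 1), all(n >= 0), all(n == floor(n)))
  1 - (1 - p)^n
}

# resolve a spectrum specification to an (unnormalised) density function
# over f in (0, 1), or a point mass
resolve_spectrum <- function(spectrum) {
  if (is.function(spectrum)) return(list(kind = "density", phi = spectrum))
  if (is.character(spectrum)) spectrum <- list(kind = spectrum)
  kind <- spectrum$kind
  if (kind == "uniform") {
    list(kind = "density", phi = function(f) rep(1, length(f)))
  } else if (kind == "point") {
    list(kind = "point", f = spectrum$f)
  } else if (kind == "truncated_1_over_f") {
    f_min <- if (is.null(spectrum$f_min)) 0.001 else spectrum$f_min
    f_max <- if (is.null(spectrum$f_max)) 0.999 else spectrum$f_max
    stopifnot(f_min > 0, f_max <= 1, f_min < f_max)
    list(kind = "density",
         phi = function(f) ifelse(f >= f_min & f <= f_max, 1 / f, 0))
  } else {
    stop("unknown frequency spectrum: ", kind)
  }
}

#' Expected fold-reduction of URP yield in sibling vs unrelated pairs
#'
#' Ratio of the two mismatch-probability formulas integrated against an
#' allele-frequency spectrum:
#' `integral(P_unrelated * phi) / integral(P_sibling * phi)`.
#' For a uniform spectrum the exact value is `(2/15) / (3/40) = 16/9`,
#' approximately the 1.8-fold reduction expected for sibling donors.
#'
#' @param spectrum `"uniform"`, `list(kind = "point", f = )`,
#'   `list(kind = "truncated_1_over_f", f_min = , f_max = )`, or a
#'   density function over `(0, 1)` (normalisation cancels in the ratio).
#' @return the fold-reduction ratio.
#' @export
expected_fold_reduction <- function(spectrum = "uniform") {
  sp <- resolve_spectrum(spectrum)
  if (sp$kind == "point") {
    f <- check_f(sp$f)
    return(pmm_unrelated(f) / pmm_sibling(f))
  }
  eps <- 1e-12
  num <- integrate(function(f) pmm_unrelated(f) * sp$phi(f),
                   eps, 1 - eps, rel.tol = 1e-10)
  den <- integrate(function(f) pmm_sibling(f) * sp$phi(f),
                   eps, 1 - eps, rel.tol = 1e-10)
  if (!is.finite(num$value) || !is.finite(den$value) || den$value <= 0) {
    stop("spectrum not integrable against the mismatch model")
  }
  num$value / den$value
}

#' Annotate URPs with mismatch probabilities
#'
#' Evaluates the relationship-appropriate mismatch model at each URP's
#' encoding-allele frequency and flags therapeutically relevant peptides
#' by probability tier.
#'
#' @param urp_records output of [classify_urps()].
#' @param relationship `"unrelated"` or `"sibling"`.
#' @param thresholds increasing probability tiers; the default `c(0.1,
#'   0.2)` marks the relevant and the prime therapeutic windows.
#' @return `urp_records` with columns `pmm` and `therapeutic_tier`
#'   (`"none"`, `">0.1"`, `">0.2"` for the defaults).
#' @export
assign_pmm <- function(urp_records, relationship = c("unrelated", "sibling"),
                       thresholds = c(0.1, 0.2)) {
  stopifnot(!is.unsorted(thresholds))
  fn <- pmm_fun(relationship)
  f <- urp_records$encoding_allele_frequency
  pmm <- rep(NA_real_, length(f))
  ok <- !is.na(f)
  pmm[ok] <- fn(f[ok])
  tier <- rep("none", length(f))
  for (t in thresholds) tier[ok & pmm > t] <- paste0(">", t)
  urp_records$pmm <- pmm
  urp_records$therapeutic_tier <- tier
  urp_records
}
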