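zero_pssm <- function(k = 9L, allele = "HLA-TST*01:01") {
  pssm(allele, matrix(0, k, 20, dimnames = list(NULL, strsplit(
    "ACDEFGHIKLMNPQRSTVWY", "")[[1]])))
}

test_that("additive scoring matches a hand-computed sum", {
  p0 <- zero_pssm()
  expect_equal(score_peptides(p0, c("AAAAAAAAA", "WYWYWYWYW")), c(0, 0))
  w <- matrix(0, 9, 20, dimnames = list(NULL, strsplit(
    "ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  w[, "A"] <- 1
  pa <- pssm("HLA-TST*01:01", w)
  expect_equal(score_peptides(pa, "AAAAAAAAA"), 9)
  expect_equal(score_peptides(pa, "AAAACAAAA"), 8)
  set.seed(9)
  wr <- matrix(rnorm(180), 9, 20, dimnames = dimnames(w))
  pr <- pssm("HLA-TST*01:01", wr)
  pep <- "MDCWYKLRT"
  manual <- sum(vapply(1:9, function(i) wr[i, substr(pep, i, i)], 0))
  expect_equal(score_peptides(pr, pep), manual)
  expect_error(score_peptides(pr, "MDCWYKLR"), "length")
  expect_error(score_peptides(pr, "MDCWYKLRX"), "nonstandard residue")
})

test_that("scoring is invariant to peptide order", {
  cfg <- simulation_config(seed = 2)
  trs <- generate_reference(cfg)
  p <- generate_pssm(cfg)
  bg <- generate_background(trs, 50, seed = 4)
  expect_equal(score_peptides(p, rev(bg)), rev(score_peptides(p, bg)))
})

test_that("calibrated cutoffs are the expected order statistics", {
  set.seed(5)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  wr <- matrix(rnorm(180), 9, 20, dimnames = list(NULL, aa))
  px <- pssm("HLA-TST*01:01", wr)
  bg <- unique(replicate(1100, paste(sample(aa, 9, replace = TRUE),
                                     collapse = "")))[1:1000]
  cal <- calibrate_thresholds(px, bg, p_strong = 0.005, p_weak = 0.02)
  sc <- sort(score_peptides(px, bg), decreasing = TRUE)
  expect_equal(cal$strong_cutoff, sc[5])   # ceiling(0.005 * 1000)
  expect_equal(cal$weak_cutoff, sc[20])
  expect_gte(cal$strong_cutoff, cal$weak_cutoff)
  expect_error(calibrate_thresholds(px, bg[1:100], p_strong = 0.005),
               "background too small")
})

test_that("tied background scores calibrate toward the stricter cutoff", {
  # score = weight of the first residue: only 20 distinct scores, so tie
  # blocks straddle every rank; the cutoff must move up so the
  # at-or-above fraction never exceeds p + 1/N
  p0 <- zero_pssm()
  w <- p0$weights; w[1, ] <- seq_len(20)
  px <- pssm("HLA-TST*01:01", w)
  set.seed(6)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bg <- replicate(1000, paste(sample(aa, 9, replace = TRUE), collapse = ""))
  cal <- calibrate_thresholds(px, bg, p_strong = 0.005, p_weak = 0.02)
  sc <- score_peptides(px, bg)
  expect_lte(mean(sc >= cal$strong_cutoff), 0.005 + 1 / 1000)
  expect_lte(mean(sc >= cal$weak_cutoff), 0.02 + 1 / 1000)
})

test_that("background fraction at or above the strong cutoff honours the contract", {
  cfg <- simulation_config(seed = 44)
  trs <- generate_reference(cfg)
  ps <- generate_pssm(cfg, anchor_weight = 2)
  bg <- generate_background(trs, 10000, seed = 45)
  cal <- calibrate_thresholds(ps, bg)
  frac_sb <- mean(score_peptides(ps, bg) >= cal$strong_cutoff)
  frac_wb <- mean(score_peptides(ps, bg) >= cal$weak_cutoff)
  expect_lte(frac_sb, cal$p_strong + 1 / length(bg))
  expect_lte(frac_wb, cal$p_weak + 1 / length(bg))
})

test_that("binder categories are a pure function of score and cutoffs", {
  p0 <- zero_pssm()
  w <- p0$weights; w[1, "A"] <- 10; w[1, "C"] <- 5
  px <- pssm("HLA-TST*01:01", w)
  cal <- structure(list(allele_name = "HLA-TST*01:01", strong_cutoff = 10,
                        weak_cutoff = 5, background_size = 1000,
                        p_strong = 0.005, p_weak = 0.02),
                   class = "threshold_calibration")
  calls <- classify_binders(c("ADDDDDDDD", "CDDDDDDDD", "DDDDDDDDD"),
                            px, cal)
  # a peptide tied with the cutoff is a binder
  expect_equal(calls$category, c("SB", "WB", "non-binder"))
  cal2 <- cal; cal2$allele_name <- "other"
  expect_error(classify_binders("ADDDDDDDD", px, cal2), "does not match")
})

test_that("lowering p_strong never grows the strong-binder set", {
  cfg <- simulation_config(seed = 46)
  trs <- generate_reference(cfg)
  ps <- generate_pssm(cfg)
  bg <- generate_background(trs, 5000, seed = 47)
  test_peps <- generate_background(trs, 300, seed = 48)
  sb_sets <- lapply(c(0.02, 0.01, 0.005, 0.002), function(p) {
    cal <- calibrate_thresholds(ps, bg, p_strong = p, p_weak = 0.05)
    calls <- classify_binders(test_peps, ps, cal)
    calls$peptide[calls$category == "SB"]
  })
  for (i in 2:4) expect_true(all(sb_sets[[i]] %in% sb_sets[[i - 1]]))
})

test_that("consensus of identical call sets is the call set itself", {
  cfg <- simulation_config(seed = 50)
  trs <- generate_reference(cfg)
  ps <- generate_pssm(cfg)
  bg <- generate_background(trs, 2000, seed = 51)
  cal <- calibrate_thresholds(ps, bg)
  peps <- generate_background(trs, 500, seed = 52)
  calls <- classify_binders(peps, ps, cal)
  expect_setequal(consensus_filter(calls, calls, "SB"),
                  calls$peptide[calls$category == "SB"])
  expect_setequal(consensus_filter(calls, calls, "WB"),
                  calls$peptide[calls$category != "non-binder"])
  # SB consensus is nested in WB consensus
  expect_true(all(consensus_filter(calls, calls, "SB") %in%
                    consensus_filter(calls, calls, "WB")))
})

test_that("consensus over a 5-peptide toy matches hand enumeration", {
  mk_calls <- function(categories) {
    structure(data.frame(peptide = paste0("P", 1:5),
                         allele_name = "HLA-TST*01:01",
                         score = 0, category = categories,
                         stringsAsFactors = FALSE),
              class = c("binding_calls", "data.frame"))
  }
  c1 <- mk_calls(c("SB", "SB", "WB", "non-binder", "WB"))
  c2 <- mk_calls(c("SB", "WB", "WB", "SB", "non-binder"))
  expect_equal(consensus_filter(c1, c2, "SB"), "P1")
  expect_setequal(consensus_filter(c1, c2, "WB"), c("P1", "P2", "P3"))
  # disjoint SB sets -> empty SB overlap
  c3 <- mk_calls(c("SB", "non-binder", "non-binder", "non-binder", "non-binder"))
  c4 <- mk_calls(c("non-binder", "SB", "non-binder", "non-binder", "non-binder"))
  expect_length(consensus_filter(c3, c4, "SB"), 0)
  c5 <- c1[1:4, ]
  expect_error(consensus_filter(c1, c5), "universes")
})

test_that("strong anchors dominate the score ordering", {
  cfg <- simulation_config(seed = 53)
  ps <- generate_pssm(cfg, anchor_weight = 10)
  pref2 <- names(which.max(ps$weights[2, ]))
  pref9 <- names(which.max(ps$weights[9, ]))
  set.seed(54)
  aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]  # avoid anchors by chance
  base <- replicate(30, paste(sample(setdiff(aa, c(pref2, pref9)), 9,
                                     replace = TRUE), collapse = ""))
  motif <- vapply(base, function(p) {
    substr(p, 2, 2) <- pref2; substr(p, 9, 9) <- pref9; p
  }, "", USE.NAMES = FALSE)
  expect_gt(min(score_peptides(ps, motif)), max(score_peptides(ps, base)))
})

test_that("allelic counterpart peptides support the co-dominance statistic", {
  tr <- make_transcript(varied_cds(40))
  v <- missense_at(tr, 20)
  ap <- allelic_peptides(tr, v, 1)
  expect_length(ap$ref, 9)
  expect_length(ap$alt, 9)
  expect_length(intersect(ap$ref, ap$alt), 0)
  # toy ratio: hand-assigned binder set
  sets <- list(
    list(ref = c("AAAAAAAAA"), alt = c("CCCCCCCCC")),  # co-dominant
    list(ref = c("DDDDDDDDD"), alt = c("EEEEEEEEE")),  # dominant (ref only)
    list(ref = c("FFFFFFFFF"), alt = c("GGGGGGGGG")),  # co-dominant
    list(ref = c("HHHHHHHHH"), alt = c("IIIIIIIII")))  # dominant (alt only)
  binders <- c("AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD", "FFFFFFFFF",
               "GGGGGGGGG", "IIIIIIIII")
  got <- codominance_ratio(sets, binders)
  expect_equal(got$ratio, 1)
  expect_equal(got$n_codominant, 2L)
  expect_equal(got$n_dominant, 2L)
  # all co-dominant -> infinity marker, not a crash
  all_co <- codominance_ratio(sets[c(1, 3)], binders)
  expect_equal(all_co$ratio, Inf)
  expect_equal(all_co$n_dominant, 0L)
})

test_that("arginine/lysine exclusion removes R/K peptides before counting", {
  sets <- list(
    list(ref = c("AAAARAAAA", "AAAAAAAAA"), alt = c("CCCCKCCCC")),
    list(ref = c("RRRRRRRRR"), alt = c("KKKKKKKKK")))
  binders <- c("AAAARAAAA", "CCCCKCCCC", "RRRRRRRRR", "KKKKKKKKK",
               "AAAAAAAAA")
  with_rk <- codominance_ratio(sets, binders, exclude_RK = FALSE)
  expect_equal(with_rk$n_codominant, 2L)
  no_rk <- codominance_ratio(sets, binders, exclude_RK = TRUE)
  # only the R/K-free ref peptide of set 1 remains: dominant
  expect_equal(no_rk$n_codominant, 0L)
  expect_equal(no_rk$n_dominant, 1L)
  expect_equal(no_rk$n_silent, 1L)
})

test_that("PSSM files round trip", {
  cfg <- simulation_config(seed = 60)
  ps <- generate_pssm(cfg, allele_name = "HLA-SYN*02:01")
  path <- tempfile(fileext = ".pssm")
  write_pssm(ps, path)
  got <- read_pssm(path)
  expect_equal(got$allele_name, "HLA-SYN*02:01")
  expect_equal(got$weights, ps$weights, tolerance = 1e-8)
})
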