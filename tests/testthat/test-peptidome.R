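# convenience: full pair run on a toy cohort returning classified URPs
toy_pair_urps <- function(transcripts, variants, gt, recipient = "R",
                          donor = "D", k = 9L) {
  co <- make_cohort(variants, gt)
  rp <- build_proteome(recipient, transcripts, co)
  dp <- build_proteome(donor, transcripts, co)
  urps <- subtract_peptidomes(extract_peptides(rp, k),
                              extract_peptides(dp, k))
  classify_urps(urps, rp, dp, co)
}

test_that("peptide extraction yields L - k + 1 windows per protein", {
  tr20 <- make_transcript(varied_cds(21))  # protein length 20
  v <- missense_at(tr20, 5)
  co <- make_cohort(v, list(S = "0|0"))
  pep <- extract_peptides(build_proteome("S", list(tr20), co), k = 9L)
  expect_equal(nrow(pep$occurrences), 2L * 12L)  # both haplotypes
  expect_equal(length(pep$peptides), 12L)        # distinct strings
  # boundary: protein of exactly k and one below
  tr9 <- make_transcript(varied_cds(10), id = "T9", chrom = "chr2")
  tr8 <- make_transcript(varied_cds(9), id = "T8", chrom = "chr3")
  co2 <- make_cohort(v, list(S = "0|0"))
  pep9 <- extract_peptides(build_proteome("S", list(tr9), co2), 9L)
  pep8 <- extract_peptides(build_proteome("S", list(tr8), co2), 9L)
  expect_equal(nrow(pep9$occurrences), 2L)
  expect_equal(length(pep9$peptides), 1L)
  expect_equal(nrow(pep8$occurrences), 0L)
})

test_that("subtracting a peptidome from itself leaves nothing", {
  cfg <- simulation_config(seed = 12, n_transcripts = 4, n_variants = 20,
                           n_samples = 2)
  trs <- generate_reference(cfg)
  vs <- generate_variant_set(cfg, trs)
  co <- generate_cohort(cfg, vs, n_samples = 2)
  p <- extract_peptides(build_proteome("S0001", trs, co))
  expect_length(subtract_peptidomes(p, p)$peptides, 0L)
  p8 <- extract_peptides(build_proteome("S0001", trs, co), k = 8L)
  expect_error(subtract_peptidomes(p, p8), "mismatched k")
})

test_that("an internal heterozygous missense SNV yields exactly 9 URPs", {
  # 40-codon transcript, missense at codon 20 (>= 9 residues from both ends)
  tr <- make_transcript(poly_asp_cds(40))
  v <- cds_variants(tr, 3L * 19L + 1L, "A", "C", 0.3)  # GAT -> GCT (D20A)
  expect_equal(classify_variant(tr, v, 1), "missense")
  urps <- toy_pair_urps(list(tr), v, list(R = "0|1", D = "0|0"))
  expect_equal(nrow(urps), 9L)
  expect_true(all(urps$polymorphism_class == "single_nsSNP"))
  expect_true(all(urps$causal_variants == "tv01:1"))
  expect_equal(unique(urps$encoding_allele_frequency), 0.3)
})

test_that("a missense SNV near the terminus yields only the fitting windows", {
  # protein of length 12, substitution at residue 5 -> windows 1..4
  tr <- make_transcript(poly_asp_cds(13))
  v <- cds_variants(tr, 3L * 4L + 1L, "A", "C", 0.5)  # D5A
  urps <- toy_pair_urps(list(tr), v, list(R = "0|1", D = "0|0"))
  expect_equal(nrow(urps), 4L)
})

test_that("m well-separated internal missense SNVs yield exactly 9m URPs", {
  tr <- make_transcript(varied_cds(80))
  codons <- c(15L, 30L, 45L, 60L)  # pairwise distance > k
  vs <- lapply(seq_along(codons), function(i) {
    missense_at(tr, codons[i], f = 0.4, id = sprintf("tv%02d", i))
  })
  v <- do.call(rbind, vs)
  class(v) <- c("variant_table", "data.frame")
  urps <- toy_pair_urps(list(tr), v,
                        list(R = rep("0|1", 4), D = rep("0|0", 4)))
  expect_equal(nrow(urps), 9L * 4L)
  expect_true(all(urps$polymorphism_class == "single_nsSNP"))
})

test_that("URP sets are invariant under transcript order permutation", {
  cfg <- simulation_config(seed = 13, n_transcripts = 5, n_variants = 30,
                           n_samples = 4)
  trs <- generate_reference(cfg)
  vs <- generate_variant_set(cfg, trs)
  co <- generate_cohort(cfg, vs, n_samples = 4)
  run <- function(transcripts) {
    rp <- build_proteome("S0001", transcripts, co)
    dp <- build_proteome("S0002", transcripts, co)
    sort(subtract_peptidomes(extract_peptides(rp),
                             extract_peptides(dp))$peptides)
  }
  expect_identical(run(trs), run(rev(trs)))
})

test_that("adjacent missense SNVs within one window classify as adjacent_nsSNPs", {
  tr <- make_transcript(poly_asp_cds(40))
  # substitutions at codons 20 and 23 (3 residues apart), both recipient-only
  v <- cds_variants(tr, 3L * c(19L, 22L) + 1L, c("A", "A"), c("C", "C"),
                    c(0.2, 0.3))
  urps <- toy_pair_urps(list(tr), v,
                        list(R = c("1|0", "1|0"), D = c("0|0", "0|0")))
  both <- urps[grepl(",", urps$causal_variants), ]
  one <- urps[!grepl(",", urps$causal_variants), ]
  expect_true(nrow(both) > 0)
  expect_true(all(both$polymorphism_class == "adjacent_nsSNPs"))
  # conservative encoding frequency: minimum of the causal alleles
  expect_equal(unique(both$encoding_allele_frequency), 0.2)
  expect_true(all(one$polymorphism_class == "single_nsSNP"))
})

test_that("donor homozygous truncating alleles explain reference-encoded URPs", {
  # nonsense at codon 25 of a 40-codon transcript; donor homozygous
  tr <- make_transcript(paste0("ATG", strrep("GAT", 22), "TAC",
                               strrep("GAT", 14), "TAA"))
  v <- cds_variants(tr, 3L * 23L + 2L, "C", "A", 0.3)  # TAC -> TAA
  expect_equal(classify_variant(tr, v, 1), "nonsense")
  urps <- toy_pair_urps(list(tr), v, list(R = "0|0", D = "1|1"))
  expect_true(all(urps$polymorphism_class == "homozygous_nonsense_donor"))
  # brute-force window enumeration oracle
  co <- make_cohort(v, list(R = "0|0", D = "1|1"))
  rp <- vapply(build_proteome("R", list(tr), co)$proteins, `[[`, "", "protein")
  dp <- vapply(build_proteome("D", list(tr), co)$proteins, `[[`, "", "protein")
  expect_setequal(urps$peptide, oracle_urps(rp, dp))
  # encoding allele is the reference allele
  expect_equal(unique(urps$encoding_allele_frequency), 0.7)
})

test_that("donor homozygous frameshift classifies analogously", {
  cds <- varied_cds(40)
  tr <- make_transcript(cds)
  # 1-bp deletion inside codon 21 (offsets 60-61)
  v <- cds_variants(tr, 60L, substr(cds, 61, 62), substr(cds, 61, 61), 0.25)
  expect_match(classify_variant(tr, v, 1), "frameshift")
  urps <- toy_pair_urps(list(tr), v, list(R = "0|0", D = "1|1"))
  expect_true(nrow(urps) > 0)
  expect_true(all(urps$polymorphism_class == "homozygous_frameshift_donor"))
  co <- make_cohort(v, list(R = "0|0", D = "1|1"))
  rp <- vapply(build_proteome("R", list(tr), co)$proteins, `[[`, "", "protein")
  dp <- vapply(build_proteome("D", list(tr), co)$proteins, `[[`, "", "protein")
  expect_setequal(urps$peptide, oracle_urps(rp, dp))
})

test_that("a donor homozygous missense makes reference peptides unique", {
  cds <- varied_cds(40, seed = 7)
  tr <- make_transcript(cds)
  # missense at codon 20: middle base swap that changes the amino acid
  off <- 3L * 19L + 1L
  base <- substr(cds, off + 1L, off + 1L)
  alt <- setdiff(c("A", "C", "G", "T"), base)
  alt <- alt[[which(vapply(alt, function(b) {
    v <- cds_variants(tr, off, base, b, 0.8)
    classify_variant(tr, v, 1) == "missense"
  }, TRUE))[1]]]
  v <- cds_variants(tr, off, base, alt, 0.8)
  urps <- toy_pair_urps(list(tr), v, list(R = "0|0", D = "1|1"))
  expect_equal(nrow(urps), 9L)
  expect_true(all(urps$polymorphism_class == "single_nsSNP"))
  # the encoding allele here is the reference allele, frequency 1 - 0.8
  expect_equal(unique(urps$encoding_allele_frequency), 0.2)
})

test_that("recipient frameshift URPs match the brute-force subtraction oracle", {
  tr <- make_transcript(poly_asp_cds(40))
  v <- cds_variants(tr, 60L, "GA", "G", 0.1)
  urps <- toy_pair_urps(list(tr), v, list(R = "0|1", D = "0|0"))
  expect_true(all(urps$polymorphism_class == "frameshift_recipient"))
  co <- make_cohort(v, list(R = "0|1", D = "0|0"))
  rp <- vapply(build_proteome("R", list(tr), co)$proteins, `[[`, "", "protein")
  dp <- vapply(build_proteome("D", list(tr), co)$proteins, `[[`, "", "protein")
  expect_setequal(urps$peptide, oracle_urps(rp, dp))
})

test_that("class and frequency-bin shares sum to one", {
  rec <- data.frame(
    peptide = sprintf("PEP%06d", 1:100),
    polymorphism_class = c(rep("single_nsSNP", 88), rep("adjacent_nsSNPs", 3),
                           rep("inframe_indel", 9)),
    causal_variants = "x:1",
    encoding_allele_frequency = c(rep(0.3, 70), rep(0.05, 18),
                                  rep(0.005, 2), rep(0.95, 10)),
    stringsAsFactors = FALSE)
  prof <- profile_pair(rec)
  expect_equal(sum(prof$class_shares), 1)
  expect_equal(unname(prof$class_shares[c("single_nsSNP", "adjacent_nsSNPs",
                                          "inframe_indel")]),
               c(0.88, 0.03, 0.09))
  # bins computed over the 91 nsSNP URPs only
  expect_equal(sum(prof$f_bin_counts), 91L)
  expect_equal(sum(prof$f_bin_shares), 1)
  expect_warning(empty <- profile_pair(rec[0, ]), "empty URP set")
  expect_equal(empty$n, 0L)
})

test_that("saturation curves are flat for identical and linear for disjoint pairs", {
  mk <- function(peps, f = 0.3) {
    data.frame(peptide = peps, polymorphism_class = "single_nsSNP",
               causal_variants = "x:1", encoding_allele_frequency = f,
               stringsAsFactors = FALSE)
  }
  same <- replicate(4, mk(sprintf("A%08d", 1:10)), simplify = FALSE)
  flat <- saturation_curve(same)
  expect_equal(flat$distinct_urps, rep(10, 4))
  disj <- lapply(1:4, function(i) mk(sprintf("B%d_%06d", i, 1:10)))
  lin <- saturation_curve(disj)
  expect_equal(lin$distinct_urps, c(10, 20, 30, 40))
  expect_equal(lin[["0.1<=f<=0.9"]], c(10, 20, 30, 40))
})

test_that("external peptide-list intersection keeps provenance and counts", {
  tr <- make_transcript(poly_asp_cds(40))
  v <- cds_variants(tr, 3L * 19L + 1L, "A", "C", 0.3)
  urps <- toy_pair_urps(list(tr), v, list(R = "0|1", D = "0|0"))
  lst <- c(urps$peptide[1], "WWWWWWWWW", "SHORT")
  got <- intersect_with_peptide_list(urps, lst)
  expect_equal(got$matches$peptide, urps$peptide[1])
  expect_equal(got$n_skipped, 1L)
  expect_equal(unname(got$f_histogram[["0.1<=f<=0.9"]]), 1L)
  expect_equal(nrow(intersect_with_peptide_list(urps, character(0))$matches),
               0L)
  all_got <- intersect_with_peptide_list(urps, urps$peptide)
  expect_equal(nrow(all_got$matches), nrow(urps))
})
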