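test_that("extract_snps classifies alleles against the reference codon", {
  aln <- c(reference = "TTTAAA", s1 = "TTTAAA", s2 = "TTTAAA")
  expect_equal(nrow(extract_snps(aln)), 0L)

  aln <- c(reference = "TTTAAA", s1 = "TTCAAA", s2 = "TTCAAA", s3 = "TTAAAA")
  snps <- extract_snps(aln)
  expect_equal(nrow(snps), 2L)  # two distinct alleles at one column
  ttc <- snps[snps$alt_codon == "TTC", ]
  expect_equal(ttc$effect, "synonymous")
  expect_true(ttc$is_transition)
  expect_equal(ttc$allele_count, 2L)
  tta <- snps[snps$alt_codon == "TTA", ]
  expect_equal(tta$effect, "missense")
  expect_false(tta$is_transition)
  expect_equal(tta$codon_index, 1L)
  expect_equal(tta$codon_position, 3L)
})

test_that("gaps and ambiguity are excluded at the right granularity", {
  # gap in a strain: only that strain's observation is lost
  aln <- c(reference = "TTTAAA", s1 = "TT-AAA", s2 = "TTCAAA")
  snps <- extract_snps(aln)
  expect_equal(nrow(snps), 1L)
  expect_equal(snps$allele_count, 1L)
  # non-ACGT in the reference codon: the whole codon's columns are skipped
  aln2 <- c(reference = "TNTAAA", s1 = "TTCAAA", s2 = "TTTAAC")
  snps2 <- extract_snps(aln2)
  expect_equal(nrow(snps2), 1L)
  expect_equal(snps2$ref_codon, "AAA")
  # nonsense polymorphism is classified as such
  aln3 <- c(reference = "TGGAAA", s1 = "TGAAAA")
  expect_equal(extract_snps(aln3)$effect, "nonsense")
})

test_that("extract_snps validates the alignment contract", {
  expect_error(extract_snps(c(reference = "TTT", s1 = "TTTAAA")),
               "unequal lengths")
  expect_error(extract_snps(c(reference = "TTTA", s1 = "TTTA")),
               "multiple of 3")
  expect_error(extract_snps(c(reference = "TTT"), "missing_id"),
               "not found")
  expect_error(extract_snps(c("TTT", "TTT")), "named")
})

test_that("fS follows the observed/expected definition", {
  # TTT has s9 = 1: with So = 1 and NSo = 8, Se = 1 and fS = 1
  snps <- data.frame(
    gene_id = NA, codon_index = 1:9, codon_position = 1L,
    ref_base = "T", alt_base = "C", ref_codon = "TTT",
    alt_codon = c("TTC", rep("CTT", 8)),
    effect = c("synonymous", rep("missense", 8)),
    is_transition = TRUE, allele_count = 1L, stringsAsFactors = FALSE)
  fs <- codon_fs_summary(snps)
  row <- fs[fs$codon == "TTT", ]
  expect_equal(row$Se, 1)
  expect_equal(row$NSe, 8)
  expect_equal(row$fS, 1)
  # accounting: So + NSo over the table equals the record count,
  # and Se + NSe = So + NSo per codon exactly
  expect_equal(sum(fs$So + fs$NSo), nrow(snps))
  expect_equal(fs$Se + fs$NSe, fs$So + fs$NSo)
  # no observations -> fS = 0; ATG/TGG -> fS undefined
  expect_equal(fs$fS[fs$codon == "AAA"], 0)
  expect_true(all(is.na(fs$fS[fs$codon %in% c("ATG", "TGG")])))
  expect_equal(nrow(fs) - sum(is.na(fs$fS)), 59L)
})

test_that("strain-weighted counting multiplies by allele counts", {
  aln <- c(reference = "TTTAAA", s1 = "TTCAAA", s2 = "TTCAAA", s3 = "TTAAAA")
  snps <- extract_snps(aln)
  fa <- codon_fs_summary(snps, count = "alleles")
  fst <- codon_fs_summary(snps, count = "strains")
  expect_equal(fa$So[fa$codon == "TTT"], 1)
  expect_equal(fst$So[fst$codon == "TTT"], 2)
  expect_equal(sum(fst$So + fst$NSo), sum(snps$allele_count))
})

test_that("rank-sum class comparison behaves on known configurations", {
  fs <- codon_fs_summary(extract_snps(c(reference = "TTT", s1 = "TTT")))
  # hand-build fS values for controlled comparisons
  fs$So <- 1  # mark all codons observed
  two <- fs$degeneracy_class == "twofold"
  four <- fs$degeneracy_class == "fourfold"
  fs$fS[two] <- rep(c(1, 2, 3), 6)
  fs$fS[four] <- c(rep(c(1, 2, 3), 6), NA, NA)
  same <- fs_class_comparison(fs)
  expect_equal(same$p_value, 1)  # identical value multisets

  fs$fS[two] <- seq(4, 5, length.out = 18)
  fs$fS[four] <- seq(1, 2, length.out = 20)
  sep <- fs_class_comparison(fs)
  expect_equal(unname(sep$U), 18 * 20)  # complete separation, first class high
  expect_lt(sep$p_value, 0.01)

  # brute-force U for {1,2,3} vs {4,5,6}
  fs$fS[two] <- NA
  fs$fS[fs$codon %in% c("TTT", "TTC", "TAT")] <- c(1, 2, 3)
  fs$fS[four] <- NA
  fs$fS[fs$codon %in% c("GGT", "GGC", "GGA")] <- c(4, 5, 6)
  u0 <- fs_class_comparison(fs)
  expect_equal(unname(u0$U), 0)

  fs$fS[two] <- NA
  empty <- fs_class_comparison(fs)
  expect_true(is.na(empty$U))
  expect_equal(empty$undefined, "fewer_than_2_codons_in_a_class")
})
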