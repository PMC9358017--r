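test_that("gene_sites sums per-codon values and handles stops and gaps", {
  gs <- gene_sites("ATGTGG", "modified", 4)
  expect_equal(gs$S_total, 0)
  expect_equal(gs$N_total, 3 + 5 / 3, tolerance = 1e-12)  # AUG 3.000 + UGG 1.667
  gs_old <- gene_sites("ATGTGG", "old")
  expect_equal(gs_old$N_total, 6)

  expect_equal(gene_sites("")$n_codons_counted, 0L)
  expect_equal(gene_sites("")$S_total, 0)

  # terminal stop stripped, ambiguous codon skipped
  gs2 <- gene_sites("ATGNNNTTTTAA", "old")
  expect_equal(gs2$n_codons_counted, 2L)
  expect_equal(gs2$n_codons_skipped, 1L)

  expect_error(gene_sites("ATGTA"), "not a multiple of 3")
  expect_error(gene_sites("ATGTAATTT"), "internal stop")
  gs3 <- gene_sites("ATGTAATTT", skip_internal_stop = TRUE)
  expect_equal(gs3$n_codons_counted, 2L)
  expect_equal(gs3$n_codons_skipped, 1L)
})

test_that("codon differences are classified per the single-substitution rule", {
  same <- count_codon_differences("ATGTTT", "ATGTTT")
  expect_equal(same[c("Sd", "Nd", "n_single", "n_multi", "n_identical")],
               list(Sd = 0L, Nd = 0L, n_single = 0L, n_multi = 0L,
                    n_identical = 2L))
  expect_equal(count_codon_differences("TTT", "TTC")$Sd, 1L)
  expect_equal(count_codon_differences("TTT", "TTC")$Nd, 0L)
  expect_equal(count_codon_differences("ATG", "ACG")$Nd, 1L)
  multi <- count_codon_differences("TTT", "TAC")
  expect_equal(multi$n_multi, 1L)
  expect_equal(multi$Sd + multi$Nd, 0L)
  # stop or ambiguous codons drop out entirely
  expect_equal(count_codon_differences("TAATTT", "TACTTT")$n_excluded, 1L)
  expect_equal(count_codon_differences("NTTAAA", "ATTAAA")$n_excluded, 1L)
  expect_error(count_codon_differences("TTT", "TTTAAA"), "unequal lengths")
})

test_that("dnds_pair arithmetic follows pN/pS with mean sites and flags undefined ratios", {
  p <- simulate_pair(n_codons = 400, substitutions_per_lineage = 40,
                     kappa = 4, omega = 0.5, seed = 7)
  r <- dnds_pair(p$a, p$b, "modified", 4)
  expect_equal(r$Sd + r$Nd, r$n_single)
  ga <- gene_sites(p$a, "modified", 4)
  gb <- gene_sites(p$b, "modified", 4)
  expect_equal(r$S_sites, (ga$S_total + gb$S_total) / 2)
  expect_equal(r$pS, r$Sd / r$S_sites)
  expect_equal(r$pN, r$Nd / r$N_sites)
  expect_equal(r$dnds, r$pN / r$pS)

  r1 <- dnds_pair(p$a, p$b, "modified", 4, sites = "first")
  expect_equal(r1$S_sites, ga$S_total)

  # identical sequences: no synonymous differences -> ratio undefined
  r0 <- dnds_pair(p$a, p$a, "modified", 4)
  expect_true(is.na(r0$dnds))
  expect_equal(r0$undefined, "no_synonymous_differences")
})

test_that("dnds_pair is symmetric and deterministic", {
  p <- simulate_pair(n_codons = 300, substitutions_per_lineage = 30,
                     kappa = 4, seed = 13)
  ab <- dnds_pair(p$a, p$b, "modified", 4)
  ba <- dnds_pair(p$b, p$a, "modified", 4)
  expect_identical(ab$dnds, ba$dnds)
  expect_identical(ab$Sd, ba$Sd)
  expect_identical(ab[c("S_sites", "N_sites", "pS", "pN")],
                   ba[c("S_sites", "N_sites", "pS", "pN")])
  expect_identical(dnds_pair(p$a, p$b, "modified", 4),
                   dnds_pair(p$a, p$b, "modified", 4))
})

test_that("Jukes-Cantor correction expands proportions as expected", {
  p <- simulate_pair(n_codons = 500, substitutions_per_lineage = 80,
                     kappa = 4, seed = 3)
  raw <- dnds_pair(p$a, p$b, "modified", 4)
  jc <- dnds_pair(p$a, p$b, "modified", 4, jc_correction = TRUE)
  expect_equal(jc$dS, -0.75 * log(1 - 4 * raw$pS / 3))
  expect_gt(jc$dS, raw$pS)
})

test_that("gene composition counts TFD, FFD and pretermination codons", {
  gc1 <- gene_composition("TGGTAT")
  expect_equal(gc1$pretermination_fraction, 1)
  gc2 <- gene_composition("TTTGGG")
  expect_equal(gc2$n_tfd, 1L)
  expect_equal(gc2$n_ffd, 1L)
  expect_equal(gc2$tfd_ffd_ratio, 1)
  gc3 <- gene_composition("ATGATGATG")
  expect_equal(gc3$n_tfd, 0L)
  expect_true(is.na(gc3$tfd_ffd_ratio))
})

test_that("compare_dnds_methods reports per-gene increases and correlations", {
  set.seed(99)
  pairs <- list()
  for (i in 1:5) {
    p <- simulate_pair(n_codons = 300, substitutions_per_lineage = 40,
                       kappa = 4, omega = 0.3)
    pairs[[sprintf("g%d", i)]] <- list(p$a, p$b)
  }
  cmp <- compare_dnds_methods(pairs, kappa = 4)
  expect_equal(nrow(cmp$genes), 5L)
  ok <- is.finite(cmp$genes$percent_increase)
  expect_equal(cmp$genes$percent_increase[ok],
               100 * (cmp$genes$dnds_new[ok] - cmp$genes$dnds_old[ok]) /
                 cmp$genes$dnds_old[ok])
  if (!is.na(cmp$r_tfd_ffd)) {
    expect_gte(cmp$r_tfd_ffd, -1)
    expect_lte(cmp$r_tfd_ffd, 1)
  }
  # fewer than 3 usable genes: correlations undefined
  cmp2 <- compare_dnds_methods(pairs[1:2], kappa = 4)
  expect_true(is.na(cmp2$r_tfd_ffd))
})
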