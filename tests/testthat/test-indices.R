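test_that("complementarity counts reverse-complement couples over total codons", {
  expect_equal(complementarity_index(c(AAT = 10, ATT = 20, CGA = 100)),
               10 / 130)
  expect_equal(complementarity_index(c(AAA = 5)), 0)
  expect_equal(complementarity_index(c(GAC = 4, GTC = 6)), 0.4)
  expect_error(complementarity_index(c(AAA = 0)),
               class = "codonscope_undefined_input")
})

test_that("complementarity is invariant under swapping a codon with its revcomp", {
  withr::with_seed(7, {
    for (i in 1:20) {
      v <- setNames(rpois(64, 5), genetic_code()$codon)
      w <- v
      w["AAT"] <- v["ATT"]
      w["ATT"] <- v["AAT"]
      expect_equal(complementarity_index(v), complementarity_index(w))
    }
  })
})

test_that("periodicity measures positional composition deviation", {
  expect_equal(periodicity_index(c(AAA = 12)), 0)
  expect_equal(periodicity_index(c(GAT = 5)), 2 / 3)
  withr::with_seed(8, {
    for (i in 1:20) {
      v <- setNames(rpois(64, 3), genetic_code()$codon)
      if (sum(v) == 0) next
      expect_gte(periodicity_index(v), 0)
    }
  })
})

test_that("periodicity depends only on codon counts, not codon order", {
  g <- genes_tbl(g1 = cds_of(rep(c("GAT", "AAA", "CCG", "TTG"), 10)))
  shuf <- shuffle_codons_within_cds(g, seed = 3)
  expect_equal(
    periodicity_index(count_codons(g)[, c("codon", "count")]),
    periodicity_index(count_codons(shuf)[, c("codon", "count")])
  )
})

test_that("bias indices hit their boundary values", {
  ref <- major_reference()
  majors <- codonscope:::default_major_codons()
  sense_majors <- majors[names(majors) != "*"]
  all_major <- setNames(rep(5, length(sense_majors)), sense_majors)
  bi <- bias_indices(all_major, ref)
  expect_equal(bi$cai, 1)
  expect_equal(bi$fop, 1)
  expect_equal(bi$cbi, 1)

  # one codon per amino acid: Nc = 20 exactly (needs n >= 2 per family)
  one_per_aa <- setNames(rep(10, length(sense_majors)), sense_majors)
  expect_equal(bias_indices(one_per_aa, ref)$nc, 20)
})

test_that("Nc approaches 61 under uniform synonymous usage", {
  # closed form: F_k = 1/k gives Nc = 2 + 9*2 + 3 + 5*4 + 3*6 = 61; a
  # 10,000-codon multinomial draw lands in [55, 61]
  tab <- genetic_code()
  sense <- tab$codon[tab$aa != "*"]
  fam_size <- table(tab$aa)[tab$aa[match(sense, tab$codon)]]
  prob <- (1 / 20) / as.numeric(fam_size) # uniform aa, uniform synonymous
  withr::with_seed(11, {
    draw <- sample(sense, 10000, replace = TRUE, prob = prob)
  })
  nc <- bias_indices(table(draw), uniform_reference())$nc
  expect_gte(nc, 55)
  expect_lte(nc, 61)

  # exact uniform counts: Nc = 61 by the closed form
  uni <- setNames(rep(60, length(sense)), sense)
  expect_equal(bias_indices(uni, uniform_reference())$nc, 61, tolerance = 1e-10)
})

test_that("GC-expected fractions follow independent-nucleotide products", {
  f <- expected_fractions_from_gc(0.5)
  sums <- tapply(f$fraction, f$family, function(x) max(x) - min(x))
  expect_true(all(sums < 1e-12)) # full symmetry at gc = 0.5

  f6 <- expected_fractions_from_gc(0.6)
  glu <- setNames(f6$fraction[f6$family == "E"], f6$codon[f6$family == "E"])
  expect_equal(glu[["GAA"]], 0.4)
  expect_equal(glu[["GAG"]], 0.6)

  expect_error(expected_fractions_from_gc(1), class = "codonscope_domain_error")
})

test_that("GC-expected fractions match simulated independent sequences", {
  # simulation oracle: independent nucleotides at gc = 0.35, codons read off
  gc <- 0.35
  withr::with_seed(21, {
    nt <- sample(c("A", "C", "G", "T"), 3 * 60000, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  })
  cod <- paste0(nt[c(TRUE, FALSE, FALSE)], nt[c(FALSE, TRUE, FALSE)],
                nt[c(FALSE, FALSE, TRUE)])
  emp <- synonymous_fractions(table(cod))
  expected <- expected_fractions_from_gc(gc)
  j <- dplyr::inner_join(emp, expected, by = c("family", "codon"),
                         suffix = c("_emp", "_exp"))
  se <- sqrt(j$fraction_exp * (1 - j$fraction_exp) / j$family_count)
  dev <- abs(j$fraction_emp - j$fraction_exp)
  # 4 s.e. keeps the family-wise error below 0.5% over the 64 simultaneous
  # per-codon comparisons
  expect_true(all(dev < 4 * pmax(se, 1e-12)))
})

test_that("major codons are family maxima with flagged alphabetical ties", {
  mt <- major_codon_table(c(GCT = 90, GCA = 5, GCC = 3, GCG = 2,
                            TAA = 98, TAG = 1, TGA = 1,
                            setNames(rep(1, 64), genetic_code()$codon)))
  expect_equal(mt$codon[mt$family == "A"], "GCT")
  expect_equal(mt$codon[mt$family == "*"], "TAA")

  tied <- setNames(rep(1, 64), genetic_code()$codon)
  tied["GCT"] <- 5
  tied["GCA"] <- 5
  mt2 <- major_codon_table(tied)
  expect_equal(mt2$codon[mt2$family == "A"], "GCA")
  expect_true(mt2$tie[mt2$family == "A"])

  missing_lys <- setNames(rep(1, 64), genetic_code()$codon)
  missing_lys[c("AAA", "AAG")] <- 0
  expect_error(major_codon_table(missing_lys),
               class = "codonscope_missing_family")
})

test_that("the per-gene bias profile is consistent with the scalar engines", {
  withr::with_seed(5, {
    gen <- generate_genome(small_config(n_genes = 12L), seed = 9)
  })
  prof <- codon_bias_profile(gen$genes, major_reference())
  expect_equal(nrow(prof), 12)
  cc <- count_codons(gen$genes)
  for (i in c(1, 7)) {
    v <- dplyr::filter(cc, gene_id == gen$genes$gene_id[i])
    expect_equal(prof$complementarity[i],
                 complementarity_index(v[, c("codon", "count")]))
    expect_equal(prof$pi[i], periodicity_index(v[, c("codon", "count")]))
    bi <- bias_indices(v[, c("codon", "count")], major_reference())
    expect_equal(prof$cai[i], bi$cai)
    expect_equal(prof$nc[i], bi$nc)
  }
  expect_true(all(prof$gc > 0 & prof$gc < 1))
  expect_true(all(prof$gc3 > 0 & prof$gc3 < 1))
})
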