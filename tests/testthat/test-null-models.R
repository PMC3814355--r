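test_that("neutral simulation draws from global fractions and preserves protein", {
  g <- genes_tbl(g1 = cds_of("GCT", "GCA", "ATG", "TGG", "TAA"),
                 g2 = cds_of("GCC", "GCG", "ATG", "TAA"))
  fr <- synonymous_fractions(
    setNames(c(1, rep(0, 3), 1, 1, 1), c("GCT", "GCA", "GCC", "GCG",
                                         "ATG", "TGG", "TAA"))
  )
  sim <- simulate_neutral_genome(g, fr, seed = 5)
  cc <- count_codons(sim)
  # {GCT: 1.0} family fraction: every Ala site becomes GCT
  expect_equal(sum(cc$count[cc$codon == "GCT"]), 4)
  expect_equal(sum(cc$count[cc$codon %in% c("GCA", "GCC", "GCG")]), 0)
  # Met/Trp and translation preserved
  expect_equal(translate_oracle(sim$cds), translate_oracle(g$cds))
})

test_that("neutral simulation matches its target fractions at scale", {
  gen <- generate_genome(small_config(n_genes = 500L), seed = 23)
  target <- expected_fractions_from_gc(0.35)
  sim <- simulate_neutral_genome(gen$genes, target, seed = 7)
  emp <- synonymous_fractions(count_codons(sim)[, c("codon", "count")])
  j <- dplyr::inner_join(emp, target, by = c("family", "codon"),
                         suffix = c("_emp", "_exp"))
  j <- j[!j$absent, ]
  se <- sqrt(j$fraction_exp * (1 - j$fraction_exp) / j$family_count)
  # 4 s.e.: family-wise bound over the 64 simultaneous comparisons
  expect_true(all(abs(j$fraction_emp - j$fraction_exp) < 4 * pmax(se, 1e-12)))
  # same seed, same genome
  expect_identical(sim, simulate_neutral_genome(gen$genes, target, seed = 7))
})

test_that("missing families in the fractions are reported", {
  g <- genes_tbl(g1 = cds_of("AAA", "TAA"))
  fr <- synonymous_fractions(c(GCT = 1))
  expect_error(simulate_neutral_genome(g, fr, seed = 1),
               class = "codonscope_missing_family")
})

test_that("z-scores standardise against the null distribution", {
  expect_equal(zscore_vs_null(5, c(4, 5, 6)), 0)
  reps <- c(1, 2, 3, 4, 5)
  expect_equal(zscore_vs_null(mean(reps) + 2 * sd(reps), reps), 2)
  expect_error(zscore_vs_null(1, c(2, 2, 2)),
               class = "codonscope_degenerate_null")
  expect_error(zscore_vs_null(1, 3), class = "codonscope_degenerate_null")
})

test_that("a draw from the null itself rarely exceeds |Z| = 4", {
  # normal-tail oracle: the held-out draw is from the same distribution
  withr::with_seed(31, {
    z <- replicate(400, {
      x <- rnorm(31)
      zscore_vs_null(x[1], x[-1])
    })
  })
  expect_gte(mean(abs(z) < 4), 0.99)
})

test_that("codon shuffling permutes order uniformly and preserves counts", {
  g1 <- genes_tbl(g1 = strrep("GCT", 6))
  expect_equal(shuffle_codons_within_cds(g1, seed = 2)$cds, g1$cds)

  g <- genes_tbl(g1 = cds_of("AAA", "CCC", "GGG", "TTT", "TAA"))
  sh <- shuffle_codons_within_cds(g, seed = 8)
  # the shuffle may move the stop codon inside; counting still matches
  expect_equal(
    sort(suppressWarnings(count_codons(sh))$codon),
    sort(count_codons(g)$codon)
  )

  # uniformity over the 6 orders of a 3-codon gene
  g3 <- genes_tbl(g1 = cds_of("AAA", "CCC", "GGG"))
  n <- 6000
  out <- vapply(seq_len(n), function(i) {
    shuffle_codons_within_cds(g3, seed = i)$cds
  }, character(1))
  freq <- table(out) / n
  expect_equal(length(freq), 6L)
  se <- sqrt((1 / 6) * (5 / 6) / n)
  expect_true(all(abs(freq - 1 / 6) < 3.5 * se))
})

test_that("equalization levels family counts to within one", {
  g <- genes_tbl(g1 = strrep("GCT", 4))
  eq <- equalize_synonymous_frequencies(g, seed = 3)
  cc <- count_codons(eq)
  ala <- cc$count[cc$codon %in% c("GCA", "GCC", "GCG", "GCT")]
  expect_equal(sort(ala), rep(1, 4))

  g2 <- genes_tbl(g1 = strrep("AAA", 5))
  eq2 <- equalize_synonymous_frequencies(g2, seed = 3)
  cc2 <- count_codons(eq2)
  lys <- sort(cc2$count[cc2$codon %in% c("AAA", "AAG")])
  expect_equal(lys, c(2, 3))
  expect_equal(attr(eq2, "n_remainder"), 1L)

  # translation preserved on a mixed genome
  gen <- generate_genome(small_config(n_genes = 40L), seed = 5)
  eq3 <- equalize_synonymous_frequencies(gen$genes, seed = 11)
  expect_equal(translate_oracle(eq3$cds), translate_oracle(gen$genes$cds))
})

test_that("identity exchange preserves fraction multisets and Nc", {
  gen <- generate_genome(small_config(n_genes = 60L), seed = 14)
  ex <- exchange_synonymous_identities(gen$genes, seed = 21, n_draws = 3,
                                       keep_genomes = TRUE)
  # applying the inverse permutation restores the original genome
  tab <- codonscope:::code_tables()
  perm <- ex$permutations[[2]]
  inv <- order(perm)
  slots <- codonscope:::codon_slots(ex$genomes[[2]], keep_text = TRUE)
  text <- slots$text
  ok <- !is.na(slots$codon)
  text[ok] <- tab$codon[inv[slots$codon[ok]]]
  restored <- codonscope:::rebuild_cds(ex$genomes[[2]], slots, text)
  expect_equal(restored$cds, gen$genes$cds)

  # Nc depends only on the fraction multisets, so it is exchange-invariant
  ref <- uniform_reference()
  nc0 <- codon_bias_profile(gen$genes, ref)$nc
  nc1 <- codon_bias_profile(ex$genomes[[1]], ref)$nc
  expect_equal(nc1, nc0)

  # per-gene fraction multisets preserved within each family
  f0 <- synonymous_fractions(count_codons(gen$genes[3, ])[, c("codon", "count")])
  f1 <- synonymous_fractions(count_codons(ex$genomes[[1]][3, ])[, c("codon", "count")])
  for (fam in c("A", "L", "K")) {
    expect_equal(sort(f0$fraction[f0$family == fam]),
                 sort(f1$fraction[f1$family == fam]))
  }

  expect_equal(translate_oracle(ex$genomes[[1]]$cds),
               translate_oracle(gen$genes$cds))
})

test_that("exchanged-identity statistics are averaged over draws", {
  gen <- generate_genome(small_config(n_genes = 30L), seed = 3)
  ex <- exchange_synonymous_identities(gen$genes, seed = 5, n_draws = 4)
  expect_equal(nrow(ex$per_draw), 4)
  expect_equal(
    ex$statistics$complementarity[1],
    mean(vapply(ex$permutations, function(p) {
      m <- codonscope:::codon_count_matrix(gen$genes[1, ])
      codonscope:::complementarity_engine(m[, order(p), drop = FALSE])
    }, numeric(1)))
  )
})

test_that("the random-major-codon null matches exact enumeration on a toy code", {
  # 3 families where complementary choices are possible:
  # rc(TTC)=GAA, rc(TTT)=AAA
  fams <- list(F = c("TTT", "TTC"), E = c("GAA", "GAG"), K = c("AAA", "AAG"))
  # brute-force enumeration over all 8 choices
  grid <- expand.grid(fams, stringsAsFactors = FALSE)
  counts <- apply(grid, 1, function(ch) {
    sum(revcomp_codon(unlist(ch)) %in% unlist(ch))
  })
  exact_p <- mean(counts >= 2)
  mc <- random_major_codon_null(2, n_reps = 20000, seed = 9, families = fams)
  se <- sqrt(exact_p * (1 - exact_p) / mc$n_reps)
  expect_lt(abs(mc$p_value - exact_p), 3 * se)
  # complementary counts always even: codons pair up
  expect_true(all(mc$counts %% 2 == 0))
})

test_that("trivial bounds of the major-codon null hold", {
  mc <- random_major_codon_null(0, n_reps = 50, seed = 1)
  expect_equal(mc$p_value, 1)
  expect_error(random_major_codon_null(19, n_reps = 10, seed = 1),
               class = "codonscope_domain_error")
  expect_error(random_major_codon_null(2, n_reps = 0, seed = 1),
               class = "codonscope_domain_error")
})

test_that("the fast PARS spread null equals an explicit codon shuffle", {
  gen <- generate_genome(small_config(n_genes = 50L), seed = 12)
  pn <- pars_spread_null(gen$genes, gen$pars, n_reps = 1, seed = 33)
  profiled <- gen$genes[gen$genes$gene_id %in% gen$pars$gene_id, ]
  sh <- shuffle_codons_within_cds(profiled, seed = 33)
  ps <- pars_codon_scores(sh, gen$pars)
  expect_equal(pn$null_sd[1], ps$spread_sd_nucleotide)
  expect_equal(pn$native_sd,
               pars_codon_scores(profiled, gen$pars)$spread_sd_nucleotide)
})
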