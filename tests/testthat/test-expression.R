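expr_tbl <- function(...) {
  v <- c(...)
  tibble::tibble(gene_id = names(v), mrna_per_cell = unname(v))
}

test_that("codon expression profile averages host-gene log2 levels", {
  g <- genes_tbl(g1 = cds_of("GCT", "GCT", "TAA"))
  p <- codon_expression_profile(g, expr_tbl(g1 = 8))
  expect_equal(p$mean_log2_level[p$codon == "GCT"], 3)
  expect_equal(p$n[p$codon == "GCT"], 2L)

  g2 <- genes_tbl(g1 = cds_of("GCT", "TAA"), g2 = cds_of("GCT", "TAA"))
  p2 <- codon_expression_profile(g2, expr_tbl(g1 = 2, g2 = 8))
  expect_equal(p2$mean_log2_level[p2$codon == "GCT"], 2) # (1 + 3)/2

  # invariant under gene reordering
  p2r <- codon_expression_profile(g2[2:1, ], expr_tbl(g1 = 2, g2 = 8))
  expect_equal(p2, p2r, ignore_attr = TRUE)

  expect_error(codon_expression_profile(g, expr_tbl(zz = 1)),
               class = "codonscope_empty_join")
})

test_that("genes without expression data are excluded and counted", {
  g <- genes_tbl(g1 = cds_of("GCT", "TAA"), g2 = cds_of("GCA", "TAA"))
  p <- codon_expression_profile(g, expr_tbl(g1 = 4))
  expect_equal(attr(p, "n_genes_excluded"), 1L)
  expect_equal(p$n[p$codon == "GCA"], 0L)
})

test_that("back-calculation reproduces homopolymer genomes exactly", {
  g <- genes_tbl(g1 = strrep("GCT", 10), g2 = strrep("AAA", 10),
                 g3 = strrep("CCG", 10))
  ex <- expr_tbl(g1 = 2, g2 = 8, g3 = 32)
  prof <- codon_expression_profile(g, ex)
  bc <- back_calculate_expression(g, prof, ex)
  expect_equal(bc$r_pearson, 1)
  expect_equal(tidy(bc)$predicted_log2, log2(c(2, 8, 32)))
})

test_that("identical codon composition leaves the correlation undefined", {
  g <- genes_tbl(g1 = strrep("GCT", 5), g2 = strrep("GCT", 5))
  ex <- expr_tbl(g1 = 2, g2 = 8)
  prof <- codon_expression_profile(g, ex)
  expect_error(back_calculate_expression(g, prof, ex),
               class = "codonscope_correlation_undefined")
})

test_that("back-calculated levels are convex combinations of profile means", {
  gen <- generate_genome(small_config(), seed = 4)
  prof <- codon_expression_profile(gen$genes, gen$expression)
  bc <- back_calculate_expression(gen$genes, prof, gen$expression)
  rng <- range(prof$mean_log2_level[prof$n > 0])
  expect_true(all(tidy(bc)$predicted_log2 >= rng[1] - 1e-12))
  expect_true(all(tidy(bc)$predicted_log2 <= rng[2] + 1e-12))
})

test_that("a profile of uncovered codons is rejected", {
  g <- genes_tbl(g1 = cds_of("GCT", "AAA", "TAA"))
  prof <- tibble::tibble(codon = "GCT", mean_log2_level = 1)
  expect_error(back_calculate_expression(g, prof),
               class = "codonscope_missing_score")
})

test_that("expression classes split at 0.5 and 32 mRNA per cell", {
  cls <- classify_genes_by_expression(
    expr_tbl(a = 0.3, b = 5, c = 40, d = 0.5, e = 32)
  )
  got <- setNames(as.character(cls$assignments$class), cls$assignments$gene_id)
  expect_equal(got, c(a = "low", b = "moderate", c = "high",
                      d = "low", e = "moderate"))
})

test_that("class shares sum to one and empty classes are kept", {
  g <- genes_tbl(a = strrep("GCT", 4), b = strrep("GCA", 8))
  cls <- classify_genes_by_expression(expr_tbl(a = 1, b = 2), genes = g)
  s <- cls$summary
  expect_equal(nrow(s), 3) # low kept although empty
  expect_equal(sum(s$share_genes), 1)
  expect_equal(sum(s$share_transcripts), 1)
  expect_equal(sum(s$share_codons), 1)
  expect_equal(s$n_genes[s$class == "low"], 0L)

  one <- classify_genes_by_expression(expr_tbl(a = 1, b = 1))
  expect_equal(sum(one$summary$n_genes > 0), 1)
})

test_that("the mutational-contribution estimator honours its boundary laws", {
  expect_equal(mutational_contribution(c(K = 0.6), c(K = 0.6))$mean_x, 1)
  expect_equal(mutational_contribution(c(K = 1.0), c(K = 0.6))$mean_x, 0)
  expect_equal(mutational_contribution(c(K = 0.64), c(K = 0.60))$mean_x, 0.9)

  # selection opposing mutation: clamped and flagged
  fit <- mutational_contribution(c(K = 0.5), c(K = 0.6))
  expect_true(fit$by_family$clamped)
  expect_equal(fit$by_family$x, 1)

  expect_error(mutational_contribution(c(K = 0.5), c(K = 1)),
               class = "codonscope_degenerate_baseline")
})

test_that("stop-codon usage fractions are per-group normalised", {
  g <- genes_tbl(a = cds_of("GCT", "TAA"), b = cds_of("GCA", "TAA"),
                 c = cds_of("GCC", "TAA"))
  su <- stop_codon_usage(g, expr_tbl(a = 0.2, b = 4, c = 50))
  expect_equal(su$fraction[su$codon == "TAA"], rep(1, 3))
  expect_equal(su$fraction[su$codon != "TAA"], rep(0, 6))
  sums <- tapply(su$fraction, su$group, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("TAA fraction rises across expression bins under the generator", {
  gen <- generate_genome(small_config(n_genes = 1500L), seed = 13)
  su <- stop_codon_usage(gen$genes, gen$expression, by = "bin", n_bins = 8)
  taa <- su[su$codon == "TAA" & !su$absent, ]
  expect_gte(cor(as.integer(as.character(taa$group)), taa$fraction,
                 method = "spearman"), 0.5)
  sums <- tapply(su$fraction[!su$absent], su$group[!su$absent], sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})
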