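test_that("outlier trimming removes floor(trim * n) per tail", {
  expect_equal(length(trim_outliers(rnorm(1000))), 996)
  expect_equal(length(trim_outliers(rnorm(100))), 100)
  v <- c(5, 1, 9, 3, 7)
  expect_equal(trim_outliers(v, trim = 0.2), c(1, 4, 5)) # drops 9 and 1
  # retained set invariant under permutation of input order
  withr::with_seed(2, {
    x <- rnorm(2000)
    p <- sample.int(2000)
  })
  expect_equal(sort(x[trim_outliers(x)]), sort(x[p][trim_outliers(x[p])]))
})

test_that("equal-width bins span the range with an inclusive last edge", {
  b <- equal_width_bins(0:19, k = 20)
  expect_equal(b, 1:20)
  expect_equal(max(equal_width_bins(c(0, 1, 2, 10), k = 5)), 5)
  expect_equal(equal_width_bins(c(0, 10), k = 4), c(1L, 4L))
  expect_error(equal_width_bins(rep(3, 5)),
               class = "codonscope_degenerate_range")
  withr::with_seed(3, {
    v <- runif(500)
  })
  expect_equal(sum(tabulate(equal_width_bins(v), nbins = 20)), 500)
})

test_that("binned fractions pool counts per bin and normalise per family", {
  # identical composition in every gene: flat trajectories
  g <- genes_tbl(a = cds_of("GCT", "GCA", "TAA"), b = cds_of("GCT", "GCA", "TAA"),
                 c = cds_of("GCT", "GCA", "TAA"), d = cds_of("GCT", "GCA", "TAA"))
  prop <- tibble::tibble(gene_id = c("a", "b", "c", "d"), value = 1:4)
  bf <- binned_synonymous_fractions(g, prop, k = 4)
  ala <- bf[bf$codon == "GCT" & !is.na(bf$fraction), ]
  expect_equal(ala$fraction, rep(0.5, 4))

  # per-bin family fractions sum to 1
  sums <- bf |>
    dplyr::filter(!is.na(fraction)) |>
    dplyr::summarise(s = sum(fraction), .by = c("bin", "family"))
  expect_true(all(abs(sums$s - 1) < 1e-12))
})

test_that("all genes in one bin reproduce whole-pool fractions", {
  gen <- generate_genome(small_config(n_genes = 40L), seed = 18)
  prop <- tibble::tibble(gene_id = gen$genes$gene_id,
                         value = c(0, rep(1, 39))) # one gene holds bin 1
  bf <- binned_synonymous_fractions(gen$genes, prop, k = 2, trim = 0)
  pool <- synonymous_fractions(
    count_codons(gen$genes[-1, ])[, c("codon", "count")]
  )
  top <- bf[bf$bin == 2, ]
  expect_equal(top$fraction[match(pool$codon, top$codon)], pool$fraction)
})

test_that("major-codon fractions rise monotonely across expression bins", {
  # realistic gene lengths: short genes leave the rare families too noisy
  gen <- generate_genome(synthetic_genome_config(n_genes = 2500L), seed = 25)
  lev <- tibble::tibble(gene_id = gen$expression$gene_id,
                        log2_level = log2(gen$expression$mrna_per_cell))
  bf <- binned_synonymous_fractions(gen$genes, lev, k = 10)
  majors <- codonscope:::default_major_codons()
  # below the low-expression breakpoint the trajectory is flat by design
  # (mutation-only regime), so the monotone rise is tested above it
  rho <- vapply(majors[c("A", "K", "E", "G")], function(cod) {
    tr <- bf[bf$codon == cod & !is.na(bf$fraction) &
               bf$bin_center > log2(0.5), ]
    cor(tr$bin, tr$fraction, method = "spearman")
  }, numeric(1))
  expect_true(all(rho > 0.9))
  # and the full trajectory is still strongly increasing overall
  full_rho <- vapply(majors[c("A", "K", "E", "G")], function(cod) {
    tr <- bf[bf$codon == cod & !is.na(bf$fraction), ]
    cor(tr$bin, tr$fraction, method = "spearman")
  }, numeric(1))
  expect_true(all(full_rho > 0.7))
})

test_that("coherence of a property with itself is perfect and positive", {
  gen <- generate_genome(small_config(n_genes = 600L), seed = 10)
  lev <- tibble::tibble(gene_id = gen$expression$gene_id,
                        log2_level = log2(gen$expression$mrna_per_cell))
  co <- coherence(gen$genes, lev, lev, k = 10)
  expect_equal(co$call, "positively coherent")
  comp <- co$by_codon[co$by_codon$computable, ]
  expect_true(all(abs(comp$r - 1) < 1e-12))
})

test_that("negating the property reverses trajectories into negative coherence", {
  gen <- generate_genome(synthetic_genome_config(n_genes = 1500L), seed = 10)
  lev <- tibble::tibble(gene_id = gen$expression$gene_id,
                        log2_level = log2(gen$expression$mrna_per_cell))
  neg <- tibble::tibble(gene_id = lev$gene_id, neg_level = -lev$log2_level)
  co <- coherence(gen$genes, lev, neg, k = 10)
  expect_equal(co$call, "negatively coherent")

  # symmetry up to transposition of the two properties
  co_ba <- coherence(gen$genes, neg, lev, k = 10)
  expect_equal(co_ba$by_codon$r, co$by_codon$r)
  expect_equal(co_ba$properties, rev(co$properties))
})

test_that("windowed bias splits codons into near-equal contiguous blocks", {
  ref <- major_reference()
  majors <- codonscope:::default_major_codons()
  # half all-major, half all-minor: Fop 1 then 0 over 2 windows
  g <- genes_tbl(g1 = cds_of(rep(majors[["A"]], 10), rep("GCG", 10)))
  wb <- windowed_codon_bias(g, ref, n_windows = 2)
  expect_equal(wb$fop, c(1, 0))
  expect_equal(wb$n_codons, c(10L, 10L))

  # window counts sum to gene counts, remainders to the earliest windows
  g2 <- genes_tbl(g1 = cds_of(rep("GCT", 11)))
  wb2 <- windowed_codon_bias(g2, ref, n_windows = 3)
  expect_equal(wb2$n_codons, c(4L, 4L, 3L))

  expect_error(windowed_codon_bias(genes_tbl(g1 = "GCTGCA"), ref, n_windows = 5),
               class = "codonscope_too_short")
})

test_that("windows of a homogeneous gene resemble the whole gene", {
  ref <- major_reference()
  withr::with_seed(40, {
    cds <- cds_of(sample(c("GCT", "GCA"), 600, replace = TRUE,
                         prob = c(0.8, 0.2)))
  })
  g <- genes_tbl(g1 = cds)
  whole <- bias_indices(count_codons(g)[, c("codon", "count")], ref)
  wb <- windowed_codon_bias(g, ref, n_windows = 5)
  expect_true(all(abs(wb$fop - whole$fop) < 0.12))
  expect_equal(sum(wb$n_codons), 600L)
})
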