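# PARS-based structural scoring. PARS assigns every transcript nucleotide a
# score for its propensity to be double-stranded; codons are scored two
# ways: by the mean score of their host transcript (PARS-gene) and by the
# mean of their own three nucleotides (PARS-nucleotide). The spread of the
# 64 PARS-nucleotide means over codons is the statistic that the
# codon-shuffle null model calibrates.

#' Build a PARS profile table
#'
#' @param gene_id Character vector of gene ids.
#' @param scores List of numeric vectors, one score per CDS nucleotide.
#' @return A tibble with columns `gene_id` and `score` (list column).
#' @export
pars_profiles <- function(gene_id, scores) {
  if (length(gene_id) != length(scores)) {
    abort("`gene_id` and `scores` lengths differ.",
          class = "codonscope_bad_input")
  }
  tibble(gene_id = as.character(gene_id), score = as.list(scores))
}

# Join genes with profiles and check per-gene alignment. Returns genes
# subset, per-gene score vectors, and the concatenated score vector.
align_profiles <- function(genes, profiles) {
  validate_genes(genes)
  if (!is.data.frame(profiles) ||
      !all(c("gene_id", "score") %in% names(profiles))) {
    abort("`profiles` must have columns `gene_id` and `score` (list).",
          class = "codonscope_bad_input")
  }
  keep <- genes$gene_id %in% profiles$gene_id
  if (!any(keep)) {
    abort("No gene has a PARS profile.", class = "codonscope_empty_join")
  }
  g <- genes[keep, , drop = FALSE]
  sc <- profiles$score[match(g$gene_id, profiles$gene_id)]
  len_cds <- nchar(g$cds)
  len_sc <- lengths(sc)
  bad <- len_sc != len_cds
  if (any(bad)) {
    abort(paste0("PARS profile length does not match CDS length for gene(s): ",
                 paste(head(g$gene_id[bad], 5), collapse = ", ")),
          class = "codonscope_alignment_error")
  }
  list(genes = g, scores = sc, flat = unlist(sc, use.names = FALSE))
}

pop_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' PARS-gene and PARS-nucleotide codon scores
#'
#' For every codon occurrence in the profiled genes, two structural scores
#' are attached: the mean PARS score of the whole host transcript
#' (PARS-gene) and the mean of the occurrence's own three nucleotides
#' (PARS-nucleotide). Averaging over all occurrences gives the per-codon
#' scores; the spread (population s.d. over observed codons, unweighted) of
#' the PARS-gene means is necessarily small compared with the
#' PARS-nucleotide spread whenever scores vary within transcripts, and the
#' excess of the native PARS-nucleotide spread over its codon-shuffle null
#' ([pars_spread_null()]) measures how non-randomly codons sit in locally
#' structured regions.
#'
#' @param genes A data frame with columns `gene_id` and `cds`.
#' @param profiles PARS profiles ([pars_profiles()] or [read_pars_profiles()]);
#'   each profile must align to its gene's CDS length exactly.
#' @return An object of class `codon_pars`: list with `scores` (tibble
#'   `codon`, `aa`, `pars_gene`, `pars_nucleotide`, `n`), `spread_sd_gene`,
#'   `spread_sd_nucleotide`, `n_genes`, `codons_missing`. `tidy()` returns
#'   the score table, `glance()` the spreads.
#' @export
pars_codon_scores <- function(genes, profiles) {
  al <- align_profiles(genes, profiles)
  tab <- code_tables()
  slots <- codon_slots(al$genes)
  s <- al$flat
  # per-slot 3-nt mean and host-gene mean
  i3 <- 3 * seq_along(slots$gene)
  slot_mean <- (s[i3 - 2] + s[i3 - 1] + s[i3]) / 3
  gene_mean <- vapply(al$scores, mean, numeric(1))
  ok <- !is.na(slots$codon)
  lab <- slots$codon[ok]
  cnts <- tabulate(lab, nbins = 64L)
  pg <- ifelse(cnts > 0,
               tabulate_sum(lab, gene_mean[slots$gene[ok]], 64L) / cnts,
               NA_real_)
  pn <- ifelse(cnts > 0, tabulate_sum(lab, slot_mean[ok], 64L) / cnts,
               NA_real_)
  structure(
    list(
      scores = tibble(codon = tab$codon, aa = tab$aa,
                      pars_gene = pg, pars_nucleotide = pn, n = cnts),
      spread_sd_gene = pop_sd(pg),
      spread_sd_nucleotide = pop_sd(pn),
      n_genes = nrow(al$genes),
      codons_missing = tab$codon[cnts == 0]
    ),
    class = "codon_pars"
  )
}

#' @export
tidy.codon_pars <- function(x, ...) x$scores

#' @export
glance.codon_pars <- function(x, ...) {
  tibble(spread_sd_gene = x$spread_sd_gene,
         spread_sd_nucleotide = x$spread_sd_nucleotide,
         n_genes = x$n_genes,
         n_codons_missing = length(x$codons_missing))
}

#' @export
print.codon_pars <- function(x, ...) {
  cat("PARS codon scores over", x$n_genes, "profiled genes\n")
  cat("spread s.d.: PARS-gene", format(x$spread_sd_gene, digits = 3),
      "| PARS-nucleotide", format(x$spread_sd_nucleotide, digits = 3), "\n")
  invisible(x)
}

#' Mean PARS score of the four nucleotides
#'
#' The mean score of each base over all profiled CDS positions, and the
#' per-codon score estimated as the mean of its three base means — the
#' nucleotide-composition predictor of the PARS-nucleotide codon scores.
#'
#' @inheritParams pars_codon_scores
#' @return An object of class `pars_base_means`: list with `base_means`
#'   (tibble `base`, `mean`, `n`; a base absent from all profiles is flagged)
#'   and `codon_estimates` (tibble `codon`, `estimate`). `tidy()` returns the
#'   codon estimates, `glance()` the base means in one row.
#' @export
nucleotide_pars_means <- function(genes, profiles) {
  al <- align_profiles(genes, profiles)
  tab <- code_tables()
  nt <- strsplit(toupper(paste(al$genes$cds, collapse = "")), "", fixed = TRUE)[[1]]
  idx <- match(nt, c("A", "C", "G", "T"))
  ok <- !is.na(idx)
  sums <- tabulate_sum(idx[ok], al$flat[ok], 4L)
  cnts <- tabulate(idx[ok], nbins = 4L)
  means <- ifelse(cnts > 0, sums / cnts, NA_real_)
  base_means <- tibble(base = c("A", "C", "G", "T"), mean = means, n = cnts,
                       missing = cnts == 0)
  if (any(base_means$missing)) {
    warn(paste0("Base(s) absent from all profiles: ",
                paste(base_means$base[base_means$missing], collapse = ", ")))
  }
  est <- (means[tab$base_index[, 1]] + means[tab$base_index[, 2]] +
            means[tab$base_index[, 3]]) / 3
  structure(
    list(base_means = base_means,
         codon_estimates = tibble(codon = tab$codon, estimate = est)),
    class = "pars_base_means"
  )
}

#' @export
tidy.pars_base_means <- function(x, ...) x$codon_estimates

#' @export
glance.pars_base_means <- function(x, ...) {
  out <- as.list(setNames(x$base_means$mean, x$base_means$base))
  as_tibble(out)
}

#' Estimate per-codon PARS scores from base means
#'
#' @param base_means A tibble with columns `base` (`A`,`C`,`G`,`T`) and
#'   `mean`, e.g. published genome-wide base scores.
#' @return A tibble `codon`, `estimate` (mean of the three base means).
#' @export
#' @examples
#' bm <- tibble::tibble(base = c("A", "C", "G", "T"),
#'                      mean = c(0.034, 0.844, 0.026, 0.540))
#' estimate_codon_pars(bm) # GAC: (0.026 + 0.034 + 0.844)/3
estimate_codon_pars <- function(base_means) {
  tab <- code_tables()
  v <- setNames(base_means$mean, base_means$base)[c("A", "C", "G", "T")]
  est <- (v[tab$base_index[, 1]] + v[tab$base_index[, 2]] +
            v[tab$base_index[, 3]]) / 3
  tibble(codon = tab$codon, estimate = unname(est))
}

#' Predict transcript PARS from codon scores
#'
#' The expected PARS score of each transcript: the mean, over its codons, of
#' the per-codon PARS-nucleotide means. Equals the codon-count-weighted
#' average of the scores.
#'
#' @param genes A data frame with columns `gene_id` and `cds`.
#' @param scores A `codon_pars` object or a tibble with columns `codon` and
#'   `pars_nucleotide` covering every codon present.
#' @return A tibble `gene_id`, `predicted_pars`, `n_codons`.
#' @export
predict_transcript_pars <- function(genes, scores) {
  validate_genes(genes)
  if (inherits(scores, "codon_pars")) scores <- scores$scores
  tab <- code_tables()
  sv <- rep(NA_real_, 64)
  sv[match(scores$codon, tab$codon)] <- scores$pars_nucleotide
  slots <- codon_slots(genes)
  ok <- !is.na(slots$codon)
  used <- sort(unique(slots$codon[ok]))
  if (anyNA(sv[used])) {
    abort(paste0("No PARS-nucleotide score for codon(s): ",
                 paste(tab$codon[used][is.na(sv[used])], collapse = ", ")),
          class = "codonscope_missing_score")
  }
  n_gene <- nrow(genes)
  sums <- tabulate_sum(slots$gene[ok], sv[slots$codon[ok]], n_gene)
  cnts <- tabulate(slots$gene[ok], nbins = n_gene)
  tibble(gene_id = genes$gene_id,
         predicted_pars = ifelse(cnts > 0, sums / cnts, NA_real_),
         n_codons = cnts)
}

#' Correlate intron folding energy with gene properties
#'
#' Pearson and Spearman correlations (with two-sided p-values) between the
#' minimum folding free energy of introns (kcal/mol, consumed as
#' precomputed input) and each supplied per-gene property, plus intron
#' length. Computed on the intersection of gene ids; pairs with fewer than
#' 3 complete observations raise an error, constant vectors are flagged
#' undefined rather than correlated.
#'
#' @param introns A data frame with columns `gene_id`, `length`, `delta_g`.
#' @param gene_properties A data frame with `gene_id` and one or more numeric
#'   property columns (e.g. `mrna_per_cell`, `cai`, `cds_length`).
#' @return A tibble with one row per property: `property`, `n`,
#'   `pearson_r`, `pearson_p`, `spearman_rho`, `spearman_p`, `undefined`.
#' @export
intron_structure_association <- function(introns, gene_properties) {
  if (!is.data.frame(introns) ||
      !all(c("gene_id", "length", "delta_g") %in% names(introns))) {
    abort("`introns` must have columns `gene_id`, `length`, `delta_g`.",
          class = "codonscope_bad_input")
  }
  if (any(!is.finite(introns$delta_g))) {
    abort("`delta_g` must be finite.", class = "codonscope_bad_input")
  }
  props <- as_tibble(gene_properties)
  num_cols <- setdiff(names(props)[vapply(props, is.numeric, logical(1))],
                      "gene_id")
  df <- introns |>
    select("gene_id", intron_length = "length", "delta_g") |>
    left_join(props, by = "gene_id")
  targets <- c(num_cols, "intron_length")
  rows <- lapply(targets, function(p) {
    cc <- stats::complete.cases(df$delta_g, df[[p]])
    x <- df$delta_g[cc]
    y <- df[[p]][cc]
    if (length(x) < 3) {
      abort(paste0("Fewer than 3 complete intron/property pairs for `", p, "`."),
            class = "codonscope_insufficient_data")
    }
    undefined <- sd(x) == 0 || sd(y) == 0
    if (undefined) {
      return(tibble(property = p, n = length(x),
                    pearson_r = NA_real_, pearson_p = NA_real_,
                    spearman_rho = NA_real_, spearman_p = NA_real_,
                    undefined = TRUE))
    }
    pe <- cor.test(x, y, method = "pearson")
    sp <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    tibble(property = p, n = length(x),
           pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
           spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
           undefined = FALSE)
  })
  bind_rows(rows)
}
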