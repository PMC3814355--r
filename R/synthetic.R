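# Synthetic genomes with known ground truth. The generator emulates the
# statistical structure the analysis assumes in a compact yeast-like
# genome: log-normal transcript levels; codon usage drawn per synonymous
# site from a mixture of GC-driven fractions and a major-codon spike whose
# weight s is 0 for lowly transcribed genes, rises linearly in log2 level
# between the class breakpoints, and saturates at s_max; per-nucleotide
# structure scores with a base-composition term plus an expression-linked
# gene offset; introns whose length (and hence folding energy) grows with
# expression; stop usage shifting toward TAA; protein output superlinear in
# mRNA; and a tRNA table adapted to major codons under wobble rules.

default_major_codons <- function() {
  # Real-yeast-like majors; 10 of the 18 form 5 reverse-complement pairs
  # (TTC/GAA, CAA/TTG, GGT/ACC, GTC/GAC, AGA/TCT), and the stop "major" is
  # TAA.
  c(F = "TTC", E = "GAA", Q = "CAA", L = "TTG", G = "GGT", T = "ACC",
    V = "GTC", D = "GAC", R = "AGA", S = "TCT", I = "ATC", A = "GCT",
    P = "CCA", Y = "TAC", H = "CAC", N = "AAC", K = "AAG", C = "TGT",
    "*" = "TAA")
}

#' Configuration for the synthetic-genome generator
#'
#' All defaults define the study conditions the analyses are validated
#' under; see the methods vignette for the rationale behind each value.
#'
#' @param n_genes Number of genes.
#' @param log2_level_mean,log2_level_sd Normal parameters of log2 mRNA/cell
#'   (i.e. levels are log-normal).
#' @param gc Mutational GC content driving the neutral codon fractions.
#' @param length_min,length_shape,length_scale Sense-codon count per gene:
#'   `length_min` plus a Gamma(shape, scale) draw, rounded.
#' @param aa_weights Named amino-acid sampling weights; default uniform over
#'   the 18 degenerate families with Met/Trp at 0.01 each.
#' @param major_codons Named map family -> major codon (must include `*`);
#'   the default contains five reverse-complement pairs.
#' @param low_max,high_min Expression breakpoints (mRNA/cell) between which
#'   the selection weight rises linearly.
#' @param s_max Maximum selection weight in \[0, 1\].
#' @param pars_fraction Fraction of genes given a PARS profile.
#' @param pars_base_means Per-base mean structure scores.
#' @param pars_level_slope Gene offset per unit log2 level.
#' @param pars_noise_sd Per-nucleotide score noise s.d.
#' @param intron_fraction Fraction of genes carrying one intron.
#' @param intron_length_intercept,intron_length_slope,intron_length_sd,intron_length_min
#'   Intron length (nt) model: intercept + slope * log2 level + noise,
#'   clamped at the minimum.
#' @param intron_dg_per_nt,intron_dg_sd Folding energy model:
#'   delta G = -(per-nt coefficient) * length + noise, kcal/mol.
#' @param protein_exponent,protein_noise_sd_log2 Protein/cell model:
#'   level^exponent times log-normal noise.
#' @param trna_excluded_anticodons Watson-Crick anticodons absent from the
#'   genome (their majors are decoded by wobble instead).
#' @param trna_scale Scale of tRNA gene-copy numbers.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_genome_config <- function(
    n_genes = 6400L,
    log2_level_mean = -0.5, log2_level_sd = 2,
    gc = 0.35,
    length_min = 60L, length_shape = 3, length_scale = 130,
    aa_weights = NULL,
    major_codons = default_major_codons(),
    low_max = 0.5, high_min = 32, s_max = 0.9,
    pars_fraction = 0.5,
    pars_base_means = c(A = 0.034, C = 0.844, G = 0.026, T = 0.540),
    pars_level_slope = 0.15, pars_noise_sd = 0.5,
    intron_fraction = 0.05,
    intron_length_intercept = 120, intron_length_slope = 25,
    intron_length_sd = 40, intron_length_min = 30,
    intron_dg_per_nt = 0.3, intron_dg_sd = 5,
    protein_exponent = 1.3, protein_noise_sd_log2 = 1,
    trna_excluded_anticodons = c("ACA", "ACC"),
    trna_scale = 10) {
  tab <- code_tables()
  if (is.null(aa_weights)) {
    aa_weights <- setNames(rep(0.98 / 18, 18), tab$degenerate_aa)
    aa_weights[c("M", "W")] <- 0.01
  }
  cfg <- list(
    n_genes = as.integer(n_genes),
    log2_level_mean = log2_level_mean, log2_level_sd = log2_level_sd,
    gc = gc,
    length_min = as.integer(length_min), length_shape = length_shape,
    length_scale = length_scale,
    aa_weights = aa_weights, major_codons = major_codons,
    low_max = low_max, high_min = high_min, s_max = s_max,
    pars_fraction = pars_fraction, pars_base_means = pars_base_means,
    pars_level_slope = pars_level_slope, pars_noise_sd = pars_noise_sd,
    intron_fraction = intron_fraction,
    intron_length_intercept = intron_length_intercept,
    intron_length_slope = intron_length_slope,
    intron_length_sd = intron_length_sd,
    intron_length_min = intron_length_min,
    intron_dg_per_nt = intron_dg_per_nt, intron_dg_sd = intron_dg_sd,
    protein_exponent = protein_exponent,
    protein_noise_sd_log2 = protein_noise_sd_log2,
    trna_excluded_anticodons = trna_excluded_anticodons,
    trna_scale = trna_scale
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  fail <- function(msg) abort(msg, class = "codonscope_config_error")
  if (cfg$n_genes < 1) fail("n_genes must be positive.")
  if (cfg$gc <= 0 || cfg$gc >= 1) fail("gc must be in (0, 1).")
  if (!(cfg$low_max > 0 && cfg$low_max < cfg$high_min)) {
    fail("Need 0 < low_max < high_min.")
  }
  if (cfg$s_max < 0 || cfg$s_max > 1) fail("s_max must be in [0, 1].")
  if (cfg$pars_fraction < 0 || cfg$pars_fraction > 1) {
    fail("pars_fraction must be in [0, 1].")
  }
  if (cfg$intron_fraction < 0 || cfg$intron_fraction > 1) {
    fail("intron_fraction must be in [0, 1].")
  }
  tab <- code_tables()
  need <- c(tab$degenerate_aa, "*")
  if (!all(need %in% names(cfg$major_codons))) {
    fail("major_codons must name every degenerate family and `*`.")
  }
  wrong <- vapply(need, function(a) {
    !(cfg$major_codons[[a]] %in% tab$family[[a]])
  }, logical(1))
  if (any(wrong)) {
    fail(paste0("major_codons not in their family: ",
                paste(need[wrong], collapse = ", ")))
  }
  if (!all(c("A", "C", "G", "T") %in% names(cfg$pars_base_means))) {
    fail("pars_base_means must name A, C, G, T.")
  }
  nums <- unlist(cfg[vapply(cfg, is.numeric, logical(1))], use.names = FALSE)
  if (any(!is.finite(nums))) fail("All numeric config entries must be finite.")
  invisible(cfg)
}

# Piecewise-linear selection weight in log2 level.
selection_weight <- function(level, cfg) {
  lo <- log2(cfg$low_max)
  hi <- log2(cfg$high_min)
  s <- cfg$s_max * (log2(level) - lo) / (hi - lo)
  pmin(pmax(s, 0), cfg$s_max)
}

#' Generate a synthetic genome with known truth
#'
#' Draws a complete synthetic data set — coding sequences, expression table,
#' PARS profiles, intron records, tRNA gene-copy table, protein table — from
#' the generative model of [synthetic_genome_config()], together with the
#' hidden parameters (`truth`) that recovery tests check against.
#' Bit-reproducible given (config, seed).
#'
#' @param config A `synthetic_config`.
#' @param seed Integer seed.
#' @return An object of class `synthetic_genome`: list with `genes`,
#'   `expression`, `pars`, `introns`, `trna`, `protein`, `truth`, `config`,
#'   `seed`.
#' @export
generate_genome <- function(config = synthetic_genome_config(), seed = 1L) {
  if (!inherits(config, "synthetic_config")) {
    abort("`config` must come from synthetic_genome_config().",
          class = "codonscope_config_error")
  }
  cfg <- config
  tab <- code_tables()
  gc_frac <- fraction_vector(expected_fractions_from_gc(cfg$gc))
  major_idx <- match(cfg$major_codons, tab$codon)
  names(major_idx) <- names(cfg$major_codons)
  withr::with_seed(seed, {
    n <- cfg$n_genes
    gene_id <- sprintf("g%05d", seq_len(n))
    log2lev <- rnorm(n, cfg$log2_level_mean, cfg$log2_level_sd)
    level <- 2^log2lev
    s <- selection_weight(level, cfg)
    len <- cfg$length_min + round(rgamma(n, cfg$length_shape, scale = cfg$length_scale))
    # amino acids for all sense sites at once
    g_site <- rep.int(seq_len(n), len)
    aa_site <- sample(names(cfg$aa_weights), sum(len), replace = TRUE,
                      prob = cfg$aa_weights)
    codon_site <- integer(sum(len))
    for (a in unique(aa_site)) {
      sel <- which(aa_site == a)
      idx <- tab$family_index[[a]]
      if (length(idx) == 1L) {
        codon_site[sel] <- idx
        next
      }
      prob <- outer(1 - s[g_site[sel]], gc_frac[idx])
      prob[, match(major_idx[[a]], idx)] <-
        prob[, match(major_idx[[a]], idx)] + s[g_site[sel]]
      codon_site[sel] <- draw_from_family(idx, prob)
    }
    # terminal stop: GC-driven fractions spiked toward the TAA "major"
    stop_idx <- tab$family_index[["*"]]
    prob_stop <- outer(1 - s, gc_frac[stop_idx])
    prob_stop[, match(major_idx[["*"]], stop_idx)] <-
      prob_stop[, match(major_idx[["*"]], stop_idx)] + s
    stop_site <- draw_from_family(stop_idx, prob_stop)
    body <- vapply(split(tab$codon[codon_site], g_site), paste, character(1),
                   collapse = "")
    genes <- tibble(gene_id = gene_id,
                    cds = paste0(body, tab$codon[stop_site]))
    expression <- tibble(gene_id = gene_id, mrna_per_cell = level)
    # PARS: base mean + expression-linked gene offset + noise, per nucleotide
    n_pars <- round(cfg$pars_fraction * n)
    pars_rows <- sort(sample.int(n, n_pars))
    pars <- tibble(gene_id = character(0), score = list())
    if (n_pars > 0) {
      nt <- strsplit(paste(genes$cds[pars_rows], collapse = ""), "",
                     fixed = TRUE)[[1]]
      nt_idx <- match(nt, c("A", "C", "G", "T"))
      g_nt <- rep.int(seq_len(n_pars), nchar(genes$cds[pars_rows]))
      score <- cfg$pars_base_means[c("A", "C", "G", "T")][nt_idx] +
        cfg$pars_level_slope * log2lev[pars_rows][g_nt] +
        rnorm(length(nt_idx), 0, cfg$pars_noise_sd)
      pars <- pars_profiles(genes$gene_id[pars_rows],
                            split(unname(score), g_nt))
    }
    # introns: length rises with expression, folding energy with length
    n_int <- round(cfg$intron_fraction * n)
    intron_rows <- sort(sample.int(n, n_int))
    ilen <- pmax(cfg$intron_length_min,
                 round(cfg$intron_length_intercept +
                         cfg$intron_length_slope * log2lev[intron_rows] +
                         rnorm(n_int, 0, cfg$intron_length_sd)))
    idg <- -cfg$intron_dg_per_nt * ilen + rnorm(n_int, 0, cfg$intron_dg_sd)
    iseq <- vapply(ilen, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                   prob = c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2,
                            (1 - cfg$gc) / 2)),
            collapse = "")
    }, character(1))
    introns <- tibble(gene_id = gene_id[intron_rows], length = ilen,
                      delta_g = idg, sequence = iseq)
    # protein: superlinear in mRNA with log-normal noise
    protein <- tibble(
      gene_id = gene_id,
      protein_per_cell = level^cfg$protein_exponent *
        2^rnorm(n, 0, cfg$protein_noise_sd_log2)
    )
    trna <- synthetic_trna_table(cfg, codon_site, stop_site, major_idx)
  })
  n_deg_gene <- tabulate(g_site[tab$family_size[codon_site] >= 2], nbins = n)
  truth <- structure(
    list(
      per_gene = tibble(
        gene_id = gene_id, mrna_per_cell = level, log2_level = log2lev,
        s = s, n_codons = len + 1L, n_degenerate = n_deg_gene,
        has_pars = seq_len(n) %in% pars_rows,
        has_intron = seq_len(n) %in% intron_rows
      ),
      mutational_share = 1 - sum(s * n_deg_gene) / sum(n_deg_gene),
      config = cfg, seed = seed
    ),
    class = "synthetic_truth"
  )
  structure(
    list(genes = genes, expression = expression, pars = pars,
         introns = introns, trna = trna, protein = protein,
         truth = truth, config = cfg, seed = seed),
    class = "synthetic_genome"
  )
}

# tRNA gene copies adapted to major-codon usage: Watson-Crick anticodon of
# each family's major codon, wobble fallback where the WC anticodon is
# excluded; copies scale with the major codon's genome-wide usage.
synthetic_trna_table <- function(cfg, codon_site, stop_site, major_idx) {
  tab <- code_tables()
  fams <- c(tab$degenerate_aa, "M", "W")
  cnt <- tabulate(codon_site, nbins = 64L)
  rows <- lapply(fams, function(a) {
    cod <- if (a %in% c("M", "W")) tab$family[[a]] else
      tab$codon[major_idx[[a]]]
    anti <- revcomp_codon(cod)
    if (anti %in% cfg$trna_excluded_anticodons) {
      anti <- wobble_anticodon(cod)
      if (is.na(anti)) {
        abort(paste0("Major codon ", cod, " (", a, ") has its Watson-Crick ",
                     "anticodon excluded and no wobble decoder."),
              class = "codonscope_config_error")
      }
    }
    usage <- cnt[match(cod, tab$codon)]
    tibble(aa = a, codon = cod, anticodon = anti,
           pairing = classify_pairing(cod, anti),
           gene_copies = max(1L, round(cfg$trna_scale * usage /
                                         max(mean(cnt[cnt > 0]), 1))))
  })
  bind_rows(rows)
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("Synthetic genome:", nrow(x$genes), "genes ( seed", x$seed, ")\n")
  cat(" ", nrow(x$pars), "PARS profiles,", nrow(x$introns), "introns,",
      nrow(x$trna), "tRNA species\n")
  cat("  true mutational share:",
      format(x$truth$mutational_share, digits = 3), "\n")
  invisible(x)
}

#' Serialize the generator's hidden parameters
#'
#' One row per gene with its level, selection weight and bookkeeping
#' columns, for recovery tests. Global model parameters travel in the
#' `params` attribute; with `path`, the table is written as TSV.
#'
#' @param truth A `synthetic_truth` (from `generate_genome()$truth`).
#' @param path Optional TSV output path.
#' @return The per-gene tibble (invisibly when written to `path`).
#' @export
truth_report <- function(truth, path = NULL) {
  if (!inherits(truth, "synthetic_truth")) {
    abort("`truth` must be a synthetic_truth.", class = "codonscope_bad_input")
  }
  out <- truth$per_gene
  attr(out, "params") <- c(
    truth$config[vapply(truth$config, function(x)
      is.numeric(x) && length(x) == 1, logical(1))],
    list(mutational_share = truth$mutational_share, seed = truth$seed)
  )
  if (!is.null(path)) {
    readr::write_tsv(out, path)
    return(invisible(out))
  }
  out
}
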