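# The four sequence-randomization null models, plus the random-major-codon
# complementarity test and Z-score machinery. Every simulator preserves the
# translated amino-acid sequence (including the stop) of every gene and is
# bit-reproducible given (input, seed): randomness runs in one seeded stream
# (withr::with_seed) with genes processed in input row order. Codon slots
# containing non-ACGT letters are left untouched by all simulators.

# Rebuild CDS strings from per-slot codon text.
rebuild_cds <- function(genes, slots, codon_text) {
  pieces <- split(codon_text, slots$gene)
  out <- genes
  out$cds[as.integer(names(pieces))] <-
    vapply(pieces, paste, character(1), collapse = "")
  out
}

# Draw one codon per slot from its family under per-slot probability rows.
# fam_idx: codon indices of the family; prob: matrix (n_slots x k).
draw_from_family <- function(fam_idx, prob) {
  k <- length(fam_idx)
  if (k == 1) return(rep(fam_idx, nrow(prob)))
  cum <- prob %*% upper.tri(diag(k), diag = TRUE)
  u <- runif(nrow(prob)) * cum[, k]
  pick <- k + 1L - as.integer(rowSums(u <= cum))
  fam_idx[pick]
}

#' Simulate a neutral genome
#'
#' Replaces every codon at a synonymous site by an independent draw from its
#' family with the supplied global fractions (by default, the genome's own
#' pooled synonymous fractions), leaving the amino-acid sequence — including
#' the stop — and any expression assignment untouched. This is the neutral
#' (mutational-only) model: codon choice independent of expression.
#'
#' @param genes A data frame with columns `gene_id` and `cds`.
#' @param fractions A fractions tibble ([synonymous_fractions()]) covering
#'   every family present; `NULL` for the genome's own pooled fractions.
#' @param seed Integer seed.
#' @return `genes` with resampled `cds`.
#' @export
simulate_neutral_genome <- function(genes, fractions = NULL, seed = 1L) {
  tab <- code_tables()
  slots <- codon_slots(genes, keep_text = TRUE)
  if (is.null(fractions)) {
    fractions <- synonymous_fractions(
      tibble(codon = tab$codon,
             count = tabulate(slots$codon[!is.na(slots$codon)], nbins = 64L))
    )
  }
  fv <- fraction_vector(fractions)
  ok <- !is.na(slots$codon)
  aa_here <- unique(tab$aa[slots$codon[ok]])
  miss <- aa_here[vapply(aa_here, function(a) {
    anyNA(fv[tab$family_index[[a]]]) || sum(fv[tab$family_index[[a]]]) <= 0
  }, logical(1))]
  if (length(miss) > 0) {
    abort(paste0("Fractions missing for family(ies): ",
                 paste(miss, collapse = ", ")),
          class = "codonscope_missing_family")
  }
  text <- slots$text
  withr::with_seed(seed, {
    for (a in aa_here) {
      idx <- tab$family_index[[a]]
      sel <- which(ok)[tab$aa[slots$codon[ok]] == a]
      if (length(idx) == 1L) next
      prob <- matrix(fv[idx], nrow = length(sel), ncol = length(idx),
                     byrow = TRUE)
      text[sel] <- tab$codon[draw_from_family(idx, prob)]
    }
  })
  rebuild_cds(genes, slots, text)
}

#' Z-score of a native statistic against null replicates
#'
#' @param native The statistic on the native data.
#' @param replicates Numeric vector of the statistic on null replicates
#'   (at least 2, with nonzero s.d.).
#' @return `(native - mean(replicates)) / sd(replicates)`.
#' @export
zscore_vs_null <- function(native, replicates) {
  if (length(replicates) < 2) {
    abort("Need at least 2 null replicates.",
          class = "codonscope_degenerate_null")
  }
  s <- sd(replicates)
  if (!is.finite(s) || s == 0) {
    abort("Null replicates have zero spread: Z undefined.",
          class = "codonscope_degenerate_null")
  }
  (native - mean(replicates)) / s
}

#' Shuffle codon order within each CDS
#'
#' Uniform random permutation of the codons of every gene (Fisher-Yates, as
#' implemented by R's `sample()`), preserving each gene's codon multiset and
#' hence every count-based statistic.
#'
#' @inheritParams simulate_neutral_genome
#' @return `genes` with codon order permuted within each `cds`.
#' @export
shuffle_codons_within_cds <- function(genes, seed = 1L) {
  slots <- codon_slots(genes, keep_text = TRUE)
  withr::with_seed(seed, {
    ord <- order(slots$gene, runif(length(slots$gene)))
  })
  rebuild_cds(genes, slots, slots$text[ord])
}

#' Equalize synonymous codon frequencies within each CDS
#'
#' Rewrites every gene so that, within each synonymous family, codon counts
#' differ by at most one: each of the k family members receives floor(n/k)
#' sites and the n mod k remainder sites go to a seeded random choice of
#' distinct members (flagged in the `n_remainder` attribute). Which sites
#' receive which codon is a seeded shuffle; the amino-acid sequence is
#' preserved exactly. This deletes codon bias while keeping composition.
#'
#' @inheritParams simulate_neutral_genome
#' @return `genes` with equalized `cds`; attribute `n_remainder` counts
#'   gene-family combinations whose counts were not exactly divisible.
#' @export
equalize_synonymous_frequencies <- function(genes, seed = 1L) {
  tab <- code_tables()
  slots <- codon_slots(genes, keep_text = TRUE)
  text <- slots$text
  ok <- which(!is.na(slots$codon))
  aa_slot <- tab$aa[slots$codon[ok]]
  key <- paste(slots$gene[ok], aa_slot)
  groups <- split(ok, key)
  n_rem <- 0L
  withr::with_seed(seed, {
    for (grp in groups) {
      a <- tab$aa[slots$codon[grp[1]]]
      idx <- tab$family_index[[a]]
      k <- length(idx)
      if (k == 1L) next
      n <- length(grp)
      base <- n %/% k
      r <- n %% k
      multiset <- rep(idx, base)
      if (r > 0) {
        n_rem <- n_rem + 1L
        multiset <- c(multiset, sample(idx, r))
      }
      text[grp] <- tab$codon[multiset[sample.int(n)]]
    }
  })
  out <- rebuild_cds(genes, slots, text)
  attr(out, "n_remainder") <- n_rem
  out
}

# One uniform random permutation per family (codon index -> codon index).
random_identity_permutation <- function(include_stop = FALSE) {
  tab <- code_tables()
  fams <- tab$degenerate_aa
  if (include_stop) fams <- c(fams, "*")
  perm <- seq_len(64L)
  for (a in fams) {
    idx <- tab$family_index[[a]]
    perm[idx] <- idx[sample.int(length(idx))]
  }
  perm
}

#' Exchange synonymous codon identities genome-wide
#'
#' Per draw, one uniform random permutation per synonymous family is applied
#' identically to every gene (e.g. all GGA become GGG, all GGC become GGT,
#' ...), preserving each gene's within-family fraction multiset — and hence
#' Nc — while re-assigning which codon identity carries which frequency.
#' The complementarity and periodicity statistics are computed per gene for
#' each draw and averaged over draws; comparing them with the native values
#' isolates the effect of the specific identities of major and minor codons
#' from the magnitude of codon bias.
#'
#' @inheritParams simulate_neutral_genome
#' @param n_draws Number of independent identity-exchange draws (default 20).
#' @param include_stop Also permute the stop family (off by default; the
#'   exchange analysis targets sense codons).
#' @param keep_genomes Return the exchanged gene tables (one per draw).
#' @return An object of class `identity_exchange`: list with `statistics`
#'   (tibble `gene_id`, `complementarity`, `pi` — averages over draws),
#'   `native` (same statistics on the input), `per_draw` (tibble `draw`,
#'   `mean_complementarity`, `mean_pi`), `permutations`, and optionally
#'   `genomes`. `tidy()` returns the per-gene averages joined with native
#'   values, `glance()` the draw-level summary.
#' @export
exchange_synonymous_identities <- function(genes, seed = 1L, n_draws = 20L,
                                           include_stop = FALSE,
                                           keep_genomes = FALSE) {
  tab <- code_tables()
  slots <- codon_slots(genes, keep_text = TRUE)
  m <- codon_count_matrix(genes, slots)
  comp_sum <- numeric(nrow(genes))
  pi_sum <- numeric(nrow(genes))
  per_draw <- vector("list", n_draws)
  perms <- vector("list", n_draws)
  genomes <- if (keep_genomes) vector("list", n_draws) else NULL
  withr::with_seed(seed, {
    for (d in seq_len(n_draws)) {
      perm <- random_identity_permutation(include_stop)
      perms[[d]] <- perm
      inv <- order(perm) # new count of codon c = old count of perm^{-1}(c)
      md <- m[, inv, drop = FALSE]
      comp <- unname(complementarity_engine(md))
      pis <- unname(periodicity_engine(md))
      comp_sum <- comp_sum + comp
      pi_sum <- pi_sum + pis
      per_draw[[d]] <- tibble(draw = d,
                              mean_complementarity = mean(comp, na.rm = TRUE),
                              mean_pi = mean(pis, na.rm = TRUE))
      if (keep_genomes) {
        ok <- !is.na(slots$codon)
        text <- slots$text
        text[ok] <- tab$codon[perm[slots$codon[ok]]]
        genomes[[d]] <- rebuild_cds(genes, slots, text)
      }
    }
  })
  out <- structure(
    list(
      statistics = tibble(gene_id = genes$gene_id,
                          complementarity = comp_sum / n_draws,
                          pi = pi_sum / n_draws),
      native = tibble(gene_id = genes$gene_id,
                      complementarity = unname(complementarity_engine(m)),
                      pi = unname(periodicity_engine(m))),
      per_draw = bind_rows(per_draw),
      permutations = perms,
      n_draws = n_draws, seed = seed
    ),
    class = "identity_exchange"
  )
  if (keep_genomes) out$genomes <- genomes
  out
}

#' @export
tidy.identity_exchange <- function(x, ...) {
  left_join(x$native, x$statistics, by = "gene_id",
            suffix = c("_native", "_exchanged"))
}

#' @export
glance.identity_exchange <- function(x, ...) {
  tibble(n_draws = x$n_draws,
         mean_complementarity_native = mean(x$native$complementarity, na.rm = TRUE),
         mean_complementarity_exchanged = mean(x$statistics$complementarity, na.rm = TRUE),
         mean_pi_native = mean(x$native$pi, na.rm = TRUE),
         mean_pi_exchanged = mean(x$statistics$pi, na.rm = TRUE))
}

#' Random-major-codon complementarity null
#'
#' Monte-Carlo test of whether an observed number of mutually complementary
#' major codons is large: in each replicate one codon is chosen uniformly
#' from each degenerate sense family (18 in the standard code) and the
#' number of chosen codons whose reverse complement is also among the chosen
#' is counted (codons, not pairs — the count is always even). The p-value is
#' the fraction of replicates with a count at least as large as observed.
#'
#' @param observed Observed number of complementary major codons (0-18 for
#'   the standard code).
#' @param n_reps Number of Monte-Carlo replicates (default 100000).
#' @param seed Integer seed.
#' @param families Optional named list of codon vectors to draw from
#'   (defaults to the 18 degenerate sense families); reduced codes are
#'   useful for exact cross-checks.
#' @return An object of class `mc_null`: list with `p_value`, `observed`,
#'   `n_reps`, `counts` (per-replicate complementary counts), `seed`.
#'   `tidy()` returns the null distribution table, `glance()` the test
#'   summary.
#' @export
random_major_codon_null <- function(observed, n_reps = 100000L, seed = 1L,
                                    families = NULL) {
  if (n_reps < 1) {
    abort("`n_reps` must be at least 1.", class = "codonscope_domain_error")
  }
  tab <- code_tables()
  if (is.null(families)) {
    families <- tab$family[tab$degenerate_aa]
  }
  nf <- length(families)
  if (!is.numeric(observed) || length(observed) != 1 ||
      observed < 0 || observed > nf) {
    abort(paste0("`observed` must be a single count in [0, ", nf, "]."),
          class = "codonscope_domain_error")
  }
  fam_idx <- lapply(families, function(f) match(f, tab$codon))
  if (anyNA(unlist(fam_idx))) {
    abort("Unknown codons in `families`.", class = "codonscope_bad_input")
  }
  withr::with_seed(seed, {
    chosen <- vapply(fam_idx, function(idx) {
      idx[sample.int(length(idx), n_reps, replace = TRUE)]
    }, integer(n_reps))
  })
  chosen <- matrix(t(chosen), nrow = nf) # nf x n_reps
  rep_col <- rep(seq_len(n_reps), each = nf)
  mem <- matrix(FALSE, nrow = 64L, ncol = n_reps)
  mem[cbind(as.vector(chosen), rep_col)] <- TRUE
  hits <- mem[cbind(tab$rc_index[as.vector(chosen)], rep_col)]
  counts <- colSums(matrix(hits, nrow = nf))
  structure(
    list(p_value = mean(counts >= observed), observed = observed,
         n_reps = n_reps, counts = counts, seed = seed),
    class = "mc_null"
  )
}

#' @export
tidy.mc_null <- function(x, ...) {
  tb <- table(x$counts)
  tibble(count = as.integer(names(tb)), n = as.integer(tb),
         proportion = as.integer(tb) / x$n_reps)
}

#' @export
glance.mc_null <- function(x, ...) {
  tibble(observed = x$observed, p_value = x$p_value, n_reps = x$n_reps,
         null_mean = mean(x$counts), null_sd = sd(x$counts))
}

#' @export
print.mc_null <- function(x, ...) {
  cat("Random-major-codon complementarity null (", x$n_reps, " reps)\n",
      sep = "")
  cat("P(count >= ", x$observed, ") = ", format(x$p_value, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Codon-shuffle null for the PARS-nucleotide spread
#'
#' Calibrates the spread (population s.d. over codons) of the per-codon
#' PARS-nucleotide means under the null in which the codon order inside each
#' CDS is randomly permuted while every per-nucleotide score stays attached
#' to its position. Equivalent to recomputing [pars_codon_scores()] on
#' [shuffle_codons_within_cds()] output for each replicate, but works on the
#' fixed per-slot score means for speed.
#'
#' @inheritParams pars_codon_scores
#' @param n_reps Number of shuffle replicates (default 1000).
#' @param seed Integer seed.
#' @return An object of class `pars_spread_null`: list with `native_sd`,
#'   `null_sd` (vector of replicate spreads), `z` (Z-score of the native
#'   spread), `n_reps`, `seed`. `glance()` summarises.
#' @export
pars_spread_null <- function(genes, profiles, n_reps = 1000L, seed = 1L) {
  al <- align_profiles(genes, profiles)
  slots <- codon_slots(al$genes)
  s <- al$flat
  i3 <- 3 * seq_along(slots$gene)
  slot_mean <- (s[i3 - 2] + s[i3 - 1] + s[i3]) / 3
  ok <- !is.na(slots$codon)
  lab <- slots$codon[ok]
  g <- slots$gene[ok]
  sm <- slot_mean[ok]
  cnts <- tabulate(lab, nbins = 64L)
  spread_of <- function(lab_perm) {
    pn <- ifelse(cnts > 0, tabulate_sum(lab_perm, sm, 64L) / cnts, NA_real_)
    pop_sd(pn)
  }
  native_sd <- spread_of(lab)
  null_sd <- numeric(n_reps)
  withr::with_seed(seed, {
    for (r in seq_len(n_reps)) {
      # permute codon labels within genes against the fixed slot scores
      ord <- order(g, runif(length(g)))
      null_sd[r] <- spread_of(lab[ord])
    }
  })
  z <- if (n_reps >= 2 && sd(null_sd) > 0) {
    zscore_vs_null(native_sd, null_sd)
  } else {
    NA_real_
  }
  structure(
    list(native_sd = native_sd, null_sd = null_sd, z = z,
         n_reps = n_reps, seed = seed),
    class = "pars_spread_null"
  )
}

#' @export
glance.pars_spread_null <- function(x, ...) {
  tibble(native_sd = x$native_sd, null_mean = mean(x$null_sd),
         null_sd = sd(x$null_sd), z = x$z, n_reps = x$n_reps)
}

#' @export
print.pars_spread_null <- function(x, ...) {
  cat("PARS-nucleotide codon spread: native s.d. =",
      format(x$native_sd, digits = 3), "\n")
  cat("codon-shuffle null:", format(mean(x$null_sd), digits = 3), "+/-",
      format(sd(x$null_sd), digits = 2), "(", x$n_reps, "reps ), Z =",
      format(x$z, digits = 3), "\n")
  invisible(x)
}

#' Per-codon expression-profile Z-scores against the neutral model
#'
#' For each codon, the Z-score of its native mean log2 transcript level
#' against replicates in which every synonymous site is redrawn from the
#' genome-wide synonymous fractions (expression assignments untouched) —
#' the neutral-genome simulation of [simulate_neutral_genome()], run on the
#' per-slot representation for speed. Native profiles of genomes under
#' expression-linked selection give |Z| far outside the null band; genomes
#' generated neutrally stay within it.
#'
#' @inheritParams codon_expression_profile
#' @param n_reps Number of neutral replicates (default 200).
#' @param seed Integer seed.
#' @param fractions Optional fractions tibble; default, the genome's own
#'   pooled synonymous fractions.
#' @return A tibble of class `profile_null` with columns `codon`, `aa`,
#'   `native_mean`, `null_mean`, `null_sd`, `z`, `n`.
#' @export
neutral_profile_zscores <- function(genes, expr, n_reps = 200L, seed = 1L,
                                    fractions = NULL) {
  tab <- code_tables()
  validate_expression(expr)
  keep <- genes$gene_id %in% expr$gene_id
  if (!any(keep)) {
    abort("No gene in `genes` has expression data.",
          class = "codonscope_empty_join")
  }
  g <- genes[keep, , drop = FALSE]
  lvl <- log2(expr$mrna_per_cell[match(g$gene_id, expr$gene_id)])
  slots <- codon_slots(g)
  ok <- !is.na(slots$codon)
  lab <- slots$codon[ok]
  site_lvl <- lvl[slots$gene[ok]]
  if (is.null(fractions)) {
    fractions <- synonymous_fractions(
      tibble(codon = tab$codon, count = tabulate(lab, nbins = 64L))
    )
  }
  fv <- fraction_vector(fractions)
  aa_site <- tab$aa[lab]
  mean_of <- function(labels) {
    cnts <- tabulate(labels, nbins = 64L)
    ifelse(cnts > 0, tabulate_sum(labels, site_lvl, 64L) / cnts, NA_real_)
  }
  native <- mean_of(lab)
  acc <- matrix(NA_real_, nrow = 64L, ncol = n_reps)
  fam_sites <- split(seq_along(lab), aa_site)
  withr::with_seed(seed, {
    for (r in seq_len(n_reps)) {
      lab_r <- lab
      for (a in names(fam_sites)) {
        idx <- tab$family_index[[a]]
        if (length(idx) == 1L) next
        sel <- fam_sites[[a]]
        prob <- matrix(fv[idx], nrow = length(sel), ncol = length(idx),
                       byrow = TRUE)
        lab_r[sel] <- draw_from_family(idx, prob)
      }
      acc[, r] <- mean_of(lab_r)
    }
  })
  null_mean <- rowMeans(acc, na.rm = TRUE)
  null_sd <- apply(acc, 1, sd, na.rm = TRUE)
  out <- tibble(
    codon = tab$codon, aa = tab$aa,
    native_mean = native, null_mean = null_mean, null_sd = null_sd,
    z = ifelse(null_sd > 0, (native - null_mean) / null_sd, NA_real_),
    n = tabulate(lab, nbins = 64L)
  )
  class(out) <- c("profile_null", class(out))
  out
}
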