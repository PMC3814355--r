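# Sequence-intrinsic codon-usage indices. The complementarity and three-base
# periodicity indices depend only on codon counts, so both have matrix
# "engines" over an n x 64 count matrix that the randomizers reuse.

complementarity_engine <- function(m) {
  # m: n x 64 counts. Each unordered reverse-complement pair {c, rc(c)}
  # contributes min(count(c), count(rc)); summing pmin over all 64 columns
  # counts every pair twice (no 3-mer is its own reverse complement).
  rc <- code_tables()$rc_index
  tot <- rowSums(m)
  ifelse(tot > 0, rowSums(pmin(m, m[, rc, drop = FALSE])) / 2 / tot, NA_real_)
}

periodicity_engine <- function(m) {
  # Positional base frequencies f(b,p) implied by the codon counts; the index
  # is the mean over positions of the squared deviation from each base's
  # positional mean: Pi = (1/3) * sum_b sum_p (f(b,p) - fbar(b))^2.
  tab <- code_tables()
  tot <- rowSums(m)
  pi <- rep(NA_real_, nrow(m))
  ok <- tot > 0
  if (!any(ok)) return(pi)
  dev2 <- 0
  fbar_parts <- vector("list", 4L)
  f <- array(0, dim = c(sum(ok), 4L, 3L))
  msub <- m[ok, , drop = FALSE]
  for (p in 1:3) {
    for (b in 1:4) {
      sel <- tab$base_index[, p] == b
      f[, b, p] <- rowSums(msub[, sel, drop = FALSE]) / tot[ok]
    }
  }
  acc <- 0
  for (b in 1:4) {
    fb <- f[, b, , drop = TRUE]
    if (is.null(dim(fb))) fb <- matrix(fb, nrow = 1)
    fbar <- rowMeans(fb)
    acc <- acc + rowSums((fb - fbar)^2)
  }
  pi[ok] <- acc / 3
  pi
}

#' Codon complementarity index
#'
#' The fraction of a gene's codons that participate in reverse-complement
#' codon couples: the number of complementary couples — each unordered pair
#' \{c, revcomp(c)\} contributes min(count(c), count(revcomp(c))) couples —
#' divided by the total number of codons. For counts of 10 AAT, 20 ATT and
#' 100 CGA the index is 10/130 = 0.077: the 10 AAT each find an ATT partner.
#'
#' @param counts Codon counts in any form accepted by [pool_codons()].
#' @return A single number in \[0, 0.5\].
#' @export
#' @examples
#' complementarity_index(c(AAT = 10, ATT = 20, CGA = 100))
complementarity_index <- function(counts) {
  v <- count_vector(counts)
  if (sum(v) == 0) {
    abort("Empty codon counts: complementarity is undefined.",
          class = "codonscope_undefined_input")
  }
  unname(complementarity_engine(matrix(v, nrow = 1)))
}

#' Three-base periodicity index (Pi)
#'
#' The degree to which nucleotide composition differs across the three codon
#' positions, as implied by the codon frequencies alone: with f(b,p) the
#' frequency of base b at codon position p and f-bar(b) its mean over the
#' three positions, Pi = (1/3) * sum over bases and positions of
#' (f(b,p) - f-bar(b))^2. Zero iff positional base composition is identical
#' across positions; invariant under codon-order shuffling.
#'
#' @inheritParams complementarity_index
#' @return A single non-negative number.
#' @export
#' @examples
#' periodicity_index(c(GAT = 7)) # 2/3: every position is a distinct base
periodicity_index <- function(counts) {
  v <- count_vector(counts)
  if (sum(v) == 0) {
    abort("Empty codon counts: periodicity is undefined.",
          class = "codonscope_undefined_input")
  }
  unname(periodicity_engine(matrix(v, nrow = 1)))
}

# Reference weights for CAI/Fop/CBI from a reference usage (fractions of a
# highly expressed pool): per degenerate sense family, w = fraction / max
# fraction, floored at 0.01 (standard practice, prevents log 0); the major
# codon is the argmax (alphabetical on ties).
reference_weights <- function(reference) {
  tab <- code_tables()
  if (is.data.frame(reference) && all(c("codon", "count") %in% names(reference)) &&
      !("fraction" %in% names(reference))) {
    reference <- synonymous_fractions(reference)
  }
  f <- fraction_vector(reference)
  w <- rep(NA_real_, 64)
  major <- rep(FALSE, 64)
  for (a in tab$degenerate_aa) {
    idx <- tab$family_index[[a]]
    fr <- f[idx]
    if (all(is.na(fr)) || max(fr, na.rm = TRUE) <= 0) {
      abort(paste0("Reference usage has no data for family ", a, "."),
            class = "codonscope_missing_family")
    }
    fr[is.na(fr)] <- 0
    w[idx] <- pmax(fr / max(fr), 0.01)
    major[idx[which.max(fr)]] <- TRUE # which.max: first (alphabetical) on ties
  }
  list(w = w, major = major)
}

bias_engine <- function(v, ref) {
  tab <- code_tables()
  deg <- tab$aa %in% tab$degenerate_aa & tab$sense
  n_deg <- sum(v[deg])
  # CAI: geometric mean of w over sense codons of degenerate families
  # (Met/Trp and stops excluded)
  cai <- if (n_deg > 0) {
    exp(sum(v[deg] * log(ref$w[deg])) / n_deg)
  } else {
    NA_real_
  }
  n_opt <- sum(v[ref$major])
  fop <- if (n_deg > 0) n_opt / n_deg else NA_real_
  # CBI: (observed optimal - random expectation) / (total - random expectation)
  n_rand <- sum(tapply(v, tab$aa, sum)[tab$degenerate_aa] /
                  lengths(tab$family)[tab$degenerate_aa])
  cbi <- if (n_deg > n_rand) (n_opt - n_rand) / (n_deg - n_rand) else NA_real_
  nc <- nc_engine(v)
  c(cai = cai, fop = fop, cbi = cbi, nc = nc)
}

# Wright's effective number of codons with the 2-3-4-6 fold grouping.
nc_engine <- function(v) {
  tab <- code_tables()
  fold_of <- lengths(tab$family)[tab$degenerate_aa]
  Fvals <- setNames(rep(NA_real_, length(tab$degenerate_aa)), tab$degenerate_aa)
  for (a in tab$degenerate_aa) {
    idx <- tab$family_index[[a]]
    n <- sum(v[idx])
    if (n >= 2) {
      p <- v[idx] / n
      Fvals[a] <- (n * sum(p^2) - 1) / (n - 1)
    }
  }
  Fbar <- tapply(Fvals, fold_of, mean, na.rm = TRUE)
  Fbar[is.nan(Fbar)] <- NA_real_
  f2 <- Fbar[["2"]]; f3 <- Fbar[["3"]]; f4 <- Fbar[["4"]]; f6 <- Fbar[["6"]]
  # standard fallback when the single 3-fold family (Ile) is unusable
  if (is.na(f3) && !is.na(f2) && !is.na(f4)) f3 <- (f2 + f4) / 2
  if (anyNA(c(f2, f3, f4, f6)) || any(c(f2, f3, f4, f6) <= 0)) {
    return(NA_real_)
  }
  min(2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6, 61)
}

#' Codon bias indices (CAI, Fop, CBI, Nc)
#'
#' Computes the four standard codon-bias indices from the literature
#' definitions: the Codon Adaptation Index (geometric mean of relative
#' adaptiveness w = fraction/max fraction in a reference pool of highly
#' expressed genes), the Frequency of optimal codons (share of codons that
#' are the reference pool's major codon), the Codon Bias Index (excess of
#' optimal codons over the uniform-usage expectation) and Wright's effective
#' number of codons (Nc, homozygosity estimator with the 2-3-4-6 fold
#' grouping; 61 under uniform synonymous usage, 20 when a single codon is
#' used per amino acid). Codons of Met, Trp and stops never enter CAI, Fop
#' or CBI.
#'
#' @inheritParams complementarity_index
#' @param reference Reference usage of a highly expressed gene pool: a
#'   fractions tibble ([synonymous_fractions()]), a counts tibble, or a named
#'   vector.
#' @return A one-row tibble with columns `cai`, `fop`, `cbi`, `nc`.
#' @export
bias_indices <- function(counts, reference) {
  v <- count_vector(counts)
  tab <- code_tables()
  if (sum(v[tab$sense]) == 0) {
    abort("No scorable sense codons.", class = "codonscope_undefined_input")
  }
  ref <- reference_weights(reference)
  as_tibble(as.list(bias_engine(v, ref)))
}

#' Synonymous fractions expected from GC content alone
#'
#' Under independent nucleotides with P(G) = P(C) = gc/2 and
#' P(A) = P(T) = (1 - gc)/2, each codon's within-family fraction is
#' proportional to the product of its three base probabilities. This is the
#' mutational-null usage against which the bias of lowly transcribed genes
#' can be compared.
#'
#' @param gc GC content in (0, 1).
#' @return A fractions tibble (`family`, `codon`, `fraction`).
#' @export
#' @examples
#' expected_fractions_from_gc(0.35)
expected_fractions_from_gc <- function(gc) {
  if (!is.numeric(gc) || length(gc) != 1 || is.na(gc) || gc <= 0 || gc >= 1) {
    abort("`gc` must be a single number strictly between 0 and 1.",
          class = "codonscope_domain_error")
  }
  tab <- code_tables()
  pb <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2) # A C G T
  p <- pb[tab$base_index[, 1]] * pb[tab$base_index[, 2]] * pb[tab$base_index[, 3]]
  fam_tot <- tapply(p, tab$aa, sum)[tab$aa]
  tibble(family = tab$aa, codon = tab$codon, fraction = unname(p / fam_tot))
}

#' Major codons of a (highly expressed) codon pool
#'
#' The major codon of each degenerate family (including the 3-codon stop
#' family) is its most frequent codon in the supplied pool. Ties are broken
#' alphabetically and flagged.
#'
#' @inheritParams complementarity_index
#' @return A tibble with columns `family`, `codon`, `count`, `fraction`,
#'   `tie`.
#' @export
major_codon_table <- function(counts) {
  tab <- code_tables()
  v <- count_vector(counts)
  fams <- c(tab$degenerate_aa, "*")
  empty <- fams[vapply(fams, function(a) sum(v[tab$family_index[[a]]]) == 0,
                       logical(1))]
  if (length(empty) > 0) {
    abort(paste0("No codons observed for family(ies): ",
                 paste(empty, collapse = ", ")),
          class = "codonscope_missing_family")
  }
  rows <- lapply(fams, function(a) {
    idx <- tab$family_index[[a]] # codons sorted alphabetically
    cnt <- v[idx]
    best <- which.max(cnt) # first max = alphabetical tie-break
    tibble(
      family = a,
      codon = tab$codon[idx[best]],
      count = unname(cnt[best]),
      fraction = unname(cnt[best] / sum(cnt)),
      tie = sum(cnt == cnt[best]) > 1
    )
  })
  bind_rows(rows)
}

#' Per-gene codon-bias profile
#'
#' One row per gene with the full set of sequence-intrinsic statistics:
#' sense-codon count, GC content, third-position GC (GC3), CAI, Fop, CBI,
#' Nc, codon complementarity and the three-base periodicity index. This is
#' the per-gene table the downstream binning/coherence analyses consume.
#'
#' @param genes A data frame with columns `gene_id` and `cds`.
#' @param reference Reference usage for CAI/Fop/CBI (see [bias_indices()]).
#' @return A tibble with columns `gene_id`, `n_sense`, `gc`, `gc3`, `cai`,
#'   `fop`, `cbi`, `nc`, `complementarity`, `pi`.
#' @export
codon_bias_profile <- function(genes, reference) {
  tab <- code_tables()
  m <- codon_count_matrix(genes)
  ref <- reference_weights(reference)
  gc_base <- c(0, 1, 1, 0) # A C G T
  codon_gc <- as.vector(gc_base[tab$base_index[, 1]] +
                          gc_base[tab$base_index[, 2]] +
                          gc_base[tab$base_index[, 3]])
  gc3 <- gc_base[tab$base_index[, 3]]
  tot <- rowSums(m)
  idx <- t(apply(m, 1, function(v) bias_engine(v, ref)))
  tibble(
    gene_id = genes$gene_id,
    n_sense = as.integer(m %*% tab$sense),
    gc = as.vector(m %*% codon_gc) / (3 * tot),
    gc3 = as.vector(m %*% gc3) / tot,
    cai = unname(idx[, "cai"]),
    fop = unname(idx[, "fop"]),
    cbi = unname(idx[, "cbi"]),
    nc = unname(idx[, "nc"]),
    complementarity = unname(complementarity_engine(m)),
    pi = unname(periodicity_engine(m))
  )
}
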