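# The binning/coherence framework: synonymous-fraction trajectories along a
# gene property (20 equal-width bins after a 0.25%-per-tail outlier trim),
# and per-codon Pearson correlation of trajectories between two properties.
# Two properties are positively (negatively) coherent when the significant
# per-codon correlations all share a positive (negative) sign.

#' Trim extreme values
#'
#' Removes the floor(trim * n) most extreme values from each tail (default
#' 0.25% per tail) and returns the indices of retained observations, sorted.
#' The retained set depends only on the values, not on input order.
#'
#' @param values Numeric vector.
#' @param trim Per-tail trim fraction.
#' @return Sorted integer indices of the retained values.
#' @export
#' @examples
#' length(trim_outliers(rnorm(1000))) # 996: floor(2.5) = 2 per tail
trim_outliers <- function(values, trim = 0.0025) {
  n <- length(values)
  if (n < 1) {
    abort("`values` must be non-empty.", class = "codonscope_bad_input")
  }
  k <- floor(trim * n)
  if (k == 0) return(seq_len(n))
  ord <- order(values)
  sort(ord[(k + 1):(n - k)])
}

#' Assign values to equal-width bins
#'
#' k intervals of equal width spanning \[min, max\] of the values; the right
#' edge of the last bin is inclusive, so the maximum lands in bin k.
#'
#' @param values Numeric vector (no NAs).
#' @param k Number of bins.
#' @return Integer bin assignments in 1..k.
#' @export
equal_width_bins <- function(values, k = 20L) {
  if (anyNA(values)) {
    abort("`values` must not contain NAs.", class = "codonscope_bad_input")
  }
  rng <- range(values)
  if (rng[1] == rng[2]) {
    abort("All values identical: bin width would be zero.",
          class = "codonscope_degenerate_range")
  }
  bin <- floor((values - rng[1]) / (rng[2] - rng[1]) * k) + 1L
  pmin(bin, as.integer(k))
}

# Normalise a property argument to tibble(gene_id, value) + its name.
as_property <- function(property, arg = "property") {
  if (is.data.frame(property)) {
    num <- setdiff(names(property)[vapply(property, is.numeric, logical(1))],
                   "gene_id")
    if (!"gene_id" %in% names(property) || length(num) < 1) {
      abort(paste0("`", arg, "` data frame needs `gene_id` and one numeric column."),
            class = "codonscope_bad_input")
    }
    list(df = tibble(gene_id = property$gene_id, value = property[[num[1]]]),
         name = num[1])
  } else if (!is.null(names(property))) {
    list(df = tibble(gene_id = names(property), value = as.numeric(property)),
         name = arg)
  } else {
    abort(paste0("`", arg, "` must be a data frame or a named numeric vector."),
          class = "codonscope_bad_input")
  }
}

#' Binned synonymous codon fractions along a gene property
#'
#' Genes are trimmed of property outliers (0.25% per tail by default) and
#' grouped into `k` equal-width bins of the property; codon counts are
#' pooled within each bin and converted to within-family fractions. The
#' major codons' fraction trajectories across bins are how codon bias is
#' read against expression, GC content, structural scores, etc.
#'
#' @param genes A data frame with columns `gene_id` and `cds`.
#' @param property Per-gene values: a data frame (`gene_id` + one numeric
#'   column) or a named numeric vector.
#' @param k Number of bins (default 20).
#' @param trim Per-tail outlier trim fraction (default 0.0025).
#' @return A tibble of class `binned_fractions`: columns `bin`,
#'   `bin_center`, `n_genes`, `family`, `codon`, `count`, `fraction`
#'   (NA where the family is absent from the bin). Attributes `property`
#'   (name) and `k`.
#' @export
binned_synonymous_fractions <- function(genes, property, k = 20L,
                                        trim = 0.0025) {
  validate_genes(genes)
  pr <- as_property(property)
  df <- inner_join(tibble(gene_id = genes$gene_id, row = seq_len(nrow(genes))),
                   pr$df, by = "gene_id")
  df <- df[is.finite(df$value), , drop = FALSE]
  if (nrow(df) == 0) {
    abort("No gene has a property value.", class = "codonscope_empty_join")
  }
  keep <- trim_outliers(df$value, trim = trim)
  df <- df[keep, , drop = FALSE]
  bin <- equal_width_bins(df$value, k = k)
  rng <- range(df$value)
  width <- (rng[2] - rng[1]) / k
  m <- codon_count_matrix(genes[df$row, , drop = FALSE])
  binned <- rowsum(m, group = bin) # bins present x 64
  tab <- code_tables()
  rows <- lapply(seq_len(k), function(b) {
    i <- match(as.character(b), rownames(binned))
    cnt <- if (is.na(i)) rep(0, 64) else binned[i, ]
    fam_tot <- tapply(cnt, tab$aa, sum)[tab$aa]
    tibble(
      bin = b,
      bin_center = rng[1] + (b - 0.5) * width,
      n_genes = sum(bin == b),
      family = tab$aa,
      codon = tab$codon,
      count = as.numeric(cnt),
      fraction = as.numeric(ifelse(fam_tot > 0, cnt / fam_tot, NA_real_))
    )
  })
  out <- bind_rows(rows)
  attr(out, "property") <- pr$name
  attr(out, "k") <- as.integer(k)
  class(out) <- c("binned_fractions", class(out))
  out
}

#' Coherence of synonymous-fraction trajectories between two properties
#'
#' Bins the genome along each of two gene properties
#' ([binned_synonymous_fractions()]) and, for every codon, correlates
#' (Pearson) its fraction trajectory across the bins of property A with the
#' trajectory across the bins of property B, pairing by bin index and
#' dropping bins where either trajectory has no data. The overall call is
#' `positively coherent` when all significant correlations are positive,
#' `negatively coherent` when all are negative, and `incoherent` otherwise
#' (or when nothing is significant). Significance is a per-codon two-sided
#' t-test on the correlation at `alpha`; codons with fewer than `min_count`
#' occurrences under either property are excluded from the call.
#'
#' @inheritParams binned_synonymous_fractions
#' @param property_a,property_b Per-gene values (data frame or named
#'   vector).
#' @param alpha Significance level for the per-codon test (default 0.05).
#' @param min_count Minimum pooled codon count under each property for a
#'   codon to enter the call (default 50).
#' @return An object of class `codon_coherence`: list with `by_codon`
#'   (tibble `codon`, `family`, `r`, `p_value`, `n_bins`, `count_a`,
#'   `count_b`, `eligible`, `significant`, `computable`), `call`,
#'   `properties`, `alpha`. `tidy()` returns the per-codon table,
#'   `glance()` the call summary.
#' @export
coherence <- function(genes, property_a, property_b, k = 20L, trim = 0.0025,
                      alpha = 0.05, min_count = 50L) {
  ba <- binned_synonymous_fractions(genes, property_a, k = k, trim = trim)
  bb <- binned_synonymous_fractions(genes, property_b, k = k, trim = trim)
  name_a <- attr(ba, "property")
  name_b <- attr(bb, "property")
  tab <- code_tables()
  fa <- matrix(ba$fraction, nrow = k, byrow = TRUE) # k x 64
  fb <- matrix(bb$fraction, nrow = k, byrow = TRUE)
  ca <- matrix(ba$count, nrow = k, byrow = TRUE)
  cb <- matrix(bb$count, nrow = k, byrow = TRUE)
  rows <- lapply(seq_len(64L), function(j) {
    va <- fa[, j]; vb <- fb[, j]
    cc <- is.finite(va) & is.finite(vb)
    nb <- sum(cc)
    computable <- nb >= 3 && sd(va[cc]) > 0 && sd(vb[cc]) > 0
    r <- p <- NA_real_
    if (computable) {
      ct <- cor.test(va[cc], vb[cc])
      r <- unname(ct$estimate)
      p <- ct$p.value
    }
    tibble(codon = tab$codon[j], family = tab$aa[j], r = r, p_value = p,
           n_bins = nb, count_a = sum(ca[, j]), count_b = sum(cb[, j]),
           computable = computable)
  })
  by_codon <- bind_rows(rows) |>
    mutate(
      eligible = .data$computable & .data$count_a >= min_count &
        .data$count_b >= min_count,
      significant = .data$eligible & .data$p_value < alpha
    )
  sig_r <- by_codon$r[by_codon$significant]
  call <- if (length(sig_r) == 0) {
    "incoherent"
  } else if (all(sig_r > 0)) {
    "positively coherent"
  } else if (all(sig_r < 0)) {
    "negatively coherent"
  } else {
    "incoherent"
  }
  structure(
    list(by_codon = by_codon, call = call,
         properties = c(name_a, name_b), alpha = alpha,
         binned_a = ba, binned_b = bb),
    class = "codon_coherence"
  )
}

#' @export
tidy.codon_coherence <- function(x, ...) x$by_codon

#' @export
glance.codon_coherence <- function(x, ...) {
  tibble(
    call = x$call,
    property_a = x$properties[1], property_b = x$properties[2],
    n_significant = sum(x$by_codon$significant),
    n_positive = sum(x$by_codon$significant & x$by_codon$r > 0),
    n_negative = sum(x$by_codon$significant & x$by_codon$r < 0),
    alpha = x$alpha
  )
}

#' @export
print.codon_coherence <- function(x, ...) {
  cat("Coherence of synonymous-fraction trajectories:",
      x$properties[1], "vs", x$properties[2], "\n")
  cat("call:", x$call, "(",
      sum(x$by_codon$significant), "significant codons )\n")
  invisible(x)
}

#' Codon bias along a gene: windowed indices
#'
#' Partitions each gene's codons into `n_windows` contiguous, near-equal
#' blocks (remainder codons to the earliest windows) and computes the
#' bias indices per window — a view of how much each intragene region
#' contributes to the gene's overall bias.
#'
#' @param genes A data frame with columns `gene_id` and `cds`; every CDS
#'   must have at least `n_windows` codons.
#' @param reference Reference usage for CAI/Fop/CBI (see [bias_indices()]).
#' @param n_windows Number of windows (default 5).
#' @param include_fractions Also return per-window synonymous fractions.
#' @return A tibble `gene_id`, `window`, `n_codons`, `cai`, `fop`, `cbi`,
#'   `nc`; with `include_fractions`, a list with `indices` and `fractions`.
#' @export
windowed_codon_bias <- function(genes, reference, n_windows = 5L,
                                include_fractions = FALSE) {
  validate_genes(genes)
  slots <- codon_slots(genes)
  short <- slots$n_codons < n_windows
  if (any(short)) {
    abort(paste0("CDS shorter than ", n_windows, " codons: ",
                 paste(head(genes$gene_id[short], 5), collapse = ", ")),
          class = "codonscope_too_short")
  }
  ref <- reference_weights(reference)
  tab <- code_tables()
  # window of slot j within a gene of nc codons: near-equal contiguous
  # blocks, remainder to the earliest windows
  nc_g <- slots$n_codons[slots$gene]
  within <- sequence(slots$n_codons)
  base <- nc_g %/% n_windows
  rem <- nc_g %% n_windows
  # first `rem` windows have size base+1
  cut1 <- rem * (base + 1)
  win <- ifelse(within <= cut1,
                (within - 1) %/% (base + 1) + 1,
                rem + (within - cut1 - 1) %/% base + 1)
  ok <- !is.na(slots$codon)
  key <- (slots$gene - 1L) * n_windows + win
  m <- matrix(
    tabulate((key[ok] - 1L) * 64L + slots$codon[ok],
             nbins = nrow(genes) * n_windows * 64L),
    ncol = 64L, byrow = TRUE
  )
  idx <- t(apply(m, 1, function(v) bias_engine(v, ref)))
  indices <- tibble(
    gene_id = rep(genes$gene_id, each = n_windows),
    window = rep(seq_len(n_windows), nrow(genes)),
    n_codons = as.integer(rowSums(m)),
    cai = idx[, "cai"], fop = idx[, "fop"],
    cbi = idx[, "cbi"], nc = idx[, "nc"]
  )
  if (!include_fractions) {
    return(indices)
  }
  fr <- lapply(seq_len(nrow(m)), function(i) {
    f <- synonymous_fractions(setNames(m[i, ], tab$codon))
    f$gene_id <- indices$gene_id[i]
    f$window <- indices$window[i]
    f
  })
  list(indices = indices,
       fractions = select(bind_rows(fr), "gene_id", "window", "family",
                          "codon", "count", "fraction"))
}
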