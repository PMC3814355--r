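# Linking codon usage to transcript abundance: per-codon expression
# profiles, back-calculation of gene levels from codon composition,
# expression-class partitioning, the mutational-contribution estimator and
# stop-codon usage trajectories. Levels are mRNA molecules per cell and all
# logarithms are base 2.

validate_expression <- function(expr) {
  if (!is.data.frame(expr) ||
      !all(c("gene_id", "mrna_per_cell") %in% names(expr))) {
    abort("`expr` must have columns `gene_id` and `mrna_per_cell`.",
          class = "codonscope_bad_input")
  }
  if (any(!is.finite(expr$mrna_per_cell)) || any(expr$mrna_per_cell <= 0)) {
    abort("`mrna_per_cell` must be positive and finite (log2 must be defined).",
          class = "codonscope_bad_input")
  }
  invisible(expr)
}

#' Per-codon transcript-level profile
#'
#' Assigns to every codon occurrence the log2-transformed level of its host
#' transcript, then averages per codon type over all genomic occurrences.
#' In a genome under expression-linked selection the 64 codon means separate
#' into two modes (major codons pulled up by highly expressed genes, minor
#' codons pulled down); the profile is the basis for back-calculating gene
#' expression from sequence alone.
#'
#' @param genes A data frame with columns `gene_id` and `cds`.
#' @param expr Expression table with columns `gene_id`, `mrna_per_cell`.
#' @return A tibble of class `codon_profile` with columns `codon`, `aa`,
#'   `mean_log2_level`, `n`; genes absent from `expr` are excluded and their
#'   number stored in the `n_genes_excluded` attribute.
#' @export
codon_expression_profile <- function(genes, expr) {
  validate_genes(genes)
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
  sums <- tabulate_sum(lab, lvl[slots$gene[ok]], 64L)
  cnts <- tabulate(lab, nbins = 64L)
  tab <- code_tables()
  out <- tibble(
    codon = tab$codon,
    aa = tab$aa,
    mean_log2_level = ifelse(cnts > 0, sums / cnts, NA_real_),
    n = cnts
  )
  attr(out, "n_genes_excluded") <- sum(!keep)
  class(out) <- c("codon_profile", class(out))
  out
}

# Sum `x` by integer label 1..nbins.
tabulate_sum <- function(label, x, nbins) {
  out <- numeric(nbins)
  s <- rowsum(x, group = label, reorder = FALSE)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Back-calculate transcript levels from codon composition
#'
#' Predicts each gene's log2 transcript level as the mean, over its codons,
#' of the per-codon profile means, and correlates the predictions with
#' measured levels (Pearson, log2 scale). Each prediction is a convex
#' combination of profile means, so it always lies within their range.
#'
#' @inheritParams codon_expression_profile
#' @param profile A `codon_profile` (or tibble with `codon` and
#'   `mean_log2_level`) covering every codon present in `genes`.
#' @return An object of class `codon_backcalc`: a list with `predictions`
#'   (tibble `gene_id`, `predicted_log2`, `observed_log2`), `r_pearson`, `n`.
#'   `tidy()` returns the predictions, `glance()` the fit summary.
#' @export
back_calculate_expression <- function(genes, profile, expr = NULL) {
  validate_genes(genes)
  pv <- rep(NA_real_, 64)
  pv[match(profile$codon, code_tables()$codon)] <- profile$mean_log2_level
  slots <- codon_slots(genes)
  ok <- !is.na(slots$codon)
  used <- sort(unique(slots$codon[ok]))
  if (anyNA(pv[used])) {
    abort(paste0("Profile does not cover codon(s): ",
                 paste(code_tables()$codon[used][is.na(pv[used])], collapse = ", ")),
          class = "codonscope_missing_score")
  }
  n_gene <- nrow(genes)
  sums <- tabulate_sum(slots$gene[ok], pv[slots$codon[ok]], n_gene)
  cnts <- tabulate(slots$gene[ok], nbins = n_gene)
  pred <- ifelse(cnts > 0, sums / cnts, NA_real_)
  obs <- rep(NA_real_, n_gene)
  if (!is.null(expr)) {
    validate_expression(expr)
    obs <- log2(expr$mrna_per_cell[match(genes$gene_id, expr$gene_id)])
  }
  predictions <- tibble(gene_id = genes$gene_id,
                        predicted_log2 = pred, observed_log2 = obs)
  cc <- stats::complete.cases(predictions[, c("predicted_log2", "observed_log2")])
  r <- NA_real_
  if (any(cc)) {
    if (sd(pred[cc]) == 0 || sd(obs[cc]) == 0) {
      abort("All predictions (or observations) identical: correlation undefined.",
            class = "codonscope_correlation_undefined")
    }
    r <- cor(pred[cc], obs[cc])
  }
  structure(
    list(predictions = predictions, r_pearson = r, n = sum(cc)),
    class = "codon_backcalc"
  )
}

#' @export
tidy.codon_backcalc <- function(x, ...) x$predictions

#' @export
glance.codon_backcalc <- function(x, ...) {
  tibble(r_pearson = x$r_pearson, n = x$n)
}

#' @export
print.codon_backcalc <- function(x, ...) {
  cat("Back-calculated transcript levels for", nrow(x$predictions), "genes\n")
  cat("Pearson R (predicted vs measured, log2):",
      format(x$r_pearson, digits = 3), "on n =", x$n, "\n")
  invisible(x)
}

#' Partition genes into expression classes
#'
#' Three classes on mRNA molecules per cell: lowly transcribed (level <=
#' `low_max`), moderately transcribed (`low_max` < level <= `high_min`) and
#' highly transcribed (level > `high_min`). The defaults, 0.5 and 32
#' molecules per cell, delimit the regime where codon bias follows the
#' mutational background, the regime of near-linear response to transcript
#' level, and the strongly selected regime. A level of exactly 0.5 is low
#' and exactly 32 is moderate.
#'
#' @inheritParams codon_expression_profile
#' @param genes Optional gene table; when given, the per-class share of
#'   codons is computed from CDS lengths.
#' @param low_max,high_min Class boundaries, mRNA/cell.
#' @return An object of class `expression_classes`: list with `assignments`
#'   (tibble `gene_id`, `mrna_per_cell`, `class`) and `summary` (per class:
#'   `n_genes`, `share_genes`, `share_transcripts`, `share_codons`).
#'   `tidy()` returns the assignments, `glance()` the summary.
#' @export
classify_genes_by_expression <- function(expr, genes = NULL,
                                         low_max = 0.5, high_min = 32) {
  validate_expression(expr)
  if (!(low_max > 0 && low_max < high_min)) {
    abort("Need 0 < low_max < high_min.", class = "codonscope_domain_error")
  }
  lvl <- expr$mrna_per_cell
  cls <- factor(
    ifelse(lvl <= low_max, "low", ifelse(lvl <= high_min, "moderate", "high")),
    levels = c("low", "moderate", "high")
  )
  assignments <- tibble(gene_id = expr$gene_id, mrna_per_cell = lvl, class = cls)
  codons <- rep(NA_real_, length(lvl))
  if (!is.null(genes)) {
    validate_genes(genes)
    codons <- nchar(genes$cds)[match(expr$gene_id, genes$gene_id)] / 3
  }
  total_codons <- sum(codons, na.rm = TRUE)
  have_codons <- !all(is.na(codons))
  summary <- assignments |>
    mutate(codons = !!codons) |>
    group_by(class, .drop = FALSE) |>
    summarise(
      n_genes = n(),
      share_genes = n() / nrow(assignments),
      share_transcripts = sum(.data$mrna_per_cell) / sum(lvl),
      share_codons = if (have_codons)
        sum(.data$codons, na.rm = TRUE) / total_codons else NA_real_,
      .groups = "drop"
    )
  structure(
    list(assignments = assignments, summary = summary,
         low_max = low_max, high_min = high_min),
    class = "expression_classes"
  )
}

#' @export
tidy.expression_classes <- function(x, ...) x$assignments

#' @export
glance.expression_classes <- function(x, ...) x$summary

#' @export
print.expression_classes <- function(x, ...) {
  cat("Expression classes (low <=", x$low_max, "< moderate <=", x$high_min,
      "< high, mRNA/cell)\n")
  print(x$summary)
  invisible(x)
}

#' Mutational contribution to codon usage from 2-fold families
#'
#' Treats the genome-wide usage of each 2-fold degenerate family as a linear
#' combination of a mutational force (the usage of lowly transcribed genes)
#' and a selective force (major-codon fraction of 1): with `fw` the major
#' codon's fraction in the whole genome and `fl` its fraction in lowly
#' transcribed genes, the mutational share is x = (1 - fw) / (1 - fl).
#' x = 1 when genome usage equals the lowly transcribed usage (pure
#' mutation); x = 0 when the major codon's fraction is 1 (pure selection).
#' Values outside \[0, 1\] (selection opposing mutation) are clamped and
#' flagged. The overall estimate is the arithmetic mean over families —
#' nine of them when applied to the standard code's 2-fold set.
#'
#' @param fw,fl Named numeric vectors (same names: family labels) of
#'   major-codon fractions in the whole genome and in lowly transcribed
#'   genes; alternatively `fw` may be a data frame with columns `family`,
#'   `fw`, `fl` and `fl` omitted.
#' @return An object of class `mutational_contribution`: list with
#'   `by_family` (tibble `family`, `fw`, `fl`, `x_raw`, `x`, `clamped`) and
#'   `mean_x`. `tidy()` returns the per-family table, `glance()` the mean.
#' @export
#' @examples
#' mutational_contribution(c(K = 0.64), c(K = 0.60)) # x = 0.36/0.40 = 0.9
mutational_contribution <- function(fw, fl = NULL) {
  if (is.data.frame(fw)) {
    df <- fw
    if (!all(c("family", "fw", "fl") %in% names(df))) {
      abort("Data-frame input needs columns `family`, `fw`, `fl`.",
            class = "codonscope_bad_input")
    }
  } else {
    if (is.null(names(fw)) || is.null(names(fl)) ||
        !setequal(names(fw), names(fl))) {
      abort("`fw` and `fl` must be named vectors over the same families.",
            class = "codonscope_bad_input")
    }
    fam <- names(fw)
    fw_v <- unname(fw)
    fl_v <- unname(fl[fam])
    df <- tibble(family = fam, fw = fw_v, fl = fl_v)
  }
  if (any(df$fl >= 1)) {
    abort("fl = 1 leaves no degrees of freedom for the mutational baseline.",
          class = "codonscope_degenerate_baseline")
  }
  if (any(df$fl <= 0)) {
    abort("fl must be strictly positive.", class = "codonscope_domain_error")
  }
  x_raw <- (1 - df$fw) / (1 - df$fl)
  x <- pmin(pmax(x_raw, 0), 1)
  by_family <- tibble(
    family = df$family, fw = df$fw, fl = df$fl,
    x_raw = x_raw, x = x, clamped = x_raw != x
  )
  structure(
    list(by_family = by_family, mean_x = mean(x)),
    class = "mutational_contribution"
  )
}

#' @export
tidy.mutational_contribution <- function(x, ...) x$by_family

#' @export
glance.mutational_contribution <- function(x, ...) {
  tibble(mean_x = x$mean_x, n_families = nrow(x$by_family),
         n_clamped = sum(x$by_family$clamped))
}

#' @export
print.mutational_contribution <- function(x, ...) {
  cat("Mutational contribution to codon usage:",
      format(100 * x$mean_x, digits = 3), "% (mean over",
      nrow(x$by_family), "2-fold families)\n")
  invisible(x)
}

#' Estimate the mutational contribution from a genome
#'
#' Pipeline form of [mutational_contribution()]: defines major codons from
#' the pooled usage of highly transcribed genes, measures each 2-fold
#' family's major-codon fraction in the whole genome (`fw`) and in the
#' lowly transcribed class (`fl`), and applies the estimator. The same major
#' codon (from the highly expressed pool) is used for both fractions.
#'
#' @inheritParams classify_genes_by_expression
#' @param genes A data frame with columns `gene_id` and `cds`.
#' @param majors Optional major-codon table ([major_codon_table()]); by
#'   default derived from the highly transcribed class.
#' @return See [mutational_contribution()]; the per-family table also
#'   carries the major codon used.
#' @export
estimate_mutational_contribution <- function(genes, expr, low_max = 0.5,
                                             high_min = 32, majors = NULL) {
  cls <- classify_genes_by_expression(expr, low_max = low_max,
                                      high_min = high_min)$assignments
  tab <- code_tables()
  counts_all <- count_codons(genes)
  if (is.null(majors)) {
    high_ids <- cls$gene_id[cls$class == "high"]
    if (length(high_ids) == 0) {
      abort("No highly transcribed genes to define major codons from.",
            class = "codonscope_missing_family")
    }
    majors <- major_codon_table(filter(counts_all, .data$gene_id %in% high_ids))
  }
  low_ids <- cls$gene_id[cls$class == "low"]
  if (length(low_ids) == 0) {
    abort("No lowly transcribed genes to estimate the mutational baseline.",
          class = "codonscope_missing_family")
  }
  frac_of <- function(counts) {
    f <- synonymous_fractions(counts)
    setNames(f$fraction, f$codon)
  }
  fw_all <- frac_of(counts_all)
  fl_all <- frac_of(filter(counts_all, .data$gene_id %in% low_ids))
  mc <- majors[majors$family %in% tab$twofold_aa, ]
  fit <- mutational_contribution(
    setNames(fw_all[mc$codon], mc$family),
    setNames(fl_all[mc$codon], mc$family)
  )
  fit$by_family <- mutate(fit$by_family,
                          major_codon = mc$codon[match(.data$family, mc$family)],
                          .after = "family")
  fit
}

#' Stop-codon usage across expression classes or bins
#'
#' The fraction of TAA, TAG and TGA among the terminal stop codons of genes,
#' grouped either by expression class (default) or by equal-width bins of
#' log2 level. Fractions within a non-empty group sum to 1; groups with no
#' stop codons are flagged absent.
#'
#' @inheritParams classify_genes_by_expression
#' @param genes A data frame with columns `gene_id` and `cds`; genes whose
#'   final codon is not a stop are dropped (with a message).
#' @param by `"class"` or `"bin"`.
#' @param n_bins Number of bins when `by = "bin"`.
#' @param trim Per-tail outlier trim fraction applied before binning.
#' @return A tibble with columns `group`, `codon`, `count`, `fraction`,
#'   `absent` (plus `mean_log2_level` per bin when `by = "bin"`).
#' @export
stop_codon_usage <- function(genes, expr, by = c("class", "bin"),
                             low_max = 0.5, high_min = 32,
                             n_bins = 20, trim = 0.0025) {
  by <- match.arg(by)
  validate_genes(genes)
  validate_expression(expr)
  len <- nchar(genes$cds)
  last <- toupper(substr(genes$cds, len - 2, len))
  is_stop <- last %in% c("TAA", "TAG", "TGA")
  if (any(!is_stop)) {
    inform(paste0(sum(!is_stop), " gene(s) without a terminal stop codon dropped."))
  }
  df <- tibble(gene_id = genes$gene_id[is_stop], stop = last[is_stop]) |>
    inner_join(expr, by = "gene_id")
  if (nrow(df) == 0) {
    abort("No genes with both a terminal stop codon and expression data.",
          class = "codonscope_empty_join")
  }
  if (by == "class") {
    cls <- classify_genes_by_expression(df[, c("gene_id", "mrna_per_cell")],
                                        low_max = low_max, high_min = high_min)
    df$group <- cls$assignments$class
  } else {
    lv <- log2(df$mrna_per_cell)
    keep <- trim_outliers(lv, trim = trim)
    df <- df[keep, , drop = FALSE]
    df$group <- factor(equal_width_bins(log2(df$mrna_per_cell), k = n_bins),
                       levels = seq_len(n_bins))
  }
  out <- df |>
    group_by(.data$group, .drop = FALSE) |>
    summarise(
      TAA = sum(.data$stop == "TAA"),
      TAG = sum(.data$stop == "TAG"),
      TGA = sum(.data$stop == "TGA"),
      mean_log2_level = mean(log2(.data$mrna_per_cell)),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(c("TAA", "TAG", "TGA"),
                        names_to = "codon", values_to = "count") |>
    group_by(.data$group) |>
    mutate(
      fraction = if (sum(.data$count) > 0)
        .data$count / sum(.data$count) else NA_real_,
      absent = sum(.data$count) == 0
    ) |>
    ungroup() |>
    select("group", "codon", "count", "fraction", "absent",
           "mean_log2_level")
  if (by == "class") out$mean_log2_level <- NULL
  out
}
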