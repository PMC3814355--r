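# ggplot2 views of the main result types.

#' @importFrom ggplot2 ggplot aes geom_histogram geom_line geom_point
#'   geom_col geom_vline facet_wrap labs theme_minimal
NULL

#' Plot a per-codon transcript-level profile
#'
#' Histogram of the 64 per-codon mean log2 transcript levels; under
#' expression-linked selection the distribution is bimodal, and the two
#' modes collapse when expression values are permuted across genes.
#'
#' @param object A `codon_profile` ([codon_expression_profile()]).
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.codon_profile <- function(object, bins = 24, ...) {
  ggplot(object, aes(x = .data$mean_log2_level)) +
    geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    labs(x = "mean log2 transcript level of codon",
         y = "codons",
         title = "Transcript-level profile of the 64 codons") +
    theme_minimal()
}

#' Plot binned synonymous-fraction trajectories
#'
#' Fraction of each codon within its family across property bins, faceted
#' by family.
#'
#' @param object A `binned_fractions` ([binned_synonymous_fractions()]).
#' @param families Families to show (default: the nine 2-fold sense
#'   families).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.binned_fractions <- function(object,
                                      families = code_tables()$twofold_aa,
                                      ...) {
  df <- object[object$family %in% families & !is.na(object$fraction), ]
  ggplot(df, aes(x = .data$bin_center, y = .data$fraction,
                 colour = .data$codon)) +
    geom_line() +
    geom_point(size = 0.8) +
    facet_wrap(~family) +
    labs(x = attr(object, "property") %||% "property bin",
         y = "synonymous fraction",
         title = "Synonymous-fraction trajectories") +
    theme_minimal()
}

#' Plot per-codon coherence correlations
#'
#' @param object A `codon_coherence` ([coherence()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.codon_coherence <- function(object, ...) {
  df <- object$by_codon[object$by_codon$computable, ]
  df <- df[order(df$r), ]
  df$codon <- factor(df$codon, levels = df$codon)
  ggplot(df, aes(x = .data$codon, y = .data$r, fill = .data$significant)) +
    geom_col() +
    labs(x = NULL, y = "Pearson R between trajectories",
         title = paste(object$properties[1], "vs", object$properties[2],
                       "-", object$call)) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Plot a Monte-Carlo null distribution
#'
#' Null distribution of the complementary-major-codon count with the
#' observed value marked.
#'
#' @param object An `mc_null` ([random_major_codon_null()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mc_null <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$count, y = .data$proportion)) +
    geom_col(fill = "grey35") +
    geom_vline(xintercept = object$observed, linetype = 2, colour = "red") +
    labs(x = "complementary major codons", y = "null proportion",
         title = paste0("Random-major-codon null (P = ",
                        format(object$p_value, digits = 3), ")")) +
    theme_minimal()
}

#' Plot PARS codon scores
#'
#' PARS-gene versus PARS-nucleotide per-codon means; the much larger spread
#' of the nucleotide-level scores is the signature of codons sitting
#' non-randomly in locally structured regions.
#'
#' @param object A `codon_pars` ([pars_codon_scores()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.codon_pars <- function(object, ...) {
  df <- object$scores[object$scores$n > 0, ]
  ggplot(df, aes(x = .data$pars_gene, y = .data$pars_nucleotide)) +
    geom_point() +
    labs(x = "PARS-gene codon mean", y = "PARS-nucleotide codon mean",
         title = "Codon structural scores") +
    theme_minimal()
}
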