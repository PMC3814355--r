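# Frame-0 codon counting. The per-site representation built here (host gene
# index + codon index for every codon slot) is shared by the expression
# profiles, the PARS scoring and all four randomizers, so it is built once
# and vectorised: all CDSs are concatenated and sliced with a single
# substring() call.

validate_genes <- function(genes, arg = "genes") {
  if (!is.data.frame(genes) || !all(c("gene_id", "cds") %in% names(genes))) {
    abort(paste0("`", arg, "` must be a data frame with columns `gene_id` and `cds`."),
          class = "codonscope_bad_input")
  }
  if (anyDuplicated(genes$gene_id)) {
    abort("Duplicate gene ids in `genes`.", class = "codonscope_duplicate_id")
  }
  len <- nchar(genes$cds)
  bad <- len < 3L | len %% 3L != 0L
  if (any(bad)) {
    abort(
      paste0("CDS length not a positive multiple of 3 for gene(s): ",
             paste(head(genes$gene_id[bad], 5), collapse = ", ")),
      class = "codonscope_frame_error"
    )
  }
  invisible(genes)
}

# Per-slot representation: list(gene = host row index, codon = index into the
# 64-codon table (NA for slots containing non-ACGT letters), n_codons = slots
# per gene, text = raw trinucleotide strings.
codon_slots <- function(genes, keep_text = FALSE) {
  validate_genes(genes)
  tab <- code_tables()
  len <- nchar(genes$cds)
  nc <- len %/% 3L
  g <- rep.int(seq_len(nrow(genes)), nc)
  big <- toupper(paste(genes$cds, collapse = ""))
  off <- cumsum(as.double(len)) - len
  start <- off[g] + (sequence(nc) - 1) * 3 + 1
  text <- substring(big, start, start + 2)
  out <- list(gene = g, codon = match(text, tab$codon), n_codons = nc)
  if (keep_text) out$text <- text
  out
}

# n_genes x 64 integer matrix of codon counts (skipped slots excluded).
codon_count_matrix <- function(genes, slots = NULL) {
  slots <- slots %||% codon_slots(genes)
  n <- nrow(genes)
  keep <- !is.na(slots$codon)
  m <- matrix(
    tabulate((slots$gene[keep] - 1L) * 64L + slots$codon[keep], nbins = n * 64L),
    nrow = n, ncol = 64L, byrow = TRUE
  )
  colnames(m) <- code_tables()$codon
  rownames(m) <- genes$gene_id
  m
}

#' Count frame-0 codons of coding sequences
#'
#' Counts the codons of each CDS read in frame 0. Codons containing letters
#' other than A/C/G/T are skipped (never silently counted); a terminal stop
#' codon is counted in the stop family. A CDS whose length is not a positive
#' multiple of 3 raises a frame error naming the gene. Internal stop codons
#' are counted as-is with a warning, since annotated CDSs are taken as given.
#'
#' @param genes A data frame with columns `gene_id` and `cds`.
#' @return A tibble with columns `gene_id`, `codon`, `aa`, `count` (observed
#'   codons only), carrying a `tally` attribute — a per-gene tibble of
#'   `n_sense`, `n_stop`, `n_skipped` — retrievable with [codon_tally()].
#' @seealso [pool_codons()], [synonymous_fractions()]
#' @export
#' @examples
#' count_codons(tibble::tibble(gene_id = "g1", cds = "ATGGGTTAA"))
count_codons <- function(genes) {
  tab <- code_tables()
  slots <- codon_slots(genes)
  n <- nrow(genes)
  skipped <- is.na(slots$codon)
  is_stop <- !skipped & !tab$sense[slots$codon]
  # stop codons occurring before the final slot of their gene
  internal <- is_stop & sequence(slots$n_codons) < slots$n_codons[slots$gene]
  if (any(internal)) {
    warn(paste0(sum(internal), " internal stop codon(s) found; counted as-is."),
         class = "codonscope_internal_stop")
  }
  m <- codon_count_matrix(genes, slots)
  tally <- tibble(
    gene_id = genes$gene_id,
    n_sense = as.integer(m %*% tab$sense),
    n_stop = as.integer(m %*% (!tab$sense)),
    n_skipped = tabulate(slots$gene[skipped], nbins = n)
  )
  idx <- which(m > 0, arr.ind = TRUE)
  out <- tibble(
    gene_id = genes$gene_id[idx[, 1]],
    codon = tab$codon[idx[, 2]],
    aa = tab$aa[idx[, 2]],
    count = m[idx]
  )
  out <- arrange(out, match(.data$gene_id, genes$gene_id), match(.data$codon, tab$codon))
  attr(out, "tally") <- tally
  out
}

#' Per-gene codon tallies
#'
#' @param counts The result of [count_codons()].
#' @return The per-gene tibble of `n_sense`, `n_stop`, `n_skipped` counts.
#' @export
codon_tally <- function(counts) {
  tally <- attr(counts, "tally")
  if (is.null(tally)) {
    abort("`counts` carries no tally; was it produced by count_codons()?",
          class = "codonscope_bad_input")
  }
  tally
}

#' Pool codon counts over genes
#'
#' @param counts A long counts tibble (from [count_codons()]) or any data
#'   frame with `codon` and `count` columns.
#' @return A tibble with one row per codon present: `codon`, `aa`, `count`.
#' @export
pool_codons <- function(counts) {
  v <- count_vector(counts)
  tab <- code_tables()
  keep <- v > 0
  tibble(codon = tab$codon[keep], aa = tab$aa[keep], count = unname(v[keep]))
}

# Coerce counts (long tibble, pooled tibble, named vector, or table) to a
# named length-64 numeric vector in canonical codon order.
count_vector <- function(counts) {
  tab <- code_tables()
  if (is.data.frame(counts)) {
    if (!all(c("codon", "count") %in% names(counts))) {
      abort("Counts data frame needs `codon` and `count` columns.",
            class = "codonscope_bad_input")
    }
    idx <- match(counts$codon, tab$codon)
    if (anyNA(idx)) {
      abort(paste0("Unknown codon(s): ",
                   paste(unique(counts$codon[is.na(idx)]), collapse = ", ")),
            class = "codonscope_bad_input")
    }
    v <- numeric(64)
    agg <- tapply(counts$count, idx, sum)
    v[as.integer(names(agg))] <- agg
  } else if (!is.null(names(counts))) {
    idx <- match(names(counts), tab$codon)
    if (anyNA(idx)) {
      abort(paste0("Unknown codon(s): ",
                   paste(unique(names(counts)[is.na(idx)]), collapse = ", ")),
            class = "codonscope_bad_input")
    }
    v <- numeric(64)
    agg <- tapply(as.numeric(counts), idx, sum)
    v[as.integer(names(agg))] <- agg
  } else {
    abort("Counts must be a data frame with codon/count or a named vector.",
          class = "codonscope_bad_input")
  }
  if (any(v < 0)) {
    abort("Negative codon counts.", class = "codonscope_bad_input")
  }
  names(v) <- tab$codon
  v
}

#' Synonymous codon fractions within families
#'
#' Within every synonymous family whose pooled count is positive, each codon's
#' fraction of the family total. Families with zero total are marked absent
#' (`fraction = NA`).
#'
#' @param counts Codon counts in any form accepted by [pool_codons()].
#' @return A tibble with columns `family` (amino acid, `*` for stop), `codon`,
#'   `count`, `family_count`, `fraction`, `absent`.
#' @export
#' @examples
#' synonymous_fractions(c(GCA = 1, GCT = 3))
synonymous_fractions <- function(counts) {
  tab <- code_tables()
  v <- count_vector(counts)
  fam_tot <- tapply(v, tab$aa, sum)[tab$aa]
  tibble(
    family = tab$aa,
    codon = tab$codon,
    count = as.numeric(v),
    family_count = as.numeric(fam_tot),
    fraction = as.numeric(ifelse(fam_tot > 0, v / fam_tot, NA_real_)),
    absent = as.numeric(fam_tot) == 0
  )
}

# Fractions as a named length-64 vector (NA where the family is absent).
fraction_vector <- function(fractions) {
  tab <- code_tables()
  if (is.data.frame(fractions)) {
    if (!all(c("codon", "fraction") %in% names(fractions))) {
      abort("Fractions data frame needs `codon` and `fraction` columns.",
            class = "codonscope_bad_input")
    }
    v <- rep(NA_real_, 64)
    idx <- match(fractions$codon, tab$codon)
    v[idx] <- fractions$fraction
  } else {
    v <- rep(NA_real_, 64)
    idx <- match(names(fractions), tab$codon)
    v[idx] <- as.numeric(fractions)
  }
  names(v) <- tab$codon
  v
}
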