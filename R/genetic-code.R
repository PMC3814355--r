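# Standard nuclear genetic code tables, built once from Biostrings and cached.
# All downstream code indexes codons 1..64 in the order of this table.

.gc_cache <- new.env(parent = emptyenv())

#' Reverse-complement trinucleotides
#'
#' Vectorised reverse complement for DNA strings (any length, but used
#' throughout for codons). No 3-mer is its own reverse complement, so codon
#' complementarity pairing never hits a self-pair.
#'
#' @param x Character vector of DNA strings (A/C/G/T).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp_codon(c("AAT", "GGT"))
revcomp_codon <- function(x) {
  y <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(y, "", fixed = TRUE),
         function(b) paste(rev(b), collapse = ""), character(1))
}

code_tables <- function() {
  if (!is.null(.gc_cache$tab)) {
    return(.gc_cache$tab)
  }
  code <- Biostrings::GENETIC_CODE
  codon <- gsub("U", "T", names(code), fixed = TRUE)
  aa <- unname(code) # "*" denotes the translation-stop signal
  fam <- split(codon, aa)
  fam <- lapply(fam, sort)
  fam_size <- lengths(fam)
  rc <- revcomp_codon(codon)
  base_idx <- t(vapply(strsplit(codon, "", fixed = TRUE),
                       function(b) match(b, c("A", "C", "G", "T")),
                       integer(3)))
  tab <- list(
    codon = codon,
    aa = aa,
    sense = aa != "*",
    family = fam,
    family_index = lapply(fam, function(f) match(f, codon)),
    family_size = unname(fam_size[aa]),
    degenerate_aa = setdiff(names(fam)[fam_size >= 2], "*"),
    twofold_aa = setdiff(names(fam)[fam_size == 2], "*"),
    rc_index = match(rc, codon),
    # base identity (1=A,2=C,3=G,4=T) at each codon position, 64 x 3
    base_index = base_idx
  )
  .gc_cache$tab <- tab
  tab
}

#' The standard genetic code as a tibble
#'
#' One row per codon with its amino acid (single-letter, `*` for stop) and the
#' size of its synonymous family. The standard nuclear code has 61 sense
#' codons and 3 stop codons; eighteen sense families carry two or more codons
#' (nine of them exactly two), and Met/Trp are singletons.
#'
#' @return A tibble with columns `codon`, `aa`, `family_size`, `degenerate`.
#' @export
#' @examples
#' genetic_code()
genetic_code <- function() {
  tab <- code_tables()
  tibble(
    codon = tab$codon,
    aa = tab$aa,
    family_size = tab$family_size,
    degenerate = tab$aa %in% tab$degenerate_aa
  )
}

#' Synonymous families of the standard code
#'
#' @param degenerate_only Keep only families with two or more codons
#'   (the 18 degenerate sense families plus, optionally, the stop family).
#' @param include_stop Include the 3-codon stop family.
#' @return A named list of codon character vectors, names are amino acids
#'   (`*` for stop).
#' @export
codon_families <- function(degenerate_only = FALSE, include_stop = TRUE) {
  tab <- code_tables()
  fam <- tab$family
  if (degenerate_only) {
    fam <- fam[names(fam) %in% c(tab$degenerate_aa, "*")]
  }
  if (!include_stop) {
    fam <- fam[names(fam) != "*"]
  }
  fam
}
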