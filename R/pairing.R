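# Codon-anticodon pairing. Both strands are written 5'->3', so a
# Watson-Crick-paired anticodon is the reverse complement of its codon, and
# the wobble position pairs codon position 3 against anticodon position 1.
# Only the G:U / U:G wobble is modelled (inosine and modified bases are not).

wc_match <- function(x, y) {
  # TRUE where single bases x and y form a Watson-Crick pair
  chartr("ACGT", "TGCA", x) == y
}

#' Classify a codon-anticodon pairing
#'
#' Both codon and anticodon are read 5'->3' (DNA alphabet; U is accepted and
#' read as T). The pair is `watson_crick` iff the anticodon is the reverse
#' complement of the codon; `wobble` iff codon positions 1-2 pair
#' Watson-Crick with anticodon positions 3-2 and the third codon base pairs
#' with the first anticodon base as U:G or G:U; otherwise `none`.
#'
#' @param codon,anticodon Character vectors of trinucleotides (recycled to a
#'   common length).
#' @return A character vector of `"watson_crick"`, `"wobble"` or `"none"`.
#' @export
#' @examples
#' classify_pairing("GGC", "GCC") # watson_crick
#' classify_pairing("GGT", "GCC") # wobble (U:G at the third codon position)
classify_pairing <- function(codon, anticodon) {
  n <- max(length(codon), length(anticodon))
  codon <- rep_len(toupper(chartr("U", "T", codon)), n)
  anticodon <- rep_len(toupper(chartr("U", "T", anticodon)), n)
  ok <- grepl("^[ACGT]{3}$", codon) & grepl("^[ACGT]{3}$", anticodon)
  if (!all(ok)) {
    abort("Codon and anticodon must be trinucleotides over A/C/G/T (or U).",
          class = "codonscope_domain_error")
  }
  c1 <- substr(codon, 1, 1); c2 <- substr(codon, 2, 2); c3 <- substr(codon, 3, 3)
  a1 <- substr(anticodon, 1, 1); a2 <- substr(anticodon, 2, 2); a3 <- substr(anticodon, 3, 3)
  wc <- wc_match(c1, a3) & wc_match(c2, a2) & wc_match(c3, a1)
  stem <- wc_match(c1, a3) & wc_match(c2, a2)
  wob <- stem & ((c3 == "T" & a1 == "G") | (c3 == "G" & a1 == "T"))
  ifelse(wc, "watson_crick", ifelse(wob, "wobble", "none"))
}

#' Wobble anticodon of a codon
#'
#' The anticodon (5'->3') that decodes the codon through a G:U or U:G pair at
#' the third codon position, with Watson-Crick pairing at positions 1-2.
#' Only codons ending in T or G have one under the modelled wobble set;
#' others return `NA`.
#'
#' @param codon Character vector of trinucleotides.
#' @return Character vector of anticodons (or `NA`).
#' @export
#' @examples
#' wobble_anticodon("GGT") # "GCC": the glycine wobble decoder
wobble_anticodon <- function(codon) {
  codon <- toupper(chartr("U", "T", codon))
  if (!all(grepl("^[ACGT]{3}$", codon))) {
    abort("`codon` must be trinucleotides over A/C/G/T (or U).",
          class = "codonscope_domain_error")
  }
  c1 <- substr(codon, 1, 1); c2 <- substr(codon, 2, 2); c3 <- substr(codon, 3, 3)
  first <- ifelse(c3 == "T", "G", ifelse(c3 == "G", "T", NA_character_))
  out <- paste0(first, chartr("ACGT", "TGCA", c2), chartr("ACGT", "TGCA", c1))
  out[is.na(first)] <- NA_character_
  out
}
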