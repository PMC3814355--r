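# Small fixtures shared across test files. Everything is built in code.

genes_tbl <- function(...) {
  seqs <- c(...)
  tibble::tibble(gene_id = names(seqs), cds = unname(seqs))
}

# Repeat codons into a CDS string.
cds_of <- function(...) {
  paste(c(...), collapse = "")
}

# A uniform reference usage: every codon equally frequent, so reference
# majors are the alphabetically first codon of each family.
uniform_reference <- function() {
  synonymous_fractions(stats::setNames(rep(10, 64), genetic_code()$codon))
}

# Reference usage whose majors are the generator's default major set.
major_reference <- function() {
  majors <- codonscope:::default_major_codons()
  counts <- stats::setNames(rep(1, 64), genetic_code()$codon)
  counts[majors] <- 90
  synonymous_fractions(counts)
}

# A small synthetic config for unit tests (NOT the acceptance conditions).
small_config <- function(n_genes = 250L, ...) {
  synthetic_genome_config(
    n_genes = n_genes, length_min = 50L, length_shape = 3, length_scale = 40,
    ...
  )
}

# Translate CDSs independently of the package's own code tables.
translate_oracle <- function(cds) {
  as.character(Biostrings::translate(
    Biostrings::DNAStringSet(cds),
    no.init.codon = TRUE, if.fuzzy.codon = "X"
  ))
}
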