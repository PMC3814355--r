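# File I/O. FASTA goes through Biostrings; tables through readr. Gene ids
# join across files by exact string match; positional outputs are 0-based.

IUPAC_CHARS <- "ACGTURYSWKMBDHVN"

#' Read coding sequences from FASTA
#'
#' Record ids are the header token before the first whitespace; sequences
#' are uppercased and U is mapped to T. Empty files, duplicate ids and
#' non-IUPAC characters raise explicit parse errors.
#'
#' @param path FASTA file.
#' @return A tibble with columns `gene_id` and `cds`.
#' @export
read_cds_fasta <- function(path) {
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("Cannot parse FASTA: ", conditionMessage(e)),
                              class = "codonscope_parse_error")
  )
  if (length(seqs) == 0) {
    abort("FASTA file contains no records.", class = "codonscope_parse_error")
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate FASTA ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "codonscope_duplicate_id")
  }
  cds <- chartr("U", "T", toupper(as.character(seqs)))
  bad <- grepl(paste0("[^", IUPAC_CHARS, "]"), cds)
  if (any(bad)) {
    abort(paste0("Non-IUPAC characters in record(s): ",
                 paste(head(ids[bad], 5), collapse = ", ")),
          class = "codonscope_parse_error")
  }
  tibble(gene_id = unname(ids), cds = unname(cds))
}

#' Write gene sequences as FASTA
#'
#' @param genes A data frame with columns `gene_id` and `cds` (or a second
#'   column named `sequence`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(genes, path) {
  seq_col <- intersect(c("cds", "sequence"), names(genes))[1]
  if (is.na(seq_col) || !"gene_id" %in% names(genes)) {
    abort("`genes` must have `gene_id` and `cds` (or `sequence`).",
          class = "codonscope_bad_input")
  }
  x <- Biostrings::BStringSet(setNames(genes[[seq_col]], genes$gene_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a per-gene property table
#'
#' TSV with a header; the first column (or `gene_id`) holds gene ids and
#' `value_column` (default: the second column) the values. Non-numeric and
#' missing values are dropped with a message; duplicate gene rows keep the
#' last occurrence with a warning.
#'
#' @param path TSV file.
#' @param value_column Name of the value column; `NULL` for the second.
#' @return A tibble with columns `gene_id` and `value`.
#' @export
read_property_table <- function(path, value_column = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  id_col <- if ("gene_id" %in% names(df)) "gene_id" else names(df)[1]
  value_column <- value_column %||% setdiff(names(df), id_col)[1]
  if (is.na(value_column) || !value_column %in% names(df)) {
    abort(paste0("Column `", value_column %||% "<second>", "` not found."),
          class = "codonscope_schema_error")
  }
  val <- suppressWarnings(as.numeric(df[[value_column]]))
  drop <- is.na(val)
  if (any(drop)) {
    inform(paste0(sum(drop), " row(s) with missing/non-numeric values dropped."))
  }
  out <- tibble(gene_id = df[[id_col]], value = val)[!drop, ]
  if (anyDuplicated(out$gene_id)) {
    warn("Duplicate gene ids: keeping the last occurrence of each.",
         class = "codonscope_duplicate_id_warning")
    out <- out[!duplicated(out$gene_id, fromLast = TRUE), ]
  }
  out
}

#' Read per-nucleotide PARS profiles from long TSV
#'
#' Expects columns `gene_id`, `position` (0-based) and `score`; positions of
#' each gene must be exactly 0..L-1.
#'
#' @param path TSV file.
#' @return A profiles tibble (`gene_id`, `score` list column).
#' @export
read_pars_profiles <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("gene_id", "position", "score")
  if (!all(need %in% names(df))) {
    abort("PARS TSV needs columns gene_id, position, score.",
          class = "codonscope_schema_error")
  }
  df <- arrange(df, .data$gene_id, .data$position)
  by_gene <- split(df, df$gene_id)
  bad <- names(by_gene)[vapply(by_gene, function(d) {
    !identical(as.integer(d$position), seq_len(nrow(d)) - 1L)
  }, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("Non-contiguous 0-based positions for gene(s): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "codonscope_parse_error")
  }
  pars_profiles(names(by_gene), lapply(by_gene, function(d) d$score))
}

#' Write PARS profiles as long TSV (0-based positions)
#'
#' @param profiles A profiles tibble (`gene_id`, `score` list column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pars_profiles <- function(profiles, path) {
  long <- tibble(
    gene_id = rep(profiles$gene_id, lengths(profiles$score)),
    position = unlist(lapply(lengths(profiles$score), seq_len)) - 1L,
    score = unlist(profiles$score)
  )
  readr::write_tsv(long, path)
  invisible(path)
}

#' Read an intron table
#'
#' @param path TSV with columns `gene_id`, `length`, `delta_g`.
#' @return A tibble.
#' @export
read_intron_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("gene_id", "length", "delta_g") %in% names(df))) {
    abort("Intron TSV needs columns gene_id, length, delta_g.",
          class = "codonscope_schema_error")
  }
  df
}

#' Write a synthetic genome to a directory
#'
#' Emits the same dialects the analysis functions read: `cds.fasta`,
#' `introns.fasta`, `expression.tsv`, `protein.tsv`, `pars.tsv` (long,
#' 0-based), `introns.tsv`, `trna.tsv`, `truth.tsv` and a JSON run
#' manifest.
#'
#' @param genome A `synthetic_genome`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_genome <- function(genome, dir) {
  if (!inherits(genome, "synthetic_genome")) {
    abort("`genome` must be a synthetic_genome.", class = "codonscope_bad_input")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cds_fasta(genome$genes, file.path(dir, "cds.fasta"))
  if (nrow(genome$introns) > 0) {
    write_cds_fasta(
      tibble(gene_id = genome$introns$gene_id,
             sequence = genome$introns$sequence),
      file.path(dir, "introns.fasta")
    )
  }
  readr::write_tsv(genome$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(genome$protein, file.path(dir, "protein.tsv"))
  if (nrow(genome$pars) > 0) {
    write_pars_profiles(genome$pars, file.path(dir, "pars.tsv"))
  }
  readr::write_tsv(genome$introns[, c("gene_id", "length", "delta_g")],
                   file.path(dir, "introns.tsv"))
  readr::write_tsv(genome$trna, file.path(dir, "trna.tsv"))
  truth_report(genome$truth, file.path(dir, "truth.tsv"))
  run_manifest("write_synthetic_genome", seed = genome$seed,
               inputs = character(0),
               path = file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Write a reproducibility manifest
#'
#' Records the command, seed, package version, input-file digests and a
#' timestamp as JSON.
#'
#' @param command Character label of the run.
#' @param seed Integer seed used.
#' @param inputs Character vector of input file paths to digest.
#' @param path Output JSON path (`NULL` to return the manifest only).
#' @return The manifest list, invisibly.
#' @export
run_manifest <- function(command, seed = NA_integer_, inputs = character(0),
                         path = NULL) {
  manifest <- list(
    command = command,
    seed = seed,
    package = "codonscope",
    version = as.character(utils::packageVersion("codonscope")),
    inputs = as.list(tools::md5sum(inputs)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(manifest)
}
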