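# Internal helpers shared across modules.

#' Reverse complement of nucleotide strings
#'
#' Vectorised reverse complement over plain character vectors. `N` maps to `N`.
#'
#' @param x Character vector of A/C/G/T/N strings.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(x) {
  stopifnot(is.character(x))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Extract the residues column from either a tibble of sequence records or a
# (possibly named) character vector.
seq_vector <- function(seqs) {
  if (is.data.frame(seqs)) {
    if (!all(c("id", "residues") %in% names(seqs))) {
      abort("sequence table must have columns `id` and `residues`",
            class = "neonull_format_error")
    }
    setNames(as.character(seqs$residues), as.character(seqs$id))
  } else if (is.character(seqs)) {
    seqs
  } else {
    abort("expected a sequence table or character vector",
          class = "neonull_format_error")
  }
}

# Deterministic short hash used in provenance headers (djb2 over the
# serialized config; stable across sessions, not cryptographic).
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

provenance_lines <- function(config = NULL, seed = NULL) {
  c(
    sprintf("# neonull %s", as.character(utils::packageVersion("neonull"))),
    sprintf("# config=%s seed=%s", config_hash(config),
            if (is.null(seed)) "NA" else as.character(seed))
  )
}

# Write a tibble as TSV with a provenance comment header.
write_report_tsv <- function(x, path, config = NULL, seed = NULL) {
  writeLines(provenance_lines(config, seed), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_report_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}
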