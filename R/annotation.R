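# Retention filters for externally produced HLA-binding predictions and
# germline allele-frequency tables, and their join onto mapping entries.

#' Filter MHC-binding predictions by percent rank
#'
#' Keeps predictions whose `%Rank` (rank of the predicted affinity against
#' random natural peptides; lower = stronger binder) is strictly below the
#' threshold. All retained predictions per epitope are kept. Rows with a
#' missing rank are rejected with a warning.
#'
#' @param rows Tibble with columns `peptide`, `allele`, `percent_rank`, and
#'   optionally `affinity_nm`.
#' @param rank_max Retention threshold (default 2, i.e. %Rank < 2%).
#' @return The retained rows, order preserved.
#' @export
filter_binding <- function(rows, rank_max = 2.0) {
  stopifnot(is.data.frame(rows))
  if (!nrow(rows)) return(as_tibble(rows))
  if (!"percent_rank" %in% names(rows)) {
    abort("binding table lacks a `percent_rank` column",
          class = "neonull_format_error")
  }
  missing <- is.na(rows$percent_rank)
  if (any(missing)) {
    warn(sprintf("%d binding row(s) lacked %%Rank and were rejected",
                 sum(missing)))
  }
  as_tibble(rows)[!missing & rows$percent_rank < rank_max, , drop = FALSE]
}

#' Filter germline variant frequencies
#'
#' Retains rows with combined allele frequency above 1e-7, a missense
#' consequence, protein-coding biotype, and an Ensembl transcript feature
#' (id starting with `ENST`).
#'
#' @param rows Tibble with columns `af`, `consequence`, `biotype`,
#'   `feature`, a `peptide` key, and optional per-ancestry frequency
#'   columns (`af_xx`, `af_xy`, `af_afr`, ... , `grpmax`).
#' @param af_min Allele-frequency floor (exclusive; default 1e-7).
#' @return The retained rows, order preserved.
#' @export
filter_germline <- function(rows, af_min = 1e-7) {
  stopifnot(is.data.frame(rows))
  if (!nrow(rows)) return(as_tibble(rows))
  need <- c("af", "consequence", "biotype", "feature")
  if (!all(need %in% names(rows))) {
    abort(sprintf("germline table lacks column(s): %s",
                  paste(setdiff(need, names(rows)), collapse = ", ")),
          class = "neonull_format_error")
  }
  keep <- !is.na(rows$af) & rows$af > af_min &
    rows$consequence == "missense_variant" &
    rows$biotype == "protein_coding" &
    stringr::str_starts(rows$feature, "ENST")
  as_tibble(rows)[keep & !is.na(keep), , drop = FALSE]
}

serialize_binding <- function(rows) {
  if (!nrow(rows)) return(NA_character_)
  aff <- if ("affinity_nm" %in% names(rows)) {
    sprintf("%s=%s nM(%%Rank %s)", rows$allele, rows$affinity_nm,
            rows$percent_rank)
  } else sprintf("%s(%%Rank %s)", rows$allele, rows$percent_rank)
  paste(aff, collapse = ";")
}

#' Join binding and germline annotations onto mapping entries
#'
#' Adds `neo_hla` (binding of the neoepitopes), `wt_hla` (binding of the
#' wildtype peptides) and `germline_af` columns to the entries. Matching is
#' exact, case-insensitive peptide equality; for entries whose peptide
#' column collapses several comma-separated peptides, all matches are
#' serialized. Unmatched entries get `NA`, never dropped. The join is
#' idempotent.
#'
#' @param entries Mapping entries tibble (or a `nullomer_mapping`).
#' @param binding Filtered binding predictions (see [filter_binding()]).
#' @param germline Filtered germline rows (see [filter_germline()]); needs a
#'   `peptide` column naming the neoepitope the variant produces.
#' @return The annotated entries tibble (or mapping, matching the input).
#' @export
join_metadata <- function(entries, binding = NULL, germline = NULL) {
  is_mapping <- inherits(entries, "nullomer_mapping")
  tbl <- if (is_mapping) entries$entries else as_tibble(entries)
  lookup_multi <- function(collapsed, fn) {
    vapply(collapsed, function(s) {
      if (is.na(s)) return(NA_character_)
      peps <- toupper(strsplit(s, ",")[[1]])
      out <- fn(peps)
      if (!length(out) || all(is.na(out))) NA_character_
      else paste(stats::na.omit(out), collapse = "|")
    }, character(1), USE.NAMES = FALSE)
  }
  if (!is.null(binding) && nrow(binding)) {
    b <- mutate(as_tibble(binding), peptide = toupper(.data$peptide))
    per_pep <- function(peps) {
      vapply(peps, function(p) {
        serialize_binding(b[b$peptide == p, , drop = FALSE])
      }, character(1), USE.NAMES = FALSE)
    }
    if ("neoepitopes" %in% names(tbl)) {
      tbl$neo_hla <- lookup_multi(tbl$neoepitopes, per_pep)
    }
    if ("wildtype_peptides" %in% names(tbl)) {
      tbl$wt_hla <- lookup_multi(tbl$wildtype_peptides, per_pep)
    }
  }
  if (!is.null(germline) && nrow(germline)) {
    g <- mutate(as_tibble(germline), peptide = toupper(.data$peptide))
    freq_cols <- intersect(c("af", "af_xx", "af_xy", "af_afr", "af_amr",
                             "af_asj", "af_eas", "af_fin", "af_mid",
                             "af_nfe", "af_sas", "grpmax"), names(g))
    per_pep <- function(peps) {
      vapply(peps, function(p) {
        rowsg <- g[g$peptide == p, , drop = FALSE]
        if (!nrow(rowsg)) return(NA_character_)
        paste(vapply(seq_len(nrow(rowsg)), function(i) {
          paste(sprintf("%s=%s", freq_cols,
                        unlist(rowsg[i, freq_cols], use.names = FALSE)),
                collapse = ",")
        }, character(1)), collapse = ";")
      }, character(1), USE.NAMES = FALSE)
    }
    if ("neoepitopes" %in% names(tbl)) {
      tbl$germline_af <- lookup_multi(tbl$neoepitopes, per_pep)
    }
  }
  if (is_mapping) {
    entries$entries <- tbl
    entries
  } else tbl
}
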