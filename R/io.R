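#' Read a clonotype table into a repertoire
#'
#' Parses a tab-delimited clonotype export in either the VDJtools dialect
#' (columns `count`, `freq`, `cdr3nt`, `cdr3aa`, `v`, `d`, `j`) or the AIRR
#' Rearrangement dialect (MiAIRR column names: `duplicate_count`,
#' `junction_aa`, `v_call`, `j_call`, optional `productive`). Clonotypes are
#' aggregated over identical `cdr3_aa` + V + J calls with counts summed, and
#' frequencies are recomputed from the aggregated counts, so the stored
#' `freq` column (if any) is advisory only.
#'
#' @param path Path to a UTF-8, tab-delimited file with a header row.
#' @param dialect `"vdjtools"` or `"airr"`.
#' @param sample_id Sample identifier; defaults to the file name sans
#'   extension.
#' @param metadata,qc Optional metadata/QC lists attached to the repertoire.
#' @inheritParams repertoire
#' @return A [repertoire()] object.
#' @seealso [write_clonotype_table()]
#' @export
read_clonotype_table <- function(path, dialect = c("vdjtools", "airr"),
                                 sample_id = NULL, metadata = list(),
                                 qc = list(), aggregate_by = c("cdr3_vj", "cdr3")) {
  dialect <- arg_match(dialect)
  aggregate_by <- arg_match(aggregate_by)
  if (!file.exists(path)) {
    abort(sprintf("clonotype table not found: %s", path), class = "tcrisk_io_error")
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)

  required <- switch(dialect,
    vdjtools = c("count", "freq", "cdr3aa", "v", "j"),
    airr = c("duplicate_count", "junction_aa", "v_call", "j_call")
  )
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    abort(sprintf("%s table is missing required column(s): %s",
                  dialect, paste(missing, collapse = ", ")),
          class = "tcrisk_format_error")
  }

  count_col <- if (dialect == "vdjtools") "count" else "duplicate_count"
  counts <- suppressWarnings(as.numeric(raw[[count_col]]))
  bad <- which(is.na(counts) & !is.na(raw[[count_col]]))
  if (length(bad) > 0L) {
    abort(sprintf("non-numeric %s '%s' at data row %d",
                  count_col, raw[[count_col]][bad[1L]], bad[1L]),
          class = "tcrisk_parse_error")
  }

  tbl <- if (dialect == "vdjtools") {
    tibble(
      cdr3_aa = raw$cdr3aa,
      cdr3_nt = if ("cdr3nt" %in% names(raw)) raw$cdr3nt else NA_character_,
      v_gene = raw$v,
      d_gene = if ("d" %in% names(raw)) raw$d else NA_character_,
      j_gene = raw$j,
      count = counts
    )
  } else {
    tibble(
      cdr3_aa = raw$junction_aa,
      cdr3_nt = if ("junction" %in% names(raw)) raw$junction else NA_character_,
      v_gene = raw$v_call,
      d_gene = if ("d_call" %in% names(raw)) raw$d_call else NA_character_,
      j_gene = raw$j_call,
      count = counts,
      # AIRR productive column ("T"/"F"/"TRUE"/"FALSE") takes precedence over
      # sequence markers when present
      productive = if ("productive" %in% names(raw)) {
        raw$productive %in% c("T", "TRUE", "true", "True")
      } else {
        NA
      }
    )
  }

  repertoire(tbl, sample_id = sample_id, metadata = metadata, qc = qc,
             aggregate_by = aggregate_by)
}

#' Write a repertoire as a clonotype table
#'
#' Writes the tab-delimited inverse of [read_clonotype_table()]; a read of the
#' written file reproduces the repertoire exactly (aggregated repertoires
#' round-trip bit-identically in both dialects).
#'
#' @param rep A `tcr_repertoire`.
#' @param path Output file path.
#' @param dialect `"vdjtools"` or `"airr"`.
#' @return `path`, invisibly.
#' @export
write_clonotype_table <- function(rep, path, dialect = c("vdjtools", "airr")) {
  dialect <- arg_match(dialect)
  out <- if (dialect == "vdjtools") {
    tibble(
      count = rep$count,
      freq = rep$frequency,
      cdr3nt = rep$cdr3_nt,
      cdr3aa = rep$cdr3_aa,
      v = rep$v_gene,
      d = rep$d_gene,
      j = rep$j_gene
    )
  } else {
    tibble(
      sequence_id = sprintf("%s_%06d", sample_id(rep), seq_len(nrow(rep))),
      junction_aa = rep$cdr3_aa,
      junction = rep$cdr3_nt,
      duplicate_count = rep$count,
      v_call = rep$v_gene,
      d_call = rep$d_gene,
      j_call = rep$j_gene,
      productive = ifelse(rep$productive, "T", "F")
    )
  }
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}
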