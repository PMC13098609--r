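#' Construct a TCR repertoire from a clonotype data frame
#'
#' A repertoire is the collection of clonotypes observed in one biological
#' sample: each row is a unique CDR3 amino-acid sequence (optionally with its
#' nucleotide sequence and V/D/J gene calls), its read count, and its frequency
#' among all reads of the sample. The object is a tibble carrying the sample
#' identifier and free-form metadata (cohort group, age, sex, tissue,
#' timepoint) as attributes, so it flows through dplyr verbs like any other
#' data frame while the package's own functions preserve its identity.
#'
#' Clonotypes are aggregated (counts summed) over the aggregation key, the
#' frequency column is recomputed as `count / sum(count)`, and rows are put in
#' the package's deterministic order: decreasing count, ties broken by
#' lexicographic `cdr3_aa`.
#'
#' @param clonotypes Data frame with at least `cdr3_aa` and `count` columns.
#'   Optional columns: `cdr3_nt`, `v_gene`, `d_gene`, `j_gene`, `productive`.
#'   When `productive` is absent it is inferred from the sequence: a CDR3
#'   containing `*` (stop codon) or `_` (frameshift) is nonproductive.
#' @param sample_id Sample identifier string.
#' @param metadata Named list of sample-level metadata (e.g. `group`, `age`,
#'   `sex`, `tissue`, `timepoint`).
#' @param qc Named list of sequencing QC fields accepted as metadata flags
#'   (e.g. `raw_gb`, `pct_primer_reads`, `pct_cdr3_reads`).
#' @param aggregate_by Aggregation key: `"cdr3_vj"` (default) merges rows with
#'   identical `cdr3_aa` + `v_gene` + `j_gene`; `"cdr3"` merges on the
#'   amino-acid sequence alone (used by the curation stage, which operates on
#'   amino-acid sequences only).
#'
#' @return A `tcr_repertoire`: a tibble with columns `cdr3_aa`, `cdr3_nt`,
#'   `v_gene`, `d_gene`, `j_gene`, `count`, `frequency`, `productive`.
#' @examples
#' rep <- repertoire(
#'   data.frame(cdr3_aa = c("CASSLGQGF", "CASRDSYEQYF"), count = c(6, 4)),
#'   sample_id = "S1"
#' )
#' total_reads(rep)
#' @export
repertoire <- function(clonotypes, sample_id = "sample",
                       metadata = list(), qc = list(),
                       aggregate_by = c("cdr3_vj", "cdr3")) {
  aggregate_by <- arg_match(aggregate_by)
  stopifnot(is.data.frame(clonotypes))
  for (col in c("cdr3_aa", "count")) {
    if (!col %in% names(clonotypes)) {
      abort(sprintf("clonotype table lacks required column '%s'", col),
            class = "tcrisk_format_error")
    }
  }
  tbl <- as_tibble(clonotypes)
  if (!is.numeric(tbl$count)) {
    bad <- which(is.na(suppressWarnings(as.numeric(tbl$count))))
    abort(sprintf("non-numeric count at row %s",
                  paste(utils::head(bad, 5L), collapse = ", ")),
          class = "tcrisk_parse_error")
  }
  if (any(tbl$count < 0)) abort("negative clone count", class = "tcrisk_domain_error")
  for (col in c("cdr3_nt", "v_gene", "d_gene", "j_gene")) {
    if (!col %in% names(tbl)) tbl[[col]] <- NA_character_
  }
  if (!"productive" %in% names(tbl) || all(is.na(tbl$productive))) {
    tbl$productive <- !stringr::str_detect(tbl$cdr3_aa, "[*_]")
  }
  tbl$productive <- as.logical(tbl$productive)

  key <- if (aggregate_by == "cdr3_vj") c("cdr3_aa", "v_gene", "j_gene") else "cdr3_aa"
  tbl <- tbl %>%
    group_by(across(all_of(key))) %>%
    summarise(
      cdr3_nt = dplyr::first(.data$cdr3_nt),
      d_gene = dplyr::first(.data$d_gene),
      count = sum(.data$count),
      productive = all(.data$productive),
      .groups = "drop"
    )
  if (aggregate_by == "cdr3") {
    tbl$v_gene <- NA_character_
    tbl$j_gene <- NA_character_
  }
  total <- sum(tbl$count)
  tbl <- tbl %>%
    mutate(frequency = if (total > 0) .data$count / total else 0) %>%
    select("cdr3_aa", "cdr3_nt", "v_gene", "d_gene", "j_gene",
           "count", "frequency", "productive") %>%
    arrange(desc(.data$count), .data$cdr3_aa)

  new_repertoire(tbl, sample_id = sample_id, metadata = metadata, qc = qc)
}

# low-level constructor: no validation/aggregation, just stamps attributes
new_repertoire <- function(tbl, sample_id, metadata = list(), qc = list()) {
  structure(
    as_tibble(tbl),
    sample_id = sample_id,
    metadata = metadata,
    qc = qc,
    class = c("tcr_repertoire", class(as_tibble(tbl)))
  )
}

# re-stamp repertoire attributes after a dplyr transformation
rebuild_repertoire <- function(tbl, template) {
  new_repertoire(tbl,
                 sample_id = sample_id(template),
                 metadata = attr(template, "metadata"),
                 qc = attr(template, "qc"))
}

#' Repertoire accessors
#'
#' `total_reads()` is the sum of clone counts, `sample_id()` the sample
#' identifier, `sample_metadata()` the metadata list.
#'
#' @param rep A `tcr_repertoire`.
#' @return An integer-valued scalar, a string, or a list respectively.
#' @export
total_reads <- function(rep) sum(rep$count)

#' @rdname total_reads
#' @export
sample_id <- function(rep) attr(rep, "sample_id") %||% "sample"

#' @rdname total_reads
#' @export
sample_metadata <- function(rep) attr(rep, "metadata") %||% list()

#' @export
print.tcr_repertoire <- function(x, ...) {
  meta <- sample_metadata(x)
  grp <- if (!is.null(meta$group)) paste0(", group ", meta$group) else ""
  cat(sprintf("# TCR repertoire '%s': %d clonotypes, %s reads%s\n",
              sample_id(x), nrow(x), format(total_reads(x), big.mark = ","), grp))
  NextMethod()
}

# internal sanity check used by downstream stages
check_normalized <- function(rep, tol = 1e-9) {
  if (nrow(rep) == 0L) abort("empty repertoire", class = "tcrisk_empty_error")
  if (abs(sum(rep$frequency) - 1) > tol) {
    abort("repertoire frequencies do not sum to 1; renormalize first",
          class = "tcrisk_domain_error")
  }
  invisible(rep)
}

#' CDR3 amino-acid length of each clonotype
#'
#' Length is the number of residues of the reported `cdr3_aa` string as-is,
#' conserved anchor residues included; no trimming is applied.
#'
#' @param rep A `tcr_repertoire`.
#' @return Integer vector, one element per clonotype.
#' @export
cdr3_lengths <- function(rep) nchar(rep$cdr3_aa)
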