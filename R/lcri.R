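#' Flag cancer-associated clones in a repertoire
#'
#' Scores every clone whose CDR3 length is covered by the model set and
#' flags it iff its model-predicted probability of the cancer-associated
#' class strictly exceeds the length-specific calibrated threshold. Clones
#' outside the length range are never flagged.
#'
#' @param rep A productive, normalized `tcr_repertoire`.
#' @param models A `scorer_set`.
#' @param thresholds A `threshold_table` covering the model lengths.
#' @param lengths Length range scored (default `11:20`).
#' @return The repertoire tibble with added columns `length`, `score`
#'   (`NA` outside the range) and `flagged`.
#' @export
flag_cancer_clones <- function(rep, models, thresholds, lengths = 11:20) {
  check_normalized(rep, tol = 1e-6)
  thr_tbl <- as_tibble(thresholds)
  missing <- setdiff(lengths, thr_tbl$length)
  if (length(missing) > 0L) {
    abort(sprintf("no threshold for length(s) %s",
                  paste(missing, collapse = ", ")),
          class = "tcrisk_domain_error")
  }
  len <- nchar(rep$cdr3_aa)
  score <- rep(NA_real_, nrow(rep))
  for (l in intersect(lengths, unique(len))) {
    model <- models[[as.character(l)]]
    if (is.null(model)) {
      abort(sprintf("no model for length %d", l), class = "tcrisk_domain_error")
    }
    sel <- which(len == l)
    score[sel] <- predict_proba(model, rep$cdr3_aa[sel])
  }
  thr <- thr_tbl$threshold[match(len, thr_tbl$length)]
  flagged <- !is.na(score) & score > thr # strict '>', matching calibration
  out <- rep
  out$length <- len
  out$score <- score
  out$flagged <- flagged
  rebuild_repertoire(out, rep)
}

#' Lung Cancer Risk Index of one sample
#'
#' The LCRI is the sum of the clonal frequencies of all clones flagged as
#' cancer-associated, a number between 0 and 1; higher values indicate
#' greater risk. Frequencies are the sample's productive-clone frequencies
#' over all productive reads (not renormalized to the scored length range),
#' so the LCRI is bounded above by the eligible frequency mass of
#' length-11-20 clones; `renormalize_eligible = TRUE` divides by that mass
#' instead.
#'
#' @param rep A repertoire already annotated by [flag_cancer_clones()], or a
#'   plain repertoire if `flags` is given.
#' @param flags Optional logical vector aligned to the clonotypes,
#'   overriding the `flagged` column.
#' @param lengths Length range defining the eligible mass (default `11:20`).
#' @param renormalize_eligible Express the LCRI relative to the eligible
#'   mass (default `FALSE`).
#' @return An `lcri_result`: one-row tibble with `sample_id`, `lcri`,
#'   `n_flagged`, `eligible_mass`, and a `per_length` list-column holding
#'   the per-length flagged-clone counts and frequency mass.
#' @export
compute_lcri <- function(rep, flags = NULL, lengths = 11:20,
                         renormalize_eligible = FALSE) {
  if (is.null(flags)) {
    if (!"flagged" %in% names(rep)) {
      abort("repertoire has no `flagged` column; run flag_cancer_clones() or pass `flags`",
            class = "tcrisk_domain_error")
    }
    flags <- rep$flagged
  }
  if (length(flags) != nrow(rep)) {
    abort(sprintf("flag vector length %d does not match %d clonotypes",
                  length(flags), nrow(rep)),
          class = "tcrisk_validation_error")
  }
  len <- nchar(rep$cdr3_aa)
  eligible <- len >= min(lengths) & len <= max(lengths)
  eligible_mass <- sum(rep$frequency[eligible])
  lcri <- sum(rep$frequency[flags])
  per_length <- tibble(length = len[flags], frequency = rep$frequency[flags]) %>%
    group_by(.data$length) %>%
    summarise(n_flagged = dplyr::n(), mass = sum(.data$frequency),
              .groups = "drop")
  if (renormalize_eligible && eligible_mass > 0) {
    lcri <- lcri / eligible_mass
    per_length$mass <- per_length$mass / eligible_mass
  }
  out <- tibble(
    sample_id = sample_id(rep),
    lcri = lcri,
    n_flagged = sum(flags),
    eligible_mass = eligible_mass,
    per_length = list(per_length)
  )
  structure(out, class = c("lcri_result", class(out)))
}

#' LCRI for a whole cohort
#'
#' Applies the standard preprocessing chain (nonproductive-clone removal,
#' then downsampling to `depth` reads), scores and flags clones, and
#' computes the LCRI for every repertoire, joining cohort metadata when
#' available.
#'
#' @param reps List of `tcr_repertoire` objects.
#' @param models A `scorer_set`.
#' @param thresholds A `threshold_table`.
#' @param metadata Optional tibble with a `sample_id` column to join.
#' @param depth Downsampling depth (`NULL` to skip; default 100,000).
#' @param seed Seed for the downsampling draws (per-sample seeds are derived
#'   deterministically from it).
#' @param lengths Scored length range.
#' @return Tibble with one LCRI row per sample (metadata columns appended).
#' @export
lcri_cohort <- function(reps, models, thresholds, metadata = NULL,
                        depth = 1e5, seed = 1L, lengths = 11:20) {
  rows <- map(seq_along(reps), function(k) {
    rep <- reps[[k]]
    ds_seed <- (seed + 7919 * k) %% 2147483647
    pre <- preprocess_repertoire(rep, depth = depth, seed = ds_seed)
    flagged <- flag_cancer_clones(pre, models, thresholds, lengths = lengths)
    compute_lcri(flagged, lengths = lengths)
  })
  out <- list_rbind(rows)
  if (!is.null(metadata)) {
    out <- left_join(out, as_tibble(metadata), by = "sample_id")
  }
  out
}

#' Write per-cohort LCRI results
#'
#' CSV export (one row per sample, without the nested per-length detail)
#' plus an optional JSON with the per-length decomposition.
#'
#' @param results Output of [lcri_cohort()].
#' @param path CSV destination.
#' @param json_path Optional JSON destination for per-sample detail.
#' @return `path` invisibly.
#' @export
write_lcri <- function(results, path, json_path = NULL) {
  flat <- as_tibble(results) %>% select(-dplyr::any_of("per_length"))
  readr::write_csv(flat, path, progress = FALSE)
  if (!is.null(json_path)) {
    detail <- map(seq_len(nrow(results)), function(i) {
      list(sample_id = results$sample_id[i], lcri = results$lcri[i],
           per_length = results$per_length[[i]])
    })
    jsonlite::write_json(detail, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
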