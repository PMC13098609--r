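#' Remove nonproductive clonotypes
#'
#' A CDR3 amino-acid sequence containing a stop codon (`*`) or a frameshift
#' marker (`_`) is nonproductive; when the input carried an explicit
#' `productive` column (AIRR dialect) that call takes precedence. Surviving
#' clone frequencies are renormalized over the productive reads by default.
#'
#' @param rep A `tcr_repertoire`.
#' @param renormalize Recompute frequencies over the surviving reads
#'   (default `TRUE`). With `FALSE` the original fractions are kept.
#' @return The filtered `tcr_repertoire`.
#' @export
filter_productive <- function(rep, renormalize = TRUE) {
  keep <- rep$productive & !stringr::str_detect(rep$cdr3_aa, "[*_]")
  out <- rep[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    abort("all clonotypes are nonproductive; nothing to analyze",
          class = "tcrisk_empty_error")
  }
  if (renormalize) out$frequency <- out$count / sum(out$count)
  rebuild_repertoire(out, rep)
}

#' Downsample a repertoire to a fixed number of reads
#'
#' Draws `n` reads without replacement from the count-weighted read multiset
#' (a multivariate hypergeometric draw), recomputes counts and frequencies,
#' and drops clones that received zero reads. Sampling without replacement
#' models selecting reads from the finite sequenced pool and avoids inflating
#' clonality. If `n` is at least the repertoire's total reads the repertoire
#' is returned unchanged with a warning.
#'
#' @param rep A `tcr_repertoire`.
#' @param n Number of reads to keep (default 100,000, the standard depth used
#'   before diversity and risk-index analyses).
#' @param seed Optional integer seed; the draw is bit-identical across runs
#'   for a fixed seed and does not disturb the global RNG state.
#' @return The downsampled `tcr_repertoire`.
#' @export
downsample_reads <- function(rep, n = 1e5, seed = NULL) {
  stopifnot(n >= 1)
  total <- total_reads(rep)
  if (n >= total) {
    warn(sprintf("requested %s reads but repertoire '%s' has only %s; returned unchanged",
                 format(n, big.mark = ","), sample_id(rep),
                 format(total, big.mark = ",")))
    return(rep)
  }
  draw <- function() {
    counts <- rep$count
    sampled <- integer(length(counts))
    remaining_pool <- total
    remaining_draw <- as.integer(n)
    for (i in seq_along(counts)) {
      if (remaining_draw == 0L) break
      # reads of clone i are "white balls" among the remaining pool
      x <- rhyper(1L, counts[i], remaining_pool - counts[i], remaining_draw)
      sampled[i] <- x
      remaining_draw <- remaining_draw - x
      remaining_pool <- remaining_pool - counts[i]
    }
    sampled
  }
  sampled <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- rep
  out$count <- sampled
  out <- out[out$count > 0L, , drop = FALSE]
  out$frequency <- out$count / sum(out$count)
  out <- arrange(out, desc(.data$count), .data$cdr3_aa)
  rebuild_repertoire(out, rep)
}

#' Standard preprocessing chain
#'
#' Applies the default per-sample preparation used before diversity profiling
#' and LCRI scoring: nonproductive-clone removal, then downsampling to a
#' fixed read depth.
#'
#' @param rep A `tcr_repertoire`.
#' @param depth Target read depth; `NULL` skips downsampling.
#' @param seed Optional seed forwarded to [downsample_reads()].
#' @inheritParams filter_productive
#' @return The preprocessed `tcr_repertoire`.
#' @export
preprocess_repertoire <- function(rep, depth = 1e5, seed = NULL,
                                  renormalize = TRUE) {
  out <- filter_productive(rep, renormalize = renormalize)
  if (!is.null(depth) && total_reads(out) > depth) {
    out <- downsample_reads(out, n = depth, seed = seed)
  }
  out
}
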