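#' Clone-frequency diversity indices
#'
#' Shannon index: \eqn{-\sum_i f_i \ln f_i} (natural log, nats).
#' Simpson index: \eqn{1 - \sum_i f_i^2}.
#' D50: the minimal proportion of unique clones whose cumulative frequency,
#' taken in decreasing order, reaches 50% of total read abundance; lower D50
#' means a more clonal repertoire.
#'
#' @param freqs Numeric vector of clone frequencies; all strictly positive and
#'   summing to 1 (a deviation beyond `1e-6` raises a warning).
#' @return A single numeric value.
#' @examples
#' shannon_index(rep(0.25, 4)) # ln 4
#' simpson_index(rep(0.25, 4)) # 1 - 1/4
#' d50(c(0.4, 0.3, 0.2, 0.1)) # 2 clones of 4 reach 50%
#' @export
shannon_index <- function(freqs) {
  check_freqs(freqs)
  -sum(freqs * log(freqs))
}

#' @rdname shannon_index
#' @export
simpson_index <- function(freqs) {
  check_freqs(freqs)
  1 - sum(freqs^2)
}

#' @rdname shannon_index
#' @export
d50 <- function(freqs) {
  check_freqs(freqs)
  sorted <- sort(freqs, decreasing = TRUE)
  k <- which(cumsum(sorted) >= 0.5)[1L]
  k / length(freqs)
}

check_freqs <- function(freqs) {
  if (length(freqs) == 0L) abort("empty frequency vector", class = "tcrisk_empty_error")
  if (any(freqs <= 0)) {
    abort("clone frequencies must be strictly positive", class = "tcrisk_domain_error")
  }
  if (abs(sum(freqs) - 1) > 1e-6) {
    warn(sprintf("clone frequencies sum to %.8f, not 1; indices assume a normalized repertoire",
                 sum(freqs)))
  }
  invisible(freqs)
}

#' Per-sample diversity profile
#'
#' Computes the six repertoire summary statistics on a productive, normalized
#' repertoire: D50, Shannon index, Simpson index, total clone types, the
#' frequency of the largest clone, and the number of high-expansion clones
#' (HECs). A HEC is a clone whose frequency strictly exceeds
#' `hec_threshold` (default 0.5% of the repertoire); a clone sitting exactly
#' on the threshold is not counted.
#'
#' @param rep A `tcr_repertoire` (productive, frequencies summing to 1).
#' @param hec_threshold High-expansion clone frequency threshold
#'   (default `0.005`); comparison is strict (`>`).
#' @return One-row tibble: `sample_id`, `d50`, `shannon`, `simpson`,
#'   `total_clone_types`, `largest_clone_freq`, `hec_count`.
#' @export
diversity_profile <- function(rep, hec_threshold = 0.005) {
  check_normalized(rep, tol = 1e-6)
  f <- rep$frequency
  tibble(
    sample_id = sample_id(rep),
    d50 = d50(f),
    shannon = shannon_index(f),
    simpson = simpson_index(f),
    total_clone_types = length(f),
    largest_clone_freq = max(f),
    hec_count = sum(f > hec_threshold)
  )
}

#' Diversity profiles for a collection of repertoires
#'
#' @param reps List of `tcr_repertoire` objects.
#' @inheritParams diversity_profile
#' @return Tibble with one row per sample.
#' @export
diversity_table <- function(reps, hec_threshold = 0.005) {
  map(reps, diversity_profile, hec_threshold = hec_threshold) %>% list_rbind()
}

#' V/J gene-segment usage profile
#'
#' Tallies the frequency mass carried by each V gene, each J gene, and each
#' V-J pair. The default weighting is by reads (sequence abundance); the
#' clone weighting counts each unique clonotype once and is offered for
#' sensitivity analysis. Rows with a missing gene call are excluded from the
#' corresponding tally with a warning.
#'
#' @param rep A `tcr_repertoire` with V/J calls.
#' @param weight `"reads"` (default) or `"clones"`.
#' @return Tibble with columns `sample_id`, `feature` (`"v"`, `"j"`, `"vj"`),
#'   `v_gene`, `j_gene`, `frequency`; frequencies sum to 1 within each
#'   feature over the observed genes.
#' @export
gene_usage <- function(rep, weight = c("reads", "clones")) {
  weight <- arg_match(weight)
  w <- if (weight == "reads") rep$count else rep(1, nrow(rep))
  tally <- function(keys) {
    ok <- !is.na(keys) & keys != "" & keys != "."
    if (any(!ok)) {
      warn(sprintf("%d clonotype(s) without a gene call excluded from usage tally",
                   sum(!ok)))
    }
    mass <- tapply(w[ok], keys[ok], sum)
    tibble(key = names(mass), frequency = as.numeric(mass) / sum(mass))
  }
  v_tab <- tally(rep$v_gene) %>%
    mutate(feature = "v", v_gene = .data$key, j_gene = NA_character_)
  j_tab <- tally(rep$j_gene) %>%
    mutate(feature = "j", v_gene = NA_character_, j_gene = .data$key)
  vj_key <- ifelse(is.na(rep$v_gene) | is.na(rep$j_gene), NA_character_,
                   paste(rep$v_gene, rep$j_gene, sep = "|"))
  vj_tab <- tally(vj_key) %>%
    mutate(feature = "vj",
           v_gene = sub("\\|.*$", "", .data$key),
           j_gene = sub("^.*\\|", "", .data$key))
  bind_rows(v_tab, j_tab, vj_tab) %>%
    mutate(sample_id = sample_id(rep)) %>%
    select("sample_id", "feature", "v_gene", "j_gene", "frequency")
}

#' Compare a per-sample statistic between two cohort groups
#'
#' Two-sided Mann-Whitney U test (tie-corrected) of a per-sample quantity —
#' a diversity index or a gene's usage frequency — between two groups, the
#' standard group comparison for repertoire summary statistics.
#'
#' @param data Data frame with one row per sample.
#' @param value Column name (string) of the statistic to compare.
#' @param group Column name (string) of the group label.
#' @param groups Length-2 character vector naming the two groups to compare;
#'   defaults to the first two observed labels.
#' @return One-row tibble from [compare_groups()].
#' @export
compare_samples <- function(data, value, group = "group", groups = NULL) {
  stopifnot(value %in% names(data), group %in% names(data))
  labs <- groups %||% head(unique(data[[group]]), 2L)
  a <- data[[value]][data[[group]] == labs[1L]]
  b <- data[[value]][data[[group]] == labs[2L]]
  compare_groups(a, b, labels = labs)
}
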