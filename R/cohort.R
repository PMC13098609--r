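#' Compare LCRI (or any per-sample statistic) between two groups
#'
#' Two-sided Mann-Whitney U test plus the AUC as a discriminative summary,
#' and optionally a Youden-optimal group cutoff. For groups of at most
#' `exact_max` samples each the p-value comes from exact enumeration of all
#' group assignments of the U statistic (valid under ties); larger groups
#' use the normal approximation with continuity and tie correction.
#'
#' @param a,b Numeric vectors of per-sample values (e.g. LCRI), group A
#'   taken as the positive class for the AUC.
#' @param labels Optional length-2 character vector of group names.
#' @param cutoff Also derive the Youden-optimal cutoff separating the
#'   groups, with its sensitivity and specificity (default `FALSE`).
#' @param exact_max Largest per-group size for exact enumeration
#'   (default 8).
#' @return A `cohort_comparison`: one-row tibble with `group_a`, `group_b`,
#'   `n_a`, `n_b`, `mean_a`, `sd_a`, `mean_b`, `sd_b`, `statistic` (U of
#'   group A), `p_value`, `auc`, `method`, and when `cutoff = TRUE` also
#'   `threshold`, `sensitivity`, `specificity`.
#' @export
compare_groups <- function(a, b, labels = c("A", "B"), cutoff = FALSE,
                           exact_max = 8L) {
  if (length(a) == 0L || length(b) == 0L) {
    abort("both groups must be non-empty", class = "tcrisk_empty_error")
  }
  n_a <- length(a)
  n_b <- length(b)
  u_stat <- function(values, is_a) {
    r <- rank(values)
    sum(r[is_a]) - sum(is_a) * (sum(is_a) + 1) / 2
  }
  values <- c(a, b)
  is_a <- c(rep(TRUE, n_a), rep(FALSE, n_b))
  u <- u_stat(values, is_a)

  if (n_a <= exact_max && n_b <= exact_max) {
    method <- "exact permutation"
    combos <- utils::combn(n_a + n_b, n_a)
    center <- n_a * n_b / 2
    u_all <- apply(combos, 2L, function(idx) {
      m <- logical(n_a + n_b)
      m[idx] <- TRUE
      u_stat(values, m)
    })
    p <- mean(abs(u_all - center) >= abs(u - center) - 1e-12)
  } else {
    method <- "normal approximation"
    wt <- suppressWarnings(
      wilcox.test(a, b, alternative = "two.sided", exact = FALSE,
                  correct = TRUE)
    )
    p <- wt$p.value
  }

  scores <- values
  labs <- as.integer(is_a)
  out <- tibble(
    group_a = labels[1L], group_b = labels[2L],
    n_a = n_a, n_b = n_b,
    mean_a = mean(a), sd_a = sd(a),
    mean_b = mean(b), sd_b = sd(b),
    statistic = u, p_value = p,
    auc = auc(scores, labs),
    method = method
  )
  if (cutoff) {
    opt <- optimal_threshold(scores, labs)
    out$threshold <- opt$threshold
    out$sensitivity <- opt$sensitivity
    out$specificity <- opt$specificity
  }
  structure(out, class = c("cohort_comparison", class(out)))
}

#' @export
tidy.cohort_comparison <- function(x, ...) as_tibble(x)

#' @export
glance.cohort_comparison <- function(x, ...) {
  as_tibble(x)[c("statistic", "p_value", "auc", "method")]
}

#' Classify a longitudinal LCRI trajectory
#'
#' Labels paired pre/post LCRI measurements by the change
#' `delta = post - pre` against the predefined meaningful-change boundary of
#' 0.01: `positive_induction` when delta > 0.01, `temporal_stability` when
#' |delta| <= 0.01 (boundary inclusive), `reduction` when delta < -0.01.
#' Two risk flags are set with strict comparisons: `strong_elevation` when
#' delta > 0.15 and `high_post` when the post value > 0.30, the pattern
#' associated with distant metastasis after radiotherapy. Deltas are
#' compared at full precision; no rounding is applied before the boundary
#' checks.
#'
#' @param pre,post Numeric vectors of LCRI values in `[0, 1]` (recycled
#'   pairwise).
#' @param patient_id Optional identifier vector.
#' @param stability_margin Meaningful-change boundary (default 0.01).
#' @param elevation_threshold Strong-elevation flag boundary (default 0.15).
#' @param high_post_threshold High post-treatment flag boundary
#'   (default 0.30).
#' @return Tibble with `patient_id`, `pre`, `post`, `delta`, `subtype`,
#'   `strong_elevation`, `high_post`.
#' @examples
#' classify_trajectory(c(0.15, 0.08, 0.33), c(0.23, 0.07, 0.23))
#' @export
classify_trajectory <- function(pre, post, patient_id = NULL,
                                stability_margin = 0.01,
                                elevation_threshold = 0.15,
                                high_post_threshold = 0.30) {
  if (any(pre < 0 | pre > 1 | post < 0 | post > 1)) {
    abort("LCRI values must lie in [0, 1]", class = "tcrisk_domain_error")
  }
  delta <- post - pre
  # guard band of 1e-9 so that boundary cases intended to be exact (e.g.
  # 0.08 -> 0.07) are not misclassified by binary floating-point residue
  eps <- 1e-9
  subtype <- case_when(
    delta > stability_margin + eps ~ "positive_induction",
    delta < -(stability_margin + eps) ~ "reduction",
    .default = "temporal_stability"
  )
  tibble(
    patient_id = patient_id %||% sprintf("P%02d", seq_along(delta)),
    pre = pre, post = post, delta = delta,
    subtype = factor(subtype, levels = c("positive_induction",
                                         "temporal_stability", "reduction")),
    strong_elevation = delta > elevation_threshold + eps,
    high_post = post > high_post_threshold + eps
  )
}

#' Age-stratified discriminative performance
#'
#' Splits samples into age bins and computes, per bin, the case/control AUC
#' and Mann-Whitney comparison of the LCRI. Bins containing a single class
#' are reported as not evaluable instead of failing. With a single bin
#' covering all ages this reduces to [compare_groups()] on the whole
#' cohort.
#'
#' @param lcris Numeric LCRI values.
#' @param labels 0/1 case labels (1 = cancer).
#' @param ages Numeric ages.
#' @param breaks Cut points defining the bins; the defaults give the four
#'   groups <41, 41-50, 51-60, >60 years.
#' @param bin_labels Optional bin names.
#' @return Tibble with one row per bin: `age_group`, `n_case`, `n_control`,
#'   `auc`, `p_value`, `evaluable`.
#' @export
age_stratified_auc <- function(lcris, labels, ages,
                               breaks = c(-Inf, 40, 50, 60, Inf),
                               bin_labels = NULL) {
  if (length(breaks) < 2L) {
    abort("need at least one age bin", class = "tcrisk_domain_error")
  }
  labels <- as.integer(labels)
  bin_labels <- bin_labels %||% default_bin_labels(breaks)
  bins <- cut(ages, breaks = breaks, labels = bin_labels,
              include.lowest = TRUE)
  map(levels(bins), function(bl) {
    sel <- which(bins == bl)
    n_case <- sum(labels[sel] == 1L)
    n_control <- sum(labels[sel] == 0L)
    if (n_case == 0L || n_control == 0L) {
      return(tibble(age_group = bl, n_case = n_case, n_control = n_control,
                    auc = NA_real_, p_value = NA_real_, evaluable = FALSE))
    }
    cmp <- compare_groups(lcris[sel][labels[sel] == 1L],
                          lcris[sel][labels[sel] == 0L])
    tibble(age_group = bl, n_case = n_case, n_control = n_control,
           auc = cmp$auc, p_value = cmp$p_value, evaluable = TRUE)
  }) %>% list_rbind()
}

default_bin_labels <- function(breaks) {
  n <- length(breaks) - 1L
  vapply(seq_len(n), function(i) {
    lo <- breaks[i]
    hi <- breaks[i + 1L]
    if (is.infinite(lo)) {
      sprintf("<%g", hi + 1)
    } else if (is.infinite(hi)) {
      sprintf(">%g", lo)
    } else {
      sprintf("%g-%g", lo + 1, hi)
    }
  }, character(1L))
}

#' Correlate age with a repertoire statistic
#'
#' Pearson correlation by default (Spearman available) between age and a
#' per-sample quantity such as D50 or LCRI.
#'
#' @param data Data frame of per-sample rows.
#' @param value,age Column names (strings).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return One-row tibble: `r`, `p_value`, `n`, `method`.
#' @export
age_correlation <- function(data, value, age = "age",
                            method = c("pearson", "spearman")) {
  method <- arg_match(method)
  ok <- stats::complete.cases(data[[value]], data[[age]])
  ct <- stats::cor.test(data[[value]][ok], data[[age]][ok], method = method,
                        exact = FALSE)
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok),
         method = method)
}
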