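#' Area under the ROC curve (Mann-Whitney pair statistic)
#'
#' AUC computed as the probability that a random positive scores above a
#' random negative, with ties counted half:
#' (concordant pairs + 0.5 * tied pairs) / (n1 * n0). Equivalent to the
#' midrank formulation, which is how it is evaluated here.
#'
#' @param scores Numeric scores.
#' @param labels Vector of 0/1 class labels (1 = positive).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    abort("AUC needs both classes present", class = "tcrisk_domain_error")
  }
  r <- rank(scores) # midranks handle ties
  u <- sum(r[labels == 1L]) - n1 * (n1 + 1) / 2
  u / (n1 * n0)
}

#' Optimal probability threshold by Youden's J
#'
#' Scans the observed score values as candidate cutoffs under the prediction
#' rule "positive iff score > threshold" and returns the cutoff maximizing
#' Youden's J = sensitivity + specificity - 1; ties in J are broken toward
#' the smallest threshold. Alternative criteria are available since the
#' notion of an "optimal cutoff" is not unique: `"closest_topleft"`
#' minimizes the Euclidean distance to the (0, 1) ROC corner, and
#' `"fixed_specificity"` maximizes sensitivity subject to specificity at
#' least `min_specificity`.
#'
#' @inheritParams auc
#' @param criterion Cutoff-optimality criterion (default `"youden"`).
#' @param min_specificity Floor used by `"fixed_specificity"`.
#' @return One-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `youden_j`.
#' @export
optimal_threshold <- function(scores, labels,
                              criterion = c("youden", "closest_topleft",
                                            "fixed_specificity"),
                              min_specificity = 0.9) {
  criterion <- arg_match(criterion)
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  if (length(pos) == 0L || length(neg) == 0L) {
    abort("threshold search needs both classes present",
          class = "tcrisk_domain_error")
  }
  cand <- sort(unique(scores))
  sens <- vapply(cand, function(t) mean(pos > t), numeric(1L))
  spec <- vapply(cand, function(t) mean(neg <= t), numeric(1L))
  obj <- switch(criterion,
    youden = sens + spec - 1,
    closest_topleft = -sqrt((1 - sens)^2 + (1 - spec)^2),
    fixed_specificity = ifelse(spec >= min_specificity, sens, -Inf)
  )
  best <- which.max(obj) # candidates ascend, so first max = smallest threshold
  tibble(threshold = cand[best], sensitivity = sens[best],
         specificity = spec[best], youden_j = sens[best] + spec[best] - 1)
}

#' ROC curve points
#'
#' @inheritParams auc
#' @return Tibble of `threshold`, `fpr`, `tpr` over the observed score
#'   values (rule: positive iff score > threshold), plus the trivial
#'   (1, 1) corner.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  cand <- c(-Inf, sort(unique(scores)))
  tibble(
    threshold = cand,
    fpr = vapply(cand, function(t) mean(neg > t), numeric(1L)),
    tpr = vapply(cand, function(t) mean(pos > t), numeric(1L))
  ) %>% arrange(.data$fpr, .data$tpr)
}

#' Calibrate per-length probability thresholds on the validation set
#'
#' Scores every validation stratum with its length-specific model and
#' derives the per-length optimal cutoff, sensitivity, specificity and AUC,
#' plus the pooled AUC over all lengths. These cutoffs are the ones used by
#' [flag_cancer_clones()] at deployment, so calibration and deployment share
#' the same strict `>` rule.
#'
#' @param models A `scorer_set` (one model per length).
#' @param split A `dataset_split` with non-empty validation strata.
#' @param lengths Lengths to calibrate; defaults to the model set's lengths.
#' @inheritParams optimal_threshold
#' @return A `threshold_table`: tibble with one row per length — `length`,
#'   `threshold`, `sensitivity`, `specificity`, `auc`, `n_val` — carrying
#'   the pooled AUC as attribute `pooled_auc`.
#' @export
calibrate_all_lengths <- function(models, split, lengths = NULL,
                                  criterion = c("youden", "closest_topleft",
                                                "fixed_specificity"),
                                  min_specificity = 0.9) {
  criterion <- arg_match(criterion)
  lengths <- lengths %||% as.integer(names(models))
  val <- as_tibble(split) %>% filter(.data$partition == "val")
  pooled_scores <- list()
  pooled_labels <- list()
  rows <- map(lengths, function(len) {
    model <- models[[as.character(len)]]
    if (is.null(model)) {
      abort(sprintf("no model for length %d", len), class = "tcrisk_domain_error")
    }
    stratum <- val %>% filter(.data$length == len)
    if (nrow(stratum) == 0L) {
      abort(sprintf("empty validation stratum for length %d", len),
            class = "tcrisk_empty_error")
    }
    s <- predict_proba(model, stratum$cdr3_aa)
    pooled_scores[[as.character(len)]] <<- s
    pooled_labels[[as.character(len)]] <<- stratum$label
    opt <- optimal_threshold(s, stratum$label, criterion = criterion,
                             min_specificity = min_specificity)
    tibble(length = len, threshold = opt$threshold,
           sensitivity = opt$sensitivity, specificity = opt$specificity,
           auc = auc(s, stratum$label), n_val = nrow(stratum))
  })
  out <- list_rbind(rows)
  pooled <- auc(unlist(pooled_scores), unlist(pooled_labels))
  structure(out, pooled_auc = pooled, criterion = criterion,
            class = c("threshold_table", class(out)))
}

#' @export
print.threshold_table <- function(x, ...) {
  cat(sprintf("# per-length threshold table (%s criterion), pooled AUC %.3f\n",
              attr(x, "criterion") %||% "youden",
              attr(x, "pooled_auc") %||% NA_real_))
  NextMethod()
}

#' Example per-length threshold table
#'
#' A fixture of per-length probability cutoffs of realistic magnitude for
#' demonstrations and interface tests. These are illustrative values only —
#' calibrated cutoffs depend on the trained models and validation data and
#' must come from [calibrate_all_lengths()].
#'
#' @return A `threshold_table` with lengths 11-20 and `NA` performance
#'   columns.
#' @export
example_threshold_table <- function() {
  out <- tibble(
    length = 11:20,
    threshold = c(0.455, 0.209, 0.151, 0.392, 0.402,
                  0.449, 0.579, 0.537, 0.603, 0.632),
    sensitivity = NA_real_, specificity = NA_real_,
    auc = NA_real_, n_val = NA_integer_
  )
  structure(out, pooled_auc = NA_real_, criterion = "youden",
            class = c("threshold_table", class(out)))
}

#' Export ROC points or a threshold table
#'
#' @param x A `threshold_table` or the output of [roc_points()].
#' @param path CSV (threshold table) or JSON destination.
#' @return `path` invisibly.
#' @export
write_threshold_table <- function(x, path) {
  jsonlite::write_json(
    list(criterion = attr(x, "criterion"),
         pooled_auc = attr(x, "pooled_auc"),
         thresholds = as_tibble(x)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
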