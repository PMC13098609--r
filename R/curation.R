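#' Build a labeled CDR3 sequence pool from a cohort of repertoires
#'
#' First curation step: from every sample, keep CDR3 amino-acid sequences
#' whose within-sample frequency strictly exceeds `min_freq` and whose length
#' lies in `length_range`, then pool across samples with duplicate removal.
#' The per-class defaults used for corpus construction are `3e-4` (>0.03%)
#' for the non-cancer class and `4e-4` (>0.04%) for the cancer class.
#'
#' @param reps List of productive, normalized `tcr_repertoire` objects.
#' @param min_freq Strict per-sample frequency threshold.
#' @param length_range Two-element inclusive CDR3 length range (default
#'   `c(11, 20)`).
#' @param label Pool label, `"cancer"` or `"non_cancer"`.
#' @return A `cdr3_pool`: tibble with columns `cdr3_aa`, `length`,
#'   `n_samples` (number of donor samples containing the sequence), carrying
#'   the label as an attribute.
#' @export
build_class_pool <- function(reps, min_freq, length_range = c(11, 20),
                             label = c("cancer", "non_cancer")) {
  label <- arg_match(label)
  per_sample <- map(reps, function(rep) {
    len <- nchar(rep$cdr3_aa)
    keep <- rep$frequency > min_freq & len >= length_range[1L] & len <= length_range[2L]
    unique(rep$cdr3_aa[keep])
  })
  all_seqs <- unlist(per_sample, use.names = FALSE)
  if (length(all_seqs) == 0L) {
    abort(sprintf(
      "empty %s pool: no sequence passed frequency > %g with length in [%d, %d] in any of %d samples",
      label, min_freq, length_range[1L], length_range[2L], length(reps)),
      class = "tcrisk_empty_error")
  }
  tab <- table(all_seqs)
  pool <- tibble(
    cdr3_aa = names(tab),
    length = nchar(names(tab)),
    n_samples = as.integer(tab)
  ) %>% arrange(desc(.data$n_samples), .data$cdr3_aa)
  new_pool(pool, label = label)
}

new_pool <- function(tbl, label) {
  structure(as_tibble(tbl), label = label,
            class = c("cdr3_pool", class(as_tibble(tbl))))
}

#' @export
print.cdr3_pool <- function(x, ...) {
  cat(sprintf("# CDR3 pool (%s): %d unique sequences\n",
              attr(x, "label") %||% "unlabeled", nrow(x)))
  NextMethod()
}

#' Exclude sequences shared with a reference pool
#'
#' Removes from the cancer pool every sequence also present in the healthy
#' pool, ensuring tumor specificity of the positive training class. The
#' result is guaranteed disjoint from `healthy`.
#'
#' @param cancer,healthy `cdr3_pool` objects (or data frames with a
#'   `cdr3_aa` column).
#' @return The filtered `cdr3_pool`.
#' @export
exclude_shared <- function(cancer, healthy) {
  out <- anti_join(as_tibble(cancer), as_tibble(healthy)["cdr3_aa"], by = "cdr3_aa")
  new_pool(out, label = attr(cancer, "label") %||% "cancer")
}

#' CD-HIT-style greedy incremental sequence clustering
#'
#' Re-implements greedy incremental clustering at desk scale (the workflow's
#' `-c 0.4 -n 2` step). Sequences are ordered by decreasing length, ties
#' broken lexicographically; the first unassigned sequence founds a cluster
#' and becomes its representative; every subsequent sequence joins the first
#' (earliest-founded) representative whose identity to it reaches
#' `identity`, otherwise it founds a new cluster.
#'
#' Identity between two sequences is the number of matched residues in an
#' optimal global alignment with free gaps (match 1, mismatch 0, gap 0 — the
#' maximal match count, equal to the longest common subsequence), divided by
#' the length of the shorter sequence, following the CD-HIT convention.
#'
#' A candidate-pruning filter (a residue-multiset upper bound on the match
#' count, in the spirit of CD-HIT's short-word filter) skips alignments that
#' cannot reach the threshold; it is an optimization only and never changes
#' assignments.
#'
#' @param pool A `cdr3_pool`, data frame with a `cdr3_aa` column, or
#'   character vector of unique sequences.
#' @param identity Identity threshold in (0, 1]; default `0.4`.
#' @param word_size Word length accepted for CD-HIT parameter parity
#'   (default 2); the pruning filter used here is exact, so the value does
#'   not affect results.
#' @param word_filter Disable with `FALSE` to force a full alignment for
#'   every candidate pair (used to verify assignment-neutrality).
#' @return A `cdr3_clustering`: tibble with columns `cdr3_aa`, `length`,
#'   `cluster` (integer id in founding order), `representative`, and
#'   `identity` (identity of the member to its representative; 1 for the
#'   representative itself).
#' @export
greedy_cluster <- function(pool, identity = 0.4, word_size = 2,
                           word_filter = TRUE) {
  seqs <- if (is.character(pool)) unique(pool) else unique(as_tibble(pool)$cdr3_aa)
  if (length(seqs) == 0L) abort("empty pool", class = "tcrisk_empty_error")
  stopifnot(identity > 0, identity <= 1)
  # deterministic CD-HIT-like processing order
  seqs <- seqs[order(-nchar(seqs), seqs, method = "radix")]
  lens <- nchar(seqs)
  n <- length(seqs)

  # residue-count matrix for the exact match-count upper bound
  comp <- letter_counts(seqs)

  cluster <- integer(n)
  rep_of <- character(n)
  ident_of <- numeric(n)
  unassigned <- seq_len(n)
  k <- 0L
  while (length(unassigned) > 0L) {
    k <- k + 1L
    ri <- unassigned[1L]
    cluster[ri] <- k
    rep_of[ri] <- seqs[ri]
    ident_of[ri] <- 1
    cand <- unassigned[-1L]
    if (length(cand) > 0L) {
      min_len <- pmin(lens[cand], lens[ri])
      todo <- cand
      if (word_filter) {
        ub <- rowSums(pmin(comp[cand, , drop = FALSE],
                           rep(comp[ri, ], each = length(cand))))
        todo <- cand[ub / min_len >= identity]
      }
      if (length(todo) > 0L) {
        matches <- alignment_matches(seqs[todo], seqs[ri])
        idv <- matches / pmin(lens[todo], lens[ri])
        hit <- todo[idv >= identity]
        if (length(hit) > 0L) {
          cluster[hit] <- k
          rep_of[hit] <- seqs[ri]
          ident_of[hit] <- idv[idv >= identity]
        }
      }
    }
    unassigned <- which(cluster == 0L)
  }

  out <- tibble(cdr3_aa = seqs, length = lens, cluster = cluster,
                representative = rep_of, identity = ident_of)
  structure(out, params = list(identity = identity, word_size = word_size),
            class = c("cdr3_clustering", class(out)))
}

# per-sequence residue counts over the 20-letter alphabet
letter_counts <- function(seqs) {
  m <- Biostrings::letterFrequency(Biostrings::AAStringSet(seqs), AA_ALPHABET)
  storage.mode(m) <- "integer"
  m
}

# maximal match count (free-gap global alignment == LCS length) of each
# sequence in `seqs` against the single sequence `ref`
alignment_matches <- function(seqs, ref) {
  aa <- AA_ALPHABET
  mat <- diag(1, length(aa))
  dimnames(mat) <- list(aa, aa)
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(seqs), Biostrings::AAString(ref),
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 0,
    type = "global", scoreOnly = TRUE))
}

#' Retain sequences from dominant clusters
#'
#' Keeps every member of each cluster whose size reaches at least
#' `fraction` of the clustered sequences (inclusive comparison, the
#' "at least 15% representation" rule). The denominator is the total number
#' of clustered sequences by default; `denominator = "largest"` uses the
#' largest cluster's size instead (an alternative reading of the rule,
#' exposed rather than silently chosen).
#'
#' @param clustering A `cdr3_clustering` from [greedy_cluster()].
#' @param fraction Retention fraction (default `0.15`).
#' @param denominator `"total"` (default) or `"largest"`.
#' @return A `cdr3_pool` of the retained sequences (`n_samples` not carried).
#' @export
retain_dominant_clusters <- function(clustering, fraction = 0.15,
                                     denominator = c("total", "largest")) {
  denominator <- arg_match(denominator)
  sizes <- table(clustering$cluster)
  denom <- switch(denominator, total = nrow(clustering), largest = max(sizes))
  keep_ids <- as.integer(names(sizes)[sizes >= fraction * denom])
  if (length(keep_ids) == 0L) {
    abort(sprintf(
      "no cluster reaches %.0f%% representation (largest: %.1f%%); lower `fraction`",
      100 * fraction, 100 * max(sizes) / denom),
      class = "tcrisk_empty_error")
  }
  out <- clustering %>%
    filter(.data$cluster %in% keep_ids) %>%
    mutate(n_samples = NA_integer_) %>%
    select("cdr3_aa", "length", "n_samples") %>%
    arrange(.data$cdr3_aa)
  new_pool(out, label = "retained")
}

#' Length-stratified test/train/validation split
#'
#' For every CDR3 length stratum and class label, samples `test_quota`
#' sequences uniformly without replacement into the test partition, then
#' splits the remainder into training and validation sets at
#' `train_frac : (1 - train_frac)` (default 4:1) by randomized allocation.
#' With ten lengths, two classes and the default quota of 500 the test set
#' holds exactly 10,000 sequences. If a stratum cannot fund the quota while
#' leaving a remainder, its quota is reduced to half the stratum size with a
#' warning; an empty stratum is an error naming the length and label.
#'
#' @param positive,negative `cdr3_pool` objects (or data frames with
#'   `cdr3_aa`); `positive` is the cancer-associated class, coded `label = 1`.
#' @param lengths Integer vector of CDR3 lengths to stratify over
#'   (default `11:20`).
#' @param test_quota Test sequences per length per label (default 500).
#' @param train_frac Training fraction of the remainder (default 0.8).
#' @param seed Integer seed; the partition is deterministic for a fixed seed.
#' @return A `dataset_split`: tibble with columns `cdr3_aa`, `label`
#'   (1 cancer / 0 non-cancer), `length`, `partition`
#'   (`"train"`, `"val"`, `"test"`).
#' @export
stratify_and_split <- function(positive, negative, lengths = 11:20,
                               test_quota = 500, train_frac = 0.8,
                               seed = 1L) {
  pools <- list(
    `1` = unique(as_tibble(positive)$cdr3_aa),
    `0` = unique(as_tibble(negative)$cdr3_aa)
  )
  split_one <- function(label, len) {
    seqs <- pools[[label]][nchar(pools[[label]]) == len]
    if (length(seqs) == 0L) {
      abort(sprintf("empty stratum: length %d, label %s", len, label),
            class = "tcrisk_empty_error")
    }
    seqs <- sort(seqs) # deterministic base order before seeded sampling
    quota <- test_quota
    if (length(seqs) <= quota) {
      quota <- floor(length(seqs) / 2)
      warn(sprintf(
        "stratum length %d label %s has %d sequences; test quota reduced to %d",
        len, label, length(seqs), quota))
    }
    test_idx <- sample.int(length(seqs), quota)
    rest <- setdiff(seq_along(seqs), test_idx)
    n_train <- floor(length(rest) * train_frac)
    train_idx <- rest[sample.int(length(rest), n_train)]
    val_idx <- setdiff(rest, train_idx)
    part <- character(length(seqs))
    part[test_idx] <- "test"
    part[train_idx] <- "train"
    part[val_idx] <- "val"
    tibble(cdr3_aa = seqs, label = as.integer(label), length = len,
           partition = part)
  }
  out <- withr::with_seed(seed, {
    pmap(expand.grid(label = c("1", "0"), len = lengths,
                     stringsAsFactors = FALSE),
         function(label, len) split_one(label, len)) %>% list_rbind()
  })
  structure(out,
            params = list(lengths = lengths, test_quota = test_quota,
                          train_frac = train_frac, seed = seed),
            class = c("dataset_split", class(out)))
}

#' Read/write sequence pools as plain text or FASTA
#'
#' `write_pool()` writes one sequence per line (default) or FASTA with
#' stable `seq<i>` identifiers; `read_pool()` is its inverse.
#'
#' @param pool A `cdr3_pool` or character vector.
#' @param path File path.
#' @param format `"text"` or `"fasta"`.
#' @param label Label attached to the pool on read.
#' @return `write_pool()` returns `path` invisibly; `read_pool()` a
#'   `cdr3_pool`.
#' @export
write_pool <- function(pool, path, format = c("text", "fasta")) {
  format <- arg_match(format)
  seqs <- if (is.character(pool)) pool else as_tibble(pool)$cdr3_aa
  if (format == "text") {
    writeLines(seqs, path)
  } else {
    set <- Biostrings::AAStringSet(seqs)
    names(set) <- sprintf("seq%d", seq_along(seqs))
    Biostrings::writeXStringSet(set, path)
  }
  invisible(path)
}

#' @rdname write_pool
#' @export
read_pool <- function(path, format = c("text", "fasta"),
                      label = c("cancer", "non_cancer")) {
  format <- arg_match(format)
  label <- arg_match(label)
  seqs <- if (format == "text") {
    readLines(path)
  } else {
    as.character(Biostrings::readAAStringSet(path))
  }
  seqs <- unique(seqs[nzchar(seqs)])
  new_pool(tibble(cdr3_aa = seqs, length = nchar(seqs),
                  n_samples = NA_integer_),
           label = label)
}
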