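# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately share no code with the package.

# longest common subsequence length by dynamic programming: the maximal
# number of matched residues in a free-gap global alignment
oracle_lcs <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1L]]
  y <- strsplit(b, "", fixed = TRUE)[[1L]]
  d <- matrix(0L, length(x) + 1L, length(y) + 1L)
  for (i in seq_along(x)) {
    for (j in seq_along(y)) {
      d[i + 1L, j + 1L] <- if (x[i] == y[j]) {
        d[i, j] + 1L
      } else {
        max(d[i, j + 1L], d[i + 1L, j])
      }
    }
  }
  d[length(x) + 1L, length(y) + 1L]
}

oracle_identity <- function(a, b) {
  oracle_lcs(a, b) / min(nchar(a), nchar(b))
}

# greedy reference clustering: scan representatives in founding order,
# full alignment identity for every candidate, no word filter
oracle_greedy_cluster <- function(seqs, identity = 0.4) {
  seqs <- seqs[order(-nchar(seqs), seqs, method = "radix")]
  cluster <- integer(length(seqs))
  reps <- integer(0)
  for (i in seq_along(seqs)) {
    assigned <- FALSE
    for (r in reps) {
      if (oracle_identity(seqs[i], seqs[r]) >= identity) {
        cluster[i] <- cluster[r]
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      cluster[i] <- length(reps)
    }
  }
  tibble::tibble(cdr3_aa = seqs, cluster = cluster)
}

# AUC by explicit enumeration of all positive-negative pairs
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# exhaustive Youden search over observed score values, rule: positive
# iff score > threshold, smallest threshold on ties
oracle_youden <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cand <- sort(unique(scores))
  best <- NULL
  for (t in cand) {
    sens <- mean(pos > t)
    spec <- mean(neg <= t)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12) {
      best <- list(threshold = t, sens = sens, spec = spec, j = j)
    }
  }
  best
}

# exact two-sided permutation p-value of the Mann-Whitney U statistic
oracle_mw_exact_p <- function(a, b) {
  values <- c(a, b)
  n_a <- length(a)
  n <- length(values)
  u_of <- function(idx) {
    r <- rank(values)
    sum(r[idx]) - n_a * (n_a + 1) / 2
  }
  obs <- u_of(seq_len(n_a))
  center <- n_a * length(b) / 2
  combos <- combn(n, n_a)
  u_all <- apply(combos, 2, u_of)
  mean(abs(u_all - center) >= abs(obs - center) - 1e-12)
}

# small deterministic repertoire for unit tests
toy_repertoire <- function(counts = c(6, 3, 1),
                           cdr3 = c("CASSLGQGAYEQYF", "CASRDRDRGNTIYF",
                                    "CASSPGTSGSYEQF")[seq_along(counts)],
                           sample_id = "toy", group = NULL) {
  meta <- if (is.null(group)) list() else list(group = group)
  repertoire(
    data.frame(cdr3_aa = cdr3, count = counts,
               v_gene = "TRBV6-2", j_gene = "TRBJ2-7"),
    sample_id = sample_id, metadata = meta
  )
}

# random canonical CDR3 strings (test-local, independent of the simulator)
random_seqs <- function(n, len_range = c(11, 20)) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  lens <- seq(len_range[1], len_range[2])
  vapply(seq_len(n), function(i) {
    L <- if (length(lens) == 1L) lens else sample(lens, 1)
    paste0("C", paste(sample(aa, L - 2, replace = TRUE), collapse = ""), "F")
  }, character(1))
}

# best achievable AUC when the only signal is motif presence with
# within-class prevalences p1 (positives) and p0 (negatives): concordant
# pairs plus half the motif-status ties
optimal_motif_auc <- function(p1, p0) {
  p1 * (1 - p0) + 0.5 * (p1 * p0 + (1 - p1) * (1 - p0))
}

# pool constructor bypassing curation, for split/training tests
make_pool <- function(seqs, label = "cancer") {
  structure(
    tibble::tibble(cdr3_aa = unique(seqs), length = nchar(unique(seqs)),
                   n_samples = 1L),
    label = label,
    class = c("cdr3_pool", class(tibble::tibble()))
  )
}

# labeled per-length strata with a planted 3-mer motif; returns a
# dataset_split-shaped tibble
make_motif_split <- function(lengths = 11:12, n_per = 400, motif = "WDR",
                             prev_pos = 0.8, prev_neg = 0.05, seed = 1) {
  withr::with_seed(seed, {
    rows <- lapply(lengths, function(L) {
      seqs <- random_seqs(2 * n_per, c(L, L))
      lab <- rep(c(1L, 0L), each = n_per)
      hit <- runif(2 * n_per) < ifelse(lab == 1L, prev_pos, prev_neg)
      pos <- 2 + floor(runif(sum(hit)) * (L - nchar(motif)))
      s <- seqs[hit]
      substr(s, pos, pos + nchar(motif) - 1) <- motif
      seqs[hit] <- s
      part <- rep(c("train", "val"), length.out = 2 * n_per)
      tibble::tibble(cdr3_aa = seqs, label = lab, length = L,
                     partition = sample(part))
    })
    out <- dplyr::bind_rows(rows)
    structure(out, class = c("dataset_split", class(out)))
  })
}
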