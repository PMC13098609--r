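#' Tokenize a CDR3 amino-acid sequence
#'
#' Maps each residue of a CDR3 string over the canonical 20-letter amino-acid
#' alphabet to its integer index (A = 1 ... Y = 20). `detokenize()` inverts
#' the mapping, so `detokenize(tokenize(s)) == s`.
#'
#' @param cdr3_aa A single CDR3 string.
#' @return Integer vector with one index per residue.
#' @examples
#' tokenize("CASSF")
#' detokenize(tokenize("CASSF"))
#' @export
tokenize <- function(cdr3_aa) {
  stopifnot(is.character(cdr3_aa), length(cdr3_aa) == 1L)
  chars <- strsplit(cdr3_aa, "", fixed = TRUE)[[1L]]
  idx <- match(chars, AA_ALPHABET)
  if (anyNA(idx)) {
    pos <- which(is.na(idx))[1L]
    abort(sprintf("invalid residue '%s' at position %d of '%s'",
                  chars[pos], pos, cdr3_aa),
          class = "tcrisk_validation_error")
  }
  idx
}

#' @rdname tokenize
#' @param tokens Integer vector of residue indices in `1:20`.
#' @export
detokenize <- function(tokens) {
  stopifnot(all(tokens >= 1L), all(tokens <= 20L))
  paste(AA_ALPHABET[tokens], collapse = "")
}

#' Numerically stable softmax over a pair of logits
#'
#' Converts the two raw output scores (logits) of a binary classifier into
#' class probabilities summing to 1, subtracting the maximum before
#' exponentiating so that large magnitudes do not overflow.
#'
#' @param logits Numeric vector of length 2, both finite.
#' @return Numeric vector of two probabilities summing to 1.
#' @examples
#' softmax_probabilities(c(1, -1))
#' @export
softmax_probabilities <- function(logits) {
  stopifnot(is.numeric(logits), length(logits) == 2L)
  if (!all(is.finite(logits))) {
    abort("logits must be finite", class = "tcrisk_domain_error")
  }
  e <- exp(logits - max(logits))
  e / sum(e)
}

#' Training configuration for per-length CDR3 scorers
#'
#' Bundles the hyperparameters of the length-stratified training stage. The
#' per-length learning rates, warmup ratio, batch size, epoch count, weight
#' decay, seed and gradient-accumulation setting parameterize the
#' `plm_finetune` backend (fine-tuning of a pretrained protein language
#' model, exported as a job spec by [export_plm_job()]); the
#' `reference_scorer` backend — a lasso-regularized logistic regression on
#' k-mer count features, trained in seconds on one CPU — uses `kmer_sizes`,
#' `nlambda` and `alpha`, with the regularization path playing the role of
#' the training trajectory.
#'
#' @param learning_rates Named numeric vector, one positive rate per CDR3
#'   length in 11-20.
#' @param warmup_ratio,batch_size,epochs,weight_decay,seed,grad_accum
#'   Fine-tuning settings (defaults 0.1, 32, 5, 0.01, 42, 1).
#' @param backend `"reference_scorer"` (default) or `"plm_finetune"`.
#' @param kmer_sizes k-mer feature sizes for the reference backend.
#' @param nlambda,alpha glmnet path length and elastic-net mixing for the
#'   reference backend.
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rates = c(`11` = 3e-5, `12` = 3e-5,
                                               `13` = 5e-6, `14` = 5e-6,
                                               `15` = 3e-7, `16` = 5e-6,
                                               `17` = 5e-6, `18` = 1e-5,
                                               `19` = 1e-5, `20` = 1e-6),
                            warmup_ratio = 0.1, batch_size = 32, epochs = 5,
                            weight_decay = 0.01, seed = 42, grad_accum = 1,
                            backend = c("reference_scorer", "plm_finetune"),
                            kmer_sizes = 1:3, nlambda = 30, alpha = 0.9) {
  backend <- arg_match(backend)
  if (any(learning_rates <= 0)) {
    abort("all learning rates must be positive", class = "tcrisk_domain_error")
  }
  structure(list(learning_rates = learning_rates, warmup_ratio = warmup_ratio,
                 batch_size = batch_size, epochs = epochs,
                 weight_decay = weight_decay, seed = seed,
                 grad_accum = grad_accum, backend = backend,
                 kmer_sizes = kmer_sizes, nlambda = nlambda, alpha = alpha),
            class = "training_config")
}

# --- k-mer featurization ----------------------------------------------------

# long table of (sequence index, k-mer) occurrences
kmer_occurrences <- function(seqs, k) {
  lens <- nchar(seqs)
  idx <- list()
  kmer <- list()
  p <- 0L
  for (L in sort(unique(lens))) {
    if (L < k) next
    sel <- which(lens == L)
    for (i in seq_len(L - k + 1L)) {
      p <- p + 1L
      idx[[p]] <- sel
      kmer[[p]] <- substring(seqs[sel], i, i + k - 1L)
    }
  }
  list(idx = unlist(idx), kmer = unlist(kmer))
}

# sparse sequence-by-kmer count matrix; when `vocab` is supplied, unseen
# k-mers are dropped and column order is fixed (prediction path)
featurize_kmers <- function(seqs, kmer_sizes = 1:3, vocab = NULL) {
  occ <- map(kmer_sizes, function(k) kmer_occurrences(seqs, k))
  idx <- unlist(map(occ, "idx"))
  kmer <- unlist(map(occ, "kmer"))
  if (is.null(vocab)) vocab <- sort(unique(kmer))
  j <- match(kmer, vocab)
  keep <- !is.na(j)
  Matrix::sparseMatrix(i = idx[keep], j = j[keep], x = 1,
                       dims = c(length(seqs), length(vocab)),
                       dimnames = list(NULL, vocab))
}

# --- training ---------------------------------------------------------------

#' Train a scorer for one CDR3 length stratum
#'
#' Fits the binary cancer-associated-vs-not scorer for a single CDR3 length
#' on the training partition and selects the model state with the best
#' validation balanced accuracy (mean of sensitivity and specificity at the
#' 0.5 probability point), ties broken toward the earliest (most
#' regularized) state. Balanced accuracy is used because validation strata
#' at tail CDR3 lengths can be strongly class-imbalanced, where plain
#' accuracy would select a degenerate always-majority model. Class 1 is the
#' cancer-associated class throughout.
#'
#' The `reference_scorer` backend fits a lasso-penalized logistic regression
#' on k-mer count features along a regularization path; each path point is
#' the analogue of a training epoch, and the returned model carries the full
#' per-step history (penalty, training deviance explained, validation
#' accuracy). The fit is deterministic: no resampling is involved.
#'
#' @param split A `dataset_split` from [stratify_and_split()].
#' @param length CDR3 length of the stratum to train.
#' @param config A [training_config()].
#' @return A `cdr3_scorer` with fields `length`, `backend`, `fit`, `lambda`,
#'   `vocab`, `history` and `classes`.
#' @export
train_length_model <- function(split, length, config = training_config()) {
  len <- length
  data <- as_tibble(split) %>% filter(.data$length == len)
  train <- data %>% filter(.data$partition == "train")
  val <- data %>% filter(.data$partition == "val")
  if (nrow(train) == 0L || nrow(val) == 0L) {
    abort(sprintf("empty train or validation stratum for length %d", len),
          class = "tcrisk_empty_error")
  }
  if (dplyr::n_distinct(train$label) < 2L) {
    abort(sprintf("training stratum for length %d has a single class", len),
          class = "tcrisk_domain_error")
  }
  if (config$backend == "plm_finetune") {
    abort(paste("the plm_finetune backend needs externally downloaded",
                "pretrained weights and a GPU toolchain; use",
                "export_plm_job() to emit its job spec, or the",
                "reference_scorer backend"),
          class = "tcrisk_backend_error")
  }

  x_train <- featurize_kmers(train$cdr3_aa, config$kmer_sizes)
  # class-balanced weights plus a small ridge component keep the fit
  # well-posed on imbalanced, perfectly separable strata, where a pure
  # lasso path can diverge and truncate to the null model
  n1 <- sum(train$label == 1L)
  n0 <- nrow(train) - n1
  w <- ifelse(train$label == 1L, 0.5 / n1, 0.5 / n0) * nrow(train)
  fit <- suppressWarnings(glmnet::glmnet(
    x_train, train$label, family = "binomial", weights = w,
    alpha = config$alpha, nlambda = config$nlambda,
    lambda.min.ratio = 0.05, maxit = 1e6, standardize = FALSE))
  x_val <- featurize_kmers(val$cdr3_aa, config$kmer_sizes,
                           vocab = colnames(x_train))
  p_val <- stats::predict(fit, x_val, type = "response")
  # balanced accuracy: validation strata can be strongly class-imbalanced
  # (tail CDR3 lengths), where plain accuracy would select the null model
  pos <- val$label == 1L
  acc <- (colMeans(p_val[pos, , drop = FALSE] > 0.5) +
            colMeans(p_val[!pos, , drop = FALSE] <= 0.5)) / 2
  best <- which.max(acc) # first maximum = most regularized = earliest state
  history <- tibble(step = seq_along(fit$lambda), lambda = fit$lambda,
                    train_dev_ratio = fit$dev.ratio,
                    val_accuracy = as.numeric(acc))

  structure(list(length = len, backend = "reference_scorer", fit = fit,
                 lambda = fit$lambda[best], vocab = colnames(x_train),
                 kmer_sizes = config$kmer_sizes, history = history,
                 n_train = nrow(train), n_val = nrow(val),
                 val_accuracy = acc[[best]],
                 classes = c("non_cancer", "cancer")),
            class = "cdr3_scorer")
}

#' Train one scorer per CDR3 length
#'
#' Runs [train_length_model()] for every length in `lengths`, producing
#' exactly one model per length.
#'
#' @inheritParams train_length_model
#' @param lengths Integer vector of CDR3 lengths (default `11:20`).
#' @return A `scorer_set`: named list of `cdr3_scorer` objects keyed by
#'   length.
#' @export
train_all_lengths <- function(split, lengths = 11:20,
                              config = training_config()) {
  models <- map(lengths, function(l) train_length_model(split, l, config))
  structure(setNames(models, as.character(lengths)), class = "scorer_set")
}

#' @export
print.cdr3_scorer <- function(x, ...) {
  cat(sprintf("# CDR3 scorer (length %s, backend %s): %d features, val accuracy %.3f\n",
              ifelse(is.na(x$length), "any", x$length), x$backend,
              length(x$vocab %||% character()), x$val_accuracy %||% NA))
  invisible(x)
}

#' @export
print.scorer_set <- function(x, ...) {
  cat(sprintf("# scorer set: %d length-specific models (lengths %s)\n",
              length(x), paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Probability of the cancer-associated class
#'
#' Scores CDR3 sequences with a trained scorer; every input must have the
#' model's own length. The returned value is the probability of class 1
#' (cancer-associated), consistent with [softmax_probabilities()] applied to
#' the model's raw outputs, in `[0, 1]`, invariant to input order and
#' batching.
#'
#' @param model A `cdr3_scorer`.
#' @param sequences Character vector of CDR3 sequences.
#' @param type `"response"` for probabilities (default) or `"link"` for raw
#'   logits (class-1 minus class-0 score).
#' @return Numeric vector of probabilities (or logits), one per sequence.
#' @export
predict_proba <- function(model, sequences, type = c("response", "link")) {
  UseMethod("predict_proba")
}

#' @export
predict_proba.cdr3_scorer <- function(model, sequences,
                                      type = c("response", "link")) {
  type <- arg_match(type)
  if (!is.na(model$length)) {
    bad <- which(nchar(sequences) != model$length)
    if (length(bad) > 0L) {
      abort(sprintf("sequence '%s' has length %d but the model handles length %d",
                    sequences[bad[1L]], nchar(sequences[bad[1L]]), model$length),
            class = "tcrisk_validation_error")
    }
  }
  if (model$backend == "motif_oracle") {
    hit <- Reduce(`|`, map(model$motifs, function(m) {
      stringr::str_detect(sequences, stringr::fixed(m))
    }))
    link <- ifelse(hit, model$logit_hit, -model$logit_hit)
  } else {
    x <- featurize_kmers(sequences, model$kmer_sizes, vocab = model$vocab)
    link <- as.numeric(stats::predict(model$fit, x, s = model$lambda,
                                      type = "link"))
  }
  if (type == "link") link else stats::plogis(link)
}

#' Oracle scorer keyed on planted motifs
#'
#' A scorer that outputs a high cancer-class probability iff any of the
#' given motifs occurs in the sequence. Used as a ground-truth stand-in in
#' tests and by the longitudinal simulator; it accepts any sequence length.
#'
#' @param motifs Character vector of motif substrings.
#' @param logit_hit Logit magnitude assigned to a motif hit (default 10,
#'   i.e. probabilities ~1 and ~0).
#' @return A `cdr3_scorer` with backend `"motif_oracle"` and `length = NA`.
#' @export
motif_scorer <- function(motifs, logit_hit = 10) {
  structure(list(length = NA_integer_, backend = "motif_oracle",
                 motifs = motifs, logit_hit = logit_hit,
                 classes = c("non_cancer", "cancer")),
            class = "cdr3_scorer")
}

#' @rdname motif_scorer
#' @param lengths Lengths the set should nominally cover.
#' @return `motif_scorer_set()`: a `scorer_set` using the oracle for every
#'   length.
#' @export
motif_scorer_set <- function(motifs, lengths = 11:20, logit_hit = 10) {
  m <- motif_scorer(motifs, logit_hit)
  structure(setNames(rep(list(m), length(lengths)), as.character(lengths)),
            class = "scorer_set")
}

#' @export
tidy.cdr3_scorer <- function(x, ...) {
  if (x$backend == "motif_oracle") {
    return(tibble(term = x$motifs, estimate = x$logit_hit))
  }
  beta <- stats::coef(x$fit, s = x$lambda)
  nz <- which(beta[, 1L] != 0)
  tibble(term = rownames(beta)[nz], estimate = beta[nz, 1L])
}

#' @export
glance.cdr3_scorer <- function(x, ...) {
  tibble(length = x$length, backend = x$backend,
         n_train = x$n_train %||% NA_integer_,
         n_val = x$n_val %||% NA_integer_,
         val_accuracy = x$val_accuracy %||% NA_real_,
         lambda = x$lambda %||% NA_real_)
}

#' Export a fine-tuning job spec for the protein-language-model backend
#'
#' The `plm_finetune` backend fine-tunes a pretrained protein language model
#' (base model `Rostlab/prot_bert`) with the [training_config()]
#' hyperparameters; running it requires downloading the pretrained weights
#' and a GPU deep-learning toolchain, so this package emits the complete job
#' description — per-length hyperparameters plus train/validation TSVs —
#' rather than executing the fine-tune itself.
#'
#' @param split A `dataset_split`.
#' @param config A [training_config()].
#' @param dir Output directory (created if needed).
#' @param lengths Lengths to cover (default `11:20`).
#' @return Path of the written JSON job spec, invisibly.
#' @export
export_plm_job <- function(split, config = training_config(backend = "plm_finetune"),
                           dir = "plm_job", lengths = 11:20) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data <- as_tibble(split) %>% filter(.data$length %in% lengths)
  for (part in c("train", "val")) {
    readr::write_tsv(
      data %>% filter(.data$partition == part) %>%
        select("cdr3_aa", "label", "length"),
      file.path(dir, paste0(part, ".tsv")), progress = FALSE)
  }
  job <- list(
    base_model = "Rostlab/prot_bert",
    task = "binary classification: cancer-associated (1) vs non-cancer (0) CDR3",
    per_length_learning_rate = as.list(config$learning_rates),
    scheduler = list(type = "linear", warmup_ratio = config$warmup_ratio),
    batch_size = config$batch_size, epochs = config$epochs,
    weight_decay = config$weight_decay, seed = config$seed,
    gradient_accumulation_steps = config$grad_accum,
    model_selection = "best validation accuracy, earliest epoch on ties",
    data = list(train = "train.tsv", val = "val.tsv")
  )
  path <- file.path(dir, "job.json")
  jsonlite::write_json(job, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
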