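test_that("tokenization is a bijection over the canonical alphabet", {
  expect_length(tokenize("CASS"), 4L)
  expect_equal(detokenize(tokenize("CASS")), "CASS")
  withr::with_seed(3, seqs <- random_seqs(1000))
  for (s in seqs[1:50]) expect_equal(detokenize(tokenize(s)), s)
  expect_true(all(vapply(seqs, function(s)
    identical(detokenize(tokenize(s)), s), logical(1))))
})

test_that("non-canonical residues are rejected with their position", {
  err <- expect_error(tokenize("CAXSF"), class = "tcrisk_validation_error")
  expect_match(conditionMessage(err), "position 3")
  expect_match(conditionMessage(err), "'X'")
  for (bad in c("CA*F", "CA_F", "CABF", "CAUF")) {
    expect_error(tokenize(bad), class = "tcrisk_validation_error")
  }
})

test_that("softmax is symmetric, stable and correct", {
  expect_equal(softmax_probabilities(c(0, 0)), c(0.5, 0.5))
  big <- softmax_probabilities(c(1000, 0))
  expect_true(all(is.finite(big)))
  expect_equal(big[1], 1, tolerance = 1e-12)
  expect_equal(softmax_probabilities(c(1, -1)), c(0.8808, 0.1192),
               tolerance = 1e-4)
  expect_equal(sum(softmax_probabilities(c(-3.2, 7.9))), 1, tolerance = 1e-12)
  expect_error(softmax_probabilities(c(Inf, 0)), class = "tcrisk_domain_error")
  expect_error(softmax_probabilities(c(NA, 0)), class = "tcrisk_domain_error")
})

test_that("training config validates rates and records the backend", {
  cfg <- training_config()
  expect_equal(unname(cfg$learning_rates[["15"]]), 3e-7)
  expect_length(cfg$learning_rates, 10L)
  expect_equal(cfg$seed, 42)
  expect_error(training_config(learning_rates = c(`11` = -1)),
               class = "tcrisk_domain_error")
})

test_that("a planted motif stratum is scored near the achievable optimum", {
  # with the motif in 80% of positives and 5% of negatives the best any
  # classifier can do is the pair-statistic optimum of ~0.8875; the
  # reference scorer should land within sampling error of it
  split <- make_motif_split(lengths = 12, n_per = 1000, prev_pos = 0.8,
                            prev_neg = 0.05, seed = 2)
  model <- train_length_model(split, 12)
  val <- split[split$partition == "val" & split$length == 12, ]
  a <- auc(predict_proba(model, val$cdr3_aa), val$label)
  bound <- optimal_motif_auc(0.8, 0.05)
  expect_gte(a, bound - 0.04)
  expect_gte(a, 0.85)
})

test_that("label permutation destroys the signal", {
  split <- make_motif_split(lengths = 12, n_per = 500, seed = 4)
  withr::with_seed(9, split$label <- sample(split$label))
  model <- train_length_model(split, 12)
  val <- split[split$partition == "val", ]
  a <- auc(predict_proba(model, val$cdr3_aa), val$label)
  expect_gte(a, 0.4)
  expect_lte(a, 0.6)
})

test_that("training and prediction are deterministic", {
  split <- make_motif_split(lengths = 11, n_per = 200, seed = 6)
  m1 <- train_length_model(split, 11)
  m2 <- train_length_model(split, 11)
  probe <- split$cdr3_aa[1:50]
  expect_identical(predict_proba(m1, probe), predict_proba(m2, probe))
})

test_that("degenerate training inputs raise errors", {
  split <- make_motif_split(lengths = 11, n_per = 100, seed = 7)
  single <- split[split$label == 1L, ]
  class(single) <- class(split)
  expect_error(train_length_model(single, 11), "single class",
               class = "tcrisk_domain_error")
  expect_error(train_length_model(split, 19), class = "tcrisk_empty_error")
  expect_error(
    train_length_model(split, 11,
                       training_config(backend = "plm_finetune")),
    class = "tcrisk_backend_error")
})

test_that("predicted probabilities honor the output contracts", {
  split <- make_motif_split(lengths = 13, n_per = 300, seed = 8)
  model <- train_length_model(split, 13)
  seqs <- split$cdr3_aa[split$length == 13][1:80]
  p <- predict_proba(model, seqs)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(predict_proba(model, c(seqs[1], seqs[1]))[1],
                   predict_proba(model, c(seqs[1], seqs[1]))[2])
  # order and batching invariance
  perm <- rev(seq_along(seqs))
  expect_equal(predict_proba(model, seqs[perm]), p[perm], tolerance = 1e-12)
  expect_equal(c(predict_proba(model, seqs[1:10]),
                 predict_proba(model, seqs[11:80])), p, tolerance = 1e-12)
  # probabilities are the softmax of the raw outputs
  link <- predict_proba(model, seqs, type = "link")
  soft <- vapply(link, function(l) softmax_probabilities(c(l, 0))[1],
                 numeric(1))
  expect_equal(p, soft, tolerance = 1e-12)
  err <- expect_error(predict_proba(model, "CASSF"),
                      class = "tcrisk_validation_error")
  expect_match(conditionMessage(err), "CASSF")
})

test_that("a 0.5 prevalence gap is scored at its achievable optimum", {
  # prevalences 0.6 vs 0.1 cap the AUC at 0.75 (motif-status ties keep
  # half weight); the scorer should track that bound across seeds
  bound <- optimal_motif_auc(0.6, 0.1)
  for (s in 1:5) {
    split <- make_motif_split(lengths = 14, n_per = 1000, prev_pos = 0.6,
                              prev_neg = 0.1, seed = 20 + s)
    model <- train_length_model(split, 14)
    val <- split[split$partition == "val", ]
    a <- auc(predict_proba(model, val$cdr3_aa), val$label)
    expect_lt(abs(a - bound), 0.05)
  }
})

test_that("model construction yields exactly one scorer per length", {
  split <- make_motif_split(lengths = 11:14, n_per = 120, seed = 10)
  models <- train_all_lengths(split, lengths = 11:14)
  expect_length(models, 4L)
  expect_equal(as.integer(names(models)), 11:14)
  for (l in 11:14) expect_equal(models[[as.character(l)]]$length, l)
})

test_that("the motif oracle scorer flags motif carriers only", {
  oracle <- motif_scorer("WDR")
  p <- predict_proba(oracle, c("CASSWDRGAYEQF", "CASSLGQGAYEQF"))
  expect_gt(p[1], 0.99)
  expect_lt(p[2], 0.01)
  set <- motif_scorer_set("WDR", lengths = 11:20)
  expect_length(set, 10L)
})

test_that("tidy and glance expose interpretable summaries", {
  split <- make_motif_split(lengths = 11, n_per = 300, motif = "WDR", seed = 12)
  model <- train_length_model(split, 11)
  td <- tidy(model)
  expect_true(all(c("term", "estimate") %in% names(td)))
  # the planted motif (or one of its sub-k-mers) carries positive weight
  motif_terms <- td$estimate[td$term %in% c("WDR", "WD", "DR")]
  expect_gt(max(motif_terms), 0)
  gl <- glance(model)
  expect_equal(gl$length, 11L)
  expect_gte(gl$val_accuracy, 0.8)
})

test_that("the PLM fine-tuning job spec is complete and faithful", {
  split <- make_motif_split(lengths = 11:12, n_per = 50, seed = 14)
  dir <- tempfile()
  path <- export_plm_job(split, dir = dir, lengths = 11:12)
  job <- jsonlite::read_json(path)
  expect_equal(job$base_model, "Rostlab/prot_bert")
  expect_equal(job$epochs, 5)
  expect_equal(job$weight_decay, 0.01)
  expect_equal(job$seed, 42)
  expect_equal(job$per_length_learning_rate$`15`, 3e-7)
  train <- readr::read_tsv(file.path(dir, "train.tsv"),
                           show_col_types = FALSE)
  expect_true(all(c("cdr3_aa", "label", "length") %in% names(train)))
})
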