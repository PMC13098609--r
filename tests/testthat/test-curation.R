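test_that("pool building applies strict frequency and length filters", {
  # three in-range clones at 0.0005/0.0003/0.0002 plus an out-of-range filler
  rep <- repertoire(data.frame(
    cdr3_aa = c("CASSLGQGAYEQYF", "CASRDRDRGNTIYF", "CASSPGTSGSYEQF",
                "CASSLGQYF"),
    count = c(5, 3, 2, 9990)
  ), sample_id = "p1")
  pool <- build_class_pool(list(rep), min_freq = 3e-4, label = "cancer")
  expect_equal(nrow(pool), 1L) # 0.0003 is excluded by the strict '>'
  expect_equal(pool$cdr3_aa, "CASSLGQGAYEQYF")
})

test_that("pooled sequences are deduplicated with provenance counts", {
  mk <- function(id) toy_repertoire(counts = c(6, 4), sample_id = id,
                                    cdr3 = c("CASSLGQGAYEQYF", "CASRDRDRGNTIYF"))
  pool <- build_class_pool(list(mk("a"), mk("b"), mk("c")),
                           min_freq = 0.5, label = "non_cancer")
  expect_equal(nrow(pool), 1L)
  expect_equal(pool$n_samples, 3L)
  expect_error(
    build_class_pool(list(mk("a")), min_freq = 0.99, label = "cancer"),
    "frequency > 0.99", class = "tcrisk_empty_error")
})

test_that("pool equals a brute-force set comprehension on a synthetic cohort", {
  cfg <- sim_config(n_clones = 300, n_motif_clones = 60, total_reads = 2e4,
                    cohort_sizes = c(HD = 20, BPN = 1, LC = 1))
  reps <- lapply(1:20, function(s) {
    filter_productive(generate_repertoire(cfg, "HD", seed = s))
  })
  pool <- build_class_pool(reps, min_freq = 1e-3, label = "non_cancer")
  oracle <- sort(unique(unlist(lapply(reps, function(r) {
    r$cdr3_aa[r$frequency > 1e-3 & nchar(r$cdr3_aa) >= 11 &
                nchar(r$cdr3_aa) <= 20]
  }))))
  expect_setequal(pool$cdr3_aa, oracle)
})

test_that("shared-sequence exclusion is an exact set difference", {
  cancer <- make_pool(c("CASSAAAAAAAAF", "CASSBBBBBBBBF", "CASSCCCCCCCCF"))
  healthy <- make_pool("CASSBBBBBBBBF", label = "non_cancer")
  out <- exclude_shared(cancer, healthy)
  expect_setequal(out$cdr3_aa, c("CASSAAAAAAAAF", "CASSCCCCCCCCF"))
  expect_length(intersect(out$cdr3_aa, healthy$cdr3_aa), 0)

  disjoint <- make_pool("CASSDDDDDDDDF", label = "non_cancer")
  expect_equal(nrow(exclude_shared(cancer, disjoint)), 3L)

  withr::with_seed(31, {
    big <- unique(random_seqs(1100))[1:1000]
    shared <- sample(big, 100)
  })
  out2 <- exclude_shared(make_pool(big), make_pool(shared, "non_cancer"))
  expect_equal(nrow(out2), 900L)
})

test_that("near-identical sequences cluster together, dissimilar apart", {
  a <- "CASSLGQGAYEF"
  b <- sub("G", "T", a) # one substitution: identity 11/12 >= 0.4
  cl <- greedy_cluster(c(a, b), identity = 0.4)
  expect_equal(max(cl$cluster), 1L)

  cl2 <- greedy_cluster(c(strrep("A", 11), strrep("C", 11)), identity = 0.4)
  expect_equal(max(cl2$cluster), 2L)
})

test_that("greedy clustering matches the brute-force reference", {
  for (s in 1:3) {
    withr::with_seed(100 + s, seqs <- unique(random_seqs(30, c(11, 16))))
    got <- greedy_cluster(seqs, identity = 0.55)
    ref <- oracle_greedy_cluster(seqs, identity = 0.55)
    merged <- merge(as.data.frame(got[c("cdr3_aa", "cluster")]),
                    as.data.frame(ref), by = "cdr3_aa")
    expect_equal(merged$cluster.x, merged$cluster.y)
  }
})

test_that("pairwise identity agrees with the LCS oracle", {
  withr::with_seed(41, {
    pairs <- replicate(15, random_seqs(2, c(11, 20)), simplify = FALSE)
  })
  for (p in pairs) {
    got <- tcrisk:::alignment_matches(p[1], p[2])
    expect_equal(got, oracle_lcs(p[1], p[2]))
  }
})

test_that("the candidate filter never changes cluster assignments", {
  withr::with_seed(43, seqs <- unique(random_seqs(80, c(11, 18))))
  with_filter <- greedy_cluster(seqs, identity = 0.6, word_filter = TRUE)
  without <- greedy_cluster(seqs, identity = 0.6, word_filter = FALSE)
  expect_identical(as.data.frame(with_filter), as.data.frame(without))
})

test_that("identity 1.0 gives singletons on a duplicate-free pool", {
  withr::with_seed(47, seqs <- unique(random_seqs(25)))
  cl <- greedy_cluster(seqs, identity = 1.0)
  expect_equal(max(cl$cluster), length(seqs))
})

test_that("dominant-cluster retention uses the inclusive 15% rule", {
  mk_clustering <- function(sizes) {
    seqs <- unique(random_seqs(sum(sizes), c(12, 12)))
    stopifnot(length(seqs) == sum(sizes))
    tbl <- tibble::tibble(
      cdr3_aa = seqs, length = 12L,
      cluster = rep(seq_along(sizes), sizes),
      representative = rep(seqs[cumsum(c(1, sizes[-length(sizes)]))], sizes),
      identity = 1
    )
    structure(tbl, params = list(identity = 0.4, word_size = 2),
              class = c("cdr3_clustering", class(tbl)))
  }
  withr::with_seed(53, cl <- mk_clustering(c(8, 1, 1)))
  expect_equal(nrow(retain_dominant_clusters(cl, 0.15)), 8L)
  withr::with_seed(59, cl2 <- mk_clustering(c(5, 5)))
  expect_equal(nrow(retain_dominant_clusters(cl2, 0.15)), 10L)
  expect_equal(nrow(retain_dominant_clusters(cl2, 0.5)), 10L) # inclusive '>='
  expect_equal(nrow(retain_dominant_clusters(cl, 0)), 10L)
  expect_error(retain_dominant_clusters(cl, 0.9), class = "tcrisk_empty_error")
})

test_that("planted motif sequences survive curation when dominant", {
  # one tight motif cluster holding >15% of the pool is fully retained
  withr::with_seed(61, {
    motif_seqs <- paste0("CASS", replicate(30, paste(
      sample(c("A", "G"), 8, TRUE), collapse = "")), "F")
    motif_seqs <- unique(motif_seqs)
    noise <- unique(random_seqs(40, c(13, 13)))
  })
  cl <- greedy_cluster(c(motif_seqs, noise), identity = 0.75)
  kept <- retain_dominant_clusters(cl, 0.15)
  expect_true(all(motif_seqs %in% kept$cdr3_aa))
})

test_that("the stratified split honors quotas, ratios and determinism", {
  withr::with_seed(67, {
    pos <- make_pool(unlist(lapply(11:12, function(L)
      unique(random_seqs(150, c(L, L))))))
    neg <- make_pool(unlist(lapply(11:12, function(L)
      unique(random_seqs(150, c(L, L))))), label = "non_cancer")
  })
  split <- stratify_and_split(pos, neg, lengths = 11:12, test_quota = 50,
                              seed = 5)
  expect_equal(sum(split$partition == "test"), 4 * 50)
  # partitions are disjoint and exhaustive per stratum
  expect_equal(nrow(split), nrow(dplyr::distinct(split[c("cdr3_aa", "label")])))
  one <- split[split$length == 11 & split$label == 1L, ]
  rem <- sum(one$partition != "test")
  expect_equal(sum(one$partition == "train"), floor(rem * 0.8))

  again <- stratify_and_split(pos, neg, lengths = 11:12, test_quota = 50,
                              seed = 5)
  expect_identical(as.data.frame(split), as.data.frame(again))
  other <- stratify_and_split(pos, neg, lengths = 11:12, test_quota = 50,
                              seed = 6)
  expect_false(identical(as.data.frame(split), as.data.frame(other)))
})

test_that("small strata reduce the quota with a warning; empty strata error", {
  withr::with_seed(71, {
    pos <- make_pool(unique(random_seqs(40, c(11, 11))))
    neg <- make_pool(unique(random_seqs(40, c(11, 11))), label = "non_cancer")
  })
  warns <- capture_warnings(
    split <- stratify_and_split(pos, neg, lengths = 11, test_quota = 500,
                                seed = 1))
  expect_match(warns, "quota reduced", all = TRUE)
  expect_length(warns, 2L) # one per label stratum
  n <- nrow(pos)
  expect_equal(sum(split$partition == "test" & split$label == 1L),
               floor(n / 2))
  expect_error(
    suppressWarnings(stratify_and_split(pos, neg, lengths = 12,
                                        test_quota = 5, seed = 1)),
    "length 12", class = "tcrisk_empty_error")
})

test_that("pools round-trip through text and FASTA", {
  withr::with_seed(73, pool <- make_pool(unique(random_seqs(20))))
  for (fmt in c("text", "fasta")) {
    path <- tempfile()
    write_pool(pool, path, format = fmt)
    back <- read_pool(path, format = fmt, label = "cancer")
    expect_setequal(back$cdr3_aa, pool$cdr3_aa)
  }
})
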