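small_cfg <- function(...) {
  sim_config(n_clones = 400, n_motif_clones = 100, total_reads = 2e4,
             cohort_sizes = c(HD = 3, BPN = 3, LC = 3), ...)
}

test_that("generated repertoires live on the frequency simplex", {
  rep <- generate_repertoire(small_cfg(), "HD", seed = 1)
  expect_equal(sum(rep$frequency), 1, tolerance = 1e-9)
  expect_equal(total_reads(rep), 2e4)
  expect_true(all(grepl("^C", rep$cdr3_aa[rep$productive])))
  expect_true(all(grepl("F$", rep$cdr3_aa[rep$productive])))
})

test_that("generation is deterministic per seed", {
  a <- generate_repertoire(small_cfg(), "LC", seed = 9)
  b <- generate_repertoire(small_cfg(), "LC", seed = 9)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_repertoire(small_cfg(), "LC", seed = 10)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("motif read mass tracks the configured group prevalence", {
  cfg <- sim_config(cohort_sizes = c(HD = 1, BPN = 1, LC = 1))
  for (g in c("HD", "LC")) {
    rep <- filter_productive(generate_repertoire(cfg, g, seed = 77))
    mass <- sum(rep$frequency[grepl("WRD", rep$cdr3_aa)])
    expect_lt(abs(mass - cfg$prevalence[[g]]), 0.02)
  }
})

test_that("prevalence ordering and zipf validation are enforced", {
  expect_error(sim_config(prevalence = c(HD = 0.3, BPN = 0.2, LC = 0.1)),
               class = "tcrisk_domain_error")
  expect_error(sim_config(zipf_exponent = 0), class = "tcrisk_domain_error")
  expect_error(generate_repertoire(small_cfg(), "XX", seed = 1),
               class = "tcrisk_domain_error")
})

test_that("cohorts honor group sizes, labels and determinism", {
  cohort <- generate_cohort(small_cfg(), seed = 3)
  expect_length(cohort$repertoires, 9L)
  expect_equal(as.vector(table(cohort$metadata$group)), c(3L, 3L, 3L))
  expect_equal(names(cohort$repertoires), cohort$metadata$sample_id)
  groups <- vapply(cohort$repertoires,
                   function(r) sample_metadata(r)$group, character(1))
  expect_equal(unname(groups), cohort$metadata$group)

  again <- generate_cohort(small_cfg(), seed = 3)
  expect_identical(cohort$metadata, again$metadata)
  expect_identical(as.data.frame(cohort$repertoires[[5]]),
                   as.data.frame(again$repertoires[[5]]))

  expect_error(generate_cohort(sim_config(cohort_sizes = c(HD = 0, BPN = 1,
                                                           LC = 1)),
                               seed = 1),
               class = "tcrisk_empty_error")
})

test_that("steeper clone-size laws reduce D50 as constructed", {
  cfg <- sim_config(n_clones = 600, n_motif_clones = 100, total_reads = 3e4,
                    zipf_exponent = c(HD = 0.7, BPN = 0.7, LC = 1.3),
                    cohort_sizes = c(HD = 8, BPN = 1, LC = 8))
  cohort <- generate_cohort(cfg, seed = 21)
  d50s <- vapply(cohort$repertoires, function(r) {
    diversity_profile(filter_productive(r))$d50
  }, numeric(1))
  groups <- cohort$metadata$group
  expect_gt(mean(d50s[groups == "HD"]), mean(d50s[groups == "LC"]))
})

test_that("the shared public catalogue creates cross-group sequence overlap", {
  cfg <- small_cfg()
  hd <- filter_productive(generate_repertoire(cfg, "HD", seed = 1))
  lc <- filter_productive(generate_repertoire(cfg, "LC", seed = 2))
  shared <- intersect(hd$cdr3_aa, lc$cdr3_aa)
  expect_gt(length(shared), 20) # expanded background is largely public
})

test_that("longitudinal pairs realize their target trajectory class", {
  cfg <- sim_config(n_clones = 1000, n_motif_clones = 200, total_reads = 5e4,
                    cohort_sizes = c(HD = 1, BPN = 1, LC = 1))
  oracle <- motif_scorer_set("WRD")
  th <- tibble::tibble(length = 11:20, threshold = 0.5,
                       sensitivity = NA_real_, specificity = NA_real_,
                       auc = NA_real_, n_val = NA_integer_)
  oracle_lcri <- function(rep) {
    compute_lcri(flag_cancer_clones(filter_productive(rep), oracle, th))$lcri
  }
  for (target in c("positive_induction", "temporal_stability", "reduction")) {
    pair <- generate_longitudinal_pair(cfg, subtype = target, seed = 13)
    delta <- oracle_lcri(pair$post) - oracle_lcri(pair$pre)
    if (target == "positive_induction") expect_gt(delta, 0.01)
    if (target == "temporal_stability") expect_lte(abs(delta), 0.01)
    if (target == "reduction") expect_lt(delta, -0.01)
  }
  p1 <- generate_longitudinal_pair(cfg, "reduction", seed = 4)
  p2 <- generate_longitudinal_pair(cfg, "reduction", seed = 4)
  expect_identical(as.data.frame(p1$pre), as.data.frame(p2$pre))
  expect_identical(as.data.frame(p1$post), as.data.frame(p2$post))
})

test_that("unreachable longitudinal targets are rejected", {
  cfg <- small_cfg(longitudinal_pre = 0.05,
                   delta_ranges = list(positive_induction = c(0.05, 0.2),
                                       temporal_stability = c(0, 0),
                                       reduction = c(0.5, 0.5)))
  expect_error(generate_longitudinal_pair(cfg, "reduction", seed = 1),
               "unreachable", class = "tcrisk_domain_error")
})

test_that("written cohorts exercise the real I/O path", {
  cohort <- generate_cohort(small_cfg(), seed = 8)
  dir <- tempfile()
  manifest <- write_cohort(cohort, dir, dialect = "vdjtools")
  expect_true(all(file.exists(manifest$path)))
  back <- read_clonotype_table(manifest$path[1], "vdjtools",
                               sample_id = manifest$sample_id[1])
  orig <- cohort$repertoires[[manifest$sample_id[1]]]
  expect_equal(back$cdr3_aa, orig$cdr3_aa)
  expect_equal(back$count, orig$count)
  meta <- readr::read_csv(file.path(dir, "metadata.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(meta), 9L)
})
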