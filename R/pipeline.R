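#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run: the input cohort (an
#' in-memory cohort, a manifest of clonotype tables, or a simulation
#' config), the preprocessing depth, curation thresholds, clustering and
#' retention parameters, split quotas, training configuration, calibration
#' criterion, and output directory.
#'
#' Exactly one of `cohort`, `manifest`, `sim` must be supplied: `cohort` as
#' returned by [generate_cohort()]; `manifest` a CSV/tibble with columns
#' `sample_id`, `path`, `group` and optionally `dialect`; `sim` a
#' [sim_config()] realized with the pipeline seed.
#'
#' @param cohort,manifest,sim Input source (see above).
#' @param negative_group,positive_group Group labels supplying the
#'   non-cancer and cancer training cohorts (defaults `"HD"`, `"LC"`).
#' @param depth Preprocessing read depth (default 100,000; `NULL` skips).
#' @param min_freq Named per-class strict frequency filters
#'   (defaults non_cancer 3e-4, cancer 4e-4).
#' @param length_range Curation CDR3 length range (default `c(11, 20)`).
#' @param cluster_identity,word_size Greedy clustering parameters
#'   (defaults 0.4, 2).
#' @param retain_fraction,retain_denominator Dominant-cluster retention
#'   rule (defaults 0.15, `"total"`).
#' @param lengths,test_quota,train_frac Split parameters
#'   (defaults 11:20, 500, 0.8).
#' @param training A [training_config()].
#' @param criterion Calibration criterion (default `"youden"`).
#' @param out_dir Directory for versioned artifacts (`NULL`: in-memory
#'   only).
#' @param seed Pipeline seed recorded in every report; all stage seeds
#'   derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = NULL, manifest = NULL, sim = NULL,
                            negative_group = "HD", positive_group = "LC",
                            depth = 1e5,
                            min_freq = c(non_cancer = 3e-4, cancer = 4e-4),
                            length_range = c(11, 20),
                            cluster_identity = 0.4, word_size = 2,
                            retain_fraction = 0.15,
                            retain_denominator = "total",
                            lengths = 11:20, test_quota = 500,
                            train_frac = 0.8,
                            training = training_config(),
                            criterion = "youden",
                            out_dir = NULL, seed = 1L) {
  if (sum(!is.null(cohort), !is.null(manifest), !is.null(sim)) != 1L) {
    abort("supply exactly one of `cohort`, `manifest`, `sim`",
          class = "tcrisk_domain_error")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

run_stage <- function(name, config, expr) {
  tryCatch(expr, error = function(e) {
    snapshot <- ""
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      snap_path <- file.path(config$out_dir, "failed_stage_config.json")
      cfg <- config[!vapply(config, is.function, logical(1L))]
      cfg$cohort <- if (!is.null(config$cohort)) "<in-memory cohort>" else NULL
      jsonlite::write_json(
        list(stage = name, error = conditionMessage(e),
             config = map(cfg, function(x) {
               if (is.atomic(x) || is.null(x)) x else "<object>"
             })),
        snap_path, auto_unbox = TRUE, digits = NA, force = TRUE)
      snapshot <- sprintf(" (input snapshot: %s)", snap_path)
    }
    abort(sprintf("pipeline stage '%s' failed: %s%s",
                  name, conditionMessage(e), snapshot),
          class = "tcrisk_pipeline_error")
  })
}

#' Run the end-to-end framework
#'
#' Executes the three phases behind one call: data processing (per-sample
#' preprocessing and pool curation), model construction (per-length
#' training and threshold calibration), and validation (per-sample LCRI
#' scoring and cohort analysis). Returns a machine-readable report of
#' counts and metrics at every stage and, when `out_dir` is set, writes
#' versioned artifacts: pools, split, threshold table, per-sample LCRI CSV,
#' cohort comparison JSON and the report itself.
#'
#' The run is deterministic for a fixed config and seed.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list with elements `seed`, `counts`,
#'   `thresholds` (a `threshold_table`), `models` (a `scorer_set`), `lcri`
#'   (per-sample tibble), `comparison` (positive vs negative group),
#'   `comparisons` (all group pairs), `age_auc` (when ages are available),
#'   and `split`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  counts <- list()

  # --- phase 1a: inputs ---
  cohort <- run_stage("load", config, {
    if (!is.null(config$cohort)) {
      config$cohort
    } else if (!is.null(config$manifest)) {
      man <- if (is.character(config$manifest)) {
        readr::read_csv(config$manifest, show_col_types = FALSE)
      } else {
        as_tibble(config$manifest)
      }
      if (!"dialect" %in% names(man)) man$dialect <- "vdjtools"
      reps <- map(seq_len(nrow(man)), function(i) {
        read_clonotype_table(man$path[i],
                             dialect = man$dialect[i],
                             sample_id = man$sample_id[i],
                             metadata = list(group = man$group[i]))
      })
      names(reps) <- man$sample_id
      list(repertoires = reps, metadata = man)
    } else {
      generate_cohort(config$sim, seed = config$seed)
    }
  })
  counts$samples_in <- length(cohort$repertoires)

  # --- phase 1b: per-sample preprocessing ---
  pre <- run_stage("preprocess", config, {
    map(seq_along(cohort$repertoires), function(k) {
      suppressWarnings(preprocess_repertoire(
        cohort$repertoires[[k]], depth = config$depth,
        seed = (config$seed + 104729 * k) %% 2147483647))
    }) %>% setNames(names(cohort$repertoires))
  })
  counts$samples_preprocessed <- length(pre)

  groups <- map_chr(pre, function(r) sample_metadata(r)$group %||% "other")

  # --- phase 1c: pool curation ---
  curated <- run_stage("curate", config, {
    # curation operates on amino-acid sequences alone
    pool_reps <- function(g) {
      map(pre[groups == g], function(r) {
        repertoire(as_tibble(r), sample_id = sample_id(r),
                   aggregate_by = "cdr3")
      })
    }
    healthy_raw <- build_class_pool(pool_reps(config$negative_group),
                                    min_freq = config$min_freq[["non_cancer"]],
                                    length_range = config$length_range,
                                    label = "non_cancer")
    cancer_raw <- build_class_pool(pool_reps(config$positive_group),
                                   min_freq = config$min_freq[["cancer"]],
                                   length_range = config$length_range,
                                   label = "cancer")
    cancer_excl <- exclude_shared(cancer_raw, healthy_raw)
    healthy <- retain_dominant_clusters(
      greedy_cluster(healthy_raw, identity = config$cluster_identity,
                     word_size = config$word_size),
      fraction = config$retain_fraction,
      denominator = config$retain_denominator)
    cancer <- retain_dominant_clusters(
      greedy_cluster(cancer_excl, identity = config$cluster_identity,
                     word_size = config$word_size),
      fraction = config$retain_fraction,
      denominator = config$retain_denominator)
    list(healthy_raw = healthy_raw, cancer_raw = cancer_raw,
         cancer_excl = cancer_excl, healthy = healthy, cancer = cancer)
  })
  counts$pool_non_cancer_filtered <- nrow(curated$healthy_raw)
  counts$pool_cancer_filtered <- nrow(curated$cancer_raw)
  counts$pool_cancer_after_exclusion <- nrow(curated$cancer_excl)
  counts$pool_non_cancer_retained <- nrow(curated$healthy)
  counts$pool_cancer_retained <- nrow(curated$cancer)

  # --- phase 1d: stratified split ---
  split <- run_stage("split", config, suppressWarnings(
    stratify_and_split(curated$cancer, curated$healthy,
                       lengths = config$lengths,
                       test_quota = config$test_quota,
                       train_frac = config$train_frac,
                       seed = config$seed)
  ))
  counts$split <- as.list(table(split$partition))

  # --- phase 2: training + calibration ---
  models <- run_stage("train", config,
                      train_all_lengths(split, lengths = config$lengths,
                                        config = config$training))
  counts$models <- length(models)
  thresholds <- run_stage("calibrate", config,
                          calibrate_all_lengths(models, split,
                                                criterion = config$criterion))

  # --- phase 3: scoring + cohort analysis ---
  lcri <- run_stage("score", config, {
    suppressWarnings(lcri_cohort(cohort$repertoires, models, thresholds,
                                 metadata = cohort$metadata,
                                 depth = config$depth, seed = config$seed,
                                 lengths = config$lengths))
  })
  counts$samples_scored <- nrow(lcri)

  analysis <- run_stage("analyze", config, {
    grp <- lcri$group
    pair_cmp <- function(ga, gb, cutoff = FALSE) {
      compare_groups(lcri$lcri[grp == ga], lcri$lcri[grp == gb],
                     labels = c(ga, gb), cutoff = cutoff)
    }
    main <- pair_cmp(config$positive_group, config$negative_group,
                     cutoff = TRUE)
    pairs <- utils::combn(sort(unique(grp)), 2L, simplify = FALSE)
    all_cmp <- map(pairs, function(p) pair_cmp(p[2L], p[1L])) %>% list_rbind()
    age_auc <- NULL
    if ("age" %in% names(lcri) && !all(is.na(lcri$age))) {
      case <- as.integer(grp == config$positive_group)
      age_auc <- age_stratified_auc(lcri$lcri, case, lcri$age)
    }
    list(main = main, all = all_cmp, age_auc = age_auc)
  })

  report <- structure(
    list(seed = config$seed, counts = counts, split = split,
         models = models, thresholds = thresholds, lcri = lcri,
         comparison = analysis$main, comparisons = analysis$all,
         age_auc = analysis$age_auc,
         pools = curated[c("healthy", "cancer")]),
    class = "pipeline_report")

  if (!is.null(config$out_dir)) {
    run_stage("write", config, write_pipeline_artifacts(report, config))
  }
  report
}

write_pipeline_artifacts <- function(report, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- config$out_dir
  write_pool(report$pools$healthy, file.path(od, "pool_non_cancer.txt"))
  write_pool(report$pools$cancer, file.path(od, "pool_cancer.txt"))
  readr::write_tsv(as_tibble(report$split), file.path(od, "split.tsv"),
                   progress = FALSE)
  write_threshold_table(report$thresholds, file.path(od, "thresholds.json"))
  write_lcri(report$lcri, file.path(od, "lcri.csv"),
             json_path = file.path(od, "lcri_detail.json"))
  jsonlite::write_json(
    list(seed = report$seed, counts = report$counts,
         comparison = as_tibble(report$comparison),
         comparisons = as_tibble(report$comparisons)),
    file.path(od, "cohort_report.json"),
    auto_unbox = TRUE, digits = NA)
  saveRDS(report$models, file.path(od, "models.rds"))
  invisible(od)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("# pipeline report\n")
  cat(sprintf("  seed: %d, samples: %d, models: %d\n",
              x$seed, x$counts$samples_in, x$counts$models))
  cat(sprintf("  pooled validation AUC: %.3f\n",
              attr(x$thresholds, "pooled_auc")))
  cat(sprintf("  %s vs %s: mean LCRI %.3f vs %.3f, AUC %.3f, p = %.3g\n",
              x$comparison$group_a, x$comparison$group_b,
              x$comparison$mean_a, x$comparison$mean_b,
              x$comparison$auc, x$comparison$p_value))
  invisible(x)
}
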