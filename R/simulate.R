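#' Simulation configuration for synthetic TCR repertoires
#'
#' Describes the statistical structure the scoring framework assumes, so
#' every pipeline stage can be exercised without controlled-access cohorts:
#' power-law (Zipf) background clone sizes; CDR3 sequences over the
#' 20-letter alphabet with conserved `C...F` anchors and a unimodal length
#' law; a planted k-mer motif carried by a dedicated set of
#' cancer-associated clones whose total read mass per group follows the
#' ordered prevalences HD < BPN < LC; a shared public-sequence catalogue
#' from which expanded background clones are drawn (so that the
#' shared-sequence exclusion step of curation has real work to do); a small
#' nonproductive fraction; and per-group age distributions.
#'
#' In healthy donors the motif budget is spread over the same number of
#' clones as in cancer, so each motif clone sits below the curation
#' frequency filters — cancer-associated-like sequences are present but not
#' expanded — while in cancer samples the same clones are expanded above
#' the filters. This mirrors the premise that specific cancer-associated
#' CDR3 sequences accumulate with disease.
#'
#' @param n_clones Background clones per sample (default 2,000).
#' @param n_motif_clones Motif-bearing clones per sample (default 400).
#' @param zipf_exponent Background clone-size power-law exponent; a scalar
#'   or a named per-group vector (default 1).
#' @param total_reads Reads per sample (default 100,000).
#' @param length_range,length_mean,length_sd Background CDR3 length law: a
#'   discretized normal over `length_range` (defaults 8-24, mode ~14.5).
#' @param motifs Planted motif k-mers (default `"WRD"`); motif clones are
#'   drawn with lengths uniform over `motif_lengths` so every model stratum
#'   is exercised.
#' @param motif_lengths Lengths of motif clones (default `11:20`).
#' @param prevalence Named motif read-mass per group; must satisfy
#'   HD < BPN < LC (defaults 0.05, 0.15, 0.30).
#' @param cohort_sizes Named per-group sample counts (default 20 each for
#'   HD, BPN, LC).
#' @param frac_nonproductive Read mass carried by nonproductive clones
#'   (default 0.05).
#' @param public_catalogue_size,n_public_expanded,p_public Public-sequence
#'   model: size of the shared catalogue, number of top background ranks
#'   eligible to be public, probability that such a rank draws from the
#'   catalogue (defaults 1,000 / 300 / 0.9).
#' @param age_mean,age_sd Per-group age distributions (means 40/52/62,
#'   sd 10), emulating the age imbalance of observational cohorts.
#' @param longitudinal_pre Baseline motif prevalence of longitudinal pairs
#'   (default 0.25, a typical cancer-sample level that keeps every
#'   trajectory subtype reachable).
#' @param delta_ranges Magnitude ranges of the post-pre prevalence shift per
#'   trajectory subtype.
#' @param seed Config-level seed fixing cohort-invariant structure (the
#'   public catalogue); per-sample randomness comes from the seeds passed to
#'   the generators.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_clones = 2000, n_motif_clones = 400,
                       zipf_exponent = 1, total_reads = 1e5,
                       length_range = c(8, 24), length_mean = 14.5,
                       length_sd = 2.2, motifs = "WRD",
                       motif_lengths = 11:20,
                       prevalence = c(HD = 0.05, BPN = 0.15, LC = 0.30),
                       cohort_sizes = c(HD = 20, BPN = 20, LC = 20),
                       frac_nonproductive = 0.05,
                       public_catalogue_size = 1000,
                       n_public_expanded = 300, p_public = 0.9,
                       age_mean = c(HD = 40, BPN = 52, LC = 62), age_sd = 10,
                       longitudinal_pre = 0.25,
                       delta_ranges = list(positive_induction = c(0.05, 0.20),
                                           temporal_stability = c(0, 0),
                                           reduction = c(0.05, 0.20)),
                       seed = 42L) {
  stopifnot(all(prevalence >= 0), all(prevalence <= 1))
  if (!all(c("HD", "BPN", "LC") %in% names(prevalence)) ||
      !(prevalence[["HD"]] < prevalence[["BPN"]] &&
        prevalence[["BPN"]] < prevalence[["LC"]])) {
    abort("motif prevalences must be named and ordered HD < BPN < LC",
          class = "tcrisk_domain_error")
  }
  if (any(zipf_exponent <= 0)) {
    abort("zipf_exponent must be positive", class = "tcrisk_domain_error")
  }
  structure(as.list(environment()), class = "sim_config")
}

group_zipf <- function(config, group) {
  z <- config$zipf_exponent
  if (!is.null(names(z)) && group %in% names(z)) z[[group]] else z[[1L]]
}

# discretized-normal probability over the background length support
length_law <- function(config) {
  support <- seq(config$length_range[1L], config$length_range[2L])
  p <- stats::dnorm(support, config$length_mean, config$length_sd)
  list(support = support, prob = p / sum(p))
}

# vectorized random CDR3s with conserved C/F anchors
random_cdr3 <- function(n, lengths) {
  out <- character(n)
  for (L in unique(lengths)) {
    sel <- which(lengths == L)
    interior <- matrix(sample(AA_ALPHABET, length(sel) * (L - 2L), replace = TRUE),
                       nrow = length(sel))
    out[sel] <- paste0("C", do.call(paste0, as.data.frame(interior)), "F")
  }
  out
}

# plant a motif at a random interior position, preserving the C/F anchors
plant_motif <- function(seqs, motif) {
  k <- nchar(motif)
  lens <- nchar(seqs)
  stopifnot(all(lens >= k + 2L))
  pos <- 2L + floor(runif(length(seqs)) * (lens - k - 1L))
  substr(seqs, pos, pos + k - 1L) <- motif
  seqs
}

# shared public background catalogue, fixed by the config seed
public_catalogue <- function(config) {
  law <- length_law(config)
  withr::with_seed(config$seed + 1L, {
    lens <- sample(law$support, config$public_catalogue_size,
                   replace = TRUE, prob = law$prob)
    unique(random_cdr3(config$public_catalogue_size, lens))
  })
}

#' Generate one synthetic repertoire
#'
#' Draws clone frequencies (Zipf background, uniform motif component scaled
#' to the group's motif prevalence, small nonproductive component),
#' allocates `total_reads` reads multinomially, attaches CDR3 sequences
#' (public-catalogue or private background, motif-planted cancer clones),
#' V/J calls and metadata. Deterministic for a fixed seed.
#'
#' @param config A [sim_config()].
#' @param group Group label: `"HD"`, `"BPN"` or `"LC"`.
#' @param seed Integer seed for this sample.
#' @param sample_id Sample identifier.
#' @param prevalence Optional override of the group's motif read-mass
#'   (used by the longitudinal generator).
#' @param age Optional age stored in the metadata.
#' @return A `tcr_repertoire`.
#' @export
generate_repertoire <- function(config, group = "HD", seed = 1L,
                                sample_id = NULL, prevalence = NULL,
                                age = NA_real_) {
  stopifnot(inherits(config, "sim_config"))
  if (!group %in% names(config$prevalence) && is.null(prevalence)) {
    abort(sprintf("unknown group '%s'", group), class = "tcrisk_domain_error")
  }
  pi_g <- prevalence %||% config$prevalence[[group]]
  sample_id <- sample_id %||% sprintf("%s_%d", group, seed)
  catalogue <- public_catalogue(config)
  law <- length_law(config)

  withr::with_seed(seed, {
    # --- frequency skeleton ---
    s <- group_zipf(config, group)
    bg <- seq_len(config$n_clones)^(-s)
    n_np <- max(1L, round(0.05 * config$n_clones))
    productive_mass <- 1 - config$frac_nonproductive
    p <- c(
      bg / sum(bg) * (1 - pi_g) * productive_mass,
      rep(pi_g * productive_mass / config$n_motif_clones,
          config$n_motif_clones),
      rep(config$frac_nonproductive / n_np, n_np)
    )
    kind <- c(rep("background", config$n_clones),
              rep("motif", config$n_motif_clones),
              rep("nonproductive", n_np))

    # --- sequences ---
    n_bg <- config$n_clones
    bg_lens <- sample(law$support, n_bg, replace = TRUE, prob = law$prob)
    bg_seqs <- random_cdr3(n_bg, bg_lens)
    n_pub <- min(config$n_public_expanded, n_bg, length(catalogue))
    is_public <- runif(n_pub) < config$p_public
    if (any(is_public)) {
      bg_seqs[seq_len(n_pub)][is_public] <-
        sample(catalogue, sum(is_public), replace = FALSE)
    }
    motif_lens <- sample(config$motif_lengths, config$n_motif_clones,
                         replace = TRUE)
    motif_seqs <- random_cdr3(config$n_motif_clones, motif_lens)
    motif_seqs <- plant_motif(motif_seqs,
                              sample(config$motifs, 1L))
    np_lens <- sample(law$support, n_np, replace = TRUE, prob = law$prob)
    np_seqs <- random_cdr3(n_np, np_lens)
    # inject a stop codon or frameshift marker at a random interior position
    np_pos <- 2L + floor(runif(n_np) * (np_lens - 2L))
    substr(np_seqs, np_pos, np_pos) <- sample(c("*", "_"), n_np, replace = TRUE)

    seqs <- c(bg_seqs, motif_seqs, np_seqs)
    counts <- as.integer(rmultinom(1L, size = config$total_reads, prob = p))

    v_genes <- sample(tcrb_v_genes(), length(seqs), replace = TRUE)
    j_genes <- sample(tcrb_j_genes(), length(seqs), replace = TRUE)
    keep <- counts > 0L
    repertoire(
      tibble(cdr3_aa = seqs[keep], v_gene = v_genes[keep],
             j_gene = j_genes[keep], count = counts[keep],
             clone_kind = kind[keep]),
      sample_id = sample_id,
      metadata = list(group = group, age = age, tissue = "blood",
                      motif_prevalence = pi_g)
    )
  })
}

# small realistic V/J gene catalogues for simulated calls
tcrb_v_genes <- function() {
  c("TRBV2", "TRBV3-1", "TRBV4-1", "TRBV4-2", "TRBV5-1", "TRBV6-2",
    "TRBV6-3", "TRBV7-4", "TRBV7-7", "TRBV9", "TRBV10-3", "TRBV18",
    "TRBV19", "TRBV20-1", "TRBV24-1", "TRBV25-1", "TRBV27", "TRBV28",
    "TRBV29-1", "TRBV30")
}

tcrb_j_genes <- function() {
  c(paste0("TRBJ1-", 1:6), paste0("TRBJ2-", 1:7))
}

#' Generate a synthetic cohort
#'
#' Generates `cohort_sizes[g]` repertoires per group with group-specific
#' motif prevalence and age distribution, plus a metadata table. All
#' randomness derives from `seed`; the public catalogue is shared across
#' the cohort.
#'
#' @param config A [sim_config()].
#' @param seed Cohort seed.
#' @return List with elements `repertoires` (named list of
#'   `tcr_repertoire`) and `metadata` (tibble: `sample_id`, `group`, `age`,
#'   `sex`).
#' @export
generate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  sizes <- config$cohort_sizes
  if (length(sizes) == 0L || any(sizes <= 0)) {
    abort("every cohort group must have a positive sample count",
          class = "tcrisk_empty_error")
  }
  plan <- tibble(
    group = rep(names(sizes), sizes),
    index = unlist(map(sizes, seq_len))
  ) %>% mutate(sample_id = sprintf("%s_%02d", .data$group, .data$index))
  draws <- withr::with_seed(seed, {
    list(
      seeds = sample.int(2147483646L, nrow(plan)),
      ages = pmin(90, pmax(20, round(rnorm(nrow(plan),
                                           config$age_mean[plan$group],
                                           config$age_sd)))),
      sex = sample(c("F", "M"), nrow(plan), replace = TRUE)
    )
  })
  reps <- map(seq_len(nrow(plan)), function(i) {
    generate_repertoire(config, group = plan$group[i], seed = draws$seeds[i],
                        sample_id = plan$sample_id[i], age = draws$ages[i])
  })
  names(reps) <- plan$sample_id
  list(
    repertoires = reps,
    metadata = tibble(sample_id = plan$sample_id, group = plan$group,
                      age = draws$ages, sex = draws$sex)
  )
}

#' Generate a longitudinal pre/post repertoire pair
#'
#' Emulates paired sampling around a treatment timepoint: the post sample's
#' motif prevalence is shifted from the baseline by a draw from the
#' subtype's configured delta range (positive for `positive_induction`,
#' zero for `temporal_stability`, negative for `reduction`), so that an
#' oracle motif scorer recovers the corresponding LCRI trajectory class.
#'
#' @param config A [sim_config()].
#' @param subtype Target trajectory class.
#' @param seed Integer seed.
#' @param patient_id Identifier used in the sample ids.
#' @return List with `pre` and `post` repertoires and the realized
#'   `target_delta`.
#' @export
generate_longitudinal_pair <- function(config,
                                       subtype = c("positive_induction",
                                                   "temporal_stability",
                                                   "reduction"),
                                       seed = 1L, patient_id = "P01") {
  subtype <- arg_match(subtype)
  stopifnot(inherits(config, "sim_config"))
  rng <- config$delta_ranges[[subtype]]
  pre_prev <- config$longitudinal_pre
  delta <- withr::with_seed(seed, runif(1L, rng[1L], rng[2L]))
  delta <- switch(subtype, positive_induction = delta,
                  temporal_stability = 0, reduction = -delta)
  post_prev <- pre_prev + delta
  if (post_prev < 0 || post_prev > 1) {
    abort(sprintf(
      "unreachable target: baseline prevalence %.3f with delta %+.3f leaves [0, 1]",
      pre_prev, delta), class = "tcrisk_domain_error")
  }
  pre <- generate_repertoire(config, group = "LC", seed = seed + 1L,
                             sample_id = paste0(patient_id, "_pre"),
                             prevalence = pre_prev)
  post <- generate_repertoire(config, group = "LC", seed = seed + 2L,
                              sample_id = paste0(patient_id, "_post"),
                              prevalence = post_prev)
  list(pre = pre, post = post, target_delta = delta, patient_id = patient_id)
}

#' Write a synthetic cohort to clonotype tables
#'
#' Exercises the real I/O path: one VDJtools or AIRR TSV per sample plus a
#' cohort metadata CSV.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory.
#' @param dialect Table dialect to write.
#' @return Tibble manifest (`sample_id`, `path`, `group`), invisibly.
#' @export
write_cohort <- function(cohort, dir, dialect = c("vdjtools", "airr")) {
  dialect <- arg_match(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- map_chr(names(cohort$repertoires), function(sid) {
    p <- file.path(dir, paste0(sid, ".tsv"))
    write_clonotype_table(cohort$repertoires[[sid]], p, dialect = dialect)
    p
  })
  readr::write_csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   progress = FALSE)
  invisible(tibble(sample_id = names(cohort$repertoires), path = paths,
                   group = cohort$metadata$group))
}
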