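#' Default pipeline configuration
#'
#' Returns the nested configuration list the pipeline runs on when no config
#' file is supplied. The `sim` block is a small demonstration dataset (a few
#' trios, an elevated mutation rate so candidates actually appear in the
#' output); `filters`, `rate`, `context` and `impact` carry the analysis
#' defaults (GQ >= 50, depth > 20, allele balance \[0.3, 0.7\], conservation
#' cut-off 12, selection rules `at_least_6` and `at_least_half`). Override
#' any entry via a YAML file with the same structure.
#'
#' @return Nested named list.
#' @export
default_pipeline_config <- function() {
  list(
    sim = list(n_trios = 6, n_sites = 4000, mu = 1e-4, mean_depth = 38.5,
               error_rate = 0.01, indel_fraction = 3 / 98,
               ts_tv_weight = 1.5),
    filters = list(min_gq = 50, min_depth_exclusive = 20,
                   ab_low = 0.3, ab_high = 0.7),
    rate = list(error_rate = 0.01),
    context = list(gerp_threshold = 12),
    impact = list(rules = c("at_least_6", "at_least_half"),
                  include_gerp = FALSE),
    seed = 1
  )
}

#' Read a pipeline configuration file
#'
#' Loads a YAML config and merges it over [default_pipeline_config()], so a
#' file only needs the entries it changes.
#'
#' @param path Path to a YAML file (or `NULL` for pure defaults).
#' @return Nested named list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(paste0("config file not found: ", path))
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

pipeline_thresholds <- function(config) {
  filter_thresholds(
    min_gq = config$filters$min_gq,
    min_depth_exclusive = config$filters$min_depth_exclusive,
    ab_low = config$filters$ab_low,
    ab_high = config$filters$ab_high
  )
}

require_input <- function(path, produced_by) {
  if (!file.exists(path)) {
    abort(paste0("missing input file: ", path,
                 " (produced by the '", produced_by, "' stage)"))
  }
  path
}

#' Run the trio DNM pipeline
#'
#' Executes one named stage, or the full chain
#' `simulate -> detect -> rate -> spectrum -> context -> impact` on
#' synthetic data (`stage = "all"`). Each stage reads its inputs from, and
#' writes its TSV outputs to, `out_dir`; a YAML run manifest records the
#' stages run, the effective thresholds, the seed and the package version.
#' Outputs are deterministic for a fixed config and seed.
#'
#' @param stage One of `"simulate"`, `"detect"`, `"rate"`, `"spectrum"`,
#'   `"context"`, `"impact"`, `"all"`.
#' @param config Config list (see [default_pipeline_config()]) or path to a
#'   YAML file.
#' @param out_dir Output directory.
#' @param seed Integer seed; overrides `config$seed` when given.
#' @return Invisibly, the list of files written by the requested stage(s).
#' @export
run_pipeline <- function(stage = "all", config = NULL, out_dir, seed = NULL) {
  stages <- c("simulate", "detect", "rate", "spectrum", "context", "impact")
  stage <- match.arg(stage, c(stages, "all"))
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- config %||% default_pipeline_config()
  seed <- seed %||% config$seed %||% 1
  pipeline_thresholds(config)  # validate thresholds before any output
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  run <- if (stage == "all") stages else stage
  written <- list()
  for (s in run) {
    written[[s]] <- switch(
      s,
      simulate = stage_simulate(config, out_dir, seed),
      detect = stage_detect(config, out_dir),
      rate = stage_rate(config, out_dir),
      spectrum = stage_spectrum(config, out_dir),
      context = stage_context(config, out_dir),
      impact = stage_impact(config, out_dir)
    )
  }
  # manifest paths are relative to out_dir so runs are relocatable and
  # reruns of single stages merge into the existing record
  root <- normalizePath(out_dir, winslash = "/")
  relativize <- function(p) {
    sub(paste0("^", root, "/"), "",
        normalizePath(p, winslash = "/", mustWork = FALSE))
  }
  manifest_path <- file.path(out_dir, "run_manifest.yaml")
  prev <- if (file.exists(manifest_path)) yaml::read_yaml(manifest_path)
  outputs <- prev$outputs %||% list()
  outputs[names(written)] <- lapply(written, relativize)
  done <- union(prev$stages %||% character(), run)
  manifest <- list(
    tool = "triodnm",
    version = as.character(packageVersion("triodnm")),
    seed = as.integer(seed),
    stages = as.list(stages[stages %in% done]),
    thresholds = config$filters,
    config = config[setdiff(names(config), "seed")],
    outputs = outputs
  )
  yaml::write_yaml(manifest, manifest_path)
  invisible(written)
}

stage_simulate <- function(config, out_dir, seed) {
  sim_args <- config$sim
  sim_args$seed <- seed
  sc <- do.call(simulation_config, sim_args)
  dataset <- simulate_trio_dataset(sc, dir = file.path(out_dir, "sim"))
  unlist(dataset$paths, use.names = FALSE)
}

read_all_trio_records <- function(config, out_dir) {
  sim_dir <- file.path(out_dir, "sim")
  ped_path <- require_input(file.path(sim_dir, "pedigree.tsv"), "simulate")
  ped <- read_pedigree(ped_path)
  purrr::map_dfr(seq_len(nrow(ped)), function(i) {
    trio <- ped[i, ]
    vcf <- require_input(file.path(sim_dir, paste0(trio$trio_id, ".vcf")),
                         "simulate")
    read_trio_vcf(vcf, trio) %>%
      mutate(trio_id = trio$trio_id, .before = 1)
  })
}

stage_detect <- function(config, out_dir) {
  records <- read_all_trio_records(config, out_dir)
  thr <- pipeline_thresholds(config)
  candidates <- records %>%
    drop_missing_records() %>%
    detect_candidates() %>%
    apply_filters(thr)
  path <- file.path(out_dir, "candidates.tsv")
  write_dnm_report(candidates, path)
  # full evidence for external review of each candidate
  evidence_path <- file.path(out_dir, "candidate_evidence.tsv")
  readr::write_tsv(candidates %>% arrange(.data$trio_id, .data$chrom,
                                          .data$pos),
                   evidence_path)
  c(path, evidence_path)
}

passing_candidates <- function(out_dir) {
  path <- require_input(file.path(out_dir, "candidates.tsv"), "detect")
  read_dnm_report(path) %>% filter(.data$filter_status == "pass")
}

stage_rate <- function(config, out_dir) {
  candidates <- passing_candidates(out_dir)
  records <- read_all_trio_records(config, out_dir) %>%
    drop_missing_records()
  thr <- pipeline_thresholds(config)
  eps <- config$rate$error_rate %||% 0.01
  informative <- records %>%
    filter(.data$child_ref_reads + .data$child_alt_reads > 0,
           .data$mother_ref_reads + .data$mother_alt_reads > 0,
           .data$father_ref_reads + .data$father_alt_reads > 0)
  callable <- site_callable_probability(informative, error_rate = eps,
                                        thresholds = thr)
  callable_path <- file.path(out_dir, "callable_sites.tsv")
  readr::write_tsv(callable, callable_path)
  sums <- callable %>%
    group_by(.data$trio_id) %>%
    summarise(p_snv_sum = sum(.data$p_snv),
              p_indel_sum = sum(.data$p_indel), .groups = "drop")
  sums_path <- file.path(out_dir, "callable_sums.tsv")
  write_callable_sums(sums, sums_path)

  trio_ids <- sums$trio_id
  count_for <- function(df) {
    df %>% count(.data$trio_id, name = "n_dnm") %>%
      tidyr::complete(trio_id = trio_ids, fill = list(n_dnm = 0L)) %>%
      arrange(match(.data$trio_id, trio_ids))
  }
  snv_counts <- count_for(candidates %>% filter(.data$variant_class == "SNV"))
  indel_counts <- count_for(candidates %>%
                              filter(.data$variant_class == "indel"))
  report <- dplyr::bind_rows(
    snv = tidy(estimate_rate(snv_counts$n_dnm, sums$p_snv_sum)),
    indel = if (sum(sums$p_indel_sum) > 0) {
      tidy(estimate_rate(indel_counts$n_dnm, sums$p_indel_sum))
    } else {
      NULL
    },
    .id = "variant_class"
  )
  report_path <- file.path(out_dir, "rate_report.tsv")
  readr::write_tsv(report, report_path)
  c(callable_path, sums_path, report_path)
}

stage_spectrum <- function(config, out_dir) {
  candidates <- passing_candidates(out_dir)
  ped <- read_pedigree(require_input(file.path(out_dir, "sim", "pedigree.tsv"),
                                     "simulate"))
  n_trios <- nrow(ped)
  snvs <- candidates %>% filter(.data$variant_class == "SNV")
  summary_tbl <- tibble(
    metric = c("n_pass", "n_snv", "n_indel", "tstv_ratio",
               "mean_dnms_per_person"),
    value = c(nrow(candidates), nrow(snvs),
              sum(candidates$variant_class == "indel"),
              if (nrow(snvs) > 0) tstv_ratio(snvs) else NA_real_,
              per_person_mean(candidates, n_trios))
  )
  p1 <- file.path(out_dir, "spectrum_summary.tsv")
  readr::write_tsv(summary_tbl, p1)
  p2 <- file.path(out_dir, "substitution_spectrum.tsv")
  readr::write_tsv(substitution_spectrum(candidates), p2)
  p3 <- file.path(out_dir, "chromosome_counts.tsv")
  readr::write_tsv(candidates %>% count(.data$chrom, name = "n_dnm"), p3)
  c(p1, p2, p3)
}

stage_context <- function(config, out_dir) {
  candidates <- passing_candidates(out_dir)
  sim_dir <- file.path(out_dir, "sim")
  callable <- readr::read_tsv(
    require_input(file.path(out_dir, "callable_sites.tsv"), "rate"),
    col_types = readr::cols(trio_id = readr::col_character(),
                            chrom = readr::col_character(),
                            .default = readr::col_double()))
  track_files <- list.files(file.path(sim_dir, "tracks"), "\\.bed$",
                            full.names = TRUE)
  if (length(track_files) == 0) {
    abort(paste0("missing input file: ", file.path(sim_dir, "tracks"),
                 " (produced by the 'simulate' stage)"))
  }
  tracks <- lapply(track_files, read_interval_track)
  names(tracks) <- sub("\\.bed$", "", basename(track_files))
  gerp <- readr::read_tsv(require_input(file.path(sim_dir, "gerp_scores.tsv"),
                                        "simulate"),
                          col_types = readr::cols(
                            chrom = readr::col_character(),
                            pos = readr::col_double(),
                            gerp_score = readr::col_double()))
  sites <- callable %>% distinct(.data$chrom, .data$pos)
  ann <- annotate_context(sites, tracks, gerp,
                          gerp_threshold = config$context$gerp_threshold %||% 12)

  features <- c("dhs", "cpg", "h3k27ac", "h3k4me1", "h3k4me3", "conserved")
  strata <- purrr::map_dfr(features, function(f) {
    purrr::map_dfr(c(1L, 0L), function(lev) {
      stratified_rate(candidates, callable, ann, f, lev) %>%
        mutate(feature = f, level = lev, .before = 1)
    })
  })
  p1 <- file.path(out_dir, "context_stratified_rates.tsv")
  readr::write_tsv(strata, p1)

  # Table-1-style per-feature OLS: per-trio DNM rate on per-trio count of
  # feature-carrying DNM positions
  sums <- read_callable_sums(require_input(
    file.path(out_dir, "callable_sums.tsv"), "rate"))
  per_trio <- candidates %>%
    count(.data$trio_id, name = "n_dnm") %>%
    right_join(sums, by = "trio_id") %>%
    mutate(n_dnm = tidyr::replace_na(.data$n_dnm, 0L),
           rate = .data$n_dnm / (2 * .data$p_snv_sum))
  ann_dnm <- candidates %>%
    left_join(ann, by = c("chrom", "pos"))
  reg <- purrr::map_dfr(features, function(f) {
    x_tbl <- ann_dnm %>%
      group_by(.data$trio_id) %>%
      summarise(x = sum(.data[[f]] == 1L, na.rm = TRUE), .groups = "drop") %>%
      right_join(per_trio, by = "trio_id") %>%
      mutate(x = tidyr::replace_na(.data$x, 0L))
    res <- tryCatch(fit_rate_regression(x_tbl$x, x_tbl$rate),
                    error = function(e) NULL)
    if (is.null(res)) {
      tibble(feature = f, beta = NA_real_, se = NA_real_,
             p_value = NA_real_, r_squared = NA_real_,
             n_obs = nrow(x_tbl))
    } else {
      tibble(feature = f, beta = res$beta, se = res$se,
             p_value = res$p_value, r_squared = res$r_squared,
             n_obs = res$n_obs)
    }
  })
  p2 <- file.path(out_dir, "context_regression.tsv")
  readr::write_tsv(reg, p2)

  ped <- read_pedigree(file.path(sim_dir, "pedigree.tsv"))
  age <- parental_age_correlation(
    ped, candidates %>% count(.data$trio_id, name = "n_dnm"))
  p3 <- file.path(out_dir, "parental_age_correlation.tsv")
  readr::write_tsv(age, p3)
  c(p1, p2, p3)
}

stage_impact <- function(config, out_dir) {
  candidates <- passing_candidates(out_dir)
  calls_path <- require_input(
    file.path(out_dir, "sim", "predictor_calls.tsv"), "simulate")
  calls <- readr::read_tsv(calls_path, col_types = readr::cols(
    pos = readr::col_double(), .default = readr::col_character()))
  profiles <- calls %>%
    dplyr::semi_join(candidates, by = c("trio_id", "chrom", "pos", "ref",
                                        "alt")) %>%
    normalize_predictor_calls()
  counts <- count_damaging(profiles)
  p1 <- file.path(out_dir, "impact_counts.tsv")
  readr::write_tsv(counts, p1)
  rules <- config$impact$rules %||% c("at_least_6", "at_least_half")
  selected <- purrr::map_dfr(rules, function(r) {
    select_likely_pathogenic(profiles, rule = r,
                             include_gerp = isTRUE(config$impact$include_gerp))
  })
  p2 <- file.path(out_dir, "impact_selected.tsv")
  readr::write_tsv(selected, p2)
  c(p1, p2)
}
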