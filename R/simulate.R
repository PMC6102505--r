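#' Configuration for the synthetic trio-exome simulator
#'
#' Bundles and validates all parameters of the trio-exome generator. The
#' defaults emulate the study design the package targets: 48 trios at mean
#' read depth 38.5 with a germline mutation rate of 2.74e-8 per position per
#' transmitted haplotype per generation, a ~1.5:1 transition:transversion
#' weight among de novo events, and a small indel fraction.
#'
#' @param n_trios Number of trios.
#' @param n_sites Number of simulated callable positions per trio (a
#'   contiguous exome slice shared by all trios).
#' @param mu De novo mutation probability per position per transmitted
#'   haplotype per generation; must lie in (0, 1) (use a tiny positive value
#'   rather than 0; `mu = 0` is accepted and yields no mutations).
#' @param mean_depth Expected per-sample read depth (Poisson mean).
#' @param error_rate Per-read base error probability, in \[0, 0.5).
#' @param maf_alpha,maf_beta Shape parameters of the Beta population
#'   allele-frequency distribution (defaults skewed toward rare variants).
#' @param indel_fraction Fraction of simulated sites carrying an indel
#'   alternate allele (and hence of de novo events that are indels).
#' @param ts_tv_weight Odds that a site's alternate allele is the transition
#'   partner of the reference rather than either transversion; equals the
#'   expected Ts/Tv ratio of de novo substitutions.
#' @param feature_tracks Named list of genomic-context features, each a list
#'   with `coverage` (fraction of the simulated region covered, in \[0, 1\])
#'   and `multiplier` (multiplicative effect on `mu` inside the feature,
#'   > 0). See [default_feature_tracks()].
#' @param mosaic_fraction Fraction of child homozygous-reference sites given
#'   low-allele-balance mosaic-like read support (artifact model for testing
#'   the allele-balance filter); default 0.
#' @param paternal_age_slope Log-linear effect of paternal age (years,
#'   centred at 30) on the per-trio mutation rate; default 0 (no effect).
#' @param clean_evidence If `TRUE`, read evidence is noiseless: fixed even
#'   depth near `mean_depth`, perfectly consistent allele counts, GQ 99.
#' @param predictor_damaging_prob Probability that a deleteriousness
#'   predictor calls an injected DNM damaging/probably damaging in the
#'   simulated predictor table.
#' @param seed Optional random seed applied at the start of generation.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_trios = 48, n_sites = 10000, mu = 2.74e-8,
                              mean_depth = 38.5, error_rate = 0.01,
                              maf_alpha = 0.5, maf_beta = 5,
                              indel_fraction = 3 / 98, ts_tv_weight = 1.5,
                              feature_tracks = default_feature_tracks(),
                              mosaic_fraction = 0, paternal_age_slope = 0,
                              clean_evidence = FALSE,
                              predictor_damaging_prob = 0.3,
                              seed = NULL) {
  stopifnot(
    n_trios >= 1, n_sites >= 1,
    mu >= 0, mu < 1,
    mean_depth > 0,
    error_rate >= 0, error_rate < 0.5,
    maf_alpha > 0, maf_beta > 0,
    indel_fraction >= 0, indel_fraction <= 1,
    ts_tv_weight > 0,
    mosaic_fraction >= 0, mosaic_fraction <= 1,
    predictor_damaging_prob >= 0, predictor_damaging_prob <= 1
  )
  for (f in feature_tracks) {
    stopifnot(f$coverage >= 0, f$coverage <= 1, f$multiplier > 0)
  }
  structure(
    list(n_trios = n_trios, n_sites = n_sites, mu = mu,
         mean_depth = mean_depth, error_rate = error_rate,
         maf_alpha = maf_alpha, maf_beta = maf_beta,
         indel_fraction = indel_fraction, ts_tv_weight = ts_tv_weight,
         feature_tracks = feature_tracks, mosaic_fraction = mosaic_fraction,
         paternal_age_slope = paternal_age_slope,
         clean_evidence = clean_evidence,
         predictor_damaging_prob = predictor_damaging_prob, seed = seed),
    class = "simulation_config"
  )
}

#' Default genomic-context feature tracks for the simulator
#'
#' Coverage fractions are loosely modelled on the exome footprint of
#' ENCODE-style annotations (open chromatin, CpG islands, enhancer/promoter
#' histone marks, deep conservation, non-tissue-specific expression); all
#' rate multipliers default to 1 (no enrichment).
#'
#' @return Named list of `list(coverage, multiplier)` entries for features
#'   `dhs`, `cpg`, `h3k27ac`, `h3k4me1`, `h3k4me3`, `conserved`,
#'   `nonspecific_expression`.
#' @export
default_feature_tracks <- function() {
  list(
    dhs = list(coverage = 0.15, multiplier = 1),
    cpg = list(coverage = 0.05, multiplier = 1),
    h3k27ac = list(coverage = 0.10, multiplier = 1),
    h3k4me1 = list(coverage = 0.10, multiplier = 1),
    h3k4me3 = list(coverage = 0.05, multiplier = 1),
    conserved = list(coverage = 0.10, multiplier = 1),
    nonspecific_expression = list(coverage = 0.50, multiplier = 1)
  )
}

# approximate autosome lengths (Mb) used to spread sites over chromosomes
AUTOSOME_MB <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135, 134,
                 115, 107, 103, 90, 81, 78, 59, 63, 48, 51)

# --- site panel -------------------------------------------------------------

TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
TV_PARTNER1 <- c(A = "C", G = "C", C = "A", T = "A")
TV_PARTNER2 <- c(A = "T", G = "T", C = "G", T = "G")

simulate_sites <- function(config) {
  n <- config$n_sites
  n_chrom <- length(AUTOSOME_MB)
  n_per <- pmax(1, round(n * AUTOSOME_MB / sum(AUTOSOME_MB)))
  # trim/pad to exactly n sites, largest chromosomes absorb the difference
  while (sum(n_per) != n) {
    i <- if (sum(n_per) > n) which.max(n_per) else which.min(n_per)
    n_per[i] <- n_per[i] + sign(n - sum(n_per))
  }
  chrom <- rep(paste0("chr", seq_len(n_chrom)), n_per)
  span <- n_per * 100L  # exome-like site density: one site per ~100 bp
  pos <- unlist(lapply(seq_len(n_chrom), function(i) {
    sort(sample.int(span[i], n_per[i]))
  }))
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  is_indel <- runif(n) < config$indel_fraction
  # substitution partner: transition with odds ts_tv_weight : 1
  w <- config$ts_tv_weight
  take_ts <- runif(n) < w / (w + 1)
  alt <- ifelse(take_ts, TS_PARTNER[ref],
                ifelse(runif(n) < 0.5, TV_PARTNER1[ref], TV_PARTNER2[ref]))
  # indel alleles: insertion (ref A, alt AC) or deletion (ref AC, alt A)
  ins <- runif(n) < 0.5
  extra <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  ref <- ifelse(is_indel & !ins, paste0(ref, extra), ref)
  alt <- ifelse(is_indel, ifelse(ins, paste0(ref, extra), substr(ref, 1, 1)),
                alt)
  sites <- tibble(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    is_indel = is_indel,
    maf = rbeta(n, config$maf_alpha, config$maf_beta)
  )
  sites
}

simulate_feature_tracks <- function(sites, config) {
  spans <- sites %>%
    group_by(.data$chrom) %>%
    summarise(span = n() * 100, .groups = "drop")
  tracks <- list()
  for (fname in names(config$feature_tracks)) {
    cov <- config$feature_tracks[[fname]]$coverage
    iv <- purrr::map_dfr(seq_len(nrow(spans)), function(i) {
      span <- spans$span[i]
      window <- 500L
      n_win <- max(1L, span %/% window)
      take <- which(runif(n_win) < cov)
      if (length(take) == 0) {
        return(tibble(chrom = character(), start = numeric(),
                      end = numeric()))
      }
      tibble(chrom = spans$chrom[i],
             start = (take - 1) * window,
             end = pmin(take * window, span))
    })
    tracks[[fname]] <- interval_track(iv)
  }
  tracks
}

annotate_site_features <- function(sites, tracks) {
  for (fname in names(tracks)) {
    sites[[fname]] <- in_track(tracks[[fname]], sites$chrom, sites$pos)
  }
  sites
}

site_mu_multiplier <- function(sites, config) {
  mult <- rep(1, nrow(sites))
  for (fname in names(config$feature_tracks)) {
    m <- config$feature_tracks[[fname]]$multiplier
    if (m != 1 && fname %in% names(sites)) {
      mult <- mult * ifelse(sites[[fname]], m, 1)
    }
  }
  mult
}

simulate_gerp_scores <- function(sites) {
  # deeply conserved sites score above the >12 threshold, others below it
  tibble(chrom = sites$chrom, pos = sites$pos,
         gerp_score = ifelse(sites$conserved,
                             runif(nrow(sites), 12.1, 20),
                             runif(nrow(sites), -5, 11.9)))
}

simulate_pedigree <- function(config) {
  n <- config$n_trios
  mother_age <- pmin(45, pmax(18, round(stats::rnorm(n, 28, 5))))
  father_age <- pmin(60, pmax(18, mother_age + round(stats::rnorm(n, 2, 3))))
  tibble(
    trio_id = sprintf("trio%02d", seq_len(n)),
    child_id = sprintf("c%02d", seq_len(n)),
    mother_id = sprintf("m%02d", seq_len(n)),
    father_id = sprintf("f%02d", seq_len(n)),
    mother_age = as.numeric(mother_age),
    father_age = as.numeric(father_age)
  )
}

# --- genotypes, transmission and mutation -----------------------------------

draw_hw_genotype <- function(maf) {
  u <- runif(length(maf))
  dplyr::case_when(
    u < (1 - maf)^2 ~ "HomR",
    u < (1 - maf)^2 + 2 * maf * (1 - maf) ~ "Het",
    TRUE ~ "HomA"
  )
}

transmit_allele <- function(gt) {
  # returns 0 (ref) or 1 (alt) transmitted by a parent of genotype gt
  ifelse(gt == "HomR", 0L,
         ifelse(gt == "HomA", 1L, as.integer(runif(length(gt)) < 0.5)))
}

gt_from_dosage <- function(d) c("HomR", "Het", "HomA")[d + 1L]

#' Simulate a full synthetic trio-exome dataset
#'
#' Generates a shared site panel (positions, population allele frequencies,
#' substitution/indel alleles), genomic-context feature tracks, a pedigree
#' with parental ages, and per-trio genotype evidence: parental genotypes are
#' Hardy-Weinberg draws at Beta-distributed allele frequencies, the child
#' receives one allele from each parent, and each transmitted allele mutates
#' (ref to alt, or alt back to ref) with probability `mu` times the site's
#' feature multipliers. Read evidence is Poisson depth with binomial allele
#' sampling under the per-read error model, genotypes are re-called by
#' maximum likelihood and GQ is the phred gap between the two best genotype
#' likelihoods (capped at 99); with `clean_evidence = TRUE` evidence is
#' noiseless. Output is deterministic for a fixed `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param dir Optional directory: when given, writes per-trio VCFs, the
#'   pedigree TSV, BED feature tracks, a conservation-score TSV, the
#'   ground-truth DNM table and a simulated predictor-call table, and adds
#'   their paths to the result.
#' @return A list of class `trio_dataset` with elements `sites`, `tracks`,
#'   `gerp`, `pedigree`, `evidence` (one row per trio-site with true and
#'   called genotypes plus read counts), `ground_truth` (injected DNMs),
#'   `predictor_calls`, `config`, and `paths` when `dir` was supplied.
#' @export
simulate_trio_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  sites <- simulate_sites(config)
  tracks <- simulate_feature_tracks(sites, config)
  sites <- annotate_site_features(sites, tracks)
  sites$mu_multiplier <- site_mu_multiplier(sites, config)
  gerp <- simulate_gerp_scores(sites)
  pedigree <- simulate_pedigree(config)

  n_sites <- nrow(sites)
  evidence_list <- vector("list", config$n_trios)
  truth_list <- vector("list", config$n_trios)

  for (i in seq_len(config$n_trios)) {
    trio <- pedigree[i, ]
    mu_trio <- config$mu *
      exp(config$paternal_age_slope * (trio$father_age - 30))
    mu_site <- pmin(1, mu_trio * sites$mu_multiplier)

    mother_gt <- draw_hw_genotype(sites$maf)
    father_gt <- draw_hw_genotype(sites$maf)
    a_m <- transmit_allele(mother_gt)
    a_f <- transmit_allele(father_gt)
    flip_m <- runif(n_sites) < mu_site
    flip_f <- runif(n_sites) < mu_site
    a_m_mut <- ifelse(flip_m, 1L - a_m, a_m)
    a_f_mut <- ifelse(flip_f, 1L - a_f, a_f)
    child_gt <- gt_from_dosage(a_m_mut + a_f_mut)

    n_flips <- as.integer(flip_m) + as.integer(flip_f)
    hit <- which(n_flips > 0)
    if (length(hit) > 0) {
      truth_list[[i]] <- tibble(
        trio_id = trio$trio_id,
        chrom = sites$chrom[hit], pos = sites$pos[hit],
        ref = sites$ref[hit], alt = sites$alt[hit],
        class = ifelse(sites$is_indel[hit], "indel", "SNV"),
        n_haplotypes_mutated = n_flips[hit],
        direction = ifelse(
          (flip_m[hit] & a_m[hit] == 0L) | (flip_f[hit] & a_f[hit] == 0L),
          "gain_alt", "revert_ref")
      )
    }

    ev <- tibble(
      trio_id = trio$trio_id,
      chrom = sites$chrom, pos = sites$pos,
      ref = sites$ref, alt = sites$alt,
      child_true_gt = child_gt, mother_true_gt = mother_gt,
      father_true_gt = father_gt
    )
    for (m in c("child", "mother", "father")) {
      true_gt <- ev[[paste0(m, "_true_gt")]]
      if (m == "child" && config$mosaic_fraction > 0) {
        mosaic <- true_gt == "HomR" & runif(n_sites) < config$mosaic_fraction
      } else {
        mosaic <- rep(FALSE, n_sites)
      }
      obs <- simulate_read_evidence(true_gt, mosaic, config)
      ev[[paste0(m, "_gt")]] <- obs$gt
      ev[[paste0(m, "_dp")]] <- obs$dp
      ev[[paste0(m, "_ref_reads")]] <- obs$ref_reads
      ev[[paste0(m, "_alt_reads")]] <- obs$alt_reads
      ev[[paste0(m, "_gq")]] <- obs$gq
    }
    evidence_list[[i]] <- ev
  }

  evidence <- dplyr::bind_rows(evidence_list)
  ground_truth <- if (length(purrr::compact(truth_list)) > 0) {
    dplyr::bind_rows(truth_list)
  } else {
    tibble(trio_id = character(), chrom = character(), pos = numeric(),
           ref = character(), alt = character(), class = character(),
           n_haplotypes_mutated = integer(), direction = character())
  }
  predictor_calls <- simulate_predictor_calls(ground_truth, config)

  dataset <- structure(
    list(sites = sites, tracks = tracks, gerp = gerp, pedigree = pedigree,
         evidence = evidence, ground_truth = ground_truth,
         predictor_calls = predictor_calls, config = config),
    class = "trio_dataset"
  )
  if (!is.null(dir)) dataset <- write_trio_dataset(dataset, dir)
  dataset
}

# read-level evidence for one member across all sites
simulate_read_evidence <- function(true_gt, mosaic, config) {
  n <- length(true_gt)
  eps <- max(config$error_rate, 1e-6)  # calling model needs eps > 0
  if (config$clean_evidence) {
    dp <- rep(2L * ceiling(config$mean_depth / 2), n)
    ar <- ifelse(true_gt == "HomR", 0L,
                 ifelse(true_gt == "Het", dp %/% 2L, dp))
    return(list(gt = true_gt, dp = dp, ref_reads = dp - ar, alt_reads = ar,
                gq = rep(99, n)))
  }
  dp <- rpois(n, config$mean_depth)
  p_alt <- ifelse(true_gt == "HomR", config$error_rate,
                  ifelse(true_gt == "Het", 0.5, 1 - config$error_rate))
  p_alt[mosaic] <- 0.15  # somatic-like low allele balance
  ar <- rbinom(n, dp, pmin(pmax(p_alt, 0), 1))
  rr <- dp - ar
  gt <- rep("Missing", n)
  gq <- rep(0, n)
  has_reads <- dp > 0
  if (any(has_reads)) {
    cg <- call_genotype(rr[has_reads], ar[has_reads], eps)
    gt[has_reads] <- cg$call
    gq[has_reads] <- round(cg$gq)
  }
  list(gt = gt, dp = dp, ref_reads = rr, alt_reads = ar, gq = gq)
}

PREDICTOR_NAMES <- c("Polyphen_HDIV", "Polyphen_HVAR", "LRT", "PROVEAN",
                     "CADD", "FATHMM", "MutationTaster", "MutationAssessor",
                     "SIFT", "FathmmMKL_coding")

simulate_predictor_calls <- function(ground_truth, config) {
  if (nrow(ground_truth) == 0) {
    return(tibble(trio_id = character(), chrom = character(), pos = numeric(),
                  ref = character(), alt = character(), predictor = character(),
                  call = character()))
  }
  p_dmg <- config$predictor_damaging_prob
  tidyr::crossing(
    ground_truth %>% select("trio_id", "chrom", "pos", "ref", "alt"),
    predictor = PREDICTOR_NAMES
  ) %>%
    mutate(call = sample(
      c("damaging", "probably_damaging", "tolerated", "unknown"),
      n(), replace = TRUE,
      prob = c(2 * p_dmg / 3, p_dmg / 3, 0.95 - p_dmg, 0.05)))
}

#' Fast genotype-level draw of per-trio DNM counts
#'
#' Samples the number of de novo events injected per trio without generating
#' read evidence: sites are grouped into strata of equal effective mutation
#' rate (base rate times feature multipliers) and each trio's count is the
#' sum of binomial draws over `2 * n_stratum` transmitted haplotype
#' positions. This is the generator's own mutation model, exact at the
#' count level, and is the natural input for large parameter-recovery
#' simulations where evidence is taken as perfect.
#'
#' @param config A [simulation_config()].
#' @return List with `counts` (tibble `trio_id`, `n_dnm`), `n_sites`, and
#'   `haplotype_positions` (`2 * n_sites`, the per-trio denominator under
#'   perfect evidence).
#' @export
simulate_dnm_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  sites <- simulate_sites(config)
  tracks <- simulate_feature_tracks(sites, config)
  sites <- annotate_site_features(sites, tracks)
  mult <- site_mu_multiplier(sites, config)
  strata <- table(mult)
  pedigree <- simulate_pedigree(config)
  counts <- vapply(seq_len(config$n_trios), function(i) {
    mu_trio <- config$mu *
      exp(config$paternal_age_slope * (pedigree$father_age[i] - 30))
    sum(vapply(seq_along(strata), function(s) {
      m <- as.numeric(names(strata)[s])
      rbinom(1, 2L * as.integer(strata[s]), min(1, mu_trio * m))
    }, numeric(1)))
  }, numeric(1))
  list(
    counts = tibble(trio_id = pedigree$trio_id, n_dnm = counts),
    pedigree = pedigree,
    n_sites = config$n_sites,
    haplotype_positions = 2 * config$n_sites
  )
}

# --- reversible indel injection ---------------------------------------------

#' Force a reversible-indel configuration at one site
#'
#' Overwrites the child's evidence at a site where both parents are called
#' homozygous for a non-reference indel allele, making the child a clean
#' homozygous-reference call (all reads supporting the reference, GQ 99).
#' The replaced child evidence is retained so the edit can be reverted with
#' [revert_reversible_indel()], and the ground truth gains a
#' reversible-indel DNM record.
#'
#' @param dataset A `trio_dataset` from [simulate_trio_dataset()].
#' @param trio_id,chrom,pos Site to edit.
#' @return The modified dataset.
#' @export
inject_reversible_indel <- function(dataset, trio_id, chrom, pos) {
  idx <- which(dataset$evidence$trio_id == trio_id &
                 dataset$evidence$chrom == chrom &
                 dataset$evidence$pos == pos)
  if (length(idx) != 1) abort("site not found in dataset evidence")
  row <- dataset$evidence[idx, ]
  if (row$mother_gt != "HomA" || row$father_gt != "HomA") {
    abort("both parents must be called HomA at the site")
  }
  if (nchar(row$ref) == 1 && nchar(row$alt) == 1) {
    abort("site allele is not an indel")
  }
  undo_key <- paste(trio_id, chrom, pos, sep = ":")
  dataset$undo[[undo_key]] <- row
  dp <- max(row$child_dp, 21)
  dataset$evidence[idx, c("child_gt", "child_dp", "child_ref_reads",
                          "child_alt_reads", "child_gq",
                          "child_true_gt")] <-
    list("HomR", dp, dp, 0, 99, "HomR")
  dataset$ground_truth <- dplyr::bind_rows(
    dataset$ground_truth,
    tibble(trio_id = trio_id, chrom = chrom, pos = pos,
           ref = row$ref, alt = row$alt, class = "indel",
           n_haplotypes_mutated = 2L, direction = "revert_ref"))
  dataset
}

#' @rdname inject_reversible_indel
#' @export
revert_reversible_indel <- function(dataset, trio_id, chrom, pos) {
  undo_key <- paste(trio_id, chrom, pos, sep = ":")
  row <- dataset$undo[[undo_key]]
  if (is.null(row)) abort("no reversible-indel edit recorded at this site")
  idx <- which(dataset$evidence$trio_id == trio_id &
                 dataset$evidence$chrom == chrom &
                 dataset$evidence$pos == pos)
  dataset$evidence[idx, names(row)] <- row
  dataset$undo[[undo_key]] <- NULL
  if (length(dataset$undo) == 0) dataset$undo <- NULL
  gt <- dataset$ground_truth
  hit <- which(gt$trio_id == trio_id & gt$chrom == chrom & gt$pos == pos &
                 gt$direction == "revert_ref" & gt$class == "indel")
  if (length(hit) > 0) gt <- gt[-hit[length(hit)], ]
  dataset$ground_truth <- gt
  dataset
}

# --- on-disk serialisation --------------------------------------------------

#' Write a simulated dataset to standard file formats
#'
#' @param dataset A `trio_dataset`.
#' @param dir Output directory (created if needed).
#' @return The dataset with a `paths` element listing every written file.
#' @export
write_trio_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "tracks"), showWarnings = FALSE)
  paths <- list(pedigree = file.path(dir, "pedigree.tsv"))
  write_pedigree(dataset$pedigree, paths$pedigree)

  paths$vcf <- character(0)
  member_cols <- paste0(rep(c("child", "mother", "father"), each = 5),
                        c("_gt", "_dp", "_ref_reads", "_alt_reads", "_gq"))
  for (i in seq_len(nrow(dataset$pedigree))) {
    trio <- dataset$pedigree[i, ]
    rec <- dataset$evidence %>%
      filter(.data$trio_id == trio$trio_id) %>%
      select(all_of(c("chrom", "pos", "ref", "alt", member_cols)))
    vcf_path <- file.path(dir, paste0(trio$trio_id, ".vcf"))
    write_trio_vcf(rec, trio, vcf_path)
    paths$vcf <- c(paths$vcf, setNames(vcf_path, trio$trio_id))
  }

  paths$tracks <- character(0)
  for (fname in names(dataset$tracks)) {
    p <- file.path(dir, "tracks", paste0(fname, ".bed"))
    write_interval_track(dataset$tracks[[fname]], p)
    paths$tracks <- c(paths$tracks, setNames(p, fname))
  }
  paths$gerp <- file.path(dir, "gerp_scores.tsv")
  readr::write_tsv(dataset$gerp, paths$gerp)
  paths$ground_truth <- file.path(dir, "ground_truth.tsv")
  readr::write_tsv(dataset$ground_truth, paths$ground_truth)
  paths$predictor_calls <- file.path(dir, "predictor_calls.tsv")
  readr::write_tsv(dataset$predictor_calls, paths$predictor_calls)
  dataset$paths <- paths
  dataset
}
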