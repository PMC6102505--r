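gt_levels <- c("HomR", "Het", "HomA")

all_triples <- function(ref = "A", alt = "G") {
  grid <- expand.grid(child = gt_levels, mother = gt_levels,
                      father = gt_levels, stringsAsFactors = FALSE)
  purrr::pmap_dfr(grid, function(child, mother, father) {
    trio_record(child, mother, father, ref = ref, alt = alt,
                pos = 1000 + nrow(grid))
  }) %>%
    dplyr::mutate(pos = dplyr::row_number())
}

test_that("exactly the three non-Mendelian configurations yield candidates", {
  snv <- detect_candidates(all_triples("A", "G"))
  expect_equal(nrow(snv), 2)
  expect_setequal(snv$config,
                  c("het_child_homref_parents", "het_child_homalt_parents"))
  expect_true(all(snv$variant_class == "SNV"))

  indel <- detect_candidates(all_triples("A", "AC"))
  expect_equal(nrow(indel), 3)
  expect_setequal(indel$config,
                  c("het_child_homref_parents", "het_child_homalt_parents",
                    "reversible_indel"))
  expect_true(all(indel$variant_class == "indel"))
  rev <- indel[indel$config == "reversible_indel", ]
  expect_equal(rev$child_gt, "HomR")
  expect_equal(rev$mother_gt, "HomA")

  # configurations explained by inheritance never fire
  inherited <- detect_candidates(
    trio_record("Het", "Het", "HomR"))
  expect_equal(nrow(inherited), 0)
})

test_that("detection requires complete genotypes", {
  expect_error(detect_candidates(trio_record("Het", "Missing", "HomR")),
               "Missing")
})

test_that("substitutions classify by purine/pyrimidine exchange", {
  expect_equal(classify_substitution("A", "G"), "transition")
  expect_equal(classify_substitution("C", "T"), "transition")
  expect_equal(classify_substitution("A", "T"), "transversion")
  expect_equal(classify_substitution("G", "C"), "transversion")
  expect_true(is.na(classify_substitution("AC", "A")))
  expect_error(classify_substitution("A", "N"), "non-ACGT")
})

test_that("filters honour the exact threshold boundaries", {
  thr <- filter_thresholds()
  base <- trio_record("Het", "HomR", "HomR")

  low_gq <- trio_record("Het", "HomR", "HomR", child_gq = 49)
  out <- apply_filters(detect_candidates(low_gq), thr)
  expect_equal(out$filter_status, "min_gq")
  out <- apply_filters(detect_candidates(trio_record("Het", "HomR", "HomR",
                                                     child_gq = 50)), thr)
  expect_equal(out$filter_status, "pass")

  # depth 20 is not "> 20"
  d20 <- trio_record("Het", "HomR", "HomR", dp = 20)
  expect_equal(apply_filters(detect_candidates(d20), thr)$filter_status,
               "min_depth")
  d21 <- trio_record("Het", "HomR", "HomR", dp = 21, child_reads = c(11, 10))
  expect_equal(apply_filters(detect_candidates(d21), thr)$filter_status,
               "pass")

  # allele-balance endpoints are inclusive for heterozygotes
  ab30 <- trio_record("Het", "HomR", "HomR", child_reads = c(28, 12))
  expect_equal(apply_filters(detect_candidates(ab30), thr)$filter_status,
               "pass")
  ab70 <- trio_record("Het", "HomR", "HomR", child_reads = c(12, 28))
  expect_equal(apply_filters(detect_candidates(ab70), thr)$filter_status,
               "pass")
  ab_low <- trio_record("Het", "HomR", "HomR", child_reads = c(30, 10))
  expect_equal(apply_filters(detect_candidates(ab_low), thr)$filter_status,
               "allele_balance")

  # a homozygous parent with mid-range allele balance betrays a missed het
  bad_parent <- trio_record("Het", "HomR", "HomR",
                            mother_reads = c(24, 16))
  expect_equal(apply_filters(detect_candidates(bad_parent), thr)$filter_status,
               "allele_balance")
  expect_equal(apply_filters(detect_candidates(base), thr)$filter_status,
               "pass")
})

test_that("filter pass-rate is monotone in the GQ and depth thresholds", {
  cfg <- simulation_config(n_trios = 4, n_sites = 5000, mu = 2e-3, seed = 21)
  ds <- simulate_trio_dataset(cfg)
  cands <- ds$evidence %>%
    drop_missing_records() %>%
    detect_candidates()
  pass_at <- function(gq, depth) {
    thr <- filter_thresholds(min_gq = gq, min_depth_exclusive = depth)
    sum(apply_filters(cands, thr)$filter_status == "pass")
  }
  gq_series <- vapply(c(0, 20, 50, 80, 99), pass_at, numeric(1), depth = 20)
  expect_true(all(diff(gq_series) <= 0))
  depth_series <- vapply(c(0, 10, 20, 30, 40), pass_at, numeric(1),
                         gq = 50)
  expect_true(all(diff(depth_series) <= 0))
})

test_that("clean error-free data with no injected DNMs yields no passing candidates", {
  cfg <- simulation_config(n_trios = 3, n_sites = 4000, mu = 0,
                           error_rate = 0, seed = 22)
  ds <- simulate_trio_dataset(cfg)
  cands <- ds$evidence %>%
    drop_missing_records() %>%
    detect_candidates() %>%
    apply_filters()
  expect_equal(sum(cands$filter_status == "pass"), 0)
})

test_that("every detectable ground-truth DNM is recovered at the genotype level", {
  cfg <- simulation_config(n_trios = 4, n_sites = 5000, mu = 1e-3,
                           clean_evidence = TRUE, seed = 23)
  ds <- simulate_trio_dataset(cfg)
  cands <- ds$evidence %>%
    drop_missing_records() %>%
    detect_candidates()
  detectable <- ds$ground_truth %>%
    dplyr::inner_join(ds$evidence,
                      by = c("trio_id", "chrom", "pos", "ref", "alt")) %>%
    dplyr::filter(
      (child_gt == "Het" & mother_gt == "HomR" & father_gt == "HomR") |
        (child_gt == "Het" & mother_gt == "HomA" & father_gt == "HomA") |
        (child_gt == "HomR" & mother_gt == "HomA" & father_gt == "HomA" &
           (nchar(ref) != 1 | nchar(alt) != 1)))
  expect_gt(nrow(detectable), 0)
  found <- detectable %>%
    dplyr::anti_join(cands, by = c("trio_id", "chrom", "pos"))
  expect_equal(nrow(found), 0)
})

test_that("outlier trios are flagged by the exact Poisson upper tail", {
  counts <- tibble::tibble(trio_id = c("t1", "t2", "t3", "t4"),
                           n_dnm = c(1, 2, 0, 113))
  flagged <- flag_outlier_trios(counts, expected_mean = 2)
  expect_equal(flagged$trio_id, "t4")

  none <- flag_outlier_trios(
    tibble::tibble(trio_id = paste0("t", 1:4), n_dnm = c(1, 2, 0, 3)),
    expected_mean = 2)
  expect_equal(nrow(none), 0)

  # an exact tail sum confirms that 16 events is beyond the 1e-6 tail of
  # Poisson(2)
  tail16 <- sum(dpois(16:200, 2))
  expect_lt(tail16, 1e-6)
  one16 <- flag_outlier_trios(
    tibble::tibble(trio_id = "t21", n_dnm = 16), expected_mean = 2)
  expect_equal(one16$trio_id, "t21")
  expect_equal(one16$p_value, tail16, tolerance = 1e-12)
})
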