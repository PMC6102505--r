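test_that("context annotation flags membership and the conservation cut-off", {
  tracks <- list(
    dhs = interval_track(tibble::tibble(chrom = "chr1", start = 99,
                                        end = 200)),
    cpg = interval_track(tibble::tibble(chrom = "chr1", start = 0,
                                        end = 50)))
  sites <- tibble::tibble(chrom = "chr1", pos = c(10, 100, 150, 300))
  scores <- tibble::tibble(chrom = "chr1", pos = c(10, 100, 150, 300),
                           gerp_score = c(15, 12, 11.9, NA))
  ann <- annotate_context(sites, tracks, scores)
  expect_equal(ann$dhs, c(0L, 1L, 1L, 0L))
  expect_equal(ann$cpg, c(1L, 0L, 0L, 0L))
  # absent tracks give all-zero flags; expression defaults to specific
  expect_equal(ann$h3k27ac, rep(0L, 4))
  expect_equal(ann$expression, rep("specific", 4))
  # score of exactly 12 is non-conserved; missing stays NA
  expect_equal(ann$conserved, c(1L, 0L, 0L, NA_integer_))
})

test_that("annotation agrees with a linear-scan oracle on random sites", {
  set.seed(6)
  iv <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 500, replace = TRUE),
                       start = sample.int(20000, 500, replace = TRUE))
  iv$end <- iv$start + sample.int(200, 500, replace = TRUE)
  tracks <- list(dhs = interval_track(iv))
  sites <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 2000,
                                         replace = TRUE),
                          pos = sample.int(21000, 2000, replace = TRUE))
  ann <- annotate_context(sites, tracks)
  expect_equal(ann$dhs,
               as.integer(interval_oracle(iv, sites$chrom, sites$pos)))
})

test_that("stratified rates use stratum-restricted numerators and denominators", {
  ann <- tibble::tibble(chrom = "chr1", pos = 1:100,
                        dhs = as.integer(1:100 <= 40))
  callable <- tidyr::crossing(trio_id = c("t1", "t2"),
                              tibble::tibble(chrom = "chr1", pos = 1:100)) %>%
    dplyr::mutate(p_snv = 0.5)
  cands <- tibble::tibble(trio_id = c("t1", "t1", "t2"), chrom = "chr1",
                          pos = c(5, 10, 50))
  inside <- stratified_rate(cands, callable, ann, "dhs", 1L)
  expect_equal(inside$n_dnm, c(2L, 0L))
  expect_equal(inside$denominator, rep(2 * 0.5 * 40, 2))
  expect_equal(inside$rate, c(2, 0) / 40)
  outside <- stratified_rate(cands, callable, ann, "dhs", 0L)
  expect_equal(outside$n_dnm, c(0L, 1L))
  # counts are conserved across the partition
  expect_equal(sum(inside$n_dnm) + sum(outside$n_dnm), nrow(cands))

  # a stratum with no callable sites excludes every trio
  empty <- stratified_rate(cands, callable,
                           ann %>% dplyr::mutate(dhs = 0L), "dhs", 1L)
  expect_equal(nrow(empty), 0)
  expect_error(stratified_rate(cands, callable, ann, "nope", 1L),
               "unknown context feature")
})

test_that("rate regression matches the closed-form normal equations", {
  # perfect line (summary.lm warns about the zero-residual fit)
  fit <- suppressWarnings(fit_rate_regression(1:5, 2 * (1:5) + 1))
  expect_equal(fit$beta, 2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_lt(fit$se, 1e-10)

  # flat response
  flat <- fit_rate_regression(1:5, rep(3, 5))
  expect_equal(flat$beta, 0)
  expect_equal(flat$r_squared, 0)

  # fixed 10-point fixture against a from-scratch OLS evaluation
  x <- c(1.2, 2.5, 3.1, 4.8, 5.0, 6.3, 7.7, 8.1, 9.9, 11.4)
  y <- c(2.1, 2.9, 4.2, 4.1, 5.8, 5.9, 7.4, 8.3, 9.1, 10.9)
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
  alpha <- mean(y) - beta * mean(x)
  rss <- sum((y - alpha - beta * x)^2)
  tss <- sum((y - mean(y))^2)
  se <- sqrt(rss / (n - 2) / sxx)
  p <- 2 * pt(-abs(beta / se), df = n - 2)
  fit <- fit_rate_regression(x, y)
  expect_equal(fit$beta, beta, tolerance = 1e-12)
  expect_equal(fit$se, se, tolerance = 1e-12)
  expect_equal(fit$p_value, p, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1 - rss / tss, tolerance = 1e-12)
  expect_equal(tidy(fit)$estimate, beta)
  expect_equal(glance(fit)$r_squared, 1 - rss / tss)

  expect_error(fit_rate_regression(rep(1, 5), 1:5), "zero variance")
  expect_error(fit_rate_regression(1:2, 1:2), "at least 3")
})

test_that("parental-age correlation reports Pearson R per parent", {
  trios <- tibble::tibble(trio_id = paste0("t", 1:8),
                          mother_age = c(22, 25, 27, 30, 31, 33, 36, 40),
                          father_age = c(24, 26, 29, 31, 33, 36, 38, 44))
  counts <- tibble::tibble(trio_id = paste0("t", 1:8),
                           n_dnm = c(0, 1, 1, 2, 2, 3, 3, 5))
  res <- parental_age_correlation(trios, counts)
  expect_equal(res$parent, c("mother", "father"))
  expect_gt(res$estimate[res$parent == "father"], 0.9)

  flat <- parental_age_correlation(
    trios, counts %>% dplyr::mutate(n_dnm = 2L))
  expect_equal(flat$estimate, c(0, 0))

  no_ages <- trios %>%
    dplyr::mutate(mother_age = NA_real_, father_age = NA_real_)
  expect_error(parental_age_correlation(no_ages, counts), "parental ages")
})

test_that("a strong paternal-age effect is recovered in sign", {
  signs <- vapply(1:40, function(s) {
    cfg <- simulation_config(n_trios = 25, n_sites = 5000, mu = 2e-3,
                             paternal_age_slope = 0.08, seed = 6000 + s)
    sim <- simulate_dnm_counts(cfg)
    res <- parental_age_correlation(sim$pedigree, sim$counts)
    sign(res$estimate[res$parent == "father"])
  }, numeric(1))
  expect_gte(mean(signs == 1), 0.95)
})
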