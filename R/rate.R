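#' Genotype posterior probabilities from read counts
#'
#' Computes posterior probabilities over the three diploid genotypes
#' (`HomR`, `Het`, `HomA`) from observed reference and alternate read counts
#' under a simple per-read error model with uniform genotype prior. With `r`
#' reference and `a` alternate reads and per-read error probability `eps`,
#' the likelihoods are `(1 - eps)^r * eps^a` (HomR), `0.5^(r + a)` (Het) and
#' `eps^r * (1 - eps)^a` (HomA); the shared binomial coefficient cancels on
#' normalisation. Computation is in log space for numerical stability.
#'
#' @param ref_reads,alt_reads Non-negative read-count vectors (recycled to a
#'   common length); each pair must have at least one informative read.
#' @param error_rate Per-read base error probability `eps`, in (0, 0.5).
#' @return Tibble with columns `p_homr`, `p_het`, `p_homa` summing to 1 per
#'   row.
#' @export
#' @examples
#' genotype_posteriors(30, 0)        # clean homozygous reference
#' genotype_posteriors(15, 15)       # balanced heterozygote
genotype_posteriors <- function(ref_reads, alt_reads, error_rate = 0.01) {
  stopifnot(error_rate > 0, error_rate < 0.5)
  n <- max(length(ref_reads), length(alt_reads))
  r <- rep_len(ref_reads, n)
  a <- rep_len(alt_reads, n)
  if (any(r < 0 | a < 0)) abort("negative read counts")
  if (any(r + a == 0)) abort("zero informative reads: posterior undefined")
  ll <- genotype_loglik(r, a, error_rate)
  mx <- pmax(ll$homr, ll$het, ll$homa)
  w_homr <- exp(ll$homr - mx)
  w_het <- exp(ll$het - mx)
  w_homa <- exp(ll$homa - mx)
  z <- w_homr + w_het + w_homa
  tibble(p_homr = w_homr / z, p_het = w_het / z, p_homa = w_homa / z)
}

# log-likelihoods of the three genotypes given read counts
genotype_loglik <- function(r, a, error_rate) {
  list(
    homr = r * log1p(-error_rate) + a * log(error_rate),
    het = (r + a) * log(0.5),
    homa = r * log(error_rate) + a * log1p(-error_rate)
  )
}

# maximum-likelihood genotype call and phred-scaled quality
# (10/log(10) * gap between best and second-best log-likelihood, capped at 99)
call_genotype <- function(r, a, error_rate) {
  ll <- genotype_loglik(r, a, error_rate)
  m <- cbind(HomR = ll$homr, Het = ll$het, HomA = ll$homa)
  best <- max.col(m, ties.method = "first")
  ord <- apply(m, 1, function(x) sort(x, decreasing = TRUE)[1:2])
  gq <- pmin(99, (ord[1, ] - ord[2, ]) * 10 / log(10))
  list(call = colnames(m)[best], gq = gq)
}

#' Probability that a true heterozygote is called and passes filters
#'
#' For a child site of given read depth, computes the probability that a true
#' heterozygous genotype would be detected as a filtered heterozygous call:
#' alternate reads are Binomial(depth, 0.5), and an outcome counts when the
#' maximum-likelihood genotype call is `Het`, its genotype quality meets
#' `min_gq`, and the allele balance lies inside the allele-balance interval.
#' Depths at or below the depth threshold return 0.
#'
#' @param depth Non-negative integer read depth (vectorised).
#' @param thresholds A [filter_thresholds()] object.
#' @param error_rate Per-read error probability used in the genotype-calling
#'   model.
#' @return Numeric vector of detection probabilities in \[0, 1\].
#' @export
het_detection_probability <- function(depth, thresholds = filter_thresholds(),
                                      error_rate = 0.01) {
  detection_probability(depth, target = "Het", p_alt = 0.5,
                        thresholds = thresholds, error_rate = error_rate)
}

#' @rdname het_detection_probability
#' @details `homref_detection_probability()` is the analogous quantity for
#'   the reversible-indel configuration: the probability that a true
#'   homozygous-reference child (alternate reads Binomial(depth,
#'   `error_rate`)) is called `HomR` with passing genotype quality and an
#'   allele balance below `ab_low`.
#' @export
homref_detection_probability <- function(depth,
                                         thresholds = filter_thresholds(),
                                         error_rate = 0.01) {
  detection_probability(depth, target = "HomR", p_alt = error_rate,
                        thresholds = thresholds, error_rate = error_rate)
}

detection_probability <- function(depth, target, p_alt, thresholds,
                                  error_rate) {
  stopifnot(inherits(thresholds, "filter_thresholds"),
            all(depth >= 0), error_rate > 0, error_rate < 0.5)
  vapply(depth, function(d) {
    if (d <= thresholds$min_depth_exclusive) return(0)
    k <- 0:d
    cg <- call_genotype(d - k, k, error_rate)
    ab <- k / d
    ab_ok <- if (target == "Het") {
      ab >= thresholds$ab_low & ab <= thresholds$ab_high
    } else if (target == "HomR") {
      ab < thresholds$ab_low
    } else {
      ab > thresholds$ab_high
    }
    ok <- cg$call == target & cg$gq >= thresholds$min_gq & ab_ok
    sum(dbinom(k[ok], d, p_alt))
  }, numeric(1))
}

#' Per-site callable probability for a trio
#'
#' For each trio site record, computes the probability that a de novo event
#' there would have been observed, combining the parental genotype posteriors
#' with the child's detection probability:
#'
#' * `p_snv = (P(M = HomR) * P(F = HomR) + P(M = HomA) * P(F = HomA)) *
#'    d_het(child depth)` — the two single-nucleotide de novo
#'   configurations;
#' * `p_indel = P(M = HomA) * P(F = HomA) * d_homref(child depth)` — the
#'   reversible-indel configuration.
#'
#' Sites where any member's depth fails the strict depth filter contribute
#' zero (a candidate there could never pass the filters), so low-coverage
#' sites add nothing to the rate denominator.
#'
#' @param records Trio site record tibble (complete genotypes; see
#'   [drop_missing_records()]).
#' @param error_rate Per-read error probability.
#' @param thresholds A [filter_thresholds()] object.
#' @return `records` keys (`trio_id` if present, `chrom`, `pos`) with
#'   `p_snv` and `p_indel` columns.
#' @export
site_callable_probability <- function(records,
                                      error_rate = 0.01,
                                      thresholds = filter_thresholds()) {
  keys <- intersect(c("trio_id", "chrom", "pos"), names(records))
  out <- records[, keys, drop = FALSE]
  if (nrow(records) == 0) {
    out$p_snv <- numeric(0)
    out$p_indel <- numeric(0)
    return(as_tibble(out))
  }
  mom <- genotype_posteriors(records$mother_ref_reads, records$mother_alt_reads,
                             error_rate)
  dad <- genotype_posteriors(records$father_ref_reads, records$father_alt_reads,
                             error_rate)
  # child detection probabilities: depth-only, so memoise over unique depths
  dch <- as.integer(records$child_dp)
  ud <- sort(unique(dch))
  d_het <- het_detection_probability(ud, thresholds, error_rate)[match(dch, ud)]
  d_homr <- homref_detection_probability(ud, thresholds,
                                         error_rate)[match(dch, ud)]
  deep_enough <- records$mother_dp > thresholds$min_depth_exclusive &
    records$father_dp > thresholds$min_depth_exclusive
  out$p_snv <- ifelse(deep_enough,
                      (mom$p_homr * dad$p_homr + mom$p_homa * dad$p_homa) * d_het,
                      0)
  out$p_indel <- ifelse(deep_enough, mom$p_homa * dad$p_homa * d_homr, 0)
  as_tibble(out)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Computes the Wilson score interval for `x` successes in `n` trials,
#' obtained by inverting the normal approximation to the score test. The
#' interval is well behaved for rare events (bounds stay inside \[0, 1\] and
#' the lower bound is 0 only when `x = 0`), which suits per-position mutation
#' rates where `x` is tens of events and `n` is billions of haplotype
#' positions.
#'
#' @param x Number of successes (`0 <= x <= n`).
#' @param n Number of trials (`> 0`).
#' @param conf_level Confidence level; default 0.95.
#' @return Named numeric vector `c(low, high)`.
#' @export
#' @examples
#' wilson_interval(95, round(95 / 2.74e-8))
wilson_interval <- function(x, n, conf_level = 0.95) {
  stopifnot(length(x) == 1, length(n) == 1, n > 0)
  if (x < 0 || x > n) abort("x must lie in [0, n]")
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  centre <- (x + z^2 / 2) / (n + z^2)
  half <- z * sqrt(x * (1 - p) + z^2 / 4) / (n + z^2)
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Estimate the per-position-per-generation mutation rate
#'
#' Combines per-trio DNM counts with callable-probability totals into the
#' rate estimator `sum(n_i) / (2 * sum_i sum_j P_ji)`: the factor 2 converts
#' callable positions into transmitted haplotype positions, so the estimate
#' is the probability of a de novo event per position per generation. The
#' 95% confidence interval treats the observed mutations as binomial
#' successes over `round(2 * sum(P))` haplotype-position trials and applies
#' the Wilson score interval.
#'
#' @param per_trio_counts Numeric vector of per-trio DNM counts `n_i`, or a
#'   tibble with columns `trio_id` and `n_dnm`.
#' @param callable_sums Numeric vector of per-trio callable-probability sums
#'   `sum_j P_ji` (same length/order as the counts), or a single total.
#' @param conf_level Confidence level for the Wilson interval.
#' @return Object of class `rate_estimate` with fields `n_mutations`,
#'   `denominator` (haplotype positions, `2 * sum(P)`), `rate`, `ci_low`,
#'   `ci_high`, `n_trios`, `conf_level`. Supports `tidy()` and `glance()`.
#' @export
#' @examples
#' estimate_rate(c(1, 1), c(50, 50))   # rate 0.01
estimate_rate <- function(per_trio_counts, callable_sums, conf_level = 0.95) {
  if (is.data.frame(per_trio_counts)) {
    n_trios <- nrow(per_trio_counts)
    counts <- per_trio_counts$n_dnm
  } else {
    n_trios <- length(per_trio_counts)
    counts <- per_trio_counts
  }
  stopifnot(all(counts >= 0), all(callable_sums >= 0))
  total_p <- sum(callable_sums)
  if (total_p <= 0) abort("zero callable-probability denominator")
  x <- sum(counts)
  denom <- 2 * total_p
  rate <- x / denom
  ci <- wilson_interval(x, round(denom), conf_level)
  structure(
    list(n_mutations = x, denominator = denom, rate = rate,
         ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
         n_trios = n_trios, conf_level = conf_level),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "De novo rate: %.3g per position per generation\n%d mutations over %.4g haplotype positions (%d trios)\n%.0f%% CI (Wilson): [%.3g, %.3g]\n",
    x$rate, x$n_mutations, x$denominator, x$n_trios,
    100 * x$conf_level, x$ci_low, x$ci_high))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a rate estimate
#'
#' @param x A `rate_estimate` object.
#' @param ... Unused.
#' @return One-row tibble with `estimate`, `conf_low`, `conf_high`,
#'   `n_mutations`, `denominator`, `n_trios`.
#' @method tidy rate_estimate
#' @export
tidy.rate_estimate <- function(x, ...) {
  tibble(estimate = x$rate, conf_low = x$ci_low, conf_high = x$ci_high,
         n_mutations = x$n_mutations, denominator = x$denominator,
         n_trios = x$n_trios)
}

#' @rdname tidy.rate_estimate
#' @method glance rate_estimate
#' @export
glance.rate_estimate <- function(x, ...) tidy(x)
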