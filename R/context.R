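#' Annotate sites with binary genomic-context features
#'
#' Attaches the binary context flags used for stratified rates and
#' regression: membership in DNase hypersensitive sites, CpG islands and the
#' three histone-mark tracks; a conservation flag from the GERP++-style
#' score (`conserved = 1` iff score strictly greater than 12; a score of
#' exactly 12 is non-conserved, and a missing score leaves the flag `NA`);
#' and expression specificity (`"nonspecific"` inside the
#' non-specific-expression track, `"specific"` outside).
#'
#' @param sites Tibble with `chrom` and `pos` (1-based) columns; extra
#'   columns are preserved.
#' @param tracks Named list of [interval_track()] objects; recognised names
#'   are `dhs`, `cpg`, `h3k27ac`, `h3k4me1`, `h3k4me3` and
#'   `nonspecific_expression` (missing tracks yield an all-zero flag).
#' @param scores Optional tibble with `chrom`, `pos`, `gerp_score`.
#' @param gerp_threshold Conservation cut-off on the score (strict `>`).
#' @return `sites` with integer columns `dhs`, `cpg`, `h3k27ac`, `h3k4me1`,
#'   `h3k4me3`, `conserved` (0/1, `NA` when the score is missing),
#'   `gerp_score`, and a character `expression` column.
#' @export
annotate_context <- function(sites, tracks, scores = NULL,
                             gerp_threshold = 12) {
  out <- as_tibble(sites)
  for (fname in c("dhs", "cpg", "h3k27ac", "h3k4me1", "h3k4me3")) {
    out[[fname]] <- if (fname %in% names(tracks)) {
      as.integer(in_track(tracks[[fname]], out$chrom, out$pos))
    } else {
      0L
    }
  }
  out$expression <- if ("nonspecific_expression" %in% names(tracks)) {
    ifelse(in_track(tracks$nonspecific_expression, out$chrom, out$pos),
           "nonspecific", "specific")
  } else {
    "specific"
  }
  if (!is.null(scores)) {
    out <- out %>%
      left_join(scores %>% select("chrom", "pos", "gerp_score"),
                by = c("chrom", "pos"))
  } else if (!"gerp_score" %in% names(out)) {
    out$gerp_score <- NA_real_
  }
  out$conserved <- ifelse(is.na(out$gerp_score), NA_integer_,
                          as.integer(out$gerp_score > gerp_threshold))
  out
}

#' Per-trio DNM rate within a context stratum
#'
#' Restricts both the numerator (candidate DNMs) and the denominator
#' (callable-probability mass) to sites where `feature == level` and returns
#' the per-trio rate `n / (2 * sum(P))`. Trios whose stratum denominator is
#' zero are excluded.
#'
#' @param candidates Passing candidate tibble with `trio_id`, `chrom`,
#'   `pos`.
#' @param callable Callable-probability tibble (`trio_id`, `chrom`, `pos`,
#'   `p_snv`) as from [site_callable_probability()].
#' @param annotations Site annotation tibble (`chrom`, `pos`, plus feature
#'   columns) as from [annotate_context()].
#' @param feature Name of the annotation column to stratify on.
#' @param level Stratum value (e.g. `1L`, `0L`, `"nonspecific"`).
#' @return Tibble with `trio_id`, `n_dnm`, `denominator`, `rate`.
#' @export
stratified_rate <- function(candidates, callable, annotations, feature,
                            level) {
  if (!feature %in% names(annotations)) {
    abort(paste0("unknown context feature: ", feature))
  }
  in_stratum <- annotations[!is.na(annotations[[feature]]) &
                              annotations[[feature]] == level,
                            c("chrom", "pos")]
  denom <- callable %>%
    inner_join(in_stratum, by = c("chrom", "pos")) %>%
    group_by(.data$trio_id) %>%
    summarise(denominator = 2 * sum(.data$p_snv), .groups = "drop") %>%
    filter(.data$denominator > 0)
  nums <- candidates %>%
    inner_join(in_stratum, by = c("chrom", "pos")) %>%
    count(.data$trio_id, name = "n_dnm")
  denom %>%
    left_join(nums, by = "trio_id") %>%
    mutate(n_dnm = tidyr::replace_na(.data$n_dnm, 0L),
           rate = .data$n_dnm / .data$denominator) %>%
    select("trio_id", "n_dnm", "denominator", "rate")
}

#' Single-predictor linear regression of DNM rate on a context covariate
#'
#' Fits ordinary least squares `y = alpha + beta * x` (via `lm()`) and
#' reports the slope with its standard error, the two-sided t-test p-value
#' on the slope, and the coefficient of determination — the per-feature
#' summary used when relating per-trio DNM rates to counts of annotated
#' positions.
#'
#' @param x Numeric predictor (e.g. per-trio count of feature-carrying DNM
#'   positions).
#' @param y Numeric response (e.g. per-trio DNM rate).
#' @return Object of class `rate_regression` with `beta`, `se`, `p_value`,
#'   `r_squared`, `intercept`, `n_obs` and the underlying `fit`. Supports
#'   `tidy()` and `glance()`.
#' @export
fit_rate_regression <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("need at least 3 complete observations")
  if (stats::var(x) == 0) abort("predictor has zero variance")
  if (stats::var(y) == 0) {
    # response is flat: slope 0 explains everything there is to explain
    return(structure(
      list(beta = 0, se = 0, p_value = 1, r_squared = 0,
           intercept = y[1], n_obs = length(x), fit = NULL),
      class = "rate_regression"))
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  structure(
    list(beta = unname(coef(fit)[2]),
         se = sm$coefficients[2, "Std. Error"],
         p_value = sm$coefficients[2, "Pr(>|t|)"],
         r_squared = sm$r.squared,
         intercept = unname(coef(fit)[1]),
         n_obs = length(x),
         fit = fit),
    class = "rate_regression"
  )
}

#' @export
print.rate_regression <- function(x, ...) {
  cat(sprintf("DNM-rate regression (n = %d)\n  beta = %.4g +/- %.4g, p = %.3g, R^2 = %.3f\n",
              x$n_obs, x$beta, x$se, x$p_value, x$r_squared))
  invisible(x)
}

#' Tidy a DNM-rate regression
#'
#' @param x A `rate_regression` object.
#' @param ... Unused.
#' @return One-row tibble with `estimate` (slope), `std_error`, `p_value`.
#' @method tidy rate_regression
#' @export
tidy.rate_regression <- function(x, ...) {
  tibble(term = "x", estimate = x$beta, std_error = x$se,
         p_value = x$p_value)
}

#' @rdname tidy.rate_regression
#' @method glance rate_regression
#' @export
glance.rate_regression <- function(x, ...) {
  tibble(r_squared = x$r_squared, n_obs = x$n_obs)
}

#' Correlation of per-trio DNM counts with parental ages
#'
#' Pearson correlation (with two-sided p-value) between each trio's DNM
#' count and the corresponding parent's age at the child's birth; trios
#' with a missing age are dropped per parent.
#'
#' @param trios Pedigree tibble with `trio_id`, `mother_age`, `father_age`.
#' @param per_trio_counts Tibble with `trio_id` and `n_dnm`.
#' @return Tibble with one row per parent: `parent`, `estimate`, `p_value`,
#'   `n`.
#' @export
parental_age_correlation <- function(trios, per_trio_counts) {
  joined <- trios %>%
    left_join(per_trio_counts, by = "trio_id") %>%
    mutate(n_dnm = tidyr::replace_na(.data$n_dnm, 0L))
  res <- purrr::map_dfr(c(mother = "mother_age", father = "father_age"),
                        .id = "parent", function(col) {
    keep <- !is.na(joined[[col]])
    if (sum(keep) < 3) {
      return(tibble(estimate = NA_real_, p_value = NA_real_,
                    n = sum(keep)))
    }
    if (stats::sd(joined[[col]][keep]) == 0 ||
          stats::sd(joined$n_dnm[keep]) == 0) {
      # a flat margin carries no association signal
      return(tibble(estimate = 0, p_value = 1, n = sum(keep)))
    }
    ct <- cor.test(joined[[col]][keep], joined$n_dnm[keep],
                   method = "pearson")
    tibble(estimate = unname(ct$estimate), p_value = ct$p.value,
           n = sum(keep))
  })
  if (all(is.na(res$estimate))) abort("no trios with recorded parental ages")
  res
}
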