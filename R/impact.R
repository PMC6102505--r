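#' Default normalisation table for predictor call codes
#'
#' Maps the one-letter (ANNOVAR-style) and spelled-out codes emitted by
#' deleteriousness predictors onto the package's call vocabulary
#' (`damaging`, `probably_damaging`, `tolerated`, `unknown`). Pass an edited
#' copy to [normalize_predictor_calls()] to accommodate other tools.
#'
#' @return Tibble with `code` and `call` columns.
#' @export
default_call_mapping <- function() {
  tibble(
    code = c("D", "A", "H", "P", "M", "T", "B", "N", "L", ".", "U", "",
             "damaging", "probably_damaging", "tolerated", "unknown"),
    call = c("damaging", "damaging", "damaging", "probably_damaging",
             "probably_damaging", "tolerated", "tolerated", "tolerated",
             "tolerated", "unknown", "unknown", "unknown",
             "damaging", "probably_damaging", "tolerated", "unknown")
  )
}

#' Normalise a wide predictor-call table into long impact profiles
#'
#' Takes an annotation table with one column per predictor (for example the
#' ten categorical tools: Polyphen HDIV/HVAR, LRT, PROVEAN, CADD, FATHMM,
#' MutationTaster, MutationAssessor, SIFT, Fathmm-MKL coding) and pivots it
#' to one row per DNM-by-predictor with calls mapped through a code table.
#' Unrecognised codes become `unknown`.
#'
#' @param calls Wide tibble: key columns plus one column per predictor, or
#'   an already-long tibble with `predictor` and `call` columns (returned
#'   unchanged apart from call normalisation).
#' @param predictors Character vector naming the predictor columns; defaults
#'   to the intersection of the ten standard tool names with `names(calls)`.
#' @param mapping Code-normalisation tibble as from
#'   [default_call_mapping()].
#' @return Long tibble: key columns, `predictor`, `call`.
#' @export
normalize_predictor_calls <- function(calls,
                                      predictors = NULL,
                                      mapping = default_call_mapping()) {
  if (all(c("predictor", "call") %in% names(calls))) {
    long <- calls
  } else {
    predictors <- predictors %||% intersect(PREDICTOR_NAMES, names(calls))
    if (length(predictors) == 0) abort("no predictor columns found")
    long <- calls %>%
      tidyr::pivot_longer(all_of(predictors), names_to = "predictor",
                          values_to = "call")
  }
  long %>%
    mutate(call = dplyr::coalesce(
      mapping$call[match(as.character(.data$call), mapping$code)],
      "unknown"))
}

#' Count damaging predictions per DNM
#'
#' @param profiles Long impact-profile tibble (`predictor`, `call`, plus key
#'   columns identifying each DNM).
#' @param key_cols Columns identifying one DNM; defaults to every column
#'   except `predictor` and `call`.
#' @return One row per DNM with `n_damaging` (calls in
#'   damaging/probably_damaging), `n_informative` (non-unknown calls) and
#'   `n_predictors`.
#' @export
count_damaging <- function(profiles, key_cols = NULL) {
  key_cols <- key_cols %||% setdiff(names(profiles), c("predictor", "call"))
  profiles %>%
    group_by(across(all_of(key_cols))) %>%
    summarise(
      n_damaging = sum(.data$call %in% c("damaging", "probably_damaging")),
      n_informative = sum(.data$call != "unknown"),
      n_predictors = dplyr::n(),
      .groups = "drop")
}

#' Select likely pathogenic DNMs from predictor votes
#'
#' Applies one of two published selection rules to per-DNM damaging-call
#' counts:
#'
#' * `"at_least_6"` — six or more damaging/probably-damaging predictions;
#' * `"at_least_half"` — damaging/probably-damaging calls from at least half
#'   of the informative (non-unknown) predictors,
#'   i.e. `n_damaging >= ceiling(n_informative / 2)` with
#'   `n_informative > 0`.
#'
#' An optional conservation score can be folded in as an additional
#' damaging-equivalent vote (`gerp_score > gerp_cutoff`); this is off by
#' default so the ten categorical tools alone are counted.
#'
#' @param profiles Long impact-profile tibble (see
#'   [normalize_predictor_calls()]).
#' @param rule `"at_least_6"` or `"at_least_half"`.
#' @param key_cols Columns identifying one DNM (default: all but
#'   `predictor`/`call`/`gerp_score`).
#' @param include_gerp If `TRUE`, a `gerp_score` column contributes one
#'   extra vote per DNM when above `gerp_cutoff`.
#' @param gerp_cutoff Conservation-score cut-off for the optional vote.
#' @return The damaging-count table (see [count_damaging()]) restricted to
#'   selected DNMs, with a `selected_by` column naming the rule.
#' @export
select_likely_pathogenic <- function(profiles,
                                     rule = c("at_least_6", "at_least_half"),
                                     key_cols = NULL,
                                     include_gerp = FALSE,
                                     gerp_cutoff = 2) {
  rule <- match.arg(rule)
  key_cols <- key_cols %||%
    setdiff(names(profiles), c("predictor", "call", "gerp_score"))
  counts <- count_damaging(profiles, key_cols)
  if (include_gerp && "gerp_score" %in% names(profiles)) {
    gerp <- profiles %>%
      distinct(across(all_of(c(key_cols, "gerp_score")))) %>%
      group_by(across(all_of(key_cols))) %>%
      summarise(gerp_vote = as.integer(any(.data$gerp_score > gerp_cutoff,
                                           na.rm = TRUE)),
                gerp_known = as.integer(any(!is.na(.data$gerp_score))),
                .groups = "drop")
    counts <- counts %>%
      left_join(gerp, by = key_cols) %>%
      mutate(n_damaging = .data$n_damaging +
               tidyr::replace_na(.data$gerp_vote, 0L),
             n_informative = .data$n_informative +
               tidyr::replace_na(.data$gerp_known, 0L)) %>%
      select(-any_of(c("gerp_vote", "gerp_known")))
  }
  selected <- switch(
    rule,
    at_least_6 = counts$n_damaging >= 6,
    at_least_half = counts$n_informative > 0 &
      counts$n_damaging >= ceiling(counts$n_informative / 2)
  )
  counts %>%
    filter(selected) %>%
    mutate(selected_by = rule)
}
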