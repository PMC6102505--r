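#' Candidate filter thresholds
#'
#' Bundles the quality thresholds applied to candidate de novo mutations:
#' a minimum phred-scaled genotype quality, a strict minimum read depth, and
#' an inclusive allele-balance interval. Defaults are GQ >= 50, depth > 20
#' and allele balance within \[0.3, 0.7\].
#'
#' @param min_gq Minimum genotype quality (phred), inclusive. Default 50.
#' @param min_depth_exclusive Read-depth threshold, strict: a sample passes
#'   only when its depth exceeds this value. Default 20.
#' @param ab_low,ab_high Inclusive allele-balance bounds for heterozygous
#'   calls. Defaults 0.3 and 0.7.
#'
#' @return A list of class `filter_thresholds`.
#' @export
#' @examples
#' filter_thresholds()
#' filter_thresholds(min_gq = 30)
filter_thresholds <- function(min_gq = 50, min_depth_exclusive = 20,
                              ab_low = 0.3, ab_high = 0.7) {
  stopifnot(
    is.numeric(min_gq), length(min_gq) == 1, min_gq >= 0,
    is.numeric(min_depth_exclusive), length(min_depth_exclusive) == 1,
    min_depth_exclusive >= 0,
    is.numeric(ab_low), is.numeric(ab_high),
    ab_low >= 0, ab_low < ab_high, ab_high <= 1
  )
  structure(
    list(min_gq = min_gq, min_depth_exclusive = min_depth_exclusive,
         ab_low = ab_low, ab_high = ab_high),
    class = "filter_thresholds"
  )
}

#' @export
print.filter_thresholds <- function(x, ...) {
  cat("Trio DNM filter thresholds\n")
  cat("  genotype quality >=", x$min_gq, "\n")
  cat("  read depth       > ", x$min_depth_exclusive, "\n")
  cat("  allele balance   [", x$ab_low, ",", x$ab_high, "]\n")
  invisible(x)
}
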