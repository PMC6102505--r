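# Builders for in-memory trio site records and small on-disk fixtures.

# read counts consistent with a called genotype at a given depth
reads_for_gt <- function(gt, dp) {
  switch(gt,
         HomR = c(dp, 0),
         Het = c(ceiling(dp / 2), floor(dp / 2)),
         HomA = c(0, dp),
         Missing = c(0, 0))
}

# one trio site record row with clean, self-consistent evidence
trio_record <- function(child_gt, mother_gt, father_gt,
                        ref = "A", alt = "G", chrom = "chr1", pos = 100,
                        trio_id = "t1", dp = 40, gq = 99,
                        child_reads = NULL, mother_reads = NULL,
                        father_reads = NULL,
                        child_dp = dp, mother_dp = dp, father_dp = dp,
                        child_gq = gq, mother_gq = gq, father_gq = gq) {
  gts <- list(child = child_gt, mother = mother_gt, father = father_gt)
  dps <- list(child = child_dp, mother = mother_dp, father = father_dp)
  gqs <- list(child = child_gq, mother = mother_gq, father = father_gq)
  reads <- list(child = child_reads, mother = mother_reads,
                father = father_reads)
  row <- tibble::tibble(trio_id = trio_id, chrom = chrom, pos = pos,
                        ref = ref, alt = alt)
  for (m in names(gts)) {
    rd <- reads[[m]] %||% reads_for_gt(gts[[m]], dps[[m]])
    row[[paste0(m, "_gt")]] <- gts[[m]]
    row[[paste0(m, "_dp")]] <- dps[[m]]
    row[[paste0(m, "_ref_reads")]] <- rd[1]
    row[[paste0(m, "_alt_reads")]] <- rd[2]
    row[[paste0(m, "_gq")]] <- gqs[[m]]
  }
  row
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a small handcrafted VCF and matching pedigree, return paths
write_fixture_vcf <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tc1\tm1\tf1"
  )
  path <- file.path(dir, "fixture.vcf")
  writeLines(c(header, lines), path)
  path
}

fixture_trio <- function() {
  tibble::tibble(trio_id = "t1", child_id = "c1", mother_id = "m1",
                 father_id = "f1", mother_age = 28, father_age = 31)
}

# independent brute-force oracle for interval membership (1-based point vs
# BED half-open interval)
interval_oracle <- function(intervals, chrom, pos) {
  mapply(function(ch, p) {
    any(intervals$chrom == ch & intervals$start < p & p <= intervals$end)
  }, chrom, pos, USE.NAMES = FALSE)
}

# independent oracle for the filtered-het detection probability: literal
# per-outcome evaluation of the three genotype likelihoods
het_detection_oracle <- function(depth, min_gq = 50, min_depth = 20,
                                 ab_low = 0.3, ab_high = 0.7, eps = 0.01,
                                 p_alt = 0.5, target = "Het") {
  if (depth <= min_depth) return(0)
  total <- 0
  for (k in 0:depth) {
    r <- depth - k
    lik <- c(HomR = (1 - eps)^r * eps^k,
             Het = 0.5^(r + k),
             HomA = eps^r * (1 - eps)^k)
    best <- names(lik)[which.max(lik)]
    srt <- sort(lik, decreasing = TRUE)
    gq <- min(99, 10 * (log10(srt[1]) - log10(srt[2])))
    ab <- k / depth
    ab_ok <- if (target == "Het") ab >= ab_low && ab <= ab_high
             else if (target == "HomR") ab < ab_low else ab > ab_high
    if (best == target && gq >= min_gq && ab_ok) {
      total <- total + dbinom(k, depth, p_alt)
    }
  }
  total
}
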