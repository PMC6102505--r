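test_that("pedigree parsing maps columns and validates trio structure", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ped.tsv")
  writeLines(c("t1\tc1\tm1\tf1\t28\t31",
               "t2\tc2\tm2\tf2"), path)
  ped <- read_pedigree(path)
  expect_equal(nrow(ped), 2)
  expect_equal(ped$trio_id, c("t1", "t2"))
  expect_equal(ped$mother_age, c(28, NA))
  expect_equal(ped$father_age, c(31, NA))

  writeLines(c("t1\tc1\tm1\tf1", "t1\tc2\tm2\tf2"), path)
  expect_error(read_pedigree(path), "duplicate trio_id")

  writeLines("t1\tc1\tc1\tf1", path)
  expect_error(read_pedigree(path), "non-distinct")

  writeLines("t1\tc1\tm1\tf1\t28\t105", path)
  expect_error(read_pedigree(path), "\\[10, 100\\]")
})

test_that("a generated pedigree round-trips with order and count preserved", {
  dir <- withr::local_tempdir()
  ids <- sprintf("fam%02d", 1:48)
  writeLines(paste(ids, paste0("c", 1:48), paste0("m", 1:48),
                   paste0("f", 1:48), 25 + (1:48) %% 15, 27 + (1:48) %% 20,
                   sep = "\t"),
             file.path(dir, "ped.tsv"))
  ped <- read_pedigree(file.path(dir, "ped.tsv"))
  expect_equal(nrow(ped), 48)
  expect_equal(ped$trio_id, ids)

  out <- file.path(dir, "ped_out.tsv")
  write_pedigree(ped, out)
  expect_equal(as.data.frame(read_pedigree(out)), as.data.frame(ped))
})

test_that("VCF genotypes map onto trio records and multiallelics decompose", {
  vcf <- write_fixture_vcf(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:DP:AD:GQ\t0/1:40:20,20:99\t0/0:38:38,0:99\t0/0:35:35,0:99",
    "chr1\t200\t.\tA\tC,T\t.\tPASS\t.\tGT:DP:AD:GQ\t1/2:40:0,20,20:80\t0/1:30:15,15,0:70\t0/2:30:15,0,15:70",
    "chr2\t50\t.\tAC\tA\t.\tPASS\t.\tGT:DP:AD:GQ\t0/0:25:25,0:99\t1/1:30:0,30:99\t1/1:28:0,28:99"
  ))
  rec <- read_trio_vcf(vcf, fixture_trio())
  # per-alt decomposition: 1 + 2 + 1 records, in file order
  expect_equal(nrow(rec), 4)
  expect_equal(rec$alt, c("G", "C", "T", "A"))

  expect_equal(rec$child_gt[1], "Het")
  expect_equal(rec$mother_gt[1], "HomR")
  expect_equal(rec$child_alt_reads[1], 20)

  # child 1/2 relative to alt C (allele 1): one allele matches -> Het
  expect_equal(rec$child_gt[2], "Het")
  # mother 0/1 relative to alt T (allele 2): no allele matches -> HomR
  expect_equal(rec$mother_gt[3], "HomR")
  expect_equal(rec$father_gt[3], "Het")
  # AD column for alt T is the third entry
  expect_equal(rec$child_alt_reads[3], 20)
  expect_equal(rec$mother_alt_reads[3], 0)

  # reversible-indel style site
  expect_equal(rec$child_gt[4], "HomR")
  expect_equal(rec$mother_gt[4], "HomA")
})

test_that("VCF reading errors on absent samples and degrades on missing FORMAT", {
  vcf <- write_fixture_vcf(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:DP:AD:GQ\t0/1:40:20,20:99\t0/0:38:38,0:99\t0/0:35:35,0:99")
  bad_trio <- fixture_trio()
  bad_trio$father_id <- "nope"
  expect_error(read_trio_vcf(vcf, bad_trio), "not in VCF header")

  vcf2 <- write_fixture_vcf(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:DP\t0/1:40\t0/0:38\t0/0:35",
    "chr1\t150\t.\tA\tG\t.\tPASS\t.\tGT:DP:AD:GQ\t./.:0:0,0:0\t0/0:30:30,0:99\t0/0:30:30,0:99"))
  expect_warning(rec <- read_trio_vcf(vcf2, fixture_trio()),
                 "missing FORMAT")
  expect_equal(rec$child_gt, c("Missing", "Missing"))
  expect_equal(rec$mother_gt, c("Missing", "HomR"))
  expect_equal(nrow(drop_missing_records(rec)), 0)
})

test_that("decomposition conserves total alt-allele count on simulated VCFs", {
  cfg <- simulation_config(n_trios = 1, n_sites = 300, mu = 1e-3,
                           seed = 11)
  dir <- withr::local_tempdir()
  ds <- simulate_trio_dataset(cfg, dir = dir)
  trio <- ds$pedigree[1, ]
  rec <- read_trio_vcf(ds$paths$vcf[[trio$trio_id]], trio)
  # simulator writes biallelic records: one output row per site
  expect_equal(nrow(rec), 300)
  ev <- ds$evidence
  expect_equal(rec$chrom, ev$chrom)
  expect_equal(rec$pos, ev$pos)
  expect_equal(rec$child_gt, ev$child_gt)
  expect_equal(rec$mother_gq, ev$mother_gq)
  expect_equal(rec$father_alt_reads, ev$father_alt_reads)
})

test_that("BED point membership honours the half-open convention", {
  trk <- interval_track(tibble::tibble(chrom = "chr1", start = 99, end = 200))
  expect_false(in_track(trk, "chr1", 99))
  expect_true(in_track(trk, "chr1", 100))
  expect_true(in_track(trk, "chr1", 200))
  expect_false(in_track(trk, "chr1", 201))
  expect_false(in_track(trk, "chr2", 150))
})

test_that("interval membership matches a linear-scan oracle on random tracks", {
  set.seed(42)
  n_iv <- 2000
  iv <- tibble::tibble(
    chrom = sample(paste0("chr", 1:3), n_iv, replace = TRUE),
    start = sample.int(50000, n_iv, replace = TRUE))
  iv$end <- iv$start + sample.int(300, n_iv, replace = TRUE)
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "t.bed")
  # unsorted input is allowed
  write.table(iv[sample.int(n_iv), ], bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  trk <- read_interval_track(bed)
  q_chrom <- sample(paste0("chr", 1:4), 3000, replace = TRUE)
  q_pos <- sample.int(52000, 3000, replace = TRUE)
  expect_equal(in_track(trk, q_chrom, q_pos),
               interval_oracle(iv, q_chrom, q_pos))
})

test_that("degenerate BED intervals are skipped with a warning", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "bad.bed")
  writeLines(c("chr1\t10\t10", "chr1\t100\t200"), bed)
  expect_warning(trk <- read_interval_track(bed), "start >= end")
  expect_equal(nrow(trk), 1)
  expect_equal(track_coverage(trk), 100)
})

test_that("DNM report writing is ordered, header-stable and round-trips", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "dnms.tsv")
  write_dnm_report(tibble::tibble(), path)
  expect_equal(length(readLines(path)), 1)

  cands <- dplyr::bind_rows(
    trio_record("Het", "HomR", "HomR", trio_id = "t2", pos = 5),
    trio_record("Het", "HomR", "HomR", trio_id = "t1", pos = 900),
    trio_record("Het", "HomR", "HomR", trio_id = "t1", pos = 20, ref = "C",
                alt = "T")
  ) %>%
    detect_candidates() %>%
    apply_filters()
  write_dnm_report(cands, path)
  expect_equal(length(readLines(path)), 4)
  back <- read_dnm_report(path)
  expect_equal(back$trio_id, c("t1", "t1", "t2"))
  expect_equal(back$pos, c(20, 900, 5))
  reread <- cands %>%
    dplyr::select(dplyr::all_of(names(back))) %>%
    dplyr::arrange(trio_id, chrom, pos)
  expect_equal(as.data.frame(back), as.data.frame(reread))
})
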