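make_fixture_vcf <- function(path, extra_record = NULL) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"AF\">",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"info\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"DS\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsampleA\tsampleB",
    "chr1\t100\trs1\tA\tG\t.\t.\tAF=0.25;INFO=0.9\tGT:DS\t0/1:0.5\t1/1:1.5",
    "chr1\t200\trs2\tC\tT\t.\t.\tAF=0.5\tGT\t0/1\t./.",
    extra_record)
  writeLines(lines, path)
  path
}

test_that("read_dosage_vcf parses DS, falls back to GT, reports line numbers", {
  f <- withr::local_tempfile(fileext = ".vcf")
  make_fixture_vcf(f)
  dm <- read_dosage_vcf(f)
  expect_s3_class(dm, "dosage_matrix")
  expect_identical(dm$samples, c("sampleA", "sampleB"))
  expect_equal(unname(dm$dosages[, "rs1"]), c(0.5, 1.5))
  expect_equal(dm$variants$info[1], 0.9)
  expect_equal(dm$variants$freq, c(0.25, 0.5))
  # DS absent: GT=0/1 -> dosage 1; ./. -> missing
  expect_equal(unname(dm$dosages[, "rs2"]), c(1, NA))

  f2 <- withr::local_tempfile(fileext = ".vcf")
  make_fixture_vcf(f2, "chr1\t300\trs3\tA\tG\t.\t.\tAF=0.1\tGT\t0/1/1\t0/0")
  expect_error(read_dosage_vcf(f2), "non-diploid")

  f3 <- withr::local_tempfile(fileext = ".vcf")
  make_fixture_vcf(f3, "chr1\t400\trs4\tA\tG\t.\t.\tAF=0.1")
  expect_error(read_dosage_vcf(f3), "line 9")
})

test_that("dosage VCF round-trips and agrees with VariantAnnotation", {
  panel <- tiny_panel(seed = 51, n_hap = 100, n_var = 12)
  coh <- simulate_case_control(panel, risk_model(prevalence = 0.2),
                               15, 15, seed = 52)
  d <- dosify(coh$dosages, 0.8, seed = 53)
  dm <- as_dm(d, coh$variants)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_dosage_vcf(dm, f)
  back <- read_dosage_vcf(f)
  expect_lt(max(abs(back$dosages - dm$dosages)), 1e-3)
  expect_identical(back$variants$id, dm$variants$id)
  expect_identical(back$variants$pos, dm$variants$pos)
  expect_equal(back$variants$info, dm$variants$info, tolerance = 1e-5)

  skip_if_not_installed("VariantAnnotation")
  vcf <- suppressWarnings(VariantAnnotation::readVcf(f))
  ds <- VariantAnnotation::geno(vcf)$DS
  expect_equal(unname(t(ds)), unname(round(dm$dosages, 3)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("annotation tracks normalize with half-open merge semantics", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20\tpeakA", "chr1\t15\t30\tpeakB",
               "chr2\t5\t8"), f)
  tr <- read_bed(f)
  expect_s3_class(tr, "annotation_track")
  expect_equal(tr$start[tr$chrom == "chr1"], 10)
  expect_equal(tr$end[tr$chrom == "chr1"], 30)
  expect_match(tr$label[tr$chrom == "chr1"], "peakA")
  expect_match(tr$label[tr$chrom == "chr1"], "peakB")

  # empty BED -> empty track, downstream overlap counts 0
  fe <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), fe)
  te <- read_bed(fe)
  expect_equal(nrow(te), 0)
  stats <- data.frame(chr = "chr1", pos = c(5, 15), p = c(0.5, 0.5))
  expect_identical(annotate_overlap(stats, te), c(FALSE, FALSE))

  # round trip
  fo <- withr::local_tempfile(fileext = ".bed")
  write_bed(tr, fo)
  expect_identical(read_bed(fo)[, c("chrom", "start", "end")],
                   tr[, c("chrom", "start", "end")])

  expect_error(annotation_track(data.frame(chrom = "chr1", start = 10,
                                           end = 10)),
               "start < end")
})

test_that("recombination maps interpolate linearly and reject disorder", {
  map <- flat_recomb_map(rate = 1, length_bp = 1e7)
  expect_equal(cm_at(map, 2500000), 2.5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_recomb_map(map, f)
  m2 <- read_recomb_map(f)
  expect_equal(cm_at(m2, c(0, 5e6, 1e7)), c(0, 5, 10))

  bad <- data.frame(position_bp = c(0, 10, 5), rate_cM_per_Mb = 1,
                    cM = c(0, 1, 2))
  expect_error(recomb_map(bad), "non-decreasing")
})

test_that("association tables round-trip", {
  panel <- tiny_panel(seed = 61, n_hap = 100, n_var = 8)
  tr <- simulate_trios(panel, risk_model(prevalence = 0.2), 40, seed = 62)
  a <- trio_assoc(tr)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_assoc_table(a, f)
  a2 <- read_assoc_table(f)
  expect_equal(a2$p, a$p, tolerance = 1e-12)
  expect_identical(a2$snp, a$snp)
})

test_that("filter_variants applies the info/MAF rules and reports reasons", {
  set.seed(1)
  n <- 200
  d <- cbind(a = rbinom(n, 2, 0.3), b = rbinom(n, 2, 0.3),
             c = rbinom(n, 2, 0.005), d = rbinom(n, 2, 0.3))
  storage.mode(d) <- "double"
  v <- data.frame(id = c("a", "b", "c", "d"), chrom = "chr1", pos = 1:4,
                  ref = "A", alt = "G", freq = colMeans(d) / 2,
                  info = c(0.35, 0.41, 0.9, 0.9))
  dm <- dosage_matrix(d, v)

  res <- filter_variants(dm)
  expect_identical(res$matrix$variants$id, c("b", "d"))
  expect_identical(res$report$reason[res$report$id == "a"], "info")
  expect_identical(res$report$reason[res$report$id == "c"], "maf")

  # info > 0.4 in ANY dataset rescues variant a
  res2 <- filter_variants(dm, extra_info = list(other = c(0.41, 0.1, 0.1, 0.1)))
  expect_true("a" %in% res2$matrix$variants$id)

  # MAF evaluated on the designated reference subset only
  ref <- seq_len(100)
  res3 <- filter_variants(dm, maf_reference = ref)
  p_ref <- colMeans(d[ref, ]) / 2
  expect_identical("c" %in% res3$matrix$variants$id,
                   unname(pmin(p_ref, 1 - p_ref)["c"] > 0.01))
  expect_error(filter_variants(dm, maf_reference = integer(0)), "empty")

  # order independence: same retained set regardless of filter order
  only_info <- filter_variants(dm, maf_min = 0)
  refil <- filter_variants(only_info$matrix, info_min = 0)
  expect_identical(refil$matrix$variants$id, res$matrix$variants$id)
})

test_that("hwe_exact_test matches a brute-force enumeration oracle", {
  # independent oracle: enumerate all heterozygote counts compatible with
  # the allele counts and weigh by the exact conditional probability
  hwe_oracle <- function(aa, ab, bb) {
    n <- aa + ab + bb
    na <- 2 * aa + ab
    hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
    pr <- vapply(hets, function(h) {
      hom_a <- (na - h) / 2
      hom_b <- n - hom_a - h
      exp(lfactorial(n) - lfactorial(hom_a) - lfactorial(h) -
            lfactorial(hom_b) + h * log(2) +
            lfactorial(na) + lfactorial(2 * n - na) - lfactorial(2 * n))
    }, numeric(1))
    obs <- pr[hets == ab]
    min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
  }
  expect_equal(hwe_exact_test(25, 50, 25), 1)
  expect_equal(hwe_exact_test(25, 50, 25), hwe_oracle(25, 50, 25))
  set.seed(42)
  for (i in 1:25) {
    cnt <- as.vector(stats::rmultinom(1, sample(20:200, 1),
                                      prob = c(0.5, 0.35, 0.15)))
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 hwe_oracle(cnt[1], cnt[2], cnt[3]), tolerance = 1e-10)
  }
  # strong HWE violation is detected
  expect_lt(hwe_exact_test(50, 0, 50), 1e-6)
})

test_that("filter_hardcall thresholds genotypes and applies variant QC", {
  set.seed(7)
  n <- 200
  status <- rep(c(1, 0), each = n / 2)

  g_clean <- rbinom(n, 2, 0.3)           # exact dosages: always called
  d_uncertain <- g_clean + 0.4           # 0.4 from integer: confidence 0.2
  d_uncertain <- pmin(d_uncertain, 2)
  g_mono <- rep(0, n)
  g_hwe <- c(rep(0, 100), rep(2, 100))[sample.int(n)]  # no hets at p = 0.5

  d <- cbind(clean = g_clean, uncertain = d_uncertain, mono = g_mono,
             hwe = g_hwe)
  storage.mode(d) <- "double"
  v <- data.frame(id = colnames(d), chrom = "chr1", pos = 1:4, ref = "A",
                  alt = "G", freq = colMeans(d) / 2, info = 1)
  dm <- dosage_matrix(d, v)
  res <- filter_hardcall(dm, status)

  expect_identical(res$kept, "clean")
  rep_ <- res$report
  expect_match(rep_$reason[rep_$id == "uncertain"], "callrate")
  expect_match(rep_$reason[rep_$id == "mono"], "monomorphic")
  expect_match(rep_$reason[rep_$id == "hwe"], "hwe")
  # dosage exactly 0.0 has confidence 1 and is called
  expect_true(all(!is.na(res$genotypes[, "clean"])))

  # differential missingness: missing only in cases
  d2 <- cbind(dm1 = as.double(rbinom(n, 2, 0.3)))
  d2[sample(which(status == 1), 30)] <- NA
  v2 <- data.frame(id = "dm1", chrom = "chr1", pos = 1, ref = "A", alt = "G",
                   freq = 0.3, info = 1)
  dm2 <- dosage_matrix(d2, v2)
  res2 <- filter_hardcall(dm2, status, callrate_min = 0.5)
  expect_match(res2$report$reason[res2$report$id == "dm1"], "diffmiss")
})
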