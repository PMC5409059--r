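## gwasio: file formats (dosage VCF, BED, recombination map, association TSV)
## and the variant/sample-level QC filters.
##
## Interval convention: everything internal is 0-based half-open [start, end),
## matching BED. VCF positions are 1-based and converted on I/O.

#' Construct a dosage matrix
#'
#' @param dosages Numeric samples x variants matrix with values in \[0, 2\]
#'   (NA = missing).
#' @param variants Data frame with columns `id`, `chrom`, `pos` (1-based bp),
#'   `ref`, `alt`, `freq`, `info`.
#' @param samples Character sample identifiers (default from rownames).
#' @return An object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(dosages, variants, samples = rownames(dosages)) {
  stopifnot(is.matrix(dosages), is.data.frame(variants))
  check_that(nrow(variants) == ncol(dosages), "variants",
             "must have one row per dosage column")
  need <- c("id", "chrom", "pos", "ref", "alt")
  check_that(all(need %in% names(variants)), "variants",
             paste("must contain columns:", paste(need, collapse = ", ")))
  check_that(all(variants$pos >= 1), "variants", "positions must be >= 1")
  check_that(all(nzchar(variants$ref)) && all(nzchar(variants$alt)),
             "variants", "alleles must be non-empty")
  rng <- range(dosages, na.rm = TRUE)
  check_that(rng[1] >= 0 && rng[2] <= 2, "dosages",
             "values must lie in [0, 2] or be NA")
  if (is.null(samples)) samples <- sprintf("S%05d", seq_len(nrow(dosages)))
  if (is.null(variants$freq)) variants$freq <- colMeans(dosages, na.rm = TRUE) / 2
  if (is.null(variants$info)) variants$info <- NA_real_
  rownames(dosages) <- samples
  colnames(dosages) <- variants$id
  structure(list(dosages = dosages, variants = variants, samples = samples),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("dosage_matrix: %d samples x %d variants\n",
              length(x$samples), nrow(x$variants)))
  invisible(x)
}

#' Write a dosage matrix as VCF with a FORMAT/DS field
#'
#' Emits VCF 4.2 with per-sample `GT` (rounded hard call) and `DS` (expected
#' alternate-allele dosage, 3 decimals); allele frequency and info score go
#' to `INFO/AF` and `INFO/INFO`.
#'
#' @param x A [dosage_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dosage_vcf <- function(x, path) {
  stopifnot(inherits(x, "dosage_matrix"))
  v <- x$variants
  hdr <- c("##fileformat=VCFv4.2",
           "##source=cleftgwas",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alternate allele frequency\">",
           "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation info score (dosage variance ratio)\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Expected alternate allele dosage\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", x$samples), collapse = "\t"))
  gt_codes <- c("0/0", "0/1", "1/1")
  lines <- vapply(seq_len(nrow(v)), function(j) {
    d <- x$dosages[, j]
    gt <- ifelse(is.na(d), "./.", gt_codes[pmin(pmax(round(d), 0), 2) + 1L])
    ds <- ifelse(is.na(d), ".", sprintf("%.3f", d))
    info <- sprintf("AF=%.6g%s", v$freq[j],
                    if (is.na(v$info[j])) "" else sprintf(";INFO=%.6g", v$info[j]))
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j], ".", ".",
            info, "GT:DS", paste(gt, ds, sep = ":")), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a VCF with per-sample dosages
#'
#' Parses a VCF 4.x file whose FORMAT includes a `DS` dosage field. Records
#' without `DS` fall back to the `GT` hard call (alternate-allele count);
#' `./.` or `.` dosage entries become missing. Malformed records are
#' reported with their line numbers; genotypes that are not diploid are
#' rejected.
#'
#' @param path VCF file path.
#' @return A [dosage_matrix()].
#' @export
read_dosage_vcf <- function(path) {
  lines <- readLines(path)
  hdr_i <- grep("^#CHROM\t", lines)
  check_that(length(hdr_i) == 1L, "path", "no #CHROM header line found")
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  check_that(length(hdr) >= 10L, "path", "VCF has no sample columns")
  samples <- hdr[-(1:9)]
  rec_i <- setdiff(seq_along(lines), seq_len(hdr_i))
  rec_i <- rec_i[nzchar(lines[rec_i])]
  n_var <- length(rec_i)
  check_that(n_var > 0L, "path", "VCF has no records")

  D <- matrix(NA_real_, length(samples), n_var)
  v <- data.frame(id = character(n_var), chrom = character(n_var),
                  pos = integer(n_var), ref = character(n_var),
                  alt = character(n_var), freq = NA_real_, info = NA_real_,
                  stringsAsFactors = FALSE)
  for (k in seq_len(n_var)) {
    ln <- rec_i[k]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(hdr))
      stop(sprintf("malformed VCF record at line %d: expected %d fields, got %d",
                   ln, length(hdr), length(f)), call. = FALSE)
    v$chrom[k] <- f[1]; v$pos[k] <- as.integer(f[2]); v$id[k] <- f[3]
    v$ref[k] <- f[4]; v$alt[k] <- f[5]
    if (is.na(v$pos[k]))
      stop(sprintf("malformed VCF record at line %d: non-numeric POS", ln),
           call. = FALSE)
    for (kv in strsplit(strsplit(f[8], ";", fixed = TRUE)[[1]], "=", fixed = TRUE)) {
      if (kv[1] == "AF") v$freq[k] <- as.numeric(kv[2])
      if (kv[1] == "INFO") v$info[k] <- as.numeric(kv[2])
    }
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    ds_i <- match("DS", fmt); gt_i <- match("GT", fmt)
    cells <- strsplit(f[-(1:9)], ":", fixed = TRUE)
    d <- vapply(cells, function(cell) {
      if (!is.na(ds_i) && length(cell) >= ds_i && !cell[ds_i] %in% c(".", "./.")) {
        return(as.numeric(cell[ds_i]))
      }
      if (!is.na(gt_i) && length(cell) >= gt_i) {
        gt <- cell[gt_i]
        if (gt %in% c(".", "./.", ".|.")) return(NA_real_)
        al <- strsplit(gt, "[/|]")[[1]]
        if (length(al) != 2L)
          stop(sprintf("non-diploid genotype '%s' at line %d", gt, ln),
               call. = FALSE)
        return(sum(al == "1"))
      }
      NA_real_
    }, numeric(1))
    if (any(!is.na(d) & (d < 0 | d > 2)))
      stop(sprintf("dosage outside [0, 2] at line %d", ln), call. = FALSE)
    D[, k] <- d
  }
  rownames(D) <- samples
  dosage_matrix(D, v, samples)
}

#' Construct / normalize an annotation track
#'
#' Intervals are 0-based half-open `[start, end)`, strand-agnostic. The
#' constructor sorts by (chromosome, start) and merges overlapping or
#' book-ended intervals (as `bedtools merge` does); labels of merged
#' intervals are concatenated.
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end` and
#'   optionally `label`.
#' @return A data frame of class `annotation_track`, normalized.
#' @export
annotation_track <- function(intervals) {
  stopifnot(is.data.frame(intervals))
  if (nrow(intervals) == 0L) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), label = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("annotation_track", "data.frame")
    return(out)
  }
  check_that(all(intervals$end > intervals$start), "intervals",
             "requires start < end for every interval")
  lab <- if (!is.null(intervals$label)) as.character(intervals$label)
         else rep(NA_character_, nrow(intervals))
  pieces <- lapply(split(seq_len(nrow(intervals)), intervals$chrom), function(ix) {
    ir <- IRanges::IRanges(start = intervals$start[ix] + 1L,
                           end = intervals$end[ix])  # 1-based closed internally
    red <- IRanges::reduce(ir)
    ov <- IRanges::findOverlaps(ir, red)
    labs <- vapply(seq_along(red), function(r) {
      l <- unique(stats::na.omit(lab[ix][S4Vectors::from(ov)[S4Vectors::to(ov) == r]]))
      if (length(l)) paste(l, collapse = ",") else NA_character_
    }, character(1))
    data.frame(chrom = intervals$chrom[ix][1],
               start = IRanges::start(red) - 1L, end = IRanges::end(red),
               label = labs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("annotation_track", "data.frame")
  out
}

#' Read a BED file (3+ columns) as an annotation track
#'
#' BED is 0-based half-open. Any fourth column is kept as the interval label;
#' the track is sorted and merged on read.
#'
#' @param path BED file path.
#' @return An [annotation_track()].
#' @export
read_bed <- function(path) {
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character(0))
  if (length(first) == 0L || !nzchar(first))
    return(annotation_track(data.frame(chrom = character(0),
                                       start = numeric(0), end = numeric(0))))
  bed <- read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE,
                    fill = TRUE)
  check_that(ncol(bed) >= 3L, "path", "BED needs at least 3 columns")
  df <- data.frame(chrom = as.character(bed[[1]]), start = bed[[2]],
                   end = bed[[3]], stringsAsFactors = FALSE)
  if (ncol(bed) >= 4L) df$label <- as.character(bed[[4]])
  annotation_track(df)
}

#' Write an annotation track as BED
#'
#' @param track An [annotation_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(track, path) {
  df <- as.data.frame(track)
  cols <- c("chrom", "start", "end")
  if (any(!is.na(df$label))) cols <- c(cols, "label")
  write.table(df[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a recombination map
#'
#' Tab-separated columns: `position_bp`, `rate_cM_per_Mb`, `cM` (cumulative).
#' Positions and cumulative cM must be non-decreasing.
#'
#' @param path File path (with header).
#' @return A data frame of class `recomb_map`.
#' @export
read_recomb_map <- function(path) {
  m <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  check_that(ncol(m) >= 3L, "path", "recombination map needs 3 columns")
  names(m)[1:3] <- c("position_bp", "rate_cM_per_Mb", "cM")
  recomb_map(m)
}

#' @rdname read_recomb_map
#' @param m Data frame with columns `position_bp`, `rate_cM_per_Mb`, `cM`.
#' @export
recomb_map <- function(m) {
  check_that(!is.unsorted(m$position_bp), "m", "positions must be non-decreasing")
  check_that(!is.unsorted(m$cM), "m", "cumulative cM must be non-decreasing")
  class(m) <- c("recomb_map", "data.frame")
  m
}

#' @rdname read_recomb_map
#' @param map A `recomb_map`.
#' @param path Output path.
#' @export
write_recomb_map <- function(map, path) {
  write.table(as.data.frame(map)[, c("position_bp", "rate_cM_per_Mb", "cM")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flat recombination map helper
#'
#' @param rate Constant rate in cM/Mb.
#' @param length_bp Chromosome length.
#' @return A `recomb_map` with two knots (0 and `length_bp`).
#' @export
flat_recomb_map <- function(rate = 1, length_bp = 1e8) {
  recomb_map(data.frame(position_bp = c(0, length_bp),
                        rate_cM_per_Mb = c(rate, rate),
                        cM = c(0, rate * length_bp / 1e6)))
}

#' Cumulative genetic distance at physical positions
#'
#' Linear interpolation of the map's cumulative cM column; positions outside
#' the map are clamped to the map ends.
#'
#' @param map A `recomb_map`.
#' @param pos Physical positions (bp).
#' @return Cumulative cM at `pos`.
#' @export
cm_at <- function(map, pos) {
  approx(map$position_bp, map$cM, xout = pos, rule = 2, ties = "ordered")$y
}

#' Read / write a per-variant association table
#'
#' TSV with columns `snp, chr, pos, effect_allele, other_allele, freq, info,
#' beta, se, z, p` (extra columns preserved).
#'
#' @param path File path.
#' @return An `assoc_table` data frame.
#' @export
read_assoc_table <- function(path) {
  a <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("snp", "chr", "pos", "beta", "se", "p")
  check_that(all(need %in% names(a)), "path",
             paste("association table needs columns:",
                   paste(need, collapse = ", ")))
  as_assoc_table(a)
}

#' @rdname read_assoc_table
#' @param a An `assoc_table` (or data frame with its columns).
#' @export
write_assoc_table <- function(a, path) {
  write.table(as.data.frame(a), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

as_assoc_table <- function(a) {
  ok <- is.na(a$p) | (a$p > 0 & a$p <= 1)
  check_that(all(ok), "a", "P-values must lie in (0, 1]")
  class(a) <- unique(c("assoc_table", class(a)))
  a
}

#' Imputation-quality and frequency variant filter
#'
#' Retains variants whose info score exceeds `info_min` in at least one
#' dataset (the matrix's own `info` metadata, plus any vectors supplied in
#' `extra_info`), and whose minor allele frequency on the designated
#' reference samples (e.g. controls, or non-transmitted parental alleles)
#' exceeds `maf_min`. Defaults mirror standard post-imputation practice
#' (info > 0.4, MAF > 1%).
#'
#' @param x A [dosage_matrix()].
#' @param info_min Info-score threshold (exclusive).
#' @param maf_min MAF threshold (exclusive).
#' @param maf_reference Logical or integer subset of samples on which MAF is
#'   computed (default: all samples).
#' @param extra_info Optional list of per-variant info-score vectors from
#'   other datasets; a variant passes the info rule if any dataset exceeds
#'   the threshold.
#' @return List with `matrix` (filtered [dosage_matrix()]) and `report`
#'   (data frame of exclusions with reasons `"info"`/`"maf"`).
#' @export
filter_variants <- function(x, info_min = 0.4, maf_min = 0.01,
                            maf_reference = NULL, extra_info = NULL) {
  stopifnot(inherits(x, "dosage_matrix"))
  if (is.null(maf_reference)) maf_reference <- seq_along(x$samples)
  sub <- x$dosages[maf_reference, , drop = FALSE]
  check_that(nrow(sub) > 0L, "maf_reference", "reference subset is empty")
  info_mat <- cbind(x$variants$info,
                    if (length(extra_info)) do.call(cbind, extra_info))
  info_ok <- apply(info_mat, 1, function(z) any(!is.na(z) & z > info_min))
  p <- colMeans(sub, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf_ok <- maf > maf_min
  keep <- info_ok & maf_ok
  reason <- character(sum(!keep))
  bad <- which(!keep)
  reason <- vapply(bad, function(j)
    paste(c(if (!info_ok[j]) "info", if (!maf_ok[j]) "maf"), collapse = ";"),
    character(1))
  report <- data.frame(id = x$variants$id[bad], reason = reason,
                       info = x$variants$info[bad], maf = maf[bad],
                       stringsAsFactors = FALSE)
  list(matrix = subset_variants(x, keep), report = report)
}

#' Subset a dosage matrix by variant
#'
#' @param x A [dosage_matrix()].
#' @param j Logical/integer/character variant index.
#' @return A [dosage_matrix()].
#' @export
subset_variants <- function(x, j) {
  if (is.character(j)) j <- match(j, x$variants$id)
  dosage_matrix(x$dosages[, j, drop = FALSE],
                x$variants[j, , drop = FALSE], x$samples)
}

#' Hard-call thresholding with variant-level QC
#'
#' Converts dosages into hard genotypes: `g = round(d)` is assigned when its
#' confidence `1 - 2 |d - round(d)|` reaches `call_threshold`, else the
#' genotype is missing. (This is a monotone surrogate for thresholding the
#' imputed genotype-probability triple, which dosage files do not carry.)
#' Variants are then dropped unless they satisfy all of: call rate >=
#' `callrate_min`, MAF >= `maf_min`, Hardy-Weinberg exact test P (controls
#' only) >= `hwe_p_min`, and a two-sided Fisher test of differential
#' missingness between cases and controls with P >= `diffmiss_p_min`.
#' Variants monomorphic after calling are flagged, not silently kept.
#'
#' @param x A [dosage_matrix()].
#' @param status 0/1 case-control labels (needed for the missingness test).
#' @param call_threshold Genotype-confidence threshold (default 0.9).
#' @param callrate_min Minimum per-variant call rate.
#' @param maf_min Minimum MAF (on called genotypes, all samples).
#' @param hwe_p_min Minimum HWE exact P in controls.
#' @param diffmiss_p_min Minimum differential-missingness P.
#' @return List with `genotypes` (samples x retained-variants matrix of
#'   0/1/2/NA), `kept` ids, and `report` of exclusions with reasons.
#' @export
filter_hardcall <- function(x, status, call_threshold = 0.9,
                            callrate_min = 0.95, maf_min = 0.01,
                            hwe_p_min = 1e-6, diffmiss_p_min = 0.05) {
  stopifnot(inherits(x, "dosage_matrix"))
  check_that(length(status) == length(x$samples) && all(status %in% c(0, 1)),
             "status", "must be 0/1 labels aligned with samples")
  d <- x$dosages
  g <- round(d)
  conf <- 1 - 2 * abs(d - g)
  g[is.na(d) | conf < call_threshold] <- NA
  ctrl <- which(status == 0)

  m <- ncol(g)
  reason <- vector("list", m)
  for (j in seq_len(m)) {
    gj <- g[, j]
    r <- character(0)
    callrate <- mean(!is.na(gj))
    if (callrate < callrate_min) r <- c(r, "callrate")
    called <- gj[!is.na(gj)]
    if (length(called)) {
      p <- mean(called) / 2
      if (min(p, 1 - p) < maf_min) r <- c(r, "maf")
      if (p %in% c(0, 1)) r <- c(r, "monomorphic")
    } else r <- c(r, "monomorphic")
    gc <- gj[ctrl]
    counts <- c(sum(gc == 0, na.rm = TRUE), sum(gc == 1, na.rm = TRUE),
                sum(gc == 2, na.rm = TRUE))
    if (sum(counts) > 0 && hwe_exact_test(counts[1], counts[2], counts[3]) < hwe_p_min)
      r <- c(r, "hwe")
    miss <- is.na(gj)
    tab <- table(factor(miss, c(FALSE, TRUE)), factor(status, c(0, 1)))
    if (any(miss) && !all(miss)) {
      if (stats::fisher.test(tab)$p.value < diffmiss_p_min)
        r <- c(r, "diffmiss")
    }
    reason[[j]] <- r
  }
  drop <- lengths(reason) > 0
  report <- data.frame(id = x$variants$id[drop],
                       reason = vapply(reason[drop], paste, character(1),
                                       collapse = ";"),
                       stringsAsFactors = FALSE)
  list(genotypes = g[, !drop, drop = FALSE], kept = x$variants$id[!drop],
       report = report)
}

#' Hardy-Weinberg exact test
#'
#' Exact (Wigginton-style) two-sided test of Hardy-Weinberg proportions from
#' genotype counts: P is the total probability of heterozygote counts whose
#' conditional probability (given allele counts) does not exceed the
#' observed one.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (major-hom, het, minor-hom order is
#'   irrelevant).
#' @return Two-sided exact P-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(NA_real_)
  n_rare <- 2 * min(n_aa, n_bb) + n_ab
  ## heterozygote counts share the parity of the rare-allele count
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  ## log P(n_ab = h | allele counts) up to a constant:
  ## C(n, (n_rare-h)/2, h, rest) 2^h  /  C(2n, n_rare)
  lp <- vapply(hets, function(h) {
    rare_hom <- (n_rare - h) / 2
    com_hom <- n - rare_hom - h
    lgamma(n + 1) - lgamma(rare_hom + 1) - lgamma(h + 1) -
      lgamma(com_hom + 1) + h * log(2)
  }, numeric(1))
  pr <- exp(lp - logsumexp(lp))
  obs <- pr[match(n_ab, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}
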