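## crmenrich: combinatorial cis-regulatory-module (CRM) definitions from
## ChIP-seq peak sets and trend-based enrichment of small association
## P-values inside annotated regions.

#' Define active and active+primed CRMs from peak tracks
#'
#' `active`: peaks bound by p300 or TFAP2A that have an H3K27ac peak within
#' `proximity_bp` (overlap counts as distance 0; the gap between nearest
#' edges is compared to the threshold). `active_and_primed`: the active CRMs
#' plus regions enriched in both H3K27ac and H3K4me1 (emitted as the
#' H3K27ac intervals that overlap an H3K4me1 peak). Both outputs are
#' normalized (sorted, merged) tracks.
#'
#' @param p300,tfap2a,k27ac,k4me1 [annotation_track()] peak sets.
#' @param proximity_bp Maximum edge-to-edge gap to H3K27ac (default 1000).
#' @return List with `active` and `active_and_primed` tracks.
#' @export
define_crms <- function(p300, tfap2a, k27ac, k4me1, proximity_bp = 1000) {
  check_number(proximity_bp, "proximity_bp", lower = 0)
  bound <- annotation_track(rbind(.track_df(p300), .track_df(tfap2a)))
  near_k27 <- .has_neighbor(bound, k27ac, proximity_bp)
  active <- annotation_track(.track_df(bound)[near_k27, , drop = FALSE])
  primed <- .has_neighbor(k27ac, k4me1, 0)   # gap 0 = overlap required
  both <- annotation_track(rbind(.track_df(active),
                                 .track_df(k27ac)[primed, , drop = FALSE]))
  list(active = active, active_and_primed = both)
}

.track_df <- function(x) {
  df <- as.data.frame(x)[, intersect(c("chrom", "start", "end", "label"),
                                     names(x)), drop = FALSE]
  df
}

## TRUE per interval of `a` having an interval of `b` within `gap` bp on the
## same chromosome (edge-to-edge distance; overlapping intervals distance 0).
.has_neighbor <- function(a, b, gap) {
  if (nrow(a) == 0L) return(logical(0))
  out <- logical(nrow(a))
  if (nrow(b) == 0L) return(out)
  for (ch in unique(a$chrom)) {
    ai <- which(a$chrom == ch)
    bi <- which(b$chrom == ch)
    if (!length(bi)) next
    ra <- IRanges::IRanges(a$start[ai] + 1L, a$end[ai])
    rb <- IRanges::IRanges(b$start[bi] + 1L, b$end[bi])
    ## distance() is 0 for overlap/adjacency; a gap of g bp between
    ## half-open intervals corresponds to distance g
    d <- rep(Inf, length(ai))
    nearest <- IRanges::distanceToNearest(ra, rb)
    d[S4Vectors::from(nearest)] <- S4Vectors::mcols(nearest)$distance
    out[ai] <- d <= gap
  }
  out
}

#' P-value binning scheme
#'
#' `"groups"`: nine ordered categories `10^(-k+1) >= P > 10^-k` for
#' k = 1..8, plus a ninth category `P <= 10^-8` (upper bounds inclusive,
#' lower bounds exclusive). `"nominal"`: two categories, `P > 0.05` and
#' `P <= 0.05`. Categories are ordered from largest to smallest P, so a
#' positive trend over categories means enrichment at smaller P.
#'
#' @param scheme `"groups"` or `"nominal"`.
#' @return An object of class `binning_scheme` with inclusive upper bounds.
#' @export
binning_scheme <- function(scheme = c("groups", "nominal")) {
  scheme <- match.arg(scheme)
  upper <- if (scheme == "groups") 10^-(0:8) else c(1, 0.05)
  structure(list(name = scheme, upper = upper,
                 n_categories = length(upper)),
            class = "binning_scheme")
}

#' Assign P-values to scheme categories
#'
#' @param p P-values in (0, 1].
#' @param scheme A [binning_scheme()] or scheme name.
#' @return Integer category per value (1 = largest-P category).
#' @export
bin_pvalues <- function(p, scheme = binning_scheme("groups")) {
  if (is.character(scheme)) scheme <- binning_scheme(scheme)
  check_that(all(p > 0 & p <= 1), "p", "P-values must lie in (0, 1]")
  up <- scheme$upper
  ## category k is up[k] >= P > up[k+1]; the last category has no lower bound
  k <- rep(1L, length(p))
  for (j in 2:length(up)) k[p <= up[j]] <- j
  k
}

#' Flag variants inside an annotation track
#'
#' A variant is inside iff its position lies in a half-open `[start, end)`
#' interval of the track on the same chromosome. Variant chromosomes absent
#' from a non-empty track are reported (they may indicate a naming
#' mismatch), not silently counted as outside.
#'
#' @param stats An `assoc_table` (needs `chr`, `pos`).
#' @param track An [annotation_track()].
#' @return Logical vector, one flag per variant.
#' @export
annotate_overlap <- function(stats, track) {
  inside <- logical(nrow(stats))
  if (nrow(track) == 0L) return(inside)
  unknown <- setdiff(unique(stats$chr), unique(track$chrom))
  if (length(unknown) && length(intersect(unique(stats$chr), track$chrom)) == 0L)
    warning("no variant chromosome matches the track (labels: ",
            paste(unknown, collapse = ", "), ")")
  for (ch in intersect(unique(stats$chr), unique(track$chrom))) {
    si <- which(stats$chr == ch)
    tr <- track[track$chrom == ch, , drop = FALSE]
    ## normalized track: disjoint sorted intervals; position in [start, end)
    idx <- findInterval(stats$pos[si], tr$start)
    hit <- idx >= 1 & stats$pos[si] < tr$end[pmax(idx, 1L)]
    inside[si] <- hit
  }
  inside
}

#' Category x in/out contingency table for an annotation track
#'
#' @param stats An `assoc_table` with valid `p`.
#' @param track An [annotation_track()].
#' @param scheme A [binning_scheme()] or name.
#' @return Integer matrix (categories x 2: `inside`, `outside`), ordered
#'   from largest- to smallest-P category.
#' @export
enrichment_table <- function(stats, track, scheme = binning_scheme("groups")) {
  if (is.character(scheme)) scheme <- binning_scheme(scheme)
  ok <- !is.na(stats$p)
  stats <- stats[ok, , drop = FALSE]
  cat_ <- bin_pvalues(stats$p, scheme)
  inside <- annotate_overlap(stats, track)
  tab <- table(factor(cat_, levels = seq_len(scheme$n_categories)),
               factor(inside, levels = c(TRUE, FALSE)))
  m <- matrix(as.integer(tab), ncol = 2,
              dimnames = list(category = rownames(tab),
                              c("inside", "outside")))
  m
}

#' One-sided Cochran-Armitage trend test for annotation enrichment
#'
#' Tests whether the proportion of variants inside annotated regions
#' increases toward smaller-P categories, on a categories x 2 table whose
#' rows are ordered from largest- to smallest-P category. Scores are the
#' equally spaced integers 1..K (the statistic is invariant to affine score
#' changes); the one-sided P is `P(Z >= z)` where positive `z` means a
#' higher in-annotation fraction at smaller P. With two categories the
#' two-sided version coincides with the 1-df chi-square test.
#'
#' @param tab Categories x 2 integer matrix (`inside`, `outside`), or the
#'   inputs of [enrichment_table()] via `stats`, `track`, `scheme`.
#' @param one_sided Return the one-sided enrichment P (default) or two-sided.
#' @return An object of class `enrichment_result`: `table`, `chisq`, `z`,
#'   `p` (one-sided unless `one_sided = FALSE`), `n_snps`, and the reason if
#'   the table is degenerate.
#' @export
trend_enrichment_test <- function(tab, one_sided = TRUE) {
  check_that(is.matrix(tab) && ncol(tab) == 2L && nrow(tab) >= 2L &&
               all(tab >= 0), "tab",
             "needs a categories x 2 matrix of non-negative counts")
  K <- nrow(tab)
  s <- seq_len(K)
  n_i <- rowSums(tab)
  N <- sum(n_i)
  R <- sum(tab[, 1])            # total inside
  res <- structure(list(table = tab, chisq = NA_real_, z = NA_real_,
                        p = NA_real_, n_snps = N, one_sided = one_sided,
                        reason = NULL),
                   class = "enrichment_result")
  if (N == 0 || R == 0 || R == N || sum(n_i > 0) < 2) {
    res$reason <- "degenerate table (empty margin)"
    return(res)
  }
  num <- N * sum(s * tab[, 1]) - R * sum(s * n_i)
  den <- R * (N - R) * (N * sum(s^2 * n_i) - sum(s * n_i)^2)
  if (den <= 0) {
    res$reason <- "degenerate table (no score variance)"
    return(res)
  }
  res$chisq <- N * num^2 / den
  res$z <- sign(num) * sqrt(res$chisq)
  res$p <- if (one_sided) pnorm(res$z, lower.tail = FALSE)
           else p_from_z(res$z)
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("trend enrichment: %d SNPs, %d categories, z = %.3f, %s P = %s\n",
              x$n_snps, nrow(x$table), x$z,
              if (x$one_sided) "one-sided" else "two-sided",
              format(x$p, digits = 4)))
  if (!is.null(x$reason)) cat("  note:", x$reason, "\n")
  invisible(x)
}

#' End-to-end enrichment analysis of an association table against a track
#'
#' Counts SNPs inside/outside the track per P-value category and applies the
#' one-sided trend test; the output mirrors a per-annotation results row
#' (number of regions, number of SNPs, P per scheme).
#'
#' @param stats An `assoc_table`.
#' @param track An [annotation_track()].
#' @param schemes Character vector of scheme names to run.
#' @return Data frame with one row per scheme: `scheme`, `n_regions`,
#'   `n_snps`, `z`, `p_one_sided`.
#' @export
crm_enrichment <- function(stats, track, schemes = c("groups", "nominal")) {
  rows <- lapply(schemes, function(sc) {
    tab <- enrichment_table(stats, track, sc)
    r <- trend_enrichment_test(tab)
    data.frame(scheme = sc, n_regions = nrow(track), n_snps = r$n_snps,
               z = r$z, p_one_sided = r$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
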