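## finemap: Bayesian refinement of association signals into credible SNP
## sets over recombination-distance windows.

#' Genomic interval at a fixed genetic distance around an index variant
#'
#' Returns the smallest physical interval whose ends are at least
#' `half_width_cm` centimorgans from the index position on the cumulative-cM
#' scale of the recombination map (linear interpolation between map knots).
#' Ends beyond the map are clipped to the map boundary with a warning.
#'
#' @param index_pos Index variant position (bp), must be covered by the map.
#' @param map A `recomb_map` (see [read_recomb_map()]).
#' @param half_width_cm Genetic half-width in cM (default 0.1).
#' @return Numeric `c(start, end)` in bp (closed physical interval).
#' @export
define_interval <- function(index_pos, map, half_width_cm = 0.1) {
  check_number(half_width_cm, "half_width_cm", lower = 0, open_lower = TRUE)
  rng <- range(map$position_bp)
  check_that(index_pos >= rng[1] && index_pos <= rng[2], "index_pos",
             "not covered by the recombination map")
  cm0 <- cm_at(map, index_pos)
  target <- c(cm0 - half_width_cm, cm0 + half_width_cm)
  cm_rng <- range(map$cM)
  clipped <- target[1] < cm_rng[1] || target[2] > cm_rng[2]
  target <- pmin(pmax(target, cm_rng[1]), cm_rng[2])
  ## invert the (non-decreasing) cumulative-cM curve; for flat stretches take
  ## the smallest interval, i.e. the innermost bp consistent with the target
  inv <- function(cm, side) {
    hit <- approx(map$cM, map$position_bp, xout = cm, rule = 2,
                  ties = if (side == "left") max else min)$y
    hit
  }
  out <- c(inv(target[1], "left"), inv(target[2], "right"))
  if (clipped)
    warning("interval clipped at the recombination-map boundary")
  out
}

#' Wakefield approximate Bayes factor
#'
#' Summary-statistic Bayes factor in favour of association for a variant
#' with estimated effect `beta` and standard error `se`, under a
#' `N(0, prior_sd^2)` prior on the true log relative risk:
#' `BF = sqrt(V / (V + W)) * exp(z^2 W / (2 (V + W)))` with `V = se^2`,
#' `W = prior_sd^2`, `z = beta / se`. Computed on the log scale.
#'
#' @param beta Effect estimate (log RR scale).
#' @param se Standard error (> 0).
#' @param prior_sd Prior standard deviation of the effect (default 0.2).
#' @param log Return the natural-log BF instead of the BF.
#' @return Bayes factor (or its log), vectorized over `beta`/`se`.
#' @export
approx_bayes_factor <- function(beta, se, prior_sd = 0.2, log = FALSE) {
  check_that(all(se > 0), "se", "must be positive")
  check_number(prior_sd, "prior_sd", lower = 0, open_lower = TRUE)
  v <- se^2
  w <- prior_sd^2
  z <- beta / se
  lbf <- 0.5 * (base::log(v) - base::log(v + w)) + z^2 * w / (2 * (v + w))
  if (log) lbf else exp(lbf)
}

#' Credible SNP set from interval association statistics
#'
#' Under a single-causal-variant assumption, the posterior probability that
#' variant *j* is causal is its Bayes factor normalized over all variants in
#' the interval, `post_j = BF_j / sum(BF_k)` (computed as
#' `exp(logBF_j - logsumexp(logBF))`). Variants are ranked by descending
#' posterior (ties broken by ascending position); the member set at each
#' level is the shortest prefix whose cumulative posterior reaches the
#' level, hence minimal and nested across levels.
#'
#' @param stats An `assoc_table` restricted to the interval (needs `snp`,
#'   `pos`, `beta`, `se`; rows with missing beta/se are dropped).
#' @param levels Credible levels (default `c(0.95, 0.99)`).
#' @param prior_sd Prior SD passed to [approx_bayes_factor()].
#' @return An object of class `credible_set`: `table` (per-variant logBF,
#'   posterior, cumulative posterior, per-level membership flags, ranked),
#'   `sets` (list of member id vectors per level), `attained` (cumulative
#'   probability reached), `span` (bp range of each member set), `index`
#'   (top-posterior variant).
#' @export
credible_set <- function(stats, levels = c(0.95, 0.99), prior_sd = 0.2) {
  check_that(all(levels > 0 & levels < 1), "levels", "must lie in (0, 1)")
  keep <- !is.na(stats$beta) & !is.na(stats$se) & stats$se > 0 &
    is.finite(stats$beta)
  s <- as.data.frame(stats)[keep, , drop = FALSE]
  check_that(nrow(s) > 0L, "stats", "no variant with finite beta/se in interval")
  lbf <- approx_bayes_factor(s$beta, s$se, prior_sd, log = TRUE)
  post <- exp(lbf - logsumexp(lbf))
  ord <- order(-post, s$pos)
  s <- s[ord, , drop = FALSE]
  tab <- data.frame(snp = s$snp, pos = s$pos, logbf = lbf[ord],
                    posterior = post[ord], cumulative = cumsum(post[ord]),
                    stringsAsFactors = FALSE)
  sets <- list(); attained <- numeric(0); span <- list()
  for (lv in sort(levels)) {
    k <- match(TRUE, tab$cumulative >= lv - 1e-12)
    if (is.na(k)) k <- nrow(tab)   # numerical guard; cumulative ends at 1
    ids <- tab$snp[seq_len(k)]
    key <- format(lv)
    sets[[key]] <- ids
    attained[key] <- tab$cumulative[k]
    span[[key]] <- range(tab$pos[seq_len(k)])
    tab[[paste0("in", sub("^0\\.", "", key))]] <- seq_len(nrow(tab)) <= k
  }
  structure(list(index = tab$snp[1], table = tab, sets = sets,
                 attained = attained, span = span, levels = sort(levels)),
            class = "credible_set")
}

#' @export
print.credible_set <- function(x, ...) {
  cat(sprintf("credible_set: index %s, %d variants in interval\n",
              x$index, nrow(x$table)))
  for (key in names(x$sets))
    cat(sprintf("  %s%% set: %d SNPs, span %s-%s bp (attained %.4f)\n",
                format(100 * as.numeric(key)), length(x$sets[[key]]),
                format(x$span[[key]][1]), format(x$span[[key]][2]),
                x$attained[key]))
  invisible(x)
}

#' Credible sets allowing multiple independent signals in an interval
#'
#' Performs a conditional association scan over the interval with the index
#' variant as covariate. If any conditional P falls below
#' `secondary_p_threshold`, a second independent signal is declared at the
#' smallest conditional P, and each signal's credible set is computed from
#' an association scan that conditions on the *other* signal's lead.
#' Otherwise a single (unconditional) credible set is returned.
#'
#' @param cohort A `cc_cohort` (individual-level data; required for
#'   conditioning).
#' @param interval_variants Variant ids (or indices) inside the interval.
#' @param index Index variant id.
#' @param secondary_p_threshold Conditional-P threshold for declaring a
#'   second signal (default 1e-3).
#' @param levels,prior_sd Passed to [credible_set()].
#' @param covariates Covariates for the logistic model (default: cohort's).
#' @return List of `credible_set` objects (length 1 or 2).
#' @export
multi_signal_refine <- function(cohort, interval_variants, index,
                                secondary_p_threshold = 1e-3,
                                levels = c(0.95, 0.99), prior_sd = 0.2,
                                covariates = NULL) {
  check_number(secondary_p_threshold, "secondary_p_threshold", lower = 0,
               upper = 1, open_lower = TRUE)
  if (is.numeric(interval_variants))
    interval_variants <- cohort$variants$id[interval_variants]
  check_that(index %in% interval_variants, "index",
             "index variant must belong to the interval")
  cond <- logistic_assoc(cohort, covariates = covariates,
                         condition_on = index, variants = interval_variants)
  cond_ok <- cond[!is.na(cond$p) & cond$snp != index &
                    !(cond$flag %in% "collinear"), , drop = FALSE]
  second <- NULL
  if (nrow(cond_ok) && min(cond_ok$p) < secondary_p_threshold)
    second <- cond_ok$snp[which.min(cond_ok$p)]

  if (is.null(second)) {
    a <- logistic_assoc(cohort, covariates = covariates,
                        variants = interval_variants)
    return(list(credible_set(a, levels, prior_sd)))
  }
  a1 <- logistic_assoc(cohort, covariates = covariates, condition_on = second,
                       variants = setdiff(interval_variants, second))
  a2 <- logistic_assoc(cohort, covariates = covariates, condition_on = index,
                       variants = setdiff(interval_variants, index))
  list(credible_set(a1, levels, prior_sd),
       credible_set(a2, levels, prior_sd))
}

#' Export a credible set as a machine-readable table
#'
#' One row per interval member with Bayes factor, posterior, cumulative
#' posterior and per-level membership flags.
#'
#' @param x A `credible_set`.
#' @param path Optional TSV output path.
#' @return The table (invisibly writes to `path` when given).
#' @export
credible_set_table <- function(x, path = NULL) {
  stopifnot(inherits(x, "credible_set"))
  tab <- x$table
  tab$bf <- exp(tab$logbf)
  if (!is.null(path))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
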