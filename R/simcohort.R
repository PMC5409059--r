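## simcohort: synthetic haplotypes, cohorts, trios, dosage degradation and
## annotation tracks with known ground truth.

#' Simulate a haplotype panel with block linkage disequilibrium
#'
#' Generates `n_haplotypes` binary haplotypes over `n_variants` sites on a
#' single synthetic chromosome. Variants are grouped into consecutive blocks
#' of `block_size`; within a block, haplotype alleles follow a Gaussian-copula
#' AR(1) latent process with parameter `within_block_correlation`, so adjacent
#' variants in a block are correlated while variants in distinct blocks are
#' generated independently. Allele frequencies are drawn uniformly from
#' `maf_range` and positions are evenly spaced over `genome_length`.
#'
#' @param n_haplotypes Number of haplotypes (>= 4).
#' @param n_variants Number of variant sites (>= 1).
#' @param maf_range Length-2 numeric, target allele-frequency range in (0, 0.5].
#' @param block_size Number of variants per LD block.
#' @param within_block_correlation Latent AR(1) correlation in \[0, 1).
#' @param genome_length Chromosome length in bp.
#' @param seed Integer seed; identical seeds give byte-identical panels.
#' @return An object of class `haplotype_panel` with elements `haplotypes`
#'   (`n_haplotypes` x `n_variants` 0/1 matrix), `positions`, `freq`
#'   (realized alternate-allele frequencies), `blocks` (list of variant index
#'   vectors), `genome_length`, `rho`, and `seed`.
#' @export
simulate_panel <- function(n_haplotypes, n_variants,
                           maf_range = c(0.05, 0.5), block_size = 10,
                           within_block_correlation = 0.8,
                           genome_length = 1e6, seed = 1) {
  n_haplotypes <- check_count(n_haplotypes, "n_haplotypes", min = 4L)
  n_variants <- check_count(n_variants, "n_variants", min = 1L)
  block_size <- check_count(block_size, "block_size", min = 1L)
  check_that(is.numeric(maf_range) && length(maf_range) == 2L &&
               all(maf_range > 0) && all(maf_range <= 0.5) &&
               maf_range[1] <= maf_range[2],
             "maf_range", "must be an increasing pair within (0, 0.5]")
  check_number(within_block_correlation, "within_block_correlation",
               lower = 0, upper = 1, open_upper = TRUE)
  check_number(genome_length, "genome_length", lower = n_variants,
               open_lower = TRUE)

  blocks <- split(seq_len(n_variants),
                  (seq_len(n_variants) - 1L) %/% block_size)
  names(blocks) <- NULL
  rho <- within_block_correlation

  with_seed(seed, {
    p <- runif(n_variants, maf_range[1], maf_range[2])
    H <- .copula_haplotypes(n_haplotypes, p, blocks, rho)
  })

  positions <- round(seq_len(n_variants) * genome_length / (n_variants + 1))
  ## strictly increasing even when the grid is dense enough that rounding ties
  if (n_variants > 1L && any(diff(positions) <= 0))
    positions <- seq_len(n_variants)

  structure(list(haplotypes = H, positions = as.integer(positions),
                 freq = colMeans(H), target_freq = p, blocks = blocks,
                 genome_length = genome_length, rho = rho, seed = seed),
            class = "haplotype_panel")
}

## Latent AR(1) Gaussian copula haplotypes; guarantees polymorphism by
## flipping one random entry of any monomorphic column.
.copula_haplotypes <- function(n_hap, p, blocks, rho) {
  m <- length(p)
  H <- matrix(0L, n_hap, m)
  thr <- qnorm(p)
  for (b in blocks) {
    z <- matrix(rnorm(n_hap * length(b)), n_hap, length(b))
    if (rho > 0 && length(b) > 1L) {
      for (k in 2:length(b))
        z[, k] <- rho * z[, k - 1L] + sqrt(1 - rho^2) * z[, k]
    }
    H[, b] <- (z < rep(thr[b], each = n_hap)) + 0L
  }
  mono <- which(colMeans(H) %in% c(0, 1))
  for (j in mono) {
    i <- sample.int(n_hap, 1L)
    H[i, j] <- 1L - H[i, j]
  }
  H
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes x %d variants, %d blocks (rho = %.2f), %s bp\n",
              nrow(x$haplotypes), ncol(x$haplotypes), length(x$blocks),
              x$rho, format(x$genome_length, big.mark = ",")))
  invisible(x)
}

#' Multiplicative disease risk model
#'
#' Defines disease risk from genotype. The default `"logistic"` type is
#' multiplicative on the odds scale: one copy of the risk (alternate) allele
#' at causal variant *j* multiplies the odds by `exp(log_rr[j])`; the
#' intercept is solved numerically so the population prevalence matches
#' `prevalence`. At low prevalence (0.1% is the conventional assumption for
#' nonsyndromic cleft lip/palate) relative risk and odds ratio coincide. The
#' `"liability"` type places a latent Gaussian threshold model with total
#' genetic liability variance `h2` split across causal variants in
#' proportion to `log_rr^2`.
#'
#' @param causal Integer indices of causal variants in a panel (may be empty).
#' @param log_rr Per-variant log relative risk (logistic) or relative effect
#'   weights (liability); recycled against `causal`.
#' @param prevalence Baseline disease prevalence in (0, 0.5).
#' @param type `"logistic"` or `"liability"`.
#' @param h2 Liability-scale genetic variance in \[0, 1) (`"liability"` only).
#' @return An object of class `risk_model`.
#' @export
risk_model <- function(causal = integer(0), log_rr = numeric(0),
                       prevalence = 0.001, type = c("logistic", "liability"),
                       h2 = NULL) {
  type <- match.arg(type)
  check_number(prevalence, "prevalence", lower = 0, upper = 0.5,
               open_lower = TRUE, open_upper = TRUE)
  causal <- as.integer(causal)
  if (length(causal)) log_rr <- rep_len(log_rr, length(causal))
  check_that(all(is.finite(log_rr)), "log_rr", "must be finite")
  if (type == "liability") {
    check_number(h2, "h2", lower = 0, upper = 1, open_upper = TRUE)
    check_that(length(causal) > 0L || h2 == 0, "causal",
               "liability model with h2 > 0 needs causal variants")
  }
  structure(list(causal = causal, log_rr = as.numeric(log_rr),
                 prevalence = prevalence, type = type, h2 = h2),
            class = "risk_model")
}

## Per-stratum haplotype pool: stratum 1 is the panel itself; higher strata
## are regenerated with allele frequencies shifted by `delta`, preserving the
## block/correlation structure (a crude but controllable ancestry axis).
.stratum_pools <- function(panel, n_strata, delta, seed) {
  pools <- vector("list", n_strata)
  pools[[1L]] <- panel$haplotypes
  if (n_strata > 1L) {
    for (s in 2:n_strata) {
      p_s <- pmin(pmax(panel$target_freq + (s - 1L) * delta, 0.02), 0.98)
      pools[[s]] <- with_seed(seed + 7919L * s,
        .copula_haplotypes(nrow(panel$haplotypes), p_s, panel$blocks, panel$rho))
    }
  }
  pools
}

## Solve the logistic intercept so that E[expit(b0 + beta'g)] = K over the
## causal genotype distribution of the given haplotype pool (Monte Carlo).
.solve_intercept <- function(pool, model, prevalence, n_mc = 50000L) {
  if (length(model$causal) == 0L)
    return(qlogis(prevalence))
  n_hap <- nrow(pool)
  i <- sample.int(n_hap, n_mc, replace = TRUE)
  j <- sample.int(n_hap, n_mc, replace = TRUE)
  eta_g <- (pool[i, model$causal, drop = FALSE] +
            pool[j, model$causal, drop = FALSE]) %*% model$log_rr
  f <- function(b0) mean(plogis(b0 + eta_g)) - prevalence
  stats::uniroot(f, c(-40, 10), tol = 1e-10)$root
}

#' Simulate an ascertained case-control cohort
#'
#' Draws individuals as random haplotype pairs from the panel, assigns disease
#' status under the risk model, and retains them by rejection sampling until
#' the requested case and control counts are met. With `n_strata > 1`,
#' individuals come from strata whose allele frequencies are shifted by
#' `stratum_freq_shift` and whose prevalence is multiplied by
#' `stratum_prev_mult` per stratum step, creating population-stratification
#' confounding; stratum indicators are returned as ancestry covariates.
#'
#' @param panel A [simulate_panel()] result.
#' @param model A [risk_model()].
#' @param n_cases,n_controls Target counts.
#' @param n_strata Number of population strata (default 1, no confounding).
#' @param stratum_freq_shift Allele-frequency shift per stratum step.
#' @param stratum_prev_mult Prevalence multiplier per stratum step.
#' @param seed Integer seed.
#' @param max_draws Rejection-sampling budget; exhaustion is an error.
#' @return An object of class `cc_cohort`: list with `dosages` (samples x
#'   variants genotype/dosage matrix), `variants` data frame, `status`
#'   (1 = case), `strata`, `covariates` (ancestry axes; zero columns when
#'   `n_strata == 1`), and `model`.
#' @export
simulate_case_control <- function(panel, model, n_cases, n_controls,
                                  n_strata = 1, stratum_freq_shift = 0,
                                  stratum_prev_mult = 3, seed = 1,
                                  max_draws = 1e7) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(model, "risk_model"))
  n_cases <- check_count(n_cases, "n_cases")
  n_controls <- check_count(n_controls, "n_controls", min = 0L)
  n_strata <- check_count(n_strata, "n_strata")
  m <- ncol(panel$haplotypes)
  check_that(all(model$causal >= 1 & model$causal <= m), "model",
             "causal variant indices outside the panel")

  with_seed(seed, {
    pools <- .stratum_pools(panel, n_strata, stratum_freq_shift, seed)
    liab <- model$type == "liability"
    if (liab) {
      w <- .liability_weights(model, panel)
      thr <- qnorm(1 - model$prevalence)
    } else {
      b0 <- vapply(seq_len(n_strata), function(s)
        .solve_intercept(pools[[s]],
                         model,
                         min(model$prevalence * stratum_prev_mult^(s - 1L), 0.5)),
        numeric(1))
    }

    acc_i <- integer(0); acc_j <- integer(0); acc_s <- integer(0)
    acc_y <- integer(0)
    need <- function() sum(acc_y == 1L) < n_cases || sum(acc_y == 0L) < n_controls
    drawn <- 0L
    batch <- max(2L * (n_cases + n_controls), 1000L)
    while (need()) {
      if (drawn >= max_draws)
        stop("rejection-sampling budget `max_draws` exhausted before reaching ",
             "the requested case/control counts", call. = FALSE)
      b <- as.integer(min(batch, max_draws - drawn)); drawn <- drawn + b
      s <- sample.int(n_strata, b, replace = TRUE)
      n_hap <- nrow(panel$haplotypes)
      i <- sample.int(n_hap, b, replace = TRUE)
      j <- sample.int(n_hap, b, replace = TRUE)
      if (length(model$causal)) {
        gci <- matrix(0L, b, length(model$causal))
        for (st in unique(s)) {
          sel <- s == st
          gci[sel, ] <- pools[[st]][i[sel], model$causal, drop = FALSE] +
            pools[[st]][j[sel], model$causal, drop = FALSE]
        }
      } else gci <- matrix(0L, b, 0L)
      if (liab) {
        gl <- if (length(model$causal))
          as.numeric(scale(gci, center = 2 * panel$freq[model$causal],
                           scale = FALSE) %*% w) else numeric(b)
        y <- as.integer(gl + rnorm(b, 0, sqrt(1 - model$h2)) > thr)
      } else {
        eta <- b0[s] + if (length(model$causal))
          as.numeric(gci %*% model$log_rr) else 0
        y <- rbinom(b, 1L, plogis(eta))
      }
      keep_case <- which(y == 1L)[seq_len(min(sum(y == 1L),
                                              n_cases - sum(acc_y == 1L)))]
      keep_ctrl <- which(y == 0L)[seq_len(min(sum(y == 0L),
                                              n_controls - sum(acc_y == 0L)))]
      keep <- c(keep_case, keep_ctrl)
      acc_i <- c(acc_i, i[keep]); acc_j <- c(acc_j, j[keep])
      acc_s <- c(acc_s, s[keep]); acc_y <- c(acc_y, y[keep])
    }
    ord <- order(acc_y, decreasing = TRUE)
    acc_i <- acc_i[ord]; acc_j <- acc_j[ord]; acc_s <- acc_s[ord]
    acc_y <- acc_y[ord]
    n <- length(acc_y)
    G <- matrix(0L, n, m)
    for (st in unique(acc_s)) {
      sel <- acc_s == st
      G[sel, ] <- pools[[st]][acc_i[sel], , drop = FALSE] +
        pools[[st]][acc_j[sel], , drop = FALSE]
    }
  })

  vr <- .panel_variants(panel)
  colnames(G) <- vr$id
  rownames(G) <- sprintf("S%05d", seq_len(nrow(G)))
  cov <- if (n_strata > 1L) {
    cm <- outer(acc_s, 2:n_strata, `==`) + 0
    colnames(cm) <- paste0("stratum", 2:n_strata)
    cm
  } else matrix(numeric(0), nrow(G), 0L)
  structure(list(dosages = G, variants = vr, status = acc_y,
                 strata = acc_s, covariates = cov, model = model,
                 seed = seed),
            class = "cc_cohort")
}

## Weights on centred genotypes so the genetic liability variance is h2
## (per-variant variance w_j^2 * 2 p_j (1 - p_j), split in proportion to
## log_rr^2).
.liability_weights <- function(model, panel) {
  a <- model$log_rr / sqrt(sum(model$log_rr^2)) * sqrt(model$h2)
  p <- panel$freq[model$causal]
  a / sqrt(2 * p * (1 - p))
}

.panel_variants <- function(panel) {
  m <- ncol(panel$haplotypes)
  ids <- if (!is.null(panel$ids)) panel$ids else sprintf("snp%05d", seq_len(m))
  data.frame(id = ids, chrom = "chr1",
             pos = panel$positions, ref = "A", alt = "G",
             freq = panel$freq, info = 1, stringsAsFactors = FALSE)
}

#' Subset a haplotype panel by variant
#'
#' Keeps the selected variant columns (original identifiers are preserved on
#' cohorts simulated from the subset); block structure collapses to the
#' surviving per-block runs.
#'
#' @param panel A [simulate_panel()] result.
#' @param j Variant column indices.
#' @return A `haplotype_panel`.
#' @export
subset_panel <- function(panel, j) {
  j <- sort(unique(as.integer(j)))
  check_that(all(j >= 1 & j <= ncol(panel$haplotypes)), "j",
             "variant index outside the panel")
  ids <- .panel_variants(panel)$id[j]
  block_of <- rep(seq_along(panel$blocks), lengths(panel$blocks))
  new_blocks <- unname(split(seq_along(j), block_of[j]))
  structure(list(haplotypes = panel$haplotypes[, j, drop = FALSE],
                 positions = panel$positions[j], freq = panel$freq[j],
                 target_freq = panel$target_freq[j], blocks = new_blocks,
                 genome_length = panel$genome_length, rho = panel$rho,
                 seed = panel$seed, ids = ids),
            class = "haplotype_panel")
}

#' @export
print.cc_cohort <- function(x, ...) {
  cat(sprintf("cc_cohort: %d cases / %d controls x %d variants (%d strata)\n",
              sum(x$status == 1), sum(x$status == 0), ncol(x$dosages),
              length(unique(x$strata))))
  invisible(x)
}

#' Simulate ascertained case-parent trios
#'
#' Parents are random haplotype pairs from the panel (or stratum pools);
#' each parent transmits one uniformly chosen haplotype to the child, and the
#' trio is retained only if the child is affected under the risk model
#' (rejection sampling). Mendelian consistency holds exactly because child
#' genotypes are literal sums of transmitted parental haplotypes.
#'
#' @inheritParams simulate_case_control
#' @param n_trios Number of affected-child trios to retain.
#' @return An object of class `trio_cohort`: `child`, `father`, `mother`
#'   genotype matrices (trios x variants), `t_father`/`t_mother` transmitted
#'   allele matrices, `variants`, `strata`.
#' @export
simulate_trios <- function(panel, model, n_trios, n_strata = 1,
                           stratum_freq_shift = 0, stratum_prev_mult = 3,
                           seed = 1, max_draws = 1e7) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(model, "risk_model"))
  n_trios <- check_count(n_trios, "n_trios")
  n_strata <- check_count(n_strata, "n_strata")
  m <- ncol(panel$haplotypes)
  check_that(all(model$causal >= 1 & model$causal <= m), "model",
             "causal variant indices outside the panel")

  with_seed(seed, {
    pools <- .stratum_pools(panel, n_strata, stratum_freq_shift, seed)
    b0 <- vapply(seq_len(n_strata), function(s)
      .solve_intercept(pools[[s]], model,
                       min(model$prevalence * stratum_prev_mult^(s - 1L), 0.5)),
      numeric(1))
    n_hap <- nrow(panel$haplotypes)
    keep <- list(); kept <- 0L; drawn <- 0L
    batch <- max(ceiling(2 * n_trios / max(model$prevalence, 1e-3)), 1000L)
    batch <- min(batch, 500000L)
    while (kept < n_trios) {
      if (drawn >= max_draws)
        stop("rejection-sampling budget `max_draws` exhausted before ",
             "ascertaining the requested number of affected-child trios",
             call. = FALSE)
      b <- as.integer(min(batch, max_draws - drawn)); drawn <- drawn + b
      s <- sample.int(n_strata, b, replace = TRUE)
      f1 <- sample.int(n_hap, b, TRUE); f2 <- sample.int(n_hap, b, TRUE)
      m1 <- sample.int(n_hap, b, TRUE); m2 <- sample.int(n_hap, b, TRUE)
      tf <- ifelse(runif(b) < 0.5, f1, f2)   # haplotype transmitted by father
      tm <- ifelse(runif(b) < 0.5, m1, m2)
      if (length(model$causal)) {
        eta <- b0[s]
        for (st in unique(s)) {
          sel <- s == st
          gc <- pools[[st]][tf[sel], model$causal, drop = FALSE] +
            pools[[st]][tm[sel], model$causal, drop = FALSE]
          eta[sel] <- eta[sel] + as.numeric(gc %*% model$log_rr)
        }
      } else eta <- b0[s]
      aff <- rbinom(b, 1L, plogis(eta)) == 1L
      idx <- which(aff)
      if (length(idx)) {
        idx <- idx[seq_len(min(length(idx), n_trios - kept))]
        keep[[length(keep) + 1L]] <-
          cbind(f1, f2, m1, m2, tf, tm, s)[idx, , drop = FALSE]
        kept <- kept + length(idx)
      }
    }
    K <- do.call(rbind, keep)
    strata <- as.integer(K[, "s"])
    child <- father <- mother <- t_f <- t_m <- matrix(0L, n_trios, m)
    for (st in unique(strata)) {
      sel <- strata == st
      P <- pools[[st]]
      father[sel, ] <- P[K[sel, "f1"], , drop = FALSE] + P[K[sel, "f2"], , drop = FALSE]
      mother[sel, ] <- P[K[sel, "m1"], , drop = FALSE] + P[K[sel, "m2"], , drop = FALSE]
      t_f[sel, ] <- P[K[sel, "tf"], , drop = FALSE]
      t_m[sel, ] <- P[K[sel, "tm"], , drop = FALSE]
    }
    child <- t_f + t_m
  })

  vr <- .panel_variants(panel)
  colnames(child) <- colnames(father) <- colnames(mother) <- vr$id
  colnames(t_f) <- colnames(t_m) <- vr$id
  structure(list(child = child, father = father, mother = mother,
                 t_father = t_f, t_mother = t_m, variants = vr,
                 strata = strata, model = model, seed = seed),
            class = "trio_cohort")
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat(sprintf("trio_cohort: %d affected-child trios x %d variants\n",
              nrow(x$child), ncol(x$child)))
  invisible(x)
}

#' Degrade hard genotypes into imputation-like dosages
#'
#' Emulates imputation uncertainty: genotypes are shrunk toward the variant
#' mean and perturbed with Gaussian noise so that the realized info score
#' (`var(dosage) / (2 p (1 - p))`, the ratio definition used by the QC
#' filters) matches `target_info`. A fraction `noise_frac` of the target
#' dosage variance comes from additive noise, the rest from the shrunk
#' genotype signal; the default 0.1 reflects that imputation posterior means
#' lose information mostly by shrinkage toward the allele frequency rather
#' than by individual-level scatter, which keeps association rankings stable
#' at high info. `target_info = 1` returns the input unchanged.
#'
#' @param genotypes Numeric matrix of hard genotypes in \{0, 1, 2\}
#'   (samples x variants).
#' @param target_info Target info score in (0, 1].
#' @param seed Integer seed.
#' @param noise_frac Fraction of dosage variance contributed by noise.
#' @return A numeric dosage matrix in \[0, 2\] of the same shape.
#' @export
dosify <- function(genotypes, target_info, seed = 1, noise_frac = 0.1) {
  check_that(is.matrix(genotypes) && all(genotypes %in% c(0, 1, 2)),
             "genotypes", "must be a matrix with values in {0, 1, 2}")
  check_number(target_info, "target_info", lower = 0, upper = 1,
               open_lower = TRUE)
  if (target_info == 1) return(genotypes)
  n <- nrow(genotypes)
  with_seed(seed, {
    D <- genotypes
    for (j in seq_len(ncol(genotypes))) {
      g <- genotypes[, j]
      p <- mean(g) / 2
      bv <- 2 * p * (1 - p)
      vg <- var(g)
      if (bv == 0 || vg == 0) next
      cc <- sqrt(target_info * (1 - noise_frac) * bv / vg)
      d <- mean(g) + cc * (g - mean(g)) +
        rnorm(n, 0, sqrt(target_info * noise_frac * bv))
      ## clamping to [0, 2] removes variance; rescale around the mean until
      ## the realized dosage variance matches the target (few iterations)
      d <- pmin(pmax(d, 0), 2)
      for (it in 1:12) {
        v_cur <- var(d)
        pm <- mean(d) / 2
        if (v_cur == 0 || pm <= 0 || pm >= 1) break
        ## realized-info target, self-consistent with the clamped mean
        adj <- sqrt(target_info * 2 * pm * (1 - pm) / v_cur)
        if (abs(adj - 1) < 5e-4) break
        d <- pmin(pmax(mean(d) + adj * (d - mean(d)), 0), 2)
      }
      D[, j] <- d
    }
    D
  })
}

#' Realized per-variant info score of a dosage matrix
#'
#' Ratio definition: `var(dosage) / (2 p (1 - p))` with `p` the mean dosage
#' over 2. This is the quantity thresholded by imputation QC filters and is
#' computable from dosages alone.
#'
#' @param dosages Samples x variants dosage matrix.
#' @return Numeric vector of info scores (capped at 1 only by sampling noise,
#'   not artificially).
#' @export
info_score <- function(dosages) {
  p <- colMeans(dosages) / 2
  v <- apply(dosages, 2, var)
  ifelse(p %in% c(0, 1), NA_real_, v / (2 * p * (1 - p)))
}

#' Specification of a synthetic annotation track
#'
#' @param n_intervals Number of intervals to place.
#' @param mean_length Mean interval length (bp, exponential lengths).
#' @param anchor_prob Probability that an interval is centred on an
#'   associated variant instead of placed uniformly.
#' @param genome_length Genome length in bp.
#' @param anchor_p Association P-value at or below which a variant counts as
#'   an anchor candidate.
#' @return An object of class `enrichment_spec`.
#' @export
enrichment_spec <- function(n_intervals, mean_length, anchor_prob,
                            genome_length, anchor_p = 5e-4) {
  n_intervals <- check_count(n_intervals, "n_intervals")
  check_number(mean_length, "mean_length", lower = 0, open_lower = TRUE)
  check_number(anchor_prob, "anchor_prob", lower = 0, upper = 1)
  check_number(genome_length, "genome_length", lower = 1)
  check_number(anchor_p, "anchor_p", lower = 0, upper = 1, open_lower = TRUE)
  structure(list(n_intervals = n_intervals, mean_length = mean_length,
                 anchor_prob = anchor_prob, genome_length = genome_length,
                 anchor_p = anchor_p),
            class = "enrichment_spec")
}

#' Simulate an annotation track with controllable enrichment
#'
#' Places intervals either uniformly on the genome or, with probability
#' `spec$anchor_prob`, centred on a randomly chosen anchor variant (by
#' default any variant with association `P <= spec$anchor_p`; override with
#' `anchor_positions`). Output intervals are clipped to the genome, sorted
#' and merged, so the track is a normalized half-open interval set.
#'
#' @param spec An [enrichment_spec()].
#' @param assoc An association table with `pos` and `p` columns.
#' @param seed Integer seed.
#' @param anchor_positions Optional explicit anchor positions (bp).
#' @return An `annotation_track` (see [annotation_track()]).
#' @export
simulate_annotation <- function(spec, assoc, seed = 1,
                                anchor_positions = NULL) {
  stopifnot(inherits(spec, "enrichment_spec"))
  check_that(all(assoc$pos <= spec$genome_length), "spec",
             "genome_length must cover all variant positions")
  if (is.null(anchor_positions)) {
    anchor_positions <- assoc$pos[!is.na(assoc$p) & assoc$p <= spec$anchor_p]
  }
  with_seed(seed, {
    len <- pmax(round(rexp(spec$n_intervals, 1 / spec$mean_length)), 1)
    anchored <- runif(spec$n_intervals) < spec$anchor_prob &
      length(anchor_positions) > 0
    centre <- numeric(spec$n_intervals)
    if (any(anchored))
      centre[anchored] <- sample(rep(anchor_positions, 2), sum(anchored),
                                 replace = TRUE)
    if (any(!anchored))
      centre[!anchored] <- runif(sum(!anchored), 0, spec$genome_length)
    start <- pmax(round(centre - len / 2), 0)
    end <- pmin(start + len, spec$genome_length)
    keep <- end > start
    annotation_track(data.frame(chrom = "chr1", start = start[keep],
                                end = end[keep],
                                stringsAsFactors = FALSE))
  })
}
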