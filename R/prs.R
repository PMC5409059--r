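## prs: polygenic-score construction and evaluation, pseudo-controls,
## the transmitted/non-transmitted trio score, and variance explained by a
## fixed locus panel.

#' Build a polygenic score model from discovery summary statistics
#'
#' Retains discovery variants with `P <= p_threshold` that pass the MAF
#' filter (discovery frequency) and, when target info scores are supplied,
#' an info filter in every target cohort. Optional greedy LD pruning walks
#' variants in ascending-P order (position tie-break) and drops any variant
#' with squared correlation `>= r2_max` to an already-kept variant in the
#' LD panel. Weights are the discovery log relative risks, oriented to the
#' effect allele.
#'
#' @param discovery An `assoc_table` (needs `snp`, `pos`, `effect_allele`,
#'   `freq`, `beta`, `p`).
#' @param p_threshold Discovery P-value threshold P_T.
#' @param prune Apply LD pruning (requires `ld_panel`).
#' @param r2_max Squared-correlation ceiling for retained pairs (default
#'   0.25).
#' @param ld_panel Dosage matrix (samples x variants, columns named by snp
#'   id) used to estimate r^2, e.g. discovery-cohort dosages.
#' @param maf_min Minimum discovery MAF (default 1%).
#' @param target_info Optional list of named per-variant info-score vectors,
#'   one per target cohort.
#' @param target_info_min Minimum info score required in each target
#'   (default 0.8).
#' @return An object of class `score_model`: data frame `variants` with
#'   `snp`, `effect_allele`, `weight`, `freq`, plus the threshold metadata.
#' @export
build_score <- function(discovery, p_threshold, prune = FALSE, r2_max = 0.25,
                        ld_panel = NULL, maf_min = 0.01, target_info = NULL,
                        target_info_min = 0.8) {
  check_number(p_threshold, "p_threshold", lower = 0, upper = 1,
               open_lower = TRUE)
  check_number(r2_max, "r2_max", lower = 0, upper = 1, open_lower = TRUE)
  d <- as.data.frame(discovery)
  keep <- !is.na(d$p) & d$p <= p_threshold
  n_p <- sum(keep)
  maf <- pmin(d$freq, 1 - d$freq)
  keep_maf <- keep & !is.na(maf) & maf >= maf_min
  if (!is.null(target_info)) {
    for (ti in target_info) keep_maf <- keep_maf & !is.na(ti) & ti >= target_info_min
  }
  keep <- keep_maf
  if (!any(keep)) {
    binding <- if (n_p == 0) "p_threshold" else "maf/info filters"
    stop("score model is empty after filtering; binding filter: ", binding,
         call. = FALSE)
  }
  d <- d[keep, , drop = FALSE]
  check_that(!anyDuplicated(d$snp), "discovery", "duplicate variant ids")
  ord <- order(d$p, d$pos)
  d <- d[ord, , drop = FALSE]
  if (prune) {
    check_that(!is.null(ld_panel), "ld_panel", "required when prune = TRUE")
    miss <- setdiff(d$snp, colnames(ld_panel))
    check_that(length(miss) == 0L, "ld_panel",
               paste("missing candidate variants:",
                     paste(head(miss, 3), collapse = ", ")))
    X <- ld_panel[, d$snp, drop = FALSE]
    kept <- integer(0)
    for (k in seq_len(nrow(d))) {
      if (!length(kept)) { kept <- k; next }
      r2 <- suppressWarnings(stats::cor(X[, k], X[, kept, drop = FALSE]))^2
      if (all(is.na(r2) | r2 < r2_max)) kept <- c(kept, k)
    }
    d <- d[kept, , drop = FALSE]
  }
  ## orient weights to the risk allele: positive weight for the effect allele
  v <- data.frame(snp = d$snp, effect_allele = d$effect_allele,
                  other_allele = d$other_allele, freq = d$freq,
                  weight = d$beta, p = d$p, stringsAsFactors = FALSE)
  structure(list(variants = v, p_threshold = p_threshold, pruned = prune,
                 r2_max = if (prune) r2_max else NA_real_),
            class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("score_model: %d variants, P_T = %s%s\n", nrow(x$variants),
              format(x$p_threshold),
              if (x$pruned) sprintf(", pruned at r2 < %.2f", x$r2_max) else ""))
  invisible(x)
}

#' Score individuals under a polygenic score model
#'
#' `score_i = sum_j w_j * dosage_ij` with dosages oriented to the effect
#' allele. Model variants absent from the target are imputed at twice the
#' model allele frequency (their expected dosage) and reported. Strand-
#' ambiguous variants (A/T or C/G with frequency near 0.5) are flagged.
#'
#' @param model A [build_score()] result.
#' @param target Samples x variants dosage matrix with columns named by snp
#'   id (a `dosage_matrix` is also accepted), oriented to the model's effect
#'   alleles.
#' @return Numeric score per individual, with attributes `imputed` (ids
#'   filled at 2 * freq) and `ambiguous` (strand-ambiguous ids).
#' @export
score_individuals <- function(model, target) {
  stopifnot(inherits(model, "score_model"))
  X <- if (inherits(target, "dosage_matrix")) target$dosages else target
  v <- model$variants
  hit <- match(v$snp, colnames(X))
  missing_ids <- v$snp[is.na(hit)]
  n <- nrow(X)
  S <- numeric(n)
  for (k in seq_len(nrow(v))) {
    d <- if (is.na(hit[k])) rep(2 * v$freq[k], n) else X[, hit[k]]
    S <- S + v$weight[k] * d
  }
  pair <- paste0(pmin(v$effect_allele, v$other_allele),
                 pmax(v$effect_allele, v$other_allele))
  ambiguous <- v$snp[pair %in% c("AT", "CG") & abs(v$freq - 0.5) < 0.1]
  attr(S, "imputed") <- missing_ids
  attr(S, "ambiguous") <- ambiguous
  S
}

#' Pseudo-controls from case-parent trios
#'
#' For each trio the affected child is the case; three pseudo-controls are
#' formed from the three parental allele combinations *not* transmitted to
#' the child. On hard genotypes the pseudo-control genotype multiset at a
#' variant is the multiset of the four equally likely allele combinations
#' minus one instance of the child genotype, which is well defined even when
#' transmission phase is ambiguous. Pseudo-genotypes are assigned to the
#' three pseudo-individuals in random order per variant (seeded), which is
#' exchangeable across variants; the score being additive, no haplotype
#' phase is needed. The matching stratum is the trio index.
#'
#' @param trios A `trio_cohort` with hard genotypes.
#' @param variants Variant ids or indices to extract (default all).
#' @param seed Seed for the per-variant assignment order.
#' @return List with `case` (n x m genotype matrix), `pseudo` (list of three
#'   n x m matrices), `strata` (trio index), `masked` (count of
#'   Mendelian-inconsistent trio-variant pairs, masked as NA).
#' @export
pseudo_controls <- function(trios, variants = NULL, seed = 1) {
  C <- trios$child; Fa <- trios$father; Mo <- trios$mother
  if (!is.null(variants)) {
    j <- if (is.character(variants)) match(variants, trios$variants$id)
         else as.integer(variants)
    check_that(!anyNA(j), "variants", "unknown variant id")
    C <- C[, j, drop = FALSE]; Fa <- Fa[, j, drop = FALSE]
    Mo <- Mo[, j, drop = FALSE]
  }
  check_that(all(C %in% c(0, 1, 2)) && all(Fa %in% c(0, 1, 2)) &&
               all(Mo %in% c(0, 1, 2)),
             "trios", "pseudo-controls require hard genotypes (0/1/2)")
  n <- nrow(C); m <- ncol(C)
  ## lookup: for each (father, mother, child) genotype triple, the
  ## pseudo-control genotype multiset = four allele combinations minus one
  ## instance of the child genotype (NA row = Mendelian inconsistency)
  lut <- matrix(NA_real_, 27, 3)
  for (f in 0:2) for (mo in 0:2) {
    cb <- as.vector(outer(c(f >= 1, f == 2) + 0, c(mo >= 1, mo == 2) + 0, `+`))
    for (ch in 0:2) {
      hit <- match(ch, cb)
      if (!is.na(hit)) lut[f * 9 + mo * 3 + ch + 1, ] <- cb[-hit]
    }
  }
  key <- Fa * 9 + Mo * 3 + C + 1
  base <- lut[key, , drop = FALSE]               # (n*m) x 3
  perm6 <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  with_seed(seed, {
    pm <- perm6[sample.int(6L, n * m, replace = TRUE), , drop = FALSE]
    ix <- seq_len(n * m)
    P1 <- matrix(base[cbind(ix, pm[, 1])], n, m, dimnames = dimnames(C))
    P2 <- matrix(base[cbind(ix, pm[, 2])], n, m, dimnames = dimnames(C))
    P3 <- matrix(base[cbind(ix, pm[, 3])], n, m, dimnames = dimnames(C))
  })
  list(case = C, pseudo = list(P1, P2, P3), strata = seq_len(n),
       masked = sum(is.na(base[, 1])))
}

#' Nagelkerke pseudo R-squared from log-likelihoods
#'
#' `R2 = (1 - exp((2/n) (l0 - l1))) / (1 - exp((2/n) l0))`.
#'
#' @param l0,l1 Null and full model log-likelihoods.
#' @param n Number of observations (matched design: number of strata times
#'   stratum size, i.e. the number of scored individuals).
#' @return Nagelkerke pseudo R-squared in \[0, 1).
#' @export
nagelkerke_r2 <- function(l0, l1, n) {
  max(0, (1 - exp((2 / n) * (l0 - l1))) / (1 - exp((2 / n) * l0)))
}

#' Test a polygenic score against disease status
#'
#' Unmatched design: logistic regression of status on the score, Wald test
#' on the score coefficient, Nagelkerke pseudo R-squared against the
#' intercept-only null. Matched design (`strata` given, e.g. case +
#' pseudo-controls per trio): conditional logistic regression within strata;
#' the null log-likelihood is the null conditional likelihood
#' (`sum(log(1/stratum size))`).
#'
#' @param scores Per-individual scores.
#' @param status 0/1 labels.
#' @param strata Optional matching stratum labels (one case per stratum).
#' @return List with `beta`, `se`, `z`, `p` (Wald), `r2` (Nagelkerke), `n`,
#'   and `converged`. Constant scores return `r2 = 0` and missing P.
#' @export
prs_association <- function(scores, status, strata = NULL) {
  check_that(all(is.finite(scores)), "scores", "must be finite")
  check_that(length(status) == length(scores) && all(status %in% c(0, 1)),
             "status", "must be 0/1 aligned with scores")
  n <- length(scores)
  if (sd(scores) == 0)
    return(list(beta = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
                r2 = 0, n = n, converged = TRUE))
  if (is.null(strata)) {
    fit1 <- glm(status ~ scores, family = binomial())
    fit0 <- glm(status ~ 1, family = binomial())
    b <- coef(fit1)["scores"]
    se <- sqrt(diag(vcov(fit1)))["scores"]
    r2 <- nagelkerke_r2(as.numeric(logLik(fit0)), as.numeric(logLik(fit1)), n)
    conv <- fit1$converged
  } else {
    check_that(length(strata) == n, "strata", "must be aligned with scores")
    ok_strata <- tapply(status, strata, sum)
    check_that(all(ok_strata == 1), "strata",
               "each matched stratum must contain exactly one case")
    df <- data.frame(status = status, scores = scores, strata = strata)
    ## conditional logistic likelihood == stratified Cox with exact ties
    fit1 <- survival::coxph(survival::Surv(rep(1, n), status) ~ scores +
                              survival::strata(strata),
                            data = df, method = "exact")
    b <- coef(fit1)[1]
    se <- sqrt(vcov(fit1)[1, 1])
    sizes <- table(strata)
    l0 <- sum(log(1 / sizes))
    l1 <- fit1$loglik[2]
    r2 <- nagelkerke_r2(l0, l1, n)
    conv <- TRUE
  }
  z <- as.numeric(b / se)
  list(beta = as.numeric(b), se = as.numeric(se), z = z, p = p_from_z(z),
       r2 = r2, n = n, converged = conv)
}

#' Transmitted vs non-transmitted trio score
#'
#' For each trio, the transmitted score is the weighted sum of the child's
#' risk-allele dosages over the panel variants; the non-transmitted score
#' uses `father + mother - child`. The per-trio difference
#' (transmitted - non-transmitted) is tested against mean zero with a
#' two-sided one-sample t-test. A positive mean difference indicates that
#' the panel's risk alleles are over-transmitted, i.e. that the panel
#' contributes to the target trait.
#'
#' @param trios A `trio_cohort`.
#' @param panel Data frame with columns `snp` and `log_rr` (weights for the
#'   risk = effect allele); typically 24 lead SNPs.
#' @return An object of class `trio_score_result`: per-trio `transmitted`,
#'   `nontransmitted`, `difference`, plus `mean`, `sd`, `t`, `p`, `n`.
#' @export
trio_transmission_score <- function(trios, panel) {
  check_that(is.data.frame(panel) && all(c("snp", "log_rr") %in% names(panel)),
             "panel", "needs columns snp and log_rr")
  j <- match(panel$snp, trios$variants$id)
  check_that(!anyNA(j), "panel", "panel variants missing from the trios")
  w <- panel$log_rr
  Tm <- trios$child[, j, drop = FALSE]
  U <- trios$father[, j, drop = FALSE] + trios$mother[, j, drop = FALSE] - Tm
  bad <- U < 0 | U > 2
  if (any(bad)) { Tm[bad] <- NA; U[bad] <- NA }   # Mendelian inconsistency
  transmitted <- rowSums(sweep(Tm, 2, w, `*`), na.rm = TRUE)
  nontransmitted <- rowSums(sweep(U, 2, w, `*`), na.rm = TRUE)
  d <- transmitted - nontransmitted
  tt <- t.test(d, mu = 0)
  structure(list(transmitted = transmitted, nontransmitted = nontransmitted,
                 difference = d, mean = mean(d), sd = sd(d),
                 t = unname(tt$statistic), p = tt$p.value, n = length(d),
                 masked = sum(bad)),
            class = "trio_score_result")
}

#' @export
print.trio_score_result <- function(x, ...) {
  cat(sprintf("trio transmission score: n = %d families\n", x$n))
  cat(sprintf("  mean difference (transmitted - non-transmitted) = %.4f +/- %.3f\n",
              x$mean, x$sd))
  cat(sprintf("  one-sample t = %.3f, two-sided P = %s\n", x$t,
              format(x$p, digits = 4)))
  invisible(x)
}

#' Variance in disease risk attributable to a fixed variant panel
#'
#' Joint logistic regression of status on all panel dosages (plus optional
#' covariates); Nagelkerke pseudo R-squared from the null-vs-full
#' likelihoods, plus the liability-scale conversion of the observed-scale
#' linear-model R-squared (Lee et al. transformation), which requires the
#' population prevalence and corrects for case-control ascertainment.
#' Collinear panel members are dropped by the fit and flagged.
#'
#' @param cohort A `cc_cohort` (or list with `dosages`, `status`).
#' @param panel Variant ids or column indices of the panel.
#' @param prevalence Population prevalence used for the liability
#'   transformation (default 0.001).
#' @param covariates Optional covariate matrix.
#' @return List with `r2_nagelkerke`, `r2_observed` (linear-model R2 on the
#'   0/1 outcome), `r2_liability`, `p` (likelihood-ratio P for the panel),
#'   `dropped` (collinear members), `n`.
#' @export
variance_explained_loci <- function(cohort, panel, prevalence = 0.001,
                                    covariates = NULL) {
  check_number(prevalence, "prevalence", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  G <- cohort$dosages
  y <- cohort$status
  j <- if (is.character(panel)) match(panel, cohort$variants$id)
       else as.integer(panel)
  check_that(!anyNA(j), "panel", "unknown panel variant")
  X <- G[, j, drop = FALSE]
  if (is.null(covariates)) covariates <- cohort$covariates
  if (is.null(covariates)) covariates <- matrix(numeric(0), nrow(X), 0)
  n <- length(y)
  Xf <- cbind(1, as.matrix(covariates), X)
  qrX <- qr(Xf)
  alias <- qrX$pivot[-seq_len(qrX$rank)] - 1L - ncol(covariates)
  dropped <- colnames(X)[alias[alias > 0]]
  fit1 <- suppressWarnings(glm.fit(Xf[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE],
                                   y, family = binomial()))
  X0 <- cbind(1, as.matrix(covariates))
  fit0 <- glm.fit(X0, y, family = binomial())
  ll <- function(f) -f$deviance / 2
  r2n <- nagelkerke_r2(ll(fit0), ll(fit1), n)
  lrt <- 2 * (ll(fit1) - ll(fit0))
  df <- fit1$rank - fit0$rank
  p <- pchisq(lrt, df, lower.tail = FALSE)
  ## observed-scale linear R2 feeding the Lee et al. liability conversion
  res0 <- stats::lm.fit(X0, y)$residuals
  resf <- stats::lm.fit(Xf[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE],
                        y)$residuals
  r2o <- max(0, 1 - sum(resf^2) / sum(res0^2))
  r2l <- liability_r2(r2o, prevalence, mean(y))
  list(r2_nagelkerke = r2n, r2_observed = r2o, r2_liability = r2l,
       p = p, dropped = dropped, n = n)
}

#' Observed-scale to liability-scale conversion for case-control R-squared
#'
#' Lee et al. transformation:
#' `R2_l = R2_o * K^2 (1 - K)^2 / (z^2 P (1 - P))` with prevalence `K`,
#' sample case fraction `P` and `z = dnorm(qnorm(1 - K))`.
#'
#' @param r2_obs Observed-scale (0/1 linear model) R-squared.
#' @param prevalence Population prevalence K.
#' @param case_fraction Case fraction P in the sample.
#' @return Liability-scale R-squared.
#' @export
liability_r2 <- function(r2_obs, prevalence, case_fraction) {
  k <- prevalence; pf <- case_fraction
  z <- dnorm(qnorm(1 - k))
  r2_obs * k^2 * (1 - k)^2 / (z^2 * pf * (1 - pf))
}

#' Default discovery P-value threshold grid
#'
#' Eleven thresholds spanning genome-wide significance to no threshold;
#' configurable wherever used.
#'
#' @return Numeric vector of 11 P_T values.
#' @export
pt_grid <- function() {
  c(5e-8, 1e-5, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.2, 0.3, 0.5, 1.0)
}
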