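## assoc: per-variant association testing (case-control and trio designs),
## conditioning, cohort combination and genomic inflation.

.empty_assoc <- function(n) {
  data.frame(snp = character(n), chr = character(n), pos = integer(n),
             effect_allele = character(n), other_allele = character(n),
             freq = NA_real_, info = NA_real_, beta = NA_real_,
             se = NA_real_, z = NA_real_, p = NA_real_, n = NA_integer_,
             flag = NA_character_, stringsAsFactors = FALSE)
}

.assoc_skeleton <- function(variants, n_samples) {
  a <- .empty_assoc(nrow(variants))
  a$snp <- variants$id; a$chr <- variants$chrom; a$pos <- variants$pos
  a$effect_allele <- variants$alt; a$other_allele <- variants$ref
  a$freq <- variants$freq
  a$info <- if (!is.null(variants$info)) variants$info else NA_real_
  a$n <- n_samples
  a
}

#' Logistic regression association on expected dosages
#'
#' Per-variant logistic regression of case-control status on the variant
#' dosage plus covariates (e.g. ancestry axes) and any conditioning variant
#' dosages, reporting the Wald beta (log odds ratio, which approximates the
#' log relative risk at low prevalence), its standard error, Z and two-sided
#' P for the alternate (effect) allele. `method = "score"` instead computes
#' the covariate-adjusted Rao score test for all variants from a single null
#' fit, which is orders of magnitude faster for genome-wide scans and
#' asymptotically equivalent under the null and local alternatives.
#'
#' Non-converged or separated fits are flagged, not dropped. A tested
#' variant that is collinear with the conditioning set (e.g. conditioning a
#' variant on itself) is reported with `beta = 0`, `p = 1` and flag
#' `"collinear"`.
#'
#' @param cohort A `cc_cohort` from [simulate_case_control()], or any list
#'   with elements `dosages` (samples x variants), `status` (0/1) and
#'   `variants`.
#' @param covariates Numeric covariate matrix (default:
#'   `cohort$covariates`).
#' @param condition_on Variant ids or column indices whose dosages enter the
#'   model as covariates (conditional analysis).
#' @param method `"wald"` (per-variant IRLS fit) or `"score"`.
#' @param variants Optional subset of variants to test (ids or indices).
#' @return An `assoc_table` data frame.
#' @export
logistic_assoc <- function(cohort, covariates = NULL, condition_on = NULL,
                           method = c("wald", "score"), variants = NULL) {
  method <- match.arg(method)
  G <- cohort$dosages
  y <- cohort$status
  check_that(length(y) == nrow(G) && all(y %in% c(0, 1)), "cohort",
             "status must be 0/1 and aligned with dosage rows")
  if (is.null(covariates)) covariates <- cohort$covariates
  if (is.null(covariates)) covariates <- matrix(numeric(0), nrow(G), 0)
  covariates <- as.matrix(covariates)
  check_that(nrow(covariates) == nrow(G), "covariates",
             "must be row-aligned with the cohort")
  cond_idx <- integer(0)
  if (length(condition_on)) {
    cond_idx <- if (is.character(condition_on))
      match(condition_on, cohort$variants$id) else as.integer(condition_on)
    check_that(!anyNA(cond_idx), "condition_on", "unknown variant id")
  }
  test_idx <- if (is.null(variants)) seq_len(ncol(G))
              else if (is.character(variants)) match(variants, cohort$variants$id)
              else as.integer(variants)
  check_that(!anyNA(test_idx), "variants", "unknown variant id")

  a <- .assoc_skeleton(cohort$variants[test_idx, , drop = FALSE], nrow(G))
  a$freq <- colMeans(G[, test_idx, drop = FALSE]) / 2
  X0 <- cbind(`(Intercept)` = 1, covariates,
              G[, cond_idx, drop = FALSE])

  if (method == "score") {
    fit0 <- glm.fit(X0, y, family = binomial())
    mu <- fit0$fitted.values
    w <- mu * (1 - mu)
    r <- y - mu
    Gt <- G[, test_idx, drop = FALSE]
    U <- as.numeric(crossprod(Gt, r))
    XtWX <- crossprod(X0 * w, X0)
    A <- crossprod(X0 * w, Gt)                       # p x m
    V <- colSums(Gt * (w * Gt)) - colSums(A * solve(XtWX, A))
    ok <- V > 1e-10
    a$z[ok] <- U[ok] / sqrt(V[ok])
    a$beta[ok] <- U[ok] / V[ok]
    a$se[ok] <- 1 / sqrt(V[ok])
    a$p[ok] <- p_from_z(a$z[ok])
    a$flag <- ifelse(ok, "score", "collinear")
    a$p[!ok] <- 1; a$beta[!ok] <- 0; a$z[!ok] <- 0
    return(as_assoc_table(a))
  }

  for (k in seq_along(test_idx)) {
    j <- test_idx[k]
    ## test dosage last so that, under collinearity with the conditioning
    ## set, the tested term is the aliased one
    X <- cbind(X0, dose = G[, j])
    fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
    p_dose <- ncol(X)
    rk <- fit$rank
    piv <- fit$qr$pivot[seq_len(rk)]
    if (!(p_dose %in% piv)) {          # aliased: collinear with conditioners
      a$beta[k] <- 0; a$z[k] <- 0; a$p[k] <- 1; a$flag[k] <- "collinear"
      next
    }
    Rmat <- qr.R(fit$qr)[seq_len(rk), seq_len(rk), drop = FALSE]
    covb <- chol2inv(Rmat)
    se_full <- rep(NA_real_, p_dose)
    se_full[piv] <- sqrt(diag(covb))
    b <- fit$coefficients[p_dose]
    s <- se_full[p_dose]
    if (!fit$converged || !is.finite(s) || s > 100 || abs(b) > 15) {
      a$flag[k] <- if (!fit$converged) "nonconverged" else "separation"
      a$beta[k] <- sign(b) * Inf; a$se[k] <- NA; a$p[k] <- NA
      next
    }
    a$beta[k] <- b; a$se[k] <- s; a$z[k] <- b / s
    a$p[k] <- p_from_z(b / s)
  }
  as_assoc_table(a)
}

#' Family-based association on trio dosages
#'
#' Dosage generalization of the transmission disequilibrium test. Per trio
#' *i* and variant, the contribution is the observed child dosage minus its
#' Mendelian expectation given the parents,
#' `U_i = d_child - (d_father + d_mother) / 2`, with transmission variance
#' `(d_f/2)(1 - d_f/2) + (d_m/2)(1 - d_m/2)` (each parental dosage read as
#' an allele-transmission probability). The statistic
#' `Z = sum(U_i) / sqrt(sum(Var_i))` reduces exactly to the classical TDT
#' `(b - c) / sqrt(b + c)` on hard genotypes. Like the TDT it is immune to
#' population stratification, because each child is compared only with its
#' own parents.
#'
#' @param trios A `trio_cohort` from [simulate_trios()], or any list with
#'   aligned `child`, `father`, `mother` dosage matrices and a `variants`
#'   data frame.
#' @return An `assoc_table`; variants with zero informative trios get a
#'   missing P and flag `"uninformative"`.
#' @export
trio_assoc <- function(trios) {
  C <- trios$child; Fa <- trios$father; Mo <- trios$mother
  check_that(all(dim(C) == dim(Fa)) && all(dim(C) == dim(Mo)), "trios",
             "child/father/mother matrices must be aligned")
  U <- colSums(C - (Fa + Mo) / 2)
  V <- colSums((Fa / 2) * (1 - Fa / 2) + (Mo / 2) * (1 - Mo / 2))
  a <- .assoc_skeleton(trios$variants, nrow(C))
  a$freq <- colMeans(C) / 2
  ok <- V > 0
  a$z[ok] <- U[ok] / sqrt(V[ok])
  a$beta[ok] <- U[ok] / V[ok]
  a$se[ok] <- 1 / sqrt(V[ok])
  a$p[ok] <- p_from_z(a$z[ok])
  a$flag[!ok] <- "uninformative"
  as_assoc_table(a)
}

#' Cochran-Armitage trend test on a 2 x 3 genotype table
#'
#' Standard 1-df trend chi-square with genotype scores (0, 1, 2), the
#' per-cohort test used in candidate-SNP replication.
#'
#' @param cases,controls Length-3 genotype counts (0, 1, 2 risk-allele
#'   copies).
#' @return List with `chisq`, `z` (signed, positive when cases carry more
#'   risk alleles) and two-sided `p` (NA for a degenerate table).
#' @export
armitage_trend <- function(cases, controls) {
  check_that(length(cases) == 3L && length(controls) == 3L &&
               all(c(cases, controls) >= 0) &&
               all(c(cases, controls) == round(c(cases, controls))),
             "cases", "needs non-negative integer genotype counts (length 3)")
  s <- c(0, 1, 2)
  n_i <- cases + controls
  N <- sum(n_i); R <- sum(cases)
  if (N == 0 || R == 0 || R == N)
    return(list(chisq = NA_real_, z = NA_real_, p = NA_real_))
  num <- N * sum(s * cases) - R * sum(s * n_i)
  den <- R * (N - R) * (N * sum(s^2 * n_i) - sum(s * n_i)^2)
  if (den <= 0) return(list(chisq = NA_real_, z = NA_real_, p = NA_real_))
  chisq <- N * num^2 / den
  z <- sign(num) * sqrt(chisq)
  list(chisq = chisq, z = z, p = p_from_z(z))
}

#' Combine association results across studies by weighted Z-scores
#'
#' Each study contributes a signed Z reconstructed from its two-sided P and
#' effect direction; the combined statistic is
#' `Z = sum(w_i Z_i) / sqrt(sum(w_i^2))` (Stouffer). A single study returns
#' its input P exactly. Computation is on the log scale, so P-values down to
#' the double-precision floor are handled; `P = 0` is rejected.
#'
#' @param p Two-sided P-values in (0, 1).
#' @param direction Effect signs (+1/-1, or any signed numeric).
#' @param weight Positive study weights; the conventional choice is
#'   `sqrt(N_eff)` with `N_eff = 4 / (1/N_cases + 1/N_controls)` for
#'   case-control studies and the trio count for trio studies. Scaling all
#'   weights leaves the result unchanged.
#' @return List with combined `z` and two-sided `p`.
#' @export
combine_z <- function(p, direction, weight = rep(1, length(p))) {
  check_that(length(p) >= 1L, "p", "needs at least one study")
  check_that(all(p > 0 & p < 1 | p == 1), "p",
             "P-values must lie in (0, 1]; P = 0 is rejected (underflow)")
  check_that(length(direction) == length(p), "direction",
             "must match the number of studies")
  check_that(all(weight > 0) && length(weight) == length(p), "weight",
             "weights must be positive, one per study")
  z_i <- z_from_p(p, sign(direction))
  z <- sum(weight * z_i) / sqrt(sum(weight^2))
  list(z = z, p = p_from_z(z))
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' @param betas,ses Per-study effects (log relative risks) and standard
#'   errors (> 0).
#' @return List with pooled `beta`, `se`, `z`, two-sided `p`, and Cochran
#'   heterogeneity `q` with `q_df` and `q_p`.
#' @export
fixed_effect_meta <- function(betas, ses) {
  check_that(length(betas) == length(ses), "ses",
             "must have one standard error per beta")
  check_that(length(betas) >= 1L, "betas", "needs at least one study")
  check_that(all(ses > 0), "ses", "standard errors must be positive")
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- sqrt(1 / sum(w))
  q <- sum(w * (betas - beta)^2)
  q_df <- length(betas) - 1L
  list(beta = beta, se = se, z = beta / se, p = p_from_z(beta / se),
       q = q, q_df = q_df,
       q_p = if (q_df > 0) pchisq(q, q_df, lower.tail = FALSE) else NA_real_)
}

#' Genomic inflation factor
#'
#' Median observed 1-df association chi-square divided by the null median
#' `qchisq(0.5, 1) = 0.4549`. Values above 1 indicate stratification
#' confounding or polygenicity.
#'
#' @param x An `assoc_table`, or a numeric vector of two-sided P-values.
#' @return Lambda (scalar).
#' @export
genomic_inflation <- function(x) {
  p <- if (is.data.frame(x)) x$p else x
  p <- p[!is.na(p)]
  if (length(p) < 100)
    warning("genomic inflation estimated from fewer than 100 variants")
  chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq) / qchisq(0.5, df = 1)
}
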