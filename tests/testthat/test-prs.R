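mk_discovery <- function(n = 6, p = NULL, beta = NULL, freq = NULL) {
  data.frame(snp = sprintf("s%02d", 1:n), chr = "chr1", pos = 1000 * (1:n),
             effect_allele = "G", other_allele = "A",
             freq = if (is.null(freq)) rep(0.3, n) else freq,
             info = 1,
             beta = if (is.null(beta)) rep(0.2, n) else beta,
             se = 0.05,
             p = if (is.null(p)) rep(0.01, n) else p,
             stringsAsFactors = FALSE)
}

test_that("build_score thresholds, filters and prunes greedily", {
  d <- mk_discovery(p = c(1e-6, 1e-4, 0.02, 0.2, 0.6, 1))

  # P_T = 1, no pruning: every passing variant enters
  m_all <- build_score(d, 1)
  expect_equal(nrow(m_all$variants), 6)

  m_thr <- build_score(d, 1e-3)
  expect_identical(sort(m_thr$variants$snp), c("s01", "s02"))

  # MAF and target-info filters
  d2 <- mk_discovery(p = rep(1e-4, 6), freq = c(0.005, rep(0.3, 5)))
  expect_false("s01" %in% build_score(d2, 1)$variants$snp)
  ti <- c(0.9, 0.75, rep(0.9, 4))
  m_ti <- build_score(d, 1, target_info = list(cohortA = ti))
  expect_false("s02" %in% m_ti$variants$snp)   # info 0.75 < 0.8

  # greedy pruning keeps the smaller-P member of a perfectly correlated pair
  set.seed(2)
  g <- rbinom(500, 2, 0.3)
  ld <- cbind(s01 = g, s02 = g, s03 = rbinom(500, 2, 0.3),
              s04 = rbinom(500, 2, 0.4), s05 = rbinom(500, 2, 0.2),
              s06 = rbinom(500, 2, 0.25))
  d3 <- mk_discovery(p = c(1e-6, 1e-4, 0.3, 0.4, 0.5, 0.9))
  m_pr <- build_score(d3, 1, prune = TRUE, ld_panel = ld)
  expect_true("s01" %in% m_pr$variants$snp)
  expect_false("s02" %in% m_pr$variants$snp)
  # no retained pair violates the r2 ceiling
  r2 <- cor(ld[, m_pr$variants$snp])^2
  expect_true(all(r2[upper.tri(r2)] < 0.25))

  # the P_T sweep gives monotonically non-decreasing model sizes
  dgrid <- mk_discovery(n = 50, p = 10^seq(-9, -0.05, length.out = 50))
  sizes <- vapply(pt_grid(), function(pt)
    tryCatch(nrow(build_score(dgrid, pt)$variants), error = function(e) 0L),
    integer(1))
  expect_true(all(diff(sizes) >= 0))
  expect_length(pt_grid(), 11)

  expect_error(build_score(d, 1e-10), "p_threshold")
})

test_that("score_individuals is weighted dosage arithmetic", {
  d <- mk_discovery(n = 2, beta = c(log(1.5), 0))
  m <- build_score(d, 1)
  X <- cbind(s01 = c(2, 1, 0), s02 = c(0, 2, 1))
  s <- score_individuals(m, X)
  expect_equal(as.numeric(s), c(2 * log(1.5), log(1.5), 0))

  # all weights zero: all scores zero
  m0 <- build_score(mk_discovery(n = 2, beta = c(0, 0)), 1)
  expect_equal(as.numeric(score_individuals(m0, X)), c(0, 0, 0))

  # flipping the stored effect allele and negating the weight shifts every
  # score by the same constant (orientation identity)
  m_f <- m
  m_f$variants$weight[1] <- -m$variants$weight[1]
  X_f <- X; X_f[, "s01"] <- 2 - X[, "s01"]
  s_f <- score_individuals(m_f, X_f)
  expect_equal(diff(as.numeric(s - s_f)), c(0, 0), tolerance = 1e-12)

  # model variant absent from target: imputed at 2 * freq and reported
  s_m <- score_individuals(m, X[, "s01", drop = FALSE])
  expect_identical(attr(s_m, "imputed"), "s02")

  # strand-ambiguous variant flagged
  d_amb <- mk_discovery(n = 1, freq = 0.52)
  d_amb$effect_allele <- "A"; d_amb$other_allele <- "T"
  expect_identical(attr(score_individuals(build_score(d_amb, 1),
                                          cbind(s01 = c(0, 1))), "ambiguous"),
                   "s01")
})

test_that("pseudo_controls performs Mendelian bookkeeping", {
  # both parents homozygous AA (genotype 2): child and all pseudo-controls 2
  tr <- list(child = matrix(2, 5, 1), father = matrix(2, 5, 1),
             mother = matrix(2, 5, 1),
             variants = data.frame(id = "v1", chrom = "chr1", pos = 1,
                                   ref = "A", alt = "G", freq = 1, info = 1))
  pc <- pseudo_controls(tr)
  expect_true(all(vapply(pc$pseudo, function(m) all(m == 2), logical(1))))

  # Aa x Aa with child AA: pseudo multiset {Aa, Aa, aa} = {1, 1, 0}
  tr2 <- list(child = matrix(2, 1, 1), father = matrix(1, 1, 1),
              mother = matrix(1, 1, 1), variants = tr$variants)
  pc2 <- pseudo_controls(tr2)
  got <- sort(vapply(pc2$pseudo, function(m) m[1, 1], numeric(1)))
  expect_equal(got, c(0, 1, 1))

  # Mendelian-inconsistent input is masked and reported
  tr3 <- list(child = matrix(2, 1, 1), father = matrix(0, 1, 1),
              mother = matrix(0, 1, 1), variants = tr$variants)
  pc3 <- pseudo_controls(tr3)
  expect_equal(pc3$masked, 1)
  expect_true(all(is.na(vapply(pc3$pseudo, function(m) m[1, 1], numeric(1)))))

  # null calibration: case minus mean pseudo-control score averages to zero
  panel <- tiny_panel(seed = 111, n_hap = 300, n_var = 24, rho = 0)
  trios <- simulate_trios(panel, risk_model(prevalence = 0.1), 2000,
                          seed = 112)
  pc4 <- pseudo_controls(trios, seed = 113)
  w <- rnorm(24, 0, 0.1)
  s_case <- as.numeric(pc4$case %*% w)
  s_pseudo <- (pc4$pseudo[[1]] + pc4$pseudo[[2]] + pc4$pseudo[[3]]) %*% w / 3
  dd <- s_case - as.numeric(s_pseudo)
  expect_lt(abs(mean(dd) / (sd(dd) / sqrt(length(dd)))), 3)
})

test_that("prs_association handles unmatched, matched and degenerate cases", {
  # constant scores: no information
  r0 <- prs_association(rep(1, 100), rep(c(0, 1), 50))
  expect_equal(r0$r2, 0)
  expect_true(is.na(r0$p))

  # unmatched: recovers a strong simulated score-disease relationship,
  # and the Nagelkerke R2 matches a direct glm-based computation
  set.seed(21)
  s <- rnorm(600)
  y <- rbinom(600, 1, plogis(-0.5 + 0.9 * s))
  r1 <- prs_association(s, y)
  expect_lt(r1$p, 1e-10)
  f1 <- glm(y ~ s, family = binomial()); f0 <- glm(y ~ 1, family = binomial())
  r2_direct <- (1 - exp((2 / 600) * (logLik(f0) - logLik(f1)))) /
    (1 - exp((2 / 600) * as.numeric(logLik(f0))))
  expect_equal(r1$r2, as.numeric(r2_direct), tolerance = 1e-8)
  expect_equal(r1$beta, unname(coef(f1)["s"]), tolerance = 1e-6)

  # matched: 1 case + 3 pseudo-controls per stratum; null likelihood log(1/4)
  set.seed(22)
  n_str <- 150
  strata <- rep(seq_len(n_str), each = 4)
  status <- rep(c(1, 0, 0, 0), n_str)
  sc <- rnorm(n_str * 4) + 0.8 * status
  rm_ <- prs_association(sc, status, strata)
  expect_lt(rm_$p, 1e-6)
  expect_gt(rm_$r2, 0)
  expect_error(prs_association(sc, rep(c(1, 1, 0, 0), n_str), strata),
               "exactly one case")
})

test_that("trio_transmission_score bookkeeping and antisymmetry", {
  # homozygous parents everywhere: transmitted = non-transmitted exactly
  tr <- list(child = matrix(c(2, 0, 2), 3, 2), father = matrix(c(2, 0, 2), 3, 2),
             mother = matrix(c(2, 0, 2), 3, 2),
             variants = data.frame(id = c("v1", "v2"), chrom = "chr1",
                                   pos = 1:2, ref = "A", alt = "G",
                                   freq = 0.5, info = 1))
  panel24 <- data.frame(snp = c("v1", "v2"), log_rr = c(0.2, 0.1))
  ts <- trio_transmission_score(tr, panel24)
  expect_equal(ts$difference, c(0, 0, 0))

  # antisymmetry: swapping transmitted and non-transmitted labels negates
  # the difference; with hard trios, swap means replacing child by f + m - c
  panel <- tiny_panel(seed = 121, n_hap = 200, n_var = 24, rho = 0)
  trios <- simulate_trios(panel,
                          risk_model(causal = 1:6, log_rr = log(1.4),
                                     prevalence = 0.05),
                          300, seed = 122)
  pan <- data.frame(snp = trios$variants$id, log_rr = rep(log(1.2), 24))
  a <- trio_transmission_score(trios, pan)
  swapped <- trios
  swapped$child <- trios$father + trios$mother - trios$child
  b <- trio_transmission_score(swapped, pan)
  expect_equal(a$difference, -b$difference, tolerance = 1e-12)
  expect_equal(a$n, 300)
})

test_that("matched pseudo-control PRS detects a shared polygenic component", {
  # design mirrors the discovery/target layout of the motivating study
  # (400/1300 discovery, 650 target trios, 24 causal loci, RR 1.1-1.35);
  # replicates scaled to 12 for runtime, each expected to reject at 1e-4
  set.seed(60)
  res <- replicate(12, {
    panel <- simulate_panel(400, 240, block_size = 10,
                            within_block_correlation = 0.8,
                            seed = sample.int(1e6, 1))
    cz <- seq(5, 235, by = 10)[1:24]
    lr <- log(runif(24, 1.1, 1.35))
    mod <- risk_model(causal = cz, log_rr = lr, prevalence = 0.01)
    disc <- simulate_case_control(panel, mod, 400, 1300,
                                  seed = sample.int(1e6, 1))
    m <- build_score(logistic_assoc(disc, method = "score"), 0.05,
                     prune = TRUE, ld_panel = disc$dosages)
    trios <- simulate_trios(panel, mod, 650, seed = sample.int(1e6, 1))
    pc <- pseudo_controls(trios, variants = m$variants$snp,
                          seed = sample.int(1e6, 1))
    scores <- c(as.numeric(score_individuals(m, pc$case)),
                unlist(lapply(pc$pseudo, function(X)
                  as.numeric(score_individuals(m, X)))))
    r <- prs_association(scores, rep(c(1, 0, 0, 0), each = 650),
                         rep(seq_len(650), 4))
    c(p = r$p, r2 = r$r2)
  })
  expect_gte(mean(res["p", ] < 1e-4 & res["r2", ] > 0), 11 / 12)

  # independent target trait: transmitted/non-transmitted mean ~ 0
  panel0 <- tiny_panel(seed = 62, n_hap = 300, n_var = 24, rho = 0)
  trios0 <- simulate_trios(panel0, risk_model(prevalence = 0.2), 500,
                           seed = 63)
  ts0 <- trio_transmission_score(
    trios0, data.frame(snp = trios0$variants$id,
                       log_rr = log(seq(1.1, 1.35, length.out = 24))))
  expect_lt(abs(ts0$mean), 3 * ts0$sd / sqrt(ts0$n))
})

test_that("variance_explained_loci behaves on null, collinear and predictive panels", {
  panel <- tiny_panel(seed = 131, n_hap = 400, n_var = 30, rho = 0)

  # null panel: R2 ~ 0
  coh0 <- simulate_case_control(panel, risk_model(prevalence = 0.1),
                                2000, 2000, seed = 132)
  v0 <- variance_explained_loci(coh0, 1:24, prevalence = 0.1)
  expect_lt(v0$r2_nagelkerke, 0.01)

  # duplicate panel member: collinear copy dropped, R2 unchanged
  coh_dup <- coh0
  coh_dup$dosages <- cbind(coh0$dosages, dup = coh0$dosages[, 3])
  coh_dup$variants <- rbind(coh0$variants,
                            within(coh0$variants[3, ], id <- "dup"))
  v_dup <- variance_explained_loci(coh_dup, c(1:24, 31L), prevalence = 0.1)
  expect_equal(v_dup$r2_nagelkerke, v0$r2_nagelkerke, tolerance = 1e-6)
  expect_identical(v_dup$dropped, "dup")

  # predictive panel yields positive R2 and a tiny LRT P
  cohA <- simulate_case_control(panel,
                                risk_model(causal = 1:4,
                                           log_rr = log(c(1.6, 1.5, 1.4, 1.5)),
                                           prevalence = 0.05),
                                1500, 1500, seed = 133)
  vA <- variance_explained_loci(cohA, 1:4, prevalence = 0.05)
  expect_gt(vA$r2_nagelkerke, 0.01)
  expect_lt(vA$p, 1e-10)
  expect_gt(vA$r2_liability, 0)
})
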