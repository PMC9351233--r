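# Logistic LRT with overdispersion correction, methylation differences,
# SLIM q-values, DML calling.

test_that("identical groups give a null fit with G near zero and p near one", {
  fit <- fit_locus(rep(5L, 8), rep(5L, 8), rep(c(1, 0), each = 4))
  expect_lt(fit$G, 1e-8)
  expect_gt(fit$p_value, 0.999)
  expect_true(fit$converged)
})

test_that("the LRT p-value matches the brute-force grid-likelihood oracle", {
  # textbook separation: 18/2 in treatment, 2/18 in control, x4 samples
  m <- c(rep(18L, 4), rep(2L, 4))
  u <- c(rep(2L, 4), rep(18L, 4))
  treat <- rep(c(1, 0), each = 4)
  fit <- fit_locus(m, u, treat)
  expect_lte(fit$phi, 1)  # identical replicates: no overdispersion
  expect_equal(fit$p_value, grid_lrt_p(m, u, treat), tolerance = 1e-6)
  # randomized small cases, coverage <= 30, against the same oracle
  set.seed(55)
  for (i in 1:20) {
    tot <- sample(5:30, 8, replace = TRUE)
    mm <- rbinom(8, tot, runif(1, 0.15, 0.85))
    mm <- pmin(pmax(mm, 1L), tot - 1L)  # keep away from separation
    f <- fit_locus(mm, tot - mm, treat, correct = FALSE)
    expect_equal(f$p_value, grid_lrt_p(mm, tot - mm, treat), tolerance = 1e-4)
  }
})

test_that("overdispersion scaling halves the statistic at phi = 2 and never deflates", {
  m <- c(rep(18L, 4), rep(2L, 4))
  u <- c(rep(2L, 4), rep(18L, 4))
  treat <- rep(c(1, 0), each = 4)
  base <- fit_locus(m, u, treat)
  # spread the same group means so the Pearson dispersion exceeds 1
  m2 <- c(20L, 16L, 19L, 17L, 1L, 3L, 0L, 4L)
  u2 <- 20L - m2
  over <- fit_locus(m2, u2, treat)
  expect_gt(over$phi, 1)
  uncorr <- fit_locus(m2, u2, treat, correct = FALSE)
  expect_equal(stats::pchisq(over$G / over$phi, 1, lower.tail = FALSE),
               over$p_value)
  expect_gt(over$p_value, uncorr$p_value)
  # phi below 1 never inflates the statistic
  expect_equal(base$p_value,
               stats::pchisq(base$G, 1, lower.tail = FALSE))
})

test_that("the ordinal covariate absorbs a maturation-stage gradient", {
  set.seed(77)
  stage <- c(0, 1, 2, 3, 0, 1, 2, 3)
  treat <- rep(c(1, 0), each = 4)
  p <- plogis(qlogis(0.3) + 0.8 * stage)  # stage effect, no treatment effect
  tot <- rep(40L, 8)
  pvals_with <- pvals_without <- numeric(60)
  for (i in 1:60) {
    m <- rbinom(8, tot, p)
    m <- pmin(pmax(m, 1L), tot - 1L)
    pvals_with[i] <- fit_locus(m, tot - m, treat, covariate = stage,
                               correct = FALSE)$p_value
    pvals_without[i] <- fit_locus(m, tot - m, treat, correct = FALSE)$p_value
  }
  # stage is balanced across groups here, so both are valid tests of the
  # treatment term; the covariate-adjusted fit must not lose calibration
  expect_gt(mean(pvals_with < 0.05), 0)
  expect_lt(mean(pvals_with < 0.05), 0.15)
  # the categorical encoding is available and consistent
  f <- fit_locus(c(10L, 12L, 3L, 4L, 10L, 12L, 3L, 4L),
                 c(10L, 8L, 17L, 16L, 10L, 8L, 17L, 16L),
                 treat, covariate = c(0, 0, 1, 1, 0, 0, 1, 1),
                 covariate_factor = TRUE)
  expect_true("stage1" %in% names(f$beta))
})

test_that("methylation difference pools counts within groups", {
  expect_equal(meth_difference(c(80L, 20L), c(20L, 80L), c(1, 0)), 60)
  expect_equal(meth_difference(c(5L, 5L), c(5L, 5L), c(1, 0)), 0)
  # unequal coverages: pooled +50, unweighted mean differs
  m <- c(9L, 1L, 0L, 0L); u <- c(1L, 9L, 10L, 10L); treat <- c(1, 1, 0, 0)
  expect_equal(meth_difference(m, u, treat, pooled = TRUE), 50)
  expect_equal(meth_difference(m, u, treat, pooled = FALSE), 50)
  m2 <- c(9L, 1L, 0L, 0L); u2 <- c(1L, 19L, 10L, 10L)
  expect_equal(meth_difference(m2, u2, treat, pooled = TRUE),
               100 * (10 / 30))
  expect_false(isTRUE(all.equal(meth_difference(m2, u2, treat, pooled = FALSE),
                                meth_difference(m2, u2, treat, pooled = TRUE))))
})

test_that("SLIM reduces to Benjamini-Hochberg at pi0 = 1", {
  set.seed(91)
  p <- c(runif(400), rbeta(100, 0.2, 5))
  q <- slim_qvalues(p, pi0 = 1)
  expect_identical(q$q, stats::p.adjust(p, method = "BH"))
  # q is monotone in p and bounded in [0, 1]
  pp <- c(runif(900), rbeta(300, 0.1, 8))
  qq <- slim_qvalues(pp)$q
  expect_true(all(qq >= 0 & qq <= 1))
  expect_true(all(diff(qq[order(pp)]) >= -1e-12))
})

test_that("pi0 is estimated near one on uniform p-values and below one under signal", {
  set.seed(93)
  u <- runif(10000)
  est <- slim_pi0(u)
  expect_gte(est$pi0, 0.9)
  expect_lte(est$pi0, 1.0)
  mix <- c(runif(7000), rbeta(3000, 0.1, 10))
  est_mix <- slim_pi0(mix)
  expect_lt(est_mix$pi0, 0.9)
  expect_gt(est_mix$pi0, 0.5)
  # extreme p-values: q bounded by the BH formula times pi0
  tiny <- slim_qvalues(rep(1e-8, 100), pi0 = 1)
  expect_true(all(tiny$q <= 1e-5))
  expect_warning(slim_qvalues(runif(50)), "fewer than 100")
})

test_that("DML calling applies strict q and inclusive difference thresholds", {
  res <- data.table::data.table(
    chrom = "chr1", pos = c(11L, 21L, 31L, 41L, 51L),
    meth_diff = c(49.9, -50.0, 75.0, 60.0, -80.0),
    p_value = 1e-6,
    q_value = c(1e-5, 0.009, 0.01, 1e-5, 1e-5))
  snps <- data.table::data.table(chrom = "chr1", pos = 52L)  # minus strand of 51
  out <- call_dml(res, snps, diff_cutoff = 50, q_cutoff = 0.01)
  # 11: diff below cutoff; 31: q not strictly below; 51: SNP overlap
  expect_equal(out$dml$pos, c(21L, 41L))
  expect_equal(out$dml$direction, c("hypo", "hyper"))
  expect_equal(out$accounting$n_candidates, 3L)
  expect_equal(out$accounting$n_snp_removed, 1L)
  expect_equal(out$accounting$n_retained, 2L)
  expect_equal(out$accounting$n_hyper + out$accounting$n_hypo,
               out$accounting$n_retained)
  # direction always matches the sign of the difference
  expect_true(all(out$dml[direction == "hyper"]$meth_diff > 0))
  expect_true(all(out$dml[direction == "hypo"]$meth_diff < 0))
})

test_that("planted DML are recovered with high sensitivity and low FDR", {
  cfg <- sim_config(genome_length_per_chrom = 50000, n_chroms = 2,
                    gc_cpg_density = 10, dml_fraction = 0.05, dml_effect = 60,
                    snp_fraction = 0.05, mean_coverage = 30,
                    dispersion_rho = 0.05, error_rate = 0, seed = 101L)
  g <- simulate_genome(cfg)
  cnt <- simulate_counts(g, NULL, cfg)
  pl <- simulate_pileups(g, cfg, cnt$truth)
  snps <- union_snp_sets(screen_genome(pl, "merged"),
                         screen_genome(pl, "per_sample"))
  de <- lapply(cnt$coverage, destrand, cg_sites = g)
  fi <- lapply(de, filter_coverage)
  no <- normalize_coverage(fi)
  mm <- unite_samples(no, cnt$samples)
  res <- dml_test(mm)
  called <- call_dml(res, snps)
  truth_key <- paste(cnt$truth$dml_truth$chrom, cnt$truth$dml_truth$pos)
  called_key <- paste(called$dml$chrom, called$dml$pos)
  # sensitivity over planted loci that survived uniting and are SNP-free
  snp_key <- paste(cnt$truth$snp_truth$chrom, cnt$truth$snp_truth$pos)
  united_key <- paste(mm$loci$chrom, mm$loci$pos)
  eligible <- setdiff(intersect(truth_key, united_key), snp_key)
  sens <- mean(eligible %in% called_key)
  fdr <- if (length(called_key) > 0) mean(!(called_key %in% truth_key)) else 0
  expect_gte(sens, 0.8)
  expect_lte(fdr, 0.05)
  # every called locus overlapping a planted SNP was excluded
  expect_length(intersect(called_key, snp_key), 0)
  # direction of every recovered DML matches the planted sign
  rec <- merge(called$dml, cnt$truth$dml_truth, by = c("chrom", "pos"))
  expect_true(all(sign(rec$meth_diff) == sign(rec$effect)))
})
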