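# Destranding, filtering, normalization, uniting, exclusion, and the
# global methylation summaries.

cov_dt <- function(pos, m, u, chrom = "chr1") {
  data.table::data.table(chrom = chrom, pos = pos, count_meth = m, count_unmeth = u)
}

test_that("destranding sums strand pairs at the CpG start", {
  cg <- data.table::data.table(chrom = "chr1", start = 5L)
  rec <- cov_dt(c(5L, 6L), c(3L, 1L), c(2L, 4L))
  out <- destrand(rec, cg)
  expect_equal(out$pos, 5L)
  expect_equal(out$count_meth, 4L)
  expect_equal(out$count_unmeth, 6L)
  # plus-only record unchanged; orphan minus reported at its CpG start
  expect_equal(destrand(cov_dt(5L, 3L, 2L), cg)$count_meth, 3L)
  orphan <- destrand(cov_dt(6L, 1L, 4L), cg)
  expect_equal(orphan$pos, 5L)
  expect_equal(orphan$count_meth, 1L)
  # non-CpG positions are dropped
  expect_equal(nrow(destrand(cov_dt(50L, 1L, 1L), cg)), 0)
})

test_that("coverage filter drops low loci and the top-percentile outlier", {
  low <- filter_coverage(cov_dt(1:3, c(2L, 3L, 10L), c(2L, 2L, 10L)),
                         lo = 5, high_percentile = 100)
  expect_equal(low$pos, c(2L, 3L))
  # 1000 loci at coverage 10, one at 100: the outlier exceeds the 99.9th
  # percentile (linear interpolation gives 99.91) and is dropped
  dt <- cov_dt(1:1000, rep(5L, 1000), c(rep(5L, 999), 95L))
  out <- filter_coverage(dt, lo = 5, high_percentile = 99.9)
  expect_equal(nrow(out), 999)
  expect_false(1000L %in% out$pos)
  # uniform coverage: nothing dropped
  flat <- cov_dt(1:10, rep(3L, 10), rep(2L, 10))
  expect_equal(nrow(filter_coverage(flat, lo = 5)), 10)
  expect_warning(filter_coverage(cov_dt(1L, 1L, 1L), lo = 5), "no loci")
})

test_that("normalization equalizes median coverages with round-half-away and a floor", {
  s1 <- cov_dt(1:3, c(5L, 5L, 5L), c(5L, 5L, 5L))      # median 10
  s2 <- cov_dt(1:3, c(10L, 10L, 10L), c(10L, 10L, 10L)) # median 20
  out <- normalize_coverage(list(a = s1, b = s2))
  expect_equal(unname(attr(out, "factors")), c(1.5, 0.75))
  # (10, 10) in the deeper sample scales to 7.5 -> rounds to (8, 8)
  expect_equal(out$b$count_meth, rep(8L, 3))
  expect_equal(out$b$count_unmeth, rep(8L, 3))
  expect_equal(out$a$count_meth, rep(8L, 3))  # 7.5 away from zero
  # identical medians: identity
  same <- normalize_coverage(list(a = s1, b = data.table::copy(s1)))
  expect_equal(same$a$count_meth, s1$count_meth)
  # a site that would scale to zero coverage is floored at 1
  tiny <- normalize_coverage(list(a = cov_dt(1:2, c(0L, 100L), c(1L, 100L)),
                                  b = cov_dt(1:2, c(50L, 50L), c(50L, 50L))))
  expect_gte(min(tiny$a$count_meth + tiny$a$count_unmeth), 1L)
})

test_that("uniting keeps only loci covered at 5x in all samples", {
  samples <- data.table::data.table(
    sample_id = c("a", "b"), treatment = c("low_pH", "ambient"), stage = c(1L, 2L))
  recs <- list(a = cov_dt(c(1L, 10L, 20L), c(5L, 3L, 6L), c(5L, 1L, 6L)),
               b = cov_dt(c(1L, 10L), c(4L, 9L), c(2L, 1L)))
  mm <- unite_samples(recs, samples, min_cov = 5)
  # locus 10 fails coverage in a (4x); locus 20 absent from b; locus 1 kept
  expect_equal(mm$loci$pos, 1L)
  expect_equal(unname(mm$M[1, ]), c(5L, 4L))
  expect_warning(
    unite_samples(list(a = cov_dt(1L, 5L, 5L), b = cov_dt(2L, 5L, 5L)),
                  samples, min_cov = 5),
    "no loci")
})

test_that("SNP exclusion removes loci hit at either strand position and counts them", {
  samples <- data.table::data.table(
    sample_id = c("a", "b"), treatment = c("low_pH", "ambient"), stage = c(0L, 0L))
  recs <- list(a = cov_dt(c(11L, 21L, 31L), 5L, 5L),
               b = cov_dt(c(11L, 21L, 31L), 5L, 5L))
  mm <- unite_samples(recs, samples, min_cov = 5)
  snps <- data.table::data.table(chrom = "chr1", pos = c(11L, 22L))  # 22 = minus strand of 21
  out <- apply_snp_exclusion(mm, snps)
  expect_equal(out$n_removed, 2L)
  expect_equal(out$matrix$loci$pos, 31L)
  # empty set: identity; full set: empty matrix
  expect_equal(apply_snp_exclusion(mm, NULL)$n_removed, 0L)
  all_gone <- apply_snp_exclusion(mm, data.table::data.table(
    chrom = "chr1", pos = c(11L, 21L, 31L)))
  expect_equal(nrow(all_gone$matrix$loci), 0)
})

test_that("classification boundaries follow the >=50 / <=10 convention", {
  samples <- data.table::data.table(
    sample_id = c("a", "b"), treatment = c("low_pH", "ambient"), stage = c(0L, 0L))
  # pooled percents: 50.0, 10.0, 10.1 (one locus each), 0
  recs <- list(a = cov_dt(1:4, c(500L, 100L, 101L, 0L), c(500L, 900L, 899L, 1000L)),
               b = cov_dt(1:4, c(500L, 100L, 101L, 0L), c(500L, 900L, 899L, 1000L)))
  mm <- unite_samples(recs, samples, min_cov = 5)
  cls <- classify_loci(mm)
  expect_equal(cls$loci$class, c("high", "low", "moderate", "low"))
  expect_equal(cls$summary[class == "low"]$n, 2L)
  # class counts always sum to the united locus count
  expect_equal(sum(cls$summary$n), nrow(mm$loci))
})

test_that("weighted and unweighted classification differ where coverages are unequal", {
  samples <- data.table::data.table(
    sample_id = c("a", "b"), treatment = c("low_pH", "ambient"), stage = c(0L, 0L))
  # a: 90/100 = 90%; b: 1/10 = 10% -> pooled (90+1)/110 = 82.7%, mean 50%
  recs <- list(a = cov_dt(1L, 90L, 10L), b = cov_dt(1L, 1L, 9L))
  mm <- unite_samples(recs, samples, min_cov = 5)
  expect_equal(classify_loci(mm, weighted = TRUE)$loci$class, "high")
  expect_equal(round(classify_loci(mm, weighted = TRUE)$loci$percent, 1), 82.7)
  expect_equal(classify_loci(mm, weighted = FALSE)$loci$percent, 50)
})

test_that("sample correlations are symmetric with unit diagonal and flag constants", {
  cfg <- sim_config(genome_length_per_chrom = 20000, n_chroms = 1, seed = 17L)
  g <- simulate_genome(cfg)
  cnt <- simulate_counts(g, NULL, cfg)
  de <- lapply(cnt$coverage, destrand, cg_sites = g)
  mm <- unite_samples(de, cnt$samples, min_cov = 5)
  cc <- sample_correlations(mm)
  expect_equal(unname(diag(cc)), rep(1, ncol(mm$M)))
  expect_equal(cc, t(cc))
  # duplicated sample correlates perfectly
  mm2 <- mm
  mm2$M <- cbind(mm$M, dup = mm$M[, 1])
  mm2$U <- cbind(mm$U, dup = mm$U[, 1])
  cc2 <- sample_correlations(mm2)
  expect_equal(unname(cc2["dup", colnames(mm$M)[1]]), 1)
})

test_that("PCA separates groups under a large global offset and reports variance fractions", {
  set.seed(33)
  n <- 200
  samples <- data.table::data.table(
    sample_id = sprintf("s%d", 1:8),
    treatment = rep(c("low_pH", "ambient"), each = 4), stage = 0L)
  M <- U <- matrix(0L, n, 8, dimnames = list(NULL, samples$sample_id))
  for (j in 1:8) {
    p <- if (j <= 4) 0.8 else 0.2
    M[, j] <- rbinom(n, 50, p)
    U[, j] <- 50L - M[, j]
  }
  mm <- structure(list(loci = data.table::data.table(chrom = "chr1", pos = 1:n),
                       M = M, U = U, samples = samples), class = "methyl_matrix")
  pca <- sample_pca(mm)
  expect_lte(sum(pca$explained), 1 + 1e-8)
  pc1 <- pca$scores[, 1]
  expect_true(all(sign(pc1[1:4]) == sign(pc1[1])))
  expect_true(all(sign(pc1[5:8]) == -sign(pc1[1])))
})

test_that("coverage files round-trip through the Bismark format", {
  cfg <- sim_config(genome_length_per_chrom = 10000, n_chroms = 1, seed = 19L)
  g <- simulate_genome(cfg)
  cnt <- simulate_counts(g, NULL, cfg)
  dir <- tempfile(); dir.create(dir)
  paths <- write_bismark_cov(cnt, dir)
  back <- read_bismark_cov(paths)
  expect_identical(names(back), names(cnt$coverage))
  orig <- cnt$coverage[[1]][, .(chrom, pos, count_meth, count_unmeth)]
  expect_equal(back[[1]], orig)
})
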