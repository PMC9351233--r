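# Per-locus differential methylation testing.
#
# Model: binomial logistic regression on methylated/total read counts,
# logit(p_i) = b0 + b1 * treatment_i + b2 * stage_i, with the treatment
# coefficient tested by a likelihood-ratio chi-squared statistic. Extra-
# binomial variance (overdispersion) is absorbed by scaling the statistic
# with the Pearson dispersion estimate of the full model before the
# chi-squared tail (the "MN" correction); the correction never deflates
# (applied only when the estimate exceeds 1).

#' Fit the per-locus logistic model and test the treatment effect
#'
#' @param count_meth,count_unmeth Integer vectors, one entry per sample.
#' @param treatment 0/1 (or logical, or factor with two levels; the second
#'   level is the treatment).
#' @param covariate Optional numeric covariate (ordinal maturation stage);
#'   `NULL` drops the term. `covariate_factor = TRUE` expands it to
#'   indicator columns instead of a single ordinal term.
#' @param correct Apply the overdispersion correction (default `TRUE`).
#' @param covariate_factor Treat the covariate as categorical.
#' @return A `locus_fit` list: `beta`, `loglik_full`, `loglik_reduced`,
#'   `G` (likelihood-ratio statistic), `phi` (Pearson dispersion), `df`,
#'   `p_value`, `converged`.
#' @export
fit_locus <- function(count_meth, count_unmeth, treatment, covariate = NULL,
                      correct = TRUE, covariate_factor = FALSE) {
  total <- count_meth + count_unmeth
  assert_that(all(total > 0), "every sample needs nonzero coverage")
  treat <- if (is.factor(treatment)) as.numeric(treatment) - 1 else as.numeric(treatment)
  assert_that(length(unique(treat)) == 2, "treatment must have two levels")
  assert_that(min(table(treat)) >= 2, "need at least two samples per group")
  y <- count_meth / total
  X_full <- cbind(`(Intercept)` = 1, treatment = treat)
  if (!is.null(covariate)) {
    if (covariate_factor) {
      f <- factor(covariate)
      if (nlevels(f) > 1) {
        dm <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(dm) <- paste0("stage", levels(f)[-1])
        X_full <- cbind(X_full, dm)
      }
    } else if (stats::sd(covariate) > 0) {
      X_full <- cbind(X_full, stage = as.numeric(covariate))
    }
  }
  X_red <- X_full[, colnames(X_full) != "treatment", drop = FALSE]
  fit_one <- function(X) {
    suppressWarnings(stats::glm.fit(X, y, weights = total,
                                    family = stats::binomial()))
  }
  fit_f <- fit_one(X_full)
  fit_r <- fit_one(X_red)
  eps <- 1e-12
  mu_f <- pmin(pmax(fit_f$fitted.values, eps), 1 - eps)
  mu_r <- pmin(pmax(fit_r$fitted.values, eps), 1 - eps)
  ll <- function(mu) sum(stats::dbinom(count_meth, total, mu, log = TRUE))
  ll_f <- ll(mu_f)
  ll_r <- ll(mu_r)
  G <- max(0, 2 * (ll_f - ll_r))
  n <- length(y)
  k <- fit_f$rank
  pearson <- sum((count_meth - total * mu_f)^2 / (total * mu_f * (1 - mu_f)))
  phi <- if (n > k) pearson / (n - k) else 1
  converged <- isTRUE(fit_f$converged) && isTRUE(fit_r$converged)
  if (!converged) {
    warning("locus fit did not converge; reporting p = 1")
    p <- 1
  } else {
    scale_by <- if (correct) max(phi, 1) else 1
    p <- stats::pchisq(G / scale_by, df = 1, lower.tail = FALSE)
  }
  structure(list(beta = fit_f$coefficients, loglik_full = ll_f,
                 loglik_reduced = ll_r, G = G, phi = phi, df = 1L,
                 p_value = p, converged = converged),
            class = "locus_fit")
}

#' Pooled methylation difference between treatments
#'
#' 100 * (pooled treatment proportion - pooled control proportion), pooling
#' counts within each group; set `pooled = FALSE` for the difference of
#' unweighted per-sample percent means.
#'
#' @param count_meth,count_unmeth Integer vectors per sample.
#' @param treatment 0/1 indicator (1 = treatment group).
#' @param pooled Pool counts within group (default `TRUE`).
#' @return Difference in percentage points.
#' @export
meth_difference <- function(count_meth, count_unmeth, treatment, pooled = TRUE) {
  treat <- as.numeric(treatment) == 1
  total <- count_meth + count_unmeth
  if (pooled) {
    p_t <- sum(count_meth[treat]) / sum(total[treat])
    p_c <- sum(count_meth[!treat]) / sum(total[!treat])
  } else {
    p_t <- mean(count_meth[treat] / total[treat])
    p_c <- mean(count_meth[!treat] / total[!treat])
  }
  100 * (p_t - p_c)
}

#' Sliding-linear-model estimate of the true-null proportion
#'
#' Bins the empirical p-value CDF over [0, 1] and regresses it on lambda in
#' sliding windows. Under the two-group model the CDF slope decreases with
#' lambda toward the true-null proportion pi0; the estimate is the slope of
#' the first window after which successive slopes stabilize (change below
#' half the median absolute slope change), clipped to (0, 1].
#'
#' @param p Numeric p-values in [0, 1].
#' @param n_bins Number of CDF bins (default 100).
#' @param window Window width in bins (default 20).
#' @return A `pi0_estimate` list: `pi0`, `slopes`, `lambda`, `n_bins`,
#'   `window`.
#' @export
slim_pi0 <- function(p, n_bins = 100, window = 20) {
  assert_that(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  lambda <- seq_len(n_bins) / n_bins
  cdf <- vapply(lambda, function(l) mean(p <= l), numeric(1))
  starts <- seq_len(n_bins - window + 1L)
  slopes <- vapply(starts, function(s) {
    idx <- s:(s + window - 1L)
    x <- lambda[idx]
    stats::cov(x, cdf[idx]) / stats::var(x)
  }, numeric(1))
  d <- abs(diff(slopes))
  tol <- stats::median(d) / 2
  stable <- which(d <= tol)
  pick <- if (length(stable) > 0) min(stable) + 1L else which.min(d) + 1L
  pi0 <- min(max(slopes[pick], 1e-8), 1)
  structure(list(pi0 = pi0, slopes = slopes, lambda = lambda[starts],
                 n_bins = n_bins, window = window),
            class = "pi0_estimate")
}

#' SLIM q-values
#'
#' Benjamini-Hochberg adjusted p-values sharpened by the sliding-linear-
#' model estimate of the true-null proportion: q = pi0 * BH(p). With fewer
#' than 100 p-values the pi0 estimate is unreliable and the function falls
#' back to pi0 = 1 (pure BH) with a warning. Forcing `pi0` reproduces BH
#' exactly at `pi0 = 1`.
#'
#' @param p Numeric p-values.
#' @param pi0 Optional fixed pi0; `NULL` estimates it with [slim_pi0()].
#' @param ... Passed to [slim_pi0()].
#' @return List: `q` (same order as `p`, monotone in p, in [0, 1]) and
#'   `pi0_estimate`.
#' @export
slim_qvalues <- function(p, pi0 = NULL, ...) {
  est <- NULL
  if (is.null(pi0)) {
    if (length(p) < 100) {
      warning("fewer than 100 p-values; using pi0 = 1 (plain BH)")
      pi0 <- 1
    } else {
      est <- slim_pi0(p, ...)
      pi0 <- est$pi0
    }
  }
  q <- pmin(pi0 * stats::p.adjust(p, method = "BH"), 1)
  list(q = q, pi0 = pi0, pi0_estimate = est)
}

#' Test every locus of a methylation matrix
#'
#' Runs [fit_locus()] and [meth_difference()] across loci and attaches SLIM
#' q-values.
#'
#' @param mm A `methyl_matrix`.
#' @param correct Overdispersion correction (default `TRUE`).
#' @param use_covariate Include the maturation-stage covariate.
#' @param pooled_diff Pooled (coverage-weighted) methylation difference.
#' @return data.table: `chrom`, `pos`, `meth_diff`, `G`, `phi`, `p_value`,
#'   `q_value`; pi0 estimate attached as attribute `pi0`.
#' @export
dml_test <- function(mm, correct = TRUE, use_covariate = TRUE,
                     pooled_diff = TRUE) {
  treat <- as.integer(mm$samples$treatment == "low_pH")
  stage <- if (use_covariate) as.numeric(mm$samples$stage) else NULL
  n <- nrow(mm$loci)
  diff <- G <- phi <- p <- numeric(n)
  for (i in seq_len(n)) {
    fit <- fit_locus(mm$M[i, ], mm$U[i, ], treat, stage, correct = correct)
    diff[i] <- meth_difference(mm$M[i, ], mm$U[i, ], treat, pooled = pooled_diff)
    G[i] <- fit$G
    phi[i] <- fit$phi
    p[i] <- fit$p_value
  }
  qres <- slim_qvalues(p)
  out <- data.table::data.table(chrom = mm$loci$chrom, pos = mm$loci$pos,
                                meth_diff = diff, G = G, phi = phi,
                                p_value = p, q_value = qres$q)
  data.table::setattr(out, "pi0", qres$pi0)
  out[]
}

#' Call differentially methylated loci
#'
#' Candidates satisfy q < `q_cutoff` (strict) and |difference| >=
#' `diff_cutoff` (inclusive). Candidates overlapping the C->T SNP exclusion
#' set (at either strand position) are removed and counted; survivors are
#' labeled hypermethylated (difference > 0: higher in treatment) or
#' hypomethylated.
#'
#' @param results data.table from [dml_test()].
#' @param snps A `snp_set` (or `NULL` for no exclusion).
#' @param diff_cutoff Methylation-difference threshold in points (50).
#' @param q_cutoff q-value threshold (0.01).
#' @return List: `dml` (retained records with `direction` and
#'   `snp_overlap`), `candidates` (pre-exclusion records) and `accounting`
#'   (list `n_candidates`, `n_snp_removed`, `n_retained`, `n_hyper`,
#'   `n_hypo`).
#' @export
call_dml <- function(results, snps = NULL, diff_cutoff = 50, q_cutoff = 0.01) {
  res <- data.table::as.data.table(results)
  res[, snp_overlap := if (is.null(snps) || nrow(snps) == 0) FALSE else
        snp_overlap_flag(res, snps)]
  res[, direction := ifelse(q_value < q_cutoff & abs(meth_diff) >= diff_cutoff,
                            ifelse(meth_diff > 0, "hyper", "hypo"), "ns")]
  candidates <- res[direction != "ns"]
  dml <- candidates[snp_overlap == FALSE]
  acc <- list(n_candidates = nrow(candidates),
              n_snp_removed = nrow(candidates) - nrow(dml),
              n_retained = nrow(dml),
              n_hyper = sum(dml$direction == "hyper"),
              n_hypo = sum(dml$direction == "hypo"))
  list(dml = dml, candidates = candidates, accounting = acc)
}

#' Accounting arithmetic for a DML call chain
#'
#' Given candidate and exclusion counts, returns the retained count and the
#' hypo/hyper percentage shares, with the conservation identities checked.
#'
#' @param n_candidates Candidate DML (passing q and difference cutoffs).
#' @param n_snp_removed Candidates removed by SNP overlap.
#' @param n_hypo,n_hyper Direction split of the retained DML (optional).
#' @return List: `n_retained`, `pct_snp_removed`, and when the split is
#'   given, `pct_hypo` / `pct_hyper`.
#' @export
dml_accounting <- function(n_candidates, n_snp_removed, n_hypo = NULL,
                           n_hyper = NULL) {
  assert_that(n_snp_removed <= n_candidates,
              "cannot remove more candidates than exist")
  retained <- n_candidates - n_snp_removed
  out <- list(n_retained = retained,
              pct_snp_removed = 100 * n_snp_removed / n_candidates)
  if (!is.null(n_hypo) && !is.null(n_hyper)) {
    assert_that(n_hypo + n_hyper == retained,
                "hypo + hyper must equal retained DML")
    out$pct_hypo <- 100 * n_hypo / retained
    out$pct_hyper <- 100 * n_hyper / retained
  }
  out
}

#' Write DML records as BED and full TSV
#' @param dml data.table of retained DML.
#' @param bed_path,tsv_path Output paths (`NULL` skips).
#' @return Invisibly, the paths written.
#' @export
write_dml <- function(dml, bed_path = NULL, tsv_path = NULL) {
  written <- character()
  if (!is.null(bed_path)) {
    bed <- data.table::data.table(chrom = dml$chrom, start = dml$pos - 1L,
                                  end = dml$pos + 1L,
                                  name = dml$direction,
                                  score = round(dml$meth_diff, 2))
    data.table::fwrite(bed, bed_path, sep = "\t", col.names = FALSE)
    written <- c(written, bed_path)
  }
  if (!is.null(tsv_path)) {
    data.table::fwrite(dml, tsv_path, sep = "\t")
    written <- c(written, tsv_path)
  }
  invisible(written)
}
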