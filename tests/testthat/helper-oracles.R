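# Independent brute-force oracles used across tests. These deliberately
# avoid the package's own code paths.

# --- base-wise interval algebra on one chromosome -------------------------

mask_from_ranges <- function(starts, ends, len) {
  m <- logical(len)
  for (i in seq_along(starts)) {
    if (ends[i] >= starts[i]) m[starts[i]:ends[i]] <- TRUE
  }
  m
}

mask_from_gr <- function(gr, chrom, len) {
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  mask_from_ranges(GenomicRanges::start(gr), GenomicRanges::end(gr), len)
}

# random unstranded track on a single toy chromosome
random_track <- function(chrom, len, n_ranges) {
  s <- sort(sample.int(len, n_ranges, replace = TRUE))
  w <- sample.int(200, n_ranges, replace = TRUE)
  e <- pmin(s + w - 1L, len)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e),
                         seqlengths = stats::setNames(len, chrom))
}

# --- binomial likelihood-ratio test by grid maximization ------------------

grid_loglik <- function(m, tot, grid) {
  vapply(grid, function(p) sum(stats::dbinom(m, tot, p, log = TRUE)), numeric(1))
}

# two free group proportions vs one pooled proportion, maximized on a grid
grid_lrt_p <- function(count_meth, count_unmeth, treatment,
                       grid = seq(1e-4, 1 - 1e-4, by = 1e-4)) {
  tot <- count_meth + count_unmeth
  trt <- treatment == 1
  ll_full <- max(grid_loglik(count_meth[trt], tot[trt], grid)) +
    max(grid_loglik(count_meth[!trt], tot[!trt], grid))
  ll_red <- max(grid_loglik(count_meth, tot, grid))
  G <- 2 * (ll_full - ll_red)
  stats::pchisq(G, df = 1, lower.tail = FALSE)
}

# --- hypergeometric upper tail (Fisher one-sided oracle) -----------------

hyper_tail_p <- function(k, K, n, N) {
  # P[X >= k], X ~ Hypergeometric(N genes, K in term, n drawn)
  kk <- seq(k, min(K, n))
  sum(stats::dhyper(kk, K, N - K, n))
}

# --- tiny worked annotation (gene 101-400 with two exons) ----------------
# 1-based closed coordinates; equivalent to the 0-based half-open toy
# gene [100,400), exons [100,200)+[300,400), CDS [150,200)+[300,350).

toy_sizes <- function(len = 1000) data.table::data.table(chrom = "chr1", length = len)

toy_annotation <- function(len = 1000) {
  sl <- c(chr1 = len)
  gr <- function(s, e, strand = "+") {
    GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e), strand = strand,
                           gene_id = "geneA", seqlengths = sl)
  }
  list(genes = gr(101, 400),
       exons = c(gr(101, 200), gr(301, 400)),
       cds = c(gr(151, 200), gr(301, 350)))
}
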