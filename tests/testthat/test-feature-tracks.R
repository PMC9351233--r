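# Interval algebra: worked examples, base-wise brute-force oracle,
# idempotence and partition identities.

test_that("CG motif finding handles single, adjacent, absent and lowercase motifs", {
  hits <- find_cg_motifs(c(chr1 = "ACGT"))
  expect_equal(GenomicRanges::start(hits), 2)
  expect_equal(GenomicRanges::end(hits), 3)
  hits2 <- find_cg_motifs(c(chr1 = "CGCG"))
  expect_equal(GenomicRanges::start(hits2), c(1, 3))
  expect_length(find_cg_motifs(c(chr1 = "AATT")), 0)
  expect_equal(GenomicRanges::start(find_cg_motifs(c(chr1 = "acgt"))), 2)
})

test_that("complement tiles the chromosome exactly once", {
  sizes <- c(chr1 = 100)
  tr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(11, 41), c(20, 50)))
  comp <- track_complement(tr, sizes)
  expect_equal(GenomicRanges::start(comp), c(1, 21, 51))
  expect_equal(GenomicRanges::end(comp), c(10, 40, 100))
  # empty track -> whole chromosome; whole chromosome -> empty
  empty <- GenomicRanges::GRanges(seqlengths = sizes)
  expect_equal(GenomicRanges::width(track_complement(empty, sizes)), 100)
  whole <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
  expect_length(track_complement(whole, sizes), 0)
  # union of track and complement covers every base exactly once
  expect_equal(sum(GenomicRanges::width(comp)) + sum(GenomicRanges::width(tr)), 100)
  out_of_bounds <- GenomicRanges::GRanges("chr1", IRanges::IRanges(90, 150))
  expect_error(track_complement(out_of_bounds, sizes), "bounds")
})

test_that("intersect and subtract follow set arithmetic", {
  a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10))
  b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(6, 15))
  expect_equal(GenomicRanges::start(track_intersect(a, b)), 6)
  expect_equal(GenomicRanges::end(track_intersect(a, b)), 10)
  expect_equal(GenomicRanges::end(track_subtract(a, b)), 5)
  expect_length(track_subtract(a, a), 0)
})

test_that("flanks respect strand, clip to bounds, and exclude gene bases", {
  sizes <- c(chr1 = 10000)
  plus_gene <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 6000),
                                      strand = "+")
  up <- track_flank(plus_gene, sizes, 1000, "upstream")
  expect_equal(GenomicRanges::start(up), 4001)
  expect_equal(GenomicRanges::end(up), 5000)
  minus_gene <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 6000),
                                       strand = "-")
  up_m <- track_flank(minus_gene, sizes, 1000, "upstream")
  expect_equal(GenomicRanges::start(up_m), 6001)
  expect_equal(GenomicRanges::end(up_m), 7000)
  # clipping at the chromosome edge plus removal of another gene's bases
  two <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 201), c(100, 300)),
                                strand = "+")
  up2 <- track_flank(two, sizes, 1000, "upstream")
  expect_equal(GenomicRanges::start(up2), 101)
  expect_equal(GenomicRanges::end(up2), 200)
})

test_that("derived tracks reproduce the worked toy gene", {
  ann <- toy_annotation()
  tracks <- build_feature_tracks(ann$genes, ann$exons, ann$cds, toy_sizes(),
                                 flank_width = 100)
  expect_equal(GenomicRanges::start(tracks$intron), 201)
  expect_equal(GenomicRanges::end(tracks$intron), 300)
  expect_equal(GenomicRanges::start(tracks$exon_UTR), c(101, 351))
  expect_equal(GenomicRanges::end(tracks$exon_UTR), c(150, 400))
  expect_equal(GenomicRanges::start(tracks$flank_up), 1)
  expect_equal(GenomicRanges::end(tracks$flank_up), 100)
  expect_equal(GenomicRanges::start(tracks$flank_down), 401)
  # single-exon gene: no intron
  sl <- c(chr1 = 1000)
  g1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 400), strand = "+",
                               seqlengths = sl)
  t1 <- build_feature_tracks(g1, g1, g1, sl)
  expect_length(t1$intron, 0)
  # nesting violation is reported with the offending interval
  bad_cds <- GenomicRanges::GRanges("chr1", IRanges::IRanges(450, 500),
                                    seqlengths = sl)
  expect_error(build_feature_tracks(ann$genes, ann$exons, bad_cds, toy_sizes()),
               "CDS not contained in exon at chr1:450-500")
})

test_that("interval algebra matches a base-wise boolean-mask oracle", {
  set.seed(71)
  len <- 10000
  sizes <- c(chrZ = len)
  for (rep in 1:5) {
    a <- random_track("chrZ", len, 30)
    b <- random_track("chrZ", len, 30)
    ma <- mask_from_gr(a, "chrZ", len)
    mb <- mask_from_gr(b, "chrZ", len)
    expect_identical(mask_from_gr(track_complement(a, sizes), "chrZ", len), !ma)
    expect_identical(mask_from_gr(track_intersect(a, b), "chrZ", len), ma & mb)
    expect_identical(mask_from_gr(track_subtract(a, b), "chrZ", len), ma & !mb)
  }
  # strand-aware flank oracle
  g <- GenomicRanges::GRanges("chrZ",
                              IRanges::IRanges(c(500, 3000, 9500), c(1500, 4000, 9900)),
                              strand = c("+", "-", "+"))
  mg <- mask_from_gr(g, "chrZ", len)
  up_mask <- mask_from_ranges(c(1, 4001, 9000), c(499, 4500, 9499), len) & !mg
  expect_identical(mask_from_gr(track_flank(g, sizes, 500, "upstream"), "chrZ", len),
                   up_mask)
})

test_that("merge and complement are idempotent/involutive", {
  set.seed(72)
  sizes <- c(chrZ = 5000)
  x <- random_track("chrZ", 5000, 40)
  red <- GenomicRanges::reduce(x)
  expect_identical(GenomicRanges::reduce(red), red)
  expect_identical(track_complement(track_complement(x, sizes), sizes), sort(red))
})

test_that("intron/exon partition gene bases and UTR/CDS partition exon bases", {
  cfg <- sim_config(genome_length_per_chrom = 20000, n_chroms = 1, seed = 13L)
  g <- simulate_genome(cfg)
  ann <- simulate_annotation(g, cfg)
  tracks <- build_feature_tracks(ann$genes, ann$exons, ann$cds, g$sizes)
  len <- g$sizes$length[1]
  m <- function(tr) mask_from_gr(tr, "chr1", len)
  expect_identical(m(tracks$intron) | m(tracks$exon), m(tracks$gene))
  expect_false(any(m(tracks$intron) & m(tracks$exon)))
  expect_identical(m(tracks$exon_UTR) | m(tracks$cds), m(tracks$exon))
  expect_false(any(m(tracks$exon_UTR) & m(tracks$cds)))
  # intergenic excludes genes and flanks entirely
  expect_false(any(m(tracks$intergenic) &
                     (m(tracks$gene) | m(tracks$flank_up) | m(tracks$flank_down))))
  # gene + flanks + intergenic tile the chromosome
  expect_true(all(m(tracks$gene) | m(tracks$flank_up) | m(tracks$flank_down) |
                    m(tracks$intergenic)))
})

test_that("adjacent genes closer than twice the flank leave no intergenic gap", {
  sl <- c(chr1 = 10000)
  genes <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(2001, 3501), c(3000, 4500)),
                                  strand = "+", seqlengths = sl)
  exons <- genes; cds <- genes
  tracks <- build_feature_tracks(genes, exons, cds, sl, flank_width = 1000)
  gap_mask <- mask_from_ranges(3001, 3500, 10000)
  inter_mask <- mask_from_gr(tracks$intergenic, "chr1", 10000)
  flank_mask <- mask_from_gr(tracks$flank_up, "chr1", 10000) |
    mask_from_gr(tracks$flank_down, "chr1", 10000)
  expect_false(any(inter_mask & gap_mask))
  expect_true(all(flank_mask[3001:3500]))
})

test_that("CpG counting in tracks uses the one-base-overlap rule", {
  cg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(2, 12), width = 2))
  feat <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 5))
  expect_equal(count_cpgs_in_track(cg, feat), 1)
  whole <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
  expect_equal(count_cpgs_in_track(cg, whole), 2)
  # motif straddling the feature boundary still counts (brute-force check)
  straddle <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10, 11))
  feat2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(11, 20))
  expect_equal(count_cpgs_in_track(straddle, feat2), 1)
  m_feat <- mask_from_gr(feat2, "chr1", 30)
  expect_true(any(m_feat[10:11]))
})

test_that("BED and GFF3 round-trips preserve coordinates", {
  ann <- toy_annotation()
  gff <- tempfile(fileext = ".gff3")
  write_annotation_gff3(list(genes = ann$genes, exons = ann$exons, cds = ann$cds), gff)
  back <- read_annotation_gff3(gff, c(chr1 = 1000))
  expect_equal(GenomicRanges::start(back$genes), 101)
  expect_equal(GenomicRanges::end(back$genes), 400)
  expect_equal(sort(GenomicRanges::start(back$cds)), c(151, 301))
  expect_equal(back$genes$gene_id, "geneA")
  bed <- tempfile(fileext = ".bed")
  write_track_bed(ann$genes, bed)
  # BED is 0-based half-open on disk
  raw <- read.table(bed, sep = "\t")
  expect_equal(raw$V2, 100)
  expect_equal(raw$V3, 400)
  rt <- read_track_bed(bed, c(chr1 = 1000))
  expect_equal(GenomicRanges::start(rt), 101)
  expect_equal(GenomicRanges::end(rt), 400)
})
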