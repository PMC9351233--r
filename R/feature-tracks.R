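# Genome feature tracks and interval algebra.
#
# All tracks are GRanges (1-based, closed intervals). Derived tracks are
# computed by base-wise set algebra, ignoring strand except where a flank's
# side depends on it: intron = gene \ exon, exon UTR = exon \ CDS, flanks =
# 1-kb windows beside genes minus any gene bases, intergenic = complement of
# genes minus flanks.

#' @keywords internal
as_seqlengths <- function(sizes) {
  if (is.numeric(sizes) && !is.null(names(sizes))) return(sizes)
  stats::setNames(sizes$length, sizes$chrom)
}

#' @keywords internal
whole_genome_gr <- function(sizes) {
  sl <- as_seqlengths(sizes)
  GenomicRanges::GRanges(names(sl), IRanges::IRanges(1L, unname(sl)),
                         seqlengths = sl)
}

#' Find CG dinucleotide motifs on the plus strand
#'
#' Scans each chromosome for occurrences of "CG" (case-insensitive) and
#' returns one width-2 range per motif, anchored at the cytosine.
#' Overlapping occurrences (as in "CGCG") are all reported.
#'
#' @param genome A `sim_genome`, a [Biostrings::DNAStringSet], or a named
#'   character vector of sequences.
#' @return A [GenomicRanges::GRanges] of CG motifs.
#' @export
find_cg_motifs <- function(genome) {
  seqs <- if (inherits(genome, "sim_genome")) genome$seq else genome
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(toupper(seqs))
  hits <- Biostrings::vmatchPattern("CG", seqs)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(names(seqs), lengths(hits)),
    ranges = unlist(IRanges::IRangesList(hits), use.names = FALSE),
    seqlengths = stats::setNames(Biostrings::width(seqs), names(seqs)))
  sort(gr)
}

#' Complement of a track within chromosome bounds
#'
#' Returns the maximal intervals covering every base not in the merged
#' input; the union of input and output tiles each chromosome exactly once.
#'
#' @param track GRanges.
#' @param sizes Chromosome sizes (data.table `chrom`/`length` or named
#'   vector).
#' @return Unstranded GRanges.
#' @export
track_complement <- function(track, sizes) {
  whole <- whole_genome_gr(sizes)
  red <- GenomicRanges::reduce(track, ignore.strand = TRUE)
  assert_that(all(GenomicRanges::start(red) >= 1) &&
                all(GenomicRanges::end(red) <=
                      as_seqlengths(sizes)[as.character(GenomicRanges::seqnames(red))]),
              "track extends beyond chromosome bounds")
  sort(GenomicRanges::setdiff(whole, red, ignore.strand = TRUE))
}

#' Base-wise intersection of two tracks
#' @param a,b GRanges.
#' @return Merged, sorted, unstranded GRanges of bases present in both.
#' @export
track_intersect <- function(a, b) {
  sort(GenomicRanges::intersect(a, b, ignore.strand = TRUE))
}

#' Base-wise subtraction (a minus b)
#' @param a,b GRanges.
#' @return Merged, sorted, unstranded GRanges of bases of `a` not in `b`.
#' @export
track_subtract <- function(a, b) {
  sort(GenomicRanges::setdiff(a, b, ignore.strand = TRUE))
}

#' Strand-aware gene flanks
#'
#' The `width`-bp window upstream or downstream of each gene relative to its
#' strand, clipped to chromosome bounds, with all gene bases removed
#' (flanks of one gene may fall inside another gene; those bases are
#' excluded). Flanks of adjacent genes may overlap each other and are merged
#' within the class.
#'
#' @param genes Stranded GRanges of genes.
#' @param sizes Chromosome sizes.
#' @param width Flank width in bp (default 1000, the putative-promoter
#'   width for upstream flanks).
#' @param side `"upstream"` or `"downstream"`.
#' @return Unstranded merged GRanges.
#' @export
track_flank <- function(genes, sizes, width = 1000, side = c("upstream", "downstream")) {
  side <- match.arg(side)
  assert_that(width > 0, "flank width must be positive")
  sl <- as_seqlengths(sizes)
  # compute windows without seqlengths, then clip to bounds explicitly
  bare <- GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                                 IRanges::ranges(genes),
                                 strand = GenomicRanges::strand(genes))
  fl <- GenomicRanges::flank(bare, width = width, start = side == "upstream")
  GenomicRanges::start(fl) <- pmax(GenomicRanges::start(fl), 1L)
  chrom_len <- unname(sl[as.character(GenomicRanges::seqnames(fl))])
  GenomicRanges::end(fl) <- pmin(GenomicRanges::end(fl), chrom_len)
  fl <- fl[GenomicRanges::width(fl) > 0]
  GenomeInfoDb::seqlevels(fl) <- names(sl)
  GenomeInfoDb::seqlengths(fl) <- sl
  track_subtract(fl, genes)
}

#' Derive the full genome feature track set
#'
#' From gene, exon and CDS tracks derives introns (gene minus exon), exon
#' UTRs (exon minus CDS), 1-kb up/downstream flanks (gene bases removed) and
#' intergenic regions (complement of genes minus flanks). Verifies the
#' base-wise nesting CDS within exon within gene before deriving.
#'
#' @param genes,exons,cds GRanges (genes/exons stranded; `gene_id` metadata
#'   on genes is preserved).
#' @param sizes Chromosome sizes.
#' @param te,lncrna Optional GRanges consumed as-is (e.g. RepeatMasker BED).
#' @param flank_width Flank width in bp.
#' @return A `feature_tracks` list of GRanges: `gene`, `exon`, `cds`,
#'   `intron`, `exon_UTR`, `flank_up`, `flank_down`, `intergenic`, plus
#'   `te`/`lncrna` when given, with `sizes` attached.
#' @export
build_feature_tracks <- function(genes, exons, cds, sizes, te = NULL,
                                 lncrna = NULL, flank_width = 1000) {
  check_nested <- function(inner, outer, lab_in, lab_out) {
    stray <- track_subtract(inner, outer)
    if (length(stray) > 0) {
      g <- stray[1]
      stop(sprintf("%s not contained in %s at %s:%d-%d", lab_in, lab_out,
                   as.character(GenomicRanges::seqnames(g)),
                   GenomicRanges::start(g), GenomicRanges::end(g)),
           call. = FALSE)
    }
  }
  check_nested(cds, exons, "CDS", "exon")
  check_nested(exons, genes, "exon", "gene")

  non_exon <- track_complement(exons, sizes)
  intron <- track_intersect(genes, non_exon)
  exon_utr <- track_subtract(exons, cds)
  flank_up <- track_flank(genes, sizes, flank_width, "upstream")
  flank_down <- track_flank(genes, sizes, flank_width, "downstream")
  non_gene <- track_complement(genes, sizes)
  intergenic <- track_subtract(non_gene,
                               GenomicRanges::union(flank_up, flank_down,
                                                    ignore.strand = TRUE))
  tracks <- list(gene = genes, exon = exons, cds = cds, intron = intron,
                 exon_UTR = exon_utr, flank_up = flank_up,
                 flank_down = flank_down, intergenic = intergenic)
  if (!is.null(te)) tracks$te <- te
  if (!is.null(lncrna)) tracks$lncrna <- lncrna
  attr(tracks, "sizes") <- as_seqlengths(sizes)
  class(tracks) <- "feature_tracks"
  tracks
}

#' Count CG motifs overlapping a feature track
#'
#' A motif is counted when it overlaps the merged track by at least one
#' base, so a CpG straddling a feature boundary counts.
#'
#' @param cg GRanges of CG motifs (width 2).
#' @param track GRanges.
#' @return Integer count.
#' @export
count_cpgs_in_track <- function(cg, track) {
  sum(IRanges::overlapsAny(cg, GenomicRanges::reduce(track, ignore.strand = TRUE),
                           minoverlap = 1L, ignore.strand = TRUE))
}

#' Build width-2 CpG locus ranges from destranded positions
#' @param chrom,pos Vectors: chromosome and 1-based plus-strand C position.
#' @param sizes Chromosome sizes.
#' @return GRanges with one width-2 range per CpG.
#' @export
cpg_granges <- function(chrom, pos, sizes = NULL) {
  sl <- if (is.null(sizes)) NULL else as_seqlengths(sizes)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos + 1L),
                         seqlengths = sl)
}

#' Write a track as BED
#' @param track GRanges.
#' @param path Output file (coordinates converted to 0-based half-open).
#' @return `path`, invisibly.
#' @export
write_track_bed <- function(track, path) {
  rtracklayer::export(track, path, format = "BED")
  invisible(path)
}

#' Read a BED track
#' @param path BED file.
#' @param sizes Optional chromosome sizes to attach.
#' @return GRanges (1-based, closed).
#' @export
read_track_bed <- function(path, sizes = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(sizes)) {
    sl <- as_seqlengths(sizes)
    GenomeInfoDb::seqlevels(gr) <- names(sl)
    GenomeInfoDb::seqlengths(gr) <- sl
  }
  gr
}

#' Write chromosome sizes as a two-column TSV
#' @param sizes data.table `chrom`/`length` or named vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(sizes, path) {
  sl <- as_seqlengths(sizes)
  data.table::fwrite(data.table::data.table(chrom = names(sl), length = unname(sl)),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a chromosome sizes TSV
#' @param path Two-column TSV (chrom, length).
#' @return data.table with `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  data.table::fread(path, header = FALSE, col.names = c("chrom", "length"))
}
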