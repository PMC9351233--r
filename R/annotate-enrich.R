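# DML and methylation-class characterization against genome features,
# contingency tests, and GO-term enrichment.

# Precedence for the mutually exclusive partition used by contingency
# tests: a locus overlapping several derived classes is assigned the first
# matching one. TE/lncRNA never enter the partition (reported only in the
# overlapping-class table).
PARTITION_CLASSES <- c("cds", "exon_UTR", "intron", "flank_up", "flank_down",
                       "intergenic")

#' Assign each CpG locus its partition feature class
#' @param loci GRanges of width-2 CpG loci (see [cpg_granges()]).
#' @param tracks A `feature_tracks` set.
#' @return Character vector, one label per locus.
#' @export
locus_partition <- function(loci, tracks) {
  label <- rep(NA_character_, length(loci))
  for (cls in PARTITION_CLASSES) {
    hit <- IRanges::overlapsAny(loci, tracks[[cls]], minoverlap = 1L,
                                ignore.strand = TRUE)
    label[is.na(label) & hit] <- cls
  }
  label[is.na(label)] <- "intergenic"
  label
}

#' Overlap a set of loci with every feature track
#'
#' Counts, per feature class, the loci overlapping the class by at least
#' one base. Classes are not mutually exclusive (a genic locus inside a
#' transposable element counts in both), so percentages may sum past 100.
#' Also returns the mutually exclusive partition (CDS > exon UTR > intron >
#' upstream flank > downstream flank > intergenic) used by contingency
#' tests.
#'
#' @param loci Destranded 1-based loci: a data.table with `chrom`, `pos`,
#'   or a GRanges.
#' @param tracks A `feature_tracks` set.
#' @return List: `table` (data.table `feature`, `n`, `percent`, including a
#'   `genic` row for gene-track overlap), `partition` (per-locus labels),
#'   `partition_counts` (named vector), `n_loci`.
#' @export
overlap_features <- function(loci, tracks) {
  gr <- if (inherits(loci, "GRanges")) loci else
    cpg_granges(loci$chrom, loci$pos, attr(tracks, "sizes"))
  n <- length(gr)
  classes <- c(genic = "gene", intron = "intron", cds = "cds",
               exon_UTR = "exon_UTR", flank_up = "flank_up",
               flank_down = "flank_down", intergenic = "intergenic",
               te = "te", lncrna = "lncrna")
  classes <- classes[unname(classes) %in% names(tracks)]
  counts <- vapply(classes, function(cls) {
    sum(IRanges::overlapsAny(gr, tracks[[cls]], minoverlap = 1L,
                             ignore.strand = TRUE))
  }, integer(1))
  tab <- data.table::data.table(feature = names(classes), n = counts,
                                percent = round(100 * counts / max(1L, n), 1))
  part <- locus_partition(gr, tracks)
  part_counts <- table(factor(part, levels = PARTITION_CLASSES))
  list(table = tab, partition = part,
       partition_counts = stats::setNames(as.integer(part_counts),
                                          names(part_counts)),
       n_loci = n)
}

#' Chi-squared contingency test of feature distributions
#'
#' Tests association between genomic location and locus status (e.g. all
#' 5x CpGs versus highly methylated CpGs, or versus DML) on a 2 x k count
#' table built from two mutually exclusive partitions. No continuity
#' correction, for 2 x 2 tables included. Categories with a zero margin are
#' dropped with a warning; expected counts below 5 trigger a warning.
#'
#' @param background_counts,query_counts Named integer vectors over the
#'   same feature categories.
#' @return List: `statistic`, `df`, `p_value`, `expected`, `observed`.
#' @export
contingency_test <- function(background_counts, query_counts) {
  cats <- union(names(background_counts), names(query_counts))
  bg <- stats::setNames(rep(0L, length(cats)), cats)
  qy <- bg
  bg[names(background_counts)] <- background_counts
  qy[names(query_counts)] <- query_counts
  keep <- bg + qy > 0
  if (!all(keep)) {
    warning("dropping zero-margin categories: ",
            paste(cats[!keep], collapse = ", "))
  }
  m <- rbind(background = bg[keep], query = qy[keep])
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  if (any(ht$expected < 5)) warning("expected count below 5 in some cell")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, expected = ht$expected, observed = m)
}

#' Per-chromosome DML density
#'
#' DML, CpG and gene counts per chromosome with the DML-per-CpG density;
#' chromosomes outside `main_chroms` are aggregated into a single
#' "scaffolds" row.
#'
#' @param dml data.table with `chrom` (one row per DML).
#' @param cpg_per_chrom Named vector or data.table (`chrom`, `n`) of CpG
#'   counts.
#' @param genes_per_chrom Named vector or data.table (`chrom`, `n`) of gene
#'   counts.
#' @param main_chroms Chromosomes reported individually (default: all in
#'   `cpg_per_chrom`).
#' @return data.table: `chrom`, `n_dml`, `n_cpg`, `n_genes`, `density`.
#' @export
chromosome_density <- function(dml, cpg_per_chrom, genes_per_chrom,
                               main_chroms = NULL) {
  as_named <- function(x) {
    if (is.numeric(x) && !is.null(names(x))) return(x)
    dt <- data.table::as.data.table(x)
    stats::setNames(dt[[2]], dt[[1]])
  }
  cpg <- as_named(cpg_per_chrom)
  genes <- as_named(genes_per_chrom)
  if (is.null(main_chroms)) main_chroms <- names(cpg)
  bucket <- function(chrom) ifelse(chrom %in% main_chroms, chrom, "scaffolds")
  dml_n <- table(bucket(dml$chrom))
  all_buckets <- unique(c(main_chroms, bucket(names(cpg))))
  out <- data.table::data.table(chrom = all_buckets)
  out[, n_dml := as.integer(dml_n[chrom])]
  out[is.na(n_dml), n_dml := 0L]
  cpg_b <- tapply(cpg, bucket(names(cpg)), sum)
  gene_b <- tapply(genes, bucket(names(genes)), sum)
  out[, n_cpg := as.integer(cpg_b[chrom])]
  out[, n_genes := as.integer(gene_b[chrom])]
  out[is.na(n_cpg), n_cpg := 0L]
  out[is.na(n_genes), n_genes := 0L]
  out[, density := ifelse(n_cpg > 0, n_dml / n_cpg, 0)]
  out[]
}

#' Count DML per gene
#'
#' A DML inside two overlapping genes counts for both; genes without DML
#' are omitted.
#'
#' @param dml data.table with `chrom`, `pos` (destranded loci).
#' @param genes GRanges with `gene_id` metadata.
#' @param sizes Optional chromosome sizes.
#' @return data.table `gene_id`, `n_dml`, sorted decreasing.
#' @export
dml_per_gene <- function(dml, genes, sizes = NULL) {
  if (nrow(dml) == 0) {
    return(data.table::data.table(gene_id = character(), n_dml = integer()))
  }
  gr <- cpg_granges(dml$chrom, dml$pos, sizes)
  hits <- GenomicRanges::findOverlaps(gr, genes, minoverlap = 1L,
                                      ignore.strand = TRUE)
  if (length(hits) == 0) {
    return(data.table::data.table(gene_id = character(), n_dml = integer()))
  }
  counts <- table(genes$gene_id[S4Vectors::subjectHits(hits)])
  out <- data.table::data.table(gene_id = names(counts),
                                n_dml = as.integer(counts))
  data.table::setorder(out, -n_dml, gene_id)
  out[]
}

#' Read a gene-to-GO mapping TSV
#' @param path Two-column TSV: gene id, comma-separated GO ids.
#' @return Named list: gene id -> character vector of GO ids.
#' @export
read_gene2go <- function(path) {
  dt <- data.table::fread(path, header = FALSE, col.names = c("gene_id", "go_ids"))
  stats::setNames(strsplit(dt$go_ids, ",", fixed = TRUE), dt$gene_id)
}

#' GO-term enrichment by one-sided Fisher's exact test
#'
#' For each GO term annotating at least one universe gene, tests
#' over-representation of the term among the genes of interest against the
#' rest of the universe (2 x 2 Fisher's exact, alternative "greater").
#' Following common practice for term-by-term GO testing, p-values are not
#' corrected for multiple comparisons; terms with p below `p_cutoff` are
#' flagged.
#'
#' @param interest_genes Character vector, must be a subset of
#'   `universe_genes` (e.g. genes containing at least one retained DML,
#'   with genes whose only DML overlapped SNPs already excluded).
#' @param universe_genes Character vector (e.g. genes containing CpGs with
#'   5x coverage in all samples).
#' @param gene2go Named list gene -> GO ids, a data.table (`gene_id`,
#'   `go_ids` comma-separated), or a path readable by [read_gene2go()].
#' @param ontology Optional named vector GO id -> ontology (`BP`/`CC`/`MF`)
#'   carried into the output.
#' @param p_cutoff Significance flag threshold (default 0.01, uncorrected).
#' @return data.table: `go_id`, `ontology`, `n_universe`, `n_interest`,
#'   `p_value`, `significant`, ordered by p.
#' @export
go_enrichment <- function(interest_genes, universe_genes, gene2go,
                          ontology = NULL, p_cutoff = 0.01) {
  if (is.character(gene2go) && length(gene2go) == 1 && file.exists(gene2go)) {
    gene2go <- read_gene2go(gene2go)
  }
  if (is.data.frame(gene2go)) {
    gene2go <- stats::setNames(strsplit(gene2go$go_ids, ",", fixed = TRUE),
                               gene2go$gene_id)
  }
  assert_that(length(universe_genes) > 0, "empty gene universe")
  assert_that(length(interest_genes) > 0, "empty interest set")
  assert_that(all(interest_genes %in% universe_genes),
              "interest genes must be a subset of the universe")
  gene2go <- gene2go[names(gene2go) %in% universe_genes]
  long <- data.table::data.table(
    gene_id = rep(names(gene2go), lengths(gene2go)),
    go_id = unlist(gene2go, use.names = FALSE))
  if (nrow(long) == 0) stop("no GO annotations for any universe gene")
  N <- length(unique(universe_genes))
  n <- length(unique(interest_genes))
  long[, in_interest := gene_id %in% interest_genes]
  per_term <- long[, .(n_universe = data.table::uniqueN(gene_id),
                       n_interest = data.table::uniqueN(gene_id[in_interest])),
                   by = go_id]
  per_term[, p_value := mapply(function(K, k) {
    m <- matrix(c(k, K - k, n - k, N - K - (n - k)), nrow = 2)
    stats::fisher.test(m, alternative = "greater")$p.value
  }, n_universe, n_interest)]
  per_term[, ontology := if (is.null(ontology)) NA_character_ else
             unname(ontology[go_id])]
  per_term[, significant := p_value < p_cutoff]
  data.table::setorder(per_term, p_value, go_id)
  per_term[, .(go_id, ontology, n_universe, n_interest, p_value, significant)]
}

#' Genes of interest for enrichment from a DML call
#'
#' A gene is of interest when it contains at least one retained DML; genes
#' whose only candidate DML overlapped C->T SNPs are excluded by
#' construction (retained DML already exclude SNP overlaps).
#'
#' @param dml Retained DML data.table (`chrom`, `pos`).
#' @param genes GRanges with `gene_id`.
#' @param sizes Optional chromosome sizes.
#' @return Character vector of gene ids.
#' @export
dml_interest_genes <- function(dml, genes, sizes = NULL) {
  dml_per_gene(dml, genes, sizes)$gene_id
}
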