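# Synthetic genome and annotation.

#' Simulate a toy genome with a controlled CpG density
#'
#' Builds random chromosome sequences in which every CG dinucleotide is
#' planted deliberately: the random background is scrubbed of incidental
#' CGs, then `round(length * density / 1000)` CG motifs are written at
#' distinct positions. The CpG count of the emitted sequence therefore
#' equals the planted count exactly, which keeps downstream truth tables
#' unambiguous.
#'
#' @param config A [sim_config()].
#' @return A `sim_genome`: list with `seq` (a [Biostrings::DNAStringSet]),
#'   `sizes` (data.table: `chrom`, `length`) and `cg` (data.table: `chrom`,
#'   `start` = 1-based position of the plus-strand C of each CpG).
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  len <- config$genome_length_per_chrom
  assert_that(len >= 2L, "chromosomes must be at least 2 bases long")
  n_cpg <- max(1L, round(len * config$gc_cpg_density / 1000))
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  seqs <- character(config$n_chroms)
  cg_list <- vector("list", config$n_chroms)
  for (i in seq_along(chroms)) {
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                prob = c(0.3, 0.2, 0.2, 0.3))
    # scrub incidental CG dinucleotides so planted motifs are the only ones
    repeat {
      hit <- which(s[-len] == "C" & s[-1] == "G")
      if (length(hit) == 0) break
      s[hit + 1] <- "A"
    }
    # plant CG motifs on odd positions: guarantees non-overlap and an exact count
    candidates <- seq(1L, len - 1L, by = 2L)
    n_here <- min(n_cpg, length(candidates))
    pos <- sort(sample(candidates, n_here))
    s[pos] <- "C"
    s[pos + 1L] <- "G"
    seqs[i] <- paste(s, collapse = "")
    cg_list[[i]] <- data.table::data.table(chrom = chroms[i], start = pos)
  }
  names(seqs) <- chroms
  out <- list(
    seq = Biostrings::DNAStringSet(seqs),
    sizes = data.table::data.table(chrom = chroms, length = len),
    cg = data.table::rbindlist(cg_list)
  )
  class(out) <- "sim_genome"
  out
}

#' Simulate a gene/exon/CDS annotation over a toy genome
#'
#' Tiles each chromosome with genes separated by variable intergenic gaps
#' (some narrower than the 1-kb flank width, so flank/intergenic arithmetic
#' is exercised). Each gene carries one to three exons; multi-exon genes
#' have derivable introns, and coding sequence is trimmed inside terminal
#' exons so exon UTRs exist. Strands alternate. Also emits a small
#' transposable-element track and marks a subset of genes as lncRNA hosts.
#'
#' @param genome A `sim_genome`.
#' @param config A [sim_config()].
#' @return List of [GenomicRanges::GRanges]: `genes`, `exons`, `cds`, `te`,
#'   `lncrna`. Gene-level ranges carry a `gene_id` metadata column.
#' @export
simulate_annotation <- function(genome, config) {
  set.seed(config$seed + 1L)
  sizes <- genome$sizes
  genes <- list(); exons <- list(); cds <- list(); te <- list()
  gid <- 0L
  for (i in seq_len(nrow(sizes))) {
    chrom <- sizes$chrom[i]; len <- sizes$length[i]
    pos <- 400L + sample(0:400, 1)
    strand_flip <- sample(c(TRUE, FALSE), 1)
    while (pos + 1200L < len - 400L) {
      gid <- gid + 1L
      glen <- sample(1000:4000, 1)
      glen <- min(glen, len - 400L - pos)
      if (glen < 600L) break
      gstart <- pos; gend <- pos + glen - 1L
      strand <- if (strand_flip) "+" else "-"
      strand_flip <- !strand_flip
      id <- sprintf("gene%04d", gid)
      genes[[length(genes) + 1L]] <- data.table::data.table(
        chrom = chrom, start = gstart, end = gend, strand = strand, gene_id = id)
      n_ex <- sample(1:3, 1, prob = c(0.2, 0.4, 0.4))
      # partition the gene span into exons separated by interior introns
      bounds <- sort(sample(seq(gstart + 150L, gend - 150L), 2L * (n_ex - 1L)))
      ex_start <- c(gstart, bounds[seq_along(bounds) %% 2 == 0] + 1L)
      ex_end <- c(bounds[seq_along(bounds) %% 2 == 1], gend)
      keep <- ex_end - ex_start >= 50L
      if (!all(keep)) { ex_start <- c(gstart, gend - 200L); ex_end <- c(gstart + 200L, gend); n_ex <- 2L }
      for (k in seq_along(ex_start)) {
        exons[[length(exons) + 1L]] <- data.table::data.table(
          chrom = chrom, start = ex_start[k], end = ex_end[k], strand = strand, gene_id = id)
        # CDS: shave a UTR margin off the first and last exon
        cstart <- ex_start[k]; cend <- ex_end[k]
        margin <- max(20L, (cend - cstart) %/% 4L)
        if (k == 1L) cstart <- cstart + margin
        if (k == length(ex_start)) cend <- cend - margin
        if (cend > cstart) {
          cds[[length(cds) + 1L]] <- data.table::data.table(
            chrom = chrom, start = cstart, end = cend, strand = strand, gene_id = id)
        }
      }
      pos <- gend + sample(c(500L, 800L, 1500L, 2500L), 1)
    }
    # transposable elements: short intervals scattered irrespective of genes
    n_te <- max(1L, len %/% 10000L)
    te_start <- sort(sample(seq(1L, len - 300L), n_te))
    te[[length(te) + 1L]] <- data.table::data.table(
      chrom = chrom, start = te_start, end = te_start + sample(100:300, n_te, replace = TRUE))
  }
  gene_dt <- data.table::rbindlist(genes)
  assert_that(nrow(gene_dt) > 0, "genome too short to place any gene")
  mk <- function(dt, stranded = TRUE) {
    GenomicRanges::GRanges(
      seqnames = dt$chrom,
      ranges = IRanges::IRanges(start = dt$start, end = dt$end),
      strand = if (stranded && "strand" %in% names(dt)) dt$strand else "*",
      gene_id = if ("gene_id" %in% names(dt)) dt$gene_id else NULL,
      seqlengths = stats::setNames(sizes$length, sizes$chrom))
  }
  lnc_ids <- gene_dt$gene_id[seq(1, nrow(gene_dt), by = 5)]
  ann <- list(
    genes = mk(gene_dt),
    exons = mk(data.table::rbindlist(exons)),
    cds = mk(data.table::rbindlist(cds)),
    te = mk(data.table::rbindlist(te), stranded = FALSE),
    lncrna = mk(gene_dt[gene_dt$gene_id %in% lnc_ids])
  )
  ann
}

#' Write a genome to FASTA
#' @param genome A `sim_genome`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$seq, filepath = path)
  invisible(path)
}

#' Read a genome FASTA into the container used by the pipeline
#' @param path FASTA file.
#' @return A `sim_genome`-shaped list (`seq`, `sizes`, `cg`).
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  cg <- find_cg_motifs(seqs)
  out <- list(
    seq = seqs,
    sizes = data.table::data.table(chrom = names(seqs), length = Biostrings::width(seqs)),
    cg = data.table::data.table(chrom = as.character(GenomicRanges::seqnames(cg)),
                                start = GenomicRanges::start(cg))
  )
  class(out) <- "sim_genome"
  out
}

#' Write gene/exon/CDS annotation as GFF3
#' @param annotation List from [simulate_annotation()].
#' @param path Output GFF3 file.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  rows <- function(gr, type) {
    if (length(gr) == 0) return(NULL)
    data.table::data.table(
      seqid = as.character(GenomicRanges::seqnames(gr)),
      source = "dmlscreen", type = type,
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      score = ".", strand = as.character(GenomicRanges::strand(gr)),
      phase = ".",
      attributes = if (type == "gene") sprintf("ID=%s", gr$gene_id)
                   else sprintf("Parent=%s", gr$gene_id))
  }
  dt <- data.table::rbindlist(list(rows(annotation$genes, "gene"),
                                   rows(annotation$exons, "exon"),
                                   rows(annotation$cds, "CDS")))
  dt$strand[dt$strand == "*"] <- "."
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(dt) > 0) {
    data.table::setorder(dt, seqid, start, end)
    utils::write.table(dt, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read gene/exon/CDS tracks from a GFF3 file
#' @param path GFF3 file.
#' @param seqlengths Optional named integer vector of chromosome lengths.
#' @return List of GRanges: `genes`, `exons`, `cds`.
#' @export
read_annotation_gff3 <- function(path, seqlengths = NULL) {
  gff <- rtracklayer::import(path, format = "gff3")
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gff) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gff) <- seqlengths
  }
  pick <- function(type) {
    gr <- gff[tolower(as.character(gff$type)) == tolower(type)]
    id <- if (type == "gene") as.character(gr$ID)
          else S4Vectors::unstrsplit(gr$Parent, ",")
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(gene_id = id)
    gr
  }
  list(genes = pick("gene"), exons = pick("exon"), cds = pick("CDS"))
}
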