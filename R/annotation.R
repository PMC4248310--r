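#' Gene annotation objects
#'
#' A `gene_annotation` holds the gene models driving quantification, null
#' construction and TSS windows: per-gene coordinates (0-based, half-open),
#' strand, the 5' TSS, the summed exonic length, and the exon intervals.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, `exonic_length`, `biotype`.
#' @param exons data.frame with columns `gene_id`, `start`, `end`.
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @return An object of class `gene_annotation`.
#' @export
gene_annotation <- function(genes, exons, chrom_lengths) {
  need <- c("gene_id", "chrom", "start", "end", "strand", "tss",
            "exonic_length", "biotype")
  if (!all(need %in% names(genes)))
    stop("genes is missing columns: ", paste(setdiff(need, names(genes)), collapse = ", "))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in annotation")
  if (any(genes$exonic_length <= 0)) stop("exonic_length must be > 0")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(genes$tss < 0) || any(genes$tss > chrom_lengths[genes$chrom]))
    stop("tss outside chromosome bounds")
  structure(list(genes = genes, exons = exons, chrom_lengths = chrom_lengths),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d genes on %d chromosome(s), %.1f%% intergenic\n",
              nrow(x$genes), length(x$chrom_lengths),
              100 * intergenic_fraction(x)))
  invisible(x)
}

#' Fraction of the genome not covered by gene spans
#' @param annotation A `gene_annotation`.
#' @return Scalar in [0, 1].
#' @export
intergenic_fraction <- function(annotation) {
  g <- annotation$genes
  covered <- sum(g$end - g$start)
  1 - covered / sum(annotation$chrom_lengths)
}

#' Simulate a gene annotation with intergenic space
#'
#' Places non-overlapping multi-exon gene models on both strands of a single
#' synthetic chromosome, leaving randomly sized intergenic gaps. At least half
#' of the genome is left intergenic by construction, so that decoy gene models
#' can later be shifted into the gaps.
#'
#' @param n_genes Number of genes (>= 1).
#' @param genome_length Chromosome length in bp; must be at least twice the
#'   total simulated gene span.
#' @param seed Integer seed; output is reproducible bit-for-bit.
#' @param span_meanlog,span_sdlog Log-normal law for gene span (bp).
#' @param max_exons Maximum exons per gene.
#' @param p_coding Fraction of genes given biotype "protein_coding".
#' @param chrom Chromosome name.
#' @return A `gene_annotation`.
#' @export
generate_annotation <- function(n_genes, genome_length, seed = 1L,
                                span_meanlog = log(2000), span_sdlog = 0.6,
                                max_exons = 6L, p_coding = 0.9,
                                chrom = "chr1") {
  if (n_genes < 1) stop("n_genes must be >= 1")
  set.seed(seed)
  spans <- pmax(200, round(stats::rlnorm(n_genes, span_meanlog, span_sdlog)))
  total_span <- sum(spans)
  if (genome_length < 2 * total_span)
    stop(sprintf("genome too small: %d bp cannot host %d bp of gene span plus equal intergenic space",
                 genome_length, total_span))
  # distribute intergenic space across n_genes + 1 gaps
  gap_total <- genome_length - total_span
  w <- stats::rgamma(n_genes + 1L, shape = 1)
  gaps <- floor(gap_total * w / sum(w))
  gaps[n_genes + 1L] <- gaps[n_genes + 1L] + (gap_total - sum(gaps))
  starts <- cumsum(gaps[seq_len(n_genes)]) + c(0, cumsum(spans))[seq_len(n_genes)]
  ends <- starts + spans
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  biotype <- ifelse(stats::runif(n_genes) < p_coding, "protein_coding", "lincRNA")
  gene_id <- sprintf("G%05d", seq_len(n_genes))

  ex_list <- vector("list", n_genes)
  exonic_length <- numeric(n_genes)
  for (i in seq_len(n_genes)) {
    s <- spans[i]
    k_max <- max(1L, min(max_exons, floor((s / 50 + 1) / 2)))
    k <- sample.int(k_max, 1L)
    n_seg <- 2L * k - 1L
    # partition span into alternating exon/intron segments, each >= 50 bp
    piece <- as.numeric(stats::rgamma(n_seg, shape = 1)) + 0.1
    widths <- pmax(50, floor(s * piece / sum(piece)))
    widths[n_seg] <- widths[n_seg] + (s - sum(widths))
    if (widths[n_seg] < 1) { widths <- s; n_seg <- 1L; k <- 1L }
    offs <- cumsum(c(0, widths))[seq_len(n_seg)]
    exon_idx <- seq(1L, n_seg, by = 2L)
    ex_list[[i]] <- data.frame(gene_id = gene_id[i],
                               start = starts[i] + offs[exon_idx],
                               end = starts[i] + offs[exon_idx] + widths[exon_idx])
    exonic_length[i] <- sum(widths[exon_idx])
  }
  exons <- do.call(rbind, ex_list)
  genes <- data.frame(gene_id = gene_id, chrom = chrom,
                      start = starts, end = ends, strand = strand,
                      tss = ifelse(strand == "+", starts, ends),
                      exonic_length = exonic_length, biotype = biotype,
                      stringsAsFactors = FALSE)
  cl <- stats::setNames(genome_length, chrom)
  gene_annotation(genes, exons, cl)
}

#' Convert gene models to a GRanges
#' @param annotation A `gene_annotation`.
#' @return A `GRanges` of gene spans (1-based, as GRanges requires).
#' @export
genes_granges <- function(annotation) {
  g <- annotation$genes
  GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand, gene_id = g$gene_id)
}

#' Write a gene annotation as GTF
#' @param annotation A `gene_annotation`.
#' @param path Output file.
#' @export
write_gtf <- function(annotation, path) {
  g <- annotation$genes
  e <- annotation$exons
  gi <- match(e$gene_id, g$gene_id)
  feat <- data.frame(
    chrom = c(g$chrom, g$chrom[gi]),
    start = c(g$start, e$start),
    end = c(g$end, e$end),
    strand = c(g$strand, g$strand[gi]),
    type = c(rep("gene", nrow(g)), rep("exon", nrow(e))),
    gene_id = c(g$gene_id, e$gene_id),
    biotype = c(g$biotype, g$biotype[gi]))
  feat <- feat[order(feat$start, feat$gene_id, feat$type != "gene"), ]
  gr <- GenomicRanges::GRanges(
    seqnames = feat$chrom,
    ranges = IRanges::IRanges(start = feat$start + 1L, end = feat$end),
    strand = feat$strand,
    type = feat$type, gene_id = feat$gene_id,
    gene_biotype = feat$biotype, source = "pgex")
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a gene annotation from GTF
#'
#' Expects gene and exon features carrying `gene_id` attributes (as written by
#' [write_gtf()]); chromosome lengths are taken from `chrom_lengths` or, if
#' absent, from the right-most feature per chromosome.
#'
#' @param path GTF file.
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @return A `gene_annotation`.
#' @export
read_gtf <- function(path, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  gg <- df[df$type == "gene", ]
  ee <- df[df$type == "exon", ]
  ex_len <- tapply(ee$end - ee$start + 1L, ee$gene_id, sum)
  genes <- data.frame(
    gene_id = gg$gene_id, chrom = as.character(gg$seqnames),
    start = gg$start - 1L, end = gg$end,
    strand = as.character(gg$strand),
    tss = ifelse(gg$strand == "+", gg$start - 1L, gg$end),
    exonic_length = as.numeric(ex_len[gg$gene_id]),
    biotype = if ("gene_biotype" %in% names(gg)) gg$gene_biotype else "protein_coding",
    stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = ee$gene_id, start = ee$start - 1L, end = ee$end)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(genes$end, genes$chrom, max) * 1.0
    chrom_lengths <- chrom_lengths + 1e4
  }
  gene_annotation(genes, exons, chrom_lengths)
}
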