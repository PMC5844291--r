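## Codon bookkeeping shared by the simulator and the effect annotator.
## GENETIC_CODE is the standard nuclear code from Biostrings.
STOP_CODONS <- c("TAA", "TAG", "TGA")

codon_table <- function() Biostrings::GENETIC_CODE

#' Place simulated gene models on a toy genome
#'
#' Chooses non-overlapping intervals on the genome, assigns each a random
#' strand, and rewrites the interval content with a valid open reading frame
#' (ATG start, sense codons drawn uniformly, one terminal stop codon) so that
#' codon-level effect annotation of planted mutations is well defined.
#' Because the input genome is random, the ORFs must be written in rather
#' than found; the returned annotation therefore carries the patched genome
#' in `$genome`, which downstream steps must use as the reference.
#'
#' @param genome A `pool_genome` from [make_genome()].
#' @param n_genes Number of genes to place.
#' @param gene_length_range Two-element vector, min/max CDS length in bases
#'   (rounded up to a multiple of 3; includes start and stop codons).
#' @param seed Integer seed.
#' @param complex_map Optional data.frame with columns `gene_id`,
#'   `complex_id` mapping a subset of genes to named protein complexes.
#' @return A `pool_annotation` object with `$genes` (data.frame: gene_id,
#'   chrom, start, end, strand), `$complex_map`, and `$genome` (the genome
#'   with ORFs written in).
#' @examples
#' g <- make_genome(20000, seed = 1)
#' ann <- make_annotation(g, n_genes = 5, gene_length_range = c(300, 900), seed = 2)
#' head(ann$genes)
#' @export
make_annotation <- function(genome, n_genes, gene_length_range = c(300, 1500),
                            seed = 1L, complex_map = NULL) {
  stopifnot(inherits(genome, "pool_genome"), n_genes >= 1)
  lo <- gene_length_range[1]; hi <- gene_length_range[2]
  if (lo < 9) stop("genes need at least 3 codons")
  local_seed(seed, {
    lens <- sample(seq(lo, hi), n_genes, replace = TRUE)
    lens <- 3L * ceiling(lens / 3)
    chroms <- sample(names(genome$seqs), n_genes, replace = TRUE,
                     prob = genome$lengths / genome$total_length)
    placed <- data.frame(gene_id = sprintf("gene%02d", seq_len(n_genes)),
                         chrom = chroms, start = NA_integer_,
                         end = NA_integer_,
                         strand = sample(c("+", "-"), n_genes, replace = TRUE),
                         stringsAsFactors = FALSE)
    # rejection-sample non-overlapping starts, chromosome by chromosome
    for (chrom in unique(placed$chrom)) {
      idx <- which(placed$chrom == chrom)
      L <- genome$lengths[[chrom]]
      taken_s <- integer(0); taken_e <- integer(0)
      for (i in idx) {
        ok <- FALSE
        for (try in 1:2000) {
          s <- sample.int(L - lens[i] + 1L, 1L)
          e <- s + lens[i] - 1L
          if (!any(s <= taken_e & e >= taken_s)) { ok <- TRUE; break }
        }
        if (!ok) stop("cannot place ", n_genes,
                      " non-overlapping genes on this genome")
        placed$start[i] <- s; placed$end[i] <- e
        taken_s <- c(taken_s, s); taken_e <- c(taken_e, e)
      }
    }
    # write a clean ORF into each interval (sense codons only)
    sense <- setdiff(names(codon_table()), STOP_CODONS)
    seqs <- genome$seqs
    for (i in seq_len(n_genes)) {
      n_codon <- lens[i] / 3L
      orf <- paste0("ATG",
                    paste(sample(sense, n_codon - 2L, replace = TRUE),
                          collapse = ""),
                    sample(STOP_CODONS, 1L))
      if (placed$strand[i] == "-") orf <- revcomp(orf)
      s <- seqs[[placed$chrom[i]]]
      seqs[[placed$chrom[i]]] <-
        paste0(substring(s, 1, placed$start[i] - 1L), orf,
               substring(s, placed$end[i] + 1L, nchar(s)))
    }
    placed <- placed[order(placed$chrom, placed$start), , drop = FALSE]
    rownames(placed) <- NULL
    structure(list(genes = placed, complex_map = complex_map,
                   genome = new_pool_genome(seqs)),
              class = "pool_annotation")
  })
}

#' @exportS3Method base::print
print.pool_annotation <- function(x, ...) {
  cat("pool_annotation:", nrow(x$genes), "genes on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  if (!is.null(x$complex_map))
    cat("  complex map:", nrow(x$complex_map), "gene(s) in",
        length(unique(x$complex_map$complex_id)), "complex(es)\n")
  invisible(x)
}

## coding sequence of one gene on its coding strand
gene_cds <- function(annotation, gene_id) {
  g <- annotation$genes[annotation$genes$gene_id == gene_id, ]
  if (nrow(g) != 1) stop("unknown gene: ", gene_id)
  s <- substring(annotation$genome$seqs[[g$chrom]], g$start, g$end)
  if (g$strand == "-") s <- revcomp(s)
  s
}

#' Write / read gene models as GFF3
#'
#' Uses [rtracklayer::export()] / [rtracklayer::import()]; intervals are
#' 1-based inclusive, one `CDS` feature per gene, phase 0.
#'
#' @param annotation A `pool_annotation` (or its `$genes` data.frame).
#' @param path GFF3 file path.
#' @return `read_gff3` returns the `genes` data.frame.
#' @export
write_gff3 <- function(annotation, path) {
  genes <- if (inherits(annotation, "pool_annotation")) annotation$genes
           else annotation
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end),
                               strand = genes$strand)
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$phase <- 0L
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "CDS"]
  data.frame(gene_id = S4Vectors::mcols(gr)$ID,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Read / write a gene-to-complex map
#'
#' Plain two-column TSV (`gene_id`, `complex_id`); the map may cover only a
#' subset of genes.
#'
#' @param path TSV path.
#' @param complex_map data.frame with columns `gene_id`, `complex_id`.
#' @export
read_complex_map <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' @rdname read_complex_map
#' @export
write_complex_map <- function(complex_map, path) {
  utils::write.table(complex_map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
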