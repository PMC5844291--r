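#' Simulate a toy reference genome
#'
#' Draws i.i.d. bases with a target GC content to stand in for a small haploid
#' yeast genome. Base identity is independent across sites, so the sequence is
#' almost surely repeat-free at k-mer scale, which is what the built-in
#' seed-and-extend aligner assumes.
#'
#' @param length Total genome length in bases. Either a single value (one
#'   chromosome, named `chrI`) or a named vector of per-chromosome lengths.
#'   Each chromosome must be at least 1000 bp so that gene models fit.
#' @param gc_fraction Target GC content in `[0, 1]`. Defaults to 0.36, the
#'   approximate GC content of the fission yeast genome.
#' @param seed Integer seed; the same seed reproduces the same genome.
#' @return A `pool_genome` object: a named character vector of upper-case
#'   A/C/G/T sequences with class attributes, plus `total_length`.
#' @examples
#' g <- make_genome(5000, gc_fraction = 0.36, seed = 1)
#' g
#' @export
make_genome <- function(length, gc_fraction = 0.36, seed = 1L) {
  if (is.null(names(length))) {
    if (base::length(length) == 1L) {
      names(length) <- "chrI"
    } else {
      names(length) <- paste0("chr", utils::as.roman(seq_along(length)))
    }
  }
  length <- vapply(length, as.numeric, 0)
  if (any(length < 1000))
    stop("each chromosome must be >= 1000 bp (too small to host genes)")
  if (anyDuplicated(names(length)))
    stop("chromosome names must be unique")
  if (gc_fraction < 0 || gc_fraction > 1)
    stop("gc_fraction must lie in [0, 1]")
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seqs <- local_seed(seed, {
    vapply(length, function(L) {
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
    }, character(1))
  })
  new_pool_genome(seqs)
}

new_pool_genome <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  structure(list(seqs = seqs,
                 lengths = vapply(seqs, nchar, 0L),
                 total_length = sum(vapply(seqs, nchar, 0L))),
            class = "pool_genome")
}

#' @exportS3Method base::print
print.pool_genome <- function(x, ...) {
  cat("pool_genome:", length(x$seqs), "chromosome(s),",
      format(x$total_length, big.mark = ","), "bp total\n")
  for (nm in names(x$seqs)) {
    s <- x$seqs[[nm]]
    gc <- sum(charToRaw(s) %in% charToRaw("GC")) / nchar(s)
    cat(sprintf("  %s  %s bp  GC %.3f\n", nm,
                format(nchar(s), big.mark = ","), gc))
  }
  invisible(x)
}

#' Write / read a reference genome as FASTA
#'
#' Thin wrappers over [Biostrings::writeXStringSet()] and
#' [Biostrings::readDNAStringSet()].
#'
#' @param genome A `pool_genome`.
#' @param path Output FASTA path.
#' @return `write_fasta` returns `path` invisibly; `read_fasta` returns a
#'   `pool_genome`.
#' @export
write_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "pool_genome"))
  dna <- Biostrings::DNAStringSet(genome$seqs)
  Biostrings::writeXStringSet(dna, filepath = path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(dna)
  names(seqs) <- sub("\\s.*$", "", names(dna))
  new_pool_genome(seqs)
}

## reverse complement for plain character vectors (delegates to Biostrings)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## fetch the reference base(s) at 1-based positions of one chromosome
ref_base <- function(genome, chrom, pos) {
  s <- genome$seqs[[chrom]]
  if (is.null(s)) stop("unknown chromosome: ", chrom)
  substring(s, pos, pos)
}

## apply a set of substitutions (data.frame chrom,pos,alt) to a genome;
## insertions (ref == "") splice `alt` in after `pos` and are applied last,
## right-to-left, so substitution coordinates stay valid.
apply_mutations <- function(genome, mut) {
  seqs <- genome$seqs
  if (nrow(mut) == 0) return(new_pool_genome(seqs))
  is_ins <- mut$ref == ""
  sub <- mut[!is_ins, , drop = FALSE]
  for (chrom in unique(sub$chrom)) {
    m <- sub[sub$chrom == chrom, , drop = FALSE]
    s <- seqs[[chrom]]
    cur <- substring(s, m$pos, m$pos)
    if (any(cur != m$ref))
      stop("ref base mismatch at ", chrom, ":", m$pos[cur != m$ref][1])
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch[m$pos] <- m$alt
    seqs[[chrom]] <- paste(ch, collapse = "")
  }
  ins <- mut[is_ins, , drop = FALSE]
  if (nrow(ins) > 0) {
    ins <- ins[order(ins$chrom, -ins$pos), , drop = FALSE]
    for (i in seq_len(nrow(ins))) {
      s <- seqs[[ins$chrom[i]]]
      p <- ins$pos[i]
      seqs[[ins$chrom[i]]] <- paste0(substring(s, 1, p), ins$alt[i],
                                     substring(s, p + 1, nchar(s)))
    }
  }
  new_pool_genome(seqs)
}

## evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
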