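# Independent oracles and small constructors used across the suite.

# Exhaustive ungapped alignment: Hamming distance at every offset on both
# strands of a single-chromosome genome. Mirrors the aligner's contract
# (unique best placement within the mismatch budget; ties unmapped) without
# seeding, so it is an independent reference.
brute_force_map <- function(read, genome_str, max_mm) {
  rl <- nchar(read)
  L <- nchar(genome_str)
  gr <- charToRaw(genome_str)
  n_off <- L - rl + 1L
  scan <- function(s) {
    rr <- charToRaw(s)
    mm <- integer(n_off)
    for (j in seq_len(rl)) mm <- mm + (gr[j:(j + n_off - 1L)] != rr[j])
    mm
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  mm_f <- scan(read)
  mm_r <- scan(rc)
  best <- min(mm_f, mm_r)
  n_best <- sum(mm_f == best) + sum(mm_r == best)
  if (best > max_mm || n_best > 1)
    return(list(mapped = FALSE))
  if (best %in% mm_f)
    list(mapped = TRUE, pos = which(mm_f == best), strand = "+", mm = best)
  else
    list(mapped = TRUE, pos = which(mm_r == best), strand = "-", mm = best)
}

# Full-CDS translation oracle for effect annotation: translate the whole
# reference and mutated CDS with Biostrings and diff the proteins, instead
# of recomputing the single affected codon.
translation_oracle <- function(cds, cds_pos, alt_cds_base, p0 = NULL) {
  mut <- cds
  substring(mut, cds_pos, cds_pos) <- alt_cds_base
  tr <- function(s) strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(s), if.fuzzy.codon = "X",
    no.init.codon = TRUE)), "")[[1]]
  if (is.null(p0)) p0 <- tr(cds)
  p1 <- tr(mut)
  d <- which(p0 != p1)
  if (length(d) == 0) return("silent")
  i <- d[1]
  if (p1[i] == "*") paste0(p0[i], i, "Stop")
  else if (p0[i] == "*") paste0("Stop", i, p1[i])
  else paste0(p0[i], i, p1[i])
}

# Construct a pool_pileup directly from a reference string and a count
# matrix (sites x A,C,G,T), bypassing alignment.
make_pileup <- function(ref_str, counts, chrom = "chrI") {
  L <- nchar(ref_str)
  stopifnot(nrow(counts) == L)
  colnames(counts) <- c("A", "C", "G", "T")
  lens <- stats::setNames(L, chrom)
  structure(list(chrom_names = chrom, lengths = lens,
                 offsets = stats::setNames(0, chrom), counts = counts,
                 ref = charToRaw(ref_str)),
            class = "pool_pileup")
}

# A pileup drawn from the caller's null: every site is reference except
# for uniform sequencing error at rate e, pooled depth ~ Poisson(lambda).
simulate_null_pileup <- function(G, lambda, e) {
  ref <- paste(sample(c("A", "C", "G", "T"), G, replace = TRUE),
               collapse = "")
  depth <- stats::rpois(G, lambda)
  alt <- matrix(stats::rbinom(3L * G, rep(depth, 3), e / 3), nrow = G)
  counts <- matrix(0L, G, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  ref_idx <- match(strsplit(ref, "")[[1]], c("A", "C", "G", "T"))
  alt_slots <- t(vapply(ref_idx, function(r) setdiff(1:4, r), integer(3)))
  for (j in 1:3) counts[cbind(seq_len(G), alt_slots[, j])] <- alt[, j]
  counts[cbind(seq_len(G), ref_idx)] <- pmax(depth - rowSums(alt), 0L)
  make_pileup(ref, counts)
}

# Build an annotation object around a hand-written ORF so tests can place
# known codons at known positions (e.g. GGC at codon 338).
manual_annotation <- function(orf, strand = "+", flank = 500, seed = 99) {
  stopifnot(nchar(orf) %% 3 == 0)
  g <- make_genome(2 * flank + nchar(orf), seed = seed)
  s <- g$seqs[[1]]
  insert <- if (strand == "-")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(orf)))
  else orf
  start <- flank + 1L
  end <- flank + nchar(orf)
  s <- paste0(substring(s, 1, flank), insert,
              substring(s, end + 1L, nchar(s)))
  genome <- structure(list(seqs = stats::setNames(s, "chrI"),
                           lengths = stats::setNames(nchar(s), "chrI"),
                           total_length = nchar(s)),
                      class = "pool_genome")
  structure(list(genes = data.frame(gene_id = "geneA", chrom = "chrI",
                                    start = start, end = end,
                                    strand = strand,
                                    stringsAsFactors = FALSE),
                 complex_map = NULL, genome = genome),
            class = "pool_annotation")
}

# An ORF of n_codons sense codons with specific codons planted at given
# 1-based codon indices.
orf_with_codons <- function(n_codons, planted = list(), seed = 7) {
  sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  withr_seed <- function(expr) { set.seed(seed); expr }
  codons <- withr_seed(sample(setdiff(sense, "ATG"), n_codons,
                              replace = TRUE))
  codons[1] <- "ATG"
  codons[n_codons] <- "TAA"
  for (i in names(planted)) codons[as.integer(i)] <- planted[[i]]
  paste(codons, collapse = "")
}

# Minimal classified-variant row for recurrence-filter fixtures.
cls_row <- function(mixture, gene, effect, chrom = "chrI", pos = 1,
                    ref = "A", alt = "T", af = 0.1) {
  data.frame(mixture_id = mixture, chrom = chrom, pos = pos, ref = ref,
             alt = alt, af = af, category = "suppressor_candidate",
             gene_id = gene, effect = effect, stringsAsFactors = FALSE)
}
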