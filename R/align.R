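#' Build an exact k-mer index of a reference genome
#'
#' Indexes every forward-strand k-mer position (k-mers never span
#' chromosome boundaries). Reverse-strand placements are handled at query
#' time by also seeding the reverse complement of the read.
#'
#' @param genome A `pool_genome`.
#' @param k Seed length, 11-31 (default 15).
#' @return A `kmer_index` used by [map_reads()].
#' @export
build_index <- function(genome, k = 15L) {
  stopifnot(inherits(genome, "pool_genome"))
  k <- as.integer(k)
  if (k < 11 || k > 31) stop("k must lie in [11, 31]")
  lens <- genome$lengths
  offsets <- c(0, cumsum(as.numeric(lens)))[seq_along(lens)]
  names(offsets) <- names(lens)
  kmers <- character(0); gpos <- numeric(0)
  for (i in seq_along(genome$seqs)) {
    s <- genome$seqs[[i]]
    L <- lens[[i]]
    if (L < k) next
    st <- seq_len(L - k + 1L)
    kmers <- c(kmers, substring(s, st, st + k - 1L))
    gpos <- c(gpos, offsets[[i]] + st)
  }
  uk <- unique(kmers)
  m <- match(kmers, uk)
  o <- order(m)
  cnt <- tabulate(m, nbins = length(uk))
  ends <- cumsum(cnt)
  structure(list(k = k, uk = uk, pos_sorted = gpos[o],
                 start = ends - cnt + 1L, count = cnt,
                 offsets = offsets, lengths = lens,
                 chrom_names = names(lens),
                 genome_raw = charToRaw(paste(genome$seqs, collapse = "")),
                 total_length = genome$total_length),
            class = "kmer_index")
}

#' @exportS3Method base::print
print.kmer_index <- function(x, ...) {
  cat("kmer_index: k =", x$k, ",", length(x$uk), "distinct k-mers over",
      format(x$total_length, big.mark = ","), "bp\n")
  invisible(x)
}

## exact positions (global coords) of one k-mer; empty if absent
lookup_kmer <- function(index, kmer) {
  qi <- match(kmer, index$uk)
  if (is.na(qi)) return(numeric(0))
  index$pos_sorted[index$start[qi] + seq_len(index$count[qi]) - 1L]
}

## global coordinate -> (chrom, local pos)
global_to_local <- function(index, g) {
  ci <- findInterval(g, c(index$offsets, index$total_length + 1),
                     rightmost.closed = FALSE)
  list(chrom = index$chrom_names[ci], pos = as.integer(g - index$offsets[ci]))
}

#' Map reads with non-overlapping k-mer seeding and ungapped extension
#'
#' For each read (and its reverse complement), every non-overlapping k-mer
#' seed is looked up in the index; each hit implies a candidate ungapped
#' placement, which is scored by Hamming distance over the full read.
#' The unique best placement is kept; ties, or a best distance above
#' `max_mismatch_fraction * length`, leave the read unmapped so that repeats
#' cannot fabricate allele counts.
#'
#' @param reads Character vector of equal-length reads (A/C/G/T).
#' @param index A [build_index()] result.
#' @param max_mismatch_fraction Maximum tolerated mismatch fraction
#'   (default 0.1).
#' @param read_ids Optional read names (default `read1`, `read2`, ...).
#' @return A `pool_alignments` data.frame with one row per read:
#'   `read_id`, `chrom`, `pos` (1-based leftmost), `strand`, `seq` (oriented
#'   to the reference), `mismatches`, `mapped`. Unmapped reads carry NA
#'   coordinates.
#' @export
map_reads <- function(reads, index, max_mismatch_fraction = 0.1,
                      read_ids = NULL) {
  stopifnot(inherits(index, "kmer_index"))
  n <- length(reads)
  if (n == 0) return(empty_alignments())
  rl <- unique(nchar(reads))
  if (length(rl) != 1) stop("map_reads expects equal-length reads")
  if (rl < index$k) stop("reads must be at least k bases long")
  if (is.null(read_ids)) read_ids <- paste0("read", seq_len(n))
  k <- index$k
  max_mm <- floor(max_mismatch_fraction * rl)
  rc <- revcomp(reads)
  seed_at <- unique(c(seq(1L, rl - k + 1L, by = k), rl - k + 1L))

  gather <- function(strs) {
    out_r <- list(); out_g <- list()
    for (o in seed_at) {
      sd <- substring(strs, o, o + k - 1L)
      qi <- match(sd, index$uk)
      nz <- which(!is.na(qi))
      if (length(nz) == 0) next
      cnt <- index$count[qi[nz]]
      ridx <- rep(nz, cnt)
      gst <- index$pos_sorted[rep(index$start[qi[nz]], cnt) +
                                sequence(cnt) - 1L] - (o - 1L)
      out_r[[length(out_r) + 1L]] <- ridx
      out_g[[length(out_g) + 1L]] <- gst
    }
    list(read = unlist(out_r), gstart = unlist(out_g))
  }

  score <- function(cand_read, cand_g, strs) {
    if (length(cand_read) == 0) return(integer(0))
    raw <- matrix(charToRaw(paste(strs, collapse = "")), nrow = rl)
    mm <- integer(length(cand_read))
    gr <- index$genome_raw
    for (j in seq_len(rl))
      mm <- mm + (gr[cand_g + j - 1] != raw[j, cand_read])
    mm
  }

  res <- list()
  for (strand in c("+", "-")) {
    strs <- if (strand == "+") reads else rc
    cand <- gather(strs)
    if (length(cand$read) == 0) next
    keep <- cand$gstart >= 1 & cand$gstart + rl - 1 <= index$total_length
    # placement must stay on one chromosome
    loc_s <- findInterval(cand$gstart, c(index$offsets,
                                         index$total_length + 1))
    loc_e <- findInterval(cand$gstart + rl - 1, c(index$offsets,
                                                  index$total_length + 1))
    keep <- keep & loc_s == loc_e
    cr <- cand$read[keep]; cg <- cand$gstart[keep]
    dk <- !duplicated(cg * n + (cr - 1))
    cr <- cr[dk]; cg <- cg[dk]
    mm <- score(cr, cg, strs)
    res[[strand]] <- data.frame(read = cr, gstart = cg, mm = mm,
                                strand = strand, stringsAsFactors = FALSE)
  }
  cand <- do.call(rbind, res)

  out <- data.frame(read_id = read_ids, chrom = NA_character_,
                    pos = NA_integer_, strand = NA_character_,
                    seq = NA_character_, mismatches = NA_integer_,
                    mapped = FALSE, stringsAsFactors = FALSE)
  if (!is.null(cand) && nrow(cand) > 0) {
    cand <- cand[cand$mm <= max_mm, , drop = FALSE]
    if (nrow(cand) > 0) {
      o <- order(cand$read, cand$mm)
      cand <- cand[o, , drop = FALSE]
      first <- !duplicated(cand$read)
      best <- cand[first, , drop = FALSE]
      # tie: the candidate right after the best, same read, same distance
      nxt <- which(first) + 1L
      tied <- nxt <= nrow(cand) &
        cand$read[pmin(nxt, nrow(cand))] == best$read &
        cand$mm[pmin(nxt, nrow(cand))] == best$mm
      best <- best[!tied, , drop = FALSE]
      if (nrow(best) > 0) {
        loc <- global_to_local(index, best$gstart)
        i <- best$read
        out$chrom[i] <- loc$chrom
        out$pos[i] <- loc$pos
        out$strand[i] <- best$strand
        out$mismatches[i] <- best$mm
        out$mapped[i] <- TRUE
        out$seq[i] <- ifelse(best$strand == "+", reads[i], rc[i])
      }
    }
  }
  class(out) <- c("pool_alignments", "data.frame")
  out
}

#' @rdname map_reads
#' @param read A single read (character scalar).
#' @export
map_read <- function(read, index, max_mismatch_fraction = 0.1) {
  map_reads(read, index, max_mismatch_fraction)
}

empty_alignments <- function() {
  structure(data.frame(read_id = character(0), chrom = character(0),
                       pos = integer(0), strand = character(0),
                       seq = character(0), mismatches = integer(0),
                       mapped = logical(0), stringsAsFactors = FALSE),
            class = c("pool_alignments", "data.frame"))
}

#' Map both mates of a simulated pool
#'
#' Convenience wrapper: maps R1 and R2 of a [simulate_pool_reads()] result
#' as independent single-end reads.
#'
#' @param reads A `pool_reads` object.
#' @param index A [build_index()] result.
#' @param max_mismatch_fraction Passed to [map_reads()].
#' @return A `pool_alignments` data.frame.
#' @export
align_pool <- function(reads, index, max_mismatch_fraction = 0.1) {
  stopifnot(inherits(reads, "pool_reads"))
  map_reads(c(reads$r1, reads$r2), index, max_mismatch_fraction,
            read_ids = c(paste0(reads$names, "/1"),
                         paste0(reads$names, "/2")))
}

#' Per-site base counts over a set of alignments
#'
#' Tallies every aligned base into the A/C/G/T count of its reference
#' coordinate. Alignments are taken as already oriented to the reference
#' (reverse-strand reads were complemented at mapping/ingestion time).
#' There is no base- or mapping-quality weighting: the simulator emits
#' constant qualities.
#'
#' @param alignments A `pool_alignments` data.frame (only `mapped` rows are
#'   used; rows out of chromosome bounds are dropped with a warning).
#' @param genome The reference `pool_genome`.
#' @return A `pool_pileup`: per-site counts of A, C, G and T plus the
#'   reference base, stored per chromosome.
#' @export
pileup <- function(alignments, genome) {
  stopifnot(inherits(genome, "pool_genome"))
  lens <- genome$lengths
  offsets <- c(0, cumsum(as.numeric(lens)))[seq_along(lens)]
  names(offsets) <- names(lens)
  G <- genome$total_length
  al <- alignments[alignments$mapped, , drop = FALSE]
  if (nrow(al) > 0) {
    wlen <- nchar(al$seq)
    bad <- !(al$chrom %in% names(lens)) |
      al$pos < 1 | al$pos + wlen - 1 > lens[al$chrom]
    if (any(bad)) {
      warning(sum(bad), " alignment(s) out of chromosome bounds; dropped")
      al <- al[!bad, , drop = FALSE]
      wlen <- wlen[!bad]
    }
  }
  counts <- matrix(0L, nrow = G, ncol = 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  if (nrow(al) > 0) {
    gstart <- offsets[al$chrom] + al$pos
    chunk <- 50000L
    bases <- charToRaw("ACGT")
    for (lo in seq(1L, nrow(al), by = chunk)) {
      hi <- min(lo + chunk - 1L, nrow(al))
      len <- nchar(al$seq[lo:hi])
      gpos <- rep(gstart[lo:hi], len) + sequence(len) - 1
      braw <- charToRaw(paste(al$seq[lo:hi], collapse = ""))
      for (b in 1:4) {
        sel <- braw == bases[b]
        if (any(sel))
          counts[, b] <- counts[, b] + tabulate(gpos[sel], nbins = G)
      }
    }
  }
  structure(list(chrom_names = names(lens), lengths = lens,
                 offsets = offsets, counts = counts,
                 ref = charToRaw(paste(genome$seqs, collapse = ""))),
            class = "pool_pileup")
}

#' @exportS3Method base::print
print.pool_pileup <- function(x, ...) {
  d <- rowSums(x$counts)
  cat("pool_pileup:", length(x$chrom_names), "chromosome(s),",
      format(length(d), big.mark = ","), "sites, mean depth",
      round(mean(d), 1), "x\n")
  invisible(x)
}

#' Write a pileup as TSV
#'
#' Columns: chrom, pos, ref, A, C, G, T, depth. Sites with zero depth are
#' included so row order is the genome coordinate.
#'
#' @param pile A `pool_pileup`.
#' @param path Output TSV path.
#' @export
write_pileup <- function(pile, path) {
  loc <- pileup_coords(pile)
  df <- data.frame(chrom = loc$chrom, pos = loc$pos,
                   ref = strsplit(rawToChar(pile$ref), "")[[1]],
                   pile$counts, depth = rowSums(pile$counts))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## (chrom, pos) for every global pileup row
pileup_coords <- function(pile) {
  list(chrom = rep(pile$chrom_names, pile$lengths),
       pos = unlist(lapply(pile$lengths, seq_len), use.names = FALSE))
}

#' Write alignments as SAM (plain text)
#'
#' Emits an `@HD`/`@SQ` header and one record per mapped block with flags
#' 0/16; unmapped reads are written with flag 4 and no coordinates. CIGAR is
#' fully `M` (the built-in aligner is ungapped); SEQ is reference-oriented,
#' as SAM requires.
#'
#' @param alignments A `pool_alignments` data.frame.
#' @param genome The reference `pool_genome` (for `@SQ` lines).
#' @param path Output SAM path.
#' @export
write_sam <- function(alignments, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome$seqs),
                   genome$lengths))
  a <- alignments
  flag <- ifelse(!a$mapped, 4L, ifelse(a$strand == "-", 16L, 0L))
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                 a$read_id, flag,
                 ifelse(a$mapped, a$chrom, "*"),
                 ifelse(a$mapped, a$pos, 0L),
                 ifelse(a$mapped, 60L, 0L),
                 ifelse(a$mapped, paste0(nchar(a$seq), "M"), "*"),
                 ifelse(a$mapped, a$seq, "N"))
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a plain-text SAM file into alignment records
#'
#' Consumes primary mapped records only (flags 4, 256 and 2048 are
#' skipped). CIGAR `M`/`X`/`=` runs are walked per operation: each run
#' becomes one contiguous alignment block; `I` and `S` consume query only,
#' `D`/`N` reference only, `H`/`P` nothing, so gapped external alignments
#' contribute the correct bases at the correct reference coordinates.
#'
#' @param path SAM path.
#' @param genome Reference `pool_genome`; `@SQ` names and lengths must
#'   match, otherwise an error names the offending sequence.
#' @return A `pool_alignments` data.frame (possibly several block rows per
#'   read).
#' @export
read_sam <- function(path, genome) {
  ln <- readLines(path)
  hdr <- ln[startsWith(ln, "@")]
  body <- ln[!startsWith(ln, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  for (s in sq) {
    f <- strsplit(s, "\t", fixed = TRUE)[[1]]
    sn <- sub("^SN:", "", f[startsWith(f, "SN:")][1])
    lnth <- as.integer(sub("^LN:", "", f[startsWith(f, "LN:")][1]))
    if (!sn %in% names(genome$seqs))
      stop("SAM header sequence not in reference: ", sn)
    if (lnth != genome$lengths[[sn]])
      stop("SAM header length mismatch for sequence: ", sn)
  }
  out <- list()
  for (line in body) {
    if (!nzchar(line)) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0 || bitwAnd(flag, 256L) > 0 ||
        bitwAnd(flag, 2048L) > 0) next
    chrom <- f[3]; pos <- as.integer(f[4]); cigar <- f[6]; seq <- f[10]
    if (!chrom %in% names(genome$seqs))
      stop("SAM record references unknown sequence: ", chrom)
    ops <- cigar_ops(cigar)
    qpos <- 1L; rpos <- pos
    strand <- if (bitwAnd(flag, 16L) > 0) "-" else "+"
    for (i in seq_len(nrow(ops))) {
      n <- ops$len[i]
      op <- ops$op[i]
      if (op %in% c("M", "=", "X")) {
        block <- substring(seq, qpos, qpos + n - 1L)
        refs <- substring(genome$seqs[[chrom]], rpos, rpos + n - 1L)
        mm <- sum(charToRaw(block) != charToRaw(refs))
        out[[length(out) + 1L]] <-
          data.frame(read_id = f[1], chrom = chrom, pos = rpos,
                     strand = strand, seq = block, mismatches = mm,
                     mapped = TRUE, stringsAsFactors = FALSE)
        qpos <- qpos + n; rpos <- rpos + n
      } else if (op %in% c("I", "S")) {
        qpos <- qpos + n
      } else if (op %in% c("D", "N")) {
        rpos <- rpos + n
      } # H, P: no-op
    }
  }
  if (length(out) == 0) return(empty_alignments())
  res <- do.call(rbind, out)
  class(res) <- c("pool_alignments", "data.frame")
  res
}

cigar_ops <- function(cigar) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  if (m[1] == -1) stop("unparseable CIGAR: ", cigar)
  tok <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  data.frame(len = as.integer(sub("[MIDNSHP=X]$", "", tok)),
             op = sub("^[0-9]+", "", tok), stringsAsFactors = FALSE)
}
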