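#' Pool composition of a DNA mixture
#'
#' Equal amounts of genomic DNA from `N` revertants is the screening
#' protocol; unequal `proportions` model pipetting error.
#'
#' @param N Number of revertants pooled.
#' @param proportions Per-revertant mass fractions, summing to 1. Default
#'   equal.
#' @return A `pool_spec` list.
#' @export
pool_spec <- function(N = 10L, proportions = NULL) {
  N <- as.integer(N)
  stopifnot(N >= 1)
  if (is.null(proportions)) proportions <- rep(1 / N, N)
  if (length(proportions) != N) stop("need one proportion per revertant")
  if (any(proportions <= 0)) stop("proportions must be positive")
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  structure(list(N = N, proportions = proportions), class = "pool_spec")
}

#' Read simulation parameters
#'
#' Defaults mirror the sequencing protocol: paired-end 2x150 bp, ~30-fold
#' coverage per genome in the pool, and a uniform per-base substitution
#' error rate. Base qualities are written as a constant Q37.
#'
#' @param read_length Read length in bases (>= 20).
#' @param insert_mean,insert_sd Fragment (insert) size distribution in
#'   bases; `insert_mean` must be at least `read_length`.
#' @param coverage_per_genome Fold coverage contributed per pooled genome;
#'   pooled depth is ~`N * coverage_per_genome`.
#' @param error_rate Per-base substitution probability in `[0, 0.25)`.
#' @param seed Integer seed; same seed gives byte-identical FASTQ.
#' @return A `read_sim_params` list.
#' @export
read_sim_params <- function(read_length = 150L, insert_mean = 400,
                            insert_sd = 40, coverage_per_genome = 30,
                            error_rate = 0.002, seed = 1L) {
  read_length <- as.integer(read_length)
  if (read_length < 20) stop("read_length must be >= 20")
  if (insert_mean < read_length) stop("insert_mean must be >= read_length")
  if (coverage_per_genome <= 0) stop("coverage_per_genome must be > 0")
  if (error_rate < 0 || error_rate >= 0.25)
    stop("error_rate must lie in [0, 0.25)")
  structure(list(read_length = read_length, paired = TRUE,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 coverage_per_genome = coverage_per_genome,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "read_sim_params")
}

#' Simulate paired-end reads from a pooled DNA mixture
#'
#' Draws fragments from the `N` revertant genomes with probability equal to
#' their pool proportions, emits both mates (R2 is the reverse complement of
#' the fragment end) and injects uniform substitution errors. Read names
#' encode the true origin (`rev<r>:<chrom>:<fragment start>:<pair>`); this
#' is test metadata only and nothing downstream may read it.
#'
#' @param revertants List of `pool_genome` revertant genomes (one mixture),
#'   e.g. `screen$mixtures[[1]]$revertants`.
#' @param pool A [pool_spec()]; its `N` must match `length(revertants)`.
#' @param params A [read_sim_params()].
#' @return A `pool_reads` object: `$r1`, `$r2` (character vectors), `$names`
#'   (shared mate names), `$qual` (constant quality string) and
#'   `$expected_pool_depth`.
#' @export
simulate_pool_reads <- function(revertants, pool = pool_spec(length(revertants)),
                                params = read_sim_params()) {
  stopifnot(inherits(pool, "pool_spec"), inherits(params, "read_sim_params"))
  if (length(revertants) != pool$N)
    stop("pool$N must match the number of revertant genomes")
  rl <- params$read_length
  glen <- revertants[[1]]$total_length
  n_pairs <- round(pool$N * params$coverage_per_genome * glen / (2 * rl))
  local_seed(params$seed, {
    origin <- sample.int(pool$N, n_pairs, replace = TRUE,
                         prob = pool$proportions)
    r1 <- character(n_pairs); r2 <- character(n_pairs)
    nm <- character(n_pairs)
    for (r in seq_len(pool$N)) {
      idx <- which(origin == r)
      if (length(idx) == 0) next
      gen <- revertants[[r]]
      chroms <- names(gen$seqs)
      ch <- if (length(chroms) == 1) rep.int(1L, length(idx))
            else sample.int(length(chroms), length(idx), replace = TRUE,
                            prob = gen$lengths / gen$total_length)
      ins <- round(stats::rnorm(length(idx), params$insert_mean,
                                params$insert_sd))
      for (ci in unique(ch)) {
        sel <- which(ch == ci)
        L <- gen$lengths[[ci]]
        insi <- pmin(pmax(ins[sel], rl), L)
        start <- 1L + floor(stats::runif(length(sel)) * (L - insi + 1))
        s <- gen$seqs[[ci]]
        fwd <- substring(s, start, start + rl - 1L)
        rev <- revcomp(substring(s, start + insi - rl, start + insi - 1L))
        r1[idx[sel]] <- fwd
        r2[idx[sel]] <- rev
        nm[idx[sel]] <- sprintf("rev%d:%s:%d:%d", r, chroms[ci], start,
                                idx[sel])
      }
    }
    if (params$error_rate > 0) {
      err <- inject_errors(c(r1, r2), params$error_rate)
      r1 <- err[seq_len(n_pairs)]
      r2 <- err[n_pairs + seq_len(n_pairs)]
    }
    structure(list(r1 = r1, r2 = r2, names = nm,
                   qual = strrep("F", rl),
                   expected_pool_depth = 2 * rl * n_pairs / glen),
              class = "pool_reads")
  })
}

#' @exportS3Method base::print
print.pool_reads <- function(x, ...) {
  cat("pool_reads:", length(x$r1), "read pairs,",
      nchar(x$r1[1]), "bp, expected pooled depth",
      round(x$expected_pool_depth, 1), "x\n")
  invisible(x)
}

## uniform substitution errors over a batch of equal-length reads, done on
## one raw vector so the per-read loop is avoided
inject_errors <- function(reads, error_rate) {
  rl <- nchar(reads[1])
  raw <- charToRaw(paste(reads, collapse = ""))
  n <- length(raw)
  n_err <- stats::rbinom(1L, n, error_rate)
  if (n_err > 0) {
    at <- sample.int(n, n_err)
    # substitute with one of the three other bases, uniformly
    bases <- charToRaw("ACGT")
    cur <- match(raw[at], bases)
    shift <- sample.int(3L, n_err, replace = TRUE)
    raw[at] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  }
  big <- rawToChar(raw)
  substring(big, seq(1L, n, by = rl), seq(rl, n, by = rl))
}

#' Write / read FASTQ (Phred+33, plain text)
#'
#' @param reads A `pool_reads` object.
#' @param r1_path,r2_path Output paths for the two mates.
#' @param path A FASTQ path to read.
#' @return `read_fastq` returns a list with `names`, `seqs`.
#' @export
write_fastq <- function(reads, r1_path, r2_path) {
  stopifnot(inherits(reads, "pool_reads"))
  for (mate in 1:2) {
    seqs <- if (mate == 1) reads$r1 else reads$r2
    path <- if (mate == 1) r1_path else r2_path
    rec <- rbind(paste0("@", reads$names, "/", mate), seqs, "+",
                 strrep(substr(reads$qual, 1, 1), nchar(seqs)))
    writeLines(as.vector(rec), path)
  }
  invisible(c(r1_path, r2_path))
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  ln <- readLines(path)
  if (length(ln) %% 4 != 0) stop("truncated FASTQ: ", path)
  i <- seq(1L, length(ln), by = 4L)
  list(names = sub("^@", "", ln[i]), seqs = ln[i + 1L])
}
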