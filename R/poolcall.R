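#' Parameters of the pooled binomial caller
#'
#' The caller tests each site's non-reference base counts against a
#' binomial sequencing-error null. `error_rate` is the aggregate per-base
#' substitution probability; the null probability of one *specific*
#' alternative base is `error_rate / 3` (uniform miscall spectrum, matching
#' the simulator's error model). Family-wise error is controlled by
#' Bonferroni over `3 * genome length` tests, after which the screen's
#' allele-frequency floor (`min_af`, 2% in the protocol) and a depth floor
#' are applied.
#'
#' @param error_rate Aggregate per-base error probability; must be below
#'   `min_af`.
#' @param alpha Family-wise significance level (default 0.05).
#' @param min_af Minimum allele frequency to report (default 0.02).
#' @param min_depth Minimum site depth to consider (default 10).
#' @return A `caller_params` list.
#' @export
caller_params <- function(error_rate = 0.002, alpha = 0.05, min_af = 0.02,
                          min_depth = 10L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (min_af < 0 || min_af >= 1) stop("min_af must lie in [0, 1)")
  if (error_rate < 0 || error_rate >= min_af)
    stop("error_rate must be non-negative and below min_af")
  structure(list(error_rate = error_rate, alpha = alpha, min_af = min_af,
                 min_depth = as.integer(min_depth)),
            class = "caller_params")
}

#' Exact binomial upper-tail site test
#'
#' `P(X >= alt_count)` for `X ~ Binomial(depth, e/3)`: the probability that
#' sequencing error alone produces at least the observed count of one
#' specific alternative base. Monotone decreasing in `alt_count` at fixed
#' depth. Vectorised over `depth`/`alt_count`.
#'
#' @param depth Site depth (> 0).
#' @param alt_count Observed count of the alternative base, `0..depth`.
#' @param e Aggregate per-base error rate in `(0, 1)`; the per-alt null
#'   probability is `e/3`.
#' @return Upper-tail p-value(s).
#' @examples
#' site_test(300, 0, 0.002)    # 1: an empty tail
#' site_test(10, 10, 0.3)      # (0.1)^10
#' @export
site_test <- function(depth, alt_count, e) {
  if (any(depth <= 0)) stop("depth must be positive")
  if (e <= 0 || e >= 1) stop("e must lie in (0, 1)")
  if (any(alt_count < 0 | alt_count > depth))
    stop("alt_count must lie in [0, depth]")
  stats::pbinom(alt_count - 1, depth, e / 3, lower.tail = FALSE)
}

#' Call non-reference alleles in a pooled pileup
#'
#' Applies [site_test()] to each of the three possible alternative bases at
#' every covered site, Bonferroni-corrects over `3 * genome length` tests,
#' and emits calls passing `q_value <= alpha`, `af >= min_af` and
#' `depth >= min_depth`, sorted by coordinate.
#'
#' @param pile A `pool_pileup`.
#' @param params A [caller_params()].
#' @param mixture_id Identifier copied into the calls (default `"mix01"`).
#' @return A `pool_calls` data.frame: `chrom`, `pos`, `ref`, `alt`,
#'   `depth`, `alt_count`, `af`, `p_value`, `q_value`, `mixture_id`.
#'   Zero rows is a valid result.
#' @export
call_mixture <- function(pile, params = caller_params(),
                         mixture_id = "mix01") {
  stopifnot(inherits(pile, "pool_pileup"), inherits(params, "caller_params"))
  counts <- pile$counts
  depth <- rowSums(counts)
  G <- nrow(counts)
  n_tests <- 3 * G
  bases <- c("A", "C", "G", "T")
  ref_idx <- match(rawToChar(pile$ref, multiple = TRUE), bases)
  loc <- pileup_coords(pile)
  out <- list()
  for (b in 1:4) {
    alt_count <- counts[, b]
    cand <- which(ref_idx != b & alt_count > 0 &
                    depth >= params$min_depth &
                    alt_count / depth >= params$min_af)
    if (length(cand) == 0) next
    p <- site_test(depth[cand], alt_count[cand], params$error_rate)
    q <- pmin(1, p * n_tests)
    keep <- q <= params$alpha
    if (!any(keep)) next
    cand <- cand[keep]
    out[[b]] <- data.frame(chrom = loc$chrom[cand], pos = loc$pos[cand],
                           ref = bases[ref_idx[cand]], alt = bases[b],
                           depth = depth[cand], alt_count = alt_count[cand],
                           af = alt_count[cand] / depth[cand],
                           p_value = p[keep], q_value = q[keep],
                           mixture_id = mixture_id,
                           stringsAsFactors = FALSE)
  }
  calls <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), depth = numeric(0),
               alt_count = numeric(0), af = numeric(0),
               p_value = numeric(0), q_value = numeric(0),
               mixture_id = character(0), stringsAsFactors = FALSE)
  calls <- calls[order(calls$chrom, calls$pos, calls$alt), , drop = FALSE]
  rownames(calls) <- NULL
  class(calls) <- c("pool_calls", "data.frame")
  calls
}

#' @exportS3Method base::print
print.pool_calls <- function(x, ...) {
  cat("pool_calls:", nrow(x), "call(s)\n")
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 20))
  invisible(x)
}

#' Estimate the sequencing error rate from a pileup
#'
#' Pools non-reference base fractions over unmasked sites:
#' `e_hat = (non-reference bases) / (total bases)`. The mask should exclude
#' called or planted variant sites so genuine alleles do not inflate the
#' estimate.
#'
#' @param pile A `pool_pileup`.
#' @param exclusion_mask Optional data.frame (`chrom`, `pos`) of sites to
#'   exclude.
#' @return `e_hat`, a scalar.
#' @export
estimate_error_rate <- function(pile, exclusion_mask = NULL) {
  counts <- pile$counts
  keep <- rep(TRUE, nrow(counts))
  if (!is.null(exclusion_mask) && nrow(exclusion_mask) > 0) {
    g <- pile$offsets[exclusion_mask$chrom] + exclusion_mask$pos
    keep[g] <- FALSE
  }
  keep <- keep & rowSums(counts) > 0
  if (sum(keep) < 1000)
    stop("need >= 1000 unmasked covered sites to estimate the error rate")
  bases <- c("A", "C", "G", "T")
  ref_idx <- match(rawToChar(pile$ref, multiple = TRUE), bases)
  total <- sum(counts[keep, ])
  ref_ct <- counts[cbind(which(keep), ref_idx[keep])]
  (total - sum(ref_ct)) / total
}

#' Write calls as VCF v4.2
#'
#' INFO fields: DP (depth), AC (alt count), AF (allele frequency), PV
#' (binomial p-value), QV (Bonferroni-adjusted), MIX (mixture id).
#'
#' @param calls A `pool_calls` (or compatible) data.frame; for plain variant
#'   tables (e.g. parental background) only `chrom`/`pos`/`ref`/`alt` are
#'   required.
#' @param genome Reference `pool_genome` for `##contig` lines.
#' @param path Output VCF path.
#' @export
write_vcf <- function(calls, genome, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(genome$seqs),
                   genome$lengths),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Pooled depth\">",
           "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alt base count\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
           "##INFO=<ID=PV,Number=1,Type=Float,Description=\"Binomial p-value\">",
           "##INFO=<ID=QV,Number=1,Type=Float,Description=\"Bonferroni-adjusted p-value\">",
           "##INFO=<ID=MIX,Number=1,Type=String,Description=\"Mixture id\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(calls) > 0) {
    info <- if (!is.null(calls$af))
      sprintf("DP=%d;AC=%d;AF=%.6g;PV=%.6g;QV=%.6g;MIX=%s",
              as.integer(calls$depth), as.integer(calls$alt_count),
              calls$af, calls$p_value, calls$q_value, calls$mixture_id)
    else "."
    ref <- ifelse(calls$ref == "", "N", calls$ref)  # insertion convention
    rec <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s", calls$chrom,
                   calls$pos, ref, calls$alt, info)
  } else rec <- character(0)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a VCF into a calls data.frame
#'
#' Uses [vcfR::read.vcfR()]; recovers the caller's INFO fields when present
#' so externally supplied calls can enter classification.
#'
#' @param path VCF path.
#' @return A data.frame with `chrom`, `pos`, `ref`, `alt` and, when
#'   available, `depth`, `alt_count`, `af`, `p_value`, `q_value`,
#'   `mixture_id`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE))
  out <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  grab <- function(key, info) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
    val <- rep(NA_character_, length(info))
    hit <- lengths(regmatches(info, gregexpr(paste0("(^|;)", key, "=[^;]+"),
                                             info))) > 0
    val[hit] <- sub(paste0("^;?", key, "="), "", m)
    val
  }
  info <- fix$INFO
  if (!is.null(info) && any(grepl("DP=", info, fixed = TRUE))) {
    out$depth <- as.numeric(grab("DP", info))
    out$alt_count <- as.numeric(grab("AC", info))
    out$af <- as.numeric(grab("AF", info))
    out$p_value <- as.numeric(grab("PV", info))
    out$q_value <- as.numeric(grab("QV", info))
    out$mixture_id <- grab("MIX", info)
  }
  out
}
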