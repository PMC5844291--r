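#' Classifier thresholds and the ts anchor locus
#'
#' A pooled mixture of N revertants of one ts mutant shows three
#' frequency strata: the shared ts mutation and parental background
#' variants near 100%, private suppressors near 1/N, and sequencing noise
#' below the reporting floor. The classifier assigns each call to exactly
#' one of `anchor_ts`, `background_common`, `suppressor_candidate`,
#' `subthreshold`.
#'
#' @param ts_locus List or one-row data.frame with `chrom`, `pos`, `alt`:
#'   the known ts mutation.
#' @param anchor_min_af Minimum allele frequency for the anchor call
#'   (default 0.9; below 1 to tolerate sampling noise and sequencing error
#'   at a fixed site).
#' @param background_min_af Allele frequency above which a non-anchor,
#'   non-parental call is treated as a fixed background variant
#'   (default 0.8).
#' @param min_af Reporting floor for suppressor candidates (default 0.02,
#'   the protocol's 2% cutoff).
#' @return A `classifier_params` list.
#' @export
classifier_params <- function(ts_locus, anchor_min_af = 0.9,
                              background_min_af = 0.8, min_af = 0.02) {
  stopifnot(!is.null(ts_locus$chrom), !is.null(ts_locus$pos),
            !is.null(ts_locus$alt))
  if (!(min_af < background_min_af && background_min_af <= anchor_min_af))
    stop("need min_af < background_min_af <= anchor_min_af")
  structure(list(ts_locus = ts_locus, anchor_min_af = anchor_min_af,
                 background_min_af = background_min_af, min_af = min_af),
            class = "classifier_params")
}

#' Classify pooled variant calls by allele frequency
#'
#' The call at the ts locus with `af >= anchor_min_af` becomes `anchor_ts`
#' (the mixture's internal control). Calls matching the parental variant
#' list, or at `af >= background_min_af` elsewhere, become
#' `background_common`. Remaining calls at `af >= min_af` are
#' `suppressor_candidate`; the rest are `subthreshold`. A missing or
#' low-frequency anchor raises a mixture-integrity warning. There is
#' deliberately no upper allele-frequency cap on candidates below
#' `background_min_af`: k revertants sharing one suppressor legitimately
#' give af ~ k/N.
#'
#' @param calls A `pool_calls` data.frame from one mixture.
#' @param params A [classifier_params()].
#' @param parental Optional data.frame of parental background variants
#'   (`chrom`, `pos`, `alt`), e.g. from [read_vcf()].
#' @param annotation Optional `pool_annotation`; when given, each call is
#'   annotated with its gene and protein-level effect.
#' @return The calls with `category`, and (if annotated) `gene_id` and
#'   `effect` columns; class `pool_classified`.
#' @export
classify_calls <- function(calls, params, parental = NULL,
                           annotation = NULL) {
  stopifnot(inherits(params, "classifier_params"))
  x <- as.data.frame(calls, stringsAsFactors = FALSE)
  key <- function(chrom, pos, alt) paste(chrom, pos, alt, sep = ":")
  ts <- params$ts_locus
  ts_key <- key(ts$chrom, ts$pos, ts$alt)
  k <- key(x$chrom, x$pos, x$alt)
  par_keys <- if (!is.null(parental) && nrow(parental) > 0)
    key(parental$chrom, parental$pos, parental$alt) else character(0)
  category <- rep("subthreshold", nrow(x))
  is_anchor <- k == ts_key & x$af >= params$anchor_min_af
  is_bg <- !is_anchor & (k %in% par_keys | x$af >= params$background_min_af)
  is_cand <- !is_anchor & !is_bg & x$af >= params$min_af
  category[is_cand] <- "suppressor_candidate"
  category[is_bg] <- "background_common"
  category[is_anchor] <- "anchor_ts"
  if (!any(is_anchor))
    warning("anchor absent: possible sample mix-up or revertant loss of ",
            "ts allele (no call at ", ts_key, " with af >= ",
            params$anchor_min_af, ")")
  x$category <- category
  if (!is.null(annotation)) {
    ann <- annotate_effects(x, annotation)
    x$gene_id <- ann$gene_id
    x$effect <- ann$effect
  }
  class(x) <- c("pool_classified", "data.frame")
  x
}

#' @exportS3Method base::print
print.pool_classified <- function(x, ...) {
  cat("pool_classified:", nrow(x), "call(s)\n")
  print(table(x$category))
  invisible(x)
}

#' Protein-level effect of a variant
#'
#' For a substitution inside an annotated CDS the affected codon is
#' recomputed on the coding strand and translated with the standard genetic
#' code: `XnY` for missense, `XnStop` for nonsense, `"silent"` for
#' synonymous changes. Insertions inside a CDS become `ins(frameshift)` or
#' `ins(in-frame)` by inserted length mod 3. Variants outside every gene
#' are `intergenic`.
#'
#' @param variant List or one-row data.frame with `chrom`, `pos`, `ref`
#'   (empty string for an insertion), `alt`.
#' @param annotation A `pool_annotation` (its `$genome` is the reference).
#' @return List with `gene_id` (NA if intergenic) and `effect`.
#' @examples
#' g <- make_genome(20000, seed = 1)
#' ann <- make_annotation(g, 4, c(300, 600), seed = 2)
#' m <- plant_coding(ann, "gene01", "missense")
#' annotate_effect(m, ann)
#' @export
annotate_effect <- function(variant, annotation) {
  stopifnot(inherits(annotation, "pool_annotation"))
  genome <- annotation$genome
  chrom <- variant$chrom; pos <- variant$pos
  is_ins <- !is.null(variant$ref) && variant$ref == ""
  if (!is_ins) {
    have <- ref_base(genome, chrom, pos)
    if (have != variant$ref)
      stop("ref base disagreement at ", chrom, ":", pos, " (reference has ",
           have, ", variant claims ", variant$ref, ")")
  }
  g <- annotation$genes
  hit <- which(g$chrom == chrom & g$start <= pos & g$end >= pos)
  if (length(hit) == 0)
    return(list(gene_id = NA_character_, effect = "intergenic"))
  g <- g[hit[1], ]
  if (is_ins) {
    eff <- if (nchar(variant$alt) %% 3 == 0) "ins(in-frame)"
           else "ins(frameshift)"
    return(list(gene_id = g$gene_id, effect = eff))
  }
  if (g$strand == "+") {
    cds_pos <- pos - g$start + 1L
    alt_cds <- variant$alt
  } else {
    cds_pos <- g$end - pos + 1L
    alt_cds <- chartr("ACGT", "TGCA", variant$alt)
  }
  cds <- gene_cds(annotation, g$gene_id)
  i <- (cds_pos - 1L) %/% 3L + 1L
  w <- (cds_pos - 1L) %% 3L + 1L
  old_codon <- substring(cds, 3L * i - 2L, 3L * i)
  new_codon <- old_codon
  substring(new_codon, w, w) <- alt_cds
  gc <- codon_table()
  old_aa <- gc[[old_codon]]; new_aa <- gc[[new_codon]]
  eff <- if (old_aa == new_aa) "silent"
         else if (new_aa == "*") paste0(old_aa, i, "Stop")
         else if (old_aa == "*") paste0("Stop", i, new_aa)
         else paste0(old_aa, i, new_aa)
  list(gene_id = g$gene_id, effect = eff)
}

## vectorised wrapper over annotate_effect
annotate_effects <- function(variants, annotation) {
  n <- nrow(variants)
  gene_id <- character(n); effect <- character(n)
  for (i in seq_len(n)) {
    a <- annotate_effect(variants[i, , drop = FALSE], annotation)
    gene_id[i] <- a$gene_id; effect[i] <- a$effect
  }
  list(gene_id = gene_id, effect = effect)
}

#' Gene- and complex-level recurrence filtering of suppressor candidates
#'
#' An independent event is one `suppressor_candidate` occurrence per
#' (mixture, variant); the same substitution seen in different mixtures
#' counts as separate events, because the revertants are independent
#' colonies. Genes with `n_events >= threshold` are reported as gene units.
#' Genes below the threshold that share a protein complex are aggregated:
#' a complex is reported when at least two distinct genes contribute and
#' their summed events reach the threshold. Units containing the ts gene
#' are flagged `intragenic`. Each event also carries the number of mixtures
#' in which its exact substitution recurs (`cross_mixture_n`), as an aid to
#' the manual-review step; recurrent mid-frequency variants are not
#' subtracted automatically since genuinely recurrent suppressors are
#' expected.
#'
#' @param classified A `pool_classified` data.frame (one or more mixtures
#'   row-bound together; must contain `mixture_id`, `category`, `gene_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `af`, `effect`).
#' @param threshold Minimum independent events per reported unit
#'   (default 2).
#' @param complex_map Optional data.frame (`gene_id`, `complex_id`).
#' @param ts_gene Optional ts gene id, used for the `intragenic` flag.
#' @return A `suppressor_report` data.frame: `unit` (gene/complex),
#'   `unit_id`, `n_events`, `n_distinct_variants`, `intragenic`,
#'   `members`, `events` (summary string); full event rows in
#'   `attr(, "events")`. Zero rows is a valid result.
#' @export
recurrence_filter <- function(classified, threshold = 2,
                              complex_map = NULL, ts_gene = NULL) {
  ev <- as.data.frame(classified, stringsAsFactors = FALSE)
  ev <- ev[ev$category == "suppressor_candidate", , drop = FALSE]
  if (is.null(ev$gene_id)) stop("classified calls must carry gene_id; ",
                                "classify with an annotation")
  vkey <- paste(ev$chrom, ev$pos, ev$ref, ev$alt, sep = ":")
  ekey <- paste(ev$mixture_id, vkey, sep = "|")
  dup <- duplicated(ekey)
  ev <- ev[!dup, , drop = FALSE]; vkey <- vkey[!dup]
  ev$variant <- vkey
  ev$cross_mixture_n <- as.integer(ave(ev$mixture_id, vkey,
                                       FUN = function(z) length(unique(z))))
  ingene <- !is.na(ev$gene_id)
  per_gene <- split(ev[ingene, , drop = FALSE], ev$gene_id[ingene])
  mk_report <- function(unit, unit_id, rows, members) {
    rows <- rows[order(rows$mixture_id, rows$variant), , drop = FALSE]
    data.frame(unit = unit, unit_id = unit_id, n_events = nrow(rows),
               n_distinct_variants = length(unique(rows$variant)),
               intragenic = !is.null(ts_gene) && ts_gene %in% members,
               members = paste(sort(unique(members)), collapse = ","),
               events = paste(sprintf("%s:%s:%s(af=%.2f)", rows$mixture_id,
                                      rows$gene_id, rows$effect, rows$af),
                              collapse = ";"),
               stringsAsFactors = FALSE)
  }
  reports <- list(); used_events <- list()
  sub_genes <- character(0)
  for (gid in names(per_gene)) {
    rows <- per_gene[[gid]]
    if (nrow(rows) >= threshold) {
      reports[[length(reports) + 1L]] <- mk_report("gene", gid, rows, gid)
      used_events[[length(used_events) + 1L]] <- rows
    } else sub_genes <- c(sub_genes, gid)
  }
  if (!is.null(complex_map) && length(sub_genes) > 0) {
    cm <- complex_map[complex_map$gene_id %in% sub_genes, , drop = FALSE]
    for (cid in unique(cm$complex_id)) {
      genes <- cm$gene_id[cm$complex_id == cid]
      rows <- do.call(rbind, per_gene[genes])
      if (is.null(rows)) next
      contributing <- unique(rows$gene_id)
      if (length(contributing) >= 2 && nrow(rows) >= threshold) {
        reports[[length(reports) + 1L]] <- mk_report("complex", cid, rows,
                                                     contributing)
        used_events[[length(used_events) + 1L]] <- rows
      }
    }
  }
  out <- if (length(reports)) do.call(rbind, reports) else
    data.frame(unit = character(0), unit_id = character(0),
               n_events = integer(0), n_distinct_variants = integer(0),
               intragenic = logical(0), members = character(0),
               events = character(0), stringsAsFactors = FALSE)
  out <- out[order(-out$n_events, out$unit_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "events") <- ev
  class(out) <- c("suppressor_report", "data.frame")
  out
}

#' @exportS3Method base::print
print.suppressor_report <- function(x, ...) {
  cat("suppressor_report:", nrow(x), "unit(s) passing recurrence filter\n")
  if (nrow(x) > 0)
    print.data.frame(as.data.frame(x)[, c("unit", "unit_id", "n_events",
                                          "n_distinct_variants",
                                          "intragenic", "members")])
  invisible(x)
}

#' Write classified variants / suppressor reports as TSV
#'
#' @param x A `pool_classified` or `suppressor_report` data.frame.
#' @param path Output TSV path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
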