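#' Default suppressor model
#'
#' Describes how private suppressor mutations are drawn for each revertant:
#' which genes can carry them (with sampling weights), the mix of effects,
#' and how many each revertant receives. Every revertant of the screen also
#' carries the shared ts anchor mutation and all parental background
#' variants.
#'
#' @param target_genes Character vector of gene ids eligible to receive
#'   suppressors; default (NULL) means every annotated gene except the ts
#'   gene (purely extragenic suppression).
#' @param weights Sampling weights over `target_genes` (recycled/normalised).
#' @param effect_bias Named probabilities over effect classes
#'   `missense`, `nonsense`, `insertion`. Insertions are planted in the
#'   revertant genome and truth table but the built-in aligner is ungapped,
#'   so insertion-bearing screens are meant for the external-SAM path.
#' @param per_revertant Number of private suppressors per revertant
#'   (0, 1 or 2; the screening protocol expects exactly 1).
#' @return A list with class `suppressor_model`.
#' @export
suppressor_model <- function(target_genes = NULL, weights = NULL,
                             effect_bias = c(missense = 0.7, nonsense = 0.3,
                                             insertion = 0),
                             per_revertant = 1L) {
  stopifnot(per_revertant %in% 0:2)
  eb <- c(missense = 0, nonsense = 0, insertion = 0)
  eb[names(effect_bias)] <- effect_bias
  if (sum(eb) <= 0) stop("effect_bias must have positive mass")
  structure(list(target_genes = target_genes, weights = weights,
                 effect_bias = eb / sum(eb),
                 per_revertant = as.integer(per_revertant)),
            class = "suppressor_model")
}

#' Simulate one suppressor screen: ts anchor, background, revertant pools
#'
#' Plants a missense ts mutation in `ts_gene` and `n_background` parental
#' strain variants shared by every revertant (both at pool allele frequency
#' 1), then builds `n_mixtures` independent pools of `N` revertant genomes,
#' each revertant carrying its own private suppressor mutation(s) drawn from
#' `model`. Suppressor positions are distinct within a mixture (each
#' revertant is an independent colony with its own hit); the same
#' substitution may recur across mixtures as independent events.
#'
#' @param annotation A `pool_annotation` from [make_annotation()]; its
#'   patched `$genome` is the reference all genomes derive from.
#' @param ts_gene Gene id carrying the temperature-sensitive mutation.
#' @param N Revertants pooled per mixture (default 10).
#' @param n_background Number of parental background variants.
#' @param model A [suppressor_model()].
#' @param seed Integer seed.
#' @param n_mixtures Number of independent pools sharing the ts mutant.
#' @return A `pool_screen` with `$ts` (anchor locus), `$parental`
#'   (background variants), `$mixtures` (per mixture: revertant genomes and
#'   suppressor table) and `$truth` (every planted mutation with role,
#'   owner, gene and protein effect).
#' @examples
#' g <- make_genome(20000, seed = 1)
#' ann <- make_annotation(g, 6, c(300, 900), seed = 2)
#' scr <- make_screen(ann, ts_gene = "gene01", N = 4, n_background = 5, seed = 3)
#' scr$truth
#' @export
make_screen <- function(annotation, ts_gene, N = 10L, n_background = 30L,
                        model = suppressor_model(), seed = 1L,
                        n_mixtures = 1L) {
  stopifnot(inherits(annotation, "pool_annotation"), N >= 1)
  genes <- annotation$genes
  if (!ts_gene %in% genes$gene_id) stop("ts_gene not in annotation: ", ts_gene)
  targets <- model$target_genes
  if (is.null(targets)) targets <- setdiff(genes$gene_id, ts_gene)
  if (!all(targets %in% genes$gene_id))
    stop("unknown suppressor target gene(s): ",
         paste(setdiff(targets, genes$gene_id), collapse = ", "))
  w <- model$weights
  if (is.null(w)) w <- rep(1, length(targets))
  w <- rep_len(w, length(targets)); w <- w / sum(w)
  genome <- annotation$genome

  local_seed(seed, {
    used <- character(0)   # "chrom:pos" occupancy across all planted variants
    key <- function(chrom, pos) paste0(chrom, ":", pos)

    ts <- plant_coding(annotation, ts_gene, "missense", used)
    used <- c(used, key(ts$chrom, ts$pos))

    parental <- plant_background(genome, n_background, used)
    used <- c(used, key(parental$chrom, parental$pos))
    if (nrow(parental) > 0) {
      pa <- annotate_effects(parental, annotation)
      parental$gene_id <- pa$gene_id
      parental$effect <- pa$effect
    }

    shared <- rbind(
      data.frame(chrom = ts$chrom, pos = ts$pos, ref = ts$ref, alt = ts$alt,
                 stringsAsFactors = FALSE),
      parental[, c("chrom", "pos", "ref", "alt")])

    mixtures <- vector("list", n_mixtures)
    truth <- list(
      data.frame(mixture = "all", chrom = ts$chrom, pos = ts$pos,
                 ref = ts$ref, alt = ts$alt, role = "ts", owner = "all",
                 gene_id = ts_gene, effect = ts$effect,
                 stringsAsFactors = FALSE),
      if (nrow(parental) > 0)
        data.frame(mixture = "all", chrom = parental$chrom,
                   pos = parental$pos, ref = parental$ref,
                   alt = parental$alt, role = "background", owner = "all",
                   gene_id = parental$gene_id, effect = parental$effect,
                   stringsAsFactors = FALSE))

    for (m in seq_len(n_mixtures)) {
      mix_id <- sprintf("mix%02d", m)
      mix_used <- used   # positions occupied within this mixture
      sups <- list()
      revertants <- vector("list", N)
      for (r in seq_len(N)) {
        muts <- shared
        for (j in seq_len(model$per_revertant)) {
          eff <- sample(names(model$effect_bias), 1L,
                        prob = model$effect_bias)
          gene <- sample(targets, 1L, prob = w)
          sp <- if (eff == "insertion")
            plant_insertion(annotation, gene, mix_used)
          else plant_coding(annotation, gene, eff, mix_used)
          mix_used <- c(mix_used, key(sp$chrom, sp$pos))
          sups[[length(sups) + 1L]] <-
            data.frame(mixture = mix_id, chrom = sp$chrom, pos = sp$pos,
                       ref = sp$ref, alt = sp$alt, role = "suppressor",
                       owner = as.character(r), gene_id = gene,
                       effect = sp$effect, stringsAsFactors = FALSE)
          muts <- rbind(muts, data.frame(chrom = sp$chrom, pos = sp$pos,
                                         ref = sp$ref, alt = sp$alt,
                                         stringsAsFactors = FALSE))
        }
        revertants[[r]] <- apply_mutations(genome, muts)
      }
      sup_df <- do.call(rbind, sups)
      truth[[length(truth) + 1L]] <- sup_df
      mixtures[[m]] <- list(mixture = mix_id, revertants = revertants,
                            suppressors = sup_df)
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    structure(list(ts = c(ts, gene_id = ts_gene), parental = parental,
                   mixtures = mixtures, truth = truth, N = as.integer(N),
                   annotation = annotation),
              class = "pool_screen")
  })
}

#' @exportS3Method base::print
print.pool_screen <- function(x, ...) {
  cat("pool_screen:", length(x$mixtures), "mixture(s) of", x$N,
      "revertants each\n")
  cat(sprintf("  ts anchor: %s %s:%d %s>%s (%s)\n", x$ts$gene_id, x$ts$chrom,
              x$ts$pos, x$ts$ref, x$ts$alt, x$ts$effect))
  cat("  background variants:", nrow(x$parental), "\n")
  cat("  planted suppressors:", sum(x$truth$role == "suppressor"), "\n")
  invisible(x)
}

#' Draw a coding substitution of a requested effect class
#'
#' Samples an internal codon of `gene_id` and a single-base substitution
#' whose translated effect is of the requested class; start and stop codons
#' and positions listed in `used` (`"chrom:pos"`) are avoided. Exposed
#' because it is convenient for building test fixtures with known effects.
#'
#' @param annotation A `pool_annotation`.
#' @param gene_id Target gene.
#' @param effect One of `"missense"`, `"nonsense"`, `"silent"`.
#' @param used Character vector of occupied `"chrom:pos"` keys.
#' @return List with `chrom`, `pos`, `ref`, `alt`, `effect`.
#' @export
plant_coding <- function(annotation, gene_id, effect = c("missense",
                         "nonsense", "silent"), used = character(0)) {
  effect <- match.arg(effect)
  g <- annotation$genes[annotation$genes$gene_id == gene_id, ]
  cds <- gene_cds(annotation, gene_id)
  n_codon <- nchar(cds) / 3L
  gc <- codon_table()
  for (try in 1:500) {
    i <- sample(2:(n_codon - 1L), 1L)          # internal codon
    wpos <- sample(1:3, 1L)
    cds_pos <- 3L * (i - 1L) + wpos
    old_codon <- substring(cds, 3L * i - 2L, 3L * i)
    old_aa <- gc[[old_codon]]
    for (b in sample(setdiff(c("A", "C", "G", "T"),
                             substring(cds, cds_pos, cds_pos)))) {
      new_codon <- old_codon
      substring(new_codon, wpos, wpos) <- b
      new_aa <- gc[[new_codon]]
      hit <- switch(effect,
                    missense = new_aa != old_aa && new_aa != "*",
                    nonsense = new_aa == "*",
                    silent   = new_aa == old_aa)
      if (!hit) next
      if (g$strand == "+") {
        gpos <- g$start + cds_pos - 1L; galt <- b
      } else {
        gpos <- g$end - cds_pos + 1L
        galt <- chartr("ACGT", "TGCA", b)
      }
      if (paste0(g$chrom, ":", gpos) %in% used) next
      eff_str <- if (effect == "nonsense") paste0(old_aa, i, "Stop")
                 else if (effect == "silent") "silent"
                 else paste0(old_aa, i, new_aa)
      return(list(chrom = g$chrom, pos = gpos,
                  ref = ref_base(annotation$genome, g$chrom, gpos),
                  alt = galt, effect = eff_str))
    }
  }
  stop("could not plant a ", effect, " substitution in ", gene_id)
}

## small insertion (1-4 bp) inside a gene; ref == "" marks insertion after pos
plant_insertion <- function(annotation, gene_id, used = character(0)) {
  g <- annotation$genes[annotation$genes$gene_id == gene_id, ]
  for (try in 1:100) {
    gpos <- sample(seq(g$start + 3L, g$end - 3L), 1L)
    if (paste0(g$chrom, ":", gpos) %in% used) next
    len <- sample(1:4, 1L)
    ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
    eff <- if (len %% 3 == 0) "ins(in-frame)" else "ins(frameshift)"
    return(list(chrom = g$chrom, pos = gpos, ref = "", alt = ins,
                effect = eff))
  }
  stop("could not plant an insertion in ", gene_id)
}

## background variants anywhere on the genome (random alt), annotated later
plant_background <- function(genome, n, used = character(0)) {
  if (n == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gene_id = character(0), effect = character(0),
                      stringsAsFactors = FALSE))
  chroms <- names(genome$seqs)
  out <- list()
  taken <- used
  while (length(out) < n) {
    chrom <- sample(chroms, 1L, prob = genome$lengths / genome$total_length)
    pos <- sample.int(genome$lengths[[chrom]], 1L)
    k <- paste0(chrom, ":", pos)
    if (k %in% taken) next
    taken <- c(taken, k)
    ref <- ref_base(genome, chrom, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    out[[length(out) + 1L]] <- data.frame(chrom = chrom, pos = pos,
                                          ref = ref, alt = alt,
                                          stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df$gene_id <- NA_character_; df$effect <- NA_character_
  df
}

#' Write a truth table as TSV
#'
#' Columns: mixture, chrom, pos, ref, alt, role, owner, gene_id, effect.
#'
#' @param screen A `pool_screen`.
#' @param path Output TSV path.
#' @export
write_truth <- function(screen, path) {
  utils::write.table(screen$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
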