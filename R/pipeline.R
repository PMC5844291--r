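#' Configuration of a full simulated screen run
#'
#' Collects every stage parameter with the protocol defaults: a 100 kb toy
#' genome with 20 genes, 3 mixtures of N = 10 revertants, one private
#' suppressor per revertant, 2x150 bp reads at 30-fold per-genome coverage
#' with error rate 0.002, the 2% / Bonferroni caller and the >= 2-event
#' recurrence filter.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Output directory for the run.
#' @param ... Overrides of any default listed in the return value.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("poolrevert_run_"),
                       ...) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              genome_length = 100000, gc_fraction = 0.36,
              n_genes = 20, gene_length_min = 300, gene_length_max = 1500,
              ts_gene = "gene01", N = 10, n_background = 30,
              n_mixtures = 3, per_revertant = 1,
              effect_missense = 0.7, effect_nonsense = 0.3,
              effect_insertion = 0,
              read_length = 150, insert_mean = 400, insert_sd = 40,
              coverage_per_genome = 30, error_rate = 0.002,
              max_mismatch_fraction = 0.1, k = 15,
              alpha = 0.05, min_af = 0.02, min_depth = 10,
              anchor_min_af = 0.9, background_min_af = 0.8,
              recurrence_threshold = 2,
              stages = "simulate,align,call,classify,design",
              ts_chrom = "", ts_pos = 0, ts_alt = "")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as plain key=value text
#'
#' @param cfg A `run_config`.
#' @param path Config file path.
#' @export
write_config <- function(cfg, path) {
  writeLines(sprintf("%s=%s", names(cfg),
                     vapply(cfg, function(v) paste(format(v, scientific = FALSE),
                                                   collapse = ","),
                            character(1))), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)
  vals <- lapply(kv, `[`, 2)
  names(vals) <- vapply(kv, `[`, "", 1)
  cfg <- run_config()
  for (k in names(vals)) {
    if (!k %in% names(cfg)) stop("unknown config field: ", k)
    v <- vals[[k]]
    cfg[[k]] <- if (is.numeric(cfg[[k]])) as.numeric(v) else v
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run a simulated suppressor screen end to end
#'
#' Orchestrates simulate, align, call, classify and design into one
#' reproducible run directory: reference FASTA, GFF3, parental VCF, truth
#' table, per-mixture FASTQ/SAM/VCF, classified-variant TSVs, the
#' suppressor report, a design report, the serialized config and a
#' timestamped log. Re-running with the same config reproduces every
#' deterministic output byte-identically. Stages listed in `cfg$stages`
#' are run; a later stage restarts from the files an earlier run left in
#' `out_dir` (stage isolation), so e.g. `stages = "call,classify,design"`
#' re-analyses existing SAM files.
#'
#' @param cfg A [run_config()] (or path to a config file).
#' @return A `pool_run` list: `out_dir`, `report` (suppressor report),
#'   `classified` (per mixture), `design` (design report data.frame),
#'   `anchor_warnings` (count of mixtures whose ts anchor was absent).
#' @export
run_screen <- function(cfg = run_config()) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$out_dir, "run.log")
  log_line <- function(stage, msg)
    cat(sprintf("%s [%s] %s\n",
                format(as.POSIXct(Sys.time(), tz = "UTC"),
                       "%Y-%m-%dT%H:%M:%SZ"), stage, msg),
        file = logf, append = TRUE)
  log_line("run", paste0("poolrevert ", as.character(
    utils::packageVersion("poolrevert")), ", seed ", cfg$seed))
  stages <- strsplit(cfg$stages, ",", fixed = TRUE)[[1]]
  p <- function(...) file.path(cfg$out_dir, paste0(...))
  mix_ids <- sprintf("mix%02d", seq_len(cfg$n_mixtures))

  genome <- NULL; annotation <- NULL; screen <- NULL
  pileups <- list(); calls <- list()

  if ("simulate" %in% stages) {
    log_line("simulate", "generating genome, annotation, screen, reads")
    genome0 <- make_genome(cfg$genome_length, cfg$gc_fraction,
                           seed = cfg$seed)
    annotation <- make_annotation(genome0, cfg$n_genes,
                                  c(cfg$gene_length_min,
                                    cfg$gene_length_max),
                                  seed = cfg$seed + 1L)
    genome <- annotation$genome
    model <- suppressor_model(effect_bias = c(
      missense = cfg$effect_missense, nonsense = cfg$effect_nonsense,
      insertion = cfg$effect_insertion),
      per_revertant = cfg$per_revertant)
    screen <- make_screen(annotation, cfg$ts_gene, N = cfg$N,
                          n_background = cfg$n_background, model = model,
                          seed = cfg$seed + 2L,
                          n_mixtures = cfg$n_mixtures)
    cfg$ts_chrom <- screen$ts$chrom
    cfg$ts_pos <- screen$ts$pos
    cfg$ts_alt <- screen$ts$alt
    write_fasta(genome, p("ref.fasta"))
    write_gff3(annotation, p("genes.gff3"))
    write_vcf(screen$parental, genome, p("parental.vcf"))
    write_truth(screen, p("truth.tsv"))
    for (m in seq_len(cfg$n_mixtures)) {
      prm <- read_sim_params(cfg$read_length, cfg$insert_mean,
                             cfg$insert_sd, cfg$coverage_per_genome,
                             cfg$error_rate, seed = cfg$seed + 100L + m)
      rd <- simulate_pool_reads(screen$mixtures[[m]]$revertants,
                                pool_spec(cfg$N), prm)
      write_fastq(rd, p(mix_ids[m], "_R1.fastq"), p(mix_ids[m], "_R2.fastq"))
      log_line("simulate", paste0(mix_ids[m], ": ", length(rd$r1),
                                  " read pairs"))
    }
  }
  write_config(cfg, p("config.txt"))

  if (is.null(genome)) genome <- read_fasta(p("ref.fasta"))

  if ("align" %in% stages) {
    idx <- build_index(genome, cfg$k)
    for (m in seq_len(cfg$n_mixtures)) {
      r1 <- read_fastq(p(mix_ids[m], "_R1.fastq"))
      r2 <- read_fastq(p(mix_ids[m], "_R2.fastq"))
      al <- map_reads(c(r1$seqs, r2$seqs), idx,
                      cfg$max_mismatch_fraction,
                      read_ids = c(r1$names, r2$names))
      write_sam(al, genome, p(mix_ids[m], ".sam"))
      pileups[[mix_ids[m]]] <- pileup(al, genome)
      log_line("align", sprintf("%s: %d/%d reads mapped", mix_ids[m],
                                sum(al$mapped), nrow(al)))
    }
  }

  if ("call" %in% stages) {
    prm <- caller_params(cfg$error_rate, cfg$alpha, cfg$min_af,
                         cfg$min_depth)
    for (m in seq_len(cfg$n_mixtures)) {
      pl <- pileups[[mix_ids[m]]]
      if (is.null(pl)) {
        al <- read_sam(p(mix_ids[m], ".sam"), genome)
        pl <- pileup(al, genome)
      }
      cl <- call_mixture(pl, prm, mixture_id = mix_ids[m])
      calls[[mix_ids[m]]] <- cl
      write_vcf(cl, genome, p(mix_ids[m], ".vcf"))
      log_line("call", paste0(mix_ids[m], ": ", nrow(cl), " calls"))
    }
  }

  classified <- list(); report <- NULL; n_warn <- 0L
  if ("classify" %in% stages) {
    if (is.null(annotation)) {
      genes <- read_gff3(p("genes.gff3"))
      annotation <- structure(list(genes = genes, complex_map = NULL,
                                   genome = genome),
                              class = "pool_annotation")
    }
    parental <- read_vcf(p("parental.vcf"))
    cp <- classifier_params(list(chrom = cfg$ts_chrom,
                                 pos = as.integer(cfg$ts_pos),
                                 alt = cfg$ts_alt),
                            cfg$anchor_min_af, cfg$background_min_af,
                            cfg$min_af)
    for (m in seq_len(cfg$n_mixtures)) {
      cl <- calls[[mix_ids[m]]]
      if (is.null(cl)) cl <- read_vcf(p(mix_ids[m], ".vcf"))
      cls <- withCallingHandlers(
        classify_calls(cl, cp, parental, annotation),
        warning = function(w) {
          if (grepl("anchor absent", conditionMessage(w))) {
            n_warn <<- n_warn + 1L
            log_line("classify", paste0(mix_ids[m], ": WARNING ",
                                        conditionMessage(w)))
            invokeRestart("muffleWarning")
          }
        })
      classified[[mix_ids[m]]] <- cls
      write_tsv(cls, p(mix_ids[m], "_classified.tsv"))
      log_line("classify", paste0(mix_ids[m], ": ",
                                  sum(cls$category == "suppressor_candidate"),
                                  " suppressor candidates"))
    }
    all_cls <- do.call(rbind, lapply(classified, as.data.frame))
    report <- recurrence_filter(all_cls, cfg$recurrence_threshold,
                                complex_map = annotation$complex_map,
                                ts_gene = cfg$ts_gene)
    write_tsv(report, p("suppressor_report.tsv"))
    log_line("classify", paste0("report: ", nrow(report),
                                " unit(s) pass recurrence filter"))
  }

  design <- NULL
  if ("design" %in% stages) {
    pw <- detection_power(power_params(
      N = cfg$N, coverage_per_genome = cfg$coverage_per_genome,
      error_rate = cfg$error_rate, min_af = cfg$min_af,
      alpha = cfg$alpha, n_tests = 3 * cfg$genome_length))
    design <- data.frame(
      quantity = c("expected_suppressor_af", "expected_pool_depth",
                   "genomes_per_lane", "detection_power"),
      value = c(expected_af(cfg$N, 1), cfg$N * cfg$coverage_per_genome,
                lane_multiplex(cfg$n_mixtures, cfg$N), pw))
    write_tsv(design, p("design_report.tsv"))
    log_line("design", sprintf("detection power at defaults: %.6f", pw))
  }
  log_line("run", "done")
  structure(list(out_dir = cfg$out_dir, config = cfg, report = report,
                 classified = classified, design = design,
                 anchor_warnings = n_warn),
            class = "pool_run")
}

#' @exportS3Method base::print
print.pool_run <- function(x, ...) {
  cat("pool_run:", x$out_dir, "\n")
  if (!is.null(x$report)) print(x$report)
  if (x$anchor_warnings > 0)
    cat("  !", x$anchor_warnings, "mixture(s) with absent ts anchor\n")
  invisible(x)
}
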