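# One shared simulated screen at the protocol's study conditions:
# 100 kb genome, 20 genes, one mixture of N = 10 revertants each carrying
# one private suppressor, 30-fold per-genome coverage (pool ~300x),
# error rate 0.002. Built once per test session and reused by every test
# that needs the full simulate -> align -> call -> classify chain.
.run_cache <- new.env(parent = emptyenv())

default_run <- function() {
  if (!is.null(.run_cache$run)) return(.run_cache$run)
  seed <- 20180L
  g0 <- make_genome(1e5, gc_fraction = 0.36, seed = seed)
  ann <- make_annotation(g0, n_genes = 20,
                         gene_length_range = c(300, 1500), seed = seed + 1L)
  scr <- make_screen(ann, ts_gene = "gene01", N = 10, n_background = 30,
                     seed = seed + 2L)
  prm <- read_sim_params(coverage_per_genome = 30, error_rate = 0.002,
                         seed = seed + 3L)
  rd <- simulate_pool_reads(scr$mixtures[[1]]$revertants, pool_spec(10), prm)
  idx <- build_index(ann$genome)
  al <- align_pool(rd, idx)
  pl <- pileup(al, ann$genome)
  cl <- call_mixture(pl, caller_params(error_rate = 0.002))
  cp <- classifier_params(list(chrom = scr$ts$chrom, pos = scr$ts$pos,
                               alt = scr$ts$alt))
  cls <- classify_calls(cl, cp, scr$parental, ann)
  .run_cache$run <- list(ann = ann, scr = scr, reads = rd, al = al,
                         pl = pl, cl = cl, cls = cls)
  .run_cache$run
}
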