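test_that("make_genome draws the requested length and GC content deterministically", {
  g <- make_genome(1e5, gc_fraction = 0.36, seed = 1)
  s <- g$seqs[[1]]
  expect_equal(nchar(s), 1e5)
  expect_true(grepl("^[ACGT]+$", s))
  gc <- sum(charToRaw(s) %in% charToRaw("GC")) / 1e5
  # 3 sigma binomial band around the target GC fraction
  expect_lt(abs(gc - 0.36), 3 * sqrt(0.36 * 0.64 / 1e5))
  expect_identical(make_genome(1e5, 0.36, seed = 1)$seqs, g$seqs)
  expect_false(identical(make_genome(1e5, 0.36, seed = 2)$seqs, g$seqs))
  expect_error(make_genome(999), "1000")
})

test_that("make_annotation places disjoint in-frame ORFs on both strands", {
  g <- make_genome(1e5, seed = 3)
  ann <- make_annotation(g, n_genes = 20, gene_length_range = c(300, 1500),
                         seed = 4)
  genes <- ann$genes
  expect_equal(nrow(genes), 20)
  expect_false(anyDuplicated(genes$gene_id) > 0)
  len <- genes$end - genes$start + 1
  expect_true(all(len %% 3 == 0))
  o <- order(genes$chrom, genes$start)
  expect_true(all(diff(genes$start[o]) > (genes$end - genes$start)[o][-20]))
  expect_true(all(c("+", "-") %in% genes$strand))
  gc <- Biostrings::GENETIC_CODE
  for (gid in genes$gene_id) {
    cds <- poolrevert:::gene_cds(ann, gid)
    codons <- substring(cds, seq(1, nchar(cds) - 2, 3),
                        seq(3, nchar(cds), 3))
    expect_identical(codons[1], "ATG")
    expect_identical(unname(gc[codons[length(codons)]]), "*")
    expect_false(any(gc[codons[-length(codons)]] == "*"))
  }
  # the genome outside gene intervals is untouched
  out <- setdiff(seq_len(1000), unlist(Map(seq, genes$start, genes$end)))
  expect_identical(substring(ann$genome$seqs[[1]], out, out),
                   substring(g$seqs[[1]], out, out))
  expect_error(make_annotation(make_genome(1000, seed = 1), n_genes = 50,
                               gene_length_range = c(300, 300)),
               "non-overlapping")
})

test_that("make_screen truth table conserves roles, owners and recurrence", {
  g <- make_genome(3e4, seed = 5)
  ann <- make_annotation(g, 8, c(300, 900), seed = 6)
  scr <- make_screen(ann, "gene02", N = 10, n_background = 12, seed = 7,
                     n_mixtures = 2)
  tr <- scr$truth
  expect_equal(sum(tr$role == "ts"), 1)
  expect_equal(sum(tr$role == "background"), 12)
  expect_equal(sum(tr$role == "suppressor"), 20)  # N per mixture
  expect_true(all(tr$owner[tr$role != "suppressor"] == "all"))
  sup <- tr[tr$role == "suppressor", ]
  for (m in unique(sup$mixture))
    expect_setequal(sup$owner[sup$mixture == m], as.character(1:10))
  # every revertant genome carries ts + background + exactly its suppressor
  rev1 <- scr$mixtures[[1]]$revertants[[1]]
  expect_identical(substring(rev1$seqs[[scr$ts$chrom]], scr$ts$pos,
                             scr$ts$pos), scr$ts$alt)
  own <- sup[sup$mixture == "mix01" & sup$owner == "1", ]
  other <- sup[sup$mixture == "mix01" & sup$owner == "2", ]
  expect_identical(substring(rev1$seqs[[own$chrom]], own$pos, own$pos),
                   own$alt)
  expect_identical(substring(rev1$seqs[[other$chrom]], other$pos, other$pos),
                   other$ref)
  expect_error(make_screen(ann, "nosuchgene"), "ts_gene")
  expect_error(make_screen(ann, "gene02",
                           model = suppressor_model(target_genes = "bogus")),
               "target gene")
})

test_that("a suppressor model biased to one gene yields recurrent independent events", {
  g <- make_genome(3e4, seed = 8)
  ann <- make_annotation(g, 6, c(300, 900), seed = 9)
  m <- suppressor_model(target_genes = "gene03",
                        effect_bias = c(nonsense = 1))
  scr <- make_screen(ann, "gene01", N = 2, n_background = 0, model = m,
                     seed = 10, n_mixtures = 2)
  sup <- scr$truth[scr$truth$role == "suppressor", ]
  expect_equal(nrow(sup), 4)
  expect_true(all(sup$gene_id == "gene03"))
  expect_true(all(grepl("Stop$", sup$effect)))
})

test_that("insertions are planted in genomes and truth when requested", {
  g <- make_genome(2e4, seed = 11)
  ann <- make_annotation(g, 4, c(300, 600), seed = 12)
  m <- suppressor_model(effect_bias = c(insertion = 1))
  scr <- make_screen(ann, "gene01", N = 2, n_background = 0, model = m,
                     seed = 13)
  sup <- scr$truth[scr$truth$role == "suppressor", ]
  expect_true(all(sup$ref == ""))
  expect_true(all(grepl("^ins\\(", sup$effect)))
  rev1 <- scr$mixtures[[1]]$revertants[[1]]
  ins1 <- sup[sup$owner == "1", ]
  expect_equal(rev1$total_length,
               ann$genome$total_length + nchar(ins1$alt))
})

test_that("pooled reads have the expected depth, origin mix and determinism", {
  g <- make_genome(1e4, seed = 14)
  ann <- make_annotation(g, 3, c(300, 600), seed = 15)
  scr <- make_screen(ann, "gene01", N = 5, n_background = 0, seed = 16)
  prm <- read_sim_params(coverage_per_genome = 4, error_rate = 0,
                         insert_mean = 300, insert_sd = 20, seed = 17)
  rd <- simulate_pool_reads(scr$mixtures[[1]]$revertants, pool_spec(5), prm)
  expect_equal(rd$expected_pool_depth, 20, tolerance = 0.01)

  # noiseless reads match their source genome exactly (origin from names)
  origin <- do.call(rbind, strsplit(rd$names, ":", fixed = TRUE))
  rev_i <- as.integer(sub("rev", "", origin[, 1]))
  starts <- as.integer(origin[, 3])
  pick <- seq(1, length(rd$r1), by = 37)
  for (i in pick) {
    src <- scr$mixtures[[1]]$revertants[[rev_i[i]]]$seqs[[origin[i, 2]]]
    expect_identical(rd$r1[i], substring(src, starts[i], starts[i] + 149))
  }

  # empirical mean depth over interior sites within 3 sigma of N * coverage
  idx <- build_index(ann$genome)
  pl <- pileup(align_pool(rd, idx), ann$genome)
  interior <- 400:(1e4 - 400)
  d <- rowSums(pl$counts)[interior]
  expect_lt(abs(mean(d) - 20), 3 * sqrt(20 / length(interior)) + 0.5)

  # same seed => byte-identical FASTQ
  rd2 <- simulate_pool_reads(scr$mixtures[[1]]$revertants, pool_spec(5), prm)
  f1 <- tempfile(); f2 <- tempfile(); f3 <- tempfile(); f4 <- tempfile()
  write_fastq(rd, f1, f2); write_fastq(rd2, f3, f4)
  expect_identical(readLines(f1), readLines(f3))
  expect_identical(readLines(f2), readLines(f4))

  expect_error(read_sim_params(insert_mean = 100), "insert_mean")
})

test_that("read-level allele fractions follow the 1/N mixture model without noise", {
  g <- make_genome(1e4, seed = 18)
  ann <- make_annotation(g, 3, c(300, 600), seed = 19)
  scr <- make_screen(ann, "gene01", N = 5, n_background = 2, seed = 20)
  prm <- read_sim_params(coverage_per_genome = 30, error_rate = 0,
                         insert_mean = 300, insert_sd = 20, seed = 21)
  rd <- simulate_pool_reads(scr$mixtures[[1]]$revertants, pool_spec(5), prm)
  pl <- pileup(align_pool(rd, build_index(ann$genome)), ann$genome)
  bases <- c(A = 1, C = 2, G = 3, T = 4)
  af_at <- function(chrom, pos, alt) {
    row <- pl$counts[pl$offsets[[chrom]] + pos, ]
    unname(row[bases[alt]] / sum(row))
  }
  expect_equal(af_at(scr$ts$chrom, scr$ts$pos, scr$ts$alt), 1)
  sup <- scr$truth[scr$truth$role == "suppressor", ]
  for (i in seq_len(nrow(sup))) {
    af <- af_at(sup$chrom[i], sup$pos[i], sup$alt[i])
    d <- sum(pl$counts[pl$offsets[[sup$chrom[i]]] + sup$pos[i], ])
    expect_lt(abs(af - 0.2), 3 * sqrt(0.2 * 0.8 / d))
  }
})

test_that("pool_spec validates proportions", {
  expect_error(pool_spec(3, c(0.5, 0.5)), "one proportion per")
  expect_error(pool_spec(2, c(0.7, 0.4)), "sum to 1")
  expect_silent(pool_spec(2, c(0.25, 0.75)))
})
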