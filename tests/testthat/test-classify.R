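mk_calls <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = "chrI", pos = r[[1]], ref = r[[2]], alt = r[[3]],
               depth = 300, alt_count = round(r[[4]] * 300),
               af = r[[4]], p_value = 1e-40, q_value = 1e-35,
               mixture_id = if (length(r) > 4) r[[5]] else "mix01",
               stringsAsFactors = FALSE)))
  class(df) <- c("pool_calls", "data.frame")
  df
}

test_that("classification partitions calls into the four frequency strata", {
  cp <- classifier_params(list(chrom = "chrI", pos = 1000, alt = "T"))
  parental <- data.frame(chrom = "chrI", pos = 500, ref = "G", alt = "A")
  calls <- mk_calls(list(1000, "C", "T", 0.98),   # anchor
                    list(500, "G", "A", 1.0),     # parental background
                    list(700, "A", "G", 0.86),    # fixed but not parental
                    list(2000, "T", "C", 0.11),   # candidate
                    list(2500, "C", "G", 0.27),   # candidate (k-sharing ~3)
                    list(3000, "G", "T", 0.015))  # subthreshold
  cls <- classify_calls(calls, cp, parental)
  expect_equal(cls$category,
               c("anchor_ts", "background_common", "background_common",
                 "suppressor_candidate", "suppressor_candidate",
                 "subthreshold"))
  # partition: every call in exactly one category
  expect_equal(sum(table(cls$category)), nrow(calls))
})

test_that("a missing or low-frequency anchor raises a mixture-integrity warning", {
  cp <- classifier_params(list(chrom = "chrI", pos = 1000, alt = "T"))
  expect_warning(classify_calls(mk_calls(list(2000, "T", "C", 0.11)), cp),
                 "anchor absent")
  # anchor position present but below anchor_min_af: degraded pool
  expect_warning(cls <- classify_calls(mk_calls(list(1000, "C", "T", 0.55)),
                                       cp),
                 "anchor absent")
  expect_equal(cls$category, "suppressor_candidate")
})

test_that("classifier_params enforces threshold ordering", {
  expect_error(classifier_params(list(chrom = "c", pos = 1, alt = "A"),
                                 anchor_min_af = 0.7,
                                 background_min_af = 0.8),
               "min_af")
})

test_that("effect naming recovers missense, nonsense and silent changes on both strands", {
  # codon 64 CAA (Q), codon 77 TGC (C), codon 338 GGC (G)
  orf <- orf_with_codons(400, planted = list(`64` = "CAA", `77` = "TGC",
                                             `338` = "GGC"))
  for (strand in c("+", "-")) {
    ann <- manual_annotation(orf, strand = strand)
    g <- ann$genes
    gpos <- function(cds_pos) if (strand == "+") g$start + cds_pos - 1L
                              else g$end - cds_pos + 1L
    base_on_genome <- function(b) if (strand == "+") b
                                  else chartr("ACGT", "TGCA", b)
    # GGC -> GAC at codon 338: G338D
    p <- gpos(3 * 337 + 2)
    eff <- annotate_effect(list(chrom = "chrI", pos = p,
                                ref = base_on_genome("G"),
                                alt = base_on_genome("A")), ann)
    expect_equal(eff$gene_id, "geneA")
    expect_equal(eff$effect, "G338D")
    # CAA -> TAA at codon 64: Q64Stop
    p <- gpos(3 * 63 + 1)
    eff <- annotate_effect(list(chrom = "chrI", pos = p,
                                ref = base_on_genome("C"),
                                alt = base_on_genome("T")), ann)
    expect_equal(eff$effect, "Q64Stop")
    # TGC -> TAC at codon 77: C77Y
    p <- gpos(3 * 76 + 2)
    eff <- annotate_effect(list(chrom = "chrI", pos = p,
                                ref = base_on_genome("G"),
                                alt = base_on_genome("A")), ann)
    expect_equal(eff$effect, "C77Y")
  }
})

test_that("third-position synonymous changes are silent and intergenic sites flagged", {
  orf <- orf_with_codons(100, planted = list(`50` = "TTA"))  # Leu
  ann <- manual_annotation(orf, strand = "+")
  p <- ann$genes$start + 3 * 49 + 2  # third base of codon 50
  eff <- annotate_effect(list(chrom = "chrI", pos = p, ref = "A",
                              alt = "G"), ann)  # TTA -> TTG, Leu -> Leu
  expect_equal(eff$effect, "silent")
  eff <- annotate_effect(list(chrom = "chrI", pos = 5,
                              ref = substring(ann$genome$seqs[[1]], 5, 5),
                              alt = setdiff(c("A", "C", "G", "T"),
                                            substring(ann$genome$seqs[[1]],
                                                      5, 5))[1]), ann)
  expect_true(is.na(eff$gene_id))
  expect_equal(eff$effect, "intergenic")
  # insertions: frameshift vs in-frame
  p <- ann$genes$start + 10
  expect_equal(annotate_effect(list(chrom = "chrI", pos = p, ref = "",
                                    alt = "AG"), ann)$effect,
               "ins(frameshift)")
  expect_equal(annotate_effect(list(chrom = "chrI", pos = p, ref = "",
                                    alt = "AGT"), ann)$effect,
               "ins(in-frame)")
  expect_error(annotate_effect(list(chrom = "chrI", pos = 5, ref = "Z",
                                    alt = "A"), ann),
               "ref base disagreement")
})

test_that("codon-level annotation agrees with a full-CDS translation oracle", {
  set.seed(50)
  g <- make_genome(5e4, seed = 51)
  ann <- make_annotation(g, 12, c(300, 1200), seed = 52)
  genes <- ann$genes
  cds_cache <- lapply(genes$gene_id, function(g)
    poolrevert:::gene_cds(ann, g))
  prot_cache <- lapply(cds_cache, function(cds)
    strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(cds), no.init.codon = TRUE)), "")[[1]])
  n <- 1000
  got <- character(n); want <- character(n)
  for (trial in seq_len(n)) {
    gi <- sample(nrow(genes), 1)
    ge <- genes[gi, ]
    cds <- cds_cache[[gi]]
    cds_pos <- sample(nchar(cds), 1)
    refb <- substring(cds, cds_pos, cds_pos)
    altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
    want[trial] <- translation_oracle(cds, cds_pos, altb,
                                      p0 = prot_cache[[gi]])
    if (ge$strand == "+") {
      pos <- ge$start + cds_pos - 1L; galt <- altb
    } else {
      pos <- ge$end - cds_pos + 1L; galt <- chartr("ACGT", "TGCA", altb)
    }
    got[trial] <- annotate_effect(list(
      chrom = ge$chrom, pos = pos,
      ref = poolrevert:::ref_base(ann$genome, ge$chrom, pos),
      alt = galt), ann)$effect
  }
  expect_equal(got, want)
})

test_that("recurrence filter selects two-hit genes and multi-gene complexes", {
  # Sgf11-style: the same gene hit in two mixtures by different mutations
  cls <- rbind(cls_row("mix01", "sgf11", "Q64Stop", pos = 190),
               cls_row("mix02", "sgf11", "C77Y", pos = 230),
               cls_row("mix01", "lonely", "A10V", pos = 900))
  rep <- recurrence_filter(cls, threshold = 2)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$unit, "gene")
  expect_equal(rep$unit_id, "sgf11")
  expect_equal(rep$n_events, 2)
  expect_equal(rep$n_distinct_variants, 2)
  expect_false(rep$intragenic)

  # SAGA-style: five genes, one event each, all in one complex
  saga <- c("ubp8", "sgf11", "sus1", "gcn5", "hfi1")
  cmap <- data.frame(gene_id = saga, complex_id = "SAGA")
  cls <- do.call(rbind, lapply(seq_along(saga), function(i)
    cls_row(sprintf("mix%02d", i), saga[i], "X1Y", pos = 100 * i)))
  rep <- recurrence_filter(cls, threshold = 2, complex_map = cmap)
  expect_equal(rep$unit, "complex")
  expect_equal(rep$unit_id, "SAGA")
  expect_equal(rep$n_events, 5)
  expect_setequal(strsplit(rep$members, ",")[[1]], saga)

  # a single gene reaching threshold alone is reported at gene level only
  cls2 <- rbind(cls_row("mix01", "ubp8", "Y86Stop", pos = 110),
                cls_row("mix02", "ubp8", "Y96C", pos = 140))
  rep2 <- recurrence_filter(cls2, threshold = 2, complex_map = cmap)
  expect_equal(rep2$unit, "gene")
  expect_equal(rep2$unit_id, "ubp8")
})

test_that("recurrence events are per (mixture, variant) and order-invariant", {
  # identical substitution in two mixtures: two independent events;
  # duplicated row within one mixture: one event
  cls <- rbind(cls_row("mix01", "wpl1", "G100D", pos = 400),
               cls_row("mix02", "wpl1", "G100D", pos = 400),
               cls_row("mix02", "wpl1", "G100D", pos = 400))
  rep <- recurrence_filter(cls, threshold = 2)
  expect_equal(rep$n_events, 2)
  expect_equal(rep$n_distinct_variants, 1)
  ev <- attr(rep, "events")
  expect_true(all(ev$cross_mixture_n == 2))
  # shuffling input rows leaves the report unchanged
  set.seed(60)
  cls3 <- rbind(cls_row("mix01", "g1", "A1V", pos = 10),
                cls_row("mix02", "g1", "A2V", pos = 20),
                cls_row("mix03", "g2", "A3V", pos = 30),
                cls_row("mix01", "g2", "A4V", pos = 40),
                cls_row("mix02", "g3", "A5V", pos = 50))
  r1 <- recurrence_filter(cls3, threshold = 2)
  r2 <- recurrence_filter(cls3[sample(nrow(cls3)), ], threshold = 2)
  attr(r1, "events") <- attr(r2, "events") <- NULL
  expect_equal(r1, r2, ignore_attr = TRUE)
})

test_that("candidates in the ts gene itself are reported as intragenic", {
  cls <- rbind(cls_row("mix01", "cdc48", "E318K", pos = 700),
               cls_row("mix02", "cdc48", "P526L", pos = 820))
  rep <- recurrence_filter(cls, threshold = 2, ts_gene = "cdc48")
  expect_true(rep$intragenic)
})
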