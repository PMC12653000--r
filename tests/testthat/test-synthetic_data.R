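test_that("expression generation is byte-reproducible under a fixed seed", {
  a <- gen_expression(n_transcripts = 100, tissues = 5, seed = 7)
  b <- gen_expression(n_transcripts = 100, tissues = 5, seed = 7)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$expr$meta, b$expr$meta)
  c <- gen_expression(n_transcripts = 100, tissues = 5, seed = 8)
  expect_false(identical(a$expr$values, c$expr$values))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(42)
  before <- .Random.seed
  gen_expression(n_transcripts = 20, tissues = 3, seed = 1)
  expect_identical(.Random.seed, before)
})

test_that("planted fold-100 transcripts are recovered at threshold 0.8", {
  gen <- gen_expression(n_transcripts = 2000, tissues = 17,
                        plan = data.frame(tissue = "tissue01", n = 50,
                                          fold = 100),
                        seed = 11)
  sp <- specificity(gen$expr)
  hits <- sp$transcript_ids[sp$normalized[, "tissue01"] > 0.8]
  planted <- gen$truth$planted$tissue01
  expect_gte(sum(planted %in% hits), 48)  # >= 95% recovery
  fp <- setdiff(hits, planted)
  expect_lte(length(fp), 0.01 * (2000 - 50))  # <= 1% false positives
})

test_that("a fold-1 background stays under the 1% false-positive budget", {
  gen <- gen_expression(n_transcripts = 10000, tissues = 33, seed = 12)
  sp <- specificity(gen$expr)
  frac <- mean(apply(sp$normalized, 1, max) > 0.8)
  expect_lt(frac, 0.01)
})

test_that("transcript-per-gene structure tracks the requested mean", {
  gen <- gen_expression(n_transcripts = 3000, tissues = 4,
                        tx_per_gene = 3.4, seed = 13)
  mean_tpg <- 3000 / length(unique(gen$expr$meta$gene_id))
  expect_equal(mean_tpg, 3.4, tolerance = 0.15)
})

test_that("synthetic genome and annotation are reproducible and readable", {
  a <- gen_genome_annotation(n_transcripts = 20, seed = 5)
  b <- gen_genome_annotation(n_transcripts = 20, seed = 5)
  expect_identical(a$genome, b$genome)
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fa"); gtf <- file.path(dir, "a.gtf")
  write_fasta(a$genome, fa)
  write_gtf(a$annotation, gtf)
  # identical bytes when rewritten from the same seed
  fa2 <- file.path(dir, "g2.fa")
  write_fasta(b$genome, fa2)
  expect_identical(readLines(fa), readLines(fa2))
  # generated files pass the package readers without warnings
  expect_no_warning(genome <- read_fasta(fa))
  expect_no_warning(ann <- read_annotation(gtf, "gtf"))
  expect_equal(nrow(ann), 20L)
  ann <- ann[match(a$annotation$transcript_id, ann$transcript_id), ]
  expect_equal(ann$start, a$annotation$start)
  expect_equal(ann$end, a$annotation$end)
  expect_equal(ann$strand, a$annotation$strand)
  expect_equal(ann$exon_count, a$annotation$exon_count)
})

test_that("the planted AT peak is recovered near -25 in the pooled profile", {
  gen <- gen_genome_annotation(n_transcripts = 500, seed = 19)
  tss <- tss_coordinates(gen$annotation)
  fl <- dedup_sequences(extract_flank(gen$genome, tss$chrom, tss$tss,
                                      tss$strand, 200, 100),
                        U = 200, D = 100)
  prof <- base_profile(fl)
  at <- prof$A + prof$T
  # restrict to upstream positions beyond the GC-rise region boundary
  upstream <- prof$position < 0
  peak_pos <- prof$position[upstream][which.max(at[upstream])]
  expect_gte(peak_pos, -30)
  expect_lte(peak_pos, -20)
})

test_that("a null signal spec yields a flat profile within binomial bands", {
  gen <- gen_genome_annotation(
    n_transcripts = 400, gc = 0.4,
    signal = list(gc_rise = 0, at_peak = 0, tg_excess = 0), seed = 23)
  tss <- tss_coordinates(gen$annotation)
  fl <- dedup_sequences(extract_flank(gen$genome, tss$chrom, tss$tss,
                                      tss$strand, 150, 100),
                        U = 150, D = 100)
  prof <- base_profile(fl)
  m <- length(fl$sequences)
  for (b in c("A", "T", "G", "C")) {
    p0 <- if (b %in% c("G", "C")) 0.2 else 0.3
    band <- 3 * sqrt(p0 * (1 - p0) / m)
    within <- abs(prof[[b]] - p0) <= band
    expect_gte(mean(within), 0.98)  # 3-sigma: a few excursions expected
  }
})

test_that("minus-strand signals appear only under strand-aware extraction", {
  gen <- gen_genome_annotation(n_transcripts = 400, seed = 29)
  ann <- gen$annotation
  minus <- tss_coordinates(ann[ann$strand == "-", ])
  aware <- base_profile(dedup_sequences(
    extract_flank(gen$genome, minus$chrom, minus$tss, minus$strand, 60, 10),
    U = 60, D = 10))
  naive <- base_profile(dedup_sequences(
    extract_flank(gen$genome, minus$chrom, minus$tss,
                  rep("+", nrow(minus)), 60, 10),
    U = 60, D = 10))
  at_aware <- aware$A + aware$T
  at_naive <- naive$A + naive$T
  window <- aware$position >= -30 & aware$position <= -20
  flank_bg <- aware$position < -40
  excess_aware <- max(at_aware[window]) - mean(at_aware[flank_bg])
  excess_naive <- max(at_naive[window]) - mean(at_naive[flank_bg])
  expect_gt(excess_aware, 0.1)
  expect_lt(excess_naive, excess_aware / 2)
})

test_that("link generation plants exact-degree hubs and honours fractions", {
  genes_a <- sprintf("a%03d", 1:300)
  genes_b <- sprintf("b%03d", 1:300)
  links <- gen_links(genes_a, genes_b, seed = 31)
  expect_length(links$truth$hubs_a, 5L)
  phys <- links$physical$a
  deg <- table(c(phys$id_a, phys$id_b))
  expect_true(all(deg[links$truth$hubs_a] == 25L))
  expect_true(all(deg[setdiff(names(deg), links$truth$hubs_a)] <= 20L))
  expect_true(all(links$orthologs$score %in% 1:15))

  none <- gen_links(genes_a, genes_b, ortholog_fraction = 0, seed = 31)
  expect_equal(nrow(none$orthologs), 0L)

  fixed <- gen_links(genes_a, genes_b, score_probs = c(rep(0, 11), 1,
                                                       rep(0, 3)),
                     seed = 31)
  expect_equal(filter_orthologs(fixed$orthologs, 12), fixed$orthologs)
})
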