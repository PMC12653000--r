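test_that("TSS coordinates follow the strand convention", {
  ann <- data.frame(transcript_id = c("p", "m"), chrom = "c",
                    start = c(99L, 99L), end = c(200L, 200L),
                    strand = c("+", "-"), gene_id = c("g1", "g2"),
                    biotype = "coding", exon_count = 1L)
  tss <- tss_coordinates(ann)
  expect_equal(tss$tss, c(99L, 199L))
  ann$strand[1] <- "."
  expect_error(tss_coordinates(ann), "strand")
})

test_that("flank extraction is strand-aware with the TSS base at index U", {
  genome <- c(c = "ACGTACGTAC")
  expect_equal(extract_flank(genome, "c", 2, "+", 2, 3), "ACGTA")
  minus <- extract_flank(genome, "c", 5, "-", 2, 3)
  expect_equal(minus, "ACGTA")
  expect_equal(substr(minus, 3, 3), "G")  # complement of C at position 5
  # out-of-contig positions N-padded, length always U + D
  padded <- extract_flank(genome, "c", 1, "+", 3, 2)
  expect_equal(padded, "NNACG")
  expect_equal(nchar(padded), 5L)
  expect_error(extract_flank(genome, "nope", 1, "+", 1, 1), "absent")
})

test_that("plus-strand extraction mirrors minus-strand on the reverse complement", {
  set.seed(91)
  for (rep in 1:10) {
    L <- sample(50:200, 1)
    g <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
    g_rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
    tss <- sample(0:(L - 1), 1)
    U <- sample(1:20, 1); D <- sample(1:20, 1)
    fwd <- extract_flank(c(c = g), "c", tss, "+", U, D)
    mirrored <- extract_flank(c(c = g_rc), "c", L - 1 - tss, "-", U, D)
    expect_identical(fwd, mirrored)
  }
})

test_that("deduplication is case-folding, order-preserving and counted", {
  fl <- dedup_sequences(c("ACGT", "acgt", "AAAA"))
  expect_equal(fl$sequences, c("ACGT", "AAAA"))
  expect_equal(fl$counts, c(2L, 1L))
  distinct <- dedup_sequences(c("AC", "GT", "TT"))
  expect_equal(length(distinct$sequences), 3L)
  empty <- dedup_sequences(character(0))
  expect_equal(length(empty$sequences), 0L)
  expect_error(dedup_sequences(c("AC", "ACG")), "mixed lengths")
})

test_that("base profiles exclude N from denominators and sum to one", {
  fl <- dedup_sequences(c("ACGT"), U = 2, D = 2)
  p <- base_profile(fl)
  expect_equal(p$position, -2:1)
  expect_equal(p$A, c(1, 0, 0, 0))
  expect_equal(p$T, c(0, 0, 0, 1))

  fl2 <- dedup_sequences(c("AAAA", "AAAN"), U = 0)
  p2 <- base_profile(fl2)
  expect_equal(p2$A[4], 1.0)
  expect_equal(p2$n_obs[4], 1L)

  fl3 <- dedup_sequences(c("AT", "TA"), U = 1)
  p3 <- base_profile(fl3)
  expect_equal(p3$A, c(0.5, 0.5))
  expect_equal(p3$T, c(0.5, 0.5))
})

test_that("profile frequencies sum to 1 and counts to the non-N total", {
  set.seed(101)
  seqs <- vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T", "N"), 40, replace = TRUE,
                 prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = ""),
    character(1))
  fl <- dedup_sequences(seqs, U = 20)
  p <- base_profile(fl)
  sums <- p$A + p$T + p$G + p$C
  expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-9))
  total_non_n <- sum(vapply(fl$sequences, function(s)
    nchar(gsub("N", "", s)), numeric(1)))
  expect_equal(sum(p$n_obs), total_non_n)
})

test_that("control set keeps transcripts never highly enriched", {
  em <- make_expr(matrix(rlnorm(30), 10, 3))
  sp <- specificity(em)
  sp$normalized[] <- 0.1
  sp$normalized[1, 1] <- 0.85
  sp$normalized[2, 2] <- 0.5
  ctrl <- control_set(sp)
  expect_false("tx1" %in% ctrl)
  expect_true("tx2" %in% ctrl)
  expect_equal(length(control_set(sp, threshold = 1.0)), 10L)
})

test_that("non-coding partitions respect the minimum set size guard", {
  ann <- data.frame(transcript_id = sprintf("t%03d", 1:300),
                    chrom = "c", start = 1:300, end = 400 + 1:300,
                    strand = "+",
                    gene_id = sprintf("g%03d", 1:300),
                    biotype = rep(c("noncoding", "coding"), c(260, 40)),
                    exon_count = 1L)
  enr_genes <- sprintf("g%03d", 1:60)  # 60 enriched non-coding
  parts <- select_noncoding(ann, enr_genes)
  expect_true(parts$enriched$profiled)
  expect_true(parts$other$profiled)
  expect_equal(length(parts$enriched$transcript_id), 60L)
  small <- select_noncoding(ann, sprintf("g%03d", 1:10))
  expect_false(small$enriched$profiled)
  expect_match(small$enriched$note, "not profiled")
  none <- select_noncoding(ann[ann$biotype == "coding", ], enr_genes)
  expect_equal(length(none$enriched$transcript_id), 0L)
})

test_that("profile distances match hand computation and detect equality", {
  fl <- dedup_sequences(c("ACGT", "AATT"), U = 2)
  p <- base_profile(fl)
  d0 <- profile_distance(p, p)
  expect_equal(d0$mse, 0)
  expect_equal(d0$euclidean, 0)

  # two-position profiles where only A differs: (0,1) vs (1,1)
  pa <- base_profile(dedup_sequences("CA", U = 1))
  pb <- base_profile(dedup_sequences("AA", U = 1))
  per_a <- profile_distance(pa, pb)$per_base
  expect_equal(per_a$mse[per_a$base == "A"], 0.5)
  expect_equal(per_a$euclidean[per_a$base == "A"], 1.0)

  p_short <- base_profile(dedup_sequences("ACG", U = 1))
  expect_error(profile_distance(p, p_short), "different position ranges")
})

test_that("profile correlation is 1 on itself and lower on reversed profiles", {
  set.seed(111)
  seqs <- vapply(1:50, function(i)
    paste(c(sample(c("A", "T"), 10, TRUE, prob = c(0.8, 0.2)),
            sample(c("G", "C"), 10, TRUE)), collapse = ""), character(1))
  p <- base_profile(dedup_sequences(seqs, U = 10))
  self <- profile_correlation(p, p)
  expect_true(all(self$per_base[!is.na(self$per_base)] == 1))
  expect_equal(self$pooled, 1)
  q <- p
  q[, c("A", "T", "G", "C")] <- q[rev(seq_len(nrow(q))), c("A", "T", "G", "C")]
  rev_cor <- profile_correlation(p, q)
  expect_lt(rev_cor$pooled, 1)
})

test_that("identical upstream, divergent downstream shows up per sub-window", {
  set.seed(121)
  upstream <- function() sample(c("A", "C", "G", "T"), 60, TRUE,
                                prob = c(0.4, 0.1, 0.1, 0.4))
  set1 <- vapply(1:200, function(i)
    paste(c(upstream(), sample(c("A", "C", "G", "T"), 60, TRUE,
                               prob = c(0.7, 0.1, 0.1, 0.1))),
          collapse = ""), character(1))
  set2 <- vapply(1:200, function(i)
    paste(c(upstream(), sample(c("A", "C", "G", "T"), 60, TRUE,
                               prob = c(0.1, 0.1, 0.7, 0.1))),
          collapse = ""), character(1))
  p1 <- base_profile(dedup_sequences(set1, U = 60))
  p2 <- base_profile(dedup_sequences(set2, U = 60))
  up <- profile_correlation(p1, p2, window = c(-60, 0))
  down <- profile_correlation(p1, p2, window = c(0, 60))
  expect_gt(up$pooled, down$pooled)
})

test_that("motif window export writes one FASTA per window and set", {
  set.seed(131)
  g <- c(chr = paste(sample(c("A", "C", "G", "T"), 5000, TRUE),
                     collapse = ""))
  target <- data.frame(transcript_id = paste0("t", 1:5), chrom = "chr",
                       tss = seq(500, 2500, length.out = 5), strand = "+")
  backgr <- data.frame(transcript_id = paste0("b", 1:7), chrom = "chr",
                       tss = seq(600, 4000, length.out = 7),
                       strand = rep(c("+", "-"), length.out = 7))
  dir <- withr::local_tempdir()
  res <- export_motif_windows(g, target, backgr, dir)
  expect_equal(nrow(res), 6L)  # 3 windows x 2 sets
  up300 <- res[res$window == "upstream300", ]
  expect_equal(up300$n_records, c(5L, 7L))
  for (f in res$file) expect_true(file.exists(f))
  # record counts equal unique-sequence counts after dedup
  fa <- read_fasta(res$file[1])
  expect_equal(length(fa), res$n_records[1])
  expect_equal(unique(nchar(fa)), 300L)
})
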