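#' Seeded synthetic expression atlas with planted enriched transcripts
#'
#' Emulates a bulk per-tissue expression atlas. Background transcripts get
#' a log-normal baseline abundance (right-skewed across transcripts, as
#' FPKM/TPM data are) modulated by modest multiplicative tissue noise; a
#' small fraction are "tissue-private" — detected in exactly one tissue —
#' as in real atlases, where they anchor the top of each tissue's
#' specificity scale. Planted enriched transcripts have their target-tissue
#' expression multiplied by `fold`. Transcript-to-gene structure and exon
#' counts are drawn from configurable distributions (defaults: mean 3.4
#' transcripts/gene "human-like"; use ~2.2 for a fly-like atlas).
#'
#' @param n_transcripts Number of transcripts.
#' @param tissues Character vector of tissue names (>= 2), or an integer
#'   count (names are generated).
#' @param plan Data frame with columns `tissue`, `n`, `fold`: how many
#'   transcripts to plant per tissue and their fold elevation (`fold = 1`
#'   plants nothing effective — a null run).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline abundance
#'   parameters (defaults 2 and 1.5: medians ~7 FPKM spanning several
#'   orders of magnitude).
#' @param tissue_cv Coefficient of variation of the multiplicative tissue
#'   noise (default 0.2).
#' @param private_fraction Fraction of background transcripts expressed in
#'   exactly one tissue (default 0.004), assigned round-robin so every
#'   tissue receives some.
#' @param tx_per_gene Mean transcripts per gene (default 3.4).
#' @param exon_mean Mean exon count (default 5).
#' @param noncoding_fraction Fraction of transcripts labelled noncoding
#'   (default 0.2).
#' @param species Species tag.
#' @param seed Integer seed; identical seeds reproduce identical output.
#' @return List with `expr` (an [ExpressionMatrix]) and `truth` (planted
#'   transcript ids per tissue, private ids, and the parameters used).
#' @export
gen_expression <- function(n_transcripts = 2000, tissues = 17, plan = NULL,
                           baseline_meanlog = 2, baseline_sdlog = 1.5,
                           tissue_cv = 0.2, private_fraction = 0.004,
                           tx_per_gene = 3.4, exon_mean = 5,
                           noncoding_fraction = 0.2,
                           species = "synthetic", seed = 1) {
  if (is.numeric(tissues) && length(tissues) == 1L)
    tissues <- sprintf("tissue%02d", seq_len(tissues))
  n_tis <- length(tissues)
  if (n_tis < 2L) stop("need at least 2 tissues")
  if (!is.null(plan)) {
    plan <- as.data.frame(plan)
    stopifnot(all(c("tissue", "n", "fold") %in% names(plan)))
    if (any(!plan$tissue %in% tissues)) stop("plan names an unknown tissue")
    if (any(plan$fold < 1)) stop("fold must be >= 1")
    if (sum(plan$n) > n_transcripts)
      stop("planted count exceeds n_transcripts")
  }
  with_seed(seed, {
    ids <- sprintf("%s_tx%05d", substr(species, 1, 3), seq_len(n_transcripts))
    baseline <- stats::rlnorm(n_transcripts, baseline_meanlog, baseline_sdlog)
    E <- baseline * pmax(matrix(1 + tissue_cv *
                                  stats::rnorm(n_transcripts * n_tis),
                                n_transcripts, n_tis), 0)
    dimnames(E) <- list(ids, tissues)

    # tissue-private transcripts: detected in exactly one tissue
    n_priv <- round(private_fraction * n_transcripts)
    priv_rows <- integer(0)
    if (n_priv > 0) {
      priv_cols <- rep(sample(n_tis), length.out = n_priv)
      priv_rows <- sample(n_transcripts, n_priv)
      for (k in seq_len(n_priv)) {
        E[priv_rows[k], ] <- 0
        E[priv_rows[k], priv_cols[k]] <- baseline[priv_rows[k]]
      }
    }

    # planted enrichment
    planted <- list()
    if (!is.null(plan) && nrow(plan)) {
      avail <- setdiff(seq_len(n_transcripts), priv_rows)
      for (k in seq_len(nrow(plan))) {
        take <- sample(avail, plan$n[k])
        avail <- setdiff(avail, take)
        E[take, plan$tissue[k]] <-
          pmax(E[take, plan$tissue[k]], 1e-3) * plan$fold[k]
        planted[[plan$tissue[k]]] <- ids[take]
      }
    }

    # transcript -> gene structure
    sizes <- 1L + stats::rpois(n_transcripts, tx_per_gene - 1)
    sizes <- sizes[cumsum(sizes) - sizes < n_transcripts]
    if (sum(sizes) < n_transcripts)
      sizes <- c(sizes, n_transcripts - sum(sizes))
    sizes[length(sizes)] <- n_transcripts - sum(sizes[-length(sizes)])
    gene_ids <- rep(sprintf("%s_g%05d", substr(species, 1, 3),
                            seq_along(sizes)), sizes)
    meta <- data.frame(
      transcript_id = ids,
      gene_id = gene_ids,
      exon_count = 1L + stats::rpois(n_transcripts, exon_mean - 1),
      biotype = ifelse(stats::runif(n_transcripts) < noncoding_fraction,
                       "noncoding", "coding"),
      stringsAsFactors = FALSE
    )
    expr <- ExpressionMatrix(E, meta, species = species)
    truth <- list(planted = planted, private = ids[priv_rows],
                  seed = seed,
                  params = list(tissue_cv = tissue_cv,
                                private_fraction = private_fraction,
                                baseline_meanlog = baseline_meanlog,
                                baseline_sdlog = baseline_sdlog))
    list(expr = expr, truth = truth)
  })
}

#' Seeded synthetic genome and annotation with planted promoter signals
#'
#' Generates an i.i.d.-background contig (configurable GC content) and
#' regularly spaced transcripts, roughly half on the minus strand. Around
#' each signal-bearing TSS, three composition signals are planted *on the
#' transcript strand* (reverse-complemented into the genome for minus
#' transcripts): a GC rise over [-100, 0), an A/T excess centered at -25
#' (width +/- 5), and a downstream T/G excess over [0, `downstream_len`).
#' A null spec (all excesses 0) yields a flat profile.
#'
#' @param n_transcripts Number of transcripts (default 500).
#' @param spacing Bases between consecutive TSSs (default 1500).
#' @param margin Contig margin before the first and after the last TSS
#'   (default 6000, enough for 5 kb windows).
#' @param gc Background GC fraction (default 0.41).
#' @param signal List with `gc_rise`, `at_peak`, `tg_excess` (probability
#'   excesses, defaults 0.15/0.20/0.10), `at_center` (-25), `at_halfwidth`
#'   (5) and `downstream_len` (100).
#' @param signal_fraction Fraction of transcripts carrying the signal
#'   (default 1); the rest are background-only.
#' @param signal_ids Optional explicit transcript ids that carry the
#'   signal (overrides `signal_fraction`).
#' @param ids Optional transcript ids (length `n_transcripts`); generated
#'   otherwise.
#' @param biotypes Optional biotype per transcript; default all coding.
#' @param gene_ids Optional gene id per transcript; default one gene per
#'   transcript.
#' @param chrom Contig name (default `"chrS"`).
#' @param tx_len Transcript length in bases (default 1000).
#' @param seed Integer seed.
#' @return List with `genome` (named character), `annotation`
#'   (`transcript_annotation` data frame) and `truth` (signal-bearing ids
#'   and the signal parameters).
#' @export
gen_genome_annotation <- function(n_transcripts = 500, spacing = 1500,
                                  margin = 6000, gc = 0.41,
                                  signal = list(), signal_fraction = 1,
                                  signal_ids = NULL,
                                  ids = NULL, biotypes = NULL,
                                  gene_ids = NULL, chrom = "chrS",
                                  tx_len = 1000, seed = 1) {
  sig <- utils::modifyList(
    list(gc_rise = 0.15, at_peak = 0.20, tg_excess = 0.10,
         at_center = -25, at_halfwidth = 5, downstream_len = 100), signal)
  if (is.null(ids))
    ids <- sprintf("syn_tx%05d", seq_len(n_transcripts))
  stopifnot(length(ids) == n_transcripts)
  if (is.null(biotypes)) biotypes <- rep("coding", n_transcripts)
  if (is.null(gene_ids)) gene_ids <- sub("_tx", "_g", ids)
  contig_len <- 2L * margin + spacing * n_transcripts + tx_len
  bases <- c("A", "C", "G", "T")
  bg_prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

  with_seed(seed, {
    seq_vec <- sample(bases, contig_len, replace = TRUE, prob = bg_prob)
    strand <- rep_len(c("+", "-"), n_transcripts)[sample(n_transcripts)]
    tss <- margin + spacing * (seq_len(n_transcripts) - 1L)  # 0-based
    carries <- if (!is.null(signal_ids)) ids %in% signal_ids
               else stats::runif(n_transcripts) < signal_fraction

    # Offsets relative to the TSS in transcript coordinates; the adjusted
    # base probabilities per offset are shared by all signal carriers, so
    # bases are drawn per offset across carriers in one call.
    idx <- which(carries)
    if (length(idx)) {
      offs <- seq.int(min(-110L, sig$at_center - sig$at_halfwidth),
                      sig$downstream_len - 1L)
      pos_strand <- strand[idx] == "+"
      for (o in offs) {
        p <- bg_prob
        if (abs(o - sig$at_center) <= sig$at_halfwidth) {
          # AT peak: an excess over the background that interrupts the
          # GC-rich core promoter (TATA-like), so it overrides the rise
          p <- p + c(1, -1, -1, 1) * sig$at_peak / 2
        } else if (o >= -100L && o < 0L) {               # GC rise
          p <- p + c(-1, 1, 1, -1) * sig$gc_rise / 2
        }
        if (o >= 0L && o < sig$downstream_len)           # T/G skew
          p <- p + c(-1, -1, 1, 1) * sig$tg_excess / 2
        p <- pmax(p, 0.01); p <- p / sum(p)
        b <- sample(bases, length(idx), replace = TRUE, prob = p)
        pos <- ifelse(pos_strand, tss[idx] + o, tss[idx] - o)
        b[!pos_strand] <- chartr("ACGT", "TGCA", b[!pos_strand])
        seq_vec[pos + 1L] <- b
      }
    }
    genome <- stats::setNames(paste(seq_vec, collapse = ""), chrom)
    start <- ifelse(strand == "+", tss, tss - tx_len + 1L)
    ann <- data.frame(transcript_id = ids, chrom = chrom,
                      start = start, end = start + tx_len,
                      strand = strand, gene_id = gene_ids,
                      biotype = biotypes,
                      exon_count = 1L + stats::rpois(n_transcripts, 3),
                      stringsAsFactors = FALSE)
    class(ann) <- c("transcript_annotation", "data.frame")
    truth <- list(signal_ids = ids[carries], signal = sig, seed = seed,
                  tss = stats::setNames(ifelse(strand == "+", tss, tss), ids))
    list(genome = genome, annotation = ann, truth = truth)
  })
}

#' Seeded synthetic ortholog, interaction and disease tables
#'
#' Ortholog links pair a fraction of the two gene universes with integer
#' support scores in 1..15. Physical interaction edges per species follow
#' a sparse random background (mean degree ~3) plus designated hub nodes
#' wired to an exact number of distinct partners. A stated fraction of
#' species-A genes gets disease annotations.
#'
#' @param genes_a,genes_b Gene id vectors for species A and B.
#' @param ortholog_fraction Fraction of A genes given an ortholog
#'   (default 0.3).
#' @param score_probs Probability weights over scores 1..15 (default
#'   uniform).
#' @param hubs List `list(a = n, b = n, degree = k)`: number of hub genes
#'   per species and their exact physical degree (default 5 hubs of
#'   degree 25 in each species).
#' @param mean_degree Mean background physical degree (default 3).
#' @param disease_fraction Fraction of A genes with a disease annotation
#'   (default 0.3).
#' @param diseases Pool of disease term labels.
#' @param seed Integer seed.
#' @return List with `orthologs`, `physical` (named list per species) and
#'   `disease` pair tables, plus `truth` (hub gene ids per species).
#' @export
gen_links <- function(genes_a, genes_b, ortholog_fraction = 0.3,
                      score_probs = rep(1, 15),
                      hubs = list(a = 5, b = 5, degree = 25),
                      mean_degree = 3, disease_fraction = 0.3,
                      diseases = sprintf("disease_%02d", 1:20),
                      seed = 1) {
  with_seed(seed, {
    n_orth <- min(round(ortholog_fraction * length(genes_a)),
                  length(genes_b))
    orth <- data.frame(
      id_a = sample(genes_a, n_orth),
      id_b = sample(genes_b, n_orth),
      score = sample(seq_along(score_probs), n_orth, replace = TRUE,
                     prob = score_probs),
      kind = rep("ortholog", n_orth), stringsAsFactors = FALSE)
    class(orth) <- c("pair_table", "data.frame")

    gen_phys <- function(genes, n_hubs, hub_degree) {
      n_edges <- round(mean_degree * length(genes) / 2)
      a <- sample(genes, n_edges, replace = TRUE)
      b <- sample(genes, n_edges, replace = TRUE)
      keep <- a != b
      df <- data.frame(id_a = a[keep], id_b = b[keep],
                       stringsAsFactors = FALSE)
      hubs_ids <- character(0)
      if (n_hubs > 0) {
        if (length(genes) < n_hubs + hub_degree)
          stop("gene universe too small for ", n_hubs, " hub(s) of degree ",
               hub_degree)
        hubs_ids <- sample(genes, n_hubs)
        # drop background edges touching hubs, then wire each hub to an
        # exact number of distinct non-hub partners
        df <- df[!(df$id_a %in% hubs_ids | df$id_b %in% hubs_ids), ,
                 drop = FALSE]
        others <- setdiff(genes, hubs_ids)
        for (h in hubs_ids) {
          partners <- sample(others, hub_degree)
          df <- rbind(df, data.frame(id_a = h, id_b = partners,
                                     stringsAsFactors = FALSE))
        }
      }
      key <- ifelse(df$id_a < df$id_b, paste(df$id_a, df$id_b),
                    paste(df$id_b, df$id_a))
      df <- df[!duplicated(key), , drop = FALSE]
      df$score <- NA_integer_; df$kind <- "physical"
      rownames(df) <- NULL
      class(df) <- c("pair_table", "data.frame")
      list(table = df, hubs = hubs_ids)
    }
    pa <- gen_phys(genes_a, hubs$a, hubs$degree)
    pb <- gen_phys(genes_b, hubs$b, hubs$degree)

    n_dis <- round(disease_fraction * length(genes_a))
    dis_genes <- sample(genes_a, n_dis)
    dis <- data.frame(
      id_a = dis_genes,
      id_b = sample(diseases, n_dis, replace = TRUE),
      score = NA_integer_, kind = "disease", stringsAsFactors = FALSE)
    class(dis) <- c("pair_table", "data.frame")

    list(orthologs = orth,
         physical = list(a = pa$table, b = pb$table),
         disease = dis,
         truth = list(hubs_a = pa$hubs, hubs_b = pb$hubs, seed = seed))
  })
}

# Run `expr` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
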