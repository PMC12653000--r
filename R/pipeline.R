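#' Write a transcript annotation as GTF
#'
#' Emits one `transcript` feature per row plus `exon` features (the
#' transcript interval split into `exon_count` contiguous blocks), with
#' `gene_id`, `transcript_id` and `transcript_biotype` attributes.
#' Internal 0-based half-open coordinates are converted to GTF's 1-based
#' closed convention at this boundary.
#'
#' @param ann A `transcript_annotation` data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gtf <- function(ann, path) {
  lines <- character(0)
  for (i in seq_len(nrow(ann))) {
    attrs <- sprintf(
      'gene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
      ann$gene_id[i], ann$transcript_id[i],
      ifelse(is.na(ann$biotype[i]), "coding", ann$biotype[i]))
    tx_line <- paste(ann$chrom[i], "tisspec", "transcript",
                     as.integer(ann$start[i]) + 1L, as.integer(ann$end[i]),
                     ".", ann$strand[i], ".", attrs, sep = "\t")
    k <- max(1L, ann$exon_count[i])
    bounds <- as.integer(round(seq(ann$start[i], ann$end[i],
                                   length.out = k + 1L)))
    exon_lines <- vapply(seq_len(k), function(e)
      paste(ann$chrom[i], "tisspec", "exon", bounds[e] + 1L, bounds[e + 1L],
            ".", ann$strand[i], ".", attrs, sep = "\t"), character(1))
    lines <- c(lines, tx_line, exon_lines)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a complete synthetic input fixture to a directory
#'
#' Produces every file the pipeline ingests, for a two-species design
#' mirroring the study layout: a 33-tissue "human-like" atlas and a
#' 17-tissue "fly-like" atlas sharing the focal tissues brain, adipose and
#' testis, with planted tissue-enriched transcripts (fold 100, most in the
#' testis), genomes with promoter composition signals planted at the TSSs
#' of the enriched transcripts, ortholog links with integer support
#' scores, physical interactions with designated hubs, and disease
#' annotations. Ground truth is written as `truth.json`.
#'
#' @param dir Output directory (created).
#' @param seed Integer seed driving every generator.
#' @param n_transcripts Transcripts per species (default 2000).
#' @param n_genome_transcripts Transcripts whose promoters enter the
#'   synthetic genome (default 500 per species, sampled to include all
#'   planted ones).
#' @param U,D Flank window the genome must accommodate (default 5000).
#' @return Named list of the file paths written, invisibly.
#' @export
write_fixture <- function(dir, seed = 1, n_transcripts = 2000,
                          n_genome_transcripts = 500, U = 5000, D = 5000) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  focal <- c("brain", "adipose", "testis")
  sp <- list(
    a = list(name = "human_like", tissues = c(focal,
             sprintf("h_tissue%02d", 4:33)), tx_per_gene = 3.4,
             plan = data.frame(tissue = focal, n = c(30, 10, 60),
                               fold = 100)),
    b = list(name = "fly_like", tissues = c(focal,
             sprintf("f_tissue%02d", 4:17)), tx_per_gene = 2.2,
             plan = data.frame(tissue = focal, n = c(15, 8, 50),
                               fold = 100))
  )
  files <- list()
  truth <- list(seed = seed)
  for (key in names(sp)) {
    s <- sp[[key]]
    gexp <- gen_expression(n_transcripts = n_transcripts,
                           tissues = s$tissues, plan = s$plan,
                           tx_per_gene = s$tx_per_gene,
                           species = s$name, seed = seed + match(key, names(sp)))
    expr <- gexp$expr
    tab <- data.frame(transcript_id = transcript_ids(expr),
                      gene_id = expr$meta$gene_id,
                      exon_count = expr$meta$exon_count,
                      biotype = expr$meta$biotype,
                      stringsAsFactors = FALSE)
    tab <- cbind(tab, as.data.frame(expr$values))
    f_expr <- file.path(dir, paste0("expression_", key, ".tsv"))
    utils::write.table(tab, f_expr, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    # genome over a subset of transcripts, always covering planted ones
    planted_ids <- unique(unlist(gexp$truth$planted))
    pool <- setdiff(transcript_ids(expr), planted_ids)
    extra <- with_seed(seed + 10 + match(key, names(sp)),
                       sample(pool, max(0, n_genome_transcripts -
                                          length(planted_ids))))
    gids <- c(planted_ids, extra)
    gann <- gen_genome_annotation(
      n_transcripts = length(gids), margin = max(U, D) + 1000,
      ids = gids,
      biotypes = expr$meta$biotype[match(gids, expr$meta$transcript_id)],
      gene_ids = expr$meta$gene_id[match(gids, expr$meta$transcript_id)],
      chrom = paste0("chr_", key),
      signal_ids = planted_ids,
      seed = seed + 20 + match(key, names(sp)))
    f_fa <- file.path(dir, paste0("genome_", key, ".fa"))
    f_gtf <- file.path(dir, paste0("annotation_", key, ".gtf"))
    write_fasta(gann$genome, f_fa)
    write_gtf(gann$annotation, f_gtf)
    files[[paste0("expression_", key)]] <- f_expr
    files[[paste0("genome_", key)]] <- f_fa
    files[[paste0("annotation_", key)]] <- f_gtf
    truth[[paste0("planted_", key)]] <- gexp$truth$planted
    truth[[paste0("signal_", key)]] <- gann$truth$signal_ids
  }

  genes_a <- unique(utils::read.delim(files$expression_a)$gene_id)
  genes_b <- unique(utils::read.delim(files$expression_b)$gene_id)
  links <- gen_links(genes_a, genes_b, seed = seed + 40)
  f_orth <- file.path(dir, "orthologs.tsv")
  utils::write.table(links$orthologs[c("id_a", "id_b", "score")], f_orth,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (key in c("a", "b")) {
    f_phys <- file.path(dir, paste0("physical_", key, ".tsv"))
    utils::write.table(links$physical[[key]][c("id_a", "id_b")], f_phys,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files[[paste0("physical_", key)]] <- f_phys
  }
  f_dis <- file.path(dir, "disease.tsv")
  utils::write.table(links$disease[c("id_a", "id_b")], f_dis, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files$orthologs <- f_orth
  files$disease <- f_dis
  truth$hubs_a <- links$truth$hubs_a
  truth$hubs_b <- links$truth$hubs_b
  f_truth <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, f_truth, auto_unbox = TRUE, pretty = TRUE)
  files$truth <- f_truth
  invisible(files)
}

#' Default run configuration
#'
#' All analysis constants surfaced as named keys with their standard
#' defaults: category boundaries (-0.20 / 0.00 / 0.80), the
#' highly-enriched cut (0.8), the ortholog-support cutoff (12), the hub
#' degree filter (20), the low-expression filter (5), and the TSS window
#' sizes.
#'
#' @param fixture_dir Directory holding the input files (layout of
#'   [write_fixture()]).
#' @param out_dir Output directory.
#' @param ... Overrides merged over the defaults.
#' @return Config list of class `run_config`.
#' @export
default_run_config <- function(fixture_dir, out_dir, ...) {
  cfg <- list(
    inputs = list(
      expression_a = file.path(fixture_dir, "expression_a.tsv"),
      expression_b = file.path(fixture_dir, "expression_b.tsv"),
      annotation_a = file.path(fixture_dir, "annotation_a.gtf"),
      annotation_b = file.path(fixture_dir, "annotation_b.gtf"),
      genome_a = file.path(fixture_dir, "genome_a.fa"),
      genome_b = file.path(fixture_dir, "genome_b.fa"),
      physical_a = file.path(fixture_dir, "physical_a.tsv"),
      physical_b = file.path(fixture_dir, "physical_b.tsv"),
      orthologs = file.path(fixture_dir, "orthologs.tsv"),
      disease = file.path(fixture_dir, "disease.tsv")
    ),
    species_names = c(a = "human_like", b = "fly_like"),
    focal_tissues = c("brain", "adipose", "testis"),
    thresholds = list(under_max = -0.20, general_max = 0.00,
                      enriched_max = 0.80, highly_enriched = 0.80,
                      ortholog_min_score = 12, hub_min_degree = 20,
                      expression_min = 5),
    windows = list(U = 5000, D = 5000, min_noncoding = 50),
    out_dir = out_dir,
    seed = 1
  )
  utils::modifyList(cfg, list(...))
}

#' Load a run configuration from a YAML file
#'
#' Keys follow [default_run_config()]; missing keys take the defaults.
#' Relative input paths are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return Config list of class `run_config`.
#' @export
load_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  cfg <- default_run_config(fixture_dir = base,
                            out_dir = file.path(base, "tisspec_out"))
  cfg <- utils::modifyList(cfg, user)
  cfg$inputs <- lapply(cfg$inputs, function(p)
    if (file.exists(p)) p else file.path(base, p))
  cfg
}

#' Run the full comparative tissue-specificity pipeline
#'
#' Orchestrates ingest, specificity, categorization, cohort statistics,
#' cross-species orthology, network construction and TSS composition
#' profiling, writing TSV/GraphML/FASTA outputs plus a JSON run manifest
#' into `config$out_dir`. All inputs are checked before any computation;
#' the run is deterministic for a given config.
#'
#' @param config A config list from [default_run_config()] or
#'   [load_run_config()].
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  missing_files <- unlist(config$inputs)[!file.exists(unlist(config$inputs))]
  if (length(missing_files))
    stop("missing input file(s): ", paste(missing_files, collapse = ", "))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  manifest <- list(tool = "tisspec",
                   version = as.character(utils::packageVersion("tisspec")),
                   seed = config$seed, stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  ## 1. ingest -------------------------------------------------------------
  expr <- list(a = read_expression_table(config$inputs$expression_a,
                                         species = config$species_names[["a"]]),
               b = read_expression_table(config$inputs$expression_b,
                                         species = config$species_names[["b"]]))
  ann <- list(a = read_annotation(config$inputs$annotation_a, "gtf"),
              b = read_annotation(config$inputs$annotation_b, "gtf"))
  genome <- list(a = read_fasta(config$inputs$genome_a),
                 b = read_fasta(config$inputs$genome_b))
  physical <- list(a = read_pair_table(config$inputs$physical_a, "physical"),
                   b = read_pair_table(config$inputs$physical_b, "physical"))
  orth_raw <- read_pair_table(config$inputs$orthologs, "ortholog")
  disease <- read_pair_table(config$inputs$disease, "disease")
  note("ingest",
       n_transcripts = vapply(expr, function(e) nrow(e$values), 0),
       n_tissues = vapply(expr, function(e) ncol(e$values), 0),
       n_ortholog_links = nrow(orth_raw))

  ## 2. specificity --------------------------------------------------------
  thresholds <- category_thresholds(th$under_max, th$general_max,
                                    th$enriched_max)
  spec <- lapply(expr, specificity)
  assign <- lapply(spec, assign_categories, thresholds = thresholds)
  for (key in names(spec))
    export_specificity_table(spec[[key]], expr[[key]], assign[[key]],
                             file.path(out, paste0("specificity_", key,
                                                   ".tsv")))
  enriched_counts <- lapply(names(spec), function(key)
    vapply(config$focal_tissues, function(tis)
      count_enriched(spec[[key]], tis, th$highly_enriched)$count, 0))
  names(enriched_counts) <- names(spec)
  note("specificity", enriched_per_focal_tissue = enriched_counts)

  ## 3. cohort statistics --------------------------------------------------
  welch_rows <- list()
  for (key in names(spec)) for (tis in config$focal_tissues) {
    gs <- group_summary(assign[[key]], expr[[key]], tis)
    utils::write.table(gs, file.path(out, sprintf("group_summary_%s_%s.tsv",
                                                  key, tis)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pw <- pairwise_welch(expr[[key]]$values[, tis], assign[[key]][, tis])
    pw$species <- key; pw$tissue <- tis
    welch_rows[[paste(key, tis)]] <- pw
  }
  welch_all <- do.call(rbind, welch_rows)
  utils::write.table(welch_all, file.path(out, "welch_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (key in names(spec)) {
    feats <- c(list(maxexp = apply(expr[[key]]$values, 1, max),
                    exon = expr[[key]]$meta$exon_count),
               stats::setNames(lapply(config$focal_tissues, function(tis)
                 spec[[key]]$normalized[, tis]),
                 paste0(config$focal_tissues, "_spec")))
    cm <- correlation_matrix(feats, method = "spearman")
    utils::write.table(round(cm$r, 4),
                       file.path(out, paste0("correlations_", key, ".tsv")),
                       sep = "\t", quote = FALSE)
  }
  note("cohort_stats", n_welch_tests = nrow(welch_all))

  ## 4. orthology ----------------------------------------------------------
  orth <- filter_orthologs(orth_raw, th$ortholog_min_score)
  he_sets <- lapply(names(spec), function(key)
    highly_enriched_gene_sets(assign[[key]], expr[[key]]$meta))
  names(he_sets) <- names(spec)
  joined <- list()
  for (tis in config$focal_tissues) {
    sa <- gene_tissue_summary(expr$a, spec$a, tis)
    sb <- gene_tissue_summary(expr$b, spec$b, tis)
    joined[[tis]] <- join_cross_species(sa, sb, orth)
    utils::write.table(joined[[tis]],
                       file.path(out, paste0("ortholog_joined_", tis, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  venns <- lapply(names(spec), function(key)
    venn_overlap(he_sets[[key]][config$focal_tissues]))
  names(venns) <- names(spec)
  disease_sums <- lapply(config$focal_tissues, function(tis) {
    genes <- intersect(he_sets$a[[tis]], orth$id_a)
    disease_summary(genes, disease)
  })
  names(disease_sums) <- config$focal_tissues
  dis_tab <- data.frame(tissue = config$focal_tissues,
                        set_size = vapply(disease_sums, `[[`, 0, "size"),
                        n_associated = vapply(disease_sums, `[[`, 0,
                                              "n_associated"),
                        percent = vapply(disease_sums, `[[`, 0, "percent"))
  utils::write.table(dis_tab, file.path(out, "disease_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("orthology", n_links_filtered = nrow(orth),
       venn_counts = lapply(venns, `[[`, "counts"),
       disease_percent = stats::setNames(dis_tab$percent, dis_tab$tissue))

  ## 5. network ------------------------------------------------------------
  gene_sets <- list()
  gene_sets[[config$species_names[["a"]]]] <-
    he_sets$a[config$focal_tissues]
  gene_sets[[config$species_names[["b"]]]] <-
    he_sets$b[config$focal_tissues]
  names(physical) <- config$species_names[c("a", "b")]
  net <- build_network(gene_sets, physical, orth)
  cent <- centrality(net)
  utils::write.table(cent, file.path(out, "centrality.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  hubs <- filter_hubs(net, cent, th$hub_min_degree)
  export_network(net, file.path(out, "network"), cent)
  export_network(hubs, file.path(out, "network_hubs"))
  subnet_counts <- lapply(config$focal_tissues, function(tis)
    igraph::vcount(ortholog_pair_subnetwork(net, tis)))
  names(subnet_counts) <- config$focal_tissues
  note("network", n_nodes = igraph::vcount(net),
       n_edges = igraph::ecount(net), n_hubs = igraph::vcount(hubs),
       ortholog_subnetwork_nodes = subnet_counts)

  ## 6. TSS profiles -------------------------------------------------------
  U <- config$windows$U; D <- config$windows$D
  profile_stats <- list()
  for (key in names(spec)) {
    tss <- tss_coordinates(ann[[key]])
    ctrl_ids <- control_set(spec[[key]], th$highly_enriched)
    focal1 <- config$focal_tissues[1]
    for (tis in config$focal_tissues) {
      he_tx <- rownames(assign[[key]])[assign[[key]][, tis] ==
                                         "highly_enriched"]
      target <- tss[tss$transcript_id %in% he_tx, , drop = FALSE]
      backgr <- tss[tss$transcript_id %in% ctrl_ids, , drop = FALSE]
      if (nrow(target) == 0L || nrow(backgr) == 0L) next
      fl_t <- dedup_sequences(extract_flank(genome[[key]], target$chrom,
                                            target$tss, target$strand,
                                            U, D), U = U, D = D)
      fl_b <- dedup_sequences(extract_flank(genome[[key]], backgr$chrom,
                                            backgr$tss, backgr$strand,
                                            U, D), U = U, D = D)
      prof_t <- base_profile(fl_t)
      prof_b <- base_profile(fl_b)
      write_profile_tsv(prof_t, file.path(out,
        sprintf("profile_%s_%s_target.tsv", key, tis)))
      write_profile_tsv(prof_b, file.path(out,
        sprintf("profile_%s_%s_control.tsv", key, tis)))
      pd <- profile_distance(prof_t, prof_b)
      profile_stats[[paste(key, tis)]] <- data.frame(
        species = key, tissue = tis,
        n_target = length(fl_t$sequences),
        n_control = length(fl_b$sequences),
        mse = pd$mse, euclidean = pd$euclidean)
      if (tis == focal1)
        export_motif_windows(genome[[key]], target, backgr,
                             file.path(out, paste0("motif_windows_", key)))
    }
  }
  ps <- do.call(rbind, profile_stats)
  if (!is.null(ps))
    utils::write.table(ps, file.path(out, "profile_distances.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  note("tss_profile",
       comparisons = if (is.null(ps)) 0L else nrow(ps))

  ## 7. manifest -----------------------------------------------------------
  cfg_path <- file.path(out, "run_config.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  manifest$n_stages <- length(manifest$stages)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Human-readable summary of a completed run
#'
#' Reads the manifest of a [run_pipeline()] output directory and prints
#' per-stage counts: category partitions per focal tissue, Venn counts,
#' disease percentages, hub counts and profile comparisons.
#'
#' @param out_dir A pipeline output directory containing `manifest.json`.
#' @return The manifest list, invisibly.
#' @export
report_summary <- function(out_dir) {
  mf_path <- file.path(out_dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", out_dir)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  cat("tisspec run (", mf$n_stages, " stages)\n", sep = "")
  for (stage in names(mf$stages)) {
    cat("--", stage, "\n")
    utils::str(mf$stages[[stage]], give.attr = FALSE, comp.str = "   ")
  }
  spec_files <- list.files(out_dir, "^specificity_.\\.tsv$",
                           full.names = TRUE)
  for (f in spec_files) {
    tab <- utils::read.delim(f)
    cat_cols <- grep("^category_", names(tab), value = TRUE)
    if (length(cat_cols)) {
      cat("-- category counts (", basename(f), ")\n", sep = "")
      for (cc in utils::head(cat_cols, 3))
        print(table(tab[[cc]]))
    }
  }
  invisible(mf)
}
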