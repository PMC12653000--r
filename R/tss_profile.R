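#' Transcription start sites from annotation coordinates
#'
#' The TSS is the genomic position of the transcript's first nucleotide on
#' its own strand: for `+` transcripts the annotation start, for `-`
#' transcripts the last base of the interval (`end - 1` in the internal
#' 0-based half-open convention).
#'
#' @param annotations A `transcript_annotation` data frame from
#'   [read_annotation()].
#' @return Data frame with `transcript_id`, `chrom`, `tss` (0-based),
#'   `strand` (plus `gene_id` and `biotype` carried through).
#' @export
tss_coordinates <- function(annotations) {
  if (any(!annotations$strand %in% c("+", "-")))
    stop("missing strand in annotation")
  data.frame(
    transcript_id = annotations$transcript_id,
    chrom = annotations$chrom,
    tss = ifelse(annotations$strand == "+", annotations$start,
                 annotations$end - 1L),
    strand = annotations$strand,
    gene_id = annotations$gene_id,
    biotype = annotations$biotype,
    stringsAsFactors = FALSE
  )
}

#' Extract a strand-oriented TSS flank
#'
#' Returns the sequence covering `U` bases upstream and `D` bases
#' downstream of the TSS *on the transcript strand*: for `-` strand
#' records the genomic slice is reverse-complemented, so "upstream" always
#' means 5' of the transcript. The result has length `U + D` with the TSS
#' base at index `U` (1-based position `U + 1`); positions falling off the
#' contig are filled with `N`.
#'
#' @param genome Named character vector from [read_fasta()].
#' @param chrom,tss,strand TSS record fields (vectorized; recycled to a
#'   common length).
#' @param U,D Upstream/downstream window lengths in bases.
#' @return Character vector of sequences of length `U + D`.
#' @export
extract_flank <- function(genome, chrom, tss, strand, U, D) {
  n <- max(length(chrom), length(tss), length(strand))
  chrom <- rep_len(chrom, n); tss <- rep_len(tss, n)
  strand <- rep_len(strand, n)
  missing_chrom <- setdiff(unique(chrom), names(genome))
  if (length(missing_chrom))
    stop("chromosome(s) absent from genome: ",
         paste(missing_chrom, collapse = ", "))
  # genomic slice [lo, hi) in 0-based half-open coordinates
  lo <- ifelse(strand == "+", tss - U, tss - D + 1L)
  hi <- lo + U + D
  out <- character(n)
  for (i in seq_len(n)) {
    len <- nchar(genome[[chrom[i]]])
    a <- max(lo[i], 0L); b <- min(hi[i], len)
    core <- if (b > a) substr(genome[[chrom[i]]], a + 1L, b) else ""
    seqi <- paste0(strrep("N", max(0L, -lo[i])), core,
                   strrep("N", max(0L, hi[i] - len)))
    out[i] <- seqi
  }
  neg <- strand == "-"
  if (any(neg))
    out[neg] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(out[neg])))
  out
}

#' Deduplicate equal-length flank sequences
#'
#' Exact string deduplication after uppercasing, preserving first-seen
#' order; the number of input records collapsed into each unique sequence
#' is recorded. Identical annotated TSSs of transcript variants collapse
#' automatically.
#'
#' @param seqs Character vector of equal-length sequences (optionally
#'   named by transcript).
#' @param U,D Window lengths stored on the result for downstream position
#'   labelling.
#' @return List of class `flank_set`: `sequences`, `counts`, `U`, `D`.
#' @export
dedup_sequences <- function(seqs, U = NULL, D = NULL) {
  if (length(seqs) && length(unique(nchar(seqs))) > 1L)
    stop("sequences have mixed lengths")
  up <- toupper(seqs)
  first <- !duplicated(up)
  uniq <- up[first]
  counts <- as.integer(table(factor(up, levels = uniq)))
  if (is.null(U)) U <- 0L
  if (is.null(D)) D <- if (length(uniq)) nchar(uniq[1]) else 0L
  structure(list(sequences = unname(uniq), counts = counts,
                 U = as.integer(U), D = as.integer(D)),
            class = "flank_set")
}

#' Per-position ATGC frequency profile
#'
#' For each position of the aligned flank set, the frequency of A, T, G
#' and C among non-N observations (`N` bases are excluded from the
#' denominator, so contig-edge padding does not bias frequencies).
#' Positions range from `-U` to `D - 1`, position 0 being the TSS base.
#'
#' @param flanks A `flank_set` from [dedup_sequences()] (each unique
#'   sequence counts once).
#' @param smooth Odd window width for an optional centered moving average
#'   applied to the frequency columns (1 = none), for plotting parity only.
#' @return Data frame of class `base_profile`: `position`, `A`, `T`, `G`,
#'   `C` (frequencies, `NA` where only N was observed), `n_obs`.
#' @export
base_profile <- function(flanks, smooth = 1L) {
  stopifnot(inherits(flanks, "flank_set"))
  if (length(flanks$sequences) == 0L) stop("empty flank set")
  L <- nchar(flanks$sequences[1])
  mat <- matrix(unlist(strsplit(flanks$sequences, "", fixed = TRUE)),
                nrow = length(flanks$sequences), byrow = TRUE)
  n_obs <- colSums(mat != "N")
  freq <- sapply(c("A", "T", "G", "C"), function(b)
    ifelse(n_obs > 0, colSums(mat == b) / pmax(n_obs, 1L), NA_real_))
  if (L == 1L) freq <- matrix(freq, nrow = 1,
                              dimnames = list(NULL, c("A", "T", "G", "C")))
  out <- data.frame(position = seq.int(-flanks$U, length.out = L),
                    freq, n_obs = n_obs)
  if (smooth > 1L) {
    if (smooth %% 2L == 0L) stop("`smooth` must be odd")
    k <- rep(1 / smooth, smooth)
    for (b in c("A", "T", "G", "C"))
      out[[b]] <- as.numeric(stats::filter(out[[b]], k, sides = 2))
  }
  class(out) <- c("base_profile", "data.frame")
  out
}

#' Transcripts never highly enriched anywhere (control set)
#'
#' The comparison background for composition and motif analyses:
#' transcripts whose maximum normalized specificity stays at or below the
#' threshold in every tissue of their species. Call once per species.
#'
#' @param spec A normalized `SpecificityMatrix` for one species.
#' @param threshold Highly-enriched cut (default 0.8).
#' @return Character vector of transcript ids.
#' @export
control_set <- function(spec, threshold = 0.8) {
  N <- need_normalized(spec)
  spec$transcript_ids[apply(N, 1, max) <= threshold]
}

#' Partition non-coding transcripts by tissue enrichment
#'
#' Splits `biotype == "noncoding"` transcripts into those whose gene is in
#' the tissue's highly-enriched set and all others. Sets smaller than
#' `min_set_size` are flagged as not profiled (too few sequences for a
#' stable composition estimate).
#'
#' @param annotations A `transcript_annotation` data frame.
#' @param enriched_genes Character vector of the tissue's highly-enriched
#'   genes.
#' @param min_set_size Minimum set size to profile (default 50).
#' @return List with elements `enriched` and `other`, each a list of
#'   `transcript_id`s and a logical `profiled` flag.
#' @export
select_noncoding <- function(annotations, enriched_genes, min_set_size = 50) {
  nc <- annotations[!is.na(annotations$biotype) &
                    annotations$biotype == "noncoding", , drop = FALSE]
  in_set <- nc$gene_id %in% enriched_genes
  part <- function(ids) list(
    transcript_id = ids,
    profiled = length(ids) >= min_set_size,
    note = if (length(ids) >= min_set_size) "ok"
           else sprintf("only %d sequences (< %d); not profiled",
                        length(ids), min_set_size))
  list(enriched = part(nc$transcript_id[in_set]),
       other = part(nc$transcript_id[!in_set]))
}

#' Distance between two base profiles
#'
#' Mean squared error and Euclidean distance over the per-position
#' frequency vectors, per base and pooled across the four bases
#' (positions where either profile is undefined are skipped pairwise).
#'
#' @param p,q `base_profile`s over identical position ranges.
#' @return List with `per_base` (data frame: base, mse, euclidean) and
#'   pooled `mse` / `euclidean`.
#' @export
profile_distance <- function(p, q) {
  check_same_positions(p, q)
  per <- lapply(c("A", "T", "G", "C"), function(b) {
    ok <- !is.na(p[[b]]) & !is.na(q[[b]])
    d <- p[[b]][ok] - q[[b]][ok]
    data.frame(base = b, mse = mean(d^2), euclidean = sqrt(sum(d^2)),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  dall <- unlist(lapply(c("A", "T", "G", "C"), function(b) {
    ok <- !is.na(p[[b]]) & !is.na(q[[b]])
    p[[b]][ok] - q[[b]][ok]
  }))
  list(per_base = per, mse = mean(dall^2), euclidean = sqrt(sum(dall^2)))
}

#' Correlation between two base profiles over a sub-window
#'
#' One coefficient per base, computed across the positions of the selected
#' sub-window, plus a pooled coefficient over the concatenated four-base
#' vectors. Default sub-windows: `upstream` = [-5000, -500), `tss` =
#' [-500, 500), `full` = everything.
#'
#' @param p,q `base_profile`s over identical position ranges.
#' @param method `"pearson"` or `"spearman"`.
#' @param window `"full"`, `"upstream"` or `"tss"`, or a length-2 numeric
#'   `c(from, to)` half-open position range.
#' @param windows Named list defining the symbolic sub-windows.
#' @return List with `per_base` (named numeric, `NA` for constant
#'   vectors), `pooled`, and the `range` used.
#' @export
profile_correlation <- function(p, q, method = c("pearson", "spearman"),
                                window = "full",
                                windows = list(upstream = c(-5000, -500),
                                               tss = c(-500, 500))) {
  method <- match.arg(method)
  check_same_positions(p, q)
  rng <- if (is.numeric(window)) window
         else if (identical(window, "full")) range(p$position) + c(0, 1)
         else if (window %in% names(windows)) windows[[window]]
         else stop("unknown window: ", window)
  sel <- p$position >= rng[1] & p$position < rng[2]
  if (!any(sel)) stop("sub-window contains no positions")
  safe_cor <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(NA_real_)
    stats::cor(x[ok], y[ok], method = method)
  }
  per <- vapply(c("A", "T", "G", "C"), function(b)
    safe_cor(p[[b]][sel], q[[b]][sel]), numeric(1))
  pooled <- safe_cor(unlist(lapply(c("A", "T", "G", "C"),
                                   function(b) p[[b]][sel])),
                     unlist(lapply(c("A", "T", "G", "C"),
                                   function(b) q[[b]][sel])))
  list(per_base = per, pooled = pooled, range = rng)
}

check_same_positions <- function(p, q) {
  stopifnot(inherits(p, "base_profile"), inherits(q, "base_profile"))
  if (nrow(p) != nrow(q) || any(p$position != q$position))
    stop("profiles cover different position ranges")
}

#' Export core-promoter motif-analysis windows as FASTA
#'
#' For each requested window, extracts strand-aware flanks for the target
#' and background TSS sets, deduplicates, and writes one FASTA per set:
#' `<window>_target.fa` and `<window>_background.fa`. The background is
#' typically the [control_set()] sequences. Files are byte-stable, ready
#' for external motif-discovery tools.
#'
#' @param genome Named character vector from [read_fasta()].
#' @param target,background TSS record data frames
#'   (from [tss_coordinates()], possibly subset).
#' @param dir Output directory (created if needed).
#' @param windows Subset of `c("upstream300", "upstream100",
#'   "downstream100")`.
#' @return Data frame listing each file written and its record count.
#' @export
export_motif_windows <- function(genome, target, background, dir,
                                 windows = c("upstream300", "upstream100",
                                             "downstream100")) {
  specs <- list(upstream300 = c(U = 300L, D = 0L),
                upstream100 = c(U = 100L, D = 0L),
                downstream100 = c(U = 0L, D = 100L))
  windows <- match.arg(windows, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (w in windows) {
    U <- specs[[w]]["U"]; D <- specs[[w]]["D"]
    for (set in c("target", "background")) {
      recs <- if (set == "target") target else background
      seqs <- extract_flank(genome, recs$chrom, recs$tss, recs$strand, U, D)
      fl <- dedup_sequences(seqs, U = U, D = D)
      named <- stats::setNames(fl$sequences,
                               paste0(w, "_", set, "_", seq_along(fl$sequences)))
      path <- file.path(dir, paste0(w, "_", set, ".fa"))
      if (length(named)) write_fasta(named, path) else file.create(path)
      rows[[length(rows) + 1L]] <- data.frame(
        window = w, set = set, file = path, n_records = length(named),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write TSS records as a BED file
#'
#' Six-column BED (0-based half-open single-base intervals) of the TSS
#' positions, strand-aware.
#'
#' @param tss TSS record data frame from [tss_coordinates()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tss_bed <- function(tss, path) {
  bed <- data.frame(tss$chrom, tss$tss, tss$tss + 1L, tss$transcript_id,
                    0L, tss$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a base profile as TSV
#' @param profile A `base_profile`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
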