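#' Read a per-tissue expression table
#'
#' Reads a TSV with one transcript per row: an id column, optional metadata
#' columns (`gene_id`, `exon_count`, `biotype`), and one numeric column per
#' tissue (or per tissue replicate). Replicate columns belonging to the same
#' tissue are averaged at ingest, so downstream statistics always see one
#' column per tissue. Reading is gzip-transparent.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param replicate_groups Optional named list mapping a tissue name to the
#'   source column names that are arithmetic-averaged into it, e.g.
#'   `list(brain = c("brainA", "brainB"))`. Columns not mentioned are kept
#'   as single-replicate tissues under their own name.
#' @param id_col,gene_col Names of the transcript-id and gene-id columns.
#'   If `gene_col` is absent from the file the transcript id doubles as the
#'   gene id.
#' @param species Species tag stored on the returned object.
#' @param id_normalize Optional function applied to transcript ids at ingest
#'   (e.g. to strip `ENST....<version>` suffixes before joining to an
#'   annotation); identifiers must still be unique afterwards.
#'
#' @return An [ExpressionMatrix].
#' @export
read_expression_table <- function(path, replicate_groups = NULL,
                                  id_col = "transcript_id",
                                  gene_col = "gene_id",
                                  species = NA_character_,
                                  id_normalize = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!id_col %in% names(df)) stop("no id column '", id_col, "' in ", path)
  ids <- as.character(df[[id_col]])
  if (!is.null(id_normalize)) ids <- vapply(ids, id_normalize, character(1))
  if (anyDuplicated(ids))
    stop("duplicate transcript id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  meta_cols <- intersect(c(id_col, gene_col, "exon_count", "biotype"), names(df))
  expr_cols <- setdiff(names(df), meta_cols)
  if (length(expr_cols) < 2L) stop("fewer than 2 expression columns in ", path)

  vals <- as.matrix(df[expr_cols])
  if (!is.numeric(vals)) stop("non-numeric expression column in ", path)
  neg <- which(apply(vals < 0, 1, any, na.rm = TRUE))
  if (length(neg))
    stop("negative expression in ", path, " at data line(s): ",
         paste(neg + 1L, collapse = ", "))  # +1 for the header line
  if (anyNA(vals)) {
    message(sum(is.na(vals)), " missing expression cells in ", path,
            " treated as 0")
    vals[is.na(vals)] <- 0
  }

  if (!is.null(replicate_groups)) {
    unknown <- setdiff(unlist(replicate_groups), expr_cols)
    if (length(unknown))
      stop("replicate group refers to absent column(s): ",
           paste(unknown, collapse = ", "))
    grouped <- vapply(replicate_groups, function(cols)
      rowMeans(vals[, cols, drop = FALSE]), numeric(nrow(vals)))
    if (nrow(vals) == 1L) grouped <- matrix(grouped, nrow = 1,
                                            dimnames = list(NULL, names(replicate_groups)))
    rest <- setdiff(expr_cols, unlist(replicate_groups))
    vals <- cbind(grouped, vals[, rest, drop = FALSE])
  }
  rownames(vals) <- ids

  meta <- data.frame(
    transcript_id = ids,
    gene_id = if (gene_col %in% names(df)) as.character(df[[gene_col]]) else ids,
    exon_count = if ("exon_count" %in% names(df))
      as.integer(df$exon_count) else NA_integer_,
    biotype = if ("biotype" %in% names(df))
      as.character(df$biotype) else NA_character_,
    stringsAsFactors = FALSE
  )
  ExpressionMatrix(vals, meta, species = species)
}

#' Read a transcript annotation (GTF or BED)
#'
#' Coordinates are converted to the package-internal 0-based half-open
#' convention at the boundary: GTF is 1-based closed, BED already 0-based
#' half-open. For GTF, `exon_count` is the number of `exon` features per
#' transcript; for BED12 it is the block count (1 when blocks are absent).
#'
#' @param path GTF or BED file (gzip-transparent via rtracklayer).
#' @param dialect Either `"gtf"` or `"bed"`.
#' @return A data frame of class `transcript_annotation` with columns
#'   `transcript_id`, `chrom`, `start`, `end` (0-based half-open), `strand`,
#'   `gene_id`, `biotype`, `exon_count`.
#' @export
read_annotation <- function(path, dialect = c("gtf", "bed")) {
  dialect <- match.arg(dialect)
  gr <- rtracklayer::import(path, format = dialect)
  if (dialect == "gtf") {
    type <- as.character(gr$type)
    tx <- gr[type == "transcript"]
    if (length(tx) == 0L) stop("no transcript features in ", path)
    exon_tab <- table(gr$transcript_id[type == "exon"])
    ann <- data.frame(
      transcript_id = as.character(tx$transcript_id),
      chrom = as.character(GenomicRanges::seqnames(tx)),
      start = GenomicRanges::start(tx) - 1L,
      end = GenomicRanges::end(tx),
      strand = as.character(GenomicRanges::strand(tx)),
      gene_id = as.character(tx$gene_id),
      biotype = classify_biotype(tx),
      stringsAsFactors = FALSE
    )
    ann$exon_count <- as.integer(exon_tab[ann$transcript_id])
    ann$exon_count[is.na(ann$exon_count)] <- 1L
  } else {
    if (length(gr) == 0L) stop("no records in ", path)
    nm <- if (!is.null(gr$name)) as.character(gr$name)
          else paste0("bed_", seq_along(gr))
    ann <- data.frame(
      transcript_id = nm,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      gene_id = nm,
      biotype = NA_character_,
      exon_count = if (!is.null(gr$blocks))
        lengths(gr$blocks) else 1L,
      stringsAsFactors = FALSE
    )
  }
  if (any(ann$strand %in% c("*", ".")))
    stop("missing strand for transcript(s): ",
         paste(utils::head(ann$transcript_id[ann$strand %in% c("*", ".")], 5),
               collapse = ", "))
  if (any(ann$end <= ann$start))
    stop("empty interval (end <= start) for: ",
         paste(utils::head(ann$transcript_id[ann$end <= ann$start], 5),
               collapse = ", "))
  class(ann) <- c("transcript_annotation", "data.frame")
  ann
}

# Map free-text biotype attributes onto the coding/noncoding dichotomy.
classify_biotype <- function(tx) {
  raw <- if (!is.null(tx$transcript_biotype)) as.character(tx$transcript_biotype)
         else if (!is.null(tx$gene_biotype)) as.character(tx$gene_biotype)
         else rep(NA_character_, length(tx))
  ifelse(is.na(raw), NA_character_,
         ifelse(raw %in% c("coding", "protein_coding"), "coding", "noncoding"))
}

#' Read a genome FASTA into named uppercase sequences
#'
#' @param path FASTA file (gzip-transparent).
#' @return Named character vector, one uppercase sequence per chromosome.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in ", path)
  nm <- sub("\\s.*$", "", names(seqs))  # keep id up to first whitespace
  if (anyDuplicated(nm))
    stop("duplicate sequence name(s) in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  out <- toupper(as.character(seqs))
  names(out) <- nm
  out
}

#' Write sequences to a 60-column FASTA file
#'
#' Output is byte-stable for identical input, so exported motif-window files
#' can be diffed across runs.
#'
#' @param sequences Named character vector over the alphabet ACGTN.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    stop("all sequences must be named")
  if (anyDuplicated(names(sequences)))
    stop("duplicate sequence name(s): ",
         paste(unique(names(sequences)[duplicated(names(sequences))]),
               collapse = ", "))
  if (any(grepl("[^ACGTN]", sequences)))
    stop("sequences contain characters outside ACGTN")
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a two-column pair table (orthologs, physical interactions, diseases)
#'
#' @param path TSV with a header and at least two columns: the two
#'   identifiers, plus an integer `score` column for ortholog tables.
#' @param kind One of `"ortholog"` (requires a score column),
#'   `"physical"` (self-loops are dropped with a message), or `"disease"`
#'   (second column is a free-text disease term).
#' @return Data frame of class `pair_table` with columns `id_a`, `id_b`,
#'   `score` (NA unless ortholog) and `kind`.
#' @export
read_pair_table <- function(path, kind = c("ortholog", "physical", "disease")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("pair table needs at least 2 columns: ", path)
  out <- data.frame(id_a = as.character(df[[1]]), id_b = as.character(df[[2]]),
                    score = NA_integer_, kind = kind,
                    stringsAsFactors = FALSE)
  if (kind == "ortholog") {
    score_col <- if ("score" %in% names(df)) df$score else df[[3]]
    if (is.null(score_col)) stop("ortholog table needs a score column: ", path)
    if (any(is.na(suppressWarnings(as.numeric(score_col)))) ||
        any(as.numeric(score_col) != round(as.numeric(score_col))))
      stop("non-integer ortholog score in ", path)
    out$score <- as.integer(score_col)
  }
  if (kind == "physical") {
    self <- out$id_a == out$id_b
    if (any(self)) {
      message("dropped ", sum(self), " physical self-loop(s) from ", path)
      out <- out[!self, , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  class(out) <- c("pair_table", "data.frame")
  out
}
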